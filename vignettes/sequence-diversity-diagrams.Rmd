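---
title: "Sequence Diversity Diagrams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence Diversity Diagrams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqdivdiag)
```

## The problem

A sequence logo summarizes one multiple sequence alignment (MSA) well: per
column, letter height encodes information content, so conserved positions
stand out. It breaks down for the *comparative* task — contrasting two or
more sets of aligned sequences, such as two bacterial subfamilies of one
protein domain — because each set needs its own logo and the reader must scan
back and forth between figures. Logos also discard *sequential* conservation:
whether the residue at position i and the residue at position i+1 co-occur in
the same sequences is invisible, since every column is summarized
independently.

A Sequence Diversity Diagram addresses both gaps with a single figure.
Alignment positions run along the x-axis; residues, grouped into functional
classes (for proteins: aliphatic, aromatic, polar uncharged, positively
charged, negatively charged, and the special residues C, G, P), run down the
y-axis with a visible vertical gap between classes. On this fixed grid, each
sample is drawn as a set of Sankey-style ribbons: one ribbon per ordered
residue pair (a at position i, b at position i+1), with stroke width
proportional to the fraction of that sample's sequences carrying the pair.
Samples are overlaid in semi-transparent colors, so flows conserved in all
samples blend optically (the default red and blue read as purple where they
coincide) while subfamily-specific flows remain visibly separate.

## The quantities

For a sample of $N$ aligned sequences with $L$ columns:

- **Position frequencies.** $f_i(a) = n_i(a) / N$, the fraction of sequences
  carrying residue $a$ at column $i$. With the default gap policy, the gap
  symbol `-` is a row of its own, so $\sum_a n_i(a) = N$ at every column.
- **Transition (pair) frequencies.** $f_i(a, b) = n_i(a, b) / N$, the
  fraction of sequences carrying $a$ at column $i$ **and** $b$ at column
  $i+1$. This is the quantity a ribbon encodes. Each sequence contributes
  exactly one ordered pair per adjacent column pair, so
  $\sum_{a,b} n_i(a,b) = N$ and the marginals reproduce the position counts:
  $\sum_b n_i(a,b) = n_i(a)$, $\sum_a n_i(a,b) = n_{i+1}(b)$. These
  invariants are property-tested against a naive double-loop count.
- **Shannon entropy and information content.** Per column,
  $H_i = -\sum_a f_i(a)\,\log_2 f_i(a)$ bits, and the logo-style information
  content $R_i = \log_2 s - (H_i + e_n)$, clamped at zero, where $s$ is the
  alphabet size and $e_n = (s-1)/(2 \ln 2 \cdot n)$ is the optional
  small-sample correction. The diagram itself encodes *frequency*, not bits;
  information content is computed for reporting (it appears in
  `summary()`) because it is the standard conservation measure readers know
  from logos.
- **Low-frequency filter.** Pairs with $f_i(a,b)$ strictly below a threshold
  (default 0.01, i.e. carried by less than one percent of the sequences) are
  removed before layout to reduce visual noise. The strictness matters: a
  pair at exactly the threshold survives. After filtering, the sum-to-$N$
  invariant no longer holds — deliberately, since the point is to drop rare
  flows. Filtering is applied per sample independently: a path common within
  a small subfamily but rare overall is exactly what a comparison must show.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `filter_threshold` | 0.01 | fraction of sequences | one percent removes sporadic pairs while keeping any subfamily above a few percent visible |
| `denominator_policy` | `per_group` | — | with unequal sample sizes, a per-sample denominator keeps a small subfamily's flows visible; `combined` divides by the pooled total instead |
| `column_spacing` | 40 | points | comfortable ribbon curvature at 40 columns |
| `row_spacing` | 14 | points | row labels remain legible at font size 9 |
| `group_gap` | 12 | points, > 0 | enough white space that functional groups parse as bands |
| `max_ribbon_weight` | 10 | points | stroke width of a frequency-1.0 ribbon; all widths scale linearly from it |
| `group_colors` | red/blue at alpha 0.5 | `#RRGGBBAA` | semi-transparent complements blend to purple where two samples coincide; exact values are package defaults, fully configurable |
| `gap_row_policy` | `own_row` | — | dropping gapped sequences would silently change $N$; a visible gap row keeps all frequencies interpretable |
| `masked_positions` | none | 1-based positions | suppresses ribbons touching a position while keeping its axis label |

All of these live in a flat YAML configuration file (template:
`system.file("extdata", "seqdiv_config_template.yml", package = "seqdivdiag")`);
command-line flags override file values, which override the defaults.

## Design choices where the design was open

- **Grouping table and y-order.** No single canonical physicochemical
  partition of the 20 amino acids exists; the package ships one standard
  choice (documented above) and makes both the partition and its order fully
  configurable. The y-order is always the configuration's declaration order —
  determinism was weighted over any particular chemistry argument.
- **Ribbon shape.** A cubic Bézier S-curve with horizontal tangents at both
  endpoints (the Sankey convention). Horizontal tangents keep each ribbon
  visually attached to its residue rows. Stroke width is constant along the
  whole path — constant-width links avoid the line-width illusion that
  tapered, Parallel-Sets-style bands suffer from.
- **Z-order.** Samples are drawn in input order; within a sample, ribbons are
  drawn in ascending weight so each sample's dominant flows land on top of
  its own minor ones. No crossing minimization is attempted: the fixed grid
  *is* the encoding.
- **Overlay color.** The "purple where both agree" effect is alpha
  compositing of the per-sample strokes, not a computed third color, so it
  generalizes unchanged to three or more samples.
- **Gap dialects.** Only `-` is a gap; `.` is rejected unless
  `dot_as_gap: true` maps it, avoiding silent dialect bugs. Ambiguity codes
  (protein X/B/Z/J, nucleotide IUPAC) are accepted only when the scheme
  declares them, and then occupy a dedicated "other" row rather than being
  dropped, which would silently change the denominators.
- **Ties.** `dominant_transition()` breaks frequency ties alphabetically on
  the ordered pair and sets a tie flag, so reports are deterministic.
- **Columns are 1-based** everywhere in the API and display, matching both R
  idiom and the "position 5" style of figure labeling.

## Numerical conventions

Entropy uses $0 \log 0 = 0$; input frequencies must sum to 1 within $10^{-6}$.
Information content is clamped at zero from below (the small-sample
correction can otherwise push a noisy column negative). Frequency-sum
invariants are asserted to $10^{-9}$ in the tests. SVG coordinates are
written with three decimal places and no timestamps, making the output
byte-deterministic for fixed inputs — the rendering tests rely on that.
Degenerate inputs fail loudly: an empty alignment, a single-column alignment,
a layout with every ribbon filtered or masked away ("nothing to draw"), and a
residue missing from the scheme are all structured errors with distinct
classes, which the CLI maps to distinct exit codes.

## The synthetic data generator

`conservation_profile()` + `generate_group()` emulate the features the
diagram is designed to reveal, without requiring any external dataset. Every
column draws a modal residue with stated probability (default 0.85) and a
background residue (uniform over the rest by default) otherwise; columns are
sampled independently. A planted *subgroup* — a stated fraction of the
sequences — follows a modal path shifted by a fixed column offset from a
start column onward, emulating the "out-of-phase" parallel path that a
single-residue insertion or deletion produces in a curated alignment.

The bundled two-sample fixture (`synthetic_akl_groups()`, also committed as
FASTA under `inst/extdata/`, labelled synthetic) uses the conditions the
package treats as its study conditions: 2 groups × 500 sequences × 40
columns, modal probability 0.85, Proline at position 5 followed by Alanine at
position 6 on the shared modal path, and a 20% subgroup in the second sample
offset by +1 from column 19. The 40-column modal string avoids equal adjacent
residues so the offset path never coincides with the main one. At these
conditions the main modal pair runs near $0.8 \times 0.85^2 \approx 0.58$ in
the subgroup-bearing sample and the offset pair near
$0.2 \times 0.85^2 \approx 0.14$ — both far above the 1% filter — while in
the sample without the subgroup the offset pair is of order $10^{-4}$ and is
always filtered.

What the generator does *not* emulate: phylogenetic correlation between
sequences, positional dependence beyond the planted shift, realistic
substitution processes, and indel placement by an aligner. Passing tests on
this data therefore demonstrate that the pipeline counts, filters, lays out
and renders correctly, and that planted signals of realistic effect size are
recovered — not that any particular biological dataset will show such
signals.

## A worked example

```{r example}
groups <- synthetic_akl_groups(n_sequences = 500)
d <- seqdiv(groups = groups)
d

# the planted sequential signal: P at 5 is followed by A at 6
dominant_transition(d$filtered$gram_negative, 5)

# the subgroup's offset path survives filtering only in gram_positive
subset(d$filtered$gram_positive$pairs, column == 25)
```

```{r plot, fig.width = 9, fig.height = 5}
plot(d, main = "two subfamilies, one figure")
```

`render_svg(d$layout, d$scheme, d$config)` returns the deterministic SVG
document; `export_diagram(d, "diagram.png")` writes PNG (or PDF/SVG by
extension). The same pipeline is scriptable from a shell via the launcher in
`system.file("exec", "seqdiv", package = "seqdivdiag")`.

## Problem sizes

The test suite and the acceptance script work at the fixture's native scale
(two samples of 500 sequences × 40 columns, plus a few hundred randomized
alignments of at most 50 × 20 for the counting-oracle and invariant
properties). These sizes were chosen because the planted effects are already
stable there; the implementation is vectorized per column and handles much
larger alignments comfortably.

## Known limitations

- Only adjacent-position dependence is shown; mutual information between
  distant positions is out of scope.
- No sequence weighting: redundant sequences count fully in all frequencies.
- Inputs must be pre-aligned FASTA; no aligner is invoked and no
  Stockholm/Clustal readers are provided.
- The figure is static; there is no interactive editing.
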