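# seqdivdiag configuration template.
# Every key is optional; omitted keys take the defaults shown here.

# Built-in alphabet: "protein" (default) or "nucleotide".
alphabet: protein

# Custom residue grouping (overrides `alphabet`). Declaration order defines
# the y-axis order, top to bottom. Values are residue strings.
# groups:
#   aliphatic: AVLIM
#   aromatic: FWY
#   polar: STNQ
#   positive: KRH
#   negative: DE
#   special: CGP

# "own_row": gaps occupy a visible bottom row (default); "excluded": dropped.
gap_row_policy: own_row

# true -> accept standard ambiguity codes (protein: X B Z J; nucleotide:
# IUPAC) on a dedicated "other" row; or list explicit symbols.
# ambiguity: true

# Nucleotide only: count U on the T row (mixed DNA/RNA input).
# merge_tu: true

filter:
  # Pairs with relative frequency strictly below this are filtered out.
  threshold: 0.01

# Per-sample colors, #RRGGBB or #RRGGBBAA. Semi-transparent defaults are
# chosen so two overlaid samples blend (red + blue reads as purple).
# colors:
#   gram_negative: "#D6272880"
#   gram_positive: "#1F77B480"

geometry:
  column_spacing: 40      # horizontal distance between positions (points)
  row_spacing: 14         # vertical distance between rows within a group
  group_gap: 12           # extra gap between functional groups
  max_ribbon_weight: 10   # stroke width of a frequency-1.0 ribbon

# 1-based positions whose ribbons are suppressed (axis labels are kept).
# mask: [1, 2, 3]

output:
  format: svg             # svg, png or pdf

# "per_group": pair frequencies relative to each sample's own size (default);
# "combined": relative to the total across samples.
denominator: per_group

# Count transitions in which either residue is a gap (they flow through the
# gap row).
gap_pairs: true

# Treat "." in input FASTA as the gap symbol "-".
dot_as_gap: false
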