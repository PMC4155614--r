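#' Build a Sequence Diversity Diagram
#'
#' The central constructor: takes one or more aligned samples and runs the
#' full pipeline — validation, per-column residue frequencies, adjacent-column
#' transition frequencies, the low-frequency filter, and ribbon layout — and
#' returns a single object that can be printed, summarised, plotted, rendered
#' to SVG or exported to PNG/PDF.
#'
#' Each sample is one aligned FASTA file (or a prebuilt [alignment_group()]);
#' all samples must share the same column count, since the overlay needs a
#' common x-axis. Ribbon width encodes the relative frequency of the ordered
#' residue pair at consecutive positions; each sample is drawn in its own
#' semi-transparent color, so positions conserved in all samples blend (red
#' over blue reads as purple) while subfamily-specific paths stay separate.
#'
#' @param fasta Character vector of aligned FASTA paths, one per sample, or a
#'   list of [alignment_group()] objects via `groups`.
#' @param groups Alternative to `fasta`: list of prebuilt alignment groups.
#' @param labels Optional sample labels (default: file name stems).
#' @param colors Optional per-sample colors (`#RRGGBB[AA]`).
#' @param scheme An [alphabet_scheme()]; default [default_protein_scheme()].
#' @param config A [diagram_config()].
#' @return An object of class `seqdiv`: list with `groups`, `scheme`,
#'   `config`, `freqs` (per-group [position_frequencies()]), `transitions`
#'   (unfiltered [transition_frequencies()]), `filtered` (after
#'   [filter_transitions()] at `config$filter_threshold`), `layout`
#'   ([compute_ribbons()]), and `validation` (the [validate_group_set()]
#'   report).
#' @examples
#' groups <- synthetic_akl_groups(n_sequences = 50)
#' d <- seqdiv(groups = groups)
#' print(d)
#' dominant_transition(d$filtered$gram_negative, 5)
#' @export
seqdiv <- function(fasta = NULL, groups = NULL, labels = NULL, colors = NULL,
                   scheme = default_protein_scheme(),
                   config = diagram_config()) {
  stopifnot(inherits(scheme, "alphabet_scheme"),
            inherits(config, "diagram_config"))
  if (is.null(groups)) {
    if (is.null(fasta) || length(fasta) == 0) {
      sdd_error("supply at least one FASTA path or alignment group",
                "sdd_missing_file")
    }
    lab_of <- function(j) {
      if (!is.null(labels) && length(labels) >= j && !is.na(labels[j])) {
        labels[j]
      } else NULL
    }
    groups <- lapply(seq_along(fasta), function(j) {
      read_alignment_fasta(fasta[j], scheme = scheme, label = lab_of(j),
                           dot_as_gap = config$dot_as_gap)
    })
  } else if (!is.null(labels)) {
    groups <- lapply(seq_along(groups), function(j) {
      g <- groups[[j]]
      if (length(labels) >= j && !is.na(labels[j])) g$label <- labels[j]
      g
    })
  }
  report <- validate_group_set(groups)
  labs <- report$labels
  names(groups) <- labs

  resolved_colors <- colors %||% config$group_colors %||%
    unlist(lapply(groups, `[[`, "color"))
  if (is.null(resolved_colors) || length(resolved_colors) < length(groups)) {
    resolved_colors <- default_group_colors(length(groups))
  }
  if (is.null(names(resolved_colors))) names(resolved_colors) <- labs
  resolved_colors <- resolved_colors[labs]

  combined_n <- sum(report$n_sequences)
  freqs <- lapply(groups, position_frequencies, scheme = scheme)
  transitions <- lapply(groups, transition_frequencies, scheme = scheme,
                        denominator_policy = config$denominator_policy,
                        combined_n = combined_n,
                        include_gap_pairs = config$include_gap_pairs)
  filtered <- lapply(transitions, filter_transitions,
                     threshold = config$filter_threshold)

  grid <- compute_grid(scheme, report$n_columns, config)
  layout <- compute_ribbons(filtered, grid, config, colors = resolved_colors)

  structure(
    list(groups = groups, scheme = scheme, config = config,
         freqs = freqs, transitions = transitions, filtered = filtered,
         layout = layout, validation = report, colors = resolved_colors,
         call = match.call()),
    class = "seqdiv"
  )
}

#' @export
print.seqdiv <- function(x, ...) {
  cat("Sequence Diversity Diagram\n")
  cat(sprintf("  samples:  %s\n",
              paste(sprintf("%s (n=%d)", x$validation$labels,
                            x$validation$n_sequences), collapse = ", ")))
  cat(sprintf("  columns:  %d\n", x$validation$n_columns))
  total <- sum(vapply(x$transitions, function(t) nrow(t$pairs), integer(1)))
  kept <- sum(vapply(x$filtered, function(t) nrow(t$pairs), integer(1)))
  cat(sprintf("  transitions: %d observed, %d surviving the %g filter\n",
              total, kept, x$config$filter_threshold))
  cat(sprintf("  ribbons:  %d\n", nrow(x$layout$ribbons)))
  invisible(x)
}

#' Summarise a Sequence Diversity Diagram
#'
#' Reports, per sample: sequence count, mean and range of per-column
#' information content (in bits, no small-sample correction, alphabet size =
#' number of grouped residues), transition counts before/after filtering, and
#' the dominant transition at each column pair.
#'
#' @param object A [seqdiv()] object.
#' @param ... Unused.
#' @return An object of class `summary.seqdiv` (list, one element per sample).
#' @export
summary.seqdiv <- function(object, ...) {
  s <- length(object$scheme$alphabet)
  out <- lapply(object$validation$labels, function(lab) {
    pf <- object$freqs[[lab]]
    ic <- apply(pf$freq, 2, function(p) {
      information_content(p / sum(p), alphabet_size = s)
    })
    dom <- lapply(seq_len(object$validation$n_columns - 1L),
                  function(i) dominant_transition(object$transitions[[lab]], i))
    list(
      label = lab,
      n_sequences = pf$n_sequences,
      information_bits = ic,
      n_pairs = nrow(object$transitions[[lab]]$pairs),
      n_pairs_filtered = nrow(object$filtered[[lab]]$pairs),
      dominant = data.frame(
        column = seq_along(dom),
        from = vapply(dom, `[[`, character(1), "from"),
        to = vapply(dom, `[[`, character(1), "to"),
        freq = vapply(dom, `[[`, numeric(1), "freq")
      )
    )
  })
  names(out) <- object$validation$labels
  structure(list(samples = out, threshold = object$config$filter_threshold),
            class = "summary.seqdiv")
}

#' @export
print.summary.seqdiv <- function(x, ...) {
  cat("Sequence Diversity Diagram summary\n")
  for (s in x$samples) {
    cat(sprintf("\n== %s (n = %d) ==\n", s$label, s$n_sequences))
    cat(sprintf("  information content: mean %.2f bits (range %.2f-%.2f)\n",
                mean(s$information_bits), min(s$information_bits),
                max(s$information_bits)))
    cat(sprintf("  transition pairs: %d observed, %d after %g filter\n",
                s$n_pairs, s$n_pairs_filtered, x$threshold))
    top <- s$dominant[order(-s$dominant$freq)[seq_len(min(3, nrow(s$dominant)))], ]
    cat("  strongest adjacent pairs:\n")
    for (r in seq_len(nrow(top))) {
      cat(sprintf("    %s(%d) -> %s(%d): %.3f\n", top$from[r], top$column[r],
                  top$to[r], top$column[r] + 1L, top$freq[r]))
    }
  }
  invisible(x)
}

#' Plot a Sequence Diversity Diagram
#'
#' Draws the diagram on the current graphics device using the same layout
#' geometry as the SVG renderer.
#'
#' @param x A [seqdiv()] object.
#' @param main Optional title.
#' @param ... Unused.
#' @export
plot.seqdiv <- function(x, main = NULL, ...) {
  draw_layout(x$layout, main = main)
}
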