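#' Per-column residue frequencies
#'
#' Tallies, for every alignment column, how often each residue row of the
#' scheme occurs, and the corresponding relative frequency with respect to the
#' group's number of sequences. With `gap_row_policy = "own_row"` gaps are
#' counted on their own row so every column sums to the number of sequences;
#' with `"excluded"` gap characters are dropped and column sums may be smaller
#' (relative frequencies are still fractions of all sequences).
#'
#' @param group An [alignment_group()].
#' @param scheme An [alphabet_scheme()]; the group must validate against it.
#' @return An object of class `position_freq_table`: list with `label`,
#'   `n_sequences`, `counts` and `freq` — matrices with one row per scheme row
#'   (see [scheme_rows()]) and one column per alignment position (1-based).
#' @examples
#' g <- alignment_group(c("PA", "PA", "LP", "PA"), "toy")
#' pf <- position_frequencies(g, default_protein_scheme())
#' pf$freq["P", 1]  # 0.75
#' @export
position_frequencies <- function(group, scheme) {
  stopifnot(inherits(group, "alignment_group"),
            inherits(scheme, "alphabet_scheme"))
  validate_group_alphabet(group, scheme)
  rows <- scheme_rows(scheme)
  m <- scheme_row_of(scheme, group_matrix(group))
  dim(m) <- c(group$n_sequences, group$n_columns)
  counts <- vapply(seq_len(group$n_columns), function(i) {
    table(factor(m[, i], levels = rows$residue))
  }, integer(nrow(rows)))
  dimnames(counts) <- list(rows$residue, seq_len(group$n_columns))
  structure(
    list(label = group$label, n_sequences = group$n_sequences,
         counts = counts, freq = counts / group$n_sequences),
    class = "position_freq_table"
  )
}

#' @export
print.position_freq_table <- function(x, ...) {
  cat(sprintf("<position_freq_table '%s': %d rows x %d columns, n = %d>\n",
              x$label, nrow(x$counts), ncol(x$counts), x$n_sequences))
  invisible(x)
}

#' @export
as.data.frame.position_freq_table <- function(x, ...) {
  df <- data.frame(
    group = x$label,
    column = rep(seq_len(ncol(x$counts)), each = nrow(x$counts)),
    residue = rep(rownames(x$counts), ncol(x$counts)),
    count = as.vector(x$counts),
    freq = as.vector(x$freq),
    stringsAsFactors = FALSE
  )
  df
}

#' Adjacent-position transition frequencies
#'
#' The quantity a Sequence Diversity Diagram ribbon encodes: for each pair of
#' consecutive columns (i, i+1), the number of sequences carrying residue `a`
#' at column i and residue `b` at column i+1, and its relative frequency. Each
#' sequence contributes exactly one ordered pair per column pair, so unfiltered
#' pair counts sum to the number of sequences at every i, and the marginals
#' over `b` (resp. `a`) reproduce the per-column counts of
#' [position_frequencies()].
#'
#' @param group An [alignment_group()].
#' @param scheme An [alphabet_scheme()].
#' @param denominator_policy `"per_group"`: frequencies are relative to this
#'   group's own sequence count (default); `"combined"`: relative to
#'   `combined_n`, the total across all overlaid samples.
#' @param combined_n Total sequence count across samples (required when
#'   `denominator_policy = "combined"`).
#' @param include_gap_pairs Count pairs in which either residue is a gap
#'   (default `TRUE`). Only meaningful with `gap_row_policy = "own_row"`.
#' @return An object of class `transition_table`: list with `label`,
#'   `n_sequences`, `denominator`, `n_columns`, `threshold` (`NA` until
#'   filtered) and `pairs`, a data frame with columns `column` (left column i,
#'   1-based), `from`, `to`, `count`, `freq` holding the non-zero entries.
#' @examples
#' g <- alignment_group(c("PA", "PA", "LP", "PA"), "toy")
#' tt <- transition_frequencies(g, default_protein_scheme())
#' tt$pairs  # (P,A) count 3 freq 0.75; (L,P) count 1 freq 0.25
#' @export
transition_frequencies <- function(group, scheme,
                                   denominator_policy = c("per_group", "combined"),
                                   combined_n = NULL,
                                   include_gap_pairs = TRUE) {
  stopifnot(inherits(group, "alignment_group"),
            inherits(scheme, "alphabet_scheme"))
  denominator_policy <- match.arg(denominator_policy)
  if (denominator_policy == "combined" && is.null(combined_n)) {
    sdd_error("combined denominator requires 'combined_n'", "sdd_bad_config")
  }
  denom <- if (denominator_policy == "combined") combined_n else group$n_sequences
  validate_group_alphabet(group, scheme)

  m <- scheme_row_of(scheme, group_matrix(group))
  dim(m) <- c(group$n_sequences, group$n_columns)
  L <- group$n_columns
  res <- vector("list", L - 1L)
  for (i in seq_len(L - 1L)) {
    from <- m[, i]
    to <- m[, i + 1L]
    if (!include_gap_pairs || scheme$gap_row_policy == "excluded") {
      keep <- from != "-" & to != "-"
      from <- from[keep]
      to <- to[keep]
    }
    if (length(from) == 0) next
    tab <- table(from, to)
    nz <- which(tab > 0, arr.ind = TRUE)
    res[[i]] <- data.frame(
      column = i,
      from = rownames(tab)[nz[, 1]],
      to = colnames(tab)[nz[, 2]],
      count = as.integer(tab[nz]),
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, res) %||%
    data.frame(column = integer(), from = character(), to = character(),
               count = integer())
  pairs <- pairs[order(pairs$column, pairs$from, pairs$to), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$freq <- pairs$count / denom
  structure(
    list(label = group$label, n_sequences = group$n_sequences,
         denominator = denom, n_columns = L, threshold = NA_real_,
         pairs = pairs),
    class = "transition_table"
  )
}

#' @export
print.transition_table <- function(x, ...) {
  filt <- if (is.na(x$threshold)) "unfiltered" else
    sprintf("filtered at %g", x$threshold)
  cat(sprintf("<transition_table '%s': %d pairs over %d column pairs, %s>\n",
              x$label, nrow(x$pairs), x$n_columns - 1L, filt))
  invisible(x)
}

#' @export
as.data.frame.transition_table <- function(x, ...) {
  cbind(group = rep(x$label, nrow(x$pairs)), x$pairs)
}

#' Shannon entropy of a column
#'
#' `H = -sum(p * log2(p))` in bits, with the convention `0 * log(0) = 0`.
#' The uncertainty of the residue distribution at one alignment position:
#' 0 for a fully conserved column, `log2(k)` for a uniform spread over k
#' residues.
#'
#' @param column_freqs Numeric vector of residue frequencies; must be
#'   non-negative and sum to 1 (tolerance 1e-6).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5))        # 1
#' shannon_entropy(rep(1 / 20, 20))    # log2(20) = 4.3219...
#' @export
shannon_entropy <- function(column_freqs) {
  p <- as.numeric(column_freqs)
  if (any(is.na(p)) || any(p < 0)) {
    sdd_error("frequencies must be non-negative", "sdd_bad_config")
  }
  if (abs(sum(p) - 1) > 1e-6) {
    sdd_error(sprintf("frequencies must sum to 1 (got %.8f)", sum(p)),
              "sdd_bad_config")
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information content of a column
#'
#' The sequence-logo stack height: `R = log2(s) - (H + e_n)` bits, where `s`
#' is the alphabet size, `H` the column's Shannon entropy and `e_n` the
#' small-sample correction `(s - 1) / (2 * ln(2) * n)` applied only when
#' `correction = TRUE`. Clamped at 0 from below. The diagram itself encodes
#' frequency, not bits; this is exposed for reporting alongside it.
#'
#' @param column_freqs As in [shannon_entropy()].
#' @param alphabet_size Number of symbols `s` in the alphabet (>= 2).
#' @param n_sequences Number of sequences `n` (required when `correction`).
#' @param correction Apply the small-sample correction. Default `FALSE`.
#' @return Information content in bits.
#' @examples
#' information_content(c(1, rep(0, 19)), 20)  # log2(20)
#' @export
information_content <- function(column_freqs, alphabet_size,
                                n_sequences = NULL, correction = FALSE) {
  if (!is.numeric(alphabet_size) || alphabet_size < 2) {
    sdd_error("alphabet_size must be >= 2", "sdd_bad_config")
  }
  e_n <- 0
  if (isTRUE(correction)) {
    if (is.null(n_sequences) || n_sequences < 1) {
      sdd_error("small-sample correction requires n_sequences >= 1",
                "sdd_bad_config")
    }
    e_n <- (alphabet_size - 1) / (2 * log(2) * n_sequences)
  }
  max(0, log2(alphabet_size) - (shannon_entropy(column_freqs) + e_n))
}

#' Filter low-frequency transitions
#'
#' Removes every pair whose relative frequency is strictly below `threshold`
#' ("less than" semantics: an entry exactly at the threshold survives). The
#' default diagram threshold is 0.01 — pairs carried by less than one percent
#' of the sequences are dropped to reduce visual noise. Filtering is applied
#' per group independently, so a pair common in a small subfamily but rare
#' overall is kept when the per-group denominator is in use. A filtered table
#' no longer sums to the number of sequences at each column pair.
#'
#' @param table A [transition_frequencies()] result.
#' @param threshold Fraction in `[0, 1]`.
#' @return A `transition_table` with the surviving pairs unchanged and
#'   `threshold` recorded.
#' @export
filter_transitions <- function(table, threshold) {
  stopifnot(inherits(table, "transition_table"))
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    sdd_error("threshold must be a single number in [0, 1]", "sdd_bad_config")
  }
  table$pairs <- table$pairs[table$pairs$freq >= threshold, , drop = FALSE]
  rownames(table$pairs) <- NULL
  table$threshold <- threshold
  table
}

#' Dominant transition at a column pair
#'
#' The most frequent ordered residue pair between columns i and i+1 — e.g.
#' "the P at position 5 is followed by the A at position 6". Ties are broken
#' alphabetically on (from, to) and flagged.
#'
#' @param table A `transition_table` (filtered or not).
#' @param i Left column index (1-based); the pair spans columns i and i+1.
#' @return List with `from`, `to`, `count`, `freq`, `tie`.
#' @export
dominant_transition <- function(table, i) {
  stopifnot(inherits(table, "transition_table"))
  p <- table$pairs[table$pairs$column == i, , drop = FALSE]
  if (nrow(p) == 0) {
    sdd_error(sprintf("no transitions at column pair (%d, %d)%s", i, i + 1,
                      if (!is.na(table$threshold)) " after filtering" else ""),
              "sdd_invalid_alignment")
  }
  p <- p[order(-p$freq, p$from, p$to), , drop = FALSE]
  list(from = p$from[1], to = p$to[1], count = p$count[1], freq = p$freq[1],
       tie = nrow(p) > 1 && isTRUE(all.equal(p$freq[2], p$freq[1])))
}

#' Export frequency and transition tables as delimited text
#'
#' Writes tab-separated long-format tables for downstream use.
#'
#' @param x A `position_freq_table` or `transition_table` (or a list of them).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(x, path) {
  if (inherits(x, "position_freq_table") || inherits(x, "transition_table")) {
    x <- list(x)
  }
  df <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
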