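# Shared fixtures and independent oracles.

# Toy alignment used throughout: 4 sequences x 2 columns.
toy_group <- function(label = "toy") {
  alignment_group(c(a = "PA", b = "PA", c = "LP", d = "PA"), label = label)
}

write_fasta_lines <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# Random alignment over a random alphabet subset; gap-free by default.
random_group <- function(n, L, alphabet = LETTERS[1:10], gap_prob = 0,
                         label = "rand") {
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(alphabet, L, replace = TRUE)
    if (gap_prob > 0) {
      chars[stats::runif(L) < gap_prob] <- "-"
    }
    paste(chars, collapse = "")
  }, character(1))
  alignment_group(seqs, label = label)
}

# Scheme whose single group is an arbitrary alphabet (for random tests).
flat_scheme <- function(alphabet) {
  alphabet_scheme(list(all = alphabet))
}

# Independent oracle: naive double loop over sequences and adjacent columns,
# one character at a time, never touching the package's counting code.
naive_bigram_counts <- function(sequences) {
  out <- list()
  for (s in sequences) {
    chars <- strsplit(s, "")[[1]]
    for (i in seq_len(length(chars) - 1)) {
      key <- paste(i, chars[i], chars[i + 1], sep = "|")
      out[[key]] <- (out[[key]] %||% 0L) + 1L
    }
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Compare a transition_table against the naive oracle exactly.
expect_matches_naive <- function(tt, sequences) {
  oracle <- naive_bigram_counts(sequences)
  got <- with(tt$pairs, stats::setNames(count, paste(column, from, to, sep = "|")))
  expect_setequal(names(got), names(oracle))
  expect_identical(as.integer(got[names(oracle)]),
                   as.integer(unlist(oracle)))
}
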