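sch <- default_protein_scheme()

test_that("position frequencies match hand counts on the toy alignment", {
  pf <- position_frequencies(toy_group(), sch)
  # column 1: P 3/4, L 1/4
  expect_equal(pf$freq["P", 1], 0.75)
  expect_equal(pf$freq["L", 1], 0.25)
  expect_equal(sum(pf$freq[, 1]), 1)
  # column 2: A 3/4, P 1/4
  expect_equal(pf$counts["A", 2], 3L, ignore_attr = TRUE)
  expect_equal(pf$counts["P", 2], 1L, ignore_attr = TRUE)
  # absent residues have count 0
  expect_equal(unname(pf$counts["W", 1]), 0L)
})

test_that("constant and all-gap columns behave at the boundaries", {
  g <- alignment_group(c("PP-", "PA-", "PA-"), "g")
  pf <- position_frequencies(g, sch)
  expect_equal(unname(pf$freq["P", 1]), 1)
  expect_equal(sum(pf$freq[, 1] > 0), 1)
  expect_equal(unname(pf$freq["-", 3]), 1)  # all-gap column, own_row policy

  excl <- default_protein_scheme(gap_row_policy = "excluded")
  pf2 <- position_frequencies(g, excl)
  expect_false("-" %in% rownames(pf2$counts))
  expect_equal(sum(pf2$counts[, 3]), 0)
})

test_that("position frequency column sums equal the sequence count", {
  set.seed(31)
  for (rep in 1:10) {
    g <- random_group(sample(1:30, 1), sample(2:12, 1),
                      alphabet = LETTERS[1:8], gap_prob = 0.1)
    pf <- position_frequencies(g, flat_scheme(LETTERS[1:8]))
    expect_true(all(colSums(pf$counts) == g$n_sequences))
    expect_true(all(abs(colSums(pf$freq) - 1) < 1e-9))
  }
})

test_that("position frequencies agree with Biostrings consensusMatrix", {
  set.seed(32)
  g <- random_group(25, 10, alphabet = c("A", "C", "D", "E", "F"))
  pf <- position_frequencies(g, flat_scheme(c("A", "C", "D", "E", "F")))
  cm <- Biostrings::consensusMatrix(Biostrings::BStringSet(g$sequences))
  for (res in rownames(cm)) {
    expect_equal(unname(pf$counts[res, ]), unname(cm[res, ]))
  }
})

test_that("transition counts match hand counts on the toy alignment", {
  tt <- transition_frequencies(toy_group(), sch)
  p <- tt$pairs
  expect_equal(nrow(p), 2)
  expect_equal(p$count[p$from == "P" & p$to == "A"], 3L)
  expect_equal(p$count[p$from == "L" & p$to == "P"], 1L)
  expect_equal(p$freq[p$from == "P" & p$to == "A"], 0.75)
  expect_equal(p$freq[p$from == "L" & p$to == "P"], 0.25)
})

test_that("a single sequence gives pair frequency 1 everywhere", {
  g <- alignment_group("PAK", "one")
  tt <- transition_frequencies(g, sch)
  expect_equal(nrow(tt$pairs), 2)
  expect_true(all(tt$pairs$freq == 1))
})

test_that("transition counts equal the naive double-loop oracle", {
  set.seed(33)
  for (rep in 1:25) {
    alpha <- sample(LETTERS, sample(3:10, 1))
    g <- random_group(sample(1:50, 1), sample(2:20, 1), alphabet = alpha,
                      gap_prob = if (rep %% 3 == 0) 0.1 else 0)
    tt <- transition_frequencies(g, flat_scheme(alpha))
    expect_matches_naive(tt, g$sequences)
  }
})

test_that("marginals of the transition table reproduce position counts", {
  set.seed(34)
  for (rep in 1:10) {
    alpha <- LETTERS[1:6]
    g <- random_group(sample(2:40, 1), sample(2:15, 1), alphabet = alpha,
                      gap_prob = 0.05)
    scheme <- flat_scheme(alpha)
    pf <- position_frequencies(g, scheme)
    tt <- transition_frequencies(g, scheme)
    for (i in seq_len(g$n_columns - 1)) {
      pi <- tt$pairs[tt$pairs$column == i, ]
      expect_equal(sum(pi$count), g$n_sequences)
      left <- tapply(pi$count, pi$from, sum)
      right <- tapply(pi$count, pi$to, sum)
      expect_equal(as.integer(left),
                   unname(pf$counts[names(left), i]))
      expect_equal(as.integer(right),
                   unname(pf$counts[names(right), i + 1]))
    }
  }
})

test_that("tables are invariant under sequence order permutation", {
  set.seed(35)
  g <- random_group(20, 8, alphabet = LETTERS[1:5])
  perm <- alignment_group(sample(g$sequences), "rand")
  scheme <- flat_scheme(LETTERS[1:5])
  expect_equal(position_frequencies(g, scheme)$counts,
               position_frequencies(perm, scheme)$counts)
  expect_equal(transition_frequencies(g, scheme)$pairs,
               transition_frequencies(perm, scheme)$pairs)
})

test_that("denominator policies divide by the right total", {
  g <- toy_group()
  per <- transition_frequencies(g, sch)
  comb <- transition_frequencies(g, sch, denominator_policy = "combined",
                                 combined_n = 16)
  expect_equal(comb$pairs$count, per$pairs$count)
  expect_equal(comb$pairs$freq, per$pairs$freq * 4 / 16)
  expect_error(transition_frequencies(g, sch, denominator_policy = "combined"),
               "combined_n", class = "sdd_bad_config")
})

test_that("gap pairs flow through the gap row or are excluded by flag", {
  g <- alignment_group(c("P-", "PA"), "g")
  with_gaps <- transition_frequencies(g, sch)
  expect_true(any(with_gaps$pairs$to == "-"))
  expect_equal(sum(with_gaps$pairs$count), 2)
  no_gaps <- transition_frequencies(g, sch, include_gap_pairs = FALSE)
  expect_false(any(no_gaps$pairs$to == "-"))
  expect_equal(sum(no_gaps$pairs$count), 1)
})

test_that("entropy matches closed forms", {
  expect_equal(shannon_entropy(rep(1 / 20, 20)), log2(20), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(1, rep(0, 5))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(shannon_entropy(c(1.2, -0.2)), "non-negative")
})

test_that("entropy is maximal at uniform and zero iff constant", {
  set.seed(36)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    p <- as.vector(stats::rmultinom(1, 200, stats::runif(k))) / 200
    H <- shannon_entropy(p)
    expect_lte(H, log2(k) + 1e-12)
    if (sum(p > 0) == 1) {
      expect_equal(H, 0)
    } else {
      expect_gt(H, 0)
    }
  }
})

test_that("information content follows the logo convention", {
  expect_equal(information_content(rep(1 / 20, 20), 20), 0, tolerance = 1e-12)
  conserved <- c(1, rep(0, 19))
  expect_equal(information_content(conserved, 20), log2(20), tolerance = 1e-12)
  # small-sample correction at n = 4, alphabet 20
  expect_equal(information_content(conserved, 20, n_sequences = 4,
                                   correction = TRUE),
               log2(20) - 19 / (2 * log(2) * 4), tolerance = 1e-12)
  expect_error(information_content(conserved, 1), "alphabet_size")
  expect_error(information_content(conserved, 20, correction = TRUE),
               "n_sequences")
})

test_that("filtering removes strictly-below-threshold pairs only", {
  tt <- transition_frequencies(toy_group(), sch)  # freqs 0.75 and 0.25
  expect_equal(nrow(filter_transitions(tt, 0)$pairs), 2)
  expect_equal(nrow(filter_transitions(tt, 1)$pairs), 0)
  # an entry exactly at threshold survives (strict "less than" removal)
  at <- filter_transitions(tt, 0.25)
  expect_equal(nrow(at$pairs), 2)
  above <- filter_transitions(tt, 0.2500001)
  expect_equal(nrow(above$pairs), 1)
  expect_error(filter_transitions(tt, 2), "threshold")
})

test_that("filtering is monotone in the threshold", {
  set.seed(37)
  g <- random_group(40, 10, alphabet = LETTERS[1:4])
  tt <- transition_frequencies(g, flat_scheme(LETTERS[1:4]))
  thresholds <- sort(stats::runif(15))
  kept <- vapply(thresholds,
                 function(th) nrow(filter_transitions(tt, th)$pairs),
                 integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("dominant transitions report the argmax with alphabetical tie-break", {
  tt <- transition_frequencies(toy_group(), sch)
  d <- dominant_transition(tt, 1)
  expect_equal(d$from, "P")
  expect_equal(d$to, "A")
  expect_false(d$tie)

  # two pairs at equal frequency: alphabetically first wins, tie flagged
  g <- alignment_group(c("PA", "LP"), "tie")
  d2 <- dominant_transition(transition_frequencies(g, sch), 1)
  expect_equal(c(d2$from, d2$to), c("L", "P"))
  expect_true(d2$tie)

  empty <- filter_transitions(tt, 1)
  expect_error(dominant_transition(empty, 1), "no transitions")
})

test_that("tables export as delimited text", {
  g <- toy_group()
  f <- tempfile(fileext = ".tsv")
  write_freq_table(list(position_frequencies(g, sch)), f)
  df <- utils::read.delim(f)
  expect_true(all(c("group", "column", "residue", "count", "freq") %in%
                    names(df)))
  expect_equal(sum(df$count), 8)  # 4 sequences x 2 columns

  write_freq_table(transition_frequencies(g, sch), f)
  df2 <- utils::read.delim(f)
  expect_equal(nrow(df2), 2)
})
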