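sch <- default_protein_scheme()

test_that("grid spacing follows rows, groups and columns", {
  cfg <- diagram_config(column_spacing = 40, row_spacing = 14, group_gap = 12)
  grid <- compute_grid(sch, 5, cfg)
  expect_equal(unname(grid$x), (0:4) * 40)

  rows <- grid$rows
  # adjacent residues in the same group differ by row_spacing
  same <- which(rows$group[-1] == rows$group[-nrow(rows)])
  expect_true(all(diff(rows$y)[same] == 14))
  # residues straddling a group boundary differ by row_spacing + group_gap
  cross <- which(rows$group[-1] != rows$group[-nrow(rows)])
  expect_true(all(diff(rows$y)[cross] == 26))
  # vertical separation across groups is at least group_gap
  for (g1 in unique(rows$group)) {
    for (g2 in setdiff(unique(rows$group), g1)) {
      gapmin <- min(abs(outer(rows$y[rows$group == g1],
                              rows$y[rows$group == g2], "-")))
      expect_gte(gapmin, 12)
    }
  }
  # determinism
  expect_identical(grid, compute_grid(sch, 5, cfg))
  expect_error(compute_grid(sch, 1, cfg), "at least 2 columns")
})

test_that("ribbon weights are strictly proportional to pair frequency", {
  cfg <- diagram_config(max_ribbon_weight = 10)
  g <- toy_group()
  tt <- filter_transitions(transition_frequencies(g, sch), 0)
  grid <- compute_grid(sch, g$n_columns, cfg)
  layout <- compute_ribbons(list(tt), grid, cfg)
  rb <- layout$ribbons
  expect_equal(rb$weight[rb$freq == 0.75], 7.5)
  expect_equal(rb$weight[rb$freq == 0.25], 2.5)
  # endpoint: frequency 1.0 maps to max_ribbon_weight
  one <- alignment_group(c("KA", "KA"), "one")
  lo <- compute_ribbons(list(transition_frequencies(one, sch)), grid, cfg)
  expect_equal(lo$ribbons$weight, 10)
  # pairwise ratios equal frequency ratios
  set.seed(41)
  gr <- random_group(30, 6, alphabet = c("A", "C", "D"))
  t2 <- transition_frequencies(gr, flat_scheme(c("A", "C", "D")))
  l2 <- compute_ribbons(list(t2),
                        compute_grid(flat_scheme(c("A", "C", "D")), 6, cfg),
                        cfg)
  w <- l2$ribbons$weight
  f <- l2$ribbons$freq
  expect_true(all(abs(outer(w, w, "/") - outer(f, f, "/")) < 1e-9))
  expect_true(all(w > 0 & w <= 10))
})

test_that("same-row transitions are horizontal and geometry lands on nodes", {
  cfg <- diagram_config()
  g <- alignment_group(c("AA", "AC"), "g")
  scheme <- flat_scheme(c("A", "C"))
  grid <- compute_grid(scheme, 2, cfg)
  layout <- compute_ribbons(list(transition_frequencies(g, scheme)), grid, cfg)
  aa <- layout$ribbons[layout$ribbons$from == "A" & layout$ribbons$to == "A", ]
  expect_equal(aa$y0, aa$y1)  # horizontal path
  expect_equal(aa$x0, unname(grid$x[1]))
  expect_equal(aa$x1, unname(grid$x[2]))
  expect_equal(aa$cx, mean(grid$x))
})

test_that("filtered-out pairs never appear as ribbons", {
  set.seed(42)
  g <- random_group(50, 8, alphabet = LETTERS[1:4])
  scheme <- flat_scheme(LETTERS[1:4])
  cfg <- diagram_config(filter_threshold = 0.05)
  tt <- transition_frequencies(g, scheme)
  ft <- filter_transitions(tt, 0.05)
  layout <- compute_ribbons(list(ft), compute_grid(scheme, 8, cfg), cfg)
  key <- function(df) paste(df$column, df$from, df$to)
  expect_setequal(key(layout$ribbons), key(ft$pairs))
  removed <- setdiff(key(tt$pairs), key(ft$pairs))
  expect_length(intersect(key(layout$ribbons), removed), 0)
})

test_that("two groups with identical tables differ only in label and color", {
  cfg <- diagram_config()
  ga <- toy_group("a")
  gb <- toy_group("b")
  grid <- compute_grid(sch, 2, cfg)
  layout <- compute_ribbons(
    list(transition_frequencies(ga, sch), transition_frequencies(gb, sch)),
    grid, cfg
  )
  ra <- layout$ribbons[layout$ribbons$group == "a",
                       !(names(layout$ribbons) %in% c("group", "color"))]
  rb <- layout$ribbons[layout$ribbons$group == "b",
                       !(names(layout$ribbons) %in% c("group", "color"))]
  expect_equal(ra, rb, ignore_attr = TRUE)
  expect_false(any(layout$ribbons$color[layout$ribbons$group == "a"] %in%
                     layout$ribbons$color[layout$ribbons$group == "b"]))
})

test_that("ribbons are ordered group-major then ascending weight", {
  set.seed(43)
  scheme <- flat_scheme(LETTERS[1:5])
  cfg <- diagram_config()
  g1 <- random_group(30, 6, alphabet = LETTERS[1:5], label = "g1")
  g2 <- random_group(30, 6, alphabet = LETTERS[1:5], label = "g2")
  layout <- compute_ribbons(
    lapply(list(g1, g2), transition_frequencies, scheme = scheme),
    compute_grid(scheme, 6, cfg), cfg
  )
  rb <- layout$ribbons
  expect_equal(rle(rb$group)$values, c("g1", "g2"))
  for (lab in c("g1", "g2")) {
    expect_true(!is.unsorted(rb$weight[rb$group == lab]))
  }
})

test_that("masking suppresses ribbons touching masked positions", {
  cfg <- diagram_config(masked_positions = c(2L))
  g <- alignment_group(c("KAD", "KAD"), "g")
  tt <- transition_frequencies(g, sch)
  layout <- compute_ribbons(list(tt), compute_grid(sch, 3, cfg), cfg)
  # pairs (1,2) and (2,3) both touch position 2
  expect_equal(nrow(layout$ribbons), 0)
  cfg3 <- diagram_config(masked_positions = 3L)
  l3 <- compute_ribbons(list(tt), compute_grid(sch, 3, cfg3), cfg3)
  expect_equal(l3$ribbons$column, 1)
})

test_that("residues outside the scheme are rejected at layout time", {
  g <- alignment_group(c("KA", "KA"), "g")
  tt <- transition_frequencies(g, sch)
  small <- flat_scheme(c("A", "C"))
  expect_error(
    compute_ribbons(list(tt), compute_grid(small, 2, diagram_config()),
                    diagram_config()),
    "unmapped residue", class = "sdd_bad_config"
  )
})
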