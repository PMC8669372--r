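test_that("judgment scale has non-decreasing modes and valid triples", {
  s <- ahp_scale()
  expect_equal(nrow(s), 9)
  expect_true(all(diff(s$m) >= 0))
  expect_true(all(s$l <= s$m & s$m <= s$u))
})

test_that("comparison matrix fills diagonal and reciprocals, validates pairs", {
  M <- build_comparison_matrix(
    data.frame(i = 1, j = 2, label = "Equal important"), c("c1", "c2"))
  expect_equal(M$entries[1, 1, ], c(l = 1, m = 1, u = 1))
  expect_equal(M$entries[2, 1, ], c(l = 1, m = 1, u = 1))

  M2 <- build_comparison_matrix(
    data.frame(i = 1, j = 2, label = "Moderate important"), c("c1", "c2"))
  expect_equal(unname(M2$entries[2, 1, ]), c(0.25, 1 / 3, 0.5))

  expect_error(build_comparison_matrix(
    data.frame(i = 1, j = 2, label = "Equal important"), paste0("c", 1:3)),
    "2:3")
  expect_error(build_comparison_matrix(
    data.frame(i = c(1, 2), j = c(2, 1), label = rep("Equal important", 2)),
    c("c1", "c2")), "duplicate")
  expect_error(build_comparison_matrix(
    data.frame(i = 1, j = 2, label = "sorta important"), c("c1", "c2")),
    "unknown judgment label")
})

test_that("fuzzy geometric means match hand values and keep ordering", {
  n <- 4
  M <- build_comparison_matrix(
    data.frame(i = utils::combn(n, 2)[1, ], j = utils::combn(n, 2)[2, ],
               label = "Equal important"), paste0("c", 1:n))
  r <- fuzzy_geometric_means(M)
  expect_equal(unclass(r), unclass(tfn(rep(1, n), rep(1, n), rep(1, n))),
               ignore_attr = TRUE)

  M2 <- build_comparison_matrix(
    data.frame(i = 1, j = 2, label = "Moderate important"), c("c1", "c2"))
  r2 <- unclass(fuzzy_geometric_means(M2))
  expect_equal(unname(r2[1, ]), c(sqrt(2), sqrt(3), 2), tolerance = 1e-12)
  expect_true(all(r2[, 1] <= r2[, 2] & r2[, 2] <= r2[, 3]))
})

test_that("fuzzy weights follow r_i x (sum r)^-1", {
  # single criterion: w = r x r^-1 = (l/u, 1, u/l)
  w1 <- unclass(fuzzy_weights(tfn(2, 3, 4)))
  expect_equal(unname(w1[1, ]), c(0.5, 1, 2))

  w4 <- unclass(fuzzy_weights(tfn(rep(1, 4), rep(1, 4), rep(1, 4))))
  expect_equal(unname(w4), matrix(0.25, 4, 3))

  M2 <- build_comparison_matrix(
    data.frame(i = 1, j = 2, label = "Moderate important"), c("c1", "c2"))
  w <- unclass(fuzzy_weights(fuzzy_geometric_means(M2)))
  expect_equal(unname(w[1, ]), c(0.5224, 0.75, 1.0448), tolerance = 1e-4)
})

test_that("normalized crisp weights sum to one and match hand values", {
  ident31 <- tfn(rep(1, 31), rep(1, 31), rep(1, 31))
  wv <- normalized_crisp_weights(fuzzy_weights(ident31))
  expect_equal(wv$normalized, rep(1 / 31, 31))
  expect_equal(sum(wv$normalized), 1, tolerance = 1e-9)

  M2 <- build_comparison_matrix(
    data.frame(i = 1, j = 2, label = "Moderate important"), c("c1", "c2"))
  wv2 <- fuzzy_ahp(data.frame(i = 1, j = 2, label = "Moderate important"),
                   c("c1", "c2"))
  expect_equal(wv2$normalized, c(0.742, 0.258), tolerance = 1e-3)
})

test_that("shipped default weights cover the instrument and sum to 0.997", {
  w <- default_criterion_weights()
  inst <- default_instrument()
  expect_setequal(names(w), inst$criteria$id)
  expect_equal(sum(w), 0.997)       # printed three-decimal rounding
  expect_equal(unname(w["C11"]), 0.074)
  expect_equal(unname(w["C45"]), 0.006)
})

test_that("weights are permutation-equivariant and reward dominance", {
  n <- 4
  j <- random_judgments(n, seed = 21)
  crit <- paste0("c", 1:n)
  w <- fuzzy_ahp(j, crit)
  perm <- c(3, 1, 4, 2)
  jp <- data.frame(i = crit[perm][match(j$i, seq_len(n))],
                   j = crit[perm][match(j$j, seq_len(n))], label = j$label)
  wp <- fuzzy_ahp(jp, crit)
  expect_equal(wp$normalized[match(crit[perm], wp$criterion)],
               w$normalized, tolerance = 1e-12)

  # one criterion extremely preferred over every other
  pairs <- utils::combn(n, 2)
  lab <- ifelse(pairs[1, ] == 1, "Extreme important", "Equal important")
  wd <- fuzzy_ahp(data.frame(i = pairs[1, ], j = pairs[2, ], label = lab),
                  crit)
  expect_equal(which.max(wd$normalized), 1L)
  expect_true(wd$normalized[1] > max(wd$normalized[-1]))
})

test_that("pipeline matches the brute-force oracle for n <= 4", {
  for (n in 2:4) for (s in 1:3) {
    j <- random_judgments(n, seed = 100 * n + s)
    crit <- paste0("c", 1:n)
    M <- build_comparison_matrix(j, crit)
    w <- normalized_crisp_weights(fuzzy_weights(fuzzy_geometric_means(M)),
                                  crit)
    o <- oracle_ahp(M$entries)
    expect_equal(cbind(w$fuzzy_l, w$fuzzy_m, w$fuzzy_u), o$fuzzy,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(w$crisp, o$crisp, tolerance = 1e-12)
    expect_equal(w$normalized, o$normalized, tolerance = 1e-12)
  }
})

test_that("consistency ratio is zero for a perfectly consistent matrix", {
  n <- 4
  pairs <- utils::combn(n, 2)
  M <- build_comparison_matrix(
    data.frame(i = pairs[1, ], j = pairs[2, ], label = "Equal important"),
    paste0("c", 1:n))
  expect_equal(consistency_ratio(M), 0, tolerance = 1e-10)
  w <- fuzzy_ahp(data.frame(i = pairs[1, ], j = pairs[2, ],
                            label = "Equal important"),
                 paste0("c", 1:n), check_consistency = TRUE)
  expect_equal(attr(w, "cr"), 0, tolerance = 1e-10)
})

test_that("judgments round-trip through a YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("criteria: [c1, c2, c3]",
               "judgments:",
               "  - {i: c1, j: c2, label: Moderate important}",
               "  - {i: c1, j: c3, label: Strong important}",
               "  - {i: c2, j: c3, label: Equal important}"), path)
  cfg <- read_judgments(path)
  expect_equal(cfg$criteria, c("c1", "c2", "c3"))
  w <- fuzzy_ahp(cfg$judgments, cfg$criteria)
  expect_equal(sum(w$normalized), 1, tolerance = 1e-9)
  out <- withr::local_tempfile(fileext = ".csv")
  write_weights_csv(w, out)
  expect_equal(utils::read.csv(out)$normalized, w$normalized,
               tolerance = 1e-6)
})
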