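test_that("rating scales carry the declared triples", {
  rs <- rating_scale()
  expect_equal(rs$label, c("VL", "L", "M", "H", "VH"))
  expect_true(all(diff(rs$m) > 0))
  expect_equal(unclass(rating_tfn("VL")), unclass(tfn(0, 0, 0.2)),
               ignore_attr = TRUE)
  ws <- relevance_scale()
  expect_equal(unclass(rating_tfn("VHR", ws)), unclass(tfn(8, 9, 10)),
               ignore_attr = TRUE)
  expect_error(rating_tfn("XX"), "unknown rating label")
})

test_that("decision-maker aggregation is min/mean/max", {
  a <- random_ratings(2, 3, seed = 1)
  expect_equal(aggregate_ratings(list(a)), a)           # K = 1 identity
  expect_equal(aggregate_ratings(list(a, a, a)), a)     # idempotent

  h <- unclass(rating_tfn("H")); m <- unclass(rating_tfn("M"))
  cell <- function(v) array(v, dim = c(1, 1, 3))
  agg <- aggregate_ratings(list(cell(h), cell(h), cell(m)))
  expect_equal(as.numeric(agg), c(0.4, mean(c(0.7, 0.7, 0.5)), 0.8),
               tolerance = 1e-12)

  # aggregate lower bound never exceeds any input lower
  b <- random_ratings(2, 3, seed = 2)
  g <- aggregate_ratings(list(a, b))
  expect_true(all(g[, , 1] <= a[, , 1] & g[, , 1] <= b[, , 1]))
  expect_error(aggregate_ratings(list(a, random_ratings(3, 3, seed = 3))),
               "shape")

  w <- aggregate_weights(list(rating_tfn("VHR", relevance_scale()),
                              rating_tfn("HR", relevance_scale())))
  expect_equal(unclass(w), unclass(tfn(6, 8, 10)), ignore_attr = TRUE)
})

test_that("normalization divides by the column max upper", {
  r <- array(c(0.6, 0.7, 0.8), dim = c(1, 1, 3))
  D <- decision_matrix(r, weights = tfn(1))
  N <- normalize_matrix(D)
  expect_equal(as.numeric(N$ratings), c(0.75, 0.875, 1))
  # already-normalized column is a fixed point
  expect_equal(normalize_matrix(N)$ratings, N$ratings)
  # identical alternatives all reach upper 1
  r2 <- array(rep(c(0.2, 0.3, 0.4), each = 3), dim = c(3, 1, 3))
  N2 <- normalize_matrix(decision_matrix(r2, weights = tfn(1)))
  expect_true(all(N2$ratings[, , 3] == 1))
  r0 <- array(0, dim = c(2, 1, 3))
  expect_error(normalize_matrix(decision_matrix(r0, weights = tfn(1))),
               "zero column maximum")
})

test_that("weighting multiplies cells by the criterion weight", {
  r <- array(c(0.75, 0.875, 1), dim = c(1, 1, 3))
  D <- decision_matrix(r, weights = 0.074)   # crisp promoted to (w, w, w)
  V <- weight_matrix(D)
  expect_equal(as.numeric(V$ratings), c(0.0555, 0.06475, 0.074))
  expect_equal(weight_matrix(decision_matrix(r, weights = tfn(1)))$ratings, r,
               ignore_attr = TRUE)
})

test_that("ideal solutions bracket the weighted matrix", {
  r <- array(c(0.75, 0.25, 0.875, 0.375, 1, 0.5), dim = c(2, 1, 3))
  V <- decision_matrix(r, weights = tfn(1))
  ideals <- ideal_solutions(V)
  expect_equal(as.numeric(ideals$fpis), 1)
  expect_equal(as.numeric(ideals$fnis), 0.25)
  expect_true(all(ideals$fpis >= ideals$fnis))
  expect_error(ideal_solutions(decision_matrix(
    array(r[1, , , drop = FALSE], c(1, 1, 3)), weights = tfn(1))),
    "two alternatives")
})

test_that("separation distances and closeness match the hand-worked toy", {
  r <- array(c(0.75, 0.25, 0.875, 0.375, 1, 0.5), dim = c(2, 1, 3),
             dimnames = list(c("A", "B"), "C1", c("l", "m", "u")))
  V <- decision_matrix(r, weights = tfn(1))
  prof <- separation_distances(V, ideal_solutions(V))
  expect_equal(prof$d_star, c(0.1614, 0.6333), tolerance = 1e-4)
  expect_equal(prof$d_minus, c(0.6333, 0.1614), tolerance = 1e-4)
  prof <- closeness_coefficients(prof)
  expect_equal(prof$cc, c(0.797, 0.203), tolerance = 1e-3)
  expect_equal(sum(prof$cc), 1, tolerance = 1e-12)  # symmetric pair
  expect_equal(rank_alternatives(prof), c("A", "B"))
})

test_that("alternative equal to FPIS has zero d* and unit closeness", {
  r <- array(c(1, 0.2, 1, 0.3, 1, 0.4), dim = c(2, 1, 3))
  V <- decision_matrix(r, weights = tfn(1))
  prof <- closeness_coefficients(
    separation_distances(V, ideal_solutions(V)))
  expect_equal(prof$d_star[1], 0)
  expect_equal(prof$cc[1], 1)
})

test_that("degenerate single-point configuration errors", {
  r <- array(rep(0.5, 6), dim = c(2, 1, 3))
  V <- decision_matrix(r, weights = tfn(1))
  prof <- separation_distances(V, ideal_solutions(V))
  expect_error(closeness_coefficients(prof), "degenerate")
})

test_that("ties in ranking break by declared alternative order", {
  prof <- structure(data.frame(alternative = c("P1", "P2", "P3"),
                               d_star = c(1, 1, 1), d_minus = c(1, 1, 1),
                               cc = 0.5),
                    class = c("separation_profile", "data.frame"))
  expect_equal(rank_alternatives(prof), c("P1", "P2", "P3"))
})

test_that("closeness is invariant to uniform positive weight scaling", {
  ratings <- random_ratings(3, 4, seed = 5)
  w <- c(0.4, 0.3, 0.2, 0.1)
  cc1 <- fuzzy_topsis(decision_matrix(ratings, w))$profile$cc
  cc2 <- fuzzy_topsis(decision_matrix(ratings, 7.3 * w))$profile$cc
  expect_equal(cc1, cc2, tolerance = 1e-12)
})

test_that("pipeline matches the brute-force oracle up to 3 x 3", {
  for (m in 2:3) for (n in 1:3) for (s in 1:3) {
    ratings <- random_ratings(m, n, seed = 10 * m + n + s)
    set.seed(s)
    w <- unclass(rtfn(n, min = 0.05, max = 1))
    res <- fuzzy_topsis(decision_matrix(ratings, tfn(w[, 1], w[, 2], w[, 3])))
    o <- oracle_topsis(ratings, w)
    expect_equal(res$profile$d_star, o$d_star, tolerance = 1e-12)
    expect_equal(res$profile$d_minus, o$d_minus, tolerance = 1e-12)
    expect_equal(res$profile$cc, o$cc, tolerance = 1e-12)
    expect_true(all(res$profile$cc >= 0 & res$profile$cc <= 1))
  }
})

test_that("audit CSV export carries distances, cc and rank", {
  res <- fuzzy_topsis(decision_matrix(random_ratings(3, 2, seed = 9),
                                      c(0.6, 0.4)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_topsis_csv(res, path)
  out <- utils::read.csv(path)
  expect_equal(out$alternative[out$rank == 1], res$ranking[1])
  expect_equal(out$cc, res$profile$cc, tolerance = 1e-6)
})
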