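# Independent brute-force oracles written directly from the defining
# formulas, plus small fixture builders. These never call the package's
# pipeline functions.

# random valid TFN vector (sorted uniform triples)
rtfn <- function(n, min = 0, max = 1) {
  v <- matrix(stats::runif(3 * n, min, max), n, 3)
  v <- t(apply(v, 1, sort))
  tfn(v[, 1], v[, 2], v[, 3])
}

# direct transliteration of the AHP weight chain: fuzzy geometric row
# means, fuzzy weights against the reciprocal of their sum, centre-of-area
# defuzzification, normalization. Input: n x n x 3 array.
oracle_ahp <- function(e) {
  n <- dim(e)[1]
  r <- matrix(NA_real_, n, 3)
  for (i in 1:n) for (k in 1:3) r[i, k] <- prod(e[i, , k])^(1 / n)
  s <- colSums(r)
  w <- cbind(r[, 1] / s[3], r[, 2] / s[2], r[, 3] / s[1])
  crisp <- rowMeans(w)
  list(fuzzy = w, crisp = crisp, normalized = crisp / sum(crisp))
}

# direct transliteration of the ranking chain: linear-scale normalization,
# weighting, ideal solutions, vertex distances, closeness coefficients.
# ratings: m x n x 3 array; w: n x 3 matrix of fuzzy weights.
oracle_topsis <- function(ratings, w) {
  m <- dim(ratings)[1]; n <- dim(ratings)[2]
  v <- array(NA_real_, dim(ratings))
  for (j in 1:n) {
    cst <- max(ratings[, j, 3])
    for (i in 1:m) for (k in 1:3) v[i, j, k] <- ratings[i, j, k] / cst * w[j, k]
  }
  fpis <- numeric(n); fnis <- numeric(n)
  for (j in 1:n) { fpis[j] <- max(v[, j, 3]); fnis[j] <- min(v[, j, 1]) }
  dv <- function(x, c) sqrt(((x[1] - c)^2 + (x[2] - c)^2 + (x[3] - c)^2) / 3)
  d_star <- numeric(m); d_minus <- numeric(m)
  for (i in 1:m) for (j in 1:n) {
    d_star[i] <- d_star[i] + dv(v[i, j, ], fpis[j])
    d_minus[i] <- d_minus[i] + dv(v[i, j, ], fnis[j])
  }
  list(d_star = d_star, d_minus = d_minus, cc = d_minus / (d_star + d_minus))
}

# random full judgment set over n criteria
random_judgments <- function(n, seed) {
  set.seed(seed)
  pairs <- utils::combn(n, 2)
  data.frame(i = pairs[1, ], j = pairs[2, ],
             label = sample(ahp_scale()$label, ncol(pairs), replace = TRUE),
             stringsAsFactors = FALSE)
}

# random ratings array from the linguistic rating scale
random_ratings <- function(n_alt, n_crit, seed) {
  set.seed(seed)
  labs <- matrix(sample(rating_scale()$label, n_alt * n_crit, replace = TRUE),
                 n_alt, n_crit)
  v <- unclass(rating_tfn(as.vector(labs)))
  array(c(v[, 1], v[, 2], v[, 3]), dim = c(n_alt, n_crit, 3))
}

# tiny hand-built labelled cohort (3 subjects) in instrument vocabulary
toy_cohort_df <- function() {
  inst <- default_instrument()
  pick <- function(k) vapply(inst$levels, `[[`, character(1), k)
  df <- as.data.frame(rbind(pick(5), pick(1), pick(3)),
                      stringsAsFactors = FALSE)
  names(df) <- inst$criteria$id
  df$subject_id <- c("a", "b", "c")
  df$label <- c("A1", "A4", "A3")
  df
}

# answer sheet at one uniform level index for every criterion
uniform_sheet <- function(k) {
  inst <- default_instrument()
  df <- as.data.frame(as.list(vapply(inst$levels, `[[`, character(1), k)),
                      stringsAsFactors = FALSE, col.names = inst$criteria$id)
  df$subject_id <- "s1"
  df
}

# four well-separated ordinal clusters for classifier checks
separable_clusters <- function(n_per = 15, p = 8, seed = 1) {
  set.seed(seed)
  centers <- rbind(rep(0, p), rep(4, p),
                   c(rep(0, p / 2), rep(4, p / 2)),
                   c(rep(4, p / 2), rep(0, p / 2)))
  x <- do.call(rbind, lapply(1:4, function(c)
    matrix(centers[c, ], n_per, p, byrow = TRUE) +
      matrix(sample(0:1, n_per * p, TRUE), n_per, p)))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c("A1", "A2", "A3", "A4"), each = n_per))
}
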