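#' Linguistic rating scales for alternatives and criterion relevance
#'
#' `rating_scale()` returns the five-point scale used to rate alternatives:
#' Very Low (0, 0, 0.2), Low (0.2, 0.3, 0.4), Medium (0.4, 0.5, 0.6),
#' High (0.6, 0.7, 0.8), Very High (0.8, 0.9, 1). `relevance_scale()` is the
#' analogous scale for the importance weight of a criterion: Very Less
#' Relevant (0, 0, 2) up to Very High Relevant (8, 9, 10).
#'
#' @return A data frame with columns `label`, `l`, `m`, `u`, modes strictly
#'   increasing.
#' @export
rating_scale <- function() {
  data.frame(label = c("VL", "L", "M", "H", "VH"),
             l = c(0, 0.2, 0.4, 0.6, 0.8),
             m = c(0, 0.3, 0.5, 0.7, 0.9),
             u = c(0.2, 0.4, 0.6, 0.8, 1),
             stringsAsFactors = FALSE)
}

#' @rdname rating_scale
#' @export
relevance_scale <- function() {
  data.frame(label = c("VLR", "LR", "R", "HR", "VHR"),
             l = c(0, 2, 4, 6, 8),
             m = c(0, 3, 5, 7, 9),
             u = c(2, 4, 6, 8, 10),
             stringsAsFactors = FALSE)
}

#' Resolve rating labels to triangular fuzzy numbers
#'
#' @param labels Character vector of scale labels.
#' @param scale A scale data frame ([rating_scale()] or [relevance_scale()]).
#' @return A `tfn` vector.
#' @export
rating_tfn <- function(labels, scale = rating_scale()) {
  idx <- match(labels, scale$label)
  if (anyNA(idx))
    stop("unknown rating label(s): ",
         paste(sQuote(unique(labels[is.na(idx)])), collapse = ", "),
         call. = FALSE)
  tfn(scale$l[idx], scale$m[idx], scale$u[idx])
}

# internal: validate an alternatives x criteria x 3 ratings array
check_ratings_array <- function(ratings) {
  if (!is.array(ratings) || length(dim(ratings)) != 3L || dim(ratings)[3L] != 3L)
    stop("ratings must be an alternatives x criteria x 3 array", call. = FALSE)
  if (anyNA(ratings)) stop("ratings array has missing cells", call. = FALSE)
  invisible(ratings)
}

#' Construct a fuzzy decision matrix
#'
#' Bundles the aggregated fuzzy ratings \eqn{\tilde y_{ij}} (alternatives in
#' rows, criteria in columns) with the per-criterion fuzzy weights
#' \eqn{\tilde w_j}. Crisp weights are promoted to degenerate TFNs.
#'
#' @param ratings An `n_alt x n_crit x 3` numeric array of TFN components,
#'   or a matrix of rating labels resolved through `scale`.
#' @param weights A `tfn` vector of length `n_crit`, or a crisp numeric
#'   vector.
#' @param alternatives,criteria Identifiers; taken from dimnames if missing.
#' @param scale Rating scale used when `ratings` is a label matrix.
#' @return A `decision_matrix` object.
#' @export
decision_matrix <- function(ratings, weights, alternatives = NULL,
                            criteria = NULL, scale = rating_scale()) {
  if (is.matrix(ratings) && is.character(ratings)) {
    lab <- ratings
    v <- unclass(rating_tfn(as.vector(lab), scale))
    ratings <- array(c(v[, 1L], v[, 2L], v[, 3L]),
                     dim = c(nrow(lab), ncol(lab), 3L),
                     dimnames = c(dimnames(lab), list(c("l", "m", "u"))))
  }
  check_ratings_array(ratings)
  n_alt <- dim(ratings)[1L]
  n_crit <- dim(ratings)[2L]
  if (is.null(alternatives))
    alternatives <- dimnames(ratings)[[1L]] %||% paste0("A", seq_len(n_alt))
  if (is.null(criteria))
    criteria <- dimnames(ratings)[[2L]] %||% paste0("C", seq_len(n_crit))
  weights <- as_tfn(weights)
  if (length(weights) != n_crit)
    stop("need one weight per criterion", call. = FALSE)
  dimnames(ratings) <- list(alternatives, criteria, c("l", "m", "u"))
  structure(list(alternatives = alternatives, criteria = criteria,
                 ratings = ratings, weights = weights),
            class = "decision_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decision_matrix <- function(x, ...) {
  r <- x$ratings
  cat("<decision_matrix> ", length(x$alternatives), " alternatives x ",
      length(x$criteria), " criteria\n", sep = "")
  out <- matrix(sprintf("(%.3g,%.3g,%.3g)", r[, , 1L], r[, , 2L], r[, , 3L]),
                dim(r)[1L], dim(r)[2L], dimnames = dimnames(r)[1:2])
  print(noquote(out))
  cat("weights:\n")
  print(x$weights)
  invisible(x)
}

#' Aggregate multiple decision-makers' fuzzy ratings
#'
#' For K decision-makers the aggregate of TFNs \eqn{(m_k, n_k, o_k)} is
#' \eqn{(\min_k m_k,\; \frac{1}{K}\sum_k n_k,\; \max_k o_k)}: pessimistic in
#' the lower support, average in the mode, optimistic in the upper support.
#' `aggregate_ratings()` applies this cell-wise to K ratings arrays;
#' `aggregate_weights()` applies it criterion-wise to K weight vectors.
#'
#' @param per_dm A list of K `n_alt x n_crit x 3` arrays (ratings) or K
#'   `tfn` vectors (weights).
#' @return A single array / `tfn` vector of the same shape.
#' @export
aggregate_ratings <- function(per_dm) {
  if (!length(per_dm)) stop("need at least one decision-maker", call. = FALSE)
  lapply(per_dm, check_ratings_array)
  d <- dim(per_dm[[1L]])
  if (!all(vapply(per_dm, function(x) identical(dim(x), d), logical(1L))))
    stop("ratings arrays differ in shape", call. = FALSE)
  l <- Reduce(pmin, lapply(per_dm, function(x) x[, , 1L, drop = FALSE]))
  m <- Reduce(`+`, lapply(per_dm, function(x) x[, , 2L, drop = FALSE])) / length(per_dm)
  u <- Reduce(pmax, lapply(per_dm, function(x) x[, , 3L, drop = FALSE]))
  out <- array(c(l, m, u), dim = d, dimnames = dimnames(per_dm[[1L]]))
  out
}

#' @rdname aggregate_ratings
#' @export
aggregate_weights <- function(per_dm) {
  if (!length(per_dm)) stop("need at least one decision-maker", call. = FALSE)
  ws <- lapply(per_dm, function(w) unclass(as_tfn(w)))
  n <- nrow(ws[[1L]])
  if (!all(vapply(ws, nrow, integer(1L)) == n))
    stop("weight vectors differ in length", call. = FALSE)
  l <- Reduce(pmin, lapply(ws, function(w) w[, 1L]))
  m <- Reduce(`+`, lapply(ws, function(w) w[, 2L])) / length(ws)
  u <- Reduce(pmax, lapply(ws, function(w) w[, 3L]))
  tfn(l, m, u)
}

#' Linear-scale normalization of a fuzzy decision matrix
#'
#' Benefit-criterion normalization: every cell of column \eqn{j} is divided
#' component-wise by \eqn{c_j^* = \max_i u_{ij}}, the column's largest upper
#' support, so all normalized uppers lie in (0, 1] with at least one exactly
#' 1 per column.
#'
#' @param D A `decision_matrix`.
#' @return The normalized `decision_matrix`.
#' @export
normalize_matrix <- function(D) {
  r <- D$ratings
  cmax <- apply(r[, , 3L, drop = FALSE], 2L, max)
  if (any(cmax <= 0)) {
    bad <- D$criteria[cmax <= 0]
    stop("zero column maximum for criterion: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (k in 1:3) r[, , k] <- sweep(r[, , k, drop = FALSE], 2L, cmax, "/")
  D$ratings <- r
  D
}

#' Apply criterion weights to a normalized decision matrix
#'
#' Each normalized cell is multiplied component-wise by its criterion's
#' fuzzy weight, giving the weighted normalized matrix \eqn{\tilde v_{ij}}.
#'
#' @param D A normalized `decision_matrix`.
#' @return The weighted `decision_matrix`.
#' @export
weight_matrix <- function(D) {
  w <- unclass(D$weights)
  r <- D$ratings
  for (k in 1:3) r[, , k] <- sweep(r[, , k, drop = FALSE], 2L, w[, k], "*")
  D$ratings <- r
  D
}

#' Fuzzy positive and negative ideal solutions
#'
#' Per criterion, the FPIS is the largest upper support over alternatives
#' and the FNIS the smallest lower support; both are crisp scalars promoted
#' to degenerate TFNs when distances are taken.
#'
#' @param V A weighted `decision_matrix` with at least two alternatives.
#' @return List with numeric vectors `fpis` and `fnis` (one per criterion).
#' @export
ideal_solutions <- function(V) {
  if (length(V$alternatives) < 2L)
    stop("ideal solutions need at least two alternatives", call. = FALSE)
  r <- V$ratings
  list(fpis = apply(r[, , 3L, drop = FALSE], 2L, max),
       fnis = apply(r[, , 1L, drop = FALSE], 2L, min))
}

#' Separation of each alternative from the ideal solutions
#'
#' \eqn{d_i^* = \sum_j d_v(\tilde v_{ij}, \tilde a_j^*)} and
#' \eqn{d_i^- = \sum_j d_v(\tilde v_{ij}, \tilde a_j^-)}: per alternative,
#' the vertex distances to the (degenerate-TFN) ideals summed over criteria.
#'
#' @param V A weighted `decision_matrix`.
#' @param ideals Output of [ideal_solutions()].
#' @return A `separation_profile` data frame: one row per alternative with
#'   `d_star` and `d_minus` (and `cc` = `NA` until
#'   [closeness_coefficients()] fills it).
#' @export
separation_distances <- function(V, ideals) {
  r <- V$ratings
  n_crit <- dim(r)[2L]
  if (length(ideals$fpis) != n_crit || length(ideals$fnis) != n_crit)
    stop("ideal vectors do not match criterion count", call. = FALSE)
  dist_to <- function(target) {
    # target: crisp per-criterion scalar promoted to (c, c, c)
    sq <- (sweep(r[, , 1L, drop = FALSE], 2L, target, "-"))^2 +
          (sweep(r[, , 2L, drop = FALSE], 2L, target, "-"))^2 +
          (sweep(r[, , 3L, drop = FALSE], 2L, target, "-"))^2
    rowSums(sqrt(sq[, , 1L, drop = FALSE] / 3), dims = 1L)
  }
  structure(
    data.frame(alternative = V$alternatives,
               d_star = as.numeric(dist_to(ideals$fpis)),
               d_minus = as.numeric(dist_to(ideals$fnis)),
               cc = NA_real_, stringsAsFactors = FALSE, row.names = NULL),
    class = c("separation_profile", "data.frame"))
}

#' Closeness coefficients
#'
#' \eqn{CC_i = d_i^- / (d_i^* + d_i^-)}: 1 when the alternative sits on the
#' positive ideal, 0 when it sits on the negative ideal.
#'
#' @param profile A `separation_profile`.
#' @return The profile with `cc` filled.
#' @export
closeness_coefficients <- function(profile) {
  tot <- profile$d_star + profile$d_minus
  if (any(tot <= 0))
    stop("degenerate separation: d* + d- is zero for alternative ",
         paste(profile$alternative[tot <= 0], collapse = ", "), call. = FALSE)
  profile$cc <- profile$d_minus / tot
  profile
}

#' Rank alternatives by closeness coefficient
#'
#' Alternatives in decreasing closeness-coefficient order; ties broken by
#' the declared alternative order. The first element is the selected level.
#'
#' @param profile A `separation_profile` with `cc` filled.
#' @return Character vector of alternative identifiers, best first.
#' @export
rank_alternatives <- function(profile) {
  if (anyNA(profile$cc)) stop("closeness coefficients not computed", call. = FALSE)
  profile$alternative[order(-profile$cc, seq_len(nrow(profile)))]
}

#' Rank alternatives by fuzzy TOPSIS
#'
#' Runs the ranking chain on a fuzzy decision matrix: linear-scale
#' normalization, weighting, fuzzy positive/negative ideal solutions, vertex
#' separation distances and closeness coefficients.
#'
#' @param D A `decision_matrix` (raw aggregated ratings + weights).
#' @return A `topsis_result`: list with the weighted matrix `weighted`,
#'   `ideals`, the `separation_profile` `profile`, and `ranking` (best
#'   first).
#' @examples
#' labs <- matrix(c("VH", "VL", "H", "L"), 2, 2,
#'                dimnames = list(c("high", "normal"), c("C1", "C2")))
#' res <- fuzzy_topsis(decision_matrix(labs, weights = c(0.6, 0.4)))
#' res$ranking
#' @export
fuzzy_topsis <- function(D) {
  V <- weight_matrix(normalize_matrix(D))
  ideals <- ideal_solutions(V)
  profile <- closeness_coefficients(separation_distances(V, ideals))
  structure(list(weighted = V, ideals = ideals, profile = profile,
                 ranking = rank_alternatives(profile)),
            class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, digits = 4, ...) {
  cat("<topsis_result> ranking: ", paste(x$ranking, collapse = " > "), "\n",
      sep = "")
  print.data.frame(x$profile, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Export a separation profile for audit
#'
#' One row per alternative with distances, closeness coefficient and rank.
#'
#' @param result A `topsis_result`.
#' @param path Output CSV path.
#' @export
write_topsis_csv <- function(result, path) {
  p <- result$profile
  p$rank <- match(p$alternative, result$ranking)
  utils::write.csv(p, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
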