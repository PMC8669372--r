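#' Linguistic scale for pairwise importance judgments
#'
#' The nine Saaty-style intensities and their triangular fuzzy numbers used
#' to fill the pairwise comparison matrix: "Equal important" (1,1,1),
#' "Moderate important" (2,3,4), "Strong important" (4,5,6), "Very strong
#' important" (6,7,8), "Extreme important" (9,9,9), with the intermediate
#' intensities 2 (1,2,3), 4 (3,4,5), 6 (5,6,7) and 8 (7,8,9). The inverse of
#' a judgment is the TFN reciprocal.
#'
#' @return A data frame with columns `label`, `intensity`, `l`, `m`, `u`,
#'   ordered by intensity.
#' @export
ahp_scale <- function() {
  data.frame(
    label = c("Equal important", "Intermediate 2", "Moderate important",
              "Intermediate 4", "Strong important", "Intermediate 6",
              "Very strong important", "Intermediate 8", "Extreme important"),
    intensity = 1:9,
    l = c(1, 1, 2, 3, 4, 5, 6, 7, 9),
    m = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
    u = c(1, 3, 4, 5, 6, 7, 8, 9, 9),
    stringsAsFactors = FALSE
  )
}

scale_lookup <- function(labels, scale = ahp_scale()) {
  idx <- match(labels, scale$label)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown judgment label(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  tfn(scale$l[idx], scale$m[idx], scale$u[idx])
}

#' Build a fuzzy pairwise comparison matrix
#'
#' Assembles the full reciprocal comparison matrix from one judgment per
#' unordered criterion pair. The diagonal is (1,1,1) and the lower triangle
#' is filled with TFN reciprocals of the stated judgments.
#'
#' @param judgments Data frame with columns `i`, `j` (criterion names or
#'   1-based indices, `i` preferred over `j`) and `label` (a scale label).
#' @param criteria Character vector of criterion identifiers.
#' @param scale Judgment scale as returned by [ahp_scale()].
#' @return A `pairwise_matrix`: list with `criteria` and an
#'   `n x n x 3` array `entries` (slices `l`, `m`, `u`).
#' @export
build_comparison_matrix <- function(judgments, criteria, scale = ahp_scale()) {
  n <- length(criteria)
  if (n < 2L) stop("need at least two criteria", call. = FALSE)
  if (anyDuplicated(criteria)) stop("criteria must be unique", call. = FALSE)
  ji <- judgments$i
  jj <- judgments$j
  if (is.character(ji)) ji <- match(ji, criteria)
  if (is.character(jj)) jj <- match(jj, criteria)
  if (anyNA(ji) || anyNA(jj))
    stop("judgment refers to unknown criterion", call. = FALSE)
  if (any(ji == jj))
    stop("self-comparisons are not allowed", call. = FALSE)
  key <- paste(pmin(ji, jj), pmax(ji, jj), sep = ":")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicate judgment for pair(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  all_pairs <- apply(utils::combn(n, 2L), 2L, paste, collapse = ":")
  missing <- setdiff(all_pairs, key)
  if (length(missing))
    stop("missing judgment for pair(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  entries <- array(NA_real_, dim = c(n, n, 3L),
                   dimnames = list(criteria, criteria, c("l", "m", "u")))
  for (k in 1:3) diag(entries[, , k]) <- 1
  v <- unclass(scale_lookup(judgments$label, scale))
  r <- unclass(tfn_reciprocal(tfn(v[, 1L], v[, 2L], v[, 3L])))
  for (q in seq_along(ji)) {
    entries[ji[q], jj[q], ] <- v[q, ]
    entries[jj[q], ji[q], ] <- r[q, ]
  }
  structure(list(criteria = criteria, entries = entries),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  n <- length(x$criteria)
  cat("<pairwise_matrix> ", n, " criteria\n", sep = "")
  e <- x$entries
  out <- matrix(sprintf("(%.3g,%.3g,%.3g)", e[, , 1L], e[, , 2L], e[, , 3L]),
                n, n, dimnames = dimnames(e)[1:2])
  print(noquote(out))
  invisible(x)
}

#' Fuzzified geometric mean of each criterion row
#'
#' For row \eqn{i} of the comparison matrix the fuzzy geometric mean is
#' \eqn{r_i = ((\prod_j l_{ij})^{1/n}, (\prod_j m_{ij})^{1/n},
#' (\prod_j u_{ij})^{1/n})}, computed per component.
#'
#' @param M A `pairwise_matrix`.
#' @return A `tfn` vector of length `n`.
#' @export
fuzzy_geometric_means <- function(M) {
  e <- M$entries
  n <- dim(e)[1L]
  gm <- function(k) exp(rowMeans(log(e[, , k, drop = TRUE])))
  if (n == 1L) return(tfn(e[1, 1, 1], e[1, 1, 2], e[1, 1, 3]))
  tfn(gm(1L), gm(2L), gm(3L))
}

#' Fuzzy criterion weights from geometric means
#'
#' \eqn{\tilde w_i = r_i \otimes (r_1 \oplus \dots \oplus r_n)^{-1}}: each
#' row's fuzzy geometric mean multiplied by the fuzzy reciprocal of their
#' sum.
#'
#' @param r A `tfn` vector of fuzzy geometric means.
#' @return A `tfn` vector of fuzzy weights.
#' @export
fuzzy_weights <- function(r) {
  r <- as_tfn(r)
  if (length(r) < 1L) stop("empty geometric-mean vector", call. = FALSE)
  s <- unclass(r)
  total <- tfn(sum(s[, 1L]), sum(s[, 2L]), sum(s[, 3L]))
  r * tfn_reciprocal(total)
}

#' Defuzzified, normalized criterion weights
#'
#' Crisp weights are the centre-of-area values of the fuzzy weights,
#' re-normalized to sum to one.
#'
#' @param w_fuzzy A `tfn` vector of fuzzy weights.
#' @param criteria Optional criterion identifiers.
#' @return A `weight_vector`: data frame with columns `criterion`,
#'   `fuzzy_l`, `fuzzy_m`, `fuzzy_u`, `crisp`, `normalized`.
#' @export
normalized_crisp_weights <- function(w_fuzzy, criteria = NULL) {
  w_fuzzy <- as_tfn(w_fuzzy)
  crisp <- coa_defuzzify(w_fuzzy)
  if (any(crisp < 0)) stop("negative defuzzified weight", call. = FALSE)
  tot <- sum(crisp)
  if (tot <= 0) stop("defuzzified weights sum to zero", call. = FALSE)
  f <- unclass(w_fuzzy)
  if (is.null(criteria)) criteria <- paste0("C", seq_len(nrow(f)))
  structure(
    data.frame(criterion = criteria, fuzzy_l = f[, 1L], fuzzy_m = f[, 2L],
               fuzzy_u = f[, 3L], crisp = crisp, normalized = crisp / tot,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("weight_vector", "data.frame"))
}

#' @export
print.weight_vector <- function(x, digits = 4, ...) {
  cat("<weight_vector> ", nrow(x), " criteria (normalized weights sum to ",
      format(sum(x$normalized), digits = 6), ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Derive criterion weights by fuzzy AHP
#'
#' Runs the full weighting chain: pairwise comparison matrix from linguistic
#' judgments, fuzzy geometric means per row, fuzzy weights, centre-of-area
#' defuzzification and normalization.
#'
#' @inheritParams build_comparison_matrix
#' @param check_consistency If `TRUE`, also compute Saaty's consistency
#'   ratio on the defuzzified matrix and store it as attribute `"cr"`
#'   (supported for up to 15 criteria). Default off.
#' @return A `weight_vector` (see [normalized_crisp_weights()]).
#' @examples
#' j <- data.frame(i = "severity", j = "history", label = "Moderate important")
#' fuzzy_ahp(j, c("severity", "history"))
#' @export
fuzzy_ahp <- function(judgments, criteria, scale = ahp_scale(),
                      check_consistency = FALSE) {
  M <- build_comparison_matrix(judgments, criteria, scale)
  w <- normalized_crisp_weights(fuzzy_weights(fuzzy_geometric_means(M)),
                                criteria = criteria)
  if (isTRUE(check_consistency)) attr(w, "cr") <- consistency_ratio(M)
  w
}

#' Saaty consistency ratio of the defuzzified comparison matrix
#'
#' Optional diagnostic: the comparison matrix is collapsed to crisp values by
#' centre-of-area, the principal eigenvalue computed, and
#' \eqn{CR = ((\lambda_{max} - n)/(n - 1)) / RI_n} returned. Values below
#' 0.1 are conventionally acceptable.
#'
#' @param M A `pairwise_matrix` with at most 15 criteria.
#' @return The consistency ratio (0 for n = 2).
#' @export
consistency_ratio <- function(M) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
          1.51, 1.48, 1.56, 1.57, 1.59)
  n <- length(M$criteria)
  if (n > length(ri))
    stop("consistency ratio supported for up to ", length(ri), " criteria",
         call. = FALSE)
  if (n <= 2L) return(0)
  A <- apply(M$entries, c(1, 2), mean)   # COA per cell
  lambda <- max(Re(eigen(A, only.values = TRUE)$values))
  ((lambda - n) / (n - 1)) / ri[n]
}

#' Read pairwise judgments from a YAML config
#'
#' The file holds a `criteria` list and a `judgments` list of
#' `{i, j, label}` entries.
#'
#' @param path Path to the YAML file.
#' @return List with elements `judgments` (data frame) and `criteria`.
#' @export
read_judgments <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$criteria) || is.null(cfg$judgments))
    stop("judgment config needs 'criteria' and 'judgments'", call. = FALSE)
  j <- do.call(rbind, lapply(cfg$judgments, function(q)
    data.frame(i = q$i, j = q$j, label = q$label, stringsAsFactors = FALSE)))
  list(judgments = j, criteria = unlist(cfg$criteria))
}

#' Write a weight vector to CSV
#'
#' @param w A `weight_vector`.
#' @param path Output path.
#' @export
write_weights_csv <- function(w, path) {
  utils::write.csv(as.data.frame(w), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default criterion weights for the 31-item instrument
#'
#' The normalized fuzzy-AHP weights shipped with the package (the reference
#' weighting validated against expert clinician ranking; the underlying
#' 31x31 judgment matrix is not published, so the normalized weights are
#' distributed as a fixture). Physical criteria C11-C14 and C16 carry the
#' highest weight; body-image item C45 the lowest. The printed values sum to
#' 0.997 (three-decimal rounding).
#'
#' @return A named numeric vector of 31 normalized weights (names C11..C45).
#' @export
default_criterion_weights <- function() {
  path <- system.file("extdata", "default_weights.csv", package = "pcoscreen",
                      mustWork = TRUE)
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(w$weight, w$criterion)
}
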