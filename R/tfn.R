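#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) is the triple \eqn{(l, m, u)} with
#' \eqn{l \le m \le u}: membership rises linearly from 0 at \eqn{l} to 1 at
#' the mode \eqn{m} and falls back to 0 at \eqn{u}. All linguistic scales,
#' expert ratings and fuzzy criterion weights in this package are TFNs.
#' `tfn()` is vectorised: it builds a length-`n` vector of TFNs stored as an
#' `n x 3` matrix with columns `l`, `m`, `u`.
#'
#' @param l Lower supports (numeric vector).
#' @param m Modes; defaults to `l` (crisp value promoted to a degenerate TFN).
#' @param u Upper supports; defaults to `m`.
#' @return An object of class `"tfn"`.
#' @examples
#' tfn(0.4, 0.5, 0.6)               # the "Medium" rating
#' tfn(2, 3, 4) + tfn(4, 5, 6)      # component-wise sum
#' tfn(0.074)                       # crisp weight as degenerate TFN
#' @export
tfn <- function(l, m = l, u = m) {
  x <- cbind(l = as.numeric(l), m = as.numeric(m), u = as.numeric(u))
  if (anyNA(x) || any(!is.finite(x)))
    stop("TFN components must be finite", call. = FALSE)
  if (any(x[, 1L] > x[, 2L] + 1e-12) || any(x[, 2L] > x[, 3L] + 1e-12))
    stop("TFN ordering violated: need l <= m <= u", call. = FALSE)
  structure(x, class = "tfn")
}

#' @export
is_tfn <- function(x) inherits(x, "tfn")

#' @rdname tfn
#' @param x Object to coerce or test.
#' @export
as_tfn <- function(x) {
  if (is_tfn(x)) return(x)
  if (is.numeric(x) && is.null(dim(x))) return(tfn(x, x, x))
  if (is.matrix(x) && ncol(x) == 3L) return(tfn(x[, 1L], x[, 2L], x[, 3L]))
  stop("cannot coerce to tfn", call. = FALSE)
}

#' @export
length.tfn <- function(x) nrow(unclass(x))

#' @export
`[.tfn` <- function(x, i, ...) {
  y <- unclass(x)[i, , drop = FALSE]
  tfn(y[, 1L], y[, 2L], y[, 3L])
}

#' @export
format.tfn <- function(x, digits = 4, ...) {
  y <- unclass(x)
  sprintf("(%s, %s, %s)",
          format(y[, 1L], digits = digits, trim = TRUE),
          format(y[, 2L], digits = digits, trim = TRUE),
          format(y[, 3L], digits = digits, trim = TRUE))
}

#' @export
print.tfn <- function(x, ...) {
  cat("<tfn[", length(x), "]>\n", sep = "")
  print(noquote(format(x, ...)))
  invisible(x)
}

#' @export
c.tfn <- function(...) {
  parts <- lapply(list(...), function(p) unclass(as_tfn(p)))
  y <- do.call(rbind, parts)
  tfn(y[, 1L], y[, 2L], y[, 3L])
}

# recycle two tfn vectors to a common length
tfn_recycle <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) != n) a <- a[rep_len(seq_len(length(a)), n)]
  if (length(b) != n) b <- b[rep_len(seq_len(length(b)), n)]
  list(a = unclass(a), b = unclass(b))
}

#' Arithmetic on triangular fuzzy numbers
#'
#' Component-wise extension arithmetic: `+` adds the three components, `*`
#' multiplies them (both operands must be non-negative for the product to
#' remain a valid TFN). Plain numerics are promoted to degenerate TFNs
#' `(v, v, v)`, which is how crisp AHP weights enter the weighted TOPSIS
#' matrix.
#'
#' @param e1,e2 `tfn` objects or non-negative numerics.
#' @export
Ops.tfn <- function(e1, e2) {
  if (.Generic %in% c("==", "!=")) {
    r <- tfn_recycle(as_tfn(e1), as_tfn(e2))
    eq <- rowSums(r$a == r$b) == 3L
    return(if (.Generic == "==") eq else !eq)
  }
  if (!.Generic %in% c("+", "*"))
    stop(sprintf("'%s' is not defined for tfn objects", .Generic), call. = FALSE)
  r <- tfn_recycle(as_tfn(e1), as_tfn(e2))
  if (.Generic == "+") {
    y <- r$a + r$b
  } else {
    if (any(r$a[, 1L] < 0) || any(r$b[, 1L] < 0))
      stop("tfn product requires non-negative operands", call. = FALSE)
    y <- r$a * r$b
  }
  tfn(y[, 1L], y[, 2L], y[, 3L])
}

#' @rdname Ops.tfn
#' @param a,b `tfn` vectors.
#' @export
tfn_add <- function(a, b) as_tfn(a) + as_tfn(b)

#' @rdname Ops.tfn
#' @export
tfn_multiply <- function(a, b) as_tfn(a) * as_tfn(b)

#' Reciprocal of a triangular fuzzy number
#'
#' For \eqn{a = (l, m, u)} with \eqn{l > 0}, the fuzzy reciprocal is
#' \eqn{(1/u, 1/m, 1/l)}. Used for the inverse pairwise judgments of the AHP
#' comparison matrix and for the weight denominator
#' \eqn{(r_1 + \dots + r_n)^{-1}}.
#'
#' @param a A `tfn` vector with strictly positive lower supports.
#' @return A `tfn` vector.
#' @export
tfn_reciprocal <- function(a) {
  a <- unclass(as_tfn(a))
  if (any(a[, 1L] <= 0))
    stop("tfn reciprocal requires strictly positive support", call. = FALSE)
  tfn(1 / a[, 3L], 1 / a[, 2L], 1 / a[, 1L])
}

#' Centre-of-area defuzzification
#'
#' Collapses a TFN to the crisp value \eqn{(l + m + u) / 3}, the centroid of
#' the triangular membership function. This is the defuzzifier used to turn
#' fuzzy AHP weights into crisp weights.
#'
#' @param a A `tfn` vector.
#' @return Numeric vector of crisp values.
#' @examples
#' coa_defuzzify(tfn(2, 3, 4))  # 3
#' @export
coa_defuzzify <- function(a) {
  a <- unclass(as_tfn(a))
  unname(rowMeans(a))
}

#' Vertex distance between triangular fuzzy numbers
#'
#' The root-mean-square distance over the three components,
#' \deqn{d_v(a, b) = \sqrt{\tfrac{1}{3}\left[(l_a-l_b)^2 + (m_a-m_b)^2 +
#'   (u_a-u_b)^2\right]},}
#' the standard companion metric of this TOPSIS formulation. It is a metric
#' on TFNs: symmetric, non-negative, zero iff the operands are equal, and it
#' satisfies the triangle inequality.
#'
#' @param a,b `tfn` vectors (recycled to a common length).
#' @return Numeric vector of distances.
#' @examples
#' vertex_distance(tfn(0.8, 0.9, 1), tfn(0, 0, 0.2))  # 0.8347
#' @export
vertex_distance <- function(a, b) {
  r <- tfn_recycle(as_tfn(a), as_tfn(b))
  unname(sqrt(rowMeans((r$a - r$b)^2)))
}

#' Triangular membership function
#'
#' Degree of membership of crisp `x` in the TFN `a` (a scalar TFN): 1 at the
#' mode, falling linearly to 0 at the supports.
#'
#' @param a A single `tfn`.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector in \[0, 1\].
#' @export
tfn_membership <- function(a, x) {
  a <- unclass(as_tfn(a))
  if (nrow(a) != 1L) stop("'a' must be a single tfn", call. = FALSE)
  l <- a[1L]; m <- a[2L]; u <- a[3L]
  up <- if (m > l) (x - l) / (m - l) else as.numeric(x >= m)
  dn <- if (u > m) (u - x) / (u - m) else as.numeric(x <= m)
  pmax(0, pmin(1, up, dn))
}
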