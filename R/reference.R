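# Loaders for the reference worked-example fixtures shipped with the
# package: the per-criterion separation distances of one screening example,
# the test-set confusion matrices of the study's evaluation, and the
# test-set level counts. These anchor the regression tests and the
# reproduction script.

ext_csv <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "pcoscreen",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Reference per-criterion separation distances
#'
#' The shipped worked screening example: for one test subject, the vertex
#' distances of each channel alternative to the positive (`star`) and
#' negative (`minus`) ideal solutions, per criterion. The raw linguistic
#' ratings behind these distances are not published, so the fixture enters
#' the pipeline at the separation-distance stage; summing a row over
#' criteria gives that alternative's total separation.
#'
#' @param channel `"physical"` or `"mental"`.
#' @return List of two matrices (`star`, `minus`), alternatives x criteria.
#' @export
reference_distances <- function(channel = c("physical", "mental")) {
  channel <- match.arg(channel)
  d <- ext_csv("reference_distances.csv")
  d <- d[d$channel == channel, ]
  alts <- unname(channel_alternatives(channel))
  alts <- alts[order(alts)]
  crits <- unique(d$criterion)
  grab <- function(which) {
    s <- d[d$ideal == which, ]
    m <- matrix(NA_real_, length(alts), length(crits),
                dimnames = list(alts, crits))
    m[cbind(match(s$alternative, alts), match(s$criterion, crits))] <- s$distance
    m
  }
  list(star = grab("star"), minus = grab("minus"))
}

#' Closeness coefficients of the reference worked example
#'
#' Sums the reference distance rows over criteria into total separations
#' and applies [closeness_coefficients()] and [rank_alternatives()].
#'
#' @inheritParams reference_distances
#' @return A `topsis_result`-like list with `profile` and `ranking`.
#' @export
reference_closeness <- function(channel = c("physical", "mental")) {
  d <- reference_distances(channel)
  profile <- structure(
    data.frame(alternative = rownames(d$star),
               d_star = rowSums(d$star), d_minus = rowSums(d$minus),
               cc = NA_real_, stringsAsFactors = FALSE, row.names = NULL),
    class = c("separation_profile", "data.frame"))
  profile <- closeness_coefficients(profile)
  list(profile = profile, ranking = rank_alternatives(profile))
}

#' Reference evaluation fixtures
#'
#' `reference_confusion()` returns the shipped test-set confusion matrix
#' (167 subjects, rows = actual) of either the fuzzy TOPSIS screening or
#' the SVM baseline. `reference_test_counts()` returns the shipped
#' test-set channel-level counts: 52 subjects at P1 and 4 at P3 (56
#' PCOS-positive), 83 at M1 and 1 at M3 (84 mental-positive).
#'
#' @param method `"topsis"` or `"svm"`.
#' @return A `confusion_matrix` / a one-row data frame of counts.
#' @export
reference_confusion <- function(method = c("topsis", "svm")) {
  method <- match.arg(method)
  d <- ext_csv("reference_confusion.csv")
  d <- d[d$method == method, ]
  m <- as.matrix(d[, category_labels()])
  rownames(m) <- d$actual
  as_confusion_matrix(m)
}

#' @rdname reference_confusion
#' @export
reference_test_counts <- function() {
  ext_csv("reference_test_counts.csv")
}

#' Reconstruct the reference test-set screening results
#'
#' Builds a per-subject level table consistent with the shipped test-set
#' fixtures — channel-positive counts from [reference_test_counts()] and
#' the A1 overlap from the [reference_confusion()] diagonal — then fuses
#' categories through the rule base. The wellness indicators computed from
#' the result depend only on these marginal counts.
#'
#' @param rules A `rule_base`.
#' @return Data frame with `p_level`, `m_level`, `category` (one row per
#'   test subject).
#' @export
reference_screening_results <- function(rules = default_rule_base()) {
  tc <- reference_test_counts()
  n_both <- unclass(reference_confusion("topsis"))["A1", "A1"]
  n_p <- tc$p1 + tc$p3
  n_m <- tc$m1 + tc$m3
  n <- tc$n_test
  stopifnot(n_both <= n_p, n_both <= n_m,
            n_p + n_m - n_both <= n)
  # lay out subjects: both-positive first, then P-only, M-only, neither;
  # within the positives place the moderate levels (P3/M3) first
  p_pos <- c(rep("P3", tc$p3), rep("P1", tc$p1))
  m_pos <- c(rep("M3", tc$m3), rep("M1", tc$m1))
  p_level <- c(p_pos[seq_len(n_both)],                       # both
               p_pos[n_both + seq_len(n_p - n_both)],        # P only
               rep("P2", n_m - n_both),                      # M only
               rep("P2", n - n_p - (n_m - n_both)))          # neither
  m_level <- c(m_pos[seq_len(n_both)],
               rep("M2", n_p - n_both),
               m_pos[n_both + seq_len(n_m - n_both)],
               rep("M2", n - n_p - (n_m - n_both)))
  data.frame(p_level = p_level, m_level = m_level,
             category = classify(p_level, m_level, rules),
             stringsAsFactors = FALSE)
}
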