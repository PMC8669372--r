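# Rule-based fusion of the two channel levels and the cohort-level
# wellness indicators.

#' Fuzzy inference rule base
#'
#' Nine rules mapping every combination of a physical level (P1 high, P2
#' normal, P3 moderate PCOS) and a mental level (M1 high, M2 normal, M3
#' moderate mental-health issues) to one of the four screening categories:
#' A1 both conditions, A2 only PCOS, A3 only mental-health issues, A4
#' normal. The default (clinician-validated) rule set sends any
#' high-or-moderate pairing on both channels to A1; note its asymmetry —
#' (P3, M3) fuses to A1 while (P2, M3) fuses to A3 — which is reproduced as
#' stated, not rationalized.
#'
#' `rule_base()` validates an arbitrary rule table; rules are data, so an
#' alternative clinical rule set can be loaded with [read_rule_base()].
#'
#' @param rules Data frame with columns `p_level`, `m_level`, `category`
#'   covering all nine combinations exactly once.
#' @return A `rule_base` data frame.
#' @export
rule_base <- function(rules) {
  need <- c("p_level", "m_level", "category")
  if (!all(need %in% names(rules)))
    stop("rule base needs columns p_level, m_level, category", call. = FALSE)
  rules <- rules[need]
  rules[] <- lapply(rules, as.character)
  if (!all(rules$p_level %in% paste0("P", 1:3)) ||
      !all(rules$m_level %in% paste0("M", 1:3)))
    stop("rule levels must be P1-P3 and M1-M3", call. = FALSE)
  if (!all(rules$category %in% category_labels()))
    stop("rule categories must be A1-A4", call. = FALSE)
  key <- paste(rules$p_level, rules$m_level)
  all_keys <- as.vector(outer(paste0("P", 1:3), paste0("M", 1:3), paste))
  if (anyDuplicated(key))
    stop("duplicate rule for: ", paste(unique(key[duplicated(key)]),
                                       collapse = ", "), call. = FALSE)
  if (!setequal(key, all_keys))
    stop("rule base is not total; missing: ",
         paste(setdiff(all_keys, key), collapse = ", "), call. = FALSE)
  structure(rules, class = c("rule_base", "data.frame"))
}

#' @rdname rule_base
#' @export
default_rule_base <- function() {
  if (is.null(the$rules)) {
    path <- system.file("extdata", "rule_base.csv", package = "pcoscreen",
                        mustWork = TRUE)
    the$rules <- rule_base(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  the$rules
}

#' @rdname rule_base
#' @param path CSV path with columns `p_level`, `m_level`, `category`.
#' @export
read_rule_base <- function(path) {
  rule_base(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.rule_base <- function(x, ...) {
  cat("<rule_base> 9 rules\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Fuse channel levels into a screening category
#'
#' Total, deterministic lookup in the rule base; vectorized over subjects.
#'
#' @param p_level Character vector of physical levels (P1/P2/P3).
#' @param m_level Character vector of mental levels (M1/M2/M3).
#' @param rules A `rule_base`.
#' @return Character vector of categories A1-A4.
#' @examples
#' classify("P1", "M1")  # A1: both conditions
#' classify("P2", "M2")  # A4: normal
#' @export
classify <- function(p_level, m_level, rules = default_rule_base()) {
  idx <- match(paste(p_level, m_level),
               paste(rules$p_level, rules$m_level))
  if (anyNA(idx))
    stop("invalid level pair: ",
         paste(unique(paste(p_level, m_level)[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  rules$category[idx]
}

indicator <- function(positive, fused_a1, what) {
  denom <- sum(positive)
  if (denom == 0L)
    stop(what, " undefined: no condition-positive subjects", call. = FALSE)
  100 * sum(positive & fused_a1) / denom
}

#' Cohort wellness indicators
#'
#' `mental_wellness_indicator()` is the percentage of PCOS-positive
#' subjects (physical level P1 or P3) whose fused category is A1, i.e. who
#' also carry mental-health issues:
#' \deqn{I_M = 100 \cdot \frac{n\{(P1 \lor P3) \land A1\}}{n\{P1 \lor P3\}}.}
#' `physical_wellness_indicator()` is the symmetric percentage over
#' mental-positive subjects (M1 or M3):
#' \deqn{I_P = 100 \cdot \frac{n\{(M1 \lor M3) \land A1\}}{n\{M1 \lor M3\}}.}
#' Both error when the denominator is empty.
#'
#' @param results Data frame of screening results with columns `p_level`,
#'   `m_level`, `category` (e.g. from [screen_cohort()]).
#' @return A percentage in \[0, 100\].
#' @export
mental_wellness_indicator <- function(results) {
  indicator(results$p_level %in% c("P1", "P3"), results$category == "A1",
            "mental wellness indicator")
}

#' @rdname mental_wellness_indicator
#' @export
physical_wellness_indicator <- function(results) {
  indicator(results$m_level %in% c("M1", "M3"), results$category == "A1",
            "physical wellness indicator")
}
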