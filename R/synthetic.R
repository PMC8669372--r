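# Synthetic labelled cohorts with controllable class structure, so every
# pipeline stage is testable without the original study data.

#' Default class-conditional response model
#'
#' Per category and criterion, a categorical distribution over the answer
#' levels. The default encodes the semantics of the four categories: A1
#' subjects are symptomatic on both channels, A2 only on the physical
#' channel, A3 only on the psychological channels, A4 on neither.
#' `separation` interpolates each distribution between uniform (0) and a
#' one-hot mass on the most (symptomatic channel) or least (asymptomatic
#' channel) symptomatic level (1).
#'
#' @param separation Scalar in \[0, 1\].
#' @param instrument An `instrument`.
#' @return A `response_model`: nested list `model[[category]][[criterion]]`
#'   of probability vectors over that criterion's levels.
#' @export
default_response_model <- function(separation = 0.9,
                                   instrument = default_instrument()) {
  if (!is.numeric(separation) || separation < 0 || separation > 1)
    stop("separation must be in [0, 1]", call. = FALSE)
  phys <- channel_criteria(instrument, "physical")
  symptomatic <- list(A1 = c(TRUE, TRUE), A2 = c(TRUE, FALSE),
                      A3 = c(FALSE, TRUE), A4 = c(FALSE, FALSE))
  model <- lapply(symptomatic, function(sy) {
    out <- lapply(instrument$levels, function(lev) {
      L <- length(lev)
      rep(1 / L, L)
    })
    for (id in instrument$criteria$id) {
      L <- length(instrument$levels[[id]])
      sympt <- if (id %in% phys) sy[1L] else sy[2L]
      onehot <- numeric(L)
      onehot[if (sympt) L else 1L] <- 1
      out[[id]] <- (1 - separation) * rep(1 / L, L) + separation * onehot
    }
    out
  })
  structure(model, class = "response_model")
}

#' Generate a synthetic labelled cohort
#'
#' Draws `n` subjects: the category label from `class_priors`, then each
#' answer independently from the label's class-conditional distribution.
#' Defaults emulate the study conditions: 624 subjects and category priors
#' (0.22, 0.14, 0.26, 0.38) matching the observed A1-A4 test-set mix,
#' with `separation = 0.9` giving strong but noisy class structure.
#'
#' @param n Subject count (default 624).
#' @param class_priors Four probabilities summing to 1 (A1-A4).
#' @param separation Passed to [default_response_model()] when no
#'   `response_model` is supplied.
#' @param response_model Optional `response_model` overriding the default.
#' @param seed Integer seed; regeneration with the same settings is identical.
#' @param instrument An `instrument`.
#' @return A labelled `cohort`.
#' @examples
#' coh <- generate_cohort(n = 50, seed = 7)
#' table(coh$label)
#' @export
generate_cohort <- function(n = 624L, class_priors = c(0.22, 0.14, 0.26, 0.38),
                            separation = 0.9, response_model = NULL,
                            seed = 1L, instrument = default_instrument()) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (length(class_priors) != 4L || any(class_priors < 0) ||
      abs(sum(class_priors) - 1) > 1e-8)
    stop("class_priors must be 4 non-negative values summing to 1",
         call. = FALSE)
  model <- response_model %||% default_response_model(separation, instrument)
  for (cat in category_labels())
    for (id in instrument$criteria$id) {
      p <- model[[cat]][[id]]
      if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("invalid response distribution for ", cat, "/", id, call. = FALSE)
    }
  set.seed(seed)
  labels <- sample(category_labels(), n, replace = TRUE, prob = class_priors)
  df <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (id in instrument$criteria$id) {
    lev <- instrument$levels[[id]]
    ans <- character(n)
    for (cat in unique(labels)) {
      sel <- labels == cat
      ans[sel] <- sample(lev, sum(sel), replace = TRUE,
                         prob = model[[cat]][[id]])
    }
    df[[id]] <- ans
  }
  df$label <- labels
  as_cohort(df, instrument)
}
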