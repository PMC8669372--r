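# End-to-end screening: per subject, one fuzzy TOPSIS ranking per channel,
# rule-base fusion, and cohort-level evaluation; plus the machine-learning
# baseline runner.

# Precompute, for one channel, the lookup array
# [answer level, criterion, alternative, tfn component] so per-subject
# rating grids are pure indexing.
channel_lookup <- function(channel, map, instrument) {
  crit <- channel_criteria(instrument, channel)
  n_lev <- max(vapply(instrument$levels[crit], length, integer(1L)))
  arr <- array(NA_real_, dim = c(n_lev, length(crit), 3L, 3L))
  scale <- rating_scale()
  for (j in seq_along(crit)) {
    m <- map[[crit[j]]]
    if (is.null(m))
      stop("rating map does not cover criterion ", crit[j], call. = FALSE)
    lev <- instrument$levels[[crit[j]]]
    if (!all(lev %in% rownames(m)))
      stop("rating map does not cover all levels of ", crit[j], call. = FALSE)
    v <- unclass(rating_tfn(as.vector(m[lev, c("high", "normal", "moderate")]),
                            scale))
    arr[seq_along(lev), j, , ] <-
      array(v, dim = c(length(lev), 3L, 3L))
  }
  list(criteria = crit, alternatives = unname(channel_alternatives(channel)),
       arr = arr)
}

screen_channel <- function(levels_mat, lookup, weights) {
  # levels_mat: subjects x channel-criteria integer matrix (1-based)
  n_crit <- length(lookup$criteria)
  w <- as_tfn(unname(weights[lookup$criteria]))
  grid <- expand.grid(alt = 1:3, j = seq_len(n_crit), comp = 1:3)
  t(apply(levels_mat, 1L, function(lev) {
    ratings <- array(lookup$arr[cbind(lev[grid$j], grid$j, grid$alt, grid$comp)],
                     dim = c(3L, n_crit, 3L),
                     dimnames = list(lookup$alternatives, lookup$criteria,
                                     c("l", "m", "u")))
    res <- fuzzy_topsis(decision_matrix(ratings, w))
    stats::setNames(res$profile$cc, res$profile$alternative)
  }))
}

#' Screen a cohort through the fuzzy pipeline
#'
#' For each subject: the physical channel ranks P1/P2/P3 and the mental
#' channel ranks M1/M2/M3 by fuzzy TOPSIS closeness coefficient (answers
#' resolved through the rating map, criteria weighted by the normalized
#' fuzzy-AHP weights); the top level of each channel is fused into the
#' final category by the rule base. When the cohort carries expert labels,
#' the confusion matrix, accuracy and the two wellness indicators are also
#' computed.
#'
#' @param cohort A `cohort`.
#' @param weights Named numeric vector of normalized criterion weights
#'   (default: the shipped fuzzy-AHP weights), or a `weight_vector`.
#' @param map A `rating_map`.
#' @param rules A `rule_base`.
#' @param instrument The cohort's instrument.
#' @return A `screening` object: list with `results` (data frame: subject
#'   id, per-alternative closeness coefficients, channel levels, fused
#'   category, expert label if known) and `metrics` (list with
#'   `confusion`, `accuracy`, `i_m`, `i_p`, or `NULL` when unlabelled).
#' @examples
#' coh <- generate_cohort(n = 40, separation = 1, seed = 3)
#' scr <- screen_cohort(coh)
#' scr$metrics$accuracy
#' @export
screen_cohort <- function(cohort, weights = default_criterion_weights(),
                          map = default_rating_map(instrument),
                          rules = default_rule_base(),
                          instrument = attr(cohort, "instrument") %||%
                            default_instrument()) {
  if (inherits(weights, "weight_vector"))
    weights <- stats::setNames(weights$normalized, weights$criterion)
  missing_w <- setdiff(instrument$criteria$id, names(weights))
  if (length(missing_w))
    stop("no weight for criterion: ", paste(missing_w, collapse = ", "),
         call. = FALSE)
  enc <- encode_ordinal(cohort)
  cc <- list()
  for (ch in c("physical", "mental")) {
    lk <- channel_lookup(ch, map, instrument)
    cc[[ch]] <- screen_channel(enc$x[, lk$criteria, drop = FALSE] + 1L,
                               lk, weights)
  }
  pick <- function(ccm) colnames(ccm)[max.col(ccm, ties.method = "first")]
  p_level <- pick(cc$physical)
  m_level <- pick(cc$mental)
  results <- data.frame(subject_id = cohort$subject_id,
                        stringsAsFactors = FALSE)
  for (a in colnames(cc$physical)) results[[paste0("cc_", a)]] <- cc$physical[, a]
  for (a in colnames(cc$mental))   results[[paste0("cc_", a)]] <- cc$mental[, a]
  results$p_level <- p_level
  results$m_level <- m_level
  results$category <- classify(p_level, m_level, rules)
  metrics <- NULL
  if ("label" %in% names(cohort)) {
    results$label <- as.character(cohort$label)
    cm <- confusion_matrix(results$label, results$category)
    metrics <- list(confusion = cm, accuracy = accuracy(cm),
                    i_m = tryCatch(mental_wellness_indicator(results),
                                   error = function(e) NA_real_),
                    i_p = tryCatch(physical_wellness_indicator(results),
                                   error = function(e) NA_real_))
  }
  structure(list(results = results, metrics = metrics), class = "screening")
}

#' @export
print.screening <- function(x, ...) {
  cat("<screening> ", nrow(x$results), " subjects\n", sep = "")
  print(table(category = x$results$category))
  if (!is.null(x$metrics)) {
    cat(sprintf("accuracy %.2f%%; I_M %.2f%%; I_P %.2f%%\n",
                x$metrics$accuracy, x$metrics$i_m, x$metrics$i_p))
  }
  invisible(x)
}

#' @export
summary.screening <- function(object, ...) {
  print(object)
  if (!is.null(object$metrics)) print(object$metrics$confusion)
  invisible(object)
}

#' Export screening results as CSV
#'
#' @param screening A `screening` object.
#' @param path Output path.
#' @export
write_screening_csv <- function(screening, path) {
  utils::write.csv(screening$results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a machine-learning baseline on a labelled cohort
#'
#' The comparison protocol: ordinal-encode the answers, stratified 80/20
#' split, balance the training partition only by nearest-neighbour mean
#' oversampling, fit the chosen classifier and predict the held-out test
#' rows.
#'
#' @param cohort A labelled `cohort`.
#' @param model `"svm"`, `"knn"` or `"dtree"`.
#' @param train_fraction Training fraction of the stratified split.
#' @param balance_k Neighbour count of the oversampler; `NA` skips
#'   balancing.
#' @param params Hyperparameter overrides for [train_and_predict()].
#' @param seed Integer seed driving split, balancing and fitting.
#' @return A `baseline_run`: list with `predictions` (data frame:
#'   `subject_id`, `actual`, `predicted`), `confusion`, `accuracy` and the
#'   partition sizes in `sizes`.
#' @export
run_baseline <- function(cohort, model = c("svm", "knn", "dtree"),
                         train_fraction = 0.8, balance_k = 5L,
                         params = list(), seed = 1L) {
  model <- match.arg(model)
  if (!"label" %in% names(cohort))
    stop("baseline requires a labelled cohort", call. = FALSE)
  enc <- encode_ordinal(cohort)
  y <- as.character(enc$labels)
  sp <- stratified_split(enc$x, y, train_fraction, seed = seed)
  xtr <- enc$x[sp$train, , drop = FALSE]
  ytr <- y[sp$train]
  n_before <- length(ytr)
  if (!is.na(balance_k)) {
    bal <- knn_balance(xtr, ytr, k = balance_k, seed = seed)
    xtr <- bal$x
    ytr <- bal$y
  }
  pred <- train_and_predict(xtr, ytr, enc$x[sp$test, , drop = FALSE],
                            model = model, params = params, seed = seed)
  actual <- y[sp$test]
  cm <- confusion_matrix(actual, pred)
  structure(list(
    predictions = data.frame(subject_id = cohort$subject_id[sp$test],
                             actual = actual, predicted = pred,
                             stringsAsFactors = FALSE),
    confusion = cm, accuracy = accuracy(cm), model = model,
    sizes = c(train = n_before, train_balanced = length(ytr),
              test = length(sp$test))),
    class = "baseline_run")
}

#' @export
print.baseline_run <- function(x, ...) {
  cat("<baseline_run> ", x$model, ": accuracy ",
      sprintf("%.2f%%", x$accuracy), " on ", x$sizes[["test"]],
      " test subjects (train ", x$sizes[["train"]], " -> ",
      x$sizes[["train_balanced"]], " after balancing)\n", sep = "")
  print(x$confusion)
  invisible(x)
}
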