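# Instrument definition, cohort CSV I/O, ordinal encoding and the
# answer -> fuzzy-rating bridge that feeds the TOPSIS channels.

the <- new.env(parent = emptyenv())  # package-local cache

#' Read an instrument definition
#'
#' An instrument file (YAML) lists the questionnaire criteria: identifier,
#' group, question text and the ordered answer levels (declared
#' least-symptomatic first). The shipped default is the 31-item screening
#' instrument: 11 physical items (C11-C111), the 10 K10 anxiety/depression
#' items (C21-C210), 5 social-phobia items (C31-C35) and 5 body-image items
#' (C41-C45), each with 5 ordered levels.
#'
#' @param path Path to an instrument YAML file.
#' @return An `instrument`: list with `criteria` (data frame `id`, `group`,
#'   `text`) and `levels` (named list of ordered level vectors).
#' @export
read_instrument <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$criteria)) stop("instrument file has no 'criteria'", call. = FALSE)
  ids <- vapply(cfg$criteria, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate criterion ids", call. = FALSE)
  crit <- data.frame(
    id = ids,
    group = vapply(cfg$criteria, `[[`, character(1L), "group"),
    text = vapply(cfg$criteria, `[[`, character(1L), "text"),
    stringsAsFactors = FALSE)
  levels <- lapply(cfg$criteria, function(q) as.character(unlist(q$levels)))
  names(levels) <- ids
  if (any(vapply(levels, length, integer(1L)) < 2L))
    stop("every criterion needs at least two answer levels", call. = FALSE)
  structure(list(criteria = crit, levels = levels), class = "instrument")
}

#' @rdname read_instrument
#' @export
default_instrument <- function() {
  if (is.null(the$instrument)) {
    path <- system.file("extdata", "instrument.yaml", package = "pcoscreen",
                        mustWork = TRUE)
    the$instrument <- read_instrument(path)
  }
  the$instrument
}

#' @export
print.instrument <- function(x, ...) {
  cat("<instrument> ", nrow(x$criteria), " criteria\n", sep = "")
  print(table(x$criteria$group))
  invisible(x)
}

#' Criteria belonging to a screening channel
#'
#' The physical channel consumes the 11 physical items; the mental channel
#' the 20 psychological items (anxiety/depression, social phobia, body
#' image).
#'
#' @param instrument An `instrument`.
#' @param channel `"physical"` or `"mental"`.
#' @return Character vector of criterion ids.
#' @export
channel_criteria <- function(instrument, channel = c("physical", "mental")) {
  channel <- match.arg(channel)
  groups <- if (channel == "physical") "physical" else
    c("anxiety_depression", "social_phobia", "body_image")
  instrument$criteria$id[instrument$criteria$group %in% groups]
}

#' Alternatives (severity levels) of a screening channel
#'
#' Declared order: high, normal, moderate — P1/P2/P3 for the physical
#' channel, M1/M2/M3 for the mental channel. The order is also the
#' deterministic tie-break in ranking.
#'
#' @inheritParams channel_criteria
#' @return Named character vector: identifiers named by semantic role.
#' @export
channel_alternatives <- function(channel = c("physical", "mental")) {
  channel <- match.arg(channel)
  p <- if (channel == "physical") "P" else "M"
  stats::setNames(paste0(p, 1:3), c("high", "normal", "moderate"))
}

category_labels <- function() c("A1", "A2", "A3", "A4")

#' Read a cohort CSV
#'
#' One row per subject: an optional `subject_id` column, one column per
#' criterion holding a declared answer level, and an optional trailing
#' `label` column with the expert category (A1-A4). Validation is strict:
#' unknown columns, unknown answer levels and missing values are errors
#' citing the offending row and column.
#'
#' @param path CSV path (header row, UTF-8).
#' @param instrument The instrument the cohort was collected with.
#' @return A `cohort`: data frame with `subject_id`, one factor column per
#'   criterion (instrument level order), and `label` if present.
#' @export
read_cohort_csv <- function(path, instrument = default_instrument()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  as_cohort(raw, instrument)
}

#' @rdname read_cohort_csv
#' @param x A data frame of answer labels to validate and classify.
#' @export
as_cohort <- function(x, instrument = default_instrument()) {
  ids <- instrument$criteria$id
  extra <- setdiff(names(x), c("subject_id", ids, "label"))
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "), call. = FALSE)
  miss <- setdiff(ids, names(x))
  if (length(miss))
    stop("missing criterion column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(x)
  if (!n) stop("cohort is empty", call. = FALSE)
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(x)) as.character(x$subject_id)
                 else sprintf("S%04d", seq_len(n)),
    stringsAsFactors = FALSE)
  for (id in ids) {
    lev <- instrument$levels[[id]]
    v <- as.character(x[[id]])
    bad <- which(is.na(v) | !nzchar(v))
    if (length(bad))
      stop(sprintf("missing value in column %s, row %d", id, bad[1L]),
           call. = FALSE)
    unk <- which(!v %in% lev)
    if (length(unk))
      stop(sprintf("unknown answer %s in column %s, row %d",
                   sQuote(v[unk[1L]]), id, unk[1L]), call. = FALSE)
    out[[id]] <- factor(v, levels = lev)
  }
  if ("label" %in% names(x)) {
    lab <- as.character(x$label)
    if (!all(is.na(lab) | !nzchar(lab))) {
      unk <- which(!is.na(lab) & nzchar(lab) & !lab %in% category_labels())
      if (length(unk))
        stop(sprintf("unknown label %s in row %d", sQuote(lab[unk[1L]]),
                     unk[1L]), call. = FALSE)
      if (any(is.na(lab) | !nzchar(lab)))
        stop("label column is partially filled", call. = FALSE)
      out$label <- factor(lab, levels = category_labels())
    }
  }
  structure(out, class = c("cohort", "data.frame"),
            instrument = instrument)
}

#' Write a cohort CSV
#'
#' Columns in canonical instrument order; the `label` column is written
#' only when the cohort carries expert labels. The write/read cycle is
#' lossless.
#'
#' @param cohort A `cohort`.
#' @param path Output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  inst <- attr(cohort, "instrument") %||% default_instrument()
  cols <- c("subject_id", inst$criteria$id,
            if ("label" %in% names(cohort)) "label")
  df <- as.data.frame(cohort)[, cols]
  df[] <- lapply(df, as.character)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x), " subjects, ",
      nrow(attr(x, "instrument")$criteria), " criteria",
      if ("label" %in% names(x)) ", labelled" else "", "\n", sep = "")
  if ("label" %in% names(x)) print(table(x$label))
  invisible(x)
}

#' Ordinal encoding of a cohort
#'
#' Each answer is replaced by its 0-based index in the criterion's declared
#' level order (least symptomatic = 0); expert labels map A1-A4 to 0-3.
#' This is the representation consumed by the machine-learning baselines.
#'
#' @param cohort A `cohort`.
#' @return List with `x` (integer matrix, subjects x criteria) and `y`
#'   (integer vector or `NULL` when unlabelled), plus `labels` (the factor)
#'   for convenience.
#' @export
encode_ordinal <- function(cohort) {
  inst <- attr(cohort, "instrument") %||% default_instrument()
  ids <- inst$criteria$id
  x <- vapply(ids, function(id) as.integer(cohort[[id]]) - 1L,
              integer(nrow(cohort)))
  x <- matrix(x, nrow = nrow(cohort), dimnames = list(cohort$subject_id, ids))
  y <- if ("label" %in% names(cohort)) as.integer(cohort$label) - 1L else NULL
  list(x = x, y = y,
       labels = if ("label" %in% names(cohort)) cohort$label else NULL)
}

#' Decode an ordinal matrix back to answer labels
#'
#' Inverse of [encode_ordinal()] for the answer matrix.
#'
#' @param x Integer matrix from [encode_ordinal()].
#' @param instrument The instrument that defined the level orders.
#' @param y Optional 0-3 integer labels.
#' @return A `cohort`.
#' @export
decode_ordinal <- function(x, instrument = default_instrument(), y = NULL) {
  ids <- instrument$criteria$id
  df <- data.frame(subject_id = rownames(x) %||% sprintf("S%04d", seq_len(nrow(x))),
                   stringsAsFactors = FALSE)
  for (id in ids) df[[id]] <- instrument$levels[[id]][x[, id] + 1L]
  if (!is.null(y)) df$label <- category_labels()[y + 1L]
  as_cohort(df, instrument)
}

#' Default answer-level to rating map
#'
#' The bridge from a subject's categorical answers to the linguistic
#' ratings of the three severity alternatives of a channel. The default is
#' monotone: the most symptomatic answer level rates the "high" alternative
#' Very High and the "normal" alternative Very Low (reversed at the other
#' end), while the "moderate" alternative peaks at mid levels
#' (L, H, VH, H, L across five levels). The true expert map behind the
#' study instrument is not published; this default reproduces its
#' qualitative behaviour (severe answer sheets select the high level, with
#' moderate ranked above normal).
#'
#' @param instrument An `instrument`.
#' @return A `rating_map`: named list, one `n_levels x 3` character matrix
#'   (columns `high`, `normal`, `moderate`) of rating labels per criterion.
#' @export
default_rating_map <- function(instrument = default_instrument()) {
  labs <- rating_scale()$label    # VL L M H VH
  map <- lapply(instrument$levels, function(lev) {
    L <- length(lev)
    s <- (seq_len(L) - 1) / (L - 1)
    m <- cbind(high = labs[1L + round(s * 4)],
               normal = labs[5L - round(s * 4)],
               moderate = labs[2L + round((1 - abs(2 * s - 1)) * 3)])
    rownames(m) <- lev
    m
  })
  structure(map, class = "rating_map")
}

#' Read / write a rating map
#'
#' Serialized as YAML: per criterion, per answer level, the three rating
#' labels for the high/normal/moderate alternatives.
#'
#' @param path YAML path.
#' @return A `rating_map`.
#' @export
read_rating_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  map <- lapply(cfg, function(q) {
    m <- cbind(high = as.character(unlist(q$high)),
               normal = as.character(unlist(q$normal)),
               moderate = as.character(unlist(q$moderate)))
    rownames(m) <- as.character(unlist(q$levels))
    m
  })
  structure(map, class = "rating_map")
}

#' @rdname read_rating_map
#' @param map A `rating_map`.
#' @export
write_rating_map <- function(map, path) {
  out <- lapply(unclass(map), function(m)
    list(levels = rownames(m), high = unname(m[, "high"]),
         normal = unname(m[, "normal"]), moderate = unname(m[, "moderate"])))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Resolve one subject's answers to a channel's fuzzy rating grid
#'
#' Looks each channel criterion's answer up in the rating map and resolves
#' the three alternatives' linguistic ratings through the rating scale,
#' yielding the 3 x n_criteria fuzzy decision grid for that subject.
#'
#' @param answers Named character vector (or one-row cohort slice) of
#'   answer levels keyed by criterion id.
#' @param channel `"physical"` or `"mental"`.
#' @param map A `rating_map`.
#' @param instrument An `instrument`.
#' @return A `3 x n_crit x 3` ratings array (alternatives x criteria x
#'   TFN components) ready for [decision_matrix()].
#' @export
responses_to_ratings <- function(answers, channel = c("physical", "mental"),
                                 map = default_rating_map(instrument),
                                 instrument = default_instrument()) {
  channel <- match.arg(channel)
  crit <- channel_criteria(instrument, channel)
  alts <- channel_alternatives(channel)
  if (is.data.frame(answers)) {
    stopifnot(nrow(answers) == 1L)
    answers <- vapply(crit, function(id) as.character(answers[[id]]), character(1L))
  }
  labels <- matrix(NA_character_, 3L, length(crit),
                   dimnames = list(unname(alts), crit))
  for (j in seq_along(crit)) {
    id <- crit[j]
    m <- map[[id]]
    if (is.null(m))
      stop("rating map does not cover criterion ", id, call. = FALSE)
    a <- answers[[id]]
    if (is.na(a) || !a %in% rownames(m))
      stop(sprintf("rating map does not cover (%s, %s)", id, a), call. = FALSE)
    labels[, j] <- m[a, c("high", "normal", "moderate")]
  }
  v <- unclass(rating_tfn(as.vector(labels)))
  array(c(v[, 1L], v[, 2L], v[, 3L]), dim = c(3L, length(crit), 3L),
        dimnames = list(unname(alts), crit, c("l", "m", "u")))
}
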