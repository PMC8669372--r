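test_that("default instrument partitions 31 criteria into the four groups", {
  inst <- default_instrument()
  expect_equal(nrow(inst$criteria), 31)
  tab <- table(inst$criteria$group)
  expect_equal(unname(tab[c("physical", "anxiety_depression",
                            "social_phobia", "body_image")]),
               c(11L, 10L, 5L, 5L), ignore_attr = TRUE)
  expect_equal(length(channel_criteria(inst, "physical")), 11)
  expect_equal(length(channel_criteria(inst, "mental")), 20)
  expect_length(intersect(channel_criteria(inst, "physical"),
                          channel_criteria(inst, "mental")), 0)
  expect_true(all(vapply(inst$levels, length, integer(1)) == 5))
})

test_that("cohort CSV round-trips losslessly and is byte-stable", {
  df <- toy_cohort_df()
  coh <- as_cohort(df)
  expect_equal(nrow(coh), 3)
  expect_equal(as.character(coh$label), df$label)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, p1)
  back <- read_cohort_csv(p1)
  expect_equal(as.data.frame(back), as.data.frame(coh))
  write_cohort_csv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  # header in canonical instrument order
  hdr <- strsplit(readLines(p1, 1), ",")[[1]]
  expect_equal(gsub('"', "", hdr),
               c("subject_id", default_instrument()$criteria$id, "label"))
})

test_that("label column is omitted when no subject is labelled", {
  df <- toy_cohort_df()
  df$label <- NULL
  coh <- as_cohort(df)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, p)
  expect_false("label" %in% gsub('"', "", strsplit(readLines(p, 1), ",")[[1]]))
})

test_that("validation errors cite the offending cell", {
  df <- toy_cohort_df()
  df$C11[2] <- "maybe"
  expect_error(as_cohort(df), "'maybe' in column C11, row 2")
  df2 <- toy_cohort_df()
  df2$C11[1] <- NA
  expect_error(as_cohort(df2), "missing value in column C11, row 1")
  df3 <- toy_cohort_df()
  df3$extra <- 1
  expect_error(as_cohort(df3), "unknown column")
  df4 <- toy_cohort_df()
  df4$C45 <- NULL
  expect_error(as_cohort(df4), "missing criterion column")
  df5 <- toy_cohort_df()
  df5$label[1] <- "A9"
  expect_error(as_cohort(df5), "unknown label")
})

test_that("ordinal encoding is 0-based in declared level order", {
  coh <- as_cohort(toy_cohort_df())
  enc <- encode_ordinal(coh)
  expect_equal(dim(enc$x), c(3, 31))
  expect_true(all(enc$x[2, ] == 0))    # subject b answered first levels
  expect_true(all(enc$x[1, ] == 4))    # subject a answered last levels
  expect_equal(enc$y, c(0L, 3L, 2L))   # A1, A4, A3
  dec <- decode_ordinal(enc$x, y = enc$y)
  expect_equal(as.data.frame(dec)[-1], as.data.frame(coh)[-1])
  # identical answers encode identically
  expect_equal(enc$x[1, ], encode_ordinal(coh[1, ])$x[1, ])
})

test_that("default rating map is monotone and covers the instrument", {
  map <- default_rating_map()
  inst <- default_instrument()
  expect_setequal(names(map), inst$criteria$id)
  m <- map[["C21"]]
  expect_equal(unname(m[, "high"]), c("VL", "L", "M", "H", "VH"))
  expect_equal(unname(m[, "normal"]), c("VH", "H", "M", "L", "VL"))
  expect_equal(unname(m[5, "moderate"]), "L")
  expect_equal(unname(m[3, "moderate"]), "VH")
})

test_that("rating map round-trips through YAML", {
  map <- default_rating_map()
  p <- withr::local_tempfile(fileext = ".yaml")
  write_rating_map(map, p)
  back <- read_rating_map(p)
  expect_equal(unclass(back), unclass(map))
})

test_that("responses resolve to a pure, channel-shaped rating grid", {
  sheet <- uniform_sheet(5)          # maximally symptomatic
  g <- responses_to_ratings(sheet, "physical")
  expect_equal(dim(g), c(3, 11, 3))
  expect_equal(dimnames(g)[[1]], c("P1", "P2", "P3"))
  # high alternative rated VH = (0.8, 0.9, 1) on every criterion
  expect_true(all(g["P1", , 1] == 0.8 & g["P1", , 2] == 0.9 & g["P1", , 3] == 1))
  expect_identical(g, responses_to_ratings(sheet, "physical"))  # purity
  gm <- responses_to_ratings(sheet, "mental")
  expect_equal(dim(gm), c(3, 20, 3))
  expect_equal(dimnames(gm)[[1]], c("M1", "M2", "M3"))
})

test_that("uncovered map entries are reported by name", {
  map <- default_rating_map()
  map[["C11"]] <- NULL
  expect_error(responses_to_ratings(uniform_sheet(1), "physical", map),
               "C11")
  map2 <- default_rating_map()
  rownames(map2[["C12"]])[1] <- "bogus"
  expect_error(responses_to_ratings(uniform_sheet(1), "physical", map2),
               "C12")
})

test_that("swapping the map's high/normal columns inverts the ranking", {
  w <- default_criterion_weights()
  sheet <- uniform_sheet(4)          # monotone symptomatic sheet
  run <- function(map) {
    g <- responses_to_ratings(sheet, "physical", map)
    fuzzy_topsis(decision_matrix(
      g, w[channel_criteria(default_instrument(), "physical")]))$ranking
  }
  swapped <- default_rating_map()
  for (id in names(swapped))
    swapped[[id]][, c("high", "normal")] <- swapped[[id]][, c("normal", "high")]
  r1 <- run(default_rating_map())
  r2 <- run(swapped)
  expect_equal(r1[1], "P1")
  expect_equal(r2[1], "P2")
  expect_equal(match("P1", r2) > match("P2", r2), TRUE)
})
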