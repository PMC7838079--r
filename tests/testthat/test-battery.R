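test_that("a long-format CSV round-trips through read and write", {
  bat <- make_battery(rbind(c(4, 1, 5, 3), c(6, 0, 6, 6)), k = 6L)
  expect_s3_class(bat, "can_battery")
  expect_equal(length(unique(bat$participant)), 2L)
  expect_equal(attr(bat, "trials_per_cell"), 6L)

  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_battery(bat, f)
  back <- read_battery(f)
  expect_equal(as.data.frame(back), as.data.frame(bat))
})

test_that("alternative response codings and column names read identically", {
  bat <- make_battery(rbind(c(4, 1, 5, 3), c(2, 2, 6, 0)), k = 6L)
  df <- as.data.frame(bat)
  df$cell <- NULL
  df$response <- ifelse(df$response == 1L, "yes", "no")
  names(df)[names(df) == "participant"] <- "subj"
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(df, f, row.names = FALSE, quote = FALSE)

  back <- read_battery(f, column_map = c(participant = "subj"),
                       response_codes = c(action = "yes", inaction = "no"))
  expect_equal(back$response, bat$response)
  expect_equal(back$participant, bat$participant)
})

test_that("schema and validation errors name the offending column/participant", {
  bat <- make_battery(c(4, 1, 5, 3), k = 6L)
  df <- as.data.frame(bat)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(df[, setdiff(names(df), c("response", "cell"))], f,
            row.names = FALSE)
  expect_error(read_battery(f), "response")

  # participant s07 lacks the prescriptive/benefits_smaller cell
  ok <- participant_rows("s01", c(3, 2, 4, 1))
  broken <- participant_rows("s07", c(3, 2, 4, 1))
  broken <- broken[broken$consequence != "benefits_smaller" |
                     broken$norm != "prescriptive", ]
  expect_error(as_battery(rbind(ok, broken)), "s07")
  expect_message(
    dropped <- as_battery(rbind(ok, broken), allow_incomplete = TRUE),
    "s07")
  expect_equal(unique(dropped$participant), "s01")
})

test_that("unknown categorical codes are rejected", {
  df <- participant_rows("s01", c(3, 2, 4, 1))
  df$norm[1] <- "sideways"
  expect_error(as_battery(df), "norm")
  df <- participant_rows("s01", c(3, 2, 4, 1))
  df$response[1] <- 2L
  expect_error(as_battery(df), "binary")
})

test_that("cell probabilities are the per-cell action proportions", {
  bat <- make_battery(rbind(c(6, 0, 6, 0), c(3, 3, 3, 3), c(4, 1, 5, 3)),
                      k = 6L)
  expect_equal(unname(cell_probabilities(bat, "s01")), c(1, 0, 1, 0))
  expect_equal(unname(cell_probabilities(bat, "s02")), rep(0.5, 4))
  expect_equal(unname(cell_probabilities(bat, "s03")), c(4, 1, 5, 3) / 6)
  expect_error(cell_probabilities(bat, "nobody"), "unknown participant")
})

test_that("aggregate counts add over participants and respect group filters", {
  bat <- make_battery(rbind(c(6, 0, 6, 0), c(0, 0, 6, 6)), k = 6L,
                      groups = c("a", "b"))
  all_counts <- aggregate_counts(bat)
  expect_equal(all_counts$actions, c(6, 0, 12, 6))
  expect_equal(all_counts$totals, rep(12, 4))

  only_a <- aggregate_counts(bat, group = "a")
  expect_equal(only_a$actions, c(6, 0, 6, 0))
  expect_equal(only_a$totals, rep(6, 4))
  expect_error(aggregate_counts(bat, group = "zz"), "no participants")
})

test_that("aggregation conserves counts and ignores row order", {
  set.seed(42)
  for (rep in 1:5) {
    k <- sample(3:8, 1)
    acts <- matrix(sample(0:k, 4 * 6, replace = TRUE), ncol = 4)
    bat <- make_battery(acts, k = k)
    agg <- aggregate_counts(bat)
    per_part <- vapply(unique(bat$participant), function(id) {
      cell_probabilities(bat, id) * k
    }, numeric(4))
    expect_equal(agg$actions, unname(rowSums(per_part)))
    expect_equal(agg$totals, rep(6 * k, 4))
    # p_i times the trial count is integral
    expect_equal(per_part, round(per_part))

    shuffled <- as_battery(as.data.frame(bat)[sample(nrow(bat)), ])
    expect_equal(aggregate_counts(shuffled), agg)
  }
})
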