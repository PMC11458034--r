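test_that("word measures reproduce the worked example", {
  ev <- data.frame(fixation_index = 1:5,
                   word_index = c(1L, 2L, 2L, 4L, 3L),
                   duration_ms = c(200, 180, 160, 220, 250))
  m <- fixations_to_word_measures(ev, 4L)
  expect_equal(m[m$word_id == 2, c("FFD", "GD", "TRT")],
               data.frame(FFD = 180, GD = 340, TRT = 340, row.names = 2L))
  expect_equal(m$SK[2], 0L); expect_equal(m$RG[2], 0L)
  expect_equal(m$SK[3], 1L)   # first fixated only after word 4
  expect_equal(m$RG[3], 1L)
  expect_equal(m$FFD[3], 250); expect_equal(m$GD[3], 250)
  expect_equal(m$TRT[3], 250)
  expect_equal(m$FFD[4], 220)
})

test_that("never-fixated and single-pass words behave as defined", {
  ev <- data.frame(fixation_index = 1:3, word_index = c(1L, 2L, 4L),
                   duration_ms = c(100, 150, 200))
  m <- fixations_to_word_measures(ev, 4L)
  expect_equal(m$SK[3], 1L); expect_equal(m$RG[3], 0L)
  expect_true(is.na(m$FFD[3]) && is.na(m$GD[3]) && is.na(m$TRT[3]))
  # single ordered fixation per word: FFD = GD = TRT, SK = RG = 0
  expect_equal(m$FFD[1], m$GD[1]); expect_equal(m$GD[1], m$TRT[1])
  expect_equal(m$SK[c(1, 2, 4)], rep(0L, 3))
  expect_equal(m$RG[c(1, 2, 4)], rep(0L, 3))
  expect_error(fixations_to_word_measures(
    data.frame(fixation_index = c(2, 1), word_index = c(1L, 2L),
               duration_ms = c(100, 100)), 2L), "ordered")
})

test_that("aggregation agrees with the brute-force replay on random streams", {
  set.seed(42)
  for (i in 1:150) {
    n_words <- sample(3:12, 1)
    ev <- random_events(n_words, sample(1:30, 1))
    expect_equal(fixations_to_word_measures(ev, n_words),
                 replay_measures(ev, n_words))
  }
})

test_that("standardized RMSE has a zero floor and unit-offset calibration", {
  h <- c(200, 250, 300, 180)
  expect_equal(standardized_rmse(h, h, sd(h)), 0)
  expect_equal(standardized_rmse(h + 20, h, 20), 1)
  expect_equal(standardized_rmse(c(110, 90), c(100, 100), 20), 0.5)
  # unit invariance
  expect_equal(standardized_rmse(h + 35, h, sd(h)),
               standardized_rmse((h + 35) / 1000, h / 1000, sd(h) / 1000))
  # pairwise deletion of missing values
  expect_equal(standardized_rmse(c(110, NA, 90), c(100, 100, 100), 20), 0.5)
  expect_error(standardized_rmse(c(NA, NA), c(1, 2), 1), "overlap")
  expect_equal(standardized_rmse(h + 20, h, 20, plus_one = TRUE), 2)
})

test_that("condition comparison uses the paired signed-rank test", {
  set.seed(3)
  a <- rnorm(100, 1.5, 0.2)
  out <- compare_conditions(a, a + 1)
  expect_lt(out$p_value, 0.001)
  expect_equal(out$band, "***")
  expect_error(compare_conditions(a, a), "zero")
  expect_error(compare_conditions(1, 2), "two")
  expect_error(compare_conditions(a, a[1:10]), "equal length")
  near <- a + rnorm(100, 0, 0.2)
  expect_gte(compare_conditions(a, near)$p_value, 0)
})

test_that("binned errors partition the feature range into equal widths", {
  set.seed(8)
  n <- 400
  rows <- data.frame(simulation = rep(1:2, each = n / 2),
                     feature = runif(n),
                     human = rnorm(n, 100, 10))
  rows$sim <- rows$human + rnorm(n, 0, 5)
  b <- binned_error(rows, human_sd = 10, n_bins = 20)
  expect_equal(nrow(b), 20L)
  expect_equal(b$lower, seq(min(rows$feature), max(rows$feature),
                            length.out = 21)[-21])
  expect_true(all(diff(b$upper - b$lower) < 1e-12))
  # error injected only above a feature cut shows up only in high bins
  rows2 <- rows
  high <- rows2$feature > 0.7
  rows2$sim[high] <- rows2$sim[high] + 50
  b2 <- binned_error(rows2, human_sd = 10, n_bins = 20)
  expect_gt(min(b2$rmse[b2$lower >= 0.7], na.rm = TRUE),
            max(b2$rmse[b2$upper <= 0.7], na.rm = TRUE))
  # constant feature falls back to a single bin equal to the global score
  rows3 <- rows; rows3$feature <- 1
  expect_warning(b3 <- binned_error(rows3, human_sd = 10), "single bin")
  z <- (rows3$sim - rows3$human) / 10
  global <- mean(tapply(z^2, rows3$simulation, function(x) sqrt(mean(x))))
  expect_equal(b3$rmse, global)
})

test_that("POS tags map onto content, function and other classes", {
  expect_equal(pos_category(c("NOUN", "VERB", "ADJ", "ADV", "PROPN")),
               rep("content", 5))
  expect_equal(pos_category(c("AUX", "ADP", "CCONJ", "SCONJ", "DET",
                              "PART", "PRON")),
               rep("function", 7))
  expect_equal(pos_category(c("NUM", "INTJ", "X")), rep("other", 3))
  expect_warning(out <- pos_category("WHAT"), "unknown")
  expect_equal(out, "other")
})

test_that("recognition accuracy counts exact matches only", {
  rec <- data.frame(position = 1:10, word = letters[1:10],
                    recognized_as = c(letters[1:9], NA),
                    correct = c(rep(TRUE, 9), NA))
  expect_equal(recognition_accuracy(rec), 0.9)
  rec$correct[1] <- FALSE   # orthographic-neighbour substitution
  expect_equal(recognition_accuracy(rec), 0.8)
})

test_that("human measures CSV round-trips with missing durations", {
  fx <- fx_small()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(fx$human, path, row.names = FALSE, na = "")
  back <- read_human_measures(path)
  expect_equal(nrow(back), nrow(fx$human))
  expect_true(all(c("skip_rate", "ffd_ms", "regression_rate") %in%
                  names(back)))
  expect_equal(back$skip_rate, fx$human$skip_rate, tolerance = 1e-10)
  # always-skipped words have empty duration cells -> NA
  if (any(is.na(fx$human$ffd_ms))) {
    expect_true(any(is.na(back$ffd_ms)))
  }
})
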