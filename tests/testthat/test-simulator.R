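test_that("activation update matches hand-computed values", {
  ap <- activation_params()
  zero_overlap <- matrix(0, 1, 1)
  # pure decay: no input, S = 0.5 -> dS = 0.5 * tau = -0.05
  expect_equal(processing_cycle(0.5, 0, zero_overlap, 0, ap), 0.45)
  # ceiling gating: at S_max, positive input contributes nothing
  expect_equal(processing_cycle(1, 10, zero_overlap, 0, ap),
               1 + (1 - 0) * (-0.1))
  # two-word toy with mutual overlap weight 0.1, hand-computed:
  d <- matrix(c(0, 0.1, 0.1, 0), 2, 2)
  S <- c(0.4, 0.5); exc <- c(0.2, 0)
  # w1: input = 0.2 - 2.5*0.1*0.5 = 0.075; dS = 0.6*0.075 - 0.04 = 0.005
  # w2: input = 0 - 2.5*0.1*0.4 = -0.1;  dS = 0.5*(-0.1) - 0.05 = -0.1
  expect_equal(processing_cycle(S, exc, d, 0, ap), c(0.405, 0.4))
  # both neighbours active: inhibition proportional to d * S
  S2 <- c(0.4, 0.8); out <- processing_cycle(S2, exc, d, 0, ap)
  expect_lt(out[1], processing_cycle(c(0.4, 0.5), exc, d, 0, ap)[1])
})

test_that("activation is clamped to bounds under extreme input", {
  ap <- activation_params()
  z <- matrix(0, 1, 1)
  expect_equal(processing_cycle(0.5, 100, z, 0, ap), 1)
  expect_equal(processing_cycle(0.5, -100, z, 0, ap), 0)
})

test_that("predictive activation enters the update additively", {
  ap <- activation_params()
  z <- matrix(0, 1, 1)
  s_with <- processing_cycle(0.2, 0.1, z, 0.05, ap)
  s_without <- processing_cycle(0.2, 0.1, z, 0, ap)
  expect_equal(s_with - s_without, (1 - 0.2) * 0.05)
})

test_that("recognition respects threshold, length and input-overlap gates", {
  lex <- toy_lexicon()   # cat, cap, dog
  S <- c(0, 0, 0); names(S) <- lex$word
  # below threshold: nothing
  expect_equal(nrow(check_recognition(S, lex, 1L, "cat", NA_integer_)), 0L)
  # cat above threshold at position of "cat": recognized correctly
  S_cat <- ifelse(lex$word == "cat", 0.99, 0)
  hit <- check_recognition(S_cat, lex, 1L, "cat", NA_integer_)
  expect_equal(lex$word[hit$word_index], "cat")
  # boosted neighbour "cap" crosses first: recognized-incorrect
  S_cap <- ifelse(lex$word == "cap", 0.99, 0)
  hit2 <- check_recognition(S_cap, lex, 1L, "cat", NA_integer_)
  expect_equal(lex$word[hit2$word_index], "cap")
  # a much longer word is not eligible despite S >= T
  lex2 <- toy_lexicon(c("cat", "caterpillar"), c(10, 10))
  S_long <- ifelse(lex2$word == "caterpillar", 0.99, 0)
  expect_equal(nrow(check_recognition(S_long, lex2, 1L, "cat", NA_integer_)),
               0L)
  # orthographically disjoint word of right length is rejected
  S_dog <- ifelse(lex$word == "dog", 0.99, 0)
  expect_equal(nrow(check_recognition(S_dog, lex, 1L, "cat", NA_integer_)),
               0L)
})

test_that("saccade initiation has a refractory floor and a forced ceiling", {
  sacc <- default_config()$saccade
  set.seed(1)
  expect_false(saccade_decision(5, sacc$min_cycles - 1, sacc))
  expect_true(saccade_decision(0, sacc$max_cycles, sacc))
  # recognition raises the initiation rate
  set.seed(2)
  p0 <- mean(replicate(2000, saccade_decision(0, 5, sacc)))
  p1 <- mean(replicate(2000, saccade_decision(1, 5, sacc)))
  expect_gt(p1, p0)
  expect_equal(p0, sacc$p_base, tolerance = 0.3)
  expect_equal(p1, sacc$p_base + sacc$gain, tolerance = 0.15)
})

test_that("attention window grows with success and saturates at its bounds", {
  sacc <- default_config()$saccade
  expect_equal(update_attention_window(TRUE, sacc$window_max, sacc),
               sacc$window_max)
  expect_equal(update_attention_window(FALSE, sacc$window_min, sacc),
               sacc$window_min)
  w <- 8
  w2 <- update_attention_window(FALSE, update_attention_window(TRUE, w, sacc),
                                sacc)
  expect_equal(w2, w)
})

test_that("saccade targeting skips recognized words and prefers near salience", {
  layout <- readsim:::passage_layout(c("first", "next", "third", "mouse"))
  rec <- rep(NA_integer_, 4)
  # everything unrecognized: nearest (most salient) word targeted
  expect_equal(select_saccade_target(layout, 1L, 3L, rec, 12), 2L)
  # n+1 recognized parafoveally -> skip to n+2
  rec2 <- rec; rec2[2] <- 99L
  expect_equal(select_saccade_target(layout, 1L, 3L, rec2, 12), 3L)
  # everything ahead recognized -> end of passage
  rec3 <- c(NA, 99L, 99L, 99L)
  expect_true(is.na(select_saccade_target(layout, 1L, 3L, rec3, 12)))
  # outside the window: falls back to the nearest unrecognized word ahead
  rec4 <- c(99L, 99L, 99L, NA)
  expect_equal(select_saccade_target(layout, 1L, 3L, rec4, 2), 4L)
})

test_that("regressions target the earliest unrecognized word in range", {
  sacc <- default_config()$saccade
  sacc$p_regress <- 1
  rec <- c(NA_integer_, 99L, NA_integer_, 99L)
  set.seed(1)
  expect_equal(schedule_regression(rec, 4L, sacc), 1L)
  # lookback limits how far back the eyes may return
  sacc2 <- sacc; sacc2$regression_lookback <- 1L
  expect_equal(schedule_regression(rec, 4L, sacc2), 3L)
  # all earlier recognized: no regression possible
  expect_true(is.na(schedule_regression(c(99L, 99L, NA), 3L, sacc)))
  # disabled mechanism
  sacc$p_regress <- 0
  expect_true(is.na(schedule_regression(rec, 4L, sacc)))
})

test_that("a single-word passage yields one fixation and no saccades", {
  lex <- toy_lexicon(c("the", "cat"), c(100, 10))
  res <- simulate_passage("the", lex, NULL, default_config(), seed = 1)
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$word_index, 1L)
  expect_gte(res$events$duration_ms, 25)
})

test_that("simulation is deterministic given the seed", {
  fx <- fx_small()
  a <- simulate_passage(fx$passages$p01, fx$lexicon, fx$cloze,
                        default_config(), seed = 5, passage_id = "p01")
  b <- simulate_passage(fx$passages$p01, fx$lexicon, fx$cloze,
                        default_config(), seed = 5, passage_id = "p01")
  expect_identical(a, b)
  c <- simulate_passage(fx$passages$p01, fx$lexicon, fx$cloze,
                        default_config(), seed = 6, passage_id = "p01")
  expect_false(identical(a$events, c$events))
})

test_that("zero predictability weight reproduces the empty-table baseline", {
  fx <- fx_small()
  cfg0 <- default_config(); cfg0$model$c_p <- 0
  with_tab <- simulate_passage(fx$passages$p02, fx$lexicon, fx$cloze,
                               cfg0, seed = 9, passage_id = "p02")
  without <- simulate_passage(fx$passages$p02, fx$lexicon, NULL,
                              default_config(), seed = 9,
                              passage_id = "p02")
  expect_identical(with_tab$events, without$events)
  expect_identical(with_tab$recognition, without$recognition)
})

test_that("passage words missing from the lexicon raise an error", {
  lex <- toy_lexicon()
  expect_error(simulate_passage(c("cat", "zebra"), lex, NULL,
                                default_config(), seed = 1),
               "zebra")
})

test_that("passage normalization lower-cases and strips punctuation", {
  expect_equal(passage_words("The cat, sat -- on THE mat!  "),
               c("the", "cat", "sat", "on", "the", "mat"))
  expect_equal(passage_words("don't stop"), c("dont", "stop"))
})

test_that("fixation durations are whole cycles and events are ordered", {
  fx <- fx_small()
  res <- simulate_passage(fx$passages$p03, fx$lexicon, NULL,
                          default_config(), seed = 2, passage_id = "p03")
  expect_true(all(res$events$duration_ms %% 25 == 0))
  expect_true(all(diff(res$events$fixation_index) == 1))
  expect_true(all(res$events$word_index >= 1 &
                  res$events$word_index <= res$n_words))
  expect_true(all(res$events$saccade_type %in%
                  c("forward", "skip", "refixation", "regression")))
})
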