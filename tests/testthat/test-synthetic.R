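test_that("fixture generation is deterministic and well-formed", {
  spec <- fixture_spec(n_passages = 3L, words_per_passage = 20L,
                       vocab_size = 60L, seed = 11L)
  g1 <- generate_passages(spec)
  g2 <- generate_passages(spec)
  expect_identical(g1, g2)
  expect_length(g1$passages, 3L)
  expect_true(all(lengths(g1$passages) == 20L))
  expect_true(all(unlist(g1$passages) %in% g1$vocab$word))
  expect_true(all(lengths(g1$pos) == 20L))
  expect_true(all(unlist(g1$pos) %in%
                  c("DET", "ADP", "PRON", "AUX", "CCONJ", "PART",
                    "NOUN", "VERB", "ADJ", "ADV", "PROPN",
                    "NUM", "INTJ", "X")))
})

test_that("vocabulary follows a Zipf profile with fixed POS assignment", {
  spec <- fixture_spec(vocab_size = 100L, seed = 2L)
  v <- generate_vocabulary(spec)
  expect_equal(nrow(v), 100L)
  expect_false(any(duplicated(v$word)))
  expect_true(all(diff(v$frequency) <= 0))
  expect_equal(v$frequency[1] / v$frequency[10], 10, tolerance = 0.01)
  # most frequent words are function words
  expect_true(all(pos_category(v$pos[1:6]) == "function"))
})

test_that("cloze tables live on the respondent grid and sum to one", {
  fx <- fx_small()
  tab <- fx$cloze
  n_resp <- 40L
  expect_true(all(abs(tab$probability * n_resp -
                      round(tab$probability * n_resp)) < 1e-9))
  sums <- tapply(tab$probability, paste(tab$passage_id, tab$position), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  supp <- table(paste(tab$passage_id, tab$position))
  expect_true(all(supp <= n_resp))
})

test_that("43 distinct distractors reproduce the minimum cloze probability", {
  spec <- fixture_spec(n_passages = 1L, words_per_passage = 4L,
                       vocab_size = 60L, seed = 3L)
  gen <- generate_passages(spec)
  tab <- generate_cloze_table(gen$passages, gen$vocab, n_respondents = 43L,
                              accuracy = 0, seed = 5L)
  expect_true(all(tab$probability >= 1 / 43 - 1e-12))
  expect_equal(round(min(tab$probability), 3), 0.023)
  expect_error(generate_cloze_table(gen$passages, gen$vocab,
                                    n_respondents = 44L), "43")
})

test_that("LM tables respect the threshold and are not renormalized", {
  fx <- fx_small()
  tab <- fx$lm
  expect_true(all(tab$probability > 0.01))
  mass <- tapply(tab$probability, paste(tab$passage_id, tab$position), sum)
  expect_true(all(mass <= 1 + 1e-9))
  expect_lt(stats::median(mass), 1)   # un-renormalized tail loss
})

test_that("sharper LM concentration raises the mean top-1 probability", {
  spec <- fixture_spec(n_passages = 2L, words_per_passage = 25L,
                       vocab_size = 80L, seed = 4L)
  gen <- generate_passages(spec)
  top1 <- function(conc) {
    ps <- vapply(1:5, function(s) {
      tab <- generate_lm_table(gen$passages, gen$vocab, accuracy = 0.3,
                               concentration = conc, seed = 100 + s)
      mean(tapply(tab$probability, paste(tab$passage_id, tab$position), max))
    }, numeric(1))
    mean(ps)
  }
  expect_gt(top1(0.05), top1(2))
})

test_that("generator outputs round-trip through the package readers", {
  spec <- fixture_spec(n_passages = 2L, words_per_passage = 15L,
                       vocab_size = 50L, seed = 6L)
  dir <- withr::local_tempdir()
  fx <- write_fixtures(spec, dir)
  expect_identical(read_passages(file.path(dir, "passages.txt")),
                   fx$passages)
  lex_back <- read_frequency_lexicon(file.path(dir, "lexicon.tsv"))
  expect_equal(lex_back$frequency[match(fx$vocab$word, lex_back$word)],
               fx$vocab$frequency)
  cloze_back <- read_prediction_table(file.path(dir, "cloze.tsv"))
  expect_equal(as.data.frame(cloze_back), as.data.frame(fx$cloze),
               tolerance = 1e-12)
  lm_back <- read_prediction_table(file.path(dir, "lm.tsv"))
  expect_equal(as.data.frame(lm_back), as.data.frame(fx$lm),
               tolerance = 1e-12)
  human_back <- read_human_measures(file.path(dir, "human.csv"))
  expect_equal(human_back$trt_ms, fx$human$trt_ms, tolerance = 1e-9)
})

test_that("noise-free pseudo-human data match their generating simulation", {
  spec <- fixture_spec(n_passages = 2L, words_per_passage = 15L,
                       vocab_size = 50L, seed = 8L)
  gen <- generate_passages(spec)
  lex <- build_lexicon(gen$passages, gen$vocab[, c("word", "frequency")])
  cfg <- default_config()
  human <- generate_pseudo_human(gen$passages, lex, NULL, cfg,
                                 k_runs = 1L, noise_sd = 0, seed = 21L)
  runs <- simulate_corpus(gen$passages, lex, NULL, cfg, n_sims = 1L,
                          seed = 21L)
  sm <- run_word_measures(runs[[1L]])
  scores <- rmse_by_measure(sm, human)
  expect_true(all(scores < 1e-9))
})
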