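#' Specification of a synthetic fixture corpus
#'
#' Controls every generated input: passage count and length (the target
#' length mirrors naturalistic multi-sentence passages of about 50
#' words), vocabulary size, the Zipf exponent of the frequency
#' distribution, the number of cloze pseudo-respondents (at most 43),
#' the sharpness of the language-model-like distributions, and the
#' probability mass each generator places on the true next word
#' (`accuracy`).
#'
#' @param n_passages Number of passages (default 10).
#' @param words_per_passage Words per passage (default 50).
#' @param vocab_size Vocabulary size (default 150).
#' @param zipf_exponent Zipf exponent of word frequencies (default 1).
#' @param n_respondents Cloze pseudo-respondents, <= 43 (default 40).
#' @param cloze_accuracy Mass the cloze generator puts on the true next
#'   word (default 0.45).
#' @param lm_accuracy Expected mass the LM generator puts on the true
#'   next word (default 0.5).
#' @param lm_concentration Dirichlet-like sharpness of the LM tail
#'   (default 0.2; smaller = sharper, higher top-1).
#' @param chain_predictability Probability that a passage word is the
#'   preferred successor of its predecessor (default 0.5); this is what
#'   makes the generated text predictable at all.
#' @param noise_sd Relative noise of the pseudo-human generator
#'   (default 0.1).
#' @param seed Generator seed.
#' @return List of class `readsim_fixture_spec`.
#' @export
fixture_spec <- function(n_passages = 10L, words_per_passage = 50L,
                         vocab_size = 150L, zipf_exponent = 1,
                         n_respondents = 40L, cloze_accuracy = 0.45,
                         lm_accuracy = 0.5, lm_concentration = 0.2,
                         chain_predictability = 0.5, noise_sd = 0.1,
                         seed = 1L) {
  if (n_respondents > 43L) stop("at most 43 cloze respondents")
  if (cloze_accuracy < 0 || cloze_accuracy > 1 ||
      lm_accuracy < 0 || lm_accuracy > 1)
    stop("accuracy must lie in [0, 1]")
  structure(as.list(environment()), class = "readsim_fixture_spec")
}

#' Generate a synthetic vocabulary with Zipf frequencies and POS tags
#'
#' Pseudo-words are random letter strings (lengths 1-9, peaked at 4-6
#' letters); frequencies follow `rank^(-zipf_exponent)` scaled to
#' integer counts; the highest-frequency words are tagged as function
#' words (DET, ADP, PRON, AUX, CCONJ, PART), the bulk as content words
#' (NOUN, VERB, ADJ, ADV, PROPN) and a small remainder as other (NUM,
#' INTJ, X), mimicking the frequency profile of natural text.
#'
#' @param spec A [fixture_spec()].
#' @return Data frame `word`, `frequency`, `pos`, sorted by rank.
#' @export
generate_vocabulary <- function(spec) {
  set.seed(spec$seed)
  n <- spec$vocab_size
  lens <- sample(1:9, n, replace = TRUE,
                 prob = c(1, 3, 8, 12, 12, 10, 6, 3, 1))
  lens[1:2] <- c(1L, 2L)          # guarantee short function words exist
  words <- character(0)
  while (length(words) < n) {
    need <- n - length(words)
    cand <- vapply(utils::head(lens[seq_len(need)], need), function(L)
      paste(sample(letters, L, replace = TRUE), collapse = ""), character(1))
    words <- unique(c(words, cand))
    lens <- c(lens, sample(2:9, need, replace = TRUE))
  }
  words <- words[seq_len(n)]
  freq <- round(1e6 * (seq_len(n))^(-spec$zipf_exponent))
  freq <- pmax(freq, 1L)
  n_func <- max(6L, round(0.15 * n))
  n_other <- max(3L, round(0.05 * n))
  func_tags <- c("DET", "ADP", "PRON", "AUX", "CCONJ", "PART")
  content_tags <- c("NOUN", "VERB", "ADJ", "ADV", "PROPN")
  other_tags <- c("NUM", "INTJ", "X")
  pos <- character(n)
  pos[seq_len(n_func)] <- rep_len(func_tags, n_func)
  other_idx <- seq.int(n - n_other + 1L, n)
  pos[other_idx] <- rep_len(other_tags, n_other)
  rest <- which(pos == "")
  pos[rest] <- sample(content_tags, length(rest), replace = TRUE)
  data.frame(word = words, frequency = freq, pos = pos,
             stringsAsFactors = FALSE)
}

# Fixed preferred-successor map: a permutation of the vocabulary, so each
# word has exactly one preferred continuation.  Derived deterministically
# from the spec seed.
successor_map <- function(spec, vocab) {
  set.seed(spec$seed + 1L)
  sample(nrow(vocab))
}

#' Generate synthetic passages with POS tags
#'
#' Passages are sampled from a first-order word chain over the
#' vocabulary: with probability `chain_predictability` the next word is
#' the current word's fixed preferred successor, otherwise it is drawn
#' frequency-weighted from the whole vocabulary.  Each word carries its
#' fixed POS tag.  Deterministic per spec seed.
#'
#' @param spec A [fixture_spec()].
#' @param vocab Vocabulary from [generate_vocabulary()] (rebuilt if
#'   omitted).
#' @return List with `passages` (named list of word vectors), `pos`
#'   (parallel list of tag vectors) and `vocab`.
#' @export
generate_passages <- function(spec, vocab = generate_vocabulary(spec)) {
  succ <- successor_map(spec, vocab)
  set.seed(spec$seed + 2L)
  n_v <- nrow(vocab)
  w_freq <- vocab$frequency / sum(vocab$frequency)
  passages <- vector("list", spec$n_passages)
  for (p in seq_len(spec$n_passages)) {
    ids <- integer(spec$words_per_passage)
    ids[1L] <- sample.int(n_v, 1L, prob = w_freq)
    for (i in seq_len(spec$words_per_passage - 1L)) {
      ids[i + 1L] <- if (stats::runif(1) < spec$chain_predictability)
        succ[ids[i]] else sample.int(n_v, 1L, prob = w_freq)
    }
    passages[[p]] <- ids
  }
  names(passages) <- sprintf("p%02d", seq_len(spec$n_passages))
  list(passages = lapply(passages, function(i) vocab$word[i]),
       pos = lapply(passages, function(i) vocab$pos[i]),
       vocab = vocab)
}

#' Generate a cloze-like predictability table
#'
#' For each position after the first, `n_respondents` pseudo-respondents
#' each produce one continuation: the true next word with a per-position
#' probability drawn from a Beta distribution with mean `accuracy`
#' (naturalistic cloze probabilities are strongly skewed, with many
#' near-zero and some near-certain continuations), otherwise a
#' frequency-weighted distractor.  Probabilities are response
#' proportions, so they lie on the grid `k / n_respondents` and sum to 1
#' per position.
#'
#' @param passages Named list of word vectors.
#' @param vocab Vocabulary data frame.
#' @param n_respondents Number of pseudo-respondents (<= 43).
#' @param accuracy Mean probability a respondent produces the true word.
#' @param spread Beta concentration of the per-position probability
#'   (default 2; smaller = more extreme positions).
#' @param seed RNG seed.
#' @return A cloze-source predictability table.
#' @export
generate_cloze_table <- function(passages, vocab, n_respondents = 40L,
                                 accuracy = 0.45, spread = 2, seed = 1L) {
  if (n_respondents > 43L) stop("at most 43 cloze respondents")
  set.seed(seed)
  w_freq <- vocab$frequency / sum(vocab$frequency)
  responses <- list()
  for (pid in names(passages)) {
    words <- passages[[pid]]
    for (pos in 2:length(words)) {
      p_true <- stats::rbeta(1, accuracy * spread, (1 - accuracy) * spread)
      correct <- stats::runif(n_respondents) < p_true
      answers <- character(n_respondents)
      answers[correct] <- words[pos]
      n_d <- sum(!correct)
      if (n_d)
        answers[!correct] <- vocab$word[sample.int(nrow(vocab), n_d,
                                                   replace = TRUE,
                                                   prob = w_freq)]
      responses[[length(responses) + 1L]] <-
        list(passage_id = pid, position = pos, answers = answers)
    }
  }
  cloze_probabilities(responses)
}

#' Generate a language-model-like predictability table
#'
#' For each position after the first, a dense distribution over the full
#' vocabulary is drawn (a Dirichlet-style gamma construction with
#' concentration proportional to word frequency, sharpened by
#' `concentration`), mixed with a per-position Beta-distributed mass on
#' the true next word (mean `accuracy`, mirroring the skewed
#' predictability profile of natural text), then thresholded at `t`
#' without renormalization — surviving probabilities are reported
#' unchanged, so per-position mass is typically below 1.
#'
#' @param passages Named list of word vectors.
#' @param vocab Vocabulary data frame.
#' @param accuracy Expected mass on the true next word.
#' @param concentration Tail sharpness (> 0; smaller = sharper).
#' @param spread Beta concentration of the per-position true-word mass
#'   (default 2).
#' @param t Survival threshold (default 0.01, strict).
#' @param seed RNG seed.
#' @return An lm-source predictability table.
#' @export
generate_lm_table <- function(passages, vocab, accuracy = 0.5,
                              concentration = 0.2, spread = 2,
                              t = 0.01, seed = 1L) {
  if (concentration <= 0) stop("concentration must be positive")
  set.seed(seed)
  n_v <- nrow(vocab)
  alpha <- concentration * n_v * vocab$frequency / sum(vocab$frequency)
  rows <- list()
  for (pid in names(passages)) {
    words <- passages[[pid]]
    for (pos in 2:length(words)) {
      p_true <- stats::rbeta(1, accuracy * spread, (1 - accuracy) * spread)
      g <- stats::rgamma(n_v, shape = alpha)
      tail_p <- g / sum(g)
      dist <- (1 - p_true) * tail_p
      true_i <- match(words[pos], vocab$word)
      dist[true_i] <- dist[true_i] + p_true
      names(dist) <- vocab$word
      keep <- filter_lm_predictions(dist, t)
      if (length(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          passage_id = pid, position = pos, candidate = names(keep),
          probability = as.numeric(keep), source = "lm",
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("readsim_pred_table", "data.frame")
  out
}

#' Generate pseudo-human word-level measures
#'
#' Ground truth for recovery experiments: runs the simulator itself with
#' a known predictability table and configuration, averages the
#' word-level measures over `k_runs` seeded runs, and adds Gaussian
#' noise with standard deviation `noise_sd` times the across-word SD of
#' each measure.  The output mimics a participant-averaged word-level
#' eye-movement file, including word features (length, normalized
#' frequency, table predictability of the text word, POS tag).
#'
#' @param passages Named list of word vectors.
#' @param lexicon A `readsim_lexicon`.
#' @param table Generating predictability table (or `NULL` baseline).
#' @param config Simulator configuration.
#' @param pos Optional parallel list of POS tag vectors.
#' @param k_runs Runs averaged (default 5).
#' @param noise_sd Relative noise level (default 0.1; 0 = no noise).
#' @param seed RNG seed.
#' @return Data frame in the human-measures CSV layout.
#' @export
generate_pseudo_human <- function(passages, lexicon, table = NULL,
                                  config = default_config(), pos = NULL,
                                  k_runs = 5L, noise_sd = 0.1, seed = 1L) {
  runs <- simulate_corpus(passages, lexicon, table, config,
                          n_sims = k_runs, seed = seed)
  per_run <- lapply(runs, run_word_measures)
  key <- per_run[[1L]][, c("passage_id", "word_id")]
  avg <- function(col) {
    m <- sapply(per_run, `[[`, col)
    rowMeans(m, na.rm = TRUE)
  }
  out <- data.frame(
    passage_id = key$passage_id, word_id = key$word_id,
    word = unlist(passages, use.names = FALSE),
    skip_rate = avg("SK"), ffd_ms = avg("FFD"), gd_ms = avg("GD"),
    trt_ms = avg("TRT"), regression_rate = avg("RG"),
    stringsAsFactors = FALSE)
  out$length <- nchar(out$word)
  out$frequency <- lexicon$freq_norm[lexicon_index(lexicon, out$word)]
  out$cloze <- 0
  if (!is.null(table)) {
    for (pid in unique(out$passage_id)) {
      idx <- index_prediction_table(table, pid, passages[[pid]], lexicon)
      sel <- out$passage_id == pid
      out$cloze[sel] <- idx$text_prob[out$word_id[sel]]
    }
  }
  out$pos <- if (!is.null(pos)) unlist(pos, use.names = FALSE) else NA
  if (noise_sd > 0) {
    set.seed(seed + 999L)
    for (col in c("skip_rate", "ffd_ms", "gd_ms", "trt_ms",
                  "regression_rate")) {
      s <- stats::sd(out[[col]], na.rm = TRUE)
      ok <- is.finite(out[[col]])
      out[[col]][ok] <- out[[col]][ok] + stats::rnorm(sum(ok), 0, noise_sd * s)
    }
    out$skip_rate <- pmin(pmax(out$skip_rate, 0), 1)
    out$regression_rate <- pmin(pmax(out$regression_rate, 0), 1)
  }
  out
}

#' Write a complete fixture set to disk
#'
#' Writes `passages.txt` (one passage per line), `lexicon.tsv`,
#' `cloze.tsv`, `lm.tsv`, `human.csv` and a `manifest.yaml` recording
#' the spec and derived seeds, then returns the in-memory objects.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param config Simulator configuration for the pseudo-human generator.
#' @return Invisibly, a list with `passages`, `pos`, `vocab`, `lexicon`,
#'   `cloze`, `lm`, `human`.
#' @export
write_fixtures <- function(spec, dir = NULL, config = default_config()) {
  gen <- generate_passages(spec)
  lexicon <- build_lexicon(gen$passages,
                           gen$vocab[, c("word", "frequency")],
                           n_top = 500L)
  cloze <- generate_cloze_table(gen$passages, gen$vocab,
                                n_respondents = spec$n_respondents,
                                accuracy = spec$cloze_accuracy,
                                seed = spec$seed + 3L)
  lm <- generate_lm_table(gen$passages, gen$vocab,
                          accuracy = spec$lm_accuracy,
                          concentration = spec$lm_concentration,
                          seed = spec$seed + 4L)
  human <- generate_pseudo_human(gen$passages, lexicon, lm, config,
                                 pos = gen$pos, noise_sd = spec$noise_sd,
                                 seed = spec$seed + 5L)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(vapply(gen$passages, paste, character(1), collapse = " "),
               file.path(dir, "passages.txt"))
    utils::write.table(gen$vocab[, c("word", "frequency")],
                       file.path(dir, "lexicon.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_prediction_table(cloze, file.path(dir, "cloze.tsv"))
    write_prediction_table(lm, file.path(dir, "lm.tsv"))
    utils::write.csv(human, file.path(dir, "human.csv"), row.names = FALSE)
    yaml::write_yaml(list(spec = unclass(spec),
                          seeds = list(vocab = spec$seed,
                                       passages = spec$seed + 2L,
                                       cloze = spec$seed + 3L,
                                       lm = spec$seed + 4L,
                                       human = spec$seed + 5L)),
                     file.path(dir, "manifest.yaml"))
  }
  invisible(list(passages = gen$passages, pos = gen$pos, vocab = gen$vocab,
                 lexicon = lexicon, cloze = cloze, lm = lm, human = human))
}
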