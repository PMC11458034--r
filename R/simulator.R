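#' One word-activation cycle
#'
#' Updates every lexicon word's activation by one 25 ms processing cycle:
#' `dS_w = (S_max - S_w) * [c_1 * excitation_w - c_2 * inhibition_w +
#' A_p(w)] + (S_w - S_min) * tau`, followed by clamping to
#' `[S_min, S_max]`.  Excitation is the summed activation of the input
#' bigrams contained in `w`; inhibition is `sum_k d[w, k] * S_k` over
#' competing words weighted by orthographic overlap (self-overlap
#' excluded); `A_p` is the predictive activation of words predicted at
#' unrecognized parafoveal positions; decay applies to every word every
#' cycle, so words outside the visual input simply decay.
#'
#' @param S Activation vector over the lexicon.
#' @param excitation Per-word bigram excitation (same length as `S`).
#' @param overlap Pairwise overlap matrix `d` with zero diagonal.
#' @param A_p Predictive activation per word (scalar 0 or vector).
#' @param params [activation_params()].
#' @return Updated activation vector, clamped to `[S_min, S_max]`.
#' @export
processing_cycle <- function(S, excitation, overlap, A_p = 0,
                             params = activation_params()) {
  inhibition <- as.vector(overlap %*% S)
  input <- params$c_1 * excitation - params$c_2 * inhibition + A_p
  S_new <- S + (params$S_max - S) * input + (S - params$S_min) * params$tau
  pmin(pmax(S_new, params$S_min), params$S_max)
}

#' Check for newly recognized words
#'
#' A text position is recognized as lexicon word `w` once `S_w` reaches
#' the word's recognition threshold, `w` is of similar length to the
#' text word at that position (within `ceiling(length_tolerance * len)`
#' letters), and `w` shares open bigrams with the visual input at that
#' position (at least `min_overlap` of its own bigram set).  The overlap
#' gate ties a candidate to the position whose input actually supports
#' it: without it, any word driven over threshold by one stimulus slot
#' could claim every other slot of similar length.  Among qualifying
#' candidates the one with the highest activation wins; the position is
#' then frozen, whether or not the winner is the actual text word.
#'
#' @param S Activation vector.
#' @param lexicon A `readsim_lexicon`.
#' @param positions Integer vector of text positions to check.
#' @param words Character vector of all passage words.
#' @param recognized Integer vector of recognized lexicon indices per
#'   position (NA where unrecognized).
#' @param length_tolerance Relative tolerance of the length gate.
#' @param min_overlap Minimum fraction of the candidate's open bigrams
#'   that must appear in the input word at the position (default 1/3,
#'   loose enough to keep orthographic-neighbour confusions possible).
#' @param text_bigrams Optional precomputed list of the passage words'
#'   bigram sets (computed on the fly when `NULL`).
#' @return Data frame with columns `position` and `word_index` for newly
#'   recognized positions (zero rows if none).
#' @export
check_recognition <- function(S, lexicon, positions, words, recognized,
                              length_tolerance = 0.25, min_overlap = 1 / 3,
                              text_bigrams = NULL) {
  hits <- list()
  above <- S >= lexicon$threshold
  if (!any(above)) {
    return(data.frame(position = integer(0), word_index = integer(0)))
  }
  cand <- which(above)
  for (p in positions) {
    if (!is.na(recognized[p])) next
    len <- nchar(words[p])
    tol <- ceiling(length_tolerance * len)
    elig <- cand[abs(lexicon$length[cand] - len) <= tol]
    if (length(elig)) {
      bg_p <- if (is.null(text_bigrams)) open_bigrams(words[p])
              else text_bigrams[[p]]
      shared <- vapply(elig, function(w) {
        bw <- lexicon$bigrams[[w]]
        sum(bw %in% bg_p) / length(bw)
      }, numeric(1))
      elig <- elig[shared >= min_overlap]
    }
    if (length(elig)) {
      winner <- elig[which.max(S[elig])]
      hits[[length(hits) + 1L]] <- c(p, winner)
      cand <- setdiff(cand, winner)   # one position per word per cycle
      if (!length(cand)) break
    }
  }
  if (!length(hits)) {
    return(data.frame(position = integer(0), word_index = integer(0)))
  }
  m <- do.call(rbind, hits)
  data.frame(position = m[, 1L], word_index = m[, 2L])
}

#' Stochastic saccade-initiation decision
#'
#' Saccades are initiated stochastically: each cycle after a refractory
#' minimum, a saccade starts with probability
#' `min(p_base + gain * newly_recognized_count, p_cap)`; successful word
#' recognition therefore increases the likelihood of moving the eyes.
#' The count is the number of words recognized since fixation onset, so
#' the elevated rate persists for the rest of the fixation rather than
#' for a single cycle — this is what lets recognition speed shape
#' fixation durations.  A hard maximum fixation duration forces
#' initiation.
#'
#' Consumes one uniform random draw when the decision is probabilistic.
#'
#' @param newly_recognized_count Words recognized during the current
#'   fixation so far.
#' @param cycles_elapsed Cycles since fixation onset.
#' @param saccade Saccade section of the configuration.
#' @return Logical: initiate now?
#' @export
saccade_decision <- function(newly_recognized_count, cycles_elapsed,
                             saccade = default_config()$saccade) {
  if (cycles_elapsed < saccade$min_cycles) return(FALSE)
  if (cycles_elapsed >= saccade$max_cycles) return(TRUE)
  p <- min(saccade$p_base + saccade$gain * newly_recognized_count,
           saccade$p_cap)
  stats::runif(1) < p
}

#' Grow or shrink the attention window
#'
#' Successful recognition widens the attention window by one step;
#' failure narrows it, both clamped to the configured bounds.
#'
#' @param recognition_success Logical.
#' @param window Current window in letters.
#' @param saccade Saccade section of the configuration.
#' @return New window size.
#' @export
update_attention_window <- function(recognition_success, window,
                                    saccade = default_config()$saccade) {
  if (isTRUE(recognition_success))
    min(window + saccade$window_step, saccade$window_max)
  else
    max(window - saccade$window_step, saccade$window_min)
}

#' Select the next forward saccade target
#'
#' Among the parafoveal words (up to three ahead) whose first letter
#' falls inside the attention window, the most visually salient
#' unrecognized word is targeted; salience is the summed letter input of
#' the word as seen from the current fixation.  Words already recognized
#' in the parafovea are excluded and hence skipped.  Ties go to the
#' nearer word.  If no window word qualifies, the nearest unrecognized
#' word ahead is targeted; if none exists, `NA` is returned (end of
#' passage).
#'
#' @param layout Passage layout from `passage_layout()`.
#' @param fixation_word,fixation_letter Current fixation.
#' @param recognized Integer vector (NA = unrecognized position).
#' @param window Attention window (letters).
#' @param vparams [visual_params()].
#' @return Target word index or `NA_integer_`.
#' @export
select_saccade_target <- function(layout, fixation_word, fixation_letter,
                                  recognized, window,
                                  vparams = visual_params()) {
  n <- nrow(layout)
  ahead <- seq_len(n)[seq_len(n) > fixation_word]
  if (!length(ahead)) return(NA_integer_)
  near <- ahead[ahead <= fixation_word + 3L &
                layout$start[ahead] <= fixation_letter + window]
  cand <- near[is.na(recognized[near])]
  if (length(cand)) {
    sal <- vapply(cand, function(w) {
      word_percept(layout$word[w], layout$start[w], fixation_letter,
                   fixation_letter, window, vparams)$salience
    }, numeric(1))
    return(cand[which.max(sal)])   # which.max keeps the nearer word on ties
  }
  fallback <- ahead[is.na(recognized[ahead])]
  if (length(fallback)) fallback[1L] else NA_integer_
}

#' Possibly schedule a regression
#'
#' At the end of a fixation, if any earlier position within the lookback
#' range is still unrecognized, the next saccade targets the earliest
#' such position with probability `p_regress`.  Consumes one uniform
#' draw when candidates exist.
#'
#' @param recognized Integer vector (NA = unrecognized).
#' @param fixation_word Current fixation word index.
#' @param saccade Saccade section of the configuration.
#' @return Regression target index, or `NA_integer_` if none scheduled.
#' @export
schedule_regression <- function(recognized, fixation_word,
                                saccade = default_config()$saccade) {
  lo <- max(1L, fixation_word - saccade$regression_lookback)
  back <- seq_len(fixation_word - 1L)
  back <- back[back >= lo & is.na(recognized[back])]
  if (!length(back)) return(NA_integer_)
  if (stats::runif(1) < saccade$p_regress) back[1L] else NA_integer_
}

#' Simulate reading of one passage
#'
#' Runs the full cycle-by-cycle simulation: the fixated word and its
#' neighbours (one behind, three ahead) are processed in parallel; bigram
#' excitation, overlap inhibition, predictive activation and decay update
#' the lexicon each 25 ms cycle; recognized positions freeze; saccades
#' are initiated stochastically and targeted by salience, with skips of
#' parafoveally recognized words and occasional regressions to
#' unrecognized earlier words.  Reading starts at the first word and ends
#' when no unrecognized word remains ahead of the eyes (abandoning, at
#' the maximum fixation duration, words that never reach threshold).
#'
#' Deterministic given `seed`.
#'
#' @param passage A passage: either a single string or a character vector
#'   of words (normalized: lowercase, no punctuation).
#' @param lexicon A `readsim_lexicon` containing every passage word.
#' @param table Optional predictability table (data frame as returned by
#'   [cloze_probabilities()] or [read_prediction_table()]); `NULL` for
#'   the no-predictability baseline.
#' @param config A [default_config()]-style configuration; `config$model$c_p`
#'   selects the predictability weight.
#' @param seed Integer seed for the run.
#' @param passage_id Identifier recorded in the output (default "p1").
#' @return List with elements `events` (one row per fixation:
#'   `passage_id`, `fixation_index`, `word_index`, `landing_letter`,
#'   `duration_ms`, `saccade_type`, `recognized_word`), `recognition`
#'   (one row per text position: recognized word, correctness, global
#'   cycle of recognition) and `n_words`.
#' @export
simulate_passage <- function(passage, lexicon, table = NULL,
                             config = default_config(), seed = 1L,
                             passage_id = "p1") {
  words <- if (length(passage) == 1L && !grepl("^\\S+$", passage))
    passage_words(passage) else as.character(passage)
  n <- length(words)
  text_idx <- lexicon_index(lexicon, words)
  if (anyNA(text_idx))
    stop("passage words absent from lexicon: ",
         paste(unique(words[is.na(text_idx)]), collapse = ", "))
  layout <- passage_layout(words)
  text_bigrams <- lapply(words, open_bigrams)
  aparams <- activation_params(S_max = config$model$S_max,
                               S_min = config$model$S_min,
                               tau = config$model$tau,
                               c_1 = config$model$c_1,
                               c_2 = config$model$c_2,
                               cycle_ms = config$model$cycle_ms)
  vparams <- do.call(visual_params, config$visual)
  sacc <- config$saccade
  c_p <- config$model$c_p
  tbl <- if (is.null(table) || c_p == 0) NULL
         else index_prediction_table(table, passage_id, words, lexicon)

  set.seed(as.integer(seed))
  S <- numeric(length(lexicon$word))
  recognized <- rep(NA_integer_, n)
  rec_correct <- rep(NA, n)
  rec_cycle <- rep(NA_integer_, n)
  window <- sacc$window_init
  fixation_word <- 1L
  fixation_letter <- round(layout$center[1L])
  global_cycle <- 0L
  events <- vector("list", 0L)
  max_fixations <- max(8L, 4L * n)

  for (fix_i in seq_len(max_fixations)) {
    pc <- fixation_percepts(layout, fixation_word, fixation_letter,
                            fixation_letter, window, vparams)
    exc <- lexical_excitation(pc$bigram_activation, lexicon)
    cycles <- 0L
    n_rec_fix <- 0L
    repeat {
      cycles <- cycles + 1L
      global_cycle <- global_cycle + 1L
      A_p <- 0
      if (!is.null(tbl)) {
        ahead <- pc$slots[pc$slots > fixation_word]
        ahead <- ahead[is.na(recognized[ahead]) & ahead >= 2L]
        if (length(ahead)) {
          A_p <- numeric(length(S))
          for (p in ahead) {
            entries <- tbl$by_pos[[p]]
            if (is.null(entries)) next
            pred_prev <- if (!is.na(recognized[p - 1L])) 1
                         else tbl$text_prob[p - 1L]
            if (pred_prev > 0)
              A_p[entries$index] <- A_p[entries$index] +
                entries$probability * pred_prev * c_p
          }
        }
      }
      S <- processing_cycle(S, exc, lexicon$inhibition, A_p, aparams)
      newrec <- check_recognition(S, lexicon, pc$slots, words, recognized,
                                  config$model$length_tolerance,
                                  config$model$min_overlap, text_bigrams)
      if (nrow(newrec)) {
        recognized[newrec$position] <- newrec$word_index
        rec_correct[newrec$position] <-
          lexicon$word[newrec$word_index] == words[newrec$position]
        rec_cycle[newrec$position] <- global_cycle
        n_rec_fix <- n_rec_fix + nrow(newrec)
        # lexical access consumes the word's activation: without the
        # reset, recognized frequent words linger at ceiling, suppress
        # every later word through overlap inhibition, and claim other
        # positions of similar length
        S[newrec$word_index] <- aparams$S_min
      }
      if (saccade_decision(n_rec_fix, cycles, sacc)) break
    }
    window <- update_attention_window(n_rec_fix > 0L, window, sacc)
    target <- schedule_regression(recognized, fixation_word, sacc)
    if (is.na(target))
      target <- select_saccade_target(layout, fixation_word, fixation_letter,
                                      recognized, window, vparams)
    type <- if (is.na(target)) "forward"
            else if (target < fixation_word) "regression"
            else if (target == fixation_word) "refixation"
            else if (target == fixation_word + 1L) "forward"
            else "skip"
    rw <- recognized[fixation_word]
    events[[fix_i]] <- data.frame(
      passage_id = passage_id, fixation_index = fix_i,
      word_index = fixation_word, landing_letter = fixation_letter,
      duration_ms = cycles * aparams$cycle_ms, saccade_type = type,
      recognized_word = if (is.na(rw)) NA_character_ else lexicon$word[rw],
      stringsAsFactors = FALSE)
    if (is.na(target)) break
    fixation_word <- target
    fixation_letter <- round(layout$center[target])
  }
  list(events = do.call(rbind, events),
       recognition = data.frame(
         position = seq_len(n), word = words,
         recognized_as = ifelse(is.na(recognized), NA_character_,
                                lexicon$word[recognized]),
         correct = rec_correct, cycle = rec_cycle,
         stringsAsFactors = FALSE),
       n_words = n)
}

#' Simulate a corpus of passages, possibly repeatedly
#'
#' @param passages Named list of passages (character vectors of words).
#' @param lexicon A `readsim_lexicon`.
#' @param table Optional predictability table.
#' @param config Configuration.
#' @param n_sims Number of independent simulations of the whole corpus.
#' @param seed Base seed; each (simulation, passage) pair derives its own
#'   sub-seed, so runs are independent but reproducible.
#' @return List of length `n_sims`; each element is a named list of
#'   [simulate_passage()] results, one per passage.
#' @export
simulate_corpus <- function(passages, lexicon, table = NULL,
                            config = default_config(), n_sims = 1L,
                            seed = 1L) {
  if (is.null(names(passages)))
    names(passages) <- paste0("p", seq_along(passages))
  lapply(seq_len(n_sims), function(s) {
    out <- lapply(seq_along(passages), function(i) {
      sub_seed <- (as.integer(seed) + 7919L * (s - 1L) + 131L * i) %% .Machine$integer.max
      simulate_passage(passages[[i]], lexicon, table, config,
                       seed = sub_seed, passage_id = names(passages)[i])
    })
    names(out) <- names(passages)
    out
  })
}

#' Write fixation events as TSV
#'
#' @param events Event data frame (possibly rbind-ed across passages).
#' @param path Output path.
#' @export
write_fixations <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Normalize and load passages
#'
#' Reads UTF-8 text, one passage per line; punctuation is removed,
#' trailing spaces stripped and words lower-cased.
#'
#' @param path Path to the text file.
#' @return Named list of character vectors of words (`p1`, `p2`, ...).
#' @export
read_passages <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, passage_words)
  names(out) <- sprintf("p%02d", seq_along(out))
  out
}

#' Split a raw passage string into normalized words
#'
#' @param text Single passage string.
#' @return Character vector of lowercase, punctuation-free words.
#' @export
passage_words <- function(text) {
  text <- tolower(text)
  text <- gsub("[^a-z' ]", " ", text)
  text <- gsub("'", "", text, fixed = TRUE)
  words <- strsplit(trimws(gsub(" +", " ", text)), " ", fixed = TRUE)[[1L]]
  words[nzchar(words)]
}

#' Calibrate the global input gain
#'
#' The absolute scale of letter input is the model's one free scaling
#' parameter: all printed constants fix only the relative structure of
#' visual processing.  This routine searches `input_gain` so that
#' simulated in-context word-recognition accuracy on the supplied
#' passages falls inside the target band (default 0.90-0.94, bracketing
#' the stable accuracy the model is expected to show).  Accuracy is
#' monotone increasing in the gain over the useful range: with too
#' little input, rare words never reach threshold when fixated.
#'
#' @param lexicon A `readsim_lexicon`.
#' @param passages Named list of passages (word vectors) to calibrate on.
#' @param config Base configuration (its visual section is varied).
#' @param target_accuracy Acceptable accuracy band.
#' @param gain_range Search interval for the gain.
#' @param seed Seed for the calibration simulations.
#' @return The calibrated gain (numeric scalar).
#' @export
calibrate_input_gain <- function(lexicon, passages,
                                 config = default_config(),
                                 target_accuracy = c(0.90, 0.94),
                                 gain_range = c(50, 2e4), seed = 1L) {
  accuracy_at <- function(gain) {
    cfg <- config
    cfg$visual$input_gain <- gain
    runs <- simulate_corpus(passages, lexicon, NULL, cfg, n_sims = 1L,
                            seed = seed)
    recognition_accuracy(runs[[1L]])
  }
  lo <- gain_range[1L]; hi <- gain_range[2L]
  mid <- sqrt(lo * hi)
  for (i in 1:25) {
    mid <- sqrt(lo * hi)
    acc <- accuracy_at(mid)
    if (acc < target_accuracy[1L]) lo <- mid
    else if (acc > target_accuracy[2L]) hi <- mid
    else return(mid)
  }
  mid
}
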