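#' Aggregate fixation events into word-level eye-movement measures
#'
#' Applies the standard word-based definitions to an ordered fixation
#' stream:
#' * `FFD` (first fixation duration): duration of the first fixation on
#'   the word;
#' * `GD` (gaze duration): sum of the consecutive fixations on the word
#'   starting at its first fixation, before the eyes move elsewhere;
#' * `TRT` (total reading time): sum of all fixation durations on the
#'   word;
#' * `SK` (first-pass skip): 1 if the word was not fixated before a
#'   fixation on any later word (or never fixated at all);
#' * `RG` (regression): 1 if the word was fixated after the eyes had
#'   already passed it (i.e. after a fixation on a later word).
#'
#' Never-fixated words have `SK = 1`, `RG = 0` and missing durations.
#'
#' @param events Fixation data frame with columns `word_index`,
#'   `duration_ms` and `fixation_index` (strictly increasing).
#' @param n_words Number of words in the passage.
#' @return Data frame with one row per word: `word_id`, `SK`, `FFD`,
#'   `GD`, `TRT`, `RG`.
#' @export
fixations_to_word_measures <- function(events, n_words) {
  if (nrow(events) && is.unsorted(events$fixation_index, strictly = TRUE))
    stop("events must be ordered by fixation_index")
  w <- events$word_index
  d <- events$duration_ms
  out <- data.frame(word_id = seq_len(n_words), SK = 1L,
                    FFD = NA_real_, GD = NA_real_, TRT = NA_real_,
                    RG = 0L)
  for (id in seq_len(n_words)) {
    fx <- which(w == id)
    if (!length(fx)) next
    first <- fx[1L]
    run_end <- first
    while (run_end < length(w) && w[run_end + 1L] == id) run_end <- run_end + 1L
    later <- which(w > id)
    out$FFD[id] <- d[first]
    out$GD[id] <- sum(d[first:run_end])
    out$TRT[id] <- sum(d[fx])
    out$SK[id] <- as.integer(any(w[seq_len(first - 1L)] > id))
    out$RG[id] <- as.integer(length(later) > 0L && any(fx > min(later)))
  }
  out
}

#' Word measures for a whole simulated corpus run
#'
#' @param run One element of the list returned by [simulate_corpus()]
#'   (a named list of per-passage simulation results).
#' @return Data frame of per-word measures with a `passage_id` column.
#' @export
run_word_measures <- function(run) {
  out <- lapply(names(run), function(pid) {
    m <- fixations_to_word_measures(run[[pid]]$events, run[[pid]]$n_words)
    cbind(passage_id = pid, m, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standardized root-mean-square error
#'
#' Differences between simulated and human per-word values are
#' standardized by the across-word human standard deviation of the
#' measure, then combined as `sqrt(mean(z^2))`.  Word pairs with a
#' missing value on either side are excluded.  The score is 0 at a
#' perfect match; `plus_one = TRUE` adds a unit reporting offset for
#' visual comparability with conventions that anchor the minimum at 1.
#'
#' @param sim,human Aligned numeric vectors of per-word values.
#' @param human_sd Human across-word standard deviation of the measure.
#' @param plus_one Add 1 to the reported score (default `FALSE`).
#' @return Non-negative scalar.
#' @export
standardized_rmse <- function(sim, human, human_sd, plus_one = FALSE) {
  if (length(sim) != length(human)) stop("sim and human must be aligned")
  if (!is.finite(human_sd) || human_sd <= 0) stop("human_sd must be positive")
  ok <- is.finite(sim) & is.finite(human)
  if (!any(ok)) stop("no overlapping words between sim and human")
  z <- (sim[ok] - human[ok]) / human_sd
  sqrt(mean(z^2)) + if (plus_one) 1 else 0
}

#' Per-measure standardized RMSE of one simulation run
#'
#' @param sim_measures Per-word measures of one run ([run_word_measures()]).
#' @param human Human word-level data ([read_human_measures()]).
#' @param measures Which measures to score.
#' @return Named numeric vector of RMSE scores.
#' @export
rmse_by_measure <- function(sim_measures, human,
                            measures = c("SK", "FFD", "GD", "TRT", "RG")) {
  key_sim <- paste(sim_measures$passage_id, sim_measures$word_id)
  key_hum <- paste(human$passage_id, human$word_id)
  idx <- match(key_hum, key_sim)
  human_cols <- c(SK = "skip_rate", FFD = "ffd_ms", GD = "gd_ms",
                  TRT = "trt_ms", RG = "regression_rate")
  vapply(measures, function(m) {
    h <- human[[human_cols[[m]]]]
    s <- sim_measures[[m]][idx]
    sd_h <- stats::sd(h, na.rm = TRUE)
    if (!is.finite(sd_h) || sd_h <= 0) {
      # degenerate human measure (e.g. nobody ever regressed): the score
      # is 0 on a perfect match and cannot be standardized otherwise
      ok <- is.finite(s) & is.finite(h)
      if (any(ok) && all(s[ok] == h[ok])) return(0)
      warning("human '", m, "' has zero variance; RMSE undefined")
      return(NA_real_)
    }
    standardized_rmse(s, h, sd_h)
  }, numeric(1))
}

#' Paired comparison of per-simulation RMSE scores
#'
#' Wilcoxon signed-rank test on paired per-simulation RMSE arrays from
#' two conditions, with the conventional significance bands.
#'
#' @param rmse_a,rmse_b Equal-length numeric vectors, one score per
#'   simulation, paired by simulation index.
#' @param adjust Unused by default; `"holm"` applies no change here but
#'   is accepted for interface symmetry with multi-comparison wrappers.
#' @return List with `statistic`, `p_value` and `band` (one of `"ns"`,
#'   `"*"`, `"**"`, `"***"`).
#' @export
compare_conditions <- function(rmse_a, rmse_b, adjust = "none") {
  if (length(rmse_a) != length(rmse_b))
    stop("paired arrays must have equal length")
  if (length(rmse_a) < 2L) stop("need at least two paired simulations")
  if (all(rmse_a == rmse_b)) stop("all paired differences are zero")
  wt <- suppressWarnings(stats::wilcox.test(rmse_a, rmse_b, paired = TRUE,
                                            exact = FALSE))
  p <- wt$p.value
  band <- if (p <= 0.001) "***" else if (p <= 0.01) "**"
          else if (p <= 0.05) "*" else "ns"
  list(statistic = unname(wt$statistic), p_value = p, band = band)
}

#' RMSE binned over a word feature
#'
#' Splits words into `n_bins` equal-width bins over the feature range,
#' computes the standardized RMSE within each bin separately per
#' simulation, and averages over simulations.  Empty bins are reported
#' as `NA`.
#'
#' @param word_rows Data frame with columns `simulation`, `feature`,
#'   `sim` and `human` (per-word values, one row per word per
#'   simulation).
#' @param human_sd Standardizing human SD of the measure.
#' @param n_bins Number of bins (default 20).
#' @return Data frame with `bin`, `lower`, `upper`, `rmse`, `n_words`.
#' @export
binned_error <- function(word_rows, human_sd, n_bins = 20L) {
  f <- word_rows$feature
  rng <- range(f, finite = TRUE)
  if (diff(rng) == 0) {
    warning("constant feature: falling back to a single bin")
    n_bins <- 1L
    rng <- rng + c(-0.5, 0.5)
  }
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- findInterval(f, edges, rightmost.closed = TRUE, all.inside = TRUE)
  z2 <- ((word_rows$sim - word_rows$human) / human_sd)^2
  ok <- is.finite(z2)
  per_sim <- lapply(split(seq_along(z2)[ok],
                          list(bin = bin[ok], sim = word_rows$simulation[ok])),
                    function(i) c(bin = bin[i[1L]], rmse = sqrt(mean(z2[i]))))
  agg <- do.call(rbind, per_sim)
  rmse <- rep(NA_real_, n_bins)
  nw <- integer(n_bins)
  if (!is.null(agg)) {
    means <- tapply(agg[, "rmse"], agg[, "bin"], mean)
    rmse[as.integer(names(means))] <- as.numeric(means)
  }
  counts <- tabulate(bin[ok], nbins = n_bins)
  data.frame(bin = seq_len(n_bins), lower = edges[-(n_bins + 1L)],
             upper = edges[-1L], rmse = rmse, n_words = counts)
}

#' Map a Universal POS tag to a word-type category
#'
#' Content words are nouns, verbs, adjectives, adverbs and proper nouns;
#' function words are auxiliaries, adpositions, conjunctions,
#' determiners, particles and pronouns; numerals, interjections and
#' miscellaneous tags are "other".  Unknown tags map to "other" with a
#' warning.
#'
#' @param tag Character vector of Universal POS tags.
#' @return Factor-free character vector in `{content, function, other}`.
#' @export
pos_category <- function(tag) {
  content <- c("NOUN", "VERB", "ADJ", "ADV", "PROPN")
  func <- c("AUX", "ADP", "CONJ", "SCONJ", "CCONJ", "DET", "PART", "PRON")
  other <- c("NUM", "INTJ", "X")
  out <- ifelse(tag %in% content, "content",
                ifelse(tag %in% func, "function", "other"))
  unknown <- !(tag %in% c(content, func, other))
  if (any(unknown))
    warning("unknown POS tag(s) mapped to 'other': ",
            paste(unique(tag[unknown]), collapse = ", "))
  out
}

#' Word-recognition accuracy of a simulation
#'
#' Fraction of text positions recognized as exactly the text word;
#' positions recognized as an orthographic neighbour, or not recognized
#' at all, count as incorrect.
#'
#' @param recognition Recognition record of [simulate_passage()], or a
#'   whole corpus run (list of results).
#' @return Proportion in `[0, 1]`.
#' @export
recognition_accuracy <- function(recognition) {
  if (is.list(recognition) && !is.data.frame(recognition))
    recognition <- do.call(rbind, lapply(recognition, `[[`, "recognition"))
  mean(recognition$correct %in% TRUE)
}

#' Read Provo-style human word-level measures
#'
#' Comma-separated with header; required columns `passage_id`, `word_id`,
#' `word`, `skip_rate`, `ffd_ms`, `gd_ms`, `trt_ms`, `regression_rate`;
#' extra columns (length, frequency, cloze, POS, ...) are kept.  Empty
#' duration cells become `NA` (always-skipped words).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_human_measures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("passage_id", "word_id", "word", "skip_rate", "ffd_ms",
            "gd_ms", "trt_ms", "regression_rate")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df$word_id <- as.integer(df$word_id)
  df
}

#' Score a set of simulation runs against human data
#'
#' @param runs Output of [simulate_corpus()].
#' @param human Human measures ([read_human_measures()]).
#' @param measures Measures to score.
#' @return Data frame with one row per (simulation, measure) and the
#'   RMSE score, plus a `mean` helper column averaged over measures per
#'   simulation available via [aggregate_fit()].
#' @export
evaluate_runs <- function(runs, human,
                          measures = c("SK", "FFD", "GD", "TRT", "RG")) {
  rows <- lapply(seq_along(runs), function(s) {
    sm <- run_word_measures(runs[[s]])
    sc <- rmse_by_measure(sm, human, measures)
    data.frame(simulation = s, measure = names(sc), rmse = as.numeric(sc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average fit per simulation across measures
#'
#' @param fit Data frame from [evaluate_runs()].
#' @return Numeric vector, mean RMSE per simulation.
#' @export
aggregate_fit <- function(fit) {
  as.numeric(tapply(fit$rmse, fit$simulation, mean, na.rm = TRUE))
}

#' Write an evaluation report
#'
#' Serializes per-condition RMSE arrays, pairwise test results and any
#' binned tables as JSON, plus a tidy CSV of the per-simulation scores.
#'
#' @param report A named list (conditions -> [evaluate_runs()] frames,
#'   optionally `comparisons` and `binned` entries).
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_evaluation_report <- function(report, json_path = NULL,
                                    csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(csv_path)) {
    tidy <- do.call(rbind, lapply(names(report$fits), function(cond) {
      cbind(condition = cond, report$fits[[cond]], stringsAsFactors = FALSE)
    }))
    utils::write.csv(tidy, csv_path, row.names = FALSE)
  }
  invisible(report)
}
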