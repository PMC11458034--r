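#' Build a predictability table from cloze responses
#'
#' Cloze probability of a continuation at a text position is the
#' proportion of respondents who produced that continuation.  Candidates
#' that no respondent produced are absent from the table (probability 0
#' implied).
#'
#' @param responses A list of per-position response sets.  Each element is
#'   itself a list with fields `passage_id`, `position` (1-based word
#'   index of the position being predicted) and `answers` (character
#'   vector, one answer per respondent).
#' @return A predictability table: data frame with columns `passage_id`,
#'   `position`, `candidate`, `probability`, `source = "cloze"`.
#'   Per-position probabilities sum to exactly 1.
#' @export
cloze_probabilities <- function(responses) {
  rows <- lapply(responses, function(r) {
    if (length(r$answers) == 0L) stop("empty response list at position ",
                                      r$position, " of passage ", r$passage_id)
    tab <- table(tolower(r$answers))
    data.frame(passage_id = r$passage_id, position = as.integer(r$position),
               candidate = names(tab),
               probability = as.numeric(tab) / length(r$answers),
               source = "cloze", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("readsim_pred_table", "data.frame")
  out
}

#' Threshold a language-model next-token distribution
#'
#' Keeps only tokens whose probability strictly exceeds the threshold
#' `t`.  Surviving probabilities are returned unchanged: no softmax and
#' no renormalization is applied after filtering, so the surviving mass
#' is typically below 1.  Renormalizing the handful of survivors would
#' crush the variation among them (see [softmax()] for the demonstration).
#'
#' @param dist Named numeric vector, token -> probability.
#' @param t Threshold (default 0.01); ties at exactly `t` are excluded.
#' @return The surviving named sub-vector, unchanged values.
#' @export
filter_lm_predictions <- function(dist, t = 0.01) {
  if (length(dist) == 0L) return(dist)
  if (any(dist < 0 | dist > 1)) stop("probabilities must lie in [0, 1]")
  dist[dist > t]
}

#' Softmax of a numeric vector
#'
#' `exp(x) / sum(exp(x))`, computed with the usual max-shift for
#' numerical stability.  Included because it is the transform whose
#' near-uniform output on a thresholded handful of likelihoods motivates
#' leaving filtered language-model probabilities un-renormalized.
#'
#' @param x Numeric vector.
#' @return Probabilities summing to 1.
#' @export
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Match a predicted sub-word token to lexicon words
#'
#' Language-model vocabularies are sub-word: a predicted token counts as
#' a prediction of every lexicon word whose first sub-word token equals
#' it ("custom" predicts "customary" when the tokenizer splits it as
#' custom + ary).  All matched words receive the token's probability.
#'
#' @param predicted_token The token string.
#' @param word_tokenizations Named list, word -> character vector of its
#'   sub-word tokens.
#' @param lexicon A `readsim_lexicon`; matches are restricted to its words.
#' @return Character vector of matched lexicon words (possibly empty).
#' @export
match_first_token <- function(predicted_token, word_tokenizations, lexicon) {
  first <- vapply(word_tokenizations, function(tk) tk[[1L]], character(1))
  hits <- names(first)[first == predicted_token]
  hits[hits %in% lexicon$word]
}

#' Predictive activation of a candidate word
#'
#' The per-cycle activation added to a word predicted at an upcoming
#' position: `A_p = pred_w * pred_prev * c_p`, where `pred_w` is the
#' candidate's predictability (cloze or language-model), `pred_prev` is
#' the certainty about the preceding word, and `c_p` the predictability
#' weight.
#'
#' @param pred_w Candidate predictability in `(0, 1]` (vectorized).
#' @param certainty A [certainty_state()] (or its `pred_prev` value).
#' @param c_p Predictability weight, one of 0.05, 0.1, 0.2 in the
#'   standard conditions.
#' @return Non-negative activation increment.
#' @export
predictive_activation <- function(pred_w, certainty, c_p) {
  pred_prev <- if (is.list(certainty)) certainty$pred_prev else certainty
  pred_w * pred_prev * c_p
}

#' Certainty about the preceding word
#'
#' The dynamic weight `pred_prev` applied to predictions at a position:
#' 1 once the preceding word's lexical access has been completed,
#' otherwise that word's own table predictability (0 when absent from
#' the table).
#'
#' @param previous_word_recognized Logical.
#' @param table_prob_of_previous The table predictability of the
#'   preceding text word (default 0, i.e. absent).
#' @return A list of class `readsim_certainty` with field `pred_prev`.
#' @export
certainty_state <- function(previous_word_recognized,
                            table_prob_of_previous = 0) {
  pred_prev <- if (isTRUE(previous_word_recognized)) 1
               else as.numeric(table_prob_of_previous)
  if (pred_prev < 0 || pred_prev > 1) stop("pred_prev must lie in [0, 1]")
  structure(list(pred_prev = pred_prev), class = "readsim_certainty")
}

#' @rdname certainty_state
#' @export
update_certainty <- certainty_state

# --- table I/O ---------------------------------------------------------------

#' Read / write predictability tables
#'
#' Tab-separated, header row required, columns `passage_id`, `position`,
#' `candidate`, `probability`, `source`.  Positions are 0-based in the
#' file (as documented in its header) and 1-based in memory.
#'
#' @param path File path.
#' @return `read_prediction_table()` returns the in-memory table.
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  need <- c("passage_id", "position", "candidate", "probability", "source")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[, need]
  df$position <- as.integer(df$position) + 1L
  df$candidate <- tolower(df$candidate)
  if (any(df$probability <= 0)) stop("table probabilities must be positive")
  class(df) <- c("readsim_pred_table", "data.frame")
  df
}

#' @rdname read_prediction_table
#' @param table An in-memory predictability table.
#' @export
write_prediction_table <- function(table, path) {
  out <- as.data.frame(table)
  out$position <- out$position - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions are 0-based word indices", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fast per-passage lookup structure: list position -> data.frame of
# (lexicon index, probability); plus per-position predictability of the
# text word itself (for the certainty chain).
index_prediction_table <- function(table, passage_id, words, lexicon) {
  sub <- table[table$passage_id == passage_id, , drop = FALSE]
  n <- length(words)
  by_pos <- vector("list", n)
  text_prob <- numeric(n)
  if (nrow(sub)) {
    bad <- sub$position < 1L | sub$position > n
    if (any(bad))
      stop("prediction table misaligned with passage '", passage_id,
           "': position(s) ", paste(unique(sub$position[bad]), collapse = ", "),
           " outside 1..", n)
    idx <- lexicon_index(lexicon, sub$candidate)
    keep <- !is.na(idx)
    dropped <- sum(!keep)
    sub <- sub[keep, , drop = FALSE]
    idx <- idx[keep]
    for (p in unique(sub$position)) {
      sel <- sub$position == p
      by_pos[[p]] <- list(index = idx[sel], probability = sub$probability[sel])
      hit <- which(sub$candidate[sel] == words[p])
      if (length(hit)) text_prob[p] <- sub$probability[sel][hit[1L]]
    }
    attr(by_pos, "dropped_candidates") <- dropped
  }
  list(by_pos = by_pos, text_prob = text_prob)
}
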