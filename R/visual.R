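#' Visual-processing parameters
#'
#' Constants governing letter-level visual input.  `c_e` scales cortical
#' magnification; eccentricity enters the acuity factor through the linear
#' form `mag_slope * e + mag_intercept`; `letter_size` converts letter
#' distances to degrees of visual angle; `c_d` discounts the otherwise
#' overly strong activation of short words (few bigrams); `input_gain` is
#' a global scaling of letter input, calibrated so that in-context word
#' recognition accuracy on a synthetic reference corpus sits near 0.92
#' (see [calibrate_input_gain()]); the absolute activation scale is a
#' free parameter of the model and only relative structure is
#' theory-driven.
#'
#' @param c_e Cortical magnification scaling (default 35.55556).
#' @param mag_slope Slope of the magnification term (default 0.018, per
#'   degree of eccentricity).
#' @param mag_intercept Intercept of the magnification term (default 10.64).
#' @param letter_size Degrees of visual angle per letter (default 0.3).
#' @param c_d Discounted ngram factor (default 5).
#' @param input_gain Global input scaling (default 800; see Details).
#' @return A list of class `readsim_visual_params`.
#' @export
visual_params <- function(c_e = 35.55556, mag_slope = 0.018,
                          mag_intercept = 10.64, letter_size = 0.3,
                          c_d = 5, input_gain = 800) {
  p <- list(c_e = c_e, mag_slope = mag_slope, mag_intercept = mag_intercept,
            letter_size = letter_size, c_d = c_d, input_gain = input_gain)
  if (any(unlist(p) <= 0)) stop("all visual parameters must be positive")
  structure(p, class = "readsim_visual_params")
}

#' Letter eccentricity in degrees of visual angle
#'
#' @param letter_pos Letter position(s) in the stimulus (any integer scale).
#' @param fixation_pos Position of the centre of fixation on the same scale.
#' @param letter_size Degrees per letter (default 0.3).
#' @return `|letter_pos - fixation_pos| * letter_size`, in degrees.
#' @export
eccentricity <- function(letter_pos, fixation_pos, letter_size = 0.3) {
  abs(letter_pos - fixation_pos) * letter_size
}

#' Crowding masking factor
#'
#' Outer letters (first and last) are less crowded than inner letters, and
#' a one-letter word is not crowded at all: returns 3 for one-letter
#' words, 1 for outer letters, 0.5 for inner letters.
#'
#' @param word The word (single string).
#' @param letter_index 1-based index (vectorized) of the letter in the word.
#' @return Numeric vector of masking factors in `{3, 1, 0.5}`.
#' @export
crowding_mask <- function(word, letter_index) {
  n <- nchar(word)
  if (any(letter_index < 1L | letter_index > n))
    stop("`letter_index` outside word")
  if (n == 1L) return(rep(3, length(letter_index)))
  ifelse(letter_index == 1L | letter_index == n, 1, 0.5)
}

#' Attentional weight of a letter
#'
#' A Gaussian attention profile centred on the focus of attention with
#' standard deviation `window / 2` letters and peak 1.  Widening the
#' window raises the weight of every off-focus letter.
#'
#' @param letter_pos Letter position(s) in text coordinates.
#' @param attention_focus Centre of the attention profile.
#' @param window Attention window size in letters (> 0).
#' @return Weights in `(0, 1]`.
#' @export
attention_weight <- function(letter_pos, attention_focus, window) {
  if (any(window <= 0)) stop("`window` must be positive")
  exp(-((letter_pos - attention_focus)^2) / (2 * (window / 2)^2))
}

#' Visual input of a single letter
#'
#' Combines eccentricity-dependent acuity, crowding and attention:
#' `v_i = input_gain * a_i * m_i * [1 / (c_e * (mag_slope * e_i +
#' mag_intercept))] / (n_word_bigrams + c_d)`.
#' The normalization by the number of open bigrams of the word containing
#' the letter (plus `c_d`) prevents short words from dominating.
#'
#' @param e_i Eccentricity in degrees (vectorized).
#' @param m_i Crowding factor.
#' @param a_i Attention weight.
#' @param params [visual_params()].
#' @param n_word_bigrams Number of open bigrams of the containing word.
#' @return Non-negative visual input, zero when `a_i` is zero.
#' @export
letter_visual_input <- function(e_i, m_i, a_i, params = visual_params(),
                                n_word_bigrams = 1L) {
  acuity <- 1 / (params$c_e * (params$mag_slope * e_i + params$mag_intercept))
  params$input_gain * a_i * m_i * acuity / (n_word_bigrams + params$c_d)
}

#' Open-bigram activation from two letter inputs
#'
#' The activation of a bigram node is the geometric mean of the visual
#' inputs of its constituent letters: `O_ij = sqrt(v_i * v_j)`.
#'
#' @param v_i,v_j Non-negative letter inputs (vectorized).
#' @return `sqrt(v_i * v_j)`.
#' @export
bigram_activation <- function(v_i, v_j) {
  if (any(v_i < 0) || any(v_j < 0)) stop("letter inputs must be non-negative")
  sqrt(v_i * v_j)
}

# --- passage layout and per-fixation percepts --------------------------------

#' Letter layout of a passage
#'
#' Assigns every word a span of global letter positions, with one space
#' between consecutive words, and records each word's centre (used for
#' landing positions and attention focus).
#'
#' @param words Character vector of passage words.
#' @return Data frame with columns `word`, `start`, `end`, `center`.
#' @keywords internal
passage_layout <- function(words) {
  len <- nchar(words)
  end <- cumsum(len + 1L) - 1L        # +1 for the trailing space
  start <- end - len + 1L
  data.frame(word = words, start = start, end = end,
             center = start + (len - 1L) / 2,
             stringsAsFactors = FALSE)
}

# Per-word percept: letter inputs and bigram activations for one stimulus
# word viewed from a given fixation/attention state.  Returns the letter
# input vector and a named bigram-activation vector (repeated pairs keep
# the maximum activation, matching set semantics of the bigram code).
word_percept <- function(word, start_pos, fixation_pos, focus, window,
                         params) {
  n <- nchar(word)
  pos <- start_pos + seq_len(n) - 1L
  e <- eccentricity(pos, fixation_pos, params$letter_size)
  m <- crowding_mask(word, seq_len(n))
  a <- attention_weight(pos, focus, window)
  nb <- if (n == 1L) 1L else length(open_bigrams(word))
  v <- letter_visual_input(e, m, a, params, nb)
  if (n == 1L) {
    bg <- stats::setNames(v, word)
  } else {
    ltr <- strsplit(word, "", fixed = TRUE)[[1L]]
    i <- rep.int(seq_len(n - 1L), pmin(3L, (n - 1L):1L))
    j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):min(n, k + 3L)),
                use.names = FALSE)
    o <- bigram_activation(v[i], v[j])
    nm <- paste0(ltr[i], ltr[j])
    # collapse duplicate pairs to their maximum activation
    bg <- vapply(split(o, nm), max, numeric(1))
  }
  list(v = v, bigrams = bg, salience = sum(v))
}

# Visual percepts for the words currently processed in parallel: the
# fixated word n and its neighbours n-1, n+1, n+2, n+3 (clipped to the
# passage).  Returns the accumulated bigram-activation map, per-word
# salience, and the slot indices.
fixation_percepts <- function(layout, fixation_word, fixation_letter,
                              focus, window, params) {
  n_words <- nrow(layout)
  slots <- intersect((fixation_word - 1L):(fixation_word + 3L), seq_len(n_words))
  bigact <- numeric(0)
  salience <- stats::setNames(numeric(length(slots)), slots)
  for (s in seq_along(slots)) {
    w <- slots[s]
    p <- word_percept(layout$word[w], layout$start[w], fixation_letter,
                      focus, window, params)
    salience[s] <- p$salience
    hit <- match(names(p$bigrams), names(bigact))
    new <- is.na(hit)
    if (any(!new))
      bigact[hit[!new]] <- bigact[hit[!new]] + p$bigrams[!new]
    if (any(new))
      bigact <- c(bigact, p$bigrams[new])
  }
  list(slots = slots, bigram_activation = bigact, salience = salience)
}

# Map an input bigram-activation vector onto per-lexicon-word excitation:
# each active bigram adds its activation to every lexicon word containing
# it.
lexical_excitation <- function(bigact, lexicon) {
  exc <- numeric(length(lexicon$word))
  idx <- lexicon$bigram_index[names(bigact)]
  for (k in seq_along(bigact)) {
    members <- idx[[k]]
    if (!is.null(members)) exc[members] <- exc[members] + bigact[[k]]
  }
  exc
}
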