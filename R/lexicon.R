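#' Open-bigram code of a word
#'
#' Decomposes a word into its set of open bigrams: ordered letter pairs
#' `(letter_i, letter_j)` with `i < j` and a positional gap of at most
#' `max_gap` letters.  Open bigrams are the orthographic code unit of the
#' recognition model: words sharing open bigrams excite and inhibit each
#' other.  Repeated pairs within a word count once (set semantics).
#' Single-letter words are represented by a one-character marker (the
#' letter itself), which can never collide with a two-letter pair.
#'
#' @param word A lowercase alphabetic word (single string).
#' @param max_gap Maximum index gap `j - i` for a pair to count (default 3).
#' @return Character vector of unique bigrams, e.g. `c("ca","ct","at")`
#'   for `"cat"`.
#' @examples
#' open_bigrams("cat")
#' open_bigrams("water")
#' @export
open_bigrams <- function(word, max_gap = 3L) {
  if (!is.character(word) || length(word) != 1L || is.na(word) || !nzchar(word))
    stop("`word` must be a single non-empty string")
  letters_w <- strsplit(word, "", fixed = TRUE)[[1L]]
  n <- length(letters_w)
  if (n == 1L) return(letters_w)
  i <- rep.int(seq_len(n - 1L), pmin(max_gap, (n - 1L):1L))
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):min(n, k + max_gap)),
              use.names = FALSE)
  unique(paste0(letters_w[i], letters_w[j]))
}

#' Frequency-dependent recognition threshold
#'
#' The activation level a lexicon word must reach to be recognized.  More
#' frequent words have lower thresholds:
#' `T = t_base * (1 - c_f * freq_norm)`, with `freq_norm` the word's
#' frequency normalized to `[0, 1]` by the lexicon maximum and `c_f` the
#' frequency weight (default 0.08).  `t_base` defaults to the activation
#' ceiling `S_max = 1`, so thresholds live on the activation scale.
#'
#' @param freq_norm Normalized frequency in `[0, 1]` (vectorized).
#' @param c_f Frequency weight constant.
#' @param t_base Threshold of a zero-frequency word.
#' @return Numeric vector of thresholds, strictly decreasing in `freq_norm`.
#' @export
recognition_threshold <- function(freq_norm, c_f = 0.08, t_base = 1) {
  if (any(!is.finite(freq_norm)) || any(freq_norm < 0) || any(freq_norm > 1))
    stop("`freq_norm` must lie in [0, 1]")
  t_base * (1 - c_f * freq_norm)
}

#' Pairwise orthographic-overlap matrix
#'
#' Counts, for every pair of lexicon words, the number of shared open
#' bigrams `d[w, k]`.  The matrix is symmetric and its diagonal is set to
#' zero: a word does not inhibit itself, so self-overlap is excluded from
#' all inhibition sums.
#'
#' @param lexicon A lexicon built by [build_lexicon()].
#' @return Integer-valued symmetric matrix with zero diagonal, dimnames
#'   set to the lexicon words.
#' @export
overlap_matrix <- function(lexicon) {
  stopifnot(inherits(lexicon, "readsim_lexicon"))
  bigrams <- lexicon$bigrams
  all_bg <- unique(unlist(bigrams, use.names = FALSE))
  n <- length(bigrams)
  m <- matrix(0, nrow = n, ncol = length(all_bg),
              dimnames = list(lexicon$word, all_bg))
  for (w in seq_len(n)) m[w, bigrams[[w]]] <- 1
  d <- tcrossprod(m)
  diag(d) <- 0
  d
}

#' Read a frequency lexicon from TSV
#'
#' Expects two tab-separated columns, `word` and `frequency`; a header row
#' is detected and skipped if the second field is not numeric.  Words are
#' lower-cased; duplicate words keep their summed frequency.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `word` and `frequency`, sorted by
#'   decreasing frequency.
#' @export
read_frequency_lexicon <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  has_header <- length(fields) >= 2L && is.na(suppressWarnings(as.numeric(fields[2L])))
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("frequency lexicon needs two columns: word, frequency")
  names(df)[1:2] <- c("word", "frequency")
  df$word <- tolower(df$word)
  agg <- stats::aggregate(frequency ~ word, data = df[, c("word", "frequency")], FUN = sum)
  agg[order(-agg$frequency), , drop = FALSE]
}

#' Build the model lexicon
#'
#' The vocabulary is the union of all words appearing in the passages and
#' the `n_top` most frequent words of the supplied frequency list.  Each
#' entry carries its raw and max-normalized frequency, length, open-bigram
#' set and recognition threshold; the lexicon also holds the pairwise
#' orthographic-overlap matrix and an inverted bigram index used by the
#' simulator to propagate bigram activation to words.
#'
#' Passage words missing from the frequency list receive frequency 0
#' (hence the maximum threshold `t_base`).
#'
#' @param passages Character vector of normalized passages (see
#'   [read_passages()]), or a list of word vectors.
#' @param frequencies Data frame with columns `word` and `frequency`, as
#'   returned by [read_frequency_lexicon()].
#' @param n_top Number of most frequent list words added beyond the
#'   passage vocabulary (default 500).
#' @param c_f Frequency weight in threshold setting (default 0.08).
#' @param t_base Threshold scale (default 0.75).  Thresholds must sit
#'   comfortably below the activation ceiling: with thresholds at the
#'   ceiling, the clamped activation update can only cross them by
#'   saturating in a single cycle, which destroys the graded
#'   cycles-to-recognition dynamics the model is built around.
#' @return An object of class `readsim_lexicon`: a list with fields
#'   `word`, `freq_raw`, `freq_norm`, `length`, `threshold`, `n_bigrams`,
#'   `bigrams` (list), `bigram_index` (bigram -> word indices), `overlap`
#'   (matrix) and the constants used.
#' @export
build_lexicon <- function(passages, frequencies, n_top = 500L,
                          c_f = 0.08, t_base = 0.75) {
  words_text <- if (is.list(passages)) unlist(passages, use.names = FALSE)
                else unlist(lapply(passages, passage_words), use.names = FALSE)
  words_text <- unique(tolower(words_text))
  if (length(words_text) == 0L) stop("no passage words supplied")
  top <- utils::head(frequencies$word[order(-frequencies$frequency)], n_top)
  vocab <- unique(c(words_text, top))
  freq_raw <- frequencies$frequency[match(vocab, frequencies$word)]
  freq_raw[is.na(freq_raw)] <- 0
  freq_max <- max(freq_raw, 1)
  freq_norm <- freq_raw / freq_max
  bigrams <- lapply(vocab, open_bigrams)
  lex <- structure(list(
    word = vocab,
    freq_raw = freq_raw,
    freq_max = freq_max,
    freq_norm = freq_norm,
    length = nchar(vocab),
    threshold = recognition_threshold(freq_norm, c_f = c_f, t_base = t_base),
    bigrams = bigrams,
    n_bigrams = lengths(bigrams),
    c_f = c_f,
    t_base = t_base
  ), class = "readsim_lexicon")
  lex$overlap <- overlap_matrix(lex)
  # inhibition weights: shared-bigram counts normalized by the geometric
  # mean of the two words' bigram-set sizes, so a full orthographic
  # neighbour weighs 1 and a single shared pair between two long words
  # weighs little; raw counts would let any co-active word with one
  # shared bigram suppress the rest of the lexicon at c_2 = 2.5
  nb <- pmax(lex$n_bigrams, 1L)
  lex$inhibition <- lex$overlap / outer(sqrt(nb), sqrt(nb))
  # inverted index: bigram -> indices of lexicon words containing it
  pairs <- data.frame(
    bigram = unlist(bigrams, use.names = FALSE),
    word = rep.int(seq_along(vocab), lengths(bigrams))
  )
  lex$bigram_index <- split(pairs$word, pairs$bigram)
  lex
}

#' @export
print.readsim_lexicon <- function(x, ...) {
  cat("<readsim_lexicon> ", length(x$word), " words, ",
      length(x$bigram_index), " distinct open bigrams\n", sep = "")
  cat("  c_f = ", x$c_f, ", threshold range [",
      round(min(x$threshold), 3), ", ", round(max(x$threshold), 3), "]\n",
      sep = "")
  invisible(x)
}

#' Look up lexicon indices for words
#'
#' @param lexicon A `readsim_lexicon`.
#' @param words Character vector.
#' @return Integer vector of indices (NA where absent).
#' @keywords internal
lexicon_index <- function(lexicon, words) {
  match(tolower(words), lexicon$word)
}
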