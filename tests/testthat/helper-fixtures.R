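# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small corpus for fast unit tests: 6 passages x 30 words, 100-word
# vocabulary.
fx_small <- function() {
  if (is.null(.fixture_cache$small)) {
    spec <- fixture_spec(n_passages = 6L, words_per_passage = 30L,
                         vocab_size = 100L, seed = 7L)
    .fixture_cache$small <- write_fixtures(spec)
  }
  .fixture_cache$small
}

# Default-scale corpus (10 x 50, vocab 150) used by the behavioural
# properties.
fx_default <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- write_fixtures(fixture_spec(seed = 1L))
  }
  .fixture_cache$default
}

# A hand-built three-word toy lexicon for recognition unit tests.
toy_lexicon <- function(words = c("cat", "cap", "dog"),
                        freqs = c(100, 80, 60)) {
  build_lexicon(list(words), data.frame(word = words, frequency = freqs),
                n_top = 0L)
}

# A predictability table targeting one position of one passage.
single_entry_table <- function(passage_id, position, candidate, probability,
                               source = "cloze") {
  structure(data.frame(passage_id = passage_id, position = position,
                       candidate = candidate, probability = probability,
                       source = source, stringsAsFactors = FALSE),
            class = c("readsim_pred_table", "data.frame"))
}

# Shuffle a table's positions within each passage (keeps position 1
# empty, since nothing is predicted there).
permute_table_positions <- function(tab, passages, seed) {
  set.seed(seed)
  out <- tab
  for (pid in unique(tab$passage_id)) {
    n <- length(passages[[pid]])
    sel <- out$passage_id == pid
    perm <- c(1L, sample(2:n))
    out$position[sel] <- perm[out$position[sel]]
  }
  out
}
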