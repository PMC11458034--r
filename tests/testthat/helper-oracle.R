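# Independent brute-force replay of the word-measure definitions: walks
# the event stream once per word, tracking first-pass state explicitly.
replay_measures <- function(events, n_words) {
  out <- data.frame(word_id = seq_len(n_words), SK = NA_integer_,
                    FFD = NA_real_, GD = NA_real_, TRT = NA_real_,
                    RG = NA_integer_)
  for (id in seq_len(n_words)) {
    passed <- FALSE        # has any later word been fixated yet?
    seen <- FALSE          # has this word been fixated yet?
    in_run <- FALSE        # inside the consecutive run from first fixation
    ffd <- NA_real_; gd <- 0; trt <- 0; rg <- 0L; sk <- NA_integer_
    for (k in seq_len(nrow(events))) {
      w <- events$word_index[k]; d <- events$duration_ms[k]
      if (w == id) {
        if (!seen) {
          seen <- TRUE; in_run <- TRUE
          ffd <- d
          sk <- if (passed) 1L else 0L
          if (passed) rg <- 1L
        } else if (passed) rg <- 1L
        if (in_run) gd <- gd + d
        trt <- trt + d
      } else {
        if (seen) in_run <- FALSE
        if (w > id) passed <- TRUE
      }
    }
    if (!seen) { sk <- 1L; rg <- 0L; gd <- NA_real_; trt <- NA_real_ }
    out$SK[id] <- sk; out$FFD[id] <- ffd; out$GD[id] <- gd
    out$TRT[id] <- trt; out$RG[id] <- rg
  }
  out
}

random_events <- function(n_words, n_events) {
  data.frame(fixation_index = seq_len(n_events),
             word_index = sample(n_words, n_events, replace = TRUE),
             duration_ms = 25 * sample(1:24, n_events, replace = TRUE))
}

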