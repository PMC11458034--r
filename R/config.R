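#' Default simulation configuration
#'
#' Returns the full nested configuration consumed by the simulator.
#' Section `model` holds the interactive-activation constants (activation
#' bounds, decay, excitation/inhibition weights, cycle duration,
#' frequency and predictability weights, length tolerance of the
#' recognition gate).  Section `visual` holds the letter-input constants
#' (see [visual_params()]).  Section `saccade` holds the oculomotor
#' reconstruction constants: these govern the stochastic initiation of
#' saccades, the attention-window dynamics and the regression mechanism,
#' for which only qualitative contracts are established; every value here
#' is a package-level choice exposed for the user to override.
#'
#' @return A nested list of class `readsim_config`.
#' @export
default_config <- function() {
  structure(list(
    model = list(
      S_max = 1, S_min = 0, tau = -0.1,
      c_1 = 1, c_2 = 2.5,            # inhibition magnitude, applied negatively
      cycle_ms = 25,
      c_f = 0.08,
      c_p = 0.1,
      length_tolerance = 0.25,       # relative: ceiling(0.25 * word length)
      min_overlap = 1 / 3            # recognition gate: shared-bigram fraction
    ),
    visual = list(
      c_e = 35.55556, mag_slope = 0.018, mag_intercept = 10.64,
      letter_size = 0.3, c_d = 5, input_gain = 800
    ),
    saccade = list(
      p_base = 0.05, gain = 0.3, p_cap = 0.9,
      min_cycles = 4, max_cycles = 24,
      p_regress = 0.15, regression_lookback = 4,
      window_init = 8, window_min = 4, window_max = 14, window_step = 1
    ),
    seed = 1L
  ), class = "readsim_config")
}

#' Read or write a configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a `readsim_config` with any missing
#'   entries filled from [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[section]]))
      cfg[[section]][names(user[[section]])] <- user[[section]]
    else cfg[[section]] <- user[[section]]
  }
  cfg
}

#' @rdname read_config
#' @param config A `readsim_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Activation-dynamics parameters
#'
#' Convenience accessor bundling the `model` section of a configuration
#' into the parameter list used by [processing_cycle()].
#'
#' @param S_max,S_min Activation bounds.
#' @param tau Passive decay per cycle (negative).
#' @param c_1 Bigram-to-word excitation weight.
#' @param c_2 Word-to-word inhibition magnitude (entered with negative
#'   sign in the update).
#' @param cycle_ms Duration of one processing cycle in milliseconds.
#' @return List of class `readsim_activation_params`.
#' @export
activation_params <- function(S_max = 1, S_min = 0, tau = -0.1,
                              c_1 = 1, c_2 = 2.5, cycle_ms = 25) {
  if (S_min >= S_max) stop("S_min must be below S_max")
  if (tau >= 0) stop("decay `tau` must be negative")
  structure(list(S_max = S_max, S_min = S_min, tau = tau,
                 c_1 = c_1, c_2 = c_2, cycle_ms = cycle_ms),
            class = "readsim_activation_params")
}
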