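# Shared fixtures: the packaged panel and convenience configs.

panel <- load_panel()

# Noise-free, suppression-free config: the generator's closed-form physics.
exact_config <- function(...) {
  synthetic_config(panel, noise_rsd = 0, suppression_rel_sd = 0, ...)
}

# Closed-form evaporated-and-surviving fraction for a species, mirroring
# the generator's documented forward model (used as the analytic reference
# in scan tests).
species_param <- function(config, name) {
  as.list(config$species[config$species$name == name, ])
}

# Straight-line data over the calibration ladder with optional noise.
ladder_responses <- function(slope = 0.5, intercept = 0, n_rep = 3,
                             sd = 0, levels = NULL) {
  if (is.null(levels)) {
    levels <- c(0.050, 0.0750, 0.125, 0.375, 0.500, 1.00, 1.75, 2.50,
                5.00, 7.50, 10.0)
  }
  x <- rep(levels, each = n_rep)
  list(x = x, y = intercept + slope * x + stats::rnorm(length(x), 0, sd))
}
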