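## Shared fixtures: desk-scale configurations and scoring helpers.

## A short race keeps the suite fast; ROF prompts are spaced so every one of
## the 8 segments still receives at least one prompt.
quick_cfg <- function(n_subjects = 1L, race_duration = 1200,
                      seed = 1L, ...) {
  sim_config(n_subjects = n_subjects, race_duration = race_duration,
             rof_interval_s = race_duration / 9, seed = seed, ...)
}

## Noise-free configuration: deterministic RR and gait values.
noiseless_cfg <- function(...) {
  z <- list(t_c = 0, t_f = 0, FSA = 0, FEA = 0, omega_s = 0, a_AP = 0,
            a_ML = 0, cadence = 0, v = 0)
  quick_cfg(rr_noise_sd = 0, lf_amp = 0, hf_amp = 0, artifact_rate = 0,
            trend_noise_sd = z, ...)
}

## Beat-matching score at a time tolerance.
beat_match <- function(detected, truth, tol = 0.010) {
  if (length(detected) == 0L) return(c(sens = 0, prec = 0))
  sens <- mean(vapply(truth, function(t) any(abs(detected - t) <= tol), TRUE))
  prec <- mean(vapply(detected, function(t) any(abs(truth - t) <= tol), TRUE))
  c(sens = sens, prec = prec)
}
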