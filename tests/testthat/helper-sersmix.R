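# Shared fixtures: small configurations and spectra built in code.

quiet_generator <- function(seed = 1, amplitude_jitter_rsd = 0,
                            shift_jitter = 0, noise_sd = 0,
                            baseline_drift = 0,
                            fluor_amp_range = c(0, 0), ...) {
  sers_generator_config(
    amplitude_jitter_rsd = amplitude_jitter_rsd,
    shift_jitter = shift_jitter, noise_sd = noise_sd,
    baseline_drift = baseline_drift, fluor_amp_range = fluor_amp_range,
    seed = seed, ...
  )
}

# a deterministic raw spectrum covering the fingerprint region
toy_raw_spectrum <- function(n = 1501) {
  wn <- seq(400, 1900, length.out = n)
  tibble::tibble(
    wavenumber = wn,
    intensity = 2 + 0.001 * wn +
      3 * exp(-(wn - 900)^2 / (2 * 15^2)) +
      1.5 * exp(-(wn - 1400)^2 / (2 * 20^2))
  )
}

tiny_model <- function(seed = 1, L = 64L, ...) {
  build_model(
    model_config("ci", input_length = L, stem_channels = 4L,
                 stage_channels = c(4L, 8L), embed_dim = 8L, ...),
    seed = seed
  )
}

# brute-force NNLS objective on a beta grid (independent oracle)
grid_nnls <- function(x, P, beta_max = 2, step = 0.05) {
  k <- ncol(P)
  grid <- do.call(expand.grid, rep(list(seq(0, beta_max, by = step)), k))
  errs <- apply(grid, 1, function(b) sum((x - P %*% b)^2))
  min(errs)
}
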