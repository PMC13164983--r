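#' Preprocessing configuration
#'
#' Parameters of the raw-spectrum-to-feature-vector chain: fingerprint
#' cropping and uniform resampling, Savitzky-Golay smoothing, iterative
#' polynomial baseline correction, and min-max plus power-law
#' normalisation.
#'
#' @param fingerprint_lo,fingerprint_hi Fingerprint region bounds in
#'   cm^-1 (default 500 and 1800).
#' @param n_points Feature-vector length L (default 2048).
#' @param sg_window,sg_order Savitzky-Golay window (odd, default 5) and
#'   polynomial order (default 2).
#' @param baseline_order Polynomial order of the baseline fit (default 5).
#' @param baseline_max_iter,baseline_tol Iteration cap and relative
#'   convergence tolerance of the clip-above-fit baseline scheme.
#' @param alpha Power-law exponent applied after min-max scaling
#'   (default 1.5).
#' @return A list of class `sers_preproc_config`.
#' @export
preproc_config <- function(fingerprint_lo = 500, fingerprint_hi = 1800,
                           n_points = 2048L, sg_window = 5L, sg_order = 2L,
                           baseline_order = 5L, baseline_max_iter = 100L,
                           baseline_tol = 1e-6, alpha = 1.5) {
  if (fingerprint_lo >= fingerprint_hi) abort("fingerprint_lo must be < hi")
  if (sg_window %% 2 == 0) abort("sg_window must be odd")
  if (sg_order >= sg_window) abort("sg_order must be < sg_window")
  if (n_points < sg_window) abort("n_points must be >= sg_window")
  if (alpha <= 0) abort("alpha must be > 0")
  structure(
    list(
      fingerprint_lo = fingerprint_lo, fingerprint_hi = fingerprint_hi,
      n_points = as.integer(n_points),
      sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
      baseline_order = as.integer(baseline_order),
      baseline_max_iter = as.integer(baseline_max_iter),
      baseline_tol = baseline_tol, alpha = alpha
    ),
    class = "sers_preproc_config"
  )
}

as_spectrum_tbl <- function(s) {
  if (is.numeric(s) && is.null(dim(s))) {
    abort("expected a spectrum data frame with wavenumber and intensity")
  }
  if (!all(c("wavenumber", "intensity") %in% names(s))) {
    abort("spectrum must have columns 'wavenumber' and 'intensity'")
  }
  s
}

#' Crop to the fingerprint region and resample to a uniform axis
#'
#' Restricts the spectrum to `[fingerprint_lo, fingerprint_hi]` cm^-1 and
#' linearly interpolates it onto `n_points` uniformly spaced wavenumbers
#' spanning the region inclusively.
#'
#' @param s Spectrum tibble (`wavenumber`, `intensity`), strictly
#'   increasing axis covering the fingerprint region.
#' @param cfg A [preproc_config()].
#' @return A spectrum tibble of length `n_points`.
#' @export
crop_resample <- function(s, cfg = preproc_config()) {
  s <- as_spectrum_tbl(s)
  if (is.unsorted(s$wavenumber, strictly = TRUE)) {
    abort("wavenumber axis must be strictly increasing")
  }
  lo <- cfg$fingerprint_lo
  hi <- cfg$fingerprint_hi
  if (min(s$wavenumber) > lo || max(s$wavenumber) < hi) {
    abort(sprintf(
      "spectrum covers [%g, %g] cm^-1 but the fingerprint region [%g, %g] is required",
      min(s$wavenumber), max(s$wavenumber), lo, hi
    ))
  }
  axis <- seq(lo, hi, length.out = cfg$n_points)
  out <- approx(s$wavenumber, s$intensity, xout = axis, method = "linear")
  new_spectrum(out$x, out$y,
               category = attr(s, "category"), id = attr(s, "id"))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; interior points use the
#' classical SG convolution kernel and edge points use the polynomial-fit
#' edge rows of the SG projection matrix (no padding artefacts).
#'
#' @param s Spectrum tibble.
#' @param window Odd window length (default 5).
#' @param order Polynomial order (default 2), less than `window`.
#' @return Smoothed spectrum tibble of the same length.
#' @export
sg_smooth <- function(s, window = 5L, order = 2L) {
  s <- as_spectrum_tbl(s)
  if (window %% 2 == 0) abort("window must be odd")
  if (order >= window) abort("order must be < window")
  if (window >= nrow(s)) abort("window must be shorter than the spectrum")
  y <- signal::sgolayfilt(s$intensity, p = order, n = window)
  new_spectrum(s$wavenumber, y,
               category = attr(s, "category"), id = attr(s, "id"))
}

#' Iterative polynomial baseline correction (modified polyfit)
#'
#' Fits a polynomial of order `baseline_order` to the spectrum, replaces
#' every intensity above the fit by the fit (so peaks stop attracting the
#' baseline), and repeats until the baseline changes by less than
#' `baseline_tol` (relative to the intensity range) or `baseline_max_iter`
#' iterations. The corrected spectrum is floored at zero.
#'
#' @param s Spectrum tibble.
#' @param cfg A [preproc_config()].
#' @return A list with elements `corrected` and `baseline` (both spectrum
#'   tibbles).
#' @export
baseline_correct <- function(s, cfg = preproc_config()) {
  s <- as_spectrum_tbl(s)
  y <- s$intensity
  if (any(!is.finite(y))) abort("spectrum contains non-finite intensities")
  if (nrow(s) < cfg$baseline_order + 1) {
    abort("spectrum shorter than baseline_order + 1")
  }
  u <- (s$wavenumber - s$wavenumber[1]) /
    diff(range(s$wavenumber))
  V <- outer(u, 0:cfg$baseline_order, `^`)
  qrV <- qr(V)
  scale <- max(abs(y), 1e-12)
  work <- y
  base <- qr.fitted(qrV, work)
  for (it in seq_len(cfg$baseline_max_iter)) {
    work <- pmin(work, base)
    new_base <- qr.fitted(qrV, work)
    delta <- max(abs(new_base - base)) / scale
    base <- new_base
    if (delta < cfg$baseline_tol) break
  }
  list(
    corrected = new_spectrum(s$wavenumber, pmax(y - base, 0),
                             category = attr(s, "category"),
                             id = attr(s, "id")),
    baseline = new_spectrum(s$wavenumber, base)
  )
}

#' Min-max normalisation followed by a power-law transform
#'
#' Maps intensities to `((y - min) / (max - min))^alpha`, so the minimum
#' maps to 0 and the maximum to 1; `alpha > 1` increases the contrast
#' between peaks and valleys.
#'
#' @param s Spectrum tibble.
#' @param alpha Power exponent (default 1.5).
#' @return Spectrum tibble with intensities in `[0, 1]`.
#' @export
normalize_power <- function(s, alpha = 1.5) {
  s <- as_spectrum_tbl(s)
  rng <- range(s$intensity)
  if (diff(rng) <= 0) abort("constant spectrum: min-max range is degenerate")
  y <- ((s$intensity - rng[1]) / diff(rng))^alpha
  new_spectrum(s$wavenumber, y,
               category = attr(s, "category"), id = attr(s, "id"))
}

#' Full preprocessing chain
#'
#' Crop/resample, Savitzky-Golay smoothing, iterative polynomial baseline
#' correction, then min-max + power-law normalisation, in that order.
#'
#' @param s Raw spectrum tibble covering the fingerprint region.
#' @param cfg A [preproc_config()].
#' @return A feature spectrum tibble: `n_points` rows spanning
#'   `[fingerprint_lo, fingerprint_hi]`, intensities in `[0, 1]`.
#' @export
#' @examples
#' cfg <- sers_generator_config()
#' x <- preprocess(component_profile("A", cfg))
#' range(x$intensity)
preprocess <- function(s, cfg = preproc_config()) {
  s |>
    crop_resample(cfg) |>
    sg_smooth(cfg$sg_window, cfg$sg_order) |>
    baseline_correct(cfg) |>
    (\(b) b$corrected)() |>
    normalize_power(cfg$alpha)
}

#' Preprocess a dataset into a feature matrix
#'
#' Applies [preprocess()] to every spectrum in a `sers_dataset` (or named
#' list of spectra) and stacks the results into a samples-by-features
#' matrix aligned with the manifest rows.
#'
#' @param dataset A `sers_dataset` from [generate_dataset()].
#' @param cfg A [preproc_config()].
#' @return A list with `features` (matrix, one row per spectrum, rownames
#'   = spectrum ids), `manifest`, and `axis` (feature wavenumbers).
#' @export
preprocess_dataset <- function(dataset, cfg = preproc_config()) {
  feats <- purrr::map(dataset$spectra, function(s) preprocess(s, cfg))
  axis <- feats[[1]]$wavenumber
  X <- do.call(rbind, purrr::map(feats, "intensity"))
  rownames(X) <- names(dataset$spectra)
  list(features = X, manifest = dataset$manifest, axis = axis)
}
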