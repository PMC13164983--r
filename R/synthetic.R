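#' Characteristic peak positions of the three target pesticides
#'
#' Returns the characteristic SERS band positions (cm^-1) used by the
#' synthetic generator: paraquat (A) at 840, 1029, 1190, 1298, 1646 and
#' 1766 cm^-1; thiram (B) at 560, 932, 1380 and 1512 cm^-1; tricyclazole
#' (C) at 596, 988, 1000, 1090, 1193, 1303, 1403, 1420 and 1589 cm^-1.
#' The reference band of each compound (840, 1380 and 1589 cm^-1
#' respectively) carries relative amplitude 1; the remaining relative
#' amplitudes and the band widths are drawn once per generator
#' configuration and stored there for reproducibility.
#'
#' Note: mixture spectra of tricyclazole are sometimes discussed in terms
#' of additional bands near 689 and 1578 cm^-1; these are not part of the
#' assignment list above and are deliberately not included in the library.
#'
#' @param component One of `"A"`, `"B"`, `"C"`.
#' @return A tibble with columns `center` (cm^-1) and `reference`
#'   (logical, `TRUE` for the compound's reference band).
#' @export
#' @examples
#' sers_peak_positions("A")
sers_peak_positions <- function(component) {
  component <- match.arg(component, .components)
  pos <- switch(component,
    A = c(840, 1029, 1190, 1298, 1646, 1766),
    B = c(560, 932, 1380, 1512),
    C = c(596, 988, 1000, 1090, 1193, 1303, 1403, 1420, 1589)
  )
  ref <- switch(component, A = 840, B = 1380, C = 1589)
  tibble(center = pos, reference = pos == ref)
}

#' Configuration of the synthetic SERS spectrum generator
#'
#' Defines the raw wavenumber axis, line shape, replicate variability,
#' baseline model, noise level, per-component enhancement factors and the
#' strength of non-linear peak masking in mixtures. Relative band
#' amplitudes (reference band fixed at 1, others drawn from
#' `[0.3, 1]`) and band widths (FWHM drawn from `[10, 16]` cm^-1) are
#' sampled once here and stored in `$libraries` so a configuration fully
#' determines every spectrum it generates.
#'
#' @param axis_start,axis_end,axis_step Raw axis in cm^-1. The axis must
#'   extend beyond the 500-1800 cm^-1 fingerprint region on both sides so
#'   that cropping is non-trivial.
#' @param peak_shape `"lorentzian"` (default; Raman line shapes are close
#'   to Lorentzian) or `"gaussian"`.
#' @param amplitude_jitter_rsd Relative standard deviation of per-band
#'   amplitude jitter between replicates (default 0.08, matching the
#'   replicate variability of the emulated measurements).
#' @param shift_jitter Maximum band-position jitter in cm^-1 (uniform in
#'   `[-shift_jitter, shift_jitter]`).
#' @param baseline_order Polynomial order of the slow baseline drift.
#' @param baseline_drift Upper bound of each drift coefficient, in
#'   intensity units where the weakest component's peak maximum is 1.
#' @param fluor_amp_range,fluor_center_range,fluor_width_range Amplitude,
#'   centre (cm^-1) and FWHM (cm^-1) ranges of the broad Gaussian
#'   fluorescence hump.
#' @param noise_sd Additive white-noise standard deviation as a fraction
#'   of the spectrum's maximum intensity.
#' @param concentration_range Range of the per-sample analyte
#'   concentration factor used by [generate_dataset()] (log-uniform
#'   draw), emulating a dilution series of working solutions: the whole
#'   analyte signal is scaled while baseline and noise floor are not, so
#'   low-concentration spectra have a worse signal-to-background ratio.
#'   Replicate generation at fixed concentration
#'   ([generate_pure()]/[generate_mixture()] with the default
#'   `concentration = 1`) is unaffected.
#' @param enhancement Named per-component SERS enhancement scalars; the
#'   default `c(A = 3, B = 1.5, C = 1)` emulates the much stronger signal
#'   of paraquat relative to tricyclazole.
#' @param masking_strength Strength of competitive peak masking in
#'   mixtures, in `[0, 1]`; 0 recovers exact linear superposition.
#' @param masking_kappa_global Fraction of the masking attenuation applied
#'   to weaker-component bands that do not overlap a stronger band
#'   (whole-spectrum competitive-adsorption suppression); overlapping
#'   bands (within one FWHM) receive the full attenuation.
#' @param seed Integer master seed; all generator randomness derives from
#'   it through named sub-streams.
#' @return A list of class `sers_generator_config`.
#' @export
#' @examples
#' cfg <- sers_generator_config(seed = 1)
#' cfg$libraries$A
sers_generator_config <- function(axis_start = 400, axis_end = 1900,
                                  axis_step = 1,
                                  peak_shape = c("lorentzian", "gaussian"),
                                  amplitude_jitter_rsd = 0.08,
                                  shift_jitter = 2,
                                  baseline_order = 2,
                                  baseline_drift = 0.25,
                                  fluor_amp_range = c(0.1, 0.5),
                                  fluor_center_range = c(800, 1400),
                                  fluor_width_range = c(300, 600),
                                  noise_sd = 0.01,
                                  concentration_range = c(0.25, 1),
                                  enhancement = c(A = 3, B = 1.5, C = 1),
                                  masking_strength = 0.5,
                                  masking_kappa_global = 0.5,
                                  seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  if (!(axis_start < 500 && axis_end > 1800)) {
    abort("axis must extend beyond the 500-1800 cm^-1 fingerprint region")
  }
  if (amplitude_jitter_rsd < 0 || shift_jitter < 0 || noise_sd < 0) {
    abort("jitter and noise parameters must be >= 0")
  }
  if (masking_strength < 0 || masking_strength > 1) {
    abort("masking_strength must lie in [0, 1]")
  }
  if (!all(.components %in% names(enhancement))) {
    abort("enhancement must name all components A, B, C")
  }
  cfg <- list(
    axis_start = axis_start, axis_end = axis_end, axis_step = axis_step,
    peak_shape = peak_shape,
    amplitude_jitter_rsd = amplitude_jitter_rsd,
    shift_jitter = shift_jitter,
    baseline_order = baseline_order, baseline_drift = baseline_drift,
    fluor_amp_range = fluor_amp_range,
    fluor_center_range = fluor_center_range,
    fluor_width_range = fluor_width_range,
    noise_sd = noise_sd,
    concentration_range = concentration_range,
    enhancement = enhancement[.components],
    masking_strength = masking_strength,
    masking_kappa_global = masking_kappa_global,
    seed = as.integer(seed)
  )
  cfg$libraries <- purrr::map(
    setNames(.components, .components),
    function(k) draw_peak_library(k, cfg)
  )
  structure(cfg, class = "sers_generator_config")
}

# Draw per-config relative amplitudes and widths for one component.
draw_peak_library <- function(component, cfg) {
  pk <- sers_peak_positions(component)
  withr::with_seed(sub_seed(cfg$seed, "library", component), {
    amp <- runif(nrow(pk), 0.3, 1.0)
    width <- runif(nrow(pk), 10, 16)
  })
  amp[pk$reference] <- 1.0
  tibble(
    component = component, center = pk$center,
    amplitude = amp, width = width, reference = pk$reference
  )
}

generator_axis <- function(cfg) {
  seq(cfg$axis_start, cfg$axis_end, by = cfg$axis_step)
}

validate_peak_library <- function(library, cfg) {
  if (nrow(library) == 0) abort("peak library is empty")
  if (is.unsorted(library$center, strictly = TRUE)) {
    abort("peak centers must be strictly increasing")
  }
  if (any(library$amplitude <= 0)) abort("peak amplitudes must be > 0")
  out <- library$center < cfg$axis_start | library$center > cfg$axis_end
  if (any(out)) {
    abort(sprintf(
      "peak at %g cm^-1 lies outside the axis [%g, %g]",
      library$center[which(out)[1]], cfg$axis_start, cfg$axis_end
    ))
  }
  invisible(library)
}

# Evaluate one spectral line kernel on the axis (unit peak height).
peak_kernel <- function(axis, center, width, shape) {
  if (shape == "lorentzian") {
    hw <- width / 2
    hw^2 / ((axis - center)^2 + hw^2)
  } else {
    exp(-4 * log(2) * (axis - center)^2 / width^2)
  }
}

# Sum of kernels for a peak table; returns the unscaled intensity vector.
peak_sum <- function(axis, peaks, shape) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(peaks))) {
    y <- y + peaks$amplitude[i] *
      peak_kernel(axis, peaks$center[i], peaks$width[i], shape)
  }
  y
}

# Scale constant mapping the ideal (unjittered) profile to peak maximum =
# enhancement factor; the same constant is applied to jittered draws so
# replicate amplitude variability survives scaling.
profile_scale <- function(component, cfg) {
  lib <- cfg$libraries[[component]]
  validate_peak_library(lib, cfg)
  ideal <- peak_sum(generator_axis(cfg), lib, cfg$peak_shape)
  unname(cfg$enhancement[component] / max(ideal))
}

#' Ideal (noiseless) spectral profile of one pure component
#'
#' Sums the component's line-shape kernels on the raw axis and scales the
#' result so its maximum equals the component's enhancement factor.
#'
#' @param component One of `"A"`, `"B"`, `"C"`.
#' @param config A [sers_generator_config()].
#' @return A spectrum tibble with columns `wavenumber`, `intensity`.
#' @export
#' @examples
#' prof <- component_profile("A", sers_generator_config())
#' prof$wavenumber[which.max(prof$intensity)]
component_profile <- function(component, config) {
  component <- match.arg(component, .components)
  lib <- config$libraries[[component]]
  validate_peak_library(lib, config)
  axis <- generator_axis(config)
  y <- peak_sum(axis, lib, config$peak_shape) * profile_scale(component, config)
  new_spectrum(axis, y, category = component)
}

new_spectrum <- function(wavenumber, intensity, category = NULL, id = NULL) {
  s <- tibble(wavenumber = wavenumber, intensity = intensity)
  attr(s, "category") <- category
  attr(s, "id") <- id
  s
}

# Per-replicate jittered peak table for one component (shared RNG stream
# between generate_pure() and generate_mixture(), keyed by replicate id).
jittered_peaks <- function(component, cfg, id) {
  lib <- cfg$libraries[[component]]
  withr::with_seed(sub_seed(cfg$seed, "jitter", component, id), {
    mult <- pmax(1 + rnorm(nrow(lib)) * cfg$amplitude_jitter_rsd, 0.05)
    shift <- runif(nrow(lib), -cfg$shift_jitter, cfg$shift_jitter)
  })
  lib$amplitude <- lib$amplitude * mult
  lib$center <- lib$center + shift
  lib
}

# Baseline = low-order polynomial drift + one broad fluorescence hump,
# in absolute intensity units (weakest component's maximum = 1).
draw_baseline <- function(cfg, id) {
  axis <- generator_axis(cfg)
  u <- (axis - cfg$axis_start) / (cfg$axis_end - cfg$axis_start)
  withr::with_seed(sub_seed(cfg$seed, "baseline", id), {
    coef <- runif(cfg$baseline_order + 1, 0, cfg$baseline_drift)
    famp <- runif(1, cfg$fluor_amp_range[1], cfg$fluor_amp_range[2])
    fcen <- runif(1, cfg$fluor_center_range[1], cfg$fluor_center_range[2])
    fwid <- runif(1, cfg$fluor_width_range[1], cfg$fluor_width_range[2])
  })
  drift <- as.vector(outer(u, seq_along(coef) - 1, `^`) %*% coef)
  sigma <- fwid / (2 * sqrt(2 * log(2)))
  drift + famp * exp(-(axis - fcen)^2 / (2 * sigma^2))
}

draw_noise <- function(cfg, id, scale, n) {
  if (cfg$noise_sd == 0) return(numeric(n))
  withr::with_seed(
    sub_seed(cfg$seed, "noise", id),
    rnorm(n, 0, cfg$noise_sd * scale)
  )
}

#' Generate replicate pure-compound SERS spectra
#'
#' Each replicate is the component's profile with per-band amplitude
#' jitter (relative SD `amplitude_jitter_rsd`) and band-position jitter,
#' plus a drawn baseline (polynomial drift + fluorescence hump) and
#' additive noise. Deterministic given the configuration seed.
#'
#' @param component One of `"A"`, `"B"`, `"C"`.
#' @param n Number of replicates (>= 1).
#' @param config A [sers_generator_config()].
#' @param ids Optional integer replicate ids (default `1:n`); spectra with
#'   the same id share jitter/baseline/noise draws across generator calls.
#' @param concentration Scalar (or per-replicate vector) analyte
#'   concentration factor scaling the signal but not baseline or noise
#'   floor (default 1: replicates at fixed concentration).
#' @return A list of spectrum tibbles.
#' @export
generate_pure <- function(component, n, config, ids = seq_len(n),
                          concentration = 1) {
  component <- match.arg(component, .components)
  if (n < 1) abort("n must be >= 1")
  stopifnot(length(ids) == n)
  axis <- generator_axis(config)
  sc <- profile_scale(component, config)
  conc <- rep_len(concentration, n)
  purrr::map2(ids, seq_len(n), function(id, i) {
    sig <- conc[i] * peak_sum(axis, jittered_peaks(component, config, id),
                              config$peak_shape) * sc
    base <- draw_baseline(config, id)
    y <- sig + base
    y <- y + draw_noise(config, id, max(c(y, 1)), length(y))
    new_spectrum(axis, y, category = component, id = id)
  })
}

#' Generate one mixture SERS spectrum with non-linear peak masking
#'
#' The mixture is a weighted sum of jittered component profiles followed
#' by competitive masking: bands of a weaker component (lower effective
#' intensity `weight * enhancement`) are attenuated by
#' `1 - masking_strength * dominance * kappa`, where `dominance` is
#' `1 - I_weak / I_strong` and `kappa` is 1 for bands lying within one
#' FWHM of a stronger component's band and `masking_kappa_global`
#' otherwise, emulating both band overlap and whole-spectrum suppression
#' by competitive adsorption. Baseline and noise are then added. With
#' `masking_strength = 0` and all jitter/noise/baseline terms zero the
#' result is the exact weighted sum of profiles.
#'
#' @param components Character vector of at least two component labels.
#' @param weights Nonnegative weights over `components`, not all zero.
#' @param config A [sers_generator_config()].
#' @param id Replicate id (shares RNG sub-streams with [generate_pure()]).
#' @param concentration Scalar concentration factor for the whole mixed
#'   sample (default 1).
#' @return A spectrum tibble.
#' @export
generate_mixture <- function(components, weights, config, id = 1L,
                             concentration = 1) {
  components <- match.arg(components, .components, several.ok = TRUE)
  if (length(components) < 2) abort("a mixture needs at least 2 components")
  if (anyDuplicated(components)) abort("duplicated component labels")
  if (length(weights) != length(components)) {
    abort("weights must match components")
  }
  if (any(weights < 0)) abort("weights must be nonnegative")
  if (all(weights == 0)) abort("weights must not all be zero")

  axis <- generator_axis(config)
  eff <- weights * unname(config$enhancement[components])
  peak_tabs <- purrr::map(components, jittered_peaks, cfg = config, id = id)
  names(peak_tabs) <- components

  sig <- numeric(length(axis))
  for (i in seq_along(components)) {
    if (weights[i] == 0) next
    pk <- peak_tabs[[i]]
    attn <- rep(1, nrow(pk))
    for (j in seq_along(components)) {
      if (j == i || eff[j] <= eff[i]) next
      dom <- 1 - eff[i] / eff[j]
      other <- peak_tabs[[j]]
      for (q in seq_len(nrow(pk))) {
        fwhm <- pmax(pk$width[q], other$width)
        overlap <- any(abs(pk$center[q] - other$center) <= fwhm)
        kappa <- if (overlap) 1 else config$masking_kappa_global
        attn[q] <- attn[q] * (1 - config$masking_strength * dom * kappa)
      }
    }
    pk$amplitude <- pk$amplitude * attn
    sig <- sig + weights[i] * profile_scale(components[i], config) *
      peak_sum(axis, pk, config$peak_shape)
  }
  base <- draw_baseline(config, id)
  y <- concentration * sig + base
  y <- y + draw_noise(config, id, max(c(y, 1)), length(y))
  new_spectrum(axis, y, category = components_category(components), id = id)
}

#' Default split sizes of the synthetic dataset
#'
#' Training covers only the pure categories (157/215/220 spectra for
#' A/B/C); validation and test cover all seven categories with 50 and 53
#' spectra per category respectively.
#'
#' @return A list with elements `train`, `val`, `test`.
#' @export
default_split_sizes <- function() {
  list(
    train = c(A = 157, B = 215, C = 220),
    val = setNames(rep(50L, 7), .categories),
    test = setNames(rep(53L, 7), .categories)
  )
}

#' Generate a full synthetic SERS dataset with manifest
#'
#' Generates pure spectra for the training split and all seven categories
#' (A, B, C, AB, AC, BC, ABC) for validation and test. Mixtures emulate
#' equal-part (1:1 or 1:1:1) mixing of equal-concentration stocks:
#' component weights are drawn per sample around 1 with a 5% relative
#' standard deviation (pipetting variability). Requesting a mixture
#' category in the training split is a protocol violation and raises an
#' error. Bit-identical output for identical configuration.
#'
#' @param config A [sers_generator_config()].
#' @param sizes Split sizes as in [default_split_sizes()]; `train` may
#'   name only pure categories.
#' @param dir Optional directory; when given, spectra are written as
#'   two-column CSV files plus a JSON manifest and a YAML config echo.
#' @return A list of class `sers_dataset` with elements `manifest`
#'   (tibble: id, category, split, path), `spectra` (named list) and
#'   `config`.
#' @export
generate_dataset <- function(config, sizes = default_split_sizes(),
                             dir = NULL) {
  for (split in names(sizes)) {
    cats <- names(sizes[[split]])
    if (is.null(cats)) abort("split sizes must be named by category")
    bad <- setdiff(cats, .categories)
    if (length(bad)) abort(sprintf("unknown category '%s'", bad[1]))
    if (split == "train" && any(nchar(cats) > 1)) {
      abort(paste0(
        "protocol violation: mixture category '",
        cats[nchar(cats) > 1][1],
        "' requested in the training split (training uses pure spectra only)"
      ))
    }
    if (any(sizes[[split]] < 1)) abort("split sizes must be positive")
  }

  manifest <- purrr::map_dfr(names(sizes), function(split) {
    tibble(
      category = rep(names(sizes[[split]]), sizes[[split]]),
      split = split
    )
  })
  manifest <- dplyr::mutate(
    manifest,
    id = sprintf("s%05d", dplyr::row_number()),
    .before = 1
  )

  cr <- config$concentration_range %||% c(1, 1)
  spectra <- purrr::map2(manifest$id, manifest$category, function(id, cat) {
    num <- as.integer(sub("^s", "", id))
    comps <- category_components(cat)
    conc <- withr::with_seed(
      sub_seed(config$seed, "conc", num),
      exp(runif(1, log(cr[1]), log(cr[2])))
    )
    if (length(comps) == 1) {
      generate_pure(comps, 1, config, ids = num, concentration = conc)[[1]]
    } else {
      w <- withr::with_seed(
        sub_seed(config$seed, "weights", num),
        pmax(rnorm(length(comps), 1, 0.05), 0.1)
      )
      generate_mixture(comps, w, config, id = num, concentration = conc)
    }
  })
  names(spectra) <- manifest$id

  manifest$path <- NA_character_
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(dir, paste0(manifest$id, ".csv"))
    purrr::walk2(spectra, manifest$path, write_spectrum)
    write_manifest(manifest, file.path(dir, "manifest.json"))
    yaml::write_yaml(
      unclass(config)[setdiff(names(config), "libraries")],
      file.path(dir, "generator.yaml")
    )
  }
  structure(
    list(manifest = manifest, spectra = spectra, config = config),
    class = "sers_dataset"
  )
}

#' @export
print.sers_dataset <- function(x, ...) {
  cat("<sers_dataset>\n")
  print(dplyr::count(x$manifest, .data$split, .data$category))
  invisible(x)
}
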