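test_that("crop/resample yields the fixed fingerprint grid", {
  out <- crop_resample(toy_raw_spectrum())
  expect_equal(nrow(out), 2048L)
  expect_equal(min(out$wavenumber), 500)
  expect_equal(max(out$wavenumber), 1800)

  # interpolation is the identity on an already-uniform input
  again <- crop_resample(out)
  expect_equal(again$intensity, out$intensity, tolerance = 1e-12)

  # linear interpolation preserves affine intensity profiles exactly
  wn <- seq(400, 1900, by = 0.8)
  aff <- tibble::tibble(wavenumber = wn, intensity = 3 + 0.01 * wn)
  res <- crop_resample(aff)
  expect_equal(res$intensity, 3 + 0.01 * res$wavenumber, tolerance = 1e-10)

  short <- tibble::tibble(wavenumber = 600:1900, intensity = rnorm(1301))
  expect_error(crop_resample(short), "fingerprint region")
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  wn <- seq_len(101)
  quad <- tibble::tibble(wavenumber = wn, intensity = 2 - 3 * wn + 0.5 * wn^2)
  sm <- sg_smooth(quad, 5, 2)
  expect_equal(sm$intensity, quad$intensity, tolerance = 1e-8)

  const <- tibble::tibble(wavenumber = wn, intensity = rep(4, 101))
  expect_equal(sg_smooth(const, 5, 2)$intensity, const$intensity)

  expect_error(sg_smooth(quad, 4, 2), "odd")
  expect_error(sg_smooth(quad, 5, 5), "order")
})

test_that("impulse response matches the closed-form SG(5,2) kernel", {
  imp <- tibble::tibble(wavenumber = seq_len(21),
                        intensity = as.numeric(seq_len(21) == 11))
  sm <- sg_smooth(imp, 5, 2)
  kern <- c(-3, 12, 17, 12, -3) / 35
  expect_equal(sm$intensity[9:13], kern, tolerance = 1e-10)
})

test_that("baseline correction removes polynomial backgrounds", {
  wn <- seq(500, 1800, length.out = 600)
  u <- (wn - 500) / 1300
  poly_only <- tibble::tibble(wavenumber = wn,
                              intensity = 2 + 3 * u - 1.5 * u^2 + 0.5 * u^4)
  bc <- baseline_correct(poly_only)
  expect_lt(max(abs(bc$corrected$intensity)),
            1e-6 * max(poly_only$intensity))

  peak <- 5 * exp(-(wn - 1100)^2 / (2 * 5^2))
  with_peak <- tibble::tibble(wavenumber = wn,
                              intensity = 2 + 3 * u - 1.5 * u^2 + peak)
  bc2 <- baseline_correct(with_peak)
  i_pk <- which.max(peak)
  expect_equal(bc2$corrected$intensity[i_pk], 5, tolerance = 0.05)
  off <- abs(wn - 1100) > 40
  expect_lt(max(bc2$corrected$intensity[off]), 0.02 * 5)
})

test_that("baseline-free peak spectra pass through nearly unchanged", {
  wn <- seq(500, 1800, length.out = 600)
  peaks <- 4 * exp(-(wn - 800)^2 / (2 * 5^2)) +
    2 * exp(-(wn - 1500)^2 / (2 * 6^2))
  s <- tibble::tibble(wavenumber = wn, intensity = peaks)
  bc <- baseline_correct(s)
  expect_lt(max(abs(bc$corrected$intensity - peaks)), 0.05 * max(peaks))
})

test_that("min-max plus power transform maps the documented values", {
  s <- tibble::tibble(wavenumber = 1:3, intensity = c(0, 0.25, 1))
  out <- normalize_power(s, alpha = 1.5)
  expect_equal(out$intensity, c(0, 0.125, 1))

  out1 <- normalize_power(s, alpha = 1)
  expect_equal(out1$intensity, c(0, 0.25, 1))

  flat <- tibble::tibble(wavenumber = 1:3, intensity = rep(2, 3))
  expect_error(normalize_power(flat), "constant")
})

test_that("the full chain emits unit-interval vectors peaking at the main band", {
  cfg <- sers_generator_config(seed = 17)
  s <- generate_pure("A", 1, cfg)[[1]]
  x <- preprocess(s)
  expect_equal(nrow(x), 2048L)
  expect_true(all(x$intensity >= 0 & x$intensity <= 1))
  expect_equal(range(x$wavenumber), c(500, 1800))

  # argmax tracks the strongest peak of the jittered noiseless signal
  qcfg <- quiet_generator(seed = 17, amplitude_jitter_rsd = 0.08)
  sq <- generate_pure("A", 1, qcfg)[[1]]
  truth <- sq$wavenumber[which.max(sq$intensity)]
  xq <- preprocess(sq)
  expect_lt(abs(xq$wavenumber[which.max(xq$intensity)] - truth), 4)
})

test_that("the chain is invariant to global intensity rescaling", {
  cfg <- sers_generator_config(seed = 23)
  s <- generate_pure("C", 1, cfg)[[1]]
  s10 <- s
  s10$intensity <- 10 * s10$intensity
  expect_equal(preprocess(s10)$intensity, preprocess(s)$intensity,
               tolerance = 1e-9)
})

test_that("the chain is near-idempotent on its own output at alpha = 1", {
  cfg1 <- preproc_config(alpha = 1)
  s <- toy_raw_spectrum()
  once <- preprocess(s, cfg1)
  twice <- preprocess(once, cfg1)
  expect_lt(max(abs(twice$intensity - once$intensity)), 1e-4)
})
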