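test_that("component profiles peak at the characteristic band positions", {
  cfg <- sers_generator_config(seed = 3)
  prof <- component_profile("A", cfg)
  expect_equal(prof$wavenumber[which.max(prof$intensity)], 840)
  expect_equal(max(prof$intensity), unname(cfg$enhancement["A"]))

  # every well-separated library band is a local maximum of its profile
  # (+- one step); tricyclazole's 988/1000 cm^-1 doublet merges into a
  # single band at realistic widths, so A and B are checked
  for (comp in c("A", "B")) {
    prof <- component_profile(comp, cfg)
    y <- prof$intensity
    local_max <- prof$wavenumber[which(diff(sign(diff(y))) == -2) + 1]
    for (ctr in sers_peak_positions(comp)$center) {
      expect_true(min(abs(local_max - ctr)) <= cfg$axis_step,
                  label = sprintf("%s band at %g is a local maximum", comp, ctr))
    }
  }
})

test_that("profile generation validates its peak library", {
  cfg <- sers_generator_config(seed = 1)
  cfg$libraries$A <- cfg$libraries$A[0, ]
  expect_error(component_profile("A", cfg), "empty")

  cfg2 <- sers_generator_config(seed = 1)
  cfg2$libraries$A$center[6] <- 1950
  expect_error(component_profile("A", cfg2), "1950")
})

test_that("pure replicates are deterministic and reduce to profile + baseline", {
  cfg <- sers_generator_config(seed = 9)
  s1 <- generate_pure("B", 3, cfg)
  s2 <- generate_pure("B", 3, cfg)
  expect_identical(s1, s2)

  cfg0 <- sers_generator_config(
    amplitude_jitter_rsd = 0, shift_jitter = 0, noise_sd = 0, seed = 9
  )
  s <- generate_pure("B", 1, cfg0, ids = 4L)[[1]]
  expected <- component_profile("B", cfg0)$intensity +
    sersmix:::draw_baseline(cfg0, 4L)
  expect_equal(s$intensity, expected, tolerance = 1e-12)
})

test_that("replicate reference-band RSD tracks the configured jitter", {
  cfg <- sers_generator_config(
    shift_jitter = 0, noise_sd = 0, baseline_drift = 0,
    fluor_amp_range = c(0, 0), seed = 21
  )
  reps <- generate_pure("B", 120, cfg)
  i1380 <- which(reps[[1]]$wavenumber == 1380)
  heights <- vapply(reps, function(s) s$intensity[i1380], numeric(1))
  rsd <- sd(heights) / mean(heights)
  expect_gt(rsd, 0.08 * 0.7)
  expect_lt(rsd, 0.08 * 1.3)
})

test_that("mixtures reduce to the exact weighted sum in the linear limit", {
  cfg <- quiet_generator(seed = 5, masking_strength = 0)
  m <- generate_mixture(c("A", "C"), c(0.7, 1.3), cfg, id = 2L)
  lin <- 0.7 * component_profile("A", cfg)$intensity +
    1.3 * component_profile("C", cfg)$intensity
  expect_equal(m$intensity, lin, tolerance = 1e-12)
})

test_that("masking attenuates the weaker component's bands", {
  cfg0 <- quiet_generator(seed = 5, masking_strength = 0)
  cfg1 <- quiet_generator(seed = 5, masking_strength = 0.9)
  lin <- generate_mixture(c("A", "C"), c(1, 1), cfg0, id = 1L)
  msk <- generate_mixture(c("A", "C"), c(1, 1), cfg1, id = 1L)
  at <- function(s, wn) s$intensity[s$wavenumber == wn]
  # tricyclazole-only band suppressed by dominant paraquat
  expect_lt(at(msk, 988), at(lin, 988))
  # dominant component's band nearly untouched (only the attenuated
  # tails of tricyclazole bands change the total there)
  expect_equal(at(msk, 840), at(lin, 840), tolerance = 1e-3)
  expect_true(all(msk$intensity <= lin$intensity + 1e-12))
})

test_that("zero-weight components leave the shared-seed pure path intact", {
  cfg <- sers_generator_config(seed = 13)
  mix <- generate_mixture(c("A", "B"), c(1, 0), cfg, id = 7L)
  pure <- generate_pure("A", 1, cfg, ids = 7L)[[1]]
  expect_equal(mix$intensity, pure$intensity, tolerance = 1e-12)
})

test_that("mixture preconditions are enforced", {
  cfg <- sers_generator_config(seed = 1)
  expect_error(generate_mixture("A", 1, cfg), "at least 2")
  expect_error(generate_mixture(c("A", "B"), c(-1, 1), cfg), "nonnegative")
  expect_error(generate_mixture(c("A", "B"), c(0, 0), cfg), "zero")
  expect_error(generate_pure("A", 0, cfg), ">= 1")
})

test_that("dataset manifests mirror the split design", {
  cfg <- sers_generator_config(seed = 2)
  sizes <- default_split_sizes()
  sizes$val <- setNames(rep(2L, 7), names(sizes$val))
  sizes$test <- setNames(rep(2L, 7), names(sizes$test))
  ds <- generate_dataset(cfg, sizes)
  man <- ds$manifest
  expect_equal(sum(man$split == "train"), 157 + 215 + 220)
  expect_equal(as.integer(table(man$category[man$split == "train"])),
               c(157L, 215L, 220L))
  expect_true(all(nchar(man$category[man$split == "train"]) == 1))
  expect_equal(length(ds$spectra), nrow(man))

  expect_error(
    generate_dataset(cfg, list(train = c(A = 5, AB = 5))),
    "protocol violation"
  )
})

test_that("validation covers all seven categories at equal counts", {
  sizes <- default_split_sizes()
  expect_equal(unname(sizes$val), rep(50L, 7))
  expect_setequal(names(sizes$val),
                  c("A", "B", "C", "AB", "AC", "BC", "ABC"))
})

test_that("identical configuration reproduces the dataset bit for bit", {
  cfg <- sers_generator_config(seed = 31)
  sizes <- list(train = c(A = 3, B = 3, C = 3),
                val = c(AB = 2, ABC = 2), test = c(AC = 2))
  d1 <- generate_dataset(cfg, sizes)
  d2 <- generate_dataset(sers_generator_config(seed = 31), sizes)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$spectra, d2$spectra)
})
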