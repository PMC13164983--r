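test_that("set-likelihood scores match direct arithmetic", {
  p <- c(0.9, 0.8, 0.1)
  expect_equal(set_likelihood(p, c("A", "B")),
               log(0.9) + log(0.8) + log(0.9), tolerance = 1e-12)
  expect_equal(set_likelihood(p, "AB"), set_likelihood(p, c("A", "B")))

  # full symmetry at p = 0.5: all pairs tie at 3 log(0.5)
  ph <- rep(0.5, 3)
  for (S in c("AB", "AC", "BC")) {
    expect_equal(set_likelihood(ph, S), 3 * log(0.5))
  }

  # saturated probabilities are clamped, the matching set wins strictly
  ps <- c(1, 1, 0)
  sAB <- set_likelihood(ps, "AB")
  expect_equal(sAB, 3 * log(1 - 1e-7), tolerance = 1e-10)
  expect_gt(sAB, set_likelihood(ps, "AC"))
  expect_gt(sAB, set_likelihood(ps, "BC"))

  expect_error(set_likelihood(p, character(0)), "non-empty")
})

test_that("stage-1 ranking equals brute-force enumeration", {
  cfg <- inference_config()
  oracle <- function(p, cands) {
    sc <- vapply(cands, function(S) {
      comps <- strsplit(S, "")[[1]]
      pc <- pmin(pmax(p, cfg$prob_clamp), 1 - cfg$prob_clamp)
      inset <- c("A", "B", "C") %in% comps
      sum(log(pc[inset])) + sum(log(1 - pc[!inset]))
    }, numeric(1))
    cands[which.max(sc)]
  }
  withr::with_seed(99, {
    for (i in 1:200) {
      p <- runif(3)
      expect_equal(rank_binary(p, cfg)$S_bin,
                   oracle(p, c("AB", "AC", "BC")))
    }
  })

  # deterministic lexicographic tie-break under full symmetry
  expect_equal(rank_binary(rep(0.5, 3), cfg)$S_bin, "AB")

  # unified mode lets a confident singleton beat every pair
  ucfg <- inference_config(candidate_mode = "unified")
  expect_equal(rank_binary(c(0.99, 0.01, 0.01), ucfg)$S_bin, "A")
})

test_that("prototypes are class-wise means", {
  X <- rbind(c(1, 2, 3), c(3, 4, 5), c(0, 0, 1), c(2, 2, 2))
  pr <- build_prototypes(X, c("A", "A", "B", "C"))
  expect_equal(unname(pr[, "A"]), c(2, 3, 4))
  expect_equal(unname(pr[, "B"]), c(0, 0, 1))
  expect_equal(unname(pr[, "C"]), c(2, 2, 2))

  one <- build_prototypes(X[c(1, 3, 4), ], c("A", "B", "C"))
  expect_equal(unname(one[, "A"]), c(1, 2, 3))
  expect_error(build_prototypes(X[1:2, ], c("A", "A")), "component 'B'")
})

test_that("NNLS reconstruction is exact on spanned inputs and at the boundary", {
  pr <- cbind(A = c(1, 0, 0, 1), B = c(0, 1, 1, 0), C = c(1, 1, 0, 0))
  x <- 0.5 * pr[, "A"] + 0.5 * pr[, "B"]
  r <- nnls_reconstruct(x, pr, c("A", "B"))
  expect_equal(unname(r$beta), c(0.5, 0.5), tolerance = 1e-10)
  expect_lt(r$e, 1e-16)

  # all-negative unconstrained fit collapses to beta = 0
  xm <- -pr[, "A"]
  rb <- nnls_reconstruct(xm, pr, "A")
  expect_equal(unname(rb$beta), 0)
  expect_equal(rb$e, sum(xm^2))

  expect_error(nnls_reconstruct(c(1, NA, 0, 0), pr, "A"), "finite")
})

test_that("NNLS matches a dense grid-search oracle on random instances", {
  withr::with_seed(7, {
    for (i in 1:20) {
      P <- matrix(runif(16 * 2), 16, 2)
      colnames(P) <- c("A", "B")
      x <- as.vector(P %*% runif(2, 0, 1.5)) + rnorm(16, sd = 0.05)
      e <- nnls_reconstruct(x, cbind(P, C = runif(16)), c("A", "B"))$e
      e_grid <- grid_nnls(x, P, beta_max = 2, step = 0.02)
      expect_lte(e, e_grid + 1e-10)
      expect_lt(abs(e - e_grid), 0.05)
    }
  })
})

test_that("ternary support never fits worse than binary support", {
  withr::with_seed(17, {
    pr <- matrix(runif(64 * 3), 64, 3)
    colnames(pr) <- c("A", "B", "C")
    for (i in 1:50) {
      x <- as.vector(pr %*% runif(3)) + rnorm(64, sd = 0.1)
      eb <- nnls_reconstruct(x, pr, "AB")$e
      et <- nnls_reconstruct(x, pr, c("A", "B", "C"))$e
      expect_lte(et, eb + 1e-10)
    }
  })
})

test_that("residual gain and missing ratio follow their definitions", {
  expect_equal(residual_gain(0.10, 0.08), 0.2, tolerance = 1e-12)
  expect_equal(residual_gain(0.5, 0.5), 0)
  expect_equal(residual_gain(0.5, 0), 1)
  expect_equal(residual_gain(0, 0), 0)
  expect_error(residual_gain(-1, 0), "nonnegative")

  tri <- list(support = c("A", "B", "C"),
              beta = c(A = 0.4, B = 0.4, C = 0.2))
  expect_equal(missing_ratio(tri, "AB"), 0.2, tolerance = 1e-12)
  tri0 <- list(support = c("A", "B", "C"), beta = c(A = 1, B = 1, C = 0))
  expect_equal(missing_ratio(tri0, "AB"), 0)
  tri1 <- list(support = c("A", "B", "C"), beta = c(A = 0, B = 0, C = 1))
  expect_equal(missing_ratio(tri1, "AB"), 1)
  triz <- list(support = c("A", "B", "C"), beta = c(A = 0, B = 0, C = 0))
  expect_equal(missing_ratio(triz, "AB"), 0)
  expect_error(missing_ratio(list(support = c("A", "B"), beta = c(1, 1)),
                             "AB"), "full support")
})

test_that("the refinement rule fires only when both thresholds are met", {
  cfg <- inference_config()
  expect_equal(refine_decision(0.05, 0.10, cfg, "AC"), "ABC")
  expect_equal(refine_decision(0.05, 0.05, cfg, "AC"), "AC")
  expect_equal(refine_decision(0.01, 0.50, cfg, "AC"), "AC")
  expect_equal(refine_decision(0.01, 0.01, cfg, "AC"), "AC")
  # thresholds are inclusive
  expect_equal(refine_decision(0.040, 0.080, cfg, "AB"), "ABC")

  # monotone: increasing g or rho never flips ternary back to binary
  gs <- seq(0, 0.2, by = 0.01)
  rhos <- seq(0, 0.3, by = 0.02)
  for (rho in rhos) {
    dec <- vapply(gs, refine_decision, character(1), rho = rho, cfg = cfg)
    expect_true(all(diff(dec == "ABC") >= 0))
  }
  for (g in gs) {
    dec <- vapply(rhos, function(r) refine_decision(g, r, cfg),
                  character(1))
    expect_true(all(diff(dec == "ABC") >= 0))
  }
})

test_that("end-to-end inference report is internally consistent", {
  model <- tiny_model(seed = 12)
  withr::with_seed(3, {
    pr <- matrix(runif(64 * 3, 0, 1), 64, 3)
    colnames(pr) <- c("A", "B", "C")
    x <- as.vector(pr %*% c(0.6, 0.5, 0)) + abs(rnorm(64, sd = 0.02))
  })
  rep1 <- infer(x, model, pr)
  expect_s3_class(rep1$stage1_scores, "tbl_df")
  expect_true(rep1$S_bin %in% c("AB", "AC", "BC"))
  expect_true(rep1$decision %in% c(rep1$S_bin, "ABC"))
  expect_lte(rep1$e_tri, rep1$e_bin + 1e-10)
  expect_equal(rep1$g, residual_gain(rep1$e_bin, rep1$e_tri))

  batch <- infer_batch(rbind(x, x), model, pr)
  expect_equal(nrow(batch), 2L)
  expect_equal(batch$decision[1], rep1$decision)
})
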