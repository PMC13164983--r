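#' Two-stage inference configuration
#'
#' Stage 1 ranks candidate component sets by their set-likelihood score;
#' stage 2 decides between the winning binary hypothesis and the ternary
#' hypothesis from nonnegative least-squares reconstruction residuals.
#'
#' @param tau_g Relative residual-gain threshold (default 0.040).
#' @param tau_rho Missing-component ratio threshold (default 0.080).
#' @param prob_clamp Probability clamp epsilon for the log-domain score
#'   (default 1e-7).
#' @param candidate_mode `"pairs_only"` (candidates AB, AC, BC; the
#'   mixture-only evaluation setting) or `"unified"` (singletons and
#'   pairs; used for seven-category validation, where a singleton winner
#'   is returned as a pure prediction without refinement).
#' @param residual_metric `"squared_l2"` (default) or `"l2"`.
#' @return A list of class `sers_inference_config`.
#' @export
inference_config <- function(tau_g = 0.040, tau_rho = 0.080,
                             prob_clamp = 1e-7,
                             candidate_mode = c("pairs_only", "unified"),
                             residual_metric = c("squared_l2", "l2")) {
  candidate_mode <- match.arg(candidate_mode)
  residual_metric <- match.arg(residual_metric)
  if (tau_g <= 0 || tau_g >= 1 || tau_rho <= 0 || tau_rho >= 1) {
    abort("thresholds must lie in (0, 1)")
  }
  if (prob_clamp <= 0 || prob_clamp >= 0.5) {
    abort("prob_clamp must lie in (0, 0.5)")
  }
  structure(
    list(
      tau_g = tau_g, tau_rho = tau_rho, prob_clamp = prob_clamp,
      candidate_mode = candidate_mode, residual_metric = residual_metric
    ),
    class = "sers_inference_config"
  )
}

candidate_sets <- function(mode) {
  if (mode == "pairs_only") .pair_categories else
    c(.components, .pair_categories)
}

#' Set-likelihood score of a candidate component set
#'
#' `Score(S) = sum_{k in S} log p_k + sum_{k not in S} log(1 - p_k)`,
#' with probabilities clamped to `[eps, 1 - eps]`; always <= 0.
#'
#' @param p Component probability vector (named by component or in
#'   A, B, C order).
#' @param S Character vector of component labels (non-empty), or a
#'   category string such as `"AB"`.
#' @param eps Probability clamp.
#' @return Scalar log-likelihood score.
#' @export
set_likelihood <- function(p, S, eps = 1e-7) {
  if (length(S) == 1 && nchar(S) > 1) S <- category_components(S)
  if (length(S) == 0) abort("candidate set must be non-empty")
  K <- length(p)
  comps <- names(p) %||% .components[seq_len(K)]
  if (!all(S %in% comps)) abort("unknown component in candidate set")
  p <- pmin(pmax(p, eps), 1 - eps)
  inset <- comps %in% S
  sum(log(p[inset])) + sum(log(1 - p[!inset]))
}

#' Rank candidate component sets by set-likelihood
#'
#' Evaluates the set-likelihood score for every candidate (binary pairs,
#' plus singletons in unified mode) and returns the winner; exact ties
#' resolve to the lexicographically smallest candidate.
#'
#' @param p Component probability vector.
#' @param cfg An [inference_config()].
#' @return A list with `S_bin` (winning category string) and
#'   `stage1_scores` (tibble: candidate, score, ordered as evaluated).
#' @export
rank_binary <- function(p, cfg = inference_config()) {
  cands <- sort(candidate_sets(cfg$candidate_mode))
  scores <- vapply(
    cands, function(S) set_likelihood(p, S, cfg$prob_clamp), numeric(1)
  )
  list(
    S_bin = cands[which.max(scores)],
    stage1_scores = tibble(candidate = cands, score = unname(scores))
  )
}

#' Build pure-component prototype spectra
#'
#' Class-wise arithmetic mean of the preprocessed pure-spectrum training
#' features, one prototype per component.
#'
#' @param features N x L matrix of preprocessed pure training spectra.
#' @param labels Component labels (`"A"/"B"/"C"`) for the rows.
#' @return An L x K matrix with one column per component.
#' @export
build_prototypes <- function(features, labels) {
  missing <- setdiff(.components, unique(labels))
  if (length(missing)) {
    abort(sprintf("no training spectra for component '%s'", missing[1]))
  }
  protos <- vapply(
    .components,
    function(k) colMeans(features[labels == k, , drop = FALSE]),
    numeric(ncol(features))
  )
  colnames(protos) <- .components
  protos
}

#' Nonnegative least-squares reconstruction under a component hypothesis
#'
#' Solves `min_{beta >= 0} ||x - P_S beta||^2` over the prototypes of the
#' support set (Lawson-Hanson active-set solution) and reports the
#' residual error.
#'
#' @param x Feature vector (or feature spectrum tibble).
#' @param prototypes L x K prototype matrix from [build_prototypes()].
#' @param support Character vector of component labels, or a category
#'   string such as `"AB"`.
#' @param metric `"squared_l2"` (default) or `"l2"` residual error.
#' @return A list with `support`, `beta` (named nonnegative weights) and
#'   `e` (residual error).
#' @export
nnls_reconstruct <- function(x, prototypes, support,
                             metric = "squared_l2") {
  if (is.data.frame(x)) x <- x$intensity
  if (any(!is.finite(x))) abort("non-finite values in input")
  if (length(support) == 1 && nchar(support) > 1) {
    support <- category_components(support)
  }
  if (length(support) == 0) abort("support must be non-empty")
  P <- prototypes[, support, drop = FALSE]
  beta <- pracma::lsqnonneg(P, as.numeric(x))$x
  names(beta) <- support
  r <- as.numeric(x) - as.vector(P %*% beta)
  e <- sum(r * r)
  if (metric == "l2") e <- sqrt(e)
  list(support = support, beta = beta, e = e)
}

#' Relative residual gain of the ternary over the binary hypothesis
#'
#' `g = (e_bin - e_tri) / e_bin`; defined as 0 when `e_bin` is 0.
#'
#' @param e_bin,e_tri Nonnegative reconstruction errors.
#' @return Scalar gain (<= 1).
#' @export
residual_gain <- function(e_bin, e_tri) {
  if (e_bin < 0 || e_tri < 0) abort("residual errors must be nonnegative")
  if (e_bin == 0) return(0)
  (e_bin - e_tri) / e_bin
}

#' Missing-component ratio of the ternary fit
#'
#' The ternary fitting weight of the component absent from the binary
#' hypothesis, normalised by the total ternary fitting weight; 0 when
#' all weights are 0.
#'
#' @param tri_result Ternary [nnls_reconstruct()] result (support = all
#'   components).
#' @param S_bin Binary category string or component vector.
#' @return Scalar ratio in `[0, 1]`.
#' @export
missing_ratio <- function(tri_result, S_bin) {
  if (length(S_bin) == 1 && nchar(S_bin) > 1) {
    S_bin <- category_components(S_bin)
  }
  if (!setequal(tri_result$support, .components)) {
    abort("ternary result must have full support A, B, C")
  }
  missing <- setdiff(.components, S_bin)
  if (length(missing) != 1) {
    abort("binary hypothesis must omit exactly one component")
  }
  total <- sum(tri_result$beta)
  if (total == 0) return(0)
  unname(tri_result$beta[missing] / total)
}

#' Apply the residual-based refinement decision
#'
#' Ternary if and only if both the residual gain and the
#' missing-component ratio reach their thresholds; otherwise the binary
#' prediction is retained.
#'
#' @param g Residual gain.
#' @param rho Missing-component ratio.
#' @param cfg An [inference_config()].
#' @param S_bin Binary category retained when refinement does not fire.
#' @return Category string.
#' @export
refine_decision <- function(g, rho, cfg = inference_config(),
                            S_bin = "AB") {
  if (g >= cfg$tau_g && rho >= cfg$tau_rho) "ABC" else S_bin
}

#' Two-stage mixture inference for one spectrum
#'
#' Stage 1 converts the evidence probabilities into a ranked list of
#' candidate sets and picks the winner. If the winner is a pair (always,
#' in pairs-only mode), stage 2 reconstructs the spectrum under the
#' binary and ternary hypotheses, computes the residual gain g and the
#' missing-component ratio rho, and upgrades to the ternary category only
#' when both thresholds are met. In unified mode a singleton winner is
#' returned directly as a pure prediction.
#'
#' @param x Preprocessed feature vector or feature spectrum tibble.
#' @param model A trained `sers_model`.
#' @param prototypes Prototype matrix from [build_prototypes()].
#' @param cfg An [inference_config()].
#' @return A list of class `sers_inference`: `p`, `stage1_scores`,
#'   `S_bin`, `beta_bin`, `beta_tri`, `e_bin`, `e_tri`, `g`, `rho`,
#'   `decision`.
#' @export
infer <- function(x, model, prototypes, cfg = inference_config()) {
  if (is.data.frame(x)) x <- x$intensity
  p <- drop(component_probabilities(x, model))
  report <- infer_from_probs(x, p, prototypes, cfg)
  structure(report, class = "sers_inference")
}

infer_from_probs <- function(x, p, prototypes, cfg) {
  stage1 <- rank_binary(p, cfg)
  S_bin <- stage1$S_bin
  if (nchar(S_bin) == 1) {
    return(list(
      p = p, stage1_scores = stage1$stage1_scores, S_bin = S_bin,
      beta_bin = NULL, beta_tri = NULL, e_bin = NA_real_, e_tri = NA_real_,
      g = NA_real_, rho = NA_real_, decision = S_bin
    ))
  }
  rb <- nnls_reconstruct(x, prototypes, S_bin, cfg$residual_metric)
  rt <- nnls_reconstruct(x, prototypes, .components, cfg$residual_metric)
  if (rt$e > rb$e * (1 + 1e-6) + 1e-12) {
    warn("ternary NNLS residual exceeds binary residual (numerical issue)")
  }
  g <- residual_gain(rb$e, rt$e)
  rho <- missing_ratio(rt, S_bin)
  list(
    p = p, stage1_scores = stage1$stage1_scores, S_bin = S_bin,
    beta_bin = rb$beta, beta_tri = rt$beta, e_bin = rb$e, e_tri = rt$e,
    g = g, rho = rho,
    decision = refine_decision(g, rho, cfg, S_bin)
  )
}

#' @export
print.sers_inference <- function(x, ...) {
  cat("<sers_inference>\n")
  cat("  p:", paste(sprintf("%s=%.3f", names(x$p) %||% .components, x$p),
                    collapse = "  "), "\n")
  cat("  stage 1 winner:", x$S_bin, "\n")
  if (!is.na(x$g)) {
    cat(sprintf("  e_bin=%.4g  e_tri=%.4g  g=%.3f  rho=%.3f\n",
                x$e_bin, x$e_tri, x$g, x$rho))
  }
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' Two-stage inference for a batch of feature vectors
#'
#' @param X N x L matrix of preprocessed features (or a single vector).
#' @param model A trained `sers_model`.
#' @param prototypes Prototype matrix from [build_prototypes()].
#' @param cfg An [inference_config()].
#' @return A tibble with one row per spectrum: `S_bin`, `e_bin`, `e_tri`,
#'   `g`, `rho`, `decision`.
#' @export
infer_batch <- function(X, model, prototypes, cfg = inference_config()) {
  X <- as_feature_rows(X, model$config$input_length)
  P <- component_probabilities(X, model)
  purrr::map_dfr(seq_len(nrow(X)), function(i) {
    r <- infer_from_probs(X[i, ], P[i, ], prototypes, cfg)
    tibble(
      S_bin = r$S_bin, e_bin = r$e_bin, e_tri = r$e_tri,
      g = r$g, rho = r$rho, decision = r$decision
    )
  })
}
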