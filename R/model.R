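#' Model configuration for the dual-branch spectral network
#'
#' The shared encoder is a 1-D residual convolutional network: an initial
#' convolutional block (conv + batch norm + ReLU + max-pool), one basic
#' residual block per stage with stride-2 transitions between stages,
#' global average pooling and a linear projection to the embedding. Two
#' parallel heads read the embedding: a large-margin cosine
#' classification head over the pure classes and a component-evidence
#' head whose scores are mapped to per-component probabilities by a
#' sigmoid.
#'
#' @param profile `"default"` (stem 32 channels, stages 32/64/128/256,
#'   embedding 128) or `"ci"`, a reduced configuration (stem 16, stages
#'   16/32/64, embedding 64) sized for quick CPU runs.
#' @param embed_dim Embedding dimension d.
#' @param stem_channels,stem_kernel,stem_stride Initial conv block.
#' @param stage_channels Channels of the residual stages (one basic block
#'   each; stride 2 between stages).
#' @param margin Cosine margin m subtracted from the target-class cosine
#'   during training (default 0.35).
#' @param s_cls,s_evi Classification and evidence scaling factors
#'   (default 16.0 each).
#' @param evidence_clip Clipping threshold c of the evidence
#'   regularizer (default 6.0).
#' @param n_components Number of pure components K (default 3).
#' @param evidence_head `"cosine"` (default: scaled cosine scores, so
#'   `|u_k| <= s_evi`) or `"linear"` (plain affine layer).
#' @param input_length Expected feature-vector length L (default 2048).
#' @return A list of class `sers_model_config`.
#' @export
model_config <- function(profile = c("default", "ci"),
                         embed_dim = NULL, stem_channels = NULL,
                         stem_kernel = 7L, stem_stride = 2L,
                         stage_channels = NULL,
                         margin = 0.35, s_cls = 16.0, s_evi = 16.0,
                         evidence_clip = 6.0, n_components = 3L,
                         evidence_head = c("cosine", "linear"),
                         input_length = 2048L) {
  profile <- match.arg(profile)
  evidence_head <- match.arg(evidence_head)
  if (profile == "default") {
    embed_dim <- embed_dim %||% 128L
    stem_channels <- stem_channels %||% 32L
    stage_channels <- stage_channels %||% c(32L, 64L, 128L, 256L)
  } else {
    embed_dim <- embed_dim %||% 64L
    stem_channels <- stem_channels %||% 16L
    stage_channels <- stage_channels %||% c(16L, 32L, 64L)
  }
  if (margin < 0 || margin >= 1) abort("margin must lie in [0, 1)")
  if (s_cls <= 0 || s_evi <= 0) abort("scaling factors must be > 0")
  if (evidence_clip <= 0) abort("evidence_clip must be > 0")
  if (n_components < 2) abort("n_components must be >= 2")
  structure(
    list(
      profile = profile, embed_dim = as.integer(embed_dim),
      stem_channels = as.integer(stem_channels),
      stem_kernel = as.integer(stem_kernel),
      stem_stride = as.integer(stem_stride),
      stage_channels = as.integer(stage_channels),
      margin = margin, s_cls = s_cls, s_evi = s_evi,
      evidence_clip = evidence_clip,
      n_components = as.integer(n_components),
      evidence_head = evidence_head,
      input_length = as.integer(input_length)
    ),
    class = "sers_model_config"
  )
}

stage_stride <- function(i) if (i == 1L) 1L else 2L

#' Initialise the dual-branch model
#'
#' He-normal initialisation for convolutional and projection weights,
#' unit-scale batch-norm, and small random head directions; all draws
#' come from the given seed.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A list of class `sers_model` with `config`, `params` and
#'   `buffers` (batch-norm running statistics).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  withr::with_seed(sub_seed(seed, "init"), {
    p <- list()
    b <- list()
    c0 <- config$stem_channels
    p$stem_W <- array(
      rnorm(config$stem_kernel * c0, sd = sqrt(2 / config$stem_kernel)),
      dim = c(config$stem_kernel, 1L, c0)
    )
    p$stem_bn_g <- rep(1, c0); p$stem_bn_b <- rep(0, c0)
    b$stem_bn_mean <- rep(0, c0); b$stem_bn_var <- rep(1, c0)
    cin <- c0
    for (i in seq_along(config$stage_channels)) {
      co <- config$stage_channels[i]
      nm <- function(x) paste0("st", i, "_", x)
      p[[nm("W1")]] <- array(
        rnorm(3 * cin * co, sd = sqrt(2 / (3 * cin))), dim = c(3L, cin, co)
      )
      p[[nm("bn1_g")]] <- rep(1, co); p[[nm("bn1_b")]] <- rep(0, co)
      b[[nm("bn1_mean")]] <- rep(0, co); b[[nm("bn1_var")]] <- rep(1, co)
      p[[nm("W2")]] <- array(
        rnorm(3 * co * co, sd = sqrt(2 / (3 * co))), dim = c(3L, co, co)
      )
      p[[nm("bn2_g")]] <- rep(1, co); p[[nm("bn2_b")]] <- rep(0, co)
      b[[nm("bn2_mean")]] <- rep(0, co); b[[nm("bn2_var")]] <- rep(1, co)
      if (stage_stride(i) != 1L || cin != co) {
        p[[nm("Wd")]] <- array(
          rnorm(cin * co, sd = sqrt(2 / cin)), dim = c(1L, cin, co)
        )
        p[[nm("bnd_g")]] <- rep(1, co); p[[nm("bnd_b")]] <- rep(0, co)
        b[[nm("bnd_mean")]] <- rep(0, co); b[[nm("bnd_var")]] <- rep(1, co)
      }
      cin <- co
    }
    d <- config$embed_dim
    p$proj_W <- matrix(rnorm(cin * d, sd = sqrt(2 / cin)), cin, d)
    p$proj_b <- rep(0, d)
    K <- config$n_components
    p$cls_W <- matrix(rnorm(d * K, sd = 1 / sqrt(d)), d, K)
    p$evi_W <- matrix(rnorm(d * K, sd = 1 / sqrt(d)), d, K)
    if (config$evidence_head == "linear") p$evi_b <- rep(0, K)
  })
  structure(list(config = config, params = p, buffers = b),
            class = "sers_model")
}

#' @export
print.sers_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<sers_model> profile=%s  stages=%s  d=%d  params=%d\n",
    x$config$profile, paste(x$config$stage_channels, collapse = "/"),
    x$config$embed_dim, n_par
  ))
  invisible(x)
}

# Full forward pass. X is an N x L feature matrix. Returns the embedding
# plus (optionally) every intermediate cache needed for the backward
# pass and Grad-CAM, and updated batch-norm buffers when training.
model_forward <- function(model, X, training = FALSE,
                          keep_cache = TRUE) {
  cfg <- model$config; p <- model$params; b <- model$buffers
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != cfg$input_length) {
    abort(sprintf("input length %d does not match model input length %d",
                  ncol(X), cfg$input_length))
  }
  N <- nrow(X); L <- ncol(X)
  A <- matrix(as.vector(t(X)), ncol = 1L)
  shape <- c(N, L)
  cache <- list()

  run_bn <- function(Y, prefix) {
    bn <- bn_fwd(Y, p[[paste0(prefix, "_g")]], p[[paste0(prefix, "_b")]],
                 b[[paste0(prefix, "_mean")]], b[[paste0(prefix, "_var")]],
                 training)
    if (training) {
      b[[paste0(prefix, "_mean")]] <<- bn$rmean
      b[[paste0(prefix, "_var")]] <<- bn$rvar
    }
    bn
  }

  cv <- conv_fwd(A, shape, p$stem_W, cfg$stem_stride, cfg$stem_kernel %/% 2L)
  bn <- run_bn(cv$Y, "stem_bn")
  rl <- relu_fwd(bn$Y)
  pool <- maxpool_fwd(rl$Y, cv$shape)
  if (keep_cache) {
    cache$stem <- list(A = A, shape = shape, cv = cv, bn = bn, rl = rl,
                       pool = pool)
  }
  A <- pool$Y; shape <- pool$shape

  for (i in seq_along(cfg$stage_channels)) {
    nm <- function(x) paste0("st", i, "_", x)
    s <- stage_stride(i)
    cin <- ncol(A); co <- cfg$stage_channels[i]
    c1 <- conv_fwd(A, shape, p[[nm("W1")]], s, 1L)
    b1 <- run_bn(c1$Y, nm("bn1"))
    r1 <- relu_fwd(b1$Y)
    c2 <- conv_fwd(r1$Y, c1$shape, p[[nm("W2")]], 1L, 1L)
    b2 <- run_bn(c2$Y, nm("bn2"))
    if (!is.null(p[[nm("Wd")]])) {
      cd <- conv_fwd(A, shape, p[[nm("Wd")]], s, 0L)
      bd <- run_bn(cd$Y, nm("bnd"))
      short <- bd$Y
    } else {
      cd <- NULL; bd <- NULL
      short <- A
    }
    sum_out <- b2$Y + short
    r2 <- relu_fwd(sum_out)
    if (keep_cache) {
      cache[[paste0("st", i)]] <- list(
        A_in = A, shape_in = shape, c1 = c1, b1 = b1, r1 = r1,
        c2 = c2, b2 = b2, cd = cd, bd = bd, r2 = r2
      )
    }
    A <- r2$Y; shape <- c1$shape
  }

  gap <- gap_fwd(A, shape)
  f <- col_op(gap$Y %*% p$proj_W, p$proj_b, `+`)
  if (keep_cache) {
    cache$gap <- gap
    cache$G <- gap$Y
    cache$last_act <- A
    cache$last_shape <- shape
  } else {
    cache <- NULL
  }
  list(f = f, cache = cache, buffers = b)
}

# Backward from the embedding gradient df down to every parameter.
model_backward <- function(model, cache, df) {
  cfg <- model$config; p <- model$params
  g <- list()
  g$proj_W <- crossprod(cache$G, df)
  g$proj_b <- colSums(df)
  dG <- df %*% t(p$proj_W)
  dA <- gap_bwd(dG, cache$gap)

  for (i in rev(seq_along(cfg$stage_channels))) {
    nm <- function(x) paste0("st", i, "_", x)
    cc <- cache[[paste0("st", i)]]
    dsum <- dA * cc$r2$mask
    db2 <- bn_bwd(dsum, cc$b2, p[[nm("bn2_g")]])
    g[[nm("bn2_g")]] <- db2$dgamma; g[[nm("bn2_b")]] <- db2$dbeta
    dc2 <- conv_bwd(db2$dX, cc$c2, p[[nm("W2")]], nrow(cc$r1$Y))
    g[[nm("W2")]] <- dc2$dW
    dr1 <- dc2$dX * cc$r1$mask
    db1 <- bn_bwd(dr1, cc$b1, p[[nm("bn1_g")]])
    g[[nm("bn1_g")]] <- db1$dgamma; g[[nm("bn1_b")]] <- db1$dbeta
    dc1 <- conv_bwd(db1$dX, cc$c1, p[[nm("W1")]], nrow(cc$A_in))
    g[[nm("W1")]] <- dc1$dW
    dA_in <- dc1$dX
    if (!is.null(cc$cd)) {
      dbd <- bn_bwd(dsum, cc$bd, p[[nm("bnd_g")]])
      g[[nm("bnd_g")]] <- dbd$dgamma; g[[nm("bnd_b")]] <- dbd$dbeta
      dcd <- conv_bwd(dbd$dX, cc$cd, p[[nm("Wd")]], nrow(cc$A_in))
      g[[nm("Wd")]] <- dcd$dW
      dA_in <- dA_in + dcd$dX
    } else {
      dA_in <- dA_in + dsum
    }
    dA <- dA_in
  }

  st <- cache$stem
  dpool <- maxpool_bwd(dA, st$pool, nrow(st$rl$Y), ncol(st$rl$Y))
  drl <- dpool * st$rl$mask
  dbn <- bn_bwd(drl, st$bn, p$stem_bn_g)
  g$stem_bn_g <- dbn$dgamma; g$stem_bn_b <- dbn$dbeta
  dcv <- conv_bwd(dbn$dX, st$cv, p$stem_W, nrow(st$A))
  g$stem_W <- dcv$dW
  g
}

#' Encode spectra into embeddings
#'
#' Runs the shared encoder in evaluation mode (frozen batch-norm
#' statistics); deterministic for fixed weights and input.
#'
#' @param x A feature spectrum tibble, a numeric length-L vector, or an
#'   N x L matrix of feature vectors.
#' @param model A `sers_model`.
#' @param chunk_size Rows encoded per forward pass (bounds memory).
#' @return An N x d embedding matrix (a 1 x d matrix for single inputs).
#' @export
encode <- function(x, model, chunk_size = 64L) {
  X <- as_feature_rows(x, model$config$input_length)
  if (nrow(X) <= chunk_size) {
    return(model_forward(model, X, training = FALSE, keep_cache = FALSE)$f)
  }
  starts <- seq(1L, nrow(X), by = chunk_size)
  do.call(rbind, lapply(starts, function(i) {
    j <- min(i + chunk_size - 1L, nrow(X))
    model_forward(model, X[i:j, , drop = FALSE], training = FALSE,
                  keep_cache = FALSE)$f
  }))
}

as_feature_rows <- function(x, L) {
  if (is.data.frame(x)) x <- x$intensity
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != L) {
    abort(sprintf("feature length %d does not match model input %d",
                  ncol(x), L))
  }
  x
}

#' Large-margin cosine classification logits
#'
#' Computes `s_cls * cos(theta_k)` between the L2-normalised embedding
#' and class weight directions. When `label` is supplied (training), the
#' margin m is subtracted from the target-class cosine before scaling.
#'
#' @param f Embedding matrix (N x d) or length-d vector.
#' @param model A `sers_model`.
#' @param label Optional integer class labels in `1..K` (length N).
#' @return N x K logit matrix.
#' @export
classify_cosine <- function(f, model, label = NULL) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  if (any(sqrt(rowSums(f^2)) < 1e-10)) abort("zero-norm embedding")
  hc <- cos_head_fwd(f, model$params$cls_W)
  logits <- hc$cos
  if (!is.null(label)) {
    if (any(label < 1 | label > model$config$n_components)) {
      abort("label out of range")
    }
    idx <- cbind(seq_len(nrow(logits)), label)
    logits[idx] <- logits[idx] - model$config$margin
  }
  model$config$s_cls * logits
}

#' Component-evidence scores and probabilities
#'
#' The evidence head maps the embedding to a K-vector of evidence scores
#' `u` (scaled cosine by default, so `|u_k| <= s_evi`) and converts them
#' to per-component probabilities `p_k = 1 / (1 + exp(-u_k))`.
#'
#' @param f Embedding matrix (N x d) or length-d vector.
#' @param model A `sers_model`.
#' @return A list with matrices `u` and `p` (both N x K).
#' @export
evidence_forward <- function(f, model) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  if (any(sqrt(rowSums(f^2)) < 1e-10)) abort("zero-norm embedding")
  if (model$config$evidence_head == "cosine") {
    u <- model$config$s_evi * cos_head_fwd(f, model$params$evi_W)$cos
  } else {
    u <- col_op(f %*% model$params$evi_W, model$params$evi_b, `+`)
  }
  colnames(u) <- .components[seq_len(model$config$n_components)]
  list(u = u, p = 1 / (1 + exp(-u)))
}

#' Component probabilities for a batch of feature vectors
#'
#' Convenience wrapper: encode, then apply the evidence head.
#'
#' @inheritParams encode
#' @return N x K matrix of component probabilities.
#' @export
component_probabilities <- function(x, model) {
  evidence_forward(encode(x, model), model)$p
}

#' Save a model (weights + configuration sidecar)
#'
#' Weights and batch-norm buffers are serialised natively; the model
#' configuration is additionally echoed to a JSON sidecar for
#' inspection.
#'
#' @param model A `sers_model`.
#' @param path Output file (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    unclass(model$config),
    paste0(sub("\\.rds$", "", path), "_config.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path File written by [save_model()].
#' @return A `sers_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sers_model")) abort("not a saved sers_model")
  model
}
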