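#' Training configuration
#'
#' AdamW optimisation of the joint objective (classification +
#' `lambda_evi` * evidence + `lambda_reg` * regularisation) on pure
#' spectra only, with a cosine-annealed learning rate and mixture-aware
#' checkpoint selection.
#'
#' @param profile `"default"` (3000 steps) or `"ci"` (800 steps, sized
#'   for quick CPU runs).
#' @param lr Initial learning rate (default 1e-3).
#' @param lr_min Final learning rate of the cosine schedule (default 1e-5).
#' @param weight_decay Decoupled weight decay (default 1e-4).
#' @param batch_size Batch size (default 32).
#' @param total_steps Number of optimisation steps.
#' @param lambda_evi,lambda_reg Loss weights (defaults 1.0 and 0.01).
#' @param warmup_steps Checkpoint tracking starts after this many steps
#'   (default 500).
#' @param pure_val_floor Minimum pure-spectrum validation accuracy for a
#'   checkpoint to be eligible (default 0.95).
#' @param eval_every Evaluation/checkpoint cadence in steps (default 50).
#' @param seed Seed for batch sampling.
#' @return A list of class `sers_train_config`.
#' @export
train_config <- function(profile = c("default", "ci"),
                         lr = 1e-3, lr_min = 1e-5, weight_decay = 1e-4,
                         batch_size = 32L, total_steps = NULL,
                         lambda_evi = 1.0, lambda_reg = 0.01,
                         warmup_steps = 500L, pure_val_floor = 0.95,
                         eval_every = 50L, seed = 1L) {
  profile <- match.arg(profile)
  total_steps <- total_steps %||% if (profile == "default") 3000L else 800L
  if (lr_min >= lr) abort("lr_min must be < lr")
  if (warmup_steps >= total_steps) abort("warmup_steps must be < total_steps")
  if (pure_val_floor <= 0 || pure_val_floor > 1) {
    abort("pure_val_floor must lie in (0, 1]")
  }
  structure(
    list(
      profile = profile, lr = lr, lr_min = lr_min,
      weight_decay = weight_decay, batch_size = as.integer(batch_size),
      total_steps = as.integer(total_steps),
      lambda_evi = lambda_evi, lambda_reg = lambda_reg,
      warmup_steps = as.integer(warmup_steps),
      pure_val_floor = pure_val_floor,
      eval_every = as.integer(eval_every), seed = as.integer(seed)
    ),
    class = "sers_train_config"
  )
}

#' Cosine-annealed learning rate at a given step
#'
#' `lr_min + 0.5 * (lr - lr_min) * (1 + cos(pi * step / total_steps))`;
#' equals `lr_min` exactly at `step = total_steps`.
#'
#' @param step Step number (0-based fractions allowed).
#' @param cfg A [train_config()].
#' @return Learning rate.
#' @export
lr_at_step <- function(step, cfg) {
  cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) *
    (1 + cos(pi * step / cfg$total_steps))
}

#' Cross-entropy loss on classification logits
#'
#' Mean cross-entropy over the batch, computed from margin-adjusted
#' cosine logits via a numerically stable log-sum-exp.
#'
#' @param logits N x K logit matrix.
#' @param y Integer labels in `1..K`.
#' @return Nonnegative scalar.
#' @export
loss_classification <- function(logits, y) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  K <- ncol(logits)
  if (any(y < 1 | y > K)) abort("label out of range")
  mx <- rowmax(logits)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[cbind(seq_len(nrow(logits)), y)])
}

#' Binary cross-entropy evidence loss
#'
#' Mean over components (and batch) of
#' `-(z * log p + (1 - z) * log(1 - p))` with probabilities clamped away
#' from 0 and 1.
#'
#' @param p Probability matrix/vector in (0, 1).
#' @param z Binary component indicators of the same shape.
#' @param clamp Clamping constant (default 1e-12).
#' @return Nonnegative scalar.
#' @export
loss_evidence <- function(p, z, clamp = 1e-12) {
  p <- pmin(pmax(p, clamp), 1 - clamp)
  mean(-(z * log(p) + (1 - z) * log(1 - p)))
}

#' Clipping-based evidence regularisation
#'
#' Mean of `max(0, |u_k| - c)^2` over the evidence scores; zero whenever
#' every score lies inside the clip interval.
#'
#' @param u Evidence score matrix/vector.
#' @param c Clipping threshold (> 0).
#' @return Nonnegative scalar.
#' @export
loss_regularization <- function(u, c = 6.0) {
  if (c <= 0) abort("clipping threshold must be > 0")
  mean(pmax(abs(u) - c, 0)^2)
}

#' Combine the three loss terms
#'
#' @param L_cls,L_evi,L_reg Scalar loss terms.
#' @param lambda_evi,lambda_reg Weights (defaults 1.0, 0.01).
#' @return A list with the three terms, the weights and `total`.
#' @export
loss_breakdown <- function(L_cls, L_evi, L_reg,
                           lambda_evi = 1.0, lambda_reg = 0.01) {
  list(
    L_cls = L_cls, L_evi = L_evi, L_reg = L_reg,
    lambda_evi = lambda_evi, lambda_reg = lambda_reg,
    total = L_cls + lambda_evi * L_evi + lambda_reg * L_reg
  )
}

adamw_update <- function(params, grads, state, lr, wd,
                         b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gr * 0
      state$v[[nm]] <- gr * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gr
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * ((state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps) +
              wd * params[[nm]])
  }
  list(params = params, state = state)
}

# Stratified class-balanced batch sampling.
sample_batch <- function(labels_by_class, batch_size) {
  K <- length(labels_by_class)
  per <- rep(batch_size %/% K, K)
  extra <- batch_size - sum(per)
  if (extra > 0) {
    bump <- sample.int(K, extra)
    per[bump] <- per[bump] + 1
  }
  unlist(purrr::map2(labels_by_class, per, function(ix, n) {
    ix[sample.int(length(ix), n, replace = n > length(ix))]
  }), use.names = FALSE)
}

#' Train the dual-branch model on pure spectra only
#'
#' Joint end-to-end AdamW optimisation of the classification, evidence
#' and regularisation terms on pure-compound spectra. Mixture categories
#' in the training labels raise an error (protocol guard). At every
#' `eval_every` steps the pure-spectrum validation accuracy
#' (classification branch) and the seven-category validation accuracy
#' (unified two-stage inference) are recorded together with a checkpoint
#' of the weights; loss values are averaged over the evaluation window.
#'
#' @param model A `sers_model` from [build_model()].
#' @param x_train N x L matrix of preprocessed pure-spectrum features.
#' @param y_train Component labels for the training rows (`"A"/"B"/"C"`).
#' @param x_val_pure,y_val_pure Pure-spectrum validation features/labels.
#' @param x_val_seven,cat_val_seven Seven-category validation features
#'   and category labels (used only for checkpoint selection).
#' @param prototypes Prototype matrix from [build_prototypes()] (used by
#'   the unified inference during validation).
#' @param cfg A [train_config()].
#' @param infer_cfg An [inference_config()]; candidate mode is forced to
#'   `"unified"` for seven-category validation.
#' @return A list of class `sers_fit`: `model` (final-step weights),
#'   `history` (tibble, one row per evaluation, with a `checkpoint`
#'   list-column), `config`.
#' @export
train <- function(model, x_train, y_train,
                  x_val_pure, y_val_pure,
                  x_val_seven, cat_val_seven,
                  prototypes, cfg = train_config(),
                  infer_cfg = inference_config()) {
  if (any(nchar(y_train) > 1)) {
    abort(paste0(
      "protocol violation: mixture category '",
      y_train[nchar(y_train) > 1][1],
      "' in the training data; training uses pure spectra only"
    ))
  }
  K <- model$config$n_components
  comp_levels <- .components[seq_len(K)]
  y_int <- match(y_train, comp_levels)
  if (anyNA(y_int)) abort("unknown component label in y_train")
  y_val_int <- match(y_val_pure, comp_levels)
  by_class <- split(seq_along(y_int), y_int)
  infer_cfg$candidate_mode <- "unified"

  p <- model$params
  state <- list(t = 0L, m = list(), v = list())
  history <- list()
  win <- c(cls = 0, evi = 0, reg = 0, n = 0)

  withr::with_seed(sub_seed(cfg$seed, "shuffle"), {
    for (step in seq_len(cfg$total_steps)) {
      lr <- lr_at_step(step, cfg)
      ix <- sample_batch(by_class, cfg$batch_size)
      X <- x_train[ix, , drop = FALSE]
      yb <- y_int[ix]
      N <- length(yb)

      model$params <- p
      fwd <- model_forward(model, X, training = TRUE)
      model$buffers <- fwd$buffers
      f <- fwd$f

      # classification branch (margin-adjusted cosine + cross-entropy)
      hc <- cos_head_fwd(f, p$cls_W)
      logits <- hc$cos
      idx <- cbind(seq_len(N), yb)
      logits[idx] <- logits[idx] - model$config$margin
      logits <- model$config$s_cls * logits
      onehot <- matrix(0, N, K)
      onehot[idx] <- 1
      L_cls <- loss_classification(logits, yb)
      soft <- exp(logits - rowmax(logits))
      soft <- soft / rowSums(soft)
      dcos_cls <- model$config$s_cls * (soft - onehot) / N
      hb_cls <- cos_head_bwd(dcos_cls, hc)

      # evidence branch (sigmoid BCE + clip regulariser)
      if (model$config$evidence_head == "cosine") {
        he <- cos_head_fwd(f, p$evi_W)
        u <- model$config$s_evi * he$cos
      } else {
        u <- col_op(f %*% p$evi_W, p$evi_b, `+`)
      }
      psig <- 1 / (1 + exp(-u))
      L_evi <- loss_evidence(psig, onehot)
      L_reg <- loss_regularization(u, model$config$evidence_clip)
      du <- cfg$lambda_evi * (psig - onehot) / (N * K) +
        cfg$lambda_reg * 2 * pmax(abs(u) - model$config$evidence_clip, 0) *
          sign(u) / (N * K)
      if (model$config$evidence_head == "cosine") {
        hb_evi <- cos_head_bwd(model$config$s_evi * du, he)
        df_evi <- hb_evi$df
        dW_evi <- hb_evi$dW
        db_evi <- NULL
      } else {
        df_evi <- du %*% t(p$evi_W)
        dW_evi <- crossprod(f, du)
        db_evi <- colSums(du)
      }

      grads <- model_backward(model, fwd$cache, hb_cls$df + df_evi)
      grads$cls_W <- hb_cls$dW
      grads$evi_W <- dW_evi
      if (!is.null(db_evi)) grads$evi_b <- db_evi

      upd <- adamw_update(p, grads, state, lr, cfg$weight_decay)
      p <- upd$params
      state <- upd$state

      win["cls"] <- win["cls"] + L_cls
      win["evi"] <- win["evi"] + L_evi
      win["reg"] <- win["reg"] + L_reg
      win["n"] <- win["n"] + 1

      if (step %% cfg$eval_every == 0 || step == cfg$total_steps) {
        model$params <- p
        f_val <- model_forward(model, x_val_pure, training = FALSE)$f
        pred_pure <- max.col(classify_cosine(f_val, model), "first")
        pure_acc <- mean(pred_pure == y_val_int)
        pred7 <- infer_batch(x_val_seven, model, prototypes, infer_cfg)
        seven_acc <- mean(pred7$decision == cat_val_seven)
        lb <- loss_breakdown(
          win["cls"] / win["n"], win["evi"] / win["n"], win["reg"] / win["n"],
          cfg$lambda_evi, cfg$lambda_reg
        )
        history[[length(history) + 1]] <- tibble(
          step = step, lr = lr,
          L_cls = unname(lb$L_cls), L_evi = unname(lb$L_evi),
          L_reg = unname(lb$L_reg), total = unname(lb$total),
          pure_val_acc = pure_acc, seven_cat_val_acc = seven_acc,
          checkpoint = list(list(params = p, buffers = model$buffers))
        )
        win <- c(cls = 0, evi = 0, reg = 0, n = 0)
      }
    }
  })
  model$params <- p
  structure(
    list(model = model, history = dplyr::bind_rows(history), config = cfg),
    class = "sers_fit"
  )
}

#' Select the checkpoint for deployment
#'
#' Among evaluation records recorded after `warmup_steps` whose
#' pure-spectrum validation accuracy is at least `pure_val_floor`,
#' returns the one with the highest seven-category validation accuracy;
#' ties resolve to the latest step (most annealed weights).
#'
#' @param history Training history tibble from [train()].
#' @param cfg The [train_config()] used.
#' @return A one-row tibble (including the `checkpoint` list-column).
#' @export
select_checkpoint <- function(history, cfg = train_config()) {
  if (nrow(history) == 0) abort("empty training history")
  elig <- dplyr::filter(
    history,
    .data$step > cfg$warmup_steps,
    .data$pure_val_acc >= cfg$pure_val_floor
  )
  if (nrow(elig) == 0) {
    abort(paste0(
      "no eligible checkpoint: no evaluation after step ", cfg$warmup_steps,
      " reached pure validation accuracy ", cfg$pure_val_floor,
      "; extend training or lower the floor"
    ))
  }
  best <- max(elig$seven_cat_val_acc)
  cand <- dplyr::filter(elig, .data$seven_cat_val_acc == best)
  cand[which.max(cand$step), ]
}

#' Load checkpoint weights into a model
#'
#' @param model A `sers_model`.
#' @param record A one-row history tibble from [select_checkpoint()], or
#'   a checkpoint list with `params` and `buffers`.
#' @return The model with restored weights and batch-norm statistics.
#' @export
restore_checkpoint <- function(model, record) {
  ckpt <- if (is.data.frame(record)) record$checkpoint[[1]] else record
  model$params <- ckpt$params
  model$buffers <- ckpt$buffers
  model
}
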