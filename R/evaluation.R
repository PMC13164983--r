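#' Confusion matrix over an ordered category list
#'
#' Rows are true categories, columns predicted categories.
#'
#' @param y_true,y_pred Equal-length character vectors of category
#'   labels.
#' @param categories Ordered category list; defaults to the categories
#'   present in `y_true`/`y_pred`, in the canonical A, B, C, AB, AC, BC,
#'   ABC order.
#' @return An integer matrix of class `sers_confusion`.
#' @export
confusion <- function(y_true, y_pred, categories = NULL) {
  if (length(y_true) == 0) abort("empty input")
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length")
  }
  categories <- categories %||%
    intersect(.categories, union(y_true, y_pred))
  bad <- setdiff(union(y_true, y_pred), categories)
  if (length(bad)) abort(sprintf("unknown category '%s'", bad[1]))
  f_true <- factor(y_true, levels = categories)
  f_pred <- factor(y_pred, levels = categories)
  cm <- table(true = f_true, predicted = f_pred)
  structure(unclass(as.matrix(cm)), class = "sers_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision (`diag / column sum`), recall (`diag / row sum`)
#' and F1, overall accuracy (`trace / total`), and unweighted macro
#' averages. A zero denominator yields 0 with a warning.
#'
#' @param cm Square confusion matrix (rows true, columns predicted).
#' @return A list of class `sers_metrics`: `accuracy`, `per_class`
#'   (tibble: class, precision, recall, f1), `macro_precision`,
#'   `macro_recall`, `macro_f1`.
#' @export
metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (sum(cm) == 0) abort("all-zero confusion matrix")
  if (nrow(cm) != ncol(cm)) abort("confusion matrix must be square")
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0)) {
      warn(sprintf("zero denominator in %s; reporting 0", what))
    }
    out
  }
  d <- diag(cm)
  precision <- safe_div(d, colSums(cm), "precision")
  recall <- safe_div(d, rowSums(cm), "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(
    list(
      accuracy = sum(d) / sum(cm),
      per_class = tibble(
        class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
        precision = unname(precision), recall = unname(recall),
        f1 = unname(f1)
      ),
      macro_precision = mean(precision),
      macro_recall = mean(recall),
      macro_f1 = mean(f1)
    ),
    class = "sers_metrics"
  )
}

#' @export
print.sers_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("Overall accuracy: %.*f\n", digits, x$accuracy))
  cat(sprintf("Macro precision / recall / F1: %.*f / %.*f / %.*f\n",
              digits, x$macro_precision, digits, x$macro_recall,
              digits, x$macro_f1))
  print(dplyr::mutate(
    x$per_class,
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits))
  ))
  invisible(x)
}

#' One-dimensional Grad-CAM attribution
#'
#' Back-propagates the inference-time class score (scaled cosine logit)
#' of `target_class` to the output of the final convolutional stage of
#' the shared encoder, weights each channel by its spatially averaged
#' gradient, applies a ReLU to the weighted activation sum, linearly
#' upsamples the map to the input length, and normalises it to a maximum
#' of 1. An all-nonpositive map is returned as all zeros with a warning.
#'
#' @param model A `sers_model`.
#' @param x Feature spectrum tibble or length-L feature vector.
#' @param target_class Component label (`"A"/"B"/"C"`) or index.
#' @return A tibble with columns `position` (1..L) and `attribution` in
#'   `[0, 1]`; if `x` was a spectrum tibble, also `wavenumber`.
#' @export
grad_cam <- function(model, x, target_class) {
  wn <- if (is.data.frame(x)) x$wavenumber else NULL
  xv <- if (is.data.frame(x)) x$intensity else as.numeric(x)
  if (is.character(target_class)) {
    target_class <- match(target_class, .components)
  }
  K <- model$config$n_components
  if (is.na(target_class) || target_class < 1 || target_class > K) {
    abort("unknown target class")
  }
  fwd <- model_forward(model, matrix(xv, nrow = 1), training = FALSE)
  hc <- cos_head_fwd(fwd$f, model$params$cls_W)
  dcos <- matrix(0, 1, K)
  dcos[1, target_class] <- model$config$s_cls
  df <- cos_head_bwd(dcos, hc)$df
  # gradient wrt the final-stage activation: through the linear
  # projection and global average pooling (constant over positions)
  dG <- df %*% t(model$params$proj_W)
  L_last <- fwd$cache$last_shape[2]
  w <- as.numeric(dG) / L_last
  cam <- pmax(as.vector(fwd$cache$last_act %*% w), 0)
  L <- model$config$input_length
  up <- approx(seq_along(cam), cam, xout = seq(1, length(cam),
                                               length.out = L))$y
  if (max(up) <= 0) {
    warn("all-nonpositive Grad-CAM map; returning zeros")
    up <- rep(0, L)
  } else {
    up <- up / max(up)
  }
  out <- tibble(position = seq_len(L), attribution = up)
  if (!is.null(wn)) out$wavenumber <- wn
  out
}
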