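#' Tidy a confusion matrix into long format
#'
#' @param x A `sers_confusion`.
#' @param ... Unused.
#' @return A tibble with columns `true`, `predicted`, `n`.
#' @export
tidy.sers_confusion <- function(x, ...) {
  m <- unclass(x)
  df <- as.data.frame.table(m, responseName = "n")
  names(df) <- c("true", "predicted", "n")
  as_tibble(df)
}

#' Tidy per-class metrics
#'
#' @param x A `sers_metrics`.
#' @param ... Unused.
#' @return Per-class tibble with class, precision, recall, f1.
#' @export
tidy.sers_metrics <- function(x, ...) x$per_class

#' One-row metrics summary
#'
#' @param x A `sers_metrics`.
#' @param ... Unused.
#' @return A one-row tibble: accuracy and macro precision/recall/F1.
#' @export
glance.sers_metrics <- function(x, ...) {
  tibble(
    accuracy = x$accuracy, macro_precision = x$macro_precision,
    macro_recall = x$macro_recall, macro_f1 = x$macro_f1
  )
}

#' Tidy a training history
#'
#' @param x A `sers_fit`.
#' @param ... Unused.
#' @return The history tibble without the checkpoint column.
#' @export
tidy.sers_fit <- function(x, ...) {
  dplyr::select(x$history, -"checkpoint")
}

#' One-row training-run summary
#'
#' @param x A `sers_fit`.
#' @param ... Unused.
#' @return A one-row tibble: steps, final losses and accuracies.
#' @export
glance.sers_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(
    total_steps = x$config$total_steps,
    final_L_cls = last$L_cls, final_L_evi = last$L_evi,
    final_L_reg = last$L_reg, final_total = last$total,
    final_pure_val_acc = last$pure_val_acc,
    final_seven_cat_val_acc = last$seven_cat_val_acc
  )
}

#' One-row pipeline-run summary
#'
#' @param x A `sers_run`.
#' @param ... Unused.
#' @return A one-row tibble with the headline test metrics.
#' @export
glance.sers_run <- function(x, ...) {
  tibble(
    selected_step = x$checkpoint$step,
    pure_test_accuracy = x$metrics_pure$accuracy,
    mixture_test_accuracy = x$metrics_mixture$accuracy,
    mixture_macro_precision = x$metrics_mixture$macro_precision,
    mixture_macro_recall = x$metrics_mixture$macro_recall,
    mixture_macro_f1 = x$metrics_mixture$macro_f1,
    seven_cat_accuracy = x$seven_cat_accuracy
  )
}
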