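#' Assemble a full run configuration
#'
#' Bundles the generator, preprocessing, model, training and inference
#' configurations with a single master seed that fans out into named
#' sub-seeds (data, init, train), so every stage is independently
#' reproducible.
#'
#' @param seed Master seed.
#' @param profile `"ci"` (reduced network and step count; quick CPU runs)
#'   or `"default"` (full-size network, 3000 steps).
#' @param out_dir Optional run directory; artifacts are written when set.
#' @param generator,preproc,model,train,inference Optional configuration
#'   overrides; defaults are derived from `seed` and `profile`.
#' @param sizes Dataset split sizes (see [default_split_sizes()]).
#' @return A list of class `sers_run_config`.
#' @export
run_config <- function(seed = 1L, profile = c("ci", "default"),
                       out_dir = NULL,
                       generator = NULL, preproc = NULL, model = NULL,
                       train = NULL, inference = NULL,
                       sizes = default_split_sizes()) {
  profile <- match.arg(profile)
  # the ci profile shortens the feature vector to 512 points alongside
  # the smaller network; the default profile keeps the full 2048
  n_points <- if (profile == "ci") 512L else 2048L
  structure(
    list(
      seed = as.integer(seed), profile = profile, out_dir = out_dir,
      generator = generator %||%
        sers_generator_config(seed = sub_seed(seed, "data")),
      preproc = preproc %||% preproc_config(n_points = n_points),
      model = model %||%
        model_config(profile = profile, input_length = n_points),
      train = train %||%
        train_config(profile = profile, seed = sub_seed(seed, "train")),
      inference = inference %||% inference_config(),
      sizes = sizes
    ),
    class = "sers_run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full pipeline: simulate, preprocess, train, infer, evaluate
#'
#' Generates the synthetic dataset, preprocesses every spectrum, builds
#' prototypes from the pure training subset, trains the dual-branch model
#' on pure spectra only, selects a checkpoint under the mixture-aware
#' protocol, and evaluates on the test split: pure-spectrum
#' classification (classification branch), mixture recognition over
#' AB/AC/BC/ABC (pairs-only two-stage inference) and seven-category
#' recognition (unified inference). Fully reproducible from the
#' configuration.
#'
#' @param config A [run_config()].
#' @return A list of class `sers_run`: `fit`, `checkpoint` (selected
#'   history row), `model` (restored weights), `prototypes`,
#'   `metrics_pure`, `metrics_mixture` (`sers_metrics`),
#'   `seven_cat_accuracy`, `predictions` (test-split tibble), `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  dataset <- run_stage("simulate", generate_dataset(config$generator,
                                                    config$sizes,
                                                    dir = config$out_dir))
  prep <- run_stage("preprocess", preprocess_dataset(dataset,
                                                     config$preproc))
  man <- prep$manifest
  X <- prep$features
  is_pure <- nchar(man$category) == 1

  tr <- man$split == "train"
  protos <- run_stage(
    "prototypes",
    build_prototypes(X[tr, , drop = FALSE], man$category[tr])
  )

  va <- man$split == "val"
  va_pure <- va & is_pure
  model <- build_model(config$model, seed = sub_seed(config$seed, "init"))
  fit <- run_stage("train", train(
    model,
    X[tr, , drop = FALSE], man$category[tr],
    X[va_pure, , drop = FALSE], man$category[va_pure],
    X[va, , drop = FALSE], man$category[va],
    protos, config$train, config$inference
  ))
  ckpt <- run_stage("select", select_checkpoint(fit$history, config$train))
  best <- restore_checkpoint(fit$model, ckpt)

  te <- man$split == "test"
  te_pure <- te & is_pure
  te_mix <- te & !is_pure
  results <- run_stage("evaluate", {
    f_pure <- encode(X[te_pure, , drop = FALSE], best)
    pred_pure <- .components[max.col(classify_cosine(f_pure, best), "first")]
    cm_pure <- confusion(man$category[te_pure], pred_pure,
                         categories = .components)

    cfg_pairs <- config$inference
    cfg_pairs$candidate_mode <- "pairs_only"
    mix_pred <- infer_batch(X[te_mix, , drop = FALSE], best, protos,
                            cfg_pairs)
    cm_mix <- confusion(man$category[te_mix], mix_pred$decision,
                        categories = c("AB", "AC", "BC", "ABC"))

    cfg_uni <- config$inference
    cfg_uni$candidate_mode <- "unified"
    seven_pred <- infer_batch(X[te, , drop = FALSE], best, protos, cfg_uni)
    list(
      metrics_pure = metrics(cm_pure),
      metrics_mixture = metrics(cm_mix),
      cm_pure = cm_pure, cm_mix = cm_mix,
      seven_cat_accuracy = mean(seven_pred$decision == man$category[te]),
      predictions = dplyr::bind_cols(
        tibble(id = man$id[te], category = man$category[te]),
        seven_pred
      )
    )
  })

  run <- structure(
    c(list(fit = fit, checkpoint = ckpt, model = best,
           prototypes = protos, axis = prep$axis, config = config),
      results),
    class = "sers_run"
  )
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

metrics_as_list <- function(m) {
  list(
    accuracy = m$accuracy,
    macro_precision = m$macro_precision,
    macro_recall = m$macro_recall,
    macro_f1 = m$macro_f1,
    per_class = m$per_class
  )
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hist <- dplyr::select(run$fit$history, -"checkpoint")
  utils::write.csv(hist, file.path(dir, "history.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      pure = metrics_as_list(run$metrics_pure),
      mixture = metrics_as_list(run$metrics_mixture),
      seven_cat_accuracy = run$seven_cat_accuracy,
      selected_step = run$checkpoint$step
    ),
    file.path(dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  utils::write.csv(run$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  write_prototypes(run$prototypes, run$axis,
                   file.path(dir, "prototypes.csv"))
  save_model(run$model, file.path(dir, "model.rds"))
  cfg <- run$config
  yaml::write_yaml(
    list(
      seed = cfg$seed, profile = cfg$profile,
      preproc = unclass(cfg$preproc),
      model = unclass(cfg$model),
      train = unclass(cfg$train),
      inference = unclass(cfg$inference)
    ),
    file.path(dir, "run_config.yaml")
  )
  invisible(dir)
}

#' @export
print.sers_run <- function(x, ...) {
  cat("<sers_run>\n")
  cat(sprintf("  selected checkpoint: step %d (pure val %.4f, 7-cat val %.4f)\n",
              x$checkpoint$step, x$checkpoint$pure_val_acc,
              x$checkpoint$seven_cat_val_acc))
  cat(sprintf("  pure test accuracy:    %.4f\n", x$metrics_pure$accuracy))
  cat(sprintf("  mixture test accuracy: %.4f\n",
              x$metrics_mixture$accuracy))
  cat(sprintf("  7-category test accuracy: %.4f\n", x$seven_cat_accuracy))
  invisible(x)
}
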