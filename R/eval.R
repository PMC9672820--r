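# Evaluation: confusion matrices, stratified splitting, end-to-end pipeline
# orchestration (normalize -> decompose -> features -> network -> metrics).

#' Confusion matrix
#'
#' @param true,pred Integer label vectors of equal length, values in
#'   `0:(n_classes - 1)`.
#' @param n_classes Number of classes `K`; defaults to one more than the
#'   largest label seen.
#' @param class_names Optional character labels for the classes.
#' @return A `confusion_matrix`: list with `counts` (K x K integer matrix,
#'   rows = true class, cols = predicted), `class_names`, `accuracy`
#'   (trace / total) and `error_rate` (`1 - accuracy`).
#' @examples
#' confusion(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
confusion <- function(true, pred, n_classes = NULL, class_names = NULL) {
  stopifnot(length(true) == length(pred))
  if (is.null(n_classes)) n_classes <- max(true, pred) + 1L
  if (any(true < 0 | true >= n_classes | pred < 0 | pred >= n_classes)) {
    stop_memdbci("labels out of range 0:(n_classes - 1).",
                 "memdbci_invalid_spec")
  }
  if (is.null(class_names)) class_names <- as.character(0:(n_classes - 1L))
  lev <- 0:(n_classes - 1L)
  counts <- table(factor(true, levels = lev), factor(pred, levels = lev))
  counts <- matrix(as.integer(counts), n_classes, n_classes,
                   dimnames = list(true = class_names, pred = class_names))
  acc <- sum(diag(counts)) / sum(counts)
  structure(list(counts = counts, class_names = class_names,
                 accuracy = acc, error_rate = 1 - acc),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> accuracy", round(x$accuracy, 4),
      "| error rate", round(x$error_rate, 4), "\n")
  print(x$counts)
  invisible(x)
}

#' @describeIn confusion Long tibble: one row per (truth, prediction) cell.
#' @param x A `confusion_matrix`.
#' @param ... Ignored.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  K <- nrow(x$counts)
  tibble::tibble(
    truth = rep(x$class_names, times = K),
    prediction = rep(x$class_names, each = K),
    n = as.vector(x$counts)
  )
}

#' @describeIn confusion One-row summary: `n`, `accuracy`, `error_rate`.
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(n = sum(x$counts), accuracy = x$accuracy,
                 error_rate = x$error_rate)
}

#' @describeIn confusion Heatmap of the counts.
#' @param object A `confusion_matrix`.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev(object$class_names)) +
    ggplot2::labs(title = sprintf("accuracy %.1f%%", 100 * object$accuracy))
}

#' Stratified train/test split
#'
#' Samples a seeded train set per class, preserving class proportions within
#' one trial; every class keeps at least one trial on each side.
#'
#' @param labels Integer label vector.
#' @param train_frac Fraction of each class assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  withr::with_seed(seed, {
    idx_by_class <- split(seq_along(labels), labels)
    train <- unlist(lapply(idx_by_class, function(idx) {
      n_tr <- min(max(round(train_frac * length(idx)), 1L), length(idx) - 1L)
      sample(idx, n_tr)
    }), use.names = FALSE)
    list(train = sort(train),
         test = sort(setdiff(seq_along(labels), train)))
  })
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: signal normalization scope,
#' decomposition method and depth, feature parameters, network architecture
#' and training controls, and the evaluation split.
#'
#' @param normalization `"trial"`, `"recording"` or `"off"` (see
#'   [normalize_trials()]).
#' @inheritParams feature_config
#' @param hidden Hidden-layer sizes of the classifier.
#' @param tf Transfer-function tag(s).
#' @param alpha,error_goal,max_epochs,init_scale Training controls (see
#'   [net_train()]).
#' @param train_frac Stratified train fraction.
#' @param scale_features Standardize each feature column (z-score on
#'   training-set statistics, applied to both splits) before training.
#'   Energy features span orders of magnitude; plain steepest descent needs
#'   comparably scaled inputs.
#' @param seed Root seed; the split and weight-init seeds are derived from
#'   it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(normalization = c("trial", "recording", "off"),
                            method = c("memd", "emd", "raw"), n_imfs = 3,
                            fuzzy_m = 2, fuzzy_r = 0.2, fuzzy_n = 2,
                            ar_order = 7, aa_as_area = FALSE,
                            sd_tol = 0.2, max_sifts = 100,
                            hidden = 10, tf = "tansig", alpha = 0.05,
                            error_goal = 1e-2, max_epochs = 2000,
                            init_scale = 0.5, train_frac = 0.7,
                            scale_features = TRUE, seed = 1L) {
  structure(list(
    normalization = match.arg(normalization),
    features = feature_config(method = match.arg(method), n_imfs = n_imfs,
                              fuzzy_m = fuzzy_m, fuzzy_r = fuzzy_r,
                              fuzzy_n = fuzzy_n, ar_order = ar_order,
                              aa_as_area = aa_as_area, sd_tol = sd_tol,
                              max_sifts = max_sifts),
    hidden = hidden, tf = tf, alpha = alpha, error_goal = error_goal,
    max_epochs = max_epochs, init_scale = init_scale,
    train_frac = train_frac, scale_features = scale_features,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Normalize -> decompose (MEMD by default) -> extract per-IMF features ->
#' stratified split -> (optionally) standardize features on training
#' statistics -> train the backpropagation network on one-hot `{-1, +1}`
#' targets -> classify the held-out trials -> confusion matrix. All
#' randomness derives from `config$seed`, so the same configuration and
#' data reproduce the report exactly.
#'
#' @param trials A `trial_set` (see [gen_mi_trials()] and [read_trials()]).
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list with `confusion`, `accuracy`,
#'   `error_rate`, the trained `fit` (an `ffbpnn`), `split`, `features`
#'   (the full feature table), `config` and derived `seeds`.
#' @examples
#' \donttest{
#' ts <- gen_mi_trials(6, 2, n_channels = 1, duration = 1, seed = 2)
#' rep <- run_pipeline(ts, pipeline_config(n_imfs = 2, max_epochs = 300))
#' rep$accuracy
#' }
#' @export
run_pipeline <- function(trials, config = pipeline_config()) {
  stopifnot(inherits(trials, "trial_set"))
  n_classes <- length(unique(trials$labels))
  if (n_classes < 2 || min(table(trials$labels)) < 4) {
    stop_memdbci("need at least 2 classes with at least 4 trials each.",
                 "memdbci_invalid_spec")
  }
  seeds <- list(split = config$seed + 1L, init = config$seed + 2L)

  normalized <- normalize_trials(trials, scope = config$normalization)
  feats <- extract_feature_table(normalized, cfg = config$features)

  split <- stratified_split(feats$label, train_frac = config$train_frac,
                            seed = seeds$split)
  feat_cols <- setdiff(names(feats), c("trial_id", "label"))
  X <- as.matrix(feats[, feat_cols])
  if (config$scale_features) {
    mu <- colMeans(X[split$train, , drop = FALSE])
    sigma <- apply(X[split$train, , drop = FALSE], 2, sd)
    sigma[sigma == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  }
  targets <- one_hot(feats$label, n_classes)

  fit <- net_train(X[split$train, , drop = FALSE],
                   targets[split$train, , drop = FALSE],
                   hidden = config$hidden, tf = config$tf,
                   alpha = config$alpha, error_goal = config$error_goal,
                   max_epochs = config$max_epochs,
                   init_scale = config$init_scale, seed = seeds$init)
  pred <- net_classify(fit, X[split$test, , drop = FALSE])
  cm <- confusion(feats$label[split$test], pred, n_classes = n_classes)

  structure(list(confusion = cm, accuracy = cm$accuracy,
                 error_rate = cm$error_rate, fit = fit, split = split,
                 features = feats, config = config, seeds = seeds),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n",
      " method:", x$config$features$method,
      "| normalization:", x$config$normalization,
      "| IMFs/channel:", x$config$features$n_imfs, "\n",
      " train/test:", length(x$split$train), "/", length(x$split$test),
      "| epochs:", x$fit$epochs_run,
      "| final MSE:", signif(utils::tail(x$fit$mse_history, 1), 4), "\n",
      " held-out accuracy:", round(x$accuracy, 4),
      "| error rate:", round(x$error_rate, 4), "\n")
  invisible(x)
}

#' @describeIn run_pipeline One-row summary of a pipeline run.
#' @param x A `pipeline_report`.
#' @param ... Ignored.
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble::tibble(
    method = x$config$features$method,
    normalization = x$config$normalization,
    n_train = length(x$split$train),
    n_test = length(x$split$test),
    epochs_run = x$fit$epochs_run,
    final_mse = utils::tail(x$fit$mse_history, 1),
    stopped_by = x$fit$stopped_by,
    accuracy = x$accuracy,
    error_rate = x$error_rate
  )
}
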