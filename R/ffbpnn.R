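# Feed-forward network trained by backpropagation of sensitivities and
# steepest descent, written from first principles:
#   forward       a^{k+1} = f^{k+1}(W^{k+1} a^k + b^{k+1})
#   output layer  s^L = -2 diag(f'^L(x^L)) (t - a^L)
#   hidden layers s^k = diag(f'^k(x^k)) (W^{k+1})' s^{k+1}
#   updates       W <- W - alpha s a'   ;   b <- b - alpha s

#' Transfer functions and their derivatives
#'
#' `purelin` is the identity, `logsig` the logistic sigmoid
#' `1 / (1 + exp(-v))`, `tansig` the hyperbolic tangent. Derivatives are
#' analytic, evaluated at the pre-activation `v`.
#'
#' @param tag One of `"purelin"`, `"logsig"`, `"tansig"`.
#' @param v Numeric vector/matrix of pre-activations.
#' @return Numeric of the same shape as `v`.
#' @export
transfer <- function(tag, v) {
  switch(tag,
    purelin = v,
    logsig = 1 / (1 + exp(-v)),
    tansig = tanh(v),
    stop_memdbci(paste0("unknown transfer function: ", tag),
                 "memdbci_invalid_spec")
  )
}

#' @rdname transfer
#' @export
transfer_deriv <- function(tag, v) {
  switch(tag,
    purelin = v * 0 + 1,
    logsig = {
      a <- 1 / (1 + exp(-v))
      a * (1 - a)
    },
    tansig = 1 - tanh(v)^2,
    stop_memdbci(paste0("unknown transfer function: ", tag),
                 "memdbci_invalid_spec")
  )
}

#' Initialize network parameters
#'
#' Weights and biases are drawn uniformly from
#' `(-init_scale, +init_scale)`, seeded for reproducibility.
#'
#' @param layer_sizes Integer vector of unit counts, input layer first,
#'   e.g. `c(42, 10, 4)`.
#' @param tf Transfer-function tag per non-input layer (a single tag is
#'   recycled).
#' @param init_scale Half-range of the uniform initialization.
#' @param seed Integer seed.
#' @return A `net_params`: list with `layer_sizes`, `W` (list of matrices,
#'   rows = layer units, cols = previous-layer units), `b` (list of column
#'   vectors) and `tf`.
#' @export
net_init <- function(layer_sizes, tf = "tansig", init_scale = 0.5,
                     seed = 1L) {
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  L <- length(layer_sizes) - 1L
  tf <- rep(tf, length.out = L)
  for (tag in tf) transfer(tag, 0)  # validate tags
  withr::with_seed(seed, {
    W <- lapply(seq_len(L), function(k) {
      matrix(runif(layer_sizes[k + 1] * layer_sizes[k],
                   -init_scale, init_scale),
             nrow = layer_sizes[k + 1], ncol = layer_sizes[k])
    })
    b <- lapply(seq_len(L), function(k) {
      matrix(runif(layer_sizes[k + 1], -init_scale, init_scale), ncol = 1)
    })
    structure(list(layer_sizes = as.integer(layer_sizes), W = W, b = b,
                   tf = tf), class = "net_params")
  })
}

#' Forward propagation
#'
#' Propagates one input vector — or a whole batch as a features x samples
#' matrix — through the network, returning every layer's activation and
#' pre-activation (both are needed by [net_sensitivities()]).
#'
#' @param params A `net_params` (see [net_init()]).
#' @param input Numeric vector of length `layer_sizes[1]`, or a matrix with
#'   that many rows (columns are samples).
#' @return List with `a` (activations `a0 ... aL`, `a0` being the input) and
#'   `x` (pre-activations `x1 ... xL`).
#' @export
net_forward <- function(params, input) {
  input <- as.matrix(input)
  if (nrow(input) != params$layer_sizes[1]) {
    stop_memdbci("input length does not match the network's input layer.",
                 "memdbci_shape_error")
  }
  L <- length(params$W)
  a <- vector("list", L + 1)
  x <- vector("list", L)
  a[[1]] <- input
  for (k in seq_len(L)) {
    x[[k]] <- params$W[[k]] %*% a[[k]] + as.vector(params$b[[k]])
    a[[k + 1]] <- transfer(params$tf[k], x[[k]])
  }
  list(a = a, x = x)
}

#' Backpropagated sensitivities
#'
#' Starting at the output layer with `s^L = -2 f'^L(x^L) * (t - a^L)` and
#' recursing backwards with `s^k = f'^k(x^k) * (W^{k+1})' s^{k+1}`. Works on
#' a single sample or a whole batch (columns).
#'
#' @param params A `net_params`.
#' @param fwd Result of [net_forward()].
#' @param target Numeric vector (or matrix, columns = samples) of targets,
#'   one entry per output unit.
#' @return List of sensitivity matrices `s1 ... sL`.
#' @export
net_sensitivities <- function(params, fwd, target) {
  L <- length(params$W)
  target <- as.matrix(target)
  aL <- fwd$a[[L + 1]]
  if (!all(dim(target) == dim(aL))) {
    stop_memdbci("target shape does not match the network output.",
                 "memdbci_shape_error")
  }
  s <- vector("list", L)
  s[[L]] <- -2 * transfer_deriv(params$tf[L], fwd$x[[L]]) * (target - aL)
  for (k in rev(seq_len(L - 1))) {
    s[[k]] <- transfer_deriv(params$tf[k], fwd$x[[k]]) *
      (t(params$W[[k + 1]]) %*% s[[k + 1]])
  }
  s
}

#' One steepest-descent parameter update
#'
#' `W^k <- W^k - alpha * s^k (a^{k-1})'` and `b^k <- b^k - alpha * s^k`,
#' as a pure function (the input `params` is not modified). When `fwd` and
#' `sens` hold a batch (columns = samples), the outer products accumulate
#' the per-sample steps and `scale` divides them (use `scale = n_samples`
#' for the mean step).
#'
#' @param params A `net_params`.
#' @param sens Sensitivities from [net_sensitivities()].
#' @param fwd Activations from [net_forward()].
#' @param alpha Learning rate (`> 0`).
#' @param scale Divisor applied to the accumulated step (default 1).
#' @return Updated `net_params`.
#' @export
net_update <- function(params, sens, fwd, alpha, scale = 1) {
  for (k in seq_along(params$W)) {
    params$W[[k]] <- params$W[[k]] -
      (alpha / scale) * sens[[k]] %*% t(fwd$a[[k]])
    params$b[[k]] <- params$b[[k]] -
      (alpha / scale) * matrix(rowSums(as.matrix(sens[[k]])), ncol = 1)
  }
  params
}

# flatten/unflatten helpers used by the finite-difference gradient check
net_gradients <- function(params, sens, fwd, scale = 1) {
  list(W = lapply(seq_along(params$W), function(k) {
         sens[[k]] %*% t(fwd$a[[k]]) / scale
       }),
       b = lapply(seq_along(params$W), function(k) {
         matrix(rowSums(as.matrix(sens[[k]])), ncol = 1) / scale
       }))
}

#' One-hot target encoding
#'
#' @param labels Integer labels in `0:(K-1)`.
#' @param n_classes Number of classes `K`.
#' @param low,high Off/on values; the `{-1, +1}` default matches the range
#'   of a `tansig` output layer.
#' @return `length(labels)` x `K` numeric matrix.
#' @export
one_hot <- function(labels, n_classes, low = -1, high = 1) {
  stopifnot(all(labels >= 0), all(labels < n_classes))
  out <- matrix(low, nrow = length(labels), ncol = n_classes)
  out[cbind(seq_along(labels), labels + 1L)] <- high
  out
}

#' Train a feed-forward backpropagation network
#'
#' Full-batch steepest descent: each epoch forward-propagates every sample,
#' records the epoch mean squared error (mean over samples and output
#' units), stops if it has reached `error_goal`, and otherwise applies the
#' mean of the per-sample weight/bias steps. `mode = "online"` instead
#' updates after every sample in order. Training is deterministic under
#' `seed` (which controls only the weight initialization).
#'
#' @param X Samples x features numeric matrix.
#' @param targets Samples x output-units numeric matrix (e.g. from
#'   [one_hot()]).
#' @param hidden Integer vector of hidden-layer sizes.
#' @param tf Transfer-function tag(s) for the non-input layers (recycled).
#' @param alpha Learning rate.
#' @param error_goal MSE threshold at which training stops.
#' @param max_epochs Epoch cap.
#' @param init_scale,seed Passed to [net_init()].
#' @param mode `"batch"` (default) or `"online"`.
#' @return An `ffbpnn` object: list with `params`, `mse_history`,
#'   `stopped_by` (`"goal"` or `"max_epochs"`), `epochs_run` and the call
#'   configuration. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
#' y <- matrix(c(-1, 1, 1, -1), ncol = 1)  # XOR in tansig range
#' fit <- net_train(X, y, hidden = 4, alpha = 0.1, error_goal = 1e-2,
#'                  max_epochs = 5000, seed = 1)
#' glance(fit)
#' @export
net_train <- function(X, targets, hidden = 10, tf = "tansig", alpha = 0.01,
                      error_goal = 1e-2, max_epochs = 1000,
                      init_scale = 0.5, seed = 1L,
                      mode = c("batch", "online")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  targets <- as.matrix(targets)
  stopifnot(nrow(X) == nrow(targets), nrow(X) >= 1,
            alpha > 0, error_goal > 0, max_epochs >= 1)
  arch <- c(ncol(X), hidden, ncol(targets))
  params <- net_init(arch, tf = tf, init_scale = init_scale, seed = seed)
  Xi <- t(X)        # features x samples
  Ti <- t(targets)  # outputs  x samples
  n <- ncol(Xi)
  mse_history <- numeric(0)
  stopped_by <- "max_epochs"
  epochs_run <- 0L
  for (epoch in seq_len(max_epochs)) {
    fwd <- net_forward(params, Xi)
    err <- Ti - fwd$a[[length(fwd$a)]]
    mse <- mean(err^2)
    if (!is.finite(mse)) {
      stop_memdbci(sprintf(
        "training diverged at epoch %d (non-finite MSE); try a smaller alpha.",
        epoch), "memdbci_divergence")
    }
    mse_history <- c(mse_history, mse)
    epochs_run <- epoch
    if (mse <= error_goal) {
      stopped_by <- "goal"
      break
    }
    if (mode == "batch") {
      sens <- net_sensitivities(params, fwd, Ti)
      params <- net_update(params, sens, fwd, alpha, scale = n)
    } else {
      for (i in seq_len(n)) {
        f1 <- net_forward(params, Xi[, i, drop = FALSE])
        s1 <- net_sensitivities(params, f1, Ti[, i, drop = FALSE])
        params <- net_update(params, s1, f1, alpha)
      }
    }
  }
  structure(list(params = params, mse_history = mse_history,
                 stopped_by = stopped_by, epochs_run = epochs_run,
                 config = list(hidden = hidden, tf = params$tf,
                               alpha = alpha, error_goal = error_goal,
                               max_epochs = max_epochs,
                               init_scale = init_scale, seed = seed,
                               mode = mode)),
            class = "ffbpnn")
}

#' Classify feature vectors with a trained network
#'
#' The predicted label is the index (0-based) of the maximum output unit;
#' exact ties go to the lowest index.
#'
#' @param fit An `ffbpnn` from [net_train()] or a bare `net_params`.
#' @param X Samples x features matrix.
#' @return Integer labels in `0:(n_out - 1)`.
#' @export
net_classify <- function(fit, X) {
  params <- if (inherits(fit, "ffbpnn")) fit$params else fit
  fwd <- net_forward(params, t(as.matrix(X)))
  out <- t(fwd$a[[length(fwd$a)]])
  max.col(out, ties.method = "first") - 1L
}

#' @export
print.ffbpnn <- function(x, ...) {
  cat("<ffbpnn> layers", paste(x$params$layer_sizes, collapse = "-"),
      "(", paste(x$params$tf, collapse = "/"), ")\n",
      " epochs:", x$epochs_run, " stopped by:", x$stopped_by,
      " final MSE:", signif(utils::tail(x$mse_history, 1), 4), "\n")
  invisible(x)
}

#' Tidy a trained network
#'
#' @param x An `ffbpnn`.
#' @param ... Ignored.
#' @return One row per parameter: `layer`, `parameter` (`"weight"` or
#'   `"bias"`), `unit`, `input` (`NA` for biases), `value`.
#' @export
tidy.ffbpnn <- function(x, ...) {
  L <- length(x$params$W)
  purrr::map_dfr(seq_len(L), function(k) {
    W <- x$params$W[[k]]
    dplyr::bind_rows(
      tibble::tibble(layer = k, parameter = "weight",
                     unit = rep(seq_len(nrow(W)), times = ncol(W)),
                     input = rep(seq_len(ncol(W)), each = nrow(W)),
                     value = as.vector(W)),
      tibble::tibble(layer = k, parameter = "bias",
                     unit = seq_len(nrow(W)), input = NA_integer_,
                     value = as.vector(x$params$b[[k]]))
    )
  })
}

#' @rdname tidy.ffbpnn
#' @return For `glance()`: a one-row tibble with the architecture, final
#'   MSE, epochs run and stopping reason.
#' @export
glance.ffbpnn <- function(x, ...) {
  tibble::tibble(
    layers = paste(x$params$layer_sizes, collapse = "-"),
    n_parameters = sum(vapply(x$params$W, length, integer(1))) +
      sum(vapply(x$params$b, length, integer(1))),
    epochs_run = x$epochs_run,
    final_mse = utils::tail(x$mse_history, 1),
    stopped_by = x$stopped_by
  )
}

#' Plot the training error curve
#'
#' @param object An `ffbpnn`.
#' @param ... Ignored.
#' @return A ggplot object (epoch vs MSE, log scale).
#' @export
autoplot.ffbpnn <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$mse_history),
                       mse = object$mse_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = object$config$error_goal,
                        linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "mean squared error")
}
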