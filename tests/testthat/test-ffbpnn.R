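test_that("transfer functions and derivatives take their textbook values", {
  expect_identical(transfer("purelin", 3.7), 3.7)
  expect_identical(transfer("tansig", 0), 0)
  expect_identical(transfer("logsig", 0), 0.5)
  expect_identical(transfer_deriv("tansig", 0), 1)
  expect_identical(transfer_deriv("logsig", 0), 0.25)
  expect_identical(transfer_deriv("purelin", c(1, 2)), c(1, 1))
  expect_error(transfer("relu", 0), class = "memdbci_invalid_spec")
})

test_that("transfer derivatives match central finite differences", {
  set.seed(51)
  v <- rnorm(20, sd = 2)
  eps <- 1e-6
  for (tag in c("purelin", "logsig", "tansig")) {
    fd <- (transfer(tag, v + eps) - transfer(tag, v - eps)) / (2 * eps)
    expect_lt(max(abs(fd - transfer_deriv(tag, v))), 1e-8)
  }
})

test_that("forward propagation follows the layer recursion", {
  id <- net_init(c(2, 2), tf = "purelin")
  id$W[[1]] <- diag(2)
  id$b[[1]] <- matrix(0, 2, 1)
  expect_equal(as.vector(net_forward(id, c(3, -1))$a[[2]]), c(3, -1))

  zero <- net_init(c(3, 4, 2), tf = "tansig")
  zero$W <- lapply(zero$W, function(w) w * 0)
  zero$b <- lapply(zero$b, function(b) b * 0)
  expect_equal(as.vector(net_forward(zero, c(1, 2, 3))$a[[3]]), c(0, 0))

  # 2-2-1 fixture, weights fixed in the test, output checked by hand
  p <- net_init(c(2, 2, 1), tf = c("tansig", "purelin"))
  p$W[[1]] <- matrix(c(0.5, -0.25, 0.1, 0.3), 2, 2)
  p$b[[1]] <- matrix(c(0.1, -0.2), 2, 1)
  p$W[[2]] <- matrix(c(1, -2), 1, 2)
  p$b[[2]] <- matrix(0.5, 1, 1)
  h <- tanh(c(0.5 * 1 + 0.1 * 2 + 0.1, -0.25 * 1 + 0.3 * 2 - 0.2))
  expect_equal(as.vector(net_forward(p, c(1, 2))$a[[3]]),
               1 * h[1] - 2 * h[2] + 0.5, tolerance = 1e-12)
  expect_error(net_forward(p, c(1, 2, 3)), class = "memdbci_shape_error")
})

test_that("sensitivities vanish at a perfect output and equal -2e at a linear unit", {
  p <- net_init(c(3, 4, 2), tf = "tansig", seed = 3)
  set.seed(52)
  input <- rnorm(3)
  fwd <- net_forward(p, input)
  s <- net_sensitivities(p, fwd, fwd$a[[3]])
  expect_true(all(abs(unlist(s)) == 0))

  lin <- net_init(c(1, 1), tf = "purelin", seed = 4)
  f1 <- net_forward(lin, 0.7)
  d <- 0.3
  s1 <- net_sensitivities(lin, f1, as.vector(f1$a[[2]]) + d)
  expect_equal(as.vector(s1[[1]]), -2 * d)
})

test_that("the backpropagated gradient matches finite differences", {
  expect_lt(grad_check_norm(c(3, 4, 2), c("tansig", "purelin"), 5), 1e-5)
  expect_lt(grad_check_norm(c(2, 3, 3, 2), c("logsig", "tansig", "purelin"),
                            6), 1e-5)
})

test_that("the steepest-descent update is the stated pure function", {
  p <- net_init(c(2, 3, 1), tf = "tansig", seed = 7)
  set.seed(53)
  input <- rnorm(2)
  fwd <- net_forward(p, input)
  sens <- net_sensitivities(p, fwd, 0.2)
  zero_s <- lapply(sens, function(s) s * 0)
  expect_identical(net_update(p, zero_s, fwd, alpha = 0.1), p)
  expect_equal(net_update(p, sens, fwd, alpha = 0), p)
  p2 <- net_update(p, sens, fwd, alpha = 0.1)
  expect_false(identical(p2$W[[1]], p$W[[1]]))

  # single linear unit: one step is the LMS rule w <- w + 2 alpha e x
  lms <- net_init(c(2, 1), tf = "purelin", seed = 8)
  x <- c(0.5, -1)
  f <- net_forward(lms, x)
  target <- 0.9
  e <- target - as.vector(f$a[[2]])
  upd <- net_update(lms, net_sensitivities(lms, f, target), f, alpha = 0.05)
  expect_equal(as.vector(upd$W[[1]]),
               as.vector(lms$W[[1]]) + 2 * 0.05 * e * x)
  expect_equal(as.vector(upd$b[[1]]), as.vector(lms$b[[1]]) + 2 * 0.05 * e)
})

test_that("training solves XOR and improves over the first epoch", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  y <- matrix(c(-1, 1, 1, -1), ncol = 1)
  fit <- net_train(X, y, hidden = 4, tf = "tansig", alpha = 0.1,
                   error_goal = 1e-2, max_epochs = 5000, seed = 1)
  expect_identical(fit$stopped_by, "goal")
  expect_lte(fit$epochs_run, 5000L)
  expect_lte(utils::tail(fit$mse_history, 1), 1e-2)
  k <- min(500L, fit$epochs_run)
  expect_lt(fit$mse_history[k], fit$mse_history[1])
})

test_that("training is deterministic and respects the stopping logic", {
  set.seed(54)
  X <- matrix(rnorm(40), 10, 4)
  y <- one_hot(rep(0:1, 5), 2)
  f1 <- net_train(X, y, hidden = 3, alpha = 0.05, max_epochs = 50,
                  error_goal = 1e-6, seed = 9)
  f2 <- net_train(X, y, hidden = 3, alpha = 0.05, max_epochs = 50,
                  error_goal = 1e-6, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$mse_history, f2$mse_history)
  expect_identical(f1$stopped_by, "max_epochs")

  fg <- net_train(X, y, hidden = 3, alpha = 0.05, max_epochs = 50,
                  error_goal = 1e12, seed = 9)
  expect_identical(fg$epochs_run, 1L)
  expect_identical(fg$stopped_by, "goal")

  expect_error(net_train(X, y, hidden = 3, tf = "purelin", alpha = 1e6,
                         max_epochs = 200, error_goal = 1e-9, seed = 9),
               class = "memdbci_divergence")
})

test_that("linearly separable Gaussian blobs are classified near-perfectly", {
  set.seed(55)
  n <- 60
  X <- rbind(cbind(rnorm(n, -2, 0.5), rnorm(n, -2, 0.5)),
             cbind(rnorm(n, 2, 0.5), rnorm(n, 2, 0.5)))
  labels <- rep(0:1, each = n)
  idx <- sample(2 * n, 80)
  fit <- net_train(X[idx, ], one_hot(labels[idx], 2), hidden = 5,
                   alpha = 0.1, error_goal = 1e-2, max_epochs = 2000,
                   seed = 10)
  pred <- net_classify(fit, X[-idx, ])
  expect_gte(mean(pred == labels[-idx]), 0.98)
})

test_that("online mode also learns", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  y <- matrix(c(-1, 1, 1, -1), ncol = 1)
  fit <- net_train(X, y, hidden = 4, tf = "tansig", alpha = 0.05,
                   error_goal = 1e-2, max_epochs = 3000, seed = 2,
                   mode = "online")
  expect_lt(utils::tail(fit$mse_history, 1), fit$mse_history[1])
})

test_that("classification decodes the maximum unit with low-index ties", {
  p <- net_init(c(4, 4), tf = "purelin")
  p$W[[1]] <- diag(4)
  p$b[[1]] <- matrix(0, 4, 1)
  expect_identical(net_classify(p, matrix(c(0.9, -0.2, 0.1, -0.8), 1)), 0L)
  expect_identical(net_classify(p, matrix(c(0.5, 0.5, 0, 0), 1)), 0L)
  labels <- c(2L, 0L, 3L, 1L)
  expect_identical(net_classify(p, one_hot(labels, 4)), labels)
})

test_that("tidy and glance summarize a fitted network", {
  fit <- net_train(matrix(rnorm(20), 10, 2), one_hot(rep(0:1, 5), 2),
                   hidden = 3, max_epochs = 5, error_goal = 1e-9, seed = 1)
  td <- tidy(fit)
  expect_identical(nrow(td), (2L * 3L + 3L) + (3L * 2L + 2L))
  gl <- glance(fit)
  expect_identical(gl$layers, "2-3-2")
  expect_identical(gl$epochs_run, 5L)
})
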