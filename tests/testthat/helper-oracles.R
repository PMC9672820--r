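# Shared fixtures and independent oracles.

# central fraction of sample indices, excluding boundary effects
interior_idx <- function(n, frac = 0.8) {
  lo <- floor(n * (1 - frac) / 2) + 1L
  hi <- n - floor(n * (1 - frac) / 2)
  lo:hi
}

tone <- function(a, f, fs, n, phase = 0) {
  a * sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

# Brute-force fuzzy approximate entropy: explicit double loop over all
# template pairs, independent of the vectorized implementation.
fuzzyen_bruteforce <- function(x, m, r_abs, n_grad) {
  phi <- function(mm) {
    N <- length(x)
    K <- N - mm + 1
    tmpl <- lapply(seq_len(K), function(i) {
      w <- x[i:(i + mm - 1)]
      w - mean(w)
    })
    lnphi <- numeric(K)
    for (i in seq_len(K)) {
      s <- 0
      for (j in seq_len(K)) {
        if (j == i) next
        d <- max(abs(tmpl[[i]] - tmpl[[j]]))
        s <- s + exp(-d^n_grad / r_abs)
      }
      lnphi[i] <- log(s / (K - 1))
    }
    mean(lnphi)
  }
  phi(m) - phi(m + 1)
}

# Norm-based relative agreement between the backpropagated gradient and a
# central finite-difference gradient of the summed-squared error.
grad_check_norm <- function(arch, tfs, seed, eps = 1e-6) {
  params <- net_init(arch, tf = tfs, seed = seed)
  set.seed(seed + 99)
  input <- rnorm(arch[1])
  target <- rnorm(arch[length(arch)])
  fwd <- net_forward(params, input)
  sens <- net_sensitivities(params, fwd, target)
  ana <- unlist(c(
    lapply(seq_along(params$W), function(k) sens[[k]] %*% t(fwd$a[[k]])),
    sens
  ))
  loss <- function(p) {
    f <- net_forward(p, input)
    sum((target - f$a[[length(f$a)]])^2)
  }
  fd <- numeric(0)
  for (field in c("W", "b")) {
    for (k in seq_along(params[[field]])) {
      for (i in seq_along(params[[field]][[k]])) {
        p1 <- params; p1[[field]][[k]][i] <- p1[[field]][[k]][i] + eps
        p2 <- params; p2[[field]][[k]][i] <- p2[[field]][[k]][i] - eps
        fd <- c(fd, (loss(p1) - loss(p2)) / (2 * eps))
      }
    }
  }
  # analytic order above is W1..WL then b1..bL, matching fd's fill order
  sqrt(sum((fd - ana)^2)) / max(sqrt(sum(fd^2)), 1e-12)
}

null_class_effect <- function(n_classes = 4, amp = 1) {
  eff <- default_class_effect(n_classes)
  eff$mu_amp <- amp
  eff$beta_amp <- amp
  eff
}
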