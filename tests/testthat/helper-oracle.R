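# Brute-force conditional-least-squares oracle: minimizes each equation's
# sum of squared one-step prediction errors numerically, independent of the
# package's solver. Used to cross-check fit_mar on small instances.
brute_force_cls <- function(y, u = NULL, mask = NULL) {
  X <- y$values
  Tn <- nrow(X)
  p <- ncol(X)
  q <- if (is.null(u)) 0L else ncol(u$values)
  if (is.null(mask)) mask <- full_mask(p, q)
  resp <- X[-1L, , drop = FALSE]
  lagX <- X[-Tn, , drop = FALSE]
  U <- if (q) u$values[-1L, , drop = FALSE] else NULL
  a <- numeric(p)
  B <- matrix(0, p, p)
  Cm <- matrix(0, p, q)
  for (i in seq_len(p)) {
    jb <- which(mask$b[i, ])
    jc <- if (q) which(mask$c[i, ]) else integer(0)
    D <- cbind(1, lagX[, jb, drop = FALSE],
               if (length(jc)) U[, jc, drop = FALSE])
    yi <- resp[, i]
    ok <- stats::complete.cases(cbind(yi, D))
    sse <- function(beta) sum((yi[ok] - D[ok, , drop = FALSE] %*% beta)^2)
    fit <- stats::optim(rep(0, ncol(D)), sse, method = "BFGS",
                        control = list(reltol = 1e-16, maxit = 5000))
    a[i] <- fit$par[1L]
    B[i, jb] <- fit$par[1L + seq_along(jb)]
    if (length(jc)) Cm[i, jc] <- fit$par[1L + length(jb) + seq_along(jc)]
  }
  list(a = a, b = B, c = Cm)
}

# Small random stationary parameter set with optional covariates.
random_small_params <- function(p, q = 0L, seed = 1L) {
  set.seed(seed)
  B <- matrix(stats::runif(p * p, -0.3, 0.3), p, p)
  diag(B) <- stats::runif(p, 0.2, 0.7)
  B <- B * (0.9 / max(1, stability_lambda(B) / 0.9))
  mar_params(stats::runif(p, -0.5, 0.5), B,
             matrix(stats::runif(p * q, -0.4, 0.4), p, q),
             stats::runif(p, 0.05, 0.3))
}

random_covariates <- function(T, q, seed = 1L) {
  if (q == 0L) return(NULL)
  set.seed(seed)
  covariate_panel(scale(matrix(stats::rnorm(T * q), T, q)))
}

# Two-regime test configuration: own-dynamics drop for the first taxon.
two_regime_config <- function(T = 300L, breakpoint = 150L, seed = 1L) {
  B1 <- matrix(c(0.8, -0.2, 0.1, 0.5), 2, 2, byrow = TRUE,
               dimnames = list(c("x1", "x2"), c("x1", "x2")))
  B2 <- B1
  B2[1, 1] <- 0.3
  pm1 <- mar_params(c(0.2, 0.5), B1, sigma2 = c(0.25, 0.25))
  pm2 <- mar_params(c(0.7, 0.5), B2, sigma2 = c(0.25, 0.25))
  regime_config(list(pm1, pm2), breakpoints = breakpoint, T = T, seed = seed)
}

# Consecutive "YYYY-MM" labels starting at `start`.
month_labels_seq <- function(start, n) {
  idx <- mwmar:::month_index(start)
  mwmar:::month_label(seq(idx, length.out = n))
}
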