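#' Fit a MAR(1) model by conditional least squares
#'
#' Estimates the model `X_t = A + B X_{t-1} + C U_t + E_t` equation by
#' equation: for each taxon `i`, the log-abundance at time `t` is regressed
#' on an intercept, the mask-included lagged abundances `X_{j,t-1}`, and the
#' mask-included contemporaneous covariates `U_{k,t}`, minimizing the sum of
#' squared one-step prediction errors. Equations are independent, so a
#' regression row with a missing value among one equation's response or
#' predictors is dropped for that equation only (casewise deletion).
#'
#' The process-error variance `sigma2[i]` is the residual sum of squares
#' divided by the number of rows actually used (maximum-likelihood flavour);
#' set `sigma2_divisor = "df"` for the unbiased divisor `n - k`.
#'
#' @param y an [abundance_panel()] with `T >= 3` rows.
#' @param u a [covariate_panel()] time-aligned with `y`, or `NULL`.
#' @param mask a [mask_spec()]; defaults to all coefficients estimated.
#' @param sigma2_divisor `"n"` (default, divisor `n_used`) or `"df"`
#'   (divisor `n_used - k`, the residual degrees of freedom).
#' @return An object of class `mar_fit`: `params` (a [mar_params()]),
#'   `residuals` (`(T-1) x p` matrix aligned to response times, `NA` where a
#'   row was dropped), `n_used` (per-equation row counts), `window_span`
#'   (first and last time label of the data used) and `mask`.
#' @examples
#' set.seed(1)
#' pan <- abundance_panel(cbind(a = cumsum(rnorm(40, sd = .2))))
#' fit_mar(pan)
#' @export
fit_mar <- function(y, u = NULL, mask = NULL, sigma2_divisor = c("n", "df")) {
  stopifnot(inherits(y, "abundance_panel"))
  sigma2_divisor <- match.arg(sigma2_divisor)
  if (!is.null(u)) {
    stopifnot(inherits(u, "covariate_panel"))
    if (ncol(u$values) == 0L) u <- NULL
  }
  check_alignment(y, u)
  p <- ncol(y$values)
  q <- if (is.null(u)) 0L else ncol(u$values)
  if (is.null(mask)) mask <- full_mask(p, q)
  stopifnot(inherits(mask, "mask_spec"))
  if (nrow(mask$b) != p || ncol(mask$c) != q) {
    stop("mask dimensions do not match the panels", call. = FALSE)
  }
  Tn <- nrow(y$values)
  max_k <- 1L + max(rowSums(mask$b) + if (q) rowSums(mask$c) else 0)
  if (Tn < max_k + 2L) {
    stop(sprintf("series too short: T = %d but an equation has %d predictors",
                 Tn, max_k - 1L), call. = FALSE)
  }

  X <- y$values
  resp <- X[-1L, , drop = FALSE]            # responses at t = 2..T
  lagX <- X[-Tn, , drop = FALSE]            # predictors at t-1
  U <- if (q) u$values[-1L, , drop = FALSE] else NULL  # contemporaneous U_t

  taxa <- colnames(X)
  covs <- if (q) colnames(u$values) else character(0)
  a <- numeric(p)
  B <- matrix(0, p, p, dimnames = list(taxa, taxa))
  Cm <- matrix(0, p, q, dimnames = list(taxa, covs))
  sigma2 <- numeric(p)
  n_used <- integer(p)
  resid <- matrix(NA_real_, Tn - 1L, p, dimnames = list(rownames(resp), taxa))

  for (i in seq_len(p)) {
    jb <- which(mask$b[i, ])
    jc <- if (q) which(mask$c[i, ]) else integer(0)
    D <- cbind(1, lagX[, jb, drop = FALSE],
               if (length(jc)) U[, jc, drop = FALSE])
    yi <- resp[, i]
    ok <- stats::complete.cases(cbind(yi, D))
    k <- ncol(D)
    if (sum(ok) < k + 1L) {
      stop(sprintf("degenerate fit for equation '%s': %d usable rows for %d coefficients",
                   taxa[i], sum(ok), k), call. = FALSE)
    }
    Dk <- D[ok, , drop = FALSE]
    if (qr(Dk)$rank < k) {
      stop(sprintf("degenerate fit for equation '%s': rank-deficient design (constant or collinear predictor)",
                   taxa[i]), call. = FALSE)
    }
    ls <- stats::lm.fit(Dk, yi[ok])
    cf <- ls$coefficients
    a[i] <- cf[1L]
    B[i, jb] <- cf[1L + seq_along(jb)]
    if (length(jc)) Cm[i, jc] <- cf[1L + length(jb) + seq_along(jc)]
    resid[ok, i] <- ls$residuals
    n_used[i] <- sum(ok)
    div <- if (sigma2_divisor == "n") n_used[i] else n_used[i] - k
    sigma2[i] <- sum(ls$residuals^2) / div
  }
  names(a) <- taxa
  names(sigma2) <- taxa
  names(n_used) <- taxa

  structure(list(
    params = mar_params(a, B, Cm, sigma2),
    residuals = resid,
    n_used = n_used,
    window_span = c(y$labels[1L], y$labels[Tn]),
    mask = mask
  ), class = "mar_fit")
}

#' Community stability: spectral radius of the interaction matrix
#'
#' Returns the largest eigenvalue modulus of `B` ("lambda"). It governs the
#' return rate to the stationary distribution after a perturbation: values
#' near 0 mean fast return (a stable community), values above 1 an unstable
#' system. Complex conjugate eigenvalue pairs are handled via their modulus.
#'
#' @param b square numeric matrix (or a [mar_params()] / `mar_fit`).
#' @return Non-negative scalar, the spectral radius of `b`.
#' @examples
#' stability_lambda(diag(c(0.3, 0.9)))  # 0.9
#' @export
stability_lambda <- function(b) {
  if (inherits(b, "mar_fit")) b <- b$params$b
  if (inherits(b, "mar_params")) b <- b$b
  b <- as.matrix(b)
  if (nrow(b) != ncol(b)) stop("b must be square", call. = FALSE)
  max(Mod(eigen(b, only.values = TRUE)$values))
}

#' One-step deterministic prediction
#'
#' Evaluates the deterministic part of the model, `A + B x_prev + C u_now`.
#' Used internally to form residuals and bootstrap replicate series.
#'
#' @param params a [mar_params()].
#' @param x_prev numeric `p`-vector, the state at `t - 1`.
#' @param u_now numeric `q`-vector of covariates at `t` (omit when `q = 0`).
#' @return Numeric `p`-vector, the predicted state at `t`.
#' @export
predict_one_step <- function(params, x_prev, u_now = NULL) {
  stopifnot(inherits(params, "mar_params"))
  p <- length(params$a)
  q <- ncol(params$c)
  if (length(x_prev) != p) stop("x_prev has wrong length", call. = FALSE)
  if (q == 0L) {
    if (!is.null(u_now) && length(u_now) > 0L) {
      stop("model has no covariates but u_now was supplied", call. = FALSE)
    }
    return(drop(params$a + params$b %*% x_prev))
  }
  if (is.null(u_now) || length(u_now) != q) {
    stop("u_now has wrong length", call. = FALSE)
  }
  drop(params$a + params$b %*% x_prev + params$c %*% u_now)
}

#' @export
print.mar_fit <- function(x, ...) {
  p <- length(x$params$a)
  cat(sprintf("<mar_fit> %d taxa, %d covariates; window %s .. %s\n",
              p, ncol(x$params$c), x$window_span[1], x$window_span[2]))
  cat(sprintf("lambda = %.4f; n_used = %s\n",
              stability_lambda(x$params$b),
              paste(x$n_used, collapse = "/")))
  invisible(x)
}

#' @export
print.mar_params <- function(x, ...) {
  cat(sprintf("<mar_params> p = %d, q = %d, lambda = %.4f\n",
              length(x$a), ncol(x$c), stability_lambda(x$b)))
  invisible(x)
}
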