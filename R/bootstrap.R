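#' Bootstrap settings
#'
#' Bundles the bootstrap configuration used by [moving_window_fit()].
#'
#' @param n_boot number of replicate data sets (default 2000).
#' @param level nominal coverage of the percentile intervals (default 0.95).
#' @param seed integer seed; each window uses `seed + window index`.
#' @param mode `"residual"` (resample fitted residual rows with replacement;
#'   default, robust to non-normal residuals) or `"gaussian"` (draw errors
#'   from mean-zero normals with the fitted variances).
#' @return A list of class `boot_settings`.
#' @export
boot_settings <- function(n_boot = 2000L, level = 0.95, seed = 1L,
                          mode = c("residual", "gaussian")) {
  mode <- match.arg(mode)
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  structure(list(n_boot = as.integer(n_boot), level = level,
                 seed = as.integer(seed), mode = mode),
            class = "boot_settings")
}

#' Parametric bootstrap confidence intervals for a window fit
#'
#' Generates `n_boot` replicate data sets from the fitted model and refits
#' each by conditional least squares. A replicate is built by iterating
#' `X_t = A + B X_{t-1} + C U_t + E_t` forward from the window's first
#' observed state, with the observed covariates held fixed and the process
#' errors `E_t` either resampled from the fitted residual rows (with
#' replacement, rows kept intact to preserve cross-taxon error structure) or
#' drawn from mean-zero normals with the fitted variances. Interval bounds
#' are percentile bounds, i.e. order statistics of each coefficient's
#' replicate sample at `(1-level)/2` and `1-(1-level)/2`.
#'
#' @param fit a `mar_fit` produced from `(y, u, mask)`.
#' @param y,u,mask the window data and mask the fit came from.
#' @param n_boot replicate count (>= 1).
#' @param level nominal coverage.
#' @param seed integer seed; identical inputs and seed give identical
#'   intervals.
#' @param mode `"residual"` or `"gaussian"` error draws.
#' @return An object of class `coef_intervals`: `lo` and `hi` (each a list
#'   with `a`, `b`, `c` shaped like the parameters, `NA` at masked cells),
#'   `level`, `n_boot`, `seed`, `mode` and `n_failed` (replicates whose
#'   refit failed; more than 50% failures is an error).
#' @export
bootstrap_intervals <- function(fit, y, u = NULL, mask = fit$mask,
                                n_boot = 2000L, level = 0.95, seed = 1L,
                                mode = c("residual", "gaussian")) {
  stopifnot(inherits(fit, "mar_fit"), inherits(y, "abundance_panel"))
  mode <- match.arg(mode)
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  pm <- fit$params
  p <- length(pm$a)
  q <- ncol(pm$c)
  Tn <- nrow(y$values)
  x0 <- y$values[1L, ]
  if (anyNA(x0)) {
    # fall back to first complete row so the recursion can start
    first_ok <- which(stats::complete.cases(y$values))[1L]
    if (is.na(first_ok)) stop("no complete state to start bootstrap from", call. = FALSE)
    x0 <- y$values[first_ok, ]
  }
  Um <- if (!is.null(u) && ncol(u$values) > 0L) u$values else NULL
  res_rows <- fit$residuals[stats::complete.cases(fit$residuals), , drop = FALSE]
  if (mode == "residual" && nrow(res_rows) == 0L) {
    stop("no complete residual rows to resample", call. = FALSE)
  }
  sd_e <- sqrt(pm$sigma2)

  # replicate coefficient draws: n_boot x (p + p*p + p*q), row-major by eqn
  draws_a <- matrix(NA_real_, n_boot, p)
  draws_b <- matrix(NA_real_, n_boot, p * p)
  draws_c <- matrix(NA_real_, n_boot, p * q)
  n_failed <- 0L

  set.seed(as.integer(seed))
  for (r in seq_len(n_boot)) {
    E <- if (mode == "residual") {
      res_rows[sample.int(nrow(res_rows), Tn - 1L, replace = TRUE), , drop = FALSE]
    } else {
      matrix(stats::rnorm((Tn - 1L) * p, sd = rep(sd_e, each = Tn - 1L)), Tn - 1L, p)
    }
    Xr <- matrix(NA_real_, Tn, p)
    Xr[1L, ] <- x0
    for (t in 2:Tn) {
      mu <- pm$a + pm$b %*% Xr[t - 1L, ]
      if (q) mu <- mu + pm$c %*% Um[t, ]
      Xr[t, ] <- mu + E[t - 1L, ]
    }
    yb <- y
    colnames(Xr) <- colnames(y$values)
    yb$values <- Xr
    rf <- tryCatch(fit_mar(yb, u, mask), error = function(e) NULL)
    if (is.null(rf)) { n_failed <- n_failed + 1L; next }
    draws_a[r, ] <- rf$params$a
    draws_b[r, ] <- rf$params$b
    draws_c[r, ] <- rf$params$c
  }
  if (n_failed > n_boot / 2) {
    stop(sprintf("bootstrap failed: %d of %d replicate fits degenerate",
                 n_failed, n_boot), call. = FALSE)
  }

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qcol <- function(m) apply(m, 2L, function(v) {
    v <- v[!is.na(v)]
    stats::quantile(v, probs, type = 1L, names = FALSE)
  })
  qa <- qcol(draws_a)
  qb <- qcol(draws_b)
  qc <- if (q) qcol(draws_c) else matrix(numeric(0), 2, 0)

  shape <- function(row, dim_, mask_keep) {
    m <- matrix(row, nrow = dim_[1], ncol = dim_[2])
    m[!mask_keep] <- NA_real_
    m
  }
  lo <- list(a = qa[1L, ],
             b = shape(qb[1L, ], c(p, p), mask$b),
             c = if (q) shape(qc[1L, ], c(p, q), mask$c) else pm$c)
  hi <- list(a = qa[2L, ],
             b = shape(qb[2L, ], c(p, p), mask$b),
             c = if (q) shape(qc[2L, ], c(p, q), mask$c) else pm$c)
  dimnames(lo$b) <- dimnames(hi$b) <- dimnames(pm$b)
  if (q) dimnames(lo$c) <- dimnames(hi$c) <- dimnames(pm$c)
  names(lo$a) <- names(hi$a) <- names(pm$a)

  structure(list(lo = lo, hi = hi, level = level, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), mode = mode, n_failed = n_failed),
            class = "coef_intervals")
}

#' Does a confidence interval exclude zero?
#'
#' A coefficient is called significant when its interval does not contain 0.
#'
#' @param lo,hi interval bounds, `lo <= hi` (vectorized).
#' @return Logical, `TRUE` iff `0` is outside `[lo, hi]`.
#' @export
is_significant <- function(lo, hi) {
  if (any(lo > hi, na.rm = TRUE)) stop("lo > hi", call. = FALSE)
  lo > 0 | hi < 0
}

#' @export
print.coef_intervals <- function(x, ...) {
  cat(sprintf("<coef_intervals> %.0f%% percentile intervals, %d replicates (%d failed), mode = %s\n",
              100 * x$level, x$n_boot, x$n_failed, x$mode))
  invisible(x)
}
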