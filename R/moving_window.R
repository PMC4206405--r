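#' Enumerate overlapping moving windows
#'
#' For a series of length `n` and window size `w`, returns the response index
#' ranges `[2, w+1], [3, w+2], ..., [n-w+1, n]` (1-based, inclusive). Each
#' window's regressions additionally consume the observation immediately
#' before its first response, supplying the lag-1 predictor, so a window
#' covers `w` data points and yields `w` one-step regressions per equation.
#' The number of windows is `n - w`.
#'
#' @param n series length (time steps).
#' @param w window size, `2 <= w < n`.
#' @return Data frame with columns `response_start`, `response_end` and
#'   `data_start` (`response_start - 1`, the first observation used).
#' @examples
#' nrow(enumerate_windows(396, 84))  # 312
#' @export
enumerate_windows <- function(n, w) {
  n <- as.integer(n); w <- as.integer(w)
  if (is.na(n) || is.na(w) || w < 2L || w >= n) {
    stop("window size must satisfy 2 <= w < n", call. = FALSE)
  }
  rs <- 2L:(n - w + 1L)
  data.frame(response_start = rs, response_end = rs + w - 1L,
             data_start = rs - 1L)
}

#' Moving-window MAR analysis
#'
#' Refits the MAR(1) model by conditional least squares on every length-`w`
#' contiguous window of the series, producing a time series of parameter
#' estimates ("trajectories"), the stability value lambda per window, and
#' optionally bootstrap confidence intervals per window. Covariates must be
#' standardized over the full series before calling (as
#' [build_covariate_panel()] does), so trajectories reflect changing
#' responses rather than changing covariate scaling.
#'
#' Windows whose fit is degenerate (for example a taxon absent for a whole
#' window, making its lag column constant) are recorded with the error
#' message in `failed`, never dropped silently.
#'
#' @inheritParams fit_mar
#' @param w window size in time steps. The default 84 is seven years of
#'   monthly data, the smallest multiple of 12 above the ~75-step accuracy
#'   breakpoint seen in simulation (see [window_size_experiment()]).
#' @param boot bootstrap settings from [boot_settings()], or `NULL` to skip
#'   confidence intervals.
#' @param progress print a progress line every 25 windows to stderr.
#' @return An object of class `mar_trajectory`: `window_size`, `results`
#'   (list of per-window records with `end_time`, `end_index`, `fit`,
#'   `lambda`, `intervals`), and `failed` (data frame of failed windows and
#'   reasons).
#' @export
moving_window_fit <- function(y, u = NULL, mask = NULL, w = 84L, boot = NULL,
                              progress = FALSE) {
  stopifnot(inherits(y, "abundance_panel"))
  check_alignment(y, u)
  n <- nrow(y$values)
  win <- enumerate_windows(n, w)
  results <- vector("list", nrow(win))
  failed <- list()
  for (k in seq_len(nrow(win))) {
    i1 <- win$data_start[k]; i2 <- win$response_end[k]
    ys <- panel_slice(y, i1, i2)
    us <- if (!is.null(u)) panel_slice(u, i1, i2) else NULL
    fit <- tryCatch(fit_mar(ys, us, mask), error = function(e) e)
    if (inherits(fit, "error")) {
      failed[[length(failed) + 1L]] <- data.frame(
        end_time = y$labels[i2], end_index = i2,
        reason = conditionMessage(fit), stringsAsFactors = FALSE)
      results[[k]] <- list(end_time = y$labels[i2], end_index = i2,
                           fit = NULL, lambda = NA_real_, intervals = NULL)
    } else {
      ci <- if (!is.null(boot)) {
        bootstrap_intervals(fit, ys, us, fit$mask,
                            n_boot = boot$n_boot, level = boot$level,
                            seed = boot$seed + k, mode = boot$mode)
      }
      results[[k]] <- list(end_time = y$labels[i2], end_index = i2,
                           fit = fit, lambda = stability_lambda(fit$params$b),
                           intervals = ci)
    }
    if (progress && k %% 25L == 0L) {
      message(sprintf("window %d/%d (end %s)", k, nrow(win), y$labels[i2]))
    }
  }
  if (all(vapply(results, function(r) is.null(r$fit), logical(1)))) {
    stop("all windows failed to fit", call. = FALSE)
  }
  structure(list(window_size = as.integer(w), results = results,
                 failed = if (length(failed)) do.call(rbind, failed) else
                   data.frame(end_time = character(0), end_index = integer(0),
                              reason = character(0))),
            class = "mar_trajectory")
}

#' Long-format table of a trajectory
#'
#' Flattens a trajectory to one record per estimated (non-masked)
#' coefficient per window, plus one stability record per window. Masked
#' coefficients never appear. Intercepts have `predictor = "(intercept)"`;
#' the stability row has `response = "(community)"`,
#' `predictor = "lambda"`. Rows are keyed by the window END time, matching
#' the reporting convention for moving-window results.
#'
#' @param tr a `mar_trajectory` from [moving_window_fit()].
#' @return Data frame with columns `end_time`, `response`, `predictor`,
#'   `estimate`, `ci_lo`, `ci_hi`, `significant`, `lambda`.
#' @export
trajectory_to_table <- function(tr) {
  stopifnot(inherits(tr, "mar_trajectory"))
  if (length(tr$results) == 0L) stop("empty trajectory", call. = FALSE)
  rows <- lapply(tr$results, function(r) {
    if (is.null(r$fit)) return(NULL)
    pm <- r$fit$params
    mk <- r$fit$mask
    taxa <- names(pm$a)
    covs <- colnames(pm$c)
    ests <- data.frame(
      response = c(taxa,
                   rep(taxa, times = rowSums(mk$b)),
                   if (ncol(mk$c)) rep(taxa, times = rowSums(mk$c)),
                   "(community)"),
      predictor = c(rep("(intercept)", length(taxa)),
                    unlist(lapply(seq_along(taxa),
                                  function(i) taxa[mk$b[i, ]]), use.names = FALSE),
                    if (ncol(mk$c))
                      unlist(lapply(seq_along(taxa),
                                    function(i) covs[mk$c[i, ]]), use.names = FALSE),
                    "lambda"),
      estimate = c(pm$a,
                   t(pm$b)[t(mk$b)],
                   if (ncol(mk$c)) t(pm$c)[t(mk$c)],
                   r$lambda),
      stringsAsFactors = FALSE)
    if (!is.null(r$intervals)) {
      iv <- r$intervals
      ests$ci_lo <- c(iv$lo$a, t(iv$lo$b)[t(mk$b)],
                      if (ncol(mk$c)) t(iv$lo$c)[t(mk$c)], NA_real_)
      ests$ci_hi <- c(iv$hi$a, t(iv$hi$b)[t(mk$b)],
                      if (ncol(mk$c)) t(iv$hi$c)[t(mk$c)], NA_real_)
      ests$significant <- ifelse(is.na(ests$ci_lo), NA,
                                 is_significant(ests$ci_lo, ests$ci_hi))
    } else {
      ests$ci_lo <- NA_real_; ests$ci_hi <- NA_real_; ests$significant <- NA
    }
    cbind(data.frame(end_time = r$end_time, stringsAsFactors = FALSE),
          ests, lambda = r$lambda)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("end_time", "response", "predictor", "estimate",
          "ci_lo", "ci_hi", "significant", "lambda")]
}

#' @export
print.mar_trajectory <- function(x, ...) {
  ok <- sum(!vapply(x$results, function(r) is.null(r$fit), logical(1)))
  cat(sprintf("<mar_trajectory> window size %d, %d windows (%d fitted, %d failed)\n",
              x$window_size, length(x$results), ok, nrow(x$failed)))
  invisible(x)
}
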