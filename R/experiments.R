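#' Bootstrap coverage experiment
#'
#' Monte-Carlo check of the percentile bootstrap: repeatedly simulates a
#' stationary panel, fits it, builds bootstrap intervals, and records
#' whether the interval for one tracked interaction coefficient covers its
#' generating value. The empirical coverage should sit near the nominal
#' level.
#'
#' @param params generating [mar_params()].
#' @param i,j row (response) and column (predictor) of the tracked `B`
#'   entry.
#' @param T panel length per replicate.
#' @param n_outer Monte-Carlo replicates.
#' @param n_boot bootstrap replicates per interval.
#' @param level nominal coverage.
#' @param seed integer seed.
#' @param mode bootstrap error-draw mode.
#' @return List: `coverage` (fraction of intervals covering the truth),
#'   `n_outer`, `n_failed` (replicates whose fit or bootstrap failed).
#' @export
bootstrap_coverage_experiment <- function(params, i = 1L, j = 1L, T = 85L,
                                          n_outer = 200L, n_boot = 500L,
                                          level = 0.95, seed = 1L,
                                          mode = "residual") {
  truth <- params$b[i, j]
  hits <- logical(0)
  n_failed <- 0L
  for (r in seq_len(n_outer)) {
    pan <- simulate_mar(params, T = T, seed = seed + 7L * r)
    ans <- tryCatch({
      fit <- fit_mar(pan)
      ci <- bootstrap_intervals(fit, pan, n_boot = n_boot, level = level,
                                seed = seed + 7L * r + 1L, mode = mode)
      truth >= ci$lo$b[i, j] && truth <= ci$hi$b[i, j]
    }, error = function(e) NA)
    if (is.na(ans)) n_failed <- n_failed + 1L else hits <- c(hits, ans)
  }
  list(coverage = mean(hits), n_outer = n_outer, n_failed = n_failed)
}

#' Regime-shift recovery experiment
#'
#' End-to-end check that a moving-window analysis recovers a piecewise
#' constant interaction: panels are simulated from a two-regime
#' configuration, fitted with a moving window, and bootstrap intervals are
#' built for windows lying wholly inside one regime (thinned for speed).
#' Reports how often those intervals cover the regime's true coefficient,
#' and the per-window stability estimates against the regimes' analytic
#' spectral radii.
#'
#' @param cfg a [regime_config()] with exactly one breakpoint.
#' @param w window size.
#' @param n_seeds number of simulated panels.
#' @param coefficient tracked coefficient id (e.g. `"b[x1,x1]"`).
#' @param n_boot bootstrap replicates per window.
#' @param thin keep every `thin`-th eligible window.
#' @param seed integer seed.
#' @param level nominal coverage.
#' @return List: `ci_recovery` (fraction of wholly-pre/post windows whose
#'   interval covers their regime's truth), `n_windows_tested`,
#'   `lambda_true` (the two analytic spectral radii), `lambda_pre` /
#'   `lambda_post` (median estimated lambda over wholly-pre / wholly-post
#'   windows), `crossed` (fraction of seeds whose lambda trajectory attains
#'   both sides of the midpoint between the regime radii).
#' @export
regime_recovery_experiment <- function(cfg, w = 84L, n_seeds = 20L,
                                       coefficient = "b[x1,x1]",
                                       n_boot = 200L, thin = 3L, seed = 1L,
                                       level = 0.95) {
  stopifnot(inherits(cfg, "regime_config"), length(cfg$breakpoints) == 1L)
  bp <- cfg$breakpoints[1L]
  p <- length(cfg$params[[1L]]$a)
  q <- ncol(cfg$params[[1L]]$c)
  mask <- full_mask(p, q)
  ids <- coef_ids(cfg$params[[1L]], mask)
  ki <- match(coefficient, ids$id)
  if (is.na(ki)) stop("unknown coefficient id", call. = FALSE)
  truth_pre <- coef_values(cfg$params[[1L]], mask)[ki]
  truth_post <- coef_values(cfg$params[[2L]], mask)[ki]
  lambda_true <- c(stability_lambda(cfg$params[[1L]]$b),
                   stability_lambda(cfg$params[[2L]]$b))
  midpoint <- mean(lambda_true)

  win <- enumerate_windows(cfg$T, w)
  pre <- which(win$response_end <= bp)
  post <- which(win$response_start > bp)
  test_idx <- c(pre[seq(1L, length(pre), by = thin)],
                post[seq(1L, length(post), by = thin)])

  hits <- integer(0)
  lam_pre <- lam_post <- numeric(0)
  crossed <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg_s <- cfg
    cfg_s$seed <- seed + 101L * s
    sim <- simulate_regime_shift(cfg_s)
    tr <- moving_window_fit(sim$panel, sim$u, mask, w = w)
    lam <- vapply(tr$results, function(r)
      if (is.null(r$fit)) NA_real_ else r$lambda, numeric(1))
    lam_pre <- c(lam_pre, stats::median(lam[pre], na.rm = TRUE))
    lam_post <- c(lam_post, stats::median(lam[post], na.rm = TRUE))
    crossed[s] <- any(lam > midpoint, na.rm = TRUE) &&
      any(lam < midpoint, na.rm = TRUE)
    for (k in test_idx) {
      r <- tr$results[[k]]
      if (is.null(r$fit)) next
      i1 <- win$data_start[k]; i2 <- win$response_end[k]
      ys <- panel_slice(sim$panel, i1, i2)
      us <- if (!is.null(sim$u)) panel_slice(sim$u, i1, i2) else NULL
      ci <- tryCatch(
        bootstrap_intervals(r$fit, ys, us, mask, n_boot = n_boot,
                            level = level, seed = seed + 1000L * s + k),
        error = function(e) NULL)
      if (is.null(ci)) next
      lo <- c(ci$lo$a, t(ci$lo$b)[t(mask$b)],
              if (q) t(ci$lo$c)[t(mask$c)])[ki]
      hi <- c(ci$hi$a, t(ci$hi$b)[t(mask$b)],
              if (q) t(ci$hi$c)[t(mask$c)])[ki]
      tru <- if (k %in% pre) truth_pre else truth_post
      hits <- c(hits, as.integer(tru >= lo && tru <= hi))
    }
  }
  list(ci_recovery = mean(hits), n_windows_tested = length(hits),
       lambda_true = lambda_true,
       lambda_pre = stats::median(lam_pre),
       lambda_post = stats::median(lam_post),
       crossed = mean(crossed))
}
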