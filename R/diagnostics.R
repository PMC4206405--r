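#' Shapiro-Wilk normality test
#'
#' Standard Shapiro-Wilk W statistic and p-value (Royston's approximation,
#' via [stats::shapiro.test()]), for residual normality checks.
#'
#' @param sample numeric vector, `3 <= n <= 5000` non-missing values.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(sample) {
  x <- sample[!is.na(sample)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Bonferroni-corrected significance level
#'
#' @param alpha nominal level, in (0, 1).
#' @param m number of null hypotheses tested, >= 1.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Residual normality scan over a trajectory
#'
#' Applies the Shapiro-Wilk test to each window-by-taxon residual vector of
#' a moving-window fit, at a Bonferroni-corrected alpha. The multiplicity
#' universe is configurable: `"pooled"` (default) corrects for
#' windows x taxa tests; `"per_taxon"` corrects within each taxon's set of
#' windows. Both per-taxon rejection counts are reported, since the two
#' conventions can disagree for borderline windows.
#'
#' Residuals heavy in one tail — e.g. from a taxon with many
#' zero-abundance months mapped to a point mass by the log transform —
#' drive rejections for that taxon specifically.
#'
#' @param tr a `mar_trajectory` with residuals stored per window.
#' @param alpha nominal level before correction (default 0.05).
#' @param m_convention `"pooled"` (m = windows x taxa) or `"per_taxon"`
#'   (m = windows).
#' @return List of class `normality_report`: `table` (window, taxon, W,
#'   p_value, reject), `rejections` (named per-taxon counts),
#'   `corrected_alpha`, `m`, `m_convention`, `n_windows`.
#' @export
residual_normality_scan <- function(tr, alpha = 0.05,
                                    m_convention = c("pooled", "per_taxon")) {
  stopifnot(inherits(tr, "mar_trajectory"))
  m_convention <- match.arg(m_convention)
  fitted <- Filter(function(r) !is.null(r$fit), tr$results)
  if (!length(fitted)) stop("trajectory has no fitted windows", call. = FALSE)
  taxa <- colnames(fitted[[1L]]$fit$residuals)
  n_win <- length(fitted)
  m <- if (m_convention == "pooled") n_win * length(taxa) else n_win
  corrected <- bonferroni_alpha(alpha, m)
  rows <- lapply(fitted, function(r) {
    res <- r$fit$residuals
    do.call(rbind, lapply(taxa, function(tx) {
      v <- res[, tx]
      sw <- shapiro_wilk(v)
      data.frame(end_time = r$end_time, taxon = tx, W = sw$W,
                 p_value = sw$p_value, reject = sw$p_value < corrected,
                 stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  rej <- tapply(tab$reject, factor(tab$taxon, levels = taxa), sum)
  structure(list(table = tab, rejections = rej, corrected_alpha = corrected,
                 m = m, m_convention = m_convention, n_windows = n_win),
            class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("<normality_report> %d windows, m = %d (%s), corrected alpha = %.3g\n",
              x$n_windows, x$m, x$m_convention, x$corrected_alpha))
  cat("rejections per taxon:\n")
  print(x$rejections)
  invisible(x)
}

#' Residual-predictor correlation scan
#'
#' The standard conditional-least-squares misfit check: within each window,
#' each equation's residual series is correlated (Pearson, two-sided test)
#' against that equation's own predictor series — the mask-included lagged
#' abundances and contemporaneous covariates. A well-specified model leaves
#' the fraction of significant correlations near the nominal alpha.
#' `pairs = "all"` instead tests residuals against every predictor column.
#'
#' Degenerate cases (constant residual or predictor within a window) have
#' an undefined correlation; they are reported as not significant with
#' `degenerate = TRUE`.
#'
#' @param tr a `mar_trajectory`.
#' @param y,u the panels the trajectory was fitted on.
#' @param alpha two-sided test level (default 0.05).
#' @param pairs `"own"` (default) or `"all"`.
#' @return List of class `correlation_report`: `fraction_significant`,
#'   `n_tests`, and `table` (window, taxon, predictor, r, p_value,
#'   significant, degenerate).
#' @export
residual_data_correlation_scan <- function(tr, y, u = NULL, alpha = 0.05,
                                           pairs = c("own", "all")) {
  stopifnot(inherits(tr, "mar_trajectory"), inherits(y, "abundance_panel"))
  pairs <- match.arg(pairs)
  q <- if (!is.null(u)) ncol(u$values) else 0L
  rows <- list()
  for (r in tr$results) {
    if (is.null(r$fit)) next
    i2 <- r$end_index
    i1 <- i2 - tr$window_size   # index of the lag-supplying observation
    lagX <- y$values[i1:(i2 - 1L), , drop = FALSE]
    Uw <- if (q) u$values[(i1 + 1L):i2, , drop = FALSE] else NULL
    mk <- r$fit$mask
    res <- r$fit$residuals
    taxa <- colnames(res)
    for (i in seq_along(taxa)) {
      preds <- if (pairs == "own") {
        c(lapply(which(mk$b[i, ]), function(j) list(nm = taxa[j], v = lagX[, j])),
          if (q) lapply(which(mk$c[i, ]), function(k)
            list(nm = colnames(Uw)[k], v = Uw[, k])))
      } else {
        c(lapply(seq_len(ncol(lagX)), function(j) list(nm = taxa[j], v = lagX[, j])),
          if (q) lapply(seq_len(q), function(k)
            list(nm = colnames(Uw)[k], v = Uw[, k])))
      }
      e <- res[, i]
      for (pr in preds) {
        ok <- !is.na(e) & !is.na(pr$v)
        degen <- sum(ok) < 3L ||
          stats::sd(e[ok]) == 0 || stats::sd(pr$v[ok]) == 0
        if (degen) {
          rows[[length(rows) + 1L]] <- data.frame(
            end_time = r$end_time, taxon = taxa[i], predictor = pr$nm,
            r = NA_real_, p_value = NA_real_, significant = FALSE,
            degenerate = TRUE, stringsAsFactors = FALSE)
        } else {
          ct <- stats::cor.test(e[ok], pr$v[ok])
          rows[[length(rows) + 1L]] <- data.frame(
            end_time = r$end_time, taxon = taxa[i], predictor = pr$nm,
            r = unname(ct$estimate), p_value = ct$p.value,
            significant = ct$p.value < alpha, degenerate = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(fraction_significant = mean(tab$significant),
                 n_tests = nrow(tab), table = tab, alpha = alpha),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d residual-predictor tests, %.2f%% significant at alpha = %g\n",
              x$n_tests, 100 * x$fraction_significant, x$alpha))
  invisible(x)
}

#' Normal QQ pairs for a residual vector
#'
#' Pairs the observed order statistics with standard-normal quantiles at
#' plotting positions `(i - 0.5)/n`, ready for a quantile-quantile plot.
#'
#' @param residuals numeric vector, `n >= 3` non-missing values.
#' @return Data frame with columns `theoretical`, `observed`, `n` rows.
#' @export
qq_export <- function(residuals) {
  x <- sort(residuals[!is.na(residuals)])
  n <- length(x)
  if (n < 3L) stop("need at least 3 residuals", call. = FALSE)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n), observed = x)
}
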