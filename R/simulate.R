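#' Simulate a stationary MAR(1) panel
#'
#' Iterates `X_t = A + B X_{t-1} + C U_t + E_t` forward from `x0`, with
#' process errors drawn independently per taxon from mean-zero normals with
#' variances `sigma2`. Seeded and reproducible: identical seeds give
#' identical panels.
#'
#' @param params a [mar_params()].
#' @param T number of time steps (>= 2).
#' @param x0 initial state (`p`-vector); defaults to the stationary mean
#'   `(I - B)^{-1} A` when the spectral radius is below 1, else zeros.
#' @param u a [covariate_panel()] with `T` rows, or `NULL` when `q = 0`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param taxon_names optional taxon labels.
#' @return An [abundance_panel()] of the simulated log abundances.
#' @export
simulate_mar <- function(params, T, x0 = NULL, u = NULL, seed = NULL,
                         taxon_names = NULL) {
  stopifnot(inherits(params, "mar_params"))
  T <- as.integer(T)
  if (T < 2L) stop("T must be >= 2", call. = FALSE)
  p <- length(params$a)
  q <- ncol(params$c)
  if (q > 0L) {
    if (is.null(u) || !inherits(u, "covariate_panel") || nrow(u$values) != T ||
        ncol(u$values) != q) {
      stop("model has covariates: supply a covariate panel with T rows and q columns",
           call. = FALSE)
    }
  }
  if (is.null(x0)) {
    lam <- stability_lambda(params$b)
    x0 <- if (lam < 1) drop(solve(diag(p) - params$b, params$a)) else rep(0, p)
  }
  if (length(x0) != p) stop("x0 has wrong length", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sd_e <- sqrt(params$sigma2)
  X <- matrix(NA_real_, T, p)
  X[1L, ] <- x0
  E <- matrix(stats::rnorm((T - 1L) * p, sd = rep(sd_e, each = T - 1L)), T - 1L, p)
  for (t in 2:T) {
    mu <- params$a + params$b %*% X[t - 1L, ]
    if (q) mu <- mu + params$c %*% u$values[t, ]
    X[t, ] <- mu + E[t - 1L, ]
  }
  if (is.null(taxon_names)) {
    taxon_names <- names(params$a)
    if (is.null(taxon_names)) taxon_names <- paste0("x", seq_len(p))
  }
  colnames(X) <- taxon_names
  abundance_panel(X, times = if (!is.null(u)) u$labels else NULL)
}

#' Configuration for a regime-shifting simulation
#'
#' @param params list of [mar_params()], one per regime (length
#'   `length(breakpoints) + 1`), dimensionally consistent.
#' @param breakpoints strictly increasing time steps inside `(1, T)`; the
#'   step at which each new regime takes effect.
#' @param T total number of steps.
#' @param x0 initial state, or `NULL` for the first regime's stationary mean.
#' @param u shared [covariate_panel()] or `NULL`.
#' @param seed integer seed.
#' @return A list of class `regime_config`.
#' @export
regime_config <- function(params, breakpoints = integer(0), T, x0 = NULL,
                          u = NULL, seed = 1L) {
  if (inherits(params, "mar_params")) params <- list(params)
  breakpoints <- as.integer(breakpoints)
  T <- as.integer(T)
  if (length(params) != length(breakpoints) + 1L) {
    stop("need one parameter set per regime (breakpoints + 1)", call. = FALSE)
  }
  if (length(breakpoints) &&
      (any(diff(breakpoints) <= 0L) || any(breakpoints <= 1L | breakpoints >= T))) {
    stop("breakpoints must be strictly increasing and inside (1, T)", call. = FALSE)
  }
  p <- length(params[[1L]]$a)
  q <- ncol(params[[1L]]$c)
  for (pm in params) {
    if (length(pm$a) != p || ncol(pm$c) != q) {
      stop("regime parameter sets are not dimensionally consistent", call. = FALSE)
    }
  }
  structure(list(params = params, breakpoints = breakpoints, T = T,
                 x0 = x0, u = u, seed = as.integer(seed)),
            class = "regime_config")
}

#' Simulate a regime-shifting MAR(1) panel
#'
#' Piecewise-constant parameters switch at the configured breakpoints; the
#' state carries across breakpoints (no reset). With zero breakpoints this
#' is identical in law to [simulate_mar()]. The true parameter set active at
#' every step is returned for scoring estimator bias.
#'
#' @param cfg a [regime_config()].
#' @return List with `panel` (an [abundance_panel()]), `u` (the covariate
#'   panel or `NULL`), and `truth`: `regime` (integer per step), `params`
#'   (per-regime [mar_params()]), `lambda` (per-regime spectral radii) and
#'   `breakpoints`.
#' @export
simulate_regime_shift <- function(cfg) {
  stopifnot(inherits(cfg, "regime_config"))
  p <- length(cfg$params[[1L]]$a)
  q <- ncol(cfg$params[[1L]]$c)
  Tn <- cfg$T
  regime <- findInterval(seq_len(Tn), c(1L, cfg$breakpoints))
  x0 <- cfg$x0
  if (is.null(x0)) {
    pm1 <- cfg$params[[1L]]
    lam <- stability_lambda(pm1$b)
    x0 <- if (lam < 1) drop(solve(diag(p) - pm1$b, pm1$a)) else rep(0, p)
  }
  set.seed(cfg$seed)
  X <- matrix(NA_real_, Tn, p)
  X[1L, ] <- x0
  for (t in 2:Tn) {
    pm <- cfg$params[[regime[t]]]
    mu <- pm$a + pm$b %*% X[t - 1L, ]
    if (q) mu <- mu + pm$c %*% cfg$u$values[t, ]
    X[t, ] <- mu + stats::rnorm(p, sd = sqrt(pm$sigma2))
  }
  nm <- names(cfg$params[[1L]]$a)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  colnames(X) <- nm
  panel <- abundance_panel(X, times = if (!is.null(cfg$u)) cfg$u$labels else NULL)
  list(panel = panel, u = cfg$u,
       truth = list(regime = regime, params = cfg$params,
                    lambda = vapply(cfg$params, function(pm)
                      stability_lambda(pm$b), numeric(1)),
                    breakpoints = cfg$breakpoints))
}

# Generating parameters for the synthetic Lake-Washington-like community.
# Taxa: DG (diatoms/greens), NDC (non-daphnid crustaceans), Daphnia,
# Oscillatoria. Covariates: season, temp_anomaly, phosphorus (standardized).
# Three phases: eutrophic / transition / clear-water. Interaction magnitudes
# sit in the ranges a moving-window fit reports for this food web; the
# transition phase has the largest spectral radius so instability peaks
# mid-series. Intrinsic growth vectors are solved from target stationary
# log-abundance means via A = (I - B) mu.
lw_truth_params <- function() {
  taxa <- c("DG", "NDC", "Daphnia", "Oscillatoria")
  covs <- c("season", "temp_anomaly", "phosphorus")
  sigma2 <- c(DG = 0.16, NDC = 0.12, Daphnia = 0.20, Oscillatoria = 0.25)

  C <- matrix(c(
    0.40, 0.10, 0.15,
    0.20, 0.10, 0.00,
    0.30, 0.10, 0.00,
    0.20, 0.10, 0.25), 4, 3, byrow = TRUE,
    dimnames = list(taxa, covs))

  B1 <- matrix(c(  # eutrophic: Oscillatoria suppresses Daphnia and DG
    0.50, 0.00, -0.05, -0.30,
    0.10, 0.70, -0.05,  0.00,
    0.10, 0.20,  0.30, -0.50,
   -0.10, 0.00, -0.10,  0.80), 4, 4, byrow = TRUE,
    dimnames = list(taxa, taxa))
  mu1 <- c(2.0, 1.5, -0.5, 3.0)

  B2 <- matrix(c(  # transition: weak density dependence, peak instability
    0.65, 0.00, -0.10, -0.30,
    0.10, 0.80, -0.10,  0.00,
    0.10, 0.20,  0.50, -0.60,
   -0.10, 0.00, -0.05,  0.88), 4, 4, byrow = TRUE,
    dimnames = list(taxa, taxa))
  mu2 <- c(2.0, 1.5, 0.5, 2.0)

  B3 <- matrix(c(  # clear-water: Daphnia structures the community
    0.55, 0.00, -0.40, -0.05,
    0.10, 0.60, -0.30,  0.00,
    0.10, 0.10,  0.60,  0.00,
    0.00, 0.00, -0.10,  0.40), 4, 4, byrow = TRUE,
    dimnames = list(taxa, taxa))
  mu3 <- c(1.5, 1.5, 2.0, -0.3)

  mk <- function(B, mu) mar_params(drop((diag(4) - B) %*% mu), B, C, sigma2)
  list(regimes = list(mk(B1, mu1), mk(B2, mu2), mk(B3, mu3)),
       breakpoints = c(169L, 241L), taxa = taxa)
}

# Synthetic monthly covariates for the fixture: a seasonal temperature cycle
# with anomalies and a mild warming trend, and a phosphorus series declining
# early (nutrient diversion) then flat. Returned on native scales.
lw_covariate_series <- function(T, start_month = c(1962L, 1L)) {
  months <- month_label(seq(start_month[1L] * 12L + start_month[2L] - 1L,
                            length.out = T))
  m <- seq_len(T)
  cal <- (month_index(months) %% 12L) + 1L
  temperature <- 11 + 6.5 * sin(2 * pi * (cal - 4) / 12) +
    0.002 * m + stats::rnorm(T, sd = 1.0)
  phosphorus <- pmax(15 + (60 - 15) * exp(-pmax(m - 12, 0) / 40), 0) +
    stats::rnorm(T, sd = 3)
  list(months = months, temperature = temperature, phosphorus = phosphorus)
}

#' Synthetic Lake-Washington-like community fixture
#'
#' Generates a 396-step (33 years, monthly) four-guild plankton panel — DG
#' (diatoms and green algae), NDC (non-daphnid cladocerans and non-cladoceran
#' crustaceans), Daphnia, and the cyanobacterium Oscillatoria — with the
#' qualitative structure of a lake recovering from nutrient loading: an
#' early Oscillatoria-dominated regime with strong negative Oscillatoria
#' effects on Daphnia and DG, a transition phase of peak instability, and a
#' late Daphnia-dominated regime with negative Daphnia effects on DG and
#' NDC. Covariates are a seasonal temperature signal with anomalies and a
#' declining phosphorus series, processed through
#' [build_covariate_panel()].
#'
#' Daphnia is rare early and Oscillatoria rare late; abundances below a
#' per-taxon detection floor are recorded as zero counts and then mapped
#' through the [log_abundance()] zero policy, mimicking months when a taxon
#' was present but absent from samples (and producing the one-sided residual
#' tails such zeros leave).
#'
#' @param seed integer seed.
#' @param zero_policy passed to [log_abundance()].
#' @return List with `y` (an [abundance_panel()], 396 x 4), `u` (a
#'   [covariate_panel()], 396 x 3), `mask` (the
#'   [default_lake_washington_mask()]), and `truth` (per-regime
#'   [mar_params()], per-step regime ids, per-regime spectral radii,
#'   breakpoints, detection floors).
#' @export
lake_washington_fixture <- function(seed = 1L, zero_policy = "offset") {
  tp <- lw_truth_params()
  T <- 396L
  set.seed(as.integer(seed))
  cov_raw <- lw_covariate_series(T)
  u <- build_covariate_panel(cov_raw$temperature, cov_raw$phosphorus,
                             cov_raw$months)
  cfg <- regime_config(tp$regimes, tp$breakpoints, T = T, u = u,
                       seed = as.integer(seed) + 1L)
  sim <- simulate_regime_shift(cfg)

  # detection floors (count scale): Daphnia unobserved in many early months,
  # Oscillatoria in many late months
  floors <- c(DG = 0, NDC = 0, Daphnia = exp(-0.4), Oscillatoria = exp(-0.1))
  counts <- exp(sim$panel$values)
  for (j in seq_along(floors)) counts[counts[, j] < floors[j], j] <- 0
  y <- log_abundance(data.frame(month = cov_raw$months, counts,
                                check.names = FALSE),
                     zero_policy = zero_policy)

  list(y = y, u = u, mask = default_lake_washington_mask(),
       truth = list(params = tp$regimes, regime = sim$truth$regime,
                    lambda = sim$truth$lambda, breakpoints = tp$breakpoints,
                    floors = floors))
}

#' Window-size accuracy experiment
#'
#' Quantifies the precision/accuracy trade-off that governs window-size
#' choice: for each replicate a stationary panel is simulated from `params`
#' and each candidate window size is fitted at a fixed anchor (the last
#' `size + 1` observations), recording each coefficient's error against the
#' generating value. Bias and RMSE per coefficient and window size are
#' aggregated over replicates.
#'
#' @param params generating [mar_params()].
#' @param sizes window sizes to compare (each `< T`).
#' @param n_reps number of replicates.
#' @param T simulated series length (`>= max(sizes) + 1`).
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param u optional [covariate_panel()] with `T` rows.
#' @param mask optional [mask_spec()].
#' @param x0 initial state passed to [simulate_mar()].
#' @return Data frame with columns `window_size`, `coefficient` (e.g.
#'   `"b[Daphnia,Oscillatoria]"`), `truth`, `bias`, `rmse`,
#'   `median_abs_error`, `n_ok`
#'   (replicates with a successful fit).
#' @export
window_size_experiment <- function(params, sizes, n_reps, T, seed = 1L,
                                   u = NULL, mask = NULL, x0 = NULL) {
  sizes <- as.integer(sizes)
  if (any(sizes >= T)) stop("all window sizes must be < T", call. = FALSE)
  p <- length(params$a)
  q <- ncol(params$c)
  if (is.null(mask)) mask <- full_mask(p, q)
  ids <- coef_ids(params, mask)
  errs <- array(NA_real_, c(n_reps, length(sizes), length(ids$id)))
  for (r in seq_len(n_reps)) {
    pan <- simulate_mar(params, T, x0 = x0, u = u, seed = as.integer(seed) + r)
    for (s in seq_along(sizes)) {
      i1 <- T - sizes[s]   # last size+1 observations
      ys <- panel_slice(pan, i1, T)
      us <- if (!is.null(u)) panel_slice(u, i1, T) else NULL
      fit <- tryCatch(fit_mar(ys, us, mask), error = function(e) NULL)
      if (is.null(fit)) next
      errs[r, s, ] <- coef_values(fit$params, mask) - ids$truth
    }
  }
  rows <- do.call(rbind, lapply(seq_along(sizes), function(s) {
    e <- errs[, s, , drop = FALSE]
    data.frame(window_size = sizes[s], coefficient = ids$id,
               truth = ids$truth,
               bias = apply(e, 3L, mean, na.rm = TRUE),
               rmse = apply(e, 3L, function(v) sqrt(mean(v^2, na.rm = TRUE))),
               median_abs_error = apply(e, 3L, function(v)
                 stats::median(abs(v), na.rm = TRUE)),
               n_ok = apply(e, 3L, function(v) sum(!is.na(v))),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

# Flatten the mask-included coefficients of a parameter set, with ids.
coef_ids <- function(params, mask) {
  taxa <- names(params$a)
  if (is.null(taxa)) taxa <- paste0("x", seq_along(params$a))
  covs <- colnames(params$c)
  id <- c(sprintf("a[%s]", taxa),
          unlist(lapply(seq_along(taxa), function(i)
            sprintf("b[%s,%s]", taxa[i], taxa[mask$b[i, ]])), use.names = FALSE),
          if (ncol(mask$c))
            unlist(lapply(seq_along(taxa), function(i)
              sprintf("c[%s,%s]", taxa[i], covs[mask$c[i, ]])), use.names = FALSE))
  list(id = id, truth = coef_values(params, mask))
}

coef_values <- function(params, mask) {
  c(params$a, t(params$b)[t(mask$b)],
    if (ncol(mask$c)) t(params$c)[t(mask$c)])
}

#' Transition-bias experiment
#'
#' Measures the bias of moving-window estimates while the system crosses a
#' regime boundary: for each replicate a regime-shifting panel is simulated
#' and fitted with a moving window, and each tracked coefficient's signed
#' error (estimate minus the true value of the regime active at the window
#' end) is recorded as a function of the window-end position relative to
#' the first breakpoint. Windows wholly inside a regime should be unbiased;
#' windows straddling the breakpoint average the two regimes.
#'
#' @param cfg a [regime_config()] with at least one breakpoint.
#' @param w window size.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param mask optional [mask_spec()].
#' @param coefficients optional character vector of coefficient ids (as in
#'   [window_size_experiment()]) to track; default all B entries.
#' @return Data frame with columns `offset` (window end minus breakpoint),
#'   `coefficient`, `mean_estimate`, `mean_error`, `se` (Monte-Carlo
#'   standard error of the mean error), `n_ok`.
#' @export
transition_bias_experiment <- function(cfg, w, n_reps, seed = 1L, mask = NULL,
                                       coefficients = NULL) {
  stopifnot(inherits(cfg, "regime_config"))
  if (!length(cfg$breakpoints)) stop("config needs at least one breakpoint", call. = FALSE)
  p <- length(cfg$params[[1L]]$a)
  q <- ncol(cfg$params[[1L]]$c)
  if (is.null(mask)) mask <- full_mask(p, q)
  ids <- coef_ids(cfg$params[[1L]], mask)
  keep <- if (is.null(coefficients)) grep("^b\\[", ids$id) else
    match(coefficients, ids$id)
  if (anyNA(keep)) stop("unknown coefficient id", call. = FALSE)
  bp <- cfg$breakpoints[1L]
  win <- enumerate_windows(cfg$T, w)
  truth_by_regime <- vapply(cfg$params, coef_values, numeric(length(ids$id)),
                            mask = mask)
  est <- array(NA_real_, c(n_reps, nrow(win), length(keep)))
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg; cfg_r$seed <- as.integer(seed) + r
    sim <- simulate_regime_shift(cfg_r)
    tr <- moving_window_fit(sim$panel, sim$u, mask, w = w)
    for (k in seq_len(nrow(win))) {
      f <- tr$results[[k]]$fit
      if (!is.null(f)) est[r, k, ] <- coef_values(f$params, mask)[keep]
    }
  }
  regime_at_end <- findInterval(win$response_end, c(1L, cfg$breakpoints))
  rows <- do.call(rbind, lapply(seq_len(nrow(win)), function(k) {
    tru <- truth_by_regime[keep, regime_at_end[k]]
    e <- sweep(est[, k, , drop = FALSE], 3L, tru)[, 1L, , drop = TRUE]
    e <- matrix(e, nrow = n_reps)
    data.frame(offset = win$response_end[k] - bp,
               coefficient = ids$id[keep],
               mean_estimate = colMeans(matrix(est[, k, ], nrow = n_reps), na.rm = TRUE),
               mean_error = colMeans(e, na.rm = TRUE),
               se = apply(e, 2L, function(v)
                 stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
               n_ok = apply(e, 2L, function(v) sum(!is.na(v))),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}
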