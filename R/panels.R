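#' Time-indexed abundance panel
#'
#' An `abundance_panel` holds a `T x p` matrix of (typically natural-log)
#' abundances on a strictly increasing, equally spaced time index. Missing
#' observations are stored as `NA` and are never silently treated as zero;
#' downstream fitting drops affected regression rows equation by equation.
#'
#' @param values numeric matrix, `T` rows (time) by `p` columns (taxa).
#' @param times time index: numeric vector of length `T`, equally spaced, or
#'   character `"YYYY-MM"` month labels (consecutive months required).
#' @param taxon_names optional character vector of `p` taxon labels; defaults
#'   to `colnames(values)` or `x1..xp`.
#' @return An object of class `abundance_panel` with elements `values`
#'   (matrix with taxa as column names), `times` (numeric index) and
#'   `labels` (display labels for the time axis).
#' @export
abundance_panel <- function(values, times = NULL, taxon_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("abundance values must be numeric", call. = FALSE)
  if (ncol(values) < 1L) stop("panel needs at least one taxon column", call. = FALSE)
  tm <- resolve_times(times, nrow(values))
  if (is.null(taxon_names)) {
    taxon_names <- colnames(values)
    if (is.null(taxon_names)) taxon_names <- paste0("x", seq_len(ncol(values)))
  }
  if (length(taxon_names) != ncol(values)) {
    stop("taxon_names length does not match number of columns", call. = FALSE)
  }
  colnames(values) <- taxon_names
  rownames(values) <- tm$labels
  structure(list(values = values, times = tm$index, labels = tm$labels),
            class = "abundance_panel")
}

#' Time-indexed environmental covariate panel
#'
#' Same layout as [abundance_panel()] but for environmental drivers. Model
#' fitting assumes covariates have been standardized over the full series
#' (mean 0, sample SD 1); [standardize()] and [build_covariate_panel()]
#' produce such columns. Standardization is checked lazily at fit time, not
#' here, so intermediate unstandardized panels can exist.
#'
#' @inheritParams abundance_panel
#' @param covariate_names optional character vector of `q` labels.
#' @return An object of class `covariate_panel`.
#' @export
covariate_panel <- function(values, times = NULL, covariate_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("covariate values must be numeric", call. = FALSE)
  tm <- resolve_times(times, nrow(values))
  if (is.null(covariate_names)) {
    covariate_names <- colnames(values)
    if (is.null(covariate_names)) covariate_names <- paste0("u", seq_len(ncol(values)))
  }
  if (length(covariate_names) != ncol(values)) {
    stop("covariate_names length does not match number of columns", call. = FALSE)
  }
  colnames(values) <- covariate_names
  rownames(values) <- tm$labels
  structure(list(values = values, times = tm$index, labels = tm$labels),
            class = "covariate_panel")
}

# Normalize a user-supplied time index to a numeric, equally spaced index
# plus display labels. Accepts NULL (1..T), numeric, or "YYYY-MM" strings.
resolve_times <- function(times, T) {
  if (T < 1L) stop("panel needs at least one row", call. = FALSE)
  if (is.null(times)) {
    return(list(index = seq_len(T), labels = as.character(seq_len(T))))
  }
  if (length(times) != T) stop("time index length does not match rows", call. = FALSE)
  if (is.character(times)) {
    if (all(grepl("^\\d{4}-\\d{2}$", times))) {
      idx <- month_index(times)
      if (anyNA(idx)) stop("unparseable YYYY-MM time labels", call. = FALSE)
      if (any(diff(idx) != 1L)) {
        stop("month labels must be consecutive calendar months", call. = FALSE)
      }
      return(list(index = idx, labels = times))
    }
    suppressWarnings(num <- as.numeric(times))
    if (anyNA(num)) stop("unparseable time labels", call. = FALSE)
    times <- num
  }
  times <- as.numeric(times)
  if (anyNA(times)) stop("time index contains NA", call. = FALSE)
  d <- diff(times)
  if (T > 1L) {
    if (any(d <= 0)) stop("time index must be strictly increasing", call. = FALSE)
    if (max(d) - min(d) > 1e-8 * max(1, abs(d[1]))) {
      stop("time index must be equally spaced", call. = FALSE)
    }
  }
  list(index = times, labels = as.character(times))
}

# "YYYY-MM" -> months since year 0
month_index <- function(labels) {
  ok <- grepl("^\\d{4}-\\d{2}$", labels)
  out <- rep(NA_integer_, length(labels))
  y <- as.integer(substr(labels[ok], 1, 4))
  m <- as.integer(substr(labels[ok], 6, 7))
  bad <- m < 1L | m > 12L
  out[ok] <- ifelse(bad, NA_integer_, y * 12L + (m - 1L))
  out
}

month_label <- function(index) {
  y <- index %/% 12L
  m <- index %% 12L + 1L
  sprintf("%04d-%02d", y, m)
}

#' Inclusion masks for the interaction and covariate matrices
#'
#' A `mask_spec` records which entries of the interaction matrix `B` (p x p)
#' and the covariate-effect matrix `C` (p x q) are estimated; `FALSE` entries
#' are a priori excluded and are exactly zero in every fit. The diagonal of
#' the `B` mask must be all `TRUE`: density dependence is always estimated.
#'
#' @param b_mask logical `p x p` matrix (rows = responses, columns =
#'   predictor taxa).
#' @param c_mask logical `p x q` matrix (rows = responses, columns =
#'   covariates); may have zero columns when there are no covariates.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(b_mask, c_mask = matrix(logical(0), nrow(b_mask), 0)) {
  b_mask <- as.matrix(b_mask); storage.mode(b_mask) <- "logical"
  c_mask <- as.matrix(c_mask); storage.mode(c_mask) <- "logical"
  if (nrow(b_mask) != ncol(b_mask)) stop("b_mask must be square", call. = FALSE)
  if (anyNA(b_mask) || anyNA(c_mask)) stop("masks must not contain NA", call. = FALSE)
  if (!all(diag(b_mask))) {
    stop("diagonal of b_mask must be TRUE: density dependence is always estimated",
         call. = FALSE)
  }
  if (nrow(c_mask) != nrow(b_mask)) {
    stop("c_mask must have one row per taxon", call. = FALSE)
  }
  structure(list(b = b_mask, c = c_mask), class = "mask_spec")
}

#' Full (all-inclusive) mask for given dimensions
#'
#' @param p number of taxa.
#' @param q number of covariates.
#' @return A `mask_spec` with every coefficient estimated.
#' @export
full_mask <- function(p, q = 0L) {
  mask_spec(matrix(TRUE, p, p), matrix(TRUE, p, q))
}

#' MAR(1) parameter set
#'
#' Container for the parameters of the model
#' `X_t = A + B X_{t-1} + C U_t + E_t`, with `E_t` independent mean-zero
#' normals with per-taxon variances `sigma2` (diagonal process-error
#' covariance).
#'
#' @param a numeric `p`-vector of intrinsic growth constants.
#' @param b numeric `p x p` interaction matrix.
#' @param c numeric `p x q` covariate-effect matrix (0 columns if none).
#' @param sigma2 numeric `p`-vector of process-error variances (>= 0).
#' @return An object of class `mar_params`.
#' @export
mar_params <- function(a, b, c = matrix(0, length(a), 0), sigma2 = rep(0, length(a))) {
  a <- as.numeric(a)
  b <- as.matrix(b)
  c <- as.matrix(c)
  sigma2 <- as.numeric(sigma2)
  p <- length(a)
  if (!all(dim(b) == c(p, p))) stop("b must be p x p", call. = FALSE)
  if (nrow(c) != p) stop("c must have p rows", call. = FALSE)
  if (length(sigma2) != p) stop("sigma2 must have length p", call. = FALSE)
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative", call. = FALSE)
  taxa <- if (!is.null(rownames(b))) rownames(b) else names(a)
  if (!is.null(taxa)) {
    names(a) <- names(sigma2) <- taxa
    dimnames(b) <- list(taxa, taxa)
    rownames(c) <- taxa
  }
  structure(list(a = a, b = b, c = c, sigma2 = sigma2), class = "mar_params")
}

#' @export
print.abundance_panel <- function(x, ...) {
  cat(sprintf("<abundance_panel> %d time steps x %d taxa (%s .. %s)\n",
              nrow(x$values), ncol(x$values), x$labels[1],
              x$labels[length(x$labels)]))
  cat("taxa:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.covariate_panel <- function(x, ...) {
  cat(sprintf("<covariate_panel> %d time steps x %d covariates\n",
              nrow(x$values), ncol(x$values)))
  cat("covariates:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mask_spec <- function(x, ...) {
  cat(sprintf("<mask_spec> B: %d/%d estimated; C: %d/%d estimated\n",
              sum(x$b), length(x$b), sum(x$c), max(1L, length(x$c)) * (length(x$c) > 0)))
  invisible(x)
}

# Check that an abundance panel and covariate panel share a time index.
check_alignment <- function(y, u) {
  if (is.null(u)) return(invisible(TRUE))
  if (!identical(length(y$times), length(u$times)) ||
      any(abs(y$times - u$times) > 1e-8)) {
    stop("abundance and covariate panels are not time-aligned", call. = FALSE)
  }
  invisible(TRUE)
}

#' Subset a panel to a contiguous row range
#'
#' Returns the rows `i1:i2` of an abundance or covariate panel, keeping the
#' class and time index. Used to extract single windows for inspection or
#' bootstrapping.
#'
#' @param panel an [abundance_panel()] or [covariate_panel()].
#' @param i1,i2 first and last row (1-based, inclusive).
#' @return A panel of the same class.
#' @export
panel_slice <- function(panel, i1, i2) {
  out <- panel
  out$values <- panel$values[i1:i2, , drop = FALSE]
  out$times <- panel$times[i1:i2]
  out$labels <- panel$labels[i1:i2]
  out
}
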