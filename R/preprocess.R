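#' Aggregate raw sampling records into monthly means
#'
#' Field monitoring records collected at irregular intervals (daily, weekly,
#' fortnightly ...) are averaged within each calendar month per variable.
#' Months with no samples for a variable are missing (`NA`); the output time
#' index is contiguous from the first to the last observed month.
#'
#' @param raw data frame with columns `timestamp` (a `Date`, or a string
#'   parseable as `YYYY-MM-DD` or `YYYY-MM`), `variable` (label) and `value`
#'   (numeric).
#' @return Wide data frame: column `month` (`"YYYY-MM"`) plus one numeric
#'   column per variable, one row per calendar month.
#' @export
aggregate_monthly <- function(raw) {
  stopifnot(is.data.frame(raw),
            all(c("timestamp", "variable", "value") %in% names(raw)))
  ts <- raw$timestamp
  if (inherits(ts, "Date")) {
    mon <- format(ts, "%Y-%m")
  } else {
    ts <- as.character(ts)
    mon <- ifelse(grepl("^\\d{4}-\\d{2}$", ts), ts,
                  format(as.Date(ts, optional = TRUE), "%Y-%m"))
    if (anyNA(mon)) {
      bad <- which(is.na(mon))[1L]
      stop(sprintf("unparseable timestamp at record %d: '%s'", bad, ts[bad]),
           call. = FALSE)
    }
  }
  idx <- month_index(mon)
  if (anyNA(idx)) stop("unparseable month labels", call. = FALSE)
  all_months <- seq(min(idx), max(idx))
  vars <- unique(as.character(raw$variable))
  out <- data.frame(month = month_label(all_months), stringsAsFactors = FALSE)
  for (v in vars) {
    sel <- raw$variable == v
    means <- tapply(raw$value[sel], idx[sel], mean)
    col <- rep(NA_real_, length(all_months))
    col[match(as.integer(names(means)), all_months)] <- as.numeric(means)
    out[[v]] <- col
  }
  out
}

#' Log-transform a monthly abundance panel
#'
#' Applies the natural log to abundances, with a configurable policy for
#' zero counts (months when a taxon was present in the lake but absent from
#' samples). The default adds, per taxon and only when that taxon has zeros,
#' an offset delta equal to half its smallest positive observed value
#' (`ln(x + delta)`); alternatives treat zeros as missing, or use a fixed
#' user-supplied delta for taxa with zeros. The policy and per-taxon deltas
#' are recorded in the result's `zero_policy` attribute.
#'
#' @param x wide monthly data frame as produced by [aggregate_monthly()]
#'   (column `month` plus taxon columns), or a numeric matrix with
#'   `"YYYY-MM"` rownames.
#' @param zero_policy `"offset"` (default), `"missing"`, or `"fixed"`.
#' @param delta fixed offset when `zero_policy = "fixed"`.
#' @return An [abundance_panel()] of log abundances, with attribute
#'   `zero_policy` documenting the policy and the delta used per taxon.
#' @export
log_abundance <- function(x, zero_policy = c("offset", "missing", "fixed"),
                          delta = NULL) {
  zero_policy <- match.arg(zero_policy)
  if (is.data.frame(x)) {
    months <- as.character(x$month)
    vals <- as.matrix(x[, setdiff(names(x), "month"), drop = FALSE])
  } else {
    vals <- as.matrix(x)
    months <- rownames(vals)
  }
  if (any(vals < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  if (zero_policy == "fixed" && (is.null(delta) || delta <= 0)) {
    stop("zero_policy = 'fixed' needs a positive delta", call. = FALSE)
  }
  deltas <- stats::setNames(numeric(ncol(vals)), colnames(vals))
  out <- vals
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    has_zero <- any(v == 0, na.rm = TRUE)
    if (has_zero) {
      if (zero_policy == "missing") {
        v[v == 0] <- NA_real_
      } else {
        d <- if (zero_policy == "fixed") delta else {
          pos <- v[!is.na(v) & v > 0]
          if (length(pos) == 0L) {
            stop(sprintf("taxon '%s' has no positive observations", colnames(vals)[j]),
                 call. = FALSE)
          }
          min(pos) / 2
        }
        deltas[j] <- d
        v <- v + d
      }
    }
    out[, j] <- log(v)
  }
  pan <- abundance_panel(out, times = months)
  attr(pan, "zero_policy") <- list(policy = zero_policy, delta = deltas)
  pan
}

#' Climatology/anomaly decomposition of a monthly series
#'
#' Splits a monthly covariate into a mean seasonal signal (the climatology:
#' the long-term mean of each calendar month) and monthly anomalies, the
#' deviations from that signal, which carry short-term events (an unusually
#' warm July) and long-term trends.
#'
#' @param values numeric monthly series (may contain `NA`).
#' @param months `"YYYY-MM"` labels, or integer calendar months `1..12`,
#'   aligned with `values`.
#' @return A list of class `seasonal_decomposition`: `climatology`
#'   (12-vector of calendar-month means, `NA` and flagged in
#'   `missing_months` when a calendar month is entirely unobserved),
#'   `anomalies` and `seasonal` (the climatology expanded along the series).
#' @export
seasonal_decompose <- function(values, months) {
  values <- as.numeric(values)
  m <- calendar_month(months)
  if (length(m) != length(values)) stop("months and values lengths differ", call. = FALSE)
  climatology <- rep(NA_real_, 12L)
  for (k in 1:12) {
    v <- values[m == k & !is.na(values)]
    if (length(v)) climatology[k] <- mean(v)
  }
  missing_months <- which(is.na(climatology))
  if (length(missing_months)) {
    warning(sprintf("calendar month(s) entirely unobserved: %s",
                    paste(missing_months, collapse = ", ")), call. = FALSE)
  }
  seasonal <- climatology[m]
  structure(list(climatology = climatology, anomalies = values - seasonal,
                 seasonal = seasonal, missing_months = missing_months),
            class = "seasonal_decomposition")
}

calendar_month <- function(months) {
  if (is.character(months)) {
    idx <- month_index(months)
    if (anyNA(idx)) stop("unparseable YYYY-MM labels", call. = FALSE)
    idx %% 12L + 1L
  } else {
    m <- as.integer(months)
    if (any(m < 1L | m > 12L, na.rm = TRUE)) stop("calendar months must be 1..12", call. = FALSE)
    m
  }
}

#' Standardize a series to mean 0, SD 1
#'
#' Centers and scales by the sample standard deviation (`n - 1` divisor),
#' with moments computed over the non-missing entries of the full series;
#' missing entries are preserved in place.
#'
#' @param x numeric vector with at least 2 non-missing values.
#' @param name label used in error messages.
#' @return Standardized numeric vector.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  obs <- x[!is.na(x)]
  if (length(obs) < 2L) {
    stop(sprintf("'%s': need at least 2 non-missing values", name), call. = FALSE)
  }
  s <- stats::sd(obs)
  if (s == 0) stop(sprintf("'%s': zero variance", name), call. = FALSE)
  (x - mean(obs)) / s
}

#' Build the standard three-column covariate panel
#'
#' Combines surface temperature and total phosphorus into the covariate
#' layout the community model uses: `season` (the temperature climatology
#' expanded over the series, then standardized — a periodic 12-level signal
#' of long-term seasonal forcing), `temp_anomaly` (standardized monthly
#' temperature deviations from the climatology), and `phosphorus` (the raw
#' series standardized). Standardization uses the full series so that
#' moving-window fits share one covariate scale.
#'
#' @param temperature numeric monthly temperature series.
#' @param phosphorus numeric monthly total-phosphorus series.
#' @param months `"YYYY-MM"` labels aligned with both series.
#' @return A [covariate_panel()] with columns
#'   `season`, `temp_anomaly`, `phosphorus`.
#' @export
build_covariate_panel <- function(temperature, phosphorus, months) {
  dec <- seasonal_decompose(temperature, months)
  vals <- cbind(season = standardize(dec$seasonal, "season"),
                temp_anomaly = standardize(dec$anomalies, "temp_anomaly"),
                phosphorus = standardize(phosphorus, "phosphorus"))
  covariate_panel(vals, times = if (is.character(months)) months else NULL)
}
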