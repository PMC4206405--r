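#' Default interaction and covariate masks for the four-guild lake food web
#'
#' The a priori model structure for the DG / NDC / Daphnia / Oscillatoria
#' community with covariates (season, temp_anomaly, phosphorus): every
#' pairwise interaction is estimated except the effect of NDC on DG (15 of
#' 16 B entries); season and temperature anomalies act on all four guilds,
#' while phosphorus — a nutrient — can act directly only on the
#' phytoplankton guilds DG and Oscillatoria, never on the zooplankton
#' grazers NDC and Daphnia (10 of 12 C entries).
#'
#' @return A [mask_spec()] for `p = 4` taxa, `q = 3` covariates.
#' @export
default_lake_washington_mask <- function() {
  taxa <- c("DG", "NDC", "Daphnia", "Oscillatoria")
  covs <- c("season", "temp_anomaly", "phosphorus")
  b <- matrix(TRUE, 4, 4, dimnames = list(taxa, taxa))
  b["DG", "NDC"] <- FALSE
  cm <- matrix(TRUE, 4, 3, dimnames = list(taxa, covs))
  cm[c("NDC", "Daphnia"), "phosphorus"] <- FALSE
  mask_spec(b, cm)
}

#' Build a mask from named include/exclude lists
#'
#' Masks are configured by (response, predictor) NAME pairs rather than
#' indices, so a configuration survives column reordering.
#'
#' @param taxa character vector of taxon names (defines `p` and order).
#' @param covariates character vector of covariate names (defines `q`).
#' @param exclude_b list of `c(response, predictor)` pairs to drop from B.
#' @param exclude_c list of `c(response, covariate)` pairs to drop from C.
#' @return A [mask_spec()].
#' @export
mask_from_names <- function(taxa, covariates = character(0),
                            exclude_b = list(), exclude_c = list()) {
  b <- matrix(TRUE, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  cm <- matrix(TRUE, length(taxa), length(covariates),
               dimnames = list(taxa, covariates))
  for (pr in exclude_b) {
    if (!all(pr %in% taxa)) stop("unknown taxon in exclude_b", call. = FALSE)
    b[pr[1L], pr[2L]] <- FALSE
  }
  for (pr in exclude_c) {
    if (!(pr[1L] %in% taxa) || !(pr[2L] %in% covariates)) {
      stop("unknown name in exclude_c", call. = FALSE)
    }
    cm[pr[1L], pr[2L]] <- FALSE
  }
  mask_spec(b, cm)
}

#' Read a wide monthly panel CSV
#'
#' Reads a wide-format CSV with a date column (`YYYY-MM`, or a full date
#' whose year-month is used) and numeric columns, splitting columns into an
#' abundance panel and a covariate panel by name. Skipped months are filled
#' in as missing rows so the index is contiguous; blank cells become `NA`.
#'
#' @param path CSV file path.
#' @param taxa character vector naming the abundance columns.
#' @param covariates character vector naming the covariate columns (may be
#'   empty).
#' @param date_col name of the date column (default `"month"`).
#' @return List with `y` (an [abundance_panel()]) and `u` (a
#'   [covariate_panel()], or `NULL` when no covariates were requested).
#' @export
read_panel_csv <- function(path, taxa, covariates = character(0),
                           date_col = "month") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!date_col %in% names(df)) {
    stop(sprintf("date column '%s' not found", date_col), call. = FALSE)
  }
  unknown <- setdiff(c(taxa, covariates), names(df))
  if (length(unknown)) {
    stop(sprintf("columns not in file: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  raw_dates <- as.character(df[[date_col]])
  mon <- ifelse(grepl("^\\d{4}-\\d{2}$", raw_dates), raw_dates,
                substr(raw_dates, 1, 7))
  idx <- month_index(mon)
  if (anyNA(idx)) {
    stop(sprintf("unparseable date at row %d: '%s'",
                 which(is.na(idx))[1L], raw_dates[which(is.na(idx))[1L]]),
         call. = FALSE)
  }
  if (anyDuplicated(idx)) {
    stop(sprintf("duplicate month at row %d", which(duplicated(idx))[1L]),
         call. = FALSE)
  }
  for (v in c(taxa, covariates)) {
    if (!is.numeric(df[[v]])) {
      suppressWarnings(num <- as.numeric(df[[v]]))
      bad <- which(!is.na(df[[v]]) & df[[v]] != "" & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric cell in column '%s' at row %d", v, bad[1L]),
             call. = FALSE)
      }
      df[[v]] <- num
    }
  }
  all_months <- seq(min(idx), max(idx))
  pos <- match(all_months, idx)
  labels <- month_label(all_months)
  y <- abundance_panel(as.matrix(df[pos, taxa, drop = FALSE]), times = labels)
  u <- if (length(covariates)) {
    covariate_panel(as.matrix(df[pos, covariates, drop = FALSE]), times = labels)
  }
  list(y = y, u = u)
}

#' Write a trajectory as a long-format CSV
#'
#' Serializes [trajectory_to_table()] with stable column order, rows keyed
#' by window END time. A comment header records the window size and
#' failed-window count so the file is self-describing.
#'
#' @param tr a `mar_trajectory`.
#' @param path output file path.
#' @param metadata optional named list appended to the comment header.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(tr, path, metadata = NULL) {
  tab <- trajectory_to_table(tr)
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(window_size = tr$window_size,
                 n_windows = length(tr$results),
                 n_failed = nrow(tr$failed)), metadata)
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, function(v) paste(format(v), collapse = " "),
                            character(1))), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read back a trajectory CSV
#'
#' @param path file written by [write_trajectory_csv()].
#' @return The long-format data frame (comment header skipped).
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write an abundance/covariate panel pair as a wide monthly CSV
#'
#' Inverse of [read_panel_csv()]: one `month` column plus one column per
#' taxon and covariate.
#'
#' @param y an [abundance_panel()].
#' @param u a [covariate_panel()] or `NULL`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_panel_csv <- function(y, u = NULL, path) {
  df <- data.frame(month = y$labels, y$values, check.names = FALSE)
  if (!is.null(u)) {
    check_alignment(y, u)
    df <- cbind(df, as.data.frame(u$values, check.names = FALSE))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
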