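test_that("wide CSV panels round-trip through read and write", {
  fx <- lake_washington_fixture(seed = 3)
  path <- tempfile(fileext = ".csv")
  write_panel_csv(fx$y, fx$u, path)
  back <- read_panel_csv(path, taxa = colnames(fx$y$values),
                         covariates = colnames(fx$u$values))
  expect_equal(back$y$values, fx$y$values, tolerance = 1e-8)
  expect_equal(back$u$values, fx$u$values, tolerance = 1e-8)
  expect_identical(back$y$labels, fx$y$labels)
  # reading never mutates the input file
  before <- file.info(path)$size
  fit_mar(back$y, back$u, fx$mask)
  expect_identical(file.info(path)$size, before)
})

test_that("small CSVs parse with declared taxa and covariates", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("month,alg,zoop,temp",
               "1980-01,1.2,0.5,3",
               "1980-02,1.4,,4",
               "1980-04,1.1,0.7,2"), path)
  out <- read_panel_csv(path, taxa = c("alg", "zoop"), covariates = "temp")
  expect_equal(nrow(out$y$values), 4)   # skipped month inserted
  expect_true(all(is.na(out$y$values["1980-03", ])))
  expect_true(is.na(out$y$values["1980-02", "zoop"]))
  expect_equal(ncol(out$u$values), 1)

  expect_error(read_panel_csv(path, taxa = c("alg", "nope")), "nope")
  writeLines(c("month,a", "1980-01,1", "1980-01,2"), path)
  expect_error(read_panel_csv(path, taxa = "a"), "duplicate")
  writeLines(c("month,a", "1980-01,1", "1980-02,oops"), path)
  expect_error(read_panel_csv(path, taxa = "a"), "non-numeric")
})

test_that("the default four-guild masks match the a priori food web", {
  mk <- default_lake_washington_mask()
  expect_equal(sum(mk$b), 15)
  expect_false(mk$b["DG", "NDC"])
  expect_true(all(diag(mk$b)))
  expect_equal(sum(mk$c), 10)
  expect_false(mk$c["NDC", "phosphorus"])
  expect_false(mk$c["Daphnia", "phosphorus"])
  expect_true(all(mk$c[, c("season", "temp_anomaly")]))
  # 4 intercepts + 15 B + 10 C = 29 estimated coefficients per window
  expect_equal(4 + sum(mk$b) + sum(mk$c), 29)
})

test_that("masks configured by name survive column reordering", {
  mk <- mask_from_names(c("b", "a"), c("v"),
                        exclude_b = list(c("a", "b")),
                        exclude_c = list(c("b", "v")))
  expect_false(mk$b["a", "b"])
  expect_true(mk$b["b", "a"])
  expect_false(mk$c["b", "v"])
  expect_error(mask_from_names(c("a", "b"), exclude_b = list(c("a", "zz"))),
               "unknown")
  expect_error(mask_spec(matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2)), "diagonal")
})

test_that("trajectory CSVs round-trip and carry the window-end convention", {
  truth <- random_small_params(2, 0, seed = 401)
  pan <- simulate_mar(truth, T = 40, seed = 402)
  tr <- moving_window_fit(pan, w = 30,
                          boot = boot_settings(n_boot = 25, seed = 3))
  tab <- trajectory_to_table(tr)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$estimate, tab$estimate, tolerance = 1e-10)
  expect_identical(names(back), names(tab))
  # one lambda row per window, keyed by end time
  lam_rows <- back[back$predictor == "lambda", ]
  expect_equal(nrow(lam_rows), 10)
  expect_identical(as.character(lam_rows$end_time),
                   sapply(tr$results, `[[`, "end_time"))
  # lambda constant within each window's rows
  for (et in unique(back$end_time)) {
    expect_equal(length(unique(back$lambda[back$end_time == et])), 1)
  }
})

test_that("the CLI wires subcommands to package functions", {
  cli <- system.file("cli", "mwmar", package = "mwmar")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  tmp <- tempfile(fileext = ".csv")
  fx <- lake_washington_fixture(seed = 5)
  inp <- tempfile(fileext = ".csv")
  write_panel_csv(fx$y, fx$u, inp)
  # mwfit over the fixture: 396 - 84 = 312 windows
  out <- suppressWarnings(system2(
    rscript, c(cli, "mwfit", "--input", inp, "--default-mask",
               "--window", "84", "--nboot", "0", "--out", tmp),
    stdout = TRUE, stderr = TRUE))
  expect_equal(attr(out, "status"), NULL)
  hdr <- grep("^#", readLines(tmp), value = TRUE)
  expect_true("# n_windows: 312" %in% hdr)
  n_failed <- as.integer(sub("# n_failed: ", "",
                             grep("n_failed", hdr, value = TRUE)))
  tab <- read_trajectory_csv(tmp)
  expect_equal(length(unique(tab$end_time)), 312 - n_failed)
  # unknown flag: nonzero exit
  bad <- suppressWarnings(system2(rscript, c(cli, "mwfit", "--nonsense"),
                                  stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(bad, "status")))
  # unknown subcommand: nonzero exit and usage text
  bad2 <- suppressWarnings(system2(rscript, c(cli, "frobnicate"),
                                   stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(bad2, "status")))
  expect_true(any(grepl("usage", bad2)))
})

test_that("whole-series fit equals a single maximal window via the CLI convention", {
  truth <- random_small_params(2, 1, seed = 411)
  u <- random_covariates(50, 1, seed = 412)
  pan <- simulate_mar(truth, T = 50, u = u, seed = 413)
  whole <- fit_mar(pan, u)
  tr <- moving_window_fit(pan, u, w = 49)
  expect_equal(tr$results[[1]]$fit$params, whole$params)
})
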