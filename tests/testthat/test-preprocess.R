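test_that("monthly aggregation averages within months and keeps the index contiguous", {
  raw <- data.frame(
    timestamp = c("1962-01-05", "1962-01-20", "1962-03-02"),
    variable = "algae",
    value = c(2, 4, 10))
  m <- aggregate_monthly(raw)
  expect_equal(m$month, c("1962-01", "1962-02", "1962-03"))
  expect_equal(m$algae, c(3, NA, 10))
  expect_error(aggregate_monthly(data.frame(timestamp = "not a date",
                                            variable = "x", value = 1)),
               "unparseable")
})

test_that("mixed-frequency sampling matches hand-computed monthly means", {
  raw <- data.frame(
    timestamp = c("1970-01-01", "1970-01-08", "1970-01-15", "1970-01-22",
                  "1970-02-10", "1970-03-01", "1970-03-31"),
    variable = rep(c("temp"), 7),
    value = c(4, 6, 5, 9, 12, 3, 5))
  m <- aggregate_monthly(raw)
  expect_equal(m$temp, c(mean(c(4, 6, 5, 9)), 12, mean(c(3, 5))))
})

test_that("log transform applies the zero policy per taxon", {
  df <- data.frame(month = c("1980-01", "1980-02", "1980-03"),
                   a = c(exp(1), exp(2), exp(1.5)),
                   b = c(2, 0, 6))
  pan <- log_abundance(df)
  # no zeros in 'a': no offset applied
  expect_equal(unname(pan$values[1:2, "a"]), c(1, 2))
  # 'b' min positive is 2 -> delta 1, zero maps to ln(1) = 0
  expect_equal(unname(pan$values[2, "b"]), 0)
  expect_equal(attr(pan, "zero_policy")$delta[["b"]], 1)
  expect_equal(attr(pan, "zero_policy")$delta[["a"]], 0)

  pan_na <- log_abundance(df, zero_policy = "missing")
  expect_true(is.na(pan_na$values[2, "b"]))
  expect_equal(unname(pan_na$values[1, "b"]), log(2))

  pan_fix <- log_abundance(df, zero_policy = "fixed", delta = 0.5)
  expect_equal(unname(pan_fix$values[2, "b"]), log(0.5))
  expect_error(log_abundance(df, zero_policy = "fixed"), "delta")
  df$a[1] <- -1
  expect_error(log_abundance(df), "non-negative")
})

test_that("offset log transform is monotone", {
  set.seed(131)
  x <- sort(c(0, runif(30, 0, 50)))
  df <- data.frame(month = month_labels_seq("1990-01", length(x)), tax = x)
  pan <- log_abundance(df)
  expect_true(all(diff(pan$values[, 1]) > 0))
})

test_that("seasonal decomposition splits climatology and anomalies", {
  # exact 12-month repeating pattern: anomalies vanish
  patt <- sin(2 * pi * (1:12) / 12) * 5 + 10
  months <- month_labels_seq("1970-01", 24)
  d <- seasonal_decompose(rep(patt, 2), months)
  expect_equal(d$anomalies, rep(0, 24), tolerance = 1e-12)
  expect_equal(d$climatology, patt)

  d2 <- seasonal_decompose(rep(3.5, 24), months)
  expect_equal(d2$climatology, rep(3.5, 12))
  expect_equal(d2$anomalies, rep(0, 24))

  # 2 years, January values b+2 and b, all else b
  v <- rep(7, 24); v[1] <- 9
  d3 <- seasonal_decompose(v, months)
  expect_equal(d3$climatology[1], 8)
  expect_equal(d3$anomalies[c(1, 13)], c(1, -1))

  # anomalies sum to zero within each calendar month
  set.seed(141)
  v4 <- rnorm(60)
  d4 <- seasonal_decompose(v4, month_labels_seq("1962-03", 60))
  cal <- (mwmar:::month_index(month_labels_seq("1962-03", 60)) %% 12) + 1
  sums <- tapply(d4$anomalies, cal, sum)
  expect_lt(max(abs(sums)), 1e-8)

  # an entirely unobserved calendar month is flagged
  v5 <- rnorm(24); v5[c(2, 14)] <- NA
  expect_warning(d5 <- seasonal_decompose(v5, months), "unobserved")
  expect_equal(d5$missing_months, 2L)
})

test_that("standardization uses sample SD over observed entries and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(151)
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  xna <- x; xna[c(3, 9)] <- NA
  zna <- standardize(xna)
  expect_true(all(is.na(zna[c(3, 9)])))
  expect_equal(mean(zna, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10), "flatcov"), "flatcov")
  expect_error(standardize(c(1, NA, NA)), "non-missing")
})

test_that("the covariate panel has season, anomaly, and phosphorus columns", {
  months <- month_labels_seq("1962-01", 120)
  cal <- (mwmar:::month_index(months) %% 12) + 1
  set.seed(161)
  temp <- 10 + 6 * sin(2 * pi * (cal - 4) / 12) + rnorm(120, sd = 0.5)
  temp[55] <- temp[55] + 8   # a warm July (month 55 is July 1966)
  phos <- seq(60, 20, length.out = 120)
  u <- build_covariate_panel(temp, phos, months)
  expect_identical(colnames(u$values), c("season", "temp_anomaly", "phosphorus"))
  expect_lt(max(abs(colMeans(u$values))), 1e-10)
  expect_equal(unname(apply(u$values, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # season is 12-periodic
  expect_equal(unname(u$values[1:12, "season"]),
               unname(u$values[13:24, "season"]), tolerance = 1e-12)
  # the spiked month carries the anomaly maximum
  expect_equal(unname(which.max(u$values[, "temp_anomaly"])), 55L)
})

test_that("climatology + anomaly reconstructs the series exactly", {
  set.seed(171)
  months <- month_labels_seq("1975-06", 90)
  v <- rnorm(90, 10, 4)
  v[c(5, 40)] <- NA
  d <- seasonal_decompose(v, months)
  rec <- d$seasonal + d$anomalies
  expect_equal(rec[!is.na(v)], v[!is.na(v)], tolerance = 1e-10)
})
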