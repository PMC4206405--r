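test_that("an exactly alternating series is fit without error", {
  pan <- abundance_panel(cbind(x = c(0, 1, 0, 1, 0, 1)))
  fit <- fit_mar(pan)
  expect_equal(unname(fit$params$a), 1, tolerance = 1e-10)
  expect_equal(unname(fit$params$b[1, 1]), -1, tolerance = 1e-10)
  expect_equal(unname(fit$params$sigma2), 0, tolerance = 1e-12)
  expect_true(all(abs(fit$residuals) < 1e-10))
  # fitted dynamics predict the flip exactly
  expect_equal(unname(predict_one_step(fit$params, 1)), 0, tolerance = 1e-10)
  expect_equal(unname(predict_one_step(fit$params, 0)), 1, tolerance = 1e-10)
})

test_that("estimates recover known generating parameters on a long series", {
  truth <- mar_params(c(0, 0), matrix(c(0.5, 0, 0, 0.5), 2, 2),
                      sigma2 = c(0.1, 0.1))
  pan <- simulate_mar(truth, T = 500, seed = 7)
  fit <- fit_mar(pan)
  expect_lt(max(abs(fit$params$a - truth$a)), 0.1)
  expect_lt(max(abs(fit$params$b - truth$b)), 0.1)
  expect_lt(max(abs(fit$params$sigma2 - truth$sigma2)), 0.05)
})

test_that("CLS equals brute-force SSE minimization on small instances", {
  for (seed in 1:8) {
    p <- 1 + seed %% 3
    q <- seed %% 2
    truth <- random_small_params(p, q, seed)
    u <- random_covariates(12, q, seed + 100)
    pan <- simulate_mar(truth, T = 12, u = u, seed = seed + 200)
    fit <- fit_mar(pan, u)
    bf <- brute_force_cls(pan, u)
    expect_lt(max(abs(fit$params$a - bf$a)), 1e-6)
    expect_lt(max(abs(unname(fit$params$b) - bf$b)), 1e-6)
    if (q) expect_lt(max(abs(unname(fit$params$c) - bf$c)), 1e-6)
  }
})

test_that("masked coefficients are exactly zero and do not affect other estimates", {
  truth <- random_small_params(3, 2, seed = 11)
  u <- random_covariates(60, 2, seed = 12)
  pan <- simulate_mar(truth, T = 60, u = u, seed = 13)
  mk <- mask_spec(matrix(c(TRUE, FALSE, TRUE,
                           TRUE, TRUE, FALSE,
                           FALSE, TRUE, TRUE), 3, 3, byrow = TRUE),
                  matrix(c(TRUE, FALSE,
                           TRUE, TRUE,
                           FALSE, TRUE), 3, 2, byrow = TRUE))
  fit <- fit_mar(pan, u, mk)
  expect_identical(unname(fit$params$b[!mk$b]), rep(0, sum(!mk$b)))
  expect_identical(unname(fit$params$c[!mk$c]), rep(0, sum(!mk$c)))
  # masked fit equals the oracle constrained to the same structure
  bf <- brute_force_cls(pan, u, mk)
  expect_lt(max(abs(unname(fit$params$b) - bf$b)), 1e-6)
})

test_that("missing values are dropped casewise per equation", {
  truth <- random_small_params(2, 0, seed = 21)
  pan <- simulate_mar(truth, T = 80, seed = 22)
  pan_na <- pan
  pan_na$values[c(10, 25, 40), 1] <- NA   # holes in taxon 1 only
  fit <- fit_mar(pan_na)
  # equation 1 loses rows where its response or any lagged predictor is NA;
  # a hole at t knocks out response row t and lag row t+1, for both equations
  expect_lt(fit$n_used[1], 79)
  expect_lt(fit$n_used[2], 79)
  # residual rows at dropped positions are NA, never fabricated
  expect_true(all(is.na(fit$residuals[c(9, 10, 24, 25, 39, 40), 1])))
  # per-equation residual mean ~ 0 (intercept estimated)
  expect_lt(max(abs(colMeans(fit$residuals, na.rm = TRUE))), 1e-8)
})

test_that("degenerate designs raise errors naming the equation", {
  pan <- abundance_panel(cbind(good = rnorm(20), flat = rep(1, 20)))
  expect_error(fit_mar(pan), "degenerate fit for equation")
  short <- abundance_panel(cbind(x = rnorm(3), y = rnorm(3)))
  expect_error(fit_mar(short), "too short")
  # misaligned covariates
  pan2 <- abundance_panel(matrix(rnorm(40), 20, 2), times = 1:20)
  u2 <- covariate_panel(matrix(rnorm(20), 20, 1), times = 21:40)
  expect_error(fit_mar(pan2, u2), "aligned")
})

test_that("stability_lambda is the spectral radius", {
  expect_identical(stability_lambda(matrix(0, 3, 3)), 0)
  expect_equal(stability_lambda(diag(c(0.3, 0.9))), 0.9)
  # complex pair: eigenvalues +/- 0.8i
  expect_equal(stability_lambda(matrix(c(0, -0.8, 0.8, 0), 2, 2)), 0.8)
  expect_error(stability_lambda(matrix(1, 2, 3)), "square")
})

test_that("lambda scales with |c| and is similarity-invariant", {
  set.seed(31)
  for (rep in 1:10) {
    B <- matrix(rnorm(9), 3, 3)
    cc <- runif(1, -2, 2)
    expect_equal(stability_lambda(cc * B), abs(cc) * stability_lambda(B),
                 tolerance = 1e-8)
    P <- matrix(rnorm(9), 3, 3) + diag(3)
    expect_equal(stability_lambda(P %*% B %*% solve(P)), stability_lambda(B),
                 tolerance = 1e-8)
  }
})

test_that("predict_one_step evaluates A + B x + C u", {
  id2 <- mar_params(c(0, 0), diag(2))
  expect_equal(predict_one_step(id2, c(3, -1)), c(3, -1))
  neg <- mar_params(1, matrix(-1, 1, 1))
  expect_equal(unname(predict_one_step(neg, 0)), 1)
  withc <- mar_params(c(1, 2), diag(2) * 0.5, matrix(c(1, 0, 0, 2), 2, 2))
  expect_equal(unname(predict_one_step(withc, c(2, 2), c(1, 1))), c(3, 5))
  expect_error(predict_one_step(withc, c(1, 1)), "u_now")
  expect_error(predict_one_step(id2, 1), "x_prev")
})

test_that("estimate error shrinks with series length", {
  truth <- random_small_params(2, 0, seed = 41)
  rmse_at <- function(T) {
    errs <- sapply(1:12, function(r) {
      fit <- fit_mar(simulate_mar(truth, T = T, seed = 1000 * T + r))
      sqrt(mean((fit$params$b - truth$b)^2))
    })
    mean(errs)
  }
  r <- c(rmse_at(100), rmse_at(400), rmse_at(1600))
  expect_true(all(diff(r) < 0))
})
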