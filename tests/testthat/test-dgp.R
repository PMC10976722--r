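test_that("covariates are bounded in [0,1] and columns have the right length", {
  set.seed(1)
  for (rho in c(0, 0.4, 0.85)) {
    cov <- draw_covariates(2000, rho)
    expect_identical(nrow(cov), 2000L)
    for (v in names(cov)) {
      expect_true(all(cov[[v]] >= 0 & cov[[v]] <= 1),
                  label = sprintf("%s in [0,1] at rho=%g", v, rho))
    }
  }
})

test_that("correlation of X_m with the blended covariates matches the closed form", {
  set.seed(2)
  for (rho in c(0, 0.3, 0.5, 0.9)) {
    cov <- draw_covariates(1e5, rho)
    expected <- rho / sqrt(rho^2 + (1 - rho)^2)
    for (v in c("X_u1", "X_u3", "X_u4")) {
      expect_lt(abs(cor(cov$X_m, cov[[v]]) - expected), 0.02)
    }
  }
})

test_that("the convex-combination rule evaluates exactly", {
  # X_u2 = 0.5 * X_u3 + 0.5 * mu with X_u3 = 0.6, mu = 0.2
  expect_equal(evaluesim:::blend(0.6, 0.2, 0.5), 0.4)
  # and the generated X_u2 always stays inside [0.5 X_u3, 0.5 X_u3 + 0.5]
  set.seed(3)
  cov <- draw_covariates(5000, 0.7)
  resid <- cov$X_u2 - 0.5 * cov$X_u3
  expect_true(all(resid >= 0 & resid <= 0.5))
})

test_that("rho outside [0,1) is rejected with the valid range named", {
  expect_error(draw_covariates(10, 1), "\\[0, 1\\)")
  expect_error(draw_covariates(10, -0.1), "\\[0, 1\\)")
  expect_error(dgp_params(rho = 1.2), "\\[0, 1\\)")
})

test_that("treatment follows the strict latent-utility threshold", {
  zeros <- data.frame(X_m = numeric(3), X_u1 = numeric(3),
                      X_u2 = numeric(3), X_u3 = numeric(3),
                      X_u4 = numeric(3))
  # Tx = 0 exactly for every patient -> nobody treated (strict inequality)
  p0 <- dgp_params(beta_T = 0, alpha = 0,
                   s_dist = list(family = "constant", value = 0))
  expect_identical(assign_treatment(zeros, p0), rep(0L, 3))
  # single patient: Tx = 1*0.2 - 0.1 + 0 = 0.1 > 0 -> treated
  p1 <- dgp_params(beta_T = 0.2, V = 1, alpha = 1,
                   s_dist = list(family = "constant", value = 0.1))
  expect_identical(assign_treatment(zeros[1, ], p1), 1L)
})

test_that("default parameters give a treated fraction near one half", {
  set.seed(4)
  p <- dgp_params(n_obs = 1e5)
  cov <- draw_covariates(p$n_obs, p$rho)
  trt <- assign_treatment(cov, p)
  # the S distribution is symmetric about the mean covariate utility, so the
  # structural treated fraction is exactly 0.5
  expect_lt(abs(mean(trt) - 0.5), 0.01)
})

test_that("cure probabilities follow the logistic model", {
  zeros <- data.frame(X_m = numeric(2e4), X_u1 = numeric(2e4),
                      X_u2 = numeric(2e4), X_u3 = numeric(2e4),
                      X_u4 = numeric(2e4))
  set.seed(5)
  p_null <- dgp_params(beta_T = 0, beta_m = 0, beta_u1 = 0, beta_u2 = 0)
  C0 <- assign_outcome(zeros, rep(0L, 2e4), p_null)
  expect_lt(abs(mean(C0) - 0.5), 3 * sqrt(0.25 / 2e4))

  p_trt <- dgp_params(beta_T = 0.2, beta_m = 0, beta_u1 = 0, beta_u2 = 0)
  C1 <- assign_outcome(zeros, rep(1L, 2e4), p_trt)
  expect_lt(abs(mean(C1) - plogis(0.2)), 3 * sqrt(0.25 / 2e4))
})

test_that("empirical cure rate matches a quadrature oracle", {
  skip_if_not_installed("pracma")
  # alpha = 0 with S ~ U(-0.5, 0.5) makes treatment independent of the
  # covariates with Pr(T) = 0.7, so the marginal cure rate has a closed
  # integral over (X_m, X_u1, X_u3, mu2)
  p <- dgp_params(alpha = 0, s_dist = list(family = "uniform",
                                           min = -0.5, max = 0.5),
                  n_obs = 2e5, rho = 0, seed = 11)
  co <- simulate_cohort(p)
  gl <- pracma::gaussLegendre(12, 0, 1)
  nodes <- gl$x; wts <- gl$w
  g <- expand.grid(xm = nodes, xu1 = nodes, xu3 = nodes, mu2 = nodes)
  gw <- expand.grid(a = wts, b = wts, c = wts, d = wts)
  wprod <- gw$a * gw$b * gw$c * gw$d
  eta <- p$beta_m * g$xm + p$beta_u1 * g$xu1 +
    p$beta_u2 * (0.5 * g$xu3 + 0.5 * g$mu2)
  p_treat <- 0.7
  cure_rate <- sum(wprod * (p_treat * plogis(eta + p$beta_T) +
                              (1 - p_treat) * plogis(eta)))
  se <- sqrt(cure_rate * (1 - cure_rate) / p$n_obs)
  expect_lt(abs(mean(co$data$C) - cure_rate), 3 * se)
})

test_that("cohort simulation is deterministic in the seed", {
  p <- dgp_params(n_obs = 3000, rho = 0.5, seed = 123)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$data, b$data)
  c2 <- simulate_cohort(dgp_params(n_obs = 3000, rho = 0.5, seed = 124))
  expect_false(identical(a$data$T, c2$data$T) && identical(a$data$C, c2$data$C))
})

test_that("degenerate cohorts are flagged with a warning, defaults are not", {
  p_bad <- dgp_params(intercept_C = 50, n_obs = 200, seed = 8)
  expect_warning(co <- simulate_cohort(p_bad), "degenerate")
  expect_true(co$degenerate)

  co_ok <- simulate_cohort(dgp_params(n_obs = 10000, rho = 0, seed = 9))
  expect_false(co_ok$degenerate)
  expect_gt(mean(co_ok$data$T), 0.05); expect_lt(mean(co_ok$data$T), 0.95)
  expect_gt(mean(co_ok$data$C), 0.05); expect_lt(mean(co_ok$data$C), 0.95)
})

test_that("cohort CSV export round-trips with the documented header", {
  co <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  expect_identical(readLines(path, n = 1), "X_m,X_u1,X_u2,X_u3,X_u4,T,C")
  back <- read.csv(path)
  expect_equal(back$T, co$data$T)
  expect_equal(back$X_u2, co$data$X_u2, tolerance = 1e-12)
})

test_that("s_dist specifications are validated", {
  expect_error(dgp_params(s_dist = list(family = "normal", sd = 1)),
               "unknown s_dist family")
  expect_error(dgp_params(s_dist = list(family = "uniform", min = 2, max = 1)),
               "min < max")
  expect_silent(dgp_params(s_dist = list(family = "constant", value = 2.2)))
})
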