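test_that("logistic fit reproduces the closed-form 2x2 log odds ratio", {
  d <- data.frame(T = rep(c(1, 1, 0, 0), c(30, 10, 20, 20)),
                  C = rep(c(1, 0, 1, 0), c(30, 10, 20, 20)))
  f <- fit_logistic(d)
  expect_true(f$converged)
  expect_equal(f$beta_T_hat, log(3), tolerance = 1e-8)
  expect_equal(f$odds_ratio, exp(f$beta_T_hat))
  # closed-form SE of a 2x2 log odds ratio
  expect_equal(f$se_beta_T, sqrt(1/30 + 1/10 + 1/20 + 1/20), tolerance = 1e-6)
  expect_identical(f$n_analytic, 80L)
})

test_that("degenerate or separated inputs never yield a silent coefficient", {
  all_cured <- data.frame(T = rep(0:1, each = 10), C = rep(1L, 20))
  f <- fit_logistic(all_cured)
  expect_false(f$converged)
  expect_true(is.na(f$beta_T_hat))

  # T perfectly predicts C: complete separation
  sep <- data.frame(T = rep(0:1, each = 15), C = rep(0:1, each = 15))
  f2 <- fit_logistic(sep)
  expect_false(f2$converged)
})

test_that("the full-information fit is consistent for the true effect", {
  co <- simulate_cohort(dgp_params(n_obs = 1e5, rho = 0.3, seed = 21))
  f <- fit_logistic(co, c("X_m", "X_u1", "X_u2"))
  expect_true(f$converged)
  expect_lt(abs(f$beta_T_hat - 0.2), 3 * f$se_beta_T)
})

test_that("weighted fits maximize the weighted likelihood", {
  # integer weights must be equivalent to row expansion
  set.seed(22)
  d <- data.frame(T = rbinom(60, 1, 0.5), X_m = runif(60))
  d$C <- rbinom(60, 1, plogis(0.3 * d$T + 0.5 * d$X_m))
  w <- sample(1:3, 60, replace = TRUE)
  f_w <- fit_logistic(d, "X_m", weights = w)
  d_exp <- d[rep(seq_len(60), w), ]
  f_e <- fit_logistic(d_exp, "X_m")
  expect_equal(f_w$beta_T_hat, f_e$beta_T_hat, tolerance = 1e-10)
})

test_that("probit propensity model agrees with an independent optimizer", {
  set.seed(23)
  x <- runif(200)
  t <- rbinom(200, 1, pnorm(-0.4 + 1.1 * x))
  d <- data.frame(X_m = x, T = t)
  ps <- fit_probit_propensity(d)
  cf <- attr(ps, "coefficients")
  opt <- optim(c(0, 0), probit_nll, gr = probit_grad, x = x, y = t,
               method = "BFGS", control = list(reltol = 1e-15, maxit = 500))
  expect_lt(max(abs(unname(cf) - opt$par)), 1e-6)
  expect_true(all(ps > 0 & ps < 1))
})

test_that("propensity scores are monotone in X_m and flat under independence", {
  set.seed(24)
  d <- data.frame(X_m = runif(5000), T = rbinom(5000, 1, 0.4))
  ps <- fit_probit_propensity(d)
  expect_lt(diff(range(ps)), 0.1)
  expect_lt(abs(mean(ps) - 0.4), 0.03)

  co <- tiny_cohort(2000, rho = 0.3, seed = 25)
  ps2 <- fit_probit_propensity(co)
  cf <- attr(ps2, "coefficients")
  expect_gt(cf[["X_m"]], 0)
  ord <- order(co$data$X_m)
  expect_true(all(diff(ps2[ord]) >= 0))
})

test_that("IPTW weights follow the inverse-probability formulas", {
  expect_equal(compute_iptw_weights(c(0.5, 0.5), c(1, 0)), c(2, 2))
  expect_equal(compute_iptw_weights(c(0.25, 0.25), c(1, 0)), c(4, 4/3))
  expect_error(compute_iptw_weights(c(0, 0.5), c(1, 0)), "strictly in")
  # ATT and stabilized variants
  expect_equal(compute_iptw_weights(c(0.25, 0.25), c(1, 0), estimand = "ATT"),
               c(1, 1/3))
  sw <- compute_iptw_weights(c(0.25, 0.25), c(1, 0), stabilized = TRUE)
  expect_equal(sw, c(4 * 0.5, 4/3 * 0.5))
})

test_that("weights sum to about 2n under a correct propensity model", {
  set.seed(26)
  n <- 2e4
  x <- runif(n)
  ps_true <- pnorm(-0.5 + 1.4 * x)
  t <- rbinom(n, 1, ps_true)
  w <- compute_iptw_weights(fit_probit_propensity(data.frame(X_m = x, T = t)),
                            t)
  expect_lt(abs(sum(w) / (2 * n) - 1), 0.05)
})

test_that("greedy matching follows the documented processing order", {
  # treated ps {0.31, 0.30}, controls {0.295, 0.32}, caliper 0.02:
  # 0.31 is processed first and takes 0.32 (distance 0.01 < 0.015),
  # 0.30 then takes 0.295
  pairs <- greedy_match(c(0.31, 0.30, 0.295, 0.32), c(1, 1, 0, 0), 0.02)
  expect_equal(unname(pairs), rbind(c(1L, 4L), c(2L, 3L)))

  # no control within the caliper -> empty result
  none <- greedy_match(c(0.9, 0.1), c(1, 0), 0.05)
  expect_identical(nrow(none), 0L)

  expect_error(greedy_match(c(0.5, 0.5), c(1, 0), 0), "positive")
})

test_that("matcher agrees with brute-force enumeration on random instances", {
  set.seed(27)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    # coarse scores provoke exact distance and value ties
    ps <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    tr <- rbinom(n, 1, 0.5)
    cal <- sample(c(0.01, 0.05, 0.11, 0.5), 1)
    got <- greedy_match(ps, tr, cal)
    want <- brute_force_greedy(ps, tr, cal)
    expect_equal(unname(got), unname(want),
                 label = sprintf("instance %d", i))
    if (nrow(got)) {
      expect_true(all(abs(ps[got[, 1]] - ps[got[, 2]]) <= cal))
      expect_false(any(duplicated(got[, 2])))
    }
  }
})

test_that("with a saturated propensity model greedy matching is exact matching", {
  set.seed(28)
  xb <- rbinom(60, 1, 0.5)
  tr <- rbinom(60, 1, ifelse(xb == 1, 0.7, 0.3))
  ps <- ifelse(xb == 1, 0.7, 0.3)
  pairs <- greedy_match(ps, tr, 1e-6)
  # every pair shares the same covariate level
  expect_true(all(xb[pairs[, 1]] == xb[pairs[, 2]]))
  # and the number of pairs per level is min(#treated, #controls)
  for (lev in 0:1) {
    expect_identical(sum(xb[pairs[, 1]] == lev),
                     min(sum(tr == 1 & xb == lev), sum(tr == 0 & xb == lev)))
  }
})

test_that("estimate_all_methods returns the full method suite deterministically", {
  co <- simulate_cohort(dgp_params(n_obs = 4000, rho = 0.2, seed = 29))
  res <- estimate_all_methods(co)
  expect_length(res$fits, 7L)
  expect_named(res$fits, c("no_confounders", "observed_confounder",
                           "all_confounders", "iptw",
                           "psm_0.001", "psm_0.010", "psm_0.100"))
  # the outcome models never see X_u3 / X_u4
  expect_identical(res$fits$all_confounders$covariates,
                   c("X_m", "X_u1", "X_u2"))
  expect_identical(res$fits$no_confounders$covariates, character(0))
  # PSM analytic samples are even (1:1 pairs)
  for (lab in c("psm_0.001", "psm_0.010", "psm_0.100")) {
    expect_identical(res$fits[[lab]]$n_analytic %% 2L, 0L)
  }
  # odds ratio consistency and per-fit risk ratio present when converged
  for (f in res$fits) {
    if (f$converged) {
      expect_equal(f$odds_ratio, exp(f$beta_T_hat))
      expect_false(is.na(f$risk_ratio))
    }
  }
  res2 <- estimate_all_methods(co)
  expect_equal(res, res2)
})
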