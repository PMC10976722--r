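#' Structural parameters of the data-generating process
#'
#' Bundles every coefficient and distribution of the simulated cohort model.
#' A patient's net utility gain from treatment is
#' \deqn{Tx = V \beta_T - S + \alpha (X_m + X_{u1} + X_{u3} + X_{u4}),}
#' and the patient is treated (\eqn{T = 1}) iff \eqn{Tx > 0} (strictly; a tie
#' at exactly zero goes untreated). The cure indicator is Bernoulli with
#' \deqn{\Pr(C = 1) = \mathrm{expit}(c_0 + \beta_T T + \beta_m X_m +
#'   \beta_{u1} X_{u1} + \beta_{u2} X_{u2}).}
#' \eqn{X_m} is the observed confounder; \eqn{X_{u1}, \ldots, X_{u4}} are
#' unobserved, correlated with \eqn{X_m} through the weight \code{rho}.
#'
#' The defaults were calibrated (see the package vignette) so that at every
#' \code{rho} the treated fraction is 0.5 and the full-information standardized
#' risk ratio implied by \code{beta_T = 0.2} is approximately 1.07, while the
#' qualitative bias-amplification patterns of the study design hold.
#'
#' @param beta_T Treatment effect on the cure log-odds; also the weight on
#'   \code{V} in the treatment utility. Default 0.2.
#' @param alpha Common weight of the confounders in the treatment utility.
#' @param beta_m,beta_u1,beta_u2 Cure-model coefficients on \eqn{X_m},
#'   \eqn{X_{u1}}, \eqn{X_{u2}}.
#' @param V Value of being cured, constant across patients.
#' @param s_dist Distribution of the per-patient treatment cost \eqn{S}: a list
#'   with element \code{family} equal to \code{"uniform"} (elements \code{min},
#'   \code{max}) or \code{"constant"} (element \code{value}).
#' @param rho Correlation weight in \eqn{[0, 1)} tying the unobserved
#'   covariates to \eqn{X_m}.
#' @param intercept_C Cure-model intercept \eqn{c_0}; the structural model has
#'   none, so the default is 0. Exposed for calibration experiments.
#' @param n_obs Cohort size (default 10,000).
#' @param seed Optional integer RNG seed; when non-\code{NULL},
#'   [simulate_cohort()] is bit-reproducible.
#'
#' @return An object of class \code{"dgp_params"} (a validated list).
#' @seealso [simulate_cohort()]
#' @examples
#' p <- dgp_params(rho = 0.3, n_obs = 500, seed = 1)
#' p
#' @export
dgp_params <- function(beta_T = 0.2,
                       alpha = 1,
                       beta_m = 0.38,
                       beta_u1 = 0.38,
                       beta_u2 = 0.38,
                       V = 1,
                       s_dist = list(family = "uniform", min = 1.95, max = 2.45),
                       rho = 0,
                       intercept_C = 0,
                       n_obs = 10000,
                       seed = NULL) {
  for (nm in c("beta_T", "alpha", "beta_m", "beta_u1", "beta_u2", "V",
               "rho", "intercept_C")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1); got ", rho, call. = FALSE)
  if (!is.numeric(n_obs) || length(n_obs) != 1L || n_obs < 1 ||
      n_obs != round(n_obs))
    stop("'n_obs' must be a positive integer", call. = FALSE)
  validate_s_dist(s_dist)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
      stop("'seed' must be a single integer or NULL", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(
    list(beta_T = beta_T, alpha = alpha, beta_m = beta_m, beta_u1 = beta_u1,
         beta_u2 = beta_u2, V = V, s_dist = s_dist, rho = rho,
         intercept_C = intercept_C, n_obs = as.integer(n_obs), seed = seed),
    class = "dgp_params"
  )
}

validate_s_dist <- function(s_dist) {
  if (!is.list(s_dist) || is.null(s_dist$family))
    stop("'s_dist' must be a list with a 'family' element", call. = FALSE)
  switch(s_dist$family,
    uniform = {
      if (is.null(s_dist$min) || is.null(s_dist$max) ||
          !is.finite(s_dist$min) || !is.finite(s_dist$max) ||
          s_dist$min >= s_dist$max)
        stop("uniform 's_dist' needs finite min < max", call. = FALSE)
    },
    constant = {
      if (is.null(s_dist$value) || !is.finite(s_dist$value))
        stop("constant 's_dist' needs a finite 'value'", call. = FALSE)
    },
    stop("unknown s_dist family '", s_dist$family,
         "' (use 'uniform' or 'constant')", call. = FALSE)
  )
  invisible(s_dist)
}

draw_s <- function(n, s_dist) {
  switch(s_dist$family,
    uniform  = runif(n, s_dist$min, s_dist$max),
    constant = rep(s_dist$value, n)
  )
}

#' @export
print.dgp_params <- function(x, ...) {
  cat("Data-generating process parameters\n")
  cat(sprintf("  beta_T = %g, alpha = %g, beta_m = %g, beta_u1 = %g, beta_u2 = %g\n",
              x$beta_T, x$alpha, x$beta_m, x$beta_u1, x$beta_u2))
  sd_txt <- if (x$s_dist$family == "uniform")
    sprintf("Uniform(%g, %g)", x$s_dist$min, x$s_dist$max)
  else sprintf("constant %g", x$s_dist$value)
  cat(sprintf("  V = %g, S ~ %s, intercept_C = %g\n", x$V, sd_txt, x$intercept_C))
  cat(sprintf("  rho = %g, n_obs = %d, seed = %s\n",
              x$rho, x$n_obs, if (is.null(x$seed)) "NULL" else x$seed))
  invisible(x)
}

# Convex combination used by both covariate-construction rules.
blend <- function(base, mu, w) w * base + (1 - w) * mu

#' Draw the covariate block
#'
#' Generates the observed confounder \eqn{X_m \sim U[0,1]} and the four
#' unobserved covariates. Each of \eqn{X_{u1}, X_{u3}, X_{u4}} equals
#' \eqn{\rho X_m + (1 - \rho)\mu} with an independent fresh \eqn{U[0,1]} draw
#' \eqn{\mu} per covariate and observation, and
#' \eqn{X_{u2} = 0.5 X_{u3} + 0.5 \mu} with a further independent draw.
#' Using independent \eqn{\mu} draws (rather than one shared draw, which would
#' make the three covariates identical) keeps the unobserved covariates
#' distinct sources of variation.
#'
#' The implied correlation is
#' \eqn{\mathrm{corr}(X_m, X_{u1}) = \rho / \sqrt{\rho^2 + (1-\rho)^2}}.
#'
#' @param n Number of observations (>= 1).
#' @param rho Correlation weight in \eqn{[0, 1)}.
#' @return A data.frame with columns \code{X_m}, \code{X_u1}, \code{X_u2},
#'   \code{X_u3}, \code{X_u4}, all bounded in \eqn{[0, 1]}.
#' @examples
#' set.seed(1)
#' head(draw_covariates(5, rho = 0.5))
#' @export
draw_covariates <- function(n, rho) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1); got ", rho, call. = FALSE)
  X_m  <- runif(n)
  X_u1 <- blend(X_m, runif(n), rho)
  X_u3 <- blend(X_m, runif(n), rho)
  X_u4 <- blend(X_m, runif(n), rho)
  X_u2 <- blend(X_u3, runif(n), 0.5)
  data.frame(X_m = X_m, X_u1 = X_u1, X_u2 = X_u2, X_u3 = X_u3, X_u4 = X_u4)
}

#' Assign treatment from the latent utility
#'
#' Draws the per-patient treatment cost \eqn{S} and computes
#' \eqn{Tx = V\beta_T - S + \alpha(X_m + X_{u1} + X_{u3} + X_{u4})};
#' treatment is assigned iff \eqn{Tx > 0} (strict, so ties at exactly zero go
#' untreated).
#'
#' @param covariates Covariate block from [draw_covariates()].
#' @param params A [dgp_params()] object.
#' @return Integer 0/1 vector of length \code{nrow(covariates)}.
#' @export
assign_treatment <- function(covariates, params) {
  stopifnot(inherits(params, "dgp_params"))
  need <- c("X_m", "X_u1", "X_u3", "X_u4")
  if (!all(need %in% names(covariates)))
    stop("covariate block is missing: ",
         paste(setdiff(need, names(covariates)), collapse = ", "), call. = FALSE)
  n <- nrow(covariates)
  S <- draw_s(n, params$s_dist)
  Tx <- params$V * params$beta_T - S +
    params$alpha * (covariates$X_m + covariates$X_u1 +
                    covariates$X_u3 + covariates$X_u4)
  as.integer(Tx > 0)
}

#' Assign the cure outcome
#'
#' Draws \eqn{C_i \sim \mathrm{Bernoulli}(p_i)} with
#' \eqn{p_i = \mathrm{expit}(c_0 + \beta_T T_i + \beta_m X_{m,i} +
#' \beta_{u1} X_{u1,i} + \beta_{u2} X_{u2,i})}. Note that \eqn{X_{u3}} and
#' \eqn{X_{u4}} never enter the outcome model: they affect the cure only
#' through treatment selection (and \eqn{X_{u2}}'s construction).
#'
#' @inheritParams assign_treatment
#' @param treatment Integer 0/1 vector from [assign_treatment()].
#' @return Integer 0/1 vector of cure indicators.
#' @export
assign_outcome <- function(covariates, treatment, params) {
  stopifnot(inherits(params, "dgp_params"))
  if (length(treatment) != nrow(covariates))
    stop("'treatment' length must match the covariate block", call. = FALSE)
  p <- cure_probability(covariates, treatment, params)
  rbinom(nrow(covariates), 1L, p)
}

cure_probability <- function(covariates, treatment, params) {
  plogis(params$intercept_C + params$beta_T * treatment +
           params$beta_m * covariates$X_m +
           params$beta_u1 * covariates$X_u1 +
           params$beta_u2 * covariates$X_u2)
}

#' Simulate one cohort
#'
#' Composes [draw_covariates()], [assign_treatment()] and [assign_outcome()]
#' on a single seeded RNG stream: identical \code{params} (including
#' \code{seed}) give a bit-identical cohort. A cohort in which treatment or
#' cure is constant (all treated, all untreated, all cured or all uncured) is
#' flagged degenerate with a warning rather than silently passed downstream.
#'
#' @param params A [dgp_params()] object.
#' @return An object of class \code{"cohort"}: a list with
#'   \describe{
#'     \item{data}{data.frame \code{X_m, X_u1, X_u2, X_u3, X_u4, T, C}.}
#'     \item{params}{the generating [dgp_params()].}
#'     \item{degenerate}{logical flag.}
#'     \item{observed_columns}{columns an analyst "sees"; default
#'       \code{c("X_m", "T", "C")}.}
#'   }
#' @examples
#' co <- simulate_cohort(dgp_params(n_obs = 200, seed = 42))
#' co
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "dgp_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  cov <- draw_covariates(params$n_obs, params$rho)
  trt <- assign_treatment(cov, params)
  out <- assign_outcome(cov, trt, params)
  dat <- cbind(cov, T = trt, C = out)
  degen <- length(unique(trt)) < 2L || length(unique(out)) < 2L
  if (degen)
    warning("degenerate cohort: treatment or outcome is constant",
            call. = FALSE)
  structure(
    list(data = dat, params = params, degenerate = degen,
         observed_columns = c("X_m", "T", "C")),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d observations (rho = %g)\n",
              nrow(x$data), x$params$rho))
  cat(sprintf("  treated fraction %.3f, cure fraction %.3f%s\n",
              mean(x$data$T), mean(x$data$C),
              if (x$degenerate) "  [DEGENERATE]" else ""))
  cat("  observed columns: ", paste(x$observed_columns, collapse = ", "), "\n")
  invisible(x)
}

#' Export a cohort as a flat CSV
#'
#' Writes one row per patient with header
#' \code{X_m,X_u1,X_u2,X_u3,X_u4,T,C}, for debugging and cross-language
#' checks.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  write.csv(cohort$data[c("X_m", "X_u1", "X_u2", "X_u3", "X_u4", "T", "C")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Extract the data.frame from a cohort or accept a plain data.frame.
cohort_data <- function(x) {
  if (inherits(x, "cohort")) x$data
  else if (is.data.frame(x)) x
  else stop("expected a 'cohort' object or a data.frame", call. = FALSE)
}
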