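#' Standardized (marginal) risk ratio from a fitted outcome model
#'
#' Converts a fitted logistic coefficient into a marginal risk ratio by
#' g-computation: using the fitted model, each analytic-sample patient's cure
#' probability is predicted with treatment forced to 1 and forced to 0, and
#' the ratio of the (weighted) means of those predictions is returned. The
#' analytic sample and weights follow the fit's method: full cohort for the
#' regression fits, weighted cohort for IPTW, matched subset for matching.
#' Because the outcome here is common (cure rates around 0.65), this marginal
#' RR is materially smaller than the odds ratio; they coincide only in the
#' rare-outcome limit.
#'
#' @param fit A converged [fit_logistic()] result.
#' @param data The cohort (or data.frame) the fit was run on.
#' @param weights Optional weights defining the standardization population.
#' @param pairs Optional matched-pair matrix restricting the population.
#' @param at_means Instead of averaging predictions, evaluate both arms at the
#'   covariate means (conditional RR at the mean patient). Off by default.
#' @return A single risk ratio (> 0); exactly 1 when \code{beta_T_hat = 0}.
#' @examples
#' d <- data.frame(T = rep(0:1, each = 50),
#'                 C = rbinom(100, 1, 0.6))
#' f <- fit_logistic(d)
#' standardized_rr(f, d)
#' @export
standardized_rr <- function(fit, data, weights = NULL, pairs = NULL,
                            at_means = FALSE) {
  stopifnot(inherits(fit, "fit_result"))
  if (!isTRUE(fit$converged) || is.null(fit$coefficients))
    stop("cannot standardize a non-converged fit", call. = FALSE)
  d <- cohort_data(data)
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights
  if (!is.null(pairs)) {
    idx <- as.integer(pairs)
    d <- d[idx, , drop = FALSE]
    w <- w[idx]
  }
  cf <- fit$coefficients
  covs <- fit$covariates
  Z <- if (length(covs)) as.matrix(d[covs]) else
    matrix(0, nrow(d), 0)
  eta_base <- rep(cf[["(Intercept)"]], nrow(d)) +
    if (length(covs)) drop(Z %*% cf[covs]) else 0
  if (at_means) {
    eta_base <- weighted.mean(eta_base, w)
    w <- 1
  }
  p1 <- plogis(eta_base + cf[["T"]])
  p0 <- plogis(eta_base)
  num <- weighted.mean(p1, w)
  den <- weighted.mean(p0, w)
  if (den <= 0) stop("degenerate denominator in risk-ratio standardization",
                     call. = FALSE)
  num / den
}

#' E-value for a point estimate
#'
#' The E-value is the minimum strength of association, on the risk-ratio
#' scale, that an unmeasured confounder would need with both treatment and
#' outcome (conditional on the measured covariates) to fully explain away an
#' observed association. For \eqn{RR \ge 1},
#' \deqn{E = RR + \sqrt{RR (RR - 1)},}
#' and a risk ratio below 1 is inverted before applying the formula, so
#' \eqn{E(rr) = E(1/rr)}. (Some presentations misprint the radicand as
#' \eqn{RR(1 - RR)}, which is negative whenever \eqn{RR > 1}; the form above
#' is the VanderWeele–Ding definition.)
#'
#' @param rr Risk ratio(s), strictly positive.
#' @return An object of class \code{"evalue_result"}: list with vectors
#'   \code{rr}, \code{evalue} (always \eqn{\ge 1}; equal to 1 iff
#'   \code{rr = 1}) and \code{rr_was_inverted}.
#' @examples
#' evalue(1.07)              # ~1.34
#' evalue(0.5)$evalue        # 2 + sqrt(2)
#' @export
evalue <- function(rr) {
  if (!is.numeric(rr) || any(!is.finite(rr)) || any(rr <= 0))
    stop("'rr' must be strictly positive and finite", call. = FALSE)
  inverted <- rr < 1
  rr_star <- ifelse(inverted, 1 / rr, rr)
  e <- rr_star + sqrt(rr_star * (rr_star - 1))
  structure(list(rr = rr, evalue = e, rr_was_inverted = inverted),
            class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  df <- data.frame(rr = x$rr, evalue = x$evalue,
                   rr_was_inverted = x$rr_was_inverted)
  cat("E-value for the point estimate\n")
  print(df, row.names = FALSE)
  invisible(x)
}
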