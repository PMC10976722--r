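#' Standardized mean difference
#'
#' Absolute standardized mean difference between treatment groups:
#' \deqn{\mathrm{SMD} = |\bar{x}_T - \bar{x}_C| /
#'   \sqrt{(s_T^2 + s_C^2) / 2}.}
#' For a weighted sample the means and variances are weighted (frequency-
#' weight convention: \eqn{s^2 = \sum w (x - \bar{x})^2 / (\sum w - 1)}); for
#' a matched sample the statistic is computed on the matched subset. By
#' default the denominator uses the standard deviations of the sample under
#' analysis; \code{denominator = "unadjusted"} standardizes by the
#' pre-adjustment group SDs instead.
#'
#' @param values Numeric covariate vector (full sample).
#' @param treatment Integer 0/1 vector (full sample).
#' @param weights Optional positive weights (e.g. IPTW).
#' @param pairs Optional matched-pair matrix from [greedy_match()]; restricts
#'   the computation to the matched subset.
#' @param denominator \code{"sample"} (default) or \code{"unadjusted"}.
#' @param signed Return the signed difference (treated minus control) rather
#'   than its absolute value.
#' @return A single number; 0 when the two group distributions coincide.
#'   Zero pooled variance with unequal means is an error.
#' @examples
#' smd(c(0.5, 0.7, 0.3, 0.5), c(1, 1, 0, 0))
#' @export
smd <- function(values, treatment, weights = NULL, pairs = NULL,
                denominator = c("sample", "unadjusted"), signed = FALSE) {
  denominator <- match.arg(denominator)
  if (length(values) != length(treatment))
    stop("'values' and 'treatment' lengths differ", call. = FALSE)
  x <- values
  tr <- treatment
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  if (length(w) != length(x) || any(w <= 0) || any(!is.finite(w)))
    stop("'weights' must be positive and match 'values'", call. = FALSE)
  denom_groups <- list(x1 = x[tr == 1], x0 = x[tr == 0],
                       w1 = rep(1, sum(tr == 1)), w0 = rep(1, sum(tr == 0)))
  if (!is.null(pairs)) {
    idx <- as.integer(pairs)
    x <- x[idx]; tr <- tr[idx]; w <- w[idx]
  }
  if (!any(tr == 1) || !any(tr == 0))
    stop("both treatment groups must be nonempty in the analytic sample",
         call. = FALSE)
  m1 <- weighted.mean(x[tr == 1], w[tr == 1])
  m0 <- weighted.mean(x[tr == 0], w[tr == 0])
  if (denominator == "sample") {
    v1 <- wvar(x[tr == 1], w[tr == 1])
    v0 <- wvar(x[tr == 0], w[tr == 0])
  } else {
    v1 <- wvar(denom_groups$x1, denom_groups$w1)
    v0 <- wvar(denom_groups$x0, denom_groups$w0)
  }
  pooled <- sqrt((v1 + v0) / 2)
  diff <- m1 - m0
  if (pooled == 0) {
    if (abs(diff) < .Machine$double.eps^0.5) return(0)
    stop("zero pooled variance with unequal group means", call. = FALSE)
  }
  out <- diff / pooled
  if (signed) out else abs(out)
}

# Weighted variance under the frequency-weight (expanded-sample) convention.
wvar <- function(x, w) {
  if (length(x) < 2L) return(0)
  m <- weighted.mean(x, w)
  sum(w * (x - m)^2) / (sum(w) - 1)
}

#' Proportion of observations in common support
#'
#' The overlap region is the closed interval
#' \eqn{[\max(\min ps_T, \min ps_C),\ \min(\max ps_T, \max ps_C)]}; the
#' returned value is the fraction of \emph{all} observations whose propensity
#' score lies inside it (endpoints included). An empty region yields 0.
#'
#' @param propensity_scores Numeric scores for all observations.
#' @param treatment Integer 0/1 vector.
#' @return Proportion in \eqn{[0, 1]}.
#' @examples
#' common_support(c(0.4, 0.6, 0.5, 0.7), c(1, 1, 0, 0))  # 0.5
#' @export
common_support <- function(propensity_scores, treatment) {
  ps <- propensity_scores
  if (length(ps) != length(treatment))
    stop("'propensity_scores' and 'treatment' lengths differ", call. = FALSE)
  if (!any(treatment == 1) || !any(treatment == 0))
    stop("both treatment groups must be nonempty", call. = FALSE)
  lo <- max(min(ps[treatment == 1]), min(ps[treatment == 0]))
  hi <- min(max(ps[treatment == 1]), max(ps[treatment == 0]))
  if (lo > hi) return(0)
  mean(ps >= lo & ps <= hi)
}

#' Bias of a treatment-effect estimate
#'
#' Returns \eqn{\beta_T - \hat{\beta}_T} — the true value minus the estimate,
#' the sign convention used throughout the study's summaries (a positive
#' upward bias of the estimate therefore yields a negative value).
#'
#' @param beta_T_true True coefficient.
#' @param beta_T_hat Estimated coefficient.
#' @return \code{beta_T_true - beta_T_hat}.
#' @examples
#' bias(0.2, 0.31)  # -0.11
#' @export
bias <- function(beta_T_true, beta_T_hat) {
  stopifnot(is.finite(beta_T_true), is.finite(beta_T_hat))
  beta_T_true - beta_T_hat
}
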