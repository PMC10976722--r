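#' Logistic regression of the cure outcome on treatment
#'
#' Maximum-likelihood logistic regression of \code{C} on \code{T} plus an
#' optional covariate set (intercept always included), optionally maximizing a
#' weighted log-likelihood. Degenerate inputs (outcome or treatment constant
#' in the analytic sample) and IRLS non-convergence are reported through the
#' \code{converged} flag with \code{NA} estimates, never as a silent
#' coefficient.
#'
#' @param data A \code{"cohort"} object or a data.frame with columns \code{T},
#'   \code{C} and any covariates used.
#' @param covariates Character vector of covariate column names entering the
#'   linear predictor besides \code{T} (may be empty).
#' @param weights Optional positive case weights (e.g. IPTW weights).
#' @param subset Optional integer vector of row indices defining the analytic
#'   sample (e.g. a matched sample).
#' @param method Label stored on the result.
#' @param robust If \code{TRUE}, report a heteroscedasticity-robust (HC0
#'   sandwich) standard error instead of the model-based one.
#'
#' @return An object of class \code{"fit_result"}: a list with
#'   \code{method}, \code{beta_T_hat}, \code{se_beta_T}, \code{odds_ratio},
#'   \code{risk_ratio} (filled by [standardized_rr()]), \code{n_analytic},
#'   \code{converged}, plus the full \code{coefficients} vector and the
#'   \code{covariates} used (needed for risk-ratio standardization).
#' @examples
#' d <- data.frame(T = rep(c(1, 1, 0, 0), c(30, 10, 20, 20)),
#'                 C = rep(c(1, 0, 1, 0), c(30, 10, 20, 20)))
#' fit_logistic(d)$beta_T_hat  # log((30 * 20) / (10 * 20)) = log 3
#' @export
fit_logistic <- function(data, covariates = character(), weights = NULL,
                         subset = NULL, method = "logistic", robust = FALSE) {
  d <- cohort_data(data)
  if (!is.null(subset)) {
    d <- d[subset, , drop = FALSE]
    if (!is.null(weights) && length(weights) != nrow(d))
      weights <- weights[subset]
  }
  n <- nrow(d)
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0))
    stop("'weights' must be positive, finite and match the analytic sample",
         call. = FALSE)
  bad <- setdiff(covariates, names(d))
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)

  failed <- function() new_fit_result(method, NA_real_, NA_real_, n,
                                      FALSE, NULL, covariates)
  if (n == 0L || length(unique(d$C)) < 2L || length(unique(d$T)) < 2L)
    return(failed())

  X <- cbind(`(Intercept)` = 1, T = d$T,
             as.matrix(d[covariates]))
  fam <- if (all(w == round(w))) binomial() else quasibinomial()
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, d$C, weights = w, family = fam)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || fit$rank < ncol(X)) return(failed())
  # Complete/quasi-separation drives fitted values to the 0/1 boundary.
  if (fit$boundary || any(fit$fitted.values > 1 - 1e-10) ||
      any(fit$fitted.values < 1e-10)) return(failed())

  cf <- fit$coefficients
  vc <- fit_vcov(fit, X, d$C, w, robust)
  new_fit_result(method, unname(cf["T"]), sqrt(vc["T", "T"]), n, TRUE,
                 cf, covariates)
}

# Model-based (Fisher information, dispersion 1) or HC0 sandwich vcov from a
# glm.fit object.
fit_vcov <- function(fit, X, y, w, robust) {
  p <- fit$rank
  Rm <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rm[lower.tri(Rm)] <- 0
  bread <- chol2inv(Rm)
  dimnames(bread) <- list(colnames(X), colnames(X))
  if (!robust) return(bread)
  mu <- fit$fitted.values
  sc <- X * (w * (y - mu))               # score contributions
  meat <- crossprod(sc)
  vc <- bread %*% meat %*% bread
  dimnames(vc) <- dimnames(bread)
  vc
}

new_fit_result <- function(method, beta, se, n, converged, coefficients,
                           covariates, risk_ratio = NA_real_) {
  structure(
    list(method = method, beta_T_hat = beta, se_beta_T = se,
         odds_ratio = exp(beta), risk_ratio = risk_ratio,
         n_analytic = as.integer(n), converged = converged,
         coefficients = coefficients, covariates = covariates),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s>\n", x$method))
  cat(sprintf("  beta_T_hat = %.4f (SE %.4f), OR = %.4f, RR = %s\n",
              x$beta_T_hat, x$se_beta_T, x$odds_ratio,
              if (is.na(x$risk_ratio)) "NA" else sprintf("%.4f", x$risk_ratio)))
  cat(sprintf("  n_analytic = %d, converged = %s\n", x$n_analytic, x$converged))
  invisible(x)
}

#' Probit propensity-score model
#'
#' Fits a maximum-likelihood probit regression of the treatment indicator on
#' the observed confounder \code{X_m} (intercept and slope) and returns the
#' fitted treatment probabilities. Fitted values are clamped into the open
#' interval \eqn{(\epsilon, 1 - \epsilon)} (\eqn{\epsilon = 10^{-12}}) so that
#' downstream inverse weights are always finite even when the assignment is
#' nearly deterministic in \code{X_m}.
#'
#' @param data A \code{"cohort"} object or data.frame with columns \code{T}
#'   and \code{X_m}.
#' @return Numeric vector of propensity scores, strictly inside (0, 1), with
#'   the fitted \code{coefficients} attached as an attribute.
#' @export
fit_probit_propensity <- function(data) {
  d <- cohort_data(data)
  if (length(unique(d$T)) < 2L)
    stop("cannot fit the propensity model: treatment is constant",
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1, X_m = d$X_m)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, d$T, family = binomial(link = "probit"))),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged)
    stop("probit propensity model failed to converge (separation on X_m?)",
         call. = FALSE)
  eps <- 1e-12
  ps <- pmin(pmax(as.numeric(fit$fitted.values), eps), 1 - eps)
  attr(ps, "coefficients") <- fit$coefficients
  ps
}

#' Inverse probability of treatment weights
#'
#' Unstabilized ATE weights: treated units get \eqn{1 / ps}, untreated
#' \eqn{1 / (1 - ps)}. Stabilized weights (multiplied by the marginal arm
#' probability) and ATT weights (treated 1, untreated \eqn{ps / (1 - ps)})
#' are available behind switches, both off by default.
#'
#' @param propensity_scores Scores strictly in (0, 1).
#' @param treatment Integer 0/1 vector.
#' @param stabilized Multiply by the marginal probability of the received arm.
#' @param estimand \code{"ATE"} (default) or \code{"ATT"}.
#' @return Positive weight vector.
#' @examples
#' compute_iptw_weights(c(0.25, 0.25), c(1, 0))  # 4 and 4/3
#' @export
compute_iptw_weights <- function(propensity_scores, treatment,
                                 stabilized = FALSE,
                                 estimand = c("ATE", "ATT")) {
  estimand <- match.arg(estimand)
  ps <- propensity_scores
  if (length(ps) != length(treatment))
    stop("'propensity_scores' and 'treatment' lengths differ", call. = FALSE)
  if (any(ps <= 0 | ps >= 1))
    stop("propensity scores must lie strictly in (0, 1)", call. = FALSE)
  t1 <- treatment == 1
  w <- if (estimand == "ATE") ifelse(t1, 1 / ps, 1 / (1 - ps))
       else ifelse(t1, 1, ps / (1 - ps))
  if (stabilized) {
    pt <- mean(t1)
    w <- w * ifelse(t1, pt, 1 - pt)
  }
  w
}

#' Greedy 1:1 caliper matching on the propensity score
#'
#' Treated units are processed in descending propensity-score order (ties
#' broken by ascending original index); each is matched to the nearest
#' not-yet-used control within \code{caliper} (distance ties broken by the
#' smallest control index); matching is without replacement and unmatched
#' treated units are dropped.
#'
#' @param propensity_scores Numeric propensity scores for all observations.
#' @param treatment Integer 0/1 vector.
#' @param caliper Maximum allowed propensity-score distance (> 0).
#' @return Integer matrix with columns \code{treated} and \code{control}
#'   (1-based row indices), zero rows when no match is feasible.
#' @examples
#' greedy_match(c(0.31, 0.30, 0.295, 0.32), c(1, 1, 0, 0), caliper = 0.02)
#' @export
greedy_match <- function(propensity_scores, treatment, caliper) {
  if (!is.numeric(caliper) || length(caliper) != 1L || caliper <= 0)
    stop("'caliper' must be a single positive number", call. = FALSE)
  if (length(propensity_scores) != length(treatment))
    stop("'propensity_scores' and 'treatment' lengths differ", call. = FALSE)
  if (any(!is.finite(propensity_scores)))
    stop("propensity scores must be finite", call. = FALSE)
  greedy_match_cpp(as.numeric(propensity_scores), as.integer(treatment),
                   caliper)
}

method_labels <- function(calipers) {
  c("no_confounders", "observed_confounder", "all_confounders", "iptw",
    paste0("psm_", format(calipers, trim = TRUE, scientific = FALSE)))
}

#' Fit all five estimation strategies on one cohort
#'
#' Runs the three outcome-regression specifications (no confounders, observed
#' confounder \code{X_m} only, and the full-information set
#' \code{X_m, X_u1, X_u2}), the IPTW fit (weighted logistic of \code{C} on
#' \code{T} alone — the weights carry the adjustment) and one matched fit per
#' caliper (unadjusted logistic of \code{C} on \code{T} within the matched
#' sample). IPTW and matching share the same probit propensity score on
#' \code{X_m}. Each fit's standardized risk ratio is filled in via
#' [standardized_rr()]. A failure in one method is recorded on its
#' \code{fit_result} and never aborts the others.
#'
#' @param cohort A [simulate_cohort()] result (or equivalent data.frame).
#' @param calipers Numeric vector of matching calipers; the study default is
#'   0.001 with 0.01 and 0.1 as sensitivity values.
#' @param methods Subset of
#'   \code{c("no_confounders", "observed_confounder", "all_confounders",
#'   "iptw", "psm")} to run.
#' @param robust Use sandwich standard errors in every fit.
#' @param stabilized,estimand Passed to [compute_iptw_weights()].
#' @return A list with \code{fits} (named list of \code{fit_result}) and
#'   \code{artifacts} (named list of propensity/weight/matching artifacts,
#'   each carrying \code{propensity_scores}, and \code{weights} or
#'   \code{matched_pairs} plus \code{caliper} and \code{common_support_prop}).
#' @export
estimate_all_methods <- function(cohort,
                                 calipers = c(0.001, 0.01, 0.1),
                                 methods = c("no_confounders",
                                             "observed_confounder",
                                             "all_confounders", "iptw", "psm"),
                                 robust = FALSE,
                                 stabilized = FALSE,
                                 estimand = "ATE") {
  methods <- match.arg(methods, several.ok = TRUE)
  d <- cohort_data(cohort)
  fits <- list()
  artifacts <- list()

  reg_sets <- list(no_confounders = character(),
                   observed_confounder = "X_m",
                   all_confounders = c("X_m", "X_u1", "X_u2"))
  for (m in intersect(names(reg_sets), methods)) {
    fits[[m]] <- fit_logistic(d, reg_sets[[m]], method = m, robust = robust)
    fits[[m]]$risk_ratio <- try_rr(fits[[m]], d)
  }

  if (any(c("iptw", "psm") %in% methods)) {
    ps <- tryCatch(fit_probit_propensity(d), error = function(e) NULL)
    if (is.null(ps)) {
      for (m in intersect(c("iptw", "psm"), methods)) {
        labs <- if (m == "iptw") "iptw" else
          method_labels(calipers)[-(1:4)]
        for (lab in labs)
          fits[[lab]] <- new_fit_result(lab, NA_real_, NA_real_, 0L, FALSE,
                                        NULL, character())
      }
    } else {
      support <- common_support(ps, d$T)
      if ("iptw" %in% methods) {
        w <- tryCatch(
          compute_iptw_weights(ps, d$T, stabilized = stabilized,
                               estimand = estimand),
          error = function(e) NULL)
        if (is.null(w)) {
          fits$iptw <- new_fit_result("iptw", NA_real_, NA_real_, 0L, FALSE,
                                      NULL, character())
        } else {
          fits$iptw <- fit_logistic(d, character(), weights = w,
                                    method = "iptw", robust = robust)
          fits$iptw$risk_ratio <- try_rr(fits$iptw, d, weights = w)
          artifacts$iptw <- list(propensity_scores = ps, weights = w,
                                 common_support_prop = support)
        }
      }
      if ("psm" %in% methods) {
        for (k in seq_along(calipers)) {
          cal <- calipers[k]
          lab <- method_labels(calipers)[4 + k]
          pairs <- greedy_match(ps, d$T, cal)
          idx <- as.integer(t(pairs))
          if (nrow(pairs) == 0L) {
            fits[[lab]] <- new_fit_result(lab, NA_real_, NA_real_, 0L, FALSE,
                                          NULL, character())
          } else {
            fits[[lab]] <- fit_logistic(d, character(), subset = idx,
                                        method = lab, robust = robust)
            fits[[lab]]$risk_ratio <- try_rr(fits[[lab]], d, pairs = pairs)
          }
          artifacts[[lab]] <- list(propensity_scores = ps,
                                   matched_pairs = pairs, caliper = cal,
                                   common_support_prop = support,
                                   retention = nrow(pairs) * 2 / nrow(d))
        }
      }
    }
  }
  list(fits = fits, artifacts = artifacts)
}

try_rr <- function(fit, d, weights = NULL, pairs = NULL) {
  if (!isTRUE(fit$converged)) return(NA_real_)
  tryCatch(standardized_rr(fit, d, weights = weights, pairs = pairs),
           error = function(e) NA_real_)
}
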