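#' Fit the binomial random-intercepts, random-slopes multilevel model
#'
#' Fits, by Laplace-approximated maximum likelihood, the two-level binomial
#' logit model for clicks out of impressions:
#' \deqn{logit(p_{ij}) = (\beta_0 + \upsilon_{0j}) + (\beta_1 +
#'   \upsilon_{1j}) hc_{ij} + \beta_2 mtc_j + \beta_3 hc_{ij} mtc_j}
#' where `hc` is the 2-SD standardized headline concreteness, `mtc` the raw
#' test concreteness mean, and \eqn{(\upsilon_{0j}, \upsilon_{1j})} a
#' bivariate normal random intercept and slope per derived test with a full
#' 2x2 covariance. Each headline enters as one binomial observation
#' (clicks, impressions), which is likelihood-equivalent to disaggregated
#' Bernoulli rows.
#'
#' @param data Data frame from [standardize_concreteness()] (columns
#'   `derived_test_id`, `headline_concreteness_std`,
#'   `test_concreteness_mean`, `impressions`, `clicks`).
#' @param optimizer Optimizer name for `lme4` (default `"bobyqa"`).
#' @param nAGQ Integer passed to [lme4::glmer()]; 1 = Laplace (default),
#'   0 = cheaper penalized-least-squares approximation used by the
#'   large-scale simulation harnesses.
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @return An object of class `ctr_glmm`: list with `beta` (named length-4),
#'   `beta_vcov` (4x4), `beta_ci` (4x2), `beta_se`, `p_values`,
#'   `re_variances` (`var_intercept`, `var_slope`, `corr`), `loglik`, `aic`,
#'   `bic`, `n_obs`, `n_groups`, `converged`, `singular`, and the underlying
#'   `lme4` fit as `fit`.
#' @export
fit_binomial_glmm <- function(data, optimizer = "bobyqa", nAGQ = 1L,
                              conf_level = 0.95) {
  req <- c("derived_test_id", "headline_concreteness_std",
           "test_concreteness_mean", "impressions", "clicks")
  stopifnot(all(req %in% names(data)))
  if (any(data$impressions < 1)) stop("all impressions must be >= 1")
  grp_sizes <- table(data$derived_test_id)
  if (length(grp_sizes) < 2 || !any(grp_sizes >= 2)) {
    stop("need at least 2 groups, with at least 2 observations each")
  }
  d <- data.frame(hc = data$headline_concreteness_std,
                  mtc = data$test_concreteness_mean,
                  grp = factor(data$derived_test_id),
                  clicks = data$clicks,
                  fails = data$impressions - data$clicks)
  fit <- lme4::glmer(cbind(clicks, fails) ~ hc * mtc + (1 + hc | grp),
                     data = d, family = stats::binomial("logit"),
                     nAGQ = as.integer(max(nAGQ, 0L)),
                     control = lme4::glmerControl(optimizer = optimizer,
                                                  calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  names(beta) <- c("intercept", "headline_concreteness",
                   "test_concreteness_mean", "interaction")
  V <- as.matrix(stats::vcov(fit))
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)
  vc <- lme4::VarCorr(fit)$grp
  re <- list(var_intercept = unname(vc[1, 1]), var_slope = unname(vc[2, 2]),
             corr = unname(attr(vc, "correlation")[1, 2]))
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- fit@optinfo$conv$opt == 0 &&
    (is.null(msgs) || !any(grepl("failed to converge", msgs)))
  structure(list(beta = beta, beta_vcov = V, beta_se = se, beta_ci = ci,
                 p_values = 2 * stats::pnorm(-abs(beta / se)),
                 re_variances = re,
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), bic = stats::BIC(fit),
                 n_obs = nrow(d), n_groups = nlevels(d$grp),
                 converged = converged,
                 singular = lme4::isSingular(fit), fit = fit),
            class = "ctr_glmm")
}

#' @export
print.ctr_glmm <- function(x, ...) {
  cat("Binomial random-intercepts, random-slopes model (logit link)\n")
  cat("  n_obs =", x$n_obs, " n_groups =", x$n_groups,
      " converged =", x$converged, "\n")
  tab <- data.frame(estimate = x$beta, se = x$beta_se,
                    lower = x$beta_ci[, 1], upper = x$beta_ci[, 2],
                    p = x$p_values)
  print(round(tab, 4))
  cat("Random effects: var(intercept) =",
      format(x$re_variances$var_intercept, digits = 4),
      " var(slope) =", format(x$re_variances$var_slope, digits = 4),
      " corr =", format(x$re_variances$corr, digits = 3), "\n")
  cat("logLik =", format(x$loglik, digits = 8), " AIC =",
      format(x$aic, digits = 8), " BIC =", format(x$bic, digits = 8), "\n")
  invisible(x)
}

#' Population-level predicted clickthrough rate
#'
#' Inverse logit of
#' `beta0 + beta1*hc + beta2*mtc + beta3*hc*mtc`
#' with random effects at zero. On the 2-SD standardized scale, `hc = +0.5`
#' is one raw standard deviation above the test mean.
#'
#' @param beta Length-4 numeric (intercept, headline concreteness, test
#'   concreteness mean, interaction) or a `ctr_glmm` fit.
#' @param hc Standardized headline concreteness value(s).
#' @param mtc Test concreteness mean value(s).
#' @return Predicted probability in (0, 1), vectorized over `hc`/`mtc`.
#' @export
#' @examples
#' b <- c(-4.929, 0.168, 0.102, -0.058)
#' round(100 * predict_ctr(b, hc = 0.5, mtc = 2.06), 2)
predict_ctr <- function(beta, hc, mtc) {
  if (inherits(beta, "ctr_glmm")) beta <- beta$beta
  stopifnot(length(beta) == 4, all(is.finite(hc)), all(is.finite(mtc)))
  stats::plogis(beta[[1]] + beta[[2]] * hc + beta[[3]] * mtc +
                  beta[[4]] * hc * mtc)
}
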