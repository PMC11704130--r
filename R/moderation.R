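get_beta_vcov <- function(object) {
  if (inherits(object, "ctr_glmm")) {
    list(beta = object$beta, vcov = object$beta_vcov)
  } else {
    stopifnot(is.list(object), length(object$beta) == 4,
              all(dim(object$vcov) == c(4, 4)))
    object
  }
}

#' Simple slope of headline concreteness at a moderator value
#'
#' The conditional (log-odds) effect of standardized headline concreteness
#' at test concreteness mean `m` is `omega = beta1 + beta3 * m`, with
#' delta-method standard error
#' `sqrt(v11 + m^2 v33 + 2 m v13)` and a two-sided normal test.
#'
#' @param object A `ctr_glmm` fit, or a list with `beta` (length 4) and
#'   `vcov` (4x4), ordered (intercept, hc, mtc, interaction).
#' @param m Moderator value(s): test concreteness mean on the raw scale.
#' @return Data frame with columns `m`, `slope`, `se`, `z`, `p`.
#' @export
#' @examples
#' b <- c(-4.929, 0.168, 0.102, -0.058)
#' V <- diag(c(0.08, 0.052, 0.026, 0.017)^2)
#' simple_slope(list(beta = b, vcov = V), m = 2.06)
simple_slope <- function(object, m) {
  bv <- get_beta_vcov(object)
  V <- bv$vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("vcov is not positive semi-definite")
  slope <- bv$beta[[2]] + bv$beta[[4]] * m
  se <- sqrt(V[2, 2] + m^2 * V[4, 4] + 2 * m * V[2, 4])
  z <- slope / se
  data.frame(m = m, slope = slope, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
}

#' Holm step-down adjustment
#'
#' Step-down Holm correction for a small hypothesis family (default family
#' size is the number of p-values supplied; the analysis pipeline uses the
#' three-hypothesis family interaction / low-end slope / high-end slope).
#' Adjusted values are monotone in the raw ordering and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param family_size Total family size `K >= length(p)`; unobserved family
#'   members are treated as having larger p-values than all observed ones.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p, family_size = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), family_size >= length(p))
  n <- length(p)
  if (n == 0) return(numeric(0))
  ord <- order(p)
  adj <- (family_size - seq_len(n) + 1) * p[ord]
  adj <- pmin(cummax(adj), 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

#' Johnson-Neyman significance region for the moderated slope
#'
#' Solves `(beta1 + beta3 m)^2 = crit^2 * (v11 + m^2 v33 + 2 m v13)` for the
#' moderator values `m` at which the conditional slope of headline
#' concreteness is exactly borderline-significant. With a negative
#' interaction the slope is significantly positive below `lower_bound` and
#' significantly negative above `upper_bound`.
#'
#' @inheritParams simple_slope
#' @param critical_value Critical |z| (default 1.96; configurable, e.g. a t
#'   quantile).
#' @param moderator_values Optional vector of observed per-test moderator
#'   values; if given, the fractions of tests below/above the bounds are
#'   reported.
#' @return List of class `jn_region`: `lower_bound`, `upper_bound`,
#'   `critical_value`, `roots`, `region` — the set of moderator values where
#'   the slope IS significant (`"outside_bounds"`, `"between_bounds"`,
#'   `"everywhere"`, `"nowhere"`), `fraction_below`, `fraction_above`.
#' @export
johnson_neyman <- function(object, critical_value = 1.96,
                           moderator_values = NULL) {
  bv <- get_beta_vcov(object)
  b1 <- bv$beta[[2]]; b3 <- bv$beta[[4]]
  V <- bv$vcov
  v11 <- V[2, 2]; v33 <- V[4, 4]; v13 <- V[2, 4]
  if (b3 == 0) stop("interaction coefficient is zero; no moderation to probe")
  cc <- critical_value^2
  A <- b3^2 - cc * v33
  B <- 2 * b1 * b3 - 2 * cc * v13
  C <- b1^2 - cc * v11
  disc <- B^2 - 4 * A * C
  roots <- if (disc >= 0 && A != 0) sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
           else if (A == 0 && B != 0) rep(-C / B, 2)
           else numeric(0)
  zfun <- function(m) (b1 + b3 * m) / sqrt(v11 + m^2 * v33 + 2 * m * v13)
  if (length(roots) == 2 && disc >= 0) {
    mid <- mean(roots)
    sig_between <- abs(zfun(mid)) >= critical_value
    region <- if (sig_between) "between_bounds" else "outside_bounds"
    lower <- roots[1]; upper <- roots[2]
  } else {
    sig0 <- abs(zfun(0)) >= critical_value
    region <- if (sig0) "everywhere" else "nowhere"
    lower <- upper <- NA_real_
  }
  fb <- fa <- NA_real_
  if (!is.null(moderator_values) && length(roots) == 2) {
    fb <- mean(moderator_values < lower)
    fa <- mean(moderator_values > upper)
  }
  structure(list(lower_bound = lower, upper_bound = upper,
                 critical_value = critical_value, roots = roots,
                 region = region, fraction_below = fb, fraction_above = fa),
            class = "jn_region")
}

#' @export
print.jn_region <- function(x, ...) {
  cat("Johnson-Neyman region (|z| >= ", x$critical_value, ")\n", sep = "")
  if (x$region %in% c("between_bounds", "outside_bounds")) {
    cat("  bounds: ", format(x$lower_bound, digits = 4), " / ",
        format(x$upper_bound, digits = 4),
        "  (slope significant ", if (x$region == "between_bounds") "between"
        else "outside", " the bounds)\n", sep = "")
    if (!is.na(x$fraction_below)) {
      cat("  tests below lower bound: ",
          format(100 * x$fraction_below, digits = 3), "%; above upper: ",
          format(100 * x$fraction_above, digits = 3), "%\n", sep = "")
    }
  } else {
    cat("  slope significant ", x$region, "\n", sep = "")
  }
  invisible(x)
}

#' Conditional-effects grid of predicted clickthrough rates
#'
#' For each moderator value, evaluates [predict_ctr()] over a grid of
#' standardized headline concreteness spanning `hc_range` (default -1 to +1,
#' i.e. two standard deviations below to two above the test mean).
#'
#' @inheritParams predict_ctr
#' @param m_values Moderator values (typically observed min, mean - SD,
#'   mean, mean + SD, max of test concreteness).
#' @param hc_range Length-2 range of standardized headline concreteness.
#' @param n_points Grid resolution per curve.
#' @return Data frame with columns `m`, `hc`, `ctr`.
#' @export
conditional_effects_grid <- function(beta, m_values, hc_range = c(-1, 1),
                                     n_points = 41) {
  if (inherits(beta, "ctr_glmm")) beta <- beta$beta
  hc <- seq(hc_range[1], hc_range[2], length.out = n_points)
  out <- expand.grid(hc = hc, m = m_values)
  out$ctr <- predict_ctr(beta, out$hc, out$m)
  out[, c("m", "hc", "ctr")]
}
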