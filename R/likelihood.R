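# Marginal likelihood of the binomial random-intercept/random-slope model,
# evaluated at fixed parameters. Two routes are provided on purpose: a
# Laplace approximation (the estimation-time approximation) and adaptive
# Gauss-Hermite quadrature over the 2-D random effect (the high-accuracy
# oracle). Both integrate, per group j,
#   integral  prod_i Bin(y_ij | n_ij, plogis(x_ij'beta + u0 + u1 hc_ij))
#             * N(u; 0, Sigma) du
# and return the summed log of those integrals.

# Gauss-Hermite nodes/weights for weight exp(-x^2), via the Golub-Welsch
# symmetric tridiagonal eigenproblem (no external dependency).
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

# log integrand (unnormalized posterior of u for one group) and derivatives
group_logf <- function(u, eta0, x, y, n, Sigma_inv) {
  eta <- eta0 + u[1] + u[2] * x
  # numerically stable log(1 + e^eta)
  log1pe <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  sum(y * eta - n * log1pe) - 0.5 * drop(t(u) %*% Sigma_inv %*% u)
}

group_mode <- function(eta0, x, y, n, Sigma_inv, max_iter = 50,
                       tol = 1e-10) {
  u <- c(0, 0)
  f <- group_logf(u, eta0, x, y, n, Sigma_inv)
  for (iter in seq_len(max_iter)) {
    eta <- eta0 + u[1] + u[2] * x
    p <- stats::plogis(eta)
    r <- y - n * p
    g <- c(sum(r), sum(r * x)) - drop(Sigma_inv %*% u)
    w <- n * p * (1 - p)
    H <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2) +
      Sigma_inv
    step <- solve(H, g)
    # damped Newton with step halving
    lambda <- 1
    repeat {
      u_new <- u + lambda * step
      f_new <- group_logf(u_new, eta0, x, y, n, Sigma_inv)
      if (f_new >= f - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    moved <- sum(abs(u_new - u))
    u <- u_new; f <- f_new
    if (moved < tol) break
  }
  eta <- eta0 + u[1] + u[2] * x
  p <- stats::plogis(eta)
  w <- n * p * (1 - p)
  H <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2) +
    Sigma_inv
  list(u = u, f = f, H = H)
}

#' Marginal log-likelihood at fixed parameters
#'
#' Evaluates the marginal log-likelihood of the binomial
#' random-intercept/random-slope logit model at user-supplied parameter
#' values, by either the Laplace approximation or adaptive Gauss-Hermite
#' quadrature (tensor grid over the bivariate random effect, centered and
#' scaled at each group's posterior mode). The quadrature route with many
#' nodes serves as the accuracy oracle for the Laplace route.
#'
#' @param data Data frame with `derived_test_id`,
#'   `headline_concreteness_std`, `test_concreteness_mean`, `impressions`,
#'   `clicks`.
#' @param beta Length-4 fixed effects (intercept, hc, mtc, interaction).
#' @param re_sd Length-2: SDs of the random intercept and random slope.
#' @param re_corr Correlation between intercept and slope deviations.
#' @param method `"laplace"` or `"aghq"`.
#' @param nodes Gauss-Hermite nodes per dimension for `"aghq"`.
#' @return Log-likelihood (includes the binomial normalizing constants).
#' @export
marginal_loglik <- function(data, beta, re_sd, re_corr = 0,
                            method = c("laplace", "aghq"), nodes = 25) {
  method <- match.arg(method)
  stopifnot(length(beta) == 4, length(re_sd) == 2, all(re_sd >= 0),
            abs(re_corr) < 1)
  Sigma <- diag(re_sd^2)
  Sigma[1, 2] <- Sigma[2, 1] <- re_corr * re_sd[1] * re_sd[2]
  if (any(re_sd == 0)) stop("re_sd must be positive for integration")
  Sigma_inv <- solve(Sigma)
  log_det_Sigma <- determinant(Sigma, logarithm = TRUE)$modulus

  x_all <- data$headline_concreteness_std
  m_all <- data$test_concreteness_mean
  eta0_all <- beta[1] + beta[2] * x_all + beta[3] * m_all +
    beta[4] * x_all * m_all
  y_all <- data$clicks
  n_all <- data$impressions
  const <- sum(lchoose(n_all, y_all))
  groups <- split(seq_len(nrow(data)), data$derived_test_id)

  gh <- if (method == "aghq") gauss_hermite(nodes) else NULL
  ll <- 0
  for (idx in groups) {
    x <- x_all[idx]; y <- y_all[idx]; n <- n_all[idx]; eta0 <- eta0_all[idx]
    md <- group_mode(eta0, x, y, n, Sigma_inv)
    # log N(u;0,Sigma) normalizer: -log(2*pi) - 0.5*log|Sigma|
    log_prior_norm <- -log(2 * pi) - 0.5 * as.numeric(log_det_Sigma)
    if (method == "laplace") {
      ll_j <- md$f + log_prior_norm + log(2 * pi) -
        0.5 * as.numeric(determinant(md$H, logarithm = TRUE)$modulus)
    } else {
      A <- solve(chol(md$H))          # upper-tri inverse: H^{-1} = A A'
      zz <- expand.grid(z1 = gh$nodes, z2 = gh$nodes)
      lw <- log(gh$weights)
      lww <- outer(lw, lw, "+")
      terms <- numeric(nrow(zz))
      for (q in seq_len(nrow(zz))) {
        z <- c(zz$z1[q], zz$z2[q])
        u <- md$u + sqrt(2) * drop(A %*% z)
        terms[q] <- group_logf(u, eta0, x, y, n, Sigma_inv) + sum(z^2)
      }
      terms <- terms + as.vector(lww)
      mx <- max(terms)
      integral_log <- mx + log(sum(exp(terms - mx))) +
        log(2) - 0.5 * as.numeric(determinant(md$H, logarithm = TRUE)$modulus)
      ll_j <- integral_log + log_prior_norm
    }
    ll <- ll + ll_j
  }
  ll + const
}
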