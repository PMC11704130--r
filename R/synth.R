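#' Configuration for the synthetic experiment generator
#'
#' Defaults describe a realistic headline A/B-test archive: tests of 2--5
#' packages (mostly 4--5), test-level mean concreteness distributed as a
#' truncated normal on \[0, 5\] with mean 3.08 and SD 0.27 (the observed
#' landmarks of the moderator distribution), within-test headline spread of
#' 0.35 raw units, Table-2-scale fixed effects and random-effect SDs, and
#' per-package impressions drawn log-normally with median ~4000.
#'
#' @param n_tests Number of A/B tests to generate.
#' @param headlines_per_test Integer range (min, max) of packages per test.
#' @param headlines_per_test_probs Sampling weights over that range.
#' @param conc_mean,conc_sd Mean and SD of test-level mean concreteness.
#' @param conc_within_sd Within-test SD of headline concreteness (raw 0--5
#'   units).
#' @param beta Length-4 true fixed effects (intercept, standardized headline
#'   concreteness, test concreteness mean, interaction), log-odds scale.
#' @param re_sd Length-2 SDs of the random intercept and random slope.
#' @param re_corr Correlation of the random intercept and slope.
#' @param impressions_meanlog,impressions_sdlog Log-normal impression
#'   parameters.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_tests = 1000,
                         headlines_per_test = c(2L, 5L),
                         headlines_per_test_probs = c(0.10, 0.15, 0.40, 0.35),
                         conc_mean = 3.08, conc_sd = 0.27,
                         conc_within_sd = 0.35,
                         beta = c(-4.929, 0.168, 0.102, -0.058),
                         re_sd = c(0.6534, 0.3651), re_corr = 0,
                         impressions_meanlog = log(4000),
                         impressions_sdlog = 0.7) {
  stopifnot(n_tests >= 1, length(beta) == 4, all(re_sd >= 0),
            abs(re_corr) <= 1,
            length(headlines_per_test) == 2,
            headlines_per_test[1] >= 2,
            length(headlines_per_test_probs) ==
              diff(headlines_per_test) + 1)
  structure(as.list(environment()), class = "synth_config")
}

# word encoding a rating with centi-unit precision: rating 2.37 -> "wcdh"
# (digits 2,3,7 mapped to letters c,d,h). All-lowercase, never a stopword,
# so the scorer resolves every token directly and reproduces the rating.
conc_word <- function(rating) {
  cents <- as.integer(round(rating * 100))
  stopifnot(all(cents >= 0 & cents <= 500))
  d1 <- cents %/% 100
  d2 <- (cents %/% 10) %% 10
  d3 <- cents %% 10
  paste0("w", letters[d1 + 1], letters[d2 + 1], letters[d3 + 1])
}

#' Synthetic lexicon covering every centi-unit rating on \[0, 5\]
#'
#' 501 generated words (`conc_word` encoding), one per rating from 0.00 to
#' 5.00, used so synthetic archives can be pushed through the real scorer
#' end-to-end.
#'
#' @return A `concreteness_lexicon`.
#' @export
synthetic_lexicon <- function() {
  ratings <- seq(0, 5, by = 0.01)
  as_lexicon(stats::setNames(ratings, conc_word(ratings)))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Generate a synthetic headline A/B-test archive with known ground truth
#'
#' Per test: draw the number of packages, a test-level target concreteness,
#' and a bivariate-normal random intercept/slope; per package: draw a
#' headline concreteness around the test target (rounded to 2 decimals,
#' which is the resolution the synthetic lexicon can encode), build a
#' headline string the scorer maps exactly to that concreteness, compute the
#' true click probability from the model equation using the same
#' standardization convention as [standardize_concreteness()], and draw
#' clicks binomially. Byte-identical output for a given seed.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List with `archive` (public archive CSV dialect:
#'   `clickability_test_id`, `headline`, `eyecatcher_id`, `impressions`,
#'   `clicks`), `truth` (per package: assigned concreteness, standardized
#'   value, test mean, true probability, and the per-test random effects),
#'   and `scaling` (the 2-SD scaling used).
#' @export
generate_archive <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(seed))
  nt <- config$n_tests
  sizes <- sample(seq(config$headlines_per_test[1],
                      config$headlines_per_test[2]),
                  nt, replace = TRUE, prob = config$headlines_per_test_probs)
  tid <- rep(seq_len(nt), sizes)
  N <- length(tid)
  test_target <- rtrunc_norm(nt, config$conc_mean, config$conc_sd, 0, 5)
  conc <- rtrunc_norm(N, test_target[tid], config$conc_within_sd, 0, 5)
  conc <- round(conc, 2)
  # random effects: bivariate normal via Cholesky
  z <- matrix(stats::rnorm(2 * nt), nt, 2)
  u0 <- config$re_sd[1] * z[, 1]
  u1 <- config$re_sd[2] * (config$re_corr * z[, 1] +
                             sqrt(1 - config$re_corr^2) * z[, 2])
  # the standardization convention of the prep stage, applied to the
  # generated sample itself
  mtc <- stats::ave(conc, tid)
  centered <- conc - mtc
  sd_centered <- stats::sd(centered)
  if (!is.finite(sd_centered) || sd_centered == 0) {
    stop("degenerate concreteness draw: zero centered SD")
  }
  hc <- centered / (2 * sd_centered)
  b <- config$beta
  eta <- (b[1] + u0[tid]) + (b[2] + u1[tid]) * hc + b[3] * mtc +
    b[4] * hc * mtc
  if (any(!is.finite(eta))) stop("configuration yields non-finite log-odds")
  p <- stats::plogis(eta)
  impressions <- pmax(1, round(stats::rlnorm(N, config$impressions_meanlog,
                                             config$impressions_sdlog)))
  clicks <- stats::rbinom(N, impressions, p)
  pkg_index <- sequence(sizes)
  headline <- vapply(seq_len(N), function(i) {
    paste(rep(conc_word(conc[i]), pkg_index[i] + 2L), collapse = " ")
  }, character(1))
  archive <- data.frame(
    clickability_test_id = sprintf("test%05d", tid),
    headline = headline,
    eyecatcher_id = sprintf("img%05d", tid),
    impressions = impressions, clicks = clicks,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    test_id = archive$clickability_test_id,
    headline = headline, concreteness = conc,
    headline_concreteness_std = hc, test_concreteness_mean = mtc,
    u0 = u0[tid], u1 = u1[tid], p = p, stringsAsFactors = FALSE)
  list(archive = archive, truth = truth,
       scaling = list(sd_centered = sd_centered, grand_mean = mean(conc),
                      centering = "group"))
}

# shared generate -> prep -> fit path; scores come from the ground truth
# unless rescore = TRUE, which pushes the headline text through the scorer
# (identical result, far slower; exercised in the end-to-end tests).
synth_fit_once <- function(config, seed, rescore = FALSE, nAGQ = 0L) {
  sim <- generate_archive(config, seed = seed)
  pkgs <- read_archive(sim$archive)
  cand <- split_by_image(pkgs)
  if (rescore) {
    scored <- score_corpus(unique(sim$archive["headline"]),
                           synthetic_lexicon())
    cand <- filter_valid(cand, scored)
  } else {
    cand$score <- sim$truth$concreteness
    cand$excluded <- FALSE
    cand <- filter_valid(cand)
  }
  std <- standardize_concreteness(cand)
  fit <- fit_binomial_glmm(std$data, nAGQ = nAGQ)
  list(fit = fit, std = std, sim = sim)
}

#' Parameter-recovery harness
#'
#' For each replicate: generate a synthetic archive from known parameters,
#' run the preparation pipeline, fit the multilevel model, and probe the
#' simple slopes. Reports per-coefficient bias, RMSE, and 95% Wald CI
#' coverage, plus the sampling distribution of the Johnson-Neyman bounds.
#'
#' @param config A [synth_config()]; its `beta` is the recovery truth.
#' @param n_replicates Number of replicates.
#' @param seed Base seed; replicate r uses `seed * 1000 + r`.
#' @param rescore Push headline text through the scorer each replicate
#'   (slow) instead of using the ground-truth scores (identical values).
#' @param nAGQ Passed to [fit_binomial_glmm()]; the default 0 keeps large
#'   harness runs tractable and agrees closely with Laplace at these sizes.
#' @return List with `results` (one row per replicate: estimates, CI limits,
#'   coverage flags, JN bounds, convergence) and `summary` (bias, RMSE,
#'   coverage per coefficient; fit failures counted).
#' @export
recovery_harness <- function(config = synth_config(), n_replicates = 10,
                             seed = 1L, rescore = FALSE, nAGQ = 0L) {
  stopifnot(n_replicates >= 1)
  truth <- config$beta
  rows <- vector("list", n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(
      synth_fit_once(config, seed = (seed * 1000 + r) %% .Machine$integer.max,
                     rescore = rescore, nAGQ = nAGQ),
      error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    fit <- res$fit
    jn <- tryCatch(johnson_neyman(fit), error = function(e) NULL)
    cover <- truth >= fit$beta_ci[, 1] & truth <= fit$beta_ci[, 2]
    rows[[r]] <- data.frame(
      replicate = r,
      t(stats::setNames(fit$beta, paste0("est_", names(fit$beta)))),
      t(stats::setNames(cover, paste0("cover_", names(fit$beta)))),
      jn_lower = if (is.null(jn)) NA_real_ else jn$lower_bound,
      jn_upper = if (is.null(jn)) NA_real_ else jn$upper_bound,
      converged = fit$converged, singular = fit$singular)
  }
  results <- do.call(rbind, rows)
  nm <- c("intercept", "headline_concreteness", "test_concreteness_mean",
          "interaction")
  est <- as.matrix(results[, paste0("est_", nm), drop = FALSE])
  cov <- as.matrix(results[, paste0("cover_", nm), drop = FALSE])
  summary <- data.frame(
    coefficient = nm, truth = truth,
    bias = colMeans(est) - truth,
    rmse = sqrt(colMeans(sweep(est, 2, truth)^2)),
    coverage = colMeans(cov), row.names = NULL)
  list(results = results, summary = summary, n_failed = n_failed)
}

#' Power analysis by simulation
#'
#' Estimates, per candidate number of tests, the probability that all three
#' hypothesis tests reject at `alpha` after Holm correction: H1 (negative
#' interaction), H2 (positive simple slope at the observed minimum test
#' concreteness mean), H3 (negative simple slope at the observed maximum).
#'
#' @param config A [synth_config()]; `n_tests` is overridden by the grid.
#' @param n_tests_grid Integer vector of archive sizes to probe.
#' @param alpha Familywise significance level.
#' @param n_replicates Replicates per grid point.
#' @param seed Base seed.
#' @param nAGQ Passed to [fit_binomial_glmm()].
#' @return Data frame with columns `n_tests`, `power` (raw fraction),
#'   `power_smoothed` (isotonic in `n_tests`), `mc_se`, `n_failed`.
#' @export
estimate_power <- function(config = synth_config(), n_tests_grid,
                           alpha = 0.05, n_replicates = 50, seed = 1L,
                           nAGQ = 0L) {
  stopifnot(length(n_tests_grid) >= 1)
  out <- lapply(seq_along(n_tests_grid), function(gi) {
    cfg <- config
    cfg$n_tests <- n_tests_grid[gi]
    reject <- logical(n_replicates)
    failed <- 0L
    for (r in seq_len(n_replicates)) {
      res <- tryCatch(
        synth_fit_once(cfg,
                       seed = (seed * 100000 + gi * 1000 + r) %%
                         .Machine$integer.max,
                       nAGQ = nAGQ),
        error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; next }
      fit <- res$fit
      mtc <- res$std$data$test_concreteness_mean
      ss <- simple_slope(fit, c(min(mtc), max(mtc)))
      p_raw <- c(h1 = fit$p_values[["interaction"]],
                 h2 = ss$p[1], h3 = ss$p[2])
      p_adj <- holm_adjust(p_raw)
      reject[r] <- p_adj[1] < alpha && fit$beta[["interaction"]] < 0 &&
        p_adj[2] < alpha && ss$slope[1] > 0 &&
        p_adj[3] < alpha && ss$slope[2] < 0
    }
    used <- n_replicates - failed
    pw <- if (used > 0) sum(reject) / used else NA_real_
    data.frame(n_tests = n_tests_grid[gi], power = pw,
               mc_se = sqrt(pw * (1 - pw) / max(used, 1)),
               n_failed = failed)
  })
  out <- do.call(rbind, out)
  out$power_smoothed <- if (nrow(out) > 1) {
    stats::isoreg(out$n_tests, out$power)$yf
  } else out$power
  out[, c("n_tests", "power", "power_smoothed", "mc_se", "n_failed")]
}
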