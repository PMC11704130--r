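make_panel <- function() {
  # 5 honest raters + 1 constant + 1 adversarial, 4 calibration items
  # spanning the scale, plus main items
  calib_truth <- c(c1 = 1, c2 = 2, c3 = 4, c4 = 5)
  rows <- list()
  for (r in 1:5) {
    rows[[length(rows) + 1]] <- data.frame(
      rater_id = paste0("r", r), headline_id = names(calib_truth),
      item_class = "calibration", rating = as.numeric(calib_truth),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      rater_id = paste0("r", r), headline_id = c("h1", "h2"),
      item_class = "main", rating = c(2, r %% 3 + 2),
      stringsAsFactors = FALSE)
  }
  # constant rater: zero variance everywhere
  rows[[length(rows) + 1]] <- data.frame(
    rater_id = "const", headline_id = c(names(calib_truth), "h1", "h2"),
    item_class = c(rep("calibration", 4), "main", "main"),
    rating = 3, stringsAsFactors = FALSE)
  # adversarial rater: anti-correlated on calibration
  rows[[length(rows) + 1]] <- data.frame(
    rater_id = "adv", headline_id = names(calib_truth),
    item_class = "calibration", rating = as.numeric(rev(calib_truth)),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

test_that("apply_rater_qc excludes constant, adversarial, attention-fail,
           and consent-revoked raters", {
  panel <- make_panel()
  res <- apply_rater_qc(panel)
  qc <- res$qc
  expect_true(qc$excluded[qc$rater_id == "const"])
  expect_equal(qc$reason[qc$rater_id == "const"], "zero_variance")
  expect_true(qc$excluded[qc$rater_id == "adv"])
  expect_equal(qc$reason[qc$rater_id == "adv"], "low_calibration_correlation")
  expect_lt(qc$calibration_r[qc$rater_id == "adv"], 0.2)
  # honest raters match the leave-one-out mean exactly: r = 1, retained
  expect_true(all(!qc$excluded[qc$rater_id %in% paste0("r", 1:5)]))
  expect_equal(qc$calibration_r[qc$rater_id == "r1"], 1)
  # their responses are gone from the clean set
  expect_false(any(res$clean$rater_id %in% c("const", "adv")))

  # attention + consent flags
  panel2 <- panel
  panel2$attention_pass <- TRUE
  panel2 <- rbind(panel2, data.frame(
    rater_id = "r1", headline_id = "att", item_class = "attention_check",
    rating = 3, attention_pass = FALSE, stringsAsFactors = FALSE))
  res2 <- apply_rater_qc(panel2)
  expect_equal(res2$qc$reason[res2$qc$rater_id == "r1"], "failed_attention")
  panel3 <- panel
  panel3$consent_revoked <- panel3$rater_id == "r2"
  res3 <- apply_rater_qc(panel3)
  expect_equal(res3$qc$reason[res3$qc$rater_id == "r2"], "revoked_consent")
})

test_that("apply_rater_qc is idempotent and drops dont_understand first", {
  panel <- make_panel()
  panel$rating[1] <- NA  # a dont_understand response
  res1 <- apply_rater_qc(panel)
  res2 <- apply_rater_qc(res1$clean)
  expect_equal(res1$clean$rating, res2$clean$rating)
  expect_equal(sort(unique(res1$clean$rater_id)),
               sort(unique(res2$clean$rater_id)))
  expect_false(any(is.na(res1$clean$rating)))
})

test_that("compute_icc matches an independent ANOVA oracle on a small design", {
  # 3 headlines x 3 raters, hand-enumerable
  d <- data.frame(
    headline_id = rep(c("a", "b", "c"), each = 3),
    rating = c(1, 2, 1, 3, 3, 4, 5, 4, 5))
  res <- compute_icc(d)
  # independent oracle: one-way ANOVA mean squares from first principles
  ybar <- mean(d$rating)
  gm <- tapply(d$rating, d$headline_id, mean)
  msb <- sum(3 * (gm - ybar)^2) / 2
  msw <- sum((d$rating - gm[d$headline_id])^2) / 6
  icc1 <- (msb - msw) / (msb + 2 * msw)       # balanced, k = 3
  icck <- (msb - msw) / msb
  expect_equal(res$icc_single, icc1, tolerance = 1e-9)
  expect_equal(res$icc_average, icck, tolerance = 1e-9)
  expect_equal(res$k, 3)
})

test_that("compute_icc edge cases", {
  # perfect agreement between raters, headlines differ -> icc_single = 1
  d <- data.frame(headline_id = rep(c("a", "b"), each = 3),
                  rating = rep(c(2, 4), each = 3))
  res <- compute_icc(d)
  expect_equal(res$icc_single, 1)
  expect_equal(res$icc_average, 1)
  # degenerate: all identical
  d2 <- data.frame(headline_id = rep(c("a", "b"), each = 2), rating = 3)
  expect_error(compute_icc(d2), "degenerate")
  expect_error(compute_icc(data.frame(headline_id = "a", rating = 1:2)),
               "at least 2")
})

test_that("icc_single is near zero for pure noise and recovers the
           variance ratio; icc_average >= icc_single", {
  set.seed(101)
  # zero between-headline variance
  d0 <- data.frame(headline_id = rep(seq_len(1000), each = 5),
                   rating = rnorm(5000))
  expect_lt(abs(compute_icc(d0)$icc_single), 0.05)
  # known ratio: sigma_b^2 = 1, sigma_w^2 = 3 -> 0.25
  nh <- 2000; k <- 10
  b <- rnorm(nh, 0, 1)
  d1 <- data.frame(headline_id = rep(seq_len(nh), each = k),
                   rating = rep(b, each = k) + rnorm(nh * k, 0, sqrt(3)))
  res <- compute_icc(d1)
  expect_equal(res$icc_single, 0.25, tolerance = 0.03)
  expect_gte(res$icc_average, res$icc_single)
})

test_that("correlate_with_computational matches the arithmetic oracle", {
  x <- c(1.0, 2.5, 3.0, 4.2, 4.9)
  y <- c(1.2, 2.0, 3.5, 3.9, 5.0)
  res <- correlate_with_computational(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(correlate_with_computational(x, x)$pearson_r, 1)
  expect_equal(correlate_with_computational(x, -x)$pearson_r, -1)
  expect_error(correlate_with_computational(x, rep(1, 5)), "zero variance")
  expect_error(correlate_with_computational(1:2, 1:2), "at least 3")
})

test_that("stratified_sample draws per_bin from each bin, seeded", {
  set.seed(5)
  n <- 2000
  corpus <- data.frame(
    headline = vapply(seq_len(n), function(i)
      paste(rep("w", 15), collapse = " "), character(1)),
    score = runif(n, 0, 5), stringsAsFactors = FALSE)
  s <- stratified_sample(corpus, per_bin = 20, seed = 9)
  expect_equal(nrow(s), 80)
  expect_equal(as.vector(table(s$bin)), rep(20, 4))
  # bins are disjoint and cover [0,5]
  expect_false(any(duplicated(rownames(s))))
  # determinism
  s2 <- stratified_sample(corpus, per_bin = 20, seed = 9)
  expect_equal(s$headline, s2$headline)
  expect_equal(s$score, s2$score)
  # empty draw and under-populated bin
  expect_equal(nrow(stratified_sample(corpus, per_bin = 0, seed = 1)), 0)
  expect_error(stratified_sample(corpus[1:5, ], per_bin = 80, seed = 1),
               "has only")
  # word-count window is enforced
  corpus$headline[1] <- "short one"
  s3 <- stratified_sample(corpus, per_bin = 20, seed = 9)
  expect_false("short one" %in% s3$headline)
})
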