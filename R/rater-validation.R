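#' Rater quality control for the human validation panel
#'
#' Excludes raters who (a) correlate below `min_calibration_r` with the
#' leave-one-out mean of all other raters on the calibration items, (b) show
#' zero variance across all their scale ratings, (c) fail the attention
#' check, or (d) revoked consent. All responses of an excluded rater are
#' removed. "Don't understand" responses are dropped before any statistic is
#' computed (they are not scale values).
#'
#' @param responses Data frame with columns `rater_id`, `headline_id`,
#'   `item_class` (`"calibration"`, `"attention_check"`, `"main"`),
#'   `rating` (integer 1--5, `NA` allowed), and optionally `dont_understand`
#'   (logical) and `consent_revoked` (logical, constant per rater).
#' @param min_calibration_r Calibration-correlation threshold (default 0.2).
#' @param attention_expected Named list or `NULL`; if the data carry an
#'   `attention_pass` logical column it is used directly.
#' @param unevaluable Policy for raters whose calibration correlation is
#'   undefined (fewer than 2 usable calibration items): `"exclude"` or
#'   `"keep"`.
#' @return List with `clean` (responses of retained raters, main items only
#'   keep their rating values) and `qc` (one row per rater: `rater_id`,
#'   `excluded`, `reason`, `calibration_r`).
#' @export
apply_rater_qc <- function(responses, min_calibration_r = 0.2,
                           attention_expected = NULL,
                           unevaluable = c("exclude", "keep")) {
  unevaluable <- match.arg(unevaluable)
  req <- c("rater_id", "headline_id", "item_class", "rating")
  if (!all(req %in% names(responses))) {
    stop("responses must have columns: ", paste(req, collapse = ", "))
  }
  if (!"dont_understand" %in% names(responses)) {
    responses$dont_understand <- is.na(responses$rating)
  }
  usable <- responses[!responses$dont_understand & !is.na(responses$rating), ]

  raters <- unique(responses$rater_id)
  calib <- usable[usable$item_class == "calibration", ]
  # leave-one-out mean per calibration item
  calib_items <- sort(unique(calib$headline_id))
  item_sum <- tapply(calib$rating, calib$headline_id, sum)
  item_n <- tapply(calib$rating, calib$headline_id, length)

  qc <- data.frame(rater_id = raters, excluded = FALSE, reason = "none",
                   calibration_r = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(raters)) {
    r <- raters[k]
    rows <- responses$rater_id == r
    if ("consent_revoked" %in% names(responses) &&
        any(responses$consent_revoked[rows], na.rm = TRUE)) {
      qc$excluded[k] <- TRUE; qc$reason[k] <- "revoked_consent"; next
    }
    if ("attention_pass" %in% names(responses)) {
      ap <- responses$attention_pass[rows & responses$item_class == "attention_check"]
      if (length(ap) && any(!ap, na.rm = TRUE)) {
        qc$excluded[k] <- TRUE; qc$reason[k] <- "failed_attention"; next
      }
    }
    own <- calib[calib$rater_id == r, ]
    if (nrow(own) >= 2) {
      loo <- (item_sum[as.character(own$headline_id)] - own$rating) /
        pmax(item_n[as.character(own$headline_id)] - 1, 1)
      r_cal <- suppressWarnings(stats::cor(own$rating, loo))
      qc$calibration_r[k] <- r_cal
      if (is.na(r_cal)) {
        # zero variance in own calibration ratings; fall through to the
        # zero-variance check below rather than judging calibration
      } else if (r_cal < min_calibration_r) {
        qc$excluded[k] <- TRUE; qc$reason[k] <- "low_calibration_correlation"
        next
      }
    } else if (unevaluable == "exclude") {
      qc$excluded[k] <- TRUE; qc$reason[k] <- "low_calibration_correlation"
      next
    }
    all_own <- usable$rating[usable$rater_id == r]
    if (length(all_own) >= 2 && stats::var(all_own) == 0) {
      qc$excluded[k] <- TRUE; qc$reason[k] <- "zero_variance"; next
    }
    if (nrow(own) >= 2 && is.na(qc$calibration_r[k])) {
      # constant calibration ratings but variance elsewhere: unevaluable
      if (unevaluable == "exclude") {
        qc$excluded[k] <- TRUE; qc$reason[k] <- "low_calibration_correlation"
      }
    }
  }
  keep <- qc$rater_id[!qc$excluded]
  clean <- usable[usable$rater_id %in% keep, ]
  list(clean = clean, qc = qc)
}

#' One-way random-effects intraclass correlations
#'
#' Computes ICC(1) for single ratings and ICC(1, k) for the average rating
#' from the one-way ANOVA decomposition, appropriate for an incomplete
#' design in which each headline is rated by a different random subset of
#' raters. For unbalanced data the effective group size
#' \eqn{k_0 = (N - \sum n_i^2 / N) / (n - 1)} is used in the variance
#' decomposition, and the averaging ICC uses \eqn{k} = the mean number of
#' ratings per headline.
#'
#' @param ratings Data frame with columns `headline_id` and `rating` (one
#'   row per individual rating).
#' @return List with `icc_single`, `icc_average`, `k` (mean ratings per
#'   headline), `msb`, `msw`, `n_headlines`, `n_ratings`.
#' @export
compute_icc <- function(ratings) {
  stopifnot(all(c("headline_id", "rating") %in% names(ratings)))
  ratings <- ratings[!is.na(ratings$rating), ]
  ni <- tapply(ratings$rating, ratings$headline_id, length)
  if (length(ni) < 2 || any(ni < 2)) {
    stop("need at least 2 headlines, each with at least 2 ratings")
  }
  if (stats::var(ratings$rating) == 0) {
    stop("degenerate ratings: all values identical")
  }
  N <- nrow(ratings)
  n <- length(ni)
  gm <- mean(ratings$rating)
  means <- tapply(ratings$rating, ratings$headline_id, mean)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((ratings$rating - means[as.character(ratings$headline_id)])^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (N - n)
  k0 <- (N - sum(ni^2) / N) / (n - 1)   # effective group size, unbalanced
  sigma_b <- max((msb - msw) / k0, 0)
  icc_single <- sigma_b / (sigma_b + msw)
  k <- mean(ni)
  # Spearman-Brown step-up of the single-rating ICC to an average of k
  icc_average <- k * icc_single / (1 + (k - 1) * icc_single)
  list(icc_single = unname(icc_single), icc_average = unname(icc_average),
       k = unname(k), msb = unname(msb), msw = unname(msw),
       n_headlines = n, n_ratings = N)
}

#' Correlate mean human ratings with the computational score
#'
#' Standard Pearson product-moment correlation with a two-sided p-value.
#'
#' @param human Numeric vector of per-headline mean human ratings.
#' @param computational Numeric vector of computational scores, same length.
#' @return List with `pearson_r`, `p_value`, `n`.
#' @export
correlate_with_computational <- function(human, computational) {
  if (length(human) != length(computational)) stop("length mismatch")
  ok <- !is.na(human) & !is.na(computational)
  human <- human[ok]; computational <- computational[ok]
  if (length(human) < 3) stop("need at least 3 paired values")
  if (stats::var(human) == 0 || stats::var(computational) == 0) {
    stop("zero variance in one of the vectors")
  }
  ct <- stats::cor.test(human, computational, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = length(human))
}

#' Stratified sample of headlines by computational concreteness
#'
#' Draws `per_bin` headlines uniformly at random from each score bin,
#' restricted to headlines whose word count lies within
#' `word_count_window` (perceived concreteness correlates with expression
#' length, so length is held near-constant). Deterministic given `seed`.
#'
#' @param scored Data frame with columns `headline`, `score` and optionally
#'   `word_count` (computed from the headline if absent).
#' @param bins Numeric vector of bin edges covering \[0, 5\]; default
#'   `c(0, 2.5, 3, 3.5, 5)`. Bins are left-closed; the last is closed.
#' @param per_bin Headlines to draw per bin.
#' @param word_count_window Length-2 integer vector, inclusive.
#' @param seed Integer seed.
#' @return Data frame of sampled rows with an added `bin` column.
#' @export
stratified_sample <- function(scored, bins = c(0, 2.5, 3, 3.5, 5),
                              per_bin = 80, word_count_window = c(14, 16),
                              seed = 1L) {
  stopifnot(all(c("headline", "score") %in% names(scored)))
  if (is.unsorted(bins) || length(bins) < 2) stop("bins must be increasing")
  scored <- scored[!is.na(scored$score), ]
  if (!"word_count" %in% names(scored)) {
    scored$word_count <- lengths(strsplit(trimws(scored$headline), "\\s+"))
  }
  scored <- scored[scored$word_count >= word_count_window[1] &
                     scored$word_count <= word_count_window[2], ]
  scored$bin <- cut(scored$score, breaks = bins, right = FALSE,
                    include.lowest = TRUE)
  # right-most edge belongs to the last bin
  scored$bin[scored$score == bins[length(bins)]] <-
    levels(scored$bin)[nlevels(scored$bin)]
  if (per_bin == 0) return(scored[0, ])
  set.seed(seed)
  out <- lapply(levels(scored$bin), function(b) {
    pool <- scored[!is.na(scored$bin) & scored$bin == b, ]
    if (nrow(pool) < per_bin) {
      stop("bin ", b, " has only ", nrow(pool), " headlines (< ", per_bin, ")")
    }
    pool[sample.int(nrow(pool), per_bin), ]
  })
  do.call(rbind, out)
}
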