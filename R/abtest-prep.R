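#' Read a headline A/B-test archive
#'
#' Reads the archive CSV dialect (one row per package: a headline--image
#' pair tested in one arm of an experiment). Rows with a missing headline or
#' non-numeric counts are dropped with a logged count; rows with
#' `clicks > impressions` are rejected.
#'
#' @param path CSV file path, or a data frame already in memory.
#' @param test_id_col,headline_col,image_id_col,impressions_col,clicks_col
#'   Column names in the file; defaults follow the public archive dialect.
#' @return Data frame with canonical columns `test_id`, `headline`,
#'   `image_id`, `impressions`, `clicks`, plus attribute `"n_dropped"`.
#' @export
read_archive <- function(path,
                         test_id_col = "clickability_test_id",
                         headline_col = "headline",
                         image_id_col = "eyecatcher_id",
                         impressions_col = "impressions",
                         clicks_col = "clicks") {
  if (is.data.frame(path)) {
    tab <- path
  } else {
    if (!file.exists(path)) stop("archive file does not exist: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  }
  cols <- c(test_id_col, headline_col, image_id_col, impressions_col,
            clicks_col)
  if (!all(cols %in% names(tab))) {
    stop("archive lacks required columns: ",
         paste(setdiff(cols, names(tab)), collapse = ", "))
  }
  out <- data.frame(test_id = as.character(tab[[test_id_col]]),
                    headline = as.character(tab[[headline_col]]),
                    image_id = as.character(tab[[image_id_col]]),
                    impressions = suppressWarnings(as.numeric(tab[[impressions_col]])),
                    clicks = suppressWarnings(as.numeric(tab[[clicks_col]])),
                    stringsAsFactors = FALSE)
  n0 <- nrow(out)
  ok <- !is.na(out$headline) & nzchar(trimws(out$headline)) &
    !is.na(out$impressions) & !is.na(out$clicks) &
    out$impressions >= 0 & out$clicks >= 0 & out$clicks <= out$impressions
  out <- out[ok, ]
  n_dropped <- n0 - nrow(out)
  if (n_dropped > 0) {
    message(n_dropped, " archive row(s) dropped (missing headline, ",
            "unparseable counts, or clicks > impressions)")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Split tests into same-image candidate bundles
#'
#' Headlines within one test are causally comparable only when shown with
#' the same image; within each `test_id` the packages are partitioned by
#' `image_id` and each partition becomes a candidate comparable test with a
#' derived id `"<test_id>#<image_id>"`. The partition neither duplicates nor
#' loses packages.
#'
#' @param packages Data frame from [read_archive()].
#' @return The same data frame with an added `derived_test_id` column.
#' @export
split_by_image <- function(packages) {
  stopifnot(all(c("test_id", "image_id") %in% names(packages)))
  packages$derived_test_id <- paste0(packages$test_id, "#", packages$image_id)
  packages
}

#' Keep only validly comparable tests
#'
#' Drops packages whose headline was excluded by the scorer, then keeps
#' candidate bundles that still contain at least two *distinct* headline
#' strings (exact comparison after whitespace normalization; case
#' differences count as distinct). Singleton bundles are removed.
#'
#' @param candidates Data frame from [split_by_image()].
#' @param scores Data frame mapping `headline` to `score` and `excluded`
#'   (e.g. the output of [score_corpus()]), or `NULL` if `candidates`
#'   already carries `score`/`excluded` columns.
#' @return Data frame of retained packages with a `score` column and
#'   attribute `"n_tests"` (number of retained derived tests).
#' @export
filter_valid <- function(candidates, scores = NULL) {
  stopifnot("derived_test_id" %in% names(candidates))
  if (!is.null(scores)) {
    stopifnot(all(c("headline", "score", "excluded") %in% names(scores)))
    idx <- match(candidates$headline, scores$headline)
    candidates$score <- scores$score[idx]
    candidates$excluded <- scores$excluded[idx]
  }
  stopifnot(all(c("score", "excluded") %in% names(candidates)))
  keep <- !is.na(candidates$score) & !candidates$excluded
  candidates <- candidates[keep, ]
  if (nrow(candidates) == 0L) {
    attr(candidates, "n_tests") <- 0L
    return(candidates)
  }
  norm <- gsub("\\s+", " ", trimws(candidates$headline))
  n_distinct <- tapply(norm, candidates$derived_test_id,
                       function(x) length(unique(x)))
  valid_ids <- names(n_distinct)[n_distinct >= 2]
  out <- candidates[candidates$derived_test_id %in% valid_ids, ]
  attr(out, "n_tests") <- length(valid_ids)
  out
}

#' Standardize headline concreteness for the multilevel model
#'
#' The individual-level predictor is the headline's concreteness centered at
#' its own test's mean and divided by two standard deviations, where the SD
#' is taken over the group-mean-centered values of the whole analysis sample
#' (so +0.5 standardized units is one raw SD above the test mean). The
#' group-level moderator `test_concreteness_mean` stays on the raw 0--5
#' scale. Group-mean centering makes the two predictors uncorrelated by
#' construction.
#'
#' @param tests Data frame from [filter_valid()] (columns `derived_test_id`,
#'   `score`, `impressions`, `clicks`).
#' @param centering `"group"` (default) or `"grand"` (sensitivity analysis).
#' @param scaling Optional scaling report from a previous call, to apply a
#'   frozen transformation (re-standardizing standardized data with its own
#'   report returns it unchanged).
#' @return List with `data` (columns `derived_test_id`,
#'   `headline_concreteness_std`, `test_concreteness_mean`, `impressions`,
#'   `clicks`, `ctr`) and `scaling` (list: `sd_centered`, `grand_mean`,
#'   `centering`).
#' @export
standardize_concreteness <- function(tests, centering = c("group", "grand"),
                                     scaling = NULL) {
  centering <- match.arg(centering)
  req <- c("derived_test_id", "score", "impressions", "clicks")
  stopifnot(all(req %in% names(tests)))
  if (length(unique(tests$derived_test_id)) < 2) {
    stop("need at least 2 tests to standardize")
  }
  group_mean <- stats::ave(tests$score, tests$derived_test_id)
  centered <- if (centering == "group") {
    tests$score - group_mean
  } else {
    tests$score - mean(tests$score)
  }
  if (is.null(scaling)) {
    sd_centered <- stats::sd(centered)
    if (!is.finite(sd_centered) || sd_centered == 0) {
      stop("zero standard deviation of centered concreteness")
    }
    scaling <- list(sd_centered = sd_centered, grand_mean = mean(tests$score),
                    centering = centering)
  }
  data.frame(derived_test_id = tests$derived_test_id,
             headline_concreteness_std = centered / (2 * scaling$sd_centered),
             test_concreteness_mean = group_mean,
             impressions = tests$impressions,
             clicks = tests$clicks,
             ctr = ifelse(tests$impressions > 0,
                          tests$clicks / tests$impressions, NA_real_),
             stringsAsFactors = FALSE) -> dat
  list(data = dat, scaling = scaling)
}

#' Clickthrough-rate summary over packages
#'
#' CTR is clicks/impressions per package. Packages with zero impressions are
#' excluded from the CTR summaries and counted separately.
#'
#' @param packages Data frame with `impressions`, `clicks`, and (optionally)
#'   `derived_test_id` or `test_id`.
#' @return List with `mean_ctr`, `median_ctr`, `n_packages`, `n_tests`,
#'   `n_zero_impressions`.
#' @export
summarize_ctr <- function(packages) {
  stopifnot(all(c("impressions", "clicks") %in% names(packages)))
  zero <- packages$impressions == 0
  ctr <- packages$clicks[!zero] / packages$impressions[!zero]
  idcol <- intersect(c("derived_test_id", "test_id"), names(packages))
  list(mean_ctr = mean(ctr), median_ctr = stats::median(ctr),
       n_packages = nrow(packages),
       n_tests = if (length(idcol)) length(unique(packages[[idcol[1]]])) else NA_integer_,
       n_zero_impressions = sum(zero))
}
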