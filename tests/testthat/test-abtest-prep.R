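lex <- fixture_lexicon()

test_that("read_archive validates rows and enforces clicks <= impressions", {
  arc <- fixture_archive()
  pk <- read_archive(arc)
  expect_equal(nrow(pk), 5)
  expect_equal(attr(pk, "n_dropped"), 0L)

  arc_bad <- rbind(arc,
                   data.frame(clickability_test_id = "t3", headline = "x",
                              eyecatcher_id = "i", impressions = 10,
                              clicks = 20, stringsAsFactors = FALSE),
                   data.frame(clickability_test_id = "t3", headline = "",
                              eyecatcher_id = "i", impressions = 10,
                              clicks = 1, stringsAsFactors = FALSE))
  expect_message(pk2 <- read_archive(arc_bad), "2 archive row")
  expect_equal(nrow(pk2), 5)
  expect_equal(attr(pk2, "n_dropped"), 2L)
  expect_error(read_archive(arc[, -1]), "required columns")

  # reading from disk matches in-memory
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(arc, tmp, row.names = FALSE)
  expect_equal(read_archive(tmp)$headline, pk$headline)
})

test_that("split_by_image partitions by (test, image) without losing or
           duplicating packages", {
  pk <- read_archive(fixture_archive())
  sp <- split_by_image(pk)
  # the illustrated scenario: within t1, headlines 1-2 share imgA,
  # headline 3 sits alone on imgB -> partitions of sizes 2 and 1
  sizes <- table(sp$derived_test_id[sp$test_id == "t1"])
  expect_equal(sort(as.vector(sizes)), c(1, 2))
  # partition property
  expect_equal(nrow(sp), nrow(pk))
  expect_equal(sort(sp$headline), sort(pk$headline))
  # single-image test -> one partition
  expect_equal(length(unique(sp$derived_test_id[sp$test_id == "t2"])), 1)
})

test_that("filter_valid drops scorer-excluded packages, singletons, and
           identical-headline pairs", {
  pk <- split_by_image(read_archive(fixture_archive()))
  scored <- score_corpus(unique(pk["headline"]), lex)
  v <- filter_valid(pk, scored)
  # the singleton t1/imgB partition is gone
  expect_false(any(v$derived_test_id == "t1#imgB"))
  expect_equal(attr(v, "n_tests"), 2L)
  # every retained test satisfies the comparable-test invariants
  for (id in unique(v$derived_test_id)) {
    sub <- v[v$derived_test_id == id, ]
    expect_gte(nrow(sub), 2)
    expect_equal(length(unique(sub$image_id)), 1)
    expect_gte(length(unique(sub$headline)), 2)
    expect_false(any(is.na(sub$score)))
  }

  # identical headline strings do not count as two distinct headlines
  dup <- data.frame(test_id = "d", headline = c("Tomato Dog", "Tomato  Dog "),
                    image_id = "i", impressions = c(10, 10), clicks = c(1, 1),
                    derived_test_id = "d#i", score = 4.9, excluded = FALSE,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(filter_valid(dup)), 0)

  # a 3-package test with one scorer-excluded headline survives with 2
  tri <- data.frame(test_id = "e",
                    headline = c("Tomato Dog", "Cat Water", "Obamacare Yes"),
                    image_id = "i", impressions = 10, clicks = 1,
                    derived_test_id = "e#i",
                    score = c(4.9, 4.9, NA), excluded = c(FALSE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  out <- filter_valid(tri)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_tests"), 1L)

  # empty input
  expect_equal(nrow(filter_valid(tri[0, ])), 0)
})

test_that("standardize_concreteness centers within test and scales by 2 SD", {
  tests <- data.frame(
    derived_test_id = rep(c("a", "b"), each = 2),
    score = c(2, 3, 4, 5), impressions = c(100, 100, 100, 100),
    clicks = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  std <- standardize_concreteness(tests)
  d <- std$data
  # two-headline test with raw scores {2,3}: centered {-0.5, +0.5}
  centered <- d$headline_concreteness_std * 2 * std$scaling$sd_centered
  expect_equal(centered[1:2], c(-0.5, 0.5))
  # per-test centered values sum to zero
  sums <- tapply(d$headline_concreteness_std, d$derived_test_id, sum)
  expect_equal(max(abs(sums)), 0, tolerance = 1e-12)
  # moderator stays on the raw scale
  expect_equal(unique(d$test_concreteness_mean), c(2.5, 4.5))
  # scaling report records the SD actually used
  expect_equal(std$scaling$sd_centered, sd(c(-0.5, 0.5, -0.5, 0.5)))
  # zero-SD error
  same <- tests; same$score <- 3
  expect_error(standardize_concreteness(same), "zero standard deviation")
  expect_error(standardize_concreteness(tests[1:2, ]), "at least 2 tests")
})

test_that("standardization is idempotent and decorrelates the predictors", {
  sim <- generate_archive(synth_config(n_tests = 300), seed = 21)
  pk <- split_by_image(read_archive(sim$archive))
  pk$score <- sim$truth$concreteness
  pk$excluded <- FALSE
  std <- standardize_concreteness(filter_valid(pk))
  d <- std$data
  r <- cor(d$headline_concreteness_std, d$test_concreteness_mean)
  expect_lt(abs(r), 0.01)
  # re-standardizing the standardized data returns it unchanged
  again <- standardize_concreteness(data.frame(
    derived_test_id = d$derived_test_id,
    score = d$headline_concreteness_std,
    impressions = d$impressions, clicks = d$clicks,
    stringsAsFactors = FALSE))
  expect_equal(again$data$headline_concreteness_std,
               d$headline_concreteness_std, tolerance = 1e-12)
})

test_that("summarize_ctr computes package-level CTR summaries", {
  pk <- data.frame(impressions = c(100, 100, 100), clicks = c(1, 2, 3),
                   test_id = "t")
  s <- summarize_ctr(pk)
  expect_equal(s$mean_ctr, 0.02)
  expect_equal(s$median_ctr, 0.02)
  expect_equal(s$n_zero_impressions, 0L)
  # single package: mean = median
  s1 <- summarize_ctr(pk[1, ])
  expect_equal(s1$mean_ctr, s1$median_ctr)
  # zero-impression packages counted separately
  pk0 <- rbind(pk, data.frame(impressions = 0, clicks = 0, test_id = "t"))
  s0 <- summarize_ctr(pk0)
  expect_equal(s0$n_zero_impressions, 1L)
  expect_equal(s0$mean_ctr, 0.02)
})

test_that("synthetic archive at the stated pilot CTR recovers ~1.33% mean", {
  # binomial sampling oracle: configure the generator so the analytic
  # population mean CTR is 1.33%, then check the sample mean
  cfg <- synth_config(n_tests = 800, re_sd = c(1e-6, 1e-6),
                      beta = c(qlogis(0.0133), 0, 0, 0))
  sim <- generate_archive(cfg, seed = 3)
  s <- summarize_ctr(read_archive(sim$archive))
  expect_equal(s$mean_ctr, 0.0133, tolerance = 0.1)
})
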