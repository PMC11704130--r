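# Shared fixtures, built in code at test time.

fixture_lexicon <- function() {
  load_lexicon(system.file("extdata", "fixture_lexicon.csv",
                           package = "concreteness"))
}

# tiny archive with a known comparable-test structure (the image-splitting
# scenario: headlines 1-2 share an image, headline 3 has another)
fixture_archive <- function() {
  data.frame(
    clickability_test_id = c("t1", "t1", "t1", "t2", "t2"),
    headline = c("Tomato House Dog", "Cat Water Tree", "Baby Photo Video",
                 "Water Tree", "Tomato Dog"),
    eyecatcher_id = c("imgA", "imgA", "imgB", "imgC", "imgC"),
    impressions = c(1000, 1200, 900, 800, 700),
    clicks = c(12, 9, 10, 8, 6),
    stringsAsFactors = FALSE)
}

table2_beta <- c(-4.929, 0.168, 0.102, -0.058)

# a well-conditioned fixed-effect covariance on the scale of the reported
# intervals (se = width/3.92)
table2_vcov_diag <- function() {
  se <- c((5.085 - 4.772) / 2, (0.271 - 0.066) / 2, (0.153 - 0.051) / 2,
          (0.091 - 0.025) / 2) / 1.96
  diag(se^2)
}

# small standardized dataset for likelihood checks: 3 groups x 3 headlines.
# Impressions are large so each group's random-effect posterior is sharply
# peaked: the irreducible Laplace approximation error is then ~1e-4 and any
# implementation bug dominates the Laplace-vs-quadrature comparison. (At
# a few hundred impressions the genuine approximation error alone is ~5e-3;
# verified against brute-force 2-D grid integration.)
fixture_glmm_data <- function(seed = 42) {
  set.seed(seed)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  hc <- as.vector(replicate(3, scale(stats::rnorm(3), scale = FALSE)))
  hc <- hc / (2 * stats::sd(hc))
  mtc <- rep(stats::runif(3, 2.5, 3.5), each = 3)
  n <- sample(20000:50000, 9, replace = TRUE)
  p <- stats::plogis(-3 + 0.3 * hc + 0.1 * mtc)
  data.frame(derived_test_id = g, headline_concreteness_std = hc,
             test_concreteness_mean = mtc, impressions = n,
             clicks = stats::rbinom(9, n, p), stringsAsFactors = FALSE)
}
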