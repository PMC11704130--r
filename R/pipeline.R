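#' Run the full analysis pipeline
#'
#' Wires the stages end to end: score headlines, decompose tests into
#' same-image comparable sets, standardize, fit the binomial multilevel
#' model, probe simple slopes (Holm-corrected over the three-hypothesis
#' family), and compute the Johnson-Neyman region. Emits a machine-readable
#' report with a provenance block (package version, seed, config hash).
#'
#' @param config Named list (or path to a JSON file) with elements:
#'   `lexicon` (path), `archive` (path or data frame), `out_dir` (optional:
#'   report written as `report.json` there), `seed` (default 1),
#'   `alpha` (default 0.05), `critical_value` (default 1.96),
#'   `centering` (`"group"`/`"grand"`), `retained_stopwords` (optional
#'   character vector), `optimizer` (default `"bobyqa"`), `nAGQ` (default 1),
#'   `holm_family_size` (default 3).
#' @return The report, an invisible list: `fit` (Table-2-style fields),
#'   `simple_slopes`, `holm`, `jn`, `ctr_summary`, `exclusions`, `scaling`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(seed = 1L, alpha = 0.05, critical_value = 1.96,
                   centering = "group", optimizer = "bobyqa", nAGQ = 1L,
                   holm_family_size = 3L)
  config <- utils::modifyList(defaults, config)
  for (key in c("lexicon", "archive")) {
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
    if (is.character(config[[key]]) && !file.exists(config[[key]])) {
      stop("config path for '", key, "' does not exist: ", config[[key]])
    }
  }
  set.seed(as.integer(config$seed))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  lex <- stage("lexicon", {
    if (inherits(config$lexicon, "concreteness_lexicon")) config$lexicon
    else load_lexicon(config$lexicon)
  })
  pkgs <- stage("read_archive", read_archive(config$archive))
  sw <- if (is.null(config$retained_stopwords)) stopword_config()
        else stopword_config(retained = config$retained_stopwords)
  scored <- stage("score", {
    uh <- unique(pkgs["headline"])
    score_corpus(uh, lex, stopwords = sw)
  })
  cand <- stage("split", split_by_image(pkgs))
  valid <- stage("filter", filter_valid(cand, scored))
  std <- stage("standardize",
               standardize_concreteness(valid, centering = config$centering))
  fit <- stage("fit", fit_binomial_glmm(std$data,
                                        optimizer = config$optimizer,
                                        nAGQ = config$nAGQ))
  mtc_by_test <- tapply(std$data$test_concreteness_mean,
                        std$data$derived_test_id, mean)
  probe <- c(min = min(mtc_by_test), mean = mean(mtc_by_test),
             max = max(mtc_by_test))
  ss <- stage("slopes", simple_slope(fit, probe))
  p_raw <- c(h1_interaction = fit$p_values[["interaction"]],
             h2_slope_at_min = ss$p[1], h3_slope_at_max = ss$p[3])
  p_holm <- holm_adjust(p_raw, family_size = config$holm_family_size)
  jn <- stage("jn", johnson_neyman(fit,
                                   critical_value = config$critical_value,
                                   moderator_values = as.numeric(mtc_by_test)))
  excl <- attr(scored, "exclusion_summary")

  cfg_hash <- local({
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(
      config[setdiff(names(config), c("archive", "lexicon"))],
      auto_unbox = TRUE), tmp)
    unname(tools::md5sum(tmp))
  })
  report <- list(
    fit = list(beta = as.list(fit$beta),
               ci = apply(fit$beta_ci, 1, as.list),
               p_values = as.list(fit$p_values),
               re_variances = fit$re_variances,
               loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
               n_obs = fit$n_obs, n_groups = fit$n_groups,
               converged = fit$converged, singular = fit$singular),
    simple_slopes = cbind(at = names(probe), ss),
    holm = list(raw = as.list(p_raw), adjusted = as.list(
      stats::setNames(p_holm, names(p_raw)))),
    jn = list(lower_bound = jn$lower_bound, upper_bound = jn$upper_bound,
              region = jn$region, critical_value = jn$critical_value,
              fraction_below = jn$fraction_below,
              fraction_above = jn$fraction_above),
    ctr_summary = summarize_ctr(std$data),
    exclusions = excl,
    scaling = std$scaling,
    provenance = list(
      package_version = as.character(utils::packageVersion("concreteness")),
      r_version = R.version.string,
      seed = config$seed, config_hash = cfg_hash,
      timestamp = format(Sys.time(), tz = "UTC"))
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(report)
}
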