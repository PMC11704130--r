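#' Standard English stopwords with headline exceptions
#'
#' Headline scoring removes stopwords, but deliberately keeps two classes of
#' function words that carry the information-gap signal in headlines:
#' forward-reference words ("this", "these", ...) and personal pronouns
#' ("she", "they", ...).
#'
#' @param retained Character vector of stopwords to keep as scoreable
#'   candidates despite appearing on the stopword list.
#' @return List with elements `remove` (stopwords to drop) and `retain`
#'   (the exception list).
#' @export
stopword_config <- function(retained = default_retained_stopwords()) {
  path <- system.file("extdata", "stopwords_en.txt",
                      package = "concreteness", mustWork = TRUE)
  all_sw <- readLines(path, warn = FALSE)
  list(remove = setdiff(all_sw, retained), retain = retained)
}

#' @rdname stopword_config
#' @export
default_retained_stopwords <- function() {
  c("this", "these", "that", "those",                 # forward references
    "she", "he", "they", "her", "him", "them",        # pronouns
    "it", "we", "you", "i")
}

#' Tokenize a headline and select scoreable candidates
#'
#' Entity spans (from [detect_entities()] on the same text) are emitted as
#' single candidate tokens flagged as entities. Remaining tokens are
#' case-folded; punctuation and cardinal numbers are dropped; stopwords are
#' dropped except those on the retained list. Possessive "'s" is stripped.
#'
#' @param headline Non-empty character scalar.
#' @param entities Data frame of entity spans (`start`, `end`, `text`,
#'   `type`), as returned by [detect_entities()].
#' @param stopwords A list from [stopword_config()].
#' @return Data frame with columns `token` (case-folded candidate, or the
#'   original entity text) and `is_entity`.
#' @export
tokenize_and_filter <- function(headline, entities,
                                stopwords = stopword_config()) {
  toks <- tokenize_raw(headline)
  out_tok <- character(0)
  out_ent <- logical(0)
  emitted_span <- rep(FALSE, nrow(entities))
  for (k in seq_len(nrow(toks))) {
    s <- toks$start[k]
    hit <- which(s >= entities$start & s <= entities$end)
    if (length(hit)) {
      if (!emitted_span[hit[1]]) {
        out_tok <- c(out_tok, entities$text[hit[1]])
        out_ent <- c(out_ent, TRUE)
        emitted_span[hit[1]] <- TRUE
      }
      next
    }
    w <- tolower(toks$token[k])
    w <- sub("['’]s$", "", w)          # possessive
    w <- gsub("’", "'", w, fixed = TRUE)
    if (!nzchar(w)) next
    if (grepl("^[0-9][0-9,.]*$", w)) next   # cardinal numbers
    if (!grepl("[a-z]", w)) next            # punctuation/symbol residue
    if (w %in% stopwords$remove) next
    out_tok <- c(out_tok, w)
    out_ent <- c(out_ent, FALSE)
  }
  data.frame(token = out_tok, is_entity = out_ent, stringsAsFactors = FALSE)
}

# --- rule-based morphology -------------------------------------------------
# Each helper returns candidate base forms, most specific first. The lexicon
# is re-queried after every candidate, so the first hit wins.

singular_candidates <- function(w) {
  out <- character(0)
  if (grepl("ies$", w) && nchar(w) > 4) out <- c(out, sub("ies$", "y", w))
  if (grepl("ves$", w)) out <- c(out, sub("ves$", "f", w), sub("ves$", "fe", w))
  if (grepl("(ch|sh|ss|x|z|o)es$", w)) out <- c(out, sub("es$", "", w))
  if (grepl("es$", w)) out <- c(out, sub("es$", "", w), sub("s$", "", w))
  if (grepl("s$", w) && !grepl("ss$", w)) out <- c(out, sub("s$", "", w))
  unique(out)
}

present_tense_candidates <- function(w) {
  out <- character(0)
  if (grepl("ied$", w)) out <- c(out, sub("ied$", "y", w))
  if (grepl("ed$", w)) {
    out <- c(out, sub("d$", "", w),          # lounged -> lounge
             sub("ed$", "", w))              # walked -> walk
    if (grepl("([b-df-hj-np-tv-z])\\1ed$", w)) {
      out <- c(out, sub("([b-df-hj-np-tv-z])\\1ed$", "\\1", w))  # stopped -> stop
    }
  }
  if (grepl("ing$", w) && nchar(w) > 4) {
    out <- c(out, sub("ing$", "", w), sub("ing$", "e", w))
    if (grepl("([b-df-hj-np-tv-z])\\1ing$", w)) {
      out <- c(out, sub("([b-df-hj-np-tv-z])\\1ing$", "\\1", w))
    }
  }
  unique(out)
}

base_adjective_candidates <- function(w) {
  out <- character(0)
  if (grepl("iest$", w)) out <- c(out, sub("iest$", "y", w))
  if (grepl("est$", w)) out <- c(out, sub("est$", "", w), sub("st$", "", w))
  if (grepl("ier$", w)) out <- c(out, sub("ier$", "y", w))
  if (grepl("er$", w)) out <- c(out, sub("er$", "", w), sub("r$", "", w))
  if (grepl("([b-df-hj-np-tv-z])\\1(est|er)$", w)) {
    out <- c(out, sub("([b-df-hj-np-tv-z])\\1(est|er)$", "\\1", w))  # biggest -> big
  }
  unique(out)
}

resolve_plain <- function(w, lexicon) {
  r <- lexicon$ratings[w]
  if (!is.na(r)) return(list(rating = unname(r), source = "direct",
                             resolved_form = w))
  for (cand in singular_candidates(w)) {
    r <- lexicon$ratings[cand]
    if (!is.na(r)) return(list(rating = unname(r), source = "singularized",
                               resolved_form = cand))
  }
  for (cand in present_tense_candidates(w)) {
    r <- lexicon$ratings[cand]
    if (!is.na(r)) return(list(rating = unname(r), source = "present_tense",
                               resolved_form = cand))
  }
  for (cand in base_adjective_candidates(w)) {
    r <- lexicon$ratings[cand]
    if (!is.na(r)) return(list(rating = unname(r), source = "base_adjective",
                               resolved_form = cand))
  }
  NULL
}

#' Resolve a non-entity token to a concreteness rating
#'
#' Iterative fallback: direct lookup, then a singular form, then a
#' present-tense form, then a base adjective — re-querying the lexicon after
#' each step and stopping at the first hit. If all steps fail and the token
#' is hyphenated, both halves are resolved by the same steps and their
#' ratings averaged.
#'
#' @param token Case-folded candidate token (not an entity).
#' @param lexicon A `concreteness_lexicon`.
#' @return A list with `surface`, `resolved_form`, `source` (one of
#'   `direct`, `singularized`, `present_tense`, `base_adjective`,
#'   `hyphen_average`), and `rating`; or `NULL` if unresolved.
#' @export
#' @examples
#' lex <- as_lexicon(c(elephant = 4.9, lounge = 3.5))
#' resolve_token("elephants", lex)$source
resolve_token <- function(token, lexicon) {
  stopifnot(inherits(lexicon, "concreteness_lexicon"))
  w <- tolower(token)
  hit <- resolve_plain(w, lexicon)
  if (!is.null(hit)) {
    return(c(list(surface = token), hit))
  }
  if (grepl("-", w, fixed = TRUE)) {
    halves <- strsplit(w, "-", fixed = TRUE)[[1]]
    halves <- halves[nzchar(halves)]
    if (length(halves) >= 2) {
      parts <- lapply(halves, resolve_plain, lexicon = lexicon)
      if (!any(vapply(parts, is.null, logical(1)))) {
        return(list(surface = token,
                    rating = mean(vapply(parts, `[[`, numeric(1), "rating")),
                    source = "hyphen_average",
                    resolved_form = paste(halves, collapse = "+")))
      }
    }
  }
  NULL
}

#' Score a single headline
#'
#' Entities (people, places, organizations) receive the maximal rating of 5;
#' remaining candidates are resolved through [resolve_token()]. The headline
#' score is the arithmetic mean of all component ratings. A headline
#' containing any unresolved token with three or more letters (alphabetic
#' characters; hyphens and digits do not count) is excluded with reason
#' `unmatched_long_word`; unresolved tokens shorter than that are silently
#' dropped. A headline with no scoreable candidates at all is excluded with
#' reason `no_scoreable_tokens`.
#'
#' @param headline Non-empty character scalar.
#' @param lexicon A `concreteness_lexicon`.
#' @param stopwords From [stopword_config()].
#' @param gazetteer,backend Passed to [detect_entities()].
#' @return An object of class `headline_score`: list with `headline`,
#'   `components` (data frame: `surface`, `resolved_form`, `source`,
#'   `rating`), `value` (mean rating, `NA` if excluded), `excluded`, and
#'   `exclusion_reason` (`"unmatched_long_word"`, `"no_scoreable_tokens"`,
#'   or `"none"`).
#' @export
#' @examples
#' lex <- as_lexicon(c(visit = 3.92))
#' score_headline("Kamala Harris Visits Poland", lex)$value  # (5+3.92+5)/3
score_headline <- function(headline, lexicon, stopwords = stopword_config(),
                           gazetteer = default_gazetteer(), backend = NULL) {
  if (!is.character(headline) || length(headline) != 1L ||
      is.na(headline) || !nzchar(trimws(headline))) {
    stop("headline must be a non-empty string")
  }
  veto <- function(w) !is.null(resolve_plain(w, lexicon))
  ents <- detect_entities(headline, gazetteer = gazetteer, backend = backend,
                          surname_veto = veto)
  cands <- tokenize_and_filter(headline, ents, stopwords)
  comp <- data.frame(surface = character(0), resolved_form = character(0),
                     source = character(0), rating = numeric(0),
                     stringsAsFactors = FALSE)
  excluded <- FALSE
  reason <- "none"
  for (k in seq_len(nrow(cands))) {
    if (cands$is_entity[k]) {
      comp <- rbind(comp, data.frame(surface = cands$token[k],
                                     resolved_form = cands$token[k],
                                     source = "entity", rating = 5,
                                     stringsAsFactors = FALSE))
      next
    }
    res <- resolve_token(cands$token[k], lexicon)
    if (is.null(res)) {
      n_letters <- nchar(gsub("[^a-z]", "", cands$token[k]))
      if (n_letters >= 3) {
        excluded <- TRUE
        reason <- "unmatched_long_word"
      }
      next
    }
    comp <- rbind(comp, data.frame(surface = res$surface,
                                   resolved_form = res$resolved_form,
                                   source = res$source, rating = res$rating,
                                   stringsAsFactors = FALSE))
  }
  if (!excluded && nrow(comp) == 0L) {
    excluded <- TRUE
    reason <- "no_scoreable_tokens"
  }
  structure(list(headline = headline, components = comp,
                 value = if (excluded) NA_real_ else mean(comp$rating),
                 excluded = excluded, exclusion_reason = reason),
            class = "headline_score")
}

#' @export
print.headline_score <- function(x, ...) {
  cat("<headline_score> ", dQuote(x$headline), "\n", sep = "")
  if (x$excluded) {
    cat("  excluded (", x$exclusion_reason, ")\n", sep = "")
  } else {
    cat("  value = ", format(x$value, digits = 4), " over ",
        nrow(x$components), " component(s)\n", sep = "")
  }
  invisible(x)
}

#' Score a corpus of headlines
#'
#' Applies [score_headline()] to every row and reports exclusions.
#'
#' @param headlines Data frame containing a headline column, or a character
#'   vector.
#' @param lexicon A `concreteness_lexicon`.
#' @param headline_col Name of the headline column.
#' @param stopwords,gazetteer,... Passed to [score_headline()].
#' @return The input data frame with added columns `score`, `excluded`,
#'   `exclusion_reason`, `n_components`, and an attribute
#'   `"exclusion_summary"` (data frame of counts and fractions by reason).
#' @export
score_corpus <- function(headlines, lexicon, headline_col = "headline",
                         stopwords = stopword_config(),
                         gazetteer = default_gazetteer(), ...) {
  if (is.character(headlines)) {
    headlines <- data.frame(headline = headlines, stringsAsFactors = FALSE)
    headline_col <- "headline"
  }
  if (!headline_col %in% names(headlines)) {
    stop("missing headline column '", headline_col, "'")
  }
  scores <- lapply(headlines[[headline_col]], function(h) {
    score_headline(h, lexicon, stopwords = stopwords, gazetteer = gazetteer,
                   ...)
  })
  headlines$score <- vapply(scores, `[[`, numeric(1), "value")
  headlines$excluded <- vapply(scores, `[[`, logical(1), "excluded")
  headlines$exclusion_reason <- vapply(scores, `[[`, character(1),
                                       "exclusion_reason")
  headlines$n_components <- vapply(scores, function(s) nrow(s$components),
                                   integer(1))
  reasons <- c("unmatched_long_word", "no_scoreable_tokens")
  summ <- data.frame(
    reason = c(reasons, "total_excluded"),
    n = c(vapply(reasons, function(r) sum(headlines$exclusion_reason == r),
                 integer(1)),
          sum(headlines$excluded)),
    stringsAsFactors = FALSE)
  summ$fraction <- summ$n / nrow(headlines)
  attr(headlines, "exclusion_summary") <- summ
  headlines
}
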