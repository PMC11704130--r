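#' Default gazetteer for the rule-based entity tagger
#'
#' The entity layer tags person, place, and organization mentions so they can
#' be assigned maximal concreteness. A statistical named-entity recognizer is
#' not available in this environment, so the default backend is a
#' deterministic gazetteer matcher over capitalized token runs. It is a
#' documented stand-in with the same contract (non-overlapping character
#' spans labeled person/place/organization); callers needing a statistical
#' tagger can pass their own backend function to [detect_entities()].
#'
#' @return A list with character-vector elements `person_first_names`,
#'   `places`, `orgs` (all lowercase), of class `concreteness_gazetteer`.
#' @export
default_gazetteer <- function() {
  rd <- function(f) {
    path <- system.file("extdata", f, package = "concreteness", mustWork = TRUE)
    readLines(path, warn = FALSE)
  }
  structure(list(person_first_names = rd("gazetteer_person_first_names.txt"),
                 places = rd("gazetteer_places.txt"),
                 orgs = rd("gazetteer_orgs.txt")),
            class = "concreteness_gazetteer")
}

# Tokens with character offsets. Hyphens and apostrophes stay inside a token
# so "super-spectacular" and "world's" are single candidates.
tokenize_raw <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+(?:['’-][A-Za-z0-9]+)*", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = as.integer(m), end = as.integer(m + len - 1L),
             stringsAsFactors = FALSE)
}

is_capitalized <- function(token) grepl("^[A-Z]", token)

#' Detect person, place, and organization entities in a headline
#'
#' Runs the entity backend on the original-cased text (capitalization carries
#' signal) and returns non-overlapping character spans. Each multi-token
#' mention is a single span. Dates, quantities, and other non-name
#' capitalized words are not entities.
#'
#' Because headlines are typically title-cased, capitalization alone carries
#' little signal; the default backend therefore works token-wise inside
#' capitalized runs: a known organization or place name becomes a
#' single-token span, and a known given name starts a person span that
#' absorbs the one following capitalized token as a surname unless that
#' token is itself a gazetteer name or is vetoed by `surname_veto` (the
#' scorer vetoes tokens that resolve as ordinary lexicon words, so
#' "Visits" in "Kamala Harris Visits Poland" is not swallowed as a
#' surname). Unknown capitalized tokens are left untagged.
#'
#' @param headline Non-empty character scalar.
#' @param gazetteer A gazetteer from [default_gazetteer()], or `NULL` to
#'   signal an unavailable backend (an explicit error, never a silent
#'   zero-entity fallback).
#' @param backend Optional custom backend: a `function(headline)` returning a
#'   data frame with columns `start`, `end`, `text`, `type`. Overrides the
#'   gazetteer matcher.
#' @param surname_veto Optional `function(token_lowercase)` returning `TRUE`
#'   if the token must not be absorbed as a surname.
#' @return Data frame with columns `start`, `end` (1-based character
#'   offsets), `text`, and `type` (`"person"`, `"place"`, `"organization"`).
#' @export
#' @examples
#' detect_entities("Kamala Harris Visits Poland")
detect_entities <- function(headline, gazetteer = default_gazetteer(),
                            backend = NULL, surname_veto = NULL) {
  if (!is.character(headline) || length(headline) != 1L || !nzchar(headline)) {
    stop("headline must be a non-empty string")
  }
  if (!is.null(backend)) {
    stopifnot(is.function(backend))
    return(backend(headline))
  }
  if (is.null(gazetteer)) {
    stop("entity-recognition backend unavailable: no gazetteer supplied")
  }
  toks <- tokenize_raw(headline)
  empty <- data.frame(start = integer(0), end = integer(0),
                      text = character(0), type = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(toks) == 0L) return(empty)
  cap <- is_capitalized(toks$token)
  folded <- tolower(gsub("['’].*$", "", toks$token))
  in_gaz <- folded %in% gazetteer$orgs | folded %in% gazetteer$places |
    folded %in% gazetteer$person_first_names
  spans <- empty
  add_span <- function(i, j, type) {
    rbind(spans, data.frame(
      start = toks$start[i], end = toks$end[j],
      text = substring(headline, toks$start[i], toks$end[j]),
      type = type, stringsAsFactors = FALSE))
  }
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    if (!cap[i]) { i <- i + 1L; next }
    if (folded[i] %in% gazetteer$orgs) {
      spans <- add_span(i, i, "organization"); i <- i + 1L; next
    }
    if (folded[i] %in% gazetteer$places) {
      spans <- add_span(i, i, "place"); i <- i + 1L; next
    }
    if (folded[i] %in% gazetteer$person_first_names) {
      j <- i
      if (i < n && cap[i + 1L] && !in_gaz[i + 1L] &&
          (is.null(surname_veto) || !isTRUE(surname_veto(folded[i + 1L])))) {
        j <- i + 1L
      }
      spans <- add_span(i, j, "person")
      i <- j + 1L
      next
    }
    i <- i + 1L
  }
  spans
}
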