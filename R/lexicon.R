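#' Load a word-concreteness lexicon
#'
#' Reads a delimited (comma or tab) ratings file mapping word forms (single
#' tokens or bigrams) to mean concreteness ratings on the 0--5 scale and
#' returns a validated lookup table. Headwords are case-folded to lowercase.
#' Rows whose rating cannot be parsed as a number, or whose rating falls
#' outside \[0, 5\], are dropped; the number of dropped rows is reported with
#' a warning and recorded on the returned object.
#'
#' Default column names follow the published word-norm file dialect
#' (`"Word"` and `"Conc.M"`).
#'
#' @param path Path to the delimited ratings file.
#' @param word_col Name of the column holding the word form.
#' @param rating_col Name of the column holding the mean rating.
#' @param sep Field separator; `NULL` (default) sniffs comma vs tab from the
#'   header line.
#' @return An object of class `concreteness_lexicon`: a list with elements
#'   `ratings` (named numeric vector, names are lowercase word forms),
#'   `n_rejected` (rows dropped during validation), and `source` (the path).
#' @seealso [lexicon_lookup()], [write_lexicon()]
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("Word,Conc.M", "tomato,5", "idea,1.62", "sound,3.7"), tmp)
#' lex <- load_lexicon(tmp)
#' lexicon_lookup(lex, c("Tomato", "idea", "wondtacular"))
load_lexicon <- function(path, word_col = "Word", rating_col = "Conc.M",
                         sep = NULL) {
  if (!file.exists(path)) {
    stop("lexicon file does not exist: ", path)
  }
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!all(c(word_col, rating_col) %in% names(tab))) {
    stop("lexicon file lacks configured columns '", word_col, "'/'",
         rating_col, "'; found: ", paste(names(tab), collapse = ", "))
  }
  words <- tolower(trimws(tab[[word_col]]))
  ratings <- suppressWarnings(as.numeric(tab[[rating_col]]))
  ok <- !is.na(ratings) & is.finite(ratings) &
    ratings >= 0 & ratings <= 5 & nzchar(words)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    warning(n_rejected, " lexicon row(s) rejected (unparseable or out of [0,5])")
  }
  if (!any(ok)) {
    stop("zero parseable rows in lexicon file: ", path)
  }
  ratings <- ratings[ok]
  names(ratings) <- words[ok]
  # last occurrence wins on duplicates, like a sequential load into a map
  ratings <- ratings[!duplicated(names(ratings), fromLast = TRUE)]
  new_lexicon(ratings, n_rejected = n_rejected, source = path)
}

new_lexicon <- function(ratings, n_rejected = 0L, source = NA_character_) {
  stopifnot(is.numeric(ratings), !is.null(names(ratings)))
  structure(list(ratings = ratings, n_rejected = as.integer(n_rejected),
                 source = source),
            class = "concreteness_lexicon")
}

#' Build a lexicon from a named numeric vector
#'
#' Convenience constructor used in tests and by the synthetic-data generator.
#' Applies the same validation as [load_lexicon()].
#'
#' @param ratings Named numeric vector; names are word forms, values ratings
#'   on \[0, 5\].
#' @return A `concreteness_lexicon`.
#' @export
as_lexicon <- function(ratings) {
  if (is.null(names(ratings)) || any(!nzchar(names(ratings)))) {
    stop("ratings must be a fully named numeric vector")
  }
  if (any(!is.finite(ratings) | ratings < 0 | ratings > 5)) {
    stop("all ratings must be finite and within [0, 5]")
  }
  names(ratings) <- tolower(names(ratings))
  new_lexicon(ratings[!duplicated(names(ratings), fromLast = TRUE)])
}

#' Look up concreteness ratings
#'
#' Case-folded exact-match lookup. Absent words yield `NA` — never a default
#' rating. No fuzzy matching happens at this layer; morphological fallback is
#' the scorer's job ([resolve_token()]).
#'
#' @param lexicon A `concreteness_lexicon`.
#' @param words Character vector of words to look up.
#' @return Numeric vector of ratings, `NA` where absent, named by the
#'   case-folded query.
#' @export
lexicon_lookup <- function(lexicon, words) {
  stopifnot(inherits(lexicon, "concreteness_lexicon"))
  if (length(words) == 0L) return(numeric(0))
  if (any(!nzchar(words))) stop("empty word in lookup")
  key <- tolower(words)
  out <- unname(lexicon$ratings[key])
  names(out) <- key
  out
}

#' Write a lexicon back to the delimited dialect
#'
#' Inverse of [load_lexicon()]: writing then reloading yields identical
#' lookups for every key.
#'
#' @inheritParams lexicon_lookup
#' @param path Output file path.
#' @param word_col,rating_col Column names to write.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path, word_col = "Word",
                          rating_col = "Conc.M", sep = ",") {
  stopifnot(inherits(lexicon, "concreteness_lexicon"))
  df <- data.frame(w = names(lexicon$ratings), r = unname(lexicon$ratings),
                   stringsAsFactors = FALSE)
  names(df) <- c(word_col, rating_col)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.concreteness_lexicon <- function(x, ...) {
  cat("<concreteness_lexicon> ", length(x$ratings), " entries, range [",
      format(min(x$ratings)), ", ", format(max(x$ratings)), "]\n", sep = "")
  invisible(x)
}
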