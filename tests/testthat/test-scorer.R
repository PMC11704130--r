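lex <- fixture_lexicon()

test_that("detect_entities finds person and place spans, one span per entity", {
  sp <- detect_entities("Kamala Harris Visits Poland")
  expect_equal(nrow(sp), 2)
  expect_equal(sp$text, c("Kamala Harris", "Poland"))
  expect_equal(sp$type, c("person", "place"))
  # spans are non-overlapping and carry correct offsets
  expect_true(all(sp$start <= sp$end))
  expect_true(all(diff(as.vector(t(sp[, c("start", "end")]))) > 0))
  expect_equal(substring("Kamala Harris Visits Poland", sp$start, sp$end),
               sp$text)
})

test_that("detect_entities degenerate inputs and backend contract", {
  expect_equal(nrow(detect_entities("ideas about freedom")), 0)
  expect_equal(nrow(detect_entities("12345 678")), 0)
  expect_error(detect_entities("Poland", gazetteer = NULL), "unavailable")
  expect_error(detect_entities(""), "non-empty")
  # custom backend overrides the gazetteer
  fake <- function(h) data.frame(start = 1L, end = 3L, text = "Foo",
                                 type = "organization",
                                 stringsAsFactors = FALSE)
  expect_equal(detect_entities("Foo bar", backend = fake)$type,
               "organization")
})

test_that("tokenize_and_filter removes stopwords with exceptions, drops
           punctuation and cardinals, and emits entities as single tokens", {
  ents <- detect_entities("This is what they got, Poland! 7 reasons...")
  cand <- tokenize_and_filter("This is what they got, Poland! 7 reasons...",
                              ents)
  expect_true(all(c("this", "they") %in% cand$token))   # retained exceptions
  expect_false(any(c("is", "what") %in% cand$token))    # removed stopwords
  expect_false("7" %in% cand$token)                     # cardinal
  expect_true("Poland" %in% cand$token[cand$is_entity])
  # all-stopword headline with no exceptions
  e2 <- detect_entities("is was of the")
  expect_equal(nrow(tokenize_and_filter("is was of the", e2)), 0)
})

test_that("resolve_token walks the fallback chain in order", {
  expect_equal(resolve_token("tomato", lex)$source, "direct")
  r <- resolve_token("elephants", lex)
  expect_equal(r$source, "singularized")
  expect_equal(r$rating, unname(lexicon_lookup(lex, "elephant")))
  r <- resolve_token("lounged", lex)
  expect_equal(r$source, "present_tense")
  expect_equal(r$rating, 3.5)
  r <- resolve_token("greatest", lex)
  expect_equal(r$source, "base_adjective")
  expect_equal(r$rating, unname(lexicon_lookup(lex, "great")))
  # hyphen average of the two fixture ratings (2.0 and 3.0)
  r <- resolve_token("super-spectacular", lex)
  expect_equal(r$source, "hyphen_average")
  expect_equal(r$rating, 2.5)
  expect_null(resolve_token("wondtacular", lex))
  # direct lookup wins before any morphology
  lex2 <- as_lexicon(c(glasses = 1.1, glass = 4.9))
  expect_equal(resolve_token("glasses", lex2)$rating, 1.1)
})

test_that("score_headline matches the worked example and exclusion rules", {
  s <- score_headline("Kamala Harris Visits Poland", lex)
  expect_false(s$excluded)
  expect_equal(s$components$rating, c(5, 3.92, 5))
  expect_equal(s$value, (5 + 3.92 + 5) / 3, tolerance = 1e-12)
  expect_equal(round(s$value, 2), 4.64)

  # headline of two entities only
  s2 <- score_headline("Poland Poland", lex)
  expect_equal(s2$value, 5)

  # unresolved long word excludes the headline
  s3 <- score_headline("Obamacare tomato", lex)
  expect_true(s3$excluded)
  expect_equal(s3$exclusion_reason, "unmatched_long_word")
  expect_true(is.na(s3$value))

  # unresolved tokens with <= 2 letters are silently dropped
  s4 <- score_headline("tomato xk", lex)
  expect_false(s4$excluded)
  expect_equal(s4$value, 5)

  # nothing scoreable at all
  s5 <- score_headline("of the and", lex)
  expect_true(s5$excluded)
  expect_equal(s5$exclusion_reason, "no_scoreable_tokens")

  expect_error(score_headline("", lex), "non-empty")
})

test_that("scorer invariants: boundedness, monotonicity, order invariance", {
  # entity dominance: adding an entity moves the score toward 5
  base <- score_headline("idea love truth", lex)$value
  with_ent <- score_headline("idea love truth Poland", lex)$value
  expect_gt(with_ent, base)
  expect_lte(with_ent, 5)
  # substitution monotonicity: tomato (5) > sound (3.7)
  lo <- score_headline("sound idea", lex)$value
  hi <- score_headline("tomato idea", lex)$value
  expect_gt(hi, lo)
  # order invariance
  expect_equal(score_headline("dog cat house", lex)$value,
               score_headline("house dog cat", lex)$value)
  # boundedness across a batch of random fixture headlines
  set.seed(7)
  words <- setdiff(names(lex$ratings), default_retained_stopwords())
  for (k in 1:20) {
    h <- paste(sample(words, 4), collapse = " ")
    v <- score_headline(h, lex)$value
    expect_gte(v, min(lex$ratings))
    expect_lte(v, 5)
  }
})

test_that("oracle equivalence: score equals hand-computed component mean", {
  set.seed(11)
  words <- c("tomato", "idea", "sound", "dog", "freedom", "water")
  for (k in 1:10) {
    pick <- sample(words, 3)
    h <- paste(pick, collapse = " ")
    expected <- mean(unname(lexicon_lookup(lex, pick)))
    expect_equal(score_headline(h, lex)$value, expected, tolerance = 1e-9)
  }
})

test_that("score_corpus reports exclusions and is deterministic", {
  hs <- c(rep("tomato dog", 4), rep("Obamacare tomato", 2),
          rep("cat water", 4))
  out <- score_corpus(hs, lex)
  expect_equal(nrow(out), 10)
  summ <- attr(out, "exclusion_summary")
  expect_equal(summ$fraction[summ$reason == "total_excluded"], 0.2)
  expect_equal(summ$n[summ$reason == "unmatched_long_word"], 2L)
  # identical headlines get identical scores
  expect_equal(out$score[1], out$score[4])
  expect_error(score_corpus(data.frame(x = 1), lex), "missing headline")
})
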