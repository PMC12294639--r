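test_that("tokenizer splits on punctuation and indexes the original text", {
  toks <- normalize_and_tokenize("h/o IVDU.")
  expect_equal(toks$token, c("h", "o", "ivdu"))
  expect_equal(toks$start[3], 4L)
  expect_equal(toks$end[3], 8L)
  expect_equal(substr("h/o IVDU.", toks$start[3] + 1, toks$end[3]), "IVDU")

  expect_equal(nrow(normalize_and_tokenize("")), 0L)
  expect_equal(nrow(normalize_and_tokenize("... -- !!")), 0L)
  expect_equal(normalize_and_tokenize("opioid-use disorder")$token,
               c("opioid", "use", "disorder"))
  expect_equal(normalize_and_tokenize("IVDU", case_sensitive = TRUE)$token,
               "IVDU")
})

test_that("edit distance handles the canonical single-typo cases", {
  expect_equal(dl_distance("heroin", "herion"), 1L)  # adjacent transposition
  expect_equal(dl_distance("x", "x"), 0L)
  expect_equal(dl_distance("fentanyl", ""), 8L)
  expect_equal(dl_distance("", "abc"), 3L)
  expect_equal(dl_distance("ab", "ba"), 1L)          # 2 under plain Levenshtein
  expect_equal(dl_distance("fentanyl", "fentanil"), 1L)
  expect_equal(dl_distance(c("aa", "abc"), c("ab", "abc")), c(1L, 0L))
})

test_that("edit distance agrees with the DP oracle on random pairs", {
  withr::with_seed(11, {
    a <- random_strings(500)
    b <- random_strings(500)
  })
  expect_equal(dl_distance(a, b),
               vapply(seq_along(a), function(i) osa_oracle(a[i], b[i]),
                      integer(1)))
  # symmetry on the same sample
  expect_equal(dl_distance(a, b), dl_distance(b, a))
})

test_that("phrase and fuzzy matching behave per the lexicon rules", {
  lex <- keyword_lexicon()
  cfg <- matcher_config()

  spans <- match_note("pt admits to drug abuse daily", lex, cfg)
  expect_equal(nrow(spans), 1L)
  expect_equal(spans$matched_text, "drug abuse")
  expect_equal(spans$distance, 0L)

  # short acronyms never match inside longer words or fuzzily
  expect_equal(nrow(match_note("sudden cardiac arrest", lex, cfg)), 0L)
  expect_equal(nrow(match_note("oud?", lex, cfg)), 1L)  # standalone token ok
  expect_equal(nrow(match_note("loud noises reported", lex, cfg)), 0L)

  # fuzzy single-token match at distance 1
  sp <- match_note("uses herion daily", lex, cfg)
  heroin <- sp[sp$lexicon_entry == "heroin", ]
  expect_equal(nrow(heroin), 1L)
  expect_equal(heroin$distance, 1L)
  expect_equal(heroin$matched_text, "herion")

  # phrase with flexible separators and case folding
  sp <- match_note("Injection-drug  USE suspected", lex, cfg)
  expect_true("injection drug use" %in% sp$lexicon_entry)

  # phrase words below the fuzzy length threshold stay exact
  expect_false(
    "drug abuse" %in% match_note("drag abuse", lex, cfg)$lexicon_entry
  )
  expect_true(
    "drug abuse" %in% match_note("drug abuze", lex, cfg)$lexicon_entry
  )
})

test_that("overlapping candidates for one entry keep lowest-distance leftmost", {
  lex <- keyword_lexicon(c("soda soda"))
  sp <- match_note("soda soda soda", lex, matcher_config())
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$start, 0L)
  expect_equal(sp$matched_text, "soda soda")

  # non-overlapping repeats are all reported
  sp2 <- match_note("heroin then heroin again", keyword_lexicon(),
                    matcher_config())
  expect_equal(sum(sp2$lexicon_entry == "heroin"), 2L)
})

test_that("raising max_distance never removes matches, lowering never adds", {
  lex <- keyword_lexicon()
  texts <- c("uses herion daily", "fentanil found on tox",
             "methadone clinic visit", "no issues today",
             "injection drog use noted", "subboxone at home")
  key <- function(sp) paste(sp$start, sp$end, sp$lexicon_entry)
  for (txt in texts) {
    s0 <- key(match_note(txt, lex, matcher_config(max_distance = 0)))
    s1 <- key(match_note(txt, lex, matcher_config(max_distance = 1)))
    s2 <- key(match_note(txt, lex, matcher_config(max_distance = 2)))
    expect_true(all(s0 %in% s1), info = txt)
    expect_true(all(s1 %in% s2), info = txt)
  }
})

test_that("reported spans re-extract and re-match from the original text", {
  lex <- keyword_lexicon()
  cfg <- matcher_config()
  texts <- c("h/o IVDU, uses herion daily.",
             "Substance use disorder documented; pt denies drug abuse!",
             "PWID with opioid overdose, fentanil on board")
  for (txt in texts) {
    sp <- match_note(txt, lex, cfg)
    expect_gt(nrow(sp), 0L)
    for (i in seq_len(nrow(sp))) {
      extracted <- substr(txt, sp$start[i] + 1L, sp$end[i])
      expect_identical(extracted, sp$matched_text[i])
      again <- match_note(extracted, lex, cfg)
      hit <- again[again$lexicon_entry == sp$lexicon_entry[i], ]
      expect_equal(nrow(hit), 1L)
      expect_equal(hit$distance, sp$distance[i])
    }
  }
})

test_that("encounter-level detection scans all notes and handles none", {
  lex <- keyword_lexicon()
  empty_enc <- list(encounter_id = "e1", notes = list())
  res <- detect_encounter(empty_enc, lex)
  expect_false(res$flag_n)
  expect_equal(nrow(res$evidence), 0L)

  enc <- list(encounter_id = "e2", notes = list(
    list(note_type = "nursing", text = "vitals stable"),
    list(note_type = "discharge_summary", text = "known PWID, follow up")
  ))
  res <- detect_encounter(enc, lex)
  expect_true(res$flag_n)
  expect_equal(res$evidence$note_index, 2L)
  expect_equal(res$evidence$lexicon_entry, "PWID")
})

test_that("lexicon construction enforces uniqueness and fuzzy eligibility", {
  lex <- keyword_lexicon()
  expect_equal(nrow(lex), 26L)
  short <- c("IVDU", "IVDA", "SUD", "OUD", "PWID")
  expect_false(any(lex$fuzzy_eligible[lex$surface %in% short]))
  expect_true(all(lex$fuzzy_eligible[lex$surface %in%
                                       c("FENTANYL", "heroin", "drug abuse")]))
  expect_true(lex$is_phrase[lex$surface == "injection drug use"])
  expect_error(keyword_lexicon(c("heroin", "Heroin")), "duplicate")

  shipped <- read_lexicon(default_lexicon_path())
  expect_equal(shipped$surface, lex$surface)
})

test_that("matcher config rejects out-of-range tolerances", {
  expect_error(matcher_config(max_distance = 3))
  expect_error(matcher_config(min_token_len_for_fuzzy = 1))
  expect_silent(matcher_config(max_distance = 0))
})
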