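#' Normalize and tokenize note text
#'
#' Tokens are maximal runs of letters and digits; all punctuation and
#' whitespace act as boundaries, so `"IVDU."` yields the token `"ivdu"`.
#' Offsets are 0-based, half-open character positions into the ORIGINAL text,
#' so `substr(text, start + 1, end)` recovers the raw token.
#'
#' @param text A single character string (may be empty).
#' @param case_sensitive Keep case? Default `FALSE` (tokens are case-folded).
#' @return Tibble with columns `token`, `start`, `end`; zero rows for empty
#'   or token-free text.
#' @examples
#' normalize_and_tokenize("h/o IVDU.")
#' @export
normalize_and_tokenize <- function(text, case_sensitive = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble::new_tibble(
    list(token = character(), start = integer(), end = integer()), nrow = 0L)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tok <- substring(text, start + 1L, start + len)
  if (!case_sensitive) tok <- tolower(tok)
  tibble::new_tibble(
    list(token = tok, start = start, end = start + as.integer(len)),
    nrow = length(tok))
}

#' Optimal string alignment Damerau-Levenshtein distance
#'
#' Edit distance with unit-cost substitutions, insertions, deletions, and
#' adjacent transpositions (each substring edited at most once). This is the
#' tolerance metric for fuzzy keyword matching: a single typo such as the
#' transposition `"heroin"` -> `"herion"` has distance 1.
#'
#' @param a,b Character vectors, recycled to common length.
#' @return Integer vector of distances.
#' @examples
#' dl_distance("heroin", "herion")   # 1
#' dl_distance("fentanyl", "")       # 8
#' @export
dl_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) >= 1L, length(b) >= 1L)
  .dl_distance_cpp(enc2utf8(a), enc2utf8(b))
}

# Empty MatchSpan tibble (one row per located keyword occurrence).
# Built once; tibble construction is too slow for the per-note hot path.
EMPTY_SPANS <- tibble::tibble(
  note_index = integer(), start = integer(), end = integer(),
  matched_text = character(), lexicon_entry = character(),
  distance = integer()
)
empty_spans <- function() EMPTY_SPANS

span_tibble <- function(note_index, start, end, matched_text, lexicon_entry,
                        distance) {
  tibble::new_tibble(
    list(note_index = note_index, start = start, end = end,
         matched_text = matched_text, lexicon_entry = lexicon_entry,
         distance = distance),
    nrow = length(start)
  )
}

#' Match lexicon keywords in one note text
#'
#' Single-token entries match any note token exactly (after case-folding
#' unless configured otherwise) or, when the entry is fuzzy-eligible and the
#' token meets the minimum fuzzy length, within `max_distance` edits. Phrase
#' entries match consecutive token runs in which each word matches its
#' counterpart under the same rule; any run of whitespace or punctuation
#' separates phrase words. All entries' matches are reported in text order;
#' for a single entry, overlapping candidates are resolved by lowest
#' distance, then leftmost start, then longest span.
#'
#' @param text Note text (single string).
#' @param lexicon A `pwud_lexicon`, from [keyword_lexicon()].
#' @param config A `pwud_matcher_config`, from [matcher_config()].
#' @param note_index Integer stored in the output's `note_index` column.
#' @return Tibble of match spans: `note_index`, `start`, `end` (0-based,
#'   half-open character offsets), `matched_text`, `lexicon_entry`,
#'   `distance` (maximum per-word edit distance within the span).
#' @examples
#' match_note("pt admits to drug abuse daily", keyword_lexicon(),
#'            matcher_config())
#' @export
match_note <- function(text, lexicon, config = matcher_config(),
                       note_index = 1L) {
  stopifnot(inherits(lexicon, "pwud_lexicon"),
            inherits(config, "pwud_matcher_config"))
  toks <- normalize_and_tokenize(text, case_sensitive = config$case_sensitive)
  if (nrow(toks) == 0L) return(empty_spans())

  fold <- if (config$case_sensitive) identity else tolower
  entry_words <- strsplit(fold(lexicon$surface), "[^[:alnum:]]+")
  entry_words <- lapply(entry_words, function(w) w[nzchar(w)])

  # one cross-distance matrix: unique note tokens x unique lexicon words
  utok <- unique(toks$token)
  uword <- unique(unlist(entry_words))
  dmat <- .dl_cross_cpp(enc2utf8(utok), enc2utf8(uword))
  rownames(dmat) <- utok
  colnames(dmat) <- uword
  tok_idx <- match(toks$token, utok)
  tokd <- dmat[tok_idx, , drop = FALSE]
  # closest note token per lexicon word: lets entries with no nearby word
  # be skipped before the positional sweep
  wmin <- apply(dmat, 2, min)

  out <- vector("list", nrow(lexicon))
  nt <- nrow(toks)
  for (e in seq_len(nrow(lexicon))) {
    words <- entry_words[[e]]
    k <- length(words)
    if (k == 0L || k > nt) next
    fuzzy_word <- lexicon$fuzzy_eligible[e] & config$max_distance > 0L &
      nchar(words) >= config$min_token_len_for_fuzzy
    wcol <- match(words, uword)
    tol <- integer(k)
    tol[fuzzy_word] <- config$max_distance
    if (any(wmin[wcol] > tol)) next

    # per-word distances at every token position; Inf where disallowed
    allowed <- matrix(FALSE, nrow = nt, ncol = k)
    dist_w <- matrix(0L, nrow = nt, ncol = k)
    for (j in seq_len(k)) {
      dj <- tokd[, wcol[j]]
      allowed[, j] <- dj <= tol[j]
      dist_w[, j] <- dj
    }
    starts <- which(
      Reduce(`&`, lapply(seq_len(k), function(j) {
        idx <- seq_len(nt - k + 1L) + (j - 1L)
        allowed[idx, j]
      }))
    )
    if (length(starts) == 0L) next
    span_dist <- vapply(starts, function(i) {
      max(dist_w[cbind(i + seq_len(k) - 1L, seq_len(k))])
    }, integer(1))
    cand <- span_tibble(
      note_index = rep(as.integer(note_index), length(starts)),
      start = toks$start[starts],
      end = toks$end[starts + k - 1L],
      matched_text = substring(text, toks$start[starts] + 1L,
                               toks$end[starts + k - 1L]),
      lexicon_entry = rep(lexicon$surface[e], length(starts)),
      distance = span_dist
    )
    # overlap resolution within this entry: lowest distance, leftmost, longest
    ord <- order(cand$distance, cand$start, -(cand$end - cand$start))
    keep <- logical(nrow(cand))
    taken_end <- integer(0)
    taken_start <- integer(0)
    for (i in ord) {
      if (!any(cand$start[i] < taken_end & cand$end[i] > taken_start)) {
        keep[i] <- TRUE
        taken_start <- c(taken_start, cand$start[i])
        taken_end <- c(taken_end, cand$end[i])
      }
    }
    out[[e]] <- cand[keep, ]
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_spans())
  res[order(res$start, res$end, res$lexicon_entry), ]
}

#' Detect keyword evidence across all notes of an encounter
#'
#' Runs [match_note()] over every note of the encounter regardless of note
#' type (nursing, physician, discharge summary, emergency); the N flag is
#' true as soon as any note yields at least one span.
#'
#' @param encounter An encounter list with a `notes` element (each note a
#'   list with `note_type` and `text`).
#' @inheritParams match_note
#' @return List with `flag_n` (logical) and `evidence` (tibble of spans from
#'   all notes, with `note_index` identifying the note).
#' @export
detect_encounter <- function(encounter, lexicon, config = matcher_config()) {
  notes <- encounter$notes
  if (is.null(notes) || length(notes) == 0L) {
    return(list(flag_n = FALSE, evidence = empty_spans()))
  }
  spans <- dplyr::bind_rows(lapply(seq_along(notes), function(i) {
    match_note(notes[[i]]$text, lexicon, config, note_index = i)
  }))
  if (nrow(spans) == 0L) spans <- empty_spans()
  list(flag_n = nrow(spans) > 0L, evidence = spans)
}
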