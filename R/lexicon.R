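#' Default PWUD keyword list
#'
#' The keyword surfaces used to flag an encounter through the note-text
#' domain (N): drug names, route-of-use abbreviations, and substance-use
#' phrases commonly written in clinical notes. Mixed case is preserved as
#' curated; matching is case-insensitive by default.
#'
#' @return Character vector of keyword surfaces.
#' @export
pwud_keywords <- function() {
  c(
    "IVDU", "FENTANYL", "Methadone", "heroin", "suboxone", "IVDA",
    "drug abuse", "SUD", "Substance use disorder", "opioid use disorder",
    "opioid abuse", "OUD", "opioid overdose", "illicit drugs", "addicted",
    "addict", "drug addict", "injection drug use", "intravenous drug use",
    "uses fentanyl", "Uses heroin", "PWID", "abuses drugs", "injects heroin",
    "injects drugs", "injects fentanyl"
  )
}

#' Build a keyword lexicon
#'
#' Compiles keyword surfaces into the lexicon used by [match_note()]. Each
#' entry records whether it is a multi-word phrase and whether it is eligible
#' for fuzzy (edit-distance) matching. Short tokens and acronyms (longest
#' token of 4 characters or fewer, e.g. `IVDU`, `SUD`, `OUD`, `PWID`) are
#' matched exactly only: allowing edits on 3-4 letter acronyms floods the
#' matcher with false positives.
#'
#' @param entries Character vector of keyword surfaces. Defaults to
#'   [pwud_keywords()].
#' @param version Lexicon version label recorded in provenance output.
#' @param min_token_len_for_fuzzy Minimum length of an entry's longest token
#'   for the entry to be fuzzy-eligible.
#' @return A tibble of class `pwud_lexicon` with columns `surface`,
#'   `is_phrase`, `fuzzy_eligible`, and a `version` attribute.
#' @examples
#' lex <- keyword_lexicon()
#' lex[lex$surface == "SUD", ]$fuzzy_eligible  # FALSE: exact match only
#' @export
keyword_lexicon <- function(entries = pwud_keywords(), version = "textbox1-v1",
                            min_token_len_for_fuzzy = 5L) {
  entries <- trimws(entries)
  entries <- entries[nzchar(entries)]
  if (anyDuplicated(tolower(entries))) {
    dup <- entries[duplicated(tolower(entries))]
    stop("duplicate lexicon entries after case-folding: ",
         paste(unique(dup), collapse = ", "))
  }
  words <- strsplit(entries, "[^[:alnum:]]+")
  longest <- vapply(words, function(w) max(nchar(w[nzchar(w)])), integer(1))
  lex <- tibble::tibble(
    surface = entries,
    is_phrase = lengths(lapply(words, function(w) w[nzchar(w)])) > 1L,
    fuzzy_eligible = longest >= min_token_len_for_fuzzy
  )
  attr(lex, "version") <- version
  class(lex) <- c("pwud_lexicon", class(lex))
  lex
}

#' Read a keyword lexicon from a plain-text file
#'
#' One entry per line; blank lines and `#` comments are ignored. The package
#' ships its default list in `inst/extdata/pwud_keywords.txt`.
#'
#' @param path Path to the lexicon file.
#' @param version Version label; defaults to the file name.
#' @inheritParams keyword_lexicon
#' @return A `pwud_lexicon` tibble, as from [keyword_lexicon()].
#' @export
read_lexicon <- function(path, version = basename(path),
                         min_token_len_for_fuzzy = 5L) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keyword_lexicon(lines[nzchar(lines)], version = version,
                  min_token_len_for_fuzzy = min_token_len_for_fuzzy)
}

#' Path to the default lexicon file shipped with the package
#' @return File path of the installed default keyword list.
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "pwud_keywords.txt", package = "pwudcohort",
              mustWork = TRUE)
}

#' Matcher configuration
#'
#' Tolerances for the note-text keyword matcher.
#'
#' @param max_distance Maximum optimal-string-alignment Damerau-Levenshtein
#'   distance allowed for fuzzy-eligible tokens (0-2; default 1, covering the
#'   dominant single-typo class such as transpositions).
#' @param min_token_len_for_fuzzy Minimum token length for fuzzy matching;
#'   shorter tokens must match exactly (default 5).
#' @param case_sensitive Match case-sensitively? Default `FALSE`.
#' @return A list of class `pwud_matcher_config`.
#' @export
matcher_config <- function(max_distance = 1L, min_token_len_for_fuzzy = 5L,
                           case_sensitive = FALSE) {
  max_distance <- as.integer(max_distance)
  min_token_len_for_fuzzy <- as.integer(min_token_len_for_fuzzy)
  stopifnot(length(max_distance) == 1L, !is.na(max_distance),
            max_distance >= 0L, max_distance <= 2L,
            length(min_token_len_for_fuzzy) == 1L,
            min_token_len_for_fuzzy >= 2L,
            is.logical(case_sensitive), length(case_sensitive) == 1L)
  structure(
    list(max_distance = max_distance,
         min_token_len_for_fuzzy = min_token_len_for_fuzzy,
         case_sensitive = case_sensitive),
    class = "pwud_matcher_config"
  )
}
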