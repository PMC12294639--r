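COHORT_SCHEMA_VERSION <- "1.0"

#' Write a cohort as JSON Lines
#'
#' One encounter per line with embedded notes; every line carries a
#' `schema_version` field so readers can refuse incompatible files.
#'
#' @param cohort List of encounters.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  lines <- vapply(cohort, function(enc) {
    enc$schema_version <- COHORT_SCHEMA_VERSION
    jsonlite::toJSON(enc, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from JSON Lines
#'
#' @param path JSONL file written by [write_cohort_jsonl()].
#' @return List of encounters.
#' @export
read_cohort_jsonl <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    enc <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        stop("malformed cohort record at line ", i, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    if (!identical(enc$schema_version, COHORT_SCHEMA_VERSION)) {
      stop("cohort schema version mismatch at line ", i, ": expected ",
           COHORT_SCHEMA_VERSION, ", found ",
           enc$schema_version %||% "<absent>", call. = FALSE)
    }
    enc$schema_version <- NULL
    enc$svi_quartile <- if (is.null(enc$svi_quartile)) NA_integer_ else
      as.integer(enc$svi_quartile)
    enc$age <- as.numeric(enc$age)
    enc$length_of_stay <- as.numeric(enc$length_of_stay)
    enc$truth_pwud <- if (is.null(enc$truth_pwud)) NULL else
      as.logical(enc$truth_pwud)
    enc
  })
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(what, " missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Write / read the per-encounter domain-flag table
#'
#' Headered CSV with columns `encounter_id`, `b`, `d`, `m`, `n`, `included`.
#'
#' @param flags Flags tibble from [classify_cohort()].
#' @param path CSV path.
#' @return `path` (write) or the flags tibble (read).
#' @export
write_flags_csv <- function(flags, path) {
  check_columns(flags, c("encounter_id", "b", "d", "m", "n"), "flags table")
  out <- flags[intersect(c("encounter_id", "b", "d", "m", "n", "included"),
                         names(flags))]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flags_csv
#' @export
read_flags_csv <- function(path) {
  if (!file.exists(path)) stop("flags file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("encounter_id", "b", "d", "m", "n"), "flags table")
  for (col in c("b", "d", "m", "n")) df[[col]] <- as.logical(df[[col]])
  tibble::as_tibble(df)
}

#' Write the match-span evidence table
#' @param spans Span tibble (attribute `"spans"` of [classify_cohort()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spans_csv <- function(spans, path) {
  write.csv(spans, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML mirroring the [pipeline_config()] arguments; `generation.seed`
#' is mandatory. Distribution fields are named maps. Unspecified fields take
#' the package defaults.
#'
#' @param path YAML file path.
#' @return A `pwud_pipeline_config`, as from [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  gen_args <- y$generation %||% list()
  if (is.null(gen_args$seed)) stop("config must set generation.seed")
  for (f in c("race_dist", "sex_dist", "svi_dist", "language_dist",
              "hcv_antibody_rate", "icd_assignment_rate", "moud_rate",
              "keyword_mention_rate")) {
    if (!is.null(gen_args[[f]])) gen_args[[f]] <- unlist(gen_args[[f]])
  }
  if (!is.null(gen_args$tox_positive_rates)) {
    gen_args$tox_positive_rates <- lapply(gen_args$tox_positive_rates, unlist)
  }
  for (f in c("age_mean_sd", "los_mean_sd")) {
    if (!is.null(gen_args[[f]])) gen_args[[f]] <- as.numeric(unlist(gen_args[[f]]))
  }
  matcher_args <- y$matcher %||% list()
  pipeline_config(
    generation = do.call(generation_config, gen_args),
    matcher = do.call(matcher_config, matcher_args),
    code_table_path = y$code_table_path,
    lexicon_path = y$lexicon_path,
    review = y$review %||% list(),
    output_dir = y$output_dir
  )
}
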