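#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end run: synthetic cohort
#' generation, note matching, code table and lexicon sources, and the
#' chart-review sampling plan (default fractions mirror the study: about 10%
#' of the D-only cell and 35% of the N-only cell).
#'
#' @param generation A `pwud_generation_config`.
#' @param matcher A `pwud_matcher_config`.
#' @param code_table_path Optional CSV path (default: packaged table).
#' @param lexicon_path Optional lexicon file path (default: packaged list).
#' @param review List with any of `d_only_fraction`, `n_only_fraction`,
#'   `d_only_n`, `n_only_n`, `review_seed` (absolute sizes win over
#'   fractions).
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @return List of class `pwud_pipeline_config`.
#' @export
pipeline_config <- function(generation, matcher = matcher_config(),
                            code_table_path = NULL, lexicon_path = NULL,
                            review = list(), output_dir = NULL) {
  stopifnot(inherits(generation, "pwud_generation_config"),
            inherits(matcher, "pwud_matcher_config"))
  review_defaults <- list(d_only_fraction = 0.10, n_only_fraction = 0.35,
                          d_only_n = NULL, n_only_n = NULL,
                          review_seed = generation$seed + 1L)
  review <- utils::modifyList(review_defaults, review)
  structure(
    list(generation = generation, matcher = matcher,
         code_table_path = code_table_path, lexicon_path = lexicon_path,
         review = review, output_dir = output_dir),
    class = "pwud_pipeline_config"
  )
}

review_ppv <- function(sample, truth_by_id) {
  confirmed <- sum(truth_by_id[sample$sampled_ids])
  ppv(confirmed, length(sample$sampled_ids))
}

#' Run the full phenotyping pipeline
#'
#' Executes generate -> detect/classify -> partition -> review-sample ->
#' evaluate. Chart review is modeled as an oracle reading the synthetic
#' ground-truth label; supplying `review_labels` (a data frame with
#' `encounter_id` and logical `confirmed`) replaces the oracle with external
#' annotations. The run is fully deterministic under the configured seeds.
#'
#' @param config A `pwud_pipeline_config`.
#' @param review_labels Optional external chart-review labels.
#' @return List of class `pwud_run_summary`: the cohort, flags, partition,
#'   comparison group sizes, review samples with their PPVs, the disparity
#'   report, and provenance (lexicon/code-table versions and seeds).
#' @export
run_pipeline <- function(config, review_labels = NULL) {
  stopifnot(inherits(config, "pwud_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  lexicon <- stage("lexicon", {
    if (is.null(config$lexicon_path)) keyword_lexicon()
    else read_lexicon(config$lexicon_path)
  })
  code_table <- stage("code_table", {
    if (is.null(config$code_table_path)) default_code_table()
    else read_code_table(config$code_table_path)
  })
  cohort <- stage("generate", generate_cohort(config$generation, lexicon))
  flags <- stage("classify",
                 classify_cohort(cohort, code_table, lexicon, config$matcher))
  partition <- stage("partition", build_partition(flags))
  groups <- comparison_groups(partition)
  enc_tab <- encounter_table(cohort)

  truth_by_id <- setNames(enc_tab$truth_pwud, enc_tab$encounter_id)
  if (!is.null(review_labels)) {
    check_columns(review_labels, c("encounter_id", "confirmed"),
                  "review labels")
    truth_by_id[review_labels$encounter_id] <- review_labels$confirmed
  }

  rv <- config$review
  samples <- list()
  for (cell in c("D", "N")) {
    if (is.null(partition$cells[[cell]])) next
    n_abs <- if (cell == "D") rv$d_only_n else rv$n_only_n
    frac <- if (cell == "D") rv$d_only_fraction else rv$n_only_fraction
    smp <- stage("sample", select_review_sample(
      partition, cell, fraction = frac, n = n_abs,
      seed = rv$review_seed + match(cell, c("D", "N"))
    ))
    samples[[cell]] <- list(sample = smp,
                            ppv = stage("evaluate", review_ppv(smp, truth_by_id)))
  }
  report <- stage("evaluate", disparity_report(partition, enc_tab))

  summary <- structure(
    list(cohort = cohort, flags = flags, partition = partition,
         n_included = partition$total_included,
         n_bdmn = length(groups$bdmn_ids),
         n_n_only = length(groups$n_only_ids),
         cell_sizes = cell_sizes(partition),
         review = samples, disparity = report,
         provenance = list(
           lexicon_version = attr(lexicon, "version"),
           schema_version = COHORT_SCHEMA_VERSION,
           generation_seed = config$generation$seed,
           review_seed = rv$review_seed
         )),
    class = "pwud_run_summary"
  )
  if (!is.null(config$output_dir)) write_run_artifacts(summary, config)
  summary
}

write_run_artifacts <- function(summary, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  write_cohort_jsonl(summary$cohort, out("cohort.jsonl"))
  enc_csv <- encounter_table(summary$cohort)
  enc_csv$schema_version <- COHORT_SCHEMA_VERSION
  write.csv(enc_csv, out("encounters.csv"), row.names = FALSE)
  write_flags_csv(summary$flags, out("flags.csv"))
  write_spans_csv(attr(summary$flags, "spans"), out("spans.csv"))
  json <- list(
    n_included = summary$n_included,
    n_bdmn = summary$n_bdmn,
    n_n_only = summary$n_n_only,
    cell_sizes = as.list(summary$cell_sizes),
    ppv = lapply(summary$review, function(x) {
      list(subcohort = x$sample$subcohort,
           reviewed = x$ppv$reviewed, confirmed = x$ppv$confirmed,
           ppv_pct = x$ppv$ppv_pct_rounded,
           ci95 = as.list(x$ppv$ci95))
    }),
    unadjusted_or = lapply(summary$disparity$unadjusted, function(o) {
      list(or = o$or_point, ci95 = as.list(o$ci95), method = o$method)
    }),
    adjusted_or = as.list(summary$disparity$adjusted$or_estimates),
    provenance = summary$provenance
  )
  jsonlite::write_json(json, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$output_dir)
}

#' @export
print.pwud_run_summary <- function(x, ...) {
  cat("PWUD phenotyping run:", x$n_included, "included encounters |",
      "BDMN", x$n_bdmn, "| N-only", x$n_n_only, "\n")
  for (cell in names(x$review)) {
    p <- x$review[[cell]]$ppv
    cat(sprintf("  %s-only chart review: %d/%d confirmed, PPV %d%%\n",
                cell, p$confirmed, p$reviewed, p$ppv_pct_rounded))
  }
  print(x$disparity)
  invisible(x)
}
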