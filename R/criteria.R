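# Closed vocabularies for structured fields.
TOX_ANALYTES <- c("opiate", "fentanyl", "oxycodone", "methadone", "cocaine",
                  "amphetamine", "suboxone")
LAB_ANALYTES <- c(TOX_ANALYTES, "hcv_antibody", "hcv_viral_load")
MOUD_DRUGS <- c("buprenorphine_sublingual", "methadone_oral")
MED_CONTEXTS <- c("outpatient_reconciliation", "inpatient_administration",
                  "discharge_prescription")
NOTE_TYPES <- c("nursing", "physician", "discharge_summary", "emergency")

#' Default diagnosis code table
#'
#' ICD-10 code-family prefixes (opioid-, cocaine- and stimulant-related
#' disorders F11/F14/F15; poisoning families T400-T406 and T436; chronic
#' hepatitis C B18.2) and ICD-9 hepatitis C codes. ICD-10 matching is by
#' dot-stripped prefix so child codes such as `F11.20` or `T40.2X1A` match
#' their family; ICD-9 matching is dot-stripped exact equality.
#'
#' @return Tibble of class `pwud_code_table` with columns `system`
#'   (`"ICD10"`/`"ICD9"`), `code`, `description`.
#' @export
default_code_table <- function() {
  read_code_table(system.file("extdata", "pwud_icd_codes.csv",
                              package = "pwudcohort", mustWork = TRUE))
}

#' Read a diagnosis code table from CSV
#'
#' Expects columns `system`, `code`, `description`; `#` comment lines are
#' skipped. ICD-10 rows are treated as code-family prefixes, ICD-9 rows as
#' exact codes.
#'
#' @param path CSV file path.
#' @return A `pwud_code_table` tibble.
#' @export
read_code_table <- function(path) {
  if (!file.exists(path)) stop("code table file not found: ", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("system", "code", "description")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("code table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(df$system %in% c("ICD9", "ICD10"))) {
    stop("code table 'system' must be ICD9 or ICD10")
  }
  tab <- tibble::as_tibble(df[required])
  class(tab) <- c("pwud_code_table", class(tab))
  tab
}

strip_code <- function(code) toupper(gsub("[^[:alnum:]]", "", code))

#' Evaluate criterion B: drug-use biomarkers
#'
#' True if any urine toxicology analyte (opiate, fentanyl, oxycodone,
#' methadone, cocaine, amphetamine, suboxone) is positive, or if a positive
#' hepatitis C antibody is conjoined with a positive or quantifiable HCV
#' viral load. A positive HCV antibody alone is insufficient (resolved prior
#' infection does not indicate current drug use).
#'
#' @param labs List of lab results, each a list with `analyte` and `result`
#'   (`"positive"`, `"negative"`, or `"quantified"`). Unknown analytes are
#'   ignored with a warning.
#' @return List with `flag` (logical) and `evidence` (character vector of
#'   provenance strings, one per triggering record).
#' @export
eval_biomarkers <- function(labs) {
  evidence <- character()
  hcv_ab <- FALSE
  hcv_vl <- FALSE
  for (lab in labs) {
    if (is.null(lab$analyte) || !(lab$analyte %in% LAB_ANALYTES)) {
      warning("ignoring lab with unknown analyte: ",
              if (is.null(lab$analyte)) "<missing>" else lab$analyte,
              call. = FALSE)
      next
    }
    if (lab$analyte %in% TOX_ANALYTES && identical(lab$result, "positive")) {
      evidence <- c(evidence,
                    paste0("urine toxicology positive: ", lab$analyte))
    }
    if (lab$analyte == "hcv_antibody" && identical(lab$result, "positive")) {
      hcv_ab <- TRUE
    }
    if (lab$analyte == "hcv_viral_load" &&
        lab$result %in% c("positive", "quantified")) {
      hcv_vl <- TRUE
    }
  }
  if (hcv_ab && hcv_vl) {
    evidence <- c(evidence,
                  "HCV antibody positive with positive/quantifiable viral load")
  }
  list(flag = length(evidence) > 0L, evidence = evidence)
}

#' Evaluate criterion D: diagnosis codes
#'
#' ICD-10 codes match when the dot-stripped code equals a table prefix or
#' extends it (`"F11.20"` matches family `F11`; `"T40.2X1A"` matches `T402`).
#' ICD-9 codes match by dot-stripped exact equality. Inactivated or
#' historical diagnoses count the same as active ones.
#'
#' @param dx_codes List of diagnosis codes, each a list with `system`
#'   (`"ICD9"`/`"ICD10"`), `code`, and optional `active`.
#' @param table A `pwud_code_table`; defaults to [default_code_table()].
#' @return List with `flag` and `evidence`, as in [eval_biomarkers()].
#' @export
eval_diagnoses <- function(dx_codes, table = default_code_table()) {
  stopifnot(inherits(table, "pwud_code_table"))
  prefixes10 <- strip_code(table$code[table$system == "ICD10"])
  exact9 <- strip_code(table$code[table$system == "ICD9"])
  evidence <- character()
  for (dx in dx_codes) {
    if (is.null(dx$code) || !nzchar(dx$code)) next
    stripped <- strip_code(dx$code)
    hit <- if (identical(dx$system, "ICD9")) {
      stripped %in% exact9
    } else {
      any(startsWith(stripped, prefixes10))
    }
    if (hit) {
      status <- if (isFALSE(dx$active)) " (inactive)" else ""
      evidence <- c(evidence,
                    paste0(dx$system, " code ", dx$code, status))
    }
  }
  list(flag = length(evidence) > 0L, evidence = evidence)
}

#' Evaluate criterion M: medications for opioid use disorder
#'
#' True if sublingual buprenorphine or oral methadone appears in outpatient
#' medication reconciliation, was given during hospitalization, or was
#' prescribed at discharge. Oral methadone for OUD is dispensed through
#' licensed programs rather than discharge prescriptions, so a
#' methadone/discharge-prescription record still counts but is flagged as
#' anomalous in its evidence string.
#'
#' @param meds List of medication records, each a list with `drug`
#'   (`"buprenorphine_sublingual"`, `"methadone_oral"`, `"other"`) and
#'   `context` (`"outpatient_reconciliation"`, `"inpatient_administration"`,
#'   `"discharge_prescription"`).
#' @return List with `flag` and `evidence`, as in [eval_biomarkers()].
#' @export
eval_medications <- function(meds) {
  evidence <- character()
  for (med in meds) {
    if (is.null(med$drug) || !(med$drug %in% MOUD_DRUGS)) next
    if (is.null(med$context) || !(med$context %in% MED_CONTEXTS)) next
    note <- if (med$drug == "methadone_oral" &&
                med$context == "discharge_prescription") {
      " [anomalous: methadone is not ordinarily prescribed at discharge]"
    } else ""
    evidence <- c(evidence, paste0(med$drug, " via ", med$context, note))
  }
  list(flag = length(evidence) > 0L, evidence = evidence)
}

#' Classify one encounter into the B/D/M/N domain flags
#'
#' Composes the three structured evaluators with note-text keyword detection.
#' An encounter enters the PWUD cohort when any flag is true.
#'
#' @param encounter Encounter list (see [generate_cohort()] for the schema).
#' @param table A `pwud_code_table`.
#' @param lexicon A `pwud_lexicon`.
#' @param config A `pwud_matcher_config`.
#' @return List of class `pwud_domain_flags`: logicals `b`, `d`, `m`, `n`,
#'   `included` (their disjunction), per-domain `evidence` (list of character
#'   vectors), and `spans` (tibble of note match spans).
#' @export
classify_encounter <- function(encounter, table = default_code_table(),
                               lexicon = keyword_lexicon(),
                               config = matcher_config()) {
  b <- eval_biomarkers(encounter$labs %||% list())
  d <- eval_diagnoses(encounter$dx_codes %||% list(), table)
  m <- eval_medications(encounter$medications %||% list())
  n <- detect_encounter(encounter, lexicon, config)
  n_evidence <- if (n$flag_n) {
    sprintf("note %d: '%s' matched lexicon entry '%s' (distance %d)",
            n$evidence$note_index, n$evidence$matched_text,
            n$evidence$lexicon_entry, n$evidence$distance)
  } else character()
  structure(
    list(b = b$flag, d = d$flag, m = m$flag, n = n$flag_n,
         included = b$flag || d$flag || m$flag || n$flag_n,
         evidence = list(b = b$evidence, d = d$evidence, m = m$evidence,
                         n = n_evidence),
         spans = n$evidence),
    class = "pwud_domain_flags"
  )
}

#' Classify a whole cohort
#'
#' @param cohort List of encounters.
#' @inheritParams classify_encounter
#' @return Tibble with one row per encounter: `encounter_id`, `b`, `d`, `m`,
#'   `n`, `included`, and an `evidence` list-column; the combined span table
#'   is attached as attribute `"spans"` (with an `encounter_id` column).
#' @export
classify_cohort <- function(cohort, table = default_code_table(),
                            lexicon = keyword_lexicon(),
                            config = matcher_config()) {
  res <- lapply(cohort, classify_encounter, table = table,
                lexicon = lexicon, config = config)
  spans <- lapply(seq_along(res), function(i) {
    sp <- res[[i]]$spans
    if (nrow(sp) > 0L) sp$encounter_id <- cohort[[i]]$encounter_id
    sp
  })
  flags <- tibble::new_tibble(
    list(
      encounter_id = vapply(cohort, `[[`, character(1), "encounter_id"),
      b = vapply(res, `[[`, logical(1), "b"),
      d = vapply(res, `[[`, logical(1), "d"),
      m = vapply(res, `[[`, logical(1), "m"),
      n = vapply(res, `[[`, logical(1), "n"),
      included = vapply(res, `[[`, logical(1), "included"),
      evidence = lapply(res, `[[`, "evidence")
    ),
    nrow = length(res)
  )
  attr(flags, "spans") <- dplyr::bind_rows(spans)
  flags
}

`%||%` <- function(x, y) if (is.null(x)) y else x
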