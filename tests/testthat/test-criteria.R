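lab <- function(analyte, result, ...) list(analyte = analyte, result = result, ...)
dx <- function(code, system = "ICD10", active = TRUE) {
  list(system = system, code = code, active = active)
}
med <- function(drug, context) list(drug = drug, context = context)

test_that("biomarker rule: any positive toxicology, or HCV antibody AND viral load", {
  expect_true(eval_biomarkers(list(lab("cocaine", "positive")))$flag)
  expect_true(eval_biomarkers(list(lab("fentanyl", "positive"),
                                   lab("opiate", "negative")))$flag)
  expect_false(eval_biomarkers(list(lab("cocaine", "negative")))$flag)
  expect_false(eval_biomarkers(list())$flag)

  # antibody alone is insufficient; the conjunction is required
  expect_false(eval_biomarkers(list(lab("hcv_antibody", "positive")))$flag)
  expect_false(eval_biomarkers(list(lab("hcv_viral_load", "positive")))$flag)
  expect_true(eval_biomarkers(list(lab("hcv_antibody", "positive"),
                                   lab("hcv_viral_load", "quantified",
                                       value = 5e4)))$flag)
  expect_false(eval_biomarkers(list(lab("hcv_antibody", "positive"),
                                    lab("hcv_viral_load", "negative")))$flag)

  expect_warning(res <- eval_biomarkers(list(lab("ethanol", "positive"))),
                 "unknown analyte")
  expect_false(res$flag)
})

test_that("diagnosis rule: ICD-10 prefix families, ICD-9 exact, inactive counts", {
  expect_true(eval_diagnoses(list(dx("F14.10")))$flag)   # cocaine family
  expect_false(eval_diagnoses(list(dx("F13.10")))$flag)  # sedatives: absent
  expect_true(eval_diagnoses(list(dx("T40.2X1A")))$flag) # T402 poisoning
  expect_true(eval_diagnoses(list(dx("F11")))$flag)      # bare parent code
  expect_true(eval_diagnoses(list(dx("B18.2")))$flag)
  expect_false(eval_diagnoses(list(dx("B18.1")))$flag)
  expect_false(eval_diagnoses(list(dx("T41.0X1A")))$flag)
  expect_false(eval_diagnoses(list())$flag)

  expect_true(eval_diagnoses(list(dx("070.41", system = "ICD9")))$flag)
  expect_true(eval_diagnoses(list(dx("07054", system = "ICD9")))$flag)
  expect_false(eval_diagnoses(list(dx("070.42", system = "ICD9")))$flag)
  # ICD-9 hepatitis codes are exact, not prefixes
  expect_false(eval_diagnoses(list(dx("070.411", system = "ICD9")))$flag)

  inact <- eval_diagnoses(list(dx("F11.20", active = FALSE)))
  expect_true(inact$flag)
  expect_match(inact$evidence, "inactive")
})

test_that("medication rule: MOUD drug in a qualifying context", {
  expect_true(eval_medications(list(
    med("buprenorphine_sublingual", "discharge_prescription")))$flag)
  expect_true(eval_medications(list(
    med("methadone_oral", "outpatient_reconciliation")))$flag)
  expect_false(eval_medications(list(med("other", "inpatient_administration")))$flag)
  expect_false(eval_medications(list())$flag)

  anom <- eval_medications(list(med("methadone_oral", "discharge_prescription")))
  expect_true(anom$flag)
  expect_match(anom$evidence, "anomalous")
})

test_that("classify_encounter composes the four domains with evidence", {
  enc_b <- list(encounter_id = "x", labs = list(lab("fentanyl", "positive")),
                dx_codes = list(), medications = list(), notes = list())
  fl <- classify_encounter(enc_b)
  expect_true(fl$b)
  expect_false(fl$d || fl$m || fl$n)
  expect_true(fl$included)

  enc_all <- list(
    encounter_id = "y",
    labs = list(lab("methadone", "positive")),
    dx_codes = list(dx("F11.20")),
    medications = list(med("methadone_oral", "outpatient_reconciliation")),
    notes = list(list(note_type = "physician", text = "h/o OUD, stable"))
  )
  fl <- classify_encounter(enc_all)
  expect_true(all(c(fl$b, fl$d, fl$m, fl$n)))

  empty <- list(encounter_id = "z", labs = list(), dx_codes = list(),
                medications = list(), notes = list())
  fl <- classify_encounter(empty)
  expect_false(fl$included)
})

test_that("every true flag carries at least one evidence string", {
  cfg <- generation_config(n_encounters = 120, seed = 41)
  cohort <- generate_cohort(cfg)
  flags <- classify_cohort(cohort)
  for (i in seq_len(nrow(flags))) {
    ev <- flags$evidence[[i]]
    for (dom in c("b", "d", "m", "n")) {
      if (flags[[dom]][i]) {
        expect_gte(length(ev[[dom]]), 1L)
        expect_true(all(nzchar(ev[[dom]])))
      }
    }
  }
})

test_that("adding records never turns a true flag false (monotonicity)", {
  cfg <- generation_config(n_encounters = 40, seed = 17)
  cohort <- generate_cohort(cfg)
  for (enc in cohort[1:20]) {
    before <- classify_encounter(enc)
    enc$labs <- c(enc$labs, list(lab("cocaine", "positive")))
    enc$dx_codes <- c(enc$dx_codes, list(dx("F11.20")))
    enc$medications <- c(enc$medications,
                         list(med("buprenorphine_sublingual",
                                  "inpatient_administration")))
    enc$notes <- c(enc$notes, list(list(note_type = "nursing",
                                        text = "reports heroin use")))
    after <- classify_encounter(enc)
    for (dom in c("b", "d", "m", "n")) {
      expect_true(!before[[dom]] || after[[dom]])
    }
  }
})

test_that("with zero false-signal rates, flags never fire off-truth", {
  cfg <- generation_config(
    n_encounters = 150, seed = 23,
    tox_positive_rates = list(
      pwud = c(fentanyl = 0.5, cocaine = 0.3),
      non_pwud = c(fentanyl = 0, cocaine = 0)
    ),
    hcv_antibody_rate = c(pwud = 0.3, non_pwud = 0),
    icd_assignment_rate = c(pwud = 0.6, non_pwud = 0),
    moud_rate = c(pwud = 0.4, non_pwud = 0),
    keyword_mention_rate = c(pwud = 0.8, non_pwud = 0)
  )
  cohort <- generate_cohort(cfg)
  flags <- classify_cohort(cohort)
  truth <- vapply(cohort, `[[`, logical(1), "truth_pwud")
  # every flagged encounter must be truly PWUD: non-PWUD carry no signals
  expect_true(all(truth[flags$included]))
})

test_that("code table reader validates structure", {
  tab <- default_code_table()
  expect_s3_class(tab, "pwud_code_table")
  expect_true(all(c("F11", "F14", "F15", "T402", "T436") %in%
                    gsub("[.]", "", tab$code[tab$system == "ICD10"])))
  expect_equal(sum(tab$system == "ICD9"), 6L)

  bad <- tempfile(fileext = ".csv")
  writeLines("system,code\nICD10,F11", bad)
  expect_error(read_code_table(bad), "description")
})
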