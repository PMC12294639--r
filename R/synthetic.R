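# Sentence banks for synthetic notes. Neutral and distractor sentences are
# constructed (and test-verified) to contain no token within the matcher's
# edit tolerance of any lexicon entry; distractors are confusable near-misses
# (e.g. "sudden" against the exact-only acronym SUD, prescribed amphetamine
# for attention deficit disorder as a false-signal lookalike).
NEUTRAL_SENTENCES <- c(
  "Patient resting comfortably, vital signs stable overnight.",
  "Plan to continue current antibiotics and reassess tomorrow morning.",
  "Chest radiograph shows no acute cardiopulmonary process.",
  "Diet advanced as tolerated, ambulating with physical therapy.",
  "Electrolytes repleted per protocol, monitoring renal function.",
  "Follow up scheduled with primary care within two weeks.",
  "Echocardiogram demonstrates preserved ejection fraction.",
  "Wound care instructions reviewed with the patient and family."
)

DISTRACTOR_SENTENCES <- c(
  "Sudden onset of shortness of breath overnight.",
  "Takes amphetamine salts prescribed for attention deficit disorder.",
  "Reports living next door to a busy clinic downtown.",
  "Medication addition planned if symptoms persist.",
  "Sudden worsening of lower extremity edema noted."
)

KEYWORD_TEMPLATES <- c(
  "Social history notable for %s.",
  "History of %s documented in prior records.",
  "Patient reports %s per admission interview.",
  "Chart review significant for %s."
)

DENIAL_TEMPLATES <- c(
  "Patient denies %s.",
  "No history of %s per family report."
)

#' Synthetic cohort generation configuration
#'
#' Defaults emulate the marginal structure of the study cohort: mean age 47.9
#' (SD 13.8) years, 62.4% male, 34.8% racially/ethnically minoritized, SVI
#' quartiles split 45.5%/54.5% between 1st-2nd and 3rd-4th with 0.4% missing,
#' and mean length of stay 38.7 (SD 26.3) days. Signal rates (toxicology,
#' ICD assignment, MOUD, keyword mentions) are conditional on the encounter's
#' ground-truth PWUD status and are loosely calibrated so that all sixteen
#' Venn cells are populated at the default cohort size; they are free
#' parameters, not fitted quantities.
#'
#' @param n_encounters Number of encounters to generate (>= 1).
#' @param prevalence_pwud Probability an encounter is truly of a PWUD.
#' @param race_dist,sex_dist,svi_dist,language_dist Named categorical
#'   distributions (must sum to 1).
#' @param svi_missing_rate Probability the SVI quartile is missing.
#' @param age_mean_sd,los_mean_sd Numeric length-2 vectors (mean, SD) for age
#'   in years and length of stay in days.
#' @param tox_positive_rates List with elements `pwud` and `non_pwud`, each a
#'   named per-analyte probability vector of a positive urine toxicology.
#' @param hcv_antibody_rate Named (`pwud`, `non_pwud`) probabilities of a
#'   positive HCV antibody.
#' @param hcv_viral_load_given_ab Probability of a positive/quantifiable
#'   viral load given a positive antibody.
#' @param icd_assignment_rate,moud_rate,keyword_mention_rate Named (`pwud`,
#'   `non_pwud`) probabilities of qualifying diagnosis codes, MOUD records,
#'   and keyword mentions in notes. The non-PWUD components are the
#'   false-signal rates.
#' @param misspelling_rate Probability a planted fuzzy-eligible keyword is
#'   perturbed by one edit.
#' @param distractor_rate Probability a non-PWUD note carries a confusable
#'   distractor sentence.
#' @param seed Integer seed (mandatory).
#' @return List of class `pwud_generation_config`.
#' @export
generation_config <- function(
    n_encounters = 4548L,
    prevalence_pwud = 0.5,
    race_dist = c(minoritized = 0.348, white_nonhispanic = 0.652),
    sex_dist = c(male = 0.624, female = 0.376),
    svi_dist = c(q1 = 0.2275, q2 = 0.2275, q3 = 0.2705, q4 = 0.2745),
    svi_missing_rate = 0.004,
    language_dist = c(english = 0.945, spanish = 0.027, other = 0.028),
    age_mean_sd = c(47.9, 13.8),
    los_mean_sd = c(38.7, 26.3),
    tox_positive_rates = list(
      pwud = c(opiate = 0.20, fentanyl = 0.45, oxycodone = 0.10,
               methadone = 0.25, cocaine = 0.30, amphetamine = 0.15,
               suboxone = 0.10),
      non_pwud = c(opiate = 0.02, fentanyl = 0.02, oxycodone = 0.02,
                   methadone = 0.02, cocaine = 0.02, amphetamine = 0.02,
                   suboxone = 0.02)
    ),
    hcv_antibody_rate = c(pwud = 0.30, non_pwud = 0.05),
    hcv_viral_load_given_ab = 0.6,
    icd_assignment_rate = c(pwud = 0.55, non_pwud = 0.10),
    moud_rate = c(pwud = 0.35, non_pwud = 0.02),
    keyword_mention_rate = c(pwud = 0.75, non_pwud = 0.06),
    misspelling_rate = 0.15,
    distractor_rate = 0.30,
    seed) {
  if (missing(seed)) stop("generation_config: seed is mandatory")
  cfg <- structure(
    list(n_encounters = as.integer(n_encounters),
         prevalence_pwud = prevalence_pwud, race_dist = race_dist,
         sex_dist = sex_dist, svi_dist = svi_dist,
         svi_missing_rate = svi_missing_rate, language_dist = language_dist,
         age_mean_sd = age_mean_sd, los_mean_sd = los_mean_sd,
         tox_positive_rates = tox_positive_rates,
         hcv_antibody_rate = hcv_antibody_rate,
         hcv_viral_load_given_ab = hcv_viral_load_given_ab,
         icd_assignment_rate = icd_assignment_rate, moud_rate = moud_rate,
         keyword_mention_rate = keyword_mention_rate,
         misspelling_rate = misspelling_rate,
         distractor_rate = distractor_rate,
         seed = as.integer(seed)),
    class = "pwud_generation_config"
  )
  validate_generation_config(cfg)
  cfg
}

validate_generation_config <- function(cfg) {
  if (is.na(cfg$n_encounters) || cfg$n_encounters < 1L) {
    stop("invalid configuration: n_encounters must be >= 1")
  }
  probs <- c(prevalence_pwud = cfg$prevalence_pwud,
             svi_missing_rate = cfg$svi_missing_rate,
             hcv_viral_load_given_ab = cfg$hcv_viral_load_given_ab,
             misspelling_rate = cfg$misspelling_rate,
             distractor_rate = cfg$distractor_rate,
             cfg$hcv_antibody_rate, cfg$icd_assignment_rate, cfg$moud_rate,
             cfg$keyword_mention_rate,
             unlist(cfg$tox_positive_rates))
  bad <- names(probs)[is.na(probs) | probs < 0 | probs > 1]
  if (length(bad) > 0L) {
    stop("invalid configuration: probabilities outside [0,1]: ",
         paste(bad, collapse = ", "))
  }
  for (field in c("race_dist", "sex_dist", "svi_dist", "language_dist")) {
    d <- cfg[[field]]
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9) {
      stop("invalid configuration: ", field, " must be a distribution summing to 1")
    }
  }
  for (field in c("hcv_antibody_rate", "icd_assignment_rate", "moud_rate",
                  "keyword_mention_rate")) {
    if (!all(c("pwud", "non_pwud") %in% names(cfg[[field]]))) {
      stop("invalid configuration: ", field, " needs 'pwud' and 'non_pwud'")
    }
  }
  if (!all(names(cfg$tox_positive_rates$pwud) %in% TOX_ANALYTES) ||
      !all(names(cfg$tox_positive_rates$non_pwud) %in% TOX_ANALYTES)) {
    stop("invalid configuration: tox_positive_rates has unknown analyte")
  }
  if (is.na(cfg$seed)) stop("invalid configuration: seed must be an integer")
  invisible(cfg)
}

#' Perturb a token by exactly one edit
#'
#' Applies one uniformly chosen edit — substitution, insertion, deletion, or
#' adjacent transposition — yielding a string at optimal-string-alignment
#' Damerau-Levenshtein distance exactly 1 from the input. This produces the
#' misspellings the fuzzy matcher must tolerate.
#'
#' @param token String of length >= 2.
#' @param seed Integer seed (deterministic output).
#' @return The perturbed string.
#' @examples
#' inject_misspelling("heroin", seed = 1)
#' @export
inject_misspelling <- function(token, seed) {
  withr::with_seed(seed, inject_misspelling_impl(token))
}

inject_misspelling_impl <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  nc <- nchar(token)
  if (nc < 2L) stop("token must have at least 2 characters")
  chars <- strsplit(token, "")[[1]]
  ops <- c("substitute", "insert", "delete")
  trans_pos <- which(tolower(chars[-nc]) != tolower(chars[-1]))
  if (length(trans_pos) > 0L) ops <- c(ops, "transpose")
  op <- sample(ops, 1L)
  if (op == "substitute") {
    pos <- sample.int(nc, 1L)
    pool <- setdiff(letters, tolower(chars[pos]))
    chars[pos] <- sample(pool, 1L)
  } else if (op == "insert") {
    pos <- sample.int(nc + 1L, 1L)  # insert before position pos
    chars <- append(chars, sample(letters, 1L), after = pos - 1L)
  } else if (op == "delete") {
    chars <- chars[-sample.int(nc, 1L)]
  } else {
    p <- if (length(trans_pos) == 1L) trans_pos else sample(trans_pos, 1L)
    chars[c(p, p + 1L)] <- chars[c(p + 1L, p)]
  }
  paste(chars, collapse = "")
}

# Perturb one fuzzy-tolerable word (nchar >= min_len) of a keyword surface;
# returns the surface unchanged if no word can be fuzzily matched back.
misspell_keyword <- function(surface, min_len = 5L) {
  parts <- strsplit(surface, " ", fixed = TRUE)[[1]]
  eligible <- which(nchar(parts) >= min_len)
  if (length(eligible) == 0L) return(surface)
  i <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  parts[i] <- inject_misspelling_impl(parts[i])
  paste(parts, collapse = " ")
}

render_note_impl <- function(note_type, keywords, misspelling_rate,
                             distractor_rate, lexicon, denial = FALSE) {
  sentences <- sample(NEUTRAL_SENTENCES, sample.int(3L, 1L) + 1L)
  for (kw in keywords) {
    entry <- lexicon[tolower(lexicon$surface) == tolower(kw), ]
    fuzzy_ok <- nrow(entry) == 1L && entry$fuzzy_eligible
    text_kw <- if (fuzzy_ok && runif(1) < misspelling_rate) {
      misspell_keyword(kw)
    } else {
      kw
    }
    template <- sample(if (denial) DENIAL_TEMPLATES else KEYWORD_TEMPLATES, 1L)
    sentences <- append(sentences, sprintf(template, text_kw),
                        after = sample.int(length(sentences), 1L))
  }
  if (runif(1) < distractor_rate) {
    sentences <- append(sentences, sample(DISTRACTOR_SENTENCES, 1L),
                        after = sample.int(length(sentences), 1L))
  }
  list(note_type = note_type, text = paste(sentences, collapse = " "))
}

#' Render one synthetic clinical note
#'
#' Builds note text from a neutral sentence bank, planting each requested
#' keyword as a standalone token (perturbed by one edit with probability
#' `misspelling_rate` when the keyword is fuzzy-eligible; exact-only
#' keywords are always planted verbatim) and inserting a confusable
#' distractor sentence with probability `distractor_rate`.
#'
#' @param note_type One of `"nursing"`, `"physician"`, `"discharge_summary"`,
#'   `"emergency"`.
#' @param keywords Character vector of lexicon surfaces to plant (may be
#'   empty).
#' @param misspelling_rate,distractor_rate Probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @param lexicon A `pwud_lexicon` (used to decide fuzzy eligibility).
#' @param denial Use denial phrasing ("Patient denies ...")? This emulates
#'   the false-positive mode of a presence-only matcher.
#' @return A note: list with `note_type` and `text`.
#' @export
render_note <- function(note_type, keywords = character(),
                        misspelling_rate = 0, distractor_rate = 0, seed,
                        lexicon = keyword_lexicon(), denial = FALSE) {
  stopifnot(note_type %in% NOTE_TYPES)
  withr::with_seed(seed, render_note_impl(note_type, keywords,
                                          misspelling_rate, distractor_rate,
                                          lexicon, denial))
}

sample_cat <- function(dist) sample(names(dist), 1L, prob = dist)

generate_encounter <- function(i, cfg, lexicon, dx_pool) {
  truth <- runif(1) < cfg$prevalence_pwud
  st <- if (truth) "pwud" else "non_pwud"
  svi <- if (runif(1) < cfg$svi_missing_rate) NA_integer_ else
    match(sample_cat(cfg$svi_dist), names(cfg$svi_dist))

  labs <- list()
  tox <- cfg$tox_positive_rates[[st]]
  for (analyte in names(tox)) {
    if (runif(1) < tox[[analyte]]) {
      labs <- c(labs, list(list(analyte = analyte, result = "positive")))
    } else if (runif(1) < 0.15) {
      labs <- c(labs, list(list(analyte = analyte, result = "negative")))
    }
  }
  if (runif(1) < cfg$hcv_antibody_rate[[st]]) {
    labs <- c(labs, list(list(analyte = "hcv_antibody", result = "positive")))
    if (runif(1) < cfg$hcv_viral_load_given_ab) {
      labs <- c(labs, list(list(
        analyte = "hcv_viral_load",
        result = sample(c("positive", "quantified"), 1L),
        value = as.integer(round(10 ^ runif(1, 3, 7)))
      )))
    } else {
      labs <- c(labs, list(list(analyte = "hcv_viral_load",
                                result = "negative")))
    }
  }

  dx_codes <- list()
  if (runif(1) < cfg$icd_assignment_rate[[st]]) {
    for (code in sample(dx_pool$code, sample.int(2L, 1L))) {
      row <- dx_pool[dx_pool$code == code, ]
      dx_codes <- c(dx_codes, list(list(system = row$system, code = row$code,
                                        active = runif(1) < 0.8)))
    }
  }
  # non-qualifying comorbidity codes present on most encounters
  for (code in sample(c("I10", "E11.9", "J18.9", "N17.9"),
                      sample.int(3L, 1L) - 1L)) {
    dx_codes <- c(dx_codes, list(list(system = "ICD10", code = code,
                                      active = TRUE)))
  }

  medications <- list()
  if (runif(1) < cfg$moud_rate[[st]]) {
    drug <- sample(MOUD_DRUGS, 1L)
    context <- if (drug == "methadone_oral") {
      sample(MED_CONTEXTS, 1L, prob = c(0.55, 0.40, 0.05))
    } else {
      sample(MED_CONTEXTS, 1L)
    }
    medications <- list(list(drug = drug, context = context,
                             route_detail = if (drug == "methadone_oral")
                               "oral solution" else "sublingual film"))
  }
  if (runif(1) < 0.5) {
    medications <- c(medications, list(list(
      drug = "other", context = sample(MED_CONTEXTS, 1L),
      route_detail = "oral tablet")))
  }

  n_notes <- sample.int(3L, 1L)
  note_types <- sample(NOTE_TYPES, n_notes, replace = TRUE)
  mention <- runif(1) < cfg$keyword_mention_rate[[st]]
  kw_note <- if (mention) sample.int(n_notes, 1L) else 0L
  notes <- lapply(seq_len(n_notes), function(j) {
    kws <- character()
    denial <- FALSE
    if (j == kw_note) {
      if (truth) {
        kws <- sample(lexicon$surface, sample.int(2L, 1L))
      } else {
        kws <- sample(lexicon$surface, 1L)
        denial <- TRUE
      }
    }
    render_note_impl(note_types[j], kws,
                     misspelling_rate = if (truth) cfg$misspelling_rate else 0,
                     distractor_rate = if (truth) 0 else cfg$distractor_rate,
                     lexicon = lexicon, denial = denial)
  })

  list(
    encounter_id = sprintf("E%06d", i),
    age = round(min(95, max(18, rnorm(1, cfg$age_mean_sd[1],
                                      cfg$age_mean_sd[2]))), 1),
    sex = sample_cat(cfg$sex_dist),
    race_eth = sample_cat(cfg$race_dist),
    svi_quartile = svi,
    primary_language = sample_cat(cfg$language_dist),
    length_of_stay = round(max(0, rnorm(1, cfg$los_mean_sd[1],
                                        cfg$los_mean_sd[2])), 1),
    labs = labs,
    dx_codes = dx_codes,
    medications = medications,
    notes = notes,
    truth_pwud = truth
  )
}

#' Generate a synthetic encounter cohort with known ground truth
#'
#' Each encounter carries structured fields (demographics, labs, diagnosis
#' codes, medications), one or more free-text notes, and a ground-truth
#' `truth_pwud` label. Signals in every channel are drawn conditionally on
#' that label from the configured rates, so downstream classification can be
#' validated against truth. Identical configurations (including seed) yield
#' identical cohorts.
#'
#' @param config A `pwud_generation_config` from [generation_config()].
#' @param lexicon A `pwud_lexicon` used for keyword planting.
#' @return List of encounters (see [generation_config()] for the schema).
#' @export
generate_cohort <- function(config, lexicon = keyword_lexicon()) {
  validate_generation_config(config)
  dx_pool <- qualifying_code_pool()
  withr::with_seed(config$seed, {
    lapply(seq_len(config$n_encounters), generate_encounter,
           cfg = config, lexicon = lexicon, dx_pool = dx_pool)
  })
}

# Child codes of the qualifying families used for planting diagnosis signals.
qualifying_code_pool <- function() {
  tibble::tibble(
    system = c(rep("ICD10", 9), rep("ICD9", 2)),
    code = c("F11.20", "F11.10", "F14.10", "F14.20", "F15.10",
             "T40.1X1A", "T40.2X1A", "T40.5X1A", "B18.2",
             "070.54", "070.70")
  )
}

#' Flatten a cohort's structured fields to one row per encounter
#'
#' @param cohort List of encounters from [generate_cohort()] (or read back
#'   from JSONL).
#' @return Tibble with demographics, length of stay, per-analyte positive
#'   toxicology indicators, note count, and `truth_pwud`.
#' @export
encounter_table <- function(cohort) {
  pos_tox <- lapply(cohort, function(enc) {
    hits <- vapply(enc$labs, function(l) {
      identical(l$result, "positive") && l$analyte %in% TOX_ANALYTES
    }, logical(1))
    vapply(enc$labs[hits], `[[`, character(1), "analyte")
  })
  cols <- list(
    encounter_id = vapply(cohort, `[[`, character(1), "encounter_id"),
    age = vapply(cohort, function(e) as.numeric(e$age), numeric(1)),
    sex = vapply(cohort, `[[`, character(1), "sex"),
    race_eth = vapply(cohort, `[[`, character(1), "race_eth"),
    svi_quartile = vapply(cohort, function(e) {
      if (is.null(e$svi_quartile) || is.na(e$svi_quartile)) NA_integer_
      else as.integer(e$svi_quartile)
    }, integer(1)),
    primary_language = vapply(cohort, `[[`, character(1),
                              "primary_language"),
    length_of_stay = vapply(cohort, function(e) as.numeric(e$length_of_stay),
                            numeric(1)),
    n_notes = vapply(cohort, function(e) length(e$notes), integer(1)),
    truth_pwud = vapply(cohort, function(e) {
      if (is.null(e$truth_pwud)) NA else as.logical(e$truth_pwud)
    }, logical(1))
  )
  for (analyte in TOX_ANALYTES) {
    cols[[paste0("tox_", analyte)]] <-
      vapply(pos_tox, function(p) analyte %in% p, logical(1))
  }
  tibble::new_tibble(cols, nrow = length(cohort))
}

#' Simulate documentation-group membership with known effect sizes
#'
#' Generates encounter-level covariates (race, SVI, age, sex with the study's
#' marginal rates) and a binary high-documentation outcome from a logistic
#' model with specified log-odds coefficients. Used to validate
#' [fit_logistic()] by parameter recovery, since the study's adjusted odds
#' ratios cannot be recomputed without the individual-level records.
#'
#' @param n Number of rows.
#' @param beta_race Log odds ratio for White/non-Hispanic vs minoritized.
#' @param beta_svi Log odds ratio for SVI 3rd-4th vs 1st-2nd quartile.
#' @param beta_age Log odds ratio per year of age (centered at 48).
#' @param beta_male Log odds ratio for male sex.
#' @param intercept Model intercept on the log-odds scale.
#' @param seed Integer seed.
#' @return Tibble with `outcome`, `race_white`, `svi_high`, `age`, `male`.
#' @export
simulate_disparity_cohort <- function(n, beta_race = log(2),
                                      beta_svi = log(1.4),
                                      beta_age = -0.01, beta_male = 0.1,
                                      intercept = 0.4, seed) {
  withr::with_seed(seed, {
    race_white <- rbinom(n, 1, 0.652)
    svi_high <- rbinom(n, 1, 0.545)
    age <- rnorm(n, 47.9, 13.8)
    male <- rbinom(n, 1, 0.624)
    lp <- intercept + beta_race * race_white + beta_svi * svi_high +
      beta_age * (age - 48) + beta_male * male
    tibble::tibble(
      outcome = rbinom(n, 1, 1 / (1 + exp(-lp))),
      race_white = race_white, svi_high = svi_high, age = age, male = male
    )
  })
}
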