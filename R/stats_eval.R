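#' Positive predictive value of a chart-review validation
#'
#' PPV = confirmed / reviewed, with an exact Clopper-Pearson 95% interval and
#' the whole-percent rounding used in reporting (half away from zero, so
#' 53/99 = 53.54% prints as 54%).
#'
#' @param confirmed Number of reviewed charts confirmed as true PWUD.
#' @param reviewed Number of charts reviewed (>= 1).
#' @return List of class `pwud_ppv`: `reviewed`, `confirmed`, `ppv`,
#'   `ppv_pct_rounded`, `ci95` (proportions).
#' @examples
#' ppv(53, 99)$ppv_pct_rounded  # 54
#' @export
ppv <- function(confirmed, reviewed) {
  confirmed <- as.integer(confirmed)
  reviewed <- as.integer(reviewed)
  if (is.na(reviewed) || reviewed < 1L) stop("reviewed must be >= 1")
  if (is.na(confirmed) || confirmed < 0L || confirmed > reviewed) {
    stop("confirmed must be between 0 and reviewed")
  }
  p <- confirmed / reviewed
  ci <- as.numeric(binom.test(confirmed, reviewed)$conf.int)
  structure(
    list(reviewed = reviewed, confirmed = confirmed, ppv = p,
         ppv_pct_rounded = as.integer(floor(100 * p + 0.5)),
         ci95 = c(low = ci[1], high = ci[2])),
    class = "pwud_ppv"
  )
}

#' @export
print.pwud_ppv <- function(x, ...) {
  cat(sprintf("PPV %d/%d = %.1f%% (%d%%); 95%% CI %.1f-%.1f%%\n",
              x$confirmed, x$reviewed, 100 * x$ppv, x$ppv_pct_rounded,
              100 * x$ci95[["low"]], 100 * x$ci95[["high"]]))
  invisible(x)
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' Table orientation is fixed: rows are exposure (level of interest, then
#' reference), columns are outcome (group 1, then group 2), so
#' OR = (a*d)/(b*c). The 95% CI is the Woolf log-normal interval,
#' exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)). With exactly one zero
#' cell the Haldane-Anscombe correction (0.5 added to every cell) is applied
#' and flagged in `method`; opposing zero cells in a cross pattern leave the
#' OR undefined and raise an error.
#'
#' @param a,b,c,d Cell counts: `a` = exposed/outcome-1, `b` =
#'   exposed/outcome-2, `c` = reference/outcome-1, `d` = reference/outcome-2.
#' @return List of class `pwud_or`: `or_point`, `log_or`, `se_log_or`,
#'   `ci95`, `method`, `table`.
#' @examples
#' odds_ratio_2x2(550, 174, 176, 114)  # OR 2.05, CI (1.53, 2.74)
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("cell counts must be non-negative")
  }
  if ((counts[["a"]] == 0 && counts[["d"]] == 0) ||
      (counts[["b"]] == 0 && counts[["c"]] == 0)) {
    stop("odds ratio undefined: zero cells in a cross pattern")
  }
  method <- "woolf"
  work <- counts
  if (sum(counts == 0) > 0) {
    work <- counts + 0.5
    method <- "woolf_haldane_anscombe"
  }
  log_or <- log(work[["a"]]) + log(work[["d"]]) -
    log(work[["b"]]) - log(work[["c"]])
  se <- sqrt(sum(1 / work))
  ci <- exp(log_or + c(-1, 1) * 1.96 * se)
  structure(
    list(or_point = exp(log_or), log_or = unname(log_or), se_log_or = se,
         ci95 = c(low = ci[1], high = ci[2]), method = method,
         table = counts),
    class = "pwud_or"
  )
}

#' @export
print.pwud_or <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), %s\n", x$or_point,
              x$ci95[["low"]], x$ci95[["high"]], x$method))
  invisible(x)
}

#' Maximum-likelihood logistic regression with Wald intervals
#'
#' Binomial-logit fit via iteratively reweighted least squares
#' (`stats::glm`), with convergence at relative deviance change below 1e-8
#' or 100 iterations. Rows with missing covariates or outcome are dropped
#' and counted. Perfect separation is reported (fit flagged, warning
#' issued) rather than masked.
#'
#' @param outcome Binary vector (0/1 or logical).
#' @param covariates Data frame of covariates; factor/character columns are
#'   expanded by `glm`'s treatment contrasts.
#' @return List of class `pwud_logistic`: `coefficients`, `or_estimates`
#'   (exponentiated coefficients), `wald_ci95` (named list of
#'   exponentiated bounds), `converged`, `separation`, `n_used`,
#'   `n_dropped`, and the underlying `fit`.
#' @export
fit_logistic <- function(outcome, covariates) {
  covariates <- as.data.frame(covariates)
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0, 1, NA))) stop("outcome must be binary 0/1")
  if (nrow(covariates) != length(outcome)) {
    stop("outcome and covariates have different lengths")
  }
  keep <- !is.na(outcome) & complete.cases(covariates)
  n_used <- sum(keep)
  if (n_used < ncol(covariates) + 2L) {
    stop("too few complete rows (", n_used, ") for ",
         ncol(covariates), " covariate(s)")
  }
  dat <- cbind(.outcome = outcome[keep], covariates[keep, , drop = FALSE])
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.outcome ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation || !fit$converged) {
    warning("possible separation or non-convergence in logistic fit; ",
            "estimates may be unstable", call. = FALSE)
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  ci <- lapply(seq_along(est), function(i) {
    c(low = exp(est[i] - 1.96 * se[i]), high = exp(est[i] + 1.96 * se[i]))
  })
  names(ci) <- names(est)
  structure(
    list(coefficients = est, or_estimates = exp(est), wald_ci95 = ci,
         converged = fit$converged && !separation, separation = separation,
         n_used = n_used, n_dropped = length(outcome) - n_used, fit = fit),
    class = "pwud_logistic"
  )
}

mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
                               sd(x, na.rm = TRUE))
n_pct <- function(k, n) sprintf("%d (%.1f)", k, ifelse(n > 0, 100 * k / n, 0))

#' Documentation-disparity report
#'
#' Describes the included cohort and contrasts the highly documented (BDMN)
#' and minimally documented (N-only) groups: per-variable counts/percents,
#' unadjusted odds ratios of BDMN membership for race/ethnicity
#' (White/non-Hispanic vs racially/ethnically minoritized reference) and SVI
#' (3rd-4th vs 1st-2nd quartile reference, missing excluded), and adjusted
#' odds ratios from a logistic model of BDMN-vs-N-only membership on race,
#' SVI, age, and sex (the race aOR is adjusted for age, sex, and SVI; the
#' SVI aOR for age, sex, and race).
#'
#' @param partition A `pwud_partition`.
#' @param encounters Tibble from [encounter_table()] (one row per encounter,
#'   demographics columns).
#' @return List of class `pwud_disparity_report`: `descriptives` tibble,
#'   `unadjusted` (list of `pwud_or` for race and svi), `adjusted`
#'   (`pwud_logistic`), group sizes, and `n_missing_svi_excluded`.
#' @export
disparity_report <- function(partition, encounters) {
  stopifnot(inherits(partition, "pwud_partition"))
  groups <- comparison_groups(partition)
  if (length(groups$bdmn_ids) == 0L || length(groups$n_only_ids) == 0L) {
    stop("both comparison groups (BDMN and N-only) must be non-empty")
  }
  included_ids <- unlist(partition$cells, use.names = FALSE)
  enc <- encounters[encounters$encounter_id %in% included_ids, ]
  grp <- function(ids) enc[enc$encounter_id %in% ids, ]
  bdmn <- grp(groups$bdmn_ids)
  nonly <- grp(groups$n_only_ids)

  desc_block <- function(g) {
    n <- nrow(g)
    c(n = as.character(n),
      age_mean_sd = mean_sd(g$age),
      male = n_pct(sum(g$sex == "male"), n),
      female = n_pct(sum(g$sex == "female"), n),
      minoritized = n_pct(sum(g$race_eth == "minoritized"), n),
      white_nonhispanic = n_pct(sum(g$race_eth == "white_nonhispanic"), n),
      los_mean_sd = mean_sd(g$length_of_stay),
      svi_3rd_4th = n_pct(sum(g$svi_quartile %in% c(3, 4)), n),
      svi_1st_2nd = n_pct(sum(g$svi_quartile %in% c(1, 2)), n),
      svi_missing = n_pct(sum(is.na(g$svi_quartile)), n),
      english = n_pct(sum(g$primary_language == "english"), n),
      non_english = n_pct(sum(g$primary_language != "english"), n))
  }
  all_col <- desc_block(enc)
  descriptives <- tibble::tibble(
    variable = names(all_col),
    all_included = unname(all_col),
    bdmn = unname(desc_block(bdmn)),
    n_only = unname(desc_block(nonly))
  )

  # unadjusted ORs: outcome = BDMN membership (vs N-only)
  or_race <- odds_ratio_2x2(
    a = sum(bdmn$race_eth == "white_nonhispanic"),
    b = sum(nonly$race_eth == "white_nonhispanic"),
    c = sum(bdmn$race_eth == "minoritized"),
    d = sum(nonly$race_eth == "minoritized")
  )
  or_svi <- odds_ratio_2x2(
    a = sum(bdmn$svi_quartile %in% c(3, 4)),
    b = sum(nonly$svi_quartile %in% c(3, 4)),
    c = sum(bdmn$svi_quartile %in% c(1, 2)),
    d = sum(nonly$svi_quartile %in% c(1, 2))
  )

  both <- rbind(cbind(bdmn, .y = 1L), cbind(nonly, .y = 0L))
  covars <- data.frame(
    race_white = as.integer(both$race_eth == "white_nonhispanic"),
    svi_high = as.integer(both$svi_quartile %in% c(3, 4)),
    age = both$age,
    male = as.integer(both$sex == "male")
  )
  covars$svi_high[is.na(both$svi_quartile)] <- NA_integer_
  adjusted <- fit_logistic(both$.y, covars)

  structure(
    list(descriptives = descriptives,
         unadjusted = list(race = or_race, svi = or_svi),
         adjusted = adjusted,
         n_all_included = nrow(enc), n_bdmn = nrow(bdmn),
         n_n_only = nrow(nonly),
         n_missing_svi_excluded = sum(is.na(both$svi_quartile))),
    class = "pwud_disparity_report"
  )
}

#' @export
print.pwud_disparity_report <- function(x, ...) {
  cat("Documentation disparity report\n")
  cat(sprintf("  included %d | BDMN %d | N-only %d (missing SVI excluded from models: %d)\n",
              x$n_all_included, x$n_bdmn, x$n_n_only, x$n_missing_svi_excluded))
  cat(sprintf("  unadjusted OR, White/non-Hispanic vs minoritized: %.2f (%.2f, %.2f)\n",
              x$unadjusted$race$or_point, x$unadjusted$race$ci95[["low"]],
              x$unadjusted$race$ci95[["high"]]))
  cat(sprintf("  unadjusted OR, SVI 3rd-4th vs 1st-2nd: %.2f (%.2f, %.2f)\n",
              x$unadjusted$svi$or_point, x$unadjusted$svi$ci95[["low"]],
              x$unadjusted$svi$ci95[["high"]]))
  aor <- x$adjusted$or_estimates
  cat(sprintf("  adjusted OR race %.2f | SVI %.2f (n used %d)\n",
              aor[["race_white"]], aor[["svi_high"]], x$adjusted$n_used))
  invisible(x)
}
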