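# Canonical key for a flag subset: letters in fixed B, D, M, N order.
normalize_cell_key <- function(key) {
  letters4 <- unique(toupper(strsplit(paste(key, collapse = ""), "")[[1]]))
  letters4 <- letters4[letters4 %in% c("B", "D", "M", "N")]
  if (length(letters4) == 0L) stop("invalid cell key: ", paste(key, collapse = ""))
  paste0(c("B", "D", "M", "N")[c("B", "D", "M", "N") %in% letters4],
         collapse = "")
}

#' Partition included encounters into the Venn cells of \{B,D,M,N\}
#'
#' Every encounter with at least one true flag is assigned to exactly one of
#' the 15 non-empty flag subsets (e.g. `"B"`, `"DN"`, `"BDMN"`); encounters
#' with no true flag are excluded from the cohort and counted separately.
#'
#' @param flags Tibble/data.frame with columns `encounter_id`, `b`, `d`,
#'   `m`, `n` (logical); encounter ids must be unique.
#' @return List of class `pwud_partition`: `cells` (named list mapping cell
#'   key to encounter-id vector), `total_included`, `excluded_ids`.
#' @examples
#' flags <- tibble::tibble(encounter_id = c("e1", "e2", "e3"),
#'                         b = c(TRUE, TRUE, FALSE), d = c(FALSE, TRUE, FALSE),
#'                         m = c(FALSE, TRUE, FALSE), n = c(FALSE, TRUE, FALSE))
#' build_partition(flags)$cells
#' @export
build_partition <- function(flags) {
  required <- c("encounter_id", "b", "d", "m", "n")
  missing <- setdiff(required, names(flags))
  if (length(missing) > 0L) {
    stop("flags missing required column(s): ", paste(missing, collapse = ", "))
  }
  dup <- flags$encounter_id[duplicated(flags$encounter_id)]
  if (length(dup) > 0L) {
    stop("duplicate encounter_id in flags: ", paste(unique(dup), collapse = ", "))
  }
  keys <- paste0(ifelse(flags$b, "B", ""), ifelse(flags$d, "D", ""),
                 ifelse(flags$m, "M", ""), ifelse(flags$n, "N", ""))
  included <- nzchar(keys)
  cells <- split(flags$encounter_id[included], keys[included])
  structure(
    list(cells = cells,
         total_included = sum(included),
         excluded_ids = flags$encounter_id[!included]),
    class = "pwud_partition"
  )
}

#' @export
print.pwud_partition <- function(x, ...) {
  cat("PWUD cohort partition:", x$total_included, "included encounters in",
      length(x$cells), "cells;", length(x$excluded_ids), "excluded\n")
  sizes <- sort(vapply(x$cells, length, integer(1)), decreasing = TRUE)
  for (k in names(sizes)) cat(sprintf("  %-4s %6d\n", k, sizes[[k]]))
  invisible(x)
}

#' Cell sizes of a partition
#' @param partition A `pwud_partition`.
#' @return Named integer vector of cell sizes, decreasing.
#' @export
cell_sizes <- function(partition) {
  stopifnot(inherits(partition, "pwud_partition"))
  sort(vapply(partition$cells, length, integer(1)), decreasing = TRUE)
}

#' Extract the documentation comparison groups
#'
#' The highly documented group is the `BDMN` cell (all four criteria
#' present); the minimally documented group is the `N`-only cell (keyword
#' evidence in notes and nothing else). An absent cell yields an empty group.
#'
#' @param partition A `pwud_partition` from [build_partition()].
#' @return List with `bdmn_ids` and `n_only_ids`.
#' @export
comparison_groups <- function(partition) {
  stopifnot(inherits(partition, "pwud_partition"))
  list(bdmn_ids = partition$cells[["BDMN"]] %||% character(),
       n_only_ids = partition$cells[["N"]] %||% character())
}

#' Draw a chart-review sample from one Venn cell
#'
#' Simple random sample without replacement, deterministic under `seed`.
#' Either a sampling fraction or an absolute sample size may be given (the
#' study reviewed roughly 10% of the D-only cell and 35% of the N-only
#' cell).
#'
#' @param partition A `pwud_partition`.
#' @param subcohort Cell key, e.g. `"D"` or `"N"` (letter order ignored).
#' @param fraction Sampling fraction in (0, 1]; sample size is
#'   `round(fraction * cell size)`.
#' @param n Absolute sample size (overrides `fraction`).
#' @param seed Integer seed.
#' @return List of class `pwud_review_sample`: `subcohort`, `sampled_ids`,
#'   `sampling_fraction`, `seed`.
#' @export
select_review_sample <- function(partition, subcohort, fraction = NULL,
                                 n = NULL, seed) {
  stopifnot(inherits(partition, "pwud_partition"))
  key <- normalize_cell_key(subcohort)
  ids <- partition$cells[[key]]
  if (is.null(ids)) stop("subcohort cell not present in partition: ", key)
  size <- length(ids)
  if (is.null(n)) {
    if (is.null(fraction) || fraction <= 0 || fraction > 1) {
      stop("need a sampling fraction in (0, 1] or an absolute n")
    }
    n <- round(fraction * size)
  }
  n <- as.integer(n)
  if (n < 1L || n > size) {
    stop("sample size ", n, " out of range for cell ", key,
         " of size ", size)
  }
  sampled <- withr::with_seed(seed, sample(ids, n, replace = FALSE))
  structure(
    list(subcohort = key, sampled_ids = sampled,
         sampling_fraction = n / size, seed = as.integer(seed)),
    class = "pwud_review_sample"
  )
}
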