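# Independent full-matrix dynamic-programming oracle for the optimal string
# alignment distance (substitution, insertion, deletion, adjacent
# transposition at unit cost). Kept deliberately separate from the package's
# compiled implementation.
osa_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0L:n
  D[1L, ] <- 0L:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- as.integer(A[i] != B[j])
      best <- min(D[i, j + 1L] + 1L, D[i + 1L, j] + 1L, D[i, j] + cost)
      if (i > 1L && j > 1L && A[i] == B[j - 1L] && A[i - 1L] == B[j]) {
        best <- min(best, D[i - 1L, j - 1L] + 1L)
      }
      D[i + 1L, j + 1L] <- best
    }
  }
  D[n + 1L, m + 1L]
}

random_strings <- function(n, max_len = 10L, alphabet = c("a", "b", "c", "d")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, sample(0:max_len, 1L), replace = TRUE),
          collapse = "")
  }, character(1))
}

# Flags tibble from cell-key strings like c("B", "BDMN", "").
make_flags <- function(keys, ids = sprintf("e%04d", seq_along(keys))) {
  tibble::tibble(
    encounter_id = ids,
    b = grepl("B", keys), d = grepl("D", keys),
    m = grepl("M", keys), n = grepl("N", keys)
  )
}

# Exact binomial interval by the beta-quantile closed form, independent of
# the package's binom.test-based implementation.
clopper_pearson_oracle <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low, high)
}
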