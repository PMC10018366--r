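# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately written as plain, slow
# re-derivations from first principles.

# junction-ratio PSI recomputed per (event, cell) by summing raw counts
oracle_psi_plate <- function(events, junction_counts, min_reads = 10) {
  cells <- colnames(junction_counts)
  out <- matrix(NA_real_, nrow(events), length(cells),
                dimnames = list(events$event_id, cells))
  for (i in seq_len(nrow(events))) {
    inc_keys <- strsplit(events$included[i], ";", fixed = TRUE)[[1]]
    exc_keys <- strsplit(events$excluded[i], ";", fixed = TRUE)[[1]]
    for (cell in cells) {
      inc <- 0; exc <- 0
      for (k in inc_keys) inc <- inc + junction_counts[k, cell]
      for (k in exc_keys) exc <- exc + junction_counts[k, cell]
      if (inc + exc >= min_reads) out[i, cell] <- inc / (inc + exc)
    }
  }
  out
}

# sequential modality rules re-stated as one lookup table walk
oracle_modality <- function(alpha, beta, tau_eq = 0.05) {
  rules <- list(
    list(test = function(a, b) a < 0.5 || b < 0.5, label = "bimodal"),
    list(test = function(a, b) (a > 2 && b < 1) || a / b > 2,
         label = "included"),
    list(test = function(a, b) (b > 2 && a < 1) || b / a > 2,
         label = "excluded"),
    list(test = function(a, b) a > 1 && b > 1 &&
           abs(a - b) <= tau_eq * max(a, b), label = "middle"),
    list(test = function(a, b) TRUE, label = "multimodal"))
  for (r in rules) if (r$test(alpha, beta)) return(r$label)
}

# tie-adjusted (midrank) two-sample Anderson-Darling statistic, computed
# directly from the distinct-value formula
oracle_ad <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  z <- sort(unique(pooled))
  L <- length(z)
  inner1 <- 0; inner2 <- 0
  Bj <- 0; M1 <- 0; M2 <- 0
  for (j in seq_len(L - 1)) {
    lj <- sum(pooled == z[j])
    f1j <- sum(x == z[j]); f2j <- sum(y == z[j])
    M1t <- M1 + f1j / 2; M2t <- M2 + f2j / 2
    Bt <- Bj + lj / 2
    denom <- Bt * (N - Bt) - N * lj / 4
    if (denom > 0) {
      inner1 <- inner1 + lj / N * (N * M1t - n1 * Bt)^2 / denom
      inner2 <- inner2 + lj / N * (N * M2t - n2 * Bt)^2 / denom
    }
    M1 <- M1 + f1j; M2 <- M2 + f2j; Bj <- Bj + lj
  }
  # include the last distinct value (midrank form sums over all L values)
  lj <- sum(pooled == z[L])
  f1j <- sum(x == z[L]); f2j <- sum(y == z[L])
  M1t <- M1 + f1j / 2; M2t <- M2 + f2j / 2
  Bt <- Bj + lj / 2
  denom <- Bt * (N - Bt) - N * lj / 4
  if (denom > 0) {
    inner1 <- inner1 + lj / N * (N * M1t - n1 * Bt)^2 / denom
    inner2 <- inner2 + lj / N * (N * M2t - n2 * Bt)^2 / denom
  }
  (N - 1) / N * (inner1 / n1 + inner2 / n2)
}

# ECDF-distance statistic: sum over pooled order-statistic gaps of the
# absolute ECDF difference weighted by 1/sqrt(Fp (1 - Fp))
oracle_dts <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- sort(c(x, y))
  total <- 0
  for (i in seq_len(N - 1)) {
    gap <- pooled[i + 1] - pooled[i]
    f1 <- sum(x <= pooled[i]) / n1
    f2 <- sum(y <= pooled[i]) / n2
    fp <- i / N
    w <- fp * (1 - fp)
    if (w > 0) total <- total + abs(f1 - f2) * gap / sqrt(w)
  }
  total
}

# first stop codon by sliding a window over the sequence (brute force)
oracle_first_stop <- function(cdna, coding_start) {
  i <- coding_start
  while (i + 2 <= nchar(cdna)) {
    if (substr(cdna, i, i + 2) %in% c("TAA", "TAG", "TGA")) return(i)
    i <- i + 3
  }
  NA_integer_
}

# random DNA with no stop codon in any reading frame
random_stop_free_dna <- function(n) {
  safe <- c("GGC", "GCC", "CGG", "CCG", "GCG", "CGC")
  paste(sample(safe, ceiling(n / 3), replace = TRUE), collapse = "") |>
    substr(1, n)
}

make_group_labels <- function(n1, n2, cells) {
  setNames(rep(c("G1", "G2"), c(n1, n2)), cells)
}
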