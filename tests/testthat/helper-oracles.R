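# Independent brute-force oracles used to cross-check the package's
# statistics. Deliberately naive: O(n^2) pair counting and exhaustive
# permutation enumeration, nothing shared with the implementation.

tau_b_oracle <- function(x, y) {
  n <- length(x)
  concordant <- 0
  discordant <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) concordant <- concordant + 1
      if (s < 0) discordant <- discordant + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) sum(sapply(table(v), function(t) t * (t - 1) / 2))
  (concordant - discordant) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

# Exact two-sided rank-sum p-value by enumerating all C(m+n, m) group
# assignments of the pooled values (tie-free inputs only).
wilcoxon_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mid <- m * length(b) / 2
  p <- if (u_obs > mid) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(2 * p, 1)
}

# Tiny two-chemical registry used across unit tests.
toy_registry <- function() {
  pd_registry(
    tibble::tibble(
      chemical = c("Arsenic", "Boron", "Aldicarb"),
      pd = c(3e-4, 0.2, 2.7e-4),
      source_code = c(1L, 1L, 3L),
      basis = "RfD"
    ),
    parent_map = tibble::tibble(
      metabolite = "Aldicarb sulfoxide", parent = "Aldicarb"
    )
  )
}

# One measurement row in the long dialect.
measurement <- function(sample_id, analyte, detected, conc = NA_real_, dl = 0.001) {
  tibble::tibble(
    sample_id = sample_id, analyte = analyte,
    measured = TRUE, detected = detected,
    concentration_mg_L = conc, detection_limit_mg_L = dl
  )
}
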