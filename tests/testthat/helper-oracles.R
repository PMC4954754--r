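# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive (loops, literal formulas) so it
# cannot share a code path with the implementation it checks.

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} min(1, m p_(j)/j),
# computed with explicit loops over the sorted p-values.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Adjusted Rand index from the contingency table, straight from the
# permutation-model formula.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# A deterministic two-plate fixture with known control statistics.
make_simple_plates <- function(high = c(100, 110, 90, 100),
                               low = c(1, 2, 0.5, 1.5),
                               compounds = c(a = 55, b = 10)) {
  mk <- function(pid, gain = 1) {
    data.frame(
      plate_id = pid,
      well_id = sprintf("%s_w%02d", pid,
                        seq_len(length(high) + length(low) +
                                  length(compounds))),
      role = c(rep("high_control", length(high)),
               rep("low_control", length(low)),
               rep("compound", length(compounds))),
      compound_id = c(rep(NA_character_, length(high) + length(low)),
                      names(compounds)),
      raw_signal = gain * c(high, low, unname(compounds)),
      stringsAsFactors = FALSE)
  }
  mk
}

# Record table builder for triage tests: one confirmation/counterscreen
# replicate triple per compound around the given means (exact, no noise).
make_records <- function(primary_pct, confirm_mean = primary_pct,
                         counter_mean = rep(0, length(primary_pct)),
                         ids = sprintf("c%03d", seq_along(primary_pct))) {
  primary <- data.frame(compound_id = ids, pct_activation = primary_pct,
                        stringsAsFactors = FALSE)
  reps <- function(m) data.frame(
    compound_id = rep(ids, each = 3),
    replicate = rep(1:3, length(ids)),
    pct = rep(m, each = 3), stringsAsFactors = FALSE)
  build_compound_records(primary, reps(confirm_mean), reps(counter_mean))
}
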