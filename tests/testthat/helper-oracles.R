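# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# cell-by-cell Bliss delta computation (loop, no vectorization)
delta_loop_oracle <- function(effect) {
  n <- nrow(effect)
  m <- ncol(effect)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      a <- effect[i, 1]
      b <- effect[1, j]
      out[i, j] <- effect[i, j] - (a + b - a * b)
    }
  }
  out
}

# hand-rolled two-sample log-rank statistic from risk sets (no survival pkg)
logrank_stat_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == unique(group)[1]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# permutation p-value of the log-rank statistic (group labels permuted)
logrank_permutation_oracle <- function(time, event, group, n_perm = 10000,
                                       seed = 1) {
  obs <- logrank_stat_oracle(time, event, group)
  set.seed(seed)
  hits <- 0
  for (b in seq_len(n_perm)) {
    perm <- sample(group)
    if (logrank_stat_oracle(time, event, perm) >= obs - 1e-12) {
      hits <- hits + 1
    }
  }
  hits / n_perm
}

# greedy centroid matching of detected vs planted foci; returns F1
foci_f1 <- function(detected, truth, tol_px = 4) {
  truth <- truth[!truth$filtered, , drop = FALSE]
  n_truth <- nrow(truth)
  n_det <- nrow(detected)
  if (n_truth == 0 && n_det == 0) return(1)
  if (n_truth == 0 || n_det == 0) return(0)
  used <- rep(FALSE, n_truth)
  tp <- 0
  for (i in seq_len(n_det)) {
    d2 <- (truth$cx - detected$cx[i])^2 + (truth$cy - detected$cy[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= tol_px^2) {
      used[j] <- TRUE
      tp <- tp + 1
    }
  }
  precision <- tp / n_det
  recall <- tp / n_truth
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# small combination-screen table written and reassembled in tests
make_single_matrix_records <- function(viability, conc = c(0, 1, 2, 4, 8, 16),
                                       cell_line = "L1",
                                       genotype = "deficient",
                                       compound_a = "drugA",
                                       compound_b = "drugB", replicate = 1) {
  stopifnot(is.matrix(viability), nrow(viability) == length(conc),
            ncol(viability) == length(conc))
  grid <- expand.grid(i = seq_along(conc), j = seq_along(conc))
  data.frame(cell_line = cell_line, genotype = genotype,
             compound_a = compound_a, compound_b = compound_b,
             conc_a = conc[grid$i], conc_b = conc[grid$j],
             replicate = replicate,
             value = viability[cbind(grid$i, grid$j)],
             stringsAsFactors = FALSE)
}
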