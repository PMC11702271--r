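# Independent oracle implementations used to cross-check the package:
# each recomputes its quantity from the definition by a different route
# (enumeration, recurrence, pairwise counting) than the implementation.

# HWE exact test by the classic recurrence over the conditional
# distribution of heterozygote counts (probability ratios between
# neighbouring tables), normalized by full enumeration.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1)) {
      h <- hets[k]
      hom_r <- (rare - h) / 2
      hom_c <- (2 * n - rare - h) / 2
      # P(h+2) / P(h) = 4 * hom_r * hom_c / ((h+2)(h+1))
      pr[k + 1] <- pr[k] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# Full conditional distribution (for the sums-to-one check).
oracle_hwe_distribution <- function(n, nA) {
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1)) {
      h <- hets[k]
      pr[k + 1] <- pr[k] * 4 * ((rare - h) / 2) * ((2 * n - rare - h) / 2) /
        ((h + 2) * (h + 1))
    }
  }
  pr / sum(pr)
}

# AUC by brute-force pairwise concordance enumeration (ties count 1/2).
oracle_auc <- function(scores, y) {
  ca <- scores[y == 1]; co <- scores[y == 0]
  tot <- 0
  for (a in ca) for (b in co)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ca) * length(co))
}

# Greedy clumping re-implemented naively from the rule: repeatedly take the
# smallest-p unassigned variant as index, discard unassigned variants on
# the same chromosome within the window with r2 > r2_max. Returns ids.
oracle_clump <- function(weights, dosage, r2_max = 0.1, window_kb = 1000) {
  w <- weights
  assigned <- rep(FALSE, nrow(w))
  index <- character()
  while (!all(assigned)) {
    open <- which(!assigned)
    o <- open[order(w$p[open], w$se[open], w$pos[open])][1]
    index <- c(index, w$id[o])
    assigned[o] <- TRUE
    for (j in which(!assigned)) {
      if (w$chrom[j] != w$chrom[o]) next
      if (abs(w$pos[j] - w$pos[o]) > window_kb * 1000) next
      r2 <- suppressWarnings(stats::cor(dosage[, w$index[o]],
                                        dosage[, w$index[j]],
                                        use = "complete.obs")^2)
      if (!is.na(r2) && r2 > r2_max) assigned[j] <- TRUE
    }
  }
  sort(index)
}
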