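# In-code fixtures shared across test files.

# Small genotype matrix from an explicit dosage matrix; variants are
# non-ambiguous A/G SNPs on one chromosome unless overridden.
toy_gm <- function(dosage, chrom = "1", pos = NULL, ref = "A", alt = "G",
                   id = NULL, info = NA_real_) {
  m <- ncol(dosage)
  variants <- data.frame(
    chrom = rep_len(chrom, m),
    pos = pos %||% (1000 * seq_len(m)),
    id = id %||% sprintf("v%02d", seq_len(m)),
    ref = rep_len(ref, m), alt = rep_len(alt, m),
    info_score = rep_len(info, m), stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weights table shaped like harmonize() output, for unit tests that start
# mid-pipeline.
toy_weights <- function(gm, beta, p = NULL, se = NULL, rows = seq_along(beta)) {
  v <- gm$variants[rows, , drop = FALSE]
  w <- data.frame(index = rows, id = v$id, chrom = v$chrom, pos = v$pos,
                  beta = beta,
                  se = se %||% rep(0.1, length(beta)),
                  p = p %||% rep(0.5, length(beta)),
                  stringsAsFactors = FALSE)
  class(w) <- c("aligned_weights", "data.frame")
  w
}

# HWE-equilibrium random dosages (independent variants).
hwe_dosage <- function(n, maf) {
  m <- length(maf)
  matrix(stats::rbinom(n * m, 2, rep(maf, each = n)), nrow = n)
}

# Internal-surface shims (kept in one place).
sim_variant_table_for_test <- function(cfg) prsbench:::sim_variant_table(cfg)
in_regions_for_test <- function(chrom, pos, rs) prsbench:::in_regions(chrom, pos, rs)

# Standard small simulated cohort reused by several files (cached).
.cohort_cache <- new.env()
cached_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    cfg <- sim_config(n_variants = 300, n_blocks = 30, n_cases = 150,
                      n_controls = 300, seed = 424242L)
    .cohort_cache$co <- simulate_cohort(cfg)
    .cohort_cache$cfg <- cfg
  }
  list(co = .cohort_cache$co, cfg = .cohort_cache$cfg)
}
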