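test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(block_rho = 1), "block_rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(h2 = 1), "h2")
  expect_error(sim_config(pi_causal = 1e-9, n_variants = 100), "pi_causal")
  expect_error(sim_config(n_blocks = 50, n_variants = 10, pi_causal = 1),
               "n_blocks")
  expect_error(sim_config(rg = 1.5), "rg")
})

test_that("genotype simulation is deterministic and respects MAF and LD", {
  cfg <- sim_config(n_variants = 200, n_blocks = 20, seed = 101L)
  g1 <- simulate_genotypes(cfg, n = 300)
  g2 <- simulate_genotypes(cfg, n = 300)
  expect_identical(g1$dosage, g2$dosage)
  expect_true(all(g1$dosage %in% 0:2))
  expect_identical(dim(g1$dosage), c(300L, nrow(g1$variants)))

  # fixed MAF 0.3: empirical frequencies within the binomial 3-SE band
  cfg_fix <- sim_config(n_variants = 60, n_blocks = 6, maf_range = c(0.3, 0.3),
                        seed = 102L)
  g <- simulate_genotypes(cfg_fix, n = 5000)
  freq <- colMeans(g$dosage) / 2
  band <- 3 * sqrt(0.3 * 0.7 / (2 * 5000))
  main <- g$variants$chrom == "1"
  expect_true(all(abs(freq[main] - 0.3) <= band + 1e-9))

  # block_rho = 0: adjacent variants essentially uncorrelated
  cfg0 <- sim_config(n_variants = 100, n_blocks = 10, block_rho = 0,
                     seed = 103L)
  g0 <- simulate_genotypes(cfg0, n = 2000)
  j <- which(g0$variants$chrom == "1")
  r <- vapply(j[-length(j)], function(k)
    stats::cor(g0$dosage[, k], g0$dosage[, k + 1]), numeric(1))
  expect_lt(max(abs(r)), 0.1)

  # block_rho high: adjacent variants within a block clearly correlated
  cfgh <- sim_config(n_variants = 100, n_blocks = 5, block_rho = 0.9,
                     seed = 104L)
  gh <- simulate_genotypes(cfgh, n = 2000)
  r2_adj <- ld_r2(gh, 1, 2)
  expect_gt(r2_adj, 0.2)
})

test_that("effect assignment matches the stated architecture", {
  cfg <- sim_config(n_variants = 500, n_blocks = 50, pi_causal = 1,
                    seed = 105L)
  vt <- simulate_genotypes(cfg, n = 2)$variants
  tr <- assign_effects(cfg, vt)
  expect_true(all(tr$causal_mask))

  cfg0 <- sim_config(n_variants = 200, n_blocks = 20, h2 = 0,
                     apoe_beta_e4 = 0, apoe_beta_e2 = 0, seed = 106L)
  vt0 <- simulate_genotypes(cfg0, n = 2)$variants
  tr0 <- assign_effects(cfg0, vt0)
  expect_true(all(tr0$beta_true == 0))
  expect_true(all(tr0$beta_true[!tr0$causal_mask] == 0))

  # marginal effects equal R %*% beta within blocks (definition check on a
  # hand-picked block)
  cfg2 <- sim_config(n_variants = 40, n_blocks = 4, block_rho = 0.6,
                     seed = 107L)
  vt2 <- simulate_genotypes(cfg2, n = 2)$variants
  tr2 <- assign_effects(cfg2, vt2)
  idx <- which(vt2$block == 2)
  R <- 0.6^abs(outer(seq_along(idx), seq_along(idx), "-"))
  expect_equal(tr2$beta_marginal[idx], drop(R %*% tr2$beta_true[idx]),
               tolerance = 1e-12)
})

test_that("liability model: heritability recovery and prevalence calibration", {
  # large causal fraction keeps the chi-square fluctuation of sum(beta^2)
  # well inside the 10% band at this problem size
  cfg <- sim_config(n_variants = 1000, n_blocks = 100, h2 = 0.25,
                    pi_causal = 0.8, block_rho = 0.5, seed = 108L)
  gm <- simulate_genotypes(cfg, n = 10000)
  tr <- assign_effects(cfg, gm$variants)
  Xs <- sweep(sweep(gm$dosage, 2, 2 * tr$maf), 2,
              sqrt(2 * tr$maf * (1 - tr$maf)), "/")
  poly <- !(gm$variants$id %in% c("APOE_e4", "APOE_e2"))
  gv <- var(drop(Xs[, poly] %*% tr$beta_true[poly]))
  expect_lt(abs(gv - cfg$h2), 0.1 * cfg$h2)

  # unascertained case fraction approx K (3-SE binomial band at n = 20000)
  cfg2 <- sim_config(n_variants = 100, n_blocks = 10, prevalence = 0.07,
                     seed = 109L)
  gm2 <- simulate_genotypes(cfg2, n = 20000)
  tr2 <- assign_effects(cfg2, gm2$variants)
  ph2 <- simulate_phenotype(gm2, tr2, cfg2)
  se <- sqrt(0.07 * 0.93 / 20000)
  expect_lt(abs(mean(ph2$status) - 0.07), 3 * se)
})

test_that("APOE e4 carriers are enriched in cases under a positive e4 effect", {
  cfg <- sim_config(n_variants = 100, n_blocks = 10, apoe_beta_e4 = 0.6,
                    n_cases = 600, n_controls = 1400, seed = 110L)
  co <- simulate_cohort(cfg)
  j4 <- which(co$genotypes$variants$id == "APOE_e4")
  carrier <- co$genotypes$dosage[, j4] > 0
  f_case <- mean(carrier[co$phenotype$status == 1])
  f_ctrl <- mean(carrier[co$phenotype$status == 0])
  expect_gt(f_case, f_ctrl)
  # controls near the configured population carrier rate order of magnitude
  expect_gt(f_ctrl, 0.15)
  expect_lt(f_ctrl, 0.45)
})

test_that("ascertainment delivers exact quotas and deterministic cohorts", {
  cfg <- sim_config(n_variants = 60, n_blocks = 6, n_cases = 40,
                    n_controls = 80, seed = 111L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$genotypes$dosage, co2$genotypes$dosage)
  expect_identical(co1$phenotype$status, co2$phenotype$status)
  expect_equal(sum(co1$phenotype$status == 1), 40)
  expect_equal(sum(co1$phenotype$status == 0), 80)
  # cases are older on average by construction
  expect_gt(mean(co1$phenotype$age[co1$phenotype$status == 1]),
            mean(co1$phenotype$age[co1$phenotype$status == 0]) - 2)
})

test_that("simulated GWAS estimates are unbiased and track the truth", {
  cfg <- sim_config(n_variants = 600, n_blocks = 60, pi_causal = 0.3,
                    h2 = 0.4, n_gwas_a = 1e6, seed = 112L)
  vt <- simulate_genotypes(cfg, n = 2)$variants
  tr <- assign_effects(cfg, vt)
  ss <- simulate_gwas(tr, cfg, "A", vt)
  truth_pa <- tr$beta_marginal / sqrt(2 * tr$maf * (1 - tr$maf))
  slope <- stats::coef(stats::lm(ss$beta ~ truth_pa))[2]
  expect_lt(abs(slope - 1), 0.05)
  expect_true(all(ss$p > 0 & ss$p <= 1))
  expect_true(all(ss$se > 0))
})

test_that("rg = 1 with zero noise reproduces trait A exactly; rg controls similarity", {
  cfg1 <- sim_config(n_variants = 300, n_blocks = 30, rg = 1,
                     n_gwas_a = Inf, n_gwas_b = Inf, seed = 113L)
  vt <- simulate_genotypes(cfg1, n = 2)$variants
  tr <- assign_effects(cfg1, vt)
  a <- simulate_gwas(tr, cfg1, "A", vt)
  b <- simulate_gwas(tr, cfg1, "B", vt)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)

  # rg = 0: near-zero correlation of the polygenic effect estimates (the
  # APOE-like locus is shared between the traits by design, so the check
  # is on the main chromosome)
  r0 <- vapply(c(114L, 115L, 116L), function(sd) {
    cfg0 <- sim_config(n_variants = 5000, n_blocks = 500, rg = 0,
                       pi_causal = 1, block_rho = 0.3,
                       n_gwas_a = Inf, n_gwas_b = Inf, seed = sd)
    vt0 <- sim_variant_table_for_test(cfg0)
    tr0 <- assign_effects(cfg0, vt0)
    a0 <- simulate_gwas(tr0, cfg0, "A", vt0)
    b0 <- simulate_gwas(tr0, cfg0, "B", vt0)
    causal <- tr0$causal_mask & vt0$chrom == "1"
    stats::cor(a0$beta[causal], b0$beta[causal])
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.05)

  # correlation rises monotonically with rg
  cors <- vapply(c(0, 0.5, 1), function(r) {
    cfg <- sim_config(n_variants = 2000, n_blocks = 200, rg = r,
                      pi_causal = 0.5, n_gwas_a = Inf, n_gwas_b = Inf,
                      seed = 115L)
    vt <- sim_variant_table_for_test(cfg)
    tr <- assign_effects(cfg, vt)
    a <- simulate_gwas(tr, cfg, "A", vt)
    b <- simulate_gwas(tr, cfg, "B", vt)
    keep <- tr$causal_mask & vt$chrom == "1"
    stats::cor(a$beta[keep], b$beta[keep])
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_equal(cors[3], 1, tolerance = 1e-9)
})

test_that("microglia annotation covers the target fraction and spares the epsilon sites", {
  cfg <- sim_config(n_variants = 2000, n_blocks = 100,
                    microglia_fraction = 0.03, seed = 116L)
  vt <- simulate_genotypes(cfg, n = 2)$variants
  rs <- annotate_microglia(vt, cfg)
  frac <- mean(in_regions_for_test(vt$chrom, vt$pos, rs))
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.04)
  expect_false(any(in_regions_for_test("19", c(44908684, 44908822), rs)))
  # sorted, non-overlapping
  expect_true(all(rs$start <= rs$end))
  for (ch in unique(rs$chrom)) {
    sub <- rs[rs$chrom == ch, ]
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }
  # APOE sub-interval present
  expect_true("19" %in% rs$chrom)
  bad <- cfg
  bad$microglia_fraction <- 0
  expect_error(annotate_microglia(vt, bad), "microglia_fraction")
})
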