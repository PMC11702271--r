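make_harmonize_fixture <- function() {
  # 6 cohort variants; summary stats with one sign flip, one mismatch, one
  # strand-ambiguous pair
  dos <- matrix(rep(0:2, 8), nrow = 4)
  gm <- genotype_matrix(dos, data.frame(
    chrom = "1", pos = (1:6) * 1000, id = paste0("v", 1:6),
    ref = c("A", "A", "A", "C", "A", "G"),
    alt = c("G", "G", "G", "T", "T", "C"),
    stringsAsFactors = FALSE))
  ss <- sumstats(data.frame(
    chrom = "1", pos = (1:6) * 1000, id = paste0("v", 1:6),
    a1 = c("G", "A", "C", "T", "A", "G"),   # v2: effect allele = ref (flip)
    a2 = c("A", "G", "A", "C", "T", "C"),   # v3: mismatch; v5 A/T, v6 G/C ambiguous
    beta = c(0.1, 0.3, 0.2, -0.4, 0.5, 0.6),
    se = rep(0.05, 6), p = c(1e-9, 1e-4, 0.2, 0.01, 0.3, 0.4)))
  list(gm = gm, ss = ss)
}

test_that("harmonization flips, drops and counts correctly", {
  fx <- make_harmonize_fixture()
  expect_message(w <- harmonize(fx$ss, fx$gm, drop_ambiguous = TRUE),
                 "harmonized")
  # kept: v1 (as-is), v2 (flipped), v4 (as-is); dropped: v3 mismatch,
  # v5/v6 ambiguous
  expect_equal(w$id, c("v1", "v2", "v4"))
  expect_equal(w$beta, c(0.1, -0.3, -0.4))
  cnt <- attr(w, "counts")
  expect_equal(unname(cnt["matched"]), 3)
  expect_equal(unname(cnt["flipped"]), 1)
  expect_equal(unname(cnt["dropped_ambiguous"]), 2)
  expect_equal(unname(cnt["dropped_mismatch"]), 1)

  # ambiguous retained when the flag is off
  w2 <- suppressMessages(harmonize(fx$ss, fx$gm, drop_ambiguous = FALSE))
  expect_true(all(c("v5", "v6") %in% w2$id))

  # zero matches is fatal
  ss_far <- fx$ss; ss_far$pos <- ss_far$pos + 1e6
  expect_error(suppressMessages(harmonize(ss_far, fx$gm)), "no variants")
})

test_that("ld_r2 equals the closed-form Pearson computation", {
  dos <- cbind(c(0, 1, 2, 1, 0), c(1, 1, 0, 2, 0))
  gm <- toy_gm(dos)
  x <- dos[, 1]; y <- dos[, 2]
  manual <- (sum((x - mean(x)) * (y - mean(y))) /
               sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(ld_r2(gm, 1, 2), manual, tolerance = 1e-12)
  expect_equal(ld_r2(gm, 1, 1), 1)
  gm2 <- toy_gm(cbind(dos[, 1], 2 - dos[, 1]))
  expect_equal(ld_r2(gm2, 1, 2), 1) # mirrored column
  gm3 <- toy_gm(cbind(dos[, 1], rep(1, 5)))
  expect_error(ld_r2(gm3, 1, 2), "zero-variance")
})

test_that("clumping follows the greedy rule on the 3-variant instance", {
  # construct dosages with target pairwise r2: high LD between v1 and v2
  set.seed(12)
  n <- 400
  base <- rbinom(n, 2, 0.4)
  noisy <- function(x, flip_p) ifelse(runif(n) < flip_p, rbinom(n, 2, 0.4), x)
  dos <- cbind(base, noisy(base, 0.25), rbinom(n, 2, 0.4))
  gm <- toy_gm(dos, pos = c(1e5, 2e5, 3e5))
  stopifnot(ld_r2(gm, 1, 2) > 0.1, ld_r2(gm, 1, 3) < 0.1,
            ld_r2(gm, 2, 3) < 0.1)
  w <- toy_weights(gm, beta = c(0.5, 0.4, 0.3), p = c(1e-10, 1e-5, 1e-3))
  kept <- clump(w, gm, clump_params(r2_max = 0.1, window_kb = 1000))
  expect_equal(sort(kept$id), c("v01", "v03"))

  # single variant retained; no-LD case retains everything
  expect_equal(nrow(clump(w[1, ], gm)), 1)
  w_far <- toy_weights(gm, beta = c(0.5, 0.4, 0.3), p = c(1e-10, 1e-5, 1e-3))
  kept_all <- clump(w_far, gm, clump_params(r2_max = 1))
  expect_equal(nrow(kept_all), 3) # r2 > 1 never happens
})

test_that("clumping matches the brute-force oracle and ignores row order", {
  set.seed(13)
  for (rep in 1:8) {
    n <- 300; m <- 12
    base <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
    dos <- sapply(seq_len(m), function(j) {
      src <- base[, (j %% 3) + 1]
      ifelse(runif(n) < 0.35, rbinom(n, 2, 0.3), src)
    })
    pos <- sort(sample(1:2e6, m))
    gm <- toy_gm(dos, pos = pos)
    w <- toy_weights(gm, beta = rnorm(m), p = runif(m)^2,
                     se = runif(m, 0.01, 0.1))
    kept <- clump(w, gm, clump_params(r2_max = 0.1, window_kb = 1000))
    expect_equal(sort(kept$id),
                 oracle_clump(w, gm$dosage, r2_max = 0.1, window_kb = 1000))
    # row-order invariance
    shuf <- w[sample(nrow(w)), ]
    class(shuf) <- class(w)
    kept2 <- clump(shuf, gm, clump_params(r2_max = 0.1, window_kb = 1000))
    expect_equal(sort(kept2$id), sort(kept$id))
  }
})

test_that("thresholding is inclusive and nested across the grid", {
  gm <- toy_gm(matrix(0:1, 2, 6))
  w <- toy_weights(gm, beta = rep(1, 3), p = c(5e-8, 3e-8, 0.2), rows = 1:3)
  expect_equal(nrow(threshold_weights(w, 5e-8)), 2) # inclusive boundary
  expect_equal(nrow(threshold_weights(w, 1)), 3)
  expect_equal(nrow(threshold_weights(w, 1e-12)), 0)
  grid <- c(1e-8, 1e-4, 0.5, 1)
  sizes <- vapply(grid, function(pt) nrow(threshold_weights(w, pt)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("region restriction respects inclusive bounds and partitions", {
  gm <- toy_gm(matrix(0:1, 2, 4), chrom = "19",
               pos = c(43899999, 43900000, 46000000, 46000001))
  w <- toy_weights(gm, beta = rep(1, 4), rows = 1:4)
  inc <- restrict_region(w, apoe_region(), "include")
  exc <- restrict_region(w, apoe_region(), "exclude")
  expect_equal(inc$pos, c(43900000, 46000000)) # both bounds inclusive
  expect_equal(exc$pos, c(43899999, 46000001))
  expect_setequal(c(inc$id, exc$id), w$id) # exact partition
})

test_that("scoring: arithmetic, mean imputation, linearity, allele-flip invariance", {
  gm <- toy_gm(matrix(c(2, 1, 0, 1, 1, 1), nrow = 1), id = paste0("v", 1:6))
  w <- toy_weights(gm, beta = c(0.1, -0.2), rows = 1:2)
  expect_equal(prs_score(gm, w)$score, 0) # 0.1*2 - 0.2*1

  w0 <- toy_weights(gm, beta = rep(0, 6))
  expect_true(all(prs_score(gm, w0)$score == 0))

  # hand-computed mean imputation on a 3x3 toy
  dos <- matrix(c(0, 1, 2,
                  1, NA, 1,
                  2, 0, 0), nrow = 3, byrow = FALSE)
  gm3 <- toy_gm(dos)
  w3 <- toy_weights(gm3, beta = c(1, 10, 100))
  sc <- suppressMessages(prs_score(gm3, w3))
  imput <- mean(c(1, 1)) # column 2 mean over non-missing
  expect_equal(sc$score, c(0 + 10 * 1 + 100 * 2,
                           1 + 10 * imput + 100 * 0,
                           2 + 10 * 1 + 100 * 0))

  # linearity in the weights
  set.seed(21)
  dosL <- hwe_dosage(20, runif(10, 0.2, 0.5))
  gmL <- toy_gm(dosL)
  b1 <- rnorm(10); b2 <- rnorm(10)
  s1 <- prs_score(gmL, toy_weights(gmL, b1))$score
  s2 <- prs_score(gmL, toy_weights(gmL, b2))$score
  s12 <- prs_score(gmL, toy_weights(gmL, b1 + b2))$score
  expect_equal(s12, s1 + s2, tolerance = 1e-12)

  # empty weights: zero scores with a warning
  expect_warning(sc0 <- prs_score(gmL, toy_weights(gmL, numeric(0), rows = integer(0))),
                 "empty")
  expect_true(all(sc0$score == 0))
  expect_equal(attr(sc0, "provenance")$n_snps, 0)
})

test_that("allele-coding flip leaves scores unchanged after harmonization", {
  set.seed(22)
  dos <- hwe_dosage(30, runif(5, 0.2, 0.5))
  gm <- toy_gm(dos, ref = "A", alt = "G")
  wf <- data.frame(chrom = "1", pos = gm$variants$pos, id = gm$variants$id,
                   effect_allele = "G", other_allele = "A",
                   weight = rnorm(5), stringsAsFactors = FALSE)
  s1 <- suppressMessages(external_scores(gm, wf))
  # flip the file's allele coding and the weight signs together
  wf2 <- wf
  wf2$effect_allele <- "A"; wf2$other_allele <- "G"; wf2$weight <- -wf$weight
  s2 <- suppressMessages(external_scores(gm, wf2))
  expect_equal(s1$score, s2$score, tolerance = 1e-12)

  expect_error(suppressMessages(external_scores(gm, wf[0, ])), "no variants")
})

test_that("ct_pipeline produces one nested score set per threshold", {
  fx <- cached_cohort()
  co <- fx$co
  ss <- simulate_gwas(co$truth, fx$cfg, "A", co$genotypes$variants)
  sets <- suppressMessages(suppressWarnings(
    ct_pipeline(ss, co$genotypes, clump_params(), "full", gwas_id = "A")))
  expect_length(sets, 8)
  ns <- vapply(sets, function(s) attr(s, "provenance")$n_snps, numeric(1))
  expect_true(all(diff(ns) >= 0)) # nested across increasing pT
  expect_equal(attr(sets[[8]], "provenance")$pt, 0.5)
  expect_equal(attr(sets[[1]], "provenance")$gwas, "A")

  # noAPOE mode drops chromosome 19 variants from scoring
  sets_no <- suppressMessages(suppressWarnings(
    ct_pipeline(ss, co$genotypes, clump_params(pt_grid = 0.5), "noAPOE",
                gwas_id = "A")))
  expect_lt(attr(sets_no[[1]], "provenance")$n_snps,
            attr(sets[[8]], "provenance")$n_snps)
})
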