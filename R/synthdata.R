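# Liability-threshold cohort simulator with block-LD genotypes, an
# APOE-like major-effect locus, and paired genetically correlated discovery
# GWAS. All ground truth (causal effects, LD-convolved marginals, latent
# liabilities) is retained so downstream methods can be validated against
# known answers.

# Positions of the two epsilon-defining sites of the APOE-like block
# (rs429358-role = e4-defining, rs7412-role = e2-defining; GRCh38-like
# coordinates inside the 43.9-46.0 Mb interval).
APOE_E4_POS <- 44908684
APOE_E2_POS <- 44908822
APOE_CHROM <- "19"

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic cohort and discovery-GWAS
#' generator. Defaults emulate a clinically diagnosed AD case/control study:
#' prevalence 5%, polygenic liability heritability 0.2 outside the major
#' locus, an APOE-like locus whose e4 allele (frequency 0.15) raises and e2
#' allele (frequency 0.08) lowers liability, and two discovery GWAS with
#' sample sizes matching a clinical AD GWAS (63,926) and a much larger
#' proxy-dementia meta-analysis (487,511), genetically correlated at 0.8.
#'
#' @param n_variants number of variants on the main (polygenic) chromosome.
#' @param n_blocks number of independent LD blocks the main chromosome is
#'   split into.
#' @param block_rho AR(1) latent correlation within a block, in \[0,1).
#' @param maf_range length-2 vector, minor-allele-frequency range (0,0.5\].
#' @param pi_causal fraction of variants that are causal, in (0,1\].
#' @param h2 liability-scale heritability of the polygenic (non-APOE)
#'   component, in \[0,1).
#' @param prevalence population disease prevalence K in (0,1).
#' @param n_cases,n_controls ascertained cohort sizes.
#' @param apoe_beta_e4,apoe_beta_e2 liability effect per e4 / e2 allele on
#'   the raw-dosage scale (signed; e4 positive, e2 negative by convention).
#' @param rg genetic correlation between the two simulated traits, in
#'   \[-1,1\].
#' @param n_gwas_a,n_gwas_b discovery effective sample sizes (may be `Inf`
#'   for the no-noise limit).
#' @param microglia_fraction target fraction of variants covered by
#'   microglia-like annotation, in (0,1).
#' @param seed integer RNG seed.
#' @param apoe_maf_e4,apoe_maf_e2 allele frequencies of the two defining
#'   sites (defaults give roughly 28% e4 carriers in the population).
#' @param apoe_block_size number of variants in the APOE-like block.
#' @param age_mean,age_sd,age_case_shift covariate model for age (years);
#'   cases are shifted upward by `age_case_shift`.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 2000L, n_blocks = 100L, block_rho = 0.8,
                       maf_range = c(0.05, 0.5), pi_causal = 0.05, h2 = 0.2,
                       prevalence = 0.05, n_cases = 500L, n_controls = 500L,
                       apoe_beta_e4 = 0.5, apoe_beta_e2 = -0.25, rg = 0.8,
                       n_gwas_a = 63926, n_gwas_b = 487511,
                       microglia_fraction = 0.03, seed = 42L,
                       apoe_maf_e4 = 0.15, apoe_maf_e2 = 0.08,
                       apoe_block_size = 20L,
                       age_mean = 72, age_sd = 7, age_case_shift = 3) {
  cfg <- list(n_variants = as.integer(n_variants), n_blocks = as.integer(n_blocks),
              block_rho = block_rho, maf_range = maf_range,
              pi_causal = pi_causal, h2 = h2, prevalence = prevalence,
              n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              apoe_beta_e4 = apoe_beta_e4, apoe_beta_e2 = apoe_beta_e2,
              rg = rg, n_gwas_a = n_gwas_a, n_gwas_b = n_gwas_b,
              microglia_fraction = microglia_fraction, seed = as.integer(seed),
              apoe_maf_e4 = apoe_maf_e4, apoe_maf_e2 = apoe_maf_e2,
              apoe_block_size = as.integer(apoe_block_size),
              age_mean = age_mean, age_sd = age_sd,
              age_case_shift = age_case_shift)
  num <- unlist(cfg[!vapply(cfg, is.character, logical(1))])
  if (any(!is.finite(num[!names(num) %in% c("n_gwas_a", "n_gwas_b")])))
    stop("all sim_config fields must be finite")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) stop("block_rho must be in [0,1)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie in (0, 0.5]")
  if (cfg$pi_causal <= 0 || cfg$pi_causal > 1) stop("pi_causal must be in (0,1]")
  if (cfg$pi_causal * cfg$n_variants < 1) stop("pi_causal * n_variants must be >= 1")
  if (cfg$h2 < 0 || cfg$h2 >= 1) stop("h2 must be in [0,1)")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1) stop("prevalence must be in (0,1)")
  if (abs(cfg$rg) > 1) stop("rg must be in [-1,1]")
  if (cfg$n_blocks > cfg$n_variants) stop("n_blocks must be <= n_variants")
  if (cfg$microglia_fraction <= 0 || cfg$microglia_fraction >= 1)
    stop("microglia_fraction must be in (0,1)")
  class(cfg) <- "sim_config"
  cfg
}

# Variant metadata table for one realization: main chromosome "1" plus the
# APOE-like block on chromosome "19". Columns block/maf carry ground truth.
sim_variant_table <- function(config) {
  m <- config$n_variants
  set.seed(child_seed(config$seed, 0L))
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  block <- sort(rep_len(seq_len(config$n_blocks), m))
  pos <- 100000 + 5000 * seq_len(m)
  alleles <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                      "G", "A", "C", "A", "G", "T", "C", "T"),
                    ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(alleles), m, replace = TRUE)
  main <- data.frame(chrom = "1", pos = pos,
                     id = sprintf("var%05d", seq_len(m)),
                     ref = alleles[pick, 1], alt = alleles[pick, 2],
                     block = block, maf = maf, stringsAsFactors = FALSE)

  bs <- max(config$apoe_block_size, 4L)
  base <- round(seq(44500000, 45400000, length.out = bs))
  drop1 <- which.min(abs(base - APOE_E4_POS))
  drop2 <- setdiff(order(abs(base - APOE_E2_POS)), drop1)[1]
  apos <- sort(unique(c(base[-c(drop1, drop2)], APOE_E4_POS, APOE_E2_POS)))
  bs <- length(apos)
  amaf <- stats::runif(bs, config$maf_range[1], config$maf_range[2])
  aid <- sprintf("apoe_blk%02d", seq_len(bs))
  aref <- rep("T", bs); aalt <- rep("C", bs)
  i4 <- which(apos == APOE_E4_POS); i2 <- which(apos == APOE_E2_POS)
  amaf[i4] <- config$apoe_maf_e4; amaf[i2] <- config$apoe_maf_e2
  aid[i4] <- "APOE_e4"; aid[i2] <- "APOE_e2"
  apoe <- data.frame(chrom = APOE_CHROM, pos = apos, id = aid,
                     ref = aref, alt = aalt,
                     block = config$n_blocks + 1L, maf = amaf,
                     stringsAsFactors = FALSE)
  vt <- rbind(main, apoe)
  vt$info_score <- round(stats::runif(nrow(vt), 0.75, 1), 4)
  rownames(vt) <- NULL
  vt
}

# One haplotype matrix (n x m, alleles 0/1) for a variant table: within each
# block a latent AR(1) Gaussian is thresholded at the quantile matching each
# variant's MAF; distinct blocks are independent. The e2-defining site uses
# the opposite tail of the latent so that, within the positively correlated
# APOE block, e2 and e4 alleles are negatively associated (they live on
# different haplotype backgrounds), as in real APOE haplotype structure.
sim_haplotypes <- function(n, vt, rho) {
  m <- nrow(vt)
  H <- matrix(0L, n, m)
  thr <- stats::qnorm(vt$maf)
  flip <- vt$id == "APOE_e2"
  for (b in unique(vt$block)) {
    idx <- which(vt$block == b)
    z <- stats::rnorm(n)
    H[, idx[1]] <- if (flip[idx[1]]) as.integer(z > -thr[idx[1]])
                   else as.integer(z < thr[idx[1]])
    if (length(idx) > 1) {
      s <- sqrt(1 - rho^2)
      for (k in idx[-1]) {
        z <- rho * z + s * stats::rnorm(n)
        H[, k] <- if (flip[k]) as.integer(z > -thr[k])
                  else as.integer(z < thr[k])
      }
    }
  }
  H
}

#' Simulate LD-structured genotypes
#'
#' Dosages in \{0,1,2\} are formed as the sum of two independent haplotypes.
#' Within each block, haplotype alleles come from thresholding a latent
#' AR(1) Gaussian at each variant's MAF quantile; distinct blocks are
#' independent. The main chromosome is accompanied by a dedicated APOE-like
#' block on chromosome 19 containing the two epsilon-defining sites; a
#' haplotype carrying both defining alleles is resolved to the e4-defining
#' allele only (the rare epsilon-1 haplotype is not modelled), so per-sample
#' e2+e4 counts never exceed 2.
#'
#' @param config a [sim_config()].
#' @param n number of samples to draw (default `n_cases + n_controls`).
#' @param seed RNG seed (default derived from `config$seed`).
#' @param variants optional pre-built variant table (internal use).
#' @return a [genotype_matrix()]; variant metadata includes ground-truth
#'   `block` and `maf` columns and a synthesized `info_score`.
#' @export
simulate_genotypes <- function(config, n = config$n_cases + config$n_controls,
                               seed = child_seed(config$seed, 1L),
                               variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  vt <- variants %||% sim_variant_table(config)
  set.seed(seed)
  h1 <- sim_haplotypes(n, vt, config$block_rho)
  h2 <- sim_haplotypes(n, vt, config$block_rho)
  i4 <- which(vt$id == "APOE_e4"); i2 <- which(vt$id == "APOE_e2")
  both1 <- h1[, i4] == 1L & h1[, i2] == 1L
  h1[both1, i2] <- 0L
  both2 <- h2[, i4] == 1L & h2[, i2] == 1L
  h2[both2, i2] <- 0L
  dos <- h1 + h2
  samples <- sprintf("S%05d", seq_len(n))
  genotype_matrix(dos, vt, samples)
}

#' Assign ground-truth causal effects
#'
#' Draws a causal mask with probability `pi_causal` per variant (the two
#' epsilon-defining sites are always causal, with per-allele effects
#' `apoe_beta_e4` / `apoe_beta_e2` converted to the standardized-genotype
#' scale), i.i.d. Normal(0, h2 / m_causal) effects for the remaining causal
#' variants, and the LD-convolved marginal effects `R beta` using each
#' block's AR(1) correlation.
#'
#' @param config a [sim_config()].
#' @param variants variant metadata (from [simulate_genotypes()]).
#' @param seed RNG seed.
#' @return list of class `truth_record` with `beta_true` (standardized
#'   scale), `causal_mask`, `beta_marginal`, `var_apoe`, plus the `maf` and
#'   `block` vectors used.
#' @export
assign_effects <- function(config, variants,
                           seed = child_seed(config$seed, 2L)) {
  stopifnot(all(c("block", "maf") %in% names(variants)))
  set.seed(seed)
  m <- nrow(variants)
  is_e4 <- variants$id == "APOE_e4"
  is_e2 <- variants$id == "APOE_e2"
  causal <- stats::runif(m) < config$pi_causal
  causal[is_e4 | is_e2] <- TRUE
  poly <- causal & !is_e4 & !is_e2
  m_causal <- sum(poly)
  if (m_causal == 0 && config$h2 > 0) stop("no causal variants outside APOE")
  beta <- numeric(m)
  if (m_causal > 0 && config$h2 > 0)
    beta[poly] <- stats::rnorm(m_causal, 0, sqrt(config$h2 / m_causal))
  sd4 <- sqrt(2 * config$apoe_maf_e4 * (1 - config$apoe_maf_e4))
  sd2 <- sqrt(2 * config$apoe_maf_e2 * (1 - config$apoe_maf_e2))
  beta[is_e4] <- config$apoe_beta_e4 * sd4
  beta[is_e2] <- config$apoe_beta_e2 * sd2
  var_apoe <- sum(beta[is_e4 | is_e2]^2)
  if (config$h2 + var_apoe >= 1)
    stop("h2 plus APOE variance must be < 1 on the liability scale")
  marg <- numeric(m)
  for (b in unique(variants$block)) {
    idx <- which(variants$block == b)
    if (!any(beta[idx] != 0)) next
    R <- config$block_rho^abs(outer(seq_along(idx), seq_along(idx), "-"))
    marg[idx] <- drop(R %*% beta[idx])
  }
  structure(list(beta_true = beta, causal_mask = causal,
                 beta_marginal = marg, var_apoe = var_apoe,
                 maf = variants$maf, block = variants$block,
                 is_e4 = is_e4, is_e2 = is_e2),
            class = "truth_record")
}

# Standardize dosages by the true allele frequency used to simulate.
standardize_dosage <- function(dosage, maf) {
  sweep(sweep(dosage, 2, 2 * maf), 2, sqrt(2 * maf * (1 - maf)), "/")
}

#' Simulate liability-threshold phenotypes and covariates
#'
#' Latent liability is the standardized-genotype genetic component plus
#' Normal environmental noise with variance `1 - h2 - var_apoe`; a sample
#' is a case iff its liability exceeds the prevalence quantile
#' `qnorm(1 - K)`. Age is Normal with cases shifted upward; sex is
#' Bernoulli(0.5). No ascertainment is applied here — see
#' [simulate_cohort()] for case/control quota sampling.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param truth matching `truth_record` from [assign_effects()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data.frame with columns `sample`, `status` (1 = case), `age`,
#'   `sex` (0/1); latent liabilities in attribute `"liability"`, genetic
#'   components in `"genetic"`.
#' @export
simulate_phenotype <- function(genotypes, truth, config,
                               seed = child_seed(config$seed, 3L)) {
  stopifnot(length(truth$beta_true) == ncol(genotypes$dosage))
  set.seed(seed)
  n <- nrow(genotypes$dosage)
  Xs <- standardize_dosage(genotypes$dosage, truth$maf)
  g <- drop(Xs %*% truth$beta_true)
  var_e <- 1 - config$h2 - truth$var_apoe
  liab <- g + stats::rnorm(n, 0, sqrt(var_e))
  status <- as.integer(liab > stats::qnorm(1 - config$prevalence))
  age <- stats::rnorm(n, config$age_mean, config$age_sd) +
    status * config$age_case_shift
  sex <- stats::rbinom(n, 1, 0.5)
  out <- data.frame(sample = genotypes$samples, status = status,
                    age = age, sex = sex, stringsAsFactors = FALSE)
  attr(out, "liability") <- liab
  attr(out, "genetic") <- g
  out
}

#' Simulate an ascertained case/control cohort
#'
#' Draws genotype/phenotype batches from the population until `n_cases`
#' cases and `n_controls` controls are accumulated (rejection sampling with
#' a hard cap of 1e7 population draws), mirroring how clinical case/control
#' cohorts over-sample cases relative to population prevalence.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` ([genotype_matrix()]), `phenotype`
#'   (data.frame as in [simulate_phenotype()]), `truth` (`truth_record`)
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  vt <- sim_variant_table(config)
  truth <- assign_effects(config, vt)
  need_ca <- config$n_cases; need_co <- config$n_controls
  dos_list <- list(); ph_list <- list(); drawn <- 0; batch <- 0L
  while (need_ca > 0 || need_co > 0) {
    batch <- batch + 1L
    bn <- min(50000L, max(2000L, ceiling(need_ca / config$prevalence * 1.3)))
    if (drawn + bn > 1e7) stop("ascertainment cap reached: prevalence too low ",
                               "for requested case count")
    gm <- simulate_genotypes(config, n = bn,
                             seed = child_seed(config$seed, 100L + batch),
                             variants = vt)
    ph <- simulate_phenotype(gm, truth, config,
                             seed = child_seed(config$seed, 200L + batch))
    drawn <- drawn + bn
    take_ca <- utils::head(which(ph$status == 1L), need_ca)
    take_co <- utils::head(which(ph$status == 0L), need_co)
    keep <- c(take_ca, take_co)
    if (length(keep)) {
      dos_list[[batch]] <- gm$dosage[keep, , drop = FALSE]
      ph_list[[batch]] <- ph[keep, , drop = FALSE]
    }
    need_ca <- need_ca - length(take_ca)
    need_co <- need_co - length(take_co)
  }
  dos <- do.call(rbind, dos_list)
  ph <- do.call(rbind, ph_list)
  ord <- order(ph$status, decreasing = TRUE)
  dos <- dos[ord, , drop = FALSE]; ph <- ph[ord, , drop = FALSE]
  ph$sample <- sprintf("S%05d", seq_len(nrow(ph)))
  gm <- genotype_matrix(dos, vt, ph$sample)
  rownames(ph) <- NULL
  list(genotypes = gm, phenotype = ph, truth = truth, config = config)
}

#' Simulate discovery GWAS summary statistics
#'
#' Trait A's per-variant marginal truth is the LD-convolved
#' `beta_marginal`; trait B's truth is `rg * A + sqrt(1 - rg^2) * C` with
#' `C` an independently drawn effect vector of equal marginal variance
#' (same causal mask, fresh Normal draws, same APOE effects). Reported
#' per-allele estimates add Normal noise with the standardized-trait
#' large-sample standard error `SE = 1 / sqrt(2 p (1-p) n_gwas)`; p-values
#' are two-sided Wald. `n_gwas = Inf` gives the zero-noise limit (SE floor
#' 0).
#'
#' @param truth `truth_record` from [assign_effects()].
#' @param config a [sim_config()].
#' @param trait `"A"` or `"B"`.
#' @param variants variant metadata matching `truth`.
#' @param seed RNG seed for the measurement noise.
#' @return a [sumstats()] table (effect allele = cohort alt allele).
#' @export
simulate_gwas <- function(truth, config, trait = c("A", "B"),
                          variants, seed = NULL) {
  trait <- match.arg(trait)
  stopifnot(nrow(variants) == length(truth$beta_true))
  p <- truth$maf
  if (any(p <= 0 | p > 0.5)) stop("allele frequencies must lie in (0, 0.5]")
  marg <- truth$beta_marginal
  if (trait == "B") {
    set.seed(child_seed(config$seed, 5L))
    m <- length(truth$beta_true)
    beta_c <- numeric(m)
    poly <- truth$causal_mask & !truth$is_e4 & !truth$is_e2
    if (any(poly) && config$h2 > 0)
      beta_c[poly] <- stats::rnorm(sum(poly), 0, sqrt(config$h2 / sum(poly)))
    beta_c[truth$is_e4] <- truth$beta_true[truth$is_e4]
    beta_c[truth$is_e2] <- truth$beta_true[truth$is_e2]
    marg_c <- numeric(m)
    for (b in unique(truth$block)) {
      idx <- which(truth$block == b)
      if (!any(beta_c[idx] != 0)) next
      R <- config$block_rho^abs(outer(seq_along(idx), seq_along(idx), "-"))
      marg_c[idx] <- drop(R %*% beta_c[idx])
    }
    marg <- config$rg * marg + sqrt(1 - config$rg^2) * marg_c
  }
  n_gwas <- if (trait == "A") config$n_gwas_a else config$n_gwas_b
  sd_g <- sqrt(2 * p * (1 - p))
  beta_per_allele <- marg / sd_g
  se <- if (is.finite(n_gwas)) 1 / sqrt(2 * p * (1 - p) * n_gwas) else rep(0, length(p))
  if (is.null(seed)) seed <- child_seed(config$seed, if (trait == "A") 4L else 6L)
  set.seed(seed)
  beta_hat <- beta_per_allele + stats::rnorm(length(p)) * se
  z <- ifelse(se > 0, beta_hat / se,
              ifelse(beta_hat == 0, 0, sign(beta_hat) * Inf))
  pval <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  sumstats(data.frame(chrom = variants$chrom, pos = variants$pos,
                      id = variants$id, a1 = variants$alt, a2 = variants$ref,
                      beta = beta_hat,
                      se = ifelse(se > 0, se, .Machine$double.eps),
                      p = pval, freq = p,
                      n = rep(if (is.finite(n_gwas)) n_gwas else NA_real_, length(p)),
                      info = variants$info_score,
                      stringsAsFactors = FALSE))
}

#' Annotate microglia-like regions
#'
#' Builds contiguous regions covering approximately `microglia_fraction` of
#' all variants, including a sub-interval of the APOE-like block that
#' deliberately excludes the two epsilon-defining sites — mirroring
#' annotations of microglia-selective regulatory regions, which overlap the
#' APOE region but not the e4 risk variants themselves.
#'
#' @param variants variant metadata from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @param seed RNG seed for region placement.
#' @return a [region_set()].
#' @export
annotate_microglia <- function(variants, config,
                               seed = child_seed(config$seed, 7L)) {
  f <- config$microglia_fraction
  if (f <= 0 || f >= 1) stop("microglia_fraction must be in (0,1)")
  set.seed(seed)
  m_total <- nrow(variants)
  target <- max(1L, round(f * m_total))
  apoe_idx <- which(variants$chrom == APOE_CHROM)
  sub <- apoe_idx[variants$pos[apoe_idx] > APOE_E2_POS]
  chrs <- character(); starts <- numeric(); ends <- numeric()
  n_apoe <- 0L
  if (length(sub) >= 2 && target > 2) {
    take <- sub[seq_len(min(length(sub), max(2L, round(target * 0.1))))]
    chrs <- APOE_CHROM
    starts <- min(variants$pos[take]); ends <- max(variants$pos[take])
    n_apoe <- length(take)
  }
  remaining <- target - n_apoe
  main_idx <- which(variants$chrom != APOE_CHROM)
  if (remaining > 0 && length(main_idx) > 0) {
    run_len <- 10L
    n_runs <- ceiling(remaining / run_len)
    max_start <- length(main_idx) - run_len + 1L
    cand <- sort(sample.int(max_start, min(max_start, n_runs * 3),
                            replace = FALSE))
    used <- rep(FALSE, length(main_idx))
    for (s in cand) {
      if (remaining <= 0) break
      len <- min(run_len, remaining)
      span <- s:(s + len - 1L)
      if (any(used[span])) next
      used[span] <- TRUE
      idx <- main_idx[span]
      chrs <- c(chrs, variants$chrom[idx[1]])
      starts <- c(starts, min(variants$pos[idx]))
      ends <- c(ends, max(variants$pos[idx]))
      remaining <- remaining - len
    }
  }
  rs <- region_set(chrs, starts, ends)
  if (any(in_regions(APOE_CHROM, c(APOE_E4_POS, APOE_E2_POS), rs)))
    stop("internal error: epsilon-defining site inside microglia annotation")
  rs
}
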