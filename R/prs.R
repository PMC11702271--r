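# Clumping + thresholding PRS engine: GWAS-to-cohort harmonization, LD r2,
# greedy clumping, p-value thresholding, region restriction, scoring, and
# ingestion of externally computed per-SNP weights.

#' Clumping + thresholding parameters
#'
#' Defaults follow the standard C+T recipe: one index variant per LD block,
#' removing variants with r2 > 0.1 within a 1000-kb window, scored across
#' the p-value threshold grid 5e-8, 1e-6, 1e-5, 1e-3, 1e-2, 0.05, 0.1, 0.5.
#'
#' @param r2_max LD threshold; variants with r2 strictly greater are
#'   removed from the index variant's window.
#' @param window_kb clumping window half-width in kb.
#' @param pt_grid strictly increasing vector of p-value thresholds.
#' @return list of class `clump_params`.
#' @export
clump_params <- function(r2_max = 0.1, window_kb = 1000,
                         pt_grid = c(5e-8, 1e-6, 1e-5, 1e-3, 1e-2, 0.05, 0.1, 0.5)) {
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must be in (0,1]")
  if (window_kb <= 0) stop("window_kb must be > 0")
  if (length(pt_grid) && any(diff(pt_grid) <= 0))
    stop("pt_grid must be strictly increasing")
  structure(list(r2_max = r2_max, window_kb = window_kb, pt_grid = pt_grid),
            class = "clump_params")
}

#' Harmonize GWAS weights to cohort genotypes
#'
#' Matches on (chrom, pos). When the effect allele equals the cohort's alt
#' allele the effect is kept; when it equals the ref allele the sign is
#' flipped; otherwise the variant is dropped as an allele mismatch.
#' Strand-ambiguous A/T and C/G variants are dropped when
#' `drop_ambiguous = TRUE`. Matched/flipped/dropped counts are logged and
#' attached as provenance.
#'
#' @param ss a [sumstats()] table (or any data.frame with `chrom`, `pos`,
#'   `a1`, `a2`, `beta`; `se`/`p` optional as for weight files).
#' @param gm a [genotype_matrix()].
#' @param drop_ambiguous drop A/T and C/G pairs.
#' @param gwas_id provenance label.
#' @return `aligned_weights`: data.frame with `index` (genotype column),
#'   `id`, `chrom`, `pos`, `beta` (on the cohort alt-allele scale), `se`,
#'   `p`; harmonization counts in attribute `"counts"`.
#' @export
harmonize <- function(ss, gm, drop_ambiguous = TRUE, gwas_id = NA_character_) {
  v <- gm$variants
  key_g <- paste(v$chrom, v$pos, sep = ":")
  key_s <- paste(normalize_chrom(ss$chrom), ss$pos, sep = ":")
  idx <- match(key_s, key_g)
  hit <- !is.na(idx)
  n_ambig <- 0L
  if (drop_ambiguous) {
    pair <- paste0(toupper(ss$a1), toupper(ss$a2))
    ambig <- pair %in% c("AT", "TA", "CG", "GC")
    n_ambig <- sum(ambig & hit)
    hit <- hit & !ambig
  }
  gi <- idx[hit]
  a1 <- toupper(ss$a1[hit]); a2 <- toupper(ss$a2[hit])
  ref <- toupper(v$ref[gi]); alt <- toupper(v$alt[gi])
  keep_as_is <- a1 == alt & a2 == ref
  flip <- a1 == ref & a2 == alt
  ok <- keep_as_is | flip
  n_mismatch <- sum(!ok)
  sel <- which(hit)[ok]
  gi <- gi[ok]
  sign <- ifelse(flip[ok], -1, 1)
  dup <- duplicated(gi)
  if (any(dup)) { sel <- sel[!dup]; gi <- gi[!dup]; sign <- sign[!dup] }
  if (!length(gi))
    stop("no variants could be harmonized (",
         sum(is.na(idx)), " unmatched, ", n_ambig, " ambiguous, ",
         n_mismatch, " allele mismatches)")
  out <- data.frame(index = gi, id = v$id[gi], chrom = v$chrom[gi],
                    pos = v$pos[gi],
                    beta = sign * ss$beta[sel],
                    se = if ("se" %in% names(ss)) ss$se[sel] else NA_real_,
                    p = if ("p" %in% names(ss)) ss$p[sel] else NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  counts <- c(matched = nrow(out), flipped = sum(sign < 0),
              dropped_unmatched = sum(is.na(idx)),
              dropped_ambiguous = n_ambig, dropped_mismatch = n_mismatch)
  message(sprintf("harmonized %d variants (%d flipped, %d unmatched, %d ambiguous, %d mismatched)",
                  counts[1], counts[2], counts[3], counts[4], counts[5]))
  attr(out, "counts") <- counts
  attr(out, "gwas") <- gwas_id
  class(out) <- c("aligned_weights", "data.frame")
  out
}

#' LD r-squared between two variants
#'
#' Squared Pearson correlation of dosages over jointly non-missing samples.
#'
#' @param gm a [genotype_matrix()].
#' @param idx_a,idx_b column indices.
#' @return r2 in \[0,1\].
#' @export
ld_r2 <- function(gm, idx_a, idx_b) {
  a <- gm$dosage[, idx_a]; b <- gm$dosage[, idx_b]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("zero-variance dosage column in r2 computation")
  stats::cor(a, b)^2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unassigned variant with the smallest p-value as an
#' index variant and removes all unassigned variants on the same chromosome
#' within `window_kb` whose r2 with the index exceeds `r2_max` (strict
#' inequality). Ties on p are broken by smaller SE, then lower genomic
#' position, so the result is independent of input row order.
#'
#' @param weights `aligned_weights` from [harmonize()].
#' @param gm the [genotype_matrix()] the weights are aligned to (in-sample
#'   LD).
#' @param params a [clump_params()].
#' @return the index-variant subset of `weights` (row order: by p).
#' @export
clump <- function(weights, gm, params = clump_params()) {
  if (nrow(weights) == 0) return(weights)
  ord <- order(weights$p, weights$se, weights$pos)
  w <- weights[ord, , drop = FALSE]
  n <- nrow(w)
  state <- rep("unassigned", n)
  win <- params$window_kb * 1000
  D <- gm$dosage
  for (i in seq_len(n)) {
    if (state[i] != "unassigned") next
    state[i] <- "index"
    cand <- which(state == "unassigned" & w$chrom == w$chrom[i] &
                    abs(w$pos - w$pos[i]) <= win)
    if (!length(cand)) next
    a <- D[, w$index[i]]
    for (j in cand) {
      b <- D[, w$index[j]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2) next
      sa <- stats::sd(a[ok]); sb <- stats::sd(b[ok])
      r2 <- if (sa == 0 || sb == 0) 0 else stats::cor(a[ok], b[ok])^2
      if (r2 > params$r2_max) state[j] <- "clumped"
    }
  }
  out <- w[state == "index", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- attr(weights, "counts")
  attr(out, "gwas") <- attr(weights, "gwas")
  class(out) <- class(weights)
  out
}

#' P-value thresholding
#'
#' Keeps variants with `p <= pt` (inclusive boundary).
#'
#' @param weights `aligned_weights`.
#' @param pt p-value threshold.
#' @return subset of `weights`.
#' @export
threshold_weights <- function(weights, pt) {
  out <- weights[!is.na(weights$p) & weights$p <= pt, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gwas") <- attr(weights, "gwas")
  class(out) <- class(weights)
  out
}

#' Region restriction
#'
#' Keeps (`mode = "include"`) or drops (`mode = "exclude"`) variants whose
#' position falls inside any region; region bounds are inclusive on both
#' ends.
#'
#' @param weights `aligned_weights` (or any data.frame with `chrom`,
#'   `pos`).
#' @param regions a [region_set()].
#' @param mode `"include"` or `"exclude"`.
#' @return subset of `weights`.
#' @export
restrict_region <- function(weights, regions, mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  inside <- in_regions(weights$chrom, weights$pos, regions)
  keep <- if (mode == "include") inside else !inside
  out <- weights[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gwas") <- attr(weights, "gwas")
  class(out) <- class(weights)
  out
}

#' Compute polygenic scores
#'
#' `score_s = sum_j beta_j * dosage_sj`, with missing dosages replaced by
#' the variant's mean dosage over non-missing samples.
#'
#' @param gm a [genotype_matrix()].
#' @param weights `aligned_weights`.
#' @param method,gwas,region_mode,pt provenance fields for the result.
#' @return a [score_set()].
#' @export
prs_score <- function(gm, weights, method = "C+T",
                      gwas = attr(weights, "gwas") %||% NA_character_,
                      region_mode = "full", pt = NA_real_) {
  if (nrow(weights) == 0) {
    warning("empty weight set: all scores 0")
    sc <- stats::setNames(rep(0, length(gm$samples)), gm$samples)
    return(score_set(sc, method = method, gwas = gwas,
                     region_mode = region_mode, pt = pt, n_snps = 0L))
  }
  if (anyDuplicated(weights$index)) stop("duplicate variant indices in weights")
  D <- gm$dosage[, weights$index, drop = FALSE]
  if (anyNA(D)) {
    cm <- colMeans(D, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    nmiss <- colSums(is.na(D))
    message(sum(nmiss > 0), " variant(s) mean-imputed at scoring")
    for (j in which(nmiss > 0)) D[is.na(D[, j]), j] <- cm[j]
  }
  sc <- drop(D %*% weights$beta)
  names(sc) <- gm$samples
  score_set(sc, method = method, gwas = gwas, region_mode = region_mode,
            pt = pt, n_snps = nrow(weights))
}

# Map a region mode keyword to the weight subset it implies.
apply_region_mode <- function(weights, region_mode, regions = NULL) {
  switch(region_mode,
         full = weights,
         noAPOE = restrict_region(weights, apoe_region(), "exclude"),
         APOEonly = restrict_region(weights, apoe_region(), "include"),
         microglia = {
           if (is.null(regions)) stop("microglia mode requires a region set")
           restrict_region(weights, regions, "include")
         },
         stop("unknown region mode: ", region_mode))
}

#' Clumping + thresholding pipeline
#'
#' harmonize -> optional region restriction -> clump -> for each p-value
#' threshold in the grid: threshold + score.
#'
#' @param ss a [sumstats()] table.
#' @param gm a [genotype_matrix()].
#' @param params a [clump_params()].
#' @param region_mode one of `"full"`, `"noAPOE"`, `"APOEonly"`,
#'   `"microglia"`.
#' @param regions [region_set()] required for `region_mode = "microglia"`.
#' @param gwas_id provenance label.
#' @param drop_ambiguous passed to [harmonize()].
#' @return named list of [score_set()]s, one per threshold (names =
#'   formatted pT).
#' @export
ct_pipeline <- function(ss, gm, params = clump_params(),
                        region_mode = "full", regions = NULL,
                        gwas_id = NA_character_, drop_ambiguous = TRUE) {
  w <- harmonize(ss, gm, drop_ambiguous = drop_ambiguous, gwas_id = gwas_id)
  w <- apply_region_mode(w, region_mode, regions)
  w <- clump(w, gm, params)
  out <- lapply(params$pt_grid, function(pt) {
    prs_score(gm, threshold_weights(w, pt), method = "C+T", gwas = gwas_id,
              region_mode = region_mode, pt = pt)
  })
  names(out) <- format(params$pt_grid, scientific = TRUE, trim = TRUE)
  out
}

#' Score a cohort with an external weight file
#'
#' Harmonizes a per-SNP weight table (no p-values, so no thresholding) and
#' scores — the ingestion surface for weights produced by external PRS
#' methods such as Bayesian continuous-shrinkage or heritability-model
#' tools.
#'
#' @param gm a [genotype_matrix()].
#' @param weightfile data.frame as from [read_weights()].
#' @param method provenance label (e.g. the external method's name).
#' @param region_mode,regions optional region restriction as in
#'   [ct_pipeline()].
#' @param drop_ambiguous passed to [harmonize()].
#' @return a [score_set()].
#' @export
external_scores <- function(gm, weightfile, method = "external",
                            region_mode = "full", regions = NULL,
                            drop_ambiguous = TRUE) {
  req <- c("chrom", "pos", "effect_allele", "weight")
  miss <- setdiff(req, names(weightfile))
  if (length(miss)) stop("weight table missing column(s): ",
                         paste(miss, collapse = ", "))
  ss_like <- data.frame(chrom = weightfile$chrom, pos = weightfile$pos,
                        id = weightfile$id %||% paste0("w", seq_len(nrow(weightfile))),
                        a1 = weightfile$effect_allele,
                        a2 = weightfile$other_allele %||% NA_character_,
                        beta = weightfile$weight, stringsAsFactors = FALSE)
  # When the file lacks the other allele, infer it from the cohort alleles.
  if (all(is.na(ss_like$a2))) {
    v <- gm$variants
    key <- match(paste(normalize_chrom(ss_like$chrom), ss_like$pos, sep = ":"),
                 paste(v$chrom, v$pos, sep = ":"))
    a1 <- toupper(ss_like$a1)
    ss_like$a2 <- ifelse(a1 == toupper(v$alt[key]), v$ref[key], v$alt[key])
  }
  w <- harmonize(ss_like, gm, drop_ambiguous = drop_ambiguous)
  w <- apply_region_mode(w, region_mode, regions)
  prs_score(gm, w, method = method, region_mode = region_mode)
}
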