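# Variant- and sample-level quality control: HWE exact test, threshold
# filters with per-filter attribution, KING-robust kinship, greedy
# relatedness pruning, and genotype PCA for ancestry covariates.

#' QC thresholds
#'
#' Defaults follow common post-imputation practice for case/control PRS
#' cohorts: INFO >= 0.7, MAF >= 0.05, missingness <= 5%, HWE exact p >
#' 1e-6, kinship <= 0.125 (second-degree and closer removed).
#'
#' @param maf_min minimum minor allele frequency.
#' @param miss_max maximum per-variant missingness fraction.
#' @param hwe_p_min minimum HWE exact-test p-value.
#' @param info_min minimum imputation INFO score.
#' @param kinship_max maximum pairwise kinship coefficient.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, miss_max = 0.05, hwe_p_min = 1e-6,
                          info_min = 0.7, kinship_max = 0.125) {
  th <- list(maf_min = maf_min, miss_max = miss_max, hwe_p_min = hwe_p_min,
             info_min = info_min, kinship_max = kinship_max)
  if (any(unlist(th) < 0 | unlist(th) > 1))
    stop("all thresholds must lie in [0,1]")
  class(th) <- "qc_thresholds"
  th
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum of probabilities, over all heterozygote counts with
#' the same parity as the observed one, of tables whose conditional
#' probability does not exceed the observed table's.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1\].
#' @export
#' @examples
#' hwe_exact_test(20, 10, 20)
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each possible heterozygote count
  lp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (2 * n - rare - h) / 2
    lfactorial(n) - lfactorial(h) - lfactorial(hom_r) - lfactorial(hom_c) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Variant-level QC filtering
#'
#' Removes variants failing, in fixed attribution order: INFO (when
#' available), MAF (folded minor-allele frequency from non-missing
#' dosages), missingness, and the HWE exact test on hard-called genotypes.
#' Each removed variant is attributed to the first filter it fails, so
#' reports are deterministic.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param info optional per-variant INFO override (defaults to the
#'   `info_score` metadata column).
#' @return list with `genotypes` (filtered matrix) and `report` (per-filter
#'   removal counts plus retained totals, class `qc_report`).
#' @export
variant_qc <- function(gm, thresholds = qc_thresholds(), info = NULL) {
  d <- gm$dosage
  m <- ncol(d)
  info <- info %||% gm$variants$info_score %||% rep(NA_real_, m)
  nm <- colSums(!is.na(d))
  miss_rate <- 1 - nm / nrow(d)
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[nm == 0] <- 0
  hc <- hard_call(d)
  hwe_p <- vapply(seq_len(m), function(j) {
    g <- hc[, j]
    n0 <- sum(g == 0, na.rm = TRUE); n1 <- sum(g == 1, na.rm = TRUE)
    n2 <- sum(g == 2, na.rm = TRUE)
    if (n0 + n1 + n2 == 0) return(1)
    hwe_exact_test(n0, n1, n2)
  }, numeric(1))

  fail_info <- !is.na(info) & info < thresholds$info_min
  fail_maf <- maf < thresholds$maf_min
  fail_miss <- miss_rate > thresholds$miss_max
  fail_hwe <- hwe_p <= thresholds$hwe_p_min
  # first-failing attribution: INFO, MAF, missingness, HWE
  cause <- rep(NA_character_, m)
  cause[fail_hwe] <- "HWE"
  cause[fail_miss] <- "missingness"
  cause[fail_maf] <- "MAF"
  cause[fail_info] <- "INFO"
  keep <- is.na(cause)
  report <- data.frame(
    filter = c("INFO", "MAF", "missingness", "HWE"),
    removed = c(sum(cause == "INFO", na.rm = TRUE),
                sum(cause == "MAF", na.rm = TRUE),
                sum(cause == "missingness", na.rm = TRUE),
                sum(cause == "HWE", na.rm = TRUE)),
    stringsAsFactors = FALSE)
  attr(report, "n_input") <- m
  attr(report, "n_retained") <- sum(keep)
  class(report) <- c("qc_report", "data.frame")
  if (!any(keep)) warning("no variants retained after QC")
  list(genotypes = subset_gm(gm, j = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("variant QC: %d input, %d retained\n",
              attr(x, "n_input"), attr(x, "n_retained")))
  print.data.frame(x)
  invisible(x)
}

#' KING-robust kinship coefficient for one sample pair
#'
#' `phi = (N_het,het - 2 N_opposite-hom) / (N_het(i) + N_het(j))` over
#' jointly non-missing hard-called sites: about 0.5 for duplicates/MZ
#' twins, 0.25 for first-degree relatives, near 0 for unrelated pairs.
#'
#' @param dos_i,dos_j dosage vectors for the two samples.
#' @return kinship estimate.
#' @export
king_kinship <- function(dos_i, dos_j) {
  gi <- hard_call(dos_i); gj <- hard_call(dos_j)
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) stop("no overlapping non-missing sites")
  gi <- gi[ok]; gj <- gj[ok]
  n_hh <- sum(gi == 1 & gj == 1)
  n_opp <- sum((gi == 0 & gj == 2) | (gi == 2 & gj == 0))
  den <- sum(gi == 1) + sum(gj == 1)
  if (den == 0) stop("kinship undefined: no heterozygous sites in either sample")
  (n_hh - 2 * n_opp) / den
}

#' Pairwise KING-robust kinship matrix
#'
#' Matrix-product formulation of [king_kinship()] over all sample pairs.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric n x n matrix (diagonal `NA`).
#' @export
kinship_matrix <- function(gm) {
  H <- hard_call(gm$dosage)
  valid <- !is.na(H)
  Het <- (H == 1) & valid
  Hom0 <- (H == 0) & valid
  Hom2 <- (H == 2) & valid
  storage.mode(Het) <- "numeric"; storage.mode(Hom0) <- "numeric"
  storage.mode(Hom2) <- "numeric"
  V <- matrix(as.numeric(valid), nrow(valid))
  n_hh <- tcrossprod(Het)
  n_opp <- tcrossprod(Hom0, Hom2) + tcrossprod(Hom2, Hom0)
  het_i <- tcrossprod(Het, V)   # het in i over sites valid in both
  het_j <- tcrossprod(V, Het)
  den <- het_i + het_j
  K <- (n_hh - 2 * n_opp) / den
  K[den == 0] <- NA
  diag(K) <- NA
  dimnames(K) <- list(gm$samples, gm$samples)
  K
}

#' Greedy relatedness pruning
#'
#' While any pair exceeds the kinship threshold, removes the member with
#' the larger number of over-threshold partners (ties: higher missingness,
#' then later sample order). The retained set has no pair above threshold.
#'
#' @param kinship symmetric kinship matrix (as from [kinship_matrix()]).
#' @param threshold kinship cutoff.
#' @param missingness optional per-sample missingness for tie-breaks.
#' @return character vector of retained sample names (or indices when the
#'   matrix is unnamed).
#' @export
prune_related <- function(kinship, threshold = 0.125, missingness = NULL) {
  n <- nrow(kinship)
  stopifnot(ncol(kinship) == n)
  ids <- rownames(kinship) %||% as.character(seq_len(n))
  if (is.null(missingness)) missingness <- rep(0, n)
  alive <- rep(TRUE, n)
  A <- !is.na(kinship) & kinship > threshold
  diag(A) <- FALSE
  repeat {
    deg <- rowSums(A[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    if (length(worst) > 1) {
      worst <- worst[missingness[worst] == max(missingness[worst])]
      worst <- worst[length(worst)] # later sample order
    }
    alive[worst] <- FALSE
    A[worst, ] <- FALSE; A[, worst] <- FALSE
  }
  ids[alive]
}

#' Genotype principal components
#'
#' Variants are mean-imputed, centered at `2*p` and scaled by
#' `sqrt(2p(1-p))` (monomorphic variants skipped); returns the top-k unit
#' eigenvectors of the sample-sample covariance, signs fixed so each PC's
#' largest-magnitude entry is positive.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components (default 8).
#' @return n x k matrix of PC coordinates (columns `PC1..PCk`); eigenvalues
#'   in attribute `"values"`.
#' @export
genotype_pca <- function(gm, k = 8L) {
  X <- gm$dosage
  if (k > min(dim(X))) stop("k exceeds matrix dimensions")
  cm <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- cm[j]
  p <- cm / 2
  poly <- p > 0 & p < 1 & apply(X, 2, stats::sd) > 0
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  Xs <- sweep(sweep(X, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(Xs)
  rank <- sum(sv$d > sv$d[1] * 1e-9)
  if (k > rank) stop("k exceeds the rank of the genotype matrix (", rank, ")")
  U <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  dimnames(U) <- list(gm$samples, paste0("PC", seq_len(k)))
  attr(U, "values") <- (sv$d[seq_len(k)]^2) / (nrow(Xs) - 1)
  U
}
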