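# Core containers. Lightweight S3, matrix + data.frame based.

#' Construct a genotype matrix
#'
#' Container pairing a samples x variants dosage matrix (values in \[0,2\],
#' `NA` = missing) with per-variant metadata.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with at least `chrom`, `pos`, `id`, `ref`,
#'   `alt`; an optional `info_score` column holds per-variant imputation
#'   accuracy in \[0,1\].
#' @param samples character vector of sample IDs (defaults to dosage
#'   rownames).
#' @return object of class `genotype_matrix` with elements `dosage`,
#'   `variants`, `samples`.
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(dosage),
            length(samples) == nrow(dosage))
  rng <- range(dosage, na.rm = TRUE)
  if (ncol(dosage) > 0 && nrow(dosage) > 0 && any(is.finite(rng)) &&
      (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  variants$chrom <- normalize_chrom(variants$chrom)
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  rownames(dosage) <- samples
  colnames(dosage) <- variants$id
  rownames(variants) <- NULL
  structure(list(dosage = dosage, variants = variants,
                 samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d chromosome(s))\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Subset samples (i) and/or variants (j) keeping metadata in step.
subset_gm <- function(gm, i = NULL, j = NULL) {
  d <- gm$dosage
  v <- gm$variants
  s <- gm$samples
  if (!is.null(i)) { d <- d[i, , drop = FALSE]; s <- s[i] }
  if (!is.null(j)) { d <- d[, j, drop = FALSE]; v <- v[j, , drop = FALSE] }
  genotype_matrix(d, v, s)
}

#' Construct a summary-statistics table
#'
#' Validates per-variant GWAS effect estimates. Rows violating the
#' invariants (`se > 0`, `p` in (0,1\], effect and other allele distinct,
#' finite beta) are dropped with a message reporting the count.
#'
#' @param df data.frame with columns `chrom`, `pos`, `id`, `a1` (effect
#'   allele), `a2` (other allele), `beta`, `se`, `p` and optionally `freq`,
#'   `n`, `info`.
#' @return validated data.frame of class `sumstats`.
#' @export
sumstats <- function(df) {
  req <- c("chrom", "pos", "id", "a1", "a2", "beta", "se", "p")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  df$chrom <- normalize_chrom(df$chrom)
  df$a1 <- toupper(df$a1); df$a2 <- toupper(df$a2)
  bad <- !is.finite(df$beta) | !is.finite(df$se) | df$se <= 0 |
    !is.finite(df$p) | df$p <= 0 | df$p > 1 | df$a1 == df$a2
  if (any(bad)) {
    message(sum(bad), " summary-statistics row(s) dropped (invalid se/p/alleles)")
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Construct a region set
#'
#' Genomic intervals, internally 1-based with both bounds inclusive.
#' Overlapping or book-ended input intervals are merged and the result is
#' sorted by chromosome then start.
#'
#' @param chrom,start,end vectors defining the intervals (recycled).
#' @return data.frame of class `region_set` with columns `chrom`, `start`,
#'   `end`.
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  if (length(chrom) == 0) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric())
    class(out) <- c("region_set", "data.frame")
    return(out)
  }
  if (any(end < start)) stop("region end < start")
  gr <- GenomicRanges::GRanges(normalize_chrom(chrom),
                               IRanges::IRanges(start, end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_set", "data.frame")
  out
}

# TRUE for each (chrom, pos) falling inside any region (bounds inclusive).
in_regions <- function(chrom, pos, regions) {
  chrom <- normalize_chrom(chrom)
  hit <- rep(FALSE, length(chrom))
  for (k in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[k] &
                    pos >= regions$start[k] & pos <= regions$end[k])
  }
  hit
}

#' Construct a score set
#'
#' Per-sample polygenic scores with provenance describing how they were
#' produced (method, discovery GWAS, region mode, p-value threshold, number
#' of variants scored).
#'
#' @param score named numeric vector (names = sample IDs) of scores.
#' @param method scoring method label, e.g. `"C+T"` or `"external"`.
#' @param gwas discovery GWAS identifier.
#' @param region_mode one of `"full"`, `"noAPOE"`, `"APOEonly"`, `"microglia"`.
#' @param pt p-value threshold used, or `NA` when not applicable.
#' @param n_snps number of variants contributing to the score.
#' @return data.frame of class `score_set` with columns `sample`, `score`;
#'   provenance is stored in the `"provenance"` attribute.
#' @export
score_set <- function(score, method = "C+T", gwas = NA_character_,
                      region_mode = "full", pt = NA_real_, n_snps = NA_integer_) {
  stopifnot(!is.null(names(score)))
  if (any(!is.finite(score))) stop("scores must be finite")
  if (!is.na(n_snps) && n_snps < 0) stop("n_snps must be >= 0")
  out <- data.frame(sample = names(score), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- list(method = method, gwas = gwas,
                                  region_mode = region_mode, pt = pt,
                                  n_snps = n_snps)
  class(out) <- c("score_set", "data.frame")
  out
}

#' @export
print.score_set <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf("score_set: %d samples | method=%s gwas=%s region=%s pT=%s n_snps=%s\n",
              nrow(x), p$method, p$gwas, p$region_mode,
              format(p$pt), format(p$n_snps)))
  invisible(x)
}
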