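# APOE epsilon-2/epsilon-4 calling from the two defining variants and the
# epsilon-3/epsilon-3 subgroup mask.

#' The APOE region
#'
#' The high-LD interval around APOE conventionally excluded or isolated
#' when constructing polygenic scores: chr19:43,900,000-46,000,000
#' (GRCh38), bounds inclusive.
#'
#' @return a single-interval [region_set()].
#' @export
#' @examples
#' apoe_region()
apoe_region <- function() {
  region_set("19", 43900000, 46000000)
}

#' Call APOE e2/e4 allele counts and diplotypes
#'
#' Counts alternate alleles at the two defining sites: the rs429358-role
#' site defines e4, the rs7412-role site defines e2, ignoring cis/trans
#' phase (the additive "e2 + e4 counts" convention). Dosages are
#' hard-called to the nearest integer; fractional dosages inside the
#' uncertainty guard bands (0.4,0.6) and (1.4,1.6) fail the call and the
#' sample is flagged not callable (logged count). The unphased double
#' heterozygote is consistent with both e2/e4 and e1/e3 and is labelled
#' `"e2e4/ambiguous"` with counts (1,1).
#'
#' @param dos_e4 dosage of the e4-defining alternate allele (rs429358
#'   role), in \[0,2\].
#' @param dos_e2 dosage of the e2-defining alternate allele (rs7412 role).
#' @param samples optional sample IDs.
#' @return data.frame of class `apoe_calls` with columns `sample`, `n_e2`,
#'   `n_e4`, `diplotype`, `ambiguous`, `callable`.
#' @export
#' @examples
#' apoe_call(c(0, 2, 1), c(0, 0, 1))
apoe_call <- function(dos_e4, dos_e2, samples = NULL) {
  stopifnot(length(dos_e4) == length(dos_e2))
  if (any(dos_e4 < 0 | dos_e4 > 2 | dos_e2 < 0 | dos_e2 > 2, na.rm = TRUE))
    stop("dosages must lie in [0,2]")
  n <- length(dos_e4)
  samples <- samples %||% paste0("S", seq_len(n))
  c4 <- hard_call(dos_e4); c2 <- hard_call(dos_e2)
  callable <- !is.na(c4) & !is.na(c2) & (c4 + c2 <= 2)
  n_fail <- sum(!callable)
  if (n_fail > 0)
    message(n_fail, " sample(s) not APOE-callable (ambiguous dosage)")
  dip <- rep(NA_character_, n)
  amb <- rep(FALSE, n)
  lab <- matrix(c("e3e3", "e3e4", "e4e4",
                  "e2e3", "e2e4/ambiguous", NA,
                  "e2e2", NA, NA), nrow = 3, byrow = TRUE)
  ok <- which(callable)
  dip[ok] <- lab[cbind(c2[ok] + 1, c4[ok] + 1)]
  amb[ok] <- c2[ok] == 1 & c4[ok] == 1
  out <- data.frame(sample = samples,
                    n_e2 = ifelse(callable, c2, NA_real_),
                    n_e4 = ifelse(callable, c4, NA_real_),
                    diplotype = dip, ambiguous = amb, callable = callable,
                    stringsAsFactors = FALSE)
  class(out) <- c("apoe_calls", "data.frame")
  out
}

#' Call APOE from a genotype matrix
#'
#' Convenience wrapper locating the two defining sites by variant ID or
#' (chrom, pos) and calling [apoe_call()].
#'
#' @param gm a [genotype_matrix()].
#' @param e4_site,e2_site variant IDs, or `"chrom:pos"` strings, of the
#'   e4- and e2-defining sites.
#' @return an `apoe_calls` data.frame.
#' @export
apoe_call_gm <- function(gm, e4_site = "APOE_e4", e2_site = "APOE_e2") {
  find_site <- function(site) {
    j <- which(gm$variants$id == site)
    if (!length(j)) {
      key <- paste(gm$variants$chrom, gm$variants$pos, sep = ":")
      j <- which(key == site)
    }
    if (length(j) != 1) stop("cannot locate APOE site '", site, "'")
    j
  }
  j4 <- find_site(e4_site); j2 <- find_site(e2_site)
  apoe_call(gm$dosage[, j4], gm$dosage[, j2], samples = gm$samples)
}

#' epsilon-3/epsilon-3 subgroup mask
#'
#' TRUE for callable samples carrying neither e2 nor e4 (the reference
#' diplotype).
#'
#' @param calls an `apoe_calls` data.frame.
#' @return logical vector, one element per sample.
#' @export
e33_mask <- function(calls) {
  calls$callable & calls$n_e2 == 0 & calls$n_e4 == 0
}
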