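# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a chromosome label
#'
#' Strips any `"chr"` prefix and unifies mitochondrial labels (`"M"`,
#' `"chrM"`) to `"MT"`, so that GWAS summary statistics, BED files and VCFs
#' written in different dialects match on the same key.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalize_chrom(c("chr19", "19", "chrM", "MT"))
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[x %in% c("M", "m")] <- "MT"
  x
}

# Hard-call fractional dosages to {0,1,2}; dosages falling in the uncertainty
# guard bands (0.4,0.6) and (1.4,1.6) are left missing (NA) so that tests
# built on hard calls (HWE, kinship, APOE) never use ambiguous imputed values.
hard_call <- function(dosage, guard = TRUE) {
  out <- round(dosage)
  if (guard) {
    amb <- !is.na(dosage) &
      ((dosage > 0.4 & dosage < 0.6) | (dosage > 1.4 & dosage < 1.6))
    out[amb] <- NA_real_
  }
  out[!is.na(out) & (out < 0 | out > 2)] <- NA_real_
  out
}

# Deterministic child-seed derivation: one global seed expands into per-stage
# seeds so that any stage can be re-run in isolation and reproduce itself.
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stage)) %% 2147483647L)
}

# Percent with one decimal, round-half-up (so 62.25 -> 62.3), matching the
# usual cohort-table formatting convention.
pct_1dp <- function(x) floor(x * 10 + 0.5 + 1e-9) / 10

stop_if_not_finite <- function(x, name) {
  if (any(!is.finite(x))) stop("non-finite values in ", name, call. = FALSE)
  invisible(x)
}
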