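# Readers/writers for the on-disk formats the pipeline touches.
# Coordinate convention: 1-based, both bounds inclusive, everywhere
# internally; only the BED boundary converts (0-based half-open on disk).

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via vcfR). Dosage is taken from the `DS` FORMAT
#' field when present, else from the `GT` allele count; missing genotypes
#' (`./.`) give missing dosage. Chromosome labels are normalized. Only
#' biallelic SNPs are supported: a multi-allelic record is a hard error
#' (with its location); indel records are dropped with a message.
#'
#' @param path path to a `.vcf` (optionally gzipped) file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-record VCF
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record at ", fix[which(multi)[1], "CHROM"], ":",
         fix[which(multi)[1], "POS"], " (only biallelic records supported)")
  ref <- fix[, "REF"]
  indel <- nchar(ref) != 1 | nchar(alt) != 1
  keep <- which(!indel)
  if (any(indel)) message(sum(indel), " indel record(s) dropped")
  if (!length(keep)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  cnt <- matrix(NA_real_, nrow(gt), ncol(gt))
  parsed <- gsub("[^01.]", "", gt) # "0/1" -> "01", "./." -> ".."
  cnt[] <- vapply(parsed, function(s) {
    if (is.na(s) || grepl(".", s, fixed = TRUE)) NA_real_
    else sum(strsplit(s, "")[[1]] == "1")
  }, numeric(1))
  fmt <- v@gt[, 1]
  has_ds <- any(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- suppressWarnings(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
    dosage <- ifelse(is.na(ds), cnt, ds)
  } else dosage <- cnt

  info_raw <- vcfR::extract.info(v, element = "INFO")
  info <- suppressWarnings(as.numeric(info_raw))
  variants <- data.frame(chrom = normalize_chrom(fix[, "CHROM"]),
                         pos = as.numeric(fix[, "POS"]),
                         id = fix[, "ID"], ref = ref, alt = alt,
                         info_score = info, stringsAsFactors = FALSE)
  variants <- variants[keep, , drop = FALSE]
  dosage <- t(dosage[keep, , drop = FALSE])
  genotype_matrix(dosage, variants, samples = colnames(gt))
}

#' Write a genotype matrix as VCF
#'
#' Emits a plain-text VCF 4.2 with `GT:DS` per sample (GT hard-called from
#' dosage, DS the dosage itself to 10 significant digits) and the variant
#' `info_score` in the INFO column.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  has_info <- "info_score" %in% names(v) && any(!is.na(v$info_score))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=prsbench",
           if (has_info)
             "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    d <- gm$dosage[, j]
    hc <- round(d)
    cell <- ifelse(is.na(d), "./.:.",
                   paste0(gt_code[pmin(pmax(hc, 0), 2) + 1], ":",
                          sprintf("%.10g", d)))
    info <- if (has_info && !is.na(v$info_score[j]))
      sprintf("INFO=%.6g", v$info_score[j]) else "."
    paste(c(v$chrom[j], format(v$pos[j], scientific = FALSE), v$id[j],
            v$ref[j], v$alt[j], ".", "PASS", info, "GT:DS", cell),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read GWAS summary statistics from a TSV
#'
#' Column names differ between GWAS releases; `column_map` maps the
#' internal names to the file's header. Rows failing the [sumstats()]
#' invariants are dropped with a logged count.
#'
#' @param path tab-separated file with a header row.
#' @param column_map named list mapping internal names (`chrom`, `pos`,
#'   `id`, `a1`, `a2`, `beta`, `se`, `p`, and optionally `freq`, `n`,
#'   `info`) to file column names.
#' @return a [sumstats()] table.
#' @export
read_sumstats <- function(path,
                          column_map = list(chrom = "CHR", pos = "BP",
                                            id = "ID", a1 = "A1", a2 = "A2",
                                            beta = "BETA", se = "SE", p = "P")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("chrom", "pos", "id", "a1", "a2", "beta", "se", "p")
  for (k in req) {
    cm <- column_map[[k]]
    if (is.null(cm) || !cm %in% names(raw))
      stop("required column '", column_map[[k]] %||% k, "' absent from ", path)
  }
  df <- data.frame(chrom = raw[[column_map$chrom]], pos = raw[[column_map$pos]],
                   id = as.character(raw[[column_map$id]]),
                   a1 = raw[[column_map$a1]], a2 = raw[[column_map$a2]],
                   beta = as.numeric(raw[[column_map$beta]]),
                   se = as.numeric(raw[[column_map$se]]),
                   p = as.numeric(raw[[column_map$p]]),
                   stringsAsFactors = FALSE)
  for (k in c("freq", "n", "info")) {
    cm <- column_map[[k]]
    if (!is.null(cm) && cm %in% names(raw)) df[[k]] <- as.numeric(raw[[cm]])
  }
  sumstats(df)
}

#' Write summary statistics
#' @param ss a [sumstats()] table.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- as.data.frame(ss)
  names(out) <- toupper(c("chr", "bp", "id", "a1", "a2", "beta", "se", "p",
                          names(out)[-(1:8)]))
  utils::write.table(format(out, digits = 12, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file as a region set
#'
#' BED's 0-based half-open intervals are converted to the internal 1-based
#' inclusive convention (`start + 1`, `end`), then merged and sorted.
#'
#' @param path BED3+ file.
#' @return a [region_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(region_set())
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0) return(region_set())
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Write a region set as BED
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) == 0) { writeLines(character(), path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write / read a score set (lossless round trip)
#'
#' Scores are written as a two-column TSV with provenance in `#key=value`
#' header comment lines, restored on read.
#'
#' @param scores a [score_set()].
#' @param path file path.
#' @return `path` invisibly (write); a [score_set()] (read).
#' @export
write_scores <- function(scores, path) {
  p <- attr(scores, "provenance")
  hdr <- sprintf("#%s=%s", names(p), vapply(p, function(x) format(x, digits = 15),
                                            character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("sample\tscore", con)
  if (nrow(scores))
    writeLines(sprintf("%s\t%.15g", scores$sample, scores$score), con)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  prov <- stats::setNames(lapply(kv, function(x) x[2]), vapply(kv, `[`, "", 1))
  for (k in c("pt", "n_snps"))
    if (!is.null(prov[[k]])) prov[[k]] <- suppressWarnings(as.numeric(prov[[k]]))
  body <- lines[!grepl("^#", lines)]
  df <- if (length(body) > 1)
    utils::read.delim(text = body, stringsAsFactors = FALSE)
  else data.frame(sample = character(), score = numeric())
  sc <- stats::setNames(as.numeric(df$score), as.character(df$sample))
  ss <- score_set(sc, method = prov$method %||% NA_character_,
                  gwas = prov$gwas %||% NA_character_,
                  region_mode = prov$region_mode %||% NA_character_,
                  pt = prov$pt %||% NA_real_,
                  n_snps = as.integer(prov$n_snps %||% NA_integer_))
  ss
}

#' Write / read a per-SNP weight file
#'
#' Tab-separated with columns `chrom pos id effect_allele weight` — the
#' ingestion surface for externally computed PRS weights (e.g. Bayesian
#' shrinkage methods). Unknown allele codes or non-finite weights are
#' errors.
#'
#' @param weights data.frame with those columns.
#' @param path file path.
#' @return `path` invisibly (write); validated data.frame (read).
#' @export
write_weights <- function(weights, path) {
  stopifnot(all(c("chrom", "pos", "id", "effect_allele", "weight") %in%
                  names(weights)))
  utils::write.table(format(weights, digits = 15, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "id", "effect_allele", "weight")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("weight file missing column(s): ",
                         paste(miss, collapse = ", "))
  df$chrom <- normalize_chrom(df$chrom)
  df$effect_allele <- toupper(df$effect_allele)
  if (!all(df$effect_allele %in% c("A", "C", "G", "T")))
    stop("unknown allele code in weight file")
  df$weight <- as.numeric(df$weight)
  stop_if_not_finite(df$weight, "weights")
  df
}

#' Write / read a covariate table
#'
#' TSV with a `sample` column plus phenotype/covariate columns (status,
#' age, sex, PCs...).
#'
#' @param covariates data.frame with a `sample` column.
#' @param path file path.
#' @return `path` invisibly (write); data.frame (read).
#' @export
write_covariates <- function(covariates, path) {
  stopifnot("sample" %in% names(covariates))
  utils::write.table(format(covariates, digits = 15, scientific = NA,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) stop("covariate table lacks 'sample' column")
  df$sample <- as.character(df$sample)
  df
}
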