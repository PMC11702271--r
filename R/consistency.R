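# Individual-level agreement between score sets: Pearson correlation and
# overlap of the low- and high-risk quintile tails.

#' Pearson correlation between two score vectors
#'
#' @param a,b numeric vectors over the same samples (length >= 3, both
#'   non-constant).
#' @return correlation in \[-1,1\].
#' @export
pearson_cor <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors differ in length")
  if (length(a) < 3) stop("at least 3 samples required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant score vector")
  stats::cor(a, b)
}

#' Assign risk quintiles
#'
#' Ranks samples by ascending score (ties broken by sample ID, stable) and
#' assigns five consecutive groups: group of 0-based rank r is
#' `floor(r*5/N) + 1`, so group sizes differ by at most one. The nominal
#' per-quintile size is reported as `round(N/5)` (round-half-to-even),
#' e.g. 114 for N = 568 and 153 for N = 766.
#'
#' @param scores numeric vector.
#' @param samples sample IDs (default names of `scores`).
#' @return list of class `quintile_assignment` with `group` (named integer
#'   vector in 1..5), `sizes`, `nominal_size`.
#' @export
quintile_assign <- function(scores, samples = names(scores)) {
  n <- length(scores)
  if (n < 5) stop("at least 5 samples required for quintiles")
  samples <- samples %||% as.character(seq_len(n))
  ord <- order(scores, samples)
  group <- integer(n)
  group[ord] <- floor((seq_len(n) - 1) * 5 / n) + 1L
  names(group) <- samples
  structure(list(group = group,
                 sizes = as.integer(table(factor(group, levels = 1:5))),
                 nominal_size = round(n / 5)),
            class = "quintile_assignment")
}

#' Quintile tail overlap
#'
#' Percentage of the first assignment's tail members that fall in the same
#' tail of the second assignment:
#' `100 * |tail_a intersect tail_b| / |tail_a|`. Symmetric whenever both
#' tails have equal size.
#'
#' @param assign_a,assign_b [quintile_assign()] results over the same
#'   sample universe.
#' @param tail `1` (low-risk) or `5` (high-risk).
#' @return overlap percentage in \[0,100\].
#' @export
tail_overlap <- function(assign_a, assign_b, tail = c(1, 5)) {
  tail <- match.arg(as.character(tail[1]), c("1", "5"))
  tail <- as.integer(tail)
  if (!setequal(names(assign_a$group), names(assign_b$group)))
    stop("assignments cover different samples")
  ta <- names(assign_a$group)[assign_a$group == tail]
  tb <- names(assign_b$group)[assign_b$group == tail]
  if (!length(ta)) stop("empty tail")
  100 * length(intersect(ta, tb)) / length(ta)
}

#' Pairwise score-set consistency matrix
#'
#' For every requested pair of score sets over the same samples: Pearson
#' correlation and the overlap of the 1st and 5th risk quintiles.
#'
#' @param scoresets named list of [score_set()]s (or named numeric vectors).
#' @param pairs `"all"` for all unordered pairs, or a 2-column character
#'   matrix of score-set names.
#' @return data.frame with columns `set_a`, `set_b`, `pearson_r`,
#'   `overlap_q1_pct`, `overlap_q5_pct`.
#' @export
consistency_matrix <- function(scoresets, pairs = "all") {
  as_vec <- function(s) {
    if (inherits(s, "score_set") || is.data.frame(s))
      stats::setNames(s$score, s$sample)
    else s
  }
  vecs <- lapply(scoresets, as_vec)
  nms <- names(vecs)
  if (length(vecs) >= 2) {
    ref <- sort(names(vecs[[1]]))
    for (v in vecs[-1])
      if (!identical(sort(names(v)), ref)) stop("score sets cover different samples")
  }
  if (identical(pairs, "all")) {
    if (length(vecs) < 2)
      return(data.frame(set_a = character(), set_b = character(),
                        pearson_r = numeric(), overlap_q1_pct = numeric(),
                        overlap_q5_pct = numeric()))
    pairs <- t(utils::combn(nms, 2))
  }
  qa <- lapply(vecs, quintile_assign)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    va <- vecs[[a]]; vb <- vecs[[b]][names(va)]
    data.frame(set_a = a, set_b = b,
               pearson_r = pearson_cor(va, vb),
               overlap_q1_pct = tail_overlap(qa[[a]], qa[[b]], 1),
               overlap_q5_pct = tail_overlap(qa[[a]], qa[[b]], 5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
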