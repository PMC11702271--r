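# Covariate adjustment, the five logistic risk models, AUC evaluation,
# optimal-threshold selection, multiple-testing accounting and descriptive
# cohort tables.

MODEL_SPECS <- list(
  M1 = c("APOE_e2_count", "APOE_e4_count"),
  M2 = "PRS_APOEonly",
  M3 = "PRS_full",
  M4 = "PRS_noAPOE",
  M5 = c("PRS_noAPOE", "APOE_e2_count", "APOE_e4_count"))

#' Covariate adjustment and standardization
#'
#' Residualizes a predictor on \[intercept, age, sex, PCs\] by ordinary
#' least squares, then z-scores the residuals (mean 0, SD 1 with
#' denominator n-1). This is applied to every genetic score and to the
#' APOE allele counts before they enter a risk model.
#'
#' @param values numeric vector, one value per sample.
#' @param covariates data.frame of covariates (e.g. `age`, `sex`,
#'   `PC1..PCk`); no missing values allowed.
#' @return standardized residual vector.
#' @export
adjust_standardize <- function(values, covariates) {
  stopifnot(length(values) == nrow(covariates))
  if (anyNA(values) || anyNA(covariates)) stop("missing values not allowed")
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  res <- stats::lm.fit(X, values)$residuals
  s <- stats::sd(res)
  if (!is.finite(s) || s < 1e-12) stop("zero residual variance after adjustment")
  (res - mean(res)) / s
}

#' Logistic regression fit
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence tolerance 1e-10, at most 100 iterations), standard
#' errors from the inverse observed information, two-sided Wald p-values.
#' Rank-deficient design matrices and (quasi-)perfect separation, detected
#' via divergence of the coefficients, are distinct errors.
#'
#' @param y binary outcome (0/1), both classes present.
#' @param X predictor matrix (without intercept; one is added).
#' @return list of class `logistic_fit` with `coef` (data.frame: `term`,
#'   `beta`, `se`, `p`), `linear_predictor`, `converged`.
#' @export
logistic_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  Xd <- cbind("(Intercept)" = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("rank-deficient predictor matrix")
  fit <- suppressWarnings(
    stats::glm.fit(Xd, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  beta <- fit$coefficients
  if (any(abs(beta) > 15))
    stop("perfect separation suspected (diverging coefficients)")
  w <- fit$weights
  XtWX <- crossprod(Xd * sqrt(w))
  V <- chol2inv(chol(XtWX))
  se <- sqrt(diag(V))
  z <- beta / se
  coef <- data.frame(term = colnames(Xd), beta = unname(beta),
                     se = unname(se), p = unname(2 * stats::pnorm(-abs(z))),
                     stringsAsFactors = FALSE)
  structure(list(coef = coef,
                 linear_predictor = drop(Xd %*% beta),
                 converged = fit$converged),
            class = "logistic_fit")
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney with midranks for ties): the probability
#' that a random case outranks a random control, ties counted one half.
#'
#' @param scores numeric predictor.
#' @param y binary outcome (0/1 or logical; 1 = case).
#' @return AUC in \[0,1\].
#' @export
#' @examples
#' auc(c(2, 3, 1, 2.5), c(1, 1, 0, 0))
auc <- function(scores, y) {
  y <- as.numeric(y) != 0 # accepts 0/1 or logical
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the five risk models
#'
#' Builds the model predictor set from the supplied score sets and APOE
#' calls, adjusts and standardizes every predictor (including the APOE
#' allele counts) per [adjust_standardize()], fits each requested model by
#' logistic regression and evaluates AUC on the fitted linear predictor.
#' The analysis set is restricted to APOE-callable samples with complete
#' covariates, so every model is evaluated on the same samples.
#'
#' Models: M1 = APOE(e2+e4) counts; M2 = PRS of the APOE region only;
#' M3 = whole-genome PRS; M4 = PRS excluding the APOE region;
#' M5 = M4's PRS plus the APOE counts.
#'
#' @param prs_scores named list with elements `PRS_full`, `PRS_noAPOE`,
#'   `PRS_APOEonly` ([score_set()]s); only those needed by `which` are
#'   required.
#' @param apoe_calls an `apoe_calls` data.frame (needed for M1/M5).
#' @param phenotype data.frame with `sample` and `status` (1 = case).
#' @param covariates data.frame with `sample` plus covariate columns.
#' @param which character vector of model IDs (subset of M1..M5).
#' @param gwas,method,region_mode,pt provenance carried into the results.
#' @return list of `model_result` objects (see [as.data.frame.model_result()]).
#' @export
run_models <- function(prs_scores, apoe_calls, phenotype, covariates,
                       which = paste0("M", 1:5), gwas = NA_character_,
                       method = NA_character_, region_mode = NA_character_,
                       pt = NA_real_) {
  stopifnot(all(which %in% names(MODEL_SPECS)))
  ids <- phenotype$sample
  cov <- covariates[match(ids, covariates$sample), , drop = FALSE]
  keep <- stats::complete.cases(cov[setdiff(names(cov), "sample")])
  if (!is.null(apoe_calls)) {
    ac <- apoe_calls[match(ids, apoe_calls$sample), , drop = FALSE]
    keep <- keep & ac$callable
  }
  ids <- ids[keep]
  y <- phenotype$status[keep]
  covm <- cov[keep, setdiff(names(cov), c("sample", "status")), drop = FALSE]

  needed <- unique(unlist(MODEL_SPECS[which]))
  predictors <- list()
  for (nm in intersect(c("PRS_full", "PRS_noAPOE", "PRS_APOEonly"), needed)) {
    if (!is.null(prs_scores[[nm]])) {
      s <- prs_scores[[nm]]
      predictors[[nm]] <- s$score[match(ids, s$sample)]
    }
  }
  if (!is.null(apoe_calls) &&
      any(c("APOE_e2_count", "APOE_e4_count") %in% needed)) {
    ac <- apoe_calls[match(ids, apoe_calls$sample), , drop = FALSE]
    predictors$APOE_e2_count <- ac$n_e2
    predictors$APOE_e4_count <- ac$n_e4
  }
  adj <- lapply(predictors, adjust_standardize, covariates = covm)

  lapply(which, function(mid) {
    need <- MODEL_SPECS[[mid]]
    miss <- setdiff(need, names(adj))
    if (length(miss)) stop(mid, " requires predictor(s): ",
                           paste(miss, collapse = ", "))
    X <- do.call(cbind, adj[need])
    colnames(X) <- need
    fit <- logistic_fit(y, X)
    structure(list(model = mid,
                   coef = fit$coef[-1, , drop = FALSE], # drop intercept row
                   auc = auc(fit$linear_predictor, y),
                   n_cases = sum(y == 1), n_controls = sum(y == 0),
                   gwas = gwas, method = method, region_mode = region_mode,
                   pt = pt),
              class = "model_result")
  })
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("%s: AUC = %.3f (%d cases / %d controls)\n",
              x$model, x$auc, x$n_cases, x$n_controls))
  print.data.frame(x$coef, row.names = FALSE)
  invisible(x)
}

#' Flatten model results to a data.frame
#'
#' One row per predictor with the model-level AUC, counts and provenance
#' repeated, plus the Bonferroni significance flag at the supplied
#' per-test alpha.
#'
#' @param x a `model_result` or list of them.
#' @param alpha per-test significance threshold (e.g. from
#'   [bonferroni_threshold()]).
#' @param ... unused.
#' @return data.frame with columns model, gwas, method, region_mode, pt,
#'   predictor, beta, se, p, auc, n_cases, n_controls, significant.
#' @export
as.data.frame.model_result <- function(x, alpha = 0.05, ...) {
  data.frame(model = x$model, gwas = x$gwas, method = x$method,
             region_mode = x$region_mode, pt = x$pt,
             predictor = x$coef$term, beta = x$coef$beta, se = x$coef$se,
             p = x$coef$p, auc = x$auc, n_cases = x$n_cases,
             n_controls = x$n_controls,
             significant = x$coef$p <= alpha,
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.model_result
#' @param results list of `model_result` objects.
#' @export
model_results_table <- function(results, alpha = 0.05) {
  do.call(rbind, lapply(results, as.data.frame.model_result, alpha = alpha))
}

#' Select the optimal p-value threshold
#'
#' Picks the threshold with maximal AUC under the criterion model; ties go
#' to the smallest threshold.
#'
#' @param pt numeric vector of thresholds evaluated.
#' @param auc_values AUC at each threshold.
#' @return the selected threshold.
#' @export
select_pt <- function(pt, auc_values) {
  stopifnot(length(pt) == length(auc_values), length(pt) >= 1)
  best <- which(auc_values == max(auc_values))
  min(pt[best])
}

#' Multiple-testing grid and Bonferroni threshold
#'
#' The benchmark's full test grid: 5 main models x 2 summary statistics x
#' 4 PRS approaches, plus 1 model for the e3e3 subgroup and 4 models for
#' the microglia scores over the same 2 x 4 combinations — 80 tests, so
#' alpha 0.05 gives a per-test threshold of 0.000625.
#'
#' @param n_models_main,n_sumstats,n_approaches,n_models_e33,n_models_microglia
#'   grid dimensions.
#' @param alpha family-wise alpha.
#' @return list of class `test_grid` with the fields plus `total`.
#' @export
test_grid <- function(n_models_main = 5L, n_sumstats = 2L, n_approaches = 4L,
                      n_models_e33 = 1L, n_models_microglia = 4L,
                      alpha = 0.05) {
  total <- n_models_main * n_sumstats * n_approaches +
    n_models_e33 * n_sumstats * n_approaches +
    n_models_microglia * n_sumstats * n_approaches
  structure(list(n_models_main = n_models_main, n_sumstats = n_sumstats,
                 n_approaches = n_approaches, n_models_e33 = n_models_e33,
                 n_models_microglia = n_models_microglia, alpha = alpha,
                 total = total),
            class = "test_grid")
}

#' @rdname test_grid
#' @param grid a `test_grid`.
#' @return per-test alpha (`alpha / total`).
#' @export
bonferroni_threshold <- function(grid = test_grid()) {
  if (grid$total == 0) stop("test grid is empty")
  grid$alpha / grid$total
}

#' M3 in the epsilon-3/epsilon-3 subgroup
#'
#' Restricts the cohort to e3e3 carriers (no e2, no e4), re-fits the
#' covariate adjustment within the subgroup, and fits the whole-genome PRS
#' model (M3).
#'
#' @param scoreset the whole-genome PRS [score_set()].
#' @param apoe_calls an `apoe_calls` data.frame.
#' @param phenotype,covariates as in [run_models()].
#' @param ... provenance passed to [run_models()].
#' @return a single `model_result`.
#' @export
e33_subgroup <- function(scoreset, apoe_calls, phenotype, covariates, ...) {
  mask <- e33_mask(apoe_calls)
  sub_ids <- apoe_calls$sample[mask]
  ph <- phenotype[phenotype$sample %in% sub_ids, , drop = FALSE]
  if (length(unique(ph$status)) < 2)
    stop("e3e3 subgroup contains a single class")
  res <- run_models(list(PRS_full = scoreset),
                    apoe_calls[mask, , drop = FALSE],
                    ph, covariates[covariates$sample %in% sub_ids, , drop = FALSE],
                    which = "M3", ...)
  res[[1]]
}

#' Descriptive cohort table
#'
#' Per-group mean (SD) with a two-sample test p-value for continuous
#' variables (t-test or Mann-Whitney U), and N (%) with a chi-squared test
#' (no continuity correction) for categorical variables. Percentages are
#' formatted to one decimal, round-half-up.
#'
#' @param phenotype data.frame with `sample`, `status`, `age`, `sex`.
#' @param apoe_calls optional `apoe_calls` for carrier rows.
#' @param continuous_test `"t"` or `"wilcox"`.
#' @return data.frame with columns `characteristic`, `cases`, `controls`,
#'   `p_value`.
#' @export
cohort_table <- function(phenotype, apoe_calls = NULL,
                         continuous_test = c("t", "wilcox")) {
  continuous_test <- match.arg(continuous_test)
  ca <- phenotype$status == 1; co <- phenotype$status == 0
  if (!any(ca) || !any(co)) stop("both cases and controls required")
  fmt_cont <- function(x, g) sprintf("%.1f (%.1f)", mean(x[g]), stats::sd(x[g]))
  fmt_cat <- function(x, g) sprintf("%d (%.1f)", sum(x[g]), pct_1dp(100 * mean(x[g])))
  p_cont <- function(x) {
    if (continuous_test == "t") stats::t.test(x[ca], x[co])$p.value
    else stats::wilcox.test(x[ca], x[co])$p.value
  }
  p_cat <- function(x) {
    tab <- table(factor(x, levels = c(0, 1)), phenotype$status)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  rows <- list(
    data.frame(characteristic = "Age: Mean (SD)",
               cases = fmt_cont(phenotype$age, ca),
               controls = fmt_cont(phenotype$age, co),
               p_value = p_cont(phenotype$age)),
    data.frame(characteristic = "Sex: Female N (%)",
               cases = fmt_cat(phenotype$sex, ca),
               controls = fmt_cat(phenotype$sex, co),
               p_value = p_cat(phenotype$sex)))
  if (!is.null(apoe_calls)) {
    acm <- apoe_calls[match(phenotype$sample, apoe_calls$sample), ]
    ok <- acm$callable
    for (def in list(c("APOE-e2 carrier: N (%)", "n_e2"),
                     c("APOE-e4 carrier: N (%)", "n_e4"))) {
      x <- as.integer(acm[[def[2]]] > 0)
      rows[[length(rows) + 1]] <-
        data.frame(characteristic = def[1],
                   cases = fmt_cat(x[ok], ca[ok]),
                   controls = fmt_cat(x[ok], co[ok]),
                   p_value = suppressWarnings(stats::chisq.test(
                     table(x[ok], phenotype$status[ok]), correct = FALSE)$p.value))
    }
    e33 <- as.integer(e33_mask(acm))
    rows[[length(rows) + 1]] <-
      data.frame(characteristic = "APOE-e3e3 carrier: N (%)",
                 cases = fmt_cat(e33[ok], ca[ok]),
                 controls = fmt_cat(e33[ok], co[ok]),
                 p_value = suppressWarnings(stats::chisq.test(
                   table(e33[ok], phenotype$status[ok]), correct = FALSE)$p.value))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
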