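# Covariate-adjusted logistic association of scores and single SNPs,
# information for discrimination, the HLA summary risk score, the case-only
# interaction test, and the control-group score-correlation check.

#' Information for discrimination of a unit-SD score
#'
#' For a score scaled to SD 1 with standardized log odds ratio `b`, the
#' expected information for discrimination is `b^2 / 2` natural log units.
#'
#' @param log_or Standardized log odds ratio.
#' @return Information in natural log units.
#' @export
info_discrimination <- function(log_or) log_or^2 / 2

#' Logistic association of a standardized score with disease
#'
#' Maximum-likelihood logistic regression of the binary outcome on the score
#' plus covariates; reports the Wald test for the score term and the
#' information for discrimination. Non-convergence or separation flags the
#' result (`converged = FALSE`) rather than returning a silent estimate.
#'
#' @param score Numeric per-individual score (unit SD for interpretable log
#'   odds ratios).
#' @param outcome Binary 0/1 vector.
#' @param covariates Optional data frame / matrix of covariates.
#' @param score_id Label carried into the result.
#' @return One-row tibble: `score_id`, `log_or`, `se`, `pvalue`,
#'   `info_discrimination`, `n_used`, `converged`.
#' @export
fit_score_association <- function(score, outcome, covariates = NULL,
                                  score_id = "score") {
  stopifnot(length(score) == length(outcome),
            all(outcome %in% c(0, 1)))
  dat <- data.frame(.y = outcome, .s = score)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(outcome))
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  aliased <- is.na(stats::coef(fit))
  if (!(".s" %in% rownames(cf)) || isTRUE(aliased[".s"])) {
    return(tibble::tibble(score_id = score_id, log_or = NA_real_,
                          se = NA_real_, pvalue = NA_real_,
                          info_discrimination = NA_real_,
                          n_used = nrow(dat), converged = FALSE))
  }
  ok <- fit$converged && !any(aliased) &&
    abs(stats::coef(fit)[".s"]) < 15 && cf[".s", "Std. Error"] < 15
  b <- unname(cf[".s", "Estimate"])
  se <- unname(cf[".s", "Std. Error"])
  tibble::tibble(
    score_id = score_id,
    log_or = b, se = se,
    pvalue = max(unname(cf[".s", "Pr(>|z|)"]), .Machine$double.xmin),
    info_discrimination = info_discrimination(b),
    n_used = nrow(dat),
    converged = ok)
}

#' Test a set of scores for disease association
#'
#' Runs [fit_score_association()] for each column of a `trans_scores` or
#' `cis_scores` object (or a plain score matrix) and joins the score
#' metadata, including the effective eQTL count for genome-wide trans-scores.
#'
#' @param scores A `trans_scores`, `cis_scores`, or numeric matrix with
#'   column names.
#' @param samples Tibble with a `status` column and the covariate columns.
#' @param covariates Character vector of covariate column names (default the
#'   first three genotypic principal components).
#' @return A tibble of class `trans_assoc`, one row per score.
#' @export
associate_scores <- function(scores, samples,
                             covariates = c("PC1", "PC2", "PC3")) {
  values <- if (is.matrix(scores)) scores else scores$values
  stopifnot(nrow(values) == nrow(samples), "status" %in% names(samples))
  covs <- if (length(covariates) > 0) samples[, covariates, drop = FALSE]
          else NULL
  res <- purrr::map_dfr(colnames(values), function(id) {
    fit_score_association(values[, id], samples$status, covs, score_id = id)
  })
  if (inherits(scores, "trans_scores") && nrow(res) > 0) {
    res <- dplyr::left_join(
      res, dplyr::rename(scores$meta, score_id = "target_id"),
      by = "score_id")
  } else if (inherits(scores, "cis_scores") && nrow(res) > 0) {
    res <- dplyr::left_join(
      res, dplyr::rename(scores$meta, score_id = "clump_id"),
      by = "score_id")
  }
  class(res) <- c("trans_assoc", class(res))
  res
}

#' Per-SNP logistic GWAS
#'
#' Tests each study SNP for disease association in a logistic model adjusted
#' for the given covariates (default sex, age, and three genotypic principal
#' components). SNPs with minor allele frequency below `maf_min` or
#' monomorphic are excluded.
#'
#' @param study Study `geno_matrix` (samples tibble must hold `status` and
#'   the covariates).
#' @param covariates Covariate column names.
#' @param maf_min Minimum minor-allele frequency (default 0.005).
#' @return Tibble: variant_id, chrom, pos, log_or, se, pvalue, maf.
#' @export
per_snp_association <- function(study,
                                covariates = c("sex", "age", "PC1", "PC2",
                                               "PC3"),
                                maf_min = 0.005) {
  X <- study$dosages
  samples <- study$samples
  freq <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- which(maf >= maf_min & maf > 0)
  covs <- samples[, covariates, drop = FALSE]
  purrr::map_dfr(keep, function(j) {
    r <- fit_score_association(X[, j], samples$status, covs,
                               score_id = colnames(X)[j])
    tibble::tibble(variant_id = r$score_id,
                   log_or = r$log_or, se = r$se, pvalue = r$pvalue,
                   maf = maf[j], converged = r$converged)
  }) |>
    dplyr::left_join(
      dplyr::select(study$variants, "variant_id", "chrom", "pos"),
      by = "variant_id") |>
    dplyr::relocate("variant_id", "chrom", "pos")
}

#' HLA summary risk score from tag SNPs
#'
#' Derives eight variables from five tag SNPs -- the five dosages, two
#' class-II haplotype-pair terms from the first two tags (a
#' double-heterozygote indicator and the dosage product), and a class-I
#' composite (carrying at least one copy of each class-I tag) -- then
#' learns their
#' weights by multiple logistic regression on the case-control outcome. The
#' derivation emulates published class I / class II tagging schemes with
#' synthetic stand-in variables. Constant or aliased variables are dropped
#' with a warning and the model refitted.
#'
#' @param tag_genotypes Numeric matrix or data frame with 5 dosage columns.
#' @param outcome Binary 0/1 vector.
#' @return A list of class `hla_risk_score`: `weights` (named coefficients),
#'   `values` (fitted per-individual linear predictor), `derived` (the
#'   variable matrix), `dropped`.
#' @export
build_hla_score <- function(tag_genotypes, outcome) {
  tg <- as.matrix(tag_genotypes)
  stopifnot(ncol(tg) == 5, nrow(tg) == length(outcome))
  d <- as.data.frame(tg)
  names(d) <- paste0("tag", 1:5)
  d$classII_het <- as.numeric(d$tag1 == 1 & d$tag2 == 1)
  d$classII_int <- d$tag1 * d$tag2
  d$classI_comp <- as.numeric(d$tag3 >= 1 & d$tag4 >= 1 & d$tag5 >= 1)
  stopifnot(ncol(d) == 8)

  constant <- vapply(d, function(v) stats::var(v) == 0, logical(1))
  dropped <- names(d)[constant]
  if (any(constant)) {
    warning("dropping constant derived variable(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    d <- d[, !constant, drop = FALSE]
  }
  fit <- suppressWarnings(
    stats::glm(outcome ~ ., data = cbind(outcome = outcome, d),
               family = stats::binomial()))
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased) > 0) {
    warning("dropping collinear derived variable(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
    d <- d[, setdiff(names(d), aliased), drop = FALSE]
    dropped <- c(dropped, aliased)
    fit <- suppressWarnings(
      stats::glm(outcome ~ ., data = cbind(outcome = outcome, d),
                 family = stats::binomial()))
  }
  structure(list(weights = stats::coef(fit),
                 values = unname(fit$linear.predictors),
                 derived = d, dropped = dropped, fit = fit),
            class = "hla_risk_score")
}

#' Case-only interaction test between a trans-score and the HLA risk score
#'
#' Linear regression of the trans-score on the HLA risk score among cases
#' only. Under a multiplicative (no-interaction) disease model with scores
#' independent in the population, the slope is null; a non-zero slope
#' indicates departure from multiplicative joint effects.
#'
#' @param trans_score,hla_score Per-individual numeric vectors (full sample).
#' @param case_mask Logical vector marking cases.
#' @param covariates Optional covariate data frame (full sample).
#' @return One-row tibble: `slope`, `se`, `pvalue`, `n_cases`.
#' @export
case_only_interaction <- function(trans_score, hla_score, case_mask,
                                  covariates = NULL) {
  stopifnot(length(trans_score) == length(case_mask),
            length(hla_score) == length(case_mask))
  n_cases <- sum(case_mask)
  if (n_cases < 30) {
    stop("case-only test needs at least 30 cases, got ", n_cases,
         call. = FALSE)
  }
  y <- trans_score[case_mask]
  x <- hla_score[case_mask]
  if (stats::var(y) == 0 || stats::var(x) == 0) {
    stop("score constant among cases; case-only test undefined",
         call. = FALSE)
  }
  dat <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) {
    dat <- cbind(dat, as.data.frame(covariates)[case_mask, , drop = FALSE])
  }
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  tibble::tibble(slope = unname(cf[".x", "Estimate"]),
                 se = unname(cf[".x", "Std. Error"]),
                 pvalue = unname(cf[".x", "Pr(>|t|)"]),
                 n_cases = n_cases)
}

#' Pairwise score correlations in the control group
#'
#' Pearson correlations of score columns among controls; pairs with squared
#' correlation above `r2_high` are flagged as highly correlated (a
#' specificity check: near-duplicate scores carry the same signal). Constant
#' scores are excluded with a warning.
#'
#' @param scores Numeric matrix (individuals x scores) or a `trans_scores`
#'   object.
#' @param control_mask Logical vector marking controls.
#' @param config A [pipeline_config()] (supplies `r2_high`).
#' @return Tibble of pairs: `score_a`, `score_b`, `r`, `r2`, `flagged`;
#'   the full correlation matrix is attached as attribute `"R"`.
#' @export
score_correlation_matrix <- function(scores, control_mask,
                                     config = pipeline_config()) {
  values <- if (is.matrix(scores)) scores else scores$values
  stopifnot(ncol(values) >= 2, length(control_mask) == nrow(values))
  V <- values[control_mask, , drop = FALSE]
  constant <- apply(V, 2, function(v) stats::var(v) == 0)
  if (any(constant)) {
    warning("excluding constant score(s) among controls: ",
            paste(colnames(V)[constant], collapse = ", "), call. = FALSE)
    V <- V[, !constant, drop = FALSE]
  }
  R <- stats::cor(V)
  idx <- which(upper.tri(R, diag = FALSE) | diag(ncol(R)) == 1, arr.ind = TRUE)
  out <- tibble::tibble(
    score_a = colnames(R)[idx[, 1]],
    score_b = colnames(R)[idx[, 2]],
    r = R[idx],
    r2 = R[idx]^2) |>
    dplyr::mutate(flagged = .data$r2 > config$r2_high) |>
    dplyr::arrange(.data$score_a, .data$score_b)
  attr(out, "R") <- R
  out
}
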