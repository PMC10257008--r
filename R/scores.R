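# Per-individual locus scores, genome-wide trans aggregation with Hill-number
# effective eQTL counts, and standardized cis scores.

#' Per-individual locus score
#'
#' Dot product of each individual's dosages with the LD-adjusted weights.
#' Missing dosages are mean-imputed per variant; weight variants absent from
#' the study genotypes are ignored (the locus is skipped when none remain).
#'
#' @param study A `geno_matrix` of study genotypes (harmonized to the
#'   summary-statistic effect alleles).
#' @param weights A `locus_weights` tibble from [adjust_weights()].
#' @return Numeric vector of per-individual scores, or `NULL` with a warning
#'   when no weight variant is present.
#' @export
locus_score <- function(study, weights) {
  present <- weights$variant_id %in% colnames(study$dosages)
  if (!any(present)) {
    warning("no weight variant present in study genotypes; locus skipped",
            call. = FALSE)
    return(NULL)
  }
  if (!all(present)) {
    warning("dropping ", sum(!present),
            " weight variant(s) absent from study genotypes", call. = FALSE)
  }
  X <- study$dosages[, weights$variant_id[present], drop = FALSE]
  X <- apply(X, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  })
  as.numeric(X %*% weights$weight[present])
}

#' Build locus scores for every clump
#'
#' For each clump: extract the reference-panel LD matrix, LD-adjust the
#' member betas, and score the study individuals. Loci that fail (no
#' matchable variants, singular LD) are skipped with a warning and recorded.
#'
#' @param study Study `geno_matrix`.
#' @param clumps Classified clump tibble.
#' @param panel Reference `geno_matrix`.
#' @param config A [pipeline_config()] (supplies `ridge_lambda`).
#' @return A list of class `locus_scores`: `values` (individuals x loci
#'   matrix of raw scores), `info` (tibble with clump metadata and the raw
#'   score variance), `skipped` (clump ids).
#' @export
build_locus_scores <- function(study, clumps, panel,
                               config = pipeline_config()) {
  vals <- list()
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(clumps))) {
    cl <- clumps[i, ]
    mem <- cl$members[[1]]
    ld <- withCallingHandlers(
      compute_ld(panel, mem$variant_id),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(ld)) {
      skipped <- c(skipped, cl$clump_id)
      next
    }
    mem <- mem[match(ld$variant_ids, mem$variant_id), , drop = FALSE]
    w <- adjust_weights(mem$beta, ld, ridge_lambda = config$ridge_lambda,
                        pvalues = mem$pvalue)
    if (is.null(w)) {
      skipped <- c(skipped, cl$clump_id)
      next
    }
    v <- locus_score(study, w)
    if (is.null(v)) {
      skipped <- c(skipped, cl$clump_id)
      next
    }
    vals[[cl$clump_id]] <- v
    rows[[cl$clump_id]] <- dplyr::mutate(
      dplyr::select(cl, -"members"),
      variance = stats::var(v))
  }
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped), " locus/loci: ",
            paste(utils::head(skipped, 5), collapse = ", "), call. = FALSE)
  }
  values <- if (length(vals) > 0) do.call(cbind, vals) else
    matrix(numeric(0), nrow(study$dosages), 0)
  structure(list(values = values, info = dplyr::bind_rows(rows),
                 skipped = skipped),
            class = "locus_scores")
}

#' @export
print.locus_scores <- function(x, ...) {
  cat("<locus_scores> ", ncol(x$values), " loci x ", nrow(x$values),
      " individuals\n", sep = "")
  invisible(x)
}

#' Hill-number effective count of contributing eQTLs
#'
#' The diversity index of the locus-score variances: with shares
#' `p_i = v_i / sum(v)`, the effective number is `2^(-sum(p_i log2 p_i))`
#' (base-2 exponential of the Shannon entropy, with `0 log 0 = 0`). Equal
#' variances of K loci give exactly K; a single dominant locus gives 1.
#'
#' @param variances Non-negative numeric vector with at least one positive
#'   entry.
#' @return The effective number, in `[1, length(variances)]`.
#' @export
hill_diversity <- function(variances) {
  if (length(variances) == 0 || any(variances < 0) || all(variances == 0) ||
      any(!is.finite(variances))) {
    stop("`variances` must be non-negative, finite, with at least one ",
         "positive entry", call. = FALSE)
  }
  p <- variances / sum(variances)
  p <- p[p > 0]
  2^(-sum(p * log2(p)))
}

#' Aggregate trans locus scores into genome-wide trans-scores
#'
#' For each target: sum the per-individual values of its trans-class loci
#' outside the HLA region, scale the sum to unit standard deviation, and
#' compute the Hill-number effective eQTL count from the raw locus-score
#' variances. Targets with no contributing locus, or a zero-variance sum,
#' yield no score (recorded in `dropped`).
#'
#' @param locus_scores A `locus_scores` object (classified loci).
#' @param config A [pipeline_config()].
#' @return A list of class `trans_scores`: `values` (individuals x targets,
#'   SD 1 columns), `meta` (target_id, n_loci, effective_n, contributing
#'   clump ids and variances as list-columns), `dropped`.
#' @export
aggregate_trans <- function(locus_scores, config = pipeline_config()) {
  info <- locus_scores$info
  keep <- info$locus_class == "trans" &
    !hla_overlap(info$chrom, info$start, info$end, config)
  info <- info[keep, , drop = FALSE]
  targets <- unique(info$target_id)
  vals <- list()
  meta <- list()
  dropped <- character(0)
  for (tg in targets) {
    sub <- info[info$target_id == tg, , drop = FALSE]
    v <- rowSums(locus_scores$values[, sub$clump_id, drop = FALSE])
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      dropped <- c(dropped, tg)
      next
    }
    vals[[tg]] <- v / s
    meta[[tg]] <- tibble::tibble(
      target_id = tg, n_loci = nrow(sub),
      effective_n = hill_diversity(sub$variance),
      contributing = list(sub$clump_id),
      variances = list(sub$variance))
  }
  values <- if (length(vals) > 0) do.call(cbind, vals) else
    matrix(numeric(0), nrow(locus_scores$values), 0)
  out <- structure(list(values = values, meta = dplyr::bind_rows(meta),
                        dropped = dropped),
                   class = "trans_scores")
  assert_trans_scores(out)
  out
}

# invariant checks run on every aggregation
assert_trans_scores <- function(x) {
  if (ncol(x$values) == 0) return(invisible(x))
  sds <- apply(x$values, 2, stats::sd)
  stopifnot(all(abs(sds - 1) < 1e-9))
  stopifnot(all(x$meta$effective_n >= 1 - 1e-9),
            all(x$meta$effective_n <= x$meta$n_loci + 1e-9))
  invisible(x)
}

#' @export
print.trans_scores <- function(x, ...) {
  cat("<trans_scores> ", ncol(x$values), " genome-wide trans-scores x ",
      nrow(x$values), " individuals\n", sep = "")
  invisible(x)
}

#' Standardized cis locus scores
#'
#' Each cis-class locus score scaled to unit SD, ready for association
#' testing. Cis-x loci are reported in the metadata (`locus_class` column)
#' but are standardized separately and never enter genome-wide trans
#' aggregation.
#'
#' @param locus_scores A `locus_scores` object.
#' @param include_cisx Also emit standardized cis-x scores (flagged by
#'   class)? Default TRUE.
#' @return A list of class `cis_scores`: `values` (individuals x loci, SD 1),
#'   `meta` (clump_id, target_id, locus_class, variance).
#' @export
build_cis_scores <- function(locus_scores, include_cisx = TRUE) {
  classes <- if (include_cisx) c("cis", "cis-x") else "cis"
  info <- locus_scores$info
  keep <- which(info$locus_class %in% classes & info$variance > 0)
  ids <- info$clump_id[keep]
  values <- locus_scores$values[, ids, drop = FALSE]
  if (length(ids) > 0) values <- scale(values)
  structure(list(values = values,
                 meta = info[keep, c("clump_id", "target_id", "locus_class",
                                     "chrom", "start", "end", "variance")]),
            class = "cis_scores")
}
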