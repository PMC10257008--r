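# broom-style accessors.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy association results
#'
#' @param x A `trans_assoc` tibble.
#' @param ... Unused.
#' @return A plain tibble with one row per score: estimate (`log_or`),
#'   `se`, `pvalue`, `info_discrimination`, and `effective_n` when present.
#' @method tidy trans_assoc
#' @export
tidy.trans_assoc <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select(dplyr::any_of(c("score_id", "log_or", "se", "pvalue",
                                  "info_discrimination", "effective_n",
                                  "n_loci", "n_used", "converged")))
}

#' Summarise association results
#'
#' @param x A `trans_assoc` tibble.
#' @param p_core Threshold counted as strongly associated.
#' @param ... Unused.
#' @return One-row tibble: number of scores, number associated below
#'   `p_core`, median effective eQTL count, total information.
#' @method glance trans_assoc
#' @export
glance.trans_assoc <- function(x, p_core = 1e-9, ...) {
  tibble::tibble(
    n_scores = nrow(x),
    n_associated = sum(x$pvalue < p_core, na.rm = TRUE),
    median_effective_n = if ("effective_n" %in% names(x))
      stats::median(x$effective_n, na.rm = TRUE) else NA_real_,
    total_information = sum(x$info_discrimination, na.rm = TRUE))
}

#' Tidy a pipeline run
#'
#' @param x A `trans_pipeline`.
#' @param ... Unused.
#' @return The core-gene call table.
#' @method tidy trans_pipeline
#' @export
tidy.trans_pipeline <- function(x, ...) x$core_calls

#' Summarise a pipeline run
#'
#' @param x A `trans_pipeline`.
#' @param ... Unused.
#' @return One-row tibble of stage counts.
#' @method glance trans_pipeline
#' @export
glance.trans_pipeline <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$architecture$genes),
    n_core_true = sum(x$architecture$genes$is_core),
    n_clumps = nrow(x$clumps),
    n_trans_scores = ncol(x$trans_scores$values),
    n_cis_scores = sum(x$cis_scores$meta$locus_class == "cis"),
    n_core_calls = nrow(x$core_calls),
    n_regions_flagged = sum(x$regions$flagged %in% TRUE))
}

#' Tidy an HLA risk score
#'
#' @param x An `hla_risk_score`.
#' @param ... Unused.
#' @return Tibble of learned weights per derived variable.
#' @method tidy hla_risk_score
#' @export
tidy.hla_risk_score <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                 se = cf[, "Std. Error"], pvalue = cf[, "Pr(>|z|)"])
}
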