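# LD reference handling: per-clump genotype correlation matrices and
# conversion of marginal summary-stat betas into LD-adjusted joint weights.

#' Reference-panel LD matrix for a set of variants
#'
#' Pearson correlations of dosage vectors in the reference panel. Variants
#' absent from the panel are dropped with a warning; missing dosage entries
#' are mean-imputed per variant before the correlation is taken.
#'
#' @param panel A `geno_matrix` reference panel.
#' @param variant_ids Character vector (or a clump row, whose `members`
#'   supply the ids).
#' @return A list of class `ld_matrix`: `variant_ids`, `R`, `n_reference`;
#'   or `NULL` (with a warning) when no variant matches the panel.
#' @export
compute_ld <- function(panel, variant_ids) {
  if (is.data.frame(variant_ids)) {
    variant_ids <- variant_ids$members[[1]]$variant_id
  }
  present <- variant_ids %in% colnames(panel$dosages)
  if (!all(present)) {
    warning("dropping ", sum(!present),
            " variant(s) missing from the reference panel", call. = FALSE)
  }
  ids <- variant_ids[present]
  if (length(ids) == 0) {
    warning("no clump variant matchable in the reference panel; locus skipped",
            call. = FALSE)
    return(NULL)
  }
  X <- panel$dosages[, ids, drop = FALSE]
  X <- apply(X, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  })
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  structure(list(variant_ids = ids, R = R,
                 n_reference = nrow(panel$dosages)),
            class = "ld_matrix")
}

#' LD-adjust marginal effect estimates into joint weights
#'
#' Premultiplies the vector of marginal betas by the inverse of the
#' reference-panel correlation matrix, approximating the coefficients of a
#' joint multiple regression on all clump SNPs. Near-duplicate variants
#' (|r| > 0.99) are pruned first, keeping the member with the smaller
#' p-value; a small ridge (`ridge_lambda`, settable to 0 for plain
#' inversion) stabilises near-singular matrices.
#'
#' @param marginal_betas Named or ordered numeric vector matching `ld`.
#' @param ld An `ld_matrix`.
#' @param ridge_lambda Ridge added to the diagonal (default 1e-3).
#' @param pvalues Optional p-values used to break pruning ties.
#' @return A tibble of class `locus_weights`: `variant_id`, `marginal_beta`,
#'   `weight`; attributes `ridge_lambda` and `pruned` (dropped ids). `NULL`
#'   with a warning when the system is numerically singular after pruning
#'   and ridging.
#' @export
adjust_weights <- function(marginal_betas, ld, ridge_lambda = 1e-3,
                           pvalues = NULL) {
  stopifnot(inherits(ld, "ld_matrix"),
            length(marginal_betas) == length(ld$variant_ids))
  ids <- ld$variant_ids
  R <- ld$R
  b <- as.numeric(marginal_betas)
  p <- if (is.null(pvalues)) rep(NA_real_, length(b)) else pvalues

  keep <- rep(TRUE, length(ids))
  if (length(ids) > 1) {
    ord <- order(ifelse(is.na(p), 1, p))  # best first
    for (i in ord) {
      if (!keep[i]) next
      dup <- which(keep & abs(R[i, ]) > 0.99)
      dup <- setdiff(dup, i)
      keep[dup] <- FALSE
    }
  }
  pruned <- ids[!keep]
  Rk <- R[keep, keep, drop = FALSE]
  bk <- b[keep]
  A <- Rk + diag(ridge_lambda, nrow(Rk))
  w <- tryCatch(solve(A, bk), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    warning("LD matrix numerically singular after pruning and ridging; ",
            "locus skipped", call. = FALSE)
    return(NULL)
  }
  out <- tibble::tibble(variant_id = ids[keep], marginal_beta = bk,
                        weight = as.numeric(w))
  class(out) <- c("locus_weights", class(out))
  attr(out, "ridge_lambda") <- ridge_lambda
  attr(out, "pruned") <- pruned
  out
}
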