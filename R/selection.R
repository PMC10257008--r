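# Core-gene selection, master-regulator region calling, and report tables.

#' Select putative core genes
#'
#' Applies the two selection criteria to genome-wide trans-score
#' associations: (1) effective number of eQTLs strictly greater than
#' `diversity_min` and association p below `p_core`; (2) membership of the
#' monogenic gene list and p below `p_core_monogenic`. A gene meeting both is
#' recorded once, under the diversity criterion. Cis-score evidence is
#' attached when the target's best cis association falls below
#' `cis_report_p`. Associated scores lacking an effective-eQTL count, or
#' flagged non-converged fits, are excluded with a warning.
#'
#' @param associations A `trans_assoc` tibble from [associate_scores()] on
#'   genome-wide trans-scores (must carry `effective_n`).
#' @param monogenic_genes Character vector of gene ids with a known monogenic
#'   disease cause (may be empty).
#' @param config A [pipeline_config()].
#' @param cis_associations Optional `trans_assoc` tibble for cis scores
#'   (its meta must carry `target_id`).
#' @return Tibble of calls: `target_id`, `criterion` ("diversity" or
#'   "monogenic"), `log_or`, `pvalue`, `effective_n`, `cis_log_or`,
#'   `cis_pvalue`.
#' @export
select_core_genes <- function(associations, monogenic_genes = character(0),
                              config = pipeline_config(),
                              cis_associations = NULL) {
  a <- tibble::as_tibble(associations)
  if (!"effective_n" %in% names(a)) {
    stop("associations must carry `effective_n` (genome-wide trans-scores)",
         call. = FALSE)
  }
  bad <- is.na(a$effective_n) | !a$converged
  if (any(bad)) {
    warning("excluding ", sum(bad), " score(s) without usable diversity or ",
            "converged fit: ",
            paste(utils::head(a$score_id[bad], 5), collapse = ", "),
            call. = FALSE)
    a <- a[!bad, , drop = FALSE]
  }
  crit1 <- a$effective_n > config$diversity_min & a$pvalue < config$p_core
  crit2 <- a$score_id %in% monogenic_genes &
    a$pvalue < config$p_core_monogenic
  calls <- a[crit1 | crit2, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(tibble::tibble(target_id = character(0), criterion = character(0),
                          log_or = numeric(0), pvalue = numeric(0),
                          effective_n = numeric(0), cis_log_or = numeric(0),
                          cis_pvalue = numeric(0)))
  }
  calls <- calls |>
    dplyr::mutate(criterion = ifelse(crit1[crit1 | crit2],
                                     "diversity", "monogenic")) |>
    dplyr::transmute(target_id = .data$score_id, criterion = .data$criterion,
                     log_or = .data$log_or, pvalue = .data$pvalue,
                     effective_n = .data$effective_n)
  calls$cis_log_or <- NA_real_
  calls$cis_pvalue <- NA_real_
  if (!is.null(cis_associations) && nrow(cis_associations) > 0 &&
      "target_id" %in% names(cis_associations)) {
    best_cis <- cis_associations |>
      dplyr::filter(.data$locus_class == "cis") |>
      dplyr::group_by(.data$target_id) |>
      dplyr::slice_min(.data$pvalue, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    m <- match(calls$target_id, best_cis$target_id)
    pv <- ifelse(is.na(m), NA_real_, best_cis$pvalue[m])
    has <- !is.na(pv) & pv < config$cis_report_p
    calls$cis_log_or[has] <- best_cis$log_or[m[has]]
    calls$cis_pvalue[has] <- pv[has]
  }
  dplyr::arrange(calls, .data$criterion, .data$pvalue)
}

# union-merge of possibly-overlapping closed intervals per chromosome
merge_intervals <- function(x) {
  x |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      run_end <- cummax(d$end)
      new_region <- c(TRUE, d$start[-1] > run_end[-nrow(d)])
      d$region <- cumsum(new_region)
      d
    }) |>
    dplyr::ungroup()
}

#' Identify master-regulator regions
#'
#' Pools the clumps contributing to every trans-score associated with disease
#' below `p_core`, merges overlapping clump intervals into regions, and
#' counts the distinct scores each region feeds. Regions feeding strictly
#' more than `master_regulator_min_scores` scores are flagged as putative
#' master regulators.
#'
#' @param associations `trans_assoc` tibble for genome-wide trans-scores
#'   (with `contributing` list-column from the score metadata).
#' @param clumps The classified clump tibble the scores were built from.
#' @param config A [pipeline_config()].
#' @param known_hits Optional known-hit region table for labeling.
#' @return Tibble of regions: `chrom`, `start`, `end`, `n_scores`,
#'   `score_ids`, `flagged`, and annotation columns when `known_hits` given.
#' @export
identify_master_regulators <- function(associations, clumps,
                                       config = pipeline_config(),
                                       known_hits = NULL) {
  a <- tibble::as_tibble(associations)
  qualifying <- a[!is.na(a$pvalue) & a$pvalue < config$p_core &
                    a$converged, , drop = FALSE]
  if (nrow(qualifying) == 0 || !"contributing" %in% names(qualifying)) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), n_scores = integer(0),
                          score_ids = character(0), flagged = logical(0)))
  }
  pool <- qualifying |>
    dplyr::select("score_id", "contributing") |>
    tidyr::unnest_longer("contributing", values_to = "clump_id") |>
    dplyr::left_join(
      dplyr::select(clumps, "clump_id", "chrom", "start", "end"),
      by = "clump_id")
  regions <- merge_intervals(pool) |>
    dplyr::group_by(.data$chrom, .data$region) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_scores = dplyr::n_distinct(.data$score_id),
                     score_ids = paste(sort(unique(.data$score_id)),
                                       collapse = ","),
                     .groups = "drop") |>
    dplyr::select(-"region") |>
    dplyr::mutate(flagged = .data$n_scores > config$master_regulator_min_scores) |>
    dplyr::arrange(dplyr::desc(.data$n_scores), .data$chrom, .data$start)
  if (!is.null(known_hits)) {
    regions <- annotate_known_regions(regions, known_hits, config)
  }
  regions
}

#' Write deterministic report tables
#'
#' Emits the core-gene call table and the master-regulator region table as
#' TSV (sorted by criterion then p-value, and by descending score count),
#' plus a JSON run-metadata sidecar with the configuration and the counts at
#' each stage, so every call's provenance chain (score, clumps, SNPs) can be
#' reconstructed.
#'
#' @param dir Output directory (created if needed).
#' @param core_calls Output of [select_core_genes()].
#' @param regions Output of [identify_master_regulators()].
#' @param associations Full association table.
#' @param config The [pipeline_config()] used.
#' @param seed Optional seed recorded in the metadata.
#' @return Named character vector of file paths, invisibly.
#' @export
report_tables <- function(dir, core_calls, regions, associations,
                          config = pipeline_config(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    core_genes = file.path(dir, "core_genes.tsv"),
    master_regulators = file.path(dir, "master_regulators.tsv"),
    associations = file.path(dir, "associations.tsv"),
    metadata = file.path(dir, "run_metadata.json"))
  readr::write_tsv(dplyr::arrange(core_calls, .data$criterion, .data$pvalue),
                   paths[["core_genes"]], progress = FALSE)
  readr::write_tsv(regions, paths[["master_regulators"]], progress = FALSE)
  assoc_flat <- dplyr::select(
    tibble::as_tibble(associations),
    -dplyr::any_of(c("contributing", "variances", "members")))
  readr::write_tsv(assoc_flat, paths[["associations"]], progress = FALSE)
  meta <- list(
    package_version = as.character(utils::packageVersion("transcores")),
    seed = seed,
    config = unclass(config),
    counts = list(core_calls = nrow(core_calls),
                  master_regions = nrow(regions),
                  flagged_regions = sum(regions$flagged %in% TRUE),
                  associations = nrow(assoc_flat)))
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
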