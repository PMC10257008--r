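# End-to-end pipeline on synthetic data: simulate, clump, score, associate,
# select.

#' Run the full aggregated trans-score pipeline on synthetic data
#'
#' Generates the architecture, reference panel, expression-GWAS cohort and
#' case-control study; computes summary statistics; clumps, classifies and
#' harmonizes them; builds LD-adjusted locus scores, genome-wide trans-scores
#' (HLA excluded) and cis scores; tests all scores for disease association;
#' and applies the core-gene and master-regulator selection criteria.
#'
#' @param config A [sim_config()].
#' @param pconfig A [pipeline_config()].
#' @param covariates Covariate columns for the score associations.
#' @return A list of class `trans_pipeline` with elements `architecture`,
#'   `panel`, `study`, `sumstats`, `clumps`, `locus_scores`, `trans_scores`,
#'   `cis_scores`, `trans_assoc`, `cis_assoc`, `core_calls`, `regions`,
#'   `config`, `pconfig`.
#' @export
run_trans_pipeline <- function(config = sim_config(),
                               pconfig = pipeline_config(),
                               covariates = c("PC1", "PC2", "PC3")) {
  arch <- simulate_architecture(config)
  panel <- simulate_reference_panel(config)
  gwas <- simulate_gwas_cohort(config)
  study <- simulate_study(config, arch)
  ss <- compute_summary_stats(gwas, arch, config)
  ss <- suppressWarnings(harmonize_to_panel(ss, panel))

  annotation <- dplyr::select(arch$genes, target_id = "gene_id", "chrom",
                              "site_start", "site_end")
  clumps <- filter_and_clump(ss, pconfig) |>
    classify_clumps(annotation, pconfig)

  ls <- suppressWarnings(build_locus_scores(study, clumps, panel, pconfig))
  ts <- aggregate_trans(ls, pconfig)
  cs <- build_cis_scores(ls)

  ta <- associate_scores(ts, study$samples, covariates)
  ca <- if (ncol(cs$values) > 0) {
    associate_scores(cs, study$samples, covariates)
  } else NULL

  monogenic <- arch$genes$gene_id[arch$genes$monogenic]
  calls <- suppressWarnings(
    select_core_genes(ta, monogenic, pconfig, cis_associations = ca))
  regions <- identify_master_regulators(ta, clumps, pconfig)

  structure(list(architecture = arch, panel = panel, study = study,
                 sumstats = ss, clumps = clumps, locus_scores = ls,
                 trans_scores = ts, cis_scores = cs, trans_assoc = ta,
                 cis_assoc = ca, core_calls = calls, regions = regions,
                 config = config, pconfig = pconfig),
            class = "trans_pipeline")
}

#' @export
print.trans_pipeline <- function(x, ...) {
  cat("<trans_pipeline>\n",
      "  genes: ", nrow(x$architecture$genes),
      " (", sum(x$architecture$genes$is_core), " core)\n",
      "  clumps: ", nrow(x$clumps), "\n",
      "  genome-wide trans-scores: ", ncol(x$trans_scores$values), "\n",
      "  core-gene calls: ", nrow(x$core_calls), "\n",
      "  master-regulator regions flagged: ",
      sum(x$regions$flagged %in% TRUE), "\n", sep = "")
  invisible(x)
}

#' Extract the five synthetic HLA tag-SNP dosages
#'
#' Convenience accessor returning five SNPs from the synthetic HLA blocks
#' (two "class II" tags from the first block, three "class I" tags from the
#' remaining HLA SNPs) for [build_hla_score()].
#'
#' @param study A `geno_matrix` built on a config with HLA blocks.
#' @param architecture The matching `true_architecture`.
#' @return Matrix of 5 dosage columns.
#' @export
hla_tag_dosages <- function(study, architecture) {
  v <- architecture$variants
  hla_ids <- v$variant_id[v$is_hla]
  if (length(hla_ids) < 5) {
    stop("need at least 5 HLA-block SNPs for tagging; have ",
         length(hla_ids), call. = FALSE)
  }
  blocks <- v$block[v$is_hla]
  first_block <- hla_ids[blocks == blocks[1]]
  classII <- first_block[c(1, min(length(first_block), 4))]
  classI <- setdiff(hla_ids, classII)[1:3]
  study$dosages[, c(classII, classI)]
}
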