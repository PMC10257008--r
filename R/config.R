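#' Simulation configuration
#'
#' Bundles every tunable parameter of the synthetic-data generator. Defaults
#' describe the package's reference study conditions: an expression GWAS of
#' 20,000 individuals, a case-control study of 1,000 cases and 1,000 controls,
#' a block-structured genome of 46 LD blocks on synthetic chromosomes, twelve
#' expression targets of which three are disease-mediating core genes, and a
#' designated two-block "HLA" region carrying both direct liability effects
#' and pleiotropic trans effects (the confounding that motivates HLA
#' exclusion).
#'
#' Core genes draw trans effects from mostly exclusive pleiotropic blocks
#' plus two master-regulator blocks shared by all core genes; bystander genes
#' draw their trans blocks from the same core pool (which makes them
#' confounded with the disease signal); two bystanders are "HLA-driven",
#' receiving strong trans effects from the HLA blocks and only a few weak
#' ones elsewhere.
#'
#' @param seed Integer seed; identical config + seed gives bit-identical output.
#' @param n_reference Reference-panel size used for LD estimation.
#' @param n_cases,n_controls Case-control study quotas (ascertained exactly).
#' @param n_gwas Expression-GWAS cohort size (disjoint from the study).
#' @param n_blocks Number of LD blocks.
#' @param snps_per_block SNPs per block (1 kb spacing within a block).
#' @param block_correlation Within-block pairwise genotype correlation in
#'   `[0, 1)`.
#' @param maf_range Length-2 numeric, allele-frequency bounds in (0, 0.5].
#'   One frequency per block is drawn uniformly from this range.
#' @param n_genes Number of expression targets.
#' @param n_core_genes Number of targets whose expression feeds disease
#'   liability.
#' @param trans_blocks_per_gene Number of unlinked pleiotropic blocks giving
#'   trans effects to each gene (at least 6 when core genes are present, so
#'   the "effective eQTLs > 5" criterion is attainable).
#' @param trans_heritability_fraction Fraction of each gene's genetic variance
#'   of expression contributed by trans variants (default 0.7, the share
#'   typically attributed to trans-acting variation in blood).
#' @param cis_effect_sd,trans_effect_sd Effect-size scales for cis and trans
#'   eQTL effects (per effect-allele copy, expression units).
#' @param liability_effect_sd Log-odds effect of one SD of a core gene's
#'   genetic expression value on disease liability.
#' @param expression_h2 Total heritability of expression (sets residual noise).
#' @param tested_snp_fraction Fraction of all SNPs reported in the trans
#'   summary statistics, emulating a platform that tests only a restricted
#'   trait-associated SNP set in trans.
#' @param hla_block_ids Integer block indices designated as the synthetic HLA
#'   region (placed at chr6 25-34 Mb); may be empty.
#' @param base_rate Baseline disease probability entering the liability
#'   intercept.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_reference = 1000L,
                       n_cases = 1000L,
                       n_controls = 1000L,
                       n_gwas = 20000L,
                       n_blocks = 46L,
                       snps_per_block = 5L,
                       block_correlation = 0.5,
                       maf_range = c(0.1, 0.5),
                       n_genes = 12L,
                       n_core_genes = 3L,
                       trans_blocks_per_gene = 12L,
                       trans_heritability_fraction = 0.7,
                       cis_effect_sd = 0.5,
                       trans_effect_sd = 0.25,
                       liability_effect_sd = 0.6,
                       expression_h2 = 0.3,
                       tested_snp_fraction = 0.6,
                       hla_block_ids = c(45L, 46L),
                       base_rate = 0.1) {
  cfg <- list(
    seed = as.integer(seed),
    n_reference = as.integer(n_reference),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    n_gwas = as.integer(n_gwas),
    n_blocks = as.integer(n_blocks),
    snps_per_block = as.integer(snps_per_block),
    block_correlation = block_correlation,
    maf_range = as.numeric(maf_range),
    n_genes = as.integer(n_genes),
    n_core_genes = as.integer(n_core_genes),
    trans_blocks_per_gene = as.integer(trans_blocks_per_gene),
    trans_heritability_fraction = trans_heritability_fraction,
    cis_effect_sd = cis_effect_sd,
    trans_effect_sd = trans_effect_sd,
    liability_effect_sd = liability_effect_sd,
    expression_h2 = expression_h2,
    tested_snp_fraction = tested_snp_fraction,
    hla_block_ids = as.integer(hla_block_ids),
    base_rate = base_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  counts <- c("n_reference", "n_cases", "n_controls", "n_gwas", "n_blocks",
              "snps_per_block", "n_genes")
  for (nm in counts) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop("`", nm, "` must be a positive count, got ", cfg[[nm]],
           call. = FALSE)
    }
  }
  if (cfg$n_core_genes < 0 || cfg$n_core_genes > cfg$n_genes) {
    stop("`n_core_genes` must lie in [0, n_genes]", call. = FALSE)
  }
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1) {
    stop("`block_correlation` must lie in [0, 1)", call. = FALSE)
  }
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || diff(cfg$maf_range) < 0) {
    stop("`maf_range` must be increasing bounds in (0, 0.5]", call. = FALSE)
  }
  if (cfg$trans_heritability_fraction < 0 ||
      cfg$trans_heritability_fraction > 1) {
    stop("`trans_heritability_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$expression_h2 <= 0 || cfg$expression_h2 >= 1) {
    stop("`expression_h2` must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$n_core_genes > 0 && cfg$trans_blocks_per_gene < 6) {
    stop("core genes require `trans_blocks_per_gene` >= 6 so that recovery ",
         "under the effective-eQTL criterion is possible", call. = FALSE)
  }
  if (any(cfg$hla_block_ids > cfg$n_blocks) || any(cfg$hla_block_ids < 1)) {
    stop("`hla_block_ids` out of range", call. = FALSE)
  }
  n_free <- cfg$n_blocks - length(cfg$hla_block_ids)
  if (n_free < cfg$trans_blocks_per_gene + cfg$n_genes) {
    stop("need at least trans_blocks_per_gene + n_genes non-HLA blocks; ",
         "have ", n_free, call. = FALSE)
  }
  if (cfg$base_rate <= 0 || cfg$base_rate >= 1) {
    stop("`base_rate` must lie in (0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Pipeline thresholds
#'
#' All fixed thresholds of the score pipeline in one place. Defaults are the
#' values used throughout the analysis: retain summary-stat records at
#' p < 1e-5, require a clump lead SNP at p < 1e-6, separate clumps by at
#' least 1 Mb, call a locus cis within 50 kb of the transcription site,
#' cis-x between 50 kb and 5 Mb, trans beyond 5 Mb or on another chromosome,
#' exclude the HLA region (chr6 25-34 Mb) from trans aggregation, annotate
#' known hits within 200 kb, and select core genes at p < 1e-9 with effective
#' eQTL count > 5 or p < 1e-6 for monogenic genes.
#'
#' @param p_retain Retention p-value threshold for summary-stat records.
#' @param p_lead Lead-SNP p-value threshold a clump must contain.
#' @param clump_gap_bp Minimum separation between clumps (bp).
#' @param cis_max_bp Maximum clump-to-site distance called cis (inclusive).
#' @param cisx_max_bp Maximum distance called cis-x (inclusive); beyond is
#'   trans.
#' @param hla_chrom,hla_start_bp,hla_end_bp The excluded HLA interval.
#' @param known_hit_window_bp Annotation window around known hit regions
#'   (inclusive).
#' @param p_core Association threshold for the diversity criterion.
#' @param p_core_monogenic Association threshold for the monogenic criterion.
#' @param diversity_min Effective eQTL count must exceed this (strict).
#' @param r2_high Squared correlation above which two scores are flagged as
#'   highly correlated.
#' @param master_regulator_min_scores A region is flagged as a master
#'   regulator when it contributes to more than this many disease-associated
#'   scores (strict).
#' @param ridge_lambda Ridge added to the LD correlation matrix diagonal
#'   before inversion; set 0 for plain inversion.
#' @param cis_report_p Cis-score association p below which cis evidence is
#'   attached to a core-gene call.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(p_retain = 1e-5,
                            p_lead = 1e-6,
                            clump_gap_bp = 1e6,
                            cis_max_bp = 5e4,
                            cisx_max_bp = 5e6,
                            hla_chrom = "6",
                            hla_start_bp = 25e6,
                            hla_end_bp = 34e6,
                            known_hit_window_bp = 2e5,
                            p_core = 1e-9,
                            p_core_monogenic = 1e-6,
                            diversity_min = 5,
                            r2_high = 0.7,
                            master_regulator_min_scores = 2,
                            ridge_lambda = 1e-3,
                            cis_report_p = 1e-3) {
  cfg <- list(
    p_retain = p_retain, p_lead = p_lead, clump_gap_bp = clump_gap_bp,
    cis_max_bp = cis_max_bp, cisx_max_bp = cisx_max_bp,
    hla_chrom = as.character(hla_chrom),
    hla_start_bp = hla_start_bp, hla_end_bp = hla_end_bp,
    known_hit_window_bp = known_hit_window_bp,
    p_core = p_core, p_core_monogenic = p_core_monogenic,
    diversity_min = diversity_min, r2_high = r2_high,
    master_regulator_min_scores = master_regulator_min_scores,
    ridge_lambda = ridge_lambda, cis_report_p = cis_report_p
  )
  class(cfg) <- "pipeline_config"
  if (cfg$p_lead > cfg$p_retain) {
    stop("`p_lead` must be <= `p_retain`", call. = FALSE)
  }
  if (cfg$cis_max_bp >= cfg$cisx_max_bp) {
    stop("`cis_max_bp` must be < `cisx_max_bp`", call. = FALSE)
  }
  if (cfg$hla_start_bp >= cfg$hla_end_bp) {
    stop("`hla_start_bp` must be < `hla_end_bp`", call. = FALSE)
  }
  cfg
}
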