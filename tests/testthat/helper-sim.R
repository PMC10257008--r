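# Shared fixtures: small simulation configs and hand-built containers.

# compact study conditions for unit tests (cheap but structurally complete)
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_reference = 400L, n_cases = 150L,
               n_controls = 200L, n_gwas = 4000L, n_blocks = 12L,
               snps_per_block = 4L, n_genes = 3L, n_core_genes = 1L,
               trans_blocks_per_gene = 6L, hla_block_ids = c(11L, 12L),
               base_rate = 0.2)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# null conditions: expression unrelated to disease
null_config <- function(seed = 1L, n_cases = 1000L, n_controls = 1000L) {
  sim_config(seed = seed, n_reference = 300L, n_cases = n_cases,
             n_controls = n_controls, n_gwas = 500L, n_blocks = 7L,
             snps_per_block = 4L, n_genes = 1L, n_core_genes = 1L,
             trans_blocks_per_gene = 6L, hla_block_ids = integer(0),
             liability_effect_sd = 0, base_rate = 0.5)
}

# a bare genotype container from a dosage matrix
make_geno <- function(dosages, chrom = "1", pos = NULL, samples = NULL) {
  m <- ncol(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("v%03d", seq_len(m))
  }
  if (is.null(pos)) pos <- 1e6 + seq_len(m) * 1000
  variants <- tibble::tibble(
    variant_id = colnames(dosages),
    block = 1L, chrom = rep_len(chrom, m), pos = pos,
    effect_allele = "A", other_allele = "G",
    maf = colMeans(dosages) / 2, is_hla = FALSE)
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = sprintf("s%04d",
                                                  seq_len(nrow(dosages))))
  }
  transcores:::new_geno_matrix(dosages, variants, samples)
}

# one-target summary-stat records at given positions/p-values
make_records <- function(pos, pvalue, chrom = "1", target = "G01",
                         beta = 0.1, se = 0.02) {
  tibble::tibble(
    variant_id = sprintf("snp%02d", seq_along(pos)),
    chrom = rep_len(chrom, length(pos)), pos = pos,
    effect_allele = "A", other_allele = "G",
    beta = rep_len(beta, length(pos)), se = rep_len(se, length(pos)),
    pvalue = pvalue, target_id = target, n = 10000L)
}

# small association + score fixture for plotting tests
make_plot_fixture <- function() {
  set.seed(99)
  scores <- cbind(A = stats::rnorm(200), B = stats::rnorm(200))
  assoc <- tibble::tibble(
    score_id = c("A", "B"), log_or = c(0.3, 0.05), se = 0.05,
    pvalue = c(1e-10, 0.3), info_discrimination = c(0.045, 0.00125),
    n_used = 200L, converged = TRUE, effective_n = c(7, 3))
  class(assoc) <- c("trans_assoc", class(assoc))
  list(scores = scores, assoc = assoc)
}

# hand-built locus_scores container
make_locus_scores <- function(values, target_id, locus_class,
                              chrom = "1", start = NULL, end = NULL) {
  k <- ncol(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("cl%02d", seq_len(k))
  }
  if (is.null(start)) start <- 1e6 * seq_len(k) * 10
  if (is.null(end)) end <- start + 1e4
  info <- tibble::tibble(
    clump_id = colnames(values),
    target_id = rep_len(target_id, k),
    chrom = rep_len(chrom, k), start = start, end = end,
    n_snps = 1L, lead_pvalue = 1e-8,
    locus_class = rep_len(locus_class, k),
    variance = apply(values, 2, stats::var))
  structure(list(values = values, info = info, skipped = character(0)),
            class = "locus_scores")
}
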