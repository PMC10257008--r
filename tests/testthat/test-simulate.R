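# The synthetic-data generator: determinism, LD structure, ascertainment,
# liability model, and the marginal summary statistics it emits.

test_that("identical config and seed give bit-identical outputs", {
  cfg <- small_config(seed = 11)
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1$dosages, p2$dosages)

  a1 <- simulate_architecture(cfg)
  a2 <- simulate_architecture(cfg)
  expect_identical(a1$effects, a2$effects)

  s1 <- simulate_study(cfg, a1)
  s2 <- simulate_study(cfg, a2)
  expect_identical(s1$dosages, s2$dosages)
  expect_identical(s1$samples, s2$samples)

  g <- simulate_gwas_cohort(cfg)
  ss1 <- compute_summary_stats(g, a1, cfg)
  ss2 <- compute_summary_stats(g, a1, cfg)
  expect_identical(ss1, ss2)
})

test_that("reference panel has block-diagonal LD at the configured level", {
  # independent SNPs when block_correlation = 0
  cfg0 <- small_config(seed = 3, block_correlation = 0, n_reference = 2000L)
  p0 <- simulate_reference_panel(cfg0)
  R <- stats::cor(p0$dosages)
  blocks <- p0$variants$block
  within <- abs(R[outer(blocks, blocks, "==") & upper.tri(R)])
  expect_lt(mean(within), 3 / sqrt(cfg0$n_reference))

  # two SNPs at correlation 0.8
  d <- transcores:::draw_block_dosages(5000, 2, 0.3, 0.8)
  expect_equal(stats::cor(d)[1, 2], 0.8, tolerance = 0.05 / 0.8)

  # across-block correlation near zero at default block_correlation
  cfg <- small_config(seed = 3, n_reference = 2000L)
  p <- simulate_reference_panel(cfg)
  R <- stats::cor(p$dosages)
  blocks <- p$variants$block
  across <- abs(R[outer(blocks, blocks, "!=") & upper.tri(R)])
  expect_lt(mean(across), 3 / sqrt(cfg$n_reference))
  # allele frequencies stay inside the configured range (+ sampling error)
  freq <- colMeans(p$dosages) / 2
  maf <- pmin(freq, 1 - freq)
  expect_true(all(maf > cfg$maf_range[1] - 0.05))
})

test_that("case-control ascertainment fills quotas exactly", {
  cfg <- small_config(seed = 5, n_cases = 100L, n_controls = 150L)
  arch <- simulate_architecture(cfg)
  st <- simulate_study(cfg, arch)
  expect_identical(sum(st$samples$status == 1), 100L)
  expect_identical(sum(st$samples$status == 0), 150L)
  expect_identical(nrow(st$dosages), 250L)
  expect_false(anyNA(st$dosages))
})

test_that("a core gene's true genetic expression is disease-associated with
           the sign of its liability coefficient", {
  cfg <- small_config(seed = 8, n_cases = 500L, n_controls = 500L)
  arch <- simulate_architecture(cfg)
  st <- simulate_study(cfg, arch)
  gv <- transcores:::gene_genetic_var(arch)
  G <- transcores:::genetic_expression(st$dosages, arch)
  gid <- arch$core$gene_id[1]
  z <- scale(G[, gid])
  fit <- stats::glm(st$samples$status ~ z, family = stats::binomial())
  b <- stats::coef(fit)[2]
  expect_gt(b * sign(arch$core$gamma[1]), 0)
  expect_lt(summary(fit)$coefficients[2, 4], 0.01)
})

test_that("marginal GWAS betas are consistent and reflect LD convolution", {
  # uncorrelated SNPs: estimated beta converges on the true effect
  cfg <- small_config(seed = 21, block_correlation = 0, n_gwas = 20000L)
  arch <- simulate_architecture(cfg)
  g <- simulate_gwas_cohort(cfg)
  ss <- compute_summary_stats(g, arch, cfg)
  truth <- dplyr::inner_join(
    ss, dplyr::select(arch$effects, "gene_id", "variant_id",
                      true_beta = "beta"),
    by = c(target_id = "gene_id", variant_id = "variant_id"))
  expect_gt(nrow(truth), 5)
  expect_lt(mean(abs(truth$beta - truth$true_beta) / truth$se), 3)

  # correlated block: non-causal neighbour picks up r * beta
  cfg2 <- small_config(seed = 22, block_correlation = 0.6, n_gwas = 20000L)
  arch2 <- simulate_architecture(cfg2)
  g2 <- simulate_gwas_cohort(cfg2)
  ss2 <- compute_summary_stats(g2, arch2, cfg2)
  vm <- arch2$variants
  e <- arch2$effects[arch2$effects$type == "trans", ]
  e <- e[1, ]
  blockmates <- vm$variant_id[vm$block == e$block &
                                vm$variant_id != e$variant_id]
  nb <- ss2[ss2$target_id == e$gene_id & ss2$variant_id %in% blockmates, ]
  expect_gt(nrow(nb), 0)
  expect_lt(mean(abs(nb$beta - 0.6 * e$beta) / nb$se), 3)
})

test_that("trans share of a core gene's genetic variance matches the
           configured fraction", {
  for (f in c(0.5, 0.7)) {
    cfg <- small_config(seed = 4, trans_heritability_fraction = f)
    arch <- simulate_architecture(cfg)
    shares <- arch$effects |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(share = sum(.data$beta^2 * .data$dosage_var *
                                     (.data$type == "trans")) /
                         sum(.data$beta^2 * .data$dosage_var))
    core <- shares$share[shares$gene_id %in% arch$core$gene_id]
    expect_true(all(abs(core - f) < 0.01))
  }
})

test_that("trans summary-stat records are restricted to the tested SNP set", {
  cfg <- small_config(seed = 9)
  arch <- simulate_architecture(cfg)
  g <- simulate_gwas_cohort(cfg)
  ss <- compute_summary_stats(g, arch, cfg)
  ann <- dplyr::select(arch$genes, target_id = "gene_id", "chrom",
                       "site_start", "site_end")
  long <- dplyr::left_join(ss, ann, by = "target_id")
  d <- ifelse(long$chrom.x != long$chrom.y, Inf,
              pmax(0, pmax(long$site_start - long$pos,
                           long$pos - long$site_end)))
  trans_records <- long[d > 5e6 | long$chrom.x != long$chrom.y, ]
  n_tested <- length(unique(trans_records$variant_id))
  expect_lte(n_tested, ceiling(cfg$tested_snp_fraction *
                                 nrow(arch$variants)) +
               length(unique(long$variant_id[d <= 5e6])))
  # every SNP of the genome is NOT present in trans for every gene
  expect_lt(n_tested, nrow(arch$variants))
})

test_that("degenerate liability models fail with a diagnostic", {
  cfg <- sim_config(seed = 2, n_reference = 50L, n_cases = 500L,
                    n_controls = 10L, n_gwas = 100L, n_blocks = 7L,
                    snps_per_block = 2L, n_genes = 1L, n_core_genes = 1L,
                    trans_blocks_per_gene = 6L,
                    hla_block_ids = integer(0), base_rate = 1e-7)
  arch <- simulate_architecture(cfg)
  expect_error(simulate_study(cfg, arch), "degenerate")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_blocks = 0), "positive count")
  expect_error(sim_config(block_correlation = 1), "block_correlation")
  expect_error(sim_config(maf_range = c(0, 0.6)), "maf_range")
  expect_error(sim_config(n_core_genes = 99), "n_core_genes")
  expect_error(sim_config(trans_blocks_per_gene = 3), ">= 6")
  expect_error(sim_config(trans_heritability_fraction = 1.2),
               "trans_heritability")
})
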