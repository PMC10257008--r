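# Filtering, positional clumping, locus classification, HLA exclusion,
# known-hit annotation, and allele harmonization.

test_that("clump formation follows the retain/lead/gap rules", {
  cfg <- pipeline_config()

  # nothing below the retention threshold
  r <- make_records(c(1e6, 2e6), pvalue = c(1e-4, 2e-5))
  expect_identical(nrow(filter_and_clump(r, cfg)), 0L)

  # a single strong SNP forms a singleton clump
  r <- make_records(1.5e6, pvalue = 1e-7)
  cl <- filter_and_clump(r, cfg)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_snps, 1L)
  expect_equal(cl$lead_pvalue, 1e-7)

  # 0.5 Mb gap merges, 1.5 Mb gap splits
  r <- make_records(c(1.0e6, 1.5e6, 3.0e6), pvalue = c(1e-8, 3e-6, 1e-7))
  cl <- filter_and_clump(r, cfg)
  expect_identical(nrow(cl), 2L)
  expect_equal(cl$start, c(1.0e6, 3.0e6))
  expect_equal(cl$end, c(1.5e6, 3.0e6))
  expect_equal(cl$lead_pvalue, c(1e-8, 1e-7))
  expect_identical(cl$n_snps, c(2L, 1L))

  # retained pair with no lead SNP is discarded entirely
  r <- make_records(c(1.0e6, 1.9e6), pvalue = c(3e-6, 3e-6))
  expect_identical(nrow(filter_and_clump(r, cfg)), 0L)

  # a gap of exactly 1 Mb separates ("separated by at least 1 Mb")
  r <- make_records(c(1.0e6, 2.0e6), pvalue = c(1e-8, 1e-8))
  expect_identical(nrow(filter_and_clump(r, cfg)), 2L)
})

test_that("clump partition is invariant to input order and clumps are
           pairwise separated by the gap", {
  set.seed(42)
  pos <- sort(sample(seq(1e6, 60e6, by = 1e4), 40))
  pv <- 10^(-stats::runif(40, 3, 10))
  r <- make_records(pos, pv)
  cl1 <- filter_and_clump(r, pipeline_config())
  cl2 <- filter_and_clump(r[sample(nrow(r)), ], pipeline_config())
  expect_equal(dplyr::select(cl1, -"members"),
               dplyr::select(cl2, -"members"))
  if (nrow(cl1) > 1) {
    gaps <- cl1$start[-1] - cl1$end[-nrow(cl1)]
    expect_true(all(gaps >= pipeline_config()$clump_gap_bp))
  }
})

test_that("tightening the retention threshold never adds retained SNPs", {
  set.seed(7)
  r <- make_records(seq(1e6, 20e6, by = 5e5),
                    10^(-stats::runif(39, 2, 9)))
  n_members <- function(p_retain) {
    cl <- filter_and_clump(r, pipeline_config(p_retain = p_retain,
                                              p_lead = min(p_retain, 1e-6)))
    sum(cl$n_snps)
  }
  counts <- vapply(c(1e-5, 1e-6, 1e-7, 1e-8), n_members, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("locus classification matches the distance rules and is
           symmetric upstream/downstream", {
  cfg <- pipeline_config()
  gene <- tibble::tibble(target_id = "G01", chrom = "1",
                         site_start = 10e6, site_end = 10.02e6)
  clump_at <- function(start, end, chrom = "1") {
    tibble::tibble(clump_id = "c", target_id = "G01", chrom = chrom,
                   start = start, end = end, n_snps = 1L,
                   lead_pvalue = 1e-8, locus_class = "unclassified",
                   members = list(tibble::tibble(variant_id = "v",
                                                 pos = start)))
  }
  # overlap of the transcription site: distance zero, cis
  expect_identical(classify_locus(clump_at(10.01e6, 10.01e6), gene, cfg),
                   "cis")
  # exactly 50 kb away is still cis (inclusive boundary)
  expect_identical(classify_locus(clump_at(10.07e6, 10.07e6), gene, cfg),
                   "cis")
  expect_identical(classify_locus(clump_at(10.070001e6, 10.070001e6),
                                  gene, cfg), "cis-x")
  # 3.7 Mb downstream is an extended-cis locus
  expect_identical(classify_locus(clump_at(13.72e6, 13.75e6), gene, cfg),
                   "cis-x")
  # symmetric: 3.7 Mb upstream gives the same class
  expect_identical(classify_locus(clump_at(6.28e6, 6.3e6), gene, cfg),
                   "cis-x")
  # beyond 5 Mb, or another chromosome, is trans
  expect_identical(classify_locus(clump_at(16e6, 16.01e6), gene, cfg),
                   "trans")
  expect_identical(classify_locus(clump_at(10e6, 10.01e6, chrom = "2"),
                                  gene, cfg), "trans")
  # unknown target stays unclassified with a warning
  gene2 <- dplyr::mutate(gene, target_id = "OTHER")
  expect_warning(
    cls <- classify_locus(clump_at(10e6, 10.01e6), gene2, cfg),
    "no annotation")
  expect_identical(cls, "unclassified")
})

test_that("HLA exclusion removes any overlapping clump", {
  cfg <- pipeline_config()
  cl <- tibble::tibble(
    clump_id = c("in", "out", "edge"),
    target_id = "G01",
    chrom = "6",
    start = c(28e6, 40e6, 24.9e6),
    end = c(28.1e6, 40.1e6, 25.1e6),
    n_snps = 1L, lead_pvalue = 1e-8, locus_class = "trans",
    members = list(tibble::tibble(), tibble::tibble(), tibble::tibble()))
  kept <- exclude_hla(cl, cfg)
  expect_identical(kept$clump_id, "out")
  # same positions on another chromosome pass through
  cl2 <- dplyr::mutate(cl, chrom = "2")
  expect_identical(nrow(exclude_hla(cl2, cfg)), 3L)
})

test_that("known-region annotation uses an inclusive 200 kb window", {
  cfg <- pipeline_config()
  hits <- tibble::tibble(chrom = "1", start = 5e6, end = 5.1e6,
                         label = "KNOWN1")
  x <- tibble::tibble(
    chrom = "1",
    start = c(5.05e6, 5.3e6, 5.4e6 + 1, 8e6),
    end = c(5.06e6, 5.35e6, 5.5e6, 8.1e6))
  ann <- annotate_known_regions(x, hits, cfg)
  # overlapping, exactly 200 kb away, just beyond, and 2.9 Mb away
  expect_identical(ann$known_hit, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(ann$known_labels[1], "KNOWN1")
  expect_error(annotate_known_regions(x, tibble::tibble(chrom = "1"), cfg),
               "known-hit table")
})

test_that("allele harmonization flips swapped alleles and drops the rest", {
  set.seed(1)
  dos <- matrix(stats::rbinom(300, 2, 0.5), 100, 3)
  colnames(dos) <- c("v1", "v2", "v3")
  panel <- make_geno(dos)
  panel$variants$effect_allele <- c("A", "C", "A")
  panel$variants$other_allele <- c("G", "T", "T")  # v3 is ambiguous A/T
  rec <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v9"),
    chrom = "1", pos = c(1e6, 2e6, 3e6, 9e6),
    effect_allele = c("G", "C", "A", "A"),
    other_allele = c("A", "T", "T", "G"),
    beta = c(0.5, 0.2, 0.1, 0.3), se = 0.05, pvalue = 1e-8,
    target_id = "G01", n = 1000L)
  expect_warning(h <- harmonize_to_panel(rec, panel), "absent")
  # v1 swapped: sign flipped and alleles reoriented
  expect_equal(h$beta[h$variant_id == "v1"], -0.5)
  expect_identical(h$effect_allele[h$variant_id == "v1"], "A")
  # v2 identical alleles: untouched
  expect_equal(h$beta[h$variant_id == "v2"], 0.2)
  # v3 ambiguous with panel MAF ~0.5: dropped; v9 absent: dropped
  expect_false("v3" %in% h$variant_id)
  expect_false("v9" %in% h$variant_id)

  # mismatched allele pairs are dropped with a warning
  rec2 <- dplyr::mutate(rec[1, ], effect_allele = "C", other_allele = "T")
  expect_warning(h2 <- harmonize_to_panel(rec2, panel), "unmatched")
  expect_identical(nrow(h2), 0L)
})
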