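# Summary-statistic handling: p-value filtering, positional clumping,
# cis / cis-x / trans classification, HLA exclusion, known-hit annotation,
# and allele harmonization against a genotype panel.

#' Read a summary-statistics table
#'
#' Reads a tab-separated summary-statistics file. `col_map` renames
#' dialect-specific headers to the canonical columns (`variant_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`,
#' `target_id`, `n`), e.g. `c(pvalue = "Pvalue", variant_id = "SNP")`.
#'
#' @param path File path.
#' @param col_map Named character vector mapping canonical name -> file header.
#' @return Tibble of summary-stat records.
#' @export
read_sumstats <- function(path, col_map = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    x <- dplyr::rename(x, !!!rlang::set_names(col_map, names(col_map)))
  }
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "se", "pvalue", "target_id")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop("summary statistics lack columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(x, chrom = as.character(.data$chrom))
}

#' Write summary statistics
#' @param records Tibble of summary-stat records.
#' @param path Output path (TSV with header).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Filter summary statistics and form positional clumps
#'
#' Retains records with `pvalue < p_retain`, then partitions the retained
#' SNPs of each target on each chromosome into maximal single-linkage chains
#' in which consecutive retained SNPs are less than `clump_gap_bp` apart
#' (so emitted clumps are pairwise separated by at least the gap). Chains
#' whose smallest p-value is not below `p_lead` are discarded. Input order is
#' irrelevant; records are sorted internally.
#'
#' @param records Tibble of summary-stat records (one or more targets).
#' @param config A [pipeline_config()].
#' @return Tibble of clumps: `clump_id`, `target_id`, `chrom`, `start`,
#'   `end`, `n_snps`, `lead_pvalue`, `locus_class` (initially
#'   "unclassified"), and a `members` list-column of record tibbles.
#' @export
filter_and_clump <- function(records, config = pipeline_config()) {
  empty <- tibble::tibble(
    clump_id = character(0), target_id = character(0), chrom = character(0),
    start = numeric(0), end = numeric(0), n_snps = integer(0),
    lead_pvalue = numeric(0), locus_class = character(0),
    members = list())
  if (nrow(records) == 0) return(empty)
  kept <- records |>
    dplyr::filter(.data$pvalue < config$p_retain) |>
    dplyr::arrange(.data$target_id, .data$chrom, .data$pos)
  if (nrow(kept) == 0) return(empty)
  kept |>
    dplyr::group_by(.data$target_id, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      gap <- c(0, diff(d$pos))
      d$grp <- cumsum(gap >= config$clump_gap_bp)
      d |>
        dplyr::group_by(.data$grp) |>
        dplyr::group_modify(function(m, k2) {
          tibble::tibble(
            start = min(m$pos), end = max(m$pos),
            n_snps = nrow(m), lead_pvalue = min(m$pvalue),
            members = list(dplyr::select(m, -dplyr::any_of("grp"))))
        }) |>
        dplyr::ungroup() |>
        dplyr::select(-"grp")
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$lead_pvalue < config$p_lead) |>
    dplyr::mutate(
      clump_id = sprintf("%s:%s:%.0f", .data$target_id, .data$chrom,
                         .data$start),
      locus_class = "unclassified") |>
    dplyr::select("clump_id", "target_id", "chrom", "start", "end",
                  "n_snps", "lead_pvalue", "locus_class", "members")
}

#' Classify clumps as cis, cis-x, or trans
#'
#' Distance from a clump to its target's transcription site is zero when the
#' clump interval overlaps the site, otherwise the minimum bp gap between any
#' member SNP and the nearer site boundary. A clump on a different chromosome
#' is trans. Distance at most `cis_max_bp` (inclusive) is cis; at most
#' `cisx_max_bp` is cis-x; beyond is trans. Targets missing from the
#' annotation stay "unclassified" with a warning.
#'
#' @param clumps Output of [filter_and_clump()].
#' @param annotation Tibble: `target_id`, `chrom`, `site_start`, `site_end`.
#' @param config A [pipeline_config()].
#' @return `clumps` with `locus_class` and `site_distance` filled in.
#' @export
classify_clumps <- function(clumps, annotation, config = pipeline_config()) {
  stopifnot(all(c("target_id", "chrom", "site_start", "site_end") %in%
                  names(annotation)))
  ann <- annotation |>
    dplyr::mutate(gene_chrom = as.character(.data$chrom)) |>
    dplyr::select("target_id", "gene_chrom", "site_start", "site_end")
  out <- dplyr::left_join(clumps, ann, by = "target_id")
  unknown <- is.na(out$gene_chrom)
  if (any(unknown)) {
    warning("no annotation for target(s): ",
            paste(unique(out$target_id[unknown]), collapse = ", "),
            "; left unclassified", call. = FALSE)
  }
  d <- ifelse(out$chrom != out$gene_chrom, Inf,
              pmax(0, pmax(out$site_start - out$end,
                           out$start - out$site_end)))
  cls <- dplyr::case_when(
    is.na(out$gene_chrom) ~ "unclassified",
    out$chrom != out$gene_chrom ~ "trans",
    d <= config$cis_max_bp ~ "cis",
    d <= config$cisx_max_bp ~ "cis-x",
    TRUE ~ "trans")
  out |>
    dplyr::mutate(locus_class = cls,
                  site_distance = ifelse(is.na(.data$gene_chrom), NA_real_, d)) |>
    dplyr::select(-"gene_chrom", -"site_start", -"site_end")
}

#' Classify a single clump (scalar convenience wrapper)
#'
#' @param clump One-row clump tibble.
#' @param gene One-row annotation tibble for the same target.
#' @param config A [pipeline_config()].
#' @return The locus class string.
#' @export
classify_locus <- function(clump, gene, config = pipeline_config()) {
  classify_clumps(clump, gene, config)$locus_class
}

hla_overlap <- function(chrom, start, end, config) {
  as.character(chrom) == config$hla_chrom &
    start <= config$hla_end_bp & end >= config$hla_start_bp
}

#' Exclude clumps overlapping the HLA region
#'
#' Removes every clump whose interval intersects the configured HLA region
#' (any overlap excludes); all other clumps pass through unchanged.
#'
#' @param clumps Clump tibble.
#' @param config A [pipeline_config()].
#' @return Filtered clump tibble.
#' @export
exclude_hla <- function(clumps, config = pipeline_config()) {
  if (nrow(clumps) == 0) return(clumps)
  dplyr::filter(clumps,
                !hla_overlap(.data$chrom, .data$start, .data$end, config))
}

#' Annotate intervals with nearby known disease-associated regions
#'
#' Flags each row whose `[start, end]` interval lies within
#' `known_hit_window_bp` (inclusive) of a known-hit interval on the same
#' chromosome, and collects the matched labels. Works for clump tables and,
#' via `start_col`/`end_col`, for gene annotations.
#'
#' @param x Tibble with `chrom` and interval columns.
#' @param known_hits Tibble: `chrom`, `start`, `end`, `label`.
#' @param config A [pipeline_config()].
#' @param start_col,end_col Names of the interval columns in `x`.
#' @return `x` plus `known_hit` (logical) and `known_labels` (comma-joined).
#' @export
annotate_known_regions <- function(x, known_hits,
                                   config = pipeline_config(),
                                   start_col = "start", end_col = "end") {
  if (!all(c("chrom", "start", "end", "label") %in% names(known_hits))) {
    stop("known-hit table must have chrom/start/end/label columns",
         call. = FALSE)
  }
  if (!all(c("chrom", start_col, end_col) %in% names(x))) {
    stop("input lacks chrom/", start_col, "/", end_col, " columns",
         call. = FALSE)
  }
  w <- config$known_hit_window_bp
  labs <- purrr::map_chr(seq_len(nrow(x)), function(i) {
    hit <- known_hits$chrom == x$chrom[i] &
      known_hits$start - w <= x[[end_col]][i] &
      known_hits$end + w >= x[[start_col]][i]
    paste(known_hits$label[hit], collapse = ",")
  })
  dplyr::mutate(x, known_hit = labs != "", known_labels = labs)
}

#' Harmonize summary statistics to a genotype panel
#'
#' Matches records to panel variants by id and allele pair: identical alleles
#' pass through, swapped effect/other alleles flip the sign of `beta`, and
#' any other combination is dropped. Strand-ambiguous A/T and C/G variants
#' with panel minor-allele frequency above 0.4 are dropped, as the strand
#' cannot be resolved from frequency.
#'
#' @param records Summary-stat tibble.
#' @param panel A `geno_matrix` (its `variants` tibble supplies alleles; its
#'   dosages supply allele frequencies).
#' @return Harmonized records (possibly fewer rows, possibly sign-flipped).
#' @export
harmonize_to_panel <- function(records, panel) {
  v <- panel$variants
  freq <- colMeans(panel$dosages, na.rm = TRUE) / 2
  v$panel_maf <- pmin(freq[v$variant_id], 1 - freq[v$variant_id])
  m <- dplyr::inner_join(
    records,
    dplyr::select(v, "variant_id",
                  panel_ea = "effect_allele", panel_oa = "other_allele",
                  "panel_maf"),
    by = "variant_id")
  dropped_ids <- setdiff(records$variant_id, m$variant_id)
  same <- m$effect_allele == m$panel_ea & m$other_allele == m$panel_oa
  swap <- m$effect_allele == m$panel_oa & m$other_allele == m$panel_ea
  ambiguous <- paste0(pmin(m$effect_allele, m$other_allele),
                      pmax(m$effect_allele, m$other_allele)) %in%
    c("AT", "CG")
  drop_amb <- ambiguous & m$panel_maf > 0.4
  bad <- !(same | swap)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unmatched alleles dropped",
            call. = FALSE)
  }
  if (length(dropped_ids) > 0) {
    warning(length(dropped_ids),
            " record(s) absent from the panel dropped", call. = FALSE)
  }
  m |>
    dplyr::filter(!bad, !drop_amb) |>
    dplyr::mutate(beta = ifelse(.data$effect_allele == .data$panel_oa,
                                -.data$beta, .data$beta),
                  ea = ifelse(.data$effect_allele == .data$panel_oa,
                              .data$panel_ea, .data$effect_allele),
                  oa = ifelse(.data$effect_allele == .data$panel_oa,
                              .data$panel_oa, .data$other_allele)) |>
    dplyr::mutate(effect_allele = .data$ea, other_allele = .data$oa) |>
    dplyr::select(-"panel_ea", -"panel_oa", -"panel_maf", -"ea", -"oa")
}
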