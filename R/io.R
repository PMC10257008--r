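# Plain-text readers and writers for the pipeline's external formats.

#' Write a genotype matrix as a plain dosage file
#'
#' Tab-separated: one row per variant (metadata columns then one dosage
#' column per individual). A companion `<path>.samples.tsv` stores the
#' sample metadata.
#'
#' @param geno A `geno_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geno_matrix <- function(geno, path) {
  wide <- dplyr::bind_cols(
    geno$variants,
    tibble::as_tibble(t(geno$dosages), .name_repair = "minimal"))
  readr::write_tsv(wide, path, progress = FALSE)
  readr::write_tsv(geno$samples, paste0(path, ".samples.tsv"),
                   progress = FALSE)
  invisible(path)
}

#' Read a genotype matrix written by [write_geno_matrix()]
#'
#' @param path Path to the dosage file.
#' @return A `geno_matrix`.
#' @export
read_geno_matrix <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  samples <- readr::read_tsv(paste0(path, ".samples.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  meta_cols <- intersect(
    c("variant_id", "block", "chrom", "pos", "effect_allele",
      "other_allele", "maf", "is_hla"), names(wide))
  variants <- dplyr::mutate(wide[, meta_cols],
                            chrom = as.character(.data$chrom))
  dos <- t(as.matrix(wide[, setdiff(names(wide), meta_cols)]))
  colnames(dos) <- variants$variant_id
  rownames(dos) <- samples$sample_id
  new_geno_matrix(dos, variants, samples)
}

#' Read a BED-like gene annotation table
#'
#' Tab-separated with columns `target_id`, `chrom`, `site_start`,
#' `site_end` (1-based, inclusive).
#'
#' @param path File path.
#' @return Annotation tibble.
#' @export
read_gene_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("target_id", "chrom", "site_start", "site_end")
  if (!all(need %in% names(x))) {
    stop("gene annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- x$site_start > x$site_end
  if (any(bad)) {
    stop("site_start > site_end for ", sum(bad), " gene(s)", call. = FALSE)
  }
  dplyr::mutate(x, chrom = as.character(.data$chrom))
}

#' Read a BED-like known-hit region table
#'
#' Tab-separated with columns `chrom`, `start`, `end`, `label`.
#'
#' @param path File path.
#' @return Region tibble.
#' @export
read_known_hits <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "label")
  if (!all(need %in% names(x))) {
    stop("known-hit table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(x, chrom = as.character(.data$chrom))
}

#' Write scores with a provenance sidecar
#'
#' Writes the individual-by-score matrix as TSV and a JSON sidecar listing,
#' per score, the contributing clumps, locus classes, raw variances, and the
#' effective eQTL count.
#'
#' @param scores A `trans_scores` or `cis_scores` object.
#' @param path Output TSV path (sidecar at `<path>.provenance.json`).
#' @param sample_ids Optional ids for the rows.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, sample_ids = NULL) {
  v <- scores$values
  d <- tibble::as_tibble(v, .name_repair = "minimal")
  if (!is.null(sample_ids)) d <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_ids), d)
  readr::write_tsv(d, path, progress = FALSE)
  jsonlite::write_json(scores$meta, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
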