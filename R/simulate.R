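# Synthetic-data generator: block-structured genotypes, a true eQTL/disease
# architecture (sparse cis effects, many weak trans effects coalescing on a
# few core genes), and eQTLGen-style marginal summary statistics.

hla_delta <- 0.5          # direct liability effect per synthetic HLA block
hla_trans_scale <- 2      # HLA trans effects on HLA-driven genes, x trans_effect_sd
n_hla_driven_max <- 2L    # bystander genes driven mainly by the HLA region
hla_weak_pleio_blocks <- 3L  # non-HLA blocks feeding HLA-driven genes
n_shared_blocks <- 2L     # master-regulator blocks shared by all core genes

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_stream_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stream_seed <- function(seed, k) (abs(seed) %% 1000000000L) + k

#' Variant map of the synthetic genome
#'
#' Lays out `n_blocks` LD blocks on named chromosomes: HLA-designated blocks
#' go to chromosome 6 inside 25-34 Mb; all other blocks are placed on
#' chromosomes 1-5, 7, 8, ... at 12 Mb spacing, so distinct blocks are always
#' more than 5 Mb apart. SNPs within a block are 1 kb apart.
#'
#' @param config A [sim_config()].
#' @return Tibble: variant_id, block, chrom, pos, effect_allele, other_allele,
#'   maf, is_hla.
#' @export
variant_map <- function(config) {
  validate_sim_config(config)
  nb <- config$n_blocks
  m <- config$snps_per_block
  is_hla <- seq_len(nb) %in% config$hla_block_ids
  # non-HLA blocks: 4 per chromosome, skipping chromosome 6
  free_chroms <- as.character(setdiff(1:22, 6))
  ord <- which(!is_hla)
  chrom <- character(nb)
  start <- numeric(nb)
  for (i in seq_along(ord)) {
    b <- ord[i]
    chrom[b] <- free_chroms[((i - 1) %/% 4) + 1]
    start[b] <- 10e6 + ((i - 1) %% 4) * 12e6
  }
  hla_ord <- which(is_hla)
  for (i in seq_along(hla_ord)) {
    b <- hla_ord[i]
    chrom[b] <- "6"
    start[b] <- 26e6 + (i - 1) * 3e6
  }
  mafs <- with_stream_seed(stream_seed(config$seed, 0L), {
    stats::runif(nb, config$maf_range[1], config$maf_range[2])
  })
  allele_pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  tibble::tibble(
    block = rep(seq_len(nb), each = m),
    snp = rep(seq_len(m), times = nb)
  ) |>
    dplyr::mutate(
      variant_id = sprintf("rs%03d%02d", .data$block, .data$snp),
      chrom = chrom[.data$block],
      pos = start[.data$block] + (.data$snp - 1) * 1000,
      effect_allele = purrr::map_chr(
        (.data$block + .data$snp) %% 4 + 1, ~ allele_pairs[[.x]][1]),
      other_allele = purrr::map_chr(
        (.data$block + .data$snp) %% 4 + 1, ~ allele_pairs[[.x]][2]),
      maf = mafs[.data$block],
      is_hla = is_hla[.data$block]
    ) |>
    dplyr::select("variant_id", "block", "chrom", "pos", "effect_allele",
                  "other_allele", "maf", "is_hla")
}

# Exchangeable-binary haplotype model: within a block every pair of SNP
# alleles on a haplotype shares a common Bernoulli(p) component with
# probability sqrt(rho), giving pairwise allele (and dosage) correlation rho
# while preserving allele frequency p and Hardy-Weinberg dosages.
draw_block_dosages <- function(n, m, p, rho) {
  a <- sqrt(rho)
  hap <- function() {
    u <- stats::rbinom(n, 1L, p)
    v <- matrix(stats::rbinom(n * m, 1L, p), n, m)
    s <- matrix(stats::rbinom(n * m, 1L, a), n, m)
    s * u + (1L - s) * v
  }
  hap() + hap()
}

draw_genotypes <- function(n, variants, rho) {
  blocks <- unique(variants$block)
  out <- matrix(0L, n, nrow(variants))
  colnames(out) <- variants$variant_id
  for (b in blocks) {
    idx <- which(variants$block == b)
    out[, idx] <- draw_block_dosages(n, length(idx),
                                     variants$maf[idx[1]], rho)
  }
  out
}

new_geno_matrix <- function(dosages, variants, samples) {
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " variants\n", sep = "")
  invisible(x)
}

#' Simulate a reference panel for LD estimation
#'
#' Generates genotype dosages with block-diagonal LD: within-block pairwise
#' correlation approximately `block_correlation`, across-block zero.
#'
#' @param config A [sim_config()].
#' @return A `geno_matrix`: dosage matrix (individuals x variants), variant
#'   and sample metadata tibbles.
#' @export
simulate_reference_panel <- function(config) {
  validate_sim_config(config)
  variants <- variant_map(config)
  dos <- with_stream_seed(stream_seed(config$seed, 1L), {
    draw_genotypes(config$n_reference, variants, config$block_correlation)
  })
  rownames(dos) <- sprintf("ref%05d", seq_len(config$n_reference))
  new_geno_matrix(dos, variants,
                  tibble::tibble(sample_id = rownames(dos)))
}

#' Simulate the true eQTL and disease architecture
#'
#' Assigns block roles (pleiotropic trans blocks shared across genes, one cis
#' "home" block per gene, the HLA blocks), draws sparse cis and many weak
#' trans effects, rescales each gene's trans effects so the trans share of
#' genetic expression variance equals `trans_heritability_fraction`, and
#' defines a logistic liability model in the core genes' genetic expression
#' values plus a direct HLA-region effect.
#'
#' Effect magnitudes are `scale * exp(N(0, 0.25))` with random sign, where
#' `scale` is `cis_effect_sd` or `trans_effect_sd`; the mild lognormal spread
#' keeps all drawn effects of comparable order so the number of detectable
#' trans loci per gene is controlled by `trans_blocks_per_gene`.
#'
#' @param config A [sim_config()].
#' @return A list of class `true_architecture` with elements `genes`,
#'   `effects`, `core`, `hla_effects`, `variants`, and `config`.
#' @export
simulate_architecture <- function(config) {
  validate_sim_config(config)
  variants <- variant_map(config)
  nb <- config$n_blocks
  non_hla <- setdiff(seq_len(nb), config$hla_block_ids)
  k <- config$trans_blocks_per_gene
  nc <- config$n_core_genes
  # pleiotropic pool: with core genes present, each core gene owns k - 2
  # exclusive blocks plus 2 master-regulator blocks shared by every core
  # gene; bystanders later sample their k blocks from this pool, which is
  # what makes them confounded with the disease signal.
  pool_size <- if (nc > 0) nc * (k - n_shared_blocks) + n_shared_blocks
               else k
  if (length(non_hla) < pool_size + config$n_genes) {
    stop("need at least ", pool_size + config$n_genes,
         " non-HLA blocks for this architecture; have ", length(non_hla),
         call. = FALSE)
  }
  pool <- non_hla[seq_len(pool_size)]
  shared <- if (nc > 0) pool[seq_len(n_shared_blocks)] else pool
  core_blocks <- if (nc > 0) {
    lapply(seq_len(nc), function(i) {
      c(shared,
        pool[n_shared_blocks + (i - 1) * (k - n_shared_blocks) +
               seq_len(k - n_shared_blocks)])
    })
  } else list()
  homes <- non_hla[pool_size + seq_len(config$n_genes)]

  block_tbl <- variants |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     b_start = min(.data$pos), b_end = max(.data$pos),
                     maf = dplyr::first(.data$maf), .groups = "drop")
  # per-gene causal SNP within a block: genes hit different (correlated)
  # SNPs of a shared block, as distinct regulatory variants would
  causal_of <- function(b, g = 1L) {
    idx <- which(variants$block == b)
    variants$variant_id[idx[(g - 1L) %% length(idx) + 1L]]
  }

  n_hd <- if (length(config$hla_block_ids) > 0) {
    min(n_hla_driven_max, config$n_genes - config$n_core_genes)
  } else 0L
  hd_ids <- if (n_hd > 0) config$n_genes - seq_len(n_hd) + 1L else integer(0)

  with_stream_seed(stream_seed(config$seed, 2L), {
    genes <- tibble::tibble(
      gene_id = sprintf("G%02d", seq_len(config$n_genes)),
      home_block = homes,
      is_core = seq_len(config$n_genes) <= config$n_core_genes,
      hla_driven = seq_len(config$n_genes) %in% hd_ids
    )
    # transcription sites at block boundaries; offsets chosen so cis,
    # cis-x and trans classes all occur among home loci
    offs <- rep(c(1e4, 4e4), length.out = config$n_genes)
    cisx_id <- config$n_core_genes + 1L  # first bystander gets a cis-x home
    if (cisx_id <= config$n_genes && !(cisx_id %in% hd_ids)) {
      offs[cisx_id] <- 2e6
    }
    genes <- genes |>
      dplyr::left_join(block_tbl, by = c(home_block = "block")) |>
      dplyr::mutate(site_start = .data$b_end + offs,
                    site_end = .data$b_end + offs + 2e4 - 1) |>
      dplyr::select("gene_id", "chrom", "site_start", "site_end",
                    "home_block", "is_core", "hla_driven")
    genes$monogenic <- genes$is_core &
      seq_len(config$n_genes) == config$n_core_genes  # last core gene

    draw_mag <- function(n, scale) scale * exp(stats::rnorm(n, 0, 0.25)) *
      sample(c(-1, 1), n, replace = TRUE)

    eff <- purrr::map_dfr(seq_len(config$n_genes), function(g) {
      gid <- genes$gene_id[g]
      cis <- tibble::tibble(
        gene_id = gid, block = genes$home_block[g], type = "cis",
        beta = draw_mag(1, config$cis_effect_sd))
      tb <- if (genes$is_core[g]) {
        core_blocks[[g]]
      } else if (genes$hla_driven[g]) {
        sample(pool, min(hla_weak_pleio_blocks, length(pool)))
      } else {
        sample(pool, min(config$trans_blocks_per_gene, length(pool)))
      }
      trans <- tibble::tibble(
        gene_id = gid, block = tb, type = "trans",
        beta = draw_mag(length(tb), config$trans_effect_sd))
      hla_tb <- if (genes$hla_driven[g]) {
        tibble::tibble(gene_id = gid, block = config$hla_block_ids,
                       type = "trans",
                       beta = draw_mag(length(config$hla_block_ids),
                                       hla_trans_scale * config$trans_effect_sd))
      } else NULL
      dplyr::bind_rows(cis, trans, hla_tb) |>
        dplyr::mutate(gene_index = g)
    })
    eff$variant_id <- vapply(seq_len(nrow(eff)), function(i) {
      causal_of(eff$block[i], eff$gene_index[i])
    }, character(1))
    eff$gene_index <- NULL
    eff <- eff |>
      dplyr::left_join(dplyr::select(block_tbl, "block", "maf"), by = "block") |>
      dplyr::mutate(dosage_var = 2 * .data$maf * (1 - .data$maf))

    # rescale trans effects per gene to the target trans heritability share
    f <- config$trans_heritability_fraction
    eff <- eff |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::group_modify(function(d, key) {
        cv <- sum(d$beta[d$type == "cis"]^2 * d$dosage_var[d$type == "cis"])
        tv <- sum(d$beta[d$type == "trans"]^2 * d$dosage_var[d$type == "trans"])
        if (f >= 1) {
          d$beta[d$type == "cis"] <- 0
        } else if (f <= 0) {
          d$beta[d$type == "trans"] <- 0
        } else if (tv > 0 && cv > 0) {
          d$beta[d$type == "trans"] <- d$beta[d$type == "trans"] *
            sqrt(f / (1 - f) * cv / tv)
        }
        d
      }) |>
      dplyr::ungroup()

    core <- tibble::tibble(
      gene_id = genes$gene_id[genes$is_core],
      gamma = config$liability_effect_sd *
        sample(c(-1, 1), sum(genes$is_core), replace = TRUE)
    )
    hla_fx <- if (length(config$hla_block_ids) > 0) {
      tibble::tibble(
        block = config$hla_block_ids,
        variant_id = vapply(config$hla_block_ids, causal_of, character(1)),
        delta = hla_delta
      ) |>
        dplyr::left_join(dplyr::select(block_tbl, "block", "maf"),
                         by = "block")
    } else {
      tibble::tibble(block = integer(0), variant_id = character(0),
                     delta = numeric(0), maf = numeric(0))
    }

    structure(list(genes = genes, effects = eff, core = core,
                   hla_effects = hla_fx, variants = variants,
                   config = config),
              class = "true_architecture")
  })
}

#' @export
print.true_architecture <- function(x, ...) {
  cat("<true_architecture> ", nrow(x$genes), " genes (",
      sum(x$genes$is_core), " core), ", nrow(x$effects),
      " causal effects\n", sep = "")
  invisible(x)
}

# analytic genetic variance of expression per gene (causal SNPs are in
# distinct blocks, hence independent)
gene_genetic_var <- function(arch) {
  arch$effects |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(gen_var = sum(.data$beta^2 * .data$dosage_var),
                     .groups = "drop")
}

# genetic expression values: n x n_genes matrix
genetic_expression <- function(dosages, arch) {
  B <- matrix(0, ncol(dosages), nrow(arch$genes),
              dimnames = list(colnames(dosages), arch$genes$gene_id))
  for (i in seq_len(nrow(arch$effects))) {
    B[arch$effects$variant_id[i], arch$effects$gene_id[i]] <-
      B[arch$effects$variant_id[i], arch$effects$gene_id[i]] +
      arch$effects$beta[i]
  }
  dosages %*% B
}

# standardized direct HLA liability component
hla_liability <- function(dosages, arch) {
  if (nrow(arch$hla_effects) == 0) return(numeric(nrow(dosages)))
  comp <- numeric(nrow(dosages))
  for (i in seq_len(nrow(arch$hla_effects))) {
    v <- arch$hla_effects$variant_id[i]
    p <- arch$hla_effects$maf[i]
    comp <- comp + arch$hla_effects$delta[i] *
      (dosages[, v] - 2 * p) / sqrt(2 * p * (1 - p))
  }
  comp
}

liability_eta <- function(dosages, arch) {
  cfg <- arch$config
  gv <- gene_genetic_var(arch)
  eta <- stats::qlogis(cfg$base_rate) + hla_liability(dosages, arch)
  if (nrow(arch$core) > 0) {
    G <- genetic_expression(dosages, arch)
    for (i in seq_len(nrow(arch$core))) {
      gid <- arch$core$gene_id[i]
      sdg <- sqrt(gv$gen_var[gv$gene_id == gid])
      if (sdg > 0) {
        eta <- eta + arch$core$gamma[i] * (G[, gid] - mean(G[, gid])) / sdg
      }
    }
  }
  eta
}

#' Simulate the case-control study
#'
#' Draws individuals from the genotype model, assigns disease status from the
#' logistic liability model (core-gene genetic expression plus a direct HLA
#' effect plus logistic noise), and ascertains exactly `n_cases` cases and
#' `n_controls` controls by sampling until both quotas are filled. Attaches
#' covariates: the first three genotypic principal components, sex, age, and
#' the true HLA-region risk component.
#'
#' @param config A [sim_config()].
#' @param architecture A [simulate_architecture()] result built from the same
#'   config (same variant universe).
#' @return A `geno_matrix` whose `samples` tibble carries `status` (1 = case),
#'   `sex`, `age`, `PC1`-`PC3`, and `hla_risk`.
#' @export
simulate_study <- function(config, architecture) {
  validate_sim_config(config)
  stopifnot(inherits(architecture, "true_architecture"))
  if (!identical(architecture$variants$variant_id,
                 variant_map(config)$variant_id)) {
    stop("architecture was generated from a different variant universe",
         call. = FALSE)
  }
  variants <- architecture$variants
  with_stream_seed(stream_seed(config$seed, 3L), {
    need_ca <- config$n_cases
    need_co <- config$n_controls
    batch <- min(50000L, max(2000L, ceiling(
      1.5 * max(need_ca / config$base_rate, need_co))))
    got_ca <- got_co <- 0L
    acc <- list()
    for (it in seq_len(60L)) {
      X <- draw_genotypes(batch, variants, config$block_correlation)
      eta <- liability_eta(X, architecture)
      status <- stats::rbinom(batch, 1L, stats::plogis(eta))
      keep_ca <- which(status == 1L)[seq_len(min(sum(status == 1L),
                                                 need_ca - got_ca))]
      keep_co <- which(status == 0L)[seq_len(min(sum(status == 0L),
                                                 need_co - got_co))]
      keep <- c(keep_ca, keep_co)
      if (length(keep) > 0) {
        acc[[length(acc) + 1]] <- list(X = X[keep, , drop = FALSE],
                                       status = status[keep])
        got_ca <- got_ca + length(keep_ca)
        got_co <- got_co + length(keep_co)
      }
      if (got_ca >= need_ca && got_co >= need_co) break
      if (it >= 10L && (got_ca == 0L || got_co == 0L)) {
        stop("liability model is degenerate: sampled ", it * batch,
             " individuals with ", got_ca, " cases / ", got_co,
             " controls", call. = FALSE)
      }
    }
    if (got_ca < need_ca || got_co < need_co) {
      stop("case-control ascertainment did not fill quotas (",
           got_ca, "/", need_ca, " cases, ", got_co, "/", need_co,
           " controls); liability model too unbalanced", call. = FALSE)
    }
    X <- do.call(rbind, lapply(acc, `[[`, "X"))
    status <- unlist(lapply(acc, `[[`, "status"))
    ord <- order(-status)  # cases first, stable
    X <- X[ord, , drop = FALSE]
    status <- status[ord]
    n <- nrow(X)
    rownames(X) <- sprintf("id%05d", seq_len(n))

    # principal-component loadings are learned among controls and all
    # individuals are projected onto them: with case-control ascertainment
    # the case-enriched sample has inflated variance along the liability
    # direction, and in a compact synthetic genome (no population
    # structure) PCs computed on everyone would absorb disease signal
    # rather than act as ancestry covariates
    Xs <- scale(X)
    Xs[, !is.finite(colSums(Xs))] <- 0
    ctl <- status == 0L
    ncomp <- min(3L, ncol(X), max(1L, sum(ctl) - 1L))
    rot <- stats::prcomp(Xs[ctl, , drop = FALSE], rank. = ncomp)$rotation
    pcs <- Xs %*% rot
    pcs <- cbind(pcs, matrix(0, n, 3 - ncomp))[, 1:3, drop = FALSE]
    colnames(pcs) <- paste0("PC", 1:3)

    samples <- tibble::tibble(
      sample_id = rownames(X),
      status = as.integer(status),
      sex = stats::rbinom(n, 1L, 0.5),
      age = pmin(90, pmax(16, round(stats::rnorm(n, 45, 12)))),
      PC1 = pcs[, 1], PC2 = pcs[, 2], PC3 = pcs[, 3],
      hla_risk = hla_liability(X, architecture)
    )
    new_geno_matrix(X, variants, samples)
  })
}

#' Simulate the expression-GWAS cohort
#'
#' A cohort disjoint from the case-control study (its own random stream),
#' used as `panel_for_gwas` in [compute_summary_stats()]; mirrors the
#' two-sample structure in which summary statistics come from an external
#' meta-analysis.
#'
#' @param config A [sim_config()].
#' @return A `geno_matrix` with `n_gwas` individuals.
#' @export
simulate_gwas_cohort <- function(config) {
  validate_sim_config(config)
  variants <- variant_map(config)
  dos <- with_stream_seed(stream_seed(config$seed, 4L), {
    draw_genotypes(config$n_gwas, variants, config$block_correlation)
  })
  rownames(dos) <- sprintf("gw%05d", seq_len(config$n_gwas))
  new_geno_matrix(dos, variants,
                  tibble::tibble(sample_id = rownames(dos)))
}

#' Compute marginal expression-GWAS summary statistics
#'
#' Simulates expression for every gene in the GWAS cohort (genetic value plus
#' Gaussian noise at the configured heritability) and runs single-SNP
#' regressions. Mirrors the reporting restriction of large trans-eQTL
#' meta-analyses: every SNP within 5 Mb of a gene's transcription site is
#' reported for that gene (cis), but trans records are emitted only for a
#' restricted "trait-associated" SNP set -- all SNPs in blocks carrying
#' liability-linked effects, topped up with random SNPs to
#' `tested_snp_fraction` of the genome.
#'
#' @param panel_for_gwas A `geno_matrix` from [simulate_gwas_cohort()].
#' @param architecture A `true_architecture`.
#' @param config The shared [sim_config()].
#' @return Tibble of summary-stat records: variant_id, chrom, pos,
#'   effect_allele, other_allele, beta, se, pvalue, target_id, n.
#' @export
compute_summary_stats <- function(panel_for_gwas, architecture, config) {
  stopifnot(inherits(panel_for_gwas, "geno_matrix"),
            inherits(architecture, "true_architecture"))
  X <- panel_for_gwas$dosages
  variants <- panel_for_gwas$variants
  n <- nrow(X)
  mono <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(mono)) {
    message("skipping ", sum(mono), " monomorphic variant(s): ",
            paste(utils::head(colnames(X)[mono], 5), collapse = ", "))
    X <- X[, !mono, drop = FALSE]
    variants <- variants[!mono, , drop = FALSE]
  }
  gv <- gene_genetic_var(architecture)
  h2 <- config$expression_h2

  with_stream_seed(stream_seed(config$seed, 5L), {
    G <- genetic_expression(X, architecture)
    noise_sd <- sqrt(pmax(gv$gen_var, 1e-12) * (1 - h2) / h2)
    names(noise_sd) <- gv$gene_id
    Y <- G + sapply(colnames(G), function(g)
      stats::rnorm(n, 0, noise_sd[[g]]))

    # vectorized single-SNP regressions with intercept
    Xc <- scale(X, center = TRUE, scale = FALSE)
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    Sxx <- colSums(Xc^2)
    Syy <- colSums(Yc^2)
    SXY <- crossprod(Xc, Yc)                       # m x g
    beta <- sweep(SXY, 1, Sxx, "/")
    rss <- pmax(outer(rep(1, nrow(beta)), Syy) - beta^2 * Sxx, 0)
    se <- sqrt(rss / (n - 2) / Sxx)
    tval <- beta / se
    pval <- 2 * stats::pt(-abs(tval), df = n - 2)

    # reporting restriction
    trait_blocks <- union(
      unique(architecture$effects$block[architecture$effects$type == "trans"]),
      architecture$hla_effects$block)
    tested <- variants$block %in% trait_blocks
    want <- ceiling(config$tested_snp_fraction * nrow(variants))
    if (sum(tested) < want) {
      extra <- sample(which(!tested), want - sum(tested))
      tested[extra] <- TRUE
    }

    genes <- architecture$genes
    purrr::map_dfr(seq_len(nrow(genes)), function(g) {
      gid <- genes$gene_id[g]
      same_chr <- variants$chrom == genes$chrom[g]
      dist <- pmax(0, pmax(genes$site_start[g] - variants$pos,
                           variants$pos - genes$site_end[g]))
      cis_win <- same_chr & dist <= 5e6
      keep <- which(cis_win | tested)
      tibble::tibble(
        variant_id = variants$variant_id[keep],
        chrom = variants$chrom[keep],
        pos = variants$pos[keep],
        effect_allele = variants$effect_allele[keep],
        other_allele = variants$other_allele[keep],
        beta = beta[keep, gid],
        se = se[keep, gid],
        pvalue = pval[keep, gid],
        target_id = gid,
        n = n
      )
    })
  })
}
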