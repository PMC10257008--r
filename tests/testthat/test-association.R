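# Logistic score association, information for discrimination, per-SNP GWAS,
# the HLA risk score, the case-only interaction test, and control-group
# score correlations.

test_that("information for discrimination is half the squared log OR and
           sign-invariant", {
  expect_equal(info_discrimination(0.23), 0.23^2 / 2)
  expect_equal(info_discrimination(0), 0)
  expect_equal(info_discrimination(-0.23), info_discrimination(0.23))
})

test_that("score association recovers a known effect and reports the
           information", {
  set.seed(20)
  n <- 4000
  s <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 0.4 * s))
  r <- fit_score_association(s, y, score_id = "toy")
  expect_true(r$converged)
  expect_lt(abs(r$log_or - 0.4), 3 * r$se)
  expect_equal(r$info_discrimination, r$log_or^2 / 2)
  expect_identical(r$n_used, as.integer(n))
})

test_that("collinear covariates and separation are flagged, never silently
           estimated", {
  set.seed(21)
  n <- 300
  s <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, 0.5)
  r <- fit_score_association(s, y, covariates = data.frame(dup = s))
  expect_false(r$converged)

  # complete separation
  y2 <- as.integer(s > 0)
  r2 <- fit_score_association(s, y2)
  expect_false(r2$converged)
})

test_that("Wald and likelihood-ratio p-values agree within an order of
           magnitude on a well-conditioned fit", {
  set.seed(22)
  n <- 2000
  s <- stats::rnorm(n)
  covs <- data.frame(c1 = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(-0.3 + 0.25 * s))
  r <- fit_score_association(s, y, covs)
  dat <- data.frame(y = y, s = s, c1 = covs$c1)
  full <- stats::glm(y ~ s + c1, data = dat, family = stats::binomial())
  red <- stats::glm(y ~ c1, data = dat, family = stats::binomial())
  lrt_p <- stats::pchisq(red$deviance - full$deviance, df = 1,
                         lower.tail = FALSE)
  expect_lt(abs(log10(r$pvalue) - log10(lrt_p)), 1)
})

test_that("per-SNP association excludes rare SNPs and is null-calibrated
           under a permuted outcome", {
  set.seed(23)
  n <- 1500
  m <- 20
  dos <- matrix(stats::rbinom(n * m, 2, 0.3), n, m)
  dos[, 1] <- stats::rbinom(n, 2, 0.003)  # MAF 0.3%
  colnames(dos) <- sprintf("v%02d", 1:m)
  samples <- tibble::tibble(
    sample_id = sprintf("s%04d", 1:n),
    status = sample(stats::rbinom(n, 1, 0.4)),
    sex = stats::rbinom(n, 1, 0.5),
    age = stats::rnorm(n, 50, 10),
    PC1 = stats::rnorm(n), PC2 = stats::rnorm(n), PC3 = stats::rnorm(n))
  study <- make_geno(dos, samples = samples)
  res <- per_snp_association(study)
  expect_false("v01" %in% res$variant_id)
  expect_identical(nrow(res), as.integer(m - 1))
  # outcome permuted independently of genotypes: p uniform
  ks <- stats::ks.test(res$pvalue, "punif")
  expect_gt(ks$p.value, 1e-3)
})

test_that("a SNP generating the outcome ranks top within its block", {
  set.seed(24)
  n <- 2000
  dos <- transcores:::draw_block_dosages(n, 5, 0.3, 0.5)
  colnames(dos) <- sprintf("v%02d", 1:5)
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.5 * scale(dos[, 3])))
  samples <- tibble::tibble(
    sample_id = seq_len(n), status = y,
    sex = stats::rbinom(n, 1, 0.5), age = stats::rnorm(n, 50, 10),
    PC1 = stats::rnorm(n), PC2 = stats::rnorm(n), PC3 = stats::rnorm(n))
  study <- make_geno(dos, samples = samples)
  res <- per_snp_association(study)
  expect_identical(res$variant_id[which.min(res$pvalue)], "v03")
})

test_that("the HLA risk score learns main-effect weights within 3 SE and
           drops degenerate variables", {
  set.seed(25)
  n <- 6000
  tags <- sapply(c(0.3, 0.25, 0.2, 0.35, 0.4),
                 function(p) stats::rbinom(n, 2, p))
  true_b <- c(0.5, -0.4, 0.3, 0.2, -0.25)
  eta <- -0.5 + tags %*% true_b
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  h <- build_hla_score(tags, y)
  est <- tidy(h)
  for (j in 1:5) {
    row <- est[est$term == paste0("tag", j), ]
    expect_lt(abs(row$estimate - true_b[j]), 3 * row$se)
  }
  # the learned score separates cases from controls
  expect_gt(stats::cor(h$values, as.numeric(y)), 0.1)

  # outcome independent of tags: score-outcome correlation is noise
  y0 <- stats::rbinom(n, 1, 0.5)
  h0 <- build_hla_score(tags, y0)
  expect_lt(abs(stats::cor(h0$values, y0)), 3 / sqrt(n) * 3)

  # constant tag column: dropped with a warning, model refits on the rest
  tags2 <- tags
  tags2[, 3] <- 0
  expect_warning(h2 <- build_hla_score(tags2, y), "constant")
  expect_true("tag3" %in% h2$dropped)
  expect_false("tag3" %in% names(h2$weights))
})

test_that("the case-only interaction test is null under independence,
           detects induced dependence, and rejects degenerate input", {
  set.seed(26)
  # null: independent scores among cases, p uniform over replicates
  pvals <- replicate(200, {
    n <- 150
    case_only_interaction(stats::rnorm(n), stats::rnorm(n),
                          rep(TRUE, n))$pvalue
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 1e-3)

  # induced positive dependence among cases is detected
  n <- 600
  h <- stats::rnorm(n)
  t <- 0.35 * h + stats::rnorm(n, sd = sqrt(1 - 0.35^2))
  r <- case_only_interaction(t, h, rep(TRUE, n))
  expect_gt(r$slope, 0)
  expect_lt(r$pvalue, 1e-3)

  # all-control mask and constant scores are errors
  expect_error(case_only_interaction(stats::rnorm(50), stats::rnorm(50),
                                     rep(FALSE, 50)), "30 cases")
  expect_error(case_only_interaction(rep(1, 50), stats::rnorm(50),
                                     rep(TRUE, 50)), "constant")
})

test_that("control-group score correlations flag near-duplicates and self
           pairs", {
  set.seed(27)
  n <- 900
  a <- stats::rnorm(n)
  scores <- cbind(A = a, B = a + stats::rnorm(n, sd = 0.1),
                  C = stats::rnorm(n))
  ctl <- rep(c(TRUE, FALSE), length.out = n)
  pairs <- score_correlation_matrix(scores, ctl)
  self <- pairs[pairs$score_a == pairs$score_b, ]
  expect_true(all(self$r == 1) && all(self$flagged))
  ab <- pairs[pairs$score_a == "A" & pairs$score_b == "B", ]
  expect_true(ab$flagged)
  ac <- pairs[pairs$score_a == "A" & pairs$score_b == "C", ]
  expect_false(ac$flagged)
  expect_lt(abs(ac$r), 3 / sqrt(sum(ctl)))

  # constant score excluded with a warning
  scores2 <- cbind(scores, D = rep(2, n))
  expect_warning(p2 <- score_correlation_matrix(scores2, ctl), "constant")
  expect_false("D" %in% c(p2$score_a, p2$score_b))
})
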