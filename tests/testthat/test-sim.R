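test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_animals = 10, segment_length = 10000,
                    divergent_region = c(4000, 9000),
                    mean_coverage = 20, n_markers = 12, seed = 99)
  a <- sim_study(cfg)
  b <- sim_study(cfg)
  expect_identical(a$depth, b$depth)
  expect_identical(a$geno, b$geno)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$production, b$production)
})

test_that("depth panel: divergent homozygotes go near zero, others stay normal", {
  cfg <- sim_config(n_animals = 12, segment_length = 20000,
                    divergent_region = c(8000, 13000),
                    divergent_allele_freq = 1.0, mean_coverage = 30,
                    seed = 4)
  dp <- sim_depth_panel(cfg)
  expect_true(all(dp$truth$divergent_genotype == 2))
  inside <- dp$depth$window_start >= 8000 & dp$depth$window_end <= 13000
  outside <- dp$depth$window_end <= 8000 | dp$depth$window_start >= 13000
  expect_lt(mean(dp$depth$count[inside]), 0.05 * 30)
  expect_equal(mean(dp$depth$count[outside]), 30, tolerance = 0.05)
})

test_that("null depth panel matches the Poisson coverage model", {
  cfg <- sim_config(n_animals = 20, segment_length = 50000,
                    divergent_region = NULL, mean_coverage = 30, seed = 21)
  dp <- sim_depth_panel(cfg)
  n_obs <- nrow(dp$depth)
  # mean of n Poisson(30) window counts: 3 SE band
  se <- sqrt(30 / n_obs)
  expect_lt(abs(mean(dp$depth$count) - 30), 3 * se * 2)  # windows correlate in pairs
})

test_that("implanted duplication doubles fold depth relative to flanks", {
  cfg <- sim_config(n_animals = 20, segment_length = 30000,
                    divergent_region = NULL,
                    dup_regions = list(c(10000, 15000, 2)),
                    mean_coverage = 30, seed = 6)
  dp <- sim_depth_panel(cfg)
  inside <- dp$depth$window_start >= 10000 & dp$depth$window_end <= 15000
  outside <- dp$depth$window_end <= 10000 | dp$depth$window_start >= 15000
  ratio <- mean(dp$depth$count[inside]) / mean(dp$depth$count[outside])
  expect_equal(ratio, 2.0, tolerance = 0.05)
})

test_that("depth simulation rejects degenerate configurations", {
  expect_error(sim_config(mean_coverage = 0), "mean_coverage")
  expect_error(sim_config(n_animals = 0), "n_animals")
  expect_error(sim_config(dup_regions = list(c(0, 1000, 0.5))), "fold-gain")
  expect_error(sim_config(divergent_allele_freq = 1.2), "divergent_allele_freq")
})

test_that("tag marker hits its target r2 across the range", {
  truth_of <- function(n, freq, seed) {
    set.seed(seed)
    rbinom(n, 2, freq)
  }
  # perfect tag
  cfg1 <- sim_config(n_animals = 300, tag_r2 = 1.0, n_markers = 2, seed = 10)
  tr <- truth_of(300, 0.5, 1)
  g1 <- sim_genotypes(cfg1, tr)
  expect_identical(g1$calls$tag_snp, as.integer(tr))
  expect_equal(genotype_r2(g1$calls$tag_snp, tr), 1)

  # unlinked tag
  cfg0 <- sim_config(n_animals = 1000, tag_r2 = 0.0, n_markers = 2, seed = 11)
  tr0 <- truth_of(1000, 0.5, 2)
  g0 <- sim_genotypes(cfg0, tr0)
  expect_lt(genotype_r2(g0$calls$tag_snp, tr0), 0.05)

  # strong but imperfect LD, the regime of a tag SNP on a divergent haplotype
  cfg97 <- sim_config(n_animals = 1000, tag_r2 = 0.97, n_markers = 2,
                      seed = 12)
  tr97 <- truth_of(1000, 0.5, 3)
  g97 <- sim_genotypes(cfg97, tr97)
  r2 <- genotype_r2(g97$calls$tag_snp, tr97)
  expect_gte(r2, 0.92)
  expect_lte(r2, 1.0)
})

test_that("generated background genotypes respect Hardy-Weinberg", {
  # exact-test p-values approximately uniform over seeded replicates
  ps <- vapply(1:300, function(s) {
    set.seed(s)
    calls <- rbinom(60, 2, runif(1, 0.1, 0.5))
    cnt <- table(factor(calls, 0:2))
    hwe_exact_p(cnt[["2"]], cnt[["1"]], cnt[["0"]])
  }, numeric(1))
  # the exact-test p is discrete and conservative, so uniformity is checked
  # as level calibration: rejection mass never exceeds the nominal level
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps < alpha), alpha + 2 * sqrt(alpha * (1 - alpha) / 300))
  }
  # and the bulk of the distribution is not shifted low
  expect_gt(median(ps), 0.25)
})

test_that("phenotype generator recovers its inputs", {
  # null genotype effect, no sire variance: trait variance ~ residual
  cfg <- sim_config(n_animals = 1000, causal_effect = 0, sire_variance = 0,
                    residual_variance = 4, seed = 31)
  ph <- sim_phenotypes(cfg, rep(1L, 1000), breeds = rep("Polypay", 1000),
                       ages = rep(3, 1000))
  expect_equal(var(ph$trait), 4, tolerance = 0.4)

  # planted per-genotype means are recovered within 3 SE
  cfg2 <- sim_config(n_animals = 900, sire_variance = 0,
                     residual_variance = 0.25, seed = 32)
  g <- rep(0:2, each = 300)
  ph2 <- sim_phenotypes(cfg2, g, breeds = rep("Polypay", 900),
                        ages = rep(0, 900),
                        geno_means = c(36.1, 34.3, 33.9), intercept = 36.1,
                        breed_effects = c(Polypay = 0))
  means <- tapply(ph2$trait, ph2$genotype, mean)
  se <- 0.5 / sqrt(300)
  expect_true(all(abs(means - c(36.1, 34.3, 33.9)) < 3 * se))
})

test_that("sire and residual variances set the intraclass correlation", {
  cfg <- sim_config(n_animals = 1000, sire_variance = 2,
                    residual_variance = 2, causal_effect = 0, seed = 33)
  sires <- rep(sprintf("s%02d", 1:50), each = 20)
  ph <- sim_phenotypes(cfg, rep(0L, 1000), breeds = rep("Polypay", 1000),
                       ages = rep(3, 1000), sires = sires)
  est <- balanced_anova_reml(ph$trait, factor(ph$sire_id))
  icc <- est["sigma2_s"] / sum(est)
  expect_equal(unname(icc), 0.5, tolerance = 0.1)
})
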