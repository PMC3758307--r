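sim_balanced_sires <- function(n_sires, per_sire, s2s, s2e, seed,
                               mu = 100) {
  set.seed(seed)
  sire <- rep(sprintf("s%02d", 1:n_sires), each = per_sire)
  u <- rnorm(n_sires, 0, sqrt(s2s))
  y <- mu + u[as.integer(factor(sire))] + rnorm(length(sire), 0, sqrt(s2e))
  tibble::tibble(animal_id = as.character(seq_along(y)), trait = y,
                 sire_id = sire)
}

test_that("REML on a balanced one-way design equals the ANOVA closed form", {
  for (seed in c(1, 2, 3)) {
    d <- sim_balanced_sires(30, 10, s2s = 2, s2e = 3, seed = seed)
    fit <- fit_trait_mixed(d, "trait", genotype = NULL, fixed = character(),
                           sire = "sire_id", sire_breed = NULL)
    oracle <- balanced_anova_reml(d$trait, factor(d$sire_id))
    expect_equal(fit$sigma2_e, unname(oracle["sigma2_e"]), tolerance = 1e-6)
    expect_equal(fit$sigma2_s, unname(oracle["sigma2_s"]), tolerance = 1e-6)
  }
})

test_that("REML matches lme4 on an unbalanced design with fixed effects", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_animals = 400, sire_variance = 2, residual_variance = 2,
                    seed = 3)
  set.seed(9)
  pr <- sim_production_traits(cfg, rbinom(400, 2, 0.5))
  fit <- fit_trait_mixed(pr, "trait", covariates = "age_at_last_lambing")
  m <- lme4::lmer(
    trait ~ factor(genotype) + breed + factor(birth_year) +
      age_at_last_lambing + (1 | sire_id),
    data = pr, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(fit$sigma2_s, vc[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_e, vc[2], tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(lme4::fixef(m)), tolerance = 1e-6)
})

test_that("zero sire variance hits the boundary and reduces to OLS", {
  d <- sim_balanced_sires(50, 20, s2s = 0, s2e = 1, seed = 11)
  fit <- fit_trait_mixed(d, "trait", genotype = NULL, fixed = character(),
                         sire = "sire_id", sire_breed = NULL)
  expect_lte(fit$sigma2_s, 0.05 * fit$sigma2_e)
  # with the boundary enforced, fixed effects equal OLS exactly
  d$genotype <- rep(0:1, length.out = nrow(d))
  fit0 <- fit_trait_mixed(d, "trait", fixed = character(), sire = "sire_id",
                          sire_breed = NULL)
  if (fit0$boundary) {
    ols <- lm(trait ~ factor(genotype), data = d)
    expect_equal(unname(fit0$beta), unname(coef(ols)), tolerance = 1e-10)
  }
})

test_that("REML variance components are invariant to fixed-effect recoding", {
  cfg <- sim_config(n_animals = 300, sire_variance = 1.5,
                    residual_variance = 2, seed = 8)
  set.seed(80)
  pr <- sim_production_traits(cfg, rbinom(300, 2, 0.4))
  f1 <- fit_trait_mixed(pr, "trait")
  pr2 <- pr
  pr2$breed <- factor(pr2$breed, levels = rev(sort(unique(pr2$breed))))
  f2 <- fit_trait_mixed(pr2, "trait")
  expect_equal(f1$sigma2_s, f2$sigma2_s, tolerance = 1e-6)
  expect_equal(f1$sigma2_e, f2$sigma2_e, tolerance = 1e-6)
  expect_equal(f1$adjusted_means$adjusted_mean,
               f2$adjusted_means$adjusted_mean, tolerance = 1e-8)
})

test_that("Tukey-Kramer with k = 2 equals the two-sided t-test", {
  est <- c(0.5, 1.7, -2.3)
  se <- c(0.3, 0.8, 1.1)
  df <- 40
  expect_equal(tukey_kramer_p(est, se, k = 2, df = df),
               2 * pt(abs(est / se), df, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(tukey_kramer_p(0, 1, k = 3, df = 10), 1)
  expect_error(tukey_kramer_p(1, 1, k = 3, df = 0), "df")
})

test_that("Tukey-Kramer k = 3 matches a Monte-Carlo studentized range", {
  q_obs <- sqrt(2) * abs(1.1) / 0.4
  p_pkg <- tukey_kramer_p(1.1, 0.4, k = 3, df = 25)
  set.seed(202)
  n_mc <- 100000
  draws <- matrix(rnorm(3 * n_mc), ncol = 3)
  s <- sqrt(stats::rchisq(n_mc, 25) / 25)
  rng <- (apply(draws, 1, max) - apply(draws, 1, min)) / s
  p_mc <- mean(rng >= q_obs)
  expect_lt(abs(p_pkg - p_mc), 0.005)
})

test_that("adjusted means and SEs match emmeans on the full model", {
  skip_if_not_installed("emmeans")
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_animals = 350, sire_variance = 1, residual_variance = 2,
                    seed = 17)
  set.seed(170)
  pr <- sim_production_traits(cfg, rbinom(350, 2, 0.5))
  fit <- fit_trait_mixed(pr, "trait", covariates = "age_at_last_lambing")
  m <- lme4::lmer(
    trait ~ genotype + breed + factor(birth_year) + age_at_last_lambing +
      (1 | sire_id),
    data = dplyr::mutate(pr, genotype = factor(genotype)), REML = TRUE)
  em <- as.data.frame(emmeans::emmeans(m, "genotype"))
  expect_equal(fit$adjusted_means$adjusted_mean, em$emmean, tolerance = 1e-4)
  expect_equal(fit$adjusted_means$se, em$SE, tolerance = 1e-3)
})

test_that("a planted 15.5-unit genotype contrast is recovered", {
  ests <- vapply(1:30, function(s) {
    cfg <- sim_config(n_animals = 400, sire_variance = 4,
                      residual_variance = 25, divergent_allele_freq = 0.7,
                      seed = 5000 + s)
    set.seed(s)
    g <- rbinom(400, 2, 0.7)
    pr <- sim_production_traits(cfg, g,
                                geno_means = c(225.6, 225.6, 241.1))
    fit <- fit_trait_mixed(pr, "trait", covariates = "age_at_last_lambing")
    ct <- genotype_contrasts(fit)
    ct$estimate[ct$level_1 == "1" & ct$level_2 == "2"]
  }, numeric(1))
  expect_equal(mean(ests), 15.5, tolerance = 3 * sd(ests) / sqrt(30))
  expect_lt(abs(mean(ests) - 15.5), 1)
})

test_that("trait_report flags sparse genotype classes and shapes output", {
  cfg <- sim_config(n_animals = 250, sire_variance = 1, residual_variance = 4,
                    divergent_allele_freq = 0.85, seed = 23)
  set.seed(230)
  # reference homozygotes (genotype 0) rare at freq 0.85
  g <- rbinom(250, 2, 0.85)
  pr <- sim_production_traits(cfg, g)
  rep1 <- trait_report(pr, traits = "trait", min_group_n = 10)
  expect_setequal(names(rep1)[1:5],
                  c("trait", "mean_1", "mean_2", "sigma2_sire",
                    "sigma2_residual"))
  sparse_rows <- rep1$level_1 == "0" | rep1$level_2 == "0"
  if (sum(g == 0) < 10) expect_true(all(rep1$insufficient_n[sparse_rows]))
  expect_false(any(rep1$insufficient_n[!sparse_rows]))
  # adjusted means are reported even for sparse classes
  expect_equal(nrow(rep1), choose(length(unique(g)), 2))
})

test_that("two observed genotype levels give a single contrast row", {
  cfg <- sim_config(n_animals = 200, sire_variance = 1, residual_variance = 2,
                    seed = 29)
  set.seed(290)
  g <- rbinom(200, 1, 0.5) + 1L  # only levels 1 and 2
  pr <- sim_production_traits(cfg, g)
  fit <- fit_trait_mixed(pr, "trait")
  ct <- genotype_contrasts(fit)
  expect_equal(nrow(ct), 1)
  # antisymmetry under level swap
  expect_equal(ct$estimate,
               -(fit$adjusted_means$adjusted_mean[1] -
                   fit$adjusted_means$adjusted_mean[2]))
})

test_that("null traits keep family-wise error controlled", {
  sig <- vapply(1:30, function(s) {
    cfg <- sim_config(n_animals = 150, sire_variance = 1,
                      residual_variance = 4, seed = 7000 + s)
    set.seed(s)
    g <- rbinom(150, 2, 0.5)
    pr <- sim_production_traits(cfg, g, geno_means = c(0, 0, 0))
    ct <- genotype_contrasts(fit_trait_mixed(pr, "trait"))
    any(ct$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(sig), 0.2)
})
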