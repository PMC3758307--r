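make_pheno <- function(n, y) {
  tibble::tibble(animal_id = sprintf("a%04d", 1:n), trait = y)
}
make_geno <- function(n, ...) {
  tibble::tibble(animal_id = sprintf("a%04d", 1:n), ...)
}

test_that("genotype encodings follow the mode of inheritance", {
  calls <- c(0L, 1L, 2L, 2L, 2L)  # allele A frequency 0.7 -> minor is "a"
  add <- encode_genotype(calls, "additive")
  expect_equal(as.numeric(add), c(2, 1, 0, 0, 0))  # copies of minor allele
  dom <- encode_genotype(calls, "dominant")
  expect_equal(as.numeric(dom), c(1, 1, 0, 0, 0))
  rec <- encode_genotype(calls, "recessive")
  expect_equal(as.numeric(rec), c(1, 0, 0, 0, 0))
  gen <- encode_genotype(calls, "genotypic")
  expect_equal(unname(gen[, "g_het"]), c(0, 1, 0, 0, 0))
  expect_equal(unname(gen[, "g_hom"]), c(1, 0, 0, 0, 0))
  # minor-allele flip: when A is minor, additive counts A copies directly
  calls2 <- c(0L, 0L, 0L, 1L, 2L)
  expect_equal(as.numeric(encode_genotype(calls2, "additive")), c(0, 0, 0, 1, 2))
  expect_null(encode_genotype(rep(1L, 5), "additive"))
})

test_that("a noiseless additive signal is recovered essentially exactly", {
  set.seed(41)
  n <- 120
  g <- rbinom(n, 2, 0.3)
  y <- 3 + 0.75 * g
  sc <- suppressWarnings(  # lm warns on an essentially perfect fit
    assoc_scan(make_pheno(n, y), make_geno(n, m1 = g), "trait",
               models = "additive"))
  expect_equal(abs(sc$beta[[1]]), 0.75, tolerance = 1e-10)
  expect_equal(sc$p_nominal, 1e-300)  # underflow guard floor
  expect_equal(sc$effect_size, 1.5, tolerance = 1e-10)
  expect_equal(sc$tier, "genome_wide_significant")
})

test_that("null markers are calibrated at the 5% level", {
  set.seed(55)
  n <- 150
  y <- rnorm(n)
  geno <- make_geno(n)
  for (j in 1:2000) geno[[sprintf("m%04d", j)]] <- rbinom(n, 2, 0.3)
  sc <- assoc_scan(make_pheno(n, y), geno, "trait", models = "additive")
  expect_lt(abs(mean(sc$p_nominal < 0.05) - 0.05), 0.012)
  expect_gt(genomic_lambda(sc$p_nominal), 0.9)
  expect_lt(genomic_lambda(sc$p_nominal), 1.1)
})

test_that("genotypic 2-df F test equals the matrix-algebra oracle", {
  set.seed(66)
  for (rep in 1:8) {
    n <- 60
    g <- rbinom(n, 2, 0.4)
    cov1 <- rnorm(n)
    y <- rnorm(n) + 0.3 * cov1 + 0.2 * (g == 1)
    pheno <- make_pheno(n, y)
    pheno$cov1 <- cov1
    sc <- assoc_scan(pheno, make_geno(n, m = g), "trait",
                     covariates = "cov1", models = "genotypic")
    enc <- encode_genotype(g, "genotypic")
    p_oracle <- partial_f_oracle(y, cbind(1, cov1), enc)
    expect_equal(sc$p_nominal, p_oracle, tolerance = 1e-10)
  }
})

test_that("best_model picks the minimum p with the fixed tie order", {
  rec <- tibble::tibble(
    marker = "m", model = c("additive", "genotypic", "dominant", "recessive"),
    n_used = 10L, beta = list(0), p_nominal = c(1e-3, 1e-7, 1e-4, 0.2),
    effect_size = 1, tier = "none"
  )
  expect_equal(best_model(rec)$model, "genotypic")
  rec$p_nominal <- rep(0.5, 4)
  expect_equal(best_model(rec)$model, "additive")
  expect_equal(best_model(rec[3, ])$model, "dominant")
})

test_that("tier assignment uses p <= sig and p < suggestive", {
  expect_equal(assign_tier(6.2e-14), "genome_wide_significant")
  expect_equal(assign_tier(5e-8), "genome_wide_significant")
  expect_equal(assign_tier(2.5e-6), "suggestive")
  expect_equal(assign_tier(1e-5), "none")
  expect_equal(assign_tier(1e-4), "none")
})

test_that("effect size is invariant to allele flips and covariate recentring", {
  set.seed(91)
  n <- 200
  g <- rbinom(n, 2, 0.35)
  age <- runif(n, 1, 8)
  y <- 30 + 0.4 * age + 0.9 * g + rnorm(n)
  ph <- make_pheno(n, y); ph$age <- age
  ph2 <- ph; ph2$age <- age - 50
  sc1 <- assoc_scan(ph, make_geno(n, m = g), "trait", covariates = "age")
  scf <- assoc_scan(ph, make_geno(n, m = 2L - g), "trait", covariates = "age")
  sc2 <- assoc_scan(ph2, make_geno(n, m = g), "trait", covariates = "age")
  expect_equal(sc1$effect_size, scf$effect_size, tolerance = 1e-9)
  expect_equal(sc1$effect_size, sc2$effect_size, tolerance = 1e-9)
  expect_equal(sc1$p_nominal, scf$p_nominal, tolerance = 1e-9)
})

test_that("injected genotypic means reproduce a 2.2-unit effect size", {
  cfg <- sim_config(n_animals = 500, sire_variance = 0,
                    residual_variance = 0.25, divergent_allele_freq = 0.5,
                    n_markers = 2, seed = 14)
  set.seed(140)
  g <- rbinom(500, 2, 0.5)
  ph <- sim_phenotypes(cfg, g, geno_means = c(36.1, 34.3, 33.9),
                       intercept = 36.1)
  geno <- make_geno(500, s_tag = g)
  names(ph)[1] <- "animal_id"
  ph$animal_id <- geno$animal_id
  sc <- assoc_scan(ph, geno, "trait", covariates = c("breed", "age"),
                   models = "genotypic")
  # planted spread |36.1 - 33.9| = 2.2
  expect_equal(sc$effect_size, 2.2, tolerance = 3 * 0.1)
  expect_equal(sc$tier, "genome_wide_significant")
})

test_that("conditioning on the causal marker removes the tag association", {
  flattened <- vapply(1:20, function(s) {
    cfg <- sim_config(n_animals = 300, n_markers = 40, tag_r2 = 0.97,
                      causal_effect = 0.8, sire_variance = 0,
                      residual_variance = 1, seed = 3000 + s)
    set.seed(s)
    truth <- rbinom(300, 2, 0.5)
    gt <- sim_genotypes(cfg, truth)
    ph <- sim_phenotypes(cfg, truth)
    geno <- dplyr::mutate(gt$calls, causal = truth)
    plain <- assoc_scan(ph, geno, "trait", covariates = c("breed", "age"),
                        models = "additive")
    cond <- assoc_scan(ph, geno, "trait", covariates = c("breed", "age"),
                       models = "additive", condition_on = "causal")
    p_tag_plain <- plain$p_nominal[plain$marker == "tag_snp"]
    p_tag_cond <- cond$p_nominal[cond$marker == "tag_snp"]
    p_tag_plain < 1e-5 && p_tag_cond > 1e-5
  }, logical(1))
  expect_gte(mean(flattened), 0.9)
})

test_that("conditioning on nothing reproduces the plain scan", {
  set.seed(101)
  n <- 100
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.3)
  ph <- make_pheno(n, rnorm(n))
  geno <- make_geno(n, m1 = g1, m2 = g2)
  plain <- assoc_scan(ph, geno, "trait")
  cond <- assoc_scan(ph, geno, "trait", condition_on = character())
  expect_equal(plain, cond)
})

test_that("manhattan layout offsets chromosomes cumulatively", {
  map <- tibble::tibble(marker = c("m1", "m2", "m3"),
                        chrom = c("1", "1", "2"),
                        bp = c(100L, 5000L, 700L))
  rec <- tibble::tibble(marker = c("m1", "m2", "m3"),
                        p_nominal = c(0.01, 1, 1e-8))
  md <- manhattan_data(rec, map)
  expect_equal(md$cum_bp[md$marker == "m1"], 100)
  expect_equal(md$cum_bp[md$marker == "m3"], 5000 + 700)
  expect_equal(md$neg_log10_p[md$marker == "m2"], 0)

  qq <- qq_data(rec$p_nominal)
  expect_equal(nrow(qq), 3)
  expect_true(all(diff(qq$observed) >= 0))
})
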