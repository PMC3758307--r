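#' Simulate quantitative phenotypes with covariates and a sire random effect
#'
#' Trait model: intercept + breed effect + age slope x age + genotype effect +
#' sire random intercept ~ Normal(0, `sire_variance`) + residual ~ Normal(0,
#' `residual_variance`). The genotype effect is either additive
#' (`causal_effect` per allele copy) or an arbitrary per-genotype mean pattern
#' via `geno_means`, which permits the non-additive patterns seen in real
#' red-cell traits.
#'
#' @param cfg A [sim_config()] (supplies `causal_effect` and the variance
#'   components unless overridden).
#' @param genotype Integer vector of 0/1/2 allele copies, one per animal.
#' @param breeds Factor/character of breed labels (default: drawn from
#'   `cfg$breed_props`).
#' @param ages Numeric ages in years (default: uniform 1-8, rounded to 1
#'   decimal).
#' @param sires Sire labels (default: animals assigned to `n_animals %/% 10 +
#'   1` sires within breed); `NULL` with `sire_variance = 0` gives a purely
#'   fixed-effects trait.
#' @param geno_means Optional length-3 numeric: trait mean for genotype 0, 1,
#'   2 copies (overrides the additive `causal_effect` parameterisation).
#' @param intercept Baseline trait value (default 34, a red-cell
#'   concentration-like scale).
#' @param breed_effects Named numeric of breed offsets (defaults to small
#'   fixed offsets per configured breed).
#' @param age_slope Trait units per year of age (default 0.05).
#' @param stream Seed-stream label, so repeated calls under one config can
#'   draw independent phenotypes.
#' @return Tibble: `animal_id`, `trait`, `genotype`, `breed`, `age`, `sire_id`.
#' @export
sim_phenotypes <- function(cfg, genotype, breeds = NULL, ages = NULL,
                           sires = NULL, geno_means = NULL, intercept = 34,
                           breed_effects = NULL, age_slope = 0.05,
                           stream = "phenotypes") {
  validate_sim_config(cfg)
  n <- length(genotype)
  abort_if(n != cfg$n_animals,
           "sim_phenotypes(): genotype length must equal n_animals")
  abort_if(cfg$sire_variance < 0 || cfg$residual_variance < 0,
           "sim_phenotypes(): variances must be >= 0")
  set.seed(derive_seed(cfg$seed, stream))
  ids <- sprintf("animal_%03d", seq_len(n))

  breed_names <- names(cfg$breed_props)
  if (is.null(breeds)) {
    breeds <- sample(breed_names, n, replace = TRUE, prob = cfg$breed_props)
  }
  abort_if(length(breeds) != n, "sim_phenotypes(): breeds length mismatch")
  if (is.null(ages)) ages <- round(runif(n, 1, 8), 1)
  abort_if(length(ages) != n, "sim_phenotypes(): ages length mismatch")
  if (is.null(sires)) {
    n_sires <- max(1L, n %/% 10L)
    sires <- paste0(breeds, "_sire_",
                    sample.int(n_sires, n, replace = TRUE))
  }
  abort_if(length(sires) != n, "sim_phenotypes(): sires length mismatch")

  if (is.null(breed_effects)) {
    breed_effects <- setNames(seq_along(breed_names) * 0.3, breed_names)
  }
  g_eff <- if (is.null(geno_means)) {
    cfg$causal_effect * genotype
  } else {
    abort_if(length(geno_means) != 3, "sim_phenotypes(): geno_means must have length 3")
    geno_means[genotype + 1L] - intercept
  }

  sire_levels <- unique(sires)
  u <- setNames(rnorm(length(sire_levels), 0, sqrt(cfg$sire_variance)),
                sire_levels)
  trait <- intercept + unname(breed_effects[breeds]) + age_slope * ages +
    g_eff + u[sires] + rnorm(n, 0, sqrt(cfg$residual_variance))

  tibble::tibble(animal_id = ids, trait = unname(trait),
                 genotype = as.integer(genotype),
                 breed = as.character(breeds), age = ages,
                 sire_id = as.character(sires))
}

#' Simulate a production-trait table with sire nested within sire breed
#'
#' Emulates lifetime production records: fixed effects of birth year, breed
#' and marker genotype, an age-at-last-lambing covariate, and a random sire
#' intercept where sires are identified uniquely inside each sire breed.
#'
#' @inheritParams sim_phenotypes
#' @param n_sires Number of sires (default `max(2, n %/% 20)`), split across
#'   breeds.
#' @param birth_years Candidate birth years (sampled uniformly).
#' @return Tibble: `animal_id`, `trait`, `genotype`, `breed`, `birth_year`,
#'   `sire_id`, `sire_breed`, `age_at_last_lambing`.
#' @export
sim_production_traits <- function(cfg, genotype, geno_means = c(225.6, 225.6,
                                                                241.1),
                                  n_sires = NULL,
                                  birth_years = 2005:2009,
                                  stream = "production") {
  validate_sim_config(cfg)
  n <- length(genotype)
  abort_if(n != cfg$n_animals,
           "sim_production_traits(): genotype length must equal n_animals")
  set.seed(derive_seed(cfg$seed, stream))
  ids <- sprintf("animal_%03d", seq_len(n))
  breed_names <- names(cfg$breed_props)
  breeds <- sample(breed_names, n, replace = TRUE, prob = cfg$breed_props)
  if (is.null(n_sires)) n_sires <- max(2L, n %/% 20L)
  sire_breed_of <- sample(breed_names, n_sires, replace = TRUE)
  sire_idx <- sample.int(n_sires, n, replace = TRUE)
  sire_breed <- sire_breed_of[sire_idx]
  sire_id <- paste0(sire_breed, "_s", sire_idx)  # unique within sire breed
  birth_year <- sample(birth_years, n, replace = TRUE)
  all_age <- round(runif(n, 3, 8), 1)

  u <- rnorm(n_sires, 0, sqrt(cfg$sire_variance))
  year_eff <- setNames(seq_along(birth_years) * 0.5, birth_years)
  breed_eff <- setNames(seq_along(breed_names) * 2, breed_names)
  trait <- geno_means[genotype + 1L] +
    unname(year_eff[as.character(birth_year)]) +
    unname(breed_eff[breeds]) + 1.5 * (all_age - mean(all_age)) +
    u[sire_idx] + rnorm(n, 0, sqrt(cfg$residual_variance))

  tibble::tibble(animal_id = ids, trait = unname(trait),
                 genotype = as.integer(genotype), breed = breeds,
                 birth_year = as.integer(birth_year), sire_id = sire_id,
                 sire_breed = sire_breed, age_at_last_lambing = all_age)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running the depth, genotype and phenotype generators
#' under one configuration, returning every input the analysis pipeline
#' consumes.
#'
#' @param cfg A [sim_config()].
#' @param geno_means Optional per-genotype phenotype means passed to
#'   [sim_phenotypes()] (indexed by copies of the divergent allele).
#' @return List with `depth`, `grid`, `truth`, `geno` (calls + map),
#'   `pheno`, `production`.
#' @export
sim_study <- function(cfg, geno_means = NULL) {
  dp <- sim_depth_panel(cfg)
  gt <- sim_genotypes(cfg, dp$truth$divergent_genotype)
  ph <- sim_phenotypes(cfg, dp$truth$divergent_genotype,
                       geno_means = geno_means)
  pr <- sim_production_traits(cfg, dp$truth$divergent_genotype)
  list(depth = dp$depth, grid = dp$grid, truth = dp$truth, geno = gt,
       pheno = ph, production = pr)
}
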