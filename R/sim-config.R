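#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the synthetic cohort: the depth panel (segment,
#' coverage, implanted duplications and a divergent non-mapping region), the
#' genotype panel (background markers plus one tag SNP in controlled LD with
#' the divergent locus), and the phenotype model (breed/age covariates,
#' genotype effects, a sire random effect).
#'
#' @param n_animals Number of animals.
#' @param segment_length Simulated segment length in bp.
#' @param read_length Read length in bp (reads are represented by their start
#'   positions; length only bounds placement).
#' @param mean_coverage Expected read-start count per 200 bp window at copy
#'   number two.
#' @param dup_regions List of `c(start, end, fold)` duplication implants;
#'   `fold` > 1.
#' @param divergent_region `c(start, end)` of the non-mapping divergent
#'   haplotype, or `NULL` for none.
#' @param divergent_allele_freq Population frequency of the divergent allele;
#'   genotypes are drawn in Hardy-Weinberg proportions.
#' @param dup_carrier_freq Fraction of animals carrying each implanted
#'   duplication (default 1: all animals).
#' @param het_depth_factor,hom_depth_factor Depth multipliers inside the
#'   divergent region for heterozygotes (one mappable haplotype, default 0.5)
#'   and divergent homozygotes (default 0.02).
#' @param n_markers Number of biallelic markers (including the tag SNP).
#' @param tag_r2 Target squared correlation between the tag SNP and the
#'   divergent-locus genotype.
#' @param causal_effect Additive trait effect per divergent allele (trait
#'   units); ignored when `geno_means` is given to [sim_phenotypes()].
#' @param breed_props Named breed proportions summing to 1.
#' @param sire_variance,residual_variance Variance components (trait units
#'   squared).
#' @param window,step Depth-grid geometry in bp.
#' @param seed Integer master seed; every generator derives its own stream
#'   from it deterministically.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_animals = 20L,
                       segment_length = 100000L,
                       read_length = 101L,
                       mean_coverage = 30,
                       dup_regions = list(),
                       divergent_region = c(40000L, 90000L),
                       divergent_allele_freq = 0.5,
                       dup_carrier_freq = 1,
                       het_depth_factor = 0.5,
                       hom_depth_factor = 0.02,
                       n_markers = 50L,
                       tag_r2 = 0.97,
                       causal_effect = 1,
                       breed_props = c(Columbia = 0.13, Polypay = 0.38,
                                       Rambouillet = 0.49),
                       sire_variance = 1,
                       residual_variance = 1,
                       window = 200L,
                       step = 100L,
                       seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals),
              segment_length = as.integer(segment_length),
              read_length = as.integer(read_length),
              mean_coverage = mean_coverage,
              dup_regions = dup_regions,
              divergent_region = divergent_region,
              divergent_allele_freq = divergent_allele_freq,
              dup_carrier_freq = dup_carrier_freq,
              het_depth_factor = het_depth_factor,
              hom_depth_factor = hom_depth_factor,
              n_markers = as.integer(n_markers),
              tag_r2 = tag_r2,
              causal_effect = causal_effect,
              breed_props = breed_props,
              sire_variance = sire_variance,
              residual_variance = residual_variance,
              window = as.integer(window),
              step = as.integer(step),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  abort_if(cfg$n_animals < 1, "sim_config: n_animals must be >= 1")
  abort_if(cfg$mean_coverage <= 0, "sim_config: mean_coverage must be > 0")
  abort_if(cfg$divergent_allele_freq < 0 || cfg$divergent_allele_freq > 1,
           "sim_config: divergent_allele_freq must lie in [0, 1]")
  abort_if(cfg$tag_r2 < 0 || cfg$tag_r2 > 1,
           "sim_config: tag_r2 must lie in [0, 1]")
  abort_if(cfg$sire_variance < 0 || cfg$residual_variance < 0,
           "sim_config: variances must be >= 0")
  abort_if(abs(sum(cfg$breed_props) - 1) > 1e-9,
           "sim_config: breed_props must sum to 1")
  for (d in cfg$dup_regions) {
    abort_if(length(d) != 3 || d[1] < 0 || d[2] > cfg$segment_length ||
               d[2] <= d[1], "sim_config: dup region outside segment")
    abort_if(d[3] <= 1, "sim_config: dup fold-gain must be > 1")
  }
  if (!is.null(cfg$divergent_region)) {
    abort_if(cfg$divergent_region[1] < 0 ||
               cfg$divergent_region[2] > cfg$segment_length ||
               cfg$divergent_region[2] <= cfg$divergent_region[1],
             "sim_config: divergent_region outside segment")
  }
  invisible(cfg)
}
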