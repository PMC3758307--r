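#' Simulate a multi-animal read-depth panel
#'
#' Draws read-start positions per animal from a piecewise-constant Poisson
#' process and counts them on the sliding-window grid with [count_windows()],
#' so overlapping windows carry the correlation real counting induces. The
#' base rate gives an expected count of `mean_coverage` per window; implanted
#' duplications multiply the rate by their fold-gain for carrier animals, and
#' the divergent region multiplies it by `hom_depth_factor` (near zero) for
#' divergent homozygotes and `het_depth_factor` for heterozygotes, emulating
#' a haplotype too diverged for reads to map.
#'
#' @param cfg A [sim_config()].
#' @return List:
#' \describe{
#'   \item{depth}{long depth tibble (`animal_id`, `window`, `window_start`,
#'     `window_end`, `count`)}
#'   \item{grid}{the window grid}
#'   \item{truth}{tibble `animal_id`, `divergent_genotype` (0/1/2 copies of
#'     the divergent allele, Hardy-Weinberg at `divergent_allele_freq`),
#'     `dup_carrier` (logical, recycled over dup regions)}
#' }
#' @export
sim_depth_panel <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, "depth_panel"))
  ids <- sprintf("animal_%03d", seq_len(cfg$n_animals))
  grid <- window_grid(0L, cfg$segment_length, cfg$window, cfg$step)

  divergent_genotype <- rbinom(cfg$n_animals, 2L, cfg$divergent_allele_freq)
  dup_carrier <- runif(cfg$n_animals) < cfg$dup_carrier_freq
  rate0 <- cfg$mean_coverage / cfg$window  # read starts per bp at copy 2

  reads <- purrr::map_dfr(seq_len(cfg$n_animals), function(i) {
    breaks <- sort(unique(c(
      0, cfg$segment_length,
      unlist(lapply(cfg$dup_regions, function(d) d[1:2])),
      cfg$divergent_region
    )))
    starts <- purrr::map(seq_len(length(breaks) - 1L), function(k) {
      lo <- breaks[k]; hi <- breaks[k + 1L]
      f <- 1
      if (dup_carrier[i]) {
        for (d in cfg$dup_regions) if (lo >= d[1] && hi <= d[2]) f <- f * d[3]
      }
      if (!is.null(cfg$divergent_region) &&
          lo >= cfg$divergent_region[1] && hi <= cfg$divergent_region[2]) {
        f <- f * switch(divergent_genotype[i] + 1L, 1,
                        cfg$het_depth_factor, cfg$hom_depth_factor)
      }
      n <- rpois(1L, rate0 * f * (hi - lo))
      if (n == 0L) return(numeric(0))
      floor(runif(n, lo, hi))
    })
    pos <- unlist(starts)
    pos <- pos[pos < grid$end[nrow(grid)]]  # grid may not tile the last bp
    if (length(pos) == 0L) return(NULL)
    tibble::tibble(animal_id = ids[i], start = as.integer(pos))
  })
  abort_if(nrow(reads) == 0L, "sim_depth_panel(): empty panel (no reads drawn)")

  depth <- count_windows(reads, grid, animal_ids = ids)
  truth <- tibble::tibble(animal_id = ids,
                          divergent_genotype = divergent_genotype,
                          dup_carrier = dup_carrier)
  list(depth = depth, grid = grid, truth = truth)
}
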