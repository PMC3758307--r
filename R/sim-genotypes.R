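#' Simulate an LD-structured genotype panel
#'
#' Generates `n_markers` biallelic markers for the animals in
#' `divergent_truth`. Background markers are drawn independently per animal in
#' Hardy-Weinberg proportions at marker-specific allele frequencies uniform on
#' `[0.05, 0.5]`. One designated tag marker (`tag_snp`, placed 20 kb from the
#' divergent region on the marker map) is constructed from the divergent-locus
#' genotypes by random per-animal resampling: each animal's tag genotype is
#' either copied from the truth or redrawn from Hardy-Weinberg, with the
#' resampling probability set to `1 - sqrt(tag_r2)` and rejection until the
#' realised squared correlation is within tolerance of the target.
#'
#' @param cfg A [sim_config()].
#' @param divergent_truth Integer vector (one per animal) of divergent-allele
#'   copies 0/1/2, e.g. `sim_depth_panel(cfg)$truth$divergent_genotype`.
#' @param tol Acceptance half-width on realised r-squared (default 0.02;
#'   best draw kept after `max_tries` rejections).
#' @param max_tries Rejection-sampling cap (default 200).
#' @return List:
#' \describe{
#'   \item{calls}{tibble `animal_id` + one integer column per marker, calls in
#'     `{0, 1, 2}` counting copies of allele A}
#'   \item{map}{tibble `marker`, `chrom`, `bp`, `allele_a`, `allele_b`}
#' }
#' @export
sim_genotypes <- function(cfg, divergent_truth, tol = 0.02, max_tries = 200L) {
  validate_sim_config(cfg)
  n <- length(divergent_truth)
  abort_if(n != cfg$n_animals,
           "sim_genotypes(): divergent_truth length must equal n_animals")
  set.seed(derive_seed(cfg$seed, "genotypes"))
  ids <- sprintf("animal_%03d", seq_len(n))

  n_bg <- cfg$n_markers - 1L
  abort_if(n_bg < 0L, "sim_genotypes(): n_markers must be >= 1")
  bg <- matrix(0L, nrow = n, ncol = n_bg)
  freqs <- runif(n_bg, 0.05, 0.5)
  for (j in seq_len(n_bg)) bg[, j] <- rbinom(n, 2L, freqs[j])

  tag <- sim_tag_marker(divergent_truth, cfg$tag_r2,
                        cfg$divergent_allele_freq, tol, max_tries)

  calls <- cbind(tag, bg)
  markers <- c("tag_snp", sprintf("bg_%04d", seq_len(n_bg)))
  colnames(calls) <- markers
  div_end <- if (is.null(cfg$divergent_region)) cfg$segment_length else
    cfg$divergent_region[2]
  map <- tibble::tibble(
    marker = markers,
    chrom = c("18", rep("1", n_bg)),
    bp = c(as.integer(div_end + 20000L), seq_len(n_bg) * 50000L),
    allele_a = "A",
    allele_b = "G"
  )
  calls_tbl <- tibble::as_tibble(as.data.frame(calls))
  calls_tbl <- dplyr::mutate(calls_tbl, animal_id = ids, .before = 1L)
  list(calls = calls_tbl, map = map)
}

# Tag construction: copy the truth genotype, then independently resample a
# fraction eps of animals from HWE at the divergent frequency. For the copied
# fraction 1 - eps the correlation with truth is 1, so cor ~ (1 - eps) and
# r2 ~ (1 - eps)^2; eps = 1 - sqrt(target). Rejection keeps the draw whose
# realised r2 is closest to target, stopping early inside tolerance.
sim_tag_marker <- function(truth, target_r2, freq, tol, max_tries) {
  n <- length(truth)
  if (target_r2 >= 1) return(as.integer(truth))
  eps <- 1 - sqrt(target_r2)
  best <- NULL
  best_gap <- Inf
  for (try in seq_len(max_tries)) {
    tag <- as.integer(truth)
    flip <- runif(n) < eps
    tag[flip] <- rbinom(sum(flip), 2L, freq)
    r2 <- if (sd(tag) == 0 || sd(truth) == 0) 0 else cor(tag, truth)^2
    gap <- abs(r2 - target_r2)
    if (gap < best_gap) {
      best <- tag
      best_gap <- gap
    }
    if (gap <= tol) break
  }
  best
}

#' Squared genotype correlation between two markers
#'
#' Pearson correlation squared between 0/1/2 call vectors, pairwise-complete.
#' Convenience used to verify realised tag LD.
#'
#' @param g1,g2 Integer call vectors.
#' @return r-squared in `[0, 1]` (0 when either vector is constant).
#' @export
genotype_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sd(g1[ok]) == 0 || sd(g2[ok]) == 0) return(0)
  cor(g1[ok], g2[ok])^2
}
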