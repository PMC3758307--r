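#' Allele frequency from genotype counts
#'
#' Frequency of allele A from biallelic genotype counts, \eqn{(2 n_{AA} +
#' n_{AB}) / (2 n)}. Vectorised over counts.
#'
#' @param n_aa,n_ab,n_bb Non-negative genotype counts (AA homozygote,
#'   heterozygote, BB homozygote).
#' @return Numeric vector of allele-A frequencies in `[0, 1]`.
#' @examples
#' allele_frequency(54, 259, 224) # ~0.342
#' @export
allele_frequency <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  abort_if(any(n < 1), "allele_frequency(): total genotype count must be >= 1")
  abort_if(any(c(n_aa, n_ab, n_bb) < 0), "allele_frequency(): counts must be non-negative")
  (2 * n_aa + n_ab) / (2 * n)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 50000) # 1e-6
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  abort_if(n_tests < 1, "bonferroni_threshold(): n_tests must be >= 1")
  alpha / n_tests
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on biallelic genotype counts: conditional on the
#' allele counts, the heterozygote count follows a hypergeometric-type exact
#' distribution; the p-value sums the probabilities of all heterozygote counts
#' no more probable than the observed one. This is the conditional exact test
#' of Wigginton, Cutler and Abecasis, computed by the ratio recurrence between
#' successive heterozygote probabilities. Vectorised over counts.
#'
#' @inheritParams allele_frequency
#' @param chisq If `TRUE`, return the 1-df chi-square goodness-of-fit p-value
#'   instead of the exact p (offered for comparison only).
#' @return p-values in `(0, 1]`; monomorphic markers return 1.
#' @examples
#' hwe_exact_p(25, 0, 25)   # extreme heterozygote deficit
#' hwe_exact_p(10, 20, 10)  # perfect HWE proportions
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb, chisq = FALSE) {
  abort_if(any(c(n_aa, n_ab, n_bb) < 0), "hwe_exact_p(): counts must be non-negative")
  n <- n_aa + n_ab + n_bb
  abort_if(any(n < 1), "hwe_exact_p(): total genotype count must be >= 1")
  if (chisq) {
    return(mapply(hwe_chisq_one, n_aa, n_ab, n_bb))
  }
  mapply(hwe_exact_one, n_aa, n_ab, n_bb)
}

# Exact distribution of the heterozygote count given allele counts, via the
# recurrence P(h + 2) / P(h) = h_a * h_b / ((h + 2)(h + 1)) where h_a, h_b are
# the homozygote-bound allele counts remaining at h hets.
hwe_het_distribution <- function(n_a, n_b) {
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2L, rare, by = 2L)
  if (length(hets) == 1L) return(setNames(1, hets))
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1L]) {
    h <- hets[i - 1L]
    n_ra <- (rare - h) / 2          # rare-allele homozygotes at h hets
    n_ca <- (max(n_a, n_b) - h) / 2 # common-allele homozygotes at h hets
    logp[i] <- logp[i - 1L] + log(4 * n_ra * n_ca) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  setNames(p / sum(p), hets)
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0L || n_b == 0L) return(1)
  dist <- hwe_het_distribution(n_a, n_b)
  p_obs <- dist[[as.character(n_ab)]]
  min(1, sum(dist[dist <= p_obs * (1 + 1e-12)]))
}

hwe_chisq_one <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

geno_cols <- function(geno) setdiff(names(geno), "animal_id")

geno_counts <- function(calls) {
  c(n_aa = sum(calls == 2L, na.rm = TRUE),
    n_ab = sum(calls == 1L, na.rm = TRUE),
    n_bb = sum(calls == 0L, na.rm = TRUE))
}

#' Filter individuals by genotype missingness
#'
#' Removes animals whose fraction of missing calls, over all markers present
#' in the table, exceeds `max_missing` (strict inequality, so an animal at
#' exactly the threshold is retained).
#'
#' @param geno Genotype tibble: `animal_id` plus one integer column per marker
#'   with calls in `{0, 1, 2, NA}` counting copies of allele A.
#' @param max_missing Maximum tolerated missing-call fraction (default 0.10).
#' @return The filtered genotype tibble, with a `qc_report` attribute
#'   (a tibble of removals) retrievable with [qc_report()].
#' @export
qc_filter_individuals <- function(geno, max_missing = 0.10) {
  abort_if(nrow(geno) == 0L, "qc_filter_individuals(): empty genotype table")
  mk <- geno_cols(geno)
  abort_if(length(mk) == 0L, "qc_filter_individuals(): no marker columns")
  miss <- rowMeans(is.na(as.matrix(geno[mk])))
  drop <- miss > max_missing
  abort_if(all(drop), "qc_filter_individuals(): all individuals removed")
  report <- tibble::tibble(
    item = geno$animal_id[drop],
    kind = "individual",
    rule = "missingness_by_individual",
    statistic = miss[drop],
    threshold = max_missing
  )
  out <- geno[!drop, , drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Filter markers by missingness, minor allele frequency and HWE
#'
#' Applies the marker screens in order: call-rate (missing fraction
#' > `max_missing` removed), minor allele frequency (MAF not greater than
#' `min_maf` removed, i.e. markers are kept only when MAF exceeds the
#' threshold), then exact Hardy-Weinberg test (p below `hwe_alpha` removed).
#' Each screen is computed on the individuals present in `geno`.
#'
#' @inheritParams qc_filter_individuals
#' @param max_missing Maximum marker missing-call fraction (default 0.03).
#' @param min_maf Minor-allele-frequency threshold; markers kept iff
#'   MAF > `min_maf` (default 0.02).
#' @param hwe_alpha Exact-test significance level below which a marker is
#'   removed (default 1e-6, i.e. 0.05 Bonferroni-corrected for 50,000 tests).
#' @return Filtered genotype tibble with a `qc_report` attribute; each removed
#'   marker lists the single rule that triggered first.
#' @export
qc_filter_markers <- function(geno, max_missing = 0.03, min_maf = 0.02,
                              hwe_alpha = 1e-6) {
  mk <- geno_cols(geno)
  abort_if(length(mk) == 0L, "qc_filter_markers(): no marker columns")
  m <- as.matrix(geno[mk])

  miss <- colMeans(is.na(m))
  freq_a <- colMeans(m, na.rm = TRUE) / 2
  maf <- pmin(freq_a, 1 - freq_a)
  hwe_p <- vapply(seq_along(mk), function(j) {
    cnt <- geno_counts(m[, j])
    if (sum(cnt) == 0L) return(1)
    hwe_exact_p(cnt[["n_aa"]], cnt[["n_ab"]], cnt[["n_bb"]])
  }, numeric(1))

  fail_miss <- miss > max_missing
  fail_maf <- !fail_miss & !(maf %na% 0 > min_maf)
  fail_hwe <- !fail_miss & !fail_maf & hwe_p < hwe_alpha

  report <- dplyr::bind_rows(
    tibble::tibble(item = mk[fail_miss], rule = "missingness_by_marker",
                   statistic = miss[fail_miss], threshold = max_missing),
    tibble::tibble(item = mk[fail_maf], rule = "minor_allele_frequency",
                   statistic = maf[fail_maf] %na% 0, threshold = min_maf),
    tibble::tibble(item = mk[fail_hwe], rule = "hardy_weinberg",
                   statistic = hwe_p[fail_hwe], threshold = hwe_alpha)
  )
  report <- dplyr::mutate(report, kind = "marker", .after = "item")
  keep <- mk[!(fail_miss | fail_maf | fail_hwe)]
  abort_if(length(keep) == 0L, "qc_filter_markers(): all markers removed")
  out <- geno[c("animal_id", keep)]
  attr(out, "qc_report") <- report
  out
}

#' Run the full genotype QC cascade
#'
#' Individual missingness first, then the marker screens (missingness, MAF,
#' HWE), mirroring PLINK's order. Marker statistics are computed on the
#' individuals that survive the first screen.
#'
#' @inheritParams qc_filter_individuals
#' @param mind,geno_miss,maf,hwe Thresholds for individual missingness, marker
#'   missingness, minor allele frequency and the HWE exact test.
#' @return Filtered genotype tibble; `qc_report` attribute holds all removals
#'   plus the thresholds used.
#' @export
qc_run <- function(geno, mind = 0.10, geno_miss = 0.03, maf = 0.02,
                   hwe = 1e-6) {
  step1 <- qc_filter_individuals(geno, max_missing = mind)
  step2 <- qc_filter_markers(step1, max_missing = geno_miss, min_maf = maf,
                             hwe_alpha = hwe)
  report <- dplyr::bind_rows(qc_report(step1), qc_report(step2))
  attr(step2, "qc_report") <- report
  attr(step2, "qc_thresholds") <- c(mind = mind, geno = geno_miss, maf = maf,
                                    hwe = hwe)
  step2
}

#' Retrieve the QC removal report attached to a filtered genotype table
#'
#' @param geno A genotype tibble returned by [qc_filter_individuals()],
#'   [qc_filter_markers()] or [qc_run()].
#' @return Tibble with one row per removal: `item`, `kind`, `rule`,
#'   `statistic`, `threshold`. Empty tibble when nothing was removed.
#' @export
qc_report <- function(geno) {
  attr(geno, "qc_report") %||%
    tibble::tibble(item = character(), kind = character(), rule = character(),
                   statistic = numeric(), threshold = numeric())
}
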