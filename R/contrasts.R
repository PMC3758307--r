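#' Tukey-Kramer adjusted p-value for a pairwise contrast
#'
#' Adjusted p = P(studentized range(k, df) >= sqrt(2) |estimate| / SE), the
#' Tukey-Kramer form valid for unequal group sizes when the SE is computed
#' from the model-based covariance of the two means. With k = 2 this equals
#' the unadjusted two-sided t-test p-value.
#'
#' @param estimate Contrast estimate(s) (difference of adjusted means).
#' @param se Standard error(s) of the contrast.
#' @param k Number of genotype groups compared.
#' @param df Error degrees of freedom (> 0).
#' @return Adjusted p-value(s) in `[0, 1]`.
#' @export
tukey_kramer_p <- function(estimate, se, k, df) {
  abort_if(df <= 0, "tukey_kramer_p(): df must be > 0")
  abort_if(k < 2, "tukey_kramer_p(): need >= 2 groups")
  ptukey(sqrt(2) * abs(estimate) / se, nmeans = k, df = df,
         lower.tail = FALSE)
}

#' Pairwise genotype contrasts with Tukey-Kramer adjustment
#'
#' All pairwise differences of the adjusted (least-squares) genotype means of
#' a [fit_trait_mixed()] fit, with model-based standard errors and
#' Tukey-Kramer adjusted p-values. Levels observed in fewer than `min_group_n`
#' animals keep their adjusted mean but have their contrasts flagged
#' `insufficient_n`, mirroring the reporting practice of suppressing
#' comparisons against a rare homozygote class.
#'
#' @param fit A `trait_mixed` object.
#' @param min_group_n Minimum observations per genotype level for a contrast
#'   to be considered supported (default 10).
#' @return Tibble: `level_1`, `level_2`, `estimate`, `se`, `df`, `p_adjusted`,
#'   `insufficient_n`.
#' @export
genotype_contrasts <- function(fit, min_group_n = 10L) {
  am <- fit$adjusted_means
  k <- nrow(am)
  abort_if(k < 2L, "genotype_contrasts(): need >= 2 genotype levels")
  pairs <- utils::combn(seq_len(k), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    l <- fit$L[i2, ] - fit$L[i1, ]
    est <- sum(l * fit$beta)
    se <- sqrt(drop(t(l) %*% fit$vcov_beta %*% l))
    tibble::tibble(
      level_1 = am$genotype[i1], level_2 = am$genotype[i2],
      estimate = est, se = se, df = fit$df_residual,
      p_adjusted = tukey_kramer_p(est, se, k, fit$df_residual),
      insufficient_n = am$n[i1] < min_group_n | am$n[i2] < min_group_n
    )
  })
}

#' Production-trait association report across traits
#'
#' Fits the mixed model for each trait column, collecting adjusted genotype
#' means and Tukey-Kramer adjusted pairwise contrasts into one tidy table —
#' the shape of a marker-by-production-trait results table.
#'
#' @param data Production-trait tibble (see [sim_production_traits()] for the
#'   expected columns).
#' @param traits Character vector of trait column names.
#' @param lifetime_traits Traits for which `age_at_last_lambing` enters as an
#'   additional fixed covariate (default: all traits, matching a table of
#'   lifetime traits; pass `character()` for none).
#' @param min_group_n Passed to [genotype_contrasts()].
#' @param ... Passed to [fit_trait_mixed()].
#' @return Tibble with one row per trait and genotype pair: adjusted means of
#'   the two levels, contrast estimate, adjusted p, flags.
#' @export
trait_report <- function(data, traits, lifetime_traits = traits,
                         min_group_n = 10L, ...) {
  purrr::map_dfr(traits, function(tr) {
    covs <- if (tr %in% lifetime_traits &&
                "age_at_last_lambing" %in% names(data))
      "age_at_last_lambing" else character()
    fit <- fit_trait_mixed(data, trait = tr, covariates = covs, ...)
    am <- fit$adjusted_means
    genotype_contrasts(fit, min_group_n = min_group_n) |>
      dplyr::mutate(
        trait = tr,
        mean_1 = am$adjusted_mean[match(.data$level_1, am$genotype)],
        mean_2 = am$adjusted_mean[match(.data$level_2, am$genotype)],
        sigma2_sire = fit$sigma2_s, sigma2_residual = fit$sigma2_e,
        .before = 1L
      )
  })
}
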