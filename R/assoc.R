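#' Encode genotype calls under a mode of inheritance
#'
#' Builds the design column(s) for one marker: `additive` counts copies of
#' the minor allele (0/1/2); `dominant` indicates at least one minor allele;
#' `recessive` indicates two; `genotypic` gives two indicator columns
#' (heterozygote, minor homozygote) against the major-homozygote reference.
#' The minor allele is determined from the sample frequency of the calls
#' supplied (ties count allele A as minor).
#'
#' @param calls Integer vector of allele-A copy counts (0/1/2, `NA` missing).
#' @param model One of `"additive"`, `"genotypic"`, `"dominant"`,
#'   `"recessive"`.
#' @return Numeric matrix with one (or two for genotypic) columns and one row
#'   per call; missing calls give `NA` rows. `NULL` for a monomorphic marker.
#' @export
encode_genotype <- function(calls, model = c("additive", "genotypic",
                                             "dominant", "recessive")) {
  model <- match.arg(model)
  freq_a <- mean(calls, na.rm = TRUE) / 2
  if (is.nan(freq_a) || length(unique(calls[!is.na(calls)])) < 2L) return(NULL)
  minor <- if (freq_a <= 0.5) calls else 2L - calls
  switch(model,
    additive = matrix(as.numeric(minor), dimnames = list(NULL, "g_add")),
    dominant = matrix(as.numeric(minor >= 1L), dimnames = list(NULL, "g_dom")),
    recessive = matrix(as.numeric(minor == 2L), dimnames = list(NULL, "g_rec")),
    genotypic = cbind(g_het = as.numeric(minor == 1L),
                      g_hom = as.numeric(minor == 2L))
  )
}

assoc_models <- c("additive", "genotypic", "dominant", "recessive")

# Fit one marker under one model by OLS. Returns NULL when the marker is
# monomorphic or the design is rank deficient in the genotype columns.
fit_marker <- function(y, covar, gcols, model) {
  keep <- if (is.null(covar)) complete.cases(y, gcols) else
    complete.cases(y, gcols, covar)
  y <- y[keep]
  g <- gcols[keep, , drop = FALSE]
  x0 <- if (is.null(covar)) matrix(nrow = length(y), ncol = 0) else
    as.matrix(covar)[keep, , drop = FALSE]
  if (any(apply(g, 2, function(v) length(unique(v)) < 2L))) return(NULL)
  if (model == "genotypic" && qr(cbind(1, g))$rank < 3L) {
    # only two genotype classes observed: drop the absent indicator
    g <- g[, apply(g, 2, function(v) length(unique(v)) > 1L), drop = FALSE]
  }
  dat <- data.frame(y = y, x0, g, check.names = TRUE)
  fit0 <- lm(y ~ ., data = data.frame(y = y, x0, check.names = TRUE))
  fit1 <- lm(y ~ ., data = dat)
  if (any(is.na(coef(fit1)))) return(NULL)
  ng <- ncol(g)
  p_cols <- tail(seq_along(coef(fit1)), ng)
  if (ng == 1L) {
    sm <- summary(fit1)$coefficients
    p <- sm[nrow(sm), 4]
    betas <- coef(fit1)[p_cols]
  } else {
    a <- anova(fit0, fit1)
    p <- a$`Pr(>F)`[2]
    betas <- coef(fit1)[p_cols]
  }
  # Effect size: largest difference among covariate-adjusted genotype means.
  # Under each encoding the adjusted means differ only through the genotype
  # coefficients, so the max pairwise difference is a function of the betas.
  eff <- switch(model,
    additive = 2 * abs(betas[[1]]),
    dominant = abs(betas[[1]]),
    recessive = abs(betas[[1]]),
    genotypic = if (length(betas) == 2L)
      max(abs(betas[1]), abs(betas[2]), abs(betas[1] - betas[2]))
    else abs(betas[[1]])
  )
  list(n_used = length(y), beta = unname(betas), p = max(p, 1e-300),
       effect_size = unname(eff))
}

#' Assign significance tiers to p-values
#'
#' @param p Numeric p-values.
#' @param sig Genome-wide significance threshold; significant iff `p <= sig`
#'   (default 5e-8).
#' @param suggestive Suggestive threshold; suggestive iff `p < suggestive`
#'   (default 1e-5).
#' @return Character vector in `{"genome_wide_significant", "suggestive",
#'   "none"}`.
#' @export
assign_tier <- function(p, sig = 5e-8, suggestive = 1e-5) {
  dplyr::case_when(
    p <= sig ~ "genome_wide_significant",
    p < suggestive ~ "suggestive",
    TRUE ~ "none"
  )
}

#' Multi-model association scan
#'
#' Fits each marker under each requested mode of inheritance by ordinary
#' least squares with the supplied covariates: the p-value is the t-test on
#' the genotype coefficient (single-column codings) or the 2-df partial
#' F-test (genotypic); the effect size is the largest covariate-adjusted
#' genotypic mean difference in trait units. Optionally conditions the scan
#' on a set of markers encoded as genotypic fixed covariates, the device used
#' to show an association peak is explained by its top markers.
#'
#' @param pheno Phenotype tibble with `animal_id`, the trait column and any
#'   covariate columns.
#' @param geno Genotype tibble (`animal_id` + marker call columns).
#' @param trait Name of the trait column in `pheno`.
#' @param covariates Character vector of covariate column names in `pheno`
#'   (factors are expanded to indicators).
#' @param models Modes of inheritance to fit (default all four).
#' @param sig,suggestive Tier thresholds (defaults 5e-8 and 1e-5).
#' @param condition_on Marker names to include as genotypic fixed covariates;
#'   they are excluded from the scanned set. Collinear conditioning columns
#'   are dropped with a message.
#' @return Tibble of class `assoc_scan`: `marker`, `model`, `n_used`, `beta`
#'   (list column), `p_nominal`, `effect_size`, `tier`, one row per marker x
#'   model; markers skipped (monomorphic/rank-deficient) are absent.
#' @export
assoc_scan <- function(pheno, geno, trait, covariates = character(),
                       models = assoc_models, sig = 5e-8, suggestive = 1e-5,
                       condition_on = NULL) {
  models <- match.arg(models, assoc_models, several.ok = TRUE)
  abort_if(!trait %in% names(pheno), "assoc_scan(): trait column not found")
  abort_if(!all(covariates %in% names(pheno)),
           "assoc_scan(): covariate column(s) not found")
  dat <- dplyr::inner_join(pheno, geno, by = "animal_id",
                           suffix = c("", ".geno"))
  abort_if(nrow(dat) == 0L, "assoc_scan(): no animals shared by pheno and geno")
  y <- dat[[trait]]

  covar <- if (length(covariates)) {
    mm <- model.matrix(~ ., data = as.data.frame(dat[covariates]))
    mm[, -1, drop = FALSE]
  } else NULL

  markers <- setdiff(geno_cols(geno), condition_on)
  if (!is.null(condition_on)) {
    abort_if(!all(condition_on %in% names(dat)),
             "assoc_scan(): conditioning marker(s) not found")
    cond_cols <- purrr::map(condition_on, function(mk) {
      enc <- encode_genotype(dat[[mk]], "genotypic")
      if (is.null(enc)) return(NULL)
      colnames(enc) <- paste0(mk, "_", colnames(enc))
      enc
    })
    cond <- do.call(cbind, purrr::compact(cond_cols))
    if (!is.null(cond) && ncol(cond) > 0L) {
      base <- cbind(rep(1, nrow(dat)), covar)
      ok <- complete.cases(cbind(base, cond))
      keep_cols <- qr_independent_cols(cbind(base, cond)[ok, , drop = FALSE],
                                       n_fixed = ncol(base))
      if (length(keep_cols) < ncol(cond)) {
        message("assoc_scan(): dropped ", ncol(cond) - length(keep_cols),
                " collinear conditioning column(s)")
      }
      covar <- cbind(covar, cond[, keep_cols, drop = FALSE])
    }
  }

  res <- purrr::map_dfr(markers, function(mk) {
    purrr::map_dfr(models, function(mdl) {
      enc <- encode_genotype(dat[[mk]], mdl)
      if (is.null(enc)) return(NULL)
      fit <- fit_marker(y, covar, enc, mdl)
      if (is.null(fit)) return(NULL)
      tibble::tibble(marker = mk, model = mdl, n_used = fit$n_used,
                     beta = list(fit$beta), p_nominal = fit$p,
                     effect_size = fit$effect_size)
    })
  })
  if (nrow(res)) res$tier <- assign_tier(res$p_nominal, sig, suggestive)
  class(res) <- c("assoc_scan", class(res))
  attr(res, "thresholds") <- c(sig = sig, suggestive = suggestive)
  res
}

# Indices of columns of `extra` (appearing after n_fixed leading columns in
# X) that keep the design full rank, scanning left to right.
qr_independent_cols <- function(X, n_fixed) {
  keep <- integer(0)
  base <- X[, seq_len(n_fixed), drop = FALSE]
  for (j in seq_len(ncol(X) - n_fixed)) {
    cand <- cbind(base, X[, n_fixed + j])
    if (qr(cand)$rank == ncol(cand)) {
      base <- cand
      keep <- c(keep, j)
    }
  }
  keep
}

#' Best-fitting model per marker
#'
#' Selects, for each marker, the record with the smallest nominal p-value;
#' ties are broken by model order (additive, genotypic, dominant, recessive),
#' reproducing the convention of reporting one best mode of inheritance per
#' SNP without a multiplicity correction (a per-marker Bonferroni across the
#' four models is available via `bonferroni_models`).
#'
#' @param records An `assoc_scan` tibble.
#' @param bonferroni_models If `TRUE`, multiply the winning p-value by the
#'   number of models fitted for that marker (capped at 1).
#' @return Tibble with one row per marker.
#' @export
best_model <- function(records, bonferroni_models = FALSE) {
  out <- records |>
    dplyr::mutate(.model_rank = match(.data$model, assoc_models)) |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(.n_models = dplyr::n()) |>
    dplyr::arrange(.data$p_nominal, .data$.model_rank, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  if (bonferroni_models) {
    out <- dplyr::mutate(out, p_nominal = pmin(1, .data$p_nominal *
                                                 .data$.n_models))
  }
  dplyr::select(out, -".model_rank", -".n_models")
}

#' Genomic inflation factor
#'
#' Lambda = median observed chi-square (from p) over the null median,
#' the usual QQ-based check for residual stratification.
#'
#' @param p Numeric p-values.
#' @return Scalar lambda.
#' @export
genomic_lambda <- function(p) {
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' Manhattan plot table
#'
#' Joins association records to the marker map and lays chromosomes end to
#' end: each chromosome is offset by the cumulative length of its
#' predecessors so `cum_bp` is a single genome-wide axis.
#'
#' @param records Association tibble with `marker` and `p_nominal` (typically
#'   from [best_model()]).
#' @param map Marker map tibble: `marker`, `chrom`, `bp`.
#' @return Tibble: `marker`, `chrom`, `bp`, `cum_bp`, `neg_log10_p`, plus the
#'   scan's threshold lines as the `thresholds` attribute.
#' @export
manhattan_data <- function(records, map) {
  abort_if(!all(records$marker %in% map$marker),
           "manhattan_data(): records contain markers missing from map")
  chrom_levels <- unique(map$chrom)
  offsets <- map |>
    dplyr::mutate(chrom = factor(.data$chrom, chrom_levels)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$bp), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  out <- records |>
    dplyr::inner_join(map, by = "marker") |>
    dplyr::mutate(chrom = factor(.data$chrom, chrom_levels)) |>
    dplyr::inner_join(offsets[c("chrom", "offset")], by = "chrom") |>
    dplyr::mutate(cum_bp = .data$bp + .data$offset,
                  neg_log10_p = -log10(.data$p_nominal)) |>
    dplyr::select("marker", "chrom", "bp", "cum_bp", "neg_log10_p") |>
    dplyr::arrange(.data$cum_bp)
  attr(out, "thresholds") <- attr(records, "thresholds") %||%
    c(sig = 5e-8, suggestive = 1e-5)
  out
}

#' Quantile-quantile plot table
#'
#' Sorted observed -log10 p against the expected uniform order statistics.
#'
#' @param p Numeric p-values.
#' @return Tibble: `expected`, `observed` (-log10 scale), ascending.
#' @export
qq_data <- function(p) {
  p <- sort(p)
  n <- length(p)
  tibble::tibble(
    expected = -log10(seq_len(n) / (n + 1)),
    observed = -log10(p)
  ) |>
    dplyr::arrange(.data$expected)
}
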