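#' Linear mixed model with a sire-within-breed random effect
#'
#' Fits `trait ~ genotype + fixed factors + covariates + (1 | sire)` where the
#' sire random intercept is nested within sire breed (sire labels are made
#' unique per breed before fitting). Because the model has exactly one random
#' effect, the restricted likelihood is profiled in the single variance ratio
#' \eqn{\lambda = \sigma^2_s / \sigma^2_e}: for fixed \eqn{\lambda} the
#' marginal covariance is block diagonal by sire with closed-form inverse and
#' determinant, generalised least squares gives the fixed effects, and a
#' bracketed 1-D minimisation over \eqn{\lambda \ge 0} yields the REML
#' estimates. A boundary fit (\eqn{\hat\sigma^2_s = 0}) is flagged, not an
#' error, and then equals ordinary least squares.
#'
#' @param data Tibble with the trait, genotype, fixed-effect and sire columns;
#'   rows with missing values in any used column are dropped.
#' @param trait Name of the response column.
#' @param genotype Name of the genotype column (coerced to factor; 2-3
#'   observed levels expected).
#' @param fixed Names of fixed-effect factor columns (default
#'   `c("breed", "birth_year")`, present-only columns are used).
#' @param covariates Names of numeric covariate columns (e.g. age at last
#'   lambing for lifetime traits).
#' @param sire,sire_breed Random-effect grouping column and the breed column
#'   it is nested within (`NULL` to use `sire` labels as-is).
#' @return Object of class `trait_mixed`: variance components, fixed-effect
#'   estimates with covariance, adjusted (least-squares) genotype means at
#'   equally weighted factor levels and mean covariates, residual df, and a
#'   `boundary` flag. Use [tidy()][generics::tidy], [glance()]
#'   [genotype_contrasts()] and [trait_report()] on it.
#' @export
fit_trait_mixed <- function(data, trait, genotype = "genotype",
                            fixed = c("breed", "birth_year"),
                            covariates = character(),
                            sire = "sire_id", sire_breed = "sire_breed") {
  fixed <- intersect(fixed, names(data))
  if (!is.null(sire_breed) && !sire_breed %in% names(data)) sire_breed <- NULL
  used <- c(trait, genotype, fixed, covariates, sire, sire_breed)
  abort_if(!all(used %in% names(data)),
           paste("fit_trait_mixed(): missing column(s):",
                 paste(setdiff(used, names(data)), collapse = ", ")))
  dat <- data[complete.cases(data[used]), used]
  abort_if(nrow(dat) < 3L, "fit_trait_mixed(): too few complete rows")

  if (!is.null(genotype)) dat[[genotype]] <- factor(dat[[genotype]])
  for (f in fixed) dat[[f]] <- factor(dat[[f]])
  sire_lab <- if (is.null(sire_breed)) as.character(dat[[sire]]) else
    paste(dat[[sire_breed]], dat[[sire]], sep = "/")
  abort_if(dplyr::n_distinct(sire_lab) < 2L,
           "fit_trait_mixed(): need >= 2 sires")

  rhs_terms <- c(genotype, fixed, covariates)
  rhs <- if (length(rhs_terms)) paste(rhs_terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste("~", rhs))
  X <- model.matrix(form, dat)
  qrX <- qr(X)
  abort_if(qrX$rank < ncol(X),
           "fit_trait_mixed(): fixed-effect design is rank deficient")
  y <- dat[[trait]]

  fit <- reml_profile(y, X, sire_lab)

  # LS means: average the prediction over an equally weighted grid of the
  # other factor levels with covariates at their observed means.
  if (!is.null(genotype)) {
    grid_parts <- c(
      setNames(list(levels(dat[[genotype]])), genotype),
      purrr::map(setNames(fixed, fixed), ~ levels(dat[[.x]])),
      purrr::map(setNames(covariates, covariates), ~ mean(dat[[.x]]))
    )
    grid <- expand.grid(grid_parts, stringsAsFactors = FALSE)
    for (f in fixed) grid[[f]] <- factor(grid[[f]], levels(dat[[f]]))
    grid[[genotype]] <- factor(grid[[genotype]], levels(dat[[genotype]]))
    mm <- model.matrix(form, grid)
    L <- t(vapply(levels(dat[[genotype]]), function(g) {
      colMeans(mm[grid[[genotype]] == g, , drop = FALSE])
    }, numeric(ncol(mm))))
    g_levels <- levels(dat[[genotype]])
    g_counts <- as.integer(table(dat[[genotype]]))
    adj_means <- tibble::tibble(
      genotype = g_levels,
      n = g_counts,
      adjusted_mean = as.numeric(L %*% fit$beta),
      se = unname(sqrt(rowSums((L %*% fit$vcov_beta) * L)))
    )
  } else {
    L <- NULL
    adj_means <- tibble::tibble(genotype = character(), n = integer(),
                                adjusted_mean = numeric(), se = numeric())
  }

  structure(list(
    trait = trait, genotype = genotype, fixed = fixed,
    covariates = covariates,
    sigma2_s = fit$sigma2_s, sigma2_e = fit$sigma2_e, lambda = fit$lambda,
    boundary = fit$boundary, beta = fit$beta, vcov_beta = fit$vcov_beta,
    reml_criterion = fit$criterion, df_residual = fit$df_residual,
    n = length(y), n_sires = dplyr::n_distinct(sire_lab),
    adjusted_means = adj_means, L = L, data = dat
  ), class = "trait_mixed")
}

# Profiled REML for y = X beta + Z u + e with one random intercept per group.
# V(lambda) = I + lambda * Z Z' is block diagonal by group, so V^{-1} A =
# A - lambda/(1 + lambda n_g) * J A per block via group sums.
reml_profile <- function(y, X, groups) {
  n <- length(y)
  p <- ncol(X)
  g <- as.factor(groups)
  ng <- as.integer(table(g))

  gi <- as.integer(g)
  vinv_mult <- function(A, lambda) {
    A <- as.matrix(A)
    shrink <- lambda / (1 + lambda * ng)  # per-group J-term weight
    sums <- rowsum(A, gi)                 # group sums, rows 1..k
    A - sums[gi, , drop = FALSE] * shrink[gi]
  }

  crit <- function(lambda) {
    ViX <- vinv_mult(X, lambda)
    Viy <- vinv_mult(y, lambda)
    XtViX <- crossprod(X, ViX)
    ch <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X, Viy)))
    r <- y - X %*% beta
    rss <- sum(r * vinv_mult(r, lambda))
    if (rss <= 0) return(Inf)
    sigma2_e <- rss / (n - p)
    sum(log1p(lambda * ng)) + 2 * sum(log(diag(ch))) +
      (n - p) * log(sigma2_e)
  }

  # coarse bracket on log-lambda, then fine Brent in the best interval
  grid <- c(0, exp(seq(log(1e-8), log(1e4), length.out = 41)))
  vals <- vapply(grid, crit, numeric(1))
  i <- which.min(vals)
  lambda_hat <- if (i <= 2L) 0 else {
    lo <- grid[max(2L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    opt <- optimize(function(l) crit(exp(l)), c(log(lo), log(hi)),
                    tol = 1e-12)
    exp(opt$minimum)
  }
  if (lambda_hat > 0 && crit(0) <= crit(lambda_hat)) lambda_hat <- 0
  boundary <- lambda_hat <= 1e-10
  if (boundary) lambda_hat <- 0

  ViX <- vinv_mult(X, lambda_hat)
  Viy <- vinv_mult(y, lambda_hat)
  XtViX <- crossprod(X, ViX)
  XtViX_inv <- chol2inv(chol(XtViX))
  beta <- drop(XtViX_inv %*% crossprod(X, Viy))
  r <- y - X %*% beta
  sigma2_e <- sum(r * vinv_mult(r, lambda_hat)) / (n - p)
  list(lambda = lambda_hat, sigma2_s = lambda_hat * sigma2_e,
       sigma2_e = sigma2_e, beta = setNames(beta, colnames(X)),
       vcov_beta = XtViX_inv * sigma2_e, criterion = crit(lambda_hat),
       df_residual = n - p, boundary = boundary)
}

#' @export
print.trait_mixed <- function(x, ...) {
  cat("Linear mixed model (REML), trait:", x$trait, "\n")
  cat(sprintf("  n = %d animals, %d sires; sigma2_sire = %.4g, sigma2_resid = %.4g%s\n",
              x$n, x$n_sires, x$sigma2_s, x$sigma2_e,
              if (x$boundary) " (boundary: sire variance clamped at 0)" else ""))
  cat("  Adjusted genotype means:\n")
  print(as.data.frame(x$adjusted_means), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-model trait fit
#'
#' @param x A `trait_mixed` object.
#' @param ... Unused.
#' @return Tibble of fixed-effect terms: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value` (Wald t on residual df).
#' @export
tidy.trait_mixed <- function(x, ...) {
  se <- sqrt(diag(x$vcov_beta))
  stat <- x$beta / se
  tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta), std_error = unname(se),
    statistic = unname(stat),
    p_value = unname(2 * pt(abs(stat), x$df_residual, lower.tail = FALSE))
  )
}

#' Glance at a mixed-model trait fit
#'
#' @param x A `trait_mixed` object.
#' @param ... Unused.
#' @return One-row tibble: `trait`, `n`, `n_sires`, `sigma2_sire`,
#'   `sigma2_residual`, `icc`, `boundary`, `reml_criterion`, `df_residual`.
#' @export
glance.trait_mixed <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, n = x$n, n_sires = x$n_sires, sigma2_sire = x$sigma2_s,
    sigma2_residual = x$sigma2_e,
    icc = x$sigma2_s / (x$sigma2_s + x$sigma2_e),
    boundary = x$boundary, reml_criterion = x$reml_criterion,
    df_residual = x$df_residual
  )
}
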