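#' EM estimation of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximises the multinomial likelihood of the four haplotype frequencies
#' (AB, Ab, aB, ab) given unphased diplotypes at two biallelic loci. Only the
#' double heterozygote is phase-ambiguous; each E-step splits it between the
#' coupling (AB/ab) and repulsion (Ab/aB) resolutions in proportion to the
#' current haplotype-frequency products. Initialised at linkage-equilibrium
#' products; when the double-heterozygote fraction exceeds 0.25 three extra
#' random restarts are run (deterministic given `seed`) and the best
#' likelihood kept.
#'
#' @param g1,g2 Integer vectors of allele-A copy counts (0/1/2, `NA`
#'   missing) at the two loci; missing calls are dropped pairwise.
#' @param tol Convergence threshold on the largest frequency change
#'   (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @param seed Seed for the random restarts.
#' @return List: `hap_freqs` (named numeric, AB/Ab/aB/ab), `loglik`,
#'   `iterations`, `converged`, `n_used`, `defined` (`FALSE` with a reason
#'   when either locus is monomorphic).
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000L,
                               seed = 1L) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- as.integer(g1[ok]); g2 <- as.integer(g2[ok])
  n <- length(g1)
  abort_if(n < 2, "em_haplotype_freqs(): need >= 2 paired non-missing calls")
  abort_if(any(g1 < 0 | g1 > 2 | g2 < 0 | g2 > 2),
           "em_haplotype_freqs(): calls must be 0/1/2")

  if (length(unique(g1)) == 1L || length(unique(g2)) == 1L) {
    return(list(hap_freqs = setNames(rep(NA_real_, 4),
                                     c("AB", "Ab", "aB", "ab")),
                loglik = NA_real_, iterations = 0L, converged = FALSE,
                n_used = n, defined = FALSE,
                reason = "monomorphic locus: LD undefined"))
  }

  counts <- table(factor(g1, 0:2), factor(g2, 0:2))  # 3x3 diplotype table
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  inits <- list(c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB)))
  if (counts["1", "1"] / n > 0.25) {
    set.seed(derive_seed(seed, "em_restarts"))
    for (r in 1:3) {
      x <- runif(4); inits[[r + 1L]] <- x / sum(x)
    }
  }

  best <- NULL
  for (p0 in inits) {
    fit <- em_run(counts, p0, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  c(best, list(n_used = n, defined = TRUE))
}

# One EM run on the 3x3 diplotype count table. Haplotype order: AB, Ab, aB,
# ab where the first symbol is locus-1 allele A (count > 0) and case encodes
# presence/absence.
em_run <- function(counts, p, tol, max_iter) {
  n <- sum(counts)
  n_dh <- counts["1", "1"]  # double heterozygotes, the only ambiguous cell
  # Haplotype contributions from unambiguous cells: genotype g at a locus
  # carries g copies of that locus's A/B allele.
  base <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in 0:2) for (j in 0:2) {
    if (i == 1 && j == 1) next
    cnt <- counts[as.character(i), as.character(j)]
    if (cnt == 0) next
    # phase is determined for non-double-het cells: e.g. (2,1) = AB + Ab
    base <- base + cnt * hap_counts_resolved(i, j)
  }
  ll_trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    coup <- p[1] * p[4]
    rep_ <- p[2] * p[3]
    w <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    e <- base
    e[c(1, 4)] <- e[c(1, 4)] + n_dh * w
    e[c(2, 3)] <- e[c(2, 3)] + n_dh * (1 - w)
    p_new <- e / (2 * n)
    ll_trace <- c(ll_trace, em_loglik(counts, p_new))
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(hap_freqs = setNames(as.numeric(p), c("AB", "Ab", "aB", "ab")),
       loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       iterations = iter, converged = converged)
}

# Haplotype copy counts (AB, Ab, aB, ab) for an unambiguous diplotype (i, j);
# i, j are allele-A/B copy counts at loci 1 and 2, not both equal to 1.
hap_counts_resolved <- function(i, j) {
  if (i == 1 && j == 1) stop("ambiguous cell")
  # any het at one locus pairs with a homozygote at the other, fixing phase
  if (i == 1) {
    if (j == 2) return(c(AB = 1, Ab = 0, aB = 1, ab = 0))
    return(c(AB = 0, Ab = 1, aB = 0, ab = 1))          # j == 0
  }
  if (j == 1) {
    if (i == 2) return(c(AB = 1, Ab = 1, aB = 0, ab = 0))
    return(c(AB = 0, Ab = 0, aB = 1, ab = 1))          # i == 0
  }
  c(AB = min(i, j) , Ab = i - min(i, j), aB = j - min(i, j),
    ab = 2 - max(i, j))
}

em_loglik <- function(counts, p) {
  ll <- 0
  for (i in 0:2) for (j in 0:2) {
    cnt <- counts[as.character(i), as.character(j)]
    if (cnt == 0) next
    ll <- ll + cnt * log(diplotype_prob(i, j, p))
  }
  ll
}

# P(diplotype (i, j)) under random union of haplotypes with frequencies p.
diplotype_prob <- function(i, j, p) {
  if (i == 1 && j == 1) return(2 * p[1] * p[4] + 2 * p[2] * p[3])
  h <- hap_counts_resolved(i, j)
  k <- which(h > 0)
  if (length(k) == 1L) p[k]^2 else 2 * p[k[1]] * p[k[2]]
}

#' LD statistics from haplotype frequencies
#'
#' D, D-prime and r-squared of two biallelic loci: \eqn{D = p_{AB} - p_A p_B};
#' \eqn{D' = |D| / D_{max}} where \eqn{D_{max} = \min(p_A q_B, q_A p_B)} for
#' positive D and \eqn{\min(p_A p_B, q_A q_B)} otherwise; \eqn{r^2 = D^2 /
#' (p_A q_A p_B q_B)}.
#'
#' @param hap_freqs Numeric length 4 (AB, Ab, aB, ab), summing to 1.
#' @return One-row tibble: `D`, `D_prime`, `r2`, `p_A`, `p_B`, `defined`.
#' @export
ld_stats <- function(hap_freqs) {
  abort_if(length(hap_freqs) != 4 || any(is.na(hap_freqs)) ||
             abs(sum(hap_freqs) - 1) > 1e-6,
           "ld_stats(): hap_freqs must be 4 non-missing values summing to 1")
  pA <- hap_freqs[1] + hap_freqs[2]
  pB <- hap_freqs[1] + hap_freqs[3]
  qA <- 1 - pA; qB <- 1 - pB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    return(tibble::tibble(D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                          p_A = unname(pA), p_B = unname(pB),
                          defined = FALSE))
  }
  D <- unname(hap_freqs[1] - pA * pB)
  d_max <- if (D > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  tibble::tibble(
    D = D,
    D_prime = if (d_max > 0) abs(D) / d_max else 0,
    r2 = D^2 / unname(pA * qA * pB * qB),
    p_A = unname(pA), p_B = unname(pB), defined = TRUE
  )
}

#' Two-locus LD from a genotype table
#'
#' Runs [em_haplotype_freqs()] on two named markers of a genotype tibble and
#' returns the full LD summary, mirroring a pairwise PLINK `--ld` query.
#'
#' @param geno Genotype tibble (`animal_id` + marker call columns).
#' @param marker1,marker2 Column names of the two markers.
#' @param ... Passed to [em_haplotype_freqs()].
#' @return One-row tibble: `marker1`, `marker2`, `n_used`, haplotype
#'   frequencies (`p_AB` ... `p_ab`), `D`, `D_prime`, `r2`, `em_iterations`,
#'   `converged`, `defined`.
#' @export
ld_pair <- function(geno, marker1, marker2, ...) {
  abort_if(!all(c(marker1, marker2) %in% names(geno)),
           "ld_pair(): markers not found in genotype table")
  em <- em_haplotype_freqs(geno[[marker1]], geno[[marker2]], ...)
  stats <- if (em$defined) ld_stats(em$hap_freqs) else
    tibble::tibble(D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                   p_A = NA_real_, p_B = NA_real_, defined = FALSE)
  tibble::tibble(
    marker1 = marker1, marker2 = marker2, n_used = em$n_used,
    p_AB = em$hap_freqs[["AB"]], p_Ab = em$hap_freqs[["Ab"]],
    p_aB = em$hap_freqs[["aB"]], p_ab = em$hap_freqs[["ab"]],
    D = stats$D, D_prime = stats$D_prime, r2 = stats$r2,
    em_iterations = em$iterations, converged = em$converged,
    defined = em$defined
  )
}
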