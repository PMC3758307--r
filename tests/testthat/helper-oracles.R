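# Independent oracles used across the suite. Each computes its quantity by a
# route different from the package implementation.

# Exact HWE p-value by direct combinatorial enumeration: the conditional
# probability of h heterozygotes given allele counts (n_a, n_b) is
#   P(h) = n! 2^h / (n_aa! h! n_bb!) * n_a! n_b! / (2n)!
# summed over all h with P(h) <= P(observed).
hwe_oracle_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  hets <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  logp <- vapply(hets, function(h) {
    lfactorial(n) + h * log(2) - lfactorial((n_a - h) / 2) - lfactorial(h) -
      lfactorial((n_b - h) / 2) + lfactorial(n_a) + lfactorial(n_b) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[hets == n_ab]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# Heterozygote-count distribution by brute-force enumeration of all equally
# likely arrangements of the 2n alleles into n ordered pairs (tiny n only).
hwe_pairing_distribution <- function(n_a, n_b) {
  slots <- n_a + n_b
  combos <- utils::combn(slots, n_a)
  hets <- apply(combos, 2, function(a_pos) {
    alleles <- rep(0L, slots)
    alleles[a_pos] <- 1L
    pairs <- matrix(alleles, nrow = 2)
    sum(pairs[1, ] != pairs[2, ])
  })
  table(hets) / ncol(combos)
}

# Multinomial log-likelihood of a 3x3 diplotype table as a function of the
# coupling haplotype frequency p11, with allele frequencies fixed.
ld_loglik_p11 <- function(counts, p11, pA, pB) {
  p <- c(p11, pA - p11, pB - p11, 1 - pA - pB + p11)
  if (any(p < 0)) return(-Inf)
  probs <- function(i, j) {
    hap_pairs <- list(
      "0_0" = p[4]^2, "0_1" = 2 * p[3] * p[4], "0_2" = p[3]^2,
      "1_0" = 2 * p[2] * p[4], "1_1" = 2 * p[1] * p[4] + 2 * p[2] * p[3],
      "1_2" = 2 * p[1] * p[3], "2_0" = p[2]^2, "2_1" = 2 * p[1] * p[2],
      "2_2" = p[1]^2
    )
    hap_pairs[[paste(i, j, sep = "_")]]
  }
  ll <- 0
  for (i in 0:2) for (j in 0:2) {
    cnt <- counts[as.character(i), as.character(j)]
    if (cnt > 0) ll <- ll + cnt * log(probs(i, j))
  }
  ll
}

# Closed-form REML estimators for a balanced one-way random-effects design:
# sigma2_e = MSW, sigma2_s = (MSB - MSW) / m.
balanced_anova_reml <- function(y, group) {
  m <- as.integer(table(group))[1]
  means <- tapply(y, group, mean)
  msb <- m * sum((means - mean(y))^2) / (length(means) - 1)
  msw <- sum((y - means[group])^2) / (length(y) - length(means))
  c(sigma2_s = max(0, (msb - msw) / m), sigma2_e = msw)
}

# Partial F-test for the last `q` columns of a design, by explicit matrix
# algebra (hat matrices), independent of lm()/anova().
partial_f_oracle <- function(y, X0, X1q) {
  X <- cbind(X0, X1q)
  q <- ncol(X1q)
  rss <- function(M) {
    b <- solve(crossprod(M), crossprod(M, y))
    sum((y - M %*% b)^2)
  }
  rss0 <- rss(X0)
  rss1 <- rss(X)
  df2 <- length(y) - ncol(X)
  f <- ((rss0 - rss1) / q) / (rss1 / df2)
  pf(f, q, df2, lower.tail = FALSE)
}

# Naive per-window read-start counting.
count_oracle <- function(reads, grid) {
  sapply(seq_len(nrow(grid)), function(j) {
    sum(reads$start >= grid$start[j] & reads$start < grid$end[j])
  })
}
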