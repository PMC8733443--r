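#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided test for a biallelic marker: with the allele counts fixed,
#' the conditional probability of every feasible heterozygote count is
#' evaluated, and the p-value is the sum of probabilities no larger than that
#' of the observed heterozygote count.  This is the standard exact HWE test
#' used to gate markers before transmission testing, since the transmission
#' chi-square is only valid at markers in HWE.
#'
#' The conditional distribution of the heterozygote count \eqn{n_{AB}} given
#' \eqn{n} genotypes and \eqn{n_A} copies of allele A is
#' \deqn{P(n_{AB}) = \frac{n!\,2^{n_{AB}}}{n_{AA}!\,n_{AB}!\,n_{BB}!} \Big/
#'   \binom{2n}{n_A},}
#' evaluated in log space over all feasible \eqn{n_{AB}} of the correct
#' parity.
#'
#' @param n_AA,n_AB,n_BB genotype counts (non-negative, total >= 1)
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("counts must be non-negative")
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop("all-zero genotype counts")
  nA <- 2L * n_AA + n_AB
  nB <- 2L * n_BB + n_AB
  # feasible heterozygote counts share the parity of the minor allele count
  k <- seq(nA %% 2L, min(nA, nB), by = 2L)
  logp <- lfactorial(n) + k * log(2) -
    lfactorial((nA - k) / 2) - lfactorial(k) - lfactorial((nB - k) / 2)
  logp <- logp - max(logp)
  p_all <- exp(logp) / sum(exp(logp))
  p_obs <- p_all[match(n_AB, k)]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-12)]))
}

#' HWE p-values for every marker of a genotype matrix
#'
#' @param genotypes a [geno_matrix]
#' @param ids optional individual ids to restrict to (e.g. the offspring
#'   generation)
#' @return named numeric vector of p-values, one per marker (NA where fewer
#'   than one genotype is observed).
#' @export
hwe_pvalues <- function(genotypes, ids = NULL) {
  m <- unclass(genotypes)
  if (!is.null(ids)) m <- m[ids, , drop = FALSE]
  vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    cnt <- c(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
             sum(x == 2L, na.rm = TRUE))
    if (sum(cnt) < 1) return(NA_real_)
    hwe_exact_test(cnt[1], cnt[2], cnt[3])
  }, numeric(1), USE.NAMES = FALSE) |> setNames(marker_map(genotypes)$marker_id)
}
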