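# Small in-code fixtures and independent oracles shared across tests.

# genotype matrix from a marker-by-individual character layout:
# rows = markers (cells "A"/"H"/"B"/NA), with a simple one-chromosome map
make_geno <- function(cells, ids, chromosome = "1", position_bp = NULL,
                      informative = TRUE) {
  code <- c(A = 0L, H = 1L, B = 2L)
  m <- matrix(code[t(cells)], nrow = length(ids),
              dimnames = list(ids, NULL))
  n_mark <- ncol(m)
  geno_matrix(m, data.frame(
    marker_id = paste0("mk", seq_len(n_mark)),
    chromosome = rep_len(chromosome, n_mark),
    position_bp = position_bp %||% seq_len(n_mark) * 1000L,
    informative = rep_len(informative, n_mark)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent HWE oracle: Wigginton-style probability recurrence
# P(k+2)/P(k) = 4 nAA nBB / ((k+2)(k+1)), normalized over feasible k
hwe_oracle <- function(n_AA, n_AB, n_BB) {
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  ks <- seq(nA %% 2, min(nA, nB), by = 2)
  pr <- numeric(length(ks))
  pr[1] <- 1
  if (length(ks) > 1) {
    for (i in 2:length(ks)) {
      k <- ks[i - 1]
      naa <- (nA - k) / 2
      nbb <- (nB - k) / 2
      pr[i] <- pr[i - 1] * 4 * naa * nbb / ((k + 2) * (k + 1))
    }
  }
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_AB, ks)] * (1 + 1e-12)])
}

# brute-force Pearson chi-square over a 3x3 table, cell by cell
chi2_oracle <- function(obs) {
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  tot <- 0
  for (i in 1:3) for (j in 1:3)
    if (expd[i, j] > 0) tot <- tot + (obs[i, j] - expd[i, j])^2 / expd[i, j]
  tot
}

# hypergeometric upper-tail by direct enumeration
hyper_tail_oracle <- function(k, set_size, universe_size, query_size) {
  ks <- k:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# pair_table built directly from matrices, for bdm_chi2 unit tests
make_pair_table <- function(obs, expd = NULL) {
  obs <- matrix(as.numeric(obs), 3, 3,
                dimnames = list(c("HOM_A", "HET", "HOM_B"),
                                c("HOM_A", "HET", "HOM_B")))
  if (is.null(expd)) expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  structure(list(marker_1 = "m1", marker_2 = "m2", observed = obs,
                 expected = expd, n = sum(obs)), class = "pair_table")
}

# tiny synthetic gene annotation with controllable nsSNP placement
make_annotation <- function(n_genes = 60, nssnp = NULL, chromosome = NULL,
                            width = 50000L) {
  data.frame(
    gene_id = sprintf("Gene%03d", seq_len(n_genes)),
    chromosome = chromosome %||% rep_len(c("1", "2", "3"), n_genes),
    start_bp = seq_len(n_genes) * 100000L,
    end_bp = seq_len(n_genes) * 100000L + width,
    biotype = "protein_coding",
    nssnp_count = nssnp %||% rep(0L, n_genes),
    predicted_flag = FALSE,
    stringsAsFactors = FALSE)
}
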