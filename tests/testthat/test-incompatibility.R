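test_that("pairwise LOD thresholds reproduce the genome-wide constants", {
  expect_equal(round(pairwise_lod_threshold(0.05, 1008), 1), 7.0)
  expect_equal(round(pairwise_lod_threshold(0.01, 1008), 1), 7.7)
  expect_equal(pairwise_lod_threshold(0.05, 1), -log10(0.1))
  # strict unordered-pair denominator stays available but differs
  expect_equal(pairwise_lod_threshold(0.05, 1008, strict_pairs = TRUE),
               -log10(0.05 / (1008 * 1007 / 2)))
})

test_that("pair table expectations are marginal products", {
  ids <- paste0("i", 1:150)
  # build genotypes realizing the diagonal-enriched table
  classes <- c("A", "H", "B")
  g1 <- character(150); g2 <- character(150)
  k <- 0
  tab <- matrix(c(30, 10, 10, 10, 30, 10, 10, 10, 30), 3, 3, byrow = TRUE)
  for (i in 1:3) for (j in 1:3) {
    idx <- k + seq_len(tab[i, j]); k <- k + tab[i, j]
    g1[idx] <- classes[i]; g2[idx] <- classes[j]
  }
  g <- make_geno(rbind(g1, g2), ids = ids, chromosome = c("1", "2"))
  pt <- pair_contingency(g, "mk1", "mk2")
  expect_equal(pt$n, 150)
  expect_equal(unname(pt$observed), tab)
  expect_true(all(abs(pt$expected - 150 / 9) < 1e-9))
  expect_equal(sum(pt$expected), pt$n, tolerance = 1e-6)

  res <- bdm_chi2(pt)
  expect_equal(res$chi2, 48.0, tolerance = 1e-9)
  expect_equal(res$chi2, chi2_oracle(unname(pt$observed)), tolerance = 1e-9)
  expect_equal(res$df, 4)
})

test_that("independence table gives chi2 = 0 and missingness shrinks n", {
  ids <- paste0("i", 1:90)
  g1 <- rep(c("A", "H", "B"), each = 30)
  g2 <- rep(rep(c("A", "H", "B"), each = 10), 3)
  g <- make_geno(rbind(g1, g2), ids = ids, chromosome = c("1", "2"))
  pt <- pair_contingency(g, "mk1", "mk2")
  expect_equal(unname(pt$observed), unname(pt$expected))
  expect_equal(bdm_chi2(pt)$chi2, 0)
  expect_equal(bdm_chi2(pt)$lod, 0)

  g2m <- g2; g2m[1] <- NA
  gm <- make_geno(rbind(g1, g2m), ids = ids, chromosome = c("1", "2"))
  ptm <- pair_contingency(gm, "mk1", "mk2")
  expect_equal(ptm$n, 89)
  expect_equal(sum(ptm$observed), 89)
  expect_equal(sum(ptm$expected), 89, tolerance = 1e-6)
})

test_that("same-chromosome pairs are refused", {
  g <- make_geno(rbind(c("A", "H"), c("B", "H")), ids = c("i1", "i2"),
                 chromosome = "1")
  expect_error(pair_contingency(g, "mk1", "mk2"), "same chromosome")
})

test_that("bdm_chi2 matches the brute-force oracle on random tables", {
  set.seed(99)
  for (i in 1:100) {
    tab <- matrix(rpois(9, lambda = sample(3:40, 1)), 3, 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- bdm_chi2(make_pair_table(tab))
    expect_equal(res$chi2, chi2_oracle(tab), tolerance = 1e-9)
    expect_equal(res$lod, -log10(res$p_value), tolerance = 1e-9)
  }
})

test_that("bdm_chi2 is symmetric under marker swap", {
  set.seed(5)
  tab <- matrix(rpois(9, 15) + 1, 3, 3)
  a <- bdm_chi2(make_pair_table(tab))
  b <- bdm_chi2(make_pair_table(t(tab)))
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$most_reduced_combo$class_1, b$most_reduced_combo$class_2)
  expect_equal(a$most_reduced_combo$class_2, b$most_reduced_combo$class_1)
})

test_that("an empty cell with the largest deficit is the most reduced combo", {
  tab <- matrix(c(30, 10, 10, 10, 30, 10, 25, 10, 0), 3, 3, byrow = TRUE)
  res <- bdm_chi2(make_pair_table(tab))
  expect_equal(res$most_reduced_combo$class_1, "HOM_B")
  expect_equal(res$most_reduced_combo$class_2, "HOM_B")
  expect_equal(res$most_reduced_combo$percent_reduction, 100)
})

test_that("degenerate tables reduce df or error", {
  tab <- matrix(c(10, 20, 5, 8, 25, 7, 0, 0, 0), 3, 3, byrow = TRUE)
  res <- bdm_chi2(make_pair_table(tab))
  expect_equal(res$df, 2)  # one empty row: (2-1) x (3-1)
  mono <- matrix(c(50, 30, 20, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  expect_error(bdm_chi2(make_pair_table(mono)), "monomorphic|degenerate")
})

test_that("simpleM recovers the marker count for independent markers and 1 for duplicates", {
  set.seed(31)
  n <- 1000
  indep <- matrix(sample(0:2, n * 50, TRUE, c(.25, .5, .25)), n, 50,
                  dimnames = list(paste0("i", 1:n), NULL))
  g <- geno_matrix(indep, data.frame(marker_id = paste0("m", 1:50),
                                     chromosome = "1",
                                     position_bp = 1:50 * 1000))
  em <- simple_m(g, fix_length = 1200, variance_fraction = 0.995)
  expect_equal(em$n_effective, 50L)

  dup <- indep[, rep(1, 50)]
  gd <- geno_matrix(dup, data.frame(marker_id = paste0("d", 1:50),
                                    chromosome = "1",
                                    position_bp = 1:50 * 1000))
  expect_equal(simple_m(gd)$n_effective, 1L)
})

test_that("blocked simpleM equals the whole-matrix eigen oracle for one block", {
  sim <- simulate_ail(sim_config(n_chromosomes = 1,
                                 markers_per_chromosome = 120,
                                 generations = 6, families_per_generation = 30,
                                 litter_size = 4, seed = 17))
  kids <- build_trios(sim$pedigree, 6, sim$genotypes)$child_id
  em <- simple_m(sim$genotypes, fix_length = 1200, ids = kids)
  # oracle: direct eigen-decomposition of the full correlation matrix
  m <- unclass(sim$genotypes)[kids, ]
  ev <- eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values
  oracle <- which(cumsum(pmax(ev, 0)) / sum(pmax(ev, 0)) >= 0.995 - 1e-12)[1]
  expect_equal(em$n_effective, oracle)
  expect_lt(em$n_effective, 120L)
  # with full coverage the estimate is the matrix rank (up to the numerical
  # fuzz of near-zero eigenvalues in an n ~ p correlation matrix)
  full <- simple_m(sim$genotypes, variance_fraction = 1,
                   ids = kids)$n_effective
  expect_lte(abs(full - qr(cor(m))$rank), 2)
})

test_that("pairwise_scan tests cross-chromosome pairs and skips same-chromosome ones", {
  sim <- simulate_ail(sim_config(n_chromosomes = 3,
                                 markers_per_chromosome = 30,
                                 generations = 5, families_per_generation = 40,
                                 litter_size = 4, seed = 23))
  map <- marker_map(sim$genotypes)
  mk_region <- function(id, idx) data.frame(
    region_id = id, chromosome = map$chromosome[idx],
    proximal_bp = map$position_bp[idx], top_bp = map$position_bp[idx],
    distal_bp = map$position_bp[idx], top_marker_id = map$marker_id[idx],
    stringsAsFactors = FALSE)
  regions <- rbind(mk_region("R1", 5), mk_region("R2", 25),  # both chr 1
                   mk_region("R3", 40), mk_region("R4", 70))
  kids <- build_trios(sim$pedigree, 5, sim$genotypes)$child_id
  # small trio counts make some expected cells < 5; that warning is expected
  res <- suppressWarnings(pairwise_scan(regions, sim$genotypes,
                                        effective = 100, individuals = kids))
  expect_equal(nrow(res), 6L)
  r12 <- res[res$region_1 == "R1" & res$region_2 == "R2", ]
  expect_equal(r12$status, "not_tested")
  tested <- res[res$status != "not_tested", ]
  expect_equal(nrow(tested), 5L)
  expect_true(all(is.finite(tested$lod)))
  thr <- attr(res, "thresholds")
  expect_equal(unname(thr[1]), pairwise_lod_threshold(0.05, 100))
})
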