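test_that("transmission chi-square follows the asymmetry formula", {
  r <- transmission_chi2(169, 48)
  expect_equal(r$chi2, 121^2 / 217)
  expect_lt(r$p_value, 1e-14)
  expect_equal(r$preferred_allele, "A")

  expect_equal(transmission_chi2(100, 100)$chi2, 0)
  expect_equal(transmission_chi2(100, 100)$p_value, 1)
  expect_equal(transmission_chi2(100, 100)$lod, 0)
  expect_equal(transmission_chi2(100, 100)$preferred_allele, "none")

  expect_equal(transmission_chi2(207, 47)$chi2, 160^2 / 254)
  expect_error(transmission_chi2(0, 0), ">= 1")
})

test_that("chi-square is symmetric in the two alleles and monotone in imbalance", {
  for (ab in list(c(10, 50), c(3, 97), c(40, 41))) {
    r1 <- transmission_chi2(ab[1], ab[2])
    r2 <- transmission_chi2(ab[2], ab[1])
    expect_equal(r1$chi2, r2$chi2)
    expect_equal(r1$p_value, r2$p_value)
    expect_setequal(c(r1$preferred_allele, r2$preferred_allele), c("A", "B"))
  }
  tot <- 200
  chi <- vapply(100:199, function(a)
    transmission_chi2(a, tot - a)$chi2, numeric(1))
  expect_true(all(diff(chi) > 0))
})

test_that("LOD is -log10(p) and extreme counts are floored, not NaN", {
  r <- transmission_chi2(5000, 10)
  expect_true(is.finite(r$lod))
  expect_true(r$underflow)
  expect_gt(r$p_value, 0)
  r2 <- transmission_chi2(60, 40)
  expect_equal(r2$lod, -log10(r2$p_value), tolerance = 1e-9)
})

test_that("distortion percent reproduces the worked transmission counts", {
  expect_equal(distortion_percent(169, 48), 55.8, tolerance = 0.05)
  expect_equal(distortion_percent(152, 30), 67.0, tolerance = 0.05)
  expect_equal(distortion_percent(10, 130), -85.7, tolerance = 0.05)
  expect_equal(distortion_percent(77, 77), 0)
})

test_that("Bonferroni LOD threshold is the closed form -log10(alpha / n)", {
  expect_equal(bonferroni_lod_threshold(0.05, 1), -log10(0.05))
  expect_equal(bonferroni_lod_threshold(0.01, 1), 2.0)
  expect_equal(bonferroni_lod_threshold(0.05, 1000), 4 + log10(2),
               tolerance = 1e-12)
})

test_that("transmissions resolve only when the co-parent pins the allele", {
  # trios: (sire, dam, child) genotype rows per marker
  ids <- c("f", "m", "c1", "c2", "c3")
  g <- make_geno(rbind(
    c("H", "A", "H", "A", "A"),   # father het, mother HOM_A
    c("H", "H", "A", "B", "H"),   # double het: never counted
    c("H", "B", "B", "H", "B")),  # father het, mother HOM_B
    ids = ids)
  trios <- data.frame(child_id = c("c1", "c2", "c3"),
                      sire_id = "f", dam_id = "m",
                      stringsAsFactors = FALSE)
  ct <- count_transmissions(g, trios, "paternal")
  # mk1: c1 HET -> B transmitted; c2,c3 HOM_A -> A transmitted
  expect_equal(ct[ct$marker_id == "mk1", c("n_A", "n_B")],
               data.frame(n_A = 2L, n_B = 1L), ignore_attr = TRUE)
  # mk2: both parents het -> all skipped
  expect_equal(ct[ct$marker_id == "mk2", "n_A"], 0L)
  expect_equal(ct[ct$marker_id == "mk2", "n_skipped_double_het"], 3L)
  # mk3: c1 HOM_B -> B; c2 HET -> A; c3 HOM_B -> B
  expect_equal(ct[ct$marker_id == "mk3", c("n_A", "n_B")],
               data.frame(n_A = 1L, n_B = 2L), ignore_attr = TRUE)
  # maternal scan of mk1: mother is not heterozygous, nothing counted
  cm <- count_transmissions(g, trios, "maternal")
  expect_equal(cm[cm$marker_id == "mk1", "n_A"] +
                 cm[cm$marker_id == "mk1", "n_B"], 0L)
})

test_that("transmission counts never exceed the heterozygous-parent meioses", {
  sim <- simulate_ail(sim_config(n_chromosomes = 2,
                                 markers_per_chromosome = 50,
                                 generations = 5, families_per_generation = 25,
                                 litter_size = 4, seed = 9))
  trios <- build_trios(sim$pedigree, 5, sim$genotypes)
  ct <- count_transmissions(sim$genotypes, trios, "paternal")
  fo <- unclass(sim$genotypes)[trios$sire_id, , drop = FALSE]
  het_meioses <- colSums(fo == 1L, na.rm = TRUE)
  expect_true(all(ct$n_A + ct$n_B <= het_meioses))
  expect_true(all(ct$n_A + ct$n_B + ct$n_skipped_double_het <= het_meioses))
})

test_that("marker eligibility enforces the 10-heterozygous-parent floor and HWE", {
  set.seed(42)
  n_par <- 24
  n_kid <- 60
  # mk1: 9 het sires (boundary fail); mk2: 10 het sires (pass);
  # mk3: gross heterozygote deficit in offspring (HWE fail)
  par_calls <- rbind(c(rep("H", 9), rep("A", n_par - 9)),
                     c(rep("H", 10), rep("A", n_par - 10)),
                     c(rep("H", 12), rep("A", n_par - 12)))
  kid_calls <- rbind(sample(c("A", "H", "B"), n_kid, TRUE, c(.25, .5, .25)),
                     sample(c("A", "H", "B"), n_kid, TRUE, c(.25, .5, .25)),
                     sample(c("A", "B"), n_kid, TRUE))   # no hets at all
  sires <- paste0("s", seq_len(n_par / 2))
  dams <- paste0("d", seq_len(n_par / 2))
  kids <- paste0("k", seq_len(n_kid))
  g <- make_geno(cbind(par_calls, kid_calls), ids = c(sires, dams, kids))
  trios <- data.frame(child_id = kids,
                      sire_id = rep(sires, length.out = n_kid),
                      dam_id = rep(dams, length.out = n_kid),
                      stringsAsFactors = FALSE)
  elig <- eligible_markers(g, trios, "paternal", scan_config())
  expect_false("mk1" %in% elig)
  expect_true("mk2" %in% elig)
  expect_false("mk3" %in% elig)
  bad <- attr(elig, "ineligible")
  expect_equal(bad$reason[bad$marker_id == "mk1"], "too_few_het_parents")
  expect_equal(bad$reason[bad$marker_id == "mk3"], "hwe")
})

test_that("region calling groups contiguous significant markers", {
  mk_res <- function(lods, pref = "A", chr = "1", bp = NULL) {
    n <- length(lods)
    data.frame(marker_id = paste0("m", seq_len(n)), chromosome = chr,
               position_bp = bp %||% seq_len(n) * 1e6,
               parent_sex = "paternal",
               n_A = 150L, n_B = 50L, n_het_parents = 60L,
               n_skipped_double_het = 0L, chi2 = 50, p_value = 1e-9,
               lod = lods, preferred_allele = pref, underflow = FALSE,
               stringsAsFactors = FALSE)
  }
  cfg <- scan_config()
  # contiguous run: one region, top = middle marker
  r1 <- call_regions(mk_res(c(8, 9, 8)), cfg)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_snps, 3L)
  expect_equal(r1$top_marker_id, "m2")
  expect_equal(r1$region_id, "Pat_R1")
  expect_equal(r1$size_bp, r1$distal_bp - r1$proximal_bp)

  # one sub-threshold marker inside: bridged at the default tolerance,
  # split when no sub-threshold markers are tolerated
  r2 <- call_regions(mk_res(c(8, 2, 9)), cfg)
  expect_equal(nrow(r2), 1L)
  r2b <- call_regions(mk_res(c(8, 2, 9)),
                      scan_config(max_nonsig_run = 0))
  expect_equal(nrow(r2b), 2L)

  # more intervening sub-threshold markers than tolerated: split
  r3 <- call_regions(mk_res(c(8, 2, 2, 2, 2, 9)), cfg)
  expect_equal(nrow(r3), 2L)

  # bp gap beyond merge_gap_bp splits even adjacent significant markers
  r4 <- call_regions(mk_res(c(8, 9), bp = c(1e6, 7.5e6)), cfg)
  expect_equal(nrow(r4), 2L)

  # opposite preferred alleles never share a region
  r5 <- call_regions(mk_res(c(8, 9, 8), pref = c("A", "B", "B")), cfg)
  expect_equal(nrow(r5), 2L)

  # LOD tie: top marker falls on the proximal member
  r6 <- call_regions(mk_res(c(8.5, 8.5, 8.5)), cfg)
  expect_equal(r6$top_marker_id, "m1")
  expect_equal(r6$top_bp, 1e6)

  # empty input
  expect_equal(nrow(call_regions(mk_res(c(1, 2, 3)), cfg)), 0L)
})

test_that("region summaries average member-marker transmissions and sign distortion", {
  res <- data.frame(marker_id = c("m1", "m2", "m3"), chromosome = "2",
                    position_bp = c(1e6, 2e6, 3e6), parent_sex = "maternal",
                    n_A = c(20L, 22L, 24L), n_B = c(130L, 128L, 120L),
                    n_het_parents = 60L, n_skipped_double_het = 0L,
                    chi2 = 70, p_value = 1e-16,
                    lod = c(16, 18, 15), preferred_allele = "B",
                    underflow = FALSE, stringsAsFactors = FALSE)
  rg <- call_regions(res, scan_config())
  expect_equal(rg$region_id, "Mat_R1")
  expect_equal(rg$mean_n_A, 22)
  expect_equal(rg$sd_n_A, sd(c(20, 22, 24)))
  expect_equal(rg$top_marker_id, "m2")
  expect_lt(rg$distortion_percent, 0)
  expect_equal(rg$distortion_percent, distortion_percent(22, 128))
  expect_equal(rg$member_markers[[1]], c("m1", "m2", "m3"))
})
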