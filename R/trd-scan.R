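#' Scan configuration
#'
#' Bundles the tunable constants of the transmission-asymmetry scan.  The
#' default LOD thresholds are the genome-wide Bonferroni constants used for
#' the marker-level scan (5% at 6.75, 1% at 7.45);
#' [bonferroni_lod_threshold()] derives thresholds for other test counts.
#'
#' @param min_het_parents minimum number of distinct heterozygous parents of
#'   the focal sex for a marker to be testable (default 10)
#' @param hwe_alpha significance level below which a marker is excluded as
#'   out of Hardy-Weinberg equilibrium in the offspring generation
#'   (default 0.01)
#' @param lod_threshold_5pct,lod_threshold_1pct genome-wide LOD thresholds
#'   (defaults 6.75 and 7.45); regions are called at the 1% threshold
#' @param merge_gap_bp maximum distance in bp between consecutive significant
#'   markers of one region (default 5e6)
#' @param max_nonsig_run maximum number of consecutive sub-threshold markers
#'   tolerated inside a region before the run is broken (default 3)
#' @return list of class `scan_config`.
#' @export
scan_config <- function(min_het_parents = 10, hwe_alpha = 0.01,
                        lod_threshold_5pct = 6.75, lod_threshold_1pct = 7.45,
                        merge_gap_bp = 5e6, max_nonsig_run = 3) {
  stopifnot(min_het_parents >= 1, hwe_alpha > 0, hwe_alpha < 1,
            lod_threshold_5pct > 0, lod_threshold_1pct > 0,
            merge_gap_bp >= 0, max_nonsig_run >= 0)
  structure(list(min_het_parents = as.integer(min_het_parents),
                 hwe_alpha = hwe_alpha,
                 lod_threshold_5pct = lod_threshold_5pct,
                 lod_threshold_1pct = lod_threshold_1pct,
                 merge_gap_bp = merge_gap_bp,
                 max_nonsig_run = as.integer(max_nonsig_run)),
            class = "scan_config")
}

#' Bonferroni-corrected LOD threshold
#'
#' @param alpha family-wise significance level in (0, 1)
#' @param n_tests number of tests
#' @return the LOD threshold `-log10(alpha / n_tests)`.
#' @export
bonferroni_lod_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  -log10(alpha / n_tests)
}

#' Markers eligible for the transmission test
#'
#' A marker is eligible when it is informative between the founders, has at
#' least `min_het_parents` distinct heterozygous parents of the focal sex
#' among the trio parents, and is in Hardy-Weinberg equilibrium in the
#' offspring generation at `hwe_alpha`.  Call-rate filtering is assumed done
#' beforehand via [marker_qc()].
#'
#' @param genotypes a [geno_matrix]
#' @param trios trio data frame ([build_trios()]); children define the
#'   offspring generation, parents the transmitting generation
#' @param parent_sex `"paternal"` or `"maternal"`
#' @param config a [scan_config()]
#' @return character vector of eligible marker ids, with attribute
#'   `ineligible` (data frame `marker_id`, `reason` in `"uninformative"`,
#'   `"too_few_het_parents"`, `"hwe"`).
#' @export
eligible_markers <- function(genotypes, trios, parent_sex = c("paternal", "maternal"),
                             config = scan_config()) {
  parent_sex <- match.arg(parent_sex)
  map <- marker_map(genotypes)
  parents <- unique(if (parent_sex == "paternal") trios$sire_id else trios$dam_id)
  pg <- unclass(genotypes)[parents, , drop = FALSE]
  n_het <- colSums(pg == 1L, na.rm = TRUE)
  hwe_p <- hwe_pvalues(genotypes, ids = unique(trios$child_id))
  uninf <- !map$informative
  few <- n_het < config$min_het_parents
  hwe_fail <- !is.na(hwe_p) & hwe_p < config$hwe_alpha
  reason <- rep(NA_character_, nrow(map))
  reason[hwe_fail] <- "hwe"
  reason[few] <- "too_few_het_parents"
  reason[uninf] <- "uninformative"
  ok <- is.na(reason)
  out <- map$marker_id[ok]
  attr(out, "ineligible") <- data.frame(marker_id = map$marker_id[!ok],
                                        reason = reason[!ok],
                                        stringsAsFactors = FALSE)
  out
}

#' Count allele transmissions from heterozygous parents
#'
#' For every trio whose focal-sex parent is heterozygous at a marker, the
#' transmitted allele is resolved from the other parent's genotype and the
#' child's genotype.  When both parents are heterozygous the transmission
#' cannot be determined and the trio is counted as skipped; trios with a
#' missing genotype or a Mendelian-impossible child are not counted.
#'
#' @param genotypes a [geno_matrix]
#' @param trios trio data frame
#' @param parent_sex `"paternal"` or `"maternal"`
#' @param markers marker ids to count (default all)
#' @return data frame, one row per marker: `marker_id`, `parent_sex`, `n_A`,
#'   `n_B`, `n_het_parents` (distinct heterozygous focal parents),
#'   `n_skipped_double_het`.
#' @export
count_transmissions <- function(genotypes, trios,
                                parent_sex = c("paternal", "maternal"),
                                markers = NULL) {
  parent_sex <- match.arg(parent_sex)
  map <- marker_map(genotypes)
  if (is.null(markers)) markers <- map$marker_id
  g <- unclass(genotypes)[, markers, drop = FALSE]
  focal_ids <- if (parent_sex == "paternal") trios$sire_id else trios$dam_id
  other_ids <- if (parent_sex == "paternal") trios$dam_id else trios$sire_id
  fo <- g[focal_ids, , drop = FALSE]
  ot <- g[other_ids, , drop = FALSE]
  ch <- g[trios$child_id, , drop = FALSE]
  het <- !is.na(fo) & fo == 1L
  # forced resolutions: non-het co-parent determines which allele came from
  # the heterozygous focal parent
  n_A <- colSums(het & !is.na(ot) & !is.na(ch) &
                   ((ot == 0L & ch == 0L) | (ot == 2L & ch == 1L)), na.rm = TRUE)
  n_B <- colSums(het & !is.na(ot) & !is.na(ch) &
                   ((ot == 0L & ch == 1L) | (ot == 2L & ch == 2L)), na.rm = TRUE)
  dbl <- colSums(het & !is.na(ot) & ot == 1L, na.rm = TRUE)
  pu <- unclass(genotypes)[unique(focal_ids), markers, drop = FALSE]
  n_het_par <- colSums(pu == 1L, na.rm = TRUE)
  data.frame(marker_id = markers, parent_sex = parent_sex,
             n_A = as.integer(n_A), n_B = as.integer(n_B),
             n_het_parents = as.integer(n_het_par),
             n_skipped_double_het = as.integer(dbl),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transmission-asymmetry chi-square test
#'
#' Tests whether transmissions from heterozygous parents deviate from the
#' Mendelian 50:50 expectation using
#' \deqn{\chi^2 = (n_A - n_B)^2 / (n_A + n_B)}
#' on one degree of freedom (no continuity correction), with the p-value
#' converted to a LOD score `-log10(p)`.  P-values below double-precision
#' underflow are floored at the smallest positive representable value and
#' flagged.
#'
#' @param n_A,n_B transmission counts of the founder-A and founder-B allele
#'   (vectors allowed; `n_A + n_B >= 1`)
#' @return data frame with `chi2`, `p_value`, `lod`, `preferred_allele`
#'   (`"A"`, `"B"` or `"none"`), `underflow` (logical).
#' @export
transmission_chi2 <- function(n_A, n_B) {
  tot <- n_A + n_B
  if (any(tot < 1)) stop("n_A + n_B must be >= 1")
  chi2 <- (n_A - n_B)^2 / tot
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  under <- p < .Machine$double.xmin
  p[under] <- .Machine$double.xmin
  data.frame(chi2 = chi2, p_value = p, lod = -log10(p),
             preferred_allele = ifelse(n_A > n_B, "A",
                                       ifelse(n_B > n_A, "B", "none")),
             underflow = under, stringsAsFactors = FALSE)
}

#' Signed transmission distortion percent
#'
#' Excess of founder-A transmissions over the Mendelian expectation,
#' `100 * (n_A - (n_A + n_B)/2) / ((n_A + n_B)/2)`; positive values mean the
#' founder-A allele is over-transmitted.
#'
#' @param n_A,n_B transmission counts (vectors allowed; total >= 1)
#' @return signed percent.
#' @export
distortion_percent <- function(n_A, n_B) {
  tot <- n_A + n_B
  if (any(tot < 1)) stop("n_A + n_B must be >= 1")
  expd <- tot / 2
  100 * (n_A - expd) / expd
}

#' Per-marker transmission-distortion scan
#'
#' Runs marker eligibility, transmission counting and the chi-square test
#' for one parental sex, returning one row per eligible marker in map order.
#'
#' @param genotypes a [geno_matrix] (after [marker_qc()])
#' @param trios trio data frame
#' @param parent_sex `"paternal"` or `"maternal"`
#' @param config a [scan_config()]
#' @return data frame: `marker_id`, `chromosome`, `position_bp`,
#'   `parent_sex`, `n_A`, `n_B`, `n_het_parents`, `n_skipped_double_het`,
#'   `chi2`, `p_value`, `lod`, `preferred_allele`, `underflow`; attribute
#'   `ineligible` as in [eligible_markers()].
#' @export
trd_scan <- function(genotypes, trios, parent_sex = c("paternal", "maternal"),
                     config = scan_config()) {
  parent_sex <- match.arg(parent_sex)
  elig <- eligible_markers(genotypes, trios, parent_sex, config)
  map <- marker_map(genotypes)
  map <- map[map$marker_id %in% elig, , drop = FALSE]
  cnt <- count_transmissions(genotypes, trios, parent_sex, markers = map$marker_id)
  cnt <- cnt[cnt$n_A + cnt$n_B >= 1, , drop = FALSE]
  map <- map[match(cnt$marker_id, map$marker_id), , drop = FALSE]
  tst <- transmission_chi2(cnt$n_A, cnt$n_B)
  out <- cbind(data.frame(marker_id = cnt$marker_id,
                          chromosome = map$chromosome,
                          position_bp = map$position_bp,
                          stringsAsFactors = FALSE),
               cnt[, c("parent_sex", "n_A", "n_B", "n_het_parents",
                       "n_skipped_double_het")],
               tst)
  rownames(out) <- NULL
  attr(out, "ineligible") <- attr(elig, "ineligible")
  out
}

#' Call transmission-distortion regions
#'
#' Groups consecutive markers above the 1% LOD threshold into regions.  A
#' region extends from the first to the last flanking significant marker of
#' a run; a run is broken by a chromosome change, a change of preferred
#' allele, a gap of more than `merge_gap_bp` between consecutive significant
#' markers, or more than `max_nonsig_run` consecutive sub-threshold markers.
#' The top marker is the member with maximal LOD, ties resolved toward the
#' proximal (smaller bp) marker; the region's distortion percent is computed
#' at the top marker.
#'
#' @param results per-marker scan results from [trd_scan()] (one parental
#'   sex, sorted by chromosome and position, as returned)
#' @param config a [scan_config()]
#' @return data frame, one row per region: `region_id` (`Pat_R#` / `Mat_R#`),
#'   `chromosome`, `proximal_bp`, `top_bp`, `distal_bp`, `size_bp`, `n_snps`,
#'   `preferred_allele`, `mean_n_A`, `sd_n_A`, `mean_n_B`, `sd_n_B`,
#'   `top_marker_id`, `top_n_A`, `top_n_B`, `distortion_percent`,
#'   `member_markers` (list column).
#' @export
call_regions <- function(results, config = scan_config()) {
  empty <- data.frame(region_id = character(), chromosome = character(),
                      proximal_bp = integer(), top_bp = integer(),
                      distal_bp = integer(), size_bp = integer(),
                      n_snps = integer(), preferred_allele = character(),
                      mean_n_A = numeric(), sd_n_A = numeric(),
                      mean_n_B = numeric(), sd_n_B = numeric(),
                      top_marker_id = character(), top_n_A = integer(),
                      top_n_B = integer(), distortion_percent = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(results)) return(empty)
  stopifnot(length(unique(results$parent_sex)) == 1)
  thr <- config$lod_threshold_1pct
  r <- results[order(chrom_rank(results$chromosome), results$position_bp), ]
  sig <- which(r$lod >= thr & r$preferred_allele != "none")
  if (!length(sig)) return(empty)
  # break runs of significant markers into regions
  grp <- integer(length(sig))
  grp[1] <- 1L
  if (length(sig) > 1) {
    for (i in 2:length(sig)) {
      a <- sig[i - 1]; b <- sig[i]
      new_region <-
        r$chromosome[b] != r$chromosome[a] ||
        r$preferred_allele[b] != r$preferred_allele[a] ||
        (r$position_bp[b] - r$position_bp[a]) > config$merge_gap_bp ||
        (b - a - 1L) > config$max_nonsig_run
      grp[i] <- grp[i - 1] + new_region
    }
  }
  prefix <- if (r$parent_sex[1] == "paternal") "Pat_R" else "Mat_R"
  regions <- lapply(split(sig, grp), function(idx) {
    mem <- r[idx, ]
    top <- idx[which.max(mem$lod)]  # which.max takes the first (proximal) tie
    row <- data.frame(chromosome = mem$chromosome[1],
               proximal_bp = mem$position_bp[1],
               top_bp = r$position_bp[top],
               distal_bp = mem$position_bp[nrow(mem)],
               size_bp = mem$position_bp[nrow(mem)] - mem$position_bp[1],
               n_snps = nrow(mem),
               preferred_allele = mem$preferred_allele[1],
               mean_n_A = mean(mem$n_A), sd_n_A = sd(mem$n_A),
               mean_n_B = mean(mem$n_B), sd_n_B = sd(mem$n_B),
               top_marker_id = r$marker_id[top],
               top_n_A = r$n_A[top], top_n_B = r$n_B[top],
               distortion_percent = distortion_percent(r$n_A[top], r$n_B[top]),
               stringsAsFactors = FALSE)
    row$member_markers <- list(mem$marker_id)
    row
  })
  out <- do.call(rbind, regions)
  out <- out[order(chrom_rank(out$chromosome), out$proximal_bp), ]
  out <- cbind(region_id = paste0(prefix, seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
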