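#' Effective number of independent tests (simpleM)
#'
#' Estimates the effective number of independent marker tests from the
#' eigenvalue spectrum of the marker-marker genotype correlation matrix,
#' accounting for linkage.  Markers are split per chromosome into consecutive
#' blocks of at most `fix_length`; within each block, genotypes coded as
#' 0/1/2 allele dosage are correlated (pairwise-complete observations) and
#' the block's contribution is the smallest number of leading eigenvalues
#' whose sum covers `variance_fraction` of the total; the estimate is the
#' sum over blocks.  Negative eigenvalues, which pairwise-complete
#' correlation matrices can produce, are clamped to zero.
#'
#' @param genotypes a [geno_matrix]
#' @param fix_length maximum markers per block (default 1200)
#' @param variance_fraction eigenvalue coverage (default 0.995)
#' @param ids optional individual ids to restrict to
#' @return list of class `effective_tests`: `n_effective`, `fix_length`,
#'   `variance_fraction`, `blocks` (per-block data frame), `n_markers_used`,
#'   `n_markers_dropped` (zero-variance markers).
#' @export
simple_m <- function(genotypes, fix_length = 1200, variance_fraction = 0.995,
                     ids = NULL) {
  stopifnot(fix_length >= 1, variance_fraction > 0, variance_fraction <= 1)
  map <- marker_map(genotypes)
  m <- unclass(genotypes)
  if (!is.null(ids)) m <- m[ids, , drop = FALSE]
  dropped <- 0L
  blocks <- list()
  for (chr in unique(map$chromosome)) {
    jj <- which(map$chromosome == chr)
    splits <- split(jj, ceiling(seq_along(jj) / fix_length))
    for (b in seq_along(splits)) {
      x <- m[, splits[[b]], drop = FALSE]
      v <- apply(x, 2, stats::var, na.rm = TRUE)
      keep <- !is.na(v) & v > 0
      dropped <- dropped + sum(!keep)
      x <- x[, keep, drop = FALSE]
      if (!ncol(x)) {
        warning(sprintf("block %s/%d has no variable markers; dropped", chr, b))
        next
      }
      if (ncol(x) == 1) {
        meff <- 1L
      } else {
        cc <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
        cc[is.na(cc)] <- 0
        diag(cc) <- 1
        ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
        ev <- pmax(ev, 0)
        meff <- which(cumsum(ev) / sum(ev) >= variance_fraction - 1e-12)[1]
      }
      blocks[[length(blocks) + 1]] <-
        data.frame(chromosome = chr, block = b, n_markers = ncol(x),
                   m_eff = as.integer(meff), stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, blocks)
  structure(list(n_effective = sum(blocks$m_eff),
                 fix_length = as.integer(fix_length),
                 variance_fraction = variance_fraction,
                 blocks = blocks,
                 n_markers_used = sum(blocks$n_markers),
                 n_markers_dropped = dropped),
            class = "effective_tests")
}

#' @export
print.effective_tests <- function(x, ...) {
  cat(sprintf("simpleM effective tests: %d (from %d markers, fixLength %d, coverage %.3f)\n",
              x$n_effective, x$n_markers_used, x$fix_length, x$variance_fraction))
  invisible(x)
}

#' Genome-wide LOD threshold for the pairwise incompatibility scan
#'
#' Bonferroni correction over the effective number of region pairs.  The
#' default denominator is `n_effective^2 * 0.5` (each unordered pair of
#' effective tests counted once); `strict_pairs = TRUE` uses
#' `n_effective * (n_effective - 1) / 2` instead.
#'
#' @param alpha family-wise significance level in (0, 1)
#' @param n_effective effective number of tests ([simple_m()])
#' @param strict_pairs use the exact unordered-pair count (default FALSE)
#' @return LOD threshold `-log10(alpha / denominator)`.
#' @export
pairwise_lod_threshold <- function(alpha, n_effective, strict_pairs = FALSE) {
  stopifnot(alpha > 0, alpha < 1, n_effective >= 1)
  denom <- if (strict_pairs) n_effective * (n_effective - 1) / 2 else
    n_effective^2 * 0.5
  -log10(alpha / denom)
}

#' Two-marker genotype co-occurrence table
#'
#' 3x3 observed counts over genotype classes (`HOM_A`, `HET`, `HOM_B`) at two
#' unlinked markers, with expected counts from the marginal products under
#' independent segregation.  Individuals missing at either marker are
#' excluded.  Markers on the same chromosome are refused: linkage, not
#' incompatibility, would dominate the table.
#'
#' @param genotypes a [geno_matrix]
#' @param marker_1,marker_2 marker ids on different chromosomes
#' @param individuals individual ids to count (default all)
#' @return list of class `pair_table`: `marker_1`, `marker_2`, `observed`,
#'   `expected` (3x3 matrices), `n`.
#' @export
pair_contingency <- function(genotypes, marker_1, marker_2,
                             individuals = NULL) {
  map <- marker_map(genotypes)
  chr <- map$chromosome[match(c(marker_1, marker_2), map$marker_id)]
  if (anyNA(chr)) stop("unknown marker id")
  if (chr[1] == chr[2])
    stop("markers on the same chromosome: incompatibility test not performed")
  m <- unclass(genotypes)
  if (!is.null(individuals)) m <- m[individuals, , drop = FALSE]
  g1 <- m[, marker_1]
  g2 <- m[, marker_2]
  ok <- !is.na(g1) & !is.na(g2)
  if (!sum(ok)) stop("no individuals genotyped at both markers")
  obs <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  obs <- matrix(as.numeric(obs), 3, 3,
                dimnames = list(GENO_LEVELS, GENO_LEVELS))
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  if (any(expd > 0 & expd < 5))
    warning("expected cell count below 5 in pair table")
  structure(list(marker_1 = marker_1, marker_2 = marker_2,
                 observed = obs, expected = expd, n = n),
            class = "pair_table")
}

#' Chi-square test of a two-marker co-occurrence table
#'
#' Tests the 3x3 observed table against independent segregation:
#' `chi2 = sum((O - E)^2 / E)` over cells with `E > 0`, with degrees of
#' freedom `(r - 1)(c - 1)` over the non-empty marginal classes (4 for a
#' full table), p-value from the chi-square upper tail, and LOD `-log10(p)`.
#' Also reports the genotype-class combination with the largest percent
#' reduction of observed relative to expected co-occurrence — the putative
#' incompatible combination.
#'
#' @param tab a [pair_contingency()] table
#' @return list of class `incompat_test`: the `pair_table` plus `chi2`, `df`,
#'   `p_value`, `lod`, `underflow`, and `most_reduced_combo` (list
#'   `class_1`, `class_2`, `percent_reduction`).
#' @export
bdm_chi2 <- function(tab) {
  obs <- tab$observed
  expd <- tab$expected
  rows <- rowSums(obs) > 0
  cols <- colSums(obs) > 0
  df <- (sum(rows) - 1) * (sum(cols) - 1)
  if (df < 1) stop("degenerate table: a marker is monomorphic among counted individuals")
  pos <- expd > 0
  chi2 <- sum((obs[pos] - expd[pos])^2 / expd[pos])
  p <- pchisq(chi2, df = df, lower.tail = FALSE)
  under <- p < .Machine$double.xmin
  if (under) p <- .Machine$double.xmin
  red <- 100 * (expd - obs) / expd
  red[!pos] <- -Inf
  top <- arrayInd(which.max(red), dim(red))
  structure(c(unclass(tab),
              list(chi2 = chi2, df = df, p_value = p, lod = -log10(p),
                   underflow = under,
                   most_reduced_combo = list(
                     class_1 = GENO_LEVELS[top[1]],
                     class_2 = GENO_LEVELS[top[2]],
                     percent_reduction = red[top]))),
            class = "incompat_test")
}

#' Pairwise incompatibility scan between TRD regions
#'
#' Tests every unordered pair of regions lying on different chromosomes for
#' non-independent segregation of their top markers; same-chromosome pairs
#' are reported as `not_tested`.  Significance is judged against the
#' genome-wide thresholds from [pairwise_lod_threshold()].
#'
#' @param regions region data frame from [call_regions()] (regions from
#'   several scans may be row-bound; >= 2 rows)
#' @param genotypes a [geno_matrix]
#' @param effective an `effective_tests` object from [simple_m()], or an
#'   integer effective-test count
#' @param alpha_levels two significance levels, `c(significant,
#'   highly_significant)` (default `c(0.05, 0.01)`)
#' @param individuals individual ids to count (default all; typically the
#'   offspring generation used for the TRD scan)
#' @return data frame, one row per region pair: ids, chromosomes, top
#'   markers, `chi2`, `lod`, `status` (`not_tested`, `ns`, `significant`,
#'   `highly_significant`), `combo_1`, `combo_2`, `percent_reduction`;
#'   attributes `thresholds` (named numeric) and `tests` (list of
#'   `incompat_test` objects, named `"id1|id2"`).
#' @export
pairwise_scan <- function(regions, genotypes, effective,
                          alpha_levels = c(0.05, 0.01), individuals = NULL) {
  if (nrow(regions) < 2) stop("need at least two regions")
  n_eff <- if (inherits(effective, "effective_tests")) effective$n_effective
           else as.integer(effective)
  thr <- vapply(alpha_levels, pairwise_lod_threshold, numeric(1),
                n_effective = n_eff)
  names(thr) <- paste0("alpha_", alpha_levels)
  pairs <- utils::combn(nrow(regions), 2)
  tests <- list()
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    base <- data.frame(region_1 = regions$region_id[i],
                       region_2 = regions$region_id[j],
                       chr_1 = regions$chromosome[i],
                       chr_2 = regions$chromosome[j],
                       marker_1 = regions$top_marker_id[i],
                       marker_2 = regions$top_marker_id[j],
                       stringsAsFactors = FALSE)
    if (regions$chromosome[i] == regions$chromosome[j])
      return(cbind(base, chi2 = NA_real_, lod = NA_real_,
                   status = "not_tested", combo_1 = NA_character_,
                   combo_2 = NA_character_, percent_reduction = NA_real_,
                   stringsAsFactors = FALSE))
    tst <- bdm_chi2(pair_contingency(genotypes, base$marker_1, base$marker_2,
                                     individuals = individuals))
    tests[[paste(base$region_1, base$region_2, sep = "|")]] <<- tst
    status <- if (tst$lod > thr[2]) "highly_significant"
              else if (tst$lod > thr[1]) "significant" else "ns"
    cbind(base, chi2 = tst$chi2, lod = tst$lod, status = status,
          combo_1 = tst$most_reduced_combo$class_1,
          combo_2 = tst$most_reduced_combo$class_2,
          percent_reduction = tst$most_reduced_combo$percent_reduction,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thr
  attr(out, "tests") <- tests
  out
}
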