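#' Permutation test for nsSNP overrepresentation
#'
#' Compares the number of nonsynonymous SNPs carried by an observed gene set
#' (e.g. the protein-coding genes inside TRD regions) against a null built by
#' repeatedly drawing the same number of distinct protein-coding genes at
#' random from the annotation, excluding predicted genes (GM/RIKEN-style
#' symbols).  The empirical p-value uses the add-one estimator
#' `(1 + r) / (n_permutations + 1)` where `r` counts permutations whose total
#' nsSNP count reaches the observed total, so a zero-exceedance run reports
#' `1/(n+1)` rather than zero.
#'
#' @param annotation data frame with columns `gene_id`, `biotype`,
#'   `nssnp_count`, and optionally `predicted_flag` (derived from
#'   `predicted_pattern` when absent)
#' @param observed_genes gene ids of the observed set
#' @param n_permutations number of random draws (default 50000)
#' @param seed RNG seed (recorded in the result)
#' @param draw_size genes per draw; defaults to `length(observed_genes)`
#' @param predicted_pattern regex marking predicted genes, default
#'   `"(^Gm[0-9]+$)|(Rik$)"`
#' @return list of class `permutation_result`: `observed_nssnps`,
#'   `observed_genes_with_nssnp`, `n_permutations`, `draw_size`,
#'   `universe_size`, `null_mean`, `null_sd`, `null_max`,
#'   `null_mean_genes_with_nssnp`, `empirical_p`, `seed`.
#' @export
nssnp_permutation_test <- function(annotation, observed_genes,
                                   n_permutations = 50000, seed = NULL,
                                   draw_size = NULL,
                                   predicted_pattern = "(^Gm[0-9]+$)|(Rik$)") {
  stopifnot(n_permutations >= 1)
  ann <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (is.null(ann$predicted_flag))
    ann$predicted_flag <- grepl(predicted_pattern, ann$gene_id)
  miss <- setdiff(observed_genes, ann$gene_id)
  if (length(miss)) stop("observed gene not in annotation: ", miss[1])
  obs_rows <- ann[match(unique(observed_genes), ann$gene_id), ]
  observed_nssnps <- sum(obs_rows$nssnp_count)
  observed_genes_with <- sum(obs_rows$nssnp_count > 0)
  universe <- ann[ann$biotype == "protein_coding" & !ann$predicted_flag, ]
  draw_size <- draw_size %||% length(unique(observed_genes))
  if (draw_size > nrow(universe))
    stop("draw size exceeds universe of eligible genes")
  if (!is.null(seed)) set.seed(seed)
  cnt <- universe$nssnp_count
  totals <- numeric(n_permutations)
  genes_with <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    drawn <- cnt[sample.int(length(cnt), draw_size)]
    totals[i] <- sum(drawn)
    genes_with[i] <- sum(drawn > 0)
  }
  structure(list(observed_nssnps = observed_nssnps,
                 observed_genes_with_nssnp = observed_genes_with,
                 n_permutations = as.integer(n_permutations),
                 draw_size = as.integer(draw_size),
                 universe_size = nrow(universe),
                 null_mean = mean(totals), null_sd = sd(totals),
                 null_max = max(totals),
                 null_mean_genes_with_nssnp = mean(genes_with),
                 empirical_p = (1 + sum(totals >= observed_nssnps)) /
                   (n_permutations + 1),
                 seed = seed), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("nsSNP permutation test: observed %d vs null %.1f +/- %.1f (max %d) in %d draws of %d genes; P = %.3g\n",
              x$observed_nssnps, x$null_mean, x$null_sd, as.integer(x$null_max),
              x$n_permutations, x$draw_size, x$empirical_p))
  invisible(x)
}

#' Percent excess over a null expectation
#'
#' @param observed observed statistic
#' @param null_mean null expectation (> 0)
#' @return `100 * (observed - null_mean) / null_mean`.
#' @export
excess_percent <- function(observed, null_mean) {
  if (any(null_mean <= 0)) stop("null_mean must be positive")
  100 * (observed - null_mean) / null_mean
}

#' Hypergeometric set overrepresentation with BH correction
#'
#' Upper-tail hypergeometric test of each named gene set against a query,
#' all intersected with the universe, with Benjamini-Hochberg adjustment
#' across the tested sets.
#'
#' @param query character vector of query gene ids (subset of `universe`)
#' @param sets named list of character vectors
#' @param universe character vector of background gene ids
#' @return data frame sorted by adjusted p: `set_id`,
#'   `k_in_set_and_query`, `set_size`, `query_size`, `universe_size`,
#'   `p_raw`, `p_bh`.
#' @export
hypergeom_overrep <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(intersect(query, universe))
  rows <- lapply(names(sets), function(nm) {
    s <- unique(intersect(sets[[nm]], universe))
    k <- length(intersect(query, s))
    p <- phyper(k - 1, m = length(s), n = length(universe) - length(s),
                k = length(query), lower.tail = FALSE)
    data.frame(set_id = nm, k_in_set_and_query = k, set_size = length(s),
               query_size = length(query), universe_size = length(universe),
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- p.adjust(out$p_raw, method = "BH")
  out <- out[order(out$p_bh, out$p_raw), ]
  rownames(out) <- NULL
  out
}

#' Assign genes to TRD regions
#'
#' A gene belongs to a region when its interval overlaps the region interval
#' by at least one base pair on the same chromosome; genes overlapping
#' several regions get one row per region.
#'
#' @param annotation data frame with `gene_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `nssnp_count`
#' @param regions region data frame from [call_regions()]
#' @return data frame: `gene_id`, `region_id`, `chromosome`, `nssnp_count`.
#' @export
assign_genes_to_regions <- function(annotation, regions) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- annotation$chromosome == regions$chromosome[i] &
      annotation$start_bp <= regions$distal_bp[i] &
      annotation$end_bp >= regions$proximal_bp[i]
    if (!any(hit)) return(NULL)
    data.frame(gene_id = annotation$gene_id[hit],
               region_id = regions$region_id[i],
               chromosome = regions$chromosome[i],
               nssnp_count = annotation$nssnp_count[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), region_id = character(),
                      chromosome = character(), nssnp_count = integer())
  rownames(out) <- NULL
  out
}

#' Overlay protein-protein interactions on incompatible region pairs
#'
#' Filters an undirected PPI edge list down to edges whose two genes both
#' carry at least one nsSNP, lie in different TRD regions on different
#' chromosomes, and whose region pair was significant in the pairwise
#' incompatibility scan.  Same-chromosome edges are dropped, mirroring the
#' exclusion of same-chromosome region pairs from the incompatibility test.
#'
#' @param edges data frame `gene_a`, `gene_b`, `score` (order-insensitive;
#'   duplicates collapsed keeping the maximum score)
#' @param gene_regions data frame from [assign_genes_to_regions()]
#' @param significant_pairs data frame with columns `region_1`, `region_2`
#'   (e.g. significant rows of [pairwise_scan()] output)
#' @return data frame of retained edges: `gene_a`, `gene_b`, `score`,
#'   `region_a`, `region_b`.
#' @export
ppi_overlay <- function(edges, gene_regions, significant_pairs) {
  if (!nrow(edges)) return(data.frame(gene_a = character(),
                                      gene_b = character(), score = numeric(),
                                      region_a = character(),
                                      region_b = character()))
  if (any(edges$gene_a == edges$gene_b)) stop("self edge in PPI list")
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b, -edges$score), ]
  edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), ]
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  sig_keys <- pair_key(significant_pairs$region_1, significant_pairs$region_2)
  with_snp <- gene_regions[gene_regions$nssnp_count > 0, ]
  rows <- lapply(seq_len(nrow(edges)), function(k) {
    ra <- with_snp[with_snp$gene_id == edges$gene_a[k], ]
    rb <- with_snp[with_snp$gene_id == edges$gene_b[k], ]
    if (!nrow(ra) || !nrow(rb)) return(NULL)
    combos <- expand.grid(i = seq_len(nrow(ra)), j = seq_len(nrow(rb)))
    ok <- which(ra$region_id[combos$i] != rb$region_id[combos$j] &
                ra$chromosome[combos$i] != rb$chromosome[combos$j] &
                pair_key(ra$region_id[combos$i], rb$region_id[combos$j]) %in%
                  sig_keys)
    if (!length(ok)) return(NULL)
    data.frame(gene_a = edges$gene_a[k], gene_b = edges$gene_b[k],
               score = edges$score[k],
               region_a = ra$region_id[combos$i[ok[1]]],
               region_b = rb$region_id[combos$j[ok[1]]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), region_a = character(),
                      region_b = character())
  rownames(out) <- NULL
  out
}
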