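#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()].  Unknown keys are rejected so
#' typos cannot silently fall back to defaults; the fully resolved
#' configuration is written next to the outputs of every run.
#'
#' @param scan a [scan_config()]
#' @param sim a [sim_config()] (used only when the pipeline simulates its
#'   own input)
#' @param generation offspring generation to scan (default: the last
#'   generation in the pedigree)
#' @param min_call_rate marker call-rate threshold (default 0.9)
#' @param misassign_threshold Mendelian-error fraction flagging a wrong
#'   parent assignment (default 0.05)
#' @param fix_length,variance_fraction simpleM parameters (defaults 1200 and
#'   0.995)
#' @param alpha_levels significance levels for the pairwise scan
#'   (default `c(0.05, 0.01)`)
#' @param parent_sexes which transmission scans to run (default both)
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scan = scan_config(), sim = sim_config(),
                            generation = NULL, min_call_rate = 0.9,
                            misassign_threshold = 0.05, fix_length = 1200,
                            variance_fraction = 0.995,
                            alpha_levels = c(0.05, 0.01),
                            parent_sexes = c("paternal", "maternal")) {
  stopifnot(inherits(scan, "scan_config"), inherits(sim, "sim_config"),
            all(parent_sexes %in% c("paternal", "maternal")))
  structure(list(scan = scan, sim = sim, generation = generation,
                 min_call_rate = min_call_rate,
                 misassign_threshold = misassign_threshold,
                 fix_length = fix_length,
                 variance_fraction = variance_fraction,
                 alpha_levels = alpha_levels,
                 parent_sexes = parent_sexes),
            class = "pipeline_config")
}

#' Run the full distortion-and-incompatibility pipeline
#'
#' Orchestrates: (1) input acquisition (simulation when no genotypes are
#' given), (2) marker and trio quality control, (3) transmission scans per
#' parental sex, (4) region calling, (5) simpleM effective-test estimation
#' and the pairwise incompatibility scan, (6) optional nsSNP enrichment when
#' an annotation is supplied.  All stage outputs are written to `out_dir` as
#' TSV/JSON together with a manifest recording stage order, thresholds, and
#' summary counts (markers loaded and marker-tests performed are reported
#' separately, since filtering makes them differ).
#'
#' @param out_dir output directory (created if needed)
#' @param genotypes optional [geno_matrix]; when `NULL` the simulator runs
#'   with `config$sim`
#' @param pedigree pedigree matching `genotypes` (ignored when simulating)
#' @param config a [pipeline_config()]
#' @param annotation optional gene annotation data frame (see
#'   [nssnp_permutation_test()] and [assign_genes_to_regions()])
#' @param ppi_edges optional PPI edge data frame (`gene_a`, `gene_b`,
#'   `score`)
#' @param n_permutations permutations for the enrichment stage (default
#'   2000 at desk scale)
#' @return invisibly, a list with all stage results (`qc`, `scans`,
#'   `regions`, `effective`, `pairs`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(out_dir, genotypes = NULL, pedigree = NULL,
                         config = pipeline_config(), annotation = NULL,
                         ppi_edges = NULL, n_permutations = 2000) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  manifest <- list()

  if (is.null(genotypes)) {
    sim <- simulate_ail(config$sim)
    genotypes <- sim$genotypes
    pedigree <- sim$pedigree
    write_genotypes(genotypes, file.path(out_dir, "genotypes.tsv"))
    write_pedigree(pedigree, file.path(out_dir, "pedigree.tsv"))
    stages <- c(stages, "simulate")
  } else if (is.null(pedigree)) {
    stop("pedigree required when genotypes are supplied")
  }
  n_loaded <- ncol(genotypes)

  qc <- marker_qc(genotypes, min_call_rate = config$min_call_rate)
  genotypes <- qc$genotypes
  generation <- config$generation %||% max(pedigree$generation)
  trios <- build_trios(pedigree, generation, genotypes)
  trio_qc <- flag_misassigned(trios, genotypes,
                              threshold = config$misassign_threshold,
                              pedigree = pedigree)
  bad <- trio_qc$removed_individuals$id
  trios <- trios[!trios$child_id %in% bad, , drop = FALSE]
  report <- qc_report(removed_individuals = trio_qc$removed_individuals,
                      removed_markers = qc$report$removed_markers,
                      thresholds = c(qc$report$thresholds,
                                     trio_qc$thresholds),
                      trio_errors = trio_qc$trio_errors)
  write_qc_report(report, file.path(out_dir, "qc_report.json"))
  stages <- c(stages, "qc")

  scans <- list(); regions_all <- list(); n_tests <- 0L
  for (sx in config$parent_sexes) {
    sc <- trd_scan(genotypes, trios, parent_sex = sx, config = config$scan)
    n_tests <- n_tests + nrow(sc)
    write.table(sc[, setdiff(names(sc), "underflow")],
                file.path(out_dir, paste0("scan_", sx, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rg <- call_regions(sc, config = config$scan)
    write_regions(rg, file.path(out_dir, paste0("regions_", sx, ".tsv")))
    write_regions(rg, file.path(out_dir, paste0("regions_", sx, ".bed")),
                  format = "bed")
    scans[[sx]] <- sc
    regions_all[[sx]] <- rg
  }
  stages <- c(stages, "scan", "regions")
  regions <- do.call(rbind, lapply(regions_all, function(r)
    r[, setdiff(names(r), "member_markers")]))
  rownames(regions) <- NULL

  effective <- simple_m(genotypes, fix_length = config$fix_length,
                        variance_fraction = config$variance_fraction,
                        ids = trios$child_id)
  pairs <- NULL
  if (!is.null(regions) && nrow(regions) >= 2) {
    pairs <- pairwise_scan(regions, genotypes, effective,
                           alpha_levels = config$alpha_levels,
                           individuals = trios$child_id)
    write.table(pairs, file.path(out_dir, "incompatibilities.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stages <- c(stages, "incompat")

  enr <- NULL
  if (!is.null(annotation) && !is.null(regions) && nrow(regions) > 0) {
    gr <- assign_genes_to_regions(annotation, regions)
    perm <- nssnp_permutation_test(annotation, unique(gr$gene_id),
                                   n_permutations = n_permutations,
                                   seed = config$sim$seed)
    enr <- list(gene_regions = gr, permutation = perm,
                excess_percent = excess_percent(perm$observed_nssnps,
                                                perm$null_mean))
    if (!is.null(ppi_edges) && !is.null(pairs)) {
      sig <- pairs[pairs$status %in% c("significant", "highly_significant"), ]
      enr$ppi <- ppi_overlay(ppi_edges, gr, sig)
    }
    jsonlite::write_json(
      list(permutation = unclass(perm), excess_percent = enr$excess_percent),
      file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  stages <- c(stages, "enrich", "report")

  sig_counts <- vapply(scans, function(s)
    sum(s$lod >= config$scan$lod_threshold_1pct), integer(1))
  manifest <- list(
    stages = stages,
    generation_scanned = generation,
    markers_loaded = n_loaded,
    markers_after_qc = ncol(genotypes),
    marker_tests_performed = n_tests,
    n_trios = nrow(trios),
    significant_snps = as.list(sig_counts),
    n_regions = as.list(vapply(regions_all, nrow, integer(1))),
    n_effective_tests = effective$n_effective,
    pairwise_thresholds = if (!is.null(pairs))
      as.list(attr(pairs, "thresholds")) else NULL,
    n_significant_pairs = if (!is.null(pairs))
      sum(pairs$status %in% c("significant", "highly_significant")) else 0L,
    n_regions_in_significant_pairs = if (!is.null(pairs)) {
      sig <- pairs$status %in% c("significant", "highly_significant")
      length(unique(c(pairs$region_1[sig], pairs$region_2[sig])))
    } else 0L,
    thresholds = c(unclass(config$scan),
                   list(min_call_rate = config$min_call_rate,
                        misassign_threshold = config$misassign_threshold)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(config_to_list(config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(qc = report, trios = trios, scans = scans,
                 regions = regions, regions_by_sex = regions_all,
                 effective = effective, pairs = pairs, enrichment = enr,
                 manifest = manifest))
}

config_to_list <- function(config) {
  l <- unclass(config)
  l$scan <- unclass(l$scan)
  l$sim <- unclass(l$sim)
  l
}
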