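#' Build trios for an offspring generation
#'
#' One trio per individual of the requested generation whose sire and dam are
#' both recorded and, when a genotype matrix is given, all three individuals
#' genotyped.  Excluded individuals are logged in the `"excluded"` attribute
#' with a reason code.
#'
#' @param pedigree a validated pedigree
#' @param generation offspring generation to analyze
#' @param genotypes optional [geno_matrix]; trios with ungenotyped members
#'   are excluded
#' @return data frame with columns `child_id`, `sire_id`, `dam_id`, and
#'   attribute `excluded` (data frame `id`, `reason`).
#' @export
build_trios <- function(pedigree, generation, genotypes = NULL) {
  if (!generation %in% pedigree$generation)
    stop("generation ", generation, " not present in pedigree")
  kids <- pedigree[pedigree$generation == generation, ]
  excluded <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  keep <- !is.na(kids$sire_id) & !is.na(kids$dam_id)
  if (any(!keep))
    excluded <- rbind(excluded, data.frame(id = kids$individual_id[!keep],
                                           reason = "missing_parent"))
  trios <- data.frame(child_id = kids$individual_id[keep],
                      sire_id = kids$sire_id[keep],
                      dam_id = kids$dam_id[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(genotypes)) {
    ids <- individuals(genotypes)
    g_ok <- trios$child_id %in% ids & trios$sire_id %in% ids &
      trios$dam_id %in% ids
    if (any(!g_ok))
      excluded <- rbind(excluded, data.frame(id = trios$child_id[!g_ok],
                                             reason = "not_genotyped"))
    trios <- trios[g_ok, , drop = FALSE]
  }
  rownames(trios) <- NULL
  attr(trios, "excluded") <- excluded
  trios
}

#' Mendelian error rate of one trio
#'
#' Fraction of informative markers, non-missing in all three individuals,
#' where the child's genotype is impossible under biallelic Mendelian
#' inheritance from the stated parents (e.g. a `HOM_B` parent with a `HOM_A`
#' child).  High rates indicate a misassigned parent.
#'
#' @param genotypes a [geno_matrix]
#' @param child_id,sire_id,dam_id individual ids
#' @return list with `n_checked`, `n_mendel_errors`, `rate`.
#' @export
mendelian_error_rate <- function(genotypes, child_id, sire_id, dam_id) {
  inf <- marker_map(genotypes)$informative
  ch <- unclass(genotypes)[child_id, inf]
  si <- unclass(genotypes)[sire_id, inf]
  da <- unclass(genotypes)[dam_id, inf]
  ok <- !is.na(ch) & !is.na(si) & !is.na(da)
  if (!any(ok)) stop("no overlapping non-missing informative markers")
  ch <- ch[ok]; si <- si[ok]; da <- da[ok]
  err <- (ch == 0L & (si == 2L | da == 2L)) |
         (ch == 2L & (si == 0L | da == 0L)) |
         (ch == 1L & ((si == 0L & da == 0L) | (si == 2L & da == 2L)))
  list(n_checked = sum(ok), n_mendel_errors = sum(err),
       rate = sum(err) / sum(ok))
}

#' Flag trios with misassigned parents
#'
#' Computes the Mendelian error rate of every trio and flags those exceeding
#' `threshold`; the flagged child and all of its descendants among the other
#' trio children are removed, mirroring the cascade removal of an individual
#' with a wrong parent assignment together with its offspring.
#'
#' @param trios data frame from [build_trios()] (possibly several
#'   generations row-bound)
#' @param genotypes a [geno_matrix]
#' @param threshold Mendelian-error fraction above which a trio is flagged
#'   (default 0.05)
#' @param pedigree optional pedigree for the descendant cascade
#' @return a `qc_report`: list with `removed_individuals` (data frame `id`,
#'   `reason`), `removed_markers`, `thresholds`, and the per-trio error table
#'   as `trio_errors`.
#' @export
flag_misassigned <- function(trios, genotypes, threshold = 0.05,
                             pedigree = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  err <- data.frame(child_id = character(), n_checked = integer(),
                    n_mendel_errors = integer(), rate = numeric(),
                    stringsAsFactors = FALSE)
  if (nrow(trios)) {
    res <- lapply(seq_len(nrow(trios)), function(i)
      mendelian_error_rate(genotypes, trios$child_id[i], trios$sire_id[i],
                           trios$dam_id[i]))
    err <- data.frame(child_id = trios$child_id,
                      n_checked = vapply(res, `[[`, integer(1), "n_checked"),
                      n_mendel_errors = vapply(res, `[[`, integer(1),
                                               "n_mendel_errors"),
                      rate = vapply(res, `[[`, numeric(1), "rate"),
                      stringsAsFactors = FALSE)
  }
  flagged <- err$child_id[err$rate > threshold]
  removed <- data.frame(id = flagged,
                        reason = rep("mendel_inconsistent", length(flagged)),
                        stringsAsFactors = FALSE)
  if (length(flagged) && !is.null(pedigree)) {
    desc <- intersect(pedigree_descendants(pedigree, flagged), trios$child_id)
    desc <- setdiff(desc, flagged)
    if (length(desc))
      removed <- rbind(removed,
                       data.frame(id = desc, reason = "parent_removed"))
  }
  qc_report(removed_individuals = removed,
            thresholds = list(misassign_threshold = threshold),
            trio_errors = err)
}

#' Marker-level quality control
#'
#' Removes markers with genotype call rate below `min_call_rate` and markers
#' flagged uninformative (founders carrying the same allele).  Idempotent.
#'
#' @param genotypes a [geno_matrix]
#' @param min_call_rate minimum fraction of non-missing calls (default 0.9)
#' @return list with elements `genotypes` (filtered) and `report`
#'   (`qc_report` with `removed_markers` reasons `"low_call_rate"` /
#'   `"uninformative"`).
#' @export
marker_qc <- function(genotypes, min_call_rate = 0.9) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1)
  map <- marker_map(genotypes)
  call_rate <- colMeans(!is.na(unclass(genotypes)))
  low <- call_rate < min_call_rate
  uninf <- !map$informative
  removed <- rbind(
    data.frame(marker_id = map$marker_id[uninf],
               reason = rep("uninformative", sum(uninf)),
               stringsAsFactors = FALSE),
    data.frame(marker_id = map$marker_id[low & !uninf],
               reason = rep("low_call_rate", sum(low & !uninf)),
               stringsAsFactors = FALSE))
  keep <- !(low | uninf)
  list(genotypes = genotypes[, keep],
       report = qc_report(removed_markers = removed,
                          thresholds = list(min_call_rate = min_call_rate)))
}

#' Assemble a QC report
#'
#' @param removed_individuals data frame `id`, `reason`
#' @param removed_markers data frame `marker_id`, `reason`
#' @param thresholds named list of thresholds applied
#' @param trio_errors optional per-trio Mendelian-error table
#' @return list of class `qc_report`.
#' @export
qc_report <- function(removed_individuals = NULL, removed_markers = NULL,
                      thresholds = list(), trio_errors = NULL) {
  structure(list(
    removed_individuals = removed_individuals %||%
      data.frame(id = character(), reason = character()),
    removed_markers = removed_markers %||%
      data.frame(marker_id = character(), reason = character()),
    thresholds = thresholds,
    trio_errors = trio_errors), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d individual(s) removed, %d marker(s) removed\n",
              nrow(x$removed_individuals), nrow(x$removed_markers)))
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `qc_report`
#' @param path output file
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
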