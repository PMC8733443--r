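#' Genotype matrix with marker map
#'
#' The canonical in-memory genotype container: an integer matrix of
#' founder-polarized biallelic calls (rows = individuals, columns = markers)
#' with an attached marker map.  Codes are `0` = `HOM_A` (homozygous for the
#' founder-A allele), `1` = `HET`, `2` = `HOM_B`, `NA` = missing.  Markers are
#' stored sorted by (chromosome, position).
#'
#' @param calls integer matrix, individuals x markers, values in
#'   `c(0, 1, 2, NA)`.  Row names are individual ids.
#' @param map data frame with columns `marker_id`, `chromosome`,
#'   `position_bp` (1-based) and optionally `informative` (logical, default
#'   `TRUE`); one row per column of `calls`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (is.null(map$informative)) map$informative <- TRUE
  req <- c("marker_id", "chromosome", "position_bp", "informative")
  if (!all(req %in% names(map)))
    stop("map must have columns: ", paste(req, collapse = ", "))
  if (ncol(calls) != nrow(map))
    stop("ncol(calls) must equal nrow(map)")
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids in map")
  if (any(map$position_bp < 1))
    stop("position_bp must be >= 1 (1-based coordinates)")
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(rownames(calls)))
    stop("calls must have row names (individual ids)")
  map$chromosome <- as.character(map$chromosome)
  ord <- order(chrom_rank(map$chromosome), map$position_bp)
  calls <- calls[, ord, drop = FALSE]
  map <- map[ord, req, drop = FALSE]
  rownames(map) <- NULL
  colnames(calls) <- map$marker_id
  structure(calls, map = map, class = c("geno_matrix", "matrix", "array"))
}

# numeric chromosomes sort numerically, others after them lexicographically
chrom_rank <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  base <- if (all(is.na(num))) 0 else max(num, na.rm = TRUE)
  nonnum <- sort(unique(chr[is.na(num)]))
  ifelse(is.na(num), base + match(chr, nonnum), num)
}

#' Marker map of a genotype matrix
#' @param g a [geno_matrix]
#' @return data frame with columns `marker_id`, `chromosome`, `position_bp`,
#'   `informative`.
#' @export
marker_map <- function(g) attr(g, "map")

#' Individual ids of a genotype matrix
#' @param g a [geno_matrix]
#' @return character vector.
#' @export
individuals <- function(g) rownames(g)

#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  map <- attr(x, "map")
  out <- unclass(x)[i, j, ..., drop = FALSE]
  if (!missing(j)) {
    jj <- if (is.character(j)) match(j, map$marker_id) else seq_len(nrow(map))[j]
    map <- map[jj, , drop = FALSE]
    rownames(map) <- NULL
  }
  structure(out, map = map, class = c("geno_matrix", "matrix", "array"))
}

#' @export
print.geno_matrix <- function(x, ...) {
  map <- marker_map(x)
  cat(sprintf("geno_matrix: %d individuals x %d markers (%d informative) on %d chromosome(s)\n",
              nrow(x), ncol(x), sum(map$informative), length(unique(map$chromosome))))
  cat(sprintf("missing calls: %.2f%%\n", 100 * mean(is.na(unclass(x)))))
  invisible(x)
}

#' Swap founder polarization of a genotype matrix
#'
#' Maps `HOM_A` to `HOM_B` and vice versa at every marker; `HET` and missing
#' calls are unchanged.  Applying it twice is the identity.
#' @param g a [geno_matrix]
#' @return a [geno_matrix] with flipped polarization.
#' @export
flip_polarization <- function(g) {
  map <- marker_map(g)
  out <- 2L - unclass(g)
  geno_matrix(out, map)
}

#' Validate a pedigree data frame
#'
#' A pedigree records one row per individual with optional sire/dam links, a
#' generation number, and sex.  Unknown parents are `NA`.  Checks: unique ids,
#' parent ids present in the pedigree, no individual its own ancestor, child
#' generation strictly greater than each parent's.
#'
#' @param ped data frame with columns `individual_id`, `sire_id`, `dam_id`,
#'   `generation`, `sex` (values `"M"`, `"F"` or `"unknown"`).
#' @return the validated data frame, with class `pedigree` prepended.
#' @export
as_pedigree <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  req <- c("individual_id", "sire_id", "dam_id", "generation", "sex")
  if (!all(req %in% names(ped)))
    stop("pedigree must have columns: ", paste(req, collapse = ", "))
  ped <- ped[, req]
  for (col in c("individual_id", "sire_id", "dam_id"))
    ped[[col]] <- as.character(ped[[col]])
  ped$generation <- as.integer(ped$generation)
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual id in pedigree: ",
         ped$individual_id[duplicated(ped$individual_id)][1])
  if (!all(ped$sex %in% c("M", "F", "unknown")))
    stop("sex must be 'M', 'F' or 'unknown'")
  for (col in c("sire_id", "dam_id")) {
    set <- !is.na(ped[[col]])
    miss <- setdiff(ped[[col]][set], ped$individual_id)
    if (length(miss))
      stop("parent id not present in pedigree: ", miss[1])
  }
  gen <- setNames(ped$generation, ped$individual_id)
  for (col in c("sire_id", "dam_id")) {
    set <- !is.na(ped[[col]])
    if (any(ped$generation[set] <= gen[ped[[col]][set]]))
      stop("child generation must exceed parent generation")
  }
  if (has_pedigree_cycle(ped)) stop("cycle detected in pedigree")
  class(ped) <- c("pedigree", "data.frame")
  ped
}

has_pedigree_cycle <- function(ped) {
  # generation ordering already forbids cycles among validated rows, but a
  # self-parent with equal generations must still be caught before validation
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$individual_id
  for (i in idx) {
    seen <- character()
    stack <- c(ped$sire_id[i], ped$dam_id[i])
    stack <- stack[!is.na(stack)]
    while (length(stack)) {
      a <- stack[1]; stack <- stack[-1]
      if (a == ped$individual_id[i]) return(TRUE)
      if (a %in% seen) next
      seen <- c(seen, a)
      j <- idx[a]
      if (!is.na(j))
        stack <- c(stack, ped$sire_id[j], ped$dam_id[j])
      stack <- stack[!is.na(stack)]
    }
  }
  FALSE
}

#' Descendants of a set of individuals
#'
#' @param ped a [as_pedigree()]-validated pedigree
#' @param ids individual ids
#' @return character vector of all descendants (children, grandchildren, ...)
#'   of `ids`, excluding `ids` themselves.
#' @export
pedigree_descendants <- function(ped, ids) {
  out <- character()
  frontier <- ids
  while (length(frontier)) {
    kids <- ped$individual_id[(ped$sire_id %in% frontier) |
                              (ped$dam_id %in% frontier)]
    kids <- setdiff(kids, c(out, ids))
    out <- c(out, kids)
    frontier <- kids
  }
  out
}
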