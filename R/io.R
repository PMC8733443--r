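#' Read a genotype matrix
#'
#' Reads biallelic genotypes from VCF (GT field), PLINK PED/MAP, or the
#' package's marker-per-row TSV dialect, and polarizes calls toward the two
#' founder lines when founder ids are supplied: `HOM_A` is homozygosity for
#' the allele carried by `founder_a_id` (which need not be the VCF REF
#' allele).  Markers where the founders carry the same allele are flagged
#' `informative = FALSE`; such markers cannot carry transmission information
#' in a two-founder cross and are excluded downstream.  Markers where both
#' founders are missing keep their arbitrary allele-1/allele-2 polarization
#' and trigger a warning.
#'
#' Non-biallelic VCF records are skipped (not split) with a warning giving
#' the count; the transmission tests are defined only for biallelic markers.
#'
#' @param path input file.  For `format = "ped_map"` either the `.ped` file
#'   (the `.map` is found by extension swap) or the common prefix.
#' @param format one of `"vcf"`, `"ped_map"`, `"tsv"`.
#' @param founder_a_id,founder_b_id optional sample ids of the two inbred
#'   founders; both must be present and genotyped when given.
#' @return a [geno_matrix].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "ped_map"),
                           founder_a_id = NULL, founder_b_id = NULL) {
  format <- match.arg(format)
  raw <- switch(format,
    vcf = read_genotypes_vcf(path),
    ped_map = read_genotypes_pedmap(path),
    tsv = read_genotypes_tsv(path))
  polarize_founders(raw, founder_a_id, founder_b_id)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_skip <- sum(!bi)
  if (n_skip > 0) {
    warning(sprintf("skipped %d non-biallelic VCF record(s)", n_skip))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  parse1 <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2) stop("ploidy != 2 in VCF GT field: ", s)
    if (any(al == ".")) return(NA_integer_)
    sum(as.integer(al))
  }
  calls <- t(apply(gt, 1, function(row) vapply(row, parse1, integer(1))))
  if (ncol(gt) == 1) calls <- t(calls)  # apply drops dims for one sample
  calls <- matrix(as.integer(calls), nrow = ncol(gt), ncol = nrow(gt),
                  byrow = TRUE,
                  dimnames = list(colnames(gt), ids))
  map <- data.frame(marker_id = ids,
                    chromosome = as.character(fix[, "CHROM"]),
                    position_bp = as.integer(fix[, "POS"]),
                    informative = TRUE,
                    stringsAsFactors = FALSE)
  list(calls = calls, map = map)
}

read_genotypes_pedmap <- function(path) {
  if (grepl("\\.ped$", path)) {
    ped_path <- path
    map_path <- sub("\\.ped$", ".map", path)
  } else {
    ped_path <- paste0(path, ".ped")
    map_path <- paste0(path, ".map")
  }
  mp <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  names(mp)[1:4] <- c("chromosome", "marker_id", "cm", "position_bp")
  pd <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(pd) != 6 + 2 * nrow(mp))
    stop("PED column count does not match MAP marker count")
  ids <- pd[[2]]
  n_mark <- nrow(mp)
  calls <- matrix(NA_integer_, nrow(pd), n_mark,
                  dimnames = list(ids, mp$marker_id))
  drop_mark <- logical(n_mark)
  for (j in seq_len(n_mark)) {
    a1 <- pd[[6 + 2 * j - 1]]
    a2 <- pd[[6 + 2 * j]]
    alleles <- setdiff(unique(c(a1, a2)), "0")
    if (length(alleles) > 2) { drop_mark[j] <- TRUE; next }
    if (length(alleles) == 0) next
    ref <- alleles[1]
    code <- (a1 != ref) + (a2 != ref)
    code[a1 == "0" | a2 == "0"] <- NA_integer_
    calls[, j] <- as.integer(code)
  }
  if (any(drop_mark)) {
    warning(sprintf("skipped %d non-biallelic PED marker(s)", sum(drop_mark)))
    calls <- calls[, !drop_mark, drop = FALSE]
    mp <- mp[!drop_mark, , drop = FALSE]
  }
  map <- data.frame(marker_id = mp$marker_id,
                    chromosome = as.character(mp$chromosome),
                    position_bp = as.integer(mp$position_bp),
                    informative = TRUE, stringsAsFactors = FALSE)
  list(calls = calls, map = map)
}

read_genotypes_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  req <- c("marker_id", "chromosome", "position_bp")
  if (!all(req %in% names(d)))
    stop("genotype TSV must start with columns: ", paste(req, collapse = ", "))
  has_inf <- "informative" %in% names(d)
  ind_cols <- setdiff(names(d), c(req, "informative"))
  if (!length(ind_cols)) stop("genotype TSV has no individual columns")
  code_of <- c(A = 0L, H = 1L, B = 2L)
  calls <- vapply(ind_cols, function(cl) {
    x <- d[[cl]]
    out <- unname(code_of[x])
    if (any(is.na(out) & !(x %in% c("-", ".", "", "NA"))))
      stop("invalid genotype cell in column ", cl)
    out
  }, integer(nrow(d)))
  calls <- t(matrix(calls, nrow = nrow(d),
                    dimnames = list(d$marker_id, ind_cols)))
  map <- data.frame(marker_id = d$marker_id,
                    chromosome = d$chromosome,
                    position_bp = as.integer(d$position_bp),
                    informative = if (has_inf) as.logical(d$informative) else TRUE,
                    stringsAsFactors = FALSE)
  list(calls = calls, map = map)
}

polarize_founders <- function(raw, founder_a_id, founder_b_id) {
  calls <- raw$calls
  map <- raw$map
  if (is.null(founder_a_id) != is.null(founder_b_id))
    stop("give both founder ids or neither")
  if (!is.null(founder_a_id)) {
    for (id in c(founder_a_id, founder_b_id))
      if (!id %in% rownames(calls)) stop("founder not genotyped: ", id)
    fa <- calls[founder_a_id, ]
    fb <- calls[founder_b_id, ]
    flip <- (!is.na(fa) & fa == 2L) | (is.na(fa) & !is.na(fb) & fb == 0L)
    calls[, flip] <- 2L - calls[, flip, drop = FALSE]
    same <- !is.na(fa) & !is.na(fb) & fa == fb
    het_founder <- (!is.na(fa) & fa == 1L) | (!is.na(fb) & fb == 1L)
    map$informative <- map$informative & !same & !het_founder
    unpol <- is.na(fa) & is.na(fb)
    if (any(unpol))
      warning(sprintf(
        "%d marker(s) unpolarizable (both founders missing); arbitrary polarization kept",
        sum(unpol)))
  }
  geno_matrix(calls, map)
}

#' Write a genotype matrix
#'
#' `"tsv"` writes the package dialect read by [read_genotypes()] (one row per
#' marker, one column per individual, cells `A`/`H`/`B`/`-`).  `"vcf"` writes
#' a minimal VCF 4.2 with GT fields where allele 0 is the founder-A allele
#' (REF/ALT written as placeholder bases `A`/`T`).
#'
#' @param g a [geno_matrix]
#' @param path output file
#' @param format `"tsv"` or `"vcf"`
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  map <- marker_map(g)
  m <- unclass(g)
  if (format == "tsv") {
    sym <- c("A", "H", "B")
    cells <- matrix(sym[m + 1L], nrow = nrow(m))
    cells[is.na(m)] <- "-"
    out <- data.frame(marker_id = map$marker_id,
                      chromosome = map$chromosome,
                      position_bp = map$position_bp,
                      informative = map$informative,
                      t(cells), check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(out)[-(1:4)] <- rownames(m)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gt_sym <- c("0/0", "0/1", "1/1")
    gt <- matrix(gt_sym[m + 1L], nrow = nrow(m))
    gt[is.na(m)] <- "./."
    header <- c("##fileformat=VCFv4.2",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", rownames(m)), collapse = "\t"))
    body <- paste(map$chromosome, map$position_bp, map$marker_id,
                  "A", "T", ".", "PASS", ".", "GT",
                  apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read a pedigree
#'
#' `"tsv"` expects columns `individual_id`, `sire_id`, `dam_id`,
#' `generation`, `sex`; `-`, `.` or `0` mark unknown parents.  `"fam"` reads
#' PLINK FAM (FID IID PAT MAT SEX PHENO; `0` = unknown parent, sex 1 = M,
#' 2 = F, 0 = unknown); generations, absent from FAM, are derived as pedigree
#' depth (founders = 0).
#'
#' @param path input file
#' @param format `"tsv"` or `"fam"`
#' @return a validated pedigree ([as_pedigree()]).
#' @export
read_pedigree <- function(path, format = c("tsv", "fam")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
    d$generation <- as.integer(d$generation)
  } else {
    f <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
    d <- data.frame(individual_id = f[[2]], sire_id = f[[3]], dam_id = f[[4]],
                    sex = c("unknown", "M", "F")[match(f[[5]], c("0", "1", "2"))],
                    stringsAsFactors = FALSE)
    d$sex[is.na(d$sex)] <- "unknown"
  }
  for (col in c("sire_id", "dam_id"))
    d[[col]][d[[col]] %in% c("0", "-", ".", "", "NA")] <- NA_character_
  if (format == "fam") d$generation <- pedigree_depth(d)
  as_pedigree(d)
}

pedigree_depth <- function(d) {
  depth <- setNames(rep(NA_integer_, nrow(d)), d$individual_id)
  repeat {
    progressed <- FALSE
    for (i in seq_len(nrow(d))) {
      if (!is.na(depth[i])) next
      ps <- c(d$sire_id[i], d$dam_id[i])
      ps <- ps[!is.na(ps) & ps %in% d$individual_id]
      if (!length(ps)) { depth[i] <- 0L; progressed <- TRUE; next }
      pv <- depth[ps]
      if (!anyNA(pv)) { depth[i] <- max(pv) + 1L; progressed <- TRUE }
    }
    if (all(!is.na(depth))) break
    if (!progressed) stop("cycle detected in pedigree")
  }
  unname(depth)
}

#' Write a pedigree
#' @param ped a pedigree
#' @param path output file
#' @param format `"tsv"` or `"fam"` (FID written as the generation number)
#' @export
write_pedigree <- function(ped, path, format = c("tsv", "fam")) {
  format <- match.arg(format)
  d <- as.data.frame(ped)
  if (format == "tsv") {
    d$sire_id[is.na(d$sire_id)] <- "-"
    d$dam_id[is.na(d$dam_id)] <- "-"
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(fid = d$generation, iid = d$individual_id,
                      pat = ifelse(is.na(d$sire_id), "0", d$sire_id),
                      mat = ifelse(is.na(d$dam_id), "0", d$dam_id),
                      sex = match(d$sex, c("M", "F"), nomatch = 3) %% 3,
                      pheno = -9)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Write TRD regions
#'
#' TSV mirrors the region summary table layout (id, chromosome, proximal /
#' top / distal positions, size, marker support, preferred founder allele,
#' per-marker transmission means and SDs, top-marker counts, signed
#' distortion percent).  BED converts the 1-based inclusive internal
#' interval to 0-based half-open coordinates.
#'
#' @param regions region data frame from [call_regions()] (empty allowed)
#' @param path output file
#' @param format `"tsv"` or `"bed"`
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  cols <- c("region_id", "chromosome", "proximal_bp", "top_bp", "distal_bp",
            "size_bp", "n_snps", "preferred_allele", "mean_n_A", "sd_n_A",
            "mean_n_B", "sd_n_B", "top_marker_id", "top_n_A", "top_n_B",
            "distortion_percent")
  if (format == "tsv") {
    out <- if (nrow(regions)) regions[, cols] else
      setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (nrow(regions)) {
      bed <- data.frame(chrom = regions$chromosome,
                        start = regions$proximal_bp - 1L,
                        end = regions$distal_bp,
                        name = regions$region_id,
                        score = pmin(1000L, round(abs(regions$distortion_percent) * 10)),
                        strand = ".")
      write.table(bed, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    } else {
      writeLines(character(0), path)
    }
  }
  invisible(path)
}
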