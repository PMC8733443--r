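#' Simulation configuration for a two-founder advanced intercross line
#'
#' Desk-scale defaults: 5 chromosomes of 100 cM carrying 200 evenly spaced
#' markers each, 10 generations (founders = generation 0, F1 = 1, then
#' random mating), 30 families per generation with litters of 4 — small
#' enough for minutes-scale runs while still exhibiting linkage structure.
#' Physical positions are synthesized at a fixed `bp_per_cM` scale (default
#' 2 Mb/cM, the mouse genome-wide average) so region output has realistic
#' coordinates.
#'
#' @param n_chromosomes number of autosomes
#' @param markers_per_chromosome markers per chromosome
#' @param chromosome_length_cM genetic length per chromosome
#' @param generations final generation index (>= 2; founders are 0, F1 is 1)
#' @param families_per_generation mating pairs formed per generation
#' @param litter_size offspring conceived per family
#' @param genotype_missing_rate fraction of calls set missing in non-founder
#'   individuals
#' @param seed RNG seed
#' @param bp_per_cM physical scale of the synthetic map
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 5, markers_per_chromosome = 200,
                       chromosome_length_cM = 100, generations = 10,
                       families_per_generation = 30, litter_size = 4,
                       genotype_missing_rate = 0, seed = 1,
                       bp_per_cM = 2e6) {
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 1,
            chromosome_length_cM > 0, generations >= 2,
            families_per_generation >= 1, litter_size >= 1,
            genotype_missing_rate >= 0, genotype_missing_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Define a meiotic-drive locus
#'
#' A heterozygous carrier of the configured sex transmits the founder-A
#' allele with probability `tau` instead of 0.5.  `tau = 0.5` is Mendelian;
#' the expected marginal distortion is `100 * (2 * tau - 1)` percent
#' ([expected_distortion()]).
#'
#' @param marker_index global marker index into the simulated map
#' @param tau transmission probability of the founder-A allele in `[0, 1]`
#' @param sex `"both"`, `"paternal"` or `"maternal"`
#' @export
driver_locus <- function(marker_index, tau,
                         sex = c("both", "paternal", "maternal")) {
  stopifnot(tau >= 0, tau <= 1, marker_index >= 1)
  list(marker_index = as.integer(marker_index), tau = tau,
       sex = match.arg(sex))
}

#' Define a two-locus viability incompatibility
#'
#' Each conceived offspring survives with probability equal to the product of
#' the viability entries indexed by its genotype classes at the two markers
#' (rows = classes `HOM_A`, `HET`, `HOM_B` at marker 1; columns at marker 2).
#' An all-ones matrix is neutral; a zero cell removes that joint class.
#'
#' @param marker_index_1,marker_index_2 global marker indices on different
#'   chromosomes
#' @param viability 3x3 matrix with entries in `[0, 1]`
#' @export
incompat_pair <- function(marker_index_1, marker_index_2, viability) {
  viability <- matrix(as.numeric(viability), 3, 3,
                      dimnames = list(GENO_LEVELS, GENO_LEVELS))
  stopifnot(all(viability >= 0), all(viability <= 1))
  list(marker_index_1 = as.integer(marker_index_1),
       marker_index_2 = as.integer(marker_index_2),
       viability = viability)
}

#' Expected marginal distortion of a drive locus
#' @param tau transmission probability of the founder-A allele in `[0, 1]`
#' @return expected distortion percent, `100 * (2 * tau - 1)`.
#' @export
expected_distortion <- function(tau) {
  stopifnot(all(tau >= 0), all(tau <= 1))
  100 * (2 * tau - 1)
}

#' Forward-in-time simulation of a two-founder advanced intercross line
#'
#' Two fully inbred founders, fixed for opposite alleles at every marker,
#' produce a uniformly heterozygous F1; each later generation is formed by
#' randomly pairing males and females of the previous generation (full-sib
#' pairs avoided when possible), each pair conceiving `litter_size`
#' offspring.  Meiosis places crossovers under a no-interference Haldane
#' model on the cM map; gametes from heterozygous carriers of a drive locus
#' transmit the founder-A allele with probability `tau` (implemented as an
#' exact conditioning of the sampled gamete, preserving the recombination
#' pattern).  Conceived offspring survive with probability equal to the
#' product of the configured two-locus viabilities given their genotypes,
#' with up to 100 re-conceptions per litter slot; slots failing the cap
#' reduce the realized litter.  Missing genotypes are injected at
#' `genotype_missing_rate` in non-founder individuals.
#'
#' At most one drive locus per chromosome is supported (the conditioning
#' flips the whole-chromosome haplotype choice).
#'
#' @param config a [sim_config()]
#' @param drivers list of [driver_locus()] definitions
#' @param incompatibilities list of [incompat_pair()] definitions
#' @return list of class `ail_sim`: `genotypes` (a [geno_matrix] including
#'   founders `FA` and `FB`), `pedigree`, `truth` (drivers with expected
#'   distortion, injected incompatibilities with their minimum-viability
#'   cells), `config`.
#' @export
simulate_ail <- function(config = sim_config(), drivers = list(),
                         incompatibilities = list()) {
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  m_chr <- config$markers_per_chromosome
  M <- n_chr * m_chr
  chr <- rep(as.character(seq_len(n_chr)), each = m_chr)
  within <- rep(seq_len(m_chr), n_chr)
  cm <- (within - 0.5) * config$chromosome_length_cM / m_chr
  bp <- as.integer(round(cm * config$bp_per_cM))
  marker_id <- sprintf("M%s_%04d", chr, within)
  map <- data.frame(marker_id = marker_id, chromosome = chr,
                    position_bp = bp, informative = TRUE,
                    stringsAsFactors = FALSE)
  chr_idx <- split(seq_len(M), chr)[as.character(seq_len(n_chr))]
  # Haldane: recombination fraction between adjacent markers
  rec <- lapply(chr_idx, function(ii) {
    d <- diff(cm[ii]) / 100
    0.5 * (1 - exp(-2 * d))
  })
  for (d in drivers) {
    stopifnot(d$marker_index >= 1, d$marker_index <= M)
  }
  drv_chr <- vapply(drivers, function(d) chr[d$marker_index], character(1))
  if (anyDuplicated(drv_chr))
    stop("at most one drive locus per chromosome is supported")
  drv_by_chr <- setNames(drivers, drv_chr)
  for (ip in incompatibilities) {
    stopifnot(ip$marker_index_1 >= 1, ip$marker_index_1 <= M,
              ip$marker_index_2 >= 1, ip$marker_index_2 <= M)
    if (chr[ip$marker_index_1] == chr[ip$marker_index_2])
      stop("incompatibility pair must be on different chromosomes")
  }

  gamete <- function(h1, h2, parent_sex) {
    g <- integer(M)
    for (cc in names(chr_idx)) {
      ii <- chr_idx[[cc]]
      sw <- c(sample(0:1, 1), rbinom(length(rec[[cc]]), 1, rec[[cc]]))
      h <- cumsum(sw) %% 2L
      d <- drv_by_chr[[cc]]
      if (!is.null(d) && (d$sex == "both" || d$sex == parent_sex)) {
        li <- d$marker_index - ii[1] + 1L
        a1 <- h1[ii][li]; a2 <- h2[ii][li]
        if (a1 != a2) {
          target <- if (runif(1) < d$tau) 0L else 1L
          cur <- if (h[li] == 0L) a1 else a2
          if (cur != target) h <- 1L - h
        }
      }
      g[ii] <- ifelse(h == 0L, h1[ii], h2[ii])
    }
    g
  }

  viability_of <- function(geno) {
    v <- 1
    for (ip in incompatibilities)
      v <- v * ip$viability[geno[ip$marker_index_1] + 1L,
                            geno[ip$marker_index_2] + 1L]
    v
  }

  ped <- data.frame(individual_id = c("FA", "FB"),
                    sire_id = NA_character_, dam_id = NA_character_,
                    generation = 0L, sex = c("M", "F"),
                    stringsAsFactors = FALSE)
  H1 <- list(FA = integer(M), FB = rep(1L, M))
  H2 <- H1
  n_f1 <- max(4L, 2L * config$families_per_generation)
  f1_ids <- sprintf("G1_%04d", seq_len(n_f1))
  for (id in f1_ids) { H1[[id]] <- integer(M); H2[[id]] <- rep(1L, M) }
  ped <- rbind(ped, data.frame(individual_id = f1_ids, sire_id = "FA",
                               dam_id = "FB", generation = 1L,
                               sex = rep_len(c("M", "F"), n_f1),
                               stringsAsFactors = FALSE))
  prev <- ped[ped$generation == 1L, ]

  for (g in 2:config$generations) {
    males <- prev$individual_id[prev$sex == "M"]
    females <- prev$individual_id[prev$sex == "F"]
    if (!length(males) || !length(females))
      stop("population extinct at generation ", g, " (no mating pairs)")
    nf <- config$families_per_generation
    dads <- sample(males, nf, replace = nf > length(males))
    moms <- sample(females, nf, replace = nf > length(females))
    # avoid full-sib pairs where the pool allows it
    par_of <- function(id) unlist(ped[ped$individual_id == id,
                                      c("sire_id", "dam_id")])
    for (pass in 1:5) {
      sib <- which(vapply(seq_len(nf), function(k)
        identical(par_of(dads[k]), par_of(moms[k])), logical(1)))
      if (!length(sib) || length(unique(moms)) == 1) break
      moms[sib] <- sample(moms)[sib]
    }
    ids <- character(0); sexes <- character(0)
    sires <- character(0); dams <- character(0)
    counter <- 0L
    for (k in seq_len(nf)) {
      d1 <- H1[[dads[k]]]; d2 <- H2[[dads[k]]]
      m1 <- H1[[moms[k]]]; m2 <- H2[[moms[k]]]
      for (slot in seq_len(config$litter_size)) {
        for (try in seq_len(100L)) {
          gp <- gamete(d1, d2, "paternal")
          gm <- gamete(m1, m2, "maternal")
          v <- if (length(incompatibilities)) viability_of(gp + gm) else 1
          if (v >= 1 || runif(1) < v) {
            counter <- counter + 1L
            id <- sprintf("G%d_%04d", g, counter)
            H1[[id]] <- gp; H2[[id]] <- gm
            ids <- c(ids, id)
            sires <- c(sires, dads[k]); dams <- c(dams, moms[k])
            break
          }
        }
      }
    }
    if (!length(ids))
      stop("population extinct at generation ", g,
           " (no viable offspring under the injected selection)")
    sexes <- rep_len(c("M", "F"), length(ids))
    newped <- data.frame(individual_id = ids, sire_id = sires, dam_id = dams,
                         generation = g, sex = sexes, stringsAsFactors = FALSE)
    ped <- rbind(ped, newped)
    prev <- newped
  }

  calls <- t(vapply(ped$individual_id, function(id) H1[[id]] + H2[[id]],
                    integer(M)))
  rownames(calls) <- ped$individual_id
  colnames(calls) <- marker_id
  if (config$genotype_missing_rate > 0) {
    non_founder <- ped$generation > 0L
    mask <- matrix(runif(sum(non_founder) * M) < config$genotype_missing_rate,
                   nrow = sum(non_founder))
    sub <- calls[non_founder, , drop = FALSE]
    sub[mask] <- NA_integer_
    calls[non_founder, ] <- sub
  }
  truth <- list(
    drivers = if (length(drivers)) data.frame(
      marker_id = marker_id[vapply(drivers, `[[`, 1L, "marker_index")],
      marker_index = vapply(drivers, `[[`, 1L, "marker_index"),
      chromosome = chr[vapply(drivers, `[[`, 1L, "marker_index")],
      tau = vapply(drivers, `[[`, 1, "tau"),
      sex = vapply(drivers, `[[`, "", "sex"),
      expected_distortion = expected_distortion(
        vapply(drivers, `[[`, 1, "tau")),
      stringsAsFactors = FALSE) else NULL,
    incompatibilities = lapply(incompatibilities, function(ip) {
      mn <- arrayInd(which.min(ip$viability), c(3, 3))
      list(marker_1 = marker_id[ip$marker_index_1],
           marker_2 = marker_id[ip$marker_index_2],
           viability = ip$viability,
           min_cell = c(class_1 = GENO_LEVELS[mn[1]],
                        class_2 = GENO_LEVELS[mn[2]]))
    }))
  structure(list(genotypes = geno_matrix(calls, map),
                 pedigree = as_pedigree(ped),
                 truth = truth, config = config),
            class = "ail_sim")
}

#' @export
print.ail_sim <- function(x, ...) {
  cat(sprintf("ail_sim: %d individuals over generations 0..%d, %d markers on %d chromosome(s); %d drive locus/loci, %d incompatibility pair(s)\n",
              nrow(x$pedigree), max(x$pedigree$generation),
              ncol(x$genotypes), x$config$n_chromosomes,
              if (is.null(x$truth$drivers)) 0L else nrow(x$truth$drivers),
              length(x$truth$incompatibilities)))
  invisible(x)
}
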