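#' @useDynLib breedsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rexp var cor sd setNames aggregate lm coef runif
#' @importFrom utils write.table read.table head tail
NULL

## ---------------------------------------------------------------------------
## Genome map
## ---------------------------------------------------------------------------

#' Build a genome map
#'
#' Lays out `n_loci` selectable (QTL or marker) loci evenly across
#' `n_chrom` chromosomes, with positions in Morgan at the midpoints of a
#' regular grid, plus `n_ibd` equidistant neutral IBD-tracer loci per
#' chromosome. QTL designation follows either the every-Nth rule
#' (`qtl_every_n`, 1-based within each chromosome) or an explicit list of
#' global locus indices (`qtl_index`), which mirrors randomly chosen QTL sets.
#'
#' When `n_loci` is not divisible by `n_chrom`, the remainder is assigned one
#' locus at a time to the first chromosomes.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome length(s) in Morgan (recycled to `n_chrom`).
#' @param n_loci total number of selectable loci across the genome.
#' @param qtl_every_n integer N: every Nth selectable locus within a
#'   chromosome is a QTL. Ignored when `qtl_index` is given.
#' @param qtl_index optional integer vector of global selectable-locus
#'   indices (1-based, genome order) to designate as QTLs.
#' @param n_ibd number of equidistant IBD-tracer loci per chromosome.
#' @return an object of class `GenomeMap`.
#' @export
build_genome_map <- function(n_chrom, lengths, n_loci, qtl_every_n = NULL,
                             qtl_index = NULL, n_ibd = 0) {
  if (n_chrom < 1 || n_loci < 1 || n_ibd < 0)
    stop("invalid genome configuration: counts must be positive")
  if (n_loci < n_chrom)
    stop("invalid genome configuration: need at least one locus per chromosome")
  lengths <- rep_len(as.numeric(lengths), n_chrom)
  if (any(lengths <= 0)) stop("invalid genome configuration: chromosome lengths must be positive")
  if (is.null(qtl_index)) {
    if (is.null(qtl_every_n) || qtl_every_n < 1)
      stop("invalid genome configuration: qtl_every_n must be >= 1 (or give qtl_index)")
  }

  per <- rep(n_loci %/% n_chrom, n_chrom)
  rem <- n_loci %% n_chrom
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1L

  chrom <- rep.int(seq_len(n_chrom), per)
  within <- unlist(lapply(per, seq_len), use.names = FALSE)
  pos <- lengths[chrom] * (within - 0.5) / per[chrom]

  role <- rep("MARKER", n_loci)
  if (!is.null(qtl_index)) {
    qtl_index <- as.integer(qtl_index)
    if (any(qtl_index < 1 | qtl_index > n_loci) || anyDuplicated(qtl_index))
      stop("invalid genome configuration: qtl_index out of range or duplicated")
    role[qtl_index] <- "QTL"
  } else {
    role[within %% qtl_every_n == 0] <- "QTL"
  }

  loc_first <- integer(n_chrom); loc_last <- integer(n_chrom)
  for (c in seq_len(n_chrom)) {
    w <- which(chrom == c)
    loc_first[c] <- w[1]; loc_last[c] <- w[length(w)]
  }

  if (n_ibd > 0) {
    ibd_chrom <- rep.int(seq_len(n_chrom), rep(n_ibd, n_chrom))
    ibd_within <- rep.int(seq_len(n_ibd), n_chrom)[order(rep(seq_len(n_ibd), n_chrom))]
    ibd_within <- unlist(lapply(seq_len(n_chrom), function(i) seq_len(n_ibd)), use.names = FALSE)
    ibd_pos <- lengths[ibd_chrom] * (ibd_within - 0.5) / n_ibd
    ibd_first <- (seq_len(n_chrom) - 1L) * n_ibd + 1L
    ibd_last <- seq_len(n_chrom) * n_ibd
  } else {
    ibd_chrom <- integer(0); ibd_pos <- numeric(0)
    ibd_first <- rep(0L, n_chrom); ibd_last <- rep(0L, n_chrom)
  }

  structure(list(
    n_chrom = as.integer(n_chrom), lengths = lengths,
    n_loci = as.integer(n_loci),
    loci = data.frame(chrom = chrom, pos = pos, role = role,
                      stringsAsFactors = FALSE),
    pos = pos, chrom = chrom,
    qtl_cols = which(role == "QTL"), marker_cols = which(role == "MARKER"),
    loc_first = loc_first, loc_last = loc_last,
    n_ibd = as.integer(n_ibd), n_ibd_total = length(ibd_pos),
    ibd_chrom = ibd_chrom, ibd_pos = ibd_pos,
    ibd_first = ibd_first, ibd_last = ibd_last
  ), class = "GenomeMap")
}

#' @export
print.GenomeMap <- function(x, ...) {
  cat("GenomeMap:", x$n_chrom, "chromosome(s),", x$n_loci, "selectable loci (",
      length(x$qtl_cols), "QTL /", length(x$marker_cols), "marker ),",
      x$n_ibd, "IBD loci per chromosome\n")
  invisible(x)
}

n_qtl <- function(map) length(map$qtl_cols)

## empty IBD matrix helper
empty_ibd <- function(n, map) matrix(0L, nrow = n, ncol = map$n_ibd_total)

## ---------------------------------------------------------------------------
## Meiosis
## ---------------------------------------------------------------------------

## internal batch interface: parents is a list(hap1, hap2, ibd1, ibd2) of
## integer matrices; rows: one gamete per entry (1-based parent row).
meiosis <- function(parents, rows, map, mutation_rate = 0) {
  ib1 <- parents$ibd1; ib2 <- parents$ibd2
  if (is.null(ib1)) { ib1 <- empty_ibd(nrow(parents$hap1), map); ib2 <- ib1 }
  .meiosis_batch(parents$hap1, parents$hap2, ib1, ib2,
                 as.integer(rows), map$pos, map$loc_first, map$loc_last,
                 map$ibd_pos, map$ibd_first, map$ibd_last,
                 map$lengths, mutation_rate)
}

#' Sample a gamete from one plant
#'
#' Simulates one meiosis: per chromosome the number of crossovers is
#' Poisson-distributed with mean equal to the chromosome length in Morgan,
#' breakpoints are uniform along the chromosome, and the transmitted strand
#' switches at each breakpoint (no interference, sex-averaged map). IBD
#' tracer alleles are inherited on the same breakpoints.
#'
#' @param h1,h2 integer allele vectors of the plant's two haplotypes
#'   (selectable loci, genome order).
#' @param map a [build_genome_map()] object.
#' @param ibd1,ibd2 optional integer IBD-label vectors.
#' @param mutation_rate per-locus probability of an allele toggle on the
#'   transmitted gamete (default 0; used by the founder phase).
#' @return list with `alleles` (integer vector) and `ibd` (integer vector,
#'   length 0 when the map carries no IBD loci).
#' @export
sample_gamete <- function(h1, h2, map, ibd1 = NULL, ibd2 = NULL,
                          mutation_rate = 0) {
  stopifnot(length(h1) == map$n_loci, length(h2) == map$n_loci)
  p <- list(hap1 = matrix(as.integer(h1), 1), hap2 = matrix(as.integer(h2), 1),
            ibd1 = if (!is.null(ibd1)) matrix(as.integer(ibd1), 1),
            ibd2 = if (!is.null(ibd2)) matrix(as.integer(ibd2), 1))
  g <- meiosis(p, 1L, map, mutation_rate)
  list(alleles = g$hap[1, ], ibd = g$ibd[1, ])
}

## ---------------------------------------------------------------------------
## Founder population (Fisher-Wright with mutation, drift, selection)
## ---------------------------------------------------------------------------

#' Founder-phase configuration
#'
#' @param n_pat,n_mat numbers of paternal and maternal founder plants.
#' @param ng_founder number of discrete founder generations.
#' @param mutation_rate per-locus, per-transmitted-gamete toggle probability.
#' @param culling_fraction fraction of each generation's offspring with the
#'   lowest TBV culled and replaced by freshly resampled offspring
#'   (default 0.05).
#' @param size_schedule optional integer vector of per-generation offspring
#'   counts (length <= ng_founder; the last value is carried forward),
#'   allowing expansion/contraction of the founder population.
#' @export
founder_config <- function(n_pat, n_mat, ng_founder, mutation_rate,
                           culling_fraction = 0.05, size_schedule = NULL) {
  if (n_pat < 1 || n_mat < 1)
    stop("invalid founder configuration: need at least 2 parents (n_pat and n_mat >= 1)")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("invalid founder configuration: mutation_rate must be in [0, 1)")
  if (culling_fraction < 0 || culling_fraction >= 1)
    stop("invalid founder configuration: culling_fraction must be in [0, 1)")
  if (!is.null(size_schedule)) {
    if (length(size_schedule) > ng_founder)
      stop("invalid founder configuration: size_schedule longer than ng_founder")
    if (any(size_schedule < 2))
      stop("invalid founder configuration: size_schedule entries must be >= 2")
  }
  structure(list(n_pat = as.integer(n_pat), n_mat = as.integer(n_mat),
                 ng_founder = as.integer(ng_founder),
                 mutation_rate = mutation_rate,
                 culling_fraction = culling_fraction,
                 size_schedule = size_schedule),
            class = "FounderConfig")
}

#' Simulate a founder population
#'
#' Runs `ng_founder` discrete generations of a Fisher-Wright model: random
#' mating without selfing (sires from the paternal pool, dams from the
#' maternal pool), recurrent bi-allelic mutation at `mutation_rate` per locus
#' per transmitted gamete, drift through finite population size, and weak
#' directional selection by culling the `culling_fraction` of each
#' generation's offspring with the lowest TBV and replacing them with freshly
#' resampled matings (replacements are not re-culled). All loci start
#' monomorphic wild-type; polymorphism and linkage disequilibrium build up
#' from mutation, drift and hitch-hiking.
#'
#' @param cfg a [founder_config()].
#' @param map a [build_genome_map()].
#' @param effects QTL-effect vector (single trait) or matrix with one column
#'   per trait (rows = QTLs in genome order).
#' @param fitness_weights weights combining per-trait TBVs into the culling
#'   criterion (default: equal weights).
#' @param init optional `FounderPool` to continue from (e.g. an imported or
#'   previously simulated pool) instead of the monomorphic wild-type start;
#'   its haplotypes are paired off into the generation-0 plants.
#' @return an object of class `FounderPool`: the pooled haplotypes of the
#'   final founder generation.
#' @export
simulate_founder_population <- function(cfg, map, effects,
                                        fitness_weights = NULL, init = NULL) {
  stopifnot(inherits(cfg, "FounderConfig"), inherits(map, "GenomeMap"))
  effects <- as.matrix(effects)
  if (nrow(effects) != n_qtl(map))
    stop("effects vector length must equal the number of QTLs")
  if (is.null(fitness_weights)) fitness_weights <- rep(1, ncol(effects))

  n0 <- cfg$n_pat + cfg$n_mat
  if (is.null(init)) {
    h1 <- matrix(0L, n0, map$n_loci)
    h2 <- matrix(0L, n0, map$n_loci)
  } else {
    stopifnot(inherits(init, "FounderPool"), init$n_loci == map$n_loci)
    d <- sample.int(init$n_haplotypes, 2 * n0, replace = 2 * n0 > init$n_haplotypes)
    h1 <- init$hap[d[seq_len(n0)], , drop = FALSE]
    h2 <- init$hap[d[n0 + seq_len(n0)], , drop = FALSE]
  }
  pat <- seq_len(cfg$n_pat)
  mat <- cfg$n_pat + seq_len(cfg$n_mat)
  n_culled <- integer(cfg$ng_founder)

  sched <- function(t) {
    s <- cfg$size_schedule
    if (is.null(s)) return(n0)
    if (t <= length(s)) s[t] else s[length(s)]
  }

  breed <- function(h1, h2, pat, mat, n_off) {
    sires <- pat[sample.int(length(pat), n_off, replace = TRUE)]
    dams <- mat[sample.int(length(mat), n_off, replace = TRUE)]
    par <- list(hap1 = h1, hap2 = h2)
    g1 <- meiosis(par, sires, map, cfg$mutation_rate)$hap
    g2 <- meiosis(par, dams, map, cfg$mutation_rate)$hap
    list(h1 = g1, h2 = g2)
  }

  for (t in seq_len(cfg$ng_founder)) {
    n_off <- sched(t)
    off <- breed(h1, h2, pat, mat, n_off)
    n_cull <- floor(cfg$culling_fraction * n_off)
    if (n_cull > 0) {
      tbv <- (off$h1[, map$qtl_cols, drop = FALSE] +
              off$h2[, map$qtl_cols, drop = FALSE]) %*% effects
      fit <- as.vector(tbv %*% fitness_weights)
      drop_idx <- order(fit, seq_along(fit))[seq_len(n_cull)]
      keep <- setdiff(seq_len(n_off), drop_idx)
      repl <- breed(h1, h2, pat, mat, n_cull)
      off$h1 <- rbind(off$h1[keep, , drop = FALSE], repl$h1)
      off$h2 <- rbind(off$h2[keep, , drop = FALSE], repl$h2)
      n_culled[t] <- n_cull
    }
    h1 <- off$h1; h2 <- off$h2
    perm <- sample.int(n_off)
    half <- n_off %/% 2
    pat <- perm[seq_len(half)]
    mat <- perm[(half + 1):n_off]
  }

  pool <- rbind(h1, h2)
  if (all(pool == pool[1, 1]))
    warning("founder pool is monomorphic at all loci")
  structure(list(hap = pool, n_haplotypes = nrow(pool),
                 n_loci = map$n_loci, provenance = "simulated",
                 n_culled = n_culled),
            class = "FounderPool")
}

#' @export
print.FounderPool <- function(x, ...) {
  cat("FounderPool:", x$n_haplotypes, "haplotypes x", x$n_loci, "loci (",
      x$provenance, ")\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Phased-genotype import / export (TSV dialect)
## ---------------------------------------------------------------------------

#' Export phased genomes
#'
#' Writes the tabular phased-genotype dialect: a map file with columns
#' `chromosome`, `locus_id`, `position_morgans`, `role` (QTL/MARKER rows for
#' selectable loci, IBD rows for tracer loci) and a genotype file with
#' columns `individual_id`, `haplotype_index` (1 or 2) followed by the allele
#' codes of the selectable loci in map order.
#'
#' @param hap1,hap2 integer haplotype matrices (plants x loci).
#' @param map a [build_genome_map()].
#' @param map_file,genotype_file output paths.
#' @param ids individual identifiers (default 1..n).
#' @export
export_phased_genomes <- function(hap1, hap2, map, map_file, genotype_file,
                                  ids = seq_len(nrow(hap1))) {
  md <- data.frame(chromosome = map$chrom,
                   locus_id = sprintf("c%d_l%04d", map$chrom,
                                      unlist(lapply(split(map$chrom, map$chrom), seq_along))),
                   position_morgans = map$pos,
                   role = map$loci$role)
  if (map$n_ibd_total > 0) {
    md <- rbind(md, data.frame(
      chromosome = map$ibd_chrom,
      locus_id = sprintf("c%d_ibd%03d", map$ibd_chrom,
                         unlist(lapply(split(map$ibd_chrom, map$ibd_chrom), seq_along))),
      position_morgans = map$ibd_pos, role = "IBD"))
  }
  write.table(md, map_file, sep = "\t", quote = FALSE, row.names = FALSE)

  n <- nrow(hap1)
  g <- matrix(0L, 2 * n, map$n_loci)
  g[seq(1, 2 * n, by = 2), ] <- hap1
  g[seq(2, 2 * n, by = 2), ] <- hap2
  gd <- data.frame(individual_id = rep(ids, each = 2),
                   haplotype_index = rep(1:2, n))
  gd <- cbind(gd, as.data.frame(g))
  names(gd)[-(1:2)] <- md$locus_id[md$role != "IBD"]
  write.table(gd, genotype_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(map_file, genotype_file))
}

#' Import phased genomes
#'
#' Reads the tabular dialect written by [export_phased_genomes()] and returns
#' the reconstructed genome map and a founder pool of haplotypes. Allele
#' codes must be 0/1; positions must be sorted within chromosome; every
#' individual must supply exactly haplotypes 1 and 2.
#'
#' @param map_file,genotype_file input paths.
#' @return list with elements `map` (a `GenomeMap`) and `pool`
#'   (a `FounderPool` tagged `imported`).
#' @export
import_phased_genomes <- function(map_file, genotype_file) {
  md <- read.table(map_file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chromosome", "locus_id", "position_morgans", "role")
  if (!all(need %in% names(md)))
    stop(sprintf("parse error in %s: missing columns %s", map_file,
                 paste(setdiff(need, names(md)), collapse = ", ")))
  sel <- md[md$role %in% c("QTL", "MARKER"), ]
  for (c in unique(sel$chromosome)) {
    p <- sel$position_morgans[sel$chromosome == c]
    if (is.unsorted(p, strictly = TRUE))
      stop(sprintf("parse error in %s: positions not strictly increasing on chromosome %s",
                   map_file, c))
  }
  map <- genome_map_from_loci(sel, md[md$role == "IBD", ])

  gd <- read.table(genotype_file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(gd) != 2 + nrow(sel))
    stop(sprintf("parse error in %s: expected %d allele columns, found %d",
                 genotype_file, nrow(sel), ncol(gd) - 2))
  alle <- as.matrix(gd[, -(1:2), drop = FALSE])
  bad <- which(!(alle %in% c(0L, 1L)))
  if (length(bad)) {
    row <- ((bad[1] - 1) %% nrow(alle)) + 1
    stop(sprintf("parse error in %s, line %d: allele codes must be 0 or 1",
                 genotype_file, row + 1))
  }
  ids <- unique(gd$individual_id)
  for (id in ids) {
    hx <- sort(gd$haplotype_index[gd$individual_id == id])
    if (!identical(as.integer(hx), 1:2))
      stop(sprintf("parse error in %s: individual %s must have haplotypes 1 and 2",
                   genotype_file, id))
  }
  o <- order(match(gd$individual_id, ids), gd$haplotype_index)
  alle <- alle[o, , drop = FALSE]
  storage.mode(alle) <- "integer"
  dimnames(alle) <- NULL
  pool <- structure(list(hap = alle, n_haplotypes = nrow(alle),
                         n_loci = ncol(alle), provenance = "imported",
                         ids = ids),
                    class = "FounderPool")
  list(map = map, pool = pool)
}

## rebuild a GenomeMap from explicit locus tables (used by importers)
genome_map_from_loci <- function(sel, ibd = NULL) {
  chroms <- sort(unique(sel$chromosome))
  chrom <- match(sel$chromosome, chroms)
  o <- order(chrom, sel$position_morgans)
  sel <- sel[o, ]; chrom <- chrom[o]
  n_chrom <- length(chroms)
  has_ibd <- !is.null(ibd) && nrow(ibd) > 0
  lengths <- vapply(seq_len(n_chrom), function(c) {
    m <- max(sel$position_morgans[chrom == c])
    if (has_ibd) m <- max(m, ibd$position_morgans[match(ibd$chromosome, chroms) == c], na.rm = TRUE)
    m * 1.0000001
  }, numeric(1))
  loc_first <- vapply(seq_len(n_chrom), function(c) which(chrom == c)[1], numeric(1))
  loc_last <- vapply(seq_len(n_chrom), function(c) max(which(chrom == c)), numeric(1))
  if (has_ibd) {
    ic <- match(ibd$chromosome, chroms)
    io <- order(ic, ibd$position_morgans)
    ibd <- ibd[io, ]; ic <- ic[io]
    ibd_first <- vapply(seq_len(n_chrom), function(c) {
      w <- which(ic == c); if (length(w)) w[1] else 0L }, numeric(1))
    ibd_last <- vapply(seq_len(n_chrom), function(c) {
      w <- which(ic == c); if (length(w)) w[length(w)] else 0L }, numeric(1))
    ibd_chrom <- ic; ibd_pos <- ibd$position_morgans
    n_ibd <- sum(ic == 1)
  } else {
    ibd_chrom <- integer(0); ibd_pos <- numeric(0)
    ibd_first <- rep(0L, n_chrom); ibd_last <- rep(0L, n_chrom); n_ibd <- 0L
  }
  structure(list(
    n_chrom = n_chrom, lengths = lengths, n_loci = nrow(sel),
    loci = data.frame(chrom = chrom, pos = sel$position_morgans,
                      role = sel$role, stringsAsFactors = FALSE),
    pos = sel$position_morgans, chrom = chrom,
    qtl_cols = which(sel$role == "QTL"),
    marker_cols = which(sel$role == "MARKER"),
    loc_first = as.integer(loc_first), loc_last = as.integer(loc_last),
    n_ibd = as.integer(n_ibd), n_ibd_total = length(ibd_pos),
    ibd_chrom = ibd_chrom, ibd_pos = ibd_pos,
    ibd_first = as.integer(ibd_first), ibd_last = as.integer(ibd_last)
  ), class = "GenomeMap")
}

#' Import phased genotypes from a VCF file
#'
#' Convenience importer for phased VCFs (GT fields like `0|1`); only
#' bi-allelic records are accepted. Physical positions are converted to
#' Morgan with `morgans_per_bp` (default 1e-8, i.e. 1 cM/Mb). All loci are
#' imported as markers unless `qtl_every_n` is given. Requires the vcfR
#' package.
#'
#' @param vcf_file path to an (uncompressed or gzipped) VCF.
#' @param morgans_per_bp map-distance conversion factor.
#' @param qtl_every_n optional every-Nth QTL designation.
#' @return list with `map` and `pool`, as [import_phased_genomes()].
#' @export
import_phased_vcf <- function(vcf_file, morgans_per_bp = 1e-8,
                              qtl_every_n = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("import_phased_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  bi <- !grepl(",", fix[, "ALT"])
  if (!all(bi)) stop(sprintf("parse error in %s: only bi-allelic records accepted", vcf_file))
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  if (any(!grepl("^[01]\\|[01]$", gt)))
    stop(sprintf("parse error in %s: genotypes must be phased 0|0, 0|1, 1|0 or 1|1", vcf_file))
  a1 <- t(matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt)))
  a2 <- t(matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt)))
  n <- ncol(gt)
  hap <- matrix(0L, 2 * n, nrow(gt))
  hap[seq(1, 2 * n, 2), ] <- a1
  hap[seq(2, 2 * n, 2), ] <- a2
  role <- rep("MARKER", nrow(gt))
  if (!is.null(qtl_every_n)) role[seq_len(nrow(gt)) %% qtl_every_n == 0] <- "QTL"
  sel <- data.frame(chromosome = fix[, "CHROM"],
                    position_morgans = as.numeric(fix[, "POS"]) * morgans_per_bp,
                    role = role, stringsAsFactors = FALSE)
  map <- genome_map_from_loci(sel)
  pool <- structure(list(hap = hap, n_haplotypes = 2 * n, n_loci = nrow(gt),
                         provenance = "imported", ids = colnames(gt)),
                    class = "FounderPool")
  list(map = map, pool = pool)
}
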