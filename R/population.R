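## ---------------------------------------------------------------------------
## Cohorts of plants
## ---------------------------------------------------------------------------

new_cohort <- function(id, sire, dam, hap1, hap2, ibd1, ibd2, tbv,
                       gen = 0L, cycle = 0L, family = NA_integer_,
                       line = NA_integer_, origin = "base") {
  n <- length(id)
  structure(list(n = n, id = as.integer(id),
                 sire = as.integer(rep_len(sire, n)),
                 dam = as.integer(rep_len(dam, n)),
                 gen = as.integer(gen), cycle = as.integer(cycle),
                 family = as.integer(rep_len(family, n)),
                 line = as.integer(rep_len(line, n)),
                 origin = rep_len(origin, n),
                 hap1 = hap1, hap2 = hap2, ibd1 = ibd1, ibd2 = ibd2,
                 tbv = as.matrix(tbv)),
            class = "cohort")
}

#' Subset a cohort
#'
#' @param cohort a cohort.
#' @param idx row indices to keep.
#' @return a cohort restricted to `idx` (order preserved as given).
#' @export
cohort_subset <- function(cohort, idx) {
  structure(list(n = length(idx), id = cohort$id[idx],
                 sire = cohort$sire[idx], dam = cohort$dam[idx],
                 gen = cohort$gen, cycle = cohort$cycle,
                 family = cohort$family[idx], line = cohort$line[idx],
                 origin = cohort$origin[idx],
                 hap1 = cohort$hap1[idx, , drop = FALSE],
                 hap2 = cohort$hap2[idx, , drop = FALSE],
                 ibd1 = cohort$ibd1[idx, , drop = FALSE],
                 ibd2 = cohort$ibd2[idx, , drop = FALSE],
                 tbv = cohort$tbv[idx, , drop = FALSE]),
            class = "cohort")
}

#' Combine cohorts
#'
#' @param cohorts list of cohorts with matching locus layouts.
#' @export
cohort_bind <- function(cohorts) {
  stopifnot(length(cohorts) >= 1)
  structure(list(
    n = sum(vapply(cohorts, `[[`, 0L, "n")),
    id = unlist(lapply(cohorts, `[[`, "id")),
    sire = unlist(lapply(cohorts, `[[`, "sire")),
    dam = unlist(lapply(cohorts, `[[`, "dam")),
    gen = cohorts[[1]]$gen, cycle = cohorts[[1]]$cycle,
    family = unlist(lapply(cohorts, `[[`, "family")),
    line = unlist(lapply(cohorts, `[[`, "line")),
    origin = unlist(lapply(cohorts, `[[`, "origin")),
    hap1 = do.call(rbind, lapply(cohorts, `[[`, "hap1")),
    hap2 = do.call(rbind, lapply(cohorts, `[[`, "hap2")),
    ibd1 = do.call(rbind, lapply(cohorts, `[[`, "ibd1")),
    ibd2 = do.call(rbind, lapply(cohorts, `[[`, "ibd2")),
    tbv = do.call(rbind, lapply(cohorts, `[[`, "tbv"))),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", x$n, "plants, generation", x$gen, "cycle", x$cycle, "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Base-population sampling
## ---------------------------------------------------------------------------

#' Sample a base population from a founder pool
#'
#' For each base plant and each chromosome, two haplotypes are drawn without
#' replacement from that chromosome's pool and replaced before the next
#' plant is drawn. When `inbred = TRUE` (self-pollinated crops assumed fully
#' inbred), the second haplotype is set identical to the first, so base
#' plants are completely homozygous.
#'
#' @param pool a [simulate_founder_population()] pool (or imported pool).
#' @param map the matching [build_genome_map()].
#' @param n_plants number of base plants.
#' @param inbred set haplotype 2 := haplotype 1?
#' @param effects optional standardized effect matrix to fill in TBVs.
#' @param id_start first plant id (default 1).
#' @return a cohort (generation 0, origin "base"); IBD tracer alleles are
#'   all 0 until [assign_ibd_alleles()] is called.
#' @export
sample_base_population <- function(pool, map, n_plants, inbred = FALSE,
                                   effects = NULL, id_start = 1L) {
  stopifnot(inherits(pool, "FounderPool"))
  nh <- pool$n_haplotypes
  if (nh < 2) stop("founder pool must contain at least 2 haplotypes")
  if (n_plants < 1) stop("n_plants must be >= 1")
  h1 <- matrix(0L, n_plants, map$n_loci)
  h2 <- matrix(0L, n_plants, map$n_loci)
  for (c in seq_len(map$n_chrom)) {
    cols <- map$loc_first[c]:map$loc_last[c]
    for (i in seq_len(n_plants)) {
      d <- sample.int(nh, 2)
      h1[i, cols] <- pool$hap[d[1], cols]
      h2[i, cols] <- pool$hap[d[2], cols]
    }
  }
  if (inbred) h2 <- h1
  tbv <- if (!is.null(effects))
    (h1[, map$qtl_cols, drop = FALSE] + h2[, map$qtl_cols, drop = FALSE]) %*% as.matrix(effects)
  else matrix(0, n_plants, 1)
  ids <- seq.int(id_start, length.out = n_plants)
  new_cohort(ids, 0L, 0L, h1, h2, empty_ibd(n_plants, map),
             empty_ibd(n_plants, map), tbv,
             origin = if (inbred) "base_inbred" else "base")
}

#' Assign unique IBD founder labels to a base cohort
#'
#' Every IBD tracer locus of a base plant receives a founder label: two
#' distinct fresh labels (one per haplotype) for non-inbred plants, a single
#' shared label for inbred plants (whose haplotypes are identical). Labels
#' are unique across plants, so any descendant allele traces back to exactly
#' one base haplotype.
#'
#' @param cohort a base cohort.
#' @param map the genome map.
#' @param label_start first label to use (default 1).
#' @return the cohort with `ibd1`/`ibd2` filled; attribute `next_label`.
#' @export
assign_ibd_alleles <- function(cohort, map, label_start = 1L) {
  if (map$n_ibd_total == 0) stop("map has no IBD loci")
  n <- cohort$n
  inbr <- cohort$origin == "base_inbred"
  lab1 <- integer(n); lab2 <- integer(n)
  nxt <- as.integer(label_start)
  for (i in seq_len(n)) {
    if (inbr[i]) {
      lab1[i] <- nxt; lab2[i] <- nxt; nxt <- nxt + 1L
    } else {
      lab1[i] <- nxt; lab2[i] <- nxt + 1L; nxt <- nxt + 2L
    }
  }
  cohort$ibd1 <- matrix(lab1, n, map$n_ibd_total)
  cohort$ibd2 <- matrix(lab2, n, map$n_ibd_total)
  attr(cohort, "next_label") <- nxt
  cohort
}

#' Realized (IBD-marker) inbreeding
#'
#' Fraction of IBD tracer loci at which a plant's two haplotypes carry the
#' same founder label.
#'
#' @param cohort a cohort with assigned IBD alleles.
#' @return numeric vector of per-plant realized inbreeding.
#' @export
ibd_inbreeding <- function(cohort) {
  if (ncol(cohort$ibd1) == 0) stop("cohort has no IBD tracer loci")
  rowMeans(cohort$ibd1 == cohort$ibd2)
}

## ---------------------------------------------------------------------------
## Pedigree: inbreeding and relationship matrices
## ---------------------------------------------------------------------------

check_pedigree <- function(pedigree) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  ped <- pedigree
  ped$sire[is.na(ped$sire)] <- 0L
  ped$dam[is.na(ped$dam)] <- 0L
  if (anyDuplicated(ped$id)) stop("pedigree ids must be unique")
  pos <- match(ped$sire, ped$id)
  if (any(!is.na(pos) & pos >= seq_len(nrow(ped))) ||
      any(!is.na(match(ped$dam, ped$id)) &
          match(ped$dam, ped$id) >= seq_len(nrow(ped))))
    stop("pedigree cycle or ordering error: parents must precede offspring")
  if (is.null(ped$dh)) ped$dh <- FALSE
  if (is.null(ped$f0)) ped$f0 <- 0
  ped
}

## tabular (recursive) numerator relationship matrix over the whole pedigree
build_A <- function(ped) {
  n <- nrow(ped)
  A <- matrix(0, n, n)
  s <- match(ped$sire, ped$id); d <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (is.na(si) && is.na(di)) {
      A[i, i] <- 1 + ped$f0[i]
    } else if (ped$dh[i]) {
      A[i, i] <- 2
    } else {
      asd <- if (!is.na(si) && !is.na(di)) A[si, di] else 0
      A[i, i] <- 1 + 0.5 * asd
    }
    if (i > 1) {
      j <- seq_len(i - 1)
      aji <- 0.5 * ((if (!is.na(si)) A[j, si] else 0) +
                    (if (!is.na(di)) A[j, di] else 0))
      ## a DH carries two copies of a single parental gamete: relationship to
      ## others equals the progenitor's (both recorded parents are the
      ## progenitor, so the tabular rule already gives a_jp)
      A[i, j] <- aji; A[j, i] <- aji
    }
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Pedigree-based inbreeding coefficients
#'
#' Wright's inbreeding via the tabular additive-relationship recursion
#' (`a_ii = 1 + F_i`, `F_i = a_sd / 2`). Base plants have F = 0 unless
#' declared inbred through the pedigree column `f0` (e.g. 1 for fully inbred
#' founders); doubled-haploid-origin plants (`dh = TRUE`) are set F = 1.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (0/NA for
#'   unknown), optional logical `dh` and numeric `f0` (founder inbreeding);
#'   parents must precede offspring.
#' @return named numeric vector of inbreeding coefficients.
#' @export
pedigree_inbreeding <- function(pedigree) {
  ped <- check_pedigree(pedigree)
  A <- build_A(ped)
  setNames(diag(A) - 1, ped$id)
}

#' Pedigree (numerator) relationship matrix
#'
#' @param pedigree as in [pedigree_inbreeding()].
#' @param ids optional subset of ids for the returned matrix.
#' @return symmetric A matrix with diagonal `1 + F`.
#' @export
relationship_matrix_pedigree <- function(pedigree, ids = NULL) {
  ped <- check_pedigree(pedigree)
  A <- build_A(ped)
  if (!is.null(ids)) {
    pos <- match(ids, ped$id)
    if (anyNA(pos)) stop("unknown id(s): ",
                         paste(ids[is.na(pos)], collapse = ", "))
    A <- A[pos, pos, drop = FALSE]
  }
  A
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = M M' / (2 sum p_j (1 - p_j))` with `M` the allele-frequency-centered
#' dosage matrix. Frequencies should be the base-population frequencies,
#' frozen at base sampling. Monomorphic loci (p = 0 or 1) are excluded.
#'
#' @param dosage plants x loci matrix of 0/1/2 mutant-allele counts
#'   (marker loci; QTLs are unknown to the breeder and excluded upstream).
#' @param p base-population allele frequencies (default: computed from
#'   `dosage`).
#' @return symmetric PSD G matrix.
#' @export
genomic_relationship <- function(dosage, p = NULL) {
  if (nrow(dosage) < 2) stop("need at least 2 plants")
  if (is.null(p)) p <- colMeans(dosage) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all loci monomorphic: cannot build G")
  M <- sweep(dosage[, keep, drop = FALSE], 2, 2 * p[keep])
  G <- tcrossprod(M) / (2 * sum(p[keep] * (1 - p[keep])))
  (G + t(G)) / 2
}

## ---------------------------------------------------------------------------
## Germplasm store
## ---------------------------------------------------------------------------

#' Create a germplasm store
#'
#' Seed-bank abstraction: immutable snapshots of plant genotypes keyed by
#' (cycle, generation), tagged with the time step of storage.
#' @export
germplasm_store <- function() {
  e <- new.env(parent = emptyenv())
  e$entries <- list()
  class(e) <- "germplasm_store"
  e
}

#' Store germplasm
#'
#' @param store a [germplasm_store()].
#' @param cohort cohort holding the plants.
#' @param idx rows of the plants whose germplasm is stored.
#' @param cycle,gen,time_step tags.
#' @param criterion optional selection-criterion values (one per stored
#'   plant), kept with the entry for criterion-based parent sourcing.
#' @export
store_germplasm <- function(store, cohort, idx, cycle, gen, time_step,
                            criterion = NULL) {
  key <- sprintf("c%d_g%d", cycle, gen)
  entry <- list(cohort = cohort_subset(cohort, idx), cycle = cycle,
                gen = gen, time_step = time_step,
                criterion = if (!is.null(criterion)) criterion else
                  rep(NA_real_, length(idx)))
  store$entries[[key]] <- entry
  invisible(store)
}

#' Fetch germplasm
#'
#' @param store a [germplasm_store()].
#' @param cycle,gen key of the stored entry.
#' @return the stored entry (list with `cohort`, `cycle`, `gen`,
#'   `time_step`). Missing keys are an error.
#' @export
fetch_germplasm <- function(store, cycle, gen) {
  key <- sprintf("c%d_g%d", cycle, gen)
  if (is.null(store$entries[[key]]))
    stop(sprintf("no germplasm stored for cycle %d generation %d", cycle, gen))
  store$entries[[key]]
}

germplasm_index <- function(store) {
  if (length(store$entries) == 0)
    return(data.frame(cycle = integer(0), gen = integer(0),
                      time_step = integer(0), n = integer(0)))
  do.call(rbind, lapply(store$entries, function(e)
    data.frame(cycle = e$cycle, gen = e$gen, time_step = e$time_step,
               n = e$cohort$n)))
}
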