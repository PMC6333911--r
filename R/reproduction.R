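## ---------------------------------------------------------------------------
## Seed propagation: crossing, selfing, cloning, doubled haploids
## ---------------------------------------------------------------------------

#' Enumerate a random cross set under a usage cap
#'
#' The candidate set is all unordered parent pairs excluding selfing (no
#' reciprocals; maternal effects are not modeled). A random subset of
#' `n_crosses` pairs is drawn such that no parent appears in more than
#' `max_uses` pairs: pairs are drawn one at a time uniformly among the
#' remaining feasible candidates, re-drawing the whole set when the draw
#' runs out of feasible pairs; after 1000 failed attempts a deterministic
#' usage-balanced greedy fill takes over (with a message).
#'
#' @param parents vector of parent ids (>= 2).
#' @param n_crosses number of crosses kept.
#' @param max_uses maximum number of crosses a single parent may enter.
#' @return data.frame with columns `sire`, `dam`; attribute `n_possible`
#'   gives the candidate-set size `choose(n_parents, 2)`.
#' @export
enumerate_crosses <- function(parents, n_crosses, max_uses = Inf) {
  np <- length(parents)
  if (np < 2) stop("need at least 2 parents")
  n_possible <- choose(np, 2)
  if (n_crosses > n_possible)
    stop(sprintf("n_crosses (%d) exceeds the %d possible pairs", n_crosses,
                 n_possible))
  if (is.finite(max_uses) && n_crosses > max_uses * np / 2)
    stop(sprintf(
      "infeasible cross set: n_crosses (%d) > max_uses * n_parents / 2 = %.1f",
      n_crosses, max_uses * np / 2))
  pairs <- t(combn(np, 2))

  draw <- function() {
    use <- integer(np)
    chosen <- integer(0)
    avail <- rep(TRUE, nrow(pairs))
    for (k in seq_len(n_crosses)) {
      ok <- which(avail & use[pairs[, 1]] < max_uses & use[pairs[, 2]] < max_uses)
      if (length(ok) == 0) return(NULL)
      pick <- ok[sample.int(length(ok), 1)]
      chosen <- c(chosen, pick)
      avail[pick] <- FALSE
      use[pairs[pick, ]] <- use[pairs[pick, ]] + 1L
    }
    chosen
  }
  chosen <- NULL
  for (att in seq_len(1000)) {
    chosen <- draw()
    if (!is.null(chosen)) break
  }
  if (is.null(chosen)) {
    message("cross enumeration fell back to greedy usage-balanced fill")
    use <- integer(np)
    ord <- sample.int(nrow(pairs))
    chosen <- integer(0)
    for (pick in ord) {
      if (use[pairs[pick, 1]] < max_uses && use[pairs[pick, 2]] < max_uses) {
        chosen <- c(chosen, pick)
        use[pairs[pick, ]] <- use[pairs[pick, ]] + 1L
        if (length(chosen) == n_crosses) break
      }
    }
    if (length(chosen) < n_crosses)
      stop("infeasible cross set even under greedy fill")
  }
  out <- data.frame(sire = parents[pairs[chosen, 1]],
                    dam = parents[pairs[chosen, 2]])
  attr(out, "n_possible") <- n_possible
  out
}

## internal engine: create offspring from parent cohort rows; selfing when
## sire_rows == dam_rows. Two independent gametes per seed.
make_offspring <- function(parents, sire_rows, dam_rows, map, effects,
                           id_start, gen, cycle, family = NULL, line = NULL,
                           origin = "cross", mutation_rate = 0) {
  m <- length(sire_rows)
  g1 <- meiosis(parents, sire_rows, map, mutation_rate)
  g2 <- meiosis(parents, dam_rows, map, mutation_rate)
  tbv <- (g1$hap[, map$qtl_cols, drop = FALSE] +
          g2$hap[, map$qtl_cols, drop = FALSE]) %*% as.matrix(effects)
  new_cohort(seq.int(id_start, length.out = m),
             parents$id[sire_rows], parents$id[dam_rows],
             g1$hap, g2$hap, g1$ibd, g2$ibd, tbv, gen = gen, cycle = cycle,
             family = if (is.null(family)) parents$family[sire_rows] else family,
             line = if (is.null(line)) parents$line[sire_rows] else line,
             origin = origin)
}

#' Cross two parent sets
#'
#' Each cross produces `n_seeds` offspring, every seed the union of one
#' gamete from the sire and one from the dam.
#'
#' @param parents a cohort holding the parents.
#' @param crosses data.frame with columns `sire`, `dam` (plant ids present
#'   in `parents`), e.g. from [enumerate_crosses()].
#' @param map,effects genome map and standardized QTL effects.
#' @param n_seeds seeds per cross (default 1, as when a single F1 stands in
#'   for the genetically identical seeds of one cross).
#' @param id_start first offspring id.
#' @param gen,cycle generation / cycle tags for the offspring.
#' @return offspring cohort; the F1 family tag is the cross index.
#' @export
cross_offspring <- function(parents, crosses, map, effects, n_seeds = 1,
                            id_start = max(parents$id) + 1L, gen = 1L,
                            cycle = parents$cycle) {
  s <- match(crosses$sire, parents$id)
  d <- match(crosses$dam, parents$id)
  if (anyNA(s) || anyNA(d)) stop("cross refers to unknown parent id")
  sire_rows <- rep(s, each = n_seeds)
  dam_rows <- rep(d, each = n_seeds)
  off <- make_offspring(parents, sire_rows, dam_rows, map, effects, id_start,
                        gen, cycle, family = rep(seq_along(s), each = n_seeds),
                        origin = "cross")
  off
}

#' Self-pollinate plants
#'
#' Each seed is formed from two independent gametes of the same plant; the
#' pedigree records the plant as both sire and dam.
#'
#' @param cohort parent cohort.
#' @param rows parent rows to self (default all).
#' @param n_seeds seeds per plant.
#' @param map,effects genome map and effects.
#' @param id_start first offspring id.
#' @export
self_progeny <- function(cohort, rows = seq_len(cohort$n), n_seeds, map,
                         effects, id_start = max(cohort$id) + 1L) {
  pr <- rep(rows, each = n_seeds)
  make_offspring(cohort, pr, pr, map, effects, id_start,
                 gen = cohort$gen + 1L, cycle = cohort$cycle,
                 origin = "self")
}

#' Clone plants
#'
#' Exact genotype copies with new ids; the pedigree notes the clonal origin
#' (sire = dam = source).
#'
#' @param cohort source cohort.
#' @param rows rows to clone.
#' @param n clones per source plant.
#' @param id_start first clone id.
#' @export
clone_progeny <- function(cohort, rows = seq_len(cohort$n), n = 1,
                          id_start = max(cohort$id) + 1L) {
  if (n == 0 || length(rows) == 0) return(cohort_subset(cohort, integer(0)))
  idx <- rep(rows, each = n)
  out <- cohort_subset(cohort, idx)
  out$sire <- cohort$id[idx]
  out$dam <- cohort$id[idx]
  out$id <- seq.int(id_start, length.out = length(idx))
  out$origin <- rep("clone", length(idx))
  out
}

#' Doubled haploids
#'
#' For each selected plant, one recombined gamete is sampled and doubled
#' into both haplotypes, giving a fully homozygous individual with
#' inbreeding F = 1; the pedigree records the single progenitor as both
#' parents with a DH origin tag.
#'
#' @param cohort source cohort.
#' @param rows rows to derive DHs from.
#' @param map,effects genome map and effects.
#' @param id_start first DH id.
#' @export
make_doubled_haploid <- function(cohort, rows = seq_len(cohort$n), map,
                                 effects, id_start = max(cohort$id) + 1L) {
  g <- meiosis(cohort, rows, map, 0)
  tbv <- 2 * (g$hap[, map$qtl_cols, drop = FALSE] %*% as.matrix(effects))
  new_cohort(seq.int(id_start, length.out = length(rows)),
             cohort$id[rows], cohort$id[rows], g$hap, g$hap, g$ibd, g$ibd,
             tbv, gen = cohort$gen + 1L, cycle = cohort$cycle,
             family = cohort$family[rows], line = cohort$line[rows],
             origin = "dh")
}
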