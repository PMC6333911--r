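## ---------------------------------------------------------------------------
## Breeding plans
## ---------------------------------------------------------------------------

## Note on max_uses: 50 unordered crosses consume 100 parent-uses, so a cap
## of 4 over 20 parents (80 uses) cannot yield 50 distinct pairs; 5 is the
## smallest feasible cap for the stated cross count.
full_scale_counts <- function() {
  list(n_parents = 20L, n_crosses = 50L, max_uses = 5L,
       f2_seeds = 10L, f2_sel = 5L, f3_seeds = 30L, f3_fam_sel = 45L,
       f4_per_fam = 60L, f4_sel = 5L, f5_seeds = 20L, f5_sel = 75L,
       line_seeds = 900L, f6_sel = 30L, f7_sel = 5L,
       f3_plots = 3L, f5_plots = 1L, line_plots = 9L)
}

## Reduced test scale: family and line funnels divided by 5; per-plant and
## per-family seed numbers and plot counts kept so the within-family
## structure matches the full plan. Parents are halved (not /5) because 10
## crosses under a usage cap of 4 need at least 5 parents and germplasm
## sourcing needs a comfortable margin.
reduced_scale_counts <- function() {
  list(n_parents = 10L, n_crosses = 10L, max_uses = 4L,
       f2_seeds = 10L, f2_sel = 5L, f3_seeds = 30L, f3_fam_sel = 9L,
       f4_per_fam = 60L, f4_sel = 5L, f5_seeds = 20L, f5_sel = 15L,
       line_seeds = 180L, f6_sel = 6L, f7_sel = 1L,
       f3_plots = 3L, f5_plots = 1L, line_plots = 9L)
}

#' Wheat line-breeding plans
#'
#' Builds one of the three shipped 8-generation wheat breeding plans:
#' `"PS"` (phenotypic selection throughout), `"GS"` (10-year phenotypic
#' burn-in, then GBLUP line selection at F5-F7 with a reference population
#' growing by one F4 cohort per year), and `"SPB"` (as GS, but F1-F4 are
#' compressed into the cycle's first year by speed breeding). A new cycle
#' starts every time step (year), so cycles overlap; early cycles draw
#' parents from the founder pool, later cycles from germplasm stored at
#' F5-F7 of previous cycles.
#'
#' Three correlated traits are simulated: breeder's visual preference (BVP,
#' individual-plant heritability 0.1), preliminary-trial yield (YP, plot
#' heritability 0.2) and advanced-trial yield (YA, plot heritability 0.3),
#' all with genetic variance 1 in standardized units.
#'
#' @param strategy `"PS"`, `"GS"` or `"SPB"`.
#' @param scale 1 for the full plan (50 crosses, 7500 F3, 225 F4 lines,
#'   75/30/5 line funnel) or 5 for the reduced test scale.
#' @param corr_yp_ya genetic correlation between YP and YA (default 0.3).
#' @param corr_bvp genetic correlation between BVP and the yield traits.
#' @param horizon number of simulated time steps (years).
#' @param burn_in last year of the phenotypic burn-in for GS/SPB.
#' @param genome,founder,counts optional overrides of the genome layout,
#'   founder configuration and stage counts.
#' @param n_std size of the outbred base cohort used to standardize QTL
#'   effects and freeze base allele frequencies.
#' @param store_pedigree keep the full pedigree in the run output?
#' @param parent_policy how germplasm-sourced parents are drawn:
#'   `"uniform"` (stored entries are already selected material, so uniform is the
#'   minimal reading) or `"truncation"` on the stored selection criterion.
#' @return an object of class `breeding_plan`.
#' @export
wheat_plan <- function(strategy = c("PS", "GS", "SPB"), scale = 1,
                       corr_yp_ya = 0.3, corr_bvp = 0, horizon = 25,
                       burn_in = 10, genome = NULL, founder = NULL,
                       counts = NULL, n_std = 500, store_pedigree = TRUE,
                       parent_policy = c("uniform", "truncation")) {
  parent_policy <- match.arg(parent_policy)
  strategy <- match.arg(strategy)
  if (is.null(counts)) {
    if (scale == 1) counts <- full_scale_counts()
    else if (scale == 5) counts <- reduced_scale_counts()
    else stop("scale must be 1 or 5 (or pass explicit counts)")
  }
  ## Reduced-scale genome: one 3-Morgan chromosome carrying all 500 loci (a
  ## single-chromosome stand-in for a multi-chromosome cereal map; a shorter
  ## map makes hitch-hiking unrealistically strong and burns out the standing
  ## variance). Founder: 500 plants, 400 Fisher-Wright generations at
  ## theta = 4*N*mu = 5, a stand-in for the marker diversity of a commercial
  ## panel, keeping QTLs and markers segregating across the 25-year horizon.
  if (is.null(genome))
    genome <- list(n_chrom = 1L, lengths = 3, n_loci = 500L,
                   qtl_every_n = 10L, n_ibd = 20L)
  if (is.null(founder))
    founder <- founder_config(250, 250, 400, 0.0025, 0.05)

  corr <- diag(3)
  corr[2, 3] <- corr[3, 2] <- corr_yp_ya
  corr[1, 2] <- corr[2, 1] <- corr_bvp
  corr[1, 3] <- corr[3, 1] <- corr_bvp
  traits <- list(names = c("BVP", "YP", "YA"), sigma_g2 = c(1, 1, 1),
                 h2 = c(0.1, NA, NA), h2_plot = c(NA, 0.2, 0.3),
                 corr = corr)

  calendar <- if (strategy == "SPB") setNames(c(0L, 0L, 0L, 0L, 1L, 2L, 3L, 4L), 1:8)
              else setNames(0:7, 1:8)
  founder_cycles <- if (strategy == "SPB") 5L else 7L
  switch_time <- if (strategy == "PS") Inf else burn_in
  if (is.finite(switch_time) && switch_time > horizon)
    stop("invalid plan: burn-in switch after the horizon")

  structure(list(name = paste0("wheat_", strategy), strategy = strategy,
                 scale = scale, genome = genome, founder = founder,
                 traits = traits, counts = counts, calendar = calendar,
                 n_gen = 8L, founder_cycles = founder_cycles,
                 parent_gens = 5:7, parent_policy = parent_policy,
                 switch_time = switch_time,
                 horizon = as.integer(horizon), n_std = as.integer(n_std),
                 store_pedigree = store_pedigree),
            class = "breeding_plan")
}

#' @export
print.breeding_plan <- function(x, ...) {
  cat("breeding_plan", x$name, "| scale 1/", x$scale, "| horizon",
      x$horizon, "| burn-in switch",
      if (is.finite(x$switch_time)) x$switch_time else "none", "\n")
  invisible(x)
}

## Per-generation stage specifications. gs = TRUE gives the genomic-selection
## variant of F5-F7 (GBLUP line selection + reference accumulation).
stage_specs <- function(plan, gs) {
  ct <- plan$counts
  specs <- vector("list", 8)
  specs[[1]] <- list(group = "family", phen = NULL, sel = NULL,
                     prop = list(per = "plant", n = ct$f2_seeds))
  specs[[2]] <- list(group = "family",
                     phen = list(trait = 1L, type = "individual"),
                     sel = list(unit = "within_family", k = ct$f2_sel,
                                criterion = "phen", trait = 1L),
                     prop = list(per = "plant", n = ct$f3_seeds))
  specs[[3]] <- list(group = "family",
                     phen = list(trait = 2L, type = "plot",
                                 n_plots = ct$f3_plots),
                     sel = list(unit = "group", k = ct$f3_fam_sel,
                                criterion = "phen", trait = 2L),
                     prop = list(per = "group", n = ct$f4_per_fam))
  specs[[4]] <- list(group = "family",
                     phen = list(trait = 1L, type = "individual"),
                     sel = list(unit = "within_family", k = ct$f4_sel,
                                criterion = "phen", trait = 1L),
                     make_lines = TRUE,
                     prop = list(per = "plant", n = ct$f5_seeds))
  mk_line_stage <- function(trait, n_plots, k) {
    s <- list(group = "line",
              phen = list(trait = trait, type = "plot", n_plots = n_plots),
              sel = list(unit = "group", k = k, criterion = "phen",
                         trait = trait),
              store = TRUE,
              prop = list(per = "group", n = ct$line_seeds))
    if (gs) {
      s$sel$criterion <- "gebv"
      s$sel$gebv_trait <- 3L
      s$ref_trait <- trait
    }
    s
  }
  specs[[5]] <- mk_line_stage(2L, ct$f5_plots, ct$f5_sel)
  specs[[6]] <- mk_line_stage(3L, ct$line_plots, ct$f6_sel)
  specs[[7]] <- mk_line_stage(3L, ct$line_plots, ct$f7_sel)
  specs[[8]] <- list(group = "line", phen = NULL, sel = NULL, prop = NULL,
                     release = TRUE)
  specs
}

## ---------------------------------------------------------------------------
## Founder setup (map, effects, pool, base frequencies)
## ---------------------------------------------------------------------------

#' Prepare the founder setup of a plan
#'
#' Builds the genome map, samples multi-trait QTL effects, runs the
#' Fisher-Wright founder phase, standardizes the effects on an outbred
#' (Hardy-Weinberg) base cohort of size `n_std` so each trait's base
#' additive variance equals its target exactly, and freezes the base allele
#' frequencies used for genomic relationships. A setup can be shared by
#' several plans within a replicate (paired comparisons).
#'
#' @param plan a [wheat_plan()] (or compatible plan).
#' @param seed RNG seed.
#' @return list with `map`, `effects`, `base_freq`, `pool`, `seed`.
#' @export
make_founder_setup <- function(plan, seed) {
  set.seed(seed)
  g <- plan$genome
  map <- build_genome_map(g$n_chrom, g$lengths, g$n_loci,
                         qtl_every_n = g$qtl_every_n,
                         qtl_index = g$qtl_index, n_ibd = g$n_ibd)
  tr <- plan$traits
  Sg <- tr$corr * tcrossprod(sqrt(tr$sigma_g2))
  eff_raw <- sample_qtl_effects_multitrait(n_qtl(map), Sg)
  pool <- simulate_founder_population(plan$founder, map, eff_raw)
  std <- sample_base_population(pool, map, plan$n_std, inbred = FALSE)
  effects <- standardize_effects(eff_raw, cohort_dosage(std, map), tr$sigma_g2)
  base_freq <- colMeans(std$hap1 + std$hap2) / 2
  list(map = map, effects = effects, base_freq = base_freq, pool = pool,
       seed = seed)
}

## ---------------------------------------------------------------------------
## Simulation state and engine
## ---------------------------------------------------------------------------

new_simulation_state <- function(plan, setup) {
  st <- new.env(parent = emptyenv())
  st$plan <- plan; st$setup <- setup
  st$clock <- 0L
  st$cycles <- list()
  st$germ <- germplasm_store()
  st$ref <- new.env(parent = emptyenv())
  st$ref$ids <- integer(0)
  st$ref$chunks <- list()
  st$ref$rec <- list()
  st$records <- list()
  st$log <- list()
  st$ped <- list()
  st$released <- list()
  st$next_id <- 1L
  st$next_ibd <- 1L
  st
}

log_event <- function(st, cycle, gen, event, value) {
  st$log[[length(st$log) + 1L]] <-
    data.frame(time_step = st$clock, cycle = cycle, generation = gen,
               event = event, value = value)
}

ped_add <- function(st, cohort, f0 = 0) {
  if (!isTRUE(st$plan$store_pedigree)) return(invisible())
  st$ped[[length(st$ped) + 1L]] <-
    data.frame(id = cohort$id, sire = cohort$sire, dam = cohort$dam,
               generation = cohort$gen, cycle = cohort$cycle,
               time_step = st$clock, origin = cohort$origin,
               dh = cohort$origin == "dh", f0 = f0)
}

## reference population (genomic selection): marker dosages keyed by plant id
## plus per-trait line-mean phenotype records
ref_add <- function(st, ids, dosage, trait, values, rvar) {
  new <- !(ids %in% st$ref$ids)
  if (any(new)) {
    st$ref$chunks[[length(st$ref$chunks) + 1L]] <- dosage[new, , drop = FALSE]
    st$ref$ids <- c(st$ref$ids, ids[new])
    st$ref$dosage <- NULL
  }
  k <- as.character(trait)
  st$ref$rec[[k]] <- rbind(st$ref$rec[[k]],
                           data.frame(plant = ids, value = values,
                                      rvar = rvar))
}

ref_dosage <- function(st) {
  if (is.null(st$ref$dosage))
    st$ref$dosage <- do.call(rbind, st$ref$chunks)
  st$ref$dosage
}

ref_gebv <- function(st, cand_ids, trait) {
  recs <- st$ref$rec[[as.character(trait)]]
  if (is.null(recs) || nrow(recs) == 0)
    stop("internal consistency error: GBLUP requested with empty reference")
  ids <- st$ref$ids
  M <- ref_dosage(st)
  p <- st$setup$base_freq[st$setup$map$marker_cols]
  G <- genomic_relationship(M, p)
  fit <- solve_mme(recs$value, match(recs$plant, ids),
                   rep(1L, nrow(recs)), G,
                   st$plan$traits$sigma_g2[trait], recs$rvar)
  u <- fit$ebv[, 1]
  u[match(cand_ids, ids)]
}

## parents for a new cycle: founder pool for early cycles, then germplasm
## stored at the eligible generations of previous cycles (most recent time
## step first, uniform without replacement within a batch).
source_parents <- function(st, plan) {
  ct <- plan$counts
  cyc_id <- st$clock
  if (cyc_id <= plan$founder_cycles) {
    p0 <- sample_base_population(st$setup$pool, st$setup$map, ct$n_parents,
                                 inbred = TRUE, effects = st$setup$effects,
                                 id_start = st$next_id)
    st$next_id <- st$next_id + p0$n
    p0 <- assign_ibd_alleles(p0, st$setup$map, st$next_ibd)
    st$next_ibd <- attr(p0, "next_label")
    p0$cycle <- cyc_id
    ped_add(st, p0, f0 = 1)
    return(p0)
  }
  gi <- germplasm_index(st$germ)
  gi <- gi[gi$gen %in% plan$parent_gens, , drop = FALSE]
  if (nrow(gi) == 0 || sum(gi$n) < ct$n_parents)
    stop(sprintf(
      "germplasm store empty or insufficient for cycle %d (generations %s)",
      cyc_id, paste(plan$parent_gens, collapse = ",")))
  ## the germplasm currently available at the eligible generations is that of
  ## the most recent storage time step(s): at time t the lines now at F5, F6
  ## and F7 are those stored at t-1. Parents are drawn across those pooled
  ## entries — uniformly without replacement by default, or by truncation on
  ## the stored selection criterion — walking back one time step at a time
  ## only if more parents are needed.
  policy <- plan$parent_policy
  if (is.null(policy)) policy <- "uniform"
  picks <- list()
  need <- ct$n_parents
  for (ts in sort(unique(gi$time_step), decreasing = TRUE)) {
    batch <- gi[gi$time_step == ts, , drop = FALSE]
    pooled <- do.call(rbind, lapply(seq_len(nrow(batch)), function(i) {
      e <- fetch_germplasm(st$germ, batch$cycle[i], batch$gen[i])
      data.frame(cycle = batch$cycle[i], gen = batch$gen[i],
                 idx = seq_len(batch$n[i]), criterion = e$criterion)
    }))
    take <- min(need, nrow(pooled))
    rows <- if (policy == "truncation")
      order(-pooled$criterion, pooled$cycle, pooled$idx)[seq_len(take)]
    else sample.int(nrow(pooled), take)
    sel <- pooled[rows, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      e <- fetch_germplasm(st$germ, sel$cycle[i], sel$gen[i])
      picks[[length(picks) + 1L]] <- cohort_subset(e$cohort, sel$idx[i])
    }
    need <- need - take
    if (need == 0) break
  }
  p0 <- cohort_bind(picks)
  p0$gen <- 0L
  p0$cycle <- cyc_id
  p0
}

do_p0 <- function(st, cyc, plan) {
  p0 <- source_parents(st, plan)
  ct <- plan$counts
  log_event(st, cyc$id, 0L, "parent_mean_tbv",
            mean(p0$tbv[, ncol(p0$tbv)]))
  crosses <- enumerate_crosses(p0$id, ct$n_crosses, ct$max_uses)
  log_event(st, cyc$id, 0L, "possible_crosses", attr(crosses, "n_possible"))
  log_event(st, cyc$id, 0L, "crosses_kept", nrow(crosses))
  f1 <- cross_offspring(p0, crosses, st$setup$map, st$setup$effects,
                        n_seeds = 1, id_start = st$next_id, gen = 1L,
                        cycle = cyc$id)
  st$next_id <- st$next_id + f1$n
  f1$family <- f1$id          # F1-families are founded by single F1 plants
  ped_add(st, f1)
  cyc$pending[["1"]] <- f1
}

execute_stage <- function(st, cyc, g, plan) {
  specs <- stage_specs(plan, gs = plan$strategy != "PS" &&
                               st$clock > plan$switch_time)
  s <- specs[[g]]
  cohort <- cyc$pending[[as.character(g)]]
  if (is.null(cohort))
    stop(sprintf("internal consistency error: cycle %d has no generation %d cohort at time %d",
                 cyc$id, g, st$clock))
  cyc$pending[[as.character(g)]] <- NULL
  map <- st$setup$map; effects <- st$setup$effects
  tr <- plan$traits
  grp <- if (identical(s$group, "line")) cohort$line else cohort$family

  ## --- phenotyping -------------------------------------------------------
  phen <- NULL; famsum <- NULL; se2 <- NA_real_; line_size <- NA_real_
  if (!is.null(s$phen)) {
    trait <- s$phen$trait
    sg2 <- tr$sigma_g2[trait]
    if (s$phen$type == "individual") {
      h2 <- tr$h2[trait]
      se2 <- sg2 * (1 - h2) / h2
    } else {
      sizes <- table(grp)
      line_size <- as.integer(sizes[1])
      Ns <- line_size / s$phen$n_plots
      H <- mean(cohort$hap1 == cohort$hap2)
      se2 <- calibrate_residual_variance(sg2, tr$h2_plot[trait], Ns, H)
    }
    phen <- cohort$tbv[, trait] + rnorm(cohort$n, 0, sqrt(se2))
    famsum <- rowsum(phen, grp)
  }

  ## --- selection ---------------------------------------------------------
  sel_idx <- seq_len(cohort$n)
  accuracy <- NA_real_
  n_selected <- NA_integer_
  grp_crit <- NULL
  if (!is.null(s$sel)) {
    trait <- s$sel$trait
    if (s$sel$criterion == "gebv") {
      lf <- cyc$line_founders
      cand <- sort(unique(grp))
      lf_rows <- match(cand, lf$id)
      ## line-mean phenotype records join the reference before the solve
      vals <- famsum[match(cand, as.integer(rownames(famsum))), 1] / line_size
      ref_add(st, cand, cohort_dosage(lf, map, map$marker_cols)[lf_rows, , drop = FALSE],
              s$ref_trait, vals, rep(se2 / line_size, length(cand)))
      log_event(st, cyc$id, g, "reference_size", length(st$ref$ids))
      gebv <- ref_gebv(st, cand, s$sel$gebv_trait)
      win <- cand[order(-gebv, cand)[seq_len(s$sel$k)]]
      sel_idx <- which(grp %in% win)
      grp_crit <- setNames(gebv, cand)
      accuracy <- selection_accuracy(gebv, lf$tbv[lf_rows, s$sel$gebv_trait])
    } else if (s$sel$unit == "within_family") {
      ids <- truncation_select(phen, s$sel$k, "within_family",
                               family = grp, ids = cohort$id)
      sel_idx <- which(cohort$id %in% ids)
      accuracy <- selection_accuracy(phen, cohort$tbv[, trait])
    } else {  # entire family / line on summed plot phenotypes
      ids <- truncation_select(phen, s$sel$k, "entire_family",
                               family = grp, ids = cohort$id)
      sel_idx <- which(cohort$id %in% ids)
      grp_crit <- setNames(famsum[, 1], rownames(famsum))
      accuracy <- selection_accuracy(phen, cohort$tbv[, trait],
                                     unit = "entire_family", family = grp)
    }
    n_selected <- length(sel_idx)
    log_event(st, cyc$id, g, "candidates", cohort$n)
    log_event(st, cyc$id, g, "selected", n_selected)
  }

  ## --- F4 lines ----------------------------------------------------------
  if (isTRUE(s$make_lines)) {
    cohort$line[sel_idx] <- cohort$id[sel_idx]
    cyc$line_founders <- cohort_subset(cohort, sel_idx)
  }

  ## --- germplasm ---------------------------------------------------------
  if (isTRUE(s$store)) {
    sel_grp <- unique(grp[sel_idx])
    keep <- vapply(sel_grp, function(f) {
      w <- sel_idx[grp[sel_idx] == f]
      w[sample.int(length(w), 1)]
    }, integer(1))
    store_germplasm(st$germ, cohort, keep, cyc$id, g, st$clock,
                    criterion = if (!is.null(grp_crit))
                      unname(grp_crit[as.character(sel_grp)]))
    log_event(st, cyc$id, g, "germplasm_stored", length(keep))
  }

  ## --- propagation -------------------------------------------------------
  if (!is.null(s$prop)) {
    if (s$prop$per == "plant") {
      rows <- rep(sel_idx, each = s$prop$n)
    } else {
      sel_grp <- unique(grp[sel_idx])
      rows <- unlist(lapply(sel_grp, function(f) {
        w <- sel_idx[grp[sel_idx] == f]
        w[sample.int(length(w), s$prop$n, replace = TRUE)]
      }), use.names = FALSE)
    }
    off <- make_offspring(cohort, rows, rows, map, effects, st$next_id,
                          gen = g + 1L, cycle = cyc$id, origin = "self")
    st$next_id <- st$next_id + off$n
    ped_add(st, off)
    log_event(st, cyc$id, g, "seeds_produced", off$n)
    cyc$pending[[as.character(g + 1L)]] <- off
  }

  ## --- records -----------------------------------------------------------
  st$records[[length(st$records) + 1L]] <-
    cohort_record(cohort, grp, phen,
                  phen_trait = if (!is.null(s$phen)) s$phen$trait else NA,
                  acc = accuracy,
                  acc_trait = if (!is.null(s$sel)) {
                    if (s$sel$criterion == "gebv") s$sel$gebv_trait else s$sel$trait
                  } else NA,
                  n_selected = n_selected, time_step = st$clock,
                  trait_names = tr$names)

  if (isTRUE(s$release)) {
    lines <- unique(cohort$line)
    st$released[[length(st$released) + 1L]] <-
      data.frame(time_step = st$clock, cycle = cyc$id,
                 n_lines_released = length(lines))
    log_event(st, cyc$id, g, "lines_released", length(lines))
  }
  invisible()
}

#' Advance the simulation by one time step
#'
#' Starts one new breeding cycle (parents from the founder pool or the
#' germplasm store), then, for every active cycle, executes all stages whose
#' calendar offset equals the cycle's age — phenotyping, breeding-value
#' estimation, selection, germplasm storage and propagation, in generation
#' order (speed-breeding calendars run several generations back-to-back
#' within one step). Completed cycles retire.
#'
#' @param st the simulation state (internal;
#'   normally driven by [run_replicate()]).
#' @param plan the breeding plan.
#' @export
advance_time_step <- function(st, plan) {
  st$clock <- st$clock + 1L
  cyc <- new.env(parent = emptyenv())
  cyc$id <- st$clock; cyc$start <- st$clock
  cyc$pending <- list(); cyc$line_founders <- NULL
  st$cycles[[as.character(st$clock)]] <- cyc

  max_off <- max(plan$calendar)
  for (key in names(st$cycles)) {
    cyc <- st$cycles[[key]]
    age <- st$clock - cyc$start
    if (age == 0) do_p0(st, cyc, plan)
    gens <- as.integer(names(plan$calendar)[plan$calendar == age])
    for (g in sort(gens)) execute_stage(st, cyc, g, plan)
    if (age >= max_off) st$cycles[[key]] <- NULL
  }
  invisible(st)
}

#' Run one replicate of a breeding plan
#'
#' Executes `horizon` time steps of the plan, fully reproducibly for a given
#' seed (identical seeds give bit-identical outputs).
#'
#' @param plan a [wheat_plan()].
#' @param seed RNG seed for this replicate.
#' @param setup optional [make_founder_setup()] result to reuse (paired plan
#'   comparisons); by default a fresh setup is generated from `seed`.
#' @param horizon number of time steps (default: the plan's).
#' @return a `breedsim_run`: list with `records` (per time step x cycle x
#'   generation x trait summaries), `log`, `released`, `pedigree` (if
#'   stored), `germplasm`, `seed`.
#' @export
run_replicate <- function(plan, seed, setup = NULL,
                          horizon = plan$horizon) {
  if (is.null(setup)) setup <- make_founder_setup(plan, seed)
  set.seed(seed)
  st <- new_simulation_state(plan, setup)
  for (t in seq_len(horizon)) advance_time_step(st, plan)
  structure(list(
    records = do.call(rbind, st$records),
    log = do.call(rbind, st$log),
    released = if (length(st$released)) do.call(rbind, st$released),
    pedigree = if (length(st$ped)) do.call(rbind, st$ped),
    germplasm = germplasm_index(st$germ),
    plan = plan$name, seed = seed),
    class = "breedsim_run")
}

#' @export
print.breedsim_run <- function(x, ...) {
  cat("breedsim_run:", x$plan, "| seed", x$seed, "|",
      nrow(x$records), "record rows\n")
  invisible(x)
}

#' Run a replicated simulation experiment
#'
#' Runs `n_replicates` replicates on seeds `base_seed + 1 ... base_seed + n`
#' and aggregates the mean and standard deviation of every reported variable
#' per (time step, generation, trait). With `unique_founder = FALSE` all
#' replicates share the founder setup of the first seed.
#'
#' @param plan a [wheat_plan()].
#' @param n_replicates number of replicates.
#' @param base_seed base RNG seed.
#' @param unique_founder fresh founder population per replicate (default)?
#' @return list with `replicates` (list of `breedsim_run`), `records` (all
#'   replicates, with a `replicate` column) and `summary`.
#' @export
run_experiment <- function(plan, n_replicates, base_seed,
                           unique_founder = TRUE) {
  stopifnot(n_replicates >= 1)
  shared <- if (!unique_founder) make_founder_setup(plan, base_seed + 1L)
  runs <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    runs[[i]] <- tryCatch(
      run_replicate(plan, base_seed + i,
                    setup = if (!unique_founder) shared),
      error = function(e) e)
  }
  failed <- vapply(runs, inherits, TRUE, "error")
  if (any(failed))
    warning(sprintf("%d replicate(s) failed: %s", sum(failed),
                    conditionMessage(runs[[which(failed)[1]]])))
  ok <- runs[!failed]
  rec <- do.call(rbind, lapply(seq_along(ok), function(i)
    cbind(replicate = i, ok[[i]]$records)))
  list(replicates = ok, records = rec,
       summary = aggregate_replicates(rec), incomplete = any(failed))
}

#' Run several plans on paired founder populations
#'
#' For each replicate seed, one founder setup is generated and shared by all
#' plans (paired comparison), then each plan is run on that seed.
#'
#' @param plans named list of [wheat_plan()]s with identical genome, founder
#'   and trait configurations.
#' @param n_replicates replicates per plan.
#' @param base_seed base RNG seed.
#' @param gain_window,gain_trait,gain_generation window (time steps) and
#'   trait for the per-replicate genetic-gain slopes.
#' @return list with `records` (plan + replicate columns) and `gains`
#'   (per plan x replicate OLS gain slopes).
#' @export
compare_plans <- function(plans, n_replicates, base_seed,
                          gain_window = c(11, 25), gain_trait = "YA",
                          gain_generation = 8) {
  stopifnot(length(names(plans)) == length(plans))
  rec_all <- list(); gains <- list()
  for (i in seq_len(n_replicates)) {
    seed <- base_seed + i
    setup <- make_founder_setup(plans[[1]], seed)
    for (pn in names(plans)) {
      run <- run_replicate(plans[[pn]], seed, setup = setup)
      rec_all[[length(rec_all) + 1L]] <-
        cbind(plan = pn, replicate = i, run$records)
      gains[[length(gains) + 1L]] <- data.frame(
        plan = pn, replicate = i,
        slope = genetic_gain_rate(run$records, trait = gain_trait,
                                  generation = gain_generation,
                                  window = gain_window)$slope)
    }
  }
  list(records = do.call(rbind, rec_all), gains = do.call(rbind, gains))
}
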