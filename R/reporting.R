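## ---------------------------------------------------------------------------
## Per-time-step records, genetic-gain rates, writers, replicate aggregation
## ---------------------------------------------------------------------------

## One record row per trait for a cohort: mean TBV, total / within- /
## between-family genetic variance (n-1 denominator; the three satisfy
## total = within + between exactly), mean phenotype of the phenotyped
## trait, selection accuracy (criterion trait only), realized IBD
## inbreeding, counts.
cohort_record <- function(cohort, grp, phen, phen_trait, acc, acc_trait,
                          n_selected, time_step, trait_names) {
  n <- cohort$n
  Tt <- ncol(cohort$tbv)
  f_ibd <- if (ncol(cohort$ibd1) > 0) mean(ibd_inbreeding(cohort)) else NA_real_
  has_grp <- !is.null(grp) && !all(is.na(grp))
  out <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    x <- cohort$tbv[, t]
    mu <- mean(x)
    vt <- if (n > 1) sum((x - mu)^2) / (n - 1) else 0
    if (has_grp && n > 1) {
      m <- rowsum(x, grp)
      ng <- as.vector(rowsum(rep(1, n), grp))
      vb <- sum(ng * (m[, 1] / ng - mu)^2) / (n - 1)
    } else vb <- NA_real_
    out[[t]] <- data.frame(
      time_step = time_step, cycle = cohort$cycle, generation = cohort$gen,
      trait = trait_names[t], n = n,
      n_families = if (has_grp) length(unique(grp)) else NA_integer_,
      mean_tbv = mu, var_total = vt,
      var_between = vb,
      var_within = if (is.na(vb)) NA_real_ else vt - vb,
      mean_phen = if (!is.na(phen_trait) && t == phen_trait) mean(phen) else NA_real_,
      accuracy = if (!is.na(acc_trait) && t == acc_trait) acc else NA_real_,
      mean_f_ibd = f_ibd, n_selected = n_selected)
  }
  do.call(rbind, out)
}

#' Rate of genetic gain
#'
#' Ordinary-least-squares slope of the final-generation mean TBV on time
#' step over a window — the per-year rate of genetic gain of the released
#' material. The slope is invariant to adding a constant to all TBVs.
#'
#' @param records a `breedsim_run$records` data.frame.
#' @param trait trait name (default `"YA"`).
#' @param generation generation whose cohorts define the gain series
#'   (default 8, the release generation).
#' @param window inclusive time-step window, e.g. `c(11, 25)`.
#' @return object of class `GainEstimate`: list with `slope`, `intercept`,
#'   `window`, `trait`, `n_points`.
#' @export
genetic_gain_rate <- function(records, trait = "YA", generation = 8,
                              window = c(11, 25)) {
  d <- records[records$trait == trait & records$generation == generation &
               records$time_step >= window[1] &
               records$time_step <= window[2], , drop = FALSE]
  if (nrow(d) < 2)
    stop("genetic_gain_rate needs at least 2 time points in the window")
  fit <- lm(mean_tbv ~ time_step, data = d)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 window = window, trait = trait, n_points = nrow(d)),
            class = "GainEstimate")
}

#' @export
print.GainEstimate <- function(x, ...) {
  cat(sprintf("Genetic gain in %s: %.4f per time step (window %d-%d, %d points)\n",
              x$trait, x$slope, x$window[1], x$window[2], x$n_points))
  invisible(x)
}

#' Aggregate records across replicates
#'
#' Mean and standard deviation of mean TBV, total genetic variance,
#' accuracy and realized inbreeding per (time step, generation, trait).
#'
#' @param records data.frame with a `replicate` column, as produced by
#'   [run_experiment()].
#' @export
aggregate_replicates <- function(records) {
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  vars <- c("mean_tbv", "var_total", "accuracy", "mean_f_ibd")
  by <- records[, c("time_step", "generation", "trait")]
  out <- aggregate(records[vars], by = by, FUN = mean, na.rm = TRUE)
  names(out)[match(vars, names(out))] <- paste0(vars, "_mean")
  sds <- aggregate(records[vars], by = by, FUN = sd0)
  names(sds)[match(vars, names(sds))] <- paste0(vars, "_sd")
  merge(out, sds, by = c("time_step", "generation", "trait"), sort = TRUE)
}

#' Write simulation outputs to a directory
#'
#' Tab-separated writers for the per-time-step records, the run log, the
#' release table, the pedigree, and (optionally) phased genotypes of the
#' germplasm in the importable dialect. Each enabled flag produces exactly
#' one file.
#'
#' @param run a `breedsim_run`.
#' @param dir output directory (created if missing).
#' @param records,log,released,pedigree logical flags.
#' @param genotypes optional list(cohort =, map =) to export phased
#'   genotypes of (writes two files: map + genotypes).
#' @return invisible character vector of the files written.
#' @export
write_outputs <- function(run, dir, records = TRUE, log = TRUE,
                          released = TRUE, pedigree = TRUE,
                          genotypes = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f) {
    path <- file.path(dir, f)
    tryCatch(write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = FALSE),
             error = function(e) stop(sprintf("failed writing %s: %s", path,
                                              conditionMessage(e))))
    path
  }
  files <- character(0)
  if (records) files <- c(files, wr(run$records, "timestep_summary.tsv"))
  if (log) files <- c(files, wr(run$log, "run_log.tsv"))
  if (released && !is.null(run$released))
    files <- c(files, wr(run$released, "released.tsv"))
  if (pedigree && !is.null(run$pedigree))
    files <- c(files, wr(run$pedigree, "pedigree.tsv"))
  if (!is.null(genotypes)) {
    mf <- file.path(dir, "genotype_map.tsv")
    gf <- file.path(dir, "genotypes.tsv")
    export_phased_genomes(genotypes$cohort$hap1, genotypes$cohort$hap2,
                          genotypes$map, mf, gf, ids = genotypes$cohort$id)
    files <- c(files, mf, gf)
  }
  invisible(files)
}

#' Write replicate-aggregate summaries
#'
#' @param experiment a [run_experiment()] result.
#' @param dir output directory.
#' @export
write_experiment_summary <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "replicate_summary.tsv")
  write.table(experiment$summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
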