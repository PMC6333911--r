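## ---------------------------------------------------------------------------
## Truncation / threshold selection
## ---------------------------------------------------------------------------

#' Truncation selection
#'
#' Selects the top-`n` candidates by criterion value. Units:
#' `population` (top n overall), `within_family` (top n within every
#' family), `entire_family` (top n families by summed criterion; all members
#' of the winning families are returned). Ties are broken by ascending
#' plant id.
#'
#' @param criterion numeric criterion per candidate (phenotype, EBV, ...).
#' @param n number selected (per family for `within_family`; number of
#'   families for `entire_family`).
#' @param unit selection unit.
#' @param family family tag per candidate (required unless unit is
#'   `population`).
#' @param ids candidate ids (default 1..n); used for tie-breaking and the
#'   return value.
#' @return selected ids.
#' @export
truncation_select <- function(criterion, n,
                              unit = c("population", "within_family",
                                       "entire_family"),
                              family = NULL, ids = seq_along(criterion)) {
  unit <- match.arg(unit)
  if (anyNA(criterion))
    stop("missing criterion values for candidates: ",
         paste(head(ids[is.na(criterion)], 10), collapse = ", "))
  if (unit == "population") {
    if (n > length(criterion)) stop("n_selected exceeds candidates")
    o <- order(-criterion, ids)
    return(sort(ids[o[seq_len(n)]]))
  }
  if (is.null(family)) stop("family tags required for family-based selection")
  if (unit == "within_family") {
    o <- order(family, -criterion, ids)
    r <- ave(seq_along(o), family[o], FUN = seq_along)
    return(sort(ids[o[r <= n]]))
  }
  ## entire_family: rank families on summed criterion
  fs <- rowsum(criterion, family)
  fam_ids <- as.integer(rownames(fs))
  if (n > length(fam_ids)) stop("n_selected exceeds number of families")
  o <- order(-fs[, 1], fam_ids)
  win <- fam_ids[o[seq_len(n)]]
  sort(ids[family %in% win])
}

#' Threshold selection
#'
#' All candidates whose phenotype is at or above the threshold; an empty
#' result is allowed (with a warning).
#'
#' @param phenotype observed values.
#' @param threshold cut-off.
#' @param ids candidate ids.
#' @export
threshold_select <- function(phenotype, threshold,
                             ids = seq_along(phenotype)) {
  sel <- ids[!is.na(phenotype) & phenotype >= threshold]
  if (length(sel) == 0) warning("threshold selection selected no candidates")
  sel
}

## ---------------------------------------------------------------------------
## Mixed-model equations (BLUP / GBLUP), possibly multi-trait
## ---------------------------------------------------------------------------

## y = Xb + Zu + e; u ~ N(0, Sigma_g (x) K); fixed effects: one mean per
## trait (or none when mean_known is supplied). Each record points at one
## (plant, trait); repeated records are allowed. rvar is the per-record
## residual variance. Dense solve; sizes here are hundreds to ~2000.
solve_mme <- function(value, plant, trait, K, Sigma_g, rvar,
                      mean_known = NULL, details = FALSE) {
  n <- nrow(K)
  Sigma_g <- as.matrix(Sigma_g)
  T <- nrow(Sigma_g)
  N <- length(value)
  stopifnot(length(plant) == N, length(trait) == N, length(rvar) == N)
  if (any(plant < 1 | plant > n)) stop("record refers to unknown plant")
  y <- value
  if (!is.null(mean_known)) y <- y - rep_len(mean_known, T)[trait]
  ri <- 1 / rvar

  build_and_solve <- function(K) {
    Kinv <- chol2inv(chol(K))
    Ginv <- kronecker(solve(Sigma_g), Kinv)
    nf <- if (is.null(mean_known)) T else 0L
    p <- nf + T * n
    C <- matrix(0, p, p)
    rhs <- numeric(p)
    ucol <- (trait - 1L) * n + plant
    ## Z'RiZ is diagonal (each record hits one u); accumulate counts
    dZ <- numeric(T * n)
    tab <- rowsum(cbind(ri, ri * y), ucol)
    at <- as.integer(rownames(tab))
    dZ[at] <- tab[, 1]
    rhs[nf + at] <- tab[, 2]
    C[(nf + 1):p, (nf + 1):p] <- Ginv
    diag(C)[(nf + 1):p] <- diag(Ginv) + dZ
    if (nf > 0) {
      for (t in seq_len(T)) {
        w <- trait == t
        C[t, t] <- sum(ri[w])
        rhs[t] <- sum(ri[w] * y[w])
        xz <- rowsum(ri[w], ucol[w])
        cols <- nf + as.integer(rownames(xz))
        C[t, cols] <- xz[, 1]
        C[cols, t] <- xz[, 1]
      }
    }
    list(sol = solve(C, rhs), C = C, rhs = rhs, nf = nf, p = p)
  }
  res <- tryCatch(build_and_solve(K), error = function(e) {
    message("relationship matrix (near-)singular; blended 0.99*K + 0.01*I")
    tryCatch(build_and_solve(0.99 * K + 0.01 * diag(n)), error = function(e2)
      tryCatch(build_and_solve(0.9 * K + 0.1 * mean(diag(K)) * diag(n)),
               error = function(e3)
                 stop("mixed-model equations singular even after blending")))
  })
  sol <- res$sol; nf <- res$nf; p <- res$p
  beta <- if (nf > 0) sol[seq_len(nf)] else rep_len(mean_known, T)
  u <- matrix(sol[(nf + 1):p], n, T)
  rownames(u) <- rownames(K)
  out <- list(ebv = u, beta = beta)
  if (details) { out$C <- res$C; out$rhs <- res$rhs; out$sol <- sol }
  out
}

#' Pedigree BLUP breeding values
#'
#' Solves the mixed-model equations for `y = Xb + Zu + e` with
#' `u ~ N(0, Sigma_g (x) A)`, A the numerator relationship matrix from the
#' pedigree. Fixed effects are one overall mean per trait (pass
#' `mean_known` to use a known mean instead). Variance components are
#' supplied by the user — in simulation studies, the true values. EBVs are
#' returned for every pedigree member, including unphenotyped ones.
#'
#' @param records data.frame with columns `id`, `value`, optional `trait`
#'   (default 1) and `rvar` (per-record residual variance; default
#'   `sigma_e2[trait]`).
#' @param pedigree pedigree data.frame (see [pedigree_inbreeding()]).
#' @param sigma_g2 genetic variance (scalar) or trait covariance matrix.
#' @param sigma_e2 residual variance(s), one per trait.
#' @param mean_known optional known overall mean(s) per trait.
#' @param details return the coefficient matrix and right-hand side too?
#' @return list with `ebv` (plants x traits matrix, rownames = ids) and
#'   `beta`.
#' @export
estimate_ebv_blup <- function(records, pedigree, sigma_g2, sigma_e2,
                              mean_known = NULL, details = FALSE) {
  A <- relationship_matrix_pedigree(pedigree)
  ids <- as.integer(rownames(A))
  trait <- if (is.null(records$trait)) rep(1L, nrow(records)) else records$trait
  rvar <- if (is.null(records$rvar)) rep_len(sigma_e2, max(trait))[trait] else records$rvar
  plant <- match(records$id, ids)
  if (anyNA(plant)) stop("record id(s) not in pedigree: ",
                         paste(records$id[is.na(plant)], collapse = ", "))
  solve_mme(records$value, plant, trait, A, as.matrix(sigma_g2), rvar,
            mean_known = mean_known, details = details)
}

#' GBLUP breeding values
#'
#' As [estimate_ebv_blup()] but with the genomic relationship matrix
#' (VanRaden) over the joint set of reference and candidate plants in place
#' of A. A singular G is blended as `0.99 G + 0.01 I` (with a message)
#' before solving. GEBVs are returned for all plants in `dosage`, so
#' unphenotyped candidates get predictions through their marker
#' relationships.
#'
#' @param records data.frame with `id`, `value`, optional `trait`, `rvar`.
#' @param dosage marker dosage matrix with rownames = plant ids (reference
#'   and candidates).
#' @param p base-population allele frequencies for centering.
#' @param sigma_g2,sigma_e2,mean_known,details as in [estimate_ebv_blup()].
#' @param G optionally a precomputed relationship matrix (overrides
#'   `dosage`/`p`).
#' @return list with `ebv` and `beta`.
#' @export
estimate_ebv_gblup <- function(records, dosage = NULL, p = NULL,
                               sigma_g2 = 1, sigma_e2 = 1,
                               mean_known = NULL, details = FALSE,
                               G = NULL) {
  if (is.null(G)) {
    if (is.null(dosage)) stop("either dosage or G must be supplied")
    G <- genomic_relationship(dosage, p)
    rownames(G) <- colnames(G) <- rownames(dosage)
  }
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  trait <- if (is.null(records$trait)) rep(1L, nrow(records)) else records$trait
  rvar <- if (is.null(records$rvar)) rep_len(sigma_e2, max(trait))[trait] else records$rvar
  plant <- match(as.character(records$id), ids)
  if (anyNA(plant)) stop("record id(s) without genotypes: ",
                         paste(records$id[is.na(plant)], collapse = ", "))
  solve_mme(records$value, plant, trait, G, as.matrix(sigma_g2), rvar,
            mean_known = mean_known, details = details)
}

## ---------------------------------------------------------------------------
## Optimum-contribution selection
## ---------------------------------------------------------------------------

#' Optimum-contribution selection
#'
#' Maximizes `U(c) = c'a - (omega/L^2) (c + Pv)' A (c + Pv)` over genetic
#' contributions `c >= 0`, `1'c = 1` (a single hermaphroditic parent pool).
#' The penalty constrains the average relationship of the selected parents,
#' trading genetic merit against inbreeding. Solved by projected-gradient
#' ascent on the simplex from a uniform start (deterministic); with
#' `omega = 0` the objective is linear and all contribution concentrates on
#' the highest-EBV candidate. Contributions are converted to integer mating
#' counts by largest-remainder apportionment.
#'
#' @param ebv vector of estimated breeding values (`a`).
#' @param A relationship matrix (pedigree or genomic) of the candidates.
#' @param omega penalty weight on the average relationship (>= 0).
#' @param L generation interval (default 1, making the penalty weight
#'   effectively `omega`).
#' @param n_matings total matings to apportion (default 0 = skip).
#' @param P,v optional contributions of existing age classes: `P` an
#'   n x k matrix, `v` a k vector; the penalty then applies to `c + P v`.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter iteration cap.
#' @return list with `contributions`, `matings`, `objective`, `penalty`
#'   (the realized `(c+Pv)'A(c+Pv)`).
#' @export
ocs_select <- function(ebv, A, omega, L = 1, n_matings = 0, P = NULL,
                       v = NULL, tol = 1e-8, max_iter = 50000) {
  n <- length(ebv)
  if (n < 2) stop("need at least 2 candidates")
  if (omega < 0) stop("omega must be >= 0")
  A <- as.matrix(A)
  pv <- if (!is.null(P) && !is.null(v)) as.vector(P %*% v) else numeric(n)

  if (omega == 0) {
    c_opt <- numeric(n)
    c_opt[order(-ebv, seq_len(n))[1]] <- 1
  } else {
    w <- omega / L^2
    lip <- 2 * w * max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
    step <- 1 / max(lip, 1e-12)
    c_opt <- rep(1 / n, n)
    for (it in seq_len(max_iter)) {
      g <- ebv - 2 * w * as.vector(A %*% (c_opt + pv))
      c_new <- project_simplex(c_opt + step * g)
      if (max(abs(c_new - c_opt)) < tol) { c_opt <- c_new; break }
      c_opt <- c_new
    }
  }
  pen <- as.numeric(t(c_opt + pv) %*% A %*% (c_opt + pv))
  obj <- sum(c_opt * ebv) - (omega / L^2) * pen
  matings <- if (n_matings > 0) largest_remainder(c_opt, n_matings) else integer(n)
  list(contributions = c_opt, matings = matings, objective = obj,
       penalty = pen)
}

## Euclidean projection onto the probability simplex (sort-based)
project_simplex <- function(x) {
  u <- sort(x, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(x - theta, 0)
}

largest_remainder <- function(p, total) {
  raw <- p * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    o <- order(-(raw - base), seq_along(p))
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

## ---------------------------------------------------------------------------
## Selection accuracy
## ---------------------------------------------------------------------------

#' Selection accuracy
#'
#' Pearson correlation between the selection criterion and the true breeding
#' values at the level of the selection unit: per plant for population or
#' within-family selection, per family (sums of both) for entire-family or
#' line selection.
#'
#' @param criterion criterion values per candidate.
#' @param tbv true breeding values per candidate.
#' @param unit selection unit.
#' @param family family tags (required for `entire_family`).
#' @return correlation, or NA (with a message) when either side has zero
#'   variance or fewer than 3 units are available.
#' @export
selection_accuracy <- function(criterion, tbv,
                               unit = c("population", "within_family",
                                        "entire_family"),
                               family = NULL) {
  unit <- match.arg(unit)
  if (unit == "entire_family") {
    if (is.null(family)) stop("family tags required")
    criterion <- rowsum(criterion, family)[, 1]
    tbv <- rowsum(tbv, family)[, 1]
  }
  if (length(criterion) < 3) { message("accuracy undefined: fewer than 3 units"); return(NA_real_) }
  if (sd(criterion) == 0 || sd(tbv) == 0) {
    message("accuracy undefined: zero variance")
    return(NA_real_)
  }
  cor(criterion, tbv)
}
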