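# Shared fixtures and independent oracles, all built in code.

# small single-chromosome map
tiny_map <- function(n_loci = 20, len = 1, qtl_every = 5, n_ibd = 4)
  build_genome_map(1, len, n_loci, qtl_every_n = qtl_every, n_ibd = n_ibd)

# a hand-made founder pool from explicit haplotypes
pool_from_haps <- function(hap) {
  storage.mode(hap) <- "integer"
  structure(list(hap = hap, n_haplotypes = nrow(hap), n_loci = ncol(hap),
                 provenance = "simulated"),
            class = "FounderPool")
}

# quick polymorphic pool via a short founder phase
quick_pool <- function(map, seed = 1, n = 20, ng = 40, mu = 0.01) {
  set.seed(seed)
  eff <- rep(0, length(map$qtl_cols))
  simulate_founder_population(founder_config(n, n, ng, mu,
                                             culling_fraction = 0),
                              map, eff)
}

# independent kinship oracle: recursive coefficient of coancestry
# f(i, j) = 0.5 (f(i, s_j) + f(i, d_j)) with f(i, i) = 0.5 (1 + F_i);
# the numerator relationship is a_ij = 2 f(i, j). Memoized top-down —
# a different algorithm from the package's iterative tabular construction.
kinship_oracle <- function(ped) {
  s <- setNames(ped$sire, ped$id); d <- setNames(ped$dam, ped$id)
  dh <- setNames(if (is.null(ped$dh)) rep(FALSE, nrow(ped)) else ped$dh, ped$id)
  f0 <- setNames(if (is.null(ped$f0)) rep(0, nrow(ped)) else ped$f0, ped$id)
  memo <- new.env()
  f <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (j > i) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == j) {
      ii <- as.character(i)
      if (dh[[ii]]) 1
      else if (s[[ii]] == 0 && d[[ii]] == 0) 0.5 * (1 + f0[[ii]])
      else 0.5 * (1 + f(s[[ii]], d[[ii]]))
    } else {
      jj <- as.character(i)  # i is the younger (larger id)
      0.5 * (f(s[[jj]], j) + f(d[[jj]], j))
    }
    memo[[key]] <- v
    v
  }
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i))
    A[i, j] <- A[j, i] <- 2 * f(ped$id[i], ped$id[j])
  A
}

# generalized-least-squares BLUP oracle (dense V inversion)
gls_blup_oracle <- function(y, Zidx, A, sigma_g2, sigma_e2,
                            mean_known = NULL) {
  n <- nrow(A); N <- length(y)
  Z <- matrix(0, N, n); Z[cbind(seq_len(N), Zidx)] <- 1
  V <- sigma_g2 * Z %*% A %*% t(Z) + diag(sigma_e2, N)
  Vi <- solve(V)
  if (is.null(mean_known)) {
    X <- matrix(1, N, 1)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)[1, 1]
  } else b <- mean_known
  u <- sigma_g2 * A %*% t(Z) %*% Vi %*% (y - b)
  list(u = as.vector(u), beta = b)
}

# small random pedigree: base plants then random matings, ids ordered
random_pedigree <- function(n_base, n_off, seed) {
  set.seed(seed)
  ped <- data.frame(id = seq_len(n_base), sire = 0L, dam = 0L)
  for (k in seq_len(n_off)) {
    id <- n_base + k
    par <- sample(ped$id, 2, replace = TRUE)  # selfing allowed
    ped <- rbind(ped, data.frame(id = id, sire = par[1], dam = par[2]))
  }
  ped
}

# fast, small breeding plan for engine tests (structure only)
tiny_plan <- function(strategy, horizon = 10, burn_in = min(10, horizon), ...) {
  wheat_plan(strategy, scale = 5, horizon = horizon, burn_in = burn_in,
             founder = founder_config(20, 20, 30, 0.005),
             genome = list(n_chrom = 1L, lengths = 1, n_loci = 200L,
                           qtl_every_n = 10L, n_ibd = 10L),
             n_std = 100, ...)
}
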