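test_that("truncation selection at all three units, with id tie-breaks", {
  # population: identity when n = all
  expect_equal(truncation_select(c(3, 1, 2), 3, "population"), 1:3)
  expect_equal(truncation_select(c(3, 1, 2), 1, "population"), 1)

  # within family: 50 families x 10 candidates, 5 kept each
  set.seed(1)
  fam <- rep(1:50, each = 10)
  crit <- rnorm(500)
  sel <- truncation_select(crit, 5, "within_family", family = fam)
  expect_length(sel, 250)
  expect_true(all(table(fam[sel]) == 5))
  # the kept ones beat the dropped ones within every family
  for (f in c(3, 27)) {
    inf <- which(fam == f)
    expect_equal(min(crit[intersect(inf, sel)]),
                 sort(crit[inf], decreasing = TRUE)[5])
  }

  # entire family: argmax family by summed criterion
  fam <- rep(1:3, each = 2)
  crit <- c(1, 1, 5, -1, 2, 2.5)   # sums 2, 4, 4.5
  expect_equal(truncation_select(crit, 1, "entire_family", family = fam),
               5:6)
  expect_equal(truncation_select(crit, 2, "entire_family", family = fam),
               3:6)

  # ties broken by ascending id
  expect_equal(truncation_select(c(1, 1, 1), 2, "population",
                                 ids = c(30, 10, 20)), c(10, 20))

  expect_error(truncation_select(c(1, NA), 2, "population"), "missing")
  expect_error(truncation_select(1:3, 4, "population"), "exceeds")
})

test_that("threshold selection returns the exact exceeding subset", {
  y <- c(-1, 0.5, 2, 3)
  expect_equal(threshold_select(y, -Inf), 1:4)
  expect_equal(threshold_select(y, 1), 3:4)
  expect_warning(none <- threshold_select(y, 10), "no candidates")
  expect_length(none, 0)
})

test_that("pedigree BLUP solves the mixed-model equations", {
  # single phenotyped plant with known mean: EBV = h2 * y
  ped <- data.frame(id = 1, sire = 0L, dam = 0L)
  rec <- data.frame(id = 1, value = 4)
  fit <- estimate_ebv_blup(rec, ped, sigma_g2 = 1, sigma_e2 = 1,
                           mean_known = 0)
  expect_equal(unname(fit$ebv[1, 1]), 2)

  # shrinkage limit: EBVs -> 0 as sigma_g2 -> 0
  fit0 <- estimate_ebv_blup(rec, ped, sigma_g2 = 1e-10, sigma_e2 = 1,
                            mean_known = 0)
  expect_lt(abs(fit0$ebv[1, 1]), 1e-8)

  # matches a dense GLS oracle on a random 8-plant pedigree, including
  # unphenotyped members and repeated records
  ped <- random_pedigree(3, 5, seed = 2)
  set.seed(3)
  ids <- c(4, 5, 6, 6, 8)          # plant 6 has two records
  y <- rnorm(5, mean = 10)
  rec <- data.frame(id = ids, value = y)
  fit <- estimate_ebv_blup(rec, ped, sigma_g2 = 2, sigma_e2 = 3,
                           details = TRUE)
  A <- relationship_matrix_pedigree(ped)
  oracle <- gls_blup_oracle(y, match(ids, ped$id), A, 2, 3)
  expect_equal(unname(fit$ebv[, 1]), oracle$u, tolerance = 1e-8)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-8)

  # the returned solution satisfies the MME by substitution
  expect_lt(max(abs(fit$C %*% fit$sol - fit$rhs)), 1e-8)

  expect_error(estimate_ebv_blup(data.frame(id = 99, value = 1), ped, 1, 1),
               "not in pedigree")
})

test_that("GBLUP equals pedigree BLUP when G := A, and handles clones", {
  ped <- random_pedigree(3, 5, seed = 4)
  set.seed(5)
  rec <- data.frame(id = c(4, 6, 7, 8), value = rnorm(4, 5))
  A <- relationship_matrix_pedigree(ped)
  fb <- estimate_ebv_blup(rec, ped, sigma_g2 = 1.5, sigma_e2 = 2)
  fg <- estimate_ebv_gblup(rec, G = A, sigma_g2 = 1.5, sigma_e2 = 2)
  expect_equal(fg$ebv, fb$ebv, tolerance = 1e-10)

  # candidate that is a genotype clone of a reference plant gets (nearly)
  # the same GEBV; the identical rows make G singular, which triggers the
  # documented 0.99 G + 0.01 I blend
  set.seed(6)
  p <- runif(80, 0.2, 0.8)
  M <- sapply(p, function(pp) rbinom(10, 2, pp))
  M <- rbind(M, M[1, ])            # plant 11 clones plant 1
  rownames(M) <- 1:11
  rec <- data.frame(id = 1:10, value = rnorm(10))
  fit <- suppressMessages(
    estimate_ebv_gblup(rec, dosage = M, p = p, sigma_g2 = 1, sigma_e2 = 1))
  expect_equal(unname(fit$ebv[11, 1]), unname(fit$ebv[1, 1]),
               tolerance = 0.05)

  # multi-trait solve agrees with two independent single-trait solves when
  # traits are uncorrelated
  set.seed(7)
  rec2 <- data.frame(id = rep(1:10, 2), value = rnorm(20),
                     trait = rep(1:2, each = 10))
  G <- genomic_relationship(M[1:10, ], p)
  rownames(G) <- colnames(G) <- 1:10
  fmt <- estimate_ebv_gblup(rec2, G = G, sigma_g2 = diag(c(1, 2)),
                            sigma_e2 = c(1, 3))
  f1 <- estimate_ebv_gblup(rec2[1:10, ], G = G, sigma_g2 = 1, sigma_e2 = 1)
  f2 <- estimate_ebv_gblup(rec2[11:20, -3], G = G, sigma_g2 = 2,
                           sigma_e2 = 3)
  expect_equal(fmt$ebv[, 1], f1$ebv[, 1], tolerance = 1e-8)
  expect_equal(fmt$ebv[, 2], f2$ebv[, 1], tolerance = 1e-8)
})

test_that("GBLUP accuracy grows with the reference and beats phenotypes", {
  map <- tiny_map(n_loci = 100, qtl_every = 5, n_ibd = 0)
  pool <- quick_pool(map, seed = 8, n = 25, ng = 40, mu = 0.01)
  sizes <- c(20, 60, 140)
  acc <- matrix(NA_real_, 25, length(sizes))
  acc_phen <- numeric(25)
  h2 <- 0.3
  for (r in 1:25) {
    set.seed(100 + r)
    eff <- sample_qtl_effects(length(map$qtl_cols))
    all <- sample_base_population(pool, map, max(sizes) + 40,
                                  inbred = FALSE)
    X <- cohort_dosage(all, map)
    eff <- standardize_effects(eff, X, 1)
    g <- as.vector(X %*% eff)
    y <- realize_phenotype(g, (1 - h2) / h2)
    p <- colMeans(cohort_dosage(all, map, map$marker_cols)) / 2
    cand <- seq_len(40) + max(sizes)
    M <- cohort_dosage(all, map, map$marker_cols)
    rownames(M) <- seq_len(nrow(M))
    for (k in seq_along(sizes)) {
      idx <- c(seq_len(sizes[k]), cand)
      fit <- suppressMessages(estimate_ebv_gblup(
        data.frame(id = seq_len(sizes[k]), value = y[seq_len(sizes[k])]),
        dosage = M[idx, ], p = p, sigma_g2 = 1, sigma_e2 = (1 - h2) / h2))
      acc[r, k] <- cor(fit$ebv[as.character(cand), 1], g[cand])
    }
    acc_phen[r] <- cor(y[cand], g[cand])
  }
  m <- colMeans(acc)
  expect_true(all(diff(m) > 0))          # monotone in reference size
  expect_gte(m[3], mean(acc_phen))       # beats own-phenotype selection
})

test_that("optimum contributions trade merit against relationship", {
  set.seed(9)
  ebv <- c(0.1, 0.9, 0.4, 0.7)
  A <- diag(4)

  # omega = 0: all contribution on the top candidate
  r0 <- ocs_select(ebv, A, omega = 0, n_matings = 10)
  expect_equal(r0$contributions, c(0, 1, 0, 0))
  expect_equal(r0$matings, c(0L, 10L, 0L, 0L))

  # omega -> infinity with A = I: uniform contributions
  rI <- ocs_select(ebv, A, omega = 1e6)
  expect_equal(rI$contributions, rep(0.25, 4), tolerance = 1e-3)

  # the relationship penalty never increases with omega
  set.seed(10)
  B <- matrix(rnorm(100), 10)
  A10 <- tcrossprod(B) / 10 + diag(10)
  e10 <- rnorm(10)
  pen <- vapply(c(0.1, 0.3, 1, 3, 10, 30), function(w)
    ocs_select(e10, A10, omega = w)$penalty, numeric(1))
  expect_true(all(diff(pen) <= 1e-6))

  # matches a brute-force simplex-grid oracle at n = 3
  e3 <- c(0.5, 0.2, -0.1)
  A3 <- matrix(c(1, 0.5, 0.2, 0.5, 1.2, 0.1, 0.2, 0.1, 0.9), 3)
  w <- 0.8
  grid <- expand.grid(c1 = seq(0, 1, 0.01), c2 = seq(0, 1, 0.01))
  grid <- grid[grid$c1 + grid$c2 <= 1, ]
  obj <- apply(grid, 1, function(r) {
    cc <- c(r[1], r[2], 1 - r[1] - r[2])
    sum(cc * e3) - w * as.numeric(t(cc) %*% A3 %*% cc)
  })
  best <- max(obj)
  fit <- ocs_select(e3, A3, omega = w)
  expect_gte(fit$objective, best - 1e-3)

  # largest-remainder apportionment conserves the mating total
  r <- ocs_select(e10, A10, omega = 1, n_matings = 17)
  expect_equal(sum(r$matings), 17L)
  expect_error(ocs_select(e3, A3, omega = -1), "omega")
})

test_that("selection accuracy is the unit-level criterion-TBV correlation", {
  g <- rnorm(100)
  expect_equal(selection_accuracy(g, g), 1)
  set.seed(11)
  expect_equal(selection_accuracy(rnorm(5000), rnorm(5000)), 0,
               tolerance = 0.05)
  # phenotype criterion at h2 = 0.25 has accuracy ~ h = 0.5
  set.seed(12)
  g <- rnorm(2e4)
  y <- realize_phenotype(g, 3)
  expect_equal(selection_accuracy(y, g), 0.5, tolerance = 0.02)
  # family-sum level
  fam <- rep(1:10, each = 3)
  gt <- rnorm(30)
  expect_equal(selection_accuracy(gt, gt, unit = "entire_family",
                                  family = fam), 1)
  expect_true(is.na(suppressMessages(
    selection_accuracy(rep(1, 10), rnorm(10)))))
})
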