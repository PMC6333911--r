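test_that("base sampling draws haplotype pairs; inbreds are doubled", {
  map <- tiny_map(n_loci = 30, qtl_every = 5, n_ibd = 3)
  pool <- quick_pool(map, seed = 1, n = 15, ng = 30, mu = 0.01)

  set.seed(2)
  base <- sample_base_population(pool, map, 200, inbred = TRUE)
  expect_true(all(base$hap1 == base$hap2))

  # a 2-haplotype pool forces the (unordered) pair
  p2 <- pool_from_haps(rbind(rep(0L, 30), rep(1L, 30)))
  b2 <- sample_base_population(p2, map, 1, inbred = FALSE)
  expect_setequal(c(b2$hap1[1, 1], b2$hap2[1, 1]), c(0L, 1L))

  # cohort allele frequencies track pool frequencies
  set.seed(3)
  big <- sample_base_population(pool, map, 2000, inbred = FALSE)
  expect_equal(colMeans(big$hap1 + big$hap2) / 2, colMeans(pool$hap),
               tolerance = 0.03)
})

test_that("IBD tracer labels are unique and measure realized inbreeding", {
  map <- tiny_map(n_loci = 40, qtl_every = 5, n_ibd = 10)
  pool <- quick_pool(map, seed = 4, n = 15, ng = 30, mu = 0.01)
  eff <- matrix(rep(0, 8), ncol = 1)

  set.seed(5)
  base <- sample_base_population(pool, map, 3, inbred = FALSE)
  base <- assign_ibd_alleles(base, map)
  expect_setequal(c(base$ibd1[, 1], base$ibd2[, 1]), 1:6)  # 6 labels live
  expect_equal(ibd_inbreeding(base), rep(0, 3))

  inb <- sample_base_population(pool, map, 2, inbred = TRUE)
  inb <- assign_ibd_alleles(inb, map, label_start = 7)
  expect_equal(ibd_inbreeding(inb), c(1, 1))

  # descendant alleles trace back to base labels
  f1 <- cross_offspring(base, data.frame(sire = base$id[1], dam = base$id[2]),
                        map, eff, n_seeds = 50)
  expect_true(all(f1$ibd1 %in% base$ibd1[1, ] | f1$ibd1 %in% base$ibd2[1, ]))
  expect_true(all(f1$ibd2 %in% c(base$ibd1[2, ], base$ibd2[2, ])))

  # one selfing of a non-inbred plant: expected autozygosity 1/2
  set.seed(6)
  s1 <- self_progeny(base, rows = 1, n_seeds = 10000, map = map,
                     effects = eff)
  expect_equal(mean(ibd_inbreeding(s1)), 0.5, tolerance = 0.02)

  # a DH is fully autozygous by construction
  dh <- make_doubled_haploid(base, rows = 1, map = map, effects = eff)
  expect_equal(ibd_inbreeding(dh), 1)
})

test_that("pedigree inbreeding follows Wright's coefficients", {
  # base plants: F = 0 (or declared founder inbreeding)
  ped <- data.frame(id = 1:2, sire = 0L, dam = 0L)
  expect_equal(unname(pedigree_inbreeding(ped)), c(0, 0))
  pedi <- data.frame(id = 1, sire = 0L, dam = 0L, f0 = 1)
  expect_equal(unname(pedigree_inbreeding(pedi)), 1)

  # one selfing: F = 1/2; full sibs mated: F = 1/4
  ped <- data.frame(id = 1:2, sire = c(0L, 1L), dam = c(0L, 1L))
  expect_equal(unname(pedigree_inbreeding(ped))[2], 0.5)
  ped <- data.frame(id = 1:5, sire = c(0L, 0L, 1L, 1L, 3L),
                    dam = c(0L, 0L, 2L, 2L, 4L))
  expect_equal(unname(pedigree_inbreeding(ped))[5], 0.25)

  # selfing chain: F_t = 1 - (1/2)^t for t <= 7 (single-seed descent)
  t <- 7
  ped <- data.frame(id = 1:(t + 1), sire = c(0L, 1:t), dam = c(0L, 1:t))
  expect_equal(unname(pedigree_inbreeding(ped)), 1 - 0.5^(0:t))

  # DH origin forces F = 1
  ped <- data.frame(id = 1:2, sire = c(0L, 1L), dam = c(0L, 1L),
                    dh = c(FALSE, TRUE))
  expect_equal(unname(pedigree_inbreeding(ped))[2], 1)

  # unordered pedigrees are rejected
  bad <- data.frame(id = 1:2, sire = c(2L, 0L), dam = c(0L, 0L))
  expect_error(pedigree_inbreeding(bad), "precede")
})

test_that("A matrix matches the independent kinship oracle", {
  ped <- data.frame(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
  A <- relationship_matrix_pedigree(ped)
  expect_equal(A[1, 2], 0)      # unrelated non-inbred pair
  expect_equal(A[1, 3], 0.5)    # parent-offspring
  expect_equal(diag(A), c(1, 1, 1), ignore_attr = TRUE)

  for (seed in 1:4) {
    ped <- random_pedigree(4, 6, seed)
    A <- relationship_matrix_pedigree(ped)
    expect_equal(A, kinship_oracle(ped), tolerance = 1e-12)
    expect_true(isSymmetric(A))
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }

  # subsetting and unknown ids
  ped <- random_pedigree(3, 4, 9)
  A <- relationship_matrix_pedigree(ped, ids = c(7, 2))
  expect_equal(dim(A), c(2, 2))
  expect_error(relationship_matrix_pedigree(ped, ids = 99), "unknown")
})

test_that("VanRaden G behaves on clones, HWE cohorts and edge cases", {
  set.seed(7)
  p <- runif(200, 0.1, 0.9)
  X <- sapply(p, function(pp) rbinom(500, 2, pp))
  G <- genomic_relationship(X, p)
  expect_true(isSymmetric(G))
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)

  # clones share their relationship row
  Xc <- rbind(X[1, ], X[1, ], X[2, ])
  Gc <- genomic_relationship(Xc, p)
  expect_equal(Gc[1, 2], Gc[1, 1])
  expect_equal(Gc[1, 3], Gc[2, 3])

  expect_error(genomic_relationship(matrix(2, 5, 4)), "monomorphic")
})

test_that("IBD inbreeding tracks pedigree F under random mating", {
  map <- tiny_map(n_loci = 60, qtl_every = 10, n_ibd = 25)
  pool <- quick_pool(map, seed = 8, n = 15, ng = 30, mu = 0.01)
  eff <- matrix(rep(0, 6), ncol = 1)
  set.seed(9)
  base <- sample_base_population(pool, map, 8, inbred = FALSE)
  base <- assign_ibd_alleles(base, map)
  ped <- data.frame(id = base$id, sire = 0L, dam = 0L)
  coh <- base
  for (gen in 1:4) {
    sires <- sample(coh$id, 60, replace = TRUE)
    dams <- sample(coh$id, 60, replace = TRUE)
    off <- cross_offspring(coh, data.frame(sire = sires, dam = dams), map,
                           eff, n_seeds = 1, id_start = max(ped$id) + 1L)
    ped <- rbind(ped, data.frame(id = off$id, sire = off$sire,
                                 dam = off$dam))
    coh <- off
  }
  f_ped <- pedigree_inbreeding(ped)[as.character(coh$id)]
  expect_equal(mean(ibd_inbreeding(coh)), mean(f_ped), tolerance = 0.06)
})

test_that("germplasm store keeps immutable snapshots", {
  map <- tiny_map(n_loci = 20, qtl_every = 5, n_ibd = 2)
  pool <- quick_pool(map, seed = 10, n = 10, ng = 20, mu = 0.01)
  set.seed(11)
  coh <- sample_base_population(pool, map, 5, inbred = TRUE)
  coh <- assign_ibd_alleles(coh, map)

  store <- germplasm_store()
  store_germplasm(store, coh, idx = c(2, 4), cycle = 1, gen = 5,
                  time_step = 3, criterion = c(1.2, -0.5))
  e <- fetch_germplasm(store, 1, 5)
  expect_equal(e$cohort$hap1, coh$hap1[c(2, 4), ])
  expect_equal(e$cohort$id, coh$id[c(2, 4)])
  expect_equal(e$criterion, c(1.2, -0.5))
  expect_equal(e$time_step, 3)

  # mutating the source cohort afterwards does not touch the snapshot
  coh$hap1[2, 1] <- 1L - coh$hap1[2, 1]
  expect_false(identical(fetch_germplasm(store, 1, 5)$cohort$hap1[1, 1],
                         coh$hap1[2, 1]))

  expect_error(fetch_germplasm(store, 9, 9), "no germplasm")
})
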