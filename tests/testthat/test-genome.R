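test_that("genome map lays out loci, QTL designation and IBD tracers", {
  map <- build_genome_map(1, 1, 100, qtl_every_n = 10, n_ibd = 5)
  expect_equal(map$qtl_cols, seq(10, 100, by = 10))
  expect_length(map$marker_cols, 90)
  expect_true(all(diff(map$pos) > 0))
  expect_true(all(map$pos > 0 & map$pos < 1))
  expect_equal(map$ibd_pos, (1:5 - 0.5) / 5)

  # single locus sits at the chromosome midpoint
  m1 <- build_genome_map(1, 2, 1, qtl_every_n = 1)
  expect_equal(m1$pos, 1)
  expect_equal(m1$loci$role, "QTL")

  # explicit QTL index list mirrors a random designation: 1039 of 9582
  set.seed(1)
  qidx <- sort(sample.int(9582, 1039))
  m2 <- build_genome_map(21, 1.5, 9582, qtl_index = qidx)
  expect_length(m2$qtl_cols, 1039)
  expect_length(m2$marker_cols, 8543)

  # multi-chromosome remainder rule and per-chromosome indexing
  m3 <- build_genome_map(3, 1, 10, qtl_every_n = 2)
  expect_equal(as.vector(table(m3$chrom)), c(4, 3, 3))
  within <- unlist(lapply(split(seq_len(10), m3$chrom), seq_along),
                   use.names = FALSE)
  expect_equal(which(within %% 2 == 0), m3$qtl_cols)

  expect_error(build_genome_map(0, 1, 10, 2), "invalid")
  expect_error(build_genome_map(1, 1, 10, 0), "invalid")
  expect_error(build_genome_map(1, -1, 10, 2), "invalid")
})

test_that("gametes obey Mendelian and Poisson-crossover laws", {
  map <- tiny_map(n_loci = 500, len = 1, qtl_every = 10, n_ibd = 0)

  # fully homozygous parent transmits its haplotype exactly
  set.seed(2)
  h <- as.integer(runif(500) < 0.5)
  for (i in 1:5) expect_equal(sample_gamete(h, h, map)$alleles, h)

  # heterozygous-everywhere parent: allele sequence reveals crossovers
  h0 <- rep(0L, 500); h1 <- rep(1L, 500)
  set.seed(3)
  n_gam <- 10000
  g <- breedsim:::meiosis(list(hap1 = matrix(h0, 1, 500, byrow = TRUE),
                               hap2 = matrix(h1, 1, 500, byrow = TRUE)),
                          rep(1L, n_gam), map)$hap
  # every transmitted allele is one of the parent's two
  expect_true(all(g %in% 0:1))
  # mean observed crossovers per gamete ~ chromosome length (1 Morgan)
  switches <- rowSums(g[, -1] != g[, -500])
  expect_equal(mean(switches), 1, tolerance = 0.05)
  # Poisson goodness of fit at alpha = 0.01
  obs <- tabulate(pmin(switches, 5) + 1, nbins = 6)
  pr <- dpois(0:4, 1); pr <- c(pr, 1 - sum(pr))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr)$p.value), 0.01)
  # 50/50 transmission at a single heterozygous locus
  expect_equal(mean(g[, 250]), 0.5, tolerance = 0.02)
})

test_that("founder phase culls, mutates and drifts as configured", {
  map <- tiny_map(n_loci = 50, qtl_every = 5, n_ibd = 0)
  eff <- rep(1, 10)

  # 5% culling of 100 offspring = exactly 5 per generation
  set.seed(4)
  cfg <- founder_config(50, 50, 10, 0.01, culling_fraction = 0.05)
  pool <- simulate_founder_population(cfg, map, eff)
  expect_equal(pool$n_culled, rep(5L, 10))
  expect_equal(pool$n_haplotypes, 200)
  expect_true(pool$n_haplotypes %% 2 == 0)

  # zero mutation from a monomorphic start stays monomorphic (with warning)
  set.seed(5)
  cfg0 <- founder_config(10, 10, 5, 0)
  expect_warning(p0 <- simulate_founder_population(cfg0, map, eff),
                 "monomorphic")
  expect_true(all(p0$hap == 0L))

  # invalid configurations are rejected
  expect_error(founder_config(0, 5, 10, 0.01), "parents")
  expect_error(founder_config(5, 5, 10, 1), "mutation_rate")
  expect_error(founder_config(5, 5, 3, 0.01, size_schedule = rep(10, 5)),
               "size_schedule")

  # size_schedule drives per-generation offspring counts
  set.seed(6)
  cfgS <- founder_config(5, 5, 3, 0.01, culling_fraction = 0,
                         size_schedule = c(10, 30, 20))
  pS <- simulate_founder_population(cfgS, map, eff)
  expect_equal(pS$n_haplotypes, 40)
})

test_that("neutral founder drift matches Wright-Fisher expectations", {
  map <- tiny_map(n_loci = 100, qtl_every = 10, n_ibd = 0)
  eff <- rep(0, 10)
  init <- quick_pool(map, seed = 7, n = 20, ng = 40, mu = 0.01)
  het <- function(pool) {
    p <- colMeans(pool$hap)
    mean(2 * p * (1 - p))
  }
  h0 <- het(init)
  expect_gt(h0, 0.05)

  # continue without mutation/culling: 10+10 parents, so Ne = 20 and
  # heterozygosity decays by (1 - 1/(2Ne)) per generation; allele
  # frequencies are a martingale
  set.seed(8)
  cfg <- founder_config(10, 10, 5, 0, culling_fraction = 0)
  ratios <- numeric(150); dfreq <- numeric(150)
  for (r in 1:150) {
    pe <- suppressWarnings(simulate_founder_population(cfg, map, eff,
                                                       init = init))
    ratios[r] <- het(pe) / h0
    dfreq[r] <- mean(colMeans(pe$hap)) - mean(colMeans(init$hap))
  }
  expect_equal(mean(ratios), (1 - 1 / 40)^5, tolerance = 0.03)
  expect_equal(mean(dfreq), 0, tolerance = 0.01)
})

test_that("phased-genotype export and import round-trip", {
  map <- tiny_map(n_loci = 12, qtl_every = 3, n_ibd = 2)
  set.seed(9)
  h1 <- matrix(as.integer(runif(24) < 0.5), 2, 12)
  h2 <- matrix(as.integer(runif(24) < 0.5), 2, 12)
  mf <- tempfile(fileext = ".tsv"); gf <- tempfile(fileext = ".tsv")
  export_phased_genomes(h1, h2, map, mf, gf)

  imp <- import_phased_genomes(mf, gf)
  expect_equal(imp$pool$n_haplotypes, 4)  # 2 individuals -> 4 haplotypes
  expect_equal(imp$pool$hap[c(1, 3), ], unname(h1))
  expect_equal(imp$pool$hap[c(2, 4), ], unname(h2))
  expect_equal(imp$map$n_loci, 12)
  expect_equal(imp$map$qtl_cols, map$qtl_cols)
  expect_equal(imp$map$n_ibd_total, 2)
  expect_equal(imp$map$pos, map$pos)

  # allele code outside {0,1} is a parse error naming the file
  g <- read.table(gf, header = TRUE, sep = "\t", check.names = FALSE)
  g[2, 5] <- 2L
  gf2 <- tempfile(fileext = ".tsv")
  write.table(g, gf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(import_phased_genomes(mf, gf2), "allele codes")

  # unsorted positions are a parse error
  m <- read.table(mf, header = TRUE, sep = "\t")
  m[1:2, "position_morgans"] <- m[2:1, "position_morgans"]
  mf2 <- tempfile(fileext = ".tsv")
  write.table(m, mf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(import_phased_genomes(mf2, gf), "increasing")
})

test_that("phased VCF import accepts bi-allelic phased records only", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t1000000\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t2000000\t.\tC\tT\t.\tPASS\t.\tGT\t0|0\t1|0"), vcf)
  imp <- import_phased_vcf(vcf)
  expect_equal(imp$pool$n_haplotypes, 4)
  expect_equal(imp$map$n_loci, 2)
  expect_equal(imp$pool$hap[, 1], c(0L, 1L, 1L, 1L))

  vcf2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t1000\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1"), vcf2)
  expect_error(import_phased_vcf(vcf2), "bi-allelic")
})
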