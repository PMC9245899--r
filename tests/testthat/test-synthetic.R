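test_that("founder simulation is reproducible and rejects bad input", {
  map <- small_map()
  f1 <- make_founders(10, 200, map, seed = 42)
  f2 <- make_founders(10, 200, map, seed = 42)
  expect_identical(f1$alleles, f2$alleles)
  expect_error(make_founders(3, 100, map), "even")
  expect_error(make_founders(10, 100, map, freq_beta_params = c(-1, 1)),
               "Beta")
})

test_that("Beta(1,1) founder frequencies are uniform on the truncated MAF range", {
  map <- uniform_map(100)
  f <- make_founders(4, 10000, map, freq_beta_params = c(1, 1), seed = 7)
  breaks <- seq(0.05, 0.95, length.out = 11)
  counts <- table(cut(f$freq, breaks, include.lowest = TRUE))
  chi <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(chi$p.value, 1e-4)
})

test_that("meiosis on a 0 cM chromosome transmits one whole parental haplotype", {
  map0 <- genetic_map(c("1", "1"), c(1, 1e6), c(0, 0))
  sites <- data.frame(chrom = "1", bp = seq(1e3, 9e5, length.out = 50),
                      cM = rep(0, 50))
  h1 <- rep(0L, 50); h2 <- rep(1L, 50)
  out <- meiosis(h1, h2, sites, map0, seed = 3)
  expect_equal(nrow(out$crossovers), 0L)
  expect_true(all(out$alleles == 0L) || all(out$alleles == 1L))
})

test_that("crossover counts are Poisson with mean = map length in Morgans", {
  map <- uniform_map(100)   # 1 Morgan
  sites <- data.frame(chrom = "1", bp = c(1, 2), cM = c(0, 0.01))
  h <- c(0L, 0L)
  set.seed(21)
  k <- replicate(4000, nrow(meiosis(h, h, sites, map)$crossovers))
  se <- sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - 1), 3 * se)
  expect_lt(abs(var(k) - 1), 4 * sqrt(2 / length(k)) + 0.15) # Poisson variance
})

test_that("identical parental haplotypes give an identical gamete", {
  map <- small_map()
  f <- small_founders()
  h <- f$alleles[1, ]
  out <- meiosis(h, h, f$sites, map, seed = 5)
  expect_identical(out$alleles, h)
})

test_that("population simulation is deterministic and smaller N means more ROH", {
  map <- small_map()
  f <- small_founders()   # 200 haplotypes: supports N <= 100 at 1 deme
  traj <- ne_trajectory(rep(40L, 13))
  a <- simulate_population(f, traj, map, seed = 9, n_sample = 8)
  b <- simulate_population(f, traj, map, seed = 9, n_sample = 8)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  big <- simulate_population(f, ne_trajectory(rep(100L, 13)), map,
                             seed = 9, n_sample = 8)
  froh_in <- function(pop) {
    mean(vapply(pop$genotypes$ids, function(id) {
      s <- true_segments(pop$truth, id, min_cM = 4)
      sum(s$length_cM[s$length_cM <= 20]) / 900
    }, numeric(1)))
  }
  expect_gt(froh_in(a), froh_in(big))
})

test_that("fully separated demes share no IBD after long isolation", {
  map <- uniform_map(rep(100, 3))
  f <- make_founders(120, 300, map, seed = 55)
  traj <- ne_trajectory(rep(30L, 16), n_demes = 2L, migration = 0)
  pop <- simulate_population(f, traj, map, seed = 56, n_sample = 5)
  ids1 <- pop$genotypes$ids[pop$genotypes$groups == "deme1"]
  ids2 <- pop$genotypes$ids[pop$genotypes$groups == "deme2"]
  for (i in ids1[1:3]) for (j in ids2[1:3])
    expect_equal(nrow(true_segments(pop$truth, i, j, min_cM = 2)), 0L)
})

test_that("true segments of a fully autozygous individual span each chromosome", {
  map <- small_map()
  axis <- insulaR:::.map_axis(map)
  m <- insulaR:::.founder_mosaic(1, axis)
  truth <- structure(list(haps = list(x = list(m, m)),
                          map = map, axis = axis,
                          sites = small_founders()$sites),
                     class = "ancestry_truth")
  s <- true_segments(truth, "x")
  expect_equal(nrow(s), 6L)
  expect_equal(sum(s$length_cM), 900)
  expect_equal(true_fraction(truth, "x"), 1)
  # unrelated founder haplotypes share nothing
  truth$haps$y <- list(insulaR:::.founder_mosaic(2, axis),
                       insulaR:::.founder_mosaic(3, axis))
  expect_equal(nrow(true_segments(truth, "y")), 0L)
  expect_error(true_segments(truth, "nope"), "unknown")
})

test_that("realised inbreeding matches analytic kinship for the classic pedigrees", {
  map <- human_map()
  f <- human_founders()
  scens <- scenario_pedigrees()
  labels <- vapply(scens, `[[`, character(1), "label")
  set.seed(31)
  for (lab in c("first_degree_sib", "second_degree_avuncular",
                "third_degree_first_cousins")) {
    sc <- scens[[which(labels == lab)]]
    fs <- replicate(150, true_fraction(drop_pedigree(sc, f, map), "FOCAL"))
    se <- sd(fs) / sqrt(length(fs))
    expect_lt(abs(mean(fs) - sc$expected_f), 3 * se)
  }
})

test_that("error injection flips alleles at the requested binomial rate", {
  map <- uniform_map(100)
  sites <- data.frame(chrom = "1", bp = 1:2000 * 100, cM = 1:2000 / 20)
  gm <- genotype_matrix(matrix(0L, 100, 2000), sites)
  expect_identical(add_errors(gm, 0, 0, seed = 1)$geno, gm$geno)
  pert <- add_errors(gm, miscall_rate = 0.005, seed = 2)
  n_alleles <- 2 * length(gm$geno)
  flipped <- sum(pert$geno)
  se <- sqrt(n_alleles * 0.005 * 0.995)
  expect_lt(abs(flipped - n_alleles * 0.005), 3 * se)
  allmiss <- add_errors(gm, 0, 1, seed = 3)
  expect_true(all(is.na(allmiss$geno)))
  expect_error(suppressMessages(filter_sites(allmiss)), "all sites")
  expect_error(add_errors(gm, 0.2, 0), "miscall_rate")
})
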