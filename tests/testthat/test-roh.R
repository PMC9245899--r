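roh_gm <- function(g, spacing_bp = 1e4, chrom = "1") {
  n <- length(g)
  sites <- data.frame(chrom = chrom, bp = seq_len(n) * spacing_bp,
                      cM = seq_len(n) * spacing_bp / 1e6)
  genotype_matrix(matrix(g, 1), sites, ids = "X")
}

test_that("an unbroken homozygous run is called as a single segment", {
  g <- rep(0L, 200)
  gm <- roh_gm(g, spacing_bp = 1e4)   # 2 Mb span
  segs <- call_roh(gm, "X")
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 200L)
  expect_equal(segs$start_bp, 1e4)
  expect_equal(segs$end_bp, 2e6)
})

test_that("regular heterozygotes veto every window", {
  g <- rep(0L, 300)
  g[seq(5, 300, by = 10)] <- 1L
  segs <- call_roh(roh_gm(g), "X")
  expect_equal(nrow(segs), 0L)
})

test_that("all-missing individual yields an empty call with a warning", {
  gm <- roh_gm(rep(NA_integer_, 100))
  expect_warning(segs <- call_roh(gm, "X"), "all-missing")
  expect_equal(nrow(segs), 0L)
})

test_that("caller matches the brute-force window semantics on random instances", {
  set.seed(71)
  for (rep in seq_len(80)) {
    n <- sample(60:300, 1)
    het_rate <- runif(1, 0, 0.25)
    mis_rate <- runif(1, 0, 0.1)
    g <- ifelse(runif(n) < het_rate, 1L, sample(c(0L, 2L), n, TRUE))
    g[runif(n) < mis_rate] <- NA_integer_
    gaps <- ifelse(runif(n) < 0.02, 8e6, sample(500:20000, n, TRUE))
    bp <- cumsum(gaps)
    p <- roh_params(window_snps = sample(c(10L, 20L, 50L), 1),
                    window_het_max = sample(0:2, 1),
                    window_missing_max = sample(0:5, 1),
                    min_snps = sample(c(10L, 25L, 50L), 1),
                    min_length_kb = sample(c(1, 100), 1),
                    max_inter_snp_gap_kb = 5000,
                    min_density_kb_per_snp = sample(c(50, 5000), 1),
                    window_hit_fraction = runif(1, 0.02, 0.2))
    sites <- data.frame(chrom = "1", bp = bp, cM = bp / 1e6)
    gm <- genotype_matrix(matrix(g, 1), sites, ids = "X")
    got <- call_roh(gm, "X", p)
    want <- brute_roh(g, bp, p)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_bp, bp[want$a])
      expect_equal(got$end_bp, bp[want$b])
      expect_equal(got$n_snps, want$b - want$a + 1L)
    }
  }
})

test_that("relaxing window or size thresholds never shrinks total called ROH", {
  set.seed(72)
  for (rep in seq_len(20)) {
    n <- 400
    g <- ifelse(runif(n) < 0.06, 1L, sample(c(0L, 2L), n, TRUE))
    bp <- cumsum(sample(500:20000, n, TRUE))
    gm <- genotype_matrix(matrix(g, 1),
                          data.frame(chrom = "1", bp = bp, cM = bp / 1e6),
                          ids = "X")
    strict <- call_roh(gm, "X", roh_params(min_snps = 50))
    loose_het <- call_roh(gm, "X", roh_params(min_snps = 50, window_het_max = 1))
    loose_snps <- call_roh(gm, "X", roh_params(min_snps = 25))
    expect_gte(sum(loose_het$length_cM), sum(strict$length_cM))
    expect_gte(sum(loose_snps$length_cM), sum(strict$length_cM))
  }
})

test_that("F_ROH arithmetic, bounds and errors behave", {
  segs <- segment_frame(kind = "ROH", id1 = "X", chrom = c("1", "2"),
                        start_bp = c(1, 1), end_bp = c(5e6, 7e6),
                        start_cM = c(0, 0), end_cM = c(5, 7),
                        n_snps = c(100L, 140L))
  expect_equal(f_roh(segs, 3000), 0.004)
  expect_equal(f_roh(segs, 3000, min_report_cM = 6), 7 / 3000)
  expect_equal(f_roh(segment_frame(), 3000), 0)
  expect_error(f_roh(segs, 0), "denominator")
  expect_error(f_roh(segs, 10), "> 1")
  tiling <- segment_frame(kind = "ROH", id1 = "X", chrom = "1",
                          start_bp = 1, end_bp = 1e8, start_cM = 0,
                          end_cM = 100, n_snps = 10L)
  expect_equal(f_roh(tiling, 100), 1)
})

test_that("length spectrum uses left-closed bins and conserves counts", {
  segs <- segment_frame(kind = "ROH", id1 = "X", chrom = "1",
                        start_bp = c(1, 10, 20, 30), end_bp = c(5, 15, 25, 35),
                        start_cM = c(0, 0, 0, 0), end_cM = c(6, 8, 25, 3),
                        n_snps = 10L)
  sp <- roh_spectrum(segs, c(4, 8, 12, 16, 20))
  expect_equal(unname(sp), c(1L, 1L, 0L, 0L),  # 6 in [4,8); 8 at edge -> [8,12)
               ignore_attr = TRUE)
  expect_equal(attr(sp, "remainder"), 2L)      # 25 and 3 outside
  expect_equal(sum(sp) + attr(sp, "remainder"), nrow(segs))
  expect_error(roh_spectrum(segs, 4), "2 bin edges")
  expect_error(roh_spectrum(segs, c(4, 4)), "strictly increasing")
})

test_that("called ROH in 4-20 cM tracks true autozygosity across individuals", {
  map <- uniform_map(rep(100, 4))
  f <- make_founders(120, 5000, map, seed = 81)  # 50 SNPs/cM
  traj <- ne_trajectory(rep(50L, 13))
  pop <- simulate_population(f, traj, map, seed = 82, n_sample = 30)
  tot <- vapply(pop$genotypes$ids, function(id) {
    called <- call_roh(pop$genotypes, id, roh_params(min_report_cM = 4))
    truth <- true_segments(pop$truth, id, min_cM = 4)
    c(called = sum(called$length_cM[called$length_cM <= 20]),
      true = sum(truth$length_cM[truth$length_cM <= 20]))
  }, numeric(2))
  expect_gte(cor(tot["called", ], tot["true", ]), 0.9)
})
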