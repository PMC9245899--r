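test_that("map interpolation hits anchors, interpolates linearly and clamps", {
  gmap <- genetic_map(rep("1", 2), c(0, 2e6), c(0, 2))
  expect_equal(map_cm_at(gmap, "1", 5e5), 0.5)
  gmap2 <- genetic_map(rep("1", 3), c(0, 1e6, 3e6), c(0, 1, 1.5))
  expect_equal(map_cm_at(gmap2, "1", 1e6), 1)
  expect_equal(map_cm_at(gmap2, "1", 5e6), 1.5)   # beyond last anchor
  expect_equal(map_cm_at(gmap2, "1", -10), 0)
  expect_error(map_cm_at(gmap2, "chr9", 100), "absent")
})

test_that("genetic map invariants are enforced and lengths add up", {
  expect_error(genetic_map("1", 100, 1), ">= 2 anchors")
  expect_error(genetic_map(c("1", "1"), c(100, 100), c(0, 1)), "strictly increasing")
  expect_error(genetic_map(c("1", "1"), c(100, 200), c(1, 0)), "non-decreasing")
  m <- uniform_map(c(a = 120, b = 80))
  expect_equal(unname(map_lengths(m)), c(120, 80))
  expect_equal(sum(map_lengths(human_autosomes())), 3605.8, tolerance = 1e-6)
  tmp <- tempfile()
  write_genetic_map(m, tmp)
  m2 <- read_genetic_map(tmp)
  expect_equal(as.data.frame(m), as.data.frame(m2))
})

test_that("VCF reading extracts diploid genotypes, skips non-SNPs, handles missing", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
           "1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
           "1\t200\t.\tA\tG,T\t.\t.\t.\tGT\t0/0\t0/0\t0/0",
           "1\t300\t.\tAT\tA\t.\t.\t.\tGT\t0/0\t0/0\t0/0",
           "1\t400\t.\tC\tT\t.\t.\t.\tGT\t./.\t0/1\t1|1")
  tmp <- tempfile(fileext = ".vcf")
  writeLines(vcf, tmp)
  gm <- suppressMessages(read_genotypes(tmp))
  expect_equal(n_sites(gm), 2L)       # multiallelic + indel skipped
  expect_equal(gm$ids, c("S1", "S2", "S3"))
  expect_equal(gm$geno[, 1L], c(0L, 1L, 2L))
  expect_equal(gm$sites$p[1L], 0.5)
  expect_true(is.na(gm$geno[1L, 2L]))
  expect_equal(gm$sites$p[2L], mean(c(1, 2)) / 2)  # from non-missing calls
  expect_error(read_genotypes(tempfile()), "not found")
})

test_that("TSV genotype dialect round-trips a random panel losslessly", {
  set.seed(11)
  sites <- data.frame(chrom = rep(c("1", "2"), each = 50),
                      bp = rep(seq(1e5, 5e6, length.out = 50), 2),
                      cM = rep(seq(0.1, 5, length.out = 50), 2))
  g <- matrix(sample(c(0L, 1L, 2L, NA), 20 * 100, replace = TRUE), nrow = 20)
  g[, 1] <- 1L  # keep site 1 polymorphic and fully typed
  gm <- genotype_matrix(g, sites)
  tmp <- tempfile()
  write_genotypes(gm, tmp)
  gm2 <- read_genotypes(tmp, format = "tsv")
  expect_identical(gm2$geno, gm$geno)
  expect_equal(gm2$sites$bp, gm$sites$bp)
  expect_equal(gm2$sites$cM, gm$sites$cM)
  expect_equal(gm2$ids, gm$ids)
})

test_that("site filters drop by missingness then MAF and are idempotent", {
  set.seed(5)
  n <- 100
  g <- matrix(rbinom(n * 4, 2, 0.5), nrow = n)
  g[1:3, 2] <- NA                       # 3% missing -> removed at 2%
  g[, 3] <- rbinom(n, 2, 0.04)          # low MAF -> removed
  while (mean(g[, 3]) / 2 >= 0.05 || mean(g[, 3]) == 0)
    g[, 3] <- rbinom(n, 2, 0.03)
  sites <- data.frame(chrom = "1", bp = c(1e5, 2e5, 3e5, 4e5))
  gm <- genotype_matrix(g, sites)
  f1 <- suppressMessages(filter_sites(gm))
  expect_equal(n_sites(f1), 2L)
  expect_equal(f1$sites$bp, c(1e5, 4e5))
  expect_equal(attr(f1, "removed"), c(missingness = 1L, maf = 1L))
  f2 <- suppressMessages(filter_sites(f1))
  expect_identical(f2$geno, f1$geno)    # idempotent
  cfg <- site_filter_config(max_missingness = 0, min_maf = 0.9)
  expect_error(suppressMessages(filter_sites(gm, cfg)), "all sites")
})

test_that("LD pruning drops perfectly correlated later sites and is idempotent", {
  set.seed(6)
  n <- 200
  base <- rbinom(n, 2, 0.5)
  g <- cbind(base, base, rbinom(n, 2, 0.4), rbinom(n, 2, 0.6))
  sites <- data.frame(chrom = "1", bp = (1:4) * 1e5)
  gm <- genotype_matrix(g, sites)
  pr <- ld_prune(gm)
  expect_equal(n_sites(pr), 3L)
  expect_equal(pr$sites$bp[1:2], c(1e5, 3e5))  # second copy dropped
  pr2 <- ld_prune(pr)
  expect_identical(pr2$geno, pr$geno)
  # mutually independent sites survive
  g2 <- matrix(rbinom(n * 60, 2, 0.5), nrow = n)
  gm2 <- genotype_matrix(g2, data.frame(chrom = "1", bp = (1:60) * 1e5))
  keep_p <- gm2$sites$p
  pruned <- ld_prune(gm2)
  expect_equal(n_sites(pruned), 60L)
})

test_that("segment BED-TSV round-trips exactly, sorted, with conventions", {
  tmp <- tempfile()
  write_segments(segment_frame(), tmp)
  empty <- read_segments(tmp)
  expect_equal(nrow(empty), 0L)
  one <- segment_frame(kind = "ROH", id1 = "X", chrom = "2",
                       start_bp = 1001, end_bp = 5000,
                       start_cM = 0.5, end_cM = 1.7, n_snps = 60L)
  write_segments(one, tmp)
  back <- read_segments(tmp)
  expect_equal(back$start0, 1000)       # 0-based half-open
  expect_equal(back$end0, 5000)
  expect_equal(back$start_bp, 1001)
  set.seed(9)
  n <- 1000
  segs <- segment_frame(kind = sample(c("ROH", "IBD"), n, TRUE),
                        id1 = sprintf("I%d", sample(99, n, TRUE)),
                        id2 = NA_character_,
                        chrom = as.character(sample(6, n, TRUE)),
                        start_bp = st <- round(runif(n, 1, 1e8)),
                        end_bp = st + round(runif(n, 1, 1e6)) + 1,
                        start_cM = sc <- runif(n, 0, 100),
                        end_cM = sc + rexp(n, 1 / 4),
                        n_snps = sample(1000L, n, TRUE),
                        lod = ifelse(runif(n) < 0.5, NA, runif(n, 3, 50)))
  segs$id2[segs$kind == "IBD"] <- "J1"
  segs$lod[segs$kind == "ROH"] <- NA
  write_segments(segs, tmp)
  back <- read_segments(tmp)
  ord <- order(match(segs$chrom, unique(segs$chrom)), segs$start_bp)
  expect_identical(back$start_bp, segs$start_bp[ord])
  expect_identical(back$end_bp, segs$end_bp[ord])
  expect_identical(back$length_cM, segs$length_cM[ord])
  expect_identical(back$lod, segs$lod[ord])
  expect_identical(back$n_snps, segs$n_snps[ord])
  expect_identical(back$id1, segs$id1[ord])
})

test_that("attach_genetic_map preserves sites and yields monotone cM", {
  set.seed(13)
  sites <- data.frame(chrom = rep(c("1", "2"), each = 30),
                      bp = rep(sort(runif(30, 1, 1.4e8)), 2))
  g <- matrix(rbinom(60 * 60, 2, 0.5), nrow = 60)
  gm <- genotype_matrix(g, sites)
  gmap <- genetic_map(rep(c("1", "2"), each = 3),
                      rep(c(0, 5e7, 1.5e8), 2), rep(c(0, 70, 150), 2))
  gm2 <- attach_genetic_map(gm, gmap)
  expect_equal(n_sites(gm2), 60L)
  expect_equal(gm2$sites$bp, gm$sites$bp)
  for (ch in c("1", "2"))
    expect_false(is.unsorted(gm2$sites$cM[gm2$sites$chrom == ch]))
  bad_map <- genetic_map(c("1", "1"), c(0, 1e8), c(0, 100))
  expect_error(attach_genetic_map(gm, bad_map), "absent")
})
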