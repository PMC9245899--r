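# shared IBD fixture: 30 outbred individuals from founder haplotype pairs,
# plus a duplicated genome and a parent-offspring-like pair built later
ibd_panel <- function() {
  fixture("ibd_panel", {
    f <- small_founders()
    g <- t(vapply(seq_len(30), function(i)
      founder_pair_genotypes(f, 2 * i - 1, 2 * i), integer(nrow(f$sites))))
    genotype_matrix(g, f$sites, ids = sprintf("U%02d", 1:30))
  })
}

test_that("site LOD equals the enumeration oracle to 1e-12", {
  for (eps in c(0.005, 0.02)) {
    for (p in c(0.05, 0.2, 0.5, 0.8, 0.95)) {
      for (g1 in 0:2) for (g2 in 0:2) {
        expect_equal(site_lod(g1, g2, p, eps),
                     oracle_site_lod(g1, g2, p, eps), tolerance = 1e-12)
      }
    }
  }
  expect_error(site_lod(0, 0, 0, 0.005), "frequency")
  expect_error(site_lod(0, 0, 1, 0.005), "frequency")
})

test_that("LOD signs follow rare-allele sharing and incompatibility", {
  expect_gt(site_lod(2, 2, 0.05), 0)     # shared rare homozygote
  expect_gt(site_lod(0, 0, 0.95), 0)
  expect_lt(site_lod(0, 2, 0.5, 0.005), 0)  # opposite homozygotes
  expect_equal(site_lod(NA, 1, 0.5), 0)     # missing contributes nothing
})

test_that("a duplicated genome is detected as IBD tiling the chromosomes", {
  f <- small_founders()
  base <- ibd_panel()
  g <- rbind(base$geno, base$geno[1, ])
  gm <- genotype_matrix(g, f$sites, ids = c(base$ids, "DUP"))
  segs <- detect_ibd(gm, "U01", "DUP")
  expect_gte(sum(segs$length_cM), 0.99 * 900)
  per_chrom <- tapply(segs$length_cM, segs$chrom, sum)
  expect_true(all(per_chrom >= 0.99 * 150))
  expect_error(detect_ibd(gm, "U01", "U01"), "distinct")
  expect_true(all(segs$length_cM >= 2))
})

test_that("kinship hits the expectation ladder", {
  f <- small_founders()
  base <- ibd_panel()
  gdup <- genotype_matrix(rbind(base$geno[1, ], base$geno[1, ]), f$sites,
                          ids = c("a", "b"))
  expect_equal(kinship(gdup, "a", "b"), 0.5)
  # parent-offspring: child gets one haplotype from the parent pair
  set.seed(41)
  phis <- replicate(20, {
    hp <- sample(200, 3)
    parent <- f$alleles[hp[1], ] + f$alleles[hp[2], ]
    transmitted <- ifelse(runif(nrow(f$sites)) < 0.5,
                          f$alleles[hp[1], ], f$alleles[hp[2], ])
    child <- transmitted + f$alleles[hp[3], ]
    gmx <- genotype_matrix(rbind(base$geno, parent, child), f$sites,
                           ids = c(base$ids, "P", "O"))
    kinship(gmx, "P", "O")
  })
  expect_lt(abs(mean(phis) - 0.25), 0.03)
  # unrelated founder pairs
  un <- vapply(seq_len(14), function(i)
    kinship(base, sprintf("U%02d", 2 * i - 1), sprintf("U%02d", 2 * i)),
    numeric(1))
  expect_lt(abs(mean(un)), 0.02)
  tiny <- genotype_matrix(matrix(c(1L, 1L, 0L, 1L), 2, 2),
                          data.frame(chrom = "1", bp = c(1, 2)), c("x", "y"))
  expect_warning(expect_true(is.na(kinship(tiny, "x", "y"))), "overlapping")
})

test_that("relative filtering removes exactly the planted close pairs", {
  f <- small_founders()
  base <- ibd_panel()
  dup <- base$geno[1, ]
  dup[1:200] <- NA                      # duplicate has more missing calls
  gm <- genotype_matrix(rbind(base$geno, dup), f$sites,
                        ids = c(base$ids, "DUP"))
  out <- filter_relatives(gm)
  expect_equal(out$removed, "DUP")      # the missing-heavy member goes
  expect_equal(sort(out$kept), sort(base$ids))
  expect_equal(out$pairs$id1, "U01")
  phi <- insulaR:::.kinship_matrix(subset_individuals(gm, out$kept))
  expect_true(all(phi[upper.tri(phi)] <= 0.0442, na.rm = TRUE))
})

test_that("the IBD matrix is symmetric with a zero diagonal and structure shows", {
  f <- small_founders()
  base <- ibd_panel()
  two <- subset_individuals(base, c("U01", "U02"))
  two$sites$p <- base$sites$p           # keep panel frequencies
  mat2 <- pairwise_ibd_matrix(two)
  expect_equal(mat2$total, matrix(0, 2, 2, dimnames = list(two$ids, two$ids)))
  expect_error(pairwise_ibd_matrix(subset_individuals(base, "U01")),
               "at least 2")
  mat <- fixture("ibd_mat_small", {
    sub <- subset_individuals(base, sprintf("U%02d", 1:8))
    sub$sites$p <- base$sites$p
    pairwise_ibd_matrix(sub)
  })
  expect_identical(mat$total, t(mat$total))
  expect_true(all(diag(mat$total) == 0))
})

test_that("group summaries average per-pair totals and ignore singletons", {
  ids <- sprintf("I%d", 1:6)
  tot <- matrix(0, 6, 6, dimnames = list(ids, ids))
  tot["I1", "I2"] <- tot["I2", "I1"] <- 10
  tot["I1", "I3"] <- tot["I3", "I1"] <- 20
  tot["I2", "I3"] <- tot["I3", "I2"] <- 30
  tot["I4", "I5"] <- tot["I5", "I4"] <- 7
  mat <- structure(list(ids = ids, total = tot,
                        segments = segment_frame()), class = "ibd_matrix")
  groups <- stats::setNames(c("a", "a", "a", "b", "b", "lone"), ids)
  gs <- group_summary(mat, groups)
  expect_equal(gs$groups, c("a", "b"))          # singleton dropped
  expect_equal(gs$mean_cM["a", "a"], 20)
  expect_equal(gs$n_pairs["a", "a"], 3L)
  expect_equal(gs$mean_cM["a", "b"], 0)
  # invariant under reordering individuals
  perm <- c(3, 1, 2, 6, 5, 4)
  mat2 <- structure(list(ids = ids[perm], total = tot[perm, perm],
                         segments = segment_frame()), class = "ibd_matrix")
  gs2 <- group_summary(mat2, groups)
  expect_equal(gs2$mean_cM, gs$mean_cM)
  expect_error(group_summary(mat, groups[1:3]), "every individual")
  expect_error(group_summary(mat, character(0)), "empty")
})

test_that("PCA of a two-block matrix separates the blocks on PC1", {
  ids <- sprintf("I%d", 1:8)
  tot <- matrix(0, 8, 8, dimnames = list(ids, ids))
  tot[1:4, 1:4] <- 50; tot[5:8, 5:8] <- 50
  diag(tot) <- 0
  pca <- ibd_pca(tot, n_components = 3)
  s1 <- sign(pca$scores[, 1])
  expect_true(all(s1[1:4] == s1[1]) && all(s1[5:8] == -s1[1]))
  expect_true(all(diff(pca$var_frac) <= 1e-12))
  expect_true(all(pca$var_frac >= 0 & pca$var_frac <= 1))
  expect_error(ibd_pca(matrix(3, 5, 5)), "constant")
  expect_error(ibd_pca(tot[1:2, 1:2]), "at least 3")
})

test_that("Ne eligibility switches exactly at 90 qualifying segments", {
  mk <- function(n, len = 3) segment_frame(
    kind = "IBD", id1 = "A1", id2 = "A2", chrom = "1",
    start_bp = seq_len(n) * 1000, end_bp = seq_len(n) * 1000 + 500,
    start_cM = seq_len(n), end_cM = seq_len(n) + len, n_snps = 10L, lod = 5)
  groups <- c(A1 = "is", A2 = "is", B1 = "main", B2 = "main")
  e89 <- ne_eligibility(mk(89), groups)
  expect_false(e89$eligible[e89$group == "is"])
  e90 <- ne_eligibility(mk(90), groups)
  expect_true(e90$eligible[e90$group == "is"])
  short <- mk(200, len = 1.9)           # < 2 cM never counts
  expect_false(ne_eligibility(short, groups)$eligible[1])
})
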