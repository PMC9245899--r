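# IBD segment detection on unphased genotypes, kinship filtering, and
# geography summaries of the pairwise total-IBD matrix.

#' IBD detection parameters
#'
#' @param errormax per-allele miscall rate assumed by both likelihood
#'   models, in (0, 0.05].
#' @param lod_min minimum total LOD for a reported segment.
#' @param min_length_cM minimum genetic segment length (segments shorter
#'   than 2 cM are conventionally excluded as unreliable).
#' @param min_maf minimum MAF expected of the input panel.
#' @return object of class `ibd_params`.
#' @export
ibd_params <- function(errormax = 0.005, lod_min = 3, min_length_cM = 2,
                       min_maf = 0.05) {
  stopifnot(errormax > 0, errormax <= 0.05, lod_min > 0, min_length_cM > 0)
  structure(list(errormax = errormax, lod_min = lod_min,
                 min_length_cM = min_length_cM, min_maf = min_maf),
            class = "ibd_params")
}

# P(observed genotype | true genotype) with per-allele miscall eps:
# rows true 0/1/2, columns observed 0/1/2
.err_kernel <- function(eps) {
  rbind(c((1 - eps)^2, 2 * eps * (1 - eps), eps^2),
        c(eps * (1 - eps), (1 - eps)^2 + eps^2, eps * (1 - eps)),
        c(eps^2, 2 * eps * (1 - eps), (1 - eps)^2))
}

# Per-site 3x3 log10 likelihood-ratio tables, vectorised over sites.
# Returns an n_sites x 9 matrix indexed by code 3*g1 + g2 + 1.
# Non-IBD model: independent error-perturbed Hardy-Weinberg genotypes.
# IBD1 model: the pair shares one allele a (alt with probability p); each
# individual carries a plus an independent population allele, then errors.
.lod_table <- function(p, eps) {
  E <- .err_kernel(eps)
  hwe <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  q <- hwe %*% E                       # marginal observed genotype probs
  # observed genotype probs given shared allele a = ref (r0) or alt (r1)
  r0 <- cbind(1 - p, p, 0) %*% E       # true genotype = 0 + Bern(p)
  r1 <- cbind(0, 1 - p, p) %*% E       # true genotype = 1 + Bern(p)
  out <- matrix(NA_real_, length(p), 9L)
  for (g1 in 0:2) for (g2 in 0:2) {
    num <- (1 - p) * r0[, g1 + 1L] * r0[, g2 + 1L] +
      p * r1[, g1 + 1L] * r1[, g2 + 1L]
    den <- q[, g1 + 1L] * q[, g2 + 1L]
    out[, 3L * g1 + g2 + 1L] <- log10(num / den)
  }
  out
}

#' Single-site IBD LOD score
#'
#' log10 likelihood ratio of the IBD1 model (the two individuals share one
#' allele identical by descent) against the non-IBD model (independent
#' Hardy-Weinberg genotypes), both with a per-allele miscall rate
#' `errormax`. Missing genotypes score 0.
#'
#' @param g1,g2 observed genotypes (0/1/2 alt-allele counts; `NA` allowed).
#' @param p alt-allele frequency in (0, 1).
#' @param errormax per-allele miscall rate.
#' @return numeric LOD score(s).
#' @export
site_lod <- function(g1, g2, p, errormax = 0.005) {
  n <- max(length(g1), length(g2), length(p))
  g1 <- rep_len(g1, n); g2 <- rep_len(g2, n); p <- rep_len(p, n)
  if (any(p <= 0 | p >= 1)) .stopf("allele frequency must be in (0, 1)")
  tab <- .lod_table(p, errormax)
  out <- numeric(n)
  ok <- !is.na(g1) & !is.na(g2)
  out[ok] <- tab[cbind(which(ok), 3L * g1[ok] + g2[ok] + 1L)]
  out
}

# Disjoint maximal-scoring intervals with score >= lod_min: find the best-
# scoring subsegment (prefix-sum scan: a candidate starts after the running
# minimum and ends at the maximum since then), report it if it clears the
# threshold, then recurse into the flanks.
.max_subsegments <- function(s, lod_min) {
  out <- list()
  stack <- list(c(1L, length(s)))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- rng[1L]; b <- rng[2L]
    if (b < a) next
    cs <- cumsum(s[a:b])
    prefix <- c(0, cs)
    cmin <- cummin(prefix[-length(prefix)])
    gain <- cs - cmin
    jrel <- which.max(gain)
    score <- gain[jrel]
    if (score < lod_min) next
    irel <- which(prefix[seq_len(jrel)] == cmin[jrel])[1L]
    i <- a + irel - 1L
    j <- a + jrel - 1L
    out[[length(out) + 1L]] <- c(i, j, score)
    stack[[length(stack) + 1L]] <- c(a, i - 1L)
    stack[[length(stack) + 1L]] <- c(j + 1L, b)
  }
  if (!length(out)) return(matrix(numeric(0), 0L, 3L))
  m <- do.call(rbind, out)
  m[order(m[, 1L]), , drop = FALSE]
}

.detect_ibd_scores <- function(scores, sites, id_i, id_j, params) {
  res <- lapply(unique(sites$chrom), function(ch) {
    sel <- which(sites$chrom == ch)
    m <- .max_subsegments(scores[sel], params$lod_min)
    if (!nrow(m)) return(NULL)
    i <- sel[m[, 1L]]; j <- sel[m[, 2L]]
    keep <- sites$cM[j] - sites$cM[i] >= params$min_length_cM & j > i
    if (!any(keep)) return(NULL)
    segment_frame(kind = "IBD", id1 = id_i, id2 = id_j, chrom = ch,
                  start_bp = sites$bp[i[keep]], end_bp = sites$bp[j[keep]],
                  start_cM = sites$cM[i[keep]], end_cM = sites$cM[j[keep]],
                  n_snps = j[keep] - i[keep] + 1L, lod = m[keep, 3L])
  })
  out <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(out)) return(.empty_segments())
  class(out) <- c("segment_frame", "data.frame")
  rownames(out) <- NULL
  out
}

#' Detect IBD segments between two individuals
#'
#' Per-site LOD scores ([site_lod()]) are scanned per chromosome for
#' disjoint maximal-scoring intervals; intervals with total LOD >=
#' `lod_min` and genetic length >= `min_length_cM` are reported with the
#' outermost contributing SNPs as endpoints. The input panel should already
#' be MAF/missingness filtered.
#'
#' @param gm a `genotype_matrix` with cM attached.
#' @param id_i,id_j distinct individual ids.
#' @param params an [ibd_params()].
#' @return a `segment_frame` of IBD segments.
#' @export
detect_ibd <- function(gm, id_i, id_j, params = ibd_params()) {
  if (identical(id_i, id_j))
    .stopf("detect_ibd needs two distinct individuals (use call_roh for autozygosity)")
  i <- match(id_i, gm$ids); j <- match(id_j, gm$ids)
  if (is.na(i) || is.na(j)) .stopf("unknown individual id")
  if (anyNA(gm$sites$cM)) .stopf("sites lack cM; attach_genetic_map() first")
  usable <- gm$sites$p > 0 & gm$sites$p < 1 & !is.na(gm$sites$p)
  tab <- .lod_table(gm$sites$p[usable], params$errormax)
  scores <- numeric(n_sites(gm))
  g1 <- gm$geno[i, usable]; g2 <- gm$geno[j, usable]
  ok <- !is.na(g1) & !is.na(g2)
  sc <- numeric(sum(usable))
  sc[ok] <- tab[cbind(which(ok), 3L * g1[ok] + g2[ok] + 1L)]
  scores[usable] <- sc
  .detect_ibd_scores(scores, gm$sites, id_i, id_j, params)
}

#' KING-robust kinship estimate for one pair
#'
#' `phi = (N_hethet - 2 N_opphom) / (N_het(i) + N_het(j))` over sites
#' non-missing in both individuals. Expectation is about 0.5 for duplicates,
#' 0.25 for parent-offspring, 0.0625 for first cousins and 0 for unrelated
#' pairs.
#'
#' @param gm a `genotype_matrix`.
#' @param id_i,id_j individual ids.
#' @param min_overlap minimum shared non-missing sites (default 100).
#' @return kinship estimate, or `NA` with a warning when overlap is
#'   insufficient.
#' @export
kinship <- function(gm, id_i, id_j, min_overlap = 100L) {
  i <- match(id_i, gm$ids); j <- match(id_j, gm$ids)
  if (is.na(i) || is.na(j)) .stopf("unknown individual id")
  g1 <- gm$geno[i, ]; g2 <- gm$geno[j, ]
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < min_overlap) {
    .warnf("kinship: only %d overlapping sites for (%s, %s); skipped",
           sum(ok), id_i, id_j)
    return(NA_real_)
  }
  g1 <- g1[ok]; g2 <- g2[ok]
  nhh <- sum(g1 == 1L & g2 == 1L)
  nopp <- sum((g1 == 0L & g2 == 2L) | (g1 == 2L & g2 == 0L))
  (nhh - 2 * nopp) / (sum(g1 == 1L) + sum(g2 == 1L))
}

# all-pairs KING-robust kinship (NA-safe matrix algebra)
.kinship_matrix <- function(gm, min_overlap = 100L) {
  M <- !is.na(gm$geno)
  g <- gm$geno; g[!M] <- 0L
  H <- (g == 1L) & M
  A0 <- (g == 0L) & M
  A2 <- (g == 2L) & M
  storage.mode(H) <- "numeric"; storage.mode(A0) <- "numeric"
  storage.mode(A2) <- "numeric"; Mm <- M; storage.mode(Mm) <- "numeric"
  nhh <- H %*% t(H)
  nopp <- A0 %*% t(A2) + A2 %*% t(A0)
  het_i <- H %*% t(Mm)              # het in i over sites shared with j
  denom <- het_i + t(het_i)
  phi <- (nhh - 2 * nopp) / denom
  overlap <- Mm %*% t(Mm)
  phi[overlap < min_overlap] <- NA_real_
  diag(phi) <- NA_real_
  dimnames(phi) <- list(gm$ids, gm$ids)
  phi
}

#' Remove close relatives from a panel
#'
#' Computes all pairwise KING-robust kinship estimates and greedily resolves
#' every pair above `threshold` (default 0.0442, the conventional cutoff
#' separating 3rd-degree relatives from more distant ones) by removing the
#' member with more missing genotypes (ties broken toward the later id),
#' starting from the highest-kinship pair, until no pair exceeds the
#' threshold.
#'
#' @param gm a `genotype_matrix`.
#' @param threshold kinship cutoff.
#' @param min_overlap minimum shared sites for a pair to be evaluated.
#' @return list with `kept` ids, `removed` ids and a `pairs` log
#'   data.frame.
#' @export
filter_relatives <- function(gm, threshold = 0.0442, min_overlap = 100L) {
  phi <- .kinship_matrix(gm, min_overlap)
  miss <- rowSums(is.na(gm$geno))
  names(miss) <- gm$ids
  alive <- gm$ids
  log <- list()
  repeat {
    sub <- phi[alive, alive, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA_real_
    over <- which(sub > threshold, arr.ind = TRUE)
    if (!nrow(over)) break
    vals <- sub[over]
    top <- over[which.max(vals), ]
    a <- alive[top[1L]]; b <- alive[top[2L]]
    drop_id <- if (miss[a] > miss[b]) a
    else if (miss[b] > miss[a]) b
    else alive[max(top)]
    log[[length(log) + 1L]] <- data.frame(id1 = a, id2 = b,
                                          kinship = sub[top[1L], top[2L]],
                                          removed = drop_id,
                                          stringsAsFactors = FALSE)
    alive <- setdiff(alive, drop_id)
  }
  list(kept = alive, removed = setdiff(gm$ids, alive),
       pairs = if (length(log)) do.call(rbind, log) else
         data.frame(id1 = character(), id2 = character(),
                    kinship = numeric(), removed = character()))
}

#' Pairwise total-IBD matrix
#'
#' Runs [detect_ibd()] for every pair and assembles symmetric matrices of
#' total shared cM and segment counts (diagonal 0). Close relatives should
#' be removed beforehand with [filter_relatives()].
#'
#' @param gm a `genotype_matrix` with cM attached.
#' @param params an [ibd_params()].
#' @return object of class `ibd_matrix`: list with `ids`, `total`, `count`
#'   and the pooled `segments`.
#' @export
pairwise_ibd_matrix <- function(gm, params = ibd_params()) {
  n <- n_individuals(gm)
  if (n < 2L) .stopf("need at least 2 individuals")
  if (anyNA(gm$sites$cM)) .stopf("sites lack cM; attach_genetic_map() first")
  usable <- gm$sites$p > 0 & gm$sites$p < 1 & !is.na(gm$sites$p)
  tab <- .lod_table(gm$sites$p[usable], params$errormax)
  widx <- which(usable)
  total <- matrix(0, n, n, dimnames = list(gm$ids, gm$ids))
  count <- matrix(0L, n, n, dimnames = list(gm$ids, gm$ids))
  segs <- list()
  for (i in seq_len(n - 1L)) {
    gi <- gm$geno[i, usable]
    for (j in seq((i + 1L), n)) {
      gj <- gm$geno[j, usable]
      ok <- !is.na(gi) & !is.na(gj)
      scores <- numeric(n_sites(gm))
      sc <- numeric(length(gi))
      sc[ok] <- tab[cbind(which(ok), 3L * gi[ok] + gj[ok] + 1L)]
      scores[widx] <- sc
      s <- .detect_ibd_scores(scores, gm$sites, gm$ids[i], gm$ids[j], params)
      total[i, j] <- total[j, i] <- sum(s$length_cM)
      count[i, j] <- count[j, i] <- nrow(s)
      if (nrow(s)) segs[[length(segs) + 1L]] <- s
    }
  }
  all_segs <- if (length(segs)) do.call(rbind, segs) else .empty_segments()
  class(all_segs) <- c("segment_frame", "data.frame")
  structure(list(ids = gm$ids, total = total, count = count,
                 segments = all_segs, params = params),
            class = "ibd_matrix")
}

#' @export
print.ibd_matrix <- function(x, ...) {
  cat(sprintf("<ibd_matrix> %d individuals, %d segments, mean pair total %.2f cM\n",
              length(x$ids), nrow(x$segments),
              mean(x$total[upper.tri(x$total)])))
  invisible(x)
}

#' Within/between-group IBD sharing summary
#'
#' Mean per-pair total shared cM within and between groups. By default
#' groups with fewer than two members are dropped entirely (they admit no
#' within-group pair); with `keep_singletons = TRUE` they are retained for
#' between-group means, their within-group cell being `NA`.
#'
#' @param mat an `ibd_matrix`.
#' @param groups named character vector id -> group label.
#' @param keep_singletons retain single-member groups in between-group rows.
#' @return object of class `ibd_group_summary`: list with `mean_cM` and
#'   `n_pairs` symmetric matrices over retained groups.
#' @export
group_summary <- function(mat, groups, keep_singletons = FALSE) {
  if (!length(groups)) .stopf("empty group table")
  if (!all(mat$ids %in% names(groups)))
    .stopf("group table does not map every individual")
  lab <- groups[mat$ids]
  sizes <- table(lab)
  keep <- names(sizes)[sizes >= if (keep_singletons) 1L else 2L]
  if (!length(keep)) .stopf("no group has >= 2 members")
  keep <- sort(keep)
  mean_cM <- matrix(NA_real_, length(keep), length(keep),
                    dimnames = list(keep, keep))
  n_pairs <- matrix(0L, length(keep), length(keep),
                    dimnames = list(keep, keep))
  for (a in seq_along(keep)) for (b in seq(a, length(keep))) {
    ia <- which(lab == keep[a]); ib <- which(lab == keep[b])
    if (a == b) {
      if (length(ia) < 2L) next    # singleton: no within-group pair
      pairs <- utils::combn(ia, 2L)
      vals <- mat$total[t(pairs)]
    } else {
      vals <- as.vector(mat$total[ia, ib])
    }
    mean_cM[a, b] <- mean_cM[b, a] <- mean(vals)
    n_pairs[a, b] <- n_pairs[b, a] <- length(vals)
  }
  structure(list(groups = keep, mean_cM = mean_cM, n_pairs = n_pairs),
            class = "ibd_group_summary")
}

#' @export
print.ibd_group_summary <- function(x, ...) {
  cat(sprintf("<ibd_group_summary> %d group(s)\n", length(x$groups)))
  print(round(x$mean_cM, 2))
  invisible(x)
}

#' PCA of the total-IBD matrix
#'
#' Rows of the symmetric total-sharing matrix are treated as feature
#' vectors, columns are mean-centred, and scores come from the singular
#' value decomposition.
#'
#' @param mat an `ibd_matrix` (or a plain symmetric numeric matrix).
#' @param n_components number of leading components to return.
#' @return list with `scores` (individuals x components), `var_frac`
#'   (variance-explained fractions) and `sdev`.
#' @export
ibd_pca <- function(mat, n_components = 10L) {
  x <- if (inherits(mat, "ibd_matrix")) mat$total else as.matrix(mat)
  if (nrow(x) < 3L) .stopf("need at least 3 individuals for PCA")
  if (all(abs(x - mean(x)) < 1e-300)) .stopf("constant IBD matrix: no variance")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_frac = var_frac[seq_len(k)], sdev = pc$sdev[seq_len(k)])
}

#' Group eligibility for trajectory-based Ne estimation
#'
#' A group qualifies when its members share at least `min_segments`
#' within-group IBD segments of length >= `min_length_cM`.
#'
#' @param segments a `segment_frame` of IBD segments.
#' @param groups named character vector id -> group.
#' @param min_segments eligibility threshold (default 90).
#' @param min_length_cM segment length floor (default 2).
#' @return data.frame with `group`, `n_segments`, `eligible`.
#' @export
ne_eligibility <- function(segments, groups, min_segments = 90L,
                           min_length_cM = 2) {
  g1 <- groups[segments$id1]
  g2 <- groups[segments$id2]
  within <- !is.na(g1) & !is.na(g2) & g1 == g2 &
    segments$length_cM >= min_length_cM
  counts <- table(factor(g1[within], levels = sort(unique(groups))))
  data.frame(group = names(counts), n_segments = as.integer(counts),
             eligible = as.integer(counts) >= min_segments,
             row.names = NULL, stringsAsFactors = FALSE)
}
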