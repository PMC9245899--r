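#' ROH calling parameters
#'
#' Defaults reproduce the widely used PLINK runs-of-homozygosity settings for
#' imputed ancient panels: scanning windows of 50 SNPs with zero
#' heterozygotes allowed, at most 5 missing calls per window, a 5% window hit
#' fraction, minimum 50 SNPs and 1 kb per reported segment, a 5000 kb
#' inter-SNP gap split, and a density ceiling of 5000 kb per SNP.
#'
#' @param window_snps scanning window size in SNPs.
#' @param window_het_max maximum heterozygous calls for a window to count as
#'   homozygous.
#' @param window_missing_max maximum missing calls per window.
#' @param min_snps minimum SNPs per reported segment.
#' @param min_length_kb minimum physical segment length (kb).
#' @param max_inter_snp_gap_kb split a run where consecutive SNPs are farther
#'   apart than this (kb).
#' @param min_density_kb_per_snp maximum kb per SNP within a segment.
#' @param window_hit_fraction minimum fraction of overlapping windows that
#'   must be homozygous for a site to be in the ROH state.
#' @param min_report_cM drop reported segments shorter than this genetic
#'   length (0 reports all; set 4/5/10/15 for length-restricted re-analyses).
#' @return object of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50L, window_het_max = 0L,
                       window_missing_max = 5L, min_snps = 50L,
                       min_length_kb = 1, max_inter_snp_gap_kb = 5000,
                       min_density_kb_per_snp = 5000,
                       window_hit_fraction = 0.05, min_report_cM = 0) {
  stopifnot(window_snps >= 1, window_het_max >= 0, window_missing_max >= 0,
            min_snps >= 1, min_length_kb >= 0, max_inter_snp_gap_kb >= 0,
            min_density_kb_per_snp >= 0, window_hit_fraction >= 0,
            min_report_cM >= 0)
  structure(list(window_snps = as.integer(window_snps),
                 window_het_max = as.integer(window_het_max),
                 window_missing_max = as.integer(window_missing_max),
                 min_snps = as.integer(min_snps),
                 min_length_kb = min_length_kb,
                 max_inter_snp_gap_kb = max_inter_snp_gap_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 window_hit_fraction = window_hit_fraction,
                 min_report_cM = min_report_cM),
            class = "roh_params")
}

# Window scan on one chromosome. Semantics:
#  (1) every window of `window_snps` consecutive sites is homozygous iff its
#      het count <= window_het_max and missing count <= window_missing_max;
#  (2) a site is in the ROH state iff the fraction of windows overlapping it
#      that are homozygous is >= window_hit_fraction;
#  (3) candidate segments are maximal runs of in-state sites, split where
#      the inter-SNP bp gap exceeds max_inter_snp_gap_kb;
#  (4) keep candidates with n_snps >= min_snps, bp length >= min_length_kb
#      and kb-per-SNP density <= min_density_kb_per_snp.
.call_roh_chrom <- function(g, bp, cM, chrom, id, p) {
  n <- length(g)
  W <- p$window_snps
  if (n < W) return(.empty_segments())
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  csh <- c(0L, cumsum(het)); csm <- c(0L, cumsum(mis))
  nwin <- n - W + 1L
  w <- seq_len(nwin)
  hom_win <- (csh[w + W] - csh[w]) <= p$window_het_max &
    (csm[w + W] - csm[w]) <= p$window_missing_max
  ch <- c(0L, cumsum(as.integer(hom_win)))
  i <- seq_len(n)
  wlo <- pmax(1L, i - W + 1L)
  whi <- pmin(nwin, i)
  hits <- ch[whi + 1L] - ch[wlo]
  in_state <- hits / (whi - wlo + 1L) >= p$window_hit_fraction
  if (!any(in_state)) return(.empty_segments())
  # maximal runs, split at large gaps
  r <- rle(in_state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    if (b > a) {
      gaps <- which(diff(bp[a:b]) > p$max_inter_snp_gap_kb * 1000)
      cutp <- c(a - 1L, a - 1L + gaps, b)
    } else cutp <- c(a - 1L, b)
    for (j in seq_len(length(cutp) - 1L)) {
      aa <- cutp[j] + 1L; bb <- cutp[j + 1L]
      nsnp <- bb - aa + 1L
      len_bp <- bp[bb] - bp[aa] + 1
      if (nsnp < p$min_snps) next
      if (len_bp < p$min_length_kb * 1000) next
      if ((len_bp / 1000) / nsnp > p$min_density_kb_per_snp) next
      segs[[length(segs) + 1L]] <- c(aa, bb)
    }
  }
  if (!length(segs)) return(.empty_segments())
  segs <- do.call(rbind, segs)
  out <- segment_frame(kind = "ROH", id1 = id, id2 = NA_character_,
                       chrom = chrom,
                       start_bp = bp[segs[, 1L]], end_bp = bp[segs[, 2L]],
                       start_cM = cM[segs[, 1L]], end_cM = cM[segs[, 2L]],
                       n_snps = segs[, 2L] - segs[, 1L] + 1L)
  out[out$length_cM >= p$min_report_cM, , drop = FALSE]
}

.call_roh_sites <- function(g, sites, id, params) {
  if (all(is.na(g))) {
    .warnf("call_roh: individual '%s' has all-missing genotypes", id)
    return(.empty_segments())
  }
  res <- lapply(unique(sites$chrom), function(ch) {
    sel <- sites$chrom == ch
    .call_roh_chrom(g[sel], sites$bp[sel], sites$cM[sel], ch, id, params)
  })
  out <- do.call(rbind, res)
  class(out) <- c("segment_frame", "data.frame")
  rownames(out) <- NULL
  out
}

#' Call runs of homozygosity for one individual
#'
#' Sliding-window scan in the PLINK style: windows of consecutive SNPs are
#' scored homozygous or not, sites enter the ROH state when enough of their
#' overlapping windows are homozygous, and maximal runs of in-state sites are
#' reported after gap splitting and size/density filters. See
#' [roh_params()] for the semantics and defaults.
#'
#' @param gm a `genotype_matrix` with cM coordinates attached.
#' @param id individual id to scan.
#' @param params a [roh_params()].
#' @return a `segment_frame` of ROH segments.
#' @export
call_roh <- function(gm, id, params = roh_params()) {
  idx <- match(id, gm$ids)
  if (is.na(idx)) .stopf("unknown individual id '%s'", id)
  if (anyNA(gm$sites$cM)) .stopf("sites lack cM coordinates; attach_genetic_map() first")
  .call_roh_sites(gm$geno[idx, ], gm$sites, id, params)
}

#' Fraction of the genome in ROH (F_ROH)
#'
#' Total genetic length of ROH segments at least `min_report_cM` long,
#' divided by the genetic length of the analysed autosomes. Estimates the
#' inbreeding coefficient.
#'
#' @param segments `segment_frame` of one individual's ROH.
#' @param autosomal_map_length_cM denominator: total map length analysed.
#' @param min_report_cM length threshold (cM) below which segments are
#'   ignored.
#' @return fraction in [0, 1].
#' @export
f_roh <- function(segments, autosomal_map_length_cM, min_report_cM = 0) {
  if (autosomal_map_length_cM <= 0) .stopf("f_roh: denominator must be > 0")
  tot <- sum(segments$length_cM[segments$length_cM >= min_report_cM])
  f <- tot / autosomal_map_length_cM
  if (f > 1 + 1e-9) .stopf("f_roh > 1: segments exceed the autosomal length")
  min(f, 1)
}

#' Histogram of ROH lengths
#'
#' Left-closed right-open bins over `bin_edges_cM`; segments outside all
#' bins are not binned but counted in the `remainder` attribute.
#'
#' @param segments a `segment_frame`.
#' @param bin_edges_cM strictly increasing numeric bin edges (>= 2).
#' @return named integer vector of counts with attribute `remainder`.
#' @export
roh_spectrum <- function(segments, bin_edges_cM) {
  if (length(bin_edges_cM) < 2L) .stopf("need at least 2 bin edges")
  if (any(diff(bin_edges_cM) <= 0)) .stopf("bin edges must be strictly increasing")
  x <- segments$length_cM
  k <- findInterval(x, bin_edges_cM)
  inside <- k >= 1L & x < bin_edges_cM[length(bin_edges_cM)]
  counts <- tabulate(k[inside], nbins = length(bin_edges_cM) - 1L)
  names(counts) <- sprintf("[%g,%g)", bin_edges_cM[-length(bin_edges_cM)],
                           bin_edges_cM[-1L])
  attr(counts, "remainder") <- sum(!inside)
  counts
}

#' Per-individual ROH profile table
#'
#' Calls ROH for each requested individual and tabulates segment counts,
#' total cM above the conventional length classes (>4, >5, >10, >15 cM) and
#' F_ROH.
#'
#' @param gm a `genotype_matrix` with cM attached.
#' @param params a [roh_params()].
#' @param ids individuals (default all).
#' @param autosomal_map_length_cM denominator for F_ROH (default: sum of
#'   per-chromosome site cM spans).
#' @param classes_cM length-class thresholds.
#' @return list with `profiles` (data.frame), `segments` (pooled
#'   `segment_frame`) and `segments_by_id` (named list, one entry per
#'   individual including empty ones — the shape [fit_ne_roh()] expects).
#' @export
roh_profile <- function(gm, params = roh_params(), ids = gm$ids,
                        autosomal_map_length_cM = NULL,
                        classes_cM = c(4, 5, 10, 15)) {
  if (is.null(autosomal_map_length_cM)) {
    autosomal_map_length_cM <- sum(vapply(unique(gm$sites$chrom), function(ch) {
      v <- gm$sites$cM[gm$sites$chrom == ch]
      max(v) - min(v)
    }, numeric(1)))
  }
  segs <- list()
  rows <- lapply(ids, function(id) {
    s <- call_roh(gm, id, params)
    segs[[id]] <<- s
    tot <- vapply(classes_cM, function(th) sum(s$length_cM[s$length_cM > th]),
                  numeric(1))
    c(n_segments = nrow(s),
      stats::setNames(tot, sprintf("total_gt%gcM", classes_cM)),
      f_roh = f_roh(s, autosomal_map_length_cM, params$min_report_cM))
  })
  profiles <- data.frame(id = ids, do.call(rbind, rows),
                         stringsAsFactors = FALSE, row.names = NULL)
  all_segs <- do.call(rbind, unname(segs))
  if (is.null(all_segs)) all_segs <- .empty_segments()
  class(all_segs) <- c("segment_frame", "data.frame")
  list(profiles = profiles, segments = all_segs, segments_by_id = segs,
       autosomal_map_length_cM = autosomal_map_length_cM)
}
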