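#' Genotype matrix objects
#'
#' Container for an unphased diploid panel: individuals x biallelic autosomal
#' sites, genotypes coded as alt-allele counts 0/1/2 with `NA` for missing.
#' Site records carry chromosome, physical position (1-based bp), genetic
#' position (cM, may be `NA` until a map is attached), ref/alt labels and the
#' alt-allele frequency `p` computed from non-missing calls.
#'
#' @param geno integer matrix, individuals in rows, sites in columns.
#' @param sites data.frame with columns `chrom`, `bp` and optionally `cM`,
#'   `ref`, `alt`.
#' @param ids character vector of individual ids (default rownames or I1..In).
#' @param groups optional named character vector mapping id -> group label.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, ids = NULL, groups = NULL) {
  geno <- as.matrix(geno)
  if (is.null(ids)) ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("I%03d", seq_len(nrow(geno)))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!all(c("chrom", "bp") %in% names(sites)))
    .stopf("sites need 'chrom' and 'bp' columns")
  sites$chrom <- as.character(sites$chrom)
  if (is.null(sites$cM)) sites$cM <- NA_real_
  if (is.null(sites$ref)) sites$ref <- "A"
  if (is.null(sites$alt)) sites$alt <- "G"
  storage.mode(geno) <- "integer"
  dimnames(geno) <- NULL
  gm <- structure(list(ids = as.character(ids), sites = sites, geno = geno,
                       groups = groups),
                  class = "genotype_matrix")
  gm$sites$p <- allele_freq(gm)
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype matrix
#'
#' Checks the structural invariants: genotype codes in \{0,1,2,NA\}, sites
#' sorted by (chromosome, bp), cM non-decreasing within chromosome, allele
#' frequencies in [0,1] and consistent with the genotypes.
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly; errors on violation.
#' @export
validate_genotype_matrix <- function(gm) {
  s <- gm$sites
  if (nrow(gm$geno) != length(gm$ids)) .stopf("ids/geno row mismatch")
  if (ncol(gm$geno) != nrow(s)) .stopf("sites/geno column mismatch")
  ok <- gm$geno %in% c(0L, 1L, 2L) | is.na(gm$geno)
  if (!all(ok)) .stopf("genotype entries outside {0,1,2,NA}")
  for (ch in unique(s$chrom)) {
    sel <- s$chrom == ch
    if (is.unsorted(s$bp[sel], strictly = FALSE))
      .stopf("sites not sorted by bp on chromosome '%s' (first offender near bp=%s)",
             ch, s$bp[sel][which(diff(s$bp[sel]) < 0)[1L] + 1L])
    cm <- s$cM[sel]
    if (!anyNA(cm) && is.unsorted(cm))
      .stopf("cM not non-decreasing on chromosome '%s'", ch)
  }
  ord <- order(match(s$chrom, unique(s$chrom)))
  if (any(ord != seq_len(nrow(s)))) .stopf("chromosome blocks interleaved")
  if (any(s$p < 0 | s$p > 1, na.rm = TRUE)) .stopf("allele frequency outside [0,1]")
  p2 <- allele_freq(gm)
  if (any(abs(p2 - s$p) > 1e-12, na.rm = TRUE))
    .stopf("stored allele frequencies inconsistent with genotypes")
  invisible(gm)
}

#' Alt-allele frequencies from non-missing genotypes
#' @param gm a `genotype_matrix`.
#' @return numeric vector, `NaN` for all-missing sites.
#' @export
allele_freq <- function(gm) colMeans(gm$geno, na.rm = TRUE) / 2

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d sites on %d chromosome(s)%s\n",
              length(x$ids), nrow(x$sites), length(unique(x$sites$chrom)),
              if (!is.null(x$groups)) sprintf(", %d group(s)",
                                              length(unique(x$groups))) else ""))
  invisible(x)
}

#' Number of individuals / sites
#' @param gm a `genotype_matrix`.
#' @return integer.
#' @export
n_individuals <- function(gm) length(gm$ids)

#' @rdname n_individuals
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Subset sites of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @param keep logical or integer index over sites.
#' @return a `genotype_matrix`.
#' @export
subset_sites <- function(gm, keep) {
  gm$geno <- gm$geno[, keep, drop = FALSE]
  gm$sites <- gm$sites[keep, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm
}

#' Subset individuals of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @param ids character ids to keep (order preserved as given).
#' @return a `genotype_matrix`; allele frequencies are recomputed.
#' @export
subset_individuals <- function(gm, ids) {
  idx <- match(ids, gm$ids)
  if (anyNA(idx)) .stopf("unknown individual id(s): %s",
                         paste(ids[is.na(idx)], collapse = ", "))
  gm$geno <- gm$geno[idx, , drop = FALSE]
  gm$ids <- gm$ids[idx]
  if (!is.null(gm$groups)) gm$groups <- gm$groups[ids]
  gm$sites$p <- allele_freq(gm)
  gm
}

#' Read a diploid genotype panel
#'
#' VCF input is parsed with the vcfR package; only the GT field is used.
#' Multiallelic and non-SNP records are skipped with a message. The TSV
#' dialect is a matrix file with header `#id <site_1> ...` and one row per
#' individual (codes 0/1/2/NA), plus a companion sites file
#' (`chrom bp cM ref alt`) found at `sites_path`.
#'
#' @param path genotype file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by extension).
#' @param sites_path companion sites TSV for `format = "tsv"`
#'   (default `paste0(path, ".sites")`).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           sites_path = paste0(path, ".sites")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("genotype file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") .read_genotypes_vcf(path) else
    .read_genotypes_tsv(path, sites_path)
}

.read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  n_skip <- sum(!snp)
  if (n_skip > 0L) .msgf("read_genotypes: skipped %d multiallelic/non-SNP record(s)", n_skip)
  if (!any(snp)) .stopf("no usable biallelic SNP records in %s", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  alleles <- substr(gt, 1L, 1L); alleles2 <- substr(gt, 3L, 3L)
  g <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  okc <- alleles %in% c("0", "1") & alleles2 %in% c("0", "1")
  g[okc] <- as.integer(alleles[okc]) + as.integer(alleles2[okc])
  sites <- data.frame(chrom = fix[snp, "CHROM"],
                      bp = as.numeric(fix[snp, "POS"]),
                      cM = NA_real_, ref = ref[snp], alt = alt[snp],
                      stringsAsFactors = FALSE)
  genotype_matrix(t(g), sites, ids = colnames(gt))
}

.read_genotypes_tsv <- function(path, sites_path) {
  if (!file.exists(sites_path)) .stopf("sites file not found: %s", sites_path)
  header <- strsplit(sub("^#", "", readLines(path, n = 1L)), "\t")[[1L]]
  tab <- utils::read.table(path, header = FALSE, sep = "\t", skip = 1L,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = c("character", rep("integer", length(header) - 1L)))
  st <- utils::read.table(sites_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  g <- as.matrix(tab[, -1L, drop = FALSE])
  if (ncol(g) != nrow(st)) .stopf("genotype/sites dimension mismatch")
  genotype_matrix(g, st, ids = tab[[1L]])
}

#' Write a genotype panel in the TSV dialect
#'
#' Writes the genotype matrix (`#id` header row) and a companion sites file.
#' The pair round-trips losslessly through [read_genotypes()].
#'
#' @param gm a `genotype_matrix`.
#' @param path output path; sites go to `paste0(path, ".sites")`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#id", sprintf("site_%d", seq_len(n_sites(gm)))),
                   collapse = "\t"), con)
  body <- apply(gm$geno, 1L, function(r) paste(ifelse(is.na(r), "NA", r),
                                               collapse = "\t"))
  writeLines(paste(gm$ids, body, sep = "\t"), con)
  st <- data.frame(chrom = gm$sites$chrom, bp = .fmt_num(gm$sites$bp),
                   cM = .fmt_num(gm$sites$cM), ref = gm$sites$ref,
                   alt = gm$sites$alt)
  utils::write.table(st, paste0(path, ".sites"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Attach genetic-map coordinates to a genotype matrix
#'
#' Sets each site's cM by linear interpolation between flanking map anchors;
#' sites outside the anchor span clamp to the terminal anchor's cM.
#' Preserves site count and order.
#'
#' @param gm a `genotype_matrix`.
#' @param map a `genetic_map` covering every chromosome present.
#' @return `gm` with `sites$cM` filled in.
#' @export
attach_genetic_map <- function(gm, map) {
  gm$sites$cM <- map_cm_at(map, gm$sites$chrom, gm$sites$bp)
  validate_genotype_matrix(gm)
  gm
}

#' Site-level filter configuration
#'
#' Defaults mirror the common aDNA imputed-panel filters: per-site
#' missingness at most 2\%, minor allele frequency at least 5\%, and LD
#' pruning in sliding windows of 50 SNPs advanced by 2 with an r^2 ceiling.
#'
#' @param max_missingness maximum fraction of missing calls per site.
#' @param min_maf minimum minor allele frequency.
#' @param ld_window_snps window size in SNPs for LD pruning.
#' @param ld_step_snps window step in SNPs.
#' @param ld_r2_max maximum pairwise genotype r^2 within a window.
#' @return object of class `site_filter_config`.
#' @export
site_filter_config <- function(max_missingness = 0.02, min_maf = 0.05,
                               ld_window_snps = 50L, ld_step_snps = 2L,
                               ld_r2_max = 0.5) {
  stopifnot(max_missingness >= 0, max_missingness <= 1,
            min_maf >= 0, min_maf <= 1,
            ld_window_snps >= ld_step_snps, ld_step_snps >= 1)
  structure(list(max_missingness = max_missingness, min_maf = min_maf,
                 ld_window_snps = as.integer(ld_window_snps),
                 ld_step_snps = as.integer(ld_step_snps),
                 ld_r2_max = ld_r2_max),
            class = "site_filter_config")
}

#' Missingness and MAF site filters
#'
#' Removes sites with missingness above `cfg$max_missingness`, then sites
#' with minor allele frequency below `cfg$min_maf`. Order-stable and
#' idempotent. Counts removed per criterion are reported as a message and
#' attached as attribute `"removed"`.
#'
#' @param gm a `genotype_matrix`.
#' @param cfg a [site_filter_config()].
#' @return filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm, cfg = site_filter_config()) {
  miss <- colMeans(is.na(gm$geno))
  keep1 <- miss <= cfg$max_missingness
  n_miss <- sum(!keep1)
  gm2 <- subset_sites(gm, keep1)
  maf <- pmin(gm2$sites$p, 1 - gm2$sites$p)
  keep2 <- !is.na(maf) & maf >= cfg$min_maf
  n_maf <- sum(!keep2)
  gm2 <- subset_sites(gm2, keep2)
  if (n_sites(gm2) == 0L) .stopf("filter_sites removed all sites")
  .msgf("filter_sites: removed %d site(s) for missingness, %d for MAF; %d remain",
        n_miss, n_maf, n_sites(gm2))
  attr(gm2, "removed") <- c(missingness = n_miss, maf = n_maf)
  gm2
}

#' Sliding-window LD pruning
#'
#' Windows of `ld_window_snps` consecutive sites advanced by `ld_step_snps`
#' per chromosome; within each window the later member of any pair with
#' genotype correlation r^2 above `ld_r2_max` is dropped greedily until no
#' such pair remains. Deterministic given input order; missing genotypes are
#' excluded pairwise from the correlations.
#'
#' @param gm a `genotype_matrix`.
#' @param cfg a [site_filter_config()].
#' @return pruned `genotype_matrix`.
#' @export
ld_prune <- function(gm, cfg = site_filter_config()) {
  keep <- rep(TRUE, n_sites(gm))
  W <- cfg$ld_window_snps; S <- cfg$ld_step_snps
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    n <- length(idx)
    starts <- if (n <= W) 1L else unique(c(seq(1L, n - W + 1L, by = S), n - W + 1L))
    for (s in starts) {
      win <- idx[s:min(s + W - 1L, n)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      x <- gm$geno[, win, drop = FALSE]
      r2 <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))^2
      for (i in seq_len(length(win) - 1L)) {
        if (!keep[win[i]]) next
        for (j in seq((i + 1L), length(win))) {
          if (keep[win[j]] && !is.na(r2[i, j]) && r2[i, j] > cfg$ld_r2_max)
            keep[win[j]] <- FALSE
        }
      }
    }
  }
  out <- subset_sites(gm, keep)
  attr(out, "removed") <- c(ld = sum(!keep))
  out
}

#' Read a group assignment table
#' @param path TSV with columns `individual_id`, `group_label` (header
#'   optional).
#' @return named character vector id -> group.
#' @export
read_groups <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("individual|group|id", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}
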