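#' Genetic map objects
#'
#' A genetic map is an ordered table of anchor points per chromosome giving
#' the cumulative genetic position (cM) at physical positions (bp). Within a
#' chromosome anchors are strictly increasing in bp and non-decreasing in cM.
#' The map provides the cM coordinate used throughout: meiosis simulation,
#' ROH/IBD segment lengths, F_ROH denominators and the Ne likelihood all work
#' in genetic distance.
#'
#' @param chrom character vector of chromosome labels (one per anchor).
#' @param bp numeric vector of physical anchor positions (1-based, >= 0).
#' @param cM numeric vector of genetic anchor positions in centiMorgans.
#' @return An object of class `genetic_map`: a data.frame with columns
#'   `chrom`, `bp`, `cM`.
#' @examples
#' gmap <- genetic_map(rep("1", 2), c(1, 2e6), c(0, 2))
#' map_lengths(gmap)
#' @export
genetic_map <- function(chrom, bp, cM) {
  stopifnot(length(chrom) == length(bp), length(bp) == length(cM))
  chrom <- as.character(chrom)
  map <- data.frame(chrom = chrom, bp = as.numeric(bp), cM = as.numeric(cM),
                    stringsAsFactors = FALSE)
  map <- map[order(match(map$chrom, unique(map$chrom)), map$bp), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2L)
      .stopf("genetic_map: chromosome '%s' needs >= 2 anchors", ch)
    if (any(diff(sub$bp) <= 0))
      .stopf("genetic_map: anchors on chromosome '%s' not strictly increasing in bp", ch)
    if (any(diff(sub$cM) < 0))
      .stopf("genetic_map: cM not non-decreasing on chromosome '%s'", ch)
    if (any(sub$bp < 0) || any(sub$cM < 0))
      .stopf("genetic_map: negative coordinates on chromosome '%s'", ch)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  len <- map_lengths(x)
  cat(sprintf("<genetic_map> %d chromosome(s), %.1f cM total\n",
              length(len), sum(len)))
  invisible(x)
}

#' Chromosome labels of a genetic map
#' @param map a `genetic_map`.
#' @return character vector in map order.
#' @export
map_chromosomes <- function(map) unique(map$chrom)

#' Genetic length per chromosome
#' @param map a `genetic_map`.
#' @return named numeric vector of cM lengths (last minus first anchor).
#' @export
map_lengths <- function(map) {
  vapply(map_chromosomes(map), function(ch) {
    v <- map$cM[map$chrom == ch]
    v[length(v)] - v[1L]
  }, numeric(1))
}

#' Build a uniform-rate genetic map
#'
#' One anchor pair per chromosome, linear bp<->cM at `bp_per_cM`.
#'
#' @param lengths_cM named (or unnamed) numeric vector of chromosome lengths
#'   in cM; unnamed chromosomes are labelled "1", "2", ...
#' @param bp_per_cM physical bases per centiMorgan (default 1e6, i.e. 1 cM/Mb).
#' @return a `genetic_map`.
#' @export
uniform_map <- function(lengths_cM, bp_per_cM = 1e6) {
  labs <- names(lengths_cM)
  if (is.null(labs)) labs <- as.character(seq_along(lengths_cM))
  genetic_map(chrom = rep(labs, each = 2L),
              bp = as.vector(rbind(1, lengths_cM * bp_per_cM)),
              cM = as.vector(rbind(0, lengths_cM)))
}

#' Approximate human autosomal genetic map
#'
#' Uniform-rate map over 22 autosomes with approximate sex-averaged genetic
#' lengths totalling about 35.9 Morgans. This is a synthetic stand-in for a
#' refined empirical map: adequate for simulation studies where only total
#' map length and chromosome count matter, not fine-scale rate variation.
#'
#' @param bp_per_cM physical bases per cM (default 1e6).
#' @return a `genetic_map`.
#' @export
human_autosomes <- function(bp_per_cM = 1e6) {
  len <- c(286.3, 268.6, 232.8, 214.2, 209.2, 194.1, 187.2, 169.7, 167.2,
           174.1, 161.1, 176.1, 131.9, 125.2, 132.4, 133.8, 137.3, 129.5,
           111.1, 114.8, 70.1, 79.1)
  names(len) <- as.character(1:22)
  uniform_map(len, bp_per_cM = bp_per_cM)
}

#' Read a genetic map from TSV
#'
#' Expects columns `chrom, bp, rate_cM_per_Mb, cM` or `chrom, bp, cM`; an
#' optional rate column is ignored. A header line is detected automatically.
#'
#' @param path file path.
#' @return a `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) .stopf("map file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) == 4L) tab <- tab[, c(1L, 2L, 4L)]
  if (ncol(tab) != 3L) .stopf("map TSV must have 3 or 4 columns, found %d", ncol(tab))
  genetic_map(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Write a genetic map to TSV
#' @param map a `genetic_map`.
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  out <- data.frame(chrom = map$chrom, bp = .fmt_num(map$bp),
                    cM = .fmt_num(map$cM))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation between flanking anchors; positions outside the
#' anchor span clamp to the terminal anchor's cM.
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome label (scalar or vector parallel to `bp`).
#' @param bp physical positions.
#' @return numeric cM positions.
#' @export
map_cm_at <- function(map, chrom, bp) {
  chrom <- as.character(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(bp))
  stopifnot(length(chrom) == length(bp))
  bad <- setdiff(unique(chrom), map_chromosomes(map))
  if (length(bad))
    .stopf("chromosome(s) absent from map: %s", paste(bad, collapse = ", "))
  out <- numeric(length(bp))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- map[map$chrom == ch, , drop = FALSE]
    out[sel] <- stats::approx(sub$bp, sub$cM, xout = bp[sel], rule = 2,
                              ties = "ordered")$y
  }
  out
}

#' Interpolate physical position (bp) at genetic positions
#'
#' Inverse of [map_cm_at()]; where the map is flat (zero recombination) the
#' first bp attaining the cM value is returned. Values outside the anchor
#' span clamp to the terminal anchor.
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome label (scalar or vector).
#' @param cM genetic positions.
#' @return numeric bp positions.
#' @export
map_bp_at <- function(map, chrom, cM) {
  chrom <- as.character(chrom)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(cM))
  stopifnot(length(chrom) == length(cM))
  out <- numeric(length(cM))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- map[map$chrom == ch, , drop = FALSE]
    out[sel] <- stats::approx(sub$cM, sub$bp, xout = cM[sel], rule = 2,
                              ties = min)$y
  }
  out
}

# Concatenated cM axis over all chromosomes of a map; the simulator and
# ancestry mosaics live on this axis. offsets[i] is the global cM at the
# start of chromosome i.
.map_axis <- function(map) {
  len <- map_lengths(map)
  off <- c(0, cumsum(len))[seq_along(len)]
  names(off) <- names(len)
  list(chrom = names(len), len = unname(len), offset = unname(off),
       total = sum(len),
       cm0 = vapply(names(len), function(ch) map$cM[map$chrom == ch][1L],
                    numeric(1)))
}

# global axis position -> (chrom index, chromosome-local map cM)
.axis_locate <- function(axis, pos) {
  ci <- findInterval(pos, c(axis$offset, axis$total), rightmost.closed = TRUE)
  ci[ci > length(axis$chrom)] <- length(axis$chrom)
  list(chrom_idx = ci, cM = pos - axis$offset[ci] + axis$cm0[ci])
}
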