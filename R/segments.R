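#' Segment tables
#'
#' ROH and IBD calls share one tabular representation: one row per maximal
#' genomic interval with 1-based inclusive bp endpoints, cM endpoints, SNP
#' count, and for IBD a LOD score and an ordered individual pair (`id2` is
#' `NA` for ROH).
#'
#' @param kind "ROH" or "IBD".
#' @param id1,id2 individual ids (`id2 = NA` for ROH).
#' @param chrom chromosome label.
#' @param start_bp,end_bp 1-based inclusive physical endpoints.
#' @param start_cM,end_cM genetic endpoints.
#' @param n_snps number of SNPs supporting the segment.
#' @param lod LOD score (IBD) or `NA`.
#' @return data.frame of class `segment_frame` with a computed `length_cM`.
#' @export
segment_frame <- function(kind = character(), id1 = character(),
                          id2 = NA_character_, chrom = character(),
                          start_bp = numeric(), end_bp = numeric(),
                          start_cM = numeric(), end_cM = numeric(),
                          n_snps = integer(), lod = NA_real_) {
  n <- max(length(chrom), length(start_bp), length(end_bp),
           length(start_cM), length(n_snps))
  if (length(chrom) == 0L) n <- 0L
  df <- data.frame(kind = rep_len(as.character(kind), n),
                   id1 = rep_len(as.character(id1), n),
                   id2 = rep_len(as.character(id2), n),
                   chrom = rep_len(as.character(chrom), n),
                   start_bp = as.numeric(start_bp), end_bp = as.numeric(end_bp),
                   start_cM = as.numeric(start_cM), end_cM = as.numeric(end_cM),
                   n_snps = as.integer(rep_len(n_snps, n)),
                   lod = as.numeric(rep_len(lod, n)),
                   stringsAsFactors = FALSE)
  df$length_cM <- df$end_cM - df$start_cM
  if (n > 0L) {
    if (any(df$end_bp <= df$start_bp)) .stopf("segment with end_bp <= start_bp")
    if (any(df$length_cM < 0)) .stopf("segment with negative cM length")
    if (any(df$n_snps < 1L)) .stopf("segment with n_snps < 1")
  }
  class(df) <- c("segment_frame", "data.frame")
  df
}

#' @export
rbind.segment_frame <- function(...) {
  out <- do.call(rbind.data.frame, lapply(list(...), function(x) {
    class(x) <- "data.frame"; x
  }))
  class(out) <- c("segment_frame", "data.frame")
  rownames(out) <- NULL
  out
}

.empty_segments <- function() segment_frame()

#' Write segments as BED-style TSV
#'
#' Columns `chrom, start0, end0, kind, id_or_pair, length_cM, n_snps, lod`
#' with 0-based half-open physical coordinates, sorted by
#' (chromosome, start). Numeric fields are written at full precision so the
#' file round-trips exactly through [read_segments()].
#'
#' @param segments a `segment_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  df <- as.data.frame(segments)
  ord <- order(match(df$chrom, unique(df$chrom)), df$start_bp)
  df <- df[ord, , drop = FALSE]
  out <- data.frame(chrom = df$chrom,
                    start0 = .fmt_num(df$start_bp - 1),
                    end0 = .fmt_num(df$end_bp),
                    kind = df$kind,
                    id_or_pair = ifelse(is.na(df$id2), df$id1,
                                        paste0(df$id1, "|", df$id2)),
                    length_cM = .fmt_num(df$length_cM),
                    n_snps = df$n_snps,
                    lod = .fmt_num(df$lod))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

#' Read a BED-style segment TSV written by [write_segments()]
#' @param path input path.
#' @return data.frame with the file's fields plus 1-based `start_bp`/`end_bp`.
#' @export
read_segments <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "character", "numeric",
                                          "integer", "numeric"))
  tab$start_bp <- tab$start0 + 1
  tab$end_bp <- tab$end0
  pair <- strsplit(tab$id_or_pair, "|", fixed = TRUE)
  tab$id1 <- vapply(pair, `[`, character(1), 1L)
  tab$id2 <- vapply(pair, function(x) if (length(x) > 1L) x[2L] else NA_character_,
                    character(1))
  tab
}
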