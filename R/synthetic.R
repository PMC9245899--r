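# Synthetic diploid panels with known demography and ground truth.
#
# Haplotypes are represented internally as founder-ancestry mosaics: matrices
# with columns (start, end, founder) on a concatenated cM axis over all
# chromosomes. Meiosis splices two parental mosaics at Poisson-sampled
# crossovers, so gene dropping costs O(#segments) per transmission and
# alleles are materialised from the founder panel only when a genotype
# matrix is needed. This also gives exact ancestry ground truth: true ROH
# and IBD segments are intervals where two mosaics carry the same founder.

#' Founder haplotype panel
#'
#' @param alleles 0/1 integer matrix, haplotypes in rows, sites in columns.
#' @param sites site table (`chrom`, `bp`, `cM`, `ref`, `alt`).
#' @param freq the per-site allele frequencies the panel was drawn from
#'   (optional).
#' @return object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, sites, freq = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (any(is.na(alleles)) || !all(alleles %in% c(0L, 1L)))
    .stopf("haplotype panel alleles must be concrete 0/1")
  if (ncol(alleles) != nrow(sites)) .stopf("alleles/sites dimension mismatch")
  structure(list(alleles = alleles, sites = as.data.frame(sites),
                 freq = freq, n_hap = nrow(alleles)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d sites\n",
              x$n_hap, nrow(x$sites)))
  invisible(x)
}

#' Simulate founder haplotypes
#'
#' Site positions are evenly spaced in cM along each chromosome of `map`.
#' Allele frequencies are drawn from a Beta distribution truncated to
#' `maf_range` (default [0.05, 0.95]), emulating a common-SNP panel after
#' MAF filtering; founder alleles are then drawn independently per site, so
#' founders carry no inbreeding, relatedness or structure.
#'
#' @param n_haplotypes even number >= 4.
#' @param n_sites_per_chrom scalar or per-chromosome vector of site counts.
#' @param map a `genetic_map`.
#' @param freq_beta_params shape1/shape2 of the Beta frequency distribution.
#' @param seed RNG seed.
#' @param maf_range truncation interval for the allele frequency.
#' @return a `haplotype_panel`.
#' @export
make_founders <- function(n_haplotypes, n_sites_per_chrom, map,
                          freq_beta_params = c(1, 1), seed = NULL,
                          maf_range = c(0.05, 0.95)) {
  if (n_haplotypes %% 2L != 0L || n_haplotypes < 4L)
    .stopf("n_haplotypes must be even and >= 4")
  if (length(freq_beta_params) != 2L || any(!is.finite(freq_beta_params)) ||
      any(freq_beta_params <= 0))
    .stopf("invalid Beta parameters")
  chroms <- map_chromosomes(map)
  lens <- map_lengths(map)
  nsites <- rep_len(n_sites_per_chrom, length(chroms))
  .with_seed(seed, {
    site_list <- lapply(seq_along(chroms), function(ci) {
      n <- nsites[ci]
      cm0 <- map$cM[map$chrom == chroms[ci]][1L]
      cm <- cm0 + (seq_len(n) - 0.5) / n * lens[ci]
      bp <- cummax(round(map_bp_at(map, chroms[ci], cm)))
      bp <- bp + cumsum(c(0, as.numeric(diff(bp) == 0)))
      data.frame(chrom = chroms[ci], bp = bp, cM = cm,
                 ref = "A", alt = "G", stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, site_list)
    ns <- nrow(sites)
    a <- freq_beta_params[1L]; b <- freq_beta_params[2L]
    u <- stats::runif(ns, stats::pbeta(maf_range[1L], a, b),
                      stats::pbeta(maf_range[2L], a, b))
    p <- stats::qbeta(u, a, b)
    alleles <- matrix(stats::rbinom(n_haplotypes * ns, 1L, rep(p, each = n_haplotypes)),
                      nrow = n_haplotypes)
    haplotype_panel(alleles, sites, freq = p)
  })
}

# global cM coordinate of each site on the concatenated axis
.site_gcm <- function(sites, axis) {
  ci <- match(sites$chrom, axis$chrom)
  axis$offset[ci] + (sites$cM - axis$cm0[ci])
}

# Draw one meiosis: crossover count per chromosome ~ Poisson(len/100 Morgans),
# positions uniform in cM; parental phase alternates at crossovers and is
# re-randomised at each chromosome start.
.draw_meiosis_cuts <- function(axis) {
  nc <- length(axis$len)
  k <- stats::rpois(nc, axis$len / 100)
  tot <- sum(k)
  cross <- if (tot > 0L)
    sort.int(rep.int(axis$offset, k) + stats::runif(tot) * rep.int(axis$len, k),
             method = "quick")
  else numeric(0)
  b <- c(axis$offset[-1L], cross)
  type <- c(rep.int(0L, nc - 1L), rep.int(1L, tot))
  o <- order(b, type, method = "radix")
  b <- b[o]; type <- type[o]
  start_ph <- sample.int(2L, nc, replace = TRUE)
  chrom_of_int <- c(1L, cumsum(type == 0L) + 1L)
  ncross_before <- c(0L, cumsum(type == 1L))
  ncs <- ncross_before - ncross_before[match(chrom_of_int, chrom_of_int)]
  phase <- 1L + (start_ph[chrom_of_int] - 1L + ncs) %% 2L
  list(b = b, phase = phase, cross = cross)
}

# Splice two parental mosaics along drawn cuts into a gamete mosaic.
.splice <- function(m1, m2, cuts, axis) {
  lo <- c(0, cuts$b); hi <- c(cuts$b, axis$total)
  keep <- hi > lo
  out <- vector("list", length(lo))
  for (ph in 1:2) {
    m <- if (ph == 1L) m1 else m2
    sel <- which(cuts$phase == ph & keep)
    if (!length(sel)) next
    i1 <- findInterval(lo[sel], m[, 1L])
    i2 <- findInterval(hi[sel], m[, 1L])
    adj <- m[i2, 1L] >= hi[sel]
    i2[adj] <- i2[adj] - 1L
    for (q in seq_along(sel)) {
      rows <- m[i1[q]:i2[q], , drop = FALSE]
      rows[1L, 1L] <- lo[sel[q]]
      rows[nrow(rows), 2L] <- hi[sel[q]]
      out[[sel[q]]] <- rows
    }
  }
  g <- do.call(rbind, out)
  if (!is.null(g) && nrow(g) > 1L) {
    same <- c(FALSE, g[-1L, 3L] == g[-nrow(g), 3L])
    if (any(same)) {
      first <- which(!same)
      last <- c(first[-1L] - 1L, nrow(g))
      g <- cbind(g[first, 1L], g[last, 2L], g[first, 3L])
    }
  }
  g
}

.founder_mosaic <- function(f, axis) matrix(c(0, axis$total, f), 1L, 3L)

# alleles of a mosaic haplotype at the panel sites
.hap_alleles <- function(mosaic, founders, site_gcm) {
  row <- findInterval(site_gcm, mosaic[, 1L])
  f <- mosaic[row, 3L]
  founders$alleles[cbind(f, seq_along(site_gcm))]
}

#' Simulate one meiosis
#'
#' Transmits a recombinant gamete from a pair of parental haplotypes.
#' Crossover counts per chromosome are Poisson with mean equal to the map
#' length in Morgans (no interference), crossover positions are uniform in
#' cM, and the starting parental phase of each chromosome is a fair coin.
#'
#' @param h1,h2 parental allele vectors (0/1) over the same sites.
#' @param sites site table with `chrom` and `cM`.
#' @param map a `genetic_map` covering the sites' chromosomes.
#' @param seed RNG seed.
#' @return list with `alleles` (gamete), `crossovers` (data.frame
#'   `chrom`, `cM`) and `start_phase`.
#' @export
meiosis <- function(h1, h2, sites, map, seed = NULL) {
  if (length(h1) != length(h2) || length(h1) != nrow(sites))
    .stopf("meiosis: parental haplotypes and sites must match")
  axis <- .map_axis(map)
  .with_seed(seed, {
    cuts <- .draw_meiosis_cuts(axis)
    gcm <- .site_gcm(sites, axis)
    iv <- findInterval(gcm, cuts$b) + 1L
    ph <- cuts$phase[iv]
    loc <- if (length(cuts$cross)) .axis_locate(axis, cuts$cross) else
      list(chrom_idx = integer(0), cM = numeric(0))
    list(alleles = ifelse(ph == 1L, h1, h2),
         crossovers = data.frame(chrom = axis$chrom[loc$chrom_idx],
                                 cM = loc$cM, stringsAsFactors = FALSE),
         start_phase = cuts$phase[1L])
  })
}

#' Demographic trajectory for the simulator
#'
#' @param sizes diploid population sizes indexed from generation 0 (present)
#'   back to generation G (founders): a vector (same size in every deme) or
#'   a (G+1) x n_demes matrix of per-deme sizes.
#' @param n_demes number of demes.
#' @param migration per-generation probability that an offspring's parents
#'   are drawn from another deme.
#' @return object of class `ne_trajectory`.
#' @export
ne_trajectory <- function(sizes, n_demes = 1L, migration = 0) {
  n_demes <- as.integer(n_demes)
  if (is.matrix(sizes)) {
    if (ncol(sizes) != n_demes) .stopf("sizes matrix needs n_demes columns")
  } else {
    sizes <- matrix(as.integer(sizes), ncol = 1L)[, rep(1L, n_demes),
                                                  drop = FALSE]
  }
  storage.mode(sizes) <- "integer"
  if (any(sizes < 2)) .stopf("population sizes must be >= 2")
  if (migration < 0 || migration >= 1) .stopf("migration must be in [0, 1)")
  structure(list(sizes = sizes, n_demes = n_demes, migration = migration),
            class = "ne_trajectory")
}

#' Forward-in-time gene dropping over a demographic trajectory
#'
#' Wright-Fisher diploid random mating: each offspring draws two distinct
#' random parents within its deme (selfing disallowed); with probability
#' `migration` the parents come from a uniformly chosen other deme. Founder
#' haplotypes populate the oldest generation; every transmission is a
#' [meiosis()]. The present generation is returned as unphased genotypes
#' with full founder-ancestry mosaics as ground truth.
#'
#' @param founders a `haplotype_panel` with at least
#'   `2 * sizes[G+1] * n_demes` haplotypes.
#' @param traj an [ne_trajectory()].
#' @param map a `genetic_map` matching the founder sites.
#' @param seed RNG seed.
#' @param n_sample number of present-day individuals to return per deme
#'   (default: all).
#' @return list with `genotypes` (a `genotype_matrix` with deme group
#'   labels) and `truth` (an `ancestry_truth`).
#' @export
simulate_population <- function(founders, traj, map, seed = NULL,
                                n_sample = NULL) {
  axis <- .map_axis(map)
  sizes <- traj$sizes
  G <- nrow(sizes) - 1L
  nd <- traj$n_demes
  m <- traj$migration
  n_need <- 2L * sum(sizes[G + 1L, ])
  if (founders$n_hap < n_need)
    .stopf("need %d founder haplotypes for generation %d (%d supplied)",
           n_need, G, founders$n_hap)
  .with_seed(seed, {
    # oldest generation: founder haplotypes paired into individuals
    pop <- vector("list", nd)
    h <- 0L
    for (d in seq_len(nd)) {
      pop[[d]] <- lapply(seq_len(sizes[G + 1L, d]), function(i) {
        list(.founder_mosaic(h + 2L * i - 1L, axis),
             .founder_mosaic(h + 2L * i, axis))
      })
      h <- h + 2L * sizes[G + 1L, d]
    }
    if (G >= 1L) for (g in seq(G - 1L, 0L)) {
      newpop <- vector("list", nd)
      for (d in seq_len(nd)) {
        N <- sizes[g + 1L, d]
        offs <- vector("list", N)
        src_all <- rep(d, N)
        if (nd > 1L && m > 0) {
          mig <- stats::runif(N) < m
          if (any(mig))
            src_all[mig] <- vapply(which(mig), function(i)
              sample(setdiff(seq_len(nd), d), 1L), integer(1))
        }
        for (i in seq_len(N)) {
          src <- pop[[src_all[i]]]
          par <- sample.int(length(src), 2L)
          p1 <- src[[par[1L]]]; p2 <- src[[par[2L]]]
          offs[[i]] <- list(
            .splice(p1[[1L]], p1[[2L]], .draw_meiosis_cuts(axis), axis),
            .splice(p2[[1L]], p2[[2L]], .draw_meiosis_cuts(axis), axis))
        }
        newpop[[d]] <- offs
      }
      pop <- newpop
    }
    # sample and materialise the present generation
    keep <- lapply(seq_len(nd), function(d) {
      n <- length(pop[[d]])
      if (is.null(n_sample) || n_sample >= n) seq_len(n)
      else sort(sample.int(n, n_sample))
    })
    ids <- unlist(lapply(seq_len(nd), function(d)
      sprintf("D%d_I%03d", d, seq_along(keep[[d]]))))
    demes <- unlist(lapply(seq_len(nd), function(d)
      rep(sprintf("deme%d", d), length(keep[[d]]))))
    gcm <- .site_gcm(founders$sites, axis)
    haps <- list()
    geno <- matrix(NA_integer_, nrow = length(ids), ncol = nrow(founders$sites))
    r <- 0L
    for (d in seq_len(nd)) for (i in keep[[d]]) {
      r <- r + 1L
      ind <- pop[[d]][[i]]
      haps[[ids[r]]] <- ind
      geno[r, ] <- .hap_alleles(ind[[1L]], founders, gcm) +
        .hap_alleles(ind[[2L]], founders, gcm)
    }
    gm <- genotype_matrix(geno, founders$sites, ids = ids,
                          groups = stats::setNames(demes, ids))
    truth <- structure(list(haps = haps, map = map, axis = axis,
                            sites = founders$sites),
                       class = "ancestry_truth")
    list(genotypes = gm, truth = truth)
  })
}

#' @export
print.ancestry_truth <- function(x, ...) {
  cat(sprintf("<ancestry_truth> %d individuals, %.1f cM axis\n",
              length(x$haps), x$axis$total))
  invisible(x)
}

# intervals (global axis) where two mosaics carry the same founder,
# broken at chromosome boundaries
.mosaic_match <- function(m1, m2, axis) {
  cutp <- sort(unique(c(0, m1[, 1L], m2[, 1L], axis$offset, axis$total)))
  cutp <- cutp[cutp < axis$total]
  f1 <- m1[findInterval(cutp, m1[, 1L]), 3L]
  f2 <- m2[findInterval(cutp, m2[, 1L]), 3L]
  state <- f1 == f2
  ci <- findInterval(cutp, axis$offset)
  grp <- cumsum(c(TRUE, state[-1L] != state[-length(state)] |
                    ci[-1L] != ci[-length(ci)]))
  ends <- c(cutp[-1L], axis$total)
  keep <- which(state)
  if (!length(keep)) return(matrix(numeric(0), 0L, 2L))
  g <- grp[keep]
  first <- keep[!duplicated(g)]
  last <- keep[!duplicated(g, fromLast = TRUE)]
  cbind(cutp[first], ends[last])
}

# merge possibly overlapping intervals (rows sorted by start), then split
# the result at chromosome boundaries so no interval spans two chromosomes
.interval_union <- function(iv, axis = NULL) {
  if (nrow(iv) > 1L) {
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    out <- iv[1L, , drop = FALSE]
    for (k in 2:nrow(iv)) {
      if (iv[k, 1L] <= out[nrow(out), 2L])
        out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[k, 2L])
      else out <- rbind(out, iv[k, , drop = FALSE])
    }
    iv <- out
  }
  if (is.null(axis) || nrow(iv) == 0L) return(iv)
  pieces <- lapply(seq_len(nrow(iv)), function(k) {
    cuts <- axis$offset[axis$offset > iv[k, 1L] & axis$offset < iv[k, 2L]]
    b <- c(iv[k, 1L], cuts, iv[k, 2L])
    cbind(b[-length(b)], b[-1L])
  })
  do.call(rbind, pieces)
}

#' True identity segments from ancestry ground truth
#'
#' Maximal intervals where the chosen haplotype mosaics carry the same
#' founder haplotype. With `id_i == id_j` this is the individual's true ROH
#' (autozygosity); with distinct ids it is true IBD, taking the union over
#' the four haplotype pairings (IBD1 or more).
#'
#' @param truth an `ancestry_truth`.
#' @param id_i,id_j individual ids.
#' @param min_cM drop intervals shorter than this.
#' @return a `segment_frame` (kind "ROH" or "IBD").
#' @export
true_segments <- function(truth, id_i, id_j = id_i, min_cM = 0) {
  hi <- truth$haps[[id_i]]; hj <- truth$haps[[id_j]]
  if (is.null(hi)) .stopf("unknown individual id '%s'", id_i)
  if (is.null(hj)) .stopf("unknown individual id '%s'", id_j)
  axis <- truth$axis
  if (identical(id_i, id_j)) {
    iv <- .mosaic_match(hi[[1L]], hi[[2L]], axis)
    kind <- "ROH"; id2 <- NA_character_
  } else {
    ivl <- list(.mosaic_match(hi[[1L]], hj[[1L]], axis),
                .mosaic_match(hi[[1L]], hj[[2L]], axis),
                .mosaic_match(hi[[2L]], hj[[1L]], axis),
                .mosaic_match(hi[[2L]], hj[[2L]], axis))
    iv <- .interval_union(do.call(rbind, ivl), axis)
    kind <- "IBD"; id2 <- id_j
  }
  iv <- iv[iv[, 2L] - iv[, 1L] >= min_cM, , drop = FALSE]
  if (!nrow(iv)) return(.empty_segments())
  la <- .axis_locate(axis, iv[, 1L])
  ci <- la$chrom_idx
  start_cM <- la$cM
  end_cM <- iv[, 2L] - axis$offset[ci] + axis$cm0[ci]
  chrom <- axis$chrom[ci]
  gcm <- .site_gcm(truth$sites, axis)
  nsnp <- findInterval(iv[, 2L], gcm) - findInterval(iv[, 1L], gcm)
  segment_frame(kind = kind, id1 = id_i, id2 = id2, chrom = chrom,
                start_bp = map_bp_at(truth$map, chrom, start_cM),
                end_bp = map_bp_at(truth$map, chrom, end_cM) + 1,
                start_cM = start_cM, end_cM = end_cM,
                n_snps = pmax(1L, nsnp))
}

#' True genome fraction shared between two mosaic haplotype sets
#'
#' For `id_j` missing this is the realised (genealogical) inbreeding
#' coefficient of the individual.
#'
#' @param truth an `ancestry_truth`.
#' @param id_i,id_j individual ids.
#' @return fraction in [0, 1].
#' @export
true_fraction <- function(truth, id_i, id_j = id_i) {
  s <- true_segments(truth, id_i, id_j)
  sum(s$end_cM - s$start_cM) / truth$axis$total
}

#' Inject genotyping errors and missingness
#'
#' Each genotype is set missing with `missing_rate`; otherwise each of its
#' two alleles is independently flipped with `miscall_rate`. Allele
#' frequencies are recomputed from the perturbed calls.
#'
#' @param gm a `genotype_matrix`.
#' @param miscall_rate per-allele flip probability in [0, 0.05].
#' @param missing_rate per-genotype dropout probability in [0, 1].
#' @param seed RNG seed.
#' @return perturbed `genotype_matrix`.
#' @export
add_errors <- function(gm, miscall_rate = 0.005, missing_rate = 0,
                       seed = NULL) {
  if (miscall_rate < 0 || miscall_rate > 0.05)
    .stopf("miscall_rate must be in [0, 0.05]")
  if (missing_rate < 0 || missing_rate > 1)
    .stopf("missing_rate must be in [0, 1]")
  .with_seed(seed, {
    g <- gm$geno
    n <- length(g)
    if (missing_rate > 0) g[stats::runif(n) < missing_rate] <- NA_integer_
    if (miscall_rate > 0) {
      obs <- which(!is.na(g))
      gv <- g[obs]
      flip0 <- gv == 0L
      flip2 <- gv == 2L
      flip1 <- gv == 1L
      gv[flip0] <- stats::rbinom(sum(flip0), 2L, miscall_rate)
      gv[flip2] <- 2L - stats::rbinom(sum(flip2), 2L, miscall_rate)
      if (any(flip1))
        gv[flip1] <- 1L + stats::rbinom(sum(flip1), 1L, miscall_rate) -
          stats::rbinom(sum(flip1), 1L, miscall_rate)
      g[obs] <- gv
    }
    gm$geno <- g
    gm$sites$p <- allele_freq(gm)
    gm
  })
}
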