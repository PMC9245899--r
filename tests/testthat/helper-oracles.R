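# Independent brute-force oracles. These deliberately use literal loops and
# direct probability enumeration, sharing no code with the package internals.

# Literal implementation of the window-based ROH semantics on one
# chromosome. Returns a data.frame of kept candidate runs (site indices).
brute_roh <- function(g, bp, p) {
  n <- length(g)
  W <- p$window_snps
  nwin <- n - W + 1L
  if (nwin < 1L) return(data.frame(a = integer(), b = integer()))
  homw <- logical(nwin)
  for (w in seq_len(nwin)) {
    win <- g[w:(w + W - 1L)]
    homw[w] <- sum(win == 1L, na.rm = TRUE) <= p$window_het_max &&
      sum(is.na(win)) <= p$window_missing_max
  }
  inst <- logical(n)
  for (i in seq_len(n)) {
    ws <- max(1L, i - W + 1L):min(nwin, i)
    inst[i] <- mean(homw[ws]) >= p$window_hit_fraction
  }
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!inst[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && inst[j + 1L]) j <- j + 1L
    a <- i
    for (k in seq(i, j)) {
      if (k > a && bp[k] - bp[k - 1L] > p$max_inter_snp_gap_kb * 1000) {
        runs[[length(runs) + 1L]] <- c(a, k - 1L)
        a <- k
      }
    }
    runs[[length(runs) + 1L]] <- c(a, j)
    i <- j + 1L
  }
  keep <- list()
  for (r in runs) {
    nsnp <- r[2L] - r[1L] + 1L
    len_bp <- bp[r[2L]] - bp[r[1L]] + 1
    if (nsnp < p$min_snps) next
    if (len_bp < p$min_length_kb * 1000) next
    if ((len_bp / 1000) / nsnp > p$min_density_kb_per_snp) next
    keep[[length(keep) + 1L]] <- r
  }
  if (!length(keep)) return(data.frame(a = integer(), b = integer()))
  m <- do.call(rbind, keep)
  data.frame(a = m[, 1L], b = m[, 2L])
}

# Enumeration oracle for the single-site IBD LOD: sums explicitly over true
# genotypes, shared/population alleles and per-allele error flips.
oracle_site_lod <- function(g1, g2, p, eps) {
  p_obs_given_alleles <- function(obs, a1, a2) {
    tot <- 0
    for (f1 in 0:1) for (f2 in 0:1) {
      o <- abs(a1 - f1) + abs(a2 - f2)
      if (o == obs)
        tot <- tot + (if (f1) eps else 1 - eps) * (if (f2) eps else 1 - eps)
    }
    tot
  }
  p_obs_given_true <- function(obs, true) {
    alleles <- switch(true + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
    p_obs_given_alleles(obs, alleles[1L], alleles[2L])
  }
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  marg <- function(obs) {
    tot <- 0
    for (t in 0:2) tot <- tot + hwe[t + 1L] * p_obs_given_true(obs, t)
    tot
  }
  den <- marg(g1) * marg(g2)
  num <- 0
  for (a in 0:1) {
    wa <- if (a == 1L) p else 1 - p
    term <- wa
    for (obs in c(g1, g2)) {
      pi <- 0
      for (b in 0:1) {
        wb <- if (b == 1L) p else 1 - p
        pi <- pi + wb * p_obs_given_true(obs, a + b)
      }
      term <- term * pi
    }
    num <- num + term
  }
  log10(num / den)
}

# Monte-Carlo oracle for the expected ROH length density: draw a geometric
# coalescence time, drop Poisson breakpoints at rate 2t per Morgan on each
# chromosome, and tally all maximal segment lengths into bins.
mc_roh_density <- function(ne, G, edges, n_reps, seed) {
  set.seed(seed)
  nb <- length(edges) - 1L
  tot <- numeric(nb)
  tot2 <- numeric(nb)
  for (r in seq_len(n_reps)) {
    cnt <- numeric(nb)
    for (g in G) {
      t <- stats::rgeom(1L, 1 / (2 * ne)) + 1L
      k <- stats::rpois(1L, 2 * t * g)
      lens <- diff(c(0, sort(stats::runif(k, 0, g)), g))
      h <- findInterval(lens, edges)
      h <- h[h >= 1L & h <= nb & lens < edges[nb + 1L]]
      if (length(h)) cnt <- cnt + tabulate(h, nb)
    }
    tot <- tot + cnt
    tot2 <- tot2 + cnt^2
  }
  mean <- tot / n_reps
  se <- sqrt(pmax(tot2 / n_reps - mean^2, 0) / n_reps)
  list(mean = mean, se = se)
}

# analytic bin integrals of the model density by fine trapezoid quadrature
model_bin_integrals <- function(ne, model, edges) {
  vapply(seq_len(length(edges) - 1L), function(b) {
    xs <- seq(edges[b], edges[b + 1L], length.out = 51L)
    y <- expected_roh_density(ne, xs, model)
    sum((y[-1L] + y[-51L]) / 2 * diff(xs))
  }, numeric(1))
}
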