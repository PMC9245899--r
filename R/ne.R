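# Maximum-likelihood constant Ne from the ROH length spectrum.
#
# Model: the two copies of a locus coalesce T generations back with
# geometric probability P(T = t) = (1/(2Ne)) (1 - 1/(2Ne))^(t-1). Conditional
# on t, recombination breakpoints accumulated over the 2t meioses form a
# Poisson process of rate 2t per Morgan, so on a chromosome of G Morgans the
# expected number of maximal homozygous-by-descent segments of length x
# (Morgans) is (2t)^2 (G - x) e^(-2tx) for interior segments plus
# 2 (2t) e^(-2tx) for the two chromosome-edge segments. Summing over t and
# chromosomes gives the expected segment density lambda(x) per genome, and a
# Poisson composite likelihood over narrow length bins yields the MLE and a
# profile-likelihood confidence interval.

#' Configuration of the ROH-spectrum Ne likelihood
#'
#' @param chrom_lengths_cM chromosome map lengths in cM.
#' @param min_len_cM,max_len_cM segment length range used in the fit (cM).
#' @param bin_range length-bin support in Morgans.
#' @param n_bins number of likelihood bins.
#' @param t_max truncation of the coalescence-time sum (generations); the
#'   geometric tail mass beyond `t_max` must be < 1e-6 at the lower Ne
#'   search bound.
#' @param ne_bounds search interval for Ne.
#' @param n_genomes number of genomes contributing segments.
#' @return object of class `roh_ne_model` with a precomputed term matrix.
#' @export
roh_ne_model <- function(chrom_lengths_cM, min_len_cM = 4, max_len_cM = 20,
                         bin_range = c(0.04, 0.5), n_bins = 1000L,
                         t_max = 2000L, ne_bounds = c(10, 1e6),
                         n_genomes = 1L) {
  stopifnot(min_len_cM > 0, min_len_cM < max_len_cM, n_bins >= 2,
            bin_range[1L] > 0, bin_range[1L] < bin_range[2L], t_max >= 1,
            ne_bounds[1L] >= 2, ne_bounds[1L] < ne_bounds[2L])
  tail_mass <- (1 - 1 / (2 * ne_bounds[1L]))^t_max
  if (tail_mass > 1e-6)
    .stopf("t_max=%d leaves geometric tail mass %.2g > 1e-6 at ne=%g",
           t_max, tail_mass, ne_bounds[1L])
  G <- as.numeric(chrom_lengths_cM) / 100
  edges <- seq(bin_range[1L], bin_range[2L], length.out = n_bins + 1L)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  width <- diff(edges)
  # term matrix A[t, b]: segment-count terms independent of Ne
  S1 <- vapply(mids, function(x) sum(pmax(G - x, 0)), numeric(1))
  S0 <- vapply(mids, function(x) sum(G > x), numeric(1))
  tt <- seq_len(t_max)
  A <- outer(tt, mids, function(t, x) exp(-2 * t * x)) *
    (outer((2 * tt)^2, S1) + outer(2 * (2 * tt), S0))
  structure(list(chrom_lengths_cM = as.numeric(chrom_lengths_cM), G = G,
                 min_len_cM = min_len_cM, max_len_cM = max_len_cM,
                 bin_range = bin_range, n_bins = as.integer(n_bins),
                 edges = edges, mids = mids, width = width,
                 t_max = as.integer(t_max), ne_bounds = ne_bounds,
                 n_genomes = as.integer(n_genomes), A = A),
            class = "roh_ne_model")
}

#' @export
print.roh_ne_model <- function(x, ...) {
  cat(sprintf("<roh_ne_model> %d chromosomes (%.1f Morgans), %d bins on [%.2f, %.2f] M, t_max = %d\n",
              length(x$G), sum(x$G), x$n_bins, x$bin_range[1L],
              x$bin_range[2L], x$t_max))
  invisible(x)
}

.geom_pt <- function(ne, t_max) {
  q <- 1 - 1 / (2 * ne)
  (1 / (2 * ne)) * q^(seq_len(t_max) - 1)
}

#' Expected ROH segment density
#'
#' Expected number of homozygous-by-descent segments per genome per Morgan
#' at segment length `x`, under constant diploid effective size `ne`.
#' Chromosomes shorter than `x` contribute zero.
#'
#' @param ne effective population size (>= 2).
#' @param x segment lengths in Morgans.
#' @param model a [roh_ne_model()].
#' @return numeric vector, same length as `x`.
#' @export
expected_roh_density <- function(ne, x, model) {
  if (ne < 2) .stopf("ne must be >= 2")
  pt <- .geom_pt(ne, model$t_max)
  tt <- seq_len(model$t_max)
  vapply(x, function(xi) {
    S1 <- sum(pmax(model$G - xi, 0))
    S0 <- sum(model$G > xi)
    sum(pt * exp(-2 * tt * xi) * ((2 * tt)^2 * S1 + 2 * (2 * tt) * S0))
  }, numeric(1))
}

# expected density at all bin midpoints via the precomputed term matrix
.lambda_bins <- function(ne, model) {
  as.vector(.geom_pt(ne, model$t_max) %*% model$A)
}

#' Poisson composite log-likelihood of a binned ROH spectrum
#'
#' `sum_b k_b log(mu_b) - mu_b` with `mu_b = m * lambda(x_b) * width_b`,
#' up to an additive constant independent of Ne.
#'
#' @param bin_counts integer counts per model bin (pooled over genomes).
#' @param ne candidate effective size.
#' @param model a [roh_ne_model()]; `model$n_genomes` scales the expectation.
#' @return log-likelihood value.
#' @export
roh_loglik <- function(bin_counts, ne, model) {
  if (length(bin_counts) != model$n_bins)
    .stopf("bin_counts must have length n_bins = %d", model$n_bins)
  if (any(bin_counts < 0)) .stopf("negative bin counts")
  mu <- model$n_genomes * .lambda_bins(ne, model) * model$width
  ll <- -sum(mu)
  pos <- bin_counts > 0
  if (any(pos)) {
    if (any(mu[pos] == 0)) return(-Inf)
    ll <- ll + sum(bin_counts[pos] * log(mu[pos]))
  }
  ll
}

#' Bin a pooled segment set onto the model grid
#' @param lengths_cM segment lengths in cM.
#' @param model a [roh_ne_model()].
#' @return integer counts per bin (segments outside the bin support or the
#'   model's min/max length range are dropped).
#' @export
bin_roh_lengths <- function(lengths_cM, model) {
  x <- lengths_cM[lengths_cM >= model$min_len_cM &
                    lengths_cM <= model$max_len_cM] / 100
  k <- findInterval(x, model$edges, rightmost.closed = TRUE)
  tabulate(k[k >= 1L & k <= model$n_bins], nbins = model$n_bins)
}

#' Fit the constant-Ne ROH-spectrum model
#'
#' Pools segments in `[min_len_cM, max_len_cM]` over the supplied genomes,
#' bins them, and maximises the Poisson composite likelihood over log(Ne)
#' by bounded 1-D optimisation (tolerance 1e-4 in log Ne). The 95% CI is the
#' profile-likelihood interval at a drop of 1.92 log-units. Individuals
#' flagged as consanguineous should be excluded via `exclude` before
#' fitting, since recent inbreeding inflates the long-ROH spectrum.
#'
#' @param segments_by_individual named list: one `segment_frame` (or
#'   data.frame with `length_cM`) per genome.
#' @param model a [roh_ne_model()].
#' @param exclude character ids to drop before pooling.
#' @return object of class `ne_roh_fit` with `print`, `summary`, `coef`,
#'   `confint` and `logLik` methods.
#' @export
fit_ne_roh <- function(segments_by_individual, model, exclude = NULL) {
  if (inherits(segments_by_individual, "data.frame"))
    segments_by_individual <- list(genome = segments_by_individual)
  ids <- names(segments_by_individual)
  if (is.null(ids)) ids <- sprintf("genome%d", seq_along(segments_by_individual))
  keep <- !(ids %in% exclude)
  used <- segments_by_individual[keep]
  model$n_genomes <- sum(keep)
  counts <- bin_roh_lengths(
    unlist(lapply(used, function(s) s$length_cM), use.names = FALSE), model)
  n_seg <- sum(counts)
  lb <- log(model$ne_bounds[1L]); ub <- log(model$ne_bounds[2L])
  boundary <- FALSE
  if (n_seg == 0L) {
    .warnf("fit_ne_roh: no usable segments; estimate at upper search bound")
    ne_hat <- model$ne_bounds[2L]
    boundary <- TRUE
    maxll <- roh_loglik(counts, ne_hat, model)
  } else {
    negll <- function(lne) -roh_loglik(counts, exp(lne), model)
    opt <- stats::optimize(negll, c(lb, ub), tol = 1e-4)
    ne_hat <- exp(opt$minimum)
    maxll <- -opt$objective
    if (opt$minimum - lb < 1e-3 || ub - opt$minimum < 1e-3) boundary <- TRUE
  }
  # profile-likelihood CI: drop of 1.92 log-likelihood units
  target <- maxll - 1.92
  prof <- function(lne) roh_loglik(counts, exp(lne), model) - target
  lhat <- log(ne_hat)
  lower <- if (n_seg == 0L || prof(lb) >= 0) model$ne_bounds[1L] else
    exp(stats::uniroot(prof, c(lb, lhat), tol = 1e-5)$root)
  upper <- if (n_seg == 0L || prof(ub) >= 0) model$ne_bounds[2L] else
    exp(stats::uniroot(prof, c(lhat, ub), tol = 1e-5)$root)
  structure(list(ne_hat = ne_hat, ci95 = c(lower = lower, upper = upper),
                 loglik = maxll, model = model, n_segments = n_seg,
                 counts = counts, n_genomes = model$n_genomes,
                 excluded = intersect(ids, exclude), boundary = boundary),
            class = "ne_roh_fit")
}

#' @export
print.ne_roh_fit <- function(x, ...) {
  cat(sprintf("ROH-spectrum Ne estimate: %.0f (95%% CI %.0f-%.0f)%s\n",
              x$ne_hat, x$ci95[1L], x$ci95[2L],
              if (x$boundary) " [at search bound]" else ""))
  cat(sprintf("  %d segments in [%g, %g] cM from %d genome(s)%s\n",
              x$n_segments, x$model$min_len_cM, x$model$max_len_cM,
              x$n_genomes,
              if (length(x$excluded))
                sprintf("; excluded: %s", paste(x$excluded, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
summary.ne_roh_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  max composite log-likelihood: %.3f\n", object$loglik))
  invisible(object)
}

#' @export
coef.ne_roh_fit <- function(object, ...) c(ne = object$ne_hat)

#' @export
confint.ne_roh_fit <- function(object, parm = "ne", level = 0.95, ...) {
  if (level != 0.95)
    .warnf("only the 95%% profile interval is computed")
  matrix(object$ci95, 1L, 2L,
         dimnames = list("ne", c("lower", "upper")))
}

#' @export
logLik.ne_roh_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, class = "logLik")
}

#' Simulate a binned ROH spectrum from the model
#'
#' Draws independent Poisson counts with the model's expected bin means:
#' the parametric-bootstrap generator matching [roh_loglik()].
#'
#' @param ne true effective size.
#' @param model a [roh_ne_model()] (uses `n_genomes`).
#' @param seed RNG seed.
#' @return integer vector of bin counts.
#' @export
simulate_roh_spectrum <- function(ne, model, seed = NULL) {
  mu <- model$n_genomes * .lambda_bins(ne, model) * model$width
  .with_seed(seed, stats::rpois(length(mu), mu))
}

#' Harmonic mean of a population-size trajectory
#'
#' Standard summary of a recent trajectory: `(count) / sum(1/N_g)` over
#' generations `g_start..g_end` inclusive.
#'
#' @param sizes numeric vector of sizes indexed by generation, or a named
#'   vector whose names are generation indices.
#' @param g_start,g_end generation range (defaults 5 and 30).
#' @return harmonic mean.
#' @export
harmonic_mean_ne <- function(sizes, g_start = 5L, g_end = 30L) {
  gen <- if (!is.null(names(sizes))) as.integer(names(sizes))
  else seq_along(sizes) - 1L
  sel <- gen >= g_start & gen <= g_end
  if (sum(sel) != g_end - g_start + 1L)
    .stopf("trajectory does not cover generations %d..%d", g_start, g_end)
  v <- sizes[sel]
  if (any(v <= 0)) .stopf("population sizes must be positive")
  sum(sel) / sum(1 / v)
}
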