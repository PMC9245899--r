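# Consanguinity null distributions by pedigree gene dropping.
#
# Six scenarios cover the three degrees of parental relatedness usually
# considered for ancient genomes; each scenario's focal offspring has a
# known expected inbreeding coefficient F = (1/2)^(degree + 1).

#' The six consanguinity scenarios
#'
#' Explicit pedigrees whose focal offspring is the child of: full siblings
#' or parent-offspring (degree 1, F = 1/4); uncle-niece or
#' grandparent-grandchild (degree 2, F = 1/8); first cousins or great
#' uncle-great niece (degree 3, F = 1/16). Each pedigree lists founders
#' (parents `NA`) and one `focal` individual; parents always precede
#' children.
#'
#' @return list of `pedigree_scenario` objects with fields `label`,
#'   `degree`, `expected_f`, `pedigree` (data.frame `id`, `father`,
#'   `mother`), `focal`, `n_founders`.
#' @export
scenario_pedigrees <- function() {
  ped <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    data.frame(id = m[, 1L], father = ifelse(m[, 2L] == "", NA, m[, 2L]),
               mother = ifelse(m[, 3L] == "", NA, m[, 3L]),
               stringsAsFactors = FALSE)
  }
  mk <- function(label, degree, pedigree) {
    structure(list(label = label, degree = degree,
                   expected_f = (1 / 2)^(degree + 1), pedigree = pedigree,
                   focal = pedigree$id[nrow(pedigree)],
                   n_founders = sum(is.na(pedigree$father))),
              class = "pedigree_scenario")
  }
  list(
    mk("first_degree_sib", 1L, ped(
      "F1", "", "", "F2", "", "",
      "S1", "F1", "F2", "S2", "F1", "F2",
      "FOCAL", "S1", "S2")),
    mk("first_degree_parent_offspring", 1L, ped(
      "F1", "", "", "F2", "", "",
      "C", "F1", "F2",
      "FOCAL", "F1", "C")),
    mk("second_degree_avuncular", 2L, ped(
      "F1", "", "", "F2", "", "", "F3", "", "",
      "S1", "F1", "F2", "S2", "F1", "F2",
      "N", "S1", "F3",
      "FOCAL", "S2", "N")),
    mk("second_degree_grandparent", 2L, ped(
      "F1", "", "", "F2", "", "", "F3", "", "",
      "C", "F1", "F2", "G", "C", "F3",
      "FOCAL", "F1", "G")),
    mk("third_degree_first_cousins", 3L, ped(
      "F1", "", "", "F2", "", "", "F3", "", "", "F4", "", "",
      "S1", "F1", "F2", "S2", "F1", "F2",
      "X", "S1", "F3", "Y", "S2", "F4",
      "FOCAL", "X", "Y")),
    mk("third_degree_great_avuncular", 3L, ped(
      "F1", "", "", "F2", "", "", "F3", "", "", "F4", "", "",
      "S1", "F1", "F2", "S2", "F1", "F2",
      "X", "S1", "F3", "Y", "X", "F4",
      "FOCAL", "S2", "Y"))
  )
}

#' @export
print.pedigree_scenario <- function(x, ...) {
  cat(sprintf("<pedigree_scenario> %s (degree %d, E[F] = %s)\n",
              x$label, x$degree, format(x$expected_f)))
  invisible(x)
}

# walk the pedigree on ancestry mosaics; founder_mosaics = list of
# 2*n_founders mosaics assigned pairwise in pedigree founder order
.gene_drop_mosaics <- function(scenario, founder_mosaics, axis) {
  ped <- scenario$pedigree
  ind <- list()
  fi <- 0L
  for (r in seq_len(nrow(ped))) {
    if (is.na(ped$father[r])) {
      ind[[ped$id[r]]] <- list(founder_mosaics[[fi + 1L]],
                               founder_mosaics[[fi + 2L]])
      fi <- fi + 2L
    } else {
      fa <- ind[[ped$father[r]]]; mo <- ind[[ped$mother[r]]]
      ind[[ped$id[r]]] <- list(
        .splice(fa[[1L]], fa[[2L]], .draw_meiosis_cuts(axis), axis),
        .splice(mo[[1L]], mo[[2L]], .draw_meiosis_cuts(axis), axis))
    }
  }
  ind
}

#' Gene-drop one pedigree scenario
#'
#' Samples founder haplotypes without replacement from the panel, simulates
#' every transmission with Poisson-crossover meiosis, and returns the focal
#' inbred offspring as unphased genotypes plus ancestry ground truth for the
#' whole pedigree.
#'
#' @param scenario a `pedigree_scenario` from [scenario_pedigrees()].
#' @param founders a `haplotype_panel`.
#' @param map a `genetic_map`.
#' @param seed RNG seed.
#' @return list with `genotypes` (integer vector over panel sites for the
#'   focal individual), `truth` (an `ancestry_truth` over all pedigree
#'   members), `focal` id and `f_true` (realised inbreeding of the focal).
#' @export
gene_drop <- function(scenario, founders, map, seed = NULL) {
  axis <- .map_axis(map)
  need <- 2L * scenario$n_founders
  if (founders$n_hap < need)
    .stopf("scenario '%s' needs %d founder haplotypes (%d supplied)",
           scenario$label, need, founders$n_hap)
  .with_seed(seed, {
    fh <- sample.int(founders$n_hap, need)
    ind <- .gene_drop_mosaics(scenario, lapply(fh, .founder_mosaic, axis), axis)
    gcm <- .site_gcm(founders$sites, axis)
    foc <- ind[[scenario$focal]]
    truth <- structure(list(haps = ind, map = map, axis = axis,
                            sites = founders$sites),
                       class = "ancestry_truth")
    list(genotypes = .hap_alleles(foc[[1L]], founders, gcm) +
           .hap_alleles(foc[[2L]], founders, gcm),
         truth = truth, focal = scenario$focal,
         f_true = true_fraction(truth, scenario$focal))
  })
}

#' Simulate the ROH null distribution of one consanguinity scenario
#'
#' Repeats [gene_drop()] with freshly sampled founders, calls ROH on each
#' focal offspring and records the point (number of ROH segments, F_ROH).
#' The resulting cloud is summarised by its mean vector and covariance
#' (regularised by 1e-9 on the diagonal).
#'
#' @param scenario a `pedigree_scenario`.
#' @param founders a `haplotype_panel`.
#' @param map a `genetic_map`.
#' @param params a [roh_params()]; its `min_report_cM` selects the segment
#'   length threshold for both the count and F_ROH.
#' @param n_reps number of replicates (>= 2).
#' @param seed RNG seed.
#' @return object of class `null_cloud`.
#' @export
simulate_null <- function(scenario, founders, map, params = roh_params(),
                          n_reps = 400L, seed = NULL) {
  if (n_reps < 2L) .stopf("n_reps must be >= 2")
  axis <- .map_axis(map)
  need <- 2L * scenario$n_founders
  gcm <- .site_gcm(founders$sites, axis)
  denom <- axis$total
  .with_seed(seed, {
    pts <- matrix(NA_real_, n_reps, 2L,
                  dimnames = list(NULL, c("n_roh", "f_roh")))
    for (r in seq_len(n_reps)) {
      fh <- sample.int(founders$n_hap, need)
      ind <- .gene_drop_mosaics(scenario, lapply(fh, .founder_mosaic, axis),
                                axis)
      foc <- ind[[scenario$focal]]
      g <- .hap_alleles(foc[[1L]], founders, gcm) +
        .hap_alleles(foc[[2L]], founders, gcm)
      segs <- .call_roh_sites(g, founders$sites, scenario$focal, params)
      pts[r, ] <- c(nrow(segs), f_roh(segs, denom, params$min_report_cM))
    }
    cv <- stats::cov(pts)
    degenerate <- !all(is.finite(cv)) || all(abs(cv) < 1e-300)
    if (degenerate) {
      .warnf("simulate_null: degenerate cloud for '%s'; identity covariance fallback",
             scenario$label)
      cv <- diag(2L)
    }
    structure(list(scenario = scenario$label, degree = scenario$degree,
                   expected_f = scenario$expected_f,
                   n_reps = as.integer(n_reps),
                   points = as.data.frame(pts),
                   mean = colMeans(pts),
                   cov = cv + diag(1e-9, 2L),
                   degenerate = degenerate,
                   min_report_cM = params$min_report_cM,
                   autosomal_map_length_cM = denom),
              class = "null_cloud")
  })
}

#' @export
print.null_cloud <- function(x, ...) {
  cat(sprintf("<null_cloud> %s: n = %d, mean n_roh = %.1f, mean F_ROH = %.4f\n",
              x$scenario, x$n_reps, x$mean[1L], x$mean[2L]))
  invisible(x)
}

#' Classify a query genome against consanguinity null clouds
#'
#' For each cloud the Mahalanobis distance of the query point
#' (ROH count, F_ROH) to the cloud mean is computed, together with the
#' empirical quantile of that distance among the cloud's own points. The
#' verdict is `inside` below the lower edge quantile, `edge` within the
#' band, `outside` beyond it; the nearest scenario is the distance argmin
#' with ties broken toward the lower degree. Apply a `min_report_cM` ROH
#' filter upstream to reproduce length-restricted (>5/>10/>15 cM)
#' re-analyses: the classification itself is threshold-agnostic.
#'
#' @param query numeric vector `c(n_roh, f_roh)` of the query genome.
#' @param clouds list of `null_cloud` objects.
#' @param edge_band quantile band `(lower, upper)` delimiting
#'   inside/edge/outside.
#' @param query_id label for the query.
#' @return data.frame of class `inbreeding_classification`, one row per
#'   cloud, with attribute `nearest`.
#' @export
classify_inbreeding <- function(query, clouds, edge_band = c(0.90, 0.99),
                                query_id = "query") {
  if (!length(clouds)) .stopf("need at least one null cloud")
  if (inherits(clouds, "null_cloud")) clouds <- list(clouds)
  q <- as.numeric(query[1:2])
  rows <- lapply(clouds, function(cl) {
    d2 <- stats::mahalanobis(matrix(q, 1L), cl$mean, cl$cov)
    pd2 <- stats::mahalanobis(as.matrix(cl$points), cl$mean, cl$cov)
    quant <- mean(pd2 <= d2)
    verdict <- if (quant < edge_band[1L]) "inside"
    else if (quant <= edge_band[2L]) "edge"
    else "outside"
    data.frame(query = query_id, scenario = cl$scenario, degree = cl$degree,
               distance = sqrt(d2), quantile = quant, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$distance, out$degree)
  attr(out, "nearest") <- out$scenario[ord[1L]]
  attr(out, "nearest_degree") <- out$degree[ord[1L]]
  class(out) <- c("inbreeding_classification", "data.frame")
  out
}

#' @export
print.inbreeding_classification <- function(x, ...) {
  cat(sprintf("Inbreeding classification (nearest: %s)\n", attr(x, "nearest")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
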