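# One-config orchestration of the full insularity analysis:
# filter -> relatives -> ROH -> pedigree nulls -> classification -> Ne ->
# IBD matrix -> group summary / PCA, with per-stage child seeds and a
# deterministic report bundle on disk.

#' Pipeline configuration
#'
#' Exactly one of `input` (paths to genotypes/map/groups) or `synthetic`
#' (a simulated study design) must be supplied.
#'
#' @param input list with `genotypes`, `map` and optionally `groups` paths.
#' @param synthetic list describing a simulated panel; see
#'   [default_demo_config()] for the fields and defaults.
#' @param filters a [site_filter_config()].
#' @param ld_prune logical: run LD pruning after the site filters.
#' @param roh a [roh_params()]; its `min_report_cM` drives both the
#'   classification inputs and F_ROH.
#' @param null_scenarios labels of consanguinity scenarios to simulate.
#' @param null_reps replicates per null cloud.
#' @param edge_band classification quantile band.
#' @param ibd an [ibd_params()].
#' @param kinship_threshold relatedness cutoff for [filter_relatives()].
#' @param ne list of [roh_ne_model()] overrides (`min_len_cM`, `max_len_cM`,
#'   `bin_range`, `n_bins`, `t_max`).
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds are derived with [derive_seed()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL,
                            filters = site_filter_config(),
                            ld_prune = FALSE,
                            roh = roh_params(min_report_cM = 4),
                            null_scenarios = c("first_degree_sib",
                                               "second_degree_avuncular",
                                               "third_degree_first_cousins"),
                            null_reps = 100L,
                            edge_band = c(0.90, 0.99),
                            ibd = ibd_params(),
                            kinship_threshold = 0.0442,
                            ne = list(),
                            out_dir = "insular_run",
                            seed = 1L) {
  if (is.null(input) == is.null(synthetic))
    .stopf("pipeline_config: supply exactly one of 'input' or 'synthetic'")
  structure(list(input = input, synthetic = synthetic, filters = filters,
                 ld_prune = ld_prune, roh = roh,
                 null_scenarios = null_scenarios,
                 null_reps = as.integer(null_reps), edge_band = edge_band,
                 ibd = ibd, kinship_threshold = kinship_threshold,
                 ne = ne, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Bundled synthetic demo configuration
#'
#' Two demes — a mainland population and a small island deme — connected by
#' weak migration, with one planted sib-mating offspring in the island
#' sample. Sized so a full run completes within a few minutes on one core.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @return a `pipeline_config`.
#' @export
default_demo_config <- function(out_dir = "insular_demo", seed = 1L) {
  pipeline_config(
    synthetic = list(
      chrom_lengths_cM = unname(map_lengths(human_autosomes())),
      snps_per_cM = 10,
      deme_sizes = c(mainland = 300L, island = 60L),
      n_generations = 25L, migration = 0.01,
      n_sample = c(18L, 14L),
      plant_inbred = "first_degree_sib", plant_deme = 2L,
      miscall_rate = 0.002, missing_rate = 0.002,
      freq_beta_params = c(1, 1)),
    null_reps = 100L,
    out_dir = out_dir, seed = seed)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with sections named after [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("input", "synthetic", "out_dir", "seed", "null_scenarios",
               "null_reps", "edge_band", "kinship_threshold", "ld_prune",
               "ne"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$filters)) args$filters <- do.call(site_filter_config, raw$filters)
  if (!is.null(raw$roh)) args$roh <- do.call(roh_params, raw$roh)
  if (!is.null(raw$ibd)) args$ibd <- do.call(ibd_params, raw$ibd)
  do.call(pipeline_config, args)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (k in which(num)) df[[k]] <- .fmt_num(df[[k]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# A genome is treated as consanguineous (and excluded from Ne fitting) if
# it is inside or at the edge of any 1st/2nd-degree cloud, or if it lies
# beyond such a cloud on the high-F_ROH side: genomes more extreme than the
# sib-mating null inflate the long-ROH spectrum just as surely.
.flag_consanguineous <- function(cls, f_roh, clouds) {
  low <- cls$degree <= 2L
  if (any(low & cls$verdict != "outside")) return(TRUE)
  for (cl in clouds) {
    if (cl$degree <= 2L && f_roh >= cl$mean["f_roh"]) return(TRUE)
  }
  FALSE
}

# build the synthetic panel stage of run_pipeline
.pipeline_simulate <- function(sy, seed) {
  map <- uniform_map(sy$chrom_lengths_cM)
  n_demes <- length(sy$deme_sizes)
  traj <- ne_trajectory(matrix(rep(as.integer(sy$deme_sizes),
                                   each = sy$n_generations + 1L),
                               ncol = n_demes),
                        n_demes = n_demes, migration = sy$migration)
  founders <- make_founders(
    n_haplotypes = 2L * sum(sy$deme_sizes),
    n_sites_per_chrom = round(sy$chrom_lengths_cM * sy$snps_per_cM),
    map = map, freq_beta_params = sy$freq_beta_params,
    seed = derive_seed(seed, "founders"))
  pop <- simulate_population(founders, traj, map,
                             seed = derive_seed(seed, "gene_drop"),
                             n_sample = NULL)
  # subsample per deme
  gm <- pop$genotypes; truth <- pop$truth
  n_sample <- rep_len(sy$n_sample, n_demes)
  keep <- .with_seed(derive_seed(seed, "sample"), {
    unlist(lapply(seq_len(n_demes), function(d) {
      ids <- gm$ids[gm$groups == sprintf("deme%d", d)]
      sort(sample(ids, min(n_sample[d], length(ids))))
    }))
  })
  gm <- subset_individuals(gm, keep)
  truth$haps <- truth$haps[keep]
  planted <- NULL
  if (!is.null(sy$plant_inbred)) {
    scen <- Filter(function(s) s$label == sy$plant_inbred,
                   scenario_pedigrees())[[1L]]
    deme_ids <- gm$ids[gm$groups == sprintf("deme%d", sy$plant_deme)]
    planted <- .with_seed(derive_seed(seed, "plant"), {
      par_ids <- sample(deme_ids, scen$n_founders)
      fm <- unlist(lapply(par_ids, function(id) truth$haps[[id]]),
                   recursive = FALSE)
      ind <- .gene_drop_mosaics(scen, fm, truth$axis)
      ind[[scen$focal]]
    })
    gcm <- .site_gcm(founders$sites, truth$axis)
    g_new <- .hap_alleles(planted[[1L]], founders, gcm) +
      .hap_alleles(planted[[2L]], founders, gcm)
    gm2 <- genotype_matrix(rbind(gm$geno, g_new), gm$sites,
                           ids = c(gm$ids, "PLANTED"),
                           groups = c(gm$groups,
                                      PLANTED = sprintf("deme%d", sy$plant_deme)))
    truth$haps[["PLANTED"]] <- planted
    gm <- gm2
  }
  gm <- add_errors(gm, miscall_rate = sy$miscall_rate,
                   missing_rate = sy$missing_rate,
                   seed = derive_seed(seed, "errors"))
  list(gm = gm, map = map, truth = truth, founders = founders,
       groups = gm$groups)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: panel construction (file input or synthetic
#' simulation), site filtering, ROH calling and F_ROH profiling, pedigree
#' null simulation and consanguinity classification, ROH-spectrum Ne
#' estimation per group (excluding flagged consanguineous genomes),
#' relatedness filtering, pairwise IBD detection, group sharing summaries
#' and PCA. All artifacts are written to `config$out_dir`; re-running with
#' the same config and seed reproduces them bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fail_marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  stage <- "init"
  res <- list(seed = cfg$seed)
  on.exit({
    writeLines(sprintf("pipeline failed at stage: %s", stage), fail_marker)
  })
  log <- c(sprintf("insulaR pipeline, seed %d", cfg$seed),
           sprintf("R %s.%s", R.version$major, R.version$minor))

  stage <- "input"
  if (!is.null(cfg$synthetic)) {
    sim <- .pipeline_simulate(cfg$synthetic, cfg$seed)
    gm <- sim$gm; map <- sim$map; groups <- sim$groups
    res$truth <- sim$truth; res$founders <- sim$founders
  } else {
    gm <- read_genotypes(cfg$input$genotypes)
    map <- read_genetic_map(cfg$input$map)
    gm <- attach_genetic_map(gm, map)
    groups <- if (!is.null(cfg$input$groups)) read_groups(cfg$input$groups)
    else stats::setNames(rep("all", length(gm$ids)), gm$ids)
    gm$groups <- groups
  }
  log <- c(log, sprintf("input: %d individuals x %d sites", length(gm$ids),
                        n_sites(gm)))

  stage <- "filter_sites"
  gm <- suppressMessages(filter_sites(gm, cfg$filters))
  if (isTRUE(cfg$ld_prune)) gm <- ld_prune(gm, cfg$filters)
  removed <- attr(gm, "removed")
  .write_tsv(data.frame(stage = names(removed), removed = as.integer(removed)),
             file.path(cfg$out_dir, "panel_filter_summary.tsv"))
  log <- c(log, sprintf("filtered panel: %d sites", n_sites(gm)))

  stage <- "roh"
  prof <- roh_profile(gm, cfg$roh)
  write_segments(prof$segments, file.path(cfg$out_dir, "roh_segments.tsv"))
  .write_tsv(prof$profiles, file.path(cfg$out_dir, "roh_profiles.tsv"))
  res$roh <- prof

  stage <- "pedigree_null"
  scens <- Filter(function(s) s$label %in% cfg$null_scenarios,
                  scenario_pedigrees())
  null_founders <- if (!is.null(res$founders)) res$founders else
    .with_seed(derive_seed(cfg$seed, "null_founders"),
               .panel_from_genotypes(gm))
  clouds <- lapply(scens, function(sc)
    simulate_null(sc, null_founders, map, cfg$roh, n_reps = cfg$null_reps,
                  seed = derive_seed(cfg$seed, paste0("null_", sc$label))))
  cloud_tab <- do.call(rbind, lapply(clouds, function(cl)
    data.frame(scenario = cl$scenario, degree = cl$degree, rep = seq_len(cl$n_reps),
               n_roh = cl$points$n_roh, f_roh = cl$points$f_roh)))
  .write_tsv(cloud_tab, file.path(cfg$out_dir, "null_clouds.tsv"))
  res$clouds <- clouds

  stage <- "classify"
  denom <- prof$autosomal_map_length_cM
  cls_rows <- lapply(gm$ids, function(id) {
    pr <- prof$profiles[prof$profiles$id == id, ]
    cls <- classify_inbreeding(c(pr$n_segments, pr$f_roh), clouds,
                               edge_band = cfg$edge_band, query_id = id)
    data.frame(id = id, n_roh = pr$n_segments, f_roh = pr$f_roh,
               nearest = attr(cls, "nearest"),
               nearest_degree = attr(cls, "nearest_degree"),
               consanguineous = .flag_consanguineous(cls, pr$f_roh, clouds),
               stringsAsFactors = FALSE)
  })
  cls_tab <- do.call(rbind, cls_rows)
  .write_tsv(cls_tab, file.path(cfg$out_dir, "classification.tsv"))
  res$classification <- cls_tab

  stage <- "ne"
  ne_args <- utils::modifyList(
    list(chrom_lengths_cM = unname(map_lengths(map))), cfg$ne)
  model <- do.call(roh_ne_model, ne_args)
  flagged <- cls_tab$id[cls_tab$consanguineous]
  segs_by_id <- prof$segments_by_id
  ne_list <- lapply(sort(unique(groups)), function(grp) {
    ids <- names(groups)[groups == grp]
    fit <- fit_ne_roh(segs_by_id[ids], model, exclude = flagged)
    list(group = grp, ne = fit$ne_hat, ci_lower = unname(fit$ci95[1L]),
         ci_upper = unname(fit$ci95[2L]), n_segments = fit$n_segments,
         n_genomes = fit$n_genomes, boundary = fit$boundary,
         excluded = fit$excluded)
  })
  names(ne_list) <- vapply(ne_list, `[[`, character(1), "group")
  jsonlite::write_json(ne_list, file.path(cfg$out_dir, "ne_estimates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$ne <- ne_list

  stage <- "relatives"
  rel <- filter_relatives(gm, threshold = cfg$kinship_threshold)
  writeLines(rel$kept, file.path(cfg$out_dir, "kept_individuals.txt"))
  .write_tsv(rel$pairs, file.path(cfg$out_dir, "removed_pairs.tsv"))
  gm_unrel <- subset_individuals(gm, rel$kept)
  res$relatives <- rel

  stage <- "ibd"
  mat <- pairwise_ibd_matrix(gm_unrel, cfg$ibd)
  write_segments(mat$segments, file.path(cfg$out_dir, "ibd_segments.tsv"))
  tot <- as.data.frame(mat$total)
  .write_tsv(cbind(data.frame(id = mat$ids), tot),
             file.path(cfg$out_dir, "ibd_matrix.tsv"))
  res$ibd <- mat

  stage <- "group_summary"
  gs <- group_summary(mat, groups)
  .write_tsv(cbind(data.frame(group = gs$groups), as.data.frame(gs$mean_cM)),
             file.path(cfg$out_dir, "group_summary.tsv"))
  elig <- ne_eligibility(mat$segments, groups,
                         min_length_cM = cfg$ibd$min_length_cM)
  .write_tsv(elig, file.path(cfg$out_dir, "ne_eligibility.tsv"))
  res$group_summary <- gs
  res$eligibility <- elig

  stage <- "pca"
  pca <- ibd_pca(mat, n_components = 5L)
  .write_tsv(cbind(data.frame(id = mat$ids),
                   as.data.frame(pca$scores),
                   deme = unname(groups[mat$ids])),
             file.path(cfg$out_dir, "pca.tsv"))
  .write_tsv(data.frame(component = seq_along(pca$var_frac),
                        var_frac = pca$var_frac),
             file.path(cfg$out_dir, "pca_variance.tsv"))
  res$pca <- pca

  stage <- "log"
  log <- c(log,
           sprintf("relatives removed: %d", length(rel$removed)),
           sprintf("ibd pairs: %d", choose(length(mat$ids), 2)),
           "parameters:",
           utils::capture.output(utils::str(cfg, give.attr = FALSE,
                                            vec.len = 8)))
  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  on.exit()
  invisible(res)
}

# fall back founder panel for null simulation when the input is a real
# panel: haplotypes drawn site-wise from the panel's allele frequencies
# (founders must be unrelated and unstructured, so resampling is adequate)
.panel_from_genotypes <- function(gm, n_haplotypes = 100L) {
  p <- gm$sites$p
  p <- pmin(pmax(p, 0.01), 0.99)
  alleles <- matrix(stats::rbinom(n_haplotypes * length(p), 1L,
                                  rep(p, each = n_haplotypes)),
                    nrow = n_haplotypes)
  haplotype_panel(alleles, gm$sites, freq = p)
}
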