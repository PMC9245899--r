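# Shared fixtures, memoised so expensive simulations are built once per run.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

small_map <- function() uniform_map(rep(150, 6))

# 200 founder haplotypes, 6 x 150 cM at 10 SNPs/cM
small_founders <- function() {
  fixture("small_founders",
          make_founders(200, 1500, small_map(), seed = 101))
}

# human-scale map and a founder panel at 25 SNPs/cM (the density used for
# pedigree-null calibration)
human_map <- function() fixture("human_map", human_autosomes())
human_founders <- function() {
  fixture("human_founders",
          make_founders(100, round(map_lengths(human_map()) * 25),
                        human_map(), seed = 103))
}

# the six null clouds at n_reps = 400 on the human-scale map (shared by the
# calibration and classification acceptance tests)
null_clouds_400 <- function() {
  fixture("null_clouds_400", {
    lapply(scenario_pedigrees(), function(sc)
      simulate_null(sc, human_founders(), human_map(),
                    roh_params(min_report_cM = 0), n_reps = 400L,
                    seed = derive_seed(202, sc$label)))
  })
}

# genotype vector of an individual formed from two founder haplotypes
founder_pair_genotypes <- function(founders, h1, h2) {
  founders$alleles[h1, ] + founders$alleles[h2, ]
}

# materialise a mosaic individual (list of two mosaics) into genotypes
mosaic_genotypes <- function(ind, founders, map) {
  axis <- insulaR:::.map_axis(map)
  gcm <- insulaR:::.site_gcm(founders$sites, axis)
  insulaR:::.hap_alleles(ind[[1L]], founders, gcm) +
    insulaR:::.hap_alleles(ind[[2L]], founders, gcm)
}

# drop one pedigree scenario and return the focal individual's mosaics plus
# an ancestry_truth over the whole pedigree
drop_pedigree <- function(scenario, founders, map) {
  axis <- insulaR:::.map_axis(map)
  fh <- sample.int(founders$n_hap, 2L * scenario$n_founders)
  ind <- insulaR:::.gene_drop_mosaics(
    scenario, lapply(fh, insulaR:::.founder_mosaic, axis), axis)
  structure(list(haps = ind, map = map, axis = axis,
                 sites = founders$sites),
            class = "ancestry_truth")
}

# segment overlap bookkeeping for recall/FDR against planted truth
coverage_of <- function(target, others) {
  if (!nrow(others)) return(0)
  ov <- pmin(others$end_cM, target$end_cM) - pmax(others$start_cM, target$start_cM)
  sel <- others$chrom == target$chrom & ov > 0
  if (!any(sel)) 0 else sum(ov[sel]) / (target$end_cM - target$start_cM)
}
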