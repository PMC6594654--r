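# Shared simulation setups.

# Four 50-Mb chromosomes with 50 informative SNPs and 50 depth bins each;
# an optional clonal whole-chromosome event on chromosome 1. The diploid
# majority keeps the logR median centered.
cond_config <- function(kind = NULL, seed = 1, purity = 0.9, depth = 100,
                        mutations = NULL, snp_density = 1) {
  events <- if (!is.null(kind) && kind != "RETAINED_HET")
    list(cn_event("1", 1, 5e7, kind, "S129", "t")) else list()
  clones <- list(clone_spec("t", 1, 1, mutations))
  sim_config(seed = seed, n_chromosomes = 4, chrom_length_bp = 5e7,
             snp_density = snp_density, mean_depth_normal = depth,
             mean_depth_tumor = depth, purity_primary = purity,
             purity_relapse = purity, events = events, clones = clones,
             bin_size_bp = 1e6)
}

# State called for chromosome 1 of the primary sample.
called_state_chr1 <- function(sim) {
  segs <- segment_track(compute_baf(snp_observations(sim, "primary")),
                        compute_logr(sim$bins_primary))
  segs$state[segs$chrom == "1"]
}

packaged_config <- function(name, seed) {
  cfg <- read_sim_config(system.file("extdata", name, package = "f1loh"))
  cfg$seed <- as.integer(seed)
  cfg
}
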