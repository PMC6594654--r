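## Synthetic F1-hybrid tumor/normal exome generator.
##
## Emulates read counts at strain-informative SNPs (heterozygous in every
## F1 cell), somatic point mutations carried by subclones, and binned depth
## of coverage, for a matched normal plus a primary/relapse tumor pair with
## known purity, copy-number events and clonal structure.

STATE_KINDS <- c("CN_LOH", "DELETION", "GAIN")
HAPLOTYPES <- c("B6", "S129")

#' Describe a somatic copy-number event
#'
#' @param chrom chromosome identifier (integer or string).
#' @param start,end 1-based inclusive interval affected.
#' @param kind one of `"CN_LOH"` (copy-neutral loss of heterozygosity /
#'   uniparental disomy), `"DELETION"` (hemizygous loss) or `"GAIN"`
#'   (single-copy gain, e.g. whole-chromosome trisomy).
#' @param haplotype the retained haplotype for CN_LOH/DELETION, or the
#'   duplicated haplotype for GAIN; `"B6"` or `"S129"`.
#' @param clone_ids character vector of clones carrying the event.
#' @return a `cn_event` list.
#' @export
cn_event <- function(chrom, start, end, kind, haplotype, clone_ids) {
  kind <- match.arg(kind, STATE_KINDS)
  haplotype <- match.arg(haplotype, HAPLOTYPES)
  if (start >= end)
    stop_f1("event interval must have start < end", class = "f1loh_config_error")
  structure(list(chrom = chrom, start = start, end = end, kind = kind,
                 haplotype = haplotype, clone_ids = as.character(clone_ids)),
            class = "cn_event")
}

#' Describe a tumor subclone
#'
#' @param clone_id unique clone label.
#' @param fraction_primary,fraction_relapse fraction of tumor cells belonging
#'   to this clone in each sample, in `[0, 1]`.
#' @param somatic_mutations data.frame with columns `chrom`, `pos`, `gene`,
#'   `multiplicity` (mutant copies per cell, 1 or 2). Multiplicity 2 models a
#'   mutant allele duplicated by uniparental disomy and is only valid inside
#'   a CN_LOH event carried by the same clone.
#' @return a `clone_spec` list.
#' @export
clone_spec <- function(clone_id, fraction_primary, fraction_relapse,
                       somatic_mutations = NULL) {
  if (fraction_primary < 0 || fraction_relapse < 0)
    stop_f1("clone fractions must be non-negative", class = "f1loh_config_error")
  if (is.null(somatic_mutations)) {
    somatic_mutations <- data.frame(chrom = character(), pos = integer(),
                                    gene = character(), multiplicity = integer())
  }
  stopifnot(all(c("chrom", "pos", "gene", "multiplicity") %in%
                  names(somatic_mutations)))
  if (!all(somatic_mutations$multiplicity %in% c(1L, 2L)))
    stop_f1("mutation multiplicity must be 1 or 2", class = "f1loh_config_error")
  structure(list(clone_id = as.character(clone_id),
                 fraction_primary = fraction_primary,
                 fraction_relapse = fraction_relapse,
                 somatic_mutations = somatic_mutations),
            class = "clone_spec")
}

#' Build a simulation configuration
#'
#' Defines the genome, sequencing depth, tumor purity, copy-number events and
#' clonal structure of one simulated matched-normal + primary/relapse trio.
#' Informative-SNP positions are laid out deterministically (evenly spaced at
#' `snp_density` per Mb), so the truth structure depends only on the
#' configuration while read counts depend on `seed`.
#'
#' @param seed master seed; all three sample-level RNG streams derive from it.
#' @param n_chromosomes number of autosomes simulated.
#' @param chrom_length_bp length of each chromosome.
#' @param snp_density strain-informative heterozygous SNPs per megabase.
#' @param mean_depth_normal,mean_depth_tumor mean reads per site.
#' @param purity_primary,purity_relapse fraction of tumor cells per sample.
#' @param events list of [cn_event()].
#' @param clones list of [clone_spec()]. Per sample the clone fractions must
#'   sum to at most 1; any remainder is tumor cells carrying no event.
#' @param target_mb callable target size in Mb, used for burden accounting.
#' @param bin_size_bp depth-of-coverage bin width (bins are 0-based
#'   half-open; SNP/variant positions are 1-based).
#' @param sites_per_bin effective number of independent sites averaged per
#'   depth bin; controls bin-level depth noise.
#' @param error_rate symmetric per-read sequencing error rate.
#' @param overdispersion extra-Poisson depth dispersion; 0 gives Poisson
#'   depths, larger values a negative binomial with variance
#'   `mu * (1 + overdispersion * mu)`.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 19L,
                       chrom_length_bp = 1e8,
                       snp_density = 1,
                       mean_depth_normal = 100,
                       mean_depth_tumor = 100,
                       purity_primary = 0.9,
                       purity_relapse = 0.9,
                       events = list(),
                       clones = list(),
                       target_mb = 50,
                       bin_size_bp = 1e6,
                       sites_per_bin = 50,
                       error_rate = 0.001,
                       overdispersion = 0) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$purity_primary < 0 || cfg$purity_primary > 1 ||
      cfg$purity_relapse < 0 || cfg$purity_relapse > 1)
    stop_f1("purity must lie in [0, 1]", class = "f1loh_config_error")
  if (cfg$snp_density <= 0)
    stop_f1("snp_density must be positive", class = "f1loh_config_error")
  if (cfg$error_rate < 0 || cfg$error_rate >= 0.5)
    stop_f1("error_rate must lie in [0, 0.5)", class = "f1loh_config_error")
  for (s in c("fraction_primary", "fraction_relapse")) {
    tot <- sum(vapply(cfg$clones, `[[`, numeric(1), s))
    if (tot > 1 + 1e-9)
      stop_f1("clone ", s, " values sum to ", signif(tot, 4), " > 1",
              class = "f1loh_config_error")
  }
  ## events on one chromosome must not overlap
  ev <- cfg$events
  if (length(ev) > 1) {
    for (i in seq_len(length(ev) - 1L)) for (j in seq(i + 1L, length(ev))) {
      a <- ev[[i]]; b <- ev[[j]]
      if (identical(a$chrom, b$chrom) && a$start <= b$end && b$start <= a$end)
        stop_f1("events ", i, " and ", j, " overlap on chromosome ", a$chrom,
                " (", a$start, "-", a$end, " vs ", b$start, "-", b$end, ")",
                class = "f1loh_config_error")
    }
  }
  ## multiplicity-2 mutations must sit inside a CN_LOH of their own clone
  for (cl in cfg$clones) {
    mut <- cl$somatic_mutations
    for (k in seq_len(nrow(mut))) {
      if (mut$multiplicity[k] == 2L) {
        ok <- any(vapply(ev, function(e) {
          e$kind == "CN_LOH" && cl$clone_id %in% e$clone_ids &&
            identical(as.character(e$chrom), as.character(mut$chrom[k])) &&
            e$start <= mut$pos[k] && mut$pos[k] <= e$end
        }, logical(1)))
        if (!ok)
          stop_f1("multiplicity-2 mutation ", mut$gene[k], " in clone ",
                  cl$clone_id, " lies outside a CN_LOH event of that clone",
                  class = "f1loh_invalid_truth")
      }
    }
  }
  invisible(cfg)
}

## Per-haplotype copy numbers (b6, s129) implied by an event kind.
event_copies <- function(kind, haplotype) {
  retained_b6 <- haplotype == "B6"
  switch(kind,
         CN_LOH   = if (retained_b6) c(2, 0) else c(0, 2),
         DELETION = if (retained_b6) c(1, 0) else c(0, 1),
         GAIN     = if (retained_b6) c(2, 1) else c(1, 2))
}

#' Expected strain B-allele fraction under a mixture of tumor and normal cells
#'
#' Cell-population accounting for the S129 allele at a germline heterozygous
#' strain-informative SNP: normal cells contribute one copy of each
#' haplotype, tumor cells `c_b6` and `c_s129` copies.
#'
#' @param c_b6,c_s129 per-haplotype copy numbers in the tumor cells.
#' @param purity fraction of tumor cells in the sample, in `[0, 1]`.
#' @return expected fraction of reads carrying the S129 allele, in `[0, 1]`.
#' @examples
#' expected_baf(1, 1, 0.9)        # diploid het: 0.5 at any purity
#' expected_baf(0, 2, 1)          # CN-LOH retaining S129, pure tumor: 1
#' expected_baf(0, 2, 0.8)        # CN-LOH retaining S129 at purity 0.8: 0.9
#' @export
expected_baf <- function(c_b6, c_s129, purity) {
  if (any(purity < 0 | purity > 1))
    stop_f1("purity must lie in [0, 1]", class = "f1loh_config_error")
  if (any(c_b6 < 0 | c_s129 < 0))
    stop_f1("copy numbers must be non-negative", class = "f1loh_config_error")
  num <- (1 - purity) * 1 + purity * c_s129
  den <- (1 - purity) * 2 + purity * (c_b6 + c_s129)
  if (any(den == 0))
    stop_f1("total copy mass is zero; allele fraction undefined",
            class = "f1loh_undefined_fraction")
  num / den
}

#' Expected somatic variant allele fraction
#'
#' Cell-population accounting for a somatic point mutation present at
#' `multiplicity` copies per cell in a fraction `cell_fraction` of all cells
#' (purity times clone fraction). Cells carrying the mutation have
#' `tumor_copy` total copies at the locus; all other cells `background_copy`.
#'
#' @param multiplicity mutant copies per mutated cell (1, or 2 after
#'   mutant-allele duplication by uniparental disomy).
#' @param cell_fraction fraction of all cells carrying the mutation.
#' @param tumor_copy total copy number at the locus in mutated cells.
#' @param background_copy total copy number in the remaining cells.
#' @return expected variant allele fraction in `[0, 1]`.
#' @examples
#' expected_vaf(2, 0.92)       # duplicated mutant in CN-LOH: VAF 0.92
#' expected_vaf(1, 1)          # clonal het in a pure diploid tumor: 0.5
#' @export
expected_vaf <- function(multiplicity, cell_fraction, tumor_copy = 2,
                         background_copy = 2) {
  if (any(cell_fraction < 0 | cell_fraction > 1))
    stop_f1("cell_fraction must lie in [0, 1]", class = "f1loh_config_error")
  if (any(multiplicity > tumor_copy))
    stop_f1("mutant multiplicity exceeds local copy number",
            class = "f1loh_invalid_truth")
  den <- cell_fraction * tumor_copy + (1 - cell_fraction) * background_copy
  if (any(den == 0))
    stop_f1("total copy mass is zero; allele fraction undefined",
            class = "f1loh_undefined_fraction")
  cell_fraction * multiplicity / den
}

#' Draw alt/ref read counts at one or more sites
#'
#' Depth is Poisson (or negative binomial when `overdispersion > 0`) with the
#' given mean; alt reads are binomial in the expected fraction. Draws come
#' from the current RNG state, so results are reproducible given a seed.
#'
#' @param expected_fraction per-site expected alt-allele fraction.
#' @param mean_depth per-site mean depth (recycled).
#' @param overdispersion extra-Poisson dispersion (0 = Poisson).
#' @return data.frame with columns `alt`, `ref`.
#' @export
sample_counts <- function(expected_fraction, mean_depth, overdispersion = 0) {
  if (any(expected_fraction < 0 | expected_fraction > 1))
    stop_f1("expected_fraction must lie in [0, 1]", class = "f1loh_config_error")
  n <- max(length(expected_fraction), length(mean_depth))
  expected_fraction <- rep_len(expected_fraction, n)
  mean_depth <- rep_len(mean_depth, n)
  depth <- if (overdispersion > 0) {
    rnbinom(n, mu = mean_depth, size = 1 / overdispersion)
  } else {
    rpois(n, mean_depth)
  }
  alt <- rbinom(n, depth, expected_fraction)
  data.frame(alt = alt, ref = depth - alt)
}

## Apply a symmetric read-error rate to a true allele fraction.
with_error <- function(f, eps) f * (1 - eps) + (1 - f) * eps

## Population mixture of one tumor sample: data.frame of (id, fraction,
## is_tumor). Residual tumor cells with no events appear as clone "".
sample_populations <- function(cfg, which_sample) {
  frac_field <- paste0("fraction_", which_sample)
  purity <- cfg[[paste0("purity_", which_sample)]]
  ids <- vapply(cfg$clones, `[[`, character(1), "clone_id")
  fr <- vapply(cfg$clones, `[[`, numeric(1), frac_field)
  resid <- max(0, 1 - sum(fr))
  data.frame(id = c(ids, "", ".normal"),
             fraction = c(purity * fr, purity * resid, 1 - purity),
             is_tumor = c(rep(TRUE, length(fr) + 1L), FALSE),
             stringsAsFactors = FALSE)
}

## Copy numbers (b6, s129) for each population at (chrom, pos).
population_copies <- function(cfg, pops, chrom, pos) {
  cb6 <- rep(1, nrow(pops)); cs129 <- rep(1, nrow(pops))
  for (e in cfg$events) {
    if (identical(as.character(e$chrom), as.character(chrom)) &&
        e$start <= pos && pos <= e$end) {
      cc <- event_copies(e$kind, e$haplotype)
      hit <- pops$is_tumor & pops$id %in% e$clone_ids
      cb6[hit] <- cc[1]; cs129[hit] <- cc[2]
    }
  }
  cbind(b6 = cb6, s129 = cs129)
}

## Expected S129 BAF and relative total copy (vs diploid) at one site.
site_expectation <- function(cfg, pops, chrom, pos) {
  cp <- population_copies(cfg, pops, chrom, pos)
  tot <- cp[, "b6"] + cp[, "s129"]
  mass <- sum(pops$fraction * tot)
  list(baf = sum(pops$fraction * cp[, "s129"]) / mass,
       rel_copy = mass / 2)
}

## Deterministic SNP layout: evenly spaced at snp_density per Mb.
snp_positions <- function(cfg) {
  spacing <- 1e6 / cfg$snp_density
  n <- floor(cfg$chrom_length_bp / spacing)
  pos <- round(spacing / 2 + spacing * (seq_len(n) - 1)) + 1L
  do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(ch)
    data.frame(chrom = as.character(ch), pos = pos)))
}

## Union of somatic mutations across clones, with per-clone multiplicity.
collect_mutations <- function(cfg) {
  rows <- list()
  for (cl in cfg$clones) {
    m <- cl$somatic_mutations
    if (nrow(m)) {
      m$clone_id <- cl$clone_id
      rows[[length(rows) + 1L]] <- m
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), pos = integer(), gene = character(),
                      multiplicity = integer(), clone_id = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos, out$clone_id), , drop = FALSE]
}

#' Simulate a matched normal and a primary/relapse tumor pair
#'
#' Generates read counts at strain-informative SNPs, somatic variant alt/ref
#' counts, and binned depth of coverage for three samples (normal, primary,
#' relapse) under the configured purity, copy-number events and clonal
#' structure, along with a ground-truth record for recovery testing.
#'
#' Each sample has its own RNG stream (derived from `config$seed`) consumed
#' in chromosome order, so extending the genome does not perturb draws on
#' earlier chromosomes. Regenerating with the same configuration reproduces
#' identical output.
#'
#' @param config a [sim_config()].
#' @return a list of class `f1loh_sim` with elements `snps` (per-site counts
#'   for all three samples), `variants` (somatic counts), `bins_primary`,
#'   `bins_relapse` (depth bins, 0-based half-open), and `truth`
#'   (a `SimTruth`-style record: config echo, expected fractions, events,
#'   per-sample clone fractions).
#' @export
simulate_pair <- function(config) {
  validate_sim_config(config)
  streams <- derive_stream_seeds(config$seed, 3L)
  snp <- snp_positions(config)
  muts <- collect_mutations(config)
  var_sites <- unique(muts[c("chrom", "pos", "gene")])
  var_sites <- var_sites[order(var_sites$chrom, var_sites$pos), , drop = FALSE]

  pops <- list(primary = sample_populations(config, "primary"),
               relapse = sample_populations(config, "relapse"))

  ## --- truth expectations (no randomness) -------------------------------
  exp_baf <- list(); exp_rel <- list(); exp_vaf <- list()
  for (s in names(pops)) {
    e <- t(vapply(seq_len(nrow(snp)), function(i) {
      x <- site_expectation(config, pops[[s]], snp$chrom[i], snp$pos[i])
      c(x$baf, x$rel_copy)
    }, numeric(2)))
    exp_baf[[s]] <- e[, 1]; exp_rel[[s]] <- e[, 2]
    if (nrow(var_sites)) {
      exp_vaf[[s]] <- vapply(seq_len(nrow(var_sites)), function(i) {
        p <- pops[[s]]
        cp <- population_copies(config, p, var_sites$chrom[i], var_sites$pos[i])
        tot <- cp[, "b6"] + cp[, "s129"]
        sel <- muts$chrom == var_sites$chrom[i] & muts$pos == var_sites$pos[i]
        mutant <- sum(vapply(which(sel), function(k) {
          f <- p$fraction[p$id == muts$clone_id[k] & p$is_tumor]
          f * muts$multiplicity[k]
        }, numeric(1)))
        mutant / sum(p$fraction * tot)
      }, numeric(1))
    } else exp_vaf[[s]] <- numeric()
  }

  eps <- config$error_rate
  n_bins <- floor(config$chrom_length_bp / config$bin_size_bp)
  bin_start <- config$bin_size_bp * (seq_len(n_bins) - 1)

  draw_sample <- function(stream_seed, snp_frac, snp_depth, var_frac,
                          var_depth, bin_rel) {
    set.seed(stream_seed)
    snp_counts <- NULL; var_counts <- NULL; bins <- NULL
    for (ch in as.character(seq_len(config$n_chromosomes))) {
      i <- which(snp$chrom == ch)
      sc <- sample_counts(snp_frac[i], snp_depth[i], config$overdispersion)
      j <- if (nrow(var_sites)) which(var_sites$chrom == ch) else integer()
      vc <- if (length(j))
        sample_counts(var_frac[j], var_depth[j], config$overdispersion)
      else NULL
      lam <- bin_rel[[ch]] * config$sites_per_bin
      bd <- rpois(n_bins, lam) / config$sites_per_bin
      snp_counts <- rbind(snp_counts, cbind(idx = i, sc))
      if (length(j)) var_counts <- rbind(var_counts, cbind(idx = j, vc))
      bins <- rbind(bins, data.frame(chrom = ch, start = bin_start,
                                     end = bin_start + config$bin_size_bp,
                                     depth = bd))
    }
    list(snp = snp_counts, var = var_counts, bins = bins)
  }

  ## per-chromosome bin mean depths (lambda per effective site)
  bin_mid <- bin_start + config$bin_size_bp / 2
  bin_rel_depth <- function(sample, depth) {
    out <- list()
    for (ch in as.character(seq_len(config$n_chromosomes))) {
      rel <- if (identical(sample, "normal")) rep(1, n_bins) else
        vapply(bin_mid, function(p)
          site_expectation(config, pops[[sample]], ch, p)$rel_copy, numeric(1))
      out[[ch]] <- depth * rel
    }
    out
  }

  nv <- nrow(var_sites)
  normal <- draw_sample(streams[1],
                        rep(with_error(0.5, eps), nrow(snp)),
                        rep(config$mean_depth_normal, nrow(snp)),
                        rep(with_error(0, eps), nv),
                        rep(config$mean_depth_normal, nv),
                        bin_rel_depth("normal", config$mean_depth_normal))
  primary <- draw_sample(streams[2],
                         with_error(exp_baf$primary, eps),
                         config$mean_depth_tumor * exp_rel$primary,
                         with_error(exp_vaf$primary, eps),
                         rep(config$mean_depth_tumor, nv),
                         bin_rel_depth("primary", config$mean_depth_tumor))
  relapse <- draw_sample(streams[3],
                         with_error(exp_baf$relapse, eps),
                         config$mean_depth_tumor * exp_rel$relapse,
                         with_error(exp_vaf$relapse, eps),
                         rep(config$mean_depth_tumor, nv),
                         bin_rel_depth("relapse", config$mean_depth_tumor))

  ord <- function(x) x[order(x$idx), c("alt", "ref")]
  snps <- data.frame(chrom = snp$chrom, pos = snp$pos,
                     b6_allele = "C", s129_allele = "T",
                     normal_ref = ord(normal$snp)$ref,
                     normal_alt = ord(normal$snp)$alt,
                     primary_ref = ord(primary$snp)$ref,
                     primary_alt = ord(primary$snp)$alt,
                     relapse_ref = ord(relapse$snp)$ref,
                     relapse_alt = ord(relapse$snp)$alt,
                     stringsAsFactors = FALSE)

  variants <- if (nv) {
    vo <- function(x) x$var[order(x$var$idx), c("alt", "ref")]
    no <- vo(normal); pr <- vo(primary); re <- vo(relapse)
    data.frame(variant_id = paste0(var_sites$gene, "_", var_sites$chrom, "_",
                                   var_sites$pos),
               gene = var_sites$gene, chrom = var_sites$chrom,
               pos = var_sites$pos, ref = "C", alt = "T",
               normal_alt = no$alt, normal_depth = no$alt + no$ref,
               primary_alt = pr$alt, primary_depth = pr$alt + pr$ref,
               relapse_alt = re$alt, relapse_depth = re$alt + re$ref,
               stringsAsFactors = FALSE, row.names = NULL)
  } else NULL

  mk_bins <- function(t) data.frame(chrom = normal$bins$chrom,
                                    start = normal$bins$start,
                                    end = normal$bins$end,
                                    normal_depth = normal$bins$depth,
                                    tumor_depth = t$bins$depth,
                                    stringsAsFactors = FALSE)

  truth <- list(
    config = unclass(config)[setdiff(names(config), c("events", "clones"))],
    seed = config$seed,
    events = lapply(config$events, unclass),
    clone_fractions = data.frame(
      clone_id = vapply(config$clones, `[[`, character(1), "clone_id"),
      fraction_primary = vapply(config$clones, `[[`, numeric(1), "fraction_primary"),
      fraction_relapse = vapply(config$clones, `[[`, numeric(1), "fraction_relapse")),
    expected_baf = data.frame(chrom = snp$chrom, pos = snp$pos,
                              primary = exp_baf$primary,
                              relapse = exp_baf$relapse),
    expected_vaf = if (nv) data.frame(variant_id = variants$variant_id,
                                      primary = exp_vaf$primary,
                                      relapse = exp_vaf$relapse) else NULL)

  structure(list(snps = snps, variants = variants,
                 bins_primary = mk_bins(primary),
                 bins_relapse = mk_bins(relapse),
                 truth = truth),
            class = "f1loh_sim")
}

#' Extract a tumor/normal SNP observation table from a simulation
#'
#' @param sim an `f1loh_sim` object.
#' @param sample `"primary"` or `"relapse"`.
#' @return data.frame with columns `chrom`, `pos`, `b6_allele`,
#'   `s129_allele`, `normal_ref`, `normal_alt`, `tumor_ref`, `tumor_alt`.
#' @export
snp_observations <- function(sim, sample = c("primary", "relapse")) {
  sample <- match.arg(sample)
  s <- sim$snps
  data.frame(chrom = s$chrom, pos = s$pos, b6_allele = s$b6_allele,
             s129_allele = s$s129_allele,
             normal_ref = s$normal_ref, normal_alt = s$normal_alt,
             tumor_ref = s[[paste0(sample, "_ref")]],
             tumor_alt = s[[paste0(sample, "_alt")]],
             stringsAsFactors = FALSE)
}
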