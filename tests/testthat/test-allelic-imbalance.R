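snp_row <- function(pos, n_ref, n_alt, t_ref, t_alt) {
  data.frame(chrom = "1", pos = pos, b6_allele = "C", s129_allele = "T",
             normal_ref = n_ref, normal_alt = n_alt,
             tumor_ref = t_ref, tumor_alt = t_alt, stringsAsFactors = FALSE)
}

test_that("compute_baf applies the het and depth gates", {
  obs <- rbind(snp_row(100, 14, 16, 3, 57),    # usable, baf 0.95
               snp_row(200, 30, 30, 30, 30),   # usable, folded 0.5
               snp_row(300, 14, 16, 9, 10),    # tumor depth 19: excluded
               snp_row(400, 50, 5, 30, 30),    # normal not het: excluded
               snp_row(500, 9, 10, 30, 30))    # normal depth 19: excluded
  baf <- compute_baf(obs, min_depth = 20)
  expect_equal(baf$pos, c(100, 200))
  expect_equal(baf$baf, c(0.95, 0.5))
  expect_equal(baf$folded_baf, c(0.95, 0.5))
  expect_identical(attr(baf, "n_excluded"), 3L)
})

test_that("compute_logr matches pure-tumor closed forms", {
  bins <- expand.grid(chrom = as.character(1:10), i = 1:10,
                      stringsAsFactors = FALSE)
  bins <- data.frame(chrom = bins$chrom, start = (bins$i - 1) * 1e6,
                     end = bins$i * 1e6, normal_depth = 100,
                     tumor_depth = 100)
  # tumor = normal everywhere: all logR zero
  expect_true(all(compute_logr(bins)$logr == 0))
  # chromosome 1 at 1.5x coverage: trisomy expectation log2(1.5)
  tri <- bins; tri$tumor_depth[tri$chrom == "1"] <- 150
  lr <- compute_logr(tri)
  expect_equal(mean(lr$logr[lr$chrom == "1"]), log2(1.5), tolerance = 1e-12)
  # hemizygous deletion at purity 1: log2(1/2) = -1
  del <- bins; del$tumor_depth[del$chrom == "1"] <- 50
  lr <- compute_logr(del)
  expect_equal(mean(lr$logr[lr$chrom == "1"]), -1, tolerance = 1e-12)
  bad <- bins; bad$normal_depth <- 0
  expect_error(compute_logr(bad), class = "f1loh_input_error")
})

test_that("classify_segment implements the BAF/logR decision table", {
  expect_identical(as.character(classify_segment(0.95, 0.02)), "CN_LOH")
  expect_identical(as.character(classify_segment(0.97, -0.9)), "DELETION")
  expect_identical(as.character(classify_segment(0.5, 0.0)), "RETAINED_HET")
  expect_identical(as.character(classify_segment(0.66, 0.55)), "GAIN")
  # LOH-level BAF with logR matching no row: retained het, flagged ambiguous
  s <- classify_segment(0.95, -0.28)
  expect_identical(as.character(s), "RETAINED_HET")
  expect_true(attr(s, "ambiguous"))
  # inconsistent thresholds rejected
  expect_error(ai_thresholds(logr_neutral = 0.4, logr_del = -0.35),
               class = "f1loh_config_error")
  expect_error(ai_thresholds(logr_neutral = 0.4, logr_gain = 0.3),
               class = "f1loh_config_error")
  expect_error(ai_thresholds(baf_loh = 0.4), class = "f1loh_config_error")
})

test_that("chromosome-mode segmentation emits one classified segment each", {
  sim <- simulate_pair(cond_config("CN_LOH", seed = 21))
  segs <- segment_track(compute_baf(snp_observations(sim, "primary")),
                        compute_logr(sim$bins_primary))
  expect_equal(nrow(segs), 4L)
  expect_identical(segs$state[segs$chrom == "1"], "CN_LOH")
  expect_true(all(segs$state[segs$chrom != "1"] == "RETAINED_HET"))
  expect_true(all(segs$n_sites == 50))
  expect_error(segment_track(compute_baf(snp_observations(sim, "primary")),
                             NULL, min_sites = 1),
               class = "f1loh_config_error")
})

test_that("binary segmentation recovers a half-chromosome CN-LOH breakpoint", {
  # 100 SNPs on one 100-Mb chromosome, CN-LOH over the first half
  cfg <- sim_config(seed = 31, n_chromosomes = 2, chrom_length_bp = 1e8,
                    snp_density = 1, mean_depth_normal = 100,
                    mean_depth_tumor = 100, purity_primary = 0.9,
                    purity_relapse = 0.9,
                    events = list(cn_event("1", 1, 5e7, "CN_LOH", "B6", "t")),
                    clones = list(clone_spec("t", 1, 1)))
  sim <- simulate_pair(cfg)
  baf <- compute_baf(snp_observations(sim, "primary"))
  segs <- segment_track(baf, compute_logr(sim$bins_primary),
                        mode = "binary_segmentation")
  chr1 <- segs[segs$chrom == "1", ]
  expect_equal(nrow(chr1), 2L)
  expect_identical(chr1$state, c("CN_LOH", "RETAINED_HET"))
  # breakpoint within 2 SNP spacings (1 Mb each) of the true 50-Mb boundary
  expect_lt(abs(chr1$end[1] - 5e7), 2e6)
  # deterministic: identical input gives identical segments
  expect_identical(segs, segment_track(baf, compute_logr(sim$bins_primary),
                                       mode = "binary_segmentation"))
})

test_that("purity is recovered from CN-LOH folded BAF", {
  expect_equal(purity_from_baf(1.0), 1.0)
  expect_equal(purity_from_baf(0.9), 0.8)
  expect_equal(purity_from_baf(0.5), 0.0)
  expect_error(purity_from_baf(0.9, state = "DELETION"),
               class = "f1loh_not_applicable")
  # recovery on simulation: |estimate - truth| <= 0.05
  for (p in c(0.7, 0.8, 0.9, 0.95)) {
    sim <- simulate_pair(cond_config("CN_LOH", seed = round(100 * p),
                                     purity = p))
    baf <- compute_baf(snp_observations(sim, "primary"))
    est <- purity_from_baf(mean(baf$folded_baf[baf$chrom == "1"]))
    expect_lt(abs(est - p), 0.05)
  }
})

test_that("mutant duplication is called from VAF plus segment state", {
  segs <- data.frame(chrom = c("6", "7", "8"), start = 0, end = 1e8,
                     state = c("CN_LOH", "CN_LOH", "DELETION"),
                     n_sites = 100, mean_folded_baf = c(0.95, 0.95, 0.97),
                     mean_logr = c(0, 0, -0.9), stringsAsFactors = FALSE)
  v <- data.frame(variant_id = c("kras", "low", "hemi", "out"),
                  chrom = c("6", "7", "8", "9"),
                  pos = c(5e7, 5e7, 5e7, 5e7),
                  primary_alt = c(127, 45, 95, 50),
                  primary_depth = c(138, 100, 100, 100),
                  stringsAsFactors = FALSE)
  expect_warning(calls <- call_mutant_duplication(v, segs), "outside")
  expect_identical(calls$duplicated, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(calls$mechanism[1], "uniparental disomy")
  expect_match(calls$mechanism[3], "hemizygous")
  expect_true(is.na(calls$segment_state[4]))
})

test_that("relabeling the strains leaves folded BAF and calls unchanged", {
  sim <- simulate_pair(cond_config("CN_LOH", seed = 41,
                                   mutations = data.frame(
                                     chrom = "1", pos = 2.5e7, gene = "Kras",
                                     multiplicity = 2L)))
  obs <- snp_observations(sim, "primary")
  swapped <- obs
  swapped[c("normal_ref", "normal_alt", "tumor_ref", "tumor_alt")] <-
    obs[c("normal_alt", "normal_ref", "tumor_alt", "tumor_ref")]
  baf <- compute_baf(obs); baf_sw <- compute_baf(swapped)
  expect_equal(baf_sw$folded_baf, baf$folded_baf)
  lr <- compute_logr(sim$bins_primary)
  expect_identical(segment_track(baf_sw, lr), segment_track(baf, lr))
})

test_that("raising the BAF cutoff never converts RETAINED_HET to CN_LOH", {
  set.seed(13)
  b <- runif(300, 0.5, 1); r <- runif(300, -1, 1)
  lo <- classify_segment(b, r, ai_thresholds(baf_loh = 0.8))
  hi <- classify_segment(b, r, ai_thresholds(baf_loh = 0.9))
  expect_false(any(lo == "RETAINED_HET" & hi == "CN_LOH"))
})
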