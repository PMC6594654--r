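test_that("reported VAFs round half-up to three decimals", {
  expect_equal(vaf(75, 137), 0.547)
  expect_equal(vaf(127, 138), 0.920)
  expect_equal(vaf(82, 150), 0.547)
  expect_equal(vaf(11, 102), 0.108)
  expect_equal(vaf(0, 100), 0)
  expect_equal(vaf(1, 2000), 0.001)   # 0.0005 ties upward
  expect_equal(vaf(75, 137, digits = NULL), 75 / 137)
  expect_error(vaf(0, 0), class = "f1loh_undefined_vaf")
  expect_error(vaf(10, 5), class = "f1loh_format_error")
})

test_that("binomial_ci is the Clopper-Pearson interval", {
  expect_equal(binomial_ci(0, 50)$lower, 0)
  expect_equal(binomial_ci(50, 50)$upper, 1)
  expect_error(binomial_ci(5, 10, confidence = 1.2),
               class = "f1loh_config_error")
  # cross-check against the independent exact implementation in binom.test
  for (alt in c(0, 1, 11, 75, 102)) {
    ref <- binom.test(alt, 102)$conf.int
    ci <- binomial_ci(alt, 102)
    expect_equal(c(ci$lower, ci$upper), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("compare_pair detects the printed primary/relapse shifts", {
  # Kras-like: 127/138 (0.920) falling to 82/150 (0.547)
  res <- compare_pair(127, 138, 82, 150)
  expect_identical(res$direction, "depleted")
  expect_lt(res$p, 0.001)
  expect_equal(res$p, fisher_enum_p(127, 11, 82, 68), tolerance = 1e-12)
  # identical counts: p = 1, stable
  res <- compare_pair(50, 100, 50, 100)
  expect_equal(res$p, 1)
  expect_identical(res$direction, "stable")
  # de novo regime: absent from the primary, half the reads at relapse
  res <- compare_pair(0, 137, 75, 137)
  expect_identical(res$direction, "enriched")
  expect_lt(res$p, 1e-15)
  expect_equal(res$p, fisher_enum_p(0, 137, 75, 62), tolerance = 1e-12)
  # both samples unsequenced: not testable
  res <- compare_pair(0, 0, 0, 0)
  expect_false(res$testable)
  expect_true(is.na(res$p))
})

test_that("compare_pair agrees with enumeration on random small tables", {
  set.seed(17)
  for (i in 1:200) {
    tp <- sample(1:40, 1); tr <- sample(1:40, 1)
    a <- sample(0:tp, 1); c <- sample(0:tr, 1)
    expect_equal(compare_pair(a, tp, c, tr)$p,
                 fisher_enum_p(a, tp - a, c, tr - c), tolerance = 1e-9)
  }
})

test_that("clonal status follows the detection-limit and q-value rules", {
  # de novo: < 3 alt reads in the primary, significant enrichment
  expect_identical(classify_status(0, 140, 75, 137, q = 1e-10), "DE_NOVO")
  expect_identical(classify_status(2, 140, 75, 137, q = 1e-10), "DE_NOVO")
  # pre-existing low-frequency mutation enriched at relapse
  expect_identical(classify_status(11, 102, 85, 137, q = 1e-3), "ENRICHED")
  expect_identical(classify_status(127, 138, 82, 150, q = 1e-3), "DEPLETED")
  expect_identical(classify_status(75, 137, 1, 140, q = 1e-10), "LOST")
  # non-significant shifts are stable whatever the direction
  expect_identical(classify_status(10, 100, 60, 100, q = 0.2), "STABLE")
})

test_that("BH adjustment is monotone and degenerate at p = 1", {
  v <- data.frame(variant_id = sprintf("v%02d", 1:6), gene = "g",
                  primary_alt = c(0, 11, 127, 50, 40, 30),
                  primary_depth = c(140, 102, 138, 100, 100, 100),
                  relapse_alt = c(75, 85, 82, 50, 42, 29),
                  relapse_depth = c(137, 137, 150, 100, 100, 100))
  calls <- compare_pair_table(v)
  expect_true(all(calls$q >= calls$p))
  o <- order(calls$p)
  expect_true(all(diff(calls$q[o]) >= -1e-12))
  expect_identical(calls$status[1:3], c("DE_NOVO", "ENRICHED", "DEPLETED"))
  # all pairs identical: every p and q is 1, everything stable
  same <- v; same$relapse_alt <- same$primary_alt
  same$relapse_depth <- same$primary_depth
  calls <- compare_pair_table(same)
  expect_true(all(calls$p == 1) && all(calls$q == 1))
  expect_true(all(calls$status == "STABLE"))
})

test_that("swapping the sample labels mirrors every status", {
  v <- data.frame(variant_id = sprintf("v%02d", 1:4), gene = "g",
                  primary_alt = c(0, 11, 127, 50),
                  primary_depth = c(140, 102, 138, 100),
                  relapse_alt = c(75, 85, 82, 50),
                  relapse_depth = c(137, 137, 150, 100))
  fwd <- compare_pair_table(v)
  sw <- v
  sw[c("primary_alt", "primary_depth", "relapse_alt", "relapse_depth")] <-
    v[c("relapse_alt", "relapse_depth", "primary_alt", "primary_depth")]
  rev <- compare_pair_table(sw)
  expect_equal(rev$p, fwd$p, tolerance = 1e-12)
  flip <- c(ENRICHED = "DEPLETED", DEPLETED = "ENRICHED", STABLE = "STABLE",
            DE_NOVO = "LOST", LOST = "DE_NOVO")
  expect_identical(rev$status, unname(flip[fwd$status]))
})

test_that("re-acquired heterozygosity needs a duplicated primary and a het relapse", {
  # duplicated mutant (0.920 in CN-LOH) falling to 82/150 at relapse
  expect_true(detect_heterozygosity_reacquisition(TRUE, 82, 150,
                                                  purity = 0.98))
  # still duplicated at relapse: no transition
  expect_false(detect_heterozygosity_reacquisition(TRUE, 135, 150))
  # never duplicated in the primary: reverse transitions reported elsewhere
  expect_false(detect_heterozygosity_reacquisition(FALSE, 135, 150))
  expect_true(is.na(detect_heterozygosity_reacquisition(NA, 82, 150)))
})

test_that("clone grouping separates distinct VAF trajectories", {
  calls <- data.frame(variant_id = c("Kras", "Pten"),
                      vaf_primary = c(0.92, 0.11),
                      vaf_relapse = c(0.55, 0.62), stringsAsFactors = FALSE)
  g <- group_clones(calls, linkage_cutoff = 0.1)
  expect_equal(length(unique(g$clone)), 2L)
  one <- data.frame(variant_id = c("a", "b", "c"), vaf_primary = 0.4,
                    vaf_relapse = 0.4)
  g <- group_clones(one)
  expect_true(all(g$clone == 1L))
  expect_true(attr(g, "clones")$ancestral)
})

test_that("clone grouping recovers simulated clone partitions", {
  skip_if_not_installed("mclust")
  centers <- list(c(0.9, 0.9), c(0.5, 0.2), c(0.1, 0.6))
  ari <- vapply(1:50, function(s) {
    set.seed(s)
    truth <- rep(1:3, each = 5)
    df <- do.call(rbind, lapply(seq_along(truth), function(i) {
      ctr <- centers[[truth[i]]]
      data.frame(variant_id = sprintf("v%02d", i),
                 vaf_primary = rbinom(1, 150, ctr[1]) / 150,
                 vaf_relapse = rbinom(1, 150, ctr[2]) / 150)
    }))
    g <- group_clones(df, linkage_cutoff = 0.1)
    mclust::adjustedRandIndex(g$clone[order(g$variant_id)], truth)
  }, numeric(1))
  expect_gte(mean(ari), 0.9)
})

test_that("Sanger peak intensities convert to allele fractions", {
  expect_equal(sanger_af(9.2, 0.8), 0.92)
  expect_equal(sanger_af(1, 1), 0.5)
  expect_equal(sanger_af(0, 5), 0)
  expect_error(sanger_af(0, 0), class = "f1loh_undefined_fraction")
  expect_error(sanger_af(-1, 2), class = "f1loh_format_error")
})
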