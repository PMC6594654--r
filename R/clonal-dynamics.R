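## Primary-versus-relapse variant allele frequency analysis.
##
## Each somatic variant's alt/ref counts in the primary and relapsed tumor
## form a 2x2 table; Fisher's exact test (exact at exome depths of ~100-150
## reads) detects enrichment or depletion under treatment selection, with
## Benjamini-Hochberg control across the variants of one pair.

VARIANT_STATUSES <- c("ENRICHED", "DEPLETED", "STABLE", "DE_NOVO", "LOST")

#' Variant allele frequency
#'
#' @param alt alt-supporting read count.
#' @param total total read depth; must be positive.
#' @param digits decimals for reporting (ties round up); `NULL` returns full
#'   precision.
#' @return `alt / total`, rounded to `digits` decimals.
#' @examples
#' vaf(75, 137)   # 0.547
#' vaf(11, 102)   # 0.108
#' @export
vaf <- function(alt, total, digits = 3) {
  if (any(total == 0))
    stop_f1("VAF undefined at zero depth", class = "f1loh_undefined_vaf")
  if (any(alt < 0 | alt > total))
    stop_f1("alt count must lie in [0, total]", class = "f1loh_format_error")
  x <- alt / total
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' @param alt,total successes and trials (vectorized).
#' @param confidence interval coverage, in (0, 1).
#' @return data.frame with columns `lower`, `upper`.
#' @export
binomial_ci <- function(alt, total, confidence = 0.95) {
  if (confidence <= 0 || confidence >= 1)
    stop_f1("confidence must lie in (0, 1)", class = "f1loh_config_error")
  if (any(alt < 0 | alt > total))
    stop_f1("alt count must lie in [0, total]", class = "f1loh_format_error")
  a <- (1 - confidence) / 2
  lower <- ifelse(alt == 0, 0, qbeta(a, alt, total - alt + 1))
  upper <- ifelse(alt == total, 1, qbeta(1 - a, alt + 1, total - alt))
  data.frame(lower = lower, upper = upper)
}

#' Exact test for a VAF shift between primary and relapse
#'
#' Two-sided Fisher's exact test on the table
#' `[[alt_primary, ref_primary], [alt_relapse, ref_relapse]]`. The direction
#' is read from the VAF comparison: `"enriched"` when the relapse VAF is
#' higher, `"depleted"` when lower, `"stable"` when equal.
#'
#' @param alt_primary,total_primary primary-sample counts.
#' @param alt_relapse,total_relapse relapse-sample counts.
#' @return list with `p`, `direction`, and `testable` (FALSE when both
#'   samples have zero depth, in which case `p` is `NA`).
#' @export
compare_pair <- function(alt_primary, total_primary, alt_relapse,
                         total_relapse) {
  if (total_primary == 0 && total_relapse == 0)
    return(list(p = NA_real_, direction = NA_character_, testable = FALSE))
  tab <- matrix(c(alt_primary, total_primary - alt_primary,
                  alt_relapse, total_relapse - alt_relapse),
                nrow = 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  vp <- if (total_primary > 0) alt_primary / total_primary else 0
  vr <- if (total_relapse > 0) alt_relapse / total_relapse else 0
  direction <- if (vr > vp) "enriched" else if (vr < vp) "depleted" else "stable"
  list(p = min(p, 1), direction = direction, testable = TRUE)
}

#' Classify a variant's clonal status across a primary/relapse pair
#'
#' Rules, applied in order at significance `q < alpha`:
#' `DE_NOVO` when the primary has fewer than `lod_reads` alt reads and the
#' relapse VAF is positive (the mutation was below the limit of detection
#' before treatment); `LOST` for the mirror case; otherwise `ENRICHED` or
#' `DEPLETED` by direction. Non-significant variants are `STABLE`.
#'
#' @param alt_primary,total_primary,alt_relapse,total_relapse counts.
#' @param q Benjamini-Hochberg adjusted p for this variant (computed across
#'   the variants of one pair).
#' @param alpha significance level.
#' @param lod_reads minimum alt reads considered detectable.
#' @return one of `"ENRICHED"`, `"DEPLETED"`, `"STABLE"`, `"DE_NOVO"`,
#'   `"LOST"`.
#' @export
classify_status <- function(alt_primary, total_primary, alt_relapse,
                            total_relapse, q, alpha = 0.05, lod_reads = 3) {
  if (is.na(q)) return("STABLE")
  vp <- if (total_primary > 0) alt_primary / total_primary else 0
  vr <- if (total_relapse > 0) alt_relapse / total_relapse else 0
  if (q >= alpha) return("STABLE")
  if (alt_primary < lod_reads && vr > 0) return("DE_NOVO")
  if (alt_relapse < lod_reads && vp > 0) return("LOST")
  if (vr > vp) "ENRICHED" else if (vr < vp) "DEPLETED" else "STABLE"
}

#' Paired primary/relapse calls for a variant table
#'
#' Convenience wrapper running [compare_pair()], Benjamini-Hochberg
#' adjustment across the pair's variants, [classify_status()] and
#' [binomial_ci()] for every variant.
#'
#' @param variants variant data.frame with `primary_alt`, `primary_depth`,
#'   `relapse_alt`, `relapse_depth` (see [read_variant_table()]).
#' @param alpha significance level.
#' @param lod_reads limit of detection in alt reads.
#' @param confidence CI coverage.
#' @return data.frame with VAFs (reported at 3 decimals), exact CIs, `p`,
#'   `q`, `direction` and `status` per variant.
#' @export
compare_pair_table <- function(variants, alpha = 0.05, lod_reads = 3,
                               confidence = 0.95) {
  n <- nrow(variants)
  res <- lapply(seq_len(n), function(i)
    compare_pair(variants$primary_alt[i], variants$primary_depth[i],
                 variants$relapse_alt[i], variants$relapse_depth[i]))
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- p.adjust(p, method = "BH")
  cip <- binomial_ci(variants$primary_alt, variants$primary_depth, confidence)
  cir <- binomial_ci(variants$relapse_alt, variants$relapse_depth, confidence)
  status <- vapply(seq_len(n), function(i)
    classify_status(variants$primary_alt[i], variants$primary_depth[i],
                    variants$relapse_alt[i], variants$relapse_depth[i],
                    q[i], alpha, lod_reads), character(1))
  safe_vaf <- function(alt, total)
    ifelse(total > 0, round_half_up(alt / pmax(total, 1), 3), NA_real_)
  data.frame(variant_id = variants$variant_id,
             gene = variants$gene %||% NA_character_,
             vaf_primary = safe_vaf(variants$primary_alt,
                                    variants$primary_depth),
             ci_primary_lower = cip$lower, ci_primary_upper = cip$upper,
             vaf_relapse = safe_vaf(variants$relapse_alt,
                                    variants$relapse_depth),
             ci_relapse_lower = cir$lower, ci_relapse_upper = cir$upper,
             p = p, q = q,
             direction = vapply(res, `[[`, character(1), "direction"),
             status = status, stringsAsFactors = FALSE)
}

#' Detect re-acquired heterozygosity of a duplicated mutant allele
#'
#' Fires when a variant called as a duplicated mutant (VAF above the
#' duplication threshold inside a CN-LOH segment) in the primary tumor is
#' consistent with heterozygosity at relapse: its purity-corrected exact CI
#' overlaps `het_band`. The reverse transition (het primary, duplicated
#' relapse) is reported separately by duplication calling, not here.
#'
#' @param primary_duplicated logical duplication call in the primary (from
#'   [call_mutant_duplication()]); `NA` (no segment context) returns `NA`.
#' @param relapse_alt,relapse_depth relapse counts for the same variant.
#' @param purity relapse tumor purity used to correct the CI (copy-neutral
#'   assumption: corrected fraction = observed / purity).
#' @param het_band VAF band treated as heterozygous.
#' @param confidence CI coverage.
#' @return `TRUE`/`FALSE`, or `NA` if not evaluable.
#' @export
detect_heterozygosity_reacquisition <- function(primary_duplicated,
                                                relapse_alt, relapse_depth,
                                                purity = 1,
                                                het_band = c(0.4, 0.6),
                                                confidence = 0.95) {
  if (is.na(primary_duplicated)) return(NA)
  if (!primary_duplicated) return(FALSE)
  if (relapse_depth == 0) return(NA)
  ci <- binomial_ci(relapse_alt, relapse_depth, confidence)
  lo <- min(ci$lower / purity, 1); hi <- min(ci$upper / purity, 1)
  hi >= het_band[1] && lo <= het_band[2]
}

#' Group variants into clones by their primary/relapse VAF trajectory
#'
#' Average-linkage hierarchical clustering of variants in
#' `(vaf_primary, vaf_relapse)` space with Euclidean distance, cut at
#' `linkage_cutoff`. This is a deliberately simple two-sample grouping, not
#' a phylogeny inference. The group whose mean VAF is maximal in both
#' samples is flagged ancestral (no flag when no group dominates both).
#' Input is ordered by variant id first, so ties resolve deterministically.
#'
#' @param calls data.frame from [compare_pair_table()] (needs `variant_id`,
#'   `vaf_primary`, `vaf_relapse`).
#' @param linkage_cutoff dendrogram height at which to cut.
#' @return `calls` with an integer `clone` column; the `"clones"` attribute
#'   holds per-clone mean VAFs and the `ancestral` flag.
#' @export
group_clones <- function(calls, linkage_cutoff = 0.1) {
  if (!nrow(calls))
    stop_f1("no variants to group", class = "f1loh_input_error")
  calls <- calls[order(calls$variant_id), , drop = FALSE]
  m <- cbind(calls$vaf_primary, calls$vaf_relapse)
  if (nrow(calls) == 1L) {
    grp <- 1L
  } else {
    hc <- hclust(dist(m), method = "average")
    grp <- cutree(hc, h = linkage_cutoff)
    grp <- as.integer(factor(grp, levels = unique(grp)))  # stable labels
  }
  calls$clone <- grp
  means <- do.call(rbind, lapply(split(seq_len(nrow(calls)), grp), function(i)
    data.frame(clone = grp[i][1], n_variants = length(i),
               mean_vaf_primary = mean(m[i, 1]),
               mean_vaf_relapse = mean(m[i, 2]))))
  top_p <- means$mean_vaf_primary >= max(means$mean_vaf_primary) - 1e-12
  top_r <- means$mean_vaf_relapse >= max(means$mean_vaf_relapse) - 1e-12
  means$ancestral <- top_p & top_r
  rownames(means) <- NULL
  attr(calls, "clones") <- means
  calls
}

#' Allele fraction from Sanger trace peak intensities
#'
#' The mutant-allele fraction implied by relative peak heights of the mutant
#' and wild-type bases at a sequenced position.
#'
#' @param mut_peak,wt_peak non-negative peak intensities; not both zero.
#' @return `mut_peak / (mut_peak + wt_peak)`.
#' @export
sanger_af <- function(mut_peak, wt_peak) {
  if (any(mut_peak < 0 | wt_peak < 0))
    stop_f1("peak intensities must be non-negative",
            class = "f1loh_format_error")
  if (any(mut_peak + wt_peak == 0))
    stop_f1("both peaks are zero; allele fraction undefined",
            class = "f1loh_undefined_fraction")
  mut_peak / (mut_peak + wt_peak)
}
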