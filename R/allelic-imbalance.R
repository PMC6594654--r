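## B-allele-frequency and copy-number log-ratio analysis.
##
## The F1-hybrid design makes every strain-informative SNP germline
## heterozygous, so somatic loss of one parental haplotype is visible as a
## genome-wide shift of the folded BAF towards 1, and the depth log-ratio
## separates copy-neutral LOH (uniparental disomy) from hemizygous deletion
## and from gain.

SEGMENT_STATES <- c("RETAINED_HET", "CN_LOH", "DELETION", "GAIN")

#' Classification thresholds for segment states
#'
#' @param baf_loh minimum mean folded BAF to declare loss of heterozygosity.
#' @param logr_neutral half-width of the copy-neutral logR band.
#' @param logr_del maximum logR compatible with hemizygous deletion
#'   (the purity-1 expectation is `log2(1/2) = -1`).
#' @param logr_gain minimum logR to call a gain (purity-1 trisomy expects
#'   `log2(3/2) = 0.585`).
#' @return a named list of validated thresholds.
#' @export
ai_thresholds <- function(baf_loh = 0.85, logr_neutral = 0.2,
                          logr_del = -0.35, logr_gain = 0.3) {
  if (baf_loh <= 0.5 || baf_loh > 1)
    stop_f1("baf_loh must lie in (0.5, 1]", class = "f1loh_config_error")
  if (logr_neutral <= 0)
    stop_f1("logr_neutral must be positive", class = "f1loh_config_error")
  if (logr_del >= -logr_neutral)
    stop_f1("deletion cutoff (", logr_del, ") must lie below the neutral ",
            "band (-", logr_neutral, ")", class = "f1loh_config_error")
  if (logr_gain <= logr_neutral)
    stop_f1("gain cutoff (", logr_gain, ") must lie above the neutral band (",
            logr_neutral, ")", class = "f1loh_config_error")
  list(baf_loh = baf_loh, logr_neutral = logr_neutral,
       logr_del = logr_del, logr_gain = logr_gain)
}

#' Compute B-allele-frequency points from SNP observations
#'
#' BAF is the tumor S129-allele read fraction. A site is usable only if the
#' normal sample looks germline heterozygous (normal BAF within `het_range`)
#' and both samples reach `min_depth` reads; other sites are excluded and
#' tallied in the `"n_excluded"` attribute.
#'
#' @param observations SNP observation data.frame (see [read_snp_table()]).
#' @param min_depth minimum depth required in both tumor and normal.
#' @param het_range allowed normal-sample BAF range for a heterozygous call.
#' @return data.frame with `chrom`, `pos`, `baf`, `folded_baf`,
#'   `tumor_depth`, `normal_depth`.
#' @export
compute_baf <- function(observations, min_depth = 20,
                        het_range = c(0.25, 0.75)) {
  x <- validate_snp_table(observations)
  ndepth <- x$normal_ref + x$normal_alt
  tdepth <- x$tumor_ref + x$tumor_alt
  nbaf <- ifelse(ndepth > 0, x$normal_alt / ndepth, NA_real_)
  keep <- !is.na(nbaf) & nbaf >= het_range[1] & nbaf <= het_range[2] &
    ndepth >= min_depth & tdepth >= min_depth
  out <- data.frame(chrom = x$chrom[keep], pos = x$pos[keep],
                    baf = x$tumor_alt[keep] / tdepth[keep],
                    tumor_depth = tdepth[keep], normal_depth = ndepth[keep],
                    stringsAsFactors = FALSE)
  out$folded_baf <- pmax(out$baf, 1 - out$baf)
  out <- out[c("chrom", "pos", "baf", "folded_baf", "tumor_depth",
               "normal_depth")]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Compute the median-centered depth log-ratio track
#'
#' Per bin, `log2(tumor_depth / normal_depth)` minus the genome-wide median
#' (so a majority-diploid genome centers at 0). Bins with zero depth in
#' either sample are excluded and tallied in the `"n_excluded"` attribute.
#'
#' @param bins depth-bin data.frame (see [read_depth_bins()]).
#' @return data.frame with `chrom`, `start`, `end`, `logr`.
#' @export
compute_logr <- function(bins) {
  if (all(bins$normal_depth == 0))
    stop_f1("all normal depths are zero; cannot form log-ratios",
            class = "f1loh_input_error")
  keep <- bins$normal_depth > 0 & bins$tumor_depth > 0
  raw <- log2(bins$tumor_depth[keep] / bins$normal_depth[keep])
  out <- data.frame(chrom = bins$chrom[keep], start = bins$start[keep],
                    end = bins$end[keep], logr = raw - median(raw),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Classify a segment from its mean folded BAF and mean logR
#'
#' Decision table: folded BAF at or above `baf_loh` with logR inside the
#' neutral band is copy-neutral LOH; with logR at or below the deletion
#' cutoff it is a hemizygous deletion. Folded BAF below `baf_loh` with logR
#' at or above the gain cutoff is a gain (a trisomy moves folded BAF only to
#' about 2/3, so gains are driven by coverage). Everything else is retained
#' heterozygosity; combinations matching no row (e.g. LOH-level BAF with
#' logR between the neutral band and the deletion cutoff) additionally carry
#' an `"ambiguous"` attribute.
#'
#' @param mean_folded_baf,mean_logr segment summaries (vectorized).
#' @param thresholds an [ai_thresholds()] list.
#' @return character vector of states with a logical `"ambiguous"` attribute.
#' @export
classify_segment <- function(mean_folded_baf, mean_logr,
                             thresholds = ai_thresholds()) {
  th <- do.call(ai_thresholds, thresholds)  # re-validate
  n <- max(length(mean_folded_baf), length(mean_logr))
  b <- rep_len(mean_folded_baf, n); r <- rep_len(mean_logr, n)
  loh <- b >= th$baf_loh
  state <- rep("RETAINED_HET", n)
  ambiguous <- rep(FALSE, n)
  state[loh & abs(r) <= th$logr_neutral] <- "CN_LOH"
  state[loh & r <= th$logr_del] <- "DELETION"
  state[!loh & r >= th$logr_gain] <- "GAIN"
  ambiguous[loh & state == "RETAINED_HET"] <- TRUE
  attr(state, "ambiguous") <- ambiguous
  state
}

## Recursive binary segmentation on folded BAF means. Splits where the
## between-side difference is maximal (leftmost on ties), accepting the
## split when the difference exceeds `split_threshold` and both sides keep
## `min_sites` points.
split_points <- function(folded, min_sites, split_threshold) {
  n <- length(folded)
  if (n < 2 * min_sites) return(integer())
  cum <- cumsum(folded)
  k <- seq(min_sites, n - min_sites)
  diff <- abs(cum[k] / k - (cum[n] - cum[k]) / (n - k))
  best <- k[which.max(diff)]
  if (max(diff) <= split_threshold) return(integer())
  left <- split_points(folded[seq_len(best)], min_sites, split_threshold)
  right <- split_points(folded[seq(best + 1, n)], min_sites, split_threshold)
  c(left, best, best + right)
}

#' Segment BAF and logR tracks and classify each segment
#'
#' In `"chromosome"` mode (the default, matching whole-chromosome allele
#' frequency plots) each chromosome becomes one segment. In
#' `"binary_segmentation"` mode chromosomes are recursively split at the
#' point maximizing the difference in mean folded BAF between the two sides,
#' accepting a split when that difference exceeds `split_threshold` and both
#' sides retain at least `min_sites` SNPs; ties break to the leftmost point,
#' so the procedure is deterministic.
#'
#' Segment boundaries are reported as 0-based half-open intervals. LogR bins
#' are assigned to segments by bin midpoint; CN_LOH segments get a purity
#' estimate from [purity_from_baf()].
#'
#' @param baf_points output of [compute_baf()], sorted by (chrom, pos).
#' @param logr_points output of [compute_logr()], sorted by (chrom, start);
#'   may be `NULL`, in which case `mean_logr` is 0 (copy-neutral assumption)
#'   and only BAF evidence is used.
#' @param min_sites minimum SNPs per segment (at least 2).
#' @param mode `"chromosome"` or `"binary_segmentation"`.
#' @param split_threshold minimum folded-BAF mean difference to accept a split.
#' @param thresholds an [ai_thresholds()] list for classification.
#' @return segment data.frame: `chrom`, `start`, `end`, `state`, `n_sites`,
#'   `mean_folded_baf`, `mean_logr`, `purity_estimate`, `ambiguous`.
#' @export
segment_track <- function(baf_points, logr_points = NULL, min_sites = 10,
                          mode = c("chromosome", "binary_segmentation"),
                          split_threshold = 0.15,
                          thresholds = ai_thresholds()) {
  mode <- match.arg(mode)
  if (min_sites < 2)
    stop_f1("min_sites must be at least 2", class = "f1loh_config_error")
  chroms <- unique(baf_points$chrom)
  segs <- list()
  for (ch in chroms) {
    p <- baf_points[baf_points$chrom == ch, , drop = FALSE]
    p <- p[order(p$pos), , drop = FALSE]
    if (!nrow(p)) {
      warning("no usable BAF sites on chromosome ", ch)
      next
    }
    cuts <- if (mode == "binary_segmentation")
      split_points(p$folded_baf, min_sites, split_threshold) else integer()
    bounds <- c(0L, cuts, nrow(p))
    for (i in seq_len(length(bounds) - 1L)) {
      idx <- seq(bounds[i] + 1L, bounds[i + 1L])
      ## breakpoints at the midpoint between flanking SNPs; outer edges at
      ## the chromosome's observed extremes
      start <- if (i == 1L) p$pos[1] - 1L else
        floor((p$pos[bounds[i]] + p$pos[bounds[i] + 1L]) / 2)
      end <- if (i == length(bounds) - 1L) p$pos[nrow(p)] else
        floor((p$pos[bounds[i + 1L]] + p$pos[bounds[i + 1L] + 1L]) / 2)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = start, end = end, n_sites = length(idx),
        mean_folded_baf = mean(p$folded_baf[idx]), stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      state = character(), n_sites = integer(),
                      mean_folded_baf = numeric(), mean_logr = numeric(),
                      purity_estimate = numeric(), ambiguous = logical()))
  out <- do.call(rbind, segs)
  ## assign logR bins to segments by midpoint; segments tile each
  ## chromosome, so outer segments absorb bins beyond the SNP extremes
  out$mean_logr <- 0
  if (!is.null(logr_points) && nrow(logr_points)) {
    mid <- (logr_points$start + logr_points$end) / 2
    for (ch in unique(out$chrom)) {
      si <- which(out$chrom == ch)
      si <- si[order(out$start[si])]
      bi <- which(logr_points$chrom == ch)
      if (!length(bi)) next
      grp <- findInterval(mid[bi], c(-Inf, out$end[si][-length(si)], Inf))
      for (g in seq_along(si)) {
        sel <- bi[grp == g]
        if (length(sel)) out$mean_logr[si[g]] <- mean(logr_points$logr[sel])
      }
    }
  }
  state <- classify_segment(out$mean_folded_baf, out$mean_logr, thresholds)
  out$state <- as.character(state)
  out$ambiguous <- attr(state, "ambiguous")
  out$purity_estimate <- ifelse(
    out$state == "CN_LOH", pmin(pmax(2 * out$mean_folded_baf - 1, 0), 1),
    NA_real_)
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "state", "n_sites",
               "mean_folded_baf", "mean_logr", "purity_estimate", "ambiguous")]
  rownames(out) <- NULL
  out
}

#' Estimate tumor purity from a copy-neutral LOH segment
#'
#' Inverts the mixture expectation for a CN-LOH segment: with purity `p` the
#' folded BAF is `(1 + p) / 2`, so `p = 2 * folded_baf - 1` (clipped to
#' `[0, 1]`).
#'
#' @param mean_folded_baf segment mean folded BAF.
#' @param state the segment's classified state; must be `"CN_LOH"`.
#' @return purity estimate in `[0, 1]`.
#' @export
purity_from_baf <- function(mean_folded_baf, state = "CN_LOH") {
  if (!all(state == "CN_LOH"))
    stop_f1("purity_from_baf applies only to CN_LOH segments",
            class = "f1loh_not_applicable")
  pmin(pmax(2 * mean_folded_baf - 1, 0), 1)
}

#' Call mutant-allele duplication for somatic variants
#'
#' A variant is called a duplicated mutant allele when its tumor VAF exceeds
#' `vaf_threshold` and the enclosing segment is copy-neutral LOH — the
#' signature of uniparental disomy duplicating the mutant copy. A high VAF
#' inside a DELETION segment is instead explained by hemizygous loss of the
#' wild-type allele and is not a duplication.
#'
#' @param variants variant data.frame with `variant_id`, `chrom`, `pos` and
#'   counts for `sample` (`<sample>_alt`, `<sample>_depth`).
#' @param segments classified segments from [segment_track()].
#' @param sample which tumor sample's counts to use.
#' @param vaf_threshold minimum VAF for a duplication call.
#' @return data.frame with `variant_id`, `vaf`, `segment_state`,
#'   `duplicated`, `mechanism`. Variants outside all segments get `NA` calls
#'   with a warning.
#' @export
call_mutant_duplication <- function(variants, segments,
                                    sample = c("primary", "relapse"),
                                    vaf_threshold = 0.8) {
  sample <- match.arg(sample)
  alt <- variants[[paste0(sample, "_alt")]]
  depth <- variants[[paste0(sample, "_depth")]]
  v <- alt / depth
  state <- rep(NA_character_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    sel <- which(segments$chrom == variants$chrom[i] &
                   segments$start < variants$pos[i] &
                   variants$pos[i] <= segments$end)
    if (length(sel) == 1L) state[i] <- segments$state[sel]
  }
  if (anyNA(state))
    warning(sum(is.na(state)), " variant(s) fall outside all segments and ",
            "are left unassigned")
  duplicated <- !is.na(state) & v > vaf_threshold & state == "CN_LOH"
  mechanism <- rep("none", nrow(variants))
  mechanism[duplicated] <-
    "copy-neutral LOH with duplicated mutant allele (uniparental disomy)"
  mechanism[!is.na(state) & v > vaf_threshold & state == "DELETION"] <-
    "hemizygous loss of the wild-type allele"
  mechanism[is.na(state)] <- NA_character_
  data.frame(variant_id = variants$variant_id, vaf = v,
             segment_state = state, duplicated = duplicated,
             mechanism = mechanism, stringsAsFactors = FALSE)
}
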