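## Cohort summaries: somatic mutation burden per callable megabase and
## per-pathway recurrence fractions.

#' Somatic mutation burden per megabase
#'
#' @param n_somatic somatic alteration count per sample (vectorized).
#' @param target_mb callable target size in megabases.
#' @return alterations per Mb.
#' @examples
#' mutation_burden(25, 50)  # 0.5 per Mb
#' @export
mutation_burden <- function(n_somatic, target_mb) {
  if (any(target_mb <= 0))
    stop_f1("target_mb must be positive", class = "f1loh_config_error")
  if (any(n_somatic < 0))
    stop_f1("n_somatic must be non-negative", class = "f1loh_format_error")
  n_somatic / target_mb
}

#' Per-pathway recurrence across a cohort
#'
#' Counts, for each pathway, the samples carrying at least one alteration in
#' a member gene. A sample counts once per pathway however many member genes
#' are hit, and alterations of every class (SNV, indel, copy-number change,
#' retroviral insertion) count equally. Genes absent from the map are
#' tallied under `"unmapped"`.
#'
#' @param alterations data.frame with columns `sample_id`, `gene` (one row
#'   per alteration; an optional `class` column is ignored here).
#' @param pathway_map data.frame with columns `gene`, `pathway` (each gene
#'   in at most one pathway; see [read_pathway_map()]).
#' @param n_samples_total cohort size used as the denominator; defaults to
#'   the number of distinct `sample_id`s in `alterations`.
#' @return data.frame with `pathway`, `n_samples`, `fraction`.
#' @export
pathway_recurrence <- function(alterations, pathway_map,
                               n_samples_total = NULL) {
  stopifnot(all(c("sample_id", "gene") %in% names(alterations)))
  dup <- duplicated(pathway_map$gene)
  if (any(dup))
    stop_f1("gene(s) mapped to more than one pathway: ",
            paste(unique(pathway_map$gene[dup]), collapse = ", "),
            class = "f1loh_format_error")
  n_total <- n_samples_total %||% length(unique(alterations$sample_id))
  pathways <- unique(pathway_map$pathway)
  idx <- match(alterations$gene, pathway_map$gene)
  pw <- ifelse(is.na(idx), "unmapped", pathway_map$pathway[idx])
  if (any(is.na(idx))) pathways <- c(pathways, "unmapped")
  hits <- unique(data.frame(sample_id = alterations$sample_id, pathway = pw,
                            stringsAsFactors = FALSE))
  n <- vapply(pathways, function(p) sum(hits$pathway == p), integer(1))
  data.frame(pathway = pathways, n_samples = n,
             fraction = if (n_total > 0) n / n_total else rep(0, length(n)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Burden summaries for a cohort table
#'
#' @param counts data.frame with `sample_id` and `n_somatic`.
#' @param target_mb callable megabases (single value or per sample).
#' @return data.frame with `sample_id`, `n_somatic`, `target_mb`,
#'   `burden_per_mb`.
#' @export
burden_summary <- function(counts, target_mb) {
  stopifnot(all(c("sample_id", "n_somatic") %in% names(counts)))
  data.frame(sample_id = counts$sample_id, n_somatic = counts$n_somatic,
             target_mb = rep_len(target_mb, nrow(counts)),
             burden_per_mb = mutation_burden(counts$n_somatic, target_mb),
             stringsAsFactors = FALSE)
}
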