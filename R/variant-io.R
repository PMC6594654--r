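## Readers and writers for the formats the pipeline touches:
## VCF 4.2 (AD/DP) and TSV for SNP and somatic-variant counts, BED-like TSV
## for depth bins and classified segments, JSON for simulation truth, and
## YAML for run configuration.

SNP_COLUMNS <- c("chrom", "pos", "b6_allele", "s129_allele",
                 "normal_ref", "normal_alt", "tumor_ref", "tumor_alt")

validate_snp_table <- function(x) {
  missing <- setdiff(SNP_COLUMNS, names(x))
  if (length(missing))
    stop_f1("SNP table is missing column(s): ", paste(missing, collapse = ", "),
            class = "f1loh_format_error")
  for (col in c("normal_ref", "normal_alt", "tumor_ref", "tumor_alt"))
    check_counts(x[[col]], col, lines = seq_len(nrow(x)))
  same <- x$b6_allele == x$s129_allele
  if (any(same))
    stop_f1("strain alleles must differ; offending line(s): ",
            paste(utils::head(which(same), 5), collapse = ", "),
            class = "f1loh_format_error")
  x
}

#' Read strain-informative SNP tumor/normal allele counts
#'
#' Accepts either a VCF 4.2 with per-sample `AD` (ref,alt allelic depths) or
#' a TSV with the columns `chrom, pos, b6_allele, s129_allele, normal_ref,
#' normal_alt, tumor_ref, tumor_alt`. In the VCF the REF allele is taken as
#' the C57Bl/6 allele and the ALT allele as the 129Sv/Jae allele.
#' Multi-allelic VCF lines are skipped; the number skipped is returned in the
#' `"n_skipped"` attribute.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param normal_sample,tumor_sample VCF sample names.
#' @return validated SNP observation data.frame.
#' @export
read_snp_table <- function(path, format = c("auto", "vcf", "tsv"),
                           normal_sample = "NORMAL", tumor_sample = "TUMOR") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path))
    stop_f1("file not found: ", path, class = "f1loh_io_error")
  if (format == "tsv") {
    x <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character",
                                   b6_allele = "character",
                                   s129_allele = "character"))
    if (!nrow(x)) warning("no SNP records in ", path)
    attr(x, "n_skipped") <- 0L
    return(validate_snp_table(x))
  }
  read_snp_vcf(path, normal_sample, tumor_sample)
}

read_snp_vcf <- function(path, normal_sample, tumor_sample) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)  # stays a matrix at one row
  if (!nrow(fix)) {
    warning("no SNP records in ", path)
    out <- data.frame(chrom = character(), pos = integer(),
                      b6_allele = character(), s129_allele = character(),
                      normal_ref = integer(), normal_alt = integer(),
                      tumor_ref = integer(), tumor_alt = integer())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  samples <- colnames(v@gt)[-1]
  for (s in c(normal_sample, tumor_sample))
    if (!s %in% samples)
      stop_f1("sample '", s, "' not present in VCF (has: ",
              paste(samples, collapse = ", "), ")",
              class = "f1loh_config_error")
  fmt <- v@gt[, "FORMAT"]
  no_ad <- which(!vapply(strsplit(fmt, ":"), function(f) "AD" %in% f, logical(1)))
  if (length(no_ad))
    stop_f1("AD field missing from FORMAT at VCF record ", no_ad[1],
            class = "f1loh_format_error")
  ad <- vcfR::extract.gt(v, element = "AD")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  keep <- which(!multi)
  parse_ad <- function(s) {
    p <- strsplit(s, ",", fixed = TRUE)
    cbind(ref = as.integer(vapply(p, `[`, character(1), 1)),
          alt = as.integer(vapply(p, `[`, character(1), 2)))
  }
  nad <- parse_ad(ad[keep, normal_sample])
  tad <- parse_ad(ad[keep, tumor_sample])
  out <- data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                    b6_allele = fix$REF[keep], s129_allele = fix$ALT[keep],
                    normal_ref = nad[, "ref"], normal_alt = nad[, "alt"],
                    tumor_ref = tad[, "ref"], tumor_alt = tad[, "alt"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- validate_snp_table(out)
  attr(out, "n_skipped") <- sum(multi)
  out
}

#' Write SNP observations as a minimal VCF 4.2
#'
#' Emits one biallelic record per site with `GT:AD:DP` for the normal and
#' tumor samples; the B6 allele is written as REF and the S129 allele as ALT.
#'
#' @param snps SNP observation data.frame (see [read_snp_table()]).
#' @param path output file.
#' @param normal_sample,tumor_sample sample column names to write.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path, normal_sample = "NORMAL",
                          tumor_sample = "TUMOR") {
  snps <- validate_snp_table(snps)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=f1loh",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", normal_sample, tumor_sample, sep = "\t"))
  gt <- function(ref, alt) sprintf("0/1:%d,%d:%d", ref, alt, ref + alt)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t%s\t%s",
                  snps$chrom, snps$pos, snps$b6_allele, snps$s129_allele,
                  gt(snps$normal_ref, snps$normal_alt),
                  gt(snps$tumor_ref, snps$tumor_alt))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write an SNP observation table as TSV
#' @param snps SNP observation data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snp_tsv <- function(snps, path) {
  validate_snp_table(snps)
  write.table(snps[SNP_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

SEGMENT_COLUMNS <- c("chrom", "start", "end", "state", "n_sites",
                     "mean_folded_baf", "mean_logr")

#' Write classified segments as an annotated BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open), state, n_sites,
#' mean_folded_baf, mean_logr. Input must be sorted by (chrom, start);
#' values round-trip losslessly through [read_segments()].
#'
#' @param segments segment data.frame from [segment_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  missing <- setdiff(SEGMENT_COLUMNS, names(segments))
  if (length(missing))
    stop_f1("segment table is missing column(s): ",
            paste(missing, collapse = ", "), class = "f1loh_format_error")
  if (nrow(segments)) {
    o <- order(segments$chrom, segments$start)
    if (!identical(o, seq_len(nrow(segments))))
      stop_f1("segments must be sorted by (chrom, start)",
              class = "f1loh_order_error")
  }
  out <- segments[SEGMENT_COLUMNS]
  for (col in c("mean_folded_baf", "mean_logr"))
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segment file written by [write_segments()]
#' @param path input file.
#' @return segment data.frame.
#' @export
read_segments <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  missing <- setdiff(SEGMENT_COLUMNS, names(x))
  if (length(missing))
    stop_f1("segment file is missing column(s): ",
            paste(missing, collapse = ", "), class = "f1loh_format_error")
  x
}

#' Read a somatic variant count table (TSV)
#'
#' Expected columns: `variant_id, gene, chrom, pos, ref, alt, normal_alt,
#' normal_depth, primary_alt, primary_depth` and optionally `relapse_alt,
#' relapse_depth`. Variants whose normal alt fraction exceeds
#' `germline_bound` are flagged (column `germline_flag`), not dropped.
#'
#' @param path input file.
#' @param germline_bound maximum tolerated normal-sample alt fraction.
#' @return validated variant data.frame.
#' @export
read_variant_table <- function(path, germline_bound = 0.05) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  validate_variant_table(x, germline_bound)
}

validate_variant_table <- function(x, germline_bound = 0.05) {
  need <- c("variant_id", "gene", "chrom", "pos", "normal_alt", "normal_depth",
            "primary_alt", "primary_depth")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_f1("variant table is missing column(s): ",
            paste(missing, collapse = ", "), class = "f1loh_format_error")
  cols <- intersect(c("normal_alt", "normal_depth", "primary_alt",
                      "primary_depth", "relapse_alt", "relapse_depth"),
                    names(x))
  for (col in cols) check_counts(x[[col]], col, lines = seq_len(nrow(x)))
  for (s in c("normal", "primary", "relapse")) {
    a <- paste0(s, "_alt"); d <- paste0(s, "_depth")
    if (all(c(a, d) %in% names(x)) && any(x[[a]] > x[[d]]))
      stop_f1(a, " exceeds ", d, " at line(s): ",
              paste(utils::head(which(x[[a]] > x[[d]]), 5), collapse = ", "),
              class = "f1loh_format_error")
  }
  x$germline_flag <- x$normal_depth > 0 &
    x$normal_alt / pmax(x$normal_depth, 1) > germline_bound
  x
}

#' Write a somatic variant count table as TSV
#' @param variants variant data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binned tumor/normal depth of coverage
#'
#' BED-like TSV with header `chrom, start, end, normal_depth, tumor_depth`;
#' intervals are 0-based half-open.
#'
#' @param path input file.
#' @return depth-bin data.frame.
#' @export
read_depth_bins <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "normal_depth", "tumor_depth")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop_f1("depth-bin file is missing column(s): ",
            paste(missing, collapse = ", "), class = "f1loh_format_error")
  if (any(x$end <= x$start))
    stop_f1("depth bins must have end > start; offending line(s): ",
            paste(utils::head(which(x$end <= x$start), 5), collapse = ", "),
            class = "f1loh_format_error")
  if (any(x$normal_depth < 0 | x$tumor_depth < 0))
    stop_f1("depths must be non-negative", class = "f1loh_format_error")
  x
}

#' Write depth bins as BED-like TSV
#' @param bins depth-bin data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_bins <- function(bins, path) {
  write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation truth record as JSON
#' @param truth the `truth` element of an `f1loh_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a gene-to-pathway map (TSV with columns `gene`, `pathway`)
#' @param path input file.
#' @return data.frame mapping each gene to at most one pathway.
#' @export
read_pathway_map <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway") %in% names(x)))
    stop_f1("pathway map needs columns 'gene' and 'pathway'",
            class = "f1loh_format_error")
  dup <- duplicated(x$gene)
  if (any(dup))
    stop_f1("gene(s) mapped to more than one pathway: ",
            paste(unique(x$gene[dup]), collapse = ", "),
            class = "f1loh_format_error")
  x
}
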