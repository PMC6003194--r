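# Region-level allelic imbalance tables (allelic coverage + total RPKM),
# monoallelic-expression classification, and reference-bias /
# false-positive diagnostics.

#' Reads per kilobase per million aligned fragments
#'
#' @param n_fragments Fragment count over the region.
#' @param region_length_bp Region length in bp.
#' @param library_size_fragments Total aligned fragments in the library.
#' @return `n_fragments * 1e9 / (region_length_bp * library_size_fragments)`.
#' @export
rpkm <- function(n_fragments, region_length_bp, library_size_fragments) {
  if (any(region_length_bp <= 0)) stop("region length must be > 0")
  if (any(library_size_fragments <= 0)) stop("library size must be > 0")
  n_fragments * 1e9 / (region_length_bp * library_size_fragments)
}

#' Count classified fragments over regions
#'
#' A fragment counts toward a region when its projected reference interval
#' overlaps it by at least 1 bp; a fragment overlapping several regions
#' counts in each. Totals include non-allelic fragments.
#'
#' @param calls Call table from [classify_fragments()].
#' @param regions `data.frame(chrom, start, end[, name])`, 0-based
#'   half-open.
#' @return `regions` with added columns `total`, `hap1`, `hap2`.
#' @export
region_counts <- function(calls, regions) {
  regions <- as.data.frame(regions)
  if (!"name" %in% names(regions))
    regions$name <- sprintf("region_%d", seq_len(nrow(regions)))
  gr_reg <- intervals_to_granges(regions)
  count_set <- function(sub) {
    if (nrow(sub) == 0L) return(integer(nrow(regions)))
    gr <- GenomicRanges::GRanges(
      sub$chrom, IRanges::IRanges(sub$ref_start + 1L,
                                  pmax(sub$ref_end, sub$ref_start + 1L)))
    GenomicRanges::countOverlaps(gr_reg, gr)
  }
  aligned <- calls[!is.na(calls$ref_start), ]
  regions$total <- count_set(aligned[aligned$call %in%
                                       c("hap1", "hap2", "non_allelic"), ])
  regions$hap1 <- count_set(aligned[aligned$call == "hap1", ])
  regions$hap2 <- count_set(aligned[aligned$call == "hap2", ])
  regions
}

#' Classify regions as monoallelic, biallelic or insufficient
#'
#' Implements the monoallelic-expression rule: a region needs total
#' enrichment `RPKM > rpkm_min` and allelic depth
#' `hap1 + hap2 > min_allelic_reads`; given both, an allelic ratio
#' `hap1 / (hap1 + hap2)` strictly above `mono_frac` is `mono_hap1`,
#' strictly below `1 - mono_frac` is `mono_hap2`, anything else
#' `biallelic`. Thresholds are strict inequalities, so a ratio of exactly
#' `mono_frac` or exactly `min_allelic_reads` allelic reads is not
#' monoallelic.
#'
#' @param total_rpkm,hap1,hap2 Vectors of region RPKM and allelic counts.
#' @param rpkm_min Total-enrichment gate (default 1).
#' @param min_allelic_reads Allelic-depth gate (default 100).
#' @param mono_frac Expression-bias gate (default 0.9).
#' @return Factor with levels `mono_hap1`, `mono_hap2`, `biallelic`,
#'   `insufficient`.
#' @export
classify_expression <- function(total_rpkm, hap1, hap2, rpkm_min = 1,
                                min_allelic_reads = 100, mono_frac = 0.9) {
  allelic <- hap1 + hap2
  ratio <- ifelse(allelic > 0, hap1 / allelic, NA_real_)
  out <- ifelse(total_rpkm <= rpkm_min | allelic <= min_allelic_reads,
                "insufficient",
                ifelse(ratio > mono_frac, "mono_hap1",
                       ifelse(ratio < 1 - mono_frac, "mono_hap2", "biallelic")))
  factor(out, levels = c("mono_hap1", "mono_hap2", "biallelic", "insufficient"))
}

#' Build the per-region allelic imbalance table
#'
#' The tab-delimited table at the centre of allelic analyses: per region,
#' total fragment count and RPKM (to filter for enrichment), per-haplotype
#' allelic counts and ratio (to measure imbalance), and the expression
#' class.
#'
#' @inheritParams region_counts
#' @param library_size Total aligned fragments; defaults to the number of
#'   aligned fragments in `calls`.
#' @param ... Threshold arguments passed to [classify_expression()].
#' @return `data.frame` with columns `name, chrom, start, end, total,
#'   total_rpkm, hap1, hap2, allelic_ratio, expression_class`.
#' @export
region_summary <- function(calls, regions, library_size = NULL, ...) {
  library_size <- library_size %||% sum(calls$call != "unaligned")
  rc <- region_counts(calls, regions)
  rc$total_rpkm <- rpkm(rc$total, rc$end - rc$start, library_size)
  rc$allelic_ratio <- ifelse(rc$hap1 + rc$hap2 > 0,
                             rc$hap1 / (rc$hap1 + rc$hap2), NA_real_)
  rc$expression_class <- classify_expression(rc$total_rpkm, rc$hap1, rc$hap2, ...)
  rc[, c("name", "chrom", "start", "end", "total", "total_rpkm",
         "hap1", "hap2", "allelic_ratio", "expression_class")]
}

#' Write the imbalance table
#'
#' @param summary Output of [region_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reference-bias report from per-chromosome allelic counts
#'
#' For a cross where haplotype 1 is the reference haplotype, the bias on a
#' chromosome is `100 * (n_hap1 - n_hap2) / (n_hap1 + n_hap2)`; a positive
#' value means excess assignment to the reference. Both the pooled
#' (count-weighted) global bias and the unweighted mean of per-chromosome
#' biases are reported, with the pooled value as headline; sex chromosomes
#' and the mitochondrion are excluded by default.
#'
#' @param x Either a call table from [classify_fragments()] or a
#'   `data.frame(chrom, n_hap1, n_hap2)`.
#' @param exclude Chromosome names dropped from the global summaries.
#' @return List of class `bias_report`: `per_chrom` (with `bias_pct`,
#'   `NA` where a chromosome has no allelic reads), `global_bias_pct`
#'   (pooled), `global_bias_pct_mean` (unweighted across chromosomes) and
#'   `n_allelic`.
#' @export
reference_bias <- function(x, exclude = c("chrX", "chrY", "chrM",
                                          "X", "Y", "M", "MT")) {
  if (!is.null(x$call)) {
    dt <- data.table::as.data.table(x)[call %in% c("hap1", "hap2")]
    counts <- dt[, .(n_hap1 = sum(call == "hap1"),
                     n_hap2 = sum(call == "hap2")), by = chrom]
    counts <- as.data.frame(counts)
  } else {
    counts <- as.data.frame(x)
  }
  counts$bias_pct <- ifelse(counts$n_hap1 + counts$n_hap2 > 0,
                            100 * (counts$n_hap1 - counts$n_hap2) /
                              (counts$n_hap1 + counts$n_hap2), NA_real_)
  inc <- !(counts$chrom %in% exclude)
  h1 <- sum(counts$n_hap1[inc]); h2 <- sum(counts$n_hap2[inc])
  structure(list(
    per_chrom = counts,
    global_bias_pct = if (h1 + h2 > 0) 100 * (h1 - h2) / (h1 + h2) else NA_real_,
    global_bias_pct_mean = mean(counts$bias_pct[inc], na.rm = TRUE),
    n_allelic = h1 + h2
  ), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("reference bias: %.3f%% pooled (%.3f%% per-chromosome mean) over %d allelic fragments\n",
              x$global_bias_pct, x$global_bias_pct_mean, x$n_allelic))
  invisible(x)
}

#' False-positive rate of allelic calls on isogenic data
#'
#' For a dataset whose fragments all truly derive from one haplotype,
#' every call to the other haplotype is a false positive. Reported both as
#' a percentage of allelic calls and of all aligned fragments; when a
#' blacklist is supplied the rates are recomputed after
#' [apply_blacklist()].
#'
#' @param calls Call table from [classify_fragments()].
#' @param true_haplotype `"hap1"` or `"hap2"`.
#' @param blacklist Optional blacklist intervals (see
#'   [apply_blacklist()]).
#' @return List of class `fp_report`: `n_allelic`, `n_wrong`,
#'   `fp_pct_of_allelic` (`NA` when there are no allelic calls),
#'   `fp_pct_of_aligned`, `per_chrom`, and `after_blacklist` (an
#'   `fp_report` or `NULL`).
#' @export
false_positive_rate <- function(calls, true_haplotype, blacklist = NULL) {
  stopifnot(true_haplotype %in% c("hap1", "hap2"))
  wrong_hap <- setdiff(c("hap1", "hap2"), true_haplotype)
  one <- function(cl) {
    allelic <- cl$call %in% c("hap1", "hap2")
    aligned <- cl$call != "unaligned"
    n_allelic <- sum(allelic)
    n_wrong <- sum(cl$call == wrong_hap)
    dt <- data.table::as.data.table(cl)[call %in% c("hap1", "hap2")]
    per_chrom <- as.data.frame(dt[, .(
      n_allelic = .N, n_wrong = sum(call == wrong_hap),
      fp_pct = 100 * sum(call == wrong_hap) / .N), by = chrom])
    structure(list(
      n_allelic = n_allelic, n_wrong = n_wrong,
      fp_pct_of_allelic = if (n_allelic > 0) 100 * n_wrong / n_allelic else NA_real_,
      fp_pct_of_aligned = if (sum(aligned) > 0) 100 * n_wrong / sum(aligned) else NA_real_,
      per_chrom = per_chrom, after_blacklist = NULL
    ), class = "fp_report")
  }
  rep0 <- one(calls)
  if (!is.null(blacklist))
    rep0$after_blacklist <- one(apply_blacklist(calls, blacklist)$calls)
  rep0
}

#' @export
print.fp_report <- function(x, ...) {
  cat(sprintf("false positives: %d of %d allelic calls (%.2f%% of allelic, %.2f%% of aligned)\n",
              x$n_wrong, x$n_allelic, x$fp_pct_of_allelic, x$fp_pct_of_aligned))
  if (!is.null(x$after_blacklist))
    cat(sprintf("  after blacklist: %.2f%% of allelic\n",
                x$after_blacklist$fp_pct_of_allelic))
  invisible(x)
}
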