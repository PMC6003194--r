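# Reference-space span of a CIGAR string: sum of M/D/N/=/X operation
# lengths (I/S/H/P consume no reference bases).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1L) return(0L)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    op <- substring(toks, nchar(toks), nchar(toks))
    len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Consuming alignments produced by an external aligner against the
# diploid pseudogenome. Fragment uniqueness from external records uses a
# configurable cascade: the NH tag when present, otherwise absence of
# secondary/supplementary flags combined with a MAPQ threshold, because
# aligners report uniqueness differently.

#' Read a SAM/BAM file into a fragment placement table
#'
#' @param path SAM or BAM path (SAM is converted via
#'   [Rsamtools::asBam()]).
#' @return `data.table(read_id, contig, start, end, mapq, nh, secondary,
#'   is_read2, strand)` of mapped records.
#' @export
read_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM/BAM")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "flag", "mapq"),
    tag = "NH")
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(res$pos)
  flag <- res$flag[mapped]
  width <- cigar_ref_width(res$cigar[mapped])
  nh <- res$tag$NH
  data.table::data.table(
    read_id = res$qname[mapped],
    contig = as.character(res$rname[mapped]),
    start = res$pos[mapped],
    end = res$pos[mapped] + width - 1L,
    mapq = res$mapq[mapped],
    nh = if (is.null(nh)) NA_integer_ else nh[mapped],
    secondary = bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L,
    is_read2 = bitwAnd(flag, 128L) > 0L,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"))
}

#' Classify fragments from external SAM/BAM alignments
#'
#' Groups records by read name and calls each fragment haplotype-specific
#' when all its primary records agree on one contig and it is unique by
#' the NH-tag / flag / MAPQ cascade; fragments with records on both
#' haplotypes, NH > 1 or MAPQ below `mapq_min` are non-allelic.
#'
#' @param path SAM/BAM path, or a table from [read_sam()].
#' @param genome The `diploid_genome` aligned to.
#' @param mapq_min MAPQ threshold used when no NH tag is present.
#' @return Call table in the format of [classify_fragments()] (mate-level
#'   columns `NA`).
#' @export
classify_sam <- function(path, genome, mapq_min = 20L) {
  recs <- if (is.character(path)) read_sam(path) else
    data.table::as.data.table(path)
  contig_haplotype(unique(recs$contig), genome$hap_names)  # validate names
  prim <- recs[secondary == FALSE]
  grp <- prim[, {
    contigs <- unique(contig)
    nh_known <- !all(is.na(nh))
    unique_frag <- if (nh_known) all(nh == 1L, na.rm = TRUE) else
      all(mapq >= mapq_min)
    .(contig = contigs[1], n_contig = length(contigs),
      start = min(start), end = max(end),
      unique_frag = unique_frag, mm = NA_integer_)
  }, by = read_id]
  grp[, call := ifelse(n_contig == 1L & unique_frag,
                       NA_character_, "non_allelic")]
  need <- which(is.na(grp$call))
  if (length(need)) {
    ch <- contig_haplotype(grp$contig[need], genome$hap_names)
    grp$call[need] <- paste0("hap", ch$hap)
  }
  ch_all <- contig_haplotype(grp$contig, genome$hap_names)
  grp[, chrom := ch_all$chrom]
  grp[, c("ref_start", "ref_end") := {
    p <- project_intervals(start - 1L, end, genome$refmaps[[contig[1]]])
    list(as.integer(p$ref_start), as.integer(p$ref_end))
  }, by = contig]
  out <- grp[, .(read_id, call = factor(call, levels = CALL_LEVELS),
                 chrom, ref_start, ref_end, contig, start, end,
                 mm, n_best = n_contig, conv = NA_character_,
                 r1_start = NA_integer_, r1_end = NA_integer_, r1_fwd = NA,
                 r2_start = NA_integer_, r2_end = NA_integer_, r2_fwd = NA)]
  data.table::setorder(out, read_id)
  out[]
}
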