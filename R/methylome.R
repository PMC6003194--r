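# Per-CpG, per-allele methylation calling from bisulfite alignments on the
# diploid genome, and region-level allelic methylation summaries.
#
# Directional protocol strand rules: a read compared on the original-top
# (C->T) strand reports methylation at the CpG's C (read C = methylated,
# read T = unmethylated); a read compared on the original-bottom (G->A)
# strand reports it at the CpG's G (read G = methylated, read A =
# unmethylated). Any other base is ambiguous and excluded from counts.

#' Call CpG methylation states from one bisulfite alignment
#'
#' @param oriented_seq Read sequence oriented to the genome forward strand
#'   (reverse-complemented if the mate aligned to the minus strand),
#'   unconverted bases as sequenced.
#' @param start 1-based haplotype start of the alignment.
#' @param conv Strand comparison the alignment was made on: `"CT"`
#'   (original top) or `"GA"` (original bottom).
#' @param contig_seq Haplotype contig sequence.
#' @param cpg_pos Optional precomputed 1-based CpG C positions of
#'   `contig_seq` (from [cpg_positions()] semantics); computed if missing.
#' @param range Optional `c(lo, hi)` restricting the scan to haplotype
#'   positions within `[lo, hi]` (used to clip overlapping mates).
#' @return `data.frame(hap_pos, state)`: 1-based CpG C position and state
#'   in `meth` / `unmeth` / `ambiguous`.
#' @export
call_read_methylation <- function(oriented_seq, start, conv, contig_seq,
                                  cpg_pos = NULL, range = NULL) {
  if (!conv %in% c("CT", "GA"))
    stop("methylation can only be called from bisulfite alignments (CT/GA)")
  len <- nchar(oriented_seq)
  end <- start + len - 1L
  if (end > nchar(contig_seq)) stop("alignment extends past contig end")
  if (is.null(cpg_pos)) cpg_pos <- cpg_positions(contig_seq)
  lo <- if (is.null(range)) start else max(start, range[1])
  hi <- if (is.null(range)) end else min(end, range[2])
  if (conv == "CT") {
    sites <- cpg_pos[cpg_pos >= lo & cpg_pos <= hi]
    obs_pos <- sites
    meth_base <- "C"; unmeth_base <- "T"
  } else {
    sites <- cpg_pos[cpg_pos + 1L >= lo & cpg_pos + 1L <= hi]
    obs_pos <- sites + 1L
    meth_base <- "G"; unmeth_base <- "A"
  }
  if (!length(sites))
    return(data.frame(hap_pos = integer(), state = character()))
  base <- substring(oriented_seq, obs_pos - start + 1L, obs_pos - start + 1L)
  state <- ifelse(base == meth_base, "meth",
                  ifelse(base == unmeth_base, "unmeth", "ambiguous"))
  data.frame(hap_pos = sites, state = state)
}

#' Extract per-read CpG methylation calls from classified fragments
#'
#' Runs [call_read_methylation()] over both mates of every aligned
#' fragment (allelic and non-allelic). When mates overlap, mate 2 is
#' clipped to the portion of the fragment not covered by mate 1, so one
#' fragment contributes at most one observation per CpG.
#'
#' @param calls Call table from [classify_fragments()] of bisulfite
#'   alignments.
#' @param reads The read table the calls were derived from (`read_id`,
#'   `seq1`, `seq2`).
#' @param genome The `diploid_genome` aligned to.
#' @return `data.table(read_id, call, contig, hap_pos, state)` with one
#'   row per (fragment, CpG) observation.
#' @export
extract_methylation <- function(calls, reads, genome) {
  reads <- as.data.frame(reads)
  seq1 <- stats::setNames(as.character(reads$seq1), reads$read_id)
  seq2 <- if ("seq2" %in% names(reads))
    stats::setNames(as.character(reads$seq2), reads$read_id) else NULL
  cpg_by_contig <- lapply(genome$contigs, cpg_positions)
  keep <- !is.na(calls$contig) & calls$conv %in% c("CT", "GA")
  al <- as.data.frame(calls)[keep, ]
  n <- nrow(al)
  # orient both mates to the genome forward strand, vectorised
  o1 <- seq1[al$read_id]
  o1[!al$r1_fwd] <- revcomp(o1[!al$r1_fwd])
  o2 <- NULL
  if (!is.null(seq2)) {
    o2 <- seq2[al$read_id]
    flip <- !is.na(al$r2_fwd) & !al$r2_fwd
    o2[flip] <- revcomp(o2[flip])
  }
  conv_v <- al$conv
  cpos <- vector("list", 3L * n); cstate <- vector("list", 3L * n)
  crow <- vector("list", 3L * n)
  slot <- 0L
  scan_mate <- function(i, oseq, s, e, lo, hi) {
    slot <<- slot + 1L
    cpg <- cpg_by_contig[[al$contig[i]]]
    if (conv_v[i] == "CT") {
      j <- (findInterval(lo - 1L, cpg) + 1L):findInterval(hi, cpg)
      if (!length(j) || j[1] > j[length(j)]) return()
      sites <- cpg[j]; obs <- sites
      mb <- "C"; ub <- "T"
    } else {
      j <- (findInterval(lo - 2L, cpg) + 1L):findInterval(hi - 1L, cpg)
      if (!length(j) || j[1] > j[length(j)]) return()
      sites <- cpg[j]; obs <- sites + 1L
      mb <- "G"; ub <- "A"
    }
    base <- substring(oseq, obs - s + 1L, obs - s + 1L)
    cpos[[slot]] <<- sites
    cstate[[slot]] <<- ifelse(base == mb, "meth",
                              ifelse(base == ub, "unmeth", "ambiguous"))
    crow[[slot]] <<- rep.int(i, length(sites))
  }
  for (i in seq_len(n)) {
    scan_mate(i, o1[i], al$r1_start[i], al$r1_end[i],
              al$r1_start[i], al$r1_end[i])
    if (!is.null(o2) && !is.na(al$r2_start[i])) {
      # clip mate 2 to hap positions not covered by mate 1
      ranges <- clip_range(al$r2_start[i], al$r2_end[i],
                           al$r1_start[i], al$r1_end[i])
      for (rg in ranges)
        scan_mate(i, o2[i], al$r2_start[i], al$r2_end[i], rg[1], rg[2])
    }
  }
  rows <- unlist(crow, use.names = FALSE)
  if (is.null(rows) || !length(rows))
    return(data.table::data.table(read_id = character(), call = character(),
                                  contig = character(), hap_pos = integer(),
                                  state = character()))
  res <- data.table::data.table(
    read_id = al$read_id[rows], call = as.character(al$call)[rows],
    contig = al$contig[rows],
    hap_pos = unlist(cpos, use.names = FALSE),
    state = unlist(cstate, use.names = FALSE))
  res[]
}

# Portions of [s2, e2] not covered by [s1, e1]; a list of c(lo, hi) pairs.
clip_range <- function(s2, e2, s1, e1) {
  if (e2 < s1 || s2 > e1) return(list(c(s2, e2)))
  out <- list()
  if (s2 < s1) out[[length(out) + 1L]] <- c(s2, s1 - 1L)
  if (e2 > e1) out[[length(out) + 1L]] <- c(e1 + 1L, e2)
  out
}

#' Aggregate per-read methylation calls into a per-CpG allelic table
#'
#' CpG haplotype positions are projected to reference coordinates through
#' the refmap of the contig the read aligned to; CpGs lying inside
#' haplotype-specific insertions have no reference coordinate and are
#' dropped. Counts accumulate per (reference position, allele) for
#' haplotype calls, and the `total` allele additionally accumulates every
#' observation regardless of allelic call (non-allelic fragments
#' contribute through their representative placement). A CpG destroyed by
#' a variant on one haplotype simply never receives calls for that
#' haplotype, because CpG sites are located on each haplotype sequence.
#'
#' @param meth_calls Output of [extract_methylation()].
#' @param refmaps Named list of `refmap`s keyed by contig (e.g.
#'   `genome$refmaps`).
#' @return `data.table(chrom, ref_pos, allele, n_meth, n_unmeth, level)`;
#'   `ref_pos` is the 0-based reference position of the CpG C and `level`
#'   the percent methylation.
#' @export
aggregate_cpg_counts <- function(meth_calls, refmaps) {
  mc <- data.table::as.data.table(meth_calls)[state != "ambiguous"]
  if (nrow(mc) == 0L)
    return(data.table::data.table(chrom = character(), ref_pos = integer(),
                                  allele = character(), n_meth = integer(),
                                  n_unmeth = integer(), level = numeric()))
  mc[, c("chrom", "ref_pos", "ok") := {
    r <- refmaps[[contig[1]]]
    p <- project_position(hap_pos - 1L, r)
    list(r$chrom, p$ref_pos, p$status == "exact")
  }, by = contig]
  mc <- mc[ok == TRUE]
  allelic <- mc[call %in% c("hap1", "hap2"),
                .(n_meth = sum(state == "meth"),
                  n_unmeth = sum(state == "unmeth")),
                by = .(chrom, ref_pos, allele = call)]
  total <- mc[, .(n_meth = sum(state == "meth"),
                  n_unmeth = sum(state == "unmeth")),
              by = .(chrom, ref_pos)][, allele := "total"]
  tab <- rbind(allelic, total[, .(chrom, ref_pos, allele, n_meth, n_unmeth)])
  tab[, level := 100 * n_meth / (n_meth + n_unmeth)]
  data.table::setorder(tab, chrom, ref_pos, allele)
  tab[]
}

#' Filter a CpG table to informative sites
#'
#' Keeps (site, allele) rows with coverage of at least `min_cov` reads,
#' the empirical definition of an informative CpG.
#'
#' @param table Output of [aggregate_cpg_counts()].
#' @param min_cov Minimum `n_meth + n_unmeth`.
#' @return Filtered table with attribute `n_informative`, the per-allele
#'   row counts.
#' @export
informative_cpgs <- function(table, min_cov = 5L) {
  if (min_cov < 1L) stop("min_cov must be >= 1")
  tab <- data.table::as.data.table(table)
  keep <- tab[n_meth + n_unmeth >= min_cov]
  data.table::setattr(keep, "n_informative",
                      table(factor(keep$allele,
                                   levels = c("hap1", "hap2", "total"))))
  keep[]
}

#' Summarise allelic methylation over regions
#'
#' For each region and each allele, reports the number of informative CpGs
#' (coverage >= `min_cov`) and the unweighted mean of their per-CpG
#' methylation percentages; regions with no informative CpG report `NA`.
#' The unweighted mean across CpGs is used because summaries are paired
#' with CpG counts rather than read totals.
#'
#' @param table Output of [aggregate_cpg_counts()].
#' @param regions `data.frame(chrom, start, end[, name])`, 0-based
#'   half-open.
#' @param min_cov Minimum per-CpG coverage for a site to count.
#' @return One row per region: region columns plus, for each of
#'   `hap1`/`hap2`/`total`, `<allele>_n_cpg` and `<allele>_mean_meth_pct`.
#' @export
region_methylation <- function(table, regions, min_cov = 5L) {
  tab <- informative_cpgs(table, min_cov)
  regions <- as.data.frame(regions)
  if (!"name" %in% names(regions))
    regions$name <- sprintf("region_%d", seq_len(nrow(regions)))
  known <- unique(tab$chrom)
  res <- regions
  for (al in c("hap1", "hap2", "total")) {
    res[[paste0(al, "_n_cpg")]] <- 0L
    res[[paste0(al, "_mean_meth_pct")]] <- NA_real_
  }
  for (i in seq_len(nrow(regions))) {
    if (!regions$chrom[i] %in% known && nrow(tab)) {
      warning("region ", regions$name[i], " on unknown chromosome ",
              regions$chrom[i])
      next
    }
    inside <- tab[chrom == regions$chrom[i] & ref_pos >= regions$start[i] &
                    ref_pos < regions$end[i]]
    for (al in c("hap1", "hap2", "total")) {
      sub <- inside[allele == al]
      res[[paste0(al, "_n_cpg")]][i] <- nrow(sub)
      if (nrow(sub))
        res[[paste0(al, "_mean_meth_pct")]][i] <- mean(sub$level)
    }
  }
  res
}

#' Write per-CpG methylation tables as bedGraph-compatible files
#'
#' One file per allele: columns chrom, start, end, level, n_meth,
#' n_unmeth (0-based half-open; the interval covers the CpG C).
#'
#' @param table Output of [aggregate_cpg_counts()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_cpg_table <- function(table, dir, prefix = "cpg") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.table::as.data.table(table)
  paths <- character()
  for (al in unique(tab$allele)) {
    sub <- tab[allele == al,
               .(chrom, start = ref_pos, end = ref_pos + 1L,
                 level, n_meth, n_unmeth)]
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, al))
    data.table::fwrite(sub, p, sep = "\t")
    paths[al] <- p
  }
  invisible(paths)
}
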