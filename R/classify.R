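# Fragment-level allelic classification: a fragment with exactly one best
# alignment location on the diploid genome is allele-specific (both mates
# inherit the call -- mate rescue); two or more equally good locations mean
# the fragment is non-allelic; no location means unaligned.

CALL_LEVELS <- c("hap1", "hap2", "non_allelic", "unaligned")

#' Classify fragments by alignment uniqueness on the diploid genome
#'
#' Works at fragment (not read) level: the pair is treated as a unit, so a
#' mate that does not itself overlap a variant is still called allelic when
#' its pair aligns uniquely. Ties in mismatch count across haplotypes at
#' the same locus produce two best locations and are therefore non-allelic.
#' Allelic and non-allelic calls carry the projected reference interval of
#' the fragment; for non-allelic fragments the lexicographically first best
#' location is used as the representative placement (for allele-agnostic
#' "total" signal).
#'
#' @param placements Fragment placements from [align_fragments()].
#' @param genome The `diploid_genome` the fragments were aligned to (or a
#'   list with elements `refmaps` and `hap_names`).
#' @param read_ids Universe of fragment ids; defaults to the attribute
#'   recorded by the aligner. Fragments absent from `placements` are
#'   reported as `unaligned`.
#' @return A `data.table` of allelic calls, one row per fragment:
#'   `read_id`, `call` (factor hap1/hap2/non_allelic/unaligned), `chrom`,
#'   `ref_start`, `ref_end` (0-based half-open projected interval),
#'   `contig`, `start`, `end`, `mm`, `n_best`, `conv` and per-mate
#'   placement columns.
#' @export
classify_fragments <- function(placements, genome, read_ids = NULL) {
  read_ids <- read_ids %||% attr(placements, "read_ids") %||%
    unique(placements$read_id)
  hap_names <- genome$hap_names
  refmaps <- genome$refmaps
  pl <- data.table::as.data.table(placements)
  if (nrow(pl)) {
    best <- pl[pl[, .I[mm == min(mm)], by = read_id]$V1]
    data.table::setorder(best, read_id, contig, start)
    best[, n_best := .N, by = read_id]
    top <- best[, .SD[1L], by = read_id]
    ch <- contig_haplotype(top$contig, hap_names)
    top[, `:=`(
      call = ifelse(n_best == 1L, paste0("hap", ch$hap), "non_allelic"),
      chrom = ch$chrom)]
    top[, c("ref_start", "ref_end") := {
      p <- project_intervals(start - 1L, end, refmaps[[contig[1]]])
      list(as.integer(p$ref_start), as.integer(p$ref_end))
    }, by = contig]
  } else {
    top <- data.table::data.table()
  }
  missing <- setdiff(read_ids, if (nrow(pl)) top$read_id else character())
  un <- data.table::data.table(
    read_id = missing, call = "unaligned", chrom = NA_character_,
    ref_start = NA_integer_, ref_end = NA_integer_, contig = NA_character_,
    start = NA_integer_, end = NA_integer_, mm = NA_integer_,
    n_best = 0L, conv = NA_character_,
    r1_start = NA_integer_, r1_end = NA_integer_, r1_fwd = NA,
    r2_start = NA_integer_, r2_end = NA_integer_, r2_fwd = NA)
  cols <- names(un)
  calls <- if (nrow(pl)) rbind(top[, ..cols], un) else un
  calls[, call := factor(call, levels = CALL_LEVELS)]
  data.table::setorder(calls, read_id)
  calls[]
}

#' Classify a single fragment alignment group
#'
#' @param group Placements of one fragment (all alignments of both mates).
#' @inheritParams classify_fragments
#' @return One-row call table (see [classify_fragments()]).
#' @export
classify_fragment <- function(group, genome) {
  classify_fragments(group, genome,
                     read_ids = unique(c(group$read_id,
                                         attr(group, "read_ids"))))
}

#' Remove allelic calls overlapping a blacklist
#'
#' Allelic calls whose projected reference interval overlaps any blacklist
#' interval by >= 1 bp are removed (satellite-repeat exclusion);
#' non-allelic and unaligned calls pass through untouched.
#'
#' @param calls Call table from [classify_fragments()].
#' @param blacklist `data.frame(chrom, start, end)` (0-based half-open) or
#'   a `GRanges`.
#' @return A list: `calls` (kept rows) and `n_removed`.
#' @export
apply_blacklist <- function(calls, blacklist) {
  if (is.null(blacklist) ||
      (is.data.frame(blacklist) && nrow(blacklist) == 0L))
    return(list(calls = calls, n_removed = 0L))
  gr_bl <- if (methods::is(blacklist, "GRanges")) blacklist
           else intervals_to_granges(blacklist)
  allelic <- calls$call %in% c("hap1", "hap2")
  idx <- which(allelic)
  if (!length(idx)) return(list(calls = calls, n_removed = 0L))
  gr <- GenomicRanges::GRanges(
    calls$chrom[idx],
    IRanges::IRanges(calls$ref_start[idx] + 1L,
                     pmax(calls$ref_end[idx], calls$ref_start[idx] + 1L)))
  hit <- IRanges::overlapsAny(gr, gr_bl)
  drop <- idx[hit]
  list(calls = calls[setdiff(seq_len(nrow(calls)), drop), ],
       n_removed = length(drop))
}

# Build a raw coverage track (chrom, start, end, value; 0-based half-open)
# from the projected reference intervals of a set of calls.
calls_to_track <- function(calls) {
  ok <- !is.na(calls$ref_start) & calls$ref_end > calls$ref_start
  calls <- calls[ok, ]
  if (nrow(calls) == 0L) {
    tr <- data.frame(chrom = character(), start = integer(),
                     end = integer(), value = numeric())
  } else {
    gr <- GenomicRanges::GRanges(
      calls$chrom, IRanges::IRanges(calls$ref_start + 1L, calls$ref_end))
    cov <- GenomicRanges::coverage(gr)
    parts <- lapply(names(cov), function(ch) {
      r <- cov[[ch]]
      df <- data.frame(chrom = ch,
                       start = cumsum(c(0L, S4Vectors::runLength(r)))[
                         seq_along(S4Vectors::runLength(r))],
                       end = cumsum(S4Vectors::runLength(r)),
                       value = as.numeric(S4Vectors::runValue(r)))
      df[df$value > 0, , drop = FALSE]
    })
    tr <- do.call(rbind, parts)
    rownames(tr) <- NULL
  }
  attr(tr, "normalization") <- "raw"
  class(tr) <- c("coverage_track", "data.frame")
  tr
}

#' Partition classified fragments into allelic and total coverage streams
#'
#' @param calls Call table from [classify_fragments()].
#' @return A list with coverage tracks `hap1`, `hap2`, `total` (total =
#'   all aligned fragments, allelic plus non-allelic, in reference
#'   coordinates) and `counts`, the per-call fragment tally.
#' @export
partition_alignments <- function(calls) {
  counts <- table(calls$call)
  list(
    hap1 = calls_to_track(calls[calls$call == "hap1", ]),
    hap2 = calls_to_track(calls[calls$call == "hap2", ]),
    total = calls_to_track(calls[calls$call %in%
                                   c("hap1", "hap2", "non_allelic"), ]),
    counts = counts
  )
}
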