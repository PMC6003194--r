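# Built-in brute-force-equivalent aligner for toy-scale diploid genomes.
#
# Placement search is seed-and-extend: every pattern is split into
# max_mismatch + 1 non-overlapping k-mers, so by pigeonhole at least one
# seed is error-free in any placement with <= max_mismatch mismatches; seed
# hits against a k-mer index of the diploid genome are then verified by
# exact Hamming comparison. The search is therefore guaranteed to
# enumerate ALL gapless placements within the mismatch budget, which is
# what fragment classification by alignment uniqueness requires. Bisulfite
# mode compares three-letter-collapsed sequences (C->T for the original-top
# strand, G->A for the original-bottom strand; directional protocol).

MAX_TOY_GENOME <- 5e6

#' Build a k-mer index of a diploid genome
#'
#' @param genome A `diploid_genome` or named character vector of contigs.
#' @param k Seed length.
#' @param bisulfite Index the three-letter-collapsed genome (both strand
#'   comparisons) instead of the raw sequence.
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(genome, k = 16L, bisulfite = FALSE) {
  contigs <- if (inherits(genome, "diploid_genome")) genome$contigs else genome
  contigs <- toupper(contigs)
  if (sum(nchar(contigs)) > MAX_TOY_GENOME)
    stop("genome larger than ", MAX_TOY_GENOME, " bp: the built-in aligner is ",
         "for toy-scale tests; align with a production aligner and import SAM")
  convs <- if (bisulfite) c("CT", "GA") else "N"
  conv_seqs <- lapply(convs, function(cv)
    vapply(contigs, bs_collapse, character(1), mode = cv))
  names(conv_seqs) <- convs
  tabs <- list()
  for (cv in convs) {
    for (ct in names(contigs)) {
      s <- conv_seqs[[cv]][[ct]]
      n <- nchar(s)
      if (n < k) next
      starts <- seq_len(n - k + 1L)
      tabs[[length(tabs) + 1L]] <- data.table::data.table(
        conv = cv, kmer = substring(s, starts, starts + k - 1L),
        contig = ct, pos = starts)
    }
  }
  tab <- data.table::rbindlist(tabs)
  data.table::setkey(tab, conv, kmer)
  structure(list(k = as.integer(k), bisulfite = bisulfite, table = tab,
                 conv_seqs = conv_seqs,
                 contig_len = nchar(contigs)),
            class = "genome_index")
}

# Enumerate all placements of a set of oriented, collapsed patterns.
# patterns: data.table(pid, conv, pattern). Returns data.table(pid, contig,
# start, mm) with one row per placement with mm <= max_mismatch.
seed_align <- function(patterns, index, max_mismatch) {
  k <- index$k
  plen <- nchar(patterns$pattern)
  n_seed <- max_mismatch + 1L
  if (any(plen < n_seed * k))
    stop("reads too short for ", max_mismatch, " mismatches at seed length ",
         k, "; lower k")
  seeds <- data.table::rbindlist(lapply(seq_len(n_seed), function(j) {
    off <- (j - 1L) * k + 1L
    data.table::data.table(
      pid = patterns$pid, conv = patterns$conv,
      kmer = substring(patterns$pattern, off, off + k - 1L), off = off)
  }))
  hits <- index$table[seeds, on = c("conv", "kmer"), nomatch = NULL,
                      allow.cartesian = TRUE]
  if (nrow(hits) == 0L)
    return(data.table::data.table(pid = integer(), contig = character(),
                                  start = integer(), mm = integer()))
  hits[, start := pos - off + 1L]
  cand <- unique(hits[, .(pid, conv, contig, start)])
  cand[, plen := plen[pid]]
  cand <- cand[start >= 1L & start + plen - 1L <= index$contig_len[contig]]
  if (nrow(cand) == 0L)
    return(data.table::data.table(pid = integer(), contig = character(),
                                  start = integer(), mm = integer()))
  # verify by Hamming distance against the collapsed genome
  cand[, txt := substring(index$conv_seqs[[conv[1]]][[contig[1]]],
                          start, start + plen - 1L),
       by = .(conv, contig)]
  cand[, pat := patterns$pattern[pid]]
  cand[, mm := str_mismatches(pat, txt)]
  cand <- cand[mm <= max_mismatch, .(pid, contig, start, mm)]
  cand
}

# Oriented pattern rows for one mate. For genomic reads each mate is tried
# forward and reverse-complemented. For directional bisulfite libraries
# mate 1 is either an original-top read (forward, C->T comparison) or an
# original-bottom read (reverse, G->A comparison); mate 2 the converse.
mate_patterns <- function(seqs, mate, bisulfite) {
  fwd <- toupper(seqs)
  rev <- revcomp(fwd)
  if (!bisulfite) {
    list(data.table::data.table(orient = "+", conv = "N", pattern = fwd),
         data.table::data.table(orient = "-", conv = "N", pattern = rev))
  } else if (mate == 1L) {
    list(data.table::data.table(orient = "+", conv = "CT",
                                pattern = bs_collapse(fwd, "CT")),
         data.table::data.table(orient = "-", conv = "GA",
                                pattern = bs_collapse(rev, "GA")))
  } else {
    list(data.table::data.table(orient = "-", conv = "CT",
                                pattern = bs_collapse(rev, "CT")),
         data.table::data.table(orient = "+", conv = "GA",
                                pattern = bs_collapse(fwd, "GA")))
  }
}

#' Align sequencing fragments to a toy diploid genome
#'
#' Enumerates all gapless placements of each fragment (both mates, both
#' strands) with at most `max_mismatch` mismatches per mate, pairs mates in
#' FR orientation within `max_insert`, and returns every minimal-structure
#' placement. Single-end input (`seq2` absent or `NA`) is supported.
#'
#' @param reads `data.frame` with columns `read_id`, `seq1` and optionally
#'   `seq2`.
#' @param genome A `diploid_genome`, named contig vector, or a prebuilt
#'   [genome_index()].
#' @param max_mismatch Maximum mismatches tolerated per mate.
#' @param bisulfite Use three-letter matching for bisulfite-converted
#'   reads (directional protocol).
#' @param max_insert Maximum fragment span for a valid pair.
#' @param k Seed length for the index (ignored when `genome` is already an
#'   index).
#' @return A `data.table` of fragment placements: `read_id`, `contig`,
#'   `start`, `end` (1-based inclusive), `mm` (summed mate mismatches),
#'   `conv`, and per-mate coordinates `r1_start`, `r1_end`, `r1_fwd`,
#'   `r2_start`, `r2_end`, `r2_fwd`. Attribute `read_ids` holds the full
#'   input universe (fragments with no placement are absent from the
#'   table but present there).
#' @export
align_fragments <- function(reads, genome, max_mismatch = 2L,
                            bisulfite = FALSE, max_insert = 1200L, k = 16L) {
  reads <- as.data.frame(reads)
  paired <- "seq2" %in% names(reads) && !all(is.na(reads$seq2))
  min_len <- min(nchar(reads$seq1), if (paired) nchar(reads$seq2) else Inf)
  k <- min(k, as.integer(min_len %/% (max_mismatch + 1L)))
  if (k < 8L)
    stop("reads too short to seed the toy aligner (need length >= ",
         8L * (max_mismatch + 1L), ")")
  index <- if (inherits(genome, "genome_index")) genome
           else genome_index(genome, k = k, bisulfite = bisulfite)
  if (index$bisulfite != bisulfite)
    stop("index was built with bisulfite=", index$bisulfite)

  place_mate <- function(seqs, mate) {
    pats <- mate_patterns(seqs, mate, bisulfite)
    out <- lapply(pats, function(p) {
      p[, pid := .I]
      pl <- seed_align(p[, .(pid, conv, pattern)], index, max_mismatch)
      if (nrow(pl) == 0L) return(NULL)
      pl[, `:=`(read_id = reads$read_id[pid],
                orient = p$orient[1], conv = p$conv[1],
                len = nchar(seqs[pid]))]
      pl[, .(read_id, contig, start, end = start + len - 1L, orient, conv, mm)]
    })
    data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  }

  m1 <- place_mate(reads$seq1, 1L)
  if (!paired) {
    if (nrow(m1)) {
      frag <- m1[, .(read_id, contig, start, end, mm, conv,
                     r1_start = start, r1_end = end, r1_fwd = orient == "+",
                     r2_start = NA_integer_, r2_end = NA_integer_,
                     r2_fwd = NA)]
      frag <- frag[frag[, .I[which.min(mm)], by = .(read_id, contig, start, end)]$V1]
    } else frag <- empty_placements()
  } else {
    m2 <- place_mate(reads$seq2, 2L)
    if (nrow(m1) == 0L || nrow(m2) == 0L) {
      frag <- empty_placements()
    } else {
      data.table::setnames(m2, c("start", "end", "orient", "conv", "mm"),
                           c("start2", "end2", "orient2", "conv2", "mm2"))
      pairs <- m1[m2, on = c("read_id", "contig"), nomatch = NULL,
                  allow.cartesian = TRUE]
      pairs <- pairs[orient != orient2 & conv == conv2]
      pairs[, `:=`(frag_start = pmin(start, start2),
                   frag_end = pmax(end, end2))]
      pairs <- pairs[frag_end - frag_start + 1L <= max_insert]
      # FR orientation: the forward-strand mate is leftmost
      pairs <- pairs[(orient == "+" & start <= start2) |
                     (orient2 == "+" & start2 <= start)]
      if (nrow(pairs) == 0L) {
        frag <- empty_placements()
      } else {
        pairs[, mm_tot := mm + mm2]
        frag <- pairs[, .(read_id, contig, start = frag_start, end = frag_end,
                          mm = mm_tot, conv,
                          r1_start = start, r1_end = end, r1_fwd = orient == "+",
                          r2_start = start2, r2_end = end2,
                          r2_fwd = orient2 == "+")]
        # one row per distinct fragment location, keeping the best score
        frag <- frag[frag[, .I[which.min(mm)],
                          by = .(read_id, contig, start, end)]$V1]
      }
    }
  }
  data.table::setattr(frag, "read_ids", reads$read_id)
  data.table::setattr(frag, "bisulfite", bisulfite)
  frag[]
}

empty_placements <- function() {
  data.table::data.table(
    read_id = character(), contig = character(), start = integer(),
    end = integer(), mm = integer(), conv = character(),
    r1_start = integer(), r1_end = integer(), r1_fwd = logical(),
    r2_start = integer(), r2_end = integer(), r2_fwd = logical())
}

#' Align a single read pair (brute-force semantics)
#'
#' Convenience wrapper around [align_fragments()] for one fragment;
#' returns all minimal-mismatch placements of the pair on the diploid
#' genome.
#'
#' @param seq1,seq2 Mate sequences (`seq2 = NULL` for single-end).
#' @param genome Diploid genome or prebuilt index.
#' @inheritParams align_fragments
#' @return `data.table` of placements (see [align_fragments()]).
#' @export
brute_force_align <- function(seq1, seq2 = NULL, genome, max_mismatch = 2L,
                              bisulfite = FALSE, max_insert = 1200L) {
  reads <- data.frame(read_id = "fragment", seq1 = seq1,
                      seq2 = if (is.null(seq2)) NA_character_ else seq2)
  align_fragments(reads, genome, max_mismatch = max_mismatch,
                  bisulfite = bisulfite, max_insert = max_insert)
}
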