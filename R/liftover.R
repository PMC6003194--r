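# Projection of haplotype-coordinate positions, intervals and coverage
# tracks back onto reference coordinates via the refmap block index.

#' Project haplotype positions onto the reference
#'
#' Positions inside a refmap block project exactly; positions in a
#' haplotype-axis gap (inside an insertion) report the reference
#' coordinate of the anchor base immediately left of the insertion, the
#' same anchoring convention VCF uses for INDEL records, so projected
#' reads stay collinear with the variant that created the insertion.
#'
#' @param hap_pos Integer vector of 0-based haplotype coordinates.
#' @param r A `refmap`.
#' @return A `data.frame` with columns `hap_pos`, `ref_pos` (0-based) and
#'   `status` (`"exact"` or `"inside_insertion"`).
#' @export
project_position <- function(hap_pos, r) {
  hap_pos <- as.integer(hap_pos)
  if (any(hap_pos < 0L | hap_pos >= r$hap_length))
    stop("hap_pos out of range [0, ", r$hap_length, ")")
  b <- r$blocks
  i <- findInterval(hap_pos, b$hap_start)
  ref_pos <- integer(length(hap_pos))
  status <- character(length(hap_pos))
  lead <- i == 0L                       # before the first block: leading insertion
  if (any(lead)) {
    ref_pos[lead] <- b$ref_start[1] - 1L
    status[lead] <- "inside_insertion"
  }
  inb <- !lead
  if (any(inb)) {
    bi <- i[inb]
    within <- hap_pos[inb] < b$hap_start[bi] + b$length[bi]
    idx <- which(inb)
    exact <- idx[within]
    ins <- idx[!within]
    ref_pos[exact] <- b$ref_start[i[exact]] + (hap_pos[exact] - b$hap_start[i[exact]])
    status[exact] <- "exact"
    ref_pos[ins] <- b$ref_start[i[ins]] + b$length[i[ins]] - 1L
    status[ins] <- "inside_insertion"
  }
  data.frame(hap_pos = hap_pos, ref_pos = ref_pos, status = status)
}

#' Project reference positions onto a haplotype
#'
#' Inverse lookup: reference positions covered by a block project exactly;
#' positions inside a deletion (a reference-axis gap) report the haplotype
#' coordinate of the last base of the preceding block with status
#' `"deleted"`.
#'
#' @param ref_pos Integer vector of 0-based reference coordinates.
#' @param r A `refmap`.
#' @return A `data.frame` with columns `ref_pos`, `hap_pos`, `status`.
#' @export
project_ref_position <- function(ref_pos, r) {
  ref_pos <- as.integer(ref_pos)
  b <- r$blocks
  ref_len <- b$ref_start[nrow(b)] + b$length[nrow(b)]
  if (any(ref_pos < 0L | ref_pos >= ref_len))
    stop("ref_pos out of range [0, ", ref_len, ")")
  i <- findInterval(ref_pos, b$ref_start)
  hap_pos <- integer(length(ref_pos))
  status <- character(length(ref_pos))
  lead <- i == 0L
  if (any(lead)) {
    hap_pos[lead] <- b$hap_start[1] - 1L
    status[lead] <- "deleted"
  }
  idx <- which(!lead)
  if (length(idx)) {
    bi <- i[idx]
    within <- ref_pos[idx] < b$ref_start[bi] + b$length[bi]
    exact <- idx[within]; del <- idx[!within]
    hap_pos[exact] <- b$hap_start[i[exact]] + (ref_pos[exact] - b$ref_start[i[exact]])
    status[exact] <- "exact"
    hap_pos[del] <- b$hap_start[i[del]] + b$length[i[del]] - 1L
    status[del] <- "deleted"
  }
  data.frame(ref_pos = ref_pos, hap_pos = hap_pos, status = status)
}

#' Project a haplotype interval onto the reference
#'
#' Returns the half-open reference interval spanned by the exact-status
#' bases of `[hap_start, hap_end)`. An interval lying entirely inside one
#' insertion returns the zero-length interval at anchor + 1. An interval
#' spanning a deletion spans it in reference space, so the projected
#' interval can be longer than the input; this stretching keeps projected
#' fragments collinear with a gapped alignment.
#'
#' @param hap_start,hap_end 0-based half-open haplotype interval.
#' @param r A `refmap`.
#' @return Integer vector `c(ref_start, ref_end)` (0-based half-open).
#' @export
project_interval <- function(hap_start, hap_end, r) {
  res <- project_intervals(hap_start, hap_end, r)
  c(res$ref_start, res$ref_end)
}

# Vectorised interval projection; same semantics as project_interval.
project_intervals <- function(hap_start, hap_end, r) {
  hap_start <- as.integer(hap_start); hap_end <- as.integer(hap_end)
  if (any(hap_end <= hap_start)) stop("empty interval")
  if (any(hap_start < 0L) || any(hap_end > r$hap_length))
    stop("interval out of range [0, ", r$hap_length, ")")
  b <- r$blocks
  nb <- nrow(b)
  blk_end <- b$hap_start + b$length

  i_s <- findInterval(hap_start, b$hap_start)
  s_exact <- i_s > 0L & hap_start < blk_end[pmax(i_s, 1L)]
  lo <- integer(length(hap_start))
  lo[s_exact] <- b$ref_start[i_s[s_exact]] +
    (hap_start[s_exact] - b$hap_start[i_s[s_exact]])
  # start inside an insertion: first exact base is the next block's start
  ins <- which(!s_exact)
  nxt <- i_s[ins] + 1L
  has_next <- nxt <= nb & ifelse(nxt <= nb, b$hap_start[pmin(nxt, nb)], NA) <
    hap_end[ins]
  lo[ins[has_next]] <- b$ref_start[nxt[has_next]]

  last <- hap_end - 1L
  i_e <- findInterval(last, b$hap_start)
  e_exact <- i_e > 0L & last < blk_end[pmax(i_e, 1L)]
  hi <- integer(length(last))
  hi[e_exact] <- b$ref_start[i_e[e_exact]] +
    (last[e_exact] - b$hap_start[i_e[e_exact]]) + 1L
  eins <- !e_exact
  hi[eins] <- ifelse(i_e[eins] == 0L, b$ref_start[1] - 1L,
                     b$ref_start[pmax(i_e[eins], 1L)] +
                       b$length[pmax(i_e[eins], 1L)] - 1L) + 1L
  # interval entirely inside one insertion: zero-length at anchor + 1
  only_ins <- ins[!has_next]
  if (length(only_ins)) {
    anchor <- ifelse(i_s[only_ins] == 0L, b$ref_start[1] - 1L,
                     b$ref_start[pmax(i_s[only_ins], 1L)] +
                       b$length[pmax(i_s[only_ins], 1L)] - 1L)
    lo[only_ins] <- anchor + 1L
    hi[only_ins] <- anchor + 1L
  }
  data.frame(ref_start = lo, ref_end = hi)
}

# Merge touching intervals with equal values in a sorted bedGraph-like
# data.frame(chrom, start, end, value).
merge_adjacent <- function(df) {
  if (nrow(df) < 2L) return(df)
  brk <- c(TRUE, df$chrom[-1L] != df$chrom[-nrow(df)] |
                 df$start[-1L] != df$end[-nrow(df)] |
                 df$value[-1L] != df$value[-nrow(df)])
  grp <- cumsum(brk)
  out <- data.frame(
    chrom = df$chrom[brk],
    start = df$start[brk],
    end = tapply(df$end, grp, function(x) x[length(x)]),
    value = df$value[brk]
  )
  rownames(out) <- NULL
  out$end <- as.integer(out$end)
  out
}

#' Project a haplotype-coordinate coverage track onto the reference
#'
#' Each interval of the sorted, non-overlapping input track is intersected
#' with the refmap blocks and each exact piece is mapped collinearly;
#' inserted-only bases carry no reference coordinate and are dropped.
#' Splitting at block boundaries (rather than stretching across deletions)
#' conserves the value at every exact-status base, so total
#' reference-base-weighted signal over exact bases is preserved and output
#' intervals never overlap. Adjacent equal-value intervals are merged.
#'
#' @param track `data.frame` with columns `start`, `end` (0-based
#'   half-open, sorted, non-overlapping) and `value`; an optional `chrom`
#'   column is ignored on input (the track lives on one haplotype contig).
#' @param r A `refmap`; the output `chrom` column is `r$chrom`.
#' @return Reference-coordinate track `data.frame(chrom, start, end,
#'   value)`.
#' @export
project_bedgraph <- function(track, r) {
  if (nrow(track)) {
    if (is.unsorted(track$start, strictly = TRUE) ||
        any(track$start[-1L] < track$end[-nrow(track)]))
      stop("input track must be sorted and non-overlapping")
    if (any(track$end <= track$start)) stop("empty track interval")
  }
  b <- r$blocks
  out <- vector("list", nrow(track))
  for (k in seq_len(nrow(track))) {
    s <- track$start[k]; e <- track$end[k]
    i1 <- max(1L, findInterval(s, b$hap_start))
    i2 <- max(1L, findInterval(e - 1L, b$hap_start))
    pieces <- list()
    for (i in i1:i2) {
      ps <- max(s, b$hap_start[i])
      pe <- min(e, b$hap_start[i] + b$length[i])
      if (pe > ps) {
        d <- b$ref_start[i] - b$hap_start[i]
        pieces[[length(pieces) + 1L]] <- c(ps + d, pe + d)
      }
    }
    if (length(pieces)) {
      pm <- do.call(rbind, pieces)
      out[[k]] <- data.frame(chrom = r$chrom, start = pm[, 1], end = pm[, 2],
                             value = track$value[k])
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  merge_adjacent(res)
}
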