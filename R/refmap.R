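# The refmap index: ordered collinear blocks mapping haplotype coordinates
# to reference coordinates across INDEL edits. SNVs never create blocks; a
# haplotype built from an INDEL-free variant set has exactly one block.

#' Construct a refmap
#'
#' A refmap records, for one haplotype of one chromosome, the collinear
#' alignment blocks between haplotype and reference coordinates that result
#' from applying INDEL edits. Within a block the two coordinate systems are
#' offset by a constant; gaps between consecutive blocks on the haplotype
#' axis are insertions, gaps on the reference axis are deletions.
#'
#' @param chrom Reference chromosome name.
#' @param hap_name Haplotype label (e.g. `"hap1"`).
#' @param hap_length Total haplotype sequence length in bp.
#' @param blocks `data.frame` with integer columns `hap_start`, `ref_start`
#'   (both 0-based) and `length` (>= 1), sorted and strictly increasing on
#'   both axes.
#' @return An object of class `refmap`.
#' @export
new_refmap <- function(chrom, hap_name, hap_length, blocks) {
  blocks <- as.data.frame(blocks)[, c("hap_start", "ref_start", "length")]
  blocks[] <- lapply(blocks, as.integer)
  r <- structure(
    list(chrom = as.character(chrom), hap_name = as.character(hap_name),
         hap_length = as.integer(hap_length), blocks = blocks),
    class = "refmap"
  )
  validate_refmap(r)
  r
}

#' Identity refmap for an unedited haplotype
#'
#' @inheritParams new_refmap
#' @param length Chromosome length in bp.
#' @return A single-block `refmap`.
#' @export
identity_refmap <- function(chrom, hap_name, length) {
  new_refmap(chrom, hap_name, length,
             data.frame(hap_start = 0L, ref_start = 0L, length = as.integer(length)))
}

validate_refmap <- function(r) {
  b <- r$blocks
  if (nrow(b) == 0L) stop("refmap must contain at least one block")
  if (any(b$length < 1L)) stop("refmap block lengths must be >= 1")
  if (nrow(b) > 1L) {
    if (any(diff(b$hap_start) <= 0L) || any(diff(b$ref_start) <= 0L))
      stop("refmap blocks must strictly increase on both axes")
    if (any(b$hap_start[-1L] < (b$hap_start + b$length)[-nrow(b)]) ||
        any(b$ref_start[-1L] < (b$ref_start + b$length)[-nrow(b)]))
      stop("refmap blocks overlap")
  }
  if (sum(b$length) > r$hap_length)
    stop("refmap blocks exceed haplotype length")
  if (b$hap_start[nrow(b)] + b$length[nrow(b)] > r$hap_length)
    stop("refmap final block extends past haplotype end")
  invisible(r)
}

#' @export
print.refmap <- function(x, ...) {
  cat(sprintf("refmap %s / %s: hap_length=%d, %d block(s)\n",
              x$chrom, x$hap_name, x$hap_length, nrow(x$blocks)))
  invisible(x)
}

#' @method all.equal refmap
#' @export
all.equal.refmap <- function(target, current, ...) {
  ok <- identical(target$chrom, current$chrom) &&
    identical(target$hap_name, current$hap_name) &&
    identical(target$hap_length, current$hap_length) &&
    isTRUE(all.equal(target$blocks, current$blocks, check.attributes = FALSE))
  if (ok) TRUE else "refmaps differ"
}

#' Write a refmap to a text file
#'
#' Format: a header line `#refmap v1 <chrom> <hap_name> <hap_length>`
#' followed by one tab-separated `hap_start ref_start length` line per
#' block, all coordinates 0-based. `read_refmap(write_refmap(r))` is an
#' exact round trip.
#'
#' @param r A `refmap`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_refmap <- function(r, path) {
  validate_refmap(r)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#refmap v1 %s %s %d", r$chrom, r$hap_name, r$hap_length), con)
  writeLines(sprintf("%d\t%d\t%d", r$blocks$hap_start, r$blocks$ref_start,
                     r$blocks$length), con)
  invisible(path)
}

#' Read a refmap from a text file
#'
#' @param path File written by [write_refmap()].
#' @return A `refmap`.
#' @export
read_refmap <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#refmap v1 "))
    stop("not a refmap file (missing '#refmap v1' header): ", path)
  hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(hdr) != 5L) stop("malformed refmap header: ", lines[1])
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("malformed refmap block at line ", bad[1] + 1L, " of ", path)
  m <- matrix(suppressWarnings(as.integer(unlist(fields))), ncol = 3L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1]
    stop("non-integer refmap block at line ", bad + 1L, " of ", path)
  }
  new_refmap(hdr[3], hdr[4], as.integer(hdr[5]),
             data.frame(hap_start = m[, 1], ref_start = m[, 2], length = m[, 3]))
}
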