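# Internal helpers shared across modules.

#' Reverse-complement DNA strings
#'
#' Vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Three-letter bisulfite collapse of a sequence. "CT" folds C into T (top
# strand comparison), "GA" folds G into A (bottom strand comparison).
bs_collapse <- function(x, mode) {
  switch(mode,
    CT = chartr("C", "T", x),
    GA = chartr("G", "A", x),
    N  = x,
    stop("unknown collapse mode: ", mode)
  )
}

# Hamming distance between equal-length string pairs. Equal strings are
# short-circuited so the byte-wise comparison only runs on mismatching pairs.
str_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- integer(length(a))
  neq <- which(a != b)
  for (i in neq) out[i] <- sum(charToRaw(a[i]) != charToRaw(b[i]))
  out
}

# 1-based positions of CpG 'C's in a sequence (case-insensitive). N bases
# never form CpGs because matching is against the literal "CG".
cpg_positions <- function(seq) {
  hits <- gregexpr("CG", toupper(seq), fixed = TRUE)[[1]]
  if (length(hits) == 1L && hits[1] == -1L) return(integer())
  as.integer(hits)
}

# Coerce a reference genome argument (named character vector, DNAStringSet,
# or single unnamed sequence) to a named uppercase-preserving character vector.
as_genome <- function(ref) {
  if (methods::is(ref, "DNAStringSet")) {
    out <- as.character(ref)
  } else if (is.character(ref)) {
    out <- ref
  } else if (is.list(ref) && !is.null(ref$seqs)) {
    out <- ref$seqs
  } else {
    stop("cannot interpret reference genome of class ", class(ref)[1])
  }
  if (is.null(names(out))) {
    if (length(out) == 1L) names(out) <- "chr1" else
      stop("multi-sequence genome must be named")
  }
  if (anyDuplicated(names(out))) stop("duplicate chromosome names in genome")
  out
}

# data.frame of 0-based half-open intervals -> GRanges
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
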