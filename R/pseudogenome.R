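# Diploid pseudogenome construction: apply phased SNVs and INDELs to the
# reference to obtain the two haplotype sequences, recording coordinate
# alterations in a refmap per haplotype.

#' Build one haplotype sequence from the reference and phased variants
#'
#' Applies the alleles carried by haplotype `hap` to `ref_seq` left to
#' right. SNV substitutions do not alter coordinates and never split refmap
#' blocks; INDEL edits close the current block after the aligned prefix
#' (the shared anchor bases) and open a new one after the inserted or
#' deleted bases. Conflicting variants (REF span overlapping an already
#' applied edit) and variants whose REF allele does not match the reference
#' sequence are skipped and counted, or abort under `strict = TRUE`.
#'
#' @param ref_seq Reference chromosome sequence (character or `DNAString`).
#' @param variants An `allelic_variants` table for this chromosome, sorted
#'   by position.
#' @param hap Haplotype to build, `1` or `2`.
#' @param chrom Chromosome name recorded in the refmap.
#' @param hap_name Haplotype label recorded in the refmap.
#' @param strict Abort on REF mismatch instead of skipping.
#' @return A list: `seq` (haplotype sequence, substituted bases uppercase,
#'   reference case otherwise preserved), `refmap`, `n_applied`,
#'   `n_skipped`, and `skipped` (a `data.frame` of skipped positions with
#'   reasons).
#' @export
build_haplotype <- function(ref_seq, variants, hap, chrom = "chr1",
                            hap_name = paste0("hap", hap), strict = FALSE) {
  ref_seq <- as.character(ref_seq)
  ref_len <- nchar(ref_seq)
  stopifnot(hap %in% c(1L, 2L))
  v <- variants[order(variants$pos), , drop = FALSE]
  allele <- haplotype_allele(v, hap)
  idx <- if (hap == 1L) v$a1 else v$a2
  edit <- which(idx > 0L)

  pieces <- character(0)
  cursor <- 1L                  # next unconsumed 1-based reference position
  offset <- 0L                  # hap coordinate - ref coordinate, current block
  blk_ref_start <- 0L           # 0-based reference start of the open block
  blocks <- list()
  n_applied <- 0L
  skip_pos <- integer(0); skip_reason <- character(0)

  for (i in edit) {
    pos <- v$pos[i]
    ra <- v$ref[i]
    aa <- allele[i]
    lr <- nchar(ra); la <- nchar(aa)
    if (pos < cursor) {
      skip_pos <- c(skip_pos, pos); skip_reason <- c(skip_reason, "overlap")
      next
    }
    if (pos + lr - 1L > ref_len) {
      msg <- sprintf("variant at %s:%d extends past chromosome end", chrom, pos)
      if (strict) stop(msg)
      skip_pos <- c(skip_pos, pos); skip_reason <- c(skip_reason, "out_of_bounds")
      next
    }
    seen <- toupper(substr(ref_seq, pos, pos + lr - 1L))
    if (seen != toupper(ra)) {
      msg <- sprintf("REF mismatch at %s:%d (VCF '%s', reference '%s')",
                     chrom, pos, ra, seen)
      if (strict) stop(msg)
      skip_pos <- c(skip_pos, pos); skip_reason <- c(skip_reason, "ref_mismatch")
      next
    }
    if (cursor <= pos - 1L)
      pieces <- c(pieces, substr(ref_seq, cursor, pos - 1L))
    pieces <- c(pieces, toupper(aa))
    if (lr != la) {
      m <- min(lr, la)            # aligned prefix (anchor bases)
      pos0 <- pos - 1L
      blk_len <- pos0 + m - blk_ref_start
      if (blk_len > 0L)
        blocks[[length(blocks) + 1L]] <-
          c(blk_ref_start + offset, blk_ref_start, blk_len)
      offset <- offset + (la - lr)
      blk_ref_start <- pos0 + lr
    }
    cursor <- pos + lr
    n_applied <- n_applied + 1L
  }
  if (cursor <= ref_len)
    pieces <- c(pieces, substr(ref_seq, cursor, ref_len))
  hap_seq <- paste(pieces, collapse = "")

  final_len <- ref_len - blk_ref_start
  if (final_len > 0L)
    blocks[[length(blocks) + 1L]] <- c(blk_ref_start + offset, blk_ref_start, final_len)
  bm <- do.call(rbind, blocks)
  rmap <- new_refmap(chrom, hap_name, nchar(hap_seq),
                     data.frame(hap_start = bm[, 1], ref_start = bm[, 2],
                                length = bm[, 3]))
  list(seq = hap_seq, refmap = rmap, n_applied = n_applied,
       n_skipped = length(skip_pos),
       skipped = data.frame(pos = skip_pos, reason = skip_reason))
}

#' Build a diploid pseudogenome
#'
#' Constructs both haplotype sequences for every reference chromosome and
#' the refmap index per contig. Contigs are named `<chrom>_<hap_name>`, so
#' the haplotype of origin is recoverable from the contig name by the
#' classification stage.
#'
#' @param ref Reference genome: named character vector or `DNAStringSet`.
#' @param variants An `allelic_variants` table (any chromosome mix).
#' @param hap_names Pair of distinct haplotype labels.
#' @param strict Abort on REF mismatches.
#' @return An object of class `diploid_genome`: `contigs` (named character
#'   vector), `refmaps` (named list of `refmap`, keyed by contig),
#'   `hap_names`, `chroms`, and `stats` (per chrom/hap applied and skipped
#'   variant counts).
#' @export
build_diploid <- function(ref, variants, hap_names = c("hap1", "hap2"),
                          strict = FALSE) {
  ref <- as_genome(ref)
  if (length(hap_names) != 2L || hap_names[1] == hap_names[2])
    stop("hap_names must be two distinct labels")
  contigs <- character(0)
  refmaps <- list()
  stats <- list()
  for (chrom in names(ref)) {
    vc <- variants[variants$chrom == chrom, , drop = FALSE]
    for (h in 1:2) {
      built <- build_haplotype(ref[[chrom]], vc, h, chrom = chrom,
                               hap_name = hap_names[h], strict = strict)
      contig <- paste0(chrom, "_", hap_names[h])
      contigs[contig] <- built$seq
      refmaps[[contig]] <- built$refmap
      stats[[length(stats) + 1L]] <- data.frame(
        chrom = chrom, hap = hap_names[h],
        n_applied = built$n_applied, n_skipped = built$n_skipped)
    }
  }
  structure(list(contigs = contigs, refmaps = refmaps, hap_names = hap_names,
                 chroms = names(ref), stats = do.call(rbind, stats)),
            class = "diploid_genome")
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf("diploid genome: %d chromosome(s) x {%s}, %s bp total\n",
              length(x$chroms), paste(x$hap_names, collapse = ", "),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

# Map a diploid contig name back to (chrom, haplotype index). Errors on
# contigs without a recognised haplotype suffix.
contig_haplotype <- function(contig, hap_names) {
  for (h in 1:2) {
    sfx <- paste0("_", hap_names[h])
    hit <- endsWith(contig, sfx)
    if (any(hit) && all(hit))
      return(list(chrom = substr(contig, 1L, nchar(contig) - nchar(sfx)), hap = h))
  }
  res_chrom <- character(length(contig))
  res_hap <- integer(length(contig))
  for (i in seq_along(contig)) {
    hap <- NA_integer_
    for (h in 1:2) {
      sfx <- paste0("_", hap_names[h])
      if (endsWith(contig[i], sfx)) {
        hap <- h
        res_chrom[i] <- substr(contig[i], 1L, nchar(contig[i]) - nchar(sfx))
        break
      }
    }
    if (is.na(hap))
      stop("contig '", contig[i], "' has no recognised haplotype suffix (_",
           paste(hap_names, collapse = " or _"), ")")
    res_hap[i] <- hap
  }
  list(chrom = res_chrom, hap = res_hap)
}

#' Write a diploid pseudogenome to disk
#'
#' Writes a multi-FASTA (wrapped at 60 columns) plus one `.refmap` file per
#' contig.
#'
#' @param dg A `diploid_genome`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_diploid <- function(dg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(dg$contigs)
  Biostrings::writeXStringSet(dna, file.path(dir, "diploid.fa"), width = 60L)
  for (contig in names(dg$refmaps))
    write_refmap(dg$refmaps[[contig]], file.path(dir, paste0(contig, ".refmap")))
  utils::write.table(dg$stats, file.path(dir, "variant_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a diploid pseudogenome written by [write_diploid()]
#'
#' @param dir Directory containing `diploid.fa` and `.refmap` files.
#' @param hap_names Haplotype labels used when the genome was built.
#' @return A `diploid_genome`.
#' @export
read_diploid <- function(dir, hap_names = c("hap1", "hap2")) {
  fa <- Biostrings::readDNAStringSet(file.path(dir, "diploid.fa"))
  contigs <- as.character(fa)
  names(contigs) <- sub(" .*", "", names(fa))
  refmaps <- lapply(names(contigs), function(ct)
    read_refmap(file.path(dir, paste0(ct, ".refmap"))))
  names(refmaps) <- names(contigs)
  ch <- contig_haplotype(names(contigs), hap_names)
  structure(list(contigs = contigs, refmaps = refmaps, hap_names = hap_names,
                 chroms = unique(ch$chrom), stats = NULL),
            class = "diploid_genome")
}
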