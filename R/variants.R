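# Phased variant model: parsing, normalisation, haplotype allele lookup and
# the variant-proximity census of CpG dinucleotides.

#' Construct a phased variant table
#'
#' The central variant container used throughout the package: one row per
#' VCF record, with the phased haplotype allele choice encoded as a pair of
#' allele indices (`0` = REF, `k` = k-th ALT allele).
#'
#' @param chrom Chromosome names.
#' @param pos 1-based reference positions of the first REF base.
#' @param ref Uppercase REF alleles (length >= 1).
#' @param alt ALT alleles; multi-allelic records as comma-separated strings.
#' @param a1,a2 Integer allele indices carried by haplotype 1 and 2.
#' @return A `data.frame` of class `allelic_variants`, sorted by
#'   `(chrom, pos)`.
#' @export
variant_table <- function(chrom, pos, ref, alt, a1, a2) {
  v <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    a1 = as.integer(a1), a2 = as.integer(a2),
    stringsAsFactors = FALSE
  )
  if (nrow(v)) {
    bad <- !grepl("^[ACGTN]+(,[ACGTN]+)*$", v$alt) | !grepl("^[ACGTN]+$", v$ref)
    if (any(bad))
      stop("non-ACGTN allele in variant record ", which(bad)[1])
    n_alt <- lengths(strsplit(v$alt, ",", fixed = TRUE))
    if (any(v$a1 < 0L | v$a1 > n_alt | v$a2 < 0L | v$a2 > n_alt))
      stop("haplotype allele index out of range")
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    rownames(v) <- NULL
  }
  class(v) <- c("allelic_variants", "data.frame")
  v
}

#' Parse phased variants from a VCF file
#'
#' Reads a VCF 4.x file (plain or gzip) and returns the variant table used
#' for pseudogenome construction. With a named `sample`, phased genotypes
#' `a|b` map the left allele to haplotype 1 and the right to haplotype 2;
#' unphased heterozygous genotypes (e.g. `0/1`) are skipped and counted,
#' keeping output deterministic. Unphased homozygous genotypes (`1/1`) are
#' unambiguous and kept. Without a sample column every record is read in
#' strain-vs-reference mode: haplotype 1 carries REF, haplotype 2 the first
#' ALT allele. Records with symbolic ALT alleles (e.g. `<DEL>`) are
#' structural variants and are dropped with a count.
#'
#' @param path VCF file path.
#' @param sample Sample name whose GT field supplies the phasing; `NULL`
#'   (default) selects strain-vs-reference mode unless the file has exactly
#'   one sample column, which is then used.
#' @param require_pass If `TRUE`, keep only records with FILTER `PASS` or
#'   `.`. The FILTER column is ignored by default because strain VCFs vary
#'   in filter conventions.
#' @return An `allelic_variants` table with attribute `skipped`, a named
#'   integer vector of per-reason skip counts.
#' @export
parse_vcf <- function(path, sample = NULL, require_pass = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  skipped <- c(unphased_het = 0L, symbolic_alt = 0L, missing_gt = 0L,
               filter_fail = 0L)
  if (n == 0L) {
    out <- variant_table(character(), integer(), character(), character(),
                         integer(), integer())
    attr(out, "skipped") <- skipped
    return(out)
  }
  keep <- rep(TRUE, n)
  alt <- fix[, "ALT"]
  symbolic <- is.na(alt) | grepl("[][<>*]", alt)
  skipped["symbolic_alt"] <- sum(symbolic)
  keep <- keep & !symbolic
  if (require_pass) {
    filt <- fix[, "FILTER"]
    fail <- !(is.na(filt) | filt %in% c("PASS", "."))
    skipped["filter_fail"] <- sum(fail & keep)
    keep <- keep & !fail
  }

  gt_mat <- vcf@gt
  have_samples <- !is.null(gt_mat) && ncol(gt_mat) >= 2L
  if (!is.null(sample) && !have_samples)
    stop("VCF has no sample columns but sample='", sample, "' was requested")
  a1 <- rep(0L, n); a2 <- rep(1L, n)
  if (!is.null(sample) || have_samples) {
    samples <- colnames(gt_mat)[-1L]
    if (is.null(sample)) {
      if (length(samples) != 1L)
        stop("VCF has ", length(samples),
             " samples; name one with the 'sample' argument")
      sample <- samples[1]
    }
    if (!sample %in% samples)
      stop("sample '", sample, "' not found in VCF (has: ",
           paste(samples, collapse = ", "), ")")
    fmt <- gt_mat[, 1L]
    val <- gt_mat[, sample]
    gt_field <- function(i) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
      j <- match("GT", keys)
      if (is.na(j)) return(NA_character_)
      strsplit(val[i], ":", fixed = TRUE)[[1]][j]
    }
    n_alt <- lengths(strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE))
    for (i in which(keep)) {
      gt <- gt_field(i)
      if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
        skipped["missing_gt"] <- skipped["missing_gt"] + 1L
        keep[i] <- FALSE
        next
      }
      if (!grepl("^[0-9]+([/|][0-9]+)?$", gt))
        stop("malformed GT '", gt, "' at record ", i, " (",
             fix[i, "CHROM"], ":", fix[i, "POS"], ")")
      phased <- grepl("|", gt, fixed = TRUE)
      parts <- as.integer(strsplit(gt, "[/|]")[[1]])
      if (length(parts) == 1L) parts <- c(parts, parts)
      if (any(parts > n_alt[i]))
        stop("allele index out of range in GT '", gt, "' at record ", i,
             " (", fix[i, "CHROM"], ":", fix[i, "POS"], ")")
      if (!phased && parts[1] != parts[2]) {
        skipped["unphased_het"] <- skipped["unphased_het"] + 1L
        keep[i] <- FALSE
        next
      }
      a1[i] <- parts[1]; a2[i] <- parts[2]
    }
  }

  out <- variant_table(fix[keep, "CHROM"], as.integer(fix[keep, "POS"]),
                       fix[keep, "REF"], alt[keep], a1[keep], a2[keep])
  attr(out, "skipped") <- skipped
  out
}

#' Allele sequence carried by one haplotype at a variant
#'
#' @param v An `allelic_variants` table.
#' @param hap Haplotype, `1` or `2`.
#' @return Character vector of allele sequences, one per variant row.
#' @export
haplotype_allele <- function(v, hap) {
  stopifnot(hap %in% c(1L, 2L))
  idx <- if (hap == 1L) v$a1 else v$a2
  alts <- strsplit(v$alt, ",", fixed = TRUE)
  vapply(seq_len(nrow(v)), function(i) {
    if (idx[i] == 0L) v$ref[i] else alts[[i]][idx[i]]
  }, character(1))
}

# Per-row variant class given the haplotype allele choice. A variant is an
# SNV iff REF and every haplotype-chosen non-REF allele have length 1;
# anything else is an INDEL. Rows with a1 == a2 do not distinguish the
# haplotypes and are classed "uninformative".
variant_class <- function(v) {
  al1 <- haplotype_allele(v, 1L)
  al2 <- haplotype_allele(v, 2L)
  cls <- ifelse(v$a1 == v$a2, "uninformative",
                ifelse(nchar(v$ref) == 1L & nchar(al1) == 1L & nchar(al2) == 1L,
                       "snv", "indel"))
  cls
}

#' Census of CpGs within reach of a genetic variant
#'
#' Counts reference CpG dinucleotides that lie within `window_bp` of a
#' haplotype-distinguishing variant, split by whether only SNVs, only
#' INDELs, or both classes occur within the window. This is the theoretical
#' count of CpGs at which allele-specific methylation can be measured with
#' a given variant catalogue: a fragment of typical insert size covering
#' the CpG can also cover a variant and hence be assigned to an allele.
#' Distance is measured from the CpG's C base to the closest base of the
#' variant's REF span, inclusive; a CpG overlapping a REF span counts as
#' distance 0. Variants whose two haplotype alleles are identical
#' (homozygous-alternate phased records) are not informative and are
#' excluded.
#'
#' @param ref_seq Chromosome sequence (character or `DNAString`).
#' @param variants An `allelic_variants` table for this chromosome.
#' @param window_bp Distance threshold in bp (default 200, an insert size
#'   typical of WGBS libraries).
#' @return A list of class `cpg_census`: `n_total_cpg`, `n_snv_only`,
#'   `n_indel_only`, `n_both`, `window_bp`.
#' @export
cpg_census <- function(ref_seq, variants, window_bp = 200L) {
  if (window_bp < 0L) stop("window_bp must be >= 0")
  ref_seq <- as.character(ref_seq)
  p <- cpg_positions(ref_seq)
  cls <- variant_class(variants)
  spans <- data.frame(start = variants$pos,
                      end = variants$pos + nchar(variants$ref) - 1L,
                      class = cls)
  if (any(spans$end > nchar(ref_seq) | spans$start < 1L))
    stop("variant outside sequence bounds")
  near <- function(class) {
    s <- spans[spans$class == class, , drop = FALSE]
    if (nrow(s) == 0L || length(p) == 0L) return(logical(length(p)))
    IRanges::overlapsAny(
      IRanges::IRanges(p, p),
      IRanges::IRanges(pmax(1L, s$start - window_bp), s$end + window_bp)
    )
  }
  snv <- near("snv"); ind <- near("indel")
  structure(list(
    n_total_cpg = length(p),
    n_snv_only = sum(snv & !ind),
    n_indel_only = sum(ind & !snv),
    n_both = sum(snv & ind),
    window_bp = as.integer(window_bp)
  ), class = "cpg_census")
}

#' @export
print.cpg_census <- function(x, ...) {
  cat(sprintf(
    "CpG census (window %d bp): %d CpGs total; %d SNV-only, %d INDEL-only, %d both\n",
    x$window_bp, x$n_total_cpg, x$n_snv_only, x$n_indel_only, x$n_both))
  invisible(x)
}

#' Write a tab-delimited CpG census report
#'
#' @param census A `cpg_census` or a named list of them (one per
#'   chromosome).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpg_census <- function(census, path) {
  if (inherits(census, "cpg_census")) census <- list(genome = census)
  df <- data.frame(
    chrom = names(census),
    n_total_cpg = vapply(census, `[[`, integer(1), "n_total_cpg"),
    n_snv_only = vapply(census, `[[`, integer(1), "n_snv_only"),
    n_indel_only = vapply(census, `[[`, integer(1), "n_indel_only"),
    n_both = vapply(census, `[[`, integer(1), "n_both"),
    window_bp = vapply(census, `[[`, integer(1), "window_bp")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant table as a VCF file
#'
#' Emits a minimal VCF 4.2 file. With a sample name, genotypes are written
#' phased (`a1|a2`); with `sample = NULL` an 8-column site-only VCF is
#' written, which [parse_vcf()] reads back in strain-vs-reference mode.
#'
#' @param v An `allelic_variants` table.
#' @param path Output path.
#' @param sample Sample name, or `NULL` for a site-only VCF.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path, sample = "F1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  hdr <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample)) hdr <- c(hdr, "FORMAT", sample)
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(v)) {
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", sep = "\t")
    if (!is.null(sample))
      body <- paste(body, "GT", sprintf("%d|%d", v$a1, v$a2), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
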