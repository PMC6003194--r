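# Fixture builders and independent oracles used across the suite. Oracles
# deliberately use different algorithms from the package implementation:
# character-vector splicing, linear block walks, exhaustive window scans
# and double loops.

# Independent haplotype-construction oracle: edits a character vector in
# place (substitution at the variant position, emptied deleted cells),
# with the same greedy left-to-right conflict rule as the builder.
oracle_splice <- function(ref_seq, variants, hap) {
  chars <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  cells <- as.list(chars)
  v <- variants[order(variants$pos), , drop = FALSE]
  allele <- haplotype_allele(v, hap)
  idx <- if (hap == 1L) v$a1 else v$a2
  last_end <- 0L
  for (i in seq_len(nrow(v))) {
    if (idx[i] == 0L) next
    pos <- v$pos[i]
    lr <- nchar(v$ref[i])
    if (pos <= last_end) next
    if (pos + lr - 1L > nchar(ref_seq)) next
    if (toupper(substr(ref_seq, pos, pos + lr - 1L)) != toupper(v$ref[i])) next
    cells[[pos]] <- toupper(allele[i])
    if (lr > 1L) for (j in (pos + 1L):(pos + lr - 1L)) cells[[j]] <- ""
    last_end <- pos + lr - 1L
  }
  paste(unlist(cells), collapse = "")
}

# Per-base projection oracle: walk the blocks linearly and fill a vector of
# reference positions (NA where the haplotype base is inside an insertion).
oracle_project_all <- function(r) {
  b <- r$blocks
  ref_pos <- rep(NA_integer_, r$hap_length)
  for (i in seq_len(nrow(b))) {
    hp <- b$hap_start[i] + seq_len(b$length[i]) - 1L
    ref_pos[hp + 1L] <- b$ref_start[i] + seq_len(b$length[i]) - 1L
  }
  ref_pos
}

# Exhaustive single-read placement oracle: every window of every contig on
# both strands, Hamming-compared; returns placements with mm <= max_mm,
# deduplicated by location keeping the best score.
oracle_scan <- function(read, contigs, max_mm) {
  read <- toupper(read)
  L <- nchar(read)
  pr <- charToRaw(read)
  rr <- charToRaw(allelign::revcomp(read))
  out <- list()
  for (ct in names(contigs)) {
    s <- toupper(contigs[[ct]])
    n <- nchar(s)
    if (n < L) next
    wins <- substring(s, 1:(n - L + 1L), L:n)
    for (p in seq_along(wins)) {
      w <- charToRaw(wins[p])
      mmf <- sum(w != pr)
      mmr <- sum(w != rr)
      if (min(mmf, mmr) <= max_mm)
        out[[length(out) + 1L]] <- data.frame(
          contig = ct, start = p, mm = min(mmf, mmr))
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(), mm = integer()))
  df <- do.call(rbind, out)
  df[order(df$contig, df$start), ]
}

# Small deterministic diploid fixture used by several files.
toy_diploid <- function(seed = 5, len = 6000L, snv_per_kb = 5,
                        indel_per_kb = 1) {
  ref <- sim_reference(seed, lengths = c(chr1 = len))
  v <- sim_variants(ref, seed + 1L, snv_per_kb = snv_per_kb,
                    indel_per_kb = indel_per_kb)
  list(ref = ref, variants = v, dg = build_diploid(ref, v))
}

# Random refmap generator for round-trip and projection property tests.
random_refmap <- function(n_blocks, chrom = "chr1", hap_name = "hapX") {
  hs <- 0L; rs <- 0L
  blocks <- list()
  for (i in seq_len(n_blocks)) {
    len <- sample(1:500, 1)
    blocks[[i]] <- c(hs, rs, len)
    gap_h <- sample(0:10, 1)
    gap_r <- sample(0:10, 1)
    if (i < n_blocks && gap_h == 0L && gap_r == 0L) gap_h <- 1L
    hs <- hs + len + gap_h
    rs <- rs + len + gap_r
  }
  m <- do.call(rbind, blocks)
  last <- m[nrow(m), ]
  new_refmap(chrom, hap_name, last[1] + last[3] + sample(0:5, 1),
             data.frame(hap_start = m[, 1], ref_start = m[, 2],
                        length = m[, 3]))
}
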