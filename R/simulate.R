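# Synthetic F1-hybrid fixture generator: reference genomes with CpG
# islands and optional satellite-like decoy arrays, phased variant sets,
# and genomic / bisulfite / enrichment-style paired-end read sets with
# complete per-fragment truth. All outputs are reproducible for a fixed
# seed.

#' Simulate a reference genome
#'
#' Background sequence is drawn i.i.d. at the requested GC fraction. CpG
#' islands are segments generated with an elevated CpG emission rate so
#' methylome analyses have structure to find. An optional satellite-like
#' decoy is a tandem array of one repeat unit, emulating the highly
#' repetitive regions that generate spurious unique alignments in real
#' data.
#'
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param lengths Named integer vector of chromosome lengths (>= 1000 bp).
#' @param gc Genome GC fraction.
#' @param islands `NULL` or `list(n, length, cpg_rate)`: per chromosome,
#'   `n` islands of `length` bp in which a CpG dinucleotide is emitted
#'   with probability `cpg_rate` per position (background CpG density is
#'   about `(gc/2)^2`).
#' @param satellite `NULL` or `list(chrom, unit_len, n_units, start)`: a
#'   tandem array of one random `unit_len`-bp unit repeated `n_units`
#'   times, spliced in at `start` (1-based).
#' @return List of class `sim_reference`: `seqs` (named character),
#'   `islands` and `satellite` (`data.frame(chrom, start, end)`, 0-based
#'   half-open, possibly empty).
#' @export
sim_reference <- function(seed, lengths = c(chr1 = 50000L), gc = 0.42,
                          islands = NULL, satellite = NULL) {
  stopifnot(all(lengths >= 1000L))
  withr::with_seed(seed, {
    prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lengths, function(n)
      paste(sample(names(prob), n, replace = TRUE, prob = prob),
            collapse = ""), character(1))
    names(seqs) <- names(lengths)
    island_df <- data.frame(chrom = character(), start = integer(),
                            end = integer())
    if (!is.null(islands)) {
      for (chrom in names(seqs)) {
        len <- nchar(seqs[[chrom]])
        slots <- pick_disjoint(islands$n, islands$length, len, margin = 500L)
        for (s in slots) {
          isl <- emit_cpg_island(islands$length, islands$cpg_rate, prob)
          substr(seqs[[chrom]], s, s + islands$length - 1L) <- isl
          island_df <- rbind(island_df, data.frame(
            chrom = chrom, start = s - 1L, end = s - 1L + islands$length))
        }
      }
    }
    sat_df <- data.frame(chrom = character(), start = integer(),
                         end = integer())
    if (!is.null(satellite)) {
      unit <- paste(sample(c("A", "C", "G", "T"), satellite$unit_len,
                           replace = TRUE), collapse = "")
      arr <- strrep(unit, satellite$n_units)
      chrom <- satellite$chrom %||% names(seqs)[1]
      s <- satellite$start
      stopifnot(s + nchar(arr) - 1L <= nchar(seqs[[chrom]]))
      substr(seqs[[chrom]], s, s + nchar(arr) - 1L) <- arr
      sat_df <- data.frame(chrom = chrom, start = s - 1L,
                           end = s - 1L + nchar(arr))
      attr(sat_df, "unit") <- unit
    }
    structure(list(seqs = seqs, islands = island_df, satellite = sat_df),
              class = "sim_reference")
  })
}

# n disjoint 1-based starts for segments of seg_len within [margin,
# len - seg_len - margin]
pick_disjoint <- function(n, seg_len, len, margin = 0L) {
  starts <- integer(0)
  for (attempt in seq_len(200L)) {
    cand <- sample(seq(margin + 1L, len - seg_len - margin), 1L)
    if (!any(abs(cand - starts) < seg_len)) starts <- c(starts, cand)
    if (length(starts) == n) break
  }
  if (length(starts) < n) stop("could not place ", n, " disjoint segments")
  sort(starts)
}

emit_cpg_island <- function(len, cpg_rate, prob) {
  # emit ~len tokens, each "CG" with probability cpg_rate else one base
  n_tok <- len
  tok <- ifelse(stats::runif(n_tok) < cpg_rate, "CG",
                sample(names(prob), n_tok, replace = TRUE, prob = prob))
  substr(paste(tok, collapse = ""), 1L, len)
}

#' Simulate a phased variant set
#'
#' Draws Poisson-distributed numbers of SNVs and INDELs per chromosome,
#' placed uniformly with non-overlapping REF spans; INDEL lengths are
#' geometric, capped at `max_indel_len`, split evenly between insertions
#' and deletions. REF alleles are taken from the reference sequence so
#' they always match. In strain-vs-reference mode (default) every variant
#' is carried by haplotype 2; in phased mode the carrying haplotype is
#' drawn at random per variant, so both haplotypes differ from the
#' reference.
#'
#' @param ref A `sim_reference` or named character vector.
#' @param seed Integer seed.
#' @param snv_per_kb,indel_per_kb Expected variant densities; strain-like
#'   catalogues have roughly a 5:1 SNV:INDEL ratio.
#' @param indel_geom_p Geometric parameter for INDEL length (1 + rgeom).
#' @param max_indel_len Maximum INDEL length in bp.
#' @param exclude Optional `data.frame(chrom, start, end)` (0-based
#'   half-open) where no variant may be placed.
#' @param phased Draw the carrying haplotype per variant instead of
#'   strain-vs-reference.
#' @return An `allelic_variants` table.
#' @export
sim_variants <- function(ref, seed, snv_per_kb = 2, indel_per_kb = 0.4,
                         indel_geom_p = 0.5, max_indel_len = 10L,
                         exclude = NULL, phased = FALSE) {
  seqs <- as_genome(ref)
  withr::with_seed(seed, {
    rows <- list()
    for (chrom in names(seqs)) {
      len <- nchar(seqs[[chrom]])
      n_snv <- stats::rpois(1L, snv_per_kb * len / 1000)
      n_ind <- stats::rpois(1L, indel_per_kb * len / 1000)
      if (n_snv + n_ind == 0L) next
      placed <- place_variants(seqs[[chrom]], n_snv, n_ind, indel_geom_p,
                               max_indel_len, exclude, chrom)
      if (nrow(placed)) {
        placed$chrom <- chrom
        rows[[length(rows) + 1L]] <- placed
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character())
    n <- nrow(df)
    if (phased) {
      hap2 <- stats::runif(n) < 0.5
      a1 <- ifelse(hap2, 0L, 1L); a2 <- ifelse(hap2, 1L, 0L)
    } else {
      a1 <- rep(0L, n); a2 <- rep(1L, n)
    }
    variant_table(df$chrom, df$pos, df$ref, df$alt, a1, a2)
  })
}

place_variants <- function(seq, n_snv, n_ind, geom_p, max_len, exclude,
                           chrom) {
  len <- nchar(seq)
  for (attempt in 1:5) {
    n <- n_snv + n_ind
    is_ind <- sample(rep(c(FALSE, TRUE), c(n_snv, n_ind)))
    pos <- sample(seq(2L, len - max_len - 2L), n)
    ind_len <- pmin(1L + stats::rgeom(n, geom_p), max_len)
    is_ins <- stats::runif(n) < 0.5
    span <- ifelse(is_ind & !is_ins, 1L + ind_len, 1L)
    o <- order(pos)
    pos <- pos[o]; is_ind <- is_ind[o]; ind_len <- ind_len[o]
    is_ins <- is_ins[o]; span <- span[o]
    # exclusion zones are removed first and do not count against density
    if (!is.null(exclude) && nrow(exclude)) {
      excl <- exclude[exclude$chrom == chrom, , drop = FALSE]
      if (nrow(excl)) {
        hit <- IRanges::overlapsAny(
          IRanges::IRanges(pos, pos + span - 1L),
          IRanges::IRanges(excl$start + 1L, excl$end))
        pos <- pos[!hit]; is_ind <- is_ind[!hit]; ind_len <- ind_len[!hit]
        is_ins <- is_ins[!hit]; span <- span[!hit]
      }
    }
    n_free <- length(pos)
    # greedy non-overlap with a 1 bp gap between REF spans
    keep <- logical(n_free); last_end <- 0L
    for (i in seq_len(n_free)) {
      if (pos[i] > last_end + 1L) {
        keep[i] <- TRUE
        last_end <- pos[i] + span[i] - 1L
      }
    }
    if (sum(keep) >= 0.7 * n_free || attempt == 5L) {
      if (sum(keep) < 0.5 * n_free)
        stop("variant density too high to satisfy non-overlap")
      pos <- pos[keep]; is_ind <- is_ind[keep]; ind_len <- ind_len[keep]
      is_ins <- is_ins[keep]
      ref <- character(length(pos)); alt <- character(length(pos))
      for (i in seq_along(pos)) {
        base <- toupper(substr(seq, pos[i], pos[i]))
        if (!is_ind[i]) {
          ref[i] <- base
          alt[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
        } else if (is_ins[i]) {
          ref[i] <- base
          alt[i] <- paste0(base, paste(sample(c("A", "C", "G", "T"),
                                              ind_len[i], replace = TRUE),
                                       collapse = ""))
        } else {
          ref[i] <- toupper(substr(seq, pos[i], pos[i] + ind_len[i]))
          alt[i] <- base
        }
      }
      return(data.frame(pos = pos, ref = ref, alt = alt))
    }
  }
}

# Shared fragment placement: haplotype choice, contig, start, insert size
# and originating strand for n fragments.
place_fragments <- function(diploid, n, read_len, insert_mean, insert_sd,
                            hap_fraction, balanced = FALSE,
                            target = NULL) {
  if (insert_mean < read_len) stop("insert size must be >= read length")
  hap_names <- diploid$hap_names
  contig_len <- nchar(diploid$contigs)
  if (any(read_len > contig_len)) stop("read length exceeds a contig length")
  hap <- if (balanced) sample(rep(1:2, length.out = n)) else
    ifelse(stats::runif(n) < hap_fraction, 1L, 2L)
  chroms <- diploid$chroms
  # chromosome proportional to its reference-haplotype length
  chrom <- if (length(chroms) == 1L) rep(chroms, n) else
    sample(chroms, n, replace = TRUE,
           prob = contig_len[paste0(chroms, "_", hap_names[1])])
  contig <- paste0(chrom, "_", hap_names[hap])
  ins <- pmax(read_len, as.integer(round(stats::rnorm(n, insert_mean,
                                                      insert_sd))))
  ins <- pmin(ins, contig_len[contig])
  start <- floor(stats::runif(n) * (contig_len[contig] - ins + 1L)) + 1L
  top <- stats::runif(n) < 0.5
  data.frame(hap = hap, chrom = chrom, contig = contig, start = start,
             insert = ins, top = top)
}

# Apply i.i.d. substitution errors to a character vector of reads.
apply_seq_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
  }
  reads
}

# Reference spans (0-based half-open) at which the two haplotypes can be
# told apart: the substituted base for SNVs, the deleted bases for
# deletions, the insertion-point junction for insertions.
distinguishing_spans <- function(variants) {
  v <- variants[variants$a1 != variants$a2, , drop = FALSE]
  if (nrow(v) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  lr <- nchar(v$ref)
  al1 <- haplotype_allele(v, 1L); al2 <- haplotype_allele(v, 2L)
  la <- pmax(nchar(al1), nchar(al2))
  start0 <- ifelse(lr == 1L & la == 1L, v$pos - 1L,          # SNV: the base
            ifelse(lr > 1L, v$pos,                           # deletion: deleted bases
                   v$pos - 1L))                              # insertion: junction
  end0 <- ifelse(lr == 1L & la == 1L, v$pos,
          ifelse(lr > 1L, v$pos + lr - 1L,
                 v$pos + 1L))
  data.frame(chrom = v$chrom, start = start0, end = end0)
}

# Count distinguishing variants overlapped by the sequenced (projected)
# read intervals of each fragment.
count_variant_overlap <- function(truth_reads, variants) {
  spans <- distinguishing_spans(variants)
  if (nrow(spans) == 0L) return(rep(0L, max(truth_reads$frag_idx %||% 0L, 0L)))
  gr_var <- intervals_to_granges(spans)
  gr_reads <- GenomicRanges::GRanges(
    truth_reads$chrom,
    IRanges::IRanges(truth_reads$ref_start + 1L,
                     pmax(truth_reads$ref_end, truth_reads$ref_start + 1L)))
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_var)
  # unique variants per fragment across both read intervals
  df <- unique(data.frame(frag = truth_reads$frag_idx[S4Vectors::queryHits(hits)],
                          var = S4Vectors::subjectHits(hits)))
  tab <- table(factor(df$frag, levels = seq_len(max(truth_reads$frag_idx))))
  as.integer(tab)
}

# Project the two sequenced mate intervals of each placed fragment to
# reference coordinates; returns one row per mate with frag_idx.
sequenced_intervals <- function(pl, read_len, diploid) {
  n <- nrow(pl)
  r1s <- pl$start; r1e <- pl$start + read_len - 1L
  r2s <- pl$start + pl$insert - read_len; r2e <- pl$start + pl$insert - 1L
  long <- data.frame(
    frag_idx = rep(seq_len(n), 2L),
    contig = rep(pl$contig, 2L), chrom = rep(pl$chrom, 2L),
    hs = c(r1s, r2s) - 1L, he = c(r1e, r2e))
  res <- do.call(rbind, lapply(split(long, long$contig), function(g) {
    p <- project_intervals(g$hs, g$he, diploid$refmaps[[g$contig[1]]])
    g$ref_start <- p$ref_start; g$ref_end <- p$ref_end
    g
  }))
  res[order(res$frag_idx), ]
}

#' Simulate genomic paired-end fragments from a diploid genome
#'
#' Each fragment is drawn from haplotype 1 with probability
#' `hap_fraction` (or exactly half with `balanced = TRUE`), placed
#' uniformly, sequenced from a random strand, and subjected to i.i.d.
#' substitution errors. Truth records the originating haplotype, the
#' projected reference interval, and the number of haplotype-
#' distinguishing variants overlapped by the sequenced read intervals.
#'
#' @param diploid A `diploid_genome`.
#' @param seed Integer seed.
#' @param n_fragments Number of fragments.
#' @param read_len Read length (both mates).
#' @param insert_mean,insert_sd Fragment insert size distribution
#'   (normal, clamped to at least `read_len`).
#' @param error_rate Per-base substitution error probability.
#' @param hap_fraction Probability that a fragment derives from
#'   haplotype 1.
#' @param balanced Assign exactly half the fragments to each haplotype
#'   (a stratified balanced design for bias benchmarking).
#' @param variants Optional `allelic_variants` used to fill the
#'   `n_var` truth column.
#' @return List of class `sim_reads`: `reads` (`read_id`, `seq1`,
#'   `seq2`) and `truth` (`read_id`, `hap`, `contig`, `chrom`,
#'   `hap_start`, `hap_end`, `ref_start`, `ref_end` (0-based half-open),
#'   `strand`, `n_var`).
#' @export
sim_fragments <- function(diploid, seed, n_fragments, read_len = 100L,
                          insert_mean = 300L, insert_sd = 30L,
                          error_rate = 0, hap_fraction = 0.5,
                          balanced = FALSE, variants = NULL) {
  withr::with_seed(seed, {
    if (n_fragments == 0L)
      return(empty_sim_reads())
    pl <- place_fragments(diploid, n_fragments, read_len, insert_mean,
                          insert_sd, hap_fraction, balanced)
    frag <- substring(diploid$contigs[pl$contig], pl$start,
                      pl$start + pl$insert - 1L)
    molecule <- ifelse(pl$top, frag, revcomp(frag))
    seq1 <- substring(molecule, 1L, read_len)
    seq2 <- revcomp(substring(molecule, nchar(molecule) - read_len + 1L,
                              nchar(molecule)))
    errd <- apply_seq_errors(c(seq1, seq2), error_rate)
    seq1 <- errd[seq_len(n_fragments)]
    seq2 <- errd[n_fragments + seq_len(n_fragments)]
    read_id <- sprintf("frag%06d", seq_len(n_fragments))
    truth <- build_truth(pl, read_len, diploid, variants, read_id)
    structure(list(
      reads = data.frame(read_id = read_id, seq1 = seq1, seq2 = seq2),
      truth = truth), class = "sim_reads")
  })
}

empty_sim_reads <- function() {
  structure(list(
    reads = data.frame(read_id = character(), seq1 = character(),
                       seq2 = character()),
    truth = data.frame(read_id = character(), hap = character(),
                       contig = character(), chrom = character(),
                       hap_start = integer(), hap_end = integer(),
                       ref_start = integer(), ref_end = integer(),
                       strand = character(), n_var = integer())),
    class = "sim_reads")
}

build_truth <- function(pl, read_len, diploid, variants, read_id) {
  si <- sequenced_intervals(pl, read_len, diploid)
  n_var <- if (is.null(variants)) rep(NA_integer_, nrow(pl)) else
    count_variant_overlap(si, variants)
  frag_proj <- do.call(rbind, lapply(split(seq_len(nrow(pl)), pl$contig),
    function(ix) {
      p <- project_intervals(pl$start[ix] - 1L,
                             pl$start[ix] + pl$insert[ix] - 1L,
                             diploid$refmaps[[pl$contig[ix[1]]]])
      data.frame(idx = ix, ref_start = p$ref_start, ref_end = p$ref_end)
    }))
  frag_proj <- frag_proj[order(frag_proj$idx), ]
  data.frame(
    read_id = read_id,
    hap = paste0("hap", pl$hap), contig = pl$contig, chrom = pl$chrom,
    hap_start = pl$start - 1L, hap_end = pl$start + pl$insert - 1L,
    ref_start = frag_proj$ref_start, ref_end = frag_proj$ref_end,
    strand = ifelse(pl$top, "+", "-"), n_var = n_var)
}

#' Simulate directional bisulfite (WGBS-style) paired-end fragments
#'
#' Fragments are placed as in [sim_fragments()]; per fragment, each CpG
#' whose informative base lies in the fragment draws a methylation state
#' from the Bernoulli rate of its allele and region, unmethylated
#' cytosines convert to thymine with probability `conversion_rate`, and
#' non-CpG cytosines always convert. Directional protocol: the molecule
#' is the originating strand, mate 1 its 5' end.
#'
#' @inheritParams sim_fragments
#' @param meth_regions Optional `data.frame(chrom, start, end,
#'   rate_hap1, rate_hap2)` in 0-based half-open reference coordinates;
#'   per-CpG rates are looked up by the CpG's reference position.
#' @param default_rates Named pair `c(hap1 = , hap2 = )` of CpG
#'   methylation rates outside `meth_regions`.
#' @param conversion_rate Bisulfite conversion probability of an
#'   unmethylated cytosine.
#' @return List of class `sim_reads` with additional element
#'   `meth_truth`: `data.frame(read_id, chrom, ref_pos, hap, meth,
#'   sequenced)` — one row per (fragment, CpG) with the drawn state and
#'   whether the informative base fell inside a sequenced read.
#' @export
sim_bisulfite <- function(diploid, seed, n_fragments, read_len = 100L,
                          insert_mean = 250L, insert_sd = 25L,
                          error_rate = 0, hap_fraction = 0.5,
                          balanced = FALSE, meth_regions = NULL,
                          default_rates = c(hap1 = 0.7, hap2 = 0.7),
                          conversion_rate = 1, variants = NULL) {
  stopifnot(all(default_rates >= 0 & default_rates <= 1))
  if (!is.null(meth_regions))
    stopifnot(all(meth_regions$rate_hap1 >= 0 & meth_regions$rate_hap1 <= 1),
              all(meth_regions$rate_hap2 >= 0 & meth_regions$rate_hap2 <= 1))
  withr::with_seed(seed, {
    if (n_fragments == 0L) {
      out <- empty_sim_reads()
      out$meth_truth <- data.frame(read_id = character(), chrom = character(),
                                   ref_pos = integer(), hap = character(),
                                   meth = logical(), sequenced = logical())
      return(out)
    }
    pl <- place_fragments(diploid, n_fragments, read_len, insert_mean,
                          insert_sd, hap_fraction, balanced)
    # per-contig lookups computed once: CpG positions, their projected
    # reference positions, and the per-haplotype methylation rate per site
    cpg_by_contig <- lapply(diploid$contigs, cpg_positions)
    site_info <- lapply(names(diploid$contigs), function(ct) {
      cpg <- cpg_by_contig[[ct]]
      rmap <- diploid$refmaps[[ct]]
      if (!length(cpg))
        return(list(cpg = cpg, ref_pos = integer(), exact = logical(),
                    rate = NULL, chrom = rmap$chrom))
      proj <- project_position(cpg - 1L, rmap)
      hap <- contig_haplotype(ct, diploid$hap_names)$hap
      list(cpg = cpg, ref_pos = proj$ref_pos,
           exact = proj$status == "exact",
           rate = site_meth_rate(rmap$chrom, proj$ref_pos, hap,
                                 meth_regions, default_rates),
           chrom = rmap$chrom)
    })
    names(site_info) <- names(diploid$contigs)
    read_id <- sprintf("frag%06d", seq_len(n_fragments))
    acc_frag <- vector("list", n_fragments)   # per-fragment site indices
    acc_meth <- vector("list", n_fragments)
    acc_seq <- vector("list", n_fragments)
    frag_all <- substring(diploid$contigs[pl$contig], pl$start,
                          pl$start + pl$insert - 1L)
    molecules <- frag_all
    molecules[!pl$top] <- revcomp(frag_all[!pl$top])
    T_BYTE <- charToRaw("T"); C_BYTE <- charToRaw("C")
    for (i in seq_len(n_fragments)) {
      ct <- pl$contig[i]
      fs <- pl$start[i]; fe <- fs + pl$insert[i] - 1L
      si <- site_info[[ct]]
      cpg <- si$cpg
      # informative base: the C (top molecule) or the G (bottom molecule)
      if (pl$top[i]) {
        idx <- (findInterval(fs - 1L, cpg) + 1L):findInterval(fe, cpg)
      } else {
        idx <- (findInterval(fs - 2L, cpg) + 1L):findInterval(fe - 1L, cpg)
      }
      if (!length(idx) || idx[1] > idx[length(idx)]) idx <- integer(0)
      sites <- cpg[idx]
      M <- fe - fs + 1L
      mol_pos <- if (pl$top[i]) sites - fs + 1L else fe - sites
      meth <- if (length(idx)) stats::runif(length(idx)) < si$rate[idx]
              else logical(0)
      # convert: all Cs in the molecule except methylated CpG Cs
      raw <- charToRaw(molecules[i])
      convertible <- setdiff(which(raw == C_BYTE), mol_pos[meth])
      if (conversion_rate < 1)
        convertible <- convertible[stats::runif(length(convertible)) <
                                     conversion_rate]
      raw[convertible] <- T_BYTE
      molecules[i] <- rawToChar(raw)
      if (length(idx)) {
        acc_frag[[i]] <- idx
        acc_meth[[i]] <- meth
        acc_seq[[i]] <- mol_pos <= read_len | mol_pos > M - read_len
      }
    }
    seq1 <- substring(molecules, 1L, read_len)
    M_all <- nchar(molecules)
    seq2 <- revcomp(substring(molecules, M_all - read_len + 1L, M_all))
    errd <- apply_seq_errors(c(seq1, seq2), error_rate)
    seq1 <- errd[seq_len(n_fragments)]
    seq2 <- errd[n_fragments + seq_len(n_fragments)]
    truth <- build_truth(pl, read_len, diploid, variants, read_id)
    n_per <- lengths(acc_frag)
    rows <- rep.int(seq_len(n_fragments), n_per)
    site_idx <- unlist(acc_frag, use.names = FALSE)
    if (length(rows)) {
      ct_rows <- pl$contig[rows]
      ref_pos_v <- integer(length(rows)); exact_v <- logical(length(rows))
      for (ct in unique(ct_rows)) {
        sel <- ct_rows == ct
        ref_pos_v[sel] <- site_info[[ct]]$ref_pos[site_idx[sel]]
        exact_v[sel] <- site_info[[ct]]$exact[site_idx[sel]]
      }
      meth_truth <- data.frame(
        read_id = read_id[rows],
        chrom = vapply(site_info, `[[`, character(1), "chrom")[ct_rows],
        ref_pos = ref_pos_v, exact = exact_v,
        hap = paste0("hap", pl$hap[rows]),
        meth = unlist(acc_meth, use.names = FALSE),
        sequenced = unlist(acc_seq, use.names = FALSE))
      rownames(meth_truth) <- NULL
    } else
      meth_truth <- data.frame(read_id = character(), chrom = character(),
                               ref_pos = integer(), exact = logical(),
                               hap = character(), meth = logical(),
                               sequenced = logical())
    structure(list(
      reads = data.frame(read_id = read_id, seq1 = seq1, seq2 = seq2),
      truth = truth, meth_truth = meth_truth), class = "sim_reads")
  })
}

site_meth_rate <- function(chrom, ref_pos, hap, meth_regions, default_rates) {
  rate <- rep(unname(default_rates[hap]), length(ref_pos))
  if (!is.null(meth_regions) && nrow(meth_regions)) {
    mr <- meth_regions[meth_regions$chrom == chrom, , drop = FALSE]
    col <- paste0("rate_hap", hap)
    for (j in seq_len(nrow(mr))) {
      inside <- ref_pos >= mr$start[j] & ref_pos < mr$end[j]
      rate[inside] <- mr[[col]][j]
    }
  }
  rate
}

#' Simulate enrichment-style (ChIP-like) paired-end fragments
#'
#' Fragment density is elevated in peaks: a fraction `background_rate` of
#' fragments is placed uniformly genome-wide (haplotype drawn 50/50), the
#' rest inside peaks chosen proportionally to length, with the haplotype
#' drawn from each peak's `allelic_ratio` (probability of haplotype 1).
#'
#' @inheritParams sim_fragments
#' @param peaks `data.frame(chrom, start, end, allelic_ratio)` in 0-based
#'   half-open reference coordinates; peaks must not overlap.
#' @param background_rate Fraction of fragments placed outside the peak
#'   model.
#' @return A `sim_reads` list; truth gains a `peak` column (peak row
#'   index or `NA` for background fragments).
#' @export
sim_enrichment <- function(diploid, seed, peaks, n_fragments,
                           background_rate = 0.2, read_len = 75L,
                           insert_mean = 200L, insert_sd = 20L,
                           error_rate = 0, variants = NULL) {
  stopifnot(all(peaks$allelic_ratio >= 0 & peaks$allelic_ratio <= 1))
  gr <- intervals_to_granges(peaks)
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L))
    stop("peaks must not overlap")
  withr::with_seed(seed, {
    in_peak <- stats::runif(n_fragments) >= background_rate
    peak_of <- rep(NA_integer_, n_fragments)
    peak_of[in_peak] <- sample(seq_len(nrow(peaks)), sum(in_peak),
                               replace = TRUE,
                               prob = peaks$end - peaks$start)
    hap <- ifelse(is.na(peak_of), stats::runif(n_fragments) < 0.5,
                  stats::runif(n_fragments) < peaks$allelic_ratio[peak_of])
    hap <- ifelse(hap, 1L, 2L)
    contig_len <- nchar(diploid$contigs)
    contig <- paste0(ifelse(is.na(peak_of),
                            sample(diploid$chroms, n_fragments, replace = TRUE),
                            peaks$chrom[peak_of]),
                     "_", diploid$hap_names[hap])
    ins <- pmax(read_len, as.integer(round(stats::rnorm(n_fragments,
                                                        insert_mean,
                                                        insert_sd))))
    ins <- pmin(ins, contig_len[contig])
    start <- integer(n_fragments)
    for (i in seq_len(n_fragments)) {
      if (is.na(peak_of[i])) {
        start[i] <- sample.int(contig_len[contig[i]] - ins[i] + 1L, 1L)
      } else {
        pk <- peaks[peak_of[i], ]
        rmap <- diploid$refmaps[[contig[i]]]
        h1 <- project_ref_position(pk$start, rmap)
        h2 <- project_ref_position(pk$end - 1L, rmap)
        lo <- max(1L, h1$hap_pos + 1L - ins[i] + 1L)
        hi <- min(contig_len[contig[i]] - ins[i] + 1L, h2$hap_pos + 1L)
        start[i] <- if (hi <= lo) lo else sample(lo:hi, 1L)
      }
    }
    pl <- data.frame(hap = hap,
                     chrom = sub("_[^_]*$", "", contig), contig = contig,
                     start = start, insert = ins,
                     top = stats::runif(n_fragments) < 0.5)
    frag <- substring(diploid$contigs[pl$contig], pl$start,
                      pl$start + pl$insert - 1L)
    molecule <- ifelse(pl$top, frag, revcomp(frag))
    seq1 <- substring(molecule, 1L, read_len)
    seq2 <- revcomp(substring(molecule, nchar(molecule) - read_len + 1L,
                              nchar(molecule)))
    errd <- apply_seq_errors(c(seq1, seq2), error_rate)
    read_id <- sprintf("frag%06d", seq_len(n_fragments))
    truth <- build_truth(pl, read_len, diploid, variants, read_id)
    truth$peak <- peak_of
    structure(list(
      reads = data.frame(read_id = read_id,
                         seq1 = errd[seq_len(n_fragments)],
                         seq2 = errd[n_fragments + seq_len(n_fragments)]),
      truth = truth), class = "sim_reads")
  })
}

#' Write paired reads as FASTQ
#'
#' Constant quality strings ("I"); qualities are not modelled.
#'
#' @param reads Read table (`read_id`, `seq1`, `seq2`).
#' @param path1,path2 Output FASTQ paths for mates 1 and 2.
#' @return Invisibly, `c(path1, path2)`.
#' @export
write_fastq <- function(reads, path1, path2 = NULL) {
  emit <- function(ids, seqs, path) {
    qual <- strrep("I", nchar(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  }
  emit(reads$read_id, reads$seq1, path1)
  if (!is.null(path2) && "seq2" %in% names(reads))
    emit(reads$read_id, reads$seq2, path2)
  invisible(c(path1, path2))
}

#' Read paired FASTQ written by [write_fastq()]
#'
#' @param path1,path2 FASTQ paths.
#' @return Read table (`read_id`, `seq1`[, `seq2`]).
#' @export
read_fastq <- function(path1, path2 = NULL) {
  parse1 <- function(path) {
    lines <- readLines(path)
    list(id = sub("^@", "", lines[seq(1L, length(lines), 4L)]),
         seq = lines[seq(2L, length(lines), 4L)])
  }
  r1 <- parse1(path1)
  out <- data.frame(read_id = r1$id, seq1 = r1$seq)
  if (!is.null(path2)) {
    r2 <- parse1(path2)
    stopifnot(identical(r1$id, r2$id))
    out$seq2 <- r2$seq
  }
  out
}

#' Write / read a simulation truth table
#'
#' Plain TSV round trip for truth tables.
#'
#' @param truth Truth `data.frame`.
#' @param path File path.
#' @return `path` / the truth `data.frame`.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}
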