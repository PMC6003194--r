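fake_placement <- function(read_id, contig, start, end, mm = 0L,
                           conv = "N") {
  data.table::data.table(
    read_id = read_id, contig = contig, start = start, end = end, mm = mm,
    conv = conv, r1_start = start, r1_end = start + 59L, r1_fwd = TRUE,
    r2_start = end - 59L, r2_end = end, r2_fwd = FALSE)
}

fake_genome <- function(len = 10000L) {
  list(hap_names = c("hap1", "hap2"),
       refmaps = list(chr1_hap1 = identity_refmap("chr1", "hap1", len),
                      chr1_hap2 = identity_refmap("chr1", "hap2", len)))
}

test_that("unique placements call the haplotype parsed from the contig suffix", {
  g <- fake_genome()
  calls <- classify_fragments(fake_placement("f1", "chr1_hap2", 101L, 300L),
                              g, read_ids = "f1")
  expect_equal(as.character(calls$call), "hap2")
  expect_equal(calls$chrom, "chr1")
  expect_equal(c(calls$ref_start, calls$ref_end), c(100L, 300L))
})

test_that("equally good placements on both haplotypes are non-allelic", {
  g <- fake_genome()
  pl <- rbind(fake_placement("f1", "chr1_hap1", 101L, 300L),
              fake_placement("f1", "chr1_hap2", 101L, 300L))
  calls <- classify_fragments(pl, g, read_ids = "f1")
  expect_equal(as.character(calls$call), "non_allelic")
  expect_equal(calls$n_best, 2L)
  # a placement strictly better on one haplotype wins back the call
  pl2 <- rbind(fake_placement("f1", "chr1_hap1", 101L, 300L, mm = 0L),
               fake_placement("f1", "chr1_hap2", 101L, 300L, mm = 1L))
  expect_equal(as.character(classify_fragments(pl2, g, "f1")$call), "hap1")
})

test_that("absent fragments are reported unaligned", {
  g <- fake_genome()
  calls <- classify_fragments(fake_placement("f1", "chr1_hap1", 1L, 200L),
                              g, read_ids = c("f1", "f2"))
  expect_equal(as.character(calls$call[calls$read_id == "f2"]), "unaligned")
})

test_that("unrecognised contig suffixes raise an error naming the contig", {
  g <- fake_genome()
  expect_error(classify_fragments(fake_placement("f1", "chr1_mystery",
                                                 1L, 200L), g, "f1"),
               "chr1_mystery")
})

test_that("mate rescue: a pair with one variant-spanning mate is fully called", {
  ref <- sim_reference(51, lengths = c(chr1 = 4000L))
  pos <- 1000L
  base <- substr(ref$seqs[["chr1"]], pos, pos)
  v <- variant_table("chr1", pos, base,
                     paste0(base, "ACGTAC"), 0, 1)   # hap2 insertion
  dg <- build_diploid(ref, v)
  # mate 1 spans the insertion; mate 2 sits 150 bp away in shared sequence
  hp <- project_ref_position(pos - 1L, dg$refmaps[["chr1_hap2"]])$hap_pos + 1L
  seq1 <- substring(dg$contigs[["chr1_hap2"]], hp - 25L, hp + 34L)
  seq2 <- revcomp(substring(dg$contigs[["chr1_hap2"]], hp + 100L, hp + 159L))
  pl <- align_fragments(data.frame(read_id = "pair1", seq1 = seq1,
                                   seq2 = seq2), dg, max_mismatch = 1)
  calls <- classify_fragments(pl, dg)
  expect_equal(as.character(calls$call), "hap2")
  # mate 2 alone is ambiguous between haplotypes
  pl2 <- align_fragments(data.frame(read_id = "m2", seq1 = seq2), dg,
                         max_mismatch = 1)
  expect_equal(as.character(classify_fragments(pl2, dg)$call), "non_allelic")
})

test_that("blacklisting removes overlapping allelic calls only", {
  g <- fake_genome()
  pl <- rbind(fake_placement("a", "chr1_hap1", 101L, 200L),
              fake_placement("b", "chr1_hap2", 501L, 600L),
              fake_placement("c", "chr1_hap1", 901L, 1000L),
              fake_placement("c", "chr1_hap2", 901L, 1000L))
  calls <- classify_fragments(pl, g, read_ids = c("a", "b", "c"))

  empty <- apply_blacklist(calls, data.frame(chrom = character(),
                                             start = integer(),
                                             end = integer()))
  expect_equal(empty$n_removed, 0L)
  expect_equal(nrow(empty$calls), 3L)

  bl <- data.frame(chrom = "chr1", start = 150L, end = 160L)
  res <- apply_blacklist(calls, bl)
  expect_equal(res$n_removed, 1L)
  expect_false("a" %in% res$calls$read_id)

  # non-allelic calls pass through even when overlapping
  bl2 <- data.frame(chrom = "chr1", start = 950L, end = 960L)
  res2 <- apply_blacklist(calls, bl2)
  expect_equal(res2$n_removed, 0L)
})

test_that("partitioning yields hap1/hap2/total streams with consistent counts", {
  g <- fake_genome()
  none <- classify_fragments(empty <- allelign:::empty_placements(), g,
                             read_ids = c("x", "y"))
  st0 <- partition_alignments(none)
  expect_equal(nrow(st0$hap1) + nrow(st0$hap2) + nrow(st0$total), 0L)

  pl <- rbind(fake_placement("a", "chr1_hap1", 101L, 200L),
              fake_placement("c", "chr1_hap1", 101L, 200L),
              fake_placement("c", "chr1_hap2", 101L, 200L))
  calls <- classify_fragments(pl, g, read_ids = c("a", "c"))
  st <- partition_alignments(calls)
  expect_equal(unname(st$counts[["hap1"]]), 1L)
  expect_equal(unname(st$counts[["non_allelic"]]), 1L)
  expect_equal(max(st$total$value), 2)
  expect_equal(max(st$hap1$value), 1)
  expect_equal(nrow(st$hap2), 0L)
})

test_that("allelic counts never exceed the total stream", {
  fx <- toy_diploid(seed = 61, len = 8000L)
  sim <- sim_fragments(fx$dg, 62, n_fragments = 500, read_len = 60,
                       insert_mean = 150, insert_sd = 10)
  calls <- classify_fragments(align_fragments(sim$reads, fx$dg), fx$dg)
  cnt <- table(calls$call)
  expect_lte(cnt[["hap1"]] + cnt[["hap2"]],
             sum(cnt[c("hap1", "hap2", "non_allelic")]))
  st <- partition_alignments(calls)
  expect_lte(sum(st$hap1$value * (st$hap1$end - st$hap1$start)) +
               sum(st$hap2$value * (st$hap2$end - st$hap2$start)),
             sum(st$total$value * (st$total$end - st$total$start)))
})
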