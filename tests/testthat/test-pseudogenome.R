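test_that("SNV substitution edits the base without splitting blocks", {
  v <- variant_table("chr1", 3, "G", "T", 0, 1)
  b <- build_haplotype("ACGTACGT", v, 2)
  expect_equal(b$seq, "ACTTACGT")
  expect_equal(b$refmap$blocks,
               data.frame(hap_start = 0L, ref_start = 0L, length = 8L))
  expect_equal(b$n_applied, 1L)
})

test_that("a deletion closes the block after the anchor base", {
  v <- variant_table("chr1", 2, "CG", "C", 0, 1)
  b <- build_haplotype("ACGTACGT", v, 2)
  expect_equal(b$seq, "ACTACGT")
  expect_equal(b$refmap$blocks,
               data.frame(hap_start = c(0L, 2L), ref_start = c(0L, 3L),
                          length = c(2L, 5L)))
})

test_that("an insertion opens a haplotype-axis gap after the anchor", {
  v <- variant_table("chr1", 5, "A", "AGG", 0, 1)
  b <- build_haplotype("ACGTACGT", v, 2)
  expect_equal(b$seq, "ACGTAGGCGT")
  expect_equal(b$refmap$blocks,
               data.frame(hap_start = c(0L, 7L), ref_start = c(0L, 5L),
                          length = c(5L, 3L)))
})

test_that("REF mismatches are skipped (or abort under strict)", {
  v <- variant_table("chr1", 3, "A", "T", 0, 1)  # reference has G at 3
  b <- build_haplotype("ACGTACGT", v, 2)
  expect_equal(b$seq, "ACGTACGT")
  expect_equal(b$n_skipped, 1L)
  expect_equal(b$skipped$reason, "ref_mismatch")
  expect_error(build_haplotype("ACGTACGT", v, 2, strict = TRUE),
               "REF mismatch")
})

test_that("overlapping variants are applied greedily left to right", {
  v <- variant_table(c("chr1", "chr1"), c(2, 3), c("CGT", "G"),
                     c("C", "A"), c(0, 0), c(1, 1))
  b <- build_haplotype("ACGTACGT", v, 2)
  expect_equal(b$seq, "ACACGT")   # deletion wins, SNV at 3 skipped
  expect_equal(b$n_applied, 1L)
  expect_equal(b$n_skipped, 1L)
  expect_equal(b$skipped$reason, "overlap")
})

test_that("a variant-free diploid yields two identical contigs", {
  ref <- sim_reference(2, lengths = c(chr1 = 1200L))
  dg <- build_diploid(ref, variant_table(character(), integer(),
                                         character(), character(),
                                         integer(), integer()))
  expect_named(dg$contigs, c("chr1_hap1", "chr1_hap2"))
  expect_identical(dg$contigs[["chr1_hap1"]], ref$seqs[["chr1"]])
  expect_identical(dg$contigs[["chr1_hap2"]], ref$seqs[["chr1"]])
  expect_equal(dg$refmaps[["chr1_hap2"]]$blocks$length, 1200L)
})

test_that("an insertion lengthens only the carrying haplotype", {
  ref <- sim_reference(3, lengths = c(chr1 = 1500L))
  pos <- 700L
  base <- substr(ref$seqs[["chr1"]], pos, pos)
  v <- variant_table("chr1", pos, base, paste0(base, "GG"), 0, 1)
  dg <- build_diploid(ref, v)
  expect_equal(nchar(dg$contigs[["chr1_hap1"]]), 1500L)
  expect_equal(nchar(dg$contigs[["chr1_hap2"]]), 1502L)
})

test_that("random builds equal the independent string-splicing oracle", {
  for (seed in c(11, 12, 13)) {
    ref <- sim_reference(seed, lengths = c(chr1 = 50000L))
    v <- sim_variants(ref, seed + 50, snv_per_kb = 1.2, indel_per_kb = 0.3)
    b <- build_haplotype(ref$seqs[["chr1"]], v, 2)
    expect_identical(b$seq, oracle_splice(ref$seqs[["chr1"]], v, 2))
    # net length bookkeeping
    applied <- v[!v$pos %in% b$skipped$pos, ]
    net <- sum(nchar(haplotype_allele(applied, 2)) - nchar(applied$ref))
    expect_equal(nchar(b$seq) - 50000L, net)
    # haplotype 1 is byte-identical to the reference in strain mode
    b1 <- build_haplotype(ref$seqs[["chr1"]], v, 1)
    expect_identical(b1$seq, ref$seqs[["chr1"]])
    # every applied SNV lands at its mapped haplotype position
    snv <- applied[nchar(applied$ref) == 1 & nchar(applied$alt) == 1, ]
    hp <- project_ref_position(snv$pos - 1L, b$refmap)
    expect_true(all(hp$status == "exact"))
    expect_identical(substring(b$seq, hp$hap_pos + 1L, hp$hap_pos + 1L),
                     snv$alt)
  }
})

test_that("duplicate chromosome names abort diploid construction", {
  expect_error(build_diploid(c(chr1 = "ACGT", chr1 = "ACGT"),
                             variant_table(character(), integer(),
                                           character(), character(),
                                           integer(), integer())),
               "duplicate")
})

test_that("refmaps round-trip exactly through their text format", {
  r <- identity_refmap("chr1", "hap1", 1000L)
  p <- tempfile(fileext = ".refmap")
  write_refmap(r, p)
  expect_true(isTRUE(all.equal(read_refmap(p), r)))

  r3 <- new_refmap("chr2", "cast", 107L,
                   data.frame(hap_start = c(0L, 12L, 40L),
                              ref_start = c(0L, 10L, 43L),
                              length = c(10L, 25L, 60L)))
  write_refmap(r3, p)
  expect_true(isTRUE(all.equal(read_refmap(p), r3)))

  set.seed(3)
  for (i in 1:300) {
    rr <- random_refmap(sample(1:30, 1))
    write_refmap(rr, p)
    expect_true(isTRUE(all.equal(read_refmap(p), rr)))
  }
})

test_that("malformed refmap files name the offending line", {
  p <- tempfile()
  writeLines(c("#refmap v1 chr1 hap1 100", "0\t0\t50", "bad\tline"), p)
  expect_error(read_refmap(p), "line 3")
  writeLines(c("not a refmap"), p)
  expect_error(read_refmap(p), "header")
})

test_that("a written diploid genome reads back identically", {
  fx <- toy_diploid(seed = 21, len = 3000L)
  dir <- tempfile()
  write_diploid(fx$dg, dir)
  dg2 <- read_diploid(dir)
  expect_identical(dg2$contigs, fx$dg$contigs)
  expect_true(isTRUE(all.equal(dg2$refmaps[["chr1_hap2"]],
                               fx$dg$refmaps[["chr1_hap2"]])))
})
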