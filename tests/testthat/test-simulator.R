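test_that("reference simulation is seed-reproducible and honours GC", {
  r1 <- sim_reference(1, lengths = c(chr1 = 2000L))
  r2 <- sim_reference(1, lengths = c(chr1 = 2000L))
  expect_identical(r1$seqs, r2$seqs)
  expect_false(identical(r1$seqs, sim_reference(2, lengths = c(chr1 = 2000L))$seqs))
  at_only <- sim_reference(3, lengths = c(chr1 = 2000L), gc = 0)
  expect_false(grepl("[CG]", at_only$seqs[["chr1"]]))
})

test_that("CpG islands are denser in CpGs than background", {
  for (seed in 1:20) {
    ref <- sim_reference(seed, lengths = c(chr1 = 12000L),
                         islands = list(n = 1, length = 1000,
                                        cpg_rate = 0.1))
    isl <- ref$islands
    seq <- ref$seqs[["chr1"]]
    p <- allelign:::cpg_positions(seq)
    in_isl <- sum(p > isl$start & p <= isl$end)
    out_len <- nchar(seq) - (isl$end - isl$start)
    dens_in <- in_isl / (isl$end - isl$start)
    dens_out <- (length(p) - in_isl) / out_len
    expect_gt(dens_in, dens_out)
  }
})

test_that("satellite decoys are exact tandem arrays", {
  ref <- sim_reference(9, lengths = c(chr1 = 10000L),
                       satellite = list(chrom = "chr1", unit_len = 20L,
                                        n_units = 50L, start = 4001L))
  sat <- ref$satellite
  arr <- substr(ref$seqs[["chr1"]], sat$start + 1L, sat$end)
  unit <- substr(arr, 1, 20)
  expect_equal(arr, strrep(unit, 50))
})

test_that("variant simulation matches requested densities and the reference", {
  ref <- sim_reference(30, lengths = c(chr1 = 50000L))
  v <- sim_variants(ref, 3, snv_per_kb = 2, indel_per_kb = 0.4)
  n_snv <- sum(nchar(v$ref) == 1 & nchar(v$alt) == 1)
  # Poisson count within 3 sigma of 100
  expect_lt(abs(n_snv - 100), 3 * sqrt(100) + 1)
  # every REF allele matches the reference sequence
  seen <- substring(ref$seqs[["chr1"]], v$pos, v$pos + nchar(v$ref) - 1L)
  expect_identical(toupper(seen), v$ref)
  # spans never overlap
  ends <- v$pos + nchar(v$ref) - 1L
  expect_true(all(v$pos[-1L] > ends[-length(ends)]))
  # zero rates give an empty set; exclusion zones are respected
  expect_equal(nrow(sim_variants(ref, 4, snv_per_kb = 0, indel_per_kb = 0)), 0L)
  excl <- data.frame(chrom = "chr1", start = 10000L, end = 40000L)
  ve <- sim_variants(ref, 5, snv_per_kb = 2, indel_per_kb = 0.4,
                     exclude = excl)
  expect_false(any(ve$pos > 10000L & ve$pos <= 40000L))
})

test_that("phased mode places variants on both haplotypes", {
  ref <- sim_reference(31, lengths = c(chr1 = 30000L))
  v <- sim_variants(ref, 6, snv_per_kb = 2, phased = TRUE)
  expect_gt(sum(v$a1 == 1L), 0L)
  expect_gt(sum(v$a2 == 1L), 0L)
  expect_true(all(v$a1 + v$a2 == 1L))
})

test_that("fragment haplotype draws follow the requested fraction", {
  fx <- toy_diploid(seed = 71, len = 10000L)
  sim <- sim_fragments(fx$dg, 2, n_fragments = 10000, read_len = 60,
                       insert_mean = 150, insert_sd = 10,
                       hap_fraction = 0.5)
  n1 <- sum(sim$truth$hap == "hap1")
  expect_lt(abs(n1 - 5000), 3 * sqrt(10000 * 0.25))
  # balanced mode is an exact split
  simb <- sim_fragments(fx$dg, 2, n_fragments = 1000, read_len = 60,
                        insert_mean = 150, insert_sd = 10, balanced = TRUE)
  expect_equal(sum(simb$truth$hap == "hap1"), 500L)
  # edge cases
  expect_equal(nrow(sim_fragments(fx$dg, 2, 0)$reads), 0L)
  expect_error(sim_fragments(fx$dg, 2, 10, read_len = 20000L,
                             insert_mean = 20000L), "exceeds")
})

test_that("simulated reads are byte-reproducible and truth-complete", {
  fx <- toy_diploid(seed = 72, len = 6000L)
  a <- sim_fragments(fx$dg, 5, 300, error_rate = 0.01, variants = fx$variants)
  b <- sim_fragments(fx$dg, 5, 300, error_rate = 0.01, variants = fx$variants)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), nrow(a$reads))
  expect_setequal(a$truth$read_id, a$reads$read_id)
})

test_that("error-free reads match their haplotype of origin exactly", {
  fx <- toy_diploid(seed = 73, len = 6000L)
  sim <- sim_fragments(fx$dg, 7, 100, read_len = 70, insert_mean = 160,
                       insert_sd = 10)
  tr <- sim$truth
  for (i in seq_len(50)) {
    contig <- fx$dg$contigs[[tr$contig[i]]]
    frag <- substring(contig, tr$hap_start[i] + 1L, tr$hap_end[i])
    mol <- if (tr$strand[i] == "+") frag else revcomp(frag)
    expect_identical(sim$reads$seq1[i], substring(mol, 1, 70))
    expect_identical(sim$reads$seq2[i],
                     revcomp(substring(mol, nchar(mol) - 69L, nchar(mol))))
  }
})

test_that("bisulfite conversion follows the drawn methylation states", {
  fx <- toy_diploid(seed = 74, len = 6000L, snv_per_kb = 3)
  # rate 1: no CpG converts; all other Cs convert
  all_m <- sim_bisulfite(fx$dg, 17, 50, read_len = 80, insert_mean = 180,
                         insert_sd = 10,
                         default_rates = c(hap1 = 1, hap2 = 1))
  expect_true(all(all_m$meth_truth$meth))
  # rate 0: every CpG C converts; reads carry no C except CpG->TG artefacts
  none_m <- sim_bisulfite(fx$dg, 17, 50, read_len = 80, insert_mean = 180,
                          insert_sd = 10,
                          default_rates = c(hap1 = 0, hap2 = 0))
  expect_false(any(none_m$meth_truth$meth))
  # reconstruct one molecule and verify base-level conversion
  tr <- all_m$truth[1, ]
  contig <- fx$dg$contigs[[tr$contig]]
  frag <- substring(contig, tr$hap_start + 1L, tr$hap_end)
  mol <- if (tr$strand == "+") frag else revcomp(frag)
  read1 <- all_m$reads$seq1[1]
  cpg_in_mol <- gregexpr("CG", mol, fixed = TRUE)[[1]]
  conv <- chartr("C", "T", mol)
  for (p in cpg_in_mol) if (p > 0) substr(conv, p, p) <- "C"
  expect_identical(read1, substring(conv, 1, 80))
})

test_that("drawn methylation rates match the requested Bernoulli rates", {
  ref <- sim_reference(75, lengths = c(chr1 = 9000L),
                       islands = list(n = 1, length = 800, cpg_rate = 0.08))
  dg <- build_diploid(ref, variant_table(character(), integer(),
                                         character(), character(),
                                         integer(), integer()))
  sim <- sim_bisulfite(dg, 17, 800, read_len = 80, insert_mean = 180,
                       insert_sd = 10,
                       default_rates = c(hap1 = 0.7, hap2 = 0.7))
  mt <- sim$meth_truth
  expect_gt(nrow(mt), 1000L)
  phat <- mean(mt$meth)
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / nrow(mt)))
  # per-region rates override the default
  gdmr <- data.frame(chrom = "chr1", start = ref$islands$start,
                     end = ref$islands$end, rate_hap1 = 0, rate_hap2 = 1)
  sim2 <- sim_bisulfite(dg, 18, 800, read_len = 80, insert_mean = 180,
                        insert_sd = 10, meth_regions = gdmr,
                        default_rates = c(hap1 = 0.5, hap2 = 0.5))
  mt2 <- sim2$meth_truth
  in_r <- mt2$ref_pos >= gdmr$start & mt2$ref_pos < gdmr$end
  expect_false(any(mt2$meth[in_r & mt2$hap == "hap1"]))
  expect_true(all(mt2$meth[in_r & mt2$hap == "hap2"]))
})

test_that("enrichment fragments follow peak ratios and background rate", {
  fx <- toy_diploid(seed = 76, len = 20000L)
  peaks <- data.frame(chrom = "chr1", start = c(3000L, 12000L),
                      end = c(3600L, 12600L), allelic_ratio = c(1.0, 0.5))
  sim <- sim_enrichment(fx$dg, 5, peaks, n_fragments = 2000,
                        background_rate = 0.2)
  tr <- sim$truth
  # all fragments of the ratio-1 peak derive from haplotype 1
  expect_true(all(tr$hap[tr$peak == 1 & !is.na(tr$peak)] == "hap1"))
  # the balanced peak splits within 3 sigma
  p2 <- tr[!is.na(tr$peak) & tr$peak == 2, ]
  expect_lt(abs(mean(p2$hap == "hap1") - 0.5), 3 * sqrt(0.25 / nrow(p2)))
  # background fraction near the requested rate
  expect_lt(abs(mean(is.na(tr$peak)) - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
  # background 0: everything lands in a peak
  sim0 <- sim_enrichment(fx$dg, 6, peaks, 300, background_rate = 0)
  expect_false(any(is.na(sim0$truth$peak)))
  over <- data.frame(chrom = "chr1", start = c(100L, 200L),
                     end = c(300L, 400L), allelic_ratio = 0.5)
  expect_error(sim_enrichment(fx$dg, 7, over, 10), "overlap")
})

test_that("FASTQ and truth tables round-trip through disk", {
  fx <- toy_diploid(seed = 77, len = 4000L)
  sim <- sim_fragments(fx$dg, 8, 50, variants = fx$variants)
  p1 <- tempfile(fileext = ".fq"); p2 <- tempfile(fileext = ".fq")
  write_fastq(sim$reads, p1, p2)
  back <- read_fastq(p1, p2)
  expect_equal(back, sim$reads)
  pt <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, pt)
  expect_equal(read_truth(pt), sim$truth)
})

test_that("simulate-align-classify recovers nearly all variant-spanning fragments", {
  fx <- toy_diploid(seed = 78, len = 20000L, snv_per_kb = 4, indel_per_kb = 1)
  sim <- sim_fragments(fx$dg, 2, 2000, read_len = 75, insert_mean = 180,
                       insert_sd = 15, variants = fx$variants)
  calls <- classify_fragments(align_fragments(sim$reads, fx$dg), fx$dg)
  m <- merge(as.data.frame(calls), sim$truth, by = "read_id")
  wrong <- (m$call == "hap1" & m$hap == "hap2") |
           (m$call == "hap2" & m$hap == "hap1")
  expect_equal(sum(wrong), 0L)
  informative <- m$n_var >= 1L
  expect_gte(mean(m$call[informative] %in% c("hap1", "hap2")), 0.99)
})
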