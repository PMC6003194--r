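# A 60 bp contig with CpGs at C positions 11 and 31 (1-based).
meth_contig <- paste0(strrep("A", 10), "CG", strrep("T", 18), "CG",
                      strrep("A", 28))

test_that("strand rules: C/T at the CpG C on OT, G/A at the CpG G on OB", {
  # OT read covering both CpGs: methylated at 11 (C kept), unmethylated
  # at 31 (C converted to T)
  ot <- paste0(strrep("A", 10), "CG", strrep("T", 18), "TG", strrep("A", 8))
  calls <- call_read_methylation(ot, 1L, "CT", meth_contig)
  expect_equal(calls$hap_pos, c(11L, 31L))
  expect_equal(calls$state, c("meth", "unmeth"))

  # OB read observes the G of the CpG: G = methylated, A = unmethylated
  ob <- paste0(strrep("A", 10), "CG", strrep("T", 18), "CA", strrep("A", 8))
  calls_ob <- call_read_methylation(ob, 1L, "GA", meth_contig)
  expect_equal(calls_ob$hap_pos, c(11L, 31L))
  expect_equal(calls_ob$state, c("meth", "unmeth"))

  # any other base is ambiguous
  odd <- paste0(strrep("A", 10), "GG", strrep("T", 48))
  expect_equal(call_read_methylation(odd, 1L, "CT", meth_contig)$state[1],
               "ambiguous")
  expect_error(call_read_methylation(strrep("A", 80), 1L, "CT", meth_contig),
               "past contig end")
  expect_error(call_read_methylation(ot, 1L, "N", meth_contig), "bisulfite")
})

test_that("aggregation accumulates counts per site and allele", {
  mc <- data.table::data.table(
    read_id = sprintf("r%d", 1:5),
    call = c("hap1", "hap1", "hap1", "hap1", "non_allelic"),
    contig = "chr1_hap1",
    hap_pos = 11L,
    state = c("meth", "meth", "meth", "unmeth", "meth"))
  refmaps <- list(chr1_hap1 = identity_refmap("chr1", "hap1", 60L))
  tab <- aggregate_cpg_counts(mc, refmaps)
  h1 <- tab[tab$allele == "hap1", ]
  expect_equal(c(h1$n_meth, h1$n_unmeth), c(3L, 1L))
  expect_equal(h1$level, 75)
  expect_equal(h1$ref_pos, 10L)
  tot <- tab[tab$allele == "total", ]
  expect_equal(tot$n_meth + tot$n_unmeth, 5L)
  # per-site total counts at least hap1 + hap2 counts
  expect_gte(tot$n_meth + tot$n_unmeth, h1$n_meth + h1$n_unmeth)
})

test_that("CpGs inside haplotype-specific insertions are dropped on projection", {
  rmap <- new_refmap("chr1", "hap2", 20L,
                     data.frame(hap_start = c(0L, 10L),
                                ref_start = c(0L, 5L),
                                length = c(5L, 10L)))
  mc <- data.table::data.table(
    read_id = c("r1", "r2"), call = "hap2", contig = "chr1_hap2",
    hap_pos = c(7L, 12L),    # 7 is inside the insertion gap [5, 10)
    state = "meth")
  tab <- aggregate_cpg_counts(mc, list(chr1_hap2 = rmap))
  expect_equal(nrow(tab[tab$allele == "hap2", ]), 1L)
  expect_equal(tab$ref_pos[tab$allele == "hap2"], 6L)
})

test_that("a CpG destroyed on one haplotype receives no calls for it", {
  ref_seq <- paste0(strrep("A", 40), "CG", strrep("T", 38))
  v <- variant_table("chr1", 41, "C", "A", 0, 1)   # destroys the CpG on hap2
  dg <- build_diploid(list(seqs = c(chr1 = ref_seq)), v)
  reads <- data.frame(read_id = "r1",
                      seq1 = chartr("C", "T", substring(
                        dg$contigs[["chr1_hap2"]], 21L, 60L)))
  pl <- align_fragments(reads, dg, max_mismatch = 0, bisulfite = TRUE, k = 10)
  calls <- classify_fragments(pl, dg)
  expect_equal(as.character(calls$call), "hap2")
  mc <- extract_methylation(calls, reads, dg)
  expect_equal(nrow(mc), 0L)   # no CpG exists on hap2
})

test_that("informative-CpG filtering matches a brute-force row scan", {
  set.seed(4)
  tab <- data.table::data.table(
    chrom = "chr1", ref_pos = rep(1:50, each = 2),
    allele = rep(c("hap1", "hap2"), 50),
    n_meth = sample(0:6, 100, replace = TRUE),
    n_unmeth = sample(0:6, 100, replace = TRUE))
  tab$level <- 100 * tab$n_meth / (tab$n_meth + tab$n_unmeth)
  kept <- informative_cpgs(tab, min_cov = 5)
  manual <- tab[tab$n_meth + tab$n_unmeth >= 5, ]
  expect_equal(as.data.frame(kept), as.data.frame(manual),
               ignore_attr = TRUE)
  expect_error(informative_cpgs(tab, min_cov = 0), "min_cov")
  # boundary: coverage 4 dropped, 5 kept
  small <- data.table::data.table(chrom = "chr1", ref_pos = c(1L, 2L),
                                  allele = "hap1", n_meth = c(2L, 3L),
                                  n_unmeth = c(2L, 2L), level = 50)
  expect_equal(informative_cpgs(small, 5)$ref_pos, 2L)
})

test_that("region summaries use unweighted per-CpG means and NA when empty", {
  tab <- data.table::data.table(
    chrom = "chr1", ref_pos = c(10L, 20L, 10L, 20L),
    allele = c("hap1", "hap1", "total", "total"),
    n_meth = c(0L, 10L, 5L, 10L), n_unmeth = c(10L, 0L, 5L, 0L))
  tab$level <- 100 * tab$n_meth / (tab$n_meth + tab$n_unmeth)
  regions <- data.frame(chrom = "chr1", start = c(0L, 100L),
                        end = c(50L, 200L), name = c("covered", "empty"))
  rs <- region_methylation(tab, regions, min_cov = 5)
  expect_equal(rs$hap1_n_cpg, c(2L, 0L))
  expect_equal(rs$hap1_mean_meth_pct, c(50, NA))
  expect_equal(rs$total_mean_meth_pct[1], 75)
  expect_warning(
    region_methylation(tab, data.frame(chrom = "chrZ", start = 0L,
                                       end = 10L)), "unknown chromosome")
})

test_that("overlapping mates contribute one observation per CpG", {
  contigs <- c(chr1_hap1 = meth_contig)
  g <- list(contigs = contigs, hap_names = c("hap1", "hap2"),
            refmaps = list(chr1_hap1 = identity_refmap("chr1", "hap1", 60L)))
  # both mates fully overlap hap positions 1..40 (CpGs at 11 and 31)
  calls <- data.table::data.table(
    read_id = "r1", call = factor("hap1", levels = allelign:::CALL_LEVELS),
    chrom = "chr1", ref_start = 0L, ref_end = 40L, contig = "chr1_hap1",
    start = 1L, end = 40L, mm = 0L, n_best = 1L, conv = "CT",
    r1_start = 1L, r1_end = 40L, r1_fwd = TRUE,
    r2_start = 1L, r2_end = 40L, r2_fwd = FALSE)
  ot <- substr(meth_contig, 1, 40)
  reads <- data.frame(read_id = "r1", seq1 = ot, seq2 = revcomp(ot))
  mc <- extract_methylation(calls, reads, g)
  expect_equal(nrow(mc), 2L)   # each CpG once, not twice
})

test_that("methylation levels recover simulated allele-specific rates", {
  ref <- sim_reference(81, lengths = c(chr1 = 8000L),
                       islands = list(n = 1, length = 600, cpg_rate = 0.1))
  v <- sim_variants(ref, 82, snv_per_kb = 6, indel_per_kb = 1)
  dg <- build_diploid(ref, v)
  sim <- sim_bisulfite(dg, 17, n_fragments = 1500, read_len = 80,
                       insert_mean = 170, insert_sd = 15,
                       default_rates = c(hap1 = 0.9, hap2 = 0.1),
                       variants = v)
  calls <- classify_fragments(
    align_fragments(sim$reads, dg, bisulfite = TRUE), dg)
  tab <- aggregate_cpg_counts(extract_methylation(calls, sim$reads, dg),
                              dg$refmaps)
  inf <- informative_cpgs(tab, min_cov = 10)
  h1 <- inf[inf$allele == "hap1", ]
  h2 <- inf[inf$allele == "hap2", ]
  expect_gt(nrow(h1), 20L)
  expect_gt(mean(h1$level), 80)
  expect_lt(mean(h2$level), 20)
  expect_true(all(tab$level >= 0 & tab$level <= 100))
})
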