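test_that("mapping-quality filter discards strictly-below-threshold pairs only", {
  p <- rbind(pair_row("a", "chr1", 100, "+", "chr1", 600, "-", mapq1 = 45,
                      mapq2 = 29),
             pair_row("b", "chr1", 100, "+", "chr1", 600, "-", mapq1 = 30,
                      mapq2 = 30),
             pair_row("c", "chr1", 100, "+", "chr1", 600, "-", mapq1 = 60,
                      mapq2 = 60))
  fm <- filter_mapq(p, 30)
  expect_setequal(fm$kept$pair_id, c("b", "c"))
  expect_equal(fm$discarded$pair_id, "a")
  e <- filter_mapq(p[0, ], 30)
  expect_equal(nrow(e$kept), 0)
  expect_equal(nrow(e$discarded), 0)
})

test_that("duplicate removal handles exact and offset copies and is idempotent", {
  base <- pair_row("p1", "chr1", 1000, "+", "chr1", 1500, "-")
  exact <- pair_row("p1_copy", "chr1", 1000, "+", "chr1", 1500, "-")
  off2 <- pair_row("p2_off", "chr1", 1002, "+", "chr1", 1500, "-")
  off3 <- pair_row("p3_far", "chr1", 1003, "+", "chr1", 1500, "-")
  # exact duplicate: one retained, smallest id wins the tie
  d <- remove_duplicates(rbind(base, exact))
  expect_equal(d$unique$pair_id, "p1")
  # offset by 2 bp on one end: duplicate
  d2 <- remove_duplicates(rbind(base, off2))
  expect_equal(nrow(d2$unique), 1)
  # offset by 3 bp: both retained
  d3 <- remove_duplicates(rbind(base, off3))
  expect_equal(nrow(d3$unique), 2)
  # highest summed mapq retained
  hi <- pair_row("p9_hi", "chr1", 1001, "+", "chr1", 1501, "-",
                 mapq1 = 60, mapq2 = 60)
  lo <- pair_row("p0_lo", "chr1", 1000, "+", "chr1", 1500, "-",
                 mapq1 = 35, mapq2 = 35)
  expect_equal(remove_duplicates(rbind(lo, hi))$unique$pair_id, "p9_hi")
  # idempotent
  all4 <- rbind(base, exact, off2, off3)
  once <- remove_duplicates(all4)$unique
  twice <- remove_duplicates(once)$unique
  expect_identical(once, twice)
})

test_that("injected PCR duplicates are fully recalled without removing true pairs", {
  ref <- tiny_ref()
  der <- plant_rearrangements(ref, list(), ploidy = 2)
  lib <- pe_lib(4000)
  clean <- simulate_read_pairs(der, lib, seed = 21)
  dirty <- simulate_read_pairs(der, lib, dup_rate = 0.05,
                               offset_dup_rate = 0.05, seed = 21)
  expect_gt(nrow(dirty), nrow(clean))
  dd <- remove_duplicates(dirty)
  # every injected duplicate removed
  expect_false(any(grepl("_dup", dd$unique$pair_id)))
  # surviving set identical to deduplicating the clean run
  expect_setequal(dd$unique$pair_id, remove_duplicates(clean)$unique$pair_id)
})

test_that("pair classification applies contig, orientation and span rules", {
  lib <- pe_lib()
  p <- rbind(
    pair_row("norm", "chr1", 1000, "+", "chr1", 1503, "-"),      # span 504
    pair_row("xchrom", "chr1", 1000, "+", "chr2", 1503, "-"),
    pair_row("farspan", "chr1", 1000, "+", "chr1", 5999, "-"),   # span 5000
    pair_row("ffpair", "chr1", 1000, "+", "chr1", 1503, "+"),
    pair_row("min_edge", "chr1", 1000, "+", "chr1", 1403, "-"),  # span 404
    pair_row("max_edge", "chr1", 1000, "+", "chr1", 1618, "-"),  # span 619
    pair_row("under", "chr1", 1000, "+", "chr1", 1402, "-"))     # span 403
  cl <- classify_pairs(p, lib)
  expect_equal(cl$class,
               c("normal", "aberrant", "aberrant", "aberrant",
                 "normal", "normal", "aberrant"))
})

test_that("realignment recheck discards pairs with a concordant alternative placement", {
  # build a reference with read2's sequence present both at the reported
  # (distant) locus and 490 bp from the mate
  set.seed(1)
  s <- random_dna(5000)
  x <- random_dna(36)
  r1 <- substr(s, 1001, 1036)                 # read1 at 0-based 1000, "+"
  substr(s, 1455, 1490) <- x                  # alternative placement
  substr(s, 3955, 3990) <- x                  # reported placement
  ref <- ref_genome(c(chr1 = s))
  lib <- pe_lib()
  p <- pair_row("homolog", "chr1", 1000, "+", "chr1", 3989, "-")
  p$seq1 <- r1
  p$seq2 <- svfuse:::revcomp(x)  # read bases of a minus-strand alignment
  rc <- realignment_recheck(p, ref, lib)
  expect_equal(rc$discarded_normal_recheck$pair_id, "homolog")
  expect_equal(nrow(rc$kept), 0)

  # a genuine junction pair in unique sequence is kept
  s2 <- random_dna(5000)
  ref2 <- ref_genome(c(chr1 = s2, chr2 = random_dna(5000)))
  q <- pair_row("real", "chr1", 1000, "+", "chr2", 2000, "-")
  q$seq1 <- substr(s2, 1001, 1036)
  q$seq2 <- svfuse:::revcomp(substr(unclass(ref2)[["chr2"]], 1966, 2001))
  rc2 <- realignment_recheck(q, ref2, lib)
  expect_equal(rc2$kept$pair_id, "real")

  # empty input, and sequence-free input, degrade gracefully
  e <- realignment_recheck(p[0, ], ref, lib)
  expect_equal(nrow(e$kept), 0)
  noseq <- pair_row("x", "chr1", 1000, "+", "chr1", 3989, "-")
  expect_warning(rc3 <- realignment_recheck(noseq, ref, lib), "skipped")
  expect_equal(nrow(rc3$kept), 1)
})

test_that("the filter cascade partitions its input exactly once per pair", {
  ref <- tiny_ref()
  der <- plant_rearrangements(
    ref, list(sv_deletion("chr1", 40000, 80000, "del1")), ploidy = 2)
  lib <- pe_lib(8000)
  rep_iv <- data.frame(chrom = "chr2", start = 10000, end = 20000)
  p <- simulate_read_pairs(der, lib, dup_rate = 0.03, offset_dup_rate = 0.02,
                           chimera_rate = 0.002, repeats = rep_iv, seed = 9)
  fc <- filter_cascade(p, lib)
  n_out <- nrow(fc$normal) + nrow(fc$aberrant) + nrow(fc$discarded_lowmapq) +
    nrow(fc$discarded_duplicate) + nrow(fc$discarded_normal_recheck)
  expect_equal(n_out, nrow(p))
  ids <- c(fc$normal$pair_id, fc$aberrant$pair_id, fc$discarded_lowmapq$pair_id,
           fc$discarded_duplicate$pair_id, fc$discarded_normal_recheck$pair_id)
  expect_equal(anyDuplicated(ids), 0L)
  expect_gt(nrow(fc$discarded_lowmapq), 0)
  expect_gt(nrow(fc$discarded_duplicate), 0)
})
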