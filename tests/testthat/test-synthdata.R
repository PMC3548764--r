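test_that("reference generation honours lengths, seed determinism and bounds", {
  ref <- generate_reference(2, c(10000, 8000), gc = 0.41, seed = 7)
  expect_equal(unname(nchar(unclass(ref))), c(10000, 8000))
  ref2 <- generate_reference(2, c(10000, 8000), gc = 0.41, seed = 7)
  expect_identical(unclass(ref), unclass(ref2))
  ref3 <- generate_reference(2, c(10000, 8000), gc = 0.41, seed = 8)
  expect_false(identical(unclass(ref), unclass(ref3)))
  expect_error(generate_reference(1, c(1000), gc = 0, seed = 1),
               class = "svfuse_parameter_error")
  expect_error(generate_reference(1, c(-5), gc = 0.5, seed = 1),
               class = "svfuse_parameter_error")
  # GC content roughly as requested
  gc_frac <- mean(strsplit(unclass(ref)[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_frac - 0.41), 0.03)
})

test_that("gene generation places non-overlapping multi-exon genes on both strands", {
  ref <- tiny_ref()
  genes <- generate_genes(ref, 20, c(2, 10), seed = 1)
  expect_length(genes, 20)
  tab <- svfuse:::gene_table(genes)
  expect_true(all(tab$n_exons >= 2))
  expect_setequal(unique(tab$strand), c("+", "-"))
  for (chrom in unique(tab$chrom)) {
    t2 <- tab[tab$chrom == chrom, ]
    t2 <- t2[order(t2$start), ]
    if (nrow(t2) > 1) expect_true(all(t2$start[-1] >= t2$end[-nrow(t2)]))
  }
  # impossible request: many genes on a tiny contig
  small <- generate_reference(1, 5000, gc = 0.5, seed = 1)
  expect_error(generate_genes(small, 40, c(8, 10), seed = 1),
               class = "svfuse_placement_error")
})

test_that("derived exon phases satisfy cumulative CDS arithmetic (brute-force oracle)", {
  ref <- tiny_ref()
  genes <- generate_genes(ref, 15, c(2, 9), seed = 3)
  for (g in genes) {
    expect_equal(exon_phases(g), oracle_phases(g), info = g$gene_id)
  }
  # minus-strand hand-built gene too
  g <- make_gene("m1", "chr1", "-", 1000, c(100, 130, 95), c(500, 700),
                 utr5 = 25, utr3 = 40)
  expect_equal(exon_phases(g), oracle_phases(g))
})

test_that("planting a deletion yields one truth junction joining the flanks", {
  der <- tiny_deletion_der(start = 40000, end = 200000 - 0.2e5)
  tr <- der$truth
  expect_equal(nrow(tr), 1)
  expect_equal(tr$pos_a, 40000)
  expect_equal(tr$side_a, "left_retained")
  expect_equal(tr$pos_b, 180000)
  expect_equal(tr$side_b, "right_retained")
  # realized derivative sequence is exactly flank + flank
  s <- derivative_sequence(der, "del1")
  ref <- der$ref
  expect_identical(s, paste0(svfuse:::ref_subseq(ref, "chr1", 0, 40000),
                             svfuse:::ref_subseq(ref, "chr1", 180000, 200000)))
})

test_that("amplicon planting emits one truth junction per fragment adjacency at its copy number", {
  ref <- tiny_ref()
  frs <- data.frame(chrom = c("chr1", "chr2", "chr1", "chr2", "chr1", "chr2"),
                    start = c(10000, 30000, 60000, 70000, 120000, 110000),
                    end = c(25000, 45000, 75000, 85000, 135000, 125000),
                    strand = "+")
  der <- plant_rearrangements(ref, list(sv_amplicon(frs, 20, "amp")), ploidy = 2)
  expect_equal(nrow(der$truth), 5)
  expect_true(all(der$truth$copy_number == 20))
  # total copy number over a fragment equals the planted copy number
  cn <- der$cn_map
  hit <- cn[cn$chrom == "chr1" & cn$start <= 15000 & cn$end > 15000, ]
  expect_equal(hit$cn, 20)
})

test_that("shard insertions are carried into the truth and derivative sequence", {
  ref <- tiny_ref()
  ev <- sv_deletion("chr1", 40000, 70000, "del1",
                    inserts = list("1" = list(shard = c("chr2", 5000, 5015))))
  der <- plant_rearrangements(ref, list(ev), ploidy = 2)
  expect_equal(nchar(der$truth$inserted_seq), 15)
  expect_identical(der$truth$inserted_seq,
                   svfuse:::ref_subseq(ref, "chr2", 5000, 5015))
  expect_equal(der$truth$microhomology_len, 0L)
  s <- derivative_sequence(der, "del1")
  expect_identical(substr(s, 40001, 40015), der$truth$inserted_seq)
})

test_that("over-consuming events on one chromosome raise a conflict error", {
  ref <- tiny_ref()
  evs <- list(sv_deletion("chr1", 10000, 30000, "d1"),
              sv_deletion("chr1", 50000, 80000, "d2"),
              sv_deletion("chr1", 100000, 130000, "d3"))
  expect_error(plant_rearrangements(ref, evs, ploidy = 2),
               class = "svfuse_conflict_error")
})

test_that("pairs from an unrearranged genome are all concordant with library geometry", {
  ref <- tiny_ref()
  der <- plant_rearrangements(ref, list(), ploidy = 2)
  lib <- pe_lib(5000)
  p <- simulate_read_pairs(der, lib, seed = 11)
  cl <- classify_pairs(p, lib)
  expect_true(all(cl$class == "normal"))
  span <- p$pos2 - p$pos1 + 1
  expect_true(all(span >= 404 & span <= 619))
  expect_true(all(p$strand1 == "+" & p$strand2 == "-"))
  # deterministic per seed
  p2 <- simulate_read_pairs(der, lib, seed = 11)
  expect_identical(p, p2)
})

test_that("without artifact injection no two pairs share both 5' coordinates and strands", {
  ref <- tiny_ref()
  der <- plant_rearrangements(ref, list(), ploidy = 2)
  p <- simulate_read_pairs(der, pe_lib(2000), dup_rate = 0,
                           chimera_rate = 0, seed = 5)
  key <- paste(p$chrom1, p$pos1, p$strand1, p$chrom2, p$pos2, p$strand2)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("read depth at junctions scales with copy number (binomial oracle over replicates)", {
  ref <- generate_reference(3, c(120000, 120000, 120000), gc = 0.41, seed = 2,
                            names = c("d1", "amp", "spare"))
  evs <- list(
    sv_deletion("d1", 30000, 60000, "del1"),
    sv_amplicon(data.frame(chrom = "amp", start = c(10000, 60000),
                           end = c(30000, 80000), strand = "+"),
                copy_number = 20, event_id = "amp1"))
  der <- plant_rearrangements(ref, evs, ploidy = 2)
  lib <- pe_lib(3000)
  tr <- der$truth
  n_rep <- 200
  sup <- matrix(0, n_rep, nrow(tr))
  for (r in seq_len(n_rep)) {
    p <- simulate_read_pairs(der, lib, seed = 1000 + r)
    cl <- classify_pairs(p, lib)
    ab <- cl[cl$class == "aberrant", ]
    for (i in seq_len(nrow(tr))) {
      sup[r, i] <- sum(ab$chrom1 == tr$chrom_a[i] & ab$chrom2 == tr$chrom_b[i] &
                       abs(ab$pos1 - tr$pos_a[i]) <= lib$frag_max &
                       abs(ab$pos2 - tr$pos_b[i]) <= lib$frag_max)
    }
  }
  m1 <- mean(sup[, tr$copy_number == 1])
  m20 <- mean(sup[, tr$copy_number == 20])
  ratio <- m20 / m1
  se_ratio <- ratio * sqrt(1 / sum(sup[, tr$copy_number == 1]) +
                           1 / sum(sup[, tr$copy_number == 20]))
  expect_lt(abs(ratio - 20), 3 * se_ratio)
})

test_that("noiseless probe profiles reproduce log copy ratios and step locations exactly", {
  der <- tiny_deletion_der(start = 40000, end = 120000)
  prof <- simulate_cgh(der, probe_spacing = 2000, noise_sd = 0, seed = 1)
  p1 <- prof[prof$chrom == "chr1", ]
  in_del <- p1$pos >= 40000 & p1$pos < 120000
  expect_true(all(p1$log2_ratio[!in_del] == 0))
  expect_true(all(p1$log2_ratio[in_del] == log2(1 / 2)))
  expect_true(all(prof$log2_ratio[prof$chrom == "chr2"] == 0))
  # copy-20 amplicon on baseline 2: probes exactly log2(10)
  ref <- tiny_ref()
  der2 <- plant_rearrangements(ref, list(
    sv_amplicon(data.frame(chrom = "chr1", start = c(20000, 80000),
                           end = c(50000, 110000), strand = "+"), 20, "amp")),
    ploidy = 2)
  prof2 <- simulate_cgh(der2, probe_spacing = 2000, noise_sd = 0, seed = 1)
  inside <- prof2$chrom == "chr1" & prof2$pos >= 20000 & prof2$pos < 50000
  expect_true(all(prof2$log2_ratio[inside] == log2(10)))
  # noiseless steps localise truth breakpoints to within one probe spacing
  segs <- segment_profile(prof, step_threshold = 0.3, min_probes = 5)
  steps <- detect_steps(segs)
  expect_equal(nrow(steps), 2)
  expect_true(all(abs(svfuse:::interval_mid(steps$start, steps$end) -
                      c(40000, 120000)) <= 2000))
})

test_that("panel of normals reflects planted polymorphisms and stays off tumour truth", {
  ref <- tiny_ref()
  expect_equal(nrow(build_panel_of_normals(ref, 18, 0, seed = 1)), 0)
  ev <- sv_deletion("chr1", 30000, 90000, "poly1")
  pan <- build_panel_of_normals(ref, 18, 0, events = list(ev), seed = 1)
  expect_equal(pan$pos1, 30000)
  expect_equal(pan$pos2, 90000)
  expect_equal(pan$n_samples_seen, 18)
  # disjoint seeds: random panel junctions never coincide with tumour truth
  pan2 <- build_panel_of_normals(ref, 18, 0.5, seed = 99)
  tum <- tiny_deletion_der()$truth
  if (nrow(pan2)) {
    expect_false(any(pan2$chrom1 == tum$chrom_a & pan2$pos1 == tum$pos_a &
                     pan2$pos2 == tum$pos_b))
  }
})
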