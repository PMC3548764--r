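test_that("genes at breakpoints include overlapping and downstream intact genes", {
  g1 <- make_gene("G1", "chrA", "+", 10000, c(150, 150), c(4000))
  g2 <- make_gene("G2", "chrA", "+", 300000, c(150, 150, 150), c(2000, 2000))
  genes <- structure(list(g1, g2), class = "gene_set")
  # breakend inside intron 1 of G1
  j <- list(id = "J1", chrom_a = "chrA", pos_a = 12000, side_a = "left_retained",
            chrom_b = "chrA", pos_b = 100000, side_b = "right_retained")
  gb <- genes_at_breakpoints(j, genes)
  expect_equal(gb$overlap_a, "G1")
  expect_length(gb$overlap_b, 0)
  # G2 is 200 kb downstream of breakend b on the retained strand
  expect_equal(gb$adjacent_b, "G2")
  # gene desert: empty window
  j2 <- list(id = "J2", chrom_a = "chrA", pos_a = 600000,
             side_a = "left_retained", chrom_b = "chrA", pos_b = 800000,
             side_b = "right_retained")
  gb2 <- genes_at_breakpoints(j2, genes, runthrough_window = 50000)
  expect_length(gb2$overlap_a, 0)
  expect_length(gb2$adjacent_b, 0)
})

test_that("direct fusions join donor 5' ends to broken acceptor 3' ends", {
  donor <- make_gene("TIAM1_like", "chrA", "+", 10000, c(200, 150), c(8000),
                     utr5 = 50)
  acceptor <- make_gene("NRIP1_like", "chrA", "+", 200000, c(150, 150, 150),
                        c(3000, 2000), utr5 = 30)
  genes <- structure(list(donor, acceptor), class = "gene_set")
  # deletion joining intron 1 of the donor to intron 1 of the acceptor
  j <- list(id = "J1", chrom_a = "chrA", pos_a = 12000, side_a = "left_retained",
            chrom_b = "chrA", pos_b = 201000, side_b = "right_retained")
  res <- predict_fusion(j, genes)
  expect_equal(nrow(res$fusions), 1)
  f <- res$fusions
  expect_equal(f$five_prime_gene, "TIAM1_like")
  expect_equal(f$five_prime_exon, 1L)
  expect_equal(f$three_prime_gene, "NRIP1_like")
  expect_equal(f$three_prime_exon, 2L)
  expect_equal(f$kind, "direct")
  expect_equal(f$frame, "in_frame")  # both phases 0 by construction
  expect_equal(nrow(res$breaks), 0)
})

test_that("run-through fusions splice into the first acceptor of an intact downstream gene", {
  donor <- make_gene("TIMM23_like", "chrA", "+", 10000,
                     c(120, 90, 90, 90, 90, 90, 150), rep(1500, 6), utr5 = 60)
  intact <- make_gene("ARHGAP32_like", "chrB", "+", 70000, c(100, 140, 160),
                      c(2000, 2000), utr5 = 41)
  far <- make_gene("FAR_like", "chrB", "+", 400000, c(100, 100), c(1000))
  genes <- structure(list(donor, intact, far), class = "gene_set")
  pos_a <- donor$exons[6, 2] + 700  # intron 6
  j <- list(id = "J1", chrom_a = "chrA", pos_a = pos_a, side_a = "left_retained",
            chrom_b = "chrB", pos_b = 20000, side_b = "right_retained")
  res <- predict_fusion(j, genes)
  f <- res$fusions
  expect_equal(nrow(f), 1)
  expect_equal(f$kind, "runthrough")
  expect_equal(f$five_prime_exon, 6L)
  expect_equal(f$three_prime_gene, "ARHGAP32_like")  # nearest partner
  expect_equal(f$three_prime_exon, 2L)
  expect_equal(f$frame, "out_of_frame")
  expect_equal(f$alternatives, "FAR_like")  # farther partner listed
})

test_that("junctions retaining two 5' ends fuse nothing and emit gene breaks", {
  g1 <- make_gene("L1", "chrA", "+", 10000, c(150, 150), c(4000))
  g2 <- make_gene("L2", "chrB", "+", 10000, c(150, 150), c(4000))
  genes <- structure(list(g1, g2), class = "gene_set")
  # both sides left_retained: both genes donate 5' ends, no transcript can cross
  j <- list(id = "J1", chrom_a = "chrA", pos_a = 12000, side_a = "left_retained",
            chrom_b = "chrB", pos_b = 12000, side_b = "left_retained")
  res <- predict_fusion(j, genes)
  expect_equal(nrow(res$fusions), 0)
  expect_equal(nrow(res$breaks), 2)
  expect_setequal(res$breaks$retained_end, "five_prime")
})

test_that("frame calls follow cumulative CDS phase arithmetic", {
  d <- svfuse:::bank_gene("D", "cX", "+", 5000, 5)
  a0 <- svfuse:::bank_gene("A0", "cX", "+", 50000, 4)            # phase 0
  a2 <- svfuse:::bank_gene("A2", "cX", "+", 90000, 4, utr5 = 31) # phase 2
  nc <- make_gene("NC", "cX", "+", 5000, c(100, 100), c(500), utr5 = NA)
  expect_equal(svfuse:::fusion_frame(d, 3, a0, 2), "in_frame")
  expect_equal(svfuse:::fusion_frame(d, 3, a2, 2), "out_of_frame")
  expect_equal(svfuse:::fusion_frame(d, 3, nc, 2), "indeterminate")
  # a gene fused to itself at the same intron is in frame
  expect_equal(svfuse:::fusion_frame(d, 2, d, 3), "in_frame")
})

test_that("frame calls agree with a translated-CDS oracle near the junction", {
  translate_str <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }
  # donor exon content is alanine codons; the acceptor's leading sequence
  # contains stops in both shifted frames but none in its own frame
  acc_seq <- paste0("CTAACTGAC", strrep("GCT", 20))
  mk <- function(id, exon_lens, utr5 = 0) {
    make_gene(id, "cO", "+", 1000, exon_lens,
              rep(500, length(exon_lens) - 1), utr5 = utr5, utr3 = 0)
  }
  donor_in <- mk("Din", c(9, 9))     # exon 1 ends at phase 0
  donor_out <- mk("Dout", c(10, 9))  # exon 1 ends at phase 1
  acc <- mk("Acc", c(9, nchar(acc_seq)))  # exon 2 starts at phase 0
  donor_cds <- function(n) strrep("GCT", ceiling(n / 3)) |> substr(1, n)
  for (case in list(list(d = donor_in, len = 9, expect = "in_frame"),
                    list(d = donor_out, len = 10, expect = "out_of_frame"))) {
    frame <- svfuse:::fusion_frame(case$d, 1, acc, 2)
    expect_equal(frame, case$expect)
    fused <- paste0(donor_cds(case$len), acc_seq)
    aa <- translate_str(substr(fused, 1, 3 * (nchar(fused) %/% 3)))
    junction_codon <- ceiling(case$len / 3)
    near <- substr(aa, 1, junction_codon + 3)
    if (frame == "in_frame") {
      expect_false(grepl("\\*", near))
    } else {
      expect_true(grepl("\\*", near))
    }
  }
})

test_that("multi-junction transcripts are traced across insert segments", {
  bank <- fusion_topology_bank()
  case <- bank[[1]]  # donor | anonymous insert | acceptor entered mid-gene
  got <- trace_multi_junction_transcript(case$path, case$genes)
  expect_equal(got$junction_ids, "J1,J2")
  expect_equal(got$five_prime_exon, case$expected$five_prime_exon)
  expect_equal(got$three_prime_exon, case$expected$three_prime_exon)
  # single-junction path reduces to predict_fusion
  g1 <- make_gene("P1", "cA", "+", 10000, c(150, 150), c(4000))
  g2 <- make_gene("P2", "cB", "+", 20000, c(150, 150, 150), c(2000, 2000))
  genes <- structure(list(g1, g2), class = "gene_set")
  path <- data.frame(chrom = c("cA", "cB"), start = c(0, 21500),
                     end = c(12000, 60000), strand = "+")
  traced <- trace_multi_junction_transcript(path, genes,
                                            junction_ids = "J1")
  direct <- predict_fusion(list(id = "J1", chrom_a = "cA", pos_a = 12000,
                                side_a = "left_retained", chrom_b = "cB",
                                pos_b = 21500, side_b = "right_retained"),
                           genes)$fusions
  expect_equal(traced[, names(direct)], direct)
  # an orientation flip in the acceptor segment disrupts splicing
  flipped <- path
  flipped$strand[2] <- "-"
  expect_null(trace_multi_junction_transcript(flipped, genes))
  # cyclic paths are rejected
  cyc <- rbind(path, path[1, ])
  expect_error(trace_multi_junction_transcript(cyc, genes),
               class = "svfuse_input_error")
})

test_that("all twelve fixture-bank fusion topologies are predicted exactly", {
  res <- evaluate_topology_bank()
  expect_equal(nrow(res), 12)
  expect_true(all(res$matched), info = paste(res$name[!res$matched],
                                             collapse = ", "))
})
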