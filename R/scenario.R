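# Packaged simulation scenarios: a desk-scale tumour-genome analogue used
# by the examples and the end-to-end tests, a coverage-calibrated
# detection experiment, and a synthetic fixture bank of fusion topologies.

# Total sampleable derivative genome size (bp, copy-weighted); the
# denominator for per-copy physical coverage on simulated data.
genome_weight <- function(der) {
  w <- sum(vapply(der$contigs, function(ct) ct$length * ct$copy, numeric(1)))
  b <- der$baseline
  w + sum((b$end - b$start) * b$copy)
}

#' Desk-scale demonstration scenario
#'
#' A five-contig, 4 Mb genome analogue of a heavily rearranged,
#' coamplified breast-cancer genome: a six-fragment coamplification of
#' two contigs at copy number 20 (with a 20 bp genomic shard at one
#' junction and a direct fusion gene pair at another), a 160 kb
#' interstitial deletion fusing two genes in their first introns, an
#' unbalanced translocation producing a run-through fusion into an intact
#' downstream gene, and a balanced 200 kb inversion. Fusion-relevant
#' genes are placed by hand so the expected fusion calls (partners,
#' retained exons, frame) are known; filler genes are placed randomly
#' away from the planted breakpoints.
#'
#' @param seed Integer seed driving every random choice.
#' @return List: `ref`, `genes`, `events`, `der`, `libs`,
#'   `expected_fusions`.
#' @export
demo_scenario <- function(seed = 1) {
  ref <- generate_reference(
    5, c(1000000, 900000, 800000, 600000, 700000), gc = 0.41, seed = seed,
    names = c("chr8a", "chr17a", "chr10a", "chr11a", "chr21a"))

  hand <- list(
    make_gene("AMP5_like", "chr8a", "+", 128000, c(150, 150), c(3000),
              utr5 = 30, utr3 = 30),
    make_gene("AMP3_like", "chr17a", "+", 198500, c(150, 150, 200),
              c(2500, 2000), utr5 = 30, utr3 = 30),
    make_gene("TIMM23_like", "chr10a", "+", 700000,
              c(120, 90, 90, 90, 90, 90, 150), rep(1500, 6),
              utr5 = 60, utr3 = 30),
    make_gene("ARHGAP32_like", "chr11a", "+", 70000, c(100, 140, 160),
              c(2000, 2000), utr5 = 41, utr3 = 30),
    make_gene("TIAM1_like", "chr21a", "+", 150000, c(200, 150, 180, 150),
              c(8000, 2000, 2000), utr5 = 50, utr3 = 30),
    make_gene("NRIP1_like", "chr21a", "+", 312000, c(150, 150, 150),
              c(3000, 2000), utr5 = 30, utr3 = 30))

  avoid <- data.frame(
    chrom = c("chr8a", "chr8a", "chr8a", "chr17a", "chr17a", "chr17a",
              "chr10a", "chr11a", "chr21a", "chr21a", "chr21a", "chr21a",
              "chr21a"),
    start = c(95000, 295000, 445000, 195000, 395000, 515000,
              695000, 15000, 145000, 305000, 445000, 645000, 595000),
    end = c(135000, 335000, 485000, 235000, 435000, 555000,
            800000, 75000, 165000, 320000, 455000, 655000, 605000))
  filler <- generate_genes(ref, 24, c(2, 8), seed = seed + 1, avoid = avoid)
  genes <- structure(c(hand, filler), class = "gene_set")

  events <- list(
    sv_amplicon(data.frame(
      chrom = c("chr8a", "chr17a", "chr8a", "chr17a", "chr8a", "chr17a"),
      start = c(100000, 200000, 300000, 400000, 450000, 520000),
      end = c(130000, 230000, 330000, 430000, 480000, 550000),
      strand = "+"), copy_number = 20, event_id = "amp1",
      inserts = list("4" = list(shard = c("chr21a", 600000, 600020)))),
    sv_deletion("chr21a", 154200, 314200, "del1"),
    sv_translocation("chr10a", 708800, "chr11a", 20000, "t1"),
    sv_inversion("chr21a", 450000, 650000, "inv1"))

  der <- plant_rearrangements(ref, events, ploidy = 2)

  libs <- list(
    pe500 = library_spec("pe500", read_length = 36, frag_median = 504,
                         frag_min = 404, frag_max = 619, n_pairs = 150000),
    mp3k = library_spec("mp3k", read_length = 36, frag_median = 3000,
                        frag_min = 2500, frag_max = 3600, n_pairs = 40000))

  expected_fusions <- data.frame(
    five_prime_gene = c("AMP5_like", "TIAM1_like", "TIMM23_like"),
    five_prime_exon = c(1L, 1L, 6L),
    three_prime_gene = c("AMP3_like", "NRIP1_like", "ARHGAP32_like"),
    three_prime_exon = c(2L, 2L, 2L),
    kind = c("direct", "direct", "runthrough"),
    frame = c("in_frame", "in_frame", "out_of_frame"))

  list(ref = ref, genes = genes, events = events, der = der, libs = libs,
       expected_fusions = expected_fusions)
}

#' Predict fusions for every candidate in a set
#'
#' @param candidates Candidate data frame (confirmed set recommended).
#' @param genes A `gene_set`.
#' @param runthrough_window Downstream window (bp).
#' @return List with stacked `fusions` and `breaks` data frames.
#' @export
predict_fusions_all <- function(candidates, genes, runthrough_window = 1e6) {
  fus <- list(); brk <- list()
  for (i in seq_len(nrow(candidates))) {
    p <- predict_fusion(candidates[i, ], genes, runthrough_window)
    if (nrow(p$fusions)) fus[[length(fus) + 1L]] <- p$fusions
    if (nrow(p$breaks)) brk[[length(brk) + 1L]] <- p$breaks
  }
  list(fusions = if (length(fus)) do.call(rbind, fus) else empty_fusions(),
       breaks = if (length(brk)) do.call(rbind, brk) else empty_breaks())
}

#' Run the demonstration scenario end to end
#'
#' Simulates the read libraries and the probe profile, runs the calling
#' pipeline, predicts fusions from the confirmed candidates and compares
#' against the simulator truth. Artifact rates default to zero; turn them
#' on to exercise the duplicate and chimera filters.
#'
#' @param seed Integer seed.
#' @param scenario Optional pre-built [demo_scenario()] output.
#' @param dup_rate,offset_dup_rate,chimera_rate Artifact rates.
#' @param outdir Optional directory: when given, writes FASTA, GFF3,
#'   pairs TSV, probe TSV, truth BEDPE, candidate BEDPE, the fusion
#'   report and a JSON run report.
#' @return List: `scenario`, `pairs`, `profile`, `call` (pipeline
#'   output), `fusions`, `sensitivity`, `recovered_expected`.
#' @export
run_demo <- function(seed = 1, scenario = NULL, dup_rate = 0,
                     offset_dup_rate = 0, chimera_rate = 0, outdir = NULL) {
  sc <- scenario %||% demo_scenario(seed)
  pairs <- rbind(
    simulate_read_pairs(sc$der, sc$libs$pe500, dup_rate, offset_dup_rate,
                        chimera_rate, seed = seed + 2),
    simulate_read_pairs(sc$der, sc$libs$mp3k, dup_rate, offset_dup_rate,
                        chimera_rate, seed = seed + 3))
  profile <- simulate_cgh(sc$der, probe_spacing = 5000, noise_sd = 0.1,
                          seed = seed + 4)
  call <- call_pipeline(pairs, sc$libs, cn_profile = profile)
  confirmed <- call$candidates[call$candidates$confirmation != "unconfirmed", ,
                               drop = FALSE]
  fus <- predict_fusions_all(confirmed, sc$genes)
  sens <- sensitivity_report(sc$der$truth, call$candidates,
                             amplified_threshold = 5, match_tol = 3600)
  exp <- sc$expected_fusions
  got <- fus$fusions
  recovered <- vapply(seq_len(nrow(exp)), function(i) {
    any(got$five_prime_gene == exp$five_prime_gene[i] &
        got$three_prime_gene == exp$three_prime_gene[i] &
        got$five_prime_exon == exp$five_prime_exon[i] &
        got$three_prime_exon == exp$three_prime_exon[i] &
        got$kind == exp$kind[i] & got$frame == exp$frame[i])
  }, logical(1))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sc$ref, file.path(outdir, "reference.fa"))
    write_gff3(sc$genes, file.path(outdir, "genes.gff3"))
    write_pairs(pairs, file.path(outdir, "pairs.tsv"))
    write_probes(profile, file.path(outdir, "cn_probes.tsv"))
    write_truth(sc$der$truth, file.path(outdir, "truth.bedpe"),
                seeds = list(seed = seed))
    write_bedpe(call$candidates, file.path(outdir, "candidates.bedpe"))
    utils::write.table(fus$fusions, file.path(outdir, "fusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_report(call$report, file.path(outdir, "run_report.json"))
  }
  list(scenario = sc, pairs = pairs, profile = profile, call = call,
       fusions = fus, sensitivity = sens, recovered_expected = recovered)
}

#' Coverage-calibrated junction-detection experiment
#'
#' Replicated simulations at a fixed per-copy physical coverage
#' (default 1.7-fold): a genome carrying eight single-copy deletion
#' junctions and a four-fragment amplicon at copy number 20 is sequenced
#' with a single short-insert library whose pair count is set so that
#' `n_pairs * frag_median / genome_weight` equals `coverage_fold`. Per
#' replicate, each truth junction's surviving supporting pairs are
#' counted and clustering is run; a junction is detected when a cluster
#' of at least two consistent pairs matches it. Empirical single-copy
#' detection can then be compared with the Poisson model
#' [detection_probability()] at the realized per-copy supporting-pair
#' rate.
#'
#' @param n_reps Number of replicate libraries.
#' @param seed Integer seed.
#' @param coverage_fold Target per-copy physical coverage.
#' @return List: `per_junction` (data frame `rep`, `junction_id`,
#'   `copy_number`, `support`, `detected`), `lambda_realized` (mean
#'   supporting pairs per copy-1 junction), `detection_copy1`,
#'   `detection_copy20`, `model_copy1` (Poisson tail at the realized
#'   rate), `n_pairs_per_rep`.
#' @export
detection_experiment <- function(n_reps = 20, seed = 1, coverage_fold = 1.7) {
  ref <- generate_reference(5, c(rep(300000, 4), 400000), gc = 0.41,
                            seed = seed,
                            names = c(paste0("d", 1:4), "amp"))
  events <- list()
  for (k in 1:4) {
    events[[length(events) + 1L]] <-
      sv_deletion(paste0("d", k), 40000, 70000, sprintf("delA%d", k))
    events[[length(events) + 1L]] <-
      sv_deletion(paste0("d", k), 150000, 190000, sprintf("delB%d", k))
  }
  events[[length(events) + 1L]] <- sv_amplicon(
    data.frame(chrom = "amp",
               start = c(30000, 100000, 200000, 300000),
               end = c(60000, 130000, 230000, 330000), strand = "+"),
    copy_number = 20, event_id = "amp1")
  der <- plant_rearrangements(ref, events, ploidy = 2)
  G <- genome_weight(der)
  n_pairs <- round(coverage_fold * G / 504)
  lib <- library_spec("pe500", 36, 504, 404, 619, n_pairs = n_pairs)

  truth <- der$truth
  rows <- list()
  for (r in seq_len(n_reps)) {
    pairs <- simulate_read_pairs(der, lib, seed = seed + 101 * r)
    cl <- classify_pairs(pairs, lib)
    ab <- cl[cl$class == "aberrant", , drop = FALSE]
    cands <- cluster_pairs(ab, lib, min_support = 2)
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      near <- ab$chrom1 == tr$chrom_a & ab$chrom2 == tr$chrom_b &
        abs(ab$pos1 - tr$pos_a) <= lib$frag_max &
        abs(ab$pos2 - tr$pos_b) <= lib$frag_max
      nearswap <- ab$chrom1 == tr$chrom_b & ab$chrom2 == tr$chrom_a &
        abs(ab$pos1 - tr$pos_b) <= lib$frag_max &
        abs(ab$pos2 - tr$pos_a) <= lib$frag_max
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, junction_id = tr$junction_id,
        copy_number = tr$copy_number,
        support = sum(near | nearswap),
        detected = truth_matched(tr, cands, lib$frag_max))
    }
  }
  pj <- do.call(rbind, rows)
  c1 <- pj[pj$copy_number == 1, ]
  c20 <- pj[pj$copy_number >= 20, ]
  lambda1 <- mean(c1$support)
  list(per_junction = pj,
       lambda_realized = lambda1,
       detection_copy1 = mean(c1$detected),
       detection_copy20 = mean(c20$detected),
       model_copy1 = detection_probability(lambda1, 1, 2),
       n_pairs_per_rep = n_pairs)
}

# --- synthetic fixture bank of fusion topologies -------------------------

bank_gene <- function(id, chrom, strand, start, n_ex, exlen = 120,
                      intron = 2000, utr5 = 30, utr3 = 30) {
  make_gene(id, chrom, strand, start, rep(exlen, n_ex),
            rep(intron, max(0, n_ex - 1)), utr5 = utr5, utr3 = utr3)
}

# Genomic position 500 bp into the intron following transcription-order
# exon k.
intron_break <- function(g, k, offset = 500) {
  if (g$strand == "+") g$exons[k, 2] + offset
  else g$exons[n_exons(g) - k + 1, 1] - offset
}

direct_junction <- function(donor, d_intron, acceptor, a_intron, id = "J1") {
  list(id = id,
       chrom_a = donor$chrom, pos_a = intron_break(donor, d_intron),
       side_a = if (donor$strand == "+") "left_retained" else "right_retained",
       chrom_b = acceptor$chrom, pos_b = intron_break(acceptor, a_intron),
       side_b = if (acceptor$strand == "+") "right_retained" else "left_retained")
}

#' Synthetic fixture bank of expressed-fusion topologies
#'
#' Twelve synthetic gene-pair fixtures reproducing the topology classes
#' reported for expressed fusions in a coamplified breast-cancer genome:
#' direct fusions (in frame, out of frame, and with a 5'-UTR breakpoint of
#' indeterminate frame), run-through fusions into an intact downstream
#' gene (in and out of frame, on both strands), and fusions transcribed
#' across more than one genomic junction (an anonymous insert segment
#' between donor and acceptor). Gene names carry a `_like` suffix: these
#' are synthetic analogues constructed to match each topology (partner
#' order, retained exons, kind, frame), not the real loci.
#'
#' @return List of cases; each has `name`, `genes`, and either `junction`
#'   (for [predict_fusion()]) or `path` (for
#'   [trace_multi_junction_transcript()]), plus an `expected` one-row data
#'   frame (`five_prime_gene`, `five_prime_exon`, `three_prime_gene`,
#'   `three_prime_exon`, `kind`, `frame`).
#' @export
fusion_topology_bank <- function() {
  cases <- list()
  add <- function(name, genes, expected, junction = NULL, path = NULL) {
    cases[[length(cases) + 1L]] <<- list(
      name = name, genes = structure(genes, class = "gene_set"),
      junction = junction, path = path, expected = expected)
  }
  exp_row <- function(five, fex, three, tex, kind, frame) {
    data.frame(five_prime_gene = five, five_prime_exon = as.integer(fex),
               three_prime_gene = three, three_prime_exon = as.integer(tex),
               kind = kind, frame = frame)
  }

  # 1. multi-junction direct fusion with a 10.4 kb anonymous insert
  A <- bank_gene("APPBP2_like", "c1", "+", 10000, 10)
  B <- bank_gene("PHF20L1_like", "c2", "+", 50000, 5)
  add("APPBP2_like-PHF20L1_like", list(A, B),
      exp_row("APPBP2_like", 9, "PHF20L1_like", 3, "direct", "in_frame"),
      path = data.frame(
        chrom = c("c1", "c3", "c2"),
        start = c(0, 1000, intron_break(B, 2)),
        end = c(intron_break(A, 9), 11400, 100000),
        strand = "+"))

  # 2. direct, in frame, exon 2 :: exon 5
  D <- bank_gene("COL14A1_like", "c4", "+", 10000, 6)
  Acc <- bank_gene("SKAP1_like", "c5", "+", 20000, 6)
  add("COL14A1_like-SKAP1_like", list(D, Acc),
      exp_row("COL14A1_like", 2, "SKAP1_like", 5, "direct", "in_frame"),
      junction = direct_junction(D, 2, Acc, 4))

  # 3. direct, in frame
  D <- bank_gene("TAOK1_like", "c6", "+", 10000, 9)
  Acc <- bank_gene("PCGF2_like", "c7", "+", 20000, 4)
  add("TAOK1_like-PCGF2_like", list(D, Acc),
      exp_row("TAOK1_like", 8, "PCGF2_like", 2, "direct", "in_frame"),
      junction = direct_junction(D, 8, Acc, 1))

  # 4. direct, out of frame (acceptor CDS phase shifted)
  D <- bank_gene("USP32_like", "c8", "+", 10000, 5)
  Acc <- bank_gene("CCDC49_like", "c9", "+", 20000, 4, utr5 = 31)
  add("USP32_like-CCDC49_like", list(D, Acc),
      exp_row("USP32_like", 3, "CCDC49_like", 2, "direct", "out_of_frame"),
      junction = direct_junction(D, 3, Acc, 1))

  # 5. direct, frame indeterminate: donor broken within its 5' UTR
  D <- bank_gene("BCAS3_like", "c10", "+", 10000, 8, utr5 = 150)
  Acc <- bank_gene("HOXB9_like", "c11", "+", 20000, 3)
  add("BCAS3_like-HOXB9_like", list(D, Acc),
      exp_row("BCAS3_like", 1, "HOXB9_like", 2, "direct", "indeterminate"),
      junction = direct_junction(D, 1, Acc, 1))

  # 6. run-through, in frame, exon 3 :: exon 2
  D <- bank_gene("TRPS1_like", "c12", "+", 10000, 5)
  Acc <- bank_gene("LASP1_like", "c13", "+", 40000, 4)
  add("TRPS1_like-LASP1_like", list(D, Acc),
      exp_row("TRPS1_like", 3, "LASP1_like", 2, "runthrough", "in_frame"),
      junction = list(id = "J1", chrom_a = "c12",
                      pos_a = intron_break(D, 3), side_a = "left_retained",
                      chrom_b = "c13", pos_b = 5000,
                      side_b = "right_retained"))

  # 7. run-through, out of frame, minus-strand donor and acceptor
  D <- bank_gene("ERBB2_like", "c14", "-", 50000, 6)
  Acc <- bank_gene("BCAS3b_like", "c15", "-", 10000, 7, utr5 = 31)
  add("ERBB2_like-BCAS3b_like", list(D, Acc),
      exp_row("ERBB2_like", 4, "BCAS3b_like", 2, "runthrough", "out_of_frame"),
      junction = list(id = "J1", chrom_a = "c14",
                      pos_a = intron_break(D, 4), side_a = "right_retained",
                      chrom_b = "c15", pos_b = 40000,
                      side_b = "left_retained"))

  # 8. run-through, in frame
  D <- bank_gene("DDX5_like", "c16", "+", 10000, 8)
  Acc <- bank_gene("DEPDC_like", "c17", "+", 80000, 5)
  add("DDX5_like-DEPDC_like", list(D, Acc),
      exp_row("DDX5_like", 5, "DEPDC_like", 2, "runthrough", "in_frame"),
      junction = list(id = "J1", chrom_a = "c16",
                      pos_a = intron_break(D, 5), side_a = "left_retained",
                      chrom_b = "c17", pos_b = 30000,
                      side_b = "right_retained"))

  # 9. direct fusion across two genomic junctions
  D <- bank_gene("PLEC1_like", "c18", "+", 10000, 12)
  Acc <- bank_gene("ENPP2_like", "c20", "+", 20000, 6)
  add("PLEC1_like-ENPP2_like", list(D, Acc),
      exp_row("PLEC1_like", 8, "ENPP2_like", 2, "direct", "in_frame"),
      path = data.frame(
        chrom = c("c18", "c19", "c20"),
        start = c(0, 2000, intron_break(Acc, 1)),
        end = c(intron_break(D, 8), 8000, 60000),
        strand = "+"))

  # 10. direct, in frame, exon 1 :: exon 2
  D <- bank_gene("TIAM1b_like", "c21", "+", 10000, 3)
  Acc <- bank_gene("NRIP1b_like", "c22", "+", 20000, 4)
  add("TIAM1b_like-NRIP1b_like", list(D, Acc),
      exp_row("TIAM1b_like", 1, "NRIP1b_like", 2, "direct", "in_frame"),
      junction = direct_junction(D, 1, Acc, 1))

  # 11. direct, out of frame, late donor exon (exon 26)
  D <- bank_gene("ZMYM4_like", "c23", "+", 5000, 27)
  Acc <- bank_gene("OPRD1_like", "c24", "+", 10000, 3, utr5 = 31)
  add("ZMYM4_like-OPRD1_like", list(D, Acc),
      exp_row("ZMYM4_like", 26, "OPRD1_like", 2, "direct", "out_of_frame"),
      junction = direct_junction(D, 26, Acc, 1))

  # 12. run-through, out of frame
  D <- bank_gene("TIMM23b_like", "c25", "+", 10000, 7)
  Acc <- bank_gene("ARHGAP32b_like", "c26", "+", 50000, 3, utr5 = 31)
  add("TIMM23b_like-ARHGAP32b_like", list(D, Acc),
      exp_row("TIMM23b_like", 6, "ARHGAP32b_like", 2, "runthrough",
              "out_of_frame"),
      junction = list(id = "J1", chrom_a = "c25",
                      pos_a = intron_break(D, 6), side_a = "left_retained",
                      chrom_b = "c26", pos_b = 5000,
                      side_b = "right_retained"))

  cases
}

#' Evaluate the fusion fixture bank
#'
#' Runs [predict_fusion()] (or [trace_multi_junction_transcript()] for
#' multi-junction cases) on every fixture in [fusion_topology_bank()] and
#' compares the prediction with the expected partners, retained exons,
#' kind and frame.
#'
#' @return Data frame with one row per case: `name`, `matched`.
#' @export
evaluate_topology_bank <- function() {
  bank <- fusion_topology_bank()
  res <- lapply(bank, function(case) {
    got <- if (!is.null(case$path)) {
      trace_multi_junction_transcript(case$path, case$genes)
    } else {
      predict_fusion(case$junction, case$genes)$fusions
    }
    exp <- case$expected
    matched <- !is.null(got) && nrow(got) >= 1 &&
      any(got$five_prime_gene == exp$five_prime_gene &
          got$five_prime_exon == exp$five_prime_exon &
          got$three_prime_gene == exp$three_prime_gene &
          got$three_prime_exon == exp$three_prime_exon &
          got$kind == exp$kind & got$frame == exp$frame)
    data.frame(name = case$name, matched = matched)
  })
  do.call(rbind, res)
}

#' Synthetic junction-sequence bank
#'
#' Seven deterministic synthetic junction sequences with the class
#' structure seen among Sanger-sequenced cancer rearrangement junctions:
#' four junctions with 1-4 bp of microhomology (lengths 2, 1, 4 and 3),
#' two blunt junctions, and one junction carrying a 15 bp genomic shard
#' copied from elsewhere in the bank's reference. These are constructed
#' stand-ins (no real junction sequences ship with the package), used to
#' exercise [measure_microhomology()], [detect_shard()] and
#' [summarize_junction_classes()].
#'
#' @param flank Flank length (bp).
#' @param seed Integer seed.
#' @return List with `ref` (a [ref_genome]) and `junctions` (data frame
#'   `junction_id`, `flank5`, `flank3`, `observed`, `mh_planted`,
#'   `insert_planted`).
#' @export
synthetic_junction_bank <- function(flank = 60, seed = 42) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rand <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    mh_lens <- c(2L, 1L, 4L, 3L, 0L, 0L, 0L)
    shard_seq <- rand(15)
    ref <- ref_genome(c(bank_ref = paste0(rand(400), shard_seq, rand(400))))
    rows <- list()
    for (i in seq_along(mh_lens)) {
      L <- mh_lens[i]
      f5 <- rand(flank)
      repeat {
        tail3 <- rand(flank - L)
        f3 <- paste0(substr(f5, flank - L + 1, flank), tail3)
        # forbid accidental longer homology
        if (mh_scan(f5, f3) == L) break
        f5 <- rand(flank)
      }
      ins <- if (i == 7L) shard_seq else ""
      rows[[i]] <- data.frame(
        junction_id = sprintf("bank_j%d", i), flank5 = f5, flank3 = f3,
        observed = paste0(f5, ins, f3), mh_planted = L,
        insert_planted = ins)
    }
    list(ref = ref, junctions = do.call(rbind, rows))
  })
}

#' Replicated end-to-end recovery experiment
#'
#' Runs the demonstration scenario's calling pipeline over `n_reps`
#' independently simulated library pairs (artifact-free) and scores, per
#' replicate, recall over planted junctions that have at least
#' `min_support` surviving supporting pairs (and at least 10 kb span when
#' intra-chromosomal) and precision of the emitted candidate set against
#' the truth.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param pe_pairs,mp_pairs Pairs per library per replicate.
#' @return Data frame with one row per replicate: `rep`, `recall`,
#'   `precision`, `n_eligible`, `n_candidates`.
#' @export
recovery_experiment <- function(n_reps = 20, seed = 1, pe_pairs = 60000,
                                mp_pairs = 15000) {
  sc <- demo_scenario(seed)
  libs <- list(
    pe500 = library_spec("pe500", 36, 504, 404, 619, n_pairs = pe_pairs),
    mp3k = library_spec("mp3k", 36, 3000, 2500, 3600, n_pairs = mp_pairs))
  truth <- sc$der$truth
  tol <- max(vapply(libs, function(s) s$frag_max, numeric(1)))
  out <- list()
  for (r in seq_len(n_reps)) {
    pairs <- rbind(
      simulate_read_pairs(sc$der, libs$pe500, seed = seed + 211 * r),
      simulate_read_pairs(sc$der, libs$mp3k, seed = seed + 211 * r + 1))
    fc <- filter_cascade(pairs, libs)
    ab <- fc$aberrant
    cands <- cluster_pairs(ab, libs, min_support = 2)
    kept <- apply_filters(cands, min_span = 10000, panel_tol = tol)$kept
    support <- vapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      near <- ab$chrom1 == tr$chrom_a & ab$chrom2 == tr$chrom_b &
        abs(ab$pos1 - tr$pos_a) <= tol & abs(ab$pos2 - tr$pos_b) <= tol
      nearswap <- ab$chrom1 == tr$chrom_b & ab$chrom2 == tr$chrom_a &
        abs(ab$pos1 - tr$pos_b) <= tol & abs(ab$pos2 - tr$pos_a) <= tol
      sum(near | nearswap)
    }, numeric(1))
    span_ok <- truth$chrom_a != truth$chrom_b |
      abs(truth$pos_b - truth$pos_a) >= 10000
    eligible <- support >= 2 & span_ok
    detected <- vapply(seq_len(nrow(truth)), function(i)
      truth_matched(truth[i, ], kept, tol), logical(1))
    tp <- vapply(seq_len(nrow(kept)), function(k) {
      any(vapply(seq_len(nrow(truth)), function(i)
        truth_matched(truth[i, ], kept[k, , drop = FALSE], tol), logical(1)))
    }, logical(1))
    out[[r]] <- data.frame(
      rep = r,
      recall = if (any(eligible)) mean(detected[eligible]) else NA_real_,
      precision = if (nrow(kept)) mean(tp) else NA_real_,
      n_eligible = sum(eligible), n_candidates = nrow(kept))
  }
  do.call(rbind, out)
}
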