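test_that("clustering requires two consistent pairs and separates orientation classes", {
  lib <- pe_lib()
  two <- rbind(pair_row("a1", "chrA", 49900, "+", "chrB", 120100, "-"),
               pair_row("a2", "chrA", 49800, "+", "chrB", 120050, "-"))
  cands <- cluster_pairs(two, lib)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$support, 2)
  expect_equal(cands$side_a, "left_retained")
  expect_equal(cands$side_b, "right_retained")
  # isolated aberrant pair: no candidate
  one <- pair_row("solo", "chrA", 10000, "+", "chrB", 90000, "-")
  expect_equal(nrow(cluster_pairs(one, lib)), 0)
  # orientation split: two (+,+) and one (-,-) at one locus -> only the
  # (+,+) group is emitted
  mix <- rbind(pair_row("p1", "chrA", 50000, "+", "chrA", 120000, "+"),
               pair_row("p2", "chrA", 50050, "+", "chrA", 120020, "+"),
               pair_row("p3", "chrA", 50025, "-", "chrA", 120010, "-"))
  cands2 <- cluster_pairs(mix, lib)
  expect_equal(nrow(cands2), 1)
  expect_equal(cands2$strand_a, "+")
  expect_setequal(strsplit(cands2$pair_ids, ",")[[1]], c("p1", "p2"))
})

test_that("clustering agrees with a brute-force pairwise-consistency oracle", {
  lib <- pe_lib()
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12
    # a few junction loci plus scattered strays
    centers <- sample(1e5:5e5, 3)
    p <- do.call(rbind, lapply(seq_len(n), function(i) {
      ctr <- sample(centers, 1)
      pair_row(sprintf("p%02d", i), "chrA",
               ctr + sample(-300:300, 1), "+",
               "chrB", 2 * ctr + sample(-300:300, 1), "-")
    }))
    cands <- cluster_pairs(p, lib, min_support = 2)
    groups <- Filter(function(g) length(g) >= 2, oracle_clusters(p, lib))
    got <- lapply(strsplit(cands$pair_ids, ","), sort)
    want <- lapply(groups, sort)
    expect_setequal(got, want)
  }
})

test_that("breakend intervals contain the implied junction and support is counted", {
  lib <- pe_lib()
  # deletion-like junction at ~chrA:50000 / ~chrA:80000
  p <- rbind(pair_row("q1", "chrA", 49700, "+", "chrA", 80150, "-"),
             pair_row("q2", "chrA", 49850, "+", "chrA", 80300, "-"),
             pair_row("q3", "chrA", 49600, "+", "chrA", 80200, "-"))
  cands <- cluster_pairs(p, lib)
  expect_equal(cands$support, 3)
  expect_true(cands$lo_a <= 50000 && cands$hi_a >= 50000)
  expect_true(cands$lo_b <= 80000 && cands$hi_b >= 80000)
  expect_equal(cands$libraries, "pe500")
})

test_that("the candidate filter cascade applies span, panel and blacklist rules", {
  mk <- function(id, chrom_a, mid_a, sa, chrom_b, mid_b, sb) {
    data.frame(id = id, chrom_a = chrom_a, lo_a = mid_a - 50, hi_a = mid_a + 50,
               strand_a = sa,
               side_a = ifelse(sa == "+", "left_retained", "right_retained"),
               chrom_b = chrom_b, lo_b = mid_b - 50, hi_b = mid_b + 50,
               strand_b = sb,
               side_b = ifelse(sb == "+", "left_retained", "right_retained"),
               support = 3, libraries = "pe500", n_libraries = 1,
               span = if (chrom_a == chrom_b) abs(mid_b - mid_a) else NA_real_,
               pair_ids = "x")
  }
  cands <- rbind(
    mk("short", "chr1", 20000, "+", "chr1", 29500, "-"),    # span 9,500
    mk("edge", "chr1", 50000, "+", "chr1", 60000, "-"),     # span 10,000
    mk("inter", "chr1", 5000, "+", "chr2", 5000, "-"),      # inter, tiny coords
    mk("inpanel", "chr1", 200000, "+", "chr1", 260000, "-"),
    mk("incnv", "chr1", 400000, "+", "chr1", 460000, "-"))
  panel <- data.frame(chrom1 = "chr1", pos1 = 200100, strand1 = "+",
                      chrom2 = "chr1", pos2 = 259900, strand2 = "-",
                      n_samples_seen = 5)
  bl <- data.frame(chrom = "chr1", start = 395000, end = 465000)
  fl <- apply_filters(cands, cnv_blacklist = bl, panel = panel,
                      min_span = 10000, panel_tol = 619)
  expect_setequal(fl$kept$id, c("edge", "inter"))
  reasons <- setNames(fl$removed$reasons, fl$removed$id)
  expect_equal(reasons[["short"]], "min_span")
  expect_equal(reasons[["inpanel"]], "panel")
  expect_equal(reasons[["incnv"]], "blacklist")
  # kept is a subset of input; reasons partition the removed set
  expect_true(all(fl$kept$id %in% cands$id))
  expect_equal(nrow(fl$kept) + nrow(fl$removed), nrow(cands))
  # malformed blacklist
  expect_error(apply_filters(cands, cnv_blacklist = data.frame(
    chrom = "chr1", start = 10, end = 5), min_span = 1e4),
    class = "svfuse_input_error")
  # panel/blacklist rule order cannot matter: each rule is a set-membership
  # test; applying them separately and intersecting equals applying both
  k_pan <- apply_filters(cands, panel = panel, min_span = 0)$kept$id
  k_bl <- apply_filters(cands, cnv_blacklist = bl, min_span = 0)$kept$id
  k_both <- apply_filters(cands, cnv_blacklist = bl, panel = panel,
                          min_span = 0)$kept$id
  expect_setequal(k_both, intersect(k_pan, k_bl))
})

test_that("confirmation prefers multi-library support, then copy-number steps", {
  cand <- data.frame(id = c("c1", "c2", "c3"),
                     chrom_a = "chr1", lo_a = c(1000, 99000, 500000),
                     hi_a = c(1200, 101000, 500200), strand_a = "+",
                     side_a = "left_retained",
                     chrom_b = "chr2", lo_b = c(5000, 5000, 5000),
                     hi_b = c(5200, 5200, 5200), strand_b = "-",
                     side_b = "right_retained", support = 4,
                     libraries = c("pe500,mp3k", "pe500", "pe500"),
                     n_libraries = c(2, 1, 1), span = NA_real_, pair_ids = "x")
  steps <- data.frame(chrom = "chr1", start = 98900, end = 99100,
                      delta_log2 = -1, direction = "down")
  conf <- confirm_candidates(cand, steps, step_tolerance = 10000)
  expect_equal(conf$confirmation, c("multi_library", "cn_step", "unconfirmed"))
})

test_that("the pipeline handles empty input and reports every stage", {
  lib <- pe_lib()
  empty <- pair_row("z", "chr1", 100, "+", "chr1", 603, "-")[0, ]
  res <- call_pipeline(empty, lib)
  expect_equal(nrow(res$candidates), 0)
  expect_named(res$report, c("input", "post_mapq", "post_dedup", "normal",
                             "aberrant", "clusters", "post_filter",
                             "confirmed"))
  expect_true(all(res$report == 0))
})

test_that("replicated simulations recover every well-supported planted junction with no false calls", {
  ref <- generate_reference(3, c(250000, 250000, 200000), gc = 0.41, seed = 5)
  evs <- list(sv_deletion("chr1", 60000, 120000, "del1"),
              sv_deletion("chr2", 80000, 170000, "del2"),
              sv_translocation("chr3", 100000, "chr1", 180000, "t1"))
  der <- plant_rearrangements(ref, evs, ploidy = 2)
  lib <- pe_lib(30000)
  truth <- der$truth
  for (r in 1:5) {
    p <- simulate_read_pairs(der, lib, seed = 300 + r)
    fc <- filter_cascade(p, lib)
    cands <- cluster_pairs(fc$aberrant, lib)
    kept <- apply_filters(cands, min_span = 10000, panel_tol = 619)$kept
    # every truth junction with >= 2 surviving supporting pairs is called
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      ab <- fc$aberrant
      sup <- sum((ab$chrom1 == tr$chrom_a & ab$chrom2 == tr$chrom_b &
                  abs(ab$pos1 - tr$pos_a) <= lib$frag_max &
                  abs(ab$pos2 - tr$pos_b) <= lib$frag_max) |
                 (ab$chrom1 == tr$chrom_b & ab$chrom2 == tr$chrom_a &
                  abs(ab$pos1 - tr$pos_b) <= lib$frag_max &
                  abs(ab$pos2 - tr$pos_a) <= lib$frag_max))
      if (sup >= 2)
        expect_true(svfuse:::truth_matched(tr, kept, lib$frag_max),
                    info = sprintf("rep %d junction %s", r, tr$junction_id))
    }
    # precision: every candidate matches some truth junction
    for (k in seq_len(nrow(kept))) {
      hit <- any(vapply(seq_len(nrow(truth)), function(i)
        svfuse:::truth_matched(truth[i, ], kept[k, , drop = FALSE],
                               lib$frag_max), logical(1)))
      expect_true(hit, info = sprintf("rep %d candidate %s", r, kept$id[k]))
    }
  }
})
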