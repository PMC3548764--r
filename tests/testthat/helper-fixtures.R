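# Shared fixtures for the suite. Everything is generated in code; no
# binary data ships with the package.

tiny_ref <- function(seed = 7, lens = c(200000, 150000)) {
  generate_reference(length(lens), lens, gc = 0.41, seed = seed)
}

tiny_deletion_der <- function(seed = 7, start = 40000, end = 70000) {
  ref <- tiny_ref(seed)
  plant_rearrangements(ref, list(sv_deletion("chr1", start, end, "del1")),
                       ploidy = 2)
}

pe_lib <- function(n_pairs = 20000) {
  library_spec("pe500", read_length = 36, frag_median = 504,
               frag_min = 404, frag_max = 619, n_pairs = n_pairs)
}

# Construct a read-pair row directly.
pair_row <- function(pair_id, chrom1, pos1, strand1, chrom2, pos2, strand2,
                     mapq1 = 60, mapq2 = 60, library = "pe500") {
  data.frame(pair_id = pair_id, library = library,
             chrom1 = chrom1, pos1 = pos1, strand1 = strand1, mapq1 = mapq1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2, mapq2 = mapq2)
}

# Independent brute-force oracle for exon phases: walk exons in
# transcription order accumulating CDS overlap directly.
oracle_phases <- function(g) {
  ex <- g$exons
  n <- nrow(ex)
  ord <- if (g$strand == "+") seq_len(n) else rev(seq_len(n))
  cum <- 0
  seen_cds <- FALSE
  out <- data.frame(exon = seq_len(n), start_phase = NA_integer_,
                    end_phase = NA_integer_)
  if (is.na(g$cds_start)) return(out)
  total_cds <- sum(pmax(0, pmin(ex[, 2], g$cds_end) - pmax(ex[, 1], g$cds_start)))
  for (k in seq_len(n)) {
    gi <- ord[k]
    ov <- max(0, min(ex[gi, 2], g$cds_end) - max(ex[gi, 1], g$cds_start))
    # start boundary inside CDS: some CDS before or exon starts exactly at CDS
    start_in <- if (g$strand == "+")
      ex[gi, 1] >= g$cds_start && ex[gi, 1] < g$cds_end
    else ex[gi, 2] <= g$cds_end && ex[gi, 2] > g$cds_start
    end_in <- if (g$strand == "+")
      ex[gi, 2] > g$cds_start && ex[gi, 2] <= g$cds_end
    else ex[gi, 1] < g$cds_end && ex[gi, 1] >= g$cds_start
    if (start_in) out$start_phase[k] <- cum %% 3
    cum <- cum + ov
    if (end_in) out$end_phase[k] <- cum %% 3
    seen_cds <- seen_cds || ov > 0
  }
  stopifnot(cum == total_cds)
  out
}

# Independent brute-force microhomology oracle: try every L.
oracle_mh <- function(flank5, flank3, max_l = 20) {
  best <- 0L
  for (L in seq_len(min(nchar(flank5), nchar(flank3), max_l))) {
    if (substr(flank5, nchar(flank5) - L + 1, nchar(flank5)) ==
        substr(flank3, 1, L)) best <- L
  }
  best
}

# Independent pairwise-consistency clustering oracle (transitive closure
# by repeated merging over the full pairwise matrix).
oracle_clusters <- function(pairs, lib) {
  w <- lib$frag_max - lib$read_length
  imply <- function(pos, strand) {
    lo <- ifelse(strand == "+", pos, pos - w + 1)
    cbind(lo, lo + w)
  }
  i1 <- imply(pairs$pos1, pairs$strand1)
  i2 <- imply(pairs$pos2, pairs$strand2)
  n <- nrow(pairs)
  consistent <- function(i, j) {
    pairs$chrom1[i] == pairs$chrom1[j] && pairs$chrom2[i] == pairs$chrom2[j] &&
      pairs$strand1[i] == pairs$strand1[j] &&
      pairs$strand2[i] == pairs$strand2[j] &&
      i1[i, 1] < i1[j, 2] && i1[j, 1] < i1[i, 2] &&
      i2[i, 1] < i2[j, 2] && i2[j, 1] < i2[i, 2]
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && consistent(i, j) && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(pairs$pair_id, comp)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
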