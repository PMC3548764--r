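#' Sequencing library specification
#'
#' Geometry of a paired-end library: short reads of `read_length` bp from
#' both ends of fragments whose length distribution is summarised by its
#' median and range (a triangular distribution with mode `frag_median` on
#' `[frag_min, frag_max]` is used, since only median and range are known).
#' The default geometry is a 36 bp short-insert library with median 504 bp
#' fragments ranging 404-619 bp; a mate-pair style library is obtained
#' with ~3 kb fragments.
#'
#' @param name Library name (appears in the `library` column of pair
#'   tables and drives multi-library confirmation).
#' @param read_length Read length in bp.
#' @param frag_median,frag_min,frag_max Fragment length summary (bp).
#' @param n_pairs Number of read pairs to simulate.
#' @return A `library_spec` object.
#' @export
library_spec <- function(name, read_length = 36, frag_median = 504,
                         frag_min = 404, frag_max = 619, n_pairs = 10000) {
  if (!(frag_min <= frag_median && frag_median <= frag_max))
    svf_stop("need frag_min <= frag_median <= frag_max", "svfuse_parameter_error")
  if (2 * read_length > frag_min)
    svf_stop("fragments must fit two reads: 2*read_length <= frag_min",
             "svfuse_parameter_error")
  structure(list(name = name, read_length = as.integer(read_length),
                 frag_median = frag_median, frag_min = frag_min,
                 frag_max = frag_max, n_pairs = as.integer(n_pairs)),
            class = "library_spec")
}

empty_pairs <- function() {
  data.frame(pair_id = character(0), library = character(0),
             chrom1 = character(0), pos1 = numeric(0), strand1 = character(0),
             mapq1 = integer(0), chrom2 = character(0), pos2 = numeric(0),
             strand2 = character(0), mapq2 = integer(0))
}

# Canonical end ordering: end1 <= end2 under (contig order, position).
canonicalize_pairs <- function(pairs, chrom_levels) {
  if (!nrow(pairs)) return(pairs)
  c1 <- match(pairs$chrom1, chrom_levels)
  c2 <- match(pairs$chrom2, chrom_levels)
  swap <- c2 < c1 | (c1 == c2 & pairs$pos2 < pairs$pos1)
  if (any(swap)) {
    tmp <- pairs[swap, ]
    pairs[swap, c("chrom1", "pos1", "strand1", "mapq1")] <-
      tmp[, c("chrom2", "pos2", "strand2", "mapq2")]
    pairs[swap, c("chrom2", "pos2", "strand2", "mapq2")] <-
      tmp[, c("chrom1", "pos1", "strand1", "mapq1")]
  }
  pairs
}

# Map read intervals [a, b) on a derivative contig back to reference
# coordinates. `forward` says whether the read is on the derivative
# forward strand (read 1) or reverse (read 2). Reads that cross an
# element boundary, or lie in inserted sequence, are unmappable.
map_der_reads <- function(ct, a, b, forward) {
  el <- ct$elements
  idx <- findInterval(a, el$der_start)
  ok <- idx >= 1 & b <= el$der_start[idx] + el$len[idx] &
    el$kind[idx] == "segment"
  w <- b - a
  off <- a - el$der_start[idx]
  seg_plus <- el$strand[idx] == "+"
  ref_left <- ifelse(seg_plus, el$start[idx] + off,
                     el$end[idx] - off - w)
  ref_strand <- if (forward) el$strand[idx] else flip_strand(el$strand[idx])
  pos5 <- ifelse(ref_strand == "+", ref_left, ref_left + w - 1)
  data.frame(chrom = el$chrom[idx], pos5 = pos5, strand = ref_strand, ok = ok)
}

#' Simulate a paired-end read library over a derivative genome
#'
#' Fragments are drawn uniformly along the derivative genome (derived
#' contigs weighted by copy number plus the remaining baseline homologues),
#' so read depth scales with copy number. Fragment lengths follow a
#' triangular distribution on the library's range. The simulator itself
#' maps reads back to reference coordinates using the known segment map;
#' reads falling across a junction or into inserted sequence are dropped
#' as unmappable. Optional artifacts: exact PCR duplicates, PCR duplicates
#' offset by 1-2 bp (a primer having lost 3' bases), coligation chimeras
#' joining two unrelated fragments, and a mapping-quality model assigning
#' `mapq` below 30 to reads in designated repeat intervals (or a random
#' fraction of reads).
#'
#' @param der A `derivative` from [plant_rearrangements()].
#' @param lib A [library_spec].
#' @param dup_rate,offset_dup_rate Per-pair probabilities of injecting an
#'   exact / offset PCR duplicate.
#' @param chimera_rate Per-pair probability of a coligation chimera.
#' @param repeats Optional data frame (`chrom`, `start`, `end`) of repeat
#'   intervals; reads overlapping them get `mapq` uniform on 0..29,
#'   all other reads mapq 60.
#' @param lowmapq_frac Fraction of reads given random low mapq regardless
#'   of position.
#' @param seed Integer seed.
#' @return Data frame of read-pair alignments with columns `pair_id`,
#'   `library`, `chrom1`, `pos1`, `strand1`, `mapq1`, `chrom2`, `pos2`,
#'   `strand2`, `mapq2`. Positions are 0-based 5' coordinates; ends are
#'   canonically ordered.
#' @export
simulate_read_pairs <- function(der, lib, dup_rate = 0, offset_dup_rate = 0,
                                chimera_rate = 0, repeats = NULL,
                                lowmapq_frac = 0, seed = NULL) {
  for (r in c(dup_rate, offset_dup_rate, chimera_rate, lowmapq_frac))
    if (r < 0 || r > 1)
      svf_stop("rates must lie in [0, 1]", "svfuse_parameter_error")
  stopifnot(inherits(der, "derivative"), inherits(lib, "library_spec"))
  chrom_levels <- names(der$ref)
  rl <- lib$read_length

  units <- rbind(
    do.call(rbind, lapply(der$contigs, function(ct) {
      data.frame(type = "der", key = ct$name, start = 0,
                 len = ct$length, copy = ct$copy)
    })),
    {
      b <- der$baseline[der$baseline$copy > 0, , drop = FALSE]
      if (nrow(b)) data.frame(type = "base", key = b$chrom, start = b$start,
                              len = b$end - b$start, copy = b$copy)
      else NULL
    })
  units <- units[units$len >= lib$frag_max, , drop = FALSE]
  if (is.null(units) || !nrow(units))
    svf_stop("derivative genome has no unit long enough for this library",
             "svfuse_input_error")
  weight <- (units$len - lib$frag_max + 1) * units$copy

  with_seed(seed, {
    n <- lib$n_pairs
    if (n == 0L) return(empty_pairs())
    ui <- sample.int(nrow(units), n, replace = TRUE, prob = weight)
    fl <- round(rtriangular(n, lib$frag_min, lib$frag_median, lib$frag_max))
    fl <- pmin(pmax(fl, lib$frag_min), lib$frag_max)
    fs <- floor(stats::runif(n) * (units$len[ui] - fl + 1))

    out1 <- data.frame(chrom = NA_character_, pos5 = NA_real_,
                       strand = NA_character_, ok = FALSE)[rep(1, n), ]
    out2 <- out1
    base_i <- which(units$type[ui] == "base")
    if (length(base_i)) {
      st <- units$start[ui[base_i]] + fs[base_i]
      out1[base_i, ] <- data.frame(chrom = units$key[ui[base_i]], pos5 = st,
                                   strand = "+", ok = TRUE)
      out2[base_i, ] <- data.frame(chrom = units$key[ui[base_i]],
                                   pos5 = st + fl[base_i] - 1,
                                   strand = "-", ok = TRUE)
    }
    for (nm in unique(units$key[ui[units$type[ui] == "der"]])) {
      sel <- which(units$type[ui] == "der" & units$key[ui] == nm)
      ct <- der$contigs[[nm]]
      out1[sel, ] <- map_der_reads(ct, fs[sel], fs[sel] + rl, forward = TRUE)
      out2[sel, ] <- map_der_reads(ct, fs[sel] + fl[sel] - rl, fs[sel] + fl[sel],
                                   forward = FALSE)
    }
    keep <- out1$ok & out2$ok
    pairs <- data.frame(pair_id = sprintf("%s_%07d", lib$name, seq_len(sum(keep))),
                        library = lib$name,
                        chrom1 = out1$chrom[keep], pos1 = out1$pos5[keep],
                        strand1 = out1$strand[keep], mapq1 = 60L,
                        chrom2 = out2$chrom[keep], pos2 = out2$pos5[keep],
                        strand2 = out2$strand[keep], mapq2 = 60L)

    # mapping-quality model
    lowq <- function(chrom, pos5, strand) {
      q <- rep(60L, length(pos5))
      lo <- ifelse(strand == "+", pos5, pos5 - rl + 1)
      hi <- lo + rl
      if (!is.null(repeats) && nrow(repeats)) {
        in_rep <- rep(FALSE, length(pos5))
        for (k in seq_len(nrow(repeats)))
          in_rep <- in_rep | (chrom == repeats$chrom[k] &
                              lo < repeats$end[k] & hi > repeats$start[k])
        q[in_rep] <- sample(0:29, sum(in_rep), replace = TRUE)
      }
      if (lowmapq_frac > 0) {
        rnd <- stats::runif(length(pos5)) < lowmapq_frac
        q[rnd] <- sample(0:29, sum(rnd), replace = TRUE)
      }
      q
    }
    pairs$mapq1 <- lowq(pairs$chrom1, pairs$pos1, pairs$strand1)
    pairs$mapq2 <- lowq(pairs$chrom2, pairs$pos2, pairs$strand2)

    # coligation chimeras: end 1 of one fragment joined to end 2 of another
    if (chimera_rate > 0 && nrow(pairs) > 1) {
      n_chim <- stats::rbinom(1, nrow(pairs), chimera_rate)
      if (n_chim > 0) {
        i <- sample.int(nrow(pairs), n_chim, replace = TRUE)
        j <- sample.int(nrow(pairs), n_chim, replace = TRUE)
        chim <- pairs[i, ]
        chim[, c("chrom2", "pos2", "strand2", "mapq2")] <-
          pairs[j, c("chrom2", "pos2", "strand2", "mapq2")]
        chim$pair_id <- sprintf("%s_chim%05d", lib$name, seq_len(n_chim))
        pairs <- rbind(pairs, chim)
      }
    }

    pairs <- canonicalize_pairs(pairs, chrom_levels)

    # PCR duplicates: exact copies, and copies offset by 1-2 bp on end 1
    if (dup_rate > 0 && nrow(pairs)) {
      d <- which(stats::runif(nrow(pairs)) < dup_rate)
      if (length(d)) {
        dup <- pairs[d, ]
        dup$pair_id <- paste0(dup$pair_id, "_dupx")
        pairs <- rbind(pairs, dup)
      }
    }
    if (offset_dup_rate > 0 && nrow(pairs)) {
      d <- which(stats::runif(nrow(pairs)) < offset_dup_rate)
      if (length(d)) {
        dup <- pairs[d, ]
        dup$pos1 <- dup$pos1 + sample(1:2, length(d), replace = TRUE)
        dup$pair_id <- paste0(dup$pair_id, "_dupo")
        pairs <- rbind(pairs, dup)
      }
    }
    rownames(pairs) <- NULL
    pairs
  })
}

#' Simulate an array-CGH-like probe profile
#'
#' Probes are laid down at fixed spacing along each reference chromosome;
#' each probe reports `log2(copy number / baseline ploidy)` plus Gaussian
#' noise. The copy-number truth comes from the derivative's piecewise map.
#' Copy number is floored at 0.25 copies before taking logs so homozygous
#' losses remain finite.
#'
#' @param der A `derivative`, or a data frame (`chrom`, `start`, `end`,
#'   `cn`) copy-number map.
#' @param probe_spacing Distance between probes (bp), > 0.
#' @param noise_sd Standard deviation of the Gaussian probe noise.
#' @param baseline Baseline ploidy for the log-ratio (defaults to the
#'   derivative's ploidy, else 2).
#' @param seed Integer seed.
#' @return Data frame (`chrom`, `pos`, `log2_ratio`), sorted by
#'   (chrom, pos).
#' @export
simulate_cgh <- function(der, probe_spacing = 5000, noise_sd = 0.1,
                         baseline = NULL, seed = NULL) {
  if (probe_spacing <= 0)
    svf_stop("probe_spacing must be > 0", "svfuse_parameter_error")
  if (inherits(der, "derivative")) {
    cn_map <- der$cn_map
    baseline <- baseline %||% der$ploidy
  } else {
    cn_map <- der
    baseline <- baseline %||% 2
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(unique(cn_map$chrom), function(chrom) {
      m <- cn_map[cn_map$chrom == chrom, , drop = FALSE]
      L <- max(m$end)
      pos <- seq(floor(probe_spacing / 2), L - 1, by = probe_spacing)
      cn <- m$cn[findInterval(pos, m$start)]
      data.frame(chrom = chrom, pos = pos,
                 log2_ratio = log2(pmax(cn, 0.25) / baseline) +
                   stats::rnorm(length(pos), 0, noise_sd))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Build a panel-of-normals junction list
#'
#' Emulates a pool of unrelated normal samples carrying polymorphic
#' structural variants (deletions): the panel records the junction
#' signatures (breakend pair plus orientation) seen in any normal sample,
#' and is used by [apply_filters()] to remove germline polymorphisms and
#' shared artifacts from tumour candidate lists.
#'
#' @param ref A [ref_genome].
#' @param n_samples Number of normal samples pooled (default 18).
#' @param polymorphic_sv_rate Expected polymorphic deletions per sample.
#' @param events Optional list of [sv_deletion()] events planted in every
#'   sample (deterministic panel content).
#' @param seed Integer seed.
#' @return Data frame (`chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'   `strand2`, `n_samples_seen`).
#' @export
build_panel_of_normals <- function(ref, n_samples = 18,
                                   polymorphic_sv_rate = 0.5,
                                   events = NULL, seed = NULL) {
  if (n_samples < 1)
    svf_stop("n_samples must be >= 1", "svfuse_parameter_error")
  lens <- contig_lengths(ref)
  with_seed(seed, {
    rows <- list()
    for (ev in events %||% list()) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom1 = ev$chrom, pos1 = ev$start, strand1 = "+",
        chrom2 = ev$chrom, pos2 = ev$end, strand2 = "-",
        n_samples_seen = n_samples)
    }
    n_poly <- stats::rpois(1, polymorphic_sv_rate * n_samples)
    for (k in seq_len(n_poly)) {
      chrom <- sample(names(lens), 1, prob = lens)
      span <- sample(20000:200000, 1)
      if (lens[[chrom]] <= span + 2) next
      start <- floor(stats::runif(1, 1, lens[[chrom]] - span - 1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom1 = chrom, pos1 = start, strand1 = "+",
        chrom2 = chrom, pos2 = start + span, strand2 = "-",
        n_samples_seen = sample.int(n_samples, 1))
    }
    if (!length(rows))
      return(data.frame(chrom1 = character(0), pos1 = numeric(0),
                        strand1 = character(0), chrom2 = character(0),
                        pos2 = numeric(0), strand2 = character(0),
                        n_samples_seen = integer(0)))
    do.call(rbind, rows)
  })
}
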