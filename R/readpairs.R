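#' Mapping-quality filter
#'
#' Discards read pairs in which either read has mapping quality below the
#' threshold (strictly below: a pair scoring exactly the threshold on both
#' ends is kept).
#'
#' @param pairs Read-pair data frame (see [simulate_read_pairs()]).
#' @param threshold Minimum acceptable mapq (default 30).
#' @return List with elements `kept` and `discarded`.
#' @export
filter_mapq <- function(pairs, threshold = 30) {
  bad <- pmin(pairs$mapq1, pairs$mapq2) < threshold
  list(kept = pairs[!bad, , drop = FALSE],
       discarded = pairs[bad, , drop = FALSE])
}

#' Remove exact and offset PCR duplicates
#'
#' Two pairs are duplicates when both ends share contig and strand and
#' both 5' position differences are at most `max_offset` bp (0 = exact
#' duplicates; the default 2 also catches duplicates whose primer lost
#' one or two 3' bases). Duplicate groups are the transitive closure of
#' this relation; within a group the pair with the highest summed mapq is
#' retained (ties broken by lexicographically smallest `pair_id`).
#'
#' @param pairs Read-pair data frame, canonically ordered.
#' @param max_offset Maximum per-end 5' offset (bp) for two pairs to be
#'   considered duplicates.
#' @return List with elements `unique` and `duplicates`.
#' @export
remove_duplicates <- function(pairs, max_offset = 2) {
  n <- nrow(pairs)
  if (!n) return(list(unique = pairs, duplicates = pairs))
  key <- paste(pairs$chrom1, pairs$strand1, pairs$chrom2, pairs$strand2,
               sep = "\r")
  pos1 <- pairs$pos1; pos2 <- pairs$pos2
  score <- pairs$mapq1 + pairs$mapq2
  pid <- pairs$pair_id
  keep <- logical(n)
  for (idx in split(seq_len(n), key)) {
    o <- idx[order(pos1[idx], pos2[idx])]
    p1 <- pos1[o]; p2 <- pos2[o]
    m <- length(o)
    ei <- integer(0); ej <- integer(0)
    if (m > 1) {
      # candidate edges: positions sorted, so only a short look-ahead window
      for (i in seq_len(m - 1L)) {
        j <- i + 1L
        while (j <= m && p1[j] - p1[i] <= max_offset) {
          if (abs(p2[j] - p2[i]) <= max_offset) { ei <- c(ei, i); ej <- c(ej, j) }
          j <- j + 1L
        }
      }
    }
    if (!length(ei)) { keep[o] <- TRUE; next }
    in_edge <- unique(c(ei, ej))
    keep[o[setdiff(seq_len(m), in_edge)]] <- TRUE
    comp <- connected_components(m, ei, ej)
    for (g in split(in_edge, comp[in_edge])) {
      rows <- o[g]
      best <- rows[order(-score[rows], pid[rows])][1]
      keep[best] <- TRUE
    }
  }
  list(unique = pairs[keep, , drop = FALSE],
       duplicates = pairs[!keep, , drop = FALSE])
}

#' Classify read pairs as normal or aberrant
#'
#' A pair is *normal* when both ends map to the same contig, in inward
#' (FR) orientation, with an outer span (5' to 5', inclusive) inside the
#' library's fragment-length range. Everything else is *aberrant*:
#' different contigs, wrong orientation, or an outer span outside
#' `[frag_min, frag_max]`.
#'
#' @param pairs Read-pair data frame (canonically ordered).
#' @param lib A [library_spec], or a named list of them keyed by library
#'   name when `pairs` mixes libraries.
#' @return The input with an added `class` column (`normal`/`aberrant`).
#' @export
classify_pairs <- function(pairs, lib) {
  libs <- if (inherits(lib, "library_spec"))
    stats::setNames(list(lib), lib$name) else lib
  li <- match(pairs$library, names(libs))
  fmin <- vapply(libs, function(s) s$frag_min, numeric(1))[li]
  fmax <- vapply(libs, function(s) s$frag_max, numeric(1))[li]
  span <- pairs$pos2 - pairs$pos1 + 1
  normal <- pairs$chrom1 == pairs$chrom2 &
    pairs$strand1 == "+" & pairs$strand2 == "-" &
    span >= fmin & span <= fmax
  pairs$class <- ifelse(normal, "normal", "aberrant")
  pairs
}

#' Recheck aberrant pairs for a concordant alternative placement
#'
#' Aligners occasionally place a read on a homologous copy instead of its
#' true locus, creating spurious discordant pairs. This recheck realigns
#' both reads of each aberrant pair against the reference (exact and
#' near-exact matches, up to `max_mismatch` mismatches, both strands) and
#' discards the pair when any alternative placement combination is
#' concordant under [classify_pairs()]. It needs read sequences (`seq1`,
#' `seq2` columns); alignment-level simulations without sequences skip
#' the check with a warning.
#'
#' @param pairs Aberrant read-pair data frame with `seq1`/`seq2` columns.
#' @param ref A [ref_genome].
#' @param lib A [library_spec] (or named list keyed by library).
#' @param max_mismatch Mismatches tolerated in an alternative placement.
#' @return List with elements `kept` and `discarded_normal_recheck`.
#' @export
realignment_recheck <- function(pairs, ref, lib, max_mismatch = 2) {
  empty <- pairs[0, , drop = FALSE]
  if (!nrow(pairs)) return(list(kept = pairs, discarded_normal_recheck = empty))
  if (is.null(pairs$seq1) || is.null(pairs$seq2)) {
    warning("read sequences absent; realignment recheck skipped")
    return(list(kept = pairs, discarded_normal_recheck = empty))
  }
  libs <- if (inherits(lib, "library_spec"))
    stats::setNames(list(lib), lib$name) else lib
  subject <- Biostrings::DNAStringSet(unclass(ref))

  placements <- function(seq) {
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") Biostrings::DNAString(seq)
             else Biostrings::reverseComplement(Biostrings::DNAString(seq))
      m <- Biostrings::vmatchPattern(pat, subject, max.mismatch = max_mismatch)
      for (ci in seq_along(m)) {
        st <- BiocGenerics::start(m[[ci]])
        if (!length(st)) next
        lo <- st - 1  # to 0-based
        pos5 <- if (strand == "+") lo else lo + nchar(seq) - 1
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = names(subject)[ci], pos5 = pos5, strand = strand)
      }
    }
    if (!length(hits)) return(NULL)
    do.call(rbind, hits)
  }

  concordant_alternative <- function(row) {
    p1 <- placements(row$seq1)
    p2 <- placements(row$seq2)
    if (is.null(p1) || is.null(p2)) return(FALSE)
    spec <- libs[[row$library]]
    for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
      a <- p1[i, ]; b <- p2[j, ]
      if (a$chrom != b$chrom) next
      lo <- if (a$pos5 <= b$pos5) a else b
      hi <- if (a$pos5 <= b$pos5) b else a
      if (lo$strand == "+" && hi$strand == "-" &&
          hi$pos5 - lo$pos5 + 1 >= spec$frag_min &&
          hi$pos5 - lo$pos5 + 1 <= spec$frag_max) return(TRUE)
    }
    FALSE
  }

  drop <- vapply(seq_len(nrow(pairs)), function(i)
    concordant_alternative(pairs[i, ]), logical(1))
  list(kept = pairs[!drop, , drop = FALSE],
       discarded_normal_recheck = pairs[drop, , drop = FALSE])
}

#' Run the full read-pair filter cascade
#'
#' Fixed stage order: mapping-quality filter, PCR-duplicate removal,
#' normal/aberrant classification, then (when read sequences are present)
#' the realignment recheck of aberrant pairs. Each input pair receives
#' exactly one label.
#'
#' @param pairs Read-pair data frame.
#' @param lib A [library_spec] or named list of them.
#' @param mapq_threshold,max_offset,max_mismatch Stage parameters.
#' @param recheck_ref Optional [ref_genome] enabling the realignment
#'   recheck.
#' @return List: `normal`, `aberrant`, `discarded_lowmapq`,
#'   `discarded_duplicate`, `discarded_normal_recheck`, and a `counts`
#'   vector.
#' @export
filter_cascade <- function(pairs, lib, mapq_threshold = 30, max_offset = 2,
                           recheck_ref = NULL, max_mismatch = 2) {
  mq <- filter_mapq(pairs, mapq_threshold)
  dd <- remove_duplicates(mq$kept, max_offset)
  cl <- classify_pairs(dd$unique, lib)
  normal <- cl[cl$class == "normal", , drop = FALSE]
  aberrant <- cl[cl$class == "aberrant", , drop = FALSE]
  rechecked <- aberrant[0, , drop = FALSE]
  if (!is.null(recheck_ref) && !is.null(pairs$seq1)) {
    rc <- realignment_recheck(aberrant, recheck_ref, lib, max_mismatch)
    aberrant <- rc$kept
    rechecked <- rc$discarded_normal_recheck
  }
  list(normal = normal, aberrant = aberrant,
       discarded_lowmapq = mq$discarded,
       discarded_duplicate = dd$duplicates,
       discarded_normal_recheck = rechecked,
       counts = c(input = nrow(pairs), post_mapq = nrow(mq$kept),
                  post_dedup = nrow(dd$unique), normal = nrow(normal),
                  aberrant = nrow(aberrant)))
}
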