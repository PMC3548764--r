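#' Cluster discordant pairs into junction candidates
#'
#' Two aberrant pairs are *consistent* when they share the contig pair and
#' orientation class and their implied breakpoint intervals overlap on
#' both ends. A read's implied interval extends from its 5' position in
#' the direction the read faces, by `frag_max - read_length` of its own
#' library (mixed-library clusters use each pair's own window). Candidates
#' are the maximal consistent groups (transitive closure of pairwise
#' consistency) with at least two supporting pairs; each breakend interval
#' is the intersection of the members' implied intervals.
#'
#' The breakend *side* follows from the read orientation: reads on `+`
#' face rightwards, so the flank left of the junction is retained
#' (`left_retained`); reads on `-` imply `right_retained`.
#'
#' @param pairs Aberrant read-pair data frame.
#' @param lib A [library_spec] or named list of them keyed by library.
#' @param min_support Minimum consistent pairs per emitted candidate.
#' @return Data frame of junction candidates: `id`, `chrom_a`, `lo_a`,
#'   `hi_a`, `strand_a`, `side_a`, (same for `b`), `support`, `libraries`,
#'   `n_libraries`, `span` (intra-chromosomal midpoint distance, `NA`
#'   otherwise), `pair_ids`.
#' @export
cluster_pairs <- function(pairs, lib, min_support = 2) {
  libs <- if (inherits(lib, "library_spec"))
    stats::setNames(list(lib), lib$name) else lib
  empty <- data.frame(id = character(0), chrom_a = character(0),
                      lo_a = numeric(0), hi_a = numeric(0),
                      strand_a = character(0), side_a = character(0),
                      chrom_b = character(0), lo_b = numeric(0),
                      hi_b = numeric(0), strand_b = character(0),
                      side_b = character(0), support = integer(0),
                      libraries = character(0), n_libraries = integer(0),
                      span = numeric(0), pair_ids = character(0))
  if (!nrow(pairs)) return(empty)

  w <- vapply(libs, function(s) s$frag_max - s$read_length, numeric(1))[
    match(pairs$library, names(libs))]
  imply <- function(pos, strand) {
    lo <- ifelse(strand == "+", pos, pos - w + 1)
    data.frame(lo = lo, hi = lo + w)
  }
  i1 <- imply(pairs$pos1, pairs$strand1)
  i2 <- imply(pairs$pos2, pairs$strand2)

  bucket <- paste(pairs$chrom1, pairs$strand1, pairs$chrom2, pairs$strand2,
                  sep = "\r")
  cands <- list()
  for (idx in split(seq_len(nrow(pairs)), bucket)) {
    m <- length(idx)
    o <- idx[order(i1$lo[idx])]
    if (m > 1) {
      lo1 <- i1$lo[o]; hi1 <- i1$hi[o]
      lo2 <- i2$lo[o]; hi2 <- i2$hi[o]
      parent <- seq_len(m)
      find <- function(i) {
        while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
        i
      }
      for (i in seq_len(m - 1)) {
        ri <- find(i)
        for (j in (i + 1):m) {
          if (lo1[j] >= hi1[i]) break
          if (lo2[j] < hi2[i] && lo2[i] < hi2[j]) {
            rj <- find(j)
            if (ri != rj) { parent[rj] <- ri }
          }
        }
      }
      comp <- vapply(seq_len(m), find, integer(1))
    } else comp <- 1L
    for (g in split(seq_len(m), comp)) {
      rows <- o[g]
      if (length(rows) < min_support) next
      lo_a <- max(i1$lo[rows]); hi_a <- min(i1$hi[rows])
      lo_b <- max(i2$lo[rows]); hi_b <- min(i2$hi[rows])
      if (hi_a <= lo_a) hi_a <- lo_a + 1  # degenerate intersection guard
      if (hi_b <= lo_b) hi_b <- lo_b + 1
      r1 <- pairs[rows[1], ]
      cands[[length(cands) + 1L]] <- data.frame(
        id = NA_character_, chrom_a = r1$chrom1, lo_a = lo_a, hi_a = hi_a,
        strand_a = r1$strand1,
        side_a = ifelse(r1$strand1 == "+", "left_retained", "right_retained"),
        chrom_b = r1$chrom2, lo_b = lo_b, hi_b = hi_b, strand_b = r1$strand2,
        side_b = ifelse(r1$strand2 == "+", "left_retained", "right_retained"),
        support = length(rows),
        libraries = paste(sort(unique(pairs$library[rows])), collapse = ","),
        n_libraries = length(unique(pairs$library[rows])),
        span = if (r1$chrom1 == r1$chrom2)
          abs(interval_mid(lo_b, hi_b) - interval_mid(lo_a, hi_a)) else NA_real_,
        pair_ids = paste(pairs$pair_id[rows], collapse = ","))
    }
  }
  if (!length(cands)) return(empty)
  out <- do.call(rbind, cands)
  out <- out[order(out$chrom_a, out$lo_a, out$chrom_b, out$lo_b), , drop = FALSE]
  out$id <- sprintf("J%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Filter cascade on junction candidates
#'
#' Removal rules, with per-candidate reasons recorded:
#' * `min_span` - intra-chromosomal candidates spanning less than
#'   `min_span` bp (strictly less: a span of exactly `min_span` is kept);
#'   inter-chromosomal candidates are never removed by this rule;
#' * `panel` - candidates matching a panel-of-normals junction (same
#'   orientation class, both breakend midpoints within `panel_tol` bp);
#' * `blacklist` - intra-chromosomal deletion/duplication-type candidates
#'   whose spanned interval reciprocally overlaps a known copy-number
#'   variant interval by at least 50%.
#'
#' @param candidates Candidates from [cluster_pairs()].
#' @param cnv_blacklist Data frame (`chrom`, `start`, `end`) or `NULL`.
#' @param panel Panel data frame (see [build_panel_of_normals()]) or `NULL`.
#' @param min_span Minimum intra-chromosomal span (bp).
#' @param panel_tol Breakend tolerance for panel matching (bp); use the
#'   `frag_max` of the widest contributing library.
#' @return List with `kept` and `removed` (the latter with a `reasons`
#'   column).
#' @export
apply_filters <- function(candidates, cnv_blacklist = NULL, panel = NULL,
                          min_span = 10000, panel_tol = 619) {
  n <- nrow(candidates)
  reasons <- vector("list", n)
  if (!is.null(cnv_blacklist) && nrow(cnv_blacklist)) {
    if (is.null(cnv_blacklist$chrom) || is.null(cnv_blacklist$start) ||
        is.null(cnv_blacklist$end) ||
        any(cnv_blacklist$end <= cnv_blacklist$start))
      svf_stop("malformed blacklist interval", "svfuse_input_error")
  }
  mid_a <- interval_mid(candidates$lo_a, candidates$hi_a)
  mid_b <- interval_mid(candidates$lo_b, candidates$hi_b)
  for (i in seq_len(n)) {
    r <- character(0)
    intra <- candidates$chrom_a[i] == candidates$chrom_b[i]
    if (intra && !is.na(candidates$span[i]) && candidates$span[i] < min_span)
      r <- c(r, "min_span")
    if (!is.null(panel) && nrow(panel)) {
      hit <- panel$chrom1 == candidates$chrom_a[i] &
        panel$chrom2 == candidates$chrom_b[i] &
        panel$strand1 == candidates$strand_a[i] &
        panel$strand2 == candidates$strand_b[i] &
        abs(panel$pos1 - mid_a[i]) <= panel_tol &
        abs(panel$pos2 - mid_b[i]) <= panel_tol
      if (any(hit)) r <- c(r, "panel")
    }
    if (!is.null(cnv_blacklist) && nrow(cnv_blacklist) && intra) {
      deldup <- (candidates$strand_a[i] == "+" & candidates$strand_b[i] == "-") |
        (candidates$strand_a[i] == "-" & candidates$strand_b[i] == "+")
      if (deldup) {
        lo <- min(mid_a[i], mid_b[i]); hi <- max(mid_a[i], mid_b[i])
        bl <- cnv_blacklist[cnv_blacklist$chrom == candidates$chrom_a[i], ,
                            drop = FALSE]
        if (nrow(bl)) {
          ov <- pmax(0, pmin(hi, bl$end) - pmax(lo, bl$start))
          recip <- ov / (hi - lo) >= 0.5 & ov / (bl$end - bl$start) >= 0.5
          if (any(recip)) r <- c(r, "blacklist")
        }
      }
    }
    reasons[[i]] <- r
  }
  removed <- lengths(reasons) > 0
  out_removed <- candidates[removed, , drop = FALSE]
  out_removed$reasons <- vapply(reasons[removed], paste, character(1),
                                collapse = ",")
  list(kept = candidates[!removed, , drop = FALSE], removed = out_removed)
}

#' Confirm candidates by multi-library support or copy-number steps
#'
#' A candidate is confirmed `multi_library` when supported by reads from
#' at least two libraries; otherwise `cn_step` when at least one breakend
#' midpoint lies within `step_tolerance` of a copy-number step (one
#' matching breakend suffices, since the partner of a balanced junction
#' leaves no step); otherwise it is retained but flagged `unconfirmed`
#' (mirroring downstream wet-lab follow-up, which is out of scope here).
#'
#' @param candidates Filtered candidates.
#' @param cn_steps Steps from [detect_steps()]; pass extra independently
#'   mapped breakpoints (e.g. from chromosome-sorting experiments) as
#'   additional pseudo-step rows if available.
#' @param step_tolerance Breakend-to-step distance tolerance (bp).
#' @return `candidates` with `confirmation` and `matched_steps` columns.
#' @export
confirm_candidates <- function(candidates, cn_steps = NULL,
                               step_tolerance = 10000) {
  n <- nrow(candidates)
  conf <- character(n)
  matched <- character(n)
  for (i in seq_len(n)) {
    if (candidates$n_libraries[i] >= 2) {
      conf[i] <- "multi_library"; matched[i] <- ""
      next
    }
    hits <- character(0)
    if (!is.null(cn_steps) && nrow(cn_steps)) {
      for (side in c("a", "b")) {
        mid <- interval_mid(candidates[[paste0("lo_", side)]][i],
                            candidates[[paste0("hi_", side)]][i])
        chrom <- candidates[[paste0("chrom_", side)]][i]
        sm <- interval_mid(cn_steps$start, cn_steps$end)
        hit <- cn_steps$chrom == chrom & abs(sm - mid) <= step_tolerance
        if (any(hit)) hits <- c(hits, sprintf("%s:%0.0f", side, sm[hit]))
      }
    }
    conf[i] <- if (length(hits)) "cn_step" else "unconfirmed"
    matched[i] <- paste(hits, collapse = ",")
  }
  candidates$confirmation <- conf
  candidates$matched_steps <- matched
  candidates
}

#' Run the junction-calling pipeline
#'
#' Orchestrates the read-pair filter cascade, clustering, candidate
#' filtering, copy-number segmentation and confirmation, and returns the
#' confirmed candidate set with a stage-count run report (the
#' candidates-to-confirmed funnel).
#'
#' @param pairs Read-pair data frame (one or several libraries).
#' @param lib A [library_spec] or named list of them.
#' @param cnv_blacklist,panel Filter inputs (see [apply_filters()]).
#' @param cn_profile Probe profile for [segment_profile()], or `NULL` to
#'   skip copy-number confirmation.
#' @param config Named list of thresholds, as produced by
#'   [default_config()]: `mapq_threshold` (30), `dedup_max_offset_bp` (2),
#'   `min_support_pairs` (2), `min_span_intra_bp` (10000),
#'   `cn_step_threshold_log2` (0.3), `cn_min_probes` (5),
#'   `step_match_tolerance_bp` (10000).
#' @param recheck_ref Optional [ref_genome] enabling the realignment
#'   recheck (requires read sequences).
#' @return List: `candidates` (confirmed/flagged set), `removed`,
#'   `steps`, `report` (named count vector).
#' @export
call_pipeline <- function(pairs, lib, cnv_blacklist = NULL, panel = NULL,
                          cn_profile = NULL, config = list(),
                          recheck_ref = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  libs <- if (inherits(lib, "library_spec"))
    stats::setNames(list(lib), lib$name) else lib
  panel_tol <- max(vapply(libs, function(s) s$frag_max, numeric(1)))

  fc <- filter_cascade(pairs, libs, cfg$mapq_threshold, cfg$dedup_max_offset_bp,
                       recheck_ref)
  cands <- cluster_pairs(fc$aberrant, libs, cfg$min_support_pairs)
  fl <- apply_filters(cands, cnv_blacklist, panel, cfg$min_span_intra_bp,
                      panel_tol)
  steps <- NULL
  if (!is.null(cn_profile)) {
    segs <- segment_profile(cn_profile, cfg$cn_step_threshold_log2,
                            cfg$cn_min_probes)
    steps <- detect_steps(segs, cfg$cn_step_threshold_log2)
  }
  conf <- confirm_candidates(fl$kept, steps, cfg$step_match_tolerance_bp)
  report <- c(fc$counts,
              clusters = nrow(cands),
              post_filter = nrow(fl$kept),
              confirmed = sum(conf$confirmation != "unconfirmed"))
  list(candidates = conf, removed = fl$removed, steps = steps,
       report = report)
}
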