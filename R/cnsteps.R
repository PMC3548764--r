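#' Segment a probe profile into copy-number segments
#'
#' Transparent recursive binary segmentation: at each step the split
#' maximising the absolute difference of flanking means is accepted while
#' the difference is at least `step_threshold` and both sides keep at
#' least `min_probes` probes. Piecewise-constant, deterministic, splits
#' reported in probe order. Chromosomes with fewer than `2 * min_probes`
#' probes yield a single segment with a warning.
#'
#' @param profile Data frame (`chrom`, `pos`, `log2_ratio`), sorted by
#'   (chrom, pos).
#' @param step_threshold Minimum |difference of segment means| (log2).
#' @param min_probes Minimum probes per segment.
#' @return Data frame (`chrom`, `start`, `end`, `n_probes`, `mean_log2`,
#'   `first_pos`, `last_pos`), segments tiling each chromosome's probed
#'   span.
#' @export
segment_profile <- function(profile, step_threshold = 0.3, min_probes = 5) {
  stopifnot(all(c("chrom", "pos", "log2_ratio") %in% names(profile)))
  out <- list()
  for (chrom in unique(profile$chrom)) {
    p <- profile[profile$chrom == chrom, , drop = FALSE]
    p <- p[order(p$pos), , drop = FALSE]
    x <- p$log2_ratio
    n <- length(x)
    cuts <- integer(0)  # last probe index of each accepted left part
    if (n < 2 * min_probes) {
      warning(sprintf("contig '%s': %d probes < 2*min_probes; single segment",
                      chrom, n))
    } else {
      segment_rec <- function(lo, hi) {
        n_seg <- hi - lo + 1
        if (n_seg < 2 * min_probes) return(invisible())
        cs <- cumsum(x[lo:hi])
        ks <- min_probes:(n_seg - min_probes)
        left_mean <- cs[ks] / ks
        right_mean <- (cs[n_seg] - cs[ks]) / (n_seg - ks)
        d <- abs(left_mean - right_mean)
        best <- which.max(d)
        if (d[best] < step_threshold) return(invisible())
        k <- lo + ks[best] - 1
        cuts <<- c(cuts, k)
        segment_rec(lo, k)
        segment_rec(k + 1, hi)
      }
      segment_rec(1L, n)
    }
    # segment probe-index ranges
    starts <- sort(unique(c(1L, cuts + 1L)))
    ends <- c(starts[-1] - 1L, n)
    for (s in seq_along(starts)) {
      i0 <- starts[s]; i1 <- ends[s]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = p$pos[i0], end = p$pos[i1] + 1,
        n_probes = i1 - i0 + 1L, mean_log2 = mean(x[i0:i1]),
        first_pos = p$pos[i0], last_pos = p$pos[i1])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract copy-number steps from segments
#'
#' One step per adjacent segment pair on the same chromosome whose mean
#' log2 ratios differ by at least `step_threshold`. The step interval runs
#' from the last probe of the left segment to the first probe of the right
#' segment (half-open), localising the change-point to one probe gap.
#'
#' @param segments Output of [segment_profile()].
#' @param step_threshold Minimum |delta log2| to report a step.
#' @return Data frame (`chrom`, `start`, `end`, `delta_log2`, `direction`).
#' @export
detect_steps <- function(segments, step_threshold = 0.3) {
  out <- list()
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2) next
    for (k in seq_len(nrow(s) - 1)) {
      d <- s$mean_log2[k + 1] - s$mean_log2[k]
      if (abs(d) < step_threshold) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s$last_pos[k], end = s$first_pos[k + 1],
        delta_log2 = d, direction = if (d > 0) "up" else "down")
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), delta_log2 = numeric(0),
                      direction = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match a junction candidate to copy-number steps
#'
#' A step matches when it lies on the same chromosome as a breakend and
#' the distance between the breakend midpoint and the step interval
#' midpoint is at most `tolerance`. Matching is monotone in `tolerance`.
#'
#' @param candidate One-row candidate data frame (see [cluster_pairs()]).
#' @param steps Steps from [detect_steps()].
#' @param tolerance Distance tolerance (bp).
#' @return The matching rows of `steps` (possibly none), with a
#'   `matched_breakend` column (`"a"`/`"b"`).
#' @export
match_junction_to_steps <- function(candidate, steps, tolerance = 10000) {
  hits <- list()
  for (side in c("a", "b")) {
    mid <- interval_mid(candidate[[paste0("lo_", side)]],
                        candidate[[paste0("hi_", side)]])
    chrom <- candidate[[paste0("chrom_", side)]]
    sm <- interval_mid(steps$start, steps$end)
    hit <- steps$chrom == chrom & abs(sm - mid) <= tolerance
    if (any(hit)) {
      h <- steps[hit, , drop = FALSE]
      h$matched_breakend <- side
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) {
    out <- steps[0, , drop = FALSE]
    out$matched_breakend <- character(0)
    return(out)
  }
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res
}

#' Detection sensitivity stratified by amplification
#'
#' Compares confirmed candidates against the simulator's truth junctions:
#' a truth junction is detected when some confirmed candidate matches its
#' contig pair and has both breakend midpoints within `match_tol` of the
#' truth positions. Reports detected/total fractions separately for
#' junctions below and at/above the amplification threshold, mirroring
#' the contrast between single-copy and amplified breakpoints.
#'
#' @param truth Truth data frame from [plant_rearrangements()].
#' @param candidates Confirmed candidates (rows where `confirmation` is
#'   not `"unconfirmed"` are used; pass `confirmed_only = FALSE` to count
#'   all candidates).
#' @param amplified_threshold Copy number at/above which a junction counts
#'   as amplified.
#' @param match_tol Breakend distance tolerance (bp); use the widest
#'   library `frag_max`.
#' @param confirmed_only Restrict to confirmed candidates.
#' @return List with `unamplified` and `amplified` entries
#'   (`detected`, `total`, `fraction`) and the per-junction `detected`
#'   logical vector.
#' @export
sensitivity_report <- function(truth, candidates, amplified_threshold = 5,
                               match_tol = 619, confirmed_only = TRUE) {
  if (!nrow(truth))
    svf_stop("empty truth set: sensitivity is undefined", "svfuse_input_error")
  cc <- candidates
  if (confirmed_only && !is.null(cc$confirmation))
    cc <- cc[cc$confirmation != "unconfirmed", , drop = FALSE]
  detected <- vapply(seq_len(nrow(truth)), function(i) {
    truth_matched(truth[i, ], cc, match_tol)
  }, logical(1))
  strat <- function(sel) {
    list(detected = sum(detected[sel]), total = sum(sel),
         fraction = if (sum(sel)) sum(detected[sel]) / sum(sel) else NA_real_)
  }
  amp <- truth$copy_number >= amplified_threshold
  list(unamplified = strat(!amp), amplified = strat(amp), detected = detected)
}

# Does any candidate match this truth junction (both breakends within tol)?
truth_matched <- function(tr, candidates, match_tol) {
  if (!nrow(candidates)) return(FALSE)
  mid_a <- interval_mid(candidates$lo_a, candidates$hi_a)
  mid_b <- interval_mid(candidates$lo_b, candidates$hi_b)
  same <- candidates$chrom_a == tr$chrom_a & candidates$chrom_b == tr$chrom_b &
    abs(mid_a - tr$pos_a) <= match_tol & abs(mid_b - tr$pos_b) <= match_tol
  swap <- candidates$chrom_a == tr$chrom_b & candidates$chrom_b == tr$chrom_a &
    abs(mid_a - tr$pos_b) <= match_tol & abs(mid_b - tr$pos_a) <= match_tol
  any(same | swap)
}
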