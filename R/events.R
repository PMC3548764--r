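#' Rearrangement event constructors
#'
#' Events describe how derivative chromosomes are built from reference
#' segments. Each event yields one derivative contig (an ordered list of
#' oriented reference segments, possibly with sequence inserted at the
#' junctions) carried at an integer copy number, and consumes copies of
#' the baseline homologues it rearranges.
#'
#' * `sv_deletion()` joins the two flanks of an interstitial deletion.
#' * `sv_inversion()` inverts an internal interval (balanced; two junctions).
#' * `sv_tandem_dup()` repeats an interval head-to-tail (one junction).
#' * `sv_translocation()` joins the left part of one chromosome to the
#'   right part of another (unbalanced unless `reciprocal = TRUE`).
#' * `sv_amplicon()` strings arbitrary oriented fragments together at a
#'   high copy number, emulating the multi-fragment coamplifications seen
#'   in breast cancer genomes; the fragments' baseline copies are consumed
#'   so the planted copy number is the total at those loci.
#'
#' `inserts` attaches sequence at a junction: a named list whose names are
#' adjacency indices ("1" = between the first and second segment) and whose
#' elements are either `list(seq = "ACGT...")` (non-templated insertion) or
#' `list(shard = c(chrom, start, end))` (a genomic shard copied from
#' elsewhere in the reference).
#'
#' @param chrom,start,end,chrom_a,pos_a,chrom_b,pos_b Reference coordinates
#'   (0-based half-open).
#' @param event_id Identifier; junction ids are derived from it.
#' @param copy_number Copies of the derivative contig (>= 1).
#' @param fragments Data frame (`chrom`, `start`, `end`, `strand`).
#' @param reciprocal Also emit the reciprocal derivative chromosome.
#' @param inserts See Details.
#' @return An `sv_event` object.
#' @name sv_events
NULL

new_event <- function(kind, event_id, copy_number, inserts = NULL, ...) {
  if (copy_number < 1)
    svf_stop("copy_number must be >= 1", "svfuse_parameter_error")
  structure(list(kind = kind, event_id = event_id,
                 copy_number = as.integer(copy_number),
                 inserts = inserts, ...),
            class = "sv_event")
}

#' @rdname sv_events
#' @export
sv_deletion <- function(chrom, start, end, event_id, inserts = NULL) {
  stopifnot(end > start)
  new_event("deletion", event_id, 1L, inserts,
            chrom = chrom, start = start, end = end)
}

#' @rdname sv_events
#' @export
sv_inversion <- function(chrom, start, end, event_id, inserts = NULL) {
  stopifnot(end > start)
  new_event("inversion", event_id, 1L, inserts,
            chrom = chrom, start = start, end = end)
}

#' @rdname sv_events
#' @export
sv_tandem_dup <- function(chrom, start, end, event_id, inserts = NULL) {
  stopifnot(end > start)
  new_event("tandem_dup", event_id, 1L, inserts,
            chrom = chrom, start = start, end = end)
}

#' @rdname sv_events
#' @export
sv_translocation <- function(chrom_a, pos_a, chrom_b, pos_b, event_id,
                             reciprocal = FALSE, inserts = NULL) {
  new_event("translocation", event_id, 1L, inserts,
            chrom_a = chrom_a, pos_a = pos_a,
            chrom_b = chrom_b, pos_b = pos_b, reciprocal = reciprocal)
}

#' @rdname sv_events
#' @export
sv_amplicon <- function(fragments, copy_number, event_id, inserts = NULL) {
  fragments <- as.data.frame(fragments)
  if (is.null(fragments$strand)) fragments$strand <- "+"
  new_event("amplicon_fragment", event_id, copy_number, inserts,
            fragments = fragments)
}

# Resolve an event into one or more derivative contig segment tables and
# the baseline consumption it implies. `lens` is the contig length map.
event_layout <- function(ev, lens, ploidy) {
  seg <- function(chrom, start, end, strand = "+") {
    data.frame(chrom = chrom, start = start, end = end, strand = strand)
  }
  L <- function(chrom) {
    if (!chrom %in% names(lens))
      svf_stop(sprintf("unknown contig '%s' in event '%s'", chrom, ev$event_id),
               "svfuse_input_error")
    lens[[chrom]]
  }
  switch(ev$kind,
    deletion = {
      list(contigs = list(rbind(seg(ev$chrom, 0, ev$start),
                                seg(ev$chrom, ev$end, L(ev$chrom)))),
           consume = seg(ev$chrom, 0, L(ev$chrom))[, 1:3] |>
             transform(n = 1))
    },
    inversion = {
      list(contigs = list(rbind(seg(ev$chrom, 0, ev$start),
                                seg(ev$chrom, ev$start, ev$end, "-"),
                                seg(ev$chrom, ev$end, L(ev$chrom)))),
           consume = seg(ev$chrom, 0, L(ev$chrom))[, 1:3] |>
             transform(n = 1))
    },
    tandem_dup = {
      list(contigs = list(rbind(seg(ev$chrom, 0, ev$end),
                                seg(ev$chrom, ev$start, L(ev$chrom)))),
           consume = seg(ev$chrom, 0, L(ev$chrom))[, 1:3] |>
             transform(n = 1))
    },
    translocation = {
      contigs <- list(rbind(seg(ev$chrom_a, 0, ev$pos_a),
                            seg(ev$chrom_b, ev$pos_b, L(ev$chrom_b))))
      if (isTRUE(ev$reciprocal))
        contigs <- c(contigs, list(rbind(seg(ev$chrom_b, 0, ev$pos_b),
                                         seg(ev$chrom_a, ev$pos_a, L(ev$chrom_a)))))
      consume <- rbind(transform(seg(ev$chrom_a, 0, L(ev$chrom_a))[, 1:3], n = 1),
                       transform(seg(ev$chrom_b, 0, L(ev$chrom_b))[, 1:3], n = 1))
      list(contigs = contigs, consume = consume)
    },
    amplicon_fragment = {
      fr <- ev$fragments
      for (k in seq_len(nrow(fr))) L(fr$chrom[k])  # bounds-check contig names
      list(contigs = list(fr[, c("chrom", "start", "end", "strand")]),
           consume = transform(fr[, c("chrom", "start", "end")], n = ploidy))
    },
    svf_stop(sprintf("unknown event kind '%s'", ev$kind), "svfuse_parameter_error")
  )
}

resolve_insert <- function(ins, ref) {
  if (is.null(ins)) return("")
  if (!is.null(ins$seq)) return(toupper(ins$seq))
  if (!is.null(ins$shard)) {
    sh <- ins$shard
    return(ref_subseq(ref, sh[[1]], as.numeric(sh[[2]]), as.numeric(sh[[3]])))
  }
  svf_stop("insert must carry `seq` or `shard`", "svfuse_parameter_error")
}

oriented_segment_seq <- function(ref, chrom, start, end, strand) {
  s <- ref_subseq(ref, chrom, start, end)
  if (strand == "-") revcomp(s) else s
}

# Maximal L such that the last L bases retained on the 5' side equal the
# first L bases retained on the 3' side (ambiguous-placement definition).
mh_scan <- function(flank5, flank3, max_l = 20) {
  lim <- min(nchar(flank5), nchar(flank3), max_l)
  for (L in rev(seq_len(lim))) {
    if (substr(flank5, nchar(flank5) - L + 1, nchar(flank5)) ==
        substr(flank3, 1, L)) return(L)
  }
  0L
}

#' Plant rearrangements into a reference genome
#'
#' Builds the derivative genome implied by a set of events: per-event
#' derivative contigs (ordered oriented segment lists with realized
#' sequence available via [derivative_sequence()]), the remaining baseline
#' homologue copy number along each reference chromosome, the ground-truth
#' junction table (one record per non-reference segment adjacency), and a
#' piecewise total copy-number map used by [simulate_cgh()].
#'
#' Baseline bookkeeping: unbalanced events consume one homologue of the
#' chromosomes they rearrange; amplicon fragments consume all baseline
#' copies of the fragment loci so that the planted copy number is the
#' total copy number there. Events that would drive the baseline negative
#' at any base raise a conflict error.
#'
#' @param ref A [ref_genome].
#' @param events List of [sv_events] objects.
#' @param ploidy Baseline copy number of every reference chromosome.
#' @param seed Unused at present (planting is deterministic); kept so all
#'   generators share a signature.
#' @return A `derivative` object: list with elements `ref`, `ploidy`,
#'   `contigs`, `baseline`, `truth`, `cn_map`.
#' @export
plant_rearrangements <- function(ref, events, ploidy = 2, seed = NULL) {
  lens <- contig_lengths(ref)
  ids <- vapply(events, function(e) e$event_id, character(1))
  if (anyDuplicated(ids))
    svf_stop("event ids must be unique", "svfuse_parameter_error")

  consume <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), n = numeric(0))
  contigs <- list()
  truth <- list()

  for (ev in events) {
    lay <- event_layout(ev, lens, ploidy)
    # bounds checks on all segments
    for (ct in lay$contigs) {
      bad <- ct$start < 0 | ct$end > lens[ct$chrom] | ct$start >= ct$end
      if (any(bad))
        svf_stop(sprintf("event '%s' has segment(s) out of reference bounds",
                         ev$event_id), "svfuse_bounds_error")
    }
    consume <- rbind(consume, lay$consume)

    for (ci in seq_along(lay$contigs)) {
      segs <- lay$contigs[[ci]]
      der_name <- if (length(lay$contigs) > 1)
        sprintf("%s_der%d", ev$event_id, ci) else ev$event_id
      # interleave inserts (only on the first/primary contig of an event)
      elements <- list()
      for (k in seq_len(nrow(segs))) {
        elements[[length(elements) + 1L]] <-
          data.frame(kind = "segment", chrom = segs$chrom[k],
                     start = segs$start[k], end = segs$end[k],
                     strand = segs$strand[k], seq = NA_character_,
                     len = segs$end[k] - segs$start[k])
        if (k < nrow(segs) && ci == 1L) {
          ins <- resolve_insert(ev$inserts[[as.character(k)]], ref)
          if (nzchar(ins))
            elements[[length(elements) + 1L]] <-
              data.frame(kind = "insert", chrom = NA_character_,
                         start = NA_real_, end = NA_real_, strand = "+",
                         seq = ins, len = nchar(ins))
        }
      }
      el <- do.call(rbind, elements)
      el$der_start <- cumsum(c(0, el$len))[seq_len(nrow(el))]
      contigs[[der_name]] <- list(name = der_name, copy = ev$copy_number,
                                  elements = el, length = sum(el$len),
                                  event_id = ev$event_id)

      # truth records: one per adjacency between consecutive segments
      seg_rows <- which(el$kind == "segment")
      jn <- 0L
      for (k in seq_len(length(seg_rows) - 1L)) {
        a <- el[seg_rows[k], ]
        b <- el[seg_rows[k + 1L], ]
        mid <- if (seg_rows[k + 1L] - seg_rows[k] > 1L)
          el[seg_rows[k] + 1L, ] else NULL
        inserted <- if (is.null(mid)) "" else mid$seq
        # skip reference-contiguous adjacencies (no junction)
        if (!nzchar(inserted) && a$chrom == b$chrom &&
            a$strand == b$strand &&
            ((a$strand == "+" && a$end == b$start) ||
             (a$strand == "-" && a$start == b$end))) next
        jn <- jn + 1L
        be_a <- if (a$strand == "+")
          list(chrom = a$chrom, pos = a$end, side = "left_retained")
        else list(chrom = a$chrom, pos = a$start, side = "right_retained")
        be_b <- if (b$strand == "+")
          list(chrom = b$chrom, pos = b$start, side = "right_retained")
        else list(chrom = b$chrom, pos = b$end, side = "left_retained")
        mh <- 0L
        if (!nzchar(inserted)) {
          f5 <- oriented_segment_seq(ref, a$chrom,
                                     max(a$start, if (a$strand == "+") a$end - 20 else a$start),
                                     if (a$strand == "+") a$end else min(a$end, a$start + 20),
                                     a$strand)
          f3 <- oriented_segment_seq(ref, b$chrom,
                                     if (b$strand == "+") b$start else max(b$start, b$end - 20),
                                     if (b$strand == "+") min(b$end, b$start + 20) else b$end,
                                     b$strand)
          mh <- mh_scan(f5, f3)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          junction_id = sprintf("%s_j%d", der_name, jn),
          chrom_a = be_a$chrom, pos_a = be_a$pos, side_a = be_a$side,
          chrom_b = be_b$chrom, pos_b = be_b$pos, side_b = be_b$side,
          copy_number = ev$copy_number, event_id = ev$event_id,
          inserted_seq = inserted, microhomology_len = mh,
          der_name = der_name,
          der_pos = if (is.null(mid)) b$der_start else mid$der_start)
      }
    }
  }

  # baseline homologue copies per chromosome, piecewise
  baseline <- do.call(rbind, lapply(names(lens), function(chrom) {
    d <- consume[consume$chrom == chrom, , drop = FALSE]
    pw <- piecewise_profile(lens[[chrom]], ploidy,
                            data.frame(start = d$start, end = d$end,
                                       delta = -d$n))
    if (any(pw$value < 0))
      svf_stop(sprintf(
        "conflicting events over-consume baseline copies on contig '%s'", chrom),
        "svfuse_conflict_error")
    data.frame(chrom = chrom, start = pw$start, end = pw$end, copy = pw$value)
  }))

  # total copy-number map: baseline plus derivative segment coverage
  der_cov <- do.call(rbind, lapply(contigs, function(ct) {
    el <- ct$elements[ct$elements$kind == "segment", , drop = FALSE]
    data.frame(chrom = el$chrom, start = el$start, end = el$end,
               delta = ct$copy)
  }))
  cn_map <- do.call(rbind, lapply(names(lens), function(chrom) {
    d1 <- consume[consume$chrom == chrom, , drop = FALSE]
    d2 <- der_cov[der_cov$chrom == chrom, , drop = FALSE]
    deltas <- rbind(
      data.frame(start = d1$start, end = d1$end, delta = -d1$n),
      data.frame(start = d2$start, end = d2$end, delta = d2$delta))
    pw <- piecewise_profile(lens[[chrom]], ploidy, deltas)
    data.frame(chrom = chrom, start = pw$start, end = pw$end, cn = pw$value)
  }))

  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    junction_id = character(0), chrom_a = character(0), pos_a = numeric(0),
    side_a = character(0), chrom_b = character(0), pos_b = numeric(0),
    side_b = character(0), copy_number = integer(0), event_id = character(0),
    inserted_seq = character(0), microhomology_len = integer(0),
    der_name = character(0), der_pos = numeric(0))
  rownames(truth) <- NULL

  structure(list(ref = ref, ploidy = ploidy, contigs = contigs,
                 baseline = baseline, truth = truth, cn_map = cn_map),
            class = "derivative")
}

#' @export
print.derivative <- function(x, ...) {
  cat(sprintf("<derivative> %d derived contig(s), %d truth junction(s), ploidy %d\n",
              length(x$contigs), nrow(x$truth), x$ploidy))
  invisible(x)
}

#' Realized sequence of a derivative contig
#'
#' @param der A `derivative` from [plant_rearrangements()].
#' @param name Derivative contig name.
#' @return A character DNA string.
#' @export
derivative_sequence <- function(der, name) {
  ct <- der$contigs[[name]]
  if (is.null(ct))
    svf_stop(sprintf("unknown derivative contig '%s'", name), "svfuse_input_error")
  el <- ct$elements
  parts <- vapply(seq_len(nrow(el)), function(k) {
    if (el$kind[k] == "insert") el$seq[k]
    else oriented_segment_seq(der$ref, el$chrom[k], el$start[k], el$end[k],
                              el$strand[k])
  }, character(1))
  paste(parts, collapse = "")
}
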