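#' Extract the sequence across a resolved junction
#'
#' Returns the reference flanks on either side of a base-resolved junction
#' (oriented as they appear in the derivative) and the observed derivative
#' sequence across it. Needs coordinates resolved to base precision:
#' simulator truth records qualify; clustered candidates (whose breakends
#' are intervals) do not, and raise an error directing the user to supply
#' resolved coordinates.
#'
#' @param junction A one-row truth record from [plant_rearrangements()]
#'   (fields `chrom_a`, `pos_a`, `side_a`, `chrom_b`, `pos_b`, `side_b`,
#'   `der_name`, `der_pos`, `inserted_seq`), or an equivalent list.
#' @param der The `derivative` the junction belongs to.
#' @param flank Flank length in bp (> 0).
#' @return List (`junction_id`, `flank5`, `flank3`, `observed`,
#'   `inserted`): `observed` is read out of the realized derivative contig
#'   and spans `flank` bases each side of the junction plus any insertion.
#' @export
extract_junction_sequence <- function(junction, der, flank = 200) {
  if (flank <= 0)
    svf_stop("flank must be > 0", "svfuse_parameter_error")
  if (!is.null(junction$lo_a))
    svf_stop(paste("breakends are intervals, not base-resolved positions;",
                   "supply resolved junction coordinates (e.g. simulator truth)"),
             "svfuse_input_error")
  ref <- der$ref
  or_flank <- function(chrom, pos, side) {
    L <- contig_lengths(ref)[[chrom]]
    if (pos < 0 || pos > L)
      svf_stop(sprintf("junction position %s off the end of contig '%s'",
                       pos, chrom), "svfuse_bounds_error")
    if (side == "left_retained") ref_subseq(ref, chrom, max(0, pos - flank), pos)
    else revcomp(ref_subseq(ref, chrom, pos, min(L, pos + flank)))
  }
  # flank5: retained side-A sequence as it reads into the junction;
  # flank3: retained side-B sequence reading away from it.
  f5 <- or_flank(junction$chrom_a, junction$pos_a, junction$side_a)
  f3 <- if (junction$side_b == "right_retained") {
    ref_subseq(ref, junction$chrom_b, junction$pos_b,
               min(contig_lengths(ref)[[junction$chrom_b]],
                   junction$pos_b + flank))
  } else {
    revcomp(ref_subseq(ref, junction$chrom_b, max(0, junction$pos_b - flank),
                       junction$pos_b))
  }
  ins <- junction$inserted_seq %||% ""
  if (is.na(ins)) ins <- ""
  der_seq <- derivative_sequence(der, junction$der_name)
  lo <- max(0, junction$der_pos - flank)
  hi <- min(nchar(der_seq), junction$der_pos + nchar(ins) + flank)
  observed <- substr(der_seq, lo + 1, hi)
  list(junction_id = junction$junction_id %||% "junction",
       flank5 = f5, flank3 = f3, observed = observed, inserted = ins)
}

#' Measure junction microhomology
#'
#' Microhomology is the length of the ambiguity in breakpoint placement:
#' the maximal `L >= 0` such that the last `L` retained reference bases on
#' the 5' side equal the first `L` retained reference bases on the 3'
#' side. When `observed` is supplied and carries inserted sequence between
#' the flanks, the junction is classed as inserted and microhomology is 0
#' (the categories blunt / microhomologous / inserted are exclusive).
#'
#' @param flank5,flank3 Retained reference flanks, oriented as in the
#'   derivative (5' flank reading into the junction, 3' flank away).
#' @param observed Optional observed sequence across the junction; must
#'   begin with a suffix of `flank5` and end with a prefix of `flank3`.
#' @param max_l Longest homology considered.
#' @return List (`mh_len`, `inserted`).
#' @export
measure_microhomology <- function(flank5, flank3, observed = NULL, max_l = 20) {
  inserted <- ""
  if (!is.null(observed) && nzchar(observed)) {
    # longest prefix of observed that matches a suffix of flank5
    pre <- 0L
    lim5 <- min(nchar(observed), nchar(flank5))
    for (L in rev(seq_len(lim5))) {
      if (substr(observed, 1, L) ==
          substr(flank5, nchar(flank5) - L + 1, nchar(flank5))) { pre <- L; break }
    }
    suf <- 0L
    lim3 <- min(nchar(observed), nchar(flank3))
    for (L in rev(seq_len(lim3))) {
      if (substr(observed, nchar(observed) - L + 1, nchar(observed)) ==
          substr(flank3, 1, L)) { suf <- L; break }
    }
    if (pre == 0L || suf == 0L)
      svf_stop("observed sequence does not align to the supplied flanks",
               "svfuse_analysis_error")
    if (pre + suf < nchar(observed))
      inserted <- substr(observed, pre + 1, nchar(observed) - suf)
  }
  if (nzchar(inserted)) return(list(mh_len = 0L, inserted = inserted))
  list(mh_len = mh_scan(flank5, flank3, max_l), inserted = "")
}

#' Locate the origin of inserted junction sequence (genomic shard)
#'
#' Searches the reference (both strands, exact matches only) for the
#' inserted sequence. A unique hit of length at least `shard_min_len`
#' identifies the shard locus; shorter inserts are treated as
#' non-templated, and ambiguous (multi-locus) or absent matches return no
#' locus with the reason recorded.
#'
#' @param inserted Inserted DNA string (non-empty).
#' @param ref A [ref_genome].
#' @param shard_min_len Minimum insert length to call a shard (bp).
#' @return List (`shard` - data frame `chrom`,`start`,`end`,`strand` or
#'   `NULL` - and `reason` - `"ok"`, `"too_short"`, `"ambiguous"`, or
#'   `"no_hit"`).
#' @export
detect_shard <- function(inserted, ref, shard_min_len = 10) {
  if (!nzchar(inserted))
    svf_stop("inserted sequence must be non-empty", "svfuse_parameter_error")
  if (nchar(inserted) < shard_min_len)
    return(list(shard = NULL, reason = "too_short"))
  subject <- Biostrings::DNAStringSet(unclass(ref))
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") Biostrings::DNAString(inserted)
           else Biostrings::reverseComplement(Biostrings::DNAString(inserted))
    m <- Biostrings::vmatchPattern(pat, subject)
    for (ci in seq_along(m)) {
      st <- BiocGenerics::start(m[[ci]])
      for (s in st)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = names(subject)[ci], start = s - 1,
          end = s - 1 + nchar(inserted), strand = strand)
    }
  }
  if (!length(hits)) return(list(shard = NULL, reason = "no_hit"))
  if (length(hits) > 1) return(list(shard = NULL, reason = "ambiguous"))
  list(shard = hits[[1]], reason = "ok")
}

#' Characterise a resolved junction
#'
#' Convenience wrapper: extracts the junction sequence, measures
#' microhomology / insertion, and attempts shard detection on any insert.
#'
#' @param junction,der,flank As in [extract_junction_sequence()].
#' @param shard_min_len As in [detect_shard()].
#' @return List (`junction_id`, `mh_len`, `inserted`, `shard`,
#'   `shard_reason`).
#' @export
junction_report <- function(junction, der, flank = 200, shard_min_len = 10) {
  xs <- extract_junction_sequence(junction, der, flank)
  mm <- measure_microhomology(xs$flank5, xs$flank3, xs$observed)
  sh <- list(shard = NULL, reason = "")
  if (nzchar(mm$inserted)) sh <- detect_shard(mm$inserted, der$ref, shard_min_len)
  list(junction_id = xs$junction_id, mh_len = mm$mh_len,
       inserted = mm$inserted, shard = sh$shard, shard_reason = sh$reason)
}

#' Summarise junction classes
#'
#' Partitions junction reports into: microhomologous with 1-4 bp (the
#' band reported for sequenced cancer junctions), longer homology
#' (>= 5 bp), blunt, inserted without a located origin, and genomic
#' shards (inserted sequence located uniquely elsewhere in the genome).
#'
#' @param reports List of reports from [junction_report()], or a data
#'   frame with `mh_len`, `inserted` and optional `shard_found` columns.
#' @return Named integer vector (`microhomology_1_4`, `longer_homology`,
#'   `blunt`, `inserted`, `shard`, `total`); the five classes partition
#'   the reports.
#' @export
summarize_junction_classes <- function(reports) {
  if (is.data.frame(reports)) {
    mh <- reports$mh_len
    ins <- nzchar(reports$inserted %||% rep("", nrow(reports)))
    shard <- reports$shard_found %||% rep(FALSE, nrow(reports))
  } else {
    mh <- vapply(reports, function(r) as.integer(r$mh_len), integer(1))
    ins <- vapply(reports, function(r) nzchar(r$inserted), logical(1))
    shard <- vapply(reports, function(r) !is.null(r$shard), logical(1))
  }
  c(microhomology_1_4 = sum(!ins & mh >= 1 & mh <= 4),
    longer_homology = sum(!ins & mh >= 5),
    blunt = sum(!ins & mh == 0),
    inserted = sum(ins & !shard),
    shard = sum(ins & shard),
    total = length(mh))
}
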