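# On-disk formats. Conventions: 0-based half-open coordinates in memory;
# GFF3 is converted to/from its native 1-based closed convention on
# read/write; BEDPE and BED are written 0-based half-open.

#' Read / write reference FASTA
#'
#' Sequences are uppercased on read (with a note) and wrapped at 60
#' columns on write. Duplicate contig names are a format error; an empty
#' file yields an empty genome with a warning.
#'
#' @param path File path.
#' @param ref A [ref_genome].
#' @return `read_fasta()` returns a [ref_genome].
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  if (!length(dss)) {
    warning(sprintf("'%s' contains no sequences; empty genome", path))
    return(structure(stats::setNames(character(0), character(0)),
                     class = "ref_genome"))
  }
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm))
    svf_stop(sprintf("duplicate contig name in '%s'", path),
             "svfuse_format_error")
  seqs <- as.character(dss)
  if (any(grepl("[acgt]", seqs))) {
    message("lowercase bases uppercased on read")
    seqs <- toupper(seqs)
  }
  ref_genome(stats::setNames(seqs, nm))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(ref, path) {
  dss <- Biostrings::DNAStringSet(unclass(ref))
  Biostrings::writeXStringSet(dss, path, width = 60)
  invisible(path)
}

#' Read / write gene models as GFF3
#'
#' Each gene is written as a `gene` feature with `exon` children and
#' per-exon `CDS` pieces. On read, exon features are grouped by their
#' `Parent`; CDS pieces must each lie within an exon (a CDS crossing an
#' exon boundary is a format error), and exons outside their gene's span
#' are a format error naming the offending gene.
#'
#' @param path File path.
#' @param genes A `gene_set`.
#' @return `read_gff3()` returns a `gene_set`.
#' @export
write_gff3 <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    gid <- g$gene_id
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = g$chrom, start = gene_start(g) + 1, end = gene_end(g),
      strand = g$strand, type = "gene", ID = gid, Parent = NA_character_,
      phase = NA_integer_)
    cds_rows <- integer(0)
    for (k in seq_len(n_exons(g))) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = g$exons[k, 1] + 1, end = g$exons[k, 2],
        strand = g$strand, type = "exon",
        ID = sprintf("%s.exon%d", gid, k), Parent = gid, phase = NA_integer_)
      if (is_coding(g)) {
        lo <- max(g$exons[k, 1], g$cds_start)
        hi <- min(g$exons[k, 2], g$cds_end)
        if (hi > lo) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = g$chrom, start = lo + 1, end = hi, strand = g$strand,
            type = "CDS", ID = sprintf("%s.cds%d", gid, k), Parent = gid,
            phase = NA_integer_)
          cds_rows <- c(cds_rows, length(rows))
        }
      }
    }
    # GFF3 CDS phase: bases to skip to reach the next codon boundary
    if (length(cds_rows)) {
      if (g$strand == "-") cds_rows <- rev(cds_rows)
      cum <- 0
      for (ri in cds_rows) {
        rows[[ri]]$phase <- (3 - cum %% 3) %% 3
        cum <- cum + rows[[ri]]$end - rows[[ri]]$start + 1
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, ID = df$ID,
    phase = df$phase,
    Parent = ifelse(is.na(df$Parent), "", df$Parent))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1,  # to 0-based
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = as.character(gr$type),
                   ID = as.character(gr$ID))
  par <- gr$Parent
  df$Parent <- vapply(seq_along(par), function(i) {
    p <- par[[i]]
    if (length(p) == 0 || !nzchar(p[1])) NA_character_ else as.character(p[1])
  }, character(1))
  genes <- list()
  for (i in which(df$type == "gene")) {
    gid <- df$ID[i]
    ex <- df[df$type == "exon" & df$Parent == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (!nrow(ex))
      svf_stop(sprintf("gene '%s' has no exons", gid), "svfuse_format_error")
    if (any(ex$start < df$start[i] | ex$end > df$end[i]))
      svf_stop(sprintf("exon outside gene span for gene '%s'", gid),
               "svfuse_format_error")
    cds <- df[df$type == "CDS" & df$Parent == gid, , drop = FALSE]
    cds_start <- NA_real_; cds_end <- NA_real_
    if (nrow(cds)) {
      for (k in seq_len(nrow(cds))) {
        inside <- any(ex$start <= cds$start[k] & ex$end >= cds$end[k])
        if (!inside)
          svf_stop(sprintf("CDS piece crosses an exon boundary in gene '%s'",
                           gid), "svfuse_format_error")
      }
      cds_start <- min(cds$start); cds_end <- max(cds$end)
    }
    genes[[length(genes) + 1L]] <- gene_model(
      gid, df$chrom[i], df$strand[i],
      cbind(ex$start, ex$end), cds_start, cds_end)
  }
  structure(genes, class = "gene_set")
}

#' Read / write read-pair tables (TSV)
#'
#' One row per pair: `pair_id`, `library`, then contig, 0-based 5'
#' position, strand and mapq for each end.
#'
#' @param pairs Read-pair data frame.
#' @param path File path.
#' @return `read_pairs()` returns the data frame.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(pair_id = "character"))
}

#' Read / write junction candidates as BEDPE with a TSV sidecar
#'
#' BEDPE columns (0-based half-open): `chrom1 start1 end1 chrom2 start2
#' end2 name score strand1 strand2` with `score` carrying the supporting
#' pair count. Fields that do not fit BEDPE (libraries, confirmation,
#' filter reasons, member pairs) go to a sidecar TSV keyed by candidate
#' id. Candidates are written in canonical order; unsorted input is
#' sorted with a note.
#'
#' @param candidates Candidate data frame (see [cluster_pairs()]).
#' @param path BEDPE path; the sidecar is `<path>.meta.tsv`.
#' @return `read_bedpe()` returns the candidate data frame.
#' @export
write_bedpe <- function(candidates, path) {
  o <- order(candidates$chrom_a, candidates$lo_a, candidates$chrom_b,
             candidates$lo_b)
  if (!identical(o, seq_len(nrow(candidates))))
    message("candidates sorted canonically on write")
  cc <- candidates[o, , drop = FALSE]
  bed <- data.frame(chrom1 = cc$chrom_a, start1 = cc$lo_a, end1 = cc$hi_a,
                    chrom2 = cc$chrom_b, start2 = cc$lo_b, end2 = cc$hi_b,
                    name = cc$id, score = cc$support,
                    strand1 = cc$strand_a, strand2 = cc$strand_b)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  meta_cols <- setdiff(names(cc), c("chrom_a", "lo_a", "hi_a", "chrom_b",
                                    "lo_b", "hi_b", "support", "strand_a",
                                    "strand_b", "side_a", "side_b"))
  utils::write.table(cc[, meta_cols, drop = FALSE],
                     paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom1", "start1", "end1", "chrom2",
                                         "start2", "end2", "name", "score",
                                         "strand1", "strand2"))
  if (any(bed$start1 >= bed$end1 | bed$start2 >= bed$end2))
    svf_stop(sprintf("start >= end in '%s'", path), "svfuse_format_error")
  if (!all(bed$strand1 %in% c("+", "-")) || !all(bed$strand2 %in% c("+", "-")))
    svf_stop(sprintf("malformed strand column in '%s'", path),
             "svfuse_format_error")
  out <- data.frame(id = as.character(bed$name),
                    chrom_a = bed$chrom1, lo_a = bed$start1, hi_a = bed$end1,
                    strand_a = bed$strand1,
                    side_a = ifelse(bed$strand1 == "+", "left_retained",
                                    "right_retained"),
                    chrom_b = bed$chrom2, lo_b = bed$start2, hi_b = bed$end2,
                    strand_b = bed$strand2,
                    side_b = ifelse(bed$strand2 == "+", "left_retained",
                                    "right_retained"),
                    support = bed$score)
  meta_path <- paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                              colClasses = c(id = "character"))
    # all-empty sidecar text columns come back logical-NA; restore ""
    for (cc in names(meta)) {
      if (is.logical(meta[[cc]]) && all(is.na(meta[[cc]])))
        meta[[cc]] <- rep("", nrow(meta))
    }
    out <- merge(out, meta, by = "id", sort = FALSE)
  }
  out <- out[order(out$chrom_a, out$lo_a, out$chrom_b, out$lo_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write probe profiles and segments (SEG-style TSV)
#'
#' @param profile Probe data frame (`chrom`, `pos`, `log2_ratio`).
#' @param segments Segment data frame from [segment_profile()].
#' @param steps Step data frame from [detect_steps()].
#' @param path File path.
#' @return Readers return the corresponding data frame.
#' @export
write_probes <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_probes
#' @export
read_probes <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  p[order(p$chrom, p$pos), , drop = FALSE]
}

#' @rdname write_probes
#' @export
write_seg <- function(segments, path) {
  utils::write.table(
    segments[, c("chrom", "start", "end", "n_probes", "mean_log2")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probes
#' @export
read_seg <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' @rdname write_probes
#' @export
write_steps_bed <- function(steps, path) {
  bed <- data.frame(chrom = steps$chrom, start = steps$start,
                    end = steps$end, name = steps$direction,
                    score = steps$delta_log2)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write simulation truth (BEDPE plus JSON sidecar)
#'
#' The BEDPE records breakend positions and orientations; the JSON
#' sidecar carries copy numbers, inserted sequences, microhomology and
#' generator seeds.
#'
#' @param truth Truth data frame from [plant_rearrangements()].
#' @param path BEDPE path; sidecar is `<path>.json`.
#' @param seeds Optional named list of seeds to record.
#' @export
write_truth <- function(truth, path, seeds = NULL) {
  strand_of <- function(side) ifelse(side == "left_retained", "+", "-")
  bed <- data.frame(chrom1 = truth$chrom_a, start1 = truth$pos_a,
                    end1 = truth$pos_a + 1, chrom2 = truth$chrom_b,
                    start2 = truth$pos_b, end2 = truth$pos_b + 1,
                    name = truth$junction_id, score = truth$copy_number,
                    strand1 = strand_of(truth$side_a),
                    strand2 = strand_of(truth$side_b))
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(seeds = seeds, junctions = truth),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Every filter threshold is named after its rule and carries the
#' conventional default: mapq below 30 discarded, duplicates within 2 bp,
#' at least 2 consistent pairs per junction, intra-chromosomal spans under
#' 10 kb discarded, copy-number steps matched within 10 kb, run-through
#' partners sought within 1 Mb. Configs round-trip through YAML
#' identically.
#'
#' @param ... Overrides of the defaults.
#' @param path YAML file path.
#' @param config A config list.
#' @return A named list.
#' @export
default_config <- function(...) {
  utils::modifyList(list(
    mapq_threshold = 30,
    dedup_max_offset_bp = 2,
    min_support_pairs = 2,
    min_span_intra_bp = 10000,
    cn_step_threshold_log2 = 0.3,
    cn_min_probes = 5,
    step_match_tolerance_bp = 10000,
    runthrough_window_bp = 1e6,
    baseline_ploidy = 2), list(...))
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' @rdname default_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a machine-readable run report
#'
#' @param report Named list or vector of stage counts.
#' @param path JSON path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
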