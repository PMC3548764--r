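# Fusion prediction from confirmed junctions and gene models.
#
# Orientation mechanics. A junction joins two retained flanks; each
# breakend records which flank survives (`left_retained` / `right_retained`).
# In the derivative, the side-A flank is read towards the junction and the
# side-B flank away from it. A broken gene donates its 5' end when its
# transcription runs towards the junction:
#   left_retained  & gene on "+"  -> 5' end retained (donor)
#   right_retained & gene on "-"  -> 5' end retained (donor)
# and a broken gene accepts (3' end retained, transcription continuing
# away from the junction) in the mirrored configurations:
#   left_retained  & gene on "-"  -> 3' end retained (acceptor)
#   right_retained & gene on "+"  -> 3' end retained (acceptor)
# A run-through fusion needs no broken acceptor: transcription from the
# donor crosses the junction and continues into the nearest intact
# co-directional gene on the retained flank, splicing into its first
# splice acceptor (exon 2 when the landing point is upstream of it).

# Normalise a candidate row (or a plain list) into a junction description.
as_junction <- function(candidate) {
  if (!is.null(candidate$pos_a)) {
    return(list(id = candidate$id %||% candidate$junction_id %||% "J",
                chrom_a = candidate$chrom_a, pos_a = candidate$pos_a,
                side_a = candidate$side_a,
                chrom_b = candidate$chrom_b, pos_b = candidate$pos_b,
                side_b = candidate$side_b))
  }
  list(id = candidate$id,
       chrom_a = candidate$chrom_a,
       pos_a = interval_mid(candidate$lo_a, candidate$hi_a),
       side_a = candidate$side_a,
       chrom_b = candidate$chrom_b,
       pos_b = interval_mid(candidate$lo_b, candidate$hi_b),
       side_b = candidate$side_b)
}

is_donor_side <- function(side, strand)
  (side == "left_retained" & strand == "+") |
  (side == "right_retained" & strand == "-")

is_acceptor_side <- function(side, strand)
  (side == "left_retained" & strand == "-") |
  (side == "right_retained" & strand == "+")

# Genes whose body contains the breakpoint position.
broken_genes <- function(genes, chrom, pos) {
  Filter(function(g) g$chrom == chrom && gene_start(g) < pos && gene_end(g) > pos,
         genes)
}

# Last retained exon of a donor broken at pos (transcription order).
donor_exon <- function(g, pos) {
  if (g$strand == "+") sum(g$exons[, 1] < pos)
  else sum(g$exons[, 2] > pos)
}

# First retained exon of a broken acceptor: the first exon whose splice
# acceptor lies 3' of the junction landing point.
acceptor_exon_broken <- function(g, pos) {
  if (g$strand == "+") sum(g$exons[, 1] < pos) + 1L
  else sum(g$exons[, 2] > pos) + 1L
}

#' Genes overlapping or adjacent to a junction's breakpoints
#'
#' Overlap is tested against the breakend intervals; "adjacent" genes are
#' the intact co-directional genes on the retained flank whose 5' end lies
#' within `runthrough_window` bp downstream of the junction in derivative
#' orientation (ordered nearest first) - the candidate partners for a
#' run-through fusion.
#'
#' @param candidate One-row candidate data frame from [cluster_pairs()],
#'   or a list with `chrom_a`, `pos_a`, `side_a`, `chrom_b`, `pos_b`,
#'   `side_b`.
#' @param genes A `gene_set` (list of [gene_model]s).
#' @param runthrough_window Downstream search window (bp).
#' @return List with `overlap_a`, `overlap_b` (gene ids overlapping each
#'   breakend) and `adjacent_a`, `adjacent_b` (downstream intact gene ids,
#'   nearest first).
#' @export
genes_at_breakpoints <- function(candidate, genes, runthrough_window = 1e6) {
  j <- as_junction(candidate)
  ov <- function(chrom, lo, hi) {
    vapply(Filter(function(g) g$chrom == chrom && gene_start(g) < hi &&
                    gene_end(g) > lo, genes),
           function(g) g$gene_id, character(1))
  }
  lo_a <- candidate$lo_a %||% j$pos_a; hi_a <- candidate$hi_a %||% j$pos_a
  lo_b <- candidate$lo_b %||% j$pos_b; hi_b <- candidate$hi_b %||% j$pos_b
  list(overlap_a = ov(j$chrom_a, lo_a, hi_a),
       overlap_b = ov(j$chrom_b, lo_b, hi_b),
       adjacent_a = downstream_intact(genes, j$chrom_a, j$pos_a, j$side_a,
                                      runthrough_window)$gene_id,
       adjacent_b = downstream_intact(genes, j$chrom_b, j$pos_b, j$side_b,
                                      runthrough_window)$gene_id)
}

# Intact co-directional genes on the retained flank, nearest first.
downstream_intact <- function(genes, chrom, pos, side, window) {
  hits <- list()
  for (g in genes) {
    if (g$chrom != chrom) next
    if (side == "right_retained" && g$strand == "+" &&
        gene_start(g) >= pos && gene_start(g) - pos <= window)
      hits[[length(hits) + 1L]] <- data.frame(gene_id = g$gene_id,
                                              distance = gene_start(g) - pos)
    if (side == "left_retained" && g$strand == "-" &&
        gene_end(g) <= pos && pos - gene_end(g) <= window)
      hits[[length(hits) + 1L]] <- data.frame(gene_id = g$gene_id,
                                              distance = pos - gene_end(g))
  }
  if (!length(hits))
    return(data.frame(gene_id = character(0), distance = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$distance), , drop = FALSE]
}

empty_fusions <- function() {
  data.frame(five_prime_gene = character(0), five_prime_exon = integer(0),
             three_prime_gene = character(0), three_prime_exon = integer(0),
             kind = character(0), frame = character(0),
             junction_ids = character(0), alternatives = character(0))
}

empty_breaks <- function() {
  data.frame(gene_id = character(0), junction_id = character(0),
             retained_end = character(0))
}

#' Predict fusion genes at a junction
#'
#' Tests both directions across the junction. A *direct* fusion is called
#' when one side retains a broken gene's 5' end and the other retains a
#' broken gene's 3' end with concordant transcriptional orientation
#' across the junction; the transcript joins the donor's last retained
#' exon to the first splice acceptor 3' of the landing point. A
#' *run-through* fusion is called when a 5' end is retained and the other
#' flank carries an intact co-directional gene within
#' `runthrough_window`; the nearest such gene is reported (farther
#' partners are listed as alternatives) and the transcript splices into
#' its second exon. Gene-overlapping breakends not absorbed into a fusion
#' are reported as gene breaks.
#'
#' @param candidate One-row candidate, or a list with `chrom_a`, `pos_a`,
#'   `side_a`, `chrom_b`, `pos_b`, `side_b` (and optionally `id`).
#' @param genes A `gene_set`.
#' @param runthrough_window Downstream window for run-through partners (bp).
#' @return List with `fusions` (data frame: `five_prime_gene`,
#'   `five_prime_exon`, `three_prime_gene`, `three_prime_exon`, `kind`
#'   (`direct`/`runthrough`), `frame`, `junction_ids`, `alternatives`)
#'   and `breaks` (data frame: `gene_id`, `junction_id`, `retained_end`).
#' @export
predict_fusion <- function(candidate, genes, runthrough_window = 1e6) {
  j <- as_junction(candidate)
  fusions <- list()
  used <- character(0)

  side_of <- function(which) {
    list(chrom = j[[paste0("chrom_", which)]],
         pos = j[[paste0("pos_", which)]],
         side = j[[paste0("side_", which)]])
  }
  for (dir in list(c("a", "b"), c("b", "a"))) {
    don <- side_of(dir[1]); acc <- side_of(dir[2])
    donors <- Filter(function(g) is_donor_side(don$side, g$strand),
                     broken_genes(genes, don$chrom, don$pos))
    if (!length(donors)) next
    acceptors <- Filter(function(g) is_acceptor_side(acc$side, g$strand),
                        broken_genes(genes, acc$chrom, acc$pos))
    for (dg in donors) {
      d_ex <- donor_exon(dg, don$pos)
      if (d_ex < 1) next
      if (length(acceptors)) {
        ag <- acceptors[[1]]
        a_ex <- acceptor_exon_broken(ag, acc$pos)
        if (a_ex > n_exons(ag)) next  # break beyond the last acceptor
        fusions[[length(fusions) + 1L]] <- data.frame(
          five_prime_gene = dg$gene_id, five_prime_exon = d_ex,
          three_prime_gene = ag$gene_id, three_prime_exon = a_ex,
          kind = "direct",
          frame = fusion_frame(dg, d_ex, ag, a_ex),
          junction_ids = j$id, alternatives = "")
        used <- c(used, dg$gene_id, ag$gene_id)
      } else {
        ds <- downstream_intact(genes, acc$chrom, acc$pos, acc$side,
                                runthrough_window)
        ds <- ds[!ds$gene_id %in% vapply(donors, `[[`, "", "gene_id"), ,
                 drop = FALSE]
        if (!nrow(ds)) next
        ag <- genes[[which(vapply(genes, `[[`, "", "gene_id") == ds$gene_id[1])]]
        a_ex <- if (n_exons(ag) >= 2) 2L else NA_integer_
        if (is.na(a_ex)) next  # single-exon gene: no splice acceptor
        fusions[[length(fusions) + 1L]] <- data.frame(
          five_prime_gene = dg$gene_id, five_prime_exon = d_ex,
          three_prime_gene = ag$gene_id, three_prime_exon = a_ex,
          kind = "runthrough",
          frame = fusion_frame(dg, d_ex, ag, a_ex),
          junction_ids = j$id,
          alternatives = paste(ds$gene_id[-1], collapse = ","))
        used <- c(used, dg$gene_id)
      }
    }
  }

  # gene-break records for broken genes not absorbed into a fusion
  brks <- list()
  ga <- broken_genes(genes, j$chrom_a, j$pos_a)
  gb <- broken_genes(genes, j$chrom_b, j$pos_b)
  both <- intersect(vapply(ga, `[[`, "", "gene_id"),
                    vapply(gb, `[[`, "", "gene_id"))
  for (g in c(ga, gb)) {
    if (g$gene_id %in% used) next
    if (g$gene_id %in% both) {
      ret <- "internal_loss"
      if (g$gene_id %in% vapply(brks, function(b) b$gene_id, character(1)))
        next
    } else {
      pos <- if (g$gene_id %in% vapply(ga, `[[`, "", "gene_id")) j$pos_a else j$pos_b
      side <- if (g$gene_id %in% vapply(ga, `[[`, "", "gene_id")) j$side_a else j$side_b
      ret <- if (is_donor_side(side, g$strand)) "five_prime" else "three_prime"
    }
    brks[[length(brks) + 1L]] <- data.frame(gene_id = g$gene_id,
                                            junction_id = j$id,
                                            retained_end = ret)
  }
  list(fusions = if (length(fusions)) do.call(rbind, fusions) else empty_fusions(),
       breaks = if (length(brks)) do.call(rbind, brks) else empty_breaks())
}

# Frame status from cumulative CDS phases: in frame iff the phase at the
# donor exon's 3' end equals the phase at the acceptor exon's 5' start.
# Indeterminate when either boundary lies outside its gene's CDS (UTR
# breaks) or a partner is non-coding.
fusion_frame <- function(donor_gene, donor_exon, acceptor_gene, acceptor_exon) {
  if (!is_coding(donor_gene) || !is_coding(acceptor_gene))
    return("indeterminate")
  pd <- exon_phases(donor_gene)$end_phase[donor_exon]
  pa <- exon_phases(acceptor_gene)$start_phase[acceptor_exon]
  if (is.na(pd) || is.na(pa)) return("indeterminate")
  if (pd == pa) "in_frame" else "out_of_frame"
}

#' Reading-frame status of a fusion prediction
#'
#' @param prediction One-row fusion data frame (from [predict_fusion()]).
#' @param genes The `gene_set` the prediction refers to.
#' @return `"in_frame"`, `"out_of_frame"`, or `"indeterminate"` (UTR
#'   breakpoints or a non-coding partner).
#' @export
check_frame <- function(prediction, genes) {
  ids <- vapply(genes, `[[`, "", "gene_id")
  dg <- genes[[match(prediction$five_prime_gene, ids)]]
  ag <- genes[[match(prediction$three_prime_gene, ids)]]
  fusion_frame(dg, prediction$five_prime_exon, ag, prediction$three_prime_exon)
}

#' Trace a transcript across several junctions of a derivative path
#'
#' Walks transcription along an ordered derivative segment path (from
#' simulator truth or user input): the donor is the co-directional gene
#' broken at the end of the first segment; subsequent segments are
#' scanned, in order, for the first co-directional splice acceptor.
#' Intervening segments without one (e.g. an intronic insert) are
#' traversed; a segment whose genes all run against the path direction
#' contributes nothing. All junctions crossed are reported, so fusions
#' spanning two or more genomic junctions reduce to one prediction.
#'
#' @param path Data frame (`chrom`, `start`, `end`, `strand`), segments in
#'   derivative order (0-based half-open reference coordinates).
#' @param genes A `gene_set`.
#' @param junction_ids Ids for the `nrow(path) - 1` junctions (default
#'   `"J1"`, ...).
#' @return One-row fusion data frame as in [predict_fusion()], or `NULL`
#'   when no fusion transcript can form along the path.
#' @export
trace_multi_junction_transcript <- function(path, genes,
                                            junction_ids = NULL) {
  path <- as.data.frame(path)
  if (nrow(path) < 2)
    svf_stop("a derivative path needs at least two segments", "svfuse_input_error")
  key <- paste(path$chrom, path$start, path$end, path$strand)
  if (anyDuplicated(key))
    svf_stop("cyclic derivative path (repeated segment)", "svfuse_input_error")
  junction_ids <- junction_ids %||% paste0("J", seq_len(nrow(path) - 1))

  seg_exit <- function(k) if (path$strand[k] == "+") path$end[k] else path$start[k]
  seg_entry <- function(k) if (path$strand[k] == "+") path$start[k] else path$end[k]
  seg_side <- function(k) if (path$strand[k] == "+") "left_retained" else "right_retained"

  # donor: co-directional gene broken at the exit of segment 1
  # (co-directional with the path means gene strand equals segment strand)
  donors <- Filter(function(g) g$strand == path$strand[1],
                   broken_genes(genes, path$chrom[1], seg_exit(1)))
  if (!length(donors)) return(NULL)
  dg <- donors[[1]]
  d_ex <- donor_exon(dg, seg_exit(1))

  for (k in 2:nrow(path)) {
    entry <- seg_entry(k)
    co <- Filter(function(g) g$chrom == path$chrom[k] &&
                   g$strand == path$strand[k] &&
                   gene_start(g) < path$end[k] && gene_end(g) > path$start[k],
                 genes)
    if (!length(co)) next
    best <- NULL; best_dist <- Inf
    for (g in co) {
      # first splice acceptor at or past the entry point, inside the segment
      if (g$strand == "+") {
        acc_idx <- which(g$exons[, 1] >= entry & g$exons[, 1] < path$end[k])
        acc_idx <- acc_idx[acc_idx >= 2]
        if (!length(acc_idx)) next
        a_ex <- min(acc_idx)
        dist <- g$exons[a_ex, 1] - entry
      } else {
        n <- n_exons(g)
        acc_gen <- which(g$exons[, 2] <= entry & g$exons[, 2] > path$start[k])
        if (!length(acc_gen)) next
        gidx <- max(acc_gen)          # nearest acceptor below the entry
        a_ex <- n - gidx + 1L         # transcription-order index
        if (a_ex < 2) next
        dist <- entry - g$exons[gidx, 2]
      }
      if (dist < best_dist) {
        best <- list(gene = g, exon = a_ex); best_dist <- dist
      }
    }
    if (!is.null(best)) {
      return(data.frame(
        five_prime_gene = dg$gene_id, five_prime_exon = d_ex,
        three_prime_gene = best$gene$gene_id, three_prime_exon = best$exon,
        kind = "direct",
        frame = fusion_frame(dg, d_ex, best$gene, best$exon),
        junction_ids = paste(junction_ids[seq_len(k - 1)], collapse = ","),
        alternatives = ""))
    }
  }
  NULL
}
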