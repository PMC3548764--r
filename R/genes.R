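#' Gene models
#'
#' A gene model is a single-transcript description: an ordered set of
#' non-overlapping exons (0-based half-open genomic coordinates), a strand,
#' and an optional CDS interval. Exons are stored in genomic order;
#' transcription order is derived from the strand. Splice phases are not
#' stored but derived from cumulative CDS length (see [exon_phases()]).
#'
#' @param gene_id Gene identifier.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of exon intervals,
#'   0-based half-open, sorted by start, non-overlapping.
#' @param cds_start,cds_end CDS interval (0-based half-open genomic) or
#'   `NA` for a non-coding gene. Must lie within the exon span.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       cds_start = NA_real_, cds_end = NA_real_) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2] <= exons[, 1]))
    svf_stop("exon ends must exceed starts", "svfuse_format_error")
  if (is.unsorted(exons[, 1], strictly = TRUE) && nrow(exons) > 1)
    svf_stop("exons must be sorted by start", "svfuse_format_error")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    svf_stop("exons must not overlap", "svfuse_format_error")
  if (!strand %in% c("+", "-"))
    svf_stop("strand must be '+' or '-'", "svfuse_format_error")
  if (!is.na(cds_start)) {
    if (cds_start < exons[1, 1] || cds_end > exons[nrow(exons), 2] ||
        cds_end <= cds_start)
      svf_stop("CDS interval must lie within the exon span", "svfuse_format_error")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds_start = as.numeric(cds_start),
                 cds_end = as.numeric(cds_end)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s)%s\n",
              x$gene_id, x$chrom, gene_start(x), gene_end(x), x$strand,
              nrow(x$exons),
              if (is.na(x$cds_start)) ", non-coding" else ""))
  invisible(x)
}

gene_start <- function(g) unname(g$exons[1, 1])
gene_end <- function(g) unname(g$exons[nrow(g$exons), 2])
n_exons <- function(g) nrow(g$exons)
is_coding <- function(g) !is.na(g$cds_start)

# Transcript (spliced) coordinate of a genomic boundary point p, measured
# from the transcription start. p is 0-based and should lie within or at
# the edge of the exon span.
genomic_to_tx <- function(g, p) {
  ex <- g$exons
  if (g$strand == "+") {
    sum(pmax(0, pmin(p, ex[, 2]) - ex[, 1]))
  } else {
    sum(pmax(0, ex[, 2] - pmax(p, ex[, 1])))
  }
}

# Inverse of genomic_to_tx: genomic boundary point at spliced offset t.
tx_to_genomic <- function(g, t) {
  ex <- g$exons
  lens <- ex[, 2] - ex[, 1]
  if (g$strand == "+") {
    ord <- seq_len(nrow(ex))
  } else {
    ord <- rev(seq_len(nrow(ex)))
  }
  rem <- t
  for (k in ord) {
    if (rem <= lens[k]) {
      return(if (g$strand == "+") ex[k, 1] + rem else ex[k, 2] - rem)
    }
    rem <- rem - lens[k]
  }
  svf_stop("spliced offset beyond transcript length", "svfuse_bounds_error")
}

# Exon table in transcription order with spliced coordinates and the CDS
# interval in spliced coordinates (NULL for non-coding genes).
tx_structure <- function(g) {
  ex <- g$exons
  ord <- if (g$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  lens <- (ex[, 2] - ex[, 1])[ord]
  tx_end <- cumsum(lens)
  tx_start <- tx_end - lens
  cds_tx <- NULL
  if (is_coding(g)) {
    a <- genomic_to_tx(g, g$cds_start)
    b <- genomic_to_tx(g, g$cds_end)
    cds_tx <- sort(c(a, b))
  }
  list(order = ord, lens = lens, tx_start = tx_start, tx_end = tx_end,
       cds_tx = cds_tx)
}

#' Splice phases per exon
#'
#' Phases are derived from cumulative CDS length: the phase at an exon
#' boundary is the number of CDS bases transcribed up to that boundary,
#' modulo 3. `start_phase`/`end_phase` are `NA` where the boundary lies
#' outside the CDS (UTR exons, or the exon containing the start/stop
#' boundary on the wrong side), and for non-coding genes.
#'
#' @param g A [gene_model].
#' @return Data frame with one row per exon in transcription order:
#'   `exon`, `start_phase`, `end_phase`.
#' @export
exon_phases <- function(g) {
  st <- tx_structure(g)
  n <- length(st$lens)
  out <- data.frame(exon = seq_len(n),
                    start_phase = NA_integer_, end_phase = NA_integer_)
  if (is.null(st$cds_tx)) return(out)
  c0 <- st$cds_tx[1]; c1 <- st$cds_tx[2]
  sp <- ifelse(st$tx_start >= c0 & st$tx_start < c1,
               (st$tx_start - c0) %% 3, NA_integer_)
  ep <- ifelse(st$tx_end > c0 & st$tx_end <= c1,
               (st$tx_end - c0) %% 3, NA_integer_)
  out$start_phase <- as.integer(sp)
  out$end_phase <- as.integer(ep)
  out
}

#' Construct a gene model from exon/intron lengths
#'
#' Convenience constructor used by the simulator and fixtures: exon and
#' intron lengths are given in transcription order; the CDS is placed
#' `utr5` spliced bases after the transcription start and ends `utr3`
#' spliced bases before the transcript end.
#'
#' @param gene_id,chrom,strand As in [gene_model()].
#' @param start Genomic start (0-based) of the gene span.
#' @param exon_lens,intron_lens Lengths in transcription order
#'   (`length(intron_lens) == length(exon_lens) - 1`).
#' @param utr5,utr3 Untranslated lengths in spliced coordinates; set to
#'   `NA` for a non-coding gene.
#' @return A [gene_model].
#' @export
make_gene <- function(gene_id, chrom, strand, start, exon_lens,
                      intron_lens = integer(0), utr5 = 30, utr3 = 30) {
  n <- length(exon_lens)
  if (n > 1 && length(intron_lens) != n - 1)
    svf_stop("need one intron length per internal junction", "svfuse_parameter_error")
  # genomic order: reverse the transcription-order lengths on the minus strand
  ex_g <- if (strand == "+") exon_lens else rev(exon_lens)
  in_g <- if (strand == "+") intron_lens else rev(intron_lens)
  starts <- start + cumsum(c(0, head(ex_g, -1) + in_g))
  ends <- starts + ex_g
  g <- gene_model(gene_id, chrom, strand, cbind(starts, ends))
  if (!is.na(utr5)) {
    total <- sum(exon_lens)
    if (utr5 + utr3 >= total)
      svf_stop("UTRs leave no room for a CDS", "svfuse_parameter_error")
    p5 <- tx_to_genomic(g, utr5)
    p3 <- tx_to_genomic(g, total - utr3)
    g$cds_start <- min(p5, p3)
    g$cds_end <- max(p5, p3)
  }
  g
}

#' Generate random non-overlapping gene models
#'
#' Places `n_genes` multi-exon genes on the reference without overlap,
#' both strands represented, every gene with at least two exons so that
#' splice-based fusion logic is exercisable. Deterministic per seed.
#'
#' @param ref A [ref_genome].
#' @param n_genes Number of genes to place.
#' @param exons_per_gene Length-2 vector: min and max exon count (min >= 2).
#' @param seed Integer seed.
#' @param avoid Optional data frame (`chrom`, `start`, `end`) of intervals
#'   genes must not touch (e.g. planted breakpoint neighbourhoods).
#' @return A list of [gene_model] objects (class `gene_set`).
#' @export
generate_genes <- function(ref, n_genes, exons_per_gene = c(2, 10), seed = 1,
                           avoid = NULL) {
  if (length(exons_per_gene) != 2 || exons_per_gene[1] < 2)
    svf_stop("`exons_per_gene` must be c(min, max) with min >= 2",
             "svfuse_parameter_error")
  lens <- contig_lengths(ref)
  with_seed(seed, {
    occupied <- if (is.null(avoid)) {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    } else {
      avoid[, c("chrom", "start", "end")]
    }
    genes <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1)
      ex_l <- sample(90:240, n_ex, replace = TRUE)
      in_l <- if (n_ex > 1) sample(300:1500, n_ex - 1, replace = TRUE) else integer(0)
      span <- sum(ex_l) + sum(in_l)
      strand <- if (i <= 2 && n_genes >= 2) c("+", "-")[i] else sample(c("+", "-"), 1)
      placed <- FALSE
      last_chrom <- names(lens)[1]
      for (try in seq_len(400)) {
        chrom <- sample(names(lens), 1, prob = lens)
        last_chrom <- chrom
        if (lens[[chrom]] <= span + 2) next
        start <- floor(stats::runif(1, 1, lens[[chrom]] - span - 1))
        clash <- occupied$chrom == chrom &
          occupied$start < start + span + 100 & occupied$end > start - 100
        if (any(clash)) next
        utr5 <- sample(10:min(60, ex_l[1] - 4), 1)
        utr3 <- sample(10:min(60, ex_l[n_ex] - 4), 1)
        genes[[i]] <- make_gene(sprintf("G%03d", i), chrom, strand, start,
                                ex_l, in_l, utr5 = utr5, utr3 = utr3)
        occupied <- rbind(occupied,
                          data.frame(chrom = chrom, start = start,
                                     end = start + span))
        placed <- TRUE
        break
      }
      if (!placed)
        svf_stop(sprintf(
          "could not place gene %d (span %d bp); insufficient space on contig '%s'",
          i, span, last_chrom), "svfuse_placement_error")
    }
    structure(genes, class = "gene_set")
  })
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %d gene model(s)\n", length(x)))
  invisible(x)
}

# Flat data.frame view of a gene set (one row per gene).
gene_table <- function(genes) {
  do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = gene_start(g), end = gene_end(g),
               n_exons = n_exons(g), coding = is_coding(g))
  }))
}
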