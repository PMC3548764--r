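#' Reference genome container
#'
#' A reference genome is stored as a named character vector of uppercase
#' DNA sequences (alphabet `ACGT`), one element per contig, with class
#' `ref_genome`. [Biostrings::DNAStringSet] is used at the FASTA boundary
#' (see [read_fasta()] / [write_fasta()]); internally plain character
#' vectors keep segment arithmetic simple.
#'
#' @param sequences Named character vector of DNA sequences.
#' @return A `ref_genome` object.
#' @export
ref_genome <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    svf_stop("contig names must be present and unique", "svfuse_format_error")
  sequences <- toupper(sequences)
  if (any(nchar(sequences) < 1L))
    svf_stop("contig lengths must be >= 1", "svfuse_format_error")
  if (any(grepl("[^ACGT]", sequences)))
    svf_stop("sequences must be over the ACGT alphabet", "svfuse_format_error")
  structure(sequences, class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %d contig(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in names(x))
    cat(sprintf("  %s  %s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

contig_lengths <- function(ref) stats::setNames(nchar(unclass(ref)), names(ref))

ref_subseq <- function(ref, chrom, start, end) {
  # 0-based half-open coordinates
  if (!chrom %in% names(ref))
    svf_stop(sprintf("unknown contig '%s'", chrom), "svfuse_input_error")
  L <- nchar(ref[[chrom]])
  if (start < 0 || end > L || start > end)
    svf_stop(sprintf("interval [%s,%s) out of bounds for contig '%s' (%d bp)",
                     start, end, chrom, L), "svfuse_bounds_error")
  substr(unclass(ref)[[chrom]], start + 1L, end)
}

#' Generate a random reference genome
#'
#' Draws i.i.d. bases with the requested GC fraction. Deterministic for a
#' given seed: two calls with identical arguments return byte-identical
#' sequences.
#'
#' @param n_chrom Number of contigs.
#' @param lengths Integer vector of contig lengths (bp), length `n_chrom`.
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @param names Contig names (default `chr1`, `chr2`, ...).
#' @return A [ref_genome] object.
#' @examples
#' ref <- generate_reference(2, c(10000, 8000), gc = 0.41, seed = 7)
#' @export
generate_reference <- function(n_chrom, lengths, gc = 0.41, seed = 1,
                               names = paste0("chr", seq_len(n_chrom))) {
  if (length(lengths) != n_chrom)
    svf_stop("`lengths` must have one entry per contig", "svfuse_parameter_error")
  if (any(lengths <= 0))
    svf_stop("contig lengths must be positive", "svfuse_parameter_error")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1)
    svf_stop("`gc` must lie strictly between 0 and 1", "svfuse_parameter_error")
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
    ref_genome(stats::setNames(seqs, names))
  })
}
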