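#' Physical (fragment-span) coverage
#'
#' A rearrangement junction is sampled when a sequenced fragment spans it,
#' so the relevant coverage is fragment-span coverage: `N * f / G`, with
#' `N` read pairs of median fragment length `f` over a ploidy-adjusted
#' genome size `G`. For a subtetraploid tumour genome, `G` is the haploid
#' genome size times the ploidy (e.g. 4 x 3.1 Gb = 12.4 Gb), so the result
#' is the coverage of a single-copy breakpoint.
#'
#' @param n_pairs Number of read pairs (N).
#' @param fragment_len Median fragment length in bp (f).
#' @param genome_size Ploidy-adjusted genome size in bp (G).
#' @return Fold coverage (numeric).
#' @examples
#' physical_coverage(43e6, 504, 12.4e9)  # ~1.75-fold
#' @export
physical_coverage <- function(n_pairs, fragment_len, genome_size) {
  if (genome_size <= 0)
    svf_stop("genome_size must be positive", "svfuse_parameter_error")
  if (n_pairs < 0 || fragment_len <= 0)
    svf_stop("n_pairs must be >= 0 and fragment_len > 0", "svfuse_parameter_error")
  n_pairs * fragment_len / genome_size
}

#' Poisson junction-detection probability
#'
#' Models the number of read pairs spanning a junction as Poisson with
#' mean `lambda * copy_number`: amplified junctions are present in many
#' copies and so are sampled proportionally more often. Detection requires
#' at least `min_pairs` spanning pairs (two consistent pairs by default,
#' matching the clustering requirement).
#'
#' @param lambda Physical coverage per junction copy.
#' @param copy_number Junction copy number (>= 1).
#' @param min_pairs Minimum supporting pairs for a call (k, default 2).
#' @return `P(X >= k)` for `X ~ Poisson(lambda * copy_number)`.
#' @examples
#' detection_probability(1.7, 1)   # ~0.51 for single-copy junctions
#' detection_probability(1.7, 20)  # ~1 for a 20-copy amplicon junction
#' @export
detection_probability <- function(lambda, copy_number = 1, min_pairs = 2) {
  if (lambda < 0 || copy_number < 1 || min_pairs < 1)
    svf_stop("need lambda >= 0, copy_number >= 1, min_pairs >= 1",
             "svfuse_parameter_error")
  stats::ppois(min_pairs - 1, lambda * copy_number, lower.tail = FALSE)
}

#' Two-list capture-recapture estimate of the total fusion count
#'
#' Lincoln-Petersen estimator: when one method finds `n1` fusions, a
#' second independent method finds `n2`, and `m` are found by both, the
#' estimated true total is `n1 * n2 / m` (uncorrected; no Chapman
#' adjustment). Symmetric in `n1` and `n2`.
#'
#' @param n1,n2 Fusions found by each method.
#' @param m Fusions found by both (>= 1; disjoint lists leave the
#'   estimate undefined).
#' @return List (`estimate` - exact ratio - and `rounded`).
#' @examples
#' capture_recapture(9, 6, 3)  # estimate 18
#' @export
capture_recapture <- function(n1, n2, m) {
  if (m < 1)
    svf_stop("m = 0: disjoint catalogues leave the estimate undefined",
             "svfuse_estimate_error")
  if (m > min(n1, n2))
    svf_stop("overlap m cannot exceed either list size", "svfuse_parameter_error")
  est <- n1 * n2 / m
  list(estimate = est, rounded = round(est))
}

#' Extrapolate a mean fusion count for a detection sensitivity
#'
#' Divides an observed per-case mean by the estimated sensitivity of the
#' detection method, giving the expected true mean per case.
#'
#' @param observed_mean Observed mean fusions per case.
#' @param sensitivity Detection sensitivity in (0, 1].
#' @return Estimated true mean.
#' @examples
#' extrapolate_mean_fusions(4.2, 0.40)  # 10.5
#' @export
extrapolate_mean_fusions <- function(observed_mean, sensitivity) {
  if (sensitivity <= 0 || sensitivity > 1)
    svf_stop("sensitivity must lie in (0, 1]", "svfuse_parameter_error")
  if (observed_mean < 0)
    svf_stop("observed_mean must be >= 0", "svfuse_parameter_error")
  observed_mean / sensitivity
}

#' Tally independently verified junctions
#'
#' Bookkeeping for junction verification: candidates confirmed by an
#' associated copy-number step only, by a positive PCR product only, or by
#' both, are disjoint classes; the verified total is their sum.
#'
#' @param n_cn_step_only,n_pcr_only,n_both Class counts.
#' @return List with the class counts and `total`.
#' @export
tally_verified_junctions <- function(n_cn_step_only, n_pcr_only, n_both) {
  if (any(c(n_cn_step_only, n_pcr_only, n_both) < 0))
    svf_stop("counts must be non-negative", "svfuse_parameter_error")
  list(cn_step_only = n_cn_step_only, pcr_only = n_pcr_only, both = n_both,
       total = n_cn_step_only + n_pcr_only + n_both)
}
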