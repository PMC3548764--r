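---
title: "Methods: junction calling, fusion prediction and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction calling, fusion prediction and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`svfuse` reconstructs, as reusable tested code, the computational core of
a structural-variant and fusion-gene survey of a rearranged cancer
genome: discordant read-pair clustering with a filter cascade,
confirmation against copy-number steps, orientation-aware fusion
prediction with reading-frame calls, junction microhomology and
genomic-shard characterisation, and the coverage / capture–recapture
side-calculations. Wet-lab validation (PCR, cloning), short-read
alignment itself, allele-specific copy-number modelling and linear
amplicon assembly are out of scope; alignments enter the pipeline as a
plain pair table.

# The evidence model

One sequenced fragment yields a read pair; a pair is *normal* when both
ends map to one contig, inward (FR), with an outer 5′-to-5′ span inside
the library's fragment range, and *aberrant* otherwise. An aberrant pair
is evidence for a junction; its read orientations say which flank of
each breakpoint survives in the derivative chromosome (a `+` read faces
right, so the left flank is retained). Junctions need at least two
consistent pairs — a single pair is indistinguishable from a chimera
artifact.

**Consistency window.** "Consistent" is never defined operationally in
descriptions of such pipelines, so the standard geometric construction
is used: a read's implied breakpoint interval extends from its 5′
position in its facing direction by `frag_max − read_length`; two pairs
are consistent when contig pair and orientation class match and the
implied intervals overlap on both ends. Mixed-library clusters use each
pair's own window. Maximal groups are the transitive closure of pairwise
consistency (union-find in canonical coordinate order; tie-breaks by
`(chrom_a, lo_a, chrom_b, lo_b)`), and a candidate's breakend interval
is the intersection of its members' implied intervals (guarded to one bp
when the intersection degenerates, which can happen for transitively
linked members).

# Filter cascade

Stage order is fixed as mapping quality → duplicates → classification →
realignment recheck. Published descriptions imply but do not pin the
order; fixing it makes stage counts reproducible, and the order chosen
discards cheaply first. Defaults, each named for its rule in
`default_config()`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `mapq_threshold` | 30 | phred | "below 30" is discarded; exactly 30 is kept |
| `dedup_max_offset_bp` | 2 | bp | PCR duplicates whose primer lost 1–2 3′ bases |
| `min_support_pairs` | 2 | pairs | minimum consistent pairs per junction |
| `min_span_intra_bp` | 10 000 | bp | shorter intra-chromosomal spans are mostly polymorphisms or outsize fragments; "less than" is strict, a 10 000 bp span survives |
| `cn_step_threshold_log2` | 0.3 | log2 | smallest accepted segment-mean difference |
| `cn_min_probes` | 5 | probes | smallest segment |
| `step_match_tolerance_bp` | 10 000 | bp | the map resolution of the confirming copy-number data |
| `runthrough_window_bp` | 1 000 000 | bp | how far downstream an intact partner may sit |
| `baseline_ploidy` | 2 | copies | log-ratio baseline; set 4 for a subtetraploid genome |

Duplicate groups are the transitive closure of "both 5′ offsets ≤ 2 bp
with equal contigs and strands"; the highest summed mapq survives, ties
broken by smallest pair id, which also makes originals beat their
injected copies in simulations. The realignment recheck — the in-package
substitute for rechecking aberrant pairs with an external aligner —
searches both strands of the reference for near-exact (≤ 2 mismatch)
alternative placements of either read via `Biostrings::vmatchPattern`
and discards the pair when any placement combination is concordant. It
needs read sequences; alignment-level simulations omit them, and the
stage then no-ops with a warning.

Candidate-level filters are independent set-membership tests (minimum
span; panel-of-normals junction match within the widest library's
`frag_max`; ≥ 50% reciprocal overlap of a deletion/duplication-type
candidate's span with a blacklist interval), so their application order
cannot change the kept set; the tests verify this exhaustively on a
constructed candidate bank.

# Copy-number confirmation

A junction is accepted when it is supported by two libraries, or when
one breakend lies within `step_match_tolerance_bp` of a copy-number
step. One matching breakend suffices by design: the partner breakend of
a balanced junction produces no step, so demanding both would
systematically reject balanced events. Candidates failing both clauses
are retained but flagged `unconfirmed`, mirroring the wet-lab follow-up
that is out of scope. An independently derived breakpoint list (e.g.
from chromosome-sorting experiments) can be appended as pseudo-step rows.

Segmentation is a deliberately transparent substitute for the published
allele-specific segmentation algorithms, which model SNP-array intensity
and are only used here to confirm breakpoint intervals: recursive binary
splitting on the probe sequence, accepting the split maximising the
absolute difference of flanking means while the difference is at least
`cn_step_threshold_log2` and both sides keep `cn_min_probes` probes.
Ties take the first index; the procedure is deterministic and on
noiseless input reproduces the true piecewise means exactly. Steps are
reported per adjacent segment pair as the probe-gap interval, so a
noiseless step localises truth to one probe spacing.

# Fusion prediction

Donor/acceptor roles follow from breakend sides: a broken gene donates
its 5′ end when transcription runs toward the junction
(`left_retained` & `+`, or `right_retained` & `−`), and accepts with its
3′ end in the mirrored configurations. Both directions across a junction
are tested. The acceptor exon is the first exon whose splice acceptor
lies 3′ of the landing point — exon 2 when the junction lands upstream
of it, matching the empirical rule that run-through transcripts splice
into the first splice acceptor, usually the second exon. When several
intact downstream partners are available the nearest is reported and the
others are listed as alternatives; surveys have missed real run-through
fusions obscured by competing downstream partners, so the alternatives
column keeps them visible. Cryptic exons and isoform selection are out
of scope; gene models are single-transcript.

Frame is pure phase arithmetic on cumulative CDS length: in frame iff
the donor exon's 3′-end phase equals the acceptor exon's 5′-start phase,
`indeterminate` when either boundary falls outside its CDS (5′-UTR
breaks) or a partner is non-coding. A translated-CDS oracle in the test
suite confirms that in-frame calls never produce a premature stop within
one codon of the junction on stop-free fixtures.

Fusions transcribed across more than one genomic junction are handled by
walking an ordered derivative segment path: the donor is the
co-directional gene broken at the first segment's exit; each following
segment is scanned for the first co-directional splice acceptor past its
entry point; segments without one (an intronic insert) are traversed,
and an acceptor-less path yields no fusion. Cyclic paths are rejected.

# The simulator

The simulator emits *alignments*, not reads: fragments are drawn
uniformly along the derivative genome (derived contigs weighted by copy
number plus the remaining baseline homologues) and mapped back to
reference coordinates with the known segment map. This isolates the
package's own computation from aligner behaviour, which is out of scope.
Fragment lengths are triangular on `[frag_min, frag_max]` with mode
`frag_median` — only the median and range of the real libraries are
known, and a triangular law is the minimal shape honouring all three
numbers. Reads crossing a junction or landing in inserted sequence are
dropped as unmappable, the alignment-level analogue of an unalignable
split read.

**Copy bookkeeping.** Each event contributes a derivative contig at an
integer copy number and consumes baseline homologues: unbalanced events
consume one homologue of the chromosomes they rearrange; amplicon
fragments consume *all* baseline copies of their loci, so the planted
copy number is the total there and a noiseless probe over a copy-20
amplicon on ploidy 2 reads exactly `log2(10)`. Events that would drive
the baseline negative anywhere raise a conflict error, which also
prevents amplicons from overlapping whole-chromosome events. One truth
record is emitted per non-reference segment adjacency, carrying copy
number, any inserted sequence, and the microhomology realised by the
flanking reference sequence.

**Artifacts.** Exact PCR duplicates, offset duplicates (end-1 5′
position shifted 1–2 bp), and coligation chimeras joining end 1 of one
fragment to end 2 of an unrelated one, each at a configurable per-pair
rate. No quantitative chimera rate is published for the motivating data;
the default in examples is 0.001 and it is a free parameter. Mapping
quality is 60 except for reads overlapping designated repeat intervals
(uniform 0–29) — the minimal mechanism that exercises the mapq filter.
Not modelled: GC-dependent coverage, sequencing base errors, and real
mate-pair chemistry (mate-pair libraries are simulated FR like the
short-insert library; the orientation convention is a constant that no
computation here depends on). Passing tests therefore show correctness
of the bookkeeping and statistics, not robustness to alignment noise in
real data.

**Scale.** Everything runs at desk scale: the demonstration scenario is
a 4 Mb, five-contig genome (six-fragment copy-20 coamplification with a
20 bp shard and an amplified fusion pair, a 160 kb deletion fusing two
genes in their first introns, an unbalanced translocation driving a
run-through fusion, a balanced 200 kb inversion), sequenced at roughly
6× fragment-span coverage per copy in the short-insert library plus a
mate-pair library. The 12.4 Gb subtetraploid scale of a real genome
enters only through `physical_coverage()`, whose worked example
(43 × 10⁶ pairs × 504 bp / 12.4 × 10⁹ bp ≈ 1.75) reproduces the
published ≈ 1.7-fold figure; the corresponding mate-pair statement
(1.25 × 10⁶ pairs × 3 kb ≈ 0.30×, published as 0.5×) does not follow
from the printed numbers — the pair count is probably per lane — and is
deliberately not reproduced.

# The detection model and its calibration

`detection_probability(lambda, c, k)` is the Poisson tail
`P(X ≥ k)`, `X ~ Poisson(λ·c)`: amplified junctions are present in many
copies and so are sampled proportionally more often. In simulation the
*supportable* window of a junction is `frag_median − 2·read_length`
rather than `frag_median`, because both 36 bp reads must clear the
junction for the pair to count; at the classic geometry that is a
(504 − 72)/504 ≈ 14% reduction. The coverage-calibrated experiment
(`detection_experiment()`) therefore compares empirical single-copy
detection with the Poisson tail at the *realized* per-copy
supporting-pair rate, which tests the distributional claim itself; the
nominal-λ value (≈ 0.51 at 1.7×) is reported alongside. Amplified
(copy-20) junctions saturate detection, reproducing the qualitative
single-copy/amplified asymmetry.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere in memory; GFF3 converts
  to 1-based closed on disk, BEDPE and BED are written 0-based.
* Spans are measured between breakend-interval midpoints; `span ==
  min_span` is kept.
* Microhomology is the ambiguous-placement length — the maximal `L` with
  the last `L` retained bases of the 5′ flank equal to the first `L` of
  the 3′ flank — scanned to 20 bp; a junction is blunt, microhomologous
  or inserted, exclusively. Shard search is exact-match only (both
  strands); near-matches are out of scope for determinism, and multi-hit
  inserts return "ambiguous" rather than a guess.
* Probe log-ratios floor copy number at 0.25 so homozygous losses stay
  finite. Chromosomes with fewer than `2·cn_min_probes` probes yield one
  segment with a warning rather than an error.
* Every generator takes a seed and restores the caller's RNG state;
  identical seeds give byte-identical output.

# Problem sizes in the tests

The suite generates all fixtures in code: genomes of 0.1–4 Mb, libraries
of 2 000–190 000 pairs, 20-replicate recovery and detection experiments,
200-replicate depth-ratio checks at 3 000 pairs, and a 48-junction
shuffled amplicon for microhomology round-trips. These sizes were chosen
so each statistical check has narrow-enough Monte-Carlo error (binomial
or Poisson standard errors are computed in the tests themselves) while
the whole suite stays interactive.

# Known limitations

Breakpoints are resolved only to read-pair intervals (no split-read or
assembly refinement); genotyping and allele-specific copy number are not
attempted; gene models are single-transcript so isoform-specific fusion
calls are out of reach; the run-through partner choice is a
nearest-gene convention, not a learned rule; and the simulator's uniform
sampling means coverage biases of real libraries are unrepresented.
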