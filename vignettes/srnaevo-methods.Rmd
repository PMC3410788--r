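---
title: "Methods and design notes for srnaevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for srnaevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaevo)
```

# Scope

`srnaevo` is an integrated toolkit for evolutionary analysis of microRNAs
from small RNA sequencing data. It covers five connected analyses:

1. **Library preprocessing** — 3' adapter trimming and collapsing of
   identical reads into unique tags with counts.
2. **Annotation filtering and expression profiling** — removal of reads
   matching an ncRNA/coding annotation database, then per-arm (5p/3p)
   counting over known hairpin precursors.
3. **Homolog identification from whole-genome alignments** — placing a
   precursor on the reference genome, excising the matching region from a
   UCSC MAF multiple alignment, and stitching per-species homolog
   sequences.
4. **Evolutionary distances** — Kimura two-parameter (K2P) distances and
   identities for precursor, mature and seed regions of each homolog pair.
5. **Expression divergence** — per-arm counting of each species' library
   against its own homolog sequences, TPM normalization, and a Poisson
   likelihood-ratio test with Benjamini–Hochberg correction.

Novel-miRNA *discovery* is out of scope: reads left over after profiling
are exported for an external probabilistic predictor, and predicted
candidates can be crosschecked against a known catalogue with
`crosscheck()`. Construction of the whole-genome alignment itself is also
out of scope; the package consumes MAF.

# Preprocessing model

Adapter trimming looks for the leftmost position at which a suffix of the
read matches a prefix of the adapter with at least `min_overlap` aligned
bases (default 6) and a mismatch fraction of at most `max_mismatch_frac`
(default 0.1). Full internal adapter occurrences trigger trimming the same
way. Inserts shorter than `min_len` (default 18 nt, a typical small-RNA
lower bound) are discarded. Reads in which no adapter is found are kept and
flagged by default (`keep_untrimmed`), since discarding them silently would
bias against long inserts; the choice is configurable because library
protocols differ.

Collapsing is exact: one tag per distinct sequence, ranked by count
descending with lexicographic tie-breaks, labelled
`<lib>_<rank>_x<count>` so counts survive FASTA round-trips. U is
normalized to T internally; report output can be rendered back as RNA.

# The internal short-read aligner

Classic small-RNA pipelines delegate read placement to an external ungapped
aligner run with "report all hits in the best stratum within *v*
mismatches, optionally forward-strand only". `srnaevo` implements exactly
this contract internally (`build_index()`, `align()`): every end-to-end
placement with at most `max_mismatch` mismatches is found, and all
placements achieving the minimal mismatch count are reported, ordered by
(target, start, strand). N counts as a mismatch on either side.

Completeness comes from pigeonhole seeding: a query is partitioned into
`max_mismatch + 1` disjoint blocks, so any placement within the bound
contains at least one exact block, which is found by exact k-mer lookup
(k = 6 by default; queries shorter than `(max_mismatch + 1) * k` fall back
to scanning all offsets). The test suite verifies exact agreement with a
brute-force Hamming oracle over all offsets and strands on randomized
instances (18–26 nt queries, up to 2 kb targets, up to 2 mismatches).

Reads are 18–26 nt and references are precursor-scale, so exhaustive seeded
search is fast at desk scale; no heuristics are needed.

# Filtering and per-arm profiling

The database filter discards a read iff it has at least one alignment
(either strand) within `max_mismatch_db` mismatches (default 2). Profiling
against known precursors is sense-only with at most 1 mismatch, mirroring
the settings those pipelines use for miRNA quantification.

Arm assignment is deliberately simple and order-free: a read is assigned to
the 5p (or 3p) arm iff at least 50% of it overlaps that arm's interval,
otherwise it is unassigned (loop-spanning reads). If a read straddles both
arms at exactly half each — only possible for an even-length read across
adjacent intervals — the larger overlap wins and exact ties go to 5p.
Multi-mapping reads contribute their full collapsed count to every
best-stratum precursor by default (mirroring all-hit reporting); an even
fractional split is available via `filter_config(fractional_counts =
TRUE)`. Counts therefore satisfy `count_5p + count_3p + unassigned ==
total` per precursor, and database order never changes any count.

# Homologs from MAF

Coordinates are 0-based half-open on the forward strand everywhere
internally; MAF's strand-relative minus-strand rows are converted at the
boundary (`[srcSize - start - size, srcSize - start)`). The species name of
a MAF row is its `src` prefix before the first dot.

`locate_precursor()` places a precursor by exact substring search on both
strands first, falling back to a seeded ungapped search (11-mer seeds,
full-length extension, ≥ 95% identity) when the genome copy has diverged
from the supplied precursor sequence. Placement must be unique; ties raise
an ambiguity error listing all loci, because silently picking one would
corrupt everything downstream.

`slice_maf()` excises, per overlapping block, the columns from the first to
the last column whose *reference* character is a non-gap base inside the
query interval. Interior columns where the reference is gapped (species
insertions) are retained. Blocks are assumed single-coverage on the
reference (multiz-style); overlap is an error, not silently resolved.
`extract_homologs()` concatenates the slices in reference order, pads
species missing from some blocks with gap columns (flagged `partial`), and
flags species missing everywhere as `absent`. Partial homologs are not
dropped: distances are computed over the covered columns and the compared
length is reported as `coverage`, so the downstream ortholog screen can
enforce its coverage rule explicitly.

The ortholog screen retains a (precursor, species) candidate when identity
≥ 0.9 over a compared length strictly greater than 50 nt with at least 10
supporting reads — thresholds mirroring the phrasing "at least 90%
identity", "greater than 50 nt", "at least ten reads", all configurable.

# Kimura two-parameter distances

For two aligned rows, columns are classified per position: both bases in
ACGT give a match, transition (A↔G, C↔T) or transversion; any gap gives a
gap column; anything else (N) an ambiguous column. Gap and ambiguous
columns are excluded from both numerator and denominator (pairwise complete
deletion — the standard K2P convention). With transition proportion
$P$ and transversion proportion $Q$ over the compared columns,

$$K = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\,\big).$$

When $1 - 2P - Q \le 0$ or $1 - 2Q \le 0$ the transform leaves its domain
and the estimate is flagged `saturated` instead of returning a number.

Regions are mapped from the ungapped reference precursor through the gapped
reference row to alignment columns: the whole precursor, each mature arm,
and each seed. The seed defaults to mature positions 2–8 (1-based; 7 nt),
the dominant convention for target-recognition sequence. The ratio of
miRNA divergence to a user-supplied synonymous divergence
(`kmir_ks_ratio()`) serves as the constraint diagnostic; values below 1
suggest purifying selection. Whether identity should be computed over
alignment columns or the shorter sequence length is ambiguous in the field;
the package uses compared columns and reports `coverage` separately so
either convention can be reconstructed.

# Hairpin structure

`fold()` maximizes total pair weight (GC = 3, AU = 2, GU wobble = 1) over
non-crossing structures with a minimum hairpin loop of 3 nt, by a
Nussinov-style dynamic program with a deterministic traceback (pair the two
ends when optimal, else leave an end unpaired, else bifurcate at the
smallest split). Thermodynamic nearest-neighbor folding is deliberately
*not* reimplemented — the weighted-pair DP is an explicit stand-in whose
optimum is verified against exhaustive enumeration in the tests, and an
externally computed dot-bracket string can be supplied wherever a fold
result is consumed (`project_structure()` accepts plain strings).

The hairpin plausibility filter restricts precursor length, pairing score
per nucleotide, terminal loop size and mature-arm pairedness, with `animal`
and `plant` presets (`hairpin_params()`); the plant preset allows longer
precursors (60–300 nt) and larger loops, reflecting the broader length
distribution of plant pre-miRNAs. All preset values are provisional
defaults, exposed in configuration, rather than calibrated constants.

# Expression divergence

Each species' reads are aligned to that species' own ungapped homolog
sequences (sense-only, ≤ 1 mismatch, best stratum), with arm intervals
projected through the homolog alignment into each species' coordinates.
The normalization total $N$ defaults to the summed collapsed count of reads
mapped to the homolog reference set, because it is the only denominator
the package can compute without external inputs; genome-wide mapped totals
can be supplied instead (`totals =`).

For counts $x_1, x_2$ with totals $N_1, N_2$, the null of a common rate
gives expected counts $\hat e_i = N_i (x_1+x_2)/(N_1+N_2)$ and the deviance

$$G = 2\sum_i x_i \ln(x_i/\hat e_i), \qquad 0\ln 0 \equiv 0,$$

compared to $\chi^2_1$. This is the closed form of the Poisson regression
(log-offset) likelihood-ratio test for two groups — identical likelihood,
no iterative fitting — and the test suite checks the equality against
`glm(..., family = poisson)` deviances. 5p and 3p arms are tested
separately; p-values are Benjamini–Hochberg adjusted across all tested
arms by default (`correction = "none"` switches to raw p). For the scatter
table one pseudocount read is added before the log2-TPM transform so zero
counts plot; the test itself always uses raw counts.

`yates_chisq()` (Pearson chi-square with continuity correction, df 1,
via `stats::chisq.test`) compares detection proportions between two
screening methods on a 2×2 table.

# Synthetic data generator

The generator (`simulation_config()`, `make_genome()`, `mutate_genome()`,
`make_maf()`, `make_hairpin()`, `simulate_library()`,
`write_demo_fixtures()`) emulates every input of the pipeline at desk
scale: uniform-composition genomes with planted perfect stem-loop
precursors; orthologous genomes mutated at known per-site transition
(p\*), transversion (q\*) and indel rates with the true column-wise
alignment returned; multi-species MAFs built by threading the pairwise
alignments on reference positions, chopped into blocks of ≤ 500 columns;
and read libraries whose per-arm counts are Poisson(rate × depth), reads
being mature-arm substrings with up to 2 nt of end wobble plus the 3'
adapter.

All randomness is behind one seeded generator, so every fixture is
reproducible byte for byte. Indels are suppressed inside planted precursors
by default so arm projection tests stay interpretable; a flag allows them.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: sequencing error and quality profiles,
ligation and composition biases, expression overdispersion beyond Poisson,
repeat-induced multi-mapping at genome scale, isomiR end-processing beyond
uniform wobble, and realistic indel length spectra. The demonstration
fixture uses a 6 kb genome, four precursors, two species at substitution
rates 0.04/0.02, and libraries of a few hundred reads; the statistical
recovery checks use 10 kb alignments at p\* = 0.10, q\* = 0.05 and 10,000
LRT replicates at expected counts 20–30. These sizes were chosen as the
smallest at which the binomial/Poisson error bounds in the tests are
meaningfully tight.

# Numerical and degenerate-input choices

* Best-stratum output is ordered by (target, start, strand) — fully
  deterministic, all ties reported, never sampled.
* `poisson_lrt()` clamps tiny negative deviances from floating-point
  rounding to 0, so equal rates give exactly G = 0, p = 1; `x1 + x2 = 0`
  is returned as undefined with p = 1 rather than an error, since empty
  arms are routine.
* K2P saturation is a flag, not an exception; degenerate zero-column
  comparisons yield NA estimates with coverage 0.
* `trim_adapter` on its own output is a no-op (idempotence is tested).
* Pipeline outputs contain no timestamps or absolute paths, so the
  manifest (MD5 of every input and output) is byte-identical across
  reruns; determinism is a tested property.

# Known limitations

* The weighted-pair fold is a structural plausibility tool, not a
  free-energy model; do not interpret its score thermodynamically.
* Gapped read alignment, quality-aware trimming and paired-end input are
  unsupported (small-RNA reads rarely need them).
* Expression testing is pairwise Poisson; overdispersed designs with
  biological replicates belong in a negative-binomial framework.
* Ks must be supplied externally; the package does not estimate synonymous
  divergence from coding alignments.
* MAF handling assumes the reference species is the first row of each
  block on the + strand (standard multiz layout).
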