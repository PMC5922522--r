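---
title: "Validating copy-number-loss calls: concordance, read depth and breakpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating copy-number-loss calls: concordance, read depth and breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvlossr)
```

## The problem

Copy-number losses (deletions) are called from two very different data
types: SNP-microarray intensity patterns and whole-genome sequencing.
Reports derived from the two platforms for the *same* individuals disagree
surprisingly often, and published callsets are additionally filtered by
cross-platform experimental confirmation, which can introduce false
negatives of its own. `cnvlossr` implements the three analyses needed to
study this situation quantitatively:

1. **Callset concordance** — how often do two loss reports agree, under an
   explicit, directional base-pair overlap rule?
2. **Read-depth validation** — does an independent sequencing dataset show
   the depressed coverage a real loss must produce?
3. **Breakpoint seeking** — can the deletion junction itself be recovered
   from raw reads by local assembly?

A fourth module simulates all required inputs (reference, deletions, reads,
probes, discordant callsets) so the entire pipeline is testable without any
external download.

## Coordinates and containers

Every interval in the package is 0-based half-open on a named chromosome.
The readers translate each format's native dialect at the boundary: BED is
already half-open; report tables declared `one_based` are shifted; VCF
structural-variant records span `(POS, END]` and become `[POS, END)`.
Fixing one internal convention removes an entire class of off-by-one bugs;
the `dialect` argument exists because supplementary tables in the wild do
not declare their convention.

Callsets, probe maps, depth profiles and all results are tibbles, so the
natural workflow is a dplyr pipe; test objects additionally provide
`tidy()`/`glance()` methods.

## The concordance rule

Two calls from different methods are considered "the same" when one covers
at least 50% of the other's base pairs. Two properties of this rule matter
and are deliberate:

* **Directional**: the fraction is measured against the *query* call's own
  length. A short call inside a long one can match while the long one fails
  in the other direction — which is exactly why the two "overlapped" counts
  of a comparison table differ.
* **Single-partner**: several partners covering 30% each do not add up.
  The published table notes attribute count asymmetries to several calls of
  one method matching a *single* call of the other, which is only coherent
  under single-partner semantics.

Two preprocessing filters make cross-platform comparison fair: sequencing
calls spanning fewer than 5 array probes are removed (an array caller that
requires 5 consecutive probes cannot possibly report them), and calls
outside annotated gene regions are removed to avoid highly repetitive
regions. Matching is within-sample; a sites-only callset (sample `"*"`)
matches against all samples. Percentages are rounded half-up to two
decimals for report parity.

`overlap_length_stats()` pairs each matched query call with its best
partner and summarises overlap lengths (mean, mode) and overlap/length
ratios; the mode is the most frequent observed value, smallest on ties.

## Read-depth tests

For a candidate region, per-base depth is extracted from the BAM counting
reads whose alignment spans the base (CIGAR M/=/X), excluding duplicate,
secondary, supplementary and unmapped records (mapping quality threshold
configurable, default 0). The region is compared with background depth in
two ways.

**Chi-square test** (H0: the region and background depth distributions are
equal). Depths are histogrammed over shared integer bins `0..d_cap` with
`d_cap` the 99th percentile of the pooled values; adjacent bins are merged
until every expected count reaches 5 (the usual validity rule); the
statistic is the standard two-sample sum of `(O - E)^2 / E` on
`bins - 1` degrees of freedom. Fewer than two surviving bins yields status
`NA` rather than a meaningless statistic.

**Permutation test** (H0: region mean depth is at least the background's).
An equal-length contiguous background stretch is drawn uniformly from the
chromosome, excluding the tested region (and optionally all other
candidates, the default in the pipeline, so the null sample is not
contaminated by other losses). Region and background are pooled; each of
R = 999 resamples draws a region-length subset without replacement and
records its mean; the reported p-value is the add-one estimate

> p = (1 + #{resample mean <= region mean}) / (R + 1).

This form avoids p = 0, makes total ties give exactly p = 1 ("the region is
at least as deep as everything resampled" — the signature of a relatively
*high*-depth region, not a loss), and with pooled sizes small enough an
exhaustive mode enumerates all C(2L, L) subsets instead. Status is `NA`
exactly when every pooled value is zero: an all-zero window carries no
resampling information (this is how a flank test inside a larger dropout
reports itself).

**Flank (concavity) tests.** A genuine loss is a dip: the same two tests
are run against the upstream and downstream flanks (flank length =
`flank_factor` x region length, default 1 — the published figures show
windows on the order of the call width, and equal lengths are what the
permutation test wants). A flank outside the contig reports `NA`.
`batch_summary()` tabulates, per test, the fraction of non-`NA` results
below each significance level plus the `NA` fraction.

No multiple-testing correction is applied anywhere; the analyses this
package reproduces report raw per-region p-values, and we keep that
contract (callers can `p.adjust` downstream).

### A calibration caveat that matters

The permutation test permutes *individual bases*. Real read depth is not
exchangeable at the base level: one read correlates coverage across its
whole length, so the variance of a regional mean is inflated by roughly the
read length relative to the i.i.d. case, while resampled means from the
pooled values are not inflated. Against read-structured coverage the
per-base permutation test is therefore sharply anticonservative under the
null (we measure ~50% rejection at alpha = 0.05 in simulations with
100 bp reads). Its practical use survives because the signal of a real
homozygous loss — depth zero against ~4x — is far beyond any calibration
error. Accordingly:

* the package's *calibration* study uses `simulate_depth_profile(model =
  "iid")`, the exchangeable null the test actually assumes, where we verify
  the type-I error sits at its nominal level;
* the *power* study uses the full read simulator (`model = "reads"`-like
  coverage from paired reads), where homozygous kilobase deletions at 4x
  reject essentially always;
* users testing subtle depth changes on real data should be aware that
  small p-values against autocorrelated background overstate evidence.

## Breakpoint seeking

For each candidate: reads overlapping the two breakpoint windows
(`candidate boundary +/- flank_bp`, default 300 bp) and unmapped reads
placed there via a mapped mate are collected and assembled with a de Bruijn
graph (k = 21 by default; nodes are (k-1)-mers, edges observed k-mers of
the reads and their reverse complements; reads are split at `N`s).
Contigs are maximal non-branching paths, extracted in lexicographic order
so assembly is reproducible without a seed, and collapsed with their
reverse complements.

Sequencing errors at low coverage produce singleton k-mer side-paths. At
10x or more the standard cure is pruning edges below multiplicity 2
(`min_count = 2`); at ~4x that pruning would destroy true contiguity
(expected true k-mer multiplicity is only ~2–3), so the default is
`min_count = 1` and error paths are removed structurally instead: short
low-coverage dead-ends (tips) and short low-coverage alternative paths
(bubbles) are clipped for two rounds before final extraction.

Each sufficiently long contig is split-aligned against the candidate's
reference window (padded by flank, insert length and read length, since
contigs overhang the read windows). Anchor placements come from exact
21-mer seeds at either end (and one k-block inward, tolerating one seed
mismatch); the split point is the leftmost maximiser of total matching
bases over all prefix/suffix decompositions. That leftmost convention
reports *left-normalized* junctions, and the simulator normalizes planted
deletions the same way, so exact-junction comparisons are well defined;
microhomology at the junction (several equally scoring splits) is flagged
`ambiguous`. An implied deletion shorter than `min_deletion` (default
50 bp; the field has no published numeric threshold for "far apart on the
reference", so this is our explicit choice separating junctions from indel
noise) is not called, and a contiguously mapping contig implies distance 0
and falls out naturally.

Evidence is classified per candidate, in strict preference order:

* `break_read` — a contig spans the junction (direct evidence);
* `paired_end` — otherwise, at least `min_pairs = 2` read pairs straddle
  the candidate with apparent insert more than 3 SDs above the fragment
  model and consistent with a deletion of roughly the candidate's length
  (breakpoints then reported at the candidate's own boundaries, imprecise);
* `unsupported` — neither signal.

The paired-end route is deliberately a fallback only for candidates
assembly fails on: at ~4x many true junctions simply have no spanning
read, and a spliced-mapping fallback was the original workaround; here it
is re-implemented internally as the anchored split alignment plus the
insert-size channel, keeping the pipeline self-contained.

## The simulator

`simulate_dataset()` generates: an i.i.d. uniform A/C/G/T reference;
non-overlapping deletions (uniform lengths in a configurable range,
left-normalized, separated by at least two read lengths plus two inserts,
clear of contig ends) assigned homozygous/heterozygous by `zygosity_mix`
on a diploid donor (haploid mode available for deterministic tests);
paired-end reads with Poisson fragment starts at `mean_depth` (default 4x,
the low-coverage regime that motivates the whole design), normal insert
lengths (300 +/- 30 by default), constant read length (100) and i.i.d.
substitution errors; a probe grid with exponential gaps (mean 1 kb,
emulating irregular array spacing); a regular gene tiling; and three
discordant callsets derived from the truth by boundary jitter, missed
calls, spurious calls and minimum-size censoring (the array-style profile
censors small calls, emulating probe-spacing blindness).

Alignment records are emitted *by construction* from the known
donor-to-reference coordinate maps rather than by running an aligner: the
test surface needs exact truth labels (which reads cross which junction,
expected depth per zygosity class), not aligner behaviour. Reads crossing
a junction are emitted unmapped and placed at their mapped mate's
coordinate (probability `u = 1` by default, mirroring the premise that
junction reads fail to map; `u < 1` exercises a soft-clip path instead).
Per-base depth is then exactly `mean_depth` over null sequence, about half
over heterozygous deletions and 0 over homozygous ones.

What the simulator does **not** model — GC bias, mappability, repeats,
indel errors, quality strings, chimeric fragments — bounds what passing
tests show: they validate the algorithms' logic and calibration under the
stated statistical regime, not robustness to every artefact of real
sequencing.

## Benchmark design choices

The packaged studies (acceptance script and test suite) use problem sizes
chosen to exercise the claims at meaningful statistical resolution while
staying desk-sized: 400–1000 null regions for calibration, 200–500
homozygous kilobase deletions at 4x for power, 60–100 planted deletions
(200 bp–5 kb) for breakpoint recovery at error-free 10x and at 4x with 1%
substitution error. Breakpoint and power benchmarks plant homozygous
deletions: power against a hemizygous half-depth signal and junction
recovery from halved junction coverage are genotype questions, not
properties of the seeker, and would confound the measurement. The
published-scale chromosome-wide inputs (hundreds of samples, real BAMs)
are out of desk scope by design; the concordance recipe for the published
chromosome-11 tables is shipped and runs as soon as the supplementary loss
lists are converted with `xlsx_to_tsv()` into `extdata/s2/`.

## Numerical details worth knowing

* Percentages in concordance rows are rounded half *up* to 2 decimals
  (base R `round()` would round half to even and change printed values).
* Permutation p-values live on the grid `k/(R+1)`; with R = 999 the
  smallest attainable p is 0.001, so "p < 0.01" and "p < 0.05" describe
  the same rejections for a region at the floor.
* Chi-square bin merging always merges the lightest bin into its lighter
  neighbour, deterministically.
* Background sampling enumerates permissible start positions explicitly
  and errors out when none exists (e.g. region covering the chromosome).
* All stochastic entry points take explicit seeds; batch runs derive
  per-region seeds deterministically from the master seed, which is what
  makes whole-pipeline reruns byte-identical.
* Tie-breaks: equal best overlap partners resolve to the earlier-sorted
  partner; equally scoring split points to the lowest coordinate; equal
  modes to the smallest value.

## Worked example

```{r example, eval = FALSE}
library(cnvlossr)

spec <- simulation_spec(ref_length = 60000, n_deletions = 4,
                        zygosity_mix = 1, mean_depth = 10,
                        error_rate = 0, seed = 7)
sim <- simulate_dataset(spec, dir = "sim_out")

v <- run_full_validation(sim$bam_path,
                         setNames(list(sim$ref$seq), "chrS"),
                         sim$truth, outdir = "val_out", seed = 5)
v$per_candidate
v$whole_summary
v$evidence_summary

st <- run_concordance_study(sim$callsets, probes = sim$probes,
                            genes = sim$genes)
st$tables
```

## Known limitations

* Gains, inversions, duplications and translocations are out of scope; the
  evidence model is deletion-specific.
* CRAM input and assembly liftover are not supported; inputs must share an
  assembly (enforced via the callset `assembly_tag`).
* The permutation test's base-level exchangeability assumption (above) is
  the main statistical caveat for real-data use.
* The split aligner handles substitutions, not indels, inside anchors; an
  indel-containing junction flank shortens the usable anchor instead.
* Depth extraction counts full alignments only (no base-quality filtering);
  this matches the conventional depth definition but differs from callers
  that weight by base quality.
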