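---
title: "Models and methods behind dsmda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dsmda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsmda)
```

# The problem

Preparing a shotgun sequencing library normally consumes far more DNA than
the sequencer itself needs: a picotiterplate (PTP) region of 340,000
enriched beads requires, under the one-bead-one-molecule notion, only
340,000 single-stranded library molecules — about 0.13 pg of 700-nt
fragments — while standard protocols start from a microgram and lose more
than 99% of it along the way. Two strategies exist for scarce samples:
**direct sequencing (DS)** of the unamplified DNA after exact qPCR
quantification of the library, and **multiple displacement amplification
(MDA)**, an isothermal whole-genome amplification with random hexamer
primers and phi29 polymerase. MDA rescues the input amount but introduces
well-known artifacts: strong coverage bias driven by uneven priming,
chimeric molecules, reagent-borne contamination, and template-free hexamer
concatemers.

`dsmda` implements, at desk scale, the complete analytical tool chain for
comparing the two strategies: a generative read simulator with known
ground truth for both protocols, read quality control, word-hash read
mapping with coverage tracks, the statistical machinery for comparing
coverage distributions, hexamer-composition attribution of unassigned
reads, duplicate clustering, and the molecule/mass/qPCR budgeting
calculator for planning minimal libraries.

# Synthetic data: what the generator emulates

## Genomes

`generate_genome(length, gc, seed)` draws i.i.d. bases with
$P(G)=P(C)=\mathrm{gc}/2$. This captures genome-scale GC composition — the
signal that drives hexamer attribution — but none of the higher-order
structure (codon bias, repeats, skew) of real genomes.
`generate_null_genome()` is the uniform-composition artificial genome used
as the compositional null. A genome description of "purine–pyrimidine
ratio 0.5" is ambiguous (a *ratio* of 0.5 would mean 1:2); we read it as a
purine *fraction* of 0.5 and implement the uniform law, with any other
base composition available through `generate_genome()`.

## DS reads

Sonication followed by bead cleanup is modelled as fragment lengths from a
truncated Normal(700, 150) on [200, 1000] bp with fragments under 400 bp
rejected (`fragment_model()`); only the range and the cutoff are
protocol-determined, the Normal shape is our choice. Fragment starts are
uniform; each read is the 5' prefix of its fragment on a uniformly chosen
strand with length $\min(\text{fragment}, \mathrm{TN}(230, 137) \ge 40)$
nt, matching typical pyrosequencing run summaries. Per-base qualities are
round(Normal(36, 3.5)) clamped to [2, 41]; no position-dependent decay is
modelled. Reads are error-free at the base level — flowgram and
homopolymer errors of the 454 chemistry are out of scope, which is why
mapping identity is exactly 1.0 in the tests and would not be on real
reads.

## MDA reads

No mechanistic MDA read model is established in the literature at this
granularity, so the package adopts the minimal mechanism that reproduces
the reported phenomena (priming-distance-driven bias):

* priming sites placed by a Poisson process at `priming_rate` sites/kb
  (default 0.1);
* each site gets a log-normal amplification weight with sdlog
  `amplification_dispersion` (default 3);
* target reads pick a site proportionally to weight and anchor their
  fragment uniformly within a `window` (default 500 bp) downstream.

With the defaults, 2,000 simulated reads over 100 kb produce coverage
spikes two orders of magnitude above the mean with most of the genome
uncovered — the qualitative severity reported for real MDA libraries
(isolated peaks above 100x over a sparse baseline). Each read is
independently re-classed as a **chimera** (5%; two half-fragments from two
independently drawn sites), a **contaminant** read (5%; drawn uniformly
from the contaminant genome, standing in for the amplification reagent's
host bacterium), or a **hexamer concatemer** (55%; a concatenation of
hexamers drawn from the contaminant genome's hexamer frequencies). The
class mix was fixed once so that the large majority of MDA material is
unassignable, as observed at full scale, and is fully configurable in
`mda_params()`. In the degenerate limit (dense priming, dispersion
$\to 0$, artifact rates 0) the read-start distribution is statistically
indistinguishable from DS, which the tests verify.

Every simulated read carries a ground-truth record (class and 0-based
half-open origin intervals on the forward strand; chimeras carry two,
concatemers none), so downstream stages are testable without any external
data.

# The library calculator

Mass and molecule counts interconvert through
$\mathrm{mass} = n \cdot \ell \cdot m / N_A \cdot 10^{12}$ pg with $m$ =
330 g/mol/nt (ssDNA) or 650 g/mol/bp (dsDNA) — the standard average
residue masses, configurable in `mass_model()`. qPCR calibration is an
OLS fit of Cq on $\log_{10}$(molecules) (`fit_standard_curve()`), with
amplification efficiency $E = 10^{-1/\text{slope}} - 1$; replicate Cq
values are averaged in Cq space (standard practice; a spread above 1 Cq is
flagged). `required_molecules()` divides a region's bead capacity evenly
across MIDs; only the 1/8-region capacity (340,000) ships as a default,
other regions must be configured. `enrichment_cycles()` returns the
smallest $n$ with $\text{current}\cdot(1+E)^n \ge \text{target} \cdot
\text{margin}$. The default `safety_margin = 2` plans for sub-nominal
amplification and downstream losses; with it, a library quantified at
41,043 molecules against a 170,000-molecule target is planned at 4 cycles
(3 under a bare margin of 1). The margin is a design choice of this
package, not a claim about how any particular laboratory derived its cycle
count.

# Read QC

Stages run in a fixed order: sliding-window quality trimming (longest
prefix whose every complete window of 10 nt has mean Phred ≥ 20), 3'
adaptor trimming, length filter (≥ 40 nt), then a trimer-entropy
low-complexity filter. Adaptor detection is Smith–Waterman local alignment
(match +2, mismatch −3, gap open −5, gap extend −2 per base) of the
adaptor against the 3'-most max(100, 2·adaptor) nt of the read, reported
at score ≥ 24 — roughly a 16-nt exact match. The threshold was calibrated
against the null: fewer than 0.1% of 10,000 random adaptor-free reads
reach score 30. This replaces an external BLAST e-value screen with an
equivalent in-package criterion. Hits are trimmed from the hit start to
the read end (adaptor read-through semantics); trimming only the matched
span would be the alternative for internal hits, which we do not attempt
to distinguish. The entropy filter requires the Shannon entropy of
overlapping trimers to reach half the attainable maximum
$\log_2 \min(4^k, \text{windows})$; homopolymer and concatemer-like reads
fall well below it. The QC report partitions every input read by its first
failing stage.

# Mapping and coverage

`build_index()` hashes every overlapping 13-mer of the forward reference
strand. `map_reads()` collects seeds for the read and its reverse
complement, votes by diagonal (`ref_pos − read_pos`), and extends the best
diagonal ungapped in both directions from the first seed block while the
running identity stays ≥ 0.9. A single seed suffices to nominate a
diagonal. Ties are fixed (most seeds, then leftmost reference position,
then forward strand), making coverage deterministic. Gapped refinement is
deliberately omitted: simulated reads are error-free and the desk-scale
use case does not need indel handling, so reported alignments have
identity 1.0 and at most 2 bp of placement slack from seed-block
boundaries. Reads below `min_match_len` aligned bases are unmapped and
flow to the attribution stage. Coverage tracks are exact per-base interval
counts; summaries expose mean, max, breadth and the depth histogram, and
tracks round-trip through fixed-step wiggle and BED.

# Coverage statistics

The two-sample Cramér–von Mises statistic is
$T = \frac{nm}{(n+m)^2}\sum_i \left(F_x(z_i) - F_y(z_i)\right)^2$ over all
pooled points (ties evaluated with multiplicity). p-values come from
random relabelling of the pooled sample,
$p = (1 + \#\{T^\ast \ge T\})/(1 + n_{\text{perm}})$, with exact
enumeration available for tiny samples; asymptotic tables are not used.
Coverage tracks are compared by the subsampling protocol: 100 replicates
of 1000 positions drawn without replacement from each track's depth
vector, one CvM test per replicate, with the median p reported (and a
pooled whole-track test available via `pooled = TRUE`, since it is not
stated whether a single pooled test or an aggregate over subsamples
produced published figures of this kind). Kruskal–Wallis is delegated to
`stats::kruskal.test` and re-checked against a naive rank oracle in the
tests.

Three numerical caveats discovered during development are worth
recording. First, per-base depths are autocorrelated over roughly a
fragment length, so a chi-square goodness-of-fit test of the raw per-base
histogram against Poisson is invalid (the statistic inflates by two
orders of magnitude); the uniformity property is therefore tested on
depths at positions spaced 1 kb apart, where it holds cleanly. Second,
permutation CvM p-values are uniformly distributed under the null only
when both samples are exchangeable; the tests verify this over hundreds
of simulated nulls. Third, for a track compared against itself the
*population* median of the per-replicate p-values sits at (slightly
above) 0.5, so the sample median of 100 replicates straddles that
boundary with a standard error of about 0.06; asserting "median ≥ 0.5"
directly would fail a fifth of all seeds under a perfectly calibrated
test. The tests therefore assert it as a one-sided sign test (the median
must not be *significantly* below 0.5 at α = 0.01), which keeps full
power against genuine anti-conservativeness.

# Hexamer attribution

`count_kmers()` counts overlapping k-mers (default k = 6) on the given
strand in lexicographic order, skipping windows with ambiguous bases;
reverse-complement pooling is available via `canonical = TRUE` but is not
the default. Genome profiles destined for comparison with read profiles
are built with `genome_profile()`, which counts the genome **and its
reverse complement** — reads sample both strands, and for near-random
sequence a one-strand genome profile would have twice the compositional
variance of what reads converge to.

Comparing abundance *distributions* across profiles of very different
depths is subtle: counts live on a lattice of 1/total and carry
depth-dependent sampling variance, and a two-sample test will detect those
nuisances rather than composition. `attribute_unassigned()` therefore
resamples every profile multinomially to the common depth
(`resample_profile()`, the with-replacement analogue of rarefaction)
before running the CvM comparisons against the null genome and each
candidate. With this convention, reads genuinely drawn from the null
genome are not rejected against it (calibration verified over repeated
seeds), while profiles of different GC reject strongly.

Hierarchical clustering is average linkage on `1 − r` (Pearson) over
relative abundances; no linkage or distance is canonical for this task and
these are the common defaults. Bootstrap supports resample the $4^k$ k-mer
columns with replacement and report the percentage of replicate trees
containing each leaf bipartition — ordinary bootstrap percentages, not
multiscale-corrected values, and labelled as such. The attribution report
names the candidate closest to the unassigned profile and the bootstrap
support of that pairing; with a single candidate the clustering is skipped
with a notice. Correspondence analysis follows the standard construction
(centred standardized residuals, SVD, principal coordinates); total
inertia equals the table's chi-square over its grand total, identical
profiles yield zero inertia and zero dimensions, and all-zero columns are
pruned and reported.

A gamma law fits genome-derived k-mer abundance distributions well;
`fit_gamma()` uses moments (shape $= \mu^2/\sigma^2$) rather than maximum
likelihood because the distribution enters only descriptively.

# Duplicate clustering

`pairwise_identity()` aligns the shorter sequence globally against the
longer with free end gaps on the longer (match +1, mismatch −1, gap −2 per
column). Identity is matches over all columns of the shorter's span —
including any overhang of the shorter beyond the longer's end, which the
underlying aligner excludes from its reported alignment but which clearly
belongs to the span. Coverage is the shorter's aligned span over the
longer's length; the stringency sweep applies it as "the candidate must
cover ≥ 80% of the representative".

`greedy_cluster()` is the classic greedy incremental scheme: reads sorted
by length (ties lexicographic), first-fit against existing
representatives. A shared-5-mer prefilter skips candidates that provably
cannot reach the identity threshold: with the shorter aligned globally,
non-match columns satisfy $e \le \frac{1-t}{t}\,L_s$, and each non-match
column destroys at most $k$ of the shorter's k-mers, so any passing pair
shares at least $(L_s - k + 1) - k\,e_{\max}$ k-mers (counted with
multiplicity). The bound is conservative by construction and the tests
assert exact equality with an unfiltered greedy pass; at thresholds of
0.8 and below the bound is vacuous and the pass is effectively brute
force. Amplified read sets collapse into clusters much faster than
unamplified ones as the threshold is relaxed, because reads anchored at
the same high-weight priming site are near-duplicates.

# Pipeline

`run_pipeline()` chains the stages in fixed order from a YAML
configuration merged over defaults (seed mandatory), writes per-stage
artifacts (FASTQ, truth TSV, SAM, wiggle, BED, Newick, TSV tables) and a
timestamped log, and aborts with the stage name on failure, keeping
partial outputs. Assignment fractions are reported on both a per-read and
a per-base basis, which can differ substantially when artifact classes
have atypical lengths. Run summaries label the base-count column
`total_bases` unambiguously.

# Problem sizes and runtime

The test and demonstration configurations use 20–100 kb genomes, 300–2,000
reads per method, 100×1000 subsampling with 199 permutations per
replicate, 300–500 bootstrap replicates for attribution, and 300-read
clustering sweeps. These sizes keep every property measurable (the
acceptance properties reproduce the qualitative full-scale contrasts with
wide margins) while the whole suite runs in minutes on a single core.
Scaling all of them up is a matter of configuration, not code.

# Known limitations

* No 454 flowgram/homopolymer error model; reads are error-free, so QC
  survival rates and mapping identities are upper bounds relative to real
  data.
* No emPCR duplicate model; MDA near-duplicates arise only through the
  priming-site mechanism.
* The MDA generative model is phenomenological — it reproduces coverage
  spikiness, chimera/contaminant/concatemer loads and their compositional
  signatures, not phi29 kinetics.
* Bootstrap supports are ordinary percentages (no multiscale correction).
* Single-reference mapping; no competitive mapping across a database, so
  "mapped to candidates" means mapped to the configured contaminant
  genomes after failing the reference.
* ANOVA over correspondence-analysis eigenvalues is not implemented: no
  usable definition of the response structure was available, so the CA
  coordinates and inertias are exported instead.
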