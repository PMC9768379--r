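---
title: "Models and methods for Pol I occupancy, pause-logo, and gap analysis"
author: "poliseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for Pol I occupancy, pause-logo, and gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poliseq)
```

## The scientific setting

RNA polymerase I synthesizes the 35S rRNA precursor from tandem rDNA
repeats. Because processing of the transcript begins cotranscriptionally,
the *kinetics* of elongation — overall rate and the propensity to pause at
particular sequences — feed directly into ribosome assembly. Two in vivo
readouts anchor this package:

* **NET-Seq** maps the 3′ end of each nascent transcript, i.e. the last
  incorporated nucleotide, at single-nucleotide resolution. Read depth at a
  position is a steady-state snapshot of polymerase occupancy: positions of
  long dwell accumulate reads.
* **Miller chromatin spreads** image single transcribed genes; an
  elongating polymerase that pauses while those downstream run off leaves a
  long polymerase-free gap.

All repeats are collapsed onto one reference transcription unit. Only the
transcribed spacers (ETS1, ITS1, ITS2, ETS2) give a clean nascent signal:
the mature 18S/5.8S/25S regions are contaminated by fragments of the vastly
abundant mature rRNA, so contamination is confined to mature regions both
in the simulator and in the interpretation of results.

## Coordinates

The R API is 1-based and closed, with position 1 the transcription start
site (so the first encoded C of the default template is reported as 56,
i.e. +56 in TSS-relative notation). On-disk region tables and bedGraph/BED
outputs use the 0-based half-open BED convention. Region boundaries follow
the half-open rule: a boundary position belongs to the downstream region.

## The dwell model

`build_pause_model()` assigns position $i$ the dwell

$$d(i) \propto \Big[\prod_{o \in W} w\big(b(i+o)\big)\Big] \cdot \beta(i),$$

where $W$ is a window of offsets relative to the 3′ end (offset 0 = last
incorporated nucleotide), $w$ is a per-base weight, $b(\cdot)$ the
nontemplate-strand base, and $\beta$ an optional position bias; dwell is
rescaled to mean 1. The default window is $W = \{-9,\dots,0\}$: offsets
$\le 0$ cover an RNA:DNA hybrid of canonical 8–10 bp length ending at the
last incorporated nucleotide. The window is configurable; the product form
makes dwell log-additive in the context, the simplest model in which
"sensitized to A/G residues in the hybrid" has a literal meaning.

NET-Seq sampling treats occupancy as directly proportional to dwell (a
snapshot interpretation). No kinetic exclusion process is simulated for
NET-Seq reads; hard-core exclusion applies only to Miller-spread placement,
where a footprint is physically visible.

### The strain-pair scenario

`make_strain_pair_scenario()` fixes the documented strong-effect defaults
used by the synthetic benchmark:

* WT: $w = (A\,0.7,\ C\,1.4,\ G\,0.7,\ T\,1.4)$ — C/T-preferring;
* mutant: the mirror image $(A\,1.4,\ C\,0.7,\ G\,1.4,\ T\,0.7)$ —
  A/G-sensitized over the hybrid window;
* mutant position bias $1 + 2e^{-(i-1)/1000}$, a 5′-end occupancy pileup
  emulating a slowed, pause-prone enzyme backing up near the promoter.

Over a 10-offset window these weights give log2-dwell a spread of roughly
±1.5 bits, so between-strain occupancy differences at a position reach
several fold — deliberately large relative to the multinomial sampling
noise of a $5\times10^5$-read library (per-position coefficient of
variation ≈ 10% at the mean). This is what makes strain identity, not
replicate noise, dominate library-level comparisons: the scenario is
defined so that the strain effect redistributes a large fraction of
occupancy mass. No quantitative pause strengths are available for either
strain; these defaults are synthetic and labeled as such.

## The read simulator

A library of depth $N$ contains exactly
$\mathrm{round}(f_{\mathrm{cont}} N)$ contaminant reads (deterministic
split — conservation tests then carry no binomial noise) with 3′ ends
uniform over mature-region positions, and $N - \mathrm{round}(f N)$
nascent reads with ends $\propto$ dwell over the whole template. Each read
is the template substring of `read_len` nt ending at its 3′ end, truncated
at the TSS (never padded). Records are laid out `[UMI][insert][adaptor]`
with phred-33 constant quality `I`; base-call error is not modeled, which
keeps the exact mapper oracle-verifiable.

What the simulator does **not** emulate: PCR amplification bias beyond
duplicate creation, sequencing error, polymerase cooperativity or pushing,
torsional stress, RNA secondary structure, and the heavy-tailed real dwell
distribution. Passing tests therefore demonstrate the correctness and
calibration of the *analysis*, not that real libraries meet the same
effect sizes.

## Read processing

Processing mirrors the standard NET-Seq order — deduplicate, trim, align —
with choices documented here:

* **Deduplication key** is the full raw record (UMI + insert + adaptor),
  i.e. sequence-level deduplication before alignment; the first occurrence
  survives and order is preserved. Applying it twice is a no-op.
* **Adaptor trimming** removes the longest read suffix that exactly
  matches an adaptor prefix with overlap ≥ `min_overlap` (default 5).
  Reads with no qualifying match are discarded and counted: without the
  adaptor the true 3′ terminus cannot be located.
* **Mapping** replaces a genome aligner with an exact single-locus mapper:
  the read's 3′-terminal `min_match`-mer (default 18, minimum 12) is
  looked up among all template k-mers. A k-mer occurring more than once on
  the template ⇒ ambiguous, discarded; a unique hit is accepted only if
  the full read matches the template substring ending there. Truncated
  reads map as long as ≥ `min_match` nt remain. Mismatch tolerance is
  zero, which keeps the mapper exactly checkable against a sliding-window
  oracle; real-data users with genome-aligned counts can construct
  profiles directly via `occupancy_profile()`.
* **Normalization** is counts per million template-mapped reads (CPM).
  The minimal scheme making libraries of different depth comparable;
  whether mature-region reads should be excluded from the denominator is
  genuinely open, and the whole-template CPM choice is exposed by
  operating on `counts` directly if an alternative is wanted.

The accounting identity
`input = dedup_removed + no_adaptor + unmapped + ambiguous + mapped`
holds for every processed library and is asserted in the tests.

## Occupancy statistics

* **Per-position test**: two-sided Welch t test on normalized replicate
  values (replicate variances are not constrained equal). Positions with
  p < α are classified by the direction of the strain medians; both-zero
  variance with equal means ⇒ p = 1, `no_change` (no NaN propagation). No
  multiple-testing correction by default — the per-position coloring
  convention — with a BH option.
* **Region KS test**: positional distributions (region counts rescaled to
  sum 1), D the max ECDF difference, p from the asymptotic two-sample
  formula with effective sample sizes equal to region read counts capped
  at 10,000 per strain. The cap is a documented, configurable choice: with
  read-level n in the millions even trivial pattern differences give
  p ≈ 0. On a discrete 700-position grid the asymptotic p is mildly
  conservative; at the depths used in the tests the p-value distribution
  under the null is indistinguishable from uniform at the assay's
  resolution.
* **Spearman / PCA**: ranks with average ties via `stats::cor`;
  covariance PCA (column-centered, unscaled) of the libraries × positions
  matrix via `stats::prcomp`.

## Pause sites and differential logos

Pause sites are the top `q`% (default 2.5%) occupied positions among
spacer-region positions of the replicate-median profile — the median, not
per-library calls, because one logo per strain is the object of interest.
Ties break toward the lower coordinate, making calls deterministic.

Contexts are extracted over a window of offsets −10…+5 (hybrid plus
downstream DNA; configurable), positions whose window exits the template
are dropped and counted. PWMs use pseudocount 0.5 per letter to keep
entropies finite on ~40-context sets. Per offset, the statistic is the
Jensen–Shannon divergence in bits (bounded by 1); signed per-letter
contributions are `probs_mutant − probs_wt`, so mutant-enriched mass is
the negative-axis side under the usual rendering convention, while the
divergence itself stays non-negative.

Significance is a pooled-label permutation test: membership of the two
context sets is permuted (sizes preserved), and
$p = (1 + \#\{JSD^{perm} \ge JSD^{obs}\})/(n_{perm}+1)$ per offset, with
no across-offset correction (per-position asterisks). Calibration is
checked at the level the test is exchangeable at: random label splits of a
common context pool give uniform p-values. Logos built from two *called*
site sets under the null are conservative rather than uniform — both
strains call largely the same top-dwell sites, so the observed divergence
is near 0 and p near 1 — which is the correct behavior, not a defect.

## Miller-spread simulation and gap analysis

Each gene receives Poisson(`target_density`, default 50) polymerases —
the density of an active rDNA repeat — placed by dwell-weighted sequential
sampling with hard-core exclusion at the footprint (default 40 nt,
interpreted from "40 packed polymerases ≈ 25% of the gene"; a
configurable interpretation, not a measured constant). Rejected draws are
retried, so the realized mean stays at the Poisson mean (occupancy ~30% is
far from the jamming limit).

Gap calling takes active-site positions on $[0, L)$, gives each a
footprint interval $[p - f/2, p + f/2)$, and reports the complement
intervals; gap start is the promoter-proximal edge. Large gaps are
`length > 0.25 L` (strict; the `> 23%` convention is available as an
alternative threshold). Start positions are binned by
$\lfloor \mathrm{start}/L \times 10 \rfloor$ (~670 bp per bin on the
default template) and frequencies are per scored gene; a gene with several
large gaps counts once in the headline fraction, matching "x% of N genes
analyzed". With threshold $t$, no large gap can start beyond $1-t$ of the
gene — the structural zero in the 3′ bins.

The spread scenario (`make_spread_scenario()`) deserves its own note.
Short-range context weights cannot generate quarter-gene empty stretches:
summed over ~1,700 positions, dwell fluctuations average out and the
probability that ~50 placements all miss a 25% window is astronomically
small. Real large gaps are kinetic — one polymerase stalls, downstream
neighbors run off. In a static snapshot the signature of such an event is
a region of strongly depressed occupancy downstream of a persistent pause
cluster. The scenario therefore multiplies dwell by a small factor
(WT 0.13, mutant 0.05) across a fixed 2,000-nt 3′ window, with a 20×
pause cluster immediately upstream. The depletion factors were chosen so
that large gaps are a minority phenotype of realistic magnitude in both
strains with the mutant clearly elevated; tests assert the direction of
the difference, not its absolute size.

## Numerical conventions and degenerate inputs

* Non-ACGT template characters are rejected, not masked: PWM and entropy
  arithmetic assume a 4-letter alphabet.
* All-zero profiles cannot be normalized (error, not NaN).
* Constant profiles give `NA` Spearman entries rather than a warning-laden
  0/0.
* JSD inputs must sum to 1 within 1e−6; the divergence is clamped at 0
  against floating-point undershoot.
* Permutation p-values use the +1-corrected estimator, so the minimum
  attainable p is $1/(n_{perm}+1)$ and p = 0 never occurs.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state.

## Problem sizes used by the test-suite benchmark

The packaged checks run the full pipeline at depth $5\times10^5$ per
library (replicate correlation and PCA), $10^5$ per library across 6,700
positions for t-test calibration, 150 × 199 permutations for null
uniformity, 200–1,000 random instances per brute-force oracle, and 150–400
simulated genes per spread comparison. These sizes were chosen as the
smallest at which the stochastic assertions have comfortable margins; the
dwell-to-occupancy convergence check accepts the expected ~0.3% of
3-sigma exceedances across 6,700 positions (≥ 99% within 3σ, none beyond
5σ) rather than asserting an all-positions bound that a correct simulator
would fail by chance.

## Known limitations

* Occupancy ∝ dwell ignores elongation-complex interactions; NET-Seq
  pileups caused by traffic jams are only reproduced where the scenario
  encodes them as position bias.
* The exact mapper is deliberately mismatch-intolerant; real reads with
  sequencing errors need an external aligner, entering via
  `occupancy_profile()`.
* The default template is synthetic (region lengths and composition are
  plausible, not database coordinates); analyses of real data should load
  the genuine reference via `load_template()`.
* The KS p-value is asymptotic on a discrete support and mildly
  conservative for coarse regions.
* Permutation significance is per offset; the optional max-statistic
  correction is not the default because the experimental convention marks
  per-position significance.
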