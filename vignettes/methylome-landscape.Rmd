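---
title: "Comparing methylome landscapes across genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing methylome landscapes across genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylandscape)
```

## The biological problem

Mouse oocytes build their DNA methylation landscape de novo during growth,
and they do it unusually: the global CG methylation level is only ~40%
(against ~70% in most somatic cells), high methylation is confined to
actively transcribed regions carrying H3K36me2/3, and non-CpG (CH)
methylation — mostly at CA — is abundant. DNMT3A is targeted to H3K36me2/3
through its PWWP domain. Single-residue substitutions in that domain do not
abolish methylation of H3K36-marked chromatin; instead they *de-repress*
methylation elsewhere, producing aberrant CG hypermethylation of
Polycomb-marked (H3K27me3), H3K9me2-marked and unmarked chromatin, with the
pericentromeric major satellite among the strongest gainers, and a gain in CA
methylation. Quantifying that redistribution requires a chain of analyses:
per-cytosine bisulfite calls are pooled into weighted methylation levels, 10-kb
bins are compared between genotypes with a fixed-delta threshold, chromatin
states are segmented from histone-mark tracks with a Bernoulli-emission HMM,
and hypermethylated bins are attributed to states.

`methylandscape` implements that chain as a reusable, tested pipeline, plus a
synthetic-data generator that reproduces the statistical structure the
analyses assume, so the whole pipeline is exercised end to end without any
external download.

## Weighted methylation

Throughout the package a region's methylation level is the *weighted*
(count-pooled) level

$$ L = \frac{\sum_i m_i}{\sum_i (m_i + u_i)} $$

over the covered cytosines in the region, with $m_i$/$u_i$ the methylated and
unmethylated read counts, never the mean of per-site fractions. Whether bean
plots in the literature pool counts or average site fractions is usually
unstated; pooling is standard WGBS practice, is invariant to how counts are
split across records, and makes bins, annotations and global levels exactly
consistent with one another (`global_level()` equals the depth-weighted mean
of `bin_levels()` — a property the test suite asserts). CG records are
strand-merged before CG analyses (`merge_cg_strands()`; CpG methylation is
symmetric, and the CG analyses here treat one CpG as one site); CH records
stay strand-resolved, as CH methylation has no complementary-strand
counterpart.

Coordinates: cytosine reports are 1-based (the Bismark cytosine-report
convention), BED and bedGraph are 0-based half-open, and bins tile each
contig from coordinate 0 with the last partial bin retained. All conversions
live in the IO module.

## Differential bins

Bins of 10 kb (configurable) are compared pairwise between two genotypes.
Bins with fewer than `min_sites` covered sites (default 5) or missing in
either track are excluded rather than treated as zero; coverage filters are
exposed as flags because published analyses rarely state theirs. A bin is
hypermethylated when the delta (test − control) is at least the threshold —
20 percentage points for CG and 10 for CA, with *inclusive* comparisons. No
statistical test is attached to bin calling, deliberately: the fixed-delta
rule is the method being reproduced, and overlap statistics
(`bin_overlap()`) report Venn counts and percentages over it. Percentages
over an empty set are undefined (`NA`), never 0. Hyper bins can be split into
delta strata (default breaks 20/40/60 points) for composition analyses.

## Chromatin states

Histone-mark count tracks in fixed windows (200 bp by default, the
conventional choice) are binarized against a Poisson background: a window is
"present" for a mark when $P(X \ge c;\ \lambda)$ falls below $10^{-4}$, with
$\lambda$ the mark's genome-wide mean count unless supplied. A count of 0 is
never called present. There is no input-control track or local background
model, matching the way the upstream data were described.

States are learned with a hidden Markov model whose emissions are products of
per-mark Bernoullis (marks conditionally independent given the state), the
same model family ChromHMM fits. Numerical choices:

* **Scaling, not logs.** The forward-backward recursions (implemented in a
  small C++ core) use per-step normalisation constants in the style of
  Rabiner's classic treatment. This is algebraically identical to log-space
  recursions — the log-likelihood is the sum of the log scaling constants —
  while avoiding `logsumexp` in the inner loop; sequences of any length
  cannot underflow.
* **Floors.** Emissions are clamped to $[\varepsilon, 1-\varepsilon]$ and
  transitions receive a pseudocount ($\varepsilon = 10^{-6}$) so EM cannot
  reach degenerate fixed points with zero likelihood.
* **Initialisation.** Emissions start at seeded uniform(0.2, 0.8) draws;
  transitions and the initial distribution start uniform. A single restart is
  the default; `n_restarts` keeps the best final likelihood.
* **Per-contig resets.** Each contig is an independent observation sequence
  of the shared model.
* **Monotonicity is asserted.** The EM log-likelihood trace is checked every
  iteration and a decrease beyond rounding error aborts the fit — a
  correctness tripwire, not a convergence heuristic.
* **Decoding.** Per-window labels are posterior argmaxes (forward-backward),
  ties broken toward the lowest state index. State labels are arbitrary, so
  reporting orders states by descending H3K36me3 emission
  (`sort_states_by_mark()`).

The number of states is always an explicit argument — never inferred — with 8
used for the five-mark fixture (and 5 a sensible choice for three-mark
panels). With more states than distinct mark signatures, EM routinely leaves
near-duplicate or empty states; downstream summaries treat empty states as
empty rather than erroring.

Per-state methylation uses single CpGs passing a depth filter (default:
depth > 15, i.e. `min_depth = 16`), each site contributing to exactly one
window's state. Composition of hypermethylation strata is the fraction of
windows per state among all windows inside each stratum's bins; rows sum
to 1.

## CH methylation

CH levels are pooled per dinucleotide (CA/CT/CC, strand-resolved; CG records
excluded). A full trinucleotide grouping exists so dinucleotide levels are
exactly the count-weighted averages of their trinucleotides, and a CHH-only
trinucleotide table mirrors the usual reporting. The next-nucleotide
preference weights the base following each CH site by methylated read count
(not a binary "methylated site" call — no site-calling rule is defined for CH
here) and reports it next to the all-read background; the informative
statistic is the preference/background enrichment, which recovers the
simulated next-base weights and distinguishes a DNMT3A-like preference for C
from a DNMT3B-like preference for G. No depth threshold is applied by
default.

## Conversion QC

The unmethylated spike-in contig (lambda phage in real libraries) measures
bisulfite conversion: `estimate_conversion()` pools *all* contexts and depths
on the spike-in — per-context estimation buys nothing when every cytosine is
truly unmethylated, and pooling dominates the noise. Absence of spike-in
coverage is an explicit QC failure, never silently a rate of 0. The rate is
reported, not used to correct methylation levels.

## What the synthetic generator emulates — and what it does not

`generate_genome()` builds two 500-kb contigs plus a 48.5-kb spike-in
(matching the lambda genome length). Domain labels (K36, K27, bivalent,
K9me2, unmarked) are placed as shuffled 10-kb blocks so realised fractions
match the configuration up to granularity, and a 234-bp × 100-copy tandem
satellite array is overlaid on the first contig. Defaults were chosen once to
mirror the oocyte contrast qualitatively:

* control CG levels 0.85 in K36 domains and 0.10–0.30 elsewhere, giving a
  bimodal 10-kb-bin histogram and a global level in the low-40s percent;
* mutant gains confined to non-K36 chromatin (K27 +0.35, K9me2 +0.30,
  unmarked +0.30, satellite +0.45 — the largest, bivalent +0.04 — nearly
  resistant, K36 +0);
* CH levels CA 5.9% → 7.2% across genotypes with CT/CC an order of magnitude
  lower, and next-base weights (A 1.2, C 1.6, G 0.4, T 0.8; mean 1 under a
  uniform base) encoding the DNMT3A-like preference for C;
* conversion error 0.5% (a typical spike-in estimate) applied only in the
  unmethylated→methylated direction — the standard bisulfite failure mode;
  over-conversion of 5mC is ignored;
* depth Poisson with mean 30 per cytosine; real library coverage models are
  protocol-specific and unstated, and Poisson is the neutral choice.

Mark tracks are Poisson counts with per-domain fold enrichments (background
mean 5 reads/200-bp window), so binarization and state learning see realistic
sparse-count input.

The generator does **not** emulate: read-level sequencing (no FASTQ, no
mapping bias), PCR duplication or coverage waviness, fine-scale CpG-island
structure, partially methylated domains' internal gradients, replicate
variability, or any enzyme kinetics beyond the single next-base weight. A
pipeline that passes on this fixture is validated for its *arithmetic and
statistics* — pooling, thresholding, EM, decoding — not for robustness to
real-data artefacts.

No quantitative model of the mutant's gain magnitude per chromatin state
exists to copy; the gain defaults above are calibrated only to reproduce the
qualitative pattern (hyper bins confined to non-K36 states, satellite the top
gainer) and are ordinary configuration, not assertions about effect sizes.

## Problem sizes and runtime

The default fixture (1 Mb + spike-in, ~440k cytosine templates, 5,000
windows, 8 states) runs the full pipeline in well under a minute on one core.
The statistical recovery tests use 10^5 simulated windows for HMM emission
recovery (±0.05), ≥10^5 CG sites at depth 30 for binomial level recovery
(±3 SE), and the spike-in's full depth for conversion-error recovery (±95%
binomial CI). Exhaustive-path oracles check the forward likelihood on
sequences of length ≤ 8 to 10^-10.

```{r example, eval = FALSE}
report <- run_comparison(run_config(seed = 1))
report$global_cg
hyper_bins(report$cg_comparison)
report$model
```

## Known limitations

* Bin calling is a fixed-delta rule; no uncertainty accompanies the calls.
* The HMM assumes mark independence given the state and a uniform background
  per mark; correlated marks or copy-number variation would need an input
  track.
* CH analyses assume the trinucleotide column is trustworthy; sites within
  2 bp of a contig end carry `N`-padded trinucleotides and are flagged.
* The pipeline is single-threaded by design — determinism from one seed is
  worth more here than wall-clock speed at these problem sizes.
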