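---
title: "Detecting selective sweeps with background-contrast statistics and a CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps with background-contrast statistics and a CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A selective sweep drags the haplotype carrying an adaptive allele to high
frequency, depleting variation on that *derived background* relative to the
*ancestral background* and distorting the site frequency spectrum and
haplotype structure around the selected site. Individual summary statistics
each see only part of that signal, and their power depends strongly on the
sweep's age, strength, starting allele frequency (SAF) and ending allele
frequency (EAF). `sweepnet` therefore combines eleven statistics — five
background-contrast statistics defined below plus six established ones (iHS,
nSL, DIND, SAFE/iSAFE, HAF, H12) — into a feature tensor over nested windows
and lets a small convolutional network learn which combinations indicate a
sweep, training on simulations from a user-specified demography.

### The five background-contrast statistics

All five condition on a *focal variant* with derived allele frequency (DAF)
in $[0.25, 0.95]$ and split the sample into derived and ancestral
backgrounds. Focal sites outside the range are skipped (not zeroed): there
is little power below 0.25, and the ancestral background vanishes above
0.95.

* **hapDAF** compares shared flanking variants between backgrounds,
  $\mathrm{hapDAF} = \sum_i (f_{di}^2 - f_{ai}^2)/k$, over flanking variants
  that (1) occur on at least one background of each type, (2) are more
  common on the derived background ($f_{di} > f_{ai}$), (3) have
  $f_{ai}$ below a threshold, and (4) have $f_{di} + f_{ai}$ above a
  threshold; 0 when no variant qualifies. `hapdaf_o` (thresholds
  0.25/0.25) targets old incomplete sweeps; `hapdaf_s` (0.1/0.1) targets
  sweeps from standing variation. All inequalities are strict, exactly as
  defined.
* **Sratio** $= S_a / S_d$, the ratio of segregating-site counts among
  ancestral- versus derived-background haplotypes in the window. When
  $S_d = 0$ the value is marked not computable and excluded from
  aggregation rather than patched with a pseudocount — low-diversity
  windows would otherwise contribute unbounded artifacts.
* **lowfreq / highfreq** summarize the derived-background SFS:
  with $f_{dd,i}$ the frequency of flanking derived allele $i$ among
  derived-background haplotypes only, lowfreq averages $(1-f_{dd,i})^2$
  over variants with $0 < f_{dd,i} < 0.25$ and highfreq averages
  $f_{dd,i}^2$ over variants with $f_{dd,i} > 0.25$. The requirement
  $f_{dd,i} > 0$ is ours: an allele absent from the derived background
  would otherwise contribute the maximal term everywhere, contradicting
  the statistics' hitchhiking motivation.

### Standardization

Raw values depend strongly on the focal DAF, so every per-SNP statistic is
standardized against neutral simulations within 2% DAF bins (50 bins on
$(0,1]$, half-open `(low, high]`): $z = (x - E_p[x]) / SD_p[x]$. Bins with
fewer than `min_per_bin` (default 20) values are pooled with their nearest
neighbors; a pooled bin with zero variance keeps pooling (a statistic can
be identically 0 for all neutral focal variants of some frequency in small
windows), and only a statistic constant across all bins is an error. Norms
are fitted per statistic *and per nested window size*, since window size
changes the scale of several statistics, and are persisted as a versioned
TSV.

The per-SNP values entering the norms are computed in exactly the windows
the feature pipeline evaluates — every focal variant of every
(center, size) window — streamed as running moments so fitting scales to
many loci. HAF and H12 take one value per locus and are standardized
locus-level; the per-window iSAFE summary (maximum per-SNP score) is
standardized per window size, because the maximum of mean-zero scores grows
with window SNP count.

### The six established statistics

iHS and nSL are computed from extended haplotype homozygosity (EHH) decay,
integrated by the trapezoid rule and truncated where EHH < 0.05 or at the
window edge; iHS integrates over genetic distance when a recombination map
is supplied, physical distance otherwise. One sign convention is used
package-wide: *a sweep on the derived background is positive*. For the
homozygosity statistics that means $\ln(\mathrm{iHH}_d/\mathrm{iHH}_a)$ and
$\ln(\mathrm{SL}_d/\mathrm{SL}_a)$; for the diversity ratios (DIND
$= \pi_a/\pi_d$, Sratio) the ancestral-over-derived orientation already
achieves it. DIND with $\pi_d = 0$ is not computable.

SAFE scores each variant by $(\phi - \kappa)/\sqrt{f(1-f)}$, where $\phi$
is the fraction of total haplotype-allele-frequency (HAF) score carried by
the variant's carriers and $\kappa$ the fraction of distinct haplotypes
carrying it. iSAFE — whose original implementation leaves some configuration details
unspecified — applies SAFE in overlapping 300-SNP windows (step
150) and averages per-SNP scores weighted by each window's maximum score.
Windows under 300 SNPs use plain SAFE, in both training and application.
The HAF summary is the mean of the top 10% of per-haplotype HAF scores
(`ceiling(0.1 n)` haplotypes), which tracks incomplete sweeps better than
the full mean. H12 uses greedy haplotype clustering at 80% identity (seeds
in descending multiplicity order, ties broken by lexicographic haplotype
content so the statistic is invariant to haplotype row order, identity =
fraction of matching alleles over window SNPs); at identity 1 it reduces
exactly to classic H12. Cluster frequencies are post-clustering.

## Feature tensor

Each locus is summarized at 21 center points spaced so the largest window
fits inside the locus (10-kb spacing on the reference 1.2-Mb geometry),
with nested windows of 50/100/200/500/1000 kb — 105 windows. Rows follow an
interleaved order (`ihs, hapdaf_o, dind, nsl, hapdaf_s, sratio, isafe,
lowfreq, haf, highfreq, h12`) so convolution kernels mix haplotype-, SFS-
and diversity-type information early; the order is configurable and
recorded in every tensor. Columns are center-major. Per-SNP statistics are
standardized per focal variant and averaged over the computable focal SNPs
of each window — no single aggregation function is canonical here; the mean is
robust to varying SNP counts. Not-computable cells
are imputed with 0 (the neutral-standardized mean, the least informative
value) and counted in a flag matrix.

Two tensor-level conveniences matter for training stability:
`squash_tensor()` applies $\mathrm{sign}(x)\log(1+|x|)$, taming the heavy
tails of the unbounded ratio statistics (single cells can reach tens of
standard deviations after a strong sweep) while staying identity-like near
the neutral mean; `mirror_tensor()`/`mirror_columns()` exploit the exact
locus-reversal symmetry of the simulated world to double the training set.
Both are applied identically at training and prediction time.

## Classifier

The network is three convolutional blocks (default 6 filters; the first
kernel spans 3 statistic rows by 5 window columns), each with ReLU, 2x2 max
pooling and dropout 0.25, then a 16-unit dense head and a sigmoid output,
trained with Adam on binary cross-entropy, 20% of the data held out for
validation, early stopping (patience 25) with best-weights restoration.
Because small networks trained on hundreds of simulations have visible
optimizer-seed variance, `train_cnn(n_models = k)` trains `k` independent
initializations and averages their probabilities; the manifest records the
seed and member count. Mirror augmentation is applied to the training
portion only, after the validation split, so validation loss stays honest.
A model refuses to predict tensors whose statistic row order or norms
provenance differ from its manifest. The output is binary
(sweep vs neutral) by design; attempting to classify sweep subtypes costs
power.

`evaluate()` reports ROC/AUC over neutral truth, a confusion matrix, and
FPR/TPR at the reporting thresholds. Two false-positive rates are emitted
and labeled: `fpr_neutral` (FP / true neutrals, the ROC sense) and
`fpr_positive` (FP / positive calls, the precision-complement sense used in
FDR-style summaries) — both senses appear in sweep-scan practice, so both
are reported rather than guessing.

## Simulated world

Training needs labeled simulations. Full-scale data (1.2-Mb loci, large
coalescent populations with selection) are expected from external
simulators via ms-format import. For self-contained fixtures the package
provides: msprime-backed neutral coalescent simulation under
piecewise-constant demography (equilibrium, decline, expansion, bottleneck,
or explicit size steps), and a forward Wright–Fisher sweep simulator
(haploid, infinite sites, single crossover, one selected site at the locus
center, standing variant chosen nearest the requested SAF or a de novo
copy, trajectory conditioned on reaching the EAF by rejection with restart
cap, selection lifted at the EAF, sampling tau generations later; founding
populations are coalescent draws so standing variation is
coalescent-shaped).

The test fixture world scales the reference setting by 0.1 in locus length
(120-kb loci, geometry scaled with them) with a forward population of
N = 400. Scaling choices preserve the population-scaled quantities that
control the signal: per-bp $\theta = 4N_e\mu$ and $\rho$ match
$N_e = 10{,}000$ human-like rates, sweep ages run to $0.125 \cdot 4N$
generations, and selection coefficients are drawn log-uniformly from
$[0.1, 0.8]$ so that $\gamma = 2Ns \in [80, 640]$ lies inside the tested
range of the full-scale setting; weaker $s$ at this population size would
violate the simulator's own requirement $s > 10/(2N)$ (selection must
dominate drift for trajectory conditioning to make sense). Two things the
fixture world deliberately does not emulate: complex non-equilibrium
demography in the training mix, and background selection / recombination
heterogeneity, which the surrounding method ingests from external
simulators only. A green test therefore establishes the machinery —
statistics, standardization, learning, scanning — at reduced scale, not the
full-scale power figures, which require simulation budgets of tens of
thousands of replicates.

## Genome scan

`scan_matrix()`/`classify_genome()` tile a chromosome into
geometry-length windows (1.2 Mb at reference scale) stepped by 10 kb,
featurize each against the neutral norms, and score it with the model at a
confidence threshold (default 0.5). Data-quality gates — fewer than 2 SNPs,
or more than 20% imputed tensor cells — flag a window unclassifiable
instead of classifying imputation artifacts; note that at fixture scale a
very strong *complete* sweep can trip the imputation gate in its central
windows precisely because it removes nearly all mid-frequency variation,
with detection then resting on the shoulders. `merge_streaks()` merges
maximal runs of consecutive sweep-classified windows into regions (span =
union of member windows, also reported as the center-step interval, since
either span convention is defensible for overlapping windows); the
peak is the center of the member window with maximum probability, ties to
the left. `estimate_fdr()` computes FDR = expected false positives /
positive calls on random sets of windows spaced at least 1 Mb apart
(default 100 sets), because adjacent 10-kb-stepped windows are almost
entirely overlapping; sets with no positives are excluded with a warning.
For low-recombination regions, the recommended two-step clean-up — rescan
candidate windows with a model retrained at lower recombination rates — is
available by passing the alternate model and region list through the same
scan functions (or the CLI).

## Numerical choices and degenerate inputs

* ms positions are rescaled to bp and rounded; collisions are jittered +1
  bp (unique positions are required downstream), with a backward jitter at
  the locus edge.
* VCF ingestion drops (and counts) multiallelic sites, sites with missing
  genotypes, and sites whose ancestral base matches neither allele;
  unphased genotypes are a hard error since every statistic is
  haplotype-based.
* EHH integration stops after the trapezoid that crosses the 0.05 cutoff
  (no interpolation); iHS/nSL are not computable when a background has
  fewer than two haplotypes or an integral is zero.
* Training tensors are squashed by default in the fixture pipeline; raw
  tensors are equally valid input if used consistently.
* The acceptance and test worlds derive every random draw from fixed seeds;
  simulation manifests record them.

## Known limitations

* The fixture-scale CNN is trained on hundreds, not tens of thousands, of
  simulations; its absolute power is well below the full-scale method and
  its decision threshold is not calibrated. Tests therefore check
  separation, monotone orderings and internal consistency, not headline
  power numbers.
* iSAFE follows the original construction, but some configuration details
  of the original tool are unspecified; SAFE/iSAFE here should be treated
  as the package's own faithful variant.
* The forward sweep simulator is a fixture generator: haploid, single
  crossover per offspring, no gene conversion, no DFE; it is not a
  replacement for discoal/SLiM at analysis scale.
* Unphased-data variants of the haplotype statistics are out of scope.
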