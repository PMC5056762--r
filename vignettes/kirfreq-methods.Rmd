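---
title: "Estimating KIR structural haplotype frequencies from low-resolution genotypes"
author: "kirfreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating KIR structural haplotype frequencies from low-resolution genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirfreq)
```

## The problem

The killer-cell immunoglobulin-like receptor (KIR) locus on chromosome 19
is one of the most structurally variable regions of the human genome. A
chromosome's KIR region is described here as a *structural haplotype*: a
vector of copy numbers (0--4) over a fixed panel of 16 genes and
pseudogenes (`kirGenes()`), with a recombination hotspot between KIR3DP1
and KIR2DL4 splitting each haplotype into a centromeric and a telomeric
motif (the `cA01~tB02`-style nomenclature).

Most KIR genotyping, however, is performed at resolutions that do not
observe haplotypes directly:

* **PA** (presence/absence): for each gene, only whether it occurs on at
  least one of the two chromosomes;
* **CNV**: the total diploid copy count per gene;
* **mixed**: some genes at CNV, the rest at PA.

Given a cohort of such genotypes and a *reference set* of known structural
haplotypes, the package answers three questions: what are the haplotype
frequencies in the cohort, which haplotype pair does each individual most
probably carry, and how much does the answer depend on the typing
resolution and on the choice of reference set.

## Model and likelihood

Each individual is assumed to carry two haplotypes drawn independently
from the population frequency vector $p$ (Hardy--Weinberg equilibrium),
restricted to the reference set $\{h_1,\dots,h_H\}$. A pair $(h_i,h_j)$ is
*compatible* with a genotype when, gene by gene, the summed copy numbers
explain the observation: a PA-present gene needs $\geq 1$ summed copies, a
PA-absent gene exactly 0, a CNV gene an exact match, and a missing gene is
always satisfied. Compatibility is the support of the indicator
$\delta(g_k, h_i, h_j)$ in the E-step below; `expandGenotypes()`
enumerates the compatible unordered pairs per genotype.

The observed-data log-likelihood of the frequency vector is

$$\ell(p) = \sum_k c_k \log \sum_{(i \le j)\,\mathrm{compat.}}
\delta_{ij}\, p_i p_j, \qquad
\delta_{ij} = \begin{cases}1 & i = j\\ 2 & i \neq j,\end{cases}$$

where $c_k$ is the multiplicity of the $k$-th distinct genotype. The
$\delta$ factor is the Hardy--Weinberg ordering correction for
heterozygous pairs. Individuals with an empty compatible set contribute no
term; they are excluded from the fit and surfaced as the *uninterpretable
rate*.

## The EM algorithm

`emFrequencies()` starts from equal frequencies and alternates:

* **E-step** (`eStep()`): per genotype, the posterior weight of each
  compatible pair,
  $a_{kij} = \delta_{ij} p_i p_j \big/ \sum_{(l \le m)} \delta_{lm} p_l p_m$;
* **M-step** (`mStep()`): gene counting,
  $p_i \leftarrow \frac{1}{2K}\sum_k c_k \left(2 a_{kii} +
  \sum_{j \neq i} a_{kij}\right)$,
  with $K$ the number of interpretable individuals.

Iteration stops when the absolute change in $\ell$ falls below `tol`
(default `1e-8`) or after `maxIter` iterations (default 1000;
non-convergence is reported through `converged()`, never as an error).
The observed log-likelihood is non-decreasing at every step -- the
classical EM guarantee -- and the test suite asserts this on every fitted
model. There is no randomness anywhere in the algorithm: identical inputs
produce bit-identical fits.

Two notational choices deserve a remark because the field's descriptions
of this estimator vary:

* We enumerate *unordered* pairs $i \le j$ and carry the heterozygosity
  factor explicitly in $\delta$, rather than enumerating ordered pairs
  with an implicit factor. The two parameterizations give identical
  posteriors; the unordered form keeps every pair list duplicate-free.
* The M-step is the standard gene-counting update. It is the unique
  update consistent with the likelihood above, and the test suite
  verifies the EM fixed point against a brute-force simplex-grid
  maximizer of $\ell$ on small instances (at grid resolution $10^{-3}$
  with local refinement), rather than trusting any printed formula.

Degenerate support: if every compatible pair of some genotype has zero
prior mass (possible once frequencies hit exactly 0), the E-step falls
back to uniform weights over that genotype's compatible pairs instead of
producing NaN. Frequencies are allowed to reach exactly 0; users who need
strictly positive estimates can pass `floor = eps`, which adds `eps`
after convergence and renormalizes.

Identical observation vectors share one expansion with a multiplicity
(`classCount`); this is algebraically identical to treating individuals
separately and makes the cost scale with the number of *distinct*
genotypes, which in real KIR cohorts is far smaller than the number of
individuals.

## Assignments and ties

`assignments()` reports, per individual, all pairs whose converged
posterior is within `tieTol` (default `1e-12`) of the maximum, ordered by
haplotype id -- never a silent arbitrary winner. Exact ties are real in
this problem: symmetric frequencies and PA-equivalent haplotypes produce
them structurally.

## Typing resolution score

`typingResolutionScore()` is $\mathrm{TRS} = \sum p^2$ over an
individual's normalized interpretation probabilities: 1 exactly for an
unambiguous assignment, $1/n$ for uniform ambiguity over $n$ pairs.
We apply it to the *haplotype-pair* posterior $a_{kij}$, since TRS $= 1$
must coincide with an unambiguous pair assignment; a marginal
per-haplotype posterior would not have that property. Uninterpretable
individuals receive no score (NA, excluded from `trsTable()`), which is
deliberately distinct from a score of 0.

`trsDistribution()` summarises cohort scores with Tukey box-plot
statistics: quartiles by linear interpolation (`stats::quantile` type 7,
configurable via `qtype` because published box plots differ in their
hinge conventions), whiskers at the most extreme points within 1.5 IQR,
outliers beyond.

Because a CNV observation constrains strictly more than its PA
down-conversion, the CNV-compatible pair set of an individual is always a
subset of the PA set; with a fixed frequency vector this forces
TRS(CNV) $\geq$ TRS(PA) per individual. At converged (hence different)
frequency vectors the per-individual inequality is no longer a theorem,
so the cohort-level claim we assert on simulations is directional: the
CNV median is at least the PA median.

## Hidden haplotypes: subset/superset diagnostics

When one reference haplotype's gene content is a subset of another's
(`subsetReport()` lists all such ordered pairs and the differing genes),
many PA genotypes cannot tell the two apart: the subset haplotype can
hide behind the superset whenever the partner haplotype supplies the
missing genes. PA-resolution estimation with such a reference set can
misattribute frequency between the pair; CNV resolution, which observes
exact counts, resolves it. Reference sets for PA data should therefore
avoid nested gene content.

`stealingExperiment()` reproduces this mechanism end to end on simulated
data. Its design deserves explanation, because the cleanest-looking setup
does not show the artifact: with a *complete* reference set, full
observation and HWE sampling, the subset haplotype's homozygote genotype
class pins its frequency near the truth at the PA maximum-likelihood
point. What breaks the pinning in real cohorts is reference
incompleteness: cohorts (especially from under-represented populations)
carry haplotypes absent from any published reference panel. The
experiment therefore simulates from a truth that includes a *fragment
haplotype outside the estimation reference set*. At PA resolution the
fragment's heterozygotes with the subset haplotype collapse onto the
subset's own signature and inflate its estimate well above truth; at CNV
resolution the same genotypes are rejected as uninterpretable (the
un-rate rises, as it does in real CNV re-typing) and the surviving
estimate returns to truth within sampling error. The acceptance script
measures exactly this triplet (truth, PA estimate, CNV estimate).

The experiment also profiles the converged PA likelihood along each
subset/superset direction: if transferring 0.01 of frequency from
superset to subset costs fewer than `flatTol` log-likelihood units
(default 2, roughly a 95% likelihood-ratio band), the split is flagged as
flat -- the data cannot distinguish it, as happens when the subset's truth
frequency is 0 and no observed genotype separates the pair.

## The simulator

`simulateCohort()` generates cohorts with precisely the structure the
estimator assumes, so that recovery tests are well-posed:

* two haplotypes per individual, i.i.d. from the truth simplex (HWE);
* down-conversion to PA/CNV/mixed per gene;
* per-gene missingness, defaulting to 10% for KIR2DP1 and 17% for
  KIR3DP1 -- the pseudogene missingness levels typical of PA registry
  typing, applied only when those genes are on the panel;
* optionally, with probability `offRefRate`, a single-gene perturbation
  (CNV increment or PA flip, retried up to 100 times) that makes the
  genotype incompatible with every reference pair, emulating
  off-reference cohort haplotypes;
* decorative population labels drawn from configured proportions.

Each individual consumes its own RNG substream derived from the global
seed and the individual's index, so the first $m$ individuals of a
size-$n$ run equal a size-$m$ run, and identical configurations are
byte-identical -- stable regression fixtures by construction.

What the simulator does *not* emulate: linkage and recombination along
the locus beyond what the reference haplotypes encode, allele-level
variation beneath the structural resolution, genotyping error (missing
is the only corruption besides the explicit off-reference perturbation),
and admixture (population labels do not mix truth simplices). Passing
recovery tests therefore demonstrate correctness of the estimator under
its own model assumptions, not robustness to violations of them.

## Reference sets and files

The shipped example set (`syntheticHapSet()`) is a synthetic
ten-haplotype illustration assembled from the structural motifs of the
KIR literature; it is not a transcription of any published table, whose
full copy-number matrices are generally published as figures rather than
data files. Users encode their own reference sets in the documented TSV
format (`readHapSet()`): gene columns are matched by name, so column
order can never be silently misread, and copy numbers outside 0--4 per
haplotype (or 0--8 per diploid genotype) are input errors, not clamps.
The set includes a PA-equivalent pair (two vs one KIR3DL1 copies) that
`collapseToPA()` merges into a joined id ("49/51"-style), a gene-content
subset of the canonical A haplotype, and a variant-tagged pair encoding
ambiguous KIR2DS3/KIR2DS5 placement; the pseudogenes get no special-case
logic anywhere -- their higher missingness is purely a data property.

Haplotypes with identical copy vectors are only permitted when their
variant tags differ, and such twins survive PA collapse as distinct
haplotypes: a genotype matching their shared content is ambiguous
between them by construction, and the EM simply splits their posterior.

In the simulation YAML config the cohort size field is spelled
`n_individuals` (a bare `n` is a boolean in YAML 1.1).

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on simulated data
at deliberate scales: toy instances of 2--4 haplotypes and at most 12
genotypes for oracle comparisons (where a brute-force simplex grid is
exact), cohorts of 200--2000 individuals for recovery and
stealing experiments (where binomial sampling error at $n = 2000$,
roughly $\pm 0.01$ on a frequency of 0.4, sits comfortably inside the
0.02 recovery tolerance), and 300--500 individuals for TRS
distributions. PA interpretation of nested reference sets converges
slowly along its near-flat likelihood directions; tests that fit such
models raise `maxIter` rather than loosening `tol`.

Ordering conventions are fixed once: pairs are stored with $i \le j$ in
reference-set order, collapsed ids join members ascending (numeric ids
numerically, others lexicographically, radix order for locale
stability), and all writers emit deterministic row order, so runs are
reproducible to the byte.

## Limitations

* Frequencies are conditional on interpretability; `reportFrequencies()`
  also emits the overall scale with an explicit "un" row, since both
  presentations are in circulation and a bar labelled with one is easily
  read as the other.
* No confidence intervals on frequencies; the likelihood flatness flag
  of `stealingExperiment()` is the only uncertainty diagnostic.
* Populations are fitted independently (the CLI splits by label); there
  is no joint or admixture model.
* No de novo haplotype discovery: genotypes outside the span of the
  reference set are counted, never explained.
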