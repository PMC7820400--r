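---
title: "Methods: forensic STR population genetics with strpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic STR population genetics with strpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpopgen)
library(dplyr)
```

strpopgen implements the statistical workflow of a forensic short-tandem-repeat
(STR) frequency survey: a laboratory types a population sample (here, the
bundled survey of 400 individuals at the 23 autosomal PowerPlex Fusion 6C
loci), publishes a locus-by-allele frequency table, and derives from it the
parameters that justify using the loci for human identification and paternity
testing. This vignette describes the models and estimators, the choices made
where the design was genuinely open, and what the synthetic-data generator
does and does not emulate.

## Data model

Genotypes are kept in a long tibble — one row per individual per locus with an
unordered pair of allele labels — so every function composes with dplyr verbs.
Allele labels follow capillary-electrophoresis nomenclature: a full repeat
count with an optional `.x` microvariant suffix (`"15.3"` = 15 repeats plus 3
bases). Labels are parsed to exact integer pairs, never floating point, so
`9.3` can never be confused with a decimal fraction; `"OL"` marks an
off-ladder allele that is excluded from every statistic until the nomenclature
module resolves it. Frequency tables carry a per-locus gene-copy count `n`
(the "2n" of survey tables) because missing calls make the denominator a
per-locus quantity.

## Per-locus forensic statistics

For allele frequencies $p_i$ and observed heterozygosity $H_o$ (the fraction
of called individuals with two distinct alleles):

* unbiased expected heterozygosity $H_e = \frac{2n}{2n-1}(1 - \sum p_i^2)$;
  the raw gene diversity $1 - \sum p_i^2$ is available by option.
* polymorphic information content
  $PIC = 1 - \sum p_i^2 - (\sum p_i^2)^2 + \sum p_i^4$.
* match probability: by default the observed-genotype estimator
  $PM = \sum_g f_g^2$ over genotype relative frequencies, which is what STR
  survey tools compute from raw genotypes. Because published tables print
  only allele frequencies, a Hardy–Weinberg expectation
  $PM = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2$ is also provided; the two
  differ in finite samples, and the package asserts only the identity
  $DP = 1 - PM$ against the published table.
* power of exclusion $PE = H_o^2 (1 - 2 H_o (1-H_o)^2)$ and typical paternity
  index $TPI = 1/(2(1-H_o))$, both strictly increasing in $H_o$.
* across loci (valid under linkage equilibrium): combined match probability
  $CMP = \prod PM_l$, combined exclusion $CPE = 1 - \prod (1 - PE_l)$.

Values are rounded half-even to three decimals only in the reporting layer;
internal computation is never rounded. Recomputing $H_e$ and $PIC$ from the
bundled 3-decimal frequency table reproduces the published statistic rows to
within ±0.002, which is the propagation of the input rounding.

```{r table1}
f <- kuwait_frequencies()
pic(f) |> filter(locus %in% c("TPOX", "SE33"))
```

## Equilibrium testing

The Hardy–Weinberg test is the conditional exact test: the probability of a
genotype array given its allele counts is
$P = \frac{n!\,\prod_i m_i!\,2^h}{(2n)!\,\prod_{i \le j} n_{ij}!}$ (with $h$
heterozygotes), computed in log space, and the p-value is the total
probability of arrays no more probable than the observed one. The null is
enumerated exhaustively when feasible — always for two alleles, where the
array space is linear in $n$, and for small multi-allelic tables up to a
$10^5$-array ceiling — and otherwise estimated by shuffling the pooled gene
copies into pairs, with the observed array counted in numerator and
denominator so $p \ge 1/(n_{perm}+1)$ and the test never reports zero.
Exhaustive p-values are seed-independent; Monte-Carlo ones take a mandatory
seed and default to $10^5$ permutations.

Linkage disequilibrium is tested per locus pair with a log-likelihood-ratio
(G) statistic on the joint two-locus genotype contingency table against
independence of the single-locus genotypes, with a permutation null obtained
by shuffling one locus across individuals. This is a deliberate design
deviation from the EM-phase likelihood-ratio test of classical software:
gametic phase is unused downstream, the permutation null needs no
distributional assumptions, and the survey workflow consumes only
significant/non-significant counts. With 23 loci there are
$\binom{23}{2} = 253$ pairs and the Bonferroni-corrected level is
$0.05/253 \approx 0.000198$.

## Repeat-structure nomenclature

Sequence-based STR nomenclature writes an allele as ordered blocks —
`"(MOTIF)n"` or a bare run, whitespace optional — and the package designates
the corresponding ladder allele purely from length: with motif length $m$ and
effective length $L$, the designation is $\lfloor L/m \rfloor$ repeats plus a
`.{L mod m}` microvariant. Length-based designation (rather than
motif-identity-based) reproduces every pentanucleotide and trinucleotide row
of the bundled off-ladder table exactly with a zero offset. SE33 ships with
designation disabled: its three bundled rows are mutually inconsistent under
any single length offset (two imply an offset of 39 bases, one an offset of
27), so a calibrated offset must be supplied explicitly rather than guessed.
Novel-allele flagging means only "absent from the supplied catalogue"
(defaulting to the bundled frequency table's alleles); the package never
asserts novelty against external databases.

## Distances, trees, ordination

Population comparisons first harmonize frequency tables: shared loci are
intersected (13 loci is a typical overlap between survey generations) and
absent alleles receive explicit zeros. Nei's $D_A$ distance,
$D_A = 1 - \frac{1}{r} \sum_{loci} \sum_i \sqrt{x_i y_i}$, averages over the
$r$ shared loci so panels with different locus counts stay comparable.
Neighbour-joining trees are built by Saitou–Nei agglomeration (delegated to
ape's implementation) and recover additive matrices exactly; negative branch
lengths are kept by default because they are a property of the algorithm, with
an optional clamp for display.

Two ordinations are provided. Population-level PCA operates on the harmonized
frequency matrix, column-centred but unscaled — frequencies already share a
scale, and no scaling convention is standard for this analysis. The
individual-level PCA encodes each person as allele dosages (0/1/2 copies per
allele) over all loci, mean-imputes missing calls per column, and takes scores
from the singular value decomposition. One-hot dosage coding is itself a
choice; any full-rank linear recoding would give the same subspace.

## Admixture inference

`run_structure()` is a Gibbs sampler for the admixture model with
*uncorrelated* cluster allele frequencies: individual $i$ has ancestry vector
$q_i$ over $K$ clusters; each gene copy picks its cluster $z$ from $q_i$ and
its allele from that cluster's frequency vector. Sweeps alternate sampling
$z$, the cluster frequencies (Dirichlet with prior $\lambda = 1$), the
ancestry rows (Dirichlet with shared $\alpha$), and $\alpha$ itself by
random-walk Metropolis on $\log \alpha$ (step 0.05, uniform prior on
$(0, 10]$). The correlated-frequencies prior used by some published analyses
is out of scope; recovery tests therefore simulate under the matched
(uncorrelated) model. Model evidence per $K$ is estimated as
$\widehat{\ln P} = \bar{\ell} - s^2_\ell / 2$ from the recorded
log-likelihood trace, and $K$ is selected by the Evanno second-difference
statistic $\Delta K = |L''(K)| / SD(L(K))$ across replicate runs, defined for
interior $K$ only. Defaults (burn-in 5,000, 10,000 sweeps, thinning 10) are
desk-scale; survey-scale schedules (100,000/100,000) are a parameter change.
Cluster labels are identifiable only up to permutation; `match_clusters()`
aligns runs greedily by ancestry-column distance.

## The synthetic-data generator

`simulate_genotypes()` emulates the survey's sampling frame: diploid
genotypes drawn i.i.d. from a frequency table (Hardy–Weinberg within
population), unlinked loci, optional subpopulations whose frequencies diverge
from the base table under the Balding–Nichols model (Dirichlet with parameter
$p_i(1-F)/F$, giving each allele mean $p_i$ and variance $F p_i (1-p_i)$),
and optional admixed individuals whose *gene copies* independently pick a
population of origin from their ancestry vector — exactly the likelihood the
admixture sampler assumes, which is what makes parameter-recovery testing
meaningful. The bundled survey's subgroup sizes (162/163/75 of 400) are the
reference configuration. Deliberately not modelled: mutation, genotyping
error, linkage, consanguinity, and the surname-based derivation of real
subgroup labels. Passing recovery tests on these simulations therefore shows
the estimators are correct under their own assumptions, not that real
populations satisfy those assumptions.

## Numerical and testing choices

* Exact-test tie comparisons use a $10^{-9}$ log-space tolerance; frequency
  sums tolerate ±0.01 (3-decimal published rounding); ancestry and frequency
  rows renormalize within $10^{-9}$.
* The HWE exhaustive/Monte-Carlo switch enumerates two-allele arrays at any
  sample size and multi-allelic arrays only while the array count stays under
  $10^5$.
* Test problem sizes are desk-scale by design: recovery runs use 10 loci and
  n = 200 with short chains (a few hundred burn-in sweeps), Evanno sweeps use
  three replicate runs per $K$ — the number below which the $SD(L(K))$
  denominator is too noisy to be meaningful — and Monte-Carlo calibrations
  use 500 replicates.
* Where a family of Monte-Carlo comparisons is asserted (one per genotype
  table), individual comparisons use a hard 4-standard-error cap and the
  family is required to meet the 2-standard-error band at its expected rate;
  a per-comparison 2-sigma bound over 150 tables would fail by construction.

## Known limitations

No θ-corrected (subpopulation) match probabilities; no kinship likelihood
ratios beyond TPI; no correlated-frequency prior or linkage model in the
admixture sampler; no bootstrap support on trees; SE33 designation requires a
user-supplied offset. The bundled survey table is a transcription of a
published 3-decimal table, so statistics recomputed from it inherit that
rounding.
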