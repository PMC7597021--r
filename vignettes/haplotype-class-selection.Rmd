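---
title: "Measuring selection on haplotype classes in Evolve-and-Resequence experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection on haplotype classes in Evolve-and-Resequence experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erhaplo)
```

`erhaplo` analyzes Evolve-and-Resequence (E&R) experiments in which a locus
segregates as a small number of near-discrete haplotype classes, and the
question is how strongly each class is selected — here, the fitness cost of
three linked insecticide-resistance substitutions in *Ace*, measured as the
selection-coefficient contrast between a resistant class (1a) and its
almost identical susceptible sister (1b), in the presence of a third,
diverse susceptible class (2). This vignette lays out the models, the
estimators, the synthetic-data generator used to validate them, and the
design choices and limitations a user should know about.

## The selection model

All selection inference assumes a single diploid Wright–Fisher locus whose
alleles are haplotype classes (no recombination within the window during the
experiment: the region behaves as tightly linked blocks). Genotype fitness
is parameterized by per-class selection coefficients $s_i$ and a dominance
coefficient $h$:

$$w_{ii} = 1 + s_i, \qquad w_{ij} = 1 + h\,(s_i + s_j),$$

which for $h = 1/2$ (co-dominance, fixed throughout, as appropriate for a
dosage-like enzymatic phenotype) reduces to additive genotype fitness. For
two alleles this gives the classic recursion implemented by
`expected_trajectory()`; for small $s$ the logit frequency changes by
$\approx (s/2)\,t$ over $t$ generations.

Two estimators are provided.

* `estimate_s()` fits one frequency trajectory against the pooled rest by
  least squares over $s \in [-0.5, 0.5]$ and the starting frequency $p_0$,
  initialized from the logit-slope regression ($s_0 = \text{slope}/h$).
  Boundary frequencies are replaced by the pseudo-frequency
  $1/(2 \cdot \text{pool haplotypes})$. A joint L-BFGS-B pass is polished by
  a one-dimensional profile search on $s$ (inner `optimize()` over $p_0$,
  tolerance $10^{-10}$), and ties are resolved toward $s = 0$: if the best
  neutral fit matches the optimum within $10^{-12}$ in residual sum of
  squares, neutrality is reported. On noise-free deterministic trajectories
  the generating $s$ is recovered to better than $10^{-6}$.
* `estimate_s_joint()` fits all three class trajectories of one replicate
  simultaneously under the three-allele recursion, with class 1b as the
  fitness baseline ($s_{1b} = 0$) and the founder composition co-estimated
  on the simplex. The fitted $s_{1a}$ *is* the 1a–1b contrast.

The joint fit is the default in `fit_all_classes()` for a reason we measured
rather than assumed: subtracting two *marginal* class-vs-rest fits leaves an
interaction bias when a third class sweeps, because the background fitness
felt by 1a and by 1b differs and enters the two least-squares problems with
different weights. On noise-free deterministic paths at the default
parameters the marginal-difference route misestimates the cold-regime
contrast by about $-0.021$; the joint fit recovers it to $<10^{-5}$. The
marginal route remains available (`method = "marginal"`) because it is the
simpler, historically common analysis.

Drift is deliberately *not* part of the fit objective (a deterministic
expectation is fitted); the replicate-specific effective size $N_e$ enters
only through reporting and the boundary pseudo-frequency. This matches a
common practice in the field and keeps the estimator transparent, but it
means per-replicate uncertainty must come from the replicate spread, not
from the fit itself.

### The drift floor on a five-replicate experiment

With $N_e \approx 250$, 51–59 generations, and five replicates, drift alone
limits how precisely any estimator can recover the contrast. Feeding the
joint fit *noise-free* class frequencies from drifting simulations, the
five-replicate mean contrast has a standard deviation of ≈ 0.021 across
experiments (≈ 0.025 with Pool-seq noise added), while remaining unbiased
(mean error ≈ 0.001 over hundreds of experiments). The per-replicate
contrast distribution is also right-heavy-tailed: when class 1b drifts close
to loss its relative trajectory is dominated by noise and occasional
replicates fit extreme positive contrasts. Any single five-replicate
experiment therefore carries an irreducible uncertainty of roughly ±0.02 on
the contrast; conclusions about a difference between regimes (e.g. −0.055
vs −0.031) lean on the replicate SEM, and recovery claims tighter than this
floor are not attainable under these conditions.

## From reads to class frequencies

`read_sync()` parses PoPoolation2 `sync` files (`A:T:C:G:N:del` per
sample; `N`/`del` are kept for exact round-trips but excluded from
coverage). The alternative allele is defined *globally* per site — the
highest-count non-reference nucleotide summed over all samples, ties broken
alphabetically — so frequencies are comparable across generations.
Coordinates are 1-based inclusive everywhere.

`filter_snps()` retains sites with minor allele count ≥ 5 (summed over all
samples; the minor allele is the rarer of reference/alternative) and
coverage at least `min_coverage` in *every* sample. The coverage default
(10×) is a pragmatic choice the user should adapt to their design; a marker
failing coverage in any sample is dropped for the whole regime, so every
sample of a regime uses the same marker set.

`class_frequencies()` implements the marker-median estimator: per sample,
$f_1$ is the median class-1-allele frequency over the usable markers (an
even count uses the mean of the central order statistics), $f_{1a}$ is the
median of the three resistance-allele frequencies, $f_{1b} = f_1 - f_{1a}$
clamped to $[0, f_1]$, and $f_2 = 1 - f_1$. Negative $f_{1b}$ arises only
from sampling noise; clamping events are counted and reported. The triple
is renormalized to sum to one and the raw values are kept alongside —
whether the original analysis renormalized is not documented, so both are
exposed. Because ~130–166 markers stand behind $f_1$ but only three sites
behind $f_{1a}$, the $f_{1a}$ channel dominates the noise budget of the
contrast.

## Haplotype classes, markers, diversity

Founder haplotypes come from line × reference-strain F1 crosses: the focal
haplotype is the non-reference allele of each heterozygous call
(`read_haplotype_vcf()`), so a sample with *only* homozygous calls signals a
failed cross and is excluded (`excluded:homozygous`). Inter-class
recombinants — haplotypes whose diagnostic alleles run in blocks of both
class types, with at least `min_block = 5` consecutive sites of each — are
excluded as `excluded:recombinant`; the block criterion is our
operationalization of a rule whose purpose (unambiguous markers) is clear
but whose exact threshold is not documented.

Class calling (`assign_classes()`) groups retained haplotypes on the
fraction of differing non-missing sites. We cut the structure into two
groups by two-medoid partitioning (`cluster::pam`) rather than by cutting an
average-linkage dendrogram: with one tight, abundant class (π ≈ 0.0004) and
one small, diverse class (π ≈ 0.0082) the within-class-2 divergence is only
marginally below the between-class divergence, and the dendrogram cut
strands single diverse haplotypes as their own top-level group in a few
percent of simulated founders, while medoid assignment placed every
haplotype correctly in 60/60 simulated panels. The average-linkage tree is
still returned for inspection, and the cut is validated (mean between-group
divergence must exceed the larger within-group mean; both groups carrying
full resistance triples is an error). Within class 1, carriers of all three
resistance alleles are 1a, carriers of none are 1b, and a strict subset —
which contradicts the expected structure of this locus — errors by default.

Marker SNPs (`find_marker_snps()`) are sites where every retained class-1
haplotype carries one allele and every retained class-2 haplotype the other;
missing calls are ignored but one conflicting call disqualifies a site, and
resistance sites are excluded (they tag 1a *within* class 1). Nucleotide
diversity uses the textbook pairwise form with pairwise deletion of missing
data, normalized by the number of nucleotides examined; `L` defaults to the
36,265 bp gene length stored in the matrix, and whether π should count all
gene positions or SNPs only is resolved by following the formula: pairwise
difference counts divided by `L`.

## Temporal Ne and the drift-adjusted CMH scan

`estimate_ne()` uses the standardized squared frequency change
$F_c = (x - y)^2 / (z(1-z))$, $z = (x+y)/2$, averaged over polymorphic
sites, minus the two-stage Pool-seq sampling terms
$1/S + 1/R - 1/(SR)$ per time point ($S$ pool haplotypes, $R$ reads), then
inverted through $N_e = -t / (2 \ln(1 - F_{corr}))$. A non-positive
corrected $F$ (drift signal below sampling noise) reports $N_e = \infty$
with a flag rather than a spurious number. At the default design (1000
SNPs, coverage 80, $t = 15$) the median estimate over seeds falls within a
few percent of the true $N_e = 250$.

`cmh_scan()` compares a first against a last generation across replicates
(intermediate time points are not used in the scan). The classic mode is
the textbook Cochran–Mantel–Haenszel statistic on read-count tables without
continuity correction — appropriate only if reads were independent draws,
which Pool-seq samples across generations are not: under neutral drift at
$N_e = 250$ over 51 generations its empirical type-I error at α = 0.05 is
≈ 0.38. The adjusted mode is a score statistic
$(\sum_k (x_k - y_k))^2 / \sum_k \text{Var}_k$ with
$\text{Var}_k = z(1-z)\left[1 - (1 - \tfrac{1}{2N_{e,k}})^t + 1/R_0 + 1/R_t
+ 1/S_0 + 1/S_t\right]$, adding the Wright–Fisher drift variance and both
sampling stages to the null variance; its simulated null is uniform
(type-I ≈ 0.04–0.05, Kolmogorov–Smirnov distance < 0.05). Raw p-values are
reported (a Benjamini–Hochberg column can be added by the user; the scan
itself reports −log₁₀ p). A characteristic phenomenon reproduces in
simulation: when class 2 is fittest, the class-1 marker SNPs (shared by
1a + 1b) reach smaller p-values than the resistance sites themselves, which
is why SNP-level scans misrank the true selection target and the
haplotype-class analysis is needed.

## Dose–response

`fit_probit()` maximizes the binomial likelihood of mortality
$= \Phi(a + b \log_{10} d)$ via `stats::glm` with a probit link and reports
$LD_{50} = 10^{-a/b}$ with a delta-method CI on the log-dose scale. Dose-0
controls are excluded from the fit (log undefined); Abbott's
natural-mortality correction is implemented but off by default since the
original assays did not report one. Complete separation yields a flagged
fit with an unbounded CI instead of an error. Vials are pooled per dose; a
Pearson heterogeneity χ² against the fitted curve flags overdispersion that
pooling would hide. `single_dose_summary()` reports mean per-vial mortality
± SEM per population.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions: founder class frequencies
(0.59, 0.25, 0.16); per-regime class selection coefficients relative to 1b
of (−0.031, 0, +0.0527) hot and (−0.055, 0, +0.0935) cold; per-replicate
$N_e$ of 252/229/268/209/245 (hot) and 209/255/259/198/175 (cold); census
and pool size 1000; sampling at generations 0/15/37/59 (hot) and
0/11/21/31/41/51 (cold); a 19 + 8 + 5 founder panel; 166 marker SNPs;
within-class π targets 0.0004 and 0.0082 over L = 36,265 bp; Poisson(80)
coverage (the real coverage distribution is not documented; the mean is
exposed in the config). Two encoded interpretations deserve note. First,
the class-2 advantage is stated as 1.7× the absolute 1a–1b difference
without a baseline; we encode it relative to 1b. Second, under these
parameters the deterministic model implies a resistance-triple frequency
drop of ≈ 45% over the experiment, larger than the ≈ 29% observed in the
original data — the published point estimates and the observed drop are not
simultaneously consistent within a clean three-class co-dominant model, so
the generator follows the stated parameters and reports the drop it
produces.

Mechanically: per-haplotype private mutations are placed on non-marker,
non-resistance sites at a Poisson rate calibrated so the *expected realized*
π matches the target (accounting for mutation collisions and, for class 1,
for the fixed 1a/1b triple difference); drift is a multinomial draw of
$2N_e$ haplotypes per generation (drift acts at $N_e$, matching how the
inference consumes it — census size only affects pool sampling); Pool-seq
observation is a binomial pool draw of $2 \times$ pool-size haplotypes
followed by binomial reads at Poisson coverage, whose two-stage variance
$p(1-p)(1/R + 1/S)$ is verified against closed form in the tests. One
master seed drives deterministic per-stage, per-replicate child streams, so
a config and seed regenerate every file bit-for-bit.

Not emulated: recombination within the window, migration, overlapping
generations, sex-specific selection, mapping/calling artifacts (reads are
never simulated, only counts), within-class frequency dynamics of private
variants (classes are the units of selection), and the additional
resistance mutation segregating outside the focal triple, which the
original analysis also set aside. Passing recovery tests on these
simulations therefore validates the estimators under the stated model, not
robustness to, e.g., recombinant haplotypes arising mid-experiment.

## Numerical conventions and problem sizes

Sites are ordered by (chromosome, position); 1-based inclusive windows;
allele matrices use 0/1/NA with pairwise deletion; class trajectories are
renormalized with raw values retained; optimizer tolerances are $10^{-10}$
on $s$ (profile stage) and `factr = 10` for L-BFGS-B; s is bounded in
[−0.5, 0.5]. The test suite runs complete-pipeline recovery on 200 seeded
experiments (five replicates, $N_e$ 250, coverage 80, 51 generations,
markers + resistance sites only, ≈ 2 minutes), CMH calibration on 1000
neutral sites × 5 replicates, and Ne calibration on 15 × 1000-SNP panels;
the acceptance script averages 20 complete experiments. These sizes were
chosen to keep Monte-Carlo error well below the effects being checked while
staying fast enough to run routinely.
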