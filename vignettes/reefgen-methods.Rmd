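---
title: "Methods and design of reefgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of reefgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

reefgen analyzes SNP genotypes from natural and hatchery-restored shellfish
reefs sampled along an estuarine environmental gradient. This vignette is
the package's account of the statistical machinery: the estimators, their
assumptions, the tunable parameters, what the bundled simulator does and
does not emulate, and the places where a design choice was genuinely open.

## The analysis pipeline

The stages mirror the workflow of a seascape-genomics study of restored
oyster reefs:

1. biallelic SNP dosages are read from VCF and screened at a global
   major-allele frequency of 0.95 (rare variants bias outlier scans);
2. loci under putative selection are flagged by two differentiation scans
   (a PCA/Mahalanobis scan and an FST scan against a trimmed chi-square
   null) and by a redundancy-analysis genotype–environment association
   (GEA); the union of flags is the *outlier* set, the intersection of the
   differentiation scans (plus an optional externally supplied method) the
   *adaptive* set, and the complement the *neutral* set;
3. the neutral set is thinned by chromosome at the distance where a LOESS
   fit of intrachromosomal r² decay first drops below a critical r²
   derived from interchromosomal pairs;
4. per-site diversity (Ho, He, rarefied allelic richness, FIS with a
   locus bootstrap, Ritland relatedness, sMLH) and the LD-based effective
   population size are computed on the thinned neutral set;
5. population structure is described by pairwise Weir–Cockerham FST, a
   Mantel test of isolation by distance on FST/(1−FST) versus water
   distance, cross-validated DAPC, and k-means/BIC cluster selection;
6. genetic variance is partitioned into unique environmental, unique
   spatial (PCNM), and joint fractions with full and partial RDAs; and
7. restored-reef genetic metrics are regressed on hatchery practices
   (broodstock number, planting seasons).

`run_pipeline()` executes all stages from one seeded configuration;
every stage is also exported on its own.

## Estimators and their numerical choices

### Heterozygosity, allelic richness, FIS

Expected heterozygosity uses the small-sample unbiased gene diversity
\(\hat h = \frac{2n}{2n-1}(1 - p^2 - q^2)\); the correction matters at the
sample sizes (tens per site) this kind of study collects. Allelic richness
is rarefied hypergeometrically to a common gene count, by default the
smallest per-site count observed, so sites with different sample sizes are
comparable; for biallelic SNPs the values live in [1, 2]. FIS is
\(1 - \bar H_o/\bar H_s\) over loci; its confidence interval resamples
loci (not individuals) with replacement, matching the convention of the
bootstrap routines this mirrors, because the locus sampling variance
dominates at genome-wide marker counts.

### Ritland relatedness and the reference population

The Ritland moment estimator weights allele sharing by reference allele
frequencies; its expectation is 0 for unrelated pairs and 0.5 for
parent–offspring pairs *relative to the reference population whose
frequencies are used*. By default frequencies come from the site itself
(the convention when reporting a per-site mean). When the question is
"how related are the individuals on a planted reef", site-internal
frequencies are the wrong reference: they absorb the founder relatedness
into the frequency estimates and the mean collapses toward
\(-1/(n-1)\). The `freqs` argument takes an external reference; the
hatchery-practice analysis uses the broodstock source population, which
recovers the pedigree expectation to within ±0.05 in validation.

### LD-based effective population size

The estimator is the single-sample linkage-disequilibrium method: mean
squared correlation \(\hat r^2\) of dosages across locus pairs, minus the
sampling expectation at the harmonic-mean joint sample size S, transformed
through \(\hat N_e = (1/3 + \sqrt{1/9 - 2.76 \hat r^2_{drift}})/(2 \hat
r^2_{drift})\) for S ≥ 30 (the published small-sample constants are used
below that). Two implementation details matter:

* each pair's squared correlation is scaled by \((S/(S-1))^2\). The
  sampling term the method subtracts, \(1/S + 3.19/S^2\), equals
  \(S^2/(S-1)^3\) to high accuracy — it was derived for the Burrows
  composite estimator with that covariance scaling. A plain Pearson r²
  has null expectation \(1/(S-1)\) and leaves the estimator ~40% high;
  with the scaling, simulations at true Ne = 100 (S = 50, 2000 unlinked
  loci) give a median estimate of ~105.
* `Pcrit` (default 0.02) drops whole loci whose within-site minor-allele
  frequency falls below it; rare alleles inflate r².

Confidence intervals are a delete-one-individual jackknife on the mean
r², carried through the transform with an effective-degrees-of-freedom
chi-square approximation; a drift signal at or below the sampling floor
maps to an infinite upper limit, which is the honest answer. For a
single-cohort sample the estimate is a number of breeders Nb;
`adjust_nb()` applies the published two-trait life-history regression
(adult lifespan AL, age at maturity α; coefficients 1.103/0.245 and
0.485/0.758, overridable for the three-trait variant that also uses
fecundity variation CVf).

### LD decay and thinning

The critical r² is the squared 95th percentile of root-transformed
interchromosomal r² — the level of LD attributable to anything but
physical linkage. (Interchromosomal pairs define it here: they are
unlinked by construction, which is the premise of the threshold.)
A degree-2 LOESS (span 0.5 by default; no canonical span exists for this
use) of intrachromosomal r² on distance is
evaluated on a 200-point grid to the 99th distance percentile, and the
thinning distance is the first grid point at or below the critical value.
A chromosome whose curve never rises above the critical r² is not
thinned. Thinning is the standard greedy left-to-right scan.

### Outlier scans

The PCA scan centers and scales dosages by \(\sqrt{2p(1-p)}\),
mean-imputes missing calls, takes K principal components (scree elbow by
default, user-set in practice), and summarizes each SNP by its vector of
regression z-scores on the K scores. Outliers are robust Mahalanobis
distances (minimum covariance determinant location/scatter, fixed seed),
rescaled by the genomic inflation factor
\(\lambda = \mathrm{median}(D^2)/\mathrm{median}(\chi^2_K)\), with
upper-tail chi-square p-values and Benjamini–Hochberg q-values. The FST
scan computes per-locus multi-population Weir–Cockerham FST *without* the
finite-sample correction terms and fits the null
\(F\,df/\bar F \sim \chi^2_{df}\) by truncated maximum likelihood on the
central 90% of the distribution (both tails trimmed at 5%), so the
trimming itself does not bias the fitted null. A reversible-jump MCMC
scan is deliberately not reimplemented; its flags can be supplied as an
external column and enter both the union and the intersection.

### GEA via redundancy analysis

The RDA regresses the centered (mode-imputed) dosage matrix on site-level
environmental predictors broadcast to individuals, then rotates the
fitted values (constrained axes). Predictors are screened iteratively at
VIF < 10. Each SNP's z-score vector on the two most informative axes —
the axis regression coefficient divided by the SNP's residual standard
deviation — feeds the same robust-Mahalanobis/inflation-factor/BH
machinery as the PCA scan, and flagged SNPs are assigned to the
environmental variable with the largest absolute dosage correlation. The
residual-SD standardization matters: raw unit-norm loadings confound
cline strength with locus variance, and in validation the standardized
z-scores separate selected loci from the neutral isolation-by-distance
background by a wide margin where raw loadings sit at 3–4 null standard
deviations.

Genotypes are centered but not variance-scaled by default (the lineage of
GEA tutorials this follows does the same); `scale_genotypes = TRUE` is
available.

### Permutation tests and site-level exchangeability

Model significance uses permutation pseudo-F tests (999 permutations by
default; partial models permute the residualized response under the
reduced model). When predictors are measured once per site — the usual
design, one monitoring buoy per locality — individuals are not
exchangeable units: any site-constant variable explains some between-site
genotype variance, and free individual permutation is badly
anti-conservative (in validation, a pure-noise site-level variable was
"significant" in essentially every run). The `blocks` argument therefore
permutes the site-to-predictor assignment instead, making sites the
exchangeable units; the pipeline uses it everywhere predictors are
site-level. This is a deliberate departure from workflows that permute
individuals, and p-value resolution is limited by the number of site
permutations.

### Variance partitioning

Three models — environment plus space, environment conditioned on space,
space conditioned on environment — give the full, unique-environment and
unique-space fractions; the joint fraction is the difference. All R²
share the total sum of squares of the uncentered-by-condition response,
so the raw fractions are additive to machine precision; adjusted values
use the Ezekiel correction \(1 - (1-R^2)(n-1)/(n-1-m)\) and their joint
fraction is reported as the difference of adjusted values (slight drift
from additivity is expected and reported as computed). PCNM spatial
predictors are principal coordinates of the water-distance matrix
truncated at the longest minimum-spanning-tree edge (entries beyond it
replaced by four times the truncation); only positive-eigenvalue axes are
used, and the first PCNM tracks the broad-scale position along an
estuary-like transect.

### DAPC and k-means/BIC

DAPC retains the number of PCs that maximizes stratified-holdout
cross-validated assignment success (default 10% holdout per group — the
source does not state its fraction — with a refinement pass ±10 PCs
around the optimum), then fits linear discriminants on all data. k-means
runs on retained PC scores with 15 restarts per k and
BIC(k) = n·ln(WSS/n) + k·ln(n); the best k minimizes BIC. On
well-separated simulated demes the two agree.

## The forward simulator

`simulate_metapop()` is a diploid Wright–Fisher forward simulator of
demes on a salinity gradient: standing variation seeded from a
Beta(0.5, 0.5) frequency draw (no mutation — desk-scale runtimes, and
every analysis here works on standing variation), per-generation
selection at a configurable number of salinity-linked loci with
multiplicative fitness \(\prod_l (1 + s_l a_l z_d)\), stepping-stone or
island migration, and recombination with crossover probability
proportional to bp distance (1 cM/Mb by default; `free_recomb = TRUE`
makes all loci independent for LD-Ne validation). Selection is
implemented as fitness-weighted parent sampling. A literal
accept–reject viability scheme (survive with probability w/max w) has
the same marginal per-locus dynamics but collapses the breeding
population when many strong loci make max(w) an extreme outlier, which
silently destroys Ne and destabilizes clines — that failure mode was
observed directly and is why the weighted-sampling form is used.

Hatchery planting events found a restored deme from `broodstock_n`
parents drawn from a source deme over one or more seasons (one
metapopulation generation per season), with Dirichlet-multinomial family
sizes whose concentration is the sweepstakes parameter — small values
emulate the extreme reproductive-success variance of high-fecundity
broadcast spawners. The per-season true number of breeders is recorded
from the realized family sizes via
\(N_b = (N\bar k - 1)/(\bar k - 1 + V_k/\bar k)\), and the one-generation
pedigree of the final cohort gives expected pairwise relatedness
(full sibs 0.5, half sibs 0.25) for estimator validation.

What the simulator does *not* emulate: mutation, overlapping generations
and age structure, linked selection/background selection, genotyping
error and allelic dropout of reduced-representation sequencing, and
within-site environmental heterogeneity. Passing validation on this
generator therefore demonstrates estimator correctness under clean
Wright–Fisher assumptions, not robustness to those artifacts.

### Validation conditions (desk scale)

The validation suite and `scripts/acceptance.R` run, on one CPU in
minutes: Ne recovery at true Ne = 100 (20 replicates, 2000 unlinked
loci, 50 sampled diploids) with rank agreement across Ne ∈ {50, 100,
400}; relatedness calibration on 200 simulated parent–offspring and
unrelated pairs at 5000 loci; scan calibration on a neutral 8-deme
island model (1500 loci) and power on two-deme splits with 50 selected
loci at 2Ns = 60; GEA recovery on a 10-deme gradient (deme N = 200,
m = 0.25, s = 0.5, 1200 loci) — the high-gene-flow, weak-drift regime
chosen because it is the realistic one for larval broadcast spawners in
an estuary, where neutral FST is of order 0.01; and a hatchery grid of
broodstock {10, 25, 50, 100} × seasons {1, 2, 4} with five replicates
per cell (800 unlinked loci, source deme N = 200). The full-scale study
dimensions (hundreds of individuals × thousands of SNPs × 9–11 sites)
run through the same code paths; the reduced sizes exist to keep the
whole suite re-runnable in minutes, and are stated here as the package's
validation design.

## Known limitations

* The LD-Ne pair weighting is unweighted across pairs; NeEstimator's
  exact weighting is not reproduced, so point estimates can differ from
  it in the second digit.
* The FST-scan chi-square null assumes an island-like migration
  structure; under strong isolation by distance it is conservative in
  the bulk and can be anti-conservative in the tail, which is one reason
  the partition takes the union of methods for exclusion and the
  intersection for the adaptive set.
* Mantel tests on FST have known low power and can misattribute
  autocorrelated environments to distance; the variance partitioning is
  the complementary view.
* With few sites, site-level permutation p-values have coarse
  resolution (6 sites: minimum attainable p ≈ 1/720 only when all
  permutations are enumerated; the sampled version bottoms out at
  1/(n_perm+1)).
* The rarefaction default ties allelic richness to the worst-sampled
  site; heavily unbalanced designs should set `rarefy_to` explicitly.
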