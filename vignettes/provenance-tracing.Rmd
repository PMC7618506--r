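---
title: "Tracing tablet provenance from pharmabiome and chemometric profiles"
author: "pharmatrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing tablet provenance from pharmabiome and chemometric profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Falsified medicines accrue trace environmental DNA — bacteria, fungi, plant
fragments — from the air, surfaces and water of the site where they are
manufactured, on top of the biological signal carried by their excipients
(cellulose, starch, magnesium stearate). They also carry a chemical
fingerprint measurable by DART mass spectrometry. `pharmatrace` implements a
complete desk-scale analysis chain for exploiting both signals to infer where
a seized tablet was made, under two investigative scenarios:

* **reference-based**: tablets of known origin from the candidate sites are
  available, and origin is predicted by supervised discriminant models;
* **reference-free**: no reference tablets exist, and the geographic
  distributions of the taxa behind origin-informative sequence variants are
  mapped directly.

The package operates on amplicon sequence variant (ASV) count tables — it
does not process raw reads — plus sample metadata, tabular BLAST hits,
centroided mass-spectral peak lists, species occurrence records and
botanical-region presence tables.

## Decontamination model

Two exclusion rules clean a count table before inference:

* **Negative-control rule.** Any ASV with more than `threshold` reads
  (default 10, strictly greater) in *any single* negative control is removed
  everywhere. The per-control reading, rather than summing across controls,
  is the conservative forensic choice: a contaminant needs to exceed the
  threshold only once to disqualify the ASV. Whether extraction and PCR
  controls should instead be pooled per batch is a genuinely open design
  point; the per-sample rule is recorded in every `filter_report`.
* **Excipient rule.** Any ASV present (count ≥ 1, no threshold) in any pure
  excipient sample is removed from the tablets. Presence rather than a read
  cutoff is deliberate: the excipients are manufactured goods whose
  biosignature is irrelevant — and actively misleading — for locating the
  production site.

A third, optional rule removes ASVs whose BLAST hits match a named taxon at
or above a percent-identity cutoff (default 90). Its canonical use is
removing corn (*Zea*) sequences from plant-marker tables of starch-containing
tablets, where the corn signal derives from the ingredient, not the
environment. All three rules are idempotent, commute with row/column
permutation, and report removed/retained identifiers so that
`removed + retained` always partitions the input.

Filter order when chained is fixed: controls → excipients → taxon.

## Diversity and community structure

Counts are rarefied by iteration: `n_iter` (default 100) independent
without-replacement subsamples of `depth` reads (default 5000) are drawn per
sample and averaged, with half-up rounding. Averaging stabilises the rarefied
profile; the expected value of each cell is the hypergeometric mean, which
the tests verify directly. Samples under the depth are dropped with a
warning. The default depth of 5000 reads sits just below the smallest
per-sample depth the generator produces (its lower bound of 5264 reads), so
no tablet is lost at the default settings.

Alpha diversity is richness and the Shannon index (natural log, the ecology
convention; a `base` argument allows bits). Group differences are tested
with the tie-corrected Kruskal–Wallis rank-sum test followed by pairwise
Dunn tests on the pooled ranks, Holm-adjusted — the standard
non-parametric chain when normality and homoscedasticity fail.

Beta diversity uses Bray–Curtis dissimilarity, principal coordinates
analysis (classical scaling; negative eigenvalues are reported and axes are
restricted to positive ones), PERMANOVA with sequential (Type-I) sums of
squares in the user-given term order and exact permutation p-values
$(1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$, and the standard multivariate
dispersion-homogeneity test (distances to group spatial medians in the
corrected PCoA embedding). The PERMANOVA, dispersion and distance machinery
is delegated to *vegan* — the field's reference implementation — behind the
package's interfaces; calibration is nonetheless verified here by
simulation: under a seeded null the rejection rate at $\alpha = 0.05$ must
sit in $[0.03, 0.07]$ over 500 simulations of 20 samples at 199
permutations (the problem size used by the test suite).

## Differential abundance

Country-discriminant ASVs are found by the chain: abundance filter (total
reads ≥ 1000 across samples) → *poscounts* size factors → per-ASV Wald test
of the country log2-fold ratio → Benjamini–Hochberg adjustment at
$q = 0.05$.

The poscounts estimator handles the zero inflation that breaks plain
median-of-ratios normalisation: each ASV's reference is the $n$-th root of
the product of its *positive* counts ($n$ = all samples), and each sample's
factor is the median count/reference ratio over ASVs positive in both. A
test cross-checks the estimator against the DESeq2 reference implementation.

The test model is deliberately simpler than a full NB GLM with dispersion
shrinkage, and is documented as such: normalized counts are modelled with
negative-binomial variance $\mu + \alpha\mu^2$, where $\alpha$ is a
method-of-moments estimate from within-cell residuals (cells = country ×
manufacturing method, mirroring the nested design
`~ country + country:method`). Raw per-ASV moment estimates are unusable at
these sample sizes — whenever the sampled variance falls below the mean the
estimate collapses and the Wald statistic explodes — so each per-ASV
estimate is floored at the table-wide median MoM dispersion before a hard
floor of $10^{-8}$. This moderation plays the role dispersion shrinkage
plays in the field's NB tools. Country means are balanced over the methods
present in each country, the fold change uses a 0.5 pseudo-mean only when a
mean is zero, standard errors come from the delta method, and p-values are
two-sided normal. The simplification is guarded by simulation: on the
planted-effect benchmark (500 shared ASVs, 50 carrying a $|{\rm lfc}| = 3$
country effect, 20 seeds) the suite requires sensitivity ≥ 0.8 and
empirical FDR ≤ 0.08, and exact antisymmetry of the contrast under
country-label swap.

## Origin classification

**DAPC.** Features are centered (unscaled by default — the inputs are
already commensurate rarefied counts; a `scale` flag exists), projected onto
principal components, and the smallest number of PCs reaching the
`var_target` cumulative variance (default 0.90) is retained, capped at
$n - \#\mathrm{classes}$ so the subsequent LDA stays solvable. Linear
discriminant analysis with equal priors (the design is near-balanced and no
prior is justified) yields at most $\#\mathrm{classes} - 1$ axes and
Gaussian posteriors.

**KDA.** Kernel Fisher discriminant analysis with a radial-basis kernel.
The upstream instrument vendor does not publish its kernel or bandwidth, so
the package defaults to the median-pairwise-distance heuristic, with the
within-class scatter ridge-regularized at $10^{-6}$ relative to its mean
diagonal. Posteriors come from a Gaussian model on the discriminant
projections. The concentric-ring fixture in the test suite is the
kernel-necessity control: linear discriminants must fail on it while KDA
must reach ≥ 0.9 leave-one-out accuracy.

**LOOCV.** Each fold refits everything on $n-1$ samples. When a feature
selector is part of the pipeline it is re-run *inside* the fold, so the
held-out sample can never influence feature choice; a leakage test asserts
that scrambling a held-out sample's features leaves its fold's selection
untouched. The alternative — selecting features once on all data before
validation, as vendor workflows commonly do — is available by selecting
first and passing the reduced matrix, but in-fold selection is the default
because it is the honest error estimate.

Ties in posteriors are broken to the lexicographically first class and
flagged.

## DART-MS chemometrics

Preprocessing: background peaks estimated from blank strips (pooled,
clustered within the m/z tolerance, averaged over blank measurements) are
subtracted from matched sample peaks; intensities are rescaled per
measurement so the base peak is 100; peaks closer than 1 m/z are merged by
single-linkage (intensity sum, intensity-weighted mean mass); and peaks are
aligned across measurements into features by greedy centroid clustering at
15 mmu (0.015 Da), chosen deterministic and order-independent after m/z
sorting. Aggregation conserves total intensity and alignment maps every
peak to exactly one feature — both are asserted properties.

Feature selection: an ANOVA pre-selection keeps features whose maximum
group-mean intensity exceeds 10% and whose two extreme groups (largest vs
smallest mean — the operationalisation of "groups showing the largest
differences") differ at p < 0.05; the two-class Fisher ratio
$(\bar x_A - \bar x_B)^2 / (s_A^2 + s_B^2)$ then ranks features, keeping
the top 95 with class-mean fold change > 1. Fold change is computed on
means offset by one intensity unit so zero means stay finite; "> 1" is read
as "any difference", matching the intent of ranking by discrimination.
Peaks outside the 50–800 m/z acquisition window are kept but flagged, never
silently dropped. Whether selection should precede or follow averaging of
technical replicates is unstated upstream; the package selects on
per-measurement values, which is the more conservative (noisier) choice.

## Reference-free geolocation

For each country, ASVs enter the mapping set when the differential test
flags them overabundant there, they occur in at least `min_samples`
(default 2) of that country's tablets, and they are entirely absent from
the other country's tablets. The absence clause is the strictest reading of
"only occurred" and guarantees mapped taxa exclusively mark one site.

Each selected ASV is resolved to taxa by the **largest-percent-identity
(LPI) rule**: among its species-rank hits, only those at the maximum
identity count; one distinct species (even via tied duplicate hits) gives a
single-species assignment, several give a set of equally possible species.
Genus-level resolution is a *country-level* fallback: only when no ASV in a
country's set resolves to species is the whole set re-resolved at genus
rank — a single species-level assignment suppresses the fallback.

Two unified map forms pool a species group's geography:

* **Point maps** pool all occurrence records of all group species and count
  observations per bin of a fixed global lattice anchored at (−180, −90) —
  hexagonal by default (width 5° of longitude; the upstream binning size is
  unpublished, and 5° keeps country-scale clusters within a few bins),
  square for oracle testing. Identical coordinates all count: the unit is
  the observation, not the locality. Bin totals always sum to the record
  count.
* **Region maps** superimpose botanical-region presence rows; each region's
  value is the number of group species present there.

Taxon names are matched by exact string comparison after whitespace
normalisation; unmatched names are warned about and listed, never silently
dropped.

## The synthetic study design

`simulate_counts()` encodes the causal structure of a two-site tableting
experiment. Eight tablet groups of three tablets: per site, direct
compression with windows closed and open, and wet granulation with local
water; site A adds a waterless wet-granulation control and a foreign-water
control (group `E-5`, always held out of model fitting). Tablet communities
are mixtures of a shared excipient pool with site-specific dust and water
pools; admixture fractions are 3% dust (closed), 10% (open), and 18% dust +
6% water (wet granulation) — dust dominating water 3:1, so the
foreign-water group is dominated by its *manufacturing* site's signature
and its correct assignment to site A is recoverable but not trivial.
Negative controls carry a sparse contamination pool that also seeps into
every sample at 0.5%.

Counts are Dirichlet-multinomial: per-sample proportions are drawn from a
Dirichlet with concentration `theta` × expected proportions, then counts
multinomially at a depth drawn uniformly from 5264–329354 reads, a
realistic per-sample range for tablet 16S libraries. `theta = 1000`
models replicate tablets pressed from one homogenised lot in one session:
strong overdispersion relative to a plain multinomial (the suite verifies
variance/mean well above 1) but with per-ASV coefficients of variation
(~60–70% at mean abundance) appropriate for near-replicates rather than
independent environmental samples. The `da_benchmark_config()` variant
disables the site pools and plants a known log2 effect on a subset of a
shared pool — the configuration under which FDR and sensitivity guarantees
are measured.

`simulate_spectra()` produces 96 measurements (8 groups × 4 tablets × 3
technical replicates): 40 shared peaks, 10 site-specific peaks per site
with a planted 50-unit intensity shift, Gaussian noise (σ = 5), and blank
strips whose 8 background peaks also contaminate every tablet spectrum.
`simulate_biogeography()` draws narrow-range species from truncated
Gaussians around the two production sites (defaults: a northern English
site and Bangkok; radius 10°, SD radius/2 so ~95% of records fall inside),
cosmopolitan species uniformly, builds a 30° synthetic region grid from the
records, and emits BLAST hits with a configurable tied-top-hit rate.

What the generator does **not** emulate: sequence-level artefacts (chimeras,
PCR bias), taxonomic mis-annotation, spatial sampling bias in occurrence
databases, shared taxa between the two sites' environments, and batch
effects across sequencing runs. Passing the recovery tests therefore shows
the *computational* chain is correct and calibrated under the declared
generative model — it does not certify performance on real seized tablets,
where these nuisances are the main difficulty.

## Numerical choices

* Rarefaction rounding is half-up on the iteration mean; column sums are
  asserted within 0.5 per ASV of the target depth.
* Permutation p-values always include the observed statistic (exactness).
* Fisher-ratio variances are floored at $10^{-12}$; Wald standard errors at
  $10^{-8}$ (so a zero contrast yields $z = 0$, $p = 1$ rather than 0/0).
* BLAST coverage/identity thresholds are inclusive (≥), matching the
  semantics of the QIIME parameters they mirror.
* All file IO is UTF-8 with "." as the decimal point, not configurable.
* Seeds are mandatory wherever randomness exists; identical seed + config
  gives byte-identical outputs, verified down to the JSON run manifests.

## Validation problem sizes

The test suite and acceptance script use desk-scale sizes chosen to make
every stochastic guarantee measurable in minutes on one CPU: 500-simulation
PERMANOVA calibration at $n = 20$ and 199 permutations; 20-seed
differential-abundance benchmarks at 500 ASVs; 200 permuted-label
classifier replicates at $n = 20$; 40–50-seed recovery loops for spectral
feature ranking and geolocation. The pipeline itself has no such limits.

## Limitations

The Wald test is a documented simplification of a full NB GLM; its
guarantees hold under the generator's model and are re-checked by
simulation, not theory. Geolocation stops at maps: no statistical
assignment of a query to a site is attempted from geography alone, because
occurrence databases are too biased for that inference to be honest.
Multi-class classification beyond three classes is supported by the code
but exercised by tests only for 2–3 classes.
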