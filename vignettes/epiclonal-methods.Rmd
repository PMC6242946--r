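---
title: "Methods: MS-AFLP epigenotyping and ordinal bud-set phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MS-AFLP epigenotyping and ordinal bud-set phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclonal)
```

# Scope and scientific setting

`epiclonal` implements an end-to-end analysis of DNA-methylation variation
and transgenerational bud-set plasticity in a clonally propagated tree
collection: donor trees of a single clone sampled across a wide climatic
range, with cuttings (ramets) grown in a common garden. The package covers

* clone identification from multilocus SSR genotypes,
* scoring of dual-enzyme (HpaII/MspI) methylation-sensitive AFLP
  fragment profiles into a binary epigenotype matrix,
* epigenetic diversity and structure statistics (Shannon index, PCoA,
  distance-based AMOVA with permutation $\Phi_{ST}$, Mantel test),
* a cumulative link mixed model (CLMM) for ordinal bud-set scores with the
  derived per-donor timing statistic $D_{50\%}$, and
* per-epilocus association tests with Benjamini–Hochberg FDR control.

Because the motivating study's deposited data are deliberately not required,
the package ships synthetic-data generators that emulate the statistical
structure of every input; all tests run against those generators.

# MS-AFLP scoring model

HpaII and MspI cut the same CCGG motif but differ in sensitivity to cytosine
methylation, so the joint presence pattern of a fragment encodes a
methylation state: $(1,1)$ unmethylated (U), $(0,1)$ internal-CG methylation
(I), $(1,0)$ hemimethylation (H), and $(0,0)$ ambiguous (A; either full
methylation or loss of the restriction site by somatic mutation).

Filtering follows standard AFLP practice: only fragments of 150–600 bp are
kept (to limit size homoplasy), and singleton loci — present in, or absent
from, exactly one sample, counting a band present in either enzyme — are
removed as likely artefacts.

Scoring error is estimated from replicated samples per primer combination as
mismatched band scores over compared band scores, pooled over both enzymes.
A locus is *methylation-susceptible* when its fraction of discordant
patterns (I, H or A) strictly exceeds the per-combination threshold
$\tau = 2e(1-e)$, the probability that two independent scorings of one band
disagree when each is flipped with error rate $e$. The threshold is
"the expected per-individual probability of obtaining a mismatch owing to
technical or scoring errors"; $2e(1-e)$ is the unique such probability under
independent symmetric flips, and it is exposed as a per-combination override
for users who prefer a binomial-test criterion. Strict exceedance (">") is
used, so with $e = 0$ any discordance is evidence of methylation variation.

Binarization maps U to 0 and I, H to 1, restricted to susceptible loci.
Pattern A counts toward susceptibility evidence (it is a discordance) but is
scored in two modes: `missing_on_double_absence` (A becomes missing, so
somatic mutation cannot masquerade as methylation — used for diversity
analyses, with fully observed loci retained) and `absence_as_unmethylated`
(A becomes 0 — used for the per-epilocus association tests, which ignore
possible somatic mutations). Carrying both modes reconciles the two uses the
analysis makes of the ambiguous pattern.

# Diversity and structure statistics

Per polymorphic epilocus with methylated-state frequency $p$, the Shannon
index is $I = -(p\ln p + (1-p)\ln(1-p))$, summarised by its mean and SD over
loci. Shared epigenotypes are found with missing entries treated as
wildcards; because that relation is not transitive, groups are merged
greedily in sample order (documented, deterministic).

Squared Euclidean distance on binary data is the mismatch count over loci
scored in both samples, rescaled by $L/L_\mathrm{complete}$ so pairs with
missing data stay comparable (a simple and reproducible missing-data
convention; the matrix metadata records it). PCoA double-centres
$-\tfrac12 D^2$ (Gower) and keeps axes for positive eigenvalues, with each
axis's sign fixed by making its largest-magnitude loading positive so output
is deterministic across linear-algebra backends.

The one-level AMOVA uses the standard unequal-size coefficient
$n_0 = (N - \sum_g n_g^2/N)/(G-1)$ and
$\Phi_{ST} = \sigma^2_A/(\sigma^2_A + \sigma^2_W)$; groups of size one are
dropped. Significance of $\Phi_{ST}$ and of the Mantel correlation uses the
permutation convention $p = (\#\{\mathrm{perm} \ge \mathrm{obs}\} + 1) /
(n_\mathrm{perm} + 1)$, which matches "$p(\mathrm{rand} \ge
\mathrm{data})$" semantics and never returns 0. Because the Mantel
statistic is sometimes reported as $r^2$, both $r$ and $r^2$ are returned;
the permutation test is on $r$. Geographic distances are haversine
great-circle distances with Earth radius 6371.0088 km.

# The bud-set model

Bud set is scored on the 7-level ordinal scale 3 (growing apical meristem)
to 0 (fully developed bud) in 0.5 steps, ordered from 3 to 0 so that "the
first $j$ categories" are the least advanced phenophases. The model is a
proportional-odds cumulative logit with day of year $D$, home site $S$
(fixed categorical, reference = alphabetically first site) and ramet
carbon:nitrogen ratio $CN$ as fixed effects, and donor (TID) and ramet
(RID) random intercepts, ramets nested in donors:

$$\mathrm{logit}\,P(Bs \le_j) = \alpha_j - \beta_D D - \beta_S S -
\beta_{CN} CN - u_{TID} - u_{RID},\qquad
u_{TID}\sim N(0,\sigma_T^2),\; u_{RID}\sim N(0,\sigma_R^2).$$

Cutting weight is recorded but excluded from the model because it is
strongly correlated with CN (the generator reproduces $r = -0.504$); only CN
enters. Site and donor are partially confounded when a site contributed a
single donor; the fit warns in that case rather than silently re-assigning
variance.

## Estimation

The marginal likelihood is maximized under a Laplace approximation that
exploits the nested design: the joint mode of each donor's random effects
(one donor intercept plus its ramets) solves an arrowhead linear system, so
the inner Newton iterations cost $O(\text{ramets})$ per donor and are fully
vectorized across donors via segment sums. Thresholds are parameterized as
$\alpha_1$ plus cumulated exponentials (strict monotonicity by
construction), standard deviations on the log scale with box bounds
$[10^{-4}, 20]$, and day and CN are centred internally for conditioning
(thresholds are shifted back to the raw day-of-year scale on output; day
itself is modelled as raw day of year). The outer optimizer is `nlminb`
with central-difference gradients (step $10^{-5}$), followed by a Newton
polish on the finite-difference gradient using one finite-difference
Hessian; convergence requires the free-parameter gradient max-norm below
$10^{-4}$. Starting values come from a fixed-effects-only cumulative logit
fit. Category probabilities at extreme linear predictors are floored at
$10^{-12}$ before logging; empty score categories are collapsed with a
warning.

A fit at the study scale used in the tests (60 donors, 12 ramets each, 6
observation days, 5 sites; about 4300 observations and 14 free parameters)
takes a few seconds. The test suite verifies the Laplace log-likelihood
against exhaustive nested Gauss–Hermite quadrature (25 nodes) on a 3-donor
toy, the $\sigma = 0$ collapse against direct likelihood maximization and
`MASS::polr`, and the binary single-day collapse against `lme4::glmer`.
Like any Laplace-based fit with few observations per cluster, variance
components carry a small downward attenuation relative to exact
integration; the parameter-recovery tests quantify it.

## D50%

Per donor, the day of year at which a ramet of that donor has 50%
probability of having at most reached score 1.5 (i.e. a score in
$\{3, 2.5, 2, 1.5\}$), at a reference $CN = 12$:

$$D_{50\%} = \frac{\alpha_{1.5} - \beta_{CN}\cdot 12 - \beta_S -
u_{TID}}{\beta_D}$$

where $\alpha_{1.5}$ is the threshold whose lower cumulative set ends at
score 1.5 (the fourth threshold when all seven categories are observed; the
threshold index is resolved from the observed labels, and the choice of
$\alpha_{1.5}$ — the equation's threshold is written without an explicit
index — follows from the statistic's definition). The tests verify by Monte
Carlo that the formula equals the empirical 50%-crossing day of the
simulated fraction of ramets with score $\ge 1.5$, within one day, across
random parameter draws; by a symmetry argument the crossing day does not
depend on $\sigma_R$. $D_{50\%}$ values are then correlated (Pearson, two-
sided t test) with home-site climate (January and July temperature, PET).

# Association tests

Per polymorphic epilocus (absence scored as unmethylated), simple logistic
regressions (`glm`, binomial, logit link; one covariate per model) of the
methylation state on each climate covariate, with Wald z tests. Complete
separation — detected as non-convergence or a standardized slope above 15 —
flags the test non-estimable and excludes it from the FDR family. Welch's
unequal-variance t test compares $D_{50\%}$ between methylation states per
epilocus; loci methylated in only one tested donor, or in all but one, are
discarded (the discard rule is applied at the level of the tested units,
donors, since $D_{50\%}$ is a per-donor statistic). Benjamini–Hochberg
adjustment is `p.adjust(method = "BH")`; the default FDR family pools all
(locus x covariate) tests of an analysis, the conservative reading, with a
per-covariate family available.

# The synthetic-data generators

All randomness flows from one integer seed; each table draws from its own
derived sub-stream so adding draws in one generator does not perturb the
others. The generators emulate, in order:

* **Sites/climate.** One latent winter-mildness factor with loadings of
  0.96 on January and March temperature, frost days (negative) and PET, so
  each of those pairs exceeds $r^2 = 0.8$ in expectation; July temperature
  loads weakly, precipitation and topsoil C:N are near-independent. Values
  are clipped to the observed ranges of the reference collection (e.g.
  January temperature in $[-1.4, 8.024]$ °C). Defaults: 20 sites x 3 donor
  trees = 60 donors (the reference study spread 60 donors over 25 sites
  with 1–6 trees each; a fixed count keeps the generator simple and the
  cluster structure comparable).
* **MS-AFLP.** Per locus a methylation frequency: 55% of loci are
  essentially unmethylated (frequency below 0.02, emulating the observed
  share of markers that fail the susceptibility threshold, 94/216), the
  rest uniform on $[0.05, 0.40]$. Per sample x locus a latent state
  (double absence with probability 0.003 — the value implied by 15 of 94
  susceptible loci showing at least one ambiguous pattern among 60 samples
  — otherwise methylated with the locus frequency, hemimethylated with
  probability 0.3 given methylated, with an optional logit shift per °C of
  site January temperature), mapped to dual-enzyme bands and flipped
  independently per band with the per-combination error rate. The seven
  default combinations carry the reference marker counts
  (29, 22, 25, 28, 20, 51, 41) and per-band flip rates chosen so the
  replicate mismatch rate $2e(1-e)$ reproduces the reference error rates
  (mean 0.028). Fourteen replicate pairs re-score latent states with
  independent flips. Double absence therefore arises both as a latent
  state and as the $(0,0)$ image of band flips, matching the two causes the
  scoring model distinguishes.
* **SSR.** A dominant clone genotype over 11 loci, five single-allele
  somatic variants (one repeat unit at one locus), optional half-sib
  genotypes, and replicate pairs with per-allele error 0.0015 (so the
  recovered rate is about 0.3%).
* **Bud set.** Ordinal draws from the CLMM above, 13 ramets per donor
  (the study mean 12.8 rounded), six weekly late-summer dates
  (day of year 218–253), donor and ramet intercept SDs 0.8 and 0.5, day
  slope 0.15 (a transition width of a few weeks on the logit scale),
  thresholds placing an average donor's $D_{50\%}$ near day 235, C:N drawn
  jointly with weight at $r = -0.504$, and a site effect linear in January
  temperature on the latent scale (the observed $D_{50\%}$–temperature
  relation is approximately linear). Its slope, −0.154 logit °C⁻¹, makes
  the expected Pearson correlation between $D_{50\%}$ and January
  temperature about 0.34 given the other defaults. The default climate
  effect on methylation is 0: the reference analysis found no
  FDR-surviving epilocus–climate association, so the generator's null is
  the faithful default.

What the generators do *not* emulate: electropherogram traces and peak
calling, fragment-size homoplasy, sample-level missingness, spatial
autocorrelation of climate beyond the single latent factor, and any direct
causal link from methylation state to phenology. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not biological conclusions about real collections.

# Numerical and design choices

* Permutation p-values are floored at $1/(n_\mathrm{perm}+1)$; permutation
  streams are seeded independently of data generation.
* Enzyme tables are matched on locus identifiers; size binning from raw
  electropherograms is upstream of this package.
* The singleton rule covers both present-in-one and absent-in-one, and is
  applied to either-enzyme presence.
* The reference (modal) multilocus genotype is the clone; ties are broken
  by first occurrence with a warning. Clone-mate classification tolerates
  `max_mismatch` alleles (default 1) when every differing allele is exactly
  one repeat unit (default 2 bp, per-locus overrides) from the reference.
* AMOVA is one-level (among/within countries), matching the single
  $\Phi_{ST}$ the analysis reports.
* Problem sizes in the tests (e.g. 50 recovery replicates at 60 x 12 x 6;
  400 null datasets with 199 permutations for calibration) were chosen as
  the smallest sizes at which the checked properties are statistically
  decisive.

# Known limitations

* Variance-component estimates inherit the Laplace approximation's small
  attenuation; no standard errors are reported for them.
* The epigenotype matching relation is order-dependent by construction
  (greedy grouping of a non-transitive relation).
* `run_full()` assumes one epigenotyped ramet per donor, as in the
  reference design; within-donor epigenetic heterogeneity is out of scope.
* No spring (bud-burst) phenology, no spline or threshold alternatives to
  the linear day effect, and no spatially explicit association models.
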