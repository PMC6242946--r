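# epiclonal

Epigenetic variation and transgenerational phenology in clonal plant
collections: methylation-sensitive AFLP (MS-AFLP) epigenotyping, epigenetic
diversity and structure statistics, and ordinal bud-set phenology modelling.

## The problem

A widely planted tree cultivar can be a single clone: genetically uniform,
yet growing in very different climates. When cuttings (ramets) from such
donor trees are raised in one common garden, any systematic phenotypic
differences between them — for example in the timing of autumn bud set —
cannot be genetic and point to transgenerationally transmitted epigenetic
or physiological carry-over effects. `epiclonal` implements the full
analysis chain for such a design, for researchers working with clonal
collections, MS-AFLP markers and ordinal phenology scores:

1. **Clone identification** from multilocus SSR genotypes (modal multilocus
   genotype = the clone; single-repeat somatic variants tolerated), with the
   replicate-based genotyping error rate
   `100 × discordant scores / (markers × individuals)`.
2. **MS-AFLP scoring**: HpaII and MspI cut the same CCGG motif with
   different methylation sensitivity, so the dual-enzyme presence pattern
   per fragment encodes a methylation state — (1,1) unmethylated, (0,1)
   internal CG methylation, (1,0) hemimethylation, (0,0) ambiguous
   (methylation or site loss). Fragments of 150–600 bp are kept, singletons
   removed, replicate scoring error estimated per primer combination, and a
   locus is methylation-susceptible when its discordance fraction exceeds
   the error threshold τ = 2e(1−e). Binary epigenotypes are produced with
   the double absence scored either as missing (diversity analyses) or as
   unmethylated (association tests).
3. **Diversity and structure**: per-locus Shannon index
   I = −[p ln p + (1−p) ln(1−p)], shared-epigenotype matching with missing
   data as wildcards, Euclidean epigenetic distances with missing-data
   rescaling, PCoA, one-level AMOVA with permutation Φ_ST, and a Mantel
   test against haversine geographic distances.
4. **Bud-set phenology**: a cumulative link mixed model on the 7-level
   score (3 → 0),

   logit P(Bs ≤ⱼ) = αⱼ − β_D·D − β_S·S − β_CN·CN − u_TID − u_RID,

   with donor and ramet random intercepts fitted by a Laplace approximation
   exploiting the nested design, and the per-donor timing statistic

   D₅₀% = (α₁.₅ − β_CN·12 − β_S − u_TID) / β_D,

   the day of year at which half of a donor's ramets have at most reached
   score 1.5. D₅₀% is correlated with home-site climate.
5. **Association tests**: per-epilocus binomial-logit regressions on
   climate, Welch's t tests of D₅₀% by methylation state, and
   Benjamini–Hochberg FDR control.

A synthetic-data module generates every input table with the statistical
structure the analysis assumes (correlated climate covariates, dual-enzyme
band patterns with technical error and replicate pairs, a clonal SSR table,
and ordinal bud-set draws from the model above), so the whole pipeline is
testable without any external download.

## Worked example

```r
library(epiclonal)

cfg <- sim_config(seed = 1)          # 60 donors, 7 primer combos, 13 ramets each
report <- run_synthetic(cfg, n_perm = 999)
report
```

```
epiclonal pipeline report
  SSR: 60 samples, 6 MLGs, 60 clone members, error 0.000%
  MSAP: 172 loci, 92 susceptible, 92 polymorphic, mean error 0.025
  Diversity: Shannon 0.434 (SD 0.167); Phi_ST 0.009 (p 0.191); Mantel r2 0.007 (p 0.072)
  Phenology: beta_day 0.155, sigma_tree 0.622, sigma_ramet 0.485; D50-t_jan r 0.518 (p 2.29e-05)
  Associations: 27/644 glm tests significant raw, 0 after FDR; 2/90 Welch, 0 after FDR
```

Reading the report: all 60 donors carry the clone's multilocus genotype
(five are single-repeat somatic variants, grouped into their own MLGs but
classified as clone members; no replicate discordances happened to be drawn
at the 0.15% per-allele error rate, hence the 0.000%). Scoring the
simulated fragment profiles keeps 172 markers after size and singleton
filtering, of which 92 exceed their primer-specific error thresholds; the
mean replicate error rate (0.025) recovers the simulated scoring noise.
Epigenetic differentiation among countries is near zero (Phi_ST = 0.009,
permutation p = 0.191 with 999 permutations) and unrelated to geographic
distance (Mantel) — as it should be, since the generator's default places
no climate effect on methylation. The bud-set model recovers the
generating parameters (day slope 0.155 vs 0.15 simulated; donor and ramet
intercept SDs 0.622/0.485 vs 0.8/0.5 — variance components carry the
Laplace approximation's small attenuation plus sampling noise), and the
derived D50% values correlate with home-site January temperature
(r = 0.52, p = 2e-5): ramets from warmer origins set bud later, even
though every tree is the same genotype. Of 644 per-epilocus climate
regressions, 27 are nominally significant and none survive FDR
correction — the expected false-positive behaviour under the null.

Individual stages are exposed as plain functions (`identify_mlgs()`,
`msap_score()`, `shannon_index()`, `amova()`, `mantel()`, `budset_clmm()`,
`d50()`, `epilocus_glm()`, `welch_test()`, ...) and accept CSV paths or
data frames; `write_study_csvs()` materializes a synthetic study on disk.
See the methods vignette (`vignettes/epiclonal-methods.Rmd`) for the model
details and every numerical choice.

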