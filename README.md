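# twinstable

Stability, heritability, and conservation of longitudinal urinary NMR
metabolomic profiles in twin cohorts.

## The problem

Repeated-measures metabolomics separates spectral regions that
fluctuate with diet and physiology from regions that track a person's
"usual level" over months. When the cohort consists of monozygotic
(MZ) and dizygotic (DZ) twin pairs, the same design also attributes
that stability to additive genetic (A), shared environmental (C) and
unique environmental (E) sources, and the stable profile can be used to
recognise individuals as themselves over time. `twinstable` is for
researchers running such a repeated-measures twin metabolomics study —
or methodologists studying the design — and implements the full
analysis chain:

1. **Preprocessing** — 0.02-ppm spectral binning over 0–10 ppm
   (trapezoidal bin areas, configurable excluded regions, 400 analysed
   bins by default), total-integral normalisation, and Johnson
   normality transformation (percentile method, rank-based
   inverse-normal fallback).
2. **Variance decomposition** — per-bin linear mixed models
   `Y = mu + X beta + B(individual) + F(family) + e` decompose total
   variance into between-individual (σ²_B), between-family (σ²_F) and
   within-individual (σ²_W) components; the intraclass correlation

   ICC = (σ²_B + σ²_F) / (σ²_B + σ²_F + σ²_W)

   is the stable fraction. Covariates (age, sex, fat-free mass,
   diet-quality score) are tested by ML likelihood-ratio tests with
   Benjamini–Hochberg FDR control across all bins × covariates, and
   significant covariates are retained when reporting ICCs.
3. **Stability classification** — excellent (ICC ≥ 0.75), good
   (0.51–0.74), fair (0.40–0.50), poor (< 0.40); bins with ICC ≥ 0.51
   form the stable metabolome.
4. **Longitudinal Cholesky ACE SEM** — lower-triangular path matrices
   a, c, e over the three visits give the expected twin-pair covariance
   [[V, R], [R', V]] with V = A+C+E and R = A+C (MZ) or ½A+C (DZ);
   maximum likelihood over both zygosity groups, squared standardized
   path coefficients (per-visit proportions of variance, summing to 1),
   profile-likelihood confidence intervals, assumption checks, and
   power simulation with the boundary-corrected χ²₀:χ²₁ mixture test.
5. **Conservation indices** — every baseline profile is correlated with
   every 2-month profile; the index 1 − (rank − 1)/(N − 1) ranks each
   person's self-correlation among their correlations with everyone
   else (1 = most similar to oneself), reported in bands 1.00,
   0.90–0.99, 0.70–0.89, < 0.70, with a stable-subset variant and a
   covariate-adjusted weighted variant.

A synthetic twin-cohort generator with known A/C/E covariance
structure, covariate effects and visit noise (default: 44 MZ + 20 DZ
same-sex pairs, 3 visits, 20% stable bins) makes every stage testable
end to end without any external data.

## A worked example

```r
library(twinstable)
cfg <- pipeline_config(n_mz_pairs = 44, n_dz_pairs = 20, n_bins = 40,
                       sem_max_bins = 3, seed = 1)
res <- run_pipeline(cfg, out_dir = "twin_run")
print(res$stable)
summarize_conservation(res$conservation[res$conservation$method == "stable", ])
```

```
stable metabolome: 6 of 40 bins (15.00%, ~15%) with ICC >= 0.51
top bins:
 bin_ppm       icc
    0.05 0.6255893
    0.03 0.6107876
    0.11 0.6039133
    0.01 0.5867920
    0.15 0.5865398
       band  n percent
1      1.00 14    10.9
2 0.90-0.99 61    47.7
3 0.70-0.89 30    23.4
4     <0.70 23    18.0
```

Six of the 40 simulated bins are classified stable at this sample size
(the generator makes 8 truly stable; estimation noise at 64 pairs drops
two below the 0.51 cutoff), and 82% of the simulated cohort has a
conservation index ≥ 0.70 — their stable profile after two months ranks
among the top 30% of their correlations with all profiles. Fitting the
longitudinal ACE model to the most stable bin:

```r
pr  <- twin_pairs(res$bins, res$cohort, bin = res$stable$bins$bin_ppm[1])
fit <- fit_cholesky_ace(pr)
fit
```

```
Longitudinal Cholesky ACE twin model (44 MZ + 20 DZ pairs, 3 visits)
  -2 log-likelihood: 915.175 (23 parameters)
  squared standardized coefficients (per-visit rows):
          A1    A2 A3    C1 C2 C3    E1    E2    E3
visit1 0.005 0.000  0 0.279  0  0 0.715 0.000 0.000
visit2 0.075 0.004  0 0.302  0  0 0.148 0.470 0.000
visit3 0.103 0.006  0 0.318  0  0 0.116 0.015 0.442
```

Each row is one visit; entries are proportions of that visit's variance
attributed to latent factors first appearing at visit 1, 2 or 3 (rows
sum to 1). Here a shared-environmental factor present at baseline (C1)
accounts for ~30% of variance at every visit, while most
unique-environmental variance is visit-specific — the typical signature
of a familially stable bin.

A thin command-line wrapper over these functions is installed at
`inst/cli/twinstable.R` with subcommands `simulate`, `bin`,
`decompose`, `classify`, `sem`, `conserve` and `run`.

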