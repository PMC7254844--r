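# progbias

Polygenic risk scores (PRS) built from disease-*incidence* GWAS are
increasingly applied to people who already have the disease, asking whether
high genetic risk also predicts *subsequent* events — recurrence, progression,
death. Those case-only analyses are haunted by **index event bias**: case
status is a collider between the genetic score and every other cause of the
disease, so conditioning on it induces spurious (typically protective)
associations between the score and prognosis even when the score has no
direct prognostic effect. Survival-dependent recruitment — severe cases dying
before they can enrol — adds a second selection distortion of the same sign.

`progbias` is an R package for biostatisticians and genetic epidemiologists
who want to (a) estimate PRS-outcome associations stratified by prevalent
case status, with heterogeneity tests and covariate profiles, and (b) detect
and correct the summary-statistic-level bias. It implements the full
workflow:

- **Summary statistics**: TSV ingestion with header mapping, record
  validation, allele harmonization (strand flips, swapped alleles,
  palindromic ambiguity), strict INFO/P filtering, greedy LD **clumping** and
  window-based LD **pruning** against a panel- or table-based r² reference.
- **PRS construction**: P-value thresholding + clumping, weights = GWAS
  log-odds, dosage scoring with allele re-orientation and mean imputation,
  pooled-SD standardization.
- **Stratified association**: per-SD logistic/linear fits, the two-sample
  heterogeneity z-test `z = (b1 − b2)/√(se1² + se2²)`, covariate values at
  the 20/40/60/80% score quantiles.
- **Index-event-bias correction**: with per-SNP incidence effects β₁ⱼ (SE
  σ₁ⱼ) and case-only prognosis effects β₂ⱼ (SE σ₂ⱼ),
  - naive slope: OLS of β₂ on β₁ across SNPs;
  - **Hedges–Olkin** slope: b = cov(β₁,β₂)/(var(β₁) − mean σ₁²), removing
    regression dilution, jackknife SE;
  - **SIMEX** slope: re-estimate under added noise of variance λσ₁ⱼ²
    (λ ∈ [0,2]), extrapolate a quadratic to λ = −1;
  - **I²GX** diagnostic: max(0, (Q − (k−1))/Q) with
    Q = Σⱼ(β₁ⱼ − β̄w)²/σ₁ⱼ², quantifying how much of var(β₁) is signal;
  - adjustment: β₂ⱼᵃᵈʲ = β₂ⱼ − b·β₁ⱼ, SE √(σ₂ⱼ² + b²σ₁ⱼ²);
  - fixed-effect **IVW**: β = Σwⱼβ₁ⱼβ₂ⱼ / Σwⱼβ₁ⱼ², wⱼ = 1/σ₂ⱼ²,
    SE = (Σwⱼβ₁ⱼ²)^(−1/2), before and after adjustment.
- **Synthetic cohorts**: a liability-threshold simulator with an unmeasured
  shared factor U and survival-dependent recruitment that reproduces the
  collider structure with known ground truth, plus per-SNP logistic GWAS of
  incidence (independent sample) and prognosis (recruited cases).

## Worked example

A scaled simulation study under the bias scenario (positive genetic effects
on incidence, *zero* direct genetic effects on prognosis, shared factor and
survival selection active):

```r
library(progbias)
cfg <- runConfig(seed = 7,
                 simulation = list(nIndividuals = 50000, nSnps = 100),
                 externalN = 30000,
                 correction = list(slope_method = "hedges_olkin"))
report <- runSimulationStudy(cfg)
report$associations
```

```
       stratum         outcome     n    beta     se        p    or ci_lower ci_upper
1 disease-free incidentDisease 47495  0.4724 0.0260 1.07e-73 1.604    1.524     1.69
2 disease-free           death 47495 -0.0295 0.0157 6.01e-02 0.971    0.942     1.00
3         case           death  1969 -0.0857 0.0522 1.01e-01 0.918    0.829     1.02
```

Per SD of the score, disease-free individuals show the expected strong
positive association with incident disease (OR 1.60), while among prevalent
cases the same score trends *protective* for death (OR 0.92) although it has
no direct prognostic effect in the generative model — the collider/selection
signature. The correction quantifies and removes it:

```r
report$correction$slope
## SlopeEstimate [hedges_olkin]: -0.2273 (95% CI -0.3952, -0.0595), 51 SNPs
##   I2GX = 0.933
report$correction$raw
## IVWResult (uncorrected, 10 instruments)
##   OR 0.847 (95% CI 0.697, 1.030), P = 0.0961
report$correction$corrected
## IVWResult (bias-corrected, 10 instruments)
##   OR 1.063 (95% CI 0.874, 1.295), P = 0.54
```

The cross-SNP regression of prognosis effects on incidence effects has a
clearly negative slope (−0.23) with I²GX = 0.93 (little attenuation from
measurement error); subtracting b·β₁ⱼ from each prognosis effect moves the
IVW estimate of "genetic liability to disease → death among cases" from a
spurious OR 0.85 back to a null-covering OR 1.06.

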