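---
title: "Case-only polygenic score associations and the index-event-bias correction"
author: "progbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only polygenic score associations and the index-event-bias correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progbias)
```

## The problem

A polygenic risk score (PRS) summarising variants associated with disease
*onset* is often carried into the diseased population to ask whether it also
predicts *subsequent* events. Two selection mechanisms distort that
case-only analysis even when every modelling step is correct:

1. **Collider stratification.** If an unmeasured factor $U$ raises both
   disease liability and post-disease event risk, then among cases the
   genetic score and $U$ become negatively correlated — someone who became a
   case despite a low score probably carries a high $U$. Any outcome driven
   by $U$ then shows a spurious *protective* association with the score.
2. **Survival-dependent recruitment.** Cases with the most severe disease
   are the least likely to survive to study enrolment, selectively removing
   high-liability (hence high-score) cases.

`progbias` implements the summary-statistic correction for this bias: the
cross-SNP regression of prognosis effects on incidence effects estimates the
proportional bias, each prognosis effect is adjusted by subtracting the
slope-scaled incidence effect, and the causal contrast is re-estimated by
fixed-effect inverse-variance weighting (IVW) before and after adjustment.

## Generative model of the simulator

The synthetic-cohort module exists so every claim the package makes can be
validated against known ground truth. Per individual $i$ with dosages
$g_{ij} \sim \mathrm{Bin}(2, f_j)$:

$$L_i = \sum_j \beta_j (g_{ij} - 2f_j) + \gamma_U U_i + \gamma_a \tilde a_i
        + \gamma_s (s_i - \tfrac12) + \varepsilon_i, \qquad
  \varepsilon_i \sim N(0,1)$$

with disease iff $L_i > T$ (probit liability model; a logit switch is
provided). $U_i \sim N(0, \sigma^2_U)$ is the unmeasured shared factor,
$\tilde a$ standardized age (Uniform(40, 69), a mid-life biobank's
recruitment window), $s$ sex. Among cases, recruitment is Bernoulli with
logit $\alpha_R - c \, z(L_i)$, $z(\cdot)$ the within-case liability
z-score, so $c$ is interpretable as the recruitment-logit drop per SD of
disease severity. For every recruited individual the binary event `death`
follows a logistic model with *direct* genetic effects
$\beta^{(d)}_j$ (zero by default), $\delta_U U_i$, and age/sex terms;
recruited disease-free individuals additionally receive an
`incidentDisease` indicator from a fresh liability draw against the same
threshold (new onset during follow-up).

Outcomes are simulated for all recruited individuals, not only cases,
because the stratified analysis compares the *same* outcome between strata;
the per-SNP prognosis GWAS itself is restricted to recruited cases.

### Default parameters (the bias scenario)

| parameter | default | rationale |
|---|---|---|
| allele frequencies | Uniform(0.05, 0.95) | common variants, as in a pruned GWAS panel |
| $\beta_j$ (incidence) | $N(0, 0.08^2)$ | per-allele log-liability effects giving a realistic polygenic signal at 100–150 SNPs |
| $\beta^{(d)}_j$ (direct prognosis) | 0 | the bias scenario: any case-only association is artefactual |
| $\gamma_U, \delta_U, \sigma^2_U$ | 1, 1, 1 | one standardized unmeasured factor loading fully on both stages (e.g. an unmeasured metabolic/behavioural burden) |
| threshold $T$ | solved for prevalence 0.05 | places expected prevalence analytically under the probit model |
| survival coefficient $c$ | 1 | one recruitment-logit per SD of severity |
| recruitment intercept | 1.5 | ≈82% of average-severity cases enrol |
| prognosis intercept | −2.5 | ≈20–25% case event rate once $U$ is added |

These values are fixed study conditions, not tuning knobs: they were chosen
to represent a strong-but-plausible confounding structure and are used
unchanged by the test-suite and the acceptance script.

### What the simulator does *not* emulate

Real LD panels (LD is optional, block-AR(1), enough to exercise clumping and
pruning but not coalescent-realistic), imputation INFO heterogeneity
(INFO ≡ 1 for simulated statistics), principal components (the prognosis
GWAS adjusts for age and sex only — a deliberate simplification of the
PC-adjusted models a real analysis would use), electronic-health-record
phenotyping, and time-to-event structure (outcomes are fixed-horizon
binaries, matching the logistic models the workflow targets). Passing tests
therefore validate the *statistical machinery* under the stated generative
model, not the fidelity of any real cohort.

## Analysis conventions and numerical choices

- **Windows and thresholds.** Positions are 1-based; a 250 kb window means
  $|\Delta bp| \le 250\,000$ (both endpoints inclusive). Filters follow the
  conventional strict readings: keep $P < p$, keep INFO $> i$, clump-reject
  at $r^2 \ge r^2_{max}$.
- **Clumping tie-break.** Equal P-values are ordered by smaller position, so
  output is deterministic.
- **Pruning semantics.** The retained set is defined inductively in position
  order (a variant survives iff every earlier survivor within the window has
  $r^2$ below threshold). This makes the result a deterministic fixed point
  of the pairwise removal rule and independent of how a scan window slides;
  the conventional step-size parameter is accepted but cannot change the
  result. The classical missingness-based drop rule is unavailable for
  summary data, so the later-position member of a violating pair always
  loses.
- **Missing LD pairs** are treated as $r^2 = 0$ with a warning: refusing
  them would empty synthetic runs backed by sparse panels.
- **Palindromic variants** (A/T, C/G) are dropped during harmonization when
  the effect-allele frequency lies in [0.4, 0.6] in either study — the
  common practice where strand cannot be inferred from frequency.
- **Standardization** uses the pooled (unstratified, n−1) SD over the
  recruited sample, so case and disease-free odds ratios share the "per SD"
  unit; per-stratum rescaling is explicitly rejected because it would make
  the heterogeneity test compare effects on different scales.
- **Slope regressions include an intercept** by default: the intercept
  absorbs any directional mean shift so the slope captures the proportional
  bias; `intercept = FALSE` is available.
- **Hedges–Olkin SE** is a leave-one-out jackknife — assumption-light, and
  well-defined without specifying the distribution of the true effects.
- **SIMEX** defaults: $\lambda \in \{0, 0.5, 1, 1.5, 2\}$, 1000 replicates
  per $\lambda$, quadratic extrapolant, fully seeded. The reported CI
  propagates the Monte-Carlo replicate spread through the extrapolation, so
  it quantifies extrapolation stability (the convergence diagnostic that
  matters in practice) rather than sampling variability; the per-$\lambda$
  means and variances are exposed in `diagnostics` for convergence
  assessment. When noise from null SNPs destabilises the extrapolation, the
  supported remedy is restricting the slope set to SNPs nominally associated
  with incidence (`pIncMax = 0.05`), which is also the default of the
  orchestrated workflow. The quadratic extrapolant is adequate when
  measurement error is modest (I²GX close to 1) and increasingly
  approximate as I²GX falls — one reason I²GX is always reported beside the
  slope.
- **Adjustment SEs** recombine per-SNP variances only
  ($\sqrt{\sigma_2^2 + b^2\sigma_1^2}$); the slope's own uncertainty is not
  propagated by default, matching the subtraction rule's treatment of $b$
  as fixed, with an optional $\mathrm{var}(b)\,\beta_1^2$ term.
- **IVW** is fixed-effect with weights $1/\sigma_2^2$. After correction the
  default weights use the *adjusted* SEs; an `"unadjusted"` mode keeps the
  raw weights, in which case corrected = raw − slope holds as an exact
  algebraic identity (used as a consistency check).
- **Instruments vs slope set.** The IVW instrument list is a deliberately
  stricter, explicit SNP list than the broad pruned slope-estimation set.
  The orchestrated study uses the clumped, P-thresholded PRS model SNPs as
  its default instrument panel; any explicit list can be supplied.
- **Degenerate inputs** raise informative errors rather than NAs: empty
  case strata, single-class outcomes, separation in logistic fits,
  zero-variance incidence effects, noise-dominated Hedges–Olkin
  denominators, constant scores.
- Wald P-values are floored at $10^{-300}$ so extreme associations cannot
  violate the $P \in (0, 1]$ record invariant by underflowing to zero.

## Validation design and problem sizes

The test-suite validates at four levels, with sizes chosen to keep the full
run within a normal interactive budget:

- **Exact oracles**: per-SNP logistic fits against `stats::glm`; clumping
  and pruning against brute-force reference implementations on 200 random
  instances of up to 50 SNPs; IVW against weighted regression through the
  origin; Hedges–Olkin and I²GX against direct formula evaluation.
- **Limit identities**: with all incidence SEs zero the three slope
  estimators coincide; zero slope is the identity adjustment; corrected IVW
  equals raw minus slope in unadjusted-weight mode.
- **Calibration**: heterogeneity-test type-I error over 2000 equal-effect
  replicates; uniformity (Kolmogorov–Smirnov) of heterogeneity P over 200
  seeds of a no-bias scenario ($\delta_U = 0$, no survival selection).
- **Recovery and end-to-end behaviour**: Hedges–Olkin and SIMEX recover a
  generative slope of −0.3 over 500 summary-level replicates (500 SNPs,
  measurement-error ratio 0.09 so the quadratic extrapolant's approximation
  error is negligible relative to Monte-Carlo spread); IVW recovers a true
  causal log-odds of 0.3; one full-scale study (200 000 individuals,
  ~5 000 recruited cases, 150 SNPs, 50 000-person external incidence GWAS)
  reproduces the stratified sign structure; the estimated slope is negative
  across 20 seeds at 60 000 individuals; and the corrected IVW CI covers
  the null in ≥90% of 200 replicates at 15 000 individuals.

## Known limitations

- The correction assumes direct genetic effects on incidence and prognosis
  are independent; when shared pathways drive both (plausible for many
  diseases), the adjustment can overshoot — the corrected estimate is a
  sensitivity analysis, not a guarantee.
- The simulator's single Gaussian $U$ is the simplest confounding structure
  producing the bias; real confounding is multivariate and partly measured.
- Binary fixed-horizon outcomes ignore censoring and competing risks.
- The SIMEX CI deliberately measures extrapolation stability, not sampling
  error; use the Hedges–Olkin jackknife CI (or both) for inference about
  the slope itself.
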