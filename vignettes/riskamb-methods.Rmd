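---
title: "Modeling valuation under risk and ambiguity and its neural encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling valuation under risk and ambiguity and its neural encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskamb)
```

## The scientific problem

Posttraumatic symptom severity has been linked to altered processing of
rewards and punishments. A productive way to probe this is a monetary
choice task with no feedback: on each trial a subject chooses between a
sure gain or loss of \$5 and a lottery whose probability is either fully
known (risk) or partially occluded (ambiguity). Because the lottery is
never played out during the task, the design isolates *valuation* from
learning. `riskamb` implements the complete analysis chain for such a
study — behavioral model fitting, first-level ROI GLMs, and group
inference — together with a fully synthetic cohort generator so that
every stage can be exercised and validated against known ground truth
without any subject data.

## The choice model

Each option's subjective value is

$$SV = \left[P - \beta \tfrac{A}{2}\right] V^{\alpha},$$

where $P$ is the outcome probability (1 for the sure option), $A$ the
ambiguity level (0 for risky lotteries), and $V$ the unsigned dollar
magnitude. $\alpha$ captures risk attitude through outcome-magnitude
curvature; $\beta$ discounts the probability linearly in the occluded
fraction and captures ambiguity attitude. Choice follows a softmax in the
subjective-value difference with noise $\gamma \ge 0$.

**Sign conventions.** Internally, loss-domain subjective values are
negative (a sure \$5 loss has $SV = -5^{\alpha}$), and the lottery-choice
probability is $1/(1 + e^{-\gamma(SV_L - SV_C)})$, so that higher-valued
options are always preferred more often. Printed versions of this softmax
sometimes carry the opposite exponent sign together with unsigned loss
magnitudes; these conventions agree domain-by-domain, and the signed
representation used here extends coherently across domains (it also
matches how loss subjective values enter the value GLM: positive for
gains, negative for losses). Fitted attitudes are reported on a common
scale where negative means averse: $\alpha_{gain}-1$, $1-\alpha_{loss}$,
$-\beta_{gain}$, $\beta_{loss}$.

**Fitting.** `fit_subject_domain()` minimizes the exact negative
log-likelihood (numerically stable log1p-exp form) separately per domain,
with one $\gamma$ shared across risky and ambiguous trials of the domain.
Bounds regularize the search: $\alpha \in [0.0894, 4.34]$ (symmetric in
log space around 1), $\beta \in [-4, 4]$, $\gamma \in [0, 20]$ on the
raw-dollar SV scale. Twenty L-BFGS-B starts are drawn from a seeded Latin
hypercube (the $\gamma$ coordinate is squared before scaling so small
noise values are explored densely); ties are broken by the
lexicographically smallest parameter vector, which makes refits
bit-reproducible. A likelihood-ratio comparison against the pure-noise
model ($\gamma = 0$, every choice at probability one half) flags fits in
which the choices carry no recoverable value signal; this matters because
$\alpha$ and $\beta$ are unidentifiable when $\gamma \to 0$. BIC is
$2\,\mathrm{NLL} + 3\ln n$.

**Quality control.** Twelve catch trials pit the sure \$5 against a
lottery over exactly \$5. In gains the sure option dominates; in losses a
chance of losing \$5 weakly dominates the sure loss, so choosing the sure
loss is the inferior response there — mirroring the gain-domain logic.
Subjects choosing inferior options on strictly more than half of the
responded catch trials fail QC.

## The task design and schedule

The design is the full factorial: per domain, (3 risk levels + 3
ambiguity levels) x 20 magnitudes = 120 unique trials, 240 in total.
Eight single-domain blocks of 30 trials run over two sessions in one of
two counterbalance orders. The within-block composition is not dictated
by the factorial; we stratify each domain's trials so every block holds
15 risky and 15 ambiguous trials spanning the magnitude range (dealt
round-robin by sorted magnitude, then shuffled under the seed). This
keeps subjective-value variance comparable across blocks — an implicit
assumption of the per-block z-normalization in the GLM stage. Each trial
occupies 6 s of display, a 3.5-s response window, and a 4/6/8-s jittered
ITI; unused response-window time is folded into the ITI, so trial onsets
are fixed at scheduling time. One block is one scan run (TR = 1 s), with
16 s of rest appended to capture the hemodynamic tail of the last trial.

## The synthetic cohort

`sample_population()` draws, per subject, a latent diagnostic class
(prevalence 19/48, grouped by a CAPS cutoff of 40), a clinical profile,
generative model parameters, and a neural encoding specification. Design
choices worth knowing:

* **Clinical profile.** One severity factor drives CAPS (split into its
  five symptom factors near their empirical proportions, with the total
  equal to the factor sum), PCL-5, depression, anxiety, and dissociation
  scores; combat exposure and childhood trauma load weakly, so a PCA of
  the battery yields a dominant general-severity component plus distinct
  exposure components — making the PCA stage meaningfully testable. All
  scores are clamped to instrument ranges.
* **Priors.** $\alpha$ is log-normal per domain (gains centered at 0.85,
  losses at 0.95), $\beta$ normal (gains centered at 0.25, losses at 0),
  $\gamma$ log-normal with median 1.0 and sdlog 0.5. The $\gamma$ median
  was calibrated so that separate per-session refits of simulated
  choices reproduce the day-to-day attitude consistency reported for
  this task (rank correlation near 0.7 for risk attitudes from 60-trial
  fits); lower medians produce subjects far noisier than real ones.
* **Symptom-behavior couplings.** Severity lowers log $\alpha_{gain}$
  and $\beta_{loss}$ with slopes (0.14 each) Monte-Carlo calibrated over
  300 cohorts of n = 57 so the generator reproduces the reported
  associations (Spearman rho of about -0.39 for risk attitude in gains
  and -0.30 for ambiguity attitude in losses).
* **Neural encoding.** Controls carry a monotonic *value* code: the
  trial-wise modulation of the ROI response follows the per-block
  z-scored signed SV. PTSD-class subjects carry a U-shaped *saliency*
  code following z-scored |SV|. Amplitudes default to 0.3 percent signal
  change per z-unit with a between-subject SD of 0.15, white noise SD
  1.0, slow cosine drift, and leakage from six random-walk motion-like
  nuisance series. These defaults make the group dissociation detectable
  in nearly every 48-subject cohort — stronger than a typical empirical
  effect, which is appropriate for a validation generator whose job is
  to make pipeline errors visible, not to emulate marginal power.

The forward neural model is built with exactly the same
microtime/HRF machinery as the estimation design matrices, so noiseless
simulations are recovered to machine precision when the estimation
design matches the generative one. What the generator does *not*
emulate: temporal autocorrelation of BOLD noise (the high-pass filtering
and AR modeling of real pipelines are out of scope), physiological
noise, motion spikes, and voxelwise spatial structure. Passing tests
therefore validate the analysis logic, not robustness to every artifact
of real scanner data.

## First-level GLMs

The five variants mirror standard parametric-modulation analysis:
condition box-cars of 6 s; signed-SV modulators (glm2 per
condition-by-domain, glm3 across domains); unsigned |SV| modulators
(glm4); and 12 SV-bin predictors (glm5: 2 uncertainty x 2 domain x 3
equal-count bins, ranked within subject, ties broken by trial id,
remainders to lower bins). Numerical choices:

* Modulators are z-normalized with the sample (n-1) SD within block x
  uncertainty cells; degenerate cells map to zero with a warning.
* The normalized modulator is multiplied into the box-car *before*
  convolution (the standard event-related convention; the alternative
  order is not distinguishable at these trial durations but changes
  betas slightly).
* Regressors are built on a 0.1-s microtime grid, convolved with a
  peak-normalized double-gamma HRF (peak 6 s, undershoot 16 s, ratio
  6:1) via zero-padded FFT, and sampled at the 1-s TR grid.
* Modulators are *not* orthogonalized against their condition box-cars;
  z-normalization already removes the mean, and silent orthogonalization
  would change the interpretation of condition betas.
* Estimation is plain OLS over concatenated runs with per-run
  intercepts and six motion nuisance columns; all-zero columns are
  dropped and reported, and rank deficiency is an error that names the
  offending columns.

Because every block holds a single domain, the glm3 (signed) and glm4
(unsigned) modulators are identical within gain blocks and sign-flipped
within loss blocks. The two codes are therefore distinguishable exactly
where they should be — in the loss domain — and a pure-value signal
projects onto the saliency regressor only through hemodynamic edge
effects (a few percent at most in the noiseless closed loop).

A consequence of per-block z-normalization worth flagging: in the glm5
bin profile, the mean normalized SV of the *worst gains* bin is negative
while that of the *best losses* bin is positive, so a pure value code
yields a profile that increases within the loss triplet and within the
gain triplet but resets at the loss-gain boundary. The saliency code
yields a global U-shape. This matches the arithmetic of the published
bin means and is what `make_report()` visualizes.

## Group inference

* Correlations with symptoms use Spearman's rank correlation for CAPS
  and Pearson's correlation for PCL-5 and principal-component scores.
* Covariate-adjusted symptom effects use a linear model with dummy-coded
  income and education bands, testing the symptom term by a full-versus-
  reduced partial F (type-II style; the sums-of-squares type is not
  dictated by the design, and type II avoids order dependence).
* The value/saliency group analysis runs four one-sample t tests
  (signal x group) with Benjamini-Hochberg FDR across the four, plus a
  Welch two-sample test on saliency betas — Welch because the group
  variances cannot be assumed equal (and fractional degrees of freedom
  are the signature of that choice).
* Exhaustive best-subset regression enumerates all $2^p - 1$ non-empty
  predictor subsets (refusing $p > 15$) and ranks them by the Gaussian
  OLS form $n \ln(\mathrm{RSS}/n) + (k+1)\ln n$. Other BIC constants
  shift all models equally and cannot change the ranking, but do change
  printed values; the convention is stated so tables are reproducible.

**A known property of BIC subset selection.** When an outcome is
generated from exactly one of seven correlated candidates, the
minimum-BIC model at n = 48 includes a *spurious extra* predictor
whenever that predictor's chance deviance improvement (a chi-square with
1 df) exceeds $\ln 48 \approx 3.87$, which happens with probability
about 0.05 per candidate — so the single-predictor model wins only about
$0.95^6 \approx 74\%$ of replicates, independent of the noise scale. The
replicated study `numbing_subset_study()` measures exactly this rate
(the true generative predictor is itself virtually always included). This
is a property of the criterion at this sample size, not an implementation
artifact; expectations of near-certain single-predictor recovery at
n = 48 are not statistically attainable.

## Problem sizes and reproducibility

The packaged simulation studies use the study's natural sizes: 50
subjects x 120 trials for parameter recovery, 20 replicates of
48-subject cohorts (29 value-coding controls, 19 saliency-coding PTSD)
for the encoding dissociation, 100 replicates for the subset-selection
study, and 1000 Monte-Carlo draws for type-I error calibration. All
randomness flows from explicit integer seeds split deterministically per
stage and subject; rerunning any study or the full `run_pipeline()` with
the same configuration is bit-reproducible.

## Limitations

Beyond the noise-model simplifications above: the package performs ROI
time-series analysis only (no voxelwise maps, spatial smoothing, or
cluster inference); it fits the single published utility family (no
probability weighting or hierarchical pooling); and the synthetic
cohort's effect sizes are set for pipeline validation, so absolute
statistic magnitudes from synthetic runs should not be read as empirical
predictions.
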