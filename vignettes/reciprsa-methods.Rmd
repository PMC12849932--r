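---
title: "Models and methods behind reciprsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reciprsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models the package implements, the
generative models its synthetic-data module uses, the numerical choices that
affect published numbers, and the design decisions taken where the problem
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The task and its arithmetic

Participants endowed with 25 yuan repeatedly choose which of two benefactors
— one perceived as altruistic, one as strategic — to repay, and how much to
allocate (0–25, integer). Both benefactors spent the same cost
(9 levels, 4–20 yuan) to reduce the participant's pain stimulation
(0.8 s per yuan, capped at 16 s). Reciprocal efficiency multiplies the
allocation by 1 or 3 before it reaches the benefactor, in three conditions:
A1S3 (altruistic ×1, strategic ×3), A1S1 (×1, ×1), A3S1 (×3, ×1). A run
contains each of the 27 condition × cost cells exactly once in randomized
order; the default design has 3 runs. The randomization is an unconstrained
within-run permutation: no constraint (e.g. against immediate condition
repeats) is documented for the paradigm, so none is imposed.

Two derived quantities carry the analysis:

* relative weight of Communal Concern
  $= |\beta_c| \,/\, (|\beta_c| + |\beta_o|)$, where $\beta_c, \beta_o$ are a
  participant's condition-wise choice-regression coefficients on the communal
  and obligation factor contrasts. The ratio is sign-blind and lies in
  $[0,1]$; it is undefined (returned as missing and excluded listwise) when
  both coefficients are exactly zero.
* Relative Self-payoff
  $= (E - a) \,/\, ((E - a) + e \cdot a)$ for allocation $a$, efficiency $e$,
  endowment $E$: strictly decreasing in both $a$ and $e$.

## 2. Behavioral stage

**Factor scoring.** The rating battery names a confirmatory two-factor
structure: communal = {perceived care, gratitude, guilt}, obligation =
{second-order belief, sense of obligation}, cross-loadings zero,
indebtedness excluded. The estimator is deliberately dependency-light: each
factor is the first principal axis of its block's *correlation* matrix,
giving scores that are invariant to affine rescaling of any variable
(second-order belief is collected on 0–25 and rescaled ×4; the scores do not
depend on that choice). Variance explained is the sum of the two blocks'
leading eigenvalues over the five standardized variables; on the default
generator it lands near the ~75% such batteries typically report. The
estimator, rotation and factor correlation of the original analysis are not
documented; this fixed-structure block-PCA honors the confirmatory pattern
while remaining exactly reproducible.

**Choice regressions.** Per condition, choice (altruistic = 1) is regressed
on the altruistic-minus-strategic factor contrasts with by-participant random
slopes. The link is logistic by default (the published description,
"predicting the probability", does not fix a link; a linear-probability mode
is available via `link = "linear"`). Per-participant coefficients are
conditional modes (fixed effect + random slope) — partial pooling means a
participant with all-identical choices in a condition still gets a finite,
shrunken coefficient rather than a separation failure. Singular fits fall
back from correlated to uncorrelated random slopes to a random intercept,
and the structure used is recorded per condition. For speed the
`lme4::glmer` fits use `nAGQ = 0`; at the package's scales this
approximation does not disturb the coefficient *ratios* the relative weight
depends on (the recovery tests pass 20/20 at default noise). A fully
independent per-participant mode (`method = "independent"`) exists for
sensitivity checks.

**Repeated-measures battery.** The one-way RM-ANOVA reports F with
Greenhouse–Geisser correction: $\hat\varepsilon$ from the double-centered
sample covariance, bounded to $[1/(k-1), 1]$, scaling both dfs (so the
corrected p can never undercut the uncorrected one). The linear trend uses
the $(-1, 0, +1)$ contrast; the reported estimate is *half* the mean
contrast score, i.e. the slope per condition step (matching the convention
in which a trend coefficient of ~0.012 accompanies an end-to-end mean
difference of ~0.025). When the contrast scores have zero variance the
statistic is reported as an exact trend (F = Inf, p = 0) with an explicit
note rather than a division error. Mann–Whitney U reports the tie-corrected
normal Z and an exact p (null U distribution) when the samples are tie-free
and moderate; Relative Self-payoff comparisons are run on participant-level
means (each participant contributes one value per condition, unpaired, since
qualifying-trial counts differ by condition); a trial-pooled mode would be a
one-line change but participant-level is the default and the tested path.

## 3. Neural expression stage

Expression is the plain dot product of a condition map with a motive weight
map over finite voxels (pairwise exclusion, failing above 5% non-finite).
Min-max normalization is applied per map across all participants ×
conditions ("global" scope): the grouping is not documented in the source
analysis; global scope preserves between-participant ordering and avoids the
per-participant degenerate case in which every participant's minimum
condition is forced to exactly 0, which would distort the ratio. A
per-participant scope ships behind `scope = "participant"` and is recorded
in the output's attributes. The neural relative weight applies the same
sign-blind ratio as the behavioral statistic; 0/0 cells are missing and
excluded with a logged count.

The permutation test permutes the three condition labels independently
within each participant (the exchangeability the design justifies),
recomputing the RM-ANOVA F and the linear-contrast coefficient per
iteration; default 10,000 iterations. The empirical p is the one-tailed
exceedance proportion with ties counted (`>=`), so p is never an
unattainable zero when the observed value recurs under the null; a reported
0 means "below 1/n_perm resolution". Exceedance is evaluated with a ~1e-8
relative tolerance so permutations equivalent to the observed labeling up to
float rounding (e.g. a common relabeling of all participants) count as ties
— without it, the empirical p would depend on the order of floating-point
summation. With 6 or fewer participants the test enumerates all $6^n$
assignments exactly instead of sampling.

## 4. RSA stage

Cognitive RDMs assign each of the 27 cells its condition's code — general
(3,1,3), altruistic (1,1,3), strategic (3,1,1), linear (1,2,3) — and use the
absolute code difference as cell dissimilarity. Cost levels inherit their
condition's code, so within-condition pairs are 0-dissimilar and anchor the
regression intercept. Absolute difference reproduces exactly the
similar/dissimilar structure the codings describe; a binary same/different
mode is provided and is proportional to the default for the three two-valued
codings, differing only for the linear model.

Neural RDMs are 1 − Pearson over a parcel's voxel vectors; parcels with a
zero-variance condition pattern are skipped with a warning and listed in the
output's `skipped` attribute (no imputation). Lower triangles are flattened
in the fixed column-of-lower-triangle order ((2,1), (3,1), …), shared by
neural and cognitive vectors.

**Mixed-effects RDM regression.** Each parcel's per-participant
dissimilarity vectors are regressed on one cognitive vector with a random
intercept per participant; Z = slope/SE against a normal reference (matching
the Z-statistics such analyses report; a Satterthwaite-df variant would
change little at these sizes and is not implemented). Because the design is
balanced and every participant shares the same predictor vector, the REML
solution is closed-form: the GLS slope equals the within-participant
least-squares slope and its variance involves only the residual variance.
The default engine uses this closed form (~1000× faster than refitting
`lmer` per parcel, which makes the 200-parcel × 4-model × 20-replicate
recovery runs tractable); `engine = "lmer"` fits the identical model with
lme4 and a unit test asserts numerical agreement of the two routes. A
singular lme4 fit falls back to pooled OLS with participant fixed effects,
which the balanced closed form coincides with when the intercept variance
estimate is non-positive.

FDR is Benjamini–Hochberg per cognitive model across parcels (two-tailed,
α = 0.05). Whether the original correction pooled models × parcels is
undocumented; per-model matches the "each model fit separately" description
and is the default. ROI mode treats each named mask as one parcel and FDRs
across the ROI set.

**Correlated codings.** The four models are distinguishable (no pair of
lower-triangle vectors correlates at 1) but not orthogonal: linear correlates
with altruistic and with strategic at r ≈ 0.73; the remaining pairs sit near
0.07. A parcel genuinely representing the linear geometry therefore has a
truly nonzero regression slope on the altruistic model, and separate fits
will (correctly) flag it. Consequently the recovery criteria count
*sensitivity* over each model's own planted parcels, and *false discoveries*
over parcels with no planted structure at all; cross-model flags among
correlated codings are true associations, not errors of the procedure. Users
comparing models should interpret per-model maps jointly, exactly as one
would with any correlated model RDMs.

## 5. The synthetic generator: what it emulates, what it does not

The study being emulated is empirical — it has no generative model of
behavior — so the generator is the package's own stand-in, built so each
stage's estimand exists by construction:

* **Ratings** follow cell means with an altruistic-vs-strategic gap per
  variable (communal variables higher for the altruistic benefactor,
  belief/obligation higher for the strategic one), gaps growing linearly
  with cost, plus a participant-level response bias (SD 5, shared across
  benefactor types, hence cancelling from all contrasts), a common cost
  drift (1 point/yuan), iid noise (SD 8) and clamping to [0, 100].
  Indebtedness is a noisy mean of guilt and obligation and is never
  factored. Defaults (gaps 20/20/15 points at the mean cost, slope 0.5/yuan)
  produce rating tables a rater of this paradigm would find unremarkable.
* **Choices** are logistic:
  $P(\text{altruistic}) = \text{logit}^{-1}(w_c[\text{cond}]\,\Delta PC_c -
  w_o[\text{cond}]\,\Delta PC_o + \varepsilon)$, with the factor contrasts
  computed by the *analysis* module's own scoring of the generated ratings —
  so behavioral recovery exercises the full ratings → factors → regression
  path. Default planted weights (0.5:3, 1.5:1.5, 3:0.5 across A1S3, A1S1,
  A3S1) encode the strictly increasing communal dominance the analysis must
  recover. Allocations are generosity × 25 plus bounded integer noise.
* **Neural maps**: each participant-condition voxel vector is
  $a[\text{cond}]\,m_c + b[\text{cond}]\,m_o + \text{parcel signals} +
  \mathcal N(0, \sigma^2)$. The motive maps $m_c, m_o$ are constructed
  orthonormal so the planted $(a, b)$ are *exactly* identifiable by dot
  products at zero noise — real trained weight maps are not orthogonal; this
  is a fixture convenience, and expression values on correlated real maps
  would share variance accordingly. Each signal parcel owns two basis
  vectors orthogonalized against the constant vector and both motive maps;
  the condition pattern rotates through an angle proportional to the
  parcel's model code, making the zero-noise parcel RDM
  $1 - \cos(\Delta\phi)$ — an exact monotone transform of the cognitive RDM.
  (A pattern merely *scaled* by the code would have correlation ±1 between
  all conditions and a degenerate RDM; the rotation construction is what
  makes the planted geometry recoverable by a correlation-distance RDM.)
  Parcels are contiguous voxel blocks; no anatomy, HRF, autocorrelation or
  realistic noise spectra are simulated. Defaults — 200 parcels × 50 voxels,
  amplitude 1, noise SD 1 — were fixed once from a pilot at that scale:
  own-parcel Z lands around 7–11, in the range parcel-wise mixed-model RSA
  reports, and post-FDR recovery holds with margin.
* **Seeds** fan out from one master seed through named child streams
  (`child_seed(seed, "ratings")`, …), so any component can be regenerated
  independently and byte-identically.

A green recovery test therefore establishes that the *pipeline* recovers
structure the generator planted under idealized geometry — not that the
method would behave identically on real fMRI data with spatial noise
correlation, non-orthogonal weight maps, or anatomical parcellations.

One caveat the tests make explicit: because the condition-varying motive
loadings $(a,b)$ live on *global* maps, every parcel inherits a weak but
participant-consistent condition structure from them. At the default scale
(10,000 voxels) this footprint stays below the FDR threshold, but at small
fixture scales it is detectable; calibration simulations (type-I error, p
uniformity) therefore use a generator with constant loadings and zero
amplitude, which is the actual null hypothesis of those tests.

## 6. Numerical choices

* GG epsilon bounded to $[1/(k-1), 1]$; F = 0 reported when all columns are
  identical rather than NaN.
* Correlation-distance RDM entries clipped at 0 against −1e-17 rounding.
* Permutation exceedance uses the float-tolerant tie rule of §3.
* `relative_weight` and `neural_relative_weight` return missing on the 0/0
  case; downstream ANOVAs drop such rows listwise and report the count.
* The trial parser rejects unknown cost levels and condition labels outright
  (no binning); missing choices are explicit missing values, excluded from
  every statistic, and an allocation without a choice is an error.
* All RNG is scoped: every stochastic function restores the caller's
  `.Random.seed` on exit.

## 7. Known limitations

* No NIfTI reader/writer: volumes are numeric matrices plus a parcellation
  vector; delimited-text serialization is provided at reduced scales. The
  analysis chain is agnostic to how voxels were ordered, so adapting to a
  NIfTI-backed workflow means flattening volumes in any fixed order.
* No searchlight mode, no cross-validated distance estimators, no spatial
  cluster correction, and no training of motive weight maps — pattern maps
  are inputs.
* The behavioral generator's logistic choice model is a stand-in, not an
  estimate of any real population; its parameters are a stated world for
  verification, not empirical claims.
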