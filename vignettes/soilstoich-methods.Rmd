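---
title: "Methods: quantifying four-decade changes in cropland soil C:N:P stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying four-decade changes in cropland soil C:N:P stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Legacy soil surveys describe profiles by *genetic horizons* — layers
delineated by pedogenic features, with one measurement per horizon of
variable thickness. Modern resampling campaigns measure fixed depth
intervals (here 0–20, 20–40, 40–60 and 60–100 cm). Comparing elemental
stoichiometry between the two eras therefore requires (i) harmonizing
horizon data to the fixed layers, (ii) quantifying the uncertainty that
this conversion introduces, and (iii) relating the estimated changes to
four decades of management and climate forcing. `soilstoich` implements
this chain and a synthetic-data generator with known ground truth so
that every stage can be validated without field data.

## Depth harmonization

Each element (SOC, TN, TP) of a legacy profile is fitted against horizon
midpoint depth with four candidate forms,

* linear: $c = a + b\,d$
* logarithmic: $c = a + b\ln d$
* exponential: $c = a e^{b d}$
* power: $c = a d^{b}$,

the measured horizon value being taken to represent the concentration at
the horizon midpoint. The exponential and power forms are
log-linearized, solved by closed-form least squares and back-transformed;
every candidate reports $R^2 = 1 - SSE/SST$ **on the original
concentration scale**, so the selection rule — highest $R^2$ — compares
like with like. Exact ties (e.g. constant profiles) are broken by a fixed
precedence linear > logarithmic > exponential > power, the simplest and
most numerically stable form first. The selected function is evaluated at
the four layer midpoints (10, 30, 50, 80 cm); predictions below a floor
of 0.01 g/kg are clamped and flagged, because molar ratios require
strictly positive values. Profiles with two usable horizons fall back to
the linear form, and a single horizon yields constant extrapolation; both
are flagged.

Two known properties of this estimator matter for interpretation. First,
log-linearization is deterministic and reproducible, but with additive
measurement noise the back-transformed prediction is biased low by
roughly $\mathrm{CV}^2/2$ (the Jensen gap between $E[\ln y]$ and
$\ln E[y]$), which in turn biases *relative changes against the legacy
baseline* upward where concentrations are small relative to the noise —
chiefly the 60–100 cm layer. A smearing-type retransformation could
reduce this, but would abandon the plain back-transform that defines the
method here, so it is not applied. Second, extrapolated exponential fits
at 80 cm occasionally collapse to the concentration floor under
resampled noise, producing heavy right tails in deep-layer change
replicates; the percentile CI absorbs these without failing.

## Conversion uncertainty: residual bootstrap and boundary perturbation

Within each profile, residuals of the selected regression (original
scale) are resampled with replacement, added back to the fitted values
at the original horizon midpoints, the originally selected form is
refitted, and the layer midpoints re-predicted (B = 1000 by default; the
replicate matrix is deterministic given a seed). Residuals are first
inflated by $\sqrt{n/(n-2)}$, correcting the variance deflation of
regression residuals. Re-running model *selection* per replicate is
available (`reselect = TRUE`) but off by default: the uncertainty read
here is conditional on the chosen form.

Only the legacy era is bootstrapped. Modern fixed-depth values are
treated as fixed: each is a composite of 21 subsamples per layer
(7 profiles × 3 plots), so its sampling error is an order of magnitude
smaller than a single legacy horizon measurement, and the target of the
analysis is specifically the horizon-to-layer conversion.

Per replicate, site-level relative changes (%) of molar C:N, C:P and N:P
against the fixed modern values are computed and averaged across sites,
giving the sampling distribution of the mean change. Reported per layer
and ratio: the mean, the percentile 95% CI, and *directional stability* —
the percentage of replicates whose mean change shares the sign of the
point estimate.

A calibration caveat, measured by this package's own acceptance
experiment: on linear-truth profiles with 4–7 horizons the percentile CI
covers the true layer value in only ≈79% of profiles, not 95%. The loss
is structural to the prescribed scheme — resampling n ≤ 7 residual atoms
truncates tails, and the spread of each profile's replicates scales with
that profile's $\hat\sigma$, whose randomness at $n-2$ degrees of
freedom a percentile interval cannot reflect (the ceiling is roughly
$P(|T_{n-2}| < 1.96)$). Bootstrap-t or parametric-residual intervals
would calibrate better but are different procedures; users should read
the CIs as conversion-uncertainty bands conditional on the fitted model,
not as exact frequentist intervals.

Boundary sensitivity shifts every internal horizon boundary by ±2 cm
(outer 0/100 cm fixed, thickness kept ≥ 1 cm), recomputes midpoints,
refits and re-predicts. The reported `boundary_delta` is the largest
absolute change of the target statistic over the two scenarios; divided
by the bootstrap CI half-width it yields a qualitative flag (negligible
< 0.5, moderate < 1, substantial otherwise — thresholds chosen here, as
only the qualitative reading is standard).

## Stoichiometry, changes, and equivalent soil mass

Mass concentrations convert to molar ratios with IUPAC atomic masses
(12.011, 14.007, 30.974 g/mol; integer masses are available for exact
arithmetic in tests), so $C{:}P = C{:}N \times N{:}P$ holds identically.
Absolute change is the plain era difference; relative change is
$(X_{2023}-X_{1980s})/X_{1980s} \times 100$, and Δ-quantities always
denote relative changes. The relative changes obey the composition
identity $(1+\Delta_{C:P}/100) = (1+\Delta_{C:N}/100)(1+\Delta_{N:P}/100)$,
which the pipeline verifies end to end.

Fixed-depth stock comparisons conflate concentration change with bulk
density change. The equivalent-soil-mass (ESM) correction accumulates
soil mass and element mass over the layers (piecewise linear), then
evaluates the non-reference era's cumulative element mass at the
reference era's layer-boundary soil masses by monotone linear
interpolation (linear extrapolation beyond the profile). The reference
defaults to the legacy era; `"modern"` and `"lighter"` are selectable
since the ESM literature admits any common mass basis. When bulk density
is era-invariant, ESM layer masses equal fixed-depth masses exactly.

Whole-profile ratios default to mass-weighted pooling of element masses
(concentration × BD × thickness) before forming ratios;
thickness-weighted and mean-of-layer-ratios modes are provided because
the aggregation rule behind published whole-profile means is typically
unstated.

## Input and climate accounting

Annual element inputs follow the standard yield-coefficient budget.
Straw: $Y_{straw} f_{return} (1-W) X_s/1000$ with moisture $W = 0.14$
and straw C concentrations 399/444/418 g/kg for wheat/maize/rice. Crop
residues combine root biomass $(Y_{grain}+Y_{straw}) R_r R_b$ (root:
aboveground ratios 0.30/0.26/0.30; topsoil root fractions 0.753 wheat,
0.851 maize — unavailable for rice, default 1.0 and configurable) and
stubble $Y_{straw} S_r$ (0.15/0.03/0.056). The published residue formula
applies the moisture-and-concentration factor only to the stubble term,
which is dimensionally incoherent (the root term would enter as raw
biomass); the default `"corrected"` mode applies $(1-W) X_s/1000$ to the
whole residue biomass, and a `"literal"` mode evaluates the printed form
for audit. Manure: $X_m (1-W) \cdot \text{Weight}/1000$ on a dry-matter
concentration basis. Mineral N and P add directly (with an optional
P₂O₅→P factor 0.4364). Straw N and P concentrations have no printed
national values; package defaults (6.5/9.2/9.1 and 0.8/1.5/1.3 g/kg) are
literature-typical and should be overridden with regional data.
Cumulative inputs are plain sums over the ledger years.

Climate covariates per site: annual MAT/MAP from monthly series (MAP is
the mean monthly value by convention here, with an annual-total option),
accumulated temperature and precipitation AT = ΣMAT, AP = ΣMAP over the
study years (a literal audit mode reproduces the variant that sums
temperature for both), temperature seasonality (Bio4, 100 × sample SD of
the monthly climatology), precipitation seasonality (Bio15, CV% of
monthly precipitation), and the relative AET change between the
1981–1985 and 2019–2023 window means.

## Driver attribution

Predictors (cumulative C/N/P inputs; AT, AP, ΔAET, Bio4, Bio15; pH,
sand, clay, baseline ratio) are screened for multicollinearity by
iterative VIF removal ($VIF_j = 1/(1-R^2_j)$, threshold 5, largest
first, exact collinearity treated as infinite). A regression random
forest (500 trees, `randomForest` defaults) reports mean decrease in
impurity and unscaled permutation importance (OOB MSE increase), with
significance from a response-permutation null: the forest is refitted on
100 permutations of the response and
$p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$, never exactly zero.
Permuting predictors instead is available; the response scheme is the
default because it tests the joint null of no association while keeping
the predictor correlation structure intact. Importances are normalized
to sum to one. Model quality: OOB $R^2$, RMSE, RMSE/range and RMSE/SD.

Partial correlations residualize both variables on the confounders by
OLS and correlate the residuals; with no confounders this is exactly
Pearson, and p-values use $t = r\sqrt{(n-2-k)/(1-r^2)}$ on $n-2-k$ df.
Baseline dependence is summarized by $\Delta = a + b \ln(x_{1980s})$;
when the relationship declines ($b<0$, $a>0$) and the zero crossing
$x^* = e^{-a/b}$ falls within the observed baseline range, $x^*$ is the
threshold separating soils predicted to increase from those predicted to
decrease. Layer (and zone/order/material) contrasts use one-way ANOVA
with Tukey HSD at α = 0.05 and an insert–absorb compact letter display
ordered by descending group mean.

## The synthetic generator and what it does (not) show

The generator emulates the sampling design: per site, a legacy profile
with 4–7 contiguous genetic horizons tiling 0–100 cm (stick-breaking
with minimum thickness 8 cm, so ±2 cm perturbations never invert a
boundary) and a modern profile at the four standard layers. The 1980s
truth uses exponential SOC (a = 16 g/kg, b = −0.025) and TN (1.35,
−0.02) and near-uniform linear TP (0.68, −0.0015), with a per-site
lognormal jitter (CV 0.15) on the scale parameters. The era effect is a
depth-dependent multiplicative field: SOC × (1.54 − 0.0102(d−10)),
TN × 1.25, TP × 1.10, planting a C:P change of +40% at 10 cm declining
to −25% at 80 cm — the topsoil-enrichment / subsoil-divergence pattern
typical of intensively fertilized croplands. Measurement noise is
additive Gaussian (SD 0.6/0.06/0.03 g/kg for SOC/TN/TP), floored at
0.01 g/kg; modern composite samples carry noise reduced by
$1/\sqrt{21}$, reflecting 7 pooled subsamples × 3 averaged plots. Bulk
density is drawn once per site and era from U(1.1, 1.6) g/cm³, constant
over depth, to isolate ESM behaviour. Management ledgers reproduce the
secular intensification of Chinese cropland (yields ×2.5 over
1980–2023, straw return rising 0.15→0.85, mineral N 60→220 kg/ha),
and climate series are seasonal sinusoids with noise. RNG streams are
split per site and component, so adding sites never perturbs existing
ones.

Passing tests on these data show that the *pipeline arithmetic and
algorithms* behave as specified under a known truth. They do not show
that real legacy surveys satisfy the generator's assumptions: real
measurement error is not additive-Gaussian or depth-constant, genetic
horizons correlate with pedogenesis rather than random sticks, era
effects are not multiplicatively smooth, and modern/legacy georeferences
carry relocation error the generator omits entirely.

## Numerical choices and problem sizes

Concentration floor 0.01 g/kg; degenerate (zero-variance) profiles get
an exact constant fit with $R^2$ defined as 1 for the linear form;
boundary shifts are truncated to preserve 1 cm thickness; replicate
ratios with non-positive legacy values are excluded and counted. The
validation suite exercises: a 100-site end-to-end run with B = 1000; CI
calibration on 500 linear-truth profiles with B = 400; 20-seed forest
ranking with 100-permutation nulls; 10⁴-record identity checks — sizes
chosen to estimate the relevant rates with useful precision while a
full run of the suite stays comfortably interactive.

## Known limitations

Percentile CIs from few-horizon profiles under-cover (measured ≈79% at
nominal 95%, see above); deep-layer relative changes carry the
log-linearization bias; the bootstrap ignores modern-era sampling error
by design; PLS-PM-style latent path modeling and geostatistical mapping
are out of scope; and the crop N/P straw concentrations are
user-supplied defaults, not survey values.
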