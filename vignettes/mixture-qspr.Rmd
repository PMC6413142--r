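---
title: "Mixture QSPR modelling of lower flammability limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture QSPR modelling of lower flammability limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixlfl)
```

## The problem

The lower flammability limit (LFL) of a fuel gas is the smallest
volume-percent concentration in air that can propagate a flame; it is the
first number a process-safety engineer asks for when a new gas blend is
proposed. Measured LFLs exist for common pure gases, but blends are
effectively unbounded in number, and measuring each composition is
impractical. Quantitative structure-property relationship (QSPR) modelling
replaces measurement with a regression from molecular structure: each pure
component is described by numerical molecular descriptors, the two
component descriptor vectors are merged into *mixture descriptors* using
the mole fractions, and a linear model maps those mixture descriptors to
the LFL in vol%.

`mixlfl` implements this workflow end to end for binary hydrocarbon gas
mixtures: native computation of the six descriptors used by the published
best model, the twelve standard binary mixing rules, genetic-algorithm
multiple linear regression (GA-MLR) descriptor selection, the standard
internal/external validation statistics, Y-randomization, and a
leverage-based applicability domain. A frozen copy of the published
six-descriptor model is included as a ready-to-use predictor.

## The descriptors

Six descriptors enter the frozen model. All are computed on the
hydrogen-suppressed heavy-atom graph parsed from SMILES.

* **RBN** — number of rotatable bonds: single, non-ring bonds whose two
  endpoints both have heavy-atom degree at least two. The conjugated
  central bond of 1,3-butadiene counts; every bond of isobutane touches a
  terminal methyl and does not.
* **MAXDP** — maximal electrotopological positive variation. Each atom
  carries a Kier–Hall intrinsic state
  $I = \left[(2/L)^2 \delta_v + 1\right] / \delta$, with $\delta$ the
  heavy-atom degree, $\delta_v$ the valence electron count minus attached
  hydrogens, and $L$ the principal quantum number. The field perturbation
  of atom $i$ is $\Delta I_i = \sum_{j \ne i} (I_i - I_j)/(d_{ij}+1)^2$
  over topological distances $d_{ij}$; MAXDP is the largest positive
  $\Delta I_i$ (0 if none).
* **Psi_i_0** — intrinsic-state pseudoconnectivity of type 0:
  $\sum_i I_i^{-1/2}$.
* **SpMax4_Bh(e)** — fourth-largest eigenvalue of the Burden matrix with
  Sanderson electronegativities (relative to carbon) on the diagonal and
  $0.1\sqrt{\text{bond order}}$ (0.001 for non-bonded pairs) off the
  diagonal.
* **Mor24u / Mor16m** — 3D-MoRSE signals
  $\mathrm{Mor}(s) = \sum_{i<j} w_i w_j \sin(s\,r_{ij})/(s\,r_{ij})$ over
  heavy-atom 3D distances, with Mor$k$ evaluated at $s = k - 1$
  Å$^{-1}$ and the $s = 0$ term defined as $w_i w_j$. Weights are 1
  (unweighted, "u") or atomic mass relative to carbon ("m").

### Conventions for degenerate cases

Methane is part of the dataset, so the single-heavy-atom case must be
well defined: $\delta$ is replaced by $\max(\delta, 1)$ in the intrinsic
state (giving $I = 1$, the convention of the common open descriptor
engines), MAXDP and every MoRSE signal of a one-atom graph are 0, and
SpMax$k$ returns 0 whenever the molecule has fewer than $k$ heavy atoms.
These paddings keep all six descriptors total functions on the dataset.

Because every heavy atom in the ten dataset hydrocarbons is carbon, the
relative electronegativity and mass weights are exactly 1 there: the
Burden diagonal is the identity and Mor16m coincides with the unweighted
Mor16 on the heavy-atom convention. The element tables nevertheless carry
H, B, C, N, O, F, Si, P, S, Cl, Br and I so the engines generalise.

### Geometry

The original modelling chain optimised geometries with a commercial
molecular-mechanics/semi-empirical pipeline that cannot be reproduced or
seeded. `mixlfl` instead embeds coordinates deterministically: seeded
random initial positions are relaxed under a harmonic distance force
field (bond lengths from covalent radii scaled by bond order, 1–3
distances encoding ideal sp/sp$^2$/sp$^3$ angles, and a soft repulsion
between atoms three or more bonds apart) with BFGS. The same SMILES and
seed always give bit-identical coordinates, and therefore bit-identical
MoRSE values. The resulting geometries are chemically sensible (C≡C
≈ 1.20 Å, C=C ≈ 1.33 Å, C–C ≈ 1.52 Å, near-tetrahedral sp$^3$ angles)
but not identical to the original pipeline's, so the 3D descriptors —
and hence predictions of the frozen model — carry a documented geometry
difference. For that reason the package ships a pinned descriptor table
for the ten hydrocarbons (`builtin_components()`), computed once with
this pipeline at seed 1; `recompute = TRUE` reproduces it exactly.

An independent cross-check against RDKit (rotatable bonds, E-state
perturbations, and MoRSE evaluated on the same coordinates) and an
independent Burden-matrix implementation agrees with the native engines
to better than $10^{-3}$ on all ten molecules; for the MoRSE signals the
agreement is bounded by the reference engine's three-decimal output
rounding, not by the geometry, because the coordinates are shared.

## Mixing rules and the deviation target

Twelve formulas (`mixing_rules()`) combine pure-component values $d_1,
d_2$ with mole fractions $x_1 + x_2 = 1$. Six *direct* combinations
(molar contribution, its norm, weighted difference, squared/square-root
mole-fraction variants) depend on composition and are regressed against
the LFL itself. Three *deviation* combinations are functions of
$\Delta x = |x_1 - x_2|$ and $\Delta d = |d_1 - d_2|$ — following the
mixture-QSPR literature this package defines both deltas as absolute
differences, which also guarantees component-swap symmetry — and are
regressed against the *deviation target*, the departure of the measured
LFL from the mole-weighted linear blend of the pure LFLs
(`deviation_target()`). The pairing is enforced automatically by the
rule's class tag. Three *other* combinations ignore composition
entirely; they are retained for completeness but cannot resolve
composition-dependent behaviour, and all twelve rules are symmetric
under swapping the two components.

The frozen best model uses the **norm of the molar contribution**,
$D = \sqrt{(x_1 d_1)^2 + (x_2 d_2)^2}$, and the linear form

$$\mathrm{LFL} = 2.720 - 0.567\,D_{\mathrm{RBN}} - 4.661\,D_{\mathrm{MAXDP}}
+ 0.642\,D_{\Psi} + 0.544\,D_{\mathrm{SpMax4}} - 2.056\,D_{\mathrm{Mor24u}}
- 23.689\,D_{\mathrm{Mor16m}},$$

with reported training statistics $R^2 = 0.964$, $s = 0.138$,
$F = 606.440$, $n = 145$. (The printed $F$ is not exactly recoverable
from the rounded $R^2$ — forward calculation gives about 616 — which we
treat as rounding in the source; the package never asserts it.)

## Model building

`qspr_lfl()` is the one-call fit. Internally:

1. `build_mixture_matrix()` applies one rule to every record.
2. `prefilter()` (optional) removes near-constant columns (variance
   $\le 10^{-8}$ after unit scaling — the threshold is a package default,
   chosen conservative and reproducible) and then correlated pairs
   ($|r| > 0.90$ by default), keeping from each offending pair the column
   more correlated with the response (lexicographic tie-break, so the
   result is deterministic).
3. `ga_select()` searches fixed-size subsets: tournament selection (size
   3), uniform crossover that preserves the genes both parents share,
   subset-size-preserving swap mutation, and one elite copied unchanged,
   so the best-fitness trace is non-decreasing. Fitness is the
   leave-one-out $Q^2$ of the candidate MLR model (adjusted $R^2$
   optionally). Defaults — population 100, 300 generations, crossover
   0.8, mutation 0.05, subset size 6 — follow common GA-MLR practice;
   all are exposed in `ga_control()` and the search is exactly
   reproducible from its seed. Model size is a free parameter: the CLI's
   `select --scan-size 2-8` sweeps it and keeps the best $Q^2_{LOO}$.
4. `fit_mlr()` is ordinary least squares with intercept, reporting
   $R^2$, $s = \sqrt{SS_{res}/(n-q-1)}$ and
   $F = (R^2/q)/((1-R^2)/(n-q-1))$. A constant response yields the
   convention $R^2 = 0$ with zero coefficients instead of an error;
   rank-deficient designs fail naming the collinear columns.

Descriptor importance uses the mean-effect percentages
$ME_j = \sum_i D_{ij} a_j \big/ \sum_k |\sum_i D_{ik} a_k| \times 100$,
whose absolute values total exactly 100 by construction.

## Validation

* **AAE / RMSE** in vol%, the field's standard error measures
  (AAE ≤ RMSE always).
* **$Q^2_{LOO}$** $= 1 - \mathrm{PRESS}/SS_{tot}$, computed by the exact
  hat-matrix shortcut $e_i/(1-h_i)$ and verified in the tests against
  the explicit $n$-fold refit loop to $10^{-10}$. PRESS ≥ $SS_{res}$, so
  $Q^2_{LOO} \le R^2$.
* **Points-out split**: `points_out_split()` holds out a random 20% of
  compositions (training size `round(0.8 N)`; 181 records split
  145/36), deterministic per seed. "Mixtures out" and "compounds out"
  strategies are deliberately not implemented as validated modes.
* **$Q^2_{ext}$** uses the *training* mean in its denominator, so
  predicting the training mean scores exactly 0.
* **$r_m^2$** $= r^2(1 - \sqrt{r^2 - r_0^2})$ with $r_0^2$ the
  through-origin coefficient of observed on predicted (the Roy 2009
  definition; the difference is clamped at 0 with a warning if numerics
  push $r_0^2$ above $r^2$).
* **Y-randomization** shuffles the response, rebuilds the model each
  time (reselecting descriptors by default, which also guards against
  selection bias; a fixed-subset mode is far cheaper) and summarises the
  separation as $(R^2_{orig} - \overline{R^2_{rand}})/SD(R^2_{rand})$.
  The literature's "mean highest random $R^2$" phrasing is ambiguous, so
  the report carries both this mean-based distance and a max-based
  variant; distances above 3 SD indicate significance at the 0.1% level.

## Applicability domain

`williams()` computes leverages $h_i = x_i^T(X^TX)^{-1}x_i$ against the
training design (their sum over training rows is $q+1$, a tested
identity) and the warning threshold $h^* = 3(q+1)/n$ — for the published
model, $3 \times 7 / 145 = 0.145$. "Cross-validated standardized
residual" is not formula-defined in the QSPR literature; this package
uses the common Williams-plot convention, the LOO residual divided by
the SD of the training LOO residuals, with test-set residuals scaled by
that same training SD by default (`residual_scale = "test"` switches to
the test SD; both are reported because sources rarely say which they
used). A record is in-domain when $h \le h^*$ and its standardized
residual is within $\pm 3$; boundary points count as acceptable
(non-strict comparisons), and an interpolating fit with zero residuals
standardizes to zero by convention rather than dividing by zero.

## The synthetic dataset generator

The experimental compilation behind the published model is not
redistributable, so the package generates datasets with the same
*shape*: 10 components, every unordered pair on a 0.1–0.9 mole-fraction
grid (45 × 9 = 405 records, optionally subsampled to 181), response

$$\mathrm{LFL}_{mix} = \mathrm{LeChatelier}(l_1, l_2, x_1)
+ A\,x_1 x_2\,s_{pair} + \varepsilon,$$

with Le Chatelier's rule $1/(x_1/l_1 + x_2/l_2)$ as the physically
motivated backbone, a pair-specific sign $s_{pair} = \pm 1$ drawn once
per pair, and $\varepsilon \sim N(0, \sigma)$. Defaults chosen once and
kept: amplitude $A = 0.4$ vol% (maximum systematic departure
$A/4 = 0.1$ vol% at equimolar composition, the order of experimental
reproducibility) and $\sigma = 0.1$ vol%, the typical experimental error
of LFL determination. The deviation shape $x_1 x_2$ vanishes at the pure
limits, exactly the nonlinearity that direct mixing rules must capture.

Pure-component LFLs are *inputs*: the source material does not print
them, so the generator requires them. `synthetic_pure_lfl()` supplies a
clearly-labelled placeholder set, fixed once so that the generated
mixtures span roughly 1.7–4.6 vol%, the magnitude range quoted for the
real compilation (1.65–4.71 vol%). "Butylene" is taken as 1-butene and
"butadiene" as 1,3-butadiene; the isomers are not specified in the
source and both choices are overridable through a custom table.

### What passing on synthetic data does and does not show

The generator's backbone is exactly Le Chatelier, and the pipeline
recovers that law perfectly on the reciprocal scale (1/LFL is linear in
the molar blend of pure 1/LFLs with $R^2 = 1$, a tested identity). A
*linear* model in norm_cont-mixed descriptors, however, can only
approximate the hyperbolic composition dependence: on noiseless
generated data the six native descriptors plus a pure-LFL column reach
$R^2 \approx 0.97$, not 1, and external $Q^2$ around 0.88–0.95
depending on the split. That ceiling is a property of the model class on
this backbone, not an implementation defect, and the end-to-end tests
assert it as such. Synthetic data also cannot validate the *chemistry*
of the frozen model — its coefficients were fit to descriptors from a
different geometry engine on unpublished measurements — so agreement
with printed headline statistics ($R^2 = 0.964$, $Q^2_{ext} = 0.988$,
AAE 0.052 vol%) is out of reach at desk scale and is not claimed.
Recovery tests that need exact linear structure (GA planted-subset
recovery, Y-randomization separation) therefore plant their signal
directly in norm_cont-mixed descriptors.

## Problem sizes used by the test-suite

Unit and property tests run on designs of 30–180 records and up to 20
descriptors; GA recovery uses a 20-descriptor pool with a planted
6-descriptor model on 181 records (population 100, 150 generations, 10
seeds); the PRESS-shortcut identity is checked on one hundred 50-by-6
problems; Y-randomization suites use 50–100 permutations in fixed-subset
mode. These sizes were chosen to exercise the estimators well inside a
single-CPU minute-scale budget while keeping every statistical assertion
comfortably powered.

## Known limitations

* Only the six descriptors of the frozen model are computed natively;
  any other descriptor enters via `read_descriptor_csv()` /
  `merge_descriptors()` (external values win on name collision, with a
  warning).
* Strictly binary mixtures; no rules for three or more components.
* Neutral organic-subset SMILES only (no charges, isotopes or
  stereochemistry — the geometry step would ignore cis/trans anyway).
* The embedding is a clean harmonic model, not a full force field:
  torsional preferences (e.g. s-trans butadiene) are not enforced, which
  is one reason native 3D descriptors differ from other engines'.
* The frozen model's applicability domain is narrow by construction (10
  light hydrocarbons); leverage flags from `williams()` should be taken
  seriously when predicting anything heavier.
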