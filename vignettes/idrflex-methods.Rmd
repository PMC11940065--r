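---
title: "Models and methods in idrflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in idrflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrflex)
```

idrflex implements the computational side of a disorder-to-order protein
engineering study: scoring conformational flexibility from sequence,
nominating rigidifying point mutations, quantifying secondary structure and
its partner-induced changes from far-UV circular dichroism (CD), and
estimating binding affinity from microscale thermophoresis (MST)
titrations. This vignette documents the models, their assumptions, the
default parameters, and the choices made where the design was genuinely
open.

## Disorder scoring and substitution scanning

### The predictor

Intrinsically disordered regions are depleted in bulky hydrophobic residues
and enriched in charged, hydrophilic ones. The package's per-residue score
is a closed-form predictor in the FoldIndex/TopIDP tradition built from
exactly those two signals. For residue $i$, over a window of
$2h + 1$ positions truncated at the termini (default halfwidth $h = 10$,
a 21-residue window typical of composition predictors):

$$\mathrm{score}_i = \operatorname{logistic}\!\big(k\,(b + w_c\,|\langle R\rangle_i| - w_h\,\langle H\rangle_i)\big)$$

where $\langle H\rangle_i$ is the windowed mean Kyte–Doolittle hydropathy
rescaled to $[0,1]$, $\langle R\rangle_i$ the windowed mean net charge
(K/R = +1, D/E = −1), and the defaults are $w_h = 3$, $w_c = 0.75$,
$b = 1.2$, steepness $k = 4$. Scores lie in $[0,1]$, are oriented so higher
means more disordered, and positions scoring ≥ 0.5 are labelled
disordered.

The coefficients were fixed by two analytic requirements, not by fitting:

* **Calibration.** Compositions averaged over the eight disorder-promoting
  residues (A, R, G, Q, S, P, E, K) must score above 0.5 and the eight
  order-promoting ones (W, C, F, I, Y, V, L, N) below it. With the defaults
  the two composition means score ≈ 0.87 and ≈ 0.04.
* **Order-substitution monotonicity.** Replacing a glutamate by tryptophan
  must never increase predicted disorder. The hydropathy gain of E→W per
  window position is $w_h \cdot 2.6/9 \approx 0.867$, strictly larger than
  the largest possible increase of the charge term, $w_c = 0.75$; because
  the logistic is monotone, every window's score can only drop.

This is deliberately a transparent surrogate for trained disorder
predictors (PONDR-family, IUPred): the scanning procedure is
predictor-agnostic, and the package makes no attempt to reproduce any
trained predictor's numeric outputs. Both scales ship as editable
plain-text files and can be swapped via `score_disorder()` arguments.
Windows are truncated at the termini rather than mirrored — the simplest
defensible behaviour, stated here so profiles near the ends are interpreted
accordingly.

### The scan

`scan_substitutions()` is a replace-and-test loop: every scanned position
is substituted with each of the other 19 residues, the **full variant
sequence** is re-scored, and the effect is the wild-type mean score minus
the variant mean score (positive = order-conferring). Results are sorted by
that delta, ties broken by position then substitute letter, so rankings are
deterministic. Whether such a scan should rank by whole-sequence mean
change or by change within a local window is not canonically defined; both
are exposed (`window = "sequence"` is the default, `"local"` restricts the
mean to the edited position's window) and the whole-sequence form is the
default because it matches how region-level disorder averages are usually
reported.

Column conservation for alignments is $1 - H/\ln 20$ per column, with $H$
the Shannon entropy of residue frequencies after removing gaps; all-gap
columns are undefined (NA) and columns over 50 % gaps are flagged rather
than dropped.

## CD spectral arithmetic

Spectra carry an explicit unit state (millidegrees, MRE, or ME) and
arithmetic refuses mixed units or mismatched wavelength grids; resampling
(`resample_spectrum()`, linear interpolation, no extrapolation) must be
invoked explicitly. The conversions are

$$\mathrm{MRE} = \frac{m°}{10\,l\,M\,n}, \qquad \mathrm{ME} = \frac{\mathrm{MRE}}{3298},$$

with $l$ the pathlength in cm, $M$ the molar concentration, and $n$ the
number of peptide bonds (residues − 1). $m°$ is interpreted as the
instrument ellipticity in millidegrees, the conventional input to this
normalization.

### The mixture normalization

For a 1:1 two-component mixture two conventions are implemented.
`convention = "paper"` divides by
$10\,l\,\frac{M_A + M_B}{2}\,\frac{n_A + n_B}{2}$, reproducing the printed
mixture formula bit-for-bit. It has a quirk: for a non-interacting
equimolar pair of equal length it returns the **sum** of the component MRE
spectra, while the non-interacting *expectation* used for difference
spectra is an **average** — so even a perfectly additive mixture would show
a nonzero "difference". `convention = "total-residue"` divides by
$10\,l\,(M_A n_A + M_B n_B)$, which makes a strictly additive mixture equal
the concentration-weighted mean of the component spectra exactly. The
total-residue convention is therefore the default, and the package's
internal-consistency contract — simulate a non-interacting mixture, expect
an identically zero difference spectrum — holds only under it. The paper
convention remains available for exact comparison with externally processed
data, and the pipeline driver logs a warning whenever it is selected.

The difference spectrum itself is *expected minus measured mixture* (the
mixture is subtracted **from** the non-interacting expectation), computed
in MRE space; deviations from zero indicate structure formed or lost on
binding. The expectation supports the plain arithmetic mean of the two MRE
spectra (the convention of the workflow this mirrors) and a
concentration-weighted mean; at equal $M\,n$ products they coincide.

`plan_dilution()` implements co-solvent dilution arithmetic by conservation
of moles and volume. Note one worked recipe: 160 µL of TFE into 240 µL of
17 µM protein gives 10.2 µM at 40 % v/v, not the nominal 10 µM sometimes
quoted for that recipe; the function reports the exact value and leaves the
reconciliation to the user.

## Secondary-structure deconvolution

Fractions $f$ are estimated by

$$\min_f \;\|y - Bf\|^2 + \lambda\|f\|^2
\quad\text{s.t.}\quad f \ge 0,\; \textstyle\sum_c f_c = 1,$$

the constrained-regularized family used by CONTIN-class CD analysis. Three
numerical choices matter:

* **Exact solver.** With $k$ classes ($k \le$ ~6 in practice) the strictly
  convex objective attains its constrained optimum on some support subset;
  the solver enumerates all $2^k - 1$ subsets, solves each equality-
  constrained KKT system, discards infeasible candidates, and keeps the
  feasible one with the lowest objective. This is globally exact — no
  active-set iteration to tune — and is verified in the tests against an
  exhaustive simplex grid search at step 0.01.
* **Conditioning.** Basis amplitudes are $O(10^4)$ deg cm² dmol⁻¹ while the
  sum-to-one constraint row is $O(1)$, which makes the raw KKT system
  numerically singular; signals are rescaled to $O(1)$ inside the solver
  (with $\lambda$ rescaled by the squared factor so the minimizer is
  unchanged).
* **Fit range.** The default fitted window is 190–240 nm, the span over
  which far-UV reference sets are informative; the goodness-of-fit is
  $\mathrm{NRMSD} = \sqrt{\sum(y - \hat y)^2 / \sum y^2}$ over that window.

Reference basis: the experimental reference sets used by CD deconvolution
services are external databases that cannot be redistributed here, so
`default_basis()` is a **parametric synthetic basis** — per-class sums of
Gaussian bands at the canonical far-UV positions (helix: +193, −208,
−222 nm; sheet: +195, −218 nm; turn: weak positive near 206 nm;
disordered: deep minimum near 198 nm) with amplitudes approximating fully
formed structure. It is faithful in shape and keeps the estimator fully
testable offline, but fractions obtained with it are not comparable to
database-derived percentages; any user basis can be supplied as a CSV with
one column per class. No ridge penalty is applied by default
($\lambda = 0$); $\lambda > 0$ trades fit for stability and NRMSD is
non-increasing as $\lambda \to 0$.

### Two-wavelength classification

The $\theta_{222}$-vs-$\theta_{200}$ plot separates random-coil from
pre-molten-globule conformations, but no canonical discriminant boundary
exists for it. The package therefore classifies by nearest centroid against
user-supplied labelled reference points, with axes standardized by the
pooled within-cohort standard deviation; per-cohort distances are always
returned so partial membership is quantifiable, and an exact tie is
reported as a tie rather than silently broken. The original reference
cohort coordinates are not redistributable, so tests use seeded synthetic
cohorts with the qualitative geometry of the published plot (coils deeper
at 200 nm and flatter at 222 nm than pre-molten globules).

## Binding analysis

Fraction bound for a ligand titrated against a fixed labelled target obeys
the exact 1:1 quadratic mass-action solution (`binding_model()`), which
accounts for target depletion and reduces to $c/(c + K_D)$ as the target
concentration $c_t \to 0$. Dilution ladders are exactly geometric; the
canonical design — 16 two-fold steps from 40 µM — ends at
$40\,\mu M / 2^{16} = 610.35$ pM, consistent with a "40 µM to 610 pM"
description only if "16-step" means 16 dilution *steps*, i.e. 17
concentrations. That reading is hard-coded in the tests.

Fitting choices:

* **Parameterization.** $K_D$ is fitted on the log scale (positivity for
  free), by Levenberg–Marquardt least squares, multi-started from 13
  log-spaced initial values between 1 nM and 1 mM; the best final sum of
  squares wins. A fitted $K_D$ at the edge of that range is flagged.
* **Uncertainty.** The standard error comes from the Jacobian at the
  optimum via the delta method ($\mathrm{se}(K_D) = K_D\,
  \mathrm{se}(\log K_D)$). On simulated single-curve titrations with
  0.02 fraction-bound noise, the ±2 SE interval covers the truth ~95–98 %
  of the time (checked in the acceptance tests). When per-point replicate
  SDs are supplied they enter as $1/\mathrm{sd}$ residual weights; note
  that SDs estimated from only two replicates are themselves very noisy,
  so weighted SEs from duplicate data should be read qualitatively.
* **Target concentration.** The labelled-target concentration is usually
  not reported alongside published titrations; the default
  $c_t = 50$ nM is typical of His-tag dye labelling chemistry, is always
  user-overridable, and is recorded in every output.
* **Saturation.** A $K_D$ is only as good as the top of its curve. The
  diagnostic passes only if the top concentration is ≥ 5 × the fitted
  $K_D$ **and** the fitted fraction bound at the top is ≥ 0.8 (both
  configurable; there is no community-standard criterion, so these
  conservative margins stand in). Non-saturating fits are written out with
  diagnostics but a blank $K_D$, mirroring how such titrations are
  tabulated in practice. Raw-fluorescence curves are normalized by fitting
  baseline and plateau jointly with $K_D$ rather than taking the min/max
  of noisy data, making the normalization exactly affine-invariant.

## Synthetic data: what it emulates

The generators define the package's study conditions and every default was
fixed once, from the acquisition designs the analysis stages expect:

* **CD**: 190–250 nm at 1 nm, pathlength 0.1 cm (1 mm cuvette), 10 µM
  protein, $n = 111$ peptide bonds (a ~112-residue construct); the binding
  partner is a ~228-residue species ($n = 227$, a linear triubiquitin-like
  chain) at the same molarity. Instrument noise defaults to
  0.2 mdeg (i.i.d. Gaussian), a realistic magnitude for averaged far-UV
  scans; recovery experiments use 2 % of each spectrum's range instead
  where a relative level is wanted.
* **Mixtures**: the 1:1 mixture signal is strictly additive except that the
  *bound portion* of component A — the fraction bound at the stated
  concentrations and $K_D$ under the mass-action model — has its structure
  fractions shifted by `induced_delta` (summing to zero, so the result
  stays on the simplex). This is the simplest mechanism consistent with a
  mixture containing both bound and free protein, and `induced_delta = 0`
  recovers exact additivity, which is the null-interaction contract the
  acceptance tests exercise.
* **Binding**: 16-step 2-fold ladder from 40 µM, $K_D = 5$ µM,
  $c_t = 50$ nM, duplicate measurements with 0.02 fraction-bound noise.
* **Sequences**: residues i.i.d. with probability mass `disorder_bias`
  (default 0.8) concentrated on the disorder-promoting set — a composition
  bias, not a model of real positional structure.

Every generator is a pure function of its config: the seed is set locally
and the caller's RNG stream is untouched, so identical configs give
bit-identical outputs.

What the generators do **not** emulate: CD band fine structure beyond the
Gaussian basis, wavelength-dependent noise and dynode-voltage artefacts,
thermophoresis physics (only the equilibrium binding isotherm is modelled),
and real phylogenetic structure in alignments. Passing recovery tests on
this synthetic data demonstrates the estimators are correct and calibrated
under their own assumptions; it does not certify accuracy on real spectra
measured against experimental reference bases.

## Problem sizes and determinism

The shipped tests and the acceptance script use 50 noiseless and 100 noisy
deconvolution recoveries, 200 simulated titrations for the $K_D$
calibration, brute-force scan oracles up to length 8 (19·L variants each),
and 61-point spectra — sizes at which every oracle is exact and the full
suite runs in well under a minute. All stochastic checks run under fixed
seeds; the acceptance script takes a single `--seed` and derives every
simulation seed from it.

## Known limitations

* The disorder predictor is a composition surrogate: adequate for ranking
  substitutions by charge/hydropathy logic, but blind to positional motifs,
  secondary-structure propensity patterns, and context a trained predictor
  would capture.
* Deconvolution quality is bounded by the basis; the shipped parametric
  basis supports method validation, not publication-grade secondary
  structure percentages.
* The two-wavelength classifier requires user reference points; it ships
  with none.
* MST normalization from raw fluorescence assumes the affine
  baseline/plateau model; cooperative or multi-site binding is out of
  scope, as is any Hill-type model.
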