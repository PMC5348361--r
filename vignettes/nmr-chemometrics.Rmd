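---
title: "Chemometrics for 1H-NMR metabolomics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemometrics for 1H-NMR metabolomics: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrpls)
library(dplyr)
```

`nmrpls` implements the statistical workflow used to read group structure
out of 1D ^1^H-NMR metabolic profiles — the kind of data produced when
comparing, say, sham-operated rats, an ischemic-stroke (MCAO) model group
and several drug-treatment arms across brain extracts and serum. The
wet-lab side (surgery, acquisition, phasing, assignment) is out of scope;
the package starts from spectra and ends at models, variable selection,
univariate tables and association networks. Because no public spectra
accompany this workflow, a first-class simulation module generates
cohorts with known ground truth, so every downstream claim is testable.

## The simulated cohort

Each metabolite is a template of stick resonances; a resonance at center
$c$ with full width at half maximum $\gamma_{\mathrm{FWHM}}$ contributes a
unit-area Lorentzian

$$L(\delta) = \frac{1}{\pi}\,
  \frac{\gamma}{(\delta - c)^2 + \gamma^2},
  \qquad \gamma = \gamma_{\mathrm{FWHM}}/2,$$

the natural lineshape of liquid-state NMR. A sample's spectrum is

$$s_i(\delta) = d_i \sum_m \kappa_{im}\, A_m \sum_{p \in m} a_p\,
  L_p(\delta) + \mathrm{baseline} + \varepsilon,$$

with $d_i$ a log-normal dilution factor, $\kappa_{im}$ the metabolite
concentration (a group-level effect factor times a per-sample log-normal
biological multiplier), $A_m$ the template's base area and $a_p$ the
relative multiplet areas. Multiplets are collapsed to stick positions —
multiplicity labels are cosmetic, and no J-coupling quantum mechanics is
simulated. Every draw (concentrations, dilutions, shift jitter,
calibration offsets) is retained in `truth`, which is what makes recovery
tests possible.

Defaults and why:

* **Grid**: 16,384 points over 0.2–10 ppm, descending — a desk-scale
  stand-in for a 32 K acquisition over a 10,000 Hz sweep.
* **Linewidth**: 0.003 ppm FWHM, typical of well-shimmed small-molecule
  spectra at 500 MHz.
* **Groups**: nine by default (sham, MCAO, three single treatments A/B/C,
  three pairs, the triple), `n_per_group = 10`. Published designs of this
  kind enroll $n \ge 20$ per arm and assay subsets of about 6; 10 is a
  deliberate middle ground that keeps two-fold cross-validation stable.
* **Dilution log-sd 0.3**: large enough that normalization has real work
  to do.
* **Biological variation (`conc_log_sd`, default 0.2)**: the design type
  carries this extra knob because without per-sample concentration
  variation the cohort is degenerate — every spectrum a scalar multiple
  of one shape — and correlation-based stages (STOCSY, PQN recovery,
  networks) have nothing to estimate.

What the generator does **not** emulate: peak overlap from hundreds of
minor metabolites, pH-dependent shift drift beyond simple jitter,
macromolecular baselines in serum, phasing errors. Passing tests
demonstrate algorithmic correctness on clean, identifiable signals; they
do not certify performance on crowded real spectra.

## Preprocessing

**Referencing.** When a TSP-like anchor is simulated, each sample's axis
is shifted so the apex lands at exactly 0 ppm (linear re-interpolation on
the shared grid). Samples without a detectable anchor are flagged and
left alone rather than silently shifted.

**Bucketing.** The spectrum is segmented into 0.0025 ppm integrated
buckets between 0.2 and 10 ppm — 3920 variables. Buckets are half-open
$[\mathrm{lo}, \mathrm{hi})$ on the ppm value and stored ascending by
center, so boundary points have a deterministic home. The bucket value is
the sum of grid intensities in the bin times the grid spacing, i.e. a
rectangle-rule integral; total signal is conserved to rounding. Bins
touching an excluded region are dropped whole: 4.65–5.25 ppm (residual
water, 240 bins) for cerebral extracts, 4.70–9.70 ppm for serum. The
serum exclusion removes most of the downfield region; it is implemented
exactly as stated upstream rather than silently narrowed.

**Probability quotient normalization.** Dilution differences scale whole
spectra; PQN estimates that scale robustly. Each total-area-normalized
spectrum is divided by the median of its bin-wise quotients against a
reference spectrum — the median spectrum of the cohort (or of a
designated reference group). The stored factor is the *total divisor
actually applied*, the row-sum times the median quotient. That bookkeeping
choice makes PQN exactly idempotent in both senses: re-applying it to its
own output reproduces the matrix bitwise, and the second-pass factors are
exactly 1. (Storing only the median quotient would make second-pass
factors repeat their first-pass values: total-area renormalization of the
output returns the pre-quotient matrix, so the same quotients reappear.)
PQN's premise is that most signals are unchanged between samples; its
factor therefore absorbs composition drift too. With $M$ metabolites of
biological log-sd $s$, the median quotient carries roughly
$1.25\,s/\sqrt{M}$ of log-noise, so near-perfect dilution recovery
($r > 0.99$ at dilution log-sd 0.3) requires the dilution-dominant regime
($s \lesssim 0.1$ with ~20 metabolites) — the regime the method assumes.

**Scaling.** Variables are mean-centered and Pareto-scaled (divided by
the square root of the $n-1$ standard deviation), damping the dominance
of intense signals without the noise inflation of full unit-variance
scaling. A useful identity for testing: the variance of a Pareto-scaled
column equals the original column's standard deviation. Zero-variance
columns cannot be scaled and are dropped with a report.

## The multivariate core

**PCA** (SVD of the centered matrix) is kept as the unsupervised look;
on realistic cohorts the group structure is usually invisible without
variable selection, which motivates the supervised chain.

**OSC.** Orthogonal signal correction removes variance that is
mathematically orthogonal to class membership (dilution residue,
instrumental drift) before discriminant modeling. The implementation is
the orthogonalize-score NIPALS variant: start from the first principal
score, project it onto the orthogonal complement of the class-indicator
matrix, regress the data on the projected score to update the weight
vector, recompute the score, repeat to convergence (relative score change
< 1e-8), then deflate. Two numerical points:

* The iteration's fixed point is the leading right singular vector of
  $P X$ ($P$ the projector orthogonal to the indicators), so the solver
  starts there and uses the loop purely as verification — the raw power
  iteration can need thousands of steps when the orthogonal spectrum is
  flat, as it is on null data.
* If the data are an exact function of class membership, $P X \approx 0$
  and there is nothing orthogonal to remove; the factor is recorded as
  null with zero removed variance instead of dividing by noise.

One factor is removed by default; every additional factor removes
variance the cross-validation can no longer see, inflating apparent
performance, which is why removal is conservative and why OSC is refit
inside every training fold and under every permutation below.

**PLS-DA.** NIPALS partial least squares against a centered dummy matrix
(one indicator column per class, also in the two-class case). Both blocks
are deflated by the X-score each component. Components default to 2 —
matching the two-dimensional score plots this workflow reports — with an
optional `"auto"` rule (add components while cross-validated $Q^2$ gains
exceed 0.01, at most 5). A deterministic sign convention (the largest-
magnitude weight entry positive per component) makes refits bitwise
reproducible. $R^2Y$ is the fraction of dummy-matrix variance explained;
$Q^2$ is its cross-validated counterpart, $1 - \mathrm{PRESS}/\mathrm{SS}$.

**Validation.** $Q^2$ comes from stratified two-fold cross-validation
repeated 50 times (the repetition averages out fold-split luck), with
centering, OSC and PLS-DA all refit inside each training fold and applied
frozen to the held-out fold. The permutation test refits that entire
chain — OSC uses labels, so excluding it would overstate significance —
under `n_perm` label shuffles and reports add-one empirical p-values
$(b+1)/(n_\mathrm{perm}+1)$, never exactly zero. A final model deserves
2000 permutations; the demo config uses 200 to stay interactive, and the
type-I-error checks in the test suite use 99 per run across 200 replicate
runs, where the add-one estimator's rejection rate at $\alpha = 0.05$ is
exactly 4% under the null.

**S-plot and colored loadings.** For each variable, the covariance and
Pearson correlation of the variable with the first predictive score;
reliable discriminators sit far from the origin in the upper-right/
lower-left. $|r|$ doubles as the color scale of the back-scaled loading
pseudo-spectrum (covariance multiplied by $\sqrt{\mathrm{sd}_j}$ to
return to pre-Pareto units).

## Univariate layer

Fold changes are ratios of group means against the reference group,
computed on PQN-normalized, *unscaled* data — ratios on Pareto-scaled
values would be meaningless. Per comparison, two-sided Welch tests across
metabolites are Benjamini–Hochberg adjusted (the family is the metabolite
panel within one comparison, matching per-column star displays), and
stars encode the adjusted values at 0.05/0.01/0.001 — the conservative
reading where the display convention leaves raw-versus-adjusted open.
Heatmap cells are group means of all-sample z-scores. The assay panel
uses one-way ANOVA with Tukey's HSD (Tukey–Kramer when unbalanced), and
qPCR tables use $2^{-\Delta\Delta CT}$ normalized to a housekeeping gene
and a control group.

## STOCSY

Resonances of one molecule rise and fall together across samples, so
their Pearson correlation is theoretically 1; correlating a driver bucket
against the whole spectrum lights up its molecule's other resonances
(e.g. driving at 2.14 ppm highlights 2.44 ppm for glutamine, and 2.10
against 2.34 ppm for glutamate). STOCSY here runs on normalized,
*unscaled* buckets: Pearson $r$ is invariant to any later column scaling,
and centering is implicit. Drivers map to bins under the same half-open
convention as bucketing. Note one practical caveat the tests respect: a
cohort whose only signal is a single metabolite becomes constant after
PQN (every spectrum is a scalar multiple of one shape), so the
theoretical-identity checks run on raw buckets where the
shared-concentration argument applies directly.

## Metabolite–phenotype networks

Sparse PLS in canonical mode links the metabolite block to the phenotype
block (biochemistry, expression, outcome scores — unit-variance scaled,
since the units are incomparable). Loadings are soft-thresholded so
exactly `keepX` / `keepY` entries survive per component (defaults 25 /
all, 3 components, recorded in the output). The association network uses
the standard relevance-network similarity
$s(j,k) = \sum_h \mathrm{cor}(x_j, z_h)\,\mathrm{cor}(y_k, z_h)$ with
$z_h$ the averaged pair of latent variates; $|s| > 0.8$ becomes an edge,
red for positive and blue for negative. Values are clipped to $[-1,1]$
with clip events counted (zero in all shipped simulations).

Identifiability matters more than the estimator here: a parameter built
from $k$ equally weighted metabolites has marginal correlation
$\approx 1/\sqrt{k}$ with each, so at threshold 0.8 only single-dominant
associations are recoverable, and a model with fewer components than
independent associations cannot carry them all. Recovery tests therefore
use single-metabolite parameters with as many components as parameters;
shipped defaults follow the same logic.

## Pipeline, sizes and determinism

`run_pipeline()` chains the stages on a simulated cohort, validates its
configuration strictly (unknown keys are typos and fail before any
computation), writes every tabular artifact as delimited text with JSON
sidecars, and logs parameters, seed, config hash and per-stage wall time.
All randomness flows from one seed through derived child seeds, so equal
configs give bitwise-equal deterministic artifacts. The bundled test
cohort (`make_fixtures()`) is a 4-group, $n = 8$ design with exactly
three planted discriminating metabolites (lactate and glutamine up,
glucose down in the model group, partially recovered under treatment) and
a 6-parameter phenotype panel; the suite checks end-to-end that those
three top the S-plot ranking and light up the heatmap.

Test problem sizes — a few dozen samples, tens to a few thousand
variables, 99–200 permutations, 20–100 simulation seeds — are chosen so
the whole suite runs in about two minutes while leaving every statistical
bound comfortably testable; they are stated alongside each test.

## Known limitations

* Stick-multiplet simulation cannot probe alignment or overlap failure
  modes; there is no peak alignment beyond single-shift referencing.
* OSC + PLS-DA on small cohorts remains easy to overfit; the guard rails
  (one OSC factor, folds-inside validation, permutations that rerun OSC)
  are faithful but no substitute for larger cohorts.
* The relevance network reports marginal-style associations through a
  low-rank model; it does not distinguish direct from mediated links.
* Serum's printed exclusion window removes most downfield signals; users
  with different instruments should override it consciously.

## A short worked example

```{r example, eval = FALSE}
fx <- make_fixtures(seed = 42)
bt <- fx$bucket_table

sel <- bt$samples$group %in% c("sham", "MCAO")
sub <- bt
sub$matrix <- bt$matrix[sel, , drop = FALSE]
sub$samples <- bt$samples[sel, ]

proc <- center_pareto(sub)
osc <- osc_filter(proc, sub$samples$group)
model <- fit_plsda(osc$x_corrected, sub$samples$group)
cv <- cross_validate(proc, sub$samples$group, seed = 1)
model$q2 <- cv$q2
glance(model)

s <- splot(model, proc)
autoplot(s)

mets <- integrate_metabolites(bt, fx$library)
fold_change_tests(mets, reference = "sham") |>
  filter(comparison == "MCAO vs sham") |>
  arrange(q_bh)
```
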