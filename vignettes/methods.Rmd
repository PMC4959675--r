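---
title: "Detecting diel transcript rhythms and propagating them to metabolic flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diel transcript rhythms and propagating them to metabolic flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanodiel)
```

## The problem

Cyanobacteria entrained to a 12-h light / 12-h dark (L/D) regime reorganize
much of their transcriptome around the diel cycle. Given a gene-by-timepoint
expression matrix sampled every 2 h over two consecutive cycles (24 samples
at t = 1, 3, ..., 47 h, starting 1 h into the first dark period), the
package answers three questions:

1. **Which transcripts cycle?** — a modified cosiner (cosinor) analysis with
   an explicit error-factor model-selection step and a hierarchical decision
   rule.
2. **How do the cycling genes organize?** — a Pearson coexpression network
   thresholded at r ≥ 0.90, whose connected components separate
   light-peaking from dark-peaking regulons.
3. **What do the rhythms imply for metabolism?** — flux balance analysis
   (FBA) on a stoichiometric model whose reaction bounds are scaled by
   cyclic gene expression through gene–protein–reaction (GPR) rules.

Every stage can be exercised against a seeded synthetic-data generator with
known ground truth, so the package is testable end to end without any
external download.

## The rhythm model

For a gene with feature-scaled values $g_1,\dots,g_{24}$ at times $t_i$, a
least-squares line $f(t)=\alpha t+\beta$ is removed first
($g_i' = g_i - f(t_i)$), so that baseline drift is not absorbed by the
cosine. For each trial period $T$ on a 12–36 h grid at 0.1-h steps (241
candidates) the detrended series is projected onto one harmonic:

$$a = \frac{2}{n}\sum_i g_i'\cos\frac{2\pi t_i}{T},\qquad
  b = \frac{2}{n}\sum_i g_i'\sin\frac{2\pi t_i}{T},\qquad n = 24,$$

giving the model $F(t)=\sqrt{a^2+b^2}\,\cos(2\pi t/T-\varphi)$ with
acrophase $\varphi$. We compute $\varphi$ with the two-argument arctangent
and wrap it to $[0,2\pi)$: the one-argument $\tan^{-1}(b/a)$ is
quadrant-ambiguous, and the wrap makes the peak time
$24\varphi/2\pi$ single-valued. Lack of fit is the **error factor**

$$E_f = \frac{1}{n}\sum_i\left[g_i' - F(t_i)\right]^2 ,$$

and the reported fit is the grid period minimizing $E_f$ (ties broken
toward the smaller period so output is deterministic). Peak-to-trough
amplitude is $2\sqrt{a^2+b^2}$.

A gene is called **cyclic** when, hierarchically,

(i) the best-fit period lies in 18–26.8 h,
(ii) $E_f \le 0.2$, and
(iii) a two-sided pooled-variance Student *t* test separating expression at
the fitted peak from the fitted trough is significant at 0.05 after Holm
step-down correction.

All three thresholds are configuration defaults, not constants.

### Decisions the method text leaves open

* **t-test groups.** Which observations constitute "peak" and "trough"
  samples is not derivable from the decision rule alone. We take the
  sampled label nearest the fitted peak (in clock time,
  $\varphi T/2\pi \bmod 24$) plus its two neighbouring labels, in both
  cycles — n = 6 per group — and the same half a period later for the
  trough. A one-label variant (n = 2) is available via `k_labels = 1`; the
  three-label default borrows strength from adjacent samples and makes the
  test well-defined when a single label happens to fall between grid
  points. With both groups constant the test is undefined and p = 1 is
  returned (p = 0 if two constant groups differ), so degenerate profiles
  are never called rhythmic by accident.
* **Holm family.** The hierarchical phrasing of the decision rule implies
  each criterion filters the survivors of the previous one, so the Holm
  family is the set of genes passing (i) and (ii), not the whole genome.
  Genes outside the family carry `NA` p-values.
* **Peak-time convention.** `peak_time` is $24\varphi/2\pi$ (circadian
  hours) as the method defines it; the fitted-curve peak in clock time,
  $\varphi T/2\pi$, is what drives the t-test grouping and the diagnostic
  comparisons, since for $T \neq 24$ the two differ.
* **Scaling before detrending.** Feature scaling precedes detrending and
  fitting; scaling is affine per gene, so the fitted period and acrophase
  are unchanged by the order, and only this order keeps the $E_f \le 0.2$
  threshold comparable across genes.

### A caution on period accuracy

A linear ramp is not orthogonal to the sine quadrature of a cosine over
whole periods, so OLS detrending removes part of the rhythm itself and
shifts the $E_f$ argmin. The bias depends on acrophase and period; at
$T \approx 24$ h it has median magnitude ≈ 0.2 h over uniform acrophases
even for noiseless data, and it grows toward the edges of the period
window. Callers comparing recovered to generating periods should expect
median errors of ~0.3 h under realistic noise: this is a property of the
detrend-then-project procedure, not of its implementation. Amplitude is
similarly attenuated when the feature-scaled profile clips the cosine's
extremes.

## Preprocessing two-channel arrays

Raw probe tables (experiment/control foreground and background intensities
per probe and array) are processed per array:

1. **Background subtraction**: corrected = max(foreground − background,
   floor), floor defaulting to 1 intensity unit so log-ratios stay defined
   for weak spots.
2. **LOWESS normalization** in MA space: $M=\log_2(\mathrm{exp}/\mathrm{ctl})$,
   $A=\tfrac12\log_2(\mathrm{exp}\cdot\mathrm{ctl})$; a LOWESS curve with a
   window covering 25% of the training points is fitted to M-vs-A and
   subtracted, values between training points obtained by linear
   interpolation. The **training set** is the package's one substantive
   preprocessing decision: when the table carries zero-ratio normalization
   control probes (as the synthetic generator emits, mirroring the control
   spots of real two-channel designs), the curve is anchored on them;
   otherwise all probes of the array are used, which assumes most genes are
   unchanged against the pooled control. Anchoring on controls is what
   makes the normalization exactly neutral on bias-free data — a curve fit
   through all probes would subtract the local mean of the true signal.
3. **Probe averaging**: a gene's value is the arithmetic mean of its
   probes' normalized log2 ratios.
4. **Feature scaling** to $[-1,+1]$ per gene (constant genes map to zero),
   so every profile contributes equally to rhythm detection and
   correlation.

## The coexpression network

Pearson correlations over the feature-scaled profiles of the cyclic genes;
edges where $r \ge 0.90$ (one-sided, following the printed inequality —
strong anti-correlation is not coexpression). Nodes carry their peak label
and peak phase; components of two or more genes are reported largest-first
with a majority-vote phase label, and degree-zero genes are listed
separately since they fall below the cutoff against every partner rather
than belonging to a regulon.

## Expression-constrained FBA

At each of the 12 distinct diel labels (cycle-averaged, per the expression
convention below) fluxes solve

$$\max v_{\mathrm{biomass}}^{\mathrm{phase}}\ \ \text{s.t.}\ \ S v = 0,\qquad
  a_j v_j^{\min} \le v_j \le a_j v_j^{\max},$$

with phase-specific nutrient caps: photons and CO2/H2CO3 open in the light,
glycogen open in the dark, and the other phase's biomass reaction closed.
The scaling factor $a_j$ comes from the GPR rule of each cyclic reaction (a
reaction is cyclic when any of its genes is): each cyclic gene's 24-point
profile is averaged across the two cycles and min–max scaled to $[0,1]$;
an AND node (protein complex) takes the minimum over its cyclic children, an
OR node (isozymes) their sum, recursively for nested rules; non-cyclic
genes inside a rule are ignored rather than zeroed, and reactions without
cyclic genes keep $a_j = 1$. Isozyme sums may exceed 1 — the rule is
applied literally, with an optional `cap = TRUE` clamp. Because $a_j$
multiplies both bounds, $a_j = 0$ closes a reversible reaction in both
directions.

Two reproducibility decisions: among alternate optima the reported vector
also minimizes total absolute flux at the fixed optimum (a secondary LP),
and pathway profiles average the **absolute** fluxes of member reactions
(so reversible members cannot cancel) before each pathway's 12-point series
is min–max scaled to $[0,1]$.

The LP itself is solved by a small dense two-phase simplex with Bland's
rule, written for this package and cross-checked in the test suite against
exhaustive vertex enumeration; reactions fixed at zero are eliminated and
only genuinely reversible reactions are split, which keeps the tableau
small and non-degenerate for curated models of the sizes used here.

## The synthetic generator

`generate_expression()` draws, per gene,
$g(t)=\alpha t+\beta+(A/2)\cos(2\pi t/T-\varphi)+\varepsilon$ with
$\varepsilon\sim N(0,\sigma^2)$ i.i.d. (no noise model is implied by the
data themselves; Gaussian is the neutral choice), non-cyclic genes dropping
the cosine. Defaults — 40% cyclic, peak-to-trough amplitudes 1–3 log2
units, noise 0.2 log2 units, trends within ±0.01 log2/h — emulate a
diurnally entrained prokaryotic transcriptome on two-channel arrays. True
periods are drawn from 23.5–24.5 h: entrainment by a 12:12 driver locks
transcript rhythms to the driver's 24-h period, and wider dispersion would
model free-running circadian drift instead. `A` is recorded peak-to-trough
to match the detector's amplitude convention, so recovery comparisons are
direct. One seed governs each generator call; fixed seed means
byte-identical output.

`generate_probe_intensities()` inverts the preprocessing model: per probe a
fixed mean log-intensity, channel foregrounds chosen so the
background-corrected log-ratio equals the matrix value plus an injected
smooth dye bias $b(A)$, additive backgrounds, some genes with two probes,
and a ladder of zero-ratio control probes across the intensity range. What
it does **not** emulate: spatial or print-tip artifacts, missing spots,
heteroscedastic or intensity-dependent noise, and outlier spots. Passing
tests therefore certify the computational pipeline, not robustness to every
artifact of physical arrays.

`generate_toy_model()` is a fixed 12-reaction diel model (photon, CO2 and
glycogen exchanges; an AND-gated carbon fixation, an OR-gated glycogen
breakdown, a nested OR-of-AND respiration; separate light and dark biomass
equations) built so that every $a_j$ rule and both phase configurations are
exercised, with hand-verifiable optima (biomass 4 in the light on 10 units
of CO2, 7 in the dark on 5 units of glycogen, 0 in the dark without
glycogen).

## Numerical choices

* Period grid values are rounded to their nominal 0.1-h resolution so
  reported periods compare exactly.
* $E_f$ is evaluated through an algebraic expansion of the residual; the
  cancellation floor is ~1e-16, and "zero" assertions use 1e-12.
* Acrophases within machine epsilon of $2\pi$ wrap to 0, keeping
  $\varphi \in [0,2\pi)$ and peak times in $[0,24)$.
* Constant profiles: feature scaling maps them to zero (they can never
  pass the cyclicity criteria); constant activity profiles map to zero;
  constant pathway flux series scale to zero. Correlation is undefined for
  constant genes, which are excluded with a warning.
* LP tolerances: pivoting at 1e-9, mass-balance residuals verified to
  1e-6, vertex-oracle agreement to 1e-8.

## Problem sizes used in validation

The shipped tests and the acceptance script run at desk scale, chosen so a
full pass stays fast while estimates remain stable: 1,000 genes for
operating characteristics (sensitivity, false-positive rate, period and
peak-time recovery), 100 random series for the exhaustive-scan equivalence
check, networks of up to 200 nodes against a union-find oracle, and the
12-reaction toy model (plus a 4-reaction chain) against vertex enumeration.

## Known limitations

* Single-harmonic fitting on an evenly sampled 24-point grid; no support
  for uneven sampling, replicates, or multi-harmonic waveforms.
* The period estimator inherits the detrending bias discussed above;
  periods are best interpreted at ±0.5 h.
* The network stage computes correlations only among cyclic genes;
  genome-wide correlation before filtering would give the same components
  restricted to cyclic nodes but is not what the pipeline does.
* FBA results are relative: nutrient cap magnitudes are model properties,
  and only the 0–1-scaled pathway profiles are comparable across models.
* The SBML reader covers Level 3 FBC flux bounds and gene associations;
  groups/annotations beyond a `subsystem` attribute are ignored, and diel
  phase roles must be supplied by the caller.
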