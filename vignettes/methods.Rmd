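---
title: "Methods: modeling and optimizing explant disinfection protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling and optimizing explant disinfection protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disinfopt)
```

## The modeling problem

Surface disinfection of explants trades off two bounded percentages
measured per treatment: disinfection efficiency (DE, contamination-free
cultures) and negative disinfection effect (NDE, phytotoxic damage among
the clean cultures). Both respond nonlinearly and interactively to the
four protocol variables — NaOCl, H₂O₂ and HgCl₂ concentrations and the
immersion time — which is why the workflow uses a small neural network as
a response-surface surrogate and a multi-objective optimizer on top of it,
rather than one-factor-at-a-time screening.

The package treats the published study artifacts as data: the 28-treatment
table (`study_table()`), the printed 4–10–2 weight matrices
(`published_mlp()`), and the scaling ranges (`published_scaler()`). NDE is
undefined for the fully contaminated control and is represented as missing,
never as zero; missing responses are excluded from fitting and metrics for
that output only.

## Normalization

All fitting and prediction happens on a min–max scale,
$m = (m_{max}-m_{min})(x-n_{min})/(n_{max}-n_{min}) + m_{min}$ with target
range $[-1, 1]$, matching the operating range of the tansig hidden layer.
The published source does not print its scaling ranges, so the convention
was determined empirically before being frozen into the packaged fixture:
with per-variable ranges taken over **all 28 records** (inputs NaOCl
$[0, 1.26]$, H₂O₂ $[0, 12.25]$, HgCl₂ $[0, 0.2]$, time $[5, 30]$ — the
control's 20 min in sterile water means the observed time minimum is 5,
not 0) and responses over $[0, 100]$, the forward pass reproduces every
printed predicted value to its printed precision (0.005). That agreement
over 55 independent values is the calibration's verification; plausible
alternatives (training-subset ranges, a time range including 0) do not
reproduce the table.

Neither map clips: raw values outside the fitted range extrapolate
linearly, and network outputs outside $[-1, 1]$ denormalize to percentages
outside $[0, 100]$. The published table itself contains a predicted DE of
134.70 %, so the unclipped convention is demonstrably the published one.
A reader should treat such values as extrapolation flags, not rates.

## Network and training

The surrogate is a single-hidden-layer perceptron, 4 inputs, $H$ tansig
hidden units (default 10, the published topology), 2 linear outputs
trained jointly. Training is full-batch Levenberg–Marquardt: with residual
vector $r(\theta)$ over all observed (row, output) pairs and Jacobian $J$
from analytic backprop through tansig ($d\,\mathrm{tansig}/dv = 1 -
\mathrm{tansig}^2$), each epoch solves $(J^\top J + \mu I)\,\delta =
-J^\top r$, multiplying $\mu$ by 10 until a step reduces the training
error and dividing it by 10 after every accepted step. Defaults
($\mu_0 = 10^{-3}$, factor 10, $\mu_{max} = 10^{10}$, patience 6,
max 1000 epochs) are the conventional values for this optimizer family.
Training stops at the epoch limit, when $\mu$ overflows (no descent
direction left), or by early stopping after `patience` consecutive
validation-MSE increases; the returned parameters are the snapshot at the
validation minimum. Initialization is uniform $[-0.7, 0.7]$ under the
caller's seed; the global RNG state is never touched.

Weight initialization and the random 70/15/15 split both matter enormously
on a 28-row table: the published correlation values (R 0.9658 / 0.9653 /
0.8937 / 0.9454 for train/validation/test/all) came from one unpublished
split and are not exactly reproducible by construction. The package
therefore asserts retraining quality as a band (best all-set R over five
seeded reruns > 0.85) and reports per-seed values.

## The optimizer

`run_moga()` is a real-coded, box-bounded, two-objective GA of the
controlled-elitist non-dominated-sorting family, the family to which the
study's named operator set (feasible creation, tournament selection,
intermediate crossover, adaptive feasible mutation) belongs. Study
settings are the defaults: population 50, crossover fraction 0.8,
migration fraction 0.2, 400 generations max, 100 stall generations.
Design choices that were genuinely open:

* **Controlled elitism.** Environmental selection of the combined
  parent+offspring population caps rank-1 members at a Pareto fraction
  (0.35) of the population, filling the rest from dominated ranks. On this
  model the true front is *disconnected in gene space* (a small basin near
  zero NaOCl, H₂O₂ ≈ 9 %, HgCl₂ ≈ 0.09 %, ~13 min carries the
  highest-DE end), and a plain fully elitist population loses such basins;
  keeping dominated individuals alive preserves the needed diversity.
* **Archive.** An archive of all non-dominated evaluated points is
  maintained (thinned by crowding distance beyond `max_archive` members,
  since a continuous front makes the non-dominated set unbounded); the
  returned front is the archive's non-dominated set. Front hypervolume is
  then non-decreasing across generations by construction. With
  `max_generations = 0` the front is simply the rank-0 set of the initial
  population.
* **Hybrid refinement.** After the generational loop the front is polished
  (the customary hybrid stage of this solver family): a uniform
  exploration sample of the box (default 20 000 vectorized model
  evaluations) seeds basins too small for the population to find reliably;
  whole-front Gaussian jitter with shrinking steps polishes locally; and
  Nelder–Mead descents on the goal-attainment scalarization
  $\max_k (f_k(x) - z_k)/w_k$ — anchored at points spread along the front,
  started from each anchor and from its front neighbours (whose genes may
  lie in the basin the anchor's cannot reach) — iterate until no start can
  improve both objectives by 1 % of their spans. Across ten seeds this
  keeps every front member within 2 DE/NDE percentage units of a 20⁴
  brute-force grid front.
* **Stall rule.** Measured as the change in the front's mean finite
  crowding distance, tolerance $10^{-4}$, over 100 consecutive
  generations; the exact published stall metric is unknown.
* **Migration.** A migration fraction without subpopulations is
  meaningless, so it is stored but inert by default; `n_subpops = 2`
  enables ring migration of the best fraction every 20 generations.
* **Recommendation.** How the single published protocol was chosen from
  the front is not stated. The default rule picks the front member closest
  to the ideal point after min–max scaling both objectives over the front
  (ties toward lower NDE). A second named rule, `"target_de"` (lowest NDE
  within 5 % of the front's best DE), encodes the study's stated aim —
  full disinfection at the least damage — and is what the synthetic
  end-to-end benchmark uses, because on a genuinely conflicting surface
  the knee rule deliberately gives up DE for NDE. Both are pluggable.

A caution the optimizer inherits from the model: over the search box the
unclipped network reaches predicted DE ≈ 250 % and NDE ≈ −160 %. The
optimizer maximizes the *model*, extrapolations included — as any
black-box run on these fitness functions must, and as the published
optimum (predicted DE 126 %, NDE −73 % under the published weights)
confirms happened. Candidate protocols from the front are hypotheses for
wet-lab validation, not guaranteed rates.

## Synthetic ground truth

`true_surface()` is deliberately *outside* the MLP family, so pipeline
validation cannot succeed by shared model bias. Each chemical's effective
exposure saturates in time, $e_c = d_c\, t/(t + \tau_c)$; kill follows a
Hill curve per chemical combined by independent action,
$DE = 100\,(1 - \prod_c (1 - e_c^{h_c}/(e_c^{h_c} + EC50_c^{h_c})))$; and
phytotoxicity is one saturating Hill response to the toxicity-weighted
total exposure. Defaults were calibrated once to the study's per-chemical
response ranges over its tested grids (NaOCl DE 27–77 % with negligible
NDE; H₂O₂ DE 66–100 % with NDE 6–46 %; HgCl₂ strongest on both axes),
giving simulated ranges NaOCl 26–70/1–10, H₂O₂ 66–93/6–46, HgCl₂
75–96/17–88. One deliberate departure from the real assay: observed HgCl₂
kill is already total at the lowest tested dose, implying a cliff at tiny
concentrations; the generator keeps that cliff finite (Hill slope 1.2) so
the surface remains learnable by a moderate network. Observation noise is
additive Gaussian (default SD 5 percentage points) truncated to
$[0, 100]$ — observed percentages are bounded even though model
predictions are not.

What the generator does **not** emulate: contamination-type structure
(fungal vs bacterial), latent contamination, between-batch variation,
non-monotone dose responses (the real table shows occasional
non-monotonicity that the mechanistic surface cannot produce), and any
interaction between chemicals beyond independent action. Passing the
synthetic benchmarks therefore demonstrates that the *pipeline* works when
its assumptions hold, not that the fitted model is true of real explants.

## Problem sizes and numerical checks

The shipped checks run at sizes chosen to make their assertions sharp yet
quick: teacher-network recovery on 80 noise-free rows (validation MSE
$< 10^{-3}$); noise-free surface recovery on 600 random-design rows with a
4–14–2 network, scored at 300 held-out points ($R^2 > 0.99$ for both
outputs — the extra hidden units resolve the HgCl₂ cliff); the noisy
regime (SD 5) on 150 rows ($R^2 > 0.8$ held out, the regime of the
published fit); the end-to-end benchmark on 200 noise-free rows with a
150-generation optimizer run; and the grid oracle for the optimizer at
20⁴ model evaluations. Reproduction of the published predictions is exact
to the table's printed precision (0.005); the published DE RMSE recomputes
from the printed residual column to within the rounding of those
residuals ($10^{-3}$).

Two published quirks are preserved and flagged rather than corrected: row
T23's printed DE residual is inconsistent with its own actual and
predicted values, and the published NDE RMSE (13.52) and both R² values do
not recompute from the published table at printed precision under any
combination we tried (printed vs full-precision predictions, with or
without the control row). `reproduce_report()` prints recomputed and
published values side by side.

## Limitations

The 28-row table is small for a 72-parameter network; retrained models are
seed-sensitive and early stopping typically halts within the first dozen
epochs. The published weights are reproduced exactly, but the published
training split is unknown, so subset-level metrics are only comparable as
bands. The optimizer's recommendations inherit the surrogate's
extrapolation behavior, and the choice-of-one-protocol rule is a
documented convention, not a published fact.
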