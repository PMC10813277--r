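---
title: "Parametric reduced-order modelling for implant placement planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric reduced-order modelling for implant placement planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantrom)
```

## The problem

Whether a dental implant osseointegrates depends on the stress it transfers
into the cortical bone under mastication: overload at the first
screw-thread contact jeopardizes the bone-implant bond. A full 3-D
finite-element analysis (FEA) of one candidate placement is far too slow
for interactive planning, so the planning layer needs a *reduced-order
model* (ROM): a closed-form formula, fitted once to simulation data, that
returns the expected cortical von Mises stress for any candidate placement
in effectively zero time.

`implantrom` implements that pipeline end to end: the placement design
space, experimental designs over it, a deterministic stress emulator
standing in for the FEA solver, polynomial surrogate fitting with
genetic-algorithm term selection, single-factor sensitivity ranking, and
the real-time safety classifier.

## The design space

Six variables control the mechanical outcome, each with five grid levels
spanning its clinically used range:

| variable | unit | levels | role |
|---|---|---|---|
| implant length *L* | mm | 8.5, 10, 11.5, 13, 15 | longer implants spread load over more bone |
| implant diameter *D* | mm | 3.0, 3.5, 4.0, 4.5, 5.0 | wider implants increase contact area |
| cancellous modulus *E_c* | GPa | 0.5, 2.0, 4.5, 7.0, 9.5 | patient- and age-dependent bone quality |
| front–rear angle | ° | 0, 2.5, 5, 7.5, 10 | off-axis load component |
| left–right angle | ° | 0, 2.5, 5, 7.5, 10 | off-axis load component |
| cortical thickness *t_c* | mm | 1.5, 1.75, 2.0, 2.25, 2.5 | outer-shell geometry |

A fixed 100 N masticatory load is applied at the abutment. The tooth region
(anterior / premolar / posterior; typical cortical thickness 1.5 / 2.0 /
2.5 mm) enters as a categorical tag — one surrogate per region — rather
than as a seventh continuous variable, because the regional geometries
differ in shape, not merely in a parameter. Placement angles are treated as
magnitudes (0–10°): the in/out and left/right senses produce one stress
value per magnitude in the reference data. The reference (baseline)
placement is *L* = 11.5 mm, *D* = 4.0 mm, *E_c* = 7.0 GPa, both angles 0°,
*t_c* = 1.5 mm.

`validate_config()` accepts any placement inside the variable ranges —
off-grid queries are the normal use of a surrogate — and rejects anything
outside them.

## Experimental designs

`taguchi_l25()` generates the L25(5⁶) orthogonal array that reduces the 5⁶
= 15,625-point grid to 25 runs. We use the two-generator construction over
GF(5): with (a, b) running over {0..4}² in row-major order, the six columns
are a, b, a+b, a+2b, a+3b, a+4b (mod 5). Because the six coefficient pairs
are pairwise linearly independent over GF(5), every ordered pair of levels
of every pair of columns occurs exactly once — the defining orthogonality —
and the construction is reproducible without a lookup table. Any assignment
of array columns to variables is statistically equivalent for main effects;
we fix the order (L, D, E_c, θ_fr, θ_lr, t_c) for determinism.
`full_factorial()` provides the complete grid when budget allows.

## The anchored stress emulator

Desk-scale development needs a stand-in for the FEA solver. The emulator is
*anchored*: for each variable it stores the published five-point
single-factor sweep of cortical stress (all other variables at baseline),
and every sweep shares the 13.81 MPa baseline value. Within a sweep we
interpolate piecewise-linearly between the five anchors — a shape-preserving
choice: the cortical-thickness sweep is genuinely non-monotone (13.81,
9.26, 17.22, 10.04, 11.58 MPa; thicker cortex spreads load but shrinks the
cancellous support, two offsetting effects), and a spline would overshoot
it. No extrapolation beyond the grid is allowed.

Across variables the response composes multiplicatively in ratios to the
baseline:

σ(x) = scale(region) · σ₀ · ∏ᵢ fᵢ(xᵢ)/σ₀,  σ₀ = 13.81 MPa.

No joint-variation reference values exist, so any composition is a
modelling choice; the multiplicative rule is the simplest one that
reproduces **all six** single-factor sweeps exactly. Its side effect is a
wide dynamic range over the joint space (soft bone × large tilt compounds
to hundreds of MPa), which is worth remembering when judging surrogate
quality below. `region_scale` defaults to 1 for all regions, since the
anchor sweeps come from a single geometry.

Two companion channels exist purely so pipelines can exercise a
three-output result: implant stress = 2.0 × cortical stress and deformation
= 0.01 · σ/E_c (mm). Both scalings are synthetic — no reference tables
exist for those channels — and are configurable; nothing downstream treats
them as physical.

The optional noise channel multiplies each output by an independent
lognormal factor with unit median and coefficient of variation `noise_cv`:
multiplicative noise preserves positivity of stresses, and the unit median
keeps the deterministic value the central one. It is seeded and
reproducible.

## Surrogate fitting and GARS

`fit_polynomial()` fits a polynomial in the design variables by ordinary
least squares. Variables are affinely mapped to [−1, 1] over their
design-space range first: the raw units span three orders of magnitude
(0.5 GPa vs 15 mm) and unnormalized polynomial bases are badly conditioned.
Basis terms are enumerated canonically (by total order, then
lexicographically with earlier variables more significant), so a model is
identified by its exponent vectors alone; the order-2 basis with
interactions over six variables has 1 + 6 + 6 + 15 = 28 terms.

Two quality metrics are reported:

- **CoD** (coefficient of determination): in-sample explained variance,
  Σ(ŷ−μ_y)²/Σ(y−μ_y)², equal to 1 − SS_res/SS_tot for OLS with intercept.
  For non-OLS predictors the residual form is used and clamped to [0, 1]
  with a flag.
- **CoP** (coefficient of prognosis): the cross-validated squared Pearson
  correlation between held-out observations and predictions, pooled over
  all folds. Pooling one correlation (rather than averaging per-fold
  correlations) keeps the statistic defined for singleton folds. The
  default partition is leave-one-out for n ≤ 30 (the L25 case) and 5-fold
  above; negative degenerate cases are clamped to 0. CoD measures how well
  the surrogate *describes* its training data; CoP measures how well it
  *predicts* new points, which is what a planning tool needs.

`gars_select()` searches for a robust term subset: a genetic algorithm over
inclusion bit-strings on the non-intercept candidate terms (the intercept
is always kept), with the LOO CoP of the restricted OLS fit as fitness. A
full interaction basis on a 25-run design overfits badly; selecting the
subset by *prognosis* rather than in-sample fit is the point of the method.
The GA hyperparameters are not prescribed anywhere, so we use standard
small-GA settings chosen once: population 40, 60 generations, binary
tournament selection (size 2), uniform crossover at 0.9, bit-flip mutation
at 1/chromosome-length, elitism 2. Ties are broken toward fewer terms, then
the lexicographically smallest chromosome, making the search deterministic
given its seed. Oversized subsets (more terms than training rows) are
penalized rather than fitted. LOO fitness is computed with the exact OLS
hat-matrix identity ŷ₍₋ᵢ₎ = yᵢ − eᵢ/(1−hᵢᵢ) — one QR factorization per
chromosome instead of n refits — and the test suite verifies it against a
literal refit loop. Support-vector and neural-network backends satisfy the
same fit/predict/quality contract conceptually but are out of scope here;
the subset-selection route is the one with reproducible behaviour.

A fitted model serializes to versioned JSON (`save_rom()` / `load_rom()`)
with exponent vectors, coefficients, normalization, quality and provenance,
and round-trips with bit-identical predictions.

### What surrogate quality to expect on the emulator

Because the emulator is multiplicative, its *log* response is exactly
additive in six univariate functions, each supported on five grid points —
i.e. exactly representable by pure powers up to order 4 per variable. Two
consequences the tests exploit: an order-4 pure-power fit (25 terms) to
log-stress on the L25 design recovers the emulator exactly at the baseline;
and raw-scale quadratics plateau around CoD ≈ 0.89 on space-filling
designs — the steep 1/E-like *E_c* factor is not quadratic. Real FEA
responses will differ; passing these tests shows the machinery is correct,
not that a quadratic suffices for real bone.

## Sensitivity analysis

`single_factor_sweep()` reproduces the one-variable-at-a-time experiments:
five grid evaluations with the other variables at baseline. The influence
statistic is the relative stress range 100·(max−min)/max — scale-invariant
and bounded in [0, 100). On the anchored emulator the sweeps give 30.0 %
(length), 57.9 % (diameter), 71.9 % (*E_c*), 42.5 % (front–rear), 42.0 %
(left–right); cortical thickness is excluded as having *no clear trend*,
operationalized as non-monotonicity across the five grid points. The
resulting influence order — *E_c* > diameter > front–rear > left–right >
length — holds whether computed from rounded or unrounded percentages.
Single-factor ranges compare variables on different physical scales, so the
ranking carries that caveat; it is a screening statistic, not a
variance-based global sensitivity index (Sobol methods are out of scope).

```{r}
sensitivity_report(anchored_emulator())
```

## The planner

`assess_placement()` applies the safety rule: a placement is **green** iff
its predicted cortical stress is strictly under the threshold (default
40 MPa), else **red**. Exactly 40 MPa is red — "under" is read strictly;
the boundary case is otherwise unspecified and a conservative reading is
the safe default. The threshold applies to whatever predictor the caller
supplies (emulator or fitted ROM); `model_id` records which one. An
optional `bands` argument exposes a finer gradation (e.g. safe / caution /
danger) consistent with the two-band rule. `batch_assess()` is the
fault-tolerant batch variant: invalid rows are reported by index as
warnings while the remaining candidates are still assessed. Prediction
through a fitted model is a constant-time polynomial evaluation, so
interactive use never waits on a simulation.

```{r}
soft <- baseline_config()
soft$cancellous_modulus <- 0.5
assess_placement(soft, anchored_emulator())[, c("cortical_stress_MPa", "status")]
```

## Numerical and design choices

- **Interpolation**: piecewise-linear, exact at anchors, bracketed between
  them; no extrapolation anywhere in the emulator.
- **Degenerate inputs**: zero-variance responses are rejected by `cod()`;
  constant pooled predictions give CoP = 0 by convention; rank-deficient
  bases are rejected naming the collinear terms; folds smaller than the
  term count fall back to the largest admissible nested basis and flag the
  report.
- **Determinism**: designs are generated, not sampled; every stochastic
  step (k-fold partitions, noise draws, the GA) takes an explicit seed and
  restores the caller's RNG state.
- **Problem sizes**: the test suite runs the L25 design (n = 25), random
  in-range designs of n = 6–80, GA populations of 10–40 over 5–40
  generations, and 20-seed replications for the statistical properties —
  sizes at which every check completes in seconds while still exercising
  the asymptotics that matter (LOO vs refit equality is exact at any n;
  orthogonality is exact by construction).

## Limitations

- The emulator's multiplicative composition is a modelling assumption; real
  joint FEA responses can interact differently. Everything anchored to
  published single-factor data is exact; everything joint is emulation.
- The implant-stress and deformation channels are synthetic scalings, for
  pipeline plumbing only.
- Published end-to-end surrogate-quality figures for the full FEA dataset
  cannot be reproduced here because that dataset is not public; the test
  suite instead proves the quality machinery correct by property (oracle
  equivalence, structure recovery, noise monotonicity).
- Sensitivity is single-factor; no variance-based global indices.
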