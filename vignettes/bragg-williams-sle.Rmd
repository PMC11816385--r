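---
title: "Modeling binary solid-liquid equilibria with a single-parameter Bragg-Williams model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling binary solid-liquid equilibria with a single-parameter Bragg-Williams model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwsle)
```

## The model

Consider two substances A and B that are fully miscible as liquids and
immiscible as solids — the situation behind simple eutectic phase
diagrams, including the non-ionic ("type V") deep eutectic solvents
formed by terpenes and fatty acids. At the liquidus, the solid of one
pure compound coexists with the liquid mixture. For an **ideal** liquid
(zero mixing enthalpy) the equilibrium condition integrates to the
Schröder–van Laar form for the branch of compound A:

$$\frac{1}{T} = \frac{1}{T_{m,A}} - \frac{R\,\ln x_A}{\Delta H_{m,A}},$$

with $T_{m,A}$ the pure melting temperature, $\Delta H_{m,A}$ the molar
enthalpy of melting, and $R = 8.31446\ \mathrm{J\,mol^{-1}K^{-1}}$. The
melting-point depression is purely entropic. The derivation assumes the
enthalpy of melting is temperature-independent ($\Delta c_p \approx 0$);
no heat-capacity correction is offered anywhere in the package.

The **Bragg–Williams** (regular-solution) lattice model adds one
interaction term. Each molecule makes $z$ contacts, contacts occur in
proportion to mole fractions, and replacing like contacts by an unlike
contact changes the energy by $w = E_{AB} - E_{AA}/2 - E_{BB}/2$. Only
the product $zw$ is identifiable, and it is the model's single
parameter. The partial molar mixing enthalpy of A becomes
$(1-x_A)^2\,zw$ (`excess_mixing_enthalpy()`), and the branch equation
picks up one term:

$$T_A(x) \;=\; \frac{1 + \dfrac{zw}{\Delta H_{m,A}}(1-x)^2}
                   {\dfrac{1}{T_{m,A}} - \dfrac{R}{\Delta H_{m,A}}\ln x}.$$

`zw = 0` reduces to the ideal branch exactly. Negative `zw` (a more
favorable mixture) depresses the whole liquidus and deepens the
eutectic; positive `zw` raises it. The liquidus at any composition is
the **higher** of the two branch temperatures, and the eutectic is the
branch crossing — the global minimum of the liquidus.

```{r curve}
reg <- bw_compounds()
pair <- binary_pair(compound(reg, "Menthol"), compound(reg, "Lauric acid"))
curve <- liquidus_curve(bw_model(pair, zw = -8000))
curve
eutectic_point(bw_model(pair, zw = -8000))
```

## Estimating zw

Because the model has one parameter, a single interior melting point
$(x_A, T)$ determines it by algebraic inversion:

$$zw = \frac{\Delta H_{m}\,(T/T_{m} - 1) - R\,T \ln x}{(1-x)^2},$$

evaluated once with A's data at $x_A$ and once with B's data at
$1 - x_A$. The numerically smaller of the two is kept
(`estimate_zw_from_point()`): the larger value would place the *other*
compound's branch above the measured temperature, contradicting the
measurement lying on the liquidus. On noise-free liquidus points this
rule recovers the generating `zw` exactly, branch flips included — a
property the test suite exercises by composing the generator with the
inversion.

`fit_zw_grid()` fits all points at once: candidate `zw` values on a
regular grid (default $-100$ to $100$ kJ/mol in steps of 0.1 kJ/mol)
are scored by the average absolute deviation (AAD, in K) between the
model liquidus — branch maximum evaluated *directly at each measured
composition*, never interpolated from a display grid — and the
measurements, and the minimizer is returned. Design choices made here,
since a grid scan plus a reported AAD does not pin everything down:

* **Objective**: the AAD itself is minimized, consistent with the
  quantity reported.
* **Ties** are broken toward the smallest $|zw|$ — parsimony toward the
  ideal model.
* The default grid contains 0, so the fitted AAD can never exceed the
  ideal-solution AAD.
* An optional golden-section **refinement** of the continuous objective
  around the grid optimum exists but is off by default, keeping the
  default protocol an exact grid scan.

```{r fit}
ds <- generate_dataset(synthetic_spec(pair, zw_true = -15000,
                                      n_points = 15, noise_sd = 1, seed = 7))
fit_zw_grid(ds)
```

## Error propagation

Each per-point estimate carries an uncertainty obtained by exact
differentiation of the inversion with respect to one error source
(`zw_error_from_temperature()`, `zw_error_from_enthalpy()`,
`zw_error_from_tm()`):

$$\Delta zw_{(T)} = \frac{\Delta H_m/T_m - R\ln x}{(1-x)^2}\,\Delta T,
\qquad
\Delta zw_{(\Delta H)} = \frac{|T/T_m - 1|}{(1-x)^2}\,\Delta(\Delta H_m),
\qquad
\Delta zw_{(T_m)} = \frac{\Delta H_m\,T/T_m^2}{(1-x)^2}\,\Delta T_m.$$

All three diverge as $(1-x)^{-2}$ toward the pure ends: points near
$x_A = 0$ or $1$ are nearly uninformative about `zw`, and the package
returns their large errors as computed rather than clipping them. The
measured temperature and the branch chosen by the smaller-`zw` rule
enter the formulas. Defaults for the magnitudes (5 K on $T$, 5 kJ/mol
on $\Delta H_m$, 5 K on $T_m$) are common analysis assumptions for
melting data, not measured noise levels; each source is propagated
separately, never combined in quadrature.

In the opposite direction, the liquidus temperature responds to a
parameter error as
$\Delta T = (1-x)^2\,T_{id}(x)\,\Delta zw/\Delta H_m$
(`curve_sensitivity()`), which is bounded on the whole interior — the
curve itself has no singular sensitivity, which is why fitting many
points is preferable to inverting one.

Per-point estimates are combined by `weighted_mean_zw()` with
inverse-variance weights; its uncertainty is the standard error of the
inverse-variance weighted mean, $1/\sqrt{\sum \sigma_i^{-2}}$ (one of
several defensible conventions; chosen because it is standard and
stated in the report schema).

```{r perpoint}
zw_point_estimates(ds)
```

## The synthetic-data generator

`generate_dataset()` emulates what a melting-point experiment measures:
compositions placed on a grid (or uniformly at random) inside
`x_range`, temperatures read off the *liquidus* of a known model —
the branch maximum, not a single named branch, so the estimator's
branch-selection rule is genuinely exercised — plus additive Gaussian
noise on the temperature only. Compositions are treated as exact:
mixtures are prepared gravimetrically and composition error is
negligible next to temperature error. Defaults, chosen once:
`x_range = c(0.05, 0.95)` (real datasets rarely probe closer to the
pure compounds), `noise_sd = 1` K (a typical reading uncertainty;
deliberately smaller than the 5 K used as a worst-case assumption in
the error bars), `design = "uniform-grid"`.

What the generator does *not* emulate: DSC peak broadening,
supercooling and metastability, solid solubility, polymorphism,
composition-dependent noise. Passing recovery tests therefore shows the
estimation machinery is correct under the model's own assumptions, not
that the model describes any particular real mixture.

`recovery_experiment()` repeats generate-then-estimate over seeded
replicates (replicate $i$ reseeds with
$(\text{seed} + 104729\,i) \bmod 2147483629$, so experiments replay
exactly) and reports bias, RMSE and the coverage of the weighted-mean
interval:

```{r recovery}
recovery_experiment(synthetic_spec(pair, zw_true = -20000, n_points = 20,
                                   noise_sd = 2, seed = 11),
                    n_replicates = 20)
```

The suite's Monte-Carlo checks use 40–200 replicates at 10–40 points —
small enough to run in seconds, large enough that the sampling error of
an RMSE comparison is well below the effects being asserted.

## Numerical choices and degenerate inputs

* **Grid convention.** "n equally spaced compositions between 0 and 1"
  is realized as the interior points $x_i = i/(n+1)$: the log term is
  singular at $x = 0$ and the endpoints are known analytically. The
  $x = 1$ limit is returned as $T_m$ exactly (assigning the analytic
  limit rather than evaluating $1/(1/T_m)$, which loses an ulp).
* **Nonphysical branches.** For strongly negative `zw` the closed
  form's numerator can reach zero or below; such points get an explicit
  `NA` marker, never a negative temperature. A branch that is
  nonphysical at a composition simply cannot be the liquidus there;
  only if *both* branches are nonphysical somewhere does the model
  error out (naming the offending `zw`).
* **Eutectic refinement.** Grid minimum first, then bisection on the
  branch difference $T_A(x) - T_B(x)$, which is continuous and locally
  monotone for the simple diagrams in scope; default tolerance
  $10^{-6}$ K. If the branches never cross (one compound dominates the
  whole range) the boundary-adjacent grid minimum is returned and
  flagged.
* **Boundary data points.** Points within $10^{-6}$ of $x = 0$ or $1$
  load fine but are excluded from estimation with a warning — the
  $(1-x)^{-2}$ factors make them singular.
* **Units.** Files and reports carry K and kJ/mol; all internal
  arithmetic is in J/mol. Conversion happens only at the I/O boundary.

## Limitations

The model assumes equal contact numbers for both species (restricting
it, in principle, to similar-sized molecules), random mixing, immiscible
solids, and a simple two-branch phase diagram. Polymorphism, solid
solutions, peritectics, ionic systems with dissociation and long-range
electrostatics, and ternary mixtures are all out of scope. `zw`,
although introduced as an enthalpic quantity, absorbs *all* deviations
from ideality, entropic ones included; it is a descriptive summary of
the mixture's non-ideality, not a pure contact energy.
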