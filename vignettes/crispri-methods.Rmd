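---
title: "Models and methods behind crispri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crispri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispri)
```

This vignette is the package's own account of the science it implements:
the binding-equilibrium model of CRISPRi repression and how it is solved,
how microplate kinetics are reduced to per-cell synthesis rates, how Hill
stages are fitted and composed into logic circuits, and what the
synthetic-data generator does and does not emulate. It also records the
numerical and design choices that were genuinely open, and the known
limitations.

## The binding equilibrium

CRISPR interference represses a promoter through two sequential binding
steps: catalytically dead Cas9 (`C`) loads a single guide RNA (`g`) to form
the repressor complex `C:g`, and the complex occupies the target promoter
(`D`) to form the transcriptionally silent `C:g:D`. Expression, degradation
and dilution are slow compared with binding, so the bound fractions are
taken at mass-action equilibrium, parameterized only by the two
dissociation constants

$$K_1 = \frac{[C][g]}{[C{:}g]}, \qquad K_2 = \frac{[C{:}g][D]}{[C{:}g{:}D]},$$

and the conserved totals $C_{tot}, g_{tot}, D_{tot}$. Eliminating the
complexes gives a three-variable implicit system in the free
concentrations,

$$C = \frac{C_{tot}}{1 + g/K_1 + gD/(K_1 K_2)}, \quad
  g = \frac{g_{tot}}{1 + C/K_1 + CD/(K_1 K_2)}, \quad
  D = \frac{D_{tot}}{1 + gC/(K_1 K_2)},$$

and the reporter output is $R = \theta D$: the repressed promoter is
assumed fully silent, and $\theta$ lumps transcription, translation,
fluorophore maturation, degradation and dilution into a single gain. All
concentrations are in nM; in *E. coli* 1 nM corresponds to roughly one
molecule per cell, so plasmid copy numbers can be used directly as
$D_{tot}$. Defaults are $K_1 = 0.3$ nM and $K_2 = 2$ nM —
biologically plausible affinities for sgRNA loading and DNA
interrogation — and $\theta = 1$, since no measurement in the package's
scope pins down the absolute gain; outputs default to the free-promoter
fraction $D/D_{tot}$ instead.

### Fixed-point solver

`solve_equilibrium()` iterates the three update equations sequentially in
the order $C$, $g$, $D$, each update using the latest values, starting
from the all-free state $(C_{tot}, g_{tot}, D_{tot})$. The iteration
contracts toward the unique physical root throughout the tested box
($10^{-2}$–$10^4$ nM in every total). Convergence is declared when the
largest relative change across $(C, g, D)$ falls below `tol` (default
$10^{-9}$, well inside the $10^{-8}$ conservation budget); if the
undamped iteration ever fails to contract for three consecutive steps it
is restarted with a damping factor of 0.5, and if `max_iter` (default
$10^5$) is exhausted the nested-bisection solver takes over and the state
is flagged `converged = FALSE`. The degenerate inputs $g_{tot} = 0$ or
$C_{tot} = 0$ are answered analytically — no complex can form — which
also avoids the $0/0$ in the explicit limit expression below.

### Independent verification route

Because the fixed-point route is iterative, the package carries a second,
structurally different solver used as ground truth in the tests.
Substituting $x = [C{:}g]$, $y = [C{:}g{:}D]$ reduces the system to

$$K_1 x = (C_{tot}-x-y)(g_{tot}-x-y), \qquad K_2 y = x\,(D_{tot}-y).$$

For fixed $y$ the first equation is a quadratic whose physical root has a
cancellation-free closed form, and the residual of the second equation is
strictly increasing in $y$, so bisection on
$y \in [0, \min(C_{tot}, g_{tot}, D_{tot})]$ converges to near machine
precision. The two solvers agree in free DNA to better than $10^{-6}$
relative error over a 1000-point Latin-hypercube of totals, which the
test suite and `scripts/acceptance.R` both recompute.

### The explicit limit

Under $g \gg C \gg D$ the output admits the Michaelis–Menten-style closed
form implemented by `explicit_output()`,

$$R = \frac{\theta D_{tot}}{1 + \dfrac{C_{tot}/K_2}{1 + \dfrac{1}{g_{tot}/K_1}}},$$

evaluated internally as
$\theta D_{tot} / (1 + (C_{tot}/K_2)\, g_{tot}/(g_{tot}+K_1))$ so
$g_{tot} = 0$ is a regular point. Inside the regime
$g_{tot} \ge 100\,C_{tot}$, $C_{tot} \ge 100\,D_{tot}$ it tracks the full
solve within 2%; outside it can be badly wrong — that is precisely the
motivation for the implicit model, whose repression curves shift with DNA
copy number rather than merely rescaling.

### Switch points and the dCas9-limited regime

`switch_point()` reports the input at which a transfer curve crosses a
given fraction of its *output range* (default one half), interpolating
log-linearly between grid points. Defining the level relative to the
curve's own range keeps the quantity meaningful for incompletely
repressed curves. Two model behaviours are worth spelling out because the
package's checks rely on them:

* Where repression does cross half the unrepressed output, the
  half-repression point in $g_{tot}$ moves to *higher* sgRNA as
  $D_{tot}$ grows: more promoter copies titrate the repressor complex,
  so strains differing only in target copy number have genuinely
  different curve shapes, not rescaled copies of one curve.
* When dCas9 is scarcer than its DNA target (e.g. $C_{tot} = 1$ nM
  against $D_{tot} \ge 1$ nM at $K_2 = 2$ nM), repression saturates far
  above one half — `sweep_transfer_curve()` shows floors of
  $D/D_{tot} \approx 0.73$–0.99 — and no half-repression point exists.
  In that corner the residual trend even inverts: extra DNA accelerates
  engagement of the limiting complex. Ordering checks on switch points
  are therefore evaluated over the panels where the half-repression
  point is defined.

The related floor property — saturating dCas9 cannot complete repression
when sgRNA is scarce (e.g. $D/D_{tot} > 0.9$ at $g_{tot} = 10$ nM,
$D_{tot} = 100$ nM for any $C_{tot}$ up to $10^4$ nM) — is recomputed by
the acceptance script against both solvers.

## Microplate kinetics reduction

`process_plate()` turns raw OD600/fluorescence time series into growth
rates and per-cell synthesis rates:

1. **Background.** Every channel has the time-pointwise mean of the
   blank-medium wells subtracted. Fluorescence channels are additionally
   corrected with an autofluorescence-control strain, interpolated as a
   function of corrected OD600 rather than time, because cellular
   autofluorescence scales with biomass. ODs outside the control's range
   are clamped to the nearest control OD (with a warning once the
   excursion exceeds 2% of the control's span); negative corrected
   values are clipped to zero and counted. The exact correction recipe
   is a package decision — standard practice for plate readers — and
   both corrections can be disabled per run.
2. **Exponential window.** The longest contiguous stretch with OD between
   5% and 50% of the series maximum whose log-linear fit reaches
   $R^2 \ge 0.99$ with at least 5 points; ties go to the earlier window.
   The band excludes both the detection floor and the approach to
   stationary phase, and plateau points appended after saturation do not
   change the selection.
3. **Growth rate.** $\mu$ is the OLS slope of $\ln(\mathrm{OD})$ against
   time in hours within the window, with $R^2$ reported.
4. **Synthesis rate.** $S(t) = (dF/dt)/\mathrm{OD}(t)$ with a
   central-difference derivative (one-sided at the ends); points with OD
   below 0.01 are masked. No smoothing is applied by default; an
   odd-width moving-average is available behind the `smooth` flag.
   $S_{ave}$ is the mean of $S(t)$ over the same well's exponential
   window, and $S_{cell} = S_{ave}/S_{ave,\mathrm{ref}}$ normalizes to a
   channel-matched constitutive reference strain measured on the same
   plate (distinct reference strains for RFP and GFP). Replicates are
   aggregated as mean ± standard error at the $S_{cell}$ level.

Units: input time in minutes, $\mu$ in h$^{-1}$, $S$ in
AU·OD$^{-1}$·min$^{-1}$ (the units cancel in $S_{cell}$).

## Hill stages and circuit composition

Each regulatory stage is a four-parameter Hill function — activation
$y = b + r\,x^n/(K_m^n + x^n)$, repression $y = b + r/(1 + (x/K_m)^n)$ —
evaluated through the ratio form that is exact at $x = 0$ and safe under
overflow. `fit_stage()` minimizes squared residuals on the log scale,
$\log(y + \varepsilon)$ with $\varepsilon = 10^{-6}\max(y)$, because
circuit outputs span decades and a linear scale would fit only the ON
state. Parameters live on the log scale inside the optimizer (positivity
is structural), Levenberg–Marquardt does the minimization, and eight
deterministic starts spread $K_m$ over the observed input decades with
Hill coefficients cycling through 1, 2, 0.5 and 4; the best residual
wins and ties break toward the smaller $n$ — the less cooperative
explanation. Random restarts are deliberately avoided so a fit is a pure
function of its data; seeds only ever enter data generation.

Circuits compose fitted stages without joint refitting, mirroring how the
stages are characterized experimentally — in isolation, each with its own
input proxy:

* **Cascade**: stage outputs feed the next stage's input; an even number
  of ideal repressions is non-decreasing in the input, an odd number
  non-increasing.
* **CRISPRi NOT gate**: an activation stage maps inducer to total sgRNA,
  which drives the full binding equilibrium; the stage output is
  $R = \theta D$. This keeps the mechanistic copy-number dependence that
  a phenomenological Hill inverter would flatten.
* **NOR gate**: two repressors with overlapping operator sites bind
  mutually exclusively, so the package multiplies the normalized
  repression terms, $y = b + r\,f_1(x_1)\,f_2(x_2)$, rather than taking
  their minimum; the shared promoter's $b$ and $r$ default to the means
  of the two fitted stages' values. The multiplicative form is a
  modelling choice (the min-based alternative is steeper around the
  switch) and is flagged as such.

## The synthetic-data generator

`generate_plate()` and `generate_curve()` produce every input the
pipeline consumes, with the generating truth saved alongside, so the
whole chain is testable without instrument files.

* **Growth** is lag → exponential → logistic deceleration: OD grows
  exponentially at `mu_true` until half the carrying capacity, then
  follows a slope-matched logistic to the plateau. Substrate-limited
  batch growth is close to exponential until nutrients run short, and a
  curve with a genuine exponential phase is what the log-linear
  reduction is entitled to assume; a pure logistic — which decelerates
  from the first doubling — would make the generator's own "growth
  rate" an ill-defined target for any exponential-phase estimator.
  Defaults: $\mu = 0.6$ h$^{-1}$ (doubling ≈ 70 min, *E. coli* in M9),
  capacity OD 0.7, 60 min lag, initial OD 0.01, 5-min sampling over
  15 h.
* **Fluorescence** accumulates as the running integral of
  $s_{true} \times \mathrm{OD}$, so the derivative-based reduction
  recovers $s_{true}$ exactly in the noise-free case. Maturation delay
  and dilution of the fluorophore pool are deliberately ignored,
  consistent with a steady-state synthesis-rate readout.
* **Noise and background** are additive channel backgrounds (OD 0.09;
  RFP 30, GFP 50 AU) plus mean-one multiplicative lognormal noise on
  every measurement (default CV 2% for plates, 10% for transfer curves,
  the plate-reader and biological-replicate scales respectively). Blank
  wells carry background only. Identical seed and configuration give
  byte-identical files.
* **Layout**: 24 wells — 3 blanks, 3 autofluorescence controls, 3 + 3
  channel-specific reference wells, and 4 sample strains in triplicate
  spanning $S_{cell}$ ratios 0.25–2.5.
* Transfer-curve grids default to the inducer assay ranges (HSL
  0.1–500 nM, IPTG 0.1–100 µM, each plus a zero point).

What passing round-trip tests show is that the *reduction pipeline* is
faithful under these mechanisms; they do not show robustness to what the
generator omits — burden feedback of expression on growth, maturation
kinetics, evaporation drift, or cell-to-cell variability.

## Problem sizes and tolerances in the checks

The test suite and `scripts/acceptance.R` use sizes chosen to exercise
the full parameter box at interactive runtimes: a 1000-point Latin
hypercube for solver agreement (relative $10^{-6}$) and residuals
(relative $10^{-8}$), 200 swapped pairs for exchange symmetry, a
100-point regime grid for the explicit limit (2%), the 4 × 3 panel grid
for switch-point ordering, one 24-well plate per noise level (1%
noise-free, 5% at 2% CV), and 100 seeded repetitions of the 8-point,
3-replicate, 10%-noise fitting experiment (median $|K_m|$ error ≤ 10%,
median $|n|$ error ≤ 15%).

## Known limitations

* Steady-state only: no kinetics of binding, induction transients, or
  time-resolved repression.
* One sgRNA species: competition of multiple guides for dCas9 is not
  modelled.
* The repressed promoter is assumed fully silent; leaky transcription
  would add a floor to $R$ that $\theta D$ cannot represent.
* $S_{cell}$ inherits the reference strain's plate-to-plate variability;
  comparisons across plates assume the reference behaves identically.
* The NOR composition is phenomenological; a mechanistic treatment of
  two repressors on one promoter would need their joint occupancy
  statistics.
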