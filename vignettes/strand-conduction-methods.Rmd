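---
title: "Multiscale models of gap-junction mediated strand conduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale models of gap-junction mediated strand conduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gjcable)
```

## The problem

Electrical impulses in cardiac muscle travel through cell interiors
(fast, Ohmic) and across gap junctions at the intercalated discs (slow,
and strongly non-Ohmic: the junctional conductance depends on the
transjunctional voltage `Vj`, with the dependence set by the connexin
composition of the channel). Tissue-scale simulators almost universally
replace this microstructure with a constant effective conductivity, which
is accurate at normal coupling but mispredicts conduction when junctional
coupling is reduced — precisely the pathological regime of interest.

`gjcable` implements four models of a 6.4 mm strand of cylindrical
myocytes (radius 11 µm, length 100 µm, intercalated-disc length ratio
`delta = 1e-4`), all driven by Luo–Rudy phase-I (1991) membrane kinetics:

* `cm_clamped` — a discrete circuit chain, 10 subcellular nodes per cell,
  junction conductance fixed at `beta * g_jo`;
* `cm_gated` — the same chain with `beta * g_jo * g_j(Vj)`;
* `lhm` — a linear homogenized cable with the constant laminate
  conductivity `1/((1-delta)/sigma_c + 1/(beta*sigma_g))`;
* `nohm` — a non-Ohmic homogenized cable whose effective conductivity
  `sigma(y)` depends on the local potential gradient through an implicit
  fixed-point relation that upscales `g_j`.

`beta` (the gap-junctional coupling fraction) scales the maximal junction
conductance `g_jo` = 2.534 µS; `beta = 1` is normal coupling and
`beta << 1` models uncoupling disease.

## Conductance laws

Two limiting regimes of the junction's gating dynamics are provided.
The *instantaneous* law (conductance right after a voltage step) is, per
polarity branch, proportional to `2*cosh(Vj/VH) - 1`, normalized by its
`Vj = 0` value so that `g(0) ≈ 1`. The *steady-state* law (after full
gating relaxation) is a Boltzmann distribution
`g = (1-gmin)/(p + exp(A*(Vj - Vj0))) + gmin`, with negative-polarity
parameters on `Vj <= d` and positive-polarity parameters on `Vj > d`;
`A = z/kT` with `kT = 25.7` meV. Parameters for Cx43-Cx43, Cx45-Cx45 and
the asymmetric heterotypic Cx43-Cx45 channel are built in
(`channel_spec()`); the heterotypic steady-state curve is strongly
asymmetric in `Vj`, which is what makes conduction direction-dependent.

Two printed conventions required a reading choice. The steady-state
branch superscripts are assigned so that the negative-polarity parameters
govern `Vj < d` — the published bell shapes and continuity at `Vj = d`
(1.291 vs 1.294 for Cx43-Cx45) confirm this assignment; the as-printed
assignment would give a flat `g ≈ 1` for all negative `Vj`. The
instantaneous expression is read as a per-branch sum of two exponential
fractions that simplifies to `2*cosh - 1` and is normalized by its value
at 0, consistent with "normalized conductance" axes and with all four
models agreeing at full coupling.

```{r gj-curves, fig.width = 6, fig.height = 3.5, eval = FALSE}
plot_gj_curve("Cx43-Cx45")
```

## Homogenization

The effective conductivity of the cytoplasm/disc laminate under a
voltage-insensitive junction is the exact harmonic mean
(`lhm_sigma()`). With a voltage-dependent junction the upscaled relation
becomes implicit (`nohm_sigma()`):

    sigma(y) = sigma_c * B / (sigma_c/sigma_g + (1 - delta) * B),
    B        = beta * g_j(S * eps * N(y)),
    N(y)     = -(1 - delta) * (sigma(y)/sigma_c - 1) * y,

where `y` is the macroscopic potential gradient (mV/mm), `N` the junction
jump density, and `S = 2` a fixed jump-scaling factor. The solver is a
damped fixed-point iteration started from the linear value (tolerance
`1e-10 * sigma_c`, 200 iterations), with a bisection fallback on the
scalar residual over `(0, sigma_c]`. The steady-state laws make the map
non-contractive at large `|y|` and the residual can have several zeros;
`sigma_table()` therefore marches outward from `y = 0` reusing each root
as the next starting value, selecting the branch continuous from zero
gradient. The default table spans ±2000 mV/mm at 1 mV/mm spacing with
linear interpolation; queries outside fall back to direct solves.

`micro_strand_steady()` is a validation oracle that bypasses
homogenization entirely: it solves the series circuit of `n` cells
(cytoplasmic resistors in series with non-linear junction elements) by
1-D root finding with continuation from zero current. For a clamped
junction it reproduces the linear value to root-finder precision; for
gated junctions it reproduces `sigma(y)` at the applied mean gradient,
and its potential profile converges to the linear macroscopic profile at
first order in the cell length.

## Membrane kinetics

The Luo–Rudy phase-I parameter set ([K]o = 5.4 mM; six currents, six
gates, one calcium pool) is taken from the original 1991 publication.
The resting state is not prescribed anywhere; `lr1_rest_state()` defines
it by relaxing an isolated membrane for 20 s (residual total current
< 1e-2 µA/cm², resting potential −84.55 mV) and caches the result.
Membrane current densities are µA/cm² at the membrane and are converted
once (× 0.01) to the solvers' µA/mm². Internal units throughout are mm,
ms, mV, mS/mm (1 mS/mm = 1 S/m), µF/mm²; the surface-to-volume ratio is
`Am = 2*RCG/r_cell ≈ 363.6 /mm` with `RCG = 2`, and `Cm` = 1 µF/cm².

Inside the strand solvers the gate rates and the voltage-dependent
current factors are linearly interpolated from tables on a 0.05 mV grid
(built once per run; the R-facing `lr1_rates()`, `ionic_current()` and
`step_gates()` evaluate the expressions exactly). The slow-inward
reversal potential, a logarithm of the slowly varying calcium
concentration, is refreshed every 16 steps. Gates are clipped to [0, 1];
values below 1e-12 are flushed to zero — during the plateau the sodium
inactivation gates decay exponentially into the subnormal floating-point
range, where arithmetic is two orders of magnitude slower, with no
physical content.

## Discretizations

**Cellular models.** Kirchhoff current balance on a uniform chain
(`dx = eps/n_div`, default 10 µm, 641 nodes), forward Euler. A junction
link's conductivity is `dx/(R_j*A_cell)` with
`R_j = 1/(beta*g_jo*g_j(Vj))`; the link replaces one `dx` segment, so a
cell contributes `n_div - 1` myoplasmic links plus one junction link.
`Vj` is sampled one cell away on each side of the junction
(`junction_vj()`), mirroring the dual-voltage-clamp protocols that
produced the conductance fits; `g_j` receives `Vj` directly, without the
`S` factor. The default time step comes from the explicit diffusion
bound `dx^2*Am*Cm/(2*sigma_c)` with a 0.7 safety factor (≈ 2e-4 ms at
10 µm) and is validated at construction. Boundary nodes use mirrored
(sealed) stencils; pacing injects an axial current density (default
30 µA/mm² for 2 ms, cycle length 800 ms) at the paced end node.

**Continuum models.** P1 Galerkin elements on a uniform mesh (65 nodes
at the default `h` = 100 µm), forward Euler, consistent mass matrix for
the capacitive term (a constant tridiagonal system factorized once; the
ionic reaction is evaluated nodally). Consistent mass is the default
because the lumped variant depresses the coarse-mesh conduction velocity
(60.5 vs 64.6 cm/s at `h` = 0.1) and inverts the mesh-size trend the
models are known for; `mass = "lumped"` remains available. Its stricter
stability bound `h^2*Am*Cm/(6*sigma_c)` sets the default `dt`
(0.005 ms at `h` = 0.1). The effective conductivity is evaluated per
element from the *lagged* gradient, keeping the update fully explicit.

For the non-Ohmic model the conductivity argument uses a recovered
gradient — the average of the nodal central-difference gradients at the
element's two ends — while the flux itself uses the element gradient.
With the raw one-point gradient a steep wavefront confined to a single
coarse element drives `sigma(y)` onto its collapsed branch and produces
spurious conduction block that disappears under mesh refinement; with
the recovered argument the 65-node mesh stays on the h-converged branch
(13.6 cm/s at `h` = 0.1 vs 13.7 cm/s at `h` = 0.02 for steady-state
Cx43-Cx45 at `beta` = 50%). `sigma_gradient = "element"` selects the raw
variant.

## Protocols and their defaults

Activation is the first upward 0 mV crossing (linear interpolation
between samples); CV is measured between the 20% and 80% strand
positions, ordered along the propagation direction. Conduction at 1%
coupling runs near 1 cm/s, so block classification uses a full 800 ms
beat and, where the question is "does the wave reach the end", the
distal strand node. `cv_beta_sweep()`, `block_threshold()`,
`restitution()` (default: 5 beats per cycle length, 800 ms down to
400 ms in coarse steps, then 10 ms decrements; the schedule stops at the
first cycle length whose last beat fails to activate the distal site)
and `mesh_study()` wrap these measurements into tidy tables.
`mesh_study()` uses a 4 ms pulse: chains coarser than 5 nodes per cell
double the diffusive sink at the paced node and a 2 ms pulse no longer
excites them, while CV itself is pulse-independent once the beat is
elicited (63.981 vs 63.977 cm/s at baseline for 2 vs 6 ms).

`traveling_wave()` produces an analytic logistic front with chosen
speed, amplitude and direction. It exercises every estimator (speed
recovery, standing-wave block, retrograde handling) without a solver,
but it deliberately lacks everything that makes the real problem hard —
saltatory junction delays, front steepening, restitution — so estimator
tests on it say nothing about solver accuracy; the solver tests and the
microscale series oracle carry that weight.

## What the models reproduce, and known limitations

At full coupling, instantaneous Cx43-Cx43, all four models give CV
between 64 and 65.1 cm/s on their baseline discretizations. The
voltage-gated cellular model under steady-state Cx43-Cx43 conducts at 1%
coupling (~1 cm/s) and blocks at 0.5%. Steady-state Cx43-Cx45 conduction
is strongly direction-dependent in the voltage-sensitive models
(e.g. NOHM 20.2 cm/s normal vs 64.5 cm/s retrograde at full coupling),
while the clamped/linear models are direction-blind. Restitution of the
heterotypic channel loses 1:1 distal capture at a 260 ms cycle length.
CV grows with mesh size in all models, far more steeply in the cellular
ones, where coarsening the subcellular segments removes myoplasmic
resistance from the chain.

Two quantitative behaviors deviate from what the homogenized model is
intended to track. First, the non-Ohmic cable's normal-direction block
boundary for heterotypic channels lies below 10% coupling here (the
voltage-gated cellular reference blocks between 50% and 20%): block is a
threshold phenomenon and its grid position is sensitive to membrane
excitability and scheme details. Second, at very low coupling the
homogenized model overestimates the cellular CV (15.2 vs 12.8 cm/s at
10%, 1.8 vs 1.0 cm/s at 1% for steady-state Cx43-Cx43): conduction there
is saltatory — the wave waits at each junction — and a quasi-static
gradient-dependent conductivity compresses that waiting time. Both are
reported by the acceptance checks rather than hidden.

Out of scope by design: 2-D/3-D tissue, bidomain/extracellular
potentials, time-resolved junction gating between the two limiting
regimes, ephaptic coupling, and ionic models other than Luo–Rudy I.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the baseline single-beat
CV measurements (40 ms windows), full-beat (790 ms) block
classifications for the cellular models, a 65-node restitution staircase
(~27 s of model time), and mesh/coupling sweeps on reduced grids
({0.02, 0.05, 0.1(, 0.2)} mm; two to three coupling levels). These sizes
were chosen so each check isolates one claim at its natural scale; the
full figure-style sweeps are available through the same functions with
denser grids.
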