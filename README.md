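# gjcable

Multiscale simulation of electrical conduction in one-dimensional strands
of cardiac myocytes coupled by voltage-dependent gap junctions.

## The problem

Action potentials cross cardiac tissue through cell interiors (Ohmic) and
through gap junctions at the intercalated discs, whose conductance depends
non-linearly on the transjunctional voltage `Vj`. Standard tissue-scale
(monodomain) models replace this microstructure with a constant effective
conductivity and consequently mispredict conduction when gap-junctional
coupling `β` is reduced — the regime of uncoupling disease, slow
conduction and block.

`gjcable` implements and compares four models of a 6.4 mm myocyte strand,
all driven by Luo–Rudy phase-I (1991) membrane kinetics:

| model | scale | junctions |
|---|---|---|
| `cm_clamped` | discrete chain, 10 nodes/cell | constant `β·g_jo` |
| `cm_gated` | discrete chain, 10 nodes/cell | `β·g_jo·g_j(Vj)` |
| `lhm` | homogenized cable, 65 nodes | constant `σ̂ = [(1−δ)/σ_c + 1/(βσ_g)]⁻¹` |
| `nohm` | homogenized cable, 65 nodes | gradient-dependent `σ̂(∂v/∂x)` |

The non-Ohmic homogenized model (`nohm`) upscales the junction law into an
implicit effective conductivity

    σ̂(y) = σ_c·B / (σ_c/σ_g + (1−δ)·B),   B = β·g_j(S·ε·[N](y)),
    [N](y) = −(1−δ)·(σ̂(y)/σ_c − 1)·y,

solved per potential gradient `y` by damped fixed-point iteration with a
bisection fallback, and tabulated for the cable solver. Instantaneous
(`2·cosh(Vj/VH) − 1`, normalized) and steady-state (Boltzmann,
`(1−g_min)/(p + e^{A(Vj−Vj0)}) + g_min`, `A = z/kT`) conductance laws are
built in for Cx43-Cx43, Cx45-Cx45 and the asymmetric heterotypic
Cx43-Cx45 channel, whose conduction is direction-dependent.

## Worked example

```r
library(gjcable)

# one paced beat of the non-Ohmic cable, full coupling
cfg <- strand_config("nohm", channel = "Cx43-Cx43",
                     regime = "instantaneous", beta = 1, out_dt = 0.1)
sim <- simulate_strand(cfg, t_end = 40)
conduction_velocity(sim)
#> # A tibble: 1 × 6
#>      t1    t2    cv blocked    x1    x2
#>   <dbl> <dbl> <dbl> <lgl>   <dbl> <dbl>
#> 1  3.68  9.53  64.9 FALSE     1.3   5.1
```

The wave crosses the 20%→80% measurement window at 64.9 cm/s — within
the 64–65 cm/s all four models give for this channel at full coupling.
Dropping the coupling of the heterotypic channel shows direction-dependent
conduction and, in the cellular models, block:

```r
cfgh <- strand_config("nohm", channel = "Cx43-Cx45",
                      regime = "steady_state", beta = 0.2)
conduction_velocity(simulate_strand(cfgh, t_end = 300))$cv          # 6.8 cm/s
cfgr <- strand_config("nohm", channel = "Cx43-Cx45",
                      regime = "steady_state", beta = 0.2,
                      direction = "retrograde")
conduction_velocity(simulate_strand(cfgr, t_end = 300))$cv          # 39.4 cm/s
```

Protocol drivers return tidy tables: `cv_beta_sweep()` (CV vs coupling),
`block_threshold()` (largest blocked β on a grid), `restitution()`
(CV vs pacing cycle length, dynamic pacing-down), `mesh_study()` (CV vs
spatial resolution), with `autoplot()`/`plot_*()` companions. The
effective-conductivity map itself is exposed (`sigma_table()`,
`nohm_sigma()`, `lhm_sigma()`), validated against a microscale
series-circuit oracle (`micro_strand_steady()`), and exportable to CSV.
A thin command-line driver lives at `inst/cli/gjcable.R`
(`simulate`, `sweep-beta`, `restitution`, `mesh-study`, `sigma-table`,
`fixtures` subcommands).

See the methods vignette (`vignettes/strand-conduction-methods.Rmd`) for
the model equations, units, numerical schemes and known limitations.

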