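# fibercapture

Simulation of single-pass capture of heparin-binding growth factors by
endothelial cells lining the hollow fibers of a perfusion bioreactor.

Circulating growth factors such as FGF-2 have one brief opportunity to bind
a vessel wall before flow carries them away. This package models that
process in the geometry where it is actually measured on the bench: a
cartridge of 20 cell-lined hollow fibers (700 µm I.D., 12 cm) fed by a
pulsatile pump from a small inlet reservoir into which a nanogram-scale
bolus is injected. It is intended for quantitative cell biologists and
bioengineers who want to ask how flow rate, diffusion, binding-site
density, affinity, and receptor–proteoglycan coupling shape ligand capture
— and to compare simulated outflow curves against collected-fraction ELISA
data.

The model has three coupled parts:

1. **Flow** — fully developed laminar tube flow, steady
   (`u(r) = 2ū(1 − r²/R²)`, `ū = q_s/(N_f πR²)`) or pulsatile
   (the same profile modulated by `1 + sin ωt`, `ω = 2π/T`, nonnegative
   and averaging to the set flow rate).
2. **Transport** — the axisymmetric convection–diffusion equation for the
   fluid-phase ligand `F(r,z,t)`, solved by a conservative finite-volume
   scheme on a uniform mesh, with the inlet fed by a per-stroke reservoir
   dilution model (`Cᵢ = Cᵢ₋₁(V_res − V_pulse)/V_res`).
3. **Surface kinetics** — a stiff mass-action network on each wall cell:
   FGFR binding (`F + R ⇌ C`), HSPG binding (`F + H ⇌ G`), coupling into
   the ternary complex `T` via both routes (`C + H ⇌ T`, `G + R ⇌ T`),
   homodimerization (`C₂`, `G₂`, `T₂`), slow ternary ligand loss
   (`k_dFHR`), and irreversible internalization (`k_int` monomers,
   `k_intD` dimers), imposed as the wall boundary flux.

Everything is accounted for in a mass ledger (reservoir, fluid, bound,
internalized, exited, nonspecific loss) that closes to machine precision.

## A worked example

```r
library(fibercapture)

cfg <- preset("fig5_control")   # 0.92 ng FGF-2, 0.63 mL/min, 32% loss
sim <- run_simulation(cfg)
glance(sim)
```

```
#> # A tibble: 1 × 11
#>   time_s injected_ng entering_ng exited_ng bound_ng internalized_ng fluid_ng
#> 1    300        0.92       0.626     0.400    0.192          0.0308  0.00204
#> # specific_retention_pct 36.0, ledger_error 4.4e-16, ...
```

Of the 0.92 ng injected, 0.29 ng never leaves the inlet reservoir
(measured nonspecific loss); of the 0.63 ng entering the fibers, 0.40 ng
exits within 5 minutes while 0.19 ng remains bound to the cell surfaces —
overwhelmingly near the fiber entrance — plus 0.03 ng already
internalized. `tidy(sim)` returns the outflow time series,
`autoplot(sim)` draws it, `fractionate(sim)` converts it to a
fixed-volume fraction table, and `retention_summary(sim)` partitions
retention by axial zone. Scenario presets (`preset_names()`) reproduce
the package's standard in-silico experiments — heparinase treatment
(`H0 = 0`), steady vs pulsatile pumping, flow-rate and affinity sweeps,
and fibers whose entrance quarter carries HSPG only. Agreement with
experimental fraction tables is scored by `amount_criterion()` and
`curve_match()`; `synth_outflow()` generates noisy test curves.

A thin command-line front end ships in `inst/cli/fibercapture.R`
(`presets`, `run --preset … --out dir`, `compare --sim … --exp …`).

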