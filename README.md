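# veincuff

Simulation of two-electrode bioimpedance spectroscopy of a venous segment
instrumented with a cuff of gold surface electrodes and an axial ground
wire, for electrode-configuration design. The package answers the question
a cuff designer actually has: **what fraction of the measured impedance
comes from the vein wall**, and how does that fraction change with the
number of surface electrodes, their radius, the ground-wire radius, the
excitation mode (all terminals driven together vs. one at a time), and the
position of the driven terminal along the vessel.

## Model

Below 1 MHz the problem is quasi-static: the complex potential solves

∇·(σ\*(f) ∇V) = 0,  σ\*(f) = σ(f) + i·2πf·ε₀·ε_r(f),

with driven electrodes at 1 V, the ground wire at 0 V, and insulating outer
boundaries. The terminal current gives Y = I/U, Z = 1/Y = R + iX,
|Z| = √(R²+X²), φ = arctan(X/R), G = Re Y, C = Im Y/ω. For a two-electrode
lead the point sensitivity is S = (J·J)/I², the volume impedance density is
z = ρS (ρ = 1/σ\*), and the measured impedance is recovered by the
reconstruction identity Z = ∫ ρS dV. Region-wise integrals of Re(z)/Re(Z),
or alternatively of the dissipated power density Re(σ\*)|E|², give each
model component's percentage contribution to the measurement.

The discretization is cell-centered finite volumes on an interface-conforming
cylindrical grid with harmonic-mean face admittivities; the complex-symmetric
system is solved by a Cholesky-preconditioned conjugate-orthogonal CG.
Analytic phantoms (slab, coaxial annulus, series bilayer, solid cylinder)
with closed-form impedances validate the whole chain; see the methods
vignette (`vignettes/cuff-impedance-model.Rmd`) for the numerics and the
declared default geometry and material table.

## Worked example

A solver sanity check against a closed form, then the terminal-position
experiment at reduced resolution:

```r
library(veincuff)

# 10 mm slab of 1 S/m with 1 cm^2 full-face electrodes: Z = L/(sigma A)
pm <- make_phantom(phantom_spec("slab", sigma = 1), c(6, 6, 10))
assemble_and_solve(pm$grid, pm$materials, pm$masks, f = 0)
#> <vc_solution> f = 0 Hz, 1 terminal(s) at 1 V
#>   Z = 100 + 0i Ohm   (cocg, 1 iters, residual 7.13e-16)

# move the single driven terminal along the vein (reduced 25x16x64 grid)
scan <- single_terminal_scan(resolution = c(25, 16, 64), f = 1e6)
tidy(scan)
#> # A tibble: 3 x 7
#>   position   electrode z_density_vein_pct power_loss_vein_pct   ReZ   ImZ  absZ
#> 1 middle            15               58.4                58.3  411. -76.2  418.
#> 2 first_end         22               58.4                58.3  411. -76.2  418.
#> 3 second_end         1               58.4                58.3  411. -76.2  418.
glance(scan)$max_pairwise_diff_pp
#> [1] 0.009
```

Reading: with one 1 mm terminal driven against the 0.5 mm axial ground
wire, about 58% of the measured impedance originates in the vein wall
(the rest is mostly the saline current path), and moving the terminal
between the middle and either end of the vein changes that share by less
than 0.01 percentage points — the measurement is insensitive to terminal
position, so a multiplexed one-at-a-time scan sees equivalent sensing
volumes at every electrode. At the full reporting resolution (32×64×128,
1 MHz) the same experiment gives 71.4% per position with a maximum pairwise
difference of 0.0089 pp. Configuration sweeps (`run_configuration_sweep()`)
reproduce the design trends: the vein share falls as electrodes are added
(60.7% at N=28 down to 52.1% at N=48, simultaneous excitation), rises with
a 1 mm ground wire (64.6% vs 60.7%), and is far higher for a single 1 mm
terminal (71.4%) than for a 2.5 mm one (50.1%).

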