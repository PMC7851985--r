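---
title: "Modeling the impedance of a cuff-electrode instrumented venous segment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the impedance of a cuff-electrode instrumented venous segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veincuff)
```

## The measurement problem

Bioimpedance spectroscopy can monitor a three-dimensional tissue construct
non-invasively: a small AC voltage is applied between electrodes, the complex
current response is recorded over a frequency band, and changes in tissue
structure appear as changes in the impedance `Z = R + iX`. For an *ex-vivo*
venous segment the natural instrumentation is a flexible cuff wrapped around
the vessel, carrying an array of small gold surface electrodes on its inner
face, with a thin gold ground wire threaded along the vessel axis. The design
question this package addresses is: **how much of the measured impedance
actually comes from the vein wall**, as opposed to the saline that perfuses
and surrounds it, and how does that share change with the number of
electrodes, their radius, the ground-wire radius, the excitation mode (all
electrodes driven together versus one at a time), and the position of the
driven electrode?

veincuff answers this with a simulation pipeline:

1. a parametric geometry (PMMA chamber, saline, glass tubes, vein, quartz
   cuff substrate, electrodes, ground wire) voxelized onto a cylindrical
   grid ([geometry_config()], [build_grid()]);
2. a quasi-static complex conduction solve per frequency
   ([assemble_and_solve()], [impedance_spectrum()]);
3. lead-field post-processing that splits the measured impedance into
   per-region contributions ([sensitivity_field()],
   [region_contributions()]);
4. sweep drivers that emit the electrode-comparison tables and slice plots
   ([run_configuration_sweep()], [single_terminal_scan()],
   [export_slice()]).

## Physical model

Below 1 MHz the field wavelength vastly exceeds the centimetre-scale
geometry and tissue inductance is negligible below roughly 10 MHz, so the
full Maxwell problem reduces to quasi-static conduction with the complex
admittivity

$$\sigma^*(f) = \sigma(f) + i\,2\pi f\,\varepsilon_0\,\varepsilon_r(f),$$

and the potential solves $\nabla\cdot(\sigma^*\nabla V)=0$ with the driven
electrodes at 1 V, the ground wire at 0 V and insulating outer boundaries.
The terminal current $I$ gives the admittance $Y = I/U$, the impedance
$Z = 1/Y$, and the derived scalars $R$, $X$, $|Z| = \sqrt{R^2+X^2}$,
$\varphi = \arctan(X/R)$, $G = \mathrm{Re}\,Y$ and $C = \mathrm{Im}\,Y/\omega$.

For a two-electrode lead the injection and measurement leads coincide, so
the point sensitivity is $S = (J\cdot J)/I^2$ (the *unconjugated* square of
the current density — this is what makes the reconstruction below an exact
complex identity), the volume impedance density is $z = \rho S$ with
$\rho = 1/\sigma^*$, and

$$Z = \int \rho S\, \mathrm{d}V.$$

Integrating $\mathrm{Re}(z)$ over one region and dividing by
$\mathrm{Re}(Z)$ gives that region's percentage contribution to the
measurement. A second, independent measure integrates the dissipated power
density $\mathrm{Re}(\sigma^*)|E|^2$ region by region (the time-average
factor ½ cancels in every fraction). When the loss angle is small the two
measures coincide; the package computes both on every run and they agree to
better than 0.1 percentage points on all shipped configurations.

## Default study conditions

The defaults reproduce the reference bench set-up: a 6 cm vein of 1.4 cm
outer diameter held between two glass tubes in a saline-filled PMMA chamber,
a quartz cuff wrapped directly around the vein, 28 surface electrodes in 4
axial rings (7 per ring, equispaced, rings centered on the vein), terminal
radius 1 mm, ground-wire radius 0.5 mm. The studied variations are
`n_electrodes` in {28, 32, 44, 48}, `r_terminal` in {1, 2, 2.5} mm and
`r_ground` in {0.5, 1} mm. The ground wire spans the whole domain and by
convention exits at the positive-z end; the "first end" terminal position is
the ring nearest that exit. Contribution tables are reported at 1 MHz, the
frequency of the slice-plot comparisons; the spectroscopy band is 10 Hz to
1 MHz, log-spaced at 5 points per decade by default.

Dimensions the bench drawing does not fix are declared defaults, chosen at
physically sensible scales and fully overridable: vein wall thickness 0.5 mm
(large-vein scale), cuff substrate 0.5 mm, chamber radius 25 mm and length
120 mm with 1 mm PMMA walls, glass tubes of 7 mm bore and 1 mm wall.

Material properties come from a declared, config-overridable table
([default_material_table()]): saline $\sigma$ = 1.6 S/m, $\varepsilon_r$ = 80;
glass/quartz/PMMA as near-perfect insulators with their textbook
permittivities; gold at $4.1\times10^7$ S/m. The vein wall emulates the
$\beta$-dispersion caused by cell-membrane charging with a single-pole Debye
relaxation: $\varepsilon_r$ falls from $10^5$ at 10 Hz to $2\times10^3$ at
1 MHz around a 10 kHz relaxation frequency, and $\sigma$ rises from
0.3 S/m to about 0.355 S/m. The conduction rise is not optional decoration:
sampling $\sigma$ and $\varepsilon_r$ from one causal relaxation keeps the
pair Kramers–Kronig consistent, making the wall a genuine passive RC medium —
a permittivity that falls at constant conductivity would have a *decreasing*
admittivity magnitude at the top of the band and an unphysical rising
$|Z|$. Dispersive properties are piecewise log-linear tables (clamped
outside the knots; Debye-sampled at 3 knots per decade) rather than
Cole–Cole fits: the tables are transparent, exactly serializable, and
sufficient for a model whose conclusions are ratios rather than absolute
levels. $\varepsilon_0$ is fixed at $8.8542\times10^{-12}$ F/m.
Electrode–electrolyte interface (double-layer) impedance and temperature
effects are out of scope.

Because the true bench materials are not pinned down numerically, the
*absolute* vein contribution under these defaults (about 63% at 1 MHz for
the 28-electrode simultaneous configuration) is not a prediction of the
bench value; the package's validated outputs are the *orderings and
differences* between configurations, which are robust to the material
choices, and these are what the test suite asserts.

## Discretization and numerics

**Grid.** Cell-centered finite volumes on a structured cylindrical grid
$(r, \theta, z)$, $\theta \in [0, 2\pi)$ periodic, z along the vessel axis.
Radial and axial grid lines are snapped to every material interface, each
interface layer gets at least two cells (an interface layer whose
proportional share of the budget falls below half a cell is a resolution
error), and radial spacing is geometrically graded so $\Delta r/r$ stays
roughly constant. Region volumes are then exact. A `conform = FALSE` mode
voxelizes by cell-center membership on uniform spacing, which is useful for
studying voxelization convergence. Face admittivities are harmonic means, so
layered interfaces are exact in the one-dimensional limit. Phantom grids may
also be Cartesian; the solver accepts both metrics.

**Electrodes.** Electrodes are ideal-conductor Dirichlet patches on the cuff
surface, not volumetric gold bodies: gold's conductivity (11 orders above
saline) makes internal drops irrelevant. The ground wire is the inner radial
boundary at 0 V, which also removes the $r = 0$ coordinate singularity.
When footprints are voxelized, each disc center is snapped to the surface
face lattice, so nominally identical electrodes receive *identical* face
patterns wherever they sit. This matters: without snapping, staircase
differences in voxelized electrode area of order one grid cell would induce
spurious position dependence of the order of a percentage point — far larger
than the genuine position effect (a few hundredths of a percentage point)
the terminal-position experiment quantifies. Undriven electrodes in
single-terminal mode are electrically absent by default (the cuff substrate
takes their place); `inactive = "floating"` instead models each as an ideal
floating conductor with one extra unknown and zero net current.

**Linear solver.** The complex-symmetric system is solved by a
conjugate-orthogonal CG (COCG) iteration preconditioned with a sparse
Cholesky factorization of $\mathrm{Re}(A) + \mathrm{Im}(A)$, which is
symmetric positive definite for passive materials; eigenvalues of the
preconditioned operator lie on the segment from 1 to $i$, bounded away from
zero, so convergence is fast (typically under 15 iterations to the default
relative residual of $10^{-8}$) and independent of the
insulator/electrolyte contrast. A BiCGSTAB fallback guards against COCG
breakdown. Orderings are fixed and nothing is randomized: identical inputs
give bitwise identical outputs.

**Contribution assembly.** The package carries two discretizations of the
densities. The *pointwise* fields ($S$, $z$, $p$ from the cell-averaged
current density) are what the slice plots show. Region contributions and
[reconstruct_impedance()] instead use the *discrete energy split*: each
face's complex energy $g_f\,\Delta V_f^2$ is divided between its two
adjacent cells in proportion to their half-resistances. This split sums to
the solver impedance to machine precision (the discrete form of the
reconstruction identity) and is exactly the quantity a finite-difference
perturbation of a region's resistivity differentiates, which is how the
test suite cross-checks it. The pointwise integral agrees with the solver
to well under 0.5% on resolved phantoms, but is *not* used for the vein
tables: at the coarse reporting grid the current-density peak under a 1 mm
electrode is unresolved by 0.7 mm faces, and squaring the averaged $J$
there loses a large fraction of the true $\int J^2$. Power-loss fractions
are assembled from the same face fluxes ($|q_f|^2\,\mathrm{Re}\,\rho$), so
the comparison of the two contribution measures isolates the physical
phase effect instead of comparing two discretization errors.

**Reporting resolution.** The shipped comparisons run at
$32 \times 64 \times 128$ cells (262,144 unknowns; about one to two minutes
per solve on one CPU). At this resolution the vein wall carries 2 radial
cells and a 1 mm electrode about 5 surface faces; phantom studies in the
test suite show the coaxial oracle error at well under 1% and second-order
convergence under radial refinement. Unit tests use a reduced
$25 \times 16 \times 64$ grid of the same model.

## Validation strategy

Everything is tested against closed forms and discrete identities, not
against reference output files:

* slab, coaxial, bilayer and solid-cylinder phantoms with analytic
  impedances (including the parallel-capacitance term), with monotone
  grid-convergence checks;
* exact discrete identities: charge conservation, reconstruction of $Z$
  from the energy split, linearity in the excitation, reciprocity under
  terminal/ground exchange;
* the finite-difference sensitivity oracle: perturbing one region's
  resistivity by 0.1% on a sub-1000-cell phantom reproduces that region's
  contribution fraction within 1%;
* passivity across the band: $G \ge 0$, $C \ge 0$,
  $\varphi \in (-90°, 0]$, $|Z|$ non-increasing in frequency;
* the configuration experiments themselves: vein contribution
  non-increasing in electrode count, increased by a thicker ground wire,
  higher for single than simultaneous excitation, higher for a 1 mm than a
  2.5 mm terminal, and nearly invariant (< 0.1 pp) under terminal position.

What passing these tests does **not** show: that the absolute contribution
percentages match any particular bench vein (the materials are declared
defaults, and real vessels have layered, anisotropic walls); that electrode
polarization is negligible at the low end of the band (double-layer
impedance is out of scope); or anything about four-electrode (tetrapolar)
leads, which use distinct injection and measurement lead fields and are not
implemented.

## Worked example

A compact version of the position experiment at reduced resolution:

```{r example, eval = FALSE}
library(veincuff)

scan <- single_terminal_scan(resolution = c(25, 16, 64), f = 1e6)
tidy(scan)
glance(scan)$max_pairwise_diff_pp

# full reporting resolution (about five minutes):
scan <- single_terminal_scan(resolution = c(32, 64, 128), f = 1e6)
```

And the electrode-count sweep:

```{r sweep, eval = FALSE}
plan <- experiment_plan(
  tibble::tibble(n_electrodes = c(28, 32, 44, 48),
                 r_terminal = 1e-3, r_ground = 0.5e-3,
                 mode = "simultaneous"))
sw <- run_configuration_sweep(plan)
plot_vein_contribution(sw)
```

## Known limitations

* The structured grid staircases the electrode discs; at the reporting
  resolution a 1 mm electrode is a handful of faces. All shipped
  conclusions are differences between configurations computed on identical
  lattices, which cancels most of this error, but absolute spreading
  resistances at coarse grids carry a few percent of discretization error.
* The vein wall is a single homogeneous layer; intima/media/adventitia
  structure, anisotropy and the surrounding adventitial tissue are not
  modeled.
* Electrode polarization impedance is omitted, so low-frequency magnitudes
  are optimistic relative to a real gold-electrolyte interface.
* Only two-electrode leads are supported; negative-sensitivity regions
  (possible in four-electrode leads) are detected and flagged but do not
  occur in this model class.
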