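face_set_outside <- function() {
  tibble::tibble(axis = 1L, i = 1L, j = 1L, k = 1L, side = -1L,
                 type = "boundary")
}

test_that("slab phantom reproduces the series-resistance closed form", {
  pp <- solve_phantom("slab", c(6, 6, 10), sigma = 1)   # 10 mm, 1 cm^2
  sol <- pp$sol
  # Z = L / (sigma A) = 100 Ohm
  expect_lt(rel_err(Re(sol$Z), 100), 0.005)
  expect_equal(Im(sol$Z), 0)
  # I = U / Z
  expect_lt(rel_err(Mod(sol$I), 0.01), 0.005)
  # V is linear in z: midplane potential 0.5 V by symmetry
  nz <- pp$grid$dims[3]
  mid <- (Re(sol$V[1, 1, nz / 2]) + Re(sol$V[1, 1, nz / 2 + 1])) / 2
  expect_equal(mid, 0.5, tolerance = 1e-9)
  zc <- (pp$grid$edges[[3]][-1] + pp$grid$edges[[3]][-(nz + 1)]) / 2
  expect_equal(as.vector(Re(sol$V[3, 3, ])), unname(1 - zc / 0.01),
               tolerance = 1e-9)
})

test_that("electrode currents balance and are antisymmetric under swap", {
  pp <- solve_phantom("slab", c(5, 5, 8), sigma = 2)
  sol <- pp$sol
  i_term <- electrode_current(sol, "terminal_1")
  i_gnd <- electrode_current(sol, "ground")
  # charge conservation: everything that leaves the terminal enters ground
  expect_lt(Mod(i_term + i_gnd) / Mod(i_term), 1e-3)
  # masks can be matched by face identity too
  expect_equal(electrode_current(sol, pp$masks$terminals[[1]]), i_term)
  expect_error(electrode_current(sol, face_set_outside()), "not part")
  # swapping terminal and ground flips the sign of the current through the
  # same physical patch, and leaves |Z| unchanged
  swapped <- veincuff:::new_masks(list(terminal_1 = pp$masks$ground),
                                  pp$masks$terminals[[1]])
  sol2 <- assemble_and_solve(pp$grid, pp$materials, swapped, 0)
  expect_equal(Mod(sol2$Z), Mod(sol$Z), tolerance = 1e-8)
  # the old terminal patch (now grounded) sinks what it used to source
  expect_equal(Re(electrode_current(sol2, "ground")), -Re(i_term),
               tolerance = 1e-6)
})

test_that("coaxial phantom converges to the analytic resistance", {
  co <- phantom_spec("coaxial", a = 1e-3, b = 2e-3, L = 0.06, sigma = 1)
  z_ref <- Re(analytic_impedance(co, 0))
  expect_equal(z_ref, log(2) / (2 * pi * 0.06), tolerance = 1e-12)
  errs <- vapply(c(32L, 64L, 128L), function(nr) {
    pm <- make_phantom(co, c(nr, 8L, 16L))
    sol <- assemble_and_solve(pm$grid, pm$materials, pm$masks, 0)
    rel_err(Re(sol$Z), z_ref)
  }, numeric(1))
  expect_lt(errs[2], 0.02)                  # within 2% at 64 radial cells
  expect_true(all(diff(errs) < 0))          # monotone convergence
  order_obs <- log2(errs[1] / errs[2])
  expect_gte(order_obs, 1.5)
})

test_that("solves are linear in the excitation and deterministic", {
  pp <- solve_phantom("series_bilayer", c(4, 4, 12), sigma = c(1, 3))
  s1 <- pp$sol
  s2 <- assemble_and_solve(pp$grid, pp$materials, pp$masks, 0, u_volts = 2)
  expect_equal(s2$I, 2 * s1$I, tolerance = 1e-10)
  expect_equal(s2$Z, s1$Z, tolerance = 1e-10)
  s3 <- assemble_and_solve(pp$grid, pp$materials, pp$masks, 0)
  expect_identical(s3$V, s1$V)              # bitwise reproducible
  expect_identical(s3$I, s1$I)
})

test_that("solver rejects bad tolerances and degenerate masks", {
  pp <- make_phantom(phantom_spec("slab"), c(4, 4, 6))
  expect_error(assemble_and_solve(pp$grid, pp$materials, pp$masks, 0,
                                  tol = 0.1), "tol")
  no_term <- veincuff:::new_masks(list(), pp$masks$ground)
  expect_error(assemble_and_solve(pp$grid, pp$materials, no_term, 0),
               "terminal")
})

test_that("admittance decomposition recovers G and C", {
  expect_identical(decompose_admittance(0.01 + 0i, 50),
                   list(G = 0.01, C = 0))
  d <- decompose_admittance(complex(real = 0.01, imaginary = 6.2832e-5), 1)
  expect_equal(d$C, 1e-5, tolerance = 1e-4)
  expect_error(decompose_admittance(0.01 + 1i, 0), "ill-defined")
  expect_identical(decompose_admittance(0.25 + 0i, 0), list(G = 0.25, C = 0))
})

test_that("slab spectrum behaves as a parallel RC with tiny loss angle", {
  ph <- phantom_spec("slab", sigma = 1, eps_r = 80)
  pm <- make_phantom(ph, c(4, 4, 8))
  freqs <- frequency_grid(10, 1e6, 1)
  sp <- impedance_spectrum(pm$grid, pm$materials, pm$masks, freqs)
  expect_identical(sp$f_Hz, freqs)
  # crossover |X| = R sits at sigma / (2 pi eps0 eps_r) ~ 2.25e8 Hz, so the
  # band is overwhelmingly resistive: |X|/R < 1e-2 throughout
  expect_true(all(abs(sp$ImZ) / sp$ReZ < 1e-2))
  expect_true(all(sp$phase_deg <= 0 & sp$phase_deg > -90))
  expect_true(all(sp$G_S >= 0 & sp$C_F >= 0))
  # |Z| non-increasing across the sweep
  expect_true(all(diff(sp$absZ) <= 0.005 * sp$absZ[-length(sp$absZ)]))
  # the capacitance matches the parallel-plate formula eps0 eps_r A / L
  c_ref <- eps0 * 80 * 1e-4 / 0.01
  expect_lt(rel_err(sp$C_F[sp$f_Hz == 1e3], c_ref), 0.01)
  # X and the phase vanish identically at DC
  s0 <- assemble_and_solve(pm$grid, pm$materials, pm$masks, 0)
  expect_identical(Im(s0$Z), 0)
  # spectrum errors carry the failing frequency
  bad <- veincuff:::new_masks(list(), pm$masks$ground)
  expect_error(impedance_spectrum(pm$grid, pm$materials, bad, freqs),
               "f = 10")
})

test_that("reciprocity holds on an asymmetric phantom", {
  pp <- solve_phantom("series_bilayer", c(4, 4, 12), sigma = c(1, 5),
                      split = 0.3)
  swapped <- veincuff:::new_masks(list(terminal_1 = pp$masks$ground),
                                  pp$masks$terminals[[1]])
  sol2 <- assemble_and_solve(pp$grid, pp$materials, swapped, 0)
  expect_equal(Mod(sol2$Z), Mod(pp$sol$Z), tolerance = 1e-8)
})

test_that("floating conductors carry zero net current", {
  cfg <- geometry_config()
  qs <- quick_vein_solve(cfg, mode = "single", position = "middle",
                         inactive = "floating")
  sol <- qs$sol
  # every floating patch sits at an intermediate potential
  vf <- Re(sol$floating_potentials)
  expect_true(all(vf > -1e-9 & vf < 1 + 1e-9))
  # net current through each floating electrode vanishes
  dh <- sol$dirichlet
  for (nm in names(sol$floating_potentials)) {
    sel <- dh$name == nm
    inet <- sum(dh$g[sel] * (dh$vd[sel] - sol$V[dh$cell[sel]]))
    expect_lt(Mod(inet), 1e-6 * Mod(sol$I))
  }
})
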