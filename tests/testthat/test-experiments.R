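test_that("frequency grids are log-spaced with inclusive endpoints", {
  expect_equal(frequency_grid(10, 1e6, 1), 10^(1:6))
  g2 <- frequency_grid(10, 1e6, 2)
  expect_length(g2, 11L)
  expect_equal(unique(round(g2[-1] / g2[-11], 10)), sqrt(10))
  expect_identical(g2[c(1, 11)], c(10, 1e6))
  expect_length(frequency_grid(10, 1e6, 5), 26L)
  expect_true(all(diff(frequency_grid(3, 9e5, 3)) > 0))
  expect_error(frequency_grid(1e6, 10), "smaller")
  expect_error(frequency_grid(-10, 1e6), "positive")
  expect_error(frequency_grid(10, 1e6, 0), "points_per_decade")
})

test_that("terminal positions resolve to distinct, correctly placed rings", {
  fp <- place_surface_electrodes(geometry_config())
  k_mid <- veincuff:::position_electrode(fp, "middle")
  k_first <- veincuff:::position_electrode(fp, "first_end")
  k_second <- veincuff:::position_electrode(fp, "second_end")
  expect_length(unique(c(k_mid, k_first, k_second)), 3L)
  # first end sits on the ring nearest the ground-wire exit (positive z)
  expect_equal(fp$z[fp$electrode == k_first], max(fp$z))
  expect_equal(fp$z[fp$electrode == k_second], min(fp$z))
  # middle resolves toward the exit side on a tie
  expect_equal(fp$z[fp$electrode == k_mid], 0.0075)
  # a single ring cannot provide end positions
  fp1 <- place_surface_electrodes(geometry_config(n_electrodes = 8,
                                                  n_rings = 1))
  expect_error(veincuff:::position_electrode(fp1, "first_end"), "two")
})

test_that("plans are validated fail-fast with every invalid config listed", {
  cfgs <- tibble::tibble(
    n_electrodes = c(28, 28, 30),
    r_terminal = c(1e-3, 8e-3, 1e-3),
    r_ground = c(0.5e-3, 0.5e-3, 0.5e-3),
    mode = "simultaneous")
  plan <- experiment_plan(cfgs, resolution = quick_vein_resolution)
  err <- tryCatch(run_configuration_sweep(plan), error = conditionMessage)
  expect_match(err, "config 2")     # terminal radius exceeds the ring pitch
  expect_match(err, "config 3")     # 30 not divisible by 4 rings
  expect_no_match(err, "config 1")
  expect_error(experiment_plan(tibble::tibble(n_electrodes = 28)), "lacks")
})

test_that("configuration sweeps report vein contributions reproducibly", {
  cfgs <- tibble::tibble(n_electrodes = 28, r_terminal = 1e-3,
                         r_ground = 0.5e-3, mode = "simultaneous")
  plan <- experiment_plan(cfgs, resolution = quick_vein_resolution)
  sw1 <- run_configuration_sweep(plan)
  expect_s3_class(sw1, "vc_sweep")
  expect_identical(nrow(sw1), 1L)
  expect_true(sw1$z_density_vein_pct > 0 && sw1$z_density_vein_pct < 100)
  expect_lt(abs(sw1$z_density_vein_pct - sw1$power_loss_vein_pct), 0.1)
  cb <- sw1$contributions[[1]]
  expect_s3_class(cb, "vc_contributions")
  expect_equal(sum(cb$z_density_pct), 100, tolerance = 1e-9)
  # bitwise reproducible: identical runs give identical numbers
  sw2 <- run_configuration_sweep(plan)
  expect_identical(sw1$z_density_vein_pct, sw2$z_density_vein_pct)
  expect_identical(sw1$ReZ, sw2$ReZ)
  expect_match(attr(sw1, "materials_fingerprint"), "^[0-9a-f]+$")
})

test_that("removing the vein raises the total conductance", {
  with_v <- quick_vein_solve(f = 1e3)
  without <- quick_vein_solve(f = 1e3, with_vein = FALSE)
  g_with <- Re(with_v$sol$I / with_v$sol$U)
  g_without <- Re(without$sol$I / without$sol$U)
  expect_gt(g_without, g_with)  # saline conducts better than the vein wall
  # and the vein region disappears from the report
  fld <- sensitivity_field(without$sol)
  cb <- region_contributions(fld, without$model$grid)
  expect_true(cb$empty[cb$region == "vein_wall"])
})

test_that("mirror-symmetric geometry gives equal end contributions", {
  sc <- single_terminal_scan(resolution = quick_vein_resolution,
                             positions = c("first_end", "second_end"))
  d <- abs(diff(sc$results$z_density_vein_pct))
  expect_lt(d, 1e-3)   # symmetric up to solver tolerance
  td <- tidy(sc)
  expect_identical(nrow(td), 2L)
  gl <- glance(sc)
  expect_identical(gl$max_pairwise_diff_pp, sc$max_pairwise_diff_pp)
})

test_that("midplane slices sample the expected field structure", {
  pp <- solve_phantom("slab", c(6, 6, 10), sigma = 1)
  sl <- export_slice(pp$sol, "potential")
  expect_true(all(sl$values >= 0 & sl$values <= 1))
  expect_identical(dim(sl$values), c(6L, 10L))
  expect_identical(sl$units, "V")
  sj <- export_slice(pp$sol, "J")
  expect_true(all(sj$values >= 0))
  expect_error(export_slice(pp$sol, "potential", offset = 1), "outside")
  expect_error(export_slice(pp$sol, "S"), "sensitivity_field")

  # coaxial |J| falls off as 1/r
  co <- solve_phantom("coaxial", c(64, 8, 8), a = 1e-3, b = 2e-3, L = 0.06,
                      sigma = 1)
  sc <- export_slice(co$sol, "J")
  ys <- sc$y[sc$y > 0]
  js <- sc$values[sc$y > 0, 4]
  expect_lt(max(abs(js * ys / (js[1] * ys[1]) - 1)), 0.03)
  fld <- sensitivity_field(co$sol)
  sz <- export_slice(fld, "z")
  expect_identical(sz$units, "Ohm/m^2")
  expect_true(all(sz$values >= 0))
})

test_that("spectra can be exported with the canonical column set", {
  pm <- make_phantom(phantom_spec("slab", sigma = 1, eps_r = 80), c(3, 3, 6))
  sp <- impedance_spectrum(pm$grid, pm$materials, pm$masks,
                           frequency_grid(10, 1e3, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("f_Hz", "ReZ", "ImZ", "absZ", "phase_deg", "G_S", "C_F"))
  expect_equal(back$absZ, sp$absZ)
})

test_that("plot builders return ggplot objects without evaluation errors", {
  pm <- make_phantom(phantom_spec("slab", sigma = 1, eps_r = 80), c(3, 3, 6))
  sp <- impedance_spectrum(pm$grid, pm$materials, pm$masks, c(10, 100))
  expect_s3_class(ggplot2::autoplot(sp), "ggplot")
  sol <- assemble_and_solve(pm$grid, pm$materials, pm$masks, 10)
  expect_s3_class(ggplot2::autoplot(export_slice(sol, "potential")),
                  "ggplot")
  fld <- sensitivity_field(sol)
  cb <- region_contributions(fld, pm$grid)
  expect_s3_class(ggplot2::autoplot(cb), "ggplot")
  expect_s3_class(glance(sol), "tbl_df")
  expect_identical(tidy(cb)$region, "medium")
})

test_that("grids tidy into a per-cell table that sums to the domain", {
  pm <- make_phantom(phantom_spec("series_bilayer", sigma = c(1, 2)),
                     c(3, 3, 8))
  td <- tidy(pm$grid)
  expect_identical(nrow(td), as.integer(prod(pm$grid$dims)))
  expect_setequal(unique(td$region), c("layer1", "layer2"))
  expect_equal(sum(td$volume_m3), 1e-6, tolerance = 1e-12)
})
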