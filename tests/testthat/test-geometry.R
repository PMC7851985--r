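test_that("geometry validation enforces the structural invariants", {
  expect_s3_class(geometry_config(), "vc_geometry")
  # ground wire must fit inside the vein lumen
  expect_error(geometry_config(r_ground = 7e-3), "r_ground")
  # terminal radius bounded by the ring spacing
  expect_error(geometry_config(r_terminal = 8e-3), "r_terminal")
  # electrode count must divide across rings
  expect_error(geometry_config(n_electrodes = 30), "divisible")
  # ground wire must span past the whole construct
  expect_error(geometry_config(ground_length = 0.1), "ground_length")
  # validate_geometry_config collects every problem instead of stopping
  cfg <- geometry_config()
  cfg$r_ground <- 1; cfg$ground_length <- 0.01
  p <- validate_geometry_config(cfg)
  expect_gte(length(p), 2L)
})

test_that("voxelized grids partition the domain and resolve every layer", {
  cfg <- geometry_config()
  g <- build_grid(cfg, c(32, 64, 128))
  expect_identical(dim(g$labels), g$dims)
  # labels partition the grid
  expect_true(all(g$labels %in% seq_along(g$regions)))
  # total volume is the analytic annulus volume
  v_dom <- pi * (cfg$chamber_radius^2 - cfg$r_ground^2) * cfg$chamber_length
  expect_lt(abs(sum(cell_volumes(g)) - v_dom) / v_dom, 1e-10)
  expect_equal(sum(region_volumes(g)), v_dom, tolerance = 1e-10)
  # vein-wall volume vs the hollow-cylinder formula pi (ro^2 - ri^2) L
  v_wall <- pi * (0.007^2 - 0.0065^2) * 0.06
  expect_equal(v_wall * 1e9, 1272.3, tolerance = 1e-4)  # 1272.3 mm^3
  expect_lt(rel_err(region_volumes(g)[["vein_wall"]], v_wall), 0.05)
  # a pathologically thin wall cannot be resolved
  expect_error(build_grid(geometry_config(vein_wall_thickness = 1e-6),
                          c(32, 64, 128)), "too coarse")
})

test_that("non-conforming voxelization converges to analytic region volumes", {
  cfg <- geometry_config()
  v_wall <- pi * (0.007^2 - 0.0065^2) * 0.06
  # center-membership voxelization of the thinnest layer: the observed error
  # decreases over three refinements (alignment makes it oscillatory, so the
  # refinement factors are uneven)
  errs <- vapply(c(100L, 240L, 576L), function(nr) {
    g <- build_grid(cfg, c(nr, 8L, 64L), conform = FALSE)
    rel_err(region_volumes(g)[["vein_wall"]], v_wall)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # conforming grids reproduce every region volume essentially exactly
  for (nr in c(32L, 48L)) {
    g <- build_grid(cfg, c(nr, 8L, 64L))
    expect_lt(rel_err(region_volumes(g)[["vein_wall"]], v_wall), 1e-10)
  }
})

test_that("relabeling with permuted priority only moves interface cells", {
  cfg <- geometry_config()
  g <- build_grid(cfg, c(128L, 8L, 48L), conform = FALSE)
  rc <- (g$edges[[1]][-1] + g$edges[[1]][-length(g$edges[[1]])]) / 2
  zc <- (g$edges[[3]][-1] + g$edges[[3]][-length(g$edges[[3]])]) / 2
  pts <- expand.grid(r = rc, z = zc)
  base <- veincuff:::region_of_cyl(cfg, pts$r, pts$z)
  perm <- rev(veincuff:::vein_regions())
  alt <- veincuff:::region_of_cyl(cfg, pts$r, pts$z, priority = perm)
  changed <- which(base != alt)
  if (length(changed)) {
    # every changed point must lie within one cell width of an interface
    ifaces_r <- c(cfg$r_ground, cfg$vein_inner_radius, cfg$vein_outer_radius,
                  cfg$vein_outer_radius + cfg$cuff_substrate_thickness,
                  cfg$tube_inner_radius + cfg$tube_wall_thickness,
                  cfg$chamber_radius - cfg$chamber_wall_thickness)
    ifaces_z <- c(-1, 1) * cfg$vein_length / 2
    dr <- diff(g$edges[[1]])[1]; dz <- diff(g$edges[[3]])[1]
    near <- vapply(changed, function(i) {
      min(abs(pts$r[i] - ifaces_r)) <= dr ||
        min(abs(pts$z[i] - ifaces_z)) <= dz
    }, logical(1))
    expect_true(all(near))
  } else succeed()
})

test_that("electrode layout follows the ring pattern and rejects overlap", {
  fp <- place_surface_electrodes(geometry_config(n_electrodes = 28))
  expect_identical(nrow(fp), 28L)
  expect_identical(as.integer(table(fp$ring)), rep(7L, 4))
  # angular pitch 2*pi/7 within a ring
  th1 <- sort(fp$theta[fp$ring == 1])
  expect_equal(unique(round(diff(th1), 12)), 2 * pi / 7)
  # rings are centered on the vein
  expect_equal(sort(unique(fp$z)), c(-0.0225, -0.0075, 0.0075, 0.0225))
  # brute-force pairwise surface distances are at least one diameter
  d <- with(fp, {
    dth <- abs(outer(theta, theta, "-")); dth <- pmin(dth, 2 * pi - dth)
    sqrt((fp$r_surface[1] * dth)^2 + outer(z, z, "-")^2)
  })
  expect_gte(min(d[upper.tri(d)]), 2e-3)
  # N = 48 with r_t = 2.5 mm: within-ring pitch 3.665 mm < 5 mm diameter,
  # caught both at validation and at layout, which reports the largest
  # feasible radius
  expect_error(geometry_config(n_electrodes = 48, r_terminal = 2.5e-3),
               "overlap")
  bad <- geometry_config(n_electrodes = 48)
  bad$r_terminal <- 2.5e-3
  expect_error(place_surface_electrodes(bad), "feasible radius")
})

test_that("electrode masks voxelize footprints disjointly per mode", {
  cfg <- geometry_config()
  g <- build_grid(cfg, c(32, 64, 128))
  fp <- place_surface_electrodes(cfg)
  mk <- electrode_masks(g, fp, mode = "simultaneous")
  expect_length(mk$terminals, 28L)
  expect_gt(nrow(mk$ground), 0L)
  # all terminal faces pairwise disjoint and disjoint from ground
  keys <- lapply(mk$terminals, function(fs) paste(fs$axis, fs$i, fs$j, fs$k))
  expect_identical(anyDuplicated(unlist(keys)), 0L)
  # identical snapped face pattern for every electrode (translates)
  counts <- vapply(mk$terminals, nrow, integer(1))
  expect_identical(unname(unique(counts)), unique(counts)[1])

  single <- electrode_masks(g, fp, mode = "single", k = 13)
  expect_length(single$terminals, 1L)
  expect_named(single$terminals, "terminal_13")
  expect_length(single$floating, 0L)
  flt <- electrode_masks(g, fp, mode = "single", k = 13,
                         inactive = "floating")
  expect_length(flt$floating, 27L)
  expect_error(electrode_masks(g, fp, mode = "single", k = 99), "index")

  # a footprint much smaller than a surface face is flagged
  tiny <- fp; tiny$radius <- 5e-5
  expect_error(electrode_masks(g, tiny), "not resolved")
})

test_that("footprint areas approximate the disc area at fine resolution", {
  cfg <- geometry_config()
  g <- build_grid(cfg, c(32, 256, 512))
  fp <- place_surface_electrodes(cfg)
  mk <- electrode_masks(g, fp, mode = "single", k = 1)
  fs <- mk$terminals[[1]]
  w2 <- diff(g$edges[[2]]); w3 <- diff(g$edges[[3]])
  area <- sum(fp$r_surface[1] * w2[fs$j] * w3[fs$k])
  expect_lt(rel_err(area, pi * cfg$r_terminal^2), 0.10)
})

test_that("model config serialization round-trips geometry and materials", {
  cfg <- geometry_config(n_electrodes = 32, r_terminal = 2e-3)
  tab <- default_material_table()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(cfg, tab, path)
  back <- read_model_config(path)
  expect_identical(back$cfg$n_electrodes, 32L)
  expect_identical(back$cfg$r_terminal, 2e-3)
  expect_identical(back$cfg$vein_length, cfg$vein_length)
  expect_identical(names(back$materials), names(tab))
})
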