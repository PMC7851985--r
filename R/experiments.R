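#' Exponentially spaced frequency grid
#'
#' Logarithmically equispaced frequencies with both endpoints included, the
#' spacing used for bioimpedance spectroscopy sweeps (default sweep:
#' 10 Hz to 1 MHz at 5 points per decade, 26 points).
#'
#' @param f_min,f_max Sweep bounds in Hz, `0 < f_min < f_max`.
#' @param points_per_decade Grid density (>= 1).
#' @return Strictly increasing numeric vector of frequencies.
#' @examples
#' frequency_grid(10, 1e6, 1)   # one point per decade: 6 frequencies
#' @export
frequency_grid <- function(f_min = 10, f_max = 1e6, points_per_decade = 5) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_min <= 0 || f_max <= 0)
    stop("frequency bounds must be positive")
  if (f_min >= f_max) stop("f_min must be smaller than f_max")
  if (points_per_decade < 1) stop("points_per_decade must be >= 1")
  n <- max(2L, round(log10(f_max / f_min) * points_per_decade) + 1L)
  f <- 10^seq(log10(f_min), log10(f_max), length.out = n)
  f[1] <- f_min; f[n] <- f_max
  f
}

#' Assemble the cuff-electrode vein model
#'
#' Convenience constructor that builds the labeled grid, electrode layout
#' and Dirichlet masks for one excitation of the vein model.
#'
#' @param cfg A [geometry_config()].
#' @param materials A [material_table()] with the six model regions.
#' @param resolution Grid resolution `c(n_r, n_theta, n_z)`.
#' @param mode `"simultaneous"` or `"single"`.
#' @param position For `mode = "single"`: `"middle"`, `"first_end"` (the
#'   ring nearest the ground-wire exit at positive z), `"second_end"`, or an
#'   explicit electrode index.
#' @param inactive Treatment of undriven electrodes in single mode:
#'   `"substrate"` (absent) or `"floating"`.
#' @param with_vein Set `FALSE` to relabel the vein wall as saline (the
#'   "without the vein" variant of the slice-plot experiments).
#' @return A list of class `vc_model` with `grid`, `masks`, `materials`,
#'   `footprints` and `cfg`.
#' @export
vein_model <- function(cfg = geometry_config(),
                       materials = default_material_table(),
                       resolution = c(32L, 64L, 128L),
                       mode = c("simultaneous", "single"),
                       position = "middle",
                       inactive = c("substrate", "floating"),
                       with_vein = TRUE) {
  mode <- match.arg(mode)
  inactive <- match.arg(inactive)
  stopifnot(inherits(cfg, "vc_geometry"))
  missing_rg <- setdiff(vein_regions(), names(materials))
  if (length(missing_rg))
    stop("material table lacks region(s): ",
         paste(missing_rg, collapse = ", "))
  grid <- build_grid(cfg, resolution)
  if (!with_vein) {
    vid <- region_id(grid, "vein_wall")
    sid <- region_id(grid, "saline")
    grid$labels[grid$labels == vid] <- sid
  }
  fp <- place_surface_electrodes(cfg)
  k <- NULL
  if (mode == "single")
    k <- if (is.character(position)) position_electrode(fp, position)
         else as.integer(position)
  masks <- electrode_masks(grid, fp, mode = mode, k = k, inactive = inactive)
  structure(list(grid = grid, masks = masks, materials = materials,
                 footprints = fp, cfg = cfg, mode = mode, position =
                   if (mode == "single") position else NA, electrode = k),
            class = "vc_model")
}

# resolve a named terminal position to an electrode index. Rings are the
# distinct footprint z values; "first_end" is the ring nearest the ground
# wire exit (positive z), "second_end" the opposite ring, "middle" the ring
# nearest z = 0 (ties resolved toward the exit side). Within the chosen
# ring, the electrode nearest theta = 0 is used.
position_electrode <- function(footprints, position) {
  position <- match.arg(position, c("middle", "first_end", "second_end"))
  ring_z <- sort(unique(footprints$z))
  if (length(ring_z) < 2L && position != "middle")
    stop("end positions need at least two electrode rings")
  zt <- switch(position,
    first_end = max(ring_z),
    second_end = min(ring_z),
    middle = {
      d <- abs(ring_z)
      cand <- ring_z[d == min(d)]
      max(cand)                       # tie toward the ground exit side
    })
  ring <- footprints[footprints$z == zt, ]
  ring$electrode[which.min(ring$theta)]
}

#' Scan the single-terminal position along the vein
#'
#' Solves the single-terminal problem with the driven electrode at the
#' middle of the vein, at the end nearest the ground-wire exit, and at the
#' far end, and reports the vein's contribution for each along with the
#' maximum pairwise difference -- the quantity used to show that the
#' terminal position does not materially change the sensed volume.
#'
#' @inheritParams vein_model
#' @param positions Character vector of terminal positions to compare.
#' @param f Frequency in Hz at which to evaluate (default 1 MHz).
#' @param tol Solver tolerance.
#' @return A list of class `vc_scan`: `results` (tibble with one row per
#'   position: electrode index, vein percentages, impedance) and
#'   `max_pairwise_diff_pp` (percentage points).
#' @export
single_terminal_scan <- function(cfg = geometry_config(),
                                 positions = c("middle", "first_end",
                                               "second_end"),
                                 materials = default_material_table(),
                                 resolution = c(32L, 64L, 128L),
                                 f = 1e6, tol = 1e-8,
                                 inactive = "substrate") {
  fp <- place_surface_electrodes(cfg)
  ks <- vapply(positions, position_electrode, integer(1),
               footprints = fp)
  if (length(unique(ks)) < length(positions))
    stop("the requested positions do not resolve to distinct electrodes")
  rows <- lapply(seq_along(positions), function(m) {
    model <- vein_model(cfg, materials, resolution, mode = "single",
                        position = positions[m], inactive = inactive)
    sol <- assemble_and_solve(model$grid, model$materials, model$masks, f,
                              tol)
    fld <- sensitivity_field(sol)
    cb <- region_contributions(fld, model$grid)
    vein <- cb[cb$region == "vein_wall", ]
    tibble::tibble(position = positions[m], electrode = ks[m],
                   z_density_vein_pct = vein$z_density_pct,
                   power_loss_vein_pct = vein$power_loss_pct,
                   ReZ = Re(sol$Z), ImZ = Im(sol$Z), absZ = Mod(sol$Z))
  })
  res <- dplyr::bind_rows(rows)
  dmax <- max(abs(outer(res$z_density_vein_pct, res$z_density_vein_pct, "-")))
  structure(list(results = res, max_pairwise_diff_pp = dmax,
                 frequency = f, resolution = resolution, cfg = cfg),
            class = "vc_scan")
}

#' @export
print.vc_scan <- function(x, ...) {
  cat("<vc_scan> terminal-position scan at ",
      format(x$frequency, digits = 4), " Hz\n", sep = "")
  print(x$results)
  cat("max pairwise vein-contribution difference: ",
      format(x$max_pairwise_diff_pp, digits = 3), " pp\n", sep = "")
  invisible(x)
}

#' Define an electrode-configuration sweep
#'
#' An experiment plan is a set of electrode configurations (number of
#' electrodes, terminal radius, ground radius, excitation mode and terminal
#' position), plus the common report frequency, resolution and solver
#' settings. [run_configuration_sweep()] validates every configuration
#' before any solve and aborts with the full list of invalid ones.
#'
#' @param configs A data frame with columns `n_electrodes`, `r_terminal`,
#'   `r_ground`, `mode` (`"simultaneous"` or `"single"`) and `position`
#'   (`NA` for simultaneous). Extra geometry fields may be supplied as
#'   additional columns.
#' @param frequency Report frequency in Hz (default 1 MHz, the frequency of
#'   the slice-plot comparisons).
#' @param resolution Grid resolution.
#' @param tol Solver tolerance.
#' @param with_vein Include the venous segment (default `TRUE`).
#' @param inactive Treatment of undriven electrodes in single mode.
#' @return A `vc_plan`.
#' @export
experiment_plan <- function(configs, frequency = 1e6,
                            resolution = c(32L, 64L, 128L), tol = 1e-8,
                            with_vein = TRUE, inactive = "substrate") {
  configs <- tibble::as_tibble(configs)
  need <- c("n_electrodes", "r_terminal", "r_ground", "mode")
  miss <- setdiff(need, names(configs))
  if (length(miss)) stop("configs lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"position" %in% names(configs)) configs$position <- NA_character_
  structure(list(configs = configs, frequency = frequency,
                 resolution = as.integer(resolution), tol = tol,
                 with_vein = with_vein, inactive = inactive),
            class = "vc_plan")
}

#' Run an electrode-configuration sweep
#'
#' Validates every configuration of the plan (fail-fast, reporting all
#' invalid ones), then solves each and tabulates the per-region contribution
#' report in the shape of the electrode-comparison tables: one row per
#' configuration with the vein's volumetric power-loss and volume-impedance
#' -density percentages, the measured impedance, and the full per-region
#' report as a list column.
#'
#' @param plan A [experiment_plan()].
#' @param materials A [material_table()] for the six model regions.
#' @return A tibble of class `vc_sweep` with provenance attributes
#'   (resolution, tolerance, material fingerprint, package version).
#' @export
run_configuration_sweep <- function(plan,
                                    materials = default_material_table()) {
  stopifnot(inherits(plan, "vc_plan"))
  cf <- plan$configs
  geo_args <- intersect(names(cf),
                        setdiff(names(formals(geometry_config)), ""))
  cfgs <- vector("list", nrow(cf)); errs <- character(0)
  for (r in seq_len(nrow(cf))) {
    args <- as.list(cf[r, geo_args])
    cfgs[[r]] <- tryCatch(do.call(geometry_config, args),
                          error = function(e) conditionMessage(e))
    if (is.character(cfgs[[r]]))
      errs <- c(errs, sprintf("config %d (N=%s, r_t=%s, r_g=%s): %s", r,
                              cf$n_electrodes[r], cf$r_terminal[r],
                              cf$r_ground[r], cfgs[[r]]))
  }
  if (length(errs))
    stop("invalid configuration(s):\n  ", paste(errs, collapse = "\n  "))
  rows <- lapply(seq_len(nrow(cf)), function(r) {
    mode <- cf$mode[r]
    model <- vein_model(cfgs[[r]], materials, plan$resolution, mode = mode,
                        position = if (mode == "single") cf$position[r]
                                   else "middle",
                        inactive = plan$inactive,
                        with_vein = plan$with_vein)
    sol <- assemble_and_solve(model$grid, model$materials, model$masks,
                              plan$frequency, plan$tol)
    fld <- sensitivity_field(sol)
    cb <- region_contributions(fld, model$grid)
    vein <- cb[cb$region == "vein_wall", ]
    tibble::tibble(
      n_electrodes = cf$n_electrodes[r],
      r_terminal = cf$r_terminal[r], r_ground = cf$r_ground[r],
      mode = mode, position = cf$position[r],
      power_loss_vein_pct = vein$power_loss_pct,
      z_density_vein_pct = vein$z_density_pct,
      ReZ = Re(sol$Z), ImZ = Im(sol$Z), absZ = Mod(sol$Z),
      phase_deg = atan(Im(sol$Z) / Re(sol$Z)) * 180 / pi,
      contributions = list(cb))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "frequency") <- plan$frequency
  attr(out, "resolution") <- plan$resolution
  attr(out, "tol") <- plan$tol
  attr(out, "materials_fingerprint") <- material_fingerprint(materials)
  attr(out, "package_version") <-
    as.character(utils::packageVersion("veincuff"))
  class(out) <- c("vc_sweep", class(out))
  out
}

#' Extract a midplane slice of a solved field
#'
#' Samples a cell-centered quantity on the y-z midplane (the plane through
#' the vessel axis) for the slice-plot comparisons: electrical potential,
#' current density magnitude, sensitivity magnitude or volume impedance
#' density magnitude. Values are absolute values (the exported slices carry
#' no direction information).
#'
#' @param x A `vc_solution` (for `potential`, `J`) or `vc_field`
#'   (for `S`, `z`; a field also carries nothing else).
#' @param quantity One of `"potential"`, `"J"`, `"S"`, `"z"`.
#' @param offset Signed normal offset of the plane from the axis in metres
#'   (Cartesian grids only); must lie inside the domain.
#' @return A `vc_slice`: list with `values` (matrix), `y`, `z` axis vectors
#'   (m), `quantity`, `units` and `frequency`.
#' @export
export_slice <- function(x, quantity = c("potential", "J", "S", "z"),
                         offset = 0) {
  quantity <- match.arg(quantity)
  units <- c(potential = "V", J = "A/m^2", S = "1/m^4", z = "Ohm/m^2")
  if (inherits(x, "vc_solution")) {
    arr <- switch(quantity,
      potential = Mod(x$V),
      J = sqrt(Mod(x$J[[1]])^2 + Mod(x$J[[2]])^2 + Mod(x$J[[3]])^2),
      stop("quantity '", quantity,
           "' is not available on a solution; use sensitivity_field()"))
    grid <- x$grid; f <- x$frequency
  } else if (inherits(x, "vc_field")) {
    arr <- switch(quantity,
      S = Mod(x$S), z = Mod(x$z),
      stop("quantity '", quantity,
           "' is not available on a sensitivity field; pass the solution"))
    grid <- x$grid; f <- x$frequency
  } else stop("x must be a vc_solution or vc_field")
  ctr <- axis_centers(grid)
  zc <- ctr[[3]]
  if (grid$kind == "cylindrical") {
    if (offset != 0) stop("cylindrical slices are taken through the axis")
    thc <- ctr[[2]]
    jp <- which.min(pmin(abs(thc - pi / 2), 2 * pi - abs(thc - pi / 2)))
    jm <- which.min(pmin(abs(thc - 3 * pi / 2),
                         2 * pi - abs(thc - 3 * pi / 2)))
    vals <- rbind(arr[rev(seq_len(grid$dims[1])), jm, ], arr[, jp, ])
    y <- c(-rev(ctr[[1]]), ctr[[1]])
  } else {
    xe <- grid$edges[[1]]
    if (offset < xe[1] || offset > xe[length(xe)])
      stop("slice plane lies outside the domain")
    i0 <- which.min(abs(ctr[[1]] - offset))
    vals <- arr[i0, , ]
    y <- ctr[[2]]
  }
  structure(list(values = vals, y = y, z = zc, quantity = quantity,
                 units = unname(units[quantity]), frequency = f),
            class = "vc_slice")
}
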