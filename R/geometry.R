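#' Parametric geometry of the cuff-electrode vein model
#'
#' Describes the measurement cell: a PMMA chamber filled with saline, two
#' glass tubes carrying a cylindrical venous segment between them, a thin
#' quartz cuff substrate wrapped around the vein carrying gold surface
#' electrodes on its inner face, and a gold ground wire running along the
#' vessel axis. All lengths are in metres. Defaults follow the reference
#' set-up: vein 6 cm long, 1.4 cm outer diameter, electrodes in 4 axial rings.
#'
#' The ground wire is modeled as spanning the whole axial extent of the
#' domain and leaving the chamber at the positive-z end; "first end" ring
#' positions are defined relative to that exit.
#'
#' @param vein_length Vein axial length (m).
#' @param vein_outer_diameter Vein outer diameter (m).
#' @param vein_wall_thickness Vein wall thickness (m).
#' @param cuff_substrate_thickness Quartz cuff substrate thickness (m).
#' @param chamber_radius,chamber_length Outer radius and length of the
#'   saline-filled PMMA chamber (m).
#' @param chamber_wall_thickness PMMA wall/cap thickness (m).
#' @param tube_inner_radius,tube_wall_thickness Glass tube bore radius and
#'   wall thickness (m).
#' @param n_electrodes Total number of surface electrodes (must be divisible
#'   by `n_rings`); the reference study used 28, 32, 44 and 48.
#' @param n_rings Number of axial electrode rings (default 4).
#' @param r_terminal Surface (terminal) electrode radius (m); reference set
#'   \{1, 2, 2.5\} mm.
#' @param r_ground Ground wire radius (m); reference set \{0.5, 1\} mm.
#' @param ground_length Ground wire length (m); must exceed the tube + vein
#'   span so the wire passes clear through the construct.
#' @return A validated object of class `vc_geometry`.
#' @examples
#' cfg <- geometry_config()
#' cfg$vein_inner_radius
#' @export
geometry_config <- function(vein_length = 0.06,
                            vein_outer_diameter = 0.014,
                            vein_wall_thickness = 5e-4,
                            cuff_substrate_thickness = 5e-4,
                            chamber_radius = 0.025,
                            chamber_length = 0.120,
                            chamber_wall_thickness = 1e-3,
                            tube_inner_radius = 0.007,
                            tube_wall_thickness = 1e-3,
                            n_electrodes = 28L,
                            n_rings = 4L,
                            r_terminal = 1e-3,
                            r_ground = 0.5e-3,
                            ground_length = 0.13) {
  cfg <- list(
    vein_length = vein_length,
    vein_outer_diameter = vein_outer_diameter,
    vein_wall_thickness = vein_wall_thickness,
    cuff_substrate_thickness = cuff_substrate_thickness,
    chamber_radius = chamber_radius,
    chamber_length = chamber_length,
    chamber_wall_thickness = chamber_wall_thickness,
    tube_inner_radius = tube_inner_radius,
    tube_wall_thickness = tube_wall_thickness,
    n_electrodes = as.integer(n_electrodes),
    n_rings = as.integer(n_rings),
    r_terminal = r_terminal,
    r_ground = r_ground,
    ground_length = ground_length)
  cfg$vein_outer_radius <- vein_outer_diameter / 2
  cfg$vein_inner_radius <- cfg$vein_outer_radius - vein_wall_thickness
  class(cfg) <- "vc_geometry"
  problems <- validate_geometry_config(cfg)
  if (length(problems))
    stop("invalid geometry configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg
}

#' Validate a geometry configuration
#'
#' Checks the structural invariants of the model; returns a character vector
#' of problems (empty when valid) rather than stopping, so that sweep drivers
#' can report every invalid configuration at once.
#'
#' @param cfg A `vc_geometry` (or a bare list with the same fields).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_geometry_config <- function(cfg) {
  p <- character(0)
  add <- function(msg) p <<- c(p, msg)
  num_pos <- c("vein_length", "vein_outer_diameter", "vein_wall_thickness",
               "cuff_substrate_thickness", "chamber_radius", "chamber_length",
               "chamber_wall_thickness", "tube_inner_radius",
               "tube_wall_thickness", "r_terminal", "r_ground", "ground_length")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      add(paste0(f, " must be a positive number"))
  if (length(p)) return(p)
  r_out <- cfg$vein_outer_diameter / 2
  r_in <- r_out - cfg$vein_wall_thickness
  if (r_in <= 0) add("vein wall thicker than the vein radius")
  if (cfg$r_ground >= r_in)
    add("r_ground must be smaller than the vein inner radius")
  if (cfg$n_electrodes < 1L || cfg$n_rings < 1L)
    add("n_electrodes and n_rings must be positive")
  if (cfg$n_electrodes %% cfg$n_rings != 0L)
    add("n_electrodes must be divisible by n_rings")
  if (cfg$r_terminal >= cfg$vein_length / (2 * cfg$n_rings))
    add("r_terminal must be smaller than vein_length / (2 * n_rings)")
  if (cfg$n_electrodes >= 1L && cfg$n_rings >= 1L &&
      cfg$n_electrodes %% cfg$n_rings == 0L) {
    n_per <- cfg$n_electrodes %/% cfg$n_rings
    if (n_per > 1L && pi * cfg$vein_outer_diameter / n_per <
        2 * cfg$r_terminal)
      add("electrode footprints would overlap within a ring")
  }
  if (cfg$vein_length >= cfg$chamber_length - 2 * cfg$chamber_wall_thickness)
    add("vein must fit inside the chamber")
  if (cfg$tube_inner_radius < r_out)
    add("glass tube bore must be at least the vein outer radius")
  if (cfg$tube_inner_radius + cfg$tube_wall_thickness >=
      cfg$chamber_radius - cfg$chamber_wall_thickness)
    add("glass tubes must fit inside the chamber wall")
  if (r_out + cfg$cuff_substrate_thickness > cfg$tube_inner_radius +
      cfg$tube_wall_thickness)
    add("cuff substrate must not extend beyond the tube outer radius")
  # the ground wire must pass clear through the tube + vein construct
  if (cfg$ground_length <= cfg$chamber_length)
    add("ground_length must exceed the tube + vein span (the chamber length)")
  p
}

#' @export
print.vc_geometry <- function(x, ...) {
  cat("<vc_geometry> vein ", x$vein_length * 100, " cm x ",
      x$vein_outer_diameter * 1000, " mm; ",
      x$n_electrodes, " electrodes in ", x$n_rings, " rings; r_t = ",
      x$r_terminal * 1000, " mm, r_g = ", x$r_ground * 1000, " mm\n", sep = "")
  invisible(x)
}

# ---- surface electrode layout -----------------------------------------------

#' Lay out the surface electrodes on the cuff
#'
#' Electrodes are circular gold patches on the inner face of the cuff (the
#' vein outer surface). They are arranged on `n_rings` equispaced axial rings
#' centered on the vein, with `n_electrodes / n_rings` electrodes equispaced
#' in angle within each ring. Footprints must not overlap in the cylinder
#' surface metric.
#'
#' @param cfg A [geometry_config()].
#' @return A tibble with one row per electrode: `electrode` (1-based index),
#'   `ring`, `index_in_ring`, `theta` (rad), `z` (m), `r_surface` (m, the
#'   cylinder radius the patch sits on) and `radius` (m, the patch radius).
#' @export
place_surface_electrodes <- function(cfg) {
  stopifnot(inherits(cfg, "vc_geometry"))
  if (cfg$n_electrodes %% cfg$n_rings != 0L)
    stop("n_electrodes must be divisible by n_rings")
  n_per <- cfg$n_electrodes %/% cfg$n_rings
  rs <- cfg$vein_outer_radius
  pitch_z <- cfg$vein_length / cfg$n_rings
  ring_z <- (seq_len(cfg$n_rings) - (cfg$n_rings + 1) / 2) * pitch_z
  fp <- tibble::tibble(
    ring = rep(seq_len(cfg$n_rings), each = n_per),
    index_in_ring = rep(seq_len(n_per), times = cfg$n_rings))
  fp$theta <- (fp$index_in_ring - 1L) * 2 * pi / n_per
  fp$z <- ring_z[fp$ring]
  fp$electrode <- seq_len(nrow(fp))
  fp$r_surface <- rs
  fp$radius <- cfg$r_terminal
  fp <- fp[, c("electrode", "ring", "index_in_ring", "theta", "z",
               "r_surface", "radius")]
  dmin <- min_footprint_distance(fp)
  if (dmin < 2 * cfg$r_terminal)
    stop(sprintf(paste0("electrode footprints overlap: minimum pairwise ",
                        "surface distance %.4g mm < electrode diameter %.4g mm",
                        " (maximum feasible radius %.4g mm)"),
                 dmin * 1e3, 2 * cfg$r_terminal * 1e3, dmin / 2 * 1e3))
  fp
}

# minimum pairwise center distance in the cylinder surface metric
min_footprint_distance <- function(fp) {
  n <- nrow(fp)
  if (n < 2L) return(Inf)
  th <- fp$theta; z <- fp$z; rs <- fp$r_surface[1]
  dth <- abs(outer(th, th, "-"))
  dth <- pmin(dth, 2 * pi - dth)
  d <- sqrt((rs * dth)^2 + outer(z, z, "-")^2)
  min(d[upper.tri(d)])
}

# ---- voxelization -----------------------------------------------------------

# allocate n cells across layers of given widths: at least 2 per layer,
# proportional to width, deterministic largest-remainder rounding. A layer
# whose proportional share falls below half a cell triggers a resolution error.
allocate_layer_cells <- function(widths, n, names, min_each = 2L) {
  share <- widths / sum(widths) * n
  thin <- share < 0.5
  if (any(thin))
    stop("resolution too coarse for layer(s) ",
         paste(names[thin], collapse = ", "),
         ": increase the cell count or thicken the layer")
  L <- length(widths)
  if (n < min_each * L)
    stop("resolution too coarse: ", n, " cells cannot give every layer (",
         paste(names, collapse = ", "), ") at least ", min_each, " cells")
  # min_each per layer, remainder split by width (largest-remainder rounding)
  extra <- widths / sum(widths) * (n - min_each * L)
  base <- rep.int(min_each, L) + floor(extra)
  rem <- n - sum(base)
  ord <- order(extra - floor(extra), decreasing = TRUE)
  if (rem > 0L) base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  base
}

# subdivide [a, b] into n cells; geometric grading (constant dr/r) when
# grade = TRUE and a > 0, else uniform
subdivide <- function(a, b, n, grade = FALSE) {
  if (grade && a > 0) a * (b / a)^(seq(0, n) / n) else seq(a, b, length.out = n + 1)
}

# region of cylindrical points (r, z): each solid is a membership predicate
# and a point takes the highest-priority solid containing it. Default
# priority: gold > substrate > vein > glass > saline > chamber.
region_of_cyl <- function(cfg, r, z, priority = vein_regions()) {
  stopifnot(setequal(priority, vein_regions()))
  r_out <- cfg$vein_outer_radius
  r_in <- cfg$vein_inner_radius
  sub_out <- r_out + cfg$cuff_substrate_thickness
  tb_in <- cfg$tube_inner_radius
  tb_out <- tb_in + cfg$tube_wall_thickness
  ch_in <- cfg$chamber_radius - cfg$chamber_wall_thickness
  zl <- cfg$vein_length / 2
  cap_in <- cfg$chamber_length / 2 - cfg$chamber_wall_thickness
  az <- abs(z)
  # solids are mutually exclusive up to their shared boundaries (half-open
  # in r and z), so the priority order only breaks boundary ties
  vein <- r >= r_in & r < r_out & az < zl
  subs <- r >= r_out & r < sub_out & az < zl
  glass <- r >= tb_in & r < tb_out & az >= zl
  chamb <- (az < cap_in & r >= ch_in) | (az >= cap_in & r >= tb_out)
  solids <- list(
    gold_electrode = rep.int(FALSE, length(r)),   # surface patches only
    quartz_substrate = subs, vein_wall = vein, glass_tube = glass,
    pmma_chamber = chamb)
  solids$saline <- !(vein | subs | glass | chamb)
  lbl <- rep.int(NA_integer_, length(r))
  for (nm in rev(priority))
    lbl[solids[[nm]]] <- match(nm, vein_regions())
  lbl
}

#' Voxelize the parametric model into a labeled cylindrical grid
#'
#' Builds a cell-centered cylindrical grid over the annulus between the
#' ground-wire surface (`r = r_ground`, the inner Dirichlet boundary) and the
#' chamber outer radius. With `conform = TRUE` (the default) the radial and
#' axial grid lines are snapped to every material interface and each
#' interface layer receives at least two cells, so region volumes are exact;
#' radial layers are geometrically graded (constant `dr/r`). With
#' `conform = FALSE` the spacing is uniform and cells take the region of
#' their center, which is useful for studying voxelization convergence.
#'
#' @param cfg A [geometry_config()].
#' @param resolution Integer vector `c(n_r, n_theta, n_z)`; each component
#'   must be at least 8.
#' @param conform Snap grid lines to material interfaces (default `TRUE`).
#' @return A [vc_grid] labeled with the six model regions.
#' @export
build_grid <- function(cfg, resolution = c(32L, 64L, 128L), conform = TRUE) {
  stopifnot(inherits(cfg, "vc_geometry"), length(resolution) == 3L)
  resolution <- as.integer(resolution)
  if (any(resolution < 8L)) stop("each resolution component must be >= 8")
  r_out <- cfg$vein_outer_radius
  sub_out <- r_out + cfg$cuff_substrate_thickness
  tb_out <- cfg$tube_inner_radius + cfg$tube_wall_thickness
  ch_in <- cfg$chamber_radius - cfg$chamber_wall_thickness
  zl <- cfg$vein_length / 2
  zc <- cfg$chamber_length / 2
  cap_in <- zc - cfg$chamber_wall_thickness

  if (conform) {
    r_br <- sort(unique(c(cfg$r_ground, cfg$vein_inner_radius, r_out, sub_out,
                          tb_out, ch_in, cfg$chamber_radius)))
    r_nm <- c("lumen", "vein_wall", "cuff_substrate", "tube_wall",
              "outer_saline", "chamber_wall")[seq_len(length(r_br) - 1)]
    nr <- allocate_layer_cells(diff(r_br), resolution[1], r_nm)
    r_edges <- unique(unlist(lapply(seq_along(nr), function(l)
      subdivide(r_br[l], r_br[l + 1], nr[l], grade = TRUE))))
    z_br <- sort(unique(c(-zc, -cap_in, -zl, zl, cap_in, zc)))
    z_nm <- c("cap", "tube_span", "vein_span", "tube_span", "cap")
    nz <- allocate_layer_cells(diff(z_br), resolution[3], z_nm)
    z_edges <- unique(unlist(lapply(seq_along(nz), function(l)
      subdivide(z_br[l], z_br[l + 1], nz[l]))))
  } else {
    r_edges <- seq(cfg$r_ground, cfg$chamber_radius,
                   length.out = resolution[1] + 1)
    z_edges <- seq(-zc, zc, length.out = resolution[3] + 1)
    # the vein wall must still be resolved by at least 2 radial cells
    if (cfg$vein_wall_thickness < 2 * diff(r_edges)[1])
      stop("resolution too coarse for layer vein_wall: ",
           "wall thinner than two radial cells")
  }
  th_edges <- seq(0, 2 * pi, length.out = resolution[2] + 1)

  rc <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  zcc <- (z_edges[-1] + z_edges[-length(z_edges)]) / 2
  n1 <- length(rc); n2 <- resolution[2]; n3 <- length(zcc)
  # the model is axisymmetric, so label an (r, z) sheet and replicate in theta
  lbl2d <- region_of_cyl(cfg, rep(rc, times = n3), rep(zcc, each = n1))
  labels <- array(0L, c(n1, n2, n3))
  l2 <- array(lbl2d, c(n1, n3))
  for (j in seq_len(n2)) labels[, j, ] <- l2
  new_grid("cylindrical", list(r_edges, th_edges, z_edges), labels,
           vein_regions())
}

# ---- electrode masks --------------------------------------------------------

# face-set tibble constructor: (axis, i, j, k, side, type)
# type "boundary": the face on `side` of cell (i,j,k);
# type "internal": the face between (i,j,k) and its axis-neighbor (side +1)
face_set <- function(axis, i, j, k, side, type) {
  tibble::tibble(axis = as.integer(axis), i = as.integer(i), j = as.integer(j),
                 k = as.integer(k), side = as.integer(side), type = type)
}

#' Build Dirichlet masks for an excitation mode
#'
#' Voxelizes the electrode footprints onto the grid's cuff surface (the
#' radial interface at the vein outer radius) and returns the Dirichlet face
#' masks for one excitation: all footprints driven at the terminal potential
#' (`mode = "simultaneous"`), or a single footprint `k` driven
#' (`mode = "single"`). The axial ground wire is always held at 0 V via the
#' inner radial boundary. Electrode centers are snapped to the surface face
#' lattice so that nominally identical electrodes receive identical face
#' patterns regardless of their angular or axial position.
#'
#' Inactive electrodes in single mode are by default electrically absent
#' (replaced by substrate); `inactive = "floating"` instead models each as an
#' ideal floating conductor carrying zero net current.
#'
#' @param grid A [build_grid()] result.
#' @param footprints A [place_surface_electrodes()] tibble.
#' @param mode `"simultaneous"` or `"single"`.
#' @param k Electrode index (1-based) when `mode = "single"`.
#' @param inactive `"substrate"` (default) or `"floating"`.
#' @return A `vc_masks` object: named list of active terminal face sets, the
#'   ground face set, and any floating face sets.
#' @export
electrode_masks <- function(grid, footprints, mode = c("simultaneous", "single"),
                            k = NULL, inactive = c("substrate", "floating")) {
  mode <- match.arg(mode)
  inactive <- match.arg(inactive)
  stopifnot(inherits(grid, "vc_grid"), grid$kind == "cylindrical")
  rs <- footprints$r_surface[1]
  r_edges <- grid$edges[[1]]
  i_face <- which.min(abs(r_edges - rs))   # interface edge index
  if (abs(r_edges[i_face] - rs) > 1e-9)
    stop("grid has no radial interface at the cuff surface radius; ",
         "build the grid with conform = TRUE")
  if (i_face < 2L || i_face > length(r_edges) - 1L)
    stop("cuff surface must be an interior radial interface")
  i_cell <- i_face - 1L                    # cell on the vein side of the face
  thc <- axis_centers(grid)[[2]]
  zc <- axis_centers(grid)[[3]]
  n2 <- grid$dims[2]; n3 <- grid$dims[3]
  # face lattice on the surface: (theta_j, z_k)
  fj <- rep(seq_len(n2), times = n3)
  fk <- rep(seq_len(n3), each = n2)
  assign_faces <- function(fp) {
    # snap each electrode center to the nearest face center
    js <- vapply(fp$theta, function(t) {
      d <- abs(thc - t); d <- pmin(d, 2 * pi - d); which.min(d) }, integer(1))
    ks <- vapply(fp$z, function(z) which.min(abs(zc - z)), integer(1))
    dth <- abs(outer(thc[fj], thc[js], "-"))
    dth <- pmin(dth, 2 * pi - dth)
    dsur <- sqrt((rs * dth)^2 + outer(zc[fk], zc[ks], "-")^2)
    inside <- dsur <= matrix(fp$radius, nrow(dsur), nrow(fp), byrow = TRUE)
    owner <- max.col(-dsur, ties.method = "first")     # nearest center
    sel <- inside[cbind(seq_along(owner), owner)]
    split(which(sel), fp$electrode[owner[sel]])
  }
  face_lists <- assign_faces(footprints)
  got <- as.integer(names(face_lists))
  missing_e <- setdiff(footprints$electrode, got)
  if (length(missing_e))
    stop("electrode footprint(s) ", paste(missing_e, collapse = ", "),
         " are finer than the grid surface faces; increase the resolution")
  # guard against grossly mis-voxelized footprints: the captured surface
  # area must be within a factor 4 of the nominal disc area
  w <- axis_widths(grid)
  for (e in got) {
    idx <- face_lists[[as.character(e)]]
    area <- sum(rs * w[[2]][fj[idx]] * w[[3]][fk[idx]])
    nominal <- pi * footprints$radius[footprints$electrode == e]^2
    if (area > 4 * nominal || area < nominal / 4)
      stop("electrode ", e, " footprint is not resolved by the grid ",
           "surface faces (voxelized area ", format(area * 1e6, digits = 3),
           " vs nominal ", format(nominal * 1e6, digits = 3),
           " mm^2); adjust the resolution")
  }
  as_face_set <- function(idx) {
    face_set(1L, rep(i_cell, length(idx)), fj[idx], fk[idx], 1L, "internal")
  }
  terminals <- list(); floating <- list()
  if (mode == "simultaneous") {
    terminals <- lapply(face_lists[order(got)], as_face_set)
    names(terminals) <- paste0("terminal_", sort(got))
  } else {
    if (is.null(k) || !k %in% footprints$electrode)
      stop("mode = 'single' requires an electrode index k in the layout")
    terminals <- list(as_face_set(face_lists[[as.character(k)]]))
    names(terminals) <- paste0("terminal_", k)
    if (inactive == "floating") {
      idle <- setdiff(got, k)
      floating <- lapply(face_lists[as.character(idle)], as_face_set)
      names(floating) <- paste0("floating_", idle)
    }
  }
  # ground: every inner radial boundary face (the wire spans the full axis)
  gj <- rep(seq_len(n2), times = n3)
  gk <- rep(seq_len(n3), each = n2)
  ground <- face_set(1L, rep(1L, length(gj)), gj, gk, -1L, "boundary")
  new_masks(terminals, ground, floating)
}

new_masks <- function(terminals, ground, floating = list(), u_volts = 1) {
  structure(list(terminals = terminals, ground = ground,
                 floating = floating, u_volts = u_volts),
            class = "vc_masks")
}

#' @export
print.vc_masks <- function(x, ...) {
  nf <- sum(vapply(x$terminals, nrow, integer(1)))
  cat("<vc_masks> ", length(x$terminals), " active terminal(s) at ",
      x$u_volts, " V (", nf, " faces), ground at 0 V (", nrow(x$ground),
      " faces)", sep = "")
  if (length(x$floating)) cat(",", length(x$floating), "floating conductor(s)")
  cat("\n")
  invisible(x)
}
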