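#' Structured region-labeled grids
#'
#' A `vc_grid` is a cell-centered structured grid in either cylindrical
#' `(r, theta, z)` or Cartesian `(x, y, z)` coordinates. Cells carry exactly
#' one region label; labels partition the grid. The cylindrical grid is
#' periodic in theta, with theta in `[0, 2*pi)` and `z` along the vessel axis.
#'
#' @name vc_grid
#' @keywords internal
NULL

# Construct a labeled grid. edges: list of three strictly increasing numeric
# vectors (for cylindrical: r, theta, z; theta edges must span [0, 2*pi]).
# labels: integer array (n1 x n2 x n3) indexing into `regions`.
new_grid <- function(kind, edges, labels, regions) {
  kind <- match.arg(kind, c("cylindrical", "cartesian"))
  stopifnot(length(edges) == 3L)
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  stopifnot(all(dims >= 1L), identical(dim(labels), dims))
  if (kind == "cylindrical") {
    stopifnot(edges[[1]][1] >= 0,
              abs(edges[[2]][1]) < 1e-12,
              abs(edges[[2]][length(edges[[2]])] - 2 * pi) < 1e-12)
  }
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > length(regions)))
    stop("labels must index into the region vector")
  structure(
    list(kind = kind, edges = edges, dims = dims,
         labels = labels, regions = regions,
         periodic = c(FALSE, kind == "cylindrical", FALSE)),
    class = "vc_grid")
}

#' @export
print.vc_grid <- function(x, ...) {
  ax <- if (x$kind == "cylindrical") c("r", "theta", "z") else c("x", "y", "z")
  cat("<vc_grid> ", x$kind, " ", paste(x$dims, collapse = " x "),
      " (", prod(x$dims), " cells)\n", sep = "")
  for (d in 1:3) {
    e <- x$edges[[d]]
    cat("  ", ax[d], ": [", format(e[1], digits = 4), ", ",
        format(e[length(e)], digits = 4), "]",
        if (x$periodic[d]) " (periodic)", "\n", sep = "")
  }
  vols <- region_volumes(x)
  cat("  regions:", paste0(names(vols), " (",
      format(vols * 1e6, digits = 3), " cm^3)", collapse = ", "), "\n")
  invisible(x)
}

# cell-center coordinates along each axis
axis_centers <- function(grid) {
  lapply(grid$edges, function(e) (e[-1] + e[-length(e)]) / 2)
}

# cell widths along each axis
axis_widths <- function(grid) {
  lapply(grid$edges, diff)
}

#' Cell volumes of a grid
#'
#' Exact cell volumes: `dx*dy*dz` for Cartesian grids and
#' `(r_o^2 - r_i^2)/2 * dtheta * dz` for cylindrical grids, so that the cell
#' volumes sum exactly to the analytic domain volume.
#'
#' @param grid A `vc_grid`.
#' @return Numeric array of dim `grid$dims`, in cubic metres.
#' @export
cell_volumes <- function(grid) {
  w <- axis_widths(grid)
  if (grid$kind == "cartesian") {
    a1 <- w[[1]]
  } else {
    e <- grid$edges[[1]]
    a1 <- (e[-1]^2 - e[-length(e)]^2) / 2
  }
  outer(outer(a1, w[[2]]), w[[3]])
}

#' Per-region volumes
#'
#' @param grid A `vc_grid`.
#' @return Named numeric vector (m^3), one entry per region name of the grid
#'   (zero for regions with no cells).
#' @export
region_volumes <- function(grid) {
  v <- cell_volumes(grid)
  out <- vapply(seq_along(grid$regions),
                function(i) sum(v[grid$labels == i]), numeric(1))
  names(out) <- grid$regions
  out
}

# integer id of each region name; error if absent from the grid's region set
region_id <- function(grid, region) {
  i <- match(region, grid$regions)
  if (any(is.na(i))) stop("unknown region(s): ",
                          paste(region[is.na(i)], collapse = ", "))
  i
}

# linear cell index from (i, j, k) triplets
cell_id <- function(dims, i, j, k) {
  i + dims[1] * ((j - 1L) + dims[2] * (k - 1L))
}

# Geometric data of every interior face normal to `axis`, vectorized.
# Returns index triplets of the low-side cell (i,j,k), the high-side cell
# (in, jn, kn), face area A, and half-distances dL, dR from the adjacent
# cell centers to the face. Periodic axes include the wrap face.
face_geometry <- function(grid, axis) {
  d <- grid$dims; e <- grid$edges; w <- axis_widths(grid)
  cy <- grid$kind == "cylindrical"
  rc <- axis_centers(grid)[[1]]
  if (axis == 1L) {
    if (d[1] < 2L) return(NULL)
    i <- rep(seq_len(d[1] - 1L), times = d[2] * d[3])
    j <- rep(rep(seq_len(d[2]), each = d[1] - 1L), times = d[3])
    k <- rep(seq_len(d[3]), each = (d[1] - 1L) * d[2])
    if (cy) A <- e[[1]][i + 1L] * w[[2]][j] * w[[3]][k]
    else A <- w[[2]][j] * w[[3]][k]
    list(i = i, j = j, k = k, ip = i + 1L, jp = j, kp = k,
         A = A, dL = w[[1]][i] / 2, dR = w[[1]][i + 1L] / 2)
  } else if (axis == 2L) {
    nf <- if (grid$periodic[2]) d[2] else d[2] - 1L
    if (nf < 1L) return(NULL)
    i <- rep(seq_len(d[1]), times = nf * d[3])
    j <- rep(rep(seq_len(nf), each = d[1]), times = d[3])
    k <- rep(seq_len(d[3]), each = d[1] * nf)
    jp <- ifelse(j == d[2], 1L, j + 1L)
    if (cy) {
      A <- w[[1]][i] * w[[3]][k]
      h <- rc[i]                       # arc metric at the cell-center radius
    } else {
      A <- w[[1]][i] * w[[3]][k]
      h <- 1
    }
    list(i = i, j = j, k = k, ip = i, jp = jp, kp = k,
         A = A, dL = h * w[[2]][j] / 2, dR = h * w[[2]][jp] / 2)
  } else {
    if (d[3] < 2L) return(NULL)
    i <- rep(seq_len(d[1]), times = d[2] * (d[3] - 1L))
    j <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3] - 1L)
    k <- rep(seq_len(d[3] - 1L), each = d[1] * d[2])
    if (cy) {
      er <- e[[1]]
      A <- (er[i + 1L]^2 - er[i]^2) / 2 * w[[2]][j]
    } else {
      A <- w[[1]][i] * w[[2]][j]
    }
    list(i = i, j = j, k = k, ip = i, jp = j, kp = k + 1L,
         A = A, dL = w[[3]][k] / 2, dR = w[[3]][k + 1L] / 2)
  }
}

# Area and half-distance of boundary faces of cells (i,j,k) on side -1/+1 of
# `axis` (vectorized over equal-length i, j, k).
boundary_face_geometry <- function(grid, axis, i, j, k, side) {
  w <- axis_widths(grid); e <- grid$edges
  cy <- grid$kind == "cylindrical"
  if (axis == 1L) {
    re <- if (side < 0) e[[1]][i] else e[[1]][i + 1L]
    A <- if (cy) re * w[[2]][j] * w[[3]][k] else w[[2]][j] * w[[3]][k]
    list(A = A, dh = w[[1]][i] / 2)
  } else if (axis == 2L) {
    rc <- axis_centers(grid)[[1]]
    A <- w[[1]][i] * w[[3]][k]
    h <- if (cy) rc[i] else 1
    list(A = A, dh = h * w[[2]][j] / 2)
  } else {
    A <- if (cy) (e[[1]][i + 1L]^2 - e[[1]][i]^2) / 2 * w[[2]][j]
         else w[[1]][i] * w[[2]][j]
    list(A = A, dh = w[[3]][k] / 2)
  }
}

# map per-cell values by region: sigma_star array for a material table at f
sigma_star_array <- function(grid, materials, f) {
  vals <- vapply(grid$regions, function(rg)
    admittivity(material_for(materials, rg), f), complex(1))
  array(vals[grid$labels], dim = grid$dims)
}

rho_array <- function(grid, materials, f) {
  vals <- vapply(grid$regions, function(rg) {
    a <- admittivity(material_for(materials, rg), f)
    if (a == 0) stop("complex resistivity undefined for region '", rg,
                     "' (zero admittivity)")
    1 / a
  }, complex(1))
  array(vals[grid$labels], dim = grid$dims)
}
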