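#' Analytic validation phantoms
#'
#' Phantoms are small models with closed-form impedances used to validate
#' the solver and the sensitivity machinery without any external data:
#'
#' * `slab`: a rectangular block with full-face electrodes on the two z
#'   faces; `Z = L / (sigma* A)`.
#' * `series_bilayer`: a slab of two materials stacked along z;
#'   `Z = L1/(sigma1* A) + L2/(sigma2* A)`, and the region contributions are
#'   the series-resistor fractions.
#' * `coaxial`: an annulus between radii `a` (ground) and `b` (terminal);
#'   `Z = ln(b/a) / (2 pi sigma* L)`.
#' * `homogeneous_cylinder`: a solid cylinder with full end-face electrodes;
#'   `Z = L / (sigma* pi (b^2 - a^2))`.
#'
#' @param kind One of `"slab"`, `"series_bilayer"`, `"coaxial"`,
#'   `"homogeneous_cylinder"`.
#' @param Lx,Ly,Lz Cartesian dimensions in metres (slab and bilayer).
#' @param a,b,L Inner radius, outer radius and length in metres (cylindrical
#'   kinds); `a = 0` is allowed for the solid cylinder.
#' @param split Fraction of `Lz` occupied by the first bilayer layer.
#' @param sigma Conductivity in S/m; a length-2 vector for the bilayer.
#' @param eps_r Relative permittivity; recycled like `sigma`.
#' @return A `vc_phantom` specification.
#' @examples
#' ph <- phantom_spec("slab", sigma = 1)
#' analytic_impedance(ph, 0)          # 100 Ohm for the 10 mm, 1 cm^2 default
#' @export
phantom_spec <- function(kind = c("slab", "series_bilayer", "coaxial",
                                  "homogeneous_cylinder"),
                         Lx = 0.01, Ly = 0.01, Lz = 0.01,
                         a = 1e-3, b = 2e-3, L = 0.06, split = 0.5,
                         sigma = 1, eps_r = 1) {
  kind <- match.arg(kind)
  n_mat <- if (kind == "series_bilayer") 2L else 1L
  sigma <- rep_len(sigma, n_mat)
  eps_r <- rep_len(eps_r, n_mat)
  if (kind %in% c("coaxial", "homogeneous_cylinder")) {
    if (b < a || a < 0 || L <= 0) stop("need 0 <= a <= b and L > 0")
    if (kind == "coaxial" && a == 0) stop("coaxial phantom needs a > 0")
  } else {
    if (Lx <= 0 || Ly <= 0 || Lz <= 0) stop("dimensions must be positive")
    if (kind == "series_bilayer" && (split <= 0 || split >= 1))
      stop("split must lie strictly inside (0, 1)")
  }
  structure(list(kind = kind, Lx = Lx, Ly = Ly, Lz = Lz, a = a, b = b,
                 L = L, split = split, sigma = sigma, eps_r = eps_r),
            class = "vc_phantom")
}

#' Closed-form impedance of a phantom
#'
#' The analytic complex impedance, including the parallel-capacitance term
#' through the complex admittivity \eqn{\sigma^* = \sigma + i\omega
#' \varepsilon_0\varepsilon_r}. The degenerate coaxial annulus (`b == a`)
#' returns 0.
#'
#' @param spec A [phantom_spec()].
#' @param f Frequency in Hz (vectorized).
#' @return Complex impedance in Ohm.
#' @export
analytic_impedance <- function(spec, f) {
  stopifnot(inherits(spec, "vc_phantom"))
  sst <- function(m) complex(real = spec$sigma[m],
                             imaginary = 2 * pi * f * eps0 * spec$eps_r[m])
  switch(spec$kind,
    slab = spec$Lz / (sst(1) * spec$Lx * spec$Ly),
    series_bilayer = spec$Lz * spec$split / (sst(1) * spec$Lx * spec$Ly) +
      spec$Lz * (1 - spec$split) / (sst(2) * spec$Lx * spec$Ly),
    coaxial = if (spec$b == spec$a) 0 + 0i else
      log(spec$b / spec$a) / (2 * pi * sst(1) * spec$L),
    homogeneous_cylinder =
      spec$L / (sst(1) * pi * (spec$b^2 - spec$a^2)),
    stop("unsupported phantom kind"))
}

#' Voxelize a phantom into a grid, masks and material table
#'
#' Builds the grid (Cartesian for slab kinds, cylindrical for the annular
#' kinds), the 1 V / 0 V Dirichlet boundary masks and a matching material
#' table, ready for [assemble_and_solve()]. The bilayer interface is snapped
#' to a grid plane. Deterministic.
#'
#' @param spec A [phantom_spec()].
#' @param resolution Integer `c(n1, n2, n3)` cell counts per axis
#'   (`r, theta, z` for cylindrical kinds).
#' @return A list with components `grid`, `masks`, `materials` and `spec`.
#' @export
make_phantom <- function(spec, resolution = c(8L, 8L, 16L)) {
  stopifnot(inherits(spec, "vc_phantom"), length(resolution) == 3L)
  n <- as.integer(resolution)
  if (any(n < 1L)) stop("resolution components must be positive")
  if (spec$kind %in% c("slab", "series_bilayer")) {
    xe <- seq(0, spec$Lx, length.out = n[1] + 1)
    ye <- seq(0, spec$Ly, length.out = n[2] + 1)
    if (spec$kind == "series_bilayer") {
      zi <- spec$Lz * spec$split
      n1 <- max(1L, round(n[3] * spec$split)); n2 <- max(1L, n[3] - n1)
      ze <- unique(c(seq(0, zi, length.out = n1 + 1),
                     seq(zi, spec$Lz, length.out = n2 + 1)))
      regions <- c("layer1", "layer2")
      zc <- (ze[-1] + ze[-length(ze)]) / 2
      lab_z <- ifelse(zc < zi, 1L, 2L)
    } else {
      ze <- seq(0, spec$Lz, length.out = n[3] + 1)
      regions <- "medium"
      lab_z <- rep(1L, n[3])
    }
    labels <- array(rep(lab_z, each = n[1] * n[2]),
                    c(n[1], n[2], length(lab_z)))
    grid <- new_grid("cartesian", list(xe, ye, ze), labels, regions)
    d <- grid$dims
    jk <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
    terminal <- face_set(3L, jk$i, jk$j, rep(1L, nrow(jk)), -1L, "boundary")
    ground <- face_set(3L, jk$i, jk$j, rep(d[3], nrow(jk)), 1L, "boundary")
    specs <- lapply(seq_along(regions), function(m)
      material_spec(regions[m], sigma = spec$sigma[m], eps_r = spec$eps_r[m]))
    names(specs) <- regions
  } else {
    re <- seq(spec$a, spec$b, length.out = n[1] + 1)
    the <- seq(0, 2 * pi, length.out = n[2] + 1)
    ze <- seq(-spec$L / 2, spec$L / 2, length.out = n[3] + 1)
    labels <- array(1L, c(n[1], n[2], n[3]))
    grid <- new_grid("cylindrical", list(re, the, ze), labels, "medium")
    d <- grid$dims
    if (spec$kind == "coaxial") {
      jk <- expand.grid(j = seq_len(d[2]), k = seq_len(d[3]))
      ground <- face_set(1L, rep(1L, nrow(jk)), jk$j, jk$k, -1L, "boundary")
      terminal <- face_set(1L, rep(d[1], nrow(jk)), jk$j, jk$k, 1L,
                           "boundary")
    } else {
      ij <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
      terminal <- face_set(3L, ij$i, ij$j, rep(1L, nrow(ij)), -1L,
                           "boundary")
      ground <- face_set(3L, ij$i, ij$j, rep(d[3], nrow(ij)), 1L, "boundary")
    }
    specs <- list(medium = material_spec("medium", sigma = spec$sigma[1],
                                         eps_r = spec$eps_r[1]))
  }
  masks <- new_masks(list(terminal_1 = terminal), ground)
  list(grid = grid, masks = masks, materials = material_table(specs),
       spec = spec)
}
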