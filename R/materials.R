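#' Vacuum permittivity
#'
#' The permittivity of free space used throughout the package,
#' \eqn{\varepsilon_0 = 8.8542 \times 10^{-12}} F/m (5 significant figures).
#'
#' @format A length-one numeric, in farad per metre.
#' @export
eps0 <- 8.8542e-12

#' Define a material with frequency-dependent electrical properties
#'
#' A material is described by its conductivity \eqn{\sigma} (S/m) and relative
#' permittivity \eqn{\varepsilon_r} (dimensionless). Either property may be a
#' single constant or a dispersion table of `(frequency, value)` pairs.
#' Between knots the property is interpolated linearly in \eqn{\log_{10} f};
#' outside the tabulated range it is clamped to the nearest knot, so the DC
#' limit of a tabulated property is its lowest-frequency value.
#'
#' @param name Material name (single string), e.g. `"saline"`.
#' @param sigma Conductivity in S/m: a non-negative constant, or a data frame /
#'   list with components `f` (Hz, strictly increasing) and `value`.
#' @param eps_r Relative permittivity (>= 1): constant or table as for `sigma`.
#' @return An object of class `vc_material`.
#' @examples
#' saline <- material_spec("saline", sigma = 1.6, eps_r = 80)
#' admittivity(saline, 1e6)
#' @export
material_spec <- function(name, sigma, eps_r) {
  stopifnot(is.character(name), length(name) == 1L)
  sigma <- as_prop_table(sigma, "sigma")
  eps_r <- as_prop_table(eps_r, "eps_r")
  if (any(sigma$value < 0))
    stop("material '", name, "': sigma must be >= 0 at every frequency")
  if (any(eps_r$value < 1))
    stop("material '", name, "': eps_r must be >= 1 at every frequency")
  structure(list(name = name, sigma = sigma, eps_r = eps_r),
            class = "vc_material")
}

# normalize a property to a (f, value) table; constants become 1-row tables
as_prop_table <- function(x, what) {
  if (is.numeric(x) && length(x) == 1L && is.null(dim(x))) {
    return(list(f = NA_real_, value = as.numeric(x), constant = TRUE))
  }
  if (is.data.frame(x)) x <- as.list(x)
  if (!is.list(x) || is.null(x$f) || is.null(x$value))
    stop("property '", what,
         "' must be a single number or a table with components f and value")
  f <- as.numeric(x$f); v <- as.numeric(x$value)
  if (length(f) != length(v) || length(f) < 1L)
    stop("property '", what, "': f and value must have equal positive length")
  if (any(f <= 0)) stop("property '", what, "': tabulated frequencies must be > 0")
  if (any(diff(f) <= 0))
    stop("property '", what, "': tabulated frequencies must be strictly increasing")
  list(f = f, value = v, constant = FALSE)
}

# evaluate a property table at frequencies f (vectorized, clamped log-linear)
prop_at <- function(tab, f) {
  if (isTRUE(tab$constant)) return(rep_len(tab$value, length(f)))
  if (length(tab$f) == 1L) return(rep_len(tab$value, length(f)))
  lf <- log10(pmax(f, tab$f[1]))          # clamp below (also handles f = 0)
  lf <- pmin(lf, log10(tab$f[length(tab$f)]))
  stats::approx(log10(tab$f), tab$value, xout = lf, rule = 2)$y
}

#' Complex admittivity of a material
#'
#' Computes \eqn{\sigma^*(f) = \sigma(f) + i\,2\pi f\,\varepsilon_0\,
#' \varepsilon_r(f)} in S/m, the complex conductivity governing quasi-static
#' AC current flow.
#'
#' @param spec A [material_spec()] object.
#' @param f Frequency in Hz (non-negative; may be a vector).
#' @return Complex admittivity in S/m, same length as `f`.
#' @export
admittivity <- function(spec, f) {
  stopifnot(inherits(spec, "vc_material"))
  f <- as.numeric(f)
  if (any(!is.finite(f)) || any(f < 0))
    stop("admittivity: frequency must be finite and >= 0")
  s <- prop_at(spec$sigma, f)
  er <- prop_at(spec$eps_r, f)
  complex(real = s, imaginary = 2 * pi * f * eps0 * er)
}

#' Complex resistivity of a material
#'
#' The reciprocal of the complex admittivity, \eqn{\rho = 1/\sigma^*}, in
#' ohm metre. Errors if the admittivity vanishes (a perfect insulator at DC).
#'
#' @inheritParams admittivity
#' @return Complex resistivity in ohm metre.
#' @export
complex_resistivity <- function(spec, f) {
  sst <- admittivity(spec, f)
  if (any(sst == 0))
    stop("complex_resistivity: admittivity of '", spec$name,
         "' is zero at some requested frequency")
  1 / sst
}

#' @export
print.vc_material <- function(x, ...) {
  fmt <- function(tab) {
    if (isTRUE(tab$constant) || length(tab$f) == 1L)
      format(tab$value[1], digits = 4)
    else paste0("table[", length(tab$f), " knots, ",
                format(tab$f[1], digits = 3), "-",
                format(tab$f[length(tab$f)], digits = 3), " Hz]")
  }
  cat("<vc_material> ", x$name,
      ": sigma = ", fmt(x$sigma), " S/m, eps_r = ", fmt(x$eps_r), "\n", sep = "")
  invisible(x)
}

#' Assemble a material table
#'
#' A material table maps region names to [material_spec()] objects. Looking
#' up a region that is not in the table is an error.
#'
#' @param specs A named list of `vc_material` objects, or unnamed (names taken
#'   from each spec).
#' @return An object of class `vc_material_table`.
#' @seealso [default_material_table()]
#' @export
material_table <- function(specs) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  ok <- vapply(specs, inherits, logical(1), "vc_material")
  if (!all(ok)) stop("material_table: all entries must be vc_material objects")
  nm <- names(specs)
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(specs, function(s) s$name, character(1))
  names(specs) <- nm
  if (anyDuplicated(nm)) stop("material_table: duplicate region names")
  structure(specs, class = "vc_material_table")
}

#' Look up the material assigned to a region
#'
#' @param table A [material_table()].
#' @param region Region name (single string).
#' @return The `vc_material` for that region; unknown regions are an error.
#' @export
material_for <- function(table, region) {
  stopifnot(inherits(table, "vc_material_table"))
  if (!region %in% names(table))
    stop("material_for: unknown region '", region, "' (table has: ",
         paste(names(table), collapse = ", "), ")")
  table[[region]]
}

# sigma(f) and eps_r(f) tables sampled from a single-pole Debye relaxation.
# Sampling both properties from one causal model keeps the conduction rise
# and the permittivity fall Kramers-Kronig consistent, so the medium is a
# genuine passive RC material (|Z| of any mixture is then non-increasing
# in frequency). Knots at `points_per_decade` per decade.
debye_material <- function(name, sigma0, eps_s, eps_inf, fc,
                           f_min = 1, f_max = 1e7, points_per_decade = 3) {
  f <- 10^seq(log10(f_min), log10(f_max),
              by = 1 / points_per_decade)
  x2 <- (f / fc)^2
  eps_r <- eps_inf + (eps_s - eps_inf) / (1 + x2)
  sigma <- sigma0 + (eps_s - eps_inf) * eps0 * 2 * pi * fc * x2 / (1 + x2)
  material_spec(name, sigma = list(f = f, value = sigma),
                eps_r = list(f = f, value = eps_r))
}

#' Default material table for the cuff-electrode vein model
#'
#' Declared package defaults for the six regions of the vein model. These are
#' order-of-magnitude representative values, fully overridable via the config
#' file: saline (0.9 percent NaCl scale) sigma = 1.6 S/m, eps_r = 80;
#' vein wall a single-pole Debye relaxation emulating beta dispersion, with
#' eps_r falling from 1e5 at 10 Hz to 2e3 at 1 MHz (relaxation frequency
#' 10 kHz) and the Kramers-Kronig-mandated conduction rise from 0.3 S/m at
#' low frequency to about 0.355 S/m at 1 MHz; glass and quartz near-perfect
#' insulators (eps_r 4.2 and 3.75); PMMA eps_r = 3; gold sigma = 4.1e7 S/m.
#' The Debye pair is sampled onto log-spaced property tables (3 knots per
#' decade, 1 Hz to 10 MHz).
#'
#' @return A `vc_material_table` with regions `saline`, `vein_wall`,
#'   `glass_tube`, `quartz_substrate`, `pmma_chamber`, `gold_electrode`.
#' @export
default_material_table <- function() {
  material_table(list(
    saline          = material_spec("saline", sigma = 1.6, eps_r = 80),
    vein_wall       = debye_material("vein_wall", sigma0 = 0.3,
                                     eps_s = 1e5, eps_inf = 1990, fc = 1e4),
    glass_tube      = material_spec("glass_tube", sigma = 1e-12, eps_r = 4.2),
    quartz_substrate = material_spec("quartz_substrate", sigma = 1e-12,
                                     eps_r = 3.75),
    pmma_chamber    = material_spec("pmma_chamber", sigma = 1e-14, eps_r = 3.0),
    gold_electrode  = material_spec("gold_electrode", sigma = 4.1e7, eps_r = 1)
  ))
}

#' @export
print.vc_material_table <- function(x, ...) {
  cat("<vc_material_table> with", length(x), "regions\n")
  for (s in x) print(s)
  invisible(x)
}

# canonical region names of the vein model, in labeling priority order
vein_regions <- function() {
  c("gold_electrode", "quartz_substrate", "vein_wall", "glass_tube",
    "saline", "pmma_chamber")
}

# ---- config (YAML) serialization --------------------------------------------
# Numbers are written as %.17g strings so a write/read round trip is bit-exact.

num_out <- function(x) sprintf("%.17g", x)

material_to_config <- function(spec) {
  one <- function(tab) {
    if (isTRUE(tab$constant) || length(tab$f) == 1L) num_out(tab$value[1])
    else list(f = num_out(tab$f), value = num_out(tab$value))
  }
  list(sigma = one(spec$sigma), eps_r = one(spec$eps_r))
}

material_from_config <- function(name, x) {
  one <- function(v) {
    if (is.list(v)) list(f = as.numeric(v$f), value = as.numeric(v$value))
    else as.numeric(v)
  }
  material_spec(name, sigma = one(x$sigma), eps_r = one(x$eps_r))
}

#' Write / read a material table as a YAML config section
#'
#' Numeric values are serialized with 17 significant digits so that
#' `read_material_table(write_material_table(x, p))` reproduces `x` bit-exactly.
#'
#' @param table A `vc_material_table`.
#' @param path File path.
#' @return `write_material_table` returns `path` invisibly;
#'   `read_material_table` returns a `vc_material_table`.
#' @export
write_material_table <- function(table, path) {
  stopifnot(inherits(table, "vc_material_table"))
  out <- list(materials = lapply(table, material_to_config))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_material_table
#' @export
read_material_table <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$materials)) stop("config has no 'materials' section")
  specs <- lapply(names(raw$materials), function(nm)
    material_from_config(nm, raw$materials[[nm]]))
  names(specs) <- names(raw$materials)
  material_table(specs)
}

# compact fingerprint of a material table for provenance records
material_fingerprint <- function(table) {
  s <- paste(vapply(names(table), function(nm) {
    sp <- table[[nm]]
    paste(nm, paste(num_out(sp$sigma$value), collapse = ","),
          paste(num_out(sp$eps_r$value), collapse = ","))
  }, character(1)), collapse = ";")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}
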