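#' Write / read a full model configuration
#'
#' Serializes a geometry configuration together with a material table into a
#' single structured YAML file (sections `geometry` and `materials`), and
#' reads it back. Numbers round-trip bit-exactly.
#'
#' @param cfg A [geometry_config()].
#' @param materials A [material_table()].
#' @param path File path.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns `list(cfg, materials)`.
#' @export
write_model_config <- function(cfg, materials, path) {
  stopifnot(inherits(cfg, "vc_geometry"),
            inherits(materials, "vc_material_table"))
  fields <- setdiff(names(formals(geometry_config)), "")
  geo <- lapply(cfg[fields], function(v)
    if (is.integer(v)) v else num_out(v))
  names(geo) <- fields
  yaml::write_yaml(list(geometry = geo,
                        materials = lapply(materials, material_to_config)),
                   path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$geometry) || is.null(raw$materials))
    stop("config must contain 'geometry' and 'materials' sections")
  geo <- raw$geometry
  int_fields <- c("n_electrodes", "n_rings")
  geo <- lapply(stats::setNames(names(geo), names(geo)), function(nm)
    if (nm %in% int_fields) as.integer(geo[[nm]]) else as.numeric(geo[[nm]]))
  cfg <- do.call(geometry_config, geo)
  specs <- lapply(names(raw$materials), function(nm)
    material_from_config(nm, raw$materials[[nm]]))
  names(specs) <- names(raw$materials)
  list(cfg = cfg, materials = material_table(specs))
}
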