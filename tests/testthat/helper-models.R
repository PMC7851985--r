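# shared fixtures: all built in code, nothing read from disk

# solve a phantom and return solution + field in one go
solve_phantom <- function(kind, resolution, f = 0, ...) {
  ph <- phantom_spec(kind, ...)
  pm <- make_phantom(ph, resolution)
  sol <- assemble_and_solve(pm$grid, pm$materials, pm$masks, f)
  list(spec = ph, grid = pm$grid, masks = pm$masks,
       materials = pm$materials, sol = sol)
}

# a vein model small enough for fast solves but still resolving every layer
quick_vein_resolution <- c(25L, 16L, 64L)

quick_vein_solve <- function(cfg = geometry_config(), f = 1e6,
                             mode = "simultaneous", position = "middle",
                             with_vein = TRUE,
                             resolution = quick_vein_resolution, ...) {
  m <- vein_model(cfg, resolution = resolution, mode = mode,
                  position = position, with_vein = with_vein, ...)
  sol <- assemble_and_solve(m$grid, m$materials, m$masks, f)
  list(model = m, sol = sol)
}

# relative error helper
rel_err <- function(x, ref) abs(x - ref) / abs(ref)
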