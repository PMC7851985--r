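#' Tidy a terminal-position scan
#'
#' @param x A `vc_scan` from [single_terminal_scan()].
#' @param ... Unused.
#' @return The per-position results tibble.
#' @method tidy vc_scan
#' @export
tidy.vc_scan <- function(x, ...) x$results

#' @rdname tidy.vc_scan
#' @method glance vc_scan
#' @export
glance.vc_scan <- function(x, ...) {
  tibble::tibble(n_positions = nrow(x$results),
                 max_pairwise_diff_pp = x$max_pairwise_diff_pp,
                 frequency = x$frequency)
}

#' Tidy a contribution report
#'
#' @param x A `vc_contributions`.
#' @param ... Unused.
#' @return A plain tibble of per-region percentages.
#' @method tidy vc_contributions
#' @export
tidy.vc_contributions <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "vc_contributions")
  out
}

#' @rdname tidy.vc_contributions
#' @method glance vc_contributions
#' @export
glance.vc_contributions <- function(x, ...) {
  Z <- attr(x, "Z")
  tibble::tibble(frequency = attr(x, "frequency"),
                 ReZ = Re(Z), ImZ = Im(Z), absZ = Mod(Z),
                 n_regions = nrow(x), n_empty = sum(x$empty))
}

#' Tidy a solved field
#'
#' @param x A `vc_solution`.
#' @param ... Unused.
#' @return One-row tibble with the impedance summary of the solve.
#' @method glance vc_solution
#' @export
glance.vc_solution <- function(x, ...) {
  Y <- x$I / x$U
  gc_ <- decompose_admittance(Y, x$frequency)
  tibble::tibble(f_Hz = x$frequency, ReZ = Re(x$Z), ImZ = Im(x$Z),
                 absZ = Mod(x$Z),
                 phase_deg = atan(Im(x$Z) / Re(x$Z)) * 180 / pi,
                 G_S = gc_$G, C_F = gc_$C,
                 iterations = x$iterations, residual = x$residual)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a labeled grid into a cell table
#'
#' One row per cell with its center coordinates, volume and region label --
#' the grid's structured-array export for visualization tools.
#'
#' @param x A `vc_grid`.
#' @param ... Unused.
#' @return A tibble with columns `i`, `j`, `k`, the two or three center
#'   coordinates (`r`/`theta`/`z` or `x`/`y`/`z`, in metres or radians),
#'   `volume_m3` and `region`.
#' @method tidy vc_grid
#' @export
tidy.vc_grid <- function(x, ...) {
  ctr <- axis_centers(x)
  d <- x$dims
  nm <- if (x$kind == "cylindrical") c("r", "theta", "z") else c("x", "y", "z")
  out <- tibble::tibble(
    i = rep(seq_len(d[1]), times = d[2] * d[3]),
    j = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    k = rep(seq_len(d[3]), each = d[1] * d[2]))
  out[[nm[1]]] <- ctr[[1]][out$i]
  out[[nm[2]]] <- ctr[[2]][out$j]
  out[[nm[3]]] <- ctr[[3]][out$k]
  out$volume_m3 <- as.vector(cell_volumes(x))
  out$region <- x$regions[as.vector(x$labels)]
  out
}
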