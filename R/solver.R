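#' Quasi-static complex conduction solver
#'
#' The conduction problem \eqn{\nabla\cdot(\sigma^*(f)\nabla V) = 0} is
#' discretized by cell-centered finite volumes on the structured grid, with
#' harmonic-mean face admittivities (so layered interfaces are exact in the
#' one-dimensional limit), Dirichlet faces at the terminal and ground
#' potentials, and insulating (zero normal current) outer boundaries. The
#' complex symmetric system is solved by a preconditioned conjugate-orthogonal
#' CG iteration; the preconditioner is a sparse Cholesky factorization of
#' `Re(A) + Im(A)`, which is symmetric positive definite for passive
#' materials. All orderings are fixed, so solves are deterministic.
#'
#' @name field_solver
#' @keywords internal
NULL

# index of an internal face (between (i,j,k) and its +axis neighbor) within
# the vectorized face list produced by face_geometry()
internal_face_index <- function(dims, axis, i, j, k, periodic) {
  if (axis == 1L) {
    i + (dims[1] - 1L) * ((j - 1L) + dims[2] * (k - 1L))
  } else if (axis == 2L) {
    nf <- if (periodic[2]) dims[2] else dims[2] - 1L
    i + dims[1] * ((j - 1L) + nf * (k - 1L))
  } else {
    i + dims[1] * ((j - 1L) + dims[2] * (k - 1L))
  }
}

# Flatten the Dirichlet mask faces of a vc_masks object into half-face
# records: one row per (cell, face) pair with its conductance geometry.
# Internal faces contribute a half-face on each side; the direct cell-cell
# coupling through such a face is removed from the bulk operator.
dirichlet_halves <- function(grid, masks, sigma_star) {
  out <- list(); blocked <- list()
  add_patch <- function(fs, name, vd) {
    if (!nrow(fs)) return()
    internal <- fs$type == "internal"
    if (any(internal)) {
      fi <- fs[internal, ]
      stopifnot(all(fi$axis == 1L))       # patches live on radial interfaces
      bg <- boundary_face_geometry(grid, 1L, fi$i, fi$j, fi$k, +1L)
      sL <- sigma_star[cbind(fi$i, fi$j, fi$k)]
      gL <- sL * bg$A / bg$dh
      bgR <- boundary_face_geometry(grid, 1L, fi$i + 1L, fi$j, fi$k, -1L)
      sR <- sigma_star[cbind(fi$i + 1L, fi$j, fi$k)]
      gR <- sR * bgR$A / bgR$dh
      out[[length(out) + 1L]] <<- list(
        name = rep(name, 2L * nrow(fi)),
        cell = c(cell_id(grid$dims, fi$i, fi$j, fi$k),
                 cell_id(grid$dims, fi$i + 1L, fi$j, fi$k)),
        g = c(gL, gR), A = c(bg$A, bgR$A), dh = c(bg$dh, bgR$dh),
        s = c(sL, sR), vd = rep(vd, 2L * nrow(fi)),
        axis = rep(1L, 2L * nrow(fi)),
        side = c(rep(1L, nrow(fi)), rep(-1L, nrow(fi))),
        i = c(fi$i, fi$i + 1L), j = c(fi$j, fi$j), k = c(fi$k, fi$k))
      blocked[[length(blocked) + 1L]] <<-
        internal_face_index(grid$dims, 1L, fi$i, fi$j, fi$k, grid$periodic)
    }
    bd <- fs[fs$type == "boundary", ]
    if (nrow(bd)) {
      for (ax in unique(bd$axis)) for (sd in unique(bd$side)) {
        bb <- bd[bd$axis == ax & bd$side == sd, ]
        if (!nrow(bb)) next
        bg <- boundary_face_geometry(grid, ax, bb$i, bb$j, bb$k, sd)
        sC <- sigma_star[cbind(bb$i, bb$j, bb$k)]
        out[[length(out) + 1L]] <<- list(
          name = rep(name, nrow(bb)),
          cell = cell_id(grid$dims, bb$i, bb$j, bb$k),
          g = sC * bg$A / bg$dh, A = bg$A, dh = bg$dh, s = sC,
          vd = rep(vd, nrow(bb)), axis = rep(ax, nrow(bb)),
          side = rep(sd, nrow(bb)), i = bb$i, j = bb$j, k = bb$k)
      }
    }
  }
  for (nm in names(masks$terminals))
    add_patch(masks$terminals[[nm]], nm, masks$u_volts)
  add_patch(masks$ground, "ground", 0)
  for (nm in names(masks$floating))
    add_patch(masks$floating[[nm]], nm, NA_real_)   # potential is an unknown
  dh <- lapply(c("name", "cell", "g", "A", "dh", "s", "vd", "axis",
                 "side", "i", "j", "k"),
               function(f) do.call(c, lapply(out, `[[`, f)))
  names(dh) <- c("name", "cell", "g", "A", "dh", "s", "vd", "axis",
                 "side", "i", "j", "k")
  list(halves = dh, blocked_axis1 = unique(do.call(c, blocked)))
}

# complex COCG iteration with SPD preconditioner chol(Re(A) + Im(A));
# falls back to BiCGSTAB on breakdown. Returns list(x, res, iters, method).
solve_complex_system <- function(AR, AI, b, tol, maxit = 500L) {
  n <- length(b)
  M <- Matrix::forceSymmetric(AR + AI)
  ch <- tryCatch(Matrix::Cholesky(M, LDL = FALSE, super = TRUE),
                 error = function(e)
                   stop("singular system (disconnected terminal/ground or ",
                        "zero admittivity): ", conditionMessage(e)))
  matv <- function(x) {
    X <- cbind(Re(x), Im(x))
    Y1 <- AR %*% X; Y2 <- AI %*% X
    complex(real = Y1[, 1] - Y2[, 2], imaginary = Y1[, 2] + Y2[, 1])
  }
  prec <- function(x) {
    S <- Matrix::solve(ch, cbind(Re(x), Im(x)), system = "A")
    complex(real = S[, 1], imaginary = S[, 2])
  }
  nb <- sqrt(sum(Mod(b)^2))
  if (nb == 0) return(list(x = complex(n), res = 0, iters = 0L,
                           method = "trivial"))
  cocg <- function() {
    x <- complex(n); r <- b
    z <- prec(r); p <- z; rz <- sum(r * z)
    for (it in seq_len(maxit)) {
      Ap <- matv(p); pAp <- sum(p * Ap)
      if (Mod(pAp) < 1e-300 || Mod(rz) < 1e-300)
        return(list(x = x, res = NA_real_, iters = it, method = "cocg"))
      alpha <- rz / pAp
      x <- x + alpha * p; r <- r - alpha * Ap
      res <- sqrt(sum(Mod(r)^2)) / nb
      if (res < tol) return(list(x = x, res = res, iters = it,
                                 method = "cocg"))
      z <- prec(r); rz2 <- sum(r * z)
      p <- z + (rz2 / rz) * p; rz <- rz2
    }
    list(x = x, res = sqrt(sum(Mod(r)^2)) / nb, iters = maxit,
         method = "cocg")
  }
  out <- cocg()
  if (is.na(out$res) || out$res >= tol) out <- bicgstab(matv, prec, b, tol,
                                                        maxit, nb)
  if (is.na(out$res) || out$res >= tol)
    stop(sprintf(paste0("field solver did not converge: achieved relative ",
                        "residual %.3e after %d iterations (tol %.1e)"),
                 out$res, out$iters, tol))
  out
}

bicgstab <- function(matv, prec, b, tol, maxit, nb) {
  n <- length(b)
  x <- complex(n); r <- b; r0 <- Conj(r)
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- complex(n)
  for (it in seq_len(maxit)) {
    rho1 <- sum(Conj(r0) * r)
    if (Mod(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    ph <- prec(p); v <- matv(ph)
    alpha <- rho1 / sum(Conj(r0) * v)
    s <- r - alpha * v
    sh <- prec(s); t <- matv(sh)
    omega <- sum(Conj(t) * s) / sum(Conj(t) * t)
    x <- x + alpha * ph + omega * sh
    r <- s - omega * t
    rho <- rho1
    res <- sqrt(sum(Mod(r)^2)) / nb
    if (res < tol) return(list(x = x, res = res, iters = it,
                               method = "bicgstab"))
  }
  list(x = x, res = sqrt(sum(Mod(r)^2)) / nb, iters = maxit,
       method = "bicgstab")
}

#' Assemble and solve the conduction problem at one frequency
#'
#' Solves for the complex potential under the given Dirichlet masks and
#' returns the field solution with all derived cell fields: electric field
#' `E = -grad V`, current density `J = sigma* E`, terminal and ground
#' currents, and the discrete per-cell energy decomposition used by the
#' sensitivity machinery.
#'
#' @param grid A [vc_grid].
#' @param materials A [material_table()] covering every region of the grid.
#' @param masks A [electrode_masks()] result (or any `vc_masks`).
#' @param f Frequency in Hz.
#' @param tol Relative residual tolerance, in `(0, 1e-3]`; default `1e-8`.
#' @param u_volts Applied terminal potential (default 1 V).
#' @return A `vc_solution` with components `V` (complex potential array),
#'   `J` (list of three complex current-density component arrays, A/m^2),
#'   `E` (V/m), `I` (total complex terminal current, A), `terminal_currents`,
#'   `ground_current`, `Z`, `e_cell` (complex energy integrals whose sum over
#'   cells times `1/I^2` is exactly `Z`), `p_cell` (dissipated power
#'   integrals, W per cell up to the constant half), `residual`, `iterations`.
#' @export
assemble_and_solve <- function(grid, materials, masks, f, tol = 1e-8,
                               u_volts = 1) {
  stopifnot(inherits(grid, "vc_grid"), inherits(masks, "vc_masks"))
  if (!(tol > 0 && tol <= 1e-3)) stop("tol must be in (0, 1e-3]")
  if (!length(masks$terminals) || !nrow(masks$ground))
    stop("masks must contain at least one terminal and a ground")
  masks$u_volts <- u_volts
  sigma_star <- sigma_star_array(grid, materials, f)
  n <- prod(grid$dims)

  dh <- dirichlet_halves(grid, masks, sigma_star)
  halves <- dh$halves

  ii <- jj <- list(); vv <- list()
  faces <- list()
  for (ax in 1:3) {
    fg <- face_geometry(grid, ax)
    if (is.null(fg)) { faces[[ax]] <- NULL; next }
    sL <- sigma_star[cbind(fg$i, fg$j, fg$k)]
    sR <- sigma_star[cbind(fg$ip, fg$jp, fg$kp)]
    g <- fg$A / (fg$dL / sL + fg$dR / sR)
    if (ax == 1L && length(dh$blocked_axis1)) g[dh$blocked_axis1] <- 0
    l <- cell_id(grid$dims, fg$i, fg$j, fg$k)
    r <- cell_id(grid$dims, fg$ip, fg$jp, fg$kp)
    ii[[length(ii) + 1L]] <- c(l, r, l, r)
    jj[[length(jj) + 1L]] <- c(r, l, l, r)
    vv[[length(vv) + 1L]] <- c(-g, -g, g, g)
    faces[[ax]] <- list(geom = fg, g = g, sL = sL, sR = sR,
                        idL = l, idR = r)
  }

  # Dirichlet half-faces: fixed-potential patches add a diagonal term and a
  # right-hand side; floating patches add one extra unknown each.
  fl_names <- names(masks$floating)
  n_extra <- length(fl_names)
  fixed <- !is.na(halves$vd)
  if (any(fixed)) {
    ii[[length(ii) + 1L]] <- halves$cell[fixed]
    jj[[length(jj) + 1L]] <- halves$cell[fixed]
    vv[[length(vv) + 1L]] <- halves$g[fixed]
  }
  if (n_extra) {
    fidx <- n + match(halves$name, fl_names)   # NA for non-floating rows
    fl <- !is.na(fidx)
    cc <- halves$cell[fl]; ff <- fidx[fl]; gg <- halves$g[fl]
    ii[[length(ii) + 1L]] <- c(cc, ff, cc, ff)
    jj[[length(jj) + 1L]] <- c(cc, ff, ff, cc)
    vv[[length(vv) + 1L]] <- c(gg, gg, -gg, -gg)
  }
  ii <- do.call(c, ii); jj <- do.call(c, jj); vv <- do.call(c, vv)
  AR <- Matrix::sparseMatrix(i = ii, j = jj, x = Re(vv),
                             dims = c(n + n_extra, n + n_extra))
  AI <- Matrix::sparseMatrix(i = ii, j = jj, x = Im(vv),
                             dims = c(n + n_extra, n + n_extra))
  # right-hand side from fixed-potential faces (accumulated properly)
  b <- complex(n + n_extra)
  if (any(fixed)) {
    agg <- rowsum(cbind(Re(halves$g[fixed] * halves$vd[fixed]),
                        Im(halves$g[fixed] * halves$vd[fixed])),
                  group = halves$cell[fixed])
    cells <- as.integer(rownames(agg))
    b[cells] <- complex(real = agg[, 1], imaginary = agg[, 2])
  }

  sol <- solve_complex_system(AR, AI, b, tol)
  x <- sol$x
  V <- array(x[seq_len(n)], dim = grid$dims)
  v_float <- if (n_extra) stats::setNames(x[n + seq_len(n_extra)], fl_names)
             else complex(0)

  # fill in the (previously unknown) floating potentials for post-processing
  if (n_extra) {
    fidx <- match(halves$name, fl_names)
    halves$vd[!is.na(fidx)] <- v_float[fidx[!is.na(fidx)]]
  }

  post <- postprocess_solution(grid, faces, halves, V, sigma_star)
  I_term <- post$currents[startsWith(names(post$currents), "terminal")]
  I_total <- sum(I_term)
  if (Mod(I_total) == 0) stop("zero total terminal current")
  Z <- u_volts / I_total

  structure(list(
    grid = grid, frequency = f, U = u_volts, V = V,
    E = post$E, J = post$J,
    I = I_total, Z = Z,
    terminal_currents = I_term,
    ground_current = post$currents[["ground"]],
    floating_potentials = v_float,
    e_cell = post$e_cell, p_cell = post$p_cell,
    sigma_star = sigma_star,
    dirichlet = halves,
    residual = sol$res, iterations = sol$iters, method = sol$method,
    tol = tol), class = "vc_solution")
}

# Derived fields: per-cell energy integrals (complex, face-split by half
# resistances), dissipated power integrals, cell-centered J and E, and the
# currents through every Dirichlet patch.
postprocess_solution <- function(grid, faces, halves, V, sigma_star) {
  n <- prod(grid$dims)
  e_cell <- complex(n); p_cell <- numeric(n)
  QL <- QH <- list()
  for (ax in 1:3) { QL[[ax]] <- numeric(0); QH[[ax]] <- numeric(0) }
  Jc <- lapply(1:3, function(ax) complex(n))
  wt <- lapply(1:3, function(ax) numeric(n))   # number of contributing faces
  for (ax in 1:3) {
    fc <- faces[[ax]]
    if (is.null(fc)) next
    flux <- fc$g * (V[fc$idL] - V[fc$idR])     # positive along +axis: L -> R
    eL <- flux^2 * (fc$geom$dL / (fc$sL * fc$geom$A))
    eR <- flux^2 * (fc$geom$dR / (fc$sR * fc$geom$A))
    pL <- Mod(flux)^2 * Re(1 / fc$sL) * fc$geom$dL / fc$geom$A
    pR <- Mod(flux)^2 * Re(1 / fc$sR) * fc$geom$dR / fc$geom$A
    e_cell <- e_cell + accum_complex(fc$idL, eL, n) +
      accum_complex(fc$idR, eR, n)
    p_cell <- p_cell + accum_real(fc$idL, pL, n) + accum_real(fc$idR, pR, n)
    q <- flux / fc$geom$A
    Jc[[ax]] <- Jc[[ax]] + accum_complex(fc$idL, q, n) +
      accum_complex(fc$idR, q, n)
    wt[[ax]] <- wt[[ax]] + accum_real(fc$idL, rep(1, length(q)), n) +
      accum_real(fc$idR, rep(1, length(q)), n)
  }
  # Dirichlet half-faces
  currents <- complex(0)
  if (length(halves$cell)) {
    flux_in <- halves$g * (halves$vd - V[halves$cell])  # into the cell
    e_d <- flux_in^2 * halves$dh / (halves$s * halves$A)
    p_d <- Mod(flux_in)^2 * Re(1 / halves$s) * halves$dh / halves$A
    e_cell <- e_cell + accum_complex(halves$cell, e_d, n)
    p_cell <- p_cell + accum_real(halves$cell, p_d, n)
    # oriented flux density along +axis for the J average
    q_d <- ifelse(halves$side > 0, -1, 1) * flux_in / halves$A
    for (ax in unique(halves$axis)) {
      selax <- halves$axis == ax
      Jc[[ax]] <- Jc[[ax]] + accum_complex(halves$cell[selax], q_d[selax], n)
      wt[[ax]] <- wt[[ax]] + accum_real(halves$cell[selax],
                                        rep(1, sum(selax)), n)
    }
    agg <- rowsum(cbind(Re(flux_in), Im(flux_in)), group = halves$name)
    currents <- complex(real = agg[, 1], imaginary = agg[, 2])
    names(currents) <- rownames(agg)
    # current leaving an electrode into the domain equals the sum of its
    # half-face fluxes into the adjacent cells
  }
  # cell-centered components: average the (up to two) face flux densities
  # per axis; insulated boundary faces carry zero flux and do not contribute
  J <- lapply(1:3, function(ax)
    array(Jc[[ax]] / pmax(wt[[ax]], 1), dim = grid$dims))
  E <- lapply(J, function(a) a / sigma_star)
  list(e_cell = array(e_cell, grid$dims), p_cell = array(p_cell, grid$dims),
       J = J, E = E, currents = currents)
}

accum_complex <- function(idx, val, n) {
  out <- complex(n)
  agg <- rowsum(cbind(Re(val), Im(val)), group = idx)
  cells <- as.integer(rownames(agg))
  out[cells] <- complex(real = agg[, 1], imaginary = agg[, 2])
  out
}

accum_real <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, group = idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' @export
print.vc_solution <- function(x, ...) {
  cat("<vc_solution> f = ", format(x$frequency, digits = 4), " Hz, ",
      length(x$terminal_currents), " terminal(s) at ", x$U, " V\n",
      "  Z = ", format(Re(x$Z), digits = 6), " ",
      ifelse(Im(x$Z) < 0, "-", "+"), " ",
      format(abs(Im(x$Z)), digits = 4), "i Ohm   (", x$method, ", ",
      x$iterations, " iters, residual ", format(x$residual, digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' Current through a Dirichlet electrode mask
#'
#' Integrates the normal current density over the exposed faces of a mask of
#' the solved problem. Sign convention: current leaving a driven (1 V)
#' terminal into the domain is positive; the ground current is then negative
#' so that all electrode currents sum to zero.
#'
#' @param sol A [assemble_and_solve()] result.
#' @param mask Either the name of a patch (`"ground"`, `"terminal_3"`, ...)
#'   or a face-set tibble that is part of the solved masks.
#' @return Complex current in ampere.
#' @export
electrode_current <- function(sol, mask) {
  stopifnot(inherits(sol, "vc_solution"))
  dh <- sol$dirichlet
  # a face is identified by its axis, the shared edge index along that axis,
  # and the transverse cell indices
  edge_key <- function(axis, i, j, k, side) {
    along <- cbind(i, j, k)[cbind(seq_along(axis), axis)]
    edge <- along + as.integer(side > 0)
    paste(axis, edge, ifelse(axis == 1L, paste(j, k),
                             ifelse(axis == 2L, paste(i, k), paste(i, j))))
  }
  if (is.character(mask) && length(mask) == 1L) {
    if (!mask %in% dh$name)
      stop("mask '", mask, "' is not part of the solved problem")
    sel <- dh$name == mask
  } else if (is.data.frame(mask)) {
    have <- edge_key(dh$axis, dh$i, dh$j, dh$k, dh$side)
    side_eff <- ifelse(mask$type == "internal", 1L, mask$side)
    want <- edge_key(mask$axis, mask$i, mask$j, mask$k, side_eff)
    sel <- have %in% want
    if (!any(sel)) stop("mask is not part of the solved problem")
    if (sum(sel) < nrow(mask))
      stop("mask contains faces that are not part of the solved problem")
  } else stop("mask must be a patch name or a face-set tibble")
  sum(dh$g[sel] * (dh$vd[sel] - sol$V[dh$cell[sel]]))
}

#' Decompose an admittance into conductance and capacitance
#'
#' Splits \eqn{Y = G + i\omega C} into its parallel conductance
#' \eqn{G = \mathrm{Re}\,Y} and capacitance \eqn{C = \mathrm{Im}\,Y / 2\pi f}.
#'
#' @param Y Complex admittance in siemens.
#' @param f Frequency in Hz (> 0, or 0 with a purely real `Y`).
#' @return Named list with `G` (S) and `C` (F).
#' @export
decompose_admittance <- function(Y, f) {
  stopifnot(length(Y) == 1L, length(f) == 1L, f >= 0)
  if (f == 0) {
    if (Im(Y) != 0) stop("f = 0 with a reactive admittance is ill-defined")
    return(list(G = Re(Y), C = 0))
  }
  list(G = Re(Y), C = Im(Y) / (2 * pi * f))
}

#' Impedance spectrum over a frequency sweep
#'
#' Runs one solve per frequency and tabulates the impedance and its derived
#' scalars: `Z = 1/Y` with `Y = I/U`, resistance `R = Re Z`, reactance
#' `X = Im Z`, magnitude `|Z|`, phase `arctan(X/R)`, conductance `G = Re Y`
#' and capacitance `C = Im Y / omega`.
#'
#' @inheritParams assemble_and_solve
#' @param freqs Strictly increasing vector of frequencies in Hz.
#' @return A tibble of class `vc_spectrum` with columns `f_Hz`, `ReZ`, `ImZ`,
#'   `absZ`, `phase_deg`, `G_S`, `C_F`.
#' @export
impedance_spectrum <- function(grid, materials, masks, freqs, tol = 1e-8,
                               u_volts = 1) {
  stopifnot(length(freqs) >= 1L, all(diff(freqs) > 0))
  rows <- lapply(freqs, function(f) {
    s <- tryCatch(assemble_and_solve(grid, materials, masks, f, tol, u_volts),
                  error = function(e)
                    stop("solve failed at f = ", format(f, digits = 6),
                         " Hz: ", conditionMessage(e), call. = FALSE))
    Y <- s$I / s$U
    gc_ <- decompose_admittance(Y, f)
    Z <- 1 / Y
    tibble::tibble(f_Hz = f, ReZ = Re(Z), ImZ = Im(Z), absZ = Mod(Z),
                   phase_deg = atan(Im(Z) / Re(Z)) * 180 / pi,
                   G_S = gc_$G, C_F = gc_$C)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vc_spectrum", class(out))
  out
}

#' Write a spectrum to CSV
#'
#' Writes the spectrum with the canonical column set
#' `f_Hz, ReZ, ImZ, absZ, phase_deg, G_S, C_F`.
#'
#' @param x A `vc_spectrum`.
#' @param path Output file path.
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "vc_spectrum"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
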