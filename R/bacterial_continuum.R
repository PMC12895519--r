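#' Bacterial transport parameters
#'
#' Population-scale parameters of the Keller-Segel-type bacterial
#' transport equation db/dt = D_b lap(b) - div((v_f + V_C) b): random
#' motility D_b, swimming speed v, chemotactic receptor constant K_C and
#' chemotactic sensitivity coefficient chi_o.  `chi_o = 0` encodes the
#' nonchemotactic control strain.
#'
#' @param v Swimming speed, um/s.
#' @param chi_o Chemotactic sensitivity coefficient, cm^2/s.
#' @param K_C Chemotactic receptor constant, mol/m^3.
#' @param D_b Bacterial random-motility coefficient, cm^2/s.
#' @return A `chemotaxis_params` list; `chi_umps`/`Db_umps` carry the
#'   um^2/s conversions used internally.
#' @export
chemotaxis_params <- function(v = 49, chi_o = 7.2e-5, K_C = 0.016,
                              D_b = 3.2e-6) {
  stopifnot(v > 0, chi_o >= 0, K_C > 0, D_b > 0)
  structure(list(v = v, chi_o = chi_o, chi_umps = chi_o * 1e8,
                 K_C = K_C, D_b = D_b, Db_umps = D_b * 1e8),
            class = "chemotaxis_params")
}

#' Chemotactic drift velocity (receptor-law tanh closure)
#'
#' V_C = (2 v / 3) tanh( chi_o / (2 v) * K_C / (K_C + a)^2 * |grad a| )
#' directed along the local attractant gradient.  The tanh saturates the
#' drift at 2v/3 however steep the gradient; the receptor factor
#' K_C/(K_C + a)^2 peaks near a = K_C, the gradient-sensing sweet spot.
#'
#' @param a Attractant concentration (mol/m^3), any numeric shape.
#' @param grad_a Gradient: a list with components `gx` and (optionally)
#'   `gy` of the same shape as `a` (mol/m^3 per um).
#' @param p [chemotaxis_params()].
#' @return List of drift components `vx`, `vy` (um/s), same shape as `a`.
#' @export
chemotactic_velocity <- function(a, grad_a, p = chemotaxis_params()) {
  if (any(a < 0)) stop("attractant concentration must be non-negative")
  gx <- grad_a$gx
  gy <- if (is.null(grad_a$gy)) gx * 0 else grad_a$gy
  gmag <- sqrt(gx^2 + gy^2)
  recept <- p$K_C / (p$K_C + a)^2
  vmag <- (2 * p$v / 3) * tanh(p$chi_umps / (2 * p$v) * recept * gmag)
  unit <- ifelse(gmag > 0, 1 / gmag, 0)
  list(vx = vmag * gx * unit, vy = vmag * gy * unit)
}

#' Steady bacterial density field
#'
#' Solves the steady bacterial transport equation with the chemotactic
#' drift evaluated from a precomputed attractant field: b = 1 at the
#' inflow (densities are normalised by the inlet density), zero total
#' flux at the walls and the NAPL-water interface, convective outflow
#' downstream.
#'
#' Two treatments of the drift term are offered.  `form = "advective"`
#' (default) discretises the transport equation exactly as written,
#' db/dt = D_b lap(b) - (v_f + V_C) . grad(b): the chemotactic drift acts
#' inside the advection operator, so drift convergence does not by itself
#' concentrate cells and accumulation is driven by the zero-total-flux
#' wall condition; this is the form that reproduces the reported
#' near-interface peaks (about 1.3 at 0.5 m/d) with the published
#' parameter set.  `form = "conservative"` uses the flux-divergence
#' (Keller-Segel) form div(D_b grad b - (v_f + V_C) b), which conserves
#' mass exactly but accumulates far more strongly at the same parameters;
#' it is provided for comparison and sensitivity analysis.
#'
#' @param geom A [channel_geometry()].
#' @param flow A [flow_profile()].
#' @param attractant Steady attractant `scalar_field2d` on the grid the
#'   bacteria should be solved on.
#' @param p [chemotaxis_params()]; `chi_o = 0` (or a zero attractant)
#'   returns the uniform field b = 1.
#' @param form `"advective"` (as-written drift, default) or
#'   `"conservative"` (flux-divergence drift).
#' @return A `density_field2d` (a `scalar_field2d` with dimensionless
#'   values and a `residual` attribute).
#' @export
solve_bacteria_steady <- function(geom, flow, attractant,
                                  p = chemotaxis_params(),
                                  form = c("advective", "conservative")) {
  form <- match.arg(form)
  grid <- attractant$grid
  fv <- flow_face_velocities(grid, flow)
  if (p$chi_umps > 0 && max(attractant$values) > 0) {
    gr <- field_gradient(attractant)
    vc <- chemotactic_velocity(attractant$values, gr, p)
    fv$u_xf <- fv$u_xf + faces_x(vc$vx)
    fv$u_yf <- fv$u_yf + faces_y(vc$vy)
  }
  bc <- list(
    west = list(type = "dirichlet", value = 1),
    east = list(type = "outflow"),
    south = list(type = "noflux"),
    north = list(type = "noflux")
  )
  sol <- solve_advdiff_steady(grid, p$Db_umps, fv$u_xf, fv$u_yf, bc,
                              divergence_correction = form == "advective")
  if (sol$residual > 1e-8) {
    stop(sprintf("steady bacterial solve did not converge (relative residual %.3g)",
                 sol$residual))
  }
  b <- sol$values
  if (min(b) < -1e-6) {
    stop(sprintf("negative bacterial density %.3g: advection scheme failure", min(b)))
  }
  b[b < 0] <- 0
  out <- scalar_field2d(grid, b, units = "normalized density")
  class(out) <- c("density_field2d", class(out))
  attr(out, "residual") <- sol$residual
  out
}

# cell-centre -> face interpolation (arithmetic mean; copies at the
# boundary faces, where no-flux conditions make the value irrelevant)
faces_x <- function(v) {
  nx <- nrow(v)
  rbind(v[1, ], (v[-nx, ] + v[-1, ]) / 2, v[nx, ])
}
faces_y <- function(v) {
  ny <- ncol(v)
  cbind(v[, 1], (v[, -ny] + v[, -1]) / 2, v[, ny])
}

#' Band-averaged density profile
#'
#' Averages a density field over one direction inside a rectangular band
#' and returns a 1-D profile along the other, emulating how densities in
#' the microscopy regions of interest are reduced: the transverse
#' (y) profile averages over the interface span in x, the along-flow (x)
#' profile averages over the first 50 um from the wall.  Cells are
#' selected by centre and weighted by their width.
#'
#' @param field A `density_field2d` (or any `scalar_field2d`).
#' @param axis `"y"` for the wall-normal profile or `"x"` along flow.
#' @param band Numeric `c(lo, hi)`: the averaged-over range (x-range for
#'   `axis = "y"`, y-range for `axis = "x"`).
#' @param extent Numeric `c(lo, hi)` range of the profile axis itself.
#' @return A `density_profile` data frame with columns `coord_um`,
#'   `density` and attributes `axis`, `band`.
#' @export
extract_profile <- function(field, axis = c("y", "x"),
                            band = NULL, extent = NULL) {
  axis <- match.arg(axis)
  g <- field$grid
  if (axis == "y") {
    if (is.null(band)) band <- c(0, 50)
    if (is.null(extent)) extent <- c(0, 200)
    sel_b <- g$xc >= band[1] & g$xc <= band[2]
    sel_a <- g$yc >= extent[1] & g$yc <= extent[2]
    if (!any(sel_b) || !any(sel_a)) stop("empty band or extent")
    w <- g$dx[sel_b]
    vals <- colSums(field$values[sel_b, sel_a, drop = FALSE] * w) / sum(w)
    coord <- g$yc[sel_a]
  } else {
    if (is.null(band)) band <- c(0, 50)
    if (is.null(extent)) extent <- c(-100, 150)
    sel_b <- g$yc >= band[1] & g$yc <= band[2]
    sel_a <- g$xc >= extent[1] & g$xc <= extent[2]
    if (!any(sel_b) || !any(sel_a)) stop("empty band or extent")
    w <- g$dy[sel_b]
    vals <- as.vector(field$values[sel_a, sel_b, drop = FALSE] %*% w) / sum(w)
    coord <- g$xc[sel_a]
  }
  density_profile(coord, vals, axis = axis, band = band)
}

#' Construct a density profile
#'
#' @param coord_um Strictly increasing coordinates, um.
#' @param density Non-negative normalized densities.
#' @param axis `"x"` or `"y"`.
#' @param band Averaging band `c(lo, hi)` (um) on the orthogonal axis.
#' @param sd Optional per-point replicate standard deviation.
#' @return A `density_profile` data frame.
#' @export
density_profile <- function(coord_um, density, axis = "y",
                            band = c(0, 50), sd = NULL) {
  stopifnot(length(coord_um) == length(density),
            all(diff(coord_um) > 0), all(density >= 0))
  df <- data.frame(coord_um = coord_um, density = density)
  if (!is.null(sd)) df$sd <- sd
  structure(df, axis = axis, band = band,
            class = c("density_profile", "data.frame"))
}

#' Extent of chemotactic accumulation along a profile
#'
#' The contiguous coordinate interval on which the normalized density
#' exceeds `threshold` (the run containing the profile maximum, with the
#' crossing points located by linear interpolation); `NULL` when the
#' profile never exceeds the threshold.
#'
#' @param profile A `density_profile`.
#' @param threshold Dimensionless density threshold (> 1).
#' @return `c(lo, hi)` in um, or `NULL`.
#' @export
accumulation_extent <- function(profile, threshold = 1.05) {
  stopifnot(threshold > 1)
  x <- profile$coord_um; v <- profile$density
  above <- v > threshold
  if (!any(above)) return(NULL)
  imax <- which.max(v)
  if (!above[imax]) imax <- which(above)[1]
  lo <- imax; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- imax; while (hi < length(v) && above[hi + 1L]) hi <- hi + 1L
  cross <- function(i1, i2) {
    x[i1] + (threshold - v[i1]) * (x[i2] - x[i1]) / (v[i2] - v[i1])
  }
  left <- if (lo > 1L) cross(lo - 1L, lo) else x[1]
  right <- if (hi < length(v)) cross(hi + 1L, hi) else x[length(v)]
  c(left, right)
}

#' Read / write density profiles as delimited text
#'
#' Tab-separated with header `axis, coord_um, density_norm, sd`.
#'
#' @param profile A `density_profile`.
#' @param path File path.
#' @return `write_profile` returns `path` invisibly; `read_profile` a
#'   `density_profile`.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(axis = attr(profile, "axis"),
                   coord_um = profile$coord_um,
                   density_norm = profile$density,
                   sd = if (is.null(profile$sd)) NA_real_ else profile$sd)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("axis", "coord_um", "density_norm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing profile columns: ", paste(miss, collapse = ", "))
  sd <- if ("sd" %in% names(df) && !all(is.na(df$sd))) df$sd else NULL
  density_profile(df$coord_um, df$density_norm, axis = df$axis[1], sd = sd)
}
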