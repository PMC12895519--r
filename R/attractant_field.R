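#' Naphthalene transport parameters
#'
#' The attractant obeys a linear advection-diffusion equation
#' da/dt = D_a lap(a) - v_f . grad(a), with the aqueous-side concentration
#' at the NAPL-water interface pinned at its equilibrium value a0 (no
#' depletion over the experiment) and no flux through the other walls.
#'
#' @param D_a Diffusivity of naphthalene in water, cm^2/s.
#' @param a0 Equilibrium aqueous concentration at the interface, mol/m^3.
#' @return An `attractant_params` list; `D_umps` is the diffusivity in
#'   um^2/s used internally.
#' @export
attractant_params <- function(D_a = 7.5e-6, a0 = 0.25) {
  stopifnot(D_a > 0, a0 >= 0)
  structure(list(D_a = D_a, D_umps = D_a * 1e8, a0 = a0),
            class = "attractant_params")
}

# Face-normal velocity matrices for the imposed channel flow (u_x = u(y),
# u_y = 0) on a grid.  x-faces see the profile at the cell-row y centre.
flow_face_velocities <- function(grid, flow) {
  uy_row <- flow$u(grid$yc)
  list(
    u_xf = matrix(rep(uy_row, each = grid$nx + 1L), grid$nx + 1L, grid$ny),
    u_yf = matrix(0, grid$nx, grid$ny + 1L)
  )
}

# south-wall bc: Dirichlet a0 on the interface segment, no-flux elsewhere
interface_south_bc <- function(grid, geom, a0, full_wall = FALSE) {
  x0 <- geom$interface_start_x
  x1 <- x0 + geom$interface_width
  on_iface <- if (full_wall) rep(TRUE, grid$nx) else
    grid$xc >= x0 & grid$xc <= x1
  list(type = ifelse(on_iface, "dirichlet", "noflux"), value = a0)
}

#' Steady naphthalene concentration field
#'
#' Solves the steady advection-diffusion equation for the attractant on
#' the channel window: a = a0 on the interface segment of the y = 0 wall
#' (Dirichlet), no flux on the remaining walls, a = 0 at the inflow and
#' convective outflow at the downstream boundary.  The discretisation is
#' conservative finite volume with hybrid central/upwind faces, solved
#' directly (the problem is linear).
#'
#' @param geom A [channel_geometry()].
#' @param flow A [flow_profile()] on the same geometry.
#' @param params [attractant_params()].
#' @param grid An `fv_grid`; defaults to [make_grid()] on `geom`.
#' @param interface_full_wall If `TRUE` the Dirichlet segment covers the
#'   whole y = 0 wall (used by 1-D verification cases).
#' @param north_bc `"noflux"` (default) or `"zero"` (Dirichlet a = 0 on
#'   the far wall, for closed-form verification).
#' @param inlet_bc `"zero"` (Dirichlet a = 0, default) or `"noflux"`
#'   (used by 1-D verification cases to suppress streamwise effects).
#' @param peclet_warn Warn if the max cell Peclet number exceeds this.
#' @return A `scalar_field2d` with attributes `residual` (relative
#'   algebraic residual) and `cell_peclet`.
#' @export
solve_attractant_steady <- function(geom, flow, params = attractant_params(),
                                    grid = make_grid(geom),
                                    interface_full_wall = FALSE,
                                    north_bc = c("noflux", "zero"),
                                    inlet_bc = c("zero", "noflux"),
                                    peclet_warn = 40) {
  north_bc <- match.arg(north_bc)
  inlet_bc <- match.arg(inlet_bc)
  fv <- flow_face_velocities(grid, flow)
  pe <- cell_peclet(grid, params$D_umps, fv$u_xf, fv$u_yf)
  if (pe > peclet_warn) {
    warning(sprintf(
      "cell Peclet number %.1f: advection under-resolved, consider a finer grid", pe))
  }
  bc <- list(
    west = list(type = if (inlet_bc == "zero") "dirichlet" else "noflux",
                value = 0),
    east = list(type = "outflow"),
    south = interface_south_bc(grid, geom, params$a0, interface_full_wall),
    north = list(type = if (north_bc == "zero") "dirichlet" else "noflux",
                 value = 0)
  )
  sol <- solve_advdiff_steady(grid, params$D_umps, fv$u_xf, fv$u_yf, bc)
  if (sol$residual > 1e-8) {
    stop(sprintf("steady attractant solve did not converge (relative residual %.3g)",
                 sol$residual))
  }
  out <- scalar_field2d(grid, sol$values, units = "mol/m^3")
  attr(out, "residual") <- sol$residual
  attr(out, "cell_peclet") <- pe
  attr(out, "a0") <- params$a0
  out
}

#' Transient naphthalene field
#'
#' Implicit-Euler time marching of the attractant equation from a = 0
#' (the channel initially carries no naphthalene), with the same boundary
#' conditions as [solve_attractant_steady()].  Implicit stepping is
#' unconditionally stable, so `dt` controls temporal accuracy only; the
#' grid Courant number is attached as a diagnostic.
#'
#' @inheritParams solve_attractant_steady
#' @param t_end Final time, s (> 0).
#' @param dt Time step, s.
#' @param save_every Save a snapshot every this many steps.
#' @return List with `fields` (list of `scalar_field2d` with time stamps)
#'   and `times`.
#' @export
solve_attractant_transient <- function(geom, flow,
                                       params = attractant_params(),
                                       grid = make_grid(geom),
                                       t_end, dt = 5,
                                       save_every = max(1L, round(60 / dt))) {
  stopifnot(t_end > 0, dt > 0)
  fv <- flow_face_velocities(grid, flow)
  bc <- list(
    west = list(type = "dirichlet", value = 0),
    east = list(type = "outflow"),
    south = interface_south_bc(grid, geom, params$a0),
    north = list(type = "noflux")
  )
  n_steps <- max(1L, ceiling(t_end / dt))
  mr <- march_advdiff(grid, params$D_umps, fv$u_xf, fv$u_yf, bc,
                      init = matrix(0, grid$nx, grid$ny),
                      dt = dt, n_steps = n_steps, save_every = save_every)
  fields <- Map(function(v, t) scalar_field2d(grid, v, time = t),
                mr$values, mr$times)
  courant <- max(abs(fv$u_xf)) * dt / min(grid$dx)
  list(fields = fields, times = mr$times, courant = courant)
}

#' Gradient of a gridded field
#'
#' Centred differences between flanking cell centres in the interior
#' (exact for linear fields, second order on smoothly varying grids),
#' one-sided differences at the boundary rows/columns.
#'
#' @param field A `scalar_field2d` with at least 3 cells per direction.
#' @return List of `gx`, `gy` matrices (field units per um).
#' @export
field_gradient <- function(field) {
  g <- field$grid
  if (g$nx < 3L || g$ny < 3L) stop("field must be at least 3 cells in each direction")
  v <- field$values
  nx <- g$nx; ny <- g$ny
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (v[3:nx, ] - v[1:(nx - 2), ]) / (g$xc[3:nx] - g$xc[1:(nx - 2)])
  gx[1, ] <- (v[2, ] - v[1, ]) / (g$xc[2] - g$xc[1])
  gx[nx, ] <- (v[nx, ] - v[nx - 1, ]) / (g$xc[nx] - g$xc[nx - 1])
  gy[, 2:(ny - 1)] <- (v[, 3:ny] - v[, 1:(ny - 2)]) /
    rep(g$yc[3:ny] - g$yc[1:(ny - 2)], each = nx)
  gy[, 1] <- (v[, 2] - v[, 1]) / (g$yc[2] - g$yc[1])
  gy[, ny] <- (v[, ny] - v[, ny - 1]) / (g$yc[ny] - g$yc[ny - 1])
  list(gx = gx, gy = gy)
}

#' Transverse decay length of the attractant plume
#'
#' Distance from the interface wall (above the interface midpoint) at
#' which the concentration first falls below `frac * a0`; shrinks as flow
#' compresses the plume against the wall.
#'
#' @param field Steady attractant `scalar_field2d` (with `a0` attribute).
#' @param geom Matching [channel_geometry()].
#' @param frac Fraction of `a0` defining the plume edge.
#' @return Distance in um.
#' @export
plume_extent_y <- function(field, geom, frac = 0.1) {
  g <- field$grid
  xm <- geom$interface_start_x + geom$interface_width / 2
  i <- which.min(abs(g$xc - xm))
  a0 <- attr(field, "a0")
  if (is.null(a0)) a0 <- max(field$values)
  col <- field$values[i, ]
  below <- which(col < frac * a0)
  if (length(below) == 0L) return(max(g$yc))
  g$yc[min(below)]
}
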