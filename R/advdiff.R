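# Finite-volume assembly of the steady linear advection-diffusion operator
#
#   div(u c) - D lap(c) = 0
#
# on an fv_grid, hybrid central/upwind face interpolation (central where the
# face Peclet number permits, upwind otherwise), conservative in the face
# fluxes so that velocity fields with nonzero divergence (flow + chemotactic
# drift) are handled by bookkeeping the net through-flow on the diagonal.
#
# Face flux convention: for a face between left/lower cell L and
# right/upper cell R with through-flow F = u_f * A and diffusive
# conductance Dc = D * A / dist,
#   J(L -> R) = cL * c_L - cR * c_R,
#   cL = max(F, Dc + F/2, 0),  cR = max(-F, Dc - F/2, 0)
# which reduces to central differencing for |F| <= 2 Dc and to first-order
# upwinding beyond, and always satisfies cL - cR = F.

pmax3 <- function(a, b, c) pmax(pmax(a, b), c)

# bc: list with entries west, east, south, north; each a list
#   type: "dirichlet" | "noflux" | "outflow" (scalar or per-face vector)
#   value: boundary value for dirichlet faces (scalar or per-face)
# u_xf: (nx+1) x ny face-normal velocities on x-faces (um/s)
# u_yf: nx x (ny+1) face-normal velocities on y-faces
assemble_advdiff <- function(grid, D, u_xf, u_yf, bc) {
  nx <- grid$nx; ny <- grid$ny
  dx <- grid$dx; dy <- grid$dy
  xc <- grid$xc; yc <- grid$yc
  N <- nx * ny
  idx <- function(i, j) i + (j - 1L) * nx

  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  rhs <- numeric(N)
  add <- function(r, c, v) {
    ii <<- c(ii, r); jj <<- c(jj, c); vv <<- c(vv, v)
  }

  ## interior x-faces: between (i, j) and (i + 1, j), i = 1..nx-1
  if (nx > 1L) {
    i <- rep(seq_len(nx - 1L), times = ny)
    j <- rep(seq_len(ny), each = nx - 1L)
    A <- dy[j]
    F <- u_xf[cbind(i + 1L, j)] * A
    Dc <- D * A / (xc[i + 1L] - xc[i])
    cL <- pmax3(F, Dc + F / 2, 0)
    cR <- pmax3(-F, Dc - F / 2, 0)
    kL <- idx(i, j); kR <- idx(i + 1L, j)
    add(kL, kL, cL); add(kL, kR, -cR)
    add(kR, kR, cR); add(kR, kL, -cL)
  }

  ## interior y-faces: between (i, j) and (i, j + 1), j = 1..ny-1
  if (ny > 1L) {
    i <- rep(seq_len(nx), times = ny - 1L)
    j <- rep(seq_len(ny - 1L), each = nx)
    A <- dx[i]
    F <- u_yf[cbind(i, j + 1L)] * A
    Dc <- D * A / (yc[j + 1L] - yc[j])
    cL <- pmax3(F, Dc + F / 2, 0)
    cR <- pmax3(-F, Dc - F / 2, 0)
    kL <- idx(i, j); kR <- idx(i, j + 1L)
    add(kL, kL, cL); add(kL, kR, -cR)
    add(kR, kR, cR); add(kR, kL, -cL)
  }

  ## boundary faces; F_o is the outward through-flow
  boundary <- function(cells_k, F_o, Dc, side_bc, nfaces) {
    type <- rep_len(side_bc$type, nfaces)
    value <- rep_len(if (is.null(side_bc$value)) 0 else side_bc$value, nfaces)
    dir <- type == "dirichlet"
    if (any(dir)) {
      cP <- pmax3(F_o[dir], Dc[dir] + F_o[dir] / 2, 0)
      cB <- pmax3(-F_o[dir], Dc[dir] - F_o[dir] / 2, 0)
      add(cells_k[dir], cells_k[dir], cP)
      rhs[cells_k[dir]] <<- rhs[cells_k[dir]] + cB * value[dir]
    }
    out <- type == "outflow"
    if (any(out)) {
      # pure advective outflow; inward flow through an outflow boundary is
      # suppressed (treated as no-flux) to keep the operator well posed
      add(cells_k[out], cells_k[out], pmax(F_o[out], 0))
    }
    # "noflux": nothing to add
  }

  j <- seq_len(ny)
  boundary(idx(1L, j), -u_xf[cbind(rep(1L, ny), j)] * dy,
           D * dy / (xc[1] - grid$xf[1]), bc$west, ny)
  boundary(idx(nx, j), u_xf[cbind(rep(nx + 1L, ny), j)] * dy,
           D * dy / (grid$xf[nx + 1] - xc[nx]), bc$east, ny)
  i <- seq_len(nx)
  boundary(idx(i, 1L), -u_yf[cbind(i, rep(1L, nx))] * dx,
           D * dx / (yc[1] - grid$yf[1]), bc$south, nx)
  boundary(idx(i, ny), u_yf[cbind(i, rep(ny + 1L, nx))] * dx,
           D * dx / (grid$yf[ny + 1] - yc[ny]), bc$north, nx)

  A_mat <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  list(A = A_mat, rhs = rhs, volumes = as.vector(outer(dx, dy)))
}

# cell-wise divergence of the face through-flows (outward sum of u_f * A)
face_divergence <- function(grid, u_xf, u_yf) {
  nx <- grid$nx; ny <- grid$ny
  Fx <- u_xf * matrix(rep(grid$dy, each = nx + 1L), nx + 1L, ny)
  Fy <- u_yf * matrix(rep(grid$dx, times = ny + 1L), nx, ny + 1L)
  (Fx[-1L, , drop = FALSE] - Fx[-(nx + 1L), , drop = FALSE]) +
    (Fy[, -1L, drop = FALSE] - Fy[, -(ny + 1L), drop = FALSE])
}

# Steady solve: returns nx x ny matrix plus the relative residual.
# divergence_correction = TRUE turns the conservative operator div(u c)
# into the advective form u . grad(c) by subtracting c * div(u).
solve_advdiff_steady <- function(grid, D, u_xf, u_yf, bc,
                                 divergence_correction = FALSE) {
  sys <- assemble_advdiff(grid, D, u_xf, u_yf, bc)
  if (divergence_correction) {
    sys$A <- sys$A -
      Matrix::Diagonal(x = as.vector(face_divergence(grid, u_xf, u_yf)))
  }
  sol <- as.numeric(Matrix::solve(sys$A, sys$rhs))
  res <- as.numeric(sqrt(sum((sys$A %*% sol - sys$rhs)^2)))
  scale <- max(sqrt(sum(sys$rhs^2)), 1e-300)
  list(values = matrix(sol, grid$nx, grid$ny), residual = res / scale)
}

# Implicit-Euler transient march from `init` (nx x ny), saving every
# `save_every`-th step.  Unconditionally stable; dt controls accuracy only.
march_advdiff <- function(grid, D, u_xf, u_yf, bc, init, dt, n_steps,
                          save_every = n_steps) {
  sys <- assemble_advdiff(grid, D, u_xf, u_yf, bc)
  Vdt <- sys$volumes / dt
  M <- sys$A + Matrix::Diagonal(x = Vdt)
  fac <- Matrix::lu(M)
  a <- as.vector(init)
  out <- list(); times <- numeric(0)
  for (s in seq_len(n_steps)) {
    a <- as.numeric(Matrix::solve(fac, Vdt * a + sys$rhs))
    if (s %% save_every == 0L || s == n_steps) {
      out[[length(out) + 1L]] <- matrix(a, grid$nx, grid$ny)
      times <- c(times, s * dt)
    }
  }
  list(values = out, times = times)
}

# max cell Peclet number (advection vs diffusion resolution diagnostic)
cell_peclet <- function(grid, D, u_xf, u_yf) {
  px <- max(abs(u_xf)) * max(grid$dx) / D
  py <- max(abs(u_yf)) * max(grid$dy) / D
  max(px, py)
}
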