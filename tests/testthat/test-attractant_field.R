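test_that("zero interface concentration yields an identically zero field", {
  geom <- test_geom()
  f <- solve_attractant_steady(geom, flow_profile(1, geom),
                               attractant_params(a0 = 0),
                               grid = make_grid(geom, h_fine_y = 10,
                                                h_fine_x = 25))
  expect_equal(max(abs(f$values)), 0, tolerance = 1e-12)
})

test_that("steady fields obey the maximum principle and peak at the interface", {
  for (v in c(0.5, 10)) {
    f <- test_attractant(v)
    a0 <- 0.25
    expect_true(min(f$values) >= -1e-10)
    expect_true(max(f$values) <= a0 + 1e-10)
    # the maximum sits in the wall cells adjacent to the interface segment
    k <- arrayInd(which.max(f$values), dim(f$values))
    expect_true(f$grid$xc[k[1]] >= 0 && f$grid$xc[k[1]] <= 50)
    expect_equal(k[2], 1L)
    expect_gt(max(f$values), 0.9 * a0)
  }
})

test_that("pure-diffusion harness case reproduces the linear closed form", {
  # zero flow, interface widened to the full wall, far wall held at zero:
  # 1-D diffusion between Dirichlet plates, a(y) = a0 (1 - y/W)
  geom <- test_geom()
  f <- solve_attractant_steady(geom, flow_profile(0, geom),
                               grid = test_grid(),
                               interface_full_wall = TRUE,
                               north_bc = "zero", inlet_bc = "noflux")
  a0 <- 0.25; W <- geom$domain_width_y
  expected <- a0 * (1 - f$grid$yc / W)
  mid <- round(f$grid$nx / 2)
  expect_equal(f$values[mid, ], expected, tolerance = 1e-10)
})

test_that("higher mean velocity compresses the plume against the interface", {
  ext <- vapply(c(0.5, 1, 5, 10), function(v) {
    plume_extent_y(test_attractant(v), test_geom())
  }, numeric(1))
  expect_true(all(diff(ext) <= 1e-9))
  expect_gt(ext[1], ext[4])
})

test_that("transient solution starts at zero, approaches the steady state monotonically, and is steady by 10 min", {
  geom <- test_geom()
  flow <- flow_profile(0.5, geom)
  grid <- make_grid(geom, h_fine_y = 5, h_fine_x = 20)
  tr <- solve_attractant_transient(geom, flow, grid = grid, t_end = 600,
                                   dt = 5, save_every = 12)
  steady <- solve_attractant_steady(geom, flow, grid = grid)
  l2 <- function(m) sqrt(sum(m^2))
  dists <- vapply(tr$fields, function(f) l2(f$values - steady$values),
                  numeric(1))
  expect_true(all(diff(dists) < 1e-9))  # monotone approach in L2
  # the observation window equilibrates within the 10-min pump-settling
  # time (the far field keeps filling for hours, so the comparison is on
  # the near-interface region the experiment actually images)
  band <- function(m) m[abs(grid$xc) <= 400, grid$yc <= 250]
  expect_lt(l2(band(tr$fields[[length(tr$fields)]]$values) -
                 band(steady$values)) / l2(band(steady$values)), 0.01)
  n <- length(tr$fields)
  expect_equal(tr$times[n - 1], 540)
  change <- l2(band(tr$fields[[n]]$values) - band(tr$fields[[n - 1]]$values)) /
    l2(band(tr$fields[[n]]$values))
  expect_lt(change, 0.01)
})

test_that("gradient is exact for linear ramps and second order for smooth fields", {
  geom <- test_geom()
  grid <- make_grid(geom, h_fine_y = 5, h_fine_x = 20)
  uni <- scalar_field2d(grid, matrix(3.2, grid$nx, grid$ny))
  g0 <- field_gradient(uni)
  expect_equal(max(abs(g0$gx)), 0)
  expect_equal(max(abs(g0$gy)), 0)

  cc <- 0.013
  ramp <- scalar_field2d(grid, outer(rep(1, grid$nx), cc * grid$yc))
  g1 <- field_gradient(ramp)
  expect_equal(max(abs(g1$gx)), 0, tolerance = 1e-15)
  expect_equal(g1$gy, matrix(cc, grid$nx, grid$ny), tolerance = 1e-10)

  # smooth field: compare with the analytic derivative on the uniform
  # fine part of the grid; centred differences are O(h^2) there
  L <- 500
  vals <- outer(sin(2 * pi * grid$xc / L), cos(2 * pi * grid$yc / L))
  sf <- scalar_field2d(grid, vals)
  g2 <- field_gradient(sf)
  gx_true <- outer(2 * pi / L * cos(2 * pi * grid$xc / L),
                   cos(2 * pi * grid$yc / L))
  fine_x <- which(grid$dx <= 20)[-1]
  fine_y <- which(grid$dy <= 5)[-1]
  err <- max(abs((g2$gx - gx_true)[fine_x, fine_y]))
  h <- 20
  expect_lt(err, 2 * (2 * pi / L)^3 * h^2)  # |f'''| h^2 bound with margin
  expect_error(field_gradient(scalar_field2d(structure(list(
    xf = 0:2, yf = 0:5, xc = c(0.5, 1.5), yc = 1:5 - 0.5,
    dx = c(1, 1), dy = rep(1, 5), nx = 2L, ny = 5L), class = "fv_grid"),
    matrix(0, 2, 5))), "at least 3 cells")
})

test_that("doubling the window length leaves interface-band profiles unchanged", {
  geom2 <- channel_geometry(domain_length_x = 8000)
  f2 <- solve_attractant_steady(geom2, flow_profile(0.5, geom2),
                                grid = make_grid(geom2))
  f1 <- test_attractant(0.5)
  p1 <- extract_profile(f1, "y")
  p2 <- extract_profile(f2, "y")
  expect_equal(p2$density, p1$density, tolerance = 0.01)
})

test_that("field text export round-trips", {
  grid <- make_grid(test_geom(), h_fine_y = 50, h_max_y = 400,
                    h_fine_x = 100, h_max_x = 800)
  f <- scalar_field2d(grid, matrix(runif(grid$nx * grid$ny), grid$nx))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_field(f, path)
  df <- read_field_table(path)
  expect_equal(nrow(df), grid$nx * grid$ny)
  expect_equal(matrix(df$value, grid$nx), f$values, tolerance = 1e-12)
})
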