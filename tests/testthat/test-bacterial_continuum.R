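test_that("chemotactic drift vanishes without a gradient and never exceeds 2v/3", {
  p <- chemotaxis_params()
  v0 <- chemotactic_velocity(0.1, list(gx = 0, gy = 0), p)
  expect_equal(v0$vx, 0)
  expect_equal(v0$vy, 0)
  # property: strict tanh bound over random concentrations and gradients
  set.seed(4)
  a <- runif(500, 0, 0.25)
  g <- list(gx = rnorm(500, 0, 2e-3), gy = rnorm(500, 0, 2e-3))
  vc <- chemotactic_velocity(a, g, p)
  mag <- sqrt(vc$vx^2 + vc$vy^2)
  expect_true(all(mag < 2 * p$v / 3))  # strict tanh bound
  # even absurdly steep gradients only approach the cap, never pass it
  vs <- chemotactic_velocity(0, list(gx = 10, gy = 0), p)
  expect_lte(vs$vx, 2 * p$v / 3)
  expect_gt(vs$vx, 0.999 * 2 * p$v / 3)
  expect_error(chemotactic_velocity(-0.1, g, p), "non-negative")
})

test_that("chemotactic drift matches its first-order series for small gradients", {
  p <- chemotaxis_params()
  a <- c(0, 0.016, 0.1)
  # gradients chosen so the tanh argument stays below 1e-2
  for (ai in a) {
    arg_scale <- p$chi_umps / (2 * p$v) * p$K_C / (p$K_C + ai)^2
    g <- 0.9e-2 / arg_scale
    vc <- chemotactic_velocity(ai, list(gx = g, gy = 0), p)
    linear <- p$chi_umps / 3 * p$K_C / (p$K_C + ai)^2 * g
    expect_equal(vc$vx, linear, tolerance = 1e-3)
  }
})

test_that("drift aligns with the gradient direction", {
  p <- chemotaxis_params()
  vc <- chemotactic_velocity(0.01, list(gx = 3e-4, gy = -4e-4), p)
  expect_equal(vc$vy / vc$vx, -4 / 3, tolerance = 1e-12)
  expect_gt(vc$vx, 0)
})

test_that("zero sensitivity or zero attractant gives the uniform unit density", {
  geom <- test_geom()
  flow <- flow_profile(0.5, geom)
  b0 <- solve_bacteria_steady(geom, flow, test_attractant(0.5),
                              chemotaxis_params(chi_o = 0))
  expect_equal(max(abs(b0$values - 1)), 0, tolerance = 1e-9)
  zero_attr <- scalar_field2d(test_grid(),
                              matrix(0, test_grid()$nx, test_grid()$ny))
  b1 <- solve_bacteria_steady(geom, flow, zero_attr)
  expect_equal(max(abs(b1$values - 1)), 0, tolerance = 1e-9)
})

test_that("bacterial density stays non-negative with unit inlet value", {
  b <- test_bacteria(0.5)
  expect_true(min(b$values) >= 0)
  # inlet value is pinned at the inflow face; the adjacent cell centre
  # deviates only by the local within-cell variation
  expect_equal(b$values[1, round(b$grid$ny / 2)], 1, tolerance = 1e-3)
})

test_that("the advective and conservative drift forms bracket the accumulation", {
  geom <- test_geom()
  flow <- flow_profile(0.5, geom)
  b_adv <- test_bacteria(0.5)
  b_con <- solve_bacteria_steady(geom, flow, test_attractant(0.5),
                                 form = "conservative")
  peak <- function(b) max(extract_profile(b, "y")$density)
  expect_gt(peak(b_adv), 1.1)        # as-written form accumulates
  expect_gt(peak(b_con), 2 * peak(b_adv))  # conservative form much more
})

test_that("profile extraction equals hand-computed band means", {
  # small grid with known cell values: oracle by direct weighted average
  geom <- channel_geometry(domain_length_x = 100, domain_width_y = 40,
                           interface_width = 50, x_upstream = 25)
  grid <- make_grid(geom, h_fine_x = 25, h_max_x = 25, fine_margin_x = 0,
                    h_fine_y = 10, h_max_y = 10, fine_extent_y = 40)
  vals <- outer(seq_len(grid$nx), seq_len(grid$ny),
                function(i, j) (i + j) %% 2 + i * 0.1)  # checkerboard + tilt
  f <- scalar_field2d(grid, vals, units = "normalized density")
  class(f) <- c("density_field2d", class(f))
  prof <- extract_profile(f, axis = "y", band = c(0, 50), extent = c(0, 40))
  sel <- grid$xc >= 0 & grid$xc <= 50
  oracle <- apply(vals[sel, , drop = FALSE], 2, stats::weighted.mean,
                  w = grid$dx[sel])
  expect_equal(prof$density, oracle, tolerance = 1e-12)
  expect_equal(prof$coord_um, grid$yc)

  uni <- scalar_field2d(grid, matrix(1, grid$nx, grid$ny))
  expect_equal(extract_profile(uni, "y", extent = c(0, 40))$density,
               rep(1, grid$ny), tolerance = 1e-15)
  expect_error(extract_profile(f, "y", band = c(1000, 2000)), "empty band")
})

test_that("accumulation extent finds threshold crossings and empty cases", {
  flat <- density_profile(seq(0, 100, 10), rep(1, 11))
  expect_null(accumulation_extent(flat, 1.05))
  # triangular bump: density 1 + 0.3 * hat centred at 50, support [20, 80];
  # crosses 1.1 where hat = 1/3: at x = 30 and x = 70
  x <- seq(0, 100, 5)
  hat <- pmax(0, 1 - abs(x - 50) / 30)
  tri <- density_profile(x, 1 + 0.3 * hat)
  ext <- accumulation_extent(tri, 1.1)
  expect_equal(ext, c(30, 70), tolerance = 1e-9)
  expect_error(accumulation_extent(tri, 0.9), "threshold > 1")
})

test_that("profile text files round-trip and report missing columns", {
  p <- density_profile(c(5, 15, 25), c(1.0, 1.2, 1.1), axis = "x",
                       sd = c(0.01, 0.02, 0.01))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, path)
  q <- read_profile(path)
  expect_equal(q$coord_um, p$coord_um)
  expect_equal(q$density, p$density)
  expect_equal(q$sd, p$sd)
  expect_equal(attr(q, "axis"), "x")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("coord_um\tdensity\n1\t2", bad)
  expect_error(read_profile(bad), "missing profile columns")
})

test_that("near-interface peak follows the apparent-sensitivity schedule across velocities", {
  peaks <- vapply(c(0.5, 1, 5, 10), function(v) {
    b <- test_bacteria(v, chi = apparent_chi(v))
    p <- extract_profile(b, "y")
    max(p$density[p$coord_um <= 50])
  }, numeric(1))
  expect_true(all(diff(peaks) <= 0.02))  # non-increasing (numerical slack)
  expect_gt(peaks[1], peaks[4] + 0.2)
})
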