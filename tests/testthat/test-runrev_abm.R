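test_that("reversal rate follows the exponential receptor law", {
  expect_equal(reversal_probability(0.1, 0, p0 = 0.5), 0.5)
  # hand evaluation: a = 0, K_C = 0.016, sigma* = 4, dadt = 0.004
  # exponent = -4 * (1/0.016) * 0.004 = -1
  expect_equal(reversal_probability(0, 0.004, p0 = 0.5, sigma_star = 4,
                                    K_C = 0.016),
               0.5 * exp(-1), tolerance = 1e-12)
  # sign behaviour: up-gradient (dadt > 0) suppresses reversals,
  # down-gradient promotes them
  set.seed(11)
  a <- runif(200, 0, 0.25)
  up <- reversal_probability(a, runif(200, 1e-4, 0.1))
  down <- reversal_probability(a, -runif(200, 1e-4, 0.1))
  expect_true(all(up < 0.5))
  expect_true(all(down > 0.5))
  # overflow guard
  expect_true(is.finite(reversal_probability(0, -1e6)))
  expect_error(reversal_probability(-1, 0), "non-negative")
})

test_that("experienced derivative is the along-trajectory difference quotient", {
  expect_equal(experienced_derivative(0.2, 0.2, 0.1), 0)
  expect_equal(experienced_derivative(0.24, 0.2, 0.1), 0.4)
  # closed-form trajectory oracle: swimming straight up a linear ramp
  # c * y at speed vy experiences dadt = c * vy
  cc <- 1e-3; vy <- 30; dt <- 0.1
  y0 <- 100
  a_prev <- cc * y0
  a_now <- cc * (y0 + vy * dt)
  expect_equal(experienced_derivative(a_now, a_prev, dt), cc * vy,
               tolerance = 1e-12)
})

test_that("agents move ballistically when reversals and stimuli are absent", {
  cfg <- abm_config(p0 = 0, velocity_m_d = 0, burn_in = 0, duration = 1,
                    n_agents = 1, speed_sd = 0)
  st <- list(x = 100, y = 200, heading = pi / 6, speed = 44,
             a_prev = 0, a_curr = 0)
  set.seed(1)
  for (k in 1:5) st <- abm_step(st, NULL, NULL, cfg)
  expect_equal(st$x, 100 + 44 * cos(pi / 6) * 0.5, tolerance = 1e-12)
  expect_equal(st$y, 200 + 44 * sin(pi / 6) * 0.5, tolerance = 1e-12)
  expect_equal(st$heading, pi / 6)
})

test_that("a non-swimming agent is a passive tracer of the Poiseuille flow", {
  cfg <- abm_config(p0 = 0, velocity_m_d = 1, burn_in = 0, duration = 1)
  flow <- flow_profile(1, channel_geometry())
  st <- list(x = 0, y = 150, heading = 0, speed = 0, a_prev = 0, a_curr = 0)
  set.seed(1)
  st2 <- abm_step(st, NULL, flow, cfg)
  expect_equal(st2$x, flow$u(150) * 0.1, tolerance = 1e-12)
  expect_equal(st2$y, 150)
})

test_that("ensemble MSD crosses from ballistic to diffusive and matches run-reverse theory", {
  # free swimmers (domain far larger than any excursion), fixed speed
  cfg <- abm_config(velocity_m_d = 0, domain_x = c(-1e5, 1e5),
                    domain_y = c(-1e5, 1e5), n_agents = 600, p0 = 0.5,
                    speed_sd = 0, sigma_star = 0, duration = 60,
                    burn_in = 0, record_tracks = TRUE, seed = 99,
                    spawn_strip = 1e-9)
  res <- run_abm(cfg, NULL, NULL)
  msd <- track_msd(res$tracks,
                   lags = round(10^seq(0, log10(500), length.out = 25)))
  # ballistic regime: at lag << 1/p0 the log-log slope is near 2
  s_early <- diff(log(msd$msd_um2[c(1, 3)])) / diff(log(msd$lag_s[c(1, 3)]))
  expect_gt(s_early, 1.85)
  # diffusive regime: slope near 1
  late <- msd$lag_s >= 20 & msd$lag_s <= 50
  fit <- stats::lm(log(msd$msd_um2[late]) ~ log(msd$lag_s[late]))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.15)
  # effective diffusivity vs correlated-random-walk theory
  # D = v^2 / (n p0 (1 - <cos theta>)), n = 2; theta = pi + delta with
  # delta ~ truncated Normal(0, 30 deg), so <cos theta> = -<cos delta>
  sd_r <- 30 * pi / 180; m <- 90 * pi / 180
  mean_cos <- stats::integrate(function(d) {
    cos(d) * stats::dnorm(d, 0, sd_r) /
      (stats::pnorm(m, 0, sd_r) - stats::pnorm(-m, 0, sd_r))
  }, -m, m)$value
  D_theory <- 44^2 / (2 * 0.5 * (1 + mean_cos))
  D_hat <- mean(msd$msd_um2[late] / (4 * msd$lag_s[late]))
  expect_equal(D_hat, D_theory, tolerance = 0.15)
})

test_that("identical configuration and seed give bit-identical results", {
  cfg <- abm_config(velocity_m_d = 1, n_agents = 300, duration = 15,
                    burn_in = 5, snapshot_every = 2, seed = 7,
                    record_tracks = TRUE)
  af <- test_attractant(1)
  r1 <- run_abm(cfg, af)
  r2 <- run_abm(cfg, af)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$tracks, r2$tracks)
  expect_identical(r1$n_history, r2$n_history)
  r3 <- run_abm(abm_config(velocity_m_d = 1, n_agents = 300, duration = 15,
                           burn_in = 5, snapshot_every = 2, seed = 8,
                           record_tracks = TRUE), af)
  expect_false(identical(r1$snapshots, r3$snapshots))
})

test_that("agents stay inside the domain and counts change only via the strips", {
  cfg <- abm_config(velocity_m_d = 1, n_agents = 400, duration = 20,
                    burn_in = 0, snapshot_every = 2, seed = 3)
  res <- run_abm(cfg, test_attractant(1))
  for (sn in res$snapshots) {
    expect_true(all(sn$x_um >= cfg$domain_x[1] & sn$x_um <= cfg$domain_x[2]))
    expect_true(all(sn$y_um >= cfg$domain_y[1] & sn$y_um <= cfg$domain_y[2]))
  }
})

test_that("without a stimulus the ensemble stays uniform across the window", {
  cfg <- abm_config(velocity_m_d = 0.5, sigma_star = 0, seed = 7,
                    duration = 250, burn_in = 120)
  res <- run_abm(cfg, test_attractant(0.5))
  prof <- density_from_agents(res)
  z <- abs(prof$density - 1) / prof$se
  expect_lt(max(z), 4)        # no single bin biased
  expect_lt(mean(z), 1.6)     # ensemble consistent with uniformity
})

test_that("agent binning matches a brute-force count on a hand-made snapshot", {
  snaps <- list(data.frame(t = 1,
                           id = 1:6,
                           x_um = c(10, 20, 30, 45, 60, 25),
                           y_um = c(5, 15, 5, 35, 5, 100)))
  prof <- density_from_agents(snaps, axis = "y", band = c(0, 50),
                              extent = c(0, 40), bin_width = 10,
                              baseline = 0.01)
  # in-band agents (x in [0,50]): y = 5, 15, 5, 35, 100 -> bins 1,2,1,4
  counts <- c(2, 1, 0, 1)
  expect_equal(prof$density, counts / (10 * 50) / 0.01)
  # degenerate: all agents in one bin
  one <- list(data.frame(t = 1, id = 1:3, x_um = rep(10, 3),
                         y_um = rep(5, 3)))
  p1 <- density_from_agents(one, axis = "y", band = c(0, 50),
                            extent = c(0, 40), bin_width = 10,
                            baseline = 0.01)
  expect_true(all(p1$density[-1] == 0) && p1$density[1] > 0)
  expect_error(density_from_agents(list(), axis = "y"), "no snapshots")
})

test_that("p0 calibration recovers the generative value and flags flat targets", {
  cfg <- abm_config(velocity_m_d = 0.5, n_agents = 600, duration = 120,
                    burn_in = 60, snapshot_every = 5, seed = 21)
  af <- test_attractant(0.5)
  target_run <- run_abm(cfg, af)
  target <- density_from_agents(target_run)
  fit <- fit_p0(target, p0_grid = c(0.1, 0.5, 1.0), cfg = cfg,
                attractant = af, replicates = 1, seed = 77)
  expect_equal(fit$p0_hat, 0.5)
  flat <- density_profile(target$coord_um, rep(1, nrow(target)), axis = "y")
  fit_flat <- fit_p0(flat, p0_grid = c(0.1, 0.5, 1.0), cfg = cfg,
                     attractant = af, replicates = 1, seed = 77)
  expect_true("at_bound" %in% fit_flat$flags)
  expect_equal(fit_flat$p0_hat, 0.1)
})

test_that("configuration invariants are enforced", {
  expect_error(abm_config(dt = 0.1, p0 = 20), "p0")
  expect_error(abm_config(dt = -1))
  expect_error(abm_config(n_agents = 0))
  expect_error(abm_config(dt = 5, p0 = 0.1, speed_range = c(5, 100)),
               "exceeds the domain")
})
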