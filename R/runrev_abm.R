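#' Configuration of the run-reverse agent-based model
#'
#' Stochastic swimmers in a 400 um x 800 um window against the interface
#' wall: straight runs at a speed drawn from a truncated normal
#' distribution, interrupted by reversals (heading + 180 degrees plus a
#' truncated-normal deviation) whose instantaneous rate is the baseline
#' p0 modulated by the experienced attractant change (see
#' [reversal_probability()]).  Agents are advected by the local Poiseuille
#' velocity, reflected from the side walls at a random inward angle,
#' removed beyond the downstream edge and topped up in an upstream spawn
#' strip so the inlet density stays at its baseline.
#'
#' @param velocity_m_d Mean fluid velocity, m/d.
#' @param domain_x,domain_y Window extents, um.  The default x window
#'   centres the 50-um interface segment (`[0, 50]` in package
#'   coordinates); y runs from the interface wall.
#' @param n_agents Baseline agent count.
#' @param dt Time step, s (one reorientation decision per step).
#' @param p0 Baseline reversal frequency, 1/s.
#' @param sigma_star Effective single-cell chemotactic sensitivity, s.
#' @param K_C Receptor constant, mol/m^3.
#' @param speed_mean,speed_sd,speed_range Run-speed distribution, um/s
#'   (normal, truncated to `speed_range`).
#' @param turn_sd_deg,turn_max_deg Reversal-deviation distribution:
#'   normal with this sd about 180 degrees, truncated to +/- `turn_max_deg`.
#' @param duration Simulated time, s.
#' @param burn_in Time discarded before snapshots/tracks, s; default two
#'   window-transit times at the mean velocity (capped at 300 s).
#' @param snapshot_every Snapshot interval after burn-in, s.
#' @param spawn_strip Width of the upstream spawn strip, um.
#' @param record_tracks Record per-step agent positions after burn-in.
#' @param seed RNG seed (the run is bit-reproducible given the config).
#' @return An `abm_config` list.
#' @export
abm_config <- function(velocity_m_d = 0.5,
                       domain_x = c(-375, 425), domain_y = c(0, 400),
                       n_agents = 4000, dt = 0.1,
                       p0 = 0.5, sigma_star = 4, K_C = 0.016,
                       speed_mean = 44, speed_sd = 15,
                       speed_range = c(5, 100),
                       turn_sd_deg = 30, turn_max_deg = 90,
                       duration = 400,
                       burn_in = NULL,
                       snapshot_every = 5,
                       spawn_strip = 40,
                       record_tracks = FALSE,
                       seed = 1L) {
  stopifnot(dt > 0, p0 >= 0, p0 * dt <= 1, n_agents > 0, sigma_star >= 0,
            K_C > 0, speed_mean > 0, speed_range[1] > 0,
            diff(domain_x) > 0, diff(domain_y) > 0, duration > 0)
  if (speed_range[2] * dt > min(diff(domain_x), diff(domain_y))) {
    stop("dt * max speed exceeds the domain size")
  }
  if (is.null(burn_in)) {
    vbar <- convert_velocity(velocity_m_d)
    burn_in <- if (vbar > 0) min(2 * diff(domain_x) / vbar, 300) else 300
  }
  structure(list(
    velocity_m_d = velocity_m_d,
    domain_x = domain_x, domain_y = domain_y,
    n_agents = n_agents, dt = dt, p0 = p0, sigma_star = sigma_star,
    K_C = K_C, speed_mean = speed_mean, speed_sd = speed_sd,
    speed_range = speed_range, turn_sd_deg = turn_sd_deg,
    turn_max_deg = turn_max_deg, duration = duration, burn_in = burn_in,
    snapshot_every = snapshot_every, spawn_strip = spawn_strip,
    record_tracks = record_tracks, seed = as.integer(seed)
  ), class = "abm_config")
}

#' Stimulus-modulated reversal rate
#'
#' p = p0 exp( - sigma* K_C / (K_C + a)^2 * Da/Dt ): cells experiencing
#' increasing attractant (swimming up-gradient) reverse less often,
#' extending favourable runs; decreasing attractant raises the rate.
#' Natural-logarithm convention; the exponent is clamped to +/- 50 to
#' guard overflow.  The per-step reversal chance is `min(rate * dt, 1)`.
#'
#' @param a Local attractant concentration, mol/m^3 (>= 0).
#' @param dadt Experienced (material) concentration derivative,
#'   mol/m^3/s.
#' @param p0 Baseline reversal frequency, 1/s.
#' @param sigma_star Effective single-cell sensitivity, s.
#' @param K_C Receptor constant, mol/m^3.
#' @return Reversal rate, 1/s (vectorised).
#' @export
reversal_probability <- function(a, dadt, p0 = 0.5, sigma_star = 4,
                                 K_C = 0.016) {
  if (any(a < 0)) stop("attractant concentration must be non-negative")
  expo <- -sigma_star * K_C / (K_C + a)^2 * dadt
  p0 * exp(clamp(expo, -50, 50))
}

#' Experienced concentration derivative along a trajectory
#'
#' First-order temporal difference of the concentration sampled at the
#' agent's successive positions; because the agent moves with both its
#' swimming velocity and the flow, this is the discrete material
#' derivative (local change plus motion through the gradient).
#'
#' @param a_now,a_prev Concentrations at the current and previous
#'   positions, mol/m^3.
#' @param dt Time step, s (> 0).
#' @return mol/m^3/s.
#' @export
experienced_derivative <- function(a_now, a_prev, dt) {
  stopifnot(dt > 0)
  (a_now - a_prev) / dt
}

# truncated-normal sampler via inverse CDF (fixed RNG draw count per call)
rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(clamp(mean, lo, hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

new_agents <- function(n, cfg, x_range, attractant) {
  x <- stats::runif(n, x_range[1], x_range[2])
  y <- stats::runif(n, cfg$domain_y[1], cfg$domain_y[2])
  a <- if (is.null(attractant)) numeric(n) else field_interp(attractant, x, y)
  list(x = x, y = y,
       heading = stats::runif(n, -pi, pi),
       speed = rtnorm(n, cfg$speed_mean, cfg$speed_sd,
                      cfg$speed_range[1], cfg$speed_range[2]),
       a_prev = a, a_curr = a)
}

#' Advance the agent ensemble one time step
#'
#' One decision-move cycle for every agent: evaluate the reversal rate
#' from the experienced attractant change, reverse (new heading
#' 180 degrees + deviation, new speed) with probability `min(rate dt, 1)`,
#' displace by swimming plus the local flow, resolve side-wall collisions
#' by mirroring back inside with a random inward heading, and resample
#' the attractant at the new position.  Streamwise boundaries
#' (spawn/removal) are handled by [run_abm()], not here.
#'
#' @param state List of equal-length vectors `x`, `y`, `heading`, `speed`,
#'   `a_prev`, `a_curr`.
#' @param attractant `scalar_field2d` or `NULL` for no attractant.
#' @param flow A [flow_profile()] (evaluated at the agent y positions) or
#'   `NULL` for quiescent fluid.
#' @param cfg An [abm_config()].
#' @return Updated state; reversal events in `state$reversed`.
#' @export
abm_step <- function(state, attractant, flow, cfg) {
  n <- length(state$x)
  dadt <- experienced_derivative(state$a_curr, state$a_prev, cfg$dt)
  rate <- reversal_probability(state$a_curr, dadt, cfg$p0, cfg$sigma_star,
                               cfg$K_C)
  rev <- stats::runif(n) < pmin(rate * cfg$dt, 1)
  n_rev <- sum(rev)
  if (n_rev > 0) {
    dev <- rtnorm(n_rev, 0, cfg$turn_sd_deg, -cfg$turn_max_deg,
                  cfg$turn_max_deg) * pi / 180
    state$heading[rev] <- state$heading[rev] + pi + dev
    state$speed[rev] <- rtnorm(n_rev, cfg$speed_mean, cfg$speed_sd,
                               cfg$speed_range[1], cfg$speed_range[2])
  }
  ux <- if (is.null(flow)) 0 else flow$u(clamp(state$y, 0, flow$W))
  state$x <- state$x + (state$speed * cos(state$heading) + ux) * cfg$dt
  state$y <- state$y + state$speed * sin(state$heading) * cfg$dt

  # wall collisions: mirror back inside with a random inward heading drawn
  # from the flux-weighted (Lambert cosine) distribution, pdf ~ sin(theta)
  # off the wall -- the choice that preserves a uniform ensemble at
  # equilibrium (uniform-in-angle re-emission over-populates shallow
  # angles and artificially piles swimmers up at the walls)
  y0 <- cfg$domain_y[1]; y1 <- cfg$domain_y[2]
  low <- state$y < y0
  if (any(low)) {
    state$y[low] <- y0 + (y0 - state$y[low])
    state$heading[low] <- acos(1 - 2 * stats::runif(sum(low)))
  }
  high <- state$y > y1
  if (any(high)) {
    state$y[high] <- y1 - (state$y[high] - y1)
    state$heading[high] <- -acos(1 - 2 * stats::runif(sum(high)))
  }
  state$y <- clamp(state$y, y0, y1)

  state$a_prev <- state$a_curr
  state$a_curr <- if (is.null(attractant)) numeric(n) else
    field_interp(attractant, state$x, state$y)
  state$reversed <- rev
  state
}

#' Run the agent-based simulation
#'
#' Time loop over `cfg$duration` at step `cfg$dt`: per-step reversal
#' decisions and motion ([abm_step()]), removal of agents carried beyond
#' the streamwise window, and top-up of the upstream spawn strip to its
#' baseline count (uniform positions, random headings) so the incoming
#' density is constant.  After `cfg$burn_in`, agent-position snapshots
#' are collected every `cfg$snapshot_every` seconds and (optionally)
#' per-step tracks of all agents.
#'
#' @param cfg An [abm_config()].
#' @param attractant Steady attractant `scalar_field2d`, or `NULL`.
#' @param flow A [flow_profile()]; defaults to the profile implied by
#'   `cfg$velocity_m_d` on the standard channel geometry.
#' @return An `abm_result`: `snapshots` (list of data frames
#'   `t, id, x_um, y_um`), `tracks` (a [track_table()] resampled at `dt`,
#'   or `NULL`), `n_history` (agent count per step) and the config echo.
#' @export
run_abm <- function(cfg, attractant = NULL,
                    flow = flow_profile(cfg$velocity_m_d)) {
  set.seed(cfg$seed)
  xr <- cfg$domain_x
  n_strip_base <- max(1L, round(cfg$n_agents * cfg$spawn_strip / diff(xr)))

  # hold a streamwise strip at its baseline agent count: insert fresh
  # agents on a deficit, thin a random excess -- the open-boundary
  # bookkeeping that keeps the up/downstream density pinned at baseline
  maintain_strip <- function(st, lo, hi, next_id) {
    inside <- which(st$x >= lo & st$x <= hi)
    diffn <- n_strip_base - length(inside)
    if (diffn > 0L) {
      fresh <- new_agents(diffn, cfg, c(lo, hi), attractant)
      fresh$id <- seq.int(next_id, length.out = diffn)
      fresh$reversed <- rep(FALSE, diffn)
      next_id <- next_id + diffn
      st <- Map(c, st[names(fresh)], fresh)
    } else if (diffn < 0L) {
      drop <- inside[sample.int(length(inside), -diffn)]
      st <- lapply(st, function(v) v[-drop])
    }
    list(st = st, next_id = next_id)
  }

  st <- new_agents(cfg$n_agents, cfg, xr, attractant)
  st$id <- seq_len(cfg$n_agents)
  next_id <- cfg$n_agents + 1L

  n_steps <- ceiling(cfg$duration / cfg$dt)
  snap_every <- max(1L, round(cfg$snapshot_every / cfg$dt))
  burn_steps <- round(cfg$burn_in / cfg$dt)
  snapshots <- list()
  track_buf <- list()
  n_history <- integer(n_steps)

  for (s in seq_len(n_steps)) {
    st <- abm_step(st, attractant, flow, cfg)

    keep <- st$x <= xr[2] & st$x >= xr[1]
    if (!all(keep)) {
      st <- lapply(st, function(v) v[keep])
    }
    ms <- maintain_strip(st, xr[1], xr[1] + cfg$spawn_strip, next_id)
    ms <- maintain_strip(ms$st, xr[2] - cfg$spawn_strip, xr[2], ms$next_id)
    st <- ms$st; next_id <- ms$next_id
    n_history[s] <- length(st$x)

    t_now <- s * cfg$dt
    if (s > burn_steps) {
      if ((s - burn_steps) %% snap_every == 0L) {
        snapshots[[length(snapshots) + 1L]] <-
          data.frame(t = t_now, id = st$id, x_um = st$x, y_um = st$y)
      }
      if (cfg$record_tracks) {
        track_buf[[length(track_buf) + 1L]] <-
          list(t = t_now, id = st$id, x = st$x, y = st$y)
      }
    }
  }

  tracks <- NULL
  if (cfg$record_tracks && length(track_buf) > 0) {
    df <- data.frame(
      TRACK_ID = unlist(lapply(track_buf, `[[`, "id")),
      POSITION_T = rep(vapply(track_buf, `[[`, numeric(1), "t"),
                       vapply(track_buf, function(b) length(b$id), integer(1))),
      POSITION_X = unlist(lapply(track_buf, `[[`, "x")),
      POSITION_Y = unlist(lapply(track_buf, `[[`, "y")))
    df <- df[order(df$TRACK_ID, df$POSITION_T), ]
    frame0 <- stats::ave(df$POSITION_T, df$TRACK_ID, FUN = min)
    df$FRAME <- as.integer(round((df$POSITION_T - frame0) / cfg$dt))
    tracks <- track_table(df[, c("TRACK_ID", "FRAME", "POSITION_T",
                                 "POSITION_X", "POSITION_Y")],
                          frame_interval = cfg$dt)
  }

  structure(list(snapshots = snapshots, tracks = tracks,
                 n_history = n_history, config = cfg),
            class = "abm_result")
}

#' @export
print.abm_result <- function(x, ...) {
  cat(sprintf("<abm_result> %d snapshots, %s tracks, final agent count %d\n",
              length(x$snapshots),
              if (is.null(x$tracks)) "no" else
                length(unique(x$tracks$TRACK_ID)),
              utils::tail(x$n_history, 1)))
  invisible(x)
}

#' Normalized density profile from agent snapshots
#'
#' Bins agent positions inside a rectangular region of interest,
#' averages the bin counts across snapshots, and normalizes by a
#' baseline areal density so an unbiased ensemble reads 1.  The
#' between-snapshot standard error of each bin is returned for
#' Monte-Carlo-aware comparisons.
#'
#' @param result An `abm_result` (or a list of snapshot data frames).
#' @param axis `"y"` (bins from the interface wall, averaging over the x
#'   band) or `"x"`.
#' @param band `c(lo, hi)` um on the orthogonal axis.
#' @param extent `c(lo, hi)` um along the profile axis.
#' @param bin_width Bin width, um.
#' @param baseline Baseline areal density (agents/um^2); default is the
#'   per-snapshot mean density over the whole window, so normalization
#'   tracks the realised agent count.
#' @return A `density_profile` with an extra `se` column.
#' @export
density_from_agents <- function(result, axis = c("y", "x"),
                                band = c(0, 50), extent = c(0, 200),
                                bin_width = 10, baseline = NULL) {
  axis <- match.arg(axis)
  snaps <- if (inherits(result, "abm_result")) result$snapshots else result
  if (length(snaps) == 0L) stop("no snapshots to bin")
  cfg <- if (inherits(result, "abm_result")) result$config else NULL
  breaks <- seq(extent[1], extent[2], by = bin_width)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin_area <- bin_width * diff(band)

  per_snap <- vapply(snaps, function(sn) {
    if (axis == "y") {
      sel <- sn$x_um >= band[1] & sn$x_um <= band[2]
      coord <- sn$y_um[sel]
    } else {
      sel <- sn$y_um >= band[1] & sn$y_um <= band[2]
      coord <- sn$x_um[sel]
    }
    inside <- coord >= extent[1] & coord <= extent[2]
    bin <- clamp_int(findInterval(coord[inside], breaks,
                                  rightmost.closed = TRUE),
                     1L, length(mids))
    counts <- tabulate(bin, nbins = length(mids))
    base <- if (!is.null(baseline)) baseline else
      nrow(sn) / (diff(cfg$domain_x) * diff(cfg$domain_y))
    counts / bin_area / base
  }, numeric(length(mids)))
  per_snap <- matrix(per_snap, nrow = length(mids))

  m <- rowMeans(per_snap)
  se <- apply(per_snap, 1, stats::sd) / sqrt(ncol(per_snap))
  out <- density_profile(mids, m, axis = axis, band = band)
  out$se <- se
  out
}

#' Grid-scan calibration of the baseline reversal frequency
#'
#' Runs the ABM over a grid of p0 values (each with `replicates` fresh
#' seeds), scores the mean squared difference between the resulting
#' near-interface profile and the target profile, and returns the
#' minimising grid point.  A relative SSE range below 1% across the grid
#' is flagged unidentifiable.
#'
#' @param target A `density_profile` (e.g. from the continuum model or
#'   from observations).
#' @param p0_grid Candidate baseline reversal frequencies, 1/s.
#' @param cfg Template [abm_config()]; `p0` and `seed` are overridden.
#' @param attractant Steady attractant field for the runs.
#' @param replicates Seeded replicate runs per grid point.
#' @param seed Base seed; replicate r of grid point k runs with seed
#'   `seed + 1000 k + r`.
#' @return List: `p0_hat`, `sse_table` (data frame), `flags`.
#' @export
fit_p0 <- function(target, p0_grid = c(0.05, 0.1, 0.2, 0.5, 1.0),
                   cfg = abm_config(), attractant = NULL,
                   replicates = 2, seed = 1L) {
  flow <- flow_profile(cfg$velocity_m_d)
  sse <- vapply(seq_along(p0_grid), function(k) {
    mean(vapply(seq_len(replicates), function(r) {
      cfg_k <- cfg
      cfg_k$p0 <- p0_grid[k]
      cfg_k$seed <- as.integer(seed + 1000L * k + r)
      res <- run_abm(cfg_k, attractant, flow)
      prof <- density_from_agents(res, axis = attr(target, "axis"),
                                  band = attr(target, "band"),
                                  extent = range(target$coord_um) +
                                    c(-1, 1) * 1e-9)
      pred <- stats::approx(prof$coord_um, prof$density,
                            xout = target$coord_um, rule = 2)$y
      sum((pred - target$density)^2)
    }, numeric(1)))
  }, numeric(1))
  flags <- character(0)
  if (diff(range(sse)) < 0.01 * max(sse)) flags <- c(flags, "unidentifiable")
  k <- which.min(sse)
  if (k == 1L || k == length(p0_grid)) flags <- c(flags, "at_bound")
  list(p0_hat = p0_grid[k],
       sse_table = data.frame(p0 = p0_grid, sse = sse),
       flags = flags)
}
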