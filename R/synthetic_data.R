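#' Synthetic noisy density-profile fixtures
#'
#' Pseudo-experimental normalized density profiles: the continuum
#' solution at a known chi_o plus independent Gaussian noise per point
#' and replicate, emulating the triplicate microscopy profiles (their
#' replicate scatter is available only graphically, so its magnitude is a
#' parameter, default 0.05 normalized-density units).
#'
#' @param true_chi Generative chi_o, cm^2/s (0 for the nonchemotactic
#'   control).
#' @param velocity_m_d Mean velocity, m/d.
#' @param noise_sd Per-point Gaussian noise sd (normalized-density
#'   units).
#' @param n_replicates Number of replicates.
#' @param seed RNG seed.
#' @param axes Profile axes to generate.
#' @param geom,grid,base_params Forwarded to [simulate_profiles()].
#' @param attractant Optional precomputed attractant field.
#' @return List: `replicates` (list of per-replicate axis-named profile
#'   lists), `mean` (replicate-averaged profiles with per-point sd),
#'   `truth` (list of the noiseless profiles and generative parameters).
#' @export
make_profile_fixtures <- function(true_chi, velocity_m_d, noise_sd = 0.05,
                                  n_replicates = 3, seed = 1L,
                                  axes = c("y", "x"),
                                  geom = channel_geometry(),
                                  grid = make_grid(geom),
                                  base_params = chemotaxis_params(),
                                  attractant = NULL) {
  stopifnot(noise_sd >= 0, n_replicates >= 1)
  clean <- simulate_profiles(true_chi, velocity_m_d, axes = axes,
                             geom = geom, grid = grid,
                             base_params = base_params,
                             attractant = attractant)
  set.seed(seed)
  reps <- lapply(seq_len(n_replicates), function(r) {
    stats::setNames(lapply(axes, function(ax) {
      p <- clean[[ax]]
      noisy <- pmax(p$density + stats::rnorm(nrow(p), 0, noise_sd), 0)
      density_profile(p$coord_um, noisy, axis = ax, band = attr(p, "band"))
    }), axes)
  })
  avg <- stats::setNames(lapply(axes, function(ax) {
    mat <- vapply(reps, function(r) r[[ax]]$density,
                  numeric(nrow(clean[[ax]])))
    mat <- matrix(mat, ncol = n_replicates)
    density_profile(clean[[ax]]$coord_um, rowMeans(mat), axis = ax,
                    band = attr(clean[[ax]], "band"),
                    sd = apply(mat, 1, stats::sd))
  }), axes)
  list(replicates = reps, mean = avg,
       truth = list(profiles = clean, chi_o = true_chi,
                    velocity_m_d = velocity_m_d, noise_sd = noise_sd,
                    seed = seed))
}

#' Synthetic TrackMate-style track fixtures
#'
#' Runs the agent-based model, resamples each agent trajectory at the
#' videomicroscopy frame interval (50 ms; linear interpolation between
#' the 0.1-s simulation steps) for `n_frames` frames, and adds Gaussian
#' localization noise to the positions, emulating 20x phase-contrast
#' imaging plus particle linking.
#'
#' @param cfg An [abm_config()]; `record_tracks` is forced on.
#' @param attractant Optional attractant field for the run.
#' @param localization_sd Position noise sd, um (default 0.2).
#' @param n_frames Frames per track (default 100).
#' @param frame_interval Frame interval, s (default 0.05).
#' @param seed Seed for the localization noise (the ABM uses
#'   `cfg$seed`).
#' @param max_tracks Keep at most this many (longest-first) tracks.
#' @return A `track_table`.
#' @export
make_track_fixtures <- function(cfg, attractant = NULL,
                                localization_sd = 0.2,
                                n_frames = 100, frame_interval = 0.05,
                                seed = cfg$seed + 1L, max_tracks = 500) {
  cfg$record_tracks <- TRUE
  res <- run_abm(cfg, attractant)
  raw <- res$tracks
  if (is.null(raw)) stop("ABM produced no tracks; increase duration past burn_in")
  parts <- split(as.data.frame(raw), raw$TRACK_ID)
  lens <- vapply(parts, nrow, integer(1))
  parts <- parts[order(-lens)][seq_len(min(max_tracks, length(parts)))]

  set.seed(seed)
  out <- lapply(parts, function(p) {
    t0 <- p$POSITION_T[1]
    t_new <- t0 + (seq_len(n_frames) - 1L) * frame_interval
    t_new <- t_new[t_new <= max(p$POSITION_T)]
    if (length(t_new) < 2L) return(NULL)
    data.frame(
      TRACK_ID = p$TRACK_ID[1],
      FRAME = seq_along(t_new) - 1L,
      POSITION_T = t_new - t0,
      POSITION_X = stats::approx(p$POSITION_T, p$POSITION_X, t_new)$y +
        stats::rnorm(length(t_new), 0, localization_sd),
      POSITION_Y = stats::approx(p$POSITION_T, p$POSITION_Y, t_new)$y +
        stats::rnorm(length(t_new), 0, localization_sd))
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  track_table(out, frame_interval = frame_interval)
}

#' Generate a full synthetic experiment bundle on disk
#'
#' Writes, for each velocity and each of the three experimental
#' conditions (chemotactic bacteria with naphthalene, chemotactic
#' bacteria without naphthalene, nonchemotactic bacteria with
#' naphthalene), triplicate x- and y-density profiles, plus per-velocity
#' track tables, and a JSON manifest recording every generative
#' parameter so each fixture is reproducible from (manifest, seed)
#' alone.  Control conditions carry no chemotactic drift, so their
#' expected profile is 1 everywhere.
#'
#' @param dir Target directory.
#' @param seed Master seed; per-file seeds are derived deterministically
#'   from it.
#' @param velocities Velocities (m/d).
#' @param true_chi Generative chi_o for the chemotactic + naphthalene
#'   condition, cm^2/s.
#' @param p0_schedule Named vector of baseline reversal frequencies per
#'   velocity for the track fixtures (velocities absent from the names
#'   reuse the smallest value).
#' @param noise_sd Profile noise sd.
#' @param n_replicates Replicates per condition.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param tracks Also generate ABM track fixtures (slower).
#' @param track_duration ABM duration for track fixtures, s.
#' @param geom,grid Geometry and solver grid.
#' @return The manifest, invisibly (also written to
#'   `dir/manifest.json`).
#' @export
make_experiment_bundle <- function(dir, seed = 1L,
                                   velocities = c(0.5, 1, 5, 10),
                                   true_chi = 7.2e-5,
                                   p0_schedule = c(`0.5` = 0.5, `1` = 0.2,
                                                   `5` = 0.1, `10` = 0.1),
                                   noise_sd = 0.05, n_replicates = 3,
                                   overwrite = FALSE, tracks = TRUE,
                                   track_duration = 40,
                                   geom = channel_geometry(),
                                   grid = make_grid(geom)) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    stop("target directory exists and is not empty; set overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conditions <- c("chemotactic_naphthalene", "chemotactic_control",
                  "nonchemotactic_control")
  manifest <- list(seed = seed, velocities = velocities,
                   true_chi = true_chi, noise_sd = noise_sd,
                   n_replicates = n_replicates, files = list())

  for (vi in seq_along(velocities)) {
    v <- velocities[vi]
    flow <- flow_profile(v, geom)
    attr_field <- solve_attractant_steady(geom, flow, grid = grid)
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      chi <- if (cond == "chemotactic_naphthalene") true_chi else 0
      # controls have no drift (no attractant or no sensing): solved
      # profiles are identically 1, so reuse the zero-chi solve
      fx <- make_profile_fixtures(chi, v, noise_sd = noise_sd,
                                  n_replicates = n_replicates,
                                  seed = seed + 97L * vi + 13L * ci,
                                  geom = geom, grid = grid,
                                  attractant = attr_field)
      for (r in seq_len(n_replicates)) {
        for (ax in names(fx$replicates[[r]])) {
          f <- sprintf("profile_v%s_%s_rep%d_%s.tsv", v, cond, r, ax)
          write_profile(fx$replicates[[r]][[ax]], file.path(dir, f))
          manifest$files[[length(manifest$files) + 1L]] <-
            list(file = f, type = "profile", velocity_m_d = v,
                 condition = cond, replicate = r, axis = ax,
                 true_chi = chi, seed = seed + 97L * vi + 13L * ci)
        }
      }
    }
    if (tracks) {
      p0 <- p0_schedule[as.character(v)]
      if (is.na(p0)) p0 <- min(p0_schedule)
      cfg <- abm_config(velocity_m_d = v, p0 = unname(p0),
                        duration = track_duration,
                        burn_in = track_duration / 2,
                        seed = seed + 7L * vi)
      tt <- make_track_fixtures(cfg, attractant = attr_field,
                                seed = seed + 7L * vi + 1L)
      f <- sprintf("tracks_v%s.tsv", v)
      write_tracks(tt, file.path(dir, f))
      manifest$files[[length(manifest$files) + 1L]] <-
        list(file = f, type = "tracks", velocity_m_d = v,
             condition = "no_attractant_gradient_window",
             true_p0 = unname(p0), seed = cfg$seed)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
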