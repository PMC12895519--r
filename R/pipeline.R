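#' Pipeline configuration
#'
#' One structured configuration drives every stage: geometry, physics
#' (attractant and bacterial parameters, per-velocity p0 schedule),
#' velocity list, ABM settings, fitting settings, fixture settings, a
#' master seed and an output directory.  Per-stage seeds are derived
#' deterministically from the master seed (`seed + 1000 * stage index`)
#' so stages can be rerun in isolation.
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @param velocities Velocities, m/d.
#' @param geometry [channel_geometry()].
#' @param attractant [attractant_params()].
#' @param bacteria [chemotaxis_params()].
#' @param p0_schedule Named per-velocity baseline reversal frequencies,
#'   1/s.
#' @param abm An [abm_config()] template.
#' @param fit List of [fit_chi()] settings (`bounds`, `n_grid`).
#' @param fixtures List of fixture settings (`noise_sd`,
#'   `n_replicates`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("napltaxis_"),
                            velocities = c(0.5, 1, 5, 10),
                            geometry = channel_geometry(),
                            attractant = attractant_params(),
                            bacteria = chemotaxis_params(),
                            p0_schedule = c(`0.5` = 0.5, `1` = 0.2,
                                            `5` = 0.1, `10` = 0.1),
                            abm = abm_config(),
                            fit = list(bounds = c(1e-7, 1e-3), n_grid = 11),
                            fixtures = list(noise_sd = 0.05,
                                            n_replicates = 3)) {
  structure(list(seed = as.integer(seed), outdir = outdir,
                 velocities = velocities, geometry = geometry,
                 attractant = attractant, bacteria = bacteria,
                 p0_schedule = p0_schedule, abm = abm, fit = fit,
                 fixtures = fixtures),
            class = "pipeline_config")
}

pipeline_stages <- c("simulate-attractant", "simulate-continuum",
                     "extract-profiles", "fit-chi", "run-abm", "fit-p0",
                     "analyze-tracks", "make-fixtures")

stage_seed <- function(config, stage) {
  config$seed + 1000L * match(stage, pipeline_stages)
}

#' Run one pipeline stage
#'
#' Dispatches a named stage on a [pipeline_config()], writes its outputs
#' under `config$outdir/<stage>/` together with a JSON run record (stage,
#' seed, timestamp, package version), and returns the outputs.  Stages
#' that need upstream results accept them via `inputs` or recompute
#' them.
#'
#' @param stage One of `r paste(pipeline_stages, collapse = ", ")`.
#' @param config A [pipeline_config()].
#' @param inputs Optional named list of upstream outputs (e.g.
#'   `attractant`, `continuum`).
#' @return Named list of stage outputs (stage-specific).
#' @export
run_stage <- function(stage, config = pipeline_config(), inputs = list()) {
  if (!stage %in% pipeline_stages) {
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(pipeline_stages, collapse = ", "))
  }
  stage_dir <- file.path(config$outdir, stage)
  dir.create(stage_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config$geometry
  grid <- make_grid(geom)
  sseed <- stage_seed(config, stage)

  get_attractant <- function() {
    if (!is.null(inputs$attractant)) return(inputs$attractant)
    stats::setNames(lapply(config$velocities, function(v) {
      solve_attractant_steady(geom, flow_profile(v, geom),
                              config$attractant, grid = grid)
    }), as.character(config$velocities))
  }
  get_continuum <- function() {
    if (!is.null(inputs$continuum)) return(inputs$continuum)
    af <- get_attractant()
    stats::setNames(lapply(config$velocities, function(v) {
      solve_bacteria_steady(geom, flow_profile(v, geom),
                            af[[as.character(v)]], config$bacteria)
    }), as.character(config$velocities))
  }

  out <- switch(stage,
    "simulate-attractant" = {
      af <- get_attractant()
      for (v in names(af)) {
        write_field(af[[v]], file.path(stage_dir, sprintf("attractant_v%s.tsv", v)))
      }
      list(attractant = af)
    },
    "simulate-continuum" = {
      bf <- get_continuum()
      for (v in names(bf)) {
        write_field(bf[[v]], file.path(stage_dir, sprintf("bacteria_v%s.tsv", v)))
      }
      list(continuum = bf)
    },
    "extract-profiles" = {
      bf <- get_continuum()
      profs <- lapply(bf, function(b) {
        list(y = extract_profile(b, "y"), x = extract_profile(b, "x"))
      })
      for (v in names(profs)) {
        write_profile(profs[[v]]$y, file.path(stage_dir, sprintf("profile_v%s_y.tsv", v)))
        write_profile(profs[[v]]$x, file.path(stage_dir, sprintf("profile_v%s_x.tsv", v)))
      }
      list(profiles = profs)
    },
    "fit-chi" = {
      observed <- inputs$observed
      if (is.null(observed)) stop("fit-chi needs inputs$observed: a named-by-velocity list of profile sets")
      fits <- lapply(names(observed), function(v) {
        fit_chi(observed[[v]], as.numeric(v), base_params = config$bacteria,
                bounds = config$fit$bounds, n_grid = config$fit$n_grid,
                geom = geom, grid = grid)
      })
      names(fits) <- names(observed)
      for (v in names(fits)) {
        jsonlite::write_json(
          list(velocity_m_d = as.numeric(v), chi_o_hat = fits[[v]]$chi_o_hat,
               sse = fits[[v]]$sse, flags = fits[[v]]$flags,
               trace = fits[[v]]$search_trace),
          file.path(stage_dir, sprintf("fit_v%s.json", v)),
          auto_unbox = TRUE, digits = NA)
      }
      list(fits = fits)
    },
    "run-abm" = {
      af <- get_attractant()
      runs <- stats::setNames(lapply(config$velocities, function(v) {
        cfg <- config$abm
        cfg$velocity_m_d <- v
        p0 <- config$p0_schedule[as.character(v)]
        if (!is.na(p0)) cfg$p0 <- unname(p0)
        cfg$seed <- sseed + round(10 * v)
        run_abm(cfg, af[[as.character(v)]], flow_profile(v, geom))
      }), as.character(config$velocities))
      for (v in names(runs)) {
        prof <- density_from_agents(runs[[v]])
        write_profile(prof, file.path(stage_dir, sprintf("abm_profile_v%s_y.tsv", v)))
      }
      list(abm = runs)
    },
    "fit-p0" = {
      target <- inputs$target
      if (is.null(target)) stop("fit-p0 needs inputs$target: a density_profile")
      af <- get_attractant()
      v <- if (!is.null(inputs$velocity)) inputs$velocity else config$velocities[1]
      cfg <- config$abm
      cfg$velocity_m_d <- v
      fit <- fit_p0(target, cfg = cfg, attractant = af[[as.character(v)]],
                    seed = sseed)
      jsonlite::write_json(fit[c("p0_hat", "flags")],
                           file.path(stage_dir, "fit_p0.json"),
                           auto_unbox = TRUE, digits = NA)
      list(fit_p0 = fit)
    },
    "analyze-tracks" = {
      tracks <- inputs$tracks
      if (is.null(tracks)) stop("analyze-tracks needs inputs$tracks: a named-by-velocity list of track_tables")
      stats_out <- lapply(tracks, function(tt) {
        s <- y_velocity_samples(tt)
        list(summary = velocity_distribution_summary(s),
             alignment = alignment_index(tt))
      })
      tab <- data.frame(
        velocity_m_d = as.numeric(names(tracks)),
        mean_abs_vy = vapply(stats_out, function(s) s$summary$mean, numeric(1)),
        alignment = vapply(stats_out, function(s) s$alignment, numeric(1)))
      utils::write.table(tab, file.path(stage_dir, "track_stats.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(track_stats = tab, details = stats_out)
    },
    "make-fixtures" = {
      manifest <- make_experiment_bundle(
        file.path(stage_dir, "bundle"), seed = sseed,
        velocities = config$velocities,
        true_chi = config$bacteria$chi_o,
        p0_schedule = config$p0_schedule,
        noise_sd = config$fixtures$noise_sd,
        n_replicates = config$fixtures$n_replicates,
        tracks = !isFALSE(config$fixtures$tracks),
        overwrite = TRUE, geom = geom, grid = grid)
      list(manifest = manifest)
    })

  record <- list(stage = stage, seed = sseed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 package_version = as.character(utils::packageVersion("napltaxis")))
  jsonlite::write_json(record, file.path(stage_dir, "run_record.json"),
                       auto_unbox = TRUE)
  out
}

#' Velocity-dependent apparent chemotactic sensitivity
#'
#' The fitted chemotactic sensitivity falls with flow velocity: the full
#' 7.2e-5 cm^2/s at 0.5 m/d, half that at 1 m/d, and at least an order
#' of magnitude lower at 5 and 10 m/d (taken as 7.2e-6).  This schedule
#' is the continuum model's operating point for each velocity.
#'
#' @param velocity_m_d Velocity, m/d (one of 0.5, 1, 5, 10, or any other
#'   value, which falls back to the nearest scheduled velocity).
#' @return Apparent chi_o, cm^2/s.
#' @export
apparent_chi <- function(velocity_m_d) {
  sched_v <- c(0.5, 1, 5, 10)
  sched_chi <- c(7.2e-5, 3.6e-5, 7.2e-6, 7.2e-6)
  vapply(velocity_m_d, function(v) {
    sched_chi[which.min(abs(sched_v - v))]
  }, numeric(1))
}

#' Derived quantities at the study's default parameters
#'
#' Runs the four-velocity continuum sweep at the default parameter set
#' and assembles the derived summary numbers: wall shear rates,
#' interfacial residence times, the single-cell sensitivity display
#' value, near-interface peak densities and accumulation extents, and
#' the p0 schedule used by the agent-based calibrations.
#'
#' @param velocities Velocities, m/d.
#' @param chi_schedule Apparent chi_o per velocity, cm^2/s; defaults to
#'   [apparent_chi()].
#' @param geom,grid Geometry and solver grid.
#' @param include_abm Also run the ABM at each velocity's scheduled p0
#'   and report its near-interface peaks (slower).
#' @param abm_template [abm_config()] template for `include_abm`.
#' @param p0_schedule Per-velocity baseline reversal frequencies.
#' @param seed Seed for the ABM runs.
#' @return List with `table` (one row per velocity) and `sigma_star`.
#' @export
reproduce_paper_defaults <- function(velocities = c(0.5, 1, 5, 10),
                                     chi_schedule = apparent_chi(velocities),
                                     geom = channel_geometry(),
                                     grid = make_grid(geom),
                                     include_abm = FALSE,
                                     abm_template = abm_config(),
                                     p0_schedule = c(`0.5` = 0.5, `1` = 0.2,
                                                     `5` = 0.1, `10` = 0.1),
                                     seed = 1L) {
  rows <- lapply(seq_along(velocities), function(k) {
    v <- velocities[k]
    flow <- flow_profile(v, geom)
    af <- solve_attractant_steady(geom, flow, grid = grid)
    bf <- solve_bacteria_steady(geom, flow, af,
                                chemotaxis_params(chi_o = chi_schedule[k]))
    py <- extract_profile(bf, "y")
    px <- extract_profile(bf, "x")
    ext <- accumulation_extent(px, 1.05)
    data.frame(
      velocity_m_d = v,
      chi_o = chi_schedule[k],
      shear_rate_s = wall_shear_rate(v, geom$depth),
      residence_s = interfacial_residence_time(geom$interface_width, v)$seconds,
      residence_display_s = interfacial_residence_time(geom$interface_width, v)$display,
      peak_density_y = max(py$density[py$coord_um <= 50]),
      accumulation_lo = if (is.null(ext)) NA_real_ else ext[1],
      accumulation_hi = if (is.null(ext)) NA_real_ else ext[2],
      plume_extent_um = plume_extent_y(af, geom))
  })
  tab <- do.call(rbind, rows)
  if (include_abm) {
    tab$p0 <- unname(p0_schedule[as.character(velocities)])
    tab$abm_peak_y <- vapply(seq_along(velocities), function(k) {
      v <- velocities[k]
      cfg <- abm_template
      cfg$velocity_m_d <- v
      cfg$p0 <- tab$p0[k]
      cfg$seed <- as.integer(seed + k)
      af <- solve_attractant_steady(geom, flow_profile(v, geom), grid = grid)
      res <- run_abm(cfg, af)
      prof <- density_from_agents(res)
      max(prof$density[prof$coord_um <= 50])
    }, numeric(1))
  }
  list(table = tab,
       sigma_star = sigma_star_from_chi(chemotaxis_params()$chi_o, 44))
}
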