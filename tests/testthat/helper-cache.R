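# Shared fixtures: the PDE solves and ABM runs are deterministic given
# their configuration, so expensive objects are computed once per test
# session and memoised here.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

test_geom <- function() cached("geom", channel_geometry())
test_grid <- function() cached("grid", make_grid(test_geom()))

test_attractant <- function(v) {
  cached(paste0("attr_", v), {
    solve_attractant_steady(test_geom(), flow_profile(v, test_geom()),
                            grid = test_grid())
  })
}

test_bacteria <- function(v, chi = 7.2e-5) {
  cached(paste0("bact_", v, "_", chi), {
    solve_bacteria_steady(test_geom(), flow_profile(v, test_geom()),
                          test_attractant(v),
                          chemotaxis_params(chi_o = chi))
  })
}

# full-size ABM run at the 0.5 m/d attractant field
test_abm_run <- function(p0, seed = 101) {
  cached(paste0("abm_", p0, "_", seed), {
    cfg <- abm_config(velocity_m_d = 0.5, p0 = p0, seed = seed)
    run_abm(cfg, test_attractant(0.5), flow_profile(0.5, test_geom()))
  })
}

# chi_o surrogate simulator at one velocity (y-profile only), shared by
# the fitting tests
test_surrogate <- function(v) {
  cached(paste0("surr_", v), {
    make_chi_surrogate(v, n_nodes = 17, axes = "y", geom = test_geom(),
                       grid = test_grid())
  })
}

# straight-line synthetic tracks with given headings/speeds (oracle
# fixture builder used by the track statistics tests)
straight_tracks <- function(headings, speed = 44, n_frames = 20,
                            dt = 0.05) {
  dfs <- lapply(seq_along(headings), function(k) {
    tt <- (seq_len(n_frames) - 1L) * dt
    data.frame(TRACK_ID = k, FRAME = seq_len(n_frames) - 1L,
               POSITION_T = tt,
               POSITION_X = speed * cos(headings[k]) * tt,
               POSITION_Y = speed * sin(headings[k]) * tt)
  })
  track_table(do.call(rbind, dfs), frame_interval = dt)
}
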