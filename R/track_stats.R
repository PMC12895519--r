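#' Particle-track tables
#'
#' Minimal TrackMate-export-compatible container for per-frame particle
#' positions: columns `TRACK_ID`, `FRAME`, `POSITION_T` (s),
#' `POSITION_X`, `POSITION_Y` (um).  Within each track, frames must be
#' strictly increasing and times consistent with the frame interval.
#'
#' @param df Data frame with the columns above (extra columns are kept).
#' @param frame_interval Frame interval, s.
#' @return A `track_table` data frame.
#' @export
track_table <- function(df, frame_interval = 0.05) {
  need <- c("TRACK_ID", "FRAME", "POSITION_T", "POSITION_X", "POSITION_Y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory track columns: ", paste(miss, collapse = ", "))
  }
  if (!all(is.finite(df$POSITION_X)) || !all(is.finite(df$POSITION_Y))) {
    stop("non-finite track coordinates")
  }
  ord <- order(df$TRACK_ID, df$FRAME)
  df <- df[ord, , drop = FALSE]
  same <- duplicated(df$TRACK_ID)
  if (any(same & c(FALSE, diff(df$FRAME) <= 0)[seq_len(nrow(df))])) {
    stop("frame indices must be strictly increasing within each track")
  }
  rownames(df) <- NULL
  structure(df, frame_interval = frame_interval,
            class = c("track_table", "data.frame"))
}

#' Read and write particle tracks as delimited text
#'
#' Tab-separated with header; `read_tracks` validates the mandatory
#' columns, reports malformed rows by line number, and preserves unknown
#' extra columns.
#'
#' @param path File path.
#' @param frame_interval Frame interval, s (stored as an attribute).
#' @param tracks A `track_table`.
#' @return `read_tracks` a `track_table`; `write_tracks` the path,
#'   invisibly.
#' @export
read_tracks <- function(path, frame_interval = 0.05) {
  if (!file.exists(path)) stop("track file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty track file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  nfield <- lengths(strsplit(lines[-1], "\t", fixed = TRUE))
  bad <- which(nfield != length(header))
  if (length(bad)) {
    stop(sprintf("malformed track row at line %d (expected %d fields, got %d)",
                 bad[1] + 1L, length(header), nfield[bad[1]]))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  track_table(df, frame_interval = frame_interval)
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  utils::write.table(as.data.frame(tracks), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# split a track table into per-track data frames with >= min_frames,
# counting the skipped short tracks
usable_tracks <- function(tracks, min_frames = 2L) {
  parts <- split(as.data.frame(tracks), tracks$TRACK_ID)
  short <- sum(vapply(parts, nrow, integer(1)) < min_frames)
  list(tracks = Filter(function(p) nrow(p) >= min_frames, parts),
       n_skipped = short)
}

#' Per-step velocity components perpendicular to the flow
#'
#' For every consecutive-frame pair of every usable track, the magnitude
#' of the transverse (y) displacement rate `|dy| / dt`; this is the
#' flow-perpendicular swimming-velocity statistic whose distribution
#' narrows as shear aligns trajectories with the flow.  Tracks shorter
#' than two frames are skipped (their count is attached).
#'
#' @param tracks A `track_table`.
#' @param signed Return signed `dy/dt` instead of magnitudes.
#' @return Numeric vector of samples (um/s) with attributes `track_id`
#'   (per-sample provenance) and `n_skipped`.
#' @export
y_velocity_samples <- function(tracks, signed = FALSE) {
  ut <- usable_tracks(tracks)
  dt_nominal <- attr(tracks, "frame_interval")
  samples <- numeric(0); prov <- integer(0)
  for (p in ut$tracks) {
    dframes <- diff(p$FRAME)
    dts <- diff(p$POSITION_T)
    if (any(abs(dts - dframes * dt_nominal) > 1e-6)) {
      stop(sprintf("track %s: frame times inconsistent with frame interval %g s",
                   p$TRACK_ID[1], dt_nominal))
    }
    v <- diff(p$POSITION_Y) / dts
    keep <- dframes == 1L  # only consecutive-frame pairs
    samples <- c(samples, v[keep])
    prov <- c(prov, rep(p$TRACK_ID[1], sum(keep)))
  }
  if (!signed) samples <- abs(samples)
  structure(samples, track_id = prov, n_skipped = ut$n_skipped)
}

#' Summary of a velocity-sample distribution
#'
#' Mean, quantiles and a kernel-density curve of the transverse velocity
#' samples, the ingredients of a violin-style display.
#'
#' @param samples Numeric samples (>= 10), e.g. from
#'   [y_velocity_samples()].
#' @param probs Quantile probabilities.
#' @param n_density Number of kernel-density grid points.
#' @return List: `mean`, `quantiles`, `density` (data frame `v`, `d`),
#'   `n`.
#' @export
velocity_distribution_summary <- function(samples,
                                          probs = c(.05, .25, .5, .75, .95),
                                          n_density = 128) {
  if (length(samples) < 10L) stop("need at least 10 velocity samples")
  dens <- if (stats::sd(samples) > 0) {
    d <- stats::density(as.numeric(samples), n = n_density)
    data.frame(v = d$x, d = d$y)
  } else {
    data.frame(v = samples[1], d = Inf)
  }
  list(mean = mean(samples),
       quantiles = stats::quantile(as.numeric(samples), probs),
       density = dens,
       n = length(samples))
}

#' Flow-alignment index of trajectories
#'
#' Mean of |cos(theta)| over per-step displacement directions theta
#' measured from the flow (x) axis: 2/pi (about 0.637) for isotropic
#' motion, 1 for perfectly flow-aligned displacement.  Zero-length
#' displacements are skipped.
#'
#' @param tracks A `track_table`.
#' @return Scalar in `[0, 1]`.
#' @export
alignment_index <- function(tracks) {
  ut <- usable_tracks(tracks)
  num <- 0; n <- 0L
  for (p in ut$tracks) {
    dx <- diff(p$POSITION_X); dy <- diff(p$POSITION_Y)
    len <- sqrt(dx^2 + dy^2)
    ok <- len > 0
    num <- num + sum(abs(dx[ok]) / len[ok])
    n <- n + sum(ok)
  }
  if (n == 0L) stop("no nonzero displacements")
  num / n
}

#' Mean squared displacement of a track ensemble
#'
#' Ensemble-averaged MSD over lag times, using only tracks long enough
#' for the requested lag; the standard diagnostic for the
#' ballistic-to-diffusive crossover of run-reverse motility (crossover
#' near the mean run time 1/p0, long-time slope 4 D_eff in 2-D).
#'
#' @param tracks A `track_table`.
#' @param max_lag_frames Largest lag (frames).
#' @param lags Optional explicit lag set (frames), e.g. log-spaced for
#'   long runs; defaults to every lag up to `max_lag_frames`.
#' @return Data frame `lag_s`, `msd_um2`, `n_pairs`.
#' @export
track_msd <- function(tracks, max_lag_frames = 50L,
                      lags = seq_len(max_lag_frames)) {
  ut <- usable_tracks(tracks)
  dt <- attr(tracks, "frame_interval")
  lags <- sort(unique(as.integer(lags)))
  nl <- length(lags)
  acc <- numeric(nl); cnt <- integer(nl)
  for (p in ut$tracks) {
    np <- nrow(p)
    for (k in seq_len(nl)) {
      L <- lags[k]
      if (np <= L) break
      i <- seq_len(np - L)
      d2 <- (p$POSITION_X[i + L] - p$POSITION_X[i])^2 +
        (p$POSITION_Y[i + L] - p$POSITION_Y[i])^2
      acc[k] <- acc[k] + sum(d2)
      cnt[k] <- cnt[k] + length(d2)
    }
  }
  ok <- cnt > 0
  data.frame(lag_s = lags[ok] * dt, msd_um2 = acc[ok] / cnt[ok],
             n_pairs = cnt[ok])
}
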