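#' Great-circle distance (Haversine)
#'
#' Haversine distance on a sphere of radius 6371 km, the convention used
#' throughout the track-segmentation machinery. Vectorised and symmetric.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 360)) {
    stop("invalid coordinates")
  }
  r <- pi / 180
  dphi <- (lat2 - lat1) * r / 2
  dlam <- (lon2 - lon1) * r / 2
  a <- sin(dphi)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlam)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Diameter of a set of GPS points
#'
#' Maximum pairwise great-circle distance, which equals the diameter of the
#' convex hull of the point set. Used as the windowed movement signal for
#' run/rest segmentation.
#'
#' @param lat,lon Coordinate vectors (>= 1 point).
#' @return Diameter in kilometres (0 for a single point).
#' @export
window_diameter <- function(lat, lon) {
  m <- length(lat)
  if (m == 0) stop("empty point set")
  if (m == 1) return(0)
  pts <- unique(cbind(lat, lon))
  m <- nrow(pts)
  if (m == 1) return(0)
  i <- rep(seq_len(m - 1), times = (m - 1):1)
  j <- sequence((m - 1):1) + i
  max(haversine_km(pts[i, 1], pts[i, 2], pts[j, 1], pts[j, 2]))
}

#' Segmentation settings for coarse GPS tracks
#'
#' Defaults follow the gull analysis: a 24 h sliding window whose convex-hull
#' diameter is evaluated 10 times per day and thresholded at 52 km, with
#' resting phases shorter than 2 days discarded (relabelled as running).
#'
#' @param window_hours Window length (h).
#' @param samples_per_day Signal evaluations per day.
#' @param threshold_km Diameter below which the window is "resting".
#' @param min_rest_days Shortest retained resting phase (days).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(window_hours = 24, samples_per_day = 10,
                                threshold_km = 52, min_rest_days = 2) {
  stopifnot(window_hours > 0, samples_per_day > 0, threshold_km > 0,
            min_rest_days > 0)
  structure(list(window_days = window_hours / 24,
                 samples_per_day = samples_per_day,
                 threshold_km = threshold_km,
                 min_rest_days = min_rest_days),
            class = "segmentation_config")
}

# track time in days: numeric `t` column taken as days since a midnight;
# POSIXct timestamps are converted relative to the first UTC midnight.
track_days <- function(track) {
  if ("t" %in% names(track)) return(as.numeric(track$t))
  if ("timestamp" %in% names(track)) {
    ts <- as.POSIXct(track$timestamp, tz = "UTC")
    day0 <- as.POSIXct(format(min(ts), "%Y-%m-%d"), tz = "UTC")
    return(as.numeric(difftime(ts, day0, units = "days")))
  }
  stop("track needs a numeric 't' (days) or a 'timestamp' column")
}

#' Segment a coarse GPS track into running and resting phases
#'
#' Computes the windowed convex-hull-diameter signal on a regular grid of
#' `samples_per_day` evaluation times per day (anchored at the track's first
#' midnight), thresholds it, and returns maximal alternating phases. Resting
#' phases shorter than `min_rest_days` are relabelled as running and merged
#' into their neighbours. Boundary windows (within half a window of either
#' end of the record) use the available points only.
#'
#' @param track Data frame with `lat`, `lon` and either `t` (days) or
#'   `timestamp` (POSIXct, UTC) columns; a single track.
#' @param cfg A [segmentation_config()].
#' @return Data frame with columns `state`, `t_start`, `t_end` (days);
#'   the thresholded signal is attached as attribute `"signal"`.
#' @export
segment_track <- function(track, cfg = segmentation_config()) {
  stopifnot(inherits(cfg, "segmentation_config"))
  tt <- track_days(track)
  o <- order(tt)
  tt <- tt[o]; lat <- track$lat[o]; lon <- track$lon[o]
  if (any(diff(tt) <= 0)) stop("timestamps must be strictly increasing")
  span <- tt[length(tt)] - tt[1]
  if (span < cfg$window_days) stop("track is shorter than the signal window")
  half <- cfg$window_days / 2
  step <- 1 / cfg$samples_per_day
  te <- seq(ceiling(tt[1] / step) * step, tt[length(tt)], by = step)
  lo <- findInterval(te - half, tt) + 1L  # first index with tt >= te - half
  lo[lo < 1] <- 1L
  hi <- findInterval(te + half, tt)       # last index with tt <= te + half
  sig <- numeric(length(te))
  for (k in seq_along(te)) {
    sig[k] <- if (hi[k] >= lo[k]) {
      window_diameter(lat[lo[k]:hi[k]], lon[lo[k]:hi[k]])
    } else NA_real_
  }
  ok <- !is.na(sig)
  te <- te[ok]; sig <- sig[ok]
  lab <- ifelse(sig < cfg$threshold_km, "rest", "run")
  r <- rle(lab)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1) + 1L)
  # phase boundaries at midpoints between adjacent evaluation times
  t_start <- ifelse(starts_idx == 1L, tt[1],
                    (te[starts_idx] + te[pmax(starts_idx - 1L, 1L)]) / 2)
  t_end <- ifelse(ends_idx == length(te), tt[length(tt)],
                  (te[ends_idx] + te[pmin(ends_idx + 1L, length(te))]) / 2)
  ph <- data.frame(state = r$values, t_start = t_start, t_end = t_end)
  # discard short rests, then merge adjacent runs
  short <- ph$state == "rest" & (ph$t_end - ph$t_start) < cfg$min_rest_days
  ph$state[short] <- "run"
  r2 <- rle(ph$state)
  e2 <- cumsum(r2$lengths); s2 <- c(1L, utils::head(e2, -1) + 1L)
  out <- data.frame(state = r2$values,
                    t_start = ph$t_start[s2],
                    t_end = ph$t_end[e2])
  attr(out, "signal") <- data.frame(t = te, diameter = sig, state = lab)
  out
}

#' Phase statistics from a finely sampled labelled track
#'
#' Extracts run/rest durations, per-run speeds and headings, turn angles
#' between consecutive runs, and the state at `t = 0` from a track whose
#' samples carry state labels (e.g. microscopy tracks annotated up front).
#' Durations are maximal constant-state sample stretches times the sampling
#' interval. The final phase is right-censored by the end of the record and
#' is never included in the duration lists; the first phase is also censored
#' (the track starts mid-phase) but is kept by default since the error it
#' introduces is small — set `truncate_first_phase = TRUE` to drop it.
#'
#' @param track Data frame with columns `t`, `x`, `y`, `state` for a single
#'   track, sampled on a regular grid.
#' @param truncate_first_phase Drop the (censored) first phase's duration?
#' @return List with `run_durations`, `rest_durations`, `run_speeds`,
#'   `turn_angles` (radians, between runs separated by one rest),
#'   `initial_state`.
#' @export
extract_phase_stats <- function(track, truncate_first_phase = FALSE) {
  stopifnot(all(c("t", "x", "y", "state") %in% names(track)))
  if (nrow(track) < 2) stop("need at least two samples")
  if (any(diff(track$t) <= 0)) stop("t must be strictly increasing")
  dtm <- stats::median(diff(track$t))
  r <- rle(as.character(track$state))
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1) + 1L)
  durs <- r$lengths * dtm
  n_ph <- length(durs)
  keep <- rep(TRUE, n_ph)
  keep[n_ph] <- FALSE                       # right-censored by record end
  if (truncate_first_phase) keep[1] <- FALSE
  is_run <- r$values == "run"
  # per-run net displacement -> heading and speed (exact for straight runs)
  head_ang <- speed <- rep(NA_real_, n_ph)
  for (i in which(is_run)) {
    a <- starts[i]; b <- ends[i]
    if (b > a) {
      dx <- track$x[b] - track$x[a]; dy <- track$y[b] - track$y[a]
      head_ang[i] <- atan2(dy, dx)
      speed[i] <- sqrt(dx^2 + dy^2) / (track$t[b] - track$t[a])
    }
  }
  run_idx <- which(is_run)
  angles <- numeric(0)
  if (length(run_idx) >= 2) {
    for (k in seq_len(length(run_idx) - 1)) {
      i <- run_idx[k]; j <- run_idx[k + 1]
      if (j - i == 2 && !is.na(head_ang[i]) && !is.na(head_ang[j])) {
        d <- (head_ang[j] - head_ang[i] + pi) %% (2 * pi) - pi
        angles <- c(angles, d)
      }
    }
  }
  list(run_durations = durs[keep & is_run],
       rest_durations = durs[keep & !is_run],
       run_speeds = speed[is_run & !is.na(speed)],
       turn_angles = angles,
       initial_state = r$values[1])
}

# initial great-circle bearing (radians clockwise from north); only bearing
# *differences* at nearly coincident points are used downstream, so the
# convention cancels out of the turn-angle statistics
bearing_rad <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  p1 <- lat1 * r; p2 <- lat2 * r; dl <- (lon2 - lon1) * r
  atan2(sin(dl) * cos(p2),
        cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
}

#' Phase statistics from a segmented GPS track
#'
#' Converts a thresholded segmentation into the quantities the model needs,
#' correcting the systematic boundary bias of windowed thresholding: a rest
#' is only labelled "resting" while most of the 24 h window fits inside it,
#' so each detected rest is labelled shorter than truth by roughly
#' \eqn{\delta \approx W/2 - d_{thr}/s} per side (window length \eqn{W},
#' threshold \eqn{d_{thr}}, adjacent run speed \eqn{s}). With
#' `correct_boundaries` (default) each detected rest's true extent is
#' recovered by position matching: rests are spatially stationary, so the
#' contiguous stretch of fixes within a small radius of the rest's centroid
#' delimits it to within half a fix interval, without any window geometry.
#' Run boundaries follow from the flanking refined rests. Interior run
#' displacements are taken between the centroids of the flanking rests
#' (the run's true endpoints).
#'
#' Turn angles are measured between local fix-to-fix headings just inside
#' the two runs flanking each detected rest, which keeps them exact even
#' when an undetected short rest has merged two true runs elsewhere.
#' Squared speeds for \eqn{S_T^2} are averaged over fix-to-fix segments
#' fully inside corrected runs (time weighting; equivalent to per-run
#' weighting when speed and duration are independent), excluding segments
#' below the detectability speed `threshold/window` — those are almost
#' always missed short rests glued into the observed run.
#'
#' @param track GPS data frame (`lat`, `lon`, `t` or `timestamp`).
#' @param phases Output of [segment_track()] for the same track.
#' @param cfg The [segmentation_config()] used.
#' @param correct_boundaries Refine rest boundaries by position matching?
#' @param truncate_first_phase Drop the censored first phase's duration?
#' @param eps_km Base radius for "at the rest location"; widened
#'   automatically when the fixes in a rest scatter (GPS jitter).
#' @return List with `run_durations`, `rest_durations`, `censored_rest`
#'   (the final phase's duration when it is a rest cut off by the record
#'   end), `run_speeds`, `seg_speeds`, `turn_angles`, `S_T2`,
#'   `initial_state`, `delta_days` (mean per-boundary shift applied) and
#'   `n_phases`.
#' @export
gps_phase_stats <- function(track, phases, cfg = segmentation_config(),
                            correct_boundaries = TRUE,
                            truncate_first_phase = FALSE, eps_km = 2) {
  tt <- track_days(track)
  o <- order(tt); tt <- tt[o]
  lat <- track$lat[o]; lon <- track$lon[o]
  fixdt <- stats::median(diff(tt))
  n_ph <- nrow(phases)
  is_run <- phases$state == "run"
  run_ids <- which(is_run)

  # raw displacement per run phase: between centroids of flanking rests
  # (interior runs) or the run's own extreme fixes (edge runs)
  rest_cent <- matrix(NA_real_, n_ph, 2)
  for (i in which(!is_run)) {
    sel <- tt >= phases$t_start[i] & tt <= phases$t_end[i]
    if (any(sel)) rest_cent[i, ] <- c(mean(lat[sel]), mean(lon[sel]))
  }
  run_disp <- rep(NA_real_, n_ph)
  for (i in run_ids) {
    p1 <- if (i > 1 && !is.na(rest_cent[i - 1, 1])) rest_cent[i - 1, ] else {
      sel <- which(tt >= phases$t_start[i]); c(lat[sel[1]], lon[sel[1]])
    }
    p2 <- if (i < n_ph && !is.na(rest_cent[i + 1, 1])) rest_cent[i + 1, ] else {
      sel <- which(tt <= phases$t_end[i])
      c(lat[sel[length(sel)]], lon[sel[length(sel)]])
    }
    run_disp[i] <- haversine_km(p1[1], p1[2], p2[1], p2[2])
  }

  # refine each detected rest's extent by matching fixes to its centroid;
  # the first/last fix at the rest location brackets the true boundary to
  # within half a fix interval
  n_fix <- length(tt)
  rest_lim <- matrix(NA_real_, n_ph, 2)
  rest_merged <- rep(FALSE, n_ph)
  deltas <- numeric(0)
  if (correct_boundaries) {
    for (i in which(!is_run)) {
      sel <- which(tt >= phases$t_start[i] & tt <= phases$t_end[i])
      if (!length(sel)) next
      dists <- haversine_km(lat, lon, rest_cent[i, 1], rest_cent[i, 2])
      eps <- max(eps_km, 5 * stats::median(dists[sel]))
      j1 <- sel[1]
      while (j1 > 1 && dists[j1 - 1] <= eps) j1 <- j1 - 1
      j2 <- sel[length(sel)]
      while (j2 < n_fix && dists[j2 + 1] <= eps) j2 <- j2 + 1
      s_ref <- if (j1 == 1) tt[1] else tt[j1] - fixdt / 2
      e_ref <- if (j2 == n_fix) tt[n_fix] else tt[j2] + fixdt / 2
      rest_lim[i, ] <- c(s_ref, e_ref)
      # a run too slow to break the diameter threshold welds two rests into
      # one detected rest; its two stationary clusters give it away
      if (length(sel) >= 6) {
        third <- floor(length(sel) / 3)
        i1 <- sel[1:third]
        i2 <- sel[(length(sel) - third + 1):length(sel)]
        c1 <- c(mean(lat[i1]), mean(lon[i1]))
        c2 <- c(mean(lat[i2]), mean(lon[i2]))
        scatter <- max(stats::median(haversine_km(lat[i1], lon[i1],
                                                  c1[1], c1[2])),
                       stats::median(haversine_km(lat[i2], lon[i2],
                                                  c2[1], c2[2])))
        rest_merged[i] <- haversine_km(c1[1], c1[2], c2[1], c2[2]) >
          max(3 * eps_km, 8 * scatter)
      }
      if (!rest_merged[i]) {
        deltas <- c(deltas, (e_ref - s_ref) -
                      (phases$t_end[i] - phases$t_start[i]))
      }
    }
  }
  t_start_c <- phases$t_start
  t_end_c <- phases$t_end
  for (i in which(!is_run)) {
    if (!is.na(rest_lim[i, 1])) {
      t_start_c[i] <- rest_lim[i, 1]; t_end_c[i] <- rest_lim[i, 2]
    }
  }
  for (i in run_ids) {
    if (i > 1 && !is.na(rest_lim[i - 1, 2])) t_start_c[i] <- rest_lim[i - 1, 2]
    if (i < n_ph && !is.na(rest_lim[i + 1, 1])) t_end_c[i] <- rest_lim[i + 1, 1]
  }
  dur <- pmax(t_end_c - t_start_c, 0)

  keep <- rep(TRUE, n_ph)
  keep[n_ph] <- FALSE
  if (truncate_first_phase) keep[1] <- FALSE

  # turn angles from local headings just inside the runs flanking each rest
  margin <- 0.5 * fixdt
  seg_head <- function(j) bearing_rad(lat[j], lon[j], lat[j + 1], lon[j + 1])
  seg_len <- function(j) haversine_km(lat[j], lon[j], lat[j + 1], lon[j + 1])
  angles <- numeric(0)
  speed_floor <- cfg$threshold_km / cfg$window_days
  for (i in which(!is_run)) {
    if (i == 1 || i == n_ph || rest_merged[i]) next
    jin <- which(tt + fixdt <= t_start_c[i] - margin &
                 tt >= t_start_c[i - 1] - 10 * cfg$window_days)
    jin <- jin[jin < length(tt)]
    jin <- rev(jin)[seg_len(rev(jin)) / fixdt >= speed_floor][1]
    jout <- which(tt >= t_end_c[i] + margin & tt + fixdt <= t_end_c[i + 1])
    jout <- jout[jout < length(tt)]
    jout <- jout[seg_len(jout) / fixdt >= speed_floor][1]
    if (!is.na(jin) && !is.na(jout)) {
      d <- (seg_head(jout) - seg_head(jin) + pi) %% (2 * pi) - pi
      angles <- c(angles, d)
    }
  }

  # segment speeds fully inside corrected runs; segments slower than the
  # detectability scale threshold/window are indistinguishable from resting
  # (they are almost always missed short rests glued into the observed run)
  # and are excluded from the speed statistics
  seg_sp <- numeric(0)
  speed_floor <- cfg$threshold_km / cfg$window_days
  for (i in run_ids) {
    j <- which(tt >= t_start_c[i] + margin & tt + fixdt <= t_end_c[i] - margin)
    j <- j[j < length(tt)]
    if (length(j)) {
      sp <- seg_len(j) / diff(tt)[j]
      seg_sp <- c(seg_sp, sp[sp >= speed_floor])
    }
  }

  # split each observed run at its sub-floor stretches: a rest too short to
  # survive the minimum-duration filter is still spatially stationary, so it
  # shows up as consecutive fixes at one location. The resulting pieces are
  # individual true runs; the stretches are the missed rests.
  split_runs <- numeric(0); split_censored <- numeric(0)
  missed_rests <- numeric(0)
  for (i in run_ids) {
    a <- t_start_c[i]; b <- t_end_c[i]
    j <- which(tt >= a - 1e-9 & tt + fixdt <= b + 1e-9)
    j <- j[j < length(tt)]
    if (length(j) < 1) {
      if (i > 1 && i < n_ph && b - a > 0) split_runs <- c(split_runs, b - a)
      next
    }
    dsp <- seg_len(j)
    slow <- (dsp / diff(tt)[j]) < speed_floor
    r3 <- rle(slow)
    e3 <- cumsum(r3$lengths); s3 <- c(1L, utils::head(e3, -1) + 1L)
    piece_start <- ifelse(s3 == 1L, a, tt[j[s3]])
    piece_end <- ifelse(e3 == length(j), b, tt[j[e3] + 1L])
    # sharpen interior stretch boundaries: the bird stops moving at the
    # rest, so the residual displacement of the transition segments over the
    # adjacent run speed locates the transition inside the segment
    np3 <- length(r3$values)
    run_speed_of <- function(k) {           # median speed of run piece k
      sp <- dsp[s3[k]:e3[k]] / diff(tt)[j][s3[k]:e3[k]]
      stats::median(sp[sp >= speed_floor])
    }
    for (k in seq_len(np3)) {
      if (!r3$values[k]) next               # only slow stretches
      if (k > 1) {
        sh <- run_speed_of(k - 1)
        if (is.finite(sh) && sh > 0 && s3[k] > 1) {
          jj <- j[s3[k]]
          trav <- dsp[s3[k] - 1] + dsp[s3[k]]
          bhat <- tt[jj - 1] + min(2 * fixdt, trav / sh)
          piece_end[k - 1] <- min(max(bhat, tt[jj - 1]), tt[jj + 1])
          piece_start[k] <- piece_end[k - 1]
        }
      }
      if (k < np3) {
        sh <- run_speed_of(k + 1)
        if (is.finite(sh) && sh > 0 && e3[k] < length(j)) {
          jj <- j[e3[k]]
          trav <- dsp[e3[k] + 1] + dsp[e3[k]]
          ehat <- tt[jj + 2] - min(2 * fixdt, trav / sh)
          piece_start[k + 1] <- min(max(ehat, tt[jj]), tt[jj + 2])
          piece_end[k] <- piece_start[k + 1]
        }
      }
    }
    pdur <- pmax(piece_end - piece_start, 0)
    run_piece <- !r3$values & pdur > fixdt / 4
    missed_rests <- c(missed_rests, pdur[r3$values])
    first_cens <- (i == 1 && truncate_first_phase)
    last_cens <- (i == n_ph)        # record ends mid-phase
    for (k in which(run_piece)) {
      cens <- (first_cens && k == 1) || (last_cens && k == length(pdur))
      if (cens) split_censored <- c(split_censored, pdur[k])
      else split_runs <- c(split_runs, pdur[k])
    }
  }

  list(run_durations = dur[keep & is_run],
       split_run_durations = split_runs,
       split_run_censored = split_censored,
       missed_rest_durations = missed_rests,
       rest_durations = dur[keep & !is_run & !rest_merged],
       n_rest_merged = sum(rest_merged),
       censored_rest = if (!is_run[n_ph] && !rest_merged[n_ph]) dur[n_ph]
                       else numeric(0),
       run_speeds = (run_disp / pmax(dur, fixdt / 2))[is_run],
       seg_speeds = seg_sp,
       turn_angles = angles,
       S_T2 = if (length(seg_sp)) mean(seg_sp^2) else NA_real_,
       initial_state = phases$state[1],
       delta_days = if (length(deltas)) mean(deltas) / 2 else 0,
       phases = data.frame(state = phases$state, t_start = t_start_c,
                           t_end = t_end_c),
       n_phases = n_ph)
}

#' Maximum-likelihood von Mises concentration with fixed zero mean
#'
#' With the mean direction fixed at 0 the MLE solves
#' \eqn{I_1(\kappa)/I_0(\kappa) = \bar R} with
#' \eqn{\bar R = \mathrm{mean}(\cos\theta)}; the persistence index is then
#' \eqn{\psi_d = \bar R} itself. Solved by bracketed root finding.
#'
#' @param angles Turn angles in radians (>= 2 values).
#' @param kappa_max Cap for degenerate (all-aligned) samples.
#' @return List with `kappa` and `psi_d`.
#' @export
fit_vonmises_kappa <- function(angles, kappa_max = 1e3) {
  if (length(angles) < 2) stop("need at least two angles")
  rbar <- mean(cos(angles))
  if (rbar <= 0) {
    warning("mean cosine <= 0: no persistence resolvable, kappa set to 0")
    return(list(kappa = 0, psi_d = 0))
  }
  if (rbar >= persistence_index(kappa_max)) {
    warning("angles nearly degenerate; kappa capped at ", kappa_max)
    return(list(kappa = kappa_max, psi_d = rbar))
  }
  kap <- stats::uniroot(function(k) persistence_index(k) - rbar,
                        c(1e-8, kappa_max), tol = 1e-8)$root
  list(kappa = kap, psi_d = rbar)
}

#' Fit a duration distribution, optionally left-truncated
#'
#' Plain maximum likelihood per family: exponential `rate = 1/mean`;
#' inverse Gaussian `mean = sample mean`,
#' `shape = n / sum(1/t - 1/mean)`; gamma via digamma root finding.
#' With `truncation = c > 0` the sample is treated as drawn from the law
#' conditioned on `t > c` (as for rests surviving a minimum-duration filter)
#' and the truncated likelihood is maximised numerically from the plain
#' estimate.
#'
#' @param durations Positive completely observed durations.
#' @param family `"exp"`, `"gamma"` or `"invgauss"`.
#' @param truncation Left-truncation point (0 for none).
#' @param censored Optional right-censored durations (phases still in
#'   progress when a record ends); each contributes a survivor term
#'   `log(1 - F(t))` to the likelihood. Ignoring them length-biases the fit
#'   low, since long phases are the ones most likely to straddle a record
#'   boundary.
#' @return A [time_dist()].
#' @export
fit_duration_dist <- function(durations, family, truncation = 0,
                              censored = numeric(0)) {
  x <- as.numeric(durations)
  if (length(x) < 2) stop("need at least two durations")
  if (any(x <= 0)) stop("durations must be positive")
  family <- norm_family(family)
  if (truncation > 0 && any(x <= truncation)) {
    stop("durations at or below the truncation point")
  }
  censored <- censored[censored > truncation]
  plain <- switch(family,
    exp = time_dist("exp", rate = 1 / mean(x)),
    invgauss = {
      mu <- mean(x)
      lam <- length(x) / sum(1 / x - 1 / mu)
      time_dist("invgauss", mean = mu, shape = lam)
    },
    gamma = {
      s <- log(mean(x)) - mean(log(x))
      k0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
      k <- stats::uniroot(function(k) log(k) - digamma(k) - s,
                          c(k0 / 10, k0 * 10), tol = 1e-10)$root
      time_dist("gamma", shape = k, scale = mean(x) / k)
    }
  )
  if (truncation <= 0 && length(censored) == 0) return(plain)
  if (family == "exp" && length(censored) == 0) {
    # memorylessness: t - c is exponential with the same rate
    return(time_dist("exp", rate = 1 / mean(x - truncation)))
  }
  nll <- function(lp) {
    d <- do.call(time_dist, c(list(family), as.list(exp(lp))))
    tail_c <- if (truncation > 0) 1 - dist_cdf(d, truncation) else 1
    if (tail_c <= 0) return(1e10)
    ll <- sum(log(pmax(dist_pdf(d, x), 1e-300))) -
      length(x) * log(tail_c)
    if (length(censored)) {
      ll <- ll + sum(log(pmax(1 - dist_cdf(d, censored), 1e-300))) -
        length(censored) * log(tail_c)
    }
    -ll
  }
  start <- log(unlist(plain$params))
  par <- if (length(start) == 1) {
    stats::optimize(nll, interval = start + c(-6, 6), tol = 1e-10)$minimum
  } else {
    stats::optim(start, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))$par
  }
  do.call(time_dist, c(list(family), as.list(exp(par))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

norm_family <- function(f) {
  switch(tolower(f),
    exp = , exponential = "exp",
    gamma = "gamma",
    invgauss = , inverse_gaussian = , ig = "invgauss",
    stop("unknown duration family: ", f)
  )
}

#' Mean squared speed from observed run speeds
#'
#' @param run_speeds Speeds of individual runs (or run segments).
#' @return \eqn{S_T^2}, the mean of the squared speeds.
#' @export
mean_squared_speed <- function(run_speeds) {
  if (length(run_speeds) < 1) stop("need at least one speed")
  mean(run_speeds^2)
}

#' De-bias run-duration moments for undetected short rests
#'
#' When rests shorter than `cutoff` are invisible to the segmentation, an
#' observed "run" is really a geometric number of true runs glued by the
#' missed short rests. With miss probability \eqn{q = F_\omega(c)} and
#' truncated-rest moments \eqn{(\tilde m, \tilde v)}, the observed moments
#' relate to the true run moments \eqn{(m_1, v_1)} by
#' \deqn{E[R] = \frac{m_1}{1-q} + \frac{q}{1-q}\tilde m, \qquad
#'  Var[R] = \frac{v_1}{1-q} + \frac{q}{1-q}\tilde v +
#'  \frac{q}{(1-q)^2}(m_1+\tilde m)^2,}
#' which invert in closed form. Requires a fitted rest law.
#'
#' @param mean_obs,var_obs Moments of the observed (possibly merged) runs.
#' @param rest_dist Fitted rest-duration [time_dist()].
#' @param cutoff Rest-detection cutoff (days).
#' @return List with de-biased `mean`, `variance`, and the miss
#'   probability `q`.
#' @export
debias_run_moments <- function(mean_obs, var_obs, rest_dist, cutoff) {
  stopifnot(inherits(rest_dist, "time_dist"), cutoff >= 0)
  q <- dist_cdf(rest_dist, cutoff)
  if (q <= 0) return(list(mean = mean_obs, variance = var_obs, q = 0))
  m1t <- stats::integrate(function(t) t * dist_pdf(rest_dist, t),
                          0, cutoff, rel.tol = 1e-10)$value / q
  m2t <- stats::integrate(function(t) t^2 * dist_pdf(rest_dist, t),
                          0, cutoff, rel.tol = 1e-10)$value / q
  vt <- m2t - m1t^2
  m1 <- (1 - q) * mean_obs - q * m1t
  a <- m1 + m1t
  v1 <- (1 - q) * var_obs - q * vt - a^2 * q / (1 - q)
  list(mean = m1, variance = max(v1, 1e-12), q = q)
}

# duration law from mean/variance (method of moments)
dist_from_moments <- function(family, m, v) {
  switch(family,
    exp = time_dist("exp", rate = 1 / m),
    invgauss = time_dist("invgauss", mean = m, shape = m^3 / v),
    gamma = time_dist("gamma", shape = m^2 / v, scale = v / m)
  )
}

#' Full parameter extraction from a set of coarse GPS tracks
#'
#' The gull-style pipeline: segment every track, pool corrected phase
#' statistics, fit the rest law by left-truncated maximum likelihood (the
#' short-rest filter makes rests below the cutoff unobservable), de-bias the
#' run moments for runs merged across missed short rests, fit the turning
#' concentration and mean squared speed, count initial states, and report
#' the implied effective diffusion constant.
#'
#' @param tracks Data frame with `track_id`, `lat`, `lon` and `t`/`timestamp`.
#' @param cfg A [segmentation_config()].
#' @param run_family,rest_family Duration families to fit.
#' @param correct Apply boundary/truncation/merging corrections (default);
#'   without it the raw segmented durations are fitted directly.
#' @return A report list: fitted `run` and `rest` [time_dist()]s, `kappa`,
#'   `psi_d`, `S_T2`, `N_p0`, `N_r0`, `D_eff`, `msd_slope`, and diagnostics
#'   (`q_missed`, `delta_days`, sample sizes).
#' @export
fit_track_parameters <- function(tracks, cfg = segmentation_config(),
                                 run_family = "invgauss",
                                 rest_family = "invgauss",
                                 correct = TRUE) {
  stopifnot("track_id" %in% names(tracks))
  ids <- unique(tracks$track_id)
  stats_list <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    ph <- segment_track(tr, cfg)
    gps_phase_stats(tr, ph, cfg, correct_boundaries = correct)
  })
  pool <- function(f) unlist(lapply(stats_list, `[[`, f))
  run_d <- pool("run_durations")
  rest_d <- pool("rest_durations")
  angles <- pool("turn_angles")
  seg_sp <- pool("seg_speeds")
  init <- vapply(stats_list, `[[`, character(1), "initial_state")
  delta <- mean(vapply(stats_list, `[[`, numeric(1), "delta_days"),
                na.rm = TRUE)
  # guaranteed-detection cutoff: each rest boundary is labelled at most half
  # a window late, so any rest longer than min_rest + window must survive
  # the minimum-duration filter; truncating there is sharp, whereas the
  # naive min_rest + 2*mean(delta) cutoff is blurred by the speed-dependent
  # per-rest boundary shifts
  cutoff <- if (correct) cfg$min_rest_days + cfg$window_days else 0
  rest_fit <- fit_duration_dist(rest_d[rest_d > cutoff], rest_family,
                                truncation = if (correct) cutoff else 0,
                                censored = if (correct) pool("censored_rest")
                                           else numeric(0))
  if (correct) {
    split_d <- pool("split_run_durations")
    run_fit <- fit_duration_dist(split_d, run_family,
                                 censored = pool("split_run_censored"))
    n_missed <- length(pool("missed_rest_durations"))
    q <- n_missed / (n_missed + length(rest_d) + length(pool("censored_rest")))
  } else {
    run_fit <- fit_duration_dist(run_d, run_family)
    q <- NA_real_
  }
  vm <- fit_vonmises_kappa(angles)
  S_T2 <- mean_squared_speed(seg_sp)
  dp <- from_model(run_fit, rest_fit, psi_d = vm$psi_d, S_T2 = S_T2)
  list(run = run_fit, rest = rest_fit,
       kappa = vm$kappa, psi_d = vm$psi_d, S_T2 = S_T2,
       N_p0 = sum(init == "run"), N_r0 = sum(init == "rest"),
       D_eff = effective_diffusion(dp), msd_slope = msd_slope(dp),
       q_missed = q, delta_days = delta,
       n_runs = length(run_d), n_rests = length(rest_d),
       n_angles = length(angles))
}

#' Split long tracks into fixed-length intervals
#'
#' Utility mirroring the practice of dividing multi-month records into
#' 28-day sample paths before averaging MSDs over them.
#'
#' @param track Data frame with a time column (`t` days or `timestamp`).
#' @param days Interval length in days.
#' @return The track with an added `interval` column and `t` rebased within
#'   each interval.
#' @export
split_track <- function(track, days = 28) {
  tt <- track_days(track)
  iv <- floor((tt - tt[1]) / days)
  out <- track
  out$interval <- iv + 1L
  out$t <- tt - tt[1] - iv * days
  out
}
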