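#' Trace runs in a kymograph
#'
#' Binarises a kymograph (Otsu threshold by default), labels connected
#' components in the (time, position) plane, and fits a least-squares line
#' (position on time) through each component to extract one run per
#' component. Components spanning fewer than `min_frames` frames are
#' discarded. Crossing tracks that merge into a single component are a
#' documented limitation of component-based tracing.
#'
#' @param kymo A `kymograph` from [render_kymograph()], or a plain matrix
#'   (rows = frames, columns = position) with `pixel_nm` and `frame_s`
#'   supplied.
#' @param threshold `"auto"` (default; background median plus 2.5 robust
#'   SDs, suited to sparse kymographs where spots cover a small pixel
#'   fraction), `"otsu"`, or an absolute intensity value.
#' @param min_frames Minimum temporal extent (frames) of a component.
#' @param min_px Minimum component size in pixels.
#' @param smooth_sigma Gaussian pre-smoothing SD (pixels) applied before
#'   thresholding; suppresses noise-driven fragmentation of dim tracks.
#'   Set to 0 to disable.
#' @param max_rms Root-mean-square line-fit residual (um) above which a
#'   component is flagged `multitrack = TRUE`: such components are almost
#'   always two crossing tracks merged into one, whose single-line fit
#'   reports a meaningless intermediate slope. Flagged runs still count as
#'   detections but are excluded from speed/run-length summaries by
#'   [summarize_motility()].
#' @param pixel_nm,frame_s Calibration when `kymo` is a plain matrix.
#' @return data.frame of runs: `t0_s`, `t1_s`, `x0_um`, `x1_um`,
#'   `speed_um_s`, `run_um`, `censored` (run ends at the image edge in
#'   space or time), `n_px`.
#' @export
trace_kymograph <- function(kymo, threshold = "auto", min_frames = 5,
                            min_px = 10, smooth_sigma = 1.5, max_rms = 0.35,
                            pixel_nm = NULL, frame_s = NULL) {
  if (inherits(kymo, "kymograph")) {
    img <- kymo$img; pixel_nm <- kymo$pixel_nm; frame_s <- kymo$frame_s
  } else {
    img <- kymo
    if (is.null(pixel_nm) || is.null(frame_s))
      stop_param("`pixel_nm` and `frame_s` required with a plain matrix")
  }
  empty <- data.frame(t0_s = numeric(0), t1_s = numeric(0),
                      x0_um = numeric(0), x1_um = numeric(0),
                      speed_um_s = numeric(0), run_um = numeric(0),
                      censored = logical(0), n_px = integer(0),
                      fit_rms = numeric(0), multitrack = logical(0))
  if (length(img) == 0 || all(img == img[1])) return(empty)

  simg <- if (smooth_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                      sigma = smooth_sigma))
  else img
  if (identical(threshold, "auto")) {
    # smoothing shrinks the noise SD several-fold while the (line-like)
    # track ridge keeps most of its amplitude, so a 5-MAD cut separates
    # cleanly without fragmenting dim tracks
    med <- stats::median(simg)
    thr <- med + 5 * stats::mad(simg)
    # (near-)noiseless image: MAD collapses to numerical dust
    if (thr - med < 0.05 * (max(simg) - med))
      thr <- med + 0.25 * (max(simg) - med)
  } else if (identical(threshold, "otsu")) {
    rng <- range(simg)
    norm <- (simg - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm)) * diff(rng) + rng[1]
  } else {
    thr <- as.numeric(threshold)
  }
  bw <- simg > thr
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- EBImage::imageData(lab)
  n_obj <- max(labm)
  if (n_obj == 0) return(empty)

  n_frames <- nrow(img); n_cols <- ncol(img)
  idx <- which(labm > 0)
  obj <- labm[idx]
  rows <- (idx - 1) %% n_frames + 1      # frame index
  cols <- (idx - 1) %/% n_frames + 1     # position index
  w <- simg[idx] - thr

  runs <- lapply(seq_len(n_obj), function(o) {
    sel <- obj == o
    if (sum(sel) < min_px) return(NULL)
    fr <- rows[sel]; px <- cols[sel]; ww <- pmax(w[sel], 1e-9)
    span <- max(fr) - min(fr) + 1L
    if (span < min_frames) return(NULL)
    # weighted per-frame centroid, then line fit position ~ time
    cen <- tapply(px * ww, fr, sum) / tapply(ww, fr, sum)
    tt <- as.numeric(names(cen)) * frame_s
    xx <- as.numeric(cen) * pixel_nm / 1000
    # smoothing + PSF extend a component by a few stationary frames at each
    # temporal end, which flattens the fitted slope; trim them off
    k_trim <- min(ceiling(2 * max(smooth_sigma, 1)),
                  max(0, floor((length(tt) - 6) / 2)))
    if (k_trim > 0) {
      keep_f <- (k_trim + 1):(length(tt) - k_trim)
      tt <- tt[keep_f]; xx <- xx[keep_f]
    }
    fit <- stats::lm(xx ~ tt)
    slope <- unname(stats::coef(fit)[2])
    rms <- sqrt(mean(stats::residuals(fit)^2))
    # run extent: full component span minus the expected blur extension
    e_ext <- ceiling(max(smooth_sigma, 1))
    t0 <- (min(fr) + e_ext) * frame_s
    t1 <- (max(fr) - e_ext) * frame_s
    if (t1 <= t0) { t0 <- min(fr) * frame_s; t1 <- max(fr) * frame_s }
    x0 <- unname(stats::predict(fit, data.frame(tt = t0)))
    x1 <- unname(stats::predict(fit, data.frame(tt = t1)))
    # right-censoring only: a run is cut short if it reaches the microtubule
    # plus end or the end of the movie. Entering at the left/start edge does
    # not censor the observed extent (exponential run lengths are memoryless).
    edge <- max(x0, x1) >= (n_cols * pixel_nm / 1000) - 0.5 ||
      max(fr) >= n_frames - 2
    data.frame(t0_s = t0, t1_s = t1, x0_um = x0, x1_um = x1,
               speed_um_s = abs(slope), run_um = abs(x1 - x0),
               censored = edge, n_px = sum(sel), fit_rms = rms)
  })
  runs <- do.call(rbind, runs)
  if (is.null(runs)) return(empty)
  runs$multitrack <- runs$fit_rms > max_rms
  runs
}

#' Partition runs into running and static
#'
#' A run is running iff its speed is strictly greater than the threshold
#' (default 25 nm/s); otherwise it is static. The partition is exhaustive
#' and disjoint.
#'
#' @param runs data.frame with a `speed_um_s` column.
#' @param threshold_nm_s Speed threshold in nm/s, default 25.
#' @return List with data.frames `running` and `static`.
#' @export
classify_runs <- function(runs, threshold_nm_s = 25) {
  check_positive(threshold_nm_s, "threshold_nm_s")
  is_running <- runs$speed_um_s * 1000 > threshold_nm_s
  list(running = runs[is_running, , drop = FALSE],
       static = runs[!is_running, , drop = FALSE])
}

#' Landing rate of one or more microtubule observations
#'
#' Events per um of microtubule per minute: `n_events / (mt_length *
#' duration)`. With several observations, events and exposure (um x min)
#' are pooled, which makes the estimate invariant to how an observation
#' window is split.
#'
#' @param obs An `mt_observation` (from [sim_motility()]) or a list of them;
#'   alternatively a data.frame with columns `n_events`, `mt_length_um`,
#'   `duration_min`.
#' @return Landing rate (events per um per min).
#' @export
landing_rate <- function(obs) {
  if (inherits(obs, "mt_observation")) obs <- list(obs)
  if (is.data.frame(obs)) {
    ev <- sum(obs$n_events); expo <- sum(obs$mt_length_um * obs$duration_min)
  } else {
    ev <- sum(vapply(obs, function(o) nrow(o$events), numeric(1)))
    expo <- sum(vapply(obs, function(o) o$mt_length * o$duration, numeric(1)))
  }
  if (expo <= 0) stop_param("total exposure (um x min) must be positive")
  ev / expo
}

#' Summarise motility statistics
#'
#' Computes mean speed and run length over running events (speed > 25 nm/s)
#' and pooled landing/running frequencies over the observed microtubules.
#' Two run-length summaries are reported: `mean_run_length`, the plain mean
#' of observed (possibly end-truncated) run extents, matching the classical
#' manual-scoring procedure; and `run_length_mle`, the censored-exponential
#' maximum-likelihood estimate (total observed run length divided by the
#' number of uncensored runs), which is consistent for the underlying mean
#' run length when runs are cut short at the microtubule plus end or the end
#' of the movie.
#'
#' @param runs data.frame of runs (as from [trace_kymograph()], or the
#'   `events` of [sim_motility()] observations); needs `speed_um_s`,
#'   `run_um` and optionally `censored`.
#' @param obs Optional `mt_observation` list (or exposure data.frame, see
#'   [landing_rate()]) for landing/running frequencies.
#' @param threshold_nm_s Running threshold, nm/s.
#' @return A `motility_summary`: `n_events`, `n_running`, `mean_speed`,
#'   `sd_speed`, `mean_run_length`, `run_length_mle`, `landing_rate`,
#'   `running_frequency` (the last two `NA` without `obs`).
#' @export
summarize_motility <- function(runs, obs = NULL, threshold_nm_s = 25) {
  clean <- if ("multitrack" %in% names(runs))
    runs[!runs$multitrack, , drop = FALSE] else runs
  parts <- classify_runs(clean, threshold_nm_s)
  rr <- parts$running
  censored <- if ("censored" %in% names(rr)) rr$censored else
    rep(FALSE, nrow(rr))
  n_unc <- sum(!censored)
  lr <- rf <- NA_real_
  if (!is.null(obs)) {
    lr <- landing_rate(obs)
    expo <- if (is.data.frame(obs)) sum(obs$mt_length_um * obs$duration_min)
    else if (inherits(obs, "mt_observation")) obs$mt_length * obs$duration
    else sum(vapply(obs, function(o) o$mt_length * o$duration, numeric(1)))
    rf <- nrow(rr) / expo
  }
  structure(list(
    n_events = nrow(runs), n_running = nrow(rr),
    mean_speed = if (nrow(rr)) mean(rr$speed_um_s) else NA_real_,
    sd_speed = if (nrow(rr) > 1) stats::sd(rr$speed_um_s) else NA_real_,
    mean_run_length = if (nrow(rr)) mean(rr$run_um) else NA_real_,
    run_length_mle = if (n_unc > 0) sum(rr$run_um) / n_unc else NA_real_,
    landing_rate = lr, running_frequency = rf
  ), class = "motility_summary")
}

#' @export
print.motility_summary <- function(x, ...) {
  cat("Motility summary:\n")
  cat(sprintf("  events: %d (%d running)\n", x$n_events, x$n_running))
  cat(sprintf("  mean speed: %.3f um/s\n", x$mean_speed))
  cat(sprintf("  mean run length (observed): %.2f um; censoring-corrected MLE: %.2f um\n",
              x$mean_run_length, x$run_length_mle))
  if (!is.na(x$landing_rate))
    cat(sprintf("  landing rate: %.3f /um/min; running frequency: %.3f /um/min\n",
                x$landing_rate, x$running_frequency))
  invisible(x)
}

#' Classify vesicle tracks as stationary or directed
#'
#' A vesicle moving less than `threshold_um` in total over the imaging
#' period is stationary; otherwise its direction is the sign of the net
#' displacement (positive = plus-end / anterograde by convention).
#'
#' @param tracks data.frame with columns `track_id`, `t_s`, `x_um`.
#' @param threshold_um Total-displacement threshold (um), default 1.5.
#' @return List with per-track classification (`track_id`, `class`) and
#'   `fractions` over `stationary`, `plus_end`, `minus_end`.
#' @export
classify_vesicle_tracks <- function(tracks, threshold_um = 1.5) {
  check_positive(threshold_um, "threshold_um")
  ids <- unique(tracks$track_id)
  cls <- vapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    if (nrow(tr) < 2) return("stationary")
    tr <- tr[order(tr$t_s), ]
    total <- abs(tr$x_um[nrow(tr)] - tr$x_um[1])
    if (total < threshold_um) "stationary"
    else if (tr$x_um[nrow(tr)] > tr$x_um[1]) "plus_end" else "minus_end"
  }, character(1))
  tab <- table(factor(cls, levels = c("stationary", "plus_end", "minus_end")))
  list(classes = data.frame(track_id = ids, class = cls),
       fractions = stats::setNames(as.numeric(tab) / length(ids), names(tab)))
}

#' Vesicle flux through a location
#'
#' Counts signed crossings of the line `x = location` per direction; a track
#' oscillating across the line contributes each crossing. Rates are per
#' minute.
#'
#' @param tracks data.frame with `track_id`, `t_s`, `x_um`.
#' @param location Position of the counting line (um).
#' @param duration Observation time (min).
#' @return List `anterograde`, `retrograde` (crossings per minute) and raw
#'   counts.
#' @export
vesicle_flux <- function(tracks, location, duration) {
  check_positive(duration, "duration")
  if (location < min(tracks$x_um) || location > max(tracks$x_um))
    stop_param("`location` outside the track coordinate range")
  antero <- retro <- 0L
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$t_s), ]
    s <- sign(tr$x_um - location)
    s <- s[s != 0]
    cross <- diff(s) != 0
    dirs <- diff(s)[cross]
    antero <- antero + sum(dirs > 0)
    retro <- retro + sum(dirs < 0)
  }
  list(anterograde = antero / duration, retrograde = retro / duration,
       counts = c(anterograde = antero, retrograde = retro))
}
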