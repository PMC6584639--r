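#' Simulate bleach-step counts from a dimer/tetramer mixture
#'
#' Each motor is a tetramer with probability `x` and a dimer otherwise; the
#' number of visible bleach steps is binomial in the number of subunits with
#' per-GFP activity `p`. Motors with zero active GFPs are undetectable in
#' TIRF and are redrawn until `n_motors` detected spots accumulate, so the
#' returned histogram has support `k = 1:4` and follows the
#' detection-conditioned pmf ([truncated_pmf()]).
#'
#' @param x Tetramer fraction in `[0, 1]`.
#' @param p Active-GFP fraction in `(0, 1]`.
#' @param n_motors Number of detected spots to simulate (>= 1).
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @return A [step_histogram()].
#' @export
sim_bleach_counts <- function(x, p, n_motors, seed) {
  check_fraction(x, "x")
  check_fraction(p, "p", allow_zero = FALSE)
  if (n_motors < 1 || n_motors != floor(n_motors))
    stop_param("`n_motors` must be a positive integer")
  with_seed(seed, {
    ks <- integer(0)
    while (length(ks) < n_motors) {
      m <- max(16L, ceiling((n_motors - length(ks)) * 1.5))
      subunits <- ifelse(stats::runif(m) < x, 4L, 2L)
      k <- stats::rbinom(m, subunits, p)
      ks <- c(ks, k[k >= 1L])
    }
    ks <- ks[seq_len(n_motors)]
    step_histogram(tabulate(ks, nbins = 4L))
  })
}

#' Simulate a stepwise photobleaching intensity trace
#'
#' Produces a piecewise-constant trace starting at `k_steps * unit_intensity`
#' that steps down by one `unit_intensity` at each bleaching event; dwell
#' times between events are exponential with mean `mean_dwell`. Gaussian
#' camera noise is added per frame. Defaults mirror typical acquisition:
#' one frame every 0.5 s for 600 s.
#'
#' @param k_steps Number of active fluorophores (>= 0).
#' @param unit_intensity Intensity of one fluorophore (AU).
#' @param noise_sd Per-frame Gaussian noise SD (AU).
#' @param mean_dwell Mean time to bleach per fluorophore (s).
#' @param frame_interval Frame interval (s), default 0.5.
#' @param n_frames Number of frames, default 1200.
#' @param seed Integer seed.
#' @return A `bleach_trace`: list with `time` (s), `intensity` (AU),
#'   `frame_interval` and ground-truth `step_times` (s).
#' @export
sim_bleach_trace <- function(k_steps, unit_intensity = 100, noise_sd = 20,
                             mean_dwell = 60, frame_interval = 0.5,
                             n_frames = 1200, seed = 0) {
  if (k_steps < 0 || k_steps != floor(k_steps))
    stop_param("`k_steps` must be a non-negative integer")
  check_positive(frame_interval, "frame_interval")
  if (n_frames <= 0) stop_param("`n_frames` must be positive")
  with_seed(seed, {
    step_times <- sort(stats::rexp(k_steps, rate = 1 / mean_dwell))
    t <- (seq_len(n_frames) - 1) * frame_interval
    n_remaining <- k_steps - findInterval(t, step_times)
    intensity <- n_remaining * unit_intensity +
      stats::rnorm(n_frames, 0, noise_sd)
    structure(list(time = t, intensity = intensity,
                   frame_interval = frame_interval,
                   step_times = step_times),
              class = "bleach_trace")
  })
}

#' Ground-truth parameters for a motility simulation
#'
#' @param landing_rate_true Landing rate (events per um of microtubule per
#'   minute).
#' @param speed_mean,speed_sd Run speed distribution (um/s); speeds are drawn
#'   from a normal truncated to positive values.
#' @param runlength_mean Mean run length (um) of the exponential run-length
#'   distribution, before truncation at the microtubule plus end.
#' @param static_fraction Fraction of landing events that remain static.
#' @return A `motility_truth` list.
#' @export
motility_truth <- function(landing_rate_true = 0.1, speed_mean = 0.45,
                           speed_sd = 0.12, runlength_mean = 8.6,
                           static_fraction = 0.3) {
  check_positive(landing_rate_true, "landing_rate_true", strict = FALSE)
  check_positive(speed_mean, "speed_mean")
  check_positive(speed_sd, "speed_sd", strict = FALSE)
  check_positive(runlength_mean, "runlength_mean")
  check_fraction(static_fraction, "static_fraction")
  structure(list(landing_rate_true = landing_rate_true,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 runlength_mean = runlength_mean,
                 static_fraction = static_fraction),
            class = "motility_truth")
}

#' Simulate single-molecule landing events on one microtubule
#'
#' Landing times follow a Poisson process with rate
#' `landing_rate_true * mt_length` per minute; landing positions are uniform
#' along the microtubule. Each event is static with probability
#' `static_fraction`; otherwise it runs toward the plus end (increasing
#' coordinate) with a truncated-normal speed and an exponential run length,
#' truncated at the microtubule end. Truncated runs are flagged censored; by
#' default the motor detaches at the plus end (set `accumulate_at_end = TRUE`
#' to let it dwell there for the remaining observation instead). Runs are
#' also cut at the end of the observation window (censored).
#'
#' @param mt_length Microtubule length (um).
#' @param duration Observation time (min).
#' @param truth A [motility_truth()].
#' @param seed Integer seed.
#' @param static_dwell_s Mean attached dwell (s) of static events
#'   (exponential).
#' @param accumulate_at_end Keep plus-end-reaching motors visible at the end
#'   until the observation finishes.
#' @return An `mt_observation`: `mt_length`, `duration`, and `events`, a
#'   data.frame with one row per landing event (`t0_s`, `x0_um`, `t1_s`,
#'   `x1_um`, `speed_um_s`, `run_um`, `static`, `censored`).
#' @export
sim_motility <- function(mt_length, duration, truth = motility_truth(),
                         seed = 0, static_dwell_s = 30,
                         accumulate_at_end = FALSE) {
  check_positive(mt_length, "mt_length")
  check_positive(duration, "duration")
  stopifnot(inherits(truth, "motility_truth"))
  with_seed(seed, {
    t_total <- duration * 60  # seconds
    n <- stats::rpois(1, truth$landing_rate_true * mt_length * duration)
    if (n == 0) {
      ev <- data.frame(t0_s = numeric(0), x0_um = numeric(0),
                       t1_s = numeric(0), x1_um = numeric(0),
                       speed_um_s = numeric(0), run_um = numeric(0),
                       static = logical(0), censored = logical(0),
                       at_end = logical(0))
      return(structure(list(mt_length = mt_length, duration = duration,
                            events = ev, truth = truth),
                       class = "mt_observation"))
    }
    t0 <- sort(stats::runif(n, 0, t_total))
    x0 <- stats::runif(n, 0, mt_length)
    static <- stats::runif(n) < truth$static_fraction

    speed <- rep(0, n)
    nrun <- sum(!static)
    if (nrun > 0) {
      s <- stats::rnorm(nrun, truth$speed_mean, truth$speed_sd)
      while (any(s <= 0))
        s[s <= 0] <- stats::rnorm(sum(s <= 0), truth$speed_mean, truth$speed_sd)
      speed[!static] <- s
    }
    run_free <- ifelse(static, 0, stats::rexp(n, 1 / truth$runlength_mean))
    dist_to_end <- mt_length - x0
    at_end <- !static & run_free >= dist_to_end
    run <- pmin(run_free, dist_to_end)

    t_detach <- ifelse(static, t0 + stats::rexp(n, 1 / static_dwell_s),
                       t0 + run / pmax(speed, .Machine$double.eps))
    if (accumulate_at_end) t_detach[at_end] <- t_total
    # cut at observation end
    time_censored <- t_detach > t_total
    t1 <- pmin(t_detach, t_total)
    run_obs <- ifelse(static, 0, pmin(run, speed * (t1 - t0)))
    x1 <- pmin(x0 + run_obs, mt_length)

    ev <- data.frame(t0_s = t0, x0_um = x0, t1_s = t1, x1_um = x1,
                     speed_um_s = speed, run_um = run_obs,
                     static = static,
                     censored = at_end | time_censored,
                     at_end = at_end)
    structure(list(mt_length = mt_length, duration = duration,
                   events = ev, truth = truth),
              class = "mt_observation")
  })
}

#' Render motor tracks into a synthetic kymograph
#'
#' Rows are frames, columns are position bins along the microtubule. Each
#' track deposits a Gaussian-blurred spot (symmetric PSF, sigma in pixels)
#' at its interpolated position in every frame it is attached; i.i.d.
#' Gaussian background noise is added. Tracks exceeding the image bounds are
#' clipped with a warning.
#'
#' @param obs An `mt_observation` from [sim_motility()], or a data.frame of
#'   events in the same format (then `mt_length` and `duration` are needed).
#' @param pixel_nm Pixel size (nm), default 105.
#' @param frame_s Frame interval (s), default 0.1.
#' @param psf_sigma_px PSF sigma (pixels), default 1.3.
#' @param signal Peak spot amplitude (AU), default 100.
#' @param noise_sd Background noise SD (AU), default 20 (SNR 5).
#' @param seed Integer seed (noise only; tracks come from `obs`).
#' @param mt_length,duration Required only if `obs` is a bare events table.
#' @return A `kymograph`: list with `img` (frames x position matrix),
#'   `pixel_nm`, `frame_s`.
#' @export
render_kymograph <- function(obs, pixel_nm = 105, frame_s = 0.1,
                             psf_sigma_px = 1.3, signal = 100, noise_sd = 20,
                             seed = 0, mt_length = NULL, duration = NULL) {
  check_positive(pixel_nm, "pixel_nm")
  check_positive(frame_s, "frame_s")
  if (inherits(obs, "mt_observation")) {
    ev <- obs$events; mt_length <- obs$mt_length; duration <- obs$duration
  } else {
    ev <- obs
    if (is.null(mt_length) || is.null(duration))
      stop_param("`mt_length` and `duration` required with a bare events table")
  }
  n_frames <- ceiling(duration * 60 / frame_s)
  n_cols <- ceiling(mt_length * 1000 / pixel_nm)
  img <- matrix(0, nrow = n_frames, ncol = n_cols)
  halfw <- ceiling(4 * psf_sigma_px)
  clipped <- FALSE
  if (nrow(ev) > 0) for (i in seq_len(nrow(ev))) {
    f0 <- max(1L, floor(ev$t0_s[i] / frame_s) + 1L)
    f1 <- min(n_frames, ceiling(ev$t1_s[i] / frame_s))
    if (f1 < f0) next
    frames <- f0:f1
    tmid <- (frames - 0.5) * frame_s
    xt <- if (ev$static[i]) rep(ev$x0_um[i], length(frames)) else
      ev$x0_um[i] + pmin(pmax(tmid - ev$t0_s[i], 0) * ev$speed_um_s[i],
                         ev$run_um[i])
    col_c <- xt * 1000 / pixel_nm + 0.5  # pixel-centre coordinate
    if (any(col_c < 0.5 | col_c > n_cols + 0.5)) clipped <- TRUE
    for (j in seq_along(frames)) {
      cc <- round(col_c[j])
      if (cc - halfw > n_cols || cc + halfw < 1) next
      cols <- max(1L, cc - halfw):min(n_cols, cc + halfw)
      img[frames[j], cols] <- img[frames[j], cols] +
        signal * exp(-((cols - col_c[j])^2) / (2 * psf_sigma_px^2))
    }
  }
  if (clipped) warning("track positions outside image bounds were clipped")
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow = n_frames))
  structure(list(img = img, pixel_nm = pixel_nm, frame_s = frame_s),
            class = "kymograph")
}

#' Simulate calibration-standard and sample elution profiles
#'
#' Generates Gaussian elution peaks whose centres lie exactly on a specified
#' linear calibration relation: for SEC (`transform = "log10_anchor"`) the
#' line is `log10(anchor) = slope * volume + intercept`; for glycerol
#' gradients (`"identity_anchor"`) it is `anchor = slope * volume +
#' intercept`. One profile is produced per species (standards plus sample),
#' plus the ground-truth peak centres.
#'
#' @param slope,intercept Calibration-line truth.
#' @param transform `"log10_anchor"` (SEC, anchor = Stokes radius nm) or
#'   `"identity_anchor"` (gradient, anchor = sedimentation coefficient S).
#' @param standards Named numeric vector of standard anchor values.
#' @param sample_anchor Anchor value of the sample species.
#' @param volumes Fraction volumes (ml) at which profiles are evaluated.
#' @param peak_width Gaussian SD of peaks (ml).
#' @param peak_height Peak amplitude (AU).
#' @param noise_sd Additive Gaussian noise SD (AU).
#' @param seed Integer seed.
#' @return List with `profiles` (named list of [elution_profile()]s,
#'   standards first then `"sample"`), `centres` (ground-truth peak centres,
#'   ml) and the calibration truth.
#' @export
sim_elution <- function(slope, intercept,
                        transform = c("log10_anchor", "identity_anchor"),
                        standards, sample_anchor,
                        volumes = seq(0, 5, by = 0.2),
                        peak_width = 0.3, peak_height = 100,
                        noise_sd = 0, seed = 0) {
  transform <- match.arg(transform)
  anchors <- c(standards, sample = sample_anchor)
  centre_of <- function(a) {
    y <- if (transform == "log10_anchor") log10(a) else a
    (y - intercept) / slope
  }
  centres <- vapply(anchors, centre_of, numeric(1))
  if (any(centres < min(volumes) | centres > max(volumes)))
    stop_param("peak centre outside the profiled volume range")
  with_seed(seed, {
    profiles <- lapply(centres, function(cc) {
      sig <- if (peak_width > 0)
        peak_height * exp(-(volumes - cc)^2 / (2 * peak_width^2))
      else peak_height * as.numeric(abs(volumes - cc) ==
                                      min(abs(volumes - cc)))
      elution_profile(volumes, sig + stats::rnorm(length(volumes), 0, noise_sd))
    })
    names(profiles) <- names(anchors)
    list(profiles = profiles, centres = centres,
         slope = slope, intercept = intercept, transform = transform)
  })
}

#' Simulate a thermophoresis (MST) titration series
#'
#' Reproduces the standard dilution/mixing scheme: a ligand stock is
#' twofold serially diluted (`n_dilutions` points) and mixed with
#' fluorescent receptor so that the final ligand concentration is
#' `stock * mix_fraction` at the top point and the receptor is constant at
#' `receptor_total`. The signal interpolates between `f_free` and `f_bound`
#' with the quadratic (ligand-depletion) bound fraction and multiplicative
#' Gaussian noise.
#'
#' @param kd Dissociation constant (uM).
#' @param receptor_total Final receptor concentration (uM), default 0.05
#'   (250 nM stock diluted 1:5).
#' @param stock Ligand stock (uM), default 37.
#' @param n_dilutions Number of titration points, default 16.
#' @param mix_fraction Ligand dilution factor on mixing, default 0.8
#'   (8 ul ligand + 2 ul receptor).
#' @param f_free,f_bound Signal of free and bound receptor (AU).
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed.
#' @return A `binding_series`: data.frame `ligand_uM`, `signal`, with
#'   attributes `receptor_total` and ground truth.
#' @export
sim_binding_series <- function(kd, receptor_total = 0.05, stock = 37,
                               n_dilutions = 16, mix_fraction = 0.8,
                               f_free = 800, f_bound = 900,
                               noise_cv = 0, seed = 0) {
  check_positive(kd, "kd")
  check_positive(receptor_total, "receptor_total")
  ligand <- stock * mix_fraction / 2^(seq_len(n_dilutions) - 1)
  fb <- bound_fraction(ligand, receptor_total, kd)
  signal <- f_free + (f_bound - f_free) * fb
  with_seed(seed, {
    if (noise_cv > 0)
      signal <- signal * (1 + stats::rnorm(n_dilutions, 0, noise_cv))
    out <- data.frame(ligand_uM = ligand, signal = signal)
    attr(out, "receptor_total") <- receptor_total
    attr(out, "truth") <- list(kd = kd, f_free = f_free, f_bound = f_bound)
    class(out) <- c("binding_series", "data.frame")
    out
  })
}

#' Rectangular region masks for a synthetic cell image
#'
#' Lays out disjoint tail, cytoplasm and background rectangles in an image
#' of the given size.
#'
#' @param nrow,ncol Image dimensions (pixels).
#' @return A `region_masks` list of three logical matrices: `tail`,
#'   `cytoplasm`, `background`.
#' @export
default_region_masks <- function(nrow = 120, ncol = 120) {
  mk <- function(r, c) {
    m <- matrix(FALSE, nrow, ncol); m[r, c] <- TRUE; m
  }
  masks <- list(tail = mk(10:39, 10:39),
                cytoplasm = mk(10:39, 70:109),
                background = mk(80:109, 10:39))
  structure(masks, class = "region_masks")
}

#' Simulate a two-channel cell image with known region intensities
#'
#' Pixels in the tail, cytoplasm and background regions take the specified
#' per-channel means plus Gaussian noise; pixels outside any region take the
#' background mean. Ground-truth enrichment ratios are attached.
#'
#' @param tail_I,cyto_I,bg_I Numeric length-2 vectors (one value per
#'   channel) of region mean intensities (AU).
#' @param masks A `region_masks` (default [default_region_masks()]).
#' @param noise_sd Gaussian noise SD (AU).
#' @param seed Integer seed.
#' @return A `two_channel_image`: list of two matrices `ch1`, `ch2` plus
#'   `pixel_size_um`; ground truth in `attr(, "truth")`.
#' @export
sim_cell_image <- function(tail_I, cyto_I, bg_I,
                           masks = default_region_masks(),
                           noise_sd = 0, seed = 0, pixel_size_um = 0.1) {
  stopifnot(inherits(masks, "region_masks"),
            length(tail_I) == 2, length(cyto_I) == 2, length(bg_I) == 2)
  dims <- dim(masks$tail)
  with_seed(seed, {
    chans <- lapply(1:2, function(ch) {
      img <- matrix(bg_I[ch], dims[1], dims[2])
      img[masks$tail] <- tail_I[ch]
      img[masks$cytoplasm] <- cyto_I[ch]
      img[masks$background] <- bg_I[ch]
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            dims[1], dims[2])
      img
    })
    out <- structure(list(ch1 = chans[[1]], ch2 = chans[[2]],
                          pixel_size_um = pixel_size_um),
                     class = "two_channel_image")
    attr(out, "truth") <- list(
      ratio = (tail_I - bg_I) / (cyto_I - bg_I))
    out
  })
}

#' Simulate a two-channel podosome field
#'
#' Places `n_objects` non-overlapping discs (rejection sampling) of the given
#' radius. Channel 1 (cortactin) shows all discs; channel 2 (actin) shows
#' only a `coloc_fraction` subset, so the ground-truth podosome count equals
#' the number of actin-coincident discs.
#'
#' @param n_objects Number of cortactin discs.
#' @param radius_px Disc radius (pixels); a radius of 3 px gives an area of
#'   about 29 px, above the 16-px size filter.
#' @param object_I,bg_I Disc and background intensities (AU).
#' @param coloc_fraction Fraction of discs also present in the actin channel.
#' @param image_size Image side length (pixels).
#' @param noise_sd Gaussian noise SD (AU).
#' @param seed Integer seed.
#' @param pixel_size_um Pixel size (um), default 0.402 so that 16 px is
#'   about 2.58 um^2.
#' @return A `two_channel_image` (`ch1` cortactin, `ch2` actin) with ground
#'   truth (`centres`, `coincident` flags, `n_coincident`) attached.
#' @export
sim_podosome_image <- function(n_objects, radius_px = 3, object_I = 100,
                               bg_I = 10, coloc_fraction = 1,
                               image_size = 128, noise_sd = 0, seed = 0,
                               pixel_size_um = 0.402) {
  check_fraction(coloc_fraction, "coloc_fraction")
  with_seed(seed, {
    centres <- matrix(numeric(0), 0, 2)
    margin <- radius_px + 2
    tries <- 0
    while (nrow(centres) < n_objects) {
      cand <- c(stats::runif(1, margin, image_size - margin),
                stats::runif(1, margin, image_size - margin))
      if (nrow(centres) == 0 ||
          all(sqrt(rowSums((t(t(centres) - cand))^2)) > 2 * radius_px + 4))
        centres <- rbind(centres, cand)
      tries <- tries + 1
      if (tries > 10000 * max(n_objects, 1))
        stop_param("could not place %d non-overlapping discs", n_objects)
    }
    n_coinc <- round(coloc_fraction * n_objects)
    coincident <- rep(FALSE, n_objects)
    if (n_objects > 0 && n_coinc > 0)
      coincident[sample.int(n_objects, n_coinc)] <- TRUE

    xg <- matrix(rep(seq_len(image_size), image_size), image_size)
    yg <- t(xg)
    draw <- function(idx) {
      img <- matrix(bg_I, image_size, image_size)
      for (i in idx) {
        d2 <- (xg - centres[i, 1])^2 + (yg - centres[i, 2])^2
        img[d2 <= radius_px^2] <- object_I
      }
      if (noise_sd > 0)
        img <- pmax(img + matrix(stats::rnorm(image_size^2, 0, noise_sd),
                                 image_size), 0)
      img
    }
    out <- structure(list(ch1 = draw(seq_len(n_objects)),
                          ch2 = draw(which(coincident)),
                          pixel_size_um = pixel_size_um),
                     class = "two_channel_image")
    attr(out, "truth") <- list(centres = centres, coincident = coincident,
                               n_objects = n_objects,
                               n_coincident = sum(coincident),
                               radius_px = radius_px)
    out
  })
}
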