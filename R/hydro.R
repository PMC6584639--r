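#' Calibration standards shipped with the package
#'
#' Stokes radii (nm) of the SEC standards and sedimentation coefficients (S)
#' of the glycerol-gradient standards commonly used for hydrodynamic sizing
#' of motor proteins.
#'
#' @format Named numeric vectors.
#' @export
sec_standards <- c(thyroglobulin = 8.5, apoferritin = 6.1,
                   catalase = 5.2, BSA = 3.48)

#' @rdname sec_standards
#' @export
gradient_standards <- c(apoferritin = 17.6, catalase = 11.3,
                        glucose_oxidase = 8, BSA = 4.6)

#' Construct an elution profile
#'
#' @param volumes Fraction volumes (ml), strictly increasing. For SEC use
#'   elution volume minus void volume (Ve - V0); for gradients use volume
#'   from the gradient top.
#' @param signal Signal per fraction (AU).
#' @param salt_mM,assay Optional metadata.
#' @return An `elution_profile`.
#' @export
elution_profile <- function(volumes, signal, salt_mM = NA, assay = NA) {
  if (length(volumes) != length(signal))
    stop_param("`volumes` and `signal` must have equal length")
  if (length(volumes) < 5)
    stop_param("at least 5 fractions are required for peak fitting")
  if (any(diff(volumes) <= 0))
    stop_param("`volumes` must be strictly increasing")
  structure(list(volumes = volumes, signal = signal,
                 salt_mM = salt_mM, assay = assay),
            class = "elution_profile")
}

#' Fit a linear calibration from standard proteins
#'
#' Ordinary least squares of the (transformed) anchor value on elution
#' volume: `log10(anchor) ~ volume` for SEC Stokes-radius calibration,
#' `anchor ~ volume` for gradient sedimentation-coefficient calibration.
#'
#' @param standards data.frame with columns `anchor_value` and
#'   `elution_volume_ml` (a `name` column is optional), or a named numeric
#'   vector of anchors with a separate `volumes` argument.
#' @param transform `"log10_anchor"` (SEC) or `"identity_anchor"` (gradient).
#' @param volumes Elution volumes (ml) if `standards` is a plain vector.
#' @return A `calibration_line`: `slope`, `intercept`, their standard errors,
#'   `r_squared`, `n_points`, `transform`.
#' @export
#' @examples
#' std <- data.frame(anchor_value = gradient_standards,
#'                   elution_volume_ml = (gradient_standards + 3.92) / 5.66)
#' fit_calibration(std, transform = "identity_anchor")
fit_calibration <- function(standards,
                            transform = c("log10_anchor", "identity_anchor"),
                            volumes = NULL) {
  transform <- match.arg(transform)
  if (is.data.frame(standards)) {
    anchor <- standards$anchor_value
    v <- standards$elution_volume_ml
  } else {
    anchor <- as.numeric(standards)
    v <- volumes
  }
  if (length(anchor) < 2 || length(unique(v)) < 2)
    stop_param("calibration requires >= 2 standards with distinct volumes")
  if (any(anchor <= 0)) stop_param("anchor values must be positive")
  y <- if (transform == "log10_anchor") log10(anchor) else anchor
  fit <- stats::lm(y ~ v)
  # summary.lm warns on an exactly collinear (zero-residual) fit; exact
  # standards are a legitimate input here
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  r2 <- if (length(y) > 2) sm$r.squared else 1
  structure(list(slope = unname(cf["v", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 slope_se = if (nrow(cf) == 2 && length(y) > 2)
                   unname(cf["v", "Std. Error"]) else 0,
                 intercept_se = if (length(y) > 2)
                   unname(cf["(Intercept)", "Std. Error"]) else 0,
                 r_squared = r2, n_points = length(y),
                 transform = transform),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("Calibration line (%s, n = %d): y = (%.4g +/- %.2g) v + (%.4g +/- %.2g), R^2 = %.4f\n",
              x$transform, x$n_points, x$slope, x$slope_se,
              x$intercept, x$intercept_se, x$r_squared))
  invisible(x)
}

#' Locate the elution peak of a profile
#'
#' Fits a Gaussian to a window of +/- 3 fractions around the maximal
#' fraction; if the fit fails, falls back to the intensity-weighted centroid
#' of the window. The reported uncertainty is never smaller than half the
#' fraction spacing (the precision of reading a peak off a fraction grid).
#'
#' @param profile An [elution_profile()].
#' @return List with `centre` (ml), `se` (ml), `method` (`"gaussian"` or
#'   `"centroid"`), and `tie` (TRUE when two fractions tie at the maximum).
#' @export
locate_peak <- function(profile) {
  stopifnot(inherits(profile, "elution_profile"))
  v <- profile$volumes; s <- profile$signal
  n <- length(v)
  imax <- which(s == max(s))
  tie <- length(imax) > 1
  if (all(diff(s) >= 0) || all(diff(s) <= 0))
    stop_param("profile is monotone: no interior peak")
  if (imax[1] == 1 || imax[length(imax)] == n)
    warning("profile maximum at a boundary fraction; peak may be truncated")
  spacing <- stats::median(diff(v))
  floor_se <- spacing / 2
  if (tie && length(imax) == 2 && diff(imax) == 1) {
    return(list(centre = mean(v[imax]), se = floor_se,
                method = "centroid", tie = TRUE))
  }
  i0 <- imax[1]
  win <- max(1, i0 - 3):min(n, i0 + 3)
  vw <- v[win]; sw <- s[win]
  base <- min(sw)
  fit <- tryCatch(
    minpack.lm::nlsLM(sw ~ a * exp(-(vw - mu)^2 / (2 * sig^2)) + c0,
                      start = list(a = max(sw) - base, mu = v[i0],
                                   sig = spacing, c0 = base),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- summary(fit)$coefficients
    mu <- cf["mu", "Estimate"]
    if (mu >= min(vw) && mu <= max(vw)) {
      return(list(centre = unname(mu),
                  se = max(unname(cf["mu", "Std. Error"]), floor_se,
                           na.rm = TRUE),
                  method = "gaussian", tie = FALSE))
    }
  }
  w <- sw - base
  list(centre = sum(vw * w) / sum(w), se = floor_se,
       method = "centroid", tie = FALSE)
}

#' Convert an elution volume into a Stokes radius or sedimentation
#' coefficient
#'
#' Inverts a fitted [fit_calibration()] line at the given elution volume:
#' SEC mode returns `10^(slope * v + intercept)` (Stokes radius, nm);
#' gradient mode returns `slope * v + intercept` (sedimentation coefficient,
#' S). Standard errors of the line parameters and of the peak location are
#' combined by first-order propagation.
#'
#' @param line A `calibration_line`.
#' @param elution_volume Peak volume (ml).
#' @param volume_se Peak-location standard error (ml), default 0.
#' @return List with `value` and `se`.
#' @export
invert_calibration <- function(line, elution_volume, volume_se = 0) {
  stopifnot(inherits(line, "calibration_line"))
  if (!is.finite(elution_volume)) stop_param("non-finite elution volume")
  yhat <- line$slope * elution_volume + line$intercept
  var_y <- (elution_volume * line$slope_se)^2 + line$intercept_se^2 +
    (line$slope * volume_se)^2
  if (line$transform == "log10_anchor") {
    value <- 10^yhat
    se <- value * log(10) * sqrt(var_y)
  } else {
    value <- yhat
    se <- sqrt(var_y)
    if (value <= 0)
      stop_param("non-physical sedimentation coefficient (%.3g <= 0)", value)
  }
  list(value = value, se = se)
}

#' Siegel-Monty molecular weight from Stokes radius and sedimentation
#' coefficient
#'
#' `M = 4205 * Rs * S` with `Rs` in nm and `S` in Svedberg, giving Daltons.
#'
#' @param rs_nm Stokes radius (nm).
#' @param s_svedberg Sedimentation coefficient (S).
#' @param rs_se,s_se Optional standard errors for propagation.
#' @return Molecular weight (Da); with SEs, a list `value`, `se`.
#' @export
molecular_weight <- function(rs_nm, s_svedberg, rs_se = NULL, s_se = NULL) {
  check_positive(rs_nm, "rs_nm")
  check_positive(s_svedberg, "s_svedberg")
  mw <- 4205 * rs_nm * s_svedberg
  if (is.null(rs_se) && is.null(s_se)) return(mw)
  rs_se <- if (is.null(rs_se)) 0 else rs_se
  s_se <- if (is.null(s_se)) 0 else s_se
  list(value = mw,
       se = mw * sqrt((rs_se / rs_nm)^2 + (s_se / s_svedberg)^2))
}

#' Frictional ratio from sedimentation coefficient and mass
#'
#' `f/f_min = S_max / S` with `S_max = 0.00361 * M^(2/3)` (M in Daltons),
#' the sedimentation coefficient of an ideal compact sphere of the same
#' mass. Values near 1 indicate a compact particle; larger values an
#' elongated one.
#'
#' @param s_svedberg Measured sedimentation coefficient (S).
#' @param mw_da Molecular mass (Da).
#' @return Dimensionless frictional ratio.
#' @export
frictional_ratio <- function(s_svedberg, mw_da) {
  check_positive(s_svedberg, "s_svedberg")
  check_positive(mw_da, "mw_da")
  s_max(mw_da) / s_svedberg
}

#' @rdname frictional_ratio
#' @export
s_max <- function(mw_da) {
  check_positive(mw_da, "mw_da")
  0.00361 * mw_da^(2 / 3)
}

#' Full hydrodynamic characterisation from two elution profiles
#'
#' Convenience wrapper: fits both calibrations, locates the sample peak in
#' the SEC and gradient profiles, inverts the calibrations, and combines
#' Stokes radius and sedimentation coefficient into a molecular weight and
#' frictional ratio with propagated uncertainties.
#'
#' @param sec_std,grad_std Calibration standards (data.frame as in
#'   [fit_calibration()]).
#' @param sec_profile,grad_profile Sample [elution_profile()]s.
#' @param expected_mass_da Optional expected mass for the frictional ratio
#'   (default: the measured mass).
#' @return A `hydro_result` with `rs_nm`, `s_svedberg`, `mw_da`, `f_ratio`
#'   and their SEs; `f_ratio < 1` is flagged.
#' @export
hydrodynamic_result <- function(sec_std, grad_std, sec_profile, grad_profile,
                                expected_mass_da = NULL) {
  sec_line <- fit_calibration(sec_std, "log10_anchor")
  grad_line <- fit_calibration(grad_std, "identity_anchor")
  pk_sec <- locate_peak(sec_profile)
  pk_grad <- locate_peak(grad_profile)
  rs <- invert_calibration(sec_line, pk_sec$centre, pk_sec$se)
  s <- invert_calibration(grad_line, pk_grad$centre, pk_grad$se)
  if (rs$value < 1 || rs$value > 20)
    warning(sprintf("Stokes radius %.2f nm outside the expected 1-20 nm range",
                    rs$value))
  if (s$value < 1 || s$value > 30)
    warning(sprintf("sedimentation coefficient %.2f S outside the expected 1-30 S range",
                    s$value))
  mw <- molecular_weight(rs$value, s$value, rs$se, s$se)
  mass_for_f <- if (is.null(expected_mass_da)) mw$value else expected_mass_da
  f <- frictional_ratio(s$value, mass_for_f)
  res <- structure(list(rs_nm = rs$value, rs_se = rs$se,
                        s_svedberg = s$value, s_se = s$se,
                        mw_da = mw$value, mw_se = mw$se,
                        f_ratio = f,
                        f_ratio_flagged = f < 1,
                        sec_line = sec_line, grad_line = grad_line),
                   class = "hydro_result")
  if (f < 1)
    warning("frictional ratio < 1: inputs are mutually inconsistent")
  res
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf("Hydrodynamic result:\n  Rs = %.2f +/- %.2f nm\n  S  = %.2f +/- %.2f S\n  MW = %.0f +/- %.0f Da\n  f/f_min = %.2f%s\n",
              x$rs_nm, x$rs_se, x$s_svedberg, x$s_se, x$mw_da, x$mw_se,
              x$f_ratio, if (x$f_ratio_flagged) " (FLAGGED < 1)" else ""))
  invisible(x)
}
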