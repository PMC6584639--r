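#' Bound fraction under the quadratic (ligand-depletion) isotherm
#'
#' Fraction of receptor bound at total ligand `L`, total receptor `R` and
#' dissociation constant `Kd`:
#' \deqn{f_b = \frac{(R+L+K_d) - \sqrt{(R+L+K_d)^2 - 4RL}}{2R}}
#' In the limit `R -> 0` this reduces to the hyperbola `L / (L + Kd)`,
#' which is used directly when `R` is negligible to avoid cancellation.
#'
#' @param ligand_total Total ligand concentration(s), uM (vectorised).
#' @param receptor_total Total receptor concentration, uM (0 allowed as the
#'   hyperbolic limit).
#' @param kd Dissociation constant, uM.
#' @return Bound fraction in `[0, 1]`.
#' @export
#' @examples
#' bound_fraction(1, 0.05, 1)   # 0.49375
bound_fraction <- function(ligand_total, receptor_total, kd) {
  check_positive(kd, "kd")
  check_positive(receptor_total, "receptor_total", strict = FALSE)
  if (any(ligand_total < 0)) stop_param("ligand concentrations must be >= 0")
  if (receptor_total < 1e-9 * kd)
    return(ligand_total / (ligand_total + kd))
  b <- receptor_total + ligand_total + kd
  disc <- b^2 - 4 * receptor_total * ligand_total
  if (any(disc < 0)) {
    if (any(disc < -1e-8 * b^2)) stop_param("negative discriminant")
    disc <- pmax(disc, 0)
  }
  (b - sqrt(disc)) / (2 * receptor_total)
}

#' Fit a dissociation constant to a titration series
#'
#' Nonlinear least squares of `signal = f_free + (f_bound - f_free) *
#' bound_fraction(L, R, Kd)` over `(Kd, f_free, f_bound)`. `Kd` is
#' log-parameterised and initialised at the mid-transition ligand
#' concentration; for each candidate `Kd` the amplitudes enter linearly, so
#' a profiled 1-D search precedes the full refinement. Fits are weighted by
#' `1/signal^2` (constant coefficient of variation, the usual error model
#' for fluorescence ratios); unweighted fitting is available via
#' `weights = "none"`.
#'
#' @param series A `binding_series` (from [sim_binding_series()]) or a
#'   data.frame with `ligand_uM` and `signal`.
#' @param receptor_total Total receptor (uM); defaults to the series
#'   attribute or 0.05.
#' @param model `"quadratic"` (default, ligand depletion) or
#'   `"hyperbolic"`.
#' @param weights `"cv"` (default, weight `1/signal^2`) or `"none"`.
#' @return A `kd_fit`: `kd`, `se_kd`, `f_free`, `f_bound`, `rss`, `model`.
#' @export
fit_kd <- function(series, receptor_total = NULL,
                   model = c("quadratic", "hyperbolic"),
                   weights = c("cv", "none")) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  if (is.null(receptor_total))
    receptor_total <- attr(series, "receptor_total")
  if (is.null(receptor_total)) receptor_total <- 0.05
  L <- series$ligand_uM; y <- series$signal
  if (length(L) < 6) stop_param("at least 6 titration points are required")
  if (any(L <= 0) || anyDuplicated(L))
    stop_param("ligand concentrations must be positive and distinct")
  if (max(L) / min(L) < 10)
    stop_param("series must span at least one decade of ligand concentration")
  R <- if (model == "hyperbolic") 0 else receptor_total

  fb <- function(kd) bound_fraction(L, R, kd)
  w <- if (weights == "cv") 1 / pmax(y, 1e-12 * max(abs(y)))^2
  else rep(1, length(y))
  # profiled RSS: for fixed kd, f_free/f_bound from linear regression
  prof <- function(logkd) {
    f <- fb(exp(logkd))
    fit <- stats::lm.wfit(cbind(1, f), y, w)
    sum(w * fit$residuals^2)
  }
  span <- log(range(L))
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    stop_param("flat series: no binding transition to fit")
  o <- stats::optimize(prof, interval = span + c(-log(100), log(100)))
  kd0 <- exp(o$minimum)
  f0 <- fb(kd0)
  amp <- stats::coef(stats::lm(y ~ f0, weights = w))
  if (!is.finite(amp[2]) || abs(amp[2]) < 1e-12 * max(abs(y), 1))
    stop_param("non-identifiable fit: no signal transition")

  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ ff + (fbnd - ff) * bound_fraction(L, R, exp(logkd)),
    start = list(logkd = log(kd0), ff = unname(amp[1]),
                 fbnd = unname(amp[1] + amp[2])),
    weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    kd <- kd0; se_kd <- NA_real_
    f_free <- unname(amp[1]); f_bound <- unname(amp[1] + amp[2])
    rss <- o$objective
  } else {
    cf <- summary(fit)$coefficients
    kd <- exp(cf["logkd", "Estimate"])
    se_kd <- kd * cf["logkd", "Std. Error"]
    f_free <- cf["ff", "Estimate"]
    f_bound <- cf["fbnd", "Estimate"]
    rss <- sum(stats::residuals(fit)^2)
  }
  structure(list(kd = kd, se_kd = se_kd, f_free = f_free,
                 f_bound = f_bound, rss = rss, model = model,
                 receptor_total = receptor_total, n = length(L)),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("Kd fit (%s isotherm, n = %d): Kd = %.3g +/- %.2g uM\n",
              x$model, x$n, x$kd, x$se_kd))
  cat(sprintf("  f_free = %.3g, f_bound = %.3g, RSS = %.3g\n",
              x$f_free, x$f_bound, x$rss))
  invisible(x)
}

#' Microtubule decoration intensity with local background subtraction
#'
#' For each microtubule region of interest, the mean pixel intensity is
#' taken and the mean of a paired nearby background region subtracted.
#'
#' @param image Numeric matrix.
#' @param mt_rois,bg_rois Paired lists of ROIs; each ROI is a logical mask
#'   matrix or an integer index vector into `image`.
#' @return data.frame with `mean_intensity`, `background`, `corrected` and
#'   `flagged` (corrected < 0, possible only within noise).
#' @export
decoration_intensity <- function(image, mt_rois, bg_rois) {
  if (length(mt_rois) != length(bg_rois))
    stop_param("each microtubule ROI needs a paired background ROI")
  roival <- function(roi) {
    if (is.logical(roi)) mean(image[roi]) else mean(image[as.integer(roi)])
  }
  mt <- vapply(mt_rois, roival, numeric(1))
  bg <- vapply(bg_rois, roival, numeric(1))
  data.frame(mean_intensity = mt, background = bg,
             corrected = mt - bg, flagged = (mt - bg) < 0)
}
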