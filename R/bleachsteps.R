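#' Mixed-binomial photobleaching model for dimer/tetramer mixtures
#'
#' A fluorescent spot containing a motor with `n` GFP-tagged subunits shows
#' `k` discrete bleach steps, where `k` is the number of GFPs that matured and
#' are active. For a population that is a mixture of dimers (2 GFPs) and
#' tetramers (4 GFPs), the probability of observing `k` bleach steps is
#'
#' \deqn{P(k) = \binom{2}{k} p^k (1-p)^{2-k} (1-x) +
#'              \binom{4}{k} p^k (1-p)^{4-k} x}
#'
#' with `x` the tetramer fraction and `p` the fraction of active GFP
#' molecules. The binomial coefficient \eqn{\binom{2}{k}} is zero for `k > 2`.
#'
#' @param k Integer step counts in `0:4` (vectorised).
#' @param x Tetramer fraction in `[0, 1]`.
#' @param p Active-GFP fraction in `(0, 1]`.
#' @return Probabilities, one per element of `k`.
#' @seealso [truncated_pmf()] for the detection-conditioned variant,
#'   [fit_oligomer()] for maximum-likelihood fitting.
#' @export
#' @examples
#' mixed_binomial_pmf(0:4, x = 0.12, p = 0.8)
mixed_binomial_pmf <- function(k, x, p) {
  check_fraction(x, "x")
  check_fraction(p, "p", allow_zero = FALSE)
  if (any(k != floor(k)) || any(k < 0) || any(k > 4))
    stop_param("`k` must be integers in 0..4")
  # dbinom(k, 2, p) is exactly C(2,k) p^k (1-p)^(2-k), with C(2,k) = 0 for
  # k > 2, and avoids the 0 * Inf ambiguity of the literal product at p = 1
  (1 - x) * stats::dbinom(k, 2, p) + x * stats::dbinom(k, 4, p)
}

#' Detection-conditioned bleach-step probabilities
#'
#' Spots in which no GFP is active (`k = 0`) are invisible in TIRF and never
#' scored, so observed histograms are drawn from the model conditioned on
#' detection: \eqn{P(k \mid k \ge 1) = P(k) / (1 - P(0))}.
#'
#' @inheritParams mixed_binomial_pmf
#' @param k Integer step counts in `1:4` (vectorised).
#' @return Probabilities summing to 1 over `k = 1:4`.
#' @export
truncated_pmf <- function(k, x, p) {
  if (any(k < 1)) stop_param("`k` must be integers in 1..4")
  p0 <- mixed_binomial_pmf(0L, x, p)
  mixed_binomial_pmf(k, x, p) / (1 - p0)
}

#' Construct a bleach-step histogram
#'
#' @param counts Named or unnamed non-negative integer vector of length 4
#'   giving the number of spots with 1, 2, 3 and 4 bleach steps.
#' @return A `step_histogram`: integer counts on support `k = 1:4`.
#' @export
step_histogram <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != 4 || any(counts < 0))
    stop_param("`counts` must be 4 non-negative integers (k = 1..4)")
  structure(list(counts = stats::setNames(counts, 1:4),
                 n_total = sum(counts)),
            class = "step_histogram")
}

#' @export
print.step_histogram <- function(x, ...) {
  cat("Bleach-step histogram (", x$n_total, " spots)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Count photobleaching steps in a fluorescence trace
#'
#' Segments a trace into piecewise-constant levels by penalized least-squares
#' change-point detection (optimal partitioning with pruning) and counts the
#' downward level changes of at least `min_step`. Upward changes (blinking,
#' re-activation) are not counted; the segmentation simply passes through
#' them, so a blink contributes at most one counted downward step when the
#' level finally drops.
#'
#' @param trace A `bleach_trace` (from [sim_bleach_trace()]) or a numeric
#'   vector of intensities.
#' @param min_step Minimum downward level change (AU) counted as a bleach
#'   step. Defaults to 3 robust noise SDs, estimated from successive
#'   differences.
#' @param penalty Segmentation penalty per change point. Default
#'   `2 * sigma^2 * log(n)` with `sigma` the robust noise SD.
#' @param quantize Count a drop of about `m` unit heights as `m` steps
#'   (unit = median qualifying drop), the usual treatment of two
#'   fluorophores bleaching within the same frame. `TRUE` by default.
#' @return List with `k` (step count), `step_frames` (frame indices of
#'   counted downward changes), `levels` (fitted segment means) and
#'   `changepoints` (all segment boundaries).
#' @export
detect_steps <- function(trace, min_step = NULL, penalty = NULL,
                         quantize = TRUE) {
  y <- if (inherits(trace, "bleach_trace")) trace$intensity else as.numeric(trace)
  n <- length(y)
  if (n < 10) stop_param("trace must have at least 10 frames")
  if (!all(is.finite(y))) stop_param("trace contains non-finite values")

  sigma <- stats::median(abs(diff(y))) / (sqrt(2) * stats::qnorm(0.75))
  if (sigma == 0) sigma <- stats::sd(y) / 10
  if (is.null(min_step)) min_step <- max(3 * sigma, .Machine$double.eps)
  if (is.null(penalty)) penalty <- max(2 * sigma^2 * log(n), .Machine$double.eps)

  cps <- pelt_meanseg(y, penalty)
  bounds <- c(0L, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(y[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))

  drops <- -diff(levels)
  keep <- drops >= min_step
  k <- if (quantize && any(keep)) {
    unit <- stats::median(drops[keep])
    sum(pmax(1, round(drops[keep] / unit)))
  } else sum(keep)
  list(k = k,
       step_frames = cps[keep],
       levels = levels,
       changepoints = cps)
}

# Optimal partitioning for piecewise-constant mean under squared-error cost
# with per-changepoint penalty; PELT pruning keeps it near-linear.
pelt_meanseg <- function(y, penalty) {
  n <- length(y)
  s1 <- c(0, cumsum(y))
  s2 <- c(0, cumsum(y^2))
  segcost <- function(i, j) {
    # cost of segment (i+1):j, i vector
    len <- j - i
    (s2[j + 1] - s2[i + 1]) - (s1[j + 1] - s1[i + 1])^2 / len
  }
  F <- c(-penalty, rep(Inf, n))
  last <- integer(n)
  cand <- 0L
  for (t in seq_len(n)) {
    costs <- F[cand + 1L] + segcost(cand, t) + penalty
    best <- which.min(costs)
    F[t + 1L] <- costs[best]
    last[t] <- cand[best]
    cand <- cand[F[cand + 1L] + segcost(cand, t) <= F[t + 1L]]
    cand <- c(cand, t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    c0 <- last[t]
    if (c0 > 0) cps <- c(c0, cps)
    t <- c0
  }
  cps
}

#' Fit the mixed-binomial oligomer model to a bleach-step histogram
#'
#' Maximises the multinomial log-likelihood of the observed step counts over
#' the tetramer fraction `x` and the active-GFP fraction `p`, on a coarse
#' grid (step 0.01) followed by bounded quasi-Newton refinement. By default
#' the detection-conditioned model ([truncated_pmf()]) is used, because spots
#' with zero active GFPs are never observed.
#'
#' @param hist A `step_histogram` (or 4-vector of counts for k = 1..4).
#' @param condition_on_detection If `TRUE` (default) fit the k >= 1 truncated
#'   model; otherwise the unconditioned model evaluated on k = 1..4.
#' @return An `oligomer_fit` with elements `x_hat`, `p_hat`, `loglik`,
#'   `chi2`, `dof`, `p_gof`, `converged`, `identifiable`,
#'   `conditioned_on_detection`, `expected` (fitted expected counts).
#' @export
#' @examples
#' h <- sim_bleach_counts(x = 0.12, p = 0.8, n_motors = 108, seed = 1)
#' fit_oligomer(h)
fit_oligomer <- function(hist, condition_on_detection = TRUE) {
  if (!inherits(hist, "step_histogram")) hist <- step_histogram(hist)
  counts <- hist$counts
  n <- hist$n_total
  if (n < 10) stop_param("histogram must contain at least 10 spots")

  probs <- function(x, p) {
    pk <- mixed_binomial_pmf(1:4, x, p)
    if (condition_on_detection) pk <- pk / (1 - mixed_binomial_pmf(0L, x, p))
    pk
  }
  nll <- function(par) {
    pk <- pmax(probs(par[1], par[2]), 1e-300)
    -sum(counts * log(pk))
  }

  xs <- seq(0, 1, by = 0.01)
  ps <- seq(0.01, 1, by = 0.01)
  D2 <- vapply(ps, function(p) stats::dbinom(0:4, 2, p), numeric(5))
  D4 <- vapply(ps, function(p) stats::dbinom(0:4, 4, p), numeric(5))
  best <- c(NA_real_, NA_real_); best_val <- Inf
  for (x in xs) {
    P <- (1 - x) * D2 + x * D4            # 5 x length(ps)
    pk <- P[2:5, , drop = FALSE]
    if (condition_on_detection)
      pk <- sweep(pk, 2, 1 - P[1, ], "/")
    ll <- colSums(counts * log(pmax(pk, 1e-300)))
    j <- which.max(ll)
    if (-ll[j] < best_val) { best_val <- -ll[j]; best <- c(x, ps[j]) }
  }
  start <- best; vals <- best_val

  opt <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(0, 1e-6), upper = c(1, 1),
                      control = list(factr = 1e7))
  refined <- if (opt$value <= vals) opt$par else start
  value <- min(opt$value, vals)

  # flat-likelihood diagnostic: all mass in one bin pins the fit to a boundary
  identifiable <- sum(counts > 0) > 1 ||
    (counts[1] == 0)  # a single bin k >= 2 still pins (x, p) usefully
  if (counts[1] == n) identifiable <- FALSE

  expected <- n * probs(refined[1], refined[2])
  chi2 <- sum((counts - expected)^2 / pmax(expected, .Machine$double.eps))
  dof <- max(length(counts) - 1L - 2L, 0L)

  structure(list(
    x_hat = refined[1], p_hat = refined[2],
    loglik = -value,
    chi2 = chi2, dof = dof,
    p_gof = if (dof > 0) stats::pchisq(chi2, dof, lower.tail = FALSE) else NA_real_,
    converged = opt$convergence == 0,
    identifiable = identifiable,
    conditioned_on_detection = condition_on_detection,
    counts = counts, expected = expected, n = n
  ), class = "oligomer_fit")
}

#' @export
print.oligomer_fit <- function(x, ...) {
  cat("Mixed-binomial oligomer fit (n = ", x$n, " spots",
      if (x$conditioned_on_detection) ", detection-conditioned", ")\n", sep = "")
  cat(sprintf("  tetramer fraction x = %.3f\n  active-GFP fraction p = %.3f\n",
              x$x_hat, x$p_hat))
  cat(sprintf("  logLik = %.2f, chi2 = %.2f (dof %d)\n", x$loglik, x$chi2, x$dof))
  if (!x$identifiable) cat("  WARNING: parameters not identifiable from this histogram\n")
  invisible(x)
}
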