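test_that("calibration fits interpolate exact standards", {
  two <- data.frame(anchor_value = 10^c(0.97 - 0.014 * 5, 0.97 - 0.014 * 25),
                    elution_volume_ml = c(5, 25))
  line <- fit_calibration(two, "log10_anchor")
  expect_equal(line$slope, -0.014, tolerance = 1e-9)
  expect_equal(line$intercept, 0.97, tolerance = 1e-9)

  v <- (gradient_standards + 3.92) / 5.66
  four <- data.frame(anchor_value = gradient_standards, elution_volume_ml = v)
  gl <- fit_calibration(four, "identity_anchor")
  expect_equal(gl$slope, 5.66, tolerance = 1e-9)
  expect_equal(gl$intercept, -3.92, tolerance = 1e-9)
  expect_equal(gl$r_squared, 1, tolerance = 1e-12)

  perm <- four[c(3, 1, 4, 2), ]
  gp <- fit_calibration(perm, "identity_anchor")
  expect_equal(gp$slope, gl$slope)
  expect_equal(gp$intercept, gl$intercept)

  expect_error(fit_calibration(four[1, , drop = FALSE], "identity_anchor"),
               "2 standards")
})

test_that("locate_peak finds noiseless and tied peaks", {
  v <- seq(0.2, 4.2, by = 0.2)
  prof <- elution_profile(v, 100 * exp(-(v - 2.1)^2 / (2 * 0.3^2)))
  pk <- locate_peak(prof)
  expect_equal(pk$centre, 2.1, tolerance = 1e-3)
  expect_equal(pk$se, 0.1)

  sig <- rep(0, length(v)); sig[c(10, 11)] <- 50
  tie <- locate_peak(elution_profile(v, sig))
  expect_true(tie$tie)
  expect_equal(tie$centre, mean(v[c(10, 11)]))

  expect_error(locate_peak(elution_profile(v, seq_along(v))), "monotone")
})

test_that("noisy peak location stays within one fraction of truth", {
  hits <- vapply(1:100, function(s) {
    sim <- sim_elution(5.66, -3.92, "identity_anchor",
                       gradient_standards["BSA"], sample_anchor = 7.4,
                       volumes = grad_volumes, noise_sd = 5, seed = s)
    abs(locate_peak(sim$profiles$sample)$centre - 2.0) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("inverting the printed calibration lines gives hand-derived values", {
  sec <- structure(list(slope = -0.014, intercept = 0.97, slope_se = 0.002,
                        intercept_se = 0.04, r_squared = 1, n_points = 4,
                        transform = "log10_anchor"),
                   class = "calibration_line")
  rs <- invert_calibration(sec, 20)
  expect_equal(rs$value, 10^0.69, tolerance = 1e-9)  # 4.90 nm
  grad <- structure(list(slope = 5.66, intercept = -3.92, slope_se = 0.49,
                         intercept_se = 1.31, r_squared = 1, n_points = 4,
                         transform = "identity_anchor"),
                    class = "calibration_line")
  s <- invert_calibration(grad, 2.0)
  expect_equal(s$value, 7.40, tolerance = 1e-9)
  expect_error(invert_calibration(grad, 0), "non-physical")
})

test_that("molecular weight and frictional ratio follow the standard formulas", {
  expect_equal(molecular_weight(3.48, 4.6), 67313.64, tolerance = 1e-6)
  expect_lt(abs(molecular_weight(3.48, 4.6) - 66500) / 66500, 0.05)
  expect_equal(molecular_weight(5.2, 11.3), 247085.8, tolerance = 1e-6)
  expect_error(molecular_weight(0, 5), "rs_nm")

  expect_equal(frictional_ratio(s_max(308000), 308000), 1, tolerance = 1e-12)
  expect_equal(frictional_ratio(10.97, 308000), 1.50, tolerance = 0.005)
  expect_equal(frictional_ratio(8.66, 308000), 1.90, tolerance = 0.005)

  # monotonicity
  expect_gt(molecular_weight(5, 10), molecular_weight(4, 10))
  expect_gt(molecular_weight(5, 11), molecular_weight(5, 10))
  expect_lt(frictional_ratio(12, 308000), frictional_ratio(10, 308000))
})

test_that("zero-noise round trip recovers the generative molecular weight", {
  rs_true <- 4.9; s_true <- 7.4
  sec <- sim_elution(-0.014, 0.97, "log10_anchor", sec_standards, rs_true,
                     volumes = sec_volumes, noise_sd = 0, seed = 1)
  grad <- sim_elution(5.66, -3.92, "identity_anchor", gradient_standards,
                      s_true, volumes = grad_volumes, noise_sd = 0, seed = 1)
  std <- function(sim, anchors) data.frame(
    anchor_value = anchors,
    elution_volume_ml = vapply(names(anchors), function(nm)
      locate_peak(sim$profiles[[nm]])$centre, numeric(1)))
  res <- hydrodynamic_result(std(sec, sec_standards),
                             std(grad, gradient_standards),
                             sec$profiles$sample, grad$profiles$sample)
  expect_lt(abs(res$mw_da / (4205 * rs_true * s_true) - 1), 0.005)
  expect_false(res$f_ratio_flagged)
})

test_that("noisy round trips land within propagated uncertainty", {
  rs_true <- 4.9; s_true <- 7.4
  mw_true <- 4205 * rs_true * s_true
  cover <- vapply(1:60, function(s) {
    sec <- sim_elution(-0.014, 0.97, "log10_anchor", sec_standards, rs_true,
                       volumes = sec_volumes, noise_sd = 5, seed = s)
    grad <- sim_elution(5.66, -3.92, "identity_anchor", gradient_standards,
                        s_true, volumes = grad_volumes, noise_sd = 5,
                        seed = s + 500)
    std <- function(sim, anchors) data.frame(
      anchor_value = anchors,
      elution_volume_ml = vapply(names(anchors), function(nm)
        locate_peak(sim$profiles[[nm]])$centre, numeric(1)))
    res <- suppressWarnings(
      hydrodynamic_result(std(sec, sec_standards),
                          std(grad, gradient_standards),
                          sec$profiles$sample, grad$profiles$sample))
    abs(res$mw_da - mw_true) < 2 * res$mw_se
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("calibration SE shrinks as standards are replicated", {
  set.seed(7)
  se_of <- function(reps) {
    v <- rep((gradient_standards + 3.92) / 5.66, reps)
    a <- rep(gradient_standards, reps)
    df <- data.frame(anchor_value = a,
                     elution_volume_ml = v + rnorm(length(v), 0, 0.05))
    fit_calibration(df, "identity_anchor")$slope_se
  }
  expect_gt(mean(replicate(10, se_of(2))), mean(replicate(10, se_of(8))))
})
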