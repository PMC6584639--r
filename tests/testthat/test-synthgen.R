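test_that("generators are pure functions of parameters and seed", {
  expect_identical(sim_bleach_counts(0.12, 0.8, 200, seed = 3)$counts,
                   sim_bleach_counts(0.12, 0.8, 200, seed = 3)$counts)
  expect_identical(sim_motility(10, 2, motility_truth(), seed = 9)$events,
                   sim_motility(10, 2, motility_truth(), seed = 9)$events)
  expect_identical(sim_binding_series(1, noise_cv = 0.05, seed = 2)$signal,
                   sim_binding_series(1, noise_cv = 0.05, seed = 2)$signal)
  k1 <- render_kymograph(single_run_events(), seed = 4, mt_length = 15,
                         duration = 3)
  k2 <- render_kymograph(single_run_events(), seed = 4, mt_length = 15,
                         duration = 3)
  expect_identical(k1$img, k2$img)
  # and the global RNG stream is left untouched
  set.seed(123); before <- .Random.seed
  invisible(sim_bleach_counts(0.5, 0.5, 10, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("bleach-count histograms follow the detection-conditioned pmf", {
  expect_identical(unname(sim_bleach_counts(0, 1, 10, seed = 1)$counts),
                   c(0L, 10L, 0L, 0L))
  expect_identical(unname(sim_bleach_counts(1, 1, 10, seed = 1)$counts),
                   c(0L, 0L, 0L, 10L))
  n <- 1e5
  h <- sim_bleach_counts(0.12, 0.8, n, seed = 42)
  pk <- truncated_pmf(1:4, 0.12, 0.8)
  se <- sqrt(pk * (1 - pk) / n)
  expect_true(all(abs(h$counts / n - pk) < 3 * se))
})

test_that("motility event counts follow the Poisson landing process", {
  truth0 <- motility_truth(landing_rate_true = 0)
  expect_equal(nrow(sim_motility(10, 2, truth0, seed = 1)$events), 0)
  truth1 <- motility_truth(landing_rate_true = 0.5, static_fraction = 1)
  ev <- sim_motility(10, 2, truth1, seed = 2)$events
  expect_true(all(ev$static))
  expect_true(all(ev$x1_um == ev$x0_um))
  counts <- vapply(1:500, function(s)
    nrow(sim_motility(10, 2, truth1, seed = s)$events), numeric(1))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 500))
})

test_that("run lengths are exponential, truncated at the plus end", {
  truth <- motility_truth(landing_rate_true = 2, static_fraction = 0)
  ev <- do.call(rbind, lapply(1:50, function(s)
    sim_motility(20, 3, truth, seed = s)$events))
  expect_true(all(ev$x1_um <= 20 + 1e-9))
  expect_true(all(ev$run_um >= 0))
  # censored-exponential MLE recovers the generative mean
  mle <- sum(ev$run_um) / sum(!ev$censored)
  expect_equal(mle, 8.6, tolerance = 0.1)
})

test_that("kymograph rendering matches the deposited tracks", {
  k0 <- render_kymograph(single_run_events()[0, ], noise_sd = 0,
                         mt_length = 10, duration = 1)
  expect_true(all(k0$img == 0))
  ks <- render_kymograph(single_run_events(static = TRUE), noise_sd = 0,
                         mt_length = 10, duration = 2)
  on_cols <- which(colSums(ks$img) > 0)
  peak_col <- which.max(colSums(ks$img))
  expect_lt(max(abs(on_cols - peak_col)), 8)  # one blurred stationary line
  rowmax <- apply(ks$img, 1, which.max)
  lit <- rowSums(ks$img) > 0
  expect_equal(length(unique(rowmax[lit])), 1)
})

test_that("elution peaks land exactly on the calibration lines", {
  sec <- sim_elution(-0.014, 0.97, "log10_anchor", sec_standards,
                     sample_anchor = 10^0.69, volumes = sec_volumes,
                     noise_sd = 0, seed = 1)
  expect_equal(unname(sec$centres["sample"]), 20, tolerance = 1e-9)
  grad <- sim_elution(5.66, -3.92, "identity_anchor", gradient_standards,
                      sample_anchor = 7.4, volumes = grad_volumes,
                      noise_sd = 0, seed = 1)
  expect_equal(unname(grad$centres["sample"]), 2.0, tolerance = 1e-9)
  # zero-noise round trip through the peak finder
  pk <- locate_peak(grad$profiles$sample)
  expect_lt(abs(pk$centre - 2.0), 0.05 * 0.2)
})

test_that("binding series reproduces the printed mixing arithmetic", {
  s <- sim_binding_series(1, noise_cv = 0)
  expect_equal(max(s$ligand_uM), 37 * 0.8)
  expect_equal(attr(s, "receptor_total"), 0.05)
  expect_equal(nrow(s), 16)
  expect_equal(s$ligand_uM[1] / s$ligand_uM[2], 2)
  # vanishing affinity: all signal at the free level
  weak <- sim_binding_series(1e6, noise_cv = 0, f_free = 800, f_bound = 900)
  expect_true(all(abs(weak$signal - 800) < 1e-2))
})

test_that("synthetic cell images carry their ground-truth ratios", {
  img <- sim_cell_image(c(100, 100), c(20, 20), c(10, 10))
  expect_equal(attr(img, "truth")$ratio, c(9, 9))
  er <- enrichment_ratio(img, default_region_masks())
  expect_equal(unname(er$ratio), c(9, 9))
  img2 <- sim_cell_image(c(20, 20), c(20, 20), c(10, 10))
  expect_equal(unname(enrichment_ratio(img2, default_region_masks())$ratio),
               c(1, 1))
})

test_that("podosome fields place the constructed number of coincident discs", {
  img0 <- sim_podosome_image(0, seed = 1)
  expect_equal(count_podosomes(img0)$count, 0)
  img5 <- sim_podosome_image(5, radius_px = 3, coloc_fraction = 1, seed = 2)
  expect_gte(min(attr(img5, "truth")$radius_px^2 * pi), 16)
  expect_equal(count_podosomes(img5)$count, 5)
  img35 <- sim_podosome_image(5, radius_px = 3, coloc_fraction = 0.6,
                              seed = 3)
  expect_equal(attr(img35, "truth")$n_coincident, 3)
  expect_equal(count_podosomes(img35)$count, 3)
})
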