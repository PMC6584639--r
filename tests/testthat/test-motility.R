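test_that("a rendered single run is traced to its slope", {
  k <- render_kymograph(single_run_events(), noise_sd = 0, mt_length = 15,
                        duration = 3)
  r <- trace_kymograph(k)
  expect_equal(nrow(r), 1)
  expect_lt(abs(r$speed_um_s - 0.45) / 0.45, 0.02)

  ks <- render_kymograph(single_run_events(static = TRUE), noise_sd = 0,
                         mt_length = 15, duration = 3)
  rs <- trace_kymograph(ks)
  expect_equal(nrow(rs), 1)
  expect_lt(rs$speed_um_s * 1000, 25)

  expect_equal(nrow(trace_kymograph(matrix(0, 100, 50), pixel_nm = 105,
                                    frame_s = 0.1)), 0)
})

test_that("running/static partition uses a strict 25 nm/s threshold", {
  runs <- data.frame(speed_um_s = c(0.026, 0.025, 0.024, 0.45))
  parts <- classify_runs(runs)
  expect_equal(parts$running$speed_um_s, c(0.026, 0.45))
  expect_equal(parts$static$speed_um_s, c(0.025, 0.024))
  expect_equal(nrow(parts$running) + nrow(parts$static), nrow(runs))
  empty <- classify_runs(data.frame(speed_um_s = numeric(0)))
  expect_equal(nrow(empty$running), 0)
})

test_that("landing rate is events per um per minute, pooling-invariant", {
  df <- data.frame(n_events = 10, mt_length_um = 10, duration_min = 2)
  expect_equal(landing_rate(df), 0.5)
  expect_equal(landing_rate(data.frame(n_events = 0, mt_length_um = 10,
                                       duration_min = 2)), 0)
  split2 <- data.frame(n_events = c(4, 6), mt_length_um = 10,
                       duration_min = 1)
  expect_identical(landing_rate(split2), landing_rate(df))
})

test_that("landing-rate estimation is unbiased under the Poisson model", {
  r_true <- 0.1
  truth <- motility_truth(landing_rate_true = r_true)
  obs <- lapply(1:500, function(s) sim_motility(10, 3, truth, seed = s))
  est <- landing_rate(obs)
  expo <- 500 * 10 * 3
  se <- sqrt(r_true / expo)
  expect_lt(abs(est - r_true), 3 * se)
})

test_that("summaries compute mean speed and run length of running events", {
  one <- data.frame(speed_um_s = 0.45, run_um = 4.5, censored = FALSE)
  s1 <- summarize_motility(one)
  expect_equal(s1$mean_speed, 0.45)
  expect_equal(s1$mean_run_length, 4.5)
  two <- data.frame(speed_um_s = c(0.4, 0.5), run_um = c(4, 5),
                    censored = FALSE)
  expect_equal(summarize_motility(two)$mean_speed, 0.45)
  # censoring-corrected estimate: total length over uncensored count
  cens <- data.frame(speed_um_s = c(0.4, 0.5), run_um = c(4, 6),
                     censored = c(FALSE, TRUE))
  expect_equal(summarize_motility(cens)$run_length_mle, 10)
})

test_that("speed summaries are invariant to consistent rescaling", {
  runs <- data.frame(speed_um_s = c(0.3, 0.5), run_um = c(3, 6),
                     censored = FALSE)
  scaled <- runs  # um <-> nm rescale cancels in speed = length/time
  scaled$run_um <- runs$run_um
  expect_identical(summarize_motility(runs)$mean_speed,
                   summarize_motility(scaled)$mean_speed)
  # tracing the same tracks at doubled pixel size gives the same speeds
  ev <- single_run_events()
  k1 <- trace_kymograph(render_kymograph(ev, pixel_nm = 105, noise_sd = 0,
                                         mt_length = 15, duration = 3))
  k2 <- trace_kymograph(render_kymograph(ev, pixel_nm = 210, noise_sd = 0,
                                         mt_length = 15, duration = 3))
  expect_equal(k1$speed_um_s, k2$speed_um_s, tolerance = 0.03)
})

test_that("tracing a simulated field recovers most events with few spurious", {
  truth <- motility_truth(landing_rate_true = 0.1)
  n_true <- 0; n_rec <- 0; n_traced <- 0; n_time_matched <- 0
  for (i in 1:20) {
    obs <- sim_motility(15, 3, truth, seed = 700 + i)
    r <- trace_kymograph(render_kymograph(obs, seed = 800 + i))
    evd <- obs$events
    n_true <- n_true + nrow(evd)
    n_traced <- n_traced + nrow(r)
    for (j in seq_len(nrow(evd))) {
      tm <- (evd$t0_s[j] + evd$t1_s[j]) / 2
      if (any(r$t0_s - 2 <= tm & r$t1_s + 2 >= tm)) n_rec <- n_rec + 1
    }
    for (j in seq_len(nrow(r))) {
      tm <- (r$t0_s[j] + r$t1_s[j]) / 2
      if (any(evd$t0_s - 2 <= tm & evd$t1_s + 2 >= tm))
        n_time_matched <- n_time_matched + 1
    }
  }
  expect_gte(n_rec / n_true, 0.9)
  expect_lte((n_traced - n_time_matched) / n_traced, 0.05)
})

test_that("vesicle tracks are classified by the 1.5-um displacement rule", {
  mk <- function(id, xs) data.frame(track_id = id, t_s = seq_along(xs),
                                    x_um = xs)
  tracks <- rbind(mk(1, c(0, 0.7, 1.4)),      # net 1.4 um: stationary
                  mk(2, c(0, 1.0, 2.0)),      # net +2.0: plus-end
                  mk(3, c(5, 5)),             # no movement
                  mk(4, c(3, 1)))             # net -2.0: minus-end
  cls <- classify_vesicle_tracks(tracks)
  expect_equal(unname(cls$classes$class), c("stationary", "plus_end",
                                            "stationary", "minus_end"))
  expect_equal(sum(cls$fractions), 1)
})

test_that("vesicle flux counts signed crossings per minute", {
  one <- data.frame(track_id = 1, t_s = c(0, 160), x_um = c(0, 10))
  fl <- vesicle_flux(one, location = 5, duration = 160 / 60)
  expect_equal(fl$anterograde, 1 / (160 / 60))
  expect_equal(fl$retrograde, 0)
  osc <- data.frame(track_id = 1, t_s = 1:5, x_um = c(0, 10, 0, 10, 0))
  fo <- vesicle_flux(osc, location = 5, duration = 1)
  expect_equal(unname(fo$counts), c(2, 2))
})

test_that("simulated two-condition flux ratios are recovered", {
  sim_flux_tracks <- function(n_a, n_r, seed) {
    set.seed(seed)
    mk <- function(id, dir) {
      t0 <- runif(1, 0, 100)
      data.frame(track_id = id, t_s = c(t0, t0 + 20),
                 x_um = if (dir > 0) c(0, 10) else c(10, 0))
    }
    do.call(rbind, c(lapply(seq_len(n_a), function(i) mk(i, 1)),
                     lapply(seq_len(n_r), function(i) mk(n_a + i, -1))))
  }
  ratios <- vapply(1:200, function(s) {
    set.seed(10000 + s)
    tr <- sim_flux_tracks(max(rpois(1, 20), 1), max(rpois(1, 10), 1),
                          seed = s)
    fl <- vesicle_flux(tr, location = 5, duration = 2)
    fl$anterograde / max(fl$retrograde, 1e-9)
  }, numeric(1))
  expect_lt(abs(median(ratios) - 2) / 2, 0.15)
})
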