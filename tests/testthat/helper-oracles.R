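# Brute-force oracle for the dimer/tetramer bleach-step pmf: enumerate every
# GFP activation pattern of a dimer (2^2) and a tetramer (2^4) explicitly.
brute_force_pmf <- function(k, x, p) {
  pattern_prob <- function(n) {
    pr <- numeric(n + 1)
    for (bits in 0:(2^n - 1)) {
      on <- sum(bitwAnd(bits, 2^(0:(n - 1))) > 0)
      pr[on + 1] <- pr[on + 1] + p^on * (1 - p)^(n - on)
    }
    pr
  }
  d <- pattern_prob(2)
  t4 <- pattern_prob(4)
  dk <- if (k <= 2) d[k + 1] else 0
  (1 - x) * dk + x * t4[k + 1]
}

# One synthetic processive run as an event table renderable by
# render_kymograph.
single_run_events <- function(t0 = 20, x0 = 2, speed = 0.45, run = 9,
                              static = FALSE) {
  data.frame(t0_s = t0, x0_um = x0,
             t1_s = if (static) t0 + 100 else t0 + run / speed,
             x1_um = if (static) x0 else x0 + run,
             speed_um_s = if (static) 0 else speed,
             run_um = if (static) 0 else run,
             static = static, censored = FALSE, at_end = FALSE)
}

# Elution volumes used throughout: SEC (Ve - V0) and glycerol gradient grids
# wide enough to hold every standard on the printed calibration lines.
sec_volumes <- seq(0, 40, by = 0.5)
grad_volumes <- seq(0.2, 4.2, by = 0.2)
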