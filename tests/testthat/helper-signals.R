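# Shared fixture builders: all fixtures are generated in code.

# Plain sinusoid trace: peak-to-trough A, frequency f Hz, resting level 0.
sinusoid_trace <- function(duration = 30, f = 0.2, A = 20, rate = 50,
                           xray_on = FALSE, offset = 0, ramp = 0) {
  t <- seq(0, duration, by = 1 / rate)
  amp <- (A / 2) * (1 - cos(2 * pi * f * t)) + offset + ramp * t
  breathing_trace(t, amp, xray_on, label = "sinusoid")
}

# Trapezoid wave: n_tops flat tops at `level` lasting `top_s`, linear ramps
# of `ramp_s`, baseline 0, `gap_s` between tops. Corners land on the grid.
trapezoid_trace <- function(n_tops = 3, level = 20, top_s = 6.5, ramp_s = 1,
                            gap_s = 5, lead_s = 5, rate = 50, tilt = 0) {
  block <- 2 * ramp_s + top_s + gap_s
  duration <- lead_s + n_tops * block
  t <- seq(0, duration, by = 1 / rate)
  amp <- numeric(length(t))
  for (i in seq_len(n_tops)) {
    r0 <- lead_s + (i - 1) * block
    f0 <- r0 + ramp_s; f1 <- f0 + top_s; r1 <- f1 + ramp_s
    up <- t >= r0 & t < f0
    amp[up] <- level * (t[up] - r0) / ramp_s
    flat <- t >= f0 & t <= f1
    amp[flat] <- level + tilt * (t[flat] - f0)
    dn <- t > f1 & t <= r1
    top_end <- level + tilt * top_s
    amp[dn] <- top_end * (1 - (t[dn] - f1) / ramp_s)
  }
  breathing_trace(t, amp, FALSE, label = "trapezoid")
}

# Random proper pitch pose for property tests.
random_theta <- function(n) stats::runif(n, -1.4, 1.4)
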