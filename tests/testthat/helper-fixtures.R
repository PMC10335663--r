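# shared fixture builders; everything is generated in code

make_cal <- function(R0 = 1.9, Ksv = 0.011, alpha = 0.05, id = "d1",
                     ratio_def = "larsen")
  calibration_curve(id, R0 = R0, Ksv = Ksv, alpha = alpha,
                    ratio_def = ratio_def)

make_cal_points <- function(cal, C = c(0, 20, 40, 60, 80, 100),
                            noise_sd = 0, replicates = 1) {
  C <- rep(C, times = replicates)  # repeated calibration sweeps
  R <- stern_volmer_forward(C, cal)
  if (noise_sd > 0) R <- R + rnorm(length(R), sd = noise_sd)
  data.frame(true_saturation = C, ratio = R)
}

# independent oracle: invert the quenching response by bisection on the
# forward model only
bisect_invert <- function(R, cal, hi = 1e6, tol = 1e-9) {
  uniroot(function(C) stern_volmer_forward(C, cal) - R,
          lower = 0, upper = hi, tol = tol)$root
}

# piecewise decline: exponential to t1, linear to t2, constant after,
# continuous at the joins
piecewise_decline <- function(t, c0 = 8, k = 0.12, t1 = 10, t2 = 42) {
  c1 <- c0 * exp(-k * t1)
  cfloor <- 0.31
  slope <- (c1 - cfloor) / (t2 - t1)
  ifelse(t <= t1, c0 * exp(-k * t),
         ifelse(t <= t2, c1 - slope * (t - t1), cfloor))
}

extdata <- function(f) system.file("extdata", f, package = "roptode")
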