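flat_sweep <- function(value, v = -145, dur = 1, rate = 1000)
  current_sweep(v, rep(value, dur * rate), rate)

test_that("the default protocol reproduces the voltage ladder", {
  p <- sweep_protocol()
  expect_equal(p$voltages[1], 20)
  expect_equal(p$voltages[13], -160)
  expect_true(all(diff(p$voltages) == -15))
  expect_true(-145 %in% p$voltages)
})

test_that("window currents on flat and ramp sweeps behave analytically", {
  w <- window_currents(flat_sweep(-1))
  expect_equal(unname(w), rep(-1, 3))

  # linear ramp 0 -> -1 uA with tiny windows: begin ~ 0, end ~ -1, avg -0.5
  rate <- 100000
  t <- (seq_len(rate) - 1) / rate
  ramp <- current_sweep(-145, -t, rate)
  w2 <- window_currents(ramp, settle = 0, window = 0.001)
  expect_equal(w2[["I_begin"]], 0, tolerance = 1e-3)
  expect_equal(w2[["I_end"]], -1, tolerance = 2e-3)
  expect_equal(w2[["I_avg"]], -0.5, tolerance = 1e-3)

  expect_error(window_currents(flat_sweep(-1), settle = 0.9, window = 0.2),
               "exceeds pulse duration")
})

test_that("windows on exponential sweeps match the analytic integral", {
  g <- 15; vr <- -50; f <- 0.12; tau <- 0.2; v <- -145
  rate <- 5000
  t <- (seq_len(rate) - 1) / rate
  ideal <- g * (v - vr) * ((1 - f) + f * exp(-t / tau)) / 1000
  sw <- current_sweep(v, ideal, rate)
  w <- window_currents(sw, settle = 0.025, window = 0.025)
  expect_equal(w[["I_begin"]],
               analytic_window_mean(g, vr, f, tau, v, 0.025, 0.05),
               tolerance = 1e-3)
  expect_equal(w[["I_end"]],
               analytic_window_mean(g, vr, f, tau, v, 0.975, 1.0),
               tolerance = 1e-3)
  expect_equal(w[["I_avg"]],
               analytic_window_mean(g, vr, f, tau, v, 0.025, 1.0),
               tolerance = 1e-3)
})

test_that("deactivation percentage is exact arithmetic on magnitudes", {
  expect_equal(deactivation_pct(-2.0, -1.76), 12)
  expect_equal(deactivation_pct(-1.5, -1.5), 0)
  expect_equal(deactivation_pct(2.0, 1.76), 12)  # outward convention too
  expect_warning(out <- deactivation_pct(0, -1), "zero")
  expect_true(is.na(out))
})

test_that("deactivation is gain-invariant and monotone in the fraction", {
  rate <- 2000
  t <- (seq_len(rate) - 1) / rate
  mk <- function(f, gain = 1)
    current_sweep(-145, gain * -2 * ((1 - f) + f * exp(-t / 0.2)), rate)
  pct <- function(sw) {
    w <- window_currents(sw)
    deactivation_pct(w[["I_begin"]], w[["I_end"]])
  }
  expect_equal(pct(mk(0.3)), pct(mk(0.3, gain = 7.5)), tolerance = 1e-12)
  fr <- c(0.05, 0.1, 0.2, 0.4)
  expect_true(all(diff(vapply(fr, function(f) pct(mk(f)), 0)) > 0))
})

test_that("IV normalization pins the reference point at magnitude 1", {
  sim <- simulate_recording(tevc_sim_config(noise_sd = 0, seed = 2))
  iv <- build_iv(sim$recordings)
  ref <- iv[iv$solution == "Na30K1" & iv$voltage == -145, ]
  expect_equal(abs(ref$current), 1, tolerance = 1e-12)
  # two identical cells: SD 0 everywhere
  recs2 <- c(sim$recordings,
             lapply(sim$recordings, function(r) {
               r$cell_id <- "simcell2"; r
             }))
  iv2 <- build_iv(recs2)
  expect_true(all(iv2$sd < 1e-12))
  expect_equal(iv2$current, iv$current, tolerance = 1e-12)
  # per-cell gain invariance
  recs3 <- lapply(sim$recordings, function(r) {
    r$sweeps <- lapply(r$sweeps, function(sw) {
      sw$samples <- sw$samples * 3.7; sw
    })
    r
  })
  iv3 <- build_iv(recs3)
  expect_equal(iv3$current, iv$current, tolerance = 1e-12)
  # missing reference point is an error
  expect_error(build_iv(sim$recordings["Na30K0"]), "reference")
})

test_that("linear synthetic IVs normalize to the closed form", {
  proto <- sweep_protocol()
  sols <- default_solutions()
  sols$deact_f <- 0  # pure linear IV
  sim <- simulate_recording(tevc_sim_config(solutions = sols,
                                            noise_sd = 0, seed = 4))
  iv <- build_iv(sim$recordings)
  ref_g <- sols$g_uS[sols$label == "Na30K1"]
  ref_vr <- sols$vrev_mV[sols$label == "Na30K1"]
  ref_mag <- abs(ref_g * (-145 - ref_vr) / 1000)
  for (i in seq_len(nrow(sols))) {
    pts <- iv[iv$solution == sols$label[i], ]
    expected <- sols$g_uS[i] * (pts$voltage - sols$vrev_mV[i]) / 1000 /
      ref_mag
    expect_equal(pts$current, expected, tolerance = 1e-9,
                 info = sols$label[i])
  }
})

test_that("reversal potentials interpolate, snap to zeros, and warn", {
  expect_equal(estimate_vrev(c(-60, -45), c(-0.5, 0.5)), -52.5)
  expect_equal(estimate_vrev(c(-60, -45, -30), c(-1, 0, 1)), -45)
  expect_warning(out <- estimate_vrev(c(-60, -45), c(-1, -0.5)),
                 "does not change sign")
  expect_true(is.na(out))
  expect_warning(v <- estimate_vrev(c(-60, -45, -30, -15),
                                    c(-1, 1, -0.5, 2)), "multiple")
  expect_equal(v, -30 + 0.5 / 2.5 * 15)
  # exact for piecewise-linear monotone input
  volts <- seq(-160, 20, by = 15)
  curr <- 0.02 * (volts - -52.5)
  expect_equal(estimate_vrev(volts, curr), -52.5)
})

test_that("ground-truth reversal potentials are recovered within 0.5 mV", {
  sim <- simulate_recording(tevc_sim_config(noise_sd = 0, seed = 6))
  iv <- build_iv(sim$recordings)
  for (i in seq_len(nrow(sim$truth$solutions))) {
    sol <- sim$truth$solutions[i, ]
    pts <- iv[iv$solution == sol$label, ]
    vr <- suppressWarnings(estimate_vrev(pts$voltage, pts$current))
    expect_lt(abs(vr - sol$vrev_mV), 0.5)
  }
})

test_that("semilog fits recover slope and the Nernst reference", {
  # exact line: slope 58, intercept -20
  conc <- c(0.3, 1, 3, 10, 30)
  fit <- fit_vrev_semilog(conc, 58 * log10(conc) - 20)
  expect_equal(fit$slope, 58)
  expect_equal(fit$intercept, -20)
  expect_equal(fit$residuals, rep(0, 5), tolerance = 1e-12)
  expect_equal(fit$ideal_slope, 58.6, tolerance = 0.01)  # 22 C
  # two points: exact line through both
  fit2 <- fit_vrev_semilog(c(0.3, 30), c(-120, -50))
  expect_equal(fit2$slope, 70 / 2)
  # noisy recovery
  set.seed(8)
  vr <- 55 * log10(conc) - 30 + rnorm(5, 0, 1)
  fit3 <- fit_vrev_semilog(conc, vr)
  expect_lt(abs(fit3$slope - 55), 2)
  expect_error(fit_vrev_semilog(c(10, 10), c(-40, -41)), "distinct")
  expect_error(fit_vrev_semilog(c(0, 10), c(-40, -41)), "positive")
})

test_that("recordings round-trip through sweep CSVs and manifest", {
  sim <- simulate_recording(tevc_sim_config(noise_sd = 0.01, seed = 10))
  rec <- sim$recordings$Na30K1
  dir <- withr::local_tempdir()
  mpath <- write_recording(rec, dir)
  rec2 <- read_recording(mpath)
  expect_equal(rec2$solution, rec$solution)
  expect_equal(rec2$na_mm, 30)
  expect_equal(length(rec2$sweeps), 13)
  for (k in c(1, 7, 13))
    expect_equal(rec2$sweeps[[k]]$samples, rec$sweeps[[k]]$samples,
                 tolerance = 1e-9)
  expect_equal(deactivation_stats(rec2), deactivation_stats(rec),
               tolerance = 1e-9)
})
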