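test_that("APD measurement is exact on the trapezoidal fixture", {
  fx <- make_fixture("trapezoid_ap", rise = 2, plateau = 250, fall = 60)
  for (f in c(0.9, 0.5, 1.0)) {
    apd <- measure_apd(fx$trace, recovery_fraction = f)
    expect_length(apd, 1L)
    expect_equal(as.numeric(apd), trapezoid_apd(fx, f),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
  flat <- data.frame(t = seq(0, 100, 0.5), V = rep(-85, 201))
  expect_length(measure_apd(flat), 0L)           # explicit no-capture
})

test_that("conduction velocity is exact on synthetic offset fronts", {
  fx <- make_fixture("synthetic_front", delay = 14, separation = 10)
  cv <- measure_cv(fx$trace_a, fx$trace_b, fx$separation)
  expect_equal(as.numeric(cv), 10 / 14, tolerance = 1e-6)
  same <- measure_cv(fx$trace_a, fx$trace_a, 10)
  expect_true(is.na(same))
  expect_true(attr(same, "no_capture"))
  flat <- data.frame(t = fx$trace_a$t, V = rep(-85, nrow(fx$trace_a)))
  expect_true(is.na(measure_cv(flat, fx$trace_b, 10)))
})

test_that("tip tracker recovers prescribed centre and drift on synthetic fields", {
  fx <- make_fixture("rotating_field", period = 120, duration = 480,
                     center = c(20, 20), drift = c(0, 0))
  traj <- track_tip(fx$frames, fx$times, fx$nx, fx$ny, fx$hs, v_iso = 0)
  expect_gt(nrow(traj), 50)
  expect_lt(abs(mean(traj$x) - 20), fx$hs / 2)   # centre within half a cell
  expect_lt(abs(mean(traj$y) - 20), fx$hs / 2)
  fx2 <- make_fixture("rotating_field", period = 120, duration = 480,
                      center = c(15, 20), drift = c(0.01, 0.005))
  tr2 <- track_tip(fx2$frames, fx2$times, fx2$nx, fx2$ny, fx2$hs, v_iso = 0)
  v <- coef(lm(cbind(x, y) ~ t, data = tr2))[2, ]
  expect_lt(abs(v[[1]] - 0.01) / 0.01, 0.05)     # drift within 5%
  expect_lt(abs(v[[2]] - 0.005) / 0.005, 0.05)
  uni <- matrix(-80, 41 * 41, 5)
  expect_identical(nrow(track_tip(uni, seq(0, 16, 4), 41, 41, 0.5)), 0L)
})

test_that("spiral metrics recover circle and cycloid parameters", {
  t <- seq(0, 1200, by = 4)
  r0 <- 3.2; T0 <- 240
  circ <- data.frame(t = t, x = 20 + r0 * cos(2 * pi * t / T0),
                     y = 25 + r0 * sin(2 * pi * t / T0))
  m <- spiral_metrics(circ)
  expect_equal(m$core_radius, r0, tolerance = 0.02)
  expect_equal(m$period, T0, tolerance = 0.02 * T0)
  expect_lt(m$drift_velocity, 0.4)               # mm/s; essentially static
  vdrift <- 0.004                                # mm/ms
  cyc <- data.frame(t = t, x = circ$x + vdrift * t, y = circ$y)
  m2 <- spiral_metrics(cyc)
  expect_lt(abs(m2$drift_velocity - vdrift * 1000) / (vdrift * 1000), 0.05)
  expect_equal(m2$core_radius, r0, tolerance = 0.1 * r0)
  one <- circ[t <= T0, ]
  expect_error(spiral_metrics(one), "rotations")
})

test_that("a single plane wave traverses the sheet and the medium recovers", {
  r <- cached("single_wave", {
    run_paced_sheet(paced_cell(), period = 600, n_beats = 1L, nx = 61, ny = 21,
                    mode = "constant_stretch", lambda = 1, params = tp())
  })
  arr_c <- arrival_times(r$trace_center)
  arr_d <- arrival_times(r$trace_down)
  expect_length(arr_c, 1L)
  expect_length(arr_d, 1L)
  expect_gt(arr_d, arr_c)                        # propagates left to right
  expect_true(all(r$state$V < -75))              # terminal quiescence
  # CV self-consistency across two probe separations
  cv1 <- measure_cv(r$trace_center, r$trace_down, r$probe_sep)
  st <- r$state
  expect_gt(cv1, 0.3); expect_lt(cv1, 1.0)       # physiological range
})

test_that("stretch waveform fixture keeps a resting cell free of SAC current", {
  wf <- make_fixture("stretch_waveform", duration = 100, lambda_min = 1,
                     lambda_rest = 1)
  expect_true(all(wf$lambda == 1))
  cur <- isac(wf$lambda, -85, sac_params(gs = 0.03))
  expect_true(all(cur == 0))
  wf2 <- make_fixture("stretch_waveform", lambda_min = 0.92)
  expect_equal(min(wf2$lambda), 0.92, tolerance = 1e-6)
  expect_equal(wf2$lambda[1], 1)
})
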