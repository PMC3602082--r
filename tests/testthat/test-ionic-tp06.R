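test_that("relaxed resting state is a current equilibrium", {
  p <- tp()
  r <- run_cell(tp06_initial_state(), duration = 10000, dt = 0.02, params = p,
                record_every = 0L)
  cur <- tp06_currents(r$state, p)
  expect_lt(abs(cur$I_tot), 1e-3)
  # total is the sum of the components (to summation round-off)
  parts <- unlist(cur[setdiff(names(cur), "I_tot")])
  expect_equal(cur$I_tot, sum(parts), tolerance = 1e-8)
})

test_that("external currents pass through additively", {
  s <- tp06_initial_state()
  p <- tp()
  base <- tp06_currents(s, p)
  withsac <- tp06_currents(s, p, i_sac = -1.25)
  expect_identical(withsac$I_tot - base$I_tot, -1.25)
  withstim <- tp06_currents(s, p, i_stim = -52)
  expect_identical(withstim$I_tot - base$I_tot, -52)
})

test_that("invalid states are rejected with a diagnostic", {
  s <- tp06_initial_state()
  s[["Ca_i"]] <- NaN
  expect_error(tp06_currents(s, tp()), "Ca_i")
  s2 <- tp06_initial_state()
  s2[["m"]] <- 1.5
  expect_error(tp06_step(s2, tp()), "\\[0,1\\]")
  expect_error(tp06_step(tp06_initial_state(), tp(), dt = -0.01), "positive")
  expect_error(tp06_step(tp06_initial_state(), tp(), dt = 0.2), "validated")
})

test_that("unstimulated cell stays at rest over long integration", {
  p <- tp()
  s0 <- run_cell(tp06_initial_state(), 5000, params = p, record_every = 0L)$state
  r <- run_cell(s0, 5000, params = p, record_every = 0L)
  expect_lt(abs(r$state[["V"]] - s0[["V"]]), 0.5)
  # 1000 explicit steps drift by much less
  r2 <- run_cell(s0, 1000 * 0.02, params = p, record_every = 0L)
  expect_lt(abs(r2$state[["V"]] - s0[["V"]]), 0.05)
})

test_that("supra-threshold stimulus elicits an action potential upstroke", {
  r <- run_cell(tp06_initial_state(), 20, params = tp(),
                stim = list(list(t0 = 2, dur = 1, amp = -52)),
                record_every = 5L)
  expect_gt(max(r$trace$V), 0)
  expect_lt(r$trace$t[min(which(r$trace$V > 0))], 10)
})

test_that("gates remain in [0,1] along an action potential", {
  p <- tp()
  s <- paced_cell()
  gate_names <- c("m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
                  "xr1", "xr2", "xs")
  for (dur in c(1, 5, 50, 200, 350)) {
    r <- run_cell(s, dur, params = p, vset = list(list(t = 0, v = 0)),
                  record_every = 0L)
    g <- r$state[gate_names]
    expect_true(all(g >= 0 & g <= 1))
  }
})

test_that("explicit scheme converges at first order in dt", {
  # forward-Euler gate mode at reduced step sizes; error against a
  # quarter-step reference halves when dt halves
  p <- tp06_params(gates = "euler")
  s <- paced_cell()
  stim <- list(list(t0 = 1, dur = 1, amp = -52))
  run_at <- function(dt) run_cell(s, 50, dt = dt, params = p, stim = stim,
                                  record_every = 0L)$state
  ref <- run_at(0.0005)
  e1 <- max(abs(run_at(0.002) - ref))
  e2 <- max(abs(run_at(0.001) - ref))
  # Richardson: with a quarter-step reference the observed ratio for a
  # first-order scheme is (e(2h))/(e(h)) ~ 2 within discretisation noise
  expect_gt(e1 / e2, 1.5)
  expect_lt(e1 / e2, 3.0)
})

test_that("pacing converges to a calcium fixed point", {
  p <- tp()
  expect_identical(pace_to_steady_state(1000, n_beats = 0L, params = p),
                   tp06_initial_state())
  st <- suppressWarnings(pace_to_steady_state(1000, n_beats = 60L, params = p,
                                              rel_tol = 2e-3))
  peaks <- attr(st, "peak_ca")
  # plateau: late beat-to-beat changes are small
  expect_lt(abs(tail(peaks, 1) - tail(peaks, 2)[1]) / tail(peaks, 1), 5e-3)
  # fixed-point property: one more beat reproduces its own peak [Ca2+]_i;
  # the returned state is sampled at the calcium peak of the final beat
  t_next <- 1000 - attr(st, "t_peak")     # due time of the next stimulus
  r <- run_cell(st, 1000, params = p, vset = list(list(t = t_next, v = 0)),
                record_every = 10L)
  expect_lt(abs(max(r$trace$Ca_i) - tail(peaks, 1)) / tail(peaks, 1), 2e-2)
  expect_error(pace_to_steady_state(100, n_beats = 5L, params = p),
               "refractory")
})
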