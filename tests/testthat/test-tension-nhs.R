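test_that("tension relaxes to ~0 at diastolic calcium", {
  np <- nhs_params()
  s <- nhs_initial_state(params = np)
  tlv <- NA
  for (i in 1:20000) {
    out <- nhs_step(s, ca_i = 7e-5, lambda = 1, dt = 0.02, params = np)
    s <- out$state
    tlv <- out$T_lv
  }
  expect_lt(tlv, 0.02 * np[["T_ref"]])
  expect_identical(t_lv(0, 1, np), 0)          # no crossbridges, no tension
  expect_gt(t_lv(0.5, 1, np), 0)
})

test_that("a calcium step produces a monotone, saturating rise of z", {
  np <- nhs_params()
  s <- nhs_initial_state(params = np)
  z <- numeric(400)
  for (i in seq_along(z)) {
    s <- nhs_step(s, ca_i = 2e-3, lambda = 1, dt = 1, params = np)$state
    z[i] <- s[["z"]]
  }
  expect_true(all(diff(z) > -1e-12))
  # saturation: late increments much smaller than early ones
  expect_lt(z[400] - z[300], 0.02 * (z[100] - z[1]))
  expect_lt(z[400], 1)
  expect_error(nhs_step(s, ca_i = -1, lambda = 1, params = np), "positive")
  expect_error(nhs_step(s, ca_i = 1e-3, lambda = -2, params = np), "positive")
})

test_that("scaling factors have the quiescent limit and expected monotonicity", {
  np <- nhs_params()
  s <- nhs_initial_state(params = np)
  sc <- update_scaling(s, lambda = 1, dlambda_dt = 0, params = np)
  expect_equal(sc$g_len, 1)
  expect_equal(sc$h_vel, 1)
  lams <- seq(0.85, 1.15, by = 0.025)
  g <- vapply(lams, function(l) update_scaling(s, l, 0, params = np)$g_len, 0)
  expect_true(all(diff(g) >= 0))
  # force-velocity depression: shortening reduces the velocity factor
  h0 <- update_scaling(s, 1, 0, params = np)$h_vel
  hneg <- update_scaling(s, 1, -0.002, params = np)$h_vel
  expect_lte(hneg, h0)
  # determinism: identical inputs give identical outputs
  expect_identical(update_scaling(s, 1.05, 1e-3, params = np),
                   update_scaling(s, 1.05, 1e-3, params = np))
})

test_that("total tension composes the factors and floors at zero", {
  expect_identical(total_tension(0, 1.3, 0.8), 0)
  expect_identical(total_tension(42, 1, 1), 42)
  expect_warning(ta <- total_tension(10, 1, -0.2), "floored")
  expect_identical(ta, 0)
  expect_error(total_tension(-1, 1, 1))
})

test_that("isometric twitch events order as upstroke, calcium peak, tension peak", {
  p <- tp()
  r <- run_cell(paced_cell(), 500, params = p, lambda = 1,
                vset = list(list(t = 5, v = 0)),
                nhs = list(params = nhs_params()), record_every = 10L)
  tr <- r$trace
  t_up <- tr$t[min(which(tr$V > 0))]
  t_ca <- tr$t[which.max(tr$Ca_i)]
  t_ta <- tr$t[which.max(tr$Ta)]
  expect_lt(t_up, t_ca)
  expect_lt(t_ca, t_ta)            # tension peak lags the calcium transient
  expect_gt(max(tr$Ta), 5)         # a real twitch develops
  # isometric limit: lambda pinned at 1 keeps h at rest, Ta == T_lv * g(1)
  expect_equal(max(tr$Ta), max(tr$T_lv), tolerance = 1e-10)
})
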