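# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is deterministic (the model has no randomness), so caching
# changes nothing but wall time.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tp <- function() cached("tp", tp06_params())

# diastolic working-cell state after short conditioning (shared by all
# tissue tests; 25 beats is enough for the qualitative suites)
paced_cell <- function() cached("paced_cell", suppressWarnings(
  paced_initial_state(1000, n_beats = 60, params = tp(), rel_tol = 2e-3)))

# small constant-stretch sheet run: conditioning + measured beats at a probe
cs_sheet <- function(gs, period = 600, lambda = 1.1, n_beats = 4L,
                     record_from = 2 * 600) {
  cached(sprintf("cs_%g_%g_%g", gs, period, lambda), {
    run_paced_sheet(paced_cell(), period = period, n_beats = n_beats,
                    nx = 61, ny = 21, mode = "constant_stretch",
                    sac = sac_params(gs = gs), lambda = lambda, params = tp(),
                    record_from = record_from)
  })
}

# contracting counterpart (smaller, mechanics on)
ct_sheet <- function(gs, period = 600, n_beats = 4L, record_from = 2 * 600) {
  cached(sprintf("ct_%g_%g", gs, period), {
    run_paced_sheet(paced_cell(), period = period, n_beats = n_beats,
                    nx = 61, ny = 31, mode = "contracting",
                    sac = sac_params(gs = gs), params = tp(),
                    record_from = record_from)
  })
}

expect_monotone <- function(x, decreasing = FALSE, label = "sequence") {
  d <- diff(x)
  if (decreasing) {
    expect_true(all(d < 0), label = sprintf("%s strictly decreasing", label))
  } else {
    expect_true(all(d > 0), label = sprintf("%s strictly increasing", label))
  }
}

# ---- shared spiral machinery (used by the convergence-robustness and
# spiral-dynamics suites) ----

spiral_init101 <- function() cached("spiral_init101", {
  s1s2_spiral_init(paced_cell(), nx = 101, ny = 101, hs = 0.5,
                   mode = "contracting", params = tp(),
                   s2_window = c(345, 355, 335, 365), cond_ms = 600)
})

spiral_run_cached <- function(mode, gs, duration) {
  cached(sprintf("spiral_%s_%g_%g", mode, gs, duration), {
    spiral_run(spiral_init101(), mode = mode, gs = gs, duration = duration,
               lambda = 1.1)
  })
}

# rotation count (heading winding), net displacement of the rotation-averaged
# centre, and RMS core radius over a possibly short window
spiral_summary <- function(traj, lag_mm = 0.75) {
  t <- traj$t; x <- traj$x; y <- traj$y
  n <- length(t)
  lag <- 1L
  repeat {
    dx <- x[(1 + lag):n] - x[1:(n - lag)]
    dy <- y[(1 + lag):n] - y[1:(n - lag)]
    if (stats::median(sqrt(dx^2 + dy^2)) >= lag_mm || lag > n %/% 4) break
    lag <- lag + 1L
  }
  th <- atan2(dy, dx)
  d <- diff(th); d <- d - 2 * pi * round(d / (2 * pi))
  rotations <- abs(sum(d)) / (2 * pi)
  window <- t[n] - t[1]
  period <- window / rotations
  half <- period / 2
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    w <- which(t >= t[i] - half & t <= t[i] + half)
    cx[i] <- mean(x[w]); cy[i] <- mean(y[w])
  }
  ok <- t >= t[1] + half & t <= t[n] - half
  if (sum(ok) < 4) ok <- rep(TRUE, n)
  i1 <- which(ok)[1]; i2 <- rev(which(ok))[1]
  disp <- sqrt((cx[i2] - cx[i1])^2 + (cy[i2] - cy[i1])^2)
  list(rotations = rotations, period = period,
       displacement = disp, duration = t[i2] - t[i1],
       disp_per_rotation = disp / (rotations * (t[i2] - t[i1]) / window),
       core_radius = sqrt(mean((x - cx)[ok]^2 + (y - cy)[ok]^2)))
}
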