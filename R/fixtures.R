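#' Deterministic synthetic fixtures
#'
#' Constructs the synthetic inputs used by the measurement oracles: a rigidly
#' rotating (optionally drifting) spiral phase field with known centre,
#' period and drift; a trapezoidal action potential with analytically known
#' APD; a twitch-like prescribed stretch waveform; and a pair of offset
#' synthetic wavefront traces for CV checks. All fixtures are fully
#' determined by their parameters (`seed` is reserved for future noise
#' studies and unused).
#'
#' @param kind one of `"rotating_field"`, `"trapezoid_ap"`,
#'   `"stretch_waveform"`, `"synthetic_front"`
#' @param ... kind-specific parameters, see Details
#' @param seed unused placeholder (fixtures are deterministic)
#'
#' @details
#' `rotating_field`: `nx, ny, hs, period, duration, frame_ms, center (mm),
#' drift (mm/ms vector), wavelength (mm), v_amp, v_off`. Produces frames of
#' `v_off + v_amp * cos(theta - omega t + 2 pi r / wavelength)` around the
#' moving centre — an Archimedean spiral rotating rigidly at the prescribed
#' period.
#'
#' `trapezoid_ap`: `baseline, peak, t_up, rise, plateau, fall, duration,
#' dt_samp`. The analytic APD at recovery fraction f is
#' `rise*f + plateau + fall*(1 - (1-f)) ... ` computed by
#' [trapezoid_apd()].
#'
#' `stretch_waveform`: `duration, dt, t_on, t_off, lambda_min, lambda_rest`;
#' a smooth (cosine-ramp) shortening episode mimicking the stretch course of
#' a contracting cell.
#'
#' `synthetic_front`: `delay, separation, duration, dt_samp, baseline, peak`;
#' two sigmoidal upstroke traces offset by `delay`.
#' @return kind-specific list
#' @export
make_fixture <- function(kind = c("rotating_field", "trapezoid_ap",
                                  "stretch_waveform", "synthetic_front"),
                         ..., seed = NULL) {
  kind <- match.arg(kind)
  args <- list(...)
  switch(kind,
    rotating_field = do.call(.fx_rotating_field, args),
    trapezoid_ap = do.call(.fx_trapezoid_ap, args),
    stretch_waveform = do.call(.fx_stretch_waveform, args),
    synthetic_front = do.call(.fx_synthetic_front, args))
}

.fx_rotating_field <- function(nx = 81, ny = 81, hs = 0.5, period = 120,
                               duration = 400, frame_ms = 4,
                               center = c(20, 20), drift = c(0, 0),
                               wavelength = 20, v_amp = 50, v_off = -25) {
  times <- seq(0, duration, by = frame_ms)
  gx <- rep((seq_len(nx) - 1) * hs, ny)
  gy <- rep((seq_len(ny) - 1) * hs, each = nx)
  om <- 2 * pi / period
  frames <- vapply(times, function(t) {
    cx <- center[1] + drift[1] * t
    cy <- center[2] + drift[2] * t
    dx <- gx - cx; dy <- gy - cy
    r <- sqrt(dx^2 + dy^2)
    v_off + v_amp * cos(atan2(dy, dx) - om * t + 2 * pi * r / wavelength)
  }, numeric(nx * ny))
  list(frames = frames, times = times, nx = nx, ny = ny, hs = hs,
       period = period, center = center, drift = drift)
}

.fx_trapezoid_ap <- function(baseline = -85, peak = 40, t_up = 50, rise = 2,
                             plateau = 250, fall = 60, duration = 500,
                             dt_samp = 0.5) {
  t <- seq(0, duration, by = dt_samp)
  V <- rep(baseline, length(t))
  V[t >= t_up & t < t_up + rise] <-
    baseline + (peak - baseline) * (t[t >= t_up & t < t_up + rise] - t_up) / rise
  V[t >= t_up + rise & t < t_up + rise + plateau] <- peak
  idx <- t >= t_up + rise + plateau & t < t_up + rise + plateau + fall
  V[idx] <- peak - (peak - baseline) *
    (t[idx] - t_up - rise - plateau) / fall
  list(trace = data.frame(t = t, V = V), baseline = baseline, peak = peak,
       t_up = t_up, rise = rise, plateau = plateau, fall = fall)
}

#' Analytic APD of the trapezoidal fixture
#' @param fx fixture from `make_fixture("trapezoid_ap")`
#' @param recovery_fraction recovery fraction
#' @return APD (ms)
#' @export
trapezoid_apd <- function(fx, recovery_fraction = 0.9) {
  f <- recovery_fraction
  # level L = baseline + (1-f)*amp; crossing during rise and during fall
  t1 <- fx$t_up + fx$rise * (1 - f)
  t2 <- fx$t_up + fx$rise + fx$plateau + fx$fall * f
  t2 - t1
}

.fx_stretch_waveform <- function(duration = 600, dt = 0.02, t_on = 60,
                                 t_off = 360, lambda_min = 0.92,
                                 lambda_rest = 1) {
  t <- seq(0, duration - dt, by = dt)
  lam <- rep(lambda_rest, length(t))
  inside <- t >= t_on & t <= t_off
  ph <- (t[inside] - t_on) / (t_off - t_on)
  lam[inside] <- lambda_rest - (lambda_rest - lambda_min) * sin(pi * ph)^2
  list(t = t, lambda = lam, dt = dt)
}

.fx_synthetic_front <- function(delay = 14, separation = 10, duration = 60,
                                dt_samp = 0.1, baseline = -85, peak = 20,
                                t0 = 20, width = 1) {
  t <- seq(0, duration, by = dt_samp)
  up <- function(tc) baseline + (peak - baseline) / (1 + exp(-(t - tc) / width))
  list(trace_a = data.frame(t = t, V = up(t0)),
       trace_b = data.frame(t = t, V = up(t0 + delay)),
       delay = delay, separation = separation)
}
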