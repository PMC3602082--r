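#' Action potential duration from a voltage trace
#'
#' Segments the trace into action potentials at upward crossings of
#' `detect_threshold`. For each AP the baseline is the pre-upstroke
#' (diastolic) voltage, the amplitude is peak minus baseline, and the
#' recovery level is `baseline + (1 - recovery_fraction) * amplitude`. APD is
#' the time between the interpolated upward and downward crossings of that
#' level, so `recovery_fraction = 0.9` is APD90 and `1.0` measures the full
#' return to baseline.
#'
#' @param trace data.frame with columns `t` (ms, strictly increasing) and `V`
#' @param recovery_fraction recovery fraction (default APD90)
#' @param detect_threshold upstroke detection level (mV)
#' @return numeric vector of APDs (ms), one per complete AP, with attribute
#'   `t_up` (upstroke times); length 0 when no AP is captured
#' @export
measure_apd <- function(trace, recovery_fraction = 0.9,
                        detect_threshold = -20) {
  t <- trace$t; V <- trace$V
  stopifnot(length(t) >= 2, !is.unsorted(t, strictly = TRUE))
  up <- which(V[-length(V)] < detect_threshold & V[-1] >= detect_threshold)
  if (!length(up)) {
    out <- numeric(0); attr(out, "t_up") <- numeric(0)
    return(out)
  }
  apds <- t_ups <- numeric(0)
  bounds <- c(1L, up, length(V))
  for (k in seq_along(up)) {
    i_pre0 <- bounds[k]                  # start of diastolic segment
    i_up <- up[k]
    i_end <- if (k < length(up)) up[k + 1] else length(V)
    base <- min(V[i_pre0:i_up])
    peak <- max(V[i_up:i_end])
    amp <- peak - base
    if (amp < 10) next                   # not an action potential
    lev <- base + (1 - recovery_fraction) * amp
    # upstroke crossing of the recovery level (search backward from detect)
    iu <- i_up
    while (iu > i_pre0 && V[iu] > lev) iu <- iu - 1L
    if (V[iu] > lev) next
    tu <- .lin_cross(t[iu], V[iu], t[iu + 1], V[iu + 1], lev)
    # repolarization crossing after the peak
    ipk <- i_up - 1L + which.max(V[i_up:i_end])
    seg <- ipk:i_end
    dn <- which(V[seg[-length(seg)]] > lev & V[seg[-1]] <= lev)
    if (!length(dn)) next                # incomplete AP
    i1 <- seg[dn[1]]
    tr_ <- .lin_cross(t[i1], V[i1], t[i1 + 1], V[i1 + 1], lev)
    apds <- c(apds, tr_ - tu)
    t_ups <- c(t_ups, tu)
  }
  attr(apds, "t_up") <- t_ups
  apds
}

.lin_cross <- function(t1, v1, t2, v2, lev) {
  if (v2 == v1) return(t1)
  t1 + (lev - v1) / (v2 - v1) * (t2 - t1)
}

#' Upstroke arrival times in a trace
#' @param trace data.frame with `t`, `V`
#' @param threshold crossing level (mV)
#' @return interpolated upward crossing times (ms)
#' @export
arrival_times <- function(trace, threshold = -20) {
  t <- trace$t; V <- trace$V
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  vapply(up, function(i) .lin_cross(t[i], V[i], t[i + 1], V[i + 1], threshold),
         numeric(1))
}

#' Conduction velocity from two probe traces
#'
#' Separation divided by the difference of upstroke threshold-crossing times
#' of the same (by default the last common) wave. In a contracting medium
#' this is an average velocity over the probe separation, since the local
#' velocity depends on position.
#'
#' @param trace_a,trace_b probe traces (data.frames with `t`, `V`);
#'   `trace_b` is downstream of `trace_a`
#' @param separation probe separation (mm)
#' @param threshold upstroke crossing level (mV)
#' @param wave index of the wave to use (`NULL` = last common)
#' @return CV (mm/ms), or `NA` with attribute `no_capture = TRUE` when either
#'   probe misses the wave or the delay is not resolvable
#' @export
measure_cv <- function(trace_a, trace_b, separation, threshold = -20,
                       wave = NULL) {
  ta <- arrival_times(trace_a, threshold)
  tb <- arrival_times(trace_b, threshold)
  n <- min(length(ta), length(tb))
  if (n == 0) return(structure(NA_real_, no_capture = TRUE))
  k <- if (is.null(wave)) n else wave
  if (k > n) return(structure(NA_real_, no_capture = TRUE))
  dt <- tb[k] - ta[k]
  if (!is.finite(dt) || dt <= 0) return(structure(NA_real_, no_capture = TRUE))
  separation / dt
}

#' Spiral tip positions by isoline intersection
#'
#' The tip is the intersection of the `V = v_iso` isoline with the `dV/dt = 0`
#' isoline, located sub-cell by solving the two bilinear interpolants in each
#' grid cell where both fields change sign. Consecutive tips are linked by
#' nearest match; frames with no (or unlinkable) intersections are recorded
#' as gaps, never fabricated.
#'
#' @param frames matrix (n_nodes x n_frames) of V fields
#' @param times frame times (ms, uniform)
#' @param nx,ny grid dimensions
#' @param hs grid spacing (mm)
#' @param v_iso isoline potential (mV)
#' @return data.frame of class `tip_trajectory` with `t`, `x`, `y` (mm);
#'   attribute `n_candidates` per frame
#' @export
track_tip <- function(frames, times, nx, ny, hs = 0.5, v_iso = -40) {
  nf <- ncol(frames)
  stopifnot(nf >= 3, nrow(frames) == nx * ny)
  dtf <- times[2] - times[1]
  res <- vector("list", nf)
  ncand <- integer(nf)
  prev_xy <- NULL
  for (k in 2:(nf - 1)) {
    Vk <- matrix(frames[, k], nx, ny)
    Dk <- matrix((frames[, k + 1] - frames[, k - 1]) / (2 * dtf), nx, ny)
    pts <- .isoline_intersections(Vk - v_iso, Dk)
    ncand[k] <- nrow(pts)
    if (nrow(pts) == 0) next
    xy <- cbind((pts[, 1] - 1) * hs, (pts[, 2] - 1) * hs)
    pick <- if (is.null(prev_xy)) {
      # start from the intersection farthest from the boundary
      bdist <- pmin(xy[, 1], (nx - 1) * hs - xy[, 1],
                    xy[, 2], (ny - 1) * hs - xy[, 2])
      which.max(bdist)
    } else {
      d2 <- (xy[, 1] - prev_xy[1])^2 + (xy[, 2] - prev_xy[2])^2
      if (min(d2) > (10 * hs)^2) NA_integer_ else which.min(d2)
    }
    if (is.na(pick)) next
    prev_xy <- xy[pick, ]
    res[[k]] <- c(times[k], prev_xy)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) out <- matrix(numeric(0), 0, 3)
  out <- as.data.frame(out)
  names(out) <- c("t", "x", "y")
  class(out) <- c("tip_trajectory", class(out))
  attr(out, "n_candidates") <- ncand
  out
}

# zero-contour intersections of two bilinear fields; returns (ix, iy) in
# 1-based fractional grid coordinates
.isoline_intersections <- function(Fm, Gm) {
  nx <- nrow(Fm); ny <- ncol(Fm)
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  id00 <- cbind(i, j); id10 <- cbind(i + 1, j)
  id01 <- cbind(i, j + 1); id11 <- cbind(i + 1, j + 1)
  f00 <- Fm[id00]; f10 <- Fm[id10]; f01 <- Fm[id01]; f11 <- Fm[id11]
  g00 <- Gm[id00]; g10 <- Gm[id10]; g01 <- Gm[id01]; g11 <- Gm[id11]
  fs <- sign(f00) + sign(f10) + sign(f01) + sign(f11)
  gs <- sign(g00) + sign(g10) + sign(g01) + sign(g11)
  cand <- which(abs(fs) < 4 & abs(gs) < 4)
  out <- matrix(numeric(0), 0, 2)
  for (c0 in cand) {
    a1 <- f00[c0]; b1 <- f10[c0] - f00[c0]; c1 <- f01[c0] - f00[c0]
    d1 <- f11[c0] - f10[c0] - f01[c0] + f00[c0]
    a2 <- g00[c0]; b2 <- g10[c0] - g00[c0]; c2 <- g01[c0] - g00[c0]
    d2 <- g11[c0] - g10[c0] - g01[c0] + g00[c0]
    al <- b2 * d1 - d2 * b1
    be <- a2 * d1 + b2 * c1 - c2 * b1 - d2 * a1
    ga <- a2 * c1 - c2 * a1
    xs <- if (abs(al) < 1e-14) {
      if (abs(be) < 1e-14) numeric(0) else -ga / be
    } else {
      disc <- be^2 - 4 * al * ga
      if (disc < 0) numeric(0)
      else (-be + c(1, -1) * sqrt(disc)) / (2 * al)
    }
    for (x in xs) {
      if (!is.finite(x) || x < 0 || x > 1) next
      den <- c1 + d1 * x
      if (abs(den) < 1e-14) next
      y <- -(a1 + b1 * x) / den
      if (!is.finite(y) || y < 0 || y > 1) next
      out <- rbind(out, c(i[c0] + x, j[c0] + y))
    }
  }
  out
}

#' Core radius, rotation period, and drift velocity of a spiral tip
#'
#' The rotation-averaged tip centre gives the core trajectory; drift velocity
#' is the net displacement of that centre over the analysis window divided by
#' its duration. Tip positions corrected for the core drift give the core
#' radius (RMS distance from the moving centre); the period is measured from
#' the last full rotation of the drift-corrected tip angle.
#'
#' @param traj `tip_trajectory` (needs at least 2 full rotations)
#' @return list with `core_radius` (mm), `period` (ms), `drift_velocity`
#'   (mm/s), `drift_direction` (radians), `rotations`
#' @export
spiral_metrics <- function(traj, min_step = 0.75) {
  if (nrow(traj) < 8) stop("trajectory too short: ", nrow(traj), " points")
  t <- traj$t; x <- traj$x; y <- traj$y
  n <- length(t)
  # rotation count from the winding of the tip heading, which is robust to
  # core meander and drift; the differencing lag adapts to tracker jitter
  lag <- 1L
  repeat {
    dx <- x[(1 + lag):n] - x[1:(n - lag)]
    dy <- y[(1 + lag):n] - y[1:(n - lag)]
    if (stats::median(sqrt(dx^2 + dy^2)) >= min_step || lag > n %/% 4) break
    lag <- lag + 1L
  }
  th <- .unwrap(atan2(dy, dx))
  tm <- (t[(1 + lag):n] + t[1:(n - lag)]) / 2
  rot_total <- abs(th[length(th)] - th[1]) / (2 * pi)
  if (rot_total < 2)
    stop(sprintf("only %.2f rotations captured; need at least 2", rot_total))
  dur_all <- tm[length(tm)] - tm[1]
  # period of the last full rotation of the heading
  th_end <- th[length(th)]
  tgt <- th_end - sign(th_end - th[1]) * 2 * pi
  idx <- if (th_end > th[1]) max(which(th <= tgt)) else max(which(th >= tgt))
  tt <- stats::approx(th[idx:(idx + 1)], tm[idx:(idx + 1)], xout = tgt,
                      ties = "ordered")$y
  period <- tm[length(tm)] - tt
  # rotation-averaged moving centre -> drift and drift-corrected core radius
  half <- (dur_all / rot_total) / 2
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    w <- which(t >= t[i] - half & t <= t[i] + half)
    cx[i] <- mean(x[w]); cy[i] <- mean(y[w])
  }
  ok <- t >= t[1] + half & t <= t[n] - half
  if (sum(ok) < 4) ok <- rep(TRUE, n)
  i1 <- which(ok)[1]; i2 <- rev(which(ok))[1]
  dur <- t[i2] - t[i1]
  vx <- (cx[i2] - cx[i1]) / dur; vy <- (cy[i2] - cy[i1]) / dur
  drift <- sqrt(vx^2 + vy^2) * 1000          # mm/ms -> mm/s
  rx <- x - cx; ry <- y - cy
  core_radius <- sqrt(mean(rx[ok]^2 + ry[ok]^2))
  list(core_radius = core_radius, period = period, drift_velocity = drift,
       drift_direction = atan2(vy, vx), rotations = rot_total,
       center_path = data.frame(t = t[ok], x = cx[ok], y = cy[ok]))
}

.unwrap <- function(th) {
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(th[1], d))
}
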