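#' Diastolic working-cell state after pacing
#'
#' Paces a single cell to steady calcium dynamics and returns the state at
#' end-diastole of the final beat (just before the next stimulus would
#' arrive). Tissue runs start every node from this state so that calcium
#' handling reflects a working cell rather than the quiescent resting state.
#'
#' @inheritParams pace_to_steady_state
#' @return `cell_state` at end-diastole; carries the pacing attributes of
#'   [pace_to_steady_state()]
#' @export
paced_initial_state <- function(period = 1000, n_beats = 100L,
                                params = tp06_params(), dt = 0.02,
                                stim_spec = list(mode = "vset", v = 0),
                                rel_tol = 2e-3) {
  pk <- pace_to_steady_state(period, n_beats = n_beats, params = params,
                             dt = dt, stim_spec = stim_spec, rel_tol = rel_tol)
  # advance from the calcium peak to the end of the beat (diastole)
  tr <- attr(pk, "peak_ca")
  out <- run_cell(pk, duration = period * 0.98, dt = dt, params = params,
                  record_every = 0L)
  st <- out$state
  attr(st, "peak_ca") <- tr
  attr(st, "converged") <- attr(pk, "converged")
  attr(st, "beats") <- attr(pk, "beats")
  st
}

#' Paced plane-wave protocol on a sheet
#'
#' Initiates a train of plane waves from one edge strip at a fixed period and
#' records probe traces at the medium centre and at a second probe displaced
#' along the propagation direction. Conduction block at short periods shows
#' up as missed upstrokes in the traces, not as an exception.
#'
#' @param cell initial `cell_state` for every node ([paced_initial_state()])
#' @param period stimulation period (ms)
#' @param n_beats number of stimuli
#' @param nx,ny electrical grid size
#' @param hs space step (mm)
#' @param D diffusivity (mm^2/ms)
#' @param dt time step (ms)
#' @param mode `"constant_stretch"` or `"contracting"`
#' @param sac `sac_params()`
#' @param lambda constant stretch (constant-stretch mode)
#' @param params TP06 parameters
#' @param mech,nhs mechanics and tension parameters (contracting mode)
#' @param probe_sep downstream probe separation (mm)
#' @param stim_width stimulus strip width (nodes)
#' @param stim_amp,stim_dur stimulus current (pA/pF) and duration (ms)
#' @param record_every trace sampling stride (steps)
#' @param record_from record only from this time (ms) onward (conditioning
#'   beats before it are simulated but not stored)
#' @param state optional pre-built `em_state` to continue from
#' @return list with `trace_center`, `trace_down` (data.frames), `state`,
#'   `mech_iters`, `probes`, `probe_sep`
#' @export
run_paced_sheet <- function(cell, period, n_beats, nx = 61, ny = 21,
                            hs = 0.5, D = 0.154, dt = 0.02,
                            mode = c("constant_stretch", "contracting"),
                            sac = sac_params(gs = 0), lambda = 1,
                            params = tp06_params(),
                            mech = mech_params(l0 = 2 * hs), nhs = nhs_params(),
                            probe_sep = 10, stim_width = 3L,
                            stim_amp = -52, stim_dur = 2,
                            record_every = 25L, record_from = 0,
                            state = NULL) {
  mode <- match.arg(mode)
  if (is.null(state))
    state <- em_init(nx, ny, hs = hs, D = D, dt = dt, mode = mode,
                     cell_state = cell, params = params, sac = sac,
                     lambda = lambda, mech = mech, nhs = nhs)
  cx <- (state$nx + 1L) %/% 2L; cy <- (state$ny + 1L) %/% 2L
  sep_nodes <- as.integer(round(probe_sep / hs))
  if (cx + sep_nodes > state$nx) stop("probe separation exceeds the sheet")
  probes <- c(node_index(state, cx, cy), node_index(state, cx + sep_nodes, cy))
  stim_nodes <- region_nodes(state, "left-strip", width = stim_width)
  stim <- lapply(seq_len(n_beats) - 1L, function(b)
    list(t0 = state$t + 5 + b * period, dur = stim_dur, amp = stim_amp,
         nodes = stim_nodes))
  dur_total <- n_beats * period
  out <- NULL
  if (record_from > 0) {
    pre <- em_run(state, min(record_from, dur_total), stim = stim,
                  record_every = 0L)
    state <- pre$state
    dur_total <- dur_total - min(record_from, dur_total)
    pre_iters <- pre$mech_iters
  } else pre_iters <- integer(0)
  out <- em_run(state, dur_total, stim = stim, probes = probes,
                record_every = record_every)
  tr <- out$trace
  list(trace_center = tr[tr$probe == 1, , drop = FALSE],
       trace_down = tr[tr$probe == 2, , drop = FALSE],
       state = out$state, mech_iters = c(pre_iters, out$mech_iters),
       probes = probes, probe_sep = sep_nodes * hs)
}

#' APD and CV restitution scan
#'
#' Measures APD and average CV per (stimulation period, G_s) after a number
#' of conditioning beats, in either stretch condition. Failed captures are
#' kept in the table and marked, never dropped; the minimal captured period
#' per G_s is reported as an attribute.
#'
#' @param periods stimulation periods (ms)
#' @param gs_values swept maximal SAC conductances (nS/pF)
#' @param mode stretch condition
#' @param cell initial cell state
#' @param n_cond conditioning beats (not measured)
#' @param n_meas measured beats
#' @param recovery_fraction APD recovery fraction
#' @param cv_threshold upstroke crossing level for CV (mV)
#' @param ... forwarded to [run_paced_sheet()]
#' @return data.frame of class `restitution_curve` with columns `period`,
#'   `gs`, `apd`, `cv`, `captured`; attribute `min_period` (per G_s)
#' @export
restitution_scan <- function(periods, gs_values = 0,
                             mode = c("constant_stretch", "contracting"),
                             cell, n_cond = 2L, n_meas = 2L,
                             recovery_fraction = 0.9, cv_threshold = -20,
                             ...) {
  mode <- match.arg(mode)
  rows <- list()
  for (gs in gs_values) {
    for (p in sort(periods, decreasing = TRUE)) {
      r <- run_paced_sheet(cell, period = p, n_beats = n_cond + n_meas,
                           mode = mode, sac = sac_params(gs = gs),
                           lambda = if (mode == "constant_stretch") 1.1 else 1,
                           record_from = n_cond * p, ...)
      apds <- measure_apd(r$trace_center, recovery_fraction)
      cap <- length(apds) >= n_meas   # every measured beat captured
      cv <- measure_cv(r$trace_center, r$trace_down, r$probe_sep,
                       threshold = cv_threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(period = p, gs = gs,
                   apd = if (length(apds)) tail(apds, 1) else NA_real_,
                   cv = as.numeric(cv), captured = cap)
    }
  }
  out <- do.call(rbind, rows)
  cap_tab <- out[out$captured, ]
  minp <- tapply(cap_tab$period, cap_tab$gs, min)
  attr(out, "min_period") <- minp
  class(out) <- c("restitution_curve", class(out))
  out
}

#' Initiate a spiral wave with an S1-S2 protocol
#'
#' An S1 plane wave from the left edge is followed by a premature S2 stimulus
#' over the bottom half of the sheet, timed into the vulnerable window of the
#' S1 repolarization tail; the broken S2 front curls into a spiral. The state
#' is then conditioned for `cond_ms` with the stretch-activated current off
#' (G_s = 0) to remove initiation artifacts; the recorded state serves as the
#' common initial condition for all subsequent G_s runs. If an S2 timing
#' fails to produce exactly one phase singularity, the timing is shifted
#' within `s2_window` and retried.
#'
#' @param cell initial `cell_state`
#' @param nx,ny,hs,D,dt grid settings
#' @param mode stretch condition used for the conditioning run (feedback is
#'   off either way; contracting mode also conditions the lattice state)
#' @param params TP06 parameters
#' @param mech,nhs mechanics / tension parameters
#' @param s2_window candidate S2 times after the S1 stimulus (ms)
#' @param cond_ms conditioning duration after S2 (ms)
#' @param stim_amp,stim_dur stimulus settings
#' @param v_iso tip-tracking isoline (mV)
#' @param check_ms window after S2 used to verify a rotating tip exists
#' @return `em_state` holding the conditioned spiral; attributes `s2_time`,
#'   `tip_check` (trajectory of the verification window)
#' @export
s1s2_spiral_init <- function(cell, nx = 101, ny = 101, hs = 0.5, D = 0.154,
                             dt = 0.02,
                             mode = c("contracting", "constant_stretch"),
                             params = tp06_params(),
                             mech = mech_params(l0 = 2 * hs),
                             nhs = nhs_params(),
                             s2_window = seq(360, 320, by = -10),
                             cond_ms = 600, stim_amp = -52, stim_dur = 2,
                             v_iso = -40, check_ms = 250) {
  mode <- match.arg(mode)
  base <- em_init(nx, ny, hs = hs, D = D, dt = dt, mode = mode,
                  cell_state = cell, params = params,
                  sac = sac_params(gs = 0), mech = mech, nhs = nhs)
  s1 <- list(t0 = 5, dur = stim_dur, amp = stim_amp,
             nodes = region_nodes(base, "left-strip", width = 3L))
  s2_nodes <- region_nodes(base, "bottom-half")
  frame_every <- as.integer(round(5 / dt))
  for (ts2 in s2_window) {
    s2 <- list(t0 = 5 + ts2, dur = stim_dur, amp = stim_amp, nodes = s2_nodes)
    r <- em_run(base, duration = 5 + ts2 + check_ms, stim = list(s1, s2),
                frame_every = frame_every)
    nfr <- ncol(r$frames)
    use <- r$frame_times >= 5 + ts2 + 50
    traj <- track_tip(r$frames[, use, drop = FALSE], r$frame_times[use],
                      nx, ny, hs, v_iso = v_iso)
    # a sustained re-entry shows a tip in most verification frames
    ok <- nrow(traj) >= 0.6 * sum(use) && nrow(traj) >= 10
    if (ok) {
      cond <- em_run(r$state, cond_ms)
      st <- cond$state
      attr(st, "s2_time") <- ts2
      attr(st, "tip_check") <- traj
      return(st)
    }
  }
  stop("no S2 timing in the window produced a sustained spiral")
}

#' Continue a conditioned spiral under a given stretch condition
#'
#' Runs the common conditioned state forward with the requested G_s and mode,
#' recording V frames for tip tracking. Constant-stretch runs reuse the
#' electrical state with the lambda field pinned at the configured stretch;
#' contracting runs continue the full coupled state.
#'
#' @param spiral_state conditioned `em_state` from [s1s2_spiral_init()]
#' @param mode stretch condition of the continuation
#' @param gs maximal SAC conductance (nS/pF)
#' @param duration run length (ms)
#' @param lambda constant stretch (constant-stretch mode)
#' @param frame_ms frame spacing for tip tracking (ms)
#' @param sac_template `sac_params()` carrying E_s / lambda_max
#' @return list with `traj` (tip trajectory), `frames`, `frame_times`,
#'   `state`
#' @export
spiral_run <- function(spiral_state, mode = c("contracting", "constant_stretch"),
                       gs = 0, duration = 800, lambda = 1.1, frame_ms = 4,
                       sac_template = sac_params()) {
  mode <- match.arg(mode)
  st <- spiral_state
  sac <- sac_params(gs = gs, es = sac_template$es,
                    lambda_max = sac_template$lambda_max,
                    rectified = sac_template$rectified)
  if (mode == "constant_stretch") {
    if (st$mode != "constant_stretch") {
      st$mode <- "constant_stretch"
      st$mesh <- NULL; st$nhs_state <- NULL; st$ta_comm <- NULL
    }
    st$lambda_field <- rep(lambda, st$nx * st$ny)
  } else if (st$mode != "contracting") {
    stop("contracting continuation needs a contracting conditioned state")
  }
  st$sac <- sac
  frame_every <- as.integer(round(frame_ms / st$dt))
  r <- em_run(st, duration, frame_every = frame_every)
  traj <- track_tip(r$frames, r$frame_times, st$nx, st$ny, st$hs)
  list(traj = traj, frames = r$frames, frame_times = r$frame_times,
       state = r$state, mech_iters = r$mech_iters)
}
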