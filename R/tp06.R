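#' TP06 epicardial myocyte parameters
#'
#' Loads the ten Tusscher-Panfilov 2006 epicardial parameter set from the
#' versioned parameter file shipped with the package and applies any
#' overrides. The `gates` argument selects the gating integrator: the
#' model's reference integration scheme advances gating variables with the
#' exponential (Rush-Larsen) update while voltage and concentrations use
#' explicit Euler; a plain forward-Euler gate update is available for
#' convergence studies at reduced time steps.
#'
#' @param file parameter file (defaults to the shipped epicardial table)
#' @param gates "exponential" (default) or "euler"
#' @param ... named numeric overrides, e.g. `G_Ks = 0.2`
#' @return named numeric parameter vector of class `tp06_params`
#' @export
tp06_params <- function(file = system.file("extdata", "tp06_epi.txt",
                                           package = "cardiomech"),
                        gates = c("exponential", "euler"), ...) {
  gates <- match.arg(gates)
  p <- read_param_file(file, required = .tp06_param_names)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown TP06 parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- as.numeric(ov)
  }
  p <- c(p, rush_larsen = if (gates == "exponential") 1 else 0)
  class(p) <- "tp06_params"
  p
}

#' Resting initial condition of the TP06 model
#'
#' The published resting state of the epicardial variant. Working-myocyte
#' initial conditions for tissue runs are obtained by pacing this state to
#' steady calcium dynamics with [pace_to_steady_state()].
#'
#' @return named numeric state vector of class `cell_state`
#' @export
tp06_initial_state <- function() {
  s <- c(V = -86.2, m = 0, h = 0.75, j = 0.75, d = 0, f = 1, f2 = 1,
         fCass = 1, r = 0, s = 1, xr1 = 0, xr2 = 1, xs = 0,
         Na_i = 7.67, K_i = 138.3, Ca_i = 0.00007, Ca_SR = 1.3,
         Ca_SS = 0.00007, R_bar = 1)
  class(s) <- "cell_state"
  s
}

.gate_names <- c("m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
                 "xr1", "xr2", "xs")
.conc_names <- c("Na_i", "K_i", "Ca_i", "Ca_SR", "Ca_SS")

validate_cell_state <- function(state) {
  if (length(state) != 19L) stop("cell state must have 19 entries")
  if (any(!is.finite(state))) {
    bad <- names(state)[!is.finite(state)]
    stop("non-finite state entry: ", paste(bad, collapse = ", "))
  }
  g <- state[.gate_names]
  tol <- 1e-10
  if (any(g < -tol | g > 1 + tol)) {
    bad <- .gate_names[g < -tol | g > 1 + tol]
    stop("gating variable outside [0,1]: ", paste(bad, collapse = ", "),
         " (integration instability; reduce dt)")
  }
  if (any(state[.conc_names] <= 0))
    stop("non-positive concentration: ",
         paste(.conc_names[state[.conc_names] <= 0], collapse = ", "))
  invisible(state)
}

#' Membrane currents of the TP06 model
#'
#' Evaluates every component current at the given state. The stretch-activated
#' current `i_sac` and the stimulus `i_stim` pass through unmodified; the total
#' is the exact sum of all components (pA/pF, outward positive).
#'
#' @param state `cell_state` vector
#' @param params `tp06_params` vector
#' @param i_sac stretch-activated current density (pA/pF)
#' @param i_stim stimulus current density (pA/pF, depolarizing = negative)
#' @return named list of component currents plus `I_tot`
#' @export
tp06_currents <- function(state, params = tp06_params(), i_sac = 0, i_stim = 0) {
  validate_cell_state(state)
  cpp_tp06_currents(unclass(state), unclass(params), i_sac, i_stim)
}

#' One explicit time step of the TP06 model
#'
#' Advances a single cell by `dt` with the model's explicit scheme. Gates must
#' remain in \[0,1\]: a gate leaving the unit interval beyond round-off is an
#' integration-instability error, never silently clamped.
#'
#' @inheritParams tp06_currents
#' @param dt time step (ms); must be positive and at most 0.05 ms, the
#'   upper end of the validated electrical step range
#' @return the advanced `cell_state`
#' @export
tp06_step <- function(state, params = tp06_params(), i_sac = 0, i_stim = 0,
                      dt = 0.02) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (dt > 0.05) stop("dt exceeds the validated electrical step (0.05 ms)")
  validate_cell_state(state)
  out <- cpp_tp06_step(unclass(state), unclass(params), i_sac, i_stim, dt)
  names(out) <- names(state)
  class(out) <- "cell_state"
  validate_cell_state(out)
  out
}

#' Integrate a single cell
#'
#' Runs one cell for `duration` ms, optionally under a prescribed stretch
#' course and with NHS tension development attached (isometric fibres and the
#' stretched-cell comparisons use this entry point).
#'
#' @param state initial `cell_state`
#' @param duration run length (ms)
#' @param dt electrical time step (ms)
#' @param params TP06 parameters
#' @param lambda prescribed pseudo sarcomere length: a scalar, or a function
#'   of time (ms) evaluated on the step grid
#' @param sac list with `gs`, `es`, `lambda_max`, `rectified` (see [sac_params()])
#' @param stim list of current stimuli, each `list(t0=, dur=, amp=)`
#' @param vset list of voltage-set stimuli, each `list(t=, v=)` (the "set V for
#'   one time step" pacing mode)
#' @param nhs `NULL` to disable tension, or a list with `params`
#'   (`nhs_params()`) and optionally `state` (`nhs_initial_state()`)
#' @param record_every record the trace every this many steps (0 = no trace)
#' @param t_start absolute start time for stimulus scheduling (ms)
#' @return list with `state`, `nhs_state`, `trace` (data.frame), `t_end`
#' @export
run_cell <- function(state, duration, dt = 0.02, params = tp06_params(),
                     lambda = 1, sac = sac_params(gs = 0), stim = list(),
                     vset = list(), nhs = NULL, record_every = 25L,
                     t_start = 0) {
  validate_cell_state(state)
  n_steps <- as.integer(round(duration / dt))
  lam <- if (is.function(lambda)) lambda(t_start + (0:(n_steps - 1)) * dt)
         else as.numeric(lambda)
  if (any(lam <= 0)) stop("lambda must be positive")
  st <- .stim_vectors(stim)
  vs <- .vset_vectors(vset)
  with_nhs <- !is.null(nhs)
  np <- if (with_nhs) unclass(nhs$params) else numeric(0)
  ns <- if (with_nhs) {
    s0 <- if (!is.null(nhs$state)) nhs$state else nhs_initial_state(params = nhs$params)
    unclass(s0)
  } else numeric(6)
  out <- cpp_run_cell(unclass(state), unclass(params), ns, np,
                      as.integer(with_nhs), dt, n_steps, t_start, lam,
                      sac$gs, sac$es, sac$lambda_max, as.integer(sac$rectified),
                      st$t0, st$dur, st$amp, vs$t, vs$v,
                      as.integer(record_every))
  class(out$state) <- "cell_state"
  if (with_nhs) {
    names(out$nhs_state) <- .nhs_state_names
    class(out$nhs_state) <- "tension_state"
  }
  out$trace <- as.data.frame(out$trace)
  out
}

.stim_vectors <- function(stim) {
  if (length(stim) == 0) return(list(t0 = numeric(0), dur = numeric(0), amp = numeric(0)))
  list(t0 = vapply(stim, `[[`, 0, "t0"),
       dur = vapply(stim, `[[`, 0, "dur"),
       amp = vapply(stim, `[[`, 0, "amp"))
}

.vset_vectors <- function(vset) {
  if (length(vset) == 0) return(list(t = numeric(0), v = numeric(0)))
  list(t = vapply(vset, `[[`, 0, "t"),
       v = vapply(vset, `[[`, 0, "v"))
}

#' Pace a single cell to steady calcium dynamics
#'
#' Stimulates a non-deforming cell periodically until the beat-to-beat change
#' in peak intracellular calcium falls below `rel_tol`, then returns the state
#' sampled at the time of peak \[Ca2+\]_i of the final beat. Reaching steady
#' calcium dynamics takes many beats, which is why tissue runs start from this
#' conditioned state rather than the resting initial condition.
#'
#' @param period pacing period (ms)
#' @param n_beats maximum number of beats (0 returns the resting state
#'   unchanged)
#' @param state0 starting state
#' @param params TP06 parameters
#' @param dt time step (ms)
#' @param stim_spec either `list(mode="vset", v=0)` (set V for one step, the
#'   single-cell pacing mode) or `list(mode="current", amp=-52, dur=1)`
#' @param rel_tol relative tolerance on the change in peak calcium over the
#'   last two beats
#' @return `cell_state` at peak calcium of the final beat; attributes
#'   `peak_ca` (per-beat peaks), `converged`, `beats`
#' @export
pace_to_steady_state <- function(period, n_beats = 100L,
                                 state0 = tp06_initial_state(),
                                 params = tp06_params(), dt = 0.02,
                                 stim_spec = list(mode = "vset", v = 0),
                                 rel_tol = 1e-3) {
  if (n_beats == 0L) return(state0)
  if (period < 250) stop("period must exceed the refractory period")
  n_steps <- as.integer(round(period / dt))
  state <- unclass(state0)
  peaks <- numeric(n_beats)
  peak_state <- NULL
  for (b in seq_len(n_beats)) {
    stim <- vset <- list()
    if (identical(stim_spec$mode, "vset")) {
      vset <- list(list(t = 0, v = stim_spec$v))
    } else {
      stim <- list(list(t0 = 0, dur = stim_spec$dur, amp = stim_spec$amp))
    }
    out <- run_cell(structure(state, class = "cell_state"), duration = period,
                    dt = dt, params = params, stim = stim, vset = vset,
                    record_every = 5L, t_start = 0)
    tr <- out$trace
    ipk <- which.max(tr$Ca_i)
    peaks[b] <- tr$Ca_i[ipk]
    converged <- b >= 3L &&
      abs(peaks[b] - peaks[b - 1]) <= rel_tol * peaks[b] &&
      abs(peaks[b - 1] - peaks[b - 2]) <= rel_tol * peaks[b]
    if (converged || b == n_beats) {
      # re-run the final beat up to the calcium peak to sample the state there
      t_peak <- tr$t[ipk]
      n_to_peak <- as.integer(round(t_peak / dt))
      fin <- run_cell(structure(state, class = "cell_state"),
                      duration = n_to_peak * dt, dt = dt, params = params,
                      stim = stim, vset = vset, record_every = 0L, t_start = 0)
      peak_state <- fin$state
      if (!converged) {
        warning(sprintf(
          "peak [Ca2+]_i not converged after %d beats; last relative changes: %s",
          b, paste(signif(diff(tail(peaks[seq_len(b)], 4)) /
                          peaks[b], 3), collapse = ", ")))
      }
      peaks <- peaks[seq_len(b)]
      attr(peak_state, "t_peak") <- t_peak
      attr(peak_state, "peak_ca") <- peaks
      attr(peak_state, "converged") <- converged
      attr(peak_state, "beats") <- b
      return(peak_state)
    }
    state <- unclass(out$state)
  }
}
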