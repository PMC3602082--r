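#' Stretch-activated channel parameters
#'
#' Linear, time-independent stretch-activated current
#' `I_sac = G_s * (lambda - 1)/(lambda_max - 1) * (V - E_s)`, gated to
#' stretch (`lambda > 1`) by default; the normalized stretch is clamped to
#' \[0, 1\]. `E_s` lies between the resting and plateau potentials, so the
#' current depolarizes resting tissue and reverses during the action
#' potential.
#'
#' @param gs maximal conductance (nS/pF)
#' @param es reversal potential (mV)
#' @param lambda_max pseudo sarcomere length of full channel activation
#' @param rectified gate the current to stretch (`lambda > 1`); the
#'   unrectified linear form is available for sensitivity studies
#' @return list of class `sac_params`
#' @export
sac_params <- function(gs = 0, es = 0, lambda_max = 1.1, rectified = TRUE) {
  stopifnot(gs >= 0, lambda_max > 1)
  structure(list(gs = gs, es = es, lambda_max = lambda_max,
                 rectified = rectified), class = "sac_params")
}

#' Pseudo normalized sarcomere length from an area element
#'
#' `lambda = sqrt(S/S0)`: the isotropic stretch whose square matches the area
#' ratio of a smallest lattice element to its undeformed area.
#'
#' @param S deformed area (mm^2)
#' @param S0 undeformed area (mm^2)
#' @return lambda (dimensionless)
#' @export
lambda_from_area <- function(S, S0) {
  if (any(!is.finite(S)) || any(S <= 0) || any(!is.finite(S0)) || any(S0 <= 0))
    stop("areas must be positive and finite")
  sqrt(S / S0)
}

#' Stretch-activated current density
#'
#' @param lambda pseudo sarcomere length (vectorized)
#' @param V membrane potential (mV, vectorized)
#' @param p `sac_params`
#' @return current density (pA/pF, outward positive)
#' @export
isac <- function(lambda, V, p) {
  frac <- (lambda - 1) / (p$lambda_max - 1)
  if (p$rectified) frac <- pmax(frac, 0)
  frac <- pmin(pmax(frac, -1), 1)
  p$gs * frac * (V - p$es)
}

#' Initialize a coupled electromechanical sheet
#'
#' Builds the electrical finite-difference grid and, in contracting mode, the
#' mechanical lattice coupled to it with the rest length of an active spring
#' spanning two electrical space steps (one mechanical point per two
#' electrical nodes). All electrical nodes start from `cell_state`; the
#' lambda field starts at the configured constant (constant-stretch mode) or
#' at 1 (undeformed lattice).
#'
#' @param nx,ny electrical nodes per side (odd in contracting mode)
#' @param hs electrical space step (mm)
#' @param D diffusivity (mm^2/ms)
#' @param dt electrical time step (ms)
#' @param mode `"constant_stretch"` (lambda held fixed, mechanics skipped) or
#'   `"contracting"` (deforming lattice, isometric fixed boundary)
#' @param cell_state initial state applied to every node (typically from
#'   [pace_to_steady_state()])
#' @param params TP06 parameters
#' @param sac `sac_params()`
#' @param lambda constant stretch for constant-stretch mode
#' @param mech `mech_params()` (contracting mode)
#' @param nhs `nhs_params()` (contracting mode)
#' @return list of class `em_state`
#' @export
em_init <- function(nx, ny = nx, hs = 0.5, D = 0.154, dt = 0.02,
                    mode = c("constant_stretch", "contracting"),
                    cell_state = tp06_initial_state(),
                    params = tp06_params(), sac = sac_params(),
                    lambda = 1, mech = mech_params(l0 = 2 * hs),
                    nhs = nhs_params()) {
  mode <- match.arg(mode)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (D * dt / hs^2 >= 0.25)
    stop(sprintf("explicit diffusion unstable: D*dt/h^2 = %.3f >= 1/4",
                 D * dt / hs^2))
  N <- nx * ny
  st <- unclass(cell_state)
  V <- rep(st[1], N)
  Y <- matrix(st[-1], nrow = 18, ncol = N)
  s <- list(nx = nx, ny = ny, hs = hs, D = D, dt = dt, mode = mode,
            params = params, sac = sac, t = 0,
            V = V, Y = Y, state_names = names(st))
  if (mode == "constant_stretch") {
    s$lambda_field <- rep(as.numeric(lambda), N)
  } else {
    if (nx %% 2L == 0L || ny %% 2L == 0L)
      stop("contracting mode needs odd nx, ny (1 mech point per 2 elec nodes)")
    if (abs(mech$l0 - 2 * hs) > 1e-9)
      stop("active spring rest length must equal two electrical space steps")
    nmx <- (nx + 1L) %/% 2L; nmy <- (ny + 1L) %/% 2L
    s$mesh <- build_lattice(c(nmx, nmy), params = mech, fixed_boundary = TRUE)
    nq <- s$mesh$nqx * s$mesh$nqy
    ns0 <- unclass(nhs_initial_state(ca_i = st[["Ca_i"]], params = nhs))
    s$nhs_params <- nhs
    s$nhs_state <- matrix(ns0, nrow = 6, ncol = nq)
    s$ta_comm <- numeric(nq)
    s$dlam_comm <- numeric(nq)
    qx <- rep(seq_len(s$mesh$nqx), s$mesh$nqy)
    qy <- rep(seq_len(s$mesh$nqy), each = s$mesh$nqx)
    s$quad_ca_node <- (2L * qy - 1L - 1L) * nx + 2L * qx
    s$lambda_field <- rep(1, N)
  }
  class(s) <- "em_state"
  s
}

#' Linear node index of an electrical grid position
#' @param state `em_state`
#' @param ix,iy 1-based grid coordinates
#' @return node index
#' @export
node_index <- function(state, ix, iy) (iy - 1L) * state$nx + ix

#' Node indices of a named stimulus region
#'
#' @param state `em_state`
#' @param region "left-strip" (plane-wave pacing electrode), "bottom-half"
#'   (S2 half-field), "all", or "point"
#' @param width strip width in nodes
#' @param at `c(ix, iy)` for "point"
#' @return integer node indices
#' @export
region_nodes <- function(state, region = c("left-strip", "bottom-half",
                                           "all", "point"),
                         width = 3L, at = NULL) {
  region <- match.arg(region)
  nx <- state$nx; ny <- state$ny
  ix <- rep(seq_len(nx), ny); iy <- rep(seq_len(ny), each = nx)
  switch(region,
    "left-strip" = which(ix <= width),
    "bottom-half" = which(iy <= ny %/% 2L),
    "all" = seq_len(nx * ny),
    "point" = node_index(state, at[1], at[2]))
}

#' Interpolate the per-quad lambda field to electrical nodes
#'
#' Quad-wise lambda values (at quad centers) interpolated bilinearly to the
#' electrical grid; an undeformed mesh yields exactly 1 everywhere.
#'
#' @param mesh `mech_mesh`
#' @param grid `em_state` (provides the electrical grid geometry)
#' @return numeric vector, one lambda per electrical node
#' @export
lambda_field <- function(mesh, grid) {
  lam_q <- lambda_from_area(area_elements(mesh), mesh$s0)
  cpp_lambda_field(lam_q, mesh$nqx, mesh$nqy, grid$nx, grid$ny)
}

#' Advance a coupled sheet
#'
#' Runs the coupled explicit scheme for `duration` ms: per electrical step,
#' (1) one Euler update of the reaction-diffusion system on the undeformed
#' grid stencil with the stretch-activated current from the current lambda
#' field, (2) one NHS step per mechanical element, (3) in contracting mode a
#' damped Verlet relaxation of the lattice under the frozen T_lv field with
#' the update method, after which the lambda field is refreshed. The
#' mechanics are updated after every electrical step.
#'
#' @param state `em_state`
#' @param duration run length (ms)
#' @param stim list of stimuli `list(t0=, dur=, amp=, nodes=)` (times absolute)
#' @param vset list of voltage-set events `list(t=, v=, nodes=)`
#' @param probes integer node indices to record
#' @param record_every steps between trace samples
#' @param frame_every steps between recorded V frames (0 = none)
#' @param reaction_on internal switch used by diffusion-only tests
#' @param lut use the tabulated voltage-dependent coefficients (the standard
#'   tissue-solver optimization; `FALSE` evaluates every rate analytically)
#' @return list with the advanced `state`, `trace`, `frames`, `frame_times`,
#'   `mech_iters`
#' @export
em_run <- function(state, duration, stim = list(), vset = list(),
                   probes = integer(0), record_every = 25L, frame_every = 0L,
                   reaction_on = TRUE, lut = TRUE) {
  n_steps <- as.integer(round(duration / state$dt))
  contracting <- state$mode == "contracting"
  stim_nodes <- lapply(stim, function(s) as.integer(s$nodes))
  vset_nodes <- lapply(vset, function(s) as.integer(s$nodes))
  st <- .stim_vectors(stim); vs <- .vset_vectors(vset)
  probes <- as.integer(probes)
  probe_quads <- if (contracting && length(probes)) {
    ix <- (probes - 1L) %% state$nx + 1L
    iy <- (probes - 1L) %/% state$nx + 1L
    qx <- pmin(pmax(ceiling((ix - 1L) / 2), 1L), state$mesh$nqx)
    qy <- pmin(pmax(ceiling((iy - 1L) / 2), 1L), state$mesh$nqy)
    as.integer((qy - 1L) * state$mesh$nqx + qx)
  } else integer(length(probes))

  out <- cpp_run_sheet(
    state$V, state$Y, unclass(state$params),
    state$nx, state$ny, state$hs, state$D, state$dt, n_steps, state$t,
    if (contracting) 1L else 0L,
    if (contracting) numeric(0) else state$lambda_field,
    state$sac$gs, state$sac$es, state$sac$lambda_max,
    as.integer(state$sac$rectified),
    if (contracting) state$mesh else list(),
    if (contracting) unclass(state$nhs_params) else numeric(0),
    if (contracting) state$nhs_state else matrix(0, 6, 0),
    if (contracting) state$ta_comm else numeric(0),
    if (contracting) state$dlam_comm else numeric(0),
    if (contracting) state$quad_ca_node else integer(0),
    stim_nodes, st$t0, st$dur, st$amp, vset_nodes, vs$t, vs$v,
    probes, probe_quads, as.integer(record_every), as.integer(frame_every),
    if (contracting) state$mesh$params$f_th else 0,
    if (contracting) state$mesh$params$max_iter else 0L,
    as.integer(reaction_on), as.integer(lut))

  state$V <- out$V; state$Y <- out$Y; state$t <- out$t_end
  state$lambda_field <- out$lambda_field
  if (contracting) {
    state$mesh$pos <- out$mech$pos
    state$mesh$prev <- out$mech$prev
    state$mesh$vel <- out$mech$vel
    state$nhs_state <- out$nhs_state
    state$ta_comm <- out$ta_comm
    state$dlam_comm <- out$dlam_comm
  }
  trace <- as.data.frame(out$trace)
  list(state = state, trace = trace, frames = out$frames,
       frame_times = out$frame_times, mech_iters = out$mech_iters)
}

#' One coupled time step
#'
#' Single electrical step plus (in contracting mode) the mechanics update; a
#' thin wrapper over [em_run()].
#' @inheritParams em_run
#' @return advanced `em_state`
#' @export
em_step <- function(state, stim = list(), vset = list()) {
  em_run(state, duration = state$dt, stim = stim, vset = vset,
         record_every = 0L)$state
}

#' Extract the full cell state at one node
#' @param state `em_state`
#' @param node node index
#' @return `cell_state`
#' @export
cell_at <- function(state, node) {
  s <- c(state$V[node], state$Y[, node])
  names(s) <- state$state_names
  class(s) <- "cell_state"
  s
}
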