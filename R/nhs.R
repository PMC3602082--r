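.nhs_state_names <- c("z", "ca_trpn", "q1", "q2", "q3", "lambda")

#' Human-tissue adjustments to the NHS tension model
#'
#' The NHS 2006 model was parameterized on rat and guinea-pig data; human
#' ventricular myocytes relax faster (body temperature) and develop a
#' different maximal tension. The adjustments are isolated here so they can
#' be swapped: a multiplier on the two crossbridge relaxation rates, the
#' maximum contractile tension at resting sarcomere length, and the calcium
#' sensitivity expressed as pCa50.
#'
#' @param relax_mult multiplier applied to `alpha_r1` and `alpha_r2`
#' @param T_ref maximum contractile tension at resting length (kPa)
#' @param pCa50 p\[Ca2+\]_i at half-maximal tension (-log10 of molar Ca50)
#' @return list of class `human_adjustments`
#' @export
human_adjustments <- function(relax_mult = 2, T_ref = 120, pCa50 = 6.2) {
  stopifnot(relax_mult > 0, T_ref > 0, pCa50 > 0)
  structure(list(relax_mult = relax_mult, T_ref = T_ref, pCa50 = pCa50),
            class = "human_adjustments")
}

#' NHS active-tension parameters
#'
#' Loads the original NHS parameter table and, by default, applies the human
#' adjustments of [human_adjustments()].
#'
#' @param file base parameter file
#' @param adjust `human_adjustments()` or `NULL` for the original set
#' @param ... named numeric overrides applied last
#' @return named numeric parameter vector of class `nhs_params`
#' @export
nhs_params <- function(file = system.file("extdata", "nhs_rat.txt",
                                          package = "cardiomech"),
                       adjust = human_adjustments(), ...) {
  p <- read_param_file(file, required = .nhs_param_names)
  if (!is.null(adjust)) {
    stopifnot(inherits(adjust, "human_adjustments"))
    p["alpha_r1"] <- p["alpha_r1"] * adjust$relax_mult
    p["alpha_r2"] <- p["alpha_r2"] * adjust$relax_mult
    p["T_ref"] <- adjust$T_ref
    p["ca_50ref"] <- 10^(-adjust$pCa50) * 1e3   # molar -> mM
  }
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown NHS parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- as.numeric(ov)
  }
  class(p) <- "nhs_params"
  p
}

#' Quiescent NHS state
#'
#' Troponin occupancy starts at its equilibrium for the given diastolic
#' calcium; crossbridges and fading memory start at zero, lambda at rest.
#'
#' @param ca_i diastolic calcium (mM)
#' @param params `nhs_params`
#' @return named numeric vector of class `tension_state`
#' @export
nhs_initial_state <- function(ca_i = 7e-5, params = nhs_params()) {
  trpn0 <- params[["ca_trpn_max"]] * params[["k_on"]] * ca_i /
    (params[["k_on"]] * ca_i + params[["k_ref_off"]])
  s <- c(z = 0, ca_trpn = unname(trpn0), q1 = 0, q2 = 0, q3 = 0, lambda = 1)
  class(s) <- "tension_state"
  s
}

#' One step of the NHS tension model
#'
#' Advances crossbridge fraction, troponin occupancy and fading memory by one
#' explicit Euler step on the electrical clock and returns the length/velocity
#' independent tension T_lv, which is held fixed during the subsequent
#' mechanical relaxation.
#'
#' @param tstate `tension_state`
#' @param ca_i intracellular calcium (mM)
#' @param lambda pseudo sarcomere length after this step
#' @param dlambda_dt stretch rate (1/ms)
#' @param dt time step (ms; equal to the electrical step)
#' @param params `nhs_params`
#' @param ta_committed committed total tension of the previous step (kPa),
#'   used by the tension-dependent troponin unbinding rate
#' @return list with `state` (advanced `tension_state`) and `T_lv` (kPa)
#' @export
nhs_step <- function(tstate, ca_i, lambda, dlambda_dt = 0, dt = 0.02,
                     params = nhs_params(), ta_committed = 0) {
  if (!is.finite(ca_i) || ca_i <= 0) stop("calcium must be positive and finite")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  s <- cpp_nhs_step(unclass(tstate), unclass(params), ca_i, lambda,
                    dlambda_dt, ta_committed, dt)
  names(s) <- .nhs_state_names
  class(s) <- "tension_state"
  list(state = s, T_lv = t_lv(s[["z"]], lambda, params))
}

#' Length/velocity independent tension
#' @param z bound-crossbridge fraction
#' @param lambda pseudo sarcomere length
#' @param params `nhs_params`
#' @return T_lv (kPa), floored at zero
#' @export
t_lv <- function(z, lambda, params = nhs_params()) {
  zmax <- nhs_z_max_r(params, lambda)
  pmax(0, params[["T_ref"]] * z / zmax)
}

nhs_clip_lambda_r <- function(params, lambda) {
  pmin(pmax(lambda, params[["lambda_lo"]]), params[["lambda_hi"]])
}

nhs_ca_trpn_50_r <- function(params, lambda) {
  lc <- nhs_clip_lambda_r(params, lambda)
  ca50 <- params[["ca_50ref"]] * (1 + params[["beta_1"]] * (lc - 1))
  params[["ca_trpn_max"]] * ca50 /
    (ca50 + (params[["k_ref_off"]] / params[["k_on"]]) *
       (1 - (1 + params[["beta_0"]] * (lc - 1)) * 0.5 / params[["gamma_trpn"]]))
}

nhs_z_max_r <- function(params, lambda) {
  zp <- params[["z_p"]]; nr <- params[["n_rel"]]; Kz <- params[["K_z"]]
  zn <- zp^nr; Kn <- Kz^nr
  K1 <- params[["alpha_r2"]] * nr * zp^(nr - 1) * Kn / (zn + Kn)^2
  K2 <- params[["alpha_r2"]] * zn / (zn + Kn) * (1 - nr * Kn / (zn + Kn))
  k <- (params[["ca_trpn_max"]] / nhs_ca_trpn_50_r(params, lambda))^params[["n_hill"]]
  (params[["alpha_0"]] * k - K2) / (params[["alpha_r1"]] + K1 + params[["alpha_0"]] * k)
}

#' Length and velocity scaling factors (update method)
#'
#' Pure algebraic functions of the trial configuration, re-evaluated inside
#' the mechanical iteration: the filament-overlap length factor and the
#' fading-memory velocity factor. The velocity factor is evaluated on the
#' one-step trial advance of the fading-memory terms at the trial stretch
#' rate, so the converged value coincides with the committed one.
#'
#' @param tstate `tension_state` (fading memory as committed at the last
#'   electrical step)
#' @param lambda trial pseudo sarcomere length
#' @param dlambda_dt trial stretch rate (1/ms)
#' @param dt electrical time step (ms)
#' @param params `nhs_params`
#' @return list with `g_len` and `h_vel`
#' @export
update_scaling <- function(tstate, lambda, dlambda_dt = 0, dt = 0.02,
                           params = nhs_params()) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  lc <- nhs_clip_lambda_r(params, lambda)
  g <- max(0, 1 + params[["beta_0"]] * (lc - 1))
  q1 <- tstate[["q1"]] + dt * (params[["A1"]] * dlambda_dt - params[["alpha_1"]] * tstate[["q1"]])
  q2 <- tstate[["q2"]] + dt * (params[["A2"]] * dlambda_dt - params[["alpha_2"]] * tstate[["q2"]])
  q3 <- tstate[["q3"]] + dt * (params[["A3"]] * dlambda_dt - params[["alpha_3"]] * tstate[["q3"]])
  Q <- q1 + q2 + q3
  a <- params[["a_xb"]]
  h <- if (Q < 0) (a * Q + 1) / (1 - Q) else (1 + (a + 2) * Q) / (1 + Q)
  list(g_len = g, h_vel = h)
}

#' Total active tension
#'
#' Composes the length/velocity independent tension with the two scaling
#' factors. A velocity term that would drive the tension negative is floored
#' at zero with a warning (springs never push apart).
#'
#' @param T_lv length/velocity independent tension (kPa)
#' @param g_len length scaling factor
#' @param h_vel velocity scaling factor
#' @return total tension Ta (kPa), non-negative
#' @export
total_tension <- function(T_lv, g_len, h_vel) {
  stopifnot(is.finite(T_lv), is.finite(g_len), is.finite(h_vel), T_lv >= 0)
  ta <- T_lv * g_len * h_vel
  if (ta < 0) {
    warning("velocity scaling drove tension negative; floored at 0")
    ta <- 0
  }
  ta
}
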