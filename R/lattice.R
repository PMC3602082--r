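#' Mechanical parameters for the mass lattice
#'
#' The macroscopic elastic behaviour is set by the Young modulus `E`; the
#' spring stiffness follows from it. For the square lattice with direct
#' (active) and diagonal (passive) central-force springs, macroscopic isotropy
#' at small strain requires a passive/active stiffness ratio of 1/2, giving
#' equal 2D Lame coefficients `lambda = mu = k/2` and `E_2D = 4k/3`; hence
#' `k = 3E/4`. Mass, damping and the Verlet pseudo-time step have no physical
#' relevance (elastostatics) and are set for fast stable convergence; the
#' damping force per spring is capped at `cap_frac` of that spring's Hooke
#' force whenever it would exceed it.
#'
#' @param E Young modulus (kPa); default gives peak twitch shortening of a
#'   free fibre is in the 10-15\% range observed for contracting myocytes
#' @param l0 rest length of an active spring (mm)
#' @param k_ratio passive/active stiffness ratio (1/2 for isotropy)
#' @param damping_ratio dimensionless damping-stiffness ratio c/k; 1 damps
#'   the slowest lattice mode near-critically, and the damping cap keeps the
#'   strongly overdamped short-wavelength modes stable
#' @param cap_frac damping cap as a fraction of the Hooke force
#' @param cap_on apply the damping cap rule
#' @param f_th_rel convergence threshold as a fraction of `k*l0`
#' @param dt_mech Verlet pseudo-time step; default 50\% of the stability limit
#' @param max_iter maximum Verlet iterations per relaxation
#' @param tension_stiffness allowance (kPa) for the active-tension length
#'   dependence when sizing the default `dt_mech`
#' @return list of class `mech_params`
#' @export
mech_params <- function(E = 280, l0 = 1, k_ratio = 0.5, damping_ratio = 0.05,
                        cap_frac = 0.9, cap_on = TRUE, f_th_rel = 1e-4,
                        dt_mech = NULL, max_iter = 20000L,
                        tension_stiffness = 900) {
  stopifnot(E > 0, l0 > 0, k_ratio > 0)
  k <- 0.75 * E
  rho <- 1 / l0^2            # mass-point surface density
  mass <- rho * l0^2         # = 1 by construction
  # stability margin includes the length-dependence of the active tension,
  # which acts as extra spring stiffness inside the relaxation loop
  if (is.null(dt_mech)) dt_mech <- 0.5 * 2 / sqrt(8 * (k + tension_stiffness) / mass)
  structure(list(
    E = E, l0 = l0, k = k, k_ratio = k_ratio, rho = rho, mass = mass,
    c = damping_ratio * k, damping_ratio = damping_ratio,
    cap_frac = cap_frac, cap_on = cap_on,
    f_th = f_th_rel * k * l0, f_th_rel = f_th_rel,
    dt_mech = dt_mech, max_iter = as.integer(max_iter),
    contract_coef = 1 / (rho * l0)), class = "mech_params")
}

#' 2D Lame coefficients of the lattice material
#' @param params `mech_params`
#' @return list with `lambda` and `mu` (kPa)
#' @export
lame_coefficients <- function(params) {
  list(lambda = params$k * params$k_ratio, mu = params$k * params$k_ratio)
}

#' Build a square mass-spring lattice
#'
#' Regular square lattice of mass points: each interior point is connected to
#' its 4 horizontal/vertical nearest neighbours by direct active springs and
#' to its 4 diagonal next-nearest neighbours by passive springs with rest
#' length `sqrt(2)*l0`. The smallest area elements are the quadrilaterals of 4
#' direct neighbours; their vertex ordering is fixed counter-clockwise at
#' build time.
#'
#' @param n_side number of mass points per side (scalar, or `c(nx, ny)`)
#' @param params `mech_params`
#' @param fixed_boundary fix the outermost ring in space (isometric
#'   contraction)
#' @return list of class `mech_mesh`
#' @export
build_lattice <- function(n_side, params = mech_params(), fixed_boundary = TRUE) {
  n_side <- as.integer(n_side)
  if (length(n_side) == 1L) n_side <- c(n_side, n_side)
  nx <- n_side[1]; ny <- n_side[2]
  if (nx < 2L || ny < 2L) stop("n_side must be at least 2")
  l0 <- params$l0
  pid <- function(ix, iy) (iy - 1L) * nx + ix
  gx <- rep(seq_len(nx), ny); gy <- rep(seq_len(ny), each = nx)
  pos <- cbind((gx - 1) * l0, (gy - 1) * l0)

  # active springs: horizontal then vertical
  ah <- cbind(pid(rep(seq_len(nx - 1L), ny), rep(seq_len(ny), each = nx - 1L)),
              pid(rep(seq_len(nx - 1L), ny) + 1L, rep(seq_len(ny), each = nx - 1L)))
  av <- cbind(pid(rep(seq_len(nx), ny - 1L), rep(seq_len(ny - 1L), each = nx)),
              pid(rep(seq_len(nx), ny - 1L), rep(seq_len(ny - 1L), each = nx) + 1L))
  active <- rbind(ah, av)
  # passive springs: both diagonals of every cell
  qx <- rep(seq_len(nx - 1L), ny - 1L); qy <- rep(seq_len(ny - 1L), each = nx - 1L)
  d1 <- cbind(pid(qx, qy), pid(qx + 1L, qy + 1L))
  d2 <- cbind(pid(qx + 1L, qy), pid(qx, qy + 1L))
  passive <- rbind(d1, d2)
  quads <- cbind(pid(qx, qy), pid(qx + 1L, qy), pid(qx + 1L, qy + 1L), pid(qx, qy + 1L))

  # active spring -> adjacent quad map (0 = none); quad index (qx, qy) ->
  # (qy-1)*(nx-1)+qx
  qid <- function(x, y) ifelse(x >= 1L & x <= nx - 1L & y >= 1L & y <= ny - 1L,
                               (y - 1L) * (nx - 1L) + x, 0L)
  hx <- rep(seq_len(nx - 1L), ny); hy <- rep(seq_len(ny), each = nx - 1L)
  sq_h <- cbind(qid(hx, hy - 1L), qid(hx, hy))
  vx <- rep(seq_len(nx), ny - 1L); vy <- rep(seq_len(ny - 1L), each = nx)
  sq_v <- cbind(qid(vx - 1L, vy), qid(vx, vy))
  spring_quads <- rbind(sq_h, sq_v)

  fixed <- integer(nx * ny)
  if (fixed_boundary) fixed[gx == 1L | gx == nx | gy == 1L | gy == ny] <- 1L

  mesh <- list(
    pos = pos, prev = pos, vel = matrix(0, nx * ny, 2),
    active = active, l0_active = rep(l0, nrow(active)),
    passive = passive, l0_passive = rep(sqrt(2) * l0, nrow(passive)),
    quads = quads, spring_quads = spring_quads,
    fixed = fixed, nmx = nx, nmy = ny, nqx = nx - 1L, nqy = ny - 1L,
    k = params$k, k_ratio = params$k_ratio, c = params$c,
    cap_frac = params$cap_frac, cap_on = as.integer(params$cap_on),
    mass = params$mass, contract_coef = params$contract_coef,
    dt_mech = params$dt_mech, s0 = l0^2, params = params)
  class(mesh) <- "mech_mesh"
  mesh
}

#' Build a one-dimensional chain of active springs
#'
#' Degenerate lattice used for the oscillator oracle and free-fibre
#' calibration: `n_pts` masses on a line joined by active springs, no
#' diagonals, no area elements.
#'
#' @param n_pts number of mass points
#' @param params `mech_params`
#' @param fixed indices of points fixed in space
#' @return `mech_mesh`
#' @export
build_chain <- function(n_pts, params = mech_params(), fixed = 1L) {
  stopifnot(n_pts >= 2L)
  l0 <- params$l0
  pos <- cbind((seq_len(n_pts) - 1) * l0, rep(0, n_pts))
  active <- cbind(seq_len(n_pts - 1L), seq_len(n_pts - 1L) + 1L)
  fx <- integer(n_pts); fx[fixed] <- 1L
  mesh <- list(
    pos = pos, prev = pos, vel = matrix(0, n_pts, 2),
    active = active, l0_active = rep(l0, n_pts - 1L),
    passive = matrix(integer(0), 0, 2), l0_passive = numeric(0),
    quads = matrix(integer(0), 0, 4),
    spring_quads = matrix(0L, n_pts - 1L, 2),
    fixed = fx, nmx = n_pts, nmy = 1L, nqx = 0L, nqy = 0L,
    k = params$k, k_ratio = params$k_ratio, c = params$c,
    cap_frac = params$cap_frac, cap_on = as.integer(params$cap_on),
    mass = params$mass, contract_coef = params$contract_coef,
    dt_mech = params$dt_mech, s0 = l0^2, params = params)
  class(mesh) <- "mech_mesh"
  mesh
}

#' Per-point spring forces
#'
#' Sum of Hooke, damping (capped) and contractile forces at the current
#' configuration. Forces on boundary-fixed points are computed but are never
#' applied by the integrator.
#'
#' @param mesh `mech_mesh`
#' @param Ta active tension per active spring (kPa); scalar recycled
#' @return matrix (n_pts x 2) of forces; attribute `fmax` is the maximum
#'   force magnitude over free points
#' @export
spring_forces <- function(mesh, Ta = 0) {
  ta <- rep_len(as.numeric(Ta), nrow(mesh$active))
  if (any(ta < 0)) stop("active tension must be non-negative")
  out <- cpp_lattice_forces(mesh, ta)
  structure(out$forces, fmax = out$fmax)
}

#' Damped Verlet relaxation to elastostatic equilibrium
#'
#' Iterates position-Verlet (half-acceleration first step, central-difference
#' velocity estimate) until the force on every free mass point is below
#' `f_th`. `Ta` may be a frozen per-spring tension vector or a function
#' `function(mesh) -> tension vector` re-evaluated every iteration (the update
#' method is the coupled solver's built-in provider of this kind).
#'
#' @param mesh `mech_mesh`
#' @param Ta per-active-spring tension (kPa), scalar, vector, or function
#' @param f_th force convergence threshold; default from `mech_params`
#' @param max_iter iteration cap; exceeding it raises a convergence-failure
#'   error carrying the residual history
#' @param reset_history zero the Verlet pseudo-velocity before relaxing
#' @return list with updated `mesh`, `iterations`, `residuals`
#' @export
verlet_relax <- function(mesh, Ta = 0, f_th = mesh$params$f_th,
                         max_iter = mesh$params$max_iter,
                         reset_history = TRUE) {
  if (is.function(Ta)) {
    resid <- numeric(0)
    it <- 0L
    first <- reset_history
    if (reset_history) { mesh$prev <- mesh$pos; mesh$vel[] <- 0 }
    repeat {
      ta <- rep_len(as.numeric(Ta(mesh)), nrow(mesh$active))
      f <- spring_forces(mesh, ta)
      resid <- c(resid, attr(f, "fmax"))
      if (attr(f, "fmax") < f_th) break
      if (it >= max_iter) {
        cond <- simpleError(sprintf(
          "Verlet relaxation did not converge in %d iterations (residual %.3g)",
          max_iter, attr(f, "fmax")))
        cond$residuals <- resid
        stop(cond)
      }
      out <- cpp_verlet_step(mesh, ta, as.integer(first))
      mesh$pos <- out$pos; mesh$prev <- out$prev; mesh$vel <- out$vel
      first <- FALSE
      it <- it + 1L
    }
    return(list(mesh = mesh, iterations = it, residuals = resid))
  }
  ta <- rep_len(as.numeric(Ta), nrow(mesh$active))
  out <- cpp_verlet_relax_fixed(mesh, ta, f_th, as.integer(max_iter),
                                as.integer(reset_history), 1L)
  if (!out$converged) {
    cond <- simpleError(sprintf(
      "Verlet relaxation did not converge in %d iterations (residual %.3g)",
      max_iter, utils::tail(out$residuals, 1)))
    cond$residuals <- out$residuals
    stop(cond)
  }
  mesh$pos <- out$pos; mesh$prev <- out$prev; mesh$vel <- out$vel
  list(mesh = mesh, iterations = out$iterations, residuals = out$residuals)
}

#' One raw Verlet iteration
#'
#' Advances the lattice by a single position-Verlet update under the given
#' per-spring active tension, without convergence checking; the building
#' block of oscillator oracles and custom relaxation loops.
#'
#' @param mesh `mech_mesh`
#' @param Ta per-active-spring tension (kPa), scalar recycled
#' @param first use the half-acceleration start formula (zero pseudo-velocity)
#' @return updated `mech_mesh`; attribute `fmax` is the pre-step residual
#' @export
verlet_step <- function(mesh, Ta = 0, first = FALSE) {
  ta <- rep_len(as.numeric(Ta), nrow(mesh$active))
  out <- cpp_verlet_step(mesh, ta, as.integer(first))
  mesh$pos <- out$pos; mesh$prev <- out$prev; mesh$vel <- out$vel
  attr(mesh, "fmax") <- out$fmax
  mesh
}

#' Areas of the smallest lattice elements
#'
#' Signed shoelace area per quadrilateral of 4 direct neighbours, returned
#' positive; a non-positive area means the mesh has tangled and is an error.
#'
#' @param mesh `mech_mesh`
#' @return numeric vector of areas (mm^2)
#' @export
area_elements <- function(mesh) cpp_area_elements(mesh)

#' Total mechanical energy of the lattice
#'
#' Elastic spring energy plus kinetic energy of the pseudo-dynamics; used by
#' the dissipation tests.
#' @param mesh `mech_mesh`
#' @return energy (arbitrary consistent units)
#' @export
lattice_energy <- function(mesh) {
  len <- function(idx, l0) {
    d <- mesh$pos[idx[, 2], , drop = FALSE] - mesh$pos[idx[, 1], , drop = FALSE]
    sqrt(rowSums(d^2)) - l0
  }
  ea <- 0.5 * mesh$k * sum(len(mesh$active, mesh$l0_active)^2)
  ep <- if (nrow(mesh$passive)) 0.5 * mesh$k * mesh$k_ratio *
    sum(len(mesh$passive, mesh$l0_passive)^2) else 0
  ek <- 0.5 * mesh$mass * sum(mesh$vel[!mesh$fixed, ]^2)
  ea + ep + ek
}

#' Seth / Hooke stress oracle
#'
#' Predicted Cauchy stress for a homogeneous deformation gradient `F` under
#' the generalized Hooke's law with the lattice's Lame coefficients, using
#' either the small strain tensor or Almansi's finite strain tensor (the Seth
#' material relation).
#'
#' @param Fdef 2x2 deformation gradient
#' @param params `mech_params`
#' @param measure "small" or "almansi"
#' @return 2x2 Cauchy stress tensor (kPa)
#' @export
seth_stress <- function(Fdef, params, measure = c("small", "almansi")) {
  measure <- match.arg(measure)
  lam <- lame_coefficients(params)
  e <- if (measure == "small") {
    0.5 * (Fdef + t(Fdef)) - diag(2)
  } else {
    B <- Fdef %*% t(Fdef)
    0.5 * (diag(2) - solve(B))
  }
  lam$lambda * sum(diag(e)) * diag(2) + 2 * lam$mu * e
}

#' Measured stress response to an imposed homogeneous strain
#'
#' Applies the affine map `x -> F x` to the whole lattice, fixes the boundary
#' ring there, relaxes the interior, and reports the virial Cauchy stress of
#' the relaxed configuration. Used to recover the effective modulus and to
#' check macroscopic isotropy against [seth_stress()].
#'
#' @param mesh undeformed `mech_mesh` (boundary need not be pre-fixed)
#' @param Fdef 2x2 deformation gradient to impose
#' @return list with `stress` (2x2), `Fdef`, `iterations`
#' @export
measure_small_strain_response <- function(mesh, Fdef) {
  stopifnot(all(dim(Fdef) == c(2, 2)))
  m <- mesh
  m$fixed <- integer(nrow(m$pos))
  gx <- m$pos[, 1]; gy <- m$pos[, 2]
  m$fixed[gx == min(gx) | gx == max(gx) | gy == min(gy) | gy == max(gy)] <- 1L
  m$pos <- m$pos %*% t(Fdef)
  m$prev <- m$pos
  r <- verlet_relax(m, Ta = 0)
  area <- sum(area_elements(r$mesh))
  s <- cpp_virial_stress(r$mesh, numeric(0), area)
  list(stress = s, Fdef = Fdef, iterations = r$iterations)
}

#' Uniaxial deformation gradient along a direction
#' @param strain engineering strain
#' @param angle direction in degrees from the lattice x axis
#' @return 2x2 deformation gradient
#' @export
uniaxial_F <- function(strain, angle = 0) {
  th <- angle * pi / 180
  n <- c(cos(th), sin(th))
  diag(2) + strain * (n %o% n)
}
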