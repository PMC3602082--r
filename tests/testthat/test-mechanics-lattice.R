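test_that("lattice construction has the prescribed topology", {
  m <- build_lattice(5, fixed_boundary = TRUE)
  deg_a <- tabulate(c(m$active), nbins = 25)
  deg_p <- tabulate(c(m$passive), nbins = 25)
  interior <- which(m$fixed == 0L)
  expect_true(all(deg_a[interior] == 4))
  expect_true(all(deg_p[interior] == 4))
  m2 <- build_lattice(2)
  expect_identical(nrow(m2$pos), 4L)
  expect_identical(nrow(m2$active), 4L)
  expect_identical(nrow(m2$passive), 2L)
  # freshly built lattice carries no force
  f <- spring_forces(m, Ta = 0)
  expect_identical(max(abs(f)), 0)
  expect_error(build_lattice(1), "at least 2")
})

test_that("a stretched spring produces equal and opposite Hooke forces", {
  mp <- mech_params(damping_ratio = 0)
  ch <- build_chain(2, params = mp, fixed = integer(0))
  d <- 0.07
  ch$pos[2, 1] <- ch$pos[2, 1] + d
  ch$prev <- ch$pos
  f <- spring_forces(ch, Ta = 0)
  expect_equal(f[1, 1], mp$k * d)
  expect_equal(f[2, 1], -mp$k * d)
  expect_equal(f[, 2], c(0, 0))
})

test_that("internal forces cancel on a free lattice (momentum and torque)", {
  m <- build_lattice(7, fixed_boundary = FALSE)
  # deform smoothly so forces are nonzero, then check the sums vanish
  m$pos <- m$pos + 0.05 * sin(m$pos / 2)
  m$prev <- m$pos
  f <- spring_forces(m, Ta = 13)
  expect_lt(max(abs(colSums(f))), 1e-9)
  torque <- sum(m$pos[, 1] * f[, 2] - m$pos[, 2] * f[, 1])
  expect_lt(abs(torque), 1e-9)
  # rigid translation of the rest state leaves all forces zero
  m2 <- build_lattice(7, fixed_boundary = FALSE)
  m2$pos <- m2$pos + 3.21
  m2$prev <- m2$pos
  expect_lt(max(abs(spring_forces(m2, Ta = 0))), 1e-12)
})

test_that("Verlet oscillator matches the analytic period at second order", {
  mp <- mech_params(damping_ratio = 0, cap_on = FALSE)
  period_error <- function(dt) {
    ch <- build_chain(2, params = mp, fixed = 1L)
    ch$dt_mech <- dt
    ch$pos[2, 1] <- ch$pos[2, 1] + 0.1
    ch$prev <- ch$pos
    x <- numeric(4000)
    first <- TRUE
    for (i in seq_along(x)) {
      out <- cpp_verlet_step(ch, numeric(1), as.integer(first))
      ch$pos <- out$pos; ch$prev <- out$prev; ch$vel <- out$vel
      first <- FALSE
      x[i] <- ch$pos[2, 1] - 1
    }
    up <- which(x[-length(x)] < 0 & x[-1] >= 0)
    t_cross <- (up + x[up] / (x[up] - x[up + 1])) * dt
    T_meas <- mean(diff(t_cross))
    abs(T_meas - 2 * pi * sqrt(mp$mass / mp$k))
  }
  T0 <- 2 * pi * sqrt(mp$mass / mp$k)
  e1 <- period_error(T0 / 40)
  e2 <- period_error(T0 / 80)
  expect_gt(e1 / e2, 3)      # quartering: second-order phase accuracy
  expect_lt(e1 / e2, 5)
})

test_that("damped relaxation dissipates mechanical energy", {
  mp <- mech_params(damping_ratio = 0.05, cap_on = FALSE)
  m <- build_lattice(9, params = mp, fixed_boundary = TRUE)
  set.seed(1)
  free <- m$fixed == 0L
  m$pos[free, ] <- m$pos[free, ] + matrix(runif(sum(free) * 2, -0.05, 0.05),
                                          ncol = 2)
  m$prev <- m$pos
  en <- numeric(300)
  first <- TRUE
  for (i in seq_along(en)) {
    out <- cpp_verlet_step(m, numeric(nrow(m$active)), as.integer(first))
    m$pos <- out$pos; m$prev <- out$prev; m$vel <- out$vel
    first <- FALSE
    en[i] <- lattice_energy(m)
  }
  expect_true(all(diff(en) <= 1e-9))
  expect_lt(en[300], 0.05 * en[1])
})

test_that("relaxation converges, reports iterations, and fails loudly", {
  m <- build_lattice(9)
  r0 <- verlet_relax(m, Ta = 0)
  expect_identical(r0$iterations, 0L)          # already converged
  expect_identical(r0$mesh$pos, m$pos)
  mid <- colMeans(matrix(m$pos[t(m$active), 1], 2))
  ta <- 20 * exp(-(mid - 4)^2 / 4)
  r <- verlet_relax(m, Ta = ta)
  expect_gt(r$iterations, 0L)
  f <- spring_forces(r$mesh, ta)
  expect_lt(attr(f, "fmax"), m$params$f_th)    # elastostatic consistency
  err <- tryCatch(verlet_relax(m, Ta = ta, max_iter = 3L), error = identity)
  expect_s3_class(err, "error")
  expect_true(length(err$residuals) > 0)
  # a function Ta provider reaches the same equilibrium
  r2 <- verlet_relax(m, Ta = function(mesh) ta)
  expect_equal(r2$mesh$pos, r$mesh$pos, tolerance = 1e-6)
})

test_that("area elements follow shoelace geometry and detect tangling", {
  m <- build_lattice(4)
  expect_equal(area_elements(m), rep(m$params$l0^2, 9))
  m2 <- m
  m2$pos <- m2$pos * 1.3
  expect_equal(area_elements(m2), rep(1.3^2 * m$params$l0^2, 9))
  # shear: unit squares become parallelograms of base 1 and height 1
  m3 <- m
  m3$pos[, 1] <- m3$pos[, 1] + 0.4 * m3$pos[, 2]
  expect_equal(area_elements(m3), rep(m$params$l0^2, 9))
  bad <- m
  bad$pos[6, ] <- bad$pos[11, ] + c(1.2, 1.2)  # fold an interior point over
  expect_error(area_elements(bad), "tangling")
})

test_that("small-strain response matches the generalized Hooke law and isotropy", {
  mp <- mech_params()
  m <- build_lattice(21, params = mp)
  lam <- lame_coefficients(mp)
  expect_equal(lam$lambda, lam$mu)
  z <- measure_small_strain_response(m, diag(2))
  expect_lt(max(abs(z$stress)), 1e-9)          # zero strain, zero stress
  for (eps in c(0.005, 0.01)) {
    r <- measure_small_strain_response(m, uniaxial_F(eps, 0))
    pred <- seth_stress(uniaxial_F(eps, 0), mp, "small")
    expect_lt(abs(r$stress[1, 1] - pred[1, 1]) / abs(pred[1, 1]), 0.02)
    # axis vs 45-degree diagonal: macroscopic isotropy
    r45 <- measure_small_strain_response(m, uniaxial_F(eps, 45))
    n <- c(1, 1) / sqrt(2)
    s45 <- drop(n %*% r45$stress %*% n)
    expect_lt(abs(s45 - r$stress[1, 1]) / abs(r$stress[1, 1]), 0.01)
  }
  # linearity between 0.5% and 1%
  r1 <- measure_small_strain_response(m, uniaxial_F(0.005, 0))
  r2 <- measure_small_strain_response(m, uniaxial_F(0.01, 0))
  expect_equal(r2$stress[1, 1] / r1$stress[1, 1], 2, tolerance = 0.02)
})

test_that("finite biaxial stretch follows the Seth (Almansi) form better", {
  mp <- mech_params()
  m <- build_lattice(21, params = mp)
  s <- 1.10
  r <- measure_small_strain_response(m, diag(c(s, s)))
  p_small <- seth_stress(diag(c(s, s)), mp, "small")[1, 1]
  p_seth <- seth_stress(diag(c(s, s)), mp, "almansi")[1, 1]
  meas <- r$stress[1, 1]
  expect_lt(abs(meas - p_seth), abs(meas - p_small))
})

test_that("refining the lattice leaves the converged stretch field consistent", {
  blob <- function(x, y) 18 * exp(-((x - 7)^2 + (y - 10)^2) / 18)
  solve_lam <- function(l0) {
    n <- as.integer(20 / l0) + 1L
    mp <- mech_params(l0 = l0)
    m <- build_lattice(n, params = mp)
    mid <- (m$pos[m$active[, 1], ] + m$pos[m$active[, 2], ]) / 2
    ta <- blob(mid[, 1], mid[, 2])
    r <- verlet_relax(m, Ta = ta, f_th = mp$f_th * 0.1)
    lam <- lambda_from_area(area_elements(r$mesh), l0^2)
    qc <- (m$pos[m$quads[, 1], ] + m$pos[m$quads[, 3], ]) / 2
    list(lam = lam, qc = qc)
  }
  co <- solve_lam(1)
  fi <- solve_lam(0.5)
  # compare at coarse quad centres via nearest fine quad
  idx <- vapply(seq_len(nrow(co$qc)), function(i) {
    which.min((fi$qc[, 1] - co$qc[i, 1])^2 + (fi$qc[, 2] - co$qc[i, 2])^2)
  }, integer(1))
  expect_lt(max(abs(fi$lam[idx] - co$lam)), 0.02)
})
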