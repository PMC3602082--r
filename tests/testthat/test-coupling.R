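test_that("pseudo sarcomere length follows the area ratio", {
  expect_identical(lambda_from_area(4, 4), 1)
  expect_equal(lambda_from_area(1.21 * 4, 4), 1.1)
  expect_equal(lambda_from_area(2.25, 1), 1.5)   # isotropic stretch by 1.5
  expect_error(lambda_from_area(-1, 4), "positive")
  expect_error(lambda_from_area(1, 0), "positive")
})

test_that("lambda field interpolation is exact for uniform deformation", {
  st <- em_init(9, 9, hs = 0.5, mode = "contracting", cell_state = paced_cell(),
                params = tp())
  expect_identical(st$mesh$nmx, 5L)        # 2 electrical nodes per spring
  f0 <- lambda_field(st$mesh, st)
  expect_identical(f0, rep(1, 81))
  m <- st$mesh
  m$pos <- m$pos * 1.07
  f1 <- lambda_field(m, st)
  expect_equal(f1, rep(1.07, 81), tolerance = 1e-12)
})

test_that("stretch-activated current has the prescribed shape", {
  p <- sac_params(gs = 0.02, es = 0, lambda_max = 1.1)
  expect_identical(isac(1, -80, p), 0)           # no stretch, no current
  expect_identical(isac(1.05, p$es, p), 0)       # reversal potential
  expect_equal(isac(1.1, -60, p), 0.02 * (-60 - p$es))  # full activation
  expect_equal(isac(1.4, -60, p), isac(1.1, -60, p))    # clamped beyond max
  expect_identical(isac(0.9, -60, p), 0)         # rectified under compression
  pu <- sac_params(gs = 0.02, es = 0, rectified = FALSE)
  # unrectified form: compression reverses the current's sign
  expect_equal(isac(0.95, -60, pu), -isac(1.05, -60, pu))
  expect_gt(isac(0.95, -60, pu), 0)
  # depolarizing below E_s, repolarizing above, for all stretched lambda
  V <- seq(-90, 40, by = 5)
  cur <- isac(1.08, V, p)
  expect_true(all(cur[V < p$es] < 0))
  expect_true(all(cur[V > p$es] > 0))
})

test_that("diffusion conserves the spatial mean with no-flux boundaries", {
  st <- em_init(15, 11, hs = 0.5, mode = "constant_stretch",
                cell_state = paced_cell(), params = tp())
  set.seed(42)
  st$V <- rnorm(15 * 11, -60, 20)
  m0 <- mean(st$V)
  r <- em_run(st, 2, record_every = 0L, reaction_on = FALSE)
  expect_equal(mean(r$state$V), m0, tolerance = 1e-13)
  expect_lt(max(abs(r$state$V - mean(r$state$V))), max(abs(st$V - m0)))
})

test_that("severed feedback (G_s = 0) leaves voltage bit-identical", {
  cell <- paced_cell()
  stim <- function(st) list(list(t0 = 2, dur = 2, amp = -52,
                                 nodes = region_nodes(st, "left-strip")))
  a <- em_init(21, 21, hs = 0.5, mode = "contracting", cell_state = cell,
               params = tp(), sac = sac_params(gs = 0))
  b <- em_init(21, 21, hs = 0.5, mode = "constant_stretch", cell_state = cell,
               params = tp(), sac = sac_params(gs = 0), lambda = 1)
  ra <- em_run(a, 60, stim = stim(a), record_every = 0L)
  rb <- em_run(b, 60, stim = stim(b), record_every = 0L)
  expect_identical(ra$state$V, rb$state$V)
  expect_identical(ra$state$Y, rb$state$Y)
  # constant stretch at lambda = 1 equals G_s = 0 with G_s > 0
  c2 <- em_init(21, 21, hs = 0.5, mode = "constant_stretch", cell_state = cell,
                params = tp(), sac = sac_params(gs = 0.03), lambda = 1)
  rc <- em_run(c2, 60, stim = stim(c2), record_every = 0L)
  expect_identical(rc$state$V, rb$state$V)
})

test_that("constant-stretch shortcut matches a pinned uniformly stretched run", {
  # a contracting-mode state whose lambda field is held at the stretched
  # configuration is what constant-stretch mode short-cuts
  cell <- paced_cell()
  cs <- em_init(21, 21, hs = 0.5, mode = "constant_stretch", cell_state = cell,
                params = tp(), sac = sac_params(gs = 0.02), lambda = 1.1)
  r <- em_run(cs, 30, record_every = 0L)
  expect_true(all(abs(r$state$lambda_field - 1.1) < 1e-12))
  # every node received the full stretch-activated conductance
  expect_equal(isac(r$state$lambda_field[1], -80, cs$sac),
               cs$sac$gs * (-80 - cs$sac$es))
})

test_that("stability guard rejects an unstable diffusion setting", {
  expect_error(em_init(11, 11, hs = 0.1, D = 0.154, dt = 0.02), "unstable")
  expect_error(em_init(10, 11, hs = 0.5, mode = "contracting",
                       cell_state = paced_cell(), params = tp()), "odd")
})

test_that("snapshot round-trip resumes a coupled run bit-identically", {
  cell <- paced_cell()
  st <- em_init(21, 21, hs = 0.5, mode = "contracting", cell_state = cell,
                params = tp(), sac = sac_params(gs = 0.02))
  stim <- list(list(t0 = 2, dur = 2, amp = -52,
                    nodes = region_nodes(st, "left-strip")))
  full <- em_run(st, 40, stim = stim, record_every = 0L)
  half <- em_run(st, 20, stim = stim, record_every = 0L)
  path <- tempfile(fileext = ".rds")
  save_snapshot(half$state, path, config_hash = "abc")
  resumed <- load_snapshot(path)
  cont <- em_run(resumed, 20, stim = stim, record_every = 0L)
  expect_identical(cont$state$V, full$state$V)
  expect_identical(cont$state$mesh$pos, full$state$mesh$pos)
  expect_identical(cont$state$nhs_state, full$state$nhs_state)
})
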