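test_that("the standard fiber discretizes into 260 uniform compartments", {
  mod <- fiber_model()
  expect_identical(nrow(mod$centers), 260L)
  expect_equal(sum(mod$length), 260e-6, tolerance = 1e-12)
  g_exact <- (pi * (2e-6)^2 / 4) / (ohm_cm(100) * 1e-6)
  expect_equal(unname(mod$g_ax), rep(g_exact, 259), tolerance = 1e-12)
  expect_equal(mod$area, rep(pi * 2e-6 * 1e-6, 260), tolerance = 1e-12)
})

test_that("a diameter step uses the series-resistance diameter combination", {
  mor <- morphology(list(list(
    points = cbind(0, c(0, 10e-6, 20e-6), 0),
    diam = c(2e-6, 2e-6, 4e-6), parent = 0L)))
  mod <- compartmentalize(mor, dx = 10e-6, Ra = 1)
  # compartment centers at 5 and 15 um carry interpolated diameters 2 and 3 um
  g_exp <- 1 / (5e-6 / (pi * (2e-6)^2 / 4) + 5e-6 / (pi * (3e-6)^2 / 4))
  expect_equal(unname(mod$g_ax[1]), g_exp, tolerance = 1e-12)
  expect_warning(compartmentalize(mor, dx = 50e-6), "single compartment")
})

test_that("halving the compartment size changes the response by < 1%", {
  p <- mea_params()
  bcs <- list(electrode_4_4 = bc_robin(g = 500, V0 = -1),
              ground_surface = bc_robin(g = 500, V0 = 0))
  sol <- solve_field(field_problem(coarse_chamber(), 0.2, bcs, 1))
  w <- waveform_rect(0, 1e-3, 1)
  res <- lapply(c(2e-6, 1e-6), function(dx) {
    mod <- compartmentalize(morphology_fiber(), dx = dx)
    Ve <- sample_potential(sol, mod$centers)
    tr <- simulate_cable(mod, Ve, w, dt = 5e-5, T_end = 1e-3)
    tr$vm[nrow(tr$vm), ]
  })
  # compare at shared centers (every other fine compartment pair average)
  fine_on_coarse <- (res[[2]][seq(1, 259, by = 2)] +
                     res[[2]][seq(2, 260, by = 2)]) / 2
  dev <- max(abs(res[[1]] - fine_on_coarse))
  expect_lt(dev / diff(range(res[[1]])), 0.01)
})

test_that("resting fiber stays at rest and the source term is gauge invariant", {
  mod <- fiber_model()
  tr <- simulate_cable(mod, rep(0, 260), waveform_rect(), dt = 1e-3,
                       T_end = 20e-3)
  expect_lt(max(abs(tr$vm - (-65e-3))), 1e-5 * 1e-3)
  expect_equal(tr$vm[1, ], rep(-65e-3, 260))  # first sample = initial value
  set.seed(1)
  Ve <- rnorm(260) * 1e-3
  w <- waveform_rect(2e-4, 1e-3, -1)
  t1 <- simulate_cable(mod, Ve, w, dt = 5e-5, T_end = 1.5e-3)
  t2 <- simulate_cable(mod, Ve + 0.37, w, dt = 5e-5, T_end = 1.5e-3)
  expect_equal(t1$vm, t2$vm, tolerance = 1e-12)
})

test_that("passive responses superpose linearly in the stimulus amplitude", {
  mod <- fiber_model()
  Ve <- sin(seq(0, 3, length.out = 260)) * 1e-3
  w <- waveform_rect(2e-4, 1e-3, 1)
  t1 <- simulate_cable(mod, Ve, w, dt = 5e-5, T_end = 1.5e-3)
  t2 <- simulate_cable(mod, Ve, w, dt = 5e-5, T_end = 1.5e-3, amplitude = 2)
  expect_lt(max(abs((t2$vm + 65e-3) - 2 * (t1$vm + 65e-3))), 1e-12)
})

test_that("three-compartment passive cable matches a dense adaptive ODE solution", {
  skip_if_not_installed("deSolve")
  mor <- morphology(list(list(points = cbind(0, c(0, 30e-6), 50e-6),
                              diam = c(2e-6, 2e-6), parent = 0L)))
  mod <- compartmentalize(mor, dx = 10e-6)
  p <- mod$membrane[[1]]
  Ve <- c(-2e-3, -5e-3, -1e-3)
  w <- waveform_rect(0, 2e-3, 1)
  L <- as.matrix(neurostimfem:::axial_laplacian(mod))
  rhs <- function(t, y, parms) {
    e <- Ve * wf_eval(w, t)
    dy <- (-p$gl * (y - p$El) * mod$area - L %*% (y + e)) / (p$cm * mod$area)
    list(as.numeric(dy))
  }
  times <- seq(0, 2e-3, by = 1e-4)
  oracle <- deSolve::lsoda(rep(p$El, 3), times, rhs, NULL,
                           rtol = 1e-11, atol = 1e-15)
  tr <- simulate_cable(mod, Ve, w, dt = 1e-7, T_end = 2e-3)
  sel <- round(times / 1e-7) + 1
  dev <- abs(tr$vm[sel, ] - oracle[, -1])
  scale <- max(abs(oracle[, -1] - p$El))
  expect_lt(max(dev) / scale, 0.001)
})

test_that("backward Euler converges at first order on a single-compartment relaxation", {
  # closed form: dV/dt = -(gl/cm) (V - El), V(0) = El + 10 mV
  mor <- morphology(list(list(points = cbind(0, c(0, 1e-6), 0),
                              diam = c(2e-6, 2e-6), parent = 0L)))
  p <- membrane_passive(gl = mS_per_cm2(1))   # tau = 1 ms
  mod <- suppressWarnings(compartmentalize(mor, dx = 2e-6, membrane = p))
  v0 <- p$El + 10e-3
  exact <- p$El + 10e-3 * exp(-1)             # after one time constant
  err <- vapply(c(5e-5, 2.5e-5), function(dt) {
    tr <- simulate_cable(mod, 0 * 1, waveform_rect(0, 1, 0), dt = dt,
                         T_end = 1e-3, V_init = v0)
    abs(tr$vm[nrow(tr$vm), 1] - exact)
  }, 1)
  expect_gt(err[1] / err[2], 1.7)   # halving dt roughly halves the error
  expect_lt(err[1] / err[2], 2.3)
})

test_that("the time-step audit accepts the standard step for the passive fiber", {
  mod <- compartmentalize(morphology_fiber(), dx = 2e-6)
  d <- sqrt(rowSums(mod$centers^2))
  Ve <- -1e-6 / (4 * pi * 0.2 * d)     # cathodic point source below the fiber
  dt <- auto_timestep(mod, Ve, waveform_rect(0, 1e-3, 1), T_end = 1e-3,
                      dt0 = 5e-5)
  expect_equal(as.numeric(dt), 5e-5)
  expect_lt(attr(dt, "rel_diff"), 0.01)
  expect_error(auto_timestep(mod, Ve, waveform_rect(0, 1e-3, 1), T_end = 1e-3,
                             dt0 = 5e-5, tol = 1e-12, dt_floor = 1e-5),
               "floor")
})

test_that("threshold search: passive never fires, active thresholds behave", {
  mor <- morphology_fiber(length = 100e-6)
  modp <- compartmentalize(mor, dx = 2e-6)
  d50 <- sqrt(rowSums(modp$centers^2))   # point source at the origin
  Ve50 <- 1e-6 / (4 * pi * 0.2 * d50)
  pulse <- waveform_rect(2e-4, 2e-4, -1)
  res <- find_threshold(modp, Ve50, pulse, detect = mV(-20),
                        bracket = c(0.1, 10), max_expand = 0)
  expect_identical(res$status, "above_bracket")

  modh <- compartmentalize(mor, dx = 2e-6, membrane = membrane_hh())
  th50 <- find_threshold(modh, Ve50, pulse, detect = mV(-20),
                         bracket = c(1, 50), dt = 2.5e-5, T_end = 3e-3)
  expect_identical(th50$status, "ok")
  # farther electrode -> larger (or equal) threshold
  off <- matrix(c(0, 0, -100e-6), nrow(modh$centers), 3, byrow = TRUE)
  d150 <- sqrt(rowSums((modh$centers - off)^2))
  Ve150 <- 1e-6 / (4 * pi * 0.2 * d150)
  th150 <- find_threshold(modh, Ve150, pulse, detect = mV(-20),
                          bracket = c(1, 200), dt = 2.5e-5, T_end = 3e-3)
  expect_identical(th150$status, "ok")
  expect_gte(th150$threshold, th50$threshold)
  # all-or-none: moving the detection level hardly moves the threshold
  th50b <- find_threshold(modh, Ve50, pulse, detect = mV(-10),
                          bracket = c(1, 50), dt = 2.5e-5, T_end = 3e-3)
  expect_lt(abs(th50b$threshold / th50$threshold - 1), 0.02)
})
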