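# closed-form slab solution: Robin(g1, V0) and Robin(g2, 0) across thickness L
slab_case <- function(order, g1 = 500, g2 = 2000, V0 = 1, L = 1e-4, sig = 0.2) {
  mesh <- build_slab_mesh(thickness = L)
  pr <- field_problem(mesh, sig,
                      list(bottom = bc_robin(g = g1, V0 = V0),
                           top = bc_robin(g = g2, V0 = 0)),
                      element_order = order)
  list(mesh = mesh, sol = solve_field(pr),
       J = V0 / (1 / g1 + L / sig + 1 / g2), area = 1e-8)
}

test_that("slab with double Robin BCs reproduces the series-resistance closed form", {
  for (order in 1:2) {
    cs <- slab_case(order)
    I_bot <- integrate_boundary_current(cs$sol, "bottom")
    I_top <- integrate_boundary_current(cs$sol, "top")
    expect_lt(abs(I_bot / (cs$J * cs$area) - 1), 1e-8)
    expect_lt(abs(I_bot + I_top), 1e-10 * abs(I_bot))   # conservation
    # gradient-based flux agrees with the Robin identity
    expect_lt(abs(neurostimfem:::flux_integral(cs$sol, cs$mesh$facets$bottom) /
                    I_bot - 1), 1e-8)
    # interior potential is the linear closed form
    pts <- cbind(5e-5, 5e-5, c(0, 2.5e-5, 5e-5, 1e-4))
    v_exact <- 1 - cs$J / 500 - cs$J / 0.2 * pts[, 3]
    expect_lt(max(abs(sample_potential(cs$sol, pts) - v_exact)), 1e-10)
  }
})

test_that("zero forcing yields the zero field and zero currents", {
  mesh <- build_slab_mesh()
  pr <- field_problem(mesh, 0.2,
                      list(bottom = bc_robin(g = 500, V0 = 0),
                           top = bc_robin(g = 2000, V0 = 0)), 1)
  sol <- solve_field(pr)
  expect_lt(max(abs(sol$u)), 1e-14)
  for (tag in names(mesh$facets)) {
    expect_lt(abs(integrate_boundary_current(sol, tag, method = "gradient")),
              1e-16)
  }
})

test_that("solution scales linearly and superposes over electrodes", {
  mesh <- coarse_chamber()
  pts <- cbind(seq(-1e-4, 1e-4, length.out = 11), 0, 50e-6)
  mk <- function(v44, v45) {
    field_problem(mesh, 0.2,
                  list(electrode_4_4 = bc_robin(g = 500, V0 = v44),
                       electrode_4_5 = bc_robin(g = 500, V0 = v45),
                       ground_surface = bc_robin(g = 500, V0 = 0)), 1)
  }
  va <- sample_potential(solve_field(mk(1, 0)), pts)
  vb <- sample_potential(solve_field(mk(0, 1)), pts)
  vab <- sample_potential(solve_field(mk(2, 3)), pts)
  expect_lt(max(abs(2 * va + 3 * vb - vab)), 1e-9 * max(abs(vab)))
})

test_that("Robin limits: g -> infinity approaches Dirichlet, g -> 0 shuts the current off", {
  mesh <- build_slab_mesh()
  base <- list(bottom = bc_robin(g = 500, V0 = 1))
  v_dir <- sample_potential(solve_field(field_problem(
    mesh, 0.2, c(base, list(top = bc_dirichlet(0))), 1)),
    cbind(5e-5, 5e-5, c(0, 5e-5, 9e-5)))
  v_rob <- sample_potential(solve_field(field_problem(
    mesh, 0.2, c(base, list(top = bc_robin(g = 1e8, V0 = 0))), 1)),
    cbind(5e-5, 5e-5, c(0, 5e-5, 9e-5)))
  expect_lt(sqrt(sum((v_rob - v_dir)^2) / sum(v_dir^2)), 0.01)
  sol0 <- solve_field(field_problem(
    mesh, 0.2, c(base, list(top = bc_robin(g = 1e-9, V0 = 0))), 1))
  expect_lt(abs(integrate_boundary_current(sol0, "top")),
            1e-9 * 500 * 1e-8)  # vanishing relative to g1 V0 S
})

test_that("maximum principle: interior values stay within the boundary trace range", {
  set.seed(42)
  cs <- slab_case(1)
  mesh <- cs$mesh
  bnd <- unique(as.vector(do.call(rbind, mesh$facets)))
  rng <- range(cs$sol$u[bnd])
  pts <- cbind(runif(50, 0, 1e-4), runif(50, 0, 1e-4), runif(50, 0, 1e-4))
  v <- sample_potential(cs$sol, pts)
  expect_true(all(v >= rng[1] - 1e-12 & v <= rng[2] + 1e-12))
})

test_that("sampling reproduces nodal values and rejects outside points", {
  cs <- slab_case(2)
  mesh <- cs$mesh
  idx <- c(1L, 37L, nrow(mesh$nodes))
  v <- sample_potential(cs$sol, mesh$nodes[idx, , drop = FALSE])
  expect_lt(max(abs(v - cs$sol$u[idx])), 1e-12)
  expect_error(sample_potential(cs$sol, cbind(2e-4, 0, 0)), "outside")
})

test_that("ill-posed and ill-formed problems are rejected", {
  mesh <- build_slab_mesh(nx = 2, ny = 2, nz = 2)
  expect_error(field_problem(mesh, 0.2, list(bottom = bc_insulating())),
               "well-posed")
  expect_error(field_problem(mesh, 0.2, list(nope = bc_dirichlet(0))),
               "unknown tag")
  expect_error(field_problem(mesh, -1, list(bottom = bc_dirichlet(0))),
               "positive")
  # disconnected electrode: zero-area never happens, but a zero-current
  # calibration target must fail cleanly
  pr <- field_problem(mesh, 0.2, list(bottom = bc_robin(g = 500, V0 = 1),
                                      top = bc_robin(g = 500, V0 = 0)), 1)
  expect_error(calibrate_stimulus(pr, "side", -1e-6), "Robin")
})

test_that("two-pass calibration hits the target current and scales linearly", {
  mesh <- coarse_chamber()
  bcs <- list(electrode_4_4 = bc_robin(g = 500, V0 = 1),
              ground_surface = bc_robin(g = 500, V0 = 0))
  pr <- field_problem(mesh, 0.2, bcs, 1)
  cal <- calibrate_stimulus(pr, "electrode_4_4", -1e-6)
  expect_lt(abs(cal$I_stim / -1e-6 - 1), 0.005)
  expect_lt(abs(cal$I_return / 1e-6 - 1), 0.02)   # conservation cross-check
  cal2 <- calibrate_stimulus(pr, "electrode_4_4", -2e-6)
  expect_lt(abs(cal2$V0 / (2 * cal$V0) - 1), 1e-9) # linearity
  # the interface approximation g V0 S agrees with the integral within 20%
  S <- sum(neurostimfem:::triangle_areas(mesh$nodes, mesh$facets$electrode_4_4))
  expect_lt(abs(500 * cal$V0 * S / cal$I_stim - 1), 0.2)
})

test_that("point-source shell field follows I/(4 pi sigma r)", {
  # octant spherical shell, Robin source inner sphere, Dirichlet outer
  sig <- 0.2
  mesh <- fixture("shell_coarse", function() {
    build_shell_mesh(r_inner = 5e-6, r_outer = 2.5e-3, n_layers = 18)
  })
  pr <- field_problem(mesh, sig, list(inner = bc_robin(g = 1e6, V0 = 1),
                                      outer = bc_dirichlet(0)), 2)
  sol <- solve_field(pr)
  I <- integrate_boundary_current(sol, "inner") * 8
  rr <- c(5e-5, 2e-4)
  v <- sample_potential(sol, outer(rr, c(1, 1, 1) / sqrt(3)))
  v_exact <- I / (4 * pi * sig) * (1 / rr - 1 / 2.5e-3)
  expect_lt(max(abs(v / v_exact - 1)), 0.02)
})
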