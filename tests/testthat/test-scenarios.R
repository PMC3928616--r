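test_that("fwhm handles triangles, Gaussians and degenerate profiles", {
  # unit triangle of base 2 -> FWHM exactly 1
  x <- seq(-1, 1, by = 0.05)
  expect_equal(fwhm(x, pmax(0, 1 - abs(x))), 1, tolerance = 1e-12)
  # Gaussian: FWHM = 2 sqrt(2 log 2) sigma ~ 2.355 sigma
  sg <- 0.31
  x <- seq(-2, 2, by = 0.01)
  expect_equal(fwhm(x, exp(-x^2 / (2 * sg^2))), 2.3548 * sg, tolerance = 1e-3)
  # monotone profile: no interior maximum
  expect_error(fwhm(x, x), "maximum")
  # peak present but half level never reached on one side
  expect_error(fwhm(seq(0, 1, 0.1), c(6, 7, 8, 9, 10, 9.5, 9, 8.5, 8, 7.5, 7)),
               "half-maximum")
})

test_that("focality runs are deterministic and internally consistent", {
  p <- mea_params()
  mesh <- coarse_chamber()
  r1 <- run_focality(p, g_sweep = c(500), mesh = mesh, n_samples = 81)
  r2 <- run_focality(p, g_sweep = c(500), mesh = mesh, n_samples = 81)
  expect_identical(r1$profiles, r2$profiles)   # deterministic pipeline
  expect_identical(r1$fwhm, r2$fwhm)
  # every profile is normalized to peak 1
  for (cf in unique(r1$profiles$config)) {
    expect_equal(max(r1$profiles$v_norm[r1$profiles$config == cf]), 1)
  }
  expect_setequal(r1$fwhm$config,
                  c("monopolar", "ground_surface_g500",
                    "ground_surface_dirichlet"))
})

test_that("zero-current mirror run reports an undefined correlation", {
  r <- run_mirror_fiber(mea_params(), I_target = 0, mesh = coarse_chamber())
  expect_identical(r$correlation, NA_real_)
  expect_equal(r$mirror_error, 0)
  expect_equal(r$p2p, 0)
})

test_that("mirror pipeline on a coarse chamber already shows the mirror shape", {
  r <- fixture("mirror_coarse", function() {
    run_mirror_fiber(mea_params(), mesh = coarse_chamber())
  })
  expect_identical(length(r$y), 260L)
  expect_gt(r$correlation, 0.99)
  expect_lt(abs(r$I_stim + 1e-6) / 1e-6, 0.005)
  # cathodic stimulation depolarizes the fiber center, hyperpolarizes the ends
  dev <- r$vm - (-65e-3)
  expect_gt(dev[130], 0)
  expect_lt(dev[1], 0)
})

test_that("scenario configuration files round-trip through the unit conversions", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "chamber:", "  radius_um: 800", "  height_um: 600", "  layout: single",
    "neuron:", "  fiber_length_um: 120", "  soma_diameter_um: 20",
    "membrane:", "  gl_mS_cm2: 2e-4", "  El_mV: -70",
    "stimulation:", "  I_uA: -2", "  width_ms: 0.5",
    "solver:", "  Ra_ohm_cm: 150", "  dt_ms: 0.025"), path)
  cfg <- read_scenario_config(path)
  expect_equal(cfg$params$chamber_radius, 800e-6)
  expect_identical(cfg$params$layout, "single")
  expect_equal(cfg$neuron$soma_diameter, 20e-6)
  expect_equal(cfg$membrane$gl, 2e-3)          # 2e-4 mS/cm^2 -> S/m^2
  expect_equal(cfg$membrane$El, -0.07)
  expect_equal(cfg$stim$I_target, -2e-6)
  expect_equal(cfg$stim$pulse$segments$t_end, 1.5e-3)
  expect_equal(cfg$solver$Ra, 1.5)
  expect_equal(cfg$solver$dt, 2.5e-5)
})

test_that("potential and trace exports round-trip through their text formats", {
  cs_mesh <- build_slab_mesh()
  sol <- solve_field(field_problem(cs_mesh, 0.2,
                                   list(bottom = bc_robin(g = 500, V0 = 1),
                                        top = bc_robin(g = 2000, V0 = 0)), 1))
  pts <- cbind(5e-5, 5e-5, c(1e-5, 9e-5))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_potential_tsv(sol, pts, path)
  back <- read_potential_tsv(path)
  expect_equal(back$V, sample_potential(sol, pts), tolerance = 1e-12)
  mod <- fiber_model(dx = 26e-6)
  tr <- simulate_cable(mod, rep(0, 10), waveform_rect(), dt = 1e-4, T_end = 5e-4)
  p2 <- withr::local_tempfile(fileext = ".csv")
  export_trace_csv(tr, p2)
  back2 <- utils::read.csv(p2)
  expect_equal(ncol(back2), 11L)
  expect_equal(back2$c1, tr$vm[, 1], tolerance = 1e-12)
})

test_that("the reduced comparison chamber preserves the field shape along the fiber", {
  # the whole-FEM comparison runs on a single-electrode reduced chamber; the
  # extracellular profile along the fiber line keeps its shape (the absolute
  # amplitude shifts because the neighboring electrodes' insulating gaps and
  # the chamber wall move, which affects both pathways identically and
  # cancels in the peak-to-peak-relative comparison metrics)
  pts <- cbind(0, seq(-130e-6, 130e-6, length.out = 27), 50e-6)
  ve_profile <- function(params, mesh) {
    stim <- neurostimfem:::stim_electrode_tag(params)
    bcs <- stats::setNames(list(bc_robin(g = 500, V0 = 1),
                                bc_robin(g = 500, V0 = 0)),
                           c(stim, "ground_surface"))
    cal <- calibrate_stimulus(field_problem(mesh, 0.2, bcs, 1), stim, -1e-6)
    sample_potential(cal$sol, pts)
  }
  v_full <- ve_profile(mea_params(), coarse_chamber())
  p_red <- mea_params(layout = "single", chamber_radius = 5e-4,
                      chamber_height = 3e-4)
  v_red <- ve_profile(p_red, build_mea_chamber(p_red, "coarse"))
  expect_gt(stats::cor(v_full, v_red), 0.99)
  # after matching mean and scale the profiles agree within 5% of peak-to-peak
  fit <- stats::lm(v_full ~ v_red)
  expect_lt(max(abs(stats::residuals(fit))) / diff(range(v_full)), 0.05)
})
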