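# Shared, lazily built fixtures. Everything is generated in code; expensive
# meshes are memoized for the duration of the test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# coarse 60-electrode chamber (tag bookkeeping, smoke tests)
coarse_chamber <- function() {
  fixture("coarse_chamber", function() {
    build_mea_chamber(mea_params(), detail = "coarse")
  })
}

# small single-electrode chamber for coupled unit tests
small_params <- function() {
  mea_params(layout = "single", chamber_radius = 4e-4, chamber_height = 2.5e-4)
}

short_fiber <- function() neuron_geometry(fiber_length = 80e-6)

small_fiber_mesh <- function() {
  fixture("small_fiber_mesh", function() {
    embed_neuron_surface(small_params(), short_fiber(), detail = "coarse")
  })
}

small_coupled <- function(V0 = -10, g_stim = 500, membrane = membrane_passive()) {
  build_coupled_problem(
    small_fiber_mesh(), 0.2, 1, membrane,
    bcs = list(electrode_1_1 = bc_robin(g = g_stim, V0 = V0),
               ground_surface = bc_robin(g = 500, V0 = 0)),
    stim_tags = "electrode_1_1")
}

# standard fiber cable model (bundled scenario parameter set)
fiber_model <- function(dx = 1e-6, membrane = membrane_passive()) {
  compartmentalize(morphology_fiber(), dx = dx, Ra = ohm_cm(100),
                   membrane = membrane)
}

# deSolve oracle for the gate ODE dx/dt = a (1 - x) - b x at fixed vtilde
gate_ode_oracle <- function(vtilde, x0, t_ms) {
  r <- hh_rates(vtilde)
  f <- function(t, y, parms) {
    list(c(r$an * (1 - y[1]) - r$bn * y[1],
           r$am * (1 - y[2]) - r$bm * y[2],
           r$ah * (1 - y[3]) - r$bh * y[3]))
  }
  out <- deSolve::lsoda(x0, c(0, t_ms), f, NULL, rtol = 1e-11, atol = 1e-12)
  out[nrow(out), -1]
}
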