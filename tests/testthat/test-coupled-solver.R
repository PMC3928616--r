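test_that("DoF bookkeeping duplicates the membrane trace and validates inputs", {
  mesh <- small_fiber_mesh()
  suppressMessages(cp1 <- build_coupled_problem(
    mesh, 0.2, 1, membrane_passive(),
    bcs = list(electrode_1_1 = bc_robin(g = 500, V0 = -1),
               ground_surface = bc_robin(g = 500, V0 = 0)),
    stim_tags = "electrode_1_1", orders = c(1L, 1L)))
  n_mem <- length(cp1$mem_vert_g)
  # with P1/P1: total DoF = unique mesh nodes + duplicated membrane vertices
  n_used <- length(unique(as.vector(mesh$tets)))
  expect_identical(cp1$se$n_dof + cp1$si$n_dof, n_used + n_mem)
  expect_message(build_coupled_problem(
    mesh, 0.2, 1, membrane_passive(),
    bcs = list(ground_surface = bc_robin(g = 500, V0 = 0)),
    orders = c(1L, 1L)), "linear")
  plain <- coarse_chamber()
  expect_error(build_coupled_problem(plain, 0.2, 1, membrane_passive(),
                                     list()), "membrane")
})

test_that("resting state is a fixed point of the coupled stepper", {
  cp <- fixture("small_coupled_passive", function() small_coupled())
  st <- coupled_rest_state(cp)
  for (k in 1:3) st <- coupled_step(cp, st, f_t = 0, dt = 5e-5)
  expect_lt(max(abs(st$V)), 1e-12)
  expect_lt(max(abs(st$Vint + 65e-3)), 1e-9)
})

test_that("passive coupled response is linear in the stimulus", {
  cp <- fixture("small_coupled_passive", function() small_coupled())
  run <- function(scale) {
    w <- waveform_rect(1e-4, 4e-4, scale)
    solve_coupled_transient(cp, w, dt = 5e-5, T_end = 5e-4)$final
  }
  a <- run(1); b <- run(2)
  dev_a <- membrane_vm(cp, a) + 65e-3
  dev_b <- membrane_vm(cp, b) + 65e-3
  expect_lt(max(abs(dev_b - 2 * dev_a)), 1e-7 * max(abs(dev_b)))
})

test_that("membrane current balances to zero over the closed interface", {
  cp <- fixture("small_coupled_passive", function() small_coupled())
  res <- solve_coupled_transient(cp, waveform_rect(1e-4, 4e-4, 1),
                                 dt = 5e-5, T_end = 5e-4)
  b <- res$balance[res$balance$I_abs > 1e-3 * max(res$balance$I_abs), ]
  expect_gt(nrow(b), 0)
  expect_lt(max(abs(b$I_net) / b$I_abs), 0.01)
})

test_that("a uniform transverse field polarizes the capsule antisymmetrically", {
  # box with Robin top/bottom plates driving a uniform field across a short
  # capsule; Vm must be antisymmetric under reflection through the axis plane
  z0 <- 50e-6
  nl <- neurostimfem:::neuron_lines(neuron_geometry(fiber_length = 40e-6), 1)
  x <- neurostimfem:::merge_lines(c(nl$x, -30e-6, 30e-6))
  y <- neurostimfem:::merge_lines(c(nl$y, -60e-6, 60e-6))
  z <- neurostimfem:::merge_lines(c(nl$z, z0 + c(-30e-6, 30e-6)))
  tm <- neurostimfem:::tensor_tet_mesh(x, y, z)
  d <- neurostimfem:::capsule_linf_distance(
    (tm$nodes[tm$tets[, 1], ] + tm$nodes[tm$tets[, 2], ] +
     tm$nodes[tm$tets[, 3], ] + tm$nodes[tm$tets[, 4], ]) / 4, z0, 20e-6)
  intra <- which(d < 1e-6)
  nodes <- neurostimfem:::map_capsule(z0, 20e-6, 1e-6, 8e-6,
                                      function(yy) rep(1e-6, length(yy)))(tm$nodes)
  tets <- neurostimfem:::orient_tets(nodes, tm$tets)
  mesh <- stim_mesh(nodes, tets,
                    subdomains = list(extracellular = setdiff(seq_len(nrow(tets)), intra),
                                      intracellular = intra))
  fi <- neurostimfem:::mesh_face_index(mesh)
  cen <- neurostimfem:::triangle_centroids(mesh$nodes, fi$boundary_faces)
  tag <- ifelse(cen[, 3] < z0 - 29.9e-6, "plate_lo",
         ifelse(cen[, 3] > z0 + 29.9e-6, "plate_hi", "insulating"))
  mesh$facets <- neurostimfem:::split_tris(fi$boundary_faces, tag)
  mesh$facets$membrane <- neurostimfem:::subdomain_interface(
    mesh, "extracellular", "intracellular")
  cp <- build_coupled_problem(
    mesh, 0.2, 1, membrane_passive(),
    bcs = list(plate_lo = bc_robin(g = 1e8, V0 = 1e-3),
               plate_hi = bc_robin(g = 1e8, V0 = -1e-3)),
    stim_tags = c("plate_lo", "plate_hi"))
  st <- coupled_rest_state(cp)
  st <- coupled_step(cp, st, f_t = 1, dt = 5e-5)
  xyz <- mesh$nodes[cp$mem_vert_g, , drop = FALSE]
  vm <- membrane_vm(cp, st) + 65e-3
  # pair each membrane vertex with its mirror image through z = z0
  key <- paste(round(xyz[, 1] * 1e9), round(xyz[, 2] * 1e9),
               round((2 * z0 - xyz[, 3]) * 1e9))
  self <- paste(round(xyz[, 1] * 1e9), round(xyz[, 2] * 1e9),
                round(xyz[, 3] * 1e9))
  mirror <- match(key, self)
  expect_false(anyNA(mirror))
  # antisymmetric up to discretization error (the tet split itself is not
  # reflection-symmetric)
  expect_lt(max(abs(vm + vm[mirror])), 0.1 * max(abs(vm)))
  # polarization scale: a transverse field E across an insulating cylinder
  # induces ~2 E a at the poles (steady state, thin membrane)
  E <- 2e-3 / 60e-6 * (0.2 * 1e8) / (0.2 * 1e8)  # plates are near-Dirichlet
  pole <- which.min(xyz[, 3])
  expect_gt(abs(vm[pole]), 0.8 * E * 1e-6)
  expect_lt(abs(vm[pole]), 3 * E * 1e-6)
})

test_that("gate fields stay in [0, 1] during an active coupled run", {
  cp <- small_coupled(V0 = -40, membrane = membrane_hh())
  res <- solve_coupled_transient(cp, waveform_rect(1e-4, 4e-4, 1),
                                 dt = 5e-5, T_end = 6e-4)
  g <- res$final$gates
  expect_true(all(unlist(g) >= 0 & unlist(g) <= 1))
  # gates actually moved off rest somewhere on the membrane
  rest <- gate_rest_state(1)
  expect_gt(max(abs(g$m - rest$m)), 1e-4)
})

test_that("membrane profile is constant at rest and side-resolved under stimulation", {
  cp <- fixture("small_coupled_passive", function() small_coupled())
  st <- coupled_rest_state(cp)
  prof <- extract_membrane_profile(cp, st, "bottom")
  expect_true(all(abs(prof$vm + 65e-3) < 1e-12))
  expect_true(!is.unsorted(prof$arclength, strictly = TRUE))
  res <- solve_coupled_transient(cp, waveform_rect(1e-4, 4e-4, 1),
                                 dt = 5e-5, T_end = 5e-4)
  bot <- extract_membrane_profile(cp, res$final, "bottom")
  top <- extract_membrane_profile(cp, res$final, "top")
  expect_true(all(bot$z <= 50e-6 + 1e-12))
  expect_true(all(top$z >= 50e-6 - 1e-12))
  # electrode-facing side is the more depolarized one above a cathode
  i0 <- which.min(abs(bot$y))
  expect_gt(bot$vm[i0], top$vm[which.min(abs(top$y))])
})

test_that("soma-pole polarization is mesh-converged under membrane-region refinement", {
  run <- function(refine) {
    par <- mea_params(layout = "single", chamber_radius = 4e-4,
                      chamber_height = 2.5e-4)
    neu <- neuron_geometry(fiber_length = 80e-6, soma_diameter = 20e-6)
    mesh <- embed_neuron_surface(par, neu, detail = "coarse", refine = refine)
    bcs <- list(electrode_1_1 = bc_robin(g = 500, V0 = 1),
                ground_surface = bc_robin(g = 500, V0 = 0))
    pr <- field_problem(mesh, list(extracellular = 0.2, intracellular = 0.2),
                        bcs, 1)
    cal <- calibrate_stimulus(pr, "electrode_1_1", -1e-6)
    bcs2 <- list(electrode_1_1 = bc_robin(g = 500, V0 = cal$V0),
                 ground_surface = bc_robin(g = 500, V0 = 0))
    cp <- build_coupled_problem(mesh, 0.2, 1, membrane_passive(), bcs2,
                                stim_tags = "electrode_1_1")
    res <- solve_coupled_transient(cp, waveform_rect(2e-4, 1e-3, 1),
                                   dt = 5e-5, T_end = 1.2e-3)
    bot <- extract_membrane_profile(cp, res$final, "bottom")
    top <- extract_membrane_profile(cp, res$final, "top")
    c(bot$vm[which.min(abs(bot$y))], top$vm[which.min(abs(top$y))]) + 65e-3
  }
  coarse <- run(1)
  fine <- run(2)   # doubled cross-section polygon order and radial rings
  expect_lt(max(abs(fine - coarse)) / max(abs(coarse)), 0.03)
})
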