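test_that("MEA chamber carries the full tag set and a consistent partition", {
  mesh <- coarse_chamber()
  tags <- names(mesh$facets)
  expect_length(grep("^electrode_", tags), 60L)
  expect_true(all(c("ground_surface", "insulating", "chamber_wall") %in% tags))
  # every electrode tag is non-empty
  ne <- vapply(mesh$facets[grep("^electrode_", tags)], nrow, 1L)
  expect_true(all(ne >= 1L))
  # tags partition the exterior boundary: counts match and no triangle is
  # tagged twice
  fi <- neurostimfem:::mesh_face_index(mesh)
  n_bnd <- nrow(fi$boundary_faces)
  all_tagged <- do.call(rbind, mesh$facets)
  expect_identical(nrow(all_tagged), n_bnd)
  keys <- neurostimfem:::face_keys(all_tagged, nrow(mesh$nodes))
  expect_false(any(duplicated(keys)))
  # positive volumes
  expect_gt(mesh_quality(mesh)$min_volume, 0)
})

test_that("substrate facet areas sum to the chamber disk area and improve with refinement", {
  p <- mea_params()
  area_err <- function(mesh) {
    tris <- do.call(rbind, mesh$facets)
    onsub <- matrix(abs(mesh$nodes[tris, 3]) < 1e-12, ncol = 3)
    tris <- tris[rowSums(onsub) == 3L, , drop = FALSE]
    abs(sum(neurostimfem:::triangle_areas(mesh$nodes, tris)) /
          (pi * p$chamber_radius^2) - 1)
  }
  e_coarse <- area_err(coarse_chamber())
  expect_lt(e_coarse, 0.01)
  e_fine <- area_err(fixture("full_chamber", function() {
    build_mea_chamber(mea_params(), detail = "full")
  }))
  expect_lt(e_fine, e_coarse)
})

test_that("disabling the ground surface leaves the substrate insulating", {
  p <- mea_params(ground_surface_enabled = FALSE)
  mesh <- build_mea_chamber(p, detail = "coarse")
  expect_null(mesh$facets$ground_surface)
  expect_length(grep("^electrode_", names(mesh$facets)), 60L)
})

test_that("embedded fiber capsule is watertight with the right volume", {
  mesh <- small_fiber_mesh()
  expect_setequal(names(mesh$subdomains), c("extracellular", "intracellular"))
  f <- mesh$facets$membrane
  expect_gt(nrow(f), 0)
  # watertight: every membrane edge shared by exactly two triangles
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2L))
  # interface triangles separate one intracellular from one extracellular tet
  side <- integer(nrow(mesh$tets))
  side[mesh$subdomains$intracellular] <- 1L
  fi <- neurostimfem:::mesh_face_index(mesh)
  mkeys <- neurostimfem:::face_keys(f, nrow(mesh$nodes))
  pk <- neurostimfem:::face_keys(fi$faces[fi$pair_a, , drop = FALSE],
                                 nrow(mesh$nodes))
  sel <- match(mkeys, pk)
  expect_false(anyNA(sel))
  s1 <- side[fi$owner[fi$pair_a[sel]]]
  s2 <- side[fi$owner[fi$pair_b[sel]]]
  expect_true(all(s1 + s2 == 1L))
  # capsule volume against the closed form (16-gon cross-section bias < 4%)
  neu <- short_fiber()
  rf <- neu$fiber_diameter / 2
  vol <- sum(neurostimfem:::tet_signed_volumes(mesh$nodes, mesh$tets)[
    mesh$subdomains$intracellular])
  v_exact <- pi * rf^2 * neu$fiber_length + 4 / 3 * pi * rf^3
  expect_lt(abs(vol / v_exact - 1), 0.04)
})

test_that("fiber-with-soma yields one connected intracellular subdomain", {
  mesh <- fixture("small_soma_mesh", function() {
    embed_neuron_surface(small_params(),
                         neuron_geometry(fiber_length = 80e-6,
                                         soma_diameter = 20e-6),
                         detail = "coarse")
  })
  intra <- mesh$subdomains$intracellular
  # connectivity via shared faces among intracellular tets
  fi <- neurostimfem:::mesh_face_index(mesh)
  side <- logical(nrow(mesh$tets)); side[intra] <- TRUE
  a <- fi$owner[fi$pair_a]; b <- fi$owner[fi$pair_b]
  keep <- side[a] & side[b]
  # breadth-first search over the intracellular face-adjacency graph
  loc <- integer(nrow(mesh$tets)); loc[intra] <- seq_along(intra)
  adj <- split(c(loc[b[keep]], loc[a[keep]]), c(loc[a[keep]], loc[b[keep]]))
  seen <- logical(length(intra)); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    nb <- unique(unlist(adj[as.character(queue)], use.names = FALSE))
    queue <- nb[!seen[nb]]
    seen[queue] <- TRUE
  }
  expect_true(all(seen))
  # soma bulge present: membrane reaches z0 +- soma radius
  mem_z <- range(mesh$nodes[unique(as.vector(mesh$facets$membrane)), 3])
  expect_lt(abs(mem_z[1] - 40e-6), 1e-9)
  expect_lt(abs(mem_z[2] - 60e-6), 1e-9)
})

test_that("neuron placement is validated", {
  expect_error(embed_neuron_surface(
    small_params(), neuron_geometry(height_above_substrate = 0.5e-6),
    detail = "coarse"), "substrate")
  expect_error(embed_neuron_surface(
    mea_params(layout = "single", chamber_radius = 1e-4, chamber_height = 1e-4),
    neuron_geometry(), detail = "coarse"), "inside the chamber")
  expect_error(neuron_geometry(soma_diameter = 1e-6), "exceed")
})

test_that("refine_near reaches the target edge, is idempotent, and refuses below the floor", {
  mesh <- coarse_chamber()
  ref <- refine_near(mesh, "electrode_4_4", 5e-6)
  expect_lte(max_edge_in_region(ref, "electrode_4_4"), 5e-6)
  # idempotence: repeating the same request changes nothing, and refining
  # the whole domain to its current maximum edge is a no-op
  again <- refine_near(ref, "electrode_4_4", 5e-6)
  expect_identical(again, ref)
  whole <- function(pts) rep(TRUE, nrow(pts))
  cur <- max(neurostimfem:::tet_edge_lengths(mesh$nodes, mesh$tets))
  expect_identical(refine_near(mesh, whole, cur), mesh)
  expect_error(refine_near(mesh, "electrode_4_4", 1e-8), "below the configured")
})

test_that("refinement controls the discretization error of the potential", {
  # probe 50 um above a small electrode: successive refinement changes the
  # potential by < 2% (two-level Richardson-style check)
  p <- mea_params()
  probe <- cbind(0, 0, 50e-6)
  bcs <- list(electrode_4_4 = bc_robin(g = 500, V0 = -1),
              ground_surface = bc_robin(g = 500, V0 = 0))
  v1 <- sample_potential(solve_field(field_problem(coarse_chamber(), 0.2, bcs, 1)),
                         probe)
  mesh2 <- fixture("full_chamber", function() {
    build_mea_chamber(mea_params(), detail = "full")
  })
  v2 <- sample_potential(solve_field(field_problem(mesh2, 0.2, bcs, 1)), probe)
  mesh3 <- refine_near(mesh2, rbind(probe, c(0, 0, 0)), 4e-6)
  v3 <- sample_potential(solve_field(field_problem(mesh3, 0.2, bcs, 1)), probe)
  expect_lt(abs(v3 / v2 - 1), 0.02)
  expect_lt(abs(v3 / v2 - 1), abs(v2 / v1 - 1))
})
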