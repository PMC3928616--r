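#' Multielectrode-array chamber parameters
#'
#' Describes the in-vitro MEA stimulation chamber: a cylindrical bath of
#' conductive medium over a planar substrate carrying circular
#' microelectrodes and, optionally, a conductive ground surface covering the
#' substrate except for an annular insulating gap around each electrode.
#'
#' Defaults follow the standard in-vitro design: 60 planar electrodes of
#' 10 um diameter on an 8-by-8 grid without the four corners, 100 um pitch,
#' 10 um electrode-to-ground gap. Chamber radius and height default to
#' 1.5 mm and 1 mm. The electrode grid is positioned so that electrode
#' (row 4, col 4) sits at the origin, which is the default stimulation site.
#'
#' @param chamber_radius,chamber_height cylinder dimensions (m).
#' @param electrode_diameter electrode disk diameter (m).
#' @param pitch electrode spacing (m).
#' @param layout `"mea60"` (8x8 minus corners) or `"single"` (one electrode at
#'   the origin, used for reduced single-electrode domains).
#' @param ground_gap width of the insulating annulus between each electrode
#'   and the ground surface (m).
#' @param ground_surface_enabled if `FALSE` the substrate outside the
#'   electrodes is insulating (monopolar support).
#' @return an object of class `mea_params`.
#' @export
mea_params <- function(chamber_radius = 1.5e-3,
                       chamber_height = 1e-3,
                       electrode_diameter = 10e-6,
                       pitch = 100e-6,
                       layout = c("mea60", "single"),
                       ground_gap = 10e-6,
                       ground_surface_enabled = TRUE) {
  layout <- match.arg(layout)
  stopifnot(electrode_diameter > 0, electrode_diameter < pitch,
            ground_gap > 0, chamber_radius > 0, chamber_height > 0)
  p <- structure(list(
    chamber_radius = chamber_radius, chamber_height = chamber_height,
    electrode_diameter = electrode_diameter, pitch = pitch, layout = layout,
    ground_gap = ground_gap, ground_surface_enabled = ground_surface_enabled
  ), class = "mea_params")
  ec <- electrode_centers(p)
  r_max <- max(sqrt(ec$x^2 + ec$y^2)) + electrode_diameter / 2 + ground_gap
  if (r_max >= 0.6 * chamber_radius) {
    stop("electrode array (extent ", format(r_max), " m) too large for the ",
         "chamber radius ", format(chamber_radius), " m")
  }
  p
}

#' Electrode site positions of an MEA layout
#'
#' @param params an [mea_params()].
#' @return data.frame with columns `name`, `row`, `col`, `x`, `y` (m).
#' @export
electrode_centers <- function(params) {
  if (params$layout == "single") {
    return(data.frame(name = "electrode_1_1", row = 1L, col = 1L, x = 0, y = 0))
  }
  g <- expand.grid(row = 1:8, col = 1:8)
  g <- g[!(g$row %in% c(1, 8) & g$col %in% c(1, 8)), ]  # drop 4 corners
  data.frame(
    name = sprintf("electrode_%d_%d", g$row, g$col),
    row = g$row, col = g$col,
    x = (g$col - 4) * params$pitch,
    y = (g$row - 4) * params$pitch
  )
}

#' Neuron geometry specification
#'
#' A straight fiber along the y axis at a given height above the substrate,
#' optionally carrying a spherical soma centered on the fiber axis at y = 0.
#' The membrane surface is a capsule (cylinder with hemispherical end caps),
#' unioned with the soma sphere when present.
#'
#' @param fiber_length fiber length (m).
#' @param fiber_diameter fiber diameter (m).
#' @param soma_diameter soma diameter (m) or `NULL` for a plain fiber.
#' @param height_above_substrate z position of the fiber axis (m).
#' @return an object of class `neuron_geometry`.
#' @export
neuron_geometry <- function(fiber_length = 260e-6,
                            fiber_diameter = 2e-6,
                            soma_diameter = NULL,
                            height_above_substrate = 50e-6) {
  stopifnot(fiber_diameter > 0, fiber_length > 0,
            height_above_substrate > 0)
  if (!is.null(soma_diameter) && soma_diameter <= fiber_diameter) {
    stop("soma_diameter must exceed fiber_diameter")
  }
  structure(list(
    fiber_length = fiber_length, fiber_diameter = fiber_diameter,
    soma_diameter = soma_diameter,
    height_above_substrate = height_above_substrate
  ), class = "neuron_geometry")
}

# radius profile r(y) of the membrane surface of revolution (y >= 0, m)
neuron_radius_profile <- function(neuron) {
  rf <- neuron$fiber_diameter / 2
  rs <- if (is.null(neuron$soma_diameter)) NULL else neuron$soma_diameter / 2
  function(y) {
    r <- rep(rf, length(y))
    if (!is.null(rs)) {
      inside <- y < rs
      r[inside] <- pmax(rf, sqrt(pmax(rs^2 - y[inside]^2, 0)))
    }
    r
  }
}

# --- grid line construction --------------------------------------------------

# In-plane lines (one axis) for the chamber: electrode-aligned fine lines,
# gap fillers, graded far region, wall blend rings. All in meters.
chamber_axis_lines <- function(centers, r_e, gap, r_blend, r_wall,
                               stim_center = 0, detail = "full") {
  centers <- sort(unique(centers))
  ln <- c()
  for (cc in centers) {
    ln <- c(ln, cc - r_e, cc, cc + r_e)
  }
  # fillers between neighboring electrode columns
  if (length(centers) > 1) {
    pit <- min(diff(centers))
    for (cc in centers[-length(centers)]) {
      if (detail == "full") {
        ln <- c(ln, cc + pit * c(0.33, 0.66))
      } else {
        ln <- c(ln, cc + pit * 0.5)
      }
    }
  }
  # local refinement around the stimulation site (profile accuracy region)
  if (detail == "full") {
    ln <- c(ln, stim_center + c(-1, 1) * rep(c(r_e + gap, 2 * r_e,
                                               2.2e-5, 3e-5, 4e-5, 5.2e-5,
                                               6.6e-5, 8.2e-5), each = 1))
  } else {
    ln <- c(ln, stim_center + c(-1, 1) * (r_e + gap))
  }
  span <- range(c(ln, stim_center))
  h0 <- if (detail == "full") 3e-5 else 8e-5
  ln <- c(ln,
          graded_seq(span[2], r_blend, h0, 1.45)[-1],
          graded_seq(span[1], -r_blend, h0, 1.45)[-1],
          graded_seq(r_blend, r_wall, (r_wall - r_blend) / 5, 1.2)[-1],
          graded_seq(-r_blend, -r_wall, (r_wall - r_blend) / 5, 1.2)[-1])
  merge_lines(ln, tol = 2e-7)
}

chamber_z_lines <- function(height, z_fiber = 50e-6, detail = "full") {
  if (detail == "full") {
    base <- c(0, 2.5, 5, 9, 15, 24, 36, 50, 65, 90, 130, 185, 260, 370, 520,
              730, 1000) * 1e-6
  } else {
    base <- c(0, 5, 12, 25, 50, 95, 180, 340, 620, 1000) * 1e-6
  }
  z <- base * (height / 1e-3)
  merge_lines(c(z[z < height], height, z_fiber), tol = 2e-7)
}

# capsule-aligned extra lines for a neuron embedding; refine >= 2 halves the
# membrane-adjacent resolution (cross-section polygon, radial rings, axial step)
neuron_lines <- function(neuron, refine = 1) {
  rf <- neuron$fiber_diameter / 2
  z0 <- neuron$height_above_substrate
  yh <- neuron$fiber_length / 2
  soma <- !is.null(neuron$soma_diameter)
  rs <- if (soma) neuron$soma_diameter / 2 else rf
  r_outer <- if (soma) 2 * rs else 8 * rf
  # radial levels: must include rf (membrane) exactly
  if (soma) {
    rl <- rf * c(0.5, 1, 1.5, 2.25, 3.5, 5.5, 8, 12, 16, 20)
    if (refine >= 2) rl <- rf * c(0.25, 0.5, 0.75, 1, 1.25, 1.6, 2.25, 3.5,
                                  5.5, 8, 10, 12, 14, 16, 18, 20)
  } else {
    rl <- rf * c(0.5, 1, 1.75, 3, 5, 8)
    if (refine >= 2) rl <- rf * c(0.25, 0.5, 0.75, 1, 1.35, 1.75, 2.4, 3, 4, 5,
                                  6.5, 8)
  }
  rl <- rl[rl <= r_outer]
  if (max(rl) < r_outer) rl <- c(rl, r_outer)
  x <- c(0, rl, -rl)
  z <- z0 + c(0, rl, -rl)
  # along the fiber: moderate axial resolution + soma profile + end caps
  ystep <- 8e-6
  y_in <- seq(0, yh, by = ystep)
  if (abs(y_in[length(y_in)] - yh) > 1e-9) y_in <- c(y_in, yh)
  if (soma) {
    ys <- c(2e-6, 4e-6, 6e-6, 8e-6, 9.2e-6, sqrt(max(rs^2 - rf^2, 0)), rs)
    y_in <- c(y_in, ys[ys < yh])
  }
  y_cap <- yh + rl
  y <- c(y_in, y_cap, -y_in, -y_cap)
  list(x = merge_lines(x, tol = 1e-8), y = merge_lines(y, tol = 1e-8),
       z = merge_lines(z, tol = 1e-8),
       r_grid = rf, r_outer = r_outer, z0 = z0, y_half = yh)
}

# --- builders ----------------------------------------------------------------

# Shared construction path: tensor grid -> maps -> tags. `lines` is a list
# with x, y, z (pre-map coordinates, m).
mea_build <- function(params, lines, neuron = NULL) {
  r_wall <- params$chamber_radius
  r_blend <- attr(lines, "r_blend")
  tm <- tensor_tet_mesh(lines$x, lines$y, lines$z)
  nodes <- tm$nodes
  sub <- NULL
  if (!is.null(neuron)) {
    nl <- attr(lines, "neuron_lines")
    d <- capsule_linf_distance(
      cbind((tm$nodes[tm$tets[, 1], 1] + tm$nodes[tm$tets[, 2], 1] +
             tm$nodes[tm$tets[, 3], 1] + tm$nodes[tm$tets[, 4], 1]) / 4,
            (tm$nodes[tm$tets[, 1], 2] + tm$nodes[tm$tets[, 2], 2] +
             tm$nodes[tm$tets[, 3], 2] + tm$nodes[tm$tets[, 4], 2]) / 4,
            (tm$nodes[tm$tets[, 1], 3] + tm$nodes[tm$tets[, 2], 3] +
             tm$nodes[tm$tets[, 3], 3] + tm$nodes[tm$tets[, 4], 3]) / 4),
      nl$z0, nl$y_half)
    intra <- which(d < nl$r_grid)
    if (!length(intra)) stop("neuron surface not resolved by the grid")
    sub <- list(extracellular = setdiff(seq_len(nrow(tm$tets)), intra),
                intracellular = intra)
    cap_map <- map_capsule(nl$z0, nl$y_half, nl$r_grid, nl$r_outer,
                           neuron_radius_profile(neuron))
    nodes <- cap_map(nodes)
  }
  wall_map <- map_cylinder_wall(r_blend, r_wall)
  nodes <- wall_map(nodes)
  tets <- orient_tets(nodes, tm$tets)

  mesh <- stim_mesh(nodes, tets, subdomains = sub)
  mesh$facets <- mea_tags(mesh, params)
  if (!is.null(neuron)) {
    mesh$facets$membrane <- subdomain_interface(mesh, "extracellular",
                                                "intracellular")
  }
  mesh$meta <- list(params = params, lines = lines, neuron = neuron,
                    builder = "mea")
  mesh
}

# classify exterior boundary triangles of the chamber
mea_tags <- function(mesh, params) {
  fi <- mesh_face_index(mesh)
  tris <- fi$boundary_faces
  cen <- triangle_centroids(mesh$nodes, tris)
  r_e <- params$electrode_diameter / 2
  gap <- params$ground_gap
  htol <- 1e-9
  on_substrate <- cen[, 3] < htol
  # wall facets: all three vertices at the chamber radius
  vr <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  on_wall <- matrix(vr[tris] > params$chamber_radius * (1 - 1e-9), ncol = 3)
  on_wall <- rowSums(on_wall) == 3 & !on_substrate

  ec <- electrode_centers(params)
  # distance from each substrate centroid to nearest electrode center
  nearest <- rep(NA_integer_, nrow(cen))
  mind <- rep(Inf, nrow(cen))
  sub_i <- which(on_substrate)
  for (k in seq_len(nrow(ec))) {
    d <- sqrt((cen[sub_i, 1] - ec$x[k])^2 + (cen[sub_i, 2] - ec$y[k])^2)
    upd <- d < mind[sub_i]
    nearest[sub_i[upd]] <- k
    mind[sub_i[upd]] <- d[upd]
  }
  tags <- rep("insulating", nrow(tris))
  tags[on_wall] <- "chamber_wall"
  is_elec <- on_substrate & mind <= r_e
  tags[is_elec] <- ec$name[nearest[is_elec]]
  in_gap <- on_substrate & mind > r_e & mind <= r_e + gap
  tags[in_gap] <- "insulating"
  far_sub <- on_substrate & mind > r_e + gap
  tags[far_sub] <- if (params$ground_surface_enabled) "ground_surface" else "insulating"

  split_idx <- split(seq_len(nrow(tris)), tags)
  out <- lapply(split_idx, function(i) tris[i, , drop = FALSE])
  # keep stable, readable order
  ord <- c(sort(intersect(ec$name, names(out))),
           intersect(c("ground_surface", "chamber_wall", "insulating"), names(out)))
  out[ord]
}

default_chamber_lines <- function(params, neuron = NULL, detail = "full",
                                  refine = 1) {
  r_blend <- 0.6 * params$chamber_radius
  ec <- electrode_centers(params)
  r_e <- params$electrode_diameter / 2
  x <- chamber_axis_lines(ec$x, r_e, params$ground_gap, r_blend,
                          params$chamber_radius, 0, detail)
  y <- chamber_axis_lines(ec$y, r_e, params$ground_gap, r_blend,
                          params$chamber_radius, 0, detail)
  zf <- if (is.null(neuron)) 50e-6 else neuron$height_above_substrate
  z <- chamber_z_lines(params$chamber_height, zf, detail)
  if (!is.null(neuron)) {
    nl <- neuron_lines(neuron, refine)
    extent <- max(abs(c(nl$x, nl$y)), nl$z0 + nl$r_outer)
    if (extent >= r_blend || nl$z0 + nl$r_outer >= params$chamber_height) {
      stop("neuron does not fit strictly inside the chamber interior ",
           "(extent ", format(extent), " m)")
    }
    if (nl$z0 - max(neuron_radius_profile(neuron)(0), nl$r_grid) <= 0) {
      stop("neuron touches the substrate")
    }
    x <- merge_lines(c(x, nl$x), tol = 1e-8)
    y <- merge_lines(c(y, nl$y), tol = 1e-8)
    z <- merge_lines(c(z, nl$z), tol = 1e-8)
    z <- z[z >= 0 & z <= params$chamber_height]
  }
  lines <- list(x = x, y = y, z = z)
  attr(lines, "r_blend") <- r_blend
  if (!is.null(neuron)) attr(lines, "neuron_lines") <- neuron_lines(neuron, refine)
  lines
}

#' Build the MEA chamber mesh
#'
#' Meshes the cylindrical chamber with a graded structured tetrahedral grid.
#' Substrate triangles are tagged per electrode (`electrode_<row>_<col>`), as
#' `ground_surface` (when enabled; substrate minus electrode disks minus the
#' annular gaps), or as `insulating`; the lateral wall is tagged
#' `chamber_wall` (used as the distant return in the monopolar
#' configuration) and the remaining exterior boundary `insulating`.
#'
#' @param params an [mea_params()].
#' @param detail `"full"` (scenario accuracy) or `"coarse"` (fast, for
#'   bookkeeping and smoke tests).
#' @return a [stim_mesh()].
#' @export
build_mea_chamber <- function(params, detail = c("full", "coarse")) {
  detail <- match.arg(detail)
  lines <- default_chamber_lines(params, NULL, detail)
  mea_build(params, lines)
}

#' Embed a neuron membrane surface in the chamber mesh
#'
#' Builds the chamber as [build_mea_chamber()] and embeds the closed membrane
#' surface of `neuron` as an internal interface: the mesh gains an
#' `intracellular` subdomain, the remaining volume is `extracellular`, and
#' the interface triangles are tagged `membrane` (shared faces of exactly one
#' intracellular and one extracellular tetrahedron, oriented with normals
#' pointing from the extracellular side into the cell).
#'
#' @param mesh_spec an [mea_params()].
#' @param neuron a [neuron_geometry()]; must lie strictly inside the chamber
#'   without touching the substrate.
#' @inheritParams build_mea_chamber
#' @return a [stim_mesh()] with `extracellular`/`intracellular` subdomains
#'   and a `membrane` facet tag.
#' @export
embed_neuron_surface <- function(mesh_spec, neuron, detail = c("full", "coarse"),
                                 refine = 1) {
  detail <- match.arg(detail)
  lines <- default_chamber_lines(mesh_spec, neuron, detail, refine)
  mea_build(mesh_spec, lines, neuron = neuron)
}

#' Refine the mesh near a region
#'
#' Subdivides grid intervals of the structured generator until the diagonal
#' of every grid cell intersecting the region is at most `target_edge`, then
#' rebuilds the mesh. Refinement acts on tensor-product grid lines, so it
#' extends along entire grid slabs through the region; intervals outside the
#' region's extent on each axis are untouched.
#'
#' @param mesh a generator-built [stim_mesh()] (carries its grid metadata).
#' @param region facet tag name, an n x 3 matrix of points, or a predicate
#'   function over point matrices.
#' @param target_edge maximum allowed element edge length in the region (m).
#' @param min_edge refusal floor: requests below this are rejected (m).
#' @return the refined [stim_mesh()].
#' @export
refine_near <- function(mesh, region, target_edge, min_edge = 5e-7) {
  if (is.null(mesh$meta) || mesh$meta$builder != "mea") {
    stop("refine_near() requires a mesh built by this package's generator")
  }
  if (target_edge <= 0) stop("target_edge must be positive")
  if (target_edge < min_edge) {
    stop("target_edge ", format(target_edge), " m is below the configured ",
         "minimum of ", format(min_edge), " m")
  }
  # bounding box of the elements intersecting the region (grid coordinates:
  # node maps are the identity in the refinable interior)
  if (is.matrix(region) || is.data.frame(region)) {
    box <- apply(as.matrix(region), 2, range)
  } else {
    sel <- region_tets(mesh, region)
    if (!length(sel)) stop("region selects no elements")
    nn <- unique(as.vector(mesh$tets[sel, , drop = FALSE]))
    box <- apply(mesh$nodes[nn, , drop = FALSE], 2, range)
  }
  lines <- mesh$meta$lines
  changed <- FALSE
  for (pass in 1:60) {
    rng <- lapply(1:3, function(a) {
      v <- lines[[a]]
      # intervals strictly overlapping the box extent on this axis
      which(v[-length(v)] < box[2, a] - 1e-12 & v[-1] > box[1, a] + 1e-12)
    })
    h <- lapply(1:3, function(a) diff(lines[[a]])[rng[[a]]])
    H <- vapply(h, function(v) if (length(v)) max(v) else 0, 1)
    if (sqrt(sum(H^2)) <= target_edge) break
    a <- which.max(H)
    v <- lines[[a]]
    iv <- rng[[a]][h[[a]] > 0.9 * H[a]]
    mids <- (v[iv] + v[iv + 1]) / 2
    lines[[a]] <- merge_lines(c(v, mids), tol = 1e-9)
    changed <- TRUE
  }
  if (!changed) return(mesh)
  mea_build(mesh$meta$params, lines, neuron = mesh$meta$neuron)
}
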