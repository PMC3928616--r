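#' Analytic validation meshes
#'
#' Small geometries whose potential problems have closed-form solutions,
#' used to validate the solver against series-resistance, point-source and
#' disk-electrode formulas:
#'
#' * `build_slab_mesh()`: a box; tags `bottom` (z = 0), `top` (z = thickness)
#'   and `side`. With Robin conditions on both faces the current density is
#'   the series-resistance value `J = V0 / (1/g1 + L/sigma + 1/g2)`.
#' * `build_shell_mesh()`: one octant of a spherical shell (inner radius
#'   `r_inner`, outer `r_outer`), coordinate planes as natural symmetry
#'   boundaries; tags `inner`, `outer`, `symmetry`. A source at the inner
#'   sphere reproduces the point-source potential
#'   `V(r) = I/(4 pi sigma) (1/r - 1/R)`.
#' * `build_disk_mesh()`: a quarter cylinder of radius `extent*a` and equal
#'   height over a substrate carrying a disk electrode of radius `a` at the
#'   origin; tags `disk`, `substrate`, `far`, `symmetry`. The access
#'   resistance of the disk against a remote ground approaches `1/(4 sigma a)`.
#'
#' @param lx,ly box cross-section (m).
#' @param thickness slab thickness (m).
#' @param nx,ny,nz grid intervals.
#' @param r_inner,r_outer shell radii (m).
#' @param n_layers radial layers (geometric grading).
#' @param a disk radius (m).
#' @param extent domain size in units of `a`.
#' @return a [stim_mesh()].
#' @name oracle_meshes
NULL

#' @rdname oracle_meshes
#' @export
build_slab_mesh <- function(lx = 1e-4, ly = 1e-4, thickness = 1e-4,
                            nx = 4, ny = 4, nz = 10) {
  x <- seq(0, lx, length.out = nx + 1)
  y <- seq(0, ly, length.out = ny + 1)
  z <- seq(0, thickness, length.out = nz + 1)
  tm <- tensor_tet_mesh(x, y, z)
  tets <- orient_tets(tm$nodes, tm$tets)
  mesh <- stim_mesh(tm$nodes, tets)
  fi <- mesh_face_index(mesh)
  cen <- triangle_centroids(mesh$nodes, fi$boundary_faces)
  tol <- thickness * 1e-9
  tag <- ifelse(cen[, 3] < tol, "bottom",
                ifelse(cen[, 3] > thickness - tol, "top", "side"))
  mesh$facets <- split_tris(fi$boundary_faces, tag)
  mesh
}

#' @rdname oracle_meshes
#' @export
build_shell_mesh <- function(r_inner = 5e-6, r_outer = 2.5e-3, n_layers = 26) {
  ratio <- (r_outer / r_inner)^(1 / n_layers)
  levels <- r_inner * ratio^(0:n_layers)
  coords <- c(0, levels)
  tm <- tensor_tet_mesh(coords, coords, coords, keep_cell = function(cx, cy, cz) {
    pmax(cx, pmax(cy, cz)) > r_inner
  })
  cm <- compact_mesh_nodes(tm$nodes, tm$tets)
  nodes <- map_ball()(cm$nodes)
  tets <- orient_tets(nodes, cm$tets)
  mesh <- stim_mesh(nodes, tets)
  fi <- mesh_face_index(mesh)
  cen <- triangle_centroids(mesh$nodes, fi$boundary_faces)
  r <- sqrt(rowSums(cen^2))
  onplane <- cen[, 1] < r_inner * 1e-6 | cen[, 2] < r_inner * 1e-6 |
             cen[, 3] < r_inner * 1e-6
  tag <- ifelse(onplane, "symmetry",
                ifelse(r < 2 * r_inner, "inner", "outer"))
  mesh$facets <- split_tris(fi$boundary_faces, tag)
  mesh
}

#' @rdname oracle_meshes
#' @export
build_disk_mesh <- function(a = 5e-6, extent = 50) {
  rl <- a * c(0.25, 0.5, 0.7, 0.85, 0.95, 1, 1.06, 1.15, 1.3, 1.55, 2, 2.7,
              3.6, 5, 7, 10, 14, 20, 28, 38, 50)
  rl <- rl[rl <= extent * a]
  if (max(rl) < extent * a) rl <- c(rl, extent * a)
  xy <- c(0, rl)
  z <- a * c(0, 0.03, 0.08, 0.16, 0.28, 0.45, 0.7, 1, 1.5, 2.2, 3.2, 4.6,
             6.5, 9, 13, 18, 25, 34, 45, 50)
  z <- z[z <= extent * a]
  if (max(z) < extent * a) z <- c(z, extent * a)
  tm <- tensor_tet_mesh(xy, xy, z)
  nodes <- map_disk()(tm$nodes)
  tets <- orient_tets(nodes, tm$tets)
  mesh <- stim_mesh(nodes, tets)
  fi <- mesh_face_index(mesh)
  cen <- triangle_centroids(mesh$nodes, fi$boundary_faces)
  r <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  R <- extent * a
  tol <- a * 1e-6
  tag <- ifelse(cen[, 1] < tol | cen[, 2] < tol, "symmetry",
         ifelse(cen[, 3] < tol & r <= a, "disk",
         ifelse(cen[, 3] < tol, "substrate", "far")))
  mesh$facets <- split_tris(fi$boundary_faces, tag)
  mesh
}

split_tris <- function(tris, tag) {
  idx <- split(seq_len(nrow(tris)), tag)
  lapply(idx, function(i) tris[i, , drop = FALSE])
}
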