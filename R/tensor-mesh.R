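# Structured tensor-product tetrahedral meshing.
#
# Meshes are built on graded tensor-product hexahedral grids, each hexahedron
# split into six tetrahedra by the Kuhn (Freudenthal) decomposition, which is
# translation-invariant and therefore conforming across the whole grid. Curved
# geometry (cylinder walls, spheres, capsule membranes) is obtained by smooth
# node maps applied after connectivity is built: grid "rings" at constant
# L-infinity radius are mapped to Euclidean circles/spheres of the same radius,
# so tagged surfaces land exactly on the analytic geometry.

# Node index for grid position (i, j, k), 1-based.
grid_index <- function(i, j, k, nx, ny) i + (j - 1L) * nx + (k - 1L) * nx * ny

# Kuhn split of the unit hex: 6 tets, one per permutation of the axes, all
# sharing the main diagonal (0,0,0)-(1,1,1). Offsets are cumulative sums of
# the permuted unit vectors.
kuhn_offsets <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    e <- diag(3)[p, , drop = FALSE]
    rbind(c(0, 0, 0), apply(e, 2, cumsum))
  })
}

# Build nodes + tets for a tensor grid with coordinate vectors x, y, z.
# `keep_cell` optionally drops hexes: function(cx, cy, cz) -> logical, applied
# to hex centroids (pre-map coordinates).
tensor_tet_mesh <- function(x, y, z, keep_cell = NULL) {
  stopifnot(!is.unsorted(x, strictly = TRUE), !is.unsorted(y, strictly = TRUE),
            !is.unsorted(z, strictly = TRUE))
  nx <- length(x); ny <- length(y); nz <- length(z)
  nodes <- cbind(
    rep(x, times = ny * nz),
    rep(rep(y, each = nx), times = nz),
    rep(z, each = nx * ny)
  )
  # hex lower corners
  hi <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  hj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  hk <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  if (!is.null(keep_cell)) {
    cx <- (x[hi] + x[hi + 1L]) / 2
    cy <- (y[hj] + y[hj + 1L]) / 2
    cz <- (z[hk] + z[hk + 1L]) / 2
    keep <- keep_cell(cx, cy, cz)
    hi <- hi[keep]; hj <- hj[keep]; hk <- hk[keep]
  }
  offs <- kuhn_offsets()
  tet_list <- vector("list", 6L)
  for (t in seq_len(6L)) {
    o <- offs[[t]]
    tet_list[[t]] <- cbind(
      grid_index(hi + o[1, 1], hj + o[1, 2], hk + o[1, 3], nx, ny),
      grid_index(hi + o[2, 1], hj + o[2, 2], hk + o[2, 3], nx, ny),
      grid_index(hi + o[3, 1], hj + o[3, 2], hk + o[3, 3], nx, ny),
      grid_index(hi + o[4, 1], hj + o[4, 2], hk + o[4, 3], nx, ny)
    )
  }
  tets <- do.call(rbind, tet_list)
  storage.mode(tets) <- "integer"
  list(nodes = nodes, tets = tets,
       grid = list(x = x, y = y, z = z),
       hex_ijk = cbind(rep(hi, 6L), rep(hj, 6L), rep(hk, 6L)))
}

# Drop nodes not referenced by any tet, renumbering tets (and returning the
# old->new index map for bookkeeping).
compact_mesh_nodes <- function(nodes, tets) {
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  tets[] <- remap[tets]
  list(nodes = nodes[used, , drop = FALSE], tets = tets, node_map = remap)
}

# Signed tet volumes (positive for correctly oriented tets).
tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
   b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
   b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

# Reorient tets with negative signed volume (swap last two nodes).
orient_tets <- function(nodes, tets) {
  v <- tet_signed_volumes(nodes, tets)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
  }
  tets
}

# --- radial coordinate maps -------------------------------------------------

# Shared radial map machinery. Given a matrix of offset vectors `o` (rows;
# 2 or 3 columns), rescales each row so that its Euclidean length becomes
# sigma(s) * k^t(s), where s = L-inf norm, k = |o|_2 / s >= 1.
# t = 0 gives perfect circles/spheres of radius sigma(s); t = 1 leaves the
# grid shape (identity when sigma(s) = s). Monotonicity in s holds whenever
# sigma is increasing and d/ds [log sigma + t log k] > 0, which the callers'
# blends guarantee.
radial_rescale <- function(o, sigma, tfun) {
  s <- apply(abs(o), 1L, max)
  d <- sqrt(rowSums(o^2))
  fac <- rep(1, nrow(o))
  pos <- s > 0
  k <- d[pos] / s[pos]
  rho <- sigma(s[pos]) * k^tfun(s[pos])
  fac[pos] <- rho / d[pos]
  o * fac
}

# Map the in-plane square ring |.|_inf = r_wall to the circle of radius
# r_wall, identity inside r_blend. Applied to (x, y); z untouched.
map_cylinder_wall <- function(r_blend, r_wall) {
  stopifnot(r_blend < 0.65 * r_wall)  # monotonicity margin for the blend
  function(nodes) {
    tf <- function(s) pmin(1, pmax(0, (r_wall - s) / (r_wall - r_blend)))
    nodes[, 1:2] <- radial_rescale(nodes[, 1:2, drop = FALSE], identity, tf)
    nodes
  }
}

# Full square -> disk map in (x, y): every L-inf ring becomes a circle.
map_disk <- function() {
  function(nodes) {
    nodes[, 1:2] <- radial_rescale(nodes[, 1:2, drop = FALSE], identity,
                                   function(s) rep(0, length(s)))
    nodes
  }
}

# Full cube -> ball map in 3D (used for spherical shells; grid coordinate
# levels double as radial levels).
map_ball <- function(center = c(0, 0, 0)) {
  function(nodes) {
    o <- sweep(nodes, 2L, center)
    o <- radial_rescale(o, identity, function(s) rep(0, length(s)))
    sweep(o, 2L, center, `+`)
  }
}

# Capsule / soma map. The neuron axis runs along y at (x = 0, z = z0) between
# y = -y_half and y = +y_half (cylindrical part); beyond the ends the offset
# gains a third component |y| - y_half so L-inf "rings" become capsule end
# caps. Grid rings at radius r_grid map exactly onto the membrane surface of
# Euclidean radius r_profile(y) (a surface of revolution: r = fiber radius
# along the fiber, bulging over the soma), blending back to the untouched
# Cartesian grid at radius r_outer.
#
# sigma is piecewise linear: [0, r_grid] -> [0, r(y)]; [r_grid, r_outer] ->
# [r(y), r_outer]. The shape exponent t rises 0 -> 1 over [r_grid, r_outer]
# so the membrane itself is an exact circle of revolution.
map_capsule <- function(z0, y_half, r_grid, r_outer, r_profile) {
  force(z0); force(y_half); force(r_grid); force(r_outer)
  function(nodes) {
    ox <- nodes[, 1]
    oy <- pmax(abs(nodes[, 2]) - y_half, 0)
    oz <- nodes[, 3] - z0
    s <- pmax(abs(ox), pmax(oy, abs(oz)))
    inside <- s < r_outer & s > 0
    if (!any(inside)) return(nodes)
    oi <- cbind(ox, oy, oz)[inside, , drop = FALSE]
    si <- s[inside]
    di <- sqrt(rowSums(oi^2))
    ry <- r_profile(pmin(abs(nodes[inside, 2]), y_half))
    sig <- ifelse(si <= r_grid,
                  si * ry / r_grid,
                  ry + (si - r_grid) * (r_outer - ry) / (r_outer - r_grid))
    tt <- pmin(1, pmax(0, (si - r_grid) / (r_outer - r_grid)))
    k <- di / si
    fac <- sig * k^tt / di
    # apply: x and z scale directly; y scales only its offset beyond y_half
    nodes[inside, 1] <- oi[, 1] * fac
    nodes[inside, 3] <- z0 + oi[, 3] * fac
    cap <- oi[, 2] > 0
    if (any(cap)) {
      idx <- which(inside)[cap]
      nodes[idx, 2] <- sign(nodes[idx, 2]) * (y_half + oi[cap, 2] * fac[cap])
    }
    nodes
  }
}

# L-infinity distance to the capsule axis in grid coordinates (pre-map);
# used to classify intracellular hexes.
capsule_linf_distance <- function(pts, z0, y_half) {
  ox <- abs(pts[, 1])
  oy <- pmax(abs(pts[, 2]) - y_half, 0)
  oz <- abs(pts[, 3] - z0)
  pmax(ox, pmax(oy, oz))
}

# Graded 1D grids -------------------------------------------------------------

# Geometric sequence of points from `from` to `to` whose first interval is
# roughly h0, each subsequent interval growing by `ratio` (last point snapped
# to `to`).
graded_seq <- function(from, to, h0, ratio = 1.4) {
  stopifnot(h0 > 0, ratio >= 1)
  span <- abs(to - from)
  if (span <= h0) return(c(from, to))
  s <- numeric(0); acc <- 0; h <- h0
  while (acc + h < span) {
    acc <- acc + h
    s <- c(s, acc)
    h <- h * ratio
  }
  pts <- from + sign(to - from) * s
  # merge a too-short last interval into the final point
  if (length(pts) && abs(to - pts[length(pts)]) < 0.35 * abs(pts[length(pts)] -
      (if (length(pts) > 1) pts[length(pts) - 1] else from))) {
    pts <- pts[-length(pts)]
  }
  c(from, pts, to)
}

# Merge sorted line sets, dropping near-duplicates (within `tol`).
merge_lines <- function(..., tol = 1e-9) {
  v <- sort(unique(unlist(list(...))))
  if (length(v) < 2) return(v)
  keep <- c(TRUE, diff(v) > tol)
  v[keep]
}
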