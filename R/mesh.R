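#' Tetrahedral mesh with tagged boundaries and subdomains
#'
#' The central geometric container of the package: a tetrahedral volume mesh
#' with named facet tags (boundary and interface triangles) and named
#' subdomain tags (tetrahedra). Coordinates are in meters.
#'
#' @param nodes numeric n x 3 matrix of node coordinates (m).
#' @param tets integer m x 4 matrix of node indices (positive orientation).
#' @param facets named list of f x 3 integer matrices; each entry is one tag's
#'   set of boundary or interface triangles.
#' @param subdomains named list of integer vectors of tetrahedron indices.
#'   Every tetrahedron must belong to exactly one subdomain.
#'
#' @return An object of class `stim_mesh`.
#' @export
stim_mesh <- function(nodes, tets, facets = list(), subdomains = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  storage.mode(tets) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4,
            max(tets) <= nrow(nodes), min(tets) >= 1)
  if (is.null(subdomains)) {
    subdomains <- list(extracellular = seq_len(nrow(tets)))
  }
  m <- structure(
    list(nodes = nodes, tets = tets, facets = facets, subdomains = subdomains),
    class = "stim_mesh"
  )
  validate_stim_mesh(m)
  m
}

validate_stim_mesh <- function(m) {
  v <- tet_signed_volumes(m$nodes, m$tets)
  if (any(v <= 0)) {
    stop("mesh has ", sum(v <= 0), " non-positively oriented tetrahedra; ",
         "smallest signed volume ", format(min(v)))
  }
  for (tag in names(m$facets)) {
    f <- m$facets[[tag]]
    if (!is.matrix(f) || ncol(f) != 3) {
      stop("facet tag '", tag, "' is not an f x 3 index matrix")
    }
  }
  invisible(m)
}

#' @export
print.stim_mesh <- function(x, ...) {
  cat("<stim_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tets), " tets\n", sep = "")
  cat("  subdomains:", paste(sprintf("%s (%d)", names(x$subdomains),
                                     lengths(x$subdomains)), collapse = ", "), "\n")
  if (length(x$facets)) {
    nf <- vapply(x$facets, nrow, 1L)
    cat("  facet tags:", length(nf), "tags,", sum(nf), "triangles\n")
  }
  bb <- apply(x$nodes, 2, range)
  cat(sprintf("  bbox [m]: x %.3g..%.3g  y %.3g..%.3g  z %.3g..%.3g\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# --- face bookkeeping --------------------------------------------------------

# The four faces of each tet, oriented so the face normal points OUT of the
# tet when its nodes are taken in order.
tet_face_table <- function(tets) {
  m <- nrow(tets)
  # local faces (opposite node 4,3,2,1): orderings chosen for outward normals
  f1 <- tets[, c(1L, 3L, 2L), drop = FALSE]
  f2 <- tets[, c(1L, 2L, 4L), drop = FALSE]
  f3 <- tets[, c(2L, 3L, 4L), drop = FALSE]
  f4 <- tets[, c(1L, 4L, 3L), drop = FALSE]
  faces <- rbind(f1, f2, f3, f4)
  owner <- rep(seq_len(m), times = 4L)
  list(faces = faces, owner = owner)
}

face_keys <- function(faces, n_nodes) {
  a <- pmin(faces[, 1], pmin(faces[, 2], faces[, 3]))
  c_ <- pmax(faces[, 1], pmax(faces[, 2], faces[, 3]))
  b <- as.numeric(faces[, 1]) + faces[, 2] + faces[, 3] - a - c_
  N <- as.numeric(n_nodes) + 1
  (a * N + b) * N + c_
}

# Exterior boundary faces (appear once) and interior shared faces (twice).
mesh_face_index <- function(m) {
  ft <- tet_face_table(m$tets)
  key <- face_keys(ft$faces, nrow(m$nodes))
  o <- order(key)
  key_s <- key[o]
  first_of_pair <- which(diff(key_s) == 0)
  is_dup <- logical(length(key_s))
  is_dup[first_of_pair] <- TRUE
  is_dup[first_of_pair + 1L] <- TRUE
  bnd <- o[!is_dup]
  list(
    boundary_faces = ft$faces[bnd, , drop = FALSE],
    boundary_owner = ft$owner[bnd],
    pair_a = o[first_of_pair],
    pair_b = o[first_of_pair + 1L],
    faces = ft$faces,
    owner = ft$owner
  )
}

# Interface triangles between two subdomains: shared faces whose two owner
# tets belong to different subdomains. Returned oriented outward from
# `from_tag`'s side.
subdomain_interface <- function(m, from_tag, to_tag) {
  fi <- mesh_face_index(m)
  side <- integer(nrow(m$tets))
  side[m$subdomains[[from_tag]]] <- 1L
  side[m$subdomains[[to_tag]]] <- 2L
  oa <- fi$owner[fi$pair_a]; ob <- fi$owner[fi$pair_b]
  sel_ab <- side[oa] == 1L & side[ob] == 2L
  sel_ba <- side[oa] == 2L & side[ob] == 1L
  rbind(fi$faces[fi$pair_a[sel_ab], , drop = FALSE],
        fi$faces[fi$pair_b[sel_ba], , drop = FALSE])
}

# --- facet geometry ----------------------------------------------------------

triangle_areas <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE] - a
  c <- nodes[tris[, 3], , drop = FALSE] - a
  nx <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  ny <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  nz <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  sqrt(nx^2 + ny^2 + nz^2) / 2
}

triangle_normals <- function(nodes, tris) {
  a <- nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 2], , drop = FALSE] - a
  c <- nodes[tris[, 3], , drop = FALSE] - a
  n <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
             b[, 3] * c[, 1] - b[, 1] * c[, 3],
             b[, 1] * c[, 2] - b[, 2] * c[, 1])
  n / sqrt(rowSums(n^2))
}

triangle_centroids <- function(nodes, tris) {
  (nodes[tris[, 1], , drop = FALSE] +
   nodes[tris[, 2], , drop = FALSE] +
   nodes[tris[, 3], , drop = FALSE]) / 3
}

# Extract one subdomain as a standalone mesh with compacted node numbering.
# Returns the submesh plus the global->local node map (0 where absent).
submesh <- function(mesh, tag) {
  sel <- mesh$subdomains[[tag]]
  if (is.null(sel)) stop("unknown subdomain '", tag, "'")
  tets <- mesh$tets[sel, , drop = FALSE]
  cm <- compact_mesh_nodes(mesh$nodes, tets)
  sm <- stim_mesh(cm$nodes, cm$tets,
                  subdomains = stats::setNames(list(seq_len(nrow(cm$tets))), tag))
  list(mesh = sm, node_map = cm$node_map, tet_sel = sel)
}

#' Mesh quality report
#'
#' Computes element volumes, edge lengths and dihedral angles, flagging
#' degenerate elements.
#'
#' @param mesh a [stim_mesh()].
#' @param vol_eps volume floor (m^3) below which a tetrahedron counts as
#'   degenerate.
#' @return list with `min_volume`, `max_edge`, `min_edge`,
#'   `min_dihedral_deg`, `n_degenerate`.
#' @export
mesh_quality <- function(mesh, vol_eps = 1e-27) {
  v <- tet_signed_volumes(mesh$nodes, mesh$tets)
  ed <- tet_edge_lengths(mesh$nodes, mesh$tets)
  list(
    min_volume = min(v),
    n_degenerate = sum(v < vol_eps),
    min_edge = min(ed),
    max_edge = max(ed),
    min_dihedral_deg = min_dihedral_angle(mesh$nodes, mesh$tets)
  )
}

tet_edge_lengths <- function(nodes, tets) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  out <- matrix(0, nrow(tets), 6)
  for (e in seq_len(6)) {
    d <- nodes[tets[, pairs[e, 1]], , drop = FALSE] -
         nodes[tets[, pairs[e, 2]], , drop = FALSE]
    out[, e] <- sqrt(rowSums(d^2))
  }
  out
}

min_dihedral_angle <- function(nodes, tets) {
  # face normals per tet (inward-consistent); dihedral between face pairs
  ft <- tet_face_table(tets)
  n <- triangle_normals(nodes, ft$faces)
  m <- nrow(tets)
  idx <- function(f) ((f - 1L) * m + 1L):(f * m)
  worst <- 180
  for (f1 in 1:3) for (f2 in (f1 + 1):4) {
    cosd <- rowSums(n[idx(f1), , drop = FALSE] * n[idx(f2), , drop = FALSE])
    ang <- 180 - acos(pmax(-1, pmin(1, cosd))) * 180 / pi
    worst <- min(worst, min(ang))
  }
  worst
}

#' Maximum edge length among elements intersecting a region
#'
#' @param mesh a [stim_mesh()].
#' @param region either a facet tag name, or a function of an n x 3 matrix of
#'   points returning a logical vector (TRUE inside the region).
#' @return maximum element edge length (m) over the selected elements.
#' @export
max_edge_in_region <- function(mesh, region) {
  sel <- region_tets(mesh, region)
  if (!length(sel)) return(0)
  max(tet_edge_lengths(mesh$nodes, mesh$tets[sel, , drop = FALSE]))
}

region_tets <- function(mesh, region) {
  if (is.character(region)) {
    f <- mesh$facets[[region]]
    if (is.null(f)) stop("unknown facet tag '", region, "'")
    nodes_in <- unique(as.vector(f))
    hits <- matrix(mesh$tets %in% nodes_in, ncol = 4)
    which(rowSums(hits) > 0)
  } else {
    inside <- region(mesh$nodes)
    hits <- matrix(inside[mesh$tets], ncol = 4)
    which(rowSums(hits) > 0)
  }
}
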