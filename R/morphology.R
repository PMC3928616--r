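#' Neuron morphology as 3D sections
#'
#' A morphology is an ordered set of sections, each a 3D polyline with
#' per-point diameters, connected in a tree. `morphology()` builds one from a
#' list of sections; each section is a list with `points` (k x 3 matrix, m),
#' `diam` (length-k vector, m), `parent` (section index, 0 for the root) and
#' `parent_end` (1 = attach to the parent's last point, 0 = first point).
#'
#' @param sections list of section descriptions (see above).
#' @return an object of class `morphology`.
#' @export
morphology <- function(sections) {
  for (s in sections) {
    stopifnot(is.matrix(s$points), ncol(s$points) == 3,
              length(s$diam) == nrow(s$points), all(s$diam > 0))
  }
  parents <- vapply(sections, function(s) as.integer(s$parent %||% 0L), 1L)
  if (sum(parents == 0L) != 1L) stop("morphology must have exactly one root section")
  # acyclicity / connectivity: every section's parent must precede it
  if (any(parents >= seq_along(sections))) {
    stop("sections must be ordered so that parents precede children")
  }
  structure(list(sections = sections), class = "morphology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Straight-fiber (optionally with soma) morphology
#'
#' The standard scenario geometry: a straight fiber along the y axis at
#' height `z` above the substrate, centered on x = y = 0. With
#' `soma_diameter`, the central compartments over the soma extent get the
#' soma diameter (a chain of soma-diameter compartments whose total lateral
#' area, `pi d^2`, equals the surface of the sphere of the same diameter).
#'
#' @param length fiber length (m).
#' @param diameter fiber diameter (m).
#' @param z height of the axis above the substrate (m).
#' @param soma_diameter soma diameter (m) or `NULL`.
#' @return a [morphology()] with a single section.
#' @export
morphology_fiber <- function(length = 260e-6, diameter = 2e-6, z = 50e-6,
                             soma_diameter = NULL) {
  half <- length / 2
  if (is.null(soma_diameter)) {
    ys <- c(-half, half)
    ds <- rep(diameter, 2)
  } else {
    rs <- soma_diameter / 2
    eps <- 1e-12
    ys <- c(-half, -rs - eps, -rs, rs, rs + eps, half)
    ds <- c(diameter, diameter, soma_diameter, soma_diameter,
            diameter, diameter)
    ys <- sort(ys)
  }
  pts <- cbind(0, ys, z)
  morphology(list(list(points = pts, diam = ds, parent = 0L)))
}

#' Read an SWC morphology file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent), coordinates
#' interpreted in micrometers per the format convention. Each maximal
#' unbranched chain becomes one section.
#'
#' @param path SWC file path.
#' @return a [morphology()].
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  tab <- tab[order(tab$id), ]
  idx <- match(tab$parent, tab$id)            # parent row per point (NA for root)
  children <- lapply(seq_len(nrow(tab)), function(i) which(idx == i))
  n_child <- lengths(children)
  root <- which(is.na(idx))
  if (length(root) != 1) stop("SWC must have exactly one root point")
  # a section starts at the root and after every branch point
  starts <- sort(unique(c(root, which(!is.na(idx) & n_child[pmax(idx, 1)] > 1))))
  sections <- list()
  sec_of_point <- integer(nrow(tab))
  for (s in starts) {
    chain <- s
    repeat {
      cur <- chain[length(chain)]
      ch <- children[[cur]]
      if (length(ch) != 1 || ch %in% starts) break
      chain <- c(chain, ch)
    }
    par_pt <- idx[chain[1]]
    sections[[length(sections) + 1]] <- list(
      points = um(as.matrix(tab[chain, c("x", "y", "z")])),
      diam = um(2 * tab$r[chain]),
      parent = if (is.na(par_pt)) 0L else sec_of_point[par_pt],
      parent_end = 1L
    )
    sec_of_point[chain] <- length(sections)
  }
  morphology(sections)
}

#' Discretize a morphology into electrical compartments
#'
#' Splits every section into compartments of length at most `dx` (at least
#' one per section), assigns cylindrical lateral areas, and connects adjacent
#' compartments by axial conductances
#' `g = (pi/4) d_h^2 / (Ra dx_centers)` where the diameter combination is the
#' series-resistance (harmonic) one across a diameter change.
#'
#' @param m a [morphology()].
#' @param dx target compartment length (m).
#' @param Ra intracellular resistivity (Ohm m); the literature's Ohm cm
#'   converts via [ohm_cm()].
#' @param membrane a [membrane_passive()]/[membrane_hh()] set, applied to all
#'   compartments, or a list of such sets (one per section).
#' @return an object of class `compartmental_model`: compartment centers,
#'   lengths, diameters, lateral areas, membrane parameters and the axial
#'   conductance graph.
#' @export
compartmentalize <- function(m, dx, Ra = ohm_cm(100),
                             membrane = membrane_passive()) {
  stopifnot(dx > 0, Ra > 0)
  per_section <- inherits(membrane, "membrane_params") == FALSE
  centers <- NULL; len <- diam <- area <- sec_id <- NULL
  edges <- NULL; g_ax <- NULL
  sec_first <- sec_last <- integer(length(m$sections))
  min_sec_len <- Inf
  for (si in seq_along(m$sections)) {
    s <- m$sections[[si]]
    seg <- diff_rows(s$points)
    seg_len <- if (nrow(s$points) > 1) sqrt(rowSums(seg^2)) else 0
    arc <- c(0, cumsum(seg_len))
    Lsec <- arc[length(arc)]
    if (Lsec == 0) {
      # single-point section (e.g. an SWC point soma): sphere-equivalent
      n <- 1L; cl <- s$diam[1]
      px <- s$points[1, 1]; py <- s$points[1, 2]; pz <- s$points[1, 3]
      dmid <- s$diam[1]
    } else {
      min_sec_len <- min(min_sec_len, Lsec)
      n <- max(1L, ceiling(Lsec / dx))
      cl <- Lsec / n
      mid <- (seq_len(n) - 0.5) * cl
      px <- stats::approx(arc, s$points[, 1], xout = mid)$y
      py <- stats::approx(arc, s$points[, 2], xout = mid)$y
      pz <- stats::approx(arc, s$points[, 3], xout = mid)$y
      dmid <- stats::approx(arc, s$diam, xout = mid)$y
    }
    base <- if (is.null(centers)) 0L else nrow(centers)
    centers <- rbind(centers, cbind(px, py, pz))
    len <- c(len, rep(cl, n)); diam <- c(diam, dmid)
    area <- c(area, pi * dmid * cl)
    sec_id <- c(sec_id, rep(si, n))
    sec_first[si] <- base + 1L; sec_last[si] <- base + n
    if (n > 1) {
      i <- base + seq_len(n - 1L); j <- i + 1L
      edges <- rbind(edges, cbind(i, j))
      g_ax <- c(g_ax, axial_g(dmid[-n], dmid[-1], cl / 2, cl / 2, Ra))
    }
    par <- s$parent %||% 0L
    if (par > 0L) {
      pend <- if ((s$parent_end %||% 1L) == 1L) sec_last[par] else sec_first[par]
      edges <- rbind(edges, cbind(pend, base + 1L))
      g_ax <- c(g_ax, axial_g(diam[pend], dmid[1], len[pend] / 2, cl / 2, Ra))
    }
  }
  if (dx > min_sec_len) {
    warning("dx (", format(dx), " m) exceeds the shortest section (",
            format(min_sec_len), " m); using a single compartment there")
  }
  mem <- if (per_section) membrane else list(membrane)
  mem_id <- if (per_section) sec_id else rep(1L, length(len))
  structure(list(
    centers = centers, length = len, diam = diam, area = area,
    edges = edges, g_ax = g_ax, Ra = Ra,
    membrane = mem, membrane_id = mem_id, section = sec_id
  ), class = "compartmental_model")
}

diff_rows <- function(x) x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]

# axial conductance between two half-compartments in series
axial_g <- function(d1, d2, l1, l2, Ra) {
  r <- Ra * l1 / (pi * d1^2 / 4) + Ra * l2 / (pi * d2^2 / 4)
  1 / r
}

#' @export
print.compartmental_model <- function(x, ...) {
  cat("<compartmental_model>", nrow(x$centers), "compartments,",
      length(x$g_ax), "axial links; Ra =", x$Ra, "Ohm m\n")
  invisible(x)
}
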