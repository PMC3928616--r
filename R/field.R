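#' Boundary conditions for the potential problem
#'
#' Three variants model the chamber surfaces:
#' * `bc_insulating()`: homogeneous Neumann, `sigma grad(V) . n = 0`
#'   (insulating walls, floating electrodes, the electrode-ground gap).
#' * `bc_robin(g, V0)`: the electrode-electrolyte interface,
#'   `sigma grad(V) . n + g V = g V0`, with `g` the surface conductance of
#'   the interface (S/m^2; the inverse of electrode impedance times area,
#'   `g = 1 / (Z * S)`) and `V0` the metal-side potential (V).
#' * `bc_dirichlet(V)`: fixed potential (the infinite-surface-conductance
#'   limit of the Robin condition).
#'
#' @param g surface conductance (S/m^2), positive.
#' @param V0,V potential (V).
#' @param Z,area alternative Robin specification: electrode impedance (Ohm)
#'   and electrode area (m^2), converted via `g = 1/(Z * area)`.
#' @return a `stim_bc` object.
#' @export
bc_robin <- function(g = NULL, V0 = 0, Z = NULL, area = NULL) {
  if (is.null(g)) {
    stopifnot(!is.null(Z), !is.null(area))
    g <- 1 / (Z * area)
  }
  stopifnot(g > 0)
  structure(list(type = "robin", g = g, V0 = V0), class = "stim_bc")
}

#' @rdname bc_robin
#' @export
bc_insulating <- function() structure(list(type = "insulating"), class = "stim_bc")

#' @rdname bc_robin
#' @export
bc_dirichlet <- function(V = 0) structure(list(type = "dirichlet", V = V),
                                          class = "stim_bc")

#' Define a quasi-static potential field problem
#'
#' The extracellular potential obeys the Poisson equation
#' `-div(sigma grad V) = 0` (no volume sources; external current density and
#' volume current source are zero) with per-tag boundary conditions. Facet
#' tags without an entry in `bcs` are insulating.
#'
#' @param mesh a [stim_mesh()].
#' @param conductivity conductivity (S/m): scalar, or named list/vector by
#'   subdomain tag.
#' @param bcs named list of [bc_robin()]/[bc_dirichlet()]/[bc_insulating()]
#'   keyed by facet tag.
#' @param element_order 1 (linear) or 2 (quadratic Lagrange).
#' @return a `field_problem` object.
#' @export
field_problem <- function(mesh, conductivity = 0.2, bcs = list(),
                          element_order = 2L) {
  stopifnot(inherits(mesh, "stim_mesh"))
  for (tag in names(bcs)) {
    if (is.null(mesh$facets[[tag]])) stop("BC references unknown tag '", tag, "'")
    if (!inherits(bcs[[tag]], "stim_bc")) stop("bcs[['", tag, "']] is not a stim_bc")
  }
  sig <- conductivity
  if (length(sig) == 1 && is.null(names(sig))) {
    sig <- stats::setNames(as.list(rep(as.numeric(sig), length(mesh$subdomains))),
                           names(mesh$subdomains))
  }
  if (any(unlist(sig) <= 0)) stop("conductivities must be positive")
  anchored <- any(vapply(bcs, function(b) b$type %in% c("robin", "dirichlet"), TRUE))
  if (!anchored) {
    stop("problem is not well-posed: all boundaries insulating ",
         "(need at least one Robin or Dirichlet condition)")
  }
  structure(list(mesh = mesh, conductivity = sig, bcs = bcs,
                 element_order = as.integer(element_order)),
            class = "field_problem")
}

# per-tet conductivity vector from the subdomain map
sigma_per_tet <- function(mesh, sig) {
  out <- numeric(nrow(mesh$tets))
  for (tag in names(mesh$subdomains)) {
    s <- sig[[tag]]
    if (is.null(s)) stop("no conductivity given for subdomain '", tag, "'")
    out[mesh$subdomains[[tag]]] <- s
  }
  out
}

#' Solve the potential field problem
#'
#' Assembles the Galerkin system with Lagrange elements of the requested
#' order and solves it with a sparse Cholesky factorization (conjugate
#' gradients above a size threshold). Robin terms enter the matrix as
#' boundary mass `g M` and the load as `g V0 integral(phi)`; Dirichlet values
#' are eliminated.
#'
#' @param problem a [field_problem()].
#' @return a `field_solution`: the problem, the FE space, and the
#'   coefficient vector `u` (V), evaluable anywhere inside the domain via
#'   [sample_potential()].
#' @export
solve_field <- function(problem) {
  mesh <- problem$mesh
  space <- fe_space(mesh, problem$element_order)
  K <- assemble_stiffness(space, sigma_per_tet(mesh, problem$conductivity))
  b <- numeric(space$n_dof)
  fixed <- logical(space$n_dof)
  xval <- numeric(space$n_dof)
  robin_cache <- list()
  for (tag in names(problem$bcs)) {
    bc <- problem$bcs[[tag]]
    if (bc$type == "robin") {
      bm <- assemble_boundary_mass(space, mesh$facets[[tag]])
      K <- K + bc$g * bm$M
      b <- b + bc$g * bc$V0 * bm$r
      robin_cache[[tag]] <- bm
    } else if (bc$type == "dirichlet") {
      dd <- unique(as.vector(tri_dofs(space, mesh$facets[[tag]])))
      fixed[dd] <- TRUE
      xval[dd] <- bc$V
    }
  }
  u <- fe_solve(K, b, fixed = fixed, xval = xval)
  if (any(!is.finite(u))) stop("field solve produced non-finite values")
  structure(list(problem = problem, space = space, u = u,
                 robin_cache = robin_cache),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution> order", x$space$order, "-", x$space$n_dof, "DoF;",
      "V range [", format(min(x$u), digits = 4), ",",
      format(max(x$u), digits = 4), "] V\n")
  invisible(x)
}

#' Integrate the normal current over a tagged boundary
#'
#' Returns the signed integral of `sigma grad(V) . n` over the tag's facets,
#' with `n` the outward normal of the conducting domain. With the sign
#' conventions of [bc_robin()], a stimulation electrode driven at negative
#' `V0` (cathodic) yields a negative current, and the return electrode the
#' opposite sign; the sum over all conducting boundaries vanishes (charge
#' conservation).
#'
#' On Robin facets the flux is integrated through the boundary-condition
#' identity `sigma grad(V) . n = g (V0 - V)` (`method = "auto"`), which is
#' discretely conservative; `method = "gradient"` integrates the finite
#' element gradient directly (required for Dirichlet/insulating tags).
#'
#' @param sol a `field_solution` from [solve_field()].
#' @param tag facet tag name.
#' @param method `"auto"` or `"gradient"`.
#' @return signed current (A).
#' @export
integrate_boundary_current <- function(sol, tag, method = c("auto", "gradient")) {
  method <- match.arg(method)
  mesh <- sol$problem$mesh
  tris <- mesh$facets[[tag]]
  if (is.null(tris)) stop("unknown facet tag '", tag, "'")
  bc <- sol$problem$bcs[[tag]]
  if (method == "auto" && !is.null(bc) && bc$type == "robin") {
    bm <- sol$robin_cache[[tag]]
    if (is.null(bm)) bm <- assemble_boundary_mass(sol$space, tris)
    area <- sum(triangle_areas(mesh$nodes, tris))
    return(bc$g * (bc$V0 * area - sum(bm$r * sol$u)))
  }
  flux_integral(sol, tris)
}

# gradient-based flux integral over oriented triangles (normals as stored)
flux_integral <- function(sol, tris) {
  mesh <- sol$problem$mesh
  space <- sol$space
  # owner tet of each facet
  fi <- mesh_face_index(mesh)
  all_keys <- face_keys(fi$faces, nrow(mesh$nodes))
  want <- face_keys(tris, nrow(mesh$nodes))
  idx <- match(want, all_keys)
  if (anyNA(idx)) stop("facet not found on the mesh boundary")
  owner <- fi$owner[idx]
  sig <- sigma_per_tet(mesh, sol$problem$conductivity)[owner]
  tg <- tet_grads(mesh$nodes, mesh$tets[owner, , drop = FALSE])
  A <- triangle_areas(mesh$nodes, tris)
  nrm <- triangle_normals(mesh$nodes, tris)
  dofs <- space$tet_dofs[owner, , drop = FALSE]
  if (space$order == 1L) {
    gradV <- matrix(0, length(owner), 3)
    for (i in 1:4) gradV <- gradV + tg$g[[i]] * sol$u[dofs[, i]]
    return(sum(sig * A * rowSums(gradV * nrm)))
  }
  # P2: integrate with a 3-point facet rule; gradient varies linearly
  q <- list(lambda = rbind(c(2/3, 1/6, 1/6), c(1/6, 2/3, 1/6), c(1/6, 1/6, 2/3)),
            w = rep(1/3, 3))
  total <- 0
  # barycentric coordinates of facet quadrature points within the owner tet
  for (qq in seq_along(q$w)) {
    pt <- q$lambda[qq, 1] * mesh$nodes[tris[, 1], , drop = FALSE] +
          q$lambda[qq, 2] * mesh$nodes[tris[, 2], , drop = FALSE] +
          q$lambda[qq, 3] * mesh$nodes[tris[, 3], , drop = FALSE]
    lam <- tet_barycentric(mesh, owner, pt, tg)
    gradV <- matrix(0, length(owner), 3)
    for (i in 1:10) {
      # grad phi_i = sum_a C[i,a](lam) grad lambda_a, rowwise lam
      Ci <- p2_grad_coef_rows(lam, i)
      gi <- Ci[, 1] * tg$g[[1]] + Ci[, 2] * tg$g[[2]] +
            Ci[, 3] * tg$g[[3]] + Ci[, 4] * tg$g[[4]]
      gradV <- gradV + gi * sol$u[dofs[, i]]
    }
    total <- total + q$w[qq] * sum(sig * A * rowSums(gradV * nrm))
  }
  total
}

# rowwise barycentric coordinates of points inside given tets
tet_barycentric <- function(mesh, tets_idx, pts, tg = NULL) {
  if (is.null(tg)) tg <- tet_grads(mesh$nodes, mesh$tets[tets_idx, , drop = FALSE])
  a <- mesh$nodes[mesh$tets[tets_idx, 1], , drop = FALSE]
  rel <- pts - a
  l2 <- rowSums(rel * tg$g[[2]])
  l3 <- rowSums(rel * tg$g[[3]])
  l4 <- rowSums(rel * tg$g[[4]])
  cbind(1 - l2 - l3 - l4, l2, l3, l4)
}

# rowwise version of p2_tet_grad_coefs for basis i: returns k x 4 matrix
p2_grad_coef_rows <- function(lam, i) {
  k <- nrow(lam)
  C <- matrix(0, k, 4)
  if (i <= 4) {
    C[, i] <- 4 * lam[, i] - 1
  } else {
    ep <- tet_edge_pairs()[i - 4, ]
    C[, ep[1]] <- 4 * lam[, ep[2]]
    C[, ep[2]] <- 4 * lam[, ep[1]]
  }
  C
}

#' Calibrate the stimulus voltage to a nominal current
#'
#' Two-pass scheme: solve with `V0 = 1` V on the stimulation tag, integrate
#' the delivered current on the larger of the stimulation electrode and the
#' return surface (whose flux is computed on more facets and is therefore
#' the more trustworthy of the two), rescale `V0` by the target/measured
#' ratio and re-solve. The problem is linear, so one rescale is exact up to
#' numerics.
#'
#' @param problem a [field_problem()]; `stim_tag` must carry a Robin BC.
#' @param stim_tag facet tag of the stimulation electrode.
#' @param I_target desired signed current through the stimulation electrode
#'   (A); negative for a cathodic stimulus.
#' @return list with `V0` (V), `sol` (the calibrated `field_solution`),
#'   `I_stim` and `I_return` (A, the check integrals).
#' @export
calibrate_stimulus <- function(problem, stim_tag, I_target) {
  bc <- problem$bcs[[stim_tag]]
  if (is.null(bc) || bc$type != "robin") {
    stop("stimulation tag '", stim_tag, "' must carry a Robin BC")
  }
  pr1 <- problem
  pr1$bcs[[stim_tag]]$V0 <- 1
  sol1 <- solve_field(pr1)
  # pick the measurement surface: the larger of stimulation and return
  ret_tag <- largest_return_tag(problem, stim_tag)
  a_stim <- sum(triangle_areas(problem$mesh$nodes, problem$mesh$facets[[stim_tag]]))
  a_ret <- if (is.null(ret_tag)) 0 else
    sum(triangle_areas(problem$mesh$nodes, problem$mesh$facets[[ret_tag]]))
  I1 <- if (a_ret > a_stim) {
    -integrate_boundary_current(sol1, ret_tag)
  } else {
    integrate_boundary_current(sol1, stim_tag)
  }
  if (abs(I1) < .Machine$double.eps * 100) {
    stop("calibration failed: no current flows through '", stim_tag,
         "' (disconnected electrode?)")
  }
  V0 <- I_target / I1
  pr2 <- problem
  pr2$bcs[[stim_tag]]$V0 <- V0
  sol2 <- solve_field(pr2)
  list(V0 = V0, sol = sol2,
       I_stim = integrate_boundary_current(sol2, stim_tag),
       I_return = if (is.null(ret_tag)) NA_real_ else
         integrate_boundary_current(sol2, ret_tag))
}

largest_return_tag <- function(problem, stim_tag) {
  cand <- setdiff(names(problem$bcs), stim_tag)
  cand <- cand[vapply(cand, function(t)
    problem$bcs[[t]]$type %in% c("robin", "dirichlet"), TRUE)]
  if (!length(cand)) return(NULL)
  areas <- vapply(cand, function(t)
    sum(triangle_areas(problem$mesh$nodes, problem$mesh$facets[[t]])), 1)
  cand[which.max(areas)]
}

#' Sample the potential at points
#'
#' Finite-element interpolation (not nearest-node) of the solution at
#' arbitrary interior points; output order matches input order.
#'
#' @param sol a `field_solution`.
#' @param points n x 3 matrix of coordinates (m).
#' @param subdomain subdomain tag to search (default: all).
#' @return numeric vector of potentials (V).
#' @export
sample_potential <- function(sol, points, subdomain = NULL) {
  points <- rbind(points)
  loc <- locate_points(sol$problem$mesh, points, subdomain)
  if (anyNA(loc$tet)) {
    bad <- which(is.na(loc$tet))
    stop("point(s) outside the meshed domain: ",
         paste(apply(points[bad, , drop = FALSE], 1, function(p)
       paste0("(", paste(format(p, digits = 6), collapse = ", "), ")")),
       collapse = "; "))
  }
  evaluate_solution(sol$space, sol$u, loc)
}

evaluate_solution <- function(space, u, loc) {
  dofs <- space$tet_dofs[loc$tet, , drop = FALSE]
  lam <- loc$lambda
  if (space$order == 1L) {
    return(rowSums(lam * matrix(u[dofs], nrow(dofs), 4)))
  }
  vals <- numeric(nrow(dofs))
  ep <- tet_edge_pairs()
  for (i in 1:4) vals <- vals + lam[, i] * (2 * lam[, i] - 1) * u[dofs[, i]]
  for (e in 1:6) {
    vals <- vals + 4 * lam[, ep[e, 1]] * lam[, ep[e, 2]] * u[dofs[, 4 + e]]
  }
  vals
}

# Locate points in the mesh: uniform-bin acceleration over tet bounding
# boxes. Returns list(tet = index or NA, lambda = barycentric rows).
locate_points <- function(mesh, pts, subdomain = NULL, tol = 1e-9) {
  tets <- mesh$tets
  sel <- NULL
  if (!is.null(subdomain)) {
    sel <- mesh$subdomains[[subdomain]]
    tets <- tets[sel, , drop = FALSE]
  }
  m <- nrow(tets)
  lo <- pmin(pmin(mesh$nodes[tets[, 1], ], mesh$nodes[tets[, 2], ]),
             pmin(mesh$nodes[tets[, 3], ], mesh$nodes[tets[, 4], ]))
  hi <- pmax(pmax(mesh$nodes[tets[, 1], ], mesh$nodes[tets[, 2], ]),
             pmax(mesh$nodes[tets[, 3], ], mesh$nodes[tets[, 4], ]))
  box_lo <- apply(lo, 2, min); box_hi <- apply(hi, 2, max)
  nb <- max(4L, as.integer(round((m / 8)^(1 / 3))))
  span <- pmax(box_hi - box_lo, 1e-300)
  binify <- function(x, d) pmin(nb, pmax(1L, 1L + as.integer(floor(
    (x - box_lo[d]) / span[d] * nb * (1 - 1e-12)))))
  # tet -> bins it overlaps
  key3 <- function(bx, by, bz) (as.numeric(bx) - 1) * nb * nb + (by - 1) * nb + bz
  tl <- cbind(binify(lo[, 1], 1), binify(lo[, 2], 2), binify(lo[, 3], 3))
  th <- cbind(binify(hi[, 1], 1), binify(hi[, 2], 2), binify(hi[, 3], 3))
  reps <- (th[, 1] - tl[, 1] + 1L) * (th[, 2] - tl[, 2] + 1L) * (th[, 3] - tl[, 3] + 1L)
  single <- which(reps == 1L)
  multi <- which(reps > 1L)
  tet_of <- c(single, rep(multi, reps[multi]))
  keys <- numeric(length(tet_of))
  keys[seq_along(single)] <- key3(tl[single, 1], tl[single, 2], tl[single, 3])
  pos <- length(single) + 1L
  for (t in multi) {
    bx <- tl[t, 1]:th[t, 1]; by <- tl[t, 2]:th[t, 2]; bz <- tl[t, 3]:th[t, 3]
    kk <- as.vector(outer(as.vector(outer((bx - 1) * nb * nb, (by - 1) * nb, `+`)), bz, `+`))
    keys[pos:(pos + length(kk) - 1L)] <- kk
    pos <- pos + length(kk)
  }
  ord <- order(keys)
  keys_s <- keys[ord]; tet_s <- tet_of[ord]
  ub <- unique(keys_s)
  starts <- match(ub, keys_s)
  ends <- c(starts[-1] - 1L, length(keys_s))

  npts <- nrow(pts)
  out_tet <- rep(NA_integer_, npts)
  out_lam <- matrix(NA_real_, npts, 4)
  pk <- key3(binify(pts[, 1], 1), binify(pts[, 2], 2), binify(pts[, 3], 3))
  for (p in seq_len(npts)) {
    bi <- match(pk[p], ub)
    if (is.na(bi)) next
    cand <- tet_s[starts[bi]:ends[bi]]
    # quick bbox filter
    keep <- pts[p, 1] >= lo[cand, 1] - tol & pts[p, 1] <= hi[cand, 1] + tol &
            pts[p, 2] >= lo[cand, 2] - tol & pts[p, 2] <= hi[cand, 2] + tol &
            pts[p, 3] >= lo[cand, 3] - tol & pts[p, 3] <= hi[cand, 3] + tol
    cand <- cand[keep]
    if (!length(cand)) next
    lam <- tet_barycentric(mesh, if (is.null(sel)) cand else sel[cand],
                           matrix(pts[p, ], length(cand), 3, byrow = TRUE))
    ok <- which(rowSums(lam < -1e-8) == 0)
    if (length(ok)) {
      out_tet[p] <- if (is.null(sel)) cand[ok[1]] else sel[cand[ok[1]]]
      out_lam[p, ] <- pmax(lam[ok[1], ], 0)
    }
  }
  list(tet = out_tet, lambda = out_lam)
}
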