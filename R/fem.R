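# Lagrange finite-element spaces and assembly on tetrahedral meshes.
#
# P1 (4-node) and P2 (10-node) elements. All assembly is vectorized across
# elements: per-element geometry reduces to the constant barycentric
# gradients (affine tets), so stiffness integrands are polynomial and exact
# quadrature rules of low order suffice.

# 4-point tet rule, exact to degree 2 (barycentric coordinates + weights)
tet_quad4 <- function() {
  a <- 0.5854101966249685; b <- 0.1381966011250105
  lam <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  list(lambda = lam, w = rep(0.25, 4))
}

# 6-point triangle rule, exact to degree 4
tri_quad6 <- function() {
  a <- 0.816847572980459;  b <- 0.091576213509771
  c_ <- 0.108103018168070; d <- 0.445948490915965
  wa <- 0.109951743655322; wb <- 0.223381589678011
  lam <- rbind(c(a, b, b), c(b, a, b), c(b, b, a),
               c(c_, d, d), c(d, c_, d), c(d, d, c_))
  list(lambda = lam, w = c(wa, wa, wa, wb, wb, wb))
}

# P2 basis on a tet in barycentric form: 4 vertex + 6 edge functions.
# Edge local order follows tet_edge_pairs().
tet_edge_pairs <- function() rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
tri_edge_pairs <- function() rbind(c(1, 2), c(2, 3), c(1, 3))

# values of the 10 P2 basis functions at barycentric lambda (vector of 4)
p2_tet_basis <- function(lam) {
  ep <- tet_edge_pairs()
  c(lam * (2 * lam - 1), 4 * lam[ep[, 1]] * lam[ep[, 2]])
}

# coefficient matrix C (10 x 4) with grad(phi_i) = sum_a C[i,a] grad(lambda_a)
p2_tet_grad_coefs <- function(lam) {
  C <- matrix(0, 10, 4)
  for (i in 1:4) C[i, i] <- 4 * lam[i] - 1
  ep <- tet_edge_pairs()
  for (e in 1:6) {
    C[4 + e, ep[e, 1]] <- 4 * lam[ep[e, 2]]
    C[4 + e, ep[e, 2]] <- 4 * lam[ep[e, 1]]
  }
  C
}

# 6 P2 basis functions on a triangle at barycentric lambda (vector of 3)
p2_tri_basis <- function(lam) {
  ep <- tri_edge_pairs()
  c(lam * (2 * lam - 1), 4 * lam[ep[, 1]] * lam[ep[, 2]])
}

# --- finite element space -----------------------------------------------------

# Build the DoF structure for a mesh and element order. For P2, edge DoFs are
# appended after vertex DoFs; `edge_key` allows facet triangles to look up
# their edge DoFs.
fe_space <- function(mesh, order = 1L) {
  order <- as.integer(order)
  stopifnot(order %in% c(1L, 2L))
  n <- nrow(mesh$nodes)
  if (order == 1L) {
    return(list(mesh = mesh, order = 1L, n_dof = n,
                tet_dofs = mesh$tets))
  }
  ep <- tet_edge_pairs()
  e_all <- NULL
  for (e in 1:6) {
    pr <- mesh$tets[, ep[e, ], drop = FALSE]
    e_all <- rbind(e_all, cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2])))
  }
  key <- as.numeric(e_all[, 1]) * (n + 1) + e_all[, 2]
  ukey <- sort(unique(key))
  eid <- match(key, ukey)
  m <- nrow(mesh$tets)
  edge_dofs <- matrix(eid, nrow = m, ncol = 6)
  edges <- cbind(ukey %/% (n + 1), ukey %% (n + 1))
  storage.mode(edges) <- "integer"
  list(mesh = mesh, order = 2L, n_dof = n + length(ukey),
       tet_dofs = cbind(mesh$tets, n + edge_dofs),
       edges = edges, edge_key = ukey, n_vertex = n)
}

# DoF coordinates (vertices, then edge midpoints for P2)
fe_dof_coords <- function(space) {
  if (space$order == 1L) return(space$mesh$nodes)
  rbind(space$mesh$nodes,
        (space$mesh$nodes[space$edges[, 1], , drop = FALSE] +
         space$mesh$nodes[space$edges[, 2], , drop = FALSE]) / 2)
}

# edge DoF lookup for triangles (P2): returns k x 3 matrix of global DoFs
tri_edge_dofs <- function(space, tris) {
  n <- space$n_vertex
  ep <- tri_edge_pairs()
  out <- matrix(0L, nrow(tris), 3)
  for (e in 1:3) {
    a <- pmin(tris[, ep[e, 1]], tris[, ep[e, 2]])
    b <- pmax(tris[, ep[e, 1]], tris[, ep[e, 2]])
    id <- match(as.numeric(a) * (n + 1) + b, space$edge_key)
    if (anyNA(id)) stop("triangle edge not found in the FE space")
    out[, e] <- n + id
  }
  out
}

# triangle DoF matrix for a facet set (k x 3 for P1, k x 6 for P2)
tri_dofs <- function(space, tris) {
  if (space$order == 1L) tris else cbind(tris, tri_edge_dofs(space, tris))
}

# --- geometry helpers ---------------------------------------------------------

# barycentric gradients per tet: list of four m x 3 matrices, plus volumes
tet_grads <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  det <- b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
         b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
         b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])
  # rows of inv([b;c;d])^T are grad(lambda_2..4); cross-product formulas
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- cross(c_, d) / det
  g3 <- cross(d, b) / det
  g4 <- cross(b, c_) / det
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det / 6)
}

# sparse symmetric stiffness matrix: integral sigma grad(u).grad(v)
# sigma: numeric scalar or per-tet vector
assemble_stiffness <- function(space, sigma, tets_sel = NULL) {
  mesh <- space$mesh
  tets <- mesh$tets
  dofs <- space$tet_dofs
  if (!is.null(tets_sel)) {
    tets <- tets[tets_sel, , drop = FALSE]
    dofs <- dofs[tets_sel, , drop = FALSE]
    if (length(sigma) > 1) sigma <- sigma[tets_sel]
  }
  tg <- tet_grads(mesh$nodes, tets)
  m <- nrow(tets)
  sv <- sigma * tg$vol
  if (space$order == 1L) {
    nb <- 4L
    ii <- jj <- xx <- vector("list", nb * nb)
    k <- 0
    for (i in 1:4) for (j in 1:4) {
      k <- k + 1
      ii[[k]] <- dofs[, i]
      jj[[k]] <- dofs[, j]
      xx[[k]] <- sv * rowSums(tg$g[[i]] * tg$g[[j]])
    }
  } else {
    # pairwise dots of barycentric gradients
    D <- vector("list", 16)
    for (a in 1:4) for (b in 1:4) {
      D[[(a - 1) * 4 + b]] <- rowSums(tg$g[[a]] * tg$g[[b]])
    }
    q <- tet_quad4()
    W <- array(0, c(10, 10, 16))   # sum_q w_q C_q[i,a] C_q[j,b]
    for (qq in seq_along(q$w)) {
      C <- p2_tet_grad_coefs(q$lambda[qq, ])
      for (a in 1:4) for (b in 1:4) {
        W[, , (a - 1) * 4 + b] <- W[, , (a - 1) * 4 + b] +
          q$w[qq] * outer(C[, a], C[, b])
      }
    }
    ii <- jj <- xx <- vector("list", 100)
    k <- 0
    for (i in 1:10) for (j in 1:10) {
      k <- k + 1
      acc <- numeric(m)
      for (ab in 1:16) {
        w <- W[i, j, ab]
        if (w != 0) acc <- acc + w * D[[ab]]
      }
      ii[[k]] <- dofs[, i]
      jj[[k]] <- dofs[, j]
      xx[[k]] <- sv * acc
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(space$n_dof, space$n_dof))
}

# boundary mass matrix over a triangle set and the load vector integral(phi)
# returns list(M = sparse n x n, r = numeric n) with unit coefficient
assemble_boundary_mass <- function(space, tris, coef = 1) {
  mesh <- space$mesh
  A <- coef * triangle_areas(mesh$nodes, tris)
  if (space$order == 1L) {
    d <- tris
    off <- A / 12
    ii <- c(d[, 1], d[, 2], d[, 3], d[, 1], d[, 1], d[, 2], d[, 2], d[, 3], d[, 3])
    jj <- c(d[, 1], d[, 2], d[, 3], d[, 2], d[, 3], d[, 1], d[, 3], d[, 1], d[, 2])
    xx <- c(2 * off, 2 * off, 2 * off, off, off, off, off, off, off)
    r <- numeric(space$n_dof)
    for (kk in 1:3) {
      r <- r + tabulate_add(d[, kk], A / 3, space$n_dof)
    }
  } else {
    d <- tri_dofs(space, tris)
    q <- tri_quad6()
    Mref <- matrix(0, 6, 6); rref <- numeric(6)
    for (qq in seq_along(q$w)) {
      ph <- p2_tri_basis(q$lambda[qq, ])
      Mref <- Mref + q$w[qq] * outer(ph, ph)
      rref <- rref + q$w[qq] * ph
    }
    ii <- jj <- xx <- vector("list", 36)
    k <- 0
    for (i in 1:6) for (j in 1:6) {
      k <- k + 1
      ii[[k]] <- d[, i]; jj[[k]] <- d[, j]; xx[[k]] <- A * Mref[i, j]
    }
    ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
    r <- numeric(space$n_dof)
    for (kk in 1:6) {
      r <- r + tabulate_add(d[, kk], A * rref[kk], space$n_dof)
    }
    M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(space$n_dof, space$n_dof))
    return(list(M = M, r = r))
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(space$n_dof, space$n_dof))
  list(M = M, r = r)
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# mixed boundary mass between two FE spaces sharing the same geometric
# triangles (used at membrane interfaces): M[i, j] = integral phi_i^A phi_j^B.
# tris_a / tris_b give the triangle connectivity in each space's numbering
# (same triangles, same vertex order).
assemble_mixed_boundary_mass <- function(space_a, tris_a, space_b, tris_b,
                                         coef = 1) {
  mesh <- space_a$mesh
  A <- coef * triangle_areas(mesh$nodes, tris_a)
  da <- tri_dofs(space_a, tris_a)
  db <- tri_dofs(space_b, tris_b)
  q <- tri_quad6()
  na <- ncol(da); nb <- ncol(db)
  Mref <- matrix(0, na, nb)
  for (qq in seq_along(q$w)) {
    pa <- if (na == 3) q$lambda[qq, ] else p2_tri_basis(q$lambda[qq, ])
    pb <- if (nb == 3) q$lambda[qq, ] else p2_tri_basis(q$lambda[qq, ])
    Mref <- Mref + q$w[qq] * outer(pa, pb)
  }
  ii <- jj <- xx <- vector("list", na * nb)
  k <- 0
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    k <- k + 1
    ii[[k]] <- da[, i]; jj[[k]] <- db[, j]; xx[[k]] <- A * Mref[i, j]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(space_a$n_dof, space_b$n_dof))
}

# --- linear solve -------------------------------------------------------------

# Solve the SPD system K x = b with optional Dirichlet constraints
# (fixed[i] = TRUE with value xval[i]). Direct CHOLMOD below dof_direct,
# Jacobi-preconditioned conjugate gradients above.
fe_solve <- function(K, b, fixed = NULL, xval = NULL,
                     dof_direct = 400000L, tol = 1e-10) {
  n <- length(b)
  x <- numeric(n)
  if (!is.null(fixed) && any(fixed)) {
    x[fixed] <- xval[fixed]
    free <- which(!fixed)
    bf <- b[free] - as.numeric(K[free, fixed, drop = FALSE] %*% x[fixed])
    x[free] <- solve_spd(K[free, free], bf, dof_direct, tol)
  } else {
    x <- solve_spd(K, b, dof_direct, tol)
  }
  x
}

solve_spd <- function(K, b, dof_direct = 400000L, tol = 1e-10) {
  n <- length(b)
  K <- methods::as(Matrix::forceSymmetric(K), "CsparseMatrix")
  if (n <= dof_direct) {
    ch <- tryCatch(Matrix::Cholesky(K, LDL = FALSE, super = TRUE),
                   error = function(e) NULL)
    if (!is.null(ch)) {
      return(as.numeric(Matrix::solve(ch, b)))
    }
    return(as.numeric(Matrix::solve(K, b)))
  }
  pcg(K, b, tol = tol)
}

# Jacobi-preconditioned conjugate gradients (fallback for very large systems)
pcg <- function(K, b, tol = 1e-10, maxit = 20000L) {
  dinv <- 1 / Matrix::diag(K)
  x <- numeric(length(b))
  r <- b
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b^2))
  hist <- numeric(0)
  for (it in seq_len(maxit)) {
    Kp <- as.numeric(K %*% p)
    alpha <- rz / sum(p * Kp)
    x <- x + alpha * p
    r <- r - alpha * Kp
    rn <- sqrt(sum(r^2))
    hist <- c(hist, rn / nb)
    if (rn <= tol * nb) return(x)
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate gradient did not converge; relative residual history tail: ",
       paste(format(utils::tail(hist, 5), digits = 3), collapse = ", "))
}
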