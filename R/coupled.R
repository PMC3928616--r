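#' Build the coupled two-domain (whole-FEM, thin-film) problem
#'
#' Prepares the simultaneous solution of the extracellular potential `V` and
#' the intracellular potential `Vint` on a mesh with an embedded neuron: the
#' membrane is a zero-thickness interface whose degrees of freedom are
#' duplicated (one trace per side), and the two Poisson problems are coupled
#' only through the membrane current density `Im` (see
#' [membrane_current_density()]): the extracellular weak form receives `+Im`
#' on the interface, the intracellular one `-Im`. Exterior boundary
#' conditions are as in [field_problem()]; tags listed in `stim_tags` have
#' their Robin `V0` multiplied by the stimulation waveform `f(t)` during
#' transient solves.
#'
#' @param mesh a [stim_mesh()] with `extracellular`/`intracellular`
#'   subdomains and a `membrane` facet tag (see [embed_neuron_surface()]).
#' @param sigma_ext,sigma_int conductivities (S/m); for a neuron derived from
#'   cable parameters, `sigma_int = 1/Ra`.
#' @param membrane a [membrane_passive()] or [membrane_hh()] set.
#' @param bcs named list of exterior boundary conditions by facet tag.
#' @param stim_tags character vector of tags whose Robin `V0` is modulated by
#'   the waveform.
#' @param orders element orders `c(extracellular, intracellular)`; the
#'   default pairs linear elements outside with quadratic elements inside.
#'   An all-linear configuration is accepted (with a message noting the
#'   reduced intracellular accuracy).
#' @return an object of class `coupled_problem`.
#' @export
build_coupled_problem <- function(mesh, sigma_ext = 0.2, sigma_int = 1,
                                  membrane = membrane_passive(),
                                  bcs = list(), stim_tags = character(),
                                  orders = c(1L, 2L)) {
  need <- c("extracellular", "intracellular")
  if (!all(need %in% names(mesh$subdomains)) || is.null(mesh$facets$membrane)) {
    stop("mesh must carry 'extracellular'/'intracellular' subdomains and a ",
         "'membrane' facet tag")
  }
  if (orders[1] == orders[2] && orders[1] == 1L) {
    message("both domains use linear elements; intracellular accuracy is ",
            "reduced relative to the default quadratic choice")
  }
  ext <- submesh(mesh, "extracellular")
  int <- submesh(mesh, "intracellular")
  se <- fe_space(ext$mesh, orders[1])
  si <- fe_space(int$mesh, orders[2])

  mem_g <- mesh$facets$membrane             # global node indices
  tris_e <- matrix(ext$node_map[mem_g], ncol = 3)
  tris_i <- matrix(int$node_map[mem_g], ncol = 3)
  if (any(tris_e == 0L) || any(tris_i == 0L)) {
    stop("membrane triangles are not shared by both subdomains")
  }
  mem_vert_g <- sort(unique(as.vector(mem_g)))
  K_e <- assemble_stiffness(se, sigma_ext)
  K_i <- assemble_stiffness(si, sigma_int)
  b0 <- numeric(se$n_dof)                   # static robin load
  bstim <- numeric(se$n_dof)                # load scaled by f(t)
  R_e <- NULL
  for (tag in names(bcs)) {
    bc <- bcs[[tag]]
    if (bc$type == "insulating") next
    if (bc$type != "robin") {
      stop("coupled solver supports insulating and Robin exterior BCs; tag '",
           tag, "' is ", bc$type)
    }
    tri_tag <- matrix(ext$node_map[mesh$facets[[tag]]], ncol = 3)
    if (any(tri_tag == 0L)) stop("BC tag '", tag, "' not on the extracellular boundary")
    bm <- assemble_boundary_mass(se, tri_tag)
    R_e <- if (is.null(R_e)) bc$g * bm$M else R_e + bc$g * bm$M
    if (tag %in% stim_tags) {
      bstim <- bstim + bc$g * bc$V0 * bm$r
    } else {
      b0 <- b0 + bc$g * bc$V0 * bm$r
    }
  }
  if (is.null(R_e)) stop("coupled problem needs at least one Robin exterior BC")

  bm_e <- assemble_boundary_mass(se, tris_e)
  bm_i <- assemble_boundary_mass(si, tris_i)
  M_ei <- assemble_mixed_boundary_mass(se, tris_e, si, tris_i)

  structure(list(
    mesh = mesh, ext = ext, int = int, se = se, si = si,
    tris_e = tris_e, tris_i = tris_i,
    mem_vert_g = mem_vert_g,
    mem_vert_e = ext$node_map[mem_vert_g], mem_vert_i = int$node_map[mem_vert_g],
    sigma_ext = sigma_ext, sigma_int = sigma_int,
    membrane = membrane, bcs = bcs, stim_tags = stim_tags, orders = orders,
    K_e = K_e, K_i = K_i, R_e = R_e, b0 = b0, bstim = bstim,
    M_ee = bm_e$M, r_e = bm_e$r, M_ii = bm_i$M, r_i = bm_i$r, M_ei = M_ei,
    cache = new.env(parent = emptyenv())
  ), class = "coupled_problem")
}

#' @export
print.coupled_problem <- function(x, ...) {
  cat("<coupled_problem>", x$se$n_dof, "extracellular +", x$si$n_dof,
      "intracellular DoF (orders", x$orders[1], "/", x$orders[2], ");",
      length(x$mem_vert_g), "membrane vertices\n")
  invisible(x)
}

#' Initial (resting) coupled state
#'
#' `V = 0` everywhere, `Vint` at the declared resting potential, gating
#' variables at their steady state for that rest.
#'
#' @param problem a [build_coupled_problem()].
#' @param v_rest resting potential (V); defaults to the membrane set's.
#' @return an object of class `coupled_state`.
#' @export
coupled_rest_state <- function(problem, v_rest = NULL) {
  p <- problem$membrane
  if (is.null(v_rest)) v_rest <- p$v_rest
  nv <- length(problem$mem_vert_g)
  structure(list(
    time = 0,
    V = numeric(problem$se$n_dof),
    Vint = rep(v_rest, problem$si$n_dof),
    gates = if (isTRUE(p$active)) gate_rest_state(nv) else NULL,
    Vm_old = rep(v_rest, nv),
    v_rest = v_rest
  ), class = "coupled_state")
}

#' Membrane potential at the interface vertices
#'
#' `Vm = Vint - V` evaluated at the membrane vertex nodes (ordered as
#' `problem$mem_vert_g`, their global mesh indices).
#'
#' @param problem a [build_coupled_problem()].
#' @param state a `coupled_state`.
#' @return numeric vector of membrane potentials (V).
#' @export
membrane_vm <- function(problem, state) {
  state$Vint[problem$mem_vert_i] - state$V[problem$mem_vert_e]
}

# per-triangle mean of a per-membrane-vertex quantity
tri_mean_vertex <- function(problem, vals) {
  idx <- matrix(match(problem$mesh$facets$membrane, problem$mem_vert_g), ncol = 3)
  (vals[idx[, 1]] + vals[idx[, 2]] + vals[idx[, 3]]) / 3
}

#' Advance the coupled system by one implicit step
#'
#' One monolithic backward-Euler step of the coupled extracellular /
#' intracellular system. The membrane current uses backward differences of
#' the interface traces (`Ic = cm (Vm - Vm_old)/dt`); for active membranes
#' the gates are advanced with the previous step's membrane potential
#' (staggered), so every step is one symmetric positive-definite sparse
#' solve. The stimulation Robin condition uses `Vref = V0 f(t_new)`.
#'
#' @param problem a [build_coupled_problem()].
#' @param state a `coupled_state`.
#' @param f_t waveform value at the new time.
#' @param dt time step (s).
#' @return the new `coupled_state`.
#' @export
coupled_step <- function(problem, state, f_t, dt) {
  stopifnot(dt > 0)
  p <- problem$membrane
  ne <- problem$se$n_dof; ni <- problem$si$n_dof
  active <- isTRUE(p$active)
  gates <- state$gates
  if (active) {
    vt <- vtilde_from_vm(membrane_vm(problem, state), state$v_rest)
    gates <- step_gates(gates, vt, dt * 1e3)
  }
  # beta (slope conductance) and constant term of Im = beta Vm_new - cst,
  # cst = (cm/dt) Vm_old + gl El + gK EK + gNa ENa
  if (active) {
    gK <- p$gK_bar * gates$n^4
    gNa <- p$gNa_bar * gates$m^3 * gates$h
    beta_v <- p$cm / dt + p$gl + gK + gNa
    cst_extra_v <- gK * p$EK + gNa * p$ENa
    beta_t <- tri_mean_vertex(problem, beta_v)
    M_ee <- assemble_boundary_mass(problem$se, problem$tris_e, beta_t)$M
    M_ii <- assemble_boundary_mass(problem$si, problem$tris_i, beta_t)$M
    M_ei <- assemble_mixed_boundary_mass(problem$se, problem$tris_e,
                                         problem$si, problem$tris_i, beta_t)
    ce <- assemble_boundary_mass(problem$se, problem$tris_e,
                                 tri_mean_vertex(problem, cst_extra_v))$r
    ci <- assemble_boundary_mass(problem$si, problem$tris_i,
                                 tri_mean_vertex(problem, cst_extra_v))$r
  } else {
    beta <- p$cm / dt + p$gl
    M_ee <- beta * problem$M_ee
    M_ii <- beta * problem$M_ii
    M_ei <- beta * problem$M_ei
    ce <- ci <- 0
  }
  # integral of (cm/dt) Vm_old phi, via the stored traces
  mVo_e <- (p$cm / dt) *
    (as.numeric(problem$M_ei %*% state$Vint) -
     as.numeric(problem$M_ee %*% state$V))
  mVo_i <- (p$cm / dt) *
    (as.numeric(problem$M_ii %*% state$Vint) -
     as.numeric(Matrix::crossprod(problem$M_ei, state$V)))
  rhs_e <- problem$b0 + f_t * problem$bstim - mVo_e - p$gl * p$El * problem$r_e - ce
  rhs_i <- mVo_i + p$gl * p$El * problem$r_i + ci

  key <- paste0("f_", format(dt, digits = 12))
  if (active || is.null(problem$cache[[key]])) {
    A <- rbind(
      cbind(problem$K_e + problem$R_e + M_ee, -M_ei),
      cbind(-Matrix::t(M_ei), problem$K_i + M_ii)
    )
    A <- methods::as(Matrix::forceSymmetric(A), "CsparseMatrix")
    if (active) {
      x <- as.numeric(Matrix::solve(A, c(rhs_e, rhs_i)))
    } else {
      problem$cache[[key]] <- Matrix::Cholesky(A, LDL = FALSE, super = TRUE)
      x <- as.numeric(Matrix::solve(problem$cache[[key]], c(rhs_e, rhs_i)))
    }
  } else {
    x <- as.numeric(Matrix::solve(problem$cache[[key]], c(rhs_e, rhs_i)))
  }
  if (any(!is.finite(x))) {
    stop("coupled solve failed at t = ", format(state$time + dt), " s")
  }
  new_state <- state
  new_state$time <- state$time + dt
  new_state$V <- x[seq_len(ne)]
  new_state$Vint <- x[ne + seq_len(ni)]
  new_state$gates <- gates
  new_state$Vm_old <- membrane_vm(problem, state)
  new_state
}

#' Run the coupled transient
#'
#' Steps [coupled_step()] over `[0, T_end]` with fixed `dt`, starting from
#' rest, recording snapshots at requested times (snapshot times are rounded
#' to step boundaries) and per-step membrane current diagnostics.
#'
#' @param problem a [build_coupled_problem()].
#' @param w a [waveform()].
#' @param dt time step (s).
#' @param T_end end time (s).
#' @param snapshot_times times (s) at which full states are kept (the final
#'   state is always kept).
#' @return list with `states` (named by time), `final` state, and
#'   `balance`: data.frame per step with net membrane current `I_net` (A) and
#'   total unsigned current `I_abs` (A).
#' @export
solve_coupled_transient <- function(problem, w = waveform_rect(), dt = 5e-5,
                                    T_end = 2e-3, snapshot_times = numeric()) {
  state <- coupled_rest_state(problem)
  nt <- ceiling(T_end / dt)
  snap_steps <- unique(pmin(nt, pmax(0L, round(snapshot_times / dt))))
  states <- list()
  I_net <- I_abs <- numeric(nt)
  for (k in seq_len(nt)) {
    t_new <- k * dt
    state <- coupled_step(problem, state, wf_eval(w, t_new), dt)
    bal <- membrane_current_balance(problem, state, dt)
    I_net[k] <- bal$net; I_abs[k] <- bal$abs
    if (k %in% snap_steps) states[[format(t_new)]] <- state
  }
  list(states = states, final = state,
       balance = data.frame(time = dt * seq_len(nt), I_net = I_net, I_abs = I_abs))
}

# net and unsigned membrane current from the pointwise Im at the vertices
# (vertex-lumped surface quadrature); the Galerkin solution satisfies the
# integral balance exactly, this reports the pointwise-quadrature residual
membrane_current_balance <- function(problem, state, dt) {
  p <- problem$membrane
  vm_new <- membrane_vm(problem, state)
  mc <- membrane_current_density(vm_new, state$Vm_old, dt, state$gates, p)
  # lumped vertex areas on the interface
  key <- "vertex_areas"
  va <- problem$cache[[key]]
  if (is.null(va)) {
    A <- triangle_areas(problem$mesh$nodes, problem$mesh$facets$membrane)
    idx <- matrix(match(problem$mesh$facets$membrane, problem$mem_vert_g), ncol = 3)
    va <- numeric(length(problem$mem_vert_g))
    for (kk in 1:3) va <- va + tabulate_add(idx[, kk], A / 3,
                                            length(problem$mem_vert_g))
    problem$cache[[key]] <- va
  }
  list(net = sum(va * mc$Im), abs = sum(va * abs(mc$Im)))
}

#' Extract a membrane potential profile along the neuron
#'
#' Samples `Vm = Vint - V` at the membrane vertices lying in the vertical
#' plane through the fiber axis, on the electrode-facing (`"bottom"`) or
#' opposite (`"top"`) side, ordered by axial position.
#'
#' @param problem a [build_coupled_problem()].
#' @param state a `coupled_state`.
#' @param side `"bottom"` (facing the substrate electrode) or `"top"`.
#' @param plane_tol half-thickness of the selection slab around the axis
#'   plane (m).
#' @return data.frame with `y` (axial position, m), `arclength` (m), `x`,
#'   `z` (m) and `vm` (V), ordered by increasing `y`.
#' @export
extract_membrane_profile <- function(problem, state,
                                     side = c("bottom", "top"),
                                     plane_tol = 1e-8) {
  side <- match.arg(side)
  g <- problem$mem_vert_g
  xyz <- problem$mesh$nodes[g, , drop = FALSE]
  z0 <- stats::median(xyz[, 3])  # fiber axis height
  onplane <- abs(xyz[, 1]) < plane_tol
  pick <- onplane & if (side == "bottom") xyz[, 3] <= z0 else xyz[, 3] >= z0
  if (!any(pick)) stop("no membrane vertices on the requested path (max ",
                       "distance from plane: ", format(min(abs(xyz[, 1]))), " m)")
  vm <- membrane_vm(problem, state)[pick]
  ord <- order(xyz[pick, 2])
  pts <- xyz[pick, , drop = FALSE][ord, , drop = FALSE]
  arc <- c(0, cumsum(sqrt(rowSums(diff_rows(pts)^2))))
  data.frame(y = pts[, 2], arclength = arc, x = pts[, 1], z = pts[, 3],
             vm = vm[ord])
}
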