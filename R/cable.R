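#' Stimulation waveforms
#'
#' A waveform is the dimensionless time course `f(t)` multiplying the
#' extracellular potential distribution during the simulation: piecewise
#' constant segments (e.g. `-1` for a cathodal rectangle, `+1` anodal, `0`
#' elsewhere). `waveform_rect()` builds a single rectangle; `waveform()`
#' accepts a data.frame of segments `t_start`, `t_end`, `value`.
#'
#' @param segments data.frame with columns `t_start`, `t_end` (s) and `value`.
#' @param delay pulse onset (s).
#' @param width pulse duration (s).
#' @param value multiplier during the pulse.
#' @return an object of class `stim_waveform`.
#' @export
waveform <- function(segments) {
  stopifnot(all(c("t_start", "t_end", "value") %in% names(segments)),
            all(segments$t_end > segments$t_start),
            all(is.finite(segments$value)))
  structure(list(segments = segments), class = "stim_waveform")
}

#' @rdname waveform
#' @export
waveform_rect <- function(delay = 1e-3, width = 1e-3, value = 1) {
  waveform(data.frame(t_start = delay, t_end = delay + width, value = value))
}

#' Evaluate a waveform
#' @param w a [waveform()] (or a plain function of t).
#' @param t times (s).
#' @return numeric multiplier values.
#' @export
wf_eval <- function(w, t) {
  if (is.function(w)) return(w(t))
  out <- numeric(length(t))
  for (k in seq_len(nrow(w$segments))) {
    s <- w$segments[k, ]
    # pulse active on (t_start, t_end]: with backward Euler the new-time
    # value applies over the step ending at t
    out[t > s$t_start & t <= s$t_end] <- s$value
  }
  out
}

# axial conductance Laplacian: (L x)_i = sum_j g_ij (x_i - x_j)
axial_laplacian <- function(model) {
  n <- nrow(model$centers)
  e <- model$edges
  if (is.null(e)) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(n, n)))
  Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2], e[, 1], e[, 2]),
    j = c(e[, 1], e[, 2], e[, 2], e[, 1]),
    x = c(model$g_ax, model$g_ax, -model$g_ax, -model$g_ax),
    dims = c(n, n))
}

#' Simulate the compartmental cable equation in an extracellular field
#'
#' Integrates the spatially discretized cable equation with the extracellular
#' mechanism: each compartment sees the time-varying external potential
#' `e_i(t) = Ve_i f(t)`, which drives the membrane through axial neighbor
#' differences (the discrete second spatial difference along the geometry).
#' Per compartment `i`:
#' `cm_i A_i dVm_i/dt + I_ion,i A_i = sum_j g_ij ((Vm_j + e_j) - (Vm_i + e_i))`
#' with sealed (no axial flux) ends. Time stepping is first-order backward
#' Euler; for active membranes the gating variables are advanced with the
#' previous step's potential (staggered), keeping each step a single sparse
#' linear solve.
#'
#' @param model a [compartmentalize()]d neuron.
#' @param Ve extracellular potential at the compartment centers (V): a vector,
#'   or a function of time returning one (for non-separable fields).
#' @param w a [waveform()] multiplier `f(t)` (ignored when `Ve` is a function).
#' @param dt time step (s).
#' @param T_end end time (s).
#' @param V_init initial membrane potential (V); defaults to the first
#'   compartment's resting potential.
#' @param amplitude global scale applied to `Ve` (used by threshold search).
#' @return an object of class `vm_trace`: `time` (s) and `vm`, an
#'   (steps + 1) x n matrix of membrane potentials (V) whose first row equals
#'   `V_init`.
#' @export
simulate_cable <- function(model, Ve, w = waveform_rect(), dt = 5e-5,
                           T_end = 2e-3, V_init = NULL, amplitude = 1) {
  n <- nrow(model$centers)
  mem <- model$membrane
  mid <- model$membrane_id
  p1 <- mem[[1]]
  if (is.null(V_init)) V_init <- p1$v_rest
  stopifnot(dt > 0, T_end > dt)
  ve_fun <- if (is.function(Ve)) {
    function(t) amplitude * Ve(t)
  } else {
    stopifnot(length(Ve) == n)
    function(t) amplitude * Ve * wf_eval(w, t)
  }
  L <- axial_laplacian(model)
  A <- model$area
  cmA <- vapply(mid, function(k) mem[[k]]$cm, 1) * A
  active <- any(vapply(mem, function(p) isTRUE(p$active), TRUE))
  gates <- if (active) gate_rest_state(n) else NULL
  v_rest <- vapply(mid, function(k) mem[[k]]$v_rest, 1)

  nt <- ceiling(T_end / dt)
  vm <- matrix(NA_real_, nt + 1L, n)
  vm[1L, ] <- V_init
  v <- rep(V_init, n)
  fact <- NULL
  for (k in seq_len(nt)) {
    t_new <- k * dt
    if (active) gates <- step_gates(gates, vtilde_from_vm(v, v_rest), dt * 1e3)
    lin <- ionic_lin_all(gates, mem, mid, n)
    e_new <- ve_fun(t_new)
    rhs <- cmA / dt * v + A * lin$c - as.numeric(L %*% e_new)
    if (active || is.null(fact)) {
      M <- L + Matrix::Diagonal(n, cmA / dt + A * lin$g)
      if (!active) {
        fact <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(M),
                                             "CsparseMatrix"), LDL = FALSE)
        v <- as.numeric(Matrix::solve(fact, rhs))
      } else {
        v <- as.numeric(Matrix::solve(M, rhs))
      }
    } else {
      v <- as.numeric(Matrix::solve(fact, rhs))
    }
    if (any(!is.finite(v))) {
      stop("cable integration produced non-finite membrane potential at step ",
           k, " (t = ", format(t_new), " s)")
    }
    vm[k + 1L, ] <- v
  }
  structure(list(time = seq(0, by = dt, length.out = nt + 1L), vm = vm,
                 model = model), class = "vm_trace")
}

# per-compartment ionic linearization at frozen gates
ionic_lin_all <- function(gates, mem, mid, n) {
  if (length(mem) == 1L) {
    li <- ionic_linearization(gates, mem[[1]])
    return(list(g = rep(li$g, length.out = n), c = rep(li$c, length.out = n)))
  }
  g <- c_ <- numeric(n)
  for (k in seq_along(mem)) {
    sel <- mid == k
    if (!any(sel)) next
    gk <- if (is.null(gates)) NULL else lapply(gates, function(x) x[sel])
    li <- ionic_linearization(gk, mem[[k]])
    g[sel] <- li$g; c_[sel] <- li$c
  }
  list(g = g, c = c_)
}

#' @export
print.vm_trace <- function(x, ...) {
  cat("<vm_trace>", nrow(x$vm) - 1, "steps x", ncol(x$vm), "compartments;",
      "Vm range [", format(min(x$vm) * 1e3, digits = 4), ",",
      format(max(x$vm) * 1e3, digits = 4), "] mV\n")
  invisible(x)
}

#' Convert a membrane-potential trace to a data frame
#'
#' @param x a `vm_trace`.
#' @param ... unused.
#' @return data.frame with columns `time` (s), `compartment`, `vm` (V).
#' @export
as.data.frame.vm_trace <- function(x, ...) {
  n <- ncol(x$vm)
  data.frame(time = rep(x$time, n),
             compartment = rep(seq_len(n), each = length(x$time)),
             vm = as.vector(x$vm))
}

#' Audit the integration time step
#'
#' Accepts the largest `dt` in `dt0, dt0/10, dt0/100, ...` for which the
#' membrane potential at the location of its largest deviation differs by
#' less than `tol` (relative) between runs at `dt` and `dt/10`.
#'
#' @param model a [compartmentalize()]d neuron.
#' @param Ve,w,T_end,V_init as in [simulate_cable()].
#' @param dt0 starting (coarsest) time step (s).
#' @param tol relative acceptance tolerance (default 1%).
#' @param dt_floor smallest dt tried before giving up (s).
#' @return accepted dt (s), with attribute `rel_diff`.
#' @export
auto_timestep <- function(model, Ve, w = waveform_rect(), T_end = 2e-3,
                          V_init = NULL, dt0 = 5e-5, tol = 0.01,
                          dt_floor = dt0 / 1000) {
  dt <- dt0
  repeat {
    d <- timestep_rel_diff(model, Ve, w, T_end, V_init, dt)
    if (d < tol) return(structure(dt, rel_diff = d))
    if (dt / 10 < dt_floor) {
      stop("time-step criterion unmet at the configured floor (achieved ",
           "relative difference ", format(d, digits = 3), " at dt = ",
           format(dt), " s)")
    }
    dt <- dt / 10
  }
}

timestep_rel_diff <- function(model, Ve, w, T_end, V_init, dt) {
  a <- simulate_cable(model, Ve, w, dt, T_end, V_init)
  b <- simulate_cable(model, Ve, w, dt / 10, T_end, V_init)
  rest <- a$vm[1, 1]
  dev <- abs(a$vm[nrow(a$vm), ] - rest)
  i <- which.max(dev)
  va <- a$vm[nrow(a$vm), i]; vb <- b$vm[nrow(b$vm), i]
  if (max(dev) == 0) return(0)
  abs(va - vb) / max(abs(vb - rest), .Machine$double.eps)
}

#' Threshold-current search by bisection (dichotomy)
#'
#' Scales the stimulation amplitude up or down by bisection until the
#' relative bracket width falls below `tol`; a spike is detected when any
#' monitored compartment's membrane potential exceeds `detect`.
#'
#' @param model an active [compartmentalize()]d neuron.
#' @param Ve extracellular potential per compartment for a unit stimulus (V).
#' @param pulse the [waveform()] shape.
#' @param detect spike-detection voltage (V). The detection level is a
#'   required choice of the caller; all-or-none dynamics make the threshold
#'   insensitive to it.
#' @param bracket `c(lo, hi)` initial amplitude bracket; `hi` should spike,
#'   `lo` not. The bracket is expanded (up to `max_expand` doublings) if not.
#' @param tol relative bracket width at convergence (default 1%).
#' @param dt,T_end,V_init integration controls.
#' @param monitor compartment indices to watch (default: all).
#' @param max_expand bracket auto-expansion limit.
#' @return list with `status` (`"ok"`, `"above_bracket"` or
#'   `"below_bracket"`), `threshold` (the spiking amplitude; `NA` unless
#'   `"ok"`), and the final `bracket`.
#' @export
find_threshold <- function(model, Ve, pulse = waveform_rect(), detect = mV(-20),
                           bracket = c(0.1, 10), tol = 0.01, dt = 2.5e-5,
                           T_end = 4e-3, V_init = NULL, monitor = NULL,
                           max_expand = 6L) {
  spikes <- function(a) {
    tr <- simulate_cable(model, Ve, pulse, dt, T_end, V_init, amplitude = a)
    vmax <- if (is.null(monitor)) tr$vm else tr$vm[, monitor, drop = FALSE]
    any(vmax > detect)
  }
  lo <- bracket[1]; hi <- bracket[2]
  ex <- 0L
  while (!spikes(hi)) {
    ex <- ex + 1L
    if (ex > max_expand) {
      return(list(status = "above_bracket", threshold = NA_real_,
                  bracket = c(lo, hi)))
    }
    lo <- hi; hi <- hi * 2
  }
  ex <- 0L
  while (spikes(lo)) {
    ex <- ex + 1L
    if (ex > max_expand) {
      return(list(status = "below_bracket", threshold = NA_real_,
                  bracket = c(lo, hi)))
    }
    hi <- lo; lo <- lo / 2
  }
  while ((hi - lo) / hi > tol) {
    mid <- sqrt(lo * hi)
    if (spikes(mid)) hi <- mid else lo <- mid
  }
  list(status = "ok", threshold = hi, bracket = c(lo, hi))
}
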