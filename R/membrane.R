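#' Membrane electrical parameters
#'
#' Single source of truth for the passive and active (Hodgkin-Huxley)
#' membrane description shared by the cable and whole-FEM solvers. All values
#' are SI: specific capacitance `cm` in F/m^2, specific conductances in
#' S/m^2, potentials in V. Use the [units] helpers to convert from the
#' uF/cm^2, mS/cm^2 and mV habits of the electrophysiology literature
#' (1 uF/cm^2 = 0.01 F/m^2; 1 mS/cm^2 = 10 S/m^2).
#'
#' `membrane_passive()` defaults are the passive fiber set used throughout
#' the bundled scenarios: cm = 1 uF/cm^2, gl = 1e-4 mS/cm^2, El = -65 mV,
#' ionic currents absent. `membrane_hh()` adds the classic squid-axon
#' channel set (gK = 36 mS/cm^2, gNa = 120 mS/cm^2, EK = -77 mV,
#' ENa = +50 mV relative to a -65 mV rest).
#'
#' @param cm specific membrane capacitance (F/m^2).
#' @param gl leak conductance (S/m^2).
#' @param El leak reversal potential (V).
#' @param gK_bar,gNa_bar maximal K/Na conductances (S/m^2).
#' @param EK,ENa ionic reversal potentials (V).
#' @param v_rest resting potential defining the gating-variable voltage
#'   origin (V); for the passive model this is `El`.
#' @return an object of class `membrane_params`.
#' @export
membrane_passive <- function(cm = uF_per_cm2(1), gl = mS_per_cm2(1e-4),
                             El = mV(-65)) {
  stopifnot(cm > 0, gl >= 0)
  structure(list(cm = cm, gl = gl, El = El, active = FALSE,
                 gK_bar = 0, gNa_bar = 0, EK = El, ENa = El, v_rest = El),
            class = "membrane_params")
}

#' @rdname membrane_passive
#' @export
membrane_hh <- function(cm = uF_per_cm2(1), gl = mS_per_cm2(0.3),
                        El = mV(-54.3), gK_bar = mS_per_cm2(36),
                        gNa_bar = mS_per_cm2(120), EK = mV(-77),
                        ENa = mV(50), v_rest = mV(-65)) {
  stopifnot(cm > 0, gl >= 0, gK_bar >= 0, gNa_bar >= 0)
  structure(list(cm = cm, gl = gl, El = El, active = TRUE,
                 gK_bar = gK_bar, gNa_bar = gNa_bar, EK = EK, ENa = ENa,
                 v_rest = v_rest),
            class = "membrane_params")
}

#' Hodgkin-Huxley rate constants
#'
#' Evaluates the six classic opening/closing rates at a membrane-potential
#' deviation expressed in the original squid-axon convention: `vtilde` is the
#' *negative* of the deviation of the membrane potential from its resting
#' value, in millivolts (so a depolarization of 10 mV gives `vtilde = -10`).
#' Rates are returned in 1/ms.
#'
#' The removable singularities of the alpha_n (at `vtilde = -10`) and
#' alpha_m (at `vtilde = -25`) expressions are filled with their analytic
#' limits (0.1 and 1.0 respectively).
#'
#' @param vtilde numeric vector, -(Vm - Vrest) in mV.
#' @return list with components `an`, `bn`, `am`, `bm`, `ah`, `bh` (1/ms).
#' @export
hh_rates <- function(vtilde) {
  xexprel <- function(x) {
    # x / (exp(x) - 1), with the analytic limit 1 at x = 0
    out <- ifelse(abs(x) < 1e-7, 1 - x / 2, x / expm1(x))
    out
  }
  list(
    an = 0.1  * xexprel((vtilde + 10) / 10),
    bn = 0.125 * exp(vtilde / 80),
    am = xexprel((vtilde + 25) / 10),
    bm = 4    * exp(vtilde / 18),
    ah = 0.07 * exp(vtilde / 20),
    bh = 1 / (exp((vtilde + 30) / 10) + 1)
  )
}

#' Steady-state open probability of a first-order gate
#'
#' The fixed point `alpha / (alpha + beta)` of
#' `dx/dt = alpha (1 - x) - beta x`.
#'
#' @param alpha,beta rate constants (1/ms), `alpha + beta > 0`.
#' @return open probability in `[0, 1]`.
#' @export
gate_steady_state <- function(alpha, beta) {
  if (any(alpha + beta <= 0)) {
    stop("gate fixed point undefined: alpha + beta must be positive")
  }
  alpha / (alpha + beta)
}

#' Gating state at rest
#'
#' n, m, h initialized at their steady states for `vtilde = 0`.
#'
#' @param n_comp number of compartments/nodes (state is replicated).
#' @return list with numeric vectors `n`, `m`, `h`.
#' @export
gate_rest_state <- function(n_comp = 1L) {
  r <- hh_rates(0)
  list(n = rep(gate_steady_state(r$an, r$bn), n_comp),
       m = rep(gate_steady_state(r$am, r$bm), n_comp),
       h = rep(gate_steady_state(r$ah, r$bh), n_comp))
}

#' Advance gating variables one backward-Euler step
#'
#' Unconditionally stable update `x' = (x + dt alpha) / (1 + dt (alpha +
#' beta))`; the result stays in `[0, 1]` for any `dt > 0` and any finite
#' `vtilde`, and preserves the steady state exactly.
#'
#' @param state list with `n`, `m`, `h` (open probabilities).
#' @param vtilde -(Vm - Vrest) in mV (scalar or per-compartment vector).
#' @param dt time step in ms.
#' @return updated state list.
#' @export
step_gates <- function(state, vtilde, dt) {
  stopifnot(dt > 0)
  r <- hh_rates(vtilde)
  be <- function(x, a, b) (x + dt * a) / (1 + dt * (a + b))
  list(n = be(state$n, r$an, r$bn),
       m = be(state$m, r$am, r$bm),
       h = be(state$h, r$ah, r$bh))
}

#' Membrane current densities
#'
#' Computes the thin-film membrane current density and its components from
#' the membrane potential at the new and previous time level:
#' capacitive `Ic = cm (Vm_new - Vm_old)/dt`, leak `Il = gl (Vm_new - El)`,
#' and, for active membranes, `IK = gK_bar n^4 (Vm_new - EK)` and
#' `INa = gNa_bar m^3 h (Vm_new - ENa)`. Sign convention: positive current
#' is outward (intracellular to extracellular). `Im = Ic + Il + IK + INa`
#' exactly.
#'
#' @param Vm_new,Vm_old membrane potential `Vint - V` at the new/previous
#'   step (V); vectors allowed.
#' @param dt time step (s).
#' @param gates list with `n`, `m`, `h` (ignored for passive membranes).
#' @param p a [membrane_passive()] / [membrane_hh()] parameter set.
#' @return list with `Im`, `Ic`, `Il`, `IK`, `INa` (A/m^2).
#' @export
membrane_current_density <- function(Vm_new, Vm_old, dt, gates, p) {
  stopifnot(dt > 0)
  Ic <- p$cm * (Vm_new - Vm_old) / dt
  Il <- p$gl * (Vm_new - p$El)
  if (isTRUE(p$active)) {
    IK <- p$gK_bar * gates$n^4 * (Vm_new - p$EK)
    INa <- p$gNa_bar * gates$m^3 * gates$h * (Vm_new - p$ENa)
  } else {
    IK <- INa <- 0 * Ic
  }
  list(Im = Ic + Il + IK + INa, Ic = Ic, Il = Il, IK = IK, INa = INa)
}

# vtilde (mV) from absolute membrane potential (V) and resting potential (V)
vtilde_from_vm <- function(Vm, v_rest) -(Vm - v_rest) * 1e3

# total ionic slope conductance and "driving" current at frozen gates:
# I_ion(V) = g_tot * (V) - c_ion, linear in the new potential
ionic_linearization <- function(gates, p) {
  g_tot <- p$gl
  c_ion <- p$gl * p$El
  if (isTRUE(p$active)) {
    gK <- p$gK_bar * gates$n^4
    gNa <- p$gNa_bar * gates$m^3 * gates$h
    g_tot <- g_tot + gK + gNa
    c_ion <- c_ion + gK * p$EK + gNa * p$ENa
  }
  list(g = g_tot, c = c_ion)
}
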