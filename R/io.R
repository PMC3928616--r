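#' Export sampled potentials as tab-separated text
#'
#' Writes one line per point: `x y z V` (meters, volts), the portable format
#' consumed by the cable pathway and external tools.
#'
#' @param sol a `field_solution`.
#' @param points n x 3 matrix of sample locations (m).
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_potential_tsv <- function(sol, points, path) {
  v <- sample_potential(sol, points)
  utils::write.table(
    data.frame(x = points[, 1], y = points[, 2], z = points[, 3], V = v),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tab-separated potential file
#'
#' Counterpart of [export_potential_tsv()]; also accepts the two-column
#' `compartment value` form.
#'
#' @param path file path.
#' @return data.frame with a `V` column (plus coordinates when present).
#' @export
read_potential_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!"V" %in% names(df)) {
    if (ncol(df) == 2) names(df) <- c("compartment", "V")
    else stop("unrecognized potential table layout in ", path)
  }
  df
}

#' Export a membrane-potential trace as CSV
#'
#' Time runs down the rows; one column per compartment.
#'
#' @param trace a `vm_trace` from [simulate_cable()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_trace_csv <- function(trace, path) {
  df <- as.data.frame(cbind(time = trace$time, trace$vm))
  names(df) <- c("time", paste0("c", seq_len(ncol(trace$vm))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a membrane profile as CSV
#'
#' @param profile data.frame from [extract_membrane_profile()].
#' @param path output file.
#' @param side label stored in the `side` column.
#' @return the path, invisibly.
#' @export
export_profile_csv <- function(profile, path, side = "bottom") {
  profile$side <- side
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' YAML configuration with the field's unit habits (lengths in um,
#' capacitance in uF/cm^2, conductances in mS/cm^2, resistivity in Ohm cm,
#' potentials in mV, times in ms, currents in uA); values convert to SI at
#' this boundary. Recognized sections: `chamber` (radius_um, height_um,
#' electrode_diameter_um, pitch_um, layout, gap_um, ground_surface),
#' `neuron` (fiber_length_um, fiber_diameter_um, soma_diameter_um, z_um),
#' `membrane` (cm_uF_cm2, gl_mS_cm2, El_mV, active, gK_mS_cm2, gNa_mS_cm2,
#' EK_mV, ENa_mV), `stimulation` (g_gs_Sm2, g_stim_Sm2, I_uA, delay_ms,
#' width_ms, value), `solver` (Ra_ohm_cm, dx_um, dt_ms, T_ms, order, detail).
#' Missing entries fall back to the package defaults, which reproduce the
#' bundled scenarios.
#'
#' @param path YAML file.
#' @return list with `params`, `neuron`, `membrane`, `stim`, `solver`.
#' @export
read_scenario_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading configuration files requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses exponent forms like "2e-4" as strings; coerce defensively
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  ch <- cfg$chamber %||% list()
  params <- mea_params(
    chamber_radius = um(num(ch$radius_um, 1500)),
    chamber_height = um(num(ch$height_um, 1000)),
    electrode_diameter = um(num(ch$electrode_diameter_um, 10)),
    pitch = um(num(ch$pitch_um, 100)),
    layout = ch$layout %||% "mea60",
    ground_gap = um(num(ch$gap_um, 10)),
    ground_surface_enabled = ch$ground_surface %||% TRUE)
  ne <- cfg$neuron %||% list()
  neuron <- neuron_geometry(
    fiber_length = um(num(ne$fiber_length_um, 260)),
    fiber_diameter = um(num(ne$fiber_diameter_um, 2)),
    soma_diameter = if (is.null(ne$soma_diameter_um)) NULL else
      um(as.numeric(ne$soma_diameter_um)),
    height_above_substrate = um(num(ne$z_um, 50)))
  me <- cfg$membrane %||% list()
  membrane <- if (isTRUE(me$active)) {
    membrane_hh(cm = uF_per_cm2(num(me$cm_uF_cm2, 1)),
                gl = mS_per_cm2(num(me$gl_mS_cm2, 0.3)),
                El = mV(num(me$El_mV, -54.3)),
                gK_bar = mS_per_cm2(num(me$gK_mS_cm2, 36)),
                gNa_bar = mS_per_cm2(num(me$gNa_mS_cm2, 120)),
                EK = mV(num(me$EK_mV, -77)), ENa = mV(num(me$ENa_mV, 50)),
                v_rest = mV(num(me$v_rest_mV, -65)))
  } else {
    membrane_passive(cm = uF_per_cm2(num(me$cm_uF_cm2, 1)),
                     gl = mS_per_cm2(num(me$gl_mS_cm2, 1e-4)),
                     El = mV(num(me$El_mV, -65)))
  }
  st <- cfg$stimulation %||% list()
  stim <- list(g_gs = num(st$g_gs_Sm2, 500),
               g_stim = num(st$g_stim_Sm2, 500),
               I_target = uA(num(st$I_uA, -1)),
               pulse = waveform_rect(ms(num(st$delay_ms, 1)),
                                     ms(num(st$width_ms, 1)),
                                     num(st$value, 1)))
  sv <- cfg$solver %||% list()
  solver <- list(Ra = ohm_cm(num(sv$Ra_ohm_cm, 100)),
                 dx = um(num(sv$dx_um, 1)),
                 dt = ms(num(sv$dt_ms, 0.05)),
                 T_end = ms(num(sv$T_ms, 2)),
                 order = as.integer(num(sv$order, 1)),
                 detail = sv$detail %||% "full")
  list(params = params, neuron = neuron, membrane = membrane, stim = stim,
       solver = solver)
}
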