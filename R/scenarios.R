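#' Full width at half maximum of a sampled profile
#'
#' Linear-interpolated width of the profile at half of its peak value. The
#' profile must attain its maximum strictly inside the sampled range and
#' cross the half level on both sides.
#'
#' @param x positions (m), strictly increasing.
#' @param v profile values (same length).
#' @return width (m).
#' @export
fwhm <- function(x, v) {
  stopifnot(length(x) == length(v), !is.unsorted(x, strictly = TRUE))
  i <- which.max(v)
  if (i == 1 || i == length(v)) {
    stop("profile has no interior maximum; FWHM undefined")
  }
  half <- v[i] / 2
  left <- which(v[seq_len(i)] <= half)
  right <- i - 1L + which(v[i:length(v)] <= half)
  if (!length(left) || !length(right)) {
    stop("profile does not cross its half-maximum on both sides")
  }
  l <- max(left)
  xl <- x[l] + (half - v[l]) / (v[l + 1] - v[l]) * (x[l + 1] - x[l])
  r <- min(right)
  xr <- x[r - 1] + (half - v[r - 1]) / (v[r] - v[r - 1]) * (x[r] - x[r - 1])
  xr - xl
}

# stimulation electrode: the site closest to the origin
stim_electrode_tag <- function(params) {
  ec <- electrode_centers(params)
  ec$name[which.min(ec$x^2 + ec$y^2)]
}

#' Field focality of monopolar vs ground-surface configurations
#'
#' Solves the chamber field for the monopolar configuration (return at the
#' distant chamber wall) and for the ground-surface configuration over a
#' sweep of surface conductances plus the Dirichlet (infinite-conductance)
#' limit. The potential is sampled along a line 50 um above the stimulation
#' electrode, normalized by its peak, and summarized by the full width at
#' half maximum.
#'
#' @param params an [mea_params()].
#' @param g_sweep ground-surface conductances (S/m^2).
#' @param g_stim stimulation-electrode surface conductance (S/m^2).
#' @param g_wall distant-ground (chamber wall) surface conductance for the
#'   monopolar configuration (S/m^2).
#' @param z_line height of the sampling line (m).
#' @param half_length half-length of the sampling line (m).
#' @param n_samples number of sample points.
#' @param element_order FE order for the solves.
#' @param detail mesh detail passed to [build_mea_chamber()].
#' @param mesh optional prebuilt chamber mesh (reused across configurations).
#' @return an object of class `focality_result`: `profiles` (data.frame:
#'   `config`, `x`, `v`, `v_norm`) and `fwhm` (data.frame: `config`,
#'   `fwhm`), configurations ordered monopolar, then increasing g, then the
#'   Dirichlet limit.
#' @export
run_focality <- function(params = mea_params(), g_sweep = c(500, 5e3, 5e4),
                         g_stim = 500, g_wall = 500, z_line = 50e-6,
                         half_length = 400e-6, n_samples = 161,
                         element_order = 1L, detail = "full", mesh = NULL) {
  if (is.null(mesh)) mesh <- build_mea_chamber(params, detail = detail)
  stim <- stim_electrode_tag(params)
  xs <- seq(-half_length, half_length, length.out = n_samples)
  pts <- cbind(xs, 0, z_line)
  configs <- list()
  configs[["monopolar"]] <- list(bcs = list(
    bc_robin(g = g_stim, V0 = -1), bc_robin(g = g_wall, V0 = 0)) |>
      stats::setNames(c(stim, "chamber_wall")))
  for (g in sort(g_sweep)) {
    configs[[sprintf("ground_surface_g%g", g)]] <- list(bcs = stats::setNames(
      list(bc_robin(g = g_stim, V0 = -1), bc_robin(g = g, V0 = 0)),
      c(stim, "ground_surface")))
  }
  configs[["ground_surface_dirichlet"]] <- list(bcs = stats::setNames(
    list(bc_robin(g = g_stim, V0 = -1), bc_dirichlet(0)),
    c(stim, "ground_surface")))

  prof <- NULL
  wid <- NULL
  for (nm in names(configs)) {
    pr <- field_problem(mesh, 0.2, configs[[nm]]$bcs, element_order)
    sol <- solve_field(pr)
    v <- sample_potential(sol, pts)
    vn <- abs(v) / max(abs(v))
    prof <- rbind(prof, data.frame(config = nm, x = xs, v = v, v_norm = vn))
    wid <- rbind(wid, data.frame(config = nm, fwhm = fwhm(xs, vn)))
  }
  structure(list(profiles = prof, fwhm = wid, stim_tag = stim,
                 z_line = z_line), class = "focality_result")
}

#' @export
print.focality_result <- function(x, ...) {
  cat("<focality_result> profile line at z =", x$z_line * 1e6, "um over",
      x$stim_tag, "\n")
  w <- x$fwhm
  w$fwhm_um <- round(w$fwhm * 1e6, 2)
  print(w[, c("config", "fwhm_um")], row.names = FALSE)
  invisible(x)
}

#' Mirror response of a passive fiber (hybrid pathway)
#'
#' The full hybrid pipeline: solve the ground-surface MEA field, calibrate
#' the stimulation electrode to the nominal cathodic current, interpolate
#' the potential at the compartment centers of a passive fiber 50 um above
#' the stimulation electrode, integrate the cable equation through a 1-ms
#' rectangular pulse, and compare the end-of-pulse membrane polarization
#' profile with the mirror image of the extracellular profile (the negated
#' potential centered on its spatial average).
#'
#' @param params an [mea_params()].
#' @param neuron a [neuron_geometry()] (fiber position/length).
#' @param membrane membrane parameter set.
#' @param Ra intracellular resistivity (Ohm m).
#' @param g_gs,g_stim surface conductances (S/m^2).
#' @param I_target nominal stimulation current (A), cathodic negative.
#' @param pulse stimulation [waveform()].
#' @param dx compartment length (m).
#' @param dt,T_end cable integration controls (s).
#' @param element_order,detail,mesh field solve controls.
#' @return an object of class `mirror_report`: per-compartment `y`, `Ve`,
#'   end-of-pulse `vm`, plus `mirror_error` (max deviation from the mirror
#'   image over the extracellular peak-to-peak), `correlation`, `mean_dev`
#'   (spatial mean of the polarization / peak-to-peak) and the calibrated
#'   `V0`.
#' @export
run_mirror_fiber <- function(params = mea_params(), neuron = neuron_geometry(),
                             membrane = membrane_passive(), Ra = ohm_cm(100),
                             g_gs = 500, g_stim = 500, I_target = -1e-6,
                             pulse = waveform_rect(1e-3, 1e-3, 1), dx = 1e-6,
                             dt = 5e-5, T_end = 2e-3, element_order = 1L,
                             detail = "full", mesh = NULL) {
  if (is.null(mesh)) mesh <- build_mea_chamber(params, detail = detail)
  stim <- stim_electrode_tag(params)
  bcs <- stats::setNames(list(bc_robin(g = g_stim, V0 = 1),
                              bc_robin(g = g_gs, V0 = 0)),
                         c(stim, "ground_surface"))
  pr <- field_problem(mesh, 0.2, bcs, element_order)
  mod <- compartmentalize(
    morphology_fiber(neuron$fiber_length, neuron$fiber_diameter,
                     neuron$height_above_substrate, neuron$soma_diameter),
    dx = dx, Ra = Ra, membrane = membrane)
  if (I_target == 0) {
    return(structure(list(y = mod$centers[, 2], Ve = rep(0, nrow(mod$centers)),
                          vm = rep(membrane$El, nrow(mod$centers)),
                          mirror_error = 0, correlation = NA_real_,
                          mean_dev = 0, p2p = 0, V0 = 0),
                     class = "mirror_report"))
  }
  cal <- calibrate_stimulus(pr, stim, I_target)
  Ve <- sample_potential(cal$sol, mod$centers)
  tr <- simulate_cable(mod, Ve, pulse, dt, T_end)
  vm_end <- tr$vm[nrow(tr$vm), ]
  dev <- vm_end - membrane$El
  mirror <- -(Ve - mean(Ve))
  p2p <- diff(range(mirror))
  structure(list(
    y = mod$centers[, 2], Ve = Ve, vm = vm_end,
    mirror_error = max(abs(dev - mirror)) / p2p,
    correlation = stats::cor(dev, mirror),
    mean_dev = mean(dev) / p2p, p2p = p2p, V0 = cal$V0,
    I_stim = cal$I_stim, I_return = cal$I_return, trace = tr
  ), class = "mirror_report")
}

#' @export
print.mirror_report <- function(x, ...) {
  cat("<mirror_report>", length(x$y), "compartments; Ve peak-to-peak",
      format(x$p2p * 1e3, digits = 4), "mV\n")
  cat("  mirror error:", format(x$mirror_error, digits = 3),
      " correlation:", format(x$correlation, digits = 6),
      " spatial mean dev:", format(x$mean_dev, digits = 3), "\n")
  invisible(x)
}

#' Hybrid vs whole-FEM comparison (fiber and fiber-with-soma)
#'
#' Runs both modeling pathways on the same reduced single-electrode
#' ground-surface chamber: (1) the hybrid pipeline (field without the neuron,
#' then cable integration), and (2) the coupled thin-film transient with the
#' neuron geometry embedded, using the same calibrated stimulation voltage.
#' Reports end-of-pulse membrane profiles along the electrode-facing
#' ("bottom") and opposite ("top") sides, the hybrid profile, the
#' cross-method agreement at the fiber ends, and the bottom-top asymmetry
#' per axial station.
#'
#' @param neuron a [neuron_geometry()]; run twice (with/without soma) via
#'   [run_comparison()]'s `geometries` argument.
#' @param geometries list of [neuron_geometry()] objects to run.
#' @param params chamber parameters; the default is a reduced cylinder
#'   (r = 0.5 mm, h = 0.3 mm) with a single electrode, which keeps the
#'   coupled transient tractable while leaving the local field unchanged.
#' @param membrane,Ra,g_gs,g_stim,I_target,pulse electrical/stimulation
#'   parameters as in [run_mirror_fiber()].
#' @param dx,dt,T_end discretization controls.
#' @param refine membrane-adjacent mesh refinement level (see
#'   [embed_neuron_surface()]).
#' @return an object of class `comparison_report`: a list per geometry with
#'   `hybrid` (data.frame y, vm), `bottom`, `top` (membrane profiles),
#'   `asymmetry` (data.frame y, asym), `end_agreement` (max relative
#'   mismatch at the two fiber ends, fraction of peak-to-peak), `p2p`, and
#'   `asym_max_y` (location of the maximal side asymmetry).
#' @export
run_comparison <- function(geometries = list(
                             fiber = neuron_geometry(),
                             soma = neuron_geometry(soma_diameter = 20e-6)),
                           params = mea_params(layout = "single",
                                               chamber_radius = 5e-4,
                                               chamber_height = 3e-4),
                           membrane = membrane_passive(), Ra = ohm_cm(100),
                           g_gs = 500, g_stim = 500, I_target = -1e-6,
                           pulse = waveform_rect(1e-3, 1e-3, 1), dx = 1e-6,
                           dt = 5e-5, T_end = 2e-3, refine = 1) {
  stim <- stim_electrode_tag(params)
  out <- list()
  for (nm in names(geometries)) {
    neuron <- geometries[[nm]]
    mesh <- embed_neuron_surface(params, neuron, detail = "full",
                                 refine = refine)
    # hybrid: field without the neuron (uniform conductivity on same mesh)
    bcs <- stats::setNames(list(bc_robin(g = g_stim, V0 = 1),
                                bc_robin(g = g_gs, V0 = 0)),
                           c(stim, "ground_surface"))
    pr <- field_problem(mesh, list(extracellular = 0.2, intracellular = 0.2),
                        bcs, element_order = 1L)
    cal <- calibrate_stimulus(pr, stim, I_target)
    mod <- compartmentalize(
      morphology_fiber(neuron$fiber_length, neuron$fiber_diameter,
                       neuron$height_above_substrate, neuron$soma_diameter),
      dx = dx, Ra = Ra, membrane = membrane)
    Ve <- sample_potential(cal$sol, mod$centers)
    tr <- simulate_cable(mod, Ve, pulse, dt, T_end)
    hybrid <- data.frame(y = mod$centers[, 2], vm = tr$vm[nrow(tr$vm), ])
    # whole-FEM: same V0, neuron embedded
    bcs2 <- stats::setNames(list(bc_robin(g = g_stim, V0 = cal$V0),
                                 bc_robin(g = g_gs, V0 = 0)),
                            c(stim, "ground_surface"))
    cp <- build_coupled_problem(mesh, 0.2, 1 / Ra, membrane, bcs2,
                                stim_tags = stim)
    res <- solve_coupled_transient(cp, pulse, dt, T_end)
    bottom <- extract_membrane_profile(cp, res$final, "bottom")
    top <- extract_membrane_profile(cp, res$final, "top")
    p2p <- diff(range(hybrid$vm))
    ys <- intersect(bottom$y, top$y)
    asym <- data.frame(
      y = ys,
      asym = bottom$vm[match(ys, bottom$y)] - top$vm[match(ys, top$y)])
    # agreement at the fiber ends: FEM side-average vs cable
    yh <- neuron$fiber_length / 2
    endm <- vapply(c(-1, 1) * (yh - 2e-6), function(yq) {
      fem <- (bottom$vm[which.min(abs(bottom$y - yq))] +
              top$vm[which.min(abs(top$y - yq))]) / 2
      cab <- hybrid$vm[which.min(abs(hybrid$y - yq))]
      abs(fem - cab) / p2p
    }, 1)
    out[[nm]] <- list(hybrid = hybrid, bottom = bottom, top = top,
                      asymmetry = asym, end_agreement = max(endm), p2p = p2p,
                      asym_max_y = asym$y[which.max(abs(asym$asym))],
                      balance = res$balance, V0 = cal$V0)
  }
  structure(out, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  for (nm in names(x)) {
    r <- x[[nm]]
    cat("<comparison_report> geometry '", nm, "': p2p ",
        format(r$p2p * 1e3, digits = 4), " mV; end agreement ",
        format(r$end_agreement, digits = 3), "; max |bottom-top| ",
        format(max(abs(r$asymmetry$asym)) * 1e3, digits = 4), " mV at y = ",
        format(r$asym_max_y * 1e6, digits = 3), " um\n", sep = "")
  }
  invisible(x)
}
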