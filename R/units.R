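#' Unit conversion helpers
#'
#' All internal quantities are SI: lengths in meters, potentials in volts,
#' conductivities in S/m, surface conductances in S/m^2, specific capacitance
#' in F/m^2, specific conductances in S/m^2, current in amperes, time in
#' seconds. Configuration files and the classic electrophysiology literature
#' use micrometres, uF/cm^2, mS/cm^2 and Ohm.cm; these helpers convert at the
#' package boundary.
#'
#' Conversion factors: 1 um = 1e-6 m; 1 uF/cm^2 = 0.01 F/m^2;
#' 1 mS/cm^2 = 10 S/m^2; 1 S/cm^2 = 1e4 S/m^2; 1 Ohm.cm = 0.01 Ohm.m;
#' 1 mV = 1e-3 V; 1 ms = 1e-3 s; 1 uA = 1e-6 A.
#'
#' @param x numeric vector in the source unit.
#' @return numeric vector in the SI target unit.
#' @name units
#' @examples
#' um(50)          # 5e-05 m
#' uF_per_cm2(1)   # 0.01 F/m^2
#' mS_per_cm2(1e-4) # 0.001 S/m^2
NULL

#' @rdname units
#' @export
um <- function(x) x * 1e-6

#' @rdname units
#' @export
mm <- function(x) x * 1e-3

#' @rdname units
#' @export
mV <- function(x) x * 1e-3

#' @rdname units
#' @export
ms <- function(x) x * 1e-3

#' @rdname units
#' @export
uA <- function(x) x * 1e-6

#' @rdname units
#' @export
uF_per_cm2 <- function(x) x * 1e-2

#' @rdname units
#' @export
mS_per_cm2 <- function(x) x * 10

#' @rdname units
#' @export
ohm_cm <- function(x) x * 1e-2
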