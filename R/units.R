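# Canonical internal units: micrometre (length), second (time), micronewton
# (force). Viscosity is then uN s um^-2 (water ~ 1e-9), pressure uN um^-2
# (identically MPa), and bending stiffness E * I emerges directly in uN um^2
# with E in MPa -- no hidden scale factors anywhere in the pipeline.

#' Convert a volumetric flow rate from uL/min to um^3/s
#'
#' Syringe pumps are programmed in microlitres per minute; all internal flow
#' computations use cubic micrometres per second (1 uL = 1e9 um^3).
#'
#' @param q Flow rate in uL/min.
#' @return Flow rate in um^3/s.
#' @export
#' @examples
#' ul_min_to_um3_s(1) # 1e9 / 60
ul_min_to_um3_s <- function(q) q * (1e9 / 60)

#' Convert a volumetric flow rate from um^3/s to uL/min
#'
#' @param q Flow rate in um^3/s.
#' @return Flow rate in uL/min.
#' @export
um3_s_to_ul_min <- function(q) q * (60 / 1e9)

#' Dynamic viscosity of water in canonical units
#'
#' Water at room temperature has a dynamic viscosity of about 1e-3 Pa s,
#' which is 1e-9 uN s um^-2 in the package's canonical unit system.
#'
#' @return Viscosity in uN s um^-2.
#' @export
water_viscosity <- function() 1e-9

# internal angle helpers (tables use degrees, the code uses radians)
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
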