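# From bending stiffness to cell-wall elasticity. The hypha is modelled as
# a thin-walled tube: an annular cross-section of outer radius r and wall
# thickness t. With k_b = E * I, the longitudinal Young's modulus of the
# wall material follows as E = k_b / I; in canonical units
# uN um^2 / um^4 = uN um^-2, which is identically MPa.

#' Second moment of area of an annular cross-section
#'
#' `I = (pi/4) (r^4 - (r - t)^4)` for a circular ring of outer radius r and
#' wall thickness t. `t = r` recovers the solid circle `pi r^4 / 4`; for
#' thin walls I approaches `pi r^3 t`.
#'
#' @param r Outer radius in um.
#' @param t Wall thickness in um (0 < t <= r).
#' @return Second moment of area in um^4.
#' @export
#' @examples
#' second_moment_annulus(1.4, 0.287)
second_moment_annulus <- function(r, t) {
  if (any(!is.numeric(r)) || any(r <= 0)) stop("`r` must be positive")
  if (any(!is.numeric(t)) || any(t <= 0) || any(t > r))
    stop("`t` must satisfy 0 < t <= r")
  (pi / 4) * (r^4 - (r - t)^4)
}

#' Cell-wall Young's modulus from bending stiffness
#'
#' `E = k_b / I` with the annular second moment of area of
#' [second_moment_annulus()]. In the package's canonical units the result
#' is in MPa with no conversion factors.
#'
#' @param k_b Bending stiffness in uN um^2 (> 0).
#' @param r Outer radius in um.
#' @param t Wall thickness in um.
#' @return An object of class `wall_elasticity` with elements `E_MPa`,
#'   `I_um4`, and the echoed inputs `k_b`, `r`, `t`.
#' @export
#' @examples
#' youngs_modulus(k_b = 18.3, r = 1.4, t = 0.287)
youngs_modulus <- function(k_b, r, t) {
  if (any(!is.numeric(k_b)) || any(k_b <= 0)) stop("`k_b` must be positive")
  I <- second_moment_annulus(r, t)
  structure(list(E_MPa = k_b / I, I_um4 = I, k_b = k_b, r = r, t = t),
            class = "wall_elasticity")
}

#' @export
print.wall_elasticity <- function(x, ...) {
  cat(sprintf("Cell-wall Young's modulus: E = %.3g MPa\n", x$E_MPa))
  cat(sprintf("  (k_b = %g uN um^2, I = %.4g um^4; r = %g um, t = %g um)\n",
              x$k_b, x$I_um4, x$r, x$t))
  invisible(x)
}
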