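#' Tube-law parameters of the collapsible brachial artery
#'
#' The arterial cross-sectional area responds to transmural pressure
#' `Ptm` (internal minus external pressure, mmHg) through the nonlinear
#' tube law
#' \deqn{A(P_{tm}) = d \left[\frac{\ln(a P_{tm} + 3.3)}{\ln 3.3}\right]
#' ^{\,1 + e^{-c P_{tm}}}}
#' The log argument is normalized to its zero-transmural value, so
#' `A(0) = d` exactly: `d` is the lumen area at zero transmural pressure
#' and the bracket is the dimensionless distension state. The law is
#' monotone non-decreasing in `Ptm`; the collapse exponent
#' `E = 1 + exp(-c Ptm)` crushes the sub-unity bracket as soon as the
#' transmural pressure turns negative, so the lumen shuts over a
#' collapse band anchored just below `Ptm = 0` for any `a`, while at
#' high distension `A` grows logarithmically and the vessel stiffens.
#'
#' @param a collapse slope (mmHg^-1); controls where the log argument, and
#'   with it the lumen, vanishes under negative transmural pressure.
#' @param c collapse steepness (mmHg^-1); controls how sharply the
#'   exponent, and hence the collapse, turns on for `Ptm < 0`.
#' @param d area scale (cm); sets the overall lumen size, with `A` in cm^2.
#' @return An object of class `tube_law`.
#' @examples
#' tl <- tube_law()
#' luminal_area(c(-80, 0, 100), tl)
#' @export
tube_law <- function(a = 0.03, c = 0.1, d = 0.08) {
  stopifnot(is.numeric(a), is.numeric(c), is.numeric(d),
            length(a) == 1, length(c) == 1, length(d) == 1)
  if (!(a > 0 && c > 0 && d > 0))
    stop("tube-law parameters a, c, d must all be strictly positive")
  structure(list(a = a, c = c, d = d), class = "tube_law")
}

#' Blood properties
#'
#' @param viscosity dynamic viscosity in mmHg s. The default corresponds
#'   to 3.5 mPa s, a standard value for whole blood.
#' @param density mass density in kg/m^3 (needed by the Bramwell-Hill wave
#'   speed).
#' @return An object of class `blood_properties`.
#' @export
blood_properties <- function(viscosity = 2.63e-5, density = 1060) {
  if (!(viscosity > 0 && density > 0))
    stop("blood viscosity and density must be strictly positive")
  structure(list(viscosity = viscosity, density = density),
            class = "blood_properties")
}

#' Arm and cuff geometry
#'
#' @param arm_length heart-to-finger path length in m.
#' @param cuff_length lateral cuff length in m; the occluded arterial
#'   segment has this length, the distal segment the remainder.
#' @return An object of class `arm_geometry`.
#' @export
arm_geometry <- function(arm_length = 1, cuff_length = 0.14) {
  if (!(cuff_length > 0 && cuff_length < arm_length))
    stop("cuff_length must satisfy 0 < cuff_length < arm_length")
  structure(list(arm_length = arm_length, cuff_length = cuff_length),
            class = "arm_geometry")
}

# numeric clamps shared across the mechanics: floor on the lumen under deep
# collapse (the tube law is undefined once its log argument reaches 1) and a
# cap standing in for a fully occluding, effectively infinite resistance.
.A_MIN <- 1e-6   # cm^2
.R_MAX <- 1e9    # mmHg s/mL
.COMPLIANCE_H <- 0.01  # mmHg, central-difference step

#' Luminal cross-sectional area under the tube law
#'
#' Vectorised in `ptm`. Below the collapse point the area is clamped at a
#' tiny positive floor (`1e-6` cm^2) rather than raising, which keeps the
#' circulation ODEs finite through deep collapse.
#'
#' @param ptm transmural pressure(s), mmHg.
#' @param tube a [tube_law()] object.
#' @return Area(s) in cm^2, `>= 1e-6`.
#' @export
luminal_area <- function(ptm, tube = tube_law()) {
  stopifnot(inherits(tube, "tube_law"))
  u <- tube$a * ptm + 3.3
  A <- rep(.A_MIN, length(ptm))
  ok <- u > 1
  if (any(ok)) {
    Aok <- tube$d * (log(u[ok]) / log(3.3))^(1 + exp(-tube$c * ptm[ok]))
    Aok[!is.finite(Aok) | Aok < .A_MIN] <- .A_MIN
    A[ok] <- Aok
  }
  A
}

#' Area compliance dA/dPtm
#'
#' Central finite difference of [luminal_area()] with a fixed step of
#' 0.01 mmHg; the area is clamped inside the stencil, so the compliance
#' is exactly zero across the collapsed (flat) region and non-negative
#' everywhere (the normalized tube law is monotone).
#'
#' @inheritParams luminal_area
#' @return dA/dPtm in cm^2/mmHg, `>= 0`.
#' @export
area_compliance <- function(ptm, tube = tube_law()) {
  h <- .COMPLIANCE_H
  dA <- (luminal_area(ptm + h, tube) - luminal_area(ptm - h, tube)) / (2 * h)
  pmax(dA, 0)
}

#' Poiseuille resistance of the cuff-occluded arterial segment
#'
#' \eqn{R = 8 \eta L_{cuff} / (\pi r^4)} with the radius taken from the
#' tube law, \eqn{r = \sqrt{A/\pi}}. With pressures in mmHg, lengths in cm
#' and volumes in mL the result is in mmHg s/mL. Where the area is clamped
#' the resistance is capped at `1e9` mmHg s/mL, representing a fully
#' occluding segment without numerical overflow.
#'
#' @inheritParams luminal_area
#' @param geometry an [arm_geometry()] object (cuff length is used).
#' @param blood a [blood_properties()] object (viscosity is used).
#' @return Resistance(s) in mmHg s/mL.
#' @export
poiseuille_resistance <- function(ptm, geometry = arm_geometry(),
                                  blood = blood_properties(),
                                  tube = tube_law()) {
  A <- luminal_area(ptm, tube)
  r2 <- A / pi                      # r^2 in cm^2
  R <- 8 * blood$viscosity * (geometry$cuff_length * 100) / (pi * r2^2)
  R[A <= .A_MIN | R > .R_MAX] <- .R_MAX
  R
}

#' Pulse wave velocity from the tube law (Bramwell-Hill)
#'
#' \eqn{PWV = \sqrt{A \,(dP/dA) / \rho}} with the pressure-derivative
#' taken from [area_compliance()] and mmHg converted to Pa, valid on the
#' distension branch (`Ptm >= 0`). Below the buckling point the
#' distension-branch relation no longer describes transmission through
#' the partially collapsed segment; with `collapse_floor = TRUE`
#' (default) the wave speed there is held at its buckling-point value --
#' the knee minimum of the wave-speed curve, as observed for arteries
#' under a cuff -- until the lumen clamps shut entirely, where the pulse
#' stops transmitting (`NA`). Note the wave speed is invariant to the
#' normalization of the tube law (the scale cancels in `A dP/dA`), so
#' `PWV(100 mmHg)` is about 7 m/s at reference parameters.
#'
#' @inheritParams luminal_area
#' @param blood a [blood_properties()] object (density is used).
#' @param collapse_floor hold the sub-buckling wave speed at the knee
#'   value instead of letting the distension-branch formula fall to zero.
#' @return Wave speed(s) in m/s; `NA` where non-transmitting.
#' @export
pulse_wave_velocity <- function(ptm, tube = tube_law(),
                                blood = blood_properties(),
                                collapse_floor = TRUE) {
  A <- luminal_area(ptm, tube)
  dAdP <- area_compliance(ptm, tube)
  out <- rep(NA_real_, length(ptm))
  ok <- A > .A_MIN & dAdP > 0
  out[ok] <- sqrt(A[ok] / dAdP[ok] * 133.322 / blood$density)
  if (collapse_floor) {
    knee <- sqrt(luminal_area(0, tube) / area_compliance(0, tube) *
                   133.322 / blood$density)
    out[ptm < 0 & (is.na(out) | out < knee)] <- knee
    out[ptm < 0 & A <= .A_MIN] <- NA_real_
  }
  out
}

#' Transit time of the pulse across an arterial segment
#'
#' `length / PWV(ptm)`, reported in milliseconds. Linear in length, so
#' transit times of sub-segments at a common transmural pressure add
#' exactly.
#'
#' @inheritParams pulse_wave_velocity
#' @param length segment length in m (recycled against `ptm`).
#' @return Transit time(s) in ms; `NA` propagates from non-transmitting
#'   segments.
#' @export
segment_transit_time <- function(ptm, length, tube = tube_law(),
                                 blood = blood_properties()) {
  1000 * length / pulse_wave_velocity(ptm, tube, blood)
}

#' Tabulate the static mechanics over a transmural-pressure grid
#'
#' Convenience used by the command-line `mech` subcommand.
#'
#' @inheritParams poiseuille_resistance
#' @return A data frame with columns `ptm_mmHg`, `area_cm2`, `dA_dP`,
#'   `R_art`, `pwv_m_s`.
#' @export
mechanics_table <- function(ptm, geometry = arm_geometry(),
                            blood = blood_properties(), tube = tube_law()) {
  data.frame(ptm_mmHg = ptm,
             area_cm2 = luminal_area(ptm, tube),
             dA_dP = area_compliance(ptm, tube),
             R_art = poiseuille_resistance(ptm, geometry, blood, tube),
             pwv_m_s = pulse_wave_velocity(ptm, tube, blood))
}
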