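#' Systemic driving input
#'
#' The systemic arterial pressure proximal to the cuff is an ideal
#' sinusoid defined by heart rate, systolic and pulse pressure:
#' `MAP + (PP/2) sin(2 pi HR t / 60)` with `MAP = SBP - PP/2`. Systemic
#' venous pressure is a fixed level.
#'
#' @param sbp systolic pressure, mmHg.
#' @param pp pulse pressure, mmHg (diastolic pressure is `sbp - pp`).
#' @param hr heart rate, beats/min.
#' @param venous systemic venous pressure, mmHg.
#' @return An object of class `systemic_input`.
#' @export
systemic_input <- function(sbp = 120, pp = 40, hr = 60, venous = 10) {
  if (!(sbp > pp && pp > 0)) stop("need SBP > PP > 0")
  if (!(sbp - pp > venous && venous >= 0))
    stop("need DBP = SBP - PP > venous pressure >= 0")
  if (!(hr > 0)) stop("heart rate must be positive")
  structure(list(sbp = sbp, pp = pp, hr = hr, venous = venous,
                 dbp = sbp - pp, map = sbp - pp / 2),
            class = "systemic_input")
}

#' Cuff inflation protocol
#'
#' Cuff pressure is zero until `start`, then ramps linearly at `rate` up
#' to `max_pressure`, where it is held for `hold` seconds. The default
#' maximum, `NULL`, resolves to systemic SBP + 50 mmHg at simulation time,
#' guaranteeing full arterial occlusion; the default hold is long enough
#' for the distal pressures to settle to their common equilibrium.
#'
#' @param rate inflation rate, mmHg/s.
#' @param start inflation start time, s (output time starts at 0 after the
#'   settling pre-roll; the pre-inflation window provides baseline beats).
#' @param max_pressure target cuff pressure, mmHg, or `NULL` for SBP + 50.
#' @param hold hold duration at the maximum, s.
#' @return An object of class `cuff_protocol`.
#' @export
cuff_protocol <- function(rate = 6, start = 6, max_pressure = NULL,
                          hold = 60) {
  if (!(rate >= 0)) stop("inflation rate must be non-negative")
  if (!is.null(max_pressure) && !(max_pressure >= 0))
    stop("max_pressure must be non-negative (or NULL for SBP + 50)")
  if (!(hold >= 0)) stop("hold must be non-negative")
  if (!(start >= 0)) stop("start must be non-negative")
  structure(list(rate = rate, start = start, max_pressure = max_pressure,
                 hold = hold),
            class = "cuff_protocol")
}

#' Circuit constants of the distal-arm RC network
#'
#' @param r_systemic systemic (through-flow) resistance of the arm,
#'   mmHg s/mL.
#' @param c_art distal arterial compliance, mL/mmHg.
#' @param c_ven distal venous compliance, mL/mmHg (about 30 x arterial).
#' @param r_ven_open venous resistance with the vein open, mmHg s/mL.
#' @param collapse_threshold cuff pressure at which the vein is collapsing,
#'   mmHg; the venous resistance transitions to effectively infinite there.
#' @param collapse_width scale of the smooth collapse transition, mmHg.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(r_systemic = 100, c_art = 0.03, c_ven = 30 * 0.03,
                           r_ven_open = 10, collapse_threshold = 30,
                           collapse_width = 2) {
  vals <- c(r_systemic, c_art, c_ven, r_ven_open, collapse_threshold,
            collapse_width)
  if (!all(is.finite(vals) & vals > 0))
    stop("all circuit parameters must be finite and strictly positive")
  structure(list(r_systemic = r_systemic, c_art = c_art, c_ven = c_ven,
                 r_ven_open = r_ven_open,
                 collapse_threshold = collapse_threshold,
                 collapse_width = collapse_width),
            class = "circuit_params")
}

#' Systemic pressure waveform
#' @param t time(s), s.
#' @param input a [systemic_input()] object.
#' @return Pressure(s) in mmHg.
#' @export
systemic_pressure <- function(t, input = systemic_input()) {
  input$map + input$pp / 2 * sin(2 * pi * input$hr / 60 * t)
}

#' Cuff pressure profile
#' @param t time(s), s.
#' @param protocol a [cuff_protocol()] object; `max_pressure` must be
#'   resolved (non-`NULL`) here.
#' @return Cuff pressure(s) in mmHg.
#' @export
cuff_pressure <- function(t, protocol = cuff_protocol(max_pressure = 170)) {
  pmax_ <- protocol$max_pressure
  if (is.null(pmax_))
    stop("max_pressure is NULL; resolve it (e.g. SBP + 50) before use")
  ifelse(t < protocol$start, 0,
         pmin(protocol$rate * (t - protocol$start), pmax_))
}

#' Venous resistance under cuff compression
#'
#' Log-space sigmoid between the open value and the occlusion cap
#' (`1e9` mmHg s/mL), centred at the collapse threshold: the vein is open
#' well below it and effectively infinite well above.
#'
#' @param p_cuff cuff pressure(s), mmHg.
#' @param circuit a [circuit_params()] object.
#' @return Resistance(s) in mmHg s/mL.
#' @export
venous_resistance <- function(p_cuff, circuit = circuit_params()) {
  s <- 1 / (1 + exp(-(p_cuff - circuit$collapse_threshold) /
                      circuit$collapse_width))
  exp(log(circuit$r_ven_open) + (log(.R_MAX) - log(circuit$r_ven_open)) * s)
}

#' Closed-form equilibrium pressure after full occlusion
#'
#' Once both artery and vein are occluded no charge leaves the two
#' capacitors, so they relax to the compliance-weighted mean
#' \eqn{(C_{art} P_a + C_{ven} P_v) / (C_{art} + C_{ven})} of the
#' pressures at occlusion. Used as an independent conservation check on
#' the simulated equilibrium.
#'
#' @param p_art,p_ven distal arterial and venous pressure at occlusion,
#'   mmHg.
#' @param circuit a [circuit_params()] object.
#' @return Equilibrium pressure, mmHg.
#' @export
equilibrium_pressure <- function(p_art, p_ven, circuit = circuit_params()) {
  (circuit$c_art * p_art + circuit$c_ven * p_ven) /
    (circuit$c_art + circuit$c_ven)
}

#' Simulate one cuff inflation of the distal-arm circulation
#'
#' Fixed-step integration (explicit Euler by default, classical RK4
#' optionally) of the two-compartment circuit. The brachial resistance is
#' re-evaluated every step at the instantaneous transmural pressure of
#' the occluded segment (`ptm_reference` selects the arterial pressure
#' used), and the venous resistance at the instantaneous cuff pressure.
#' The state is initialised at systemic MAP /
#' venous pressure and integrated through a discarded pre-roll before
#' output time zero.
#'
#' @param input a [systemic_input()] object.
#' @param protocol a [cuff_protocol()] object; a `NULL` `max_pressure`
#'   resolves to `input$sbp + 50`.
#' @param circuit a [circuit_params()] object.
#' @param geometry an [arm_geometry()] object.
#' @param tube a [tube_law()] object.
#' @param blood a [blood_properties()] object.
#' @param dt integration step, s; must be `<= 1e-3`.
#' @param pre_roll settling time before output starts, s.
#' @param method `"euler"` or `"rk4"`.
#' @param ptm_reference which arterial pressure defines the transmural
#'   pressure of the occluded segment: `"proximal"` (default; systemic
#'   pressure minus cuff pressure -- the segment acts as a
#'   pressure-gated valve driven by the upstream pulse, the vascular
#'   waterfall of a collapsible tube), `"midpoint"` (mean of systemic
#'   and distal arterial pressure minus cuff), or `"distal"` (distal
#'   arterial pressure minus cuff; this couples the valve to the
#'   downstream state and chokes inflow through a falling distal
#'   pressure). See the methods vignette.
#' @return An object of class `arm_sim`: the time-gridded pressures
#'   (`time`, `p_art_sys`, `p_cuff`, `p_art_distal`, `p_ven_distal`), the
#'   resolved parameter objects, and scalars `p_end`, `slope_end`,
#'   `t_occlusion`, `t_end` used by the metric extraction.
#' @examples
#' sim <- simulate_arm(dt = 1e-3, pre_roll = 5)
#' print(sim)
#' @export
simulate_arm <- function(input = systemic_input(),
                         protocol = cuff_protocol(),
                         circuit = circuit_params(),
                         geometry = arm_geometry(),
                         tube = tube_law(),
                         blood = blood_properties(),
                         dt = 5e-4, pre_roll = 10,
                         method = c("euler", "rk4"),
                         ptm_reference = c("proximal", "midpoint",
                                           "distal")) {
  method <- match.arg(method)
  ptm_reference <- match.arg(ptm_reference)
  stopifnot(inherits(input, "systemic_input"),
            inherits(protocol, "cuff_protocol"),
            inherits(circuit, "circuit_params"),
            inherits(geometry, "arm_geometry"),
            inherits(tube, "tube_law"),
            inherits(blood, "blood_properties"))
  if (!(dt > 0 && dt <= 1e-3))
    stop("dt must be positive and at most 1e-3 s")
  protocol <- resolve_protocol(protocol, input)
  raw <- .sim_core(sim_pars(input, protocol, circuit, geometry, tube, blood,
                            pre_roll, method, ptm_reference),
                   dt, TRUE)
  structure(c(raw$series,
              list(dt = dt, input = input, protocol = protocol,
                   circuit = circuit, geometry = geometry, tube = tube,
                   blood = blood, pre_roll = pre_roll, method = method,
                   p_end = raw$p_end, pv_end = raw$pv_end,
                   slope_end = raw$slope_end, pulse_end = raw$pulse_end,
                   t_end = raw$t_end,
                   t_occlusion = raw$t_occlusion,
                   ptm_reference = ptm_reference,
                   beats_cpp = raw$beats)),
            class = "arm_sim")
}

resolve_protocol <- function(protocol, input) {
  if (is.null(protocol$max_pressure))
    protocol$max_pressure <- input$sbp + 50
  protocol
}

sim_pars <- function(input, protocol, circuit, geometry, tube, blood,
                     pre_roll, method, ptm_reference = "proximal") {
  list(a = tube$a, c = tube$c, d = tube$d,
       sbp = input$sbp, pp = input$pp, hr = input$hr,
       pven_sys = input$venous,
       rate = protocol$rate, t_start = protocol$start,
       p_max = protocol$max_pressure, hold = protocol$hold,
       r_sys = circuit$r_systemic, c_art = circuit$c_art,
       c_ven = circuit$c_ven, r_ven_open = circuit$r_ven_open,
       ven_thresh = circuit$collapse_threshold,
       ven_width = circuit$collapse_width,
       arm_len = geometry$arm_length, cuff_len = geometry$cuff_length,
       eta = blood$viscosity, a_min = .A_MIN, r_max = .R_MAX,
       pre_roll = pre_roll, method = if (method == "euler") 0L else 1L,
       ptm_mode = switch(ptm_reference, proximal = 0L, midpoint = 1L,
                         distal = 2L))
}

#' Effective arterial occlusion time
#'
#' First time at which the occluded segment's lumen is clamped shut for a
#' full cardiac period (no inflow at any phase of the beat); `NA` if flow
#' never fully stops. This is the moment from which the distal circuit is
#' charge-conserving and relaxes exponentially to the equilibrium
#' pressure.
#'
#' @param sim an [simulate_arm()] result.
#' @return Time in s, or `NA`.
#' @export
occlusion_time <- function(sim) {
  stopifnot(inherits(sim, "arm_sim"))
  ptm <- switch(sim$ptm_reference,
                midpoint = (sim$p_art_sys + sim$p_art_distal) / 2 -
                  sim$p_cuff,
                distal = sim$p_art_distal - sim$p_cuff,
                sim$p_art_sys - sim$p_cuff)
  open <- luminal_area(ptm, sim$tube) > .A_MIN
  t_beat <- 60 / sim$input$hr
  w <- as.integer(round(t_beat / sim$dt))
  shut <- which(!open)
  if (!length(shut)) return(NA_real_)
  # first shut sample followed by a full beat of shut samples
  run <- rle(open)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  i <- which(!run$values & run$lengths >= w)[1]
  if (is.na(i)) return(NA_real_)
  sim$time[starts[i]]
}

#' @export
print.arm_sim <- function(x, ...) {
  cat("Distal-arm cuff inflation simulation\n")
  cat(sprintf("  systemic BP %g/%g mmHg, HR %g bpm, venous %g mmHg\n",
              x$input$sbp, x$input$dbp, x$input$hr, x$input$venous))
  cat(sprintf("  cuff: %g mmHg/s from t = %g s to %g mmHg, hold %g s\n",
              x$protocol$rate, x$protocol$start, x$protocol$max_pressure,
              x$protocol$hold))
  cat(sprintf("  %d samples at dt = %g ms (%s), t in [0, %.1f] s\n",
              length(x$time), 1000 * x$dt, x$method, x$t_end))
  cat(sprintf("  distal pressure at hold end: %.2f mmHg (dP/dt %.2g mmHg/s)\n",
              x$p_end, x$slope_end))
  invisible(x)
}

#' @export
as.data.frame.arm_sim <- function(x, ...) {
  data.frame(time = x$time, p_art_sys = x$p_art_sys, p_cuff = x$p_cuff,
             p_art_distal = x$p_art_distal, p_ven_distal = x$p_ven_distal)
}

#' @export
summary.arm_sim <- function(object, ...) {
  x <- object
  i_col <- which(x$p_cuff >= x$circuit$collapse_threshold)[1]
  out <- list(
    baseline_map = mean(x$p_art_distal[x$time < x$protocol$start]),
    venous_collapse_t = if (length(i_col)) x$time[i_col] else NA_real_,
    t_occlusion = x$t_occlusion,
    p_eq = x$p_end, slope_end = x$slope_end,
    max_p_ven = max(x$p_ven_distal))
  class(out) <- "summary.arm_sim"
  out
}

#' @export
print.summary.arm_sim <- function(x, ...) {
  cat(sprintf("baseline distal MAP     %8.2f mmHg\n", x$baseline_map))
  cat(sprintf("venous collapse at t =  %8.2f s\n", x$venous_collapse_t))
  cat(sprintf("arterial occlusion t =  %8.2f s\n", x$t_occlusion))
  cat(sprintf("max distal venous P     %8.2f mmHg\n", x$max_p_ven))
  cat(sprintf("equilibrium pressure    %8.2f mmHg (dP/dt %.2g mmHg/s)\n",
              x$p_eq, x$slope_end))
  invisible(x)
}

#' @export
plot.arm_sim <- function(x, thin = 20L, ...) {
  i <- seq(1, length(x$time), by = thin)
  matplot(x$time[i],
          cbind(x$p_art_sys[i], x$p_cuff[i], x$p_art_distal[i],
                x$p_ven_distal[i]),
          type = "l", lty = 1, col = c("gray60", "black", "firebrick",
                                       "steelblue"),
          xlab = "time (s)", ylab = "pressure (mmHg)", ...)
  legend("topleft", bty = "n", lty = 1,
         col = c("gray60", "black", "firebrick", "steelblue"),
         legend = c("systemic", "cuff", "distal arterial", "distal venous"))
  invisible(x)
}
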