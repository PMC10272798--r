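# Per-beat segmentation, transit-time series, and the six response metrics
# of one simulated inflation. The workhorses operate on plain beat tables
# so the vectorised batch runner of the sensitivity analysis can share them
# with the single-run path.

.METRIC_COLS <- c("max_dptt_distal", "max_dpat_total", "max_dmap", "p_eq",
                  "max_ddbp", "dptt_onset")
.METRIC_LABELS <- c("max|dPTT_distal|", "max|dPAT_total|", "max|dMAP|",
                    "P_eq", "max|dDBP|", "dPTT_onset")
.N_BASELINE_BEATS <- 5L
.ONSET_EPS_MS <- 0.5       # on the distal PTT drop per reference distal path
.ONSET_SUSTAIN <- 3L
.ONSET_MAP_EPS <- 0.5
.REF_DISTAL_LENGTH <- 0.86 # m, reference arm minus reference cuff
.PEQ_SLOPE_TOL <- 0.01   # mmHg/s convergence guard on P_eq
.PEQ_PULSE_TOL <- 0.1    # mmHg residual pulsation allowed at hold end

#' Segment a simulation into beats
#'
#' Beats are consecutive windows of one cardiac period, aligned to the
#' troughs of the systemic sinusoid; per-beat distal SBP/DBP are the
#' window maximum/minimum of the distal arterial pressure and MAP its
#' window mean (the driving input is an ideal sinusoid, so the beat mean
#' is the time-average MAP).
#'
#' @param sim an [simulate_arm()] result.
#' @return A `beat_series` data frame: `beat`, `t_start` (s), distal
#'   `sbp`, `dbp`, `map` (mmHg), systemic `sys_dbp` (mmHg), beat-mean
#'   cuff pressure `p_cuff` (mmHg), and `is_baseline` (window entirely
#'   before inflation start).
#' @export
segment_beats <- function(sim) {
  stopifnot(inherits(sim, "arm_sim"))
  t_beat <- 60 / sim$input$hr
  off <- 0.75 * t_beat
  n_beat <- max(0L, floor((sim$t_end - off) / t_beat))
  if (n_beat < 2) stop("simulation covers fewer than 2 full beats")
  k <- floor((sim$time - off) / t_beat)
  keep <- k >= 0 & k < n_beat
  kf <- factor(k[keep], levels = 0:(n_beat - 1))
  pa <- sim$p_art_distal[keep]
  beats <- data.frame(
    beat = seq_len(n_beat),
    t_start = off + (0:(n_beat - 1)) * t_beat,
    sbp = as.numeric(tapply(pa, kf, max)),
    dbp = as.numeric(tapply(pa, kf, min)),
    map = as.numeric(tapply(pa, kf, mean)),
    sys_dbp = sim$input$dbp,
    p_cuff = as.numeric(tapply(sim$p_cuff[keep], kf, mean)))
  beats$is_baseline <- beats$t_start + t_beat <= sim$protocol$start
  class(beats) <- c("beat_series", "data.frame")
  beats
}

# beat table from the accumulators that the compiled core maintains; same
# definitions as segment_beats() on the stored series.
beats_from_core <- function(core, input, protocol) {
  b <- core$beats
  t_beat <- 60 / input$hr
  beats <- data.frame(beat = seq_along(b$t_start), t_start = b$t_start,
                      sbp = b$sbp, dbp = b$dbp, map = b$map,
                      sys_dbp = input$dbp, p_cuff = b$p_cuff)
  beats$is_baseline <- beats$t_start + t_beat <= protocol$start
  class(beats) <- c("beat_series", "data.frame")
  beats
}

#' Per-beat transit-time changes during inflation
#'
#' Clinical fiducials are waveform feet, so all transit times are
#' evaluated at per-beat diastolic pressures. For each beat the cuff
#' segment travels at the wave speed of the tube law at
#' `mean(systemic DBP, distal DBP) - P_cuff` over the cuff length, and the
#' distal segment at the wave speed at the distal DBP over the remaining
#' arm length. Changes are referenced to the mean of the last five
#' pre-inflation beats; total pulse-arrival-time change is the exact sum
#' of the two components (the pre-ejection period is constant under cuff
#' inflation and cancels in the difference). Beats whose cuff segment no
#' longer transmits a pulse (cuff pressure at or above systemic SBP, or
#' tube law collapsed at the cuff evaluation pressure) are flagged
#' non-transmitting: their `dptt_cuff_ms` and `dpat_total_ms` are `NA`
#' (nothing arrives at the finger), while `dptt_distal_ms`, a
#' model-internal decomposition, stays defined as long as the distal
#' segment itself transmits.
#'
#' @param sim an [simulate_arm()] result.
#' @param beats a [segment_beats()] table (computed if missing).
#' @param tube tube law used by the transit-time stage. Defaults to the
#'   law the simulation ran with; the sensitivity analysis instead fixes
#'   it at the reference constants, emulating a measurement chain whose
#'   wave-speed calibration does not follow the sampled vessel (see
#'   [run_model_batch()] and the methods vignette).
#' @return A `ptt_series` data frame: `beat`, absolute transit times
#'   `t_cuff_ms`, `t_distal_ms`, changes `dptt_cuff_ms`, `dptt_distal_ms`,
#'   `dpat_total_ms`, and `transmitting`.
#' @export
ptt_series <- function(sim, beats = segment_beats(sim), tube = sim$tube) {
  stopifnot(inherits(sim, "arm_sim"))
  ptt_from_beats(beats, sim$geometry, tube, sim$blood, sim$input)
}

ptt_from_beats <- function(beats, geometry, tube, blood, input) {
  ptm_cuff <- (beats$sys_dbp + beats$dbp) / 2 - beats$p_cuff
  t_cuff <- segment_transit_time(ptm_cuff, geometry$cuff_length, tube, blood)
  t_dist <- segment_transit_time(beats$dbp,
                                 geometry$arm_length - geometry$cuff_length,
                                 tube, blood)
  # pulses stop reaching the finger once the cuff pressure exceeds the
  # systemic systolic pressure (or the lumen clamps shut at the foot's
  # evaluation pressure, whichever comes first)
  transmitting <- beats$p_cuff < input$sbp &
    is.finite(t_cuff) & is.finite(t_dist)
  ib <- which(beats$is_baseline)
  if (!length(ib)) stop("no pre-inflation baseline beats available")
  ib <- utils::tail(ib, .N_BASELINE_BEATS)
  base_cuff <- mean(t_cuff[ib])
  base_dist <- mean(t_dist[ib])
  if (!is.finite(base_cuff) || !is.finite(base_dist))
    stop("baseline beats are non-transmitting; check parameters")
  out <- data.frame(beat = beats$beat,
                    t_cuff_ms = t_cuff, t_distal_ms = t_dist,
                    dptt_cuff_ms = t_cuff - base_cuff,
                    dptt_distal_ms = t_dist - base_dist,
                    transmitting = transmitting)
  out$dpat_total_ms <- out$dptt_cuff_ms + out$dptt_distal_ms
  out$dptt_cuff_ms[!transmitting] <- NA_real_
  out$dpat_total_ms[!transmitting] <- NA_real_
  out$dptt_distal_ms[!is.finite(t_dist)] <- NA_real_
  class(out) <- c("ptt_series", "data.frame")
  out
}

#' Detect the onset of the distal filling effect
#'
#' First beat at which the distal transit-time change falls below
#' `-eps_ms` and stays below it for `sustain` consecutive beats. The
#' drop is normalized to the reference distal path length (0.86 m)
#' before thresholding, so the detection sensitivity does not depend on
#' the cuff length splitting the arm; the threshold itself is set above
#' the slow venous-creep contribution so that detection keys on the
#' fast distal pressurization once the cuff pinches the artery.
#'
#' @param beats a [segment_beats()] table.
#' @param ptt the matching [ptt_series()] table.
#' @param eps_ms detection threshold on the distal PTT drop per
#'   reference distal length, ms.
#' @param sustain number of consecutive beats required.
#' @param distal_length actual distal path length in m used to normalize
#'   the drop.
#' @return A list with `beat` (index, `NA` if never triggered), `t_start`
#'   and `p_cuff` of the onset beat.
#' @export
detect_onset <- function(beats, ptt, eps_ms = .ONSET_EPS_MS,
                         sustain = .ONSET_SUSTAIN,
                         distal_length = .REF_DISTAL_LENGTH) {
  stopifnot(nrow(beats) == nrow(ptt))
  dnorm_ <- ptt$dptt_distal_ms * (.REF_DISTAL_LENGTH / distal_length)
  below <- !is.na(dnorm_) & dnorm_ < -eps_ms
  idx <- onset_index(below, sustain)
  if (is.na(idx))
    return(list(beat = NA_integer_, t_start = NA_real_, p_cuff = NA_real_))
  # refine the crossing below the beat grid: linear interpolation of the
  # drop between the last beat above threshold and the onset beat
  t_on <- beats$t_start[idx]
  p_on <- beats$p_cuff[idx]
  if (idx > 1 && !is.na(dnorm_[idx - 1]) && dnorm_[idx] < dnorm_[idx - 1]) {
    frac <- (-eps_ms - dnorm_[idx - 1]) / (dnorm_[idx] - dnorm_[idx - 1])
    frac <- min(max(frac, 0), 1)
    t_on <- beats$t_start[idx - 1] +
      frac * (beats$t_start[idx] - beats$t_start[idx - 1])
    p_on <- beats$p_cuff[idx - 1] +
      frac * (beats$p_cuff[idx] - beats$p_cuff[idx - 1])
  }
  list(beat = beats$beat[idx], t_start = t_on, p_cuff = p_on)
}

onset_index <- function(below, sustain) {
  if (sustain <= 1) return(which(below)[1])
  run <- 0L
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run == sustain) return(i - sustain + 1L)
  }
  NA_integer_
}

#' Extract the six response metrics of one inflation
#'
#' The scalar summaries of the distal filling effect:
#' \describe{
#'   \item{`max_dptt_distal`}{largest per-beat drop of the distal transit
#'     time below its pre-inflation baseline, ms.}
#'   \item{`max_dpat_total`}{largest absolute total PAT change over
#'     transmitting beats, ms.}
#'   \item{`max_dmap`}{maximum beat-averaged distal MAP minus its
#'     baseline, mmHg.}
#'   \item{`p_eq`}{distal arterial pressure at the end of the occlusion
#'     hold, mmHg, guarded by a convergence check `|dP/dt| < 0.01`
#'     mmHg/s over the final second.}
#'   \item{`max_ddbp`}{maximum per-beat distal diastolic pressure minus
#'     its baseline, mmHg.}
#'   \item{`dptt_onset`}{systemic MAP minus cuff pressure at the onset
#'     beat of the distal PTT decrease, mmHg.}
#' }
#'
#' @param sim an [simulate_arm()] result whose protocol reaches full
#'   occlusion and holds it long enough to settle.
#' @param beats,ptt precomputed tables (computed if missing).
#' @return An object of class `response_metrics`.
#' @export
response_metrics <- function(sim, beats = segment_beats(sim),
                             ptt = ptt_series(sim, beats)) {
  stopifnot(inherits(sim, "arm_sim"))
  metrics_from_beats(beats, ptt, sim$p_end, sim$slope_end, sim$input,
                     sim$geometry$arm_length - sim$geometry$cuff_length,
                     sim$pulse_end)
}

metrics_from_beats <- function(beats, ptt, p_end, slope_end, input,
                               distal_length = .REF_DISTAL_LENGTH,
                               pulse_end = 0) {
  ib <- utils::tail(which(beats$is_baseline), .N_BASELINE_BEATS)
  if (!length(ib)) stop("no pre-inflation baseline beats available")
  base_map <- mean(beats$map[ib])
  base_dbp <- mean(beats$dbp[ib])
  if (!is.finite(p_end) || abs(slope_end) >= .PEQ_SLOPE_TOL ||
        pulse_end >= .PEQ_PULSE_TOL)
    stop(sprintf(paste("equilibrium pressure did not converge",
                       "(|dP/dt| = %.3g mmHg/s, residual pulsation %.3g",
                       "mmHg at hold end); extend the hold or check that",
                       "the protocol reaches full occlusion"),
                 abs(slope_end), pulse_end))
  onset <- detect_onset(beats, ptt, distal_length = distal_length)
  m <- list(
    max_dptt_distal = max(-ptt$dptt_distal_ms, 0, na.rm = TRUE),
    max_dpat_total = max(abs(ptt$dpat_total_ms), 0, na.rm = TRUE),
    max_dmap = max(beats$map) - base_map,
    p_eq = p_end,
    max_ddbp = max(beats$dbp) - base_dbp,
    dptt_onset = if (is.na(onset$beat)) NA_real_ else
      input$map - onset$p_cuff)
  structure(c(m, list(onset = onset, baseline_map = base_map,
                      baseline_dbp = base_dbp)),
            class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat("Cuff-inflation response metrics\n")
  v <- unlist(x[.METRIC_COLS])
  units <- c("ms", "ms", "mmHg", "mmHg", "mmHg", "mmHg")
  for (i in seq_along(v))
    cat(sprintf("  %-18s %9.3f %s\n", .METRIC_LABELS[i], v[i], units[i]))
  if (!is.na(x$onset$beat))
    cat(sprintf("  onset at beat %d (t = %.2f s, P_cuff = %.1f mmHg)\n",
                x$onset$beat, x$onset$t_start, x$onset$p_cuff))
  else cat("  no onset detected\n")
  invisible(x)
}

#' @export
as.data.frame.response_metrics <- function(x, ...) {
  as.data.frame(x[.METRIC_COLS])
}

#' Beats, transit times and metrics of one simulation in a single call
#'
#' @param sim an [simulate_arm()] result.
#' @return A list with elements `beats`, `ptt`, `metrics`.
#' @export
arm_metrics <- function(sim) {
  beats <- segment_beats(sim)
  ptt <- ptt_series(sim, beats)
  list(beats = beats, ptt = ptt,
       metrics = response_metrics(sim, beats, ptt))
}
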