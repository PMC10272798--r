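# Synthetic measurement-chain emulation: ECG/ABP/PPG-like traces from a
# simulated inflation, fiducial detection (R-peaks, pulse feet by
# intersecting tangents) and beat-to-beat interval measurement. The point
# is to exercise the interval-measurement pipeline against known inserted
# delays, not morphological realism.

.FS_ECG <- 500   # Hz
.FS_PPG <- 125   # Hz, also ABP
.CONDUCTION_DELAY <- 0.10  # s, heart-to-wrist offset of the ABP site

#' Synthesize an ECG/ABP/PPG-like recording from a simulation
#'
#' ECG is a train of narrow unit-amplitude R waves at the beat starts
#' (500 Hz). ABP is the distal arterial pressure delayed by a constant
#' conduction offset (125 Hz). PPG is a low-pass-filtered, normalized
#' copy of the arterial pulse delayed additionally by the per-beat total
#' transit time from the PTT table, so the inserted ECG-to-PPG delay per
#' beat is known exactly; beats whose cuff segment no longer transmits
#' produce no PPG pulse (the trace holds its last level). White noise of
#' standard deviation `noise_sd` (relative to each channel's pulse
#' amplitude) is added on top.
#'
#' @param sim an [simulate_arm()] result.
#' @param ptt matching [ptt_series()] (computed if missing).
#' @param noise_sd relative noise level (fraction of pulse amplitude).
#' @param seed integer seed for the noise.
#' @return An object of class `synthetic_recording`: per channel a data
#'   frame `t`, `value`; plus `truth` (per-beat R-peak times, inserted
#'   delays in ms, transmitting flags) and the sampling rates.
#' @export
synthesize_recording <- function(sim, ptt = NULL, noise_sd = 0,
                                 seed = NULL) {
  stopifnot(inherits(sim, "arm_sim"), noise_sd >= 0)
  beats <- segment_beats(sim)
  if (is.null(ptt)) ptt <- ptt_series(sim, beats)
  t_end <- max(sim$time)
  te <- seq(0, t_end, by = 1 / .FS_ECG)
  tp <- seq(0, t_end, by = 1 / .FS_PPG)

  # ECG: triangular R wave, 20 ms wide, at each beat start
  ecg <- numeric(length(te))
  for (tb in beats$t_start) {
    w <- abs(te - tb) <= 0.01
    ecg[w] <- pmax(ecg[w], 1 - abs(te[w] - tb) / 0.01)
  }

  abp <- approx(sim$time + .CONDUCTION_DELAY, sim$p_art_distal, xout = tp,
                rule = 2)$y

  # per-beat total ECG->PPG delay: conduction offset + cuff and distal
  # transit; NA (non-transmitting) beats carry no pulse
  delay_ms <- ptt$t_cuff_ms + ptt$t_distal_ms
  delay_ms[!ptt$transmitting] <- NA
  # piecewise-linear delay anchored at the beat starts, so the inserted
  # delay evolves smoothly across each pulse instead of stepping at the
  # foot itself
  ok_d <- which(!is.na(delay_ms))
  delay_at <- function(tt) {
    if (length(ok_d) < 2) return(rep(NA_real_, length(tt)))
    out <- approx(beats$t_start[ok_d], delay_ms[ok_d], xout = tt,
                  rule = 2)$y
    last_ok <- max(beats$t_start[ok_d]) + 60 / sim$input$hr
    out[tt > last_ok] <- NA
    out
  }
  # smoothed, normalized pulse shape
  ppg_src <- stats::filter(sim$p_art_distal, rep(1 / 81, 81), sides = 2)
  ppg_src[is.na(ppg_src)] <- sim$p_art_distal[is.na(ppg_src)]
  rng <- range(sim$p_art_distal[sim$time < sim$protocol$start])
  ppg_shape <- (as.numeric(ppg_src) - rng[1]) / diff(rng)
  d_tp <- delay_at(tp - .CONDUCTION_DELAY)
  ppg <- approx(sim$time, ppg_shape,
                xout = tp - .CONDUCTION_DELAY - d_tp / 1000, rule = 2)$y
  # hold last level through non-transmitting stretches
  if (anyNA(ppg)) {
    idx <- cummax(ifelse(is.na(ppg), 0L, seq_along(ppg)))
    ppg[idx > 0] <- ppg[idx[idx > 0]]
    ppg[idx == 0] <- ppg[which(idx > 0)[1]]
  }

  if (noise_sd > 0) {
    nz <- with_seed(if (is.null(seed)) 1L else seed,
                    list(e = rnorm(length(ecg)), a = rnorm(length(abp)),
                         p = rnorm(length(ppg))))
    ecg <- ecg + noise_sd * 1 * nz$e
    abp <- abp + noise_sd * diff(rng) * nz$a
    ppg <- ppg + noise_sd * 1 * nz$p
  }

  truth <- data.frame(beat = beats$beat, r_peak_t = beats$t_start,
                      delay_ms = delay_ms,
                      transmitting = ptt$transmitting)
  structure(list(ecg = data.frame(t = te, value = ecg),
                 abp = data.frame(t = tp, value = abp),
                 ppg = data.frame(t = tp, value = ppg),
                 truth = truth, fs_ecg = .FS_ECG, fs_ppg = .FS_PPG,
                 conduction_delay = .CONDUCTION_DELAY,
                 noise_sd = noise_sd, hr = sim$input$hr),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "Synthetic recording: %.1f s, ECG %d Hz, ABP/PPG %d Hz, noise %.3g\n",
    max(x$ecg$t), x$fs_ecg, x$fs_ppg, x$noise_sd))
  cat(sprintf("  %d beats (%d transmitting)\n", nrow(x$truth),
              sum(x$truth$transmitting)))
  invisible(x)
}

# local maxima above an adaptive threshold, refractory-separated
find_peaks <- function(t, v, min_gap, thr_frac = 0.5) {
  if (!length(v) || max(v) <= 0) return(numeric(0))
  thr <- thr_frac * stats::quantile(v[v > 0.05 * max(v)], 0.95)
  peaks <- numeric(0)
  for (i in which(v > thr)) {
    lo <- max(1, i - 2)
    hi <- min(length(v), i + 2)
    if (v[i] == max(v[lo:hi])) {
      if (!length(peaks) || t[i] - peaks[length(peaks)] > min_gap)
        peaks <- c(peaks, t[i])
    }
  }
  peaks
}

# foot of one pulse by intersecting tangents: the max-upslope tangent
# meets the horizontal line through the pre-upstroke minimum; the window
# is smoothed first so the tangent is not picked off noise spikes
foot_intersect <- function(t, v, smooth_k = 5L) {
  if (length(t) < smooth_k + 4) return(NA_real_)
  if (smooth_k > 1) {
    vs <- stats::filter(v, rep(1 / smooth_k, smooth_k), sides = 2)
    v <- ifelse(is.na(vs), v, as.numeric(vs))
  }
  imax <- which.max(v)
  if (imax < 4) return(NA_real_)
  if (v[imax] - min(v) < 4 * stats::mad(diff(v)))
    return(NA_real_)   # no discernible pulse in the window
  imin <- which.min(v[1:imax])
  if (imax - imin < 5) return(NA_real_)
  # max-slope point on the upstroke, from a smoothed derivative; the
  # tangent itself is a local linear fit around that point so a single
  # noisy sample cannot steer it
  dv <- diff(v[imin:imax])
  dvs <- stats::filter(dv, rep(1 / 5, 5), sides = 2)
  dvs[is.na(dvs)] <- dv[is.na(dvs)]
  i <- imin + which.max(as.numeric(dvs)) - 1L
  lo <- max(imin, i - 4L)
  hi <- min(imax, i + 4L)
  cf <- stats::coef(stats::lm.fit(cbind(1, t[lo:hi]), v[lo:hi]))
  slope <- cf[2]
  if (!is.finite(slope) || slope <= 0) return(NA_real_)
  # baseline level: mean around the pre-upstroke minimum
  b0 <- mean(v[max(1, imin - 3):min(imax, imin + 3)])
  tf <- (b0 - cf[1]) / slope
  if (tf < t[1] - 0.2 || tf > t[length(t)]) NA_real_ else tf
}

#' Detect fiducials in a synthetic recording
#'
#' R-peaks by thresholded local-maximum search on the ECG; pulse feet on
#' ABP and PPG by the intersecting-tangent method applied beat by beat
#' (search window anchored on each R-peak). Beats with no detectable
#' foot are reported as `NA`.
#'
#' @param rec a [synthesize_recording()] result.
#' @return A list with `r_peaks` (times, s) and data frames `abp`,
#'   `ppg` of per-beat foot times aligned to the R-peaks.
#' @export
detect_fiducials <- function(rec) {
  stopifnot(inherits(rec, "synthetic_recording"))
  t_beat <- 60 / rec$hr
  r_peaks <- find_peaks(rec$ecg$t, rec$ecg$value, min_gap = 0.6 * t_beat)
  feet <- function(ch, lo_off, hi_off) {
    vapply(r_peaks, function(tr) {
      w <- ch$t >= tr + lo_off & ch$t <= tr + hi_off
      foot_intersect(ch$t[w], ch$value[w])
    }, numeric(1))
  }
  # feet fall between ~the conduction delay and most of a beat later;
  # the window stops short of the next pulse's peak
  list(r_peaks = r_peaks,
       abp = data.frame(r_peak = r_peaks,
                        foot = feet(rec$abp, 0.02, 0.9 * t_beat)),
       ppg = data.frame(r_peak = r_peaks,
                        foot = feet(rec$ppg, 0.02, 0.9 * t_beat)))
}

#' Beat-to-beat interval changes from detected fiducials
#'
#' Per matched beat, the pulse arrival time `PAT` (R-peak to PPG foot)
#' and the transit time `PTT` (ABP foot to PPG foot), each referenced to
#' the mean over the first `baseline_beats` beats; undetected beats
#' propagate as `NA` gaps.
#'
#' @param fiducials a [detect_fiducials()] result.
#' @param baseline_beats number of initial beats defining the baseline.
#' @return Data frame `beat`, `t`, `pat_ms`, `ptt_ms`, `dpat_ms`,
#'   `dptt_ms`.
#' @export
measure_intervals <- function(fiducials, baseline_beats = 5) {
  f <- fiducials
  if (nrow(f$abp) != nrow(f$ppg))
    stop("unmatched channel lengths in fiducial table")
  pat <- 1000 * (f$ppg$foot - f$r_peaks)
  ptt <- 1000 * (f$ppg$foot - f$abp$foot)
  nb <- min(baseline_beats, length(pat))
  base_pat <- mean(pat[seq_len(nb)], na.rm = TRUE)
  base_ptt <- mean(ptt[seq_len(nb)], na.rm = TRUE)
  data.frame(beat = seq_along(pat), t = f$r_peaks,
             pat_ms = pat, ptt_ms = ptt,
             dpat_ms = pat - base_pat, dptt_ms = ptt - base_ptt)
}
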