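# Beat segmentation, the per-beat transit-time series, onset detection
# and the six response metrics.

test_that("beats are one cardiac period each with ordered pressure stats", {
  b <- ref_parts()$beats
  sim <- ref_parts()$sim
  expect_equal(unique(round(diff(b$t_start), 9)), 1)
  expect_equal(nrow(b), floor((sim$t_end - 0.75) / 1))
  expect_true(all(b$dbp <= b$map & b$map <= b$sbp))
  expect_equal(sum(b$is_baseline), 5)
})

test_that("beat statistics are stationary without a perturbation", {
  sim <- simulate_arm(protocol = cuff_protocol(max_pressure = 0, hold = 24),
                      dt = 1e-3)
  b <- segment_beats(sim)
  late <- b$t_start > 12
  expect_lt(diff(range(b$map[late])), 0.2)
  expect_lt(diff(range(b$dbp[late])), 0.2)
})

test_that("compiled per-beat accumulators agree with R segmentation", {
  sim <- ref_sim()
  b_r <- segment_beats(sim)
  b_c <- cuffsim:::beats_from_core(list(beats = sim$beats_cpp), sim$input,
                                   sim$protocol)
  expect_equal(nrow(b_r), nrow(b_c))
  for (col in c("t_start", "sbp", "dbp", "map", "p_cuff"))
    expect_equal(b_r[[col]], b_c[[col]], tolerance = 1e-8)
})

test_that("transit-time changes are zero at baseline and decompose exactly", {
  p <- ref_parts()$ptt
  b <- ref_parts()$beats
  base <- which(b$is_baseline)
  expect_true(all(abs(p$dptt_cuff_ms[base]) < 0.01))
  expect_true(all(abs(p$dptt_distal_ms[base]) < 0.01))
  tr <- which(p$transmitting)
  expect_identical(p$dpat_total_ms[tr],
                   p$dptt_cuff_ms[tr] + p$dptt_distal_ms[tr])
})

test_that("the distal PTT falls while distal diastolic pressure is elevated", {
  b <- ref_parts()$beats
  p <- ref_parts()$ptt
  elevated <- which(b$dbp > b$sys_dbp + 2 & !is.na(p$dptt_distal_ms))
  expect_gt(length(elevated), 2)
  expect_true(all(p$dptt_distal_ms[elevated] < 0))
})

test_that("onset detection triggers on a sustained constructed drop", {
  mk <- function(drop) {
    beats <- data.frame(beat = 1:20, t_start = 0:19, p_cuff = (0:19) * 6,
                        is_baseline = c(rep(TRUE, 5), rep(FALSE, 15)))
    ptt <- data.frame(dptt_distal_ms = drop)
    list(beats = beats, ptt = ptt)
  }
  # sustained crossing at beat 8
  d <- c(rep(0, 7), rep(-1, 13))
  f <- mk(d)
  on <- detect_onset(f$beats, f$ptt)
  expect_identical(on$beat, 8L)
  # crossing of -eps interpolated between beats 7 (0 ms) and 8 (-1 ms)
  expect_equal(on$p_cuff, 39)
  # a two-beat dip does not trigger
  d2 <- c(rep(0, 7), -1, -1, rep(0, 11))
  expect_true(is.na(detect_onset(mk(d2)$beats, mk(d2)$ptt)$beat))
  # flat series never triggers
  expect_true(is.na(detect_onset(mk(rep(0, 20))$beats,
                                 mk(rep(0, 20))$ptt)$beat))
})

test_that("PTT onset and distal MAP onset are near-simultaneous", {
  parts <- ref_parts()
  on <- parts$metrics$onset
  expect_false(is.na(on$beat))
  base_map <- parts$metrics$baseline_map
  map_onset <- which(parts$beats$map > base_map + 0.5)[1]
  expect_lte(abs(on$beat - map_onset), 2)
})

test_that("the six metrics are finite with the expected signs and bounds", {
  m <- ref_parts()$metrics
  sim <- ref_parts()$sim
  expect_true(all(is.finite(unlist(m[cuffsim:::.METRIC_COLS]))))
  expect_gt(m$max_dmap, 0)
  expect_gt(m$max_ddbp, m$max_dmap)      # diastole rises more than the mean
  expect_lte(m$max_ddbp, sim$input$pp)   # bounded by the pulse amplitude
  expect_gt(m$max_dptt_distal, 0)
  expect_gt(m$max_dpat_total, m$max_dptt_distal)
  expect_true(m$p_eq > sim$input$venous && m$p_eq < sim$input$map)
  # onset happens once the cuff starts pinching the artery at diastole
  expect_equal(m$onset$p_cuff, sim$input$dbp, tolerance = 25)
})

test_that("metrics error out when the equilibrium never establishes", {
  sim <- simulate_arm(protocol = cuff_protocol(max_pressure = 0, hold = 24),
                      dt = 1e-3)
  expect_error(response_metrics(sim), "converge")
})

test_that("slower inflation deepens the distal filling effect", {
  m4 <- response_metrics(simulate_arm(protocol = cuff_protocol(rate = 4)))
  m8 <- response_metrics(simulate_arm(protocol = cuff_protocol(rate = 8)))
  expect_gt(m4$p_eq, m8$p_eq)
  expect_gt(m4$max_dmap, m8$max_dmap)
  expect_gt(m4$max_dptt_distal, m8$max_dptt_distal)
})

test_that("a longer cuff produces a larger total PAT change", {
  m_long <- response_metrics(
    simulate_arm(geometry = arm_geometry(cuff_length = 0.18)))
  m_short <- response_metrics(
    simulate_arm(geometry = arm_geometry(cuff_length = 0.10)))
  expect_gt(m_long$max_dpat_total, m_short$max_dpat_total)
})
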