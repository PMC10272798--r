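# Shared fixtures, computed lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

ref_sim <- function() fixture("ref_sim", simulate_arm())

ref_parts <- function() fixture("ref_parts", {
  sim <- ref_sim()
  beats <- segment_beats(sim)
  ptt <- ptt_series(sim, beats)
  list(sim = sim, beats = beats, ptt = ptt,
       metrics = response_metrics(sim, beats, ptt))
})

# the shared sensitivity analysis used by the acceptance checks
acceptance_sobol <- function() fixture("acc_sobol", {
  run_sobol_analysis(n = 256, seed = 42)
})

# short run that never occludes; every beat keeps transmitting
open_sim <- function() fixture("open_sim", {
  simulate_arm(protocol = cuff_protocol(rate = 6, start = 6,
                                        max_pressure = 70, hold = 10),
               dt = 1e-3, pre_roll = 5)
})
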