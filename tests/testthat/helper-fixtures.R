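# Shared, lazily computed simulation fixtures. Long runs are expensive, so
# each is computed once per test session and reused across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

fx_rest <- function() fixture("rest", function()
  find_resting_state(hsy_pars(nu = 0)))

# open-cell agonist step, dense output for sub-second peak timing
fx_agonist <- function(nu) fixture(paste0("agonist", nu), function()
  simulate_protocol(make_protocol("agonist_step", nu = nu)))

fx_pulse_train <- function() fixture("pulse_train", function() {
  traj <- simulate_protocol(make_protocol("ip3_pulse"))
  trajectory_spikes(traj, "C")
})

fx_plc_train <- function() fixture("plc_train", function() {
  traj <- simulate_protocol(make_protocol("plc_inhibition"))
  trajectory_spikes(traj, "C")
})

fx_calcium_free <- function() fixture("calcium_free", function()
  simulate_protocol(make_protocol("calcium_free")))

# long-run stable period under constant uncaging (slow drift in Ct means
# the orbit stabilises only after ~1.2e4 s of simulated time)
fx_stable_period <- function(psi2, V_S) {
  key <- sprintf("stable_%g_%g", psi2, V_S)
  fixture(key, function() {
    traj <- simulate_protocol(make_protocol("psi2_scan", psi2 = psi2,
                                            V_S = V_S, t_final = 15000,
                                            record_step = 0.05))
    tr <- trajectory_spikes(traj, "C")
    oscillation_metrics(tr, last_n = 5)$mean_period
  })
}

# reference schedule used in several synthetic-trace tests
two_phase_schedule <- function()
  data.frame(start_min = c(0, 10), period_s = c(62, 35), amplitude = 1)
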