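test_that("the unstimulated resting state is a genuine equilibrium", {
  rest <- fx_rest()
  p <- hsy_pars(nu = 0)
  expect_lte(max(abs(unlist(hsy_rhs(0, rest, p)))), 1e-10)
  # no stimulation: receptors essentially shut, ER full
  expect_lt(open_probability(rest, p)$O_IPR, 1e-4)
  expect_gt(compute_CER(rest, p), 600)
  # closed-cell equilibrium at fixed total calcium
  restc <- find_resting_state(hsy_pars(nu = 0, epsilon = 0), Ct = 68)
  expect_equal(restc[["Ct"]], 68)
  expect_lte(max(abs(unlist(hsy_rhs(0, restc,
                                    hsy_pars(nu = 0, epsilon = 0))))),
             1e-10)
})

test_that("protocol constructors encode the published schedules", {
  pu <- make_protocol("ip3_pulse")
  expect_equal(length(pu$segments), 3L)
  expect_equal(pu$segments[[2]]$t_start, 200)
  expect_equal(pu$segments[[2]]$t_end, 200.7)
  expect_equal(pu$segments[[2]]$vs_plc, 0.04)
  expect_true(pu$ps_active)

  pi3 <- make_protocol("plc_inhibition")
  seg2 <- pi3$segments[[2]]
  expect_equal(seg2$t_start, 600)
  expect_equal(seg2$overrides$psi2, 0.4)
  expect_equal(seg2$overrides$V_S, 9.5)
  seg3 <- pi3$segments[[3]]
  expect_equal(seg3$t_start, 900)
  expect_equal(seg3$overrides$psi2, 0)
  expect_equal(seg3$overrides$V_S, 9)
  expect_equal(seg2$vs_plc, 0.0006)

  cf <- make_protocol("calcium_free")
  expect_false(cf$segments[[2]]$jin_enabled)
  expect_equal(cf$segments[[2]]$t_start, 120)

  ua <- make_protocol("uncaging_after_inhibition")
  expect_equal(ua$segments[[1]]$overrides$V_S, 9)
  expect_equal(ua$segments[[1]]$vs_plc, 0)
  expect_equal(ua$segments[[2]]$vs_plc, 0.0006)
  # alternative reported light level is settable
  ua2 <- make_protocol("uncaging_after_inhibition", k_s_plc = 0.00056)
  expect_equal(ua2$segments[[2]]$vs_plc, 0.00056)

  # identity schedule: no stimulation, single segment
  a0 <- make_protocol("agonist_step", nu = 0)
  expect_equal(length(a0$segments), 1L)
  expect_equal(a0$segments[[1]]$overrides$nu, 0)

  expect_error(make_protocol("not_a_protocol"), "unknown protocol")
  expect_error(make_protocol("agonist_step", nu = -3), "inadmissible")
  expect_error(make_protocol("ip3_pulse", wrong_knob = 1), "unknown option")
})

test_that("splitting a constant run into segments changes nothing", {
  p1 <- make_protocol("agonist_step", nu = 15, t_final = 200,
                      record_step = 0.05)
  p2 <- make_protocol("agonist_step",
                      nu_schedule = data.frame(t_start = c(0, 100),
                                               nu = c(15, 15)),
                      t_final = 200, record_step = 0.05)
  t1 <- simulate_protocol(p1)
  t2 <- simulate_protocol(p2)
  expect_equal(nrow(t1), nrow(t2))
  expect_lt(max(abs(t1$C - t2$C)), 1e-5)
  expect_lt(max(abs(t1$P - t2$P)), 1e-6)
})

test_that("closed-cell trajectories conserve total calcium exactly", {
  traj <- simulate_protocol(make_protocol("closed_cell", t_final = 300,
                                          record_step = 0.05))
  expect_lte(max(abs(traj$Ct - traj$Ct[1])) / traj$Ct[1], 1e-8)
  # and the run oscillates at the reference total calcium
  expect_true(is_oscillatory(traj, window = c(100, 300)))
})

test_that("numerical photoreleased IP3 tracks the analytic solution", {
  traj <- simulate_protocol(make_protocol("psi2_scan", t_final = 600,
                                          record_step = 0.5))
  expect_lt(max(abs(traj$Ps - ps_analytic(traj$time_s, hsy_pars()))), 1e-6)
})

test_that("gate variables stay in [0, 1] along oscillating trajectories", {
  traj <- fx_agonist(15)
  expect_true(all(traj$m42 >= 0 & traj$m42 <= 1))
  expect_true(all(traj$h42 >= 0 & traj$h42 <= 1))
  expect_true(all(traj$O_IPR >= 0 & traj$O_IPR <= 10500 / 14510))
  expect_true(all(traj$CER >= 0))
})

test_that("higher agonist concentration speeds the oscillation", {
  m15 <- oscillation_metrics(trajectory_spikes(fx_agonist(15)),
                             window = c(300, 600), last_n = 5)
  m20 <- oscillation_metrics(trajectory_spikes(fx_agonist(20)),
                             window = c(300, 600), last_n = 5)
  expect_lt(m20$mean_period, m15$mean_period)
})

test_that("calcium peaks precede IP3 peaks in coupled oscillations", {
  traj <- fx_agonist(15)
  ca <- trajectory_spikes(traj, "C")
  ip3 <- trajectory_spikes(traj, "P_total", min_prominence = 0.02)
  dl <- peak_delay(ca, ip3)
  expect_gt(dl, 0)
  expect_lt(dl, 2)
})

test_that("protocols and trajectories round-trip through files", {
  proto <- make_protocol("plc_inhibition")
  f <- withr::local_tempfile(fileext = ".json")
  write_protocol(proto, f)
  proto2 <- read_protocol(f)
  expect_equal(proto2$segments, proto$segments)
  expect_equal(proto2$base, proto$base)
  expect_equal(proto2$t_final, proto$t_final)
  expect_true(proto2$ps_active)

  traj <- simulate_protocol(make_protocol("agonist_step", nu = 15,
                                          t_final = 30,
                                          record_step = 0.1))
  g <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, g)
  traj2 <- read_trajectory(g)
  expect_equal(traj2$C, traj$C, tolerance = 1e-10)
  expect_equal(traj2$O_IPR, traj$O_IPR, tolerance = 1e-10)
  expect_error(read_trajectory(withr::local_tempfile(lines = "a,b\n1,2")),
               "not a trajectory")
})

test_that("oscillatory-range scan rejects bad grids and returns flags", {
  expect_error(closed_cell_oscillatory_range(Ct_grid = c(70, 60)),
               "increasing")
  res <- closed_cell_oscillatory_range(Ct_grid = c(30, 68), t_final = 800,
                                       window_length = 400)
  expect_identical(res$oscillatory, c(FALSE, TRUE))
})
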