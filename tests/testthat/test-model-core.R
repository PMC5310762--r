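p0 <- hsy_pars()

test_that("ER concentration follows the compartment balance", {
  expect_equal(compute_CER(hsy_state(0, 68, 0, 0, 0, 1), p0), 680)
  expect_equal(compute_CER(hsy_state(5, 5, 0, 0, 0, 1), p0), 0)
  # microdomain volume weighting: Cb enters divided by gamma1
  expect_equal(compute_CER(hsy_state(0, 68, 100, 0, 0, 1), p0),
               10 * (68 - 1))
})

test_that("flux formulas give half-maxima and known values", {
  s <- function(C) hsy_state(C = C, Ct = 68, Cb = 0.3, P = 0.1,
                             m42 = 0.1, h42 = 0.9)
  expect_equal(compute_fluxes(s(0.24), p0, 0)$J_SERCA, 5)
  expect_equal(compute_fluxes(s(0.45), p0, 0)$J_pm, 0.0165)
  # frozen from a 30-digit independent evaluation of V_S/(1 + K_S^1.75)
  expect_equal(compute_fluxes(s(1), p0, 0)$J_SERCA, 9.2396311653551443,
               tolerance = 1e-12)
  fl <- compute_fluxes(s(0.5), p0, O_IPR = 0.2)
  expect_equal(fl$J_in, fl$J_leakin + fl$J_ROCC + fl$J_SOCC)
  expect_equal(fl$J_diff, 10 * (0.3 - 0.5))
  CER <- compute_CER(s(0.5), p0)
  expect_equal(fl$J_IPR, 0.038 * 0.2 * (CER - 0.3))
  expect_equal(fl$J_leak, 0.0032 * (CER - 0.5))
  expect_error(
    compute_fluxes(unclass(s(0.1)) - c(1, 0, 0, 0, 0, 0, 0), p0, 0),
    "invalid state")
})

test_that("IPR coefficient functions match their closed forms", {
  co0 <- gating_coefficients(0)
  expect_equal(co0$V24, 282)
  expect_equal(co0$a24, 21)
  expect_equal(co0$V42, 0)
  expect_equal(co0$a42, 0)
  expect_equal(co0$k42, 0.49)
  expect_equal(co0$k_m42, 0.41)
  # saturating limits
  coInf <- gating_coefficients(1e6)
  expect_equal(coInf$V24, 62, tolerance = 1e-9)
  expect_equal(coInf$a24, 1, tolerance = 1e-9)
  expect_equal(coInf$V42, 110, tolerance = 1e-9)
  expect_equal(coInf$a42, 1.8, tolerance = 1e-9)
  # the two constants are IP3-independent
  for (P in c(0, 0.3, 7)) {
    expect_equal(gating_coefficients(P)$k24, 0.35)
    expect_equal(gating_coefficients(P)$k_m24, 80)
  }
  # frozen from a 30-digit independent evaluation at P = 2
  co2 <- gating_coefficients(2)
  expect_equal(co2$V24, 172)
  expect_equal(co2$k42, 0.5503333333333333, tolerance = 1e-12)
  expect_equal(co2$k_m42, 1.1177140835102619, tolerance = 1e-12)
  expect_error(gating_coefficients(-1), "non-negative")
})

test_that("gate quasi-equilibria behave at limits and half-saturation", {
  co <- gating_coefficients(0.3)
  eq0 <- gating_equilibria(0, 0, co)
  expect_equal(eq0$m42_inf, 0)
  expect_equal(eq0$h42_inf, 1)
  expect_equal(eq0$m24_inf, 0)
  expect_equal(eq0$h24_inf, 1)
  expect_equal(gating_equilibria(co$k42, 100, co)$m42_inf, 0.5)
  expect_equal(gating_equilibria(co$k_m42, 100, co)$h42_inf, 0.5)
  expect_equal(gating_equilibria(1, co$k24, co)$m24_inf, 0.5)
  expect_equal(gating_equilibria(1, co$k_m24, co)$h24_inf, 0.5)
})

test_that("pore calcium equals C_p0 at the reference ER concentration", {
  s <- hsy_state(C = 0, Ct = 68, Cb = 0, P = 0.2, m42 = 0.1, h42 = 0.9)
  expect_equal(compute_CER(s, p0), 680)
  expect_equal(open_probability(s, p0)$Cp, 700)
})

test_that("open probability vanishes at zero IP3 and is bounded above", {
  s0 <- hsy_state(C = 0.1, Ct = 68, Cb = 0.2, P = 0, m42 = 0.5, h42 = 0.5)
  op0 <- open_probability(s0, p0)
  expect_equal(op0$q42, 0)
  expect_equal(op0$D, 0)
  expect_equal(op0$O_IPR, 0)
  # drive-mode ceiling, frozen from exact rational q26/(q26+q62)
  ceiling <- 10500 / 14510
  expect_equal(ceiling, 0.7236388697450034, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    s <- hsy_state(C = runif(1, 0, 2), Ct = runif(1, 40, 90),
                   Cb = runif(1, 0, 30), P = runif(1, 0, 5),
                   m42 = runif(1), h42 = runif(1))
    op <- open_probability(s, p0)
    expect_gte(op$D, 0); expect_lte(op$D, 1)
    expect_gte(op$O_IPR, 0); expect_lte(op$O_IPR, ceiling)
    eqs <- unlist(op[c("m42_inf", "h42_inf", "m24_inf", "h24_inf")])
    expect_true(all(eqs >= 0 & eqs <= 1))
    # with L = H the h-gate relaxation rate is constant
    expect_equal(op$lambda_h42, 0.1)
  }
})

test_that("IP3 production combines agonist and calcium terms", {
  expect_equal(ip3_production(0, 0, p0), 0)
  expect_equal(ip3_production(p0$K_plc, p0$K_nu, p0), 0.65)
  expect_equal(ip3_production(0, 15, p0), 0.5 * 15 / 60)
  # psi2 = 0 removes all calcium feedback
  pf <- hsy_pars(psi2 = 0)
  expect_equal(ip3_production(10, 15, pf), ip3_production(0, 15, pf))
  expect_lt(ip3_production(100, 1e6, p0), p0$psi1 + p0$psi2)
})

test_that("uncaging rate honours the Heaviside endpoint convention", {
  p <- hsy_pars(M = 0.04, t0 = 200, Delta = 0.7, k_s_plc = 0.0006)
  expect_equal(uncaging_rate(100, p, "pulse"), 0)
  expect_equal(uncaging_rate(200, p, "pulse"), 0)       # left endpoint
  expect_equal(uncaging_rate(200.3, p, "pulse"), 0.04)
  expect_equal(uncaging_rate(200.7, p, "pulse"), 0)     # right endpoint
  expect_equal(uncaging_rate(300, p, "pulse"), 0)
  expect_equal(uncaging_rate(12, p, "constant"), 0.0006)
  expect_equal(uncaging_rate(12, p, "off"), 0)
})

test_that("closed cell and calcium-free flags shape the Ct equation", {
  s <- hsy_state(C = 0.3, Ct = 68, Cb = 1, P = 0.2, m42 = 0.3, h42 = 0.8)
  d_closed <- hsy_rhs(0, s, hsy_pars(epsilon = 0, nu = 15))[[1]]
  expect_identical(d_closed[["Ct"]], 0)
  d_nofree <- hsy_rhs(0, s, hsy_pars(epsilon = 1, nu = 20),
                      jin_enabled = FALSE)[[1]]
  fl <- compute_fluxes(s, hsy_pars(), open_probability(s, hsy_pars())$O_IPR)
  expect_equal(d_nofree[["Ct"]], -fl$J_pm)
  expect_lt(d_nofree[["Ct"]], 0)
})

test_that("exported rhs and the integrator's inlined core agree", {
  set.seed(7)
  modes <- c("off", "constant")
  for (i in 1:25) {
    s <- hsy_state(C = runif(1, 0, 1.5), Ct = runif(1, 50, 80),
                   Cb = runif(1, 0, 20), P = runif(1, 0, 2),
                   m42 = runif(1), h42 = runif(1), Ps = runif(1, 0, 0.2))
    pr <- hsy_pars(nu = runif(1, 0, 30), psi2 = runif(1, 0, 0.8))
    mode <- sample(modes, 1)
    a <- unlist(hsy_rhs(1, s, pr, mode = mode))
    b <- unlist(hsycalcium:::rhs_core(
      1, unclass(s), pr, vs = uncaging_rate(1, pr, mode),
      jin_enabled = TRUE, ps_active = !identical(mode, "off")))
    expect_equal(unname(a), unname(b), tolerance = 1e-14)
  }
})

test_that("rhs signals invalid states instead of clipping", {
  s <- c(C = 0.1, Ct = 0.05, Cb = 10, P = 0.1, m42 = 0.1, h42 = 0.9, Ps = 0)
  expect_error(hsy_rhs(0, s, p0), "invalid state")  # C_ER < 0
})

test_that("photoreleased IP3 has the exact linear-relaxation solution", {
  p <- hsy_pars(k_s_plc = 0.0006, r_s_deg = 0.006)
  expect_equal(ps_analytic(0, p), 0)
  expect_equal(ps_analytic(1e9, p), 0.1)
  expect_equal(ps_analytic(log(2) / 0.006, p), 0.05)
})
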