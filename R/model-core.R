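#' ER calcium concentration implied by a state
#'
#' The model tracks total free calcium `Ct` rather than ER calcium directly;
#' the ER concentration follows from the compartment balance
#' \deqn{C_{ER} = \gamma_2 (C_t - C - C_b/\gamma_1).}
#' The value may be negative for an inadmissible state; callers that
#' integrate the model treat a materially negative value as an error.
#'
#' @param state an [hsy_state()] (or any named vector with `C`, `Ct`, `Cb`).
#' @param pars an [hsy_pars()] parameter set.
#' @return ER calcium concentration (uM).
#' @examples
#' compute_CER(hsy_state(0, 68, 0, 0, 0, 1), hsy_pars())  # 680
#' @export
compute_CER <- function(state, pars) {
  unname(pars$gamma2 * (state[["Ct"]] - state[["C"]] -
                          state[["Cb"]] / pars$gamma1))
}

#' Calcium fluxes at a given state
#'
#' Evaluates every calcium flux of the model (all uM/s, cytosolic-volume
#' units):
#' release through the IPR `J_IPR = k_IPR O_IPR (C_ER - C_b)`, microdomain
#' drainage `J_diff = k_diff (C_b - C)`, ER leak `J_leak = k_leak (C_ER - C)`,
#' SERCA re-uptake `J_SERCA = V_S C^1.75 / (C^1.75 + K_S^1.75)`, the plasma
#' membrane influx components `J_leakin`, `J_ROCC = V_ROCC P_eff`,
#' `J_SOCC = V_SOCC K_SOCC^4 / (K_SOCC^4 + C_ER^4)`, their sum `J_in`, and
#' PMCA extrusion `J_pm = V_pm C^2 / (C^2 + K_pm^2)`.
#'
#' Receptor-operated entry responds to the total effective IP3 `P_eff`,
#' i.e. `P + Ps` when photoreleased IP3 is present.
#'
#' @param state an [hsy_state()].
#' @param pars an [hsy_pars()].
#' @param O_IPR IPR open probability, in \[0, 1\].
#' @param P_eff total effective IP3 concentration (uM); defaults to
#'   `P + Ps` from `state`.
#' @return Named list with components `J_IPR`, `J_diff`, `J_leak`,
#'   `J_SERCA`, `J_leakin`, `J_ROCC`, `J_SOCC`, `J_in`, `J_pm`.
#' @examples
#' p <- hsy_pars()
#' s <- hsy_state(C = 0.24, Ct = 68, Cb = 0.3, P = 0.1, m42 = 0, h42 = 1)
#' compute_fluxes(s, p, O_IPR = 0)$J_SERCA  # half-maximal: 5
#' @export
compute_fluxes <- function(state, pars, O_IPR,
                           P_eff = state[["P"]] + state[["Ps"]]) {
  C <- state[["C"]]
  if (C < 0)
    stop("invalid state: C < 0 (fractional SERCA exponent undefined)")
  if (O_IPR < 0 || O_IPR > 1) stop("O_IPR must lie in [0, 1]")
  Cb <- state[["Cb"]]
  CER <- compute_CER(state, pars)
  C175 <- C^1.75
  J_ROCC <- pars$V_ROCC * P_eff
  J_SOCC <- pars$V_SOCC * pars$K_SOCC^4 / (pars$K_SOCC^4 + CER^4)
  list(
    J_IPR   = pars$k_IPR * O_IPR * (CER - Cb),
    J_diff  = pars$k_diff * (Cb - C),
    J_leak  = pars$k_leak * (CER - C),
    J_SERCA = pars$V_S * C175 / (C175 + pars$K_S^1.75),
    J_leakin = pars$J_leakin,
    J_ROCC  = J_ROCC,
    J_SOCC  = J_SOCC,
    J_in    = pars$J_leakin + J_ROCC + J_SOCC,
    J_pm    = pars$V_pm * C^2 / (C^2 + pars$K_pm^2)
  )
}

#' IPR mode-transition coefficient functions
#'
#' The park/drive mode-switching rates of the IPR gating model are built
#' from eight IP3-dependent coefficients:
#' \deqn{V_{24} = 62 + 880/(P^2 + 4), \quad a_{24} = 1 + 5/(P^2 + 0.25),}
#' \deqn{k_{24} = 0.35, \quad k_{-24} = 80,}
#' \deqn{V_{42} = 110 P^2/(P^2 + 0.01), \quad a_{42} = 1.8 P^2/(P^2 + 0.34),}
#' \deqn{k_{42} = 0.49 + 0.543 P^3/(P^3 + 64), \quad
#'       k_{-42} = 0.41 + 25 P^3/(P^3 + 274.6),}
#' where `P` is the total effective IP3 (including photoreleased IP3).
#'
#' @param P_eff total effective IP3 concentration (uM), `>= 0`.
#' @return Named list `V24`, `a24`, `k24`, `k_m24`, `V42`, `a42`, `k42`,
#'   `k_m42` (the `m` prefix marks the negative-subscript constants).
#' @examples
#' gating_coefficients(0)$V24  # 282
#' @export
gating_coefficients <- function(P_eff) {
  if (P_eff < 0) stop("P_eff must be non-negative")
  P2 <- P_eff^2
  P3 <- P_eff^3
  list(
    V24 = 62 + 880 / (P2 + 4),
    a24 = 1 + 5 / (P2 + 0.25),
    k24 = 0.35,
    k_m24 = 80,
    V42 = 110 * P2 / (P2 + 0.01),
    a42 = 1.8 * P2 / (P2 + 0.34),
    k42 = 0.49 + 0.543 * P3 / (P3 + 64),
    k_m42 = 0.41 + 25 * P3 / (P3 + 274.6)
  )
}

#' Quasi-equilibrium gate values
#'
#' Gate equilibria driven by microdomain calcium `C_b` (opening kinetics)
#' and pore calcium `C_p` (closing kinetics):
#' \deqn{m_{42\infty} = C_b^3/(C_b^3 + k_{42}^3), \quad
#'       h_{42\infty} = k_{-42}^3/(C_b^3 + k_{-42}^3),}
#' \deqn{m_{24\infty} = C_p^3/(C_p^3 + k_{24}^3), \quad
#'       h_{24\infty} = k_{-24}^2/(C_p^2 + k_{-24}^2).}
#' The closing-gate exponent asymmetry (cubic `m`, quadratic `h`) is part of
#' the gating model. Pore calcium is supplied by the caller as
#' `C_p = C_p0 * (C_ER / C_ER_ref)`.
#'
#' @param Cb microdomain calcium (uM), `>= 0`.
#' @param Cp pore calcium (uM), `>= 0`.
#' @param coeffs output of [gating_coefficients()].
#' @return Named list `m42_inf`, `h42_inf`, `m24_inf`, `h24_inf`, each in
#'   \[0, 1\].
#' @export
gating_equilibria <- function(Cb, Cp, coeffs) {
  if (Cb < 0 || Cp < 0) stop("Cb and Cp must be non-negative")
  Cb3 <- Cb^3
  Cp3 <- Cp^3
  list(
    m42_inf = Cb3 / (Cb3 + coeffs$k42^3),
    h42_inf = coeffs$k_m42^3 / (Cb3 + coeffs$k_m42^3),
    m24_inf = Cp3 / (Cp3 + coeffs$k24^3),
    h24_inf = coeffs$k_m24^2 / (Cp^2 + coeffs$k_m24^2)
  )
}

#' IPR open probability and mode occupancy
#'
#' Assembles the full gating picture at one instant: the mode-switching
#' rates
#' \deqn{q_{24} = a_{24} + V_{24}(1 - m_{24\infty} h_{24\infty}), \quad
#'       q_{42} = a_{42} + V_{42} m_{42} h_{42},}
#' the drive-mode occupancy
#' \deqn{D = q_{42}(q_{62} + q_{26}) /
#'       (q_{42} q_{62} + q_{42} q_{26} + q_{24} q_{62}),}
#' the open probability \eqn{O_{IPR} = D\, q_{26}/(q_{62} + q_{26})}, and
#' the inactivation-gate relaxation rate
#' \eqn{\lambda_{h42} = (1 - D) L + D H}.
#'
#' `m42` and `h42` are the dynamic gate values carried in the state; the
#' quasi-equilibria entering `q_24` come from pore calcium, computed here
#' from the instantaneous ER concentration.
#'
#' @param state an [hsy_state()].
#' @param pars an [hsy_pars()].
#' @param P_eff total effective IP3 (uM); defaults to `P + Ps`.
#' @return Named list with `q24`, `q42`, `D`, `O_IPR`, `lambda_h42`, the
#'   coefficients of [gating_coefficients()], the equilibria of
#'   [gating_equilibria()], and `Cp`.
#' @examples
#' p <- hsy_pars()
#' s <- hsy_state(C = 0.1, Ct = 68, Cb = 0.1, P = 0, m42 = 0, h42 = 1)
#' open_probability(s, p)$O_IPR  # 0 at zero IP3
#' @export
open_probability <- function(state, pars,
                             P_eff = state[["P"]] + state[["Ps"]]) {
  co <- gating_coefficients(P_eff)
  CER <- compute_CER(state, pars)
  Cp <- pars$C_p0 * (CER / pars$C_ER_ref)
  eq <- gating_equilibria(state[["Cb"]], max(Cp, 0), co)
  q24 <- co$a24 + co$V24 * (1 - eq$m24_inf * eq$h24_inf)
  q42 <- co$a42 + co$V42 * state[["m42"]] * state[["h42"]]
  denom <- q42 * pars$q62 + q42 * pars$q26 + q24 * pars$q62
  if (denom == 0)
    stop("degenerate rates: q24 = q42 = 0")
  D <- q42 * (pars$q62 + pars$q26) / denom
  c(list(
    q24 = q24, q42 = q42, D = D,
    O_IPR = pars$q26 / (pars$q62 + pars$q26) * D,
    lambda_h42 = (1 - D) * pars$L + D * pars$H,
    Cp = Cp
  ), co, eq)
}

#' IP3 production rate from PLC
#'
#' Production by agonist-stimulated PLC-beta and calcium-stimulated
#' PLC-delta:
#' \deqn{V_{plc} = \psi_1 \nu/(K_\nu + \nu) +
#'       \psi_2 C^4/(C^4 + K_{plc}^4).}
#' Setting `psi2 = 0` removes all calcium feedback, leaving production
#' driven by agonist alone.
#'
#' @param C cytosolic calcium (uM), `>= 0`.
#' @param nu applied agonist concentration (uM), `>= 0`.
#' @param pars an [hsy_pars()].
#' @return Production rate (uM/s), in `[0, psi1 + psi2)`.
#' @examples
#' ip3_production(C = 0.8, nu = 45, hsy_pars())  # 0.25 + 0.4
#' @export
ip3_production <- function(C, nu, pars) {
  if (C < 0 || nu < 0) stop("C and nu must be non-negative")
  C4 <- C^4
  pars$psi1 * nu / (pars$K_nu + nu) +
    pars$psi2 * C4 / (C4 + pars$K_plc^4)
}

#' Photoreleased-IP3 production rate
#'
#' UV uncaging of caged IP3, in one of three modes: `"off"` (no uncaging,
#' rate 0), `"pulse"` (a flash of duration `Delta` starting at `t0`,
#' \eqn{V_{s\_plc}(t) = M H(t - t_0) H(t_0 + \Delta - t)} with the
#' convention \eqn{H(x) = 0} for \eqn{x \le 0}, so the rate is exactly 0 at
#' both endpoints), or `"constant"` (continuous low-level light,
#' \eqn{V_{s\_plc} = k_{s\_plc}}).
#'
#' @param t time (s).
#' @param pars an [hsy_pars()]; fields `M`, `t0`, `Delta`, `k_s_plc`.
#' @param mode one of `"off"`, `"pulse"`, `"constant"`.
#' @return Production rate of photoreleased IP3 (uM/s).
#' @examples
#' uncaging_rate(200, hsy_pars(), "pulse")    # 0 at the left endpoint
#' uncaging_rate(200.3, hsy_pars(), "pulse")  # M = 0.04
#' @export
uncaging_rate <- function(t, pars, mode = c("off", "pulse", "constant")) {
  mode <- match.arg(mode)
  switch(mode,
    off = 0,
    pulse = pars$M * as.numeric(t > pars$t0) *
      as.numeric(pars$t0 + pars$Delta - t > 0),
    constant = pars$k_s_plc
  )
}

#' Right-hand side of the model ODE system
#'
#' The seven-component derivative of the state
#' `(C, Ct, Cb, P, m42, h42, Ps)`:
#' \deqn{dC/dt = J_{diff} + J_{leak} - J_{SERCA} +
#'       \epsilon (J_{in} - J_{pm}),}
#' \deqn{dC_t/dt = \epsilon (J_{in} - J_{pm}), \quad
#'       dC_b/dt = \gamma_1 (J_{IPR} - J_{diff}),}
#' \deqn{dP/dt = V_{plc} - r_{deg} P, \quad
#'       dm_{42}/dt = \lambda_{m42}(m_{42\infty} - m_{42}), \quad
#'       dh_{42}/dt = \lambda_{h42}(h_{42\infty} - h_{42}),}
#' \deqn{dP_s/dt = V_{s\_plc}(t) - r_{s\_deg} P_s,}
#' with `dPs/dt` identically 0 when `mode = "off"`. The IPR gating and the
#' receptor-operated influx use the total effective IP3 `P + Ps`. With
#' `jin_enabled = FALSE` the plasma-membrane influx `J_in` is replaced by 0
#' in both the `C` and `Ct` equations (calcium-free medium). `epsilon = 0`
#' gives the closed-cell model with `dCt/dt = 0` exactly.
#'
#' The signature is `deSolve`-compatible: the extra arguments have defaults
#' so the function can be passed directly to [deSolve::ode()].
#'
#' @param t time (s).
#' @param state named numeric vector `(C, Ct, Cb, P, m42, h42, Ps)`.
#' @param pars an [hsy_pars()].
#' @param mode uncaging mode, see [uncaging_rate()]; alternatively the
#'   protocol layer passes a precomputed constant rate via `vs_plc`.
#' @param jin_enabled logical; `FALSE` zeroes the plasma-membrane influx.
#' @param vs_plc optional constant uncaging production rate (uM/s)
#'   overriding `mode`; used by the integrator inside protocol segments
#'   where the rate is piecewise constant.
#' @return `list(derivative)`, as expected by `deSolve`.
#' @export
hsy_rhs <- function(t, state, pars, mode = "off", jin_enabled = TRUE,
                    vs_plc = NULL) {
  C <- state[["C"]]
  CER <- compute_CER(state, pars)
  if (C < -1e-9 || CER < -1e-9)
    stop(sprintf(
      "invalid state at t = %.6g: C = %.6g, C_ER = %.6g (negative)",
      t, C, CER))
  # guard tiny negative excursions within solver tolerance
  if (C < 0) {
    state[["C"]] <- 0
    C <- 0
  }
  P_eff <- state[["P"]] + state[["Ps"]]
  op <- open_probability(state, pars, P_eff)
  fl <- compute_fluxes(state, pars, op$O_IPR, P_eff)
  J_in <- if (jin_enabled) fl$J_in else 0
  pm_net <- pars$epsilon * (J_in - fl$J_pm)
  Vplc <- ip3_production(C, pars$nu, pars)
  Vs <- if (!is.null(vs_plc)) vs_plc else uncaging_rate(t, pars, mode)
  dPs <- if (is.null(vs_plc) && identical(mode, "off")) 0 else
    Vs - pars$r_s_deg * state[["Ps"]]
  list(c(
    C   = fl$J_diff + fl$J_leak - fl$J_SERCA + pm_net,
    Ct  = pm_net,
    Cb  = pars$gamma1 * (fl$J_IPR - fl$J_diff),
    P   = Vplc - pars$r_deg * state[["P"]],
    m42 = pars$lambda_m42 * (op$m42_inf - state[["m42"]]),
    h42 = op$lambda_h42 * (op$h42_inf - state[["h42"]]),
    Ps  = dPs
  ))
}

#' Closed-form photoreleased IP3 under constant uncaging
#'
#' Under continuous uncaging the photoreleased-IP3 equation
#' \eqn{dP_s/dt = k_{s\_plc} - r_{s\_deg} P_s} is linear with steady state
#' \eqn{\bar P_s = k_{s\_plc}/r_{s\_deg}}; from `Ps(0) = 0`,
#' \deqn{P_s(t) = \bar P_s (1 - e^{-r_{s\_deg} t}).}
#' Serves as an exact oracle for the numerical integrator.
#'
#' @param t time (s), scalar or vector.
#' @param pars an [hsy_pars()]; uses `k_s_plc` and `r_s_deg`.
#' @return Photoreleased IP3 concentration(s) (uM).
#' @examples
#' ps_analytic(c(0, 1e6), hsy_pars())  # 0 and the 0.1 uM steady state
#' @export
ps_analytic <- function(t, pars) {
  if (pars$r_s_deg <= 0) return(pars$k_s_plc * t)
  pars$k_s_plc / pars$r_s_deg * (1 - exp(-pars$r_s_deg * t))
}
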