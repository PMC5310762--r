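#' Model parameters for the HSY-cell calcium model
#'
#' Construct the full parameter set of the HSY-cell calcium/IP3 model.
#' Defaults are the published reference values: the calcium-flux constants,
#' the two-mode IP3-receptor (IPR) gating constants, and the PLC/IP3
#' production constants, in micromolar and seconds throughout.
#'
#' Protocol-level knobs (`nu`, `epsilon`, `psi2`, `V_S`, the uncaging fields)
#' are ordinary parameters here; the protocol layer overrides them per time
#' segment.
#'
#' @param ... named overrides of any default listed below.
#'
#' @details Parameter groups (defaults in parentheses):
#' \describe{
#'   \item{Compartments}{`gamma1` (100), volume ratio cytosol/microdomain;
#'     `gamma2` (10), cytosol/ER.}
#'   \item{ER fluxes}{`k_IPR` (0.038 /s) IPR flux coefficient; `k_diff`
#'     (10 /s) microdomain-to-cytosol diffusion; `k_leak` (0.0032 /s) ER
#'     leak; `V_S` (10 uM/s) and `K_S` (0.24 uM) SERCA maximum and
#'     half-activation.}
#'   \item{Plasma membrane}{`J_leakin` (0.0019 uM/s) basal influx; `V_ROCC`
#'     (0.03 /s) receptor-operated entry coefficient; `V_SOCC` (0.3 uM/s)
#'     and `K_SOCC` (100 uM) store-operated entry; `V_pm` (0.033 uM/s) and
#'     `K_pm` (0.45 uM) PMCA extrusion.}
#'   \item{IPR gating}{`q26` (10500 /s), `q62` (4010 /s) open/close rates
#'     inside the drive mode; `lambda_m42` (1 /s) activation-gate relaxation;
#'     `L`, `H` (0.1 /s each) bounds of the inactivation-gate relaxation
#'     rate; `C_p0` (700 uM) pore-calcium scale; `C_ER_ref` (680 uM) the
#'     reference ER concentration in the pore-calcium expression.}
#'   \item{IP3 dynamics}{`K_nu` (45 uM) agonist half-activation; `K_plc`
#'     (0.8 uM) calcium half-activation of PLC-delta; `psi1` (0.5 uM/s),
#'     `psi2` (0.8 uM/s) maximal agonist- and calcium-driven production;
#'     `r_deg` (1.4 /s) IP3 turnover.}
#'   \item{Protocol switches}{`nu` (0 uM) applied agonist; `epsilon` (1)
#'     open-cell (1) vs closed-cell (0) switch; `r_s_deg` (0.006 /s)
#'     photoreleased-IP3 turnover; `M` (0.04 uM/s), `t0` (200 s), `Delta`
#'     (0.7 s) uncaging pulse magnitude, onset, duration; `k_s_plc`
#'     (0.0006 uM/s) continuous uncaging rate.}
#' }
#'
#' @return A named list of class `"hsy_pars"`.
#' @examples
#' p <- hsy_pars(nu = 15)
#' p$V_S
#' @export
hsy_pars <- function(...) {
  pars <- list(
    # compartment volume ratios
    gamma1 = 100, gamma2 = 10,
    # ER membrane fluxes
    k_IPR = 0.038, k_diff = 10, k_leak = 0.0032,
    V_S = 10, K_S = 0.24,
    # plasma membrane fluxes
    J_leakin = 0.0019, V_ROCC = 0.03, V_SOCC = 0.3, K_SOCC = 100,
    V_pm = 0.033, K_pm = 0.45,
    # IPR gating
    q26 = 10500, q62 = 4010,
    lambda_m42 = 1, L = 0.1, H = 0.1,
    C_p0 = 700, C_ER_ref = 680,
    # IP3 production / degradation
    K_nu = 45, K_plc = 0.8, psi1 = 0.5, psi2 = 0.8, r_deg = 1.4,
    # protocol-level switches
    nu = 0, epsilon = 1,
    # photoreleased IP3
    r_s_deg = 0.006, M = 0.04, t0 = 200, Delta = 0.7, k_s_plc = 0.0006
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(over), names(pars))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    pars[names(over)] <- over
  }
  validate_hsy_pars(structure(pars, class = "hsy_pars"))
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rates and concentrations, strict positivity
#' of half-saturation constants and volume ratios, and that `epsilon` is 0
#' or 1.
#'
#' @param pars an object from [hsy_pars()].
#' @return `pars`, invisibly unchanged, or an error.
#' @export
validate_hsy_pars <- function(pars) {
  num <- vapply(pars, function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num))
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(pars)[!num], collapse = ", "))
  neg <- vapply(pars, function(x) x < 0, logical(1))
  if (any(neg))
    stop("negative parameter(s): ", paste(names(pars)[neg], collapse = ", "))
  strict <- c("gamma1", "gamma2", "K_S", "K_pm", "K_SOCC", "K_nu", "K_plc",
              "r_deg")
  zero <- strict[vapply(strict, function(nm) pars[[nm]] <= 0, logical(1))]
  if (length(zero))
    stop("parameter(s) must be strictly positive: ",
         paste(zero, collapse = ", "))
  if (!pars$epsilon %in% c(0, 1))
    stop("epsilon must be 0 (closed cell) or 1 (open cell)")
  pars
}

#' Construct a model state
#'
#' The dynamical variables of the model: cytosolic calcium `C`, total free
#' calcium `Ct` (in cytosolic-volume units), microdomain calcium `Cb`, IP3
#' `P` (all uM), the IPR activation and inactivation gates `m42`, `h42`
#' (dimensionless, in \[0, 1\]), and photoreleased IP3 `Ps` (uM; fixed 0
#' outside uncaging protocols).
#'
#' @param C,Ct,Cb,P,m42,h42,Ps numeric scalars.
#' @return A named numeric vector of class `"hsy_state"`.
#' @examples
#' s <- hsy_state(C = 0.1, Ct = 68, Cb = 0.1, P = 0, m42 = 0, h42 = 1)
#' @export
hsy_state <- function(C, Ct, Cb, P, m42, h42, Ps = 0) {
  s <- c(C = C, Ct = Ct, Cb = Cb, P = P, m42 = m42, h42 = h42, Ps = Ps)
  if (!all(is.finite(s))) stop("state components must be finite")
  if (any(s[c("C", "Ct", "Cb", "P", "Ps")] < 0))
    stop("concentrations must be non-negative")
  if (m42 < 0 || m42 > 1 || h42 < 0 || h42 > 1)
    stop("gating variables m42, h42 must lie in [0, 1]")
  structure(s, class = "hsy_state")
}

state_names <- c("C", "Ct", "Cb", "P", "m42", "h42", "Ps")
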