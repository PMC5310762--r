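## Protocol layer: each virtual experiment is a time-segmented schedule of
## parameter overrides driven through the stiff integrator.

# Inlined right-hand side used inside the integrator. Same mathematics as
# hsy_rhs() but without per-call validation or list assembly; parameters
# arrive as a plain environment/list `p` plus segment-constant uncaging rate
# `vs`, influx flag and Ps-activity flag. Consistency with hsy_rhs() is
# asserted in the test suite.
rhs_core <- function(t, y, p, vs, jin_enabled, ps_active) {
  C <- y[[1L]]; Ct <- y[[2L]]; Cb <- y[[3L]]; P <- y[[4L]]
  m42 <- y[[5L]]; h42 <- y[[6L]]; Ps <- y[[7L]]
  CER <- p$gamma2 * (Ct - C - Cb / p$gamma1)
  if (C < -1e-9 || CER < -1e-9)
    stop(sprintf(
      "invalid state at t = %.6g: C = %.6g, C_ER = %.6g (negative)",
      t, C, CER))
  if (C < 0) C <- 0
  P_eff <- P + Ps
  P2 <- P_eff^2; P3 <- P_eff^3
  V24 <- 62 + 880 / (P2 + 4)
  a24 <- 1 + 5 / (P2 + 0.25)
  V42 <- 110 * P2 / (P2 + 0.01)
  a42 <- 1.8 * P2 / (P2 + 0.34)
  k42 <- 0.49 + 0.543 * P3 / (P3 + 64)
  k_m42 <- 0.41 + 25 * P3 / (P3 + 274.6)
  Cp <- p$C_p0 * (CER / p$C_ER_ref)
  if (Cp < 0) Cp <- 0
  Cb3 <- Cb^3; Cp3 <- Cp^3
  m42_inf <- Cb3 / (Cb3 + k42^3)
  h42_inf <- k_m42^3 / (Cb3 + k_m42^3)
  m24_inf <- Cp3 / (Cp3 + 0.35^3)
  h24_inf <- 80^2 / (Cp^2 + 80^2)
  q24 <- a24 + V24 * (1 - m24_inf * h24_inf)
  q42 <- a42 + V42 * m42 * h42
  D <- q42 * (p$q62 + p$q26) / (q42 * p$q62 + q42 * p$q26 + q24 * p$q62)
  O_IPR <- p$q26 / (p$q62 + p$q26) * D
  lambda_h42 <- (1 - D) * p$L + D * p$H
  C175 <- C^1.75
  J_IPR <- p$k_IPR * O_IPR * (CER - Cb)
  J_diff <- p$k_diff * (Cb - C)
  J_leak <- p$k_leak * (CER - C)
  J_SERCA <- p$V_S * C175 / (C175 + p$K_S^1.75)
  J_pm <- p$V_pm * C^2 / (C^2 + p$K_pm^2)
  J_in <- if (jin_enabled)
    p$J_leakin + p$V_ROCC * P_eff +
      p$V_SOCC * p$K_SOCC^4 / (p$K_SOCC^4 + CER^4)
  else 0
  pm_net <- p$epsilon * (J_in - J_pm)
  C4 <- C^4
  Vplc <- p$psi1 * p$nu / (p$K_nu + p$nu) + p$psi2 * C4 / (C4 + p$K_plc^4)
  dPs <- if (ps_active) vs - p$r_s_deg * Ps else 0
  list(c(
    J_diff + J_leak - J_SERCA + pm_net,
    pm_net,
    p$gamma1 * (J_IPR - J_diff),
    Vplc - p$r_deg * P,
    p$lambda_m42 * (m42_inf - m42),
    lambda_h42 * (h42_inf - h42),
    dPs
  ))
}

#' Resting state of the model
#'
#' Computes the unstimulated steady state used as the initial condition of
#' every protocol: a long relaxation integration followed by damped Newton
#' refinement of `rhs = 0`. For a closed cell (`epsilon = 0`) the total
#' calcium `Ct` is a fixed parameter of the equilibrium, not an unknown.
#'
#' @param pars an [hsy_pars()]; protocols call this with `nu = 0`.
#' @param Ct total free calcium (uM) held fixed when `epsilon = 0`; also
#'   used as the starting guess for the open-cell unknown.
#' @param ps_active logical; if `TRUE`, `Ps` relaxes to its own steady
#'   state, otherwise it is held at 0.
#' @param tol convergence tolerance on the max-norm of the derivative.
#' @param t_relax pre-integration horizon (s) before Newton refinement.
#' @return An [hsy_state()] with `max |rhs| <= tol`.
#' @export
find_resting_state <- function(pars, Ct = 68, ps_active = FALSE,
                               tol = 1e-10, t_relax = 2000) {
  closed <- pars$epsilon == 0
  y0 <- c(C = 0.08, Ct = Ct, Cb = 0.08, P = 0.001, m42 = 0.01, h42 = 0.98,
          Ps = 0)
  f_full <- function(y) unlist(rhs_core(0, y, pars, vs = 0,
                                        jin_enabled = TRUE,
                                        ps_active = ps_active))
  # indices of the unknowns: drop Ct for a closed cell, drop Ps unless active
  idx <- setdiff(seq_len(7L),
                 c(if (closed) 2L, if (!ps_active) 7L))
  f_sub <- function(x) {
    y <- y0
    y[idx] <- x
    f_full(y)[idx]
  }
  newton <- function(x) {
    for (it in seq_len(60L)) {
      fx <- f_sub(x)
      if (max(abs(fx)) <= tol) return(list(x = x, ok = TRUE))
      J <- pracma::jacobian(f_sub, x)
      step <- tryCatch(solve(J, fx), error = function(e) NULL)
      if (is.null(step)) return(list(x = x, ok = FALSE))
      lam <- 1
      repeat {
        xn <- x - lam * step
        fn <- tryCatch(f_sub(xn), error = function(e) NULL)
        if (!is.null(fn) && all(is.finite(fn)) &&
            max(abs(fn)) < max(abs(fx))) break
        lam <- lam / 2
        if (lam < 1e-8) return(list(x = x, ok = FALSE))
      }
      x <- xn
    }
    list(x = x, ok = max(abs(f_sub(x))) <= tol)
  }
  relax <- function(y, t_end) {
    out <- deSolve::ode(
      y = y, times = c(0, t_end),
      func = function(t, y, parms) rhs_core(t, y, pars, 0, TRUE, ps_active),
      parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
    y1 <- out[nrow(out), -1]
    if (closed) y1[["Ct"]] <- Ct
    if (!ps_active) y1[["Ps"]] <- 0
    y1
  }
  y <- relax(y0, t_relax)
  res <- newton(y[idx])
  if (!res$ok) {
    y <- relax(y, 5 * t_relax)
    res <- newton(y[idx])
  }
  if (!res$ok)
    stop("no convergence: resting state not found (nu = ", pars$nu, ")")
  y[idx] <- res$x
  hsy_state(C = y[["C"]], Ct = y[["Ct"]], Cb = y[["Cb"]], P = y[["P"]],
            m42 = min(max(y[["m42"]], 0), 1),
            h42 = min(max(y[["h42"]], 0), 1), Ps = y[["Ps"]])
}

new_segment <- function(t_start, t_end, overrides = list(), vs_plc = 0,
                        jin_enabled = TRUE) {
  list(t_start = t_start, t_end = t_end, overrides = overrides,
       vs_plc = vs_plc, jin_enabled = jin_enabled)
}

new_protocol <- function(name, segments, t_final, record_step,
                         base = list(), ps_active = FALSE,
                         equilibrate = list()) {
  starts <- vapply(segments, `[[`, numeric(1), "t_start")
  ends <- vapply(segments, `[[`, numeric(1), "t_end")
  if (starts[1] != 0 || ends[length(ends)] != t_final ||
      (length(starts) > 1 && any(abs(starts[-1] - ends[-length(ends)]) >
                                   1e-12)))
    stop("segments must be contiguous, non-overlapping and cover [0, t_final]")
  structure(list(name = name, segments = segments, t_final = t_final,
                 record_step = record_step, base = base,
                 ps_active = ps_active, equilibrate = equilibrate),
            class = "hsy_protocol")
}

#' Construct a virtual experimental protocol
#'
#' Builds one of the model's virtual experiments as a time-segmented
#' schedule of parameter overrides, pre-filled with the published protocol
#' settings; `...` overrides the documented knobs of each protocol.
#'
#' @param name one of:
#' \describe{
#'   \item{`"agonist_step"`}{open cell stimulated with agonist `nu`
#'     (default 15 uM) from `t = 0`; alternatively a stepwise
#'     `nu_schedule` data frame with columns `t_start`, `nu`.
#'     Knobs: `nu`, `nu_schedule`, `t_final` (600 s), `record_step` (0.01 s).}
#'   \item{`"closed_cell"`}{closed cell (`epsilon = 0`) at fixed total
#'     calcium `Ct` (68 uM), stimulated with `nu` (15 uM) from `t = 0`.
#'     Knobs: `nu`, `Ct`, `t_final` (600 s), `record_step` (0.01 s).}
#'   \item{`"calcium_free"`}{open cell at `nu` (20 uM); plasma-membrane
#'     influx removed (`J_in = 0`) for `t > t_cut` (120 s).
#'     Knobs: `nu`, `t_cut`, `t_final` (2500 s), `record_step` (0.05 s).}
#'   \item{`"ip3_pulse"`}{open cell at `nu` (15 uM) with a photoreleased-IP3
#'     pulse of magnitude `M` (0.04 uM/s) and duration `Delta` (0.7 s) at
#'     `t0` (200 s); `r_s_deg` 0.006 /s.
#'     Knobs: `nu`, `M`, `Delta`, `t0`, `r_s_deg`, `t_final` (600 s),
#'     `record_step` (0.01 s).}
#'   \item{`"plc_inhibition"`}{no agonist; continuous uncaging at `k_s_plc`
#'     (0.0006 uM/s) from `t = 0`; PLC inhibitor modelled as stepwise drops
#'     of `(psi2, V_S)` from (0.8, 10) to (0.4, 9.5) at `t1` (600 s) and to
#'     (0, 9) at `t2` (900 s).
#'     Knobs: `k_s_plc`, `r_s_deg`, `t1`, `t2`, `stages` (3x2 matrix-like
#'     data frame with columns `psi2`, `V_S`), `t_final` (1200 s),
#'     `record_step` (0.05 s).}
#'   \item{`"uncaging_after_inhibition"`}{PLC fully inhibited from the start
#'     (`psi2 = 0`, `V_S = 9` uM/s); continuous uncaging switched on at
#'     `t_uv` (200 s) with `k_s_plc` (0.0006 uM/s; 0.00056 is the
#'     alternative reported setting).
#'     Knobs: `k_s_plc`, `r_s_deg`, `t_uv`, `psi2`, `V_S`,
#'     `t_final` (1200 s), `record_step` (0.05 s).}
#'   \item{`"psi2_scan"`}{no agonist; continuous uncaging at `k_s_plc`
#'     (0.0006 uM/s) from `t = 0` with fixed `psi2` (0.8 uM/s) and `V_S`
#'     (10 uM/s); used to measure long-term stable periods as a function of
#'     `(psi2, V_S, k_s_plc)`.
#'     Knobs: `psi2`, `V_S`, `k_s_plc`, `r_s_deg`, `t_final` (2500 s),
#'     `record_step` (0.05 s).}
#' }
#' @param ... protocol knobs, as listed above.
#' @return An object of class `"hsy_protocol"`.
#' @examples
#' make_protocol("ip3_pulse")$segments[[2]]  # the 0.7-s pulse segment
#' @export
make_protocol <- function(name, ...) {
  opts <- list(...)
  grab <- function(key, default) if (key %in% names(opts)) opts[[key]] else
    default
  allow <- function(keys) {
    bad <- setdiff(names(opts), keys)
    if (length(bad))
      stop("unknown option(s) for protocol '", name, "': ",
           paste(bad, collapse = ", "))
  }
  switch(name,
    agonist_step = {
      allow(c("nu", "nu_schedule", "t_final", "record_step"))
      t_final <- grab("t_final", 600)
      rs <- grab("record_step", 0.01)
      sched <- grab("nu_schedule",
                    data.frame(t_start = 0, nu = grab("nu", 15)))
      if (any(sched$nu < 0)) stop("inadmissible option: nu must be >= 0")
      bounds <- c(sched$t_start, t_final)
      segs <- lapply(seq_len(nrow(sched)), function(i)
        new_segment(bounds[i], bounds[i + 1],
                    overrides = list(nu = sched$nu[i])))
      new_protocol(name, segs, t_final, rs)
    },
    closed_cell = {
      allow(c("nu", "Ct", "t_final", "record_step"))
      t_final <- grab("t_final", 600)
      nu <- grab("nu", 15)
      if (nu < 0) stop("inadmissible option: nu must be >= 0")
      segs <- list(new_segment(0, t_final, overrides = list(nu = nu)))
      new_protocol(name, segs, t_final, grab("record_step", 0.01),
                   base = list(epsilon = 0),
                   equilibrate = list(Ct = grab("Ct", 68)))
    },
    calcium_free = {
      allow(c("nu", "t_cut", "t_final", "record_step"))
      t_final <- grab("t_final", 2500)
      t_cut <- grab("t_cut", 120)
      nu <- grab("nu", 20)
      segs <- list(
        new_segment(0, t_cut, overrides = list(nu = nu)),
        new_segment(t_cut, t_final, overrides = list(nu = nu),
                    jin_enabled = FALSE))
      new_protocol(name, segs, t_final, grab("record_step", 0.05))
    },
    ip3_pulse = {
      allow(c("nu", "M", "Delta", "t0", "r_s_deg", "t_final", "record_step"))
      t_final <- grab("t_final", 600)
      t0 <- grab("t0", 200)
      M <- grab("M", 0.04)
      Delta <- grab("Delta", 0.7)
      nu <- grab("nu", 15)
      segs <- list(
        new_segment(0, t0, overrides = list(nu = nu)),
        new_segment(t0, t0 + Delta, overrides = list(nu = nu), vs_plc = M),
        new_segment(t0 + Delta, t_final, overrides = list(nu = nu)))
      new_protocol(name, segs, t_final, grab("record_step", 0.01),
                   base = list(r_s_deg = grab("r_s_deg", 0.006)),
                   ps_active = TRUE)
    },
    plc_inhibition = {
      allow(c("k_s_plc", "r_s_deg", "t1", "t2", "stages", "t_final",
              "record_step"))
      t_final <- grab("t_final", 1200)
      ks <- grab("k_s_plc", 0.0006)
      stages <- grab("stages",
                     data.frame(psi2 = c(0.8, 0.4, 0), V_S = c(10, 9.5, 9)))
      bounds <- c(0, grab("t1", 600), grab("t2", 900), t_final)
      segs <- lapply(1:3, function(i)
        new_segment(bounds[i], bounds[i + 1],
                    overrides = list(nu = 0, psi2 = stages$psi2[i],
                                     V_S = stages$V_S[i]),
                    vs_plc = ks))
      new_protocol(name, segs, t_final, grab("record_step", 0.05),
                   base = list(r_s_deg = grab("r_s_deg", 0.006),
                               k_s_plc = ks),
                   ps_active = TRUE)
    },
    uncaging_after_inhibition = {
      allow(c("k_s_plc", "r_s_deg", "t_uv", "psi2", "V_S", "t_final",
              "record_step"))
      t_final <- grab("t_final", 1200)
      ks <- grab("k_s_plc", 0.0006)
      t_uv <- grab("t_uv", 200)
      ov <- list(nu = 0, psi2 = grab("psi2", 0), V_S = grab("V_S", 9))
      segs <- list(
        new_segment(0, t_uv, overrides = ov),
        new_segment(t_uv, t_final, overrides = ov, vs_plc = ks))
      new_protocol(name, segs, t_final, grab("record_step", 0.05),
                   base = list(r_s_deg = grab("r_s_deg", 0.006),
                               k_s_plc = ks),
                   ps_active = TRUE)
    },
    psi2_scan = {
      allow(c("psi2", "V_S", "k_s_plc", "r_s_deg", "t_final", "record_step"))
      t_final <- grab("t_final", 2500)
      ks <- grab("k_s_plc", 0.0006)
      segs <- list(new_segment(0, t_final,
                               overrides = list(nu = 0,
                                                psi2 = grab("psi2", 0.8),
                                                V_S = grab("V_S", 10)),
                               vs_plc = ks))
      new_protocol(name, segs, t_final, grab("record_step", 0.05),
                   base = list(r_s_deg = grab("r_s_deg", 0.006),
                               k_s_plc = ks),
                   ps_active = TRUE)
    },
    stop("unknown protocol name: '", name, "'")
  )
}

#' Simulate a protocol
#'
#' Integrates the model over a protocol's schedule with the stiff `lsoda`
#' integrator, restarting at every segment boundary (parameter switches and
#' pulse edges are instantaneous, never smoothed). The run starts from the
#' unstimulated resting state ([find_resting_state()] at `nu = 0`, under
#' `epsilon = 0` and the protocol's fixed `Ct` for closed-cell protocols)
#' unless `initial_state` is given.
#'
#' @param protocol an [make_protocol()] object.
#' @param pars base parameters; protocol overrides are applied on top.
#' @param initial_state optional [hsy_state()] to start from.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @return A data frame of class `"hsy_trajectory"` with columns `time_s`,
#'   the seven state variables, and the derived series `CER`, `P_total`,
#'   `O_IPR`; the generating protocol and solver diagnostics are attached
#'   as attributes `"protocol"` and `"diagnostics"`.
#' @examples
#' \donttest{
#' traj <- simulate_protocol(make_protocol("agonist_step", t_final = 200))
#' range(traj$C)
#' }
#' @export
simulate_protocol <- function(protocol, pars = hsy_pars(),
                              initial_state = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "hsy_protocol"))
  base <- pars
  if (length(protocol$base))
    base <- do.call(hsy_pars, utils::modifyList(unclass(base),
                                                protocol$base))
  if (is.null(initial_state)) {
    eq <- protocol$equilibrate
    rest_pars <- do.call(hsy_pars, utils::modifyList(unclass(base),
                                                     list(nu = 0)))
    initial_state <- find_resting_state(
      rest_pars,
      Ct = if (!is.null(eq$Ct)) eq$Ct else 68)
  }
  y <- unclass(initial_state)[state_names]
  rows <- vector("list", length(protocol$segments))
  nsteps <- 0L
  for (i in seq_along(protocol$segments)) {
    seg <- protocol$segments[[i]]
    seg_pars <- if (length(seg$overrides))
      do.call(hsy_pars, utils::modifyList(unclass(base), seg$overrides))
    else base
    times <- seq(seg$t_start, seg$t_end, by = protocol$record_step)
    if (times[length(times)] < seg$t_end) times <- c(times, seg$t_end)
    out <- tryCatch(
      deSolve::ode(y = y, times = times,
                   func = function(t, y, parms)
                     rhs_core(t, y, seg_pars, seg$vs_plc, seg$jin_enabled,
                              protocol$ps_active),
                   parms = NULL, method = "lsoda",
                   rtol = rtol, atol = atol),
      error = function(e)
        stop("simulation of '", protocol$name, "' failed in segment ", i,
             " [", seg$t_start, ", ", seg$t_end, "] s: ",
             conditionMessage(e), call. = FALSE))
    nsteps <- nsteps + attr(out, "istate")[3]
    y <- out[nrow(out), state_names]
    rows[[i]] <- if (i == 1L) out else out[-1L, , drop = FALSE]
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df)[1] <- "time_s"
  df$CER <- base$gamma2 * (df$Ct - df$C - df$Cb / base$gamma1)
  df$P_total <- df$P + df$Ps
  df$O_IPR <- open_probability_series(df, base)
  structure(df, class = c("hsy_trajectory", "data.frame"),
            protocol = protocol,
            diagnostics = list(n_steps = nsteps, rtol = rtol, atol = atol,
                               initial_state = initial_state))
}

# Vectorised open probability along a trajectory (gating constants do not
# change across protocol segments).
open_probability_series <- function(df, pars) {
  P_eff <- df$P + df$Ps
  P2 <- P_eff^2; P3 <- P_eff^3
  V24 <- 62 + 880 / (P2 + 4)
  a24 <- 1 + 5 / (P2 + 0.25)
  V42 <- 110 * P2 / (P2 + 0.01)
  a42 <- 1.8 * P2 / (P2 + 0.34)
  k42 <- 0.49 + 0.543 * P3 / (P3 + 64)
  k_m42 <- 0.41 + 25 * P3 / (P3 + 274.6)
  Cp <- pmax(pars$C_p0 * (df$CER / pars$C_ER_ref), 0)
  Cb3 <- df$Cb^3; Cp3 <- Cp^3
  m24_inf <- Cp3 / (Cp3 + 0.35^3)
  h24_inf <- 80^2 / (Cp^2 + 80^2)
  q24 <- a24 + V24 * (1 - m24_inf * h24_inf)
  q42 <- a42 + V42 * df$m42 * df$h42
  D <- q42 * (pars$q62 + pars$q26) /
    (q42 * pars$q62 + q42 * pars$q26 + q24 * pars$q62)
  pars$q26 / (pars$q62 + pars$q26) * D
}

#' Closed-cell oscillation scan over total calcium
#'
#' For each fixed total calcium `Ct`, simulates the closed-cell model at
#' agonist `nu` and classifies the run as oscillatory or not by spike
#' counting over the final analysis window (at least 3 spikes of amplitude
#' `min_prominence` or more above the running baseline).
#'
#' @param pars base parameters (`epsilon` is forced to 0).
#' @param nu agonist concentration (uM).
#' @param Ct_grid increasing vector of total calcium values (uM).
#' @param t_final simulated time per grid point (s).
#' @param window_length length of the final classification window (s).
#' @param min_prominence spike amplitude threshold (uM).
#' @return Data frame with columns `Ct`, `oscillatory` (logical, `NA` when
#'   the simulation failed) and `error` (message or `NA`).
#' @export
closed_cell_oscillatory_range <- function(pars = hsy_pars(), nu = 15,
                                          Ct_grid, t_final = 2000,
                                          window_length = 600,
                                          min_prominence = 0.05) {
  if (any(diff(Ct_grid) <= 0) || any(Ct_grid <= 0))
    stop("Ct_grid must be positive and increasing")
  res <- lapply(Ct_grid, function(Ct) {
    tryCatch({
      proto <- make_protocol("closed_cell", nu = nu, Ct = Ct,
                             t_final = t_final, record_step = 0.05)
      traj <- simulate_protocol(proto, pars)
      list(osc = is_oscillatory(traj,
                                window = c(t_final - window_length, t_final),
                                min_prominence = min_prominence),
           err = NA_character_)
    }, error = function(e) list(osc = NA, err = conditionMessage(e)))
  })
  data.frame(Ct = Ct_grid,
             oscillatory = vapply(res, `[[`, logical(1), "osc"),
             error = vapply(res, `[[`, character(1), "err"))
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time_s, C, Ct, Cb, CER, P, Ps, P_total, m42, h42, O_IPR`.
#'
#' @param traj an `"hsy_trajectory"` (or compatible data frame).
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the data frame.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time_s", "C", "Ct", "Cb", "CER", "P", "Ps", "P_total",
            "m42", "h42", "O_IPR")
  utils::write.csv(as.data.frame(traj)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "C", "P")
  if (!all(need %in% names(df)))
    stop("not a trajectory file: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  structure(df, class = c("hsy_trajectory", "data.frame"))
}

#' Serialize / deserialize a protocol as JSON
#'
#' Round-trips the full segment schedule, so protocols can be stored beside
#' the trajectories they generated.
#'
#' @param protocol an `"hsy_protocol"`.
#' @param path file path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol` the
#'   protocol object.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  segs <- lapply(x$segments, function(s)
    new_segment(s$t_start, s$t_end,
                overrides = lapply(s$overrides, identity),
                vs_plc = s$vs_plc, jin_enabled = s$jin_enabled))
  new_protocol(x$name, segs, x$t_final, x$record_step,
               base = lapply(x$base, identity),
               ps_active = isTRUE(x$ps_active),
               equilibrate = lapply(x$equilibrate, identity))
}
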