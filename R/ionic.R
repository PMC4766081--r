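#' Ionic remodeling scalers
#'
#' Multiplicative factors applied to the maximal conductances/currents of the
#' Courtemanche human atrial cell model.  The persistent-AF ("peaf") set
#' reduces INa to 90%, Ito to 30%, ICaL to 50% and IKur to 50%, doubles IK1,
#' and increases INaCa(max) by 40% and Iup(max) by 25%; this remodeling
#' shortens the action potential enough for reentry to be sustained.
#'
#' @param preset "control" (all ones) or "peaf".
#' @return named numeric vector of class `remodeling_scalers` with elements
#'   sNa, sTo, sCaL, sK1, sKur, sNaCa, sUp.
#' @export
remodeling_scalers <- function(preset = c("control", "peaf")) {
  preset <- match.arg(preset)
  s <- if (preset == "peaf") {
    c(sNa = 0.9, sTo = 0.3, sCaL = 0.5, sK1 = 2.0, sKur = 0.5,
      sNaCa = 1.4, sUp = 1.25)
  } else {
    c(sNa = 1, sTo = 1, sCaL = 1, sK1 = 1, sKur = 1, sNaCa = 1, sUp = 1)
  }
  structure(s, class = "remodeling_scalers", preset = preset)
}

#' Ionic parameter set for the atrial cell model
#'
#' Control maximal conductances (nS/pF) and maximal currents (pA/pF, mM/ms) of
#' the Courtemanche model: gNa 7.8, gto 0.1652, gCaL 0.1238, gK1 0.09,
#' INaCa(max) 1600, Iup(max) 0.005.  The voltage-dependent IKur conductance is
#' represented by its scale factor `sKur` applied to [gkur()].
#'
#' @param preset "control" or "peaf"; "peaf" applies [remodeling_scalers()].
#' @return list of class `ionic_params`.
#' @seealso [apply_remodeling()], [gkur()]
#' @export
ionic_params <- function(preset = c("control", "peaf")) {
  preset <- match.arg(preset)
  p <- structure(list(gNa = 7.8, gto = 0.1652, gCaL = 0.1238, gK1 = 0.09,
                      sKur = 1.0, INaCaMax = 1600, IupMax = 0.005,
                      preset = "control"),
                 class = "ionic_params")
  if (preset == "peaf") p <- apply_remodeling(p, remodeling_scalers("peaf"))
  p
}

#' Apply conductance remodeling to a control parameter set
#'
#' @param params control `ionic_params`.
#' @param s `remodeling_scalers` (or named vector with the same elements).
#' @return remodeled `ionic_params`.
#' @export
apply_remodeling <- function(params, s) {
  if (any(unlist(s) < 0)) stopf("negative remodeling scaler rejected")
  params$gNa <- params$gNa * s[["sNa"]]
  params$gto <- params$gto * s[["sTo"]]
  params$gCaL <- params$gCaL * s[["sCaL"]]
  params$gK1 <- params$gK1 * s[["sK1"]]
  params$sKur <- params$sKur * s[["sKur"]]
  params$INaCaMax <- params$INaCaMax * s[["sNaCa"]]
  params$IupMax <- params$IupMax * s[["sUp"]]
  pr <- attr(s, "preset")
  params$preset <- if (!is.null(pr)) pr else "custom"
  params
}

#' Voltage-dependent maximal conductance of IKur
#'
#' gKur(V) = 0.005 + 0.05 / (1 + exp(-(V - 15)/13)) nS/pF.
#'
#' @param V membrane potential (mV).
#' @return conductance (nS/pF).
#' @export
gkur <- function(V) 0.005 + 0.05 / (1 + exp(-(V - 15) / 13))

#' State variable names of the 21-variable atrial cell model
#' @return character vector of length 21.
#' @export
cell_state_names <- function() {
  c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
    "d", "f", "fCa", "u", "v", "w", "Nai", "Ki", "Cai", "CaUp", "CaRel")
}

#' Resting cell state
#'
#' The published Courtemanche resting initial condition, optionally relaxed to
#' the model's quiescent fixed point for the given (possibly remodeled)
#' parameter set.
#'
#' @param params `ionic_params`; default control.
#' @param settle_ms quiescent integration time (ms) used to relax to rest;
#'   0 returns the published values unmodified.
#' @return named numeric vector of length 21.
#' @export
resting_state <- function(params = ionic_params(), settle_ms = 20000) {
  s <- crn_resting_state_cpp()
  if (settle_ms > 0) {
    s <- crn_cell_sim_cpp(s, params, settle_ms, 0.05, settle_ms,
                          numeric(0), 2, 0)$state
  }
  names(s) <- cell_state_names()
  s
}

#' Time derivatives of the cell state
#'
#' Right-hand side of the 21-variable Courtemanche ODE system: dV/dt =
#' -(Iion + Is) with Iion the sum of the 12 membrane currents, plus all gate
#' and concentration derivatives.
#'
#' @param state numeric vector of length 21 (see [cell_state_names()]).
#' @param params `ionic_params`.
#' @param stim stimulus current density (pA/pF; inward negative).
#' @return named numeric vector of derivatives (per ms).
#' @export
ionic_rhs <- function(state, params = ionic_params(), stim = 0) {
  ds <- crn_rhs_cpp(as.numeric(state), params, stim)
  names(ds) <- cell_state_names()
  ds
}

#' Integrate a single cell
#'
#' Rush-Larsen (gates) / forward-Euler (V, concentrations) integration of one
#' cell with periodic current-pulse pacing.
#'
#' @param params `ionic_params`.
#' @param state0 initial state; default published resting state.
#' @param duration total time (ms).
#' @param pace_cl pacing cycle length (ms); `NA` disables pacing.
#' @param pace_amp,pace_dur pulse amplitude (pA/pF) and width (ms).
#' @param dt ODE step (ms).
#' @param sample_dt output sampling (ms).
#' @param full_state also return all 21 sampled variables.
#' @return list with `t`, `v`, final `state`, and optionally `states`
#'   (21 x samples matrix).
#' @export
simulate_cell <- function(params = ionic_params(), state0 = NULL,
                          duration = 2000, pace_cl = 1000, pace_amp = -30,
                          pace_dur = 2, dt = 0.02, sample_dt = 1,
                          full_state = FALSE) {
  if (is.null(state0)) state0 <- crn_resting_state_cpp()
  stim_times <- if (is.na(pace_cl)) numeric(0) else seq(1, duration, by = pace_cl)
  out <- crn_cell_sim_cpp(as.numeric(state0), params, duration, dt, sample_dt,
                          stim_times, pace_dur, pace_amp, full_state)
  names(out$state) <- cell_state_names()
  out
}

#' Action potential duration at 90% repolarization
#'
#' @param t,v sampled time (ms) and membrane potential (mV) of one beat
#'   (upstroke included).
#' @return APD90 in ms (NA if no complete AP).
#' @export
apd90 <- function(t, v) {
  vr <- v[1]
  vmax <- max(v)
  thr <- vmax - 0.9 * (vmax - vr)
  above <- v > thr
  up <- which(diff(above) == 1)
  if (!length(up) && above[1]) up <- 0L
  if (!length(up)) return(NA_real_)
  up <- up[1]
  dn <- which(diff(above) == -1)
  dn <- dn[dn > up]
  if (!length(dn)) return(NA_real_)
  t[dn[1]] - t[max(up, 1L)]
}

#' @export
print.ionic_params <- function(x, ...) {
  cat("Atrial ionic parameter set (preset:", x$preset, ")\n")
  cat(sprintf("  gNa %.4g  gto %.4g  gCaL %.4g  gK1 %.4g nS/pF\n",
              x$gNa, x$gto, x$gCaL, x$gK1))
  cat(sprintf("  IKur scale %.3g;  INaCa(max) %.4g pA/pF;  Iup(max) %.4g mM/ms\n",
              x$sKur, x$INaCaMax, x$IupMax))
  invisible(x)
}
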