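#' Channel kinetics parameter sets
#'
#' Gating kinetics for the six conductances carried by the model: Nav1.2,
#' Nav1.6, delayed-rectifier K (Kdr), low-threshold slowly inactivating Kv1
#' (ID-type), P/Q-type Ca, and ohmic leak. The rate equations follow the
#' standard forms of the published L5 axon model family: trap-function
#' alpha/beta rates for Nav (m^3 h) and Kdr (n), Boltzmann steady states with
#' a fixed slow inactivation time constant for Kv1 (m h), and a Boltzmann
#' activation scheme for the presynaptic Ca channel. The reproduced study
#' prints channel densities but not rate equations, so the rate constants
#' live here as data and can be swapped wholesale (see
#' \code{\link{default_kinetics}}).
#'
#' Voltages are mV, times ms, temperature is fixed at 37 C: the Nav/Kdr rate
#' constants are defined at 23 C and scaled by a Q10 of 2.3; Kv1 and Ca
#' constants are given directly at 37 C (the 1,500 ms Kv1 inactivation time
#' constant is the operative value at simulation temperature).
#'
#' @return A named list with one entry per channel; each entry is a list of
#'   numeric parameters plus the reversal potential \code{erev} (mV).
#' @export
default_kinetics <- function() {
  q10 <- 2.3^((37 - 23) / 10)
  list(
    erev = c(na = 60, k = -90, ca = 140),
    nav12 = list(
      gates = "m3h", erev = 60, rate_scale = q10,
      tha = -23, qa = 9, Ra = 0.182, Rb = 0.124,
      thi1 = -38, thi2 = -63, qd = 5, qg = 5, Rd = 0.024, Rg = 0.0091,
      thinf = -53, qinf = 6.2
    ),
    nav16 = list(
      gates = "m3h", erev = 60, rate_scale = q10,
      tha = -35, qa = 9, Ra = 0.182, Rb = 0.124,
      thi1 = -50, thi2 = -75, qd = 5, qg = 5, Rd = 0.024, Rg = 0.0091,
      thinf = -65, qinf = 12
    ),
    kdr = list(
      gates = "n", erev = -90, rate_scale = q10,
      tha = 25, qa = 9, Ra = 0.02, Rb = 0.002
    ),
    kv1 = list(
      gates = "mh", erev = -90,
      vm_half = -51.2, vm_k = 6, taum_min = 0.5, taum_amp = 0.3,
      taum_vhalf = -50, taum_k = 10,
      vh_half = -70, vh_k = 9, tauh = 1500
    ),
    capq = list(
      gates = "m_pow", erev = 140, power = 2,
      vm_half = 15, vm_k = 12, taum_min = 0.3, taum_amp = 0.3,
      taum_vhalf = -25, taum_k = 10
    )
  )
}

## trap rate with removable singularity at v == th
trap_rate <- function(v, th, a, q) {
  x <- v - th
  ifelse(abs(x / q) < 1e-6, a * q * (1 + x / (2 * q)), a * x / (1 - exp(-x / q)))
}

boltz <- function(v, vhalf, k) 1 / (1 + exp(-(v - vhalf) / k))

#' Steady-state gating values and time constants
#'
#' Evaluate the activation/inactivation steady states and time constants of
#' one channel at membrane potential \code{v}. Used for initialization, for
#' the steady-state solver, and as the R-side reference the compiled stepper
#' is tested against.
#'
#' @param kin one channel entry of \code{\link{default_kinetics}}
#' @param v membrane potential (mV), vectorized
#' @return list with per-gate \code{inf} and \code{tau} (ms)
#' @export
gate_steady <- function(kin, v) {
  if (kin$gates %in% c("m3h")) {
    am <- trap_rate(v, kin$tha, kin$Ra, kin$qa)
    bm <- trap_rate(-v, -kin$tha, kin$Rb, kin$qa)
    ah <- trap_rate(v, kin$thi1, kin$Rd, kin$qd)
    bh <- trap_rate(-v, -kin$thi2, kin$Rg, kin$qg)
    s <- kin$rate_scale
    list(
      m = list(inf = am / (am + bm), tau = 1 / (s * (am + bm))),
      h = list(inf = boltz(-v, -kin$thinf, kin$qinf), tau = 1 / (s * (ah + bh)))
    )
  } else if (kin$gates == "n") {
    an <- trap_rate(v, kin$tha, kin$Ra, kin$qa)
    bn <- trap_rate(-v, -kin$tha, kin$Rb, kin$qa)
    s <- kin$rate_scale
    list(n = list(inf = an / (an + bn), tau = 1 / (s * (an + bn))))
  } else if (kin$gates == "mh") {
    list(
      m = list(
        inf = boltz(v, kin$vm_half, kin$vm_k),
        tau = kin$taum_min + kin$taum_amp * boltz(-v, -kin$taum_vhalf, kin$taum_k)
      ),
      h = list(inf = boltz(-v, -kin$vh_half, kin$vh_k), tau = rep(kin$tauh, length(v)))
    )
  } else if (kin$gates == "m_pow") {
    list(m = list(
      inf = boltz(v, kin$vm_half, kin$vm_k),
      tau = kin$taum_min + kin$taum_amp * boltz(-v, -kin$taum_vhalf, kin$taum_k)
    ))
  } else {
    stop("unknown gate scheme: ", kin$gates)
  }
}

#' Open fraction of a channel at steady state
#'
#' @inheritParams gate_steady
#' @return open probability (product of gates raised to their powers)
#' @export
open_fraction_steady <- function(kin, v) {
  g <- gate_steady(kin, v)
  switch(kin$gates,
    m3h = g$m$inf^3 * g$h$inf,
    n = g$n$inf,
    mh = g$m$inf * g$h$inf,
    m_pow = g$m$inf^kin$power
  )
}

#' Initialize all gating variables at their steady state
#'
#' Sets every gate of every channel to its steady-state value at the clamped
#' potential \code{v}, so that d(state)/dt = 0 when the voltage is held.
#'
#' @param v membrane potential (mV), scalar or per-compartment vector
#' @param kinetics kinetics set, default \code{\link{default_kinetics}()}
#' @return named list of gate vectors (m12, h12, m16, h16, n_kdr, m_kv1,
#'   h_kv1, m_ca), each the length of \code{v}
#' @export
init_steady_state <- function(v, kinetics = default_kinetics()) {
  g12 <- gate_steady(kinetics$nav12, v)
  g16 <- gate_steady(kinetics$nav16, v)
  gk <- gate_steady(kinetics$kdr, v)
  g1 <- gate_steady(kinetics$kv1, v)
  gc <- gate_steady(kinetics$capq, v)
  list(
    m12 = g12$m$inf, h12 = g12$h$inf,
    m16 = g16$m$inf, h16 = g16$h$inf,
    n_kdr = gk$n$inf,
    m_kv1 = g1$m$inf, h_kv1 = g1$h$inf,
    m_ca = gc$m$inf
  )
}

## flatten one kinetics set to the numeric vector layout the C++ stepper uses
kinetics_pack <- function(kinetics) {
  k <- kinetics
  c(
    # nav12: tha qa Ra Rb thi1 thi2 qd qg Rd Rg thinf qinf scale
    k$nav12$tha, k$nav12$qa, k$nav12$Ra, k$nav12$Rb, k$nav12$thi1, k$nav12$thi2,
    k$nav12$qd, k$nav12$qg, k$nav12$Rd, k$nav12$Rg, k$nav12$thinf, k$nav12$qinf,
    k$nav12$rate_scale,
    k$nav16$tha, k$nav16$qa, k$nav16$Ra, k$nav16$Rb, k$nav16$thi1, k$nav16$thi2,
    k$nav16$qd, k$nav16$qg, k$nav16$Rd, k$nav16$Rg, k$nav16$thinf, k$nav16$qinf,
    k$nav16$rate_scale,
    # kdr: tha qa Ra Rb scale
    k$kdr$tha, k$kdr$qa, k$kdr$Ra, k$kdr$Rb, k$kdr$rate_scale,
    # kv1: vm_half vm_k taum_min taum_amp taum_vhalf taum_k vh_half vh_k tauh
    k$kv1$vm_half, k$kv1$vm_k, k$kv1$taum_min, k$kv1$taum_amp,
    k$kv1$taum_vhalf, k$kv1$taum_k, k$kv1$vh_half, k$kv1$vh_k, k$kv1$tauh,
    # capq: vm_half vm_k taum_min taum_amp taum_vhalf taum_k power
    k$capq$vm_half, k$capq$vm_k, k$capq$taum_min, k$capq$taum_amp,
    k$capq$taum_vhalf, k$capq$taum_k, k$capq$power,
    # reversals: na k ca
    k$nav12$erev, k$kdr$erev, k$capq$erev
  )
}
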