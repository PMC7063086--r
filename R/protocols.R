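#' Stimulation protocol descriptions
#'
#' The three somatic current injections: a 3 nA / 3 ms spike trigger, a
#' +322 pA / 10 s conditioning depolarization (d-ADF; soma to about -55 mV)
#' and a -344 pA / 200 ms conditioning hyperpolarization (h-ADF; soma to
#' about -85 mV). The conditioning current stays on during the trigger, so
#' the spike leaves from the conditioned potential.
#'
#' @param kind "rest" (trigger only), "dadf" or "hadf"
#' @param cond_amp conditioning amplitude (nA); defaults 0.322 / -0.344
#' @param cond_dur conditioning duration (ms); defaults 10000 / 200
#' @param trigger_amp,trigger_dur spike trigger (nA, ms)
#' @param window_ms recorded spike window from trigger onset (ms)
#' @param dt_spike,dt_sub time steps for the spike window and the
#'   conditioning phase (ms)
#' @return list of class \code{stim_protocol}
#' @export
stim_protocol <- function(kind = c("rest", "dadf", "hadf"),
                          cond_amp = NULL, cond_dur = NULL,
                          trigger_amp = 3, trigger_dur = 3,
                          window_ms = 30, dt_spike = 6.25e-3,
                          dt_sub = NULL) {
  kind <- match.arg(kind)
  if (is.null(cond_amp)) {
    cond_amp <- switch(kind, rest = 0, dadf = 0.322, hadf = -0.344)
  }
  if (is.null(cond_dur)) {
    cond_dur <- switch(kind, rest = 0, dadf = 10000, hadf = 200)
  }
  if (is.null(dt_sub)) dt_sub <- switch(kind, rest = 0.5, dadf = 0.5, hadf = 0.05)
  if (kind != "rest" && cond_dur <= 0) stop("conditioning duration must be > 0")
  # the 10 s depolarization settles every state variable (the slowest, Kv1
  # inactivation, has tau 1.5 s; the sheathed-internode relaxation ~0.3 s),
  # so it is computed with the steady-state fast path by default; the 200 ms
  # hyperpolarization is explicitly non-stationary and runs in the time domain
  cond_mode <- switch(kind, rest = "none", dadf = "steady", hadf = "time")
  structure(
    list(
      kind = kind, cond_amp = cond_amp, cond_dur = cond_dur,
      trigger_amp = trigger_amp, trigger_dur = trigger_dur,
      window_ms = window_ms, dt_spike = dt_spike, dt_sub = dt_sub,
      cond_mode = cond_mode
    ),
    class = "stim_protocol"
  )
}

#' Run a somatic stimulation protocol
#'
#' Initializes at rest, applies the conditioning phase (time domain, coarse
#' implicit steps), then records the spike window at the fine step at the
#' main-axon measurement nodes and the requested presynaptic sites.
#'
#' @param model \code{cable_model}
#' @param protocol \code{\link{stim_protocol}}
#' @param sites site indices (rows of the morphology site table) to record;
#'   defaults to all sites
#' @param rest optional precomputed \code{\link{rest_state}}
#' @return \code{trace_set}: time base \code{t} (ms, 0 at trigger onset),
#'   node and site voltage matrices, site Ca currents, the end-of-conditioning
#'   voltage vector \code{cond_V} and the rest voltage vector \code{rest_V},
#'   plus the stimulus record
#' @export
run_protocol <- function(model, protocol, sites = NULL, rest = NULL) {
  if (is.null(rest)) rest <- rest_state(model)
  if (is.null(sites)) sites <- seq_along(model$site_comp)
  site_comp <- model$site_comp[sites]
  rec_v <- c(model$soma_comp, model$axon_start_comp, model$node_comp, site_comp)
  soma <- model$soma_comp

  state <- rest
  cond_V <- rest$V
  if (protocol$kind != "rest" && protocol$cond_dur > 0 && protocol$cond_amp != 0) {
    if (identical(protocol$cond_mode, "steady")) {
      state <- steady_state(
        model, data.frame(comp = soma, amp = protocol$cond_amp), v0 = rest$V
      )
    } else {
      cond <- run_sim(
        model, state, protocol$dt_sub, protocol$cond_dur,
        inj = data.frame(comp = soma, amp = protocol$cond_amp)
      )
      state <- cond$state
    }
    cond_V <- state$V
  }
  inj_on <- data.frame(
    comp = c(soma, soma), amp = c(protocol$cond_amp, protocol$trigger_amp)
  )
  if (protocol$kind == "rest") inj_on <- data.frame(comp = soma, amp = protocol$trigger_amp)
  seg1 <- run_sim(
    model, state, protocol$dt_spike, protocol$trigger_dur,
    inj = inj_on, record = rec_v, record_ca = site_comp
  )
  inj_off <- if (protocol$kind == "rest") {
    NULL
  } else {
    data.frame(comp = soma, amp = protocol$cond_amp)
  }
  seg2 <- run_sim(
    model, seg1$state, protocol$dt_spike,
    protocol$window_ms - protocol$trigger_dur,
    inj = inj_off, record = rec_v, record_ca = site_comp
  )
  t <- c(seg1$t, protocol$trigger_dur + seg2$t)
  V <- cbind(seg1$V, seg2$V)
  ICa <- cbind(seg1$ICa, seg2$ICa)
  nn <- length(model$node_comp)
  structure(
    list(
      t = t,
      soma_V = V[1, ],
      axon_start_V = V[2, ],
      node_V = V[2 + seq_len(nn), , drop = FALSE],
      node_dist = model$node_dist,
      site_V = V[2 + nn + seq_along(site_comp), , drop = FALSE],
      site_ICa = ICa,
      sites = sites,
      site_dist = model$morph$sites$path_distance[sites],
      cond_V = cond_V, rest_V = rest$V,
      protocol = protocol,
      stim = data.frame(
        phase = c("conditioning", "trigger"),
        amp_nA = c(protocol$cond_amp, protocol$trigger_amp),
        dur_ms = c(protocol$cond_dur, protocol$trigger_dur)
      )
    ),
    class = "trace_set"
  )
}

.count_spikes <- function(v, thresh = 0) {
  above <- v > thresh
  sum(diff(above) == 1) + as.integer(above[1])
}

#' Spike waveform metrics
#'
#' Peak, overshoot (peak above 0 mV), amplitude (peak above the local
#' pre-spike baseline), half-width at 50 percent of the amplitude, and the
#' spike area: the integral of (V - reference) over the contiguous interval
#' around the peak where V exceeds the gate. The default reference is the
#' common resting potential (-70 mV) with a -20 mV gate isolating the spike,
#' so areas are comparable between rest and conditioned spikes.
#'
#' @param t time base (ms)
#' @param v voltage trace (mV), containing exactly one spike
#' @param baseline pre-spike baseline; default: the first sample
#' @param area_ref area reference level (mV)
#' @param area_gate gate level (mV) delimiting the integration interval
#' @return list of class \code{spike_metrics}
#' @export
spike_metrics <- function(t, v, baseline = NULL, area_ref = -70, area_gate = -20) {
  ns <- .count_spikes(v)
  if (ns != 1) {
    stop("expected exactly one spike in the window, found ", ns)
  }
  if (is.null(baseline)) baseline <- v[1]
  pk <- which.max(v)
  peak <- v[pk]
  amp <- peak - baseline
  half <- baseline + amp / 2
  cross <- function(i0, i1, level) {
    # linear interpolation of the level crossing between samples i0, i1
    t[i0] + (level - v[i0]) * (t[i1] - t[i0]) / (v[i1] - v[i0])
  }
  iu <- pk
  while (iu > 1 && v[iu - 1] > half) iu <- iu - 1
  if (iu == 1) stop("spike rising phase not contained in window")
  idn <- pk
  while (idn < length(v) && v[idn + 1] > half) idn <- idn + 1
  if (idn == length(v)) stop("spike falling phase not contained in window")
  hw <- cross(idn, idn + 1, half) - cross(iu - 1, iu, half)
  # area over the contiguous supra-gate interval around the peak
  ia <- pk
  while (ia > 1 && v[ia - 1] > area_gate) ia <- ia - 1
  ib <- pk
  while (ib < length(v) && v[ib + 1] > area_gate) ib <- ib + 1
  sel <- ia:ib
  area <- sum(diff(t[sel]) * (head(v[sel], -1) + tail(v[sel], -1) - 2 * area_ref) / 2)
  structure(
    list(
      peak = peak, overshoot = peak, amplitude = amp, baseline = baseline,
      half_width = hw, area = area, t_peak = t[pk]
    ),
    class = "spike_metrics"
  )
}

#' Spike-evoked calcium charge
#'
#' Time integral of the inward (negative) Ca-current transient over the
#' window, after subtracting the standing pre-spike current so that only the
#' spike-evoked charge is counted.
#'
#' @param t time base (ms)
#' @param ica Ca current (nA, inward negative)
#' @param baseline standing current to subtract; default: the first sample
#' @return charge (nA ms, positive)
#' @export
ca_charge <- function(t, ica, baseline = NULL) {
  if (length(t) < 2) stop("empty Ca integration window")
  if (is.null(baseline)) baseline <- ica[1]
  drv <- pmax(0, -(ica - baseline))
  sum(diff(t) * (head(drv, -1) + tail(drv, -1)) / 2)
}

#' Synaptic weight from the Ca charge power law
#'
#' W = A * Q_Ca^2.5: transmitter release scales supralinearly with the
#' spike-evoked presynaptic Ca charge.
#'
#' @param q_ca Ca charge (nA ms), >= 0
#' @param a scaling factor
#' @param power exponent, default 2.5
#' @return synaptic weight (peak alpha-synapse conductance, uS)
#' @export
synaptic_weight <- function(q_ca, a = 1, power = 2.5) {
  if (any(q_ca < 0)) stop("Ca charge must be non-negative")
  a * q_ca^power
}

#' Passive postsynaptic cell + alpha synapse defaults
#'
#' A single passive compartment (input resistance 100 MOhm, membrane time
#' constant 20 ms, rest -70 mV) receiving an alpha-function conductance
#' (tau 1 ms, reversal 0 mV). None of these are constrained by the reproduced
#' study; only facilitation ratios matter and they are insensitive to the
#' postsynaptic parameters in the small-EPSP regime.
#'
#' @param tau_syn alpha synapse time constant (ms)
#' @param e_syn synaptic reversal (mV)
#' @param r_in postsynaptic input resistance (MOhm)
#' @param tau_m postsynaptic membrane time constant (ms)
#' @param v_rest postsynaptic rest (mV)
#' @return list of class \code{synapse_model}
#' @export
synapse_model <- function(tau_syn = 1, e_syn = 0, r_in = 100, tau_m = 20,
                          v_rest = -70) {
  structure(
    list(tau_syn = tau_syn, e_syn = e_syn, r_in = r_in, tau_m = tau_m,
         v_rest = v_rest),
    class = "synapse_model"
  )
}

#' EPSP amplitude for one or many synaptic weights
#'
#' Integrates the passive postsynaptic compartment under the alpha
#' conductance g(t) = W (t/tau) exp(1 - t/tau) (peak conductance W) and
#' returns the peak depolarization from rest. Vectorized over weights (RK4,
#' fixed 0.01 ms step over 12 synaptic time constants).
#'
#' @param w synaptic weight(s), uS
#' @param synapse \code{\link{synapse_model}}
#' @return EPSP amplitude(s), mV
#' @export
epsp_amplitude <- function(w, synapse = synapse_model()) {
  if (any(w < 0)) stop("synaptic weight must be >= 0")
  if (!length(w)) return(numeric(0))
  tau <- synapse$tau_syn
  cm <- synapse$tau_m / synapse$r_in # nF
  gl <- 1 / synapse$r_in # uS
  tmax <- max(12 * tau, 3 * synapse$tau_m)
  dt <- 0.01
  nt <- ceiling(tmax / dt)
  galpha <- function(t) ifelse(t <= 0, 0, (t / tau) * exp(1 - t / tau))
  v <- rep(0, length(w)) # deviation from rest
  pk <- v
  f <- function(t, v) {
    g <- galpha(t) * w
    (-gl * v - g * (v + synapse$v_rest - synapse$e_syn)) / cm
  }
  t <- 0
  for (i in seq_len(nt)) {
    k1 <- f(t, v)
    k2 <- f(t + dt / 2, v + dt / 2 * k1)
    k3 <- f(t + dt / 2, v + dt / 2 * k2)
    k4 <- f(t + dt, v + dt * k3)
    v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    pk <- pmax(pk, v)
  }
  pk
}
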