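#' Conductance-model neuron parameters
#'
#' Parameters of the single-compartment model used throughout the simulator:
#' an exponential integrate-and-fire spike mechanism augmented with a
#' hyperpolarization-activated cation current (I_h, first-order activation
#' gate) and a slowly inactivating subthreshold D-type potassium current
#' (I_D, activation x slow inactivation). Gate steady states are logistic in
#' voltage; a positive slope `k` means the gate opens with depolarization, a
#' negative slope means it opens with hyperpolarization.
#'
#' Defaults are tuned to reproduce typical in vivo CA1 pyramidal-cell
#' passive properties (input resistance near 50 MOhm, sag ratio near 0.85,
#' resting spike output of roughly 8-14 spikes on a 300 ms maximal step).
#'
#' @param Cm membrane capacitance (pF).
#' @param gL leak conductance (nS).
#' @param EL leak reversal potential (mV).
#' @param VT spike-initiation threshold of the exponential term (mV).
#' @param DeltaT spike slope factor (mV).
#' @param Vreset post-spike reset potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @param Vcut numerical spike cutoff (mV); crossing it registers a spike.
#' @param gh_max maximal I_h conductance (nS).
#' @param Eh I_h reversal potential (mV).
#' @param h_vhalf,h_k,h_tau I_h activation gate: half-activation voltage
#'   (mV), slope (mV, negative: opens on hyperpolarization), time constant (ms).
#' @param gD_max maximal D-type K+ conductance (nS).
#' @param EK potassium reversal potential (mV).
#' @param Da_vhalf,Da_k,Da_tau D-current activation gate parameters.
#' @param Di_vhalf,Di_k,Di_tau D-current inactivation gate parameters; the
#'   inactivation time constant must exceed the activation time constant.
#' @param noise_sd stationary standard deviation of the membrane-voltage
#'   noise (mV), implemented as an Ornstein-Uhlenbeck perturbation with the
#'   passive membrane time constant.
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(Cm = 200, gL = 15, EL = -70,
                          VT = -50, DeltaT = 2, Vreset = -58, t_ref = 2.5,
                          Vcut = 20,
                          gh_max = 9, Eh = -30,
                          h_vhalf = -82, h_k = -9, h_tau = 40,
                          gD_max = 20, EK = -90,
                          Da_vhalf = -44, Da_k = 10, Da_tau = 6,
                          Di_vhalf = -72, Di_k = -7, Di_tau = 300,
                          noise_sd = 1.4) {
  p <- list(Cm = Cm, gL = gL, EL = EL, VT = VT, DeltaT = DeltaT,
            Vreset = Vreset, t_ref = t_ref, Vcut = Vcut,
            gh_max = gh_max, Eh = Eh,
            h_vhalf = h_vhalf, h_k = h_k, h_tau = h_tau,
            gD_max = gD_max, EK = EK,
            Da_vhalf = Da_vhalf, Da_k = Da_k, Da_tau = Da_tau,
            Di_vhalf = Di_vhalf, Di_k = Di_k, Di_tau = Di_tau,
            noise_sd = noise_sd)
  class(p) <- "neuron_params"
  validate_neuron_params(p)
  p
}

validate_neuron_params <- function(p) {
  if (p$Cm <= 0) stop("Cm must be positive", call. = FALSE)
  if (p$gL < 0 || p$gh_max < 0 || p$gD_max < 0) {
    stop("conductances must be non-negative", call. = FALSE)
  }
  if (p$t_ref < 0) stop("t_ref must be non-negative", call. = FALSE)
  if (p$Di_tau <= p$Da_tau) {
    stop("D-current inactivation must be slower than activation (Di_tau > Da_tau)",
         call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  passive: Cm=%.0f pF, gL=%.1f nS, EL=%.0f mV (tau_m=%.1f ms)\n",
              x$Cm, x$gL, x$EL, x$Cm / x$gL))
  cat(sprintf("  spike:   VT=%.1f mV, DeltaT=%.1f mV, reset=%.0f mV, t_ref=%.1f ms\n",
              x$VT, x$DeltaT, x$Vreset, x$t_ref))
  cat(sprintf("  I_h:     gh_max=%.1f nS, Eh=%.0f mV, V1/2=%.0f mV, tau=%.0f ms\n",
              x$gh_max, x$Eh, x$h_vhalf, x$h_tau))
  cat(sprintf("  I_D:     gD_max=%.1f nS, EK=%.0f mV, act V1/2=%.0f mV, inact tau=%.0f ms\n",
              x$gD_max, x$EK, x$Da_vhalf, x$Di_tau))
  cat(sprintf("  noise:   sd=%.2f mV\n", x$noise_sd))
  invisible(x)
}

#' Spike-count-dependent plasticity rule
#'
#' Linear-with-saturation transfer from the number of spikes evoked during
#' theta-burst stimulation to fractional conductance changes: the D-type K+
#' conductance increases by `alpha_D` per evoked spike (capped at `cap_D`)
#' and the I_h conductance decreases by `alpha_h` per spike (capped at
#' `cap_h`). The rule is a phenomenological stand-in calibrated to the
#' magnitude of the measured group effects, not a mechanistic claim.
#'
#' @param alpha_D fractional increase in `gD_max` per evoked spike.
#' @param alpha_h fractional decrease in `gh_max` per evoked spike.
#' @param cap_D,cap_h saturation bounds on the total fractional change.
#' @return an object of class `plasticity_rule`.
#' @export
plasticity_rule <- function(alpha_D = 4 / 300, alpha_h = 0.36 / 300,
                            cap_D = 4, cap_h = 0.4) {
  if (alpha_D < 0 || alpha_h < 0) stop("alpha coefficients must be >= 0", call. = FALSE)
  if (cap_D < 0 || cap_h < 0 || cap_h > 1) {
    stop("caps must be >= 0 and cap_h <= 1 (gh_max cannot go negative)", call. = FALSE)
  }
  structure(list(alpha_D = alpha_D, alpha_h = alpha_h,
                 cap_D = cap_D, cap_h = cap_h),
            class = "plasticity_rule")
}

#' Apply the spike-count-dependent plasticity rule to a neuron
#'
#' Scales `gD_max` by `1 + min(alpha_D * n_spikes, cap_D)` and `gh_max` by
#' `1 - min(alpha_h * n_spikes, cap_h)`; all other parameters are unchanged.
#'
#' @param params a [neuron_params()] object.
#' @param rule a [plasticity_rule()] object.
#' @param n_spikes number of spikes evoked during the induction protocol.
#' @return a new `neuron_params` object.
#' @export
apply_plasticity <- function(params, rule, n_spikes) {
  stopifnot_scalar(n_spikes, "n_spikes")
  if (n_spikes < 0) stop("n_spikes must be non-negative", call. = FALSE)
  out <- params
  out$gD_max <- params$gD_max * (1 + min(rule$alpha_D * n_spikes, rule$cap_D))
  out$gh_max <- params$gh_max * (1 - min(rule$alpha_h * n_spikes, rule$cap_h))
  validate_neuron_params(out)
  out
}

#' Current-step and theta-burst stimulation protocol
#'
#' The testing protocol: 300 ms current steps with a 1.5 s inter-sweep
#' interval, three hyperpolarizing amplitudes (-300, -250, -200 pA) followed
#' by depolarizing steps whose range is adjusted per cell, each repeated 10
#' times from a holding potential of -60 mV. The theta-burst stimulation
#' (TBS) is a train of EPSC-like current waveforms: 10 pulses at 100 Hz per
#' burst, 10 bursts at 5 Hz per series, 3 series at 15 s intervals (300
#' pulses in total).
#'
#' @param step_duration step length (ms).
#' @param inter_sweep_interval interval between sweeps (ms); sweeps are
#'   simulated independently because the interval far exceeds the membrane
#'   time constant.
#' @param hyper_amps hyperpolarizing step amplitudes (pA, negative).
#' @param depol_amps depolarizing step amplitudes (pA, positive, increasing).
#' @param n_repeats repeats per amplitude.
#' @param holding_target holding potential maintained by bias current (mV).
#' @param tbs_spec list with elements `pulses_per_burst`, `intra_burst_hz`,
#'   `bursts_per_series`, `burst_hz`, `n_series`, `inter_series_s`,
#'   `epsc_rise_ms`, `epsc_decay_ms`, `epsc_amp_pA`.
#' @return an object of class `stim_protocol`.
#' @export
stim_protocol <- function(step_duration = 300,
                          inter_sweep_interval = 1500,
                          hyper_amps = c(-300, -250, -200),
                          depol_amps = c(150, 250, 350, 450),
                          n_repeats = 10,
                          holding_target = -60,
                          tbs_spec = list(pulses_per_burst = 10,
                                          intra_burst_hz = 100,
                                          bursts_per_series = 10,
                                          burst_hz = 5,
                                          n_series = 3,
                                          inter_series_s = 15,
                                          epsc_rise_ms = 0.5,
                                          epsc_decay_ms = 3,
                                          epsc_amp_pA = 2500)) {
  if (step_duration <= 0) stop("step_duration must be positive", call. = FALSE)
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  if (length(hyper_amps) && any(hyper_amps >= 0)) {
    stop("hyper_amps must be negative", call. = FALSE)
  }
  if (length(depol_amps) && (any(depol_amps <= 0) || is.unsorted(depol_amps, strictly = TRUE))) {
    stop("depol_amps must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(step_duration = step_duration,
                 inter_sweep_interval = inter_sweep_interval,
                 hyper_amps = hyper_amps, depol_amps = depol_amps,
                 n_repeats = n_repeats, holding_target = holding_target,
                 tbs_spec = tbs_spec),
            class = "stim_protocol")
}

#' Total number of EPSC pulses in a TBS protocol
#' @param proto a [stim_protocol()] object.
#' @return integer pulse count.
#' @export
tbs_pulse_count <- function(proto) {
  s <- proto$tbs_spec
  as.integer(s$pulses_per_burst * s$bursts_per_series * s$n_series)
}

#' Place-cell session generator parameters
#'
#' A virtual linear track traversed back and forth at constant speed. The
#' firing rate is an in-field Gaussian bump plus an out-of-field baseline;
#' both change multiplicatively lap by lap (`in_field_gain_per_lap` and
#' `drift_per_lap`), emulating within-session synaptic potentiation in the
#' field and an excitability drift outside it.
#'
#' @param track_length track length (cm).
#' @param n_laps number of traversals per running direction.
#' @param field_center,field_width place-field centre and Gaussian full width
#'   at half maximum (cm).
#' @param peak_rate_in peak in-field rate on lap 1 (Hz, above baseline).
#' @param base_rate_out out-of-field baseline rate on lap 1 (Hz).
#' @param drift_per_lap multiplicative change of the baseline per lap.
#' @param in_field_gain_per_lap multiplicative change of the field peak per lap.
#' @param speed running speed (cm/s).
#' @param pos_hz position sampling rate (Hz).
#' @param seed RNG seed for spike generation.
#' @return an object of class `place_session_params`.
#' @export
place_session_params <- function(track_length = 200, n_laps = 30,
                                 field_center = 100, field_width = 40,
                                 peak_rate_in = 8, base_rate_out = 1.6,
                                 drift_per_lap = 0.985,
                                 in_field_gain_per_lap = 1.005,
                                 speed = 15, pos_hz = 50, seed = 1L) {
  if (peak_rate_in < 0 || base_rate_out < 0) stop("rates must be >= 0", call. = FALSE)
  if (field_width <= 0 || field_width >= track_length) {
    stop("field_width must lie in (0, track_length)", call. = FALSE)
  }
  if (drift_per_lap <= 0 || in_field_gain_per_lap <= 0) {
    stop("drift factors must be positive", call. = FALSE)
  }
  if (speed <= 0 || track_length <= 0 || n_laps < 1) {
    stop("speed, track_length must be positive and n_laps >= 1", call. = FALSE)
  }
  structure(list(track_length = track_length, n_laps = n_laps,
                 field_center = field_center, field_width = field_width,
                 peak_rate_in = peak_rate_in, base_rate_out = base_rate_out,
                 drift_per_lap = drift_per_lap,
                 in_field_gain_per_lap = in_field_gain_per_lap,
                 speed = speed, pos_hz = pos_hz, seed = as.integer(seed)),
            class = "place_session_params")
}
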