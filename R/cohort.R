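#' Condition regimes for cohort simulation
#'
#' Maps an experimental condition label to a simulator regime: whether TBS
#' is applied, how the cell parameters are modified by the drug, and how the
#' plasticity rule is modified.
#'
#' * `TBS` — stimulation applied, rule as given.
#' * `control` — no stimulation; repeated testing only.
#' * `BAPTA` — calcium chelation: stimulation applied but plasticity
#'   induction abolished (`alpha_D = alpha_h = 0`).
#' * `MK801` — NMDAR block: no effect on induction (rule as given).
#' * `ZD` — I_h block: `gh_max = 0`, stimulation applied, rule as given.
#' * `DTX` — Kv1.1 block: `gD_max` reduced to 30% and `alpha_D` halved.
#'
#' @param condition condition label.
#' @param params baseline [neuron_params()].
#' @param rule baseline [plasticity_rule()].
#' @return list with `params`, `rule`, `apply_tbs`.
#' @export
condition_regime <- function(condition, params = neuron_params(),
                             rule = plasticity_rule()) {
  conditions <- c("TBS", "control", "BAPTA", "MK801", "ZD", "DTX")
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% conditions) {
    stop("unknown condition label; expected one of: ",
         paste(conditions, collapse = ", "), call. = FALSE)
  }
  apply_tbs <- condition != "control"
  if (condition == "BAPTA") {
    rule$alpha_D <- 0
    rule$alpha_h <- 0
  } else if (condition == "ZD") {
    params$gh_max <- 0
  } else if (condition == "DTX") {
    params$gD_max <- params$gD_max * 0.3
    rule$alpha_D <- rule$alpha_D * 0.5
  }
  list(params = params, rule = rule, apply_tbs = apply_tbs)
}

# draw per-cell heterogeneity: log-normal (given CV) around the defaults on
# the main conductances and capacitance, additive jitter on VT
draw_cell_params <- function(base, cv = 0.1) {
  jitter_ln <- function(x) {
    if (x <= 0) return(x)
    sdlog <- sqrt(log(1 + cv^2))
    x * exp(rnorm(1, -sdlog^2 / 2, sdlog))
  }
  p <- base
  p$Cm <- jitter_ln(base$Cm)
  p$gL <- jitter_ln(base$gL)
  p$gh_max <- jitter_ln(base$gh_max)
  p$gD_max <- jitter_ln(base$gD_max)
  p$VT <- base$VT + rnorm(1, 0, 1)
  validate_neuron_params(p)
  p
}

# pick per-cell depolarizing amplitudes, emulating the experimental practice
# of adjusting the step range to the cell's excitability: the smallest step
# already evokes a handful of spikes (min_spikes) and the largest drives
# robust firing (max_spikes); four evenly spaced steps in between
choose_depol_amps <- function(params, proto, dt, min_spikes = 4,
                              max_spikes = 14, grid = seq(100, 800, by = 25),
                              n_steps = 4) {
  quiet <- params
  quiet$noise_sd <- 0
  count_at <- function(amp) {
    sw <- simulate_sweep(quiet, amp, proto, dt, baseline_ms = 50, post_ms = 10)
    nrow(detect_spikes(sw))
  }
  a_lo <- a_hi <- grid[length(grid)]
  for (amp in grid) {
    if (count_at(amp) >= min_spikes) {
      a_lo <- amp
      break
    }
  }
  for (amp in grid[grid > a_lo]) {
    if (count_at(amp) >= max_spikes) {
      a_hi <- amp
      break
    }
  }
  if (a_hi <= a_lo) a_hi <- a_lo + 150
  round(seq(a_lo, a_hi, length.out = n_steps))
}

# one testing block: every amplitude x n_repeats noisy sweeps plus a
# spontaneous segment for the Vm-variance feature; uses the batched
# integrator (one model build for the whole block). `sweep_jitter_pA` and
# `block_offset_pA` are slow standing-current fluctuations of excitability
# (per sweep and per block), emulating brain-state variability between
# trials and across the recording.
simulate_block <- function(params, proto, dt, spont_s = 15,
                           baseline_ms = 100, post_ms = 50,
                           sweep_jitter_pA = 0, block_offset_pA = 0) {
  amps <- rep(c(proto$hyper_amps, proto$depol_amps), each = proto$n_repeats)
  bias <- block_offset_pA + if (sweep_jitter_pA > 0) {
    rnorm(length(amps), 0, sweep_jitter_pA)
  } else {
    numeric(length(amps))
  }
  n_pre <- as.integer(round(baseline_ms / dt))
  n_step <- as.integer(round(proto$step_duration / dt))
  n_post <- as.integer(round(post_ms / dt))
  v_hold <- proto$holding_target
  sim <- eif_step_block_cpp(unclass(params), dt, n_pre, n_step, n_post, amps,
                            v0 = v_hold,
                            h0 = sigmoid_inf(v_hold, params$h_vhalf, params$h_k),
                            a0 = sigmoid_inf(v_hold, params$Da_vhalf, params$Da_k),
                            d0 = sigmoid_inf(v_hold, params$Di_vhalf, params$Di_k),
                            I_hold = holding_current(params, v_hold),
                            with_noise = params$noise_sd > 0,
                            sweep_bias = bias)
  sweeps <- lapply(seq_along(amps), function(k) {
    new_step_sweep(dt, sim$v[, k],
                   step_onset = n_pre + 1L, step_offset = n_pre + n_step,
                   step_amp = amps[k])
  })
  list(sweeps = sweeps,
       spont = simulate_spontaneous(params, duration_s = spont_s, dt = 0.5,
                                    holding = proto$holding_target))
}

#' Simulate a cohort of cells through the full experiment
#'
#' For each cell: draws heterogeneous parameters, adjusts the depolarizing
#' step range to its excitability, records a pre block, applies (or not) the
#' theta-burst stimulation, transfers the evoked spike count through the
#' plasticity rule, and records post blocks at the requested timepoints.
#' The EPSC amplitude is calibrated on the regime's baseline cell and then
#' jittered per cell (log-normal, `entrain_cv`) to emulate the variable
#' quality of entrainment across recordings; this is what spreads the evoked
#' spike counts below the 300-pulse ceiling.
#'
#' @param n_cells number of cells.
#' @param condition condition label (see [condition_regime()]).
#' @param rule baseline [plasticity_rule()].
#' @param seed master seed; every cell derives its own stream from it.
#' @param proto a [stim_protocol()] object.
#' @param base_params baseline [neuron_params()].
#' @param dt integration step (ms).
#' @param timepoints post-stimulation block labels (minutes).
#' @param heterogeneity_cv log-normal CV of the per-cell parameter jitter.
#' @param entrain_cv log-normal CV of the per-cell EPSC amplitude.
#' @param spont_s spontaneous segment length per block (s).
#' @param depol_min_spikes,depol_max_spikes targets for the per-cell
#'   depolarizing step range: the smallest step evokes about
#'   `depol_min_spikes`, the largest about `depol_max_spikes` (noise-free).
#' @param sweep_jitter_pA sd of the per-sweep standing-current fluctuation
#'   (pA), emulating trial-to-trial brain-state variability of excitability.
#' @param block_jitter_pA sd of a per-block standing-current offset (pA),
#'   emulating slower drifts between testing timepoints.
#' @return list of cells; each has `id`, `condition`, `params_pre`,
#'   `params_post`, `n_tbs_spikes`, `tbs` (per-series traces or `NULL`) and
#'   `blocks` (named list: `pre`, then one entry per timepoint).
#' @export
generate_cohort <- function(n_cells, condition = "TBS",
                            rule = plasticity_rule(), seed = 1L,
                            proto = stim_protocol(),
                            base_params = neuron_params(),
                            dt = 0.025, timepoints = c(10, 20, 30),
                            heterogeneity_cv = 0.1, entrain_cv = 0.35,
                            spont_s = 15,
                            depol_min_spikes = 8, depol_max_spikes = 18,
                            sweep_jitter_pA = 40, block_jitter_pA = 12) {
  regime <- condition_regime(condition, base_params, rule)
  amp0 <- calibrate_epsc_amp(regime$params, proto, dt)
  cells <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    set.seed(derive_seed(seed, ci))
    p <- draw_cell_params(regime$params, heterogeneity_cv)
    cell_proto <- proto
    cell_proto$depol_amps <- choose_depol_amps(p, proto, dt,
                                               min_spikes = depol_min_spikes,
                                               max_spikes = depol_max_spikes)
    sdlog <- sqrt(log(1 + entrain_cv^2))
    cell_proto$tbs_spec$epsc_amp_pA <- amp0 * exp(rnorm(1, -sdlog^2 / 2, sdlog))

    blocks <- list(pre = simulate_block(p, cell_proto, dt, spont_s,
                                        sweep_jitter_pA = sweep_jitter_pA,
                                        block_offset_pA = rnorm(1, 0, block_jitter_pA)))

    if (regime$apply_tbs) {
      tbs <- simulate_tbs(p, cell_proto, dt)
      n_spikes <- tbs$n_spikes
      p_post <- apply_plasticity(p, regime$rule, n_spikes)
    } else {
      tbs <- NULL
      n_spikes <- 0L
      p_post <- p
    }
    for (tp in timepoints) {
      blocks[[as.character(tp)]] <- simulate_block(
        p_post, cell_proto, dt, spont_s,
        sweep_jitter_pA = sweep_jitter_pA,
        block_offset_pA = rnorm(1, 0, block_jitter_pA))
    }
    cells[[ci]] <- list(id = sprintf("%s_%02d", condition, ci),
                        condition = condition,
                        params_pre = p, params_post = p_post,
                        n_tbs_spikes = n_spikes, tbs = tbs,
                        blocks = blocks)
  }
  cells
}
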