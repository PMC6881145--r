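#' Current-clamp sweep container
#'
#' One trial of the testing protocol: sampled membrane voltage, the command
#' current (relative to the holding bias), and step metadata. Indices are
#' 1-based; the step occupies samples `step_onset` to `step_offset`
#' inclusive.
#'
#' @param dt sampling interval (ms).
#' @param v voltage samples (mV).
#' @param i command-current samples (pA, relative to holding).
#' @param step_onset index of the first step sample.
#' @param step_offset index of the last step sample.
#' @param step_amp step amplitude (pA).
#' @return an object of class `ie_sweep`.
#' @export
ie_sweep <- function(dt, v, i, step_onset, step_offset, step_amp) {
  s <- structure(list(dt = dt, v = as.numeric(v), i = as.numeric(i),
                      step_onset = as.integer(step_onset),
                      step_offset = as.integer(step_offset),
                      step_amp = step_amp),
                 class = "ie_sweep")
  validate_sweep(s)
  s
}

validate_sweep <- function(s) {
  if (!is.null(s$i) && length(s$v) != length(s$i)) {
    stop("voltage and current traces must have equal length", call. = FALSE)
  }
  if (s$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (s$step_onset < 1L || s$step_onset >= s$step_offset ||
      s$step_offset > length(s$v)) {
    stop("step window must satisfy 1 <= step_onset < step_offset <= length(v)",
         call. = FALSE)
  }
  invisible(s)
}

#' @export
print.ie_sweep <- function(x, ...) {
  cat(sprintf("<ie_sweep> %d samples @ dt=%.3g ms, step %.0f pA [%.0f, %.0f] ms\n",
              length(x$v), x$dt, x$step_amp,
              (x$step_onset - 1) * x$dt, (x$step_offset - 1) * x$dt))
  invisible(x)
}

# internal fast constructor for rectangular-step sweeps: the command trace
# is implicit in the step metadata and materialized on demand
new_step_sweep <- function(dt, v, step_onset, step_offset, step_amp) {
  structure(list(dt = dt, v = v, i = NULL,
                 step_onset = as.integer(step_onset),
                 step_offset = as.integer(step_offset),
                 step_amp = step_amp),
            class = "ie_sweep")
}

# command-current trace of a sweep (pA, relative to holding)
sweep_command <- function(s) {
  if (!is.null(s$i)) return(s$i)
  i <- numeric(length(s$v))
  i[s$step_onset:s$step_offset] <- s$step_amp
  i
}

# times (ms) of samples, 0 at the first sample
sweep_times <- function(s) (seq_along(s$v) - 1) * s$dt

# mean voltage over the 50 ms immediately preceding step onset
sweep_baseline <- function(s, window_ms = 50) {
  i0 <- max(1L, s$step_onset - as.integer(round(window_ms / s$dt)))
  mean(s$v[i0:(s$step_onset - 1L)])
}
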