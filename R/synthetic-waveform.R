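#' Pulsatile arterial waveform specification
#'
#' Parameterizes a synthetic intra-renal pulsed-wave Doppler velocity trace:
#' heart rate, peak systolic velocity (PSV), end-diastolic velocity (EDV), an
#' optional target cycle-mean velocity (MV), number of cycles, sampling rate
#' and additive noise.
#'
#' Each cardiac cycle is built from four phases (fractions of the period):
#' a linear systolic upstroke from EDV to PSV over the first 15%, a
#' shifted-exponential decay to a post-systolic trough, a half-cosine
#' recovery from the trough to EDV, and an end-diastolic plateau at EDV.
#' With no `mv_target` the trough equals EDV, giving the classic monotone
#' low-resistance decay. When `mv_target` is given, the decay shape constant
#' (and, if needed, the trough depth, which may undershoot EDV) is solved
#' numerically so the cycle-mean velocity matches the target within 0.1%.
#' EDV remains the pre-upstroke velocity in all cases.
#'
#' @param hr heart rate, beats/min.
#' @param psv peak systolic velocity, mm/s.
#' @param edv end-diastolic velocity, mm/s; `0 <= edv <= psv`.
#' @param mv_target optional cycle-mean velocity, mm/s; must be achievable
#'   (strictly between the deepest-trough cycle mean and the slowest-decay
#'   cycle mean, both inside `(0, psv)`).
#' @param n_cycles number of cardiac cycles (>= 3).
#' @param sampling_rate Hz.
#' @param noise_sd additive Gaussian noise SD, mm/s.
#' @param seed integer seed.
#' @return object of class `"waveform_spec"`.
#' @export
waveform_spec <- function(hr = 400, psv = 30, edv = 15, mv_target = NULL,
                          n_cycles = 4L, sampling_rate = 1000, noise_sd = 0,
                          seed = 1L) {
  assert_scalar_number(hr, "hr", 0, strict_min = TRUE)
  assert_scalar_number(psv, "psv", 0, strict_min = TRUE)
  assert_scalar_number(edv, "edv", 0)
  if (edv > psv)
    stop_husphen("validation_error", "'edv' must satisfy 0 <= edv <= psv")
  if (!is.null(mv_target)) {
    assert_scalar_number(mv_target, "mv_target", 0, strict_min = TRUE)
    if (mv_target >= psv)
      stop_husphen("infeasible_target_error",
                   "mv_target (%.3f) must be below psv (%.3f)", mv_target, psv)
  }
  if (n_cycles < 3)
    stop_husphen("validation_error", "'n_cycles' must be >= 3")
  assert_scalar_number(sampling_rate, "sampling_rate", 0, strict_min = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", 0)
  structure(list(hr = hr, psv = psv, edv = edv, mv_target = mv_target,
                 n_cycles = as.integer(n_cycles),
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "waveform_spec")
}

# phase boundaries of one cycle, as fractions of the period
.wf_phase <- c(up = 0.15, decay_end = 0.80, recover_end = 0.88)

# velocity at phase s in [0, 1) for shape constant k and trough velocity
.wf_cycle <- function(s, psv, edv, k, trough) {
  p <- .wf_phase
  v <- numeric(length(s))
  i1 <- s < p["up"]
  v[i1] <- edv + (psv - edv) * s[i1] / p["up"]
  i2 <- s >= p["up"] & s < p["decay_end"]
  u <- (s[i2] - p["up"]) / (p["decay_end"] - p["up"])
  # shifted-scaled exponential: equals 1 at u=0 and exactly 0 at u=1
  ek <- (exp(-k * u) - exp(-k)) / (1 - exp(-k))
  v[i2] <- trough + (psv - trough) * ek
  i3 <- s >= p["decay_end"] & s < p["recover_end"]
  u <- (s[i3] - p["decay_end"]) / (p["recover_end"] - p["decay_end"])
  v[i3] <- trough + (edv - trough) * (1 - cos(pi * u)) / 2
  i4 <- s >= p["recover_end"]
  v[i4] <- edv
  v
}

# exact-enough cycle mean on a dense grid (periodic, so plain mean = integral)
.wf_cycle_mean <- function(psv, edv, k, trough, n = 8192L) {
  mean(.wf_cycle((seq_len(n) - 1) / n, psv, edv, k, trough))
}

# solve (k, trough) so the cycle mean hits mv_target within 0.1% relative
.wf_calibrate <- function(psv, edv, mv_target) {
  k_lo <- 1e-3; k_hi <- 60
  m_slow <- .wf_cycle_mean(psv, edv, k_lo, edv)   # near-linear decay, largest mean
  m_fast <- .wf_cycle_mean(psv, edv, k_hi, edv)   # immediate drop to EDV
  if (mv_target > m_slow || mv_target >= psv)
    stop_husphen("infeasible_target_error",
                 "mv_target %.3f above achievable cycle mean %.3f", mv_target, m_slow)
  if (mv_target >= m_fast) {
    k <- uniroot(function(k) .wf_cycle_mean(psv, edv, k, edv) - mv_target,
                 c(k_lo, k_hi), tol = 1e-10)$root
    return(list(k = k, trough = edv))
  }
  # target below what a monotone decay to EDV can reach: deepen the trough
  k <- 8
  m_deep <- .wf_cycle_mean(psv, edv, k, 0)
  if (mv_target <= m_deep)
    stop_husphen("infeasible_target_error",
                 "mv_target %.3f below achievable cycle mean %.3f", mv_target, m_deep)
  tr <- uniroot(function(tr) .wf_cycle_mean(psv, edv, k, tr) - mv_target,
                c(0, edv), tol = 1e-10)$root
  list(k = k, trough = tr)
}

#' Generate a pulsatile Doppler velocity trace
#'
#' @param spec a [waveform_spec()].
#' @return A `doppler_trace`: tibble with `time_s` and `velocity_mm_s`
#'   (uniform sampling), plus attributes `hr_hint` (bpm), `sampling_rate`
#'   and, when calibrated, the solved decay constant and trough velocity.
#' @export
generate_waveform <- function(spec) {
  if (!inherits(spec, "waveform_spec"))
    stop_husphen("validation_error", "'spec' must be built by waveform_spec()")
  period <- 60 / spec$hr
  n <- round(spec$n_cycles * period * spec$sampling_rate)
  t <- (seq_len(n) - 1) / spec$sampling_rate
  cal <- if (is.null(spec$mv_target)) list(k = 4, trough = spec$edv)
         else .wf_calibrate(spec$psv, spec$edv, spec$mv_target)
  phase <- (t / period) %% 1
  v <- .wf_cycle(phase, spec$psv, spec$edv, cal$k, cal$trough)
  # the systolic peak phase rarely falls exactly on the sampling grid; snap
  # the nearest sample of each cycle onto PSV so the sampled trace attains it
  for (c in seq_len(spec$n_cycles) - 1L) {
    idx <- round((c + .wf_phase[["up"]]) * period * spec$sampling_rate) + 1L
    if (idx >= 1L && idx <= n) v[idx] <- spec$psv
  }
  if (spec$noise_sd > 0)
    v <- with_seed(spec$seed, v + rnorm(n, 0, spec$noise_sd))
  out <- tibble::tibble(time_s = t, velocity_mm_s = v)
  attr(out, "hr_hint") <- spec$hr
  attr(out, "sampling_rate") <- spec$sampling_rate
  attr(out, "decay_k") <- cal$k
  attr(out, "trough_mm_s") <- cal$trough
  class(out) <- c("doppler_trace", class(out))
  out
}

#' Construct a Doppler trace from raw vectors
#'
#' @param time_s time stamps (s), uniformly sampled.
#' @param velocity_mm_s velocities (mm/s).
#' @param hr_hint optional heart rate hint (beats/min) used by cycle
#'   detection; if absent the dominant spectral peak is used.
#' @return a `doppler_trace` tibble.
#' @export
doppler_trace <- function(time_s, velocity_mm_s, hr_hint = NULL) {
  if (length(time_s) != length(velocity_mm_s) || length(time_s) < 8)
    stop_husphen("validation_error", "time and velocity must match, length >= 8")
  dt <- diff(time_s)
  if (any(abs(dt - dt[1]) > 1e-9 * max(1, dt[1])))
    stop_husphen("validation_error", "sampling grid must be uniform")
  out <- tibble::tibble(time_s = time_s, velocity_mm_s = velocity_mm_s)
  attr(out, "hr_hint") <- hr_hint
  attr(out, "sampling_rate") <- 1 / dt[1]
  class(out) <- c("doppler_trace", class(out))
  out
}

#' @importFrom stats uniroot
NULL
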