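#' Detect cardiac cycles in a Doppler velocity trace
#'
#' Systolic peaks are local maxima above the trace midline, separated by at
#' least 60% of the expected beat interval. The heart rate comes from the
#' trace's `hr_hint` attribute when present, otherwise from the dominant
#' spectral peak of the demeaned velocity signal.
#'
#' @param trace a `doppler_trace` (see [doppler_trace()]).
#' @return list with `peaks` (sample indices of systolic peaks), `windows`
#'   (list of `c(start, end)` index pairs, peak to peak), and `hr_est`
#'   (beats/min used for the separation constraint).
#' @export
detect_cycles <- function(trace) {
  v <- trace$velocity_mm_s
  fs <- attr(trace, "sampling_rate") %||% (1 / diff(trace$time_s[1:2]))
  hr <- attr(trace, "hr_hint")
  if (is.null(hr)) {
    # dominant frequency of the demeaned signal, restricted to a plausible
    # murine band (2-20 Hz, i.e. 120-1200 bpm)
    x <- v - mean(v)
    if (sd_pop(x) < 1e-12)
      stop_husphen("insufficient_cycles_error",
                   "constant-velocity trace: no pulsatility to segment")
    sp <- Mod(fft(x))^2
    freqs <- (seq_along(x) - 1) * fs / length(x)
    band <- freqs >= 2 & freqs <= 20
    if (!any(band))
      stop_husphen("insufficient_cycles_error", "trace too short to estimate rate")
    hr <- 60 * freqs[band][which.max(sp[band])]
  }
  min_dist <- max(1L, floor(0.6 * (60 / hr) * fs))
  thresh <- min(v) + 0.5 * (max(v) - min(v))
  pk <- pracma::findpeaks(v, minpeakdistance = min_dist,
                          minpeakheight = thresh, zero = "+", sortstr = FALSE)
  if (is.null(pk) || nrow(pk) < 3)
    stop_husphen("insufficient_cycles_error",
                 "fewer than 3 cardiac cycles detected (%d)",
                 if (is.null(pk)) 0L else nrow(pk))
  idx <- sort(pk[, 2])
  windows <- lapply(seq_len(length(idx) - 1L),
                    function(i) c(idx[i], idx[i + 1L]))
  list(peaks = idx, windows = windows, hr_est = hr)
}

# pre-upstroke (end-diastolic) sample behind a systolic peak: walking back
# from the peak, the first index that is the minimum of its +/- 5-sample
# neighbourhood. Requiring a window minimum (not a simple local minimum)
# keeps shallow noise dips on the steep upstroke from being mistaken for
# end-diastole; on clean traces the window minimum is the upstroke foot.
.pre_upstroke_min <- function(v, peak, lower_bound, w = 5L) {
  for (i in seq(peak - 1L, lower_bound, by = -1L)) {
    lo <- max(lower_bound, i - w); hi <- min(peak, i + w)
    if (v[i] <= min(v[lo:hi])) return(i)
  }
  NA_integer_
}

# running mean with replicated edges
.runmean <- function(x, w) {
  y <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  h <- (w - 1L) %/% 2L
  n <- length(y)
  y[seq_len(h)] <- y[h + 1L]
  y[(n - h + 1L):n] <- y[n - h]
  y
}

# per-cycle PSV and EDV from an (possibly pre-smoothed) envelope
.cycle_features <- function(env, peak, lower_bound, smoothed) {
  back_off <- if (smoothed) 2L else 0L
  foot <- .pre_upstroke_min(env, peak, lower_bound)
  if (is.na(foot)) {
    edv <- NA_real_; full <- FALSE
  } else {
    lo <- foot - back_off - 9L
    full <- lo >= 1L
    hi <- max(1L, foot - back_off)
    edv <- mean(env[max(1L, lo):hi])
  }
  list(psv = env[peak], edv = edv, edv_full = full)
}

# PSV and EDV from one folded (cycle-averaged) beat aligned at its peak,
# with all windows scaled to the cycle length L so behaviour is invariant to
# the sampling rate. The running mean composed with the apex average rounds
# the sharp systolic corner down by (|up slope| + |down slope|)/2 * E|t| of
# the effective kernel; the apex is de-rounded with flank slopes fitted away
# from the corner (intersecting-tangents refinement).
.beat_features <- function(folded, peak, L) {
  w <- 2L * max(2L, floor(0.0167 * L)) + 1L      # detection-grade smoothing
  fenv <- .runmean(folded, w)
  n <- length(fenv)
  h <- max(2L, round(0.015 * L))                 # apex half-width
  apex <- mean(fenv[max(1L, peak - h):min(n, peak + h)])
  # E|t| of the composed kernel MA_w * MA_(2h+1), computed exactly
  k <- stats::convolve(rep(1 / w, w), rep(1 / (2 * h + 1), 2 * h + 1),
                       type = "open")
  e_abs_t <- sum(abs(seq_along(k) - (length(k) + 1) / 2) * k)
  near <- max(h + 2L, round(0.027 * L))
  far <- max(near + 4L, round(0.08 * L))
  li <- (peak - far):(peak - near); ri <- (peak + near):(peak + far)
  li <- li[li >= 1L]; ri <- ri[ri <= n]
  psv <- if (length(li) >= 4L && length(ri) >= 4L) {
    s_up <- coef(lm(fenv[li] ~ li))[2]
    s_dn <- coef(lm(fenv[ri] ~ ri))[2]
    apex + max(0, (abs(s_up) + abs(s_dn)) / 2 * e_abs_t)
  } else fenv[peak]
  foot <- .pre_upstroke_min(fenv, peak, 1L, w = max(5L, round(0.033 * L)))
  if (is.na(foot)) return(NULL)
  back <- max(2L, round(0.015 * L))              # clear the smoothing radius
  win <- max(9L, round(0.08 * L))
  hi <- max(1L, foot - back)
  edv <- mean(fenv[max(1L, foot - back - win + 1L):hi])
  list(psv = unname(psv), edv = edv)
}

#' Extract pulsed-wave Doppler indices
#'
#' From a detected-cycle segmentation: PSV is the mean of the systolic peak
#' velocities over the first 3-4 cycles; EDV the mean of the local minima
#' immediately preceding each systolic upstroke (true end-diastole, which can
#' exceed the mid-diastolic trough); VTI the time-integral of the envelope
#' over one representative cycle (the cycle whose peak is the median of the
#' used peaks); MV the mean of the envelope over that same cycle; and
#' `RI = (PSV - EDV)/PSV`, `PI = (PSV - EDV)/MV`.
#'
#' @param trace a `doppler_trace`.
#' @param envelope `"none"` uses the trace as its own envelope (clean or
#'   synthetic input); `"smooth"` applies a 5-sample running mean before
#'   feature extraction (noisy input); `"movmax"` a 5-sample moving maximum
#'   (spectral-envelope style).
#' @param mv_all_cycles if `TRUE`, MV (and VTI) average over all used cycles
#'   instead of the single representative cycle.
#' @return tibble: `psv, edv, mv, vti, ri, pi, n_cycles_used` (velocities
#'   mm/s, VTI mm).
#' @export
doppler_indices <- function(trace, envelope = c("none", "smooth", "movmax"),
                            mv_all_cycles = FALSE) {
  envelope <- match.arg(envelope)
  v <- trace$velocity_mm_s
  env <- switch(envelope,
    none = v,
    smooth = as.numeric(stats::filter(v, rep(1 / 5, 5), sides = 2)),
    movmax = vapply(seq_along(v), function(i)
      max(v[max(1, i - 2):min(length(v), i + 2)]), numeric(1))
  )
  if (envelope == "smooth") {       # pad the filter's NA edges
    env[1:2] <- env[3]; n <- length(env); env[(n - 1):n] <- env[n - 2]
  }
  etr <- trace
  etr$velocity_mm_s <- env
  cyc <- detect_cycles(etr)
  n_use <- min(4L, length(cyc$peaks))    # 3-4 cycles per protocol
  peaks <- cyc$peaks[seq_len(n_use)]
  feats <- NULL
  if (envelope == "smooth" && length(cyc$peaks) >= 2) {
    # cycle-synchronous averaging: fold the used cycles onto a common grid
    # aligned at the systolic peaks, then extract PSV/EDV from the folded
    # beat — suppresses noise without further blurring the waveform
    L <- round(median(diff(cyc$peaks)))
    fl <- round(0.35 * L); fr <- round(0.12 * L)
    usable <- peaks[peaks - fl >= 1 & peaks + fr <= length(v)]
    if (length(usable) >= 2) {
      seg <- vapply(usable, function(p) v[(p - fl):(p + fr)],
                    numeric(fl + fr + 1))
      folded <- rowMeans(seg)
      feats <- .beat_features(folded, peak = fl + 1L, L = L)
    }
  }
  if (is.null(feats)) {
    lowers <- c(1L, cyc$peaks)[seq_len(n_use)]   # previous peak (or start)
    smoothed <- envelope != "none"
    per_cycle <- lapply(seq_len(n_use), function(j)
      .cycle_features(env, peaks[j], lowers[j], smoothed = smoothed))
    psv_vals <- vapply(per_cycle, `[[`, numeric(1), "psv")
    edv_vals <- vapply(per_cycle, `[[`, numeric(1), "edv")
    good_edv <- vapply(per_cycle, `[[`, logical(1), "edv_full")
    if (any(good_edv)) edv_vals <- edv_vals[good_edv]
    edv_vals <- edv_vals[!is.na(edv_vals)]
    if (!length(edv_vals))
      stop_husphen("extraction_inconsistency_error",
                   "no pre-upstroke minimum found for any cycle")
    feats <- list(psv = mean(psv_vals), edv = mean(edv_vals))
  }
  psv <- feats$psv
  edv <- feats$edv
  if (edv > psv)
    stop_husphen("extraction_inconsistency_error",
                 "extracted EDV (%.3f) exceeds PSV (%.3f)", edv, psv)

  windows <- cyc$windows[seq_len(min(n_use, length(cyc$windows)))]
  win_mean <- function(w) {
    i <- w[1]:w[2]
    vti <- pracma::trapz(trace$time_s[i], env[i])
    c(vti = vti, mv = vti / (trace$time_s[w[2]] - trace$time_s[w[1]]))
  }
  if (mv_all_cycles) {
    wm <- vapply(windows, win_mean, numeric(2))
    vti <- mean(wm["vti", ]); mv <- mean(wm["mv", ])
  } else {
    # representative cycle: starting peak closest to the median peak velocity
    pk_v <- env[vapply(windows, `[`, numeric(1), 1)]
    rep_w <- windows[[which.min(abs(pk_v - median(pk_v)))]]
    wm <- win_mean(rep_w)
    vti <- wm[["vti"]]; mv <- wm[["mv"]]
  }
  tibble::tibble(psv = psv, edv = edv, mv = mv, vti = vti,
                 ri = (psv - edv) / psv,
                 pi = (psv - edv) / mv,
                 n_cycles_used = n_use)
}

#' Renal cortical thickness normalized to body weight
#'
#' @param thickness_mm cortical thickness, mm (> 0).
#' @param bw_g body weight, g (> 0).
#' @return CRT/BW, mm/g.
#' @export
crt_bw <- function(thickness_mm, bw_g) {
  if (any(thickness_mm <= 0, na.rm = TRUE))
    stop_husphen("domain_error", "'thickness_mm' must be > 0")
  if (any(bw_g <= 0, na.rm = TRUE))
    stop_husphen("domain_error", "'bw_g' must be > 0")
  thickness_mm / bw_g
}

#' Change in cortical echogenicity from baseline
#'
#' Per mouse, subtracts the earliest-age cortical ROI mean from every later
#' value; comparisons of echogenicity over time use these deltas.
#'
#' @param series data frame with `age_weeks`, `cortex_mean_echo` and
#'   optionally `mouse_id` (one series if absent).
#' @return tibble `mouse_id (if present), age_weeks, echo_change` (a.u.).
#' @export
cortex_echo_change <- function(series) {
  if (!all(c("age_weeks", "cortex_mean_echo") %in% names(series)))
    stop_husphen("validation_error",
                 "'series' needs age_weeks and cortex_mean_echo")
  one <- function(df) {
    df <- df[order(df$age_weeks), ]
    if (anyNA(df$cortex_mean_echo[1]))
      stop_husphen("missing_data_error", "missing baseline cortical echo value")
    df$echo_change <- df$cortex_mean_echo - df$cortex_mean_echo[1]
    df
  }
  if ("mouse_id" %in% names(series)) {
    out <- series |>
      dplyr::group_by(.data$mouse_id) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
    tibble::as_tibble(out)
  } else {
    tibble::as_tibble(one(as.data.frame(series)))
  }
}

#' @importFrom stats fft
NULL
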