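test_that("cycle detection finds the systolic peaks at the configured rate", {
  tr <- generate_waveform(waveform_spec(hr = 400, psv = 30, edv = 15, n_cycles = 4))
  cyc <- detect_cycles(tr)
  expect_length(cyc$peaks, 4)
  spacing <- diff(tr$time_s[cyc$peaks])
  expect_true(all(abs(spacing - 0.15) <= 0.01))
  # rate recovery also works without the hint, from the spectrum
  tr2 <- doppler_trace(tr$time_s, tr$velocity_mm_s)
  cyc2 <- detect_cycles(tr2)
  expect_length(cyc2$peaks, 4)
})

test_that("a constant trace has no cycles to detect", {
  tr <- doppler_trace(seq(0, 1, by = 1e-3), rep(20, 1001))
  expect_error(detect_cycles(tr), class = "insufficient_cycles_error")
})

test_that("noisy traces keep the noiseless peak count in >= 95/100 seeds", {
  hits <- vapply(1:100, function(s) {
    tr <- generate_waveform(waveform_spec(hr = 400, psv = 30, edv = 15,
                                          n_cycles = 4, noise_sd = 3, seed = s))
    tr$velocity_mm_s <- as.numeric(stats::filter(tr$velocity_mm_s,
                                                 rep(1 / 5, 5), sides = 2))
    tr$velocity_mm_s[is.na(tr$velocity_mm_s)] <- 15
    length(detect_cycles(tr)$peaks) == 4
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("indices from a noiseless 30/15 trace give RI exactly 0.5", {
  tr <- generate_waveform(waveform_spec(hr = 400, psv = 30, edv = 15, n_cycles = 4))
  di <- doppler_indices(tr)
  expect_equal(di$psv, 30)
  expect_equal(di$edv, 15)
  expect_equal(di$ri, 0.5)
  expect_equal(di$ri, 1 - di$edv / di$psv, tolerance = 1e-15)  # identity form
  expect_true(di$n_cycles_used >= 3 && di$n_cycles_used <= 4)
})

test_that("MV-calibrated trace yields the matching pulsatility index", {
  tr <- generate_waveform(waveform_spec(hr = 400, psv = 30, edv = 15,
                                        mv_target = 12.71, n_cycles = 4))
  di <- doppler_indices(tr)
  expect_equal(di$edv, 15)          # EDV is pre-upstroke, not the trough
  expect_lt(abs(di$pi - 15 / 12.71), 0.005)
  expect_lt(abs(di$mv - 12.71), 0.06)
})

test_that("a flat-systole trace (psv = edv) gives zero RI and PI", {
  # pulse with tiny residual peaks so detection works, then exact flat check
  t <- seq(0, 0.6, by = 1e-3)
  v <- 20 + 1e-6 * sin(2 * pi * t / 0.15)
  tr <- doppler_trace(t, v, hr_hint = 400)
  di <- doppler_indices(tr)
  expect_equal(di$ri, 0, tolerance = 1e-6)
  expect_equal(di$pi, 0, tolerance = 1e-6)
})

test_that("RI and PI are scale-invariant; PSV, EDV, MV and VTI scale linearly", {
  tr <- generate_waveform(waveform_spec(hr = 400, psv = 30, edv = 15,
                                        mv_target = 16, n_cycles = 4))
  d1 <- doppler_indices(tr)
  tr$velocity_mm_s <- tr$velocity_mm_s * 3.2
  d2 <- doppler_indices(tr)
  expect_equal(d2$ri, d1$ri, tolerance = 1e-12)
  expect_equal(d2$pi, d1$pi, tolerance = 1e-12)
  expect_equal(d2$psv, 3.2 * d1$psv)
  expect_equal(d2$edv, 3.2 * d1$edv)
  expect_equal(d2$mv, 3.2 * d1$mv, tolerance = 1e-12)
  expect_equal(d2$vti, 3.2 * d1$vti, tolerance = 1e-12)
})

test_that("PI >= RI whenever MV <= PSV, across generated traces", {
  for (s in 1:20) {
    psv <- runif(1, 20, 60); edv <- runif(1, 0.2, 0.9) * psv
    tr <- generate_waveform(waveform_spec(hr = 400, psv = psv, edv = edv,
                                          n_cycles = 4, noise_sd = 0, seed = s))
    di <- doppler_indices(tr)
    expect_lte(di$mv, di$psv)
    expect_gte(di$pi, di$ri)
  }
})

test_that("RI recovered within 0.02 on noisy traces in >= 95/100 seeds", {
  # noise at 5% of PSV on a finely sampled envelope (2 kHz, in keeping with
  # the high pulse-repetition frequency of the acquisition)
  ok <- vapply(1:100, function(s) {
    tr <- generate_waveform(waveform_spec(hr = 400, psv = 30, edv = 15,
                                          n_cycles = 4, noise_sd = 1.5,
                                          sampling_rate = 2000, seed = s))
    di <- doppler_indices(tr, envelope = "smooth")
    abs(di$ri - 0.5) < 0.02
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("CRT/BW and cortical echo change follow their definitions", {
  expect_equal(crt_bw(0.9, 30), 0.03)
  expect_equal(crt_bw(0.9, 60), 0.015)     # doubling BW halves it
  expect_error(crt_bw(0, 30), class = "domain_error")
  ser <- tibble::tibble(mouse_id = rep("m1", 3), age_weeks = c(8, 16, 24),
                        cortex_mean_echo = c(100, 110, 115))
  ch <- cortex_echo_change(ser)
  expect_equal(ch$echo_change, c(0, 10, 15))
  flat <- tibble::tibble(age_weeks = c(8, 16), cortex_mean_echo = c(95, 95))
  expect_true(all(cortex_echo_change(flat)$echo_change == 0))
})

test_that("a configured cortical echogenicity shift is recovered from phantoms", {
  est <- vapply(1:30, function(s) {
    base <- generate_phantom(liver_kidney_phantom_spec(94.8, 120, seed = s))
    follow <- generate_phantom(liver_kidney_phantom_spec(94.8, 130, seed = s + 500))
    roi <- roi_spec(c(300, 480), 1)
    roi_stats(follow, roi)$mean - roi_stats(base, roi)$mean
  }, numeric(1))
  expect_lt(abs(mean(est) - 10), 2)
})
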