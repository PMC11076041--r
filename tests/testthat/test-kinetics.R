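prot <- protocol_standard()

make_traces <- function(raw, roi_id = 1L) {
  tibble::tibble(roi_id = roi_id, frame = seq_along(prot$frame_times),
                 time = prot$frame_times, raw_f = raw)
}

test_that("dF/F0 normalization is exact and gain-invariant", {
  n <- length(prot$frame_times)
  flat <- make_traces(rep(80, n))
  d <- compute_dff(flat, prot)
  expect_equal(d$f0, rep(80, n))
  expect_equal(d$dff, rep(0, n))

  raw <- rep(80, n); raw[10] <- 160
  d2 <- compute_dff(make_traces(raw), prot)
  expect_equal(max(d2$dff), 1)

  for (g in c(0.5, 3, 100)) {
    dg <- compute_dff(make_traces(raw * g), prot)
    expect_equal(dg$dff, d2$dff, tolerance = 1e-12)
  }
})

test_that("non-positive baselines are flagged invalid", {
  d <- compute_dff(make_traces(rep(0, length(prot$frame_times))), prot)
  expect_false(any(d$f0_valid))
})

test_that("responder gate drops flat traces and keeps strong responders", {
  par <- kinetic_params()
  n <- length(prot$frame_times)
  resp <- simulate_trace(par, prot, noise_sd = 0, roi_id = 1L)
  flat <- make_traces(rep(par$f_max_scale * par$f_rest, n), roi_id = 2L)
  d <- compute_dff(dplyr::bind_rows(resp[names(flat)], flat), prot)
  expect_message(kept <- exclude_nonresponders(d, prot), "1 of 2")
  expect_equal(unique(kept$roi_id), 1L)
  expect_equal(attr(kept, "excluded"), 2L)
})

test_that("strong responders are retained at SNR 10 across seeds", {
  par <- kinetic_params()
  retained <- vapply(1:50, function(s) {
    tr <- simulate_experiment(par, prot, n_roi = 1, noise_snr = 10,
                              scale_jitter_sd = 0, seed = s)
    d <- compute_dff(tr, prot)
    k <- suppressMessages(exclude_nonresponders(d, prot))
    nrow(k) > 0
  }, logical(1))
  expect_gte(mean(retained), 0.99)
})

test_that("pure-noise traces are rarely retained by the 3-sigma gate", {
  n <- length(prot$frame_times)
  retained <- vapply(1:200, function(s) {
    raw <- withr::with_seed(s, 100 + rnorm(n, 0, 5))
    d <- compute_dff(make_traces(raw), prot)
    k <- suppressMessages(exclude_nonresponders(d, prot))
    nrow(k) > 0
  }, logical(1))
  expect_lte(mean(retained), 0.05)
})

test_that("trace averaging follows mean/SEM conventions", {
  par <- kinetic_params()
  one <- compute_dff(simulate_trace(par, prot), prot)
  m1 <- average_traces(one)
  expect_equal(m1$mean_dff, one$dff)
  expect_equal(m1$sem_dff, rep(0, nrow(m1)))

  # traces mirror-symmetric about their shared baseline average to zero
  n <- length(prot$frame_times)
  bump <- c(rep(0, 6), seq_len(n - 6))
  up <- make_traces(100 + bump, roi_id = 1L)
  dn <- make_traces(100 - bump, roi_id = 2L)
  m2 <- average_traces(compute_dff(dplyr::bind_rows(up, dn), prot))
  expect_equal(m2$mean_dff, rep(0, n), tolerance = 1e-12)

  expect_error(average_traces(one[0, ]), "no traces")
})

test_that("peak dF/F0 of simulated experiments recovers generator truth", {
  par <- kinetic_params()
  truth <- {
    tr <- simulate_trace(par, prot, noise_sd = 0)
    max((tr$f_true[!tr$nh4cl] - par$f_max_scale * par$f_rest) /
          (par$f_max_scale * par$f_rest))
  }
  mt <- mean_trace_for(par, prot, n_roi = 30, noise_snr = 10, seed = 9)
  expect_lt(abs(peak_dff(mt, prot) - truth) / truth, 0.05)
  # per-ROI option averages individual maxima and is >= mean-trace peak
  d <- compute_dff(simulate_experiment(par, prot, n_roi = 30, noise_snr = 10,
                                       seed = 9), prot)
  expect_gte(peak_dff(d, prot, per_roi = TRUE), peak_dff(mt, prot))
})

test_that("endocytosis fit recovers noise-free generating parameters", {
  par <- kinetic_params(tau_endo = 30)
  mt <- mean_trace_for(par, prot, n_roi = 1, noise_snr = Inf)
  f <- fit_endocytosis(mt, prot)
  expect_true(f$valid)
  expect_equal(f$tau, 30, tolerance = 0.1 / 30)
  expect_equal(f$y0, 0, tolerance = 1e-6)
  # amplitude absorbs the window offset: A = dff(t1) * exp(t1 / tau)
  dff_t1 <- mt$mean_dff[mt$time == 15]
  expect_equal(f$amplitude, dff_t1 * exp(15 / 30), tolerance = 1e-4)
  expect_equal(nrow(f$window), 32)
  expect_equal(f$window$time[1], 20)
})

test_that("slow decays beyond the fit window are discarded", {
  par <- kinetic_params(tau_endo = 300)
  mt <- mean_trace_for(par, prot, n_roi = 1, noise_snr = Inf)
  f <- fit_endocytosis(mt, prot)
  expect_false(f$valid)
  expect_equal(f$tau, 300, tolerance = 0.01)
})

test_that("insufficient post-stimulation frames raise a named error", {
  short <- stim_protocol(frame_times = ((1:20) - 7) * 5, baseline_frames = 6)
  par <- kinetic_params()
  mt <- mean_trace_for(par, short, n_roi = 1, noise_snr = Inf)
  expect_error(fit_endocytosis(mt, short), "32 frames")
})

test_that("recycling pool fraction follows the plateau/F_max definition", {
  bprot <- protocol_bafilomycin()
  n <- length(bprot$frame_times)
  pre <- setdiff(seq_len(n), bprot$nh4cl_frames)
  base <- rep(100, n)
  raw <- base
  raw[bprot$nh4cl_frames] <- 600                  # F_max
  raw[utils::tail(pre, 3)] <- 100 + 0.6 * 500     # plateau at 60%
  tr <- tibble::tibble(frame = seq_len(n), time = bprot$frame_times, raw_f = raw)
  pf <- recycling_pool_fraction(tr, bprot)
  expect_true(pf$valid)
  expect_equal(pf$fraction, 0.6)

  # plateau exactly at F_max
  raw2 <- raw; raw2[utils::tail(pre, 3)] <- 600
  expect_equal(recycling_pool_fraction(
    tibble::tibble(frame = seq_len(n), time = bprot$frame_times, raw_f = raw2),
    bprot)$fraction, 1)

  # affine invariance
  pf2 <- recycling_pool_fraction(
    tibble::tibble(frame = seq_len(n), time = bprot$frame_times,
                   raw_f = 3.7 * raw + 42), bprot)
  expect_equal(pf2$fraction, pf$fraction, tolerance = 1e-12)

  # F_max at baseline -> invalid
  raw3 <- rep(100, n)
  pf3 <- recycling_pool_fraction(
    tibble::tibble(frame = seq_len(n), time = bprot$frame_times, raw_f = raw3),
    bprot)
  expect_false(pf3$valid)
})

test_that("bafilomycin simulation recovers the generating pool fraction", {
  bprot <- protocol_bafilomycin()
  par <- kinetic_params(k_exo = 0.025, recycling_fraction = 0.45,
                        bafilomycin = TRUE)
  tr <- simulate_trace(par, bprot, noise_sd = 0)
  pf <- recycling_pool_fraction(tr, bprot)
  expect_lte(abs(pf$fraction - 0.45), 0.01)
})

test_that("peak response increases monotonically with the exocytosis rate", {
  peaks <- vapply(c(0.002, 0.004, 0.006, 0.008, 0.01), function(k) {
    par <- kinetic_params(k_exo = k)
    mt <- mean_trace_for(par, prot, n_roi = 1, noise_snr = Inf)
    peak_dff(mt, prot)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
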