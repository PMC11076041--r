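# Shared fixtures, all generated in code.

# Digital disc mask of radius r (pixels with center distance <= r).
digital_disc <- function(r) {
  n <- 2L * ceiling(r) + 3L
  c0 <- ceiling(r) + 2L
  d2 <- outer(seq_len(n), seq_len(n), function(i, j) (i - c0)^2 + (j - c0)^2)
  (d2 <= r^2) * 1L
}

# Paste a binary mask into an image at a top-left position, scaled by `value`.
stamp <- function(image, mask, row, col, value) {
  rr <- row:(row + nrow(mask) - 1)
  cc <- col:(col + ncol(mask) - 1)
  image[rr, cc] <- image[rr, cc] + mask * value
  image
}

# Noise-free single-experiment mean dF/F0 trace for given kinetics.
mean_trace_for <- function(params, protocol, n_roi = 30, noise_snr = Inf,
                           seed = 1) {
  tr <- simulate_experiment(params, protocol, n_roi = n_roi,
                            noise_snr = noise_snr,
                            scale_jitter_sd = if (n_roi > 1) 0.2 else 0,
                            seed = seed)
  d <- compute_dff(tr, protocol)
  average_traces(d)
}

expect_no_shared_pixels <- function(puncta) {
  px <- unlist(puncta$pixels)
  expect_equal(anyDuplicated(px), 0L)
}
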