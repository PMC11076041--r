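#' Ground-truth kinetic parameters for synthetic sypHy traces
#'
#' The generator uses a one-compartment surface-fraction model: `f(t)` is the
#' fraction of reporter on the plasma-membrane surface (unquenched). During
#' stimulation vesicles fuse at rate `k_exo`, limited by the recycling pool
#' (`recycling_fraction`); retrieved reporter is re-quenched with time constant
#' `tau_endo`:
#'
#'   df/dt = k_exo * (1 - f / recycling_fraction) * s(t) - f / tau_endo
#'
#' with `s(t) = 1` during stimulation and 0 otherwise. Under bafilomycin the
#' re-quenching term is dropped (reacidification blocked), so exocytosis is
#' cumulative and saturates at `recycling_fraction`. After stimulation the
#' model decays as a single exponential with time constant `tau_endo`, the
#' same functional form the endocytosis fit assumes, so the generating
#' `tau_endo` is an analytic truth for [fit_endocytosis()].
#'
#' Fluorescence maps the surface fraction linearly:
#' `F(t) = f_max_scale * (f_rest + (1 - f_rest) * f(t))`, and NH4Cl frames
#' report `f_max_scale` (full alkalinization).
#'
#' @param f_rest Resting surface fraction in `[0, 1)` (default 0.05).
#' @param k_exo Exocytosis rate during stimulation, per second (default 0.005).
#' @param tau_endo Endocytosis (re-quench) time constant, seconds (default 30).
#' @param recycling_fraction Recycling-pool fraction of total vesicles, in
#'   `(0, 1]` (default 0.45).
#' @param f_max_scale Fluorescence units corresponding to surface fraction 1
#'   (default 1000).
#' @param bafilomycin Logical; drop the re-quench term (default `FALSE`).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(f_rest = 0.05,
                           k_exo = 0.005,
                           tau_endo = 30,
                           recycling_fraction = 0.45,
                           f_max_scale = 1000,
                           bafilomycin = FALSE) {
  vals <- c(f_rest, k_exo, tau_endo, recycling_fraction, f_max_scale)
  if (!all(is.finite(vals))) {
    stop("kinetic parameters must be finite", call. = FALSE)
  }
  stopifnot(f_rest >= 0, f_rest < 1, k_exo >= 0, tau_endo > 0,
            recycling_fraction > 0, recycling_fraction <= 1,
            f_max_scale > 0, is.logical(bafilomycin))
  structure(
    list(f_rest = f_rest, k_exo = k_exo, tau_endo = tau_endo,
         recycling_fraction = recycling_fraction,
         f_max_scale = f_max_scale, bafilomycin = bafilomycin),
    class = "kinetic_params"
  )
}

# Closed-form surface fraction f(t) of the one-compartment model.
# During stimulation the ODE is linear with rate b = k/R + [!baf] 1/tau and
# steady state k/b; afterwards it is free exponential decay (or constant
# under bafilomycin).
surface_fraction <- function(t, params, protocol) {
  t0 <- protocol$stim_start
  t1 <- t0 + protocol$stim_duration
  k <- params$k_exo
  R <- params$recycling_fraction
  b <- k / R + if (params$bafilomycin) 0 else 1 / params$tau_endo
  fss <- if (b > 0) k / b else 0
  f1 <- fss * (1 - exp(-b * (t1 - t0)))      # value at stimulation end
  f <- numeric(length(t))
  during <- t >= t0 & t < t1
  after <- t >= t1
  f[during] <- fss * (1 - exp(-b * (t[during] - t0)))
  f[after] <- if (params$bafilomycin) f1 else
    f1 * exp(-(t[after] - t1) / params$tau_endo)
  f
}

#' Simulate a single sypHy fluorescence trace
#'
#' Samples the one-compartment surface-fraction model (see [kinetic_params()])
#' at the protocol's frame times, maps to raw fluorescence, sets NH4Cl frames
#' to the alkalinization level `f_max_scale`, and adds Gaussian read noise.
#' With `noise_sd = 0` the output is deterministic and independent of `seed`.
#'
#' @param params A [kinetic_params()] object.
#' @param protocol A [stim_protocol()].
#' @param noise_sd Additive Gaussian noise SD, fluorescence units.
#' @param seed Optional integer seed (local to this call).
#' @param roi_id Identifier stored in the `roi_id` column (default 1).
#' @return A tibble with one row per frame: `roi_id`, `frame`, `time`,
#'   `raw_f`, `f_surface` (noise-free ground-truth surface fraction),
#'   `f_true` (noise-free fluorescence), `nh4cl`.
#' @export
simulate_trace <- function(params, protocol, noise_sd = 0, seed = NULL,
                           roi_id = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(protocol, "stim_protocol"),
            is.numeric(noise_sd), is.finite(noise_sd), noise_sd >= 0)
  t <- protocol$frame_times
  f <- surface_fraction(t, params, protocol)
  f_true <- params$f_max_scale * (params$f_rest + (1 - params$f_rest) * f)
  nh4cl <- is_nh4cl_frame(protocol)
  f_true[nh4cl] <- params$f_max_scale
  raw <- f_true
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      raw <- withr::with_seed(seed, f_true + stats::rnorm(length(t), 0, noise_sd))
    } else {
      raw <- f_true + stats::rnorm(length(t), 0, noise_sd)
    }
  }
  tibble::tibble(
    roi_id = roi_id, frame = seq_along(t), time = t,
    raw_f = raw, f_surface = f, f_true = f_true, nh4cl = nh4cl
  )
}

#' Simulate a multi-ROI pHluorin experiment
#'
#' Generates `n_roi` bouton traces sharing one protocol and one set of kinetic
#' parameters, with optional per-bouton log-normal jitter of the fluorescence
#' scale (inter-bouton brightness variability) and per-frame Gaussian noise.
#' `noise_snr` expresses the per-ROI noise as peak dF/F0 signal-to-noise: the
#' noise SD is set to `f0 * peak_dff_true / noise_snr` for each bouton.
#'
#' @param params A [kinetic_params()].
#' @param protocol A [stim_protocol()].
#' @param n_roi Number of boutons (default 30, the minimum analysed per
#'   experiment in the assays this package models).
#' @param noise_snr Peak-dF/F0 signal-to-noise ratio per ROI (default 10);
#'   `Inf` for noise-free.
#' @param scale_jitter_sd SD of log-normal per-bouton brightness jitter
#'   (default 0.2; 0 disables).
#' @param seed Integer seed.
#' @return A tibble of stacked traces (see [simulate_trace()]).
#' @export
simulate_experiment <- function(params, protocol, n_roi = 30,
                                noise_snr = 10, scale_jitter_sd = 0.2,
                                seed = NULL) {
  stopifnot(n_roi >= 1)
  run <- function() {
    f <- surface_fraction(protocol$frame_times, params, protocol)
    peak_dff <- max((1 - params$f_rest) * f / params$f_rest)
    purrr::map_dfr(seq_len(n_roi), function(i) {
      scale <- if (scale_jitter_sd > 0)
        exp(stats::rnorm(1, 0, scale_jitter_sd)) else 1
      p_i <- params
      p_i$f_max_scale <- params$f_max_scale * scale
      f0_i <- p_i$f_max_scale * p_i$f_rest
      sd_i <- if (is.finite(noise_snr) && peak_dff > 0)
        f0_i * peak_dff / noise_snr else 0
      simulate_trace(p_i, protocol, noise_sd = sd_i, roi_id = i)
    })
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
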