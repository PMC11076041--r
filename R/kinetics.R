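#' Normalize raw ROI traces to dF/F0
#'
#' The baseline `F0` of each ROI is the mean raw fluorescence over the
#' protocol's pre-stimulation baseline frames (six in the standard protocol);
#' the increment `dF(t) = F(t) - F0` is divided by `F0`. NH4Cl frames are
#' flagged and carried separately — they report total reporter fluorescence
#' (`F_max`) and are excluded from kinetic statistics. dF/F0 is invariant to a
#' multiplicative gain on the raw trace.
#'
#' @param traces Tibble with columns `roi_id`, `frame`, `time`, `raw_f`
#'   (stacked ROI traces sharing the protocol's frame schedule).
#' @param protocol A [stim_protocol()] with at least 6 baseline frames.
#' @return The input tibble with added columns `f0`, `dff`, `nh4cl` and
#'   `f0_valid` (`FALSE` when `f0 <= 0`; such traces are excluded downstream).
#' @export
compute_dff <- function(traces, protocol) {
  stopifnot(inherits(protocol, "stim_protocol"),
            all(c("roi_id", "frame", "time", "raw_f") %in% names(traces)))
  if (protocol$baseline_frames < 6) {
    stop("at least 6 pre-stimulation baseline frames are required", call. = FALSE)
  }
  base_idx <- baseline_frame_idx(protocol)
  nh4cl <- is_nh4cl_frame(protocol)
  traces <- tibble::as_tibble(traces)
  traces$nh4cl <- nh4cl[traces$frame]
  out <- dplyr::mutate(
    dplyr::group_by(traces, .data$roi_id),
    f0 = mean(.data$raw_f[.data$frame %in% base_idx]),
    f0_valid = .data$f0 > 0,
    dff = ifelse(.data$f0 > 0, (.data$raw_f - .data$f0) / .data$f0, NA_real_)
  )
  dplyr::ungroup(out)
}

#' Exclude non-responding ROIs
#'
#' Retains ROIs whose mean dF/F0 over the stimulation window exceeds
#' `criterion_sd_mult` times that ROI's baseline dF/F0 standard deviation — a
#' standard signal-detection gate for puncta that do not respond to
#' stimulation. The window runs from just after stimulation onset to
#' stimulation end (the onset frame itself still sits at baseline). ROIs with
#' invalid baselines (`f0 <= 0`) are always excluded.
#'
#' @param dff_traces Output of [compute_dff()].
#' @param protocol The shared [stim_protocol()].
#' @param criterion_sd_mult Gate multiplier (default 3).
#' @return The retained traces; attribute `excluded` lists dropped `roi_id`s.
#'   A message reports the counts.
#' @export
exclude_nonresponders <- function(dff_traces, protocol, criterion_sd_mult = 3) {
  stim_idx <- response_window_frames(protocol)
  base_idx <- baseline_frame_idx(protocol)
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(dff_traces, .data$roi_id),
    base_sd = stats::sd(.data$dff[.data$frame %in% base_idx]),
    stim_mean = mean(.data$dff[.data$frame %in% stim_idx]),
    ok = all(.data$f0_valid), .groups = "drop"
  )
  keep <- stats_tbl$ok & !is.na(stats_tbl$stim_mean) &
    stats_tbl$stim_mean > criterion_sd_mult * dplyr::coalesce(stats_tbl$base_sd, 0)
  excluded <- stats_tbl$roi_id[!keep]
  message(sprintf("excluded %d of %d ROIs as non-responders",
                  length(excluded), nrow(stats_tbl)))
  out <- dplyr::filter(dff_traces, !(.data$roi_id %in% excluded))
  attr(out, "excluded") <- excluded
  out
}

#' Average dF/F0 traces across ROIs
#'
#' Per-frame mean and SEM of dF/F0 across ROIs (the experiment-level trace the
#' kinetic fits operate on). With a single ROI the SEM is 0 by convention.
#'
#' @param dff_traces Output of [compute_dff()] (after responder filtering).
#' @return Tibble with `frame`, `time`, `nh4cl`, `mean_dff`, `sem_dff`, `n`.
#' @export
average_traces <- function(dff_traces) {
  if (!nrow(dff_traces)) {
    stop("no traces to average (all ROIs excluded?)", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(dff_traces, .data$frame),
    time = .data$time[1], nh4cl = .data$nh4cl[1],
    mean_dff = mean(.data$dff), n = dplyr::n(),
    sem_dff = ifelse(dplyr::n() > 1,
                     stats::sd(.data$dff) / sqrt(dplyr::n()), 0),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$frame)
}

#' Peak dF/F0 response
#'
#' The peak is the maximum of the mean dF/F0 trace over frames from
#' stimulation onset to the end of the recording, excluding NH4Cl frames
#' (matching peak values read from plotted mean traces). Alternatively,
#' `per_roi = TRUE` averages each ROI's own maximum.
#'
#' @param x A mean trace from [average_traces()] (default) or, with
#'   `per_roi = TRUE`, ROI-level dF/F0 traces from [compute_dff()].
#' @param protocol The [stim_protocol()].
#' @param per_roi Average per-ROI maxima instead (default `FALSE`).
#' @return Peak dF/F0 (scalar).
#' @export
peak_dff <- function(x, protocol, per_roi = FALSE) {
  sel <- x$time >= protocol$stim_start & !x$nh4cl
  if (!any(sel)) stop("no post-onset non-NH4Cl frames", call. = FALSE)
  if (per_roi) {
    m <- dplyr::summarise(dplyr::group_by(x[sel, ], .data$roi_id),
                          pk = max(.data$dff), .groups = "drop")
    return(mean(m$pk))
  }
  max(x$mean_dff[sel])
}

# Variable-projection fit of y = y0 + A exp(-t/tau): global grid over tau with
# linear least squares for (y0, A), then Levenberg-Marquardt refinement.
fit_exp_decay <- function(t, y, tau_bounds = c(1e-3, 1e4)) {
  rss_tau <- function(tau) {
    X <- cbind(1, exp(-t / tau))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  taus <- exp(seq(log(tau_bounds[1]), log(tau_bounds[2]), length.out = 120))
  rss <- vapply(taus, rss_tau, numeric(1))
  i <- which.min(rss)
  br <- c(taus[max(1, i - 1)], taus[min(length(taus), i + 1)])
  tau0 <- stats::optimize(rss_tau, br)$minimum
  cf0 <- stats::lm.fit(cbind(1, exp(-t / tau0)), y)$coefficients
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(y0 = cf0[[1]], A = cf0[[2]], tau = tau0),
      fn = function(p) y - (p$y0 + p$A * exp(-t / p$tau)),
      lower = c(-Inf, -Inf, tau_bounds[1]),
      upper = c(Inf, Inf, tau_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    # keep the variable-projection solution, itself a global minimizer in tau
    return(list(y0 = cf0[[1]], amplitude = cf0[[2]], tau = tau0,
                converged = TRUE,
                residual_rms = sqrt(rss_tau(tau0) / length(t))))
  }
  cf <- fit$par
  list(y0 = cf$y0, amplitude = cf$A, tau = cf$tau,
       converged = TRUE,
       residual_rms = sqrt(fit$deviance / length(t)))
}

#' Fit the endocytosis decay of a mean dF/F0 trace
#'
#' Fits the single-exponential decay `y = y0 + A * exp(-t / tau)` to the 32
#' frames (160 s at 0.2 Hz) beginning 5 s after stimulation cessation, with
#' `t` measured in absolute time from stimulation onset (so the amplitude
#' absorbs the window offset). The fit is discarded (`valid = FALSE`) when the
#' recovered `tau` exceeds the fit-window duration (160 s) or the fit fails.
#'
#' @param mean_trace Tibble from [average_traces()] (columns `time`,
#'   `mean_dff`, `nh4cl`); a ROI-level trace with a `dff` column also works.
#' @param protocol The [stim_protocol()].
#' @param n_points Number of fitted frames (default 32).
#' @param start_gap Seconds between stimulation cessation and the first fitted
#'   frame (default 5).
#' @param max_tau Discard threshold for `tau`, seconds (default 160, the fit
#'   window duration).
#' @return An object of class `decay_fit`: `y0`, `amplitude`, `tau`, `valid`,
#'   `residual_rms`, plus the fitted window. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_endocytosis <- function(mean_trace, protocol, n_points = 32,
                            start_gap = 5, max_tau = 160) {
  ycol <- if ("mean_dff" %in% names(mean_trace)) "mean_dff" else "dff"
  stopifnot(all(c("time", "nh4cl", ycol) %in% names(mean_trace)))
  t_begin <- protocol$stim_start + protocol$stim_duration + start_gap
  win <- mean_trace[!mean_trace$nh4cl & mean_trace$time >= t_begin, ]
  if (nrow(win) < n_points) {
    stop(sprintf(
      "endocytosis fit needs %d frames from %g s after stimulation onset; only %d available",
      n_points, t_begin, nrow(win)), call. = FALSE)
  }
  win <- win[seq_len(n_points), ]
  f <- fit_exp_decay(win$time, win[[ycol]])
  structure(
    list(y0 = f$y0, amplitude = f$amplitude, tau = f$tau,
         valid = isTRUE(f$converged) && f$tau <= max_tau,
         converged = isTRUE(f$converged),
         residual_rms = f$residual_rms,
         max_tau = max_tau, n_points = n_points,
         window = tibble::tibble(time = win$time, dff = win[[ycol]])),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> y = y0 + A exp(-t/tau)\n")
  cat(sprintf("  y0 = %.4g, A = %.4g, tau = %.4g s (%s)\n",
              x$y0, x$amplitude, x$tau,
              if (x$valid) "valid" else sprintf("discarded: tau > %g s or fit failed", x$max_tau)))
  cat(sprintf("  residual RMS %.3g over %d frames\n", x$residual_rms, x$n_points))
  invisible(x)
}

#' Recycling-pool fraction from a bafilomycin trace
#'
#' With reacidification blocked, cumulative exocytosis saturates at the
#' recycling pool. The relative pool size is the ratio of the
#' baseline-subtracted saturation plateau (mean of the last three frames
#' before NH4Cl exposure) to the baseline-subtracted total fluorescence
#' `F_max` (mean over the NH4Cl frames). The statistic is invariant to affine
#' intensity transforms of the whole trace.
#'
#' @param trace A raw trace tibble (columns `frame`, `time`, `raw_f`) — a
#'   single ROI or a ROI-averaged raw trace — acquired under a bafilomycin
#'   protocol.
#' @param protocol A [stim_protocol()] with NH4Cl frames and at least 3
#'   pre-NH4Cl frames.
#' @return An object of class `pool_fraction`: `fraction`, `f_max`, `plateau`,
#'   `f0`, `valid` (`FALSE` when `F_max` does not exceed baseline).
#' @export
recycling_pool_fraction <- function(trace, protocol) {
  stopifnot(inherits(protocol, "stim_protocol"),
            all(c("frame", "raw_f") %in% names(trace)))
  if (!length(protocol$nh4cl_frames)) {
    stop("protocol has no NH4Cl frames; F_max is undefined", call. = FALSE)
  }
  pre <- setdiff(seq_along(protocol$frame_times), protocol$nh4cl_frames)
  if (length(pre) < 3) stop("need at least 3 pre-NH4Cl frames", call. = FALSE)
  f <- trace$raw_f[match(seq_along(protocol$frame_times), trace$frame)]
  f0 <- mean(f[baseline_frame_idx(protocol)])
  plateau <- mean(f[utils::tail(pre, 3)])
  f_max <- mean(f[protocol$nh4cl_frames])
  valid <- is.finite(f_max) && f_max > f0
  structure(
    list(fraction = if (valid) (plateau - f0) / (f_max - f0) else NA_real_,
         f_max = f_max, plateau = plateau, f0 = f0, valid = valid),
    class = "pool_fraction"
  )
}

#' @export
print.pool_fraction <- function(x, ...) {
  cat("<pool_fraction>\n")
  if (x$valid) {
    cat(sprintf("  recycling pool fraction = %.3f\n", x$fraction))
  } else {
    cat("  invalid: F_max does not exceed baseline\n")
  }
  cat(sprintf("  baseline %.4g, plateau %.4g, F_max %.4g\n",
              x$f0, x$plateau, x$f_max))
  invisible(x)
}
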