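#' Fit a Gaussian-on-offset model to a line profile
#'
#' Least-squares fit of `F(x) = F_axon + F_syn * exp(-(x - x_c)^2 / (2 w^2))`
#' to an intensity profile drawn along an axon and through a synaptic
#' punctum. `F_axon` is the axonal (offset) intensity, `F_syn` the synaptic
#' amplitude, `x_c` the punctum center and `w` the Gaussian SD. Fits that fail
#' to converge, or that recover a non-positive synaptic amplitude (no peak),
#' are flagged `converged = FALSE` and excluded from downstream summaries.
#'
#' @param profile Tibble with columns `x` (strictly increasing positions) and
#'   `intensity`; at least 5 points.
#' @return An object of class `profile_fit`: `f_axon`, `f_syn`, `x_c`, `w`
#'   (positive), `fwhm` (`2.355 w`, see [fwhm_from_sigma()]), `converged`,
#'   `residual_rms`. Supports [generics::tidy()] and [generics::glance()].
#'   A fit is treated as peakless (`converged = FALSE`) when the recovered
#'   amplitude does not exceed twice the residual RMS.
#' @export
fit_profile <- function(profile) {
  stopifnot(all(c("x", "intensity") %in% names(profile)))
  x <- profile$x; y <- profile$intensity
  if (length(x) < 5) stop("profile needs at least 5 points", call. = FALSE)
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing", call. = FALSE)
  failed <- structure(
    list(f_axon = NA_real_, f_syn = NA_real_, x_c = NA_real_, w = NA_real_,
         fwhm = NA_real_, converged = FALSE, residual_rms = NA_real_),
    class = "profile_fit")
  if (stats::sd(y) == 0) return(failed)
  span <- diff(range(x))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(fa = min(y), fs = max(y) - min(y),
                 xc = x[which.max(y)], w = span / 6),
      fn = function(p) y - (p$fa + p$fs * exp(-(x - p$xc)^2 / (2 * p$w^2))),
      lower = c(-Inf, -Inf, min(x), 1e-9),
      upper = c(Inf, Inf, max(x), span),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) return(failed)
  cf <- fit$par
  rms <- sqrt(fit$deviance / length(x))
  # no peak: non-positive amplitude, or amplitude buried in the residuals
  if (cf$fs <= 0 || cf$fs <= 2 * rms) return(failed)
  w <- abs(cf$w)
  structure(
    list(f_axon = cf$fa, f_syn = cf$fs, x_c = cf$xc, w = w,
         fwhm = fwhm_from_sigma(w), converged = TRUE,
         residual_rms = sqrt(fit$deviance / length(x))),
    class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat("<profile_fit> F(x) = F_axon + F_syn exp(-(x-x_c)^2 / 2w^2)\n")
  if (!x$converged) {
    cat("  not converged (flat or peakless profile)\n")
    return(invisible(x))
  }
  cat(sprintf("  F_axon = %.4g, F_syn = %.4g, x_c = %.4g, w = %.4g\n",
              x$f_axon, x$f_syn, x$x_c, x$w))
  cat(sprintf("  FWHM = %.4g, residual RMS %.3g\n", x$fwhm, x$residual_rms))
  invisible(x)
}

#' Convert a Gaussian SD to full width at half maximum
#'
#' `FWHM = 2 sqrt(2 ln 2) sigma = 2 sqrt(ln 4) sigma`, approximately
#' `2.355 sigma`: the distance between the half-maximum crossings of a
#' Gaussian with standard deviation `sigma`.
#'
#' @param sigma Gaussian SD (non-negative; same units as the profile axis).
#' @return FWHM in the same units.
#' @export
fwhm_from_sigma <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma < 0)) {
    stop("`sigma` must be non-negative and finite", call. = FALSE)
  }
  2 * sqrt(2 * log(2)) * sigma
}

#' Two-channel synaptic enrichment
#'
#' Excess of the reporter's synapse-to-axon intensity ratio over that of the
#' volume marker:
#' `E% = ((F_syn_red / F_axon_red) / (F_syn_blue / F_axon_blue) - 1) * 100`.
#' E% is invariant to independent multiplicative rescaling of either channel;
#' identical channel ratios give 0.
#'
#' @param red_fit,blue_fit Converged [fit_profile()] results for the reporter
#'   (red) and volume (blue) channels.
#' @return An object of class `enrichment_result`: `e_percent`, `red_ratio`,
#'   `blue_ratio`, `valid` (`FALSE` when either fit failed or any intensity
#'   component is non-positive).
#' @export
enrichment <- function(red_fit, blue_fit) {
  stopifnot(inherits(red_fit, "profile_fit"), inherits(blue_fit, "profile_fit"))
  comps <- c(red_fit$f_axon, red_fit$f_syn, blue_fit$f_axon, blue_fit$f_syn)
  valid <- isTRUE(red_fit$converged) && isTRUE(blue_fit$converged) &&
    all(is.finite(comps)) && all(comps > 0)
  if (!valid) {
    return(structure(list(e_percent = NA_real_, red_ratio = NA_real_,
                          blue_ratio = NA_real_, valid = FALSE),
                     class = "enrichment_result"))
  }
  rr <- red_fit$f_syn / red_fit$f_axon
  br <- blue_fit$f_syn / blue_fit$f_axon
  structure(list(e_percent = (rr / br - 1) * 100,
                 red_ratio = rr, blue_ratio = br, valid = TRUE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  if (x$valid) {
    cat(sprintf("  E%% = %.2f (red ratio %.3g, blue ratio %.3g)\n",
                x$e_percent, x$red_ratio, x$blue_ratio))
  } else {
    cat("  undefined (failed fit or non-positive intensity component)\n")
  }
  invisible(x)
}

#' Fit a table of line profiles
#'
#' Applies [fit_profile()] to each `(profile_id, channel)` group of a tidy
#' profile table and returns one row per fit.
#'
#' @param profiles Tibble with columns `x`, `intensity`, `profile_id` and
#'   optionally `channel` and `experiment_id`.
#' @return Tibble with identifiers and the fitted parameters (`f_axon`,
#'   `f_syn`, `x_c`, `w`, `fwhm`, `converged`, `residual_rms`).
#' @export
fit_profiles <- function(profiles) {
  stopifnot(all(c("x", "intensity", "profile_id") %in% names(profiles)))
  keys <- intersect(c("profile_id", "channel", "experiment_id"), names(profiles))
  grouped <- dplyr::group_by(tibble::as_tibble(profiles),
                             dplyr::across(dplyr::all_of(keys)))
  dplyr::summarise(
    grouped,
    {
      f <- fit_profile(dplyr::pick(dplyr::everything()))
      tibble::tibble(f_axon = f$f_axon, f_syn = f$f_syn, x_c = f$x_c,
                     w = f$w, fwhm = f$fwhm, converged = f$converged,
                     residual_rms = f$residual_rms)
    },
    .groups = "drop"
  )
}

#' Per-experiment mean FWHM
#'
#' Non-converged fits are excluded; FWHM values are averaged per experiment.
#' Experiment means — not individual profiles — are the statistical units
#' passed to group comparisons. Experiments with no converged fit are dropped
#' with a warning.
#'
#' @param fits Tibble of fits (e.g. from [fit_profiles()]) with columns
#'   `fwhm`, `converged` and `experiment_id`.
#' @return Tibble with `experiment_id`, `mean_fwhm`, `n_profiles`.
#' @export
fwhm_experiment <- function(fits) {
  stopifnot(all(c("fwhm", "converged", "experiment_id") %in% names(fits)))
  n_exp <- dplyr::n_distinct(fits$experiment_id)
  ok <- dplyr::filter(tibble::as_tibble(fits), .data$converged)
  out <- dplyr::summarise(
    dplyr::group_by(ok, .data$experiment_id),
    mean_fwhm = mean(.data$fwhm), n_profiles = dplyr::n(), .groups = "drop"
  )
  if (nrow(out) < n_exp) {
    warning(sprintf("%d experiment(s) dropped: no converged profile fits",
                    n_exp - nrow(out)), call. = FALSE)
  }
  out
}
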