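#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decay fit
#'
#' One row per parameter of the endocytosis decay model.
#'
#' @param x A `decay_fit` from [fit_endocytosis()].
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("y0", "amplitude", "tau"),
                 estimate = c(x$y0, x$amplitude, x$tau))
}

#' @rdname tidy.decay_fit
#' @return For `glance`: a one-row tibble with `tau`, `valid`,
#'   `residual_rms`, `n_points`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, valid = x$valid,
                 residual_rms = x$residual_rms, n_points = x$n_points)
}

#' Tidy a Gaussian profile fit
#'
#' @param x A `profile_fit` from [fit_profile()].
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @method tidy profile_fit
#' @export
tidy.profile_fit <- function(x, ...) {
  tibble::tibble(term = c("f_axon", "f_syn", "x_c", "w", "fwhm"),
                 estimate = c(x$f_axon, x$f_syn, x$x_c, x$w, x$fwhm))
}

#' @rdname tidy.profile_fit
#' @return For `glance`: a one-row tibble with `w`, `fwhm`, `converged`,
#'   `residual_rms`.
#' @method glance profile_fit
#' @export
glance.profile_fit <- function(x, ...) {
  tibble::tibble(w = x$w, fwhm = x$fwhm, converged = x$converged,
                 residual_rms = x$residual_rms)
}

#' Tidy a gated group comparison
#'
#' Returns the posthoc table when one exists, otherwise the single test
#' result.
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  if (!is.null(x$posthoc)) return(x$posthoc)
  tibble::tibble(test = x$chosen_test, p_value = x$p_value, stars = x$stars)
}

#' @rdname tidy.group_comparison
#' @return For `glance`: a one-row tibble with the chosen test, p-value,
#'   stars, normality verdict and outlier count.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(chosen_test = x$chosen_test, p_value = x$p_value,
                 stars = x$stars, all_normal = x$all_normal,
                 n_outliers_removed = sum(lengths(x$outliers_removed)))
}
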