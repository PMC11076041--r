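gauss_profile <- function(f_axon, f_syn, x_c, w, x = seq(-12, 12, by = 0.25)) {
  tibble::tibble(x = x,
                 intensity = f_axon + f_syn * exp(-(x - x_c)^2 / (2 * w^2)))
}

test_that("profile fit recovers noise-free generating parameters", {
  f <- fit_profile(gauss_profile(10, 40, 0.7, 2))
  expect_true(f$converged)
  expect_equal(f$f_axon, 10, tolerance = 1e-6)
  expect_equal(f$f_syn, 40, tolerance = 1e-6)
  expect_equal(f$x_c, 0.7, tolerance = 1e-6)
  expect_equal(f$w, 2, tolerance = 1e-6)
  expect_equal(f$fwhm, 2 * sqrt(2 * log(2)) * 2)
})

test_that("flat or peakless profiles are flagged non-converged", {
  flat <- tibble::tibble(x = seq(0, 10), intensity = rep(5, 11))
  expect_false(fit_profile(flat)$converged)
  dip <- gauss_profile(50, -30, 0, 2)  # negative amplitude: a trough
  expect_false(fit_profile(dip)$converged)
  expect_error(fit_profile(tibble::tibble(x = 1:3, intensity = 1:3)),
               "at least 5")
  expect_error(fit_profile(tibble::tibble(x = c(1, 1, 2, 3, 4),
                                          intensity = rep(1, 5))),
               "increasing")
})

test_that("sigma-to-FWHM conversion is linear and matches half-max crossings", {
  expect_equal(round(fwhm_from_sigma(1), 3), 2.355)
  expect_equal(fwhm_from_sigma(0), 0)
  expect_error(fwhm_from_sigma(-1), "non-negative")
  expect_equal(fwhm_from_sigma(3 * 1.7), 3 * fwhm_from_sigma(1.7))

  # numeric oracle: distance between half-maximum crossings on a dense grid
  sigma <- 2
  x <- seq(-12, 12, length.out = 1e5)
  y <- exp(-x^2 / (2 * sigma^2))
  above <- which(y >= 0.5)
  lo <- min(above); hi <- max(above)
  cross_left <- x[lo - 1] + (0.5 - y[lo - 1]) / (y[lo] - y[lo - 1]) * diff(x)[1]
  cross_right <- x[hi] + (y[hi] - 0.5) / (y[hi] - y[hi + 1]) * diff(x)[1]
  oracle <- cross_right - cross_left
  expect_lt(abs(fwhm_from_sigma(sigma) - oracle) / oracle, 1e-6)
})

test_that("noisy profile fits recover width within tolerance (Monte Carlo)", {
  errs <- vapply(1:60, function(s) {
    pp <- simulate_profile_pair(
      red = list(f_axon = 10, f_syn = 40, x_c = 0, w = 2),
      blue = list(f_axon = 10, f_syn = 40, x_c = 0, w = 2),
      noise_sd = 2, seed = s)   # 5% of F_syn
    f <- fit_profile(pp[pp$channel == "red", ])
    abs(f$w - 2) / 2
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("enrichment matches the ratio-of-ratios definition", {
  red <- fit_profile(gauss_profile(10, 30, 0, 2))
  blue <- fit_profile(gauss_profile(10, 20, 0, 2))
  e <- enrichment(red, blue)
  expect_true(e$valid)
  expect_equal(e$e_percent, 50, tolerance = 1e-6)

  same <- enrichment(red, red)
  expect_equal(same$e_percent, 0, tolerance = 1e-9)
})

test_that("enrichment is channel-gain invariant and swap-equivariant", {
  red <- fit_profile(gauss_profile(10, 30, 0, 2))
  red7 <- fit_profile(gauss_profile(70, 210, 0, 2))   # every red value x 7
  blue <- fit_profile(gauss_profile(5, 10, 0, 2))
  expect_equal(enrichment(red7, blue)$e_percent,
               enrichment(red, blue)$e_percent, tolerance = 1e-6)
  e <- enrichment(red, blue)$e_percent
  e_rev <- enrichment(blue, red)$e_percent
  expect_equal(e_rev, (1 / (1 + e / 100) - 1) * 100, tolerance = 1e-6)
})

test_that("enrichment is undefined for failed fits or non-positive components", {
  red <- fit_profile(gauss_profile(10, 30, 0, 2))
  flat <- fit_profile(tibble::tibble(x = seq(0, 10), intensity = rep(5, 11)))
  expect_false(enrichment(red, flat)$valid)
  no_axon <- fit_profile(gauss_profile(-2, 30, 0, 2))  # non-positive F_axon
  expect_false(enrichment(no_axon, red)$valid)
})

test_that("per-experiment FWHM averages converged fits only", {
  fits <- tibble::tibble(
    experiment_id = "e1",
    fwhm = fwhm_from_sigma(c(1, 2, 3)),
    converged = TRUE
  )
  out <- fwhm_experiment(fits)
  expect_equal(out$mean_fwhm, fwhm_from_sigma(2))

  none <- tibble::tibble(experiment_id = "e2", fwhm = NA_real_,
                         converged = FALSE)
  expect_warning(out2 <- fwhm_experiment(none), "dropped")
  expect_equal(nrow(out2), 0)
})

test_that("dispersed boutons double the compact FWHM (generator truth)", {
  fit_w <- function(sigma_true, seed) {
    pp <- simulate_profile_pair(
      red = list(f_axon = 10, f_syn = 40, x_c = 0, w = sigma_true),
      blue = list(f_axon = 10, f_syn = 40, x_c = 0, w = sigma_true),
      noise_sd = 2, seed = seed)
    fit_profile(pp[pp$channel == "red", ])
  }
  compact <- purrr::map(1:20, ~fit_w(1.5, .x))
  dispersed <- purrr::map(1:20, ~fit_w(3, 100 + .x))
  tab <- tibble::tibble(
    experiment_id = rep(c("compact", "dispersed"), each = 20),
    fwhm = vapply(c(compact, dispersed), `[[`, numeric(1), "fwhm"),
    converged = vapply(c(compact, dispersed), `[[`, logical(1), "converged")
  )
  means <- fwhm_experiment(tab)
  ratio <- means$mean_fwhm[means$experiment_id == "dispersed"] /
    means$mean_fwhm[means$experiment_id == "compact"]
  expect_lte(abs(ratio - 2), 0.1)
})

test_that("fit_profiles maps over a tidy profile table", {
  tbl <- dplyr::bind_rows(
    dplyr::mutate(gauss_profile(10, 30, 0, 2), profile_id = 1L,
                  channel = "red", experiment_id = "e1"),
    dplyr::mutate(gauss_profile(10, 20, 0, 2), profile_id = 1L,
                  channel = "blue", experiment_id = "e1")
  )
  fits <- fit_profiles(tbl)
  expect_equal(nrow(fits), 2)
  expect_true(all(fits$converged))
  expect_equal(sort(fits$f_syn), c(20, 30), tolerance = 1e-6)
})
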