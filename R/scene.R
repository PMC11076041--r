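#' Configuration for a synthetic bouton field
#'
#' Describes a 2-D field of synaptic boutons: isotropic Gaussian spots on dim
#' axonal lines over a constant offset, optionally corrupted by Poisson
#' resampling followed by additive Gaussian read noise.
#'
#' Coordinates are 1-based with `(x, y) = (column, row)` and pixel centers at
#' integer positions; pixel `i` covers `[i - 0.5, i + 0.5]`. Spots are
#' integrated over pixel area (not point-sampled), so spot peak pixel values
#' and total flux have closed forms (error-function differences).
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param boutons Tibble/data frame with columns `x`, `y` (subpixel centers,
#'   inside the image), `sigma` (> 0, pixels) and `amplitude` (>= 0, peak of
#'   the continuous Gaussian, fluorescence units). May have zero rows.
#' @param axons Optional tibble with columns `x0`, `y0`, `x1`, `y1`,
#'   `intensity`: line segments rendered with a Gaussian cross-section.
#' @param axon_sigma Cross-sectional SD of axon lines, pixels (default 1).
#' @param offset Constant background level (default 0).
#' @param noise_gaussian_sd Additive Gaussian noise SD (default 0).
#' @param noise_poisson Logical; Poisson-resample the noiseless image first
#'   (default `FALSE`).
#' @param seed Integer seed used when rendering noise.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(128, 128),
                         boutons = tibble::tibble(
                           x = numeric(), y = numeric(),
                           sigma = numeric(), amplitude = numeric()),
                         axons = NULL,
                         axon_sigma = 1,
                         offset = 0,
                         noise_gaussian_sd = 0,
                         noise_poisson = FALSE,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 4))
  boutons <- tibble::as_tibble(boutons)
  if (nrow(boutons)) {
    stopifnot(all(c("x", "y", "sigma", "amplitude") %in% names(boutons)),
              all(boutons$sigma > 0), all(boutons$amplitude >= 0),
              all(boutons$x >= 1 & boutons$x <= image_shape[2]),
              all(boutons$y >= 1 & boutons$y <= image_shape[1]))
  }
  if (!is.null(axons)) {
    axons <- tibble::as_tibble(axons)
    stopifnot(all(c("x0", "y0", "x1", "y1", "intensity") %in% names(axons)))
  }
  structure(
    list(image_shape = as.integer(image_shape), boutons = boutons,
         axons = axons, axon_sigma = axon_sigma, offset = offset,
         noise_gaussian_sd = noise_gaussian_sd,
         noise_poisson = isTRUE(noise_poisson), seed = as.integer(seed)),
    class = "scene_config"
  )
}

# Pixel-integrated isotropic Gaussian spot: value of pixel (row j, col i) is
# the integral of amplitude * exp(-((x-xc)^2+(y-yc)^2)/(2 sigma^2)) over the
# pixel, i.e. amplitude * 2 pi sigma^2 * dPhi_x * dPhi_y.
spot_image <- function(shape, xc, yc, sigma, amplitude) {
  cols <- seq_len(shape[2]); rows <- seq_len(shape[1])
  dx <- stats::pnorm((cols + 0.5 - xc) / sigma) -
    stats::pnorm((cols - 0.5 - xc) / sigma)
  dy <- stats::pnorm((rows + 0.5 - yc) / sigma) -
    stats::pnorm((rows - 0.5 - yc) / sigma)
  amplitude * 2 * pi * sigma^2 * (dy %o% dx)
}

# Gaussian-tube line segment, point-sampled at pixel centers (adequate for
# sigma >= ~0.7 px; the aliasing error of midpoint sampling is < 1e-4).
segment_image <- function(shape, x0, y0, x1, y1, intensity, sigma) {
  cols <- seq_len(shape[2]); rows <- seq_len(shape[1])
  px <- matrix(cols, shape[1], shape[2], byrow = TRUE)
  py <- matrix(rows, shape[1], shape[2])
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  tt <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  d2 <- (px - (x0 + tt * vx))^2 + (py - (y0 + tt * vy))^2
  intensity * exp(-d2 / (2 * sigma^2))
}

#' Render a synthetic bouton field
#'
#' Sums pixel-integrated Gaussian spots, Gaussian-profile axon lines and a
#' constant offset, then (optionally, in this order) Poisson-resamples and
#' adds Gaussian read noise. Rendering is seeded and reproducible.
#'
#' @param config A [scene_config()].
#' @return A list of class `bouton_scene` with elements `image` (numeric
#'   matrix), `noiseless` (pre-noise image), `truth` (tibble: `bouton`, `x`,
#'   `y`, `sigma`, `amplitude`, `flux` where `flux = amplitude * 2 pi sigma^2`
#'   is the analytic spot integral), `axon_flux` (analytic total line flux)
#'   and `config`.
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  shape <- config$image_shape
  img <- matrix(config$offset, shape[1], shape[2])
  b <- config$boutons
  for (i in seq_len(nrow(b))) {
    img <- img + spot_image(shape, b$x[i], b$y[i], b$sigma[i], b$amplitude[i])
  }
  axon_flux <- 0
  if (!is.null(config$axons)) {
    a <- config$axons
    for (i in seq_len(nrow(a))) {
      img <- img + segment_image(shape, a$x0[i], a$y0[i], a$x1[i], a$y1[i],
                                 a$intensity[i], config$axon_sigma)
      len <- sqrt((a$x1[i] - a$x0[i])^2 + (a$y1[i] - a$y0[i])^2)
      axon_flux <- axon_flux + a$intensity[i] *
        (len * config$axon_sigma * sqrt(2 * pi) + 2 * pi * config$axon_sigma^2)
    }
  }
  noiseless <- img
  if (config$noise_poisson || config$noise_gaussian_sd > 0) {
    img <- withr::with_seed(config$seed, {
      out <- noiseless
      if (config$noise_poisson) {
        out <- matrix(stats::rpois(length(out), pmax(out, 0)),
                      nrow(out), ncol(out))
      }
      if (config$noise_gaussian_sd > 0) {
        out <- out + stats::rnorm(length(out), 0, config$noise_gaussian_sd)
      }
      out
    })
  }
  truth <- tibble::tibble(
    bouton = seq_len(nrow(b)),
    x = b$x, y = b$y, sigma = b$sigma, amplitude = b$amplitude,
    flux = b$amplitude * 2 * pi * b$sigma^2
  )
  structure(list(image = img, noiseless = noiseless, truth = truth,
                 axon_flux = axon_flux, config = config),
            class = "bouton_scene")
}

#' Random well-separated bouton field configuration
#'
#' Places `n_boutons` at uniform random subpixel positions with a minimum
#' pairwise separation (rejection sampling) and a border margin, optionally
#' with a random axon polyline threaded through the bouton centers.
#'
#' @param n_boutons Number of spots.
#' @param image_shape `c(height, width)`.
#' @param sigma Spot SD in pixels (single value or per-bouton vector).
#' @param amplitude Spot amplitude (single value or vector); per-bouton values
#'   are jittered uniformly within `amplitude_jitter` of the nominal value.
#' @param amplitude_jitter Relative jitter of amplitudes (default 0.2).
#' @param min_separation Minimum center-to-center distance, pixels.
#' @param margin Border margin, pixels.
#' @param axons Logical; add an axon polyline through the boutons.
#' @param axon_intensity Line intensity (default 5 percent of `amplitude`).
#' @param seed Integer seed (also stored in the config for noise rendering).
#' @inheritParams scene_config
#' @return A [scene_config()].
#' @export
random_scene <- function(n_boutons = 15,
                         image_shape = c(256, 256),
                         sigma = 2,
                         amplitude = 150,
                         amplitude_jitter = 0.2,
                         min_separation = 6 * max(sigma),
                         margin = 8,
                         axons = FALSE,
                         axon_intensity = 0.05 * max(amplitude),
                         offset = 0,
                         noise_gaussian_sd = 0,
                         noise_poisson = FALSE,
                         seed = 1L) {
  withr::with_seed(seed, {
    xs <- ys <- numeric(0)
    tries <- 0
    while (length(xs) < n_boutons && tries < 20000) {
      tries <- tries + 1
      x <- stats::runif(1, 1 + margin, image_shape[2] - margin)
      y <- stats::runif(1, 1 + margin, image_shape[1] - margin)
      if (!length(xs) || min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_separation) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    if (length(xs) < n_boutons) {
      stop("could not place boutons with the requested separation", call. = FALSE)
    }
    amp <- rep_len(amplitude, n_boutons) *
      stats::runif(n_boutons, 1 - amplitude_jitter, 1 + amplitude_jitter)
    boutons <- tibble::tibble(x = xs, y = ys,
                              sigma = rep_len(sigma, n_boutons),
                              amplitude = amp)
    ax <- NULL
    if (axons && n_boutons >= 2) {
      ord <- order(xs)
      ax <- tibble::tibble(
        x0 = xs[ord][-n_boutons], y0 = ys[ord][-n_boutons],
        x1 = xs[ord][-1], y1 = ys[ord][-1],
        intensity = axon_intensity
      )
    }
    scene_config(image_shape = image_shape, boutons = boutons, axons = ax,
                 offset = offset, noise_gaussian_sd = noise_gaussian_sd,
                 noise_poisson = noise_poisson, seed = seed)
  })
}

#' Multi-frame image stack
#'
#' Lightweight container for an ordered set of 2-D frames with per-frame
#' timestamps and a channel label.
#'
#' @param frames List of numeric matrices of identical dimensions.
#' @param frame_times Numeric vector of acquisition times, one per frame.
#' @param channel Channel label (default `"sypHy"`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_times, channel = "sypHy") {
  stopifnot(is.list(frames), length(frames) == length(frame_times))
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) stop("all frames must share dimensions", call. = FALSE)
  structure(list(frames = frames, frame_times = as.numeric(frame_times),
                 channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d, channel %s\n",
              length(x$frames), d[1], d[2], x$channel))
  invisible(x)
}

#' Render a synthetic sypHy time-lapse stack
#'
#' Couples kinetic traces to a bouton field: frame by frame, each bouton's
#' spot amplitude is set to its trace's raw fluorescence, then the scene is
#' rendered with the configured offset, axons and noise. This gives an
#' end-to-end testbed (detection on the baseline frame, ROI extraction,
#' dF/F0 kinetics) with analytic ground truth.
#'
#' @param config A [scene_config()]; its `boutons` define positions/sigmas.
#' @param traces Tibble of stacked traces (as from [simulate_experiment()])
#'   with `roi_id` in `1:nrow(config$boutons)`; all traces must share the
#'   frame schedule.
#' @return An `image_stack` with attribute `truth` (the scene truth table).
#' @export
render_timelapse <- function(config, traces) {
  stopifnot(inherits(config, "scene_config"))
  n_b <- nrow(config$boutons)
  ids <- sort(unique(traces$roi_id))
  if (!identical(as.integer(ids), seq_len(n_b))) {
    stop("need exactly one trace per bouton (roi_id 1..n_boutons)", call. = FALSE)
  }
  schedules <- dplyr::group_split(dplyr::group_by(traces, .data$roi_id))
  times <- schedules[[1]]$time
  for (s in schedules) {
    if (!isTRUE(all.equal(s$time, times))) {
      stop("all traces must share the frame schedule", call. = FALSE)
    }
  }
  amp <- tidyr::pivot_wider(traces[, c("roi_id", "frame", "raw_f")],
                            names_from = "roi_id", values_from = "raw_f")
  amp <- as.matrix(amp[order(amp$frame), as.character(seq_len(n_b))])
  frames <- withr::with_seed(config$seed, {
    lapply(seq_len(nrow(amp)), function(k) {
      cfg_k <- config
      cfg_k$boutons$amplitude <- pmax(amp[k, ], 0)
      shape <- cfg_k$image_shape
      img <- matrix(cfg_k$offset, shape[1], shape[2])
      b <- cfg_k$boutons
      for (i in seq_len(nrow(b))) {
        img <- img + spot_image(shape, b$x[i], b$y[i], b$sigma[i], b$amplitude[i])
      }
      if (!is.null(cfg_k$axons)) {
        a <- cfg_k$axons
        for (i in seq_len(nrow(a))) {
          img <- img + segment_image(shape, a$x0[i], a$y0[i], a$x1[i], a$y1[i],
                                     a$intensity[i], cfg_k$axon_sigma)
        }
      }
      if (cfg_k$noise_poisson) {
        img <- matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
      }
      if (cfg_k$noise_gaussian_sd > 0) {
        img <- img + stats::rnorm(length(img), 0, cfg_k$noise_gaussian_sd)
      }
      img
    })
  })
  out <- image_stack(frames, times)
  attr(out, "truth") <- tibble::tibble(
    bouton = seq_len(n_b),
    x = config$boutons$x, y = config$boutons$y,
    sigma = config$boutons$sigma
  )
  out
}

#' Simulate a two-channel (reporter + volume marker) line profile
#'
#' Generates paired line profiles obeying the Gaussian-on-offset model
#' `F(x) = F_axon + F_syn * exp(-(x - x_c)^2 / (2 w^2))` for a red reporter
#' channel and a blue volume channel, with additive Gaussian noise. The
#' generating parameters define the true synaptic enrichment
#' `E% = (ratio_red / ratio_blue - 1) * 100` with `ratio = F_syn / F_axon`.
#'
#' @param red,blue Named lists/vectors with `f_axon`, `f_syn`, `x_c`, `w`
#'   (`w > 0`).
#' @param x Positions at which to sample (strictly increasing).
#' @param noise_sd Additive Gaussian noise SD (single value or per-channel
#'   vector of length 2, red then blue).
#' @param seed Optional integer seed.
#' @return A tibble with columns `x`, `intensity`, `channel` ("red"/"blue")
#'   and attribute `truth` (generating parameters and true `e_percent`).
#' @export
simulate_profile_pair <- function(red, blue, x = seq(-12, 12, by = 0.25),
                                  noise_sd = 0, seed = NULL) {
  red <- as.list(red); blue <- as.list(blue)
  stopifnot(red$w > 0, blue$w > 0, all(diff(x) > 0))
  noise_sd <- rep_len(noise_sd, 2)
  model <- function(p) p$f_axon + p$f_syn * exp(-(x - p$x_c)^2 / (2 * p$w^2))
  run <- function() {
    n <- length(x)
    vals <- c(model(red) + stats::rnorm(n, 0, noise_sd[1]),
              model(blue) + stats::rnorm(n, 0, noise_sd[2]))
    tibble::tibble(x = rep(x, 2), intensity = vals,
                   channel = rep(c("red", "blue"), each = n))
  }
  out <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  e_true <- if (red$f_syn > 0 && blue$f_syn > 0) {
    ((red$f_syn / red$f_axon) / (blue$f_syn / blue$f_axon) - 1) * 100
  } else NA_real_
  attr(out, "truth") <- list(red = red, blue = blue, e_percent = e_true)
  out
}
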