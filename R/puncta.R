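#' Detector configuration for iterative-threshold puncta detection
#'
#' The detector descends a schedule of thresholds; at each level it binarizes
#' the (optionally pre-smoothed) image, labels connected components, accepts
#' components passing the area and roundness filters, records them and blanks
#' their pixels so they cannot be re-detected at lower levels.
#'
#' @param threshold_start Starting threshold; a quantile in `(0, 1]` under
#'   `"auto"`/`"quantile"` modes (default 0.999), an absolute level otherwise.
#' @param threshold_floor Final threshold. Ignored under the default `"auto"`
#'   mode, where the floor is a robust background ceiling,
#'   `median + mad_mult * MAD` of the working image; under `"quantile"` it is
#'   a quantile (e.g. 0.5, the median), under `"absolute"` an absolute level.
#'   Must be below `threshold_start`.
#' @param n_steps Number of threshold levels, descending geometrically from
#'   start to floor (default 20). Falls back to a linear schedule when the
#'   floor is not positive.
#' @param threshold_mode `"auto"` (robust background floor; gain-invariant),
#'   `"quantile"` (gain-invariant) or `"absolute"`.
#' @param mad_mult Multiplier of the image MAD in the `"auto"` floor
#'   (default 4).
#' @param floor_frac Lower bound of the `"auto"` floor as a fraction of the
#'   start-to-median intensity range above the median (default 0.02); keeps
#'   the floor above background on noise-free images where the MAD vanishes.
#' @param area_min,area_max Accepted component area in pixels (defaults 4 and
#'   200, suited to ~0.1 um/px scale).
#' @param roundness_min Minimum roundness `4 pi A / P^2` (default 0.7).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @param smooth_sigma SD of the Gaussian pre-smoothing applied to the working
#'   image before thresholding, pixels (default 1; 0 disables). Peak
#'   intensities are always read from the unsmoothed image.
#' @param focus_sd_min Optional focus filter: reject components whose internal
#'   intensity SD is below this floor (default 0 = disabled). This replaces
#'   by-eye rejection of out-of-focus objects with a programmatic criterion.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(threshold_start = 0.999,
                            threshold_floor = 0.5,
                            n_steps = 20,
                            threshold_mode = c("auto", "quantile", "absolute"),
                            mad_mult = 4,
                            floor_frac = 0.02,
                            area_min = 4,
                            area_max = 200,
                            roundness_min = 0.7,
                            connectivity = 8,
                            smooth_sigma = 1,
                            focus_sd_min = 0) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(threshold_mode == "auto" || threshold_floor < threshold_start,
            mad_mult >= 0, floor_frac >= 0, floor_frac < 1, n_steps >= 2,
            area_min >= 1, area_max >= area_min,
            roundness_min > 0, roundness_min <= 1,
            connectivity %in% c(4, 8), smooth_sigma >= 0, focus_sd_min >= 0)
  structure(
    list(threshold_start = threshold_start, threshold_floor = threshold_floor,
         n_steps = as.integer(n_steps), threshold_mode = threshold_mode,
         mad_mult = mad_mult, floor_frac = floor_frac,
         area_min = area_min, area_max = area_max,
         roundness_min = roundness_min, connectivity = connectivity,
         smooth_sigma = smooth_sigma, focus_sd_min = focus_sd_min),
    class = "detector_config"
  )
}

# Perimeter of a binary component: crack-boundary edge count with diagonal
# corner cutting (each right-angle turn replaces two half-edges by a
# hypotenuse), scaled by the standard 0.95 digitization correction so that
# digitized discs score close to their analog perimeter.
component_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  edges <- sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
  s <- m[-nrow(m), -ncol(m)] + m[-nrow(m), -1] + m[-1, -ncol(m)] + m[-1, -1]
  turns <- sum(s == 1L | s == 3L)
  0.95 * (edges - turns * (1 - sqrt(2) / 2))
}

#' Roundness (isoperimetric ratio) of a binary component
#'
#' Computes `4 pi A / P^2`, clamped to at most 1, where `A` is the pixel area
#' and `P` the component perimeter measured by a corner-cut crack-boundary
#' estimator (fixed across the package). A single-pixel component returns 1
#' by convention. Compact discs score near 1; thin bars and lines score well
#' below the default 0.7 acceptance filter.
#'
#' @param mask Logical (or 0/1) matrix marking the component's pixels.
#' @return Roundness in `(0, 1]`.
#' @export
roundness <- function(mask) {
  mask <- mask > 0
  a <- sum(mask)
  if (a == 0) stop("empty component", call. = FALSE)
  if (a == 1) return(1)
  min(1, 4 * pi * a / component_perimeter(mask)^2)
}

# Label connected components. EBImage::bwlabel is 4-connected; 8-connectivity
# merges diagonally adjacent labels with union-find.
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left diagonal pairs
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs)) {
    parent <- seq_len(max(lab))
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_along(parent), find, integer(1))
    relabel <- match(roots, sort(unique(roots)))
    nz <- lab > 0
    lab[nz] <- relabel[lab[nz]]
  }
  lab
}

#' Detect synaptic puncta by iterative threshold descent
#'
#' Implements threshold-descent segmentation: starting from a high threshold,
#' the image is binarized, connected components are filtered by area and
#' roundness, accepted objects are recorded and blanked so they cannot be
#' picked up again, and the threshold is lowered until the floor is reached.
#' Blanking removes the accepted object's entire above-floor support (the
#' floor-level connected component containing it), so a punctum accepted at a
#' high threshold does not reappear as an annulus at lower levels. Detection
#' is deterministic for a fixed image and configuration, and — under
#' `"auto"`/`"quantile"` threshold modes — invariant to a global
#' multiplicative gain.
#'
#' @param image Numeric matrix of intensities (all finite).
#' @param config A [detector_config()].
#' @param keep_pixels Attach each punctum's pixel indices as a list column
#'   `pixels` (default `FALSE`).
#' @return A tibble of puncta sorted by descending detection threshold:
#'   `label`, `x`, `y` (intensity-weighted center of mass, 1-based),
#'   `area`, `roundness`, `peak_intensity` (mean of the 2x2 block at the
#'   center of mass, from the unsmoothed image), `detection_threshold`.
#' @export
detect_puncta <- function(image, config = detector_config(),
                          keep_pixels = FALSE) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!all(is.finite(image))) stop("image contains non-finite pixels", call. = FALSE)
  stopifnot(inherits(config, "detector_config"))
  empty <- tibble::tibble(
    label = integer(), x = numeric(), y = numeric(), area = integer(),
    roundness = numeric(), peak_intensity = numeric(),
    detection_threshold = numeric()
  )
  if (diff(range(image)) == 0) return(empty)

  work <- if (config$smooth_sigma > 0) {
    as.matrix(EBImage::gblur(image, sigma = config$smooth_sigma))
  } else image
  if (config$threshold_mode == "auto") {
    t_start <- stats::quantile(work, config$threshold_start, names = FALSE)
    med <- stats::median(work)
    t_floor <- max(med + config$mad_mult * stats::mad(work),
                   med + config$floor_frac * (t_start - med))
  } else if (config$threshold_mode == "quantile") {
    t_start <- stats::quantile(work, config$threshold_start, names = FALSE)
    t_floor <- stats::quantile(work, config$threshold_floor, names = FALSE)
  } else {
    t_start <- config$threshold_start
    t_floor <- config$threshold_floor
  }
  if (t_start <= t_floor) return(empty)
  thresholds <- if (t_floor > 0 && t_start > 0) {
    exp(seq(log(t_start), log(t_floor), length.out = config$n_steps))
  } else {
    seq(t_start, t_floor, length.out = config$n_steps)
  }
  blank_value <- t_floor - 1
  floor_lab <- label_components(work > t_floor, config$connectivity)

  recs <- list()
  next_label <- 1L
  for (thr in thresholds) {
    mask <- work > thr
    if (!any(mask)) next
    lab <- label_components(mask, config$connectivity)
    n_comp <- max(lab)
    if (n_comp == 0) next
    areas <- tabulate(lab[lab > 0], nbins = n_comp)
    candidates <- which(areas >= config$area_min & areas <= config$area_max)
    for (cid in candidates) {
      px <- which(lab == cid)
      rows <- ((px - 1L) %% nrow(lab)) + 1L
      cols <- ((px - 1L) %/% nrow(lab)) + 1L
      sub <- matrix(0L, diff(range(rows)) + 1L, diff(range(cols)) + 1L)
      sub[cbind(rows - min(rows) + 1L, cols - min(cols) + 1L)] <- 1L
      rnd <- roundness(sub)
      if (rnd <= config$roundness_min) next
      vals <- image[px]
      if (config$focus_sd_min > 0 &&
          (length(vals) < 2 || stats::sd(vals) < config$focus_sd_min)) next
      wsum <- sum(vals)
      if (wsum <= 0) { vals <- rep(1, length(vals)); wsum <- length(vals) }
      cx <- sum(cols * vals) / wsum
      cy <- sum(rows * vals) / wsum
      peak <- tryCatch(peak_intensity(image, c(cx, cy)), error = function(e) NA_real_)
      rec <- tibble::tibble(
        label = next_label, x = cx, y = cy, area = length(px),
        roundness = rnd, peak_intensity = peak, detection_threshold = thr
      )
      if (keep_pixels) rec$pixels <- list(px)
      recs[[length(recs) + 1L]] <- rec
      next_label <- next_label + 1L
      sup <- unique(floor_lab[px])
      sup <- sup[sup > 0]
      work[px] <- blank_value
      if (length(sup)) work[floor_lab %in% sup] <- blank_value
    }
  }
  if (!length(recs)) return(empty)
  out <- dplyr::bind_rows(recs)
  out[order(-out$detection_threshold, out$label), ]
}

#' Peak punctum intensity at the center of mass
#'
#' Mean of the 2x2-pixel block whose top-left pixel is `floor(centroid)`,
#' read from the given image.
#'
#' @param image Numeric matrix.
#' @param centroid Numeric `(x, y)` center of mass (1-based, `x` = column).
#' @return Mean intensity of the 2x2 block.
#' @export
peak_intensity <- function(image, centroid) {
  stopifnot(is.matrix(image), length(centroid) == 2)
  cx <- floor(centroid[1]); cy <- floor(centroid[2])
  if (cx < 1 || cy < 1 || cx + 1 > ncol(image) || cy + 1 > nrow(image)) {
    stop("centroid too close to the image border for a 2x2 block", call. = FALSE)
  }
  mean(image[cy:(cy + 1), cx:(cx + 1)])
}

#' Normalize per-image intensities by each session's control mean
#'
#' Divides every value by the mean of the control condition measured in the
#' same imaging session, so control means map to 1 and inter-session gain
#' differences cancel. Sessions lacking a control image are dropped with a
#' warning.
#'
#' @param data Tibble with columns `session`, `condition` and `value` (one row
#'   per image).
#' @param control_condition Label of the control condition (default
#'   `"control"`).
#' @return The input tibble with an added `value_norm` column, restricted to
#'   sessions that contain the control condition.
#' @export
normalize_sessions <- function(data, control_condition = "control") {
  stopifnot(all(c("session", "condition", "value") %in% names(data)))
  data <- tibble::as_tibble(data)
  ctrl <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(data, .data$condition == control_condition),
                    .data$session),
    control_mean = mean(.data$value), .groups = "drop"
  )
  missing <- setdiff(unique(data$session), ctrl$session)
  if (length(missing)) {
    warning("dropping sessions without a control condition: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::inner_join(data, ctrl, by = "session")
  out$value_norm <- out$value / out$control_mean
  out$control_mean <- NULL
  out
}

#' Condition means of session-normalized intensities
#'
#' Averages normalized values across sessions per condition (session means
#' first, then across sessions), returning the condition-level summary.
#'
#' @param norm_data Output of [normalize_sessions()].
#' @return Tibble with `condition`, `mean_norm`, `sem_norm`, `n_sessions`.
#' @export
condition_summary <- function(norm_data) {
  per_session <- dplyr::summarise(
    dplyr::group_by(norm_data, .data$condition, .data$session),
    m = mean(.data$value_norm), .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(per_session, .data$condition),
    mean_norm = mean(.data$m),
    sem_norm = stats::sd(.data$m) / sqrt(dplyr::n()),
    n_sessions = dplyr::n(), .groups = "drop"
  )
}

#' Match detected puncta against a ground-truth table
#'
#' Greedy nearest-neighbour matching within a distance cutoff; each truth
#' punctum is matched at most once. Reports precision and recall.
#'
#' @param detected Tibble with columns `x`, `y` (e.g. from [detect_puncta()]).
#' @param truth Tibble with columns `x`, `y` (e.g. a scene truth table).
#' @param max_dist Matching radius in pixels (default 2).
#' @return List with `precision`, `recall`, `n_matched`, `n_detected`,
#'   `n_truth`.
#' @export
match_puncta <- function(detected, truth, max_dist = 2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(precision = ifelse(nd == 0, NA_real_, 0),
                recall = ifelse(nt == 0, NA_real_, 0),
                n_matched = 0L, n_detected = nd, n_truth = nt))
  }
  d <- outer(detected$x, truth$x, "-")^2 + outer(detected$y, truth$y, "-")^2
  d <- sqrt(d)
  matched <- 0L
  repeat {
    i <- which.min(d)
    if (d[i] > max_dist) break
    matched <- matched + 1L
    row <- ((i - 1L) %% nd) + 1L; col <- ((i - 1L) %/% nd) + 1L
    d[row, ] <- Inf; d[, col] <- Inf
    if (matched == min(nd, nt)) break
  }
  list(precision = matched / nd, recall = matched / nt,
       n_matched = matched, n_detected = nd, n_truth = nt)
}
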