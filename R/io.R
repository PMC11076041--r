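#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 32-bit float (default) or 16-bit integer TIFF pages.
#' TIFF storage requires values in `[0, 1]`, so frames are divided by a scale
#' factor recorded — together with frame times, channel and bit depth — in a
#' JSON sidecar (`<path>.json`). 16-bit integer data round-trips exactly;
#' float data round-trips at 32-bit float precision.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param bits 16 (integer data) or 32 (float, default).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 32L) {
  stopifnot(inherits(stack, "image_stack"), bits %in% c(16L, 32L))
  lo <- min(vapply(stack$frames, min, numeric(1)))
  if (lo < 0) stop("negative intensities cannot be stored; offset the stack first",
                   call. = FALSE)
  hi <- max(vapply(stack$frames, max, numeric(1)))
  scale <- if (bits == 16L) 65535 else max(hi, 1)
  frames <- lapply(stack$frames, function(f) f / scale)
  if (bits == 16L && hi > 65535) {
    stop("16-bit storage requires values in [0, 65535]", call. = FALSE)
  }
  suppressWarnings(tiff::writeTIFF(frames, path, bits.per.sample = bits,
                                   reduce = FALSE))
  jsonlite::write_json(
    list(scale = scale, frame_times = stack$frame_times,
         channel = stack$channel, bits = bits,
         n_frames = length(stack$frames)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path; the JSON sidecar `<path>.json` restores scale,
#'   frame times and channel. Without a sidecar, frames are returned as
#'   stored (in `[0, 1]`) with frame indices as times.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) {
                      stop("unreadable TIFF: ", path, " (", conditionMessage(e), ")",
                           call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) > 2) p[, , 1] else p)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frames <- lapply(pages, function(p) p * meta$scale)
    if (meta$bits == 16) frames <- lapply(frames, round)
    return(image_stack(frames, meta$frame_times, meta$channel))
  }
  image_stack(pages, seq_along(pages))
}

#' Extract square-ROI mean traces from an image stack
#'
#' For each punctum, averages the `(2 * roi_halfwidth + 1)^2` square of pixels
#' centered on the rounded centroid, per frame. ROIs are equal-size by
#' construction; out-of-bounds ROIs are dropped with a warning, and
#' overlapping ROIs are permitted (a message reports how many overlap).
#'
#' @param stack An [image_stack()].
#' @param puncta Tibble with columns `x`, `y` (e.g. from [detect_puncta()] or
#'   a scene truth table).
#' @param roi_halfwidth ROI half-width in pixels (default 3).
#' @return Tibble of traces: `roi_id`, `frame`, `time`, `raw_f`.
#' @export
extract_roi_traces <- function(stack, puncta, roi_halfwidth = 3) {
  stopifnot(inherits(stack, "image_stack"),
            all(c("x", "y") %in% names(puncta)), roi_halfwidth >= 0)
  d <- dim(stack$frames[[1]])
  cx <- round(puncta$x); cy <- round(puncta$y)
  h <- roi_halfwidth
  inb <- cx - h >= 1 & cx + h <= d[2] & cy - h >= 1 & cy + h <= d[1]
  if (any(!inb)) {
    warning(sprintf("dropping %d out-of-bounds ROI(s)", sum(!inb)), call. = FALSE)
  }
  keep <- which(inb)
  if (!length(keep)) stop("no in-bounds ROIs", call. = FALSE)
  if (length(keep) > 1) {
    dd <- as.matrix(stats::dist(cbind(cx[keep], cy[keep])))
    n_overlap <- sum(dd[upper.tri(dd)] <= 2 * h)
    if (n_overlap > 0) message(n_overlap, " ROI pair(s) overlap")
  }
  purrr::map_dfr(seq_along(keep), function(i) {
    k <- keep[i]
    rows <- (cy[k] - h):(cy[k] + h)
    cols <- (cx[k] - h):(cx[k] + h)
    tibble::tibble(
      roi_id = i,
      frame = seq_along(stack$frames),
      time = stack$frame_times,
      raw_f = vapply(stack$frames, function(f) mean(f[rows, cols]), numeric(1))
    )
  })
}
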