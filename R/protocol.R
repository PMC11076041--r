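#' Stimulation and acquisition protocol
#'
#' A `stim_protocol` records everything the analysis needs to know about how a
#' pHluorin experiment was acquired: when field stimulation started and ended,
#' when each frame was taken, which frames were acquired under NH4Cl
#' (alkalinization, revealing total reporter fluorescence `F_max`), and how
#' many pre-stimulation frames define the baseline `F0`.
#'
#' Stimulation onset is at `stim_start` (0 s by convention); all frame times
#' are on the same clock, so baseline frames have negative times.
#'
#' @param frame_times Numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @param stim_start Stimulation onset in seconds (default 0).
#' @param stim_duration Stimulation duration in seconds.
#' @param stim_rate Stimulation rate in Hz (action potentials per second).
#' @param nh4cl_frames Integer indices of frames acquired under NH4Cl. If
#'   non-empty they must be the terminal frames of the recording.
#' @param baseline_frames Number of pre-stimulation frames averaged for `F0`
#'   (at least 1; all must precede `stim_start`).
#'
#' @return An object of class `stim_protocol`.
#' @seealso [protocol_standard()], [protocol_bafilomycin()]
#' @export
stim_protocol <- function(frame_times,
                          stim_start = 0,
                          stim_duration = 15,
                          stim_rate = 20,
                          nh4cl_frames = integer(),
                          baseline_frames = 6) {
  stopifnot(is.numeric(frame_times), length(frame_times) >= 1,
            all(is.finite(frame_times)))
  if (any(diff(frame_times) <= 0)) {
    stop("`frame_times` must be strictly increasing", call. = FALSE)
  }
  if (baseline_frames < 1) {
    stop("`baseline_frames` must be >= 1", call. = FALSE)
  }
  if (baseline_frames > length(frame_times) ||
      any(frame_times[seq_len(baseline_frames)] >= stim_start)) {
    stop("all baseline frames must precede `stim_start`", call. = FALSE)
  }
  nh4cl_frames <- as.integer(nh4cl_frames)
  n <- length(frame_times)
  if (length(nh4cl_frames)) {
    expected <- seq.int(n - length(nh4cl_frames) + 1L, n)
    if (!identical(sort(nh4cl_frames), expected)) {
      stop("`nh4cl_frames` must be the terminal frames", call. = FALSE)
    }
    nh4cl_frames <- expected
  }
  structure(
    list(
      frame_times = as.numeric(frame_times),
      stim_start = stim_start,
      stim_duration = stim_duration,
      stim_rate = stim_rate,
      nh4cl_frames = nh4cl_frames,
      baseline_frames = as.integer(baseline_frames)
    ),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  n <- length(x$frame_times)
  cat("<stim_protocol>\n")
  cat(sprintf("  %d frames, t = %.1f .. %.1f s\n", n,
              x$frame_times[1], x$frame_times[n]))
  cat(sprintf("  stimulation: %g s at %g Hz from t = %g s\n",
              x$stim_duration, x$stim_rate, x$stim_start))
  cat(sprintf("  baseline frames: %d; NH4Cl frames: %d\n",
              x$baseline_frames, length(x$nh4cl_frames)))
  invisible(x)
}

#' Standard vesicle-recycling protocol
#'
#' Fifty frames: 43 at 0.2 Hz (5-s spacing) followed by 7 at 0.125 Hz (8-s
#' spacing). Six baseline frames precede stimulation at t = 0; stimulation is
#' 300 action potentials delivered for 15 s at 20 Hz. The terminal 7 slow
#' frames are acquired under NH4Cl to read out `F_max`.
#'
#' @return A `stim_protocol`.
#' @export
protocol_standard <- function() {
  fast <- ((1:43) - 7) * 5          # frames 1..43; frame 7 at t = 0
  slow <- fast[43] + (1:7) * 8
  stim_protocol(
    frame_times = c(fast, slow),
    stim_start = 0, stim_duration = 15, stim_rate = 20,
    nh4cl_frames = 44:50, baseline_frames = 6
  )
}

#' Bafilomycin (cumulative exocytosis) protocol
#'
#' Frames at 0.2 Hz throughout; six baseline frames; stimulation at t = 0 for
#' 2 min at 20 Hz (2400 action potentials), driving cumulative exocytosis to
#' saturation while bafilomycin blocks reacidification. The final frames are
#' acquired under NH4Cl for `F_max`.
#'
#' @param n_frames Total number of frames (default 60).
#' @param n_nh4cl Number of terminal NH4Cl frames (default 6).
#' @return A `stim_protocol`.
#' @export
protocol_bafilomycin <- function(n_frames = 60, n_nh4cl = 6) {
  times <- (seq_len(n_frames) - 7) * 5
  stim_protocol(
    frame_times = times,
    stim_start = 0, stim_duration = 120, stim_rate = 20,
    nh4cl_frames = seq.int(n_frames - n_nh4cl + 1L, n_frames),
    baseline_frames = 6
  )
}

# frames (indices) that fall in the stimulation window [start, start+duration)
stim_window_frames <- function(protocol) {
  t <- protocol$frame_times
  which(t >= protocol$stim_start &
          t < protocol$stim_start + protocol$stim_duration)
}

# frames where the evoked response has developed: (start, start+duration] —
# the onset frame still sits at baseline and would dilute a response average
response_window_frames <- function(protocol) {
  t <- protocol$frame_times
  which(t > protocol$stim_start &
          t <= protocol$stim_start + protocol$stim_duration)
}

baseline_frame_idx <- function(protocol) seq_len(protocol$baseline_frames)

is_nh4cl_frame <- function(protocol) {
  seq_along(protocol$frame_times) %in% protocol$nh4cl_frames
}
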