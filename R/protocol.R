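#' Acquisition protocol timing models
#'
#' An acquisition protocol is the timing skeleton of a dynamic CT series:
#' frame start times, the per-frame integration window over which the scanner
#' averages the true contrast signal, and the number of leading mask frames
#' (unenhanced runs used for background subtraction).
#'
#' `mdctp_protocol()` models a conventional multidetector perfusion
#' acquisition: 30 contrast phases covering roughly 48 s, each volume acquired
#' in about 0.5 s, no mask runs. `fdctp_protocol()` models a C-arm flat-panel
#' acquisition: 10 rotational sweeps of 5 s each separated by a 1 s turnaround
#' (6 s pitch), the first two sweeps serving as mask runs.
#'
#' @param times numeric vector of frame start times (s), strictly increasing.
#' @param integration per-frame integration duration (s); scalar or vector.
#' @param n_mask number of leading mask frames.
#' @param label protocol label.
#' @return object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(times, integration, n_mask = 0L,
                                 label = "custom") {
  n <- length(times)
  integration <- rep_len(integration, n)
  if (n < 1) stopf("protocol needs at least one frame")
  if (any(diff(times) <= 0)) stopf("frame start times must be strictly increasing")
  if (any(integration <= 0)) stopf("integration durations must be positive")
  ends <- times + integration
  if (n > 1 && any(ends[-n] > times[-1] + 1e-9))
    stopf("frame integration windows overlap")
  if (n_mask < 0 || n_mask >= n) stopf("invalid mask-frame count")
  structure(list(times = as.numeric(times),
                 integration = as.numeric(integration),
                 n_mask = as.integer(n_mask), label = label),
            class = "acquisition_protocol")
}

#' @rdname acquisition_protocol
#' @param n_frames number of contrast phases (multidetector default 30).
#' @param pitch time between consecutive frame starts (s).
#' @param start acquisition start time (s) on the injection clock; a
#'   multidetector scan is triggered a few seconds before cerebral bolus
#'   arrival, whereas the flat-panel acquisition starts with the injection.
#' @export
mdctp_protocol <- function(n_frames = 30, pitch = 1.65, integration = 0.5,
                           start = 0) {
  acquisition_protocol(times = start + seq(0, by = pitch,
                                           length.out = n_frames),
                       integration = integration, n_mask = 0L,
                       label = "MDCTP-like")
}

#' @rdname acquisition_protocol
#' @param n_sweeps number of rotational sweeps (flat-panel default 10).
#' @param sweep_duration rotation time (s).
#' @param turnaround C-arm turnaround between sweeps (s).
#' @export
fdctp_protocol <- function(n_sweeps = 10, sweep_duration = 5, turnaround = 1,
                           n_mask = 2L) {
  pitch <- sweep_duration + turnaround
  acquisition_protocol(times = seq(0, by = pitch, length.out = n_sweeps),
                       integration = sweep_duration, n_mask = n_mask,
                       label = "FDCTP-like")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("%s protocol: %d frames, %d mask, span %.1f s, integration %.2g s\n",
              x$label, n, x$n_mask, x$times[n] + x$integration[n] - x$times[1],
              x$integration[1]))
  invisible(x)
}

# total acquisition span (first frame start to last frame end), seconds
protocol_span <- function(protocol) {
  n <- length(protocol$times)
  protocol$times[n] + protocol$integration[n] - protocol$times[1]
}

# frame-center times, the nominal time stamp of each frame
frame_centers <- function(times, integration) times + integration / 2
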