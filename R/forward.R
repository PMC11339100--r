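#' Indicator-dilution tissue enhancement curve
#'
#' Forward model of contrast passage through tissue:
#' \deqn{c(t) = \mathrm{CBF} \cdot (\mathrm{AIF} \circledast R)(t - \mathrm{delay}),
#'   \qquad R(t) = e^{-t/\mathrm{MTT}},}
#' evaluated by dt-scaled discrete convolution on a uniform time grid. The
#' central volume theorem holds on the grid:
#' `sum(c)*dt / sum(aif)*dt = CBF * MTT = CBV` up to quadrature error.
#'
#' @param cbf flow in 1/s (relative units; any flow unit works, the central
#'   volume identity is then expressed in that unit).
#' @param mtt mean transit time (s), > 0.
#' @param delay bolus delay (s), >= 0.
#' @param aif an [aif_model()] (evaluated analytically at `t - delay`) or a
#'   numeric concentration vector sampled on `t` (shifted by interpolation).
#' @param t uniform time grid (s).
#' @return non-negative concentration curve on `t`, causal in the delay.
#' @export
tissue_curve <- function(cbf, mtt, delay, aif, t) {
  if (mtt <= 0) stopf("mtt must be positive")
  if (delay < 0) stopf("delay must be non-negative")
  n <- length(t)
  if (n < 2) stopf("time grid too short")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8 * max(dt))
    stopf("time grid must be uniformly spaced (resample before calling)")
  dt <- dt[1]
  a <- if (inherits(aif, "aif_model")) {
    aif_concentration(aif, t - delay)
  } else {
    if (length(aif) != n) stopf("numeric aif must be sampled on t")
    if (delay == 0) as.numeric(aif)
    else approx(t, aif, xout = t - delay, rule = 1, yleft = 0)$y
  }
  a[is.na(a)] <- 0
  r <- exp(-(t - t[1]) / mtt)
  # causal discrete convolution, dt-scaled; the lag-0 residue sample gets
  # trapezoidal half weight so the quadrature of (AIF (*) R) is O(dt^2)
  # accurate and the central volume identity holds on fine grids
  r[1] <- r[1] / 2
  conv <- convolve(a, rev(r), type = "open")[seq_len(n)]
  pmax(cbf * dt * conv, 0)
}

#' 4D CT time series container
#'
#' @param data 4D array `[x, y, z, frame]` of HU values.
#' @param times frame start times (s), strictly increasing.
#' @param integration per-frame integration durations (s).
#' @param n_mask number of leading mask frames.
#' @param spacing voxel spacing (mm).
#' @param label free-text protocol label.
#' @return object of class `ct_series`.
#' @export
ct_series <- function(data, times, integration, n_mask = 0L,
                      spacing = c(1, 1, 1), label = "") {
  stopifnot(length(dim(data)) == 4)
  nt <- dim(data)[4]
  if (length(times) != nt) stopf("length(times) must match frame count")
  integration <- rep_len(integration, nt)
  if (nt > 1 && any(diff(times) <= 0)) stopf("times must be strictly increasing")
  structure(list(data = data, times = as.numeric(times),
                 integration = as.numeric(integration),
                 n_mask = as.integer(n_mask),
                 spacing = as.numeric(spacing), label = label),
            class = "ct_series")
}

#' @export
print.ct_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ct_series %s: %dx%dx%d voxels, %d frames (%d mask), %.1f-%.1f s\n",
              x$label, d[1], d[2], d[3], d[4], x$n_mask,
              x$times[1], x$times[d[4]] + x$integration[d[4]]))
  invisible(x)
}

#' Render a perfusion scene into a noisy 4D HU time series
#'
#' Simulates an acquisition: every frame holds the per-voxel baseline HU plus
#' the mean of the voxel's noiseless enhancement curve over the frame's
#' integration window (on a 0.1 s quadrature grid), plus i.i.d. Gaussian HU
#' noise. Mask frames carry baseline (and noise) only; air and skull voxels
#' carry their baseline HU (about -1000 / +1000) in every frame. Vessel-label
#' voxels carry the window-averaged measured arterial curve `aif`, while
#' tissue is perfused by the true arterial concentration
#' `aif / scene$vessel_partial_volume` (see [make_default_scene()]).
#'
#' Flow in the scene (ml/100g/min) is converted to 1/s by dividing by 6000.
#'
#' @param scene a [make_default_scene()] scene.
#' @param aif an [aif_model()].
#' @param protocol an [acquisition_protocol()].
#' @param noise_sd Gaussian noise standard deviation in HU (>= 0).
#' @param seed integer; renders are deterministic given the seed.
#' @param motion optional `n_frames x 3` matrix of per-frame rigid voxel
#'   translations injected before noise (default: no motion).
#' @return a [ct_series()].
#' @export
render <- function(scene, aif, protocol, noise_sd = 2, seed = 1,
                   motion = NULL) {
  stopifnot(inherits(scene, "perfusion_scene"),
            inherits(aif, "aif_model"),
            inherits(protocol, "acquisition_protocol"))
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  times <- protocol$times; dur <- protocol$integration
  nt <- length(times); n_mask <- protocol$n_mask
  dt <- 0.1
  tfine <- seq(0, max(times + dur) + dt, by = dt)

  # unique (cbf, mtt, delay) combinations over tissue voxels: the scene is
  # piecewise constant, so curves are computed once per region
  shape <- scene$shape
  labs <- scene$labels
  tis <- labs == 2L | labs == 3L
  key <- paste(scene$cbf[tis], scene$mtt[tis], scene$delay[tis], sep = "|")
  ukey <- unique(key)
  # tissue is perfused by the true arterial concentration; the vessel voxels
  # (and hence any detected AIF) record only the partial-volume fraction
  pv <- if (is.null(scene$vessel_partial_volume)) 1
        else scene$vessel_partial_volume
  aif_true <- aif
  aif_true$amplitude <- aif$amplitude / pv
  curves <- vapply(ukey, function(k) {
    p <- as.numeric(strsplit(k, "|", fixed = TRUE)[[1]])
    tissue_curve(p[1] / 6000, p[2], p[3], aif_true, tfine)
  }, numeric(length(tfine)))
  aif_fine <- aif_concentration(aif, tfine)

  # per-frame window averages of each unique curve and of the AIF
  win <- lapply(seq_len(nt), function(f)
    which(tfine >= times[f] - 1e-9 & tfine <= times[f] + dur[f] + 1e-9))
  frame_avg <- function(y) vapply(win, function(s) mean(y[s]), 0)
  curve_avg <- apply(curves, 2, frame_avg)           # nt x n_unique
  if (is.null(dim(curve_avg))) curve_avg <- matrix(curve_avg, nrow = nt)
  aif_avg <- frame_avg(aif_fine)

  base <- array(scene$baseline_hu[["air"]], dim = shape)
  base[labs == 1L] <- scene$baseline_hu[["skull"]]
  base[labs == 2L] <- scene$baseline_hu[["white"]]
  base[labs == 3L] <- scene$baseline_hu[["gray"]]
  base[labs == 4L] <- scene$baseline_hu[["vessel"]]

  kidx <- match(key, ukey)
  ves <- labs == 4L
  data <- array(0, dim = c(shape, nt))
  for (f in seq_len(nt)) {
    vol <- base
    if (f > n_mask) {
      vol[tis] <- vol[tis] + curve_avg[f, kidx]
      vol[ves] <- vol[ves] + aif_avg[f]
    }
    if (!is.null(motion) && any(motion[f, ] != 0))
      vol <- shift_volume(vol, motion[f, ])
    data[, , , f] <- vol
  }
  if (noise_sd > 0)
    data <- data + with_seed(seed,
      array(rnorm(length(data), sd = noise_sd), dim = dim(data)))
  ct_series(data, times, dur, n_mask, scene$spacing, protocol$label)
}
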