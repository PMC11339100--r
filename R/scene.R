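#' Digital perfusion phantom scene
#'
#' Builds a desk-scale brain-shaped perfusion scene: an ellipsoidal brain
#' (cortical gray-matter rim around a white-matter centre) inside a skull
#' shell surrounded by air, with one wedge-shaped hypoperfused lesion in the
#' right hemisphere and a small vessel cluster in the left (healthy)
#' hemisphere that carries the undiluted arterial input curve. Every voxel
#' carries ground-truth cerebral blood flow (CBF, ml/100g/min), mean transit
#' time (MTT, s) and bolus delay (s); the lesion adds `lesion_delay` seconds
#' of delay over the whole hypoperfused extent and scales CBF by
#' `lesion_cbf_fraction` there, with a stricter `core_cbf_fraction` inside a
#' deep white-matter core. The scene is mirror-symmetric in tissue labels
#' about the sagittal midline so that homologous contralateral voxels exist
#' for every lesion voxel.
#'
#' The `seed` jitters lesion geometry (wedge direction, angular width, radial
#' reach) so repeated calls emulate a cohort of middle-cerebral-artery-like
#' deficits of varying size (extent on the order of 60-150 ml).
#'
#' @param seed integer; the scene is deterministic given the seed.
#' @param lesion_delay added bolus delay inside the lesion (s), > 0.
#' @param lesion_cbf_fraction CBF multiplier in the hypoperfused extent,
#'   in (0, 1) and larger than `core_cbf_fraction`.
#' @param core_cbf_fraction CBF multiplier in the infarct core.
#' @param shape integer grid dimensions `c(nx, ny, nz)`.
#' @param spacing voxel spacing in mm `c(sx, sy, sz)`.
#' @param healthy_delay baseline bolus delay c(gray, white) on the healthy
#'   side (s).
#' @param healthy_gradient extra anterior-to-posterior arrival spread (s)
#'   added linearly across the brain; healthy tissue in vivo enhances over a
#'   2-3 s window, not simultaneously.
#' @param delay_taper fraction by which the added lesion delay falls off
#'   towards the lesion edge: the added delay is
#'   `lesion_delay * (1 - delay_taper * edge_frac)` with `edge_frac` 0 at the
#'   lesion centre and 1 at its rim. 0 (default) gives a homogeneous lesion
#'   whose whole extent is delayed by exactly `lesion_delay`; cohort
#'   simulations use 0.5-0.8 to emulate the centre-to-periphery severity
#'   gradient of real penumbrae.
#' @param vessel_partial_volume fraction of the true arterial concentration
#'   that a vessel-label voxel records (partial-volume effect of a 3-4 mm
#'   artery in coarse voxels). Tissue is perfused by the *true* arterial
#'   curve, i.e. the rendered AIF divided by this fraction, so measured
#'   tissue enhancement relative to the measured AIF matches clinical CT
#'   perfusion (gray-matter peak ~25 delta-HU against a ~200 delta-HU AIF).
#' @return object of class `perfusion_scene` with fields `labels`
#'   (0 air, 1 skull, 2 white, 3 gray, 4 vessel), `cbf`, `mtt`, `delay`
#'   (3D arrays), `extent`/`core`/`brain` logical masks, `midline` (last
#'   x-index of the left hemisphere), `baseline_hu`, and `truth` (true map
#'   summaries incl. lesion volumes in ml).
#' @export
make_default_scene <- function(seed = 1, lesion_delay = 8,
                               lesion_cbf_fraction = 0.4,
                               core_cbf_fraction = 0.15,
                               shape = c(64, 64, 24),
                               spacing = c(2, 2, 4),
                               healthy_delay = c(gray = 0.3, white = 0.7),
                               healthy_gradient = 1.5,
                               delay_taper = 0,
                               vessel_partial_volume = 0.3) {
  if (delay_taper < 0 || delay_taper >= 1)
    stopf("delay_taper must be in [0, 1)")
  if (vessel_partial_volume <= 0 || vessel_partial_volume > 1)
    stopf("vessel_partial_volume must be in (0, 1]")
  if (!(core_cbf_fraction > 0 && core_cbf_fraction < lesion_cbf_fraction &&
        lesion_cbf_fraction < 1))
    stopf("need 0 < core_cbf_fraction < lesion_cbf_fraction < 1")
  if (lesion_delay <= 0) stopf("lesion_delay must be > 0")
  shape <- as.integer(shape)
  if (any(shape < 16))
    stopf("invalid configuration: grid %s too small to contain skull, brain and lesion",
          paste(shape, collapse = "x"))

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  # brain semi-axes in voxels: leave a 4-voxel margin for the skull shell
  ax <- nx / 2 - 6; ay <- ny / 2 - 3; az <- nz / 2 - 2

  xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
  u <- array(rep((xs - cx) / ax, times = ny * nz), dim = shape)
  v <- array(rep(rep((ys - cy) / ay, each = nx), times = nz), dim = shape)
  w <- array(rep((zs - cz) / az, each = nx * ny), dim = shape)
  r2 <- u^2 + v^2 + w^2
  us <- u * ax / (ax + 2.5); vs <- v * ay / (ay + 2.5); ws <- w * az / (az + 2.5)
  r2_skull <- us^2 + vs^2 + ws^2

  labels <- array(0L, dim = shape)            # air
  labels[r2_skull <= 1] <- 1L                 # skull shell ...
  brain <- r2 <= 1
  labels[brain & r2 > 0.55] <- 3L             # gray rim
  labels[brain & r2 <= 0.55] <- 2L            # white centre

  # lesion wedge: seeded geometry in the right hemisphere (x > midline)
  geom <- with_seed(seed, list(
    phi0 = runif(1, -0.4, 0.4),
    halfwidth = runif(1, 0.55, 0.95),
    rmax = runif(1, 0.92, 1.0)))
  phi <- atan2(v, u)
  wedge_ang <- abs(phi - geom$phi0)
  extent <- brain & u > 0 & wedge_ang <= geom$halfwidth & r2 <= geom$rmax^2
  core <- extent & labels == 2L & r2 <= 0.45 & wedge_ang <= 0.6 * geom$halfwidth
  if (!any(extent) || !any(core))
    stopf("invalid configuration: grid too small for a non-empty lesion")

  # vessel cluster in the healthy hemisphere, deep inside the brain
  # 3x3x5-voxel tube so that its centre survives a radius-1 median filter,
  # like a real large artery does
  vyz <- expand.grid(x = round(cx - 0.35 * ax) + (-1:1),
                     y = round(cy) + (-1:1),
                     z = round(cz) + (-2:2))
  vi <- cbind(vyz$x, vyz$y, vyz$z)
  if (any(!(labels[vi] %in% c(2L, 3L))))
    stopf("invalid configuration: vessel cluster falls outside brain tissue")
  labels[vi] <- 4L

  # the core's mirrored contralateral voxels must be plain tissue (the
  # relative-CBF contract compares against the homologous healthy voxel)
  core_idx <- which(core, arr.ind = TRUE)
  mirror_lab <- labels[cbind(nx + 1L - core_idx[, 1], core_idx[, 2],
                             core_idx[, 3])]
  core[core_idx[mirror_lab == 4L, , drop = FALSE]] <- FALSE

  cbf <- array(0, dim = shape); mtt <- array(0, dim = shape)
  delay <- array(0, dim = shape)
  gm <- labels == 3L; wm <- labels == 2L
  cbf[gm] <- 60; cbf[wm] <- 25
  mtt[gm] <- 4;  mtt[wm] <- 5
  # smooth anterior-to-posterior arrival gradient: healthy tissue does not
  # enhance simultaneously (territory and drainage differences), which also
  # de-phases healthy curves relative to any sweep grid
  ap_ramp <- healthy_gradient * (v + 1) / 2
  delay[gm] <- healthy_delay[["gray"]] + ap_ramp[gm]
  delay[wm] <- healthy_delay[["white"]] + ap_ramp[wm]
  healthy_map <- delay

  tissue_lesion <- extent & (gm | wm)
  core_t <- core & (gm | wm)
  ext_only <- tissue_lesion & !core_t
  cbf[ext_only] <- cbf[ext_only] * lesion_cbf_fraction
  cbf[core_t] <- cbf[core_t] * core_cbf_fraction
  # transit time lengthens as flow drops; capped at 6 s so lesion curves
  # still decay within a ~48 s acquisition (full CBV preservation would give
  # transit times no protocol here could resolve, and the truncated tails
  # would masquerade as extra flow)
  mtt[ext_only] <- pmin(mtt[ext_only] / lesion_cbf_fraction, 6)
  mtt[core_t] <- pmin(mtt[core_t] / core_cbf_fraction, 6)
  # centre-to-rim severity gradient of the added delay
  edge_frac <- pmax(wedge_ang[tissue_lesion] / geom$halfwidth,
                    sqrt(r2[tissue_lesion]) / geom$rmax)
  edge_frac <- pmin(pmax(edge_frac, 0), 1)
  delay[tissue_lesion] <- delay[tissue_lesion] +
    lesion_delay * (1 - delay_taper * edge_frac)

  voxel_ml <- prod(spacing) / 1000
  baseline_hu <- c(air = -1000, skull = 1000, white = 30, gray = 35,
                   vessel = 50)
  structure(list(
    shape = shape, spacing = as.numeric(spacing),
    labels = labels, cbf = cbf, mtt = mtt, delay = delay,
    extent = tissue_lesion, core = core_t, brain = gm | wm,
    healthy_tmax = healthy_map,
    midline = as.integer(floor(nx / 2)),
    baseline_hu = baseline_hu,
    vessel_partial_volume = vessel_partial_volume,
    lesion = list(delay = lesion_delay, cbf_fraction = lesion_cbf_fraction,
                  core_fraction = core_cbf_fraction, taper = delay_taper,
                  geometry = geom),
    truth = list(
      tmax = delay,                      # exponential residue peaks at onset
      extent_ml = sum(tissue_lesion) * voxel_ml,
      core_ml = sum(core_t) * voxel_ml,
      voxel_ml = voxel_ml),
    seed = seed), class = "perfusion_scene")
}

#' @export
print.perfusion_scene <- function(x, ...) {
  cat(sprintf(
    paste0("perfusion scene %dx%dx%d @ %gx%gx%g mm: extent %.1f ml, ",
           "core %.1f ml, lesion delay %g s\n"),
    x$shape[1], x$shape[2], x$shape[3], x$spacing[1], x$spacing[2],
    x$spacing[3], x$truth$extent_ml, x$truth$core_ml, x$lesion$delay))
  invisible(x)
}

#' Default contralateral reference regions of interest
#'
#' Places three reference ROI centres in the deep white matter of the healthy
#' (left) hemisphere, in the anterior, middle and posterior thirds of the
#' centrum-semiovale-like region, for relative-CBF normalization.
#'
#' @param scene a [make_default_scene()] scene.
#' @return 3x3 integer matrix of voxel coordinates (one ROI centre per row).
#' @export
default_reference_rois <- function(scene) {
  nx <- scene$shape[1]; ny <- scene$shape[2]; nz <- scene$shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  # deep white matter, clearly medial to the vessel tube at ~0.35 ax
  x0 <- round(cx - 0.18 * (nx / 2 - 6))
  dy <- round(0.28 * (ny / 2 - 3))
  centers <- rbind(c(x0, round(cy) - dy, round(nz / 2)),
                   c(x0, round(cy),      round(nz / 2)),
                   c(x0, round(cy) + dy, round(nz / 2)))
  for (i in seq_len(3))
    if (scene$labels[centers[i, 1], centers[i, 2], centers[i, 3]] != 2L)
      stopf("reference ROI %d does not fall in white matter", i)
  centers
}
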