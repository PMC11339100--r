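# Hypoperfusion / infarct-core volumetry: visible-extent masks, absolute and
# relative thresholds, reference-ROI relative CBF, hemispheric median
# normalization, and volume / mismatch computation in ml.

#' Segmentation configuration
#'
#' Thresholds and reference-ROI layout for the volumetry stage. Defaults
#' follow the established stroke-imaging conventions: hypoperfusion at
#' Tmax > 6 s, infarct core at rCBF < 30% (with the more permissive < 45%
#' variant for flat-panel maps), and normalized-map cuts at Tmax above 150%
#' and CBF below 30% of the healthy-hemisphere median. The reference regions
#' are three 7 mm spheres (3.5 mm radius) in the contralateral deep white
#' matter.
#'
#' @param tmax_abs_threshold absolute Tmax cut (s).
#' @param rcbf_thresholds relative-CBF core cuts (fractions of the reference).
#' @param norm_tmax_threshold normalized-Tmax cut (percent of healthy median).
#' @param norm_cbf_threshold normalized-CBF cut (percent of healthy median).
#' @param roi_radius_mm reference-ROI radius (mm); 7 mm "size" read as
#'   diameter.
#' @param roi_centers 3 x 3 matrix of reference-ROI voxel coordinates
#'   (one per row), or NULL to derive from a phantom scene at run time.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(tmax_abs_threshold = 6,
                                rcbf_thresholds = c(0.30, 0.45),
                                norm_tmax_threshold = 150,
                                norm_cbf_threshold = 30,
                                roi_radius_mm = 3.5,
                                roi_centers = NULL) {
  stopifnot(tmax_abs_threshold > 0, all(rcbf_thresholds > 0),
            norm_tmax_threshold > 0, norm_cbf_threshold > 0,
            roi_radius_mm > 0)
  if (!is.null(roi_centers)) {
    roi_centers <- as.matrix(roi_centers)
    if (nrow(roi_centers) != 3 || ncol(roi_centers) != 3)
      stopf("exactly three reference ROIs (rows) with 3 coordinates each")
  }
  structure(list(tmax_abs_threshold = tmax_abs_threshold,
                 rcbf_thresholds = rcbf_thresholds,
                 norm_tmax_threshold = norm_tmax_threshold,
                 norm_cbf_threshold = norm_cbf_threshold,
                 roi_radius_mm = roi_radius_mm,
                 roi_centers = roi_centers),
            class = "segmentation_config")
}

# separable box sum along all three axes (zero-padded at the borders)
box_sum3d <- function(arr, r) {
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    for (s in -r:r) {
      lo <- max(1, 1 + s); hi <- min(d[ax], d[ax] + s)
      lo0 <- max(1, 1 - s); hi0 <- min(d[ax], d[ax] - s)
      if (ax == 1) out[lo:hi, , ] <- out[lo:hi, , ] + arr[lo0:hi0, , ]
      else if (ax == 2) out[, lo:hi, ] <- out[, lo:hi, ] + arr[, lo0:hi0, ]
      else out[, , lo:hi] <- out[, , lo:hi] + arr[, , lo0:hi0]
    }
    arr <- out
  }
  arr
}

# mask-weighted local mean: values outside the mask neither contribute nor
# dilute; radius in voxels
masked_box_mean <- function(vol, mask, r = 2) {
  num <- box_sum3d(vol * mask, r)
  den <- box_sum3d(mask * 1, r)
  out <- num / pmax(den, 1)
  out[den == 0] <- 0
  out
}

# label 6-connected components of a logical 3D mask; returns integer array
label_components <- function(mask) {
  d <- dim(mask)
  nxy <- d[1] * d[2]
  lab <- array(0L, dim = d)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  current <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    frontier <- seed
    lab[seed] <- current
    while (length(frontier) > 0) {
      co <- arrayInd(frontier, d)
      nb <- c(frontier[co[, 1] > 1] - 1L, frontier[co[, 1] < d[1]] + 1L,
              frontier[co[, 2] > 1] - d[1], frontier[co[, 2] < d[2]] + d[1],
              frontier[co[, 3] > 1] - nxy, frontier[co[, 3] < d[3]] + nxy)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- current
      frontier <- nb
    }
  }
  lab
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# one-iteration 6-neighbourhood erosion of a logical mask
erode_mask <- function(mask) {
  d <- dim(mask)
  sh <- function(dx, dy, dz) {
    out <- array(FALSE, d)
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- mask[max(1, 1 - dx):min(d[1], d[1] - dx),
                            max(1, 1 - dy):min(d[2], d[2] - dy),
                            max(1, 1 - dz):min(d[3], d[3] - dz)]
    out
  }
  mask & sh(1, 0, 0) & sh(-1, 0, 0) & sh(0, 1, 0) & sh(0, -1, 0) &
    sh(0, 0, 1) & sh(0, 0, -1)
}

# hemisphere masks from the midline x-index (left: x <= midline)
hemisphere_masks <- function(shape, midline) {
  xidx <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]),
                dim = shape)
  list(left = xidx <= midline, right = xidx > midline)
}

#' Maximum visible extent of hypoperfused tissue
#'
#' Programmatic stand-in for the manual slice-by-slice delineation of the
#' hypoperfusion a reader "sees" on a Tmax map. In `"ground-truth"` mode the
#' phantom's true extent mask is returned (for recovery tests); in
#' `"heuristic"` mode the Tmax map is first pooled over a local
#' neighbourhood (a reader judges coherent colour regions, not single
#' voxels), then thresholded at the healthy-hemisphere median + 1 s, with
#' candidates restricted to the affected hemisphere (a reader delineates the
#' stroke side) and reduced to the largest 6-connected component.
#'
#' @param maps a `perfusion_maps` object.
#' @param mode `"ground-truth"` or `"heuristic"`.
#' @param scene the generating [make_default_scene()] (required for
#'   ground-truth mode; supplies the midline for the heuristic too).
#' @param midline last x-index of the left hemisphere (defaults to the
#'   scene's, else nx/2).
#' @param pool_radius neighbourhood radius (voxels) of the reader's spatial
#'   pooling.
#' @param margin visibility margin (s) above the healthy-hemisphere median.
#' @return logical 3D mask.
#' @export
visible_extent <- function(maps, mode = c("heuristic", "ground-truth"),
                           scene = NULL, midline = NULL, pool_radius = 2,
                           margin = 1) {
  mode <- match.arg(mode)
  if (mode == "ground-truth") {
    if (is.null(scene)) stopf("ground-truth mode requires the phantom scene")
    return(scene$extent)
  }
  d <- dim(maps$tmax)
  if (is.null(midline)) midline <- if (!is.null(scene)) scene$midline
                        else as.integer(floor(d[1] / 2))
  hemi <- hemisphere_masks(d, midline)
  mt_left <- mean(maps$tmax[maps$tissue & hemi$left])
  mt_right <- mean(maps$tmax[maps$tissue & hemi$right])
  healthy <- if (mt_left <= mt_right) hemi$left else hemi$right
  affected <- if (mt_left <= mt_right) hemi$right else hemi$left
  pooled <- masked_box_mean(maps$tmax, maps$tissue, r = pool_radius)
  cut <- median(pooled[maps$tissue & healthy]) + margin
  cand <- maps$tissue & pooled > cut & affected
  if (!any(cand)) return(cand)
  # pooling dilates a sharp lesion boundary by about one voxel; erode once
  # to put the delineation back on the edge a reader would trace
  erode_mask(largest_component(cand))
}

#' Threshold a map within a restriction mask
#'
#' @param map 3D numeric array.
#' @param op `"greater"` or `"less"`.
#' @param cutoff threshold value.
#' @param restrict logical 3D mask; the result is always a subset of it.
#' @return logical 3D mask.
#' @export
threshold_within <- function(map, op = c("greater", "less"), cutoff,
                             restrict) {
  op <- match.arg(op)
  if (!identical(dim(map), dim(restrict)))
    stopf("map and restriction mask have different shapes")
  sel <- if (op == "greater") map > cutoff else map < cutoff
  sel & restrict
}

#' Relative CBF map from contralateral reference regions
#'
#' Divides the CBF map by the mean CBF over three spherical reference ROIs
#' placed in the healthy-hemisphere deep white matter (the
#' centrum-semiovale-like reference of standard core estimation).
#'
#' @param maps a `perfusion_maps` object.
#' @param cfg a [segmentation_config()] whose `roi_centers` are set.
#' @return 3D array of CBF as a fraction of the reference value; the
#'   reference value is attached as `attr(, "reference")`.
#' @export
rcbf_reference <- function(maps, cfg) {
  stopifnot(inherits(cfg, "segmentation_config"))
  if (is.null(cfg$roi_centers)) stopf("cfg$roi_centers must be supplied")
  d <- dim(maps$cbf)
  roi_means <- numeric(3)
  for (i in 1:3) {
    ctr <- cfg$roi_centers[i, ]
    rx <- ceiling(cfg$roi_radius_mm / maps$spacing)
    xs <- max(1, ctr[1] - rx[1]):min(d[1], ctr[1] + rx[1])
    ys <- max(1, ctr[2] - rx[2]):min(d[2], ctr[2] + rx[2])
    zs <- max(1, ctr[3] - rx[3]):min(d[3], ctr[3] + rx[3])
    g <- expand.grid(x = xs, y = ys, z = zs)
    dist2 <- ((g$x - ctr[1]) * maps$spacing[1])^2 +
      ((g$y - ctr[2]) * maps$spacing[2])^2 +
      ((g$z - ctr[3]) * maps$spacing[3])^2
    sphere <- as.matrix(g[dist2 <= cfg$roi_radius_mm^2, , drop = FALSE])
    in_tissue <- maps$tissue[sphere]
    if (!any(in_tissue))
      stopf("reference ROI %d at (%d,%d,%d) lies outside the tissue mask",
            i, ctr[1], ctr[2], ctr[3])
    roi_means[i] <- mean(maps$cbf[sphere[in_tissue, , drop = FALSE]])
  }
  ref <- mean(roi_means)
  if (ref <= 0) stopf("degenerate reference CBF (<= 0)")
  out <- maps$cbf / ref
  attr(out, "reference") <- ref
  attr(out, "roi_means") <- roi_means
  out
}

#' Hemispheric median normalization of a perfusion map
#'
#' Identifies the healthy hemisphere (lower mean Tmax; higher mean CBF as the
#' secondary criterion, with Tmax deciding on conflict), takes the median of
#' the map over healthy-hemisphere tissue as the normalization factor, and
#' returns the map expressed in percent of that factor, so that the healthy
#' hemisphere's median normalizes to 100.
#'
#' @param map 3D numeric array to normalize (a Tmax or CBF map).
#' @param tissue logical 3D brain-tissue mask (nonempty in both hemispheres).
#' @param kind `"tmax"` or `"cbf"` (which map is being normalized).
#' @param tmax,cbf the Tmax and CBF maps used to pick the healthy hemisphere
#'   (default: `map` itself for its own kind).
#' @param midline last x-index of the left hemisphere.
#' @param min_factor lower bound for the normalization factor. Tmax maps can
#'   have healthy-side medians at or near 0 (no resolvable delay); flooring
#'   the factor at the map's sampling quantum (1 s in the canonical chain)
#'   keeps the percent scale meaningful. 0 (default) disables the floor, and
#'   a zero factor is then an error.
#' @return object of class `normalization_result`: fields `healthy`
#'   (`"left"`/`"right"`), `factor` (map units), `normalized` (percent map).
#' @export
normalize_hemispheric <- function(map, tissue, kind = c("tmax", "cbf"),
                                  tmax = NULL, cbf = NULL,
                                  midline = floor(dim(map)[1] / 2),
                                  min_factor = 0) {
  kind <- match.arg(kind)
  if (kind == "tmax" && is.null(tmax)) tmax <- map
  if (kind == "cbf" && is.null(cbf)) cbf <- map
  d <- dim(map)
  hemi <- hemisphere_masks(d, midline)
  if (!any(tissue & hemi$left) || !any(tissue & hemi$right))
    stopf("tissue mask must be nonempty in both hemispheres")
  vote <- function(m, lower_is_healthy) {
    if (is.null(m)) return(0L)
    ml <- mean(m[tissue & hemi$left]); mr <- mean(m[tissue & hemi$right])
    s <- if (ml < mr) 1L else if (ml > mr) -1L else 0L
    if (lower_is_healthy) s else -s
  }
  v_tmax <- vote(tmax, lower_is_healthy = TRUE)
  v_cbf <- vote(cbf, lower_is_healthy = FALSE)
  # Tmax criterion decides on conflict or when only one map is available
  side <- if (v_tmax != 0) v_tmax else v_cbf
  healthy <- if (side >= 0) "left" else "right"
  hmask <- tissue & hemi[[healthy]]
  factor <- max(median(map[hmask]), min_factor)
  if (factor == 0) stopf("degenerate map: healthy-hemisphere median is 0")
  structure(list(healthy = healthy, factor = factor,
                 normalized = map / factor * 100, midline = midline),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("normalization: healthy hemisphere %s, factor %.4g (map units)\n",
              x$healthy, x$factor))
  invisible(x)
}

#' Volumes and mismatch volumes from named masks
#'
#' Volume(ml) = voxel count x voxel volume / 1000. Mismatches are
#' minuend - subtrahend volume pairs, floored at 0.
#'
#' @param masks named list of logical 3D masks on one grid.
#' @param spacing voxel spacing (mm).
#' @param mismatches optional named list of `c(minuend, subtrahend)` mask-name
#'   pairs.
#' @return object of class `volume_report`: data frame `volumes`
#'   (name, voxels, ml) and data frame `mismatches` (name, ml).
#' @export
compute_volumes <- function(masks, spacing, mismatches = NULL) {
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d)) stopf("masks do not share one grid")
  if (length(spacing) != 3 || any(spacing <= 0))
    stopf("inconsistent voxel spacing")
  voxel_ml <- prod(spacing) / 1000
  counts <- vapply(masks, sum, 0)
  vols <- data.frame(name = names(masks), voxels = as.integer(counts),
                     ml = counts * voxel_ml, row.names = NULL)
  mm <- NULL
  if (!is.null(mismatches)) {
    mm <- data.frame(
      name = names(mismatches),
      ml = vapply(mismatches, function(p)
        max(vols$ml[vols$name == p[1]] - vols$ml[vols$name == p[2]], 0), 0),
      row.names = NULL)
  }
  structure(list(volumes = vols, mismatches = mm, voxel_ml = voxel_ml),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat("volumes (ml):\n")
  print(x$volumes, row.names = FALSE)
  if (!is.null(x$mismatches)) {
    cat("mismatch volumes (ml):\n")
    print(x$mismatches, row.names = FALSE)
  }
  invisible(x)
}

#' Full volumetry of one set of perfusion maps
#'
#' Reproduces the standard segmentation battery on one subject's maps:
#' visible extent (heuristic reader stand-in, or ground truth when a scene is
#' given and `visible_mode = "ground-truth"`), absolute Tmax cut, rCBF core
#' cuts inside the visible extent, normalized-Tmax and normalized-CBF cuts
#' inside the visible extent, and the four extent/core mismatch combinations.
#'
#' @param maps a `perfusion_maps` object.
#' @param cfg a [segmentation_config()]; `roi_centers` default to
#'   [default_reference_rois()] of `scene` when missing.
#' @param scene optional generating scene (ground truth, midline, ROIs).
#' @param visible_mode passed to [visible_extent()].
#' @return a [compute_volumes()] report; masks in `attr(, "masks")`,
#'   normalization details in `attr(, "normalization")`.
#' @export
segment_hypoperfusion <- function(maps, cfg = segmentation_config(),
                                  scene = NULL,
                                  visible_mode = c("heuristic", "ground-truth")) {
  visible_mode <- match.arg(visible_mode)
  if (is.null(cfg$roi_centers)) {
    if (is.null(scene)) stopf("reference ROI centers needed (cfg or scene)")
    cfg$roi_centers <- default_reference_rois(scene)
  }
  midline <- if (!is.null(scene)) scene$midline else floor(dim(maps$tmax)[1] / 2)
  vis <- visible_extent(maps, visible_mode, scene = scene, midline = midline)
  tmax6 <- threshold_within(maps$tmax, "greater", cfg$tmax_abs_threshold, vis)
  rcbf <- rcbf_reference(maps, cfg)
  core30 <- threshold_within(rcbf, "less", cfg$rcbf_thresholds[1], vis)
  core45 <- threshold_within(rcbf, "less", cfg$rcbf_thresholds[2], vis)
  ntm <- normalize_hemispheric(maps$tmax, maps$tissue, "tmax",
                               cbf = maps$cbf, midline = midline,
                               min_factor = 1)
  ncb <- normalize_hemispheric(maps$cbf, maps$tissue, "cbf",
                               tmax = maps$tmax, midline = midline)
  norm_tmax <- threshold_within(ntm$normalized, "greater",
                                cfg$norm_tmax_threshold, vis)
  norm_cbf <- threshold_within(ncb$normalized, "less",
                               cfg$norm_cbf_threshold, vis)
  masks <- list(visible = vis, tmax_gt6 = tmax6, core_rcbf30 = core30,
                core_rcbf45 = core45, norm_tmax150 = norm_tmax,
                norm_cbf30 = norm_cbf)
  rep <- compute_volumes(masks, maps$spacing, mismatches = list(
    mismatch_visible_rcbf30 = c("visible", "core_rcbf30"),
    mismatch_visible_rcbf45 = c("visible", "core_rcbf45"),
    mismatch_tmax6_rcbf30 = c("tmax_gt6", "core_rcbf30"),
    mismatch_tmax6_rcbf45 = c("tmax_gt6", "core_rcbf45")))
  attr(rep, "masks") <- masks
  attr(rep, "normalization") <- list(tmax = ntm, cbf = ncb)
  attr(rep, "rcbf_reference") <- attr(rcbf, "reference")
  rep
}
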