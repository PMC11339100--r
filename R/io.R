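# NIfTI + JSON-sidecar interchange for 4D series, maps and masks.

#' Write a 4D series as per-frame NIfTI files with a JSON sidecar
#'
#' Each frame becomes `frame_###.nii.gz`; `series.json` records frame start
#' times, integration durations, mask-frame count, spacing and label.
#'
#' @param series a [ct_series()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_nifti_series <- function(series, dir) {
  stopifnot(inherits(series, "ct_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- dim(series$data)[4]
  files <- sprintf("frame_%03d.nii.gz", seq_len(nt) - 1)
  for (f in seq_len(nt)) {
    img <- RNifti::asNifti(series$data[, , , f])
    RNifti::pixdim(img) <- series$spacing
    RNifti::writeNifti(img, file.path(dir, files[f]))
  }
  sidecar <- list(frame_times = series$times,
                  integration = series$integration,
                  n_mask = series$n_mask,
                  spacing = series$spacing,
                  label = series$label,
                  files = files)
  jsonlite::write_json(sidecar, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a 4D series written by [write_nifti_series()]
#'
#' @param dir directory holding `series.json` and the per-frame NIfTI files.
#' @return a [ct_series()]; spacing is taken from the NIfTI headers (mm).
#' @export
read_nifti_series <- function(dir) {
  sidecar_path <- file.path(dir, "series.json")
  if (!file.exists(sidecar_path))
    stopf("missing sidecar %s", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  needed <- c("frame_times", "integration", "n_mask", "files")
  miss <- setdiff(needed, names(sc))
  if (length(miss) > 0)
    stopf("sidecar %s lacks fields: %s", sidecar_path,
          paste(miss, collapse = ", "))
  frames <- lapply(sc$files, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stopf("missing frame file %s", path)
    RNifti::readNifti(path)
  })
  d0 <- dim(frames[[1]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), d0))
      stopf("frame %s has shape %s, expected %s", sc$files[i],
            paste(dim(frames[[i]]), collapse = "x"),
            paste(d0, collapse = "x"))
  spacing <- RNifti::pixdim(frames[[1]])[1:3]
  data <- array(0, dim = c(d0, length(frames)))
  for (i in seq_along(frames)) data[, , , i] <- frames[[i]]
  ct_series(data, sc$frame_times, sc$integration, as.integer(sc$n_mask),
            spacing = as.numeric(spacing),
            label = if (!is.null(sc$label)) sc$label else "")
}

#' Write perfusion maps (and the tissue mask) as NIfTI volumes
#'
#' @param maps a `perfusion_maps` object.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_perfusion_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "perfusion_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("tmax", "ttp", "cbf", "cbv", "mtt")) {
    img <- RNifti::asNifti(maps[[nm]])
    RNifti::pixdim(img) <- maps$spacing
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  msk <- RNifti::asNifti(array(as.integer(maps$tissue),
                               dim = dim(maps$tissue)))
  RNifti::pixdim(msk) <- maps$spacing
  RNifti::writeNifti(msk, file.path(dir, "tissue_mask.nii.gz"),
                     datatype = "uint8")
  invisible(dir)
}

#' Resample a 3D map or mask to a new slice thickness
#'
#' Trilinear (maps) or nearest-neighbour (masks) resampling onto a grid with
#' the requested spacing, matching the physical extent of the input. Used to
#' emulate reformatting maps to a different slice thickness before
#' volumetry.
#'
#' @param vol 3D array.
#' @param spacing current voxel spacing (mm).
#' @param new_spacing target voxel spacing (mm).
#' @param mask logical; treat `vol` as a binary mask.
#' @return list with `data` and `spacing`.
#' @export
resample_volume <- function(vol, spacing, new_spacing, mask = FALSE) {
  d <- dim(vol)
  extent <- d * spacing
  nd <- pmax(1, round(extent / new_spacing))
  # voxel-centre world coordinates: (i - 0.5) * spacing
  src_of <- function(i, ax) ((i - 0.5) * new_spacing[ax]) / spacing[ax] + 0.5
  g <- as.matrix(expand.grid(x = src_of(seq_len(nd[1]), 1),
                             y = src_of(seq_len(nd[2]), 2),
                             z = src_of(seq_len(nd[3]), 3)))
  if (mask) {
    g <- round(pmin(pmax(g, 1), matrix(d, nrow(g), 3, byrow = TRUE)))
    vals <- (vol * 1)[g] > 0.5
  } else {
    gc <- pmin(pmax(g, 1), matrix(d, nrow(g), 3, byrow = TRUE))
    vals <- trilinear_sample(vol * 1, gc, fill = 0)
  }
  list(data = array(vals, dim = nd), spacing = new_spacing)
}
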