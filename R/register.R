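# Rigid 3D-3D registration of dynamic frames to the first frame.
#
# Intensity-based: mean-squared-difference cost, coarse integer-translation
# search followed by Nelder-Mead refinement of the 6 rigid parameters
# (3 voxel translations + 3 rotations about the grid centre), trilinear
# resampling. Scaled for phantom work, not clinical anatomy.

# sample vol (3D array) at fractional voxel coordinates (n x 3, 1-based);
# outside the grid returns `fill`
trilinear_sample <- function(vol, coords, fill = NA_real_) {
  d <- dim(vol)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  inside <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(fill, nrow(coords))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) i + d[1] * (j - 1 + d[2] * (k - 1))
  v <- vol[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    vol[idx(x0 + 1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
    vol[idx(x0, y0 + 1, z0)] * (1 - fx) * fy * (1 - fz) +
    vol[idx(x0 + 1, y0 + 1, z0)] * fx * fy * (1 - fz) +
    vol[idx(x0, y0, z0 + 1)] * (1 - fx) * (1 - fy) * fz +
    vol[idx(x0 + 1, y0, z0 + 1)] * fx * (1 - fy) * fz +
    vol[idx(x0, y0 + 1, z0 + 1)] * (1 - fx) * fy * fz +
    vol[idx(x0 + 1, y0 + 1, z0 + 1)] * fx * fy * fz
  out[inside] <- v
  out
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# apply the rigid transform p -> R (p - c) + c + shift to a volume
# (resampled at the inverse-mapped coordinates)
rigid_transform_volume <- function(vol, shift, angles = c(0, 0, 0),
                                   fill = NA_real_) {
  d <- dim(vol)
  ctr <- (d + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                             z = seq_len(d[3])))
  rot <- rotation_matrix(angles)
  src <- sweep(g, 2, ctr + shift) %*% rot +     # R^{-1} = t(R), applied as x R
    matrix(ctr, nrow(g), 3, byrow = TRUE)
  array(trilinear_sample(vol, src, fill = fill), dim = d)
}

#' Translate a volume by a (possibly fractional) voxel shift
#'
#' @param vol 3D array.
#' @param shift length-3 voxel translation.
#' @param fill value used outside the grid (default: the corner voxel,
#'   i.e. background).
#' @return shifted array of the same dimension.
#' @export
shift_volume <- function(vol, shift, fill = vol[1, 1, 1]) {
  rigid_transform_volume(vol, shift = shift, fill = fill)
}

# MSD cost between fixed and a rigidly transformed moving frame, evaluated
# on a subsampled set of non-air voxels of the fixed frame
register_cost_factory <- function(fixed, moving, subsample = 2) {
  d <- dim(fixed)
  ctr <- (d + 1) / 2
  g <- as.matrix(expand.grid(x = seq(1, d[1], by = subsample),
                             y = seq(1, d[2], by = subsample),
                             z = seq_len(d[3])))
  fvals <- fixed[g]
  keep <- fvals > -500          # ignore air, register on head content
  g <- g[keep, , drop = FALSE]; fvals <- fvals[keep]
  function(par) {
    rot <- rotation_matrix(par[4:6])
    src <- sweep(g, 2, ctr + par[1:3]) %*% rot +
      matrix(ctr, nrow(g), 3, byrow = TRUE)
    mv <- trilinear_sample(moving, src)
    ok <- !is.na(mv)
    if (sum(ok) < 50) return(1e12)
    mean((mv[ok] - fvals[ok])^2)
  }
}

# estimate the rigid transform aligning `moving` onto `fixed`
estimate_rigid <- function(fixed, moving, subsample = 2, max_shift = 3L) {
  cost <- register_cost_factory(fixed, moving, subsample)
  # multi-start: coarse integer-translation grid
  grid <- as.matrix(expand.grid(x = -max_shift:max_shift,
                                y = -max_shift:max_shift,
                                z = -1:1))
  cvals <- apply(grid, 1, function(s) cost(c(s, 0, 0, 0)))
  start <- c(grid[which.min(cvals), ], 0, 0, 0)
  fit <- tryCatch(
    optim(start, cost, method = "Nelder-Mead",
          control = list(maxit = 400, reltol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  fit$par
}

#' Rigidly register every frame of a series to the first frame
#'
#' 6-degree-of-freedom (translation + rotation) intensity-based registration
#' with a mean-squared-difference cost; frames whose estimated transform is
#' negligible are passed through untouched, and frames where the optimizer
#' fails are passed through with a warning.
#'
#' @param series a [ct_series()] with at least 2 frames.
#' @param subsample voxel decimation factor for the cost evaluation.
#' @return the registered [ct_series()]; estimated per-frame parameters
#'   (shift x/y/z in voxels, rotations in radians) in `attr(, "transforms")`.
#' @export
register_frames <- function(series, subsample = 2) {
  stopifnot(inherits(series, "ct_series"))
  nt <- dim(series$data)[4]
  if (nt < 2) stopf("registration needs at least 2 frames")
  fixed <- series$data[, , , 1]
  out <- series
  transforms <- matrix(0, nt, 6)
  for (f in 2:nt) {
    moving <- series$data[, , , f]
    par <- estimate_rigid(fixed, moving, subsample)
    if (is.null(par)) {
      warnf("registration failed for frame %d; passing frame through", f)
      next
    }
    transforms[f, ] <- par
    if (max(abs(par[1:3])) < 0.05 && max(abs(par[4:6])) < 1e-3) next
    reg <- rigid_transform_volume(moving, shift = par[1:3],
                                  angles = par[4:6], fill = NA_real_)
    reg[is.na(reg)] <- fixed[is.na(reg)]   # re-entering margin: borrow frame 0
    out$data[, , , f] <- reg
  }
  attr(out, "transforms") <- transforms
  out
}
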