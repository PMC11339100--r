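# Perfusion postprocessing chain: subtraction, filtering, resampling, tissue
# masking, AIF detection and truncated-SVD deconvolution.

make_conc <- function(curves, t, spacing = c(2, 2, 4)) {
  arr <- array(0, dim = c(length(curves), 1, 1, length(t)))
  for (i in seq_along(curves)) arr[i, 1, 1, ] <- curves[[i]]
  structure(list(data = arr, t = t, spacing = spacing, label = "synthetic"),
            class = "concentration_series")
}

make_aif_curve <- function(conc_values, t) {
  structure(list(conc = conc_values, t = t, voxels = matrix(1, 1, 3)),
            class = "aif_curve")
}

test_that("mask subtraction removes the two-frame template exactly", {
  ser <- ramp_series(n_mask = 2)
  sub <- subtract_mask(ser)
  nt <- dim(ser$data)[4]
  template <- (ser$data[, , , 1] + ser$data[, , , 2]) / 2
  for (k in seq_len(nt - 2))
    expect_equal_array(sub$data[, , , k], ser$data[, , , k + 2] - template)
  expect_equal(sub$n_mask, 0L)
  expect_equal(sub$times, ser$times[3:nt])
  expect_error(subtract_mask(ct_series(ser$data[, , , 1:2, drop = FALSE],
                                       0:1, 0.5, n_mask = 2L)), "mask")
})

test_that("constant-in-time series subtracts to all zeros", {
  d <- c(5, 4, 3, 6)
  data <- array(rep(rnorm(prod(d[1:3])), d[4]), dim = d)
  ser <- ct_series(data, times = seq(0, 30, length.out = 6), 5, n_mask = 2L)
  sub <- subtract_mask(ser)
  expect_equal(max(abs(sub$data)), 0)
})

test_that("noise-free vessel voxels subtract to the rendered AIF averages", {
  sc <- small_scene(seed = 1)
  aif <- aif_model(t0 = 15)
  prot <- fdctp_protocol()
  ser <- render(sc, aif, prot, noise_sd = 0, seed = 1)
  sub <- subtract_mask(ser)
  ves <- which(sc$labels == 4L, arr.ind = TRUE)[1, ]
  tfine <- seq(0, 61, by = 0.1)
  af <- aif_concentration(aif, tfine)
  for (k in c(1, 4, 8)) {
    f <- k + 2
    sel <- tfine >= prot$times[f] - 1e-9 &
      tfine <= prot$times[f] + prot$integration[f] + 1e-9
    expect_equal(sub$data[ves[1], ves[2], ves[3], k], mean(af[sel]),
                 tolerance = 1e-9)
  }
})

test_that("pre-bolus baseline is found automatically without mask frames", {
  sc <- small_scene(seed = 1)
  ser <- render(sc, aif_model(t0 = 15), mdctp_protocol(), noise_sd = 0,
                seed = 1)
  sub <- subtract_mask(ser)
  frames <- attr(sub, "baseline_frames")
  # bolus arrives at 15 s (frame 10 of the 1.65 s pitch); all baseline
  # frames must be pre-contrast
  expect_true(all(ser$times[frames] < 15))
  expect_gte(length(frames), 3)
  gm <- which(sc$labels == 3L, arr.ind = TRUE)[1, ]
  expect_equal(attr(sub, "baseline")[gm[1], gm[2], gm[3]], 35,
               tolerance = 1e-9)
})

test_that("median filter matches a brute-force oracle and its bounds", {
  set.seed(21)
  d <- c(6, 5, 4)
  vol <- array(rnorm(prod(d)), dim = d)
  ser <- ct_series(array(vol, dim = c(d, 1)), 0, 1)
  got <- nonlinear_filter(ser)$data[, , , 1]
  oracle <- array(0, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    nb <- vol[max(1, i - 1):min(d[1], i + 1),
              max(1, j - 1):min(d[2], j + 1),
              max(1, k - 1):min(d[3], k + 1)]
    oracle[i, j, k] <- median(nb)
  }
  expect_equal_array(got, oracle, tol = 1e-12)

  const <- ct_series(array(7, dim = c(d, 1)), 0, 1)
  expect_equal(range(nonlinear_filter(const)$data), c(7, 7))

  imp <- array(0, dim = c(d, 1)); imp[3, 3, 2, 1] <- 100
  ser2 <- ct_series(imp, 0, 1)
  expect_equal(max(abs(nonlinear_filter(ser2)$data)), 0)  # impulse removed
})

test_that("two filter passes equal one pass applied twice", {
  set.seed(33)
  d <- c(6, 6, 4)
  ser <- ct_series(array(rnorm(prod(d) * 2), dim = c(d, 2)), c(0, 6), 5)
  expect_identical(nonlinear_filter(ser, passes = 2)$data,
                   nonlinear_filter(nonlinear_filter(ser))$data)
})

test_that("1 s resampling reproduces knots and cubic polynomials", {
  # knots already on an integer grid: interpolant equals the samples
  d <- c(4, 3, 2)
  nt <- 10
  set.seed(14)
  data <- array(rnorm(prod(d) * nt), dim = c(d, nt))
  ser <- ct_series(data, times = 0:9, integration = 1e-9, spacing = c(2, 2, 4))
  rs <- resample_1s(ser)
  expect_equal(rs$t, 0:9)
  expect_equal_array(rs$data, pmax(data, 0), tol = 1e-6)

  # cubic polynomial sampled irregularly (frame centers): exact inside span
  times <- c(0, 1.4, 3.1, 4.9, 7.2, 8.8, 10.5, 13)
  p <- function(x) 2 + 0.5 * x + 0.2 * x^2 + 0.03 * x^3
  vals <- p(times + 0.05)   # centers at times + integration/2
  data2 <- array(rep(vals, each = prod(d)), dim = c(d, length(times)))
  ser2 <- ct_series(data2, times, integration = 0.1, spacing = c(2, 2, 4))
  rs2 <- resample_1s(ser2)
  inside <- rs2$t >= times[1] + 0.05 & rs2$t <= times[8] + 0.05
  expect_equal(rs2$data[1, 1, 1, inside], p(rs2$t[inside]), tolerance = 1e-8)
})

test_that("sparse sweep sampling of a bolus has the expected spline error", {
  # flat-panel-like 6 s knots under-resolve a ~10 s bolus: error is bounded
  # but not small, while 2 s sampling recovers the curve to ~1%
  g <- function(x) aif_concentration(aif_model(peak = 100, t0 = 15,
                                               alpha = 3, beta = 3), x)
  d <- c(2, 2, 2)
  sample_curve <- function(times, integr) {
    centers <- times + integr / 2
    ct_series(array(rep(g(centers), each = prod(d)),
                    dim = c(d, length(times))),
              times, integr, spacing = c(2, 2, 4))
  }
  fd <- resample_1s(sample_curve(seq(12, 54, by = 6), 5))
  tt <- fd$t[fd$t >= 15 & fd$t <= 56]
  err_fd <- max(abs(fd$data[1, 1, 1, fd$t %in% tt] - g(tt))) / 100
  expect_lt(err_fd, 0.25)

  md <- resample_1s(sample_curve(seq(12, 54, by = 2), 0.5))
  tt2 <- md$t[md$t >= 15 & md$t <= 54]
  err_md <- max(abs(md$data[1, 1, 1, md$t %in% tt2] - g(tt2))) / 100
  expect_lt(err_md, 0.01)
  expect_gt(err_fd, err_md)   # temporal resolution drives fidelity
})

test_that("fewer than 4 frames falls back to linear interpolation", {
  d <- c(2, 2, 2)
  data <- array(rep(c(0, 6, 3), each = prod(d)), dim = c(d, 3))
  ser <- ct_series(data, times = c(0, 3, 6), integration = 1e-9)
  expect_warning(rs <- resample_1s(ser), "linear")
  expect_equal(rs$data[1, 1, 1, ], approx(c(0, 3, 6), c(0, 6, 3), 0:6)$y)
})

test_that("tissue mask applies the HU window and vessel cut", {
  sc <- small_scene(seed = 1)
  ser <- render(sc, aif_model(t0 = 15), mdctp_protocol(), noise_sd = 0,
                seed = 1)
  mask <- make_tissue_mask(ser)
  expect_false(mask[1, 1, 1])                       # air, -1000 HU
  skull <- which(sc$labels == 1L, arr.ind = TRUE)[1, ]
  expect_false(mask[skull[1], skull[2], skull[3]])  # bone, +1000 HU
  gm <- which(sc$labels == 3L & !sc$extent, arr.ind = TRUE)
  expect_true(mean(mask[gm]) > 0.95)                # parenchyma kept
  ves <- which(sc$labels == 4L)
  expect_true(all(!mask[ves]))                      # arteries excluded
})

test_that("AIF detection finds the vessel cluster deterministically", {
  sc <- small_scene(seed = 1)
  ser <- render(sc, aif_model(t0 = 15), mdctp_protocol(), noise_sd = 2,
                seed = 3)
  sub <- nonlinear_filter(subtract_mask(ser), passes = 2)
  conc <- resample_1s(sub)
  aifc <- detect_aif(conc)
  sel <- aifc$voxels
  expect_true(all(sc$labels[sel] == 4L))     # selected voxels in the vessel
  aifc2 <- detect_aif(conc)
  expect_identical(aifc$conc, aifc2$conc)    # deterministic

  # two identical strong candidates: both pooled, mean equals either
  t <- 0:40
  strong <- 200 * exp(-(t - 10)^2 / 8) * (t > 2)
  weak <- 10 * exp(-(t - 20)^2 / 40) * (t > 8)
  conc2 <- make_conc(list(strong, strong, weak), t)
  a2 <- detect_aif(conc2)
  expect_equal(nrow(a2$voxels), 2)
  expect_equal(a2$conc, strong)

  # only delayed low-amplitude tissue curves: no arterial candidate
  conc3 <- make_conc(list(weak, 0.8 * weak), t)
  expect_error(detect_aif(conc3), "AIF manually")
})

test_that("deconvolution recovers CBF and Tmax from exact forward convolution", {
  t <- 0:119
  a <- aif_concentration(aif_model(peak = 200, t0 = 10), t)
  aifc <- make_aif_curve(a, t)
  cases <- expand.grid(delay = seq(0, 12, by = 2), mtt = c(4, 6))
  cbf_true <- 0.008
  curves <- lapply(seq_len(nrow(cases)), function(i) {
    r <- cbf_true * exp(-pmax(t - cases$delay[i], 0) / cases$mtt[i]) *
      (t >= cases$delay[i])
    convolve(a, rev(r), type = "open")[seq_along(t)]
  })
  conc <- make_conc(curves, t)
  maps <- deconvolve(conc, aifc, psi = 1e-3, adaptive = FALSE)  # noiseless
  expect_true(all(abs(maps$cbf[, 1, 1] / cbf_true - 1) < 0.05))
  expect_true(all(abs(maps$tmax[, 1, 1] - cases$delay) <= 1))
  # CBV equals CBF x the rectangle-rule residue integral (the discrete
  # analogue of CBF * MTT; the geometric sum of exp(-t/MTT) on a 1 s grid)
  mtt_disc <- 1 / (1 - exp(-1 / cases$mtt))
  expect_equal(maps$cbv[, 1, 1], cbf_true * mtt_disc, tolerance = 1e-3)
  expect_equal(maps$mtt[, 1, 1], mtt_disc, tolerance = 1e-2)

  # determinism: bit-identical maps on identical input
  maps2 <- deconvolve(conc, aifc, psi = 1e-3, adaptive = FALSE)
  expect_identical(maps$cbf, maps2$cbf)
})

test_that("tissue curve equal to the AIF deconvolves to Tmax 0", {
  t <- 0:60
  a <- aif_concentration(aif_model(t0 = 8), t)
  maps <- deconvolve(make_conc(list(a), t), make_aif_curve(a, t),
                     psi = 0.05, adaptive = FALSE)
  expect_equal(maps$tmax[1, 1, 1], 0)
})

test_that("a uniform extra delay moves Tmax, not CBF", {
  t <- 0:119
  a <- aif_concentration(aif_model(peak = 200, t0 = 10), t)
  mk <- function(delay) {
    r <- 0.01 * exp(-pmax(t - delay, 0) / 5) * (t >= delay)
    convolve(a, rev(r), type = "open")[seq_along(t)]
  }
  maps <- deconvolve(make_conc(list(mk(0), mk(8)), t), make_aif_curve(a, t),
                     psi = 0.05, adaptive = FALSE)
  expect_equal(maps$tmax[2, 1, 1] - maps$tmax[1, 1, 1], 8, tolerance = 1)
  expect_lt(abs(maps$cbf[2, 1, 1] / maps$cbf[1, 1, 1] - 1), 0.05)
})

test_that("degenerate inputs are handled explicitly", {
  t <- 0:30
  flat <- numeric(length(t))
  a <- aif_concentration(aif_model(t0 = 5), t)
  expect_error(deconvolve(make_conc(list(a), t), make_aif_curve(flat, t)),
               "all-zero AIF")
  maps <- deconvolve(make_conc(list(flat, a), t), make_aif_curve(a, t))
  expect_false(maps$tissue[1, 1, 1])    # dead voxel dropped from the mask
  expect_equal(maps$cbf[1, 1, 1], 0)
  expect_true(maps$tissue[2, 1, 1])
})

test_that("TTP shifts exactly with a shifted tissue curve", {
  t <- 0:50
  a <- aif_concentration(aif_model(t0 = 5), t)
  base <- 10 * exp(-(t - 15)^2 / 30)
  shifted <- c(numeric(4), base[1:(length(t) - 4)])
  maps <- deconvolve(make_conc(list(base, shifted), t), make_aif_curve(a, t))
  expect_equal(maps$ttp[2, 1, 1] - maps$ttp[1, 1, 1], 4)
  # absolute convention
  maps_abs <- deconvolve(make_conc(list(base, shifted), t),
                         make_aif_curve(a, t), ttp_relative = FALSE)
  expect_equal(maps_abs$ttp[1, 1, 1], 15)
})

test_that("noiseless end-to-end recovery under both protocols", {
  # lesion-vs-mirrored-healthy comparisons: the lesion/healthy CBF ratio
  # recovers the generating flow fraction and the Tmax excess recovers the
  # added delay (absolute Tmax carries the deconvolution's grid offset,
  # which cancels in the contrast); the flat-panel protocol gets the wider
  # band its 6 s sampling warrants
  # arrival chosen per protocol's design: multidetector scans start a few
  # seconds before cerebral arrival, the flat-panel protocol's arrival
  # follows its two mask sweeps
  sc <- small_scene(seed = 1, lesion_delay = 8)
  recov <- function(prot, t0) {
    ser <- render(sc, aif_model(t0 = t0, beta = 3), prot, noise_sd = 0,
                  seed = 1)
    maps <- compute_perfusion_maps(ser)
    lesion <- sc$extent & maps$tissue
    idx <- which(lesion, arr.ind = TRUE)
    mirror <- cbind(sc$shape[1] + 1L - idx[, 1], idx[, 2], idx[, 3])
    keep <- maps$tissue[mirror]
    mir <- mirror[keep, , drop = FALSE]
    c(ratio = median(maps$cbf[lesion][keep]) / median(maps$cbf[mir]),
      excess = median(maps$tmax[lesion][keep]) - median(maps$tmax[mir]))
  }
  m <- recov(mdctp_protocol(), t0 = 8)
  expect_lt(abs(m[["ratio"]] - 0.4), 0.1)
  expect_lte(abs(m[["excess"]] - 8), 1.5)
  f <- recov(fdctp_protocol(), t0 = 15)
  expect_lt(abs(f[["ratio"]] - 0.4), 0.1)
  expect_lte(abs(f[["excess"]] - 8), 2)
})
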