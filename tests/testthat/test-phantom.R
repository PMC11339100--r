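# Digital phantom: bolus model, protocol timing, scene construction and the
# indicator-dilution forward model.

test_that("gamma-variate AIF is causal, peaks as requested and integrates", {
  aif <- aif_model(peak = 200, t0 = 5, alpha = 3, beta = 1.5)
  t <- seq(0, 60, by = 0.01)
  conc <- aif_concentration(aif, t)
  expect_true(all(conc[t <= 5] == 0))
  expect_true(all(conc >= 0))
  expect_equal(max(conc), 200, tolerance = 1e-4)
  expect_equal(t[which.max(conc)], 5 + 3 * 1.5, tolerance = 0.02)
  # analytic integral A * gamma(alpha+1) * beta^(alpha+1)
  expect_equal(sum(conc) * 0.01,
               aif$amplitude * gamma(4) * 1.5^4, tolerance = 1e-3)
})

test_that("default protocols match their acquisition timing", {
  m <- mdctp_protocol()
  expect_length(m$times, 30)
  expect_equal(m$n_mask, 0L)
  span_m <- m$times[30] + m$integration[30] - m$times[1]
  expect_gte(span_m, 46.3); expect_lte(span_m, 50.0)
  expect_equal(unique(m$integration), 0.5)

  f <- fdctp_protocol()
  expect_length(f$times, 10)
  expect_equal(f$n_mask, 2L)
  expect_equal(unique(diff(f$times)), 6)
  expect_equal(unique(f$integration), 5)

  expect_error(acquisition_protocol(c(0, 1), integration = 2), "overlap")
  expect_error(acquisition_protocol(c(0, -1), integration = 0.1),
               "increasing")
})

test_that("scene construction is deterministic and satisfies its invariants", {
  sc1 <- small_scene(seed = 5)
  sc2 <- small_scene(seed = 5)
  expect_identical(sc1$labels, sc2$labels)
  expect_identical(sc1$cbf, sc2$cbf)
  expect_false(identical(small_scene(seed = 6)$extent, sc1$extent))

  sc <- sc1
  tis <- sc$brain
  expect_true(all(sc$cbf[tis] > 0))
  expect_true(all(sc$mtt[tis] > 0))
  expect_true(all(sc$delay >= 0))
  expect_true(all(sc$extent[sc$core]))            # core within extent
  expect_true(all(tis[sc$extent]))                # extent within tissue
  # extent confined to the right hemisphere
  xidx <- which(sc$extent, arr.ind = TRUE)[, 1]
  expect_true(all(xidx > sc$midline))
  # tissue labels are mirror-symmetric about the midline (vessel aside)
  lab <- sc$labels; lab[lab == 4L] <- 2L
  expect_identical(lab, lab[rev(seq_len(sc$shape[1])), , ])
  expect_gt(sum(sc$labels == 4L), 0)
  expect_error(make_default_scene(shape = c(8, 8, 4)), "invalid config")
})

test_that("uniform lesion delays the whole extent by exactly lesion_delay", {
  sc <- small_scene(seed = 1, lesion_delay = 8)   # delay_taper = 0
  excess <- (sc$delay - sc$healthy_tmax)[sc$extent]
  expect_true(all(abs(excess - 8) < 1e-12))
  expect_equal(sc$truth$tmax, sc$delay)
  expect_equal(sc$truth$extent_ml, sum(sc$extent) * prod(sc$spacing) / 1000)
})

test_that("delay taper ramps severity from rim to centre", {
  sc <- small_scene(seed = 2, lesion_delay = 10, delay_taper = 0.6)
  excess <- (sc$delay - sc$healthy_tmax)[sc$extent]
  expect_lte(max(excess), 10)
  expect_gte(min(excess), 10 * (1 - 0.6) - 1e-9)
  expect_gt(max(excess) - min(excess), 2)   # a real gradient
  expect_error(small_scene(delay_taper = 1.2), "delay_taper")
})

test_that("core voxels sit below 30% of their mirrored contralateral CBF", {
  sc <- small_scene(seed = 4, lesion_cbf_fraction = 0.4,
                    core_cbf_fraction = 0.15)
  idx <- which(sc$core, arr.ind = TRUE)
  mirrored <- cbind(sc$shape[1] + 1L - idx[, 1], idx[, 2], idx[, 3])
  ratio <- sc$cbf[idx] / sc$cbf[mirrored]
  expect_true(all(ratio < 0.30))
  expect_error(make_default_scene(lesion_cbf_fraction = 0.2,
                                  core_cbf_fraction = 0.4), "core_cbf")
})

test_that("tissue_curve reduces to CBF * residue for an impulse input", {
  t <- seq(0, 30, by = 0.5)
  imp <- numeric(length(t)); imp[1] <- 1 / 0.5     # unit-area impulse
  got <- tissue_curve(3, mtt = 4, delay = 0, aif = imp, t = t)
  # lag 0 carries the trapezoidal half weight; beyond it the identity is exact
  expect_equal(got[-1], 3 * exp(-t[-1] / 4), tolerance = 1e-10)
  expect_equal(got[1], 3 / 2, tolerance = 1e-10)
  expect_error(tissue_curve(1, mtt = 0, delay = 0, imp, t), "mtt")
  expect_error(tissue_curve(1, 4, 0, imp, t = c(0, 1, 3)), "uniform")
})

test_that("tissue_curve is time-invariant in the delay", {
  t <- seq(0, 80, by = 0.2)
  aif <- aif_model(t0 = 5)
  c0 <- tissue_curve(0.01, 4, delay = 0, aif, t)
  c8 <- tissue_curve(0.01, 4, delay = 8, aif, t)
  shift <- 8 / 0.2
  expect_equal(c8[(shift + 1):length(t)],
               c0[1:(length(t) - shift)], tolerance = 1e-9)
  expect_true(all(c8[t < 5 + 8] < 1e-12))          # causal
})

test_that("central volume theorem holds within 1% on a 0.1 s grid", {
  t <- seq(0, 140, by = 0.1)
  aif <- aif_model(t0 = 5)
  a <- aif_concentration(aif, t)
  trapz <- function(y) (sum(y) - (y[1] + y[length(y)]) / 2) * 0.1
  set.seed(99)
  for (i in 1:25) {
    cbf <- runif(1, 0.001, 0.02); mtt <- runif(1, 2, 9)
    delay <- runif(1, 0, 12)
    cv <- tissue_curve(cbf, mtt, delay, aif, t)
    expect_equal(trapz(cv) / trapz(a), cbf * mtt,
                 tolerance = 0.01)
  }
})

test_that("noise-free rendering equals window-averaged ground truth", {
  sc <- small_scene(seed = 1)
  aif <- aif_model(t0 = 15)
  prot <- mdctp_protocol()
  ser <- render(sc, aif, prot, noise_sd = 0, seed = 1)
  # oracle: recompute one gray voxel's frame values by direct quadrature
  vox <- which(sc$labels == 3L & !sc$extent, arr.ind = TRUE)[1, ]
  tfine <- seq(0, 50, by = 0.1)
  aif_true <- aif; aif_true$amplitude <- aif$amplitude / sc$vessel_partial_volume
  curve <- tissue_curve(sc$cbf[vox[1], vox[2], vox[3]] / 6000,
                        sc$mtt[vox[1], vox[2], vox[3]],
                        sc$delay[vox[1], vox[2], vox[3]], aif_true, tfine)
  for (f in c(1, 10, 20, 30)) {
    sel <- tfine >= prot$times[f] - 1e-9 &
      tfine <= prot$times[f] + prot$integration[f] + 1e-9
    expect_equal(ser$data[vox[1], vox[2], vox[3], f],
                 35 + mean(curve[sel]), tolerance = 1e-9)
  }
  # air and skull carry their baselines in every frame
  expect_true(all(ser$data[1, 1, 1, ] == -1000))
  skull_vox <- which(sc$labels == 1L, arr.ind = TRUE)[1, ]
  expect_true(all(ser$data[skull_vox[1], skull_vox[2], skull_vox[3], ] == 1000))
})

test_that("sweep integration attenuates a peak falling between sweep centres", {
  sc <- small_scene(seed = 1)
  aif <- aif_model(t0 = 15)
  ser <- render(sc, aif, fdctp_protocol(), noise_sd = 0, seed = 1)
  ves <- which(sc$labels == 4L, arr.ind = TRUE)[1, ]
  frame_peak <- max(ser$data[ves[1], ves[2], ves[3], ] - 50)
  true_peak <- max(aif_concentration(aif, seq(0, 60, by = 0.01)))
  expect_lt(frame_peak, true_peak)
  # mask frames are baseline only
  expect_true(all(ser$data[ves[1], ves[2], ves[3], 1:2] == 50))
})

test_that("rendering is reproducible for a fixed seed", {
  sc <- small_scene(seed = 2)
  aif <- aif_model(t0 = 15)
  s1 <- render(sc, aif, fdctp_protocol(), noise_sd = 4, seed = 7)
  s2 <- render(sc, aif, fdctp_protocol(), noise_sd = 4, seed = 7)
  expect_identical(s1$data, s2$data)
  s3 <- render(sc, aif, fdctp_protocol(), noise_sd = 4, seed = 8)
  expect_false(identical(s1$data, s3$data))
})
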