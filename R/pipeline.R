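# Pipeline configuration and end-to-end orchestration:
# simulate -> maps (both protocols) -> segment (both) -> compare.

default_config <- function() {
  list(
    seed = 1L,
    n_subjects = 5L,
    out_dir = file.path(tempdir(), "ctperf_run"),
    log_level = "info",
    scene = list(shape = c(64L, 64L, 24L), spacing = c(2, 2, 4),
                 lesion_delay = 8, lesion_cbf_fraction = 0.4,
                 core_cbf_fraction = 0.15),
    # t0 is the cerebral bolus arrival; with injection at acquisition start
    # (the flat-panel protocol's design) the arm-to-brain transit puts it
    # well after the two mask sweeps. beta = 3 gives a first-pass bolus of
    # ~12 s FWHM, the clinical width; narrower boluses alias badly under
    # 6 s sweep sampling
    aif = list(peak = 200, t0 = 18, alpha = 3, beta = 3),
    protocols = list(mdctp_noise_sd = 2, fdctp_noise_sd = 4),
    engine = list(psi = 0.15, filter_radius = 1L, filter_passes = 2L,
                  register = FALSE),
    segmentation = list(tmax_abs_threshold = 6,
                        rcbf_thresholds = c(0.30, 0.45),
                        norm_tmax_threshold = 150,
                        norm_cbf_threshold = 30,
                        roi_radius_mm = 3.5),
    population = list(lesion_delay = c(8, 16),
                      lesion_cbf_fraction = c(0.30, 0.50),
                      core_cbf_fraction = c(0.10, 0.20),
                      delay_taper = c(0.75, 0.9),
                      aif_t0 = c(16, 20)),
    # the two acquisitions are separate injections ~3/4 h apart: the
    # flat-panel scan uses a double, longer bolus (60 vs 30 ml) and the
    # stroke physiology evolves between scans
    inter_scan = list(t0_shift = c(-2, 2),
                      beta_scale = c(1.15, 1.5),
                      lesion_delay_shift = c(-1.5, 1.5))
  )
}

check_known_keys <- function(x, ref, path = "") {
  unknown <- setdiff(names(x), names(ref))
  if (length(unknown) > 0)
    stopf("unknown config key%s: %s", if (length(unknown) > 1) "s" else "",
          paste0(path, unknown, collapse = ", "))
  for (nm in names(x))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_known_keys(as.list(x[[nm]]), ref[[nm]], paste0(path, nm, "$"))
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Builds the single document that fully determines a pipeline run: scene
#' parameters, bolus model, protocol noise, engine parameters, segmentation
#' thresholds, the per-subject population ranges used when simulating a
#' cohort, seed and output directory. Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults; nested lists are merged
#'   (e.g. `engine = list(psi = 0.2)` keeps the other engine defaults).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- default_config()
  overrides <- list(...)
  check_known_keys(overrides, cfg)
  cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param cfg a [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# per-subject scene/AIF draws: cohort heterogeneity in lesion severity,
# geometry and bolus arrival
draw_subject_params <- function(cfg, subject_seed, cohort = TRUE) {
  if (!cohort) {
    return(list(seed = subject_seed,
                lesion_delay = cfg$scene$lesion_delay,
                lesion_cbf_fraction = cfg$scene$lesion_cbf_fraction,
                core_cbf_fraction = cfg$scene$core_cbf_fraction,
                delay_taper = 0,
                t0 = cfg$aif$t0,
                t0_shift = 0, beta_scale = 1, lesion_delay_shift = 0))
  }
  pop <- cfg$population
  isc <- cfg$inter_scan
  with_seed(subject_seed + 104729L, list(
    seed = subject_seed,
    lesion_delay = runif(1, pop$lesion_delay[1], pop$lesion_delay[2]),
    lesion_cbf_fraction = runif(1, pop$lesion_cbf_fraction[1],
                                pop$lesion_cbf_fraction[2]),
    core_cbf_fraction = runif(1, pop$core_cbf_fraction[1],
                              pop$core_cbf_fraction[2]),
    delay_taper = runif(1, pop$delay_taper[1], pop$delay_taper[2]),
    t0 = runif(1, pop$aif_t0[1], pop$aif_t0[2]),
    t0_shift = runif(1, isc$t0_shift[1], isc$t0_shift[2]),
    beta_scale = runif(1, isc$beta_scale[1], isc$beta_scale[2]),
    lesion_delay_shift = runif(1, isc$lesion_delay_shift[1],
                               isc$lesion_delay_shift[2])))
}

# simulate, map and segment one subject under both protocols
pipeline_subject <- function(cfg, subject_seed, cohort = TRUE) {
  pars <- draw_subject_params(cfg, subject_seed, cohort)
  scene <- make_default_scene(
    seed = pars$seed, lesion_delay = pars$lesion_delay,
    lesion_cbf_fraction = pars$lesion_cbf_fraction,
    core_cbf_fraction = pars$core_cbf_fraction,
    delay_taper = pars$delay_taper,
    shape = cfg$scene$shape, spacing = cfg$scene$spacing)
  aif <- aif_model(peak = cfg$aif$peak, t0 = pars$t0,
                   alpha = cfg$aif$alpha, beta = cfg$aif$beta)
  # the flat-panel acquisition is a second injection 3/4 h later: double,
  # longer bolus, slightly different arrival, and evolved lesion severity
  # (the geometry and masks are identical)
  aif_f <- aif_model(peak = cfg$aif$peak,
                     t0 = pars$t0 + pars$t0_shift,
                     alpha = cfg$aif$alpha,
                     beta = cfg$aif$beta * pars$beta_scale)
  scene_f <- make_default_scene(
    seed = pars$seed,
    lesion_delay = max(pars$lesion_delay + pars$lesion_delay_shift, 0.5),
    lesion_cbf_fraction = pars$lesion_cbf_fraction,
    core_cbf_fraction = pars$core_cbf_fraction,
    delay_taper = pars$delay_taper,
    shape = cfg$scene$shape, spacing = cfg$scene$spacing)
  # the multidetector scan is triggered shortly before cerebral arrival;
  # the flat-panel acquisition is locked to the injection at t = 0
  ser_m <- render(scene, aif,
                  mdctp_protocol(start = max(pars$t0 - 8, 0)),
                  noise_sd = cfg$protocols$mdctp_noise_sd,
                  seed = subject_seed)
  ser_f <- render(scene_f, aif_f, fdctp_protocol(),
                  noise_sd = cfg$protocols$fdctp_noise_sd,
                  seed = subject_seed + 500000L)
  seg_cfg <- do.call(segmentation_config, cfg$segmentation)
  seg_cfg$roi_centers <- default_reference_rois(scene)
  eng <- cfg$engine
  maps_m <- compute_perfusion_maps(ser_m, psi = eng$psi,
                                   filter_radius = eng$filter_radius,
                                   filter_passes = eng$filter_passes,
                                   register = eng$register)
  maps_f <- compute_perfusion_maps(ser_f, psi = eng$psi,
                                   filter_radius = eng$filter_radius,
                                   filter_passes = eng$filter_passes,
                                   register = eng$register)
  rep_m <- segment_hypoperfusion(maps_m, seg_cfg, scene = scene)
  rep_f <- segment_hypoperfusion(maps_f, seg_cfg, scene = scene)
  list(params = pars, scene = scene, aif = aif,
       series = list(mdctp = ser_m, fdctp = ser_f),
       maps = list(mdctp = maps_m, fdctp = maps_f),
       reports = list(mdctp = rep_m, fdctp = rep_f))
}

report_row <- function(rep) {
  v <- rep$volumes
  out <- as.list(setNames(v$ml, v$name))
  c(out, as.list(setNames(rep$mismatches$ml, rep$mismatches$name)))
}

#' Simulate a cohort and tabulate paired volumes under both protocols
#'
#' For each seed, draws a subject (lesion severity, geometry and bolus
#' arrival jittered over the configured population ranges), renders the
#' scene under the multidetector-like and flat-panel-like protocols, computes
#' maps, segments, and returns one row of paired volumes per subject.
#'
#' @param n_subjects number of simulated subjects.
#' @param seed base seed; subject i uses `seed * 1000 + i`.
#' @param cfg a [pipeline_config()].
#' @return data frame with per-subject true volumes and, per protocol
#'   (suffix `_mdctp` / `_fdctp`), the segmented volumes (ml).
#' @export
protocol_comparison_batch <- function(n_subjects = 20, seed = 1,
                                      cfg = pipeline_config()) {
  rows <- lapply(seq_len(n_subjects), function(i) {
    sub <- pipeline_subject(cfg, subject_seed = seed * 1000L + i,
                            cohort = TRUE)
    rm_ <- report_row(sub$reports$mdctp)
    rf_ <- report_row(sub$reports$fdctp)
    data.frame(subject = i,
               true_extent_ml = sub$scene$truth$extent_ml,
               true_core_ml = sub$scene$truth$core_ml,
               lesion_delay = sub$params$lesion_delay,
               as.data.frame(setNames(rm_, paste0(names(rm_), "_mdctp"))),
               as.data.frame(setNames(rf_, paste0(names(rf_), "_fdctp"))))
  })
  do.call(rbind, rows)
}

log_stage <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[ctperf] ", fmt), ...))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline and emit a reproducibility manifest
#'
#' Simulates `n_subjects` phantoms, renders both protocols, computes maps,
#' segments volumes, compares the paired volumes across protocols, writes all
#' artifacts (series, maps, volume tables, agreement report, config) under
#' `cfg$out_dir`, and returns a manifest with seeds, package version and
#' per-file MD5 checksums. Deterministic stages reproduce bit-identical
#' artifacts for identical config and seed.
#'
#' @param cfg a [pipeline_config()].
#' @param write_series also write the raw 4D series (largest artifacts).
#' @return object of class `run_manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), write_series = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  started <- Sys.time()
  cfg_path <- file.path(out, "config.yaml")
  write_pipeline_config(cfg, cfg_path)

  n <- cfg$n_subjects
  seeds <- cfg$seed * 1000L + seq_len(n)
  vol_rows <- vector("list", n)
  for (i in seq_len(n)) {
    log_stage(cfg, "subject %d/%d (seed %d)", i, n, seeds[i])
    sub <- run_stage("simulate/maps/segment",
                     pipeline_subject(cfg, seeds[i], cohort = n > 1))
    sdir <- file.path(out, sprintf("subject_%02d", i))
    if (write_series) {
      run_stage("write series", {
        write_nifti_series(sub$series$mdctp, file.path(sdir, "mdctp_series"))
        write_nifti_series(sub$series$fdctp, file.path(sdir, "fdctp_series"))
      })
    }
    run_stage("write maps", {
      write_perfusion_maps(sub$maps$mdctp, file.path(sdir, "mdctp_maps"))
      write_perfusion_maps(sub$maps$fdctp, file.path(sdir, "fdctp_maps"))
    })
    rm_ <- report_row(sub$reports$mdctp)
    rf_ <- report_row(sub$reports$fdctp)
    vol_rows[[i]] <- data.frame(
      subject = i, seed = seeds[i],
      true_extent_ml = sub$scene$truth$extent_ml,
      true_core_ml = sub$scene$truth$core_ml,
      as.data.frame(setNames(rm_, paste0(names(rm_), "_mdctp"))),
      as.data.frame(setNames(rf_, paste0(names(rf_), "_fdctp"))))
  }
  volumes <- do.call(rbind, vol_rows)
  vol_path <- file.path(out, "volumes.csv")
  write.csv(volumes, vol_path, row.names = FALSE)

  agreement <- NULL
  if (n >= 5) {
    log_stage(cfg, "compare stage (%d paired subjects)", n)
    agreement <- run_stage("compare", {
      measures <- c("visible", "tmax_gt6", "norm_tmax150", "core_rcbf30")
      setNames(lapply(measures, function(m)
        agreement_report(volumes[[paste0(m, "_mdctp")]],
                         volumes[[paste0(m, "_fdctp")]],
                         label = paste0(m, ": MDCTP vs FDCTP"))), measures)
    })
    agr_json <- lapply(agreement, function(x)
      x[c("label", "pearson", "icc", "bland_altman", "dc")])
    jsonlite::write_json(agr_json, file.path(out, "agreement.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  checks <- tools::md5sum(files)
  names(checks) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", out),
                              "/?"), "", names(checks))
  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("ctperf")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed, subject_seeds = seeds,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    out_dir = out, checksums = as.list(checks)),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "volumes") <- volumes
  attr(manifest, "agreement") <- agreement
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("ctperf run %s: %d artifacts under %s (config %s)\n",
              x$package_version, length(x$checksums), x$out_dir,
              substr(x$config_hash, 1, 8)))
  invisible(x)
}
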