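## End-to-end experiment driver: generate or load a multi-site cohort,
## label outcomes, smooth, mask, extract features, run the bootstrapped
## site-matched leave-two-out evaluation and (optionally) the permutation
## test, then write JSON/TSV reports plus a reproducibility manifest.

#' Cuboid voxel region helper
#'
#' Linear indices of the axis-aligned cuboid `lo[i]..hi[i]` (1-based,
#' inclusive) on a grid — convenient for defining planted effect regions.
#'
#' @param grid_shape Length-3 grid dimensions.
#' @param lo,hi Length-3 inclusive corner indices.
#' @return Integer vector of linear voxel indices.
#' @export
cuboid_region <- function(grid_shape, lo, hi) {
  stopifnot(all(lo >= 1L), all(hi <= grid_shape), all(lo <= hi))
  idx <- as.matrix(expand.grid(x = lo[1L]:hi[1L], y = lo[2L]:hi[2L],
                               z = lo[3L]:hi[3L]))
  as.integer(idx[, 1L] + (idx[, 2L] - 1L) * grid_shape[1L] +
               (idx[, 3L] - 1L) * grid_shape[1L] * grid_shape[2L])
}

## default site profiles: mild offset/gain/noise/smoothness differences,
## the kind of systematic between-scanner variation pooling must absorb
default_site_profiles <- function(site_ids) {
  offs <- c(0, 0.02, -0.02, 0.01, -0.01)
  gains <- c(1, 1.05, 0.95, 1.02, 0.98)
  psfs <- c(2, 4, 3, 2.5, 3.5)
  lapply(seq_along(site_ids), function(i) {
    j <- (i - 1L) %% 5L + 1L
    site_profile(site_ids[i], intensity_offset = offs[j],
                 intensity_gain = gains[j], noise_sd = 0.05,
                 psf_fwhm_mm = psfs[j])
  })
}

## default planted effects on the 16^3 grid: a strong localized sex effect
## and a weaker illness-course effect in a disjoint region
default_effects <- function(grid_shape = c(16L, 16L, 16L),
                            sex_effect = 2, course_effect = 0.5) {
  efs <- list()
  if (sex_effect != 0)
    efs <- c(efs, list(effect_map("sex",
      cuboid_region(grid_shape, c(10, 8, 7), c(13, 11, 9)), sex_effect)))
  if (course_effect != 0)
    efs <- c(efs, list(effect_map("course",
      cuboid_region(grid_shape, c(4, 5, 8), c(7, 8, 10)), course_effect)))
  efs
}

#' Experiment configuration
#'
#' Bundles every knob of a classification experiment. Defaults reproduce
#' the reference analysis settings: 0.03 gray-matter threshold, 4-mm FWHM
#' smoothing, 100 bootstrapped balanced leave-two-out runs and 1000 label
#' permutations.
#'
#' @param task `"sex"` or `"course"` (outcome classification).
#' @param scope `"multi_site"`, or a single site label to restrict to.
#' @param males_only For the course task, restrict to males.
#' @param mask_threshold Gray-matter probability cutoff (default 0.03).
#' @param smooth_fwhm_mm Smoothing kernel FWHM in mm (default 4).
#' @param n_bootstraps Balanced-resample repetitions (default 100).
#' @param n_permutations Label permutations; 0 skips the significance test
#'   (default 1000).
#' @param c_grid Candidate SVM penalties (default `10^(-3:3)`).
#' @param seed Master seed (default 1).
#' @param input A [synthetic_config()] to generate data from, or a
#'   directory containing `metadata.tsv` plus one `<subject_id>.nii.gz`
#'   per subject.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(task = c("sex", "course"),
                              scope = "multi_site", males_only = FALSE,
                              mask_threshold = 0.03, smooth_fwhm_mm = 4,
                              n_bootstraps = 100L, n_permutations = 1000L,
                              c_grid = 10^(-3:3), seed = 1L, input = NULL) {
  task <- match.arg(task)
  stopifnot(mask_threshold >= 0, mask_threshold <= 1, smooth_fwhm_mm >= 0,
            n_bootstraps >= 1, n_permutations >= 0)
  structure(list(task = task, scope = scope, males_only = males_only,
                 mask_threshold = mask_threshold,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 n_bootstraps = as.integer(n_bootstraps),
                 n_permutations = as.integer(n_permutations),
                 c_grid = c_grid, seed = as.integer(seed), input = input),
            class = "experiment_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

config_fingerprint <- function(config) {
  x <- config
  x$input <- if (inherits(x$input, "synthetic_config"))
    list(kind = "synthetic", seed = x$input$seed,
         grid = x$input$grid_shape,
         n = sum(x$input$per_site_counts$n)) else as.character(x$input)
  j <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile(); writeLines(as.character(j), f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

load_experiment_input <- function(input) {
  if (inherits(input, "synthetic_config")) return(generate_cohort(input))
  if (is.character(input) && dir.exists(input)) {
    cohort <- read_metadata(file.path(input, "metadata.tsv"))
    maps <- lapply(cohort$subject_id, function(id) {
      p <- file.path(input, paste0(id, ".nii.gz"))
      if (!file.exists(p)) p <- file.path(input, paste0(id, ".nii"))
      if (!file.exists(p)) stop("no volume found for subject ", id)
      read_nifti_map(p)
    })
    return(list(maps = maps, cohort = cohort))
  }
  stop("input must be a synthetic_config or an existing data directory")
}

#' Run a full classification experiment
#'
#' Executes the pipeline: load or generate the cohort, restrict it to the
#' task's subjects (outcome groups, optionally males only; sex models use
#' everyone), smooth every map, build the group gray-matter mask, extract
#' features, run [bootstrap_ensemble()] and, when `n_permutations > 0`,
#' [permutation_test()]. Reports are written to `out_dir`:
#' `report.json` (all metrics), `metrics.tsv` (per-site and overall rows),
#' `decision_values.tsv`, and `manifest.json` (configuration fingerprint,
#' seeds, package/R versions). Outputs are byte-reproducible for a fixed
#' configuration.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if missing).
#' @return The result list (ensemble, permutation result, mask summary),
#'   invisibly; report files as a side effect.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dat <- with_stage("load", load_experiment_input(config$input))
  cohort <- dat$cohort; maps <- dat$maps
  keep <- with_stage("label", {
    validate_cohort(cohort)
    if (config$task == "course") {
      sel <- select_outcome_cohort(cohort, males_only = config$males_only)
      cohort$subject_id %in% sel$subject_id
    } else rep(TRUE, nrow(cohort))
  })
  if (!identical(config$scope, "multi_site"))
    keep <- keep & cohort$site %in% config$scope
  cohort <- cohort[keep, , drop = FALSE]
  maps <- maps[keep]
  if (nrow(cohort) == 0L) stop("[stage label] no subjects left after selection")
  smoothed <- with_stage("smooth",
    lapply(maps, gm_smooth, fwhm_mm = config$smooth_fwhm_mm))
  mask <- with_stage("mask", build_mask(smoothed, config$mask_threshold))
  if (mask$n_features == 0L)
    stop("[stage mask] mask is empty at threshold ", config$mask_threshold)
  X <- with_stage("features", extract_features(smoothed, mask, cohort))
  class_field <- config$task
  ens <- with_stage("evaluate",
    bootstrap_ensemble(cohort, X, class_field,
                       n_bootstraps = config$n_bootstraps,
                       c_grid = config$c_grid, seed = config$seed))
  perm <- NULL
  if (config$n_permutations > 0L)
    perm <- with_stage("permtest",
      permutation_test(cohort, X, class_field,
                       n_permutations = config$n_permutations,
                       n_bootstraps = 1L, c_grid = config$c_grid,
                       seed = config$seed))
  with_stage("report", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reports(config, ens, perm, mask, out_dir)
  })
  invisible(list(ensemble = ens, permutation = perm, mask = mask,
                 cohort = cohort))
}

metrics_table <- function(config, ens) {
  tab <- rbind(ens$per_site,
               data.frame(site = "Overall",
                          ppa = ens$mean_metrics$ppa,
                          npa = ens$mean_metrics$npa,
                          sensitivity = ens$mean_metrics$sensitivity,
                          specificity = ens$mean_metrics$specificity,
                          stringsAsFactors = FALSE))
  if (config$task == "sex") {
    ## sex reports use percent correctly classified per class
    data.frame(site = tab$site,
               male_pct = round(100 * tab$sensitivity, 1L),
               female_pct = round(100 * tab$specificity, 1L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(site = tab$site,
               ppa_pct = round(100 * tab$ppa, 1L),
               npa_pct = round(100 * tab$npa, 1L),
               stringsAsFactors = FALSE)
  }
}

write_reports <- function(config, ens, perm, mask, out_dir) {
  tab <- metrics_table(config, ens)
  write.table(tab, file.path(out_dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  export_decision_values(ens, file.path(out_dir, "decision_values.tsv"))
  report <- list(task = config$task, scope = config$scope,
                 males_only = config$males_only,
                 positive_class = ens$class_labels[2L],
                 n_bootstraps = ens$n_bootstraps,
                 n_features = mask$n_features,
                 mean_metrics = ens$mean_metrics,
                 per_site = ens$per_site, metrics_table = tab)
  if (!is.null(perm))
    report$permutation <- list(metric = perm$metric, observed = perm$observed,
                               n_permutations = perm$n_permutations,
                               p_value = perm$p_value)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(config_fingerprint = config_fingerprint(config),
                   seed = config$seed,
                   settings = list(task = config$task, scope = config$scope,
                                   males_only = config$males_only,
                                   mask_threshold = config$mask_threshold,
                                   smooth_fwhm_mm = config$smooth_fwhm_mm,
                                   n_bootstraps = config$n_bootstraps,
                                   n_permutations = config$n_permutations,
                                   c_grid = config$c_grid),
                   versions = list(
                     package = as.character(utils::packageVersion("gmpool")),
                     r = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a ready-to-run synthetic fixture to disk
#'
#' Emits NIfTI volumes, a `metadata.tsv` and a `config.yaml` for one of
#' three presets: `"multicenter_roster"` reproduces the published
#' five-center roster (389 subjects); `"tiny"` is a 2-site, 40-subject
#' cohort for fast end-to-end runs; `"null"` matches `tiny` with all
#' planted effect sizes set to zero.
#'
#' @param out_dir Writable output directory (created if missing).
#' @param preset One of `"multicenter_roster"`, `"tiny"`, `"null"`.
#' @param seed Master seed (default 1).
#' @return Invisible list with the `synthetic_config` used and file paths.
#' @export
make_fixture <- function(out_dir,
                         preset = c("tiny", "null", "multicenter_roster"),
                         seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  grid <- c(16L, 16L, 16L)
  cfg <- switch(preset,
    multicenter_roster = {
      roster <- multicenter_roster()
      synthetic_config(default_site_profiles(unique(roster$site)), roster,
                       effects = default_effects(grid), seed = seed)
    },
    tiny = {
      counts <- expand.grid(site = c("siteA", "siteB"),
                            sex = c("male", "female"),
                            course = c("continuous", "remitting"),
                            stringsAsFactors = FALSE)
      counts$n <- 5L
      synthetic_config(default_site_profiles(c("siteA", "siteB")), counts,
                       effects = default_effects(grid), seed = seed)
    },
    null = {
      counts <- expand.grid(site = c("siteA", "siteB"),
                            sex = c("male", "female"),
                            course = c("continuous", "remitting"),
                            stringsAsFactors = FALSE)
      counts$n <- 5L
      synthetic_config(default_site_profiles(c("siteA", "siteB")), counts,
                       effects = list(), seed = seed)
    })
  dat <- generate_cohort(cfg)
  for (i in seq_along(dat$maps))
    write_nifti_map(dat$maps[[i]],
                    file.path(out_dir,
                              paste0(dat$cohort$subject_id[i], ".nii.gz")))
  write_metadata(dat$cohort, file.path(out_dir, "metadata.tsv"))
  write_config(cfg, file.path(out_dir, "config.yaml"))
  invisible(list(config = cfg, dir = out_dir,
                 metadata = file.path(out_dir, "metadata.tsv"),
                 n_subjects = nrow(dat$cohort)))
}
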