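## Synthetic multi-site gray-matter cohorts with planted site, sex and
## illness-course effects. The generator emulates the *output* of tissue
## segmentation and spatial normalization: modulated gray-matter probability
## maps on a shared grid, differing across acquisition sites in intensity
## offset/gain, per-voxel noise and intrinsic smoothness.

#' Describe one acquisition site's systematic image characteristics
#'
#' Stands in for scanner/protocol differences between centers: an additive
#' intensity offset, a multiplicative gain, a per-voxel Gaussian noise scale
#' and a site point-spread blur (FWHM in mm).
#'
#' @param site_id Site label.
#' @param intensity_offset Additive shift (dimensionless, default 0).
#' @param intensity_gain Multiplicative factor (> 0, default 1).
#' @param noise_sd Per-voxel Gaussian noise SD (>= 0, default 0.05).
#' @param psf_fwhm_mm Site blur FWHM in mm (>= 0, default 0).
#' @return An object of class `site_profile`.
#' @export
site_profile <- function(site_id, intensity_offset = 0, intensity_gain = 1,
                         noise_sd = 0.05, psf_fwhm_mm = 0) {
  if (intensity_gain <= 0) stop("intensity_gain must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  structure(list(site_id = as.character(site_id),
                 intensity_offset = intensity_offset,
                 intensity_gain = intensity_gain,
                 noise_sd = noise_sd, psf_fwhm_mm = psf_fwhm_mm),
            class = "site_profile")
}

#' Plant a localized class effect in the synthetic maps
#'
#' Adds `effect_size * noise_sd` to every voxel of `region_voxels` for the
#' positive level of the target factor (males for `sex`, continuous for
#' `course`), before the site gain is applied. Because the shift is scaled
#' by the site's noise SD, `effect_size` reads as a per-voxel Cohen's d.
#'
#' @param target_factor `"sex"` or `"course"`.
#' @param region_voxels Integer vector of linear voxel indices (nonempty).
#' @param effect_size Standardized per-voxel shift (finite).
#' @return An object of class `effect_map`.
#' @export
effect_map <- function(target_factor = c("sex", "course"), region_voxels,
                       effect_size) {
  target_factor <- match.arg(target_factor)
  region_voxels <- as.integer(region_voxels)
  if (length(region_voxels) == 0L) stop("region_voxels must be nonempty")
  if (!is.finite(effect_size)) stop("effect_size must be finite")
  structure(list(target_factor = target_factor,
                 region_voxels = region_voxels,
                 effect_size = effect_size),
            class = "effect_map")
}

#' Smooth pseudo-brain baseline template
#'
#' A deterministic nonuniform scalar field in `[0.05, 0.95]` inside an
#' ellipsoidal support (zero outside): a superposition of fixed 3D Gaussian
#' blobs mimicking the broad spatial structure of a mean gray-matter map,
#' without any claim of anatomical realism. Gives the mask-building step a
#' realistic in/out structure without external atlases.
#'
#' @param grid_shape Length-3 positive integer grid dimensions.
#' @return 3D numeric array.
#' @export
baseline_template <- function(grid_shape = c(16L, 16L, 16L)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L))
  ## normalized coordinates in [-1, 1]
  cc <- lapply(grid_shape, function(n) {
    if (n == 1L) 0 else seq(-1, 1, length.out = n)
  })
  X <- array(rep(cc[[1L]], times = grid_shape[2L] * grid_shape[3L]), grid_shape)
  Y <- array(rep(rep(cc[[2L]], each = grid_shape[1L]), times = grid_shape[3L]),
             grid_shape)
  Z <- array(rep(cc[[3L]], each = grid_shape[1L] * grid_shape[2L]), grid_shape)
  support <- (X / 0.85)^2 + (Y / 0.85)^2 + (Z / 0.85)^2 <= 1
  ## fixed blob layout: centers/widths chosen once, loosely cortical vs deep
  blobs <- list(c(0.45, 0.25, 0.1, 0.35), c(-0.45, 0.25, 0.1, 0.35),
                c(0.3, -0.4, -0.2, 0.3), c(-0.3, -0.4, -0.2, 0.3),
                c(0, 0.1, 0.45, 0.4), c(0, 0, -0.45, 0.45))
  f <- array(0, grid_shape)
  for (b in blobs)
    f <- f + exp(-((X - b[1L])^2 + (Y - b[2L])^2 + (Z - b[3L])^2) /
                   (2 * b[4L]^2))
  f <- f / max(f)
  v <- array(0, grid_shape)
  v[support] <- 0.05 + 0.90 * f[support]
  v
}

#' Configuration of a synthetic multi-site cohort
#'
#' @param sites List of [site_profile()]s.
#' @param per_site_counts data.frame with columns `site, sex, course, n`
#'   giving the number of subjects per cell (`n >= 0`).
#' @param effects List of [effect_map()]s (may be empty).
#' @param grid_shape Length-3 grid dimensions (default `c(16, 16, 16)`).
#' @param voxel_size_mm Length-3 voxel size in mm (default 2 mm isotropic).
#' @param baseline Baseline template array (default
#'   [baseline_template()] on `grid_shape`); values must lie in `[0, 1]`.
#' @param follow_up_years_range Range the per-subject follow-up length is
#'   drawn from, in years (default `c(3, 7)`).
#' @param seed Master seed; every downstream draw derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(sites, per_site_counts, effects = list(),
                             grid_shape = c(16L, 16L, 16L),
                             voxel_size_mm = c(2, 2, 2),
                             baseline = NULL,
                             follow_up_years_range = c(3, 7),
                             seed = 1L) {
  stopifnot(all(vapply(sites, inherits, logical(1L), "site_profile")))
  site_ids <- vapply(sites, `[[`, character(1L), "site_id")
  if (anyDuplicated(site_ids)) stop("duplicate site_id in sites")
  req <- c("site", "sex", "course", "n")
  if (!all(req %in% names(per_site_counts)))
    stop("per_site_counts needs columns site, sex, course, n")
  if (any(per_site_counts$n < 0)) stop("counts must be nonnegative")
  if (!all(per_site_counts$site %in% site_ids))
    stop("per_site_counts refers to unknown site(s)")
  if (!all(per_site_counts$sex %in% SEX_LEVELS) ||
      !all(per_site_counts$course %in% COURSE_LEVELS))
    stop("per_site_counts has invalid sex or course levels")
  grid_shape <- as.integer(grid_shape)
  if (is.null(baseline)) baseline <- baseline_template(grid_shape)
  if (!identical(dim(baseline), grid_shape))
    stop("baseline dimensions disagree with grid_shape")
  if (any(baseline < 0) || any(baseline > 1))
    stop("baseline values must lie in [0, 1]")
  nvox <- prod(grid_shape)
  for (ef in effects) {
    stopifnot(inherits(ef, "effect_map"))
    if (any(ef$region_voxels < 1L) || any(ef$region_voxels > nvox))
      stop("effect region outside the grid")
  }
  structure(list(sites = setNames(sites, site_ids),
                 per_site_counts = per_site_counts, effects = effects,
                 grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 baseline = baseline,
                 follow_up_years_range = follow_up_years_range,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate one synthetic gray-matter map
#'
#' The generative model, in order: start from the baseline template; add
#' `effect_size * noise_sd` inside each applicable effect region (an effect
#' applies when the subject carries the positive level — male, or
#' continuous); add the site intensity offset; multiply by the site gain;
#' add per-voxel Gaussian noise (`noise_sd`); blur with the site
#' point-spread function; clip to `[0, 1]` last so outputs stay valid
#' probabilities. Identical `(config, site, sex, course, subject_seed)`
#' reproduce the identical volume bit for bit.
#'
#' @param config A [synthetic_config()].
#' @param site Site id (must be in `config$sites`).
#' @param sex `"male"` or `"female"`.
#' @param course `"continuous"`, `"remitting"` or `"excluded"`.
#' @param subject_seed Integer seed for this subject's noise draw.
#' @param add_noise Set `FALSE` to produce the noiseless expectation (used
#'   for effect-size checks).
#' @return A [gm_map()].
#' @export
generate_subject_map <- function(config, site, sex, course, subject_seed,
                                 add_noise = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!site %in% names(config$sites)) stop("unknown site: ", site)
  if (!sex %in% SEX_LEVELS) stop("unknown sex label: ", sex)
  if (!course %in% COURSE_LEVELS) stop("unknown course label: ", course)
  sp <- config$sites[[site]]
  v <- config$baseline
  for (ef in config$effects) {
    positive <- switch(ef$target_factor,
                       sex = identical(sex, "male"),
                       course = identical(course, "continuous"))
    if (positive)
      v[ef$region_voxels] <- v[ef$region_voxels] + ef$effect_size * sp$noise_sd
  }
  v <- (v + sp$intensity_offset) * sp$intensity_gain
  if (add_noise && sp$noise_sd > 0) {
    noise <- with_seed(subject_seed,
                       array(rnorm(length(v), sd = sp$noise_sd), dim(v)))
    v <- v + noise
  }
  if (sp$psf_fwhm_mm > 0)
    v <- separable_convolve(
      v, sp$psf_fwhm_mm / (config$voxel_size_mm * 2 * sqrt(2 * log(2))))
  v <- pmin(pmax(v, 0), 1)
  gm_map(array(v, config$grid_shape), config$voxel_size_mm)
}

#' Generate a full synthetic cohort
#'
#' Walks `config$per_site_counts` in row order and produces one subject per
#' requested count: a gray-matter map from [generate_subject_map()], a
#' follow-up history from [simulate_episode_history()] consistent with the
#' requested course label, and a metadata row. Per-subject seeds derive from
#' `config$seed` and a subject counter, so the whole cohort is a pure
#' function of the configuration.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `maps` (list of [gm_map()]) and `cohort`
#'   (metadata data.frame, one row per map).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  counts <- config$per_site_counts
  total <- sum(counts$n)
  maps <- vector("list", total)
  ids <- character(total); sites <- character(total)
  sexes <- character(total); courses <- character(total)
  fu <- numeric(total); hist <- vector("list", total)
  k <- 0L
  for (r in seq_len(nrow(counts))) {
    for (j in seq_len(counts$n[r])) {
      k <- k + 1L
      sseed <- derive_seed(config$seed, "subject", k)
      ids[k] <- sprintf("S%04d_%s", k, counts$site[r])
      sites[k] <- counts$site[r]
      sexes[k] <- counts$sex[r]
      courses[k] <- counts$course[r]
      fu[k] <- with_seed(derive_seed(sseed, "fu"),
                         round(runif(1L, config$follow_up_years_range[1L],
                                     config$follow_up_years_range[2L]), 1L))
      hist[[k]] <- simulate_episode_history(counts$course[r], fu[k],
                                            derive_seed(sseed, "history"))
      maps[[k]] <- generate_subject_map(config, counts$site[r], counts$sex[r],
                                        counts$course[r], sseed)
    }
  }
  cohort <- data.frame(subject_id = ids, site = sites, sex = sexes,
                       course = courses, follow_up_years = fu,
                       stringsAsFactors = FALSE)
  cohort$history <- hist
  if (total == 0L) cohort$history <- list()
  validate_cohort(cohort)
  list(maps = maps, cohort = cohort)
}

#' Per-site roster of the published five-center first-episode cohort
#'
#' Transcribes the demographic bookkeeping of a five-center first-episode
#' psychosis sample (London, Utrecht, Melbourne, Santander, Sao Paulo;
#' 389 patients in total): per-site counts by sex and illness-course group,
#' with patients fitting neither the continuous nor the remitting extreme
#' recorded as `excluded`. Summing the table reproduces the published
#' marginals — 133 females, 94 continuous, 118 remitting, and 141 males in
#' the outcome groups (75 continuous, 66 remitting).
#'
#' @return data.frame with columns `site, sex, course, n` (one row per
#'   nonempty cell), suitable as `per_site_counts` for
#'   [synthetic_config()].
#' @export
#' @examples
#' r <- multicenter_roster()
#' sum(r$n)                         # 389
#' sum(r$n[r$sex == "female"])      # 133
multicenter_roster <- function() {
  ## per site: total males/females; remitting/continuous totals and their
  ## male subsets; the remainder per sex is the excluded group
  tab <- data.frame(
    site = c("London", "Utrecht", "Melbourne", "Santander", "SaoPaulo"),
    males = c(61, 58, 37, 62, 38),
    females = c(36, 9, 17, 45, 26),
    remitting = c(27, 15, 16, 41, 19),
    continuous = c(30, 24, 14, 16, 10),
    remitting_m = c(13, 14, 9, 21, 9),
    continuous_m = c(22, 21, 12, 12, 8),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    t <- tab[i, ]
    rem_f <- t$remitting - t$remitting_m
    con_f <- t$continuous - t$continuous_m
    exc_m <- t$males - t$remitting_m - t$continuous_m
    exc_f <- t$females - rem_f - con_f
    rows[[i]] <- data.frame(
      site = t$site,
      sex = rep(c("male", "female"), each = 3L),
      course = rep(c("remitting", "continuous", "excluded"), 2L),
      n = c(t$remitting_m, t$continuous_m, exc_m, rem_f, con_f, exc_f),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[out$n > 0, , drop = FALSE]
}

## YAML round-trip of a synthetic_config ----------------------------------

#' Write / read a synthetic-cohort configuration as YAML
#'
#' The YAML mirrors the [synthetic_config()] fields one-for-one; the
#' baseline template is not embedded (it is recomputed from `grid_shape`
#' unless a `baseline_nifti` path is given).
#'
#' @param config A [synthetic_config()].
#' @param path YAML file path.
#' @return `write_config`: `path` invisibly; `read_config`: a
#'   [synthetic_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  x <- list(
    grid_shape = as.integer(config$grid_shape),
    voxel_size_mm = as.numeric(config$voxel_size_mm),
    seed = config$seed,
    follow_up_years_range = as.numeric(config$follow_up_years_range),
    sites = lapply(unname(config$sites), function(s) unclass(s)),
    effects = lapply(config$effects, function(e) unclass(e)),
    per_site_counts = lapply(seq_len(nrow(config$per_site_counts)),
                             function(i) as.list(config$per_site_counts[i, ])))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  counts <- do.call(rbind, lapply(x$per_site_counts, as.data.frame))
  synthetic_config(
    sites = lapply(x$sites, function(s) do.call(site_profile, s)),
    per_site_counts = counts,
    effects = lapply(x$effects, function(e)
      effect_map(e$target_factor, e$region_voxels, e$effect_size)),
    grid_shape = x$grid_shape,
    voxel_size_mm = x$voxel_size_mm,
    follow_up_years_range = x$follow_up_years_range,
    seed = x$seed)
}
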