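## Volume-level operations: gray-matter probability maps, Gaussian smoothing,
## gray-matter masking, and flattening volumes to the subjects x voxels
## feature matrix.

#' Construct a gray-matter probability map
#'
#' A 3D scalar field of per-voxel gray-matter probabilities (values in
#' `[0, 1]`) on a regular grid with a stated voxel size, as produced by
#' modulated normalized tissue segmentation of a T1-weighted MRI.
#'
#' @param values 3D numeric array with all values finite and in `[0, 1]`.
#' @param voxel_size_mm Length-3 positive voxel dimensions in mm.
#' @return An object of class `gm_map`.
#' @export
gm_map <- function(values, voxel_size_mm = c(2, 2, 2)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("gray-matter probabilities must be finite and within [0, 1]")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive numbers")
  structure(list(values = values, voxel_size_mm = voxel_size_mm),
            class = "gm_map")
}

#' @export
print.gm_map <- function(x, ...) {
  cat(sprintf("Gray-matter map %s, voxel %s mm, range [%.3f, %.3f]\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

## 1D Gaussian kernel, unit sum, truncated at 4 sigma
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

## convolution matrix with mirror (reflect) boundary handling; n x n
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -r:r) {
      j <- i + o
      ## reflect about the edges (half-sample symmetric, period 2n)
      j <- ((j - 1L) %% (2L * n))
      j <- ifelse(j >= n, 2L * n - 1L - j, j) + 1L
      K[i, j] <- K[i, j] + kernel[o + r + 1L]
    }
  }
  K
}

## separable 3D convolution via per-axis matrix products
separable_convolve <- function(vol, sigmas_vox) {
  d <- dim(vol)
  for (ax in 1:3) {
    if (sigmas_vox[ax] <= 0) next
    K <- conv_matrix(d[ax], gauss_kernel(sigmas_vox[ax]))
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dv <- dim(v)
    v <- K %*% matrix(v, nrow = dv[1L])
    dim(v) <- dv
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Smooth a gray-matter map with a Gaussian kernel
#'
#' Separable Gaussian convolution with per-axis standard deviation (in
#' voxels) `fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))`. Boundaries use
#' mirror (reflect) padding, which conserves mass for interior sources;
#' `fwhm_mm = 0` is the identity. Output values are clipped to `[0, 1]`
#' unless `clip = FALSE` (the unclipped operator is exactly linear).
#'
#' @param map A [gm_map()].
#' @param fwhm_mm Kernel full width at half maximum in mm (>= 0).
#' @param clip Clip the result to `[0, 1]` (default `TRUE`).
#' @return A smoothed [gm_map()].
#' @export
gm_smooth <- function(map, fwhm_mm, clip = TRUE) {
  stopifnot(inherits(map, "gm_map"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm < 0)
    stop("fwhm_mm must be a single nonnegative number")
  if (fwhm_mm == 0) return(map)
  sigmas <- fwhm_mm / (map$voxel_size_mm * 2 * sqrt(2 * log(2)))
  v <- separable_convolve(map$values, sigmas)
  if (clip) v <- pmin(pmax(v, 0), 1)
  out <- map
  out$values <- array(v, dim(map$values))
  out
}

#' Build a group-level gray-matter inclusion mask
#'
#' Restricts the feature space to voxels that actually contain gray matter:
#' a voxel is included when the cohort-mean gray-matter probability is at
#' least `threshold` (default rule), or — with `rule = "all"` — when every
#' subject individually reaches the threshold. All subjects share one mask,
#' which defines one common feature space for the classifier.
#'
#' @param maps List of [gm_map()]s on identical grids.
#' @param threshold Probability cutoff in `[0, 1]` (conventional default
#'   0.03).
#' @param rule `"mean"` (cohort mean over subjects) or `"all"` (every
#'   subject).
#' @return An object of class `voxel_mask`: logical 3D array `include`,
#'   integer `n_features`, and the `threshold` used.
#' @export
build_mask <- function(maps, threshold = 0.03, rule = c("mean", "all")) {
  rule <- match.arg(rule)
  if (length(maps) < 1L) stop("need at least one map")
  stopifnot(all(vapply(maps, inherits, logical(1L), "gm_map")))
  d <- dim(maps[[1L]]$values)
  if (!all(vapply(maps, function(m) identical(dim(m$values), d), logical(1L))))
    stop("all maps must share one grid shape")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  include <- switch(rule,
    mean = {
      acc <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
      acc >= threshold
    },
    all = Reduce(`&`, lapply(maps, function(m) m$values >= threshold)))
  structure(list(include = include, n_features = sum(include),
                 threshold = threshold, rule = rule,
                 voxel_size_mm = maps[[1L]]$voxel_size_mm),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("Voxel mask %s: %d/%d voxels included (threshold %.3g, %s rule)\n",
              paste(dim(x$include), collapse = "x"), x$n_features,
              length(x$include), x$threshold, x$rule))
  invisible(x)
}

#' Flatten masked volumes into a subjects-by-voxels feature matrix
#'
#' Row `i` holds the masked gray-matter probabilities of `cohort` subject
#' `i`; columns follow the package's fixed voxel ordering (R's native array
#' order: the first grid index varies fastest), so weight vectors can always
#' be folded back onto the grid.
#'
#' @param maps List of [gm_map()]s, one per cohort row, in cohort order.
#' @param mask A [build_mask()] result on the same grid.
#' @param cohort Optional cohort data.frame supplying `subject_id` rownames.
#' @return Numeric matrix `length(maps) x mask$n_features`.
#' @export
extract_features <- function(maps, mask, cohort = NULL) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!is.null(cohort) && nrow(cohort) != length(maps))
    stop("cohort and maps lengths differ")
  d <- dim(mask$include)
  idx <- which(mask$include)
  X <- matrix(NA_real_, nrow = length(maps), ncol = length(idx))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (!identical(dim(m$values), d)) stop("map grid differs from mask grid")
    X[i, ] <- m$values[idx]
  }
  if (!is.null(cohort)) rownames(X) <- cohort$subject_id
  X
}

## NIfTI I/O ---------------------------------------------------------------

#' Write / read gray-matter maps as NIfTI-1 volumes
#'
#' @param map A [gm_map()].
#' @param path File path, conventionally ending in `.nii` or `.nii.gz`.
#' @return `write_nifti_map`: `path` invisibly; `read_nifti_map`: a
#'   [gm_map()].
#' @export
write_nifti_map <- function(map, path) {
  stopifnot(inherits(map, "gm_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_map
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  v <- array(as.numeric(img), dim(img)[1:3])
  ## segmentation outputs are probabilities; tolerate tiny numeric spill
  v <- pmin(pmax(v, 0), 1)
  gm_map(v, RNifti::pixdim(img)[1:3])
}

#' Write a voxel mask as a 0/1 NIfTI volume
#' @param mask A [build_mask()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nifti_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  img <- RNifti::asNifti(array(as.numeric(mask$include), dim(mask$include)))
  RNifti::pixdim(img) <- mask$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
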