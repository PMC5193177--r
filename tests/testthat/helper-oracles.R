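## Independent oracles used across the suite. These deliberately share no
## code with the package internals they check.

## Soft-margin linear SVM via kernlab's interior-point QP solver (a code
## path independent of libsvm): solves the standard dual
##   max sum(a) - 1/2 a' (yy' . XX') a,  0 <= a <= C,  sum(a y) = 0
## y must be +-1.
qp_svm_oracle <- function(x, y, C) {
  n <- nrow(x)
  Q <- (y %*% t(y)) * tcrossprod(x)
  sol <- kernlab::ipop(c = rep(-1, n), H = Q + diag(1e-12, n),
                       A = matrix(y, 1L), b = 0, l = rep(0, n),
                       u = rep(C, n), r = 0, sigf = 14, maxiter = 1000)
  a <- kernlab::primal(sol)
  w <- as.numeric(t(x) %*% (a * y))
  on_margin <- which(a > 1e-6 * C & a < C * (1 - 1e-6))
  b <- mean(y[on_margin] - x[on_margin, , drop = FALSE] %*% w)
  list(w = w, b = b, alpha = a, support = which(a > 1e-6 * C))
}

## Brute-force 3D Gaussian convolution with mirror (half-sample symmetric)
## boundary handling, as explicit loops over the full 3D kernel.
reflect_index <- function(j, n) {
  j <- (j - 1L) %% (2L * n)
  if (j >= n) 2L * n - 1L - j + 1L else j + 1L
}
conv_oracle <- function(vol, sigmas_vox) {
  d <- dim(vol)
  k1 <- lapply(1:3, function(ax) {
    s <- sigmas_vox[ax]
    if (s <= 0) return(1)
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k / sum(k)
  })
  out <- array(0, d)
  rr <- vapply(k1, function(k) (length(k) - 1L) %/% 2L, integer(1L))
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) for (l in seq_len(d[3L])) {
    acc <- 0
    for (oi in -rr[1L]:rr[1L]) for (oj in -rr[2L]:rr[2L])
      for (ol in -rr[3L]:rr[3L]) {
        w <- k1[[1L]][oi + rr[1L] + 1L] * k1[[2L]][oj + rr[2L] + 1L] *
          k1[[3L]][ol + rr[3L] + 1L]
        acc <- acc + w * vol[reflect_index(i + oi, d[1L]),
                             reflect_index(j + oj, d[2L]),
                             reflect_index(l + ol, d[3L])]
      }
    out[i, j, l] <- acc
  }
  out
}

## Independently coded truth table of the illness-course clauses, driven by
## the sufficient statistics of a history (threshold fixed at 183 days).
course_oracle <- function(ep_durs, rem_durs) {
  long_rem <- length(rem_durs) > 0 && max(rem_durs) >= 183
  long_ep <- length(ep_durs) > 0 && max(ep_durs) > 183
  short_history <- length(ep_durs) == 0 ||
    (length(ep_durs) == 1 && ep_durs[1] <= 183)
  truth <- list(
    list(long_rem = TRUE,  long_ep = TRUE,  label = "excluded"),
    list(long_rem = TRUE,  long_ep = FALSE, label = "remitting"),
    list(long_rem = FALSE, short = TRUE,    label = "remitting"),
    list(long_rem = FALSE, short = FALSE,   label = "continuous"))
  for (row in truth) {
    if (!is.null(row$long_ep)) {
      if (row$long_rem == long_rem && row$long_ep == long_ep)
        return(row$label)
    } else if (row$long_rem == long_rem && row$short == short_history) {
      return(row$label)
    }
  }
  stop("truth table fell through")  # unreachable if the table is exhaustive
}

## Small two-site synthetic configuration used by several tests.
tiny_config <- function(seed, sex_effect = 0, course_effect = 0,
                        noise_sd = 0.05, per_cell = 5L,
                        sites = c("siteA", "siteB")) {
  grid <- c(16L, 16L, 16L)
  profs <- list(
    site_profile(sites[1L], 0, 1, noise_sd, 2),
    site_profile(sites[2L], 0.02, 1.05, noise_sd, 4))
  counts <- expand.grid(site = sites, sex = c("male", "female"),
                        course = c("continuous", "remitting"),
                        stringsAsFactors = FALSE)
  counts$n <- per_cell
  effects <- list()
  if (sex_effect != 0)
    effects <- c(effects, list(effect_map(
      "sex", cuboid_region(grid, c(10, 8, 7), c(13, 11, 9)), sex_effect)))
  if (course_effect != 0)
    effects <- c(effects, list(effect_map(
      "course", cuboid_region(grid, c(4, 5, 8), c(8, 9, 9)), course_effect)))
  synthetic_config(profs, counts, effects = effects, grid_shape = grid,
                   seed = seed)
}

## generate -> smooth -> mask -> features, returning cohort + matrix
prepare_features <- function(config, fwhm = 4, threshold = 0.03) {
  dat <- generate_cohort(config)
  sm <- lapply(dat$maps, gm_smooth, fwhm_mm = fwhm)
  mask <- build_mask(sm, threshold)
  list(cohort = dat$cohort, X = extract_features(sm, mask, dat$cohort),
       mask = mask)
}

## expand a per-site count table into a metadata-only cohort (no volumes)
cohort_from_counts <- function(counts) {
  idx <- rep(seq_len(nrow(counts)), counts$n)
  data.frame(subject_id = sprintf("S%04d", seq_along(idx)),
             site = counts$site[idx], sex = counts$sex[idx],
             course = counts$course[idx], stringsAsFactors = FALSE)
}
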