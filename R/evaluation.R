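## Resampling and inference: balanced subsampling, site-matched leave-two-out
## cross-validation, PPA/NPA and per-class accuracies, the bootstrap
## ensemble, and permutation significance testing.

## positive-class convention: fixes the PPA/NPA orientation of reports
default_positive <- function(class_field) {
  switch(class_field, sex = "male", course = "continuous",
         stop("no default positive class for field '", class_field,
              "'; supply positive_class"))
}

class_pair <- function(labels, class_field, positive_class = NULL) {
  lev <- unique(as.character(labels))
  if (length(lev) != 2L)
    stop("class field must take exactly two values, got: ",
         paste(lev, collapse = ", "))
  if (is.null(positive_class)) positive_class <- default_positive(class_field)
  if (!positive_class %in% lev)
    stop("positive class '", positive_class, "' absent from labels")
  c(setdiff(lev, positive_class), positive_class)
}

#' Draw a site-matched balanced subsample
#'
#' Builds a class-balanced cohort the way a balanced model-building sample
#' is drawn from an unbalanced multi-center pool: within each site, every
#' member of the (globally) minority class is kept, together with an
#' equally sized uniformly random subset of the majority class at that
#' site. If a site holds fewer majority-class members than minority ones,
#' all of them are kept and the deficit is drawn from the unused
#' majority-class members of the other sites, so the overall class counts
#' are exactly equal.
#'
#' @param cohort Cohort data.frame.
#' @param class_field Column name holding the two-level class (e.g. `"sex"`
#'   or `"course"`).
#' @param seed Integer seed for the random subset.
#' @param positive_class Optional; orientation only, does not affect the
#'   draw.
#' @return The subsampled cohort (original row order preserved).
#' @export
balanced_subsample <- function(cohort, class_field, seed,
                               positive_class = NULL) {
  labels <- as.character(cohort[[class_field]])
  cls <- class_pair(labels, class_field, positive_class)
  n_by <- table(factor(labels, levels = cls))
  minority <- cls[which.min(n_by)]
  majority <- setdiff(cls, minority)
  keep <- labels == minority
  deficit <- 0L
  leftover <- integer(0)
  with_seed(derive_seed(seed, "balance"), {
    for (s in unique(cohort$site)) {
      at_site <- cohort$site == s
      min_idx <- which(at_site & labels == minority)
      maj_idx <- which(at_site & labels == majority)
      take <- min(length(min_idx), length(maj_idx))
      sel <- maj_idx[sample.int(length(maj_idx))]
      keep[sel[seq_len(take)]] <- TRUE
      deficit <- deficit + (length(min_idx) - take)
      if (length(sel) > take)
        leftover <- c(leftover, sel[(take + 1L):length(sel)])
    }
    if (deficit > 0L) {
      if (length(leftover) < deficit)
        stop("not enough majority-class subjects to balance the cohort")
      leftover <- leftover[sample.int(length(leftover))]
      keep[leftover[seq_len(deficit)]] <- TRUE
    }
  })
  cohort[keep, , drop = FALSE]
}

#' Confusion counts and predictive accuracies
#'
#' `ppa = TP / (TP + FP)` and `npa = TN / (TN + FN)` (the predictive
#' accuracies of the positive and negative calls); per-class accuracies are
#' the sensitivity `TP / (TP + FN)` and specificity `TN / (TN + FP)` (e.g.
#' correctly classified males over all males). Zero denominators yield
#' `NA`, which propagates as "undefined" through averaging.
#'
#' @param confusion Named vector or list with `TP`, `FP`, `TN`, `FN`.
#' @return List with `ppa`, `npa`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' compute_metrics(c(TP = 3, FP = 1, TN = 4, FN = 2))
compute_metrics <- function(confusion) {
  cf <- as.list(confusion)
  rat <- function(a, b) if ((a + b) == 0) NA_real_ else a / (a + b)
  list(ppa = rat(cf$TP, cf$FP), npa = rat(cf$TN, cf$FN),
       sensitivity = rat(cf$TP, cf$FN), specificity = rat(cf$TN, cf$FP))
}

confusion_from_records <- function(true, pred, positive) {
  c(TP = sum(true == positive & pred == positive),
    FP = sum(true != positive & pred == positive),
    TN = sum(true != positive & pred != positive),
    FN = sum(true == positive & pred != positive))
}

#' Site-matched leave-two-out cross-validation
#'
#' Within each site, subjects of the two classes are randomly matched into
#' disjoint pairs (the held-out pair is always one subject of each class
#' from the same center). For every pair, the penalty C is selected by
#' nested inner cross-validation on all remaining subjects, a linear SVM is
#' trained on them, and the held-out pair's decision values and predicted
#' classes are recorded. Every pairable subject is tested exactly once per
#' run; subjects left unpaired at a site (class-count imbalance, or a site
#' holding only one class) stay in every training set but are never tested.
#'
#' The per-site pairing seed is derived from `seed` and the site label
#' alone, so dropping a site never changes the fold composition of the
#' others.
#'
#' @param cohort Cohort data.frame.
#' @param features Feature matrix, rows aligned with `cohort`.
#' @param class_field Cohort column with the two-level class.
#' @param c_grid Candidate C values for [select_C()] (a single value skips
#'   the inner loop).
#' @param seed Integer seed (pairing and inner folds).
#' @param positive_class Positive class label (defaults: `male` for sex,
#'   `continuous` for course).
#' @param inner_folds Inner folds for C selection (default 5).
#' @return Object of class `l2o_cv`: `per_subject` records (decision value,
#'   prediction, `times_tested`), `confusion`, `metrics`, `selected_C`
#'   values, and bookkeeping (`n_tested`, `n_unpaired`).
#' @export
leave_two_out_cv <- function(cohort, features, class_field, c_grid = 10^(-3:3),
                             seed = 1L, positive_class = NULL,
                             inner_folds = 5L) {
  features <- as.matrix(features)
  if (nrow(cohort) != nrow(features))
    stop("cohort rows and feature rows differ")
  labels <- as.character(cohort[[class_field]])
  cls <- class_pair(labels, class_field, positive_class)
  yfac <- factor(labels, levels = cls)
  ## pair subjects within site
  pairs <- list(); unpaired <- integer(0)
  for (s in unique(cohort$site)) {
    neg_idx <- which(cohort$site == s & labels == cls[1L])
    pos_idx <- which(cohort$site == s & labels == cls[2L])
    if (length(neg_idx) == 0L || length(pos_idx) == 0L)
      warning("site '", s, "' holds only one class; its subjects are ",
              "training-only")
    with_seed(derive_seed(seed, "pairing", s), {
      neg_idx <- neg_idx[sample.int(length(neg_idx))]
      pos_idx <- pos_idx[sample.int(length(pos_idx))]
    })
    np <- min(length(neg_idx), length(pos_idx))
    for (p in seq_len(np)) pairs[[length(pairs) + 1L]] <-
        c(neg_idx[p], pos_idx[p])
    if (length(neg_idx) > np)
      unpaired <- c(unpaired, neg_idx[(np + 1L):length(neg_idx)])
    if (length(pos_idx) > np)
      unpaired <- c(unpaired, pos_idx[(np + 1L):length(pos_idx)])
  }
  n <- nrow(cohort)
  ## all folds reuse one Gram matrix; libsvm then runs in Gram space, which
  ## is exactly equivalent for the linear kernel and far cheaper per fold
  G <- tcrossprod(features)
  dv <- rep(NA_real_, n); pred <- rep(NA_character_, n)
  tested <- integer(n); selC <- numeric(length(pairs))
  for (k in seq_along(pairs)) {
    hold <- pairs[[k]]
    tr <- setdiff(seq_len(n), hold)
    Ck <- if (length(c_grid) == 1L) c_grid else
      select_C_gram(G[tr, tr, drop = FALSE], yfac[tr], c_grid = c_grid,
                    inner_folds = inner_folds,
                    seed = derive_seed(seed, "inner", k))
    dvf <- gram_linsvm(G[tr, tr, drop = FALSE], yfac[tr], C = Ck)
    dv[hold] <- dvf(G[tr, hold, drop = FALSE])
    pred[hold] <- ifelse(dv[hold] >= 0, cls[2L], cls[1L])
    tested[hold] <- tested[hold] + 1L
    selC[k] <- Ck
  }
  ok <- tested > 0L
  confusion <- confusion_from_records(labels[ok], pred[ok], cls[2L])
  pair_tab <- if (length(pairs)) data.frame(
    site = cohort$site[vapply(pairs, `[`, integer(1L), 1L)],
    negative_id = cohort$subject_id[vapply(pairs, `[`, integer(1L), 1L)],
    positive_id = cohort$subject_id[vapply(pairs, `[`, integer(1L), 2L)],
    stringsAsFactors = FALSE) else
    data.frame(site = character(0), negative_id = character(0),
               positive_id = character(0), stringsAsFactors = FALSE)
  structure(list(
    pairs = pair_tab,
    per_subject = data.frame(subject_id = cohort$subject_id,
                             site = cohort$site, true_label = labels,
                             decision_value = dv, predicted_label = pred,
                             times_tested = tested, stringsAsFactors = FALSE),
    confusion = confusion, metrics = compute_metrics(confusion),
    class_labels = cls, selected_C = selC,
    n_tested = sum(ok), n_unpaired = length(unpaired), seed = seed),
    class = "l2o_cv")
}

#' @export
print.l2o_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Leave-two-out CV: %d subjects tested (%d unpaired)\n",
              x$n_tested, x$n_unpaired))
  cat(sprintf("  classes: %s (-) vs %s (+)\n", x$class_labels[1L],
              x$class_labels[2L]))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n", x$confusion["TP"],
              x$confusion["FP"], x$confusion["TN"], x$confusion["FN"]))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, PPA %s, NPA %s\n",
              m$sensitivity, m$specificity,
              formatC(m$ppa, digits = 3, format = "f"),
              formatC(m$npa, digits = 3, format = "f")))
  invisible(x)
}

per_site_confusions <- function(cv) {
  ps <- cv$per_subject[cv$per_subject$times_tested > 0L, , drop = FALSE]
  lapply(split(ps, ps$site), function(d)
    confusion_from_records(d$true_label, d$predicted_label,
                           cv$class_labels[2L]))
}

#' Bootstrap ensemble of balanced leave-two-out runs
#'
#' Repeats, `n_bootstraps` times with independently derived seeds: draw a
#' site-matched balanced subsample, then run a completely independent
#' site-matched leave-two-out cross-validation on it. Reported predictive
#' values are arithmetic means over the runs (overall and per site),
#' averaging only runs where a metric is defined.
#'
#' @inheritParams leave_two_out_cv
#' @param n_bootstraps Number of repetitions (>= 1; 100 for headline runs).
#' @param seed Master seed; run `r` uses seeds derived from `(seed, r)`.
#' @return Object of class `svm_ensemble`: `per_bootstrap` (list of
#'   [leave_two_out_cv()] results), `mean_metrics`, `per_site` mean-metric
#'   table, and the pooled per-subject mean decision values.
#' @export
bootstrap_ensemble <- function(cohort, features, class_field,
                               n_bootstraps = 100L, c_grid = 10^(-3:3),
                               seed = 1L, positive_class = NULL,
                               inner_folds = 5L) {
  if (n_bootstraps < 1L) stop("n_bootstraps must be >= 1")
  features <- as.matrix(features)
  runs <- vector("list", n_bootstraps)
  for (r in seq_len(n_bootstraps)) {
    rs <- derive_seed(seed, "bootstrap", r)
    sub <- balanced_subsample(cohort, class_field, seed = rs,
                              positive_class = positive_class)
    rows <- match(sub$subject_id, cohort$subject_id)
    runs[[r]] <- leave_two_out_cv(sub, features[rows, , drop = FALSE],
                                  class_field, c_grid = c_grid, seed = rs,
                                  positive_class = positive_class,
                                  inner_folds = inner_folds)
  }
  metric_names <- c("ppa", "npa", "sensitivity", "specificity")
  mean_def <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  mean_metrics <- sapply(metric_names, function(mn)
    mean_def(vapply(runs, function(cv) cv$metrics[[mn]], numeric(1L))))
  ## per-site mean metrics
  sites <- unique(cohort$site)
  per_site <- do.call(rbind, lapply(sites, function(s) {
    vals <- sapply(metric_names, function(mn)
      mean_def(vapply(runs, function(cv) {
        cfs <- per_site_confusions(cv)
        if (is.null(cfs[[s]])) NA_real_ else compute_metrics(cfs[[s]])[[mn]]
      }, numeric(1L))))
    data.frame(site = s, t(vals), stringsAsFactors = FALSE)
  }))
  ## pooled per-subject mean decision value across the runs testing them
  all_ps <- do.call(rbind, lapply(runs, function(cv)
    cv$per_subject[cv$per_subject$times_tested > 0L, , drop = FALSE]))
  dv_mean <- aggregate(decision_value ~ subject_id + site + true_label,
                       data = all_ps, FUN = mean)
  times <- aggregate(times_tested ~ subject_id, data = all_ps, FUN = sum)
  dv_mean <- merge(dv_mean, times, by = "subject_id", sort = FALSE)
  structure(list(n_bootstraps = n_bootstraps, per_bootstrap = runs,
                 mean_metrics = as.list(mean_metrics), per_site = per_site,
                 decision_values = dv_mean,
                 class_labels = runs[[1L]]$class_labels, seed = seed),
            class = "svm_ensemble")
}

#' @export
print.svm_ensemble <- function(x, ...) {
  m <- x$mean_metrics
  cat(sprintf("Bootstrap ensemble of %d balanced leave-two-out runs\n",
              x$n_bootstraps))
  cat(sprintf("  classes: %s (-) vs %s (+)\n", x$class_labels[1L],
              x$class_labels[2L]))
  cat(sprintf("  mean sensitivity %.3f, specificity %.3f, PPA %.3f, NPA %.3f\n",
              m$sensitivity, m$specificity, m$ppa, m$npa))
  invisible(x)
}

#' @export
summary.svm_ensemble <- function(object, ...) {
  cat(sprintf("Bootstrap ensemble (%d runs), positive class '%s'\n\n",
              object$n_bootstraps, object$class_labels[2L]))
  tab <- rbind(object$per_site,
               data.frame(site = "Overall", ppa = object$mean_metrics$ppa,
                          npa = object$mean_metrics$npa,
                          sensitivity = object$mean_metrics$sensitivity,
                          specificity = object$mean_metrics$specificity))
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(tab)
}

#' Decision-value strip plot of an ensemble
#'
#' Plots each tested subject's mean decision value, one horizontal band per
#' site, plotting symbol by true class; the vertical line at zero is the
#' decision boundary, so positive-class subjects should fall right of it.
#'
#' @param x A [bootstrap_ensemble()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.svm_ensemble <- function(x, ...) {
  dv <- x$decision_values
  sites <- sort(unique(dv$site))
  ypos <- match(dv$site, sites) + ifelse(dv$true_label == x$class_labels[2L],
                                         0.15, -0.15)
  pch <- ifelse(dv$true_label == x$class_labels[2L], 16L, 2L)
  plot(dv$decision_value, ypos, pch = pch, yaxt = "n",
       xlab = "mean decision value (w.x + b)", ylab = "",
       main = "Per-subject decision values by site", ...)
  axis(2L, at = seq_along(sites), labels = sites, las = 1L)
  abline(v = 0)
  legend("topleft", pch = c(2L, 16L), bty = "n",
         legend = paste(x$class_labels, c("(-)", "(+)")))
  invisible(x)
}

#' Export per-subject decision values as TSV
#'
#' @param x An `svm_ensemble` or `l2o_cv` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_decision_values <- function(x, path) {
  dv <- if (inherits(x, "svm_ensemble")) x$decision_values
        else x$per_subject[x$per_subject$times_tested > 0L, , drop = FALSE]
  write.table(dv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Permutation significance test of the classification pipeline
#'
#' Re-runs the full balanced-subsample + leave-two-out pipeline under class
#' labels permuted within site, `n_permutations` times, and counts null
#' metrics greater than or equal to the observed one; the p-value is that
#' count divided by `n_permutations` (the plain estimator, so `p = 0` is
#' representable; `smoothed = TRUE` uses `(count + 1) / (n + 1)`).
#' Permutations reuse the observed pipeline's seed stream, so only the
#' labels differ between the observed run and each null run.
#'
#' @inheritParams bootstrap_ensemble
#' @param n_permutations Number of label permutations (>= 1; 1000 for
#'   headline runs).
#' @param metric Metric compared between observed and null runs:
#'   `"balanced_accuracy"` (mean of the two per-class accuracies, default),
#'   `"ppa"`, `"npa"`, `"sensitivity"`, or `"specificity"`.
#' @param smoothed Use the add-one p-value estimator (default `FALSE`).
#' @return Object of class `perm_test`: `observed`, `null_values`,
#'   `p_value`, plus the observed ensemble.
#' @export
permutation_test <- function(cohort, features, class_field,
                             n_permutations = 1000L, n_bootstraps = 1L,
                             c_grid = 10^(-3:3), seed = 1L,
                             positive_class = NULL, inner_folds = 5L,
                             metric = "balanced_accuracy", smoothed = FALSE) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  features <- as.matrix(features)
  metric_of <- function(ens) {
    m <- ens$mean_metrics
    switch(metric,
           balanced_accuracy = mean(c(m$sensitivity, m$specificity)),
           ppa = m$ppa, npa = m$npa, sensitivity = m$sensitivity,
           specificity = m$specificity,
           stop("unknown metric '", metric, "'"))
  }
  run <- function(coh) bootstrap_ensemble(coh, features, class_field,
                                          n_bootstraps = n_bootstraps,
                                          c_grid = c_grid, seed = seed,
                                          positive_class = positive_class,
                                          inner_folds = inner_folds)
  observed_ens <- run(cohort)
  observed <- metric_of(observed_ens)
  null_values <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    perm <- cohort
    with_seed(derive_seed(seed, "perm", p), {
      for (s in unique(perm$site)) {
        at <- which(perm$site == s)
        perm[[class_field]][at] <-
          perm[[class_field]][at][sample.int(length(at))]
      }
    })
    null_values[p] <- metric_of(run(perm))
  }
  cnt <- sum(null_values >= observed)
  p_value <- if (smoothed) (cnt + 1) / (n_permutations + 1)
             else cnt / n_permutations
  structure(list(observed = observed, null_values = null_values,
                 p_value = p_value, metric = metric,
                 n_permutations = n_permutations, smoothed = smoothed,
                 ensemble = observed_ens),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations, metric: %s)\n",
              x$n_permutations, x$metric))
  cat(sprintf("  observed %.4f, null mean %.4f, p = %.4g\n",
              x$observed, mean(x$null_values), x$p_value))
  invisible(x)
}
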