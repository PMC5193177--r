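make_cohort <- function(site, sex, course = "excluded") {
  data.frame(subject_id = sprintf("s%03d", seq_along(site)), site = site,
             sex = sex, course = course, stringsAsFactors = FALSE)
}

test_that("balanced subsampling keeps the minority class and matches per site", {
  # a site like Utrecht's 58 males / 9 females
  cohort <- make_cohort(rep("U", 67), rep(c("male", "female"), c(58, 9)))
  sub <- balanced_subsample(cohort, "sex", seed = 1)
  expect_equal(sum(sub$sex == "female"), 9L)
  expect_equal(sum(sub$sex == "male"), 9L)
  # an already balanced cohort comes back unchanged
  cohort2 <- make_cohort(rep(c("A", "B"), each = 6),
                         rep(c("male", "female"), 6))
  sub2 <- balanced_subsample(cohort2, "sex", seed = 5)
  expect_setequal(sub2$subject_id, cohort2$subject_id)
  # one class globally empty errors
  expect_error(balanced_subsample(make_cohort(rep("A", 4), rep("male", 4)),
                                  "sex", 1), "exactly two")
})

test_that("every majority member at a site is eventually sampled", {
  cohort <- make_cohort(rep("A", 9), rep(c("male", "female"), c(6, 3)))
  seen <- character(0)
  for (s in 1:200) {
    sub <- balanced_subsample(cohort, "sex", seed = s)
    expect_equal(sum(sub$sex == "male"), 3L)
    seen <- union(seen, sub$subject_id[sub$sex == "male"])
  }
  expect_setequal(seen, cohort$subject_id[cohort$sex == "male"])
})

test_that("a site short of majority subjects borrows the deficit elsewhere", {
  # site A: 5 female / 2 male; site B: 3 female / 8 male; minority = female
  cohort <- make_cohort(rep(c("A", "B"), c(7, 11)),
                        c(rep("female", 5), rep("male", 2),
                          rep("female", 3), rep("male", 8)))
  sub <- balanced_subsample(cohort, "sex", seed = 3)
  expect_equal(sum(sub$sex == "female"), 8L)
  expect_equal(sum(sub$sex == "male"), 8L)
  # all of A's two males must be in, plus six from B
  expect_true(all(c("s006", "s007") %in% sub$subject_id))
  expect_equal(sum(sub$site == "B" & sub$sex == "male"), 6L)
})

test_that("predictive accuracies follow the confusion-count formulas", {
  m <- compute_metrics(c(TP = 3, FP = 1, TN = 4, FN = 2))
  expect_equal(m$ppa, 0.75)
  expect_equal(m$npa, 4 / 6)
  expect_equal(m$sensitivity, 3 / 5)
  expect_equal(m$specificity, 4 / 5)
  expect_equal(compute_metrics(c(TP = 2, FP = 0, TN = 1, FN = 1))$ppa, 1)
  # zero denominator is undefined, not zero and not an error
  expect_true(is.na(compute_metrics(c(TP = 0, FP = 0, TN = 3, FN = 1))$ppa))
})

test_that("leave-two-out folds test each pairable subject exactly once", {
  set.seed(2)
  cohort <- make_cohort(rep("A", 6), rep(c("male", "female"), 3))
  X <- matrix(rnorm(6 * 5), 6, 5)
  cv <- leave_two_out_cv(cohort, X, "sex", c_grid = 1, seed = 4)
  expect_equal(nrow(cv$pairs), 3L)
  expect_equal(cv$per_subject$times_tested, rep(1L, 6))
  expect_equal(cv$n_unpaired, 0L)
  expect_equal(sum(cv$confusion), 6)
  # confusion equals a brute-force recount from the per-subject records
  ps <- cv$per_subject
  expect_equal(unname(cv$confusion["TP"]),
               sum(ps$true_label == "male" & ps$predicted_label == "male"))
  expect_equal(unname(cv$confusion["FN"]),
               sum(ps$true_label == "male" & ps$predicted_label == "female"))
  # a single-class site is warned about and kept training-only
  cohort2 <- rbind(cohort, make_cohort(rep("B", 2), rep("male", 2)))
  cohort2$subject_id <- sprintf("s%03d", 1:8)
  expect_warning(cv2 <- leave_two_out_cv(cohort2, rbind(X, X[1:2, ]), "sex",
                                         c_grid = 1, seed = 4),
                 "only one class")
  expect_equal(cv2$n_unpaired, 2L)
  expect_equal(cv2$per_subject$times_tested[7:8], c(0L, 0L))
})

test_that("dropping a site leaves the other sites' pairings untouched", {
  set.seed(6)
  cohort <- make_cohort(rep(c("A", "B", "C"), each = 8),
                        rep(c("male", "female"), 12))
  X <- matrix(rnorm(24 * 6), 24, 6)
  cv_all <- leave_two_out_cv(cohort, X, "sex", c_grid = 1, seed = 9)
  keep <- cohort$site != "C"
  cv_ab <- leave_two_out_cv(cohort[keep, ], X[keep, ], "sex", c_grid = 1,
                            seed = 9)
  pa <- cv_all$pairs[cv_all$pairs$site != "C", ]
  pb <- cv_ab$pairs
  expect_equal(pa[order(pa$negative_id), c("negative_id", "positive_id")],
               pb[order(pb$negative_id), c("negative_id", "positive_id")],
               ignore_attr = TRUE)
})

test_that("the ensemble averages runs and is seed-deterministic", {
  cfg <- tiny_config(seed = 31, sex_effect = 1.5, per_cell = 3L)
  prep <- prepare_features(cfg)
  e1 <- bootstrap_ensemble(prep$cohort, prep$X, "sex", n_bootstraps = 1L,
                           c_grid = 1, seed = 11)
  expect_equal(e1$mean_metrics$sensitivity,
               e1$per_bootstrap[[1]]$metrics$sensitivity)
  e3 <- bootstrap_ensemble(prep$cohort, prep$X, "sex", n_bootstraps = 3L,
                           c_grid = 1, seed = 11)
  sens <- vapply(e3$per_bootstrap, function(cv) cv$metrics$sensitivity,
                 numeric(1L))
  expect_equal(e3$mean_metrics$sensitivity, mean(sens))
  e3b <- bootstrap_ensemble(prep$cohort, prep$X, "sex", n_bootstraps = 3L,
                            c_grid = 1, seed = 11)
  expect_identical(e3$mean_metrics, e3b$mean_metrics)
  expect_identical(e3$decision_values, e3b$decision_values)
  # per-site rows exist for both sites
  expect_setequal(e3$per_site$site, c("siteA", "siteB"))
})

test_that("permutation p-values implement the plain counting estimator", {
  cfg <- tiny_config(seed = 41, sex_effect = 3, per_cell = 3L)
  prep <- prepare_features(cfg)
  pt <- permutation_test(prep$cohort, prep$X, "sex", n_permutations = 20L,
                         n_bootstraps = 1L, c_grid = 1, seed = 13)
  expect_equal(pt$p_value, mean(pt$null_values >= pt$observed))
  expect_equal(length(pt$null_values), 20L)
  expect_gte(pt$p_value, 0); expect_lte(pt$p_value, 1)
  # the smoothed variant adds one to numerator and denominator
  pt2 <- permutation_test(prep$cohort, prep$X, "sex", n_permutations = 10L,
                          n_bootstraps = 1L, c_grid = 1, seed = 13,
                          smoothed = TRUE)
  expect_equal(pt2$p_value,
               (sum(pt2$null_values >= pt2$observed) + 1) / 11)
})
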