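test_that("compute_metrics reproduces the percentage definitions", {
  m <- compute_metrics(tp = 57, fp = 10, tn = 54, fn = 6)
  expect_equal(round_half_up(m$accuracy), 87.40)
  expect_equal(round_half_up(m$sensitivity), 90.48)
  expect_equal(round_half_up(m$specificity), 84.38)
  m0 <- compute_metrics(tp = 0, fp = 0, tn = 64, fn = 63)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 100)
  m5 <- compute_metrics(1, 1, 1, 1)
  expect_equal(unlist(m5), c(accuracy = 50, sensitivity = 50, specificity = 50))
  expect_error(compute_metrics(0, 0, 0, 0), "no evaluated")
  expect_error(compute_metrics(0, 5, 5, 0), "sensitivity")
  expect_error(compute_metrics(5, 0, 0, 5), "specificity")
})

test_that("roc_auc handles separation, ties, and matches pair counting", {
  sep <- roc_auc(c(3, 2, 1, -1, -2), c(1, 1, 1, -1, -1))
  expect_equal(sep$auc, 1.0)
  ties <- roc_auc(rep(0, 6), c(1, -1, 1, -1, 1, -1))
  expect_equal(ties$auc, 0.5)
  set.seed(1)
  for (r in 1:10) {
    s <- round(rnorm(8), 1)                      # coarse grid forces ties
    y <- sample(c(rep(1, 4), rep(-1, 4)))
    got <- roc_auc(s, y)
    expect_equal(got$auc, oracle_auc(s, y), tolerance = 1e-12)
    expect_true(all(diff(got$roc_points$fpr) >= 0))
    expect_true(all(diff(got$roc_points$tpr) >= 0))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("delong_test: identical scores give p = 1, reversal is maximal", {
  y <- rep(c(1, -1), each = 10)
  set.seed(2)
  s <- rnorm(20) + (y == 1)
  d0 <- delong_test(s, s, y)
  expect_identical(d0$z, 0)
  expect_identical(d0$p, 1)
  ssep <- ifelse(y == 1, abs(s) + 1, -abs(s) - 1)
  d1 <- delong_test(ssep, -ssep, y)
  expect_equal(abs(d1$auc_a - d1$auc_b), 1)
  expect_lt(d1$p, 1e-4)
  expect_error(delong_test(s[-1], s, y), "align")
})

test_that("delong_test p agrees with a bootstrap-variance oracle", {
  # two correlated noisy score vectors; the DeLong variance of the AUC
  # difference should match a label-preserving bootstrap estimate, hence
  # similar normal p. Cross-method agreement tolerance 0.05 absolute.
  set.seed(7)
  n <- 60
  y <- rep(c(1, -1), each = n / 2)
  base <- rnorm(n) + 0.9 * (y == 1)
  sa <- base + rnorm(n, sd = 0.6)
  sb <- base + rnorm(n, sd = 0.9)
  dl <- delong_test(sa, sb, y)
  B <- 10000
  set.seed(8)
  diffs <- replicate(B, {
    ip <- sample(which(y == 1), replace = TRUE)
    im <- sample(which(y == -1), replace = TRUE)
    idx <- c(ip, im)
    roc_auc(sa[idx], y[idx])$auc - roc_auc(sb[idx], y[idx])$auc
  })
  z_boot <- (dl$auc_a - dl$auc_b) / sd(diffs)
  p_boot <- 2 * pnorm(-abs(z_boot))
  expect_lt(abs(dl$p - p_boot), 0.05)
})

test_that("ttest_select keeps null features at the nominal rate and obvious ones always", {
  set.seed(3)
  y <- rep(c(1, -1), each = 30)
  F <- matrix(rnorm(60 * 500), 60, 500)
  sel <- ttest_select(F, y, alpha = 0.05)
  frac <- length(sel) / 500
  ci <- 0.05 + c(-1.96, 1.96) * sqrt(0.05 * 0.95 / 500)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
  strong <- cbind(ifelse(y == 1, 1, -1) + rnorm(60, sd = 0.1), F[, 1:5])
  expect_true(1 %in% ttest_select(strong, y, 0.05))
  expect_equal(ttest_select(F, y, alpha = 1), seq_len(500), ignore_attr = TRUE)
  Fz <- cbind(F[, 1:3], 0)
  sel2 <- ttest_select(Fz, y, 0.05)
  expect_equal(attr(sel2, "excluded"), 4L)
})

test_that("ttest_select agrees with per-column t.test p-values", {
  set.seed(4)
  y <- rep(c(1, -1), each = 8)
  F <- matrix(rnorm(16 * 40), 16, 40)
  pvals <- apply(F, 2, function(col)
    t.test(col[y == 1], col[y == -1])$p.value)
  expect_equal(sort(ttest_select(F, y, 0.2)), sort(which(pvals < 0.2)),
               ignore_attr = TRUE)
})

test_that("nested_loocv produces one fold per subject and a consistent report", {
  co <- tiny_cohort(51, n_per_group = 6, n_rois = 8, t = 60)
  rep <- nested_loocv(co$subjects, co$labels, patterns = "PC")
  expect_named(rep, "PC")
  r <- rep$PC
  expect_length(r$decision_values, 12)
  expect_length(r$per_fold_chosen_params, 12)
  expect_length(r$per_fold_selected_features, 12)
  conf <- r$confusion
  expect_equal(conf$tp + conf$fp + conf$tn + conf$fn, 12)
  m <- compute_metrics(conf)
  expect_equal(r$accuracy, m$accuracy)
  expect_equal(r$auc, oracle_auc(r$decision_values, co$labels), tolerance = 1e-12)
})

test_that("all seven method rows appear with three patterns", {
  co <- tiny_cohort(52, n_per_group = 4, n_rois = 6, t = 50)
  rep <- nested_loocv(co$subjects, co$labels)
  expect_named(rep, c("PC", "SR", "GCM", "PC + SR", "PC + GCM", "SR + GCM", "MCPC"))
  tab <- report_table(rep)
  expect_equal(nrow(tab), 7)
})

test_that("the held-out subject cannot influence its own training fold", {
  co <- tiny_cohort(53, n_per_group = 5, n_rois = 6, t = 60)
  rep1 <- nested_loocv(co$subjects, co$labels, patterns = "PC")
  k <- 3
  co2 <- co
  sig <- co2$subjects[[k]]$signal
  set.seed(99)
  co2$subjects[[k]] <- subject_ts(co2$subjects[[k]]$subject_id,
                                  matrix(rnorm(length(sig)), nrow(sig)))
  rep2 <- nested_loocv(co2$subjects, co2$labels, patterns = "PC")
  # fold k's selected features and hyperparameters are untouched
  expect_identical(rep1$PC$per_fold_selected_features[[k]],
                   rep2$PC$per_fold_selected_features[[k]])
  expect_identical(rep1$PC$per_fold_chosen_params[[k]]$C,
                   rep2$PC$per_fold_chosen_params[[k]]$C)
  # other folds saw a changed training set, so their models may differ;
  # only fold k's prediction is allowed to change through the test row
})

test_that("per-fold lambda selection mode runs and records lambda", {
  co <- tiny_cohort(54, n_per_group = 4, n_rois = 5, t = 40)
  cv <- cv_config(lam_mode = "cv", lam_grid = 2^c(0, 3), c_grid = 2^c(-1, 1))
  rep <- nested_loocv(co$subjects, co$labels, patterns = "SR", cv = cv)
  lams <- vapply(rep$SR$per_fold_chosen_params, function(p) p$lam, 0)
  expect_true(all(lams %in% 2^c(0, 3)))
})

test_that("input validation catches bad labels and patterns", {
  co <- tiny_cohort(55, n_per_group = 3, n_rois = 5, t = 40)
  expect_error(nested_loocv(co$subjects, rep(1, 6), "PC"), "both classes")
  expect_error(nested_loocv(co$subjects, co$labels, "XX"), "patterns")
  expect_error(nested_loocv(co$subjects[1:3], co$labels[1:3], "PC"), "at least 4")
})
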