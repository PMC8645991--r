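#' Cross-validation configuration
#'
#' Settings for the nested leave-one-out protocol: the SVM cost grid, the
#' sparse-representation penalty (fixed at the protocol default `2^3`, or
#' re-chosen per fold from `lam_grid` when `lam_mode = "cv"`), the per-fold
#' feature-selection filter, and the connectivity options.
#'
#' @param c_grid SVM cost candidates (default `2^-5 .. 2^5`).
#' @param lam_grid SR penalty candidates for `lam_mode = "cv"`.
#' @param lam fixed SR penalty used when `lam_mode = "fixed"`.
#' @param lam_mode `"fixed"` (default) or `"cv"` (inner-LOOCV choice).
#' @param feature_selection `"ttest"` (two-sample t-test filter, default)
#'   or `"none"`.
#' @param ttest_alpha selection threshold in (0, 1).
#' @param sr_symmetrize symmetrize SR matrices before vectorization.
#' @param gcm_lag Granger lag order.
#' @param standardize z-score features with training-fold statistics.
#' @param seed integer seed recorded with the run.
#' @return an object of class `cv_config`.
#' @export
cv_config <- function(c_grid = 2^(-5:5), lam_grid = 2^(-5:5), lam = 2^3,
                      lam_mode = c("fixed", "cv"),
                      feature_selection = c("ttest", "none"),
                      ttest_alpha = 0.05, sr_symmetrize = TRUE, gcm_lag = 1L,
                      standardize = TRUE, seed = 1L) {
  lam_mode <- match.arg(lam_mode)
  feature_selection <- match.arg(feature_selection)
  if (length(c_grid) < 1 || any(c_grid <= 0)) stop_mcpc("c_grid must be positive")
  if (length(lam_grid) < 1 || any(lam_grid < 0)) stop_mcpc("lam_grid must be nonnegative")
  if (!(ttest_alpha > 0 && ttest_alpha <= 1)) stop_mcpc("ttest_alpha must be in (0, 1]")
  structure(list(c_grid = sort(c_grid), lam_grid = sort(lam_grid), lam = lam,
                 lam_mode = lam_mode, feature_selection = feature_selection,
                 ttest_alpha = ttest_alpha, sr_symmetrize = sr_symmetrize,
                 gcm_lag = as.integer(gcm_lag), standardize = standardize,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`, returned as unrounded percentages (round only
#' at presentation).
#'
#' @param tp,fp,tn,fn nonnegative integer counts, or a single list with
#'   those fields passed as `tp`.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent).
#' @export
compute_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; tn <- tp$tn; fn <- tp$fn; tp <- tp$tp }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_mcpc("confusion counts must be nonnegative integers")
  if (sum(counts) == 0) stop_mcpc("undefined metric: no evaluated subjects")
  if (tp + fn == 0) stop_mcpc("undefined sensitivity: no positive subjects")
  if (tn + fp == 0) stop_mcpc("undefined specificity: no negative subjects")
  list(accuracy = 100 * (tp + tn) / sum(counts),
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp))
}

#' ROC curve and AUC from continuous decision values
#'
#' The ROC is traced by sweeping a threshold over the unique decision
#' values; the AUC is the probability that a random positive outranks a
#' random negative, ties counted 1/2 (the rank / Mann-Whitney
#' formulation).
#'
#' @param decision_values numeric scores (larger = more positive).
#' @param labels +1/-1 vector.
#' @return list with `roc_points` (data.frame fpr, tpr) and `auc`.
#' @export
roc_auc <- function(decision_values, labels) {
  labels <- as.numeric(labels)
  if (length(decision_values) != length(labels)) stop_mcpc("length mismatch")
  npos <- sum(labels == 1); nneg <- sum(labels == -1)
  if (npos == 0 || nneg == 0) stop_mcpc("both classes must be present")
  r <- rank(decision_values, ties.method = "average")
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  ord <- order(decision_values, decreasing = TRUE)
  s <- decision_values[ord]; y <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)   # last point of each tied block
  tpr <- cumsum(y == 1)[keep] / npos
  fpr <- cumsum(y == -1)[keep] / nneg
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  list(roc_points = roc, auc = auc)
}

delong_placements <- function(scores, labels) {
  X <- scores[labels == 1]; Y <- scores[labels == -1]
  cmp <- outer(X, Y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors over the same
#' subjects, using the placement-value covariance estimate and a two-sided
#' normal reference. Identical score vectors give `z = 0`, `p = 1` exactly.
#'
#' @param scores_a,scores_b decision values aligned to `labels`.
#' @param labels +1/-1 vector.
#' @return list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.numeric(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop_mcpc("score vectors must align with labels")
  if (!all(labels %in% c(-1, 1)) || length(unique(labels)) < 2)
    stop_mcpc("labels must contain both classes as +1/-1")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels == 1); n <- sum(labels == -1)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  z <- if (var_diff <= 0) {
    if (d == 0) 0 else sign(d) * Inf   # degenerate variance, unequal AUCs
  } else d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-sample t-test feature filter
#'
#' Selects the columns of `features` whose Welch two-sample t-test between
#' the label groups has `p < alpha`, using only the supplied (training)
#' subjects. Zero-variance columns are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @param features n x d numeric matrix.
#' @param labels +1/-1 vector of length n.
#' @param alpha threshold; `alpha >= 1` selects every valid feature.
#' @return integer vector of selected column indices.
#' @export
ttest_select <- function(features, labels, alpha = 0.05) {
  labels <- as.numeric(labels)
  g1 <- labels == 1; g2 <- labels == -1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop_mcpc("each class needs at least 2 subjects")
  m1 <- colMeans(features[g1, , drop = FALSE])
  m2 <- colMeans(features[g2, , drop = FALSE])
  v1 <- apply(features[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(features[g2, , drop = FALSE], 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  valid <- se2 > 0
  sel <- if (alpha >= 1) {
    which(valid)
  } else {
    tstat <- (m1 - m2)[valid] / sqrt(se2[valid])
    df <- se2[valid]^2 / ((v1[valid] / n1)^2 / (n1 - 1) + (v2[valid] / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    which(valid)[p < alpha]
  }
  attr(sel, "excluded") <- which(!valid)
  sel
}

pattern_key <- function(p) toupper(p)

method_table <- function(patterns) {
  patterns <- pattern_key(patterns)
  methods <- lapply(seq_along(patterns), function(k) patterns[k])
  if (length(patterns) >= 2) {
    cmb <- utils::combn(patterns, 2, simplify = FALSE)
    methods <- c(methods, cmb)
  }
  if (length(patterns) >= 3)
    methods <- c(methods, list(patterns))
  names(methods) <- vapply(methods, function(ps) {
    if (length(ps) == length(patterns) && length(patterns) >= 3) "MCPC"
    else paste(ps, collapse = " + ")
  }, "")
  methods
}

compute_pattern_matrices <- function(subjects, patterns, cv) {
  out <- list()
  for (p in pattern_key(patterns)) {
    cms <- switch(p,
      PC = lapply(subjects, pearson_network),
      SR = lapply(subjects, sr_network, lam = cv$lam,
                  symmetrize = cv$sr_symmetrize),
      GCM = lapply(subjects, gcm_network, p = cv$gcm_lag),
      stop_mcpc(sprintf("unknown pattern '%s'", p)))
    out[[p]] <- pattern_features(cms)
  }
  out
}

# z-score columns by training statistics; returns train/test matrices and
# the set of usable (nonconstant-on-train) columns
standardize_features <- function(M, train_idx, standardize) {
  tr <- M[train_idx, , drop = FALSE]
  mu <- colMeans(tr)
  sdev <- apply(tr, 2, stats::sd)
  valid <- which(sdev > 0)
  if (standardize) {
    Z <- sweep(sweep(M[, valid, drop = FALSE], 2, mu[valid]), 2, sdev[valid], "/")
  } else {
    Z <- M[, valid, drop = FALSE]
  }
  list(Z = Z, valid = valid)
}

#' Nested leave-one-out cross-validation over connection-pattern methods
#'
#' Runs the full evaluation protocol: each subject is held out once; the
#' two-sample t-test feature filter, feature standardization statistics,
#' and the SVM cost C (chosen by an inner leave-one-out grid search over
#' `cv$c_grid`, ties toward the smallest C) are computed strictly from the
#' remaining training subjects. For multi-kernel methods the kernel
#' weights beta are learned on each training fold by SimpleMKL (once per
#' candidate C, with the inner folds re-fitting only the SVM dual at fixed
#' beta). Decision values, per-fold selected features and chosen
#' hyperparameters are recorded; confusion counts aggregate over the outer
#' folds.
#'
#' @param subjects list of [subject_ts()] objects.
#' @param labels +1/-1 vector (+1 = patient analog, the positive class).
#' @param patterns connection patterns to estimate, subset of
#'   `c("PC", "SR", "GCM")`.
#' @param cv a [cv_config()].
#' @param methods optional character vector restricting which method rows
#'   to evaluate (e.g. `"MCPC"`); default all singles, pairs and the full
#'   combination.
#' @param progress print per-fold progress.
#' @param precomputed optional precomputed per-pattern feature list (as
#'   built internally), to avoid re-estimating connectivity.
#' @return named list of `evaluation_report` objects, one per method, with
#'   attributes `feature_index` (per pattern) and `labels`.
#' @export
nested_loocv <- function(subjects, labels, patterns = c("PC", "SR", "GCM"),
                         cv = cv_config(), methods = NULL, progress = FALSE,
                         precomputed = NULL) {
  labels <- as.numeric(labels)
  n <- length(subjects)
  if (n < 4) stop_mcpc("need at least 4 subjects")
  if (length(labels) != n || !all(labels %in% c(-1, 1)))
    stop_mcpc("labels must be +1/-1, one per subject")
  if (length(unique(labels)) < 2) stop_mcpc("both classes must be present")
  patterns <- pattern_key(patterns)
  if (length(patterns) < 1 || !all(patterns %in% c("PC", "SR", "GCM")))
    stop_mcpc("patterns must be a non-empty subset of PC, SR, GCM")

  feats <- precomputed %||% compute_pattern_matrices(subjects, patterns, cv)
  sr_feats_by_lam <- NULL
  if (cv$lam_mode == "cv" && "SR" %in% patterns) {
    sr_feats_by_lam <- lapply(cv$lam_grid, function(l) {
      cv2 <- cv; cv2$lam <- l
      compute_pattern_matrices(subjects, "SR", cv2)$SR
    })
    names(sr_feats_by_lam) <- as.character(cv$lam_grid)
  }

  meth <- method_table(patterns)
  if (!is.null(methods)) {
    missing <- setdiff(methods, names(meth))
    if (length(missing))
      stop_mcpc(sprintf("unknown method(s): %s", paste(missing, collapse = ", ")))
    meth <- meth[methods]
  }

  decisions <- matrix(NA_real_, n, length(meth),
                      dimnames = list(NULL, names(meth)))
  chosen <- vector("list", length(meth)); names(chosen) <- names(meth)
  selected <- vector("list", n)

  inner_eval <- function(grams_tr, y_tr, cgrid) {
    M <- length(grams_tr)
    cube <- array(unlist(grams_tr), dim = c(nrow(grams_tr[[1]]),
                                            nrow(grams_tr[[1]]), M))
    .mkl_inner_loocv_cpp(cube, y_tr, cgrid, learn_beta = M > 1)
  }

  for (k in seq_len(n)) {
    train <- setdiff(seq_len(n), k)
    y_tr <- labels[train]
    # per-pattern feature prep on the training fold
    fold <- list()
    for (p in patterns) {
      st <- standardize_features(feats[[p]]$matrix, train, cv$standardize)
      sel <- if (cv$feature_selection == "ttest")
        st$valid[ttest_select(st$Z[train, , drop = FALSE], y_tr, cv$ttest_alpha)]
      else st$valid
      if (length(sel) == 0) sel <- st$valid   # selection fallback: keep all usable
      cols <- match(sel, st$valid)
      Gtr <- linear_kernel(st$Z[train, cols, drop = FALSE])
      Kte <- cross_kernel(st$Z[k, cols, drop = FALSE],
                          st$Z[train, cols, drop = FALSE], attr(Gtr, "scale"))
      fold[[p]] <- list(G = Gtr, Kte = Kte, selected = sel)
    }
    selected[[k]] <- lapply(fold, function(f) f$selected)

    for (mi in seq_along(meth)) {
      ps <- meth[[mi]]
      use_lam_cv <- !is.null(sr_feats_by_lam) && "SR" %in% ps
      if (!use_lam_cv) {
        grams <- lapply(fold[ps], function(f) f$G)
        inn <- inner_eval(grams, y_tr, cv$c_grid)
        best <- which.max(inn$accuracy)     # ties -> smallest C (grid sorted)
        Cstar <- cv$c_grid[best]
        lamstar <- if ("SR" %in% ps) cv$lam else NA_real_
        ks <- kernel_set(grams, y_tr, pattern_names = ps, check_psd = FALSE)
      } else {
        best_acc <- -1; Cstar <- cv$c_grid[1]; lamstar <- cv$lam_grid[1]
        best_grams <- NULL
        for (l in cv$lam_grid) {
          stl <- standardize_features(sr_feats_by_lam[[as.character(l)]]$matrix,
                                      train, cv$standardize)
          sell <- if (cv$feature_selection == "ttest")
            stl$valid[ttest_select(stl$Z[train, , drop = FALSE], y_tr, cv$ttest_alpha)]
          else stl$valid
          if (length(sell) == 0) sell <- stl$valid
          colsl <- match(sell, stl$valid)
          Gsr <- linear_kernel(stl$Z[train, colsl, drop = FALSE])
          grams <- lapply(fold[setdiff(ps, "SR")], function(f) f$G)
          grams <- c(grams, list(SR = Gsr))[ps]
          inn <- inner_eval(grams, y_tr, cv$c_grid)
          bi <- which.max(inn$accuracy)
          if (inn$accuracy[bi] > best_acc) {
            best_acc <- inn$accuracy[bi]; Cstar <- cv$c_grid[bi]; lamstar <- l
            best_grams <- grams
            fold[["SR"]] <- list(
              G = Gsr,
              Kte = cross_kernel(stl$Z[k, colsl, drop = FALSE],
                                 stl$Z[train, colsl, drop = FALSE],
                                 attr(Gsr, "scale")),
              selected = sell)
          }
        }
        ks <- kernel_set(best_grams, y_tr, pattern_names = ps, check_psd = FALSE)
      }
      model <- train_mkl(ks, Cstar)
      pred <- predict_mkl(model, lapply(fold[ps], function(f) f$Kte))
      decisions[k, mi] <- pred$decision_values
      chosen[[mi]][[k]] <- list(C = Cstar, lam = lamstar, beta = model$beta)
    }
    if (progress) message(sprintf("fold %d/%d", k, n))
  }

  reports <- lapply(seq_along(meth), function(mi) {
    f <- decisions[, mi]
    pred <- ifelse(f >= 0, 1, -1)
    conf <- list(tp = sum(pred == 1 & labels == 1),
                 fp = sum(pred == 1 & labels == -1),
                 tn = sum(pred == -1 & labels == -1),
                 fn = sum(pred == -1 & labels == 1))
    met <- compute_metrics(conf)
    roc <- roc_auc(f, labels)
    structure(list(method_name = names(meth)[mi], confusion = conf,
                   accuracy = met$accuracy, sensitivity = met$sensitivity,
                   specificity = met$specificity, auc = roc$auc,
                   roc_points = roc$roc_points, decision_values = f,
                   predictions = pred,
                   per_fold_selected_features = lapply(selected, function(s)
                     s[intersect(names(s), meth[[mi]])]),
                   per_fold_chosen_params = chosen[[mi]]),
              class = "evaluation_report")
  })
  names(reports) <- names(meth)
  attr(reports, "feature_index") <- lapply(feats, function(f) f$feature_index)
  attr(reports, "per_fold_selected") <- selected
  attr(reports, "labels") <- labels
  reports
}

#' Format evaluation reports as a classification table
#'
#' One row per method with accuracy/sensitivity/specificity as percentages
#' (2 decimals, half-up) and AUC (3 decimals).
#'
#' @param reports result of [nested_loocv()].
#' @return data.frame.
#' @export
report_table <- function(reports) {
  data.frame(
    method = vapply(reports, function(r) r$method_name, ""),
    accuracy = round_half_up(vapply(reports, function(r) r$accuracy, 0), 2),
    sensitivity = round_half_up(vapply(reports, function(r) r$sensitivity, 0), 2),
    specificity = round_half_up(vapply(reports, function(r) r$specificity, 0), 2),
    auc = round_half_up(vapply(reports, function(r) r$auc, 0), 3),
    row.names = NULL)
}
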