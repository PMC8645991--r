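#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of multivariate ROI time series generated from a
#' stationary VAR(1) process in which the two groups differ on a sparse,
#' known set of connections. Contemporaneous (innovation-covariance) edge
#' differences drive the correlation-based patterns (PC, SR); lag-1
#' transition-matrix differences drive Granger causality (GCM).
#'
#' @param n_per_group subjects per group.
#' @param n_rois number of ROIs (nodes). Default 116, the AAL atlas size.
#' @param n_timepoints retained series length after burn-in. Default 140,
#'   a typical resting-state scan length.
#' @param n_diff_edges_cov number of undirected edges whose innovation
#'   covariance differs between groups.
#' @param n_diff_edges_lag number of directed edges whose lag-1 coefficient
#'   differs between groups.
#' @param effect_size magnitude of each planted difference (covariance units
#'   of `noise_sd^2` for contemporaneous edges; raw VAR coefficient units for
#'   lagged edges).
#' @param noise_sd innovation standard deviation.
#' @param seed integer RNG seed; identical specs reproduce bit-identical
#'   cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group, n_rois = 116L, n_timepoints = 140L,
                        n_diff_edges_cov = 6L, n_diff_edges_lag = 6L,
                        effect_size = 0.15, noise_sd = 1, seed = 1L) {
  n_per_group <- check_scalar_int(n_per_group, "n_per_group")
  n_rois <- check_scalar_int(n_rois, "n_rois", min = 2L)
  n_timepoints <- check_scalar_int(n_timepoints, "n_timepoints", min = 3L)
  n_diff_edges_cov <- check_scalar_int(n_diff_edges_cov, "n_diff_edges_cov", min = 0L)
  n_diff_edges_lag <- check_scalar_int(n_diff_edges_lag, "n_diff_edges_lag", min = 0L)
  if (n_diff_edges_cov > n_rois * (n_rois - 1) / 2)
    stop_mcpc("n_diff_edges_cov exceeds the number of undirected ROI pairs")
  if (n_diff_edges_lag > n_rois * (n_rois - 1))
    stop_mcpc("n_diff_edges_lag exceeds the number of ordered ROI pairs")
  if (!is.finite(effect_size) || effect_size < 0)
    stop_mcpc("'effect_size' must be a nonnegative number")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop_mcpc("'noise_sd' must be positive")
  structure(list(n_per_group = n_per_group, n_rois = n_rois,
                 n_timepoints = n_timepoints,
                 n_diff_edges_cov = n_diff_edges_cov,
                 n_diff_edges_lag = n_diff_edges_lag,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' Simulate a two-group VAR(1) cohort with known connectivity differences
#'
#' Group +1 (the patient-analog, positive class) carries the planted
#' alterations; group -1 is the baseline. Each subject is an independent
#' realization `x_t = A_g x_{t-1} + e_t`, `e_t ~ N(0, Sigma_g)`, with a
#' 100-sample burn-in discarded.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `subjects` (list of [subject_ts()] objects), `labels`
#'   (+1/-1 integer vector) and `ground_truth` (group transition matrices,
#'   innovation covariances, and the planted edge lists).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  N <- spec$n_rois
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  A_base <- diag(0.3, N)
  Sigma_base <- diag(spec$noise_sd^2, N)

  # planted contemporaneous differences: undirected pairs, alternating sign
  all_pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  cov_idx <- if (spec$n_diff_edges_cov > 0)
    all_pairs[sample.int(nrow(all_pairs), spec$n_diff_edges_cov), , drop = FALSE]
  else all_pairs[0, , drop = FALSE]
  Sigma_alt <- Sigma_base
  if (nrow(cov_idx) > 0) {
    signs <- rep_len(c(1, -1), nrow(cov_idx))
    delta <- signs * spec$effect_size * spec$noise_sd^2
    Sigma_alt[cov_idx] <- Sigma_alt[cov_idx] + delta
    Sigma_alt[cov_idx[, c(2, 1), drop = FALSE]] <- Sigma_alt[cov_idx]
  }

  # planted lagged differences: ordered pairs (from -> to), alternating sign
  all_ord <- which(diag(N) == 0, arr.ind = TRUE)   # (row=to, col=from) order below
  lag_idx <- if (spec$n_diff_edges_lag > 0)
    all_ord[sample.int(nrow(all_ord), spec$n_diff_edges_lag), , drop = FALSE]
  else all_ord[0, , drop = FALSE]
  A_alt <- A_base
  if (nrow(lag_idx) > 0) {
    signs <- rep_len(c(1, -1), nrow(lag_idx))
    # A[to, from]: entry (r, c) of lag_idx is interpreted as from = c, to = r
    A_alt[lag_idx] <- A_alt[lag_idx] + signs * spec$effect_size
  }

  for (A in list(A_base, A_alt)) {
    sr <- spectral_radius(A)
    if (sr >= 1)
      stop_mcpc(sprintf(
        "non-stationary transition matrix (spectral radius %.3f >= 1); reduce effect_size", sr))
  }
  chol_base <- tryCatch(chol(Sigma_base), error = function(e) NULL)
  chol_alt <- tryCatch(chol(Sigma_alt), error = function(e) NULL)
  if (is.null(chol_base) || is.null(chol_alt))
    stop_mcpc("innovation covariance is not positive definite; reduce effect_size or n_diff_edges_cov")

  burn <- 100L
  Ttot <- spec$n_timepoints + burn
  roi_labels <- paste0("ROI_", seq_len(N))
  n_total <- 2L * spec$n_per_group
  labels <- rep(c(1L, -1L), each = spec$n_per_group)
  simulate_one <- function(A, cholSigma) {
    E <- matrix(stats::rnorm(Ttot * N, sd = 1), Ttot, N) %*% cholSigma
    X <- matrix(0, Ttot, N)
    X[1, ] <- E[1, ]
    for (t in 2:Ttot) X[t, ] <- as.vector(A %*% X[t - 1, ]) + E[t, ]
    X[(burn + 1):Ttot, , drop = FALSE]
  }
  subjects <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    alt <- labels[s] == 1L
    X <- simulate_one(if (alt) A_alt else A_base, if (alt) chol_alt else chol_base)
    subjects[[s]] <- subject_ts(sprintf("sub_%03d", s), X, roi_labels)
  }

  gt <- list(
    group_transition_matrices = list(positive = A_alt, negative = A_base),
    group_innovation_covariances = list(positive = Sigma_alt, negative = Sigma_base),
    diff_edge_list_cov = unname(cov_idx),
    # report lagged edges as (from, to): lag index rows are (to, from)
    diff_edge_list_lag = unname(lag_idx[, c(2, 1), drop = FALSE]))
  list(subjects = subjects, labels = labels, ground_truth = gt)
}

#' Write a cohort to a directory of per-subject TSV files
#'
#' One TSV per subject (T rows, N columns, ROI-label header), a
#' `manifest.tsv` (subject_id, file, label) and a `ground_truth.json`
#' sidecar when ground truth is present.
#'
#' @param cohort result of [simulate_cohort()], or a list with `subjects`
#'   and `labels`.
#' @param dir output directory, created if needed.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    files[i] <- paste0(s$subject_id, ".tsv")
    df <- as.data.frame(s$signal)
    names(df) <- s$roi_labels
    utils::write.table(df, file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- data.frame(
    subject_id = vapply(cohort$subjects, function(s) s$subject_id, ""),
    file = files, label = cohort$labels)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    jsonlite::write_json(
      list(diff_edge_list_cov = gt$diff_edge_list_cov,
           diff_edge_list_lag = gt$diff_edge_list_lag,
           group_transition_matrices = gt$group_transition_matrices,
           group_innovation_covariances = gt$group_innovation_covariances),
      file.path(dir, "ground_truth.json"), digits = NA, matrix = "rowmajor")
  }
  invisible(mpath)
}

#' Read a cohort from a manifest
#'
#' @param manifest path to a `manifest.tsv` as written by [write_cohort()],
#'   or a directory containing one.
#' @return a list with `subjects` and `labels`.
#' @export
read_cohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.tsv")
  man <- validate_manifest(manifest)
  dir <- dirname(manifest)
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    df <- utils::read.table(file.path(dir, man$file[i]), header = TRUE,
                            sep = "\t", check.names = FALSE)
    subject_ts(man$subject_id[i], as.matrix(df), colnames(df))
  })
  list(subjects = subjects, labels = man$label)
}
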