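#' Validate a cohort manifest
#'
#' Checks that every listed subject file exists and is readable, that the
#' ROI count is consistent across subjects (time-point counts may vary only
#' with `allow_varying_t`), and that labels are binary. String labels
#' `MCI`/`NC` are mapped to `+1`/`-1` (patients positive) and the mapping
#' is reported.
#'
#' @param path manifest TSV with columns `subject_id`, `file`, `label`.
#' @param allow_varying_t permit differing series lengths across subjects.
#' @return the manifest data.frame with numeric labels.
#' @export
validate_manifest <- function(path, allow_varying_t = FALSE) {
  if (!file.exists(path)) stop_mcpc(sprintf("manifest not found: %s", path))
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "file", "label")
  if (!all(need %in% names(man)))
    stop_mcpc("manifest must have columns subject_id, file, label")
  lab <- man$label
  if (is.character(lab)) {
    u <- sort(unique(lab))
    if (setequal(u, c("MCI", "NC"))) {
      message("mapping labels: MCI -> +1 (positive), NC -> -1")
      lab <- ifelse(lab == "MCI", 1, -1)
    } else {
      stop_mcpc(sprintf("unknown label values: %s", paste(u, collapse = ", ")))
    }
  }
  if (!all(lab %in% c(-1, 1)))
    stop_mcpc("labels must be +1/-1 (or MCI/NC)")
  man$label <- as.numeric(lab)
  dir <- dirname(path)
  dims <- matrix(0L, nrow(man), 2)
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f))
      stop_mcpc(sprintf("missing time-series file for subject '%s': %s",
                        man$subject_id[i], man$file[i]))
    d <- utils::read.table(f, header = TRUE, sep = "\t", nrows = 1)
    nr <- length(utils::count.fields(f, sep = "\t")) - 1L
    dims[i, ] <- c(nr, ncol(d))
  }
  if (length(unique(dims[, 2])) != 1)
    stop_mcpc("inconsistent ROI count (N) across subjects")
  if (!allow_varying_t && length(unique(dims[, 1])) != 1)
    stop_mcpc("inconsistent time-point count (T) across subjects; set allow_varying_t")
  man
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate (or load) -> connectivity estimation -> nested
#' LOOCV evaluation -> hub and consensus analyses, writing all tables under
#' one run directory: per-subject connectivity matrices, a classification
#' report (one row per method: each pattern, each pair, and the full
#' combination), ROC points, DeLong comparisons of the full combination
#' against each single pattern, per-group hub tables, consensus-connection
#' tables, and a machine-readable run manifest. Identical configuration and
#' seed reproduce identical numeric outputs.
#'
#' @param config a list, or path to a YAML file, with entries `seed`,
#'   `cohort` (either [cohort_spec()] fields or `manifest: <path>`),
#'   `patterns`, and optional `connectivity` (`lam`, `lam_mode`,
#'   `sr_symmetrize`, `gcm_lag`), `cv` (`feature_selection`, `ttest_alpha`,
#'   `standardize`), `network` (`hub_fraction`, `consensus_threshold`).
#' @param out_dir parent directory for the run.
#' @param run_id directory name for this run; defaults to a timestamp.
#' @param progress print stage progress.
#' @return the run directory path, invisibly.
#' @export
run_all <- function(config, out_dir = ".",
                    run_id = format(Sys.time(), "run_%Y%m%d_%H%M%S"),
                    progress = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- "configuration"
  say <- function(...) if (progress) message(sprintf("[%s] ", stage), ...)
  tryCatch({
    patterns <- toupper(config$patterns %||% c("PC", "SR", "GCM"))
    if (length(patterns) == 0 || !all(patterns %in% c("PC", "SR", "GCM")))
      stop_mcpc("patterns must be a non-empty subset of PC, SR, GCM")
    seed <- as.integer(config$seed %||% 1L)
    conn <- config$connectivity %||% list()
    cvc <- config$cv %||% list()
    cv <- cv_config(
      lam = conn$lam %||% 2^3,
      lam_mode = conn$lam_mode %||% "fixed",
      sr_symmetrize = conn$sr_symmetrize %||% TRUE,
      gcm_lag = conn$gcm_lag %||% 1L,
      feature_selection = cvc$feature_selection %||% "ttest",
      ttest_alpha = cvc$ttest_alpha %||% 0.05,
      standardize = cvc$standardize %||% TRUE,
      seed = seed)
    net <- config$network %||% list()
    hub_fraction <- net$hub_fraction %||% 0.05
    consensus_threshold <- net$consensus_threshold %||% 1

    run_dir <- file.path(out_dir, run_id)
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

    stage <- "cohort"
    if (!is.null(config$cohort$manifest)) {
      say("loading cohort from ", config$cohort$manifest)
      cohort <- read_cohort(config$cohort$manifest)
    } else {
      co <- config$cohort
      spec <- cohort_spec(
        n_per_group = co$n_per_group,
        n_rois = co$n_rois %||% 116L,
        n_timepoints = co$n_timepoints %||% 140L,
        n_diff_edges_cov = co$n_diff_edges_cov %||% 6L,
        n_diff_edges_lag = co$n_diff_edges_lag %||% 6L,
        effect_size = co$effect_size %||% 0.15,
        noise_sd = co$noise_sd %||% 1,
        seed = seed)
      say(sprintf("simulating cohort: %d subjects, %d ROIs, T=%d",
                  2 * spec$n_per_group, spec$n_rois, spec$n_timepoints))
      cohort <- simulate_cohort(spec)
      write_cohort(cohort, file.path(run_dir, "cohort"))
    }
    subjects <- cohort$subjects
    labels <- cohort$labels

    stage <- "connectivity"
    cms <- list()
    feats <- list()
    for (p in patterns) {
      say("estimating ", p, " networks")
      cms[[p]] <- switch(p,
        PC = lapply(subjects, pearson_network),
        SR = lapply(subjects, sr_network, lam = cv$lam,
                    symmetrize = cv$sr_symmetrize),
        GCM = lapply(subjects, gcm_network, p = cv$gcm_lag))
      feats[[p]] <- pattern_features(cms[[p]])
      pdir <- file.path(run_dir, "connectivity", tolower(p))
      dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
      for (m in cms[[p]]) {
        write_tsv(as.data.frame(m$weights),
                  file.path(pdir, paste0(m$subject_id, ".tsv")))
      }
      jsonlite::write_json(
        list(pattern = p,
             lam = if (p == "SR") cv$lam else NULL,
             lag_order = if (p == "GCM") cv$gcm_lag else NULL),
        file.path(pdir, "params.json"), auto_unbox = TRUE, digits = NA)
    }

    stage <- "evaluation"
    say("nested LOOCV over ", length(subjects), " subjects")
    reports <- nested_loocv(subjects, labels, patterns, cv,
                            precomputed = feats)
    tab <- report_table(reports)
    write_tsv(tab, file.path(run_dir, "report.tsv"))
    for (r in reports)
      write_tsv(r$roc_points,
                file.path(run_dir, paste0("roc_", gsub(" \\+ ", "_", r$method_name), ".tsv")))
    if ("MCPC" %in% names(reports)) {
      dl <- do.call(rbind, lapply(patterns, function(p) {
        d <- delong_test(reports$MCPC$decision_values,
                         reports[[p]]$decision_values, labels)
        data.frame(comparison = paste0("MCPC vs ", p),
                   auc_mcpc = d$auc_a, auc_other = d$auc_b, z = d$z, p = d$p)
      }))
      write_tsv(dl, file.path(run_dir, "delong.tsv"))
    }

    stage <- "network_analysis"
    ann <- ncol(subjects[[1]]$signal) == 116
    for (p in patterns) {
      gm <- group_network(cms[[p]], ifelse(labels == 1, "positive", "negative"))
      for (g in names(gm)) {
        kinds <- if (p == "GCM") c("in", "out") else "undirected"
        for (kind in kinds) {
          hubs <- find_hubs(gm[[g]], fraction = hub_fraction,
                            degree_kind = kind, annotate = ann)
          write_tsv(hubs, file.path(run_dir, sprintf(
            "hubs_%s_%s%s.tsv", tolower(p), g,
            if (kind == "undirected") "" else paste0("_", kind))))
        }
      }
      fold_sets <- lapply(attr(reports, "per_fold_selected"),
                          function(s) s[[p]])
      cmap <- consensus_edges(fold_sets, attr(reports, "feature_index")[[p]],
                              threshold = consensus_threshold, pattern = p)
      write_tsv(cmap$edges, file.path(run_dir,
                                      sprintf("consensus_edges_%s.tsv", tolower(p))))
      top <- top_consensus_degree(cmap, k = 10, annotate = ann)
      if (cmap$directed) {
        write_tsv(top$`in`, file.path(run_dir, sprintf("consensus_top_%s_in.tsv", tolower(p))))
        write_tsv(top$out, file.path(run_dir, sprintf("consensus_top_%s_out.tsv", tolower(p))))
      } else {
        write_tsv(top, file.path(run_dir, sprintf("consensus_top_%s.tsv", tolower(p))))
      }
    }

    stage <- "manifest"
    jsonlite::write_json(
      list(config = config, seed = seed, config_hash = config_hash(config),
           package_version = as.character(utils::packageVersion("mcpc")),
           n_subjects = length(subjects), patterns = patterns,
           methods = names(reports)),
      file.path(run_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
    say("run complete: ", run_dir)
    invisible(run_dir)
  }, error = function(e) {
    stop_mcpc(sprintf("pipeline failed at stage '%s': %s", stage,
                      conditionMessage(e)))
  })
}
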