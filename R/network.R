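.mcpc_env <- new.env(parent = emptyenv())

#' AAL-116 region and subnetwork lookup table
#'
#' Region names follow the Automated Anatomical Labeling atlas; subnetwork
#' codes (DMN, VN, FTC, SH, CTC, DAN, AN, SN, SBN) are assigned where a
#' published mapping exists and `"unassigned"` elsewhere.
#'
#' @return data.frame with `aal_number`, `region_name`, `subnetwork`.
#' @export
aal_table <- function() {
  if (is.null(.mcpc_env$aal)) {
    path <- system.file("extdata", "aal116_subnetworks.tsv", package = "mcpc")
    .mcpc_env$aal <- utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE)
  }
  .mcpc_env$aal
}

#' Annotate an AAL ROI number
#'
#' @param aal_number integer in 1..116 (vectorized).
#' @return data.frame row(s) with `aal_number`, `region_name`,
#'   `subnetwork`.
#' @export
annotate_roi <- function(aal_number) {
  tab <- aal_table()
  if (any(aal_number < 1 | aal_number > nrow(tab) | aal_number != round(aal_number)))
    stop_mcpc("aal_number must be an integer in 1..116")
  tab[aal_number, , drop = FALSE]
}

#' Per-group mean connectivity matrices
#'
#' Entrywise mean of each group's subject matrices; the result is the
#' group-level network on which hubs are computed.
#'
#' @param cms list of `conn_matrix` objects sharing one pattern.
#' @param groups group label per matrix (any two values).
#' @return named list of mean matrices, one per group level.
#' @export
group_network <- function(cms, groups) {
  if (length(cms) != length(groups)) stop_mcpc("one group label per matrix")
  pats <- unique(vapply(cms, function(m) m$pattern, ""))
  if (length(pats) != 1) stop_mcpc("mixed connection patterns")
  dims <- unique(vapply(cms, function(m) nrow(m$weights), 0L))
  if (length(dims) != 1) stop_mcpc("matrices differ in size")
  out <- lapply(split(cms, groups), function(g)
    Reduce(`+`, lapply(g, function(m) m$weights)) / length(g))
  attr(out, "pattern") <- pats
  out
}

#' Identify hub nodes of a group-level network
#'
#' Weighted degree on the absolute mean matrix (no binarization):
#' undirected degree sums each node's incident absolute weights (the
#' matrix is symmetrized first); `in` uses column sums, `out` row sums.
#' The nominal hub count is `ceiling(fraction * N)`; ties at the cutoff
#' degree are all included and flagged.
#'
#' @param mean_matrix square numeric matrix (a group mean).
#' @param fraction top fraction of nodes to report (default 0.05).
#' @param degree_kind `"undirected"`, `"in"` or `"out"`.
#' @param annotate attach AAL annotation (only meaningful for N = 116;
#'   defaults accordingly).
#' @return data.frame of hubs (node, degree, optional annotation), degrees
#'   nonincreasing, with attributes `nominal_count` and `tie_expanded`.
#' @export
find_hubs <- function(mean_matrix, fraction = 0.05,
                      degree_kind = c("undirected", "in", "out"),
                      annotate = nrow(mean_matrix) == 116) {
  degree_kind <- match.arg(degree_kind)
  W <- as.matrix(mean_matrix)
  if (nrow(W) != ncol(W)) stop_mcpc("mean matrix must be square")
  if (!(fraction > 0 && fraction < 1)) stop_mcpc("fraction must be in (0, 1)")
  A <- abs(W)
  deg <- switch(degree_kind,
                undirected = rowSums((A + t(A)) / 2),
                `in` = colSums(A),
                out = rowSums(A))
  N <- length(deg)
  count <- ceiling(fraction * N)
  ord <- order(-deg, seq_len(N))
  cutoff <- deg[ord[count]]
  keep <- ord[deg[ord] >= cutoff]
  res <- data.frame(node = keep, degree = deg[keep])
  if (annotate) {
    ann <- annotate_roi(res$node)
    res$region_name <- ann$region_name
    res$subnetwork <- ann$subnetwork
  }
  attr(res, "nominal_count") <- count
  attr(res, "tie_expanded") <- nrow(res) > count
  attr(res, "degree_kind") <- degree_kind
  res
}

#' Consensus connections across cross-validation folds
#'
#' Edges (feature columns) selected in at least `threshold` of the folds;
#' the default `threshold = 1` keeps the intersection — connections
#' selected in every outer fold, the most discriminative features.
#'
#' @param fold_sets list (one per fold) of selected feature column
#'   indices.
#' @param feature_index edge lookup for the columns, as produced by
#'   [edge_feature_index()] (the `feature_index` attribute of
#'   [nested_loocv()] reports).
#' @param threshold minimum selection frequency in (0, 1].
#' @param pattern optional pattern tag carried through.
#' @return object of class `consensus_map`: `edges` (i, j, frequency),
#'   `node_degree` (per-node incident consensus edges, split in/out for
#'   directed patterns), `directed`, `threshold`, `n_folds`.
#' @export
consensus_edges <- function(fold_sets, feature_index, threshold = 1,
                            pattern = NULL) {
  if (length(fold_sets) < 2) stop_mcpc("need at least 2 fold sets")
  if (any(vapply(fold_sets, length, 0L) == 0)) stop_mcpc("empty fold set")
  if (!(threshold > 0 && threshold <= 1)) stop_mcpc("threshold must be in (0, 1]")
  nf <- length(fold_sets)
  freq <- table(unlist(lapply(fold_sets, unique)))
  keep <- as.integer(names(freq))[as.numeric(freq) / nf >= threshold]
  keep <- sort(keep)
  directed <- feature_index$directed[1]
  edges <- data.frame(i = feature_index$i[keep], j = feature_index$j[keep],
                      frequency = as.numeric(freq[as.character(keep)]) / nf)
  n <- max(feature_index$i, feature_index$j)
  if (directed) {
    node_degree <- data.frame(
      node = seq_len(n),
      in_degree = tabulate(edges$j, n),
      out_degree = tabulate(edges$i, n))
  } else {
    node_degree <- data.frame(
      node = seq_len(n),
      degree = tabulate(edges$i, n) + tabulate(edges$j, n))
  }
  structure(list(pattern = pattern, edges = edges, node_degree = node_degree,
                 directed = directed, threshold = threshold, n_folds = nf),
            class = "consensus_map")
}

rank_degree <- function(node, degree, k, annotate) {
  ord <- order(-degree, node)
  top <- ord[seq_len(min(k, length(ord)))]
  res <- data.frame(node = node[top], degree = degree[top])
  if (annotate) {
    ann <- annotate_roi(res$node)
    res$region_name <- ann$region_name
    res$subnetwork <- ann$subnetwork
  }
  res
}

#' Top-k nodes by consensus degree
#'
#' Nodes ranked by the number of incident consensus connections,
#' descending, ties broken by ascending ROI number. Directed patterns get
#' separate in- and out-degree tables.
#'
#' @param cm a [consensus_edges()] result.
#' @param k table length (default 10).
#' @param annotate attach AAL annotation (default when the network has 116
#'   nodes).
#' @return data.frame, or for directed patterns a list with `in` and
#'   `out` data.frames.
#' @export
top_consensus_degree <- function(cm, k = 10,
                                 annotate = nrow(cm$node_degree) == 116) {
  stopifnot(inherits(cm, "consensus_map"))
  nd <- cm$node_degree
  if (cm$directed) {
    list(`in` = rank_degree(nd$node, nd$in_degree, k, annotate),
         out = rank_degree(nd$node, nd$out_degree, k, annotate))
  } else {
    rank_degree(nd$node, nd$degree, k, annotate)
  }
}
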