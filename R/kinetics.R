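#' @title Multi-matrix semi-quantitative kinetics
#' @description The pie-chart reading of a multi-matrix molecular network made
#'   algorithmic: per-node feature intensities are aggregated by sample group
#'   (timepoint, matrix, ...) and normalised to proportions, and pairwise
#'   group trends are classified.
#' @name matrix_kinetics
NULL

#' Per-group intensity profiles of network nodes
#'
#' @param net A [build_network()] result whose nodes carry per-sample
#'   intensity columns.
#' @param grouping Named character vector mapping sample label -> group label.
#'   Every sample column of the network must be mapped.
#' @param agg Aggregation across samples within a group: `"mean"` (default;
#'   replicate-aware) or `"sum"`.
#' @return Data frame with class `"group_profiles"`: one row per node x
#'   group, columns `node`, `feature_id`, `mz`, `rt_min`, `group`,
#'   `intensity`, `proportion` (sums to 1 over groups per node; `NA` and
#'   `absent = TRUE` when the node is all-zero).
#' @export
#' @examples
#' # grouping for a two-timepoint plasma matrix:
#' # group_profiles(net, c(H1 = "H1", H3 = "H3"))
group_profiles <- function(net, grouping, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  samples <- net$samples
  unknown <- setdiff(samples, names(grouping))
  if (length(unknown) > 0) {
    stop("unmapped sample label(s): ", paste(unknown, collapse = ", "))
  }
  groups <- unique(unname(grouping[samples]))
  fun <- if (agg == "mean") mean else sum
  rows <- lapply(seq_len(nrow(net$nodes)), function(i) {
    node <- net$nodes[i, ]
    vals <- vapply(groups, function(g) {
      cols <- samples[grouping[samples] == g]
      fun(as.numeric(node[cols]))
    }, numeric(1))
    total <- sum(vals)
    data.frame(
      node = node$id, feature_id = node$feature_id, mz = node$mz,
      rt_min = node$rt_min, group = groups, intensity = unname(vals),
      proportion = if (total > 0) unname(vals) / total else NA_real_,
      absent = total <= 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_profiles", "data.frame")
  out
}

#' Classify the kinetic trend of one node between two groups
#'
#' @param profile A [group_profiles()] data frame (or the subset for one
#'   node).
#' @param node Node id to classify.
#' @param g1,g2 Group labels.
#' @param fold_threshold Classified `higher_at_<g1>` iff
#'   `intensity(g1) > fold_threshold * intensity(g2)` (and symmetrically);
#'   otherwise `flat`. Default 1 = strict comparison.
#' @return One of `"higher_at_<g1>"`, `"higher_at_<g2>"`, `"flat"`.
#' @export
kinetic_trend <- function(profile, node, g1, g2, fold_threshold = 1) {
  p <- profile[profile$node == node, ]
  i1 <- p$intensity[p$group == g1]
  i2 <- p$intensity[p$group == g2]
  if (length(i1) != 1L || length(i2) != 1L) {
    stop("groups ", g1, "/", g2, " not found for node ", node)
  }
  if (i1 > fold_threshold * i2) {
    paste0("higher_at_", g1)
  } else if (i2 > fold_threshold * i1) {
    paste0("higher_at_", g2)
  } else {
    "flat"
  }
}

#' Trend table over all nodes
#'
#' @inheritParams kinetic_trend
#' @return Data frame `node`, `feature_id`, `mz`, `rt_min`, `trend`.
#' @export
kinetic_trends <- function(profile, g1, g2, fold_threshold = 1) {
  nodes <- unique(profile$node)
  out <- unique(profile[, c("node", "feature_id", "mz", "rt_min")])
  out$trend <- vapply(out$node, function(nd) {
    kinetic_trend(profile, nd, g1, g2, fold_threshold)
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Write group profiles and trends as CSV
#'
#' @param profile A [group_profiles()] result.
#' @param path Output path.
#' @export
write_kinetics_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
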