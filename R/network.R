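#' @title MS/MS molecular networking
#' @description Builds a molecular network from MS/MS spectra: all spectrum
#'   pairs are scored with a (modified) cosine similarity, edges are kept when
#'   the score exceeds a threshold with enough matched fragment ions, and the
#'   surviving edges are pruned to mutual top-k neighbourhoods. Connected
#'   components are the spectral families ("clusters") of the network.
#' @name molecular_network
NULL

#' Networking parameters
#'
#' Defaults follow standard high-resolution feature-based molecular
#' networking practice: 0.02 Da fragment and precursor tolerances, cosine
#' threshold 0.70, at least 6 matched fragment ions, mutual top-10 edges, and
#' minimum cluster size 1 (singletons retained).
#'
#' @param fragment_tol,precursor_tol Mass tolerances (Da).
#' @param cosine_threshold Minimum cosine score (edges require score strictly
#'   greater).
#' @param min_matched_peaks Minimum number of matched fragment ions.
#' @param top_k Mutual nearest-neighbour rank cutoff.
#' @param min_cluster_size Components smaller than this are dropped.
#' @param score_mode `"shifted"` (modified cosine: fragment pairs offset by
#'   the precursor mass difference also match) or `"unshifted"` (plain
#'   cosine).
#' @param intensity_weighting `"sqrt"` (default) or `"raw"`.
#' @return List with class `"network_params"`.
#' @export
network_params <- function(fragment_tol = 0.02, precursor_tol = 0.02,
                           cosine_threshold = 0.70, min_matched_peaks = 6L,
                           top_k = 10L, min_cluster_size = 1L,
                           score_mode = c("shifted", "unshifted"),
                           intensity_weighting = c("sqrt", "raw")) {
  score_mode <- match.arg(score_mode)
  intensity_weighting <- match.arg(intensity_weighting)
  stopifnot(fragment_tol > 0, precursor_tol > 0,
            cosine_threshold >= 0, cosine_threshold <= 1, top_k >= 1)
  structure(
    list(fragment_tol = fragment_tol, precursor_tol = precursor_tol,
         cosine_threshold = cosine_threshold,
         min_matched_peaks = as.integer(min_matched_peaks),
         top_k = as.integer(top_k),
         min_cluster_size = as.integer(min_cluster_size),
         score_mode = score_mode, intensity_weighting = intensity_weighting),
    class = "network_params"
  )
}

weight_peaks <- function(peaks, weighting) {
  w <- peaks[, "intensity"]
  if (weighting == "sqrt") w <- sqrt(w)
  n <- sqrt(sum(w^2))
  if (n > 0) w <- w / n
  w
}

#' Modified cosine similarity between two spectra
#'
#' Intensities are square-root transformed and L2-normalised. Candidate
#' matches are peak pairs within `fragment_tol`, and in shifted mode also
#' pairs whose m/z difference equals the precursor mass difference within
#' `fragment_tol`. A one-to-one assignment is then chosen greedily by
#' descending intensity product; the score is the sum of matched products and
#' lies in \[0, 1\]. Symmetric in its arguments.
#'
#' @param a,b [msms_spectrum()] objects (each with at least one peak).
#' @param params [network_params()].
#' @return List: `score`, `matched` (matched peak-pair count).
#' @export
#' @examples
#' s <- msms_spectrum("x", 211.087, 5.8,
#'                    cbind(mz = c(118.065, 183.092), intensity = c(1, 1)))
#' spectral_similarity(s, s)$score # 1
spectral_similarity <- function(a, b, params = network_params()) {
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L) {
    stop("spectral_similarity requires non-empty peak lists")
  }
  wa <- weight_peaks(a$peaks, params$intensity_weighting)
  wb <- weight_peaks(b$peaks, params$intensity_weighting)
  dm <- outer(a$peaks[, "mz"], b$peaks[, "mz"], function(x, y) y - x)
  ok <- abs(dm) <= params$fragment_tol
  if (params$score_mode == "shifted") {
    shift <- b$precursor_mz - a$precursor_mz
    ok <- ok | (abs(dm - shift) <= params$fragment_tol)
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(score = 0, matched = 0L))
  prod <- wa[idx[, 1]] * wb[idx[, 2]]
  ord <- order(-prod, idx[, 1], idx[, 2])
  used_a <- logical(length(wa))
  used_b <- logical(length(wb))
  score <- 0
  matched <- 0L
  for (k in ord) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE
    used_b[j] <- TRUE
    score <- score + prod[k]
    matched <- matched + 1L
  }
  list(score = min(score, 1), matched = matched)
}

#' Build a molecular network from spectra
#'
#' All-pairs similarity, threshold and minimum-matched-ion filtering, then
#' mutual top-k pruning (each retained edge must rank within the top `k` most
#' similar neighbours of both endpoints; ranking by score descending, absolute
#' precursor shift ascending, node id ascending). Components smaller than
#' `min_cluster_size` are dropped; with the default of 1 singletons are kept.
#'
#' @param spectra List of [msms_spectrum()].
#' @param params [network_params()].
#' @return Object of class `"molecular_network"`: `nodes` (data frame: `id`,
#'   `feature_id`, `mz`, `rt_min`, plus one intensity column per sample) and
#'   `edges` (data frame: `source`, `target`, `score`, `matched`, `shift` =
#'   precursor m/z of target minus source).
#' @export
build_network <- function(spectra, params = network_params()) {
  stopifnot(length(spectra) >= 1L)
  n <- length(spectra)
  samp <- unique(unlist(lapply(spectra, function(s) names(s$sample_intensities))))
  nodes <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- spectra[[i]]
    row <- data.frame(id = i, feature_id = s$feature_id, mz = s$precursor_mz,
                      rt_min = s$rt_min, stringsAsFactors = FALSE)
    for (sm in samp) {
      row[[sm]] <- if (sm %in% names(s$sample_intensities)) {
        s$sample_intensities[[sm]]
      } else 0
    }
    row
  }))

  edges <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        sim <- spectral_similarity(spectra[[i]], spectra[[j]], params)
        if (sim$score > params$cosine_threshold &&
            sim$matched >= params$min_matched_peaks) {
          edges[[length(edges) + 1L]] <- data.frame(
            source = i, target = j, score = sim$score, matched = sim$matched,
            shift = spectra[[j]]$precursor_mz - spectra[[i]]$precursor_mz
          )
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = integer(0), target = integer(0), score = numeric(0),
               matched = integer(0), shift = numeric(0))
  edges <- prune_top_k(edges, params$top_k)

  net <- structure(list(nodes = nodes, edges = edges, params = params,
                        samples = samp),
                   class = "molecular_network")
  if (params$min_cluster_size > 1L) {
    memb <- cluster_membership(net)
    sizes <- table(memb)
    keep <- nodes$id[memb %in% as.integer(names(sizes)[sizes >= params$min_cluster_size])]
    net$nodes <- nodes[nodes$id %in% keep, , drop = FALSE]
    net$edges <- edges[edges$source %in% keep & edges$target %in% keep, ,
                       drop = FALSE]
  }
  net
}

# Mutual top-k rule. Rank each node's incident edges by score desc, |shift|
# asc, partner id asc; keep an edge only if it ranks <= k at both endpoints.
prune_top_k <- function(edges, k) {
  if (nrow(edges) == 0L) return(edges)
  rank_ok <- function(node) {
    inc <- which(edges$source == node | edges$target == node)
    partner <- ifelse(edges$source[inc] == node, edges$target[inc],
                      edges$source[inc])
    ord <- inc[order(-edges$score[inc], abs(edges$shift[inc]), partner)]
    utils::head(ord, k)
  }
  nodes <- unique(c(edges$source, edges$target))
  kept_per_node <- lapply(nodes, rank_ok)
  names(kept_per_node) <- nodes
  keep <- vapply(seq_len(nrow(edges)), function(e) {
    e %in% kept_per_node[[as.character(edges$source[e])]] &&
      e %in% kept_per_node[[as.character(edges$target[e])]]
  }, logical(1))
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(net$edges)) net$edges else
      data.frame(source = integer(0), target = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, net$nodes[-1],
                          check.names = FALSE)
  )
  g
}

cluster_membership <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  stats::setNames(comp$membership[as.character(net$nodes$id)], net$nodes$id)
}

#' Connected components of a molecular network
#'
#' @param net A [build_network()] result.
#' @return List of integer vectors of node ids, ordered by decreasing size.
#' @export
network_clusters <- function(net) {
  memb <- cluster_membership(net)
  cl <- split(net$nodes$id, memb)
  cl[order(-lengths(cl))]
}

#' Export / import a network as GraphML
#'
#' Node attributes: feature id, precursor m/z, RT and per-sample intensities;
#' edge attributes: cosine score, matched ion count, precursor shift.
#'
#' @param net A `molecular_network`.
#' @param path Output path.
#' @return `export_graphml()` returns `path` invisibly; `import_graphml()`
#'   the igraph object.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write the edge list as CSV
#'
#' @param net A `molecular_network`.
#' @param path Output path.
#' @export
write_edgelist_csv <- function(net, path) {
  utils::write.csv(
    net$edges[, c("source", "target", "score", "matched", "shift")],
    path, row.names = FALSE)
  invisible(path)
}

#' @export
print.molecular_network <- function(x, ...) {
  cat("<molecular_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(network_clusters(x)), " clusters\n", sep = "")
  invisible(x)
}
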