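#' @title Biotransformation mass-shift annotation
#' @description Reads network edges as metabolic reactions: a library of
#'   biotransformation mass deltas (single reactions and chains thereof) is
#'   matched against precursor mass shifts, and formula/chain proposals are
#'   propagated outward from the identified parent node through its cluster —
#'   the "information propagation" reading of a drug-metabolism molecular
#'   network, made algorithmic.
#' @name shift_annotation
NULL

# Family-level deltas used for annotation; hydroxylation and N-oxidation share
# +O and collapse to one library entry at the formula level.
.annotation_families <- list(
  hydroxylation = c(O = 1),
  methylation = c(C = 1, H = 2),
  sulfation = c(S = 1, O = 3),
  glucuronidation = c(C = 6, H = 8, O = 6)
)

#' Build a biotransformation delta library
#'
#' Enumerates all multisets of up to `max_depth` rule applications over the
#' base reaction families (hydroxylation +O, methylation +CH2, sulfation +SO3,
#' glucuronidation +C6H8O6), deduplicated by delta formula. Depth counts total
#' applications, so chains like 2 x hydroxylation + 2 x glucuronidation need
#' `max_depth = 4`.
#'
#' @param families Named list of elemental deltas (defaults above).
#' @param max_depth Maximum number of rule applications per chain (>= 1).
#' @param conv [mass_conventions()].
#' @return Data frame with class `"delta_library"`: `name` (canonical chain
#'   name), `delta_formula`, `delta_mass`, `depth`, plus a `counts` matrix
#'   attribute (one row per entry, one column per family).
#' @export
#' @examples
#' lib <- build_delta_library(max_depth = 2)
#' lib[lib$name == "glucuronidation", "delta_mass"]
build_delta_library <- function(families = .annotation_families,
                                max_depth = 4L, conv = mass_conventions()) {
  stopifnot(max_depth >= 1L)
  k <- length(families)
  grid <- expand.grid(rep(list(0:max_depth), k))
  names(grid) <- names(families)
  tot <- rowSums(grid)
  grid <- grid[tot >= 1L & tot <= max_depth, , drop = FALSE]

  entries <- lapply(seq_len(nrow(grid)), function(i) {
    counts <- unlist(grid[i, ])
    delta <- integer(0)
    fams <- character(0)
    for (f in names(families)) {
      if (counts[[f]] == 0L) next
      fams <- c(fams, rep(f, counts[[f]]))
      d <- families[[f]] * counts[[f]]
      for (el in names(d)) {
        delta[el] <- (if (el %in% names(delta)) delta[[el]] else 0L) + d[[el]]
      }
    }
    df <- new_formula(delta)
    list(name = chain_name(fams), delta_formula = format_formula(df),
         delta_mass = monoisotopic_mass(df, conv), depth = sum(counts),
         counts = counts)
  })
  # deduplicate by delta formula, keeping the shallowest chain
  forms <- vapply(entries, `[[`, "", "delta_formula")
  depths <- vapply(entries, function(e) e$depth, numeric(1))
  keep <- !duplicated(forms[order(depths)])[order(order(depths))]
  entries <- entries[keep]
  lib <- data.frame(
    name = vapply(entries, `[[`, "", "name"),
    delta_formula = vapply(entries, `[[`, "", "delta_formula"),
    delta_mass = vapply(entries, function(e) e$delta_mass, numeric(1)),
    depth = vapply(entries, function(e) e$depth, numeric(1)),
    stringsAsFactors = FALSE
  )
  lib <- lib[order(lib$delta_mass), ]
  rownames(lib) <- NULL
  attr(lib, "counts") <- do.call(rbind, lapply(entries, `[[`, "counts"))[
    order(vapply(entries, function(e) e$delta_mass, numeric(1))), ,
    drop = FALSE]
  class(lib) <- c("delta_library", "data.frame")
  lib
}

best_library_match <- function(shift, lib, delta_tol) {
  err <- abs(shift - lib$delta_mass)
  i <- which(err <= delta_tol)
  if (length(i) == 0L) return(NULL)
  # minimal mass error, ties to the shallower chain
  i <- i[order(err[i], lib$depth[i])][1]
  list(index = i, name = lib$name[i], delta_formula = lib$delta_formula[i],
       error = shift - lib$delta_mass[i])
}

#' Annotate network edges with biotransformation reactions
#'
#' Each edge's absolute precursor shift is matched to the library entry with
#' minimal mass error within `delta_tol`; unmatched edges are labelled
#' `"unannotated"`.
#'
#' @param net A [build_network()] result.
#' @param lib A [build_delta_library()] result.
#' @param delta_tol Mass-shift tolerance (Da). The default 0.01 is tighter
#'   than the 0.02 fragment tolerance because precursor masses are
#'   high-resolution.
#' @return The network with edge columns `reaction`, `delta_formula`,
#'   `shift_error` added.
#' @export
annotate_edges <- function(net, lib = build_delta_library(),
                           delta_tol = 0.01) {
  e <- net$edges
  ann <- lapply(abs(e$shift), best_library_match, lib = lib,
                delta_tol = delta_tol)
  e$reaction <- vapply(ann, function(a) if (is.null(a)) "unannotated" else a$name,
                       character(1))
  e$delta_formula <- vapply(ann, function(a) if (is.null(a)) NA_character_ else
    a$delta_formula, character(1))
  e$shift_error <- vapply(ann, function(a) if (is.null(a)) NA_real_ else
    a$error, numeric(1))
  net$edges <- e
  net
}

#' Propagate chain proposals from the parent node
#'
#' Breadth-first traversal of the parent's connected component. Each node is
#' assigned the chain whose delta mass best matches its precursor shift from
#' the parent within `delta_tol` (direct-shift matching, which also covers
#' composite shifts read across several edges); nodes with no match — decoys,
#' or nodes whose printed shift is inconsistent with any chain — are flagged
#' unassigned.
#'
#' @param net A `molecular_network`.
#' @param parent Either a node id, a feature id, or a numeric m/z (the node
#'   with the nearest precursor is taken, standing in for spectral-library
#'   identification of the parent).
#' @param parent_formula Elemental formula of the parent (string or
#'   `elemental_formula`).
#' @param lib A [build_delta_library()].
#' @param delta_tol Mass-shift tolerance (Da).
#' @param conv [mass_conventions()].
#' @return Data frame with class `"node_annotations"`: `node`, `feature_id`,
#'   `mz`, `rt_min`, `assigned`, `chain`, `formula`, `mass_error_mda`,
#'   `hops` (graph distance from the parent), plus the parent row flagged by
#'   `is_parent`. Attribute `"parent"` records the parent node id, m/z and
#'   formula.
#' @export
propagate_from_parent <- function(net, parent, parent_formula,
                                  lib = build_delta_library(),
                                  delta_tol = 0.01,
                                  conv = mass_conventions()) {
  nodes <- net$nodes
  pid <- resolve_parent(nodes, parent)
  parent_formula <- as_formula(parent_formula)
  parent_mz <- nodes$mz[nodes$id == pid]

  g <- as_igraph(net)
  dist <- igraph::distances(g, v = as.character(pid))[1, ]
  comp <- names(dist)[is.finite(dist)]
  member <- nodes$id %in% as.integer(comp)

  rows <- lapply(which(member), function(i) {
    nid <- nodes$id[i]
    base <- data.frame(
      node = nid, feature_id = nodes$feature_id[i], mz = nodes$mz[i],
      rt_min = nodes$rt_min[i], is_parent = nid == pid,
      hops = unname(dist[as.character(nid)]),
      stringsAsFactors = FALSE
    )
    if (nid == pid) {
      base$assigned <- TRUE
      base$chain <- "parent"
      base$formula <- format_formula(parent_formula)
      base$mass_error_mda <- 0
      return(base)
    }
    shift <- nodes$mz[i] - parent_mz
    m <- if (shift > 0) best_library_match(shift, lib, delta_tol) else NULL
    if (is.null(m)) {
      base$assigned <- FALSE
      base$chain <- NA_character_
      base$formula <- NA_character_
      base$mass_error_mda <- NA_real_
    } else {
      base$assigned <- TRUE
      base$chain <- m$name
      base$formula <- format_formula(
        combine_formula(parent_formula, parse_formula(m$delta_formula)))
      base$mass_error_mda <- m$error * 1000
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "parent") <- list(node = pid, mz = parent_mz,
                              formula = format_formula(parent_formula))
  class(out) <- c("node_annotations", "data.frame")
  out
}

resolve_parent <- function(nodes, parent) {
  if (is.character(parent)) {
    i <- match(parent, nodes$feature_id)
    if (is.na(i)) stop("parent feature '", parent, "' not in network")
    return(nodes$id[i])
  }
  if (parent %in% nodes$id) return(as.integer(parent))
  # interpret as m/z: nearest precursor
  i <- which.min(abs(nodes$mz - parent))
  if (abs(nodes$mz[i] - parent) > 0.05) {
    stop("no network node within 0.05 Da of parent m/z ", parent)
  }
  nodes$id[i]
}

#' Cross-reference annotations with in silico candidates
#'
#' @param annotations A [propagate_from_parent()] result.
#' @param candidates A [predict_metabolites()] result.
#' @param mz_tol m/z tolerance (Da) for matching.
#' @param label Predictor label recorded for supported annotations.
#' @return The annotations with columns `insilico_support` (logical),
#'   `insilico_labels` and `insilico_agreement` (chain multisets match) added.
#' @export
match_to_insilico <- function(annotations, candidates, mz_tol = 0.01,
                              label = "rules") {
  norm_chain <- function(x) {
    # canonical multiset key for a chain name
    parts <- strsplit(x, " \\+ ")[[1]]
    expand <- unlist(lapply(parts, function(p) {
      m <- regmatches(p, regexec("^([0-9]+) .? (.*)$", p))[[1]]
      if (length(m) == 3) rep(m[3], as.integer(m[2])) else p
    }))
    paste(sort(trimws(expand)), collapse = "|")
  }
  hit <- lapply(seq_len(nrow(annotations)), function(i) {
    if (nrow(candidates) == 0L || !isTRUE(annotations$assigned[i]) ||
        isTRUE(annotations$is_parent[i])) {
      return(list(support = FALSE, agree = FALSE))
    }
    near <- abs(candidates$mz - annotations$mz[i]) <= mz_tol
    if (!any(near)) return(list(support = FALSE, agree = FALSE))
    agree <- any(vapply(candidates$chain[near], norm_chain, "") ==
                   norm_chain(annotations$chain[i]))
    list(support = TRUE, agree = agree)
  })
  annotations$insilico_support <- vapply(hit, `[[`, logical(1), "support")
  annotations$insilico_labels <- ifelse(annotations$insilico_support, label, "")
  annotations$insilico_agreement <- vapply(hit, `[[`, logical(1), "agree")
  annotations
}

#' Write node annotations as CSV
#'
#' @param annotations A `node_annotations` data frame.
#' @param path Output path.
#' @export
write_annotation_csv <- function(annotations, path) {
  utils::write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}
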