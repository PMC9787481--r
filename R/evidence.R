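#' @title Cross-sectional evidence integration
#' @description Merges the annotated networks of the two matrices with the in
#'   silico candidate set into a single metabolite evidence table with
#'   canonical M-number/isomer-letter naming and summary counts — the final
#'   deliverable of the cross-sectional workflow.
#' @name evidence_report
NULL

#' Integrate per-matrix annotations into evidence records
#'
#' Assigned annotations from the two matrices are merged on (chain, m/z
#' rounded to 3 dp, RT within `rt_window` minutes); presence booleans record
#' which matrix each record was seen in. The parent row is carried through
#' (flagged `is_parent`) but excluded from counts downstream.
#'
#' @param annot_invitro,annot_invivo [propagate_from_parent()] results (either
#'   may be `NULL`); both must share the same parent formula.
#' @param rt_window RT matching window in minutes (default 0.1).
#' @return Data frame with class `"evidence_records"`: `chain`, `formula`,
#'   `mz`, `shift`, `rt_min`, `in_vitro`, `in_vivo`, `insilico_labels`,
#'   `is_parent`.
#' @export
integrate_evidence <- function(annot_invitro = NULL, annot_invivo = NULL,
                               rt_window = 0.1) {
  take <- function(ann, matrix_label) {
    if (is.null(ann)) return(NULL)
    a <- as.data.frame(ann)[isTRUE_v(ann$assigned), , drop = FALSE]
    if (nrow(a) == 0L) return(NULL)
    a$matrix <- matrix_label
    if (is.null(a$insilico_labels)) a$insilico_labels <- ""
    a[, c("chain", "formula", "mz", "rt_min", "is_parent", "matrix",
          "insilico_labels")]
  }
  p1 <- attr(annot_invitro, "parent")
  p2 <- attr(annot_invivo, "parent")
  if (!is.null(p1) && !is.null(p2) && !identical(p1$formula, p2$formula)) {
    stop("matrices annotated against different parents: ",
         p1$formula, " vs ", p2$formula)
  }
  rows <- rbind(take(annot_invitro, "invitro"), take(annot_invivo, "invivo"))
  if (is.null(rows) || nrow(rows) == 0L) {
    out <- data.frame(chain = character(0), formula = character(0),
                      mz = numeric(0), shift = numeric(0),
                      rt_min = numeric(0), in_vitro = logical(0),
                      in_vivo = logical(0), insilico_labels = character(0),
                      is_parent = logical(0))
    class(out) <- c("evidence_records", "data.frame")
    return(out)
  }

  parent_mz <- if (!is.null(p1)) p1$mz else p2$mz
  merged <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    hit <- NA_integer_
    for (j in seq_along(merged)) {
      m <- merged[[j]]
      if (m$chain == r$chain && round(m$mz, 3) == round(r$mz, 3) &&
          abs(m$rt_min - r$rt_min) <= rt_window) {
        hit <- j
        break
      }
    }
    if (is.na(hit)) {
      merged[[length(merged) + 1L]] <- list(
        chain = r$chain, formula = r$formula, mz = r$mz, rt_min = r$rt_min,
        is_parent = r$is_parent,
        in_vitro = r$matrix == "invitro", in_vivo = r$matrix == "invivo",
        insilico_labels = r$insilico_labels
      )
    } else {
      m <- merged[[hit]]
      m$in_vitro <- m$in_vitro || r$matrix == "invitro"
      m$in_vivo <- m$in_vivo || r$matrix == "invivo"
      labs <- unique(c(strsplit(m$insilico_labels, ";")[[1]],
                       strsplit(r$insilico_labels, ";")[[1]]))
      m$insilico_labels <- paste(labs[nzchar(labs)], collapse = ";")
      merged[[hit]] <- m
    }
  }
  out <- do.call(rbind, lapply(merged, function(m) {
    data.frame(chain = m$chain, formula = m$formula, mz = m$mz,
               shift = m$mz - parent_mz, rt_min = m$rt_min,
               in_vitro = m$in_vitro, in_vivo = m$in_vivo,
               insilico_labels = m$insilico_labels, is_parent = m$is_parent,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(!out$is_parent, out$mz, out$rt_min), ]
  rownames(out) <- NULL
  class(out) <- c("evidence_records", "data.frame")
  out
}

isTRUE_v <- function(x) !is.na(x) & x

#' Assign canonical metabolite identifiers
#'
#' Distinct (chain, formula) groups are numbered M1, M2, ... by ascending
#' m/z; within a group isomers get letters a, b, c by ascending RT; singleton
#' groups get a bare M-number. The parent row keeps the id `"parent"`.
#'
#' @param records An [integrate_evidence()] result.
#' @return The records with a `metabolite_id` column, sorted by m/z and RT.
#' @export
assign_metabolite_ids <- function(records) {
  rec <- as.data.frame(records)
  rec$metabolite_id <- NA_character_
  met <- which(!rec$is_parent)
  if (length(met) > 0) {
    key <- paste(rec$chain[met], rec$formula[met], sep = "::")
    group_mz <- tapply(rec$mz[met], key, min)
    group_rank <- rank(group_mz, ties.method = "first")
    for (g in names(group_mz)) {
      idx <- met[key == g]
      num <- paste0("M", group_rank[[g]])
      if (length(idx) == 1L) {
        rec$metabolite_id[idx] <- num
      } else {
        ord <- order(rec$rt_min[idx])
        rec$metabolite_id[idx[ord]] <- paste0(num, letters[seq_along(idx)])
      }
    }
  }
  rec$metabolite_id[isTRUE_v(rec$is_parent)] <- "parent"
  rec <- rec[order(!rec$is_parent, rec$mz, rec$rt_min), ]
  rownames(rec) <- NULL
  class(rec) <- c("evidence_records", "data.frame")
  rec
}

#' Summary counts of an evidence report
#'
#' Counts exclude the parent; isomers count separately.
#'
#' @param records An [assign_metabolite_ids()] (or [integrate_evidence()])
#'   result.
#' @return List: `n_total`, `n_in_vivo`, `n_in_vitro`, `n_phase2_only`
#'   (records whose chain contains conjugations only).
#' @export
summarize_evidence <- function(records) {
  rec <- as.data.frame(records)
  rec <- rec[!isTRUE_v(rec$is_parent), , drop = FALSE]
  phase2 <- c("methylation", "sulfation", "glucuronidation")
  is_p2 <- vapply(rec$chain, function(ch) {
    fams <- gsub("^[0-9]+ \u00d7 ", "", trimws(strsplit(ch, "\\+")[[1]]))
    length(fams) > 0 && all(trimws(fams) %in% phase2)
  }, logical(1))
  list(
    n_total = nrow(rec),
    n_in_vivo = sum(rec$in_vivo),
    n_in_vitro = sum(rec$in_vitro),
    n_phase2_only = sum(is_p2)
  )
}

#' Write the evidence report as TSV
#'
#' Columns mirror a conventional metabolite evidence table: id, formula,
#' biotransformation, m/z, mass shift, RT and per-matrix presence marks.
#'
#' @param records An [assign_metabolite_ids()] result.
#' @param path Output path.
#' @export
write_evidence_tsv <- function(records, path) {
  rec <- as.data.frame(records)
  out <- data.frame(
    metabolite = rec$metabolite_id,
    formula = rec$formula,
    biotransformation = rec$chain,
    mz = sprintf("%.3f", rec$mz),
    mass_shift = sprintf("%.3f", rec$shift),
    rt_min = sprintf("%.1f", rec$rt_min),
    in_vivo = ifelse(rec$in_vivo, "X", "-"),
    in_vitro = ifelse(rec$in_vitro, "X", "-"),
    in_silico = ifelse(nzchar(rec$insilico_labels), rec$insilico_labels, "-"),
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.evidence_records <- function(x, ...) {
  s <- summarize_evidence(x)
  cat("Evidence report: ", s$n_total, " metabolites (",
      s$n_in_vivo, " in vivo, ", s$n_in_vitro, " in vitro, ",
      s$n_phase2_only, " phase II only)\n", sep = "")
  y <- as.data.frame(x)
  y$mz <- round(y$mz, 3)
  y$shift <- round(y$shift, 3)
  cols <- intersect(c("metabolite_id", "formula", "chain", "mz", "shift",
                      "rt_min", "in_vivo", "in_vitro", "insilico_labels"),
                    names(y))
  print(y[, cols], ...)
  invisible(x)
}
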