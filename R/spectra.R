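#' @title MS/MS spectra and their file formats
#' @description An `msms_spectrum` holds a precursor m/z, retention time,
#'   fragment peak list and (optionally) per-sample feature intensities; it is
#'   the unit of molecular networking. Spectra travel as MGF (Mascot generic
#'   format), per-sample intensities as an MZmine-style feature table CSV.
#' @name spectra_io
NULL

#' Construct an MS/MS spectrum
#'
#' @param feature_id Feature identifier (string).
#' @param precursor_mz Precursor m/z (Da); must lie in the acquisition range
#'   100--700.
#' @param rt_min Retention time in minutes.
#' @param peaks Two-column matrix or data frame (`mz`, `intensity`); rows are
#'   sorted by ascending m/z on construction.
#' @param sample_intensities Named numeric vector of per-sample intensities
#'   (may be empty).
#' @return An object of class `"msms_spectrum"`.
#' @export
msms_spectrum <- function(feature_id, precursor_mz, rt_min, peaks,
                          sample_intensities = numeric(0)) {
  peaks <- as.matrix(peaks)
  colnames(peaks) <- c("mz", "intensity")
  stopifnot(all(peaks[, "mz"] > 0), all(peaks[, "intensity"] >= 0))
  if (precursor_mz < 100 || precursor_mz > 700) {
    stop("precursor m/z ", round(precursor_mz, 4),
         " outside acquisition range [100, 700]")
  }
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(
    list(feature_id = as.character(feature_id),
         precursor_mz = as.numeric(precursor_mz),
         rt_min = as.numeric(rt_min),
         peaks = peaks,
         sample_intensities = sample_intensities),
    class = "msms_spectrum"
  )
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat("<msms_spectrum> ", x$feature_id,
      "  precursor ", round(x$precursor_mz, 4),
      "  RT ", round(x$rt_min, 2), " min  ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Write spectra to an MGF file
#'
#' One `BEGIN IONS`/`END IONS` block per spectrum with `TITLE`, `PEPMASS`,
#' `RTINSECONDS` and `CHARGE=1+` headers and one `mz intensity` line per peak.
#'
#' @param spectra List of [msms_spectrum()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    paste(c(
      "BEGIN IONS",
      paste0("TITLE=", s$feature_id),
      paste0("PEPMASS=", sprintf("%.5f", s$precursor_mz)),
      paste0("RTINSECONDS=", sprintf("%.3f", s$rt_min * 60)),
      "CHARGE=1+",
      sprintf("%.5f %.4f", s$peaks[, "mz"], s$peaks[, "intensity"]),
      "END IONS"
    ), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path MGF file path.
#' @return List of [msms_spectrum()] objects (without sample intensities;
#'   those live in the feature table).
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  }
  lapply(seq_along(begins), function(i) {
    body <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    body <- body[nzchar(body)]
    is_header <- grepl("=", body, fixed = TRUE)
    headers <- body[is_header]
    keys <- toupper(sub("=.*$", "", headers))
    vals <- sub("^[^=]*=", "", headers)
    if (!"PEPMASS" %in% keys) stop("MGF block ", i, " missing PEPMASS")
    pep <- as.numeric(strsplit(vals[match("PEPMASS", keys)], "[ \t]+")[[1]][1])
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else paste0("spectrum_", i)
    rt_s <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[match("RTINSECONDS", keys)])
    } else NA_real_
    pk <- body[!is_header]
    if (length(pk) == 0L) stop("MGF block ", i, " has no peaks")
    mat <- do.call(rbind, lapply(strsplit(pk, "[ \t]+"), function(x) {
      as.numeric(x[1:2])
    }))
    if (anyNA(mat)) stop("malformed peak line in MGF block ", i)
    msms_spectrum(title, pep, rt_s / 60, mat)
  })
}

#' Write / read an MZmine-style feature table
#'
#' Columns: `feature_id`, `mz`, `rt_min`, then one intensity column per
#' sample.
#'
#' @param ft Data frame as described.
#' @param path CSV path.
#' @param samples Expected sample labels; reading errors if the file's
#'   intensity columns do not match.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the data frame.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(all(c("feature_id", "mz", "rt_min") %in% names(ft)))
  utils::write.csv(ft, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, samples = NULL) {
  ft <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("feature_id", "mz", "rt_min") %in% names(ft))) {
    stop("feature table must have feature_id, mz, rt_min columns")
  }
  got <- setdiff(names(ft), c("feature_id", "mz", "rt_min"))
  if (!is.null(samples) && !setequal(got, samples)) {
    stop("feature table sample columns (", paste(got, collapse = ", "),
         ") do not match expected (", paste(samples, collapse = ", "), ")")
  }
  ft
}

#' Attach feature-table intensities to spectra
#'
#' @param spectra List of [msms_spectrum()].
#' @param ft Feature table from [read_feature_table()].
#' @return The spectra with `sample_intensities` filled from matching
#'   `feature_id` rows; errors on ids absent from the table.
#' @export
attach_intensities <- function(spectra, ft) {
  samples <- setdiff(names(ft), c("feature_id", "mz", "rt_min"))
  lapply(spectra, function(s) {
    i <- match(s$feature_id, ft$feature_id)
    if (is.na(i)) stop("feature ", s$feature_id, " absent from feature table")
    s$sample_intensities <- stats::setNames(as.numeric(ft[i, samples]), samples)
    s
  })
}
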