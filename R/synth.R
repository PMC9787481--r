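#' @title Synthetic LC-HRMS/MS study generator
#' @description Emulates the two matrices of the sibiriline metabolism study —
#'   hepatocyte (HepaRG) culture supernatant sampled at incubation times
#'   H0/H8/H24/H48 and mouse plasma sampled 1 h and 3 h after intraperitoneal
#'   dosing — as MS/MS spectra plus per-sample feature intensities, so every
#'   downstream stage is testable without instrument data. Conjugate spectra
#'   inherit the parent fragment set unshifted (neutral-loss fragmentation
#'   typical of glucuronides and sulfates) plus a few precursor-shifted
#'   fragments, which is what links them to the parent in the network.
#' @name synth_study
NULL

# Fragment ions of the protonated parent used across all related spectra.
# 118.065 and 183.092 are the two diagnostic transitions of the parent.
.parent_fragments <- cbind(
  mz = c(91.0542, 118.0651, 130.0651, 156.0808, 167.0730, 183.0917,
         194.0839, 211.0871),
  intensity = c(30, 100, 45, 25, 20, 80, 35, 60)
)

#' Reference truth set: the parent and its 14 reported metabolites
#'
#' One row per isomer-resolved metabolite, with its biotransformation chain,
#' formula, protonated m/z, retention time and matrix presence, plus the two
#' external in silico predictor flags. The parent row has `chain = "parent"`.
#' The M8 m/z is the value implied by its own chain (2 x hydroxylation +
#' 2 x glucuronidation on the parent, C25H26N2O15, \[M+H\]+ 595.141); see the
#' package vignette for why a chain-inconsistent printed value is not used.
#'
#' @return Data frame with columns `id_hint`, `chain`, `formula`, `mz`,
#'   `rt_min`, `in_vivo`, `in_vitro`, `glx`, `bt3`, `kinetic_exception`.
#' @export
#' @examples
#' nrow(sibiriline_truth_set()) # parent + 14
sibiriline_truth_set <- function() {
  tab <- rbind(
    c("parent", "parent",                                  "C13H10N2O",   211.087, 5.8, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    c("M1a", "hydroxylation",                              "C13H10N2O2",  227.082, 5.0, TRUE,  FALSE, TRUE,  TRUE,  FALSE),
    c("M1b", "hydroxylation",                              "C13H10N2O2",  227.082, 5.2, TRUE,  FALSE, TRUE,  TRUE,  FALSE),
    c("M2a", "sulfation",                                  "C13H10N2O4S", 291.044, 4.4, FALSE, TRUE,  TRUE,  TRUE,  FALSE),
    c("M2b", "sulfation",                                  "C13H10N2O4S", 291.044, 5.2, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    c("M3a", "hydroxylation + sulfation",                  "C13H10N2O5S", 307.038, 4.4, FALSE, TRUE,  FALSE, TRUE,  FALSE),
    c("M3b", "hydroxylation + sulfation",                  "C13H10N2O5S", 307.038, 5.2, TRUE,  TRUE,  FALSE, TRUE,  FALSE),
    c("M4",  "2 \u00d7 methylation + sulfation",           "C15H14N2O4S", 319.075, 5.1, FALSE, TRUE,  FALSE, FALSE, FALSE),
    c("M5a", "glucuronidation",                            "C19H18N2O7",  387.119, 3.7, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    c("M5b", "glucuronidation",                            "C19H18N2O7",  387.119, 4.8, TRUE,  TRUE,  TRUE,  TRUE,  FALSE),
    c("M6a", "hydroxylation + glucuronidation",            "C19H18N2O8",  403.113, 4.1, TRUE,  TRUE,  FALSE, TRUE,  FALSE),
    c("M6b", "hydroxylation + glucuronidation",            "C19H18N2O8",  403.113, 4.3, TRUE,  TRUE,  FALSE, TRUE,  TRUE),
    c("M6c", "hydroxylation + glucuronidation",            "C19H18N2O8",  403.113, 5.0, FALSE, TRUE,  FALSE, TRUE,  FALSE),
    c("M7",  "2 \u00d7 methylation + glucuronidation",     "C21H22N2O7",  415.150, 4.3, FALSE, TRUE,  FALSE, FALSE, FALSE),
    c("M8",  "2 \u00d7 hydroxylation + 2 \u00d7 glucuronidation",
                                                           "C25H26N2O15", 595.141, 5.9, FALSE, TRUE,  FALSE, FALSE, FALSE)
  )
  data.frame(
    id_hint = tab[, 1], chain = tab[, 2], formula = tab[, 3],
    mz = as.numeric(tab[, 4]), rt_min = as.numeric(tab[, 5]),
    in_vivo = as.logical(tab[, 6]), in_vitro = as.logical(tab[, 7]),
    glx = as.logical(tab[, 8]), bt3 = as.logical(tab[, 9]),
    kinetic_exception = as.logical(tab[, 10]),
    stringsAsFactors = FALSE
  )
}

#' Default study design
#'
#' Two matrices: `invitro` (samples H0, H8, H24, H48 — incubation times of the
#' hepatocyte supernatant) and `invivo` (samples H1, H3 — plasma 1 h and 3 h
#' post dose). Metabolite intensities follow appearance-then-decline kinetics
#' in vitro and decline from H1 to H3 in vivo, except the one designated
#' exception isomer (M6b) which rises. Noise defaults stress the 0.02 Da
#' tolerance without breaking edges: precursor/fragment m/z jitter sd
#' 0.005 Da, intensity CV 0.2, 5 noise peaks per spectrum and 20 spectrally
#' unrelated decoy features per matrix.
#'
#' @param seed Integer seed governing all stochastic draws.
#' @param zero_noise If `TRUE`, m/z jitter, intensity noise and noise peaks
#'   are turned off and decoys reduced to 5; precursors equal truth m/z
#'   exactly.
#' @param mz_jitter_sd,intensity_cv,n_noise_peaks,n_decoy_features Noise
#'   parameters (see above).
#' @return A list with class `"study_design"`.
#' @export
default_study_design <- function(seed = 42L, zero_noise = FALSE,
                                 mz_jitter_sd = 0.005, intensity_cv = 0.2,
                                 n_noise_peaks = 5L, n_decoy_features = 20L) {
  if (zero_noise) {
    mz_jitter_sd <- 0
    intensity_cv <- 0
    n_noise_peaks <- 0L
    n_decoy_features <- 5L
  }
  stopifnot(mz_jitter_sd < 0.02)
  structure(
    list(
      truth = sibiriline_truth_set(),
      matrices = list(
        invitro = list(samples = c("H0", "H8", "H24", "H48"),
                       presence_col = "in_vitro"),
        invivo = list(samples = c("H1", "H3"), presence_col = "in_vivo")
      ),
      parent_fragments = .parent_fragments,
      noise = list(mz_jitter_sd = mz_jitter_sd, intensity_cv = intensity_cv,
                   n_noise_peaks = n_noise_peaks,
                   n_decoy_features = as.integer(n_decoy_features)),
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

# Deterministic per-entry intensity kinetics (arbitrary units). Shapes encode
# the qualitative study kinetics; magnitudes are free parameters.
.kinetic_shape <- function(entry, samples) {
  if (entry$chain == "parent") {
    base <- 1e6
    shape <- switch(paste(samples, collapse = ","),
      "H0,H8,H24,H48" = c(1, 0.65, 0.35, 0.15),
      "H1,H3" = c(0.8, 0.2)
    )
  } else {
    base <- 1e5 * (1 + 0.1 * entry$idx)
    shape <- switch(paste(samples, collapse = ","),
      "H0,H8,H24,H48" = c(0, 0.4, 1, 0.6),
      "H1,H3" = if (entry$kinetic_exception) c(0.4, 1) else c(1, 0.3)
    )
  }
  stats::setNames(base * shape, samples)
}

noisy <- function(x, cv) {
  if (cv <= 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), -sdlog^2 / 2, sdlog))
}

simulate_entry_spectrum <- function(entry, feature_id, samples, fragments,
                                    noise) {
  delta <- entry$mz - 211.087
  peaks <- fragments
  if (entry$chain != "parent") {
    # Conjugate spectra inherit an entry-specific subset of 6 of the 8 parent
    # fragments (always including the diagnostic 118.065 ion) with a mild
    # entry-specific intensity pattern, plus two precursor-shifted companions
    # and a few fragments unique to this metabolite. Distinct metabolites thus
    # keep >= 6 fragment ions in common with the parent while sharing fewer
    # with each other, as real conjugate spectra do.
    idx <- entry$idx
    rest <- setdiff(seq_len(nrow(fragments)), 2L)
    keep <- sort(c(2L, rest[((idx + seq_len(5) * 2) %% 7) + 1]))
    mod <- 0.7 + 0.6 * (((idx * 3 + seq_along(keep)) * 5) %% 7) / 6
    inherited <- cbind(mz = fragments[keep, "mz"],
                       intensity = fragments[keep, "intensity"] * mod)
    cidx <- setdiff(seq_len(nrow(fragments)), keep)
    shifted <- cbind(mz = fragments[cidx, "mz"] + delta,
                     intensity = fragments[cidx, "intensity"] * 0.5)
    nuniq <- 2L + idx %% 2L
    uniq <- cbind(
      mz = 80 + ((idx * 37.61 + 17.3 * seq_len(nuniq)) %% (entry$mz - 95)),
      intensity = 14
    )
    peaks <- rbind(inherited, shifted, uniq)
  }
  peaks[, "intensity"] <- noisy(peaks[, "intensity"], noise$intensity_cv)
  if (noise$mz_jitter_sd > 0) {
    peaks[, "mz"] <- peaks[, "mz"] +
      stats::rnorm(nrow(peaks), 0, noise$mz_jitter_sd)
  }
  if (noise$n_noise_peaks > 0) {
    npk <- cbind(mz = stats::runif(noise$n_noise_peaks, 80, entry$mz + 30),
                 intensity = stats::runif(noise$n_noise_peaks, 1, 15))
    peaks <- rbind(peaks, npk)
  }
  prec <- entry$mz + if (noise$mz_jitter_sd > 0) {
    stats::rnorm(1, 0, noise$mz_jitter_sd)
  } else 0
  inten <- noisy(.kinetic_shape(entry, samples), noise$intensity_cv)
  msms_spectrum(feature_id, prec, entry$rt_min, peaks, inten)
}

simulate_decoy_spectrum <- function(feature_id, samples) {
  prec <- stats::runif(1, 120, 680)
  n <- 8L
  peaks <- cbind(mz = sort(stats::runif(n, 60, prec)),
                 intensity = stats::runif(n, 10, 100))
  inten <- stats::setNames(stats::runif(length(samples), 1e4, 8e4), samples)
  msms_spectrum(feature_id, prec, round(stats::runif(1, 1, 14), 1), peaks,
                inten)
}

#' Simulate the synthetic study
#'
#' Deterministic for a fixed design seed: the RNG state is saved, seeded and
#' restored, and draws are consumed matrix by matrix (in vitro first), truth
#' entries in table order, then decoys.
#'
#' @param design A [default_study_design()] object.
#' @return A list with class `"synthetic_study"`: per matrix, `spectra` (list
#'   of [msms_spectrum()]) and `feature_table` (data frame), plus the design.
#' @export
#' @examples
#' study <- simulate_study(default_study_design(seed = 1, zero_noise = TRUE))
#' length(study$matrices$invitro$spectra)
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(design$seed) &&
      (design$noise$mz_jitter_sd > 0 || design$noise$intensity_cv > 0 ||
       design$noise$n_noise_peaks > 0 || design$noise$n_decoy_features > 0)) {
    stop("a seed is required when any stochastic component is enabled")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)

  truth <- design$truth
  truth$idx <- seq_len(nrow(truth))
  matrices <- lapply(names(design$matrices), function(mx) {
    m <- design$matrices[[mx]]
    present <- truth[truth[[m$presence_col]], , drop = FALSE]
    spectra <- lapply(seq_len(nrow(present)), function(i) {
      entry <- as.list(present[i, ])
      fid <- sprintf("%s_F%03d", mx, i)
      simulate_entry_spectrum(entry, fid, m$samples,
                              design$parent_fragments, design$noise)
    })
    nd <- design$noise$n_decoy_features
    if (nd > 0) {
      decoys <- lapply(seq_len(nd), function(i) {
        simulate_decoy_spectrum(sprintf("%s_D%03d", mx, i), m$samples)
      })
      spectra <- c(spectra, decoys)
    }
    ft <- do.call(rbind, lapply(spectra, function(s) {
      cbind(data.frame(feature_id = s$feature_id, mz = s$precursor_mz,
                       rt_min = s$rt_min, stringsAsFactors = FALSE),
            as.data.frame(as.list(s$sample_intensities)))
    }))
    list(spectra = spectra, feature_table = ft, samples = m$samples)
  })
  names(matrices) <- names(design$matrices)
  structure(list(matrices = matrices, design = design),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  for (mx in names(x$matrices)) {
    m <- x$matrices[[mx]]
    cat("  ", mx, ": ", length(m$spectra), " spectra, samples ",
        paste(m$samples, collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}
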