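#' @title Exact elemental-formula arithmetic
#' @description Elemental formulas are represented as named integer vectors
#'   (element symbol -> count) with class `"elemental_formula"`. All mass
#'   arithmetic is done at full double precision from a fixed monoisotopic
#'   isotope table embedded in the package, so results never depend on an
#'   external dependency's constants.
#' @name formula_engine
NULL

# Monoisotopic masses (Da) of the most abundant isotope. C is exactly 12 by
# definition of the unified atomic mass unit.
.isotope_masses <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

.hydrogen_atom_mass <- 1.0078250319
.proton_mass <- 1.00727646677

#' Mass conventions for protonated m/z computation
#'
#' Positive-mode \[M+H\]+ m/z can be computed by adding either the mass of a
#' hydrogen atom (neutral-mass bookkeeping, the convention behind most printed
#' metabolomics m/z tables) or the mass of a bare proton (physically exact,
#' accounting for the electron). The two differ by the electron mass
#' (~0.00055 Da); both constants lie in 1.0072--1.0079 Da.
#'
#' @param protonation_mode `"hydrogen-atom"` (default) or `"proton"`.
#' @return A list with class `"mass_conventions"`: the isotope table, the mode,
#'   and both adduct masses.
#' @export
#' @examples
#' mass_conventions()$hydrogen_atom_mass
mass_conventions <- function(protonation_mode = c("hydrogen-atom", "proton")) {
  protonation_mode <- match.arg(protonation_mode)
  structure(
    list(
      isotope_masses = .isotope_masses,
      protonation_mode = protonation_mode,
      hydrogen_atom_mass = .hydrogen_atom_mass,
      proton_mass = .proton_mass
    ),
    class = "mass_conventions"
  )
}

#' Parse an elemental formula string
#'
#' Accepts the plain dialect (`"C13H10N2O"`) and the underscore dialect
#' (`"C_13_H_10_N_2_O"`). Each element symbol may be followed by an optional
#' positive integer count; repeated symbols accumulate.
#'
#' @param text Formula string.
#' @return An `elemental_formula`: named integer vector of counts.
#' @export
#' @examples
#' parse_formula("C13H10N2O")
#' parse_formula("C_6_H_8_O_6_")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string")
  }
  clean <- gsub("_", "", text, fixed = TRUE)
  if (!nzchar(clean)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean, perl = TRUE)[[1]]
  tokens <- regmatches(clean, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(clean)) {
    stop("malformed formula string: ", text)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% names(.isotope_masses)) {
      stop("unknown element symbol '", sym, "' in formula ", text)
    }
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (is.na(n) || n <= 0L) stop("zero or negative count for ", sym, " in ", text)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  new_formula(counts)
}

new_formula <- function(counts) {
  counts <- counts[counts != 0L]
  if (any(counts < 0L)) stop("negative element count")
  # Hill order: C, H, then remaining elements alphabetically
  syms <- names(counts)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  structure(as.integer(counts[ord]), names = ord, class = "elemental_formula")
}

#' Format an elemental formula
#'
#' @param f An `elemental_formula`.
#' @param dialect `"plain"` (`C13H10N2O`) or `"underscore"` (`C_13_H_10_N_2_O`).
#' @return A single string; counts of 1 are omitted in the plain dialect.
#' @export
format_formula <- function(f, dialect = c("plain", "underscore")) {
  dialect <- match.arg(dialect)
  if (length(f) == 0L) return("")
  n <- unclass(f)
  if (dialect == "plain") {
    paste0(names(n), ifelse(n == 1L, "", n), collapse = "")
  } else {
    paste0(names(n), "_", n, "_", collapse = "")
  }
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "  (", round(monoisotopic_mass(x), 4),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
format.elemental_formula <- function(x, ...) format_formula(x)

#' Monoisotopic mass of a formula
#'
#' @param f An `elemental_formula` (or formula string).
#' @param conv A [mass_conventions()] object supplying the isotope table.
#' @return Mass in Da; the empty formula has mass 0.
#' @export
#' @examples
#' monoisotopic_mass(parse_formula("C6H8O6")) # 176.0321
monoisotopic_mass <- function(f, conv = mass_conventions()) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  masses <- conv$isotope_masses[names(f)]
  if (anyNA(masses)) {
    stop("element(s) absent from isotope table: ",
         paste(names(f)[is.na(masses)], collapse = ", "))
  }
  sum(unclass(f) * masses)
}

#' Protonated m/z of a formula
#'
#' Neutral monoisotopic mass plus the hydrogen-atom mass (default convention,
#' the one behind printed metabolite m/z tables) or plus the proton mass,
#' depending on `conv$protonation_mode`.
#'
#' @inheritParams monoisotopic_mass
#' @return \[M+H\]+ m/z in Da (charge 1).
#' @export
#' @examples
#' protonated_mz(parse_formula("C13H10N2O")) # 211.0871
protonated_mz <- function(f, conv = mass_conventions()) {
  adduct <- switch(conv$protonation_mode,
    "hydrogen-atom" = conv$hydrogen_atom_mass,
    "proton" = conv$proton_mass
  )
  monoisotopic_mass(f, conv) + adduct
}

#' Apply a signed elemental delta to a formula
#'
#' @param f An `elemental_formula` (or string).
#' @param delta Named numeric/integer vector of signed element changes,
#'   e.g. `c(O = 1)` or `c(C = -6, H = -4, O = -1)`; may also be an
#'   `elemental_formula` (all-positive delta).
#' @return The combined `elemental_formula`.
#'   Errors with class `"infeasible_transformation"` if any resulting count
#'   would be negative, signalling a rule not applicable to this formula.
#' @export
#' @examples
#' combine_formula(parse_formula("C13H10N2O"), c(C = 6, H = 8, O = 6))
combine_formula <- function(f, delta) {
  f <- as_formula(f)
  d <- if (inherits(delta, "elemental_formula")) unclass(delta) else delta
  if (length(d) > 0 && (is.null(names(d)) || any(!nzchar(names(d))))) {
    stop("delta must be a named vector")
  }
  syms <- union(names(f), names(d))
  out <- stats::setNames(integer(length(syms)), syms)
  out[names(f)] <- out[names(f)] + unclass(f)
  out[names(d)] <- out[names(d)] + as.integer(d)
  if (any(out < 0L)) {
    stop(structure(
      class = c("infeasible_transformation", "error", "condition"),
      list(message = paste0(
             "transformation would give negative count for ",
             paste(syms[out < 0L], collapse = ", ")),
           call = sys.call(-1))
    ))
  }
  new_formula(out)
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) f else parse_formula(f)
}
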