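#' @title Rule-based phase I/II metabolite prediction
#' @description A small reaction-rule engine working at the elemental-formula /
#'   functional-group level. Each rule carries an elemental delta, a metabolic
#'   phase, an enzyme label, a site requirement over the functional-group
#'   profile of the substrate, and the group adjustments it makes when it
#'   fires. Candidates are enumerated breadth-first over rule chains.
#' @name insilico_rules
NULL

#' Construct a biotransformation rule
#'
#' @param name Reaction label, e.g. `"O-glucuronidation"`.
#' @param family Generic reaction family used for chain naming and mass-shift
#'   annotation (`"hydroxylation"`, `"oxidation"`, `"methylation"`,
#'   `"sulfation"`, `"glucuronidation"`, ...).
#' @param phase `"I"` or `"II"`.
#' @param delta Named signed element mapping, e.g. `c(C = 6, H = 8, O = 6)`.
#' @param site_requirement Name of the functional-group count that must be
#'   positive for the rule to fire, or `"none"`.
#' @param enzyme_label Free-text enzyme annotation.
#' @param consumes,produces Named integer vectors of functional-group
#'   adjustments applied after the rule fires.
#' @param enabled Logical; low-confidence rules ship disabled.
#' @param priority Small integer used only for ordering candidates.
#' @return A list with class `"bt_rule"`.
#' @export
bt_rule <- function(name, family, phase, delta, site_requirement = "none",
                    enzyme_label = "", consumes = NULL, produces = NULL,
                    enabled = TRUE, priority = 99L) {
  stopifnot(phase %in% c("I", "II"))
  structure(
    list(name = name, family = family, phase = phase, delta = delta,
         site_requirement = site_requirement, enzyme_label = enzyme_label,
         consumes = consumes, produces = produces, enabled = enabled,
         priority = as.integer(priority)),
    class = "bt_rule"
  )
}

#' Default phase I/II biotransformation rule set
#'
#' The six base reactions seen in hepatic xenobiotic metabolism of a phenolic
#' parent: aromatic hydroxylation and N-oxidation (phase I), O-/N-glucuronidation,
#' sulfation and O-methylation (phase II). Site requirements are expressed over
#' the [functional-group profile][profile_from_smiles]: conjugations of the
#' phenol consume a phenol OH, hydroxylation consumes an aromatic CH and
#' creates a new phenol OH.
#'
#' @param include_low_confidence Also include the disabled-by-default
#'   quinone-formation and ring-cleavage rules (formula-level stand-ins for two
#'   low-scoring predicted products, kept out of default chains).
#' @return List of [bt_rule()] objects.
#' @export
#' @examples
#' vapply(default_ruleset(), `[[`, "", "name")
default_ruleset <- function(include_low_confidence = FALSE) {
  rules <- list(
    bt_rule("O-glucuronidation", "glucuronidation", "II",
            c(C = 6, H = 8, O = 6), "phenol_oh",
            "UDP-glucuronosyltransferase",
            consumes = c(phenol_oh = 1), priority = 1L),
    bt_rule("sulfation", "sulfation", "II",
            c(S = 1, O = 3), "phenol_oh",
            "Aryl sulfotransferase",
            consumes = c(phenol_oh = 1), priority = 2L),
    bt_rule("O-methylation", "methylation", "II",
            c(C = 1, H = 2), "phenol_oh",
            "Catechol O-methyltransferase",
            consumes = c(phenol_oh = 1), priority = 5L),
    bt_rule("N-glucuronidation", "glucuronidation", "II",
            c(C = 6, H = 8, O = 6), "secondary_nh",
            "UDP-glucuronosyltransferase",
            consumes = c(secondary_nh = 1), priority = 6L),
    bt_rule("aromatic hydroxylation", "hydroxylation", "I",
            c(O = 1), "aromatic_ch",
            "CYP1A2",
            consumes = c(aromatic_ch = 1), produces = c(phenol_oh = 1),
            priority = 3L),
    bt_rule("N-oxidation", "oxidation", "I",
            c(O = 1), "basic_ring_n",
            "CYP2C8",
            consumes = c(basic_ring_n = 1), priority = 4L)
  )
  if (include_low_confidence) {
    rules <- c(rules, list(
      bt_rule("oxidation of 4-substituted phenol to quinone", "cleavage", "I",
              c(C = -7, H = -6, N = -2, O = 1), "phenol_oh",
              "low-confidence", enabled = FALSE, priority = 90L),
      bt_rule("ring cleavage", "cleavage", "I",
              c(C = -6, H = -4, O = -1), "none",
              "low-confidence", enabled = FALSE, priority = 91L)
    ))
  }
  rules
}

.group_smarts <- c(
  phenol_oh = "[OX2H]c",
  aromatic_ch = "[cH]",
  basic_ring_n = "[nX2H0]",
  secondary_nh = "[NX3;H1;!$([nH])]"
)

#' Functional-group profile of a molecule from its SMILES
#'
#' Counts the metabolically relevant sites by SMARTS substructure search
#' (OpenBabel via ChemmineOB): phenolic OH, aromatic CH, pyridine-type ring N,
#' non-aromatic secondary NH, plus a catechol flag.
#'
#' @param smiles A single SMILES string.
#' @return Named list: `phenol_oh`, `aromatic_ch`, `basic_ring_n`,
#'   `secondary_nh` counts and logical `catechol`.
#' @export
#' @examples
#' \dontrun{profile_from_smiles("Oc1ccc(O)cc1")}
profile_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("profile_from_smiles requires the ChemmineOB package")
  }
  mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  counts <- vapply(.group_smarts, function(p) {
    as.numeric(ChemmineOB::smartsSearch_OB(mol, p, uniqueMatches = FALSE))
  }, numeric(1))
  if (all(counts == 0) &&
      ChemmineOB::prop_OB(mol)$cansmi %in% c("", NA)) {
    stop("unparseable SMILES: ", smiles)
  }
  cat_n <- as.numeric(ChemmineOB::smartsSearch_OB(
    mol, "[OX2H]c1ccccc1[OX2H]", uniqueMatches = FALSE))
  list(phenol_oh = counts[["phenol_oh"]],
       aromatic_ch = counts[["aromatic_ch"]],
       basic_ring_n = counts[["basic_ring_n"]],
       secondary_nh = counts[["secondary_nh"]],
       catechol = cat_n > 0)
}

rule_applicable <- function(rule, profile) {
  req <- rule$site_requirement
  if (identical(req, "none")) return(TRUE)
  !is.null(profile[[req]]) && profile[[req]] >= 1
}

apply_rule_to_profile <- function(rule, profile) {
  for (g in names(rule$consumes)) profile[[g]] <- profile[[g]] - rule$consumes[[g]]
  for (g in names(rule$produces)) {
    profile[[g]] <- (if (is.null(profile[[g]])) 0 else profile[[g]]) + rule$produces[[g]]
  }
  if (any(unlist(profile[setdiff(names(profile), "catechol")]) < 0)) {
    stop("rule drove a functional-group count below zero")
  }
  profile
}

#' Canonical display name of a biotransformation chain
#'
#' Multiplicities are collapsed (`"2 × methylation + sulfation"`) and
#' families ordered phase I first, then methylation, sulfation,
#' glucuronidation, matching conventional metabolite-table naming.
#'
#' @param families Character vector of reaction families (one entry per
#'   applied rule, order-free).
#' @return A single string; `"parent"` for an empty chain.
#' @export
chain_name <- function(families) {
  if (length(families) == 0L) return("parent")
  order_key <- c(hydroxylation = 1, oxidation = 2, methylation = 3,
                 sulfation = 4, glucuronidation = 5, cleavage = 6)
  tab <- table(families)
  fams <- names(tab)
  fams <- fams[order(ifelse(is.na(order_key[fams]), 99, order_key[fams]), fams)]
  parts <- vapply(fams, function(f) {
    k <- tab[[f]]
    if (k == 1L) f else paste0(k, " \u00d7 ", f)
  }, character(1))
  paste(parts, collapse = " + ")
}

#' Enumerate metabolite candidates by chaining rules
#'
#' Breadth-first enumeration of rule chains up to `max_steps` applications.
#' Site requirements are enforced and the functional-group profile updated
#' after each step (hydroxylation creates a phenol OH that later conjugation
#' can consume). Candidates are deduplicated on (formula, rule-name multiset)
#' and sorted by ascending m/z then chain length.
#'
#' @param parent_formula `elemental_formula` (or string) of the parent drug.
#' @param profile Functional-group profile, e.g. from [profile_from_smiles()].
#' @param rules List of [bt_rule()]; disabled rules are skipped.
#' @param max_steps Maximum number of rule applications per chain (>= 1).
#' @param conv [mass_conventions()].
#' @return A data frame with class `"metabolite_candidates"`: columns `chain`
#'   (canonical family chain), `rule_chain` (specific rule names, `" + "`
#'   joined in application order), `formula`, `mz`, `shift`, `phase`
#'   (`I-only`/`II-only`/`mixed`), `n_steps`, `isomer_multiplicity`,
#'   `priority`.
#' @export
predict_metabolites <- function(parent_formula, profile,
                                rules = default_ruleset(), max_steps = 2L,
                                conv = mass_conventions()) {
  stopifnot(max_steps >= 1L)
  rules <- Filter(function(r) isTRUE(r$enabled), rules)
  if (length(rules) == 0L) stop("empty ruleset")
  parent_formula <- as_formula(parent_formula)
  parent_mz <- protonated_mz(parent_formula, conv)

  state_key <- function(formula, rule_names) {
    paste(format_formula(formula), paste(sort(rule_names), collapse = "|"),
          sep = "::")
  }
  frontier <- list(list(formula = parent_formula, profile = profile,
                        chain = character(0), fams = character(0),
                        mult = 1, prio = Inf))
  seen <- character(0)
  out <- list()
  for (step in seq_len(max_steps)) {
    nxt <- list()
    for (st in frontier) {
      for (r in rules) {
        if (!rule_applicable(r, st$profile)) next
        f2 <- tryCatch(combine_formula(st$formula, r$delta),
                       infeasible_transformation = function(e) NULL)
        if (is.null(f2)) next
        key <- state_key(f2, c(st$chain, r$name))
        if (key %in% seen) next
        seen <- c(seen, key)
        sites <- if (identical(r$site_requirement, "none")) 1
                 else st$profile[[r$site_requirement]]
        cand <- list(
          formula = f2,
          profile = apply_rule_to_profile(r, st$profile),
          chain = c(st$chain, r$name),
          fams = c(st$fams, r$family),
          mult = st$mult * sites,
          prio = min(st$prio, r$priority)
        )
        nxt[[length(nxt) + 1L]] <- cand
        out[[length(out) + 1L]] <- cand
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }

  phases <- vapply(rules, `[[`, "", "phase")
  names(phases) <- vapply(rules, `[[`, "", "name")
  rows <- lapply(out, function(cand) {
    mz <- protonated_mz(cand$formula, conv)
    ph <- unique(phases[cand$chain])
    data.frame(
      chain = chain_name(cand$fams),
      rule_chain = paste(cand$chain, collapse = " + "),
      formula = format_formula(cand$formula),
      mz = mz,
      shift = mz - parent_mz,
      phase = if (length(ph) > 1) "mixed" else paste0(ph, "-only"),
      n_steps = length(cand$chain),
      isomer_multiplicity = cand$mult,
      priority = cand$prio,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$mz, res$n_steps, res$priority, res$rule_chain), ]
  rownames(res) <- NULL
  class(res) <- c("metabolite_candidates", "data.frame")
  res
}

#' @export
print.metabolite_candidates <- function(x, ...) {
  cat("Metabolite candidates:", nrow(x), "chains\n")
  y <- as.data.frame(x)
  y$mz <- round(y$mz, 4)
  y$shift <- round(y$shift, 3)
  print(y[, c("chain", "formula", "mz", "shift", "phase", "n_steps")], ...)
  invisible(x)
}
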