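---
title: "Methods: cross-sectional metabolite elucidation with xenonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-sectional metabolite elucidation with xenonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenonet)
```

# The problem and the approach

Identifying the metabolites of a new drug candidate from untargeted LC-HRMS/MS
data is a triangulation exercise: no single line of evidence is conclusive.
xenonet implements the cross-sectional strategy in which (i) a rule engine
predicts which phase I/II products are chemically plausible for the parent
structure, (ii) MS/MS molecular networks of an in vitro hepatocyte matrix and
an in vivo plasma matrix group spectrally related ions, (iii) precursor mass
shifts between the parent node and its neighbours are read as
biotransformation reactions, and (iv) the three evidence streams are merged
into one metabolite table. The built-in study is sibiriline (C13H10N2O,
[M+H]+ 211.0871), a phenolic RIPK1 inhibitor whose metabolism is dominated by
glucuronidation and sulfation of the phenol.

# Mass conventions

All masses come from a fixed monoisotopic table embedded in the package
(C = 12 exactly, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
S = 31.97207069 Da), so results cannot drift with an external dependency's
constants. Protonated m/z defaults to neutral mass + hydrogen-atom mass
(1.00783 Da) rather than + proton mass (1.00728 Da): published metabolite
tables in this field are computed with the hydrogen-atom convention (the
parent prints as 211.0871, not 211.0866), and bit-compatibility with printed
values matters more here than the 0.55 mDa electron-mass correction. The
physically exact proton mode is available via
`mass_conventions("proton")`. Internal arithmetic is double precision;
display rounds shifts to 3 dp and m/z to 4 dp, matching table practice.

# The in silico rule engine

Rules operate at the elemental-formula / functional-group level, not on
atom-mapped structures. Each rule carries an elemental delta, a site
requirement over a functional-group profile (phenolic OH, aromatic CH,
pyridine-type ring N, non-aromatic secondary NH, counted by SMARTS search on
the parent SMILES via OpenBabel), and the group adjustments it makes:
conjugation consumes a phenol OH, hydroxylation consumes an aromatic CH and
creates a phenol OH — which is exactly what licenses chains like
hydroxylation followed by a second glucuronidation. The justification for
staying at formula level is that high-resolution mass shifts distinguish
formulas, not regiochemistry: the six distinct aromatic hydroxylation sites
of the parent all collapse to C13H10N2O2 at m/z 227.082, so candidates carry
an isomer-multiplicity attribute instead of per-site products. Probability
scores of external predictors are out of scope; candidates are ordered by a
fixed rule-priority rank (phenol conjugations first) purely for stable
output. Two low-confidence transformations (quinone formation with ring
loss, ring cleavage) are shipped disabled because the products they would
generate are inconsistent with the parent's conjugation-dominated chemistry;
enabling them is a one-argument opt-in.

`max_steps` defaults to 2 — enough for every conjugate with in silico support
in the reference study — and must be raised to 4 to reach the deepest chain
(2 × hydroxylation + 2 × glucuronidation, C25H26N2O15).

# Molecular networking

Similarity is the modified (shift-tolerant) cosine: intensities are
square-root transformed (damping the dominance of base peaks, standard
networking practice) and L2-normalised; candidate peak pairs match either
directly within the 0.02 Da fragment tolerance or offset by the precursor
mass difference; a greedy one-to-one assignment by descending intensity
product yields the score. The greedy assignment is checked in the test suite
against an exhaustive-optimum oracle on small spectra (equality on the
shipped toys, ≥ 0.95 of the optimum on random cases). Whether the original
networking runs scored plain or modified cosine is not documentable from the
study description alone; both modes are implemented
(`network_params(score_mode = )`) and the shifted mode is the default because
the observed networks link precursors differing by large conjugation shifts,
which plain cosine cannot do when fragment sets shift with the precursor.

Edges require score > 0.70 and ≥ 6 matched ions; surviving edges are pruned
to mutual top-10 neighbourhoods, in that order (filter first, then top-k).
Ranking ties break by smaller absolute precursor shift, then smaller node id,
so networks are deterministic for a fixed input. Minimum cluster size
defaults to 1 (singletons kept). Tolerances are 0.02 Da for fragments and
precursors — high-resolution orbitrap settings.

# Mass-shift annotation

The delta library enumerates all multisets of up to `max_depth = 4`
applications of the four base reaction families (hydroxylation, methylation,
sulfation, glucuronidation), deduplicated by delta formula — 69 distinct
deltas. Depth counts rule applications, so the four-reaction chain above
needs depth 4. Hydroxylation and N-oxidation share +O and collapse to a
single library entry; at formula level they are indistinguishable.

Propagation starts from a user-identified parent node (by id, feature id, or
nearest precursor m/z — standing in for spectral-library identification) and
walks its connected component. Each node gets the chain minimising the
absolute error between its precursor shift from the parent and a library
delta, accepted within `delta_tol = 0.01` Da; ties go to the shorter chain.
The tolerance is tighter than the 0.02 fragment tolerance because precursor
masses are high-resolution and the printed shift table is given to 3 dp.
Direct parent-to-node shifts are matched first; this also covers the
composite readings seen across multi-edge paths, since a path's cumulative
delta equals the direct precursor difference. Negative shifts are never
assigned (no rule removes mass in the default families), which is what keeps
decoy nodes and in-source artefacts unannotated.

## A deliberate departure from the printed reference table

The reference metabolite table prints the deepest metabolite (M8, 2 ×
hydroxylation + 2 × glucuronidation) at m/z 595.183 with shift 384.096. That
value is irreconcilable with its own chain: the chain's delta formula
C12H16O13 has monoisotopic mass 384.054, and C25H26N2O15 [M+H]+ computes to
595.141 under either protonation convention. (The related in-text reading of
"+192.060" between 403.113 and 595.183 disagrees with the rule-derived
192.027 by the same 42 mDa.) The package's truth set therefore carries M8 at
the chain-consistent 595.141; every other row uses the printed m/z, which
agrees with its chain to < 2 mDa. With the printed value, no annotation
within 0.01 Da is possible and the full-table reconstruction would be
unreachable by any faithful algorithm — a documented inconsistency, not a
tuning choice.

# The synthetic study generator

`default_study_design()` encodes the study conditions: an in vitro matrix
with incubation timepoints H0/H8/H24/H48, an in vivo matrix with plasma at
1 h and 3 h after a 5 mg/kg IP dose, the parent at m/z 211.087 / RT 5.8 min
with its eight reference fragments (including the diagnostic 118.065 and
183.092 transitions), and the 14 isomer-resolved truth metabolites with their
published m/z, RT and matrix presence. Conjugates fragment by neutral loss of
the conjugate moiety, so each metabolite spectrum inherits six of the eight
parent fragments (an entry-specific subset with an entry-specific intensity
pattern) plus the two remaining fragments shifted by the biotransformation
delta and a few fragments unique to the metabolite. This reproduces the two
structural facts the pipeline depends on: every metabolite shares ≥ 6
fragment ions with the parent, while two different metabolites share fewer
ions with each other than either does with the parent — without the second
property, near-duplicate conjugate spectra would crowd the parent out of the
mutual top-10 neighbourhoods.

Intensity kinetics are deterministic shapes scaled per entry:
appearance-then-decline in vitro (zero at H0, peak at H24), decline from H1
to H3 in vivo for all metabolites except one designated isomer of the
hydroxy-glucuronide (m/z 403.113, RT 4.3) which rises — the one exception
reported in the reference study. Noise defaults stress the tolerances
without breaking the network: m/z jitter sd 0.005 Da on fragments and
precursors, log-normal intensity noise with CV 0.2, five noise peaks per
spectrum, and 20 spectrally unrelated decoy features per matrix. All draws
run from a single seed with a fixed stream order (matrices in declaration
order, truth entries in table order, then decoys), so a design plus seed is
byte-reproducible down to the MGF output.

What the generator does **not** emulate: chromatographic peak shapes (RT is
metadata), isotope patterns, adducts other than [M+H]+, in-source
fragmentation, co-eluting background, or realistic precursor-intensity
dynamics. Passing tests therefore demonstrate algorithmic correctness of the
pipeline on data with known ground truth — not robustness to every artefact
of real acquisitions. Precursor jitter in the noisy default regime
deliberately exceeds the 0.01 Da annotation tolerance in ~15 % of draws, so
noisy runs exercise the unassigned path; identity claims (100 % recall, 0 %
decoy assignment) hold on the zero-noise configuration.

# Pharmacokinetics

The simulation model is the standard one-compartment, first-order absorption
form; `ka = Inf` gives the bolus limit, and `ka = ke` is rejected as
degenerate. The scenario (`pk_scenario()`) uses the published design — 5
mg/kg IP, sampling at 15/30/60/120/180/240 min — with ke = ln 2/21 per min
and V/F = 3247 mL/kg, and a default absorption rate ka = 0.5 per min chosen
once on realism grounds: IP uptake of a small hydrophilic molecule in
solution is fast, and the resulting Tmax ≈ 5.8 min is consistent with the
peak being observed at the first 15-min sample.

NCA follows standard practice: λz from the best-adjusted-R² log-linear fit
over suffixes of ≥ 3 points strictly after Tmax; linear-up/log-down
trapezoids; AUC∞ = AUC_last + C_last/λz. Because the first sample falls a
whole elimination half-life after dosing, the absorption-phase AUC is not
observable from the samples themselves: with the extravascular convention
C(0) = 0 the linear first segment misses the early peak and Vz/F is biased
high by ~20–40 % depending on ka. `nca(c0 = "extrapolate")` therefore offers
the bolus-style treatment — back-extrapolating C0 from the terminal fit —
which is appropriate whenever absorption is essentially complete before the
first sample. Its residual bias is −ke/ka (the back-extrapolated intercept
overshoots D/V by ka/(ka−ke)): about −7 % at the scenario's ka = 0.5 and
−0.3 % in the fast-absorption limit (ka = 10) used for the noiseless
recovery check. This absorption-phase bias is inherent to the sampling
schedule, not to the estimator, and is reported rather than hidden. All
volume/clearance outputs are /F quantities, since bioavailability is
inseparable for IP dosing.

# Problem sizes and determinism

The shipped tests and the acceptance script run the study at its natural
size: 33 + 29 spectra in the two noisy matrices (18 + 14 at zero noise), a
69-entry delta library, and 200 noise replicates for PK recovery — a few
seconds end to end. Networks, reports and MGF outputs are byte-identical
for a fixed seed; the CLI (`inst/exec/xenonet`) exposes each stage with
`--seed`, `--config` (YAML) and `--out`.

# Known limitations

At formula level, isomers are distinguishable only by RT; regiochemistry and
MS/MS fragment-level structure assignment are out of scope, as is spectral
library matching (the parent is user-identified). The kinetics module is
semi-quantitative by design — raw feature intensities, no statistical
testing, matching the descriptive use of multi-matrix networks. Quantitative
cross-species extrapolation of the PK estimates is not attempted.
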