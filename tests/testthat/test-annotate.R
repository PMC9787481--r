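test_that("the delta library reproduces the biotransformation shift table", {
  lib1 <- build_delta_library(max_depth = 1)
  expect_equal(nrow(lib1), 4)
  expect_setequal(round(lib1$delta_mass, 3),
                  c(15.995, 14.016, 79.957, 176.032))
  lib <- build_delta_library(max_depth = 4)
  get <- function(name) lib$delta_mass[lib$name == name]
  expect_equal(round(get("2 × methylation + sulfation"), 3), 107.988)
  expect_equal(round(get("hydroxylation + glucuronidation"), 3), 192.027)
  expect_equal(round(get("hydroxylation + sulfation"), 3), 95.952)
  expect_equal(round(get("2 × methylation + glucuronidation"), 3), 204.063)
  expect_equal(round(get("2 × hydroxylation + 2 × glucuronidation"), 3),
               384.054)
  expect_false(any(duplicated(lib$delta_formula)))
  expect_true(all(lib$delta_mass > 0))
})

test_that("edges are annotated by nearest in-tolerance delta", {
  s <- list(
    msms_spectrum("p", 211.087, 5.8, cbind(mz = 1:6 * 20 + 10, intensity = 50)),
    msms_spectrum("g", 387.119, 3.7, cbind(mz = 1:6 * 20 + 10, intensity = 50)),
    msms_spectrum("s", 291.043, 4.4, cbind(mz = 1:6 * 20 + 10, intensity = 50)),
    msms_spectrum("x", 261.087, 6.0, cbind(mz = 1:6 * 20 + 10, intensity = 50))
  )
  net <- annotate_edges(build_network(s), build_delta_library(max_depth = 4))
  e <- net$edges
  lab <- function(i, j) e$reaction[(e$source == i & e$target == j) |
                                     (e$source == j & e$target == i)]
  expect_equal(lab(1, 2), "glucuronidation")
  expect_equal(lab(1, 3), "sulfation")
  expect_equal(lab(1, 4), "unannotated") # +50.000 matches no reaction
})

test_that("propagation from the parent recovers truth chains and no decoys", {
  study <- simulate_study(default_study_design(seed = 6, zero_noise = TRUE))
  tr <- sibiriline_truth_set()
  lib <- build_delta_library(max_depth = 4)
  for (mx in c("invitro", "invivo")) {
    net <- build_network(study$matrices[[mx]]$spectra)
    ann <- propagate_from_parent(net, 211.087, "C13H10N2O", lib)
    truth <- tr[tr[[study$design$matrices[[mx]]$presence_col]] &
                  tr$chain != "parent", ]
    met <- ann[!ann$is_parent & grepl("_F", ann$feature_id), ]
    met <- met[order(met$node), ]
    expect_equal(nrow(met), nrow(truth))
    expect_true(all(met$assigned))
    expect_equal(met$chain, truth$chain)
    expect_equal(met$formula, truth$formula)
    # chain-mass consistency
    parent_mz <- ann$mz[ann$is_parent]
    for (i in seq_len(nrow(met))) {
      chain_mass <- lib$delta_mass[lib$name == met$chain[i]]
      expect_lte(abs((met$mz[i] - parent_mz) - chain_mass), 0.01)
    }
    decoys <- ann[grepl("_D", ann$feature_id), ]
    expect_true(all(!decoys$assigned))
  }
})

test_that("a spectrally linked node with a nonsense shift stays unassigned", {
  peaks <- cbind(mz = 1:7 * 15 + 20, intensity = 60)
  s <- list(
    msms_spectrum("parent", 211.087, 5.8, peaks),
    msms_spectrum("decoy", 244.420, 6.0, peaks) # shift 33.333
  )
  net <- build_network(s)
  expect_equal(nrow(net$edges), 1) # identical fragments: spectrally linked
  ann <- propagate_from_parent(net, "parent", "C13H10N2O",
                               build_delta_library(max_depth = 4))
  expect_false(ann$assigned[ann$feature_id == "decoy"])
})

test_that("annotation is invariant to node enumeration order", {
  study <- simulate_study(default_study_design(seed = 6, zero_noise = TRUE))
  sp <- study$matrices$invivo$spectra
  lib <- build_delta_library(max_depth = 4)
  ann1 <- propagate_from_parent(build_network(sp), 211.087, "C13H10N2O", lib)
  set.seed(1)
  perm <- sample(seq_along(sp))
  ann2 <- propagate_from_parent(build_network(sp[perm]), 211.087,
                                "C13H10N2O", lib)
  a1 <- as.data.frame(ann1)[order(ann1$feature_id),
                            c("feature_id", "assigned", "chain", "formula")]
  a2 <- as.data.frame(ann2)[order(ann2$feature_id),
                            c("feature_id", "assigned", "chain", "formula")]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("propagation requires the parent to be in the network", {
  s <- list(msms_spectrum("a", 300, 1, cbind(mz = 150, intensity = 10)))
  net <- build_network(s)
  expect_error(propagate_from_parent(net, 211.087, "C13H10N2O"),
               "no network node")
  expect_error(propagate_from_parent(net, "missing", "C13H10N2O"),
               "not in network")
})

test_that("in silico cross-referencing flags supported annotations", {
  study <- simulate_study(default_study_design(seed = 6, zero_noise = TRUE))
  net <- build_network(study$matrices$invitro$spectra)
  ann <- propagate_from_parent(net, 211.087, "C13H10N2O",
                               build_delta_library(max_depth = 4))
  cand <- predict_metabolites("C13H10N2O", sibiriline_profile(), max_steps = 2)
  out <- match_to_insilico(ann, cand)
  sup <- function(mz) out$insilico_support[round(out$mz, 3) == mz & out$assigned]
  expect_true(all(sup(403.113)))
  expect_true(all(sup(387.119)))
  # the dimethylated conjugates have no depth-2 rule chain
  expect_false(any(sup(319.075)))
  expect_false(any(sup(415.150)))
  agree <- out$insilico_agreement[round(out$mz, 3) == 403.113 & out$assigned]
  expect_true(all(agree))
  # empty candidate set leaves all flags unset
  none <- match_to_insilico(ann, cand[0, ])
  expect_false(any(none$insilico_support))
})
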