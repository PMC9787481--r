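toy_spectrum <- function(id, prec, mz, int, rt = 1) {
  msms_spectrum(id, prec, rt, cbind(mz = mz, intensity = int))
}

test_that("self-similarity is 1 with every peak matched", {
  s <- toy_spectrum("a", 211.087, c(91.05, 118.07, 183.09, 211.09),
                    c(30, 100, 80, 60))
  sim <- spectral_similarity(s, s)
  expect_equal(sim$score, 1, tolerance = 1e-9)
  expect_equal(sim$matched, 4L)
})

test_that("disjoint spectra score zero", {
  a <- toy_spectrum("a", 200, c(101, 120), c(10, 10))
  b <- toy_spectrum("b", 200, c(150, 170), c(10, 10))
  sim <- spectral_similarity(a, b)
  expect_equal(sim$score, 0)
  expect_equal(sim$matched, 0L)
})

test_that("shifted mode matches fragment pairs offset by the precursor delta", {
  # 4-peak toy: one directly shared peak, one peak shifted by the precursor
  # difference (+176.032), two unrelated peaks
  a <- toy_spectrum("a", 211.087, c(118.065, 150.00, 183.092, 190.00),
                    c(100, 20, 80, 10))
  b <- toy_spectrum("b", 387.119, c(118.065, 240.00, 359.124, 380.00),
                    c(90, 15, 70, 12))
  sim <- spectral_similarity(a, b)
  expect_equal(sim$matched, 2L)
  oracle <- brute_force_similarity(a, b)
  expect_equal(sim$score, oracle$score, tolerance = 1e-12)
  unshifted <- spectral_similarity(a, b, network_params(score_mode = "unshifted"))
  expect_equal(unshifted$matched, 1L)
  expect_lt(unshifted$score, sim$score)
})

test_that("similarity is symmetric, bounded and scale-invariant", {
  set.seed(21)
  for (i in 1:20) {
    a <- random_spectrum("a")
    b <- random_spectrum("b")
    s1 <- spectral_similarity(a, b)
    s2 <- spectral_similarity(b, a)
    expect_equal(s1$score, s2$score, tolerance = 1e-12)
    expect_equal(s1$matched, s2$matched)
    expect_gte(s1$score, 0)
    expect_lte(s1$score, 1)
    b_scaled <- b
    b_scaled$peaks[, "intensity"] <- b$peaks[, "intensity"] * 37.5
    expect_equal(spectral_similarity(a, b_scaled)$score, s1$score,
                 tolerance = 1e-12)
  }
})

test_that("greedy assignment tracks the exhaustive optimum", {
  set.seed(33)
  worst <- 1
  for (i in 1:40) {
    a <- random_spectrum("a", n_peaks = sample(3:8, 1))
    b <- random_spectrum("b", n_peaks = sample(3:8, 1))
    # compress m/z so collisions actually occur
    a$peaks[, "mz"] <- 100 + (a$peaks[, "mz"] %% 3)
    b$peaks[, "mz"] <- 100 + (b$peaks[, "mz"] %% 3)
    a$peaks <- a$peaks[order(a$peaks[, "mz"]), ]
    b$peaks <- b$peaks[order(b$peaks[, "mz"]), ]
    g <- spectral_similarity(a, b)
    o <- brute_force_similarity(a, b)
    expect_lte(g$score, o$score + 1e-12)
    if (o$score > 0) worst <- min(worst, g$score / o$score)
  }
  expect_gte(worst, 0.95)
})

test_that("two identical spectra give one zero-shift edge", {
  s1 <- toy_spectrum("a", 211.087, c(91.05, 118.07, 130.07, 156.08, 183.09,
                                     211.09), rep(50, 6))
  s2 <- s1
  s2$feature_id <- "b"
  net <- build_network(list(s1, s2))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$shift, 0)
  expect_equal(net$edges$matched, 6L)
})

test_that("network construction matches an independent reference", {
  set.seed(55)
  for (rep in 1:3) {
    spectra <- lapply(1:12, function(i) random_spectrum(paste0("s", i)))
    # add a couple of correlated families so edges exist
    base <- random_spectrum("base", n_peaks = 8)
    for (k in 1:4) {
      s <- base
      s$feature_id <- paste0("fam", k)
      s$precursor_mz <- base$precursor_mz + k * 10
      s$peaks[, "intensity"] <- s$peaks[, "intensity"] * runif(8, 0.7, 1.3)
      spectra[[12 + k]] <- s
    }
    net <- build_network(spectra)
    ref <- reference_network_edges(spectra)
    expect_equal(nrow(net$edges), nrow(ref))
    if (nrow(ref) > 0) {
      key <- function(e) paste(e$source, e$target, round(e$score, 10))
      expect_setequal(key(net$edges), key(ref))
    }
  }
})

test_that("raising the cosine threshold only removes edges", {
  study <- simulate_study(default_study_design(seed = 13, zero_noise = TRUE))
  sp <- study$matrices$invitro$spectra
  e1 <- build_network(sp, network_params(cosine_threshold = 0.70))$edges
  e2 <- build_network(sp, network_params(cosine_threshold = 0.85))$edges
  expect_lte(nrow(e2), nrow(e1))
  k1 <- paste(e1$source, e1$target)
  k2 <- paste(e2$source, e2$target)
  expect_true(all(k2 %in% k1))
})

test_that("top-k pruning with k = n - 1 is a no-op", {
  study <- simulate_study(default_study_design(seed = 13, zero_noise = TRUE))
  sp <- study$matrices$invivo$spectra
  n <- length(sp)
  full <- build_network(sp, network_params(top_k = n - 1L))
  nolimit <- build_network(sp, network_params(top_k = 10000L))
  expect_equal(full$edges, nolimit$edges)
})

test_that("the parent reaches every in-matrix truth metabolite in its cluster", {
  study <- simulate_study(default_study_design(seed = 4, zero_noise = TRUE))
  for (mx in c("invitro", "invivo")) {
    sp <- study$matrices[[mx]]$spectra
    net <- build_network(sp)
    cl <- network_clusters(net)
    parent_cluster <- cl[[which(vapply(cl, function(ids) 1 %in% ids, logical(1)))]]
    truth_ids <- net$nodes$id[grepl("_F", net$nodes$feature_id)]
    expect_true(all(truth_ids %in% parent_cluster))
  }
})

test_that("clusters and GraphML export behave", {
  set.seed(77)
  spectra <- lapply(1:5, function(i) random_spectrum(paste0("s", i)))
  net <- build_network(spectra)
  if (nrow(net$edges) == 0) {
    expect_equal(length(network_clusters(net)), 5)
  }
  study <- simulate_study(default_study_design(seed = 4, zero_noise = TRUE))
  net2 <- build_network(study$matrices$invivo$spectra)
  path <- tempfile(fileext = ".graphml")
  export_graphml(net2, path)
  g <- import_graphml(path)
  expect_equal(igraph::ecount(g), nrow(net2$edges))
  expect_equal(igraph::vcount(g), nrow(net2$nodes))
})
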