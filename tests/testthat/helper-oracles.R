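# Independent oracles used across the suite. These deliberately re-derive
# results with different algorithms (exhaustive search, plain loops) from the
# package implementations they check.

# Exhaustive-optimum modified cosine: enumerates every one-to-one assignment
# over the candidate peak pairs and returns the maximum achievable score.
brute_force_similarity <- function(a, b, params = network_params()) {
  wt <- function(p) {
    w <- p[, "intensity"]
    if (params$intensity_weighting == "sqrt") w <- sqrt(w)
    w / sqrt(sum(w^2))
  }
  wa <- wt(a$peaks)
  wb <- wt(b$peaks)
  pairs <- list()
  shift <- b$precursor_mz - a$precursor_mz
  for (i in seq_along(wa)) {
    for (j in seq_along(wb)) {
      d <- b$peaks[j, "mz"] - a$peaks[i, "mz"]
      direct <- abs(d) <= params$fragment_tol
      shifted <- params$score_mode == "shifted" &&
        abs(d - shift) <= params$fragment_tol
      if (direct || shifted) {
        pairs[[length(pairs) + 1L]] <- c(i, j, wa[i] * wb[j])
      }
    }
  }
  if (length(pairs) == 0L) return(list(score = 0, matched = 0L))
  best <- list(score = 0, matched = 0L)
  recurse <- function(k, used_a, used_b, score, matched) {
    if (k > length(pairs)) {
      if (score > best$score ||
          (score == best$score && matched > best$matched)) {
        best <<- list(score = score, matched = matched)
      }
      return(invisible())
    }
    p <- pairs[[k]]
    if (!used_a[p[1]] && !used_b[p[2]]) {
      ua <- used_a; ua[p[1]] <- TRUE
      ub <- used_b; ub[p[2]] <- TRUE
      recurse(k + 1L, ua, ub, score + p[3], matched + 1L)
    }
    recurse(k + 1L, used_a, used_b, score, matched)
  }
  recurse(1L, logical(length(wa)), logical(length(wb)), 0, 0L)
  best$score <- min(best$score, 1)
  best
}

# Straight-line reference network builder: all pairs, filters, then the
# mutual top-k rule re-derived with plain sorting. Uses the package's
# similarity so that build_network's edge assembly is what is under test;
# pass similarity = brute_force_similarity for full independence on tiny
# fixtures.
reference_network_edges <- function(spectra, params = network_params(),
                                    similarity = spectral_similarity) {
  n <- length(spectra)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      s <- similarity(spectra[[i]], spectra[[j]], params)
      if (s$score > params$cosine_threshold &&
          s$matched >= params$min_matched_peaks) {
        rows[[length(rows) + 1L]] <- data.frame(
          source = i, target = j, score = s$score, matched = s$matched,
          shift = spectra[[j]]$precursor_mz - spectra[[i]]$precursor_mz)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(source = integer(0), target = integer(0)))
  }
  e <- do.call(rbind, rows)
  top <- function(node) {
    inc <- which(e$source == node | e$target == node)
    partner <- ifelse(e$source[inc] == node, e$target[inc], e$source[inc])
    inc[order(-e$score[inc], abs(e$shift[inc]), partner)][
      seq_len(min(params$top_k, length(inc)))]
  }
  keep <- vapply(seq_len(nrow(e)), function(k) {
    k %in% top(e$source[k]) && k %in% top(e$target[k])
  }, logical(1))
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random spectrum generator for property-style tests.
random_spectrum <- function(id, n_peaks = sample(3:8, 1),
                            mz_range = c(100, 650)) {
  prec <- runif(1, mz_range[1] + 50, mz_range[2])
  msms_spectrum(
    feature_id = id,
    precursor_mz = prec,
    rt_min = runif(1, 0.5, 14),
    peaks = cbind(mz = sort(runif(n_peaks, 60, prec)),
                  intensity = runif(n_peaks, 5, 100))
  )
}

# Shared fragment count between two spectra by exhaustive greedy pairing at a
# tolerance (direct matches only), for checking the generator contract.
shared_fragment_count <- function(a, b, tol = 0.02) {
  da <- a$peaks[, "mz"]
  db <- b$peaks[, "mz"]
  used <- logical(length(db))
  n <- 0L
  for (x in da) {
    j <- which(!used & abs(db - x) <= tol)
    if (length(j) > 0) {
      used[j[1]] <- TRUE
      n <- n + 1L
    }
  }
  n
}

sibiriline_profile <- function() {
  list(phenol_oh = 1, aromatic_ch = 7, basic_ring_n = 1, secondary_nh = 1,
       catechol = FALSE)
}
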