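fake_annotations <- function(df, parent_mz = 211.087) {
  df$feature_id <- paste0("f", seq_len(nrow(df)))
  df$node <- seq_len(nrow(df))
  df$assigned <- TRUE
  df$mass_error_mda <- 0
  if (is.null(df$is_parent)) df$is_parent <- df$chain == "parent"
  class(df) <- c("node_annotations", "data.frame")
  attr(df, "parent") <- list(node = 1, mz = parent_mz, formula = "C13H10N2O")
  df
}

test_that("matrix merging sets presence flags and keeps isomers apart", {
  iv <- fake_annotations(data.frame(
    chain = c("parent", "sulfation", "2 × methylation + sulfation"),
    formula = c("C13H10N2O", "C13H10N2O4S", "C15H14N2O4S"),
    mz = c(211.087, 291.044, 319.075),
    rt_min = c(5.8, 4.4, 5.1)
  ))
  vv <- fake_annotations(data.frame(
    chain = c("parent", "sulfation"),
    formula = c("C13H10N2O", "C13H10N2O4S"),
    mz = c(211.087, 291.044),
    rt_min = c(5.8, 5.2)
  ))
  rec <- integrate_evidence(iv, vv)
  met <- rec[!rec$is_parent, ]
  expect_equal(nrow(met), 3)
  m4 <- met[met$mz == 319.075, ]
  expect_true(m4$in_vitro && !m4$in_vivo)
  # sulfation at different RTs stays two isomer records
  sul <- met[met$chain == "sulfation", ]
  expect_equal(nrow(sul), 2)
  expect_equal(sort(sul$rt_min), c(4.4, 5.2))
  expect_equal(sul$in_vivo[order(sul$rt_min)], c(FALSE, TRUE))
  # same RT in both matrices collapses to one record present in both
  both <- integrate_evidence(
    fake_annotations(data.frame(chain = "glucuronidation",
                                formula = "C19H18N2O7", mz = 387.119,
                                rt_min = 3.7, is_parent = FALSE)),
    fake_annotations(data.frame(chain = "glucuronidation",
                                formula = "C19H18N2O7", mz = 387.119,
                                rt_min = 3.7, is_parent = FALSE)))
  expect_equal(nrow(both), 1)
  expect_true(both$in_vivo && both$in_vitro)
  expect_equal(both$shift, 387.119 - 211.087, tolerance = 1e-9)
  empty <- integrate_evidence(NULL, NULL)
  expect_equal(nrow(empty), 0)
})

test_that("metabolite ids follow m/z order with RT-ordered isomer letters", {
  rec <- integrate_evidence(fake_annotations(data.frame(
    chain = c("parent", "hydroxylation", "hydroxylation", "glucuronidation",
              "glucuronidation", "sulfation"),
    formula = c("C13H10N2O", "C13H10N2O2", "C13H10N2O2", "C19H18N2O7",
                "C19H18N2O7", "C13H10N2O4S"),
    mz = c(211.087, 227.082, 227.082, 387.119, 387.119, 291.044),
    rt_min = c(5.8, 5.2, 5.0, 3.7, 4.8, 4.4)
  )), NULL)
  ids <- assign_metabolite_ids(rec)
  expect_equal(ids$metabolite_id[ids$is_parent], "parent")
  expect_equal(ids$metabolite_id[ids$rt_min == 5.0 & ids$mz == 227.082], "M1a")
  expect_equal(ids$metabolite_id[ids$rt_min == 5.2 & ids$mz == 227.082], "M1b")
  expect_equal(ids$metabolite_id[ids$mz == 291.044], "M2")
  expect_equal(ids$metabolite_id[ids$rt_min == 3.7], "M3a")
  expect_equal(ids$metabolite_id[ids$rt_min == 4.8], "M3b")
})

test_that("id assignment is invariant to input order", {
  base <- data.frame(
    chain = c("parent", "hydroxylation", "hydroxylation", "sulfation"),
    formula = c("C13H10N2O", "C13H10N2O2", "C13H10N2O2", "C13H10N2O4S"),
    mz = c(211.087, 227.082, 227.082, 291.044),
    rt_min = c(5.8, 5.2, 5.0, 4.4)
  )
  r1 <- assign_metabolite_ids(integrate_evidence(fake_annotations(base), NULL))
  perm <- base[c(3, 1, 4, 2), ]
  r2 <- assign_metabolite_ids(integrate_evidence(fake_annotations(perm), NULL))
  cols <- c("metabolite_id", "chain", "mz", "rt_min")
  expect_equal(as.data.frame(r1)[cols], as.data.frame(r2)[cols])
})

test_that("summary counts exclude the parent and respect bounds", {
  rec <- integrate_evidence(fake_annotations(data.frame(
    chain = c("parent", "hydroxylation", "sulfation"),
    formula = c("C13H10N2O", "C13H10N2O2", "C13H10N2O4S"),
    mz = c(211.087, 227.082, 291.044),
    rt_min = c(5.8, 5.0, 4.4)
  )), NULL)
  s <- summarize_evidence(rec)
  expect_equal(s$n_total, 2)
  expect_equal(s$n_in_vitro, 2)
  expect_equal(s$n_in_vivo, 0)
  expect_equal(s$n_phase2_only, 1)
  expect_lte(s$n_in_vivo, s$n_total)
  expect_lte(s$n_in_vitro, s$n_total)
})

test_that("the report TSV mirrors the evidence table", {
  rec <- assign_metabolite_ids(integrate_evidence(fake_annotations(data.frame(
    chain = c("parent", "glucuronidation"),
    formula = c("C13H10N2O", "C19H18N2O7"),
    mz = c(211.087, 387.119),
    rt_min = c(5.8, 3.7)
  )), NULL))
  path <- tempfile(fileext = ".tsv")
  write_evidence_tsv(rec, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(tab$metabolite, c("parent", "M1"))
  expect_equal(tab$mz, c(211.087, 387.119))
  expect_equal(tab$in_vitro, c("X", "X"))
  expect_equal(tab$in_vivo, c("-", "-"))
})
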