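didx <- entity_index(c("d1", "d2", "d3"), "drug")
cidx <- entity_index(c("c1", "c2"), "cell")

test_that("association matrices are exact indicator constructions", {
  tab <- association_table(
    data.frame(entity_id = c("d1", "d1", "d2"),
               partner_id = c("t1", "t2", "t2")),
    partner_vocabulary = c("t1", "t2"))
  M <- build_association_matrix(tab, entity_index(c("d1", "d2"), "drug"))
  expect_equal(unclass(M), matrix(c(1, 0, 1, 1), 2, 2,
                                  dimnames = list(c("d1", "d2"), c("t1", "t2"))),
               ignore_attr = TRUE)
  expect_equal(attr(M, "value_range"), "binary")

  # duplicate edges collapse to one
  tab2 <- association_table(
    data.frame(entity_id = c("d1", "d1"), partner_id = c("t1", "t1")),
    partner_vocabulary = c("t1", "t2"))
  M2 <- build_association_matrix(tab2, entity_index(c("d1", "d2"), "drug"))
  expect_equal(max(M2), 1)
  expect_equal(sum(M2), 1)

  # empty edge list: all-zero rows, all flagged
  tab3 <- association_table(
    data.frame(entity_id = character(0), partner_id = character(0)),
    partner_vocabulary = "t1")
  M3 <- build_association_matrix(tab3, didx)
  expect_equal(dim(M3), c(3L, 1L))
  expect_true(all(M3 == 0))
  expect_true(all(attr(M3, "zero_rows")))

  # unknown entity is a hard error naming the id
  tab4 <- association_table(
    data.frame(entity_id = "nope", partner_id = "t1"),
    partner_vocabulary = "t1")
  expect_error(build_association_matrix(tab4, didx), "nope")
})

test_that("combined scores are scaled by 1000, symmetrized, unit diagonal", {
  tab <- association_table(
    data.frame(entity_id = "d1", partner_id = "d2", score = 500),
    partner_vocabulary = didx$ids)
  M <- build_combined_score_matrix(tab, didx)
  expect_equal(M["d1", "d2"], 0.5)
  expect_equal(M["d2", "d1"], 0.5)
  expect_equal(diag(unclass(M)), setNames(rep(1, 3), didx$ids))
  expect_true(attr(M, "zero_rows")["d3"])
  expect_false(attr(M, "zero_rows")["d1"])

  # upper bound maps to 1; no scores -> identity-diagonal matrix
  tab2 <- association_table(
    data.frame(entity_id = "d1", partner_id = "d2", score = 1000),
    partner_vocabulary = didx$ids)
  expect_equal(build_combined_score_matrix(tab2, didx)["d1", "d2"], 1)
  tab0 <- association_table(
    data.frame(entity_id = character(0), partner_id = character(0),
               score = numeric(0)),
    partner_vocabulary = didx$ids)
  expect_equal(unclass(build_combined_score_matrix(tab0, didx)),
               diag(3), ignore_attr = TRUE)

  tab_bad <- association_table(
    data.frame(entity_id = "d1", partner_id = "d2", score = 1500),
    partner_vocabulary = didx$ids)
  expect_error(build_combined_score_matrix(tab_bad, didx), "1000")
})

test_that("IC50 profile matrices place triples and transpose exactly", {
  d2 <- entity_index(c("d1", "d2"), "drug")
  tri <- data.frame(drug_id = c("d1", "d2"), cell_id = c("c1", "c2"),
                    ic50 = c(0.5, 1.5))
  prof <- build_ic50_profile_matrices(tri, d2, cidx)
  expect_equal(unclass(prof$M_CD),
               matrix(c(0.5, 0, 0, 1.5), 2, 2,
                      dimnames = list(c("c1", "c2"), c("d1", "d2"))),
               ignore_attr = TRUE)
  expect_equal(unclass(prof$M_DC), t(unclass(prof$M_CD)), ignore_attr = TRUE)

  # conflicting duplicates error; consistent duplicates collapse
  tri_bad <- rbind(tri, data.frame(drug_id = "d1", cell_id = "c1", ic50 = 9))
  expect_error(build_ic50_profile_matrices(tri_bad, d2, cidx), "conflicting")
  tri_dup <- rbind(tri, tri[1, ])
  expect_silent(build_ic50_profile_matrices(tri_dup, d2, cidx))

  # dense table: no fill value used
  tri_full <- expand.grid(drug_id = d2$ids, cell_id = cidx$ids,
                          stringsAsFactors = FALSE)
  tri_full$ic50 <- 1:4
  pf <- build_ic50_profile_matrices(tri_full, d2, cidx, fill = -99)
  expect_false(any(pf$M_CD == -99))
})

test_that("fingerprint views have canonical widths and deterministic rows", {
  idx <- entity_index(c("a", "b", "c"), "drug")
  sm <- c(a = "CCO", b = "CCO", c = "c1ccccc1N")
  fps <- build_fingerprint_matrices(smiles = sm, index = idx)
  expect_named(fps, c("ECFP", "PSFP", "DFP", "RDKFP", "ESPFP", "ERGFP"))
  widths <- vapply(fps, ncol, 1L)
  expect_equal(unname(widths), c(1024L, 881L, 2048L, 200L, 2586L, 315L))
  for (v in names(fps)) {
    # identical SMILES -> identical rows in every view
    expect_equal(fps[[v]]["a", ], fps[[v]]["b", ])
    expect_false(isTRUE(all.equal(fps[[v]]["a", ], fps[[v]]["c", ])))
  }
  expect_true(all(fps$ECFP %in% c(0, 1)))
  expect_true(min(fps$RDKFP) >= 0 && max(fps$RDKFP) <= 1)

  # precomputed path validates column counts
  dims <- c(ECFP = 1024L, PSFP = 881L, DFP = 2048L,
            RDKFP = 200L, ESPFP = 2586L, ERGFP = 315L)
  pre <- lapply(dims, function(d) matrix(0, 3, d))
  expect_silent(build_fingerprint_matrices(index = idx, precomputed = pre))
  pre$ECFP <- matrix(0, 3, 1000)
  expect_error(build_fingerprint_matrices(index = idx, precomputed = pre),
               "1024")

  expect_error(build_fingerprint_matrices(smiles = c(a = "CCO", b = "", c = "C"),
                                          index = idx), "b")
})

test_that("feature matrices enforce row alignment and value ranges", {
  expect_error(feature_matrix(matrix(0, 2, 2), didx, "target"), "3 entities")
  expect_error(feature_matrix(matrix(0.5, 3, 2), didx, "target"), "binary")
  expect_error(feature_matrix(matrix(2, 3, 3), didx, "combined"), "\\[0,1\\]")
  M <- feature_matrix(matrix(c(1, 0, 0, 0, 0, 0), 3, 2), didx, "target")
  expect_equal(rownames(M), didx$ids)
  expect_equal(unname(attr(M, "zero_rows")), c(FALSE, TRUE, TRUE))
})
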