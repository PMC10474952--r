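test_that("snf_fuse matches the dense-loop oracle on random fixtures", {
  for (cfg in list(list(K = 3, T = 10, mu = 0.5), list(K = 5, T = 20, mu = 0.8))) {
    Ws <- lapply(1:3, function(s) random_similarity(8, seed = 100 + s))
    views <- lapply(Ws, similarity_view, index = NULL, view_name = "v")
    fused <- snf_fuse(views, snf_params(K = cfg$K, T = cfg$T, mu = cfg$mu))
    expect_equal(unclass(fused), oracle_snf(Ws, cfg$K, cfg$T),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_symmetric(fused)
    expect_true(min(fused) >= 0)
  }
})

test_that("identical views reproduce the oracle on a 5x5 fixture", {
  A <- random_similarity(5, seed = 7)
  v <- similarity_view(A, NULL, "v")
  fused <- snf_fuse(list(v, v, v), snf_params(K = 3, T = 10))
  expect_equal(unclass(fused), oracle_snf(list(A, A, A), 3, 10),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("T = 0 returns the mean of the normalized inputs", {
  Ws <- lapply(1:2, function(s) random_similarity(6, seed = 20 + s))
  views <- lapply(Ws, similarity_view, index = NULL, view_name = "v")
  fused <- snf_fuse(views, snf_params(K = 3, T = 0))
  Pmean <- (drpfuse:::snf_p_normalize(Ws[[1]]) +
            drpfuse:::snf_p_normalize(Ws[[2]])) / 2
  expect_equal(unclass(fused), (Pmean + t(Pmean)) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("fusion preserves shared block structure", {
  blk <- function(noise_seed) {
    set.seed(noise_seed)
    A <- matrix(0.05, 6, 6)
    A[1:3, 1:3] <- 0.8; A[4:6, 4:6] <- 0.8
    A <- A + matrix(runif(36, 0, 0.05), 6, 6)
    A <- (A + t(A)) / 2; diag(A) <- 1
    A
  }
  views <- lapply(1:2, function(s) similarity_view(blk(s), NULL, "v"))
  fused <- unclass(snf_fuse(views, snf_params(K = 3, T = 10)))
  off <- fused; diag(off) <- NA
  within <- mean(c(off[1:3, 1:3], off[4:6, 4:6]), na.rm = TRUE)
  between <- mean(off[1:3, 4:6])
  expect_gt(within, between)
})

test_that("snf_fuse is permutation-equivariant", {
  Ws <- lapply(1:3, function(s) random_similarity(6, seed = 40 + s))
  views <- lapply(Ws, similarity_view, index = NULL, view_name = "v")
  prm <- c(3, 1, 6, 2, 5, 4)
  views_p <- lapply(Ws, function(W)
    similarity_view(W[prm, prm], NULL, "v"))
  f1 <- unclass(snf_fuse(views, snf_params(K = 3, T = 10)))
  f2 <- unclass(snf_fuse(views_p, snf_params(K = 3, T = 10)))
  expect_equal(f1[prm, prm], f2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("snf_fuse validates its inputs", {
  A <- random_similarity(5, seed = 1)
  v <- similarity_view(A, NULL, "v")
  expect_error(snf_fuse(list(v), snf_params()), "at least 2")
  expect_error(snf_fuse(list(v, v), snf_params(K = 5)), "K = 5")
  B <- A; B[1, 2] <- B[1, 2] + 0.5   # break symmetry, bypass constructor
  vb <- v; attr_backup <- attributes(v)
  vb <- structure(B, class = class(v), index = NULL, view_name = "v",
                  metric = "precomputed", zero_row_mask = rep(FALSE, 5))
  expect_error(snf_fuse(list(v, vb), snf_params(K = 3)), "symmetric")
})

test_that("completion replaces exactly the zero-row entities", {
  set.seed(8)
  n <- 6
  S <- random_similarity(n, seed = 8)
  mask <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  S[mask, ] <- 0; S[, mask] <- 0; diag(S) <- 1
  view <- similarity_view(S, NULL, "target", zero_row_mask = mask)
  fused <- structure(random_similarity(n, seed = 88),
                     class = c("fused_similarity", "matrix", "array"))
  done <- fill_sparse_view(view, fused)
  expect_symmetric(done)
  expect_equal(unname(diag(unclass(done))), rep(1, n))
  # filled rows/cols come from the fused matrix
  expect_equal(unclass(done)[2, -2], unclass(fused)[2, -2])
  expect_equal(unclass(done)[, 5][-5], unclass(fused)[, 5][-5])
  # the complement is bit-identical
  keep <- !mask
  expect_identical(unclass(done)[keep, keep], S[keep, keep])
  expect_equal(attr(done, "filled_entities"), which(mask))

  # no zero rows -> identity pass-through
  v2 <- similarity_view(random_similarity(n, seed = 9), NULL, "target")
  expect_equal(unclass(fill_sparse_view(v2, fused)), unclass(v2),
               ignore_attr = TRUE)
  expect_length(attr(fill_sparse_view(v2, fused), "filled_entities"), 0)
})

test_that("fingerprint fusion feeds completion of all five sparse views", {
  bundle <- tiny_bundle(seed = 3)
  asm <- assemble_features(bundle, bundle$pairs)
  expect_setequal(unname(attr(asm$fused_smiles, "source_views")),
                  c("ECFP", "PSFP", "DFP", "RDKFP", "ESPFP", "ERGFP"))
  # every designated zero-row drug was filled in its view
  for (v in c("combined", "target", "disease", "miRNA", "ADR")) {
    filled <- attr(asm$views$drug[[v]], "filled_entities")
    expect_setequal(filled, bundle$truth$zero_rows[[v]])
    expect_false(any(attr(asm$views$drug[[v]], "zero_row_mask")))
  }
  expect_length(attr(asm$fused_all, "source_views"), 12L)
  expect_error(fuse_all_drug_views(asm$views$drug[1:11]), "12")
})
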