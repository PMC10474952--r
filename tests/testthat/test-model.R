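# helper: a minimal 2-drug-view x 2-cell-view model whose residual blocks
# have matching channel counts (C_in = 4), so shortcuts are identities
small_block_model <- function(s = 4L, seed = 3L) {
  spec <- model_spec(s = s, cnn_channels = c(4L, 4L, 4L), kernel = 3L,
                     inner_sizes = c(16L, 16L, 8L, 4L),
                     head_sizes = c(16L, 8L, 4L, 1L))
  drp_model(spec, drug_view_dims = c(5L, 5L), cell_view_dims = c(5L, 5L),
            fused_dim = 5L, seed = seed)
}

rand_batch <- function(model, B, seed = 1L) {
  set.seed(seed)
  list(drug = lapply(model$dims$drug_view_dims,
                     function(n) matrix(rnorm(B * n), B, n)),
       fused = matrix(rnorm(B * model$dims$fused_dim), B, model$dims$fused_dim),
       cell = lapply(model$dims$cell_view_dims,
                     function(n) matrix(rnorm(B * n), B, n)))
}

# reconstruct the outer map of channel (k, l) for sample b from the cache
outer_map_from_cache <- function(cache, model, k, l, b) {
  s <- model$spec$s; hw <- s * s
  chn <- (k - 1L) * model$dims$Vc + l
  matrix(cache$X[(b - 1L) * hw + seq_len(hw), chn], s, s)
}

test_that("identity projection passes similarity rows through unchanged", {
  m <- small_block_model(s = 5L)   # s equals the input width
  for (k in 1:2) m$params[[sprintf("G%02d", k)]] <- diag(5)
  b <- rand_batch(m, B = 3)
  fw <- drp_forward(m, b)
  expect_equal(fw$cache$g[[1]], b$drug[[1]])
  # zero input row projects to the zero vector (no bias)
  b$drug[[2]][2, ] <- 0
  fw2 <- drp_forward(m, b)
  expect_equal(fw2$cache$g[[2]][2, ], rep(0, 5))
})

test_that("interaction maps are exact outer/inner products", {
  s <- 4L
  m <- small_block_model(s = s)
  b <- rand_batch(m, B = 2)
  fw <- drp_forward(m, b)
  # verify the cached maps against direct products of the projected vectors
  g <- fw$cache$g; h <- fw$cache$h
  for (k in 1:2) for (l in 1:2) {
    O <- outer_map_from_cache(fw$cache, m, k, l, b = 1)
    expect_equal(O, outer(g[[k]][1, ], h[[l]][1, ]), tolerance = 1e-12)
    chn <- (k - 1L) * 2L + l
    inner <- fw$cache$inner[1, (chn - 1L) * s + seq_len(s)]
    expect_equal(inner, g[[k]][1, ] * h[[l]][1, ], tolerance = 1e-12)
    # inner vector is the diagonal of the outer map; outer map has rank 1
    expect_equal(inner, diag(O), tolerance = 1e-12)
    expect_lte(qr(O)$rank, 1L)
  }
  # hand-arithmetic example: g = (1,2), h = (3,4)
  expect_equal(outer(c(1, 2), c(3, 4)), matrix(c(3, 6, 4, 8), 2, 2))
  expect_equal(c(1, 2) * c(3, 4), c(3, 8))
})

test_that("view counts drive interaction-map counts", {
  spec <- tiny_spec()
  m_full <- drp_model(spec, rep(10L, 12), rep(6L, 4), 10L, seed = 1)
  expect_equal(m_full$dims$C_in, 48L)
  m_ablate_drug <- drp_model(spec, rep(10L, 11), rep(6L, 4), 10L, seed = 1)
  expect_equal(m_ablate_drug$dims$C_in, 44L)
  m_ablate_cell <- drp_model(spec, rep(10L, 12), rep(6L, 3), 10L, seed = 1)
  expect_equal(m_ablate_cell$dims$C_in, 36L)
  # inner MLP input width is C_in * s
  expect_equal(nrow(m_full$params$in1_W), 48L * spec$s)
})

test_that("zeroed residual branches make each block the identity", {
  m <- small_block_model()
  for (nm in c("c1a_W", "c1a_b", "c1b_W", "c1b_b",
               "c2a_W", "c2a_b", "c2b_W", "c2b_b"))
    m$params[[nm]][] <- 0
  b <- rand_batch(m, B = 2)
  fw <- drp_forward(m, b)
  expect_equal(fw$cache$x1, fw$cache$X, tolerance = 1e-12)
  expect_equal(fw$cache$x2, fw$cache$x1, tolerance = 1e-12)
})

test_that("all-zero interaction maps give a bias-determined embedding", {
  m <- small_block_model()
  b <- rand_batch(m, B = 2)
  for (k in 1:2) b$drug[[k]][] <- 0
  fw1 <- drp_forward(m, b)
  fw2 <- drp_forward(m, b)
  expect_identical(fw1$pred, fw2$pred)
  expect_true(all(fw1$cache$X == 0))
})

test_that("channel order matters for the CNN (documented non-invariance)", {
  m <- small_block_model()
  b <- rand_batch(m, B = 2)
  fw <- drp_forward(m, b)
  b_swapped <- b
  b_swapped$drug <- b$drug[c(2, 1)]
  fw_swapped <- drp_forward(m, b_swapped)
  expect_false(isTRUE(all.equal(fw$pred, fw_swapped$pred)))
})

test_that("batched prediction equals single-pair prediction", {
  m <- small_block_model()
  B <- 5
  bt <- rand_batch(m, B = B, seed = 2)
  pred_batch <- drp_forward(m, bt)$pred
  pred_single <- vapply(seq_len(B), function(i) {
    one <- list(drug = lapply(bt$drug, function(M) M[i, , drop = FALSE]),
                fused = bt$fused[i, , drop = FALSE],
                cell = lapply(bt$cell, function(M) M[i, , drop = FALSE]))
    drp_forward(m, one)$pred
  }, numeric(1))
  expect_equal(pred_batch, pred_single, tolerance = 1e-6)
})

test_that("ReLU embedding activations are nonnegative and shapes compose", {
  spec <- tiny_spec(s = 8L)
  m <- drp_model(spec, rep(10L, 12), rep(6L, 4), 10L, seed = 5)
  set.seed(5)
  b <- rand_batch(m, B = 3)
  fw <- drp_forward(m, b)
  # drug embedding = [MLPFused | MLPDrug] -> 2s; cell embedding -> s
  expect_equal(ncol(fw$cache$fu$a2), 8L)
  expect_equal(ncol(fw$cache$dr$a2), 8L)
  expect_equal(ncol(fw$cache$ce$a2), 8L)
  expect_true(min(fw$cache$fu$a1) >= 0 && min(fw$cache$ce$a2) >= 0)
  expect_equal(ncol(fw$cache$ha[[1]]),
               spec$cnn_channels[3] + spec$inner_sizes[4] + 2L * 8L + 8L)
})

test_that("analytic gradients match finite differences", {
  spec <- model_spec(s = 4L, cnn_channels = c(5L, 5L, 3L), kernel = 3L,
                     inner_sizes = c(7L, 6L, 5L, 4L),
                     head_sizes = c(6L, 5L, 4L, 1L))
  m <- drp_model(spec, c(6L, 6L, 6L), c(5L, 7L), fused_dim = 6L, seed = 7)
  set.seed(42)
  # move biases off zero so no pre-activation sits exactly on the ReLU kink
  for (nm in grep("_b$", names(m$params), value = TRUE))
    m$params[[nm]] <- rnorm(length(m$params[[nm]]), sd = 0.3)
  b <- rand_batch(m, B = 3, seed = 42)
  y <- rnorm(3)
  fw <- drp_forward(m, b)
  gr <- drpfuse:::drp_backward(m, fw$cache, 2 * (fw$pred - y) / 3)
  loss <- function(params)
    mean((drp_forward(drpfuse:::model_with(m, params), b)$pred - y)^2)
  eps <- 1e-6
  for (nm in names(m$params)) {
    expect_false(is.null(gr[[nm]]), info = nm)
    idxs <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (i in idxs) {
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- m$params; p3[[nm]][i] <- p3[[nm]][i] - eps
      g_num <- (loss(p2) - loss(p3)) / (2 * eps)
      expect_equal(gr[[nm]][i], g_num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("training is deterministic and stops by patience arithmetic", {
  expect_equal(early_stop_epoch(seq(1, 2, length.out = 50), patience = 10), 11)
  expect_equal(early_stop_epoch(c(5, 4, 3, 2, 1), patience = 10), 5)
  expect_equal(early_stop_epoch(c(3, 2, 4, 4, 4), patience = 3), 5)
  expect_equal(early_stop_epoch(rep(1, 100), patience = Inf), 100)

  inputs <- random_inputs(8, 6, Vd = 3, Vc = 2, seed = 1)
  set.seed(2)
  pairs <- data.frame(drug_idx = sample(8, 40, TRUE),
                      cell_idx = sample(6, 40, TRUE),
                      ic50 = rnorm(40),
                      split = rep(c("train", "val"), c(32, 8)))
  spec <- model_spec(s = 4L, cnn_channels = c(6L, 6L, 4L),
                     inner_sizes = c(16L, 16L, 8L, 4L),
                     head_sizes = c(16L, 8L, 4L, 1L),
                     lr = 1e-3, batch_size = 16L, max_epochs = 8L)
  m <- drp_model(spec, rep(8L, 3), rep(6L, 2), 8L, seed = 3)
  t1 <- train_drp(m, inputs[c("drug_views", "fused", "cell_views")],
                  pairs, seed = 9)
  t2 <- train_drp(m, inputs[c("drug_views", "fused", "cell_views")],
                  pairs, seed = 9)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
  # the trainer's stopping epoch agrees with the early-stop rule
  expect_equal(nrow(t1$history),
               min(early_stop_epoch(t1$history$val_loss, spec$patience),
                   spec$max_epochs))
  expect_error(train_drp(m, inputs, pairs[pairs$split == "val", ]),
               "empty training split")
})
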