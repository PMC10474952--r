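#' Model architecture and training hyperparameters
#'
#' Collects every architecture constant of the interaction-module regressor
#' and the training recipe. Defaults follow the reference configuration:
#' projection dimension `s = 128`, inner-product MLP with layer widths
#' 1024/1024/512/128, a CNN of two residual blocks plus one convolution over
#' the stacked outer-product maps, ReLU activations throughout, mean squared
#' error loss, Adam with learning rate 1e-4 and weight decay 3e-4, and early
#' stopping with patience 10 on the validation loss.
#'
#' @param s projection dimension (each view's row is mapped to length `s`).
#' @param cnn_channels integer vector of 3: channels of residual block 1,
#'   residual block 2 and the final convolution.
#' @param kernel odd convolution kernel size.
#' @param inner_sizes widths of the four fully connected layers applied to
#'   the concatenated inner-product vectors.
#' @param head_sizes widths of the four prediction-head layers (last must
#'   be 1).
#' @param lr,weight_decay Adam learning rate and L2-coupled weight decay.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); `Inf` disables early stopping.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @return a `model_spec` list.
#' @export
model_spec <- function(s = 128L, cnn_channels = c(32L, 32L, 32L), kernel = 3L,
                       inner_sizes = c(1024L, 1024L, 512L, 128L),
                       head_sizes = c(512L, 256L, 128L, 1L),
                       lr = 1e-4, weight_decay = 3e-4, patience = 10,
                       batch_size = 128L, max_epochs = 300L) {
  stopifnot(s >= 2, length(cnn_channels) == 3, length(inner_sizes) == 4,
            length(head_sizes) == 4, head_sizes[4] == 1,
            kernel %% 2 == 1, lr > 0, weight_decay >= 0, batch_size >= 1)
  structure(list(s = as.integer(s), cnn_channels = as.integer(cnn_channels),
                 kernel = as.integer(kernel),
                 inner_sizes = as.integer(inner_sizes),
                 head_sizes = as.integer(head_sizes),
                 lr = lr, weight_decay = weight_decay, patience = patience,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs)),
            class = "model_spec")
}

#' Desk-scale model configuration
#'
#' A small instantiation of the same architecture for fixture-sized problems
#' (tens of drugs and cell lines): `s = 8`, 16-channel CNN, 256/128/64/32
#' inner MLP, 64/32/16/1 head, learning rate 1e-3, at most 120 epochs. Used
#' by the test-suite and the synthetic benchmark runs.
#'
#' @param ... overrides passed to [model_spec()].
#' @return a `model_spec`.
#' @export
small_model_spec <- function(...) {
  args <- modifyList(list(s = 8L, cnn_channels = c(16L, 16L, 16L),
                          inner_sizes = c(256L, 128L, 64L, 32L),
                          head_sizes = c(64L, 32L, 16L, 1L),
                          lr = 1e-3, max_epochs = 120L), list(...))
  do.call(model_spec, args)
}

#' Build the interaction-module drug-response model
#'
#' Initializes all parameters: one bias-free projection per drug view
#' (`G_k`, input width x s) and per cell view (`H_l`), the residual CNN over
#' the stacked outer-product maps, the inner-product MLP, the fused / drug /
#' cell embedding MLPs (two hidden layers of width s each), and the four-layer
#' prediction head. View counts are taken from the supplied input widths, so
#' leave-one-view-out configurations get correctly shaped parameters (and a
#' correspondingly smaller stack of interaction maps).
#'
#' @param spec a [model_spec()].
#' @param drug_view_dims integer vector: input width of each drug similarity
#'   view (normally 12 entries, all equal to the number of drugs).
#' @param cell_view_dims integer vector: input width of each cell feature
#'   view.
#' @param fused_dim width of the fused similarity vector.
#' @param seed RNG seed for the parameter initialization.
#' @return a `drp_model` with elements `spec`, `dims`, `params`, `geom`.
#' @export
drp_model <- function(spec, drug_view_dims, cell_view_dims, fused_dim,
                      seed = 1L) {
  Vd <- length(drug_view_dims); Vc <- length(cell_view_dims)
  stopifnot(Vd >= 1, Vc >= 1)
  s <- spec$s; ch <- spec$cnn_channels; k <- spec$kernel
  C_in <- Vd * Vc
  set.seed(seed)
  p <- list()
  for (kk in seq_len(Vd))
    p[[sprintf("G%02d", kk)]] <- init_weight(drug_view_dims[kk], s, gain = 1)
  for (ll in seq_len(Vc))
    p[[sprintf("H%d", ll)]] <- init_weight(cell_view_dims[ll], s, gain = 1)
  # residual CNN over the C_in stacked s x s outer maps
  p$c1a_W <- init_weight(k * k * C_in, ch[1]); p$c1a_b <- numeric(ch[1])
  p$c1b_W <- init_weight(k * k * ch[1], ch[1]); p$c1b_b <- numeric(ch[1])
  if (C_in != ch[1]) p$sc1_W <- init_weight(C_in, ch[1], gain = 1)
  p$c2a_W <- init_weight(k * k * ch[1], ch[2]); p$c2a_b <- numeric(ch[2])
  p$c2b_W <- init_weight(k * k * ch[2], ch[2]); p$c2b_b <- numeric(ch[2])
  if (ch[1] != ch[2]) p$sc2_W <- init_weight(ch[1], ch[2], gain = 1)
  p$c3_W <- init_weight(k * k * ch[2], ch[3]); p$c3_b <- numeric(ch[3])
  # inner-product MLP
  w_in <- C_in * s
  for (j in 1:4) {
    p[[sprintf("in%d_W", j)]] <- init_weight(w_in, spec$inner_sizes[j])
    p[[sprintf("in%d_b", j)]] <- numeric(spec$inner_sizes[j])
    w_in <- spec$inner_sizes[j]
  }
  # embedding MLPs: two hidden layers of width s each
  mk_mlp <- function(prefix, d_in) {
    p[[paste0(prefix, "1_W")]] <<- init_weight(d_in, s)
    p[[paste0(prefix, "1_b")]] <<- numeric(s)
    p[[paste0(prefix, "2_W")]] <<- init_weight(s, s)
    p[[paste0(prefix, "2_b")]] <<- numeric(s)
  }
  mk_mlp("fu", fused_dim)
  mk_mlp("dr", Vd * s)
  mk_mlp("ce", Vc * s)
  # prediction head over [outer_embed, inner_embed, drug_emb, cell_emb]
  w_in <- ch[3] + spec$inner_sizes[4] + 2L * s + s
  for (j in 1:4) {
    gain <- if (j == 4) 1 else 2
    p[[sprintf("hd%d_W", j)]] <- init_weight(w_in, spec$head_sizes[j], gain)
    p[[sprintf("hd%d_b", j)]] <- numeric(spec$head_sizes[j])
    w_in <- spec$head_sizes[j]
  }
  structure(list(spec = spec, params = p,
                 dims = list(Vd = Vd, Vc = Vc, C_in = C_in,
                             drug_view_dims = as.integer(drug_view_dims),
                             cell_view_dims = as.integer(cell_view_dims),
                             fused_dim = as.integer(fused_dim)),
                 geom = conv_geom(s, k), seed = as.integer(seed)),
            class = "drp_model")
}

#' @export
print.drp_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<drp_model> %d drug x %d cell views, s=%d, %s interaction maps, %d parameters\n",
              x$dims$Vd, x$dims$Vc, x$spec$s, x$dims$C_in, np))
  invisible(x)
}

# Outer-product index helpers: pixel p = (q-1)*s + r
outer_idx <- function(s) {
  list(rr = rep(seq_len(s), times = s), qq = rep(seq_len(s), each = s),
       Rind = outer(rep(seq_len(s), times = s), seq_len(s), `==`) * 1,
       Qind = outer(rep(seq_len(s), each = s), seq_len(s), `==`) * 1)
}

#' Forward pass of the interaction-module model
#'
#' Computes predictions for a batch and returns the full activation cache
#' needed for backpropagation (and for white-box inspection of the residual
#' blocks and interaction maps).
#'
#' @param model a [drp_model()].
#' @param batch list with `drug` (list of Vd matrices, B x view width),
#'   `fused` (B x fused width), `cell` (list of Vc matrices).
#' @return list with `pred` (length-B vector) and `cache`.
#' @export
drp_forward <- function(model, batch) {
  p <- model$params; s <- model$spec$s
  Vd <- model$dims$Vd; Vc <- model$dims$Vc; C_in <- model$dims$C_in
  ch <- model$spec$cnn_channels
  B <- nrow(batch$fused)
  hw <- s * s
  oi <- outer_idx(s)

  g <- vector("list", Vd); h <- vector("list", Vc)
  for (k in seq_len(Vd)) g[[k]] <- batch$drug[[k]] %*% p[[sprintf("G%02d", k)]]
  for (l in seq_len(Vc)) h[[l]] <- batch$cell[[l]] %*% p[[sprintf("H%d", l)]]

  # interaction maps: inner vectors (concatenated) and outer maps (stacked
  # as C_in channels of an s x s grid)
  inner <- matrix(0, B, C_in * s)
  X <- matrix(0, B * hw, C_in)
  for (k in seq_len(Vd)) for (l in seq_len(Vc)) {
    chn <- (k - 1L) * Vc + l
    inner[, ((chn - 1L) * s + 1L):(chn * s)] <- g[[k]] * h[[l]]
    tmp <- g[[k]][, oi$rr, drop = FALSE] * h[[l]][, oi$qq, drop = FALSE]
    X[, chn] <- as.vector(t(tmp))
  }

  # residual CNN + global max-pool
  geom <- model$geom
  cv1a <- conv_forward(X, p$c1a_W, p$c1a_b, geom, B); a1a <- relu(cv1a$Y)
  cv1b <- conv_forward(a1a, p$c1b_W, p$c1b_b, geom, B)
  short1 <- if (is.null(p$sc1_W)) X else X %*% p$sc1_W
  x1 <- cv1b$Y + short1
  cv2a <- conv_forward(x1, p$c2a_W, p$c2a_b, geom, B); a2a <- relu(cv2a$Y)
  cv2b <- conv_forward(a2a, p$c2b_W, p$c2b_b, geom, B)
  short2 <- if (is.null(p$sc2_W)) x1 else x1 %*% p$sc2_W
  x2 <- cv2b$Y + short2
  cv3 <- conv_forward(x2, p$c3_W, p$c3_b, geom, B); a3 <- relu(cv3$Y)
  mp <- maxpool_forward(a3, B, hw)

  # inner-product MLP (ReLU after every layer)
  iz <- vector("list", 4); ia <- vector("list", 5)
  ia[[1]] <- inner
  for (j in 1:4) {
    iz[[j]] <- add_bias(ia[[j]] %*% p[[sprintf("in%d_W", j)]],
                        p[[sprintf("in%d_b", j)]])
    ia[[j + 1]] <- relu(iz[[j]])
  }

  # embedding MLPs
  mlp2 <- function(prefix, x0) {
    z1 <- add_bias(x0 %*% p[[paste0(prefix, "1_W")]], p[[paste0(prefix, "1_b")]])
    a1 <- relu(z1)
    z2 <- add_bias(a1 %*% p[[paste0(prefix, "2_W")]], p[[paste0(prefix, "2_b")]])
    list(z1 = z1, a1 = a1, z2 = z2, a2 = relu(z2))
  }
  gcat <- do.call(cbind, g)
  hcat <- do.call(cbind, h)
  fu <- mlp2("fu", batch$fused)
  dr <- mlp2("dr", gcat)
  ce <- mlp2("ce", hcat)

  # prediction head
  hin <- cbind(mp$Y, ia[[5]], fu$a2, dr$a2, ce$a2)
  hz <- vector("list", 4); ha <- vector("list", 5)
  ha[[1]] <- hin
  for (j in 1:4) {
    hz[[j]] <- add_bias(ha[[j]] %*% p[[sprintf("hd%d_W", j)]],
                        p[[sprintf("hd%d_b", j)]])
    ha[[j + 1]] <- if (j < 4) relu(hz[[j]]) else hz[[j]]
  }
  pred <- as.vector(ha[[5]])

  cache <- list(B = B, batch = batch, g = g, h = h, inner = inner, X = X,
                cv1a = cv1a, a1a = a1a, cv1b = cv1b, x1 = x1,
                cv2a = cv2a, a2a = a2a, cv2b = cv2b, x2 = x2,
                cv3 = cv3, a3 = a3, mp = mp,
                iz = iz, ia = ia, fu = fu, dr = dr, ce = ce,
                gcat = gcat, hcat = hcat, hz = hz, ha = ha, oi = oi)
  list(pred = pred, cache = cache)
}

# Backward pass: gradient of the scalar loss wrt every parameter, given
# d(loss)/d(pred). Mirrors drp_forward exactly.
drp_backward <- function(model, cache, dpred) {
  p <- model$params; s <- model$spec$s
  Vd <- model$dims$Vd; Vc <- model$dims$Vc; C_in <- model$dims$C_in
  ch <- model$spec$cnn_channels
  B <- cache$B; hw <- s * s; geom <- model$geom; oi <- cache$oi
  gr <- list()

  # head
  d <- matrix(dpred, B, 1)
  for (j in 4:1) {
    if (j < 4) d <- d * (cache$hz[[j]] > 0)
    gr[[sprintf("hd%d_W", j)]] <- crossprod(cache$ha[[j]], d)
    gr[[sprintf("hd%d_b", j)]] <- colSums(d)
    d <- tcrossprod(d, p[[sprintf("hd%d_W", j)]])
  }
  w1 <- ch[3]; w2 <- model$spec$inner_sizes[4]; w3 <- s
  dpool <- d[, seq_len(w1), drop = FALSE]
  dinner_out <- d[, w1 + seq_len(w2), drop = FALSE]
  dfu <- d[, w1 + w2 + seq_len(s), drop = FALSE]
  ddr <- d[, w1 + w2 + s + seq_len(s), drop = FALSE]
  dce <- d[, w1 + w2 + 2L * s + seq_len(s), drop = FALSE]

  # embedding MLPs
  mlp2_back <- function(prefix, st, x0, dout) {
    dz2 <- dout * (st$z2 > 0)
    gr[[paste0(prefix, "2_W")]] <<- crossprod(st$a1, dz2)
    gr[[paste0(prefix, "2_b")]] <<- colSums(dz2)
    da1 <- tcrossprod(dz2, p[[paste0(prefix, "2_W")]])
    dz1 <- da1 * (st$z1 > 0)
    gr[[paste0(prefix, "1_W")]] <<- crossprod(x0, dz1)
    gr[[paste0(prefix, "1_b")]] <<- colSums(dz1)
    tcrossprod(dz1, p[[paste0(prefix, "1_W")]])
  }
  dfused_in <- mlp2_back("fu", cache$fu, cache$batch$fused, dfu)
  dgcat <- mlp2_back("dr", cache$dr, cache$gcat, ddr)
  dhcat <- mlp2_back("ce", cache$ce, cache$hcat, dce)

  # inner MLP
  d <- dinner_out
  for (j in 4:1) {
    d <- d * (cache$iz[[j]] > 0)
    gr[[sprintf("in%d_W", j)]] <- crossprod(cache$ia[[j]], d)
    gr[[sprintf("in%d_b", j)]] <- colSums(d)
    d <- tcrossprod(d, p[[sprintf("in%d_W", j)]])
  }
  dinner <- d   # B x (C_in*s)

  # CNN
  da3 <- maxpool_backward(dpool, cache$mp$argmax, B, hw, ch[3])
  dz3 <- da3 * (cache$cv3$Y > 0)
  bk3 <- conv_backward(dz3, cache$cv3$col, p$c3_W, geom, B, ch[2])
  gr$c3_W <- bk3$dW; gr$c3_b <- bk3$db
  dx2 <- bk3$dX
  # block 2
  bk2b <- conv_backward(dx2, cache$cv2b$col, p$c2b_W, geom, B, ch[2])
  gr$c2b_W <- bk2b$dW; gr$c2b_b <- bk2b$db
  dz2a <- bk2b$dX * (cache$cv2a$Y > 0)
  bk2a <- conv_backward(dz2a, cache$cv2a$col, p$c2a_W, geom, B, ch[1])
  gr$c2a_W <- bk2a$dW; gr$c2a_b <- bk2a$db
  dx1 <- bk2a$dX
  if (is.null(p$sc2_W)) dx1 <- dx1 + dx2
  else { gr$sc2_W <- crossprod(cache$x1, dx2); dx1 <- dx1 + tcrossprod(dx2, p$sc2_W) }
  # block 1
  bk1b <- conv_backward(dx1, cache$cv1b$col, p$c1b_W, geom, B, ch[1])
  gr$c1b_W <- bk1b$dW; gr$c1b_b <- bk1b$db
  dz1a <- bk1b$dX * (cache$cv1a$Y > 0)
  bk1a <- conv_backward(dz1a, cache$cv1a$col, p$c1a_W, geom, B, C_in)
  gr$c1a_W <- bk1a$dW; gr$c1a_b <- bk1a$db
  dX <- bk1a$dX
  if (is.null(p$sc1_W)) dX <- dX + dx1
  else { gr$sc1_W <- crossprod(cache$X, dx1); dX <- dX + tcrossprod(dx1, p$sc1_W) }

  # gradients into the projected vectors
  dg <- vector("list", Vd); dh <- vector("list", Vc)
  for (k in seq_len(Vd)) dg[[k]] <- dgcat[, ((k - 1L) * s + 1L):(k * s), drop = FALSE]
  for (l in seq_len(Vc)) dh[[l]] <- dhcat[, ((l - 1L) * s + 1L):(l * s), drop = FALSE]
  for (k in seq_len(Vd)) for (l in seq_len(Vc)) {
    chn <- (k - 1L) * Vc + l
    dI <- dinner[, ((chn - 1L) * s + 1L):(chn * s), drop = FALSE]
    dg[[k]] <- dg[[k]] + dI * cache$h[[l]]
    dh[[l]] <- dh[[l]] + dI * cache$g[[k]]
    # outer map channel: d(outer[b, p]) with p = (q-1)*s + r
    dO <- t(matrix(dX[, chn], hw, B))         # B x hw
    dg[[k]] <- dg[[k]] + (dO * cache$h[[l]][, oi$qq, drop = FALSE]) %*% oi$Rind
    dh[[l]] <- dh[[l]] + (dO * cache$g[[k]][, oi$rr, drop = FALSE]) %*% oi$Qind
  }
  for (k in seq_len(Vd))
    gr[[sprintf("G%02d", k)]] <- crossprod(cache$batch$drug[[k]], dg[[k]])
  for (l in seq_len(Vc))
    gr[[sprintf("H%d", l)]] <- crossprod(cache$batch$cell[[l]], dh[[l]])
  gr
}

# Slice per-pair input rows out of the full view matrices.
make_batch <- function(inputs, di, ci) {
  list(drug = lapply(inputs$drug_views, function(M) M[di, , drop = FALSE]),
       fused = inputs$fused[di, , drop = FALSE],
       cell = lapply(inputs$cell_views, function(M) M[ci, , drop = FALSE]))
}

#' Predict IC50 for (drug, cell) pairs
#'
#' @param model a trained [drp_model()].
#' @param inputs model input container from [prepare_model_inputs()].
#' @param pairs data frame with integer columns `drug_idx`, `cell_idx`.
#' @param batch_size forward batch size.
#' @return numeric vector of predicted IC50 values.
#' @export
predict_drp <- function(model, inputs, pairs,
                        batch_size = model$spec$batch_size) {
  n <- nrow(pairs)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    b <- make_batch(inputs, pairs$drug_idx[idx], pairs$cell_idx[idx])
    out[idx] <- drp_forward(model, b)$pred
  }
  out
}

#' Train the model with Adam and early stopping
#'
#' Minimizes mean squared error on the training pairs; after each epoch the
#' validation loss is evaluated, and training stops once it has not improved
#' for `spec$patience` epochs (or at `spec$max_epochs`). The parameters from
#' the best-validation epoch are returned.
#'
#' @param model a [drp_model()].
#' @param inputs input container from [prepare_model_inputs()].
#' @param pairs data frame with `drug_idx`, `cell_idx`, `ic50`, `split`
#'   (containing `"train"` and `"val"` rows).
#' @param seed RNG seed controlling shuffling (training is fully
#'   deterministic given the seed).
#' @param verbose print per-epoch losses.
#' @return the model with trained `params` and a `history` data frame
#'   (epoch, train_loss, val_loss) plus `best_epoch`.
#' @export
train_drp <- function(model, inputs, pairs, seed = 1L, verbose = FALSE) {
  spec <- model$spec
  tr <- pairs[pairs$split == "train", ]
  va <- pairs[pairs$split == "val", ]
  if (nrow(tr) == 0L) stop("train_drp: empty training split")
  if (nrow(va) == 0L) stop("train_drp: empty validation split")
  set.seed(seed)
  params <- model$params
  state <- adam_init(params)
  best_val <- Inf; best_epoch <- 0L; best_params <- params
  hist_tr <- numeric(0); hist_va <- numeric(0)

  val_loss <- function(params) {
    m2 <- model; m2$params <- params
    pv <- predict_drp(m2, inputs, va)
    mean((pv - va$ic50)^2)
  }
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(nrow(tr))
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, nrow(tr), by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1L, nrow(tr))]
      b <- make_batch(inputs, tr$drug_idx[idx], tr$cell_idx[idx])
      fw <- drp_forward(model_with(model, params), b)
      err <- fw$pred - tr$ic50[idx]
      ep_loss <- ep_loss + sum(err^2); ep_n <- ep_n + length(err)
      gr <- drp_backward(model_with(model, params), fw$cache,
                         2 * err / length(err))
      upd <- adam_step(params, gr, state, spec$lr, spec$weight_decay)
      params <- upd$params; state <- upd$state
    }
    vl <- val_loss(params)
    hist_tr <- c(hist_tr, ep_loss / ep_n); hist_va <- c(hist_va, vl)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / ep_n, vl))
    if (vl < best_val) { best_val <- vl; best_epoch <- epoch; best_params <- params }
    if (is.finite(spec$patience) && epoch - best_epoch >= spec$patience) break
  }
  model$params <- best_params
  model$history <- data.frame(epoch = seq_along(hist_tr),
                              train_loss = hist_tr, val_loss = hist_va)
  model$best_epoch <- best_epoch
  model
}

model_with <- function(model, params) { model$params <- params; model }
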