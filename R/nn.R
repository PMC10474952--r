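# Minimal dense/conv neural-network engine.
#
# All layers operate on batches as plain matrices so that forward and
# backward passes reduce to BLAS calls. Convolutions use im2col: a batch of
# C-channel s x s grids is stored as a (B*s^2) x C matrix whose rows iterate
# pixels fastest within a sample (pixel p = (q-1)*s + r for grid cell
# (r, q)); gathering the k^2 shifted copies turns each convolution into a
# single matrix product.

relu <- function(x) (x > 0) * x

add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

# He-scaled Gaussian init for ReLU layers; callers seed the RNG.
init_weight <- function(fan_in, fan_out, gain = 2) {
  matrix(rnorm(fan_in * fan_out, sd = sqrt(gain / fan_in)), fan_in, fan_out)
}

# Convolution geometry for an s x s grid with an odd k x k kernel,
# same-padding, stride 1. Memoizes the batch-expanded gather indices per
# batch size B (the padding dummy row is B*s^2 + 1).
conv_geom <- function(s, k) {
  if (k %% 2 != 1) stop("conv_geom: kernel size must be odd")
  if (s < k) stop(sprintf("conv_geom: grid %d smaller than kernel %d", s, k))
  pad <- (k - 1L) %/% 2L
  hw <- s * s
  r <- rep(seq_len(s), times = s)
  q <- rep(seq_len(s), each = s)
  idx <- vector("list", k * k)
  o <- 0L
  for (dq in -pad:pad) for (dr in -pad:pad) {
    o <- o + 1L
    r2 <- r + dr; q2 <- q + dq
    ok <- r2 >= 1L & r2 <= s & q2 >= 1L & q2 <= s
    v <- ifelse(ok, (q2 - 1L) * s + r2, NA_integer_)
    idx[[o]] <- v
  }
  env <- new.env(parent = emptyenv())
  list(s = s, k = k, hw = hw, idx = idx, cache = env)
}

conv_gather_idx <- function(geom, B) {
  key <- as.character(B)
  g <- geom$cache[[key]]
  if (!is.null(g)) return(g)
  hw <- geom$hw
  off <- rep((seq_len(B) - 1L) * hw, each = hw)
  pad_row <- B * hw + 1L
  g <- lapply(geom$idx, function(iv) {
    gv <- off + rep(iv, times = B)
    gv[is.na(gv)] <- pad_row
    gv
  })
  geom$cache[[key]] <- g
  g
}

# im2col: (B*hw) x C input -> (B*hw) x (k^2*C) patch matrix
conv_im2col <- function(X, geom, B) {
  C <- ncol(X)
  k2 <- geom$k^2
  gidx <- conv_gather_idx(geom, B)
  Xext <- rbind(X, 0)
  col <- matrix(0, B * geom$hw, k2 * C)
  for (o in seq_len(k2))
    col[, ((o - 1L) * C + 1L):(o * C)] <- Xext[gidx[[o]], ]
  col
}

conv_forward <- function(X, W, b, geom, B) {
  col <- conv_im2col(X, geom, B)
  list(Y = add_bias(col %*% W, b), col = col)
}

conv_backward <- function(dY, col, W, geom, B, C_in) {
  k2 <- geom$k^2
  dW <- crossprod(col, dY)
  db <- colSums(dY)
  dcol <- tcrossprod(dY, W)
  gidx <- conv_gather_idx(geom, B)
  dXext <- matrix(0, B * geom$hw + 1L, C_in)
  for (o in seq_len(k2)) {
    g <- gidx[[o]]
    real <- g <= B * geom$hw     # non-pad targets are unique within an offset
    dXext[g[real], ] <- dXext[g[real], ] + dcol[real, ((o - 1L) * C_in + 1L):(o * C_in)]
  }
  list(dX = dXext[seq_len(B * geom$hw), , drop = FALSE], dW = dW, db = db)
}

# Global max-pool over the spatial grid: (B*hw) x C -> B x C, remembering
# argmax positions for the backward pass. Ties break at the first pixel.
maxpool_forward <- function(Y, B, hw) {
  C <- ncol(Y)
  M <- matrix(as.vector(Y), hw, B * C)   # column (b, c), b fastest
  am <- max.col(t(M), ties.method = "first")
  val <- M[cbind(am, seq_len(B * C))]
  list(Y = matrix(val, B, C), argmax = am)
}

maxpool_backward <- function(dpool, argmax, B, hw, C) {
  dY <- matrix(0, B * hw, C)
  g <- seq_len(B * C)
  b <- (g - 1L) %% B + 1L
  cc <- (g - 1L) %/% B + 1L
  dY[cbind((b - 1L) * hw + argmax, cc)] <- dpool[cbind(b, cc)]
  dY
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zero, v = zero, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam step with L2-coupled weight decay (decay added to the gradient,
# the convention of the reference deep-learning optimizers).
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Early-stopping rule on validation losses
#'
#' Returns the 1-based epoch at which training stops: the first epoch whose
#' distance from the best (lowest) validation loss so far reaches `patience`,
#' or the final epoch if the rule never fires. With `patience = 10` and a
#' validation loss that never improves after epoch 1, training stops at
#' epoch 11.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience epochs to wait for an improvement.
#' @return integer stopping epoch.
#' @export
early_stop_epoch <- function(val_losses, patience) {
  if (!is.finite(patience)) return(length(val_losses))
  best <- Inf; best_e <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) { best <- val_losses[e]; best_e <- e }
    if (e - best_e >= patience) return(e)
  }
  length(val_losses)
}
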