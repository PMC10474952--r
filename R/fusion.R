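#' SNF hyperparameters
#'
#' @param K neighborhood size for the sparse kernel; default
#'   `max(3, round(n/10))`, resolved against the matrix size at fusion time.
#' @param T number of cross-diffusion iterations.
#' @param mu kernel bandwidth scaling, used when affinities are built from
#'   distances; carried in the run metadata (the fusion of ready-made
#'   similarity views does not need it).
#' @return list of class `snf_params`.
#' @export
snf_params <- function(K = NULL, T = 20L, mu = 0.5) {
  stopifnot(T >= 0, mu > 0, is.null(K) || K >= 1)
  structure(list(K = K, T = as.integer(T), mu = mu), class = "snf_params")
}

# Full-kernel normalization: diagonal 1/2, off-diagonal rows summing to 1/2.
# Rows with no off-diagonal mass keep zero off-diagonals.
snf_p_normalize <- function(W) {
  n <- nrow(W)
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# K-nearest-neighbour sparse kernel, row-normalized over the K neighbours.
# The entity itself counts as a candidate neighbour (its self-similarity is
# maximal); ties break deterministically by index order.
snf_knn_kernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    keep <- order(-W[i, ], seq_len(n))[seq_len(K)]
    w <- W[i, keep]
    tot <- sum(w)
    if (tot == 0) { w <- rep(1 / K, K); tot <- 1; w <- w * tot }
    S[i, keep] <- w / max(tot, 1e-12)
  }
  S
}

#' Fuse similarity views by similarity network fusion
#'
#' Standard SNF cross-diffusion: each view is (a) normalized to a full kernel
#' `P_v` with diagonal 1/2 and off-diagonal rows summing to 1/2, and (b)
#' reduced to a row-normalized K-nearest-neighbour kernel `S_v`. Then for T
#' rounds each `P_v` is replaced by `S_v %*% mean(P_u, u != v) %*% t(S_v)`,
#' symmetrized and re-normalized. The output is the symmetrized mean of the
#' final `P_v`. With `T = 0` the output is simply the mean of the normalized
#' inputs.
#'
#' @param views list of >= 2 [similarity_view()] objects on one entity index.
#' @param params [snf_params()].
#' @return A `fused_similarity`: symmetric nonnegative matrix with attributes
#'   `index`, `source_views`, `snf_params`.
#' @export
snf_fuse <- function(views, params = snf_params()) {
  if (length(views) < 2L) stop("snf_fuse: need at least 2 views")
  n <- nrow(views[[1]])
  if (n < 3L) stop("snf_fuse: need at least 3 entities")
  index <- attr(views[[1]], "index")
  for (v in views) {
    if (nrow(v) != n || ncol(v) != n) stop("snf_fuse: views differ in size")
    if (max(abs(unclass(v) - t(unclass(v)))) > 1e-8)
      stop("snf_fuse: non-symmetric input view")
    iv <- attr(v, "index")
    if (!is.null(index) && !is.null(iv) && !same_index(iv, index))
      stop("snf_fuse: views on different entity indices")
  }
  K <- if (is.null(params$K)) max(3L, round(n / 10)) else as.integer(params$K)
  if (K >= n) stop(sprintf("snf_fuse: K = %d must be < n = %d", K, n))
  Tn <- params$T

  Ws <- lapply(views, function(v) unclass(v))
  P <- lapply(Ws, snf_p_normalize)
  S <- lapply(Ws, snf_knn_kernel, K = K)
  V <- length(P)
  if (Tn > 0) {
    for (t in seq_len(Tn)) {
      Psum <- Reduce(`+`, P)
      Pnew <- vector("list", V)
      for (v in seq_len(V)) {
        Pbar <- (Psum - P[[v]]) / (V - 1)
        Q <- S[[v]] %*% Pbar %*% t(S[[v]])
        Q <- (Q + t(Q)) / 2
        Pnew[[v]] <- snf_p_normalize(Q)
      }
      P <- Pnew
    }
  }
  fused <- Reduce(`+`, P) / V
  fused <- (fused + t(fused)) / 2
  src <- vapply(views, function(v) {
    vn <- attr(v, "view_name"); if (is.null(vn)) NA_character_ else vn
  }, character(1))
  if (!is.null(index)) dimnames(fused) <- list(index$ids, index$ids)
  structure(fused, index = index, source_views = src,
            snf_params = list(K = K, T = Tn, mu = params$mu),
            class = c("fused_similarity", "matrix", "array"))
}

#' @export
print.fused_similarity <- function(x, ...) {
  p <- attr(x, "snf_params")
  cat(sprintf("<fused_similarity> %d x %d from %d views (K=%d, T=%d)\n",
              nrow(x), ncol(x), length(attr(x, "source_views")), p$K, p$T))
  invisible(x)
}

#' Fuse the six fingerprint similarity views
#'
#' Convenience wrapper over [snf_fuse()] for the SMILES-derived views; the
#' result is the dense structural similarity used to complete sparse
#' association views.
#'
#' @param fingerprint_views named list containing the six fingerprint
#'   `similarity_view`s (ECFP, PSFP, DFP, RDKFP, ESPFP, ERGFP).
#' @param params [snf_params()].
#' @return a `fused_similarity` whose `source_views` are the six fingerprint
#'   names.
#' @export
fuse_smiles_views <- function(fingerprint_views, params = snf_params()) {
  fp <- names(FINGERPRINT_DIMS)
  missing <- setdiff(fp, names(fingerprint_views))
  if (length(missing))
    stop("fuse_smiles_views: missing fingerprint view(s): ",
         paste(missing, collapse = ", "))
  snf_fuse(fingerprint_views[fp], params)
}

#' Complete a sparse similarity view from the fused fingerprint similarity
#'
#' For every entity whose source feature row was all-zero (no recorded
#' associations), the corresponding row AND column of the similarity view are
#' replaced by the same row/column of the fused fingerprint similarity; all
#' other entries are untouched, symmetry is preserved and the diagonal is
#' re-forced to 1.
#'
#' @param view a [similarity_view()] with a `zero_row_mask`.
#' @param fused_smiles a `fused_similarity` from [fuse_smiles_views()].
#' @return the completed `similarity_view`, with attribute `filled_entities`
#'   (character vector of replaced entity ids, empty when nothing was
#'   filled).
#' @export
fill_sparse_view <- function(view, fused_smiles) {
  stopifnot(inherits(view, "similarity_view"))
  if (nrow(view) != nrow(fused_smiles))
    stop("fill_sparse_view: size mismatch between view and fused matrix")
  iv <- attr(view, "index"); ifu <- attr(fused_smiles, "index")
  if (!is.null(iv) && !is.null(ifu) && !same_index(iv, ifu))
    stop("fill_sparse_view: view and fused matrix on different entity indices")
  mask <- attr(view, "zero_row_mask")
  S <- unclass(view)
  Ffu <- unclass(fused_smiles)
  if (any(mask)) {
    S[mask, ] <- Ffu[mask, ]
    S[, mask] <- Ffu[, mask]
    diag(S) <- 1
  }
  out <- similarity_view(S, iv, attr(view, "view_name"),
                         metric = attr(view, "metric"),
                         zero_row_mask = rep(FALSE, nrow(S)))
  attr(out, "filled_entities") <-
    if (is.null(iv)) which(mask) else iv$ids[mask]
  out
}

#' Fuse all twelve drug similarity views
#'
#' Applies [snf_fuse()] to the full drug view set (six fingerprint views,
#' five completed association-derived views, and the response-profile view);
#' the result provides each drug's fused similarity vector for the model.
#'
#' @param drug_views named list of exactly 12 `similarity_view`s.
#' @param params [snf_params()].
#' @return a `fused_similarity`.
#' @export
fuse_all_drug_views <- function(drug_views, params = snf_params()) {
  if (length(drug_views) != 12L)
    stop("fuse_all_drug_views: expected 12 views, got ", length(drug_views))
  snf_fuse(drug_views, params)
}
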