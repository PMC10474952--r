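#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates the structure of a GDSC/CCLE-style benchmark at
#' fixture scale: drugs and cell lines carry low-dimensional latent vectors;
#' fingerprints are thresholded random projections of the drug latents (so
#' structurally similar drugs get similar bit patterns), association edges
#' are sampled with probability increasing in latent similarity to per-view
#' anchors, omics matrices are noisy linear read-outs of the cell latents,
#' and IC50 is a planted bilinear signal `u_i' A w_j` (scaled to unit
#' standard deviation) plus Gaussian noise.
#'
#' @param n_drugs,m_cells entity counts (>= 3).
#' @param latent_dim latent dimension of the planted signal.
#' @param noise_sd IC50 noise standard deviation, relative to the unit-sd
#'   signal (0.1 = 10% of the signal scale).
#' @param zero_row_fraction fraction of drugs per association view left with
#'   no edges (in \[0, 0.5\]); these are the entities the completion step
#'   must fill.
#' @param pair_density fraction of the drug x cell grid with an observed
#'   IC50.
#' @param n_genes number of genes in the omics panel (the full-scale panel
#'   has 706 cancer genes; fixtures use fewer).
#' @param assoc_sizes named partner-vocabulary sizes for the four
#'   association views.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `synthetic_config`.
#' @export
synthetic_config <- function(n_drugs = 30L, m_cells = 40L, latent_dim = 4L,
                             noise_sd = 0.1, zero_row_fraction = 0.1,
                             pair_density = 0.85, n_genes = 50L,
                             assoc_sizes = c(target = 40L, disease = 60L,
                                             miRNA = 30L, ADR = 50L),
                             seed = 1L) {
  stopifnot(n_drugs >= 3, m_cells >= 3, latent_dim >= 1, noise_sd >= 0,
            zero_row_fraction >= 0, zero_row_fraction <= 0.5,
            pair_density > 0, pair_density <= 1,
            all(DRUG_ASSOC_VIEWS %in% names(assoc_sizes)))
  structure(list(n_drugs = as.integer(n_drugs), m_cells = as.integer(m_cells),
                 latent_dim = as.integer(latent_dim), noise_sd = noise_sd,
                 zero_row_fraction = zero_row_fraction,
                 pair_density = pair_density, n_genes = as.integer(n_genes),
                 assoc_sizes = assoc_sizes, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic input bundle with a planted bilinear signal
#'
#' @param cfg a [synthetic_config()].
#' @return a bundle list: `drug_index`, `cell_index`, `fingerprints` (six
#'   precomputed matrices), `assoc` (four [association_table()]s),
#'   `combined` (weighted [association_table()]), `omics` (exp/mu/cnv),
#'   `pairs` (drug_id, cell_id, ic50), and `truth` (latents, mixing matrix
#'   and zero-row designations, for oracle checks).
#' @export
generate_bundle <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_drugs; m <- cfg$m_cells; d <- cfg$latent_dim
  d_idx <- entity_index(sprintf("drug%03d", seq_len(n)), "drug")
  c_idx <- entity_index(sprintf("cell%03d", seq_len(m)), "cell")
  U <- matrix(rnorm(n * d), n, d)
  W <- matrix(rnorm(m * d), m, d)

  # six fingerprint views: thresholded (binary) or squashed (continuous)
  # random projections of the drug latents
  fingerprints <- lapply(names(FINGERPRINT_DIMS), function(v) {
    nb <- FINGERPRINT_DIMS[[v]]
    R <- matrix(rnorm(d * nb), d, nb)
    Z <- U %*% R
    M <- if (v == "RDKFP") stats::plogis(Z) else (Z > 0) * 1
    rownames(M) <- d_idx$ids
    M
  })
  names(fingerprints) <- names(FINGERPRINT_DIMS)

  # association views: edge probability increases with latent alignment to
  # per-partner anchors; designated drugs get all edges removed
  n_zero <- floor(cfg$zero_row_fraction * n)
  zero_rows <- list()
  assoc <- list()
  for (v in DRUG_ASSOC_VIEWS) {
    q <- cfg$assoc_sizes[[v]]
    A <- matrix(rnorm(d * q), d, q)
    P <- stats::plogis(1.5 * (U %*% A) / sqrt(d) - 0.5)
    E <- matrix(runif(n * q), n, q) < P
    zr <- if (n_zero > 0) sample.int(n, n_zero) else integer(0)
    E[zr, ] <- FALSE
    ij <- which(E, arr.ind = TRUE)
    assoc[[v]] <- association_table(
      data.frame(entity_id = d_idx$ids[ij[, 1]],
                 partner_id = sprintf("%s_%03d", v, ij[, 2])),
      partner_vocabulary = sprintf("%s_%03d", v, seq_len(q)))
    zero_rows[[v]] <- d_idx$ids[zr]
  }

  # combined scores: latent-kernel similarity on the 1..1000 scale, with
  # designated score-less drugs
  D2 <- as.matrix(stats::dist(U))^2
  score <- round(1000 * exp(-D2 / (2 * d)))
  score <- pmin(pmax(score, 1), 1000)
  zr_comb <- if (n_zero > 0) sample.int(n, n_zero) else integer(0)
  ut <- which(upper.tri(score), arr.ind = TRUE)
  keep <- !(ut[, 1] %in% zr_comb) & !(ut[, 2] %in% zr_comb)
  ut <- ut[keep, , drop = FALSE]
  combined <- association_table(
    data.frame(entity_id = d_idx$ids[ut[, 1]], partner_id = d_idx$ids[ut[, 2]],
               score = score[ut]),
    partner_vocabulary = d_idx$ids)
  zero_rows$combined <- d_idx$ids[zr_comb]

  # omics: noisy linear read-outs of the cell latents
  p <- cfg$n_genes
  mk_readout <- function() W %*% matrix(rnorm(d * p), d, p) +
    0.5 * matrix(rnorm(m * p), m, p)
  exp_m <- mk_readout()
  mu_m <- (mk_readout() > 0.8) * 1
  cnv_m <- mk_readout()
  dimnames(exp_m) <- dimnames(mu_m) <- dimnames(cnv_m) <-
    list(c_idx$ids, sprintf("gene%03d", seq_len(p)))

  # planted bilinear response, unit signal sd
  A0 <- matrix(rnorm(d * d), d, d)
  Sg <- U %*% A0 %*% t(W)
  Sg <- Sg / sd(Sg)
  n_pairs <- max(10L, floor(cfg$pair_density * n * m))
  sel <- sample.int(n * m, n_pairs)
  di <- (sel - 1L) %% n + 1L
  ci <- (sel - 1L) %/% n + 1L
  ic50 <- Sg[cbind(di, ci)] + cfg$noise_sd * rnorm(n_pairs)
  pairs <- data.frame(drug_id = d_idx$ids[di], cell_id = c_idx$ids[ci],
                      ic50 = ic50)

  list(drug_index = d_idx, cell_index = c_idx, fingerprints = fingerprints,
       assoc = assoc, combined = combined,
       omics = list(exp = exp_m, mu = mu_m, cnv = cnv_m),
       pairs = pairs,
       truth = list(U = U, W = W, A = A0, signal = Sg, zero_rows = zero_rows,
                    config = cfg))
}

#' Held-out accuracy of the planted-signal oracle
#'
#' Fits the bilinear generative model by least squares on the true latents
#' (features: all products `u_i[a] * w_j[b]` plus an intercept) using the
#' training pairs, and reports the Pearson correlation on the test pairs.
#' This is the ceiling against which the neural model's synthetic-benchmark
#' performance is judged; with `noise_sd = 0` it reaches r = 1.
#'
#' @param bundle a bundle from [generate_bundle()] (needs `truth`).
#' @param pairs split pair table from [split_pairs()] with `drug_idx`,
#'   `cell_idx` columns (resolved against the bundle indices).
#' @return Pearson r on the test split.
#' @export
planted_signal_check <- function(bundle, pairs) {
  if (is.null(bundle$truth)) stop("planted_signal_check: bundle has no latents")
  U <- bundle$truth$U; W <- bundle$truth$W
  feats <- function(px) {
    X <- matrix(0, nrow(px), ncol(U) * ncol(W))
    k <- 0L
    for (a in seq_len(ncol(U))) for (b in seq_len(ncol(W))) {
      k <- k + 1L
      X[, k] <- U[px$drug_idx, a] * W[px$cell_idx, b]
    }
    cbind(1, X)
  }
  tr <- pairs[pairs$split %in% c("train", "val"), ]
  te <- pairs[pairs$split == "test", ]
  fit <- stats::lm.fit(feats(tr), tr$ic50)
  pred <- feats(te) %*% fit$coefficients
  cor(as.vector(pred), te$ic50)
}
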