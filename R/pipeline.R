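#' Split (drug, cell, IC50) pairs for evaluation
#'
#' Supported schemes:
#' * `random`: pairs shuffled into train/val/test at 8:1:1.
#' * `es1` (drug-blind): 20% of drugs are blinded; all their pairs form the
#'   test set and never appear in train or val. Of the remaining pairs,
#'   `val_fraction` go to validation.
#' * `es2` (cell-blind): the same with cell lines blinded.
#' * `independent`: an external pair table becomes the test set verbatim;
#'   the base pairs are split into train and validation.
#'
#' For `es1`/`es2`, `entity_ratio_411 = TRUE` switches to the entity-level
#' reading of the 4:1:1 ratio: the selected 20% of entities are themselves
#' distributed 4:1:1 into blinded-test, blinded-validation and
#' returned-to-train buckets.
#'
#' @param pairs data frame with `drug_id`, `cell_id`, `ic50` (and optionally
#'   pre-resolved `drug_idx`, `cell_idx`).
#' @param scheme one of `"random"`, `"es1"`, `"es2"`, `"independent"`.
#' @param seed RNG seed; identical seeds give identical splits.
#' @param blind_fraction fraction of entities blinded under es1/es2.
#' @param val_fraction fraction of non-test pairs used for validation.
#' @param entity_ratio_411 alternative es1/es2 interpretation (see above).
#' @param independent_pairs external test pairs for `scheme = "independent"`.
#' @return `pairs` with a `split` factor column (`train`/`val`/`test`).
#' @export
split_pairs <- function(pairs, scheme = c("random", "es1", "es2", "independent"),
                        seed = 1L, blind_fraction = 0.2, val_fraction = 1 / 6,
                        entity_ratio_411 = FALSE, independent_pairs = NULL) {
  scheme <- match.arg(scheme)
  if (nrow(pairs) < 10L) stop("split_pairs: need at least 10 pairs")
  set.seed(seed)
  n <- nrow(pairs)
  pairs$split <- NA_character_
  if (scheme == "random") {
    ord <- sample.int(n)
    n_test <- floor(n / 10); n_val <- floor(n / 10)
    pairs$split[ord[seq_len(n_test)]] <- "test"
    pairs$split[ord[n_test + seq_len(n_val)]] <- "val"
    pairs$split[is.na(pairs$split)] <- "train"
  } else if (scheme %in% c("es1", "es2")) {
    key <- if (scheme == "es1") pairs$drug_id else pairs$cell_id
    ents <- unique(key)
    if (length(ents) < 6L)
      stop("split_pairs: need >= 6 distinct blinded entities, have ",
           length(ents))
    n_blind <- max(1L, round(blind_fraction * length(ents)))
    blinded <- sample(ents, n_blind)
    if (entity_ratio_411) {
      # distribute the blinded entities 4:1:1 test : val-only : train-visible
      shuf <- sample(blinded)
      n_t <- max(1L, round(length(shuf) * 4 / 6))
      n_v <- max(1L, min(round(length(shuf) / 6), length(shuf) - n_t))
      test_ents <- shuf[seq_len(n_t)]
      val_ents <- shuf[n_t + seq_len(n_v)]
      pairs$split[key %in% test_ents] <- "test"
      pairs$split[key %in% val_ents] <- "val"
      rest <- which(is.na(pairs$split))
      pairs$split[rest] <- "train"
    } else {
      pairs$split[key %in% blinded] <- "test"
      rest <- which(is.na(pairs$split))
      nv <- max(1L, floor(length(rest) * val_fraction))
      pairs$split[sample(rest, nv)] <- "val"
      pairs$split[is.na(pairs$split)] <- "train"
    }
  } else { # independent
    if (is.null(independent_pairs))
      stop("split_pairs: scheme 'independent' needs independent_pairs")
    ord <- sample.int(n)
    nv <- max(1L, floor(n * val_fraction))
    pairs$split[ord[seq_len(nv)]] <- "val"
    pairs$split[is.na(pairs$split)] <- "train"
    independent_pairs$split <- "test"
    pairs <- rbind(pairs[, c("drug_id", "cell_id", "ic50", "split")],
                   independent_pairs[, c("drug_id", "cell_id", "ic50", "split")])
  }
  pairs$split <- factor(pairs$split, levels = c("train", "val", "test"))
  attr(pairs, "scheme") <- scheme
  attr(pairs, "seed") <- seed
  pairs
}

#' Regression metrics for predicted IC50 values
#'
#' Root mean square error, mean absolute error and the Pearson correlation
#' between predictions and ground truth. A constant truth (or prediction)
#' vector leaves the correlation undefined; it is then reported as `NA` with
#' `r_defined = FALSE` rather than silently propagating `NaN`.
#'
#' @param pred,truth equal-length numeric vectors, `length >= 2`.
#' @return a `metrics_report` list: `rmse`, `mae`, `pearson_r`, `n_pairs`,
#'   `r_defined`.
#' @export
evaluate_predictions <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("evaluate_predictions: length mismatch")
  if (length(pred) < 2L) stop("evaluate_predictions: need >= 2 pairs")
  err <- pred - truth
  r_def <- sd(truth) > 0 && sd(pred) > 0
  structure(list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 pearson_r = if (r_def) cor(pred, truth) else NA_real_,
                 n_pairs = length(pred), r_defined = r_def),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  RMSE %.4f  MAE %.4f  r %s\n",
              x$n_pairs, x$rmse, x$mae,
              if (x$r_defined) sprintf("%.4f", x$pearson_r) else "undefined"))
  invisible(x)
}

#' Assemble all feature and similarity views from a data bundle
#'
#' Runs the featurize / similarity / completion / fusion stages: builds the
#' 12 drug and 4 cell feature matrices (IC50 profiles from the training
#' triples only, so evaluation labels never leak into the features), converts
#' them to similarity views, SNF-fuses the six fingerprint views, completes
#' the five sparse association-derived views from that fused matrix, and
#' finally fuses all 12 drug views.
#'
#' @param bundle input bundle (see [generate_bundle()] for the layout).
#' @param train_triples data frame of training-split `drug_id`, `cell_id`,
#'   `ic50` used for the response-profile matrices.
#' @param snf [snf_params()].
#' @param metric distance metric for the similarity views.
#' @return list with `views` (completed drug views + cell views),
#'   `fused_smiles`, `fused_all`, and the raw `features`.
#' @export
assemble_features <- function(bundle, train_triples, snf = snf_params(),
                              metric = "chebyshev") {
  d_idx <- bundle$drug_index; c_idx <- bundle$cell_index
  fps <- if (!is.null(bundle$fingerprints))
    build_fingerprint_matrices(index = d_idx, precomputed = bundle$fingerprints)
  else
    build_fingerprint_matrices(smiles = bundle$smiles, index = d_idx)
  drug_feats <- fps
  for (v in DRUG_ASSOC_VIEWS)
    drug_feats[[v]] <- build_association_matrix(bundle$assoc[[v]], d_idx, v)
  drug_feats$combined <- build_combined_score_matrix(bundle$combined, d_idx)
  prof <- build_ic50_profile_matrices(train_triples, d_idx, c_idx)
  # drugs present in training triples must have a nonzero response profile
  seen <- d_idx$ids %in% unique(train_triples$drug_id)
  if (any(seen & attr(prof$M_DC, "zero_rows")))
    warning("assemble_features: drug(s) in training triples with all-zero IC50 profile")
  drug_feats$ic50_profile <- prof$M_DC
  cell_feats <- list(exp = feature_matrix(bundle$omics$exp, c_idx, "exp"),
                     mu = feature_matrix(bundle$omics$mu, c_idx, "mu"),
                     cnv = feature_matrix(bundle$omics$cnv, c_idx, "cnv"),
                     ic50_profile = prof$M_CD)
  views <- build_all_views(drug_feats, cell_feats, metric = metric)
  fused_smiles <- fuse_smiles_views(views$drug[names(FINGERPRINT_DIMS)], snf)
  for (v in c("combined", DRUG_ASSOC_VIEWS))
    views$drug[[v]] <- fill_sparse_view(views$drug[[v]], fused_smiles)
  fused_all <- fuse_all_drug_views(views$drug, snf)
  list(views = views, fused_smiles = fused_smiles, fused_all = fused_all,
       features = list(drug = drug_feats, cell = cell_feats))
}

#' Prepare the model input container
#'
#' Unwraps the similarity/feature views into plain matrices and z-scores the
#' omics views per feature using statistics from the training cell lines
#' only (cold-start cells reuse the train-fitted statistics).
#'
#' @param views output `views` of [assemble_features()].
#' @param fused the all-view `fused_similarity`.
#' @param train_cells integer indices of cell lines appearing in training
#'   pairs; `NULL` uses all cells.
#' @return list with `drug_views` (list of 12 matrices), `fused`,
#'   `cell_views` (list of 4 matrices), and the standardization statistics.
#' @export
prepare_model_inputs <- function(views, fused, train_cells = NULL) {
  drug_views <- lapply(views$drug, function(v) unclass(v))
  cell_views <- lapply(views$cell, function(v) unclass(v))
  stats <- list()
  for (v in intersect(c("exp", "cnv", "mu"), names(cell_views))) {
    M <- cell_views[[v]]
    ref <- if (is.null(train_cells)) M else M[train_cells, , drop = FALSE]
    ctr <- colMeans(ref)
    scl <- apply(ref, 2, sd); scl[scl == 0 | !is.finite(scl)] <- 1
    cell_views[[v]] <- sweep(sweep(M, 2, ctr), 2, scl, "/")
    stats[[v]] <- list(center = ctr, scale = scl)
  }
  list(drug_views = drug_views, fused = unclass(fused),
       cell_views = cell_views, standardization = stats)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline on a bundle
#'
#' featurize -> similarity -> completion/fusion -> split -> train ->
#' evaluate, with per-stage error reporting. All randomness derives from
#' `seed`.
#'
#' @param bundle input bundle (from [generate_bundle()] or [read_bundle()]).
#' @param scheme evaluation scheme passed to [split_pairs()].
#' @param spec a [model_spec()]; defaults to [small_model_spec()] sized for
#'   fixture-scale bundles.
#' @param snf [snf_params()].
#' @param seed integer seed for split, initialization and training.
#' @param out optional directory; when given, features, views, fused
#'   matrices, the training history and metrics are serialized there.
#' @param ... extra arguments for [split_pairs()].
#' @return list: `pairs`, `assembled`, `inputs`, `model`, `predictions`,
#'   `metrics`.
#' @export
run_pipeline <- function(bundle, scheme = "random", spec = small_model_spec(),
                         snf = snf_params(), seed = 1L, out = NULL, ...) {
  pairs <- with_stage("split",
    split_pairs(bundle$pairs, scheme, seed = seed, ...))
  pairs$drug_idx <- with_stage("split",
    match_ids(pairs$drug_id, bundle$drug_index, "drug"))
  pairs$cell_idx <- with_stage("split",
    match_ids(pairs$cell_id, bundle$cell_index, "cell"))
  train_triples <- pairs[pairs$split == "train", ]
  asm <- with_stage("featurize+similarity+fusion",
    assemble_features(bundle, train_triples, snf))
  inputs <- with_stage("prepare",
    prepare_model_inputs(asm$views, asm$fused_all,
                         train_cells = unique(train_triples$cell_idx)))
  model <- with_stage("model", {
    m <- drp_model(spec,
                   drug_view_dims = vapply(inputs$drug_views, ncol, 1L),
                   cell_view_dims = vapply(inputs$cell_views, ncol, 1L),
                   fused_dim = ncol(inputs$fused), seed = seed)
    train_drp(m, inputs, pairs, seed = seed)
  })
  test <- pairs[pairs$split == "test", ]
  pred <- with_stage("evaluate", predict_drp(model, inputs, test))
  metrics <- with_stage("evaluate", evaluate_predictions(pred, test$ic50))
  metrics$scheme <- scheme
  res <- list(pairs = pairs, assembled = asm, inputs = inputs, model = model,
              predictions = data.frame(test[, c("drug_id", "cell_id", "ic50")],
                                       pred = pred),
              metrics = metrics)
  if (!is.null(out)) with_stage("serialize", write_run_artifacts(res, out, seed, snf))
  res
}

#' Leave-one-view-out ablation harness
#'
#' Retrains the model from scratch once per excluded view: each of the 12
#' drug views and each of the 4 cell views is dropped in turn (16 runs with
#' the full configuration). Dropping a drug view also removes it from the
#' all-view fusion; model shapes adapt to the reduced view counts, so an
#' 11 x 4 run uses 44 interaction maps and a 12 x 3 run uses 36.
#'
#' @param bundle input bundle.
#' @param scheme,spec,snf,seed as in [run_pipeline()].
#' @return data frame: `excluded`, `side`, `n_maps`, `rmse`, `mae`,
#'   `pearson_r`.
#' @export
ablate_views <- function(bundle, scheme = "random", spec = small_model_spec(),
                         snf = snf_params(), seed = 1L) {
  pairs <- split_pairs(bundle$pairs, scheme, seed = seed)
  pairs$drug_idx <- match_ids(pairs$drug_id, bundle$drug_index, "drug")
  pairs$cell_idx <- match_ids(pairs$cell_id, bundle$cell_index, "cell")
  train_triples <- pairs[pairs$split == "train", ]
  asm <- assemble_features(bundle, train_triples, snf)
  test <- pairs[pairs$split == "test", ]

  run_one <- function(excl, side) {
    views <- asm$views
    if (side == "drug") {
      views$drug <- views$drug[setdiff(names(views$drug), excl)]
      fused <- snf_fuse(views$drug, snf)
    } else {
      views$cell <- views$cell[setdiff(names(views$cell), excl)]
      fused <- asm$fused_all
    }
    inputs <- prepare_model_inputs(views, fused,
                                   train_cells = unique(train_triples$cell_idx))
    m <- drp_model(spec,
                   drug_view_dims = vapply(inputs$drug_views, ncol, 1L),
                   cell_view_dims = vapply(inputs$cell_views, ncol, 1L),
                   fused_dim = ncol(inputs$fused), seed = seed)
    m <- train_drp(m, inputs, pairs, seed = seed)
    met <- evaluate_predictions(predict_drp(m, inputs, test), test$ic50)
    data.frame(excluded = excl, side = side,
               n_maps = length(views$drug) * length(views$cell),
               rmse = met$rmse, mae = met$mae, pearson_r = met$pearson_r)
  }
  rows <- c(lapply(DRUG_VIEW_NAMES, run_one, side = "drug"),
            lapply(CELL_VIEW_NAMES, run_one, side = "cell"))
  do.call(rbind, rows)
}
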