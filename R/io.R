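# Serialization: every matrix goes to CSV (entity ids in the first column,
# descriptor/entity ids in the header) with an adjacent .json sidecar
# recording the view name, shape and value range / metric / SNF parameters.

#' Write a matrix with a JSON sidecar
#'
#' @param M matrix (feature, similarity or fused view).
#' @param path output CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @param meta extra sidecar fields (overrides the derived ones).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path, meta = list()) {
  base <- list(view_name = attr(M, "view_name"),
               shape = dim(M),
               value_range = attr(M, "value_range"),
               metric = attr(M, "metric"),
               snf_params = attr(M, "snf_params"),
               source_views = attr(M, "source_views"),
               zero_row_mask = attr(M, "zero_row_mask"))
  meta <- modifyList(base[!vapply(base, is.null, TRUE)], meta)
  df <- data.frame(id = rownames(M) %||% as.character(seq_len(nrow(M))),
                   as.data.frame(unclass(M)), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a matrix written by [write_matrix_csv()]
#'
#' @param path CSV path.
#' @return matrix with rownames and, when a sidecar is present, its metadata
#'   attached as attributes.
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in intersect(names(meta),
                         c("view_name", "value_range", "metric",
                           "snf_params", "source_views", "zero_row_mask")))
      attr(M, nm) <- meta[[nm]]
  }
  M
}

#' Read/write pair tables (drug_id, cell_id, ic50[, split])
#'
#' @param pairs data frame to write.
#' @param path CSV path.
#' @return the path (write) or the data frame (read).
#' @export
write_pairs_csv <- function(pairs, path) {
  write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs_csv
#' @export
read_pairs_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "cell_id", "ic50")
  if (!all(need %in% names(df)))
    stop("read_pairs_csv: need columns ", paste(need, collapse = ", "))
  df
}

edge_file <- function(tbl, path, weighted = FALSE) {
  e <- tbl$edges
  cols <- c("entity_id", "partner_id", if (weighted) "score")
  write.csv(e[, cols], path, row.names = FALSE)
  writeLines(tbl$partner_vocabulary, paste0(path, ".vocab"))
  invisible(path)
}

read_edge_file <- function(path, weighted = FALSE) {
  e <- read.csv(path, stringsAsFactors = FALSE)
  association_table(e, partner_vocabulary = readLines(paste0(path, ".vocab")))
}

#' Write an input bundle to a directory
#'
#' Serializes everything the pipeline consumes as plain CSV/TSV: the six
#' fingerprint matrices, the four association edge lists, the combined-score
#' edge list, the three omics matrices and the IC50 pair table. Synthetic
#' bundles also write their latent factors (`synthetic_latents_*.csv`) so
#' oracle checks survive a round-trip.
#'
#' @param bundle a bundle (see [generate_bundle()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- file.path
  writeLines(bundle$drug_index$ids, fp(dir, "drugs.txt"))
  writeLines(bundle$cell_index$ids, fp(dir, "cells.txt"))
  if (!is.null(bundle$smiles))
    write.table(data.frame(drug_id = names(bundle$smiles),
                           smiles = unname(bundle$smiles)),
                fp(dir, "smiles.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
  if (!is.null(bundle$fingerprints))
    for (v in names(bundle$fingerprints))
      write_matrix_csv(bundle$fingerprints[[v]], fp(dir, sprintf("fp_%s.csv", v)),
                       meta = list(view_name = v))
  for (v in names(bundle$assoc))
    edge_file(bundle$assoc[[v]], fp(dir, sprintf("assoc_%s.csv", v)))
  edge_file(bundle$combined, fp(dir, "combined.csv"), weighted = TRUE)
  for (v in names(bundle$omics))
    write_matrix_csv(bundle$omics[[v]], fp(dir, sprintf("omics_%s.csv", v)),
                     meta = list(view_name = v))
  write_pairs_csv(bundle$pairs, fp(dir, "pairs.csv"))
  if (!is.null(bundle$truth)) {
    write_matrix_csv(bundle$truth$U, fp(dir, "synthetic_latents_drug.csv"))
    write_matrix_csv(bundle$truth$W, fp(dir, "synthetic_latents_cell.csv"))
  }
  invisible(dir)
}

#' Read an input bundle from a directory
#'
#' @param dir directory written by [write_bundle()] (or hand-assembled in
#'   the same layout).
#' @return a bundle list.
#' @export
read_bundle <- function(dir) {
  fp <- file.path
  if (!file.exists(fp(dir, "pairs.csv")))
    stop("read_bundle: no pairs.csv in ", dir)
  d_idx <- entity_index(readLines(fp(dir, "drugs.txt")), "drug")
  c_idx <- entity_index(readLines(fp(dir, "cells.txt")), "cell")
  bundle <- list(drug_index = d_idx, cell_index = c_idx)
  if (file.exists(fp(dir, "smiles.tsv"))) {
    sm <- read.delim(fp(dir, "smiles.tsv"), stringsAsFactors = FALSE)
    bundle$smiles <- setNames(sm$smiles, sm$drug_id)
  }
  if (file.exists(fp(dir, "fp_ECFP.csv")))
    bundle$fingerprints <- setNames(
      lapply(names(FINGERPRINT_DIMS),
             function(v) read_matrix_csv(fp(dir, sprintf("fp_%s.csv", v)))),
      names(FINGERPRINT_DIMS))
  bundle$assoc <- setNames(
    lapply(DRUG_ASSOC_VIEWS,
           function(v) read_edge_file(fp(dir, sprintf("assoc_%s.csv", v)))),
    DRUG_ASSOC_VIEWS)
  bundle$combined <- read_edge_file(fp(dir, "combined.csv"), weighted = TRUE)
  bundle$omics <- setNames(
    lapply(c("exp", "mu", "cnv"),
           function(v) read_matrix_csv(fp(dir, sprintf("omics_%s.csv", v)))),
    c("exp", "mu", "cnv"))
  bundle$pairs <- read_pairs_csv(fp(dir, "pairs.csv"))
  if (file.exists(fp(dir, "synthetic_latents_drug.csv")))
    bundle$truth <- list(U = read_matrix_csv(fp(dir, "synthetic_latents_drug.csv")),
                         W = read_matrix_csv(fp(dir, "synthetic_latents_cell.csv")))
  bundle
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; recognized top-level keys: `fixtures` (arguments of
#'   [synthetic_config()]), `input_dir`, `scheme`, `seed`, `model`
#'   (overrides of [small_model_spec()]), `snf` (K/T/mu), `out`.
#' @return config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  cfg
}

# Serialize a run's artifacts: views, fused matrices, training log, metrics.
write_run_artifacts <- function(res, out, seed, snf) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (v in names(res$assembled$views$drug))
    write_matrix_csv(res$assembled$views$drug[[v]],
                     file.path(out, sprintf("drug_view_%s.csv", v)))
  for (v in names(res$assembled$views$cell))
    write_matrix_csv(res$assembled$views$cell[[v]],
                     file.path(out, sprintf("cell_view_%s.csv", v)))
  write_matrix_csv(res$assembled$fused_smiles, file.path(out, "fused_smiles.csv"))
  write_matrix_csv(res$assembled$fused_all, file.path(out, "fused_all.csv"))
  write_pairs_csv(res$pairs, file.path(out, "pairs_split.csv"))
  write.table(res$model$history, file.path(out, "training_log.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write_pairs_csv(res$predictions, file.path(out, "predictions.csv"))
  jsonlite::write_json(
    list(seed = seed, snf_params = unclass(snf),
         scheme = res$metrics$scheme, best_epoch = res$model$best_epoch,
         metrics = list(rmse = res$metrics$rmse, mae = res$metrics$mae,
                        pearson_r = res$metrics$pearson_r,
                        n_pairs = res$metrics$n_pairs)),
    file.path(out, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
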