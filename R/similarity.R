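#' Chebyshev distance between two feature vectors
#'
#' The L-infinity distance: the maximum absolute coordinate difference. This
#' is the row-wise distance from which every similarity view is derived.
#'
#' @param v_a,v_b numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
chebyshev_distance <- function(v_a, v_b) {
  if (length(v_a) != length(v_b))
    stop("chebyshev_distance: length mismatch (", length(v_a), " vs ",
         length(v_b), ")")
  if (anyNA(v_a) || anyNA(v_b) || any(!is.finite(c(v_a, v_b))))
    stop("chebyshev_distance: non-finite values")
  max(abs(v_a - v_b))
}

pairwise_distances <- function(F, metric) {
  switch(metric,
    chebyshev = as.matrix(stats::dist(F, method = "maximum")),
    euclidean = as.matrix(stats::dist(F, method = "euclidean")),
    manhattan = as.matrix(stats::dist(F, method = "manhattan")),
    cosine = {
      nrm <- sqrt(rowSums(F^2))
      nrm[nrm == 0] <- 1            # zero rows: treat as orthogonal
      C <- tcrossprod(F / nrm)
      D <- 1 - pmin(pmax(C, -1), 1)
      diag(D) <- 0
      D
    },
    stop("unknown metric: ", metric))
}

#' Similarity view from a feature matrix
#'
#' Computes pairwise row distances (Chebyshev by default) and maps them to
#' similarities. When all distances already lie in \[0, 1\] (as for binary or
#' unit-range features under Chebyshev), `S = 1 - D`; otherwise distances are
#' first scaled by the matrix maximum, so similarities always land in
#' \[0, 1\]. The diagonal is forced to 1 and the zero-row flags of the source
#' features are carried along for downstream completion.
#'
#' Note that on strictly binary features the Chebyshev distance saturates:
#' any two distinct rows are at distance exactly 1, so the view degenerates
#' towards an identity matrix. This is a property of the distance itself;
#' alternative metrics are available via `metric`.
#'
#' @param F a [feature_matrix()] (or plain matrix with >= 2 rows).
#' @param metric one of `"chebyshev"`, `"euclidean"`, `"manhattan"`,
#'   `"cosine"`.
#' @param index [entity_index()]; taken from `F` when it is a
#'   `feature_matrix`.
#' @param view_name view label; taken from `F` when available.
#' @return A `similarity_view`: symmetric matrix in \[0, 1\] with unit
#'   diagonal and attributes `index`, `view_name`, `metric`, `zero_row_mask`.
#' @export
similarity_from_features <- function(F, metric = "chebyshev",
                                     index = attr(F, "index"),
                                     view_name = attr(F, "view_name")) {
  if (nrow(F) < 2L) stop("similarity_from_features: need >= 2 rows")
  zr <- attr(F, "zero_rows")
  if (is.null(zr)) zr <- rowSums(abs(F)) == 0
  D <- pairwise_distances(unclass(F), metric)
  dmax <- max(D)
  d_norm <- if (dmax > 1) max(dmax, 1e-12) else 1
  S <- 1 - D / d_norm
  diag(S) <- 1
  similarity_view(S, index, view_name, metric = metric, zero_row_mask = zr)
}

#' Construct a similarity view
#'
#' Low-level constructor validating symmetry, the \[0, 1\] range and the unit
#' diagonal.
#'
#' @param S square similarity matrix.
#' @param index [entity_index()].
#' @param view_name view label.
#' @param metric how `S` was derived (recorded in the sidecar on export).
#' @param zero_row_mask logical per entity; TRUE where the source feature row
#'   was all-zero.
#' @return a `similarity_view`.
#' @export
similarity_view <- function(S, index, view_name, metric = "precomputed",
                            zero_row_mask = rep(FALSE, nrow(S))) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("similarity_view: matrix not square")
  if (max(abs(S - t(S))) > 1e-8) stop("similarity_view: matrix not symmetric")
  S <- (S + t(S)) / 2
  if (min(S) < -1e-12 || max(S) > 1 + 1e-12)
    stop("similarity_view: values outside [0,1]")
  S <- pmin(pmax(S, 0), 1)
  if (!is.null(index)) {
    if (nrow(S) != length(index)) stop("similarity_view: index size mismatch")
    dimnames(S) <- list(index$ids, index$ids)
  }
  stopifnot(length(zero_row_mask) == nrow(S))
  structure(S, index = index, view_name = view_name, metric = metric,
            zero_row_mask = zero_row_mask,
            class = c("similarity_view", "matrix", "array"))
}

#' @export
print.similarity_view <- function(x, ...) {
  cat(sprintf("<similarity_view> '%s' (%s): %d x %d, %d zero-row entit%s\n",
              attr(x, "view_name"), attr(x, "metric"), nrow(x), ncol(x),
              sum(attr(x, "zero_row_mask")),
              if (sum(attr(x, "zero_row_mask")) == 1) "y" else "ies"))
  invisible(x)
}

#' Build all similarity/feature views for drugs and cell lines
#'
#' Drug side: the six fingerprint views, the four association views and the
#' IC50 response-profile view are converted to similarity views by row-wise
#' distance; the combined-score view is already a similarity and passes
#' through unchanged. Cell side: the cell x drug IC50 profile matrix becomes
#' the single cell similarity view, while the three omics matrices stay raw
#' feature views consumed directly by the model.
#'
#' @param drug_features named list of the 12 drug [feature_matrix()] objects
#'   (names: ECFP, PSFP, DFP, RDKFP, ESPFP, ERGFP, target, disease, miRNA,
#'   ADR, combined, ic50_profile).
#' @param cell_features named list of the 4 cell feature matrices (exp, mu,
#'   cnv, ic50_profile = the cell x drug matrix `M_CD`).
#' @param metric distance metric for the converted views.
#' @return list with `drug` (12 `similarity_view`s) and `cell` (3 raw
#'   `feature_matrix` views plus `ic50_profile` as a `similarity_view`).
#' @export
build_all_views <- function(drug_features, cell_features,
                            metric = "chebyshev") {
  missing_d <- setdiff(DRUG_VIEW_NAMES, names(drug_features))
  missing_c <- setdiff(CELL_VIEW_NAMES, names(cell_features))
  if (length(missing_d) || length(missing_c))
    stop("build_all_views: missing view(s): ",
         paste(c(missing_d, missing_c), collapse = ", "))
  d_index <- attr(drug_features[[1]], "index")
  for (v in DRUG_VIEW_NAMES)
    if (!same_index(attr(drug_features[[v]], "index"), d_index))
      stop("build_all_views: drug view '", v, "' has a different entity index")
  drug_views <- lapply(DRUG_VIEW_NAMES, function(v) {
    f <- drug_features[[v]]
    if (v == "combined") {
      # combined scores are similarities already; pass through
      similarity_view(unclass(f), d_index, v, metric = "combined-score",
                      zero_row_mask = attr(f, "zero_rows"))
    } else {
      similarity_from_features(f, metric = metric)
    }
  })
  names(drug_views) <- DRUG_VIEW_NAMES
  cell_views <- cell_features[c("exp", "mu", "cnv")]
  cell_views$ic50_profile <-
    similarity_from_features(cell_features$ic50_profile, metric = metric)
  list(drug = drug_views, cell = cell_views)
}
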