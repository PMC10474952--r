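# Fixed view vocabulary. Fingerprint views carry canonical column counts
# (ECFP 1024, PubChem substructure 881, Daylight 2048, RDKit-2D-normalized
# 200, explainable substructure partition 2586, extended reduced graph 315);
# association views are sized by their partner vocabulary.
FINGERPRINT_DIMS <- c(ECFP = 1024L, PSFP = 881L, DFP = 2048L,
                      RDKFP = 200L, ESPFP = 2586L, ERGFP = 315L)
DRUG_ASSOC_VIEWS <- c("target", "disease", "miRNA", "ADR")
DRUG_VIEW_NAMES <- c(names(FINGERPRINT_DIMS), DRUG_ASSOC_VIEWS,
                     "combined", "ic50_profile")
CELL_VIEW_NAMES <- c("exp", "mu", "cnv", "ic50_profile")
BINARY_VIEWS <- c("ECFP", "PSFP", "DFP", "ESPFP", "ERGFP",
                  DRUG_ASSOC_VIEWS, "mu")

#' Feature matrix for one view
#'
#' A dense matrix whose rows are entities (aligned to an [entity_index()]) and
#' whose columns are view-specific descriptors. Binary views are validated to
#' contain only 0/1; the combined-score view must lie in \[0, 1\]. Rows that
#' are entirely zero are flagged so downstream completion can find them.
#'
#' @param values numeric matrix, rows = entities in index order.
#' @param index [entity_index()] the rows are aligned to.
#' @param view_name one of the fixed view labels (see `DRUG_VIEW_NAMES`,
#'   `CELL_VIEW_NAMES`).
#' @param value_range `"binary"`, `"unit"` (values in \[0,1\]) or `"real"`.
#'   Defaults by view.
#' @return A `feature_matrix`: the matrix with `index`, `view_name`,
#'   `value_range` and `zero_rows` attributes.
#' @export
feature_matrix <- function(values, index, view_name,
                           value_range = default_value_range(view_name)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(index))
    stop(sprintf("feature_matrix[%s]: %d rows but index has %d entities",
                 view_name, nrow(values), length(index)))
  if (anyNA(values) || any(!is.finite(values)))
    stop(sprintf("feature_matrix[%s]: missing/non-finite values", view_name))
  if (value_range == "binary" && !all(values %in% c(0, 1)))
    stop(sprintf("feature_matrix[%s]: binary view contains values outside {0,1}",
                 view_name))
  if (value_range == "unit" && (min(values) < 0 || max(values) > 1))
    stop(sprintf("feature_matrix[%s]: values outside [0,1]", view_name))
  rownames(values) <- index$ids
  structure(values,
            index = index, view_name = view_name, value_range = value_range,
            zero_rows = rowSums(abs(values)) == 0,
            class = c("feature_matrix", "matrix", "array"))
}

default_value_range <- function(view_name) {
  if (view_name %in% BINARY_VIEWS) "binary"
  else if (view_name %in% c("combined", "RDKFP")) "unit"
  else "real"
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> view '%s' (%s): %d x %d, %d zero row(s)\n",
              attr(x, "view_name"), attr(x, "value_range"),
              nrow(x), ncol(x), sum(attr(x, "zero_rows"))))
  invisible(x)
}

#' Association table
#'
#' Edge list of (entity, partner) pairs, optionally weighted, plus the ordered
#' partner vocabulary that defines the columns of the derived indicator
#' matrix. Duplicate edges collapse to one.
#'
#' @param edges data frame with columns `entity_id`, `partner_id` and
#'   optionally `score`.
#' @param partner_vocabulary ordered character vector of partner ids; defaults
#'   to the sorted distinct partners in `edges`.
#' @return An `association_table`.
#' @export
association_table <- function(edges, partner_vocabulary = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("entity_id", "partner_id") %in% names(edges)))
    stop("association_table: edges need columns entity_id, partner_id")
  edges$entity_id <- as.character(edges$entity_id)
  edges$partner_id <- as.character(edges$partner_id)
  if (is.null(partner_vocabulary))
    partner_vocabulary <- sort(unique(edges$partner_id))
  partner_vocabulary <- as.character(partner_vocabulary)
  if (anyDuplicated(partner_vocabulary))
    stop("association_table: duplicate partner ids in vocabulary")
  structure(list(edges = edges, partner_vocabulary = partner_vocabulary),
            class = "association_table")
}

#' Build a binary association matrix
#'
#' Indicator matrix over a partner vocabulary: entry (i, j) is 1 iff the edge
#' (entity i, partner j) is present. Entities with no edges yield all-zero
#' rows, which are preserved and flagged for downstream completion.
#'
#' @param table an [association_table()].
#' @param index [entity_index()] for the rows.
#' @param view_name view label, one of `"target"`, `"disease"`, `"miRNA"`,
#'   `"ADR"`.
#' @return A binary [feature_matrix()] of size n x |vocabulary|.
#' @export
build_association_matrix <- function(table, index, view_name = "target") {
  stopifnot(inherits(table, "association_table"))
  vocab <- table$partner_vocabulary
  if (length(vocab) == 0L) stop("build_association_matrix: empty partner vocabulary")
  M <- matrix(0, length(index), length(vocab),
              dimnames = list(index$ids, vocab))
  if (nrow(table$edges) > 0L) {
    i <- match_ids(table$edges$entity_id, index, "entity")
    j <- match(table$edges$partner_id, vocab)
    if (anyNA(j)) {
      bad <- unique(table$edges$partner_id[is.na(j)])
      stop("build_association_matrix: partner id(s) not in vocabulary: ",
           paste(head(bad, 5L), collapse = ", "))
    }
    M[cbind(i, j)] <- 1   # duplicates collapse: assignment is idempotent
  }
  feature_matrix(M, index, view_name, "binary")
}

#' Build the chemical-chemical combined-score matrix
#'
#' Pairwise drug-drug combined scores (STITCH convention, integers in
#' \[1, 1000\]) divided by 1000 so values land in \[0, 1\]. Unknown pairs are
#' 0, the matrix is symmetrized by the elementwise max of the two directions,
#' and the diagonal is set to 1 (self-similarity convention).
#'
#' @param table an [association_table()] whose edges carry a `score` column
#'   and whose partners are themselves drugs in `index`.
#' @param index drug [entity_index()].
#' @return A [feature_matrix()] (`combined` view), n x n in \[0, 1\].
#' @export
build_combined_score_matrix <- function(table, index) {
  stopifnot(inherits(table, "association_table"))
  e <- table$edges
  n <- length(index)
  M <- matrix(0, n, n, dimnames = list(index$ids, index$ids))
  if (nrow(e) > 0L) {
    if (is.null(e$score)) stop("build_combined_score_matrix: edges need a score column")
    if (any(e$score < 1 | e$score > 1000))
      stop("build_combined_score_matrix: scores must lie in [1, 1000]")
    i <- match_ids(e$entity_id, index, "drug")
    j <- match_ids(e$partner_id, index, "drug")
    M[cbind(i, j)] <- e$score / 1000
  }
  M <- pmax(M, t(M))
  no_scores <- rowSums(M) == 0   # before the diagonal is set
  diag(M) <- 1
  fm <- feature_matrix(M, index, "combined", "unit")
  attr(fm, "zero_rows") <- no_scores
  fm
}

#' Build IC50 response-profile matrices
#'
#' Arranges known (drug, cell, IC50) triples into the cell x drug matrix
#' `M_CD` and its transpose `M_DC` (drug x cell). Unknown pairs take a fill
#' value (default 0). To avoid leaking evaluation labels into the features,
#' pass only the training portion of the triples.
#'
#' @param triples data frame with columns `drug_id`, `cell_id`, `ic50`.
#' @param drug_index,cell_index entity indices.
#' @param fill value for unknown pairs.
#' @return list with elements `M_CD` (cell x drug) and `M_DC` (drug x cell),
#'   both [feature_matrix()] objects with view `"ic50_profile"`.
#' @export
build_ic50_profile_matrices <- function(triples, drug_index, cell_index,
                                        fill = 0) {
  stopifnot(is.data.frame(triples),
            all(c("drug_id", "cell_id", "ic50") %in% names(triples)))
  di <- match_ids(triples$drug_id, drug_index, "drug")
  ci <- match_ids(triples$cell_id, cell_index, "cell")
  key <- paste(di, ci)
  if (anyDuplicated(key)) {
    agg <- tapply(triples$ic50, key, function(v) diff(range(v)))
    if (any(agg > 0))
      stop("build_ic50_profile_matrices: conflicting IC50 for duplicated (drug, cell) pair(s)")
    keep <- !duplicated(key)
    di <- di[keep]; ci <- ci[keep]; triples <- triples[keep, ]
  }
  M_CD <- matrix(fill, length(cell_index), length(drug_index),
                 dimnames = list(cell_index$ids, drug_index$ids))
  M_CD[cbind(ci, di)] <- triples$ic50
  list(M_CD = feature_matrix(M_CD, cell_index, "ic50_profile", "real"),
       M_DC = feature_matrix(t(M_CD), drug_index, "ic50_profile", "real"))
}

#' Build the six molecular-fingerprint matrices
#'
#' Produces the ECFP, PSFP (PubChem substructure), DFP (Daylight), RDKFP
#' (RDKit 2D normalized, continuous), ESPFP and ERGFP views with their
#' canonical widths (1024, 881, 2048, 200, 2586, 315). Two input paths:
#'
#' * `precomputed`: a named list of matrices (one per view); each is validated
#'   against the canonical column count.
#' * `smiles`: named character vector of SMILES strings; views are derived by
#'   a deterministic hashed n-gram backend (`backend = "hashed"`). This is a
#'   lightweight structural hashing of the SMILES text, suitable for fixtures
#'   and smoke runs; for real cheminformatics work supply precomputed
#'   fingerprints from a chemistry toolkit.
#'
#' Identical SMILES map to identical rows in every view.
#'
#' @param smiles named character vector (names = drug ids in index order), or
#'   NULL when `precomputed` is given.
#' @param index drug [entity_index()].
#' @param precomputed optional named list of matrices keyed by view name.
#' @param backend fingerprinting backend for the SMILES path.
#' @return named list of six [feature_matrix()] objects.
#' @export
build_fingerprint_matrices <- function(smiles = NULL, index,
                                       precomputed = NULL,
                                       backend = c("hashed")) {
  backend <- match.arg(backend)
  views <- names(FINGERPRINT_DIMS)
  if (!is.null(precomputed)) {
    missing <- setdiff(views, names(precomputed))
    if (length(missing))
      stop("build_fingerprint_matrices: missing precomputed view(s): ",
           paste(missing, collapse = ", "))
    out <- lapply(views, function(v) {
      M <- as.matrix(precomputed[[v]])
      if (ncol(M) != FINGERPRINT_DIMS[[v]])
        stop(sprintf("fingerprint view %s: expected %d columns, got %d",
                     v, FINGERPRINT_DIMS[[v]], ncol(M)))
      feature_matrix(M, index, v)
    })
    return(setNames(out, views))
  }
  if (is.null(smiles)) stop("build_fingerprint_matrices: need smiles or precomputed")
  smiles <- smiles[index$ids]
  if (anyNA(smiles) || any(!nzchar(smiles))) {
    bad <- index$ids[is.na(smiles) | !nzchar(smiles)]
    stop("build_fingerprint_matrices: missing/empty SMILES for drug(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  out <- lapply(views, function(v) {
    M <- t(vapply(smiles, hashed_fingerprint, numeric(FINGERPRINT_DIMS[[v]]),
                  view = v))
    feature_matrix(M, index, v)
  })
  setNames(out, views)
}

# Deterministic hashed character n-gram fingerprint of a SMILES string.
# Each view uses its own n-gram lengths and hash salt so the six views are
# distinct; RDKFP is continuous in [0,1] (normalized n-gram counts), the
# others are bit vectors. Not a chemistry-aware fingerprint.
hashed_fingerprint <- function(smi, view) {
  dim <- FINGERPRINT_DIMS[[view]]
  salt <- match(view, names(FINGERPRINT_DIMS))
  ngram_lens <- switch(view,
    ECFP = 1:3, PSFP = 2:3, DFP = 1:4, RDKFP = 1:2, ESPFP = 2:4, ERGFP = 3:4)
  codes <- utf8ToInt(smi)
  idx <- integer(0)
  for (L in ngram_lens) {
    if (length(codes) < L) next
    # polynomial rolling hash of each length-L window, offset by the salt
    h <- rep(salt * 7919, length(codes) - L + 1L)
    for (k in seq_len(L)) {
      h <- (h * 131 + codes[k:(length(codes) - L + k)]) %% 1048573
    }
    idx <- c(idx, (h %% dim) + 1L)
  }
  v <- numeric(dim)
  if (view == "RDKFP") {
    tb <- table(idx)
    v[as.integer(names(tb))] <- as.numeric(tb)
    if (max(v) > 0) v <- v / max(v)
  } else {
    v[unique(idx)] <- 1
  }
  v
}
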