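#' Entity index
#'
#' An ordered, unique set of entity identifiers (drugs or cell lines). Every
#' matrix produced in a run is row-aligned to one of these indices; the order
#' is fixed at construction and shared by all downstream views.
#'
#' @param ids character vector of unique entity identifiers.
#' @param role `"drug"` or `"cell"`.
#' @return An `entity_index` object.
#' @export
entity_index <- function(ids, role = c("drug", "cell")) {
  role <- match.arg(role)
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("entity_index: empty id list")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("entity_index: duplicate ids: ", paste(head(dup, 5L), collapse = ", "))
  }
  structure(list(ids = ids, role = role), class = "entity_index")
}

#' @export
length.entity_index <- function(x) length(x$ids)

#' @export
print.entity_index <- function(x, ...) {
  cat(sprintf("<entity_index> %d %ss: %s%s\n", length(x$ids), x$role,
              paste(head(x$ids, 4L), collapse = ", "),
              if (length(x$ids) > 4L) ", ..." else ""))
  invisible(x)
}

# resolve ids against an index; hard error naming offenders
match_ids <- function(ids, index, what = "entity") {
  pos <- match(as.character(ids), index$ids)
  if (anyNA(pos)) {
    bad <- unique(as.character(ids)[is.na(pos)])
    stop(sprintf("unknown %s id(s): %s", what,
                 paste(head(bad, 5L), collapse = ", ")))
  }
  pos
}

same_index <- function(a, b) {
  identical(a$ids, b$ids) && identical(a$role, b$role)
}
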