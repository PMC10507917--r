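## Internal helpers shared across modules.

# Coerce bulk/ reference count input to a base matrix with gene-id rownames.
# Accepts: matrix / Matrix with rownames, or a data frame whose first column
# holds gene ids and remaining columns numeric counts.
as_count_matrix <- function(x, arg = "counts") {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      abort(sprintf("`%s`: non-numeric values in count columns.", arg))
    }
    rownames(m) <- ids
    x <- m
  } else if (inherits(x, "Matrix")) {
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix or a data frame with gene ids in the first column.", arg))
  }
  if (is.null(rownames(x))) {
    abort(sprintf("`%s` must carry gene ids as rownames (or a first id column).", arg))
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("`%s`: duplicate gene ids are not allowed.", arg))
  }
  if (any(x < 0)) {
    abort(sprintf("`%s`: negative counts are not allowed.", arg))
  }
  x
}

# Proportion tables travel as tibbles with a `sample` id column followed by
# one numeric column per cell type. Convert to a plain sample x K matrix.
proportions_to_matrix <- function(p) {
  if (is.matrix(p)) {
    return(p)
  }
  stopifnot(is.data.frame(p))
  id_col <- if ("sample" %in% names(p)) "sample" else names(p)[1]
  m <- as.matrix(p[, setdiff(names(p), id_col), drop = FALSE])
  rownames(m) <- as.character(p[[id_col]])
  m
}

matrix_to_proportions <- function(m) {
  out <- as_tibble(m, rownames = "sample")
  out
}

# Named-vector or two-column data frame -> named numeric vector.
as_named_vector <- function(x, value_col = NULL, arg = "x") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) abort(sprintf("`%s` needs an id column and a value column.", arg))
    vcol <- value_col %||% names(x)[2]
    v <- setNames(as.numeric(x[[vcol]]), as.character(x[[1]]))
    return(v)
  }
  if (!is.numeric(x) || is.null(names(x))) {
    abort(sprintf("`%s` must be a named numeric vector or a two-column data frame.", arg))
  }
  x
}
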