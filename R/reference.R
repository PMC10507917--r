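#' Assemble a labelled single-nuclei reference
#'
#' Bundles a gene x cell count matrix with its cell metadata (cell type and
#' subject of origin for every cell) into a validated `reference_counts`
#' object, the input to [build_signature()] and [build_pooled_profile()].
#'
#' Genes with zero counts in every cell are dropped (with a message): they
#' carry no deconvolution signal and would break downstream capture-quotient
#' computations.
#'
#' @param cell_metadata Data frame with columns `barcode`, `cell_type` and
#'   `subject`; one row per cell, barcodes matching `colnames(counts)`.
#' @param counts Gene x cell matrix of non-negative counts (dense or sparse
#'   `Matrix`), gene ids as rownames and cell barcodes as colnames; or a data
#'   frame whose first column holds gene ids.
#' @return A `reference_counts` object: list with `counts` (sparse gene x cell
#'   matrix), `cells` (tibble of per-cell labels), `gene_ids`, `type_labels`
#'   and `subject_labels`.
#' @examples
#' counts <- matrix(rpois(40, 3), nrow = 10,
#'                  dimnames = list(paste0("g", 1:10), paste0("c", 1:4)))
#' md <- data.frame(barcode = paste0("c", 1:4),
#'                  cell_type = c("AST", "AST", "GLU", "GLU"),
#'                  subject = c("s1", "s2", "s1", "s2"))
#' ref <- reference_counts(md, counts)
#' @export
reference_counts <- function(cell_metadata, counts) {
  stopifnot(is.data.frame(cell_metadata))
  missing_cols <- setdiff(c("barcode", "cell_type", "subject"), names(cell_metadata))
  if (length(missing_cols)) {
    abort(paste0("`cell_metadata` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- as_count_matrix(counts, "counts")
  if (is.null(colnames(counts))) {
    abort("`counts` must carry cell barcodes as colnames.")
  }
  cells <- tibble(
    barcode   = as.character(cell_metadata$barcode),
    cell_type = as.character(cell_metadata$cell_type),
    subject   = as.character(cell_metadata$subject)
  )
  if (anyDuplicated(cells$barcode)) abort("duplicate barcodes in `cell_metadata`.")
  if (anyNA(cells)) abort("`cell_metadata` contains missing labels.")
  unmatched <- setdiff(colnames(counts), cells$barcode)
  if (length(unmatched)) {
    abort(sprintf("%d cell(s) in `counts` have no metadata row (e.g. %s).",
                  length(unmatched), unmatched[1]))
  }
  cells <- cells[match(colnames(counts), cells$barcode), ]
  if (anyNA(cells$barcode)) abort("`cell_metadata` must cover every column of `counts`.")

  keep <- Matrix::rowSums(counts) > 0
  if (!all(keep)) {
    inform(sprintf("Dropping %d gene(s) with zero counts in every cell.", sum(!keep)))
    counts <- counts[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0) abort("no gene with nonzero counts remains.")

  structure(
    list(
      counts = Matrix::Matrix(counts, sparse = TRUE),
      cells = cells,
      gene_ids = rownames(counts),
      type_labels = sort(unique(cells$cell_type)),
      subject_labels = sort(unique(cells$subject))
    ),
    class = "reference_counts"
  )
}

#' @export
print.reference_counts <- function(x, ...) {
  cat(sprintf("<reference_counts> %d genes x %d cells | %d cell types, %d subjects\n",
              length(x$gene_ids), ncol(x$counts),
              length(x$type_labels), length(x$subject_labels)))
  invisible(x)
}

#' Pooled per-type expression profiles
#'
#' Sums counts over all cells of each type and normalizes each type's profile
#' to sum to one, giving the relative mean expression of every gene within a
#' cell type. The normalized profile is the mixing basis of the pseudo-bulk
#' simulator ([simulate_bulk()]).
#'
#' @param ref A [reference_counts()] object.
#' @return List with `profile` (type x gene raw pooled counts) and
#'   `profile_norm` (type x gene, each row summing to 1).
#' @export
build_pooled_profile <- function(ref) {
  stopifnot(inherits(ref, "reference_counts"))
  types <- ref$type_labels
  X <- matrix(0, nrow = length(types), ncol = length(ref$gene_ids),
              dimnames = list(types, ref$gene_ids))
  for (k in types) {
    idx <- which(ref$cells$cell_type == k)
    X[k, ] <- Matrix::rowSums(ref$counts[, idx, drop = FALSE])
  }
  totals <- rowSums(X)
  if (any(totals == 0)) {
    abort(sprintf("cell type(s) with zero total counts: %s",
                  paste(types[totals == 0], collapse = ", ")))
  }
  list(profile = X, profile_norm = X / totals)
}

#' Build a deconvolution signature from a multi-subject reference
#'
#' Computes, for every cell type k and gene g, the cross-subject mean
#' `theta[k, g]` and cross-subject variance `sigma[k, g]` of the subject-level
#' relative expression (per-subject mean count in that subject's type-k cells,
#' normalized to sum 1 over genes), plus the cell-size factor `S_k` (mean over
#' subjects of the mean per-cell library size of type-k cells). This is the
#' multi-subject weighting signature of the MuSiC family of deconvolution
#' methods; variances use the population (1/n) denominator, so a single
#' subject yields `sigma = 0` everywhere.
#'
#' @inheritParams build_pooled_profile
#' @return A `signature_set`: list with `theta` and `sigma` (type x gene
#'   matrices), `cell_size` (named vector), `type_labels`, `gene_ids`,
#'   `n_subjects`, and the pooled `profile` / `profile_norm` from
#'   [build_pooled_profile()].
#' @seealso [write_signature()], [deconvolute()]
#' @export
build_signature <- function(ref) {
  stopifnot(inherits(ref, "reference_counts"))
  types <- ref$type_labels
  subjects <- ref$subject_labels
  genes <- ref$gene_ids
  G <- length(genes)
  lib_size <- Matrix::colSums(ref$counts)

  theta <- sigma <- matrix(NA_real_, length(types), G, dimnames = list(types, genes))
  cell_size <- setNames(numeric(length(types)), types)

  for (k in types) {
    rel <- list()   # per-subject relative profiles, subjects with type-k cells only
    sizes <- numeric(0)
    for (j in subjects) {
      idx <- which(ref$cells$cell_type == k & ref$cells$subject == j)
      if (!length(idx)) next
      mean_counts <- Matrix::rowSums(ref$counts[, idx, drop = FALSE]) / length(idx)
      tot <- sum(mean_counts)
      if (tot == 0) next   # subject contributed only empty cells for this type
      rel[[j]] <- mean_counts / tot
      sizes <- c(sizes, mean(lib_size[idx]))
    }
    if (!length(rel)) {
      abort(sprintf("cell type '%s' has no expressing cells in any subject.", k))
    }
    R <- do.call(rbind, rel)                      # n_j x G
    theta[k, ] <- colMeans(R)
    sigma[k, ] <- colMeans(R^2) - colMeans(R)^2   # population variance; 0 when n_j = 1
    cell_size[k] <- mean(sizes)
  }
  sigma[sigma < 0] <- 0   # guard tiny negative round-off

  pooled <- build_pooled_profile(ref)
  structure(
    list(theta = theta, sigma = sigma, cell_size = cell_size,
         type_labels = types, gene_ids = genes,
         n_subjects = length(subjects),
         profile = pooled$profile, profile_norm = pooled$profile_norm),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d cell types x %d genes (from %d subject(s))\n",
              length(x$type_labels), length(x$gene_ids), x$n_subjects))
  cat("  cell sizes:", paste(sprintf("%s=%.0f", x$type_labels, x$cell_size),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a signature into a long tibble
#'
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return Tibble with columns `cell_type`, `gene`, `theta`, `sigma`.
#' @export
tidy.signature_set <- function(x, ...) {
  out <- as_tibble(x$theta, rownames = "cell_type")
  out <- tidyr::pivot_longer(out, -"cell_type", names_to = "gene", values_to = "theta")
  sig <- tidyr::pivot_longer(as_tibble(x$sigma, rownames = "cell_type"),
                             -"cell_type", names_to = "gene", values_to = "sigma")
  dplyr::left_join(out, sig, by = c("cell_type", "gene"))
}
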