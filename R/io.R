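#' Read a count matrix from TSV or a Matrix Market triplet
#'
#' Two layouts: `"dense_tsv"` — a (optionally gzipped) TSV/CSV with gene ids
#' in the first column, one column per sample or cell; `"mtx_triplet"` — a
#' 10x-style directory (or matrix file path) with `matrix.mtx`,
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`, genes in rows. Duplicate
#' gene ids and dimension mismatches between the matrix and its id files are
#' rejected.
#'
#' @param path File (dense) or directory (triplet) to read.
#' @param layout `"dense_tsv"` or `"mtx_triplet"`; default guesses from
#'   `path` (directory => triplet).
#' @return Numeric matrix, genes in rows, ids as dimnames.
#' @export
read_counts <- function(path, layout = c("auto", "dense_tsv", "mtx_triplet")) {
  layout <- match.arg(layout)
  if (layout == "auto") {
    layout <- if (dir.exists(path)) "mtx_triplet" else "dense_tsv"
  }
  if (layout == "dense_tsv") {
    delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
    if (ncol(d) < 2) abort("dense table needs a gene-id column and at least one count column.")
    if (!all(vapply(d[-1], is.numeric, logical(1)))) {
      abort(sprintf("non-numeric count column(s) in %s", path))
    }
    return(as_count_matrix(as.data.frame(d), path))
  }
  dir <- if (dir.exists(path)) path else dirname(path)
  mtx <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(dir, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- readr::read_tsv(feat, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)[[1]]
  cells <- readr::read_tsv(bc, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    abort(sprintf("MTX dimensions %dx%d do not match %d features / %d barcodes.",
                  nrow(m), ncol(m), length(genes), length(cells)))
  }
  dimnames(m) <- list(genes, cells)
  if (anyDuplicated(genes)) abort("duplicate gene ids in features file.")
  if (any(m < 0)) abort("negative counts in MTX file.")
  m
}

first_existing <- function(dir, names) {
  for (n in names) {
    p <- file.path(dir, n)
    if (file.exists(p)) return(p)
  }
  abort(sprintf("none of %s found under %s", paste(names, collapse = "/"), dir))
}

#' Write a count matrix
#'
#' `write_counts_tsv()` writes the canonical dense layout (gene ids in the
#' first column, header row); `write_counts_mtx()` writes a 10x-style
#' Matrix Market triplet directory.
#'
#' @param counts Gene x sample (or gene x cell) matrix with dimnames.
#' @param path Output file (TSV) or directory (triplet).
#' @return The path, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(!is.null(rownames(counts)))
  readr::write_tsv(as_tibble(as.matrix(counts), rownames = "gene"), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
write_counts_mtx <- function(counts, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  readr::write_tsv(tibble(x = rownames(counts)), file.path(path, "features.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble(x = colnames(counts)), file.path(path, "barcodes.tsv"),
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a cell-metadata table
#'
#' TSV with columns `barcode`, `cell_type`, `subject`.
#'
#' @param path File to read.
#' @return Tibble with the three columns.
#' @export
read_cell_metadata <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("barcode", "cell_type", "subject"), names(d))
  if (length(missing)) {
    abort(paste0(path, " is missing column(s): ", paste(missing, collapse = ", ")))
  }
  d
}

#' Write a run manifest
#'
#' Serializes the subcommand, full configuration, seed, input checksums
#' (md5), package version and timestamp next to a command's outputs, enough
#' to re-run deterministic stages bit-identically.
#'
#' @param out_dir Output directory of the run.
#' @param subcommand Name of the pipeline stage.
#' @param config Named list echoing every parameter of the run.
#' @param seed Integer seed used (or `NULL`).
#' @param inputs Character vector of input paths to checksum.
#' @return Path of the written `manifest.json`, invisibly.
#' @export
write_run_manifest <- function(out_dir, subcommand, config, seed = NULL,
                               inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  dirs <- dir.exists(inputs)
  inputs <- c(inputs[!dirs],
              unlist(lapply(inputs[dirs], list.files, full.names = TRUE,
                            recursive = TRUE)))
  manifest <- list(
    subcommand = subcommand,
    config = config,
    seed = seed,
    input_checksums = as.list(tools::md5sum(inputs)),
    package_version = as.character(utils::packageVersion("detrem")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
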