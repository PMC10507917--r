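#' Write / read a signature as a directory of TSVs
#'
#' Persists a [build_signature()] result for reuse: `theta.tsv`, `sigma.tsv`
#' (genes in rows, cell types in columns), `cell_size.tsv`, and
#' `profile_norm.tsv` (the pooled per-type mixing profile used by the
#' simulator). `read_signature()` restores the object.
#'
#' @param signature A `signature_set`.
#' @param dir Output directory (created if absent).
#' @return `write_signature()` returns `dir` invisibly; `read_signature()`
#'   returns a `signature_set`.
#' @export
write_signature <- function(signature, dir) {
  stopifnot(inherits(signature, "signature_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- function(m) as_tibble(t(m), rownames = "gene")
  readr::write_tsv(wide(signature$theta), file.path(dir, "theta.tsv"))
  readr::write_tsv(wide(signature$sigma), file.path(dir, "sigma.tsv"))
  readr::write_tsv(wide(signature$profile_norm), file.path(dir, "profile_norm.tsv"))
  readr::write_tsv(wide(signature$profile), file.path(dir, "profile.tsv"))
  readr::write_tsv(
    tibble(cell_type = signature$type_labels,
           cell_size = unname(signature$cell_size[signature$type_labels]),
           n_subjects = signature$n_subjects),
    file.path(dir, "cell_size.tsv")
  )
  invisible(dir)
}

#' @rdname write_signature
#' @export
read_signature <- function(dir) {
  grab <- function(name) {
    d <- readr::read_tsv(file.path(dir, name), show_col_types = FALSE)
    m <- t(as.matrix(d[, -1, drop = FALSE]))
    colnames(m) <- d[[1]]
    m
  }
  theta <- grab("theta.tsv")
  sigma <- grab("sigma.tsv")
  profile_norm <- grab("profile_norm.tsv")
  profile <- grab("profile.tsv")
  cs <- readr::read_tsv(file.path(dir, "cell_size.tsv"), show_col_types = FALSE)
  structure(
    list(theta = theta, sigma = sigma,
         cell_size = setNames(cs$cell_size, cs$cell_type),
         type_labels = rownames(theta), gene_ids = colnames(theta),
         n_subjects = cs$n_subjects[1],
         profile = profile, profile_norm = profile_norm),
    class = "signature_set"
  )
}
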