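# Small in-code fixtures shared across test files.

# Hand-sized random labelled reference: counts drawn once per call under the
# caller's seed.
random_reference <- function(n_genes = 30, n_types = 3, n_subjects = 3,
                             cells_per = 4, lambda = 5) {
  types <- LETTERS[seq_len(n_types)]
  subjects <- paste0("s", seq_len(n_subjects))
  combos <- expand.grid(type = types, subject = subjects,
                        cell = seq_len(cells_per), stringsAsFactors = FALSE)
  n_cells <- nrow(combos)
  counts <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("cell%03d", seq_len(n_cells))))
  md <- data.frame(barcode = colnames(counts),
                   cell_type = combos$type, subject = combos$subject)
  reference_counts(md, counts)
}

# Well-conditioned signature for recovery tests (built from synthetic data).
recovery_signature <- function(seed = 7, n_genes = 400) {
  spec <- synthetic_reference_spec(n_genes = n_genes, cells_per_type = 50)
  ref <- make_reference(spec, seed = seed)
  build_signature(ref)
}

unit_quotient <- function(signature) {
  stats::setNames(rep(1, length(signature$gene_ids)), signature$gene_ids)
}
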