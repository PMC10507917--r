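#' Specify a fully synthetic multi-subject single-nuclei reference
#'
#' Describes the generative model used by [make_reference()]: log-normal
#' baseline gene means shared by all cell types; a disjoint block of marker
#' genes per type whose expression is multiplied by `marker_fold` in that
#' type only; multiplicative log-normal subject effects per gene (shared
#' across types within a subject), giving genuine cross-subject variance in
#' the relative profiles; log-normal per-cell library sizes; and Poisson
#' counts around the scaled per-cell means. A companion "real bulk" dataset
#' with planted per-gene capture bias is produced by
#' [make_biased_bulk_companion()].
#'
#' Defaults are sized for fast end-to-end runs (5 types, 1000 genes, 4
#' subjects, 100 cells per subject-type, bulk depth 1e5 reads); raise
#' `companion_depth` towards 1e7 for full-scale experiments.
#'
#' @param n_types,n_genes,n_subjects,cells_per_type Reference dimensions.
#' @param markers_per_type Marker-block size per type
#'   (`n_types * markers_per_type <= n_genes`).
#' @param marker_fold Expression fold-up of a marker gene in its own type.
#' @param subject_sd SD (log scale) of the per-subject, per-gene effect;
#'   0 removes cross-subject variation.
#' @param library_size,library_size_sd Mean per-cell library size and its
#'   log-scale SD.
#' @param nb_dispersion Gamma-Poisson (negative binomial) overdispersion of
#'   the counts (variance `mu + nb_dispersion * mu^2`); 0 (default) gives
#'   plain Poisson counts, which keeps brute-force oracles simple.
#' @param capture_bias_prob Fraction of genes differentially captured in the
#'   companion bulk; the rest keep factor 1, so most genes are relatively
#'   unchanged with roughly equal numbers shifted up and down, the structure
#'   observed when real bulk capture is compared with single-nuclei capture.
#' @param capture_bias_sd SD (log scale) of the affected genes' capture
#'   factors; 0 makes the companion unbiased.
#' @param companion_depth Read depth per companion bulk sample.
#' @return A `synthetic_reference_spec` object. Cell-type labels follow the
#'   human-cortex convention (GLU, GAB, AST, ODC, MIC, OPC, END) up to
#'   `n_types = 7`, generic labels beyond.
#' @export
synthetic_reference_spec <- function(n_types = 5, n_genes = 1000,
                                     n_subjects = 4, cells_per_type = 100,
                                     markers_per_type = 25, marker_fold = 8,
                                     subject_sd = 0.15,
                                     library_size = 2000, library_size_sd = 0.3,
                                     nb_dispersion = 0,
                                     capture_bias_prob = 0.25,
                                     capture_bias_sd = 1.5,
                                     companion_depth = 1e5) {
  stopifnot(n_types >= 1, n_genes >= 1, n_subjects >= 1, cells_per_type >= 1,
            markers_per_type >= 0, marker_fold > 0, subject_sd >= 0,
            library_size > 0, library_size_sd >= 0, nb_dispersion >= 0,
            capture_bias_prob >= 0, capture_bias_prob <= 1,
            capture_bias_sd >= 0, companion_depth >= 1)
  if (n_types * markers_per_type > n_genes) {
    abort("marker blocks exceed the number of genes; they must be disjoint.")
  }
  brain <- c("GLU", "GAB", "AST", "ODC", "MIC", "OPC", "END")
  labels <- if (n_types <= length(brain)) brain[seq_len(n_types)] else
    sprintf("T%02d", seq_len(n_types))
  structure(
    list(n_types = n_types, n_genes = n_genes, n_subjects = n_subjects,
         cells_per_type = cells_per_type, markers_per_type = markers_per_type,
         marker_fold = marker_fold, subject_sd = subject_sd,
         library_size = library_size, library_size_sd = library_size_sd,
         nb_dispersion = nb_dispersion,
         capture_bias_prob = capture_bias_prob, capture_bias_sd = capture_bias_sd,
         companion_depth = companion_depth,
         type_labels = labels,
         gene_ids = sprintf("gene%04d", seq_len(n_genes)),
         subject_labels = sprintf("subj%d", seq_len(n_subjects))),
    class = "synthetic_reference_spec"
  )
}

# Planted per-type mean profiles (type x gene, rows normalized to sum 1).
planted_profiles <- function(spec, base_means) {
  M <- matrix(rep(base_means, each = spec$n_types), nrow = spec$n_types,
              dimnames = list(spec$type_labels, spec$gene_ids))
  if (spec$markers_per_type > 0) {
    for (k in seq_len(spec$n_types)) {
      block <- ((k - 1) * spec$markers_per_type + 1):(k * spec$markers_per_type)
      M[k, block] <- M[k, block] * spec$marker_fold
    }
  }
  M / rowSums(M)
}

#' Generate a synthetic labelled single-nuclei reference
#'
#' Draws counts under the model of [synthetic_reference_spec()] and returns
#' a [reference_counts()] object. The planted per-type normalized profiles,
#' per-subject effects and the spec are attached as attributes
#' (`planted_profiles`, `spec`) for oracle checks.
#'
#' @param spec A `synthetic_reference_spec`.
#' @param seed Optional integer seed.
#' @return A `reference_counts` object.
#' @export
make_reference <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_reference_spec"))
  if (!is.null(seed)) set.seed(seed)
  G <- spec$n_genes
  base_means <- rlnorm(G, meanlog = 0, sdlog = 1)
  truth <- planted_profiles(spec, base_means)
  subj_effect <- matrix(rlnorm(G * spec$n_subjects, 0, spec$subject_sd),
                        nrow = spec$n_subjects,
                        dimnames = list(spec$subject_labels, spec$gene_ids))

  n_cells <- spec$n_types * spec$n_subjects * spec$cells_per_type
  counts <- matrix(0L, nrow = G, ncol = n_cells)
  barcodes <- character(n_cells)
  type_of <- character(n_cells)
  subj_of <- character(n_cells)
  mlog <- log(spec$library_size) - spec$library_size_sd^2 / 2
  col <- 0L
  for (j in spec$subject_labels) {
    for (k in spec$type_labels) {
      q <- truth[k, ] * subj_effect[j, ]
      q <- q / sum(q)
      libs <- rlnorm(spec$cells_per_type, meanlog = mlog,
                     sdlog = spec$library_size_sd)
      lam <- outer(q, libs)                      # G x cells
      if (spec$nb_dispersion > 0) {
        lam <- lam * rgamma(length(lam), shape = 1 / spec$nb_dispersion,
                            scale = spec$nb_dispersion)
      }
      idx <- col + seq_len(spec$cells_per_type)
      counts[, idx] <- matrix(rpois(length(lam), lam), nrow = G)
      barcodes[idx] <- sprintf("%s_%s_c%03d", j, k, seq_len(spec$cells_per_type))
      type_of[idx] <- k
      subj_of[idx] <- j
      col <- col + spec$cells_per_type
    }
  }
  dimnames(counts) <- list(spec$gene_ids, barcodes)
  ref <- reference_counts(
    tibble(barcode = barcodes, cell_type = type_of, subject = subj_of),
    counts
  )
  attr(ref, "planted_profiles") <- truth[, ref$gene_ids, drop = FALSE]
  attr(ref, "spec") <- spec
  ref
}

#' Proportion ranges matching a synthetic spec's cell types
#'
#' Moderately wide, feasible uniform ranges over the spec's free types with
#' the first label (GLU at defaults) as residual; convenient glue between
#' [make_reference()] and [simulate_bulk()].
#'
#' @param spec A `synthetic_reference_spec`.
#' @return A [proportion_ranges()] object.
#' @export
synthetic_ranges <- function(spec) {
  stopifnot(inherits(spec, "synthetic_reference_spec"))
  free <- spec$type_labels[-1]
  K <- length(free)
  if (K == 0) abort("need at least two cell types for proportion ranges.")
  # Equal-width ranges leaving the residual type a healthy share.
  a <- rep(0.05, K)
  b <- rep(min(0.35, 0.8 / K), K)
  proportion_ranges(tibble(cell_type = free, a = a, b = pmax(b, a + 0.01)),
                    residual_type = spec$type_labels[1])
}

#' Generate a capture-biased companion bulk dataset
#'
#' Builds pseudo-bulk samples from the reference's pooled per-type profiles
#' at known proportions, then multiplies each gene by a planted log-normal
#' capture factor before read sampling — emulating a real bulk dataset whose
#' per-gene capture differs from the single-nuclei reference. The planted
#' factors are returned as ground truth, so [quotient_bias()] estimates can
#' be checked against them.
#'
#' @param spec A `synthetic_reference_spec` (its `capture_bias_sd` and
#'   `companion_depth` are used).
#' @param reference The [make_reference()] output.
#' @param n_samples Number of bulk samples; default 24.
#' @param seed Optional integer seed.
#' @return A `simulated_bulk` object with an extra `capture_factors` field
#'   (named per-gene ground truth).
#' @export
make_biased_bulk_companion <- function(spec, reference, n_samples = 24,
                                       seed = NULL) {
  stopifnot(inherits(spec, "synthetic_reference_spec"),
            inherits(reference, "reference_counts"))
  if (!is.null(seed)) set.seed(seed)
  G <- length(reference$gene_ids)
  factors <- setNames(rep(1, G), reference$gene_ids)
  hit <- runif(G) < spec$capture_bias_prob
  factors[hit] <- rlnorm(sum(hit), 0, spec$capture_bias_sd)
  pooled <- build_pooled_profile(reference)
  sim <- simulate_bulk(pooled$profile, synthetic_ranges(spec), n_samples,
                       depth_range = c(spec$companion_depth, spec$companion_depth),
                       bias = bias_quotient(factors), seed = NULL)
  sim$capture_factors <- factors
  sim$seed <- seed
  sim
}
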