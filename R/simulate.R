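#' Cell-type proportion ranges for pseudo-bulk simulation
#'
#' Defines, for all but one cell type, a uniform sampling range
#' `[a_k, b_k]` for its mixture proportion; the remaining `residual_type`
#' receives `1 - sum(P_k)`. Draws with a negative residual are rejected and
#' redrawn, so the free proportions keep their uniform marginals conditional
#' on feasibility.
#'
#' @param ranges Data frame with columns `cell_type`, `a`, `b` (one row per
#'   free type; `0 <= a <= b <= 1`).
#' @param residual_type Label of the type set to one minus the sum of the
#'   free proportions.
#' @return A `proportion_ranges` object.
#' @seealso [brain_proportion_ranges()] for shipped cortex defaults,
#'   [draw_proportions()].
#' @export
proportion_ranges <- function(ranges, residual_type) {
  stopifnot(is.data.frame(ranges),
            all(c("cell_type", "a", "b") %in% names(ranges)))
  ranges <- tibble(cell_type = as.character(ranges$cell_type),
                   a = as.numeric(ranges$a), b = as.numeric(ranges$b))
  if (anyDuplicated(c(ranges$cell_type, residual_type))) {
    abort("cell-type labels (including the residual type) must be unique.")
  }
  if (any(ranges$a < 0) || any(ranges$b > 1) || any(ranges$a > ranges$b)) {
    abort("ranges must satisfy 0 <= a <= b <= 1 for every free type.")
  }
  if (sum(ranges$a) > 1) {
    abort("infeasible ranges: the minima alone sum to more than 1.")
  }
  structure(list(ranges = ranges, residual_type = as.character(residual_type)),
            class = "proportion_ranges")
}

#' Default human-cortex proportion ranges
#'
#' Plausible prefrontal-cortex abundance ranges for the seven major brain
#' cell types, with glutamatergic neurons (GLU) as the residual type. These
#' are package defaults chosen as reasonable brain cell-type abundances, not
#' values tied to any particular cohort; supply your own table to
#' [proportion_ranges()] for other tissues.
#'
#' @return A `proportion_ranges` object over AST, END, MIC, ODC, OPC, GAB
#'   (free) and GLU (residual).
#' @export
brain_proportion_ranges <- function() {
  proportion_ranges(
    tibble(
      cell_type = c("AST", "END", "MIC", "ODC", "OPC", "GAB"),
      a = c(0.05, 0.01, 0.02, 0.10, 0.01, 0.05),
      b = c(0.25, 0.08, 0.12, 0.40, 0.08, 0.20)
    ),
    residual_type = "GLU"
  )
}

#' Draw feasible cell-type proportion vectors
#'
#' Samples each free proportion uniformly from its range and assigns the
#' residual type `1 - sum`; whole vectors with a negative residual are
#' rejected and redrawn.
#'
#' @param ranges A [proportion_ranges()] object.
#' @param n_samples Number of proportion vectors to draw.
#' @param max_attempts Cap on rejection rounds before erroring.
#' @return Tibble with a `sample` id column and one proportion column per
#'   cell type (free types first, residual last); rows sum to 1.
#' @export
draw_proportions <- function(ranges, n_samples, max_attempts = 1000L) {
  stopifnot(inherits(ranges, "proportion_ranges"), n_samples >= 1)
  rr <- ranges$ranges
  K_free <- nrow(rr)
  kept <- matrix(numeric(0), ncol = K_free)
  attempts <- 0L
  while (nrow(kept) < n_samples) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf("rejection sampling failed to find %d feasible draws in %d rounds.",
                    n_samples, max_attempts))
    }
    need <- n_samples - nrow(kept)
    draw <- vapply(seq_len(K_free),
                   function(k) runif(need, rr$a[k], rr$b[k]),
                   numeric(need))
    draw <- matrix(draw, nrow = need)
    ok <- rowSums(draw) <= 1
    kept <- rbind(kept, draw[ok, , drop = FALSE])
  }
  kept <- kept[seq_len(n_samples), , drop = FALSE]
  resid <- 1 - rowSums(kept)
  resid[abs(resid) < 1e-12] <- 0
  out <- as_tibble(kept, .name_repair = ~ rr$cell_type)
  out[[ranges$residual_type]] <- resid
  dplyr::bind_cols(tibble(sample = sprintf("S%d", seq_len(n_samples))), out)
}

#' Per-gene capture-bias models
#'
#' Three bias models for [simulate_bulk()]: none; gamma bias
#' `B_g = log2(Gamma(shape, rate) + 1)` drawn independently per gene; and a
#' fixed quotient bias `B_g = Q_g`, typically the capture quotient of a real
#' bulk dataset against the single-nuclei reference ([quotient_bias()]).
#'
#' @param shape,rate Gamma parameters (both `> 0`). The simulation designs
#'   used for benchmarking use (0.25, 0.025), (0.75, 0.25) and (1.0, 0.5).
#' @param quotient Named per-gene vector (or tibble from [quotient_bias()])
#'   of nonnegative finite factors.
#' @return A `bias_model` object.
#' @export
bias_gamma <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  structure(list(kind = "gamma", shape = shape, rate = rate), class = "bias_model")
}

#' @rdname bias_gamma
#' @export
bias_none <- function() structure(list(kind = "none"), class = "bias_model")

#' @rdname bias_gamma
#' @export
bias_quotient <- function(quotient) {
  q <- as_named_vector(quotient, arg = "quotient")
  if (any(!is.finite(q) & !is.na(q)) || any(q < 0, na.rm = TRUE)) {
    abort("quotient bias factors must be nonnegative and finite.")
  }
  structure(list(kind = "quotient", quotient = q), class = "bias_model")
}

#' Gamma-derived per-gene bias factors
#'
#' Draws `B_g = log2(G + 1)` with `G ~ Gamma(shape, rate)`, one factor per
#' gene; always nonnegative.
#'
#' @param n_genes Number of factors to draw.
#' @inheritParams bias_gamma
#' @return Numeric vector of length `n_genes`.
#' @export
gamma_bias <- function(n_genes, shape, rate) {
  stopifnot(n_genes >= 1, shape > 0, rate > 0)
  log2(rgamma(n_genes, shape = shape, rate = rate) + 1)
}

#' Capture quotient between a bulk dataset and a single-nuclei reference
#'
#' Sums expression per gene in each dataset, normalizes each total vector to
#' sum 1 over the shared genes, and returns `Q_g = bulk' / reference'`: the
#' per-gene ratio of normalized bulk capture to normalized single-nuclei
#' capture. `Q_g > 1` marks genes captured preferentially by bulk
#' sequencing. Genes absent from either input are excluded (intersection);
#' genes with zero reference capture get `NA`.
#'
#' @param ref_totals Named per-gene totals (or tibble) from the single-nuclei
#'   reference; a [reference_counts()] or `signature_set` may be given
#'   directly.
#' @param bulk_totals Named per-gene totals from the bulk dataset, or a
#'   gene x sample count matrix / data frame (totals are row sums).
#' @return Named numeric vector of quotients over the shared genes, in
#'   reference gene order.
#' @export
quotient_bias <- function(ref_totals, bulk_totals) {
  x <- gene_totals(ref_totals, "ref_totals")
  y <- gene_totals(bulk_totals, "bulk_totals")
  shared <- intersect(names(x), names(y))
  if (!length(shared)) abort("reference and bulk share no genes.")
  x <- x[shared]
  y <- y[shared]
  if (any(x < 0) || any(y < 0)) abort("totals must be nonnegative.")
  xn <- x / sum(x)
  yn <- y / sum(y)
  q <- ifelse(xn > 0, yn / xn, NA_real_)
  setNames(q, shared)
}

gene_totals <- function(x, arg) {
  if (inherits(x, "reference_counts")) {
    return(setNames(as.numeric(Matrix::rowSums(x$counts)), x$gene_ids))
  }
  if (inherits(x, "signature_set")) {
    return(setNames(colSums(x$profile), x$gene_ids))
  }
  if (inherits(x, "simulated_bulk")) x <- x$counts
  if ((is.matrix(x) || inherits(x, "Matrix")) && ncol(x) > 1) {
    return(setNames(as.numeric(Matrix::rowSums(x)), rownames(x)))
  }
  if (is.data.frame(x) && ncol(x) > 2) {
    m <- as_count_matrix(x, arg)
    return(setNames(rowSums(m), rownames(m)))
  }
  if (is.matrix(x)) {
    return(setNames(as.numeric(x[, 1]), rownames(x)))
  }
  as_named_vector(x, arg = arg)
}

#' Multiply a per-type expression profile by per-gene bias factors
#'
#' Applies `X[k, g] <- X[k, g] * B[g]` for every cell type; renormalize the
#' result per type (rows to sum 1) with [normalize_profile()] before feeding
#' it to [simulate_bulk()].
#'
#' @param profile Type x gene matrix.
#' @param bias Per-gene factor vector, length `ncol(profile)` (matched by
#'   name when both are named).
#' @return Matrix of the same shape.
#' @export
apply_bias <- function(profile, bias) {
  stopifnot(is.matrix(profile))
  if (length(bias) != ncol(profile)) {
    abort("`bias` length must equal the number of genes in `profile`.")
  }
  if (!is.null(names(bias)) && !is.null(colnames(profile))) {
    if (!setequal(names(bias), colnames(profile))) {
      abort("`bias` gene names do not match `profile` genes.")
    }
    bias <- bias[colnames(profile)]
  }
  sweep(profile, 2, bias, `*`)
}

#' @rdname apply_bias
#' @export
normalize_profile <- function(profile) {
  tot <- rowSums(profile)
  if (any(tot == 0)) {
    abort(sprintf("cell type(s) with all-zero profile after bias: %s",
                  paste(rownames(profile)[tot == 0], collapse = ", ")))
  }
  profile / tot
}

#' Simulate pseudo-bulk RNA-seq with known cell-type fractions
#'
#' For each sample: draws cell-type proportions from `ranges`, mixes the
#' per-type normalized expression profiles into per-gene relative abundances
#' `R_g = sum_k P_k * X'[k, g]`, renormalizes, draws a sequencing depth
#' uniformly from `depth_range`, and assigns every read to a gene by a single
#' multinomial draw over `R'` (exactly equivalent to sampling reads one at a
#' time, and much faster). Under a bias model, the raw pooled profile is
#' first multiplied gene-wise by the bias factors and renormalized per type.
#'
#' @param signature A `signature_set` (its pooled profile is used), or a
#'   type x gene profile matrix with rows summing to 1 (raw pooled rows when
#'   a bias model is given).
#' @param ranges A [proportion_ranges()] object covering the profile's types.
#' @param n_samples Number of pseudo-bulk samples.
#' @param depth_range Inclusive integer range for per-sample read depth;
#'   default 8-12 million reads.
#' @param bias A `bias_model` ([bias_none()], [bias_gamma()],
#'   [bias_quotient()]).
#' @param seed Optional integer seed; recorded in the result, making the
#'   dataset bit-reproducible.
#' @return A `simulated_bulk` object: `counts` (gene x sample integer
#'   matrix), `true_proportions` (tibble, rows summing to 1),
#'   `bias_vector` (named per-gene factors actually applied), `depth`
#'   (per-sample totals) and `seed`.
#' @export
simulate_bulk <- function(signature, ranges, n_samples,
                          depth_range = c(8e6, 12e6),
                          bias = bias_none(), seed = NULL) {
  stopifnot(inherits(ranges, "proportion_ranges"), n_samples >= 1,
            length(depth_range) == 2, depth_range[1] >= 1,
            depth_range[1] <= depth_range[2],
            inherits(bias, "bias_model"))
  if (!is.null(seed)) set.seed(seed)

  profile <- if (inherits(signature, "signature_set")) signature$profile else signature
  stopifnot(is.matrix(profile))
  genes <- colnames(profile)

  bias_vec <- switch(bias$kind,
    none = setNames(rep(1, ncol(profile)), genes),
    gamma = setNames(gamma_bias(ncol(profile), bias$shape, bias$rate), genes),
    quotient = {
      q <- bias$quotient
      missing <- setdiff(genes, names(q))
      if (length(missing)) {
        abort(sprintf("quotient bias lacks %d gene(s) of the profile.", length(missing)))
      }
      q <- q[genes]
      q[is.na(q)] <- 0   # undefined capture: gene contributes nothing
      q
    }
  )
  profile <- normalize_profile(apply_bias(profile, bias_vec))

  props <- draw_proportions(ranges, n_samples)
  P <- proportions_to_matrix(props)
  if (!setequal(colnames(P), rownames(profile))) {
    abort("`ranges` cell types must match the profile's cell types exactly.")
  }
  R <- P[, rownames(profile), drop = FALSE] %*% profile   # n_samples x G

  depth <- as.integer(floor(runif(n_samples, depth_range[1], depth_range[2] + 1)))
  depth <- pmin(depth, as.integer(depth_range[2]))

  counts <- matrix(0L, nrow = ncol(profile), ncol = n_samples,
                   dimnames = list(genes, props$sample))
  for (j in seq_len(n_samples)) {
    r <- R[j, ]
    if (sum(r) <= 0) abort(sprintf("sample %s has an all-zero relative-abundance vector.", props$sample[j]))
    counts[, j] <- rmultinom(1, size = depth[j], prob = r / sum(r))[, 1]
  }

  structure(
    list(counts = counts, true_proportions = props,
         bias_vector = bias_vec, depth = setNames(depth, props$sample),
         bias_kind = bias$kind, seed = seed),
    class = "simulated_bulk"
  )
}

#' @export
print.simulated_bulk <- function(x, ...) {
  cat(sprintf("<simulated_bulk> %d genes x %d samples | bias: %s | depth %s-%s\n",
              nrow(x$counts), ncol(x$counts), x$bias_kind,
              format(min(x$depth), big.mark = ","), format(max(x$depth), big.mark = ",")))
  invisible(x)
}
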