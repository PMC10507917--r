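#' Deconvolution configuration
#'
#' Collects the tuning parameters of the iterated weighted-NNLS estimator.
#'
#' @param method `"music"` (cross-subject variance weighting only) or
#'   `"detrem"` (additionally divides gene weights by the capture-quotient
#'   penalty, see [detrem_penalty()]).
#' @param center Subtract the mean of each working vector (the weighted bulk
#'   vector and each weighted signature column) before every NNLS solve
#'   (the "C" variant).
#' @param normalize Divide each working vector by its standard deviation
#'   before every NNLS solve (the "N" variant). Both flags together give the
#'   "CN" variant.
#' @param nu Regulation parameter guarding the weight denominator; default
#'   `1e-4`.
#' @param eps Convergence threshold on the maximum absolute change in any
#'   estimated proportion between iterations; default 0.01.
#' @param max_iter Iteration cap; default 1000.
#' @param penalty_scale Multiplier of `|log2 Q|` in the capture penalty;
#'   default 10.
#' @param literal_clamp Use the literal published clamp (keep
#'   `penalty_scale * |log2 Q|` when below 1, else 1, and divide by it) which
#'   *amplifies* weights of concordant genes; the default `FALSE` uses the
#'   objective-consistent form `max(1, penalty_scale * |log2 Q|)` so that no
#'   gene weight is ever increased. Kept for auditability.
#' @param normalize_bulk Divide each bulk sample by its total so bulk and
#'   signature are on comparable relative scales; default `TRUE`.
#' @return A `deconv_config` object.
#' @export
deconv_config <- function(method = c("music", "detrem"),
                          center = FALSE, normalize = FALSE,
                          nu = 1e-4, eps = 0.01, max_iter = 1000L,
                          penalty_scale = 10, literal_clamp = FALSE,
                          normalize_bulk = TRUE) {
  method <- match.arg(method)
  stopifnot(nu > 0, eps > 0, max_iter >= 1, penalty_scale > 0)
  structure(list(method = method, center = center, normalize = normalize,
                 nu = nu, eps = eps, max_iter = as.integer(max_iter),
                 penalty_scale = penalty_scale, literal_clamp = literal_clamp,
                 normalize_bulk = normalize_bulk),
            class = "deconv_config")
}

#' Working gene set shared by a signature and a bulk dataset
#'
#' Intersects the signature genes having nonzero expression in at least one
#' cell type with the bulk genes having a nonzero grand total, returned in
#' signature order (so the result is invariant to bulk gene order).
#'
#' @param signature A `signature_set`.
#' @param bulk Gene x sample count matrix (or data frame with a gene-id
#'   first column).
#' @return Character vector of gene ids.
#' @export
common_genes <- function(signature, bulk) {
  stopifnot(inherits(signature, "signature_set"))
  bulk <- as_count_matrix(bulk, "bulk")
  expressed_sig <- signature$gene_ids[apply(signature$theta > 0, 2, any)]
  expressed_bulk <- rownames(bulk)[rowSums(bulk) > 0]
  genes <- expressed_sig[expressed_sig %in% expressed_bulk]
  if (!length(genes)) abort("signature and bulk share no expressed genes.")
  genes
}

#' MuSiC-style gene weights
#'
#' Computes `w_g = 1 / (sigma_g + r_g^2 + nu)` with
#' `sigma_g = sum_k (S_k * theta[k, g])^2 * sigma[k, g]`: genes whose
#' relative expression varies across subjects in the cell types where they
#' are most expressed, or which fit poorly (large residual), are
#' down-weighted. Strictly positive and bounded above by `1 / nu`.
#'
#' @param residual Per-gene residual vector from the current fit.
#' @param theta,sigma Type x gene signature mean / cross-subject variance on
#'   the working gene set.
#' @param cell_size Per-type cell-size factors `S_k`.
#' @param nu Regulation parameter.
#' @return Per-gene weight vector.
#' @export
music_weights <- function(residual, theta, sigma, cell_size, nu = 1e-4) {
  stopifnot(length(residual) == ncol(theta),
            all(dim(theta) == dim(sigma)),
            length(cell_size) == nrow(theta), nu > 0)
  sigma_g <- colSums((cell_size * theta)^2 * sigma)
  1 / (sigma_g + residual^2 + nu)
}

#' Capture-quotient weight penalty
#'
#' Converts per-gene capture quotients `Q_g` ([quotient_bias()]) into weight
#' divisors: `D_g = max(1, penalty_scale * |log2 Q_g|)` so that genes
#' captured very differently by the reference and target technologies have
#' their weights divided by up to `penalty_scale * |log2 Q_g|`, while
#' concordant genes (`Q_g` near 1) are untouched — no gene weight is ever
#' increased. With `literal = TRUE` the clamp is applied as originally
#' printed (values below 1 are kept and divided by), which amplifies
#' concordant genes' weights instead; retained for auditability.
#'
#' @param quotient Per-gene capture quotients, strictly positive.
#' @param penalty_scale Multiplier of `|log2 Q|`; default 10.
#' @param literal Use the literal clamp form.
#' @return Per-gene divisor vector `D_g` (`>= 1` unless `literal`).
#' @export
detrem_penalty <- function(quotient, penalty_scale = 10, literal = FALSE) {
  if (any(!is.finite(quotient)) || any(quotient <= 0)) {
    abort("quotients must be strictly positive and finite (drop undefined genes upstream).")
  }
  qp <- penalty_scale * abs(log2(quotient))
  if (literal) ifelse(qp < 1, qp, 1) else pmax(1, qp)
}

#' Deconvolute one bulk expression vector
#'
#' Iterated weighted NNLS: starting from unit weights, repeatedly solve the
#' nonnegative least-squares system `sqrt(w) * y ~ sqrt(w) * D` with design
#' `D[g, k] = S_k * theta[k, g]`, compute per-gene residuals on the original
#' scale, update weights via [music_weights()] (divided by the
#' [detrem_penalty()] when `method = "detrem"`), and stop when no estimated
#' proportion moves by more than `eps`. Proportions are the NNLS
#' coefficients normalized to sum 1; NNLS zeros are exact.
#'
#' @param y Named bulk expression vector on (a superset of) the signature's
#'   genes.
#' @param signature A `signature_set`.
#' @param config A [deconv_config()].
#' @param quotient Per-gene capture quotients (required for
#'   `method = "detrem"`); genes with undefined or nonpositive quotients are
#'   dropped from the working set with a message.
#' @return List with `proportions` (named, summing to 1; all-`NA` when NNLS
#'   returns the zero vector), `raw_coefficients`, `converged`,
#'   `iterations`, `weights` (final per-gene weights) and `gene_ids`.
#' @export
deconvolute_sample <- function(y, signature, config = deconv_config(),
                               quotient = NULL, genes = NULL) {
  stopifnot(inherits(signature, "signature_set"), inherits(config, "deconv_config"))
  y <- as_named_vector(y, arg = "y")
  if (all(y == 0)) abort("bulk vector is all zero.")
  prep <- prepare_system(y, signature, config, quotient, genes)
  fit <- wnnls_iterate(prep$y, prep$design, prep$theta, prep$sigma,
                       signature$cell_size, config, prep$penalty)
  c(fit, list(gene_ids = prep$genes))
}

# Align y / signature on the working gene set and precompute the design and
# (for detrem) the penalty divisor. `genes` may be supplied (dataset-level
# working set from deconvolute()); otherwise it is derived from this vector.
prepare_system <- function(y, signature, config, quotient, genes = NULL) {
  if (is.null(genes)) {
    bulk_mat <- matrix(y, ncol = 1, dimnames = list(names(y), "s"))
    genes <- common_genes(signature, bulk_mat)
    if (config$method == "detrem") {
      if (is.null(quotient)) {
        abort("method = 'detrem' needs per-gene capture quotients (see quotient_bias()).")
      }
      genes <- quotient_defined_genes(genes, quotient, verbose = TRUE)
    }
  } else {
    missing <- setdiff(genes, names(y))
    if (length(missing)) abort("`y` lacks genes of the working set.")
  }
  penalty <- NULL
  if (config$method == "detrem") {
    q <- as_named_vector(quotient, arg = "quotient")[genes]
    penalty <- detrem_penalty(q, config$penalty_scale, config$literal_clamp)
  }
  theta <- signature$theta[, genes, drop = FALSE]
  sigma <- signature$sigma[, genes, drop = FALSE]
  yv <- y[genes]
  if (config$normalize_bulk) yv <- yv / sum(yv)
  design <- t(theta * signature$cell_size)   # G x K, column k = S_k * theta_k.
  list(y = yv, design = design, theta = theta, sigma = sigma,
       genes = genes, penalty = penalty)
}

quotient_defined_genes <- function(genes, quotient, verbose = FALSE) {
  q <- as_named_vector(quotient, arg = "quotient")[genes]
  bad <- is.na(q) | !is.finite(q) | q <= 0
  if (any(bad) && verbose) {
    inform(sprintf("Dropping %d gene(s) with undefined capture quotient.", sum(bad)))
  }
  genes <- genes[!bad]
  if (!length(genes)) abort("no gene with a defined capture quotient remains.")
  genes
}

# Lawson-Hanson NNLS; rank-deficient weighted systems (possible once extreme
# weights concentrate mass on fewer genes than cell types, or after
# centering) fall back to a vanishingly small ridge augmentation.
nnls_solve <- function(A, b) {
  fit <- tryCatch(pracma::lsqnonneg(A, b), error = function(e) NULL)
  if (!is.null(fit)) return(fit$x)
  lambda <- sqrt(1e-10 * mean(colSums(A^2)))
  A_aug <- rbind(A, diag(lambda, ncol(A)))
  pracma::lsqnonneg(A_aug, c(b, rep(0, ncol(A))))$x
}

wnnls_iterate <- function(y, design, theta, sigma, cell_size, config, penalty) {
  K <- ncol(design)
  w <- rep(1, length(y))
  p_prev <- NULL
  p <- rep(NA_real_, K)
  converged <- FALSE
  iter <- 0L
  b <- rep(0, K)
  for (iter in seq_len(config$max_iter)) {
    sw <- sqrt(w)
    yw <- y * sw
    Dw <- design * sw
    if (config$center) {
      yw <- yw - mean(yw)
      Dw <- sweep(Dw, 2, colMeans(Dw))
    }
    if (config$normalize) {
      sdy <- sd(yw)
      if (sdy > 0) yw <- yw / sdy
      sdc <- apply(Dw, 2, sd)
      sdc[sdc == 0] <- 1
      Dw <- sweep(Dw, 2, sdc, `/`)
    }
    b <- nnls_solve(Dw, yw)
    if (all(b == 0)) {
      return(list(proportions = setNames(rep(NA_real_, K), colnames(design)),
                  raw_coefficients = setNames(b, colnames(design)),
                  converged = FALSE, iterations = iter, weights = w))
    }
    p <- b / sum(b)
    if (!is.null(p_prev) && max(abs(p - p_prev)) < config$eps) {
      converged <- TRUE
      break
    }
    p_prev <- p
    r <- as.numeric(y - design %*% b)
    w <- music_weights(r, theta, sigma, cell_size, config$nu)
    if (!is.null(penalty)) w <- w / penalty
  }
  list(proportions = setNames(p, colnames(design)),
       raw_coefficients = setNames(b, colnames(design)),
       converged = converged, iterations = iter, weights = w)
}

#' Deconvolute a bulk RNA-seq dataset
#'
#' Runs [deconvolute_sample()] independently on every column of `bulk`. For
#' `method = "detrem"` the capture quotient is computed once from the whole
#' bulk dataset against the reference ([quotient_bias()]) and shared by all
#' samples; pass either `reference` (labelled single-nuclei counts or a
#' signature carrying its pooled profile) or a precomputed `quotient`.
#'
#' @param bulk Gene x sample count matrix, data frame with a gene-id first
#'   column, or a `simulated_bulk` object.
#' @param signature A `signature_set` from [build_signature()].
#' @param config A [deconv_config()].
#' @param reference Optional [reference_counts()] / `signature_set` used to
#'   derive the capture quotient for `method = "detrem"`.
#' @param quotient Optional precomputed per-gene quotient vector (overrides
#'   `reference`).
#' @return A `deconv_result`: `proportions` tibble (`sample` column plus one
#'   column per cell type; rows sum to 1, `NA` rows flag samples whose NNLS
#'   solution was identically zero), `raw_coefficients`, `convergence`
#'   tibble, `weights` (gene x sample matrix of final weights), `gene_ids`,
#'   `method` and `config`.
#' @examples
#' spec <- synthetic_reference_spec(n_genes = 300, cells_per_type = 40)
#' ref <- make_reference(spec, seed = 1)
#' sig <- build_signature(ref)
#' sim <- simulate_bulk(sig, synthetic_ranges(spec), n_samples = 5,
#'                      depth_range = c(5e4, 1e5), seed = 2)
#' fit <- deconvolute(sim, sig)
#' fit$proportions
#' @export
deconvolute <- function(bulk, signature, config = deconv_config(),
                        reference = NULL, quotient = NULL) {
  stopifnot(inherits(signature, "signature_set"), inherits(config, "deconv_config"))
  if (inherits(bulk, "simulated_bulk")) bulk <- bulk$counts
  bulk <- as_count_matrix(bulk, "bulk")
  if (is.null(colnames(bulk))) colnames(bulk) <- sprintf("S%d", seq_len(ncol(bulk)))

  if (config$method == "detrem" && is.null(quotient)) {
    if (is.null(reference)) {
      abort("method = 'detrem' needs `reference` or `quotient` to derive capture quotients.")
    }
    quotient <- quotient_bias(reference, bulk)
  }

  ## One working gene set for the whole dataset, shared by every sample.
  genes <- common_genes(signature, bulk)
  if (config$method == "detrem") {
    genes <- quotient_defined_genes(genes, quotient, verbose = TRUE)
  }

  fits <- purrr::imap(
    setNames(seq_len(ncol(bulk)), colnames(bulk)),
    function(j, id) {
      tryCatch(
        deconvolute_sample(bulk[, j], signature, config,
                           quotient = quotient, genes = genes),
        error = function(e) {
          abort(sprintf("sample '%s': %s", id, conditionMessage(e)), parent = e)
        }
      )
    }
  )

  types <- signature$type_labels
  prop <- dplyr::bind_rows(purrr::map(fits, ~ as_tibble(as.list(.x$proportions))))
  proportions <- dplyr::bind_cols(tibble(sample = colnames(bulk)), prop)
  raw <- dplyr::bind_cols(tibble(sample = colnames(bulk)),
                          dplyr::bind_rows(purrr::map(fits, ~ as_tibble(as.list(.x$raw_coefficients)))))
  convergence <- tibble(
    sample = colnames(bulk),
    converged = purrr::map_lgl(fits, "converged"),
    iterations = purrr::map_int(fits, ~ as.integer(.x$iterations))
  )
  genes <- fits[[1]]$gene_ids
  weights <- vapply(fits, function(f) {
    w <- setNames(rep(NA_real_, length(genes)), genes)
    w[f$gene_ids] <- f$weights
    w
  }, numeric(length(genes)))
  dimnames(weights) <- list(genes, colnames(bulk))

  structure(
    list(proportions = proportions, raw_coefficients = raw,
         convergence = convergence, weights = weights,
         gene_ids = genes, method = config$method, config = config),
    class = "deconv_result"
  )
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> method: %s | %d samples x %d cell types | %d genes\n",
              x$method, nrow(x$proportions), ncol(x$proportions) - 1L,
              length(x$gene_ids)))
  cat(sprintf("  converged: %d/%d samples\n",
              sum(x$convergence$converged), nrow(x$convergence)))
  print(head(x$proportions, 5))
  invisible(x)
}
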