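#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. Unlike Pearson's r it penalizes location and
#' scale shifts: it equals 1 only when `y = x` exactly.
#'
#' @param x,y Equal-length finite numeric vectors (length >= 2).
#' @return Scalar in `[-1, 1]`; `NA` when both vectors are constant with
#'   equal means (zero denominator).
#' @export
ccc <- function(x, y) {
  check_pair(x, y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(NA_real_)
  2 * cxy / denom
}

#' Root mean square error and Pearson correlation
#'
#' @inheritParams ccc
#' @return `rmse()`: `sqrt(mean((x - y)^2))`. `pearson_r()`: product-moment
#'   correlation, `NA` when either input is constant.
#' @export
rmse <- function(x, y) {
  check_pair(x, y)
  sqrt(mean((x - y)^2))
}

#' @rdname rmse
#' @export
pearson_r <- function(x, y) {
  check_pair(x, y)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("need at least two paired observations.")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("inputs must be finite.")
  invisible(NULL)
}

#' Count exact-zero proportion estimates per cell type
#'
#' NNLS produces exact zeros for inactive cell types, so "absent" calls can
#' be counted directly. Fractions are over samples with a defined (non-`NA`)
#' estimate.
#'
#' @param result A `deconv_result` or a proportions table (`sample` column
#'   plus one column per cell type).
#' @return Tibble with `cell_type`, `zero_count`, `zero_fraction`, `n`.
#' @export
zero_calls <- function(result) {
  P <- proportions_to_matrix(extract_proportions(result))
  tibble(
    cell_type = colnames(P),
    zero_count = vapply(seq_len(ncol(P)), function(k) {
      sum(P[, k] == 0, na.rm = TRUE)
    }, integer(1)),
    zero_fraction = vapply(seq_len(ncol(P)), function(k) {
      n <- sum(!is.na(P[, k]))
      if (n == 0) NA_real_ else sum(P[, k] == 0, na.rm = TRUE) / n
    }, numeric(1)),
    n = vapply(seq_len(ncol(P)), function(k) sum(!is.na(P[, k])), integer(1))
  )
}

extract_proportions <- function(x) {
  if (inherits(x, "deconv_result")) x$proportions else x
}

#' Concordance of estimates with an external measurement
#'
#' Matches per-sample proportion estimates with an external per-sample
#' measurement of the same cell type (IHC fraction, marker-gene expression,
#' cell density), optionally excludes samples with an exact-zero estimate,
#' min-max scales both retained vectors to `[0, 1]`, and reports their
#' Pearson correlation. Scaling follows exclusion, so the observed min/max
#' are those of the retained samples.
#'
#' @param estimates Tibble with columns `sample` and `value` (or a named
#'   vector) of proportion estimates for one cell type.
#' @param external Same shape: external measurement per sample.
#' @param drop_zeros Exclude samples with a zero estimate before scaling;
#'   default `TRUE`.
#' @return One-row tibble: `r`, `n_retained`, `note` (`NA` unless the
#'   correlation is undefined, in which case `r` is `NA` and `note` says
#'   why).
#' @export
scaled_concordance <- function(estimates, external, drop_zeros = TRUE) {
  e <- as_named_vector(estimates, arg = "estimates")
  x <- as_named_vector(external, arg = "external")
  shared <- intersect(names(e), names(x))
  e <- e[shared]; x <- x[shared]
  keep <- !is.na(e) & !is.na(x)
  if (drop_zeros) keep <- keep & e != 0
  e <- e[keep]; x <- x[keep]
  if (length(e) < 3) {
    return(tibble(r = NA_real_, n_retained = length(e),
                  note = "fewer than 3 retained pairs"))
  }
  rs <- pearson_r(minmax(e), minmax(x))
  tibble(r = rs, n_retained = length(e),
         note = if (is.na(rs)) "constant retained vector" else NA_character_)
}

minmax <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(0, length(v)))
  (v - rng[1]) / diff(rng)
}

#' Combine GABAergic and glutamatergic neuron estimates
#'
#' Adds a total-neuron column (`NEU = GLU + GAB` by default) for comparison
#' with pan-neuronal measurements such as NeuN immunohistochemistry. The
#' component columns are retained; rows still sum to 1 when `NEU` is counted
#' once in place of its parts.
#'
#' @param proportions Proportions table or `deconv_result`.
#' @param glu,gab Labels of the two neuron columns.
#' @param name Name of the combined column.
#' @return The proportions tibble with the extra column.
#' @export
aggregate_neurons <- function(proportions, glu = "GLU", gab = "GAB", name = "NEU") {
  p <- extract_proportions(proportions)
  stopifnot(is.data.frame(p))
  missing <- setdiff(c(glu, gab), names(p))
  if (length(missing)) {
    abort(paste0("missing neuron column(s): ", paste(missing, collapse = ", ")))
  }
  p[[name]] <- p[[glu]] + p[[gab]]
  as_tibble(p)
}

#' Score deconvolution estimates against ground truth
#'
#' Per cell type (matching samples by id): Lin's CCC, Pearson r, RMSE over
#' samples with a defined estimate, plus exact-zero counts and fractions.
#'
#' @param result A `deconv_result` or proportions table of estimates.
#' @param truth Proportions table of true fractions (same shape).
#' @return An `evaluation_report`: tibble with one row per cell type and
#'   columns `cell_type`, `ccc`, `pearson_r`, `rmse`, `zero_count`,
#'   `zero_fraction`, `n`.
#' @export
evaluate_deconvolution <- function(result, truth) {
  est <- proportions_to_matrix(extract_proportions(result))
  tru <- proportions_to_matrix(extract_proportions(truth))
  shared_samples <- intersect(rownames(est), rownames(tru))
  shared_types <- intersect(colnames(est), colnames(tru))
  if (length(shared_samples) < 2) abort("fewer than 2 samples shared with truth.")
  if (!length(shared_types)) abort("no cell type shared with truth.")
  est <- est[shared_samples, shared_types, drop = FALSE]
  tru <- tru[shared_samples, shared_types, drop = FALSE]

  zeros <- zero_calls(matrix_to_proportions(est))
  metrics <- purrr::map_dfr(shared_types, function(k) {
    e <- est[, k]; t_ <- tru[, k]
    ok <- !is.na(e) & !is.na(t_)
    if (sum(ok) < 2) {
      return(tibble(cell_type = k, ccc = NA_real_, pearson_r = NA_real_,
                    rmse = NA_real_))
    }
    tibble(cell_type = k, ccc = ccc(e[ok], t_[ok]),
           pearson_r = pearson_r(e[ok], t_[ok]), rmse = rmse(e[ok], t_[ok]))
  })
  out <- dplyr::left_join(metrics, zeros, by = "cell_type")
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Summarize an evaluation report
#'
#' Unweighted means of the per-type metrics, skipping `NA` cells.
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return One-row tibble: `mean_ccc`, `mean_r`, `mean_rmse`, `n_types`,
#'   `total_zero_calls`.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(
    mean_ccc = mean(x$ccc, na.rm = TRUE),
    mean_r = mean(x$pearson_r, na.rm = TRUE),
    mean_rmse = mean(x$rmse, na.rm = TRUE),
    n_types = nrow(x),
    total_zero_calls = sum(x$zero_count)
  )
}
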