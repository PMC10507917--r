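# Brute-force oracles: deliberately naive nested-loop implementations,
# independent of the vectorized package code they check.

oracle_pooled_profile <- function(counts, cell_type_of) {
  types <- sort(unique(cell_type_of))
  X <- matrix(0, length(types), nrow(counts),
              dimnames = list(types, rownames(counts)))
  for (k in types) {
    for (g in seq_len(nrow(counts))) {
      s <- 0
      for (c in which(cell_type_of == k)) s <- s + counts[g, c]
      X[k, g] <- s
    }
  }
  Xn <- X
  for (k in types) Xn[k, ] <- X[k, ] / sum(X[k, ])
  list(profile = X, profile_norm = Xn)
}

oracle_signature <- function(counts, cell_type_of, subject_of) {
  types <- sort(unique(cell_type_of))
  subjects <- sort(unique(subject_of))
  G <- nrow(counts)
  theta <- sigma <- matrix(NA_real_, length(types), G,
                           dimnames = list(types, rownames(counts)))
  cell_size <- numeric(length(types))
  names(cell_size) <- types
  for (k in types) {
    profs <- NULL
    szs <- c()
    for (j in subjects) {
      cells <- which(cell_type_of == k & subject_of == j)
      if (!length(cells)) next
      mc <- rep(0, G)
      for (g in seq_len(G)) mc[g] <- mean(counts[g, cells])
      if (sum(mc) == 0) next
      profs <- rbind(profs, mc / sum(mc))
      szs <- c(szs, mean(colSums(counts)[cells]))
    }
    for (g in seq_len(G)) {
      v <- profs[, g]
      theta[k, g] <- mean(v)
      sigma[k, g] <- mean((v - mean(v))^2)   # population variance
    }
    cell_size[k] <- mean(szs)
  }
  list(theta = theta, sigma = sigma, cell_size = cell_size)
}

oracle_music_weights <- function(residual, theta, sigma, cell_size, nu) {
  G <- length(residual)
  w <- numeric(G)
  for (g in seq_len(G)) {
    sg <- 0
    for (k in seq_len(nrow(theta))) {
      sg <- sg + (cell_size[k] * theta[k, g])^2 * sigma[k, g]
    }
    w[g] <- 1 / (sg + residual[g]^2 + nu)
  }
  w
}

oracle_quotient <- function(ref_totals, bulk_totals) {
  genes <- intersect(names(ref_totals), names(bulk_totals))
  x <- ref_totals[genes] / sum(ref_totals[genes])
  y <- bulk_totals[genes] / sum(bulk_totals[genes])
  q <- rep(NA_real_, length(genes))
  names(q) <- genes
  for (g in seq_along(genes)) if (x[g] > 0) q[g] <- y[g] / x[g]
  q
}

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  2 * cxy / (vx + vy + (mx - my)^2)
}

oracle_rmse <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s / length(x))
}

# Straight-line re-implementation of the iterated weighted-NNLS update for
# the plain (music) method, written as an explicit script: no shared code
# with the package beyond the NNLS solver primitive.
oracle_wnnls_music <- function(y, theta, sigma, cell_size, nu = 1e-4,
                               eps = 0.01, max_iter = 1000) {
  y <- y / sum(y)
  D <- matrix(0, ncol(theta), nrow(theta))
  for (g in seq_len(ncol(theta))) {
    for (k in seq_len(nrow(theta))) D[g, k] <- cell_size[k] * theta[k, g]
  }
  w <- rep(1, length(y))
  p_old <- NULL
  for (it in seq_len(max_iter)) {
    b <- pracma::lsqnonneg(D * sqrt(w), y * sqrt(w))$x
    if (all(b == 0)) return(rep(NA_real_, nrow(theta)))
    p <- b / sum(b)
    if (!is.null(p_old) && max(abs(p - p_old)) < eps) break
    p_old <- p
    r <- y - as.numeric(D %*% b)
    sg <- numeric(length(y))
    for (g in seq_along(y)) {
      sg[g] <- sum((cell_size * theta[, g])^2 * sigma[, g])
    }
    w <- 1 / (sg + r^2 + nu)
  }
  names(p) <- rownames(theta)
  p
}
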