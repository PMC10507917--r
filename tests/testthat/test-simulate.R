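test_that("degenerate point-mass ranges give deterministic proportions", {
  rng <- proportion_ranges(
    data.frame(cell_type = paste0("T", 1:6), a = 0.1, b = 0.1),
    residual_type = "T7"
  )
  p <- draw_proportions(rng, n_samples = 5)
  m <- detrem:::proportions_to_matrix(p)
  expect_true(all(abs(m[, paste0("T", 1:6)] - 0.1) < 1e-12))
  expect_equal(unname(m[, "T7"]), rep(0.4, 5))
})

test_that("with one free type the residual is exactly its complement", {
  rng <- proportion_ranges(data.frame(cell_type = "A", a = 0, b = 1),
                           residual_type = "B")
  set.seed(5)
  p <- draw_proportions(rng, 100)
  expect_equal(p$B, 1 - p$A)
  expect_true(all(p$A >= 0 & p$A <= 1))
})

test_that("free proportions keep rejection-adjusted uniform marginals", {
  set.seed(99)
  rng <- brain_proportion_ranges()
  p <- draw_proportions(rng, 5000)
  m <- detrem:::proportions_to_matrix(p)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  rr <- rng$ranges
  for (i in seq_len(nrow(rr))) {
    v <- m[, rr$cell_type[i]]
    expect_true(all(v >= rr$a[i] - 1e-12 & v <= rr$b[i] + 1e-12))
  }
  expect_true(all(m[, rng$residual_type] >= 0))

  # independent rejection-sampling oracle for the feasible-mean of each type
  draws <- vapply(seq_len(nrow(rr)),
                  function(k) runif(2e4, rr$a[k], rr$b[k]), numeric(2e4))
  keep <- rowSums(draws) <= 1
  oracle_mean <- colMeans(draws[keep, ])
  got_mean <- colMeans(m[, rr$cell_type])
  expect_equal(unname(got_mean), unname(oracle_mean), tolerance = 0.02)
})

test_that("infeasible or malformed ranges are rejected", {
  expect_error(proportion_ranges(data.frame(cell_type = "A", a = 0.6, b = 0.5), "B"))
  expect_error(proportion_ranges(data.frame(cell_type = c("A", "B"),
                                            a = c(0.6, 0.6), b = c(0.7, 0.7)), "C"),
               "infeasible")
  rng <- proportion_ranges(data.frame(cell_type = c("A", "B"),
                                      a = c(0.49, 0.49), b = c(0.999, 0.999)), "C")
  expect_error(draw_proportions(rng, 500, max_attempts = 1L), "rejection")
})

test_that("gamma bias is log2(1 + gamma) and matches a Monte-Carlo oracle", {
  expect_equal(log2(0 + 1), 0)   # zero draw maps to zero bias
  set.seed(13)
  b <- gamma_bias(1e5, shape = 1.0, rate = 0.5)
  expect_true(all(is.finite(b)) && all(b >= 0))
  oracle <- mean(log2(rgamma(1e5, 1.0, rate = 0.5) + 1))
  expect_equal(mean(b), oracle, tolerance = 0.02)
  # the three benchmark parameterizations are accepted
  for (pars in list(c(0.25, 0.025), c(0.75, 0.25), c(1.0, 0.5))) {
    bb <- gamma_bias(100, pars[1], pars[2])
    expect_true(all(is.finite(bb)) && all(bb >= 0))
  }
  expect_error(gamma_bias(10, -1, 1))
})

test_that("capture quotient matches direct normalization arithmetic", {
  q <- quotient_bias(c(g1 = 1, g2 = 1), c(g1 = 3, g2 = 1))
  expect_equal(q, c(g1 = 1.5, g2 = 0.5))
  expect_equal(quotient_bias(c(a = 2, b = 2), c(a = 5, b = 5)), c(a = 1, b = 1))
  expect_error(quotient_bias(c(a = 1), c(b = 1)), "no genes")

  set.seed(17)
  x <- setNames(runif(500, 0, 10), sprintf("g%03d", 1:500))
  x[sample(500, 20)] <- 0
  y <- setNames(runif(500, 0, 10), names(x))
  expect_equal(quotient_bias(x, y), oracle_quotient(x, y))
})

test_that("apply_bias is an elementwise gene-wise product", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("A", "B"), c("g1", "g2", "g3")))
  expect_equal(apply_bias(m, c(1, 1, 1)), m)
  b0 <- c(g1 = 1, g2 = 0, g3 = 1)
  expect_true(all(apply_bias(m, b0)[, "g2"] == 0))
  expect_error(apply_bias(m, c(1, 2)), "length")
  set.seed(19)
  mm <- matrix(runif(50), 5, 10,
               dimnames = list(paste0("t", 1:5), paste0("g", 1:10)))
  bb <- runif(10)
  loop <- mm
  for (k in 1:5) for (g in 1:10) loop[k, g] <- mm[k, g] * bb[g]
  expect_equal(apply_bias(mm, bb), loop)
})

test_that("simulated counts conserve depth and are seed-reproducible", {
  spec <- synthetic_reference_spec(n_genes = 200, cells_per_type = 30)
  sig <- build_signature(make_reference(spec, seed = 3))
  rng <- synthetic_ranges(spec)
  sim <- simulate_bulk(sig, rng, n_samples = 8, depth_range = c(5e4, 8e4), seed = 4)
  expect_equal(unname(colSums(sim$counts)), unname(as.numeric(sim$depth)))
  expect_true(all(sim$depth >= 5e4 & sim$depth <= 8e4))
  m <- detrem:::proportions_to_matrix(sim$true_proportions)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))

  sim2 <- simulate_bulk(sig, rng, n_samples = 8, depth_range = c(5e4, 8e4), seed = 4)
  expect_identical(sim$counts, sim2$counts)
  expect_equal(sim$true_proportions, sim2$true_proportions)
})

test_that("a pure sample from a symmetric profile splits reads evenly", {
  profile <- matrix(c(0.5, 0.3, 0.5, 0.7), 2, 2,
                    dimnames = list(c("A", "B"), c("g1", "g2")))
  rng <- proportion_ranges(data.frame(cell_type = "B", a = 0, b = 0),
                           residual_type = "A")   # P(A) = 1 always
  set.seed(23)
  sim <- simulate_bulk(profile, rng, n_samples = 1, depth_range = c(1e6, 1e6))
  # 4 sigma binomial band around the even split of type A's profile
  expect_lt(abs(sim$counts["g1", 1] - 5e5), 4 * sqrt(1e6 * 0.25))
})

test_that("unbiased per-gene means are proportional to the mixed profile", {
  spec <- synthetic_reference_spec(n_genes = 300, cells_per_type = 30)
  sig <- build_signature(make_reference(spec, seed = 5))
  sim <- simulate_bulk(sig, synthetic_ranges(spec), n_samples = 40,
                       depth_range = c(1e5, 1e5), seed = 6)
  P <- detrem:::proportions_to_matrix(sim$true_proportions)
  expected <- colMeans(P[, rownames(sig$profile_norm)] %*% sig$profile_norm)
  observed <- rowMeans(sim$counts) / 1e5
  expect_gt(cor(expected, observed), 0.999)
})

test_that("quotient-biased simulation inflates up-captured genes downstream", {
  spec <- synthetic_reference_spec(n_genes = 200, cells_per_type = 30)
  sig <- build_signature(make_reference(spec, seed = 8))
  q <- setNames(rep(1, 200), sig$gene_ids)
  up <- sig$gene_ids[1:5]
  q[up] <- 4
  sim_b <- simulate_bulk(sig, synthetic_ranges(spec), 20,
                         depth_range = c(1e5, 1e5), bias = bias_quotient(q), seed = 9)
  sim_u <- simulate_bulk(sig, synthetic_ranges(spec), 20,
                         depth_range = c(1e5, 1e5), seed = 9)
  expect_equal(sim_b$bias_vector[up], q[up])
  expect_gt(mean(rowMeans(sim_b$counts[up, ])) / mean(rowMeans(sim_u$counts[up, ])), 2)
})
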