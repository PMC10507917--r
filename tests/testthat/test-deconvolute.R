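test_that("common genes are the expressed intersection in signature order", {
  set.seed(61)
  sig <- build_signature(random_reference(n_genes = 25))
  bulk <- matrix(5, length(sig$gene_ids), 2,
                 dimnames = list(sig$gene_ids, c("s1", "s2")))
  expect_equal(common_genes(sig, bulk), sig$gene_ids)

  # bulk missing one gene, zero in another: both excluded
  bulk2 <- bulk[-3, ]
  bulk2[1, ] <- 0
  got <- common_genes(sig, bulk2)
  expect_false(sig$gene_ids[3] %in% got)
  expect_false(sig$gene_ids[1] %in% got)

  # invariant to bulk row order
  shuffled <- bulk[sample(nrow(bulk)), ]
  expect_identical(common_genes(sig, shuffled), common_genes(sig, bulk))

  bulk3 <- matrix(1, 2, 1, dimnames = list(c("nope1", "nope2"), "s"))
  expect_error(common_genes(sig, bulk3), "no")
})

test_that("music weights follow the variance-residual formula", {
  K <- 3; G <- 100
  set.seed(71)
  theta <- matrix(runif(K * G), K, G)
  sigma <- matrix(runif(K * G, 0, 0.1), K, G)
  S <- runif(K, 500, 2000)
  r <- rnorm(G, 0, 0.01)
  w <- music_weights(r, theta, sigma, S, nu = 1e-4)
  expect_equal(w, oracle_music_weights(r, theta, sigma, S, 1e-4))

  # zero variance and zero residual hit the ceiling 1/nu
  w0 <- music_weights(rep(0, G), theta, matrix(0, K, G), S, nu = 1e-4)
  expect_equal(w0, rep(1e4, G))
  # monotone decreasing in |r|; always positive and bounded by 1/nu
  w1 <- music_weights(rep(0.05, G), theta, sigma, S, nu = 1e-4)
  expect_true(all(w1 < w))
  expect_true(all(w > 0 & w <= 1e4))
})

test_that("capture penalty clamps exactly as specified", {
  expect_equal(detrem_penalty(1), 1)                      # concordant gene untouched
  expect_equal(detrem_penalty(2), 10)                     # 10 * |log2 2|
  expect_equal(detrem_penalty(2^0.05), 1)                 # 0.5 clamped up to 1
  expect_equal(detrem_penalty(c(0.25, 4)), c(20, 20))     # symmetric in log2
  expect_error(detrem_penalty(c(1, 0)), "positive")
  # literal published form amplifies concordant genes when divided by
  lit <- detrem_penalty(2^0.05, literal = TRUE)
  expect_equal(lit, 0.5)
  # increasing |log2 Q| never increases the effective weight
  qs <- 2^seq(0, 3, by = 0.1)
  eff <- 1 / detrem_penalty(qs)
  expect_true(all(diff(eff) <= 1e-12))
})

test_that("noiseless model input is recovered exactly by both methods", {
  sig <- recovery_signature()
  p_star <- setNames(c(0.4, 0.15, 0.2, 0.15, 0.1), sig$type_labels)
  y <- as.numeric(t(sig$theta * sig$cell_size) %*% p_star)
  names(y) <- sig$gene_ids
  fit <- deconvolute_sample(y, sig, deconv_config("music"))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$proportions - p_star)), 0.01)
  fit_d <- deconvolute_sample(y, sig, deconv_config("detrem"),
                              quotient = unit_quotient(sig))
  expect_lt(max(abs(fit_d$proportions - p_star)), 0.01)
})

test_that("detrem with unit quotients is bit-identical to music", {
  spec <- synthetic_reference_spec(n_genes = 300, cells_per_type = 40)
  sig <- build_signature(make_reference(spec, seed = 12))
  sim <- simulate_bulk(sig, synthetic_ranges(spec), n_samples = 6,
                       depth_range = c(5e4, 5e4), seed = 13)
  music <- deconvolute(sim, sig, deconv_config("music"))
  detrem <- deconvolute(sim, sig, deconv_config("detrem"),
                        quotient = unit_quotient(sig))
  expect_identical(music$proportions, detrem$proportions)
  expect_identical(music$weights, detrem$weights)
})

test_that("per-sample estimates match an independent re-implementation", {
  spec <- synthetic_reference_spec(n_genes = 300, cells_per_type = 40)
  sig <- build_signature(make_reference(spec, seed = 14))
  sim <- simulate_bulk(sig, synthetic_ranges(spec), n_samples = 20,
                       depth_range = c(5e4, 5e4), seed = 15)
  fit <- deconvolute(sim, sig, deconv_config("music"))
  P <- detrem:::proportions_to_matrix(fit$proportions)
  genes <- fit$gene_ids
  for (j in seq_len(ncol(sim$counts))) {
    oracle <- oracle_wnnls_music(sim$counts[genes, j],
                                 sig$theta[, genes], sig$sigma[, genes],
                                 sig$cell_size)
    expect_equal(unname(P[j, names(oracle)]), unname(oracle), tolerance = 1e-10)
  }
  # and recovery is tight on unbiased data
  rep <- evaluate_deconvolution(fit, sim$true_proportions)
  expect_true(all(rep$ccc > 0.9))
})

test_that("proportion rows are nonnegative and sum to one", {
  spec <- synthetic_reference_spec(n_genes = 300, cells_per_type = 40)
  sig <- build_signature(make_reference(spec, seed = 16))
  sim <- simulate_bulk(sig, synthetic_ranges(spec), n_samples = 10,
                       depth_range = c(5e4, 5e4), seed = 17)
  for (cfg in list(deconv_config("music"),
                   deconv_config("music", center = TRUE),
                   deconv_config("music", normalize = TRUE),
                   deconv_config("music", center = TRUE, normalize = TRUE))) {
    P <- detrem:::proportions_to_matrix(deconvolute(sim, sig, cfg)$proportions)
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  }
})

test_that("single-sample dataset equals the standalone sample path", {
  spec <- synthetic_reference_spec(n_genes = 200, cells_per_type = 30)
  sig <- build_signature(make_reference(spec, seed = 18))
  sim <- simulate_bulk(sig, synthetic_ranges(spec), n_samples = 1,
                       depth_range = c(5e4, 5e4), seed = 19)
  whole <- deconvolute(sim, sig)
  single <- deconvolute_sample(sim$counts[, 1], sig)
  expect_equal(unname(unlist(whole$proportions[1, -1])),
               unname(single$proportions))
})

test_that("permuting samples permutes result rows only", {
  spec <- synthetic_reference_spec(n_genes = 200, cells_per_type = 30)
  sig <- build_signature(make_reference(spec, seed = 20))
  sim <- simulate_bulk(sig, synthetic_ranges(spec), n_samples = 5,
                       depth_range = c(5e4, 5e4), seed = 21)
  res <- deconvolute(sim$counts, sig)
  perm <- c(3, 1, 5, 2, 4)
  res_p <- deconvolute(sim$counts[, perm], sig)
  reordered <- res$proportions[match(res_p$proportions$sample,
                                     res$proportions$sample), ]
  expect_equal(res_p$proportions, reordered, ignore_attr = TRUE)
})

test_that("failures carry the offending sample id", {
  spec <- synthetic_reference_spec(n_genes = 100, cells_per_type = 20, markers_per_type = 10)
  sig <- build_signature(make_reference(spec, seed = 22))
  bulk <- matrix(5, length(sig$gene_ids), 2,
                 dimnames = list(sig$gene_ids, c("ok", "broken")))
  bulk[, "broken"] <- 0
  expect_error(deconvolute(bulk, sig), "broken")
  expect_error(deconvolute(bulk[, "ok", drop = FALSE], sig,
                           deconv_config("detrem")), "quotient|reference")
})

test_that("detrem drops quotient-undefined genes with a message", {
  spec <- synthetic_reference_spec(n_genes = 100, cells_per_type = 20, markers_per_type = 10)
  sig <- build_signature(make_reference(spec, seed = 23))
  sim <- simulate_bulk(sig, synthetic_ranges(spec), 2,
                       depth_range = c(2e4, 2e4), seed = 24)
  q <- unit_quotient(sig)
  q[1:10] <- NA
  expect_message(res <- deconvolute(sim, sig, deconv_config("detrem"), quotient = q),
                 "10 gene")
  expect_false(any(names(q)[1:10] %in% res$gene_ids))
})

test_that("tidiers and plots expose the fitted object", {
  spec <- synthetic_reference_spec(n_genes = 150, cells_per_type = 20)
  sig <- build_signature(make_reference(spec, seed = 25))
  sim <- simulate_bulk(sig, synthetic_ranges(spec), 4,
                       depth_range = c(2e4, 2e4), seed = 26)
  fit <- deconvolute(sim, sig)
  td <- tidy(fit)
  expect_named(td, c("sample", "cell_type", "proportion"))
  expect_equal(nrow(td), 4 * length(sig$type_labels))
  gl <- glance(fit)
  expect_equal(gl$n_samples, 4L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_concordance(fit, sim$true_proportions), "ggplot")
})
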