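test_that("feature mask replaces exactly round(p*n) rows bitwise", {
  set.seed(8)
  n <- 10; d1 <- 4
  Hg <- matrix(rnorm(n * d1), n)
  Hm <- matrix(rnorm(n * d1), n)
  for (p in c(0, 0.1, 0.25, 0.3, 0.5, 1)) {
    plan <- make_mask_plan(n, p, seed = 1)
    expect_length(plan$masked_indices, round(p * n))
    out <- apply_feature_mask(Hg, Hm, plan)
    idx <- plan$masked_indices
    expect_identical(out[idx, , drop = FALSE], Hm[idx, , drop = FALSE])
    keep <- setdiff(seq_len(n), idx)
    expect_identical(out[keep, , drop = FALSE], Hg[keep, , drop = FALSE])
  }
  expect_identical(apply_feature_mask(Hg, Hm, make_mask_plan(n, 0)), Hg)
  expect_identical(apply_feature_mask(Hg, Hm, make_mask_plan(n, 1)), Hm)
})

test_that("shared encoder is the propagation-operator matrix product and is pure", {
  fx <- small_model_fixture()
  H <- matrix(rnorm(fx$n * fx$cfg$d1), fx$n)
  W1 <- matrix(rnorm(fx$cfg$d1 * fx$cfg$d2), fx$cfg$d1)
  W2 <- matrix(rnorm(fx$cfg$d2^2), fx$cfg$d2)
  Z1 <- shared_encode(H, fx$graph, W1, W2)
  ## matrix-product oracle computed directly from the operator
  S <- as.matrix(fx$graph$norm_operator)
  Z1_oracle <- S %*% pmax(S %*% H %*% W1, 0) %*% W2
  expect_equal(Z1, Z1_oracle, tolerance = 1e-12)
  ## zero weights annihilate any input; repeated calls agree exactly
  expect_true(all(shared_encode(H, fx$graph, W1 * 0, W2) == 0))
  expect_identical(Z1, shared_encode(H, fx$graph, W1, W2))
  expect_error(shared_encode(H[, -1], fx$graph, W1, W2), "columns")
})

test_that("fusion concatenates gene-first and supports injected-weight contracts", {
  fx <- small_model_fixture()
  d3 <- fx$cfg$d3; d4 <- fx$cfg$d4
  Zg <- matrix(rnorm(fx$n * d3), fx$n)
  Zm <- matrix(rnorm(fx$n * d4), fx$n)
  p0 <- fx$params
  p0$Wf <- matrix(0, d3 + d4, d3); p0$bf <- numeric(d3)
  expect_true(all(fuse_embeddings(Zg, Zm, p0) == 0))
  ## identity slice selecting the first d3 columns returns Zg exactly
  p0$Wf <- rbind(diag(d3), matrix(0, d4, d3))
  expect_equal(fuse_embeddings(Zg, Zm, p0), Zg, tolerance = 1e-15)
  expect_equal(dim(fuse_embeddings(Zg, Zm, fx$params)), c(fx$n, d3))
})

test_that("reconstruction losses match elementwise brute-force sums", {
  set.seed(12)
  n <- 5; g <- 3; d3 <- 4
  Xg <- matrix(rnorm(n * g), n)
  Z <- matrix(rnorm(n * d3), n)
  params <- list(Wd = matrix(rnorm(d3 * g), d3), bd = rnorm(g))
  R <- Z %*% params$Wd + matrix(params$bd, n, g, byrow = TRUE)
  ## brute force: explicit double loop over spots and genes
  brute <- 0
  for (i in 1:n) for (j in 1:g) brute <- brute + (Xg[i, j] - R[i, j])^2
  expect_equal(loss_fusion(Xg, Z, params), brute, tolerance = 1e-10)

  ## zero target: loss is the sum of squared reconstructions
  expect_equal(loss_fusion(Xg * 0, Z, params), sum(R^2), tolerance = 1e-10)

  ## exact reconstruction gives zero loss
  exact <- list(Wd = diag(1, d3, g), bd = numeric(g))
  X_exact <- Z %*% exact$Wd
  expect_equal(loss_fusion(X_exact, Z, exact), 0)

  ## masked variant: restricted to the masked rows only
  plan <- list(masked_indices = c(2L, 4L))
  brute_m <- 0
  for (i in plan$masked_indices) {
    for (j in 1:g) brute_m <- brute_m + (Xg[i, j] - R[i, j])^2
  }
  expect_equal(loss_gene_mask(Xg, Z, params, plan), brute_m,
               tolerance = 1e-10)
  expect_identical(loss_gene_mask(Xg, Z, params,
                                  list(masked_indices = integer(0))), 0)
  full_plan <- list(masked_indices = 1:n)
  expect_equal(loss_gene_mask(X_exact, Z, exact, full_plan), 0)
})

test_that("contrastive loss reproduces hand-computed binary cross-entropy", {
  ## chance-level discriminator scores give log(2)
  expect_equal(loss_contrastive(rep(0.5, 4), rep(0.5, 4)), log(2),
               tolerance = 1e-12)
  ## near-perfect discrimination drives the loss toward zero
  expect_lt(loss_contrastive(rep(1 - 1e-9, 4), rep(1e-9, 4)), 1e-6)
  ## injected scores vs scalar arithmetic
  pos <- c(0.9, 0.8, 0.7); neg <- c(0.2, 0.1, 0.3)
  by_hand <- -(sum(log(pos)) + sum(log(1 - neg))) / (2 * 3)
  expect_equal(loss_contrastive(pos, neg), by_hand, tolerance = 1e-12)
  ## clamping keeps the loss finite at the boundary
  expect_true(is.finite(loss_contrastive(c(0, 1), c(0, 1))))
})

test_that("total objective is the alpha-weighted sum with default alpha 10", {
  expect_equal(total_loss(1, 2, 3, alpha = 10), 15)
  expect_equal(total_loss(1, 2, 3, alpha = 0), 5)
  expect_equal(formals(total_loss)$alpha, 10)
  expect_equal(mml_config()$alpha, 10)
})

test_that("analytic gradients match finite differences", {
  fx <- small_model_fixture()
  Xg <- fx$ds$expr; Xm <- fx$ds$image_feats
  plan <- make_mask_plan(fx$n, fx$cfg$mask_fraction, seed = 2)
  perm <- with(list(), {set.seed(3); sample.int(fx$n)})
  fw <- spotfuse:::forward_mml(fx$params, Xg, Xm, fx$graph, plan, perm,
                               fx$cfg)
  gr <- spotfuse:::backward_mml(fx$params, fw, Xg, Xm, fx$graph, fx$cfg)
  num_grad <- function(nm, i, h = 1e-6) {
    f <- function(delta) {
      p2 <- fx$params
      p2[[nm]][i] <- p2[[nm]][i] + delta
      spotfuse:::forward_mml(p2, Xg, Xm, fx$graph, plan, perm,
                             fx$cfg)$losses[["l_total"]]
    }
    (f(h) - f(-h)) / (2 * h)
  }
  for (nm in c("Wd", "Wf", "Wgb", "W1", "Wp", "Wg0", "Wm0", "Wdisc", "bd")) {
    for (i in unique(c(1L, length(fx$params[[nm]])))) {
      a <- unname(gr[[nm]][i])
      fd <- num_grad(nm, i)
      expect_equal(a, fd, tolerance = 1e-4,
                   label = sprintf("analytic d/d%s[%d]", nm, i))
    }
  }
})

test_that("p = 0 and p = 1 reduce the gene input to pure-gene and pure-image passes", {
  fx <- small_model_fixture()
  cfg0 <- fx$cfg; cfg0$mask_fraction <- 0
  cfg1 <- fx$cfg; cfg1$mask_fraction <- 1
  perm <- seq_len(fx$n)
  fw0 <- spotfuse:::forward_mml(fx$params, fx$ds$expr, fx$ds$image_feats,
                                fx$graph, make_mask_plan(fx$n, 0), perm, cfg0)
  expect_identical(fw0$Hgp, fw0$Hg)
  fw1 <- spotfuse:::forward_mml(fx$params, fx$ds$expr, fx$ds$image_feats,
                                fx$graph, make_mask_plan(fx$n, 1), perm, cfg1)
  expect_identical(fw1$Hgp, fw1$Hm)
})

test_that("perturbing shared encoder weights moves both modality encodings", {
  fx <- small_model_fixture()
  plan <- make_mask_plan(fx$n, 0.3, seed = 2)
  perm <- seq_len(fx$n)
  fw <- spotfuse:::forward_mml(fx$params, fx$ds$expr, fx$ds$image_feats,
                               fx$graph, plan, perm, fx$cfg)
  p2 <- fx$params
  p2$W1 <- p2$W1 + 0.05
  fw2 <- spotfuse:::forward_mml(p2, fx$ds$expr, fx$ds$image_feats,
                                fx$graph, plan, perm, fx$cfg)
  expect_gt(max(abs(fw2$eg$Z1 - fw$eg$Z1)), 0)
  expect_gt(max(abs(fw2$em$Z1 - fw$em$Z1)), 0)
})

test_that("training is reproducible, records finite non-negative losses, and supports epochs = 0", {
  sim <- tiny_sim(seed = 6, n_rows = 6, n_cols = 8, n_markers = 3,
                  n_background = 14)
  ds <- sim$processed
  graph <- build_knn_graph(ds$coords, k = 4)
  cfg <- mml_config(d1 = 16, d2 = 8, d3 = 8, d4 = 8, epochs = 15, seed = 42)
  fit1 <- train_mml(ds, graph, cfg)
  fit2 <- train_mml(ds, graph, cfg)
  expect_identical(fit1$loss_trace, fit2$loss_trace)
  expect_identical(fit1$Zfusion, fit2$Zfusion)
  expect_true(all(is.finite(as.matrix(fit1$loss_trace[-1]))))
  expect_true(all(as.matrix(fit1$loss_trace[-1]) >= 0))
  ## total dominates the fusion component when all weights are non-negative
  expect_true(all(fit1$loss_trace$l_total >= fit1$loss_trace$l_fusion))

  fit0 <- train_mml(ds, graph, mml_config(d1 = 16, d2 = 8, d3 = 8, d4 = 8,
                                          epochs = 0, seed = 42))
  expect_equal(nrow(fit0$loss_trace), 0)
  expect_equal(dim(fit0$Zfusion), c(nrow(ds$expr), 8))
  expect_true(all(is.finite(fit0$Zfusion)))

  ## missing image features are a hard error, not a silent fallback
  ds_noimg <- ds; ds_noimg$image_feats <- NULL
  expect_error(train_mml(ds_noimg, graph, cfg), "image features")
})

test_that("contrastive training separates real from corrupted pairs", {
  sim <- tiny_sim(seed = 14, n_rows = 8, n_cols = 10, n_markers = 4,
                  n_background = 20)
  ds <- sim$processed
  graph <- build_knn_graph(ds$coords, k = 6)
  fit <- train_mml(ds, graph,
                   mml_config(d1 = 24, d2 = 12, d3 = 12, d4 = 12,
                              epochs = 80, seed = 5))
  expect_gt(mean(fit$final_scores$pos), mean(fit$final_scores$neg))
})
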