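## A deterministic 3-domain strip layout used across the screens:
## domain 0 (left), 1 (middle), 2 (right) on a unit grid.
strip_fixture <- function(n_rows = 10, n_cols = 15, seed = 31,
                          marker_effect = 4) {
  sim <- generate_synthetic(synthetic_spec(
    n_rows = n_rows, n_cols = n_cols, K = 3, n_markers_per_domain = 4,
    n_background_genes = 18, marker_effect = marker_effect, seed = seed))
  sim$labels <- as.integer(sim$dataset$labels)
  sim$ds <- preprocess(sim$dataset, n_hvg = ncol(sim$dataset$expr))
  sim
}

test_that("radius calibration hits the requested mean neighbor count", {
  coords <- as.matrix(expand.grid(x = 1:20, y = 1:10))
  labels <- ifelse(coords[, "x"] <= 10, 0L, 1L)
  r <- calibrate_radius(coords, labels, target_domain = 0L,
                        target_mean_neighbors = 10)
  ## brute-force count at the returned radius
  ct <- coords[labels == 0, ]; co <- coords[labels == 1, ]
  counts <- apply(ct, 1, function(p) {
    sum(sqrt((co[, 1] - p[1])^2 + (co[, 2] - p[2])^2) <= r)
  })
  expect_gte(mean(counts), 9)
  expect_lte(mean(counts), 11)

  ## scale equivariance: doubling coordinates doubles the radius
  r2 <- calibrate_radius(coords * 2, labels, 0L, 10)
  expect_equal(r2, 2 * r, tolerance = 1e-12)

  ## saturation: more neighbors requested than exist
  few <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_warning(
    rs <- calibrate_radius(few, c(0, 0, 1), 0L, target_mean_neighbors = 10),
    "max radius")
  expect_equal(rs, max(sqrt(c(4, 1))))
})

test_that("neighborhood construction applies the strict 50% membership rule", {
  ## 3 domains on a line; brute-force distance check for domain membership
  coords <- cbind(c(1:4, 6:9, 20:23), 0)
  labels <- rep(0:2, each = 4)
  nb <- build_neighborhood(coords, labels, target_domain = 0L, radius = 3)
  ## spots at x=6 (dist 2) and x=7 (dist 3) are within radius of x=4:
  ## 2/4 of domain 1 is exactly 50% -> NOT neighboring (strict rule)
  expect_equal(sort(nb$neighbor_set), which(coords[, 1] %in% c(6, 7)))
  expect_false(1L %in% nb$neighboring_domains)
  ## one step further captures 3/4 of domain 1 -> neighboring
  nb2 <- build_neighborhood(coords, labels, 0L, radius = 4)
  expect_true(1L %in% nb2$neighboring_domains)
  expect_equal(nb2$non_neighboring_domains, 2L)
  ## target spots never enter the neighbor set; partition covers all domains
  expect_false(any(labels[nb2$neighbor_set] == 0L))
  expect_setequal(c(0L, nb2$neighboring_domains, nb2$non_neighboring_domains),
                  0:2)
  ## no domain within reach -> warning and empty neighboring set
  expect_warning(build_neighborhood(coords, labels, 2L, radius = 1),
                 "fall back")
})

test_that("fine-grained fold changes match a two-loop brute force and scale invariantly", {
  fx <- strip_fixture()
  nb <- build_neighborhood(fx$ds$coords, fx$labels, 1L,
                           calibrate_radius(fx$ds$coords, fx$labels, 1L))
  fine <- fine_grained_screen(fx$ds$expr_linear, fx$labels, 1L, nb)
  ## brute force over spots and genes
  E <- fx$ds$expr_linear
  cmp_idx <- which(fx$labels %in% nb$neighboring_domains)
  for (j in seq_len(ncol(E))) {
    mt <- mean(E[fx$labels == 1L, j])
    mn <- mean(E[cmp_idx, j])
    expect_equal(unname(fine$fold_change[j]), mt / (mn + 1e-9),
                 tolerance = 1e-12)
  }
  ## global positive rescaling leaves fold changes (essentially) unchanged
  fine10 <- fine_grained_screen(E * 10, fx$labels, 1L, nb)
  expect_equal(fine10$fold_change, fine$fold_change, tolerance = 1e-6)
  ## identical expression in both regions -> fold change 1, not selected
  Eflat <- matrix(2, nrow(E), 3,
                  dimnames = list(NULL, c("f1", "f2", "f3")))
  flat <- fine_grained_screen(Eflat, fx$labels, 1L, nb)
  expect_equal(unname(flat$fold_change), rep(1, 3), tolerance = 1e-6)
  expect_length(flat$genes, 0)
  ## explicit arithmetic case: 3.0 vs 1.0 -> fold change 3, selected
  Ehi <- Eflat
  Ehi[fx$labels == 1L, 1] <- 3; Ehi[fx$labels != 1L, 1] <- 1
  hi <- fine_grained_screen(Ehi, fx$labels, 1L, nb)
  expect_equal(unname(hi$fold_change[1]), 3, tolerance = 1e-6)
  expect_true("f1" %in% hi$genes)
  ## raising the threshold never grows the selected set
  stricter <- fine_grained_screen(E, fx$labels, 1L, nb, fc_threshold = 2.5)
  expect_true(all(stricter$genes %in% fine$genes))
})

test_that("coarse-grained screen selects separated genes and respects the FDR cutoff", {
  fx <- strip_fixture()
  coarse <- coarse_grained_screen(fx$ds$expr_linear, fx$labels, 1L)
  ## planted markers of domain 1 should clear the screen
  markers1 <- fx$truth_svgs[["1"]]
  expect_true(all(markers1 %in% coarse$genes))
  ## a gene expressed only in the target is always selected
  E2 <- fx$ds$expr_linear
  E2[, 1] <- ifelse(fx$labels == 1L, 5, 0)
  c2 <- coarse_grained_screen(E2, fx$labels, 1L)
  expect_true(colnames(E2)[1] %in% c2$genes)
  ## a constant gene gets padj 1 by convention
  E2[, 2] <- 3
  c3 <- coarse_grained_screen(E2, fx$labels, 1L)
  expect_equal(unname(c3$padj[2]), 1)
  ## lowering alpha shrinks the set (monotonicity)
  strict <- coarse_grained_screen(fx$ds$expr_linear, fx$labels, 1L,
                                  alpha_fdr = 0.001)
  expect_true(all(strict$genes %in% coarse$genes))
  expect_error(coarse_grained_screen(E2, rep(1L, length(fx$labels)), 1L),
               "at least 2")
})

test_that("constraint screen enforces the strictly-greater mean rule", {
  fx <- strip_fixture()
  nb <- build_neighborhood(fx$ds$coords, fx$labels, 0L,
                           calibrate_radius(fx$ds$coords, fx$labels, 0L))
  expect_equal(nb$non_neighboring_domains, 2L)
  E <- fx$ds$expr_linear
  res <- constraint_screen(E, fx$labels, 0L, nb)
  ## brute-force mean comparison against the non-neighboring domain
  for (j in seq_len(ncol(E))) {
    mt <- mean(E[fx$labels == 0L, j])
    mc <- mean(E[fx$labels == 2L, j])
    expect_identical(colnames(E)[j] %in% res$genes, mt > mc)
  }
  ## exact equality is NOT adopted
  Eeq <- matrix(1, nrow(E), 2, dimnames = list(NULL, c("e1", "e2")))
  req <- constraint_screen(Eeq, fx$labels, 0L, nb)
  expect_length(req$genes, 0)
  ## uniformly higher target passes everything
  Ehi <- Eeq; Ehi[fx$labels == 0L, ] <- 2
  expect_setequal(constraint_screen(Ehi, fx$labels, 0L, nb)$genes,
                  c("e1", "e2"))
})

test_that("final SVG sets are the exact three-way intersection and recover planted markers", {
  fx <- strip_fixture()
  report <- detect_svgs(fx$ds, fx$labels)
  for (d in names(report$domains)) {
    pd <- report$domains[[d]]
    expect_setequal(pd$final_set,
                    intersect(intersect(pd$fine_set, pd$coarse_set),
                              pd$constraint_set))
    expect_true(all(pd$final_set %in% pd$fine_set))
    expect_true(all(pd$final_set %in% pd$coarse_set))
    expect_true(all(pd$final_set %in% pd$constraint_set))
    ## planted markers of this domain are all recovered
    expect_true(all(fx$truth_svgs[[d]] %in% pd$final_set))
  }
  ## single-domain assignment cannot define neighbors
  expect_error(detect_svgs(fx$ds, rep(0L, length(fx$labels))),
               "at least 2 domains")
  ## set algebra on injected screen outputs
  expect_equal(intersect(intersect(c("a", "b", "c"), c("b", "c", "d")),
                         c("c", "d")), "c")
})

test_that("Moran's I matches brute force and behaves at its known reference points", {
  ## path graph: smooth gradient is strongly autocorrelated
  n <- 100
  coords <- cbind(seq_len(n), 0)
  g <- build_knn_graph(coords, k = 2)
  grad <- seq_len(n) / n
  expect_gt(morans_i(grad, g), 0.9)
  ## random permutation sits near the null expectation -1/(n-1)
  set.seed(2)
  perms <- replicate(30, morans_i(sample(grad), g))
  expect_equal(mean(perms), -1 / (n - 1), tolerance = 0.05)
  ## checkerboard alternation is anti-correlated
  expect_lt(morans_i(rep(c(1, -1), n / 2), g), 0)
  ## brute-force oracle on a small irregular graph
  set.seed(6)
  coords6 <- matrix(runif(16), 8, 2)
  g6 <- build_knn_graph(coords6, k = 3)
  x <- rnorm(8)
  W <- as.matrix(g6$context_operator)
  expect_equal(morans_i(x, g6), brute_morans_i(x, W), tolerance = 1e-10)
  ## constant vector: zero with a warning
  expect_warning(mi0 <- morans_i(rep(2, 8), g6), "constant")
  expect_identical(mi0, 0)
})
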