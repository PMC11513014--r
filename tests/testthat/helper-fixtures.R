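## Shared fixtures: everything is generated in code at test time.

## Small labeled multi-modal dataset, already preprocessed.
tiny_sim <- function(seed = 3, n_rows = 10, n_cols = 12, K = 3,
                     n_markers = 5, n_background = 45, ...) {
  sim <- generate_synthetic(synthetic_spec(
    n_rows = n_rows, n_cols = n_cols, K = K,
    n_markers_per_domain = n_markers, n_background_genes = n_background,
    seed = seed, ...))
  sim$processed <- preprocess(sim$dataset,
                              n_hvg = ncol(sim$dataset$expr))
  sim
}

## Hand-written 3-spot x 2-gene tabular fixture on disk.
write_tiny_tabular <- function(dir, extra_coord_barcode = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, "expr.csv")
  coords_path <- file.path(dir, "coords.csv")
  writeLines(c("spot,geneA,geneB", "s1,1,0", "s2,2,3", "s3,0,5"), expr_path)
  ids <- c("s1", "s2", "s3", extra_coord_barcode)
  coords <- data.frame(spot_id = ids, x = seq_along(ids), y = 0)
  write.csv(coords, coords_path, row.names = FALSE, quote = FALSE)
  list(expr = expr_path, coords = coords_path)
}

## Deterministic small model setup for forward/backward tests.
small_model_fixture <- function(seed = 7, n_rows = 2, n_cols = 5,
                                cfg = mml_config(d1 = 6, d2 = 5, d3 = 4,
                                                 d4 = 3, mask_fraction = 0.3,
                                                 seed = 5)) {
  sim <- generate_synthetic(synthetic_spec(
    n_rows = n_rows, n_cols = n_cols, K = 2, n_markers_per_domain = 2,
    n_background_genes = 3, image_dim = 5, seed = seed))
  ds <- preprocess(sim$dataset, n_hvg = 7)
  graph <- build_knn_graph(ds$coords, k = 3)
  params <- init_mml_params(ncol(ds$expr), ncol(ds$image_feats), cfg)
  list(ds = ds, graph = graph, params = params, cfg = cfg,
       n = nrow(ds$expr))
}

## Independent Moran's I oracle: direct double loop over the weight matrix.
brute_morans_i <- function(x, W) {
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * xc[i] * xc[j]
    }
  }
  (n / sum(W)) * num / sum(xc^2)
}

## Independent ARI oracle from the contingency table.
brute_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
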