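#' Assemble a spatial dataset object
#'
#' Container for one spatial transcriptomics slice: a spot-by-gene expression
#' matrix, 2-D spot coordinates, and optionally a spot-by-feature image
#' embedding (e.g. CNN features of histology patches) and reference domain
#' labels. All components are joined to the expression matrix's row order by
#' spot ID; every matrix shares the same n_spots rows.
#'
#' @param expr numeric n_spots x n_genes matrix of non-negative expression
#'   values (counts or normalized), with spot IDs as rownames and gene names
#'   as colnames.
#' @param coords numeric n_spots x 2 matrix of planar coordinates, rownames
#'   matching `expr`.
#' @param image_feats optional numeric n_spots x m image-feature matrix.
#' @param labels optional per-spot reference domain labels (character or
#'   factor), named by spot ID or in expression row order.
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(expr, coords, image_feats = NULL, labels = NULL) {
  expr <- as.matrix(expr)
  coords <- as.matrix(coords)
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("spot_", seq_len(nrow(expr)))
  }
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("gene_", seq_len(ncol(expr)))
  }
  spot_ids <- rownames(expr)
  coords <- join_to_spots(coords, spot_ids, "coordinates")
  if (ncol(coords) != 2L) stop("coords must have exactly 2 columns")
  if (!is.null(image_feats)) {
    image_feats <- join_to_spots(as.matrix(image_feats), spot_ids,
                                 "image features")
  }
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      labels <- join_to_spots(cbind(labels), spot_ids, "labels")[, 1L]
    } else if (length(labels) != length(spot_ids)) {
      stop("labels length does not match number of spots")
    }
    labels <- as.character(labels)
    names(labels) <- spot_ids
  }
  ds <- structure(
    list(
      expr = expr,
      coords = coords,
      image_feats = image_feats,
      labels = labels,
      gene_names = colnames(expr),
      spot_ids = spot_ids,
      expr_linear = NULL,
      processed = FALSE
    ),
    class = "spatial_dataset"
  )
  validate_dataset(ds)
}

## Reorder a per-spot table to the canonical expression row order, erroring
## with the offending IDs on any mismatch.
join_to_spots <- function(x, spot_ids, what) {
  rn <- rownames(x)
  if (is.null(rn)) {
    if (nrow(x) != length(spot_ids)) {
      stop(sprintf("%s have %d rows but expression has %d spots and no IDs to join by",
                   what, nrow(x), length(spot_ids)), call. = FALSE)
    }
    rownames(x) <- spot_ids
    return(x)
  }
  missing_in_x <- setdiff(spot_ids, rn)
  extra_in_x <- setdiff(rn, spot_ids)
  if (length(missing_in_x) || length(extra_in_x)) {
    stop(sprintf(
      "spot ID mismatch joining %s: %d missing (%s), %d extra (%s)",
      what,
      length(missing_in_x), paste(head(missing_in_x, 5L), collapse = ", "),
      length(extra_in_x), paste(head(extra_in_x, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  x[spot_ids, , drop = FALSE]
}

validate_dataset <- function(ds) {
  assert_finite_matrix(ds$expr, "expression matrix")
  assert_finite_matrix(ds$coords, "coordinate matrix")
  if (any(ds$expr < 0)) {
    bad <- which(ds$expr < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("expression contains negative values (e.g. spot %s, gene %s)",
                 ds$spot_ids[bad[1L]], ds$gene_names[bad[2L]]), call. = FALSE)
  }
  if (anyDuplicated(ds$gene_names)) {
    stop("gene names are not unique: ",
         paste(head(unique(ds$gene_names[duplicated(ds$gene_names)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ds$spot_ids)) stop("spot IDs are not unique")
  if (!is.null(ds$image_feats)) {
    assert_finite_matrix(ds$image_feats, "image feature matrix")
    stopifnot(nrow(ds$image_feats) == nrow(ds$expr))
  }
  ds
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d spots x %d genes%s%s%s\n",
              nrow(x$expr), ncol(x$expr),
              if (!is.null(x$image_feats))
                sprintf(", image features (m=%d)", ncol(x$image_feats)) else "",
              if (!is.null(x$labels)) ", labeled" else "",
              if (isTRUE(x$processed)) ", preprocessed" else ""))
  invisible(x)
}

#' Read a spatial dataset from disk
#'
#' Supports three layouts: `"tabular"` (expression CSV/TSV with a header row
#' of gene names and spot IDs in the first column, plus a coordinate table
#' with columns spot_id, x, y), `"mtx"` (10x-style MatrixMarket triplet:
#' a directory with matrix.mtx, barcodes.tsv and features.tsv, genes as
#' features, plus the same coordinate table), and `"h5ad"` (a single
#' AnnData container with coordinates under `obsm["spatial"]` and image
#' features under `obsm["image_feats"]`; read through the system `python`
#' with the anndata library).
#'
#' @param expr_path expression CSV path (`tabular`), MatrixMarket directory
#'   (`mtx`), or `.h5ad` file (`h5ad`).
#' @param coords_path coordinate CSV with columns spot_id, x, y (ignored for
#'   `h5ad`).
#' @param image_path optional CSV of image features (first column spot_id).
#' @param labels_path optional CSV with columns spot_id, label.
#' @param format input layout, see Details.
#' @return A [spatial_dataset()].
#' @export
read_dataset <- function(expr_path, coords_path = NULL, image_path = NULL,
                         labels_path = NULL,
                         format = c("tabular", "mtx", "h5ad")) {
  format <- match.arg(format)
  if (format == "h5ad") {
    return(read_h5ad_dataset(expr_path))
  }
  expr <- switch(format,
    tabular = {
      if (!file.exists(expr_path)) stop("expression file not found: ", expr_path)
      sep <- if (grepl("\\.tsv$", expr_path)) "\t" else ","
      as.matrix(read.csv(expr_path, row.names = 1L, check.names = FALSE,
                         sep = sep))
    },
    mtx = read_mtx_dir(expr_path)
  )
  if (is.null(coords_path) || !file.exists(coords_path)) {
    stop("coordinate file not found: ", coords_path %||% "<missing>")
  }
  ctab <- read.csv(coords_path, check.names = FALSE)
  coords <- as.matrix(ctab[, c("x", "y")])
  rownames(coords) <- as.character(ctab$spot_id)
  image_feats <- NULL
  if (!is.null(image_path)) {
    if (!file.exists(image_path)) stop("image feature file not found: ", image_path)
    itab <- read.csv(image_path, row.names = 1L, check.names = FALSE)
    image_feats <- as.matrix(itab)
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    ltab <- read.csv(labels_path, check.names = FALSE)
    labels <- as.character(ltab$label)
    names(labels) <- as.character(ltab$spot_id)
  }
  spatial_dataset(expr, coords, image_feats = image_feats, labels = labels)
}

read_mtx_dir <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  bc <- file.path(dir, "barcodes.tsv")
  ft <- file.path(dir, "features.tsv")
  for (f in c(mtx, bc, ft)) {
    if (!file.exists(f)) stop("triplet-matrix file not found: ", f)
  }
  m <- Matrix::readMM(mtx)        # genes x spots, 10x convention
  barcodes <- readLines(bc)
  features <- read.csv(ft, sep = "\t", header = FALSE)[[1L]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop("matrix.mtx dimensions do not match barcodes/features")
  }
  expr <- t(as.matrix(m))
  dimnames(expr) <- list(barcodes, as.character(features))
  expr
}

#' Write a spatial dataset as tabular files
#'
#' Writes expression, coordinates and (when present) image features and
#' labels as CSV files that [read_dataset()] reads back bit-identically
#' (numeric values are serialized with 17 significant digits).
#'
#' @param ds a [spatial_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(expr = file.path(dir, "expression.csv"),
                coords = file.path(dir, "coords.csv"))
  write_num_csv(ds$expr, paths$expr)
  ctab <- data.frame(spot_id = ds$spot_ids,
                     x = fmt17(ds$coords[, 1L]), y = fmt17(ds$coords[, 2L]))
  write.csv(ctab, paths$coords, row.names = FALSE, quote = FALSE)
  if (!is.null(ds$image_feats)) {
    paths$image <- file.path(dir, "image_feats.csv")
    write_num_csv(ds$image_feats, paths$image)
  }
  if (!is.null(ds$labels)) {
    paths$labels <- file.path(dir, "labels.csv")
    write.csv(data.frame(spot_id = ds$spot_ids, label = ds$labels),
              paths$labels, row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

fmt17 <- function(x) sprintf("%.17g", x)

write_num_csv <- function(m, path) {
  out <- matrix(fmt17(m), nrow = nrow(m), dimnames = dimnames(m))
  write.csv(as.data.frame(out, check.names = FALSE), path, quote = FALSE)
}

## AnnData bridge: export slots with the system python, then read them back.
read_h5ad_dataset <- function(path) {
  if (!file.exists(path)) stop("h5ad file not found: ", path)
  py <- Sys.which("python")
  if (py == "") {
    stop("reading .h5ad requires a python interpreter with the anndata ",
         "library on PATH; none was found", call. = FALSE)
  }
  out <- tempfile("h5ad_export_")
  dir.create(out)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "try:",
    "    import anndata, numpy as np, pandas as pd",
    "except ImportError:",
    "    sys.exit(42)",
    "ad = anndata.read_h5ad(sys.argv[1])",
    "out = sys.argv[2]",
    "X = ad.X.toarray() if hasattr(ad.X, 'toarray') else np.asarray(ad.X)",
    "df = pd.DataFrame(X, index=ad.obs_names, columns=ad.var_names)",
    "df.to_csv(out + '/expression.csv', float_format='%.17g')",
    "sp = np.asarray(ad.obsm['spatial'])",
    "pd.DataFrame({'spot_id': ad.obs_names, 'x': sp[:,0], 'y': sp[:,1]}).to_csv(out + '/coords.csv', index=False, float_format='%.17g')",
    "if 'image_feats' in ad.obsm:",
    "    pd.DataFrame(np.asarray(ad.obsm['image_feats']), index=ad.obs_names).to_csv(out + '/image_feats.csv', float_format='%.17g')",
    "if 'label' in ad.obs.columns:",
    "    pd.DataFrame({'spot_id': ad.obs_names, 'label': ad.obs['label']}).to_csv(out + '/labels.csv', index=False)"
  ), script)
  status <- system2(py, c(script, shQuote(path), shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status == 42L) {
    stop("reading .h5ad requires the python anndata library, which is not ",
         "importable from the system python", call. = FALSE)
  }
  if (status != 0L) stop("failed to read h5ad container: ", path)
  img <- file.path(out, "image_feats.csv")
  lab <- file.path(out, "labels.csv")
  read_dataset(file.path(out, "expression.csv"), file.path(out, "coords.csv"),
               image_path = if (file.exists(img)) img else NULL,
               labels_path = if (file.exists(lab)) lab else NULL,
               format = "tabular")
}

#' Preprocess expression: normalize, log-transform, select variable genes
#'
#' Per-spot library sizes are scaled to the median library size (computed on
#' the full gene set), genes are ranked by the variance of their
#' log1p-normalized values, and the expression matrix is restricted to the
#' `n_hvg` most variable genes (ties broken by gene index; all genes are kept
#' when there are fewer than `n_hvg`). The linear-scale (normalized, pre-log)
#' matrix is retained in `$expr_linear` for fold-change computations; `$expr`
#' carries log1p values when `log1p = TRUE`.
#'
#' @param ds a [spatial_dataset()] with non-negative expression.
#' @param n_hvg number of highly variable genes to keep (default 3000).
#' @param normalize scale each spot to the median library size.
#' @param log1p apply `log(1 + x)` after normalization.
#' @return The preprocessed `spatial_dataset`.
#' @export
preprocess <- function(ds, n_hvg = 3000, normalize = TRUE, log1p = TRUE) {
  stopifnot(inherits(ds, "spatial_dataset"), n_hvg >= 1)
  if (any(ds$expr < 0)) stop("expression must be non-negative before preprocessing")
  lib <- rowSums(ds$expr)
  if (any(lib == 0)) {
    stop("cannot normalize: all-zero expression for spot(s) ",
         paste(head(ds$spot_ids[lib == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  target <- median(lib)
  norm_full <- ds$expr / lib * target
  logm <- log1p(norm_full)
  v <- apply(logm, 2L, var)
  keep <- top_k_stable(v, n_hvg)
  expr_raw <- ds$expr[, keep, drop = FALSE]
  expr_linear <- if (normalize) norm_full[, keep, drop = FALSE] else expr_raw
  expr <- if (log1p) log1p(expr_linear) else expr_linear
  ds$expr <- expr
  ds$expr_linear <- expr_linear
  ds$gene_names <- colnames(expr)
  ds$processed <- TRUE
  ds
}

#' Attach or validate image features
#'
#' Precomputed image features (e.g. CNN embeddings of histology patches, one
#' row per spot) pass through unchanged after a row-count check. An extractor
#' function may be supplied to compute features from raw patches; feature
#' extraction itself is a pluggable input, not part of the core pipeline.
#'
#' @param x precomputed n x m feature matrix, or raw input for `extractor`.
#' @param n_spots expected number of rows.
#' @param extractor optional function mapping `x` to an n x m matrix.
#' @return An n x m numeric matrix.
#' @export
embed_image_features <- function(x = NULL, n_spots = NULL, extractor = NULL) {
  if (is.null(x) && is.null(extractor)) {
    stop("no image features supplied and no extractor available; provide a ",
         "precomputed spot-by-feature matrix or an extractor function",
         call. = FALSE)
  }
  if (!is.null(extractor)) {
    if (!is.function(extractor)) {
      stop("image feature extractor requested but not available as a function",
           call. = FALSE)
    }
    x <- extractor(x)
  }
  x <- as.matrix(x)
  assert_finite_matrix(x, "image feature matrix")
  if (!is.null(n_spots) && nrow(x) != n_spots) {
    stop(sprintf("image feature matrix has %d rows but %d spots expected",
                 nrow(x), n_spots), call. = FALSE)
  }
  x
}
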