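#' Calibrate the neighborhood radius for a target domain
#'
#' Finds the radius at which the mean number of non-target spots within a
#' closed ball around each target spot is as close as possible to
#' `target_mean_neighbors` (about 10 by default). The neighbor-count curve
#' is a step function of the radius, so the search runs exactly over the
#' sorted target-to-non-target distances and returns the closest achievable
#' mean; the result scales linearly with the coordinates.
#'
#' @param coords n x 2 coordinates.
#' @param labels per-spot domain labels.
#' @param target_domain the domain to calibrate for.
#' @param target_mean_neighbors desired mean neighbor count (default 10).
#' @return Positive radius. Warns and returns the maximum distance when
#'   fewer neighbors than requested exist even at full range.
#' @export
calibrate_radius <- function(coords, labels, target_domain,
                             target_mean_neighbors = 10) {
  in_target <- labels == target_domain
  if (!any(in_target)) stop("target domain has no spots")
  if (all(in_target)) stop("no non-target spots to calibrate against")
  ct <- coords[in_target, , drop = FALSE]
  co <- coords[!in_target, , drop = FALSE]
  cross <- cross_dist(ct, co)
  n_t <- nrow(ct)
  dvals <- sort(as.vector(cross))
  ## mean neighbor count at radius dvals[k] (closed ball) is k / n_t
  means <- seq_along(dvals) / n_t
  if (max(means) < target_mean_neighbors) {
    warning(sprintf(
      "only %.2f non-target neighbors available on average; returning max radius",
      max(means)))
    return(max(dvals))
  }
  k <- which.min(abs(means - target_mean_neighbors))
  dvals[k]
}

cross_dist <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Build the neighborhood of a target domain
#'
#' The neighbor set is every non-target spot within `radius` (closed ball)
#' of at least one target spot. A non-target domain is classified as a
#' neighboring domain when strictly more than 50% of its spots fall in the
#' neighbor set; the neighboring domains aggregate into the fine-grained
#' comparison region, the remainder are the non-neighboring domains used by
#' the granularity-supplemented constraint.
#'
#' @param coords n x 2 coordinates.
#' @param labels per-spot domain labels.
#' @param target_domain target domain id.
#' @param radius neighborhood radius (see [calibrate_radius()]).
#' @return List of class `neighborhood_spec`: `target`, `radius`,
#'   `neighbor_set` (spot indices), `neighboring_domains`,
#'   `non_neighboring_domains`.
#' @export
build_neighborhood <- function(coords, labels, target_domain, radius) {
  stopifnot(radius > 0)
  in_target <- labels == target_domain
  if (!any(in_target)) stop("target domain has no spots")
  idx_other <- which(!in_target)
  cross <- cross_dist(coords[in_target, , drop = FALSE],
                      coords[idx_other, , drop = FALSE])
  within <- apply(cross <= radius, 2L, any)
  neighbor_set <- idx_other[within]
  other_domains <- setdiff(unique(labels), target_domain)
  frac_in <- vapply(other_domains, function(d) {
    members <- which(labels == d)
    mean(members %in% neighbor_set)
  }, numeric(1))
  neighboring <- other_domains[frac_in > 0.5]  # strictly more than half
  non_neighboring <- setdiff(other_domains, neighboring)
  if (length(neighboring) == 0) {
    warning(sprintf(
      "no domain has >50%% of its spots within radius %.4g of domain %s; ",
      radius, target_domain),
      "fine-grained screen will fall back to the non-target spots in the neighbor set")
  }
  structure(list(target = target_domain, radius = radius,
                 neighbor_set = neighbor_set,
                 neighboring_domains = neighboring,
                 non_neighboring_domains = non_neighboring,
                 membership_fraction = stats::setNames(frac_in,
                                                       other_domains)),
            class = "neighborhood_spec")
}

#' Fine-grained screen: fold change against neighboring domains
#'
#' Per-gene fold change between the target domain and the aggregated
#' neighboring domains, on the linear (normalized, pre-log) scale:
#' `fc = mean_target / (mean_neighbor + 1e-9)`. A gene passes when its fold
#' change strictly exceeds `fc_threshold` (1.5 by default).
#'
#' @param expr_linear n x g linear-scale expression matrix.
#' @param labels per-spot domain labels.
#' @param target target domain id.
#' @param nbhd a [build_neighborhood()] result.
#' @param fc_threshold fold-change cutoff.
#' @param eps denominator stabilizer.
#' @return List with `genes` (selected names), `fold_change`,
#'   `mean_target`, `mean_neighbor`.
#' @export
fine_grained_screen <- function(expr_linear, labels, target, nbhd,
                                fc_threshold = 1.5, eps = 1e-9) {
  idx_target <- which(labels == target)
  idx_cmp <- if (length(nbhd$neighboring_domains)) {
    which(labels %in% nbhd$neighboring_domains)
  } else {
    nbhd$neighbor_set  # fallback: non-target spots inside the radius
  }
  if (!length(idx_cmp)) stop("no comparison spots for the fine-grained screen")
  mt <- colMeans(expr_linear[idx_target, , drop = FALSE])
  mn <- colMeans(expr_linear[idx_cmp, , drop = FALSE])
  fc <- mt / (mn + eps)
  genes <- colnames(expr_linear) %||% as.character(seq_along(fc))
  list(genes = genes[fc > fc_threshold], fold_change = fc,
       mean_target = mt, mean_neighbor = mn)
}

#' Coarse-grained screen: one-vs-rest rank test
#'
#' For each gene, a one-sided Wilcoxon rank-sum test of the target domain's
#' spots against all remaining spots (alternative: target greater), with
#' Benjamini-Hochberg adjustment across genes. A gene passes when its
#' adjusted p-value is strictly below `alpha_fdr`. Genes constant across all
#' spots get an adjusted p-value of 1.
#'
#' @param expr_linear n x g linear-scale expression matrix.
#' @param labels per-spot domain labels.
#' @param target target domain id.
#' @param alpha_fdr FDR cutoff (default 0.05).
#' @return List with `genes`, `padj`, `pvalue`.
#' @export
coarse_grained_screen <- function(expr_linear, labels, target,
                                  alpha_fdr = 0.05) {
  idx_target <- which(labels == target)
  idx_rest <- which(labels != target)
  if (length(idx_target) < 2 || length(idx_rest) < 2) {
    stop("need at least 2 spots in the target domain and in the rest")
  }
  pvals <- apply(expr_linear, 2L, function(x) {
    xt <- x[idx_target]
    xr <- x[idx_rest]
    if (max(x) == min(x)) return(1)  # constant gene: no evidence
    suppressWarnings(
      wilcox.test(xt, xr, alternative = "greater", exact = FALSE)$p.value
    )
  })
  padj <- p.adjust(pvals, method = "BH")
  genes <- colnames(expr_linear) %||% as.character(seq_along(padj))
  list(genes = genes[padj < alpha_fdr], padj = padj, pvalue = pvals)
}

#' Granularity-supplemented constraint screen
#'
#' Compares the target domain's mean expression against a comparison region
#' assembled from a portion of the non-neighboring domains (all of them by
#' default, ranked by size). A gene is adopted only when its target mean is
#' strictly greater than the comparison mean. When no non-neighboring domain
#' exists the screen passes all genes with a warning.
#'
#' @param expr_linear n x g linear-scale expression matrix.
#' @param labels per-spot domain labels.
#' @param target target domain id.
#' @param nbhd a [build_neighborhood()] result.
#' @param portion fraction of non-neighboring domains (largest first) to
#'   include in the comparison region.
#' @return List with `genes`, `mean_target`, `mean_comparison`.
#' @export
constraint_screen <- function(expr_linear, labels, target, nbhd,
                              portion = 1.0) {
  stopifnot(portion > 0, portion <= 1)
  genes <- colnames(expr_linear) %||% as.character(seq_len(ncol(expr_linear)))
  mt <- colMeans(expr_linear[labels == target, , drop = FALSE])
  nn <- nbhd$non_neighboring_domains
  if (!length(nn)) {
    warning("no non-neighboring domains; constraint screen passes all genes")
    return(list(genes = genes, mean_target = mt, mean_comparison = NULL))
  }
  sizes <- vapply(nn, function(d) sum(labels == d), numeric(1))
  nn_use <- nn[order(-sizes)][seq_len(max(1L, ceiling(portion * length(nn))))]
  idx_cmp <- which(labels %in% nn_use)
  mc <- colMeans(expr_linear[idx_cmp, , drop = FALSE])
  list(genes = genes[mt > mc], mean_target = mt, mean_comparison = mc)
}

#' Detect spatially variable genes per domain
#'
#' Runs the three screens for every domain — fine-grained fold change
#' against radius-defined neighboring domains, coarse-grained one-vs-rest
#' rank test, and the granularity-supplemented mean constraint — and takes
#' their intersection as the final SVG set of each domain.
#'
#' @param ds a preprocessed [spatial_dataset()] (`$expr_linear` present).
#' @param assignment a [cluster_embedding()] result, or a vector of per-spot
#'   domain labels.
#' @param fc_threshold fine-grained fold-change cutoff (default 1.5).
#' @param alpha_fdr coarse-grained FDR cutoff (default 0.05).
#' @param portion fraction of non-neighboring domains used by the
#'   constraint screen (default all).
#' @param target_mean_neighbors radius calibration goal (default 10).
#' @return An object of class `svg_report`: `domains` (per-domain lists with
#'   `fine_set`, `coarse_set`, `constraint_set`, `final_set`, `radius`,
#'   fold changes, adjusted p-values) and a long-format `table`.
#' @export
detect_svgs <- function(ds, assignment, fc_threshold = 1.5,
                        alpha_fdr = 0.05, portion = 1.0,
                        target_mean_neighbors = 10) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.null(ds$expr_linear)) {
    stop("dataset has no linear-scale matrix; run preprocess() first")
  }
  labels <- if (inherits(assignment, "domain_assignment"))
    assignment$labels else assignment
  stopifnot(length(labels) == nrow(ds$expr_linear))
  domains <- sort(unique(labels))
  if (length(domains) < 2) {
    stop("SVG detection requires at least 2 domains (no neighboring domain ",
         "can exist for a single-domain assignment)")
  }
  expr_linear <- ds$expr_linear
  genes <- colnames(expr_linear)
  per_domain <- list()
  rows <- list()
  for (d in domains) {
    radius <- calibrate_radius(ds$coords, labels, d, target_mean_neighbors)
    nbhd <- suppressWarnings(build_neighborhood(ds$coords, labels, d, radius))
    fine <- fine_grained_screen(expr_linear, labels, d, nbhd, fc_threshold)
    coarse <- coarse_grained_screen(expr_linear, labels, d, alpha_fdr)
    constr <- constraint_screen(expr_linear, labels, d, nbhd, portion)
    final <- intersect(intersect(fine$genes, coarse$genes), constr$genes)
    per_domain[[as.character(d)]] <- list(
      radius = radius, neighborhood = nbhd,
      fine_set = fine$genes, coarse_set = coarse$genes,
      constraint_set = constr$genes, final_set = final,
      fold_change = fine$fold_change, padj = coarse$padj,
      mean_target = fine$mean_target, mean_neighbor = fine$mean_neighbor
    )
    rows[[as.character(d)]] <- data.frame(
      domain = d, gene = genes,
      mean_target = fine$mean_target,
      mean_neighbor = fine$mean_neighbor,
      fold_change = fine$fold_change,
      padj = coarse$padj,
      constraint_pass = genes %in% constr$genes,
      in_final = genes %in% final,
      row.names = NULL
    )
  }
  structure(list(domains = per_domain,
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 params = list(fc_threshold = fc_threshold,
                               alpha_fdr = alpha_fdr, portion = portion,
                               target_mean_neighbors = target_mean_neighbors)),
            class = "svg_report")
}

#' @export
print.svg_report <- function(x, ...) {
  cat(sprintf("<svg_report> %d domains\n", length(x$domains)))
  for (d in names(x$domains)) {
    pd <- x$domains[[d]]
    cat(sprintf("  domain %s: fine %d, coarse %d, constraint %d -> final %d genes\n",
                d, length(pd$fine_set), length(pd$coarse_set),
                length(pd$constraint_set), length(pd$final_set)))
  }
  invisible(x)
}

#' Write an SVG report to disk
#'
#' Long-format CSV of per-(domain, gene) statistics, plain-text per-domain
#' final gene lists, and a JSON summary of per-screen counts.
#'
#' @param report an [detect_svgs()] result.
#' @param dir output directory.
#' @export
write_svg_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$table, file.path(dir, "svg_report.csv"), row.names = FALSE)
  summary <- list()
  for (d in names(report$domains)) {
    pd <- report$domains[[d]]
    writeLines(pd$final_set, file.path(dir, sprintf("svgs_domain_%s.txt", d)))
    summary[[d]] <- list(fine = length(pd$fine_set),
                         coarse = length(pd$coarse_set),
                         constraint = length(pd$constraint_set),
                         final = length(pd$final_set))
  }
  jsonlite::write_json(summary, file.path(dir, "svg_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Moran's I spatial autocorrelation
#'
#' Moran's I of a per-spot value over the row-normalized spatial kNN
#' adjacency (the same graph used for embedding). Near 1 for smooth spatial
#' patterns, near `-1/(n-1)` under spatial randomness. A constant vector
#' returns 0 with a warning.
#'
#' @param x length-n numeric vector (e.g. one gene's expression).
#' @param graph a [build_knn_graph()] result.
#' @return Scalar Moran's I.
#' @export
morans_i <- function(x, graph) {
  stopifnot(inherits(graph, "spot_graph"), length(x) == graph$n, graph$n >= 2)
  if (var(x) == 0) {
    warning("constant vector has no spatial autocorrelation; returning 0")
    return(0)
  }
  W <- as.matrix(graph$context_operator)
  ape::Moran.I(x, W, scaled = FALSE)$observed
}
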