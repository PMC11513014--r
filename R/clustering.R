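#' Cluster the fused embedding into spatial domains
#'
#' The default method fits a Gaussian mixture with a shared full covariance
#' (mclust model "EEE") after reducing the embedding to its leading
#' principal components; k-means and Leiden graph-community detection are
#' available as alternates. Deterministic given `seed`.
#'
#' @param Z n x d embedding matrix (typically `fit$Zfusion`).
#' @param K number of domains (user-supplied, e.g. the annotated layer
#'   count).
#' @param method `"gmm"` (default), `"kmeans"` or `"leiden"`.
#' @param seed RNG seed.
#' @param pca_dims reduce to this many principal components before
#'   clustering when `ncol(Z)` exceeds it (stabilizes the mixture fit in
#'   high dimensions); set `Inf` to disable.
#' @return An object of class `domain_assignment` with integer `labels` in
#'   `[0, K)`, `K`, `method`, and the embedding reference.
#' @export
cluster_embedding <- function(Z, K, method = c("gmm", "kmeans", "leiden"),
                              seed = 0, pca_dims = 20) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  stopifnot(K >= 1, K <= n)
  assert_finite_matrix(Z, "embedding")
  if (all(apply(Z, 2L, sd) == 0)) {
    stop("embedding has zero variance in every dimension; inspect training ",
         "(loss trace, learning rate) before clustering", call. = FALSE)
  }
  if (is.finite(pca_dims) && ncol(Z) > pca_dims) {
    Z <- prcomp(Z, rank. = pca_dims)$x
  }
  labels <- if (K == 1L) {
    rep(0L, n)
  } else if (K == n) {
    seq_len(n) - 1L
  } else {
    with_seed(seed, switch(method,
      gmm = {
        mclustBIC <- mclust::mclustBIC  # Mclust resolves this in our frame
        fit <- mclust::Mclust(Z, G = K, modelNames = "EEE",
                              verbose = FALSE)
        if (is.null(fit)) {
          stop("Gaussian mixture fit failed; embedding may be degenerate")
        }
        as.integer(fit$classification) - 1L
      },
      kmeans = {
        km <- kmeans(Z, centers = K, nstart = 10, iter.max = 100)
        as.integer(km$cluster) - 1L
      },
      leiden = leiden_labels(Z, K)
    ))
  }
  ## compact label ids if a component ended up empty
  used <- sort(unique(labels))
  if (length(used) < K) {
    warning(sprintf("only %d of %d requested domains are populated",
                    length(used), K))
    labels <- match(labels, used) - 1L
    K <- length(used)
  }
  structure(list(labels = labels, K = K, method = method,
                 embedding_ref = Z),
            class = "domain_assignment")
}

## Leiden on a kNN graph of the embedding; resolution is bisected toward K
## communities (K is not always exactly achievable for community detection).
leiden_labels <- function(Z, K, knn = 15L, max_iter = 30L) {
  n <- nrow(Z)
  knn <- min(knn, n - 1L)
  D <- as.matrix(dist(Z))
  diag(D) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, order(D[i, ], seq_len(n))[seq_len(knn)])
  }))
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- igraph::simplify(gr)
  lo <- 1e-4; hi <- 5
  best <- NULL; best_gap <- Inf
  for (it in seq_len(max_iter)) {
    res <- (lo + hi) / 2
    cl <- igraph::cluster_leiden(gr, objective_function = "modularity",
                                 resolution = res)
    k_found <- length(unique(igraph::membership(cl)))
    gap <- abs(k_found - K)
    if (gap < best_gap) {
      best <- as.integer(igraph::membership(cl)) - 1L
      best_gap <- gap
    }
    if (k_found == K) break
    if (k_found < K) lo <- res else hi <- res
  }
  best
}

#' Agreement between two labelings
#'
#' Adjusted Rand index (chance-corrected pair agreement, in \[-1, 1\]) and
#' normalized mutual information (arithmetic normalization, in \[0, 1\]).
#' Both are invariant to relabeling of either argument.
#'
#' @param pred,truth equal-length label vectors.
#' @return List with `ari` and `nmi`.
#' @export
score_agreement <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  list(ari = mclust::adjustedRandIndex(pred, truth),
       nmi = nmi_score(pred, truth))
}

## NMI with arithmetic-mean normalization: I(a;b) / ((H(a)+H(b))/2).
nmi_score <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ha <- h(pi_); hb <- h(pj_)
  if (ha + hb == 0) return(1)  # both partitions trivial (and identical)
  if (ha == 0 || hb == 0) return(0)
  2 * mi / (ha + hb)
}

#' Majority-vote spatial smoothing of domain labels
#'
#' Optional refinement: each spot takes the most frequent label among its
#' graph neighbors and itself (ties keep the current label). Off by default
#' in the pipeline.
#'
#' @param assignment a [cluster_embedding()] result.
#' @param graph a [build_knn_graph()] result.
#' @param iterations number of sweeps.
#' @return The assignment with smoothed labels.
#' @export
refine_domains <- function(assignment, graph, iterations = 1) {
  labels <- assignment$labels
  for (it in seq_len(iterations)) {
    new_labels <- labels
    for (i in seq_len(graph$n)) {
      nb <- c(i, graph$neighbor_lists[[i]])
      tab <- table(labels[nb])
      top <- names(tab)[tab == max(tab)]
      if (!as.character(labels[i]) %in% top) {
        new_labels[i] <- as.integer(top[1L])
      }
    }
    labels <- new_labels
  }
  assignment$labels <- labels
  assignment
}

#' Write a domain assignment as CSV
#'
#' @param assignment a [cluster_embedding()] result.
#' @param spot_ids spot identifiers, expression row order.
#' @param path output CSV path (columns spot_id, domain).
#' @export
write_domains <- function(assignment, spot_ids, path) {
  write.csv(data.frame(spot_id = spot_ids, domain = assignment$labels),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scatter plot of domains on the slide coordinates
#'
#' @param assignment a [cluster_embedding()] result or label vector.
#' @param coords n x 2 spot coordinates.
#' @param file optional PNG path; when given the plot is written there
#'   instead of the active device.
#' @param pt_cex point size.
#' @export
plot_domains <- function(assignment, coords, file = NULL, pt_cex = 0.8) {
  labels <- if (inherits(assignment, "domain_assignment"))
    assignment$labels else assignment
  stopifnot(length(labels) == nrow(coords))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cols <- grDevices::hcl.colors(length(unique(labels)), "Dark 3")
  graphics::plot(coords[, 1], coords[, 2], col = cols[as.factor(labels)],
                 pch = 16, cex = pt_cex, asp = 1,
                 xlab = "x", ylab = "y", main = "spatial domains")
  graphics::legend("topright", legend = sort(unique(labels)),
                   col = cols[as.factor(sort(unique(labels)))], pch = 16,
                   cex = 0.8, bty = "n")
  if (!is.null(file)) invisible(file) else invisible(NULL)
}
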