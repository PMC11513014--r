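#' Specification for a synthetic spatial dataset
#'
#' Describes a Visium-like slice on a rectangular grid with K spatially
#' contiguous domains, negative-binomial counts, planted domain markers and
#' surrogate image features. Markers of domain d have their mean multiplied
#' by `marker_effect` inside d; image features are the domain's centroid
#' vector plus Gaussian noise, emulating CNN embeddings of histology patches
#' that correlate with domain identity.
#'
#' @param n_rows,n_cols grid dimensions (spots = n_rows * n_cols).
#' @param K number of domains.
#' @param layout `"layered"` (contiguous vertical bands, mirroring cortical
#'   layers) or `"voronoi"` (nearest of K random centers).
#' @param n_markers_per_domain planted marker genes per domain.
#' @param n_background_genes non-marker genes.
#' @param marker_effect multiplicative mean elevation of a marker inside its
#'   domain (1 = null dataset).
#' @param base_mean_range per-gene baseline means are drawn log-uniformly
#'   from this range.
#' @param dispersion negative-binomial dispersion (variance = mu + disp *
#'   mu^2).
#' @param image_dim surrogate image-feature dimension m.
#' @param image_noise_sd Gaussian noise sd added to the domain centroid
#'   vectors (centroids are standard normal).
#' @param seed RNG seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rows = 25, n_cols = 40, K = 4,
                           layout = c("layered", "voronoi"),
                           n_markers_per_domain = 10,
                           n_background_genes = 160,
                           marker_effect = 4.0,
                           base_mean_range = c(0.5, 2),
                           dispersion = 0.5,
                           image_dim = 16, image_noise_sd = 0.5,
                           seed = 1) {
  layout <- match.arg(layout)
  stopifnot(n_rows >= 1, n_cols >= K, K >= 1, marker_effect > 0,
            dispersion > 0, image_dim >= 1, image_noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic spatial dataset with planted markers
#'
#' Deterministic given `spec$seed`. Counts are negative binomial with
#' per-gene baseline means; each domain's markers are elevated
#' `marker_effect`-fold inside the domain. Image features are the domain
#' centroid embedding plus noise. Ground-truth domain labels and the planted
#' per-domain marker sets are returned for scoring.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (a labeled [spatial_dataset()]),
#'   `truth_svgs` (per-domain marker gene names, names are domain ids
#'   `0..K-1`), and `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_rows * spec$n_cols
    coords <- as.matrix(expand.grid(x = seq_len(spec$n_cols),
                                    y = seq_len(spec$n_rows)))[, c("x", "y")]
    domains <- switch(spec$layout,
      layered = {
        band <- ceiling(coords[, "x"] / (spec$n_cols / spec$K))
        pmin(band, spec$K) - 1L
      },
      voronoi = {
        centers <- cbind(runif(spec$K, 1, spec$n_cols),
                         runif(spec$K, 1, spec$n_rows))
        d2 <- cross_dist(coords, centers)
        max.col(-d2) - 1L
      }
    )
    g_total <- spec$K * spec$n_markers_per_domain + spec$n_background_genes
    gene_names <- sprintf("gene_%03d", seq_len(g_total))
    marker_idx <- matrix(seq_len(spec$K * spec$n_markers_per_domain),
                         nrow = spec$n_markers_per_domain)
    truth_svgs <- stats::setNames(
      lapply(seq_len(spec$K), function(k) gene_names[marker_idx[, k]]),
      as.character(seq_len(spec$K) - 1L)
    )
    base_mean <- exp(runif(g_total, log(spec$base_mean_range[1]),
                           log(spec$base_mean_range[2])))
    mu <- matrix(base_mean, n, g_total, byrow = TRUE)
    for (k in seq_len(spec$K)) {
      in_k <- domains == (k - 1L)
      mu[in_k, marker_idx[, k]] <- mu[in_k, marker_idx[, k]] *
        spec$marker_effect
    }
    counts <- matrix(
      rnbinom(n * g_total, mu = as.vector(mu), size = 1 / spec$dispersion),
      n, g_total
    )
    ## guard: normalization needs a nonzero library for every spot
    zero_lib <- rowSums(counts) == 0
    if (any(zero_lib)) counts[zero_lib, 1L] <- 1L
    dimnames(counts) <- list(sprintf("spot_%04d", seq_len(n)), gene_names)
    centroids <- matrix(rnorm(spec$K * spec$image_dim), spec$K)
    image_feats <- centroids[domains + 1L, , drop = FALSE] +
      matrix(rnorm(n * spec$image_dim, sd = spec$image_noise_sd), n)
    colnames(image_feats) <- sprintf("feat_%02d", seq_len(spec$image_dim))
    ds <- spatial_dataset(counts, coords,
                          image_feats = image_feats,
                          labels = as.character(domains))
    list(dataset = ds, truth_svgs = truth_svgs, spec = spec)
  })
}

#' Score recovery of planted marker genes
#'
#' Matches detected domains to ground-truth domains (maximum-agreement
#' assignment on the label confusion matrix; exact over all permutations for
#' K <= 8, greedy beyond) and computes set precision / recall / F1 of each
#' domain's final SVG set against its planted markers. An empty detected
#' set scores precision 0 by convention.
#'
#' @param report an [detect_svgs()] result.
#' @param truth_svgs per-domain planted gene sets (names = truth domain
#'   ids).
#' @param pred_labels,truth_labels per-spot labelings used to match report
#'   domains to truth domains; omit both when the report was computed on
#'   the ground-truth labels directly.
#' @return Data frame with one row per truth domain (`precision`, `recall`,
#'   `f1`) plus macro averages as attributes `macro_precision`,
#'   `macro_recall`, `macro_f1`.
#' @export
score_svg_recovery <- function(report, truth_svgs, pred_labels = NULL,
                               truth_labels = NULL) {
  stopifnot(inherits(report, "svg_report"))
  report_domains <- names(report$domains)
  mapping <- if (is.null(pred_labels) || is.null(truth_labels)) {
    stats::setNames(report_domains, report_domains)
  } else {
    match_domains(pred_labels, truth_labels)
  }
  rows <- lapply(names(truth_svgs), function(td) {
    truth_set <- truth_svgs[[td]]
    pd <- names(mapping)[mapping == td]
    final <- if (length(pd) && pd %in% report_domains)
      report$domains[[pd]]$final_set else character(0)
    tp <- length(intersect(final, truth_set))
    precision <- if (length(final)) tp / length(final) else 0
    recall <- if (length(truth_set)) tp / length(truth_set) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(truth_domain = td,
               report_domain = if (length(pd)) pd else NA_character_,
               n_truth = length(truth_set), n_detected = length(final),
               precision = precision, recall = recall, f1 = f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "macro_precision") <- mean(out$precision)
  attr(out, "macro_recall") <- mean(out$recall)
  attr(out, "macro_f1") <- mean(out$f1)
  out
}

## Maximum-agreement matching of predicted to truth domain ids on the
## confusion matrix: exact permutation search for small K, greedy otherwise.
## Returns a named vector: names = predicted ids, values = truth ids.
match_domains <- function(pred_labels, truth_labels) {
  stopifnot(length(pred_labels) == length(truth_labels))
  tab <- table(pred = as.character(pred_labels),
               truth = as.character(truth_labels))
  preds <- rownames(tab)
  truths <- colnames(tab)
  np <- length(preds); nt <- length(truths)
  if (np <= 8 && np == nt) {
    perms <- all_permutations(np)
    scores <- vapply(seq_len(nrow(perms)), function(r) {
      sum(tab[cbind(seq_len(np), perms[r, ])])
    }, numeric(1))
    best <- perms[which.max(scores), ]
    return(stats::setNames(truths[best], preds))
  }
  ## greedy fallback: repeatedly take the largest remaining cell
  mapping <- stats::setNames(rep(NA_character_, np), preds)
  tab_work <- tab
  for (step in seq_len(min(np, nt))) {
    cell <- which(tab_work == max(tab_work), arr.ind = TRUE)[1L, ]
    mapping[rownames(tab_work)[cell[1L]]] <- colnames(tab_work)[cell[2L]]
    tab_work <- tab_work[-cell[1L], -cell[2L], drop = FALSE]
    if (!length(tab_work)) break
  }
  mapping
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
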