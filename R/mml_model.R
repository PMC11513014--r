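#' Configuration for the multi-modal embedding model
#'
#' @param d1 shared-projection dimension (gene and image features are mapped
#'   to this common width before masking).
#' @param d2 shared graph-encoder output dimension.
#' @param d3 gene-branch / fused embedding dimension.
#' @param d4 image-branch dimension.
#' @param mask_fraction fraction p of spots whose projected gene rows are
#'   replaced by the corresponding image rows (modality-bias mitigation).
#' @param alpha weight of the masked gene-reconstruction loss in the total
#'   objective.
#' @param epochs full-graph gradient steps.
#' @param learning_rate Adam step size.
#' @param seed RNG seed controlling initialization, the mask plan and the
#'   per-epoch corruption permutations.
#' @param mask_per_epoch redraw the mask plan every epoch instead of once at
#'   the start of training.
#' @param use_mask,share_weights,use_contrastive ablation switches: disable
#'   the feature mask, untie the graph-encoder weights across modalities, or
#'   drop the contrastive term.
#' @param loss_reduction `"sum"` (summed squared residuals, the convention
#'   `alpha` is calibrated against) or `"mean"`.
#' @return A list of class `mml_config`.
#' @export
mml_config <- function(d1 = 128, d2 = 64, d3 = 64, d4 = 64,
                       mask_fraction = 0.1, alpha = 10,
                       epochs = 600, learning_rate = 1e-3, seed = 0,
                       mask_per_epoch = FALSE,
                       use_mask = TRUE, share_weights = TRUE,
                       use_contrastive = TRUE,
                       loss_reduction = c("sum", "mean")) {
  stopifnot(mask_fraction >= 0, mask_fraction <= 1, alpha >= 0,
            d1 > 0, d2 > 0, d3 > 0, d4 > 0, epochs >= 0, learning_rate > 0)
  structure(
    list(d1 = d1, d2 = d2, d3 = d3, d4 = d4,
         mask_fraction = mask_fraction, alpha = alpha, epochs = epochs,
         learning_rate = learning_rate, seed = seed,
         mask_per_epoch = mask_per_epoch, use_mask = use_mask,
         share_weights = share_weights, use_contrastive = use_contrastive,
         loss_reduction = match.arg(loss_reduction)),
    class = "mml_config"
  )
}

#' Draw a mask plan
#'
#' Samples the spot subset whose projected gene rows will be replaced by
#' image rows. Exactly `round(p * n)` distinct spots are selected.
#'
#' @param n number of spots.
#' @param p mask fraction in \[0, 1\].
#' @param seed optional seed for a temporary RNG stream.
#' @return List with `masked_indices` (sorted) and `fraction_realized`.
#' @export
make_mask_plan <- function(n, p, seed = NULL) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  n_mask <- round(p * n)
  idx <- if (n_mask == 0) integer(0) else if (is.null(seed)) {
    sort(sample.int(n, n_mask))
  } else {
    sort(with_seed(seed, sample.int(n, n_mask)))
  }
  list(masked_indices = idx, fraction_realized = n_mask / n)
}

#' Apply the feature mask
#'
#' Row i of the output equals the image row `Hm[i, ]` when spot i is in the
#' mask plan, and the gene row `Hg[i, ]` otherwise.
#'
#' @param Hg,Hm n x d1 projected gene and image embeddings.
#' @param plan a [make_mask_plan()] result.
#' @return n x d1 matrix.
#' @export
apply_feature_mask <- function(Hg, Hm, plan) {
  stopifnot(identical(dim(Hg), dim(Hm)))
  out <- Hg
  idx <- plan$masked_indices
  if (length(idx)) out[idx, ] <- Hm[idx, , drop = FALSE]
  out
}

## Glorot-uniform weight matrix.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize model parameters
#'
#' All learnable maps: modality input projections, the shared one-layer
#' projection into the common space, the two-layer shared graph encoder,
#' the gene-branch graph convolution and image-branch linear map, the fusion
#' map, the gene decoder (shared between the fused and gene-branch
#' reconstructions), and the bilinear discriminator.
#'
#' @param g,m input gene / image feature dimensions.
#' @param cfg an [mml_config()].
#' @param seed optional seed for a temporary RNG stream (defaults to
#'   `cfg$seed`).
#' @return Named list of parameter matrices/vectors, class `mml_params`.
#' @export
init_mml_params <- function(g, m, cfg, seed = cfg$seed) {
  draw <- function() {
    p <- list(
      Wg0 = glorot(g, cfg$d1), bg0 = numeric(cfg$d1),
      Wm0 = glorot(m, cfg$d1), bm0 = numeric(cfg$d1),
      Wp = glorot(cfg$d1, cfg$d1), bp = numeric(cfg$d1),
      W1 = glorot(cfg$d1, cfg$d2),
      W2 = glorot(cfg$d2, cfg$d2),
      Wgb = glorot(cfg$d2, cfg$d3),
      Wmb = glorot(cfg$d2, cfg$d4), bmb = numeric(cfg$d4),
      Wf = glorot(cfg$d3 + cfg$d4, cfg$d3), bf = numeric(cfg$d3),
      Wd = glorot(cfg$d3, g), bd = numeric(g),
      Wdisc = glorot(cfg$d3, cfg$d3)
    )
    if (!cfg$share_weights) {
      ## untied copies for the image pass (ablation); same initial values so
      ## the ablation differs only in the tying
      p$W1_img <- p$W1
      p$W2_img <- p$W2
    }
    p
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(p, class = "mml_params")
}

#' Shared graph encoder
#'
#' Two graph-convolution layers over the renormalized operator S =
#' D^{-1/2}(A + I)D^{-1/2}: `Z1 = S relu(S H W1) W2`. The same weights are
#' applied to the masked gene embedding and to the image embedding, which is
#' what couples the modalities during joint learning.
#'
#' @param H n x d1 input embedding.
#' @param graph a [build_knn_graph()] result.
#' @param W1,W2 layer weights.
#' @return When `cache = FALSE` (default), the n x d2 encoding; otherwise a
#'   list with intermediates for backpropagation.
#' @param cache return intermediates.
#' @export
shared_encode <- function(H, graph, W1, W2, cache = FALSE) {
  if (ncol(H) != nrow(W1)) {
    stop(sprintf("encoder input has %d columns but W1 expects %d",
                 ncol(H), nrow(W1)))
  }
  S <- graph$norm_operator
  SH <- as.matrix(S %*% H)
  U <- SH %*% W1
  R <- relu(U)
  SR <- as.matrix(S %*% R)
  Z1 <- SR %*% W2
  if (cache) list(SH = SH, U = U, R = R, SR = SR, Z1 = Z1) else Z1
}

#' Fuse gene and image branch embeddings
#'
#' Concatenates the gene-branch and image-branch embeddings (gene first) and
#' applies the fusion map: `Zfusion = concat(Zg, Zm) Wf + bf`.
#'
#' @param Zg n x d3 gene-branch embedding.
#' @param Zm n x d4 image-branch embedding.
#' @param params an [init_mml_params()] list (uses `Wf`, `bf`).
#' @return n x d3 fused embedding.
#' @export
fuse_embeddings <- function(Zg, Zm, params) {
  stopifnot(nrow(Zg) == nrow(Zm))
  addb(cbind(Zg, Zm) %*% params$Wf, params$bf)
}

## reduction scale factor: 1 for "sum", 1/(rows*cols) for "mean"
loss_scale <- function(reduction, n_rows, n_cols) {
  if (reduction == "mean") 1 / max(1, n_rows * n_cols) else 1
}

#' Fused-reconstruction loss
#'
#' Squared reconstruction error of the expression matrix from the fused
#' embedding through the gene decoder, summed over all spots:
#' `sum_i || Xg_i - (Zfusion Wd + bd)_i ||^2`.
#'
#' @param Xg n x g expression matrix (reconstruction target).
#' @param Zfusion n x d3 fused embedding.
#' @param params parameter list (uses decoder `Wd`, `bd`).
#' @param reduction `"sum"` or `"mean"`.
#' @return Non-negative scalar.
#' @export
loss_fusion <- function(Xg, Zfusion, params, reduction = "sum") {
  Xhat <- addb(Zfusion %*% params$Wd, params$bd)
  sum((Xg - Xhat)^2) * loss_scale(reduction, nrow(Xg), ncol(Xg))
}

#' Masked gene-reconstruction loss
#'
#' Same squared-error form as [loss_fusion()], but decoding the gene-branch
#' embedding and summing only over the masked spots — the spots whose gene
#' rows were replaced by image rows. It anchors the model so masking does not
#' lose gene-expression information.
#'
#' @param Xg n x g expression matrix.
#' @param Zg n x d3 gene-branch embedding.
#' @param params parameter list (uses decoder `Wd`, `bd`).
#' @param plan a [make_mask_plan()] result.
#' @param reduction `"sum"` or `"mean"`.
#' @return Non-negative scalar (0 when the mask is empty).
#' @export
loss_gene_mask <- function(Xg, Zg, params, plan, reduction = "sum") {
  idx <- plan$masked_indices
  if (!length(idx)) return(0)
  Xhat <- addb(Zg[idx, , drop = FALSE] %*% params$Wd, params$bd)
  sum((Xg[idx, , drop = FALSE] - Xhat)^2) *
    loss_scale(reduction, length(idx), ncol(Xg))
}

#' Bilinear discriminator
#'
#' Scores embedding/context pairs: `Phi(z, g) = sigmoid(z' Wdisc g)`,
#' evaluated row-wise.
#'
#' @param Z n x d3 embeddings.
#' @param G n x d3 local-context rows.
#' @param Wdisc d3 x d3 bilinear form.
#' @return Length-n vector in (0, 1).
#' @export
discriminator_scores <- function(Z, G, Wdisc) {
  sigmoid(rowSums((Z %*% Wdisc) * G))
}

.PHI_EPS <- 1e-7

#' Contrastive (local-context) loss
#'
#' Binary cross-entropy over positive pairs (real fused embedding, local
#' context) and negative pairs (corrupted fused embedding, same context):
#' `-(1/2n) sum_i [log Phi(Z_i, G_i) + log(1 - Phi(Z'_i, G_i))]`.
#' Discriminator outputs are clamped to `[1e-7, 1 - 1e-7]` inside the logs.
#'
#' @param pos,neg length-n discriminator scores for positive and negative
#'   pairs (see [discriminator_scores()]).
#' @return Non-negative scalar.
#' @export
loss_contrastive <- function(pos, neg) {
  stopifnot(length(pos) == length(neg))
  pos <- pmin(pmax(pos, .PHI_EPS), 1 - .PHI_EPS)
  neg <- pmin(pmax(neg, .PHI_EPS), 1 - .PHI_EPS)
  -(mean(log(pos)) + mean(log(1 - neg))) / 2
}

#' Total training objective
#'
#' `L = alpha * L_gene_mask + L_fusion + L_contrastive`.
#'
#' @param l_mask,l_fusion,l_contrastive component losses.
#' @param alpha weight on the masked reconstruction term (default 10).
#' @return Scalar total loss.
#' @export
total_loss <- function(l_mask, l_fusion, l_contrastive, alpha = 10) {
  alpha * l_mask + l_fusion + l_contrastive
}

## ---------------------------------------------------------------------------
## Forward pass. Returns every intermediate needed by the backward pass.
forward_mml <- function(params, Xg, Xm, graph, plan, perm, cfg) {
  sw <- cfg$share_weights
  W1i <- if (sw) params$W1 else params$W1_img
  W2i <- if (sw) params$W2 else params$W2_img

  A0g <- addb(Xg %*% params$Wg0, params$bg0)
  A0m <- addb(Xm %*% params$Wm0, params$bm0)
  Pg <- addb(A0g %*% params$Wp, params$bp); Hg <- relu(Pg)
  Pm <- addb(A0m %*% params$Wp, params$bp); Hm <- relu(Pm)
  Hgp <- if (cfg$use_mask) apply_feature_mask(Hg, Hm, plan) else Hg

  eg <- shared_encode(Hgp, graph, params$W1, params$W2, cache = TRUE)
  em <- shared_encode(Hm, graph, W1i, W2i, cache = TRUE)

  S <- graph$norm_operator
  Qg <- as.matrix(S %*% eg$Z1)
  Zg <- Qg %*% params$Wgb
  Zmo <- addb(em$Z1 %*% params$Wmb, params$bmb)
  Zf <- fuse_embeddings(Zg, Zmo, params)

  red <- cfg$loss_reduction
  l_fus <- loss_fusion(Xg, Zf, params, red)
  plan_eff <- if (cfg$use_mask) plan else list(masked_indices = integer(0))
  l_mask <- loss_gene_mask(Xg, Zg, params, plan_eff, red)

  cc <- NULL
  l_con <- 0
  if (cfg$use_contrastive) {
    Xgc <- Xg[perm, , drop = FALSE]
    A0gc <- addb(Xgc %*% params$Wg0, params$bg0)
    Pgc <- addb(A0gc %*% params$Wp, params$bp); Hgc <- relu(Pgc)
    egc <- shared_encode(Hgc, graph, params$W1, params$W2, cache = TRUE)
    Qgc <- as.matrix(S %*% egc$Z1)
    Zgc <- Qgc %*% params$Wgb
    Zfc <- fuse_embeddings(Zgc, Zmo, params)
    G <- local_context(Zf, graph)
    pos <- discriminator_scores(Zf, G, params$Wdisc)
    neg <- discriminator_scores(Zfc, G, params$Wdisc)
    l_con <- loss_contrastive(pos, neg)
    cc <- list(Xgc = Xgc, A0gc = A0gc, Pgc = Pgc, egc = egc, Qgc = Qgc,
               Zgc = Zgc, Zfc = Zfc, G = G, pos = pos, neg = neg)
  }

  list(A0g = A0g, A0m = A0m, Pg = Pg, Pm = Pm, Hg = Hg, Hm = Hm, Hgp = Hgp,
       eg = eg, em = em, Qg = Qg, Zg = Zg, Zmo = Zmo, Zf = Zf,
       corrupt = cc, plan = plan_eff, perm = perm,
       losses = c(l_mask = l_mask, l_fusion = l_fus, l_contrastive = l_con,
                  l_total = total_loss(l_mask, l_fus, l_con, cfg$alpha)))
}

## Backward pass: analytic gradients of the total objective w.r.t. every
## parameter. Derivation mirrors forward_mml step by step (reverse order);
## shared weights accumulate contributions from the gene, image and
## corrupted passes.
backward_mml <- function(params, fw, Xg, Xm, graph, cfg) {
  S <- graph$norm_operator
  n <- nrow(Xg); g <- ncol(Xg)
  d3 <- ncol(fw$Zg); d4 <- ncol(fw$Zmo)
  sw <- cfg$share_weights
  gr <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  gr <- lapply(gr, function(x) if (is.matrix(x)) x else as.numeric(x))

  ## fused reconstruction
  sc_f <- loss_scale(cfg$loss_reduction, n, g)
  Xhf <- addb(fw$Zf %*% params$Wd, params$bd)
  dXhf <- -2 * sc_f * (Xg - Xhf)
  gr$Wd <- t(fw$Zf) %*% dXhf
  gr$bd <- colSums(dXhf)
  dZf <- dXhf %*% t(params$Wd)

  ## masked gene reconstruction
  idx <- fw$plan$masked_indices
  dZg <- matrix(0, n, d3)
  if (length(idx)) {
    sc_m <- cfg$alpha * loss_scale(cfg$loss_reduction, length(idx), g)
    Zg_i <- fw$Zg[idx, , drop = FALSE]
    Xhg_i <- addb(Zg_i %*% params$Wd, params$bd)
    dXhg_i <- -2 * sc_m * (Xg[idx, , drop = FALSE] - Xhg_i)
    gr$Wd <- gr$Wd + t(Zg_i) %*% dXhg_i
    gr$bd <- gr$bd + colSums(dXhg_i)
    dZg[idx, ] <- dXhg_i %*% t(params$Wd)
  }

  ## contrastive term
  dZfc <- NULL
  if (cfg$use_contrastive) {
    cc <- fw$corrupt
    u <- -(1 - cc$pos) / (2 * n)   # d l_con / d score(pos)
    v <- cc$neg / (2 * n)          # d l_con / d score(neg)
    WdT <- t(params$Wdisc)
    dZf <- dZf + u * (cc$G %*% WdT)
    dZfc <- v * (cc$G %*% WdT)
    dG <- u * (fw$Zf %*% params$Wdisc) + v * (cc$Zfc %*% params$Wdisc)
    gr$Wdisc <- t(fw$Zf) %*% (u * cc$G) + t(cc$Zfc) %*% (v * cc$G)
    ## G = sigmoid(M Zf): route context gradient back into Zf
    dZf <- dZf +
      as.matrix(Matrix::t(graph$context_operator) %*%
                  (dG * cc$G * (1 - cc$G)))
  }

  ## fusion (real pass)
  C <- cbind(fw$Zg, fw$Zmo)
  gr$Wf <- t(C) %*% dZf
  gr$bf <- colSums(dZf)
  dC <- dZf %*% t(params$Wf)
  dZg <- dZg + dC[, seq_len(d3), drop = FALSE]
  dZmo <- dC[, d3 + seq_len(d4), drop = FALSE]

  dZgc <- NULL
  if (cfg$use_contrastive) {
    cc <- fw$corrupt
    Cc <- cbind(cc$Zgc, fw$Zmo)
    gr$Wf <- gr$Wf + t(Cc) %*% dZfc
    gr$bf <- gr$bf + colSums(dZfc)
    dCc <- dZfc %*% t(params$Wf)
    dZgc <- dCc[, seq_len(d3), drop = FALSE]
    dZmo <- dZmo + dCc[, d3 + seq_len(d4), drop = FALSE]
  }

  ## gene branch graph convolution: Zg = S Z1g Wgb
  gr$Wgb <- t(fw$Qg) %*% dZg
  dZ1g <- as.matrix(S %*% (dZg %*% t(params$Wgb)))
  if (!is.null(dZgc)) {
    gr$Wgb <- gr$Wgb + t(fw$corrupt$Qgc) %*% dZgc
  }

  ## image branch: Zmo = Z1m Wmb + bmb
  gr$Wmb <- t(fw$em$Z1) %*% dZmo
  gr$bmb <- colSums(dZmo)
  dZ1m <- dZmo %*% t(params$Wmb)

  ## shared encoder backward (one modality pass)
  enc_back <- function(e, dZ1, W1, W2) {
    gW2 <- t(e$SR) %*% dZ1
    dR <- as.matrix(S %*% dZ1) %*% t(W2)
    dU <- dR * (e$U > 0)
    gW1 <- t(e$SH) %*% dU
    dH <- as.matrix(S %*% (dU %*% t(W1)))
    list(gW1 = gW1, gW2 = gW2, dH = dH)
  }

  bg <- enc_back(fw$eg, dZ1g, params$W1, params$W2)
  gr$W1 <- bg$gW1; gr$W2 <- bg$gW2
  dHgp <- bg$dH

  W1i <- if (sw) params$W1 else params$W1_img
  W2i <- if (sw) params$W2 else params$W2_img
  bm <- enc_back(fw$em, dZ1m, W1i, W2i)
  if (sw) {
    gr$W1 <- gr$W1 + bm$gW1; gr$W2 <- gr$W2 + bm$gW2
  } else {
    gr$W1_img <- bm$gW1; gr$W2_img <- bm$gW2
  }
  dHm <- bm$dH

  dHgc <- NULL
  if (cfg$use_contrastive) {
    dZ1gc <- as.matrix(S %*% (dZgc %*% t(params$Wgb)))
    bc <- enc_back(fw$corrupt$egc, dZ1gc, params$W1, params$W2)
    gr$W1 <- gr$W1 + bc$gW1; gr$W2 <- gr$W2 + bc$gW2
    dHgc <- bc$dH
  }

  ## feature mask: masked rows route to Hm, the rest to Hg
  dHg <- dHgp
  if (cfg$use_mask && length(idx)) {
    dHg[idx, ] <- 0
    dHm[idx, ] <- dHm[idx, , drop = FALSE] + dHgp[idx, , drop = FALSE]
  }

  ## shared projection PG and the modality input linears
  proj_back <- function(P, A0, dH) {
    dP <- dH * (P > 0)
    list(gWp = t(A0) %*% dP, gbp = colSums(dP), dA0 = dP %*% t(params$Wp))
  }
  pg <- proj_back(fw$Pg, fw$A0g, dHg)
  pm <- proj_back(fw$Pm, fw$A0m, dHm)
  gr$Wp <- pg$gWp + pm$gWp
  gr$bp <- pg$gbp + pm$gbp
  gr$Wg0 <- t(Xg) %*% pg$dA0
  gr$bg0 <- colSums(pg$dA0)
  gr$Wm0 <- t(Xm) %*% pm$dA0
  gr$bm0 <- colSums(pm$dA0)
  if (cfg$use_contrastive) {
    pc <- proj_back(fw$corrupt$Pgc, fw$corrupt$A0gc, dHgc)
    gr$Wp <- gr$Wp + pc$gWp
    gr$bp <- gr$bp + pc$gbp
    gr$Wg0 <- gr$Wg0 + t(fw$corrupt$Xgc) %*% pc$dA0
    gr$bg0 <- gr$bg0 + colSums(pc$dA0)
  }
  gr
}

## One Adam step; state carries first/second moments and the step counter.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the multi-modal embedding model
#'
#' Full-graph gradient training of the total objective: the masked
#' gene-reconstruction loss (weight `alpha`), the fused-reconstruction loss,
#' and the local-context contrastive loss with a freshly permuted corrupted
#' view each epoch. The mask plan is drawn once at the start (set
#' `mask_per_epoch = TRUE` in the config to redraw it). Fully reproducible
#' given `cfg$seed`.
#'
#' @param ds a preprocessed [spatial_dataset()]; image features must be
#'   present (supply surrogate features through [embed_image_features()] if
#'   histology is unavailable).
#' @param graph a [build_knn_graph()] on the same spots.
#' @param cfg an [mml_config()].
#' @return An object of class `mml_fit`: `Zfusion`, `Zg`, `Zm` (final
#'   embeddings), `loss_trace` (per-epoch data frame), `params`, `plan`,
#'   `config`.
#' @export
train_mml <- function(ds, graph, cfg = mml_config()) {
  stopifnot(inherits(ds, "spatial_dataset"), inherits(graph, "spot_graph"))
  if (is.null(ds$image_feats)) {
    stop("image features are required for multi-modal training; attach a ",
         "precomputed or surrogate matrix via embed_image_features()",
         call. = FALSE)
  }
  Xg <- ds$expr
  Xm <- ds$image_feats
  n <- nrow(Xg)
  stopifnot(graph$n == n, n >= 2)

  res <- with_seed(cfg$seed, {
    params <- init_mml_params(ncol(Xg), ncol(Xm), cfg, seed = NULL)
    state <- list(
      t = 0L,
      m = lapply(params, function(p) p * 0),
      v = lapply(params, function(p) p * 0)
    )
    plan <- make_mask_plan(n, cfg$mask_fraction)
    trace <- vector("list", cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      if (cfg$mask_per_epoch) plan <- make_mask_plan(n, cfg$mask_fraction)
      perm <- sample.int(n)
      fw <- forward_mml(params, Xg, Xm, graph, plan, perm, cfg)
      if (!all(is.finite(fw$losses))) {
        stop(sprintf(
          "non-finite loss at epoch %d (mask %.4g, fusion %.4g, contrastive %.4g)",
          epoch, fw$losses[["l_mask"]], fw$losses[["l_fusion"]],
          fw$losses[["l_contrastive"]]), call. = FALSE)
      }
      trace[[epoch]] <- fw$losses
      gr <- backward_mml(params, fw, Xg, Xm, graph, cfg)
      upd <- adam_step(params, gr, state, cfg$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    perm <- sample.int(n)
    fw <- forward_mml(params, Xg, Xm, graph, plan, perm, cfg)
    list(params = params, plan = plan, fw = fw, trace = trace)
  })

  trace_df <- if (cfg$epochs > 0) {
    df <- as.data.frame(do.call(rbind, res$trace))
    df$epoch <- seq_len(nrow(df))
    df[, c("epoch", "l_mask", "l_fusion", "l_contrastive", "l_total")]
  } else {
    data.frame(epoch = integer(0), l_mask = numeric(0),
               l_fusion = numeric(0), l_contrastive = numeric(0),
               l_total = numeric(0))
  }
  fw <- res$fw
  structure(
    list(Zfusion = fw$Zf, Zg = fw$Zg, Zm = fw$Zmo,
         loss_trace = trace_df, params = res$params, plan = res$plan,
         final_scores = if (cfg$use_contrastive)
           list(pos = fw$corrupt$pos, neg = fw$corrupt$neg) else NULL,
         config = cfg),
    class = "mml_fit"
  )
}

#' @export
print.mml_fit <- function(x, ...) {
  lt <- x$loss_trace
  cat(sprintf("<mml_fit> %d spots, d3 = %d, %d epochs",
              nrow(x$Zfusion), ncol(x$Zfusion), nrow(lt)))
  if (nrow(lt) > 0) {
    cat(sprintf("; total loss %.4g -> %.4g",
                lt$l_total[1L], lt$l_total[nrow(lt)]))
  }
  cat("\n")
  invisible(x)
}

#' Export the per-epoch loss trace as CSV
#'
#' @param fit an [train_mml()] result.
#' @param path output CSV path.
#' @export
write_loss_trace <- function(fit, path) {
  write.csv(fit$loss_trace, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single serialized archive of the fitted object
#' (weights, mask plan, embeddings, loss trace) plus a human-readable JSON
#' sidecar recording the configuration.
#'
#' @param fit an [train_mml()] result.
#' @param path checkpoint file path (the sidecar is written alongside as
#'   `<path>.json`).
#' @return `write_mml_checkpoint` invisibly returns `path`;
#'   `read_mml_checkpoint` returns the restored `mml_fit`.
#' @export
write_mml_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "mml_fit"))
  saveRDS(fit, path)
  jsonlite::write_json(unclass(fit$config), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mml_checkpoint
#' @export
read_mml_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "mml_fit")) stop("not a model checkpoint: ", path)
  fit
}
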