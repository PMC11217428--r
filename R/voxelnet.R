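#' Specify the voxel-classification network
#'
#' A transformer encoder over 3D patches with a convolutional U-Net-style
#' decoder. A `32^3` sub-grid is cut into `(32/16)^3 = 8` patches of edge 16,
#' embedded into `embed_dim` dimensions with a learnable positional encoding,
#' and passed through `num_blocks` identical blocks (layer norm, multi-head
#' self-attention, layer norm, MLP). Features tapped at `tap_blocks` are
#' reshaped to a `2^3` grid and progressively upsampled (x2 transposed
#' convolutions), concatenated U-Net-style with the next-shallower tap, and
#' refined by `3^3` convolutions with instance normalization and Leaky-ReLU;
#' the original density enters through a stem convolution at full resolution.
#' A final `1^3` convolution maps `decoder_feature_size` channels to
#' `out_channels` per-voxel class logits.
#'
#' The default decoder widths (121, 80, 68, 31) together with the 768-dim,
#' 12-block encoder give exactly 92,281,604 trainable parameters for the
#' 4-class atom model and 92,281,893 for the 21-class amino-acid model.
#'
#' @param out_channels Number of output classes: 4 for backbone-atom
#'   classification (CA, C, N, none), 21 for amino-acid classification.
#' @param embed_dim Token embedding dimension (default 768).
#' @param num_blocks Number of encoder blocks (default 12).
#' @param tap_blocks Four encoder blocks whose outputs feed the decoder
#'   (default 3, 6, 9, 12).
#' @param num_heads Attention heads (default 12).
#' @param mlp_dim Hidden width of the block MLP (default `4 * embed_dim`).
#' @param decoder_widths Channel widths of the four decoder stages at
#'   resolutions 4^3, 8^3, 16^3, 32^3.
#' @param decoder_feature_size Channels of the final hidden feature map
#'   (default 16).
#' @param input_size,patch_size Input edge (32) and patch edge (16) in voxels.
#' @param dropout Dropout rate in encoder blocks during training (default 0.1).
#' @return A `network_spec` list.
#' @export
#' @examples
#' spec <- network_spec(out_channels = 4)
#' spec$num_patches
network_spec <- function(out_channels,
                         embed_dim = 768L,
                         num_blocks = 12L,
                         tap_blocks = c(3L, 6L, 9L, 12L),
                         num_heads = 12L,
                         mlp_dim = 4L * embed_dim,
                         decoder_widths = c(121L, 80L, 68L, 31L),
                         decoder_feature_size = 16L,
                         input_size = 32L,
                         patch_size = 16L,
                         dropout = 0.1) {
  if (input_size %% patch_size != 0L) {
    abort("`patch_size` must divide `input_size`.")
  }
  if (input_size != 2L * patch_size) {
    abort("this decoder topology requires input_size == 2 * patch_size (four x2 upsampling stages).")
  }
  if (embed_dim %% num_heads != 0L) abort("`num_heads` must divide `embed_dim`.")
  if (length(tap_blocks) != 4L || any(tap_blocks > num_blocks) || is.unsorted(tap_blocks)) {
    abort("`tap_blocks` must be four increasing block indices <= num_blocks.")
  }
  if (length(decoder_widths) != 4L || any(decoder_widths < 1L)) {
    abort("`decoder_widths` must be four positive channel widths.")
  }
  if (out_channels < 2L) abort("`out_channels` must be >= 2.")
  structure(list(out_channels = as.integer(out_channels),
                 embed_dim = as.integer(embed_dim),
                 num_blocks = as.integer(num_blocks),
                 tap_blocks = as.integer(tap_blocks),
                 num_heads = as.integer(num_heads),
                 mlp_dim = as.integer(mlp_dim),
                 decoder_widths = as.integer(decoder_widths),
                 decoder_feature_size = as.integer(decoder_feature_size),
                 input_size = as.integer(input_size),
                 patch_size = as.integer(patch_size),
                 num_patches = as.integer((input_size / patch_size)^3),
                 dropout = dropout),
            class = "network_spec")
}

#' Build (initialize) a voxel-classification network
#'
#' Allocates all trainable parameters of the architecture described by
#' [network_spec()]. Weights are drawn from N(0, 0.02^2), biases start at 0,
#' normalization gains at 1.
#'
#' @param spec A [network_spec()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return A `vox_network` (list of `spec` and `params`).
#' @export
build_network <- function(spec, seed = NULL) {
  if (!inherits(spec, "network_spec")) abort("`spec` must be a network_spec.")
  if (!is.null(seed)) set.seed(seed)
  K <- spec$embed_dim
  P3 <- spec$patch_size^3
  w <- function(...) array(rnorm(prod(c(...)), sd = 0.02), c(...))
  z <- function(n) numeric(n)
  blocks <- lapply(seq_len(spec$num_blocks), function(i) {
    list(ln1_g = rep(1, K), ln1_b = z(K),
         Wq = w(K, K), bq = z(K), Wk = w(K, K), bk = z(K),
         Wv = w(K, K), bv = z(K), Wo = w(K, K), bo = z(K),
         ln2_g = rep(1, K), ln2_b = z(K),
         W1 = w(K, spec$mlp_dim), b1 = z(spec$mlp_dim),
         W2 = w(spec$mlp_dim, K), b2 = z(K))
  })
  dw <- spec$decoder_widths
  a <- dw[1]; b <- dw[2]; cc <- dw[3]; d <- dw[4]
  fs <- spec$decoder_feature_size
  params <- list(
    patch_W = w(P3, K), patch_b = z(K),
    pos = w(spec$num_patches, K),
    blocks = blocks,
    upA_W = w(2, 2, 2, K, a), upA_b = z(a),
    skipA_W = w(2, 2, 2, K, a), skipA_b = z(a),
    convA_W = w(3, 3, 3, 2 * a, a), convA_b = z(a),
    inA_g = rep(1, a), inA_b = z(a),
    upB_W = w(2, 2, 2, a, b), upB_b = z(b),
    skipB1_W = w(2, 2, 2, K, b), skipB1_b = z(b),
    skipB2_W = w(2, 2, 2, b, b), skipB2_b = z(b),
    convB_W = w(3, 3, 3, 2 * b, b), convB_b = z(b),
    inB_g = rep(1, b), inB_b = z(b),
    upC_W = w(2, 2, 2, b, cc), upC_b = z(cc),
    skipC1_W = w(2, 2, 2, K, cc), skipC1_b = z(cc),
    skipC2_W = w(2, 2, 2, cc, cc), skipC2_b = z(cc),
    skipC3_W = w(2, 2, 2, cc, cc), skipC3_b = z(cc),
    convC_W = w(3, 3, 3, 2 * cc, cc), convC_b = z(cc),
    inC_g = rep(1, cc), inC_b = z(cc),
    upD_W = w(2, 2, 2, cc, d), upD_b = z(d),
    stem_W = w(3, 3, 3, 1, d), stem_b = z(d),
    inS_g = rep(1, d), inS_b = z(d),
    convD_W = w(3, 3, 3, 2 * d, fs), convD_b = z(fs),
    inD_g = rep(1, fs), inD_b = z(fs),
    head_W = w(fs, spec$out_channels), head_b = z(spec$out_channels)
  )
  structure(list(spec = spec, params = params), class = "vox_network")
}

#' Count trainable parameters of a network
#'
#' @param network A `vox_network`.
#' @return Integer-valued numeric: total number of trainable scalars.
#' @export
count_parameters <- function(network) {
  sum(unlist(rapply(network$params, length, how = "unlist")))
}

#' @export
print.vox_network <- function(x, ...) {
  cat(sprintf("<vox_network> %d output classes, %s trainable parameters\n",
              x$spec$out_channels,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

patchify <- function(x, P, g) {
  dim(x) <- c(P, g, P, g, P, g)
  y <- aperm(x, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(y) <- c(P^3, g^3)
  t(y)                                    # N x P^3, patches in grid order
}

unpatchify_grad <- function(d_tokens, P, g) {
  y <- t(d_tokens)
  dim(y) <- c(P, P, P, g, g, g)
  x <- aperm(y, c(1L, 4L, 2L, 5L, 3L, 6L))
  dim(x) <- c(P * g, P * g, P * g)
  x
}

token_to_vol <- function(z, g) array(z, c(g, g, g, ncol(z)))
vol_to_token_grad <- function(dv, g) matrix(dv, g^3, dim(dv)[4])

vnet_forward <- function(network, x, train = FALSE) {
  sp <- network$spec; p <- network$params
  P <- sp$patch_size; g <- sp$input_size / P
  C <- list()
  xv <- patchify(unclass(x), P, g)
  emb <- linear_fwd(xv, p$patch_W, p$patch_b)
  C$xv <- xv
  tok <- emb$out + p$pos
  taps <- list()
  C$blocks <- vector("list", sp$num_blocks)
  for (i in seq_len(sp$num_blocks)) {
    bp <- p$blocks[[i]]
    bc <- list()
    ln1 <- layernorm_fwd(tok, bp$ln1_g, bp$ln1_b); bc$ln1 <- ln1$cache
    at <- attention_fwd(ln1$out, bp, sp$num_heads); bc$at <- at$cache
    do1 <- dropout_fwd(at$out, sp$dropout, train); bc$do1 <- do1$cache
    tok <- tok + do1$out
    ln2 <- layernorm_fwd(tok, bp$ln2_g, bp$ln2_b); bc$ln2 <- ln2$cache
    l1 <- linear_fwd(ln2$out, bp$W1, bp$b1); bc$l1 <- l1$cache
    ge <- gelu_fwd(l1$out); bc$ge <- ge$cache
    l2 <- linear_fwd(ge$out, bp$W2, bp$b2); bc$l2 <- l2$cache
    do2 <- dropout_fwd(l2$out, sp$dropout, train); bc$do2 <- do2$cache
    tok <- tok + do2$out
    C$blocks[[i]] <- bc
    if (i %in% sp$tap_blocks) taps[[match(i, sp$tap_blocks)]] <- tok
  }
  z3 <- token_to_vol(taps[[1]], g); z6 <- token_to_vol(taps[[2]], g)
  z9 <- token_to_vol(taps[[3]], g); z12 <- token_to_vol(taps[[4]], g)

  upA <- deconv2_fwd(z12, p$upA_W, p$upA_b);   C$upA <- upA$cache
  skA <- deconv2_fwd(z9, p$skipA_W, p$skipA_b); C$skA <- skA$cache
  ccA <- concat4_fwd(upA$out, skA$out);        C$ccA <- ccA$cache
  cvA <- conv3_fwd(ccA$out, p$convA_W, p$convA_b); C$cvA <- cvA$cache
  inA <- instnorm_fwd(cvA$out, p$inA_g, p$inA_b);  C$inA <- inA$cache
  lrA <- leaky_relu_fwd(inA$out);              C$lrA <- lrA$cache

  upB <- deconv2_fwd(lrA$out, p$upB_W, p$upB_b); C$upB <- upB$cache
  sB1 <- deconv2_fwd(z6, p$skipB1_W, p$skipB1_b); C$sB1 <- sB1$cache
  sB2 <- deconv2_fwd(sB1$out, p$skipB2_W, p$skipB2_b); C$sB2 <- sB2$cache
  ccB <- concat4_fwd(upB$out, sB2$out);        C$ccB <- ccB$cache
  cvB <- conv3_fwd(ccB$out, p$convB_W, p$convB_b); C$cvB <- cvB$cache
  inB <- instnorm_fwd(cvB$out, p$inB_g, p$inB_b);  C$inB <- inB$cache
  lrB <- leaky_relu_fwd(inB$out);              C$lrB <- lrB$cache

  upC <- deconv2_fwd(lrB$out, p$upC_W, p$upC_b); C$upC <- upC$cache
  sC1 <- deconv2_fwd(z3, p$skipC1_W, p$skipC1_b); C$sC1 <- sC1$cache
  sC2 <- deconv2_fwd(sC1$out, p$skipC2_W, p$skipC2_b); C$sC2 <- sC2$cache
  sC3 <- deconv2_fwd(sC2$out, p$skipC3_W, p$skipC3_b); C$sC3 <- sC3$cache
  ccC <- concat4_fwd(upC$out, sC3$out);        C$ccC <- ccC$cache
  cvC <- conv3_fwd(ccC$out, p$convC_W, p$convC_b); C$cvC <- cvC$cache
  inC <- instnorm_fwd(cvC$out, p$inC_g, p$inC_b);  C$inC <- inC$cache
  lrC <- leaky_relu_fwd(inC$out);              C$lrC <- lrC$cache

  upD <- deconv2_fwd(lrC$out, p$upD_W, p$upD_b); C$upD <- upD$cache
  x4 <- array(unclass(x), c(dim(x), 1L))
  stm <- conv3_fwd(x4, p$stem_W, p$stem_b);    C$stm <- stm$cache
  inS <- instnorm_fwd(stm$out, p$inS_g, p$inS_b); C$inS <- inS$cache
  lrS <- leaky_relu_fwd(inS$out);              C$lrS <- lrS$cache
  ccD <- concat4_fwd(upD$out, lrS$out);        C$ccD <- ccD$cache
  cvD <- conv3_fwd(ccD$out, p$convD_W, p$convD_b); C$cvD <- cvD$cache
  inD <- instnorm_fwd(cvD$out, p$inD_g, p$inD_b);  C$inD <- inD$cache
  lrD <- leaky_relu_fwd(inD$out);              C$lrD <- lrD$cache
  hd <- conv1_fwd(lrD$out, p$head_W, p$head_b); C$hd <- hd$cache

  list(logits = hd$out, cache = C)
}

vnet_backward <- function(network, cache, dlogits) {
  sp <- network$spec; p <- network$params
  P <- sp$patch_size; g <- sp$input_size / P
  G <- list()
  hb <- conv1_bwd(dlogits, cache$hd, p$head_W)
  G$head_W <- hb$dW; G$head_b <- hb$db
  d <- leaky_relu_bwd(hb$dx, cache$lrD)
  ib <- instnorm_bwd(d, cache$inD); G$inD_g <- ib$dg; G$inD_b <- ib$db
  cb <- conv3_bwd(ib$dx, cache$cvD, p$convD_W); G$convD_W <- cb$dW; G$convD_b <- cb$db
  sp2 <- concat4_bwd(cb$dx, cache$ccD)
  dlrS <- leaky_relu_bwd(sp2$db, cache$lrS)
  ibS <- instnorm_bwd(dlrS, cache$inS); G$inS_g <- ibS$dg; G$inS_b <- ibS$db
  sb <- conv3_bwd(ibS$dx, cache$stm, p$stem_W); G$stem_W <- sb$dW; G$stem_b <- sb$db
  ub <- deconv2_bwd(sp2$da, cache$upD, p$upD_W); G$upD_W <- ub$dW; G$upD_b <- ub$db

  d <- leaky_relu_bwd(ub$dx, cache$lrC)
  ib <- instnorm_bwd(d, cache$inC); G$inC_g <- ib$dg; G$inC_b <- ib$db
  cb <- conv3_bwd(ib$dx, cache$cvC, p$convC_W); G$convC_W <- cb$dW; G$convC_b <- cb$db
  sp2 <- concat4_bwd(cb$dx, cache$ccC)
  s3 <- deconv2_bwd(sp2$db, cache$sC3, p$skipC3_W); G$skipC3_W <- s3$dW; G$skipC3_b <- s3$db
  s2 <- deconv2_bwd(s3$dx, cache$sC2, p$skipC2_W); G$skipC2_W <- s2$dW; G$skipC2_b <- s2$db
  s1 <- deconv2_bwd(s2$dx, cache$sC1, p$skipC1_W); G$skipC1_W <- s1$dW; G$skipC1_b <- s1$db
  dz3 <- s1$dx
  ub <- deconv2_bwd(sp2$da, cache$upC, p$upC_W); G$upC_W <- ub$dW; G$upC_b <- ub$db

  d <- leaky_relu_bwd(ub$dx, cache$lrB)
  ib <- instnorm_bwd(d, cache$inB); G$inB_g <- ib$dg; G$inB_b <- ib$db
  cb <- conv3_bwd(ib$dx, cache$cvB, p$convB_W); G$convB_W <- cb$dW; G$convB_b <- cb$db
  sp2 <- concat4_bwd(cb$dx, cache$ccB)
  s2 <- deconv2_bwd(sp2$db, cache$sB2, p$skipB2_W); G$skipB2_W <- s2$dW; G$skipB2_b <- s2$db
  s1 <- deconv2_bwd(s2$dx, cache$sB1, p$skipB1_W); G$skipB1_W <- s1$dW; G$skipB1_b <- s1$db
  dz6 <- s1$dx
  ub <- deconv2_bwd(sp2$da, cache$upB, p$upB_W); G$upB_W <- ub$dW; G$upB_b <- ub$db

  d <- leaky_relu_bwd(ub$dx, cache$lrA)
  ib <- instnorm_bwd(d, cache$inA); G$inA_g <- ib$dg; G$inA_b <- ib$db
  cb <- conv3_bwd(ib$dx, cache$cvA, p$convA_W); G$convA_W <- cb$dW; G$convA_b <- cb$db
  sp2 <- concat4_bwd(cb$dx, cache$ccA)
  sk <- deconv2_bwd(sp2$db, cache$skA, p$skipA_W); G$skipA_W <- sk$dW; G$skipA_b <- sk$db
  dz9 <- sk$dx
  ub <- deconv2_bwd(sp2$da, cache$upA, p$upA_W); G$upA_W <- ub$dW; G$upA_b <- ub$db
  dz12 <- ub$dx

  # gradients flowing into the token stream at each tap
  dtap <- list(vol_to_token_grad(dz3, g), vol_to_token_grad(dz6, g),
               vol_to_token_grad(dz9, g), vol_to_token_grad(dz12, g))
  dtok <- matrix(0, sp$num_patches, sp$embed_dim)
  G$blocks <- vector("list", sp$num_blocks)
  for (i in rev(seq_len(sp$num_blocks))) {
    if (i %in% sp$tap_blocks) dtok <- dtok + dtap[[match(i, sp$tap_blocks)]]
    bp <- p$blocks[[i]]; bc <- cache$blocks[[i]]
    gb <- list()
    dmlp <- dropout_bwd(dtok, bc$do2)
    l2 <- linear_bwd(dmlp, bc$l2, bp$W2); gb$W2 <- l2$dW; gb$b2 <- l2$db
    dge <- gelu_bwd(l2$dx, bc$ge)
    l1 <- linear_bwd(dge, bc$l1, bp$W1); gb$W1 <- l1$dW; gb$b1 <- l1$db
    ln2 <- layernorm_bwd(l1$dx, bc$ln2); gb$ln2_g <- ln2$dg; gb$ln2_b <- ln2$db
    dtok <- dtok + ln2$dx
    datt <- dropout_bwd(dtok, bc$do1)
    ab <- attention_bwd(datt, bc$at, bp)
    gb$Wq <- ab$grads$Wq; gb$bq <- ab$grads$bq
    gb$Wk <- ab$grads$Wk; gb$bk <- ab$grads$bk
    gb$Wv <- ab$grads$Wv; gb$bv <- ab$grads$bv
    gb$Wo <- ab$grads$Wo; gb$bo <- ab$grads$bo
    ln1 <- layernorm_bwd(ab$dx, bc$ln1); gb$ln1_g <- ln1$dg; gb$ln1_b <- ln1$db
    dtok <- dtok + ln1$dx
    G$blocks[[i]] <- gb
  }
  G$pos <- dtok
  lb <- linear_bwd(dtok, cache$xv, p$patch_W)
  G$patch_W <- lb$dW; G$patch_b <- lb$db
  G
}

# ---- loss -------------------------------------------------------------------

#' Per-class weights for imbalanced voxel classification
#'
#' Each class weight is one minus the class's share of all samples:
#' `w_c = 1 - n_c / sum_k n_k`, so the weights of C classes always sum to
#' `C - 1` and rare classes receive weights near 1.
#'
#' @param class_counts Non-negative per-class sample counts (at least one
#'   positive); names are kept if present.
#' @return A tibble with columns `class`, `count`, `weight`.
#' @export
#' @examples
#' class_weights(c(none = 90, ca = 10))
class_weights <- function(class_counts) {
  if (length(class_counts) < 1L || any(class_counts < 0) || sum(class_counts) == 0) {
    abort("`class_counts` must be non-negative with a positive total.")
  }
  tibble(class = names(class_counts) %||% as.character(seq_along(class_counts)),
         count = as.numeric(class_counts),
         weight = 1 - class_counts / sum(class_counts))
}

#' Weighted cross-entropy loss
#'
#' The mean over N samples of the class weight at the true class times the
#' negative log-softmax of its logit. Note the division is by the sample
#' count N, not by the sum of selected weights.
#'
#' @param logits N x C numeric matrix of unnormalized scores.
#' @param labels Integer vector of true classes in `1..C`.
#' @param weights Length-C numeric vector, or a [class_weights()] tibble.
#' @return Scalar loss.
#' @export
#' @examples
#' weighted_ce_loss(matrix(0, 1, 4), 1L, rep(1, 4))  # log(4)
weighted_ce_loss <- function(logits, labels, weights) {
  w <- if (is.data.frame(weights)) weights$weight else as.numeric(weights)
  logits <- as.matrix(logits)
  labels <- as.integer(labels)
  if (length(w) != ncol(logits)) abort("`weights` length must equal the number of classes.")
  if (any(labels < 1L) || any(labels > ncol(logits))) {
    abort(sprintf("labels must lie in [1, %d].", ncol(logits)))
  }
  if (length(labels) != nrow(logits)) abort("one label per logit row required.")
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  nll <- lse - logits[cbind(seq_along(labels), labels)]
  sum(w[labels] * nll) / length(labels)
}

# gradient of weighted_ce_loss wrt logits, with an extra 1/scale for batching
weighted_ce_grad <- function(logits, labels, w, scale = nrow(logits)) {
  pr <- softmax_rows(logits)
  pr[cbind(seq_along(labels), labels)] <-
    pr[cbind(seq_along(labels), labels)] - 1
  pr * (w[labels] / scale)
}

# ---- parameter-tree utilities and NADAM ------------------------------------

tree_zero <- function(p) rapply(p, function(x) x * 0, how = "replace")

# NADAM update (beta1 = 0.9, beta2 = 0.999); returns updated (params, m, v)
tree_nadam <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- names(p) %||% seq_along(p)     # align trees by name, not position
      out <- lapply(keys, function(k) step(p[[k]], g[[k]], m[[k]], v[[k]]))
      names(out) <- names(p)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mhat <- m2 / (1 - beta1^t)
    vhat <- v2 / (1 - beta2^t)
    upd <- (beta1 * mhat + (1 - beta1) * g / (1 - beta1^t)) / (sqrt(vhat) + eps)
    list(p = p - lr * upd, m = m2, v = v2)
  }
  step(p, g, m, v)
}

tree_add <- function(a, b) {
  if (is.list(a)) mapply(tree_add, a, b, SIMPLIFY = FALSE) else a + b
}

# ---- training ---------------------------------------------------------------

#' Train a network on a small labeled dataset
#'
#' A single-device training loop: NADAM (learning rate `lr`), the weighted
#' cross-entropy loss of [weighted_ce_loss()] with weights computed from the
#' dataset's label counts, plateau-based learning-rate decay (if the
#' validation loss has not improved for `patience` consecutive epochs the
#' learning rate is multiplied by `factor`), and best-model selection by
#' validation macro F1. Intended for small, overfittable datasets; the
#' full-scale training regime (thousands of maps, large batches, many GPUs)
#' is out of scope.
#'
#' @param network A `vox_network` from [build_network()].
#' @param dataset List of training samples, each
#'   `list(x = 32^3 density array, labels = 32^3 integer array in 1..C)`.
#' @param epochs Number of passes over the dataset.
#' @param lr Initial learning rate (default 1e-4).
#' @param patience,factor Plateau decay: epochs without validation-loss
#'   improvement before the rate is multiplied by `factor` (defaults 5, 0.1).
#' @param validation Optional held-out sample list; defaults to `dataset`.
#' @param seed Seed for dropout masks.
#' @return A `vox_training` list: `network` (best by validation F1), `final`
#'   (last state), and `history`, a tibble with one row per epoch
#'   (`epoch`, `lr`, `loss`, `val_loss`, `val_f1`).
#' @export
train_toy <- function(network, dataset, epochs = 10L, lr = 1e-4,
                      patience = 5L, factor = 0.1,
                      validation = NULL, seed = NULL) {
  if (length(dataset) == 0L) abort("`dataset` must contain at least one sample.")
  if (!is.null(seed)) set.seed(seed)
  validation <- validation %||% dataset
  C <- network$spec$out_channels
  counts <- numeric(C)
  tab <- table(factor(unlist(lapply(dataset, function(s) as.integer(s$labels))),
                      levels = seq_len(C)))
  counts <- as.numeric(tab)
  w <- class_weights(counts)$weight
  p <- network$params
  m <- tree_zero(p); v <- tree_zero(p)
  history <- vector("list", epochs)
  best <- list(f1 = -Inf, params = p)
  bad_epochs <- 0L
  prev_best_val <- Inf
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    for (s in dataset) {
      net_cur <- list(spec = network$spec, params = p)
      fw <- vnet_forward(net_cur, s$x, train = TRUE)
      lg <- matrix(fw$logits, length(s$labels), C)
      lab <- as.integer(s$labels)
      ep_loss <- ep_loss + weighted_ce_loss(lg, lab, w)
      dl <- weighted_ce_grad(lg, lab, w)
      g <- vnet_backward(net_cur, fw$cache, array(dl, dim(fw$logits)))
      t_step <- t_step + 1L
      upd <- tree_nadam(p, g, m, v, lr, t_step)
      p <- upd$p; m <- upd$m; v <- upd$v
    }
    ep_loss <- ep_loss / length(dataset)
    val <- evaluate_samples(list(spec = network$spec, params = p), validation, w)
    if (val$f1 > best$f1) best <- list(f1 = val$f1, params = p)
    if (val$loss < prev_best_val - 1e-12) {
      prev_best_val <- val$loss
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= patience) {
        lr <- lr * factor
        bad_epochs <- 0L
      }
    }
    history[[ep]] <- tibble(epoch = ep, lr = lr, loss = ep_loss,
                            val_loss = val$loss, val_f1 = val$f1)
  }
  structure(list(network = structure(list(spec = network$spec, params = best$params),
                                     class = "vox_network"),
                 final = structure(list(spec = network$spec, params = p),
                                   class = "vox_network"),
                 history = bind_rows(history)),
            class = "vox_training")
}

evaluate_samples <- function(net, samples, w) {
  C <- net$spec$out_channels
  loss <- 0
  tp <- fp <- fn <- numeric(C)
  for (s in samples) {
    fw <- vnet_forward(net, s$x, train = FALSE)
    lg <- matrix(fw$logits, length(s$labels), C)
    lab <- as.integer(s$labels)
    loss <- loss + weighted_ce_loss(lg, lab, w)
    pred <- max.col(lg, ties.method = "first")
    for (k in seq_len(C)) {
      tp[k] <- tp[k] + sum(pred == k & lab == k)
      fp[k] <- fp[k] + sum(pred == k & lab != k)
      fn[k] <- fn[k] + sum(pred != k & lab == k)
    }
  }
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom > 0, 2 * tp / denom, NA_real_)
  list(loss = loss / length(samples), f1 = mean(f1, na.rm = TRUE))
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load network weights
#'
#' Single-file checkpoint (RDS) carrying a format version, the
#' [network_spec()] and all parameters.
#'
#' @param network A `vox_network`.
#' @param path Checkpoint file path.
#' @return `save_network()` returns `path` invisibly; `load_network()` a
#'   `vox_network`.
#' @export
save_network <- function(network, path) {
  saveRDS(list(format = "voxtrace-checkpoint-1", spec = network$spec,
               params = network$params), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "voxtrace-checkpoint-1")) {
    abort("not a recognized voxtrace checkpoint.")
  }
  structure(list(spec = x$spec, params = x$params), class = "vox_network")
}

# ---- inference --------------------------------------------------------------

#' Construct per-voxel prediction grids
#'
#' @param atom_probs 4D array `shape x 4`: per-voxel probabilities over
#'   (CA, C, N, none), each vector summing to 1.
#' @param aa_probs 4D array `shape x 21`: probabilities over the 20 standard
#'   amino acids (alphabetical one-letter order) plus a none/unknown class.
#' @return A `prediction_grids` list.
#' @export
prediction_grids <- function(atom_probs, aa_probs) {
  da <- dim(atom_probs); db <- dim(aa_probs)
  if (length(da) != 4L || da[4] != 4L) abort("`atom_probs` must be shape x 4.")
  if (length(db) != 4L || db[4] != 21L) abort("`aa_probs` must be shape x 21.")
  if (!identical(da[1:3], db[1:3])) abort("atom and amino-acid grids have mismatched shapes.")
  check_simplex <- function(x, nm) {
    m <- matrix(x, prod(dim(x)[1:3]), dim(x)[4])
    if (any(m < -1e-9)) abort(sprintf("negative probabilities in %s.", nm))
    if (max(abs(rowSums(m) - 1)) > 1e-6) {
      abort(sprintf("%s probability vectors must sum to 1 within 1e-6.", nm))
    }
  }
  check_simplex(atom_probs, "atom_probs")
  check_simplex(aa_probs, "aa_probs")
  structure(list(atom_probs = atom_probs, aa_probs = aa_probs),
            class = "prediction_grids")
}

#' @export
print.prediction_grids <- function(x, ...) {
  cat(sprintf("<prediction_grids> %s voxels (4 atom classes, 21 amino-acid classes)\n",
              paste(dim(x$atom_probs)[1:3], collapse = " x ")))
  invisible(x)
}

#' Predict per-voxel class probabilities for a density grid
#'
#' Tiles the (normalized) grid into 32^3 sub-grids, runs both classification
#' networks on every tile, softmax-normalizes the logits voxel-wise and
#' stitches the tiles back to the parent shape. `source` may instead be a
#' surrogate: a function `grid -> prediction_grids` (or a ready-made
#' `prediction_grids`), which replaces the networks entirely — this is how
#' synthetic probability grids drive the pipeline without trained weights.
#'
#' @param source Either `list(atom = vox_network, aa = vox_network)`, a
#'   function of the grid, or a `prediction_grids`.
#' @param grid A [density_grid()].
#' @param normalize Min-max normalize the density first (default TRUE).
#' @return A [prediction_grids()] matching `dim(grid)`.
#' @export
predict_grids <- function(source, grid, normalize = TRUE) {
  if (inherits(source, "prediction_grids")) {
    if (!identical(dim(source$atom_probs)[1:3], dim(grid))) {
      abort("supplied prediction grids do not match the map shape.")
    }
    return(source)
  }
  if (is.function(source)) {
    out <- source(grid)
    if (!inherits(out, "prediction_grids")) abort("surrogate must return prediction_grids.")
    return(out)
  }
  if (!is.list(source) || !inherits(source$atom, "vox_network") ||
      !inherits(source$aa, "vox_network")) {
    abort("`source` must be list(atom=, aa=) networks, a surrogate function, or prediction_grids.")
  }
  g <- if (normalize) normalize_density(grid) else grid
  tiles <- tile_into_subgrids(g)
  run_net <- function(net) {
    lapply(tiles, function(t) {
      lg <- vnet_forward(net, t$values, train = FALSE)$logits
      pm <- softmax_rows(matrix(lg, prod(dim(lg)[1:3]), dim(lg)[4]))
      list(values = array(pm, dim(lg)), offset = t$offset)
    })
  }
  atom <- stitch_predictions(run_net(source$atom), dim(grid))
  aa <- stitch_predictions(run_net(source$aa), dim(grid))
  prediction_grids(atom, aa)
}
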