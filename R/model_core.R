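## The three-part network: dilated residual convolutional encoder (per-
## position embeddings), hard-attention selector (policy network over
## acceptor/donor logits), and gated pre-LN transformer with a kernel-size-1
## softmax prediction head.

#' Model configuration
#'
#' Defaults reproduce the published full-scale architecture: 45,000 nt
#' context, 32-dimensional embeddings from a SpliceAI-10k-style residual
#' stack, 512 selector slots split evenly between acceptors and donors, and
#' eight gated transformer encoder layers with four heads and a
#' 512-dimensional GELU feed-forward block.
#'
#' @param context Model input window length in nt.
#' @param embed_dim Embedding dimension d.
#' @param block_plan List of `c(kernel, dilation, repeats)` residual-unit
#'   groups; each unit holds two convolutions at that kernel/dilation.
#' @param slots Length-2 integer vector `(n_acceptor, n_donor)` selector
#'   slots.
#' @param n_layers,n_heads Transformer encoder layers and attention heads.
#' @param ff_dim Feed-forward hidden dimension.
#' @param policy_hidden Hidden units of the selector policy network.
#' @param use_transformer If `FALSE`, the transformer stage is removed and
#'   all positions are predicted from the raw encoder embedding
#'   (encoder-only ablation).
#' @param margin Tiling margin for whole-chromosome prediction; defaults to
#'   the encoder's one-sided receptive field.
#' @return List of class `spliceformer_config`.
#' @export
spliceformer_config <- function(context = 45000L, embed_dim = 32L,
                                block_plan = spliceai_block_plan(),
                                slots = c(256L, 256L),
                                n_layers = 8L, n_heads = 4L, ff_dim = 512L,
                                policy_hidden = 4L, use_transformer = TRUE,
                                margin = NULL) {
  stopifnot(embed_dim %% n_heads == 0L, length(slots) == 2L)
  cfg <- structure(list(context = as.integer(context),
                        embed_dim = as.integer(embed_dim),
                        block_plan = block_plan,
                        slots = as.integer(slots),
                        n_layers = as.integer(n_layers),
                        n_heads = as.integer(n_heads),
                        ff_dim = as.integer(ff_dim),
                        policy_hidden = as.integer(policy_hidden),
                        use_transformer = isTRUE(use_transformer)),
                   class = "spliceformer_config")
  rf <- receptive_field(cfg)
  cfg$margin <- if (is.null(margin)) (rf - 1L) %/% 2L else as.integer(margin)
  if (cfg$context < rf) stop("context shorter than encoder receptive field")
  cfg
}

#' The published SpliceAI-10k residual block plan
#'
#' Four groups of four residual units at kernel/dilation (11,1), (11,4),
#' (21,10), (41,25), giving a ~10,000 nt receptive field.
#' @return List of `c(kernel, dilation, repeats)` rows.
#' @export
spliceai_block_plan <- function() {
  list(c(11L, 1L, 4L), c(11L, 4L, 4L), c(21L, 10L, 4L), c(41L, 25L, 4L))
}

#' Desk-scale model configuration
#'
#' A scaled-down preset that trains on a CPU in minutes: 3,000 nt context,
#' 16-dimensional embeddings from two residual units, two transformer
#' layers with two heads, 32 selector slots, 64-dimensional feed-forward.
#' @param ... Overrides passed to [spliceformer_config()].
#' @return A `spliceformer_config`.
#' @export
scaled_config <- function(...) {
  args <- list(context = 3000L, embed_dim = 16L,
               block_plan = list(c(9L, 1L, 1L), c(9L, 3L, 1L)),
               slots = c(16L, 16L), n_layers = 2L, n_heads = 2L,
               ff_dim = 64L)
  override <- list(...)
  args[names(override)] <- override
  do.call(spliceformer_config, args)
}

#' Encoder receptive field in nucleotides
#'
#' Total width `1 + sum over convolutions of (kernel - 1) * dilation`; the
#' embedding of a position cannot depend on bases further than half this
#' width away.
#' @param config A `spliceformer_config`.
#' @return Odd integer receptive field in nt.
#' @export
receptive_field <- function(config) {
  w <- 1L
  for (row in config$block_plan) {
    w <- w + 2L * row[[3L]] * (row[[1L]] - 1L) * row[[2L]]
  }
  w
}

#' @export
print.spliceformer_config <- function(x, ...) {
  cat(sprintf(paste0("spliceformer_config: context %d nt, d = %d, ",
                     "receptive field %d nt\n"),
              x$context, x$embed_dim, receptive_field(x)))
  cat(sprintf("  selector slots: %d acceptor + %d donor\n",
              x$slots[1L], x$slots[2L]))
  if (x$use_transformer) {
    cat(sprintf("  transformer: %d layer(s), %d head(s), ff dim %d\n",
                x$n_layers, x$n_heads, x$ff_dim))
  } else {
    cat("  transformer: disabled (encoder-only ablation)\n")
  }
  invisible(x)
}

## ---- parameter initialisation ---------------------------------------------

#' Initialise model parameters
#'
#' @param config A [spliceformer_config()].
#' @param seed Integer seed for the weight draw.
#' @return Object of class `spliceformer` (untrained).
#' @export
spliceformer_init <- function(config = spliceformer_config(), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- config$embed_dim
  units <- list()
  for (row in config$block_plan) {
    for (r in seq_len(row[[3L]])) {
      units[[length(units) + 1L]] <- list(
        bn1 = bn_init(d), conv1 = conv1d_init(row[[1L]], d, d),
        bn2 = bn_init(d), conv2 = conv1d_init(row[[1L]], d, d),
        dil = row[[2L]])
    }
  }
  encoder <- list(conv_in = conv1d_init(1L, 4L, d), units = units)
  ## the policy output layer starts at zero so the initial selection
  ## distribution is exactly uniform: exploration survives until genuine
  ## reward events shape each slot type's logit head
  selector <- list(lin1 = linear_init(d, config$policy_hidden),
                   lin2 = list(W = matrix(0, config$policy_hidden, 2L),
                               b = numeric(2L)))
  transformer <- NULL
  if (config$use_transformer) {
    transformer <- lapply(seq_len(config$n_layers), function(i) {
      list(ln1 = ln_init(d),
           q = linear_init(d, d), k = linear_init(d, d),
           v = linear_init(d, d), g = linear_init(d, d),
           o = linear_init(d, d),
           ln2 = ln_init(d),
           f1 = linear_init(d, config$ff_dim),
           f2 = linear_init(config$ff_dim, d))
    })
  }
  head <- linear_init(d, 3L)  # kernel-size-1 convolution
  structure(list(config = config,
                 params = list(encoder = encoder, selector = selector,
                               transformer = transformer, head = head),
                 history = NULL, seed = seed, trained = FALSE),
            class = "spliceformer")
}

## ---- encoder ---------------------------------------------------------------

## X: L x 4 one-hot; returns L x d embeddings (+ caches for backward)
encode_forward <- function(params, config, X, train = FALSE) {
  enc <- params$encoder
  c_in <- conv1d_forward(enc$conv_in, X, 1L)
  h <- c_in$Y
  caches <- vector("list", length(enc$units))
  for (i in seq_along(enc$units)) {
    u <- enc$units[[i]]
    b1 <- bn_forward(u$bn1, h, train); u$bn1 <- b1$par
    r1 <- relu_forward(b1$Y)
    v1 <- conv1d_forward(u$conv1, r1$Y, u$dil)
    b2 <- bn_forward(u$bn2, v1$Y, train); u$bn2 <- b2$par
    r2 <- relu_forward(b2$Y)
    v2 <- conv1d_forward(u$conv2, r2$Y, u$dil)
    h <- h + v2$Y
    caches[[i]] <- list(b1 = b1$cache, r1 = r1$cache, v1 = v1$cache,
                        b2 = b2$cache, r2 = r2$cache, v2 = v2$cache)
    enc$units[[i]] <- u  # running stats updated in train mode
  }
  params$encoder <- enc
  list(E = h, params = params,
       cache = list(conv_in = c_in$cache, units = caches))
}

encode_backward <- function(params, config, cache, dE) {
  enc <- params$encoder
  g_units <- vector("list", length(enc$units))
  dh <- dE
  for (i in rev(seq_along(enc$units))) {
    u <- enc$units[[i]]; cc <- cache$units[[i]]
    bv2 <- conv1d_backward(u$conv2, cc$v2, dh)
    dr2 <- relu_backward(cc$r2, bv2$dX)
    bb2 <- bn_backward(u$bn2, cc$b2, dr2)
    bv1 <- conv1d_backward(u$conv1, cc$v1, bb2$dX)
    dr1 <- relu_backward(cc$r1, bv1$dX)
    bb1 <- bn_backward(u$bn1, cc$b1, dr1)
    g_units[[i]] <- list(bn1 = bb1$grads, conv1 = bv1$grads,
                         bn2 = bb2$grads, conv2 = bv2$grads)
    dh <- dh + bb1$dX  # residual skip
  }
  b_in <- conv1d_backward(enc$conv_in, cache$conv_in, dh)
  list(grads = list(conv_in = b_in$grads, units = g_units), dX = b_in$dX)
}

#' Encode a window into per-position embeddings
#'
#' @param model A `spliceformer` (or its parameter list plus config).
#' @param window One-hot matrix (length x 4) from [one_hot_encode()], at
#'   least as long as the encoder receptive field.
#' @param train Use batch statistics and update running statistics.
#' @return Length x d embedding matrix.
#' @export
encode <- function(model, window, train = FALSE) {
  stopifnot(inherits(model, "spliceformer"))
  if (nrow(window) < receptive_field(model$config)) {
    stop("window shorter than encoder receptive field")
  }
  encode_forward(model$params, model$config, window, train)$E
}

## ---- selector --------------------------------------------------------------

#' Selector policy logits
#'
#' Maps each position's embedding through the policy network (one hidden
#' layer, leaky ReLU) to an (acceptor, donor) logit pair.
#'
#' @param model A `spliceformer`.
#' @param embeddings Length x d embedding matrix.
#' @return Length x 2 matrix of (acceptor, donor) logits.
#' @export
policy_logits <- function(model, embeddings) {
  sel <- model$params$selector
  if (ncol(embeddings) != nrow(sel$lin1$W)) {
    stop("embedding dimension does not match policy input")
  }
  h <- leaky_relu_forward(linear_forward(sel$lin1, embeddings)$Y)$Y
  out <- linear_forward(sel$lin2, h)$Y
  colnames(out) <- c("acceptor", "donor")
  out
}

.masked_softmax <- function(z, mask) {
  z[mask] <- -Inf
  m <- max(z)
  e <- exp(z - m)
  e / sum(e)
}

#' Sample candidate splice sites from the policy (hard attention)
#'
#' Alternates between drawing acceptor and donor positions from categorical
#' distributions over the policy logits, without replacement: the mask of
#' previous draws is updated after every draw so no position is selected
#' twice, and each draw's log-probability is taken under the distribution
#' renormalised over the unmasked positions at draw time.
#'
#' @param logits Length x 2 matrix of (acceptor, donor) logits.
#' @param slots Integer vector `(n_acceptor, n_donor)`.
#' @return `data.frame` of class `selected_sites` with columns `pos`,
#'   `type`, `logp` in draw order.
#' @export
sample_sites <- function(logits, slots = c(256L, 256L)) {
  L <- nrow(logits)
  total <- min(sum(slots), L)
  mask <- rep(FALSE, L)
  pos <- integer(total); type <- character(total); logp <- numeric(total)
  left <- c(slots[1L], slots[2L])
  cur <- 1L  # 1 = acceptor, 2 = donor
  for (t in seq_len(total)) {
    if (left[cur] == 0L) cur <- 3L - cur
    p <- .masked_softmax(logits[, cur], mask)
    i <- sample.int(L, 1L, prob = p)
    pos[t] <- i
    type[t] <- c("acceptor", "donor")[cur]
    logp[t] <- log(p[i])
    mask[i] <- TRUE
    left[cur] <- left[cur] - 1L
    cur <- 3L - cur
  }
  structure(data.frame(pos = pos, type = type, logp = logp),
            class = c("selected_sites", "data.frame"))
}

#' Greedy site selection (test time)
#'
#' Selects the `n_acceptor` positions with the largest acceptor logits and
#' the `n_donor` positions with the largest donor logits. A position winning
#' both lists is assigned to its higher-logit type and the other list takes
#' its next candidate; ties break towards the lower position index (and
#' towards the acceptor type).
#'
#' @inheritParams sample_sites
#' @return `data.frame` of class `selected_sites` with columns `pos`,
#'   `type`, `logp` (log softmax of the per-type logits over the window).
#' @export
select_sites_greedy <- function(logits, slots = c(256L, 256L)) {
  L <- nrow(logits)
  na <- min(slots[1L], L); nd <- min(slots[2L], L)
  qa <- order(-logits[, 1L], seq_len(L))
  qd <- order(-logits[, 2L], seq_len(L))
  taken <- rep(FALSE, L)
  sel_pos <- integer(0); sel_type <- character(0)
  ia <- 1L; id <- 1L; got_a <- 0L; got_d <- 0L
  while (got_a < na || got_d < nd) {
    while (ia <= L && taken[qa[ia]]) ia <- ia + 1L
    while (id <= L && taken[qd[id]]) id <- id + 1L
    can_a <- got_a < na && ia <= L
    can_d <- got_d < nd && id <= L
    if (!can_a && !can_d) break
    pick_a <- if (can_a && can_d) {
      la <- logits[qa[ia], 1L]; ld <- logits[qd[id], 2L]
      la > ld || (la == ld && qa[ia] <= qd[id])
    } else can_a
    if (pick_a) {
      sel_pos <- c(sel_pos, qa[ia]); sel_type <- c(sel_type, "acceptor")
      taken[qa[ia]] <- TRUE; got_a <- got_a + 1L
    } else {
      sel_pos <- c(sel_pos, qd[id]); sel_type <- c(sel_type, "donor")
      taken[qd[id]] <- TRUE; got_d <- got_d + 1L
    }
  }
  ord <- order(sel_pos)
  tcol <- ifelse(sel_type == "acceptor", 1L, 2L)
  lsm <- apply(logits, 2L, function(z) z - log(sum(exp(z - max(z)))) - max(z))
  structure(data.frame(pos = sel_pos[ord], type = sel_type[ord],
                       logp = lsm[cbind(sel_pos, tcol)][ord]),
            class = c("selected_sites", "data.frame"))
}

## ---- gated attention -------------------------------------------------------

#' Gated scaled dot-product attention
#'
#' Computes `sigmoid(G) * softmax(Q K' / sqrt(d)) V`: standard scaled
#' dot-product attention whose value output is modulated elementwise by a
#' learned sigmoid gate. The pre-gating softmax rows sum to one.
#'
#' @param Q,K,V,G Conformable matrices (n x d_k for Q/K, n x d_v for V/G).
#' @param d Scale dimension under the square root.
#' @return List with `Y` (gated output), `A` (post-softmax, pre-gating
#'   attention matrix).
#' @export
gated_attention <- function(Q, K, V, G, d = ncol(K)) {
  A <- softmax_rows(Q %*% t(K) / sqrt(d))
  list(Y = stats::plogis(G) * (A %*% V), A = A)
}

## fixed sinusoidal position encoding over absolute window coordinates
positional_encoding <- function(positions, d) {
  i <- seq_len(d %/% 2L)
  freq <- 1 / 10000^((2 * (i - 1L)) / d)
  ang <- outer(positions, freq)
  pe <- matrix(0, length(positions), d)
  pe[, seq.int(1L, d, 2L)] <- sin(ang)
  pe[, seq.int(2L, d, 2L)] <- cos(ang)
  pe
}

## ---- transformer -----------------------------------------------------------

.head_idx <- function(h, dh) ((h - 1L) * dh + 1L):(h * dh)

tf_layer_forward <- function(layer, X, n_heads) {
  d <- ncol(X); dh <- d %/% n_heads
  l1 <- ln_forward(layer$ln1, X)
  Q <- linear_forward(layer$q, l1$Y); K <- linear_forward(layer$k, l1$Y)
  V <- linear_forward(layer$v, l1$Y); G <- linear_forward(layer$g, l1$Y)
  O <- matrix(0, nrow(X), d)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    ix <- .head_idx(h, dh)
    ga <- gated_attention(Q$Y[, ix, drop = FALSE], K$Y[, ix, drop = FALSE],
                          V$Y[, ix, drop = FALSE], G$Y[, ix, drop = FALSE],
                          d = dh)
    O[, ix] <- ga$Y
    heads[[h]] <- list(A = ga$A, sig = stats::plogis(G$Y[, ix, drop = FALSE]))
  }
  oo <- linear_forward(layer$o, O)
  X1 <- X + oo$Y
  l2 <- ln_forward(layer$ln2, X1)
  f1 <- linear_forward(layer$f1, l2$Y)
  ge <- gelu_forward(f1$Y)
  f2 <- linear_forward(layer$f2, ge$Y)
  X2 <- X1 + f2$Y
  list(Y = X2,
       cache = list(l1 = l1$cache, Q = Q, K = K, V = V, G = G, heads = heads,
                    O = O, oo = oo$cache, l2 = l2$cache, f1 = f1$cache,
                    ge = ge$cache, f2 = f2$cache, dh = dh))
}

tf_layer_backward <- function(layer, cache, dY, n_heads) {
  dh <- cache$dh
  ## feed-forward branch
  bf2 <- linear_backward(layer$f2, cache$f2, dY)
  dge <- gelu_backward(cache$ge, bf2$dX)
  bf1 <- linear_backward(layer$f1, cache$f1, dge)
  bl2 <- ln_backward(layer$ln2, cache$l2, bf1$dX)
  dX1 <- dY + bl2$dX
  ## attention branch
  boo <- linear_backward(layer$o, cache$O, dX1)
  dO <- boo$dX
  dQ <- matrix(0, nrow(dO), ncol(dO)); dK <- dQ; dV <- dQ; dG <- dQ
  for (h in seq_len(n_heads)) {
    ix <- .head_idx(h, dh)
    hc <- cache$heads[[h]]
    Vh <- cache$V$Y[, ix, drop = FALSE]
    AV <- hc$A %*% Vh
    dOh <- dO[, ix, drop = FALSE]
    dG[, ix] <- dOh * AV * hc$sig * (1 - hc$sig)
    dAV <- dOh * hc$sig
    dA <- dAV %*% t(Vh)
    dV[, ix] <- crossprod(hc$A, dAV)
    dS <- softmax_rows_backward(hc$A, dA) / sqrt(dh)
    dQ[, ix] <- dS %*% cache$K$Y[, ix, drop = FALSE]
    dK[, ix] <- crossprod(dS, cache$Q$Y[, ix, drop = FALSE])
  }
  bq <- linear_backward(layer$q, cache$Q$cache, dQ)
  bk <- linear_backward(layer$k, cache$K$cache, dK)
  bv <- linear_backward(layer$v, cache$V$cache, dV)
  bg <- linear_backward(layer$g, cache$G$cache, dG)
  bl1 <- ln_backward(layer$ln1, cache$l1,
                     bq$dX + bk$dX + bv$dX + bg$dX)
  dX <- dX1 + bl1$dX
  list(grads = list(ln1 = bl1$grads, q = bq$grads, k = bk$grads,
                    v = bv$grads, g = bg$grads, o = boo$grads,
                    ln2 = bl2$grads, f1 = bf1$grads, f2 = bf2$grads),
       dX = dX)
}

#' Transformer refinement of selected-site embeddings
#'
#' Adds a fixed sinusoidal position encoding over the sites' absolute window
#' coordinates, then applies the configured stack of pre-layer-normalised
#' encoder layers (gated multi-head self-attention + GELU feed-forward, each
#' with a skip connection).
#'
#' @param model A `spliceformer` with `use_transformer = TRUE`.
#' @param site_embeddings n_sites x d matrix of encoder embeddings.
#' @param positions Window coordinates of the sites (same order).
#' @param record_attention Also return the post-softmax attention matrices
#'   of every layer and head.
#' @return Refined n_sites x d matrix; with `record_attention`, a list with
#'   elements `Y` and `attention`.
#' @export
transformer_forward <- function(model, site_embeddings, positions,
                                record_attention = FALSE) {
  stopifnot(model$config$use_transformer)
  res <- .tf_forward(model$params, model$config, site_embeddings, positions)
  if (record_attention) {
    list(Y = res$Y, attention = .tf_attention(res$caches))
  } else {
    res$Y
  }
}

.tf_forward <- function(params, config, site_emb, positions) {
  X <- site_emb + positional_encoding(positions, ncol(site_emb))
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    st <- tf_layer_forward(params$transformer[[l]], X, config$n_heads)
    X <- st$Y
    caches[[l]] <- st$cache
  }
  list(Y = X, caches = caches)
}

.tf_backward <- function(params, config, caches, dY) {
  grads <- vector("list", config$n_layers)
  dX <- dY
  for (l in rev(seq_len(config$n_layers))) {
    bl <- tf_layer_backward(params$transformer[[l]], caches[[l]], dX,
                            config$n_heads)
    grads[[l]] <- bl$grads
    dX <- bl$dX
  }
  list(grads = grads, dX = dX)
}

.tf_attention <- function(caches) {
  lapply(caches, function(cc) lapply(cc$heads, `[[`, "A"))
}

## ---- prediction head -------------------------------------------------------

#' Per-position splice probabilities from embeddings
#'
#' Kernel-size-1 convolution from d dimensions to three classes followed by
#' a softmax; every row is a probability triple (no splice, acceptor,
#' donor).
#'
#' @param model A `spliceformer`.
#' @param embeddings Length x d embedding matrix.
#' @return Length x 3 probability matrix (rows sum to 1).
#' @export
predict_track <- function(model, embeddings) {
  P <- softmax_rows(linear_forward(model$params$head, embeddings)$Y)
  colnames(P) <- .LABEL_LEVELS
  P
}

## ---- full forward ----------------------------------------------------------

#' Full model forward pass on one window
#'
#' Encode, select candidate sites (sampled under the policy in `train` mode,
#' greedy in `eval` mode), refine the selected embeddings with the
#' transformer, and emit per-position probability triples. Positions not
#' selected are predicted from their raw encoder embedding; selected
#' positions from their transformer-refined embedding.
#'
#' @param model A `spliceformer`.
#' @param window One-hot matrix (length x 4).
#' @param mode `"eval"` (deterministic) or `"train"` (stochastic selection).
#' @param record_attention Record post-softmax attention matrices.
#' @return List with `track` (length x 3 probability matrix), `sites`
#'   (`selected_sites`), `logits`, and with `record_attention` the
#'   per-layer/head `attention` matrices.
#' @export
spliceformer_forward <- function(model, window, mode = c("eval", "train"),
                                 record_attention = FALSE) {
  mode <- match.arg(mode)
  train <- mode == "train"
  ef <- encode_forward(model$params, model$config, window, train = train)
  E <- ef$E
  logits <- policy_logits(model, E)
  sites <- if (train) sample_sites(logits, model$config$slots) else
    select_sites_greedy(logits, model$config$slots)
  P <- predict_track(model, E)
  attn <- NULL
  if (model$config$use_transformer && nrow(sites) > 0L) {
    tf <- .tf_forward(model$params, model$config,
                      E[sites$pos, , drop = FALSE], sites$pos)
    P[sites$pos, ] <- predict_track(model, tf$Y)
    if (record_attention) attn <- .tf_attention(tf$caches)
  }
  out <- list(track = P, sites = sites, logits = logits)
  if (record_attention) out$attention <- attn
  out
}

## ---- S3 methods ------------------------------------------------------------

#' @export
print.spliceformer <- function(x, ...) {
  cat("spliceformer model",
      if (x$trained) "(trained)\n" else "(untrained)\n")
  print(x$config)
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("  final epoch %d: train CE/pos %.4f, val CE/pos %.4f\n",
                nrow(h), h$train_ce[nrow(h)], h$val_ce[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.spliceformer <- function(object, ...) {
  np <- function(x) {
    if (is.list(x)) sum(vapply(x, np, numeric(1))) else length(x)
  }
  cat("spliceformer model\n")
  print(object$config)
  cat(sprintf("  parameters: %d\n", np(object$params)))
  if (!is.null(object$history)) {
    cat("training history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.spliceformer <- function(object, ...) object$params

#' Predict splice probabilities over chromosomes
#'
#' Tiles each chromosome with overlapping windows of the model context,
#' keeps only the interior of each window (every emitted position has full
#' encoder context), and returns per-position probability triples for the
#' requested strands. Minus-strand predictions are computed on the reverse
#' complement and mapped back to genomic coordinates.
#'
#' @param object A trained `spliceformer`.
#' @param genome A [genome_store].
#' @param chroms Chromosomes to score (default all).
#' @param strands `"+"`, `"-"`, or both.
#' @param ... Unused.
#' @return Nested list `tracks[[chrom]][[strand]]`, each a length x 3
#'   probability matrix in genomic coordinates.
#' @export
predict.spliceformer <- function(object, genome, chroms = NULL,
                                 strands = c("+", "-"), ...) {
  .scan_genome(object, genome, chroms, strands)$tracks
}

## tile the chromosomes once, collecting both the per-position probability
## tracks and the greedy-selected sites of every window interior
.scan_genome <- function(object, genome, chroms = NULL,
                         strands = c("+", "-")) {
  if (is.null(chroms)) chroms <- names(genome$seq)
  W <- object$config$context
  M <- max(object$config$margin, 1L)
  out <- list()
  picked <- character(0)
  for (cn in chroms) {
    L <- genome$lengths[[cn]]
    out[[cn]] <- list()
    for (st in strands) {
      track <- matrix(NA_real_, L, 3L, dimnames = list(NULL, .LABEL_LEVELS))
      starts <- seq.int(1L, max(L - 2L * M, 1L), by = W - 2L * M)
      for (s0 in starts) {
        oh <- one_hot_encode(extract_window(genome, cn, s0, W, st))
        fw <- spliceformer_forward(object, oh, mode = "eval")
        ## keep the genomic interior of the tile; extend to chromosome edges
        lo_g <- if (s0 == 1L) 1L else s0 + M
        hi_g <- if (s0 + W - 1L >= L) L else s0 + W - 1L - M
        w_idx <- seq_len(W)
        g_idx <- if (st == "+") s0 + w_idx - 1L else s0 + W - w_idx
        ok <- g_idx >= lo_g & g_idx <= hi_g
        track[g_idx[ok], ] <- fw$track[w_idx[ok], , drop = FALSE]
        gs <- if (st == "+") s0 + fw$sites$pos - 1L else s0 + W - fw$sites$pos
        oks <- gs >= lo_g & gs <= hi_g
        picked <- c(picked,
                    paste(cn, st, gs[oks], fw$sites$type[oks], sep = ":"))
        if (s0 + W - 1L >= L) break
      }
      out[[cn]][[st]] <- track
    }
  }
  list(tracks = out, picked = unique(picked))
}

## ---- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Single-file archive holding the configuration, weights, training history
#' and a format version.
#'
#' @param model A `spliceformer` or `spliceformer_ensemble`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
save_spliceformer <- function(model, path) {
  stopifnot(inherits(model, c("spliceformer", "spliceformer_ensemble")))
  saveRDS(list(format_version = 1L, class = class(model)[1L],
               model = unclass(model)), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_spliceformer()].
#' @return The restored `spliceformer` (or ensemble).
#' @export
load_spliceformer <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported checkpoint format")
  }
  structure(obj$model, class = obj$class)
}
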