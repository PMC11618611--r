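test_that("encoder emits d-dimensional embeddings deterministically", {
  m <- tiny_model()
  win <- random_window(200, seed = 2)
  E <- encode(m, win)
  expect_equal(dim(E), c(200L, 8L))
  expect_identical(E, encode(m, win))
  expect_error(encode(m, win[1:10, , drop = FALSE]), "receptive field")
  ## default full-scale configuration embeds into 32 dimensions
  expect_equal(spliceformer_config()$embed_dim, 32L)
})

test_that("embeddings respect the encoder receptive field", {
  m <- tiny_model()
  rf <- receptive_field(m$config)
  expect_equal(rf, 1 + 2 * (4 * 1 + 4 * 2))  # (5,1)x1 + (5,2)x1 units
  set.seed(5)
  for (rep in 1:5) {
    win <- random_window(200, seed = rep)
    E <- encode(m, win)
    i <- 100L
    far <- i + (rf - 1L) %/% 2L + 1L + sample.int(20L, 1L)
    win2 <- win
    win2[far, ] <- as.numeric(seq_len(4) == sample.int(4L, 1L))
    E2 <- encode(m, win2)
    expect_equal(E2[i, ], E[i, ], tolerance = 1e-12)
    ## a mutation inside the receptive field does move the embedding
    win3 <- win
    win3[i + 2L, ] <- 1 - win3[i + 2L, ]
    expect_false(isTRUE(all.equal(encode(m, win3)[i, ], E[i, ])))
  }
})

test_that("policy logits match a pencil-and-paper forward pass", {
  ## 1-unit toy: all weights 1, biases 0, leaky-ReLU hidden
  m <- tiny_model()
  m$params$selector <- list(
    lin1 = list(W = matrix(1, 8, 1), b = 0),
    lin2 = list(W = matrix(1, 1, 2), b = c(0, 0)))
  E <- rbind(rep(0.5, 8), rep(-0.25, 8), rep(0, 8))
  lg <- policy_logits(m, E)
  ## hidden = leaky_relu(sum(e)); logits = hidden in both columns
  h <- c(4, -2 * 0.01, 0)
  expect_equal(unname(lg), unname(cbind(h, h)))
  ## zero embedding rows share the bias-path value
  expect_equal(unname(lg[3, 1]), unname(lg[3, 2]))
  expect_true(all(is.finite(policy_logits(tiny_model(),
                                          random_window(200, 3) %*%
                                            matrix(1, 4, 8)))))
  expect_error(policy_logits(tiny_model(), matrix(0, 5, 3)), "dimension")
})

test_that("sampled selections are duplicate-free and slot-balanced", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(30:100, 1)
    logits <- matrix(rnorm(L * 2, sd = 2), L, 2)
    s <- sample_sites(logits, slots = c(8L, 8L))
    expect_equal(nrow(s), 16L)
    expect_false(anyDuplicated(s$pos) > 0)
    expect_equal(sum(s$type == "acceptor"), 8L)
    expect_equal(sum(s$type == "donor"), 8L)
    expect_true(all(s$logp <= 0))
  }
  ## a near-degenerate categorical puts the hot position first
  logits <- matrix(-1e6, 50, 2)
  logits[37, 1] <- 1e6
  s <- sample_sites(logits, slots = c(2L, 2L))
  expect_equal(s$pos[1], 37L)
  expect_equal(s$type[1], "acceptor")
  ## short windows select every position
  s_all <- sample_sites(matrix(0, 5, 2), slots = c(8L, 8L))
  expect_equal(sort(s_all$pos), 1:5)
})

test_that("greedy selection follows logits with index tie-breaks", {
  ## strictly decreasing acceptor logits -> lowest positions win
  logits <- cbind(seq(5, 0.5, length.out = 10), rep(-10, 10))
  s <- select_sites_greedy(logits, slots = c(3L, 0L))
  expect_equal(sort(s$pos), 1:3)
  ## exhaustive check against direct enumeration on a 10-position input
  set.seed(21)
  for (rep in 1:20) {
    lg <- matrix(rnorm(20), 10, 2)
    s <- select_sites_greedy(lg, slots = c(3L, 3L))
    expect_equal(nrow(s), 6L)
    expect_false(anyDuplicated(s$pos) > 0)
    ## the selected acceptor set dominates: no unselected position has an
    ## acceptor logit above the lowest selected acceptor (allowing for the
    ## dual-type conflict rule)
    acc <- s$pos[s$type == "acceptor"]
    don <- s$pos[s$type == "donor"]
    free <- setdiff(1:10, s$pos)
    if (length(free)) {
      expect_lte(max(lg[free, 1]), min(lg[acc, 1]))
      expect_lte(max(lg[free, 2]), min(lg[don, 2]))
    }
  }
  ## all-equal logits: lowest indices selected
  s_eq <- select_sites_greedy(matrix(0, 10, 2), slots = c(2L, 2L))
  expect_equal(sort(s_eq$pos), 1:4)
  ## determinism
  lg <- matrix(rnorm(20), 10, 2)
  expect_identical(select_sites_greedy(lg, c(3L, 3L)),
                   select_sites_greedy(lg, c(3L, 3L)))
  ## a position winning both lists goes to its higher-logit type
  lg2 <- matrix(-5, 6, 2)
  lg2[2, ] <- c(3, 4)   # wins both; donor logit higher
  lg2[5, ] <- c(2, 1)
  s2 <- select_sites_greedy(lg2, slots = c(1L, 1L))
  expect_equal(s2$type[s2$pos == 2], "donor")
  expect_equal(s2$pos[s2$type == "acceptor"], 5L)
})

test_that("gated attention matches the explicit triple-loop oracle", {
  oracle <- function(Q, K, V, G, d) {
    n <- nrow(Q)
    Y <- matrix(0, n, ncol(V))
    for (i in seq_len(n)) {
      w <- numeric(n)
      for (j in seq_len(n)) w[j] <- exp(sum(Q[i, ] * K[j, ]) / sqrt(d))
      w <- w / sum(w)
      for (cc in seq_len(ncol(V))) {
        s <- 0
        for (j in seq_len(n)) s <- s + w[j] * V[j, cc]
        Y[i, cc] <- 1 / (1 + exp(-G[i, cc])) * s
      }
    }
    Y
  }
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:6, 1); dk <- sample(2:8, 1)
    Q <- matrix(rnorm(n * dk), n); K <- matrix(rnorm(n * dk), n)
    V <- matrix(rnorm(n * dk), n); G <- matrix(rnorm(n * dk), n)
    ga <- gated_attention(Q, K, V, G, d = dk)
    expect_lt(max(abs(ga$Y - oracle(Q, K, V, G, dk))), 1e-6)
    expect_equal(unname(rowSums(ga$A)), rep(1, n), tolerance = 1e-9)
  }
  ## single position: softmax of a scalar is 1, output = sigmoid(G) * V
  ga1 <- gated_attention(matrix(1, 1, 3), matrix(2, 1, 3),
                         matrix(c(1, 2, 3), 1), matrix(0.5, 1, 3))
  expect_equal(ga1$Y, plogis(0.5) * matrix(c(1, 2, 3), 1))
  ## saturating gate recovers plain scaled dot-product attention
  set.seed(4)
  Q <- matrix(rnorm(12), 4); K <- matrix(rnorm(12), 4)
  V <- matrix(rnorm(12), 4)
  ga_inf <- gated_attention(Q, K, V, matrix(1e4, 4, 3))
  expect_equal(ga_inf$Y, ga_inf$A %*% V, tolerance = 1e-12)
})

test_that("transformer refinement is shape-preserving and equivariant", {
  m <- tiny_model()
  set.seed(41)
  S <- matrix(rnorm(12 * 8), 12, 8)
  pos <- sort(sample(1:200, 12))
  Y <- transformer_forward(m, S, pos)
  expect_equal(dim(Y), dim(S))
  ## permuting sites together with their positions permutes the output
  perm <- sample(12)
  Y_perm <- transformer_forward(m, S[perm, ], pos[perm])
  expect_equal(Y_perm, Y[perm, ], tolerance = 1e-10)
  ## default configuration depth and heads
  cfg <- spliceformer_config()
  expect_equal(cfg$n_layers, 8L)
  expect_equal(cfg$n_heads, 4L)
  expect_equal(cfg$slots, c(256L, 256L))
})

test_that("prediction head emits probability triples", {
  m <- tiny_model()
  E <- matrix(rnorm(40 * 8), 40, 8)
  P <- predict_track(m, E)
  expect_equal(unname(rowSums(P)), rep(1, 40), tolerance = 1e-6)
  expect_true(all(P >= 0))
  ## zero-weight head gives the uniform distribution
  m0 <- m
  m0$params$head <- list(W = matrix(0, 8, 3), b = numeric(3))
  expect_equal(unname(predict_track(m0, E)),
               matrix(1 / 3, 40, 3), tolerance = 1e-12)
  ## hand-set weights on a 1-position toy against a manual softmax
  m1 <- m
  m1$params$head <- list(W = matrix(c(1, 0, 0, 0, 0, 0, 0, 0,
                                      0, 1, 0, 0, 0, 0, 0, 0,
                                      0, 0, 1, 0, 0, 0, 0, 0), 8, 3),
                         b = c(0.1, 0.2, 0.3))
  e1 <- matrix(c(1, 2, 3, 0, 0, 0, 0, 0), 1)
  z <- c(1.1, 2.2, 3.3)
  expect_equal(unname(predict_track(m1, e1)[1, ]), exp(z) / sum(exp(z)))
})

test_that("forward pass yields valid deterministic tracks in eval mode", {
  m <- tiny_model()
  win <- random_window(200, seed = 6)
  fw <- spliceformer_forward(m, win, mode = "eval")
  expect_equal(unname(rowSums(fw$track)), rep(1, 200), tolerance = 1e-6)
  fw2 <- spliceformer_forward(m, win, mode = "eval")
  expect_identical(fw$track, fw2$track)
  expect_equal(nrow(fw$sites), 12L)
})

test_that("a zeroed-residual transformer reduces to encoder-only output", {
  m <- tiny_model()
  ## zero every residual branch: output projection and second feed-forward
  for (l in seq_along(m$params$transformer)) {
    m$params$transformer[[l]]$o$W[] <- 0
    m$params$transformer[[l]]$o$b[] <- 0
    m$params$transformer[[l]]$f2$W[] <- 0
    m$params$transformer[[l]]$f2$b[] <- 0
  }
  win <- random_window(200, seed = 8)
  fw <- spliceformer_forward(m, win, mode = "eval")
  ## with identity refinement, selected positions still differ by the
  ## position encoding added to the transformer input; remove it too
  E <- encode(m, win)
  P_enc <- predict_track(m, E + spliceformer:::positional_encoding(1:200, 8))
  expect_equal(fw$track[fw$sites$pos, ], P_enc[fw$sites$pos, ],
               tolerance = 1e-10)
  ## the encoder-only ablation with the same weights predicts every
  ## position from the raw embedding
  m_abl <- tiny_model(use_transformer = FALSE)
  m_abl$params$encoder <- m$params$encoder
  m_abl$params$selector <- m$params$selector
  m_abl$params$head <- m$params$head
  fw_abl <- spliceformer_forward(m_abl, win, mode = "eval")
  expect_equal(fw_abl$track, predict_track(m_abl, E), tolerance = 1e-12)
})

test_that("model methods print, summarise and expose coefficients", {
  m <- tiny_model()
  expect_output(print(m), "untrained")
  expect_output(summary(m), "parameters")
  expect_named(coef(m), c("encoder", "selector", "transformer", "head"))
  expect_output(print(m$config), "receptive field")
})
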