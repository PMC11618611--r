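test_that("cross-entropy satisfies its closed-form identities", {
  ## perfect predictions give zero loss
  lab <- c(0L, 1L, 2L, 0L)
  expect_equal(cross_entropy_loss(lab, labels_to_onehot(lab)), 0)
  ## uniform predictions over N positions give N * log 3
  uni <- matrix(1 / 3, 5, 3)
  expect_equal(cross_entropy_loss(integer(5), uni), 5 * log(3))
  ## random 4-position case against an independent scalar-loop oracle
  set.seed(13)
  for (rep in 1:10) {
    P <- matrix(rexp(12), 4, 3); P <- P / rowSums(P)
    lab <- sample(0:2, 4, TRUE)
    Y <- labels_to_onehot(lab)
    oracle <- 0
    for (i in 1:4) for (j in 1:3) {
      oracle <- oracle - Y[i, j] * log(P[i, j])
    }
    expect_equal(cross_entropy_loss(lab, P), unname(oracle))
  }
  ## zero probability at a labelled class is clamped with a warning
  Pz <- rbind(c(1, 0, 0))
  expect_warning(v <- cross_entropy_loss(1L, Pz), "clamped")
  expect_equal(v, -log(1e-12))
})

test_that("rewards encode right-type +1, unannotated 0, wrong-type -1", {
  sel <- data.frame(pos = c(5L, 9L, 12L, 20L),
                    type = c("acceptor", "donor", "acceptor", "donor"),
                    logp = 0)
  lab <- integer(30)
  lab[5] <- 1L   # annotated acceptor, acceptor slot -> +1
  lab[9] <- 2L   # annotated donor, donor slot -> +1
  lab[12] <- 2L  # annotated donor, acceptor slot -> -1
  ## position 20 unannotated -> 0
  expect_equal(compute_rewards(sel, lab), c(1, 1, -1, 0))
})

test_that("policy loss reproduces hand arithmetic", {
  expect_equal(policy_loss(c(-1, -2), c(0, 0)), 0)
  expect_equal(policy_loss(log(1), 1), 0)
  ## probs (0.5, 0.25), rewards (+1, -1): -(ln .5 - ln .25) = -ln 2
  expect_equal(policy_loss(log(c(0.5, 0.25)), c(1, -1)), -log(2))
  ## trajectory averaging
  expect_equal(policy_loss(log(c(0.5, 0.25)), c(1, -1), S = 2), -log(2) / 2)
})

test_that("combined loss reduces and scales as specified", {
  expect_equal(combined_loss(1.7, 99, lambda = 0), 1.7)
  expect_equal(combined_loss(1.0, 2.0, lambda = 0.5), 2.0)
  ## published default scale
  expect_equal(formals(combined_loss)$lambda, 1e-6)
  expect_error(combined_loss(1, 1, lambda = -1))
})

test_that("learning rate ramps, holds and halves", {
  sch <- optimizer_schedule()
  expect_equal(learning_rate(0, 1, sch), 0)
  expect_equal(learning_rate(500, 1, sch), 0.001)
  expect_equal(learning_rate(2000, 3, sch), 0.002)
  ## halved per epoch after epoch 5
  expect_equal(learning_rate(2000, 6, sch), 0.001)
  expect_equal(learning_rate(2000, 8, sch), 0.00025)
  ## fine-tuning preset: 4 epochs at 2e-4, no warm-up, no halving
  ft <- finetune_schedule()
  expect_equal(ft$epochs, 4L)
  expect_equal(learning_rate(0, 1, ft), 2e-4)
  expect_equal(learning_rate(10, 4, ft), 2e-4)
})

test_that("REINFORCE gradient matches finite differences on a toy policy", {
  ## 3-action, 1-step softmax policy; Monte-Carlo average of the policy
  ## loss gradient must equal the gradient of expected reward
  theta <- c(0.3, -0.4, 0.1)
  reward <- c(1, -1, 0.5)
  p <- exp(theta) / sum(exp(theta))
  n <- 20000L
  set.seed(77)
  counts <- drop(rmultinom(1, n, p))
  ## gradient of the loss for drawing action a, via the package's replay
  grad_for <- function(a) {
    sel <- data.frame(pos = a, type = "acceptor", logp = log(p[a]))
    spliceformer:::.policy_logits_grad(cbind(theta, -1e9), sel, reward[a])[, 1]
  }
  mc <- Reduce(`+`, lapply(1:3, function(a) counts[a] * grad_for(a))) / n
  ## finite-difference gradient of expected reward J = sum_a p_a r_a
  J <- function(th) { pp <- exp(th) / sum(exp(th)); sum(pp * reward) }
  fd <- vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- 1e-6
    (J(theta + e) - J(theta - e)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(-mc - fd)) / max(abs(fd)), 0.05)
})

test_that("training-step gradients match finite differences", {
  ## end-to-end check through encoder, transformer and head on a frozen
  ## selector trajectory (cross-entropy path; policy loss checked above)
  cfg <- spliceformer_config(context = 60L, embed_dim = 4L,
                             block_plan = list(c(3L, 1L, 1L)),
                             slots = c(3L, 3L), n_layers = 1L, n_heads = 2L,
                             ff_dim = 8L)
  model <- spliceformer_init(cfg, seed = 3)
  win <- random_window(60, seed = 5)
  lab <- integer(60); lab[c(10, 30)] <- c(1L, 2L)
  loss_at <- function(params) {
    m <- model; m$params <- params
    set.seed(99)
    spliceformer:::.train_step(m, win, lab, lambda = 0)$ce / 60
  }
  set.seed(99)
  st <- spliceformer:::.train_step(model, win, lab, lambda = 0)
  paths <- list(list("encoder", "conv_in", "W"),
                list("encoder", "units", 1L, "conv1", "W"),
                list("encoder", "units", 1L, "bn2", "gamma"),
                list("transformer", 1L, "q", "W"),
                list("transformer", 1L, "g", "W"),
                list("transformer", 1L, "f1", "W"),
                list("transformer", 1L, "ln1", "gamma"),
                list("head", "W"))
  get_leaf <- function(tree, path) { for (p in path) tree <- tree[[p]]; tree }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1L) { tree[[path[[1L]]]] <- val; return(tree) }
    tree[[path[[1L]]]] <- set_leaf(tree[[path[[1L]]]], path[-1L], val)
    tree
  }
  eps <- 1e-5
  for (pth in paths) {
    g <- get_leaf(st$grads, pth)
    par <- get_leaf(model$params, pth)
    i <- which.max(abs(g))
    pp <- par; pp[i] <- pp[i] + eps
    pm <- par; pm[i] <- pm[i] - eps
    fd <- (loss_at(set_leaf(model$params, pth, pp)) -
             loss_at(set_leaf(model$params, pth, pm))) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("a short fit run decreases training loss and is reproducible", {
  sim <- generate_genome(n_genes = 5L,
                         chromosome_plan = c(chr2 = 80000L), seed = 21L)
  cfg <- scaled_config(context = 1000L, embed_dim = 8L,
                       block_plan = list(c(7L, 1L, 1L), c(7L, 3L, 1L)),
                       slots = c(8L, 8L), n_layers = 1L, n_heads = 2L,
                       ff_dim = 32L)
  sch <- optimizer_schedule(warmup_steps = 20L, epochs = 2L,
                            halve_after = Inf, batch_size = 4L)
  m <- spliceformer(sim, config = cfg, schedule = sch, seed = 2L,
                    windows_per_epoch = 40L, validation_fraction = 0)
  expect_true(m$trained)
  expect_equal(nrow(m$history), 2L)
  expect_lt(m$history$train_ce[2], m$history$train_ce[1])
  m2 <- spliceformer(sim, config = cfg, schedule = sch, seed = 2L,
                     windows_per_epoch = 40L, validation_fraction = 0)
  expect_equal(m$params$head, m2$params$head, tolerance = 1e-12)
  ## fine-tuning continues from the same weights for 4 more epochs
  ft <- fine_tune(m, sim, schedule = finetune_schedule(batch_size = 4L,
                                                       epochs = 1L),
                  seed = 3L, windows_per_epoch = 10L)
  expect_equal(nrow(ft$history), 3L)
})
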