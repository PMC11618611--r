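## Losses, reward assignment, AdamW with warm-up/halving schedule, and the
## training loop (including the fine-tuning preset).

#' Cross-entropy classification loss
#'
#' `-sum_i sum_j y_ij log p_ij` over a window: non-negative, and zero
#' exactly when the predictions equal the one-hot labels. Probabilities are
#' clamped at 1e-12 before the log (with a warning when a labelled class had
#' probability zero).
#'
#' @param labels Either an integer label vector (0 = no splice, 1 =
#'   acceptor, 2 = donor) or a length x 3 one-hot matrix.
#' @param predictions Length x 3 probability matrix.
#' @return Scalar loss (sum over positions).
#' @export
cross_entropy_loss <- function(labels, predictions) {
  Y <- if (is.matrix(labels)) labels else labels_to_onehot(labels)
  stopifnot(nrow(Y) == nrow(predictions))
  p_lab <- predictions[Y > 0]
  if (any(p_lab < 1e-12)) {
    warning("prediction of 0 at a labelled class; clamped at 1e-12")
  }
  -sum(log(pmax(p_lab, 1e-12)) * Y[Y > 0])
}

#' Per-step selector rewards
#'
#' An acceptor-slot selection of an annotated acceptor (or donor slot of an
#' annotated donor) earns +1; selecting an unannotated position earns 0, so
#' the policy is not penalised for exploring non-splice sites; selecting an
#' annotated site with the wrong slot type earns -1.
#'
#' @param selected A `selected_sites` data frame (window coordinates).
#' @param labels Integer label vector for the same window.
#' @return Numeric reward per selection step, in draw order.
#' @export
compute_rewards <- function(selected, labels) {
  lab <- labels[selected$pos]
  want <- ifelse(selected$type == "acceptor", 1L, 2L)
  other <- 3L - want
  ifelse(lab == want, 1, ifelse(lab == other, -1, 0))
}

#' REINFORCE policy loss
#'
#' `-(1/S) sum_s sum_t log pi(a_t | X, C_{t-1}) R_t` over the stored
#' selection log-probabilities and their rewards.
#'
#' @param selected A `selected_sites` data frame with a `logp` column, or a
#'   numeric vector of log-probabilities.
#' @param rewards Numeric reward per step.
#' @param S Number of trajectories averaged (default 1).
#' @return Scalar policy loss.
#' @export
policy_loss <- function(selected, rewards, S = 1L) {
  logp <- if (is.data.frame(selected)) selected$logp else selected
  stopifnot(length(logp) == length(rewards))
  -sum(logp * rewards) / S
}

#' Combined training loss
#'
#' `cross-entropy + lambda * policy loss`; during training `lambda` scales
#' the selector's REINFORCE term against the classification term.
#'
#' @param ce Cross-entropy loss.
#' @param pl Policy loss.
#' @param lambda Policy-loss scale (>= 0); the published full-scale value is
#'   1e-6.
#' @return Scalar combined loss.
#' @export
combined_loss <- function(ce, pl, lambda = 1e-6) {
  stopifnot(lambda >= 0)
  ce + lambda * pl
}

## gradient of policy_loss w.r.t. the logit matrix, replaying the masked
## sequential draws; selection indices are non-differentiable, so this is
## the only gradient path out of the policy loss (selector parameters only)
.policy_logits_grad <- function(logits, selected, rewards, S = 1L) {
  L <- nrow(logits)
  dlogits <- matrix(0, L, 2L)
  mask <- rep(FALSE, L)
  for (t in seq_len(nrow(selected))) {
    cur <- if (selected$type[t] == "acceptor") 1L else 2L
    if (rewards[t] != 0) {
      p <- .masked_softmax(logits[, cur], mask)
      e <- numeric(L); e[selected$pos[t]] <- 1
      dlogits[, cur] <- dlogits[, cur] - rewards[t] * (e - p)
    }
    mask[selected$pos[t]] <- TRUE
  }
  dlogits / S
}

## ---- optimizer -------------------------------------------------------------

#' Optimiser schedule
#'
#' AdamW with a linear learning-rate warm-up over the first `warmup_steps`
#' optimisation steps, the base rate through epoch `halve_after`, and
#' halving each subsequent epoch. Defaults are the published full-scale
#' settings.
#'
#' @param base_lr Base learning rate.
#' @param beta1,beta2,eps AdamW moment parameters.
#' @param weight_decay Decoupled weight decay.
#' @param warmup_steps Linear warm-up steps.
#' @param epochs Training epochs.
#' @param halve_after Last epoch at the base rate; afterwards the rate
#'   halves each epoch.
#' @param batch_size Windows per optimisation step.
#' @return List of class `optimizer_schedule`.
#' @export
optimizer_schedule <- function(base_lr = 0.002, beta1 = 0.9, beta2 = 0.999,
                               eps = 1e-8, weight_decay = 1e-5,
                               warmup_steps = 1000L, epochs = 10L,
                               halve_after = 5L, batch_size = 96L) {
  structure(list(base_lr = base_lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay,
                 warmup_steps = as.integer(warmup_steps),
                 epochs = as.integer(epochs), halve_after = halve_after,
                 batch_size = as.integer(batch_size)),
            class = "optimizer_schedule")
}

#' Fine-tuning schedule preset
#'
#' Four additional epochs at a 2e-4 learning rate, with no warm-up restart
#' and no halving; all weights stay trainable and the selector is not
#' re-initialised.
#'
#' @param base_lr,epochs,batch_size Overrides of the preset.
#' @param ... Further overrides passed to [optimizer_schedule()].
#' @return An `optimizer_schedule`.
#' @export
finetune_schedule <- function(base_lr = 2e-4, epochs = 4L, batch_size = 96L,
                              ...) {
  optimizer_schedule(base_lr = base_lr, epochs = epochs,
                     warmup_steps = 0L, halve_after = Inf,
                     batch_size = batch_size, ...)
}

#' Learning rate at a given step and epoch
#'
#' Linear ramp from 0 to the base rate over `warmup_steps`, then the base
#' rate through epoch `halve_after`, halved each subsequent epoch.
#'
#' @param step Global optimisation step (0-based at the ramp start).
#' @param epoch Training epoch (1-based).
#' @param schedule An [optimizer_schedule()].
#' @return Learning rate.
#' @export
learning_rate <- function(step, epoch, schedule = optimizer_schedule()) {
  stopifnot(step >= 0)
  ramp <- if (schedule$warmup_steps > 0L) {
    min(step / schedule$warmup_steps, 1)
  } else 1
  decay <- if (epoch > schedule$halve_after) {
    0.5^(epoch - schedule$halve_after)
  } else 1
  schedule$base_lr * ramp * decay
}

.adamw_step <- function(params, grads, state, lr, schedule) {
  state$t <- (state$t %||% 0L) + 1L
  t <- state$t
  b1 <- schedule$beta1; b2 <- schedule$beta2
  res <- .tree_map(params, grads, state$tree, function(par, g, st) {
    if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    mhat <- st$m / (1 - b1^t)
    vhat <- st$v / (1 - b2^t)
    par <- par - lr * (mhat / (sqrt(vhat) + schedule$eps) +
                         schedule$weight_decay * par)
    list(par = par, state = st)
  })
  state$tree <- res$state
  list(params = res$par, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- one training step on one window ---------------------------------------

## forward + backward; cross-entropy gradients are normalised per position
## (mean CE drives the optimiser; the reported CE is the summed form)
.train_step <- function(model, window, labels, lambda, baseline = NULL) {
  config <- model$config
  L <- nrow(window)
  ef <- encode_forward(model$params, config, window, train = TRUE)
  model$params <- ef$params  # batch-norm running stats
  E <- ef$E
  ## selector forward with cache
  sel <- model$params$selector
  s1 <- linear_forward(sel$lin1, E)
  sa <- leaky_relu_forward(s1$Y)
  s2 <- linear_forward(sel$lin2, sa$Y)
  logits <- s2$Y
  sites <- sample_sites(logits, config$slots)
  rewards <- compute_rewards(sites, labels)
  pl <- policy_loss(sites, rewards)
  ## optional variance-reduction baseline: subtracted from the rewards in
  ## the gradient estimator only (off by default)
  rewards_g <- if (is.null(baseline)) rewards else rewards - baseline(rewards)
  ## prediction paths
  Y <- labels_to_onehot(labels)
  head_par <- model$params$head
  Z_raw <- .add_col(E %*% head_par$W, head_par$b)
  use_tf <- config$use_transformer && nrow(sites) > 0L
  if (use_tf) {
    tf <- .tf_forward(model$params, config, E[sites$pos, , drop = FALSE],
                      sites$pos)
    Z_sel <- .add_col(tf$Y %*% head_par$W, head_par$b)
  }
  P <- softmax_rows(Z_raw)
  if (use_tf) P[sites$pos, ] <- softmax_rows(Z_sel)
  ce <- cross_entropy_loss(Y, P)
  ## backward: dZ = (P - Y) / L at every position
  dZ <- (P - Y) / L
  dE <- matrix(0, L, config$embed_dim)
  gh <- list(W = matrix(0, config$embed_dim, 3L), b = colSums(dZ))
  unsel <- rep(TRUE, L)
  g_tf <- NULL
  if (use_tf) {
    unsel[sites$pos] <- FALSE
    dZ_sel <- dZ[sites$pos, , drop = FALSE]
    gh$W <- gh$W + crossprod(tf$Y, dZ_sel)
    dT <- dZ_sel %*% t(head_par$W)
    tb <- .tf_backward(model$params, config, tf$caches, dT)
    g_tf <- tb$grads
    dE[sites$pos, ] <- dE[sites$pos, ] + tb$dX
  }
  dZ_raw <- dZ[unsel, , drop = FALSE]
  gh$W <- gh$W + crossprod(E[unsel, , drop = FALSE], dZ_raw)
  dE[unsel, ] <- dE[unsel, ] + dZ_raw %*% t(head_par$W)
  ## policy gradients -> selector parameters only
  dlogits <- lambda * .policy_logits_grad(logits, sites, rewards_g)
  b2g <- linear_backward(sel$lin2, s2$cache, dlogits)
  dH <- leaky_relu_backward(sa$cache, b2g$dX)
  b1g <- linear_backward(sel$lin1, s1$cache, dH)
  g_sel <- list(lin1 = b1g$grads, lin2 = b2g$grads)
  ## encoder
  eb <- encode_backward(model$params, config, ef$cache, dE)
  grads <- list(encoder = eb$grads, selector = g_sel, head = gh)
  if (use_tf) grads$transformer <- g_tf
  list(model = model, grads = grads, ce = ce, pl = pl,
       reward = sum(rewards))
}

## ---- window sampling --------------------------------------------------------

## one window spec: chrom, strand, forward start; background windows are
## drawn only from the training chromosomes -- a held-out chromosome must
## never contribute labels, not even implicit no-splice ones
.sample_window <- function(store, transcripts, context,
                           background_fraction, chroms = names(store$seq)) {
  if (length(transcripts) == 0L || stats::runif(1L) < background_fraction) {
    cn <- if (length(chroms) == 1L) chroms else sample(chroms, 1L)
    list(chrom = cn, strand = sample(c("+", "-"), 1L),
         start = sample.int(max(store$lengths[[cn]] - context, 1L), 1L))
  } else {
    tr <- transcripts[[sample.int(length(transcripts), 1L)]]
    lo <- min(tr$exons); hi <- max(tr$exons)
    center <- round(stats::runif(1L, lo, hi))
    list(chrom = tr$chromosome, strand = tr$strand,
         start = max(center - context %/% 2L, 1L))
  }
}

.window_ce <- function(model, store, sites, spec, context) {
  oh <- one_hot_encode(extract_window(store, spec$chrom, spec$start, context,
                                      spec$strand))
  lab <- .window_labels(sites, spec$chrom, spec$start, context, spec$strand)
  fw <- spliceformer_forward(model, oh, mode = "eval")
  cross_entropy_loss(lab, fw$track) / context
}

## ---- fit --------------------------------------------------------------------

#' Fit a splice site prediction model
#'
#' Trains the three-part network (encoder, hard-attention selector,
#' gated transformer) on windows drawn from the training transcripts, with
#' the combined loss `cross-entropy + lambda * policy loss`, one sampled
#' selector trajectory per window, and AdamW under the given schedule.
#' Transcripts on the held-out chromosomes are never seen during training; a
#' seeded fraction of the remainder is set aside for per-epoch validation
#' cross-entropy.
#'
#' @param genome A [genome_store] (or a `synthetic_genome`, whose store and
#'   transcripts are used).
#' @param transcripts A `transcript_set`; ignored when `genome` is a
#'   `synthetic_genome`.
#' @param config A [spliceformer_config()].
#' @param schedule An [optimizer_schedule()].
#' @param lambda Policy-loss scale.
#' @param n_inits Number of independently initialised models to train (the
#'   published procedure uses ten); with `n_inits > 1` a
#'   `spliceformer_ensemble` is returned.
#' @param seed Integer seed governing weight initialisation, the
#'   train/validation split and window sampling.
#' @param windows_per_epoch Training windows per epoch (default
#'   `20 * n_transcripts`, at least 120).
#' @param background_fraction Fraction of windows drawn uniformly from the
#'   genome rather than centred on a training transcript, so intergenic
#'   sequence (including any decoy motifs) contributes labels.
#' @param validation_fraction Fraction of non-held-out transcripts reserved
#'   for validation.
#' @param holdout Held-out (test) chromosome names, never trained on.
#' @param keep_best Restore the parameters of the epoch with the lowest
#'   validation cross-entropy at the end of training.
#' @param baseline Optional variance-reduction baseline for the policy
#'   gradient: a function of the window's reward vector returning the
#'   scalar subtracted from every reward in the gradient estimator.
#'   `NULL` (the default) matches the published procedure (no baseline).
#' @param verbose Print per-epoch progress.
#' @return A trained `spliceformer` (or `spliceformer_ensemble`), with a
#'   `history` data frame of per-epoch training and validation
#'   cross-entropy per position and selector reward.
#' @export
spliceformer <- function(genome, transcripts = NULL,
                         config = spliceformer_config(),
                         schedule = optimizer_schedule(), lambda = 1e-6,
                         n_inits = 1L, seed = 1L,
                         windows_per_epoch = NULL,
                         background_fraction = 0.3,
                         validation_fraction = 0.1,
                         holdout = c("1", "3", "5", "7", "9"),
                         keep_best = TRUE, baseline = NULL,
                         verbose = FALSE) {
  if (inherits(genome, "synthetic_genome")) {
    transcripts <- genome$transcripts
    genome <- genome$store
  }
  stopifnot(inherits(genome, "genome_store"),
            inherits(transcripts, "transcript_set"))
  if (n_inits > 1L) {
    models <- lapply(seq_len(n_inits), function(i) {
      spliceformer(genome, transcripts, config, schedule, lambda,
                   n_inits = 1L, seed = seed + 7919L * (i - 1L),
                   windows_per_epoch = windows_per_epoch,
                   background_fraction = background_fraction,
                   validation_fraction = validation_fraction,
                   holdout = holdout, keep_best = keep_best,
                   baseline = baseline, verbose = verbose)
    })
    return(structure(models, class = "spliceformer_ensemble"))
  }
  split <- split_by_chromosome(transcripts, validation_fraction, seed,
                               holdout)
  model <- spliceformer_init(config, seed)
  model <- .fit_loop(model, genome, split$train, split$validation, schedule,
                     lambda, seed, windows_per_epoch, background_fraction,
                     keep_best, baseline, verbose)
  model$holdout <- holdout
  model
}

#' Fine-tune a trained model
#'
#' Continues training an existing model's weights (selector included, no
#' re-initialisation) under the fine-tuning preset: by default four epochs
#' at learning rate 2e-4 with no warm-up.
#'
#' @param model A trained `spliceformer`.
#' @param genome A [genome_store] or `synthetic_genome`.
#' @param transcripts A `transcript_set` carrying the (possibly RNA-Seq
#'   derived) splice site annotations to fine-tune on.
#' @param schedule An [optimizer_schedule()], default [finetune_schedule()].
#' @param lambda Policy-loss scale.
#' @param seed Integer seed.
#' @param ... Passed to the internal training loop (`windows_per_epoch`,
#'   `background_fraction`, `verbose`).
#' @return The fine-tuned `spliceformer`.
#' @export
fine_tune <- function(model, genome, transcripts = NULL,
                      schedule = finetune_schedule(), lambda = 1e-6,
                      seed = 1L, ...) {
  if (inherits(genome, "synthetic_genome")) {
    transcripts <- genome$transcripts
    genome <- genome$store
  }
  split <- split_by_chromosome(transcripts, 0.1, seed,
                               model$holdout %||% c("1", "3", "5", "7", "9"))
  .fit_loop(model, genome, split$train, split$validation, schedule, lambda,
            seed, ...)
}

.fit_loop <- function(model, genome, train_tr, val_tr, schedule, lambda,
                      seed, windows_per_epoch = NULL,
                      background_fraction = 0.3, keep_best = TRUE,
                      baseline = NULL, verbose = FALSE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 104729L)
  context <- model$config$context
  sites_train <- splice_sites(train_tr)
  sites_val <- splice_sites(val_tr)
  train_chroms <- unique(vapply(train_tr, `[[`, "", "chromosome"))
  sites_all <- rbind(sites_train, sites_val)  # labels visible to both
  if (is.null(windows_per_epoch)) {
    windows_per_epoch <- max(120L, 20L * length(train_tr))
  }
  ## fixed validation windows: one centred on each validation transcript
  val_specs <- lapply(val_tr, function(tr) {
    list(chrom = tr$chromosome, strand = tr$strand,
         start = max((min(tr$exons) + max(tr$exons)) %/% 2L -
                       context %/% 2L, 1L))
  })
  state <- list()
  step <- 0L
  hist <- list()
  best_val <- Inf
  best_params <- NULL
  for (epoch in seq_len(schedule$epochs)) {
    ep_ce <- 0; ep_pl <- 0; ep_rew <- 0; nw <- 0L
    batch_grads <- NULL; in_batch <- 0L
    for (w in seq_len(windows_per_epoch)) {
      spec <- .sample_window(genome, train_tr, context, background_fraction,
                             train_chroms)
      oh <- one_hot_encode(extract_window(genome, spec$chrom, spec$start,
                                          context, spec$strand))
      lab <- .window_labels(sites_train, spec$chrom, spec$start, context,
                            spec$strand)
      st <- .train_step(model, oh, lab, lambda, baseline)
      model <- st$model
      batch_grads <- .tree_add(batch_grads, st$grads)
      in_batch <- in_batch + 1L
      ep_ce <- ep_ce + st$ce / context; ep_pl <- ep_pl + st$pl
      ep_rew <- ep_rew + st$reward; nw <- nw + 1L
      if (in_batch == schedule$batch_size || w == windows_per_epoch) {
        lr <- learning_rate(step, epoch, schedule)
        upd <- .adamw_step(model$params,
                           .tree_scale(batch_grads, 1 / in_batch),
                           state, lr, schedule)
        model$params <- upd$params
        state <- upd$state
        step <- step + 1L
        batch_grads <- NULL; in_batch <- 0L
      }
    }
    val_ce <- if (length(val_specs)) {
      mean(vapply(val_specs, function(sp) {
        .window_ce(model, genome, sites_all, sp, context)
      }, numeric(1)))
    } else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, train_ce = ep_ce / nw,
                                val_ce = val_ce, policy_loss = ep_pl / nw,
                                mean_reward = ep_rew / nw)
    ## checkpoint selection is restricted to the cool-down epochs (after
    ## the halving point): earlier epochs can minimise validation CE while
    ## the REINFORCE selector is still warming up
    cooled <- !is.finite(schedule$halve_after) ||
      epoch > min(schedule$halve_after, schedule$epochs - 2L)
    if (keep_best && cooled && !is.na(val_ce) && val_ce < best_val) {
      best_val <- val_ce
      best_params <- model$params
    }
    if (verbose) {
      message(sprintf(
        "epoch %d: train CE/pos %.4f, val CE/pos %s, mean reward %.1f",
        epoch, ep_ce / nw,
        if (is.na(val_ce)) "NA" else sprintf("%.4f", val_ce), ep_rew / nw))
    }
  }
  model$history <- rbind(model$history, do.call(rbind, hist))
  if (keep_best && !is.null(best_params)) model$params <- best_params
  model$trained <- TRUE
  model
}
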