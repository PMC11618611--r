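## Metrics and analyses: PR-AUC, top-k accuracy with exact-k thresholding,
## bootstrap confidence intervals, total variation distance disagreement
## sets, ensemble averaging, and attention summaries.

.metric_result <- function(name, estimate, ci = NULL, n = NA_integer_,
                           k = NA_integer_, threshold = NA_real_) {
  structure(list(name = name, estimate = estimate, ci = ci, n = n, k = k,
                 threshold = threshold),
            class = "splice_metric")
}

#' @export
print.splice_metric <- function(x, ...) {
  ci <- if (!is.null(x$ci)) sprintf(" [%.3f, %.3f]", x$ci[1L], x$ci[2L]) else ""
  cat(sprintf("%s: %.4f%s (n = %s%s)\n", x$name, x$estimate, ci, x$n,
              if (!is.na(x$k)) sprintf(", k = %d", x$k) else ""))
  invisible(x)
}

#' @export
as.double.splice_metric <- function(x, ...) x$estimate

#' Area under the precision-recall curve
#'
#' Step interpolation (average-precision convention): the area is
#' `sum_i (R_i - R_{i-1}) P_i` over descending unique score thresholds.
#'
#' @param scores Numeric score per position.
#' @param labels Binary labels (0/1 or logical).
#' @param ci Also compute a bootstrap confidence interval.
#' @param n_boot,seed Bootstrap settings (positions are resampled).
#' @return A `splice_metric` with the PR-AUC estimate.
#' @export
pr_auc <- function(scores, labels, ci = FALSE, n_boot = 1000L, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  if (sum(labels) == 0L) stop("PR-AUC undefined: no positive labels")
  if (sum(labels) == length(labels)) stop("PR-AUC undefined: no negatives")
  est <- .pr_auc_value(scores, labels)
  interval <- NULL
  if (ci) {
    dat <- cbind(scores, labels)
    interval <- bootstrap_ci(function(d) {
      if (sum(d[, 2L]) %in% c(0L, nrow(d))) return(NA_real_)
      .pr_auc_value(d[, 1L], d[, 2L])
    }, dat, n_boot = n_boot, seed = seed)
  }
  .metric_result("PR-AUC", est, interval, n = length(labels),
                 k = sum(labels))
}

.pr_auc_value <- function(scores, labels) {
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  ## evaluate at the last index of each tied score block
  last <- which(s != c(s[-1L], NA) | seq_along(s) == length(s))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / sum(labels)
  sum(diff(c(0, rec)) * prec)
}

#' Top-k accuracy with exact-k thresholding
#'
#' The fraction of the `k` highest-scored positions that are true positives,
#' where `k` equals the number of true positives and the decision threshold
#' is the realised k-th score, so that exactly `k` positions are predicted.
#' Ties at the k-th score break towards the lower position index.
#'
#' @param scores Numeric score per position.
#' @param labels Binary labels; `k` must equal `sum(labels)`.
#' @param k Number of positives (defaults to `sum(labels)`).
#' @param ci,n_boot,seed Bootstrap settings.
#' @return A `splice_metric` with the accuracy estimate and the realised
#'   decision threshold.
#' @export
top_k_accuracy <- function(scores, labels, k = NULL, ci = FALSE,
                           n_boot = 1000L, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  if (is.null(k)) k <- sum(labels)
  if (k > length(scores)) stop("k exceeds the number of positions")
  if (k < 1L) stop("k must be at least 1")
  if (k != sum(labels)) {
    stop("k (", k, ") must equal the number of true positives (",
         sum(labels), ")")
  }
  ord <- order(-scores, seq_along(scores))
  est <- mean(labels[ord[seq_len(k)]])
  thr <- scores[ord[k]]
  interval <- NULL
  if (ci) {
    dat <- cbind(scores, labels)
    interval <- bootstrap_ci(function(d) {
      kk <- sum(d[, 2L])
      if (kk == 0L) return(NA_real_)
      oo <- order(-d[, 1L], seq_len(nrow(d)))
      mean(d[oo[seq_len(kk)], 2L])
    }, dat, n_boot = n_boot, seed = seed)
  }
  .metric_result("top-k accuracy", est, interval, n = length(labels), k = k,
                 threshold = thr)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (evaluation positions) with replacement and returns the
#' 2.5/97.5 percentile interval of the statistic over `n_boot` seeded
#' resamples.
#'
#' @param statistic Function of the resampled data returning a scalar.
#' @param data Matrix or data frame; rows are resampled.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param probs Interval probabilities.
#' @return Numeric `(lower, upper)`.
#' @export
bootstrap_ci <- function(statistic, data, n_boot = 1000L, seed = 1L,
                         probs = c(0.025, 0.975)) {
  stopifnot(n_boot >= 2L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(data)
  vals <- vapply(seq_len(n_boot), function(b) {
    statistic(data[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(1))
  unname(stats::quantile(vals, probs, na.rm = TRUE))
}

#' Total variation distance between discrete distributions
#'
#' `0.5 * sum |P(w) - Q(w)|` over the three-outcome sample space (no
#' splice, acceptor, donor); a metric on the probability simplex with
#' values in \[0, 1\].
#'
#' @param p,q Probability vectors, or matrices of per-position
#'   distributions (rowwise).
#' @return Scalar, or vector of per-position distances.
#' @export
tvd <- function(p, q) {
  if (is.matrix(p)) {
    stopifnot(all(dim(p) == dim(q)))
    0.5 * rowSums(abs(p - q))
  } else {
    0.5 * sum(abs(p - q))
  }
}

#' Positions where two prediction tracks disagree
#'
#' All and only the positions whose total variation distance between the
#' two per-position distributions reaches the threshold (default 0.1, the
#' disagreement cut-off used for model comparison).
#'
#' @param track_a,track_b Length x 3 probability matrices of equal length.
#' @param threshold Minimum TVD to call a disagreement.
#' @return List of class `disagreement_set` with `positions` and `tvd`
#'   (the distances at those positions).
#' @export
disagreement_set <- function(track_a, track_b, threshold = 0.1) {
  if (nrow(track_a) != nrow(track_b)) {
    stop("prediction tracks have different lengths")
  }
  d <- tvd(track_a, track_b)
  idx <- which(d >= threshold)
  structure(list(positions = idx, tvd = d[idx], threshold = threshold),
            class = "disagreement_set")
}

#' @export
print.disagreement_set <- function(x, ...) {
  cat(sprintf("disagreement_set: %d position(s) with TVD >= %.3g\n",
              length(x$positions), x$threshold))
  invisible(x)
}

#' Average prediction tracks over an ensemble
#'
#' Positionwise arithmetic mean; a convex combination of distributions, so
#' rows still sum to one.
#'
#' @param tracks List of length x 3 probability matrices of equal length.
#' @return The averaged track.
#' @export
ensemble_average <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  Reduce(`+`, tracks) / length(tracks)
}

#' Averaged attention matrices for a window
#'
#' Runs each model on the window in greedy (evaluation) mode, records the
#' post-softmax (pre-gating) attention matrix of every transformer layer and
#' head, and averages over layers, heads and models. The gate modulates the
#' value output, not the attention distribution, so rows of the average
#' still sum to one.
#'
#' @param models A `spliceformer`, a `spliceformer_ensemble`, or a list of
#'   models sharing a configuration.
#' @param window One-hot matrix (length x 4).
#' @return List with `attention` (n_sites x n_sites mean matrix) and
#'   `sites` (the greedy-selected sites per model).
#' @export
attention_summary <- function(models, window) {
  if (inherits(models, "spliceformer")) models <- list(models)
  mats <- list(); sites <- list()
  for (m in models) {
    stopifnot(m$config$use_transformer)
    fw <- spliceformer_forward(m, window, mode = "eval",
                               record_attention = TRUE)
    for (layer in fw$attention) for (A in layer) {
      mats[[length(mats) + 1L]] <- A
    }
    sites[[length(sites) + 1L]] <- fw$sites
  }
  list(attention = Reduce(`+`, mats) / length(mats), sites = sites)
}

## ---- genome-level evaluation -----------------------------------------------

## pool per-position scores and labels for one class over chromosomes and
## strands of a predicted track set
.pool_class <- function(tracks, sites, class_col, type) {
  scores <- numeric(0); labels <- integer(0)
  for (cn in names(tracks)) {
    for (st in names(tracks[[cn]])) {
      tr <- tracks[[cn]][[st]]
      ok <- !is.na(tr[, 1L])
      sc <- tr[ok, class_col]
      lab <- integer(sum(ok))
      sel <- sites[sites$chrom == cn & sites$strand == st &
                     sites$type == type, , drop = FALSE]
      pos_map <- which(ok)
      if (nrow(sel)) {
        hit <- match(sel$pos, pos_map)
        lab[hit[!is.na(hit)]] <- 1L
      }
      scores <- c(scores, sc); labels <- c(labels, lab)
    }
  }
  list(scores = scores, labels = labels)
}

#' Evaluate predictions against annotated splice sites
#'
#' Scores the requested chromosomes on both strands with
#' [predict.spliceformer()], pools per-position acceptor and donor scores,
#' and reports per-class and combined top-k accuracy plus the pooled PR-AUC
#' over both classes.
#'
#' @param model A trained `spliceformer` (or precomputed `tracks`).
#' @param genome A [genome_store] or `synthetic_genome`.
#' @param sites Splice-site table ([splice_sites()]); defaults to the
#'   synthetic genome's ground truth.
#' @param chroms Chromosomes to evaluate.
#' @param tracks Optional precomputed output of [predict.spliceformer()].
#' @return List with `top_k` (combined `splice_metric`), `top_k_acceptor`,
#'   `top_k_donor`, `pr_auc` (pooled), and the `tracks` used.
#' @export
evaluate_genome <- function(model, genome, sites = NULL, chroms = NULL,
                            tracks = NULL) {
  if (inherits(genome, "synthetic_genome")) {
    if (is.null(sites)) sites <- genome$sites
    genome <- genome$store
  }
  if (is.null(chroms)) chroms <- names(genome$seq)
  scan <- NULL
  if (is.null(tracks)) {
    scan <- .scan_genome(model, genome, chroms)
    tracks <- scan$tracks
  }
  acc <- .pool_class(tracks, sites, "acceptor", "acceptor")
  don <- .pool_class(tracks, sites, "donor", "donor")
  m_acc <- top_k_accuracy(acc$scores, acc$labels)
  m_don <- top_k_accuracy(don$scores, don$labels)
  k_tot <- m_acc$k + m_don$k
  combined <- (m_acc$estimate * m_acc$k + m_don$estimate * m_don$k) / k_tot
  pooled <- pr_auc(c(acc$scores, don$scores), c(acc$labels, don$labels))
  list(top_k = .metric_result("top-k accuracy (combined)", combined,
                              n = length(acc$scores) + length(don$scores),
                              k = k_tot),
       top_k_acceptor = m_acc, top_k_donor = m_don,
       pr_auc = pooled, tracks = tracks, scan = scan)
}

#' Greedy selector recall of annotated sites
#'
#' Tiles the chromosomes with model windows on both strands, collects the
#' greedy-selected positions (with slot type) from each window interior,
#' and reports the fraction of annotated splice sites recovered.
#'
#' @param model A trained `spliceformer`.
#' @param genome A [genome_store] or `synthetic_genome`.
#' @param sites Splice-site table; defaults to the synthetic ground truth.
#' @param chroms Chromosomes to evaluate.
#' @param scan Optional precomputed result of an internal genome scan (as
#'   stored in the `scan` element of [evaluate_genome()] output), reusing
#'   its tiled forward passes.
#' @return List with `recall`, the count `selected`, and the per-site hit
#'   indicator.
#' @export
selector_recall <- function(model, genome, sites = NULL, chroms = NULL,
                            scan = NULL) {
  if (inherits(genome, "synthetic_genome")) {
    if (is.null(sites)) sites <- genome$sites
    genome <- genome$store
  }
  if (is.null(chroms)) chroms <- names(genome$seq)
  if (is.null(scan)) scan <- .scan_genome(model, genome, chroms)
  sel <- sites[sites$chrom %in% chroms, , drop = FALSE]
  key <- paste(sel$chrom, sel$strand, sel$pos, sel$type, sep = ":")
  hit <- key %in% scan$picked
  list(recall = mean(hit), selected = length(scan$picked), hit = hit)
}

## ---- ensemble methods -------------------------------------------------------

#' @export
print.spliceformer_ensemble <- function(x, ...) {
  cat("spliceformer_ensemble:", length(x), "model(s)\n")
  print(x[[1L]]$config)
  invisible(x)
}

#' @export
predict.spliceformer_ensemble <- function(object, genome, chroms = NULL,
                                          strands = c("+", "-"), ...) {
  all_tracks <- lapply(object, function(m) {
    stats::predict(m, genome, chroms, strands, ...)
  })
  out <- all_tracks[[1L]]
  for (cn in names(out)) {
    for (st in names(out[[cn]])) {
      out[[cn]][[st]] <- ensemble_average(
        lapply(all_tracks, function(tt) tt[[cn]][[st]]))
    }
  }
  out
}
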