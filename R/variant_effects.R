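## Variant delta scores: the maximum absolute change in predicted acceptor
## or donor probability between the reference sequence and the
## variant-substituted sequence, plus a ClinVar-style labelling and
## classification harness.

.predict_window_fun <- function(model, context) {
  if (is.function(model)) {
    if (is.null(context)) stop("'context' must be given for a plug-in predictor")
    list(fun = function(s) model(s), context = context)
  } else if (inherits(model, "spliceformer_ensemble")) {
    ctx <- model[[1L]]$config$context
    list(fun = function(s) {
      ensemble_average(lapply(model, function(m) {
        spliceformer_forward(m, one_hot_encode(s), mode = "eval")$track
      }))
    }, context = ctx)
  } else {
    stopifnot(inherits(model, "spliceformer"))
    list(fun = function(s) {
      spliceformer_forward(model, one_hot_encode(s), mode = "eval")$track
    }, context = model$config$context)
  }
}

#' Delta score of a sequence variant
#'
#' Predicts splice probabilities for the reference window centred on the
#' variant and for the same window with the alternate allele substituted,
#' and reports the largest absolute acceptor/donor probability difference
#' within `scan_radius` nt of the variant. The sign and class of that
#' difference give the event type (acceptor/donor gain or loss). Simple
#' indels are handled by realigning the alternate track to reference
#' coordinates downstream of the edit. With `strands = c("+", "-")` both
#' orientations are scanned and the larger change wins.
#'
#' @param variant List or single-row data frame with `chrom`, `pos`
#'   (1-based), `ref`, `alt`.
#' @param genome A [genome_store].
#' @param model A trained `spliceformer`, a `spliceformer_ensemble`
#'   (per-model tracks are averaged before differencing), or a plug-in
#'   function mapping a window string to a length x 3 probability matrix.
#' @param scan_radius Scan half-width around the variant in nt.
#' @param context Window length; defaults to the model's context.
#' @param strands Strands to scan.
#' @return List of class `delta_score` with `score` (in \[0, 1\]), `event`
#'   (e.g. `"acceptor loss"`), `position` (genomic argmax), `strand`.
#' @export
delta_score <- function(variant, genome, model, scan_radius = 50L,
                        context = NULL, strands = c("+", "-")) {
  pw <- .predict_window_fun(model, context)
  context <- pw$context
  chrom <- variant$chrom; pos <- variant$pos
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  .check_chrom(genome, chrom)
  lr <- nchar(ref); la <- nchar(alt)
  stored <- extract_window(genome, chrom, pos, lr, "+")
  if (stored != ref) {
    stop("reference allele mismatch at ", chrom, ":", pos, " (genome has '",
         stored, "', variant says '", ref, "')")
  }
  start <- pos - context %/% 2L
  ref_win <- extract_window(genome, chrom, start, context + lr, "+")
  anchor <- pos - start + 1L
  alt_win <- paste0(substr(ref_win, 1L, anchor - 1L), alt,
                    substring(ref_win, anchor + lr))
  ref_win <- substr(ref_win, 1L, context)
  alt_win <- substr(alt_win, 1L, context)
  ## genomic coordinates comparable between ref and alt tracks
  g_all <- seq.int(pos - scan_radius, pos + scan_radius)
  i_ref <- g_all - start + 1L
  j_alt <- ifelse(g_all <= pos, g_all - start + 1L,
                  ifelse(g_all >= pos + lr, g_all - start + 1L + (la - lr),
                         NA_integer_))
  ok <- !is.na(j_alt) & i_ref >= 1L & i_ref <= context &
    j_alt >= 1L & j_alt <= context
  best <- list(score = 0, event = "none", position = NA_real_,
               strand = NA_character_)
  for (st in strands) {
    if (st == "+") {
      pr <- pw$fun(ref_win); pa <- pw$fun(alt_win)
      ir <- i_ref[ok]; ja <- j_alt[ok]
    } else {
      pr <- pw$fun(reverse_complement(ref_win))
      pa <- pw$fun(reverse_complement(alt_win))
      ir <- context + 1L - i_ref[ok]; ja <- context + 1L - j_alt[ok]
    }
    for (cls in c("acceptor", "donor")) {
      ci <- if (cls == "acceptor") 2L else 3L
      dd <- pa[ja, ci] - pr[ir, ci]
      w <- which.max(abs(dd))
      if (length(w) && abs(dd[w]) > best$score) {
        best <- list(score = abs(dd[w]),
                     event = paste(cls, if (dd[w] > 0) "gain" else "loss"),
                     position = g_all[ok][w], strand = st)
      }
    }
  }
  structure(best, class = "delta_score")
}

#' @export
print.delta_score <- function(x, ...) {
  cat(sprintf("delta score %.4f (%s at %s, strand %s)\n", x$score, x$event,
              format(x$position), x$strand))
  invisible(x)
}

#' Delta scores for a variant table
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `class`/`label` columns (carried through).
#' @inheritParams delta_score
#' @return The input data frame with `score`, `event` and `event_position`
#'   columns appended.
#' @export
score_variants <- function(variants, genome, model, scan_radius = 50L,
                           context = NULL, strands = c("+", "-")) {
  res <- lapply(seq_len(nrow(variants)), function(i) {
    delta_score(variants[i, ], genome, model, scan_radius, context, strands)
  })
  variants$score <- vapply(res, `[[`, numeric(1), "score")
  variants$event <- vapply(res, `[[`, character(1), "event")
  variants$event_position <- vapply(res, function(x) {
    as.numeric(x$position)
  }, numeric(1))
  variants
}

#' Label ClinVar-style variants from a VCF
#'
#' Variants whose clinical significance is pathogenic or likely pathogenic
#' are labelled `pathogenic`; benign or likely benign become `benign`; all
#' others (including records without a significance field) are excluded,
#' with the excluded count reported in a message.
#'
#' @param path Path to a VCF with `CLNSIG` INFO annotations.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `label`.
#' @export
label_clinvar <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required to read VCF files")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  sig <- vcfR::extract.info(vcf, element = "CLNSIG")
  norm <- tolower(sig)
  classify <- function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    parts <- strsplit(s, "[|/,]")[[1L]]
    parts <- trimws(parts[nzchar(parts)])
    if (all(parts %in% c("pathogenic", "likely_pathogenic"))) {
      "pathogenic"
    } else if (all(parts %in% c("benign", "likely_benign"))) {
      "benign"
    } else NA_character_
  }
  label <- vapply(norm, classify, character(1), USE.NAMES = FALSE)
  n_excl <- sum(is.na(label))
  if (n_excl > 0L) {
    message(n_excl, " variant(s) excluded (no pathogenic/benign significance)")
  }
  keep <- !is.na(label)
  data.frame(chrom = fix[keep, "CHROM"],
             pos = as.numeric(fix[keep, "POS"]),
             ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
             label = label[keep], stringsAsFactors = FALSE)
}

#' Classification performance of delta scores
#'
#' PR-AUC of the delta score for separating a positive from a negative
#' variant class, plus the fraction of each class detected at a decision
#' threshold.
#'
#' @param scored Data frame from [score_variants()] with a `score` column
#'   and a class column (`class` or `label`).
#' @param positives,negatives Class values treated as positive/negative.
#' @param threshold Decision threshold for the detection fractions.
#' @return List with `pr_auc` (a `splice_metric`) and `detection` (named
#'   fraction of each class scoring at or above the threshold).
#' @export
evaluate_variants <- function(scored, positives = "pathogenic",
                              negatives = "benign", threshold = 0.1) {
  cls <- if ("label" %in% names(scored)) scored$label else scored$class
  pos <- scored$score[cls %in% positives]
  neg <- scored$score[cls %in% negatives]
  if (!length(pos)) stop("no variants in the positive class")
  if (!length(neg)) stop("no variants in the negative class")
  auc <- pr_auc(c(pos, neg), rep(c(1L, 0L), c(length(pos), length(neg))))
  detection <- vapply(split(scored$score, cls),
                      function(s) mean(s >= threshold), numeric(1))
  list(pr_auc = auc, detection = detection)
}
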