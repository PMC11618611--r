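## RNA-Seq splice-junction pipeline: junction extraction from spliced
## alignments (CIGAR arithmetic) or pre-extracted evidence tables,
## per-individual and aggregate filters, grouping into sets of overlapping
## splice junctions (SOSJ), and percent-spliced-in (PSI) quantification.

.EVIDENCE_COLS <- c("individual", "chrom", "intron_start", "intron_end",
                    "strand", "left_overhang", "right_overhang",
                    "multimapped")

.junction_key <- function(df) {
  paste(df$chrom, df$intron_start, df$intron_end, df$strand, sep = ":")
}

#' Extract junction-supporting fragment evidence
#'
#' Accepts a fragment evidence data frame or TSV (columns `individual`,
#' `chrom`, `intron_start`, `intron_end`, `strand`, `left_overhang`,
#' `right_overhang`, `multimapped`), or spliced alignments in SAM/BAM from
#' which junctions are derived by CIGAR arithmetic: each `N` gap yields one
#' junction whose intron is the gapped reference interval and whose
#' overhangs are the reference-aligned lengths flanking the gap. Fragments
#' are deduplicated on (individual, read name, junction), so mates
#' supporting the same junction count once. The individual is taken from
#' the `RG` tag (falling back to the read-name prefix before `:`), the
#' multimapping flag from `NH > 1`, and the junction strand from the `XS`
#' tag. Malformed CIGAR strings are skipped with a warning.
#'
#' @param x Data frame, or path to a `.tsv`/`.sam`/`.bam` file (BAM needs
#'   the Rsamtools package).
#' @return Evidence data frame with the columns above.
#' @export
extract_junctions <- function(x) {
  if (is.data.frame(x)) {
    missing_cols <- setdiff(.EVIDENCE_COLS, names(x))
    if (length(missing_cols)) {
      stop("evidence table lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    return(x[, .EVIDENCE_COLS])
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("\\.sam$", x, ignore.case = TRUE)) {
    .junctions_from_sam(x)
  } else if (grepl("\\.bam$", x, ignore.case = TRUE)) {
    .junctions_from_bam(x)
  } else {
    ev <- utils::read.delim(x, stringsAsFactors = FALSE)
    extract_junctions(ev)
  }
}

## ref-consuming CIGAR walk; returns per-junction (start, end, left, right)
.cigar_junctions <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  cursor <- pos
  run <- 0L  # reference-aligned length since the last gap
  out <- NULL
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X", "D")) {
      cursor <- cursor + n[i]
      run <- run + n[i]
    } else if (op[i] == "N") {
      out <- rbind(out, c(start = cursor, end = cursor + n[i] - 1L,
                          left = run, right = 0L))
      cursor <- cursor + n[i]
      run <- 0L
    }
    ## I, S, H, P do not consume reference
  }
  if (!is.null(out)) {
    for (j in seq_len(nrow(out))) {
      out[j, "right"] <- if (j < nrow(out)) {
        out[j + 1L, "left"]
      } else run
    }
  }
  out
}

.alignment_evidence <- function(qname, rname, pos, cigar, rg, nh, xs) {
  rows <- list()
  for (i in seq_along(qname)) {
    jx <- tryCatch(.cigar_junctions(pos[i], cigar[i]), error = function(e) {
      warning(conditionMessage(e))
      NULL
    })
    if (is.null(jx)) next
    ind <- if (!is.na(rg[i])) rg[i] else sub(":.*$", "", qname[i])
    for (j in seq_len(nrow(jx))) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind, chrom = rname[i],
        intron_start = unname(jx[j, "start"]),
        intron_end = unname(jx[j, "end"]),
        strand = if (is.na(xs[i])) "*" else xs[i],
        left_overhang = unname(jx[j, "left"]),
        right_overhang = unname(jx[j, "right"]),
        multimapped = !is.na(nh[i]) && nh[i] > 1L,
        qname = qname[i], stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev)) {
    ev <- data.frame(individual = character(), chrom = character(),
                     intron_start = numeric(), intron_end = numeric(),
                     strand = character(), left_overhang = numeric(),
                     right_overhang = numeric(), multimapped = logical(),
                     qname = character())
  }
  ## fragment-level dedup: mates supporting the same junction count once
  dup <- duplicated(ev[, c("individual", "qname", "chrom", "intron_start",
                           "intron_end")])
  ev <- ev[!dup, .EVIDENCE_COLS]
  rownames(ev) <- NULL
  ev
}

.junctions_from_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  tag <- function(fields, prefix) {
    hit <- fields[startsWith(fields, prefix)]
    if (length(hit)) sub(prefix, "", hit[[1L]], fixed = TRUE) else NA_character_
  }
  .alignment_evidence(
    qname = vapply(f, `[[`, "", 1L),
    rname = vapply(f, `[[`, "", 3L),
    pos = as.integer(vapply(f, `[[`, "", 4L)),
    cigar = vapply(f, `[[`, "", 6L),
    rg = vapply(f, tag, "", "RG:Z:"),
    nh = as.integer(vapply(f, tag, "", "NH:i:")),
    xs = vapply(f, tag, "", "XS:A:"))
}

.junctions_from_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("package 'Rsamtools' is required to read BAM files")
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "cigar"),
                               tag = c("RG", "NH", "XS"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  .alignment_evidence(qname = b$qname, rname = as.character(b$rname),
                      pos = b$pos, cigar = b$cigar,
                      rg = as.character(b$tag$RG %||% rep(NA, length(b$pos))),
                      nh = as.integer(b$tag$NH %||% rep(NA, length(b$pos))),
                      xs = as.character(b$tag$XS %||% rep(NA, length(b$pos))))
}

#' Base-2 Shannon entropy of pooled overhang lengths
#'
#' The empirical distribution pools all observed left and right overhang
#' lengths of a junction in one individual.
#'
#' @param left,right Overhang length vectors.
#' @return Entropy in bits.
#' @export
overhang_entropy <- function(left, right) {
  p <- table(c(left, right))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Per-individual junction filter
#'
#' A junction passes for one individual iff (1) at least 4 fragments map to
#' it, (2) the maximum over fragments of the shorter overhang exceeds 7 nt,
#' (3) the base-2 entropy of the pooled left/right overhang lengths is at
#' least 2 bits, and (4) the donor or acceptor side lies within an
#' annotated gene boundary (skipped when `gene_bounds` is `NULL`).
#'
#' @param evidence Fragment evidence rows for one junction and one
#'   individual.
#' @param gene_bounds Optional data frame with `chrom`, `start`, `end` gene
#'   intervals.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed criteria among `"fragment_count"`, `"overhang"`, `"entropy"`,
#'   `"gene_boundary"`).
#' @export
filter_individual <- function(evidence, gene_bounds = NULL) {
  reasons <- character(0)
  if (nrow(evidence) < 4L) reasons <- c(reasons, "fragment_count")
  if (nrow(evidence) == 0L ||
      max(pmin(evidence$left_overhang, evidence$right_overhang)) <= 7) {
    reasons <- c(reasons, "overhang")
  }
  if (nrow(evidence) == 0L ||
      overhang_entropy(evidence$left_overhang, evidence$right_overhang) < 2) {
    reasons <- c(reasons, "entropy")
  }
  if (!is.null(gene_bounds) && nrow(evidence)) {
    gb <- gene_bounds[gene_bounds$chrom == evidence$chrom[1L], , drop = FALSE]
    s <- evidence$intron_start[1L]; e <- evidence$intron_end[1L]
    inside <- nrow(gb) > 0L &&
      any((s >= gb$start & s <= gb$end) | (e >= gb$start & e <= gb$end))
    if (!inside) reasons <- c(reasons, "gene_boundary")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Aggregate junction filter
#'
#' Pooled over the individuals that passed the per-individual filter, a
#' junction fails if more than 20% of its alignments are multimapped, or if
#' its maximum per-individual fragment count is less than 5% of the
#' expected transcript abundance. Failure requires strict violation:
#' exactly 20% multimapping or exactly 5% of abundance still passes. A
#' missing abundance skips the abundance test.
#'
#' @param summary List or single-row data frame with `multimapped_fraction`
#'   and `max_count`.
#' @param abundance Expected transcript abundance for the junction, or `NA`.
#' @param multimap_max,abundance_min_fraction Thresholds.
#' @return List with `pass` and `reasons` (among `"multimapped_fraction"`,
#'   `"abundance"`).
#' @export
filter_aggregate <- function(summary, abundance = NA_real_,
                             multimap_max = 0.2,
                             abundance_min_fraction = 0.05) {
  reasons <- character(0)
  if (summary$multimapped_fraction > multimap_max) {
    reasons <- c(reasons, "multimapped_fraction")
  }
  if (!is.na(abundance) && summary$max_count < abundance_min_fraction *
        abundance) {
    reasons <- c(reasons, "abundance")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Group junctions into sets of overlapping splice junctions (SOSJ)
#'
#' Connected components of the graph whose nodes are junctions and whose
#' edges join two junctions sharing a donor or an acceptor coordinate
#' (same chromosome and strand), transitively closed.
#'
#' @param junctions Data frame with `chrom`, `intron_start`, `intron_end`,
#'   `strand` (unique junctions).
#' @return Integer SOSJ id per junction row.
#' @export
group_sosj <- function(junctions) {
  n <- nrow(junctions)
  if (n == 0L) return(integer(0))
  keys <- .junction_key(junctions)
  stopifnot(!anyDuplicated(keys))
  edges <- NULL
  for (side in c("intron_start", "intron_end")) {
    grp <- split(seq_len(n), paste(junctions$chrom, junctions$strand,
                                   junctions[[side]]))
    for (g in grp) {
      if (length(g) > 1L) {
        edges <- rbind(edges, cbind(keys[g[1L]], keys[g[-1L]]))
      }
    }
  }
  gr <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = character(0),
                                       to = character(0)) else
      data.frame(from = edges[, 1L], to = edges[, 2L]),
    directed = FALSE, vertices = data.frame(name = keys))
  memb <- igraph::components(gr)$membership
  as.integer(memb[keys])
}

#' Percent spliced in (PSI)
#'
#' For each individual, a junction's PSI is its fragment count divided by
#' the total fragment count over its SOSJ; when the denominator is zero the
#' value is missing (`NA`), not zero.
#'
#' @param counts Junction x individual fragment count matrix.
#' @param sosj Integer SOSJ id per junction row (e.g. from [group_sosj()]).
#' @return PSI matrix of the same shape.
#' @export
compute_psi <- function(counts, sosj) {
  stopifnot(all(counts >= 0, na.rm = TRUE), nrow(counts) == length(sosj))
  psi <- counts
  for (g in unique(sosj)) {
    rows <- which(sosj == g)
    tot <- colSums(counts[rows, , drop = FALSE])
    denom <- matrix(tot, length(rows), length(tot), byrow = TRUE)
    psi[rows, ] <- ifelse(denom > 0, counts[rows, , drop = FALSE] / denom,
                          NA_real_)
  }
  psi
}

#' Flag junctions present in a reference annotation
#'
#' A junction is annotated iff both its donor and acceptor coordinates
#' match an intron of a reference transcript exactly.
#'
#' @param junctions Data frame with `chrom`, `intron_start`, `intron_end`.
#' @param reference A `transcript_set`, or data frame with `chrom`,
#'   `start`, `end` intron intervals.
#' @return Logical vector per junction row.
#' @export
annotate_junctions <- function(junctions, reference) {
  if (inherits(reference, "transcript_set")) {
    reference <- transcript_introns(reference)
  }
  if (nrow(reference) == 0L) return(rep(FALSE, nrow(junctions)))
  ref_key <- paste(reference$chrom, reference$start, reference$end)
  paste(junctions$chrom, junctions$intron_start, junctions$intron_end) %in%
    ref_key
}

#' Run the full junction filtering pipeline
#'
#' Normalises the fragment evidence, applies the per-individual criteria
#' (a junction is retained when at least one individual fulfils all four),
#' pools the passing individuals for the aggregate multimapping and
#' abundance filters, groups the surviving junctions into SOSJ, and
#' computes per-individual PSI.
#'
#' @param evidence Anything accepted by [extract_junctions()].
#' @param gene_bounds Optional gene interval data frame (`chrom`, `start`,
#'   `end`, optionally `gene_id`) for criterion (4) and for the default
#'   abundance estimate.
#' @param reference Optional reference annotation for [annotate_junctions()].
#' @param abundance Optional named vector of expected transcript abundance
#'   per junction key (`chrom:start:end:strand`). When `NULL` and
#'   `gene_bounds` has a `gene_id` column, each junction's abundance
#'   defaults to the median max fragment count over its gene's
#'   stage-one-passing junctions; otherwise the abundance test is skipped.
#' @return List of class `junction_summary` with elements `junctions` (one
#'   row per junction: coordinates, pooled statistics, verdicts with
#'   reasons, SOSJ id, annotated flag), `psi` (junction x individual matrix
#'   over passing junctions) and `evidence`.
#' @export
junction_pipeline <- function(evidence, gene_bounds = NULL, reference = NULL,
                              abundance = NULL) {
  ev <- extract_junctions(evidence)
  key <- .junction_key(ev)
  jx <- ev[!duplicated(key), c("chrom", "intron_start", "intron_end",
                               "strand")]
  jx$key <- key[!duplicated(key)]
  rownames(jx) <- NULL
  split_key <- split(seq_len(nrow(ev)), key)

  res <- lapply(jx$key, function(k) {
    rows <- ev[split_key[[k]], , drop = FALSE]
    by_ind <- split(rows, rows$individual)
    verdicts <- lapply(by_ind, filter_individual, gene_bounds = gene_bounds)
    pass_ind <- vapply(verdicts, `[[`, logical(1), "pass")
    reasons <- unique(unlist(lapply(verdicts, `[[`, "reasons")))
    passing <- rows[rows$individual %in% names(by_ind)[pass_ind], ,
                    drop = FALSE]
    counts_pass <- if (nrow(passing)) table(passing$individual) else
      integer(0)
    list(pass_individual = any(pass_ind),
         reasons_individual = reasons,
         multimapped_fraction = if (nrow(passing)) {
           mean(passing$multimapped)
         } else NA_real_,
         max_count = if (length(counts_pass)) max(counts_pass) else 0L,
         counts_all = table(rows$individual))
  })
  jx$pass_individual <- vapply(res, `[[`, logical(1), "pass_individual")
  jx$multimapped_fraction <- vapply(res, `[[`, numeric(1),
                                    "multimapped_fraction")
  jx$max_count <- vapply(res, function(r) as.numeric(r$max_count),
                         numeric(1))

  ## expected transcript abundance
  jx$gene <- NA_character_
  if (!is.null(gene_bounds) && "gene_id" %in% names(gene_bounds)) {
    for (i in seq_len(nrow(jx))) {
      gb <- gene_bounds[gene_bounds$chrom == jx$chrom[i], , drop = FALSE]
      hit <- which((jx$intron_start[i] >= gb$start &
                      jx$intron_start[i] <= gb$end) |
                     (jx$intron_end[i] >= gb$start &
                        jx$intron_end[i] <= gb$end))
      if (length(hit)) jx$gene[i] <- gb$gene_id[hit[1L]]
    }
  }
  jx$abundance <- NA_real_
  if (!is.null(abundance)) {
    jx$abundance <- unname(abundance[jx$key])
  } else if (any(!is.na(jx$gene))) {
    for (g in unique(stats::na.omit(jx$gene))) {
      rows <- which(jx$gene == g & jx$pass_individual)
      if (length(rows)) {
        jx$abundance[jx$gene == g] <- stats::median(jx$max_count[rows])
      }
    }
  }

  agg <- lapply(seq_len(nrow(jx)), function(i) {
    if (!jx$pass_individual[i]) {
      return(list(pass = FALSE, reasons = character(0)))
    }
    filter_aggregate(jx[i, ], jx$abundance[i])
  })
  jx$pass_aggregate <- vapply(agg, `[[`, logical(1), "pass")
  jx$pass <- jx$pass_individual & jx$pass_aggregate
  jx$reasons <- vapply(seq_len(nrow(jx)), function(i) {
    paste(c(if (!jx$pass_individual[i]) res[[i]]$reasons_individual,
            agg[[i]]$reasons), collapse = ",")
  }, character(1))
  if (!is.null(reference)) {
    jx$annotated <- annotate_junctions(
      data.frame(chrom = jx$chrom, intron_start = jx$intron_start,
                 intron_end = jx$intron_end), reference)
  }

  ## SOSJ and PSI over passing junctions
  pass_idx <- which(jx$pass)
  jx$sosj_id <- NA_integer_
  psi <- NULL
  if (length(pass_idx)) {
    jx$sosj_id[pass_idx] <- group_sosj(jx[pass_idx, , drop = FALSE])
    inds <- sort(unique(ev$individual))
    counts <- matrix(0, length(pass_idx), length(inds),
                     dimnames = list(jx$key[pass_idx], inds))
    for (r in seq_along(pass_idx)) {
      tab <- res[[pass_idx[r]]]$counts_all
      counts[r, names(tab)] <- as.numeric(tab)
    }
    psi <- compute_psi(counts, jx$sosj_id[pass_idx])
  }
  structure(list(junctions = jx, psi = psi, evidence = ev),
            class = "junction_summary")
}

#' @export
print.junction_summary <- function(x, ...) {
  cat(sprintf("junction_summary: %d junction(s), %d passing (%d SOSJ)\n",
              nrow(x$junctions), sum(x$junctions$pass),
              length(unique(stats::na.omit(x$junctions$sosj_id)))))
  invisible(x)
}
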