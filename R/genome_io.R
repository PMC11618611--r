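## Genome and annotation input: sparse per-chromosome nucleotide storage,
## transcript parsing, per-position splice labels, strand-aware windows.
##
## Coordinates are 1-based inclusive throughout the package (the R/Bioconductor
## convention); BED output converts to 0-based half-open at the I/O boundary.

.BASES <- c("A", "C", "G", "T")

## integer codes: 0 = unknown/N, 1..4 = A,C,G,T
.seq_to_code <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  code <- match(ch, .BASES)
  bad <- is.na(code) & !(ch %in% c("N", "X", "-", "."))
  if (any(bad)) {
    stop("sequence contains invalid characters: ",
         paste(unique(ch[bad]), collapse = ", "))
  }
  code[is.na(code)] <- 0L
  code
}

.code_to_seq <- function(code) {
  paste(c("N", .BASES)[code + 1L], collapse = "")
}

#' Create a genome store
#'
#' A genome store holds per-chromosome nucleotide sequence as integer-coded
#' vectors in which positions outside annotated genes may be masked to an
#' "unknown" token. Unknown positions one-hot encode to the zero vector, so
#' they are invisible to the model.
#'
#' @param sequences Named list of character strings (one per chromosome) or of
#'   integer code vectors (0 = unknown, 1..4 = A,C,G,T).
#' @return An object of class `genome_store`.
#' @export
genome_store <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("'sequences' must be a named list of chromosomes")
  }
  seqs <- lapply(sequences, function(s) {
    if (is.character(s)) .seq_to_code(s) else as.integer(s)
  })
  for (s in seqs) {
    if (any(s < 0L | s > 4L)) stop("sequence codes must lie in 0..4")
  }
  structure(list(seq = seqs, lengths = vapply(seqs, length, integer(1))),
            class = "genome_store")
}

#' @export
print.genome_store <- function(x, ...) {
  cat("genome_store:", length(x$seq), "chromosome(s)\n")
  for (nm in names(x$seq)) {
    known <- sum(x$seq[[nm]] != 0L)
    cat(sprintf("  %s: %d nt (%d known)\n", nm, x$lengths[[nm]], known))
  }
  invisible(x)
}

.check_chrom <- function(store, chrom) {
  if (!chrom %in% names(store$seq)) {
    stop("chromosome '", chrom, "' not present in genome store")
  }
}

#' Read a FASTA genome into a sparse genome store
#'
#' Sequence inside `gene_intervals` is retained; everything else is stored as
#' the unknown token (encoding to a zero one-hot vector). With
#' `gene_intervals = NULL` the full sequence is kept.
#'
#' @param path Path to a FASTA file.
#' @param gene_intervals Optional `data.frame` with columns `chrom`, `start`,
#'   `end` (1-based inclusive) delimiting gene bodies to retain.
#' @return A [genome_store].
#' @export
parse_fasta <- function(path, gene_intervals = NULL) {
  dna <- Biostrings::readDNAStringSet(path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  store <- genome_store(as.list(as.character(dna)))
  if (!is.null(gene_intervals)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(gene_intervals)))
    masked <- lapply(names(store$seq), function(nm) {
      keep <- rep(FALSE, store$lengths[[nm]])
      iv <- gene_intervals[gene_intervals$chrom == nm, , drop = FALSE]
      if (nrow(iv)) {
        if (any(iv$start < 1L) || any(iv$end > store$lengths[[nm]])) {
          stop("gene interval outside bounds of chromosome '", nm, "'")
        }
        for (i in seq_len(nrow(iv))) keep[iv$start[i]:iv$end[i]] <- TRUE
      }
      s <- store$seq[[nm]]
      s[!keep] <- 0L
      s
    })
    names(masked) <- names(store$seq)
    store$seq <- masked
  }
  missing <- setdiff(unique(gene_intervals$chrom), names(store$seq))
  if (length(missing)) {
    stop("chromosome '", missing[[1L]], "' not present in FASTA")
  }
  store
}

#' Reverse complement a nucleotide string
#'
#' `N` (unknown) is preserved. An involution: `reverse_complement` applied
#' twice is the identity.
#'
#' @param seq Nucleotide string.
#' @return The reverse complemented string.
#' @export
reverse_complement <- function(seq) {
  ch <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(ch, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' One-hot encode a nucleotide sequence
#'
#' A, C, G, T map to the four unit vectors in that order; `N` and unknown
#' positions map to the zero vector. Any other character is an error.
#'
#' @param seq Nucleotide string, character vector of single bases, or integer
#'   code vector (0..4).
#' @return A length-by-4 numeric matrix.
#' @export
one_hot_encode <- function(seq) {
  code <- if (is.numeric(seq)) {
    as.integer(seq)
  } else if (length(seq) == 1L) {
    ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    code <- match(ch, .BASES)
    if (any(is.na(code) & ch != "N")) {
      stop("invalid characters in sequence: ",
           paste(unique(ch[is.na(code) & ch != "N"]), collapse = ", "))
    }
    code[is.na(code)] <- 0L
    code
  } else {
    code <- match(toupper(seq), .BASES)
    if (any(is.na(code) & toupper(seq) != "N")) stop("invalid characters in sequence")
    code[is.na(code)] <- 0L
    code
  }
  m <- matrix(0, length(code), 4L, dimnames = list(NULL, .BASES))
  known <- code > 0L
  m[cbind(which(known), code[known])] <- 1
  m
}

#' Extract a strand-aware sequence window
#'
#' Positions beyond chromosome bounds are padded with the unknown token `N`.
#' On the minus strand the reverse complement of the forward slice is
#' returned, i.e. the window reads in transcription order.
#'
#' @param store A [genome_store].
#' @param chrom Chromosome name.
#' @param start 1-based start position of the forward-strand slice.
#' @param length Window length in nucleotides (> 0).
#' @param strand `"+"` or `"-"`.
#' @return Nucleotide string of the requested length.
#' @export
extract_window <- function(store, chrom, start, length, strand = "+") {
  stopifnot(length > 0)
  .check_chrom(store, chrom)
  s <- store$seq[[chrom]]
  idx <- seq.int(start, start + length - 1L)
  code <- integer(base::length(idx))
  ok <- idx >= 1L & idx <= base::length(s)
  code[ok] <- s[idx[ok]]
  if (strand == "-") {
    comp <- c(0L, 4L, 3L, 2L, 1L)  # N->N, A->T, C->G, G->C, T->A
    code <- rev(comp[code + 1L])
  }
  .code_to_seq(code)
}

## ---- transcripts ----------------------------------------------------------

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of exon (start, end) genomic intervals,
#'   1-based inclusive; sorted by start, non-overlapping.
#' @param biotype Transcript biotype (e.g. `"protein_coding"`).
#' @param support_level ENSEMBL transcript support level (integer or `NA`).
#' @return A list of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chromosome, strand,
                             exons, biotype = "protein_coding",
                             support_level = NA_integer_) {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("exons of transcript '", transcript_id, "' overlap")
  }
  if (any(exons[, 2L] < exons[, 1L])) stop("exon end before start")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chromosome = chromosome, strand = strand, exons = exons,
                 biotype = biotype, support_level = support_level),
            class = "transcript_model")
}

transcript_set <- function(transcripts) {
  structure(transcripts, class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", length(x), "transcript(s) on",
      length(unique(vapply(x, `[[`, "", "chromosome"))), "chromosome(s)\n")
  invisible(x)
}

#' @export
`[.transcript_set` <- function(x, i) transcript_set(unclass(x)[i])

.parse_gtf_attrs <- function(attr, dialect) {
  if (dialect == "gff3") {
    kv <- strsplit(strsplit(attr, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  } else {
    parts <- strsplit(attr, ";", fixed = TRUE)[[1L]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    kv <- regmatches(parts, regexec('^(\\S+)\\s+"?([^"]*)"?$', parts))
    kv <- lapply(kv, function(m) m[-1L])
  }
  kv <- kv[vapply(kv, length, integer(1)) == 2L]
  if (!length(kv)) stop("no parseable attributes")
  vals <- vapply(kv, `[[`, "", 2L)
  names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
  vals
}

#' Parse transcripts from a GTF or GFF3 annotation
#'
#' Auto-detects the attribute dialect (GTF `key "value";` vs GFF3
#' `key=value`). Returns only protein-coding transcripts with at least one
#' splice junction (two or more exons). In `ensembl` mode transcripts must
#' additionally carry transcript support level 1; `gencode` mode does not
#' apply the support-level filter. Records with malformed attribute fields
#' are skipped with a warning.
#'
#' @param path Path to a GTF/GFF3 file.
#' @param mode `"ensembl"` or `"gencode"`.
#' @return A `transcript_set` (list of [transcript_model] objects).
#' @export
parse_gtf_transcripts <- function(path, mode = c("ensembl", "gencode")) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_bad <- 0L
  ## transcript metadata gathered from transcript/mRNA records (GFF3 keeps
  ## biotype there) and from exon records (GTF repeats attributes per exon)
  meta <- new.env(parent = emptyenv())
  exons <- new.env(parent = emptyenv())
  for (f in fields) {
    if (length(f) != 9L) { n_bad <- n_bad + 1L; next }
    type <- f[[3L]]
    if (!type %in% c("exon", "transcript", "mRNA")) next
    dialect <- if (grepl("=", f[[9L]], fixed = TRUE) &&
                   !grepl("\"", f[[9L]], fixed = TRUE)) "gff3" else "gtf"
    at <- tryCatch(.parse_gtf_attrs(f[[9L]], dialect),
                   error = function(e) NULL)
    if (is.null(at)) { n_bad <- n_bad + 1L; next }
    pick <- function(keys) {
      for (k in keys) if (!is.na(at[k])) return(unname(at[k]))
      NA_character_
    }
    if (type %in% c("transcript", "mRNA")) {
      tid <- pick(c("transcript_id", "ID"))
      tid <- sub("^transcript:", "", tid)
      if (is.na(tid)) { n_bad <- n_bad + 1L; next }
      m <- list(gene_id = sub("^gene:", "",
                              pick(c("gene_id", "Parent"))),
                chromosome = f[[1L]], strand = f[[7L]],
                biotype = pick(c("transcript_biotype", "transcript_type",
                                 "biotype", "gene_biotype")),
                tsl = pick(c("transcript_support_level")))
      assign(tid, m, envir = meta)
    } else {
      tid <- pick(c("transcript_id", "Parent"))
      tid <- sub("^transcript:", "", tid)
      if (is.na(tid)) { n_bad <- n_bad + 1L; next }
      start <- suppressWarnings(as.numeric(f[[4L]]))
      end <- suppressWarnings(as.numeric(f[[5L]]))
      if (is.na(start) || is.na(end)) { n_bad <- n_bad + 1L; next }
      rec <- c(start, end)
      prev <- if (exists(tid, envir = exons)) get(tid, envir = exons) else NULL
      assign(tid, rbind(prev, rec), envir = exons)
      if (!exists(tid, envir = meta)) {
        m <- list(gene_id = pick(c("gene_id")), chromosome = f[[1L]],
                  strand = f[[7L]],
                  biotype = pick(c("transcript_biotype", "transcript_type",
                                   "biotype", "gene_biotype")),
                  tsl = pick(c("transcript_support_level")))
        assign(tid, m, envir = meta)
      } else if (type == "exon") {
        ## GTF exon lines may carry biotype/tsl missing on transcript line
        m <- get(tid, envir = meta)
        if (is.na(m$biotype)) m$biotype <- pick(c("transcript_biotype",
                                                  "transcript_type", "biotype",
                                                  "gene_biotype"))
        if (is.na(m$tsl)) m$tsl <- pick(c("transcript_support_level"))
        assign(tid, m, envir = meta)
      }
    }
  }
  if (n_bad > 0L) {
    warning(n_bad, " malformed record(s) skipped")
  }
  out <- list()
  for (tid in ls(exons)) {
    m <- get(tid, envir = meta)
    ex <- get(tid, envir = exons)
    if (is.na(m$biotype) || m$biotype != "protein_coding") next
    if (nrow(ex) < 2L) next
    tsl <- suppressWarnings(as.integer(sub("^(\\d+).*", "\\1", m$tsl)))
    if (mode == "ensembl" && (is.na(tsl) || tsl != 1L)) next
    out[[tid]] <- transcript_model(tid, m$gene_id, m$chromosome, m$strand,
                                   ex, m$biotype, tsl)
  }
  if (!length(out)) stop("no transcripts retained after filtering")
  transcript_set(unname(out[order(names(out))]))
}

#' Split transcripts into train/validation/test partitions
#'
#' Transcripts on the held-out chromosomes (by default 1, 3, 5, 7 and 9,
#' with or without a `chr` prefix) form the test partition. A seeded random
#' fraction of the remaining transcripts forms the validation partition.
#'
#' @param transcripts A `transcript_set`.
#' @param validation_fraction Proportion in \[0, 1) of non-held-out
#'   transcripts moved to validation.
#' @param seed Integer seed for the validation draw.
#' @param holdout Character vector of held-out chromosome names (no `chr`
#'   prefix).
#' @return List with `train`, `validation` and `test` transcript sets;
#'   disjoint and exhaustive.
#' @export
split_by_chromosome <- function(transcripts, validation_fraction = 0.1,
                                seed = 1L,
                                holdout = c("1", "3", "5", "7", "9")) {
  stopifnot(validation_fraction >= 0, validation_fraction < 1)
  chroms <- vapply(transcripts, `[[`, "", "chromosome")
  is_test <- sub("^chr", "", chroms) %in% holdout
  rest <- which(!is_test)
  n_val <- floor(validation_fraction * length(rest))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  val <- if (n_val > 0L) sort(sample(rest, n_val)) else integer(0)
  list(train = transcripts[setdiff(rest, val)],
       validation = transcripts[val],
       test = transcripts[which(is_test)])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## ---- labels ---------------------------------------------------------------

## label codes: 0 = no splice, 1 = acceptor, 2 = donor
.LABEL_LEVELS <- c("no_splice", "acceptor", "donor")

#' Per-transcript splice site positions
#'
#' For a plus-strand transcript the first nucleotide of each non-first exon
#' is an acceptor and the last nucleotide of each non-last exon is a donor;
#' on the minus strand the roles are taken with respect to transcription
#' direction (in genomic coordinates the donor sits at the exon start).
#'
#' @param transcripts A `transcript_set` or list of [transcript_model]s.
#' @param dedupe Drop duplicated (chrom, pos, strand, type) rows.
#' @return `data.frame` with columns `chrom`, `pos`, `strand`, `type`
#'   (`"acceptor"`/`"donor"`) and `transcript_id`.
#' @export
splice_sites <- function(transcripts, dedupe = TRUE) {
  rows <- lapply(transcripts, function(tr) {
    ex <- tr$exons
    m <- nrow(ex)
    if (m < 2L) return(NULL)
    if (tr$strand == "+") {
      don <- ex[seq_len(m - 1L), 2L]
      acc <- ex[seq.int(2L, m), 1L]
    } else {
      don <- ex[seq.int(2L, m), 1L]
      acc <- ex[seq_len(m - 1L), 2L]
    }
    data.frame(chrom = tr$chromosome, pos = c(acc, don), strand = tr$strand,
               type = rep(c("acceptor", "donor"), c(length(acc), length(don))),
               transcript_id = tr$transcript_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = numeric(),
                      strand = character(), type = character(),
                      transcript_id = character())
  }
  if (dedupe && nrow(out)) {
    out <- out[!duplicated(out[, c("chrom", "pos", "strand", "type")]), ]
    rownames(out) <- NULL
  }
  out
}

#' Build a per-position splice label track
#'
#' Labels are the union over all supplied transcripts. A position claimed as
#' acceptor by one transcript and donor by another is a hard error.
#'
#' @param transcripts A `transcript_set`.
#' @param store A [genome_store]; exons must lie within its chromosomes.
#' @return Object of class `label_track`: a named list of integer vectors
#'   (0 = no splice, 1 = acceptor, 2 = donor), one per chromosome in `store`.
#' @export
build_label_track <- function(transcripts, store) {
  track <- lapply(store$lengths, function(L) integer(L))
  sites <- splice_sites(transcripts, dedupe = TRUE)
  for (tr in transcripts) {
    .check_chrom(store, tr$chromosome)
    if (any(tr$exons < 1) ||
        any(tr$exons > store$lengths[[tr$chromosome]])) {
      stop("exon of transcript '", tr$transcript_id,
           "' outside chromosome bounds")
    }
  }
  if (nrow(sites)) {
    code <- ifelse(sites$type == "acceptor", 1L, 2L)
    for (i in seq_len(nrow(sites))) {
      cur <- track[[sites$chrom[i]]][sites$pos[i]]
      if (cur != 0L && cur != code[i]) {
        stop("conflicting splice labels at ", sites$chrom[i], ":",
             sites$pos[i], " (acceptor vs donor)")
      }
      track[[sites$chrom[i]]][sites$pos[i]] <- code[i]
    }
  }
  structure(track, class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  for (nm in names(x)) {
    cat(sprintf("%s: %d acceptor(s), %d donor(s) over %d nt\n", nm,
                sum(x[[nm]] == 1L), sum(x[[nm]] == 2L), length(x[[nm]])))
  }
  invisible(x)
}

#' One-hot encode a label vector
#'
#' @param labels Integer vector (0 = no splice, 1 = acceptor, 2 = donor).
#' @return Length-by-3 matrix with rows `[1,0,0]`, `[0,1,0]`, `[0,0,1]`.
#' @export
labels_to_onehot <- function(labels) {
  m <- matrix(0, length(labels), 3L, dimnames = list(NULL, .LABEL_LEVELS))
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

## labels (0/1/2) for a strand-aware window in window coordinates
.window_labels <- function(sites, chrom, start, length, strand) {
  lab <- integer(length)
  sel <- sites[sites$chrom == chrom & sites$strand == strand, , drop = FALSE]
  if (!nrow(sel)) return(lab)
  if (strand == "+") {
    w <- sel$pos - start + 1L
  } else {
    w <- start + length - sel$pos
  }
  ok <- w >= 1L & w <= length
  lab[w[ok]] <- ifelse(sel$type[ok] == "acceptor", 1L, 2L)
  lab
}

#' Write splice site positions as BED
#'
#' Output is 0-based half-open, one row per site, name = site type, score
#' column carries an optional per-site score.
#'
#' @param sites `data.frame` as returned by [splice_sites()], optionally with
#'   a `score` column.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_labels_bed <- function(sites, path) {
  score <- if ("score" %in% names(sites)) sites$score else 0
  bed <- data.frame(sites$chrom, sites$pos - 1L, sites$pos, sites$type,
                    score, sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
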