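## Synthetic genomes with a planted splice grammar.
##
## The generator emulates the features of real splice determinants that the
## model architecture is built to exploit: strong local position-weight-matrix
## motifs anchored on the essential GT/AG dinucleotides, and a long-range
## pairing signal (a donor-side hexamer that predicts its paired acceptor's
## hexamer across the intron) that lies outside any local encoder's receptive
## field. Decoy motifs -- locally indistinguishable from true sites but
## planted in isolation far from genes -- give a long-context model room to
## beat a purely local one.

.pwm_check <- function(pwm) {
  stopifnot(nrow(pwm) == 4L)
  if (any(abs(colSums(pwm) - 1) > 1e-8) || any(pwm < 0)) {
    stop("PWM columns must be probability distributions")
  }
  pwm
}

.pwm_consensus <- function(cons, conc) {
  ch <- strsplit(cons, "", fixed = TRUE)[[1L]]
  pwm <- matrix((1 - conc) / 3, 4L, length(ch), dimnames = list(.BASES, NULL))
  pwm[cbind(match(ch, .BASES), seq_along(ch))] <- conc
  pwm
}

#' Define a planted splice grammar
#'
#' The donor signature on the transcribed strand is three exonic PWM
#' positions, the invariant GT, and a six-nucleotide pairing hexamer; the
#' acceptor signature is the partner hexamer, an eight-nucleotide
#' polypyrimidine tract, the invariant AG, and one exonic PWM position.
#' With probability `pairing_strength` an intron's acceptor hexamer is the
#' deterministic partner of its donor's hexamer; otherwise it is drawn at
#' random. Decoy sites carry the full local signature but are planted in
#' isolation in intergenic sequence, at a rate of `decoy_rate` decoys per
#' true splice site.
#'
#' @param donor_pwm 4x5 PWM (3 exonic positions + GT); GT columns must be
#'   degenerate.
#' @param acceptor_pwm 4x11 PWM (8 polypyrimidine positions + AG + 1 exonic).
#' @param donor_hex,acceptor_hex Equal-length character vectors of paired
#'   hexamer classes.
#' @param pairing_strength Probability in \[0,1\] that an acceptor hexamer
#'   matches its donor's partner class.
#' @param exon_length,intron_length Integer ranges (min, max) in nt.
#' @param n_exons Integer range of exons per gene.
#' @param decoy_rate Decoy sites per true splice site.
#' @param consensus_conc Per-position probability of the consensus base in
#'   the exonic PWM columns.
#' @return List of class `splice_grammar`.
#' @export
splice_grammar <- function(donor_pwm = NULL, acceptor_pwm = NULL,
                           donor_hex = c("ACGTAC", "TTGACA", "GGCATG",
                                         "CATTGC"),
                           acceptor_hex = c("GTACGT", "TGTCAA", "CATGCC",
                                            "GCAATG"),
                           pairing_strength = 1,
                           exon_length = c(80L, 300L),
                           intron_length = c(200L, 2000L),
                           n_exons = c(3L, 8L),
                           decoy_rate = 0.2,
                           consensus_conc = 0.97) {
  stopifnot(pairing_strength >= 0, pairing_strength <= 1,
            length(donor_hex) == length(acceptor_hex))
  if (is.null(donor_pwm)) {
    donor_pwm <- cbind(.pwm_consensus("CAG", consensus_conc),
                       .pwm_consensus("GT", 1))
  }
  if (is.null(acceptor_pwm)) {
    poly <- matrix(rep(c(0.02, 0.48, 0.02, 0.48), 8L), 4L, 8L,
                   dimnames = list(.BASES, NULL))  # pyrimidine-rich C/T
    acceptor_pwm <- cbind(poly, .pwm_consensus("AG", 1),
                          .pwm_consensus("G", consensus_conc))
  }
  .pwm_check(donor_pwm); .pwm_check(acceptor_pwm)
  if (donor_pwm["G", 4L] != 1 || donor_pwm["T", 5L] != 1) {
    stop("donor PWM must be anchored on GT")
  }
  if (acceptor_pwm["A", 9L] != 1 || acceptor_pwm["G", 10L] != 1) {
    stop("acceptor PWM must be anchored on AG")
  }
  structure(list(donor_pwm = donor_pwm, acceptor_pwm = acceptor_pwm,
                 donor_hex = donor_hex, acceptor_hex = acceptor_hex,
                 pairing_strength = pairing_strength,
                 exon_length = exon_length, intron_length = intron_length,
                 n_exons = n_exons, decoy_rate = decoy_rate),
            class = "splice_grammar")
}

.sample_pwm <- function(pwm, cols = seq_len(ncol(pwm))) {
  vapply(cols, function(j) sample.int(4L, 1L, prob = pwm[, j]), integer(1))
}

## donor fragment in transcribed orientation; site (last exonic nt) at index 3
.donor_fragment <- function(grammar, hex_class, gt = "GT") {
  c(.sample_pwm(grammar$donor_pwm, 1:3),
    match(strsplit(gt, "")[[1L]], .BASES),
    match(strsplit(grammar$donor_hex[hex_class], "")[[1L]], .BASES))
}

## acceptor fragment; site (first exonic nt) at index 17
.acceptor_fragment <- function(grammar, hex_class) {
  c(match(strsplit(grammar$acceptor_hex[hex_class], "")[[1L]], .BASES),
    .sample_pwm(grammar$acceptor_pwm, 1:8),
    match(c("A", "G"), .BASES),
    .sample_pwm(grammar$acceptor_pwm, 11L))
}

.revcomp_code <- function(code) {
  comp <- c(0L, 4L, 3L, 2L, 1L)
  rev(comp[code + 1L])
}

#' Generate a synthetic genome with planted splice sites
#'
#' Places multi-exon genes (random strand) on the planned chromosomes,
#' stamps donor/acceptor motifs from the grammar at every exon-intron
#' boundary on the transcribed strand, plants isolated decoy motifs in
#' intergenic sequence and one near-miss donor motif (GT written as GC) in
#' one intron per gene, and returns the genome together with ground-truth
#' annotations.
#'
#' @param grammar A [splice_grammar].
#' @param n_genes Total number of genes to place.
#' @param chromosome_plan Named integer vector of chromosome lengths in nt.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param intergenic_min Minimum gap between genes and the minimum distance
#'   of any decoy from a gene, in nt.
#' @return Object of class `synthetic_genome`: a list with elements `store`
#'   ([genome_store]), `transcripts` (`transcript_set`), `sites`
#'   (ground-truth [splice_sites()] table), `decoys`, `near_misses`,
#'   `grammar` and `seed`.
#' @export
generate_genome <- function(grammar = splice_grammar(), n_genes = 40L,
                            chromosome_plan = c(chr1 = 250000L,
                                                chr2 = 250000L),
                            seed = 1L, intergenic_min = 3000L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  K <- length(grammar$donor_hex)
  chroms <- names(chromosome_plan)
  seqs <- lapply(chromosome_plan, function(L) sample.int(4L, L, replace = TRUE))
  transcripts <- list()
  near <- list()
  gene_spans <- lapply(chroms, function(x) NULL)
  names(gene_spans) <- chroms
  ## round-robin gene placement over chromosomes
  cursors <- stats::setNames(rep(1L, length(chroms)), chroms)
  gi <- 0L
  placed <- 0L
  exhausted <- stats::setNames(rep(FALSE, length(chroms)), chroms)
  while (placed < n_genes) {
    if (all(exhausted)) stop("chromosome plan too small for requested genes")
    for (cn in chroms) {
      if (placed >= n_genes || exhausted[[cn]]) next
      L <- chromosome_plan[[cn]]
      nex <- sample(seq.int(grammar$n_exons[1L], grammar$n_exons[2L]), 1L)
      elen <- sample(seq.int(grammar$exon_length[1L], grammar$exon_length[2L]),
                     nex, replace = TRUE)
      ilen <- sample(seq.int(grammar$intron_length[1L],
                             grammar$intron_length[2L]),
                     nex - 1L, replace = TRUE)
      span <- sum(elen) + sum(ilen)
      gap <- round(stats::runif(1L, intergenic_min, 2 * intergenic_min))
      gstart <- cursors[[cn]] + gap
      if (gstart + span - 1L > L - intergenic_min) {
        exhausted[[cn]] <- TRUE
        next
      }
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1L)
      ## transcribed-strand gene sequence
      gseq <- sample.int(4L, span, replace = TRUE)
      bounds <- cumsum(c(rbind(elen, c(ilen, NA)))[-2L * nex])
      estart <- c(1L, utils::head(bounds, -1L) + 1L)[seq.int(1L, 2L * nex - 1L,
                                                             2L)]
      eend <- bounds[seq.int(1L, 2L * nex - 1L, 2L)]
      for (j in seq_len(nex - 1L)) {
        k <- sample.int(K, 1L)
        dfr <- .donor_fragment(grammar, k)
        gseq[(eend[j] - 2L):(eend[j] + 8L)] <- dfr
        k_acc <- if (stats::runif(1L) < grammar$pairing_strength) k else
          sample.int(K, 1L)
        afr <- .acceptor_fragment(grammar, k_acc)
        q <- estart[j + 1L]
        gseq[(q - 16L):q] <- afr
      }
      ## one near-miss donor (GC instead of GT) in a random intron
      if (nex >= 2L) {
        j <- sample.int(nex - 1L, 1L)
        nm_site <- eend[j] + 30L + sample.int(ilen[j] - 80L, 1L)
        nfr <- .donor_fragment(grammar, sample.int(K, 1L), gt = "GC")
        gseq[(nm_site - 2L):(nm_site + 8L)] <- nfr
        nm_mut_t <- nm_site + 2L  # the C that a variant flips back to T
        if (strand == "+") {
          near[[length(near) + 1L]] <- data.frame(
            chrom = cn, site_pos = gstart + nm_site - 1L, strand = strand,
            mut_pos = gstart + nm_mut_t - 1L, ref = "C", alt = "T")
        } else {
          gend <- gstart + span - 1L
          near[[length(near) + 1L]] <- data.frame(
            chrom = cn, site_pos = gend - nm_site + 1L, strand = strand,
            mut_pos = gend - nm_mut_t + 1L, ref = "G", alt = "A")
        }
      }
      ## write into genomic coordinates
      if (strand == "+") {
        seqs[[cn]][gstart:(gstart + span - 1L)] <- gseq
        ex <- cbind(gstart + estart - 1L, gstart + eend - 1L)
      } else {
        seqs[[cn]][gstart:(gstart + span - 1L)] <- .revcomp_code(gseq)
        gend <- gstart + span - 1L
        ex <- cbind(gend - eend + 1L, gend - estart + 1L)
      }
      gid <- sprintf("gene%03d", gi)
      transcripts[[gid]] <- transcript_model(
        paste0(gid, ".t1"), gid, cn, strand, ex,
        biotype = "protein_coding", support_level = 1L)
      gene_spans[[cn]] <- rbind(gene_spans[[cn]],
                                c(gstart, gstart + span - 1L))
      cursors[[cn]] <- gstart + span - 1L
      placed <- placed + 1L
    }
  }
  transcripts <- transcript_set(unname(transcripts))
  sites <- splice_sites(transcripts)
  ## decoys: full local signature, isolated in intergenic sequence
  n_decoys <- round(grammar$decoy_rate * nrow(sites))
  decoys <- list()
  placed_decoys <- lapply(chroms, function(x) numeric(0))
  names(placed_decoys) <- chroms
  tries <- 0L
  while (length(decoys) < n_decoys && tries < 200L * max(n_decoys, 1L)) {
    tries <- tries + 1L
    cn <- sample(chroms, 1L)
    L <- chromosome_plan[[cn]]
    p <- sample.int(L - 400L, 1L) + 200L
    gs <- gene_spans[[cn]]
    if (!is.null(gs) &&
        any(p >= gs[, 1L] - intergenic_min & p <= gs[, 2L] + intergenic_min)) {
      next
    }
    if (length(placed_decoys[[cn]]) &&
        min(abs(placed_decoys[[cn]] - p)) < 1000L) next
    strand <- sample(c("+", "-"), 1L)
    type <- if (length(decoys) %% 2L == 0L) "donor" else "acceptor"
    k <- sample.int(K, 1L)
    if (type == "donor") {
      frag <- .donor_fragment(grammar, k); site_idx <- 3L
    } else {
      frag <- .acceptor_fragment(grammar, k); site_idx <- 17L
    }
    if (strand == "+") {
      fs <- p - site_idx + 1L
      seqs[[cn]][fs:(fs + length(frag) - 1L)] <- frag
    } else {
      rc <- .revcomp_code(frag)
      fs <- p - (length(frag) - site_idx)
      seqs[[cn]][fs:(fs + length(frag) - 1L)] <- rc
    }
    placed_decoys[[cn]] <- c(placed_decoys[[cn]], p)
    decoys[[length(decoys) + 1L]] <- data.frame(
      chrom = cn, pos = p, strand = strand, type = type, hex_class = k)
  }
  decoys <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(chrom = character(), pos = numeric(), strand = character(),
               type = character(), hex_class = integer())
  near <- if (length(near)) do.call(rbind, near) else
    data.frame(chrom = character(), site_pos = numeric(), strand = character(),
               mut_pos = numeric(), ref = character(), alt = character())
  structure(list(store = genome_store(seqs), transcripts = transcripts,
                 sites = sites, decoys = decoys, near_misses = near,
                 grammar = grammar, seed = seed),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", length(x$transcripts), "gene(s),",
      nrow(x$sites), "splice site(s),", nrow(x$decoys), "decoy(s) on",
      length(x$store$seq), "chromosome(s)\n")
  invisible(x)
}

#' Generate labelled sequence variants for a synthetic genome
#'
#' Disrupting variants mutate one base of a planted GT or AG dinucleotide;
#' creating variants complete a planted near-miss donor motif (GC -> GT);
#' neutral variants are single-base changes at least `min_neutral_distance`
#' nt from every planted site, decoy and near-miss.
#'
#' @param sim A `synthetic_genome` from [generate_genome()].
#' @param n_disrupting,n_creating,n_neutral Requested counts per class.
#' @param min_neutral_distance Minimum distance (nt) from any planted
#'   feature for neutral variants.
#' @param seed Integer seed.
#' @return `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `class`.
#' @export
generate_variants <- function(sim, n_disrupting = 20L, n_creating = 10L,
                              n_neutral = 20L, min_neutral_distance = 500L,
                              seed = 1L) {
  stopifnot(inherits(sim, "synthetic_genome"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  store <- sim$store
  base_at <- function(chrom, pos) .BASES[store$seq[[chrom]][pos]]
  out <- list()
  ## disrupting: hit one of the two essential dinucleotide positions
  sites <- sim$sites
  if (n_disrupting > 0L) {
    idx <- sample.int(nrow(sites), min(n_disrupting, nrow(sites)))
    for (i in idx) {
      s <- sites[i, ]
      ess <- switch(paste0(s$type, s$strand),
                    "donor+" = s$pos + 1:2, "donor-" = s$pos - 1:2,
                    "acceptor+" = s$pos - 2:1, "acceptor-" = s$pos + 2:1)
      p <- sample(ess, 1L)
      ref <- base_at(s$chrom, p)
      alt <- sample(setdiff(.BASES, ref), 1L)
      out[[length(out) + 1L]] <- data.frame(chrom = s$chrom, pos = p,
                                            ref = ref, alt = alt,
                                            class = "disrupting")
    }
  }
  if (n_creating > 0L) {
    nm <- sim$near_misses
    if (nrow(nm) < n_creating) {
      stop("only ", nrow(nm), " near-miss motifs available for ",
           n_creating, " creating variants")
    }
    idx <- sample.int(nrow(nm), n_creating)
    for (i in idx) {
      out[[length(out) + 1L]] <- data.frame(chrom = nm$chrom[i],
                                            pos = nm$mut_pos[i],
                                            ref = nm$ref[i], alt = nm$alt[i],
                                            class = "creating")
    }
  }
  if (n_neutral > 0L) {
    feat <- rbind(data.frame(chrom = sites$chrom, pos = sites$pos),
                  data.frame(chrom = sim$decoys$chrom, pos = sim$decoys$pos),
                  data.frame(chrom = sim$near_misses$chrom,
                             pos = sim$near_misses$site_pos))
    placed <- 0L
    tries <- 0L
    while (placed < n_neutral) {
      tries <- tries + 1L
      if (tries > 500L * n_neutral) {
        stop("cannot place requested neutral variants at distance ",
             min_neutral_distance)
      }
      cn <- sample(names(store$seq), 1L)
      p <- sample.int(store$lengths[[cn]], 1L)
      f <- feat[feat$chrom == cn, "pos"]
      if (length(f) && min(abs(f - p)) < min_neutral_distance) next
      if (store$seq[[cn]][p] == 0L) next
      ref <- base_at(cn, p)
      out[[length(out) + 1L]] <- data.frame(chrom = cn, pos = p, ref = ref,
                                            alt = sample(setdiff(.BASES, ref),
                                                         1L),
                                            class = "neutral")
      placed <- placed + 1L
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate junction-supporting fragments
#'
#' Each planted junction (intron) of each transcript is supported by a
#' Poisson(`depth`) number of fragments per individual, each carrying left
#' and right overhang lengths drawn from `overhang_dist` and a multimapping
#' flag set with probability `multimap_fraction`.
#'
#' @param transcripts A `transcript_set`.
#' @param depth Mean fragments per junction per individual.
#' @param overhang_dist Either an integer vector of overhang lengths sampled
#'   uniformly, or a `data.frame` with columns `length` and `prob`. Default
#'   uniform over 8..40 nt.
#' @param multimap_fraction Probability a fragment is flagged multimapping.
#' @param n_individuals Number of individuals.
#' @param seed Integer seed.
#' @return `data.frame` of fragment evidence with columns `individual`,
#'   `chrom`, `intron_start`, `intron_end`, `strand`, `left_overhang`,
#'   `right_overhang`, `multimapped`.
#' @export
generate_fragments <- function(transcripts, depth = 10, overhang_dist = NULL,
                               multimap_fraction = 0.05, n_individuals = 5L,
                               seed = 1L) {
  stopifnot(depth > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(overhang_dist)) overhang_dist <- 8:40
  if (is.data.frame(overhang_dist)) {
    ov_val <- overhang_dist$length; ov_p <- overhang_dist$prob
  } else {
    ov_val <- overhang_dist; ov_p <- NULL
  }
  introns <- transcript_introns(transcripts)
  rows <- vector("list", nrow(introns) * n_individuals)
  ri <- 0L
  for (j in seq_len(nrow(introns))) {
    for (ind in seq_len(n_individuals)) {
      n <- stats::rpois(1L, depth)
      if (n == 0L) next
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        individual = sprintf("ind%02d", ind),
        chrom = introns$chrom[j],
        intron_start = introns$start[j], intron_end = introns$end[j],
        strand = introns$strand[j],
        left_overhang = sample(ov_val, n, replace = TRUE, prob = ov_p),
        right_overhang = sample(ov_val, n, replace = TRUE, prob = ov_p),
        multimapped = stats::runif(n) < multimap_fraction)
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}

#' Intron intervals of a transcript set
#'
#' @param transcripts A `transcript_set`.
#' @return `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   inclusive intron interval), `strand`, `transcript_id`; deduplicated.
#' @export
transcript_introns <- function(transcripts) {
  rows <- lapply(transcripts, function(tr) {
    m <- nrow(tr$exons)
    if (m < 2L) return(NULL)
    data.frame(chrom = tr$chromosome,
               start = tr$exons[seq_len(m - 1L), 2L] + 1L,
               end = tr$exons[seq.int(2L, m), 1L] - 1L,
               strand = tr$strand, transcript_id = tr$transcript_id)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      transcript_id = character()))
  }
  out <- out[!duplicated(out[, c("chrom", "start", "end", "strand")]), ]
  rownames(out) <- NULL
  out
}

## ---- file writers ---------------------------------------------------------

#' Write a genome store as FASTA
#' @param store A [genome_store]; unknown positions are written as `N`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_genome_fasta <- function(store, path) {
  dna <- Biostrings::DNAStringSet(vapply(store$seq, .code_to_seq,
                                         character(1)))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write transcripts as GTF
#' @param transcripts A `transcript_set`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##format: gtf", con)
  for (tr in transcripts) {
    tsl <- if (is.na(tr$support_level)) "NA" else tr$support_level
    attrs <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                            'transcript_biotype "%s"; ',
                            'transcript_support_level "%s";'),
                     tr$gene_id, tr$transcript_id, tr$biotype, tsl)
    span <- c(min(tr$exons[, 1L]), max(tr$exons[, 2L]))
    writeLines(paste(tr$chromosome, "spliceformer", "transcript", span[1L],
                     span[2L], ".", tr$strand, ".", attrs, sep = "\t"), con)
    for (i in seq_len(nrow(tr$exons))) {
      writeLines(paste(tr$chromosome, "spliceformer", "exon",
                       tr$exons[i, 1L], tr$exons[i, 2L], ".", tr$strand, ".",
                       attrs, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write variants as VCF
#' @param variants `data.frame` with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `class` (stored in INFO).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##INFO=<ID=CLASS,Number=1,Type=String,",
                      'Description="Synthetic variant class">'),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info <- if ("class" %in% names(variants)) {
    paste0("CLASS=", variants$class)
  } else rep(".", nrow(variants))
  writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                   variants$alt, ".", "PASS", info, sep = "\t"), con)
  invisible(path)
}

#' Write fragment evidence as tab-delimited text
#' @param fragments `data.frame` from [generate_fragments()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fragments_tsv <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write fragment evidence as spliced SAM alignments
#'
#' Emits one single-end alignment per fragment with a `xMyNzM` CIGAR
#' spanning the junction, a read group identifying the individual, and an
#' `NH` tag (2 for multimapping fragments, 1 otherwise). The junction strand
#' is carried in the `XS` tag, as spliced aligners do.
#'
#' @param fragments `data.frame` from [generate_fragments()].
#' @param store A [genome_store] used for sequence and header lengths.
#' @param path Output path (SAM text).
#' @return Invisibly, the path.
#' @export
write_fragments_sam <- function(fragments, store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(store$seq)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, store$lengths[[nm]]), con)
  }
  for (ind in unique(fragments$individual)) {
    writeLines(sprintf("@RG\tID:%s\tSM:%s", ind, ind), con)
  }
  for (i in seq_len(nrow(fragments))) {
    fr <- fragments[i, ]
    pos <- fr$intron_start - fr$left_overhang
    gap <- fr$intron_end - fr$intron_start + 1L
    cigar <- sprintf("%dM%dN%dM", fr$left_overhang, gap, fr$right_overhang)
    rlen <- fr$left_overhang + fr$right_overhang
    seq_str <- paste0(
      extract_window(store, fr$chrom, pos, fr$left_overhang, "+"),
      extract_window(store, fr$chrom, fr$intron_end + 1L, fr$right_overhang,
                     "+"))
    nh <- if (isTRUE(fr$multimapped)) 2L else 1L
    writeLines(paste(sprintf("%s:frag%06d", fr$individual, i),
                     0L, fr$chrom, pos, if (nh > 1L) 0L else 60L, cigar,
                     "*", 0L, 0L, seq_str,
                     paste(rep("I", rlen), collapse = ""),
                     sprintf("RG:Z:%s", fr$individual),
                     sprintf("NH:i:%d", nh),
                     sprintf("XS:A:%s", fr$strand), sep = "\t"), con)
  }
  invisible(path)
}
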