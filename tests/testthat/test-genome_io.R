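test_that("parse_fasta keeps gene intervals and masks the rest", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 test", "ACGT"), fa)
  store <- parse_fasta(fa)
  expect_equal(extract_window(store, "chr1", 1, 4, "+"), "ACGT")
  masked <- parse_fasta(fa, data.frame(chrom = "chr1", start = 2, end = 3))
  expect_equal(extract_window(masked, "chr1", 1, 4, "+"), "NCGN")
  expect_error(parse_fasta(fa, data.frame(chrom = "chrX", start = 1, end = 2)),
               "chrX")
  expect_error(extract_window(store, "chrZ", 1, 4), "chrZ")
})

test_that("one-hot encoding maps bases to unit vectors and N to zero", {
  expect_equal(unname(one_hot_encode("A")[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(one_hot_encode("N")[1, ]), c(0, 0, 0, 0))
  expect_equal(unname(one_hot_encode("ACGT")), diag(4))
  expect_error(one_hot_encode("AXZ"))
  ## row sums: 1 for known bases, 0 for unknown
  oh <- one_hot_encode("ACGNTN")
  expect_equal(unname(rowSums(oh)), c(1, 1, 1, 0, 1, 0))
})

test_that("windows are strand-aware and pad beyond bounds with N", {
  store <- genome_store(list(c1 = "AGGT"))
  expect_equal(extract_window(store, "c1", 1, 4, "+"), "AGGT")
  expect_equal(extract_window(store, "c1", 1, 4, "-"), "ACCT")
  expect_equal(extract_window(store, "c1", 1, 6, "+"), "AGGTNN")
  expect_equal(extract_window(store, "c1", -1, 4, "+"), "NNAG")
})

test_that("reverse complement is an involution", {
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 30, TRUE), collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("label track follows the splice-site conventions on both strands", {
  store <- tiny_store()
  tr <- tiny_transcripts()
  track <- build_label_track(tr, store)
  ## + strand: donor at last nt of non-last exon, acceptor at first nt of
  ## non-first exon
  expect_equal(which(track$chrA == 2L), 10L)
  expect_equal(which(track$chrA == 1L), 21L)
  ## - strand: roles taken in transcription direction
  expect_equal(which(track$chrB == 1L), 10L)
  expect_equal(which(track$chrB == 2L), 21L)
  expect_true(all(track$chrA[-c(10L, 21L)] == 0L))
})

test_that("label tracks mirror under strand reflection of the genome", {
  ## a transcript and its strand-reflected copy on the reverse complement
  ## genome produce mirror-image tracks with acceptor/donor swapped
  store <- tiny_store()
  tr_plus <- spliceformer:::transcript_set(list(
    transcript_model("t", "g", "chrA", "+", rbind(c(3, 12), c(23, 32)))))
  L <- store$lengths[["chrA"]]
  rc_store <- genome_store(list(
    chrA = reverse_complement(extract_window(store, "chrA", 1, L, "+"))))
  tr_minus <- spliceformer:::transcript_set(list(
    transcript_model("t", "g", "chrA", "-",
                     rbind(L + 1 - c(32, 23), L + 1 - c(12, 3)))))
  a <- build_label_track(tr_plus, store)$chrA
  b <- build_label_track(tr_minus, rc_store)$chrA
  ## mirror image: the reflected copy transcribes the same RNA, so each
  ## site keeps its type at the mirrored coordinate ...
  expect_equal(a, rev(b))
  ## ... while in genomic order the donor/acceptor succession swaps
  expect_equal(b[b > 0], rev(a[a > 0]))
})

test_that("label conflicts across transcripts are a hard error", {
  store <- tiny_store()
  ## donor at 10 from t1, acceptor at 10 from t3
  tr <- spliceformer:::transcript_set(list(
    transcript_model("t1", "g1", "chrA", "+", rbind(c(1, 10), c(21, 30))),
    transcript_model("t3", "g3", "chrA", "+", rbind(c(2, 6), c(10, 18)))))
  expect_error(build_label_track(tr, store), "onflict")
  tr_oob <- spliceformer:::transcript_set(list(
    transcript_model("t1", "g1", "chrA", "+", rbind(c(1, 10), c(35, 60)))))
  expect_error(build_label_track(tr_oob, store), "bounds")
})

test_that("single-exon transcripts yield no labelled positions", {
  store <- tiny_store()
  tr <- spliceformer:::transcript_set(list(
    transcript_model("t1", "g1", "chrA", "+", rbind(c(5, 20)))))
  expect_equal(sum(build_label_track(tr, store)$chrA), 0)
  expect_equal(nrow(splice_sites(tr)), 0L)
})

test_that("GTF parsing filters biotype, junction count and support level", {
  gtf <- tempfile(fileext = ".gtf")
  line <- function(chrom, type, s, e, strand, attrs) {
    paste(chrom, "src", type, s, e, ".", strand, ".", attrs, sep = "\t")
  }
  at <- function(t, b, tsl) {
    sprintf(paste0('gene_id "g_%s"; transcript_id "%s"; transcript_biotype ',
                   '"%s"; transcript_support_level "%s";'), t, t, b, tsl)
  }
  writeLines(c(
    "#comment",
    line("chr2", "exon", 1, 10, "+", at("keep", "protein_coding", "1")),
    line("chr2", "exon", 21, 30, "+", at("keep", "protein_coding", "1")),
    line("chr2", "exon", 1, 10, "+", at("tsl2", "protein_coding", "2")),
    line("chr2", "exon", 21, 30, "+", at("tsl2", "protein_coding", "2")),
    line("chr2", "exon", 1, 10, "+", at("lnc", "lncRNA", "1")),
    line("chr2", "exon", 21, 30, "+", at("lnc", "lncRNA", "1")),
    line("chr2", "exon", 1, 10, "+", at("mono", "protein_coding", "1"))),
    gtf)
  tr <- parse_gtf_transcripts(gtf, mode = "ensembl")
  expect_equal(vapply(tr, `[[`, "", "transcript_id"), "keep")
  ## gencode mode keeps the support-level-2 transcript
  tr_g <- parse_gtf_transcripts(gtf, mode = "gencode")
  expect_setequal(vapply(tr_g, `[[`, "", "transcript_id"), c("keep", "tsl2"))
})

test_that("GFF3 dialect and malformed records are handled", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "src", "mRNA", 1, 30, ".", "+", ".",
          "ID=transcript:tA;Parent=gene:gA;biotype=protein_coding;transcript_support_level=1",
          sep = "\t"),
    paste("chr1", "src", "exon", 1, 10, ".", "+", ".",
          "Parent=transcript:tA", sep = "\t"),
    paste("chr1", "src", "exon", 21, 30, ".", "+", ".",
          "Parent=transcript:tA", sep = "\t"),
    "chr1\tbroken line without fields"), gff)
  expect_warning(tr <- parse_gtf_transcripts(gff, mode = "ensembl"),
                 "malformed")
  expect_equal(tr[[1]]$transcript_id, "tA")
  expect_equal(unname(tr[[1]]$exons), rbind(c(1, 10), c(21, 30)))
  ## zero retained transcripts is an explicit error
  gtf_empty <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "s", "exon", 1, 10, ".", "+", ".",
                   'gene_id "g"; transcript_id "t"; transcript_biotype "lncRNA";',
                   sep = "\t"), gtf_empty)
  expect_error(parse_gtf_transcripts(gtf_empty), "no transcripts")
})

test_that("chromosome split is held-out, seeded and exhaustive", {
  trs <- lapply(1:100, function(i) {
    transcript_model(paste0("t", i), paste0("g", i),
                     if (i <= 20) "chr1" else "chr2", "+",
                     rbind(c(1, 10), c(21, 30)))
  })
  trs <- spliceformer:::transcript_set(trs)
  sp <- split_by_chromosome(trs, validation_fraction = 0.1, seed = 4L)
  expect_equal(length(sp$test), 20L)
  expect_true(all(vapply(sp$test, `[[`, "", "chromosome") == "chr1"))
  expect_equal(length(sp$validation), 8L)  # 10% of the 80 non-held-out
  expect_equal(length(sp$train) + length(sp$validation) + length(sp$test),
               100L)
  ids <- function(x) vapply(x, `[[`, "", "transcript_id")
  expect_equal(length(unique(c(ids(sp$train), ids(sp$validation),
                               ids(sp$test)))), 100L)
  sp2 <- split_by_chromosome(trs, validation_fraction = 0.1, seed = 4L)
  expect_identical(ids(sp$validation), ids(sp2$validation))
})

test_that("BED output is 0-based half-open", {
  sites <- data.frame(chrom = "chr1", pos = 21L, strand = "+",
                      type = "acceptor", transcript_id = "t")
  path <- tempfile(fileext = ".bed")
  write_labels_bed(sites, path)
  bed <- utils::read.table(path)
  expect_equal(bed$V2, 20L)
  expect_equal(bed$V3, 21L)
})
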