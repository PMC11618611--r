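## helper: evidence rows for one junction/individual with given overhangs
ev_rows <- function(overhangs, individual = "s1", chrom = "chr1",
                    start = 1051, end = 1150, strand = "+", mm = FALSE) {
  data.frame(individual = individual, chrom = chrom, intron_start = start,
             intron_end = end, strand = strand,
             left_overhang = overhangs[, 1], right_overhang = overhangs[, 2],
             multimapped = mm)
}

good_overhangs <- cbind(c(10, 30, 12, 35), c(20, 40, 28, 15))

test_that("CIGAR arithmetic yields junction bounds and overhangs", {
  j <- spliceformer:::.cigar_junctions(1001L, "50M100N50M")
  ## 0-based start 1000 -> gap [1050, 1150) half-open = [1051, 1150] 1-based
  expect_equal(unname(j[1, ]), c(1051, 1150, 50, 50))
  ## no N operation, no junction
  expect_null(spliceformer:::.cigar_junctions(1001L, "100M"))
  ## two junctions from one read
  j2 <- spliceformer:::.cigar_junctions(1L, "20M10N20M5N20M")
  expect_equal(unname(j2[1, ]), c(21, 30, 20, 20))
  expect_equal(unname(j2[2, ]), c(51, 55, 20, 20))
  ## deletions consume reference; insertions and clips do not
  j3 <- spliceformer:::.cigar_junctions(1L, "5S10M2D3I10M100N10M")
  expect_equal(unname(j3[1, ]), c(23, 122, 22, 10))
  expect_error(spliceformer:::.cigar_junctions(1L, "10Q"), "malformed")
})

test_that("SAM round-trip recovers the generated fragment evidence", {
  sim <- generate_genome(n_genes = 3L, chromosome_plan = c(chrS = 60000L),
                         seed = 14L)
  fr <- generate_fragments(sim$transcripts, depth = 5, n_individuals = 2L,
                           multimap_fraction = 0.3, seed = 2L)
  sam <- tempfile(fileext = ".sam")
  write_fragments_sam(fr, sim$store, sam)
  back <- extract_junctions(sam)
  expect_equal(nrow(back), nrow(fr))
  key <- function(d) paste(d$individual, d$chrom, d$intron_start,
                           d$intron_end, d$left_overhang, d$right_overhang)
  expect_setequal(key(back), key(fr))
  expect_equal(sum(back$multimapped), sum(fr$multimapped))
  expect_setequal(unique(back$strand), unique(fr$strand))
})

test_that("SAM text agrees with samtools-converted BAM when available", {
  skip_if_not_installed("Rsamtools")
  sim <- generate_genome(n_genes = 2L, chromosome_plan = c(chrS = 60000L),
                         seed = 15L)
  fr <- generate_fragments(sim$transcripts, depth = 3, n_individuals = 1L,
                           seed = 3L)
  sam <- tempfile(fileext = ".sam")
  write_fragments_sam(fr, sim$store, sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  a <- extract_junctions(sam)
  b <- extract_junctions(bam)
  o <- function(d) d[order(d$intron_start, d$left_overhang), ]
  expect_equal(o(a)$intron_start, o(b)$intron_start)
  expect_equal(o(a)$left_overhang, o(b)$left_overhang)
  expect_equal(o(a)$multimapped, o(b)$multimapped)
})

test_that("mates supporting the same junction count once", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:chr1\tLN:10000",
               paste("s1:r1", 0, "chr1", 1001, 60, "50M100N50M", "*", 0, 0,
                     "*", "*", "NH:i:1", sep = "\t"),
               paste("s1:r1", 0, "chr1", 1021, 60, "30M100N70M", "*", 0, 0,
                     "*", "*", "NH:i:1", sep = "\t"),
               paste("s1:r2", 0, "chr1", 1001, 60, "50M100N50M", "*", 0, 0,
                     "*", "*", "NH:i:1", sep = "\t")), sam)
  ev <- extract_junctions(sam)
  ## the two mates of r1 support the same junction -> one fragment each for
  ## r1 and r2
  expect_equal(nrow(ev), 2L)
  expect_equal(unique(ev$individual), "s1")
})

test_that("per-individual criteria fail for the documented reasons", {
  ## 3 fragments -> fragment count
  f <- filter_individual(ev_rows(good_overhangs[1:3, ]))
  expect_false(f$pass)
  expect_true("fragment_count" %in% f$reasons)
  ## all min-overhangs <= 7
  f <- filter_individual(ev_rows(cbind(c(5, 6, 7, 3), c(50, 60, 7, 70))))
  expect_false(f$pass)
  expect_equal(f$reasons, "overhang")
  ## identical overhang pairs: entropy 0 even with 8 fragments
  f <- filter_individual(ev_rows(cbind(rep(20, 8), rep(20, 8))))
  expect_false(f$pass)
  expect_equal(f$reasons, "entropy")
  ## outside every gene boundary
  f <- filter_individual(ev_rows(good_overhangs),
                         gene_bounds = data.frame(chrom = "chr1",
                                                  start = 5000, end = 9000))
  expect_equal(f$reasons, "gene_boundary")
  ## and a junction passing everything
  f <- filter_individual(ev_rows(good_overhangs),
                         gene_bounds = data.frame(chrom = "chr1",
                                                  start = 1000, end = 2000))
  expect_true(f$pass)
  expect_length(f$reasons, 0L)
})

test_that("overhang entropy pools both sides in bits", {
  ## four equiprobable pooled lengths -> 2 bits exactly
  expect_equal(overhang_entropy(c(10, 20), c(30, 40)), 2)
  expect_equal(overhang_entropy(rep(5, 4), rep(5, 4)), 0)
  ## boundary: entropy exactly 2 passes (criterion is >= 2)
  f <- filter_individual(ev_rows(cbind(c(10, 10, 20, 20),
                                       c(30, 30, 40, 40))))
  expect_true(f$pass)
})

test_that("aggregate filter fails only on strict violation", {
  s <- function(mm, mx) list(multimapped_fraction = mm, max_count = mx)
  expect_false(filter_aggregate(s(0.21, 100), abundance = 100)$pass)
  expect_false(filter_aggregate(s(0.1, 4), abundance = 100)$pass)
  ## boundary cases pass: exactly 20% multimapped, exactly 5% abundance
  expect_true(filter_aggregate(s(0.20, 5), abundance = 100)$pass)
  ## missing abundance skips the abundance test
  expect_true(filter_aggregate(s(0.0, 1), abundance = NA)$pass)
})

test_that("filters are order-independent", {
  ## the verdict is the conjunction of independent criteria, so applying
  ## them in any order gives the same result; check via reason sets on
  ## evidence violating several criteria at once
  bad <- ev_rows(cbind(c(5, 5), c(5, 5)))
  f <- filter_individual(bad, gene_bounds = data.frame(chrom = "chrX",
                                                       start = 1, end = 2))
  expect_setequal(f$reasons, c("fragment_count", "overhang", "entropy",
                               "gene_boundary"))
})

test_that("SOSJ grouping is the transitive closure of shared sites", {
  jx <- data.frame(chrom = "chr1",
                   intron_start = c(100, 100, 300, 500, 700, 900),
                   intron_end = c(200, 250, 400, 600, 800, 800),
                   strand = "+")
  ids <- group_sosj(jx)
  ## (d1->a1), (d1->a2) share the donor -> one SOSJ
  expect_equal(ids[1], ids[2])
  ## disjoint junctions are singletons
  expect_false(ids[3] %in% ids[c(1, 2, 4, 5, 6)])
  ## shared acceptor groups 5 and 6
  expect_equal(ids[5], ids[6])
  ## chain closure: (d1->a1), (d2->a1), (d2->a3) -> one SOSJ of 3
  chain <- data.frame(chrom = "c", intron_start = c(1, 50, 50),
                      intron_end = c(10, 10, 90), strand = "+")
  expect_equal(length(unique(group_sosj(chain))), 1L)
  ## strand-aware: same coordinates on opposite strands do not join
  two <- data.frame(chrom = "c", intron_start = c(1, 1),
                    intron_end = c(10, 20), strand = c("+", "-"))
  expect_equal(length(unique(group_sosj(two))), 2L)
})

test_that("PSI is the junction share of its SOSJ, NA when unexpressed", {
  counts <- rbind(c(3, 0), c(1, 0), c(5, 2))
  psi <- compute_psi(counts, sosj = c(1L, 1L, 2L))
  expect_equal(psi[, 1], c(0.75, 0.25, 1))
  expect_true(all(is.na(psi[1:2, 2])))
  expect_equal(psi[3, 2], 1)
  ## PSI within an SOSJ sums to 1 when nothing was filtered
  expect_equal(sum(psi[1:2, 1]), 1)
})

test_that("junction annotation requires both coordinates to match", {
  ref <- data.frame(chrom = "chr1", start = 101, end = 200)
  jx <- data.frame(chrom = "chr1", intron_start = c(101, 102, 101),
                   intron_end = c(200, 200, 201))
  expect_equal(annotate_junctions(jx, ref), c(TRUE, FALSE, FALSE))
  expect_equal(annotate_junctions(jx, ref[0, ]), rep(FALSE, 3))
})

test_that("pipeline recovers planted junctions end to end", {
  sim <- generate_genome(n_genes = 5L, chromosome_plan = c(chrJ = 100000L),
                         seed = 17L)
  fr <- generate_fragments(sim$transcripts, depth = 12, n_individuals = 3L,
                           multimap_fraction = 0.05, seed = 4L)
  bounds <- do.call(rbind, lapply(sim$transcripts, function(tr) {
    data.frame(chrom = tr$chromosome, start = min(tr$exons),
               end = max(tr$exons), gene_id = tr$gene_id)
  }))
  res <- junction_pipeline(fr, gene_bounds = bounds,
                           reference = sim$transcripts)
  introns <- transcript_introns(sim$transcripts)
  ## every planted junction passes at the default generator settings
  expect_equal(sum(res$junctions$pass), nrow(introns))
  expect_true(all(res$junctions$annotated[res$junctions$pass]))
  ## per-individual PSI within an SOSJ sums to 1 where expressed
  psi <- res$psi
  ids <- res$junctions$sosj_id[res$junctions$pass]
  for (g in unique(ids)) {
    s <- colSums(psi[ids == g, , drop = FALSE])
    expect_true(all(abs(s[!is.na(s)] - 1) < 1e-12))
  }
})
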