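test_that("the k-mer index enumerates occurrences on both strands", {
  g <- structure(c(chr1 = "ACGTACGT"), class = "genome")
  idx <- build_index(g, k = 4)
  hits <- index_lookup(idx, "ACGT")
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$pos, c(0L, 4L))
  ## ACGT is its own reverse complement: same loci on the minus strand
  minus <- hits[hits$strand == "-", ]
  expect_equal(minus$pos, c(0L, 4L))
  gt <- index_lookup(build_index(g, k = 2), "GT")
  expect_equal(gt[gt$strand == "+", "pos"], c(2L, 6L))
  expect_equal(nrow(index_lookup(idx, "AAAA")), 0L)
  expect_error(build_index(g, k = 10), "shortest chromosome")
  expect_error(index_lookup(idx, "ACGTA"), "length")
})

test_that("linear mapping places error-free reads and rejects junctions", {
  ref <- tiny_reference()
  circs <- plant_circrnas(ref, n = 6, alt_circ_genes = 1, seed = 12)
  reads <- simulate_reads(ref, circs, junction_reads = 3, linear_depth = 2,
                          seed = 12)
  lm <- linear_map(reads[, c("read_id", "sequence")], ref$genome)
  jx <- grepl("_jx_", reads$read_id)
  expect_true(all(!lm$mapped[jx]))
  ## contiguous single-exon reads map; spliced reads do not
  lin_mapped <- lm$mapped[!jx]
  expect_gt(mean(lin_mapped), 0.3)
  for (i in which(lm$mapped)[1:10]) {
    gseq <- genome_subseq(ref$genome, lm$chrom[i], lm$pos[i],
                          lm$pos[i] + lm$len[i])
    rd <- if (lm$strand[i] == "+") reads$sequence[i] else revcomp(reads$sequence[i])
    expect_equal(gseq, rd)
  }
  nn <- data.frame(read_id = "n", sequence = strrep("N", 100))
  expect_false(linear_map(nn, ref$genome)$mapped)
})

test_that("detect_junction recovers planted breakpoints exactly", {
  ref <- tiny_reference()
  circs <- plant_circrnas(ref, n = 8, alt_circ_genes = 1, seed = 13)
  reads <- simulate_reads(ref, circs, junction_reads = 2, linear_depth = 0,
                          seed = 13)
  for (i in seq_len(nrow(reads))) {
    cand <- detect_junction(reads$sequence[i], ref$genome, ref$genes)
    truth <- circs[circs$circ_id == reads$source[i], ]
    expect_false(is.null(cand))
    expect_equal(cand$chrom, truth$chrom)
    expect_equal(cand$start, truth$start)
    expect_equal(cand$end, truth$end)
    expect_equal(cand$strand, truth$strand)
  }
})

test_that("forward-order and signal-less breakpoints are rejected", {
  ref <- tiny_reference()
  ## a spliced linear read: anchors in forward order -> no junction
  g <- ref$genes[[1]]
  tseq <- transcript_sequence(ref$genome, g, g$transcripts[[1]])
  ex1 <- g$transcripts[[1]]$exons[1, 2] - g$transcripts[[1]]$exons[1, 1]
  spliced <- substr(tseq, max(1, ex1 - 50), max(1, ex1 - 50) + 99)
  expect_null(detect_junction(spliced, ref$genome, ref$genes))
  ## a chimeric read joining two loci without the splice signal
  gseq <- ref$genome[[1]]
  S <- 9000L; E <- 12000L
  repeat {
    up <- substr(gseq, S - 1, S)
    down <- substr(gseq, E + 1, E + 2)
    if (!(up %in% c("AG", "AC")) && !(down %in% c("GT", "CT"))) break
    S <- S + 1L; E <- E + 1L
  }
  fake <- paste0(substr(gseq, E - 49, E), substr(gseq, S + 1, S + 50))
  expect_null(detect_junction(fake, ref$genome, ref$genes))
})

test_that("circRNA calling filters, merges and sorts candidates", {
  fix <- detection_fixture()
  det <- fix$det
  ## support filter: the planted 1-read circs never appear
  expect_false(any(circ_key(fix$low) %in% circ_key(det$circs)))
  ## distance filter: planted > 100 kb junctions never appear
  expect_false(any(circ_key(fix$long) %in% circ_key(det$circs)))
  expect_true(all(det$circs$end - det$circs$start <= 100000))
  expect_true(all(det$circs$junction_reads >= 2))
  ## counts: planted 20 junction reads are all recovered
  main_hit <- merge(det$circs, fix$main, by = c("chrom", "start", "end"))
  expect_true(all(main_hit$junction_reads == 20))
  ## sorted output
  expect_false(is.unsorted(order(det$circs$chrom, det$circs$start)))
  ## every reported signal matches the genomic dinucleotides on its strand
  for (i in seq_len(nrow(det$circs))) {
    sd <- if (det$circs$strand[i] == "+") c("AG", "GT") else c("AC", "CT")
    expect_equal(genome_subseq(fix$ref$genome, det$circs$chrom[i],
                               det$circs$start[i] - 2L, det$circs$start[i]),
                 sd[1])
    expect_equal(genome_subseq(fix$ref$genome, det$circs$chrom[i],
                               det$circs$end[i], det$circs$end[i] + 2L), sd[2])
  }
})

test_that("calling is invariant to read input order", {
  ref <- tiny_reference()
  circs <- plant_circrnas(ref, n = 6, alt_circ_genes = 1, seed = 14)
  reads <- simulate_reads(ref, circs, junction_reads = 5, linear_depth = 1,
                          seed = 14)[, c("read_id", "sequence")]
  d1 <- call_circrnas(reads, ref$genome, ref$genes)
  set.seed(99)
  d2 <- call_circrnas(reads[sample(nrow(reads)), ], ref$genome, ref$genes)
  expect_equal(d1$circs[, c("chrom", "start", "end", "strand",
                            "junction_reads")],
               d2$circs[, c("chrom", "start", "end", "strand",
                            "junction_reads")])
  expect_equal(d1$circs$supporting_reads, d2$circs$supporting_reads)
})

test_that("no reads yields an empty result with a warning", {
  ref <- tiny_reference()
  empty <- data.frame(read_id = character(0), sequence = character(0))
  expect_warning(res <- call_circrnas(empty, ref$genome), "no reads")
  expect_equal(nrow(res$circs), 0L)
})
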