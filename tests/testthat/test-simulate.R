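test_that("reference generation is deterministic and respects the config", {
  cfg <- sim_config(seed = 7, n_chrom = 1, chrom_length = 200000, n_genes = 10)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$genome, r2$genome)
  f1 <- tempfile(); f2 <- tempfile()
  write_annotation(r1$genes, f1); write_annotation(r2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_length(r1$genes, 10)
  n_ex <- vapply(r1$genes, function(g) nrow(g$transcripts[[1]]$exons), integer(1))
  expect_true(all(n_ex >= 4 & n_ex <= 8))
  ## genes non-overlapping
  spans <- do.call(rbind, lapply(r1$genes, function(g) c(g$start, g$end)))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
  expect_error(generate_reference(sim_config(seed = 1, chrom_length = 5000,
                                             n_genes = 10)),
               "too small")
})

test_that("planted circRNAs match their class and carry splice signals", {
  ref <- tiny_reference()
  circs <- plant_circrnas(ref, n = 20, alt_circ_genes = 3, seed = 9)
  expect_equal(as.vector(table(circs$class)[c("within", "overlap", "intergenic")]),
               c(10L, 4L, 6L))
  for (i in seq_len(nrow(circs))) {
    cls <- classify_position(circs$chrom[i], circs$start[i], circs$end[i],
                             ref$genes)
    expected <- c(within = "within_gene", overlap = "overlap_gene",
                  intergenic = "intergenic")[[circs$class[i]]]
    expect_equal(cls, expected)
    sd <- if (circs$strand[i] == "+") c("AG", "GT") else c("AC", "CT")
    expect_equal(genome_subseq(ref$genome, circs$chrom[i],
                               circs$start[i] - 2L, circs$start[i]), sd[1])
    expect_equal(genome_subseq(ref$genome, circs$chrom[i], circs$end[i],
                               circs$end[i] + 2L), sd[2])
  }
  ## alternative circularization: planted genes parent >= 2 distinct isoforms
  multi <- table(circs$parent_gene[circs$class == "within"])
  expect_gte(sum(multi >= 2), 3)
  ## determinism
  expect_identical(circs, plant_circrnas(ref, n = 20, alt_circ_genes = 3,
                                         seed = 9))
})

test_that("junction reads concatenate the circ 3' end with its 5' start", {
  ref <- tiny_reference()
  circs <- plant_circrnas(ref, n = 6, alt_circ_genes = 1, seed = 4)
  reads <- simulate_reads(ref, circs, junction_reads = 15, linear_depth = 0,
                          error_rate = 0, seed = 4)
  expect_equal(nrow(reads), 6 * 15)
  plus <- circs[circs$strand == "+", ][1, ]
  rr <- reads[reads$source == plus$circ_id, ]
  ## error-free: the first 20 nt lie immediately upstream of the end
  ## coordinate, i.e. are an exact genome substring ending at `end`
  end_ctx <- genome_subseq(ref$genome, plus$chrom, plus$end - 80L, plus$end)
  start_ctx <- genome_subseq(ref$genome, plus$chrom, plus$start,
                             plus$start + 80L)
  for (s in rr$sequence[1:5]) {
    expect_true(grepl(substr(s, 1, 20), end_ctx, fixed = TRUE))
    expect_true(grepl(substr(s, nchar(s) - 19, nchar(s)), start_ctx,
                      fixed = TRUE))
  }
  ## junction string present exactly for every read of an error-free circ
  junc <- paste0(genome_subseq(ref$genome, plus$chrom, plus$end - 20L, plus$end),
                 genome_subseq(ref$genome, plus$chrom, plus$start,
                               plus$start + 20L))
  ## the breakpoint sits >= 20 nt from both read ends, so the 40-nt junction
  ## string is contained in every error-free junction read
  expect_true(all(vapply(rr$sequence, grepl, logical(1), pattern = junc,
                         fixed = TRUE)))
  ## determinism
  reads2 <- simulate_reads(ref, circs, junction_reads = 15, linear_depth = 0,
                           error_rate = 0, seed = 4)
  expect_identical(reads, reads2)
  expect_error(simulate_reads(ref, circs, read_length = 30), "anchor")
})

test_that("planted decoy designs record verdicts and feasibility", {
  expect_error(decoy_design(seed_mm = 8), "seed_mm")
  expect_error(decoy_design(central_ins = 7), "central_ins")
  set.seed(1)
  circ_seqs <- stats::setNames(vapply(1:3, function(i) random_dna(150),
                                      character(1)), paste0("c", 1:3))
  designs <- list(decoy_design(central_mm = 3, other_mm = 1),
                  decoy_design(seed_mm = 1, central_mm = 3),
                  decoy_design(central_mm = 0))
  pl <- plant_decoy_sites(circ_seqs, designs, seed = 2)
  expect_equal(pl$truth$expected_pass, c(TRUE, FALSE, FALSE))
  expect_equal(pl$truth$expected_failing_rule, c(NA_integer_, 2L, 1L))
  expect_true(all(nchar(pl$mirnas) == 21))
  expect_identical(pl, plant_decoy_sites(circ_seqs, designs, seed = 2))
})

test_that("expression profiles plant tissue specificity and fold changes", {
  ids <- sprintf("c%02d", 1:40)
  prof <- plant_expression_profiles(ids, n_tissues = 5, n_specific = 8,
    de_pairs = list(list(pair = c("ctrl", "heat"), fold_change = 4,
                         n_affected = 10)), seed = 3)
  expect_equal(nrow(prof$tissue_truth), 8)
  for (i in seq_len(nrow(prof$tissue_truth))) {
    row <- prof$tissue_counts[prof$tissue_truth$circ_id[i], ]
    other <- row[setdiff(names(row), prof$tissue_truth$tissue[i])]
    expect_true(all(other == 0))
    expect_gte(row[[prof$tissue_truth$tissue[i]]], 10)
  }
  de <- prof$de[["ctrl:heat"]]
  expect_equal(dim(de$counts), c(40L, 6L))
  expect_error(plant_expression_profiles(ids, n_specific = 50), "exceeds")
  expect_identical(prof, plant_expression_profiles(ids, n_tissues = 5,
    n_specific = 8, de_pairs = list(list(pair = c("ctrl", "heat"),
    fold_change = 4, n_affected = 10)), seed = 3))
})

test_that("proteome pairs encode the requested divergence", {
  pp0 <- generate_proteome_pair(n_orthologs = 10, divergence = 0, seed = 5,
                                n_paralogs = 0, n_unpaired = 0)
  expect_equal(unname(pp0$proteome_a), unname(pp0$proteome_b))
  expect_equal(nrow(pp0$ortholog_truth), 10)
  pp <- generate_proteome_pair(n_orthologs = 10, divergence = 0.1, seed = 5)
  ident <- vapply(seq_len(10), function(i) {
    a <- strsplit(pp$proteome_a[[pp$ortholog_truth$gene_a[i]]], "")[[1]]
    b <- strsplit(pp$proteome_b[[pp$ortholog_truth$gene_b[i]]], "")[[1]]
    mean(a == b)
  }, numeric(1))
  expect_true(all(ident > 0.8))
  expect_error(generate_proteome_pair(divergence = 1), "divergence")
})
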