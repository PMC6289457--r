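test_that("positional classes are exhaustive and mutually exclusive", {
  genes <- toy_genes()
  expect_equal(classify_position("chr1", 1000, 2000, genes), "within_gene")
  expect_equal(classify_position("chr1", 2500, 3500, genes), "overlap_gene")
  expect_equal(classify_position("chr1", 10000, 11000, genes), "intergenic")
  expect_equal(classify_position("chr2", 1000, 2000, genes), "intergenic")
  ## boundary containment counts as within
  expect_equal(classify_position("chr1", 500, 3000, genes), "within_gene")
})

test_that("back-splice site labels follow feature precedence", {
  genes <- toy_genes()
  expect_equal(label_backsplice_sites("chr1", 700, 2000, "+", genes)$site_label,
               c("CDS", "CDS"))
  expect_equal(label_backsplice_sites("chr1", 1300, 1400, "+", genes)$site_label,
               c("intron", "intron"))
  lab <- label_backsplice_sites("chr1", 2950, 3500, "+", genes)
  expect_equal(lab$site_label, c("3'UTR", "intergenic"))
  expect_equal(lab$canonical, "3'UTR-intergenic")
  ## minus-strand circs report the 5' boundary (genomic end) first
  expect_equal(label_backsplice_sites("chr1", 550, 2000, "-", genes)$site_label,
               c("CDS", "5'UTR"))
})

test_that("boundary status compares against annotated exon edges", {
  genes <- toy_genes()
  expect_equal(boundary_status("chr1", 1500, 2300, genes), "both_known")
  expect_equal(boundary_status("chr1", 1500, 2295, genes), "one_known")
  expect_equal(boundary_status("chr1", 1300, 2400, genes), "none_known")
})

test_that("a 3'UTR-intergenic circ is exonic but not within a gene", {
  genes <- toy_genes()
  circs <- data.frame(circ_id = "cx", chrom = "chr1", start = 2950L,
                      end = 3500L, strand = "+")
  ann <- annotate_circs(circs, genes)
  expect_equal(ann$positional_class, "overlap_gene")
  expect_true(ann$is_exonic)
  expect_equal(ann$site_label, "3'UTR-intergenic")
})

test_that("alternative circularization groups genes with >= 2 isoforms", {
  genes <- toy_genes()
  circs <- data.frame(circ_id = c("c1", "c2", "c3"), chrom = "chr1",
                      start = c(500L, 1500L, 5000L),
                      end = c(1200L, 2300L, 5600L), strand = "+")
  ann <- annotate_circs(circs, genes)
  grp <- group_alternative_circularization(ann)
  expect_equal(names(grp$groups), "g1")
  expect_setequal(grp$groups$g1, c("c1", "c2"))
  expect_equal(ann$alt_group_size[1:2], c(2L, 2L))
  ## all genes parenting <= 1 circ -> empty map
  solo <- annotate_circs(circs[1, ], genes)
  expect_length(group_alternative_circularization(solo)$groups, 0)
})

test_that("lincRNA overlap reports intergenic circs only, half-open", {
  genes <- toy_genes()
  lincs <- data.frame(lincrna_id = c("L1", "L2"), chrom = "chr1",
                      start = c(5000L, 8000L), end = c(6000L, 9000L))
  circs <- data.frame(circ_id = c("ci", "cw", "cadj"), chrom = "chr1",
                      start = c(5200L, 600L, 6000L),
                      end = c(5800L, 1000L, 6400L), strand = "+")
  ann <- annotate_circs(circs, genes, lincs)
  ov <- lincrna_overlap(circs, ann, lincs)
  ## within-gene circ excluded; adjacency (zero-length intersection) excluded
  expect_equal(ov$circ_id, "ci")
  expect_equal(ov$lincrna_id, "L1")
})

test_that("planted classes are recovered exactly from detection output", {
  fix <- detection_fixture()
  det <- fix$det
  ann <- annotate_circs(det$circs, fix$ref$genes, fix$ref$lincrnas)
  ## classes partition the called set
  expect_equal(sum(table(ann$positional_class)), nrow(det$circs))
  m <- merge(cbind(det$circs, class_called = ann$positional_class),
             fix$main, by = c("chrom", "start", "end"))
  expected <- c(within = "within_gene", overlap = "overlap_gene",
                intergenic = "intergenic")[m$class]
  expect_equal(m$class_called, unname(expected))
  ## planted alternative-circularization genes recovered with correct sizes
  grp <- group_alternative_circularization(ann)
  planted_multi <- table(fix$main$parent_gene[fix$main$class == "within"])
  planted_multi <- planted_multi[planted_multi >= 2]
  called_parents <- names(grp$groups)
  expect_true(all(names(planted_multi) %in% called_parents))
})
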