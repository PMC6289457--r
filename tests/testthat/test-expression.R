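test_that("RPM and circular-to-linear ratio follow their definitions", {
  expect_equal(rpm(50, 1e7), 5)
  expect_equal(rpm(0, 123), 0)
  ## conservation: RPM scaled back by total/1e6 recovers the counts
  cnt <- c(3, 17, 250)
  expect_equal(sum(rpm(cnt, 2e6) * 2e6 / 1e6), sum(cnt))
  expect_error(rpm(1, 0), "positive")
  expect_equal(circular_to_linear_ratio(10, 20), 0.5)
  expect_equal(circular_to_linear_ratio(0, 20), 0)
  expect_equal(circular_to_linear_ratio(10, 0), Inf)
})

test_that("expression binning is left-closed right-open with an open top", {
  h <- bin_expression(c(0.5, 0.2, 1, 4.9, 10, 11, Inf), kind = "circ")
  expect_equal(unname(h), c(1L, 1L, 2L, 0L, 3L))
  expect_equal(sum(h), 7L)
  g <- bin_expression(c(2500, 49.999, 500), kind = "gene")
  expect_equal(unname(g), c(1L, 0L, 0L, 1L, 1L))
  expect_equal(sum(bin_expression(numeric(0), "circ")), 0L)
  expect_error(bin_expression(c(-1, 2), "circ"), ">= 0")
})

test_that("tissue-specificity index matches its closed forms", {
  expect_equal(tissue_specific_index(c(10, 0, 0, 0, 0)), 1)
  expect_equal(tissue_specific_index(rep(7, 6)), 0)
  expect_equal(tissue_specific_index(c(10, 5, 0, 0, 5)), 0.75)
  expect_true(is.na(tissue_specific_index(c(0, 0, 0))))
  expect_error(tissue_specific_index(5), "two tissues")
})

test_that("tissue index is bounded, maximal only for single-tissue vectors,
           and decreases when a zero tissue is raised", {
  set.seed(31)
  for (rep in 1:50) {
    v <- round(stats::rexp(sample(3:8, 1)) * 20)
    if (all(v == 0)) v[1] <- 5
    idx <- tissue_specific_index(v)
    expect_gte(idx, 0); expect_lte(idx, 1)
    expect_equal(idx == 1, sum(v > 0) == 1)
    if (any(v == 0) && max(v) > 0) {
      v2 <- v
      v2[which(v == 0)[1]] <- max(v) / 2
      expect_lt(tissue_specific_index(v2), idx)
    }
  }
})

test_that("Benjamini-Hochberg matches the hand step-up and the reference", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:25) {
    p <- stats::runif(sample(c(1, 5, 100), 1))
    expect_equal(benjamini_hochberg(p), stats::p.adjust(p, "BH"),
                 tolerance = 1e-14)
  }
})

test_that("coexpression recovers planted correlated pairs with power", {
  set.seed(77)
  n <- 20
  ids <- sprintf("c%02d", 1:30)
  latent <- matrix(stats::rnorm(30 * n, 10, 4), 30, n)
  circ <- latent + stats::rnorm(30 * n, 0, 1)
  gene <- latent + stats::rnorm(30 * n, 0, 1)       # first 15 share the latent
  gene[16:30, ] <- matrix(stats::rnorm(15 * n, 10, 4), 15, n)
  rownames(circ) <- ids; rownames(gene) <- sub("c", "g", ids)
  pairs <- data.frame(circ_id = ids, gene_id = sub("c", "g", ids))
  res <- coexpression(circ, gene, pairs)
  expect_true(all(res$r >= -1 & res$r <= 1))
  expect_gte(mean(res$significant[1:15]), 0.8)
  ## exact limiting cases
  v <- matrix(rep(c(1, 3, 7, 2, 9), 2), 2, 5, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  w <- rbind(a = v[1, ], b = -v[1, ])
  r2 <- coexpression(v, w, data.frame(circ_id = c("a", "b"),
                                      gene_id = c("a", "b")))
  expect_equal(r2$r, c(1, -1))
  ## zero-variance pairs are skipped with a message
  z <- rbind(a = rep(2, 5))
  expect_message(res0 <- coexpression(z, z, data.frame(circ_id = "a",
                                                       gene_id = "a")),
                 "zero-variance")
  expect_equal(nrow(res0), 0L)
})

test_that("differential expression direction is antisymmetric in conditions", {
  counts <- matrix(c(10, 12, 9, 44, 38, 41,
                     20, 22, 18, 21, 19, 20), 2, 6, byrow = TRUE,
                   dimnames = list(c("cup", "cns"), NULL))
  cond <- rep(c("A", "B"), each = 3)
  libs <- rep(1e6, 6)
  fwd <- differential_expression(counts, factor(cond, c("A", "B")),
                                 library_sizes = libs)
  rev <- differential_expression(counts, factor(cond, c("B", "A")),
                                 library_sizes = libs)
  expect_equal(fwd$fold_change, 1 / rev$fold_change, tolerance = 1e-12)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  swap <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(swap[fwd$direction]), rev$direction)
  ## identical counts in both conditions: fold change 1, not called
  same <- matrix(rep(c(30, 35, 28), 2), 1, 6,
                 dimnames = list("c1", NULL))
  r <- differential_expression(same, cond, library_sizes = libs)
  expect_equal(r$fold_change, 1)
  expect_equal(r$direction, "ns")
})

test_that("linear boundary counts and parent RPKM come from alignments", {
  circs <- data.frame(circ_id = "c1", chrom = "chr1", start = 1000L,
                      end = 1500L)
  al <- data.frame(chrom = "chr1",
                   pos = c(950L, 995L, 1480L, 700L, 1493L),
                   len = 100L)
  ## start boundary: read at 950 crosses with >= 8 nt both sides; read at
  ## 995 leaves only 5 nt on the left -> not counted
  ## end boundary: 1480 crosses; 1493 leaves 7 nt -> not counted
  lc <- circ_linear_counts(circs, al)
  expect_equal(unname(lc), (1 + 1) / 2)
  genes <- toy_genes()
  rk <- gene_rpkm(genes, al, total_mapped = 1e6)
  ## exon kb = (700 + 800 + 300)/1000 = 1.8; reads overlapping exons: all 5
  expect_equal(unname(rk), 5 / 1.8)
})
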