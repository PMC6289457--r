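## Expression analysis: junction RPM, circular-to-linear ratio, parent-gene
## RPKM, binned abundance summaries, tissue-specificity index, circ/parent
## coexpression, and count-based differential expression with BH FDR
## control. The DE test is a two-sided Fisher exact test on per-condition
## pooled junction counts against the library remainder; fold changes use
## counts scaled to the geometric-mean library size with a +0.5 pseudocount.

#' Junction reads per million mapped reads
#'
#' @param junction_count junction read count(s).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return RPM value(s).
#' @export
rpm <- function(junction_count, total_mapped) {
  if (any(total_mapped <= 0)) stop_fmt("total_mapped must be positive")
  junction_count / total_mapped * 1e6
}

#' Circular-to-linear expression ratio
#'
#' The linear denominator is the mean of linear-orientation reads crossing
#' the circ's start and end boundaries (see [circ_linear_counts()]). A zero
#' denominator yields `Inf`, which the binning step places in the top
#' (">10") bin.
#'
#' @param circ_count junction read count.
#' @param linear_count linear boundary-crossing read count.
#' @return ratio (possibly `Inf`).
#' @export
circular_to_linear_ratio <- function(circ_count, linear_count) {
  ifelse(linear_count == 0, Inf, circ_count / linear_count)
}

#' Bin expression values into the reporting levels
#'
#' circRNA values (ratio or RPM) use levels 0-0.5, 0.5-1, 1-5, 5-10, >10;
#' parent genes (RPKM) use 0-50, 50-100, 100-500, 500-2000, >2000. Bins are
#' left-closed right-open, the last bin open-ended.
#'
#' @param values non-negative numeric vector (`Inf` allowed).
#' @param kind `"circ"` or `"gene"`.
#' @return named integer vector of bin counts (sums to `length(values)`).
#' @export
bin_expression <- function(values, kind = c("circ", "gene")) {
  kind <- match.arg(kind)
  if (any(values < 0, na.rm = TRUE)) stop_fmt("expression values must be >= 0")
  br <- if (kind == "circ") c(0, 0.5, 1, 5, 10, Inf) else c(0, 50, 100, 500, 2000, Inf)
  labs <- if (kind == "circ") c("0-0.5", "0.5-1", "1-5", "5-10", ">10")
          else c("0-50", "50-100", "100-500", "500-2000", ">2000")
  v <- values[!is.na(values)]
  cuts <- cut(pmin(v, br[5] + 1), breaks = br, labels = labs, right = FALSE,
              include.lowest = TRUE)
  out <- table(factor(cuts, levels = labs))
  stats::setNames(as.integer(out), labs)
}

#' Tissue-specificity index
#'
#' `sum(1 - exp_i / exp_max) / (n - 1)` over the `n` tissues: 0 for uniform
#' expression, 1 for expression confined to a single tissue. All-zero
#' vectors are undefined and return `NA`.
#'
#' @param exp non-negative per-tissue expression vector, length >= 2.
#' @return index in `[0, 1]`, or `NA` for an all-zero vector.
#' @export
tissue_specific_index <- function(exp) {
  n <- length(exp)
  if (n < 2) stop_fmt("need expression in at least two tissues")
  if (any(exp < 0)) stop_fmt("expression values must be >= 0")
  m <- max(exp)
  if (m == 0) return(NA_real_)
  sum(1 - exp / m) / (n - 1)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_fmt("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Coexpression of circRNAs with their parent genes
#'
#' Pearson correlation per (circ, gene) pair across samples, with BH FDR.
#' Pairs with zero variance in either vector are skipped.
#'
#' @param circ_expr matrix circ x sample (RPM).
#' @param gene_expr matrix gene x sample (RPKM).
#' @param pairs data.frame with `circ_id`, `gene_id`.
#' @param alpha FDR threshold for the `significant` flag.
#' @return data.frame with `circ_id`, `gene_id`, `r`, `p_value`, `fdr`,
#'   `significant`.
#' @export
coexpression <- function(circ_expr, gene_expr, pairs, alpha = 0.05) {
  if (ncol(circ_expr) < 3) stop_fmt("need >= 3 samples for correlation")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    cv <- circ_expr[pairs$circ_id[i], ]
    gv <- gene_expr[pairs$gene_id[i], ]
    if (stats::sd(cv) == 0 || stats::sd(gv) == 0) {
      message(sprintf("skipping zero-variance pair %s / %s",
                      pairs$circ_id[i], pairs$gene_id[i]))
      next
    }
    ct <- stats::cor.test(cv, gv, method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(circ_id = pairs$circ_id[i],
      gene_id = pairs$gene_id[i], r = unname(ct$estimate),
      p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(circ_id = character(0), gene_id = character(0),
                      r = numeric(0), p_value = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p_value)
  out$significant <- out$fdr < alpha
  out
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Differential expression of circRNAs between two conditions
#'
#' Per circRNA, junction counts are pooled within each condition and tested
#' against the pooled library remainder with a two-sided Fisher exact test;
#' p-values are BH-adjusted. Fold change is the ratio of mean counts scaled
#' to the geometric-mean library size, with a +0.5 pseudocount. Calls
#' require FDR < `alpha` and fold change > `fc_cutoff` (up) or <
#' 1/`fc_cutoff` (down).
#'
#' @param counts circ x sample junction count matrix.
#' @param condition factor/character of length `ncol(counts)` with exactly
#'   two levels (first level = reference condition A).
#' @param library_sizes per-sample totals; defaults to column sums (plus 1
#'   to stay positive on toy inputs).
#' @param alpha FDR threshold.
#' @param fc_cutoff fold-change threshold (> 1).
#' @return data.frame with `circ_id`, `fold_change`, `p_value`, `fdr`,
#'   `direction` (`"up"`, `"down"`, `"ns"`). Metadata attribute `method`
#'   records the test.
#' @export
differential_expression <- function(counts, condition,
                                    library_sizes = pmax(colSums(counts), 1),
                                    alpha = 0.05, fc_cutoff = 2) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop_fmt("condition must have exactly 2 levels")
  if (length(condition) != ncol(counts)) stop_fmt("condition length mismatch")
  a <- condition == levels(condition)[1]
  b <- !a
  lib_a <- sum(library_sizes[a]); lib_b <- sum(library_sizes[b])
  scale_fac <- geometric_mean(library_sizes) / library_sizes
  norm <- sweep(counts, 2, scale_fac, `*`)
  mean_a <- rowMeans(norm[, a, drop = FALSE])
  mean_b <- rowMeans(norm[, b, drop = FALSE])
  fc <- (mean_b + 0.5) / (mean_a + 0.5)
  ca <- rowSums(counts[, a, drop = FALSE])
  cb <- rowSums(counts[, b, drop = FALSE])
  pv <- vapply(seq_len(nrow(counts)), function(i) {
    tbl <- matrix(c(ca[i], max(lib_a - ca[i], 0),
                    cb[i], max(lib_b - cb[i], 0)), 2, 2)
    stats::fisher.test(round(tbl))$p.value
  }, numeric(1))
  fdr <- benjamini_hochberg(pv)
  direction <- rep("ns", nrow(counts))
  direction[fdr < alpha & fc > fc_cutoff] <- "up"
  direction[fdr < alpha & fc < 1 / fc_cutoff] <- "down"
  out <- data.frame(circ_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                    fold_change = fc, p_value = pv, fdr = fdr,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "method") <- "pooled two-sided Fisher exact test vs library remainder; BH FDR"
  out
}

#' Linear boundary-crossing read counts for circRNAs
#'
#' For each circRNA, counts linearly mapped reads whose alignment crosses
#' the circ start (respectively end) boundary with at least `min_flank`
#' bases on both sides, and returns the mean of the two boundary counts —
#' the denominator of the circular-to-linear ratio.
#'
#' @param circs circ data.frame (`circ_id`, `chrom`, `start`, `end`).
#' @param alignments linear alignment data.frame from [call_circrnas()]
#'   (`chrom`, `pos`, `len`).
#' @param min_flank minimum bases required on each side of the boundary.
#' @return numeric vector named by `circ_id`.
#' @export
circ_linear_counts <- function(circs, alignments, min_flank = 8L) {
  vapply(seq_len(nrow(circs)), function(i) {
    al <- alignments[alignments$chrom == circs$chrom[i], , drop = FALSE]
    cross <- function(b) sum(al$pos + min_flank <= b & b <= al$pos + al$len - min_flank)
    (cross(circs$start[i]) + cross(circs$end[i])) / 2
  }, numeric(1)) -> v
  stats::setNames(v, circs$circ_id)
}

#' Parent-gene RPKM from linear alignments
#'
#' Reads overlapping the exon union of each gene are counted and normalized
#' by exon kilobases and million mapped reads.
#'
#' @param genes named list of gene models.
#' @param alignments linear alignment data.frame (`chrom`, `pos`, `len`).
#' @param total_mapped total mapped reads in the sample.
#' @return numeric vector named by gene id.
#' @export
gene_rpkm <- function(genes, alignments, total_mapped) {
  vapply(genes, function(g) {
    ex <- do.call(rbind, lapply(g$transcripts, `[[`, "exons"))
    red <- IRanges::reduce(IRanges::IRanges(ex[, 1] + 1L, ex[, 2]))
    exu <- ivmat(IRanges::start(red) - 1L, IRanges::end(red))
    kb <- sum(exu[, 2] - exu[, 1]) / 1000
    al <- alignments[alignments$chrom == g$chrom, , drop = FALSE]
    cnt <- 0L
    for (r in seq_len(nrow(exu)))
      cnt <- cnt + sum(al$pos < exu[r, 2] & exu[r, 1] < al$pos + al$len)
    cnt / (kb * total_mapped / 1e6)
  }, numeric(1))
}
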