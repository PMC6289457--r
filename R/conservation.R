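## Cross-species circRNA conservation: ortholog pairs of parent genes by
## reciprocal best hit (Smith-Waterman, BLOSUM62, affine gaps 11/1), then a
## sequence-similarity gate on the circRNAs from orthologous parents.

#' Reciprocal-best-hit ortholog pairs between two proteomes
#'
#' Each protein of A is locally aligned (BLOSUM62, gap open 11, extend 1)
#' against every protein of B; a pair is reported when each is the other's
#' best-scoring hit with score at least `min_score`. Score ties are broken
#' by lexicographic id.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences.
#' @param min_score minimum raw Smith-Waterman score.
#' @return data.frame with `gene_a`, `gene_b`, `score`.
#' @export
reciprocal_best_hit <- function(proteome_a, proteome_b, min_score = 50) {
  na <- length(proteome_a); nb <- length(proteome_b)
  if (na == 0 || nb == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  ## score all pairs; order ids first so tie-breaking is lexicographic
  ord_a <- order(names(proteome_a)); ord_b <- order(names(proteome_b))
  pa <- proteome_a[ord_a]; pb <- proteome_b[ord_b]
  aset <- Biostrings::AAStringSet(pa)
  scores <- matrix(NA_real_, na, nb, dimnames = list(names(pa), names(pb)))
  for (j in seq_len(nb)) {
    scores[, j] <- Biostrings::pairwiseAlignment(aset,
      Biostrings::AAString(pb[[j]]), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
  }
  best_b_for_a <- apply(scores, 1, which.max)   # first max = lexicographic
  best_a_for_b <- apply(scores, 2, which.max)
  rows <- list()
  for (i in seq_len(na)) {
    j <- best_b_for_a[i]
    if (scores[i, j] < min_score) next
    if (best_a_for_b[j] == i)
      rows[[length(rows) + 1L]] <- data.frame(gene_a = names(pa)[i],
        gene_b = names(pb)[j], score = scores[i, j], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
    else data.frame(gene_a = character(0), gene_b = character(0),
                    score = numeric(0))
  rownames(out) <- NULL
  out[order(out$gene_a), , drop = FALSE]
}

#' Conserved circRNAs between two species
#'
#' Candidate pairs are circRNAs whose parent genes form an ortholog pair;
#' a pair is kept when a local nucleotide alignment of the circ sequences
#' reaches the identity and coverage thresholds (coverage relative to the
#' shorter circ).
#'
#' @param circs_a,circs_b data.frames with `circ_id` and `parent_gene`.
#' @param orthologs data.frame from [reciprocal_best_hit()].
#' @param seqs_a,seqs_b named character vectors of circ sequences.
#' @param min_identity minimum fractional identity over the aligned region.
#' @param min_coverage minimum aligned fraction of the shorter circ.
#' @return data.frame with `circ_id_a`, `circ_id_b`, `gene_a`, `gene_b`,
#'   `identity`, `coverage`.
#' @export
conserved_circrnas <- function(circs_a, circs_b, orthologs, seqs_a, seqs_b,
                               min_identity = 0.5, min_coverage = 0.5) {
  rows <- list()
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
  for (k in seq_len(nrow(orthologs))) {
    ca <- circs_a[!is.na(circs_a$parent_gene) &
                    circs_a$parent_gene == orthologs$gene_a[k], , drop = FALSE]
    cb <- circs_b[!is.na(circs_b$parent_gene) &
                    circs_b$parent_gene == orthologs$gene_b[k], , drop = FALSE]
    for (i in seq_len(nrow(ca))) for (j in seq_len(nrow(cb))) {
      sa <- seqs_a[[ca$circ_id[i]]]; sb <- seqs_b[[cb$circ_id[j]]]
      if (is.null(sa) || is.null(sb)) next
      aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(sa),
        Biostrings::DNAString(sb), type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      ident <- Biostrings::pid(aln, type = "PID1") / 100
      cov <- Biostrings::nchar(aln) / min(nchar(sa), nchar(sb))
      if (ident >= min_identity && cov >= min_coverage)
        rows[[length(rows) + 1L]] <- data.frame(circ_id_a = ca$circ_id[i],
          circ_id_b = cb$circ_id[j], gene_a = orthologs$gene_a[k],
          gene_b = orthologs$gene_b[k], identity = ident, coverage = cov,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(circ_id_a = character(0), circ_id_b = character(0),
                  gene_a = character(0), gene_b = character(0),
                  identity = numeric(0), coverage = numeric(0))
}
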