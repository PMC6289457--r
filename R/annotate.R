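## Positional classification of circRNAs against gene models: class
## (within_gene / overlap_gene / intergenic), back-splice site labels
## (CDS / 5'UTR / 3'UTR / intron / intergenic), exonic status, boundary
## annotation status, alternative-circularization grouping, and lincRNA
## overlap. "Gene interval" means the span of the gene feature, so a circRNA
## can be exonic without being within_gene (e.g. a 3'UTR-intergenic circ).

gene_span_table <- function(genes) {
  data.frame(gene_id = vapply(genes, `[[`, character(1), "gene_id"),
             chrom = vapply(genes, `[[`, character(1), "chrom"),
             start = vapply(genes, `[[`, integer(1), "start"),
             end = vapply(genes, `[[`, integer(1), "end"),
             strand = vapply(genes, `[[`, character(1), "strand"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Positional class of a circRNA against gene spans
#'
#' `within_gene` when the circ interval is contained in some gene span,
#' `intergenic` when it overlaps no gene, `overlap_gene` otherwise. The
#' three classes are exhaustive and mutually exclusive.
#'
#' @param chrom,start,end circ interval (0-based half-open).
#' @param genes named list of gene models.
#' @return one of `"within_gene"`, `"overlap_gene"`, `"intergenic"`.
#' @export
classify_position <- function(chrom, start, end, genes) {
  spans <- gene_span_table(genes)
  ov <- spans$chrom == chrom & spans$start < end & start < spans$end
  if (!any(ov)) return("intergenic")
  if (any(ov & spans$start <= start & end <= spans$end)) return("within_gene")
  "overlap_gene"
}

## Feature label of a genomic point (0-based base index) under precedence
## CDS > 5'UTR/3'UTR > intron > intergenic, across all transcripts of all
## overlapping genes.
point_label <- function(chrom, p, genes) {
  best <- "intergenic"
  rank <- c(CDS = 1, `5'UTR` = 2, `3'UTR` = 2, intron = 3, intergenic = 4)
  for (g in genes) {
    if (g$chrom != chrom || p < g$start || p >= g$end) next
    lab <- "intron"
    for (tx in g$transcripts) {
      inm <- function(m) nrow(m) > 0 && any(m[, 1] <= p & p < m[, 2])
      if (inm(tx$cds)) { lab <- "CDS"; break }
      if (inm(tx$utr5)) lab <- "5'UTR"
      else if (inm(tx$utr3) && lab == "intron") lab <- "3'UTR"
    }
    if (rank[lab] < rank[best]) best <- lab
  }
  best
}

#' Label the two back-splice boundaries of a circRNA
#'
#' Each boundary is labeled by the feature containing it (CDS > UTR >
#' intron > intergenic precedence). The pair is ordered (5' boundary on the
#' circ's strand first); `canonical` gives the unordered category name used
#' for aggregate reporting.
#'
#' @param chrom,start,end,strand circ coordinates.
#' @param genes named list of gene models.
#' @return list with `site_label` (length-2 character) and `canonical`.
#' @export
label_backsplice_sites <- function(chrom, start, end, strand, genes) {
  lab_start <- point_label(chrom, start, genes)
  lab_end <- point_label(chrom, end - 1L, genes)
  pair <- if (strand == "-") c(lab_end, lab_start) else c(lab_start, lab_end)
  list(site_label = pair,
       canonical = paste(sort(pair), collapse = "-"))
}

#' Boundary annotation status of a circRNA
#'
#' A boundary is "known" when it coincides exactly with an annotated exon
#' start or end of any transcript.
#'
#' @param chrom,start,end circ coordinates.
#' @param genes named list of gene models.
#' @return `"both_known"`, `"one_known"` or `"none_known"`.
#' @export
boundary_status <- function(chrom, start, end, genes) {
  edges <- unlist(lapply(genes, function(g) {
    if (g$chrom != chrom) return(integer(0))
    unlist(lapply(g$transcripts, function(tx) as.vector(tx$exons)))
  }), use.names = FALSE)
  known <- (start %in% edges) + (end %in% edges)
  c("none_known", "one_known", "both_known")[known + 1L]
}

#' Annotate a set of circRNAs against gene models
#'
#' @param circs data.frame with `circ_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param genes named list of gene models.
#' @param lincrnas optional data.frame (`lincrna_id`, `chrom`, `start`,
#'   `end`) of lincRNA intervals.
#' @return data.frame with one row per circ: `positional_class`,
#'   `site_5p`, `site_3p`, `site_label` (canonical), `is_exonic`,
#'   `parent_genes` (comma-joined), `primary_parent`, `boundary_status`,
#'   `alt_group_size`, `lincrna_overlap`, `multi_gene_conflict` (flags a
#'   circ overlapping genes on both strands).
#' @export
annotate_circs <- function(circs, genes, lincrnas = NULL) {
  n <- nrow(circs)
  spans <- gene_span_table(genes)
  out <- data.frame(circ_id = circs$circ_id, positional_class = character(n),
                    site_5p = character(n), site_3p = character(n),
                    site_label = character(n), is_exonic = logical(n),
                    parent_genes = NA_character_,
                    primary_parent = NA_character_,
                    boundary_status = character(n), alt_group_size = 1L,
                    lincrna_overlap = NA_character_,
                    multi_gene_conflict = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    chrom <- circs$chrom[i]; s <- circs$start[i]; e <- circs$end[i]
    out$positional_class[i] <- classify_position(chrom, s, e, genes)
    lab <- label_backsplice_sites(chrom, s, e, circs$strand[i], genes)
    out$site_5p[i] <- lab$site_label[1]; out$site_3p[i] <- lab$site_label[2]
    out$site_label[i] <- lab$canonical
    out$boundary_status[i] <- boundary_status(chrom, s, e, genes)
    ov <- which(spans$chrom == chrom & spans$start < e & s < spans$end)
    if (length(ov)) {
      ovlen <- pmin(e, spans$end[ov]) - pmax(s, spans$start[ov])
      ord <- ov[order(-ovlen, spans$gene_id[ov])]
      out$parent_genes[i] <- paste(spans$gene_id[ord], collapse = ",")
      out$primary_parent[i] <- spans$gene_id[ord[1]]
      out$multi_gene_conflict[i] <- length(unique(spans$strand[ov])) > 1L
    }
    exonic <- FALSE
    for (g in genes) {
      if (g$chrom != chrom) next
      for (tx in g$transcripts)
        if (any(tx$exons[, 1] < e & s < tx$exons[, 2])) { exonic <- TRUE; break }
      if (exonic) break
    }
    out$is_exonic[i] <- exonic
    if (!is.null(lincrnas) && out$positional_class[i] == "intergenic") {
      lov <- lincrnas$chrom == chrom & lincrnas$start < e & s < lincrnas$end
      if (any(lov))
        out$lincrna_overlap[i] <- paste(lincrnas$lincrna_id[lov], collapse = ",")
    }
  }
  tab <- table(out$primary_parent[!is.na(out$primary_parent)])
  has_parent <- !is.na(out$primary_parent)
  out$alt_group_size[has_parent] <- as.integer(tab[out$primary_parent[has_parent]])
  out
}

#' Alternative-circularization groups
#'
#' @param annotations output of [annotate_circs()].
#' @return list with `groups` (named list: parent gene -> circ ids, only
#'   genes parenting >= 2 circs) and `histogram` (table of genes by isoform
#'   count).
#' @export
group_alternative_circularization <- function(annotations) {
  ok <- !is.na(annotations$primary_parent)
  sp <- split(annotations$circ_id[ok], annotations$primary_parent[ok])
  groups <- sp[vapply(sp, length, integer(1)) >= 2L]
  histo <- table(vapply(sp, length, integer(1)))
  list(groups = groups, histogram = histo)
}

#' Overlaps between intergenic circRNAs and lincRNAs
#'
#' @param circs circ data.frame (`circ_id`, `chrom`, `start`, `end`).
#' @param annotations output of [annotate_circs()] for the same circs.
#' @param lincrnas data.frame of lincRNA intervals.
#' @return data.frame of (`circ_id`, `lincrna_id`) pairs with >= 1 bp
#'   overlap, restricted to intergenic circRNAs.
#' @export
lincrna_overlap <- function(circs, annotations, lincrnas) {
  out <- list()
  inter <- annotations$circ_id[annotations$positional_class == "intergenic"]
  for (i in which(circs$circ_id %in% inter)) {
    hit <- lincrnas$chrom == circs$chrom[i] &
      lincrnas$start < circs$end[i] & circs$start[i] < lincrnas$end
    for (lid in lincrnas$lincrna_id[hit])
      out[[length(out) + 1L]] <- data.frame(circ_id = circs$circ_id[i],
                                            lincrna_id = lid,
                                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(circ_id = character(0), lincrna_id = character(0))
}
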