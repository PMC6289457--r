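## I/O for the standard formats the pipeline touches. One coordinate
## convention internally: 0-based half-open [start, end). GFF3 files are
## 1-based inclusive, BED files 0-based half-open; conversion happens here
## and nowhere else.

#' Read a reference genome from FASTA
#'
#' @param path path to a FASTA file.
#' @return named character vector, one uppercase sequence per chromosome,
#'   with class `"genome"`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_fmt("genome FASTA not found: %s", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop_fmt("malformed FASTA '%s': %s",
                                                path, conditionMessage(e)))
  if (length(seqs) == 0) {
    warn_fmt("empty FASTA: %s", path)
    return(structure(character(0), class = "genome"))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop_fmt("duplicate chromosome ids in %s", path)
  g <- toupper(as.character(seqs))
  names(g) <- ids
  structure(g, class = "genome")
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_genome <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome)) {
    writeLines(paste0(">", id), con)
    s <- genome[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Extract a genomic subsequence
#'
#' 0-based half-open coordinates; out-of-range ends are clipped.
#'
#' @param genome a `"genome"` object.
#' @param chrom chromosome id.
#' @param start,end interval (0-based half-open).
#' @return character subsequence.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  s <- genome[[chrom]]
  if (is.null(s)) stop_fmt("unknown chromosome: %s", chrom)
  substr(s, max(0L, start) + 1L, min(nchar(s), end))
}

genome_lengths <- function(genome) vapply(unclass(genome), nchar, integer(1))

## ---- gene models ----------------------------------------------------------

## A gene model is a list: gene_id, chrom, strand, start, end (0-based
## half-open span) and transcripts: named list of transcripts, each a list
## with transcript_id and interval matrices (columns start, end; 0-based
## half-open; sorted by start): exons, cds, utr5, utr3.

ivmat <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  m[order(m[, 1]), , drop = FALSE]
}

new_gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1)
  allex <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = min(allex[, 1]), end = max(allex[, 2]),
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d transcript(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              length(x$transcripts)))
  invisible(x)
}

## Interval difference a \ b for interval matrices (0-based half-open).
interval_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(a)
  ia <- IRanges::IRanges(a[, 1] + 1L, a[, 2])
  ib <- if (nrow(b) == 0) IRanges::IRanges() else IRanges::IRanges(b[, 1] + 1L, b[, 2])
  d <- IRanges::setdiff(ia, ib)
  ivmat(IRanges::start(d) - 1L, IRanges::end(d))
}

## Infer UTR intervals from exon and CDS extents when the annotation lacks
## explicit UTR features. Non-CDS exon sequence upstream of the CDS (in
## transcript orientation) is 5' UTR, downstream is 3' UTR.
infer_utrs <- function(exons, cds, strand) {
  non_cds <- interval_setdiff(exons, cds)
  if (nrow(cds) == 0 || nrow(non_cds) == 0)
    return(list(utr5 = ivmat(integer(0), integer(0)),
                utr3 = ivmat(integer(0), integer(0))))
  cds_lo <- min(cds[, 1]); cds_hi <- max(cds[, 2])
  left  <- non_cds[non_cds[, 2] <= cds_lo, , drop = FALSE]
  right <- non_cds[non_cds[, 1] >= cds_hi, , drop = FALSE]
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' Read gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS (and, when present, five_prime_UTR /
#' three_prime_UTR) features linked by `Parent` attributes. GFF3 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention. Missing UTR features are inferred from exon minus CDS extent.
#'
#' @param path path to a GFF3 file.
#' @return named list of `gene_model` objects, keyed by gene id.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_fmt("annotation not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df$ID <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  df$Parent <- if ("Parent" %in% names(df))
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  else NA_character_
  ## internal coordinates: GFF3 [start, end] 1-based -> [start-1, end)
  df$start0 <- df$start - 1L
  df$end0 <- df$end

  genes_df <- df[df$type == "gene", , drop = FALSE]
  mrna_df <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  known_ids <- c(genes_df$ID, mrna_df$ID)
  orphans <- mrna_df$Parent[!(mrna_df$Parent %in% genes_df$ID)]
  child_df <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), , drop = FALSE]
  orphans <- c(orphans, unique(child_df$Parent[!(child_df$Parent %in% mrna_df$ID)]))
  if (length(orphans))
    stop_fmt("unresolvable Parent attribute(s) in %s: %s", path,
             paste(unique(orphans), collapse = ", "))

  models <- list()
  for (gi in seq_len(nrow(genes_df))) {
    g <- genes_df[gi, ]
    tx_rows <- mrna_df[mrna_df$Parent == g$ID, , drop = FALSE]
    txs <- list()
    for (ti in seq_len(nrow(tx_rows))) {
      tid <- tx_rows$ID[ti]
      ch <- child_df[child_df$Parent == tid, , drop = FALSE]
      exons <- ch[ch$type == "exon", , drop = FALSE]
      if (nrow(exons) == 0) stop_fmt("mRNA %s has no exon features", tid)
      exs <- ivmat(exons$start0, exons$end0)
      cds <- ch[ch$type == "CDS", , drop = FALSE]
      cdsm <- ivmat(cds$start0, cds$end0)
      u5 <- ch[ch$type == "five_prime_UTR", , drop = FALSE]
      u3 <- ch[ch$type == "three_prime_UTR", , drop = FALSE]
      if (nrow(u5) || nrow(u3)) {
        utr5 <- ivmat(u5$start0, u5$end0); utr3 <- ivmat(u3$start0, u3$end0)
      } else {
        u <- infer_utrs(exs, cdsm, as.character(g$strand))
        utr5 <- u$utr5; utr3 <- u$utr3
      }
      txs[[tid]] <- list(transcript_id = tid, exons = exs, cds = cdsm,
                         utr5 = utr5, utr3 = utr3)
    }
    if (length(txs) == 0) next
    models[[g$ID]] <- new_gene_model(g$ID, as.character(g$seqnames),
                                     as.character(g$strand), txs)
  }
  models
}

#' Write gene models to GFF3
#'
#' Internal 0-based half-open intervals are emitted as 1-based inclusive
#' GFF3. Output is deterministic (fixed feature order).
#'
#' @param genes named list of `gene_model` objects.
#' @param path output path.
#' @export
write_annotation <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, s0, e0, strand, attrs)
    sprintf("%s\tcircseed\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s0 + 1L, e0, strand, attrs)
  for (g in genes) {
    writeLines(fmt(g$chrom, "gene", g$start, g$end, g$strand,
                   paste0("ID=", g$gene_id)), con)
    for (tx in g$transcripts) {
      writeLines(fmt(g$chrom, "mRNA", min(tx$exons[, 1]), max(tx$exons[, 2]),
                     g$strand, paste0("ID=", tx$transcript_id, ";Parent=", g$gene_id)), con)
      emit <- function(m, type) {
        for (i in seq_len(nrow(m)))
          writeLines(fmt(g$chrom, type, m[i, 1], m[i, 2], g$strand,
                         paste0("Parent=", tx$transcript_id)), con)
      }
      emit(tx$exons, "exon"); emit(tx$cds, "CDS")
      emit(tx$utr5, "five_prime_UTR"); emit(tx$utr3, "three_prime_UTR")
    }
  }
  invisible(path)
}

#' Spliced transcript sequence in transcript orientation
#'
#' @param genome a `"genome"` object.
#' @param gene a gene model.
#' @param tx one transcript of `gene`.
#' @return character sequence (reverse-complemented for minus-strand genes).
#' @export
transcript_sequence <- function(genome, gene, tx) {
  parts <- vapply(seq_len(nrow(tx$exons)), function(i)
    genome_subseq(genome, gene$chrom, tx$exons[i, 1], tx$exons[i, 2]), character(1))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

## ---- reads (FASTQ) --------------------------------------------------------

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  con <- file(path, "w")
  on.exit(close(con))
  if (n > 0) {
    qual <- strrep("I", nchar(reads$sequence))
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to an (uncompressed) FASTQ file.
#' @return data.frame with columns `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTQ not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(seqs)),
             sequence = toupper(as.character(seqs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---- circRNA candidates (BED6) -------------------------------------------

#' Write circRNA candidates to BED6
#'
#' 0-based half-open, score column carries the junction read count.
#'
#' @param circs data.frame with columns `circ_id`, `chrom`, `start`, `end`,
#'   `strand`, `junction_reads`.
#' @param path output path.
#' @export
write_circ_bed <- function(circs, path) {
  if (nrow(circs) > 0 && any(circs$start >= circs$end))
    stop_fmt("invalid circ interval: start >= end")
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(circs) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", circs$chrom,
                       as.integer(circs$start), as.integer(circs$end),
                       circs$circ_id, as.integer(circs$junction_reads),
                       circs$strand), con)
  invisible(path)
}

#' Read circRNA candidates from BED6
#'
#' @param path path to a BED6 file written by [write_circ_bed()].
#' @return data.frame with columns `circ_id`, `chrom`, `start`, `end`,
#'   `strand`, `junction_reads`.
#' @export
read_circ_bed <- function(path) {
  if (!file.exists(path)) stop_fmt("BED not found: %s", path)
  cols <- c("chrom", "start", "end", "circ_id", "junction_reads", "strand")
  if (file.size(path) == 0)
    return(stats::setNames(data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), circ_id = character(0),
                                      junction_reads = integer(0),
                                      strand = character(0)), cols)[,
             c("circ_id", "chrom", "start", "end", "strand", "junction_reads")])
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE)
  df[, c("circ_id", "chrom", "start", "end", "strand", "junction_reads")]
}

#' Write a protein or nucleotide set to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(path)
}

#' Read a FASTA file as a plain named character vector
#'
#' @param path path to a FASTA file.
#' @param type `"DNA"`, `"RNA"` or `"AA"`.
#' @return named character vector, uppercase.
#' @export
read_fasta <- function(path, type = c("DNA", "RNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_fmt("FASTA not found: %s", path)
  rd <- switch(type, DNA = Biostrings::readDNAStringSet,
               RNA = Biostrings::readRNAStringSet,
               AA = Biostrings::readAAStringSet)
  seqs <- rd(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
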