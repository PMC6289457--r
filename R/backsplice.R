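## Back-splice junction detection by split-anchor alignment. Reads that fail
## contiguous (linear) placement have their terminal anchors aligned to the
## genome independently; anchor pairs landing on one chromosome and strand in
## reversed genomic order relative to their order in the read mark a
## candidate back-splice. Anchors are extended inward to the breakpoint,
## which must be flanked by the canonical GU/AG signal (genomic GT..AG on
## plus, AC..CT on minus), span at most `max_dist`, and accumulate at least
## `min_reads` distinct supporting reads to be reported.

DEFAULT_ANCHOR <- 20L
DEFAULT_MIN_READS <- 2L
DEFAULT_MAX_DIST <- 100000L

#' Build an exact k-mer lookup index over a genome
#'
#' A thin exact-match index: it resolves any k-mer (and its reverse
#' complement) to all genomic occurrences. Serves as the toy-scale aligner
#' behind anchor mapping.
#'
#' @param genome a `"genome"` object from [read_genome()] or
#'   [generate_reference()].
#' @param k anchor length (nt).
#' @return object of class `"anchor_index"`.
#' @export
build_index <- function(genome, k = DEFAULT_ANCHOR) {
  lens <- genome_lengths(genome)
  if (length(lens) == 0) stop_fmt("empty genome")
  if (k > min(lens))
    stop_fmt("k = %d exceeds the shortest chromosome (%d nt)", k, min(lens))
  structure(list(genome = genome, k = as.integer(k)), class = "anchor_index")
}

#' Look up all genomic occurrences of a k-mer
#'
#' @param index an [build_index()] object.
#' @param kmer a k-length nucleotide string.
#' @return data.frame with `chrom`, `pos` (0-based start of the occurrence)
#'   and `strand` (`"-"` rows are occurrences of the reverse complement).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "anchor_index"))
  if (nchar(kmer) != index$k)
    stop_fmt("query length %d != index k (%d)", nchar(kmer), index$k)
  out <- list()
  for (chrom in names(index$genome)) {
    subj <- Biostrings::DNAString(index$genome[[chrom]])
    for (st in c("+", "-")) {
      q <- if (st == "+") kmer else revcomp(kmer)
      hits <- Biostrings::matchPattern(Biostrings::DNAString(q), subj)
      if (length(hits))
        out[[length(out) + 1L]] <- data.frame(chrom = chrom,
          pos = Biostrings::start(hits) - 1L, strand = st,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(0), pos = integer(0), strand = character(0))
}

## Batch exact plus-strand matching of constant-width patterns. Returns, per
## pattern, the total hit count and (chrom, pos) of the hit when unique.
batch_exact_hits <- function(patterns, genome) {
  n <- length(patterns)
  nhit <- integer(n)
  hchrom <- rep(NA_character_, n)
  hpos <- rep(NA_integer_, n)
  ok <- !is.na(patterns) & !grepl("[^ACGT]", patterns)
  widths <- nchar(patterns)
  for (w in unique(widths[ok])) {
    sel <- which(ok & widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns[sel]))
    for (chrom in names(genome)) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome[[chrom]]))
      si <- Biostrings::startIndex(m)
      cnt <- S4Vectors::elementNROWS(si)
      has <- which(cnt > 0)
      nhit[sel[has]] <- nhit[sel[has]] + cnt[has]
      first <- vapply(si[has], `[`, integer(1), 1L)
      hchrom[sel[has]] <- chrom
      hpos[sel[has]] <- first - 1L
    }
  }
  list(nhit = nhit, chrom = hchrom, pos = hpos)
}

#' Map reads linearly to the genome
#'
#' A read is linearly mapped when it matches contiguously (up to
#' `max_mismatch` substitutions, no indels) at a unique genomic locus on
#' either strand. Exact matches are found wholesale; inexact placements are
#' rescued by seeding with the terminal anchors. Unmapped reads proceed to
#' back-splice detection.
#'
#' @param reads data.frame with `read_id`, `sequence`.
#' @param genome a `"genome"` object.
#' @param max_mismatch substitution tolerance for contiguous placement.
#' @param anchor_length seed length for the inexact rescue (nt).
#' @return data.frame with `read_id`, `mapped`, `chrom`, `pos` (0-based
#'   leftmost), `strand`, `n_hits`.
#' @export
linear_map <- function(reads, genome, max_mismatch = 2L,
                       anchor_length = DEFAULT_ANCHOR) {
  n <- nrow(reads)
  seqs <- reads$sequence
  if (n == 0)
    return(data.frame(read_id = character(0), mapped = logical(0),
                      chrom = character(0), pos = integer(0),
                      strand = character(0), len = integer(0),
                      n_hits = integer(0), stringsAsFactors = FALSE))
  res <- data.frame(read_id = reads$read_id, mapped = FALSE,
                    chrom = NA_character_, pos = NA_integer_,
                    strand = NA_character_, len = nchar(reads$sequence),
                    n_hits = 0L, stringsAsFactors = FALSE)
  fw <- batch_exact_hits(seqs, genome)
  rc <- batch_exact_hits(revcomp(seqs), genome)
  tot <- fw$nhit + rc$nhit
  res$n_hits <- tot
  uniq <- tot == 1L
  res$mapped[uniq] <- TRUE
  take_f <- uniq & fw$nhit == 1L
  res$chrom[take_f] <- fw$chrom[take_f]; res$pos[take_f] <- fw$pos[take_f]
  res$strand[take_f] <- "+"
  take_r <- uniq & rc$nhit == 1L
  res$chrom[take_r] <- rc$chrom[take_r]; res$pos[take_r] <- rc$pos[take_r]
  res$strand[take_r] <- "-"

  ## inexact rescue for reads with no exact placement
  if (max_mismatch > 0) {
    todo <- which(tot == 0L & nchar(seqs) >= 2L * anchor_length &
                    !grepl("[^ACGT]", seqs))
    if (length(todo)) {
      L <- nchar(seqs[todo])
      rcs <- revcomp(seqs[todo])
      cand <- c(substr(seqs[todo], 1L, anchor_length),
                substr(seqs[todo], L - anchor_length + 1L, L),
                substr(rcs, 1L, anchor_length),
                substr(rcs, L - anchor_length + 1L, L))
      ua <- unique(cand)
      ah <- batch_exact_hits(ua, genome)
      ki <- matrix(match(cand, ua), ncol = 4L)
      for (jj in seq_along(todo)) {
        i <- todo[jj]
        L1 <- nchar(seqs[i])
        hits <- list()
        for (ori in c("+", "-")) {
          s <- if (ori == "+") seqs[i] else rcs[jj]
          for (side in c("head", "tail")) {
            k <- ki[jj, (if (ori == "+") 0L else 2L) + (if (side == "head") 1L else 2L)]
            if (is.na(k) || ah$nhit[k] != 1L) next
            off <- if (side == "head") 0L else L1 - anchor_length
            p0 <- ah$pos[k] - off
            chrom <- ah$chrom[k]
            if (p0 < 0 || p0 + L1 > nchar(genome[[chrom]])) next
            gseq <- genome_subseq(genome, chrom, p0, p0 + L1)
            if (hamming(s, gseq) <= max_mismatch)
              hits[[paste(chrom, p0, ori)]] <- list(chrom = chrom, pos = p0,
                                                    strand = ori)
          }
        }
        if (length(hits) == 1L) {
          h <- hits[[1]]
          res$mapped[i] <- TRUE
          res$chrom[i] <- h$chrom; res$pos[i] <- h$pos; res$strand[i] <- h$strand
          res$n_hits[i] <- 1L
        } else res$n_hits[i] <- length(hits)
      }
    }
  }
  res
}

## Which back-splice strands are supported by the flanking dinucleotides at
## [start, end)? Returns subset of c("+", "-").
signal_strands <- function(genome, chrom, start, end) {
  glen <- nchar(genome[[chrom]])
  if (start < 2L || end + 2L > glen) return(character(0))
  up <- genome_subseq(genome, chrom, start - 2L, start)
  down <- genome_subseq(genome, chrom, end, end + 2L)
  out <- character(0)
  if (up == "AG" && down == "GT") out <- c(out, "+")
  if (up == "AC" && down == "CT") out <- c(out, "-")
  out
}

## Pick the reported strand when both strands carry the signal: prefer the
## strand of an overlapping annotated gene, else plus.
resolve_strand <- function(strands, genes, chrom, start, end) {
  if (length(strands) == 1L) return(strands)
  if (length(strands) == 0L) return(NA_character_)
  if (!is.null(genes)) {
    gs <- unique(vapply(genes, function(g) {
      if (g$chrom == chrom && g$start < end && start < g$end) g$strand else NA_character_
    }, character(1)))
    gs <- gs[!is.na(gs)]
    if (length(gs) == 1L && gs %in% strands) return(gs)
  }
  "+"
}

## Core breakpoint search for a read already oriented to the plus strand of
## the genome, given unique anchor positions pH (head) and pT (tail) on one
## chromosome with pH > pT. Returns NULL or a list(chrom, start, end, strand,
## signal).
extend_breakpoint <- function(seq, chrom, pH, pT, genome, genes,
                              anchor_length, max_dist) {
  L <- nchar(seq)
  cs <- genome[[chrom]]
  glen <- nchar(cs)
  span <- (pH - pT) + (L - anchor_length)
  if (span > max_dist) return(NULL)
  smax <- min(L - anchor_length, glen - pH)
  if (smax < anchor_length) return(NULL)
  ## longest prefix of the read matching the genome from pH
  rp <- charToRaw(substr(seq, 1L, smax))
  gp <- charToRaw(substr(cs, pH + 1L, pH + smax))
  mm <- which(rp != gp)
  prefix_max <- if (length(mm)) mm[1] - 1L else smax
  ## longest suffix matching the genome ending at pT + anchor_length
  tmax <- min(L - anchor_length, pT + anchor_length)
  rs <- charToRaw(substr(seq, L - tmax + 1L, L))
  gs <- charToRaw(substr(cs, pT + anchor_length - tmax + 1L, pT + anchor_length))
  mm2 <- which(rs != gs)
  suffix_max <- if (length(mm2)) tmax - mm2[length(mm2)] else tmax
  lo <- max(anchor_length, L - suffix_max)
  hi <- min(L - anchor_length, prefix_max)
  if (lo > hi) return(NULL)
  ## leftmost breakpoint carrying the splice signal wins
  for (s in lo:hi) {
    S <- pT + anchor_length - L + s
    E <- pH + s
    if (S < 0 || E > glen || S >= E) next
    strands <- signal_strands(genome, chrom, S, E)
    if (length(strands) == 0L) next
    st <- resolve_strand(strands, genes, chrom, S, E)
    sig <- if (st == "+") "AG..GT" else "AC..CT"
    return(list(chrom = chrom, start = S, end = E, strand = st, signal = sig))
  }
  NULL
}

#' Detect a back-splice breakpoint in a single read
#'
#' The read's two terminal anchors are aligned exactly to the genome. When
#' both anchors land uniquely on the same chromosome in reversed genomic
#' order, they are extended inward to a breakpoint flanked by the canonical
#' splice signal within the distance cutoff.
#'
#' @param sequence the read sequence (character).
#' @param genome a `"genome"` object.
#' @param genes optional gene models for strand disambiguation.
#' @param anchor_length anchor length (nt).
#' @param max_dist maximum genomic span of the junction (nt).
#' @return `NULL`, or a list with `chrom`, `start`, `end`, `strand`,
#'   `signal`.
#' @export
detect_junction <- function(sequence, genome, genes = NULL,
                            anchor_length = DEFAULT_ANCHOR,
                            max_dist = DEFAULT_MAX_DIST) {
  L <- nchar(sequence)
  if (L < 2L * anchor_length) return(NULL)
  if (grepl("[^ACGT]", sequence)) return(NULL)
  for (seq in c(sequence, revcomp(sequence))) {
    headA <- substr(seq, 1L, anchor_length)
    tailA <- substr(seq, L - anchor_length + 1L, L)
    h <- batch_exact_hits(c(headA, tailA), genome)
    if (h$nhit[1] != 1L || h$nhit[2] != 1L) next
    if (h$chrom[1] != h$chrom[2]) next
    if (h$pos[1] <= h$pos[2]) next
    cand <- extend_breakpoint(seq, h$chrom[1], h$pos[1], h$pos[2], genome,
                              genes, anchor_length, max_dist)
    if (!is.null(cand)) return(cand)
  }
  NULL
}

#' Call circRNAs from one or more read sets
#'
#' Runs linear mapping, routes unmapped reads through breakpoint detection,
#' merges candidates with identical (chrom, start, end, strand), and applies
#' the read-support and distance filters. Output is sorted by coordinate and
#' is invariant to read input order.
#'
#' @param samples named list of read data.frames (columns `read_id`,
#'   `sequence`), one per sample; a single data.frame is accepted.
#' @param genome a `"genome"` object.
#' @param genes optional gene models (strand disambiguation).
#' @param min_reads minimum distinct junction reads supporting a reported
#'   circRNA (summed over samples).
#' @param max_dist maximum genomic span (nt).
#' @param anchor_length anchor length (nt).
#' @param max_mismatch substitution tolerance for linear placement.
#' @return list with `circs` (data.frame: `circ_id`, `chrom`, `start`,
#'   `end`, `strand`, `signal`, `junction_reads`, `supporting_reads`),
#'   `counts` (circ x sample junction-read matrix), `linear` (per-sample
#'   linear alignment data.frames) and `total_mapped` (per-sample mapped
#'   read totals, linear + junction).
#' @export
call_circrnas <- function(samples, genome, genes = NULL,
                          min_reads = DEFAULT_MIN_READS,
                          max_dist = DEFAULT_MAX_DIST,
                          anchor_length = DEFAULT_ANCHOR, max_mismatch = 2L) {
  if (is.data.frame(samples)) samples <- list(s1 = samples)
  if (is.null(names(samples)))
    names(samples) <- sprintf("s%d", seq_along(samples))
  hits <- list()
  linear <- list()
  total_mapped <- stats::setNames(numeric(length(samples)), names(samples))
  for (sn in names(samples)) {
    reads <- samples[[sn]]
    if (nrow(reads) == 0) { warn_fmt("sample %s has no reads", sn) }
    lm <- linear_map(reads, genome, max_mismatch = max_mismatch,
                     anchor_length = anchor_length)
    linear[[sn]] <- lm[lm$mapped, , drop = FALSE]
    unm <- which(!lm$mapped & lm$n_hits == 0L)
    njx <- 0L
    if (length(unm)) {
      seqs <- reads$sequence[unm]
      L <- nchar(seqs)
      long_enough <- L >= 2L * anchor_length
      ## batch anchor lookup for both orientations
      rcs <- revcomp(seqs)
      anc <- c(substr(seqs, 1L, anchor_length),
               substr(seqs, L - anchor_length + 1L, L),
               substr(rcs, 1L, anchor_length),
               substr(rcs, L - anchor_length + 1L, L))
      ua <- unique(anc[rep(long_enough, 4L)])
      ah <- batch_exact_hits(ua, genome)
      ki <- matrix(match(anc, ua), ncol = 4L)  # head_f, tail_f, head_r, tail_r
      uni <- function(col) { k <- ki[, col]
        !is.na(k) & ah$nhit[k] == 1L }
      screen <- function(h, t) { # both anchors unique, same chrom, reversed
        ok <- long_enough & uni(h) & uni(t)
        kh <- ki[, h]; kt <- ki[, t]
        ok[ok] <- ah$chrom[kh[ok]] == ah$chrom[kt[ok]] &
          ah$pos[kh[ok]] > ah$pos[kt[ok]]
        ok
      }
      ok_f <- screen(1L, 2L); ok_r <- screen(3L, 4L)
      for (jj in which(ok_f | ok_r)) {
        for (ori in 1:2) {
          if (ori == 1L && !ok_f[jj]) next
          if (ori == 2L && !ok_r[jj]) next
          s <- if (ori == 1L) seqs[jj] else rcs[jj]
          kh <- ki[jj, if (ori == 1L) 1L else 3L]
          kt <- ki[jj, if (ori == 1L) 2L else 4L]
          cand <- extend_breakpoint(s, ah$chrom[kh], ah$pos[kh], ah$pos[kt],
                                    genome, genes, anchor_length, max_dist)
          if (!is.null(cand)) {
            hits[[length(hits) + 1L]] <- data.frame(sample = sn,
              read_id = reads$read_id[unm[jj]], chrom = cand$chrom,
              start = cand$start, end = cand$end, strand = cand$strand,
              signal = cand$signal, stringsAsFactors = FALSE)
            njx <- njx + 1L
            break  # a read supports at most one junction
          }
        }
      }
    }
    total_mapped[sn] <- nrow(linear[[sn]]) + njx
  }
  empty <- data.frame(circ_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), signal = character(0),
                      junction_reads = integer(0),
                      supporting_reads = character(0))
  if (length(hits) == 0)
    return(list(circs = empty,
                counts = matrix(0L, 0, length(samples),
                                dimnames = list(NULL, names(samples))),
                linear = linear, total_mapped = total_mapped))
  h <- do.call(rbind, hits)
  h <- h[!duplicated(h[, c("sample", "read_id")]), , drop = FALSE]
  key <- paste(h$chrom, h$start, h$end, h$strand, sep = "|")
  agg <- h[!duplicated(key), c("chrom", "start", "end", "strand", "signal")]
  agg$key <- key[!duplicated(key)]
  agg$junction_reads <- as.integer(table(key)[agg$key])
  agg$supporting_reads <- vapply(agg$key, function(k)
    paste(sort(h$read_id[key == k]), collapse = ","), character(1))
  counts <- matrix(0L, nrow(agg), length(samples),
                   dimnames = list(agg$key, names(samples)))
  tab <- table(key, factor(h$sample, levels = names(samples)))
  counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  keep <- agg$junction_reads >= min_reads & (agg$end - agg$start) <= max_dist
  agg <- agg[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  ord <- order(agg$chrom, agg$start, agg$end, agg$strand)
  agg <- agg[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  agg$circ_id <- sprintf("circ_%05d", seq_len(nrow(agg)))
  rownames(counts) <- agg$circ_id
  rownames(agg) <- NULL
  list(circs = agg[, c("circ_id", "chrom", "start", "end", "strand", "signal",
                       "junction_reads", "supporting_reads")],
       counts = counts, linear = linear, total_mapped = total_mapped)
}
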