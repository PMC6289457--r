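## Synthetic-data generators with planted ground truth. Every generator is a
## pure function of (config, seed): rerunning with the same arguments gives
## byte-identical output. The geometry mirrors a compact plant genome: multi-
## exon genes with UTR/CDS structure separated by intergenic space, canonical
## splice signals stamped at every intron boundary so that back-splice
## junctions planted at exon edges carry the genomic GT..AG (minus strand:
## AC..CT) signal the detector requires.

#' Simulation configuration
#'
#' @param seed integer seed driving all randomness.
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome (nt).
#' @param n_genes total number of genes (split across chromosomes).
#' @param exons_per_gene integer range `c(min, max)`.
#' @param exon_length integer range (nt).
#' @param intron_length integer range (nt).
#' @param utr5_length,utr3_length UTR lengths carved from terminal exons (nt).
#' @param intergenic_gap integer range for gaps between genes (nt).
#' @param n_lincrnas lincRNA intervals placed in intergenic space.
#' @param read_length simulated read length (nt).
#' @param error_rate per-base substitution rate in `[0, 1)`.
#' @param anchor_length detector anchor length (nt).
#' @param n_tissues number of tissues for expression profiles.
#' @param n_samples_per_condition replicates per condition in DE designs.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 500000L,
                       n_genes = 100L, exons_per_gene = c(4L, 8L),
                       exon_length = c(120L, 300L), intron_length = c(80L, 400L),
                       utr5_length = 60L, utr3_length = 80L,
                       intergenic_gap = c(500L, 3000L), n_lincrnas = 10L,
                       read_length = 100L, error_rate = 0,
                       anchor_length = 20L, n_tissues = 5L,
                       n_samples_per_condition = 3L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              utr5_length = as.integer(utr5_length),
              utr3_length = as.integer(utr3_length),
              intergenic_gap = as.integer(intergenic_gap),
              n_lincrnas = as.integer(n_lincrnas),
              read_length = as.integer(read_length),
              error_rate = as.numeric(error_rate),
              anchor_length = as.integer(anchor_length),
              n_tissues = as.integer(n_tissues),
              n_samples_per_condition = as.integer(n_samples_per_condition))
  counts <- c(cfg$n_chrom, cfg$chrom_length, cfg$n_genes, cfg$exons_per_gene,
              cfg$exon_length, cfg$intron_length, cfg$read_length,
              cfg$anchor_length, cfg$n_tissues, cfg$n_samples_per_condition)
  if (any(counts <= 0)) stop_fmt("all sim_config counts must be positive")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop_fmt("error_rate must lie in [0, 1)")
  if (cfg$read_length < 2L * cfg$anchor_length)
    stop_fmt("read_length must be at least 2 x anchor_length")
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

## Overwrite genome[chrom][pos, pos+nchar(sub)) with `sub` (0-based).
stamp <- function(seqs, chrom, pos, sub) {
  substr(seqs[[chrom]], pos + 1L, pos + nchar(sub)) <- sub
  seqs
}

#' Generate a reference genome with annotated gene models
#'
#' Genes are laid out non-overlapping along each chromosome with intergenic
#' gaps; every intron is given canonical splice-site dinucleotides on the
#' gene's strand (GT..AG on plus; AC..CT in plus-strand coordinates for
#' minus-strand genes). Terminal exons carry 5'/3' UTRs; internal exon
#' sequence is CDS. lincRNA intervals are placed in intergenic space.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (named character, class `"genome"`),
#'   `genes` (named list of gene models), `lincrnas` (data.frame with
#'   `lincrna_id`, `chrom`, `start`, `end`), and `intergenic` (data.frame of
#'   gaps usable for intergenic planting).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    chrom_ids <- sprintf("chr%d", seq_len(config$n_chrom))
    seqs <- stats::setNames(vapply(chrom_ids, function(i)
      rand_dna(config$chrom_length), character(1)), chrom_ids)

    per_chrom <- apportion(config$n_genes, rep(1, config$n_chrom))
    max_span <- max(config$exons_per_gene) * max(config$exon_length) +
      (max(config$exons_per_gene) - 1L) * max(config$intron_length)
    need <- max(per_chrom) * (max_span + max(config$intergenic_gap)) +
      max(config$intergenic_gap)
    if (need > config$chrom_length)
      stop_fmt("chrom_length %d too small: need at least %d for %d genes",
               config$chrom_length, need, max(per_chrom))

    genes <- list()
    gaps <- list()
    gnum <- 0L
    for (ci in seq_len(config$n_chrom)) {
      chrom <- chrom_ids[ci]
      pos <- sample(seq(config$intergenic_gap[1], config$intergenic_gap[2]), 1)
      for (gi in seq_len(per_chrom[ci])) {
        gnum <- gnum + 1L
        gene_id <- sprintf("G%04d", gnum)
        strand <- sample(c("+", "-"), 1)
        n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
        ex_len <- sample(seq(config$exon_length[1], config$exon_length[2]),
                         n_ex, replace = TRUE)
        in_len <- if (n_ex > 1)
          sample(seq(config$intron_length[1], config$intron_length[2]),
                 n_ex - 1L, replace = TRUE) else integer(0)
        ex_start <- pos + c(0L, cumsum(ex_len[-n_ex] + in_len))
        ex_end <- ex_start + ex_len
        gene_end <- ex_end[n_ex]
        ## splice signals at every intron boundary, on the gene's strand
        for (ii in seq_len(n_ex - 1L)) {
          a <- ex_end[ii]; b <- ex_start[ii + 1L]
          if (strand == "+") {
            seqs <- stamp(seqs, chrom, a, "GT")
            seqs <- stamp(seqs, chrom, b - 2L, "AG")
          } else {
            seqs <- stamp(seqs, chrom, a, "CT")
            seqs <- stamp(seqs, chrom, b - 2L, "AC")
          }
        }
        exons <- ivmat(ex_start, ex_end)
        ## UTRs at transcript ends: carve from the terminal exons
        first_ex <- exons[1, ]; last_ex <- exons[n_ex, ]
        if (strand == "+") {
          u5 <- ivmat(first_ex[1], min(first_ex[1] + config$utr5_length, first_ex[2]))
          u3 <- ivmat(max(last_ex[2] - config$utr3_length, last_ex[1]), last_ex[2])
        } else {
          u5 <- ivmat(max(last_ex[2] - config$utr5_length, last_ex[1]), last_ex[2])
          u3 <- ivmat(first_ex[1], min(first_ex[1] + config$utr3_length, first_ex[2]))
        }
        cds <- interval_setdiff(exons, rbind(u5, u3))
        tid <- paste0(gene_id, ".1")
        genes[[gene_id]] <- new_gene_model(gene_id, chrom, strand,
          stats::setNames(list(list(transcript_id = tid, exons = exons,
                                    cds = cds, utr5 = u5, utr3 = u3)), tid))
        nxt <- gene_end + sample(seq(config$intergenic_gap[1],
                                     config$intergenic_gap[2]), 1)
        gaps[[length(gaps) + 1L]] <- data.frame(chrom = chrom, start = gene_end,
                                                end = min(nxt, config$chrom_length))
        pos <- nxt
      }
      gaps[[length(gaps) + 1L]] <- data.frame(chrom = chrom, start = pos,
                                              end = config$chrom_length)
    }
    intergenic <- do.call(rbind, gaps)
    intergenic <- intergenic[intergenic$end - intergenic$start >=
                               config$intergenic_gap[1], , drop = FALSE]
    rownames(intergenic) <- NULL

    ## lincRNAs inside intergenic gaps
    linc <- data.frame(lincrna_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0))
    big <- intergenic[intergenic$end - intergenic$start >= 600L, , drop = FALSE]
    n_linc <- min(config$n_lincrnas, nrow(big))
    if (n_linc > 0) {
      pick <- sample(nrow(big), n_linc)
      ls <- big$start[pick] + 50L
      le <- pmin(ls + 400L, big$end[pick] - 50L)
      linc <- data.frame(lincrna_id = sprintf("LINC%03d", seq_len(n_linc)),
                         chrom = big$chrom[pick], start = ls, end = le)
    }
    list(genome = structure(seqs, class = "genome"), genes = genes,
         lincrnas = linc, intergenic = intergenic)
  })
}

## All 0-based positions p in [lo, hi) where genome[chrom][p, p+2) == dinuc.
find_dinuc <- function(genome, chrom, lo, hi, dinuc) {
  if (hi - lo < 2) return(integer(0))
  s <- genome_subseq(genome, chrom, lo, hi)
  m <- gregexpr(dinuc, s, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  ## overlapping occurrences matter little for 2-mers here; gregexpr's
  ## non-overlapping scan is enough for AG/GT/AC/CT
  as.integer(m) - 1L + lo
}

## Splice-signal dinucleotides flanking a back-splice on each strand:
## plus:  genome[start-2,start)=="AG", genome[end,end+2)=="GT"
## minus: genome[start-2,start)=="AC", genome[end,end+2)=="CT"
signal_dinucs <- function(strand) {
  if (strand == "+") c(acceptor = "AG", donor = "GT")
  else c(acceptor = "AC", donor = "CT")
}

has_backsplice_signal <- function(genome, chrom, start, end, strand) {
  sd <- signal_dinucs(strand)
  genome_subseq(genome, chrom, start - 2L, start) == sd[["acceptor"]] &&
    genome_subseq(genome, chrom, end, end + 2L) == sd[["donor"]]
}

#' Plant circRNAs of all positional classes into a reference
#'
#' Within-gene circRNAs are anchored at internal exon boundaries (where the
#' stamped intron signals provide the genomic GT..AG); gene-overlapping and
#' intergenic circRNAs are anchored at positions where the required signal
#' dinucleotides occur in the sequence. Optionally plants extra-long
#' junctions (span above the detector's distance cutoff) as negative
#' controls, and guarantees a number of genes carrying at least two distinct
#' circRNA isoforms (alternative circularization).
#'
#' @param reference output of [generate_reference()].
#' @param n total number of circRNAs to plant.
#' @param class_mix proportions for classes within / overlap / intergenic
#'   (largest-remainder apportionment).
#' @param alt_circ_genes number of genes that must parent >= 2 isoforms.
#' @param n_long extra circRNAs planted with span > `long_span_min`.
#' @param long_span_min minimum span for the long negative controls (nt).
#' @param seed integer seed.
#' @return data.frame of planted circRNAs: `circ_id`, `chrom`, `start`,
#'   `end`, `strand`, `class`, `parent_gene`, `span`, `is_long`.
#' @export
plant_circrnas <- function(reference, n = 60L,
                           class_mix = c(within = 0.5, overlap = 0.2, intergenic = 0.3),
                           alt_circ_genes = 5L, n_long = 0L,
                           long_span_min = 100001L, seed = 1L) {
  genes <- reference$genes
  genome <- reference$genome
  counts <- apportion(n, class_mix)
  names(counts) <- c("within", "overlap", "intergenic")
  with_seed(seed + 7919L, {
    out <- list()
    add <- function(chrom, start, end, strand, class, parent) {
      out[[length(out) + 1L]] <<- data.frame(chrom = chrom,
        start = as.integer(start), end = as.integer(end), strand = strand,
        class = class, parent_gene = parent, stringsAsFactors = FALSE)
    }
    ## -- within-gene circs at internal exon boundaries ---------------------
    elig <- Filter(function(g) nrow(g$transcripts[[1]]$exons) >= 3, genes)
    if (length(elig) < max(counts[["within"]] - alt_circ_genes, alt_circ_genes))
      stop_fmt("not enough multi-exon genes to host within-gene circRNAs")
    exon_pair <- function(g, avoid = NULL) {
      ex <- g$transcripts[[1]]$exons
      m <- nrow(ex)
      combos <- expand.grid(i = 2:(m - 1), j = 2:(m - 1))
      combos <- combos[combos$i <= combos$j, , drop = FALSE]
      combos <- combos[sample(nrow(combos)), , drop = FALSE]
      for (r in seq_len(nrow(combos))) {
        s <- ex[combos$i[r], 1]; e <- ex[combos$j[r], 2]
        key <- paste(s, e)
        if (!is.null(avoid) && key %in% avoid) next
        if (has_backsplice_signal(genome, g$chrom, s, e, g$strand))
          return(c(s, e))
      }
      NULL
    }
    n_within <- counts[["within"]]
    if (alt_circ_genes * 2L > n_within)
      stop_fmt("alt_circ_genes too large for the within-gene quota")
    host_ids <- sample(names(elig), min(length(elig), n_within - alt_circ_genes))
    alt_ids <- host_ids[seq_len(alt_circ_genes)]
    planted_keys <- list()
    planted_within <- 0L
    for (gid in host_ids) {
      if (planted_within >= n_within) break
      p <- exon_pair(genes[[gid]])
      if (is.null(p)) next
      add(genes[[gid]]$chrom, p[1], p[2], genes[[gid]]$strand, "within", gid)
      planted_keys[[gid]] <- paste(p[1], p[2])
      planted_within <- planted_within + 1L
    }
    for (gid in alt_ids) {
      if (planted_within >= n_within) break
      p <- exon_pair(genes[[gid]], avoid = planted_keys[[gid]])
      if (is.null(p)) stop_fmt("cannot place a second isoform in gene %s", gid)
      add(genes[[gid]]$chrom, p[1], p[2], genes[[gid]]$strand, "within", gid)
      planted_keys[[gid]] <- c(planted_keys[[gid]], paste(p[1], p[2]))
      planted_within <- planted_within + 1L
    }
    if (planted_within < n_within)
      stop_fmt("could only place %d of %d within-gene circRNAs",
               planted_within, n_within)

    ## -- gene-overlapping circs: start at internal exon boundary, end in the
    ##    downstream intergenic gap -----------------------------------------
    gaps <- reference$intergenic
    placed <- 0L
    cand_genes <- sample(names(elig))
    for (gid in cand_genes) {
      if (placed >= counts[["overlap"]]) break
      g <- genes[[gid]]
      ex <- g$transcripts[[1]]$exons
      s <- ex[sample(2:(nrow(ex) - 1L), 1), 1]
      sd <- signal_dinucs(g$strand)
      if (genome_subseq(genome, g$chrom, s - 2L, s) != sd[["acceptor"]]) next
      gp <- gaps[gaps$chrom == g$chrom & gaps$start >= g$end, , drop = FALSE]
      gp <- gp[order(gp$start), , drop = FALSE]
      if (nrow(gp) == 0) next
      hits <- find_dinuc(genome, g$chrom, gp$start[1] + 20L,
                         gp$end[1] - 2L, sd[["donor"]])
      if (length(hits) == 0) next
      add(g$chrom, s, hits[1], g$strand, "overlap", gid)
      placed <- placed + 1L
    }
    if (placed < counts[["overlap"]])
      stop_fmt("could only place %d of %d gene-overlapping circRNAs",
               placed, counts[["overlap"]])

    ## -- intergenic circs inside a single gap ------------------------------
    big <- gaps[gaps$end - gaps$start >= 500L, , drop = FALSE]
    placed <- 0L
    for (k in sample(nrow(big))) {
      if (placed >= counts[["intergenic"]]) break
      gp <- big[k, ]
      acc <- find_dinuc(genome, gp$chrom, gp$start + 10L,
                        min(gp$start + 200L, gp$end), "AG")
      if (length(acc) == 0) next
      s <- acc[1] + 2L
      don <- find_dinuc(genome, gp$chrom, s + 250L, gp$end - 2L, "GT")
      if (length(don) == 0) next
      add(gp$chrom, s, don[1], "+", "intergenic", NA_character_)
      placed <- placed + 1L
    }
    if (placed < counts[["intergenic"]])
      stop_fmt("could only place %d of %d intergenic circRNAs",
               placed, counts[["intergenic"]])

    ## -- long-span negative controls (exceed the distance filter) ---------
    if (n_long > 0) {
      placed <- 0L
      for (chrom in names(genome)) {
        if (placed >= n_long) break
        glen <- nchar(genome[[chrom]])
        if (glen < long_span_min + 4000L) next
        gpc <- gaps[gaps$chrom == chrom, , drop = FALSE]
        left <- gpc[gpc$start < glen - long_span_min - 2000L, , drop = FALSE]
        for (k in seq_len(nrow(left))) {
          if (placed >= n_long) break
          acc <- find_dinuc(genome, chrom, left$start[k] + 10L,
                            left$end[k] - 2L, "AG")
          if (length(acc) == 0) next
          s <- acc[1] + 2L
          right <- gpc[gpc$start >= s + long_span_min, , drop = FALSE]
          if (nrow(right) == 0) next
          don <- find_dinuc(genome, chrom, right$start[1] + 10L,
                            right$end[1] - 2L, "GT")
          if (length(don) == 0) next
          add(chrom, s, don[1], "+", "long_span", NA_character_)
          placed <- placed + 1L
        }
      }
      if (placed < n_long)
        stop_fmt("could not place %d long-span circRNAs", n_long)
    }

    circs <- do.call(rbind, out)
    circs <- circs[order(circs$chrom, circs$start, circs$end), , drop = FALSE]
    circs$circ_id <- sprintf("planted_circ_%03d", seq_len(nrow(circs)))
    circs$span <- circs$end - circs$start
    circs$is_long <- circs$class == "long_span"
    rownames(circs) <- NULL
    circs[, c("circ_id", "chrom", "start", "end", "strand", "class",
              "parent_gene", "span", "is_long")]
  })
}

#' circRNA sequence in transcript orientation
#'
#' The genomic span of the circ; reverse-complemented for minus-strand
#' circRNAs.
#'
#' @param genome a `"genome"` object.
#' @param chrom,start,end,strand circ coordinates.
#' @return character sequence.
#' @export
circ_sequence <- function(genome, chrom, start, end, strand) {
  s <- genome_subseq(genome, chrom, start, end)
  if (strand == "-") revcomp(s) else s
}

apply_substitution_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < error_rate)
    if (length(hit) == 0) return(s)
    v <- chars(s)
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate single-end reads for one sample
#'
#' Junction reads concatenate a suffix of the circRNA 3' end with a prefix of
#' its 5' start, with the breakpoint placed uniformly at internal offsets at
#' least one anchor length from both read ends. Linear reads are drawn
#' uniformly from spliced transcripts in random orientation (unstranded
#' library). Substitution errors are applied at `error_rate`.
#'
#' @param reference output of [generate_reference()].
#' @param circs planted circRNAs ([plant_circrnas()] output or compatible).
#' @param junction_reads integer vector (recycled) or named by `circ_id`:
#'   junction reads per circRNA.
#' @param linear_depth mean fold-coverage of each transcript by linear reads.
#' @param read_length read length (nt).
#' @param error_rate per-base substitution probability.
#' @param anchor_length detector anchor length (nt); breakpoint offsets are
#'   kept at least this far from the read ends.
#' @param seed integer seed.
#' @param sample_id string used in read ids.
#' @return data.frame with `read_id`, `sequence`, and truth columns `origin`
#'   (`"junction"`/`"linear"`) and `source` (circ or transcript id).
#' @export
simulate_reads <- function(reference, circs, junction_reads = 20L,
                           linear_depth = 50, read_length = 100L,
                           error_rate = 0, anchor_length = 20L, seed = 1L,
                           sample_id = "s1") {
  if (read_length < 2L * anchor_length)
    stop_fmt("read_length must be at least 2 x anchor_length")
  genome <- reference$genome
  L <- as.integer(read_length)
  a_min <- as.integer(anchor_length)
  jr <- junction_reads
  if (is.null(names(jr))) jr <- stats::setNames(rep_len(as.integer(jr), nrow(circs)),
                                                circs$circ_id)
  with_seed(seed + 104729L, {
    recs <- list()
    for (i in seq_len(nrow(circs))) {
      cid <- circs$circ_id[i]
      nr <- jr[[cid]] %||% 0L
      if (is.na(nr) || nr <= 0) next
      S <- circs$start[i]; E <- circs$end[i]
      chrom <- circs$chrom[i]; strand <- circs$strand[i]
      offs <- sample(seq(a_min, L - a_min), nr, replace = TRUE)
      seqs <- vapply(offs, function(a) {
        if (strand == "+") {
          paste0(genome_subseq(genome, chrom, E - a, E),
                 genome_subseq(genome, chrom, S, S + (L - a)))
        } else {
          paste0(revcomp(genome_subseq(genome, chrom, S, S + a)),
                 revcomp(genome_subseq(genome, chrom, E - (L - a), E)))
        }
      }, character(1))
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = sprintf("%s_jx_%s_%03d", sample_id, cid, seq_len(nr)),
        sequence = seqs, origin = "junction", source = cid,
        stringsAsFactors = FALSE)
    }
    if (linear_depth > 0) {
      for (g in reference$genes) {
        tx <- g$transcripts[[1]]
        tseq <- transcript_sequence(genome, g, tx)
        tlen <- nchar(tseq)
        if (tlen < L) next
        nr <- max(1L, as.integer(round(linear_depth * tlen / L)))
        starts <- sample(seq_len(tlen - L + 1L), nr, replace = TRUE)
        seqs <- substring(tseq, starts, starts + L - 1L)
        flip <- stats::runif(nr) < 0.5
        seqs[flip] <- revcomp(seqs[flip])
        recs[[length(recs) + 1L]] <- data.frame(
          read_id = sprintf("%s_lin_%s_%04d", sample_id, tx$transcript_id,
                            seq_len(nr)),
          sequence = seqs, origin = "linear", source = tx$transcript_id,
          stringsAsFactors = FALSE)
      }
    }
    reads <- if (length(recs)) do.call(rbind, recs)
      else data.frame(read_id = character(0), sequence = character(0),
                      origin = character(0), source = character(0))
    reads$sequence <- apply_substitution_errors(reads$sequence, error_rate)
    rownames(reads) <- NULL
    reads
  })
}

## ---- decoy-site planting --------------------------------------------------

RNA_PAIRS <- list(A = "U", U = "A", G = "C", C = "G")

pairs_with <- function(mi, tb) {
  (mi == "A" && tb == "U") || (mi == "U" && tb == "A") ||
  (mi == "G" && tb == "C") || (mi == "C" && tb == "G") ||
  (mi == "G" && tb == "U") || (mi == "U" && tb == "G")
}

## A base that neither Watson-Crick- nor wobble-pairs with `tb`.
non_pairing_base <- function(tb) {
  for (b in c("A", "C", "G", "U")) if (!pairs_with(b, tb)) return(b)
}

#' Design a decoy-site plan
#'
#' @param seed_mm mismatches planted in miRNA positions 2-8.
#' @param central_mm mismatches planted in positions 9-20.
#' @param central_ins target-side bulge bases inserted between positions
#'   12 and 13 (counted as central insertions).
#' @param other_mm mismatches planted at position 1 and/or 21+.
#' @return list of class `"decoy_design"`.
#' @export
decoy_design <- function(seed_mm = 0L, central_mm = 0L, central_ins = 0L,
                         other_mm = 0L) {
  d <- list(seed_mm = as.integer(seed_mm), central_mm = as.integer(central_mm),
            central_ins = as.integer(central_ins), other_mm = as.integer(other_mm))
  if (d$seed_mm < 0 || d$seed_mm > 7) stop_fmt("seed_mm must be in 0..7")
  if (d$central_mm < 0 || d$central_mm > 12) stop_fmt("central_mm must be in 0..12")
  if (d$central_ins < 0 || d$central_ins > 6) stop_fmt("central_ins must be in 0..6")
  if (d$other_mm < 0 || d$other_mm > 2) stop_fmt("other_mm must be in 0..2")
  structure(d, class = "decoy_design")
}

## Expected verdict for a design under the decoy rules (central bulge
## required: 1-6 central defects, perfect seed, <= 4 defects elsewhere).
design_verdict <- function(d) {
  central <- d$central_mm + d$central_ins
  if (d$seed_mm > 0) list(pass = FALSE, failing_rule = 2L)
  else if (central < 1 || central > 6) list(pass = FALSE, failing_rule = 1L)
  else if (d$other_mm > 4) list(pass = FALSE, failing_rule = 3L)
  else list(pass = TRUE, failing_rule = NA_integer_)
}

#' Plant miRNA decoy sites into circRNA sequences
#'
#' For each design, a target window is chosen in a circRNA sequence and a
#' 21-nt miRNA is derived as the (reverse) complement of that window, then
#' defects are introduced into the miRNA so that the planted site's
#' per-region mismatch/insertion counts equal the design exactly. The
#' expected rule verdict is recorded.
#'
#' @param circ_seqs named character vector of circRNA sequences (DNA or RNA).
#' @param designs list of [decoy_design()] objects, one miRNA planted each.
#' @param mirna_length miRNA length (nt).
#' @param seed integer seed.
#' @return list with `mirnas` (named character, RNA alphabet) and `truth`
#'   (data.frame: `mirna_id`, `circ_id`, `site_start` (0-based offset in the
#'   circ sequence), design counts, `expected_pass`, `expected_failing_rule`).
#' @export
plant_decoy_sites <- function(circ_seqs, designs, mirna_length = 21L, seed = 1L) {
  stopifnot(length(circ_seqs) >= 1, length(designs) >= 1)
  L <- as.integer(mirna_length)
  with_seed(seed + 15485863L, {
    mirnas <- character(0)
    truth <- list()
    for (di in seq_along(designs)) {
      d <- designs[[di]]
      stopifnot(inherits(d, "decoy_design"))
      cid <- names(circ_seqs)[((di - 1L) %% length(circ_seqs)) + 1L]
      cs <- chartr("T", "U", toupper(circ_seqs[[cid]]))
      wlen <- L + d$central_ins
      if (nchar(cs) < wlen + 2L) stop_fmt("circ %s too short for a decoy site", cid)
      off <- sample(seq_len(nchar(cs) - wlen - 1L), 1)
      window <- substr(cs, off + 1L, off + wlen)
      ## target read 3'->5' against miRNA 5'->3': reverse the window
      tgt <- rev(chars(window))
      ## assign target positions to miRNA positions; bulge between 12 and 13
      mir <- character(L)
      ti <- 1L
      for (p in seq_len(L)) {
        mir[p] <- RNA_PAIRS[[tgt[ti]]]
        ti <- ti + 1L
        if (p == 12L && d$central_ins > 0) ti <- ti + d$central_ins
      }
      mm_at <- function(pos) {
        for (p in pos) mir[p] <<- non_pairing_base(partner[p])
      }
      ## partner base of each miRNA position (for mismatch derivation)
      partner <- character(L)
      ti <- 1L
      for (p in seq_len(L)) {
        partner[p] <- tgt[ti]; ti <- ti + 1L
        if (p == 12L && d$central_ins > 0) ti <- ti + d$central_ins
      }
      if (d$seed_mm > 0) mm_at(seq(2L, 8L)[seq_len(d$seed_mm)])
      if (d$central_mm > 0) mm_at(c(9L, 10L, 11L, 14L, 15L, 16L, 17L, 18L,
                                    19L, 20L, 12L, 13L)[seq_len(d$central_mm)])
      if (d$other_mm > 0) mm_at(c(1L, 21L)[seq_len(d$other_mm)])
      mid <- sprintf("mir%03d", di)
      mirnas[[mid]] <- paste(mir, collapse = "")
      v <- design_verdict(d)
      mm <- d$seed_mm + d$central_mm + d$other_mm
      exp_score <- (L - mm) - mm - 2L * d$central_ins
      truth[[di]] <- data.frame(mirna_id = mid, circ_id = cid,
        site_start = off, seed_mm = d$seed_mm, central_mm = d$central_mm,
        central_ins = d$central_ins, other_mm = d$other_mm,
        expected_pass = v$pass, expected_failing_rule = v$failing_rule,
        expected_score = exp_score,
        discoverable = exp_score >= DECOY_SCORING$min_score,
        stringsAsFactors = FALSE)
    }
    list(mirnas = mirnas, truth = do.call(rbind, truth))
  })
}

## ---- expression profiles --------------------------------------------------

#' Plant per-tissue and differential expression profiles
#'
#' Baseline junction counts are drawn from a negative binomial with the given
#' mean and dispersion. Tissue-specific circRNAs receive counts only in their
#' assigned tissue; differentially expressed circRNAs receive mean counts
#' scaled by the stated fold change in the second condition.
#'
#' @param circ_ids character vector of circRNA ids.
#' @param n_tissues number of tissues (one count column per tissue).
#' @param n_specific number of circRNAs planted tissue-specific.
#' @param de_pairs list of DE designs: each `list(pair = c("A","B"),
#'   fold_change = 4, n_affected = 10)`.
#' @param n_reps replicates per condition in DE count tables.
#' @param baseline_mean negative-binomial mean for expressed circRNAs.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param seed integer seed.
#' @return list with `tissue_counts` (matrix circ x tissue),
#'   `tissue_truth` (data.frame `circ_id`, `tissue`), `de` (named list per
#'   condition pair: `counts` matrix circ x samples, `condition` factor,
#'   `truth` data.frame `circ_id`, `fold_change`).
#' @export
plant_expression_profiles <- function(circ_ids, n_tissues = 5L,
                                      n_specific = 10L, de_pairs = list(),
                                      n_reps = 3L, baseline_mean = 50,
                                      dispersion = 0.1, seed = 1L) {
  n <- length(circ_ids)
  if (n_specific > n) stop_fmt("n_specific (%d) exceeds planted circRNAs (%d)",
                               n_specific, n)
  with_seed(seed + 32452843L, {
    rnb <- function(k, mu) stats::rnbinom(k, mu = mu, size = 1 / dispersion)
    tissues <- sprintf("tissue%d", seq_len(n_tissues))
    tc <- matrix(0L, n, n_tissues, dimnames = list(circ_ids, tissues))
    spec_idx <- sample(n, n_specific)
    spec_tissue <- sample(n_tissues, n_specific, replace = TRUE)
    for (i in seq_len(n)) {
      if (i %in% spec_idx) {
        t <- spec_tissue[match(i, spec_idx)]
        tc[i, t] <- max(10L, rnb(1, baseline_mean))
      } else {
        tc[i, ] <- pmax(10L, rnb(n_tissues, baseline_mean))
      }
    }
    tissue_truth <- data.frame(circ_id = circ_ids[spec_idx],
                               tissue = tissues[spec_tissue],
                               stringsAsFactors = FALSE)

    de <- list()
    for (dp in de_pairs) {
      fc <- dp$fold_change
      aff <- sample(n, dp$n_affected)
      mu_a <- rep(baseline_mean, n)
      mu_b <- mu_a
      mu_b[aff] <- mu_a[aff] * fc
      counts <- cbind(
        matrix(rnb(n * n_reps, mu_a), n, n_reps),
        matrix(rnb(n * n_reps, mu_b), n, n_reps))
      dimnames(counts) <- list(circ_ids,
        c(sprintf("%s_%d", dp$pair[1], seq_len(n_reps)),
          sprintf("%s_%d", dp$pair[2], seq_len(n_reps))))
      de[[paste(dp$pair, collapse = ":")]] <- list(
        counts = counts,
        condition = factor(rep(dp$pair, each = n_reps), levels = dp$pair),
        truth = data.frame(circ_id = circ_ids[aff], fold_change = fc,
                           stringsAsFactors = FALSE))
    }
    list(tissue_counts = tc, tissue_truth = tissue_truth, de = de)
  })
}

## ---- proteome pairs -------------------------------------------------------

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mutate_protein <- function(s, rate) {
  v <- chars(s)
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit))
    v[hit] <- vapply(v[hit], function(a) sample(setdiff(AA20, a), 1), character(1))
  paste(v, collapse = "")
}

#' Generate a pair of proteomes with known orthologs
#'
#' Proteome B contains one diverged copy of each A protein (the true
#' ortholog), plus paralog-like near-duplicates and unpaired extras to
#' exercise reciprocal-best-hit filtering.
#'
#' @param n_orthologs number of true ortholog pairs.
#' @param divergence per-residue substitution rate applied to orthologs
#'   (must be < 1).
#' @param protein_length range `c(min, max)` of protein lengths (aa).
#' @param n_paralogs paralog-like decoys added to proteome B (mutated at
#'   about three times the ortholog divergence).
#' @param n_unpaired species-specific proteins added to each proteome.
#' @param seed integer seed.
#' @return list with `proteome_a`, `proteome_b` (named character vectors) and
#'   `ortholog_truth` (data.frame `gene_a`, `gene_b`).
#' @export
generate_proteome_pair <- function(n_orthologs = 25L, divergence = 0.1,
                                   protein_length = c(120L, 200L),
                                   n_paralogs = 5L, n_unpaired = 5L, seed = 1L) {
  if (divergence >= 1) stop_fmt("divergence must be < 1")
  with_seed(seed + 49979687L, {
    lens <- sample(seq(protein_length[1], protein_length[2]), n_orthologs,
                   replace = TRUE)
    pa <- stats::setNames(vapply(lens, function(l)
      paste(sample(AA20, l, replace = TRUE), collapse = ""), character(1)),
      sprintf("geneA_%03d", seq_len(n_orthologs)))
    pb <- stats::setNames(vapply(pa, mutate_protein, character(1),
                                 rate = divergence),
                          sprintf("geneB_%03d", seq_len(n_orthologs)))
    truth <- data.frame(gene_a = names(pa), gene_b = names(pb),
                        stringsAsFactors = FALSE)
    if (n_paralogs > 0) {
      src <- sample(n_orthologs, min(n_paralogs, n_orthologs))
      para <- stats::setNames(vapply(pa[src], mutate_protein, character(1),
                                     rate = min(0.95, divergence * 3 + 0.15)),
                              sprintf("geneB_par_%03d", seq_along(src)))
      pb <- c(pb, para)
    }
    if (n_unpaired > 0) {
      mk <- function(prefix) stats::setNames(vapply(seq_len(n_unpaired), function(i)
        paste(sample(AA20, sample(seq(protein_length[1], protein_length[2]), 1),
                     replace = TRUE), collapse = ""), character(1)),
        sprintf("gene%s_x_%03d", prefix, seq_len(n_unpaired)))
      pa <- c(pa, mk("A")); pb <- c(pb, mk("B"))
    }
    list(proteome_a = pa, proteome_b = pb, ortholog_truth = truth)
  })
}
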