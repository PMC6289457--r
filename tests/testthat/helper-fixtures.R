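## Shared fixtures, memoized so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

## Small reference: 1 chromosome, 20 genes.
tiny_reference <- function() memo("tiny_ref", {
  generate_reference(sim_config(seed = 101, n_chrom = 1, chrom_length = 200000,
                                n_genes = 20))
})

## Study-scale detection fixture: 2 x 500 kb, 100 genes, 60 planted circs
## (class mix 0.5/0.2/0.3, 5 alternative-circularization genes) at 20
## error-free junction reads each over 50x linear background, plus negative
## controls: two circs supported by exactly 1 read and two spanning > 100 kb.
detection_fixture <- function() memo("det_fix", {
  cfg <- sim_config(seed = 202, n_chrom = 2, chrom_length = 500000,
                    n_genes = 100)
  ref <- generate_reference(cfg)
  circs <- plant_circrnas(ref, n = 62, alt_circ_genes = 5, n_long = 2,
                          seed = 202)
  regular <- circs$circ_id[!circs$is_long]
  main <- regular[seq_len(60)]
  low <- regular[61:62]
  jr <- stats::setNames(rep(20L, nrow(circs)), circs$circ_id)
  jr[low] <- 1L
  reads <- simulate_reads(ref, circs, junction_reads = jr, linear_depth = 50,
                          seed = 202)
  t0 <- Sys.time()
  det <- call_circrnas(reads[, c("read_id", "sequence")], ref$genome,
                       ref$genes)
  det_secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(ref = ref, circs = circs, det_secs = det_secs,
       main = circs[circs$circ_id %in% main, ],
       low = circs[circs$circ_id %in% low, ],
       long = circs[circs$is_long, ], reads = reads, det = det)
})

circ_key <- function(d) paste(d$chrom, d$start, d$end, d$strand)

## ---- independent brute-force junction oracle ------------------------------
## Scans every breakpoint split of the read (both orientations) using
## Biostrings::matchPattern only: no shared code with the detector's index,
## screening or extension machinery. Applies the declared contract: unique
## 20-nt anchors, reversed genomic order, inward extension to a signal-
## flanked breakpoint, span cutoff, leftmost breakpoint, gene-strand
## preference on palindromic signals.
oracle_detect_junction <- function(sequence, genome, genes = NULL,
                                   anchor_length = 20L, max_dist = 100000L) {
  occurrences <- function(pat, subj)
    Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(pat), subj)) - 1L
  subjects <- lapply(unclass(genome), Biostrings::DNAString)
  L <- nchar(sequence)
  if (L < 2L * anchor_length || grepl("[^ACGT]", sequence)) return(NULL)
  for (seq in c(sequence, revcomp(sequence))) {
    headA <- substr(seq, 1L, anchor_length)
    tailA <- substr(seq, L - anchor_length + 1L, L)
    ah <- lapply(subjects, function(s) occurrences(headA, s))
    at <- lapply(subjects, function(s) occurrences(tailA, s))
    if (sum(lengths(ah)) != 1L || sum(lengths(at)) != 1L) next
    chrom_h <- names(which(lengths(ah) == 1L))
    chrom_t <- names(which(lengths(at) == 1L))
    if (chrom_h != chrom_t) next
    pH <- ah[[chrom_h]][1]; pT <- at[[chrom_t]][1]
    if (pH <= pT) next
    subj <- subjects[[chrom_h]]
    glen <- length(subj)
    found <- NULL
    for (s in anchor_length:(L - anchor_length)) {
      S <- pT + anchor_length - L + s
      E <- pH + s
      if (S < 2L || E + 2L > glen || S >= E || E - S > max_dist) next
      prefix <- substr(seq, 1L, s)
      suffix <- substr(seq, s + 1L, L)
      if (!(pH %in% occurrences(prefix, subj))) next
      if (!((pT + anchor_length - (L - s)) %in% occurrences(suffix, subj))) next
      up <- as.character(subj[(S - 1L):S])
      down <- as.character(subj[(E + 1L):(E + 2L)])
      strands <- c(if (up == "AG" && down == "GT") "+",
                   if (up == "AC" && down == "CT") "-")
      if (length(strands) == 0L) next
      st <- strands[1]
      if (length(strands) == 2L) {
        st <- "+"
        if (!is.null(genes)) {
          gs <- unique(vapply(genes, function(g)
            if (g$chrom == chrom_h && g$start < E && S < g$end) g$strand
            else NA_character_, character(1)))
          gs <- gs[!is.na(gs)]
          if (length(gs) == 1L) st <- gs
        }
      }
      found <- list(chrom = chrom_h, start = S, end = E, strand = st)
      break
    }
    if (!is.null(found)) return(found)
  }
  NULL
}

## A hand-built single-gene annotation:
## gene g1 chr1:[500,3000)+ with exons [500,1200), [1500,2300), [2700,3000);
## 5'UTR [500,600), 3'UTR [2900,3000), CDS the rest of the exons.
toy_genes <- function() {
  exons <- circseed:::ivmat(c(500, 1500, 2700), c(1200, 2300, 3000))
  u5 <- circseed:::ivmat(500, 600); u3 <- circseed:::ivmat(2900, 3000)
  cds <- circseed:::interval_setdiff(exons, rbind(u5, u3))
  list(g1 = circseed:::new_gene_model("g1", "chr1", "+", list(
    t1 = list(transcript_id = "t1", exons = exons, cds = cds,
              utr5 = u5, utr3 = u3))))
}

## Random RNA string.
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
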