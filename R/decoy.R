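## miRNA decoy (target mimic) prediction. The miRNA (5'->3') is aligned
## antiparallel against circRNA sequence; pairing admits Watson-Crick and
## G:U wobble pairs. Candidate duplexes are scored match +1 / mismatch -1 /
## gap -2 and sites at or above a minimum score are evaluated against three
## positional rules in miRNA coordinates (position 1 = miRNA 5' terminal
## base):
##   rule 1: 1-6 mismatches/insertions in positions 9-20 (a central bulge is
##           required - a perfect duplex is cleavage-competent, not a decoy);
##   rule 2: perfect pairing at positions 2-8 (the seed);
##   rule 3: at most 4 mismatches/indels in the other regions (position 1
##           and 21+).
## An MFE ratio (site energy over the energy of a perfectly paired miRNA,
## with fixed per-pair energies AU -2, GC -3, GU -1) is reported, never
## filtered on.

DECOY_SCORING <- list(match = 1, mismatch = -1, gap = -2, min_score = 10)

normalize_rna <- function(x) {
  u <- chartr("Tt", "Uu", toupper(x))
  if (any(grepl("[^ACGUN]", u))) stop_fmt("invalid characters in RNA sequence")
  u
}

## Antiparallel pairing between a miRNA base and a target base (both given
## 5'->3'): WC plus G:U wobble.
rna_pairs <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

pair_energy <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("AU", "UA")) -2
  else if (key %in% c("GC", "CG")) -3
  else if (key %in% c("GU", "UG")) -1
  else 0
}

## ---- alignment ------------------------------------------------------------

## Alignments are stored as an ops string over columns:
##   M = paired, X = mismatch, D = gap in target (miRNA base unpaired),
##   I = gap in miRNA (inserted target base).
## The miRNA is consumed globally; the target window is free at both ends.
## Insertions are not allowed before position 1 or after the last miRNA
## position (they would only extend the window).

## Semi-global DP of miRNA m (chars) vs reversed target window r (chars).
## Returns list(score, endpoints j) or NULL if below min_score.
duplex_dp <- function(m, r, sc = DECOY_SCORING) {
  Lm <- length(m); Lt <- length(r)
  S <- matrix(-Inf, Lm + 1L, Lt + 1L)
  S[1, ] <- 0
  for (i in seq_len(Lm)) {
    S[i + 1L, 1L] <- S[i, 1L] + sc$gap
    for (j in seq_len(Lt)) {
      diag <- S[i, j] + if (rna_pairs(m[i], r[j])) sc$match else sc$mismatch
      del <- S[i, j + 1L] + sc$gap
      ins <- if (i > 0L && i < Lm) S[i + 1L, j] + sc$gap else -Inf
      S[i + 1L, j + 1L] <- max(diag, del, ins)
    }
  }
  list(S = S, best = max(S[Lm + 1L, ]))
}

## All optimal tracebacks from the DP matrix (capped). Each result:
## list(ops, j_start, j_end) with j over the reversed-target coordinates.
traceback_all <- function(S, m, r, sc = DECOY_SCORING, cap = 200L) {
  Lm <- length(m)
  best <- max(S[Lm + 1L, ])
  out <- list()
  walk <- function(i, j, ops) {
    if (length(out) >= cap) return()
    if (i == 0L) {
      out[[length(out) + 1L]] <<- list(ops = rev(ops), j_start = j + 1L)
      return()
    }
    if (j >= 1L) {
      d <- S[i, j] + if (rna_pairs(m[i], r[j])) sc$match else sc$mismatch
      if (S[i + 1L, j + 1L] == d)
        walk(i - 1L, j - 1L, c(ops, if (rna_pairs(m[i], r[j])) "M" else "X"))
    }
    if (S[i + 1L, j + 1L] == S[i, j + 1L] + sc$gap)
      walk(i - 1L, j, c(ops, "D"))
    if (i > 0L && i < Lm && j >= 1L &&
        S[i + 1L, j + 1L] == S[i + 1L, j] + sc$gap)
      walk(i, j - 1L, c(ops, "I"))
  }
  for (j in which(S[Lm + 1L, ] == best)) {
    je <- j - 1L
    walk(Lm, je, character(0))
    if (length(out) >= cap) break
  }
  lapply(out, function(a) { a$score <- best; a })
}

## Per-region defect counts of an ops string. Insertions are attributed to
## the region of the following miRNA position; deletions inside 9-20 fall
## into the "other" tally (rule 1 covers mismatches and insertions only).
region_counts <- function(ops) {
  pos <- 0L
  seed <- 0L; central <- 0L; other <- 0L
  region <- function(p) if (p >= 2L && p <= 8L) "seed"
                        else if (p >= 9L && p <= 20L) "central" else "other"
  for (op in ops) {
    if (op %in% c("M", "X", "D")) pos <- pos + 1L
    if (op == "M") next
    reg <- if (op == "I") region(pos + 1L) else region(pos)
    if (op == "X") {
      if (reg == "seed") seed <- seed + 1L
      else if (reg == "central") central <- central + 1L
      else other <- other + 1L
    } else if (op == "I") {
      if (reg == "seed") seed <- seed + 1L
      else if (reg == "central") central <- central + 1L
      else other <- other + 1L
    } else if (op == "D") {
      if (reg == "seed") seed <- seed + 1L
      else other <- other + 1L  # central deletions are tallied as "other"
    }
  }
  c(seed = seed, central = central, other = other)
}

## The seed requirement (rule 2) is decisive: it is reported as the failing
## rule whenever violated; otherwise the central-bulge range (rule 1), then
## the other-region cap (rule 3).
decoy_verdict <- function(counts) {
  if (counts[["seed"]] > 0L)
    list(pass = FALSE, failing_rule = 2L)
  else if (counts[["central"]] < 1L || counts[["central"]] > 6L)
    list(pass = FALSE, failing_rule = 1L)
  else if (counts[["other"]] > 4L)
    list(pass = FALSE, failing_rule = 3L)
  else list(pass = TRUE, failing_rule = NA_integer_)
}

## Canonical choice among equal-score alignments: prefer a passing duplex,
## then fewer total defects, then the lexicographically smallest ops string.
select_alignment <- function(alns) {
  if (length(alns) == 0L) return(NULL)
  keys <- vapply(alns, function(a) {
    rc <- region_counts(a$ops)
    v <- decoy_verdict(rc)
    sprintf("%d|%02d|%s", as.integer(!v$pass), sum(rc),
            paste(a$ops, collapse = ""))
  }, character(1))
  alns[[order(keys)[1]]]
}

#' Align a miRNA against a target sequence (duplex search)
#'
#' Semi-global alignment of the full miRNA against the target read
#' antiparallel, scored match +1 / mismatch -1 / gap -2 (G:U wobble counts
#' as a pair). Non-overlapping sites scoring at least `min_score` are
#' returned, best first.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param target target sequence, 5'->3'.
#' @param min_score minimum alignment score for a reported site.
#' @return list of alignments; each has `ops` (column string over M/X/D/I),
#'   `score`, `target_start`, `target_end` (0-based half-open window on the
#'   target), `counts` (seed/central/other defects).
#' @export
duplex_align <- function(mirna, target, min_score = DECOY_SCORING$min_score) {
  m <- chars(normalize_rna(mirna))
  tgt <- normalize_rna(target)
  Lt <- nchar(tgt)
  if (Lt < 4L || length(m) < 4L) return(list())
  ## reversed target: column j pairs miRNA position i antiparallel
  r_all <- rev(chars(tgt))
  sites <- list()
  search <- function(lo, hi) {   # on reversed coordinates, inclusive
    if (hi - lo + 1L < 4L) return()
    r <- r_all[lo:hi]
    dp <- duplex_dp(m, r)
    if (dp$best < min_score) return()
    alns <- traceback_all(dp$S, m, r)
    a <- select_alignment(alns)
    js <- a$j_start + lo - 1L; je <- attr_end(a, lo)
    rc <- region_counts(a$ops)
    sites[[length(sites) + 1L]] <<- list(
      ops = paste(a$ops, collapse = ""), score = a$score,
      target_start = Lt - je, target_end = Lt - js + 1L,
      counts = rc)
    search(lo, js - 1L)
    search(je + 1L, hi)
  }
  attr_end <- function(a, lo) {
    used <- sum(a$ops %in% c("M", "X", "I"))
    a$j_start + lo - 1L + max(used - 1L, 0L)
  }
  search(1L, length(r_all))
  sites[order(-vapply(sites, `[[`, numeric(1), "score"))]
}

#' Apply the decoy rules to a duplex alignment
#'
#' @param aln one alignment from [duplex_align()].
#' @return the alignment augmented with `seed_mismatches`,
#'   `central_defects`, `other_defects`, `pass`, `failing_rule`.
#' @export
apply_decoy_rules <- function(aln) {
  rc <- aln$counts %||% region_counts(chars(aln$ops))
  v <- decoy_verdict(rc)
  aln$seed_mismatches <- rc[["seed"]]
  aln$central_defects <- rc[["central"]]
  aln$other_defects <- rc[["other"]]
  aln$pass <- v$pass
  aln$failing_rule <- v$failing_rule
  aln
}

#' MFE ratio of a duplex site
#'
#' Site energy is the sum of fixed per-pair energies over paired columns
#' (AU -2, GC -3, GU -1; defects contribute 0); the reference is the energy
#' of the same miRNA perfectly Watson-Crick paired. The ratio lies in
#' `[0, 1]` and is reported for ranking only.
#'
#' @param aln an alignment from [duplex_align()].
#' @param mirna the miRNA sequence.
#' @param target the target sequence given to [duplex_align()].
#' @return list with `mfe_site`, `mfe_perfect`, `mfe_ratio`.
#' @export
mfe_ratio <- function(aln, mirna, target) {
  m <- chars(normalize_rna(mirna))
  tgt <- normalize_rna(target)
  window <- rev(chars(substr(tgt, aln$target_start + 1L, aln$target_end)))
  mfe_perfect <- sum(vapply(m, function(b)
    switch(b, A = -2, U = -2, G = -3, C = -3, 0), numeric(1)))
  i <- 0L; j <- 0L; e <- 0
  for (op in chars(aln$ops)) {
    if (op == "M") { i <- i + 1L; j <- j + 1L; e <- e + pair_energy(m[i], window[j]) }
    else if (op == "X") { i <- i + 1L; j <- j + 1L }
    else if (op == "D") i <- i + 1L
    else j <- j + 1L
  }
  list(mfe_site = e, mfe_perfect = mfe_perfect,
       mfe_ratio = if (mfe_perfect == 0) 0 else e / mfe_perfect)
}

## Rotate a circRNA sequence so the back-splice junction is internal: the
## final `overhang` bases are prepended, making junction-spanning sites
## discoverable on a linear string.
rotate_circ <- function(s, overhang = 30L) {
  n <- nchar(s)
  k <- min(overhang, n)
  paste0(substr(s, n - k + 1L, n), s)
}

#' Predict circRNAs acting as miRNA decoys
#'
#' Every (miRNA, circRNA) pair is searched for duplex sites on the
#' junction-rotated circ sequence; sites are rule-checked and the
#' best-scoring passing site per pair is reported. The audit table retains
#' every evaluated site with its verdict.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param circ_seqs named character vector of circRNA sequences.
#' @param min_score minimum duplex score.
#' @param rotate whether to rotate the circ sequence across the junction.
#' @return list with `hits` (passing sites, one row per miRNA-circ pair) and
#'   `audit` (all evaluated sites). Columns: `mirna_id`, `circ_id`,
#'   `target_start`, `target_end` (on the rotated sequence), `score`,
#'   `ops`, `seed_mismatches`, `central_defects`, `other_defects`, `pass`,
#'   `failing_rule`, `mfe_site`, `mfe_perfect`, `mfe_ratio`.
#' @export
predict_decoys <- function(mirnas, circ_seqs,
                           min_score = DECOY_SCORING$min_score,
                           rotate = TRUE) {
  audit <- list()
  hits <- list()
  for (mid in names(mirnas)) {
    for (cid in names(circ_seqs)) {
      tgt <- if (rotate) rotate_circ(normalize_rna(circ_seqs[[cid]]))
             else normalize_rna(circ_seqs[[cid]])
      sites <- duplex_align(mirnas[[mid]], tgt, min_score = min_score)
      if (length(sites) == 0) next
      rows <- lapply(sites, function(s) {
        s <- apply_decoy_rules(s)
        mfe <- mfe_ratio(s, mirnas[[mid]], tgt)
        data.frame(mirna_id = mid, circ_id = cid,
                   target_start = s$target_start, target_end = s$target_end,
                   score = s$score, ops = s$ops,
                   seed_mismatches = s$seed_mismatches,
                   central_defects = s$central_defects,
                   other_defects = s$other_defects, pass = s$pass,
                   failing_rule = s$failing_rule, mfe_site = mfe$mfe_site,
                   mfe_perfect = mfe$mfe_perfect, mfe_ratio = mfe$mfe_ratio,
                   stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      audit[[length(audit) + 1L]] <- df
      ok <- df[df$pass, , drop = FALSE]
      if (nrow(ok))
        hits[[length(hits) + 1L]] <- ok[which.max(ok$score), , drop = FALSE]
    }
  }
  empty <- data.frame(mirna_id = character(0), circ_id = character(0),
                      target_start = integer(0), target_end = integer(0),
                      score = numeric(0), ops = character(0),
                      seed_mismatches = integer(0), central_defects = integer(0),
                      other_defects = integer(0), pass = logical(0),
                      failing_rule = integer(0), mfe_site = numeric(0),
                      mfe_perfect = numeric(0), mfe_ratio = numeric(0))
  list(hits = if (length(hits)) do.call(rbind, hits) else empty,
       audit = if (length(audit)) do.call(rbind, audit) else empty)
}

#' Brute-force reference search for the best duplex alignment
#'
#' Exhaustively enumerates every alignment of the full miRNA against any
#' window of the target (branch-and-bound on the attainable score, so the
#' optimum is exact), and applies the same canonical selection among
#' optimal alignments as the dynamic-programming engine. Intended as an
#' independent cross-check on short targets.
#'
#' @param mirna miRNA sequence.
#' @param target target sequence (keep below ~80 nt).
#' @param min_score minimum reported score.
#' @return `NULL` if no alignment reaches `min_score`, else list with
#'   `score`, `ops`, `counts`, `pass`, `failing_rule`.
#' @export
enumerate_best_duplex <- function(mirna, target,
                                  min_score = DECOY_SCORING$min_score) {
  sc <- DECOY_SCORING
  m <- chars(normalize_rna(mirna))
  r <- rev(chars(normalize_rna(target)))
  Lm <- length(m); Lt <- length(r)
  best_score <- min_score - 1
  found <- list()
  recurse <- function(i, j, score, ops) {
    if (score + (Lm - i) * sc$match < best_score) return()
    if (i == Lm) {
      if (score > best_score) { best_score <<- score; found <<- list() }
      if (score == best_score)
        found[[length(found) + 1L]] <<- list(score = score, ops = ops)
      return()
    }
    if (j < Lt)
      recurse(i + 1L, j + 1L, score +
                if (rna_pairs(m[i + 1L], r[j + 1L])) sc$match else sc$mismatch,
              c(ops, if (rna_pairs(m[i + 1L], r[j + 1L])) "M" else "X"))
    recurse(i + 1L, j, score + sc$gap, c(ops, "D"))
    if (i > 0L && i < Lm && j < Lt)
      recurse(i, j + 1L, score + sc$gap, c(ops, "I"))
  }
  for (j0 in 0:(Lt - 1L)) recurse(0L, j0, 0, character(0))
  if (best_score < min_score) return(NULL)
  found <- Filter(function(a) a$score == best_score, found)
  if (length(found) == 0L) return(NULL)
  a <- select_alignment(found)
  rc <- region_counts(a$ops)
  v <- decoy_verdict(rc)
  list(score = a$score, ops = paste(a$ops, collapse = ""), counts = rc,
       pass = v$pass, failing_rule = v$failing_rule)
}
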