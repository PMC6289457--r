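---
title: "circseed: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circseed: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circseed)
```

## Scope

circseed reimplements, as a tested and reusable pipeline, a plant circRNA
analysis workflow: back-splice junction detection from single-end RNA-seq
reads, positional classification of the detected circRNAs against gene
models, expression and tissue-specificity analysis, count-based
differential expression, miRNA-decoy (target mimic) prediction, ceRNA
network construction, and cross-species conservation through
reciprocal-best-hit orthologs. Because the workflow is defined by rules and
filters rather than by a single statistical model, the package ships a
synthetic-data module that plants ground truth for every stage; all claims
the test suite makes are claims about recovery of that planted truth.

## Back-splice detection

A junction-spanning read cannot be placed contiguously on the genome.
Reads are therefore first mapped linearly (exact placement, then a rescue
allowing up to `max_mismatch = 2` substitutions, no indels — a deliberately
simple stand-in for a seed-and-extend aligner that is adequate at the
simulated error rates). For each surviving read, the two terminal 20-nt
anchors are aligned exactly; both must map to a *unique* position (anchors
with more than one exact occurrence are discarded outright). When the
anchors land on one chromosome with their genomic order reversed relative
to their order in the read, they are extended inward: a breakpoint at split
`s` is consistent when the read prefix of length `s` matches the genome
from the head-anchor position and the remaining suffix matches ending at
the tail anchor. A consistent breakpoint is accepted only if the genomic
dinucleotides flanking the circ interval are the canonical splice signal —
`AG` immediately upstream of `start` and `GT` at `end` for a plus-strand
circ, `AC`/`CT` for minus — and the span is at most 100 kb. Candidates are
merged by exact coordinate identity, and a circRNA is reported when at
least 2 distinct reads support it.

Decisions where the procedure is underdetermined:

* **Breakpoint ambiguity.** When sequence repeats around the junction make
  several splits consistent, the leftmost signal-carrying breakpoint is
  chosen. This is a pure tie-break; it keeps output deterministic and
  input-order invariant.
* **Strand assignment.** The signal is tested on both strands. If both
  match (possible on palindromic flanks) the strand of a uniquely
  overlapping annotated gene wins, else `+`.
* **One junction per read.** A read supports at most one junction (the
  first accepted orientation), preventing double counting.
* **Merging** is by exact coordinate identity; no fuzzy clustering, so
  read support counts are reproducible.

The detector is checked against an independent brute-force oracle that
enumerates every breakpoint split of the read with plain pattern matching;
on 20 kb genomes the two agree on 200/200 simulated junction reads.

## Synthetic data

The generator emulates a compact plant genome: non-overlapping multi-exon
genes (4–8 exons of 120–300 nt, introns 80–400 nt) with 5'/3' UTRs carved
from terminal exons, separated by 0.5–3 kb intergenic gaps, on random
uniform base composition. Every intron boundary is stamped with the
canonical splice dinucleotides on the gene's strand, so circRNAs planted at
internal exon boundaries carry the required back-splice signal by
construction; gene-overlapping and intergenic circRNAs are anchored at
positions where the signal occurs in the sequence (in random sequence a
given dinucleotide occurs every ~16 nt, so placement virtually always
succeeds and errors out otherwise). Junction reads concatenate a suffix of
the circ 3' end with a prefix of its 5' start, with the breakpoint placed
uniformly at least one anchor length from both read ends — the geometry the
detector assumes. Linear reads are drawn uniformly from spliced transcripts
in random orientation. Sequencing errors are substitutions only; indels
would exercise nothing in the covered computation. Expression counts are
negative binomial with dispersion 0.1 — overdispersed enough to exercise
the DE test beyond a Poisson idealization.

What the simulation does *not* model: non-uniform coverage, quality-score
structure, repeats and multi-mapping beyond chance k-mer collisions,
paired-end reads, isoform-level linear splicing variation, GC bias. Tests
passing on this data show the algorithms implement their contracts; they do
not certify performance on real libraries.

Default study-scale conditions used by the acceptance checks: 2 chromosomes
× 500 kb with 100 genes, 60 planted circRNAs in class proportions
0.5/0.2/0.3 (within / overlapping / intergenic), 5 genes with two circRNA
isoforms, 20 error-free junction reads per circ over 50× linear coverage,
plus negative controls (single-read support; spans above 100 kb). The
end-to-end and determinism runs use a scaled-down genome (1 × 130 kb, 12
genes, 12 circRNAs) so that two full repetitions stay cheap.

## Classification

"Gene interval" means the span of the GFF3 `gene` feature, not the exon
union; this preserves the distinction between *within-gene* and *exonic*
(a circ can overlap a terminal exon and run into intergenic space — exonic
but not within a gene). Back-splice boundary labels use feature precedence
CDS > UTR > intron > intergenic across all transcripts of all overlapping
genes, which makes labels deterministic under isoform ambiguity. The label
pair is ordered 5'→3' on the circ's strand; aggregate reporting uses the
unordered canonical form. A boundary is "known" only when it coincides
exactly with an annotated exon edge. Parent genes are all overlapping
genes; the largest overlap is "primary" and drives
alternative-circularization grouping; circs overlapping genes on both
strands are flagged (`multi_gene_conflict`) rather than silently resolved.

## Expression

* **RPM** = junction reads / total mapped reads × 10⁶. Total mapped reads
  (linear + junction) is used as the denominator, the standard usage.
  RPM is also the input to the tissue-specificity index.
* **Circular-to-linear ratio.** The linear denominator is the mean of
  linearly mapped reads crossing the circ's start and end boundaries with
  ≥ 8 nt on each side. With reads simulated from spliced transcripts,
  genomically contiguous boundary-crossing reads are rare, so the ratio is
  often the `Inf` sentinel, which the binning places in the top (">10")
  level; the definition is kept because it is symmetric and computable
  from the same alignments as everything else.
* **Bins** are left-closed right-open with an open top: 0–0.5, 0.5–1, 1–5,
  5–10, >10 for circRNAs (ratio or RPM), 0–50, 50–100, 100–500, 500–2000,
  >2000 for parent-gene RPKM.
* **Tissue-specificity index** = Σᵢ(1 − expᵢ/exp_max)/(n − 1): 0 for
  uniform, 1 for single-tissue expression; > 0.9 is called
  tissue-specific. All-zero vectors are undefined (0/0) and reported `NA`,
  excluded from tissue-specific counts.
* **Differential expression.** Junction counts are pooled per condition
  and tested against the pooled library remainder with a two-sided Fisher
  exact test; BH-adjusted. Fold change is the ratio of mean counts scaled
  to the geometric-mean library size with a +0.5 pseudocount. Calls
  require FDR < 0.05 *and* fold change > 2 or < 0.5. This replaces a
  negative-binomial exact test on purpose: it is self-contained and fully
  reproducible, at the cost of anti-conservative p-values under biological
  overdispersion — the fold-change requirement is what keeps the realized
  false-call rate low (≈1.4% on all-null simulations at dispersion 0.1,
  versus the 5% nominal level). Library sizes should be the per-sample
  total mapped reads; junction counts are a vanishing fraction of a
  library, so using their column sums instead would let composition bias
  absorb real signal.

## miRNA decoys

The miRNA is aligned antiparallel to circRNA sequence; Watson–Crick and
G:U wobble pairs both count as paired. Scoring is match +1 / mismatch −1 /
gap −2 with a minimum reported site score of 10; the full miRNA is
consumed (semi-global alignment, free target ends). The three positional
rules are evaluated in miRNA coordinates (position 1 = 5' terminal base):

1. 1–6 mismatches or inserted (target-bulge) bases in positions 9–20 —
   read as *requiring* a central defect: a perfectly paired duplex is
   cleavage-competent, not a decoy, consistent with plant target-mimic
   convention. The audit table retains every evaluated site, so the
   upper-bound-only reading is recoverable by filtering on
   `central_defects >= 0`.
2. perfect pairing at seed positions 2–8 (any defect attributed to the
   seed, including an insertion between seed positions, breaks it);
3. at most 4 mismatches/indels in the other regions (position 1 and 21+).
   Deletions of central miRNA bases are tallied here too, since rule 1
   enumerates mismatches and insertions only.

The seed rule is decisive in reporting: a seed violation is recorded as
the failing rule regardless of the central count. Insertions are
attributed to the region of the following miRNA position, so the classic
bulge between positions 12 and 13 counts as central. Among equal-score
alignments the engine prefers a rule-passing duplex, then fewer defects,
then a lexicographic tie-break on the alignment string — and the
brute-force enumerator used as an oracle applies the identical selection,
making the equivalence check exact rather than tie-lucky.

The MFE ratio uses a fixed per-pair energy table (AU −2, GC −3, GU −1,
defects 0) rather than a nearest-neighbor model: only the *ratio*
(site/perfect) is reported, never filtered on, and a rank statistic does
not justify thermodynamic machinery. Circ sequences are rotated (last
30 nt prepended) so junction-spanning sites are discoverable; duplicated
sites in the overlap deduplicate to the best-scoring one.

Note an interaction between the score threshold and the rules: a duplex
with six central mismatches scores 21 − 12 = 9 < 10 and is undiscoverable
at default scoring even though rule 1 tolerates it. The planted-truth
generator records an `expected_score`/`discoverable` flag for exactly this
reason, and heavy designs can also be *re-explained* by the optimal
alignment with fewer defects than designed; planted-verdict tests
therefore use designs in the discoverable range.

## ceRNA network

miRNA–circRNA edges come from decoy prediction; miRNA–mRNA edges reuse the
same aligner with cleavage-competent criteria (perfect seed, ≤ 2 central
defects, ≤ 4 elsewhere — stricter centrally than decoys, since a cleavable
target should not carry a protective bulge). The graph is undirected and
unweighted (scores kept as edge attributes), tripartite in node types with
miRNAs in the middle: circRNA–mRNA or same-type edges are structurally
impossible and asserted against. Exports: GraphML (round-trips types),
SIF, TSV.

## Conservation

Ortholog pairs are reciprocal best hits under Smith–Waterman with BLOSUM62
and affine gaps 11/1, raw score ≥ 50; ties break lexicographically by id.
Raw scores replace BLAST E-values deliberately: E-values depend on
database size and are irreproducible on toy proteomes. Conserved circRNAs
are gated first by orthologous parents, then by a local nucleotide
alignment at ≥ 50% identity over ≥ 50% of the shorter circ; both
thresholds are arguments. "Best paired genes" is read as reciprocal best
hit — the standard operationalization of ortholog pairing; one-directional
best hits are demonstrably not symmetric and not one-to-one.

## Determinism and numerics

Every generator is a pure function of (config, seed); randomness runs
through an isolated RNG scope so library calls cannot perturb the stream.
Two end-to-end runs with the same seed produce byte-identical outputs
(provenance headers carry version, seed and a config hash — no
timestamps). Degenerate inputs have defined behavior throughout: empty
FASTA warns and returns an empty genome, empty read sets warn and return
empty calls, zero-variance coexpression pairs are skipped with a message,
all-zero tissue vectors are `NA`, a zero linear denominator is an `Inf`
sentinel binned as ">10".

## Limitations

Single-end reads only; the toy aligner tolerates ≤ 2 substitutions and no
indels in linear placement, and junction anchors must be exact — at realistic
error rates some junction reads are lost before the support filter. The
Fisher-based DE test inherits anti-conservative p-values under strong
overdispersion and leans on the fold-change gate. The MFE table ignores
stacking; absolute energies are not comparable to RNAplex/RNAhybrid
output. GO/KEGG enrichment, figure rendering, and repeat annotation are
out of scope.
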