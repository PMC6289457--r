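#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @importFrom methods as is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#'
#' Plain character in, plain character out. U is treated as T.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  up <- chartr("u", "U", x)
  up <- chartr("U", "T", toupper(up))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
}

## Split a character string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Hamming distance between two equal-length strings (fast byte compare).
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## RNG stream is untouched. All generators route randomness through this.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

## Largest-remainder apportionment of n into parts proportional to p.
apportion <- function(n, p) {
  stopifnot(all(p >= 0), sum(p) > 0)
  q <- n * p / sum(p)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(q - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
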