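## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded operations are
#' reproducible without perturbing the global random stream. A NULL seed
#' evaluates the expression under the current stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed, kept inside 32-bit integer range.
childSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  ## double arithmetic keeps the product exact; the result fits in 32 bits
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 7919) %%
               2147483629)
}

#' Random DNA sequences
#' @noRd
randomDNA <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""), character(1))
}

## Reverse complement on plain character vectors (Biostrings-backed).
revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

assertProb <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop("'", what, "' must be in [0, 1]")
  invisible(x)
}

assertDNA <- function(x, what) {
  if (!is.character(x) || length(x) == 0L || any(is.na(x)) ||
      any(!grepl("^[ACGT]+$", x)))
    stop("'", what, "' must be non-empty strings over {A,C,G,T}")
  invisible(x)
}

## Split strings into per-character matrices and back.
seqToInt <- function(x) match(strsplit(x, "", fixed = TRUE)[[1]], DNA_BASES)
intToSeq <- function(v) paste(DNA_BASES[v], collapse = "")

#' Read a FASTQ file into a named character vector of sequences
#' @noRd
readFastqSeqs <- function(path) {
  x <- readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write sequences as 4-line Sanger FASTQ with a constant placeholder quality
#'
#' Per-base qualities are not modelled downstream (purity is identity-based),
#' so reads carry a constant Q20 ('5') quality string.
#' @noRd
writeFastqSeqs <- function(seqs, path, append = FALSE) {
  dna <- DNAStringSet(seqs)
  qual <- BStringSet(vapply(width(dna), function(w)
    paste(rep("5", w), collapse = ""), character(1)))
  writeXStringSet(dna, filepath = path, format = "fastq",
                  qualities = qual, append = append)
  invisible(path)
}
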