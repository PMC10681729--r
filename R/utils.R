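## Internal helpers shared across modules: DNA alphabet handling, integer
## base encodings used by the k-mer/MI/scanning hot paths, and seeded RNG.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @examples
#' revcomp(c("TTGAC", "ACGT"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

stop_if_not_dna <- function(x, what, allow_n = FALSE) {
  bad <- which(!is_dna(x, allow_n = allow_n))
  if (length(bad)) {
    stop(sprintf("%s contains non-ACGT%s characters (first offender: element %d)",
                 what, if (allow_n) "/N" else "", bad[1]), call. = FALSE)
  }
  invisible(x)
}

## Integer encoding A=1, C=2, G=3, T=4, anything else NA. Rows are reads.
## All reads must have equal length.
base_code_matrix <- function(reads) {
  n <- length(reads)
  if (n == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  L <- nchar(reads[1])
  if (any(nchar(reads) != L)) stop("reads must have uniform length", call. = FALSE)
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  codes <- lut[utf8ToInt(paste(reads, collapse = ""))]
  matrix(codes, nrow = n, ncol = L, byrow = TRUE)
}

codes_to_strings <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  chars <- DNA_BASES[t(mat)]
  apply(matrix(chars, ncol = nrow(mat)), 2, paste, collapse = "")
}

## Evaluate expr with a locally seeded RNG; global .Random.seed restored on
## exit. All stochastic operations funnel through this, so a single integer
## seed fully determines their output (documented stream: Mersenne-Twister,
## one stream per call).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Derive a child seed from a parent seed and a stream index, staying below
## 2^31. Deterministic and collision-poor for the handful of streams used.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483647)
}

## All substrings of length k starting at each offset (vectorized over reads).
## Returns a character vector of length n_reads * n_offsets, read-major per
## offset (offset varies slowest).
sliding_windows <- function(reads, k) {
  L <- nchar(reads[1])
  if (k > L) stop(sprintf("window size %d exceeds read length %d", k, L), call. = FALSE)
  starts <- seq_len(L - k + 1L)
  unlist(lapply(starts, function(s) substr(reads, s, s + k - 1L)), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
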