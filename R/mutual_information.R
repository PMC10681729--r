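## mutual_information: joint 3-mer distributions at position pairs and the
## E-MI / D-MI statistics over the triangular position-pair grid.
##
## A TF footprint contacts two nearby 3-bp windows of the ligand, biasing
## the joint distribution of 3-mers at those windows in an enriched
## library. E-MI sums the top-10 pointwise mutual-information contributions
## at a position pair; D-MI restricts the sum to identical or
## reverse-complement 3-mer pairs, which is where dimeric CREs introduce
## their bias.

TRIMER_NAMES <- local({
  b <- c("A", "C", "G", "T")
  idx <- 0:63
  paste0(b[idx %/% 16 + 1], b[(idx %/% 4) %% 4 + 1], b[idx %% 4 + 1])
})

## revcomp of trimer code 16a+4b+c is 16(3-c)+4(3-b)+(3-a)
TRIMER_RC <- local({
  idx <- 0:63
  a <- idx %/% 16; b <- (idx %/% 4) %% 4; c <- idx %% 4
  16L * (3L - c) + 4L * (3L - b) + (3L - a)
})

## n x (L-2) matrix of trimer codes 0..63 (NA where any base is N)
trimer_code_matrix <- function(reads) {
  m <- base_code_matrix(reads) - 1L
  L <- ncol(m)
  if (L < 3L) stop("reads shorter than 3 bp", call. = FALSE)
  16L * m[, 1:(L - 2L), drop = FALSE] +
    4L * m[, 2:(L - 1L), drop = FALSE] +
    m[, 3:L, drop = FALSE]
}

joint_from_codes <- function(c1, c2) {
  ok <- !is.na(c1) & !is.na(c2)
  tab <- tabulate(c1[ok] * 64L + c2[ok] + 1L, nbins = 4096L)
  matrix(tab, nrow = 64L, ncol = 64L, byrow = TRUE,
         dimnames = list(pos1 = TRIMER_NAMES, pos2 = TRIMER_NAMES))
}

#' Joint 3-mer distribution at a pair of non-overlapping positions
#'
#' @param lib a [ligand_library()] with uniform read length, or a character
#'   vector of sequences.
#' @param pos1,pos2 0-based offsets of the two 3-bp windows;
#'   `pos2 >= pos1 + 3` (non-overlapping) and `pos2 + 3 <= read length`.
#' @return an object of class `trimer_joint`: 64 x 64 joint counts, the
#'   positions, and the number of reads counted. Reads with N in either
#'   window are skipped.
#' @export
trimer_joint <- function(lib, pos1, pos2) {
  reads <- if (inherits(lib, "ligand_library")) lib$reads else as.character(lib)
  L <- nchar(reads[1])
  if (pos2 < pos1 + 3L) stop("windows overlap: pos2 must be >= pos1 + 3", call. = FALSE)
  if (pos2 + 3L > L) stop("pos2 window extends past read end", call. = FALSE)
  tc <- trimer_code_matrix(reads)
  joint <- joint_from_codes(tc[, pos1 + 1L], tc[, pos2 + 1L])
  structure(list(pos1 = as.integer(pos1), pos2 = as.integer(pos2),
                 joint = joint, n = sum(joint)),
            class = "trimer_joint")
}

#' @export
print.trimer_joint <- function(x, ...) {
  cat(sprintf("trimer_joint at (pos1=%d, pos2=%d): n=%d reads\n", x$pos1, x$pos2, x$n))
  invisible(x)
}

as_joint_matrix <- function(joint) {
  if (inherits(joint, "trimer_joint")) joint$joint else as.matrix(joint)
}

## Pointwise MI contributions P * log2(P / (P1 P2)) with the 0*log0 := 0
## convention; no pseudocounts (they would bias the null upward).
mi_contributions <- function(joint) {
  m <- as_joint_matrix(joint)
  n <- sum(m)
  if (n <= 0) stop("empty joint table", call. = FALSE)
  P <- m / n
  E <- outer(rowSums(P), colSums(P))
  contrib <- matrix(0, 64L, 64L, dimnames = dimnames(P))
  nz <- P > 0
  contrib[nz] <- P[nz] * log2(P[nz] / E[nz])
  contrib
}

#' Full mutual information of a 3-mer joint distribution
#'
#' Plug-in (maximum likelihood) estimate over all 4096 3-mer pairs, in bits.
#'
#' @param joint a `trimer_joint` or a 64 x 64 count matrix.
#' @return bits (>= 0).
#' @export
full_mi <- function(joint) sum(mi_contributions(joint))

#' Enriched-sequence mutual information (E-MI)
#'
#' Sum of the `top_n` largest pointwise MI contributions
#' `P * log2(P / (P1 P2))` over all 4096 3-mer pairs. "Most enriched" is
#' ranked by contribution by default; ranking by the observed/expected
#' ratio is available as an alternative.
#'
#' @param joint a `trimer_joint` or 64 x 64 count matrix.
#' @param top_n number of pairs summed (default 10).
#' @param ranking `"contribution"` (default) or `"ratio"`.
#' @return bits.
#' @export
emi <- function(joint, top_n = 10L, ranking = c("contribution", "ratio")) {
  ranking <- match.arg(ranking)
  contrib <- mi_contributions(joint)
  if (ranking == "contribution") {
    sum(sort(as.vector(contrib), decreasing = TRUE)[seq_len(min(top_n, 4096L))])
  } else {
    m <- as_joint_matrix(joint)
    P <- m / sum(m)
    E <- outer(rowSums(P), colSums(P))
    ratio <- ifelse(P > 0, P / E, -Inf)
    ord <- order(ratio, decreasing = TRUE)[seq_len(min(top_n, sum(P > 0)))]
    sum(contrib[ord])
  }
}

#' Dimeric-sequence mutual information (D-MI)
#'
#' Sum of pointwise MI contributions over the 128 3-mer pairs that are
#' identical (`x`, `x`) or reverse-complement (`x`, `revcomp(x)`) — the
#' pairs where dimeric CREs bias the joint distribution.
#'
#' @param joint a `trimer_joint` or 64 x 64 count matrix.
#' @return bits, with attributes `identical` and `revcomp` holding the two
#'   partial sums.
#' @export
dmi <- function(joint) {
  contrib <- mi_contributions(joint)
  ident <- sum(diag(contrib))
  rc <- sum(contrib[cbind(1:64, TRIMER_RC + 1L)])
  structure(ident + rc, identical = ident, revcomp = rc)
}

valid_position_pairs <- function(L) {
  pairs <- expand.grid(pos1 = 0:(L - 6L), pos2 = 0:(L - 3L))
  pairs <- pairs[pairs$pos2 >= pairs$pos1 + 3L & pairs$pos2 + 3L <= L, , drop = FALSE]
  pairs[order(pairs$pos1, pairs$pos2), , drop = FALSE]
}

#' Mutual-information statistic over all valid position pairs
#'
#' Evaluates E-MI, D-MI or the full MI at every pair of non-overlapping
#' 3-bp windows within the core (`pos2 - pos1 >= 3`,
#' `pos2 + 3 <= core length`). TF signals concentrate near the hypotenuse
#' of the triangle (closely spaced pairs).
#'
#' @param lib a [ligand_library()] with uniform read length >= 6.
#' @param statistic `"emi"`, `"dmi"` or `"full"`.
#' @param top_n passed to [emi()].
#' @return a data.frame (class `mi_triangle`) with columns pos1, pos2, bits
#'   (plus identical/revcomp partial sums for D-MI).
#' @export
mi_triangle <- function(lib, statistic = c("emi", "dmi", "full"), top_n = 10L) {
  statistic <- match.arg(statistic)
  reads <- if (inherits(lib, "ligand_library")) lib$reads else as.character(lib)
  L <- nchar(reads[1])
  if (L < 6L) stop("core shorter than 6 bp: no valid position pair", call. = FALSE)
  tc <- trimer_code_matrix(reads)
  pairs <- valid_position_pairs(L)
  res <- vapply(seq_len(nrow(pairs)), function(i) {
    joint <- joint_from_codes(tc[, pairs$pos1[i] + 1L], tc[, pairs$pos2[i] + 1L])
    switch(statistic,
           emi = c(emi(joint, top_n = top_n), NA_real_, NA_real_),
           full = c(full_mi(joint), NA_real_, NA_real_),
           dmi = {
             d <- dmi(joint)
             c(as.numeric(d), attr(d, "identical"), attr(d, "revcomp"))
           })
  }, numeric(3))
  out <- data.frame(pos1 = pairs$pos1, pos2 = pairs$pos2, bits = res[1, ])
  if (statistic == "dmi") {
    out$identical <- res[2, ]
    out$revcomp <- res[3, ]
  }
  attr(out, "statistic") <- statistic
  class(out) <- c("mi_triangle", "data.frame")
  out
}
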