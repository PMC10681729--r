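## dimer_landscape: counts and enrichment of a dimeric core k-mer pair
## (default the WRKY W-box, TTGAC) by relative orientation and spacing.
##
## Orientation convention for a 5'->3' core C with reverse complement R,
## scanning the given strand left to right:
##   DR (direct repeat):  C...C  — and equivalently R...R, which is the
##                                same configuration seen from the minus
##                                strand, canonicalized to DR;
##   IR (inverted repeat, head-to-head): C...R;
##   ER (everted repeat, tail-to-tail):  R...C.
## Spacing is the number of bases strictly BETWEEN the two core matches
## (adjacent cores have spacing 0). This convention is load-bearing: an
## off-by-one here shifts the whole landscape.

#' Dimeric core specification
#'
#' @param core the monomer core sequence (default `TTGAC`, the W-box).
#' @param orientations subset of `c("DR","IR","ER")`.
#' @param spacing_range integer spacings (bases strictly between cores).
#' @return object of class `dimer_spec`.
#' @export
dimer_spec <- function(core = "TTGAC", orientations = c("DR", "IR", "ER"),
                       spacing_range = 0:20) {
  stop_if_not_dna(core, "core")
  orientations <- match.arg(orientations, c("DR", "IR", "ER"), several.ok = TRUE)
  structure(list(core = core, orientations = orientations,
                 spacing_range = as.integer(spacing_range),
                 palindromic = core == revcomp(core)),
            class = "dimer_spec")
}

overlapping_match_starts <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Count dimeric core pairs by orientation and spacing
#'
#' Every ordered pair of core matches within a sequence is classified and
#' counted once; a run of three cores yields all three pairs. Overlapping
#' cores (negative spacing) are excluded. Counting the given strand
#' already covers both strands because a minus-strand direct repeat reads
#' as `R...R` on the plus strand (canonicalized to DR) and IR/ER are
#' strand-symmetric classes. A palindromic core makes the orientations
#' degenerate; such pairs are counted once, as DR.
#'
#' @param seqs character vector of sequences, a [ligand_library()], or a
#'   `DNAStringSet` (e.g. peak sequences).
#' @param spec a [dimer_spec()].
#' @return object of class `dimer_landscape`: `counts` matrix
#'   (orientations x spacings), `n_sequences`, `spec`,
#'   `values = "counts"`.
#' @export
count_dimers <- function(seqs, spec = dimer_spec()) {
  if (inherits(seqs, "ligand_library")) seqs <- seqs$reads
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  seqs <- toupper(seqs)
  core <- spec$core
  rc <- revcomp(core)
  len <- nchar(core)
  spacings <- spec$spacing_range
  counts <- matrix(0L, nrow = length(spec$orientations), ncol = length(spacings),
                   dimnames = list(spec$orientations, as.character(spacings)))
  smin <- min(spacings); smax <- max(spacings)
  for (s in seqs) {
    cpos <- overlapping_match_starts(s, core)
    rpos <- if (spec$palindromic) integer(0) else overlapping_match_starts(s, rc)
    pos <- c(cpos, rpos)
    if (length(pos) < 2L) next
    lab <- c(rep("C", length(cpos)), rep("R", length(rpos)))
    ord <- order(pos)
    pos <- pos[ord]; lab <- lab[ord]
    for (i in seq_len(length(pos) - 1L)) for (j in (i + 1L):length(pos)) {
      sp <- pos[j] - pos[i] - len
      if (sp < smin) next
      if (sp > smax) break
      ori <- if (lab[i] == "C" && lab[j] == "C") "DR"
             else if (lab[i] == "R" && lab[j] == "R") "DR"
             else if (lab[i] == "C") "IR" else "ER"
      if (ori %in% spec$orientations)
        counts[ori, as.character(sp)] <- counts[ori, as.character(sp)] + 1L
    }
  }
  structure(list(counts = counts, n_sequences = length(seqs), spec = spec,
                 values = "counts"),
            class = "dimer_landscape")
}

#' @export
print.dimer_landscape <- function(x, ...) {
  cat(sprintf("dimer_landscape (%s) for core %s over %d sequences:\n",
              x$values, x$spec$core, x$n_sequences))
  print(x$counts)
  invisible(x)
}

#' Orientation/spacing enrichment against a matched control
#'
#' Per-cell `log2` ratio of frequency-normalized counts with a
#' pseudocount: `log2(((obs+pc)/n_obs) / ((ctrl+pc)/n_ctrl))`.
#'
#' @param obs,ctrl `dimer_landscape` count objects with identical specs.
#' @param pseudocount added to each cell.
#' @return a `dimer_landscape` with `values = "log2_enrichment"`.
#' @export
dimer_enrichment <- function(obs, ctrl, pseudocount = 1) {
  stopifnot(inherits(obs, "dimer_landscape"), inherits(ctrl, "dimer_landscape"))
  if (!identical(obs$spec$core, ctrl$spec$core) ||
      !identical(dim(obs$counts), dim(ctrl$counts)))
    stop("landscape specifications differ", call. = FALSE)
  lr <- log2(((obs$counts + pseudocount) / obs$n_sequences) /
               ((ctrl$counts + pseudocount) / ctrl$n_sequences))
  structure(list(counts = lr, n_sequences = obs$n_sequences, spec = obs$spec,
                 values = "log2_enrichment"),
            class = "dimer_landscape")
}

#' Sum landscapes across libraries
#'
#' Element-wise sum, the "all libraries" overview row of a landscape panel.
#'
#' @param landscapes list of `dimer_landscape`s with identical specs.
#' @return a `dimer_landscape`.
#' @export
sum_landscapes <- function(landscapes) {
  stopifnot(length(landscapes) >= 1L)
  counts <- Reduce(`+`, lapply(landscapes, `[[`, "counts"))
  structure(list(counts = counts,
                 n_sequences = sum(vapply(landscapes, `[[`, numeric(1), "n_sequences")),
                 spec = landscapes[[1]]$spec, values = landscapes[[1]]$values),
            class = "dimer_landscape")
}

#' Dimeric gapped 10-mer enrichment table
#'
#' Gapped 10-mers restricted to pairs of two identical or two
#' reverse-complement pentamers, with log frequencies in a library and its
#' control — the dimeric-CRE view of the gapped k-mer scatter.
#'
#' @param lib,ctrl [ligand_library()]s.
#' @param w half-width (default 5).
#' @param gaps gap widths (default 0..8).
#' @param pseudocount passed to [enrichment_scatter()].
#' @return data.frame: left, right, gap, relation
#'   ("identical"/"revcomp"), counts, log frequencies and log2 ratio,
#'   sorted by decreasing ratio.
#' @export
dimeric_tenmer_scatter <- function(lib, ctrl, w = 5L, gaps = 0:8, pseudocount = 1) {
  gap_spec <- list(w = as.integer(w), gap = as.integer(gaps))
  sc <- enrichment_scatter(count_kmers(lib, gap_spec = gap_spec),
                           count_kmers(ctrl, gap_spec = gap_spec),
                           pseudocount = pseudocount)
  parts <- data.table::tstrsplit(sc$kmer, ".", fixed = TRUE)
  left <- parts[[1]]; gap <- as.integer(parts[[2]]); right <- parts[[3]]
  ident <- right == left
  rcmp <- right == revcomp(left)
  keep <- ident | rcmp
  out <- cbind(data.frame(left = left[keep], right = right[keep], gap = gap[keep],
                          relation = ifelse(ident[keep], "identical", "revcomp"),
                          stringsAsFactors = FALSE),
               sc[keep, c("count_obs", "count_ctrl", "log_freq_obs",
                          "log_freq_ctrl", "log2_ratio"), drop = FALSE])
  rownames(out) <- NULL
  out
}
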