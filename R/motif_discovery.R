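## motif_discovery: locally maximal enriched k-mer seeds and multinomial
## PFM construction, with information content summaries.
##
## A seed is a k-mer (k = 8..10, both strands pooled under the
## lexicographically smaller of k-mer/revcomp) whose count strictly exceeds
## every neighbour's count and reaches the local-max count cutoff (40 by
## default). The neighbourhood is all Hamming-1 substitutions plus
## single-base left/right shifts — a documented simplification of the
## Huddinge-distance neighbourhood used by the original autoseed.
## Multinomial-1 counting builds PFM column j from read windows that match
## the seed at every position except j.

#' Discovery configuration
#'
#' @param multinomial 0 (exact-match counting) or 1 (all-but-one column).
#' @param seed_lengths k-mer lengths scanned for seeds.
#' @param local_max_cutoff minimum count for a local-max k-mer to be a seed.
#' @param flank_extension PFM columns added on each side of the seed,
#'   trimmed back while a terminal flank column has IC < 0.1 bits.
#' @param ppm_pseudocount count added per PPM cell.
#' @return an object of class `discovery_config`.
#' @export
discovery_config <- function(multinomial = 1L, seed_lengths = c(8L, 9L, 10L),
                             local_max_cutoff = 40L, flank_extension = 2L,
                             ppm_pseudocount = 1) {
  multinomial <- as.integer(multinomial)
  if (!multinomial %in% 0:1)
    stop("multinomial must be 0 or 1", call. = FALSE)
  if (local_max_cutoff < 1L) stop("local_max_cutoff must be >= 1", call. = FALSE)
  structure(list(multinomial = multinomial,
                 seed_lengths = as.integer(seed_lengths),
                 local_max_cutoff = as.integer(local_max_cutoff),
                 flank_extension = as.integer(flank_extension),
                 ppm_pseudocount = ppm_pseudocount),
            class = "discovery_config")
}

canonical_kmer <- function(x) pmin(x, revcomp(x))

## counts of canonical k-mers: occurrences of a k-mer and of its reverse
## complement pooled under the lexicographically smaller representative
## (scanning the given strand once counts each double-stranded site once)
canonical_kmer_counts <- function(reads, k) {
  keys <- sliding_windows(reads, k)
  keys <- keys[!grepl("N", keys, fixed = TRUE)]
  dt <- data.table::data.table(word = keys)
  agg <- dt[, .N, by = "word"]
  agg[, canon := canonical_kmer(word)]
  agg2 <- agg[, list(N = sum(N)), by = "canon"]
  stats::setNames(agg2$N, agg2$canon)
}

substitution_neighbors <- function(kmers, j, base) {
  k <- nchar(kmers[1])
  paste0(substr(kmers, 1L, j - 1L), base, substr(kmers, j + 1L, k))
}

#' Find locally maximal enriched k-mer seeds
#'
#' @param lib a core-extracted, deduplicated [ligand_library()].
#' @param config a [discovery_config()].
#' @return data.frame of seed candidates (kmer, k, count, is_local_max),
#'   sorted by count descending; only local maxima at or above the cutoff
#'   are returned. Ties with a neighbour disqualify both.
#' @export
find_local_max_seeds <- function(lib, config = discovery_config()) {
  reads <- if (inherits(lib, "ligand_library")) lib$reads else as.character(lib)
  if (length(reads) == 0L)
    return(data.frame(kmer = character(0), k = integer(0), count = integer(0),
                      is_local_max = logical(0)))
  out <- list()
  for (k in config$seed_lengths) {
    counts <- canonical_kmer_counts(reads, k)
    cand <- names(counts)[counts >= config$local_max_cutoff]
    if (length(cand) == 0L) next
    ccount <- counts[cand]
    nmax <- numeric(length(cand))
    lookup <- function(kmers) {
      v <- counts[canonical_kmer(kmers)]
      v[is.na(v)] <- 0
      unname(v)
    }
    for (j in seq_len(k)) {
      orig <- substr(cand, j, j)
      for (b in DNA_BASES) {
        nb <- substitution_neighbors(cand, j, b)
        cnt <- lookup(nb)
        cnt[orig == b] <- 0  # self, not a neighbour
        nmax <- pmax(nmax, cnt)
      }
    }
    for (b in DNA_BASES) {
      nmax <- pmax(nmax, lookup(paste0(substr(cand, 2L, k), b)))      # left shift
      nmax <- pmax(nmax, lookup(paste0(b, substr(cand, 1L, k - 1L)))) # right shift
    }
    is_max <- ccount > nmax
    if (any(is_max))
      out[[length(out) + 1L]] <- data.frame(kmer = cand[is_max], k = k,
                                            count = as.integer(ccount[is_max]),
                                            is_local_max = TRUE,
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(kmer = character(0), k = integer(0), count = integer(0),
                      is_local_max = logical(0)))
  res <- do.call(rbind, out)
  res <- res[order(-res$count, res$kmer), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Shannon information content of a motif column
#'
#' `sum(p * log2(p / 0.25))` over A, C, G, T with the 0*log0 := 0
#' convention; 0.25 is the uniform background. Range 0..2 bits.
#'
#' @param column numeric vector of 4 probabilities summing to 1.
#' @return bits.
#' @export
information_content <- function(column) {
  if (any(column < 0)) stop("negative probability", call. = FALSE)
  if (abs(sum(column) - 1) > 1e-6) stop("column does not sum to 1", call. = FALSE)
  nz <- column > 0
  sum(column[nz] * log2(column[nz] / 0.25))
}

#' Consensus and information-content summary of a motif matrix
#'
#' @param pfm optional 4 x L count matrix (rows A,C,G,T).
#' @param ppm 4 x L probability matrix (columns sum to 1).
#' @return list with consensus (argmax base per column; ties resolved in
#'   A,C,G,T order), ic_per_column, total_ic and per_base_ic.
#' @export
motif_summary <- function(pfm = NULL, ppm) {
  stopifnot(nrow(ppm) == 4L)
  ic <- apply(ppm, 2, information_content)
  cons <- paste(DNA_BASES[apply(ppm, 2, which.max)], collapse = "")
  list(consensus = cons, ic_per_column = unname(ic),
       total_ic = sum(ic), per_base_ic = sum(ic) / ncol(ppm))
}

new_motif_model <- function(pfm, ppm, seed = NULL, id = NULL, name = NULL,
                            provenance = NULL) {
  rownames(pfm) <- rownames(ppm) <- DNA_BASES
  s <- motif_summary(pfm, ppm)
  structure(list(id = id %||% (seed$kmer %||% "motif"),
                 name = name %||% id %||% (seed$kmer %||% "motif"),
                 pfm = pfm, ppm = ppm, seed = seed,
                 consensus = s$consensus, ic_per_column = s$ic_per_column,
                 total_ic = s$total_ic, per_base_ic = s$per_base_ic,
                 provenance = provenance),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s': %d columns, consensus %s, total IC %.2f bits (%.2f/bp)\n",
              x$name, ncol(x$ppm), x$consensus, x$total_ic, x$per_base_ic))
  invisible(x)
}

#' Build a motif model from a seed by multinomial counting
#'
#' For each seed column j, base frequencies are counted over read windows
#' (both strands) that match the seed at all positions except j
#' (multinomial-1; exact match everywhere for multinomial-0). Flank columns
#' (`flank_extension` per side) are counted from windows matching the full
#' seed, then trimmed back while a terminal flank column has IC < 0.1 bits.
#'
#' @param lib a [ligand_library()].
#' @param seed a seed k-mer string, or one row of [find_local_max_seeds()]
#'   output.
#' @param config a [discovery_config()].
#' @return a `motif_model`.
#' @export
build_pfm_multinomial <- function(lib, seed, config = discovery_config()) {
  reads <- if (inherits(lib, "ligand_library")) lib$reads else as.character(lib)
  seed_count <- NA_integer_
  if (is.data.frame(seed)) { seed_count <- seed$count[1]; seed <- seed$kmer[1] }
  stop_if_not_dna(seed, "seed")
  k <- nchar(seed)
  ext <- config$flank_extension
  L <- nchar(reads[1])
  if (k > L) stop("seed longer than reads", call. = FALSE)

  both <- c(reads, revcomp(reads))
  m <- base_code_matrix(both)           # NA at N positions
  scode <- base_code_matrix(seed)[1, ]
  n2 <- nrow(m)
  offsets <- seq_len(L - k + 1L)

  pfm_seed <- matrix(0L, 4L, k)
  pfm_left <- matrix(0L, 4L, ext)
  pfm_right <- matrix(0L, 4L, ext)
  n_windows_used <- 0L

  for (o in offsets) {
    d <- matrix(FALSE, n2, k)
    for (j in seq_len(k)) {
      cmp <- m[, o + j - 1L] != scode[j]
      cmp[is.na(cmp)] <- TRUE            # N never matches
      d[, j] <- cmp
    }
    mm <- rowSums(d)
    exact <- which(mm == 0L)
    if (length(exact)) {
      n_windows_used <- n_windows_used + length(exact)
      pfm_seed[cbind(scode, seq_len(k))] <-
        pfm_seed[cbind(scode, seq_len(k))] + length(exact)
      if (ext > 0L) {
        for (f in seq_len(ext)) {
          lp <- o - f
          if (lp >= 1L) {
            b <- m[exact, lp]
            tb <- tabulate(b[!is.na(b)], 4L)
            pfm_left[, ext - f + 1L] <- pfm_left[, ext - f + 1L] + tb
          }
          rp <- o + k - 1L + f
          if (rp <= L) {
            b <- m[exact, rp]
            tb <- tabulate(b[!is.na(b)], 4L)
            pfm_right[, f] <- pfm_right[, f] + tb
          }
        }
      }
    }
    if (config$multinomial >= 1L) {
      one <- which(mm == 1L)
      if (length(one)) {
        n_windows_used <- n_windows_used + length(one)
        for (j in seq_len(k)) {
          sel <- one[d[one, j]]
          if (length(sel)) {
            b <- m[sel, o + j - 1L]
            pfm_seed[, j] <- pfm_seed[, j] + tabulate(b[!is.na(b)], 4L)
          }
        }
      }
    }
  }
  if (sum(pfm_seed) == 0L)
    stop(sprintf("no window matches seed '%s'", seed), call. = FALSE)

  pfm <- cbind(pfm_left, pfm_seed, pfm_right)
  is_flank <- c(rep(TRUE, ext), rep(FALSE, k), rep(TRUE, ext))
  ## drop flank columns with no observations (window ran off the read end)
  keep <- colSums(pfm) > 0L | !is_flank
  pfm <- pfm[, keep, drop = FALSE]; is_flank <- is_flank[keep]

  ppm <- sweep(pfm + config$ppm_pseudocount, 2,
               colSums(pfm + config$ppm_pseudocount), "/")
  ic <- apply(ppm, 2, information_content)
  while (ncol(ppm) > k && is_flank[1] && ic[1] < 0.1) {
    pfm <- pfm[, -1, drop = FALSE]; ppm <- ppm[, -1, drop = FALSE]
    ic <- ic[-1]; is_flank <- is_flank[-1]
  }
  while (ncol(ppm) > k && is_flank[length(is_flank)] && ic[length(ic)] < 0.1) {
    nc <- ncol(ppm)
    pfm <- pfm[, -nc, drop = FALSE]; ppm <- ppm[, -nc, drop = FALSE]
    ic <- ic[-nc]; is_flank <- is_flank[-nc]
  }

  prov <- if (inherits(lib, "ligand_library"))
    list(sample = lib$sample_name, round = lib$round) else NULL
  new_motif_model(pfm, ppm,
                  seed = list(kmer = seed, count = seed_count),
                  id = seed, provenance = prov)
}

#' Discover motif models from a library
#'
#' Convenience wrapper: find local-max seeds, build a multinomial PFM for
#' each (up to `max_seeds`, in count order).
#'
#' @param lib a [ligand_library()].
#' @param config a [discovery_config()].
#' @param max_seeds maximum number of seeds expanded into models.
#' @return list of `motif_model`s.
#' @export
discover_motifs <- function(lib, config = discovery_config(), max_seeds = 10L) {
  seeds <- find_local_max_seeds(lib, config)
  seeds <- utils::head(seeds, max_seeds)
  lapply(seq_len(nrow(seeds)), function(i)
    build_pfm_multinomial(lib, seeds[i, , drop = FALSE], config))
}
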