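## kmer_stats: continuous and gapped k-mer counting, enrichment against
## shuffled controls, and the gapped-10-mer rank matrix for library
## comparison.

new_kmer_table <- function(counts, k, gap_spec = NULL, n_reads = NA_integer_) {
  structure(list(k = as.integer(k), gap_spec = gap_spec,
                 counts = counts, total = sum(counts),
                 n_reads = as.integer(n_reads)),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  gs <- if (is.null(x$gap_spec)) "" else
    sprintf(" (gapped: w=%d, gap=%s)", x$gap_spec$w, paste(x$gap_spec$gap, collapse = ","))
  cat(sprintf("kmer_table k=%d%s: %d distinct keys, %d windows counted\n",
              x$k, gs, length(x$counts), x$total))
  invisible(x)
}

tabulate_keys <- function(keys) {
  dt <- data.table::data.table(word = keys)
  agg <- dt[, .N, by = "word"]
  data.table::setorder(agg, "word")
  stats::setNames(agg$N, agg$word)
}

gapped_window_keys <- function(reads, w, gap) {
  L <- nchar(reads[1])
  span <- 2L * w + gap
  if (span > L) stop(sprintf("window span %d exceeds read length %d", span, L), call. = FALSE)
  starts <- seq_len(L - span + 1L)
  unlist(lapply(starts, function(s) {
    left <- substr(reads, s, s + w - 1L)
    right <- substr(reads, s + w + gap, s + w + gap + w - 1L)
    paste0(left, ".", gap, ".", right)
  }), use.names = FALSE)
}

#' Count continuous or gapped k-mers in a library
#'
#' Every window position of every read is counted once per requested strand;
#' windows containing N are skipped. Gapped windows are keyed as
#' `"LEFT.gap.RIGHT"`. Ligand libraries are orientation-fixed, so the
#' default counts the sequenced strand only; `strands = "both"` additionally
#' counts the reverse complement of every read (for genomic inputs).
#'
#' @param lib a [ligand_library()] (or character vector of sequences).
#' @param k word length for continuous counting.
#' @param gap_spec `NULL`, or `list(w =, gap =)` for two `w`-mers separated
#'   by `gap` bases; `gap` may be a vector, in which case all gaps are
#'   pooled into one table (keys carry the gap).
#' @param strands `"given"` or `"both"`.
#' @return a `kmer_table`.
#' @export
count_kmers <- function(lib, k = 8L, gap_spec = NULL, strands = c("given", "both")) {
  strands <- match.arg(strands)
  reads <- if (inherits(lib, "ligand_library")) lib$reads else as.character(lib)
  if (length(reads) == 0L) return(new_kmer_table(integer(0), k, gap_spec, 0L))
  if (length(unique(nchar(reads))) != 1L)
    stop("count_kmers requires uniform read length", call. = FALSE)
  if (strands == "both") reads <- c(reads, revcomp(reads))
  if (is.null(gap_spec)) {
    keys <- sliding_windows(reads, k)
  } else {
    stopifnot(is.numeric(gap_spec$w), is.numeric(gap_spec$gap))
    keys <- unlist(lapply(gap_spec$gap, function(g)
      gapped_window_keys(reads, as.integer(gap_spec$w), as.integer(g))),
      use.names = FALSE)
    k <- 2L * as.integer(gap_spec$w)
  }
  keys <- keys[!grepl("N", keys, fixed = TRUE)]
  new_kmer_table(tabulate_keys(keys), k, gap_spec, length(reads))
}

check_same_spec <- function(a, b) {
  same_gap <- (is.null(a$gap_spec) && is.null(b$gap_spec)) ||
    (!is.null(a$gap_spec) && !is.null(b$gap_spec) &&
       a$gap_spec$w == b$gap_spec$w && identical(a$gap_spec$gap, b$gap_spec$gap))
  if (a$k != b$k || !same_gap)
    stop("k-mer tables have mismatched k/gap specifications", call. = FALSE)
}

#' Observed-versus-control k-mer enrichment table
#'
#' For every key present in either table, computes log2 frequencies with a
#' shared pseudocount: `log2((count + pc) / (total + pc * n_keys))`, where
#' `n_keys` is the size of the key union, plus their difference
#' (`log2_ratio`).
#'
#' @param obs,ctrl `kmer_table`s with identical specifications.
#' @param pseudocount added to every count.
#' @return a data.frame with columns kmer, count_obs, count_ctrl,
#'   log_freq_obs, log_freq_ctrl, log2_ratio, sorted by decreasing ratio.
#' @export
enrichment_scatter <- function(obs, ctrl, pseudocount = 1) {
  stopifnot(inherits(obs, "kmer_table"), inherits(ctrl, "kmer_table"))
  check_same_spec(obs, ctrl)
  keys <- sort(union(names(obs$counts), names(ctrl$counts)))
  co <- obs$counts[keys]; co[is.na(co)] <- 0L
  cc <- ctrl$counts[keys]; cc[is.na(cc)] <- 0L
  nk <- length(keys)
  lo <- log2((co + pseudocount) / (obs$total + pseudocount * nk))
  lc <- log2((cc + pseudocount) / (ctrl$total + pseudocount * nk))
  out <- data.frame(kmer = keys, count_obs = as.integer(co),
                    count_ctrl = as.integer(cc),
                    log_freq_obs = unname(lo), log_freq_ctrl = unname(lc),
                    log2_ratio = unname(lo - lc),
                    stringsAsFactors = FALSE)
  out[order(-out$log2_ratio, out$kmer), , drop = FALSE]
}

#' Gapped 10-mer rank matrix across libraries, with principal components
#'
#' For each library, gapped 10-mers (two `w`-mers with `gaps` intervening
#' bases) are scored by enrichment against that library's own
#' mononucleotide-shuffled control. Each library contributes its `top_n`
#' 10-mers; the union of these is the feature set, and each library's row
#' holds the rank (1 = most enriched) of every feature under that library's
#' enrichment, ties broken lexicographically. Features effectively absent
#' from a library fall to the worst ranks through their pseudocount-backed
#' enrichment.
#'
#' @param libs list of [ligand_library()] objects (>= 2).
#' @param w half-width of the gapped word.
#' @param gaps integer vector of gap widths.
#' @param top_n features contributed per library.
#' @param seed RNG seed used to build shuffled controls (one child stream
#'   per library).
#' @param controls optional list of pre-built control libraries.
#' @return list with `ranks` (libraries x features matrix), `pca`
#'   (the `prcomp` fit on the rank matrix) and `coords` (library
#'   coordinates on the principal components).
#' @export
rank_feature_matrix <- function(libs, w = 5L, gaps = 0:8, top_n = 10000L,
                                seed = NULL, controls = NULL) {
  if (length(libs) < 2L) stop("need at least two libraries", call. = FALSE)
  if (is.null(controls))
    controls <- lapply(seq_along(libs), function(i)
      shuffle_control(libs[[i]], seed = child_seed(seed, i)))
  gap_spec <- list(w = as.integer(w), gap = as.integer(gaps))
  per_lib <- lapply(seq_along(libs), function(i) {
    sc <- enrichment_scatter(count_kmers(libs[[i]], gap_spec = gap_spec),
                             count_kmers(controls[[i]], gap_spec = gap_spec))
    sc
  })
  chosen <- lapply(per_lib, function(sc) {
    if (nrow(sc) < top_n)
      warning(sprintf("only %d distinct gapped words available (< top_n = %d); using all",
                      nrow(sc), top_n))
    utils::head(sc$kmer, top_n)
  })
  features <- sort(Reduce(union, chosen))
  ranks <- t(vapply(per_lib, function(sc) {
    ratio <- stats::setNames(sc$log2_ratio, sc$kmer)[features]
    nk_union <- nrow(sc)  # pseudocount scale already applied in scatter
    ratio[is.na(ratio)] <- -Inf  # never counted in either table: worst
    ord <- order(-ratio, features)
    r <- integer(length(features)); r[ord] <- seq_along(features)
    r
  }, integer(length(features))))
  rownames(ranks) <- vapply(libs, function(l) l$sample_name, character(1))
  colnames(ranks) <- features
  pca <- stats::prcomp(ranks, center = TRUE, scale. = FALSE)
  list(ranks = ranks, pca = pca, coords = pca$x)
}
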