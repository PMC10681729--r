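## cistrome_context: footprint depth with control subtraction,
## footprint-accessibility correlation and positive/negative model
## classification, bound/unbound site splitting, TPM, and the bound-CRE
## dose-response against expression.
##
## This module consumes already bias-corrected (or synthetic) per-base cut
## tracks; Tn5 sequence-bias correction itself is outside its boundary.

#' Transcripts per million
#'
#' `TPM_g = 1e6 * (c_g / l_g) / sum(c / l)`; sums to 1e6 over genes.
#'
#' @param read_counts named (or plain) numeric vector of read counts.
#' @param gene_lengths gene lengths in bp, same order.
#' @return data.frame (class `expression_table`): gene_id, count, length,
#'   tpm.
#' @export
tpm <- function(read_counts, gene_lengths) {
  stopifnot(length(read_counts) == length(gene_lengths))
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (any(read_counts < 0)) stop("negative read counts", call. = FALSE)
  if (all(read_counts == 0)) stop("all-zero read counts", call. = FALSE)
  rate <- read_counts / gene_lengths
  ids <- names(read_counts) %||% paste0("gene", seq_along(read_counts))
  out <- data.frame(gene_id = ids, count = as.numeric(read_counts),
                    length = as.numeric(gene_lengths),
                    tpm = 1e6 * rate / sum(rate), stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

## a cut track is a list of per-base numeric vectors, one per sequence
as_cut_track <- function(x, seqlengths = NULL) {
  if (is.list(x) && !inherits(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1L)
    x <- rtracklayer::import(x, format = "bedGraph")
  stopifnot(inherits(x, "GRanges"))
  seqs <- unique(as.character(GenomicRanges::seqnames(x)))
  out <- lapply(seqs, function(s) {
    g <- x[as.character(GenomicRanges::seqnames(x)) == s]
    len <- seqlengths[[s]] %||% max(GenomicRanges::end(g))
    v <- numeric(len)
    st <- GenomicRanges::start(g); en <- GenomicRanges::end(g)
    for (i in seq_along(g)) v[st[i]:en[i]] <- g$score[i]
    v
  })
  stats::setNames(out, seqs)
}

#' Aggregate per-base cut counts around CRE sites
#'
#' Extracts a `window`-wide slice of the cut track centered on each hit
#' midpoint; minus-strand hits are flipped so motif orientation aligns
#' across rows. Sites whose window runs off the sequence are dropped and
#' counted.
#'
#' @param cut_track bedGraph path, `GRanges` with a score column, or a
#'   named list of per-base numeric vectors.
#' @param hits data.frame from [scan_sequences()].
#' @param window odd window width (default 121 bp).
#' @param seqlengths optional named sequence lengths (for track expansion).
#' @return object of class `cut_profile`: `mat` (sites x positions),
#'   `site_ids`, `window`, `n_dropped`.
#' @export
aggregate_profile <- function(cut_track, hits, window = 121L, seqlengths = NULL) {
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  track <- as_cut_track(cut_track, seqlengths)
  half <- (window - 1L) %/% 2L
  mid <- hit_midpoints(hits) + 1L  # 1-based
  rows <- vector("list", nrow(hits))
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    v <- track[[hits$seqname[i]]]
    if (is.null(v)) next
    lo <- mid[i] - half; hi <- mid[i] + half
    if (lo < 1L || hi > length(v)) next
    slice <- v[lo:hi]
    if (identical(hits$strand[i], "-")) slice <- rev(slice)
    rows[[i]] <- slice
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no hit window lies within the cut track", call. = FALSE)
  mat <- do.call(rbind, rows[keep])
  structure(list(mat = mat,
                 site_ids = sprintf("%s:%d-%d(%s)", hits$seqname[keep],
                                    hits$start[keep], hits$end[keep],
                                    hits$strand[keep]),
                 window = as.integer(window), n_dropped = sum(!keep)),
            class = "cut_profile")
}

#' @export
print.cut_profile <- function(x, ...) {
  cat(sprintf("cut_profile: %d sites x %d bp (dropped %d edge sites)\n",
              nrow(x$mat), x$window, x$n_dropped))
  invisible(x)
}

profile_depth_cols <- function(window, core_width, flank_width) {
  if (core_width + 2L * flank_width > window)
    stop("core_width + 2*flank_width exceeds the window", call. = FALSE)
  center <- (window + 1L) %/% 2L
  half_core <- core_width %/% 2L
  core <- (center - half_core):(center - half_core + core_width - 1L)
  flank <- c((core[1] - flank_width):(core[1] - 1L),
             (core[length(core)] + 1L):(core[length(core)] + flank_width))
  list(core = core, flank = flank)
}

#' Footprint depth of an aggregated cut profile
#'
#' Depth = mean cut frequency in the flanking regions minus the mean in
#' the (centered) footprint core, minus the same quantity computed on a
#' protein-free control profile. Positive depth indicates protection of
#' the core, i.e. TF occupancy.
#'
#' @param profile a `cut_profile`.
#' @param core_width footprint core width (typically the motif length).
#' @param flank_width flank width on each side (default 25 bp).
#' @param control_profile a `cut_profile` from the control library, same
#'   window; `NULL` for no subtraction.
#' @return object of class `footprint_result`: `depth`, `per_site`,
#'   `control_depth`, `core_width`, `flank_width`.
#' @export
footprint_depth <- function(profile, core_width, flank_width = 25L,
                            control_profile = NULL) {
  stopifnot(inherits(profile, "cut_profile"))
  cols <- profile_depth_cols(profile$window, core_width, flank_width)
  per_site <- unname(rowMeans(profile$mat[, cols$flank, drop = FALSE]) -
                       rowMeans(profile$mat[, cols$core, drop = FALSE]))
  ctrl <- 0
  if (!is.null(control_profile)) {
    stopifnot(inherits(control_profile, "cut_profile"))
    if (control_profile$window != profile$window)
      stop("control window width differs", call. = FALSE)
    ctrl <- mean(rowMeans(control_profile$mat[, cols$flank, drop = FALSE]) -
                   rowMeans(control_profile$mat[, cols$core, drop = FALSE]))
  }
  structure(list(depth = mean(per_site) - ctrl, per_site = per_site,
                 control_depth = ctrl, core_width = as.integer(core_width),
                 flank_width = as.integer(flank_width)),
            class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf("footprint_result: depth %.4f cuts/bp over %d sites (control %.4f)\n",
              x$depth, length(x$per_site), x$control_depth))
  invisible(x)
}

#' Classify motifs by footprint-accessibility correlation
#'
#' For each motif, the Pearson correlation across samples between its
#' footprint depths and its open-chromatin enrichment ratios. Motifs with
#' r > `pos` are `positive` models (occupancy tracks openness), r < `neg`
#' `negative`, the rest `unclassified`. Zero-variance inputs yield an NA
#' correlation and `unclassified`, with a warning.
#'
#' @param depths,ths_ratios motif x sample matrices (>= 3 samples).
#' @param pos,neg classification thresholds.
#' @return data.frame: motif, r, category.
#' @export
accessibility_classify <- function(depths, ths_ratios, pos = 0.5, neg = -0.5) {
  stopifnot(identical(dim(depths), dim(ths_ratios)), ncol(depths) >= 3L)
  r <- vapply(seq_len(nrow(depths)), function(i) {
    x <- depths[i, ]; y <- ths_ratios[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }, numeric(1))
  if (anyNA(r)) warning("zero-variance rows: correlation undefined, left unclassified")
  category <- ifelse(is.na(r), "unclassified",
                     ifelse(r > pos, "positive",
                            ifelse(r < neg, "negative", "unclassified")))
  data.frame(motif = rownames(depths) %||% paste0("motif", seq_len(nrow(depths))),
             r = r, category = category, stringsAsFactors = FALSE)
}

#' Label-permuted null for the accessibility correlation
#'
#' Recomputes per-motif correlations after permuting the sample labels of
#' the accessibility matrix; the pooled r distribution is the reordered
#' null (unimodal near 0 when no real coupling exists).
#'
#' @param depths,ths_ratios motif x sample matrices.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return numeric vector of null correlations (n_perm x n motifs).
#' @export
accessibility_null <- function(depths, ths_ratios, n_perm = 100L, seed = NULL) {
  with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(p) {
      perm <- sample.int(ncol(ths_ratios))
      vapply(seq_len(nrow(depths)), function(i) {
        x <- depths[i, ]; y <- ths_ratios[i, perm]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
      }, numeric(1))
    }))
  })
}

#' Split CRE sites into bound and unbound
#'
#' A site is bound iff its footprint depth exceeds the control mean by
#' more than `k` control standard deviations.
#'
#' @param per_site_depths numeric vector of site depths (sample library).
#' @param control_depths site depths from the protein-free control
#'   (>= 10 sites).
#' @param k SD multiplier (default 1).
#' @return list: `labels` ("bound"/"unbound"), `threshold`,
#'   `fraction_bound`.
#' @export
split_bound_unbound <- function(per_site_depths, control_depths, k = 1) {
  if (length(control_depths) < 10L)
    stop("need >= 10 control sites to estimate the bound threshold", call. = FALSE)
  thr <- mean(control_depths) + k * stats::sd(control_depths)
  labels <- ifelse(per_site_depths > thr, "bound", "unbound")
  list(labels = labels, threshold = thr,
       fraction_bound = mean(labels == "bound"))
}

promoter_cre_counts <- function(hits, genes, promoter_window) {
  mid <- hit_midpoints(hits) + 1L
  vapply(seq_len(nrow(genes)), function(gi) {
    g <- genes[gi, ]
    if (g$strand == "+") {
      sum(hits$seqname == g$seqname & mid >= g$tss - promoter_window & mid < g$tss)
    } else {
      sum(hits$seqname == g$seqname & mid > g$tss & mid <= g$tss + promoter_window)
    }
  }, numeric(1))
}

#' Median expression by bound-CRE count class
#'
#' Genes are grouped by the number of bound CREs in their promoter
#' (default 1 kb upstream of the TSS, strand-aware) into classes 0, 1, 2,
#' ">=3", and the median TPM of each class is reported.
#'
#' @param bound_hits data.frame of bound CRE hits (as from
#'   [scan_sequences()], filtered to bound sites).
#' @param genes gene table.
#' @param expression expression table from [tpm()] or named TPM vector.
#' @param promoter_window promoter width upstream of the TSS (bp).
#' @return data.frame: cre_class, n_genes, median_tpm.
#' @export
cre_dose_response <- function(bound_hits, genes, expression,
                              promoter_window = 1000L) {
  tpmv <- tpm_vector(expression)[genes$gene_id]
  ncre <- promoter_cre_counts(bound_hits, genes, promoter_window)
  cls <- ifelse(ncre >= 3, ">=3", as.character(ncre))
  lev <- c("0", "1", "2", ">=3")
  lev <- lev[lev %in% cls]
  data.frame(cre_class = lev,
             n_genes = vapply(lev, function(l) sum(cls == l), numeric(1)),
             median_tpm = vapply(lev, function(l) stats::median(tpmv[cls == l]),
                                 numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
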