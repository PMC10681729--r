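## genome_scan: log-odds PWMs with exact p-value score thresholds
## (dynamic-programming convolution over integer-scaled scores), sequence
## scanning, and accessibility / gene-context enrichments.
##
## Coordinates: hits are reported 0-based half-open (BED convention);
## GFF3 gene input (1-based inclusive) is converted on read.

#' Log-odds PWM with an exact p-value score threshold
#'
#' Scores are `log2(ppm / background)`, scaled to integers
#' (`floor(score * score_scale)`; flooring makes the threshold
#' conservative). The exact null score distribution under `background` is
#' computed by dynamic-programming convolution over columns, and the
#' threshold is the smallest score t with `P(score >= t) <= pvalue`.
#'
#' @param ppm 4 x L probability matrix (rows A,C,G,T). `motif_model`s are
#'   accepted.
#' @param background base probabilities (default uniform).
#' @param pvalue match p-value (0 < pvalue <= 1).
#' @param score_scale integer units per bit.
#' @return object of class `pwm_model`: `log_odds`, `int_scores`,
#'   `background`, `threshold_int`, `threshold` (bits), `pvalue`,
#'   `score_scale`, `motif_id`, `width`.
#' @export
pwm_threshold <- function(ppm, background = rep(0.25, 4), pvalue = 1e-4,
                          score_scale = 1000L) {
  motif_id <- NULL
  if (inherits(ppm, "motif_model")) { motif_id <- ppm$id; ppm <- ppm$ppm }
  stopifnot(nrow(ppm) == 4L, pvalue > 0, pvalue <= 1)
  if (any(background <= 0)) stop("degenerate background", call. = FALSE)
  background <- background / sum(background)
  if (any(ppm <= 0))
    stop("ppm contains zeros; apply a pseudocount before log-odds", call. = FALSE)
  log_odds <- log2(ppm / background)
  S <- matrix(as.integer(floor(log_odds * score_scale)), nrow = 4L)
  L <- ncol(S)

  ## DP over the exact null score distribution
  lo <- cumsum(apply(S, 2, min)); hi <- cumsum(apply(S, 2, max))
  dist <- 1
  base <- 0L  # dist[i] = P(score == base + i - 1)
  for (j in seq_len(L)) {
    cl <- min(S[, j]); ch <- max(S[, j])
    new <- numeric(length(dist) + ch - cl)
    for (b in 1:4) {
      off <- S[b, j] - cl
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + background[b] * dist
    }
    dist <- new
    base <- base + cl
  }
  tail_p <- rev(cumsum(rev(dist)))
  ## smallest ACHIEVABLE score t with P(score >= t) <= pvalue
  ok <- which(tail_p <= pvalue + 1e-15 & dist > 0)
  threshold_int <- if (length(ok)) base + ok[1] - 1L else base + length(dist)  # unattainable
  structure(list(log_odds = log_odds, int_scores = S, background = background,
                 threshold_int = as.integer(threshold_int),
                 threshold = threshold_int / score_scale,
                 pvalue = pvalue, score_scale = as.integer(score_scale),
                 motif_id = motif_id, width = L),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("pwm_model%s: width %d, threshold %.3f bits at p <= %g\n",
              if (is.null(x$motif_id)) "" else paste0(" '", x$motif_id, "'"),
              x$width, x$threshold, x$pvalue))
  invisible(x)
}

## integer window scores along one sequence (NA where a window contains N)
scan_scores_int <- function(codes, S) {
  L <- ncol(S); M <- length(codes)
  if (M < L) return(integer(0))
  n <- M - L + 1L
  sc <- S[codes[seq_len(n)], 1L]
  if (L > 1L) for (j in 2:L) sc <- sc + S[codes[j:(n + j - 1L)], j]
  sc
}

as_named_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*", "", names(x))
    return(out)
  }
  x <- as.character(x)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  x
}

#' Scan sequences for PWM hits above a threshold
#'
#' Both strands are scanned; every window scoring at or above the
#' threshold is reported (overlapping hits allowed; a palindromic site can
#' yield one hit per strand). Coordinates are 0-based half-open on the
#' forward strand.
#'
#' @param seqs FASTA path, `DNAStringSet`, or (named) character vector.
#' @param pwm a `pwm_model` from [pwm_threshold()].
#' @param threshold integer-scaled score threshold; defaults to the
#'   model's exact p-value threshold.
#' @return data.frame (seqname, start, end, strand, score in bits),
#'   ordered by (seqname, start, strand).
#' @export
scan_sequences <- function(seqs, pwm, threshold = NULL) {
  stopifnot(inherits(pwm, "pwm_model"))
  threshold <- as.integer(threshold %||% pwm$threshold_int)
  seqs <- as_named_sequences(seqs)
  stop_if_not_dna(seqs, "sequences", allow_n = TRUE)
  S <- pwm$int_scores; L <- pwm$width
  res <- vector("list", 2L * length(seqs))
  k <- 0L
  for (i in seq_along(seqs)) {
    M <- nchar(seqs[i])
    if (M < L) next
    codes <- base_code_matrix(seqs[i])[1, ]
    fwd <- scan_scores_int(codes, S)
    hit <- which(!is.na(fwd) & fwd >= threshold)
    if (length(hit)) {
      k <- k + 1L
      res[[k]] <- data.frame(seqname = names(seqs)[i], start = hit - 1L,
                             end = hit - 1L + L, strand = "+",
                             score = fwd[hit] / pwm$score_scale,
                             stringsAsFactors = FALSE)
    }
    rcodes <- rev(5L - codes)  # reverse complement in code space (NA safe)
    rev_sc <- scan_scores_int(rcodes, S)
    hit <- which(!is.na(rev_sc) & rev_sc >= threshold)
    if (length(hit)) {
      k <- k + 1L
      res[[k]] <- data.frame(seqname = names(seqs)[i],
                             start = M - (hit - 1L) - L,
                             end = M - (hit - 1L), strand = "-",
                             score = rev_sc[hit] / pwm$score_scale,
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res[seq_len(k)])
  out <- out[order(out$seqname, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## total number of PWM matches (both strands) in uniform-length reads
count_pwm_matches <- function(reads, pwm, threshold = NULL) {
  if (length(reads) == 0L) return(0L)
  threshold <- as.integer(threshold %||% pwm$threshold_int)
  S <- pwm$int_scores; L <- pwm$width
  both <- c(reads, revcomp(reads))
  m <- base_code_matrix(both)
  if (ncol(m) < L) return(0L)
  total <- 0L
  for (o in seq_len(ncol(m) - L + 1L)) {
    sc <- S[m[, o], 1L]
    if (L > 1L) for (j in 2:L) sc <- sc + S[m[, o + j - 1L], j]
    total <- total + sum(!is.na(sc) & sc >= threshold)
  }
  total
}

#' Write hits as BED
#' @param hits data.frame from [scan_sequences()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  bed <- data.frame(hits$seqname, hits$start, hits$end,
                    name = ".", score = round(hits$score * 100),
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED interval file as a peak set
#'
#' Overlapping intervals are merged on load.
#'
#' @param path BED file path.
#' @return a `GRanges` of merged peaks.
#' @export
read_peaks <- function(path) {
  GenomicRanges::reduce(rtracklayer::import(path, format = "BED"))
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene` records; converts to the internal table with strand-aware
#' TSS/TTS (1-based genomic coordinates).
#'
#' @param path GFF3 file path.
#' @return data.frame: gene_id, seqname, strand, start, end, tss, tts,
#'   length.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path, format = "GFF3")
  g <- g[g$type == "gene"]
  ids <- g$ID %||% g$gene_id
  if (is.null(ids)) ids <- paste0("gene", seq_along(g))
  gene_table(ids, as.character(GenomicRanges::seqnames(g)),
             as.character(GenomicRanges::strand(g)),
             GenomicRanges::start(g), GenomicRanges::end(g))
}

#' Build a gene model table
#'
#' @param gene_id,seqname,strand,start,end vectors of equal length;
#'   `start`/`end` 1-based inclusive genomic coordinates.
#' @return data.frame with tss, tts (strand-aware) and length columns.
#' @export
gene_table <- function(gene_id, seqname, strand, start, end) {
  stopifnot(all(strand %in% c("+", "-")), all(end >= start))
  data.frame(gene_id = as.character(gene_id), seqname = as.character(seqname),
             strand = strand, start = as.integer(start), end = as.integer(end),
             tss = ifelse(strand == "+", start, end),
             tts = ifelse(strand == "+", end, start),
             length = as.integer(end - start + 1L),
             stringsAsFactors = FALSE)
}

hits_as_granges <- function(hits) {
  GenomicRanges::GRanges(hits$seqname,
                         IRanges::IRanges(hits$start + 1L, hits$end),
                         strand = hits$strand)
}

hit_midpoints <- function(hits) {
  ## 0-based midpoint position
  floor((hits$start + hits$end - 1L) / 2)
}

#' Motif-hit density ratio inside versus outside open chromatin
#'
#' `((hits_in + 1) / bp_in) / ((hits_out + 1) / bp_out)`, with hits
#' assigned by midpoint.
#'
#' @param hits data.frame from [scan_sequences()].
#' @param peaks `GRanges` of THS intervals (merged).
#' @param genome_length total genome size in bp.
#' @return the density ratio (numeric).
#' @export
ths_enrichment <- function(hits, peaks, genome_length) {
  bp_in <- sum(GenomicRanges::width(peaks))
  bp_out <- genome_length - bp_in
  if (bp_out <= 0) stop("peaks cover the whole genome", call. = FALSE)
  mid <- hit_midpoints(hits)
  mg <- GenomicRanges::GRanges(hits$seqname, IRanges::IRanges(mid + 1L, mid + 1L))
  n_in <- sum(IRanges::overlapsAny(mg, peaks))
  n_out <- nrow(hits) - n_in
  ((n_in + 1) / bp_in) / ((n_out + 1) / bp_out)
}

#' Metagene profile of motif-hit density
#'
#' Gene bodies are linearly rescaled to `body_length` (2 kb by default);
#' hit midpoints falling within `flank` bp of the TSS/TTS or inside the
#' body are mapped to bins over `[-flank, body_length + flank)`,
#' strand-aware (minus-strand genes flipped). A hit near several genes
#' contributes to each.
#'
#' @param hits data.frame from [scan_sequences()].
#' @param genes gene table from [gene_table()]/[read_gene_models()].
#' @param body_length normalized gene-body length (bp).
#' @param flank actual-scale flank on each side (bp).
#' @param bin bin width (bp).
#' @return list: `mids` (bin midpoints, 0 = TSS), `counts`, `density`
#'   (counts / n genes), `n_mapped`, `n_genes`.
#' @export
metagene_profile <- function(hits, genes, body_length = 2000L, flank = 1000L,
                             bin = 50L) {
  breaks <- seq(-flank, body_length + flank, by = bin)
  counts <- numeric(length(breaks) - 1L)
  mid <- hit_midpoints(hits)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    sel <- hits$seqname == g$seqname
    if (!any(sel)) next
    m0 <- mid[sel] + 1L  # 1-based genomic position
    rel <- if (g$strand == "+") m0 - g$start else g$end - m0
    glen <- g$length
    x <- ifelse(rel < 0, rel,
                ifelse(rel < glen, rel / glen * body_length,
                       rel - glen + body_length))
    x <- x[x >= -flank & x < body_length + flank]
    if (length(x))
      counts <- counts + tabulate(findInterval(x, breaks), length(counts))
  }
  list(mids = breaks[-length(breaks)] + bin / 2, counts = counts,
       density = counts / nrow(genes), n_mapped = sum(counts),
       n_genes = nrow(genes))
}

tpm_vector <- function(expression) {
  if (is.data.frame(expression)) stats::setNames(expression$tpm, expression$gene_id)
  else expression
}

hits_near_tss <- function(hits, genes, window) {
  mid <- hit_midpoints(hits) + 1L  # 1-based
  vapply(seq_len(nrow(genes)), function(gi) {
    g <- genes[gi, ]
    sum(hits$seqname == g$seqname & abs(mid - g$tss) <= window)
  }, numeric(1))
}

#' TSS-proximal hit enrichment in high- versus low-expression genes
#'
#' Hits within `window` bp of the TSS are counted for the top and bottom
#' expression quantiles (by TPM; ties broken by gene id) and compared as a
#' size-normalized pseudocounted ratio.
#'
#' @param hits data.frame from [scan_sequences()].
#' @param genes gene table.
#' @param expression expression table from [tpm()] or a named TPM vector
#'   covering the genes.
#' @param window half-width around the TSS (bp).
#' @param quantile fraction of genes in each tail (default 0.15).
#' @return list: `ratio`, `n_top`, `n_bottom`, `hits_top`, `hits_bottom`.
#' @export
tss_window_enrichment <- function(hits, genes, expression, window = 300L,
                                  quantile = 0.15) {
  tpmv <- tpm_vector(expression)[genes$gene_id]
  if (anyNA(tpmv)) stop("expression table does not cover all genes", call. = FALSE)
  n <- nrow(genes)
  n_sel <- max(1L, floor(quantile * n))
  if (2L * n_sel > n) stop("quantile sets overlap: too few genes", call. = FALSE)
  ord_hi <- order(-tpmv, genes$gene_id)
  ord_lo <- order(tpmv, genes$gene_id)
  top <- ord_hi[seq_len(n_sel)]
  bottom <- ord_lo[seq_len(n_sel)]
  per_gene <- hits_near_tss(hits, genes, window)
  ratio <- ((sum(per_gene[top]) + 1) / n_sel) / ((sum(per_gene[bottom]) + 1) / n_sel)
  list(ratio = ratio, n_top = n_sel, n_bottom = n_sel,
       hits_top = sum(per_gene[top]), hits_bottom = sum(per_gene[bottom]))
}
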