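# Fixture builders shared by the suite. Everything is generated in code;
# seeds are fixed where randomness is involved.

BASES <- c("A", "C", "G", "T")

rand_seqs <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}

## a PPM with the given consensus (base indices or string) and probability p
make_ppm <- function(consensus, p = 0.85) {
  if (is.character(consensus)) consensus <- match(strsplit(consensus, "")[[1]], BASES)
  L <- length(consensus)
  ppm <- matrix((1 - p) / 3, 4, L)
  ppm[cbind(consensus, seq_len(L))] <- p
  ppm
}

make_motif <- function(consensus, p = 0.85, n = 1000, id = NULL) {
  ppm <- make_ppm(consensus, p)
  pfm <- round(ppm * n)
  seaati:::new_motif_model(pfm, ppm, id = id %||% paste0("m_", paste(consensus, collapse = "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## plant `site` at fixed or random offsets into a fraction of reads
plant_site <- function(reads, site, fraction = 1, offset = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(reads)
  idx <- if (fraction >= 1) seq_len(n) else sample.int(n, round(fraction * n))
  L <- nchar(reads[1]); w <- nchar(site)
  for (i in idx) {
    o <- if (is.null(offset)) sample.int(L - w + 1L, 1L) else offset
    substr(reads[i], o, o + w - 1L) <- site
  }
  reads
}

## brute-force pointwise-MI oracle: naive double loop, independent of the
## vectorized implementation path
oracle_mi_contributions <- function(joint) {
  n <- sum(joint)
  P <- joint / n
  p1 <- rowSums(P); p2 <- colSums(P)
  out <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    if (P[i, j] > 0) out[i, j] <- P[i, j] * log2(P[i, j] / (p1[i] * p2[j]))
  }
  out
}

oracle_emi <- function(joint, top_n = 10) {
  v <- sort(as.vector(oracle_mi_contributions(joint)), decreasing = TRUE)
  sum(v[seq_len(top_n)])
}

oracle_dmi <- function(joint) {
  contrib <- oracle_mi_contributions(joint)
  trimers <- seaati:::TRIMER_NAMES
  rc <- match(as.character(revcomp(trimers)), trimers)
  s <- 0
  for (i in 1:64) s <- s + contrib[i, i] + contrib[i, rc[i]]
  s
}

random_joint <- function(seed) {
  set.seed(seed)
  matrix(rpois(4096, lambda = runif(1, 0.5, 30)), 64, 64)
}

## exhaustive PWM-threshold oracle: score all 4^L sequences
oracle_pwm_threshold <- function(int_scores, background, pvalue) {
  L <- ncol(int_scores)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- integer(nrow(grid))
  pr <- numeric(nrow(grid)) + 1
  for (j in seq_len(L)) {
    sc <- sc + int_scores[grid[, j], j]
    pr <- pr * background[grid[, j]]
  }
  ord <- order(sc, decreasing = TRUE)
  cum <- cumsum(pr[ord])
  scs <- sc[ord]
  ## smallest t with P(score >= t) <= pvalue
  uniq <- !duplicated(scs)
  tails <- vapply(scs[uniq], function(t) sum(pr[sc >= t]), numeric(1))
  cand <- scs[uniq][tails <= pvalue + 1e-15]
  if (length(cand)) min(cand) else max(sc) + 1L
}
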