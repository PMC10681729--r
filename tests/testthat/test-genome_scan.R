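test_that("pwm_threshold anchors: consensus-only and everything", {
  ppm <- make_ppm("TTGAC", p = 0.85)
  ## p = 4^-5: only the single best sequence under uniform background
  pt <- pwm_threshold(ppm, pvalue = 4^-5)
  consensus_score <- sum(apply(pt$int_scores, 2, max))
  expect_equal(pt$threshold_int, consensus_score)
  ## p = 1: minimal possible score
  pt1 <- pwm_threshold(ppm, pvalue = 1)
  expect_equal(pt1$threshold_int, sum(apply(pt1$int_scores, 2, min)))
  expect_error(pwm_threshold(ppm, background = c(0, 0.5, 0.25, 0.25)),
               "degenerate")
  expect_error(pwm_threshold(make_ppm("ACG", 1)), "zeros")
})

test_that("pwm_threshold matches the exhaustive oracle (random PWMs)", {
  set.seed(71)
  for (i in 1:10) {
    L <- sample(4:6, 1)
    ppm <- matrix(stats::runif(4 * L, 0.02, 1), 4)
    ppm <- sweep(ppm, 2, colSums(ppm), "/")
    pv <- 10^stats::runif(1, -4, -1)
    pt <- pwm_threshold(ppm, pvalue = pv)
    t_or <- oracle_pwm_threshold(pt$int_scores, pt$background, pv)
    ## the induced match sets must coincide exactly
    grid <- as.matrix(expand.grid(rep(list(1:4), L)))
    sc <- integer(nrow(grid))
    for (j in seq_len(L)) sc <- sc + pt$int_scores[grid[, j], j]
    expect_identical(sum(sc >= pt$threshold_int), sum(sc >= t_or))
  }
})

test_that("scan_sequences reports strand-mirrored hits", {
  ppm <- make_ppm("TTGACGCA", p = 0.9)
  pt <- pwm_threshold(ppm, pvalue = 1e-4)
  seqv <- paste0(strrep("A", 10), "TTGACGCA", strrep("C", 12))
  hits <- scan_sequences(c(chrA = seqv), pt)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 10L)
  expect_equal(hits$end, 18L)
  expect_equal(hits$strand, "+")

  rhits <- scan_sequences(c(chrA = as.character(revcomp(seqv))), pt)
  expect_equal(rhits$strand, "-")
  expect_equal(rhits$start, nchar(seqv) - hits$end)
  expect_equal(rhits$end, nchar(seqv) - hits$start)

  ## mirror property on a random sequence with several plants
  set.seed(72)
  s <- plant_site(rand_seqs(1, 400), "TTGACGCA", fraction = 1, offset = 101)
  s <- plant_site(s, "TTGACGCA", fraction = 1, offset = 301)
  h_f <- scan_sequences(c(x = s), pt)
  h_r <- scan_sequences(c(x = as.character(revcomp(s))), pt)
  expect_equal(nrow(h_f), nrow(h_r))
  expect_setequal(nchar(s) - h_f$end, h_r$start)

  expect_error(scan_sequences(c(x = "ACGU"), pt), "non-ACGT")
})

test_that("ths_enrichment follows the density-ratio definition", {
  hits <- data.frame(seqname = "chr1",
                     start = c(seq(0, 900, length.out = 10),
                               seq(1000, 9900, length.out = 90)),
                     end = NA, strand = "+")
  hits$start <- as.integer(round(hits$start))
  hits$end <- hits$start + 8L
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  r <- ths_enrichment(hits, peaks, genome_length = 10000)
  expect_equal(r, ((10 + 1) / 1000) / ((90 + 1) / 9000))
  expect_equal(r, 1, tolerance = 0.1)

  all_in <- hits[1:10, ]
  expect_gt(ths_enrichment(all_in, peaks, 10000), 10)
  expect_error(ths_enrichment(hits, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 10000)), 10000), "whole genome")
})

test_that("metagene_profile maps hits strand-aware and conserves mass", {
  genes <- gene_table(c("g1", "g2"), "chr1", c("+", "-"),
                      c(5000, 20000), c(6999, 21999))
  ## hits exactly at each TSS
  tss_hits <- data.frame(seqname = "chr1", start = c(4999, 21998),
                         end = c(5000, 21999), strand = "+")
  prof <- metagene_profile(tss_hits, genes, body_length = 2000, flank = 1000,
                           bin = 50)
  expect_equal(sum(prof$counts), 2)
  expect_equal(prof$mids[which.max(prof$counts)], 25)  # the [0,50) TSS bin

  ## hits 50 bp upstream of the TSS on either gene strand: the -50 bin
  up_hits <- data.frame(seqname = "chr1",
                        start = c(5000 - 51, 22048), end = c(5000 - 50, 22049),
                        strand = "+")
  prof2 <- metagene_profile(up_hits, genes, bin = 50)
  expect_equal(sum(prof2$counts), 2)
  expect_equal(prof2$mids[which.max(prof2$counts)], -25)

  ## uniform hits give a roughly flat in-body profile
  set.seed(73)
  u <- data.frame(seqname = "chr1",
                  start = sort(sample(4000:8000, 2000, replace = TRUE)),
                  strand = "+")
  u$end <- u$start + 1L
  g1 <- genes[1, ]
  prof3 <- metagene_profile(u, g1, bin = 100)
  body <- prof3$counts[prof3$mids > 0 & prof3$mids < 2000]
  expect_lt(stats::sd(body) / mean(body), 0.25)
})

test_that("tss_window_enrichment contrasts expression quantiles", {
  genes <- gene_table(sprintf("g%02d", 1:20), "chr1", rep("+", 20),
                      seq(1000, 96000, by = 5000), seq(2500, 97500, by = 5000))
  expr <- stats::setNames(seq_len(20) * 10, genes$gene_id)  # g20 highest
  ## one hit at every TSS: ratio 1
  h_all <- data.frame(seqname = "chr1", start = genes$tss - 1L,
                      end = genes$tss, strand = "+")
  res <- tss_window_enrichment(h_all, genes, expr)
  expect_equal(res$ratio, 1)
  ## hits only at the top-15% TSSs
  top_ids <- genes$gene_id[order(-expr)][1:3]
  h_top <- h_all[genes$gene_id %in% top_ids, ]
  expect_gt(tss_window_enrichment(h_top, genes, expr)$ratio, 1)
  expect_error(tss_window_enrichment(h_all, genes, expr[-1]), "cover")
})

test_that("BED and gene-model IO round-trips through rtracklayer", {
  hits <- data.frame(seqname = "chr1", start = c(10L, 50L), end = c(18L, 58L),
                     strand = c("+", "-"), score = c(9.5, 8.1))
  bed <- tempfile(fileext = ".bed")
  write_bed(hits, bed)
  peaks <- read_peaks(bed)
  expect_s4_class(peaks, "GRanges")
  expect_equal(GenomicRanges::start(peaks), c(11L, 51L))  # 1-based on read

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t1999\t.\t+\t.\tID=gA",
               "chr1\tsrc\tgene\t5000\t6999\t.\t-\t.\tID=gB"), gff)
  g <- read_gene_models(gff)
  expect_equal(g$gene_id, c("gA", "gB"))
  expect_equal(g$tss, c(100L, 6999L))
  expect_equal(g$length, c(1900L, 2000L))
})
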