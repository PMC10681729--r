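test_that("curation filters implement the IC rules with labelled rejections", {
  homo <- make_motif(rep(1, 10), p = 0.97)      # 10-column A-run
  weak <- make_motif("ACG", p = 0.50)           # low total IC
  good <- make_motif("ACGTACGTACGT", p = 0.90)  # 12 columns, high per-base IC

  expect_gt(consensus_ic(homo), 1.8)
  expect_lt(weak$total_ic, 2)
  expect_gt(good$per_base_ic, 0.2)

  res <- curate_motifs(list(homo, weak, good))
  expect_length(res$retained, 1L)
  expect_equal(res$retained[[1]]$id, good$id)
  expect_setequal(res$rejected$reason, c("consensus_ic", "total_ic_low"))
  expect_true(res$stats$homopolymer[1])
  expect_false(res$stats$homopolymer[3])

  ## filters are pure predicates: re-curation of retained is a no-op
  again <- curate_motifs(res$retained)
  expect_length(again$retained, 1L)
})

test_that("align_motifs finds exact self and revcomp alignments", {
  m <- make_motif("TTGACGCA", p = 0.8)
  a <- align_motifs(m, m)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$offset, 0L)
  expect_equal(a$strand, "fwd")

  rc <- seaati:::revcomp_ppm(m$ppm)
  a2 <- align_motifs(m, rc)
  expect_equal(a2$pearson_r, 1)
  expect_equal(a2$strand, "revcomp")

  expect_error(align_motifs(m$ppm[, 1:3], m$ppm[, 1:3]), "overlap")
})

test_that("align_motifs equals an exhaustive offset/strand oracle", {
  oracle_align <- function(p1, p2, min_overlap = 4) {
    best <- -Inf
    for (strand in 1:2) {
      q <- if (strand == 1) p2 else seaati:::revcomp_ppm(p2)
      for (off in -(ncol(q) - 1):(ncol(p1) - 1)) {
        c1 <- max(1, 1 + off):min(ncol(p1), ncol(q) + off)
        if (length(c1) < min_overlap || c1[1] > c1[length(c1)]) next
        r <- suppressWarnings(cor(as.vector(p1[, c1, drop = FALSE]),
                                  as.vector(q[, c1 - off, drop = FALSE])))
        if (!is.na(r)) best <- max(best, r)
      }
    }
    best
  }
  set.seed(31)
  for (i in 1:10) {
    p1 <- matrix(stats::runif(4 * 8), 4); p1 <- sweep(p1, 2, colSums(p1), "/")
    p2 <- p1[, sample(8)]
    expect_equal(align_motifs(p1, p2)$pearson_r, oracle_align(p1, p2),
                 tolerance = 1e-12)
  }
})

test_that("dedup_motifs keeps the highest-IC member of each component", {
  base <- make_ppm("TTGACGCAT", p = 0.9)
  jitter_ppm <- function(ppm, eps, seed) {
    set.seed(seed)
    p <- ppm + matrix(runif(length(ppm), 0, eps), nrow = 4)
    sweep(p, 2, colSums(p), "/")
  }
  mk <- function(ppm, id) seaati:::new_motif_model(round(ppm * 1000), ppm, id = id)
  A <- mk(base, "A")
  B <- mk(jitter_ppm(base, 0.05, 1), "B")          # r ~ 0.99 with A
  C <- mk(make_ppm("ACACACACA", p = 0.9), "C")     # unrelated
  expect_gt(align_motifs(A, B)$pearson_r, 0.9)
  kept <- dedup_motifs(list(A, B, C))
  expect_length(kept, 2L)
  ics <- c(A = A$total_ic, B = B$total_ic)
  expect_true(names(which.max(ics)) %in% vapply(kept, `[[`, "", "id"))
  expect_true("C" %in% vapply(kept, `[[`, "", "id"))

  ## below-threshold pair survives intact
  D <- mk(make_ppm("TTGACGCAT", p = 0.55), "D")
  expect_lt(align_motifs(C, D)$pearson_r, 0.9)
  expect_length(dedup_motifs(list(C, D)), 2L)

  ## chain rule: A~B, B~B2 strongly, A./B2 weakly -> one survivor
  B2 <- mk(jitter_ppm(base, 0.08, 2), "B2")
  expect_length(dedup_motifs(list(A, B, B2)), 1L)
  ## idempotence and order-invariance
  expect_length(dedup_motifs(dedup_motifs(list(A, B, C))), 2L)
  ids1 <- sort(vapply(dedup_motifs(list(A, B, C)), `[[`, "", "id"))
  ids2 <- sort(vapply(dedup_motifs(list(C, B, A)), `[[`, "", "id"))
  expect_identical(ids1, ids2)
})

test_that("classify_motifs assigns categories and names; revcomp-invariant", {
  ref1 <- make_motif("TTGACGCAT", p = 0.9, id = "REF_WRKYX")
  ref2 <- make_motif("GGGCCCAAT", p = 0.9, id = "REF_OTHER")
  identical_m <- make_motif("TTGACGCAT", p = 0.9)
  similar_m <- make_motif("TTGACGAGT", p = 0.75)   # partial match
  distinct_m <- make_motif("ATATATATA", p = 0.9)

  cl <- classify_motifs(list(identical_m, distinct_m), list(ref1, ref2))
  expect_equal(cl$category, c("reported", "distinct"))
  expect_equal(cl$name[1], "REF_WRKYX")
  expect_match(cl$name[2], "seaATId")

  ## similar band is driven by the threshold arguments
  r_sim <- align_motifs(similar_m, ref1)$pearson_r
  cl2 <- classify_motifs(list(similar_m), list(ref1, ref2),
                         r_reported = min(0.99, r_sim + 0.05),
                         r_similar = r_sim - 0.05)
  expect_equal(cl2$category, "similar")

  ## reverse-complementing a reference motif changes nothing
  ref1_rc <- seaati:::new_motif_model(ref1$pfm[4:1, ncol(ref1$pfm):1],
                                      seaati:::revcomp_ppm(ref1$ppm),
                                      id = "REF_WRKYX")
  cl3 <- classify_motifs(list(identical_m, distinct_m), list(ref1_rc, ref2))
  expect_equal(cl3$category, cl$category)

  expect_warning(cl4 <- classify_motifs(list(distinct_m), list()), "empty")
  expect_equal(cl4$category, "distinct")
})

test_that("JASPAR round trip preserves matrices", {
  motifs <- list(make_motif("TTGACGCAT", p = 0.9, id = "M1"),
                 make_motif("ACGT", p = 0.7, id = "M2"))
  path <- tempfile(fileext = ".jaspar")
  write_jaspar(motifs, path)
  back <- read_jaspar(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$id, "M1")
  expect_equal(unname(back[[1]]$pfm), unname(motifs[[1]]$pfm))
  expect_equal(back[[2]]$consensus, "ACGT")
})

test_that("motif activity is zero on self and highest for the planted motif", {
  planted <- make_motif("TTGACGCAT", p = 0.9, id = "planted")
  other <- make_motif("GGGCCCAAT", p = 0.9, id = "other")
  lib <- ligand_library(plant_site(rand_seqs(800, 30, seed = 41), "TTGACGCAT",
                                   fraction = 0.3, seed = 42), sample_name = "t1")
  ctrl <- shuffle_control(lib, seed = 43)
  expect_equal(motif_activity(lib, planted, lib), 0)
  expect_gt(motif_activity(lib, planted, ctrl),
            motif_activity(lib, other, ctrl))
  ## motif absent from both libraries: zero
  absent <- make_motif("CGCGCGCGCGCG", p = 0.95)
  tiny <- ligand_library(rep(strrep("A", 30), 5))
  expect_equal(motif_activity(tiny, absent, tiny), 0)
})

test_that("specificity_contrast detects higher SD in distinct models", {
  set.seed(51)
  act <- rbind(matrix(rnorm(40, sd = 2), 4, 10),   # distinct: high spread
               matrix(rnorm(40, sd = 0.5), 4, 10))
  cats <- c(rep("distinct", 4), rep("reported", 4))
  res <- specificity_contrast(act, cats)
  expect_gt(res$statistic, 0)
  expect_lt(res$p_value, 0.05)

  ## permuted labels: |t| small on average
  set.seed(52)
  tstats <- replicate(30, {
    specificity_contrast(act, sample(cats))$statistic
  })
  expect_lt(abs(mean(tstats)), 1)

  expect_error(specificity_contrast(act, rep("reported", 8)), "non-empty")
  const <- matrix(1, 4, 5)
  expect_error(specificity_contrast(const, c("distinct", "distinct",
                                             "reported", "reported")),
               "undefined|constant")
})
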