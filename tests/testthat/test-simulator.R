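test_that("initial libraries have the stated architecture and determinism", {
  cfg <- sim_config(n_ligands = 500L)
  lib <- simulate_initial_library(cfg, seed = 1)
  expect_true(all(nchar(lib$reads) == 76L))
  expect_equal(lib$round, 0L)
  lib2 <- simulate_initial_library(cfg, seed = 1)
  expect_identical(lib2$reads, lib$reads)
  expect_false(identical(simulate_initial_library(cfg, seed = 2)$reads, lib$reads))
})

test_that("core base composition is uniform within binomial bounds", {
  cfg <- sim_config(n_ligands = 100000L)
  lib <- simulate_initial_library(cfg, seed = 3)
  cores <- substr(lib$reads, 24, 53)
  counts <- table(strsplit(paste(cores, collapse = ""), "")[[1]])
  n <- sum(counts)
  p <- counts / n
  tol <- 3 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(p - 0.25) < tol))
})

test_that("a null TF leaves consensus frequency unchanged within noise", {
  cfg <- sim_config(n_ligands = 5000L, n_rounds = 1L)
  lib0 <- simulate_initial_library(cfg, seed = 4)
  tf_null <- sim_tf(ppm = make_ppm("TTGACAAT"), beta = 1e-6)
  lib1 <- selection_round(lib0, tf_null, cfg, seed = 5)
  f <- function(l) mean(grepl("TTGACAAT", l$reads, fixed = TRUE))
  p0 <- f(lib0)
  ## binomial CI on the selected library's frequency
  expect_lt(abs(f(lib1) - p0), 4 * sqrt(p0 * (1 - p0) / length(lib1)) + 1e-4)
})

test_that("consensus k-mer frequency increases strictly across rounds", {
  cfg <- sim_config(n_ligands = 20000L, n_rounds = 4L)
  libs <- simulate_experiment(sim_tf(ppm = make_ppm("TTGACAAT"), beta = 1.5),
                              cfg, seed = 6)
  freq <- vapply(libs, function(l) mean(grepl("TTGACAAT", l$reads, fixed = TRUE)),
                 numeric(1))
  expect_true(all(diff(freq) > 0))
})

test_that("a dimeric DR-spacing-2 TF shapes the landscape argmax", {
  ## a short core keeps enough dimer-bearing ligands at desk-scale n
  aff <- matrix(0, 3, 11, dimnames = list(c("DR", "IR", "ER"), 0:10))
  aff["DR", "2"] <- 0.8
  tf <- sim_tf(dimer = list(core = "TGA", affinity = aff))
  cfg <- sim_config(n_ligands = 8000L, n_rounds = 3L)
  libs <- simulate_experiment(tf, cfg, seed = 7)
  final <- extract_cores(libs[[length(libs)]], cfg$adaptor)
  ctrl <- shuffle_control(final, seed = 8)
  spec <- dimer_spec(core = "TGA", spacing_range = 0:10)
  enr <- dimer_enrichment(count_dimers(final, spec), count_dimers(ctrl, spec))
  idx <- which(enr$counts == max(enr$counts), arr.ind = TRUE)
  expect_equal(rownames(enr$counts)[idx[1, 1]], "DR")
  expect_equal(colnames(enr$counts)[idx[1, 2]], "2")
})

test_that("genome track simulation plants recoverable structure", {
  motif <- make_motif("TTGACGCATT", p = 0.95, id = "m1")
  cfg <- genome_sim_config(genome_length = 60000L, n_cres = 30L, n_genes = 20L)
  sim <- simulate_genome_tracks(motif, cfg, occupancy = 1, seed = 9)
  expect_equal(nrow(sim$cres), 30L)
  expect_equal(sum(sim$expression$tpm), 1e6, tolerance = 1e-6)

  ## planted sites are recovered by scanning at p = 1e-4
  pt <- pwm_threshold(motif, pvalue = 1e-4)
  hits <- scan_sequences(sim$genome, pt)
  mids <- floor((sim$cres$start + sim$cres$end - 1) / 2)
  found <- vapply(seq_len(nrow(sim$cres)), function(i)
    any(hits$start <= mids[i] & hits$end > mids[i]), logical(1))
  expect_gt(mean(found), 0.9)

  ## aggregated footprint at occupied CREs is positive after control subtraction
  cre_hits <- sim$cres[, c("seqname", "start", "end", "strand")]
  prof_s <- aggregate_profile(sim$cuts_sample, cre_hits, window = 121)
  prof_c <- aggregate_profile(sim$cuts_control, cre_hits, window = 121)
  fp <- footprint_depth(prof_s, core_width = 10, control_profile = prof_c)
  expect_gt(fp$depth, 0)

  ## file outputs round-trip
  dir <- tempfile()
  sim2 <- simulate_genome_tracks(motif, genome_sim_config(
    genome_length = 20000L, n_cres = 8L, n_genes = 6L), seed = 10, dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "cres.bed", "peaks.bed", "cuts_sample.bedGraph",
    "cuts_control.bedGraph", "expression.tsv", "manifest.json")))))
  ss <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(unname(as.character(ss)), unname(sim2$genome))
  tr <- seaati:::as_cut_track(file.path(dir, "cuts_sample.bedGraph"))
  expect_equal(tr$chr1, sim2$cuts_sample$chr1)
})

test_that("footprint depth rises monotonically with planted occupancy", {
  motif <- make_motif("TTGACGCATT", p = 0.95, id = "m1")
  cfg <- genome_sim_config(genome_length = 40000L, n_cres = 25L, n_genes = 10L)
  depth_at <- function(occ) {
    sim <- simulate_genome_tracks(motif, cfg, occupancy = occ, seed = 11)
    cre_hits <- sim$cres[, c("seqname", "start", "end", "strand")]
    prof_s <- aggregate_profile(sim$cuts_sample, cre_hits, window = 121)
    prof_c <- aggregate_profile(sim$cuts_control, cre_hits, window = 121)
    footprint_depth(prof_s, core_width = 10, control_profile = prof_c)$depth
  }
  d <- vapply(c(0.2, 0.6, 1), depth_at, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("bound/unbound splitting recovers planted occupancy labels", {
  ## strong occupancy signal: deep coverage (5 cuts/bp) and a 90% dip
  motif <- make_motif("TTGACGCATT", p = 0.95, id = "m1")
  cfg <- genome_sim_config(genome_length = 80000L, n_cres = 40L, n_genes = 20L,
                           background_rate = 5, footprint_effect = 0.9)
  sim <- simulate_genome_tracks(motif, cfg, occupancy = 0.5, seed = 12)
  ## keep sites whose 121-bp window is inside the genome so rows align
  keep <- sim$cres$start >= 61 & sim$cres$end + 61 <= cfg$genome_length
  cres <- sim$cres[keep, ]
  cre_hits <- cres[, c("seqname", "start", "end", "strand")]
  prof_s <- aggregate_profile(sim$cuts_sample, cre_hits, window = 121)
  prof_c <- aggregate_profile(sim$cuts_control, cre_hits, window = 121)
  fp_s <- footprint_depth(prof_s, core_width = 10)
  fp_c <- footprint_depth(prof_c, core_width = 10)
  res <- split_bound_unbound(fp_s$per_site, fp_c$per_site)
  acc <- mean((res$labels == "bound") == cres$occupied)
  expect_gte(acc, 0.9)
})

test_that("expression couples to occupied promoter CREs (dose response)", {
  motif <- make_motif("TTGACGCATT", p = 0.95, id = "m1")
  cfg <- genome_sim_config(genome_length = 150000L, n_cres = 30L, n_genes = 50L)
  sim <- simulate_genome_tracks(motif, cfg, occupancy = 1,
                                expression_effect = 4, seed = 13)
  occ_hits <- sim$cres[sim$cres$occupied, c("seqname", "start", "end", "strand")]
  res <- cre_dose_response(occ_hits, sim$genes, sim$expression)
  with_cre <- res$median_tpm[res$cre_class != "0"]
  expect_gt(min(with_cre), res$median_tpm[res$cre_class == "0"])
})
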