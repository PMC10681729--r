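test_that("tpm follows the length-normalized formula and conserves 1e6", {
  one <- tpm(c(gA = 50), 1500)
  expect_equal(one$tpm, 1e6)

  two <- tpm(c(a = 10, b = 20), c(1000, 2000))
  expect_equal(two$tpm, c(5e5, 5e5))

  set.seed(81)
  n <- 200
  t3 <- tpm(rpois(n, 50), sample(500:5000, n))
  expect_equal(sum(t3$tpm), 1e6, tolerance = 1e-6)

  expect_error(tpm(c(0, 0), c(100, 100)), "all-zero")
  expect_error(tpm(c(1, 2), c(100, 0)), "> 0")
})

make_track <- function(values) list(chr1 = values)

test_that("aggregate_profile slices, flips and drops edge sites", {
  track <- make_track(rep(7, 500))
  hits <- data.frame(seqname = "chr1", start = c(100L, 490L), end = c(108L, 498L),
                     strand = c("+", "+"))
  prof <- aggregate_profile(track, hits, window = 121)
  expect_true(all(prof$mat == 7))
  expect_equal(nrow(prof$mat), 1L)     # second site runs off the edge
  expect_equal(prof$n_dropped, 1L)

  ## single site: row equals the raw track slice; minus strand reversed
  v <- seq_len(400)
  tr <- make_track(as.numeric(v))
  h1 <- data.frame(seqname = "chr1", start = 200L, end = 201L, strand = "+")
  ## hit covers the single base at 0-based 200 = 1-based 201
  p1 <- aggregate_profile(tr, h1, window = 21)
  expect_equal(as.numeric(p1$mat[1, ]), as.numeric(191:211))
  h2 <- h1; h2$strand <- "-"
  p2 <- aggregate_profile(tr, h2, window = 21)
  expect_equal(as.numeric(p2$mat[1, ]), as.numeric(211:191))

  expect_error(aggregate_profile(tr, h1, window = 20), "odd")
  far <- data.frame(seqname = "chr1", start = 1L, end = 2L, strand = "+")
  expect_error(aggregate_profile(make_track(rep(1, 5)), far, window = 21),
               "within")
})

test_that("footprint_depth is the flank-minus-core mean, control-subtracted", {
  ## crafted profile: flanks 10, core 4 over a 121-bp window, core width 11
  win <- 121; core_w <- 11; flank_w <- 25
  cols <- seaati:::profile_depth_cols(win, core_w, flank_w)
  row <- rep(10, win); row[cols$core] <- 4
  prof <- structure(list(mat = rbind(row, row), site_ids = c("s1", "s2"),
                         window = win, n_dropped = 0L), class = "cut_profile")
  ctrl_row <- rep(5, win); ctrl_row[cols$core] <- 4
  ctrl <- structure(list(mat = rbind(ctrl_row), site_ids = "c1",
                         window = win, n_dropped = 0L), class = "cut_profile")
  fp <- footprint_depth(prof, core_w, flank_w, ctrl)
  expect_equal(fp$depth, (10 - 4) - (5 - 4))  # 5.0
  expect_equal(fp$per_site, c(6, 6))

  ## flat profile, flat control: zero
  flat <- structure(list(mat = matrix(3, 2, win), site_ids = c("a", "b"),
                         window = win, n_dropped = 0L), class = "cut_profile")
  expect_equal(footprint_depth(flat, core_w, flank_w, flat)$depth, 0)

  ## linearity: scaling profile and control by c scales depth by c
  scale_prof <- function(p, c) { p$mat <- p$mat * c; p }
  d1 <- footprint_depth(prof, core_w, flank_w, ctrl)$depth
  d3 <- footprint_depth(scale_prof(prof, 3), core_w, flank_w,
                        scale_prof(ctrl, 3))$depth
  expect_equal(d3, 3 * d1)

  expect_error(footprint_depth(prof, 200, flank_w), "exceeds")
  bad_ctrl <- ctrl; bad_ctrl$window <- 61L
  expect_error(footprint_depth(prof, core_w, flank_w, bad_ctrl), "differs")
})

test_that("accessibility_classify applies the correlation thresholds", {
  x <- c(1, 2, 3, 4, 5)
  noise <- c(0.2, -0.1, 0.3, -0.2, 0)
  depths <- rbind(pos = x, neg = x, mid = x, flat = rep(1, 5))
  ths <- rbind(pos = x + noise,              # r ~ 1
               neg = -x + noise,             # r ~ -1
               mid = c(2, 1, 3, 1, 2),       # |r| small
               flat = c(1, 2, 1, 2, 1))
  expect_warning(res <- accessibility_classify(depths, ths), "zero-variance")
  expect_equal(res$category, c("positive", "negative", "unclassified",
                               "unclassified"))
  expect_gt(res$r[1], 0.5)
  expect_lt(res$r[2], -0.5)
  expect_true(is.na(res$r[4]))
})

test_that("label-permuted accessibility correlations are centred at zero", {
  set.seed(82)
  depths <- matrix(rnorm(20 * 8), 20, 8)
  ths <- depths + matrix(rnorm(20 * 8, sd = 0.2), 20, 8)  # strongly coupled
  real_r <- accessibility_classify(depths, ths)$r
  expect_gt(mean(real_r > 0.5), 0.8)
  null_r <- accessibility_null(depths, ths, n_perm = 50, seed = 83)
  expect_lt(abs(mean(null_r)), 0.15)
  expect_gt(mean(abs(null_r) < 0.5), mean(abs(null_r) >= 0.5))
})

test_that("split_bound_unbound thresholds on the control distribution", {
  set.seed(84)
  ctrl <- rnorm(50, mean = 0, sd = 1)
  at_mean <- rep(mean(ctrl), 20)
  res <- split_bound_unbound(at_mean, ctrl)
  expect_true(all(res$labels == "unbound"))
  ## k -> infinity: everything unbound
  res_inf <- split_bound_unbound(rnorm(20, 10), ctrl, k = 1e9)
  expect_true(all(res_inf$labels == "unbound"))
  ## clearly separated sites
  res2 <- split_bound_unbound(c(rep(8, 10), rep(-2, 10)), ctrl)
  expect_equal(res2$fraction_bound, 0.5)
  expect_error(split_bound_unbound(1:5, rnorm(5)), ">= 10")
})

test_that("cre_dose_response groups genes by promoter CRE count", {
  genes <- gene_table(c("g1", "g2", "g3"), "chr1", c("+", "+", "-"),
                      c(5000, 15000, 25000), c(6999, 16999, 26999))
  expr <- stats::setNames(c(10, 100, 1000), genes$gene_id)
  ## g2: one CRE 200 bp upstream; g3 (minus strand): two CREs upstream
  hits <- data.frame(seqname = "chr1",
                     start = c(15000 - 201, 27199, 27499),
                     end = c(15000 - 193, 27207, 27507), strand = "+")
  res <- cre_dose_response(hits, genes, expr)
  expect_equal(res$cre_class, c("0", "1", "2"))
  expect_equal(res$n_genes, c(1, 1, 1))
  expect_equal(res$median_tpm, c(10, 100, 1000))

  ## no CREs anywhere: a single class 0
  none <- hits[0, ]
  res0 <- cre_dose_response(none, genes, expr)
  expect_equal(res0$cre_class, "0")
  expect_equal(res0$n_genes, 3)
})
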