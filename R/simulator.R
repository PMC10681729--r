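## simulator: synthetic selection experiments (randomized ligand libraries
## enriched by PWM-defined TFs over 3-5 rounds, with PCR duplication) and
## synthetic genome-context fixtures (genome, planted CREs, peaks, cut
## tracks, expression) with full ground truth.

#' A simulated transcription factor
#'
#' Binding is monomeric (PWM-defined), dimeric (orientation/spacing
#' affinity for a core pair), or both. Monomeric occupancy of a window
#' with score s is `plogis(beta * (s - s_max))`, where `s_max` is the
#' consensus score, so the consensus site is bound with probability 0.5
#' per encounter and weaker sites fall off on a Boltzmann-like scale of
#' `beta` per bit.
#'
#' @param ppm 4 x L probability matrix (or `motif_model`); `NULL` for a
#'   purely dimeric TF.
#' @param beta binding strength per bit (> 0).
#' @param dimer optional `list(core =, affinity =)` where `affinity` is an
#'   orientation x spacing matrix of per-occurrence occupancies in `[0,1]`
#'   (rows DR/IR/ER, columns spacings "0","1",...).
#' @return object of class `sim_tf`.
#' @export
sim_tf <- function(ppm = NULL, beta = 2, dimer = NULL) {
  if (inherits(ppm, "motif_model")) ppm <- ppm$ppm
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (!is.null(dimer)) {
    stopifnot(is.matrix(dimer$affinity),
              all(dimer$affinity >= 0), all(dimer$affinity <= 1))
    stop_if_not_dna(dimer$core, "dimer core")
  }
  if (is.null(ppm) && is.null(dimer))
    stop("a sim_tf needs a ppm and/or a dimer spec", call. = FALSE)
  structure(list(ppm = ppm, beta = beta, dimer = dimer), class = "sim_tf")
}

#' Simulation configuration for selection experiments
#'
#' Defaults state the simulated world: 76-bp ligands with a 30-bp uniform
#' random core, 4 selection rounds (valid range 3-5 in the assay), 20% of
#' molecules recovered per round, and PCR regrowth back to the input
#' library size: each selected template is kept once and duplicates make
#' up `pcr_duplication_rate` of the regrown library, so the duplication
#' factor is `1 / (1 - rate)` — 5x at the default 0.8, which exactly
#' undoes a 20% selection (sequencing a fixed depth from an amplified
#' pool keeps library size constant across rounds).
#'
#' @param n_ligands library size.
#' @param adaptor an [adaptor_spec()] (defines core and total lengths).
#' @param n_rounds selection rounds.
#' @param selection_fraction fraction of molecules recovered per round.
#' @param pcr_duplication_rate duplicate fraction after PCR regrowth, in
#'   `[0, 1)`; 0 disables duplication.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_ligands = 10000L, adaptor = adaptor_spec(),
                       n_rounds = 4L, selection_fraction = 0.2,
                       pcr_duplication_rate = 0.8) {
  stopifnot(n_rounds >= 1L, selection_fraction > 0, selection_fraction <= 1,
            pcr_duplication_rate >= 0, pcr_duplication_rate < 1)
  structure(list(n_ligands = as.integer(n_ligands), adaptor = adaptor,
                 n_rounds = as.integer(n_rounds),
                 selection_fraction = selection_fraction,
                 pcr_duplication_rate = pcr_duplication_rate),
            class = "sim_config")
}

random_cores <- function(n, len) {
  codes <- matrix(sample.int(4L, n * len, replace = TRUE), nrow = n)
  codes_to_strings(codes)
}

#' Simulate the round-0 (unselected) ligand library
#'
#' i.i.d. uniform ACGT cores between the fixed adaptor flanks.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (fixed seed gives a byte-identical library).
#' @return a [ligand_library()] of full-length ligands, round 0.
#' @export
simulate_initial_library <- function(config = sim_config(), seed = NULL) {
  ad <- config$adaptor
  cores <- with_seed(seed, random_cores(config$n_ligands, ad$core_length))
  ligand_library(paste0(ad$flank5, cores, ad$flank3),
                 ids = paste0("lig", seq_len(config$n_ligands)),
                 sample_name = "simulated", round = 0L)
}

## per-read log survival, log(prod(1 - occupancy)), over monomeric windows;
## kept in log space so weights of weak binders do not underflow to zero
monomer_logsurv <- function(reads, tf) {
  lo <- log2(pmax(tf$ppm, 1e-9) / 0.25)
  L <- ncol(lo)
  smax <- sum(apply(lo, 2, max))
  acc <- numeric(length(reads))
  for (m in list(base_code_matrix(reads), base_code_matrix(revcomp(reads)))) {
    W <- ncol(m)
    if (W < L) next
    for (o in seq_len(W - L + 1L)) {
      sc <- lo[m[, o], 1L]
      if (L > 1L) for (j in 2:L) sc <- sc + lo[m[, o + j - 1L], j]
      occ <- stats::plogis(tf$beta * (sc - smax))
      occ[is.na(occ)] <- 0
      acc <- acc + log1p(-occ)
    }
  }
  acc
}

dimer_logsurv <- function(reads, tf) {
  aff <- tf$dimer$affinity
  spec <- dimer_spec(core = tf$dimer$core,
                     orientations = rownames(aff),
                     spacing_range = as.integer(colnames(aff)))
  core <- spec$core; rc <- revcomp(core); len <- nchar(core)
  smin <- min(spec$spacing_range); smax <- max(spec$spacing_range)
  vapply(reads, function(s) {
    cpos <- overlapping_match_starts(s, core)
    rpos <- if (spec$palindromic) integer(0) else overlapping_match_starts(s, rc)
    pos <- c(cpos, rpos)
    if (length(pos) < 2L) return(0)
    lab <- c(rep("C", length(cpos)), rep("R", length(rpos)))
    ord <- order(pos); pos <- pos[ord]; lab <- lab[ord]
    acc <- 0
    for (i in seq_len(length(pos) - 1L)) for (j in (i + 1L):length(pos)) {
      sp <- pos[j] - pos[i] - len
      if (sp < smin) next
      if (sp > smax) break
      ori <- if (lab[i] == lab[j]) "DR" else if (lab[i] == "C") "IR" else "ER"
      if (ori %in% rownames(aff)) acc <- acc + log1p(-aff[ori, as.character(sp)])
    }
    acc
  }, numeric(1), USE.NAMES = FALSE)
}

#' One round of affinity-based selection with PCR regrowth
#'
#' Each read gets binding weight `1 - prod(1 - occupancy)` over all its
#' monomeric windows (both strands) and dimeric core-pair occurrences,
#' combined across TFs. The bound pool — `selection_fraction * n`
#' molecules — is drawn with replacement with probability proportional to
#' weight (concentration dynamics: enrichment compounds across rounds, as
#' it does when a bound fraction is amplified), then PCR duplicates are
#' appended (duplicate ids carry a `_dup` suffix) so the duplication
#' factor is `1 / (1 - pcr_duplication_rate)`.
#'
#' @param lib a [ligand_library()].
#' @param tfs list of [sim_tf()]s (a single `sim_tf` is accepted).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return the selected [ligand_library()], round incremented.
#' @export
selection_round <- function(lib, tfs, config = sim_config(), seed = NULL) {
  if (inherits(tfs, "sim_tf")) tfs <- list(tfs)
  n <- length(lib$reads)
  if (n == 0L) stop("empty library", call. = FALSE)
  acc <- numeric(n)
  for (tf in tfs) {
    if (!is.null(tf$ppm)) acc <- acc + monomer_logsurv(lib$reads, tf)
    if (!is.null(tf$dimer)) acc <- acc + dimer_logsurv(lib$reads, tf)
  }
  weight <- -expm1(acc)
  ## renormalize so sample() sees well-scaled probabilities even when all
  ## reads are weak binders
  if (any(weight > 0)) weight <- weight / max(weight)
  if (all(weight == 0)) {
    warning("all binding weights are zero; sampling uniformly")
    weight <- rep(1, n)
  }
  n_sel <- max(1L, round(config$selection_fraction * n))
  with_seed(seed, {
    sel <- sample.int(n, n_sel, replace = TRUE, prob = weight)
    reads <- lib$reads[sel]; ids <- lib$ids[sel]
    if (config$pcr_duplication_rate > 0) {
      n_dup <- round(n_sel * config$pcr_duplication_rate /
                       (1 - config$pcr_duplication_rate))
      dup <- sample.int(n_sel, n_dup, replace = TRUE)
      reads <- c(reads, reads[dup])
      ids <- c(ids, paste0(ids[dup], "_dup", seq_len(n_dup)))
      ord <- sample.int(length(reads))
      reads <- reads[ord]; ids <- ids[ord]
    }
    ligand_library(reads, ids = ids, sample_name = lib$sample_name,
                   round = lib$round + 1L)
  })
}

#' Run a full selection experiment
#'
#' @param tfs list of [sim_tf()]s.
#' @param config a [sim_config()].
#' @param seed RNG seed (one child stream per round).
#' @return list of [ligand_library()]s, rounds 0..n_rounds.
#' @export
simulate_experiment <- function(tfs, config = sim_config(), seed = NULL) {
  libs <- vector("list", config$n_rounds + 1L)
  libs[[1]] <- simulate_initial_library(config, seed = child_seed(seed, 0L))
  for (r in seq_len(config$n_rounds)) {
    libs[[r + 1L]] <- selection_round(libs[[r]], tfs, config,
                                      seed = child_seed(seed, r))
  }
  names(libs) <- paste0("round", 0:config$n_rounds)
  libs
}

#' Genome-context simulation configuration
#'
#' The stated toy world: a 100-kb single-chromosome genome; 50 planted
#' CREs; ATAC-like cut tracks with a background of 1 cut/bp, 4-fold
#' elevation inside 500-bp peaks, an 80% cut depletion over occupied CRE
#' cores, and a 10% residual depletion in the protein-free control (bias
#' correction never removes the footprint entirely); 40 genes of 1-2 kb
#' with log-normal baseline expression.
#'
#' @param genome_length,chrom genome size (bp) and chromosome name.
#' @param n_cres planted CRE sites.
#' @param peak_fraction fraction of CREs centered in a peak.
#' @param peak_halfwidth peak half-width (bp).
#' @param background_rate,peak_rate Poisson cut rates (cuts/bp).
#' @param footprint_effect fractional cut depletion over an occupied core.
#' @param control_residual residual depletion fraction in the control.
#' @param n_genes,gene_length_range genes and their length range (bp).
#' @param promoter_window promoter width upstream of the TSS (bp).
#' @return object of class `genome_sim_config`.
#' @export
genome_sim_config <- function(genome_length = 100000L, chrom = "chr1",
                              n_cres = 50L, peak_fraction = 0.6,
                              peak_halfwidth = 250L, background_rate = 1,
                              peak_rate = 4, footprint_effect = 0.8,
                              control_residual = 0.1, n_genes = 40L,
                              gene_length_range = c(1000L, 2000L),
                              promoter_window = 1000L) {
  structure(as.list(environment()), class = "genome_sim_config")
}

sample_motif_site <- function(ppm) {
  paste(DNA_BASES[apply(ppm, 2, function(p) sample.int(4L, 1L, prob = p))],
        collapse = "")
}

write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    r <- rle(track[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    utils::write.table(data.frame(chrom, starts, ends, r$values), con,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Simulate a toy genome with planted CREs, peaks, cut tracks and expression
#'
#' Plants motif instances (sampled from each motif's PPM) at recorded
#' non-overlapping coordinates: one CRE in the promoter of each of a
#' subset of genes (so expression coupling is testable) and the rest
#' intergenic. Draws peaks around a fraction of CREs; builds per-base cut
#' tracks (background Poisson + peak elevation, thinned over occupied CRE
#' cores) and a protein-free control (same landscape, residual thinning
#' only); couples expression counts multiplicatively to the number of
#' occupied promoter CREs.
#'
#' @param motifs list of `motif_model`s (or 4 x L PPMs) to plant.
#' @param config a [genome_sim_config()].
#' @param occupancy probability that a planted CRE is occupied.
#' @param expression_effect multiplicative expression effect per occupied
#'   promoter CRE.
#' @param seed RNG seed.
#' @param dir if non-NULL, write genome.fa, cres.bed, peaks.bed,
#'   cuts_sample.bedGraph, cuts_control.bedGraph, expression.tsv and
#'   manifest.json there.
#' @return list: `genome` (named character), `cres` (data.frame with
#'   motif, strand, occupied), `peaks` (GRanges), `cuts_sample`,
#'   `cuts_control` (cut tracks), `expression` (expression_table),
#'   `genes` (gene table), `config`.
#' @export
simulate_genome_tracks <- function(motifs, config = genome_sim_config(),
                                   occupancy = 1, expression_effect = 2,
                                   seed = NULL, dir = NULL) {
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  ppms <- lapply(motifs, function(m) if (inherits(m, "motif_model")) m$ppm else m)
  ids <- vapply(seq_along(motifs), function(i) {
    m <- motifs[[i]]
    if (inherits(m, "motif_model")) m$id else paste0("motif", i)
  }, character(1))
  G <- config$genome_length
  max_w <- max(vapply(ppms, ncol, integer(1)))
  if (config$n_cres * (max_w + 20L) > G / 2)
    stop("over-dense CRE planting for this genome length", call. = FALSE)

  with_seed(seed, {
    genome_codes <- sample.int(4L, G, replace = TRUE)

    ## genes: non-overlapping, random strand, placed on a jittered grid
    n_genes <- config$n_genes
    slot <- G %/% n_genes
    glen <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                   n_genes, replace = TRUE)
    gstart <- pmin(pmax((seq_len(n_genes) - 1L) * slot +
                          sample.int(max(1L, slot %/% 4L), n_genes, replace = TRUE) +
                          config$promoter_window + 10L, 1L),
                   G - glen)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- gene_table(sprintf("g%03d", seq_len(n_genes)), config$chrom,
                        strand, gstart, gstart + glen - 1L)

    ## CREs: one per promoter for the first ceil(n_cres/2) genes (cycled),
    ## remainder intergenic
    n_prom <- min(config$n_cres, n_genes)
    cre <- vector("list", config$n_cres)
    for (i in seq_len(config$n_cres)) {
      mi <- (i - 1L) %% length(ppms) + 1L
      w <- ncol(ppms[[mi]])
      site <- sample_motif_site(ppms[[mi]])
      s <- sample(c("+", "-"), 1L)
      start0 <- NA_integer_
      if (i <= n_prom) {
        g <- genes[i, ]
        off <- sample.int(config$promoter_window - w - 10L, 1L) + 5L
        start0 <- if (g$strand == "+") g$tss - off - w else g$tss + off - 1L
        if (start0 < 0L || start0 + w > G) start0 <- NA_integer_  # off the edge
      }
      if (is.na(start0)) {
        for (try in 1:200) {
          start0 <- sample.int(G - w - 1L, 1L)
          near_gene <- any(start0 + w >= genes$start - config$promoter_window &
                             start0 <= genes$end + config$promoter_window)
          if (!near_gene) break
        }
      }
      cre[[i]] <- data.frame(seqname = config$chrom, start = start0,
                             end = start0 + w, strand = s, motif = ids[mi],
                             site = site, stringsAsFactors = FALSE)
    }
    cres <- do.call(rbind, cre)
    cres$occupied <- stats::runif(nrow(cres)) < occupancy

    ## write CRE sequences into the genome (strand-aware)
    for (i in seq_len(nrow(cres))) {
      s <- cres$site[i]
      if (cres$strand[i] == "-") s <- revcomp(s)
      genome_codes[(cres$start[i] + 1L):cres$end[i]] <- base_code_matrix(s)[1, ]
    }
    genome <- stats::setNames(codes_to_strings(matrix(genome_codes, nrow = 1)),
                              config$chrom)

    ## peaks around a CRE subset
    in_peak <- stats::runif(nrow(cres)) < config$peak_fraction
    centers <- floor((cres$start + cres$end) / 2)[in_peak]
    pk <- IRanges::IRanges(pmax(1L, centers - config$peak_halfwidth),
                           pmin(G, centers + config$peak_halfwidth))
    peaks <- GenomicRanges::reduce(GenomicRanges::GRanges(config$chrom, pk))

    ## cut tracks
    rate <- rep(config$background_rate, G)
    if (length(peaks)) {
      for (i in seq_along(peaks)) {
        idx <- GenomicRanges::start(peaks)[i]:GenomicRanges::end(peaks)[i]
        rate[idx] <- rate[idx] + config$peak_rate
      }
    }
    cuts_sample <- stats::rpois(G, rate)
    cuts_control <- stats::rpois(G, rate)
    thin <- function(v, idx, effect) {
      v[idx] <- stats::rbinom(length(idx), v[idx], 1 - effect)
      v
    }
    for (i in seq_len(nrow(cres))) {
      idx <- (cres$start[i] + 1L):cres$end[i]
      if (cres$occupied[i])
        cuts_sample <- thin(cuts_sample, idx, config$footprint_effect)
      cuts_control <- thin(cuts_control, idx, config$control_residual)
    }
    cuts_sample <- stats::setNames(list(as.numeric(cuts_sample)), config$chrom)
    cuts_control <- stats::setNames(list(as.numeric(cuts_control)), config$chrom)

    ## expression coupled to occupied promoter CREs
    occ_hits <- cres[cres$occupied, , drop = FALSE]
    n_occ <- promoter_cre_counts(occ_hits, genes, config$promoter_window)
    mu <- stats::rlnorm(n_genes, meanlog = log(100), sdlog = 1) *
      (1 + expression_effect)^n_occ
    counts <- stats::rnbinom(n_genes, size = 10, mu = mu)
    if (all(counts == 0)) counts[1] <- 1L
    expr <- tpm(stats::setNames(counts, genes$gene_id), genes$length)

    out <- list(genome = genome, cres = cres, peaks = peaks,
                cuts_sample = cuts_sample, cuts_control = cuts_control,
                expression = expr, genes = genes, config = config)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      ss <- Biostrings::DNAStringSet(genome)
      Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"))
      utils::write.table(cres[, c("seqname", "start", "end", "motif",
                                  "occupied", "strand")],
                         file.path(dir, "cres.bed"), sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      utils::write.table(data.frame(config$chrom,
                                    GenomicRanges::start(peaks) - 1L,
                                    GenomicRanges::end(peaks)),
                         file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      write_bedgraph(cuts_sample, file.path(dir, "cuts_sample.bedGraph"))
      write_bedgraph(cuts_control, file.path(dir, "cuts_control.bedGraph"))
      utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(n_cres = nrow(cres), occupancy = occupancy,
                                expression_effect = expression_effect,
                                motifs = ids),
                           file.path(dir, "manifest.json"), auto_unbox = TRUE)
    }
    out
  })
}
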