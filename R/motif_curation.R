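## motif_curation: IC-based filtering, Pearson-alignment deduplication,
## classification against a reference motif library, and per-library
## activity / tissue-specificity summaries.

#' Curation filter thresholds
#'
#' Defaults follow the curation rules for randomized-library motifs:
#' consensus IC below 1.8 bits (rejects homonucleotide runs, which reach
#' ~2 bits per consensus position), total IC between 2 and 30 bits, and
#' per-base IC above 0.2 bits.
#'
#' @param consensus_ic_max,total_ic_min,total_ic_max,per_base_ic_min bits.
#' @return an object of class `curation_filters`.
#' @export
curation_filters <- function(consensus_ic_max = 1.8, total_ic_min = 2,
                             total_ic_max = 30, per_base_ic_min = 0.2) {
  stopifnot(total_ic_min < total_ic_max)
  structure(list(consensus_ic_max = consensus_ic_max,
                 total_ic_min = total_ic_min, total_ic_max = total_ic_max,
                 per_base_ic_min = per_base_ic_min),
            class = "curation_filters")
}

#' Mean information content carried by the consensus base
#'
#' `(1/L) * sum_j p_j(consensus_j) * log2(p_j(consensus_j) / 0.25)` — the
#' per-position IC contributed by the consensus base, averaged over
#' columns. Near 2 bits for homonucleotide runs, lower for mixed motifs.
#'
#' @param motif a `motif_model` or a 4 x L PPM.
#' @return bits.
#' @export
consensus_ic <- function(motif) {
  ppm <- if (inherits(motif, "motif_model")) motif$ppm else motif
  p <- apply(ppm, 2, max)
  mean(ifelse(p > 0, p * log2(p / 0.25), 0))
}

is_homopolymer <- function(motif, frac = 0.9) {
  cons <- if (inherits(motif, "motif_model")) motif$consensus else
    motif_summary(ppm = motif)$consensus
  max(table(strsplit(cons, "")[[1]])) >= frac * nchar(cons)
}

#' Filter motifs by information-content criteria
#'
#' Retains a motif iff consensus IC < `consensus_ic_max`, total IC strictly
#' inside (`total_ic_min`, `total_ic_max`), and per-base IC >
#' `per_base_ic_min`. Each rejection is labelled with the first failing
#' rule. A homopolymer flag (>= 90% of consensus positions share one base)
#' is reported for all motifs.
#'
#' @param motifs list of `motif_model`s.
#' @param filters a [curation_filters()].
#' @return list with `retained` (motif list) and `rejected` (data.frame of
#'   id, reason, plus the measured statistics and homopolymer flag for
#'   every input motif in `stats`).
#' @export
curate_motifs <- function(motifs, filters = curation_filters()) {
  stats_df <- data.frame(
    id = vapply(motifs, function(m) m$id, character(1)),
    consensus_ic = vapply(motifs, consensus_ic, numeric(1)),
    total_ic = vapply(motifs, function(m) m$total_ic, numeric(1)),
    per_base_ic = vapply(motifs, function(m) m$per_base_ic, numeric(1)),
    homopolymer = vapply(motifs, is_homopolymer, logical(1)),
    stringsAsFactors = FALSE)
  reason <- rep(NA_character_, nrow(stats_df))
  reason[is.na(reason) & stats_df$consensus_ic >= filters$consensus_ic_max] <- "consensus_ic"
  reason[is.na(reason) & stats_df$total_ic <= filters$total_ic_min] <- "total_ic_low"
  reason[is.na(reason) & stats_df$total_ic >= filters$total_ic_max] <- "total_ic_high"
  reason[is.na(reason) & stats_df$per_base_ic <= filters$per_base_ic_min] <- "per_base_ic"
  keep <- is.na(reason)
  list(retained = motifs[keep],
       rejected = data.frame(id = stats_df$id[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE),
       stats = stats_df)
}

revcomp_ppm <- function(ppm) ppm[4:1, rev(seq_len(ncol(ppm))), drop = FALSE]

align_at_offset <- function(p1, p2, offset) {
  L1 <- ncol(p1); L2 <- ncol(p2)
  c1 <- max(1L, 1L + offset):min(L1, L2 + offset)
  if (length(c1) < 1L || c1[1] > c1[length(c1)]) return(NULL)
  c2 <- c1 - offset
  x <- as.vector(p1[, c1, drop = FALSE])
  y <- as.vector(p2[, c2, drop = FALSE])
  r <- suppressWarnings(stats::cor(x, y))
  list(r = r, n = length(c1))
}

#' Best ungapped alignment between two motifs
#'
#' Maximizes the Pearson correlation of the flattened overlapping PPM cells
#' over all ungapped offsets and both orientations of `m2`. Ties are broken
#' toward the smaller |offset|, then the forward strand.
#'
#' @param m1,m2 `motif_model`s or 4 x L PPMs.
#' @param min_overlap minimum overlapping columns.
#' @return list (class `motif_alignment`): offset (of m2 relative to m1),
#'   strand ("fwd"/"revcomp"), pearson_r, n_overlap_columns.
#' @export
align_motifs <- function(m1, m2, min_overlap = 4L) {
  p1 <- if (inherits(m1, "motif_model")) m1$ppm else m1
  p2 <- if (inherits(m2, "motif_model")) m2$ppm else m2
  L1 <- ncol(p1); L2 <- ncol(p2)
  offsets <- (-(L2 - min_overlap)):(L1 - min_overlap)
  if (length(offsets) == 0L || min(L1, L2) < min_overlap)
    stop(sprintf("no offset with >= %d overlapping columns", min_overlap), call. = FALSE)
  best <- NULL
  for (strand in c("fwd", "revcomp")) {
    q <- if (strand == "fwd") p2 else revcomp_ppm(p2)
    for (off in offsets) {
      a <- align_at_offset(p1, q, off)
      if (is.null(a) || a$n < min_overlap) next
      r <- if (is.na(a$r)) -Inf else a$r
      cand <- list(offset = off, strand = strand, pearson_r = r,
                   n_overlap_columns = a$n)
      if (is.null(best) ||
          r > best$pearson_r + 1e-12 ||
          (abs(r - best$pearson_r) <= 1e-12 &&
           (abs(off) < abs(best$offset) ||
            (abs(off) == abs(best$offset) && strand == "fwd" && best$strand == "revcomp"))))
        best <- cand
    }
  }
  if (is.null(best))
    stop(sprintf("no offset with >= %d overlapping columns", min_overlap), call. = FALSE)
  structure(best, class = "motif_alignment")
}

#' Remove near-duplicate motifs
#'
#' Builds a graph with an edge wherever the best aligned Pearson r is
#' strictly greater than `r_threshold` (default 0.90), and keeps the
#' highest-total-IC motif of each connected component (ties by id).
#'
#' @param motifs list of `motif_model`s.
#' @param r_threshold Pearson correlation above which motifs are considered
#'   identical.
#' @param min_overlap passed to [align_motifs()].
#' @return the retained motifs, in input order.
#' @export
dedup_motifs <- function(motifs, r_threshold = 0.90, min_overlap = 4L) {
  n <- length(motifs)
  if (n <= 1L) return(motifs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- tryCatch(align_motifs(motifs[[i]], motifs[[j]], min_overlap)$pearson_r,
                  error = function(e) -Inf)
    if (r > r_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ic <- vapply(motifs, function(m) m$total_ic, numeric(1))
  ids <- vapply(motifs, function(m) m$id, character(1))
  keep <- vapply(unique(comp), function(cp) {
    members <- which(comp == cp)
    members[order(-ic[members], ids[members])][1]
  }, integer(1))
  motifs[sort(keep)]
}

#' Classify motifs against a reference library
#'
#' Each motif is aligned against every reference motif; the best Pearson r
#' determines the category: `reported` (r >= `r_reported`), `similar`
#' (`r_similar` <= r < `r_reported`), otherwise `distinct`. Reported and
#' similar motifs are named after the best match; distinct motifs receive
#' sequential `seaATId` names. The numeric thresholds stand in for the
#' manual examination used in practice and are configurable.
#'
#' @param motifs list of `motif_model`s.
#' @param reference_library list of `motif_model`s (e.g. from
#'   [read_jaspar()]).
#' @param r_reported,r_similar category thresholds.
#' @param min_overlap passed to [align_motifs()].
#' @return data.frame: id, category, best_match, best_r, name.
#' @export
classify_motifs <- function(motifs, reference_library,
                            r_reported = 0.85, r_similar = 0.70,
                            min_overlap = 4L) {
  if (length(reference_library) == 0L) {
    warning("empty reference library: all motifs classified as distinct")
    return(data.frame(id = vapply(motifs, function(m) m$id, character(1)),
                      category = "distinct", best_match = NA_character_,
                      best_r = NA_real_,
                      name = paste0(seq_along(motifs), "_seaATId"),
                      stringsAsFactors = FALSE))
  }
  ref_names <- vapply(reference_library, function(m) m$name %||% m$id, character(1))
  res <- lapply(motifs, function(m) {
    rs <- vapply(reference_library, function(ref)
      tryCatch(align_motifs(m, ref, min_overlap)$pearson_r,
               error = function(e) -Inf), numeric(1))
    best <- which.max(rs)
    list(best_match = ref_names[best], best_r = rs[best])
  })
  best_r <- vapply(res, `[[`, numeric(1), "best_r")
  category <- ifelse(best_r >= r_reported, "reported",
                     ifelse(best_r >= r_similar, "similar", "distinct"))
  name <- character(length(motifs))
  n_distinct <- 0L
  for (i in seq_along(motifs)) {
    if (category[i] == "distinct") {
      n_distinct <- n_distinct + 1L
      name[i] <- sprintf("%d_seaATId", n_distinct)
    } else name[i] <- res[[i]]$best_match
  }
  data.frame(id = vapply(motifs, function(m) m$id, character(1)),
             category = category,
             best_match = vapply(res, `[[`, character(1), "best_match"),
             best_r = ifelse(is.finite(best_r), best_r, NA_real_),
             name = name, stringsAsFactors = FALSE)
}

#' Motif activity in a library relative to its control
#'
#' Per-read-normalized log2 ratio of PWM match counts between a library and
#' its matched (shuffled) control, with matches called at an exact p-value
#' threshold (see [pwm_threshold()]).
#'
#' @param lib,ctrl [ligand_library()]s.
#' @param motif a `motif_model`.
#' @param match_pvalue PWM match p-value.
#' @return activity score (log2; 0 when lib equals ctrl).
#' @export
motif_activity <- function(lib, motif, ctrl, match_pvalue = 1e-4) {
  pt <- pwm_threshold(motif$ppm, pvalue = match_pvalue)
  n_obs <- count_pwm_matches(lib$reads, pt)
  n_ctl <- count_pwm_matches(ctrl$reads, pt)
  log2(((n_obs + 1) / length(lib$reads)) / ((n_ctl + 1) / length(ctrl$reads)))
}

#' Activity matrix of motifs across libraries
#'
#' @param motifs list of `motif_model`s.
#' @param libs list of [ligand_library()]s (e.g. tissues).
#' @param controls matched control libraries; built by [shuffle_control()]
#'   with `seed` when omitted.
#' @param match_pvalue PWM match p-value.
#' @param seed RNG seed for control construction.
#' @return motifs x libraries numeric matrix.
#' @export
activity_matrix <- function(motifs, libs, controls = NULL,
                            match_pvalue = 1e-4, seed = NULL) {
  if (is.null(controls))
    controls <- lapply(seq_along(libs), function(i)
      shuffle_control(libs[[i]], seed = child_seed(seed, i)))
  m <- vapply(seq_along(libs), function(j)
    vapply(motifs, function(mo)
      motif_activity(libs[[j]], mo, controls[[j]], match_pvalue), numeric(1)),
    numeric(length(motifs)))
  m <- matrix(m, nrow = length(motifs))
  rownames(m) <- vapply(motifs, function(mo) mo$id, character(1))
  colnames(m) <- vapply(libs, function(l) l$sample_name, character(1))
  m
}

#' Tissue-specificity contrast between motif categories
#'
#' Compares per-motif standard deviations of activity across tissues
#' between `distinct` motifs and all others (Welch two-sample t-test).
#'
#' @param activity activity matrix (motifs x tissues).
#' @param categories character vector per motif (as from
#'   [classify_motifs()]).
#' @return list: `sd` (named per-motif SD), `statistic`, `p_value`.
#' @export
specificity_contrast <- function(activity, categories) {
  stopifnot(nrow(activity) == length(categories), ncol(activity) >= 2L)
  sds <- apply(activity, 1, stats::sd)
  a <- sds[categories == "distinct"]
  b <- sds[categories != "distinct"]
  if (length(a) == 0L || length(b) == 0L)
    stop("both 'distinct' and other categories must be non-empty", call. = FALSE)
  tt <- tryCatch(stats::t.test(a, b),
                 error = function(e)
                   stop("specificity contrast undefined: ", conditionMessage(e),
                        call. = FALSE))
  if (!is.finite(tt$statistic))
    stop("specificity contrast undefined: zero variance in both groups",
         call. = FALSE)
  list(sd = sds, statistic = unname(tt$statistic), p_value = tt$p.value)
}
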