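## ligand_io: reading sequencing output, adaptor-anchored core extraction,
## PCR deduplication and shuffled controls.

#' Adaptor specification for fixed-architecture ligands
#'
#' Describes the constant architecture of a synthetic double-stranded DNA
#' ligand: a randomized core of `core_length` bp flanked by two fixed
#' adaptors. The defaults describe a 76-bp ligand with a 30-bp randomized
#' core (flanks sum to 46 bp). The default flank sequences are placeholders
#' of the correct lengths; real libraries should supply their own.
#'
#' @param flank5,flank3 fixed adaptor sequences (ACGT only).
#' @param core_length length of the randomized core in bp.
#' @return an object of class `adaptor_spec`.
#' @examples
#' spec <- adaptor_spec()
#' nchar(spec$flank5) + spec$core_length + nchar(spec$flank3)  # 76
#' @export
adaptor_spec <- function(flank5 = "ACACTCTTTCCCTACACGACGCT",
                         flank3 = "AGATCGGAAGAGCACACGTCTGA",
                         core_length = 30L) {
  stop_if_not_dna(flank5, "flank5")
  stop_if_not_dna(flank3, "flank3")
  core_length <- as.integer(core_length)
  if (core_length < 1L) stop("core_length must be >= 1", call. = FALSE)
  structure(list(flank5 = flank5, flank3 = flank3, core_length = core_length),
            class = "adaptor_spec")
}

#' Construct a ligand library
#'
#' A ligand library is an ordered set of reads from one sample and selection
#' round. Round 0 denotes the unselected input library.
#'
#' @param reads character vector of sequences (A/C/G/T/N).
#' @param ids read identifiers; generated when omitted.
#' @param sample_name sample label.
#' @param round selection round (integer >= 0).
#' @param is_control whether this is a shuffled/control library.
#' @return an object of class `ligand_library`.
#' @export
ligand_library <- function(reads, ids = NULL, sample_name = "sample",
                           round = 0L, is_control = FALSE) {
  reads <- toupper(as.character(reads))
  stop_if_not_dna(reads, "reads", allow_n = TRUE)
  if (is.null(ids)) ids <- if (length(reads)) paste0("read", seq_along(reads)) else character(0)
  if (length(ids) != length(reads)) stop("ids and reads lengths differ", call. = FALSE)
  structure(list(reads = reads, ids = as.character(ids),
                 sample_name = sample_name, round = as.integer(round),
                 is_control = isTRUE(is_control)),
            class = "ligand_library")
}

#' @export
length.ligand_library <- function(x) length(x$reads)

#' @export
print.ligand_library <- function(x, ...) {
  lens <- unique(nchar(x$reads))
  cat(sprintf("ligand_library '%s' (round %d%s): %d reads, length %s\n",
              x$sample_name, x$round, if (x$is_control) ", control" else "",
              length(x$reads),
              if (length(lens) == 0) "NA" else paste(range(lens), collapse = "-")))
  invisible(x)
}

read_fastq_validated <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) return(list(ids = character(0), reads = character(0), quals = character(0)))
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4", path, n), call. = FALSE)
  idx <- seq(1L, n, by = 4L)
  headers <- lines[idx]
  bad <- which(!startsWith(headers, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ record at line %d: header does not start with '@'",
                 idx[bad[1]]), call. = FALSE)
  plus <- lines[idx + 2L]
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ record at line %d: separator line is not '+'",
                 idx[bad[1]] + 2L), call. = FALSE)
  seqs <- lines[idx + 1L]
  quals <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("malformed FASTQ record at line %d: sequence and quality lengths differ",
                 idx[bad[1]]), call. = FALSE)
  list(ids = sub("^@", "", sub("\\s.*", "", headers)), reads = seqs, quals = quals)
}

#' Read a sequence file into a ligand library
#'
#' FASTA is parsed with Biostrings; FASTQ with a validating reader that
#' reports the line number of the first malformed record (mismatched
#' sequence/quality lengths, bad headers). Files may be gzip-compressed.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param sample_name,round,is_control metadata stored on the library.
#' @return a [ligand_library()]; record order is preserved.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           sample_name = NULL, round = 0L, is_control = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  }
  if (is.null(sample_name))
    sample_name <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path, format = "fasta")
    ids <- sub("\\s.*", "", names(ss))
    reads <- as.character(ss)
  } else {
    rec <- read_fastq_validated(path)
    ids <- rec$ids
    reads <- rec$reads
  }
  if (length(reads) == 0L) warning(sprintf("empty sequence file: %s", path))
  message(sprintf("read %d records from %s", length(reads), basename(path)))
  ligand_library(reads, ids = ids, sample_name = sample_name,
                 round = round, is_control = is_control)
}

count_flank_mismatches <- function(region, flank) {
  ## region: character vector of equal length substrings; flank: single string
  mm <- integer(length(region))
  for (j in seq_len(nchar(flank))) {
    mm <- mm + (substr(region, j, j) != substr(flank, j, j))
  }
  mm
}

#' Extract the randomized core from ligand reads
#'
#' Flank anchoring is exact-position: the 5' adaptor is expected at the very
#' start of the read and the 3' adaptor immediately after the core, as the
#' ligand architecture is fixed. Reads whose length equals `core_length`
#' exactly are accepted as already trimmed. Reads whose flanks exceed
#' `max_flank_mismatch` mismatches, reads too short to contain the full
#' architecture, and cores containing N are dropped and counted.
#'
#' @param lib a [ligand_library()].
#' @param spec an [adaptor_spec()].
#' @param max_flank_mismatch maximum total mismatches allowed across both flanks.
#' @return a [ligand_library()] of cores, with a `dropped` attribute
#'   (named integer: flank_mismatch, has_n, too_short).
#' @export
extract_cores <- function(lib, spec = adaptor_spec(), max_flank_mismatch = 0L) {
  stopifnot(inherits(lib, "ligand_library"), inherits(spec, "adaptor_spec"))
  n5 <- nchar(spec$flank5); n3 <- nchar(spec$flank3); cl <- spec$core_length
  len <- nchar(lib$reads)
  pre_trimmed <- len == cl
  full <- len >= n5 + cl + n3
  too_short <- !pre_trimmed & !full

  cores <- character(length(lib$reads))
  cores[pre_trimmed] <- lib$reads[pre_trimmed]
  keep <- pre_trimmed
  if (any(full)) {
    r <- lib$reads[full]
    mm <- count_flank_mismatches(substr(r, 1L, n5), spec$flank5) +
      count_flank_mismatches(substr(r, n5 + cl + 1L, n5 + cl + n3), spec$flank3)
    ok <- mm <= max_flank_mismatch
    cores[full] <- substr(r, n5 + 1L, n5 + cl)
    keep[full] <- ok
    n_flank <- sum(!ok)
  } else n_flank <- 0L

  has_n <- keep & grepl("N", cores, fixed = TRUE)
  keep <- keep & !has_n
  out <- ligand_library(cores[keep], ids = lib$ids[keep],
                        sample_name = lib$sample_name, round = lib$round,
                        is_control = lib$is_control)
  attr(out, "dropped") <- c(flank_mismatch = n_flank, has_n = sum(has_n),
                            too_short = sum(too_short))
  if (length(out$reads) == 0L && length(lib$reads) > 0L)
    warning("no read matched the adaptor specification; returning an empty library")
  out
}

#' Remove exact PCR duplicates
#'
#' Keeps the first occurrence of each exact sequence, preserving order.
#'
#' @param lib a [ligand_library()] of uniform-length cores.
#' @return list with `library` (deduplicated) and `n_removed`.
#' @export
dedup_exact <- function(lib) {
  stopifnot(inherits(lib, "ligand_library"))
  dup <- duplicated(lib$reads)
  out <- ligand_library(lib$reads[!dup], ids = lib$ids[!dup],
                        sample_name = lib$sample_name, round = lib$round,
                        is_control = lib$is_control)
  list(library = out, n_removed = sum(dup))
}

#' Mononucleotide-shuffled control library
#'
#' Each read is independently permuted, preserving its base composition
#' exactly. The result carries `is_control = TRUE`. A fixed seed gives a
#' byte-identical result.
#'
#' @param lib a [ligand_library()] of uniform-length reads.
#' @param seed integer RNG seed.
#' @param mode shuffle mode; only per-read mononucleotide permutation is
#'   provided (a dinucleotide-preserving shuffle is deliberately not
#'   implemented; see the methods vignette).
#' @return a shuffled [ligand_library()].
#' @export
shuffle_control <- function(lib, seed = NULL, mode = c("mononucleotide")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lib, "ligand_library"))
  if (length(lib$reads) == 0L) return(lib)
  m <- base_code_matrix(lib$reads)
  L <- ncol(m)
  shuffled <- with_seed(seed, {
    t(apply(m, 1, function(r) r[sample.int(L)]))
  })
  ligand_library(codes_to_strings(shuffled), ids = lib$ids,
                 sample_name = paste0(lib$sample_name, "_shuffled"),
                 round = lib$round, is_control = TRUE)
}

#' Write a ligand library to FASTA or FASTQ
#'
#' @param lib a [ligand_library()].
#' @param path output path; FASTQ gets constant dummy qualities ("I").
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(lib, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(inherits(lib, "ligand_library"))
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(lib$reads)
    names(ss) <- lib$ids
    Biostrings::writeXStringSet(ss, path)
  } else {
    qual <- vapply(nchar(lib$reads), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", lib$ids, "\n", lib$reads, "\n+\n", qual), path)
  }
  invisible(path)
}
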