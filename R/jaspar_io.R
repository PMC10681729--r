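## JASPAR-style PFM text reader/writer used for reference motif libraries
## and for exporting discovered motifs.

#' Read a JASPAR-style PFM file
#'
#' Accepts the bracketed four-line matrix format:
#' ```
#' >MA0001.1 NAME
#' A [ 10  5  0 ]
#' C [  0  5 20 ]
#' G [  5  5  0 ]
#' T [  5  5  0 ]
#' ```
#' Unbracketed whitespace-separated rows are also accepted.
#'
#' @param path file path.
#' @param ppm_pseudocount pseudocount per cell when normalizing counts to
#'   probabilities.
#' @return list of `motif_model`s.
#' @export
read_jaspar <- function(path, ppm_pseudocount = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no '>' header found in ", path, call. = FALSE)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    id <- parts[1]
    name <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else id
    rows <- lines[(starts[i] + 1L):(starts[i] + 4L)]
    vals <- lapply(rows, function(l) {
      l <- sub("^\\s*[ACGTacgt]?\\s*\\[?", "", l)
      l <- sub("\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1L || anyNA(unlist(vals)))
      stop("unparseable matrix for motif ", id, call. = FALSE)
    pfm <- do.call(rbind, vals)
    ppm <- sweep(pfm + ppm_pseudocount, 2, colSums(pfm + ppm_pseudocount), "/")
    out[[i]] <- new_motif_model(pfm, ppm, id = id, name = name,
                                provenance = list(source = basename(path)))
  }
  out
}

#' Write motifs as JASPAR-style PFM text
#'
#' @param motifs list of `motif_model`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$id, m$name), con)
    for (b in seq_len(4)) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(format(m$pfm[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Write motif metadata sidecar as JSON
#'
#' Provenance and information-content fields accompanying a JASPAR export.
#'
#' @param motifs list of `motif_model`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_json <- function(motifs, path) {
  meta <- lapply(motifs, function(m) list(
    id = m$id, name = m$name, consensus = m$consensus,
    width = ncol(m$ppm), seed = m$seed$kmer %||% NA,
    total_ic = m$total_ic, per_base_ic = m$per_base_ic,
    ic_per_column = m$ic_per_column, provenance = m$provenance))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
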