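# Readers and writers for the on-disk interchange formats: per-GRE
# multi-FASTA, 4-column BED, JASPAR 2022 text PFMs, and headered TSV
# matrices.

#' Write per-GRE alignments as multi-FASTA files
#'
#' One file per GRE (`<gre_id>.fa`), one record per taxon, record id =
#' taxon name.
#'
#' @param alignments Named list of named character vectors.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_alignments_fasta <- function(alignments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(alignments), function(gid) {
    path <- file.path(dir, paste0(gid, ".fa"))
    x <- Biostrings::DNAStringSet(alignments[[gid]])
    Biostrings::writeXStringSet(x, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read per-GRE alignments from a directory of multi-FASTA files
#'
#' @param dir Directory of `*.fa` files written by
#'   [write_alignments_fasta()].
#' @return Named list (GRE id = file stem) of named character vectors.
#' @export
read_alignments_fasta <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fa$", full.names = TRUE))
  if (!length(files)) abort(sprintf("no .fa files under %s", dir))
  out <- lapply(files, function(f) {
    x <- Biostrings::readDNAStringSet(f)
    stats::setNames(as.character(x), names(x))
  })
  names(out) <- sub("\\.fa$", "", basename(files))
  out
}

#' Write position frequency matrices in JASPAR text format
#'
#' @param pfms Named list of 4 x L count matrices (rows A, C, G, T).
#' @param path Output file.
#' @param tf_names Optional TF names per motif (defaults to the motif ids).
#' @return Invisibly, `path`.
#' @export
write_jaspar <- function(pfms, path, tf_names = NULL) {
  if (is.null(tf_names)) tf_names <- names(pfms)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(pfms)) {
    cat(sprintf(">%s %s\n", names(pfms)[i], tf_names[i]), file = con)
    pfm <- pfms[[i]]
    for (b in 1:4) {
      cat(sprintf("%s  [ %s ]\n", .BASES[b],
                  paste(format(pfm[b, ], trim = TRUE), collapse = " ")),
          file = con)
    }
  }
  invisible(path)
}

#' Read a JASPAR-format PFM file
#'
#' @param path JASPAR 2022 text file (`>id name` header, four bracketed
#'   count rows).
#' @return Named list of 4 x L count matrices with attribute `tf` per
#'   element.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (!length(starts)) abort("no JASPAR records found")
  out <- list()
  for (s in starts) {
    hdr <- strsplit(sub("^>", "", lines[s]), "\\s+")[[1]]
    rows <- lines[s + 1:4]
    vals <- lapply(rows, function(r) {
      as.numeric(strsplit(trimws(gsub(".*\\[|\\].*", "", r)), "\\s+")[[1]])
    })
    if (length(unique(lengths(vals))) != 1L) {
      abort("malformed JASPAR record (ragged count rows)")
    }
    m <- do.call(rbind, vals)
    rownames(m) <- .BASES
    attr(m, "tf") <- if (length(hdr) > 1) hdr[2] else hdr[1]
    out[[hdr[1]]] <- m
  }
  out
}

#' Write intervals as 4-column BED
#'
#' @param tbl Tibble with `chrom`, `start`, `end` and an id column
#'   (`gre_id`/`name`/`id`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(tbl, path) {
  idc <- intersect(c("gre_id", "name", "id"), names(tbl))[1]
  if (is.na(idc)) abort("no id column (gre_id/name/id)")
  readr::write_tsv(tbl[, c("chrom", "start", "end", idc)], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a 4-column BED file
#'
#' @param path BED file (0-based half-open).
#' @return Tibble `chrom`, `start`, `end`, `gre_id`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "gre_id"),
                  col_types = "ciic", progress = FALSE)
}

# matrix <-> headered TSV with an `id` first column
write_matrix_tsv <- function(m, path) {
  tbl <- tibble::as_tibble(m, rownames = "id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(tbl[, -1L])
  rownames(m) <- tbl[[1L]]
  m
}
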