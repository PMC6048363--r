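# Readers/writers for the delimited tables and sequence formats the
# pipeline touches. All genomic coordinates are 0-based half-open
# internally and on disk (BED convention); sequences are canonicalized
# to the DNA alphabet (U -> T, upper case).

.EVENT_COLUMNS <- c("event_id", "event_type", "chrom", "strand", "gene_id",
                    "up_start", "up_end", "alt_start", "alt_end",
                    "down_start", "down_end", "score")

#' Read a plate table
#'
#' Reads a delimited per-well table of screen readouts into a
#' [PlateSet-class]. The file must carry the annotation columns
#' `plate_id, replicate, row, col, well_role, sirna_id, gene_id`; every
#' remaining numeric column is treated as a readout.
#'
#' @param path path to a delimited text file.
#' @param sep field delimiter (default `","`).
#' @return A [PlateSet-class].
#' @export
readPlateTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("plate_id", "replicate", "row", "col", "well_role",
            "sirna_id", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("plate table format error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  PlateSet(df)
}

#' Write a plate table
#'
#' @param x a [PlateSet-class].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
writePlateTable <- function(x, path, sep = ",") {
  stopifnot(is(x, "PlateSet"))
  write.table(wells(x), path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a splicing event table
#'
#' Reads the BED-derived event table used throughout the splicing and
#' RNA-map stages. Columns (tab-separated, in order):
#' `event_id, event_type, chrom, strand, gene_id, up_start, up_end,
#' alt_start, alt_end, down_start, down_end, score`. Coordinates are
#' 0-based half-open; `up`/`alt`/`down` are the upstream exon, the
#' alternative region and the downstream exon, ordered along the genomic
#' axis (so on the minus strand `up_*` is genomically rightmost... the
#' intervals are stored in genomic order and the strand decides which
#' boundary is the 3' splice site).
#'
#' @param path path to a tab-separated event table.
#' @return data.frame with the columns above.
#' @export
readEventsBed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.EVENT_COLUMNS, names(df))
  if (length(miss) > 0)
    stop(sprintf("event table format error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  df <- df[, .EVENT_COLUMNS]
  validateEvents(df)
  df
}

#' @rdname readEventsBed
#' @param events event data.frame to validate or write.
#' @export
validateEvents <- function(events) {
  bad_type <- setdiff(unique(events$event_type), .EVENT_TYPES)
  if (length(bad_type) > 0)
    stop(sprintf("event table format error: unknown event_type %s",
                 paste(bad_type, collapse = ", ")))
  bad_strand <- setdiff(unique(events$strand), c("+", "-"))
  if (length(bad_strand) > 0)
    stop(sprintf("event table format error: strand must be + or -, got %s",
                 paste(bad_strand, collapse = ", ")))
  for (reg in c("up", "alt", "down")) {
    s <- events[[paste0(reg, "_start")]]
    e <- events[[paste0(reg, "_end")]]
    bad <- which(s >= e)
    if (length(bad) > 0)
      stop(sprintf(
        "event table format error: start >= end for %s interval of event %s",
        reg, events$event_id[bad[1L]]))
  }
  bad <- which(!(events$up_end <= events$alt_start &
                   events$alt_end <= events$down_start))
  if (length(bad) > 0)
    stop(sprintf(
      "event table format error: intervals overlap or are unordered for event %s",
      events$event_id[bad[1L]]))
  invisible(TRUE)
}

#' @rdname readEventsBed
#' @export
writeEventsBed <- function(events, path) {
  validateEvents(events)
  write.table(events[, .EVENT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Sequences are upper-cased and canonicalized to the DNA alphabet
#' (`U` is accepted and stored as `T`); characters outside
#' `{A,C,G,T,U,N}` are a format error.
#'
#' @param path path to a FASTA file.
#' @return `readFasta`: a named character vector of sequences.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(sprintf("FASTA format error: invalid characters in record '%s'",
                 names(seqs)[which(bad)[1L]]))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' @rdname readFasta
#' @param seqs named character vector of sequences.
#' @export
writeFasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(chartr("U", "T", toupper(seqs))), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then tab-separated member
#' gene ids.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT format error: line with fewer than 3 fields: '%s'",
                   substr(l, 1, 40)))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions (default `"na"`).
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample count matrix
#'
#' Tab-separated, first column = gene id, remaining columns = samples.
#'
#' @param path path to the TSV.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
readCountsTsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("count matrix format error: non-numeric entries")
  rownames(m) <- df[[1L]]
  m
}

#' @rdname readCountsTsv
#' @param mat numeric matrix with gene rownames.
#' @export
writeCountsTsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table with stable column order
#'
#' @param records data.frame of results.
#' @param path output path.
#' @export
writeResultsTsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif matrix from TSV
#'
#' Four rows named A/C/G/U (or T), one column per motif position. A
#' synthetic CU-rich example matrix (a stand-in for published
#' polypyrimidine-tract-binding motifs, not a published matrix) ships
#' with the package:
#' `system.file("extdata", "cu_rich_motif_synthetic.tsv", package = "sasptools")`.
#'
#' @param path path to the TSV.
#' @inheritParams motifMatrix
#' @return A [MotifMatrix-class].
#' @export
readMotifMatrix <- function(path, background = rep(0.25, 4),
                            pseudocount = 1e-3) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.delim(path, row.names = 1L)
  motifMatrix(as.matrix(df), background = background,
              pseudocount = pseudocount)
}
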