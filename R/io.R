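#' Read a FASTA file as a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] accepting wrapped or
#' unwrapped, plain or gzipped multi-record FASTA. Record names are
#' truncated at the first whitespace, matching common annotation usage.
#'
#' @param path Path to the FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("FASTA file not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                 error = function(e) stop("cannot read FASTA '", path,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = as.integer(width))
  invisible(path)
}

.motif_tsv_cols <- c("Sequence_name", "Source", "Type", "Start", "Stop",
                     "Length", "Unit", "Copies", "Sequence")

#' Write motif hits to a tab-separated file
#'
#' Serializes a hit table (from [scan_zdna()]/[scan_str()]) in a
#' tab-separated layout with columns `Sequence_name`, `Source`, `Type`,
#' `Start`, `Stop`, `Length`, `Unit`, `Copies`, `Sequence`; coordinates are
#' 1-based inclusive. The file round-trips exactly through
#' [read_motif_tsv()].
#'
#' @param hits Hit data frame.
#' @param path Output path.
#' @param source Value for the `Source` column.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(hits, path, source = "zdnaphylo") {
  stopifnot(is.data.frame(hits))
  need <- c("seq_id", "start", "stop", "length", "motif_class", "unit",
            "copies", "sequence")
  if (!all(need %in% names(hits)))
    stop("hits is missing columns: ",
         paste(setdiff(need, names(hits)), collapse = ", "))
  if (nrow(hits) > 0L && any(hits$stop < hits$start))
    stop("invalid hits: Stop < Start")
  if (nrow(hits) == 0L) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(.motif_tsv_cols, collapse = "\t"), con)
    return(invisible(path))
  }
  out <- data.frame(
    Sequence_name = hits$seq_id,
    Source = source,
    Type = hits$motif_class,
    Start = hits$start,
    Stop = hits$stop,
    Length = hits$length,
    Unit = hits$unit,
    Copies = ifelse(is.na(hits$copies), "", as.character(hits$copies)),
    Sequence = hits$sequence,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.motif_tsv_cols, collapse = "\t"), con)
  if (nrow(out) > 0L)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read motif hits from a tab-separated file
#'
#' Inverse of [write_motif_tsv()]. Malformed lines (wrong field count,
#' non-numeric coordinates, `Stop < Start`, inconsistent `Length`) raise an
#' error naming the 1-based line number.
#'
#' @param path Path to a motif TSV.
#' @return Hit data frame as produced by the scanners.
#' @export
read_motif_tsv <- function(path) {
  if (!file.exists(path)) stop("motif TSV not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("motif TSV '", path, "' is empty")
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr, .motif_tsv_cols))
    stop("line 1: unexpected header in '", path, "'")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(.empty_hits())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty Sequence field would be a data error anyway; require 9
  bad <- which(nf != 9L)
  if (length(bad) > 0L)
    stop("line ", bad[1L] + 1L, ": expected 9 tab-separated fields, got ",
         nf[bad[1L]])
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4L]))
  stop_ <- suppressWarnings(as.integer(m[, 5L]))
  len <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(start) | is.na(stop_) | is.na(len))
  if (length(bad) > 0L)
    stop("line ", bad[1L] + 1L, ": non-integer coordinate field")
  bad <- which(stop_ < start)
  if (length(bad) > 0L)
    stop("line ", bad[1L] + 1L, ": Stop < Start")
  bad <- which(len != stop_ - start + 1L)
  if (length(bad) > 0L)
    stop("line ", bad[1L] + 1L, ": Length != Stop - Start + 1")
  copies <- suppressWarnings(as.integer(m[, 8L]))
  copies[m[, 8L] == ""] <- NA_integer_
  data.frame(
    seq_id = m[, 1L], start = start, stop = stop_, length = len,
    motif_class = m[, 3L], unit = m[, 7L], copies = copies,
    sequence = m[, 9L], stringsAsFactors = FALSE
  )
}
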