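#' Scanner parameters
#'
#' Bundle of thresholds controlling Z-DNA and short tandem repeat (STR)
#' detection. Defaults follow the conventions of non-B DNA motif search
#' tools: Z-DNA tracts are maximal alternating purine/pyrimidine runs of at
#' least 10 nt with A-T steps disallowed; STRs are perfect tandem arrays of
#' a primitive 2-6 bp unit with at least 3 full copies spanning at least
#' 10 nt.
#'
#' @param zdna_min_len Minimum Z-DNA tract length in nucleotides (>= 2).
#' @param zdna_allow_at_steps Permit adjacent A/T pairs inside a Z-DNA
#'   tract. ApT and TpA dinucleotide steps have poor Z-forming propensity
#'   and are excluded by default.
#' @param str_unit_min,str_unit_max Bounds on the primitive repeat unit
#'   length in bp (1 <= min <= max <= 9).
#' @param str_min_copies Minimum number of complete unit copies (>= 2).
#' @param str_min_len Minimum STR tract length in nucleotides, counting a
#'   partial trailing copy.
#' @param include_softmasked Scan lowercase (soft-masked) bases as if
#'   uppercase. If `FALSE`, lowercase bases terminate tracts like `N`.
#' @return An object of class `scan_params` (a named list).
#' @export
#' @examples
#' scan_params(zdna_min_len = 12)
scan_params <- function(zdna_min_len = 10L,
                        zdna_allow_at_steps = FALSE,
                        str_unit_min = 2L,
                        str_unit_max = 6L,
                        str_min_copies = 3L,
                        str_min_len = 10L,
                        include_softmasked = TRUE) {
  p <- list(
    zdna_min_len = as.integer(zdna_min_len),
    zdna_allow_at_steps = isTRUE(zdna_allow_at_steps),
    str_unit_min = as.integer(str_unit_min),
    str_unit_max = as.integer(str_unit_max),
    str_min_copies = as.integer(str_min_copies),
    str_min_len = as.integer(str_min_len),
    include_softmasked = isTRUE(include_softmasked)
  )
  if (is.na(p$zdna_min_len) || p$zdna_min_len < 2L)
    stop("zdna_min_len must be >= 2")
  if (is.na(p$str_unit_min) || is.na(p$str_unit_max) ||
      p$str_unit_min < 1L || p$str_unit_min > p$str_unit_max ||
      p$str_unit_max > 9L)
    stop("need 1 <= str_unit_min <= str_unit_max <= 9")
  if (is.na(p$str_min_copies) || p$str_min_copies < 2L)
    stop("str_min_copies must be >= 2")
  if (is.na(p$str_min_len) || p$str_min_len < 1L)
    stop("str_min_len must be >= 1")
  class(p) <- "scan_params"
  p
}

#' @export
print.scan_params <- function(x, ...) {
  cat("Motif scan parameters\n")
  cat(sprintf("  Z-DNA : min length %d nt, A-T steps %s\n",
              x$zdna_min_len,
              if (x$zdna_allow_at_steps) "allowed" else "excluded"))
  cat(sprintf("  STR   : unit %d-%d bp, >= %d copies, min length %d nt\n",
              x$str_unit_min, x$str_unit_max, x$str_min_copies,
              x$str_min_len))
  cat(sprintf("  soft-masked bases %s\n",
              if (x$include_softmasked) "scanned" else "skipped"))
  invisible(x)
}

# Encode a nucleotide string as integer codes 1=A 2=C 3=G 4=T, NA otherwise.
# Lowercase handling depends on include_softmasked.
.encode_seq <- function(seq, include_softmasked = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (include_softmasked)
    seq <- chartr("acgtn", "ACGTN", seq)
  b <- as.integer(charToRaw(seq))
  match(b, c(65L, 67L, 71L, 84L))  # A C G T
}

# Empty hit table with canonical column order/types.
.empty_hits <- function() {
  data.frame(
    seq_id = character(0), start = integer(0), stop = integer(0),
    length = integer(0), motif_class = character(0), unit = character(0),
    copies = integer(0), sequence = character(0),
    stringsAsFactors = FALSE
  )
}

.check_scan_args <- function(seq, seq_id, params) {
  if (!is.character(seq_id) || length(seq_id) != 1L || is.na(seq_id) ||
      !nzchar(seq_id))
    stop("seq_id must be a non-empty string")
  if (!inherits(params, "scan_params"))
    stop("params must be created by scan_params()")
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("seq must be a single character string")
}

#' Detect Z-DNA-prone motifs in a nucleotide sequence
#'
#' Reports every maximal tract in which each adjacent base pair alternates
#' purine (A/G) vs pyrimidine (C/T) -- the hallmark of Z-DNA-forming
#' sequence such as (TG)n, (CA)n and (GC)n repeats -- subject to the
#' thresholds in `params`. A/T adjacencies are excluded unless
#' `zdna_allow_at_steps` is set, and any non-ACGT symbol (e.g. `N`, or
#' lowercase when soft-masked bases are skipped) terminates a tract.
#' Maximality means no reported tract can be extended in either direction
#' and remain valid, so hits never overlap.
#'
#' @param seq A single nucleotide string over `A,C,G,T,N` (case per
#'   `params$include_softmasked`).
#' @param seq_id Sequence (contig) identifier; must be non-empty.
#' @param params A [scan_params()] object.
#' @return A data frame of motif hits with columns `seq_id`, `start`,
#'   `stop` (1-based, inclusive), `length`, `motif_class` (`"ZDNA"`),
#'   `unit` (empty), `copies` (`NA`), `sequence`, ordered by `start`.
#' @seealso [scan_str()], [scan_fasta()], [write_motif_tsv()]
#' @export
#' @examples
#' scan_zdna(strrep("TG", 19), "chr1", scan_params())
scan_zdna <- function(seq, seq_id, params = scan_params()) {
  .check_scan_args(seq, seq_id, params)
  code <- .encode_seq(seq, params$include_softmasked)
  n <- length(code)
  if (n < params$zdna_min_len) return(.empty_hits())
  a <- code[-n]
  b <- code[-1L]
  pur_a <- a == 1L | a == 3L
  pur_b <- b == 1L | b == 3L
  ok <- !is.na(a) & !is.na(b) & xor(pur_a, pur_b)
  if (!params$zdna_allow_at_steps)
    ok <- ok & !((a == 1L & b == 4L) | (a == 4L & b == 1L))
  ok[is.na(ok)] <- FALSE

  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$zdna_min_len - 1L
  if (!any(keep)) return(.empty_hits())
  s <- starts[keep]            # first step index -> tract start position
  e <- ends[keep] + 1L         # last step index + 1 -> tract stop position
  data.frame(
    seq_id = seq_id, start = s, stop = e, length = e - s + 1L,
    motif_class = "ZDNA", unit = "", copies = NA_integer_,
    sequence = substring(seq, s, e),
    stringsAsFactors = FALSE
  )
}

# Is `unit` (integer codes) primitive, i.e. not a whole-number repetition of
# a shorter string?
.is_primitive_unit <- function(unit) {
  u <- length(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (all(unit == rep_len(unit[seq_len(d)], u))) return(FALSE)
  }
  TRUE
}

#' Detect perfect short tandem repeats (STRs)
#'
#' Reports maximal perfect tandem arrays whose primitive repeat unit length
#' lies within `[str_unit_min, str_unit_max]`, with at least
#' `str_min_copies` complete copies and total tract length at least
#' `str_min_len`. A partial trailing copy extends the tract (and its `stop`)
#' but does not count toward `copies`. Each tract is reported once, labelled
#' by its primitive unit read in leftmost phase. Tracts with the same unit
#' never overlap; tracts with different units may.
#'
#' @inheritParams scan_zdna
#' @return A data frame as in [scan_zdna()] with `motif_class = "STR"`,
#'   `unit` the primitive repeat unit and `copies` the number of full
#'   copies, ordered by `start`, then `stop`, then `unit`.
#' @export
#' @examples
#' scan_str("ACACACACACAC", "chr1", scan_params())
scan_str <- function(seq, seq_id, params = scan_params()) {
  .check_scan_args(seq, seq_id, params)
  code <- .encode_seq(seq, params$include_softmasked)
  n <- length(code)
  if (n < params$str_min_len) return(.empty_hits())
  acgt <- !is.na(code)
  out <- vector("list", params$str_unit_max - params$str_unit_min + 1L)
  ii <- 0L
  for (u in params$str_unit_min:params$str_unit_max) {
    if (n < u + 1L) break
    # m[i]: position i matches position i+u and both are A/C/G/T
    i1 <- seq_len(n - u)
    m <- acgt[i1] & acgt[i1 + u] & code[i1] == code[i1 + u]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep) == 0L) next
    s <- starts[keep]
    stop_ <- ends[keep] + u          # run end matched against +u
    len <- stop_ - s + 1L
    copies <- len %/% u
    sel <- copies >= params$str_min_copies & len >= params$str_min_len
    if (!any(sel)) next
    s <- s[sel]; stop_ <- stop_[sel]; len <- len[sel]; copies <- copies[sel]
    prim <- vapply(s, function(p) .is_primitive_unit(code[p:(p + u - 1L)]),
                   logical(1))
    if (!any(prim)) next
    s <- s[prim]; stop_ <- stop_[prim]; len <- len[prim]
    copies <- copies[prim]
    ii <- ii + 1L
    out[[ii]] <- data.frame(
      seq_id = seq_id, start = s, stop = stop_, length = len,
      motif_class = "STR",
      unit = substring(seq, s, s + u - 1L),
      copies = as.integer(copies),
      sequence = substring(seq, s, stop_),
      stringsAsFactors = FALSE
    )
  }
  if (ii == 0L) return(.empty_hits())
  hits <- do.call(rbind, out[seq_len(ii)])
  hits <- hits[order(hits$start, hits$stop, hits$unit), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a FASTA file for Z-DNA and STR motifs
#'
#' Applies [scan_zdna()] and/or [scan_str()] to every record of a
#' (optionally gzipped) FASTA file.
#'
#' @param path Path to a FASTA file.
#' @param params A [scan_params()] object.
#' @param classes Motif classes to scan, subset of `c("ZDNA", "STR")`.
#' @return A hit data frame (see [scan_zdna()]) over all records, ordered
#'   by record, class and start.
#' @export
scan_fasta <- function(path, params = scan_params(),
                       classes = c("ZDNA", "STR")) {
  classes <- match.arg(classes, several.ok = TRUE)
  seqs <- read_fasta(path)
  out <- list()
  for (id in names(seqs)) {
    if ("ZDNA" %in% classes)
      out[[length(out) + 1L]] <- scan_zdna(seqs[[id]], id, params)
    if ("STR" %in% classes)
      out[[length(out) + 1L]] <- scan_str(seqs[[id]], id, params)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(.empty_hits())
  res <- res[order(match(res$seq_id, names(seqs)), res$start,
                   res$motif_class, res$stop, res$unit), , drop = FALSE]
  rownames(res) <- NULL
  res
}
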