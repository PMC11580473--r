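#' Extract one start-codon record per gene from a GTF/GFF annotation
#'
#' Uses `start_codon` features when the annotation provides them, otherwise
#' falls back to the 5' end of the 5'-most CDS. When a gene has several
#' transcripts the 5'-most start codon is kept (smallest coordinate on the
#' `+` strand, largest on `-`). The supported dialects are the GTF layouts
#' exported by the UCSC table browser (`augustus`, `ncbiRefSeq`,
#' `xenoRefGene`); they share attribute conventions, so the dialect mainly
#' documents provenance and is validated against the supported list.
#'
#' @param path Path to a GTF/GFF file.
#' @param dialect One of `"augustus"`, `"ncbiRefSeq"`, `"xenoRefGene"`.
#' @return Data frame with columns `gene_id`, `seq_id`, `strand`
#'   (`"+"`/`"-"`) and `start_codon_pos`, the genomic coordinate (1-based)
#'   of the first base of the start codon on its strand.
#' @export
extract_start_codons <- function(path,
                                 dialect = c("augustus", "ncbiRefSeq",
                                             "xenoRefGene")) {
  if (!is.character(dialect) || length(dialect) < 1L ||
      !all(dialect %in% c("augustus", "ncbiRefSeq", "xenoRefGene")))
    stop("unknown annotation dialect; supported: augustus, ncbiRefSeq, ",
         "xenoRefGene")
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("cannot parse annotation '", path,
                                          "': ", conditionMessage(e)))
  md <- as.data.frame(gr)
  types <- tolower(as.character(md$type))
  use <- which(types == "start_codon")
  if (length(use) == 0L) use <- which(types == "cds")
  if (length(use) == 0L)
    stop("no start_codon or CDS features found in '", path, "'")
  md <- md[use, , drop = FALSE]
  gid <- if (!is.null(md$gene_id)) as.character(md$gene_id)
         else if (!is.null(md$transcript_id)) as.character(md$transcript_id)
         else stop("annotation '", path, "' lacks gene_id/transcript_id ",
                   "attributes")
  bad <- is.na(gid) | !nzchar(gid)
  if (any(bad) && !is.null(md$transcript_id))
    gid[bad] <- as.character(md$transcript_id)[bad]
  strand <- as.character(md$strand)
  if (any(!strand %in% c("+", "-")))
    stop("features without +/- strand cannot anchor an upstream window")
  # per (gene, strand, seq): 5'-most position over all features/transcripts
  pos <- ifelse(strand == "+", md$start, md$end)
  spl <- split(data.frame(pos = pos, strand = strand,
                          seq = as.character(md$seqnames),
                          gid = gid, stringsAsFactors = FALSE),
               gid)
  out <- lapply(spl, function(d) {
    # a gene is assumed to live on one contig/strand; take the first
    s <- d$strand[[1L]]
    p <- if (s == "+") min(d$pos) else max(d$pos)
    data.frame(gene_id = d$gid[[1L]], seq_id = d$seq[[1L]], strand = s,
               start_codon_pos = as.integer(p), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$seq_id, res$start_codon_pos), , drop = FALSE]
}

#' Assign motifs to upstream windows of start codons
#'
#' For each gene, considers the window of `L` bp immediately upstream of
#' the start codon (`[pos - L, pos - 1]` on `+`, `[pos + 1, pos + L]` on
#' `-`). A motif is assigned to the gene when its anchor coordinate falls
#' inside the window. Under the default `"oriented"` convention the anchor
#' is the motif end nearest the gene in transcription direction (the
#' `stop` column on `+`, the `start` column on `-`); the `"genomic"`
#' convention uses the `stop` column for both strands. `distance_bp` is
#' the 1-based distance from the start codon, and `bin_index =
#' ceiling(distance_bp / bin_bp)`. One assignment is made per (gene,
#' motif) pair; a motif may serve several genes.
#'
#' @param genes Data frame from [extract_start_codons()].
#' @param hits Motif hit data frame (typically Z-DNA hits).
#' @param L Window length in bp; must be a positive multiple of `bin_bp`.
#' @param convention `"oriented"` (default) or `"genomic"`.
#' @param bin_bp Distance bin width in bp.
#' @param seq_lengths Optional named vector of contig lengths used to flag
#'   windows truncated by contig ends.
#' @return Data frame with columns `gene_id`, `seq_id`, `motif_start`,
#'   `motif_stop`, `anchor`, `distance_bp`, `bin_index`, `truncated`.
#' @export
assign_upstream_motifs <- function(genes, hits, L = 10000L,
                                   convention = c("oriented", "genomic"),
                                   bin_bp = 1000L, seq_lengths = NULL) {
  convention <- match.arg(convention)
  L <- as.numeric(L); bin_bp <- as.numeric(bin_bp)
  if (is.na(L) || L <= 0 || L %% bin_bp != 0)
    stop("L must be a positive multiple of the bin width (", bin_bp, " bp)")
  stopifnot(is.data.frame(genes), is.data.frame(hits))
  empty <- data.frame(
    gene_id = character(0), seq_id = character(0),
    motif_start = integer(0), motif_stop = integer(0), anchor = integer(0),
    distance_bp = integer(0), bin_index = integer(0), truncated = logical(0),
    stringsAsFactors = FALSE
  )
  if (nrow(genes) == 0L || nrow(hits) == 0L) return(empty)
  hit_by_seq <- split(hits, hits$seq_id)
  out <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    h <- hit_by_seq[[genes$seq_id[[g]]]]
    if (is.null(h)) next
    pos <- genes$start_codon_pos[[g]]
    if (genes$strand[[g]] == "+") {
      anchor <- h$stop
      lo <- pos - L; hi <- pos - 1
      truncated <- lo < 1
      lo <- max(lo, 1)
      dist <- pos - anchor
    } else {
      anchor <- if (convention == "oriented") h$start else h$stop
      lo <- pos + 1; hi <- pos + L
      clen <- seq_lengths[[genes$seq_id[[g]]]]
      truncated <- !is.null(clen) && hi > clen
      if (!is.null(clen)) hi <- min(hi, clen)
      dist <- anchor - pos
    }
    in_win <- anchor >= lo & anchor <= hi
    if (!any(in_win)) next
    out[[g]] <- data.frame(
      gene_id = genes$gene_id[[g]], seq_id = genes$seq_id[[g]],
      motif_start = h$start[in_win], motif_stop = h$stop[in_win],
      anchor = anchor[in_win], distance_bp = as.integer(dist[in_win]),
      bin_index = as.integer(ceiling(dist[in_win] / bin_bp)),
      truncated = truncated, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Positional motif profile for one species
#'
#' Sums upstream assignments over all genes into counts per distance bin.
#'
#' @param assignments Data frame from [assign_upstream_motifs()] for one
#'   species.
#' @param k Number of distance bins (columns of the region matrix).
#' @return List with `bin_counts` (integer vector of length `k`, names
#'   `"bin1"..`) and `distance_counts` (data frame of per-distance tallies).
#' @export
positional_profile <- function(assignments, k = 10L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  stopifnot(is.data.frame(assignments))
  bins <- integer(k)
  names(bins) <- paste0("bin", seq_len(k))
  if (nrow(assignments) > 0L) {
    if (any(assignments$bin_index > k))
      stop("assignment bin_index exceeds k = ", k)
    t0 <- table(factor(assignments$bin_index, levels = seq_len(k)))
    bins[] <- as.integer(t0)
  }
  dist_counts <- if (nrow(assignments) > 0L) {
    d <- as.data.frame(table(assignments$distance_bp),
                       stringsAsFactors = FALSE)
    names(d) <- c("distance_bp", "count")
    d$distance_bp <- as.integer(d$distance_bp)
    d
  } else {
    data.frame(distance_bp = integer(0), count = integer(0))
  }
  list(bin_counts = bins, distance_counts = dist_counts)
}

#' Species-by-region count matrix
#'
#' Stacks per-species bin counts (from [positional_profile()]) into the
#' complete species x distance-bin matrix fed to the Friedman/Nemenyi
#' battery.
#'
#' @param profiles Named list of per-species `bin_counts` vectors (or
#'   [positional_profile()] results).
#' @return Integer matrix, rows = species, columns = bins.
#' @export
region_matrix <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0L ||
      is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a non-empty named list")
  rows <- lapply(profiles, function(p) {
    if (is.list(p) && !is.null(p$bin_counts)) p$bin_counts else p
  })
  ks <- lengths(rows)
  if (length(unique(ks)) != 1L)
    stop("all species profiles must have the same number of bins")
  m <- do.call(rbind, rows)
  storage.mode(m) <- "integer"
  if (anyNA(m)) stop("region matrix must be complete (no missing cells)")
  m
}

#' Select the top fraction of genes by upstream motif count
#'
#' Ranks genes by count (descending), takes `m = ceiling(q * G)` genes and
#' returns every gene whose count is at least that of the m-th gene, so the
#' result is a tie-inclusive superset of the strict top `m`.
#'
#' @param counts Named numeric/integer vector of per-gene motif counts.
#' @param q Fraction in (0, 1); default 0.05 (top 5 percent).
#' @return List with `genes` (character vector), `threshold` (count of the
#'   m-th gene) and `m`.
#' @export
#' @examples
#' top_percent_genes(setNames(c(9, 8, 7, 6, 5, 5, 5, rep(0, 93)),
#'                            paste0("g", 1:100)))
top_percent_genes <- function(counts, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    stop("q must lie strictly between 0 and 1")
  if (length(counts) < 1L) stop("need at least one gene")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by gene id")
  G <- length(counts)
  m <- as.integer(ceiling(q * G))
  sorted <- sort(counts, decreasing = TRUE)
  threshold <- unname(sorted[[m]])
  genes <- names(counts)[counts >= threshold]
  list(genes = genes, threshold = threshold, m = m)
}

#' Write a gene list (one id per line)
#'
#' Plain-text export suitable for external GO/enrichment services.
#'
#' @param genes Character vector of gene ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}
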