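#' Total assembly length of a FASTA file
#'
#' Sums the lengths of all records. Every symbol counts, including `N`
#' (assembly gaps) and soft-masked lowercase bases; set `ungapped = TRUE`
#' to exclude `N`/`n` positions.
#'
#' @param fasta Path to a FASTA file.
#' @param ungapped Exclude `N` symbols from the total.
#' @return Genome size in bp (numeric scalar).
#' @export
genome_size <- function(fasta, ungapped = FALSE) {
  if (!is.character(fasta) || length(fasta) != 1L || !file.exists(fasta))
    stop("FASTA file not found: ", fasta)
  ss <- tryCatch(Biostrings::readDNAStringSet(fasta, format = "fasta"),
                 error = function(e) stop("cannot read FASTA '", fasta,
                                          "': ", conditionMessage(e)))
  if (length(ss) == 0L) stop("FASTA file '", fasta, "' contains no records")
  total <- sum(as.numeric(Biostrings::width(ss)))
  if (ungapped) {
    freq <- Biostrings::alphabetFrequency(ss, collapse = TRUE)
    total <- total - as.numeric(freq[["N"]])
  }
  total
}

#' Motif density in motifs per megabase
#'
#' @param count Motif count (>= 0).
#' @param genome_size_bp Genome size in bp (> 0).
#' @return `count * 1e6 / genome_size_bp`.
#' @export
#' @examples
#' motif_density(150, 1.5e6)  # 100 motifs/Mb
motif_density <- function(count, genome_size_bp) {
  if (!is.numeric(genome_size_bp) || any(genome_size_bp <= 0))
    stop("genome_size_bp must be > 0")
  if (!is.numeric(count) || any(count < 0))
    stop("count must be >= 0")
  count * 1e6 / genome_size_bp
}

#' Per-species genome/motif summary
#'
#' @param species Species label (must match a phylogeny tip label for the
#'   comparative stages).
#' @param genome_size_bp Assembly size in bp.
#' @param zdna_count,str_count Motif counts.
#' @return A one-row data frame with densities in motifs/Mb.
#' @export
species_summary <- function(species, genome_size_bp, zdna_count, str_count) {
  if (!is.character(species) || length(species) != 1L || !nzchar(species))
    stop("species must be a non-empty string")
  data.frame(
    species = species,
    genome_size_bp = as.numeric(genome_size_bp),
    zdna_count = as.integer(zdna_count),
    str_count = as.integer(str_count),
    zdna_density_per_mb = motif_density(zdna_count, genome_size_bp),
    str_density_per_mb = motif_density(str_count, genome_size_bp),
    stringsAsFactors = FALSE
  )
}

#' Assemble the multi-species density table
#'
#' Binds per-species summaries (from [species_summary()]) into the table
#' consumed by the phylogenetic stages, keyed by species label.
#'
#' @param summaries A list of one-row summary data frames, or a single
#'   data frame with the same columns.
#' @return Data frame with columns `species`, `genome_size_bp`,
#'   `zdna_count`, `str_count`, `zdna_density_per_mb`,
#'   `str_density_per_mb`.
#' @export
build_density_table <- function(summaries) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  if (!is.list(summaries) || length(summaries) == 0L)
    stop("summaries must be a non-empty list of species summaries")
  tab <- do.call(rbind, summaries)
  cols <- c("species", "genome_size_bp", "zdna_count", "str_count",
            "zdna_density_per_mb", "str_density_per_mb")
  if (!all(cols %in% names(tab)))
    stop("summaries missing columns: ",
         paste(setdiff(cols, names(tab)), collapse = ", "))
  tab <- tab[, cols, drop = FALSE]
  dup <- unique(tab$species[duplicated(tab$species)])
  if (length(dup) > 0L)
    stop("duplicate species in density table: ", paste(dup, collapse = ", "))
  rownames(tab) <- NULL
  tab
}

#' Write/read the density table as CSV
#'
#' @param tab Density table from [build_density_table()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_density_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) {
  if (!file.exists(path)) stop("density CSV not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  build_density_table(tab)
}
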