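#' Read a taxonomy table
#'
#' Reads a tab-separated table assigning each protein record to a species and
#' a higher-level taxonomic group. The table must carry the columns `id`,
#' `species` and `taxon_group`, with every `id` appearing exactly once.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` with columns `id`, `species`, `taxon_group`.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) .stopf("taxonomy file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "taxon_group")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    .stopf("taxonomy table lacks column(s): %s", paste(miss, collapse = ", "))
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup))
    .stopf("duplicate id in taxonomy table: '%s'", dup[1])
  tab[need]
}

#' Read candidate protein sequences from FASTA
#'
#' Headers are either `id|species|taxon_group` (a single FASTA then carries
#' its own taxonomy) or a plain id, in which case species and group are
#' joined from a taxonomy table. Sequences are uppercased and a terminal
#' `*` stop symbol is stripped; any other non-standard residue is an error.
#'
#' @param path Path to a protein FASTA file.
#' @param taxonomy Optional `data.frame` from [readTaxonomy()] used to
#'   resolve plain-id headers.
#' @return An [Biostrings::AAStringSet] named by record id, with
#'   `species`, `taxon_group` and `source` in its `mcols()`.
#' @export
readProteinFasta <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  raw <- Biostrings::readAAStringSet(path)
  if (length(raw) == 0L) .stopf("empty FASTA file: %s", path)
  headers <- sub("\\s.*$", "", names(raw))
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (any(ids == "")) .stopf("empty id in FASTA header")
  dup <- ids[duplicated(ids)]
  if (length(dup)) .stopf("duplicate id in FASTA: '%s'", dup[1])
  if (any(grepl("[(),:;]", ids)))
    .stopf("id '%s' contains characters reserved by Newick",
           ids[grepl("[(),:;]", ids)][1])
  species <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_, "")
  group <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_, "")
  if (!is.null(taxonomy)) {
    hit <- match(ids, taxonomy$id)
    fill <- is.na(species)
    if (any(fill & is.na(hit)))
      .stopf("id '%s' absent from taxonomy table", ids[fill & is.na(hit)][1])
    species[fill] <- taxonomy$species[hit[fill]]
    group[fill] <- taxonomy$taxon_group[hit[fill]]
  }
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) .stopf("empty sequence for record '%s'", ids[i])
    .checkResidues(seqs[i], ids[i])
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    species = species, taxon_group = group, source = basename(path))
  out
}

#' Write a protein set to FASTA
#'
#' Emits `id|species|taxon_group` headers when metadata are present in
#' `mcols()`, otherwise plain ids.
#'
#' @param proteins An `AAStringSet` as returned by [readProteinFasta()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeProteinFasta <- function(proteins, path) {
  md <- S4Vectors::mcols(proteins)
  ids <- names(proteins)
  if (!is.null(md) && all(c("species", "taxon_group") %in% names(md)) &&
      !anyNA(md$species)) {
    hdr <- paste(ids, md$species, md$taxon_group, sep = "|")
  } else hdr <- ids
  out <- proteins
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

.detectAlignmentFormat <- function(path) {
  first <- readLines(path, n = 25L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (!length(first)) .stopf("empty alignment file: %s", path)
  if (startsWith(first[1], ">")) "fasta"
  else if (grepl("^CLUSTAL", first[1], ignore.case = TRUE)) "clustal"
  else .stopf("cannot detect alignment dialect of %s", path)
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal dialects; gap characters are normalized
#' to `-` (a `.` on input is accepted as a gap). All rows must have equal
#' length.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (detect from content), `"fasta"` or `"clustal"`.
#' @return A named character vector of equal-length gapped rows.
#' @export
readAlignmentFile <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("alignment file not found: %s", path)
  if (format == "auto") format <- .detectAlignmentFormat(path)
  if (format == "fasta") {
    raw <- Biostrings::readAAStringSet(path)
    if (length(raw) == 0L) .stopf("empty alignment file: %s", path)
    rows <- as.character(raw)
    names(rows) <- sub("\\s.*$", "", names(raw))
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    rows <- as.character(aln)
  }
  rows <- chartr(".", "-", toupper(rows))
  w <- nchar(rows)
  if (length(unique(w)) > 1L) {
    off <- names(rows)[w != w[1]][1]
    .stopf("ragged alignment rows (id '%s': %d columns vs %d)",
           off, nchar(rows[[off]]), w[1])
  }
  rows
}

#' Write a multiple sequence alignment
#'
#' @param aln Named character vector of equal-length gapped rows.
#' @param path Output file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return Invisibly, `path`.
#' @export
writeAlignmentFile <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  stopifnot(length(aln) > 0L, !is.null(names(aln)))
  if (length(unique(nchar(aln))) > 1L) .stopf("ragged rows cannot be written")
  if (format == "fasta") {
    writeLines(paste0(">", names(aln), "\n", aln), path)
  } else {
    width <- max(nchar(names(aln))) + 3L
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("CLUSTAL W multiple sequence alignment", "", ""), con)
    ncol <- nchar(aln[[1]])
    for (from in seq(1L, ncol, by = 60L)) {
      to <- min(from + 59L, ncol)
      chunk <- substr(aln, from, to)
      writeLines(sprintf("%-*s%s", width, names(aln), chunk), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Write a results table as TSV
#'
#' Writes a header row and one row per record; numeric columns are rendered
#' with six significant digits so repeated runs diff byte-for-byte.
#'
#' @param rows A `data.frame` (zero rows allowed).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeResultsTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmtNum(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a results table written by [writeResultsTable()]
#'
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
readResultsTable <- function(path) {
  if (!file.exists(path)) .stopf("results table not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
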