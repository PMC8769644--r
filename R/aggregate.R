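#' Per-taxon summary of extracellular sequon presence
#'
#' For every taxonomic group in the taxonomy table, counts accepted
#' proteins, accepted proteins with at least one passing extracellular
#' sequon, the resulting fraction, and the mean number of isoforms per
#' species. Only accepted records enter the counts (screen first, then
#' summarize); species are counted over accepted records.
#'
#' @param result A [ScreenResult].
#' @param taxonomy `data.frame` from [readTaxonomy()]; defines the set of
#'   groups (a group with no accepted protein yields a row with missing
#'   fraction).
#' @return `data.frame` sorted by `taxon_group` with columns `taxon_group`,
#'   `n_species`, `n_proteins`, `n_with_el_ngs`, `fraction_with_el_ngs`,
#'   `mean_isoforms_per_species`.
#' @export
summarizeByTaxon <- function(result, taxonomy) {
  v <- verdicts(result)
  acc <- v[v$status == "ACCEPTED", , drop = FALSE]
  groups <- sort(unique(taxonomy$taxon_group))
  rows <- lapply(groups, function(g) {
    a <- acc[acc$taxon_group == g, , drop = FALSE]
    nP <- nrow(a)
    nS <- length(unique(a$species))
    data.frame(
      taxon_group = g, n_species = nS, n_proteins = nP,
      n_with_el_ngs = sum(a$has_el_ngs),
      fraction_with_el_ngs = if (nP > 0L) sum(a$has_el_ngs) / nP else NA_real_,
      mean_isoforms_per_species = if (nS > 0L) nP / nS else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-taxon NGS universality
#'
#' A group is universal when every accepted protein of every one of its
#' species carries at least one passing extracellular sequon — the pipeline
#' analogue of a clade in which each isoform of each species is
#' glycosylation-competent. An empty group is vacuously universal (a
#' warning is emitted).
#'
#' @param result A [ScreenResult].
#' @param taxonomy `data.frame` from [readTaxonomy()].
#' @return Named logical vector over the taxonomy's groups.
#' @export
speciesNgsUniversality <- function(result, taxonomy) {
  v <- verdicts(result)
  acc <- v[v$status == "ACCEPTED", , drop = FALSE]
  groups <- sort(unique(taxonomy$taxon_group))
  out <- vapply(groups, function(g) {
    a <- acc[acc$taxon_group == g, , drop = FALSE]
    if (nrow(a) == 0L) {
      warning(sprintf("group '%s' has no accepted protein; universality is vacuous", g),
              call. = FALSE)
      return(TRUE)
    }
    all(a$has_el_ngs)
  }, TRUE)
  stats::setNames(out, groups)
}

#' Combinatorial hemichannel diversity bound
#'
#' A hemichannel is an oligomer of eight innexins or six connexins; with N
#' co-expressed isoforms, up to N^8 (innexins) or N^6 (connexins) distinct
#' ordered subunit arrangements are possible. This returns the exact upper
#' bound.
#'
#' @param nIsoforms Number of co-expressed isoforms (positive integer).
#' @param subunits Subunits per hemichannel: 8 for innexins (default) or 6
#'   for connexins; any positive integer is accepted.
#' @return `nIsoforms ^ subunits` as an exact number.
#' @export
hemichannelDiversity <- function(nIsoforms, subunits = 8L) {
  nIsoforms <- as.numeric(nIsoforms)
  subunits <- as.integer(subunits)
  if (is.na(nIsoforms) || nIsoforms < 1 || nIsoforms != round(nIsoforms))
    .stopf("nIsoforms must be a positive integer")
  if (is.na(subunits) || subunits < 1L)
    .stopf("subunits must be a positive integer")
  out <- nIsoforms^subunits
  if (out > 2^53) .stopf("bound exceeds exact integer range")
  out
}
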