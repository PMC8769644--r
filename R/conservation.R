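#' Map residue positions to alignment columns
#'
#' For one gapped alignment row, the k-th non-gap character maps to its
#' 1-based column index.
#'
#' @param gappedRow Gapped string over residues and `-`.
#' @return Integer vector: entry k is the column of residue k.
#' @export
residueToColumn <- function(gappedRow) {
  ch <- strsplit(gappedRow, "", fixed = TRUE)[[1]]
  cols <- which(ch != "-")
  if (!length(cols)) .stopf("all-gap alignment row")
  cols
}

#' Trim unreliable alignment columns
#'
#' A parameter-light surrogate for block-based alignment cleaning: columns
#' whose gap fraction exceeds `maxGapFraction` are removed, and surviving
#' runs of consecutive columns shorter than `minBlock` are removed too. The
#' kept (original) column indices are reported so motif columns can be
#' re-expressed after trimming.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @param maxGapFraction Columns with a gap fraction strictly above this
#'   are dropped (default 0.5).
#' @param minBlock Minimum surviving block length in columns (default 5).
#' @return List with `alignment` (trimmed rows) and `kept` (strictly
#'   increasing original column indices).
#' @export
trimColumns <- function(alignment, maxGapFraction = 0.5, minBlock = 5L) {
  stopifnot(length(alignment) > 0L)
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  gapFrac <- colMeans(m == "-")
  keep <- gapFrac <= maxGapFraction
  r <- rle(keep)
  r$values[r$values & r$lengths < minBlock] <- FALSE
  keep <- inverse.rle(r)
  if (!any(keep)) .stopf("trimming removed every alignment column")
  kept <- which(keep)
  trimmed <- apply(m[, kept, drop = FALSE], 1L, paste, collapse = "")
  names(trimmed) <- names(alignment)
  list(alignment = trimmed, kept = kept)
}

#' Sequon conservation across alignment columns
#'
#' Maps every passing extracellular sequon of every member onto its
#' alignment column and, per group, counts how many members (species by
#' default) carry a passing sequon at each column. A column is conserved in
#' a group when every member carries one; a group is conserved when any
#' column is.
#'
#' @param alignment Named character vector of gapped rows; names are member
#'   ids.
#' @param memberSequons `data.frame` of sequon calls with columns
#'   `protein_id`, `n_position`, `loop_label`, `passes` (e.g.
#'   `sequons(screenDataset(...))`).
#' @param groups Named character vector mapping member id to group label.
#' @param speciesOf Optional named character vector mapping member id to
#'   species; by default each member is its own species, so counting is
#'   per member. With a real mapping, a species with several isoforms
#'   counts once if any isoform carries the column sequon.
#' @return List with `perColumn` (`data.frame`: `group`, `column`,
#'   `n_with`, `n_members`, `conserved_all`; columns with at least one
#'   carrier) and `perGroup` (`data.frame`: `group`, `n_members`,
#'   `group_conserved`).
#' @export
sequonColumnConservation <- function(alignment, memberSequons, groups,
                                     speciesOf = NULL) {
  members <- names(groups)
  miss <- setdiff(members, names(alignment))
  if (length(miss)) .stopf("member '%s' missing from alignment", miss[1])
  if (is.null(speciesOf)) speciesOf <- stats::setNames(members, members)
  hits <- memberSequons[memberSequons$passes &
                          memberSequons$loop_label %in% c("EL1", "EL2") &
                          memberSequons$protein_id %in% members, ,
                        drop = FALSE]
  hitCols <- if (nrow(hits)) {
    cols <- integer(nrow(hits))
    for (i in seq_len(nrow(hits))) {
      map <- residueToColumn(alignment[[hits$protein_id[i]]])
      p <- hits$n_position[i]
      if (p > length(map))
        .stopf("sequon position %d beyond ungapped length of '%s'",
               p, hits$protein_id[i])
      cols[i] <- map[p]
    }
    data.frame(member = hits$protein_id, column = cols,
               stringsAsFactors = FALSE)
  } else data.frame(member = character(), column = integer(),
                    stringsAsFactors = FALSE)
  perColumn <- NULL
  perGroup <- NULL
  for (g in sort(unique(unname(groups)))) {
    gm <- members[groups[members] == g]
    nMembers <- length(unique(speciesOf[gm]))
    gh <- hitCols[hitCols$member %in% gm, , drop = FALSE]
    groupConserved <- FALSE
    if (nrow(gh)) {
      gh$sp <- speciesOf[gh$member]
      cnt <- tapply(gh$sp, gh$column, function(s) length(unique(s)))
      cols <- as.integer(names(cnt))
      df <- data.frame(group = g, column = cols,
                       n_with = as.integer(cnt), n_members = nMembers,
                       stringsAsFactors = FALSE)
      df <- df[order(df$column), , drop = FALSE]
      df$conserved_all <- df$n_with == df$n_members
      groupConserved <- any(df$conserved_all)
      perColumn <- rbind(perColumn, df)
    }
    perGroup <- rbind(perGroup, data.frame(
      group = g, n_members = nMembers, group_conserved = groupConserved,
      stringsAsFactors = FALSE))
  }
  if (is.null(perColumn))
    perColumn <- data.frame(group = character(), column = integer(),
                            n_with = integer(), n_members = integer(),
                            conserved_all = logical(),
                            stringsAsFactors = FALSE)
  rownames(perColumn) <- rownames(perGroup) <- NULL
  list(perColumn = perColumn, perGroup = perGroup)
}
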