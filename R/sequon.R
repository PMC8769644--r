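#' Scoring rules for sequon occupancy
#'
#' The rule-based surrogate for neural-network occupancy prediction starts
#' from a base potential and applies context adjustments: N-X-T sites are
#' favored over N-X-S, a proline immediately downstream of the motif
#' (position +3) is penalized, and sites hugging a transmembrane boundary
#' are penalized as sterically occluded. The final score is clamped to
#' [0, 1] and a site passes when it exceeds `passThreshold`.
#'
#' @param base Base potential for any valid sequon (default 0.55).
#' @param thrBonus Bonus when the +2 residue is threonine (default 0.15).
#' @param prolinePenalty Penalty when the +3 residue is proline
#'   (default 0.25).
#' @param membranePenalty Penalty when the asparagine lies within
#'   `membraneDistance` residues of a TM boundary (default 0.10).
#' @param membraneDistance Boundary proximity in residues (default 3).
#' @param passThreshold Strict lower bound a passing score must exceed
#'   (default 0.5).
#' @return A list of class `sequonRules`.
#' @export
sequonRules <- function(base = 0.55, thrBonus = 0.15, prolinePenalty = 0.25,
                        membranePenalty = 0.10, membraneDistance = 3L,
                        passThreshold = 0.5) {
  structure(list(base = base, thrBonus = thrBonus,
                 prolinePenalty = prolinePenalty,
                 membranePenalty = membranePenalty,
                 membraneDistance = as.integer(membraneDistance),
                 passThreshold = passThreshold),
            class = "sequonRules")
}

#' Find N-glycosylation sequons in a sequence
#'
#' Scans for the consensus motif Asn-X-Ser/Thr where X is any residue
#' except proline. Overlapping matches are all reported, in order of
#' strictly increasing position.
#'
#' @param sequence Amino-acid string.
#' @return `data.frame` with columns `n_position` (1-based index of the
#'   asparagine) and `triplet`.
#' @export
findSequons <- function(sequence) {
  .checkResidues(sequence)
  n <- nchar(sequence)
  empty <- data.frame(n_position = integer(), triplet = character(),
                      stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  i <- seq_len(n - 2L)
  hit <- ch[i] == "N" & ch[i + 1L] != "P" & ch[i + 2L] %in% c("S", "T")
  pos <- i[hit]
  if (!length(pos)) return(empty)
  data.frame(n_position = pos,
             triplet = paste0(ch[pos], ch[pos + 1L], ch[pos + 2L]),
             stringsAsFactors = FALSE)
}

.segmentAt <- function(topology, pos) {
  seg <- topoSegments(topology)
  i <- which(seg$start <= pos & seg$end >= pos)
  if (!length(i)) NA_character_ else seg$label[i[1]]
}

#' Localize sequons on a topology model
#'
#' Each sequon is assigned the label of the segment containing its
#' asparagine: `EL1` or `EL2` for extracellular sites, `NONE` for any other
#' compartment. Localization is decided by the N residue alone (the glycan
#' attaches there); the triplet may straddle a boundary.
#'
#' @param sequons `data.frame` from [findSequons()].
#' @param topology A [TopologyModel].
#' @return Input `data.frame` with a `loop_label` column appended, input
#'   order preserved.
#' @export
localizeSequons <- function(sequons, topology) {
  if (nrow(sequons) == 0L) {
    sequons$loop_label <- character()
    return(sequons)
  }
  if (any(sequons$n_position < 1L | sequons$n_position > seqLength(topology)))
    .stopf("sequon position outside topology span [1, %d]",
           seqLength(topology))
  lab <- vapply(sequons$n_position, function(p) .segmentAt(topology, p), "")
  sequons$loop_label <- ifelse(lab %in% c("EL1", "EL2"), lab, "NONE")
  sequons
}

#' Rule-based sequon occupancy score
#'
#' @param sequence Amino-acid string.
#' @param nPosition 1-based position of the sequon's asparagine; the
#'   triplet starting there must be a valid sequon.
#' @param topology A [TopologyModel] for the same sequence.
#' @param rules A [sequonRules()] list.
#' @return Numeric score in [0, 1].
#' @export
occupancyScore <- function(sequence, nPosition, topology,
                           rules = sequonRules()) {
  n <- nchar(sequence)
  if (nPosition < 1L || nPosition + 2L > n)
    .stopf("sequon at %d does not fit in a sequence of %d residues",
           nPosition, n)
  trip <- substr(sequence, nPosition, nPosition + 2L)
  ch <- strsplit(trip, "", fixed = TRUE)[[1]]
  if (ch[1] != "N" || ch[2] == "P" || !ch[3] %in% c("S", "T"))
    .stopf("'%s' at position %d is not a valid N-X-S/T sequon",
           trip, nPosition)
  score <- rules$base
  if (ch[3] == "T") score <- score + rules$thrBonus
  if (nPosition + 3L <= n &&
      substr(sequence, nPosition + 3L, nPosition + 3L) == "P")
    score <- score - rules$prolinePenalty
  seg <- topoSegments(topology)
  bounds <- c(seg$start[grepl("^TM", seg$label)],
              seg$end[grepl("^TM", seg$label)])
  if (length(bounds) && min(abs(nPosition - bounds)) <= rules$membraneDistance)
    score <- score - rules$membranePenalty
  min(1, max(0, score))
}

#' Scan, localize and score all sequons of one protein
#'
#' @param sequence Amino-acid string.
#' @param topology A [TopologyModel] for the same sequence.
#' @param rules A [sequonRules()] list.
#' @return `data.frame` with columns `n_position`, `triplet`, `loop_label`,
#'   `score`, `passes`; a site passes iff it lies in EL1/EL2 and its score
#'   strictly exceeds the pass threshold.
#' @export
scoreSequons <- function(sequence, topology, rules = sequonRules()) {
  sq <- localizeSequons(findSequons(sequence), topology)
  if (nrow(sq) == 0L) {
    sq$score <- numeric()
    sq$passes <- logical()
    return(sq)
  }
  sq$score <- vapply(sq$n_position, function(p)
    occupancyScore(sequence, p, topology, rules), 0)
  sq$passes <- sq$loop_label %in% c("EL1", "EL2") &
    sq$score > rules$passThreshold
  sq
}

#' Count cysteines in the extracellular loops
#'
#' Innexin extracellular loops canonically carry two cysteines each; some
#' family members carry more. This reports the raw counts per loop.
#'
#' @param sequence Amino-acid string.
#' @param topology A [TopologyModel] for the same sequence.
#' @return Named integer vector `c(EL1 = ..., EL2 = ...)`.
#' @export
countLoopCysteines <- function(sequence, topology) {
  cnt <- function(lab) {
    sp <- segmentSpan(topology, lab)
    if (is.null(sp)) return(0L)
    sum(strsplit(substr(sequence, sp["start"], sp["end"]), "",
                 fixed = TRUE)[[1]] == "C")
  }
  c(EL1 = cnt("EL1"), EL2 = cnt("EL2"))
}
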