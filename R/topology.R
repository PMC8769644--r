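#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values on the Kyte-Doolittle scale, ranging from
#' -4.5 (Arg) to +4.5 (Ile).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
kdScale <- function() c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

.SEG_LABELS <- c("NTERM_IN", "TM1", "EL1", "TM2", "CL", "TM3", "EL2", "TM4",
                 "CTERM_IN")

#' Membrane topology model
#'
#' An S4 container describing how labeled segments (intracellular termini,
#' four transmembrane helices TM1-TM4, extracellular loops EL1/EL2 and the
#' cytoplasmic loop CL) tile a protein sequence. Segments are contiguous,
#' non-overlapping, in the fixed innexin order, and use 1-based inclusive
#' coordinates.
#'
#' @slot segments `data.frame` with columns `label`, `start`, `end`.
#' @slot seqLength Integer sequence length the segments tile.
#' @export
setClass("TopologyModel",
         representation(segments = "data.frame", seqLength = "integer"),
         validity = function(object) {
  seg <- object@segments
  msgs <- character()
  if (!all(c("label", "start", "end") %in% names(seg)))
    return("segments must have columns label, start, end")
  if (any(seg$start > seg$end)) msgs <- c(msgs, "segment with start > end")
  if (seg$start[1] != 1L || seg$end[nrow(seg)] != object@seqLength)
    msgs <- c(msgs, "segments must tile [1, seqLength]")
  if (nrow(seg) > 1L && any(seg$start[-1] != seg$end[-nrow(seg)] + 1L))
    msgs <- c(msgs, "segments must be contiguous and non-overlapping")
  if (sum(grepl("^TM", seg$label)) != 4L)
    msgs <- c(msgs, "model must contain exactly four TM segments")
  keep <- .SEG_LABELS[.SEG_LABELS %in% seg$label]
  if (!identical(seg$label, keep))
    msgs <- c(msgs, "segments out of canonical order")
  core <- c("TM1", "EL1", "TM2", "CL", "TM3", "EL2", "TM4")
  if (!all(core %in% seg$label))
    msgs <- c(msgs, "TM1..TM4 and the three loops are mandatory")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TopologyModel Compact display of the segment layout.
#' @param object A `TopologyModel`.
#' @export
setMethod("show", "TopologyModel", function(object) {
  cat(sprintf("TopologyModel over %d residues\n  %s\n",
              object@seqLength, formatTopology(object)))
})

#' @rdname topoAccessors
#' @export
setGeneric("topoSegments", function(x) standardGeneric("topoSegments"))

#' @rdname topoAccessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' Topology model accessors
#'
#' `topoSegments()` returns the segment table; `seqLength()` the tiled
#' sequence length; `segmentSpan()` the `(start, end)` of one labeled
#' segment or `NULL` when absent.
#'
#' @param x A [TopologyModel].
#' @param label Segment label, e.g. `"EL1"`.
#' @name topoAccessors
NULL

#' @rdname topoAccessors
#' @export
setMethod("topoSegments", "TopologyModel", function(x) x@segments)

#' @rdname topoAccessors
#' @export
setMethod("seqLength", "TopologyModel", function(x) x@seqLength)

#' @rdname topoAccessors
#' @export
segmentSpan <- function(x, label) {
  seg <- topoSegments(x)
  i <- match(label, seg$label)
  if (is.na(i)) return(NULL)
  c(start = seg$start[i], end = seg$end[i])
}

#' Render a topology as a compact string
#'
#' @param model A [TopologyModel].
#' @return A string `"label:start-end"` joined by semicolons.
#' @export
formatTopology <- function(model) {
  seg <- topoSegments(model)
  paste(sprintf("%s:%d-%d", seg$label, seg$start, seg$end), collapse = ";")
}

#' Windowed hydropathy profile
#'
#' Computes the sliding-window mean Kyte-Doolittle hydropathy at every
#' residue. Near the termini the window is truncated to the available
#' residues, so the profile has exactly one value per residue.
#'
#' @param sequence Amino-acid string over the 20 standard codes.
#' @param window Odd window length between 5 and 31 (default 19, standard
#'   practice for transmembrane helix plots).
#' @return Numeric vector of per-residue mean hydropathy, with the window
#'   stored in `attr(, "window")`.
#' @export
hydropathyProfile <- function(sequence, window = 19L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) .stopf("window must be odd, got %d", window)
  if (window < 5L || window > 31L)
    .stopf("window must lie in [5, 31], got %d", window)
  .checkResidues(sequence)
  n <- nchar(sequence)
  if (window > n)
    .stopf("window (%d) longer than sequence (%d)", window, n)
  vals <- unname(kdScale()[strsplit(sequence, "", fixed = TRUE)[[1]]])
  cs <- c(0, cumsum(vals))
  half <- (window - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  prof <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  attr(prof, "window") <- window
  prof
}

#' Call transmembrane segments from a hydropathy profile
#'
#' Finds maximal runs of positions at or above `threshold`, merges runs
#' separated by fewer than `mergeGap` sub-threshold positions, discards runs
#' shorter than `minLen`, and splits intervals longer than `maxLen` at their
#' lowest internal profile value when both halves stay at least `minLen`
#' long (a guard against fused-helix artifacts).
#'
#' @param profile Numeric profile from [hydropathyProfile()].
#' @param threshold Hydropathy call threshold (default 1.6).
#' @param minLen Minimum helix length in residues (default 15).
#' @param mergeGap Runs separated by fewer than this many positions are
#'   merged (default 3).
#' @param maxLen Intervals longer than this are candidates for splitting
#'   (default 35).
#' @return Integer matrix with columns `start`, `end`; zero rows when no
#'   run qualifies.
#' @export
callTmSegments <- function(profile, threshold = 1.6, minLen = 15L,
                           mergeGap = 3L, maxLen = 35L) {
  above <- profile >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(start = starts[r$values], end = ends[r$values])
  if (nrow(iv) == 0L) return(iv)
  # merge runs separated by < mergeGap sub-threshold positions
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[k, "start"] - merged[last, "end"] - 1L < mergeGap)
      merged[last, "end"] <- iv[k, "end"]
    else merged <- rbind(merged, iv[k, , drop = FALSE])
  }
  merged <- merged[merged[, "end"] - merged[, "start"] + 1L >= minLen, ,
                   drop = FALSE]
  if (nrow(merged) == 0L) return(merged)
  # split over-long intervals at the internal profile minimum
  out <- NULL
  queue <- lapply(seq_len(nrow(merged)), function(i) merged[i, ])
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    s <- cur[1]; e <- cur[2]
    len <- e - s + 1L
    if (len > maxLen && len >= 2L * minLen + 1L) {
      inner <- (s + 1L):(e - 1L)
      m <- inner[which.min(profile[inner])]
      if (m - s >= minLen && e - m >= minLen) {
        queue <- c(list(c(s, m - 1L), c(m + 1L, e)), queue)
        next
      }
    }
    out <- rbind(out, c(start = s, end = e))
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Topology call failure token
#'
#' Returned by [assignTopology()] when the observed transmembrane count is
#' not four (or the four helices leave no loop between them).
#'
#' @param x Object to test.
#' @return `isTopologyFailure()` returns a logical scalar.
#' @export
isTopologyFailure <- function(x) inherits(x, "innexTopologyFailure")

.topologyFailure <- function(nTM, reason = "NOT_FOUR_TM") {
  structure(list(nTM = as.integer(nTM), reason = reason),
            class = "innexTopologyFailure")
}

#' @export
print.innexTopologyFailure <- function(x, ...) {
  cat(sprintf("topology failure: %s (observed %d TM segment(s))\n",
              x$reason, x$nTM))
  invisible(x)
}

#' Assign an innexin topology to called TM intervals
#'
#' Under the family's fixed N-inside orientation, four transmembrane
#' intervals imply the segment order NTERM_IN, TM1, EL1, TM2, CL, TM3, EL2,
#' TM4, CTERM_IN; empty termini are omitted. Any other interval count yields
#' a failure token carrying the observed count.
#'
#' @param tmIntervals Integer matrix of sorted, disjoint `(start, end)`
#'   intervals within the sequence.
#' @param seqLen Sequence length in residues.
#' @return A [TopologyModel], or a failure token (see
#'   [isTopologyFailure()]).
#' @export
assignTopology <- function(tmIntervals, seqLen) {
  seqLen <- as.integer(seqLen)
  iv <- tmIntervals
  if (is.null(iv) || nrow(iv) == 0L) return(.topologyFailure(0L))
  if (any(iv[, "start"] < 1L) || any(iv[, "end"] > seqLen))
    .stopf("TM interval outside sequence bounds [1, %d]", seqLen)
  if (is.unsorted(iv[, "start"]) ||
      any(iv[-1, "start"] <= iv[-nrow(iv), "end"]))
    .stopf("TM intervals must be sorted and disjoint")
  if (nrow(iv) != 4L) return(.topologyFailure(nrow(iv)))
  loops <- c("EL1", "CL", "EL2")
  for (k in 1:3)
    if (iv[k + 1L, "start"] - iv[k, "end"] < 2L)
      return(.topologyFailure(4L, reason = "ADJACENT_TM"))
  seg <- data.frame(label = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  add <- function(lab, s, e)
    rbind(seg, data.frame(label = lab, start = as.integer(s),
                          end = as.integer(e), stringsAsFactors = FALSE))
  if (iv[1, "start"] > 1L) seg <- add("NTERM_IN", 1L, iv[1, "start"] - 1L)
  for (k in 1:4) {
    seg <- add(paste0("TM", k), iv[k, "start"], iv[k, "end"])
    if (k < 4L) seg <- add(loops[k], iv[k, "end"] + 1L, iv[k + 1L, "start"] - 1L)
  }
  if (iv[4, "end"] < seqLen) seg <- add("CTERM_IN", iv[4, "end"] + 1L, seqLen)
  methods::new("TopologyModel", segments = seg, seqLength = seqLen)
}

#' Infer topology directly from a sequence
#'
#' Convenience wrapper chaining [hydropathyProfile()], [callTmSegments()]
#' and [assignTopology()].
#'
#' @param sequence Amino-acid string.
#' @param window,threshold,minLen,mergeGap,maxLen See [hydropathyProfile()]
#'   and [callTmSegments()].
#' @return A [TopologyModel] or a failure token.
#' @export
inferTopology <- function(sequence, window = 19L, threshold = 1.6,
                          minLen = 15L, mergeGap = 3L, maxLen = 35L) {
  if (nchar(sequence) < window) return(.topologyFailure(0L, "TOO_SHORT"))
  prof <- hydropathyProfile(sequence, window)
  iv <- callTmSegments(prof, threshold, minLen, mergeGap, maxLen)
  assignTopology(iv, nchar(sequence))
}
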