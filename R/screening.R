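#' Screening configuration
#'
#' Bundles the tunable parameters of the candidate screen: topology calling
#' (window, threshold, helix length, merge gap), the fragment length cutoff,
#' and the sequon scoring rule table.
#'
#' @param minLength Records shorter than this many residues are flagged as
#'   fragments (default 200; full-length innexins span roughly 350-600 aa).
#' @param window,threshold,minTmLen,mergeGap,maxTmLen Topology parameters,
#'   see [hydropathyProfile()] and [callTmSegments()].
#' @param rules Sequon scoring rules from [sequonRules()].
#' @return A list of class `screenConfig`.
#' @export
screenConfig <- function(minLength = 200L, window = 19L, threshold = 1.6,
                         minTmLen = 15L, mergeGap = 3L, maxTmLen = 35L,
                         rules = sequonRules()) {
  structure(list(minLength = as.integer(minLength),
                 window = as.integer(window), threshold = threshold,
                 minTmLen = as.integer(minTmLen),
                 mergeGap = as.integer(mergeGap),
                 maxTmLen = as.integer(maxTmLen), rules = rules),
            class = "screenConfig")
}

#' Screening result container
#'
#' Holds one verdict per screened record, all sequon calls of accepted
#' records, and the accepted topology models.
#'
#' @slot verdicts `data.frame` with one row per record: `protein_id`,
#'   `species`, `taxon_group`, `status`, `reason_codes`, `n_sequons_total`,
#'   `n_sequons_el`, `has_el_ngs`, `topology`.
#' @slot sequons `data.frame` of sequon calls (`protein_id`, `n_position`,
#'   `triplet`, `loop_label`, `score`, `passes`).
#' @slot topologies Named list of [TopologyModel] objects for accepted
#'   records.
#' @export
setClass("ScreenResult",
         representation(verdicts = "data.frame", sequons = "data.frame",
                        topologies = "list"),
         validity = function(object) {
  v <- object@verdicts
  msgs <- character()
  need <- c("protein_id", "species", "taxon_group", "status", "reason_codes",
            "n_sequons_total", "n_sequons_el", "has_el_ngs", "topology")
  if (!all(need %in% names(v))) return("verdict table lacks mandatory columns")
  if (!all(v$status %in% c("ACCEPTED", "REJECTED")))
    msgs <- c(msgs, "status must be ACCEPTED or REJECTED")
  if (any((v$status == "REJECTED") != nzchar(v$reason_codes)))
    msgs <- c(msgs, "REJECTED iff reason codes present")
  if (any(object@sequons$protein_id %in%
          v$protein_id[v$status == "REJECTED"]))
    msgs <- c(msgs, "rejected records must carry no sequons")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ScreenResult Summary display.
#' @param object A `ScreenResult`.
#' @export
setMethod("show", "ScreenResult", function(object) {
  v <- object@verdicts
  cat(sprintf(paste0("ScreenResult: %d record(s); %d accepted, %d rejected;",
                     " %d with extracellular NGS\n"),
              nrow(v), sum(v$status == "ACCEPTED"),
              sum(v$status == "REJECTED"), sum(v$has_el_ngs)))
})

#' @rdname screenAccessors
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))

#' @rdname screenAccessors
#' @export
setGeneric("sequons", function(x) standardGeneric("sequons"))

#' @rdname screenAccessors
#' @export
setGeneric("topologies", function(x) standardGeneric("topologies"))

#' Screening result accessors
#'
#' @param x A [ScreenResult].
#' @name screenAccessors
NULL

#' @rdname screenAccessors
#' @export
setMethod("verdicts", "ScreenResult", function(x) x@verdicts)

#' @rdname screenAccessors
#' @export
setMethod("sequons", "ScreenResult", function(x) x@sequons)

#' @rdname screenAccessors
#' @export
setMethod("topologies", "ScreenResult", function(x) x@topologies)

#' Flag duplicate entries within species
#'
#' Records of one species with byte-identical sequences form a duplicate
#' group; every member except the lexicographically smallest id is flagged.
#' Identical sequences in different species are not duplicates.
#'
#' @param ids Character vector of unique record ids.
#' @param species Character vector of species, parallel to `ids`.
#' @param sequences Character vector of sequences, parallel to `ids`.
#' @return Character vector of flagged ids (possibly empty).
#' @export
detectDuplicates <- function(ids, species, sequences) {
  stopifnot(length(ids) == length(species),
            length(ids) == length(sequences), !anyDuplicated(ids))
  key <- paste(species, sequences, sep = "\r")
  flagged <- character()
  for (grp in split(ids, key)) {
    if (length(grp) > 1L)
      flagged <- c(flagged, sort(grp)[-1L])
  }
  sort(flagged)
}

.emptySequonDF <- function() {
  data.frame(protein_id = character(), n_position = integer(),
             triplet = character(), loop_label = character(),
             score = numeric(), passes = logical(),
             stringsAsFactors = FALSE)
}

#' Screen one candidate record
#'
#' Applies the inclusion criteria to a single record: fragments (length
#' below the cutoff), non-four-TM topologies, and records flagged as
#' within-species duplicates are rejected; all checks run so every violated
#' rule is reported. Accepted records get localized, scored sequon calls.
#'
#' @param id,species,taxonGroup,sequence Record fields.
#' @param config A [screenConfig()].
#' @param duplicateFlags Character vector of ids flagged by
#'   [detectDuplicates()].
#' @return A list with `verdict` (one-row `data.frame`), `sequons`
#'   (`data.frame`) and `topology` ([TopologyModel] or `NULL`).
#' @export
screenRecord <- function(id, species, taxonGroup, sequence,
                         config = screenConfig(),
                         duplicateFlags = character()) {
  reasons <- character()
  if (nchar(sequence) < config$minLength) reasons <- c(reasons, "FRAGMENT")
  topo <- inferTopology(sequence, config$window, config$threshold,
                        config$minTmLen, config$mergeGap, config$maxTmLen)
  if (isTopologyFailure(topo)) reasons <- c(reasons, "NOT_FOUR_TM")
  if (id %in% duplicateFlags) reasons <- c(reasons, "DUPLICATE")
  accepted <- length(reasons) == 0L
  sq <- .emptySequonDF()
  if (accepted) {
    calls <- scoreSequons(sequence, topo, config$rules)
    if (nrow(calls))
      sq <- cbind(data.frame(protein_id = id, stringsAsFactors = FALSE),
                  calls)
  }
  verdict <- data.frame(
    protein_id = id, species = species, taxon_group = taxonGroup,
    status = if (accepted) "ACCEPTED" else "REJECTED",
    reason_codes = paste(reasons, collapse = ","),
    n_sequons_total = nrow(sq),
    n_sequons_el = sum(sq$loop_label %in% c("EL1", "EL2")),
    has_el_ngs = any(sq$passes),
    topology = if (accepted) formatTopology(topo) else "",
    stringsAsFactors = FALSE)
  list(verdict = verdict, sequons = sq,
       topology = if (accepted) topo else NULL)
}

#' Screen a whole candidate dataset
#'
#' Runs [screenRecord()] over every record, in input order, after flagging
#' within-species duplicates. Metadata come from the protein set's
#' `mcols()` or are joined from `taxonomy`; a record missing from the
#' taxonomy is an error.
#'
#' @param proteins `AAStringSet` from [readProteinFasta()] (or any named
#'   `AAStringSet`).
#' @param taxonomy Optional `data.frame` from [readTaxonomy()].
#' @param config A [screenConfig()].
#' @param verbose Emit per-stage counts on `stderr`.
#' @return A [ScreenResult].
#' @export
screenDataset <- function(proteins, taxonomy = NULL,
                          config = screenConfig(), verbose = FALSE) {
  if (length(proteins) == 0L)
    .stopf("refusing to screen an empty record set")
  ids <- names(proteins)
  if (is.null(ids) || anyDuplicated(ids))
    .stopf("protein set must carry unique names")
  md <- S4Vectors::mcols(proteins)
  species <- if (!is.null(md) && "species" %in% names(md))
    as.character(md$species) else rep(NA_character_, length(ids))
  group <- if (!is.null(md) && "taxon_group" %in% names(md))
    as.character(md$taxon_group) else rep(NA_character_, length(ids))
  if (!is.null(taxonomy)) {
    hit <- match(ids, taxonomy$id)
    if (anyNA(hit))
      .stopf("record '%s' absent from taxonomy table", ids[is.na(hit)][1])
    species <- taxonomy$species[hit]
    group <- taxonomy$taxon_group[hit]
  }
  if (anyNA(species) || anyNA(group))
    .stopf("record '%s' lacks species/taxon metadata",
           ids[is.na(species) | is.na(group)][1])
  seqs <- as.character(proteins)
  dup <- detectDuplicates(ids, species, seqs)
  vlist <- vector("list", length(ids))
  slist <- vector("list", length(ids))
  topo <- list()
  for (i in seq_along(ids)) {
    res <- screenRecord(ids[i], species[i], group[i], seqs[i], config, dup)
    vlist[[i]] <- res$verdict
    slist[[i]] <- res$sequons
    if (!is.null(res$topology)) topo[[ids[i]]] <- res$topology
  }
  v <- do.call(rbind, vlist)
  s <- do.call(rbind, slist)
  if (is.null(s) || nrow(s) == 0L) s <- .emptySequonDF()
  rownames(v) <- rownames(s) <- NULL
  if (verbose) {
    rej <- unlist(strsplit(v$reason_codes[v$status == "REJECTED"], ","))
    message(sprintf("screen: read=%d accepted=%d rejected=%d [%s] with_el_ngs=%d",
                    nrow(v), sum(v$status == "ACCEPTED"),
                    sum(v$status == "REJECTED"),
                    paste(sprintf("%s=%d", names(table(rej)), table(rej)),
                          collapse = " "),
                    sum(v$has_el_ngs)))
  }
  methods::new("ScreenResult", verdicts = v, sequons = s, topologies = topo)
}
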