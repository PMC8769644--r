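# Alphabets for synthetic innexin-like sequences. TM residues are strongly
# hydrophobic; loop/termini residues exclude N, S and T so that no sequon can
# arise outside the planted sites, making the ground truth exhaustive. The
# loop composition is weighted toward glycine so the expected hydropathy
# threshold crossing sits about one residue inside a true TM boundary at the
# default window of 19 (see the methods vignette for the arithmetic).
.TM_ALPHA <- c("I", "V", "L", "F")
.TM_WEIGHTS <- c(0.3, 0.3, 0.3, 0.1)
.LOOP_ALPHA <- c("G", "P", "Y", "W", "Q", "E", "D", "K", "H", "R")
.LOOP_WEIGHTS <- c(0.45, 0.12, 0.10, 0.08, 0.07, 0.06, 0.05, 0.04, 0.02, 0.01)
.LOOP_ALPHA_FULL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.drawTm <- function(n) sample(.TM_ALPHA, n, replace = TRUE, prob = .TM_WEIGHTS)
.drawLoop <- function(n, realistic = FALSE) {
  if (realistic) sample(.LOOP_ALPHA_FULL, n, replace = TRUE)
  else sample(.LOOP_ALPHA, n, replace = TRUE, prob = .LOOP_WEIGHTS)
}

#' Describe one simulated taxonomic group
#'
#' @param name Group label (also used as the id/species prefix; must be free
#'   of Newick-reserved characters).
#' @param nSpecies Number of species in the group.
#' @param isoformRange Integer range `c(lo, hi)`; each species draws its
#'   isoform count uniformly from it.
#' @param pElNgs Probability that a simulated protein gets one planted
#'   extracellular sequon.
#' @param loopWeights Named weights over `c(EL1, EL2)` for the planted
#'   loop.
#' @return A list of class `simTaxon`.
#' @export
simTaxon <- function(name, nSpecies, isoformRange = c(1L, 5L), pElNgs = 0.5,
                     loopWeights = c(EL1 = 0.5, EL2 = 0.5)) {
  stopifnot(nSpecies >= 1L, length(isoformRange) == 2L,
            isoformRange[1] >= 1L, isoformRange[1] <= isoformRange[2],
            pElNgs >= 0, pElNgs <= 1)
  if (grepl("[(),:;|[:space:]]", name))
    .stopf("taxon name '%s' contains reserved characters", name)
  structure(list(name = name, nSpecies = as.integer(nSpecies),
                 isoformRange = as.integer(isoformRange), pElNgs = pElNgs,
                 loopWeights = loopWeights[c("EL1", "EL2")]),
            class = "simTaxon")
}

#' Default simulated study design
#'
#' Three groups echoing the screen's qualitative landscape: a
#' ctenophore-like group where about two thirds of the proteins carry an
#' extracellular sequon, a lancelet-like group with a single isoform per
#' species that always carries one, and a mammal-like group where every
#' isoform carries one.
#'
#' @return List of [simTaxon()] objects.
#' @export
defaultTaxa <- function() list(
  simTaxon("ctenophora", nSpecies = 10L, isoformRange = c(2L, 6L),
           pElNgs = 0.67),
  simTaxon("lancelets", nSpecies = 5L, isoformRange = c(1L, 1L),
           pElNgs = 1.0),
  simTaxon("mammals", nSpecies = 8L, isoformRange = c(2L, 5L), pElNgs = 1.0))

#' Simulation configuration
#'
#' Defines a synthetic innexin-like dataset: the taxa, segment length
#' ranges, the hydropathy margin separating TM and loop composition from the
#' calling threshold, contamination fractions (decoys with the wrong TM
#' count, sub-200-residue fragments, within-species duplicate entries), the
#' per-site substitution rate for clade alignments, and cysteines planted in
#' the extracellular loops.
#'
#' @param seed Integer RNG seed; identical configurations yield
#'   byte-identical datasets.
#' @param taxa List of [simTaxon()] descriptions.
#' @param segLengths Named list of integer ranges per segment label
#'   (`TM` applies to every helix).
#' @param tmMargin Required hydropathy margin: TM mean composition at least
#'   `threshold + tmMargin`, loops at most `threshold - tmMargin`
#'   (default 0.5; checked against the alphabets).
#' @param decoyFraction,fragmentFraction,duplicateFraction Contaminant
#'   counts as fractions of the true innexin count (rounded).
#' @param substitutionRate Per-site substitution probability for
#'   [simulateCladeAlignment()] (must be below 1).
#' @param elCysteines Named integer counts of cysteines planted per
#'   extracellular loop.
#' @param realisticLoops Use the full 20-letter alphabet in loops (ground
#'   truth is then no longer exhaustive; intended for stress tests).
#' @param threshold Hydropathy threshold the margins are measured against.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L, taxa = defaultTaxa(),
                      segLengths = list(NTERM_IN = c(30L, 60L),
                                        TM = c(24L, 30L),
                                        EL1 = c(40L, 80L),
                                        CL = c(60L, 120L),
                                        EL2 = c(40L, 80L),
                                        CTERM_IN = c(40L, 100L)),
                      tmMargin = 0.5,
                      decoyFraction = 0.10, fragmentFraction = 0.05,
                      duplicateFraction = 0.05, substitutionRate = 0.05,
                      elCysteines = c(EL1 = 2L, EL2 = 2L),
                      realisticLoops = FALSE, threshold = 1.6) {
  for (p in c(decoyFraction, fragmentFraction, duplicateFraction))
    if (p < 0 || p > 1) .stopf("contaminant fractions must lie in [0, 1]")
  if (substitutionRate < 0) .stopf("substitutionRate must be non-negative")
  if (tmMargin <= 0) .stopf("tmMargin must be positive")
  for (lab in c("NTERM_IN", "TM", "EL1", "CL", "EL2", "CTERM_IN")) {
    r <- segLengths[[lab]]
    if (is.null(r) || length(r) != 2L || r[1] < 1L || r[1] > r[2])
      .stopf("invalid length range for segment '%s'", lab)
  }
  for (lab in c("EL1", "EL2"))
    if (segLengths[[lab]][1] < 12L + 2L * elCysteines[[lab]])
      .stopf("segment '%s' too short to host a planted sequon", lab)
  kd <- kdScale()
  tmMean <- sum(kd[.TM_ALPHA] * .TM_WEIGHTS)
  loopMean <- sum(kd[.LOOP_ALPHA] * .LOOP_WEIGHTS)
  if (tmMean < threshold + tmMargin || loopMean > threshold - tmMargin)
    .stopf("alphabet composition violates the requested hydropathy margin")
  structure(list(seed = as.integer(seed), taxa = taxa,
                 segLengths = lapply(segLengths, as.integer),
                 tmMargin = tmMargin, decoyFraction = decoyFraction,
                 fragmentFraction = fragmentFraction,
                 duplicateFraction = duplicateFraction,
                 substitutionRate = substitutionRate,
                 elCysteines = elCysteines,
                 realisticLoops = isTRUE(realisticLoops),
                 threshold = threshold),
            class = "simConfig")
}

# Assemble one sequence from a segment plan; returns chars, true spans and
# the planted sequon (if any).
.buildProtein <- function(config, tmCount = 4L, pElNgs = 0,
                          loopWeights = c(EL1 = 0.5, EL2 = 0.5)) {
  sl <- config$segLengths
  plan <- switch(as.character(tmCount),
    "4" = c("NTERM_IN", "TM1", "EL1", "TM2", "CL", "TM3", "EL2", "TM4",
            "CTERM_IN"),
    "3" = c("NTERM_IN", "TM1", "EL1", "TM2", "CL", "TM3", "CTERM_IN"),
    "5" = c("NTERM_IN", "TM1", "EL1", "TM2", "CL", "TM5x", "CL2x", "TM3",
            "EL2", "TM4", "CTERM_IN"),
    .stopf("unsupported TM count %d", tmCount))
  lens <- vapply(plan, function(lab) {
    key <- if (grepl("^TM", lab)) "TM" else if (lab == "CL2x") "CL" else lab
    r <- sl[[key]]
    if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  }, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  segs <- data.frame(label = plan, start = starts, end = ends,
                     stringsAsFactors = FALSE, row.names = NULL)
  chars <- character(ends[length(ends)])
  for (k in seq_along(plan)) {
    idx <- starts[k]:ends[k]
    chars[idx] <- if (grepl("^TM", plan[k])) .drawTm(length(idx))
                  else .drawLoop(length(idx), config$realisticLoops)
  }
  sequon <- NULL
  if (tmCount == 4L && stats::runif(1) < pElNgs) {
    lab <- sample(c("EL1", "EL2"), 1L, prob = loopWeights)
    k <- match(lab, plan)
    s <- starts[k]; e <- ends[k]
    # keep the asparagine at least 4 residues from both TM boundaries and
    # leave room for a non-proline +3 context inside the loop
    nPos <- (s + 3L):(e - 4L)
    nPos <- nPos[sample.int(length(nPos), 1L)]
    xAlpha <- setdiff(if (config$realisticLoops) .LOOP_ALPHA_FULL
                      else .LOOP_ALPHA, c("P", "N", "S", "T", "C"))
    chars[nPos] <- "N"
    chars[nPos + 1L] <- xAlpha[sample.int(length(xAlpha), 1L)]
    chars[nPos + 2L] <- sample(c("S", "T"), 1L)
    chars[nPos + 3L] <- xAlpha[sample.int(length(xAlpha), 1L)]
    sequon <- data.frame(n_position = nPos, loop_label = lab,
                         stringsAsFactors = FALSE)
  }
  # plant extracellular cysteines clear of boundaries and the sequon site
  if (tmCount == 4L) for (lab in c("EL1", "EL2")) {
    nC <- config$elCysteines[[lab]]
    if (is.null(nC) || nC < 1L) next
    k <- match(lab, plan)
    cand <- (starts[k] + 4L):(ends[k] - 4L)
    if (!is.null(sequon) && sequon$loop_label == lab)
      cand <- setdiff(cand, (sequon$n_position - 1L):(sequon$n_position + 4L))
    pick <- cand[sample.int(length(cand), min(nC, length(cand)))]
    chars[pick] <- "C"
  }
  list(chars = chars, segments = segs, sequon = sequon)
}

#' Simulate one innexin-like protein
#'
#' Assembles NTERM - TM1 - EL1 - TM2 - CL - TM3 - EL2 - TM4 - CTERM from the
#' configured length ranges, drawing TM residues from a hydrophobic alphabet
#' and loop residues from a hydrophilic alphabet that excludes N, S and T,
#' so the planted extracellular sequons are provably the only ones present.
#' With probability `pElNgs` one N-X-S/T sequon (X hydrophilic, not
#' proline) is planted at an interior loop position at least four residues
#' from any TM boundary. Uses (and advances) the current RNG state.
#'
#' @param config A [simConfig()].
#' @param pElNgs Planting probability (default: the first configured
#'   taxon's).
#' @param id,species,taxonGroup Metadata for the emitted record.
#' @return List with `record` (list: `id`, `species`, `taxon_group`,
#'   `sequence`) and `truth` (list: `class`, `segments` `data.frame`,
#'   `sequons` `data.frame`).
#' @export
simulateProtein <- function(config, pElNgs = config$taxa[[1]]$pElNgs,
                            id = "prot1", species = "sp1",
                            taxonGroup = "taxon1") {
  built <- .buildProtein(config, 4L, pElNgs)
  sq <- built$sequon
  if (is.null(sq))
    sq <- data.frame(n_position = integer(), loop_label = character(),
                     stringsAsFactors = FALSE)
  list(record = list(id = id, species = species, taxon_group = taxonGroup,
                     sequence = paste(built$chars, collapse = "")),
       truth = list(class = "INNEXIN", segments = built$segments,
                    sequons = sq))
}

#' Simulate a multi-taxon screening dataset with ground truth
#'
#' Emits true innexins per the configured taxa, then appends contaminants:
#' decoys built with three or five TM helices (alternating), fragments
#' truncated below 200 residues, and duplicate entries re-emitting an
#' existing record under a new id within the same species. All outputs are
#' deterministic functions of the configuration (including its seed).
#'
#' @param config A [simConfig()].
#' @param dir Optional directory; when given, `proteins.fasta`,
#'   `taxonomy.tsv`, `truth_classes.tsv` and `truth_sequons.tsv` are
#'   written there.
#' @return List with `proteins` (`AAStringSet` with metadata columns),
#'   `taxonomy` (`data.frame`), `truthClasses` (`data.frame`: `id`,
#'   `class`) and `truthSequons` (`data.frame`: `id`, `n_position`,
#'   `loop_label`; true innexins only).
#' @export
simulateDataset <- function(config, dir = NULL) {
  set.seed(config$seed)
  recs <- list(); classes <- list(); sqs <- list()
  for (tx in config$taxa) {
    for (s in seq_len(tx$nSpecies)) {
      sp <- sprintf("%s_sp%02d", tx$name, s)
      nIso <- if (tx$isoformRange[1] == tx$isoformRange[2]) tx$isoformRange[1]
              else sample(tx$isoformRange[1]:tx$isoformRange[2], 1L)
      for (j in seq_len(nIso)) {
        id <- sprintf("%s_i%02d", sp, j)
        built <- .buildProtein(config, 4L, tx$pElNgs, tx$loopWeights)
        recs[[id]] <- list(species = sp, group = tx$name,
                           sequence = paste(built$chars, collapse = ""))
        classes[[id]] <- "INNEXIN"
        if (!is.null(built$sequon))
          sqs[[id]] <- cbind(data.frame(id = id, stringsAsFactors = FALSE),
                             built$sequon)
      }
    }
  }
  nInx <- length(recs)
  if (nInx == 0L) .stopf("configuration yields zero proteins")
  allSpecies <- unique(vapply(recs, `[[`, "", "species"))
  spGroup <- vapply(recs, `[[`, "", "group")
  names(spGroup) <- vapply(recs, `[[`, "", "species")
  pickSpecies <- function() {
    sp <- allSpecies[sample.int(length(allSpecies), 1L)]
    c(sp, spGroup[[sp]])
  }
  nDecoy <- round(config$decoyFraction * nInx)
  for (k in seq_len(nDecoy)) {
    tm <- if (k %% 2L == 1L) 3L else 5L
    who <- pickSpecies()
    id <- sprintf("decoy%dtm_%03d", tm, k)
    built <- .buildProtein(config, tm, 0)
    recs[[id]] <- list(species = who[1], group = who[2],
                       sequence = paste(built$chars, collapse = ""))
    classes[[id]] <- sprintf("DECOY_%dTM", tm)
  }
  nFrag <- round(config$fragmentFraction * nInx)
  for (k in seq_len(nFrag)) {
    who <- pickSpecies()
    id <- sprintf("frag_%03d", k)
    built <- .buildProtein(config, 4L, 0)
    len <- sample(150:199, 1L)
    recs[[id]] <- list(species = who[1], group = who[2],
                       sequence = paste(built$chars[seq_len(len)],
                                        collapse = ""))
    classes[[id]] <- "FRAGMENT"
  }
  nDup <- round(config$duplicateFraction * nInx)
  innexIds <- names(classes)[unlist(classes) == "INNEXIN"]
  for (k in seq_len(nDup)) {
    src <- innexIds[sample.int(length(innexIds), 1L)]
    id <- sprintf("%s_dup%02d", src, k)
    recs[[id]] <- recs[[src]]
    classes[[id]] <- "DUPLICATE"
  }
  ids <- names(recs)
  seqs <- vapply(recs, `[[`, "", "sequence")
  proteins <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  S4Vectors::mcols(proteins) <- S4Vectors::DataFrame(
    species = unname(vapply(recs, `[[`, "", "species")),
    taxon_group = unname(vapply(recs, `[[`, "", "group")),
    source = "simulated")
  taxonomy <- data.frame(id = ids,
                         species = unname(vapply(recs, `[[`, "", "species")),
                         taxon_group = unname(vapply(recs, `[[`, "", "group")),
                         stringsAsFactors = FALSE, row.names = NULL)
  truthClasses <- data.frame(id = ids, class = unlist(classes)[ids],
                             stringsAsFactors = FALSE, row.names = NULL)
  truthSequons <- if (length(sqs)) do.call(rbind, unname(sqs))
    else data.frame(id = character(), n_position = integer(),
                    loop_label = character(), stringsAsFactors = FALSE)
  rownames(truthSequons) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeProteinFasta(proteins, file.path(dir, "proteins.fasta"))
    writeResultsTable(taxonomy, file.path(dir, "taxonomy.tsv"))
    writeResultsTable(truthClasses, file.path(dir, "truth_classes.tsv"))
    writeResultsTable(truthSequons, file.path(dir, "truth_sequons.tsv"))
  }
  list(proteins = proteins, taxonomy = taxonomy,
       truthClasses = truthClasses, truthSequons = truthSequons)
}

#' Simulate an ortholog clade alignment with controlled sequon fate
#'
#' Generates one ancestral innexin carrying a single extracellular sequon,
#' then derives `nMembers` descendants by independent per-site
#' substitutions at the configured rate, drawing replacements from the
#' segment-appropriate alphabet so the topology survives mutation. The
#' sequon context (sites N..+3) is held fixed for members with
#' `preserveSequon = TRUE` and the asparagine is overwritten with glutamine
#' for the others. No indels are introduced, so the true alignment is the
#' trivial one.
#'
#' @param config A [simConfig()]; `substitutionRate` must be below 1.
#' @param nMembers Number of descendants (at least 2).
#' @param preserveSequon Logical vector of length `nMembers`.
#' @return List with `alignment` (named character vector, no gaps),
#'   `sequonPosition`, `loopLabel`, `preserve`, and the ancestor's
#'   `segments`.
#' @export
simulateCladeAlignment <- function(config, nMembers,
                                   preserveSequon = rep(TRUE, nMembers)) {
  if (nMembers < 2L) .stopf("a clade needs at least 2 members")
  if (length(preserveSequon) != nMembers)
    .stopf("preserveSequon must have one entry per member")
  rate <- config$substitutionRate
  if (rate >= 1) .stopf("substitution rate must be below 1")
  anc <- .buildProtein(config, 4L, pElNgs = 1)
  chars <- anc$chars
  n <- length(chars)
  isTm <- logical(n)
  for (k in seq_len(nrow(anc$segments)))
    if (grepl("^TM", anc$segments$label[k]))
      isTm[anc$segments$start[k]:anc$segments$end[k]] <- TRUE
  nPos <- anc$sequon$n_position
  frozen <- nPos:(nPos + 3L)
  rows <- character(nMembers)
  for (i in seq_len(nMembers)) {
    ch <- chars
    mut <- which(stats::runif(n) < rate)
    if (preserveSequon[i]) mut <- setdiff(mut, frozen)
    for (p in mut)
      ch[p] <- if (isTm[p]) .drawTm(1L)
               else .drawLoop(1L, config$realisticLoops)
    if (!preserveSequon[i]) ch[nPos] <- "Q"
    rows[i] <- paste(ch, collapse = "")
  }
  names(rows) <- sprintf("m%02d", seq_len(nMembers))
  list(alignment = rows, sequonPosition = nPos,
       loopLabel = anc$sequon$loop_label, preserve = preserveSequon,
       segments = anc$segments)
}
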