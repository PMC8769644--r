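# Independent oracles and small fixture builders shared across tests.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomSeq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# exhaustive three-residue sequon check, independent of the scanner
oracleSequons <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- integer()
  if (length(ch) >= 3L) for (i in 1:(length(ch) - 2L)) {
    if (ch[i] == "N" && ch[i + 1L] != "P" && ch[i + 2L] %in% c("S", "T"))
      out <- c(out, i)
  }
  out
}

# regex-with-overlap oracle (perl lookahead)
regexSequons <- function(sequence) {
  m <- gregexpr("N(?=[^P][ST])", sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

# toy four-TM topology: helices at fixed spans inside a 400-residue protein
toyIntervals <- function() {
  cbind(start = c(51L, 131L, 231L, 331L), end = c(70L, 150L, 250L, 350L))
}

toyTopology <- function(seqLen = 400L) assignTopology(toyIntervals(), seqLen)

# a sequence tailored to a toy topology: baseline lysines (no N/S/T/P) with
# substrings planted at chosen positions
plantedSeq <- function(seqLen, plants = list()) {
  ch <- rep("K", seqLen)
  for (p in plants) {
    s <- strsplit(p$what, "", fixed = TRUE)[[1]]
    ch[p$at:(p$at + length(s) - 1L)] <- s
  }
  paste(ch, collapse = "")
}

# minimal hand-built ScreenResult for aggregation tests
makeScreenResult <- function(ids, species, group, status, hasNgs,
                             sequons = NULL) {
  v <- data.frame(protein_id = ids, species = species, taxon_group = group,
                  status = status,
                  reason_codes = ifelse(status == "REJECTED", "NOT_FOUR_TM", ""),
                  n_sequons_total = 0L, n_sequons_el = 0L,
                  has_el_ngs = hasNgs, topology = "",
                  stringsAsFactors = FALSE)
  if (is.null(sequons))
    sequons <- data.frame(protein_id = character(), n_position = integer(),
                          triplet = character(), loop_label = character(),
                          score = numeric(), passes = logical(),
                          stringsAsFactors = FALSE)
  methods::new("ScreenResult", verdicts = v, sequons = sequons,
               topologies = list())
}

expect_model_tiles <- function(model) {
  seg <- topoSegments(model)
  expect_equal(seg$start[1], 1L)
  expect_equal(seg$end[nrow(seg)], seqLength(model))
  if (nrow(seg) > 1L)
    expect_equal(seg$start[-1], seg$end[-nrow(seg)] + 1L)
}
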