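test_that("residue-to-column maps are exact and inverse-consistent", {
  expect_equal(residueToColumn("MNAT"), 1:4)
  expect_equal(residueToColumn("M-NT"), c(1L, 3L, 4L))
  expect_error(residueToColumn("----"), "all-gap")
  set.seed(51)
  for (k in 1:25) {
    ch <- sample(c(AA20, "-", "-"), 80, replace = TRUE)
    if (all(ch == "-")) ch[1] <- "M"
    row <- paste(ch, collapse = "")
    map <- residueToColumn(row)
    expect_true(all(diff(map) > 0))
    # reading the mapped columns back reproduces the ungapped sequence
    expect_equal(paste(ch[map], collapse = ""), gsub("-", "", row))
  }
})

test_that("column trimming removes gappy columns and short blocks", {
  clean <- c(a = "MKLVWE", b = "MKLVWD", c = "MKIVWE")
  tr <- trimColumns(clean)
  expect_identical(tr$alignment, clean)
  expect_equal(tr$kept, 1:6)
  # a column that is 60% gaps at threshold 0.5 is removed (minBlock 1)
  rows <- c(a = "MK-LVW", b = "MK-LVW", c = "MKALVW", d = "MK-LVW",
            e = "MK-LVW")
  tr <- trimColumns(rows, minBlock = 1L)
  expect_equal(tr$kept, c(1:2, 4:6))
  expect_equal(unname(tr$alignment["c"]), "MKLVW")
  # idempotence
  tr2 <- trimColumns(tr$alignment, minBlock = 1L)
  expect_identical(tr2$alignment, tr$alignment)
})

test_that("surviving blocks shorter than minBlock are dropped too", {
  rows <- c(a = "MKL--ABCDEFG", b = "MKL--ABCDEFG", c = "MKL--ABCDEFG")
  rows <- gsub("B", "W", rows) # keep residues legal
  tr <- trimColumns(rows, minBlock = 5L)
  expect_equal(tr$kept, 6:12)
  allgap <- c(a = "M----", b = "K----", c = "L----")
  expect_error(trimColumns(allgap, minBlock = 5L), "every")
})

test_that("clade-wide sequon preservation yields group conservation", {
  cfg <- simConfig(seed = 52)
  cl <- simulateCladeAlignment(cfg, 8)
  tax <- data.frame(id = names(cl$alignment), species = names(cl$alignment),
                    taxon_group = "cladeA", stringsAsFactors = FALSE)
  res <- screenDataset(Biostrings::AAStringSet(cl$alignment), tax)
  groups <- stats::setNames(tax$taxon_group, tax$id)
  rep1 <- sequonColumnConservation(cl$alignment, sequons(res), groups)
  expect_true(rep1$perGroup$group_conserved)
  anc <- rep1$perColumn[rep1$perColumn$column == cl$sequonPosition, ]
  expect_equal(anc$n_with, 8L)
  expect_true(anc$conserved_all)
})

test_that("a single knockout breaks conservation at the ancestral column", {
  cfg <- simConfig(seed = 53)
  cl <- simulateCladeAlignment(cfg, 8, c(rep(TRUE, 7), FALSE))
  tax <- data.frame(id = names(cl$alignment), species = names(cl$alignment),
                    taxon_group = "cladeA", stringsAsFactors = FALSE)
  res <- screenDataset(Biostrings::AAStringSet(cl$alignment), tax)
  groups <- stats::setNames(tax$taxon_group, tax$id)
  rep1 <- sequonColumnConservation(cl$alignment, sequons(res), groups)
  anc <- rep1$perColumn[rep1$perColumn$column == cl$sequonPosition, ]
  expect_equal(anc$n_with, 7L)
  expect_false(anc$conserved_all)
  expect_false(rep1$perGroup$group_conserved)
})

test_that("single-member groups and missing members behave as specified", {
  aln <- c(m1 = "KKNGTKK")
  sq <- data.frame(protein_id = "m1", n_position = 3L, triplet = "NGT",
                   loop_label = "EL1", score = 0.7, passes = TRUE,
                   stringsAsFactors = FALSE)
  rep1 <- sequonColumnConservation(aln, sq, c(m1 = "g"))
  expect_true(rep1$perGroup$group_conserved)
  expect_equal(rep1$perColumn$n_with, 1L)
  expect_error(sequonColumnConservation(aln, sq, c(m1 = "g", m2 = "g")),
               "m2")
})

test_that("per-species counting collapses isoforms of one species", {
  aln <- c(p1 = "KKNGTKK", p2 = "KKNGTKK", p3 = "KKQGTKK")
  sq <- data.frame(protein_id = c("p1", "p2"), n_position = 3L,
                   triplet = "NGT", loop_label = "EL1", score = 0.7,
                   passes = TRUE, stringsAsFactors = FALSE)
  groups <- c(p1 = "g", p2 = "g", p3 = "g")
  spec <- c(p1 = "spA", p2 = "spA", p3 = "spB")
  rep1 <- sequonColumnConservation(aln, sq, groups, spec)
  expect_equal(rep1$perColumn$n_with, 1L)   # spA counted once
  expect_equal(rep1$perColumn$n_members, 2L)
  expect_false(rep1$perGroup$group_conserved)
})

test_that("all-gap-column trimming leaves conservation unchanged on kept columns", {
  cfg <- simConfig(seed = 54)
  cl <- simulateCladeAlignment(cfg, 4)
  padded <- paste0(substr(cl$alignment, 1, 200), "------",
                   substring(cl$alignment, 201))
  names(padded) <- names(cl$alignment)
  tax <- data.frame(id = names(padded), species = names(padded),
                    taxon_group = "g", stringsAsFactors = FALSE)
  res <- screenDataset(Biostrings::AAStringSet(cl$alignment), tax)
  groups <- stats::setNames(tax$taxon_group, tax$id)
  before <- sequonColumnConservation(padded, sequons(res), groups)
  tr <- trimColumns(padded)
  after <- sequonColumnConservation(tr$alignment, sequons(res), groups)
  # re-express untrimmed columns in trimmed coordinates
  beforeKept <- before$perColumn[before$perColumn$column %in% tr$kept, ]
  beforeKept$column <- match(beforeKept$column, tr$kept)
  rownames(beforeKept) <- NULL
  expect_equal(beforeKept, after$perColumn)
})

test_that("ungapped alignments reduce to the identity-map limit", {
  cfg <- simConfig(seed = 55)
  cl <- simulateCladeAlignment(cfg, 5)
  tax <- data.frame(id = names(cl$alignment), species = names(cl$alignment),
                    taxon_group = "g", stringsAsFactors = FALSE)
  res <- screenDataset(Biostrings::AAStringSet(cl$alignment), tax)
  groups <- stats::setNames(tax$taxon_group, tax$id)
  rep1 <- sequonColumnConservation(cl$alignment, sequons(res), groups)
  pass <- sequons(res)[sequons(res)$passes, ]
  expect_setequal(rep1$perColumn$column, unique(pass$n_position))
  expect_equal(sum(rep1$perColumn$n_with), nrow(pass))
})
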