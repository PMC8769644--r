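test_that("without planting, no sequon can exist in default-alphabet loops", {
  set.seed(81)
  cfg <- simConfig(seed = 81)
  for (k in 1:20) {
    p <- simulateProtein(cfg, pElNgs = 0)
    expect_equal(nrow(p$truth$sequons), 0L)
    expect_equal(nrow(findSequons(p$record$sequence)), 0L)
  }
})

test_that("with certain planting, the scanner finds exactly the planted site", {
  set.seed(82)
  cfg <- simConfig(seed = 82)
  for (k in 1:20) {
    p <- simulateProtein(cfg, pElNgs = 1)
    expect_equal(nrow(p$truth$sequons), 1L)
    found <- findSequons(p$record$sequence)
    expect_equal(found$n_position, p$truth$sequons$n_position)
    # the planted site is inside the true extracellular span
    lab <- p$truth$sequons$loop_label
    span <- p$truth$segments[p$truth$segments$label == lab, ]
    expect_gte(found$n_position, span$start)
    expect_lte(found$n_position + 2L, span$end)
  }
})

test_that("identical configurations yield byte-identical datasets", {
  cfg <- simConfig(seed = 83)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(as.character(d1$proteins), as.character(d2$proteins))
  expect_identical(d1$taxonomy, d2$taxonomy)
  expect_identical(d1$truthClasses, d2$truthClasses)
  expect_identical(d1$truthSequons, d2$truthSequons)
  set.seed(84)
  p1 <- simulateProtein(cfg)
  set.seed(84)
  p2 <- simulateProtein(cfg)
  expect_identical(p1, p2)
})

test_that("dataset composition follows the configured design", {
  cfg <- simConfig(seed = 85, taxa = list(
    simTaxon("tA", 3L, c(1L, 1L), 0.5),
    simTaxon("tB", 3L, c(1L, 1L), 0.5)),
    decoyFraction = 0, fragmentFraction = 0, duplicateFraction = 0)
  ds <- simulateDataset(cfg)
  expect_length(ds$proteins, 6L)
  expect_true(all(ds$truthClasses$class == "INNEXIN"))
  # lancelet-like design: one isoform per species, one sequon each
  cfgL <- simConfig(seed = 86, taxa = list(
    simTaxon("lanceletLike", 6L, c(1L, 1L), 1.0)),
    decoyFraction = 0, fragmentFraction = 0, duplicateFraction = 0)
  dsL <- simulateDataset(cfgL)
  expect_length(dsL$proteins, 6L)
  expect_equal(nrow(dsL$truthSequons), 6L)
  expect_setequal(dsL$truthSequons$id, names(dsL$proteins))
})

test_that("contaminant bookkeeping matches the emitted records", {
  cfg <- simConfig(seed = 87, taxa = list(
    simTaxon("tA", 20L, c(2L, 3L), 0.5)),
    decoyFraction = 0.1, fragmentFraction = 0.05, duplicateFraction = 0.1)
  ds <- simulateDataset(cfg)
  cls <- table(ds$truthClasses$class)
  nInx <- cls[["INNEXIN"]]
  expect_equal(sum(cls[c("DECOY_3TM", "DECOY_5TM")]), round(0.1 * nInx))
  expect_equal(cls[["FRAGMENT"]], round(0.05 * nInx))
  expect_equal(cls[["DUPLICATE"]], round(0.1 * nInx))
  # duplicates share species with their source and sort after it
  dups <- ds$truthClasses$id[ds$truthClasses$class == "DUPLICATE"]
  for (d in dups) {
    src <- sub("_dup[0-9]+$", "", d)
    expect_true(src %in% names(ds$proteins))
    expect_true(d > src)
    expect_equal(ds$taxonomy$species[ds$taxonomy$id == d],
                 ds$taxonomy$species[ds$taxonomy$id == src])
    expect_equal(as.character(ds$proteins[[d]]),
                 as.character(ds$proteins[[src]]))
  }
  frag <- ds$truthClasses$id[ds$truthClasses$class == "FRAGMENT"]
  expect_true(all(Biostrings::width(ds$proteins[frag]) < 200L))
})

test_that("clade simulation respects rate, preservation and determinism", {
  cfg0 <- simConfig(seed = 88, substitutionRate = 0)
  set.seed(88)
  cl0 <- simulateCladeAlignment(cfg0, 3)
  expect_equal(unname(cl0$alignment[1]), unname(cl0$alignment[2]))
  expect_equal(unname(cl0$alignment[2]), unname(cl0$alignment[3]))
  cfg <- simConfig(seed = 89, substitutionRate = 0.08)
  set.seed(89)
  cl <- simulateCladeAlignment(cfg, 6, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  w <- nchar(cl$alignment)
  expect_equal(length(unique(w)), 1L)
  trip <- substr(cl$alignment, cl$sequonPosition, cl$sequonPosition + 2L)
  expect_true(all(startsWith(trip[1:4], "N")))
  expect_true(all(startsWith(trip[5:6], "Q")))
  expect_error(simulateCladeAlignment(cfg, 1), "at least 2")
  badCfg <- cfg
  badCfg$substitutionRate <- 1
  expect_error(simulateCladeAlignment(badCfg, 4), "below 1")
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(decoyFraction = 1.5), "\\[0, 1\\]")
  expect_error(simConfig(segLengths = list(
    NTERM_IN = c(30L, 60L), TM = c(21L, 28L), EL1 = c(5L, 8L),
    CL = c(60L, 120L), EL2 = c(40L, 80L), CTERM_IN = c(40L, 100L))),
    "EL1")
  expect_error(simTaxon("bad name", 3L), "reserved")
  expect_error(simulateDataset(simConfig(taxa = list())), "zero")
})
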