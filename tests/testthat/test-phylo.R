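test_that("p-distance implements pairwise deletion exactly", {
  expect_equal(pDistance(c(a = "MKAT", b = "MKAT"))["a", "b"], 0)
  expect_equal(pDistance(c(a = "MKAT", b = "MKCT"))["a", "b"], 0.25)
  expect_equal(pDistance(c(a = "M-AT", b = "MKAT"))["a", "b"], 0)
  expect_error(pDistance(c(a = "M--", b = "-KA")), "comparable")
  expect_error(pDistance(c(a = "MK")), "at least two")
})

test_that("p-distance agrees with a per-pair counting oracle", {
  set.seed(61)
  for (k in 1:10) {
    rows <- vapply(1:4, function(i)
      paste(sample(c(AA20, "-"), 50, replace = TRUE), collapse = ""), "")
    names(rows) <- paste0("s", 1:4)
    d <- pDistance(rows)
    expect_equal(diag(d), stats::setNames(rep(0, 4), names(rows)))
    expect_equal(d, t(d))
    m <- do.call(rbind, strsplit(rows, ""))
    for (i in 1:3) for (j in (i + 1):4) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      expect_equal(d[i, j], sum(m[i, ok] != m[j, ok]) / sum(ok))
    }
  }
})

test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  bl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers topologies from additive distances", {
  set.seed(62)
  for (k in 1:20) {
    tr <- ape::rtree(sample(5:12, 1))
    d <- ape::cophenetic.phylo(tr)
    rec <- njTree(d)
    expect_equal(robinsonFoulds(tr, rec), 0L)
    expect_true(all(rec$edge.length >= 0))
  }
})

test_that("ultrametric cherries pair correctly", {
  ids <- c("A", "B", "C", "D")
  # AB and CD are cherries at height 1, joined at height 4
  d <- matrix(8, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  truth <- ape::read.tree(text = "((A:1,B:1):3,(C:1,D:1):3);")
  expect_equal(robinsonFoulds(njTree(d), truth), 0L)
})

test_that("negative NJ branch lengths are clamped to zero", {
  set.seed(63)
  for (k in 1:10) {
    tr <- ape::rtree(8)
    d <- ape::cophenetic.phylo(tr)
    noise <- matrix(stats::runif(64, 0, 0.4), 8)
    d <- d + noise + t(noise)
    diag(d) <- 0
    rec <- njTree(d)
    expect_true(all(rec$edge.length >= 0))
  }
})

test_that("Robinson-Foulds counts bipartition differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinsonFoulds(t1, t1), 0L)
  expect_equal(robinsonFoulds(t1, t2), 2L)
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  resolved <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_equal(robinsonFoulds(star, resolved), 2L)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(robinsonFoulds(t1, t3), "leaf sets")
})

test_that("Robinson-Foulds matches the phangorn implementation", {
  skip_if_not_installed("phangorn")
  set.seed(64)
  for (k in 1:20) {
    n <- sample(5:15, 1)
    t1 <- ape::rtree(n)
    t2 <- ape::rtree(n)
    t2$tip.label <- sample(t1$tip.label)
    expect_equal(robinsonFoulds(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("tree annotation mirrors verdicts leaf by leaf", {
  cfg <- simConfig(seed = 65, taxa = list(
    simTaxon("tA", 4L, c(1L, 2L), 0.5)),
    decoyFraction = 0, fragmentFraction = 0, duplicateFraction = 0)
  ds <- simulateDataset(cfg)
  res <- screenDataset(ds$proteins, ds$taxonomy)
  ids <- names(ds$proteins)
  tr <- ape::rtree(length(ids))
  tr$tip.label <- sample(ids)
  ann <- annotateTree(tr, res)
  expect_equal(nrow(ann), length(ids))
  v <- verdicts(res)
  expect_equal(sum(ann$color_class == "with_NGS"), sum(v$has_el_ngs))
  expect_identical(ann$color_class == "with_NGS",
                   v$has_el_ngs[match(ann$leaf, v$protein_id)])
  expect_identical(ann$el1_bar | ann$el2_bar, ann$color_class == "with_NGS")
  tr$tip.label[1] <- "ghost"
  expect_error(annotateTree(tr, res), "ghost")
})

test_that("all-red annotation emerges when every protein carries a sequon", {
  cfg <- simConfig(seed = 66, taxa = list(
    simTaxon("chordateLike", 5L, c(1L, 2L), 1.0)),
    decoyFraction = 0, fragmentFraction = 0, duplicateFraction = 0)
  ds <- simulateDataset(cfg)
  res <- screenDataset(ds$proteins, ds$taxonomy)
  tr <- ape::rtree(length(ds$proteins))
  tr$tip.label <- names(ds$proteins)
  ann <- annotateTree(tr, res)
  expect_true(all(ann$color_class == "with_NGS"))
})
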