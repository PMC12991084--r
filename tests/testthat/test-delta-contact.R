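# Delta matrices, residue scores, quality exclusions, aggregation,
# significance flags and mutation neighborhoods.

mkDelta <- function(df) {
  new("DeltaMatrix", category = "rna-rna", cutoff = 4.0, delta = df,
      excluded = data.frame(reskey = character(), reason = character(),
                            stringsAsFactors = FALSE))
}

test_that("self-comparison yields an identically zero delta", {
  m <- generateToyComplex(20, 8, seed = 21)
  map <- buildResidueMap(m, m)
  ct <- findContacts(m)
  for (cat in c("rna-rna", "rna-protein", "protein-protein")) {
    dm <- deltaMatrix(contactMatrix(ct, cat), contactMatrix(ct, cat), map)
    expect_true(all(deltaCounts(dm)$delta == 0), info = cat)
    sc <- residueDeltaScores(dm)
    expect_true(all(sc$net == 0) && all(sc$gains == 0))
  }
})

test_that("planted contact gains appear with the right sign and size", {
  pr <- plantedPair(seed = 2)
  map <- buildResidueMap(pr$perturbed, pr$base)
  dm <- deltaMatrix(contactMatrix(findContacts(pr$perturbed), "rna-protein"),
                    contactMatrix(findContacts(pr$base), "rna-protein"),
                    map)
  d <- deltaCounts(dm)
  gt <- pr$truth$contact_deltas
  cp <- RiboDelta:::.canonPairs(gt$keyA, gt$keyB)
  hit <- d[d$keyA == cp$keyA & d$keyB == cp$keyB, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$delta, gt$delta)
  expect_gte(hit$delta, 3L)
})

test_that("delta is antisymmetric under swapping the models", {
  pr <- plantedPair(seed = 3)
  mapAB <- buildResidueMap(pr$perturbed, pr$base)
  mapBA <- buildResidueMap(pr$base, pr$perturbed)
  ctA <- findContacts(pr$perturbed); ctB <- findContacts(pr$base)
  dAB <- deltaCounts(deltaMatrix(contactMatrix(ctA, "rna-rna"),
                                 contactMatrix(ctB, "rna-rna"), mapAB))
  dBA <- deltaCounts(deltaMatrix(contactMatrix(ctB, "rna-rna"),
                                 contactMatrix(ctA, "rna-rna"), mapBA))
  # identical residue numbering on both sides here, so keys line up
  k <- paste(dAB$keyA, dAB$keyB)
  expect_setequal(k, paste(dBA$keyA, dBA$keyB))
  expect_equal(dAB$delta, -dBA$delta[match(k, paste(dBA$keyA, dBA$keyB))])
})

test_that("low-Q residues are excluded with a recorded reason", {
  m <- generateToyComplex(16, 6, seed = 22)
  map <- buildResidueMap(m, m)
  ct <- findContacts(m)
  cm <- contactMatrix(ct, "rna-rna")
  r <- residues(m)
  # pick an RNA residue that actually has rna-rna contacts
  busy <- contactCounts(cm)$keyA[1]
  qt_bad <- generateQualityTable(m, base_q = 0.8, bad_residues = busy,
                                 seed = 5)
  qt_ok <- generateQualityTable(m, base_q = 0.8, seed = 5)
  dm <- deltaMatrix(cm, cm, map, qualA = qt_ok, qualB = qt_bad)
  ex <- excludedResidues(dm)
  expect_true(busy %in% ex$reskey)
  expect_equal(unique(ex$reason[ex$reskey == busy]), "q_below_threshold")
  expect_false(busy %in% c(deltaCounts(dm)$keyA, deltaCounts(dm)$keyB))
  # threshold semantics: 0.39 excluded, 0.41 retained
  rows <- qualityRows(qt_ok)
  rows$q_score[] <- 0.41
  rows$q_score[rows$reskey == busy] <- 0.39
  qt2 <- qualityTable(rows)
  dm2 <- deltaMatrix(cm, cm, map, qualA = qt2, qualB = qt2)
  expect_true(busy %in% excludedResidues(dm2)$reskey)
  others <- setdiff(c(contactCounts(cm)$keyA, contactCounts(cm)$keyB), busy)
  expect_true(any(others %in% c(deltaCounts(dm2)$keyA,
                                deltaCounts(dm2)$keyB)))
})

test_that("unmapped residues are excluded from the delta", {
  m <- generateToyComplex(12, 0, seed = 23)
  a <- atoms(m)
  m2 <- RiboDelta:::.newStructureModel(
    a[!a$resno %in% 6, setdiff(names(a), c("hydrogen", "reskey"))],
    label = "del")
  map <- buildResidueMap(m, m2)
  dm <- deltaMatrix(contactMatrix(findContacts(m), "rna-rna"),
                    contactMatrix(findContacts(m2), "rna-rna"), map)
  ex <- excludedResidues(dm)
  expect_true("A:6:" %in% ex$reskey[ex$reason == "unmapped"])
  expect_false("A:6:" %in% c(deltaCounts(dm)$keyA, deltaCounts(dm)$keyB))
})

test_that("category or cutoff mismatches error", {
  m <- generateToyComplex(8, 0, seed = 1)
  map <- buildResidueMap(m, m)
  ct <- findContacts(m)
  expect_error(deltaMatrix(contactMatrix(ct, "rna-rna"),
                           contactMatrix(ct, "rna-protein"), map),
               "categories")
  expect_error(deltaMatrix(contactMatrix(ct, "rna-rna", cutoff = 4),
                           contactMatrix(ct, "rna-rna", cutoff = 5), map),
               "cutoff")
})

test_that("residue scores follow the gains/losses arithmetic", {
  dm <- mkDelta(data.frame(keyA = c("A:1:", "A:1:"),
                           keyB = c("A:5:", "A:7:"),
                           delta = c(2L, -5L), stringsAsFactors = FALSE))
  sc <- residueDeltaScores(dm)
  g <- function(k, col) sc[[col]][sc$reskey == k]
  expect_equal(g("A:1:", "gains"), 2L)
  expect_equal(g("A:1:", "losses"), 5L)
  expect_equal(g("A:1:", "net"), -3L)
  expect_equal(g("A:5:", "net"), 2L)
  expect_equal(g("A:7:", "net"), -5L)
  expect_equal(sc$net, sc$gains - sc$losses)
})

test_that("residue nets sum to twice the pair-delta sum (conservation)", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    keys <- sprintf("A:%d:", seq_len(n + 1))
    pairs <- t(combn(keys, 2))
    pick <- sample(nrow(pairs), n)
    dm <- mkDelta(data.frame(keyA = pairs[pick, 1], keyB = pairs[pick, 2],
                             delta = sample(-6:6, n, replace = TRUE),
                             stringsAsFactors = FALSE))
    sc <- residueDeltaScores(dm)
    expect_equal(sum(sc$net), 2L * sum(deltaCounts(dm)$delta))
  }
})

test_that("aggregation keeps RNA per nucleotide and sums protein chains", {
  m <- generateToyComplex(10, 4, seed = 25)
  sc <- data.frame(reskey = c("A:1:", "A:2:", "B:1:", "B:3:"),
                   gains = c(2L, 0L, 1L, 0L), losses = c(0L, 1L, 0L, 4L),
                   net = c(2L, -1L, 1L, -4L), stringsAsFactors = FALSE)
  pn <- aggregateScores(sc, m, "per_nucleotide")
  expect_equal(pn$reskey, c("A:1:", "A:2:"))
  expect_equal(pn$net, c(2L, -1L))
  pc <- aggregateScores(sc, m, "per_chain")
  expect_equal(pc$chain, "B")
  expect_equal(pc$net, -3L)
  expect_equal(pc$gains, 1L)
  expect_equal(pc$losses, 4L)
  # RNA-only model under per_chain: empty
  rna <- generateToyComplex(8, 0, seed = 1)
  expect_equal(nrow(aggregateScores(sc[1:2, ], rna, "per_chain")), 0L)
})

test_that("significance flags follow the stated thresholds", {
  m <- generateToyComplex(8, 0, seed = 26)
  map <- buildResidueMap(m, m)
  mk <- function(q, lr) qualityTable(data.frame(
    chain = "A", seq_id = 1:8, q_score = q, local_resolution = lr))
  qB <- mk(rep(0.80, 8), rep(2.8, 8))
  qA <- mk(c(0.70, 0.74, rep(0.80, 6)), c(2.8, 2.8, 3.5, 3.2, rep(2.8, 4)))
  fl <- flagSignificantSites(qA, qB, map)
  # 12.5% Q change flagged; 7.5% not; 0.7 A locres change flagged; 0.4 not
  expect_true("A:1:" %in% fl$keyA)
  expect_equal(fl$criterion[fl$keyA == "A:1:"], "q_score")
  expect_false("A:2:" %in% fl$keyA)
  expect_true("A:3:" %in% fl$keyA)
  expect_equal(fl$criterion[fl$keyA == "A:3:"], "local_resolution")
  expect_false("A:4:" %in% fl$keyA)
  # identical tables flag nothing
  expect_equal(nrow(flagSignificantSites(qB, qB, map)), 0L)
})

test_that("mutation neighborhoods apply the 10 A radius and 3 A filter", {
  m <- generateToyComplex(20, 0, seed = 27)
  a <- atoms(m)
  site <- "A:10:"
  # brute-force 10 A neighborhood
  sa <- a[a$reskey == site, ]
  near <- unique(a$reskey[apply(as.matrix(a[, c("x", "y", "z")]), 1,
    function(p) min(sqrt((sa$x - p[1])^2 + (sa$y - p[2])^2 +
                           (sa$z - p[3])^2)) <= 10)])
  nb <- mutationNeighborhood(m, site)[[site]]
  expect_setequal(nb, near)
  expect_true(site %in% nb)
  # local-resolution filter removes poorly resolved neighbors
  other <- setdiff(nb, site)[1]
  r <- residues(m)
  qt <- qualityTable(data.frame(chain = r$chain, seq_id = r$resno,
                                q_score = 0.8,
                                local_resolution = ifelse(
                                  r$reskey == other, 3.4, 2.5)))
  nb2 <- mutationNeighborhood(m, site, qual = qt)[[site]]
  expect_false(other %in% nb2)
  expect_setequal(nb2, setdiff(nb, other))
  expect_error(mutationNeighborhood(m, "A:99:"), "A:99:")
})

test_that("an isolated residue's neighborhood is itself", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N1    C A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  N1    C A   2      50.000   0.000   0.000  1.00  0.00           N",
    "END"), f)
  m <- readStructure(f)
  expect_equal(mutationNeighborhood(m, "A:1:")[["A:1:"]], "A:1:")
})

test_that("delta nets survive the B-factor encode/read cycle", {
  m <- generateToyComplex(12, 5, seed = 28)
  sc <- data.frame(reskey = c("A:2:", "A:3:", "B:1:"),
                   gains = c(0L, 7L, 0L), losses = c(3L, 0L, 99L),
                   net = c(-3L, 7L, -99L), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".pdb")
  encodeDeltaPdb(m, sc, f)
  b <- atoms(readStructure(f))
  for (i in seq_len(nrow(sc)))
    expect_true(all(b$b[b$reskey == sc$reskey[i]] == sc$net[i]))
  expect_true(all(b$b[!b$reskey %in% sc$reskey] == 0))
})

test_that("quality tables round-trip through TSV", {
  m <- generateToyComplex(10, 4, seed = 29)
  qt <- generateQualityTable(m, base_q = 0.75, bad_residues = "A:4:",
                             seed = 3)
  f <- tempfile(fileext = ".tsv")
  writeQualityTable(qt, f)
  qt2 <- readQualityTable(f)
  expect_equal(qualityRows(qt2)$reskey, qualityRows(qt)$reskey)
  expect_equal(qualityRows(qt2)$q_score, qualityRows(qt)$q_score,
               tolerance = 1e-4)
  expect_lt(qualityRows(qt2)$q_score[qualityRows(qt2)$reskey == "A:4:"],
            0.4)
})
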