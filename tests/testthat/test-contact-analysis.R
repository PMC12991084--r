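# Contact detection against the all-pairs oracle, categorization,
# interface counts and polar proximities.

test_that("cell-list contact search equals the all-pairs scan", {
  for (seed in c(1, 7, 23)) {
    m <- generateToyComplex(20, 8, seed = seed)
    got <- findContacts(m, 4.0)
    want <- bruteForceContacts(m, 4.0)
    key <- function(r1, a1, r2, a2) {
      sw <- r2 < r1 | (r1 == r2 & a2 < a1)
      paste(ifelse(sw, r2, r1), ifelse(sw, a2, a1),
            ifelse(sw, r1, r2), ifelse(sw, a1, a2))
    }
    expect_setequal(key(got$resA, got$atomA, got$resB, got$atomB),
                    key(want$resA, want$atomA, want$resB, want$atomB))
    expect_equal(nrow(got), nrow(want))
    expect_equal(sort(got$distance), sort(want$distance), tolerance = 1e-12)
  }
})

test_that("contacts respect the closed distance cutoff", {
  mk <- function(d) {
    f <- tempfile(fileext = ".pdb")
    writeLines(c(
      sprintf("ATOM      1  N1    C A   1       0.000   0.000   0.000  1.00  0.00           N"),
      sprintf("ATOM      2  N1    C A   2      %7.3f   0.000   0.000  1.00  0.00           N", d),
      "END"), f)
    readStructure(f)
  }
  expect_equal(nrow(findContacts(mk(3.9), 4.0)), 1L)
  expect_equal(nrow(findContacts(mk(4.1), 4.0)), 0L)
  expect_equal(nrow(findContacts(mk(4.0), 4.0)), 1L)  # closed bound
})

test_that("contact sets are monotone in the cutoff and rigid-invariant", {
  m <- generateToyComplex(16, 6, seed = 9)
  pairKeys <- function(ct) paste(ct$resA, ct$atomA, ct$resB, ct$atomB)
  c3 <- findContacts(m, 3.0); c4 <- findContacts(m, 4.0)
  c5 <- findContacts(m, 5.0)
  expect_true(all(pairKeys(c3) %in% pairKeys(c4)))
  expect_true(all(pairKeys(c4) %in% pairKeys(c5)))

  set.seed(13)
  R <- randomRotation(); tr <- rnorm(3, sd = 20)
  m2 <- m
  xyz <- as.matrix(atoms(m)[, c("x", "y", "z")]) %*% t(R)
  m2@atoms$x <- xyz[, 1] + tr[1]
  m2@atoms$y <- xyz[, 2] + tr[2]
  m2@atoms$z <- xyz[, 3] + tr[3]
  cR <- findContacts(m2, 4.0)
  expect_setequal(pairKeys(cR), pairKeys(c4))
  expect_equal(sort(cR$distance), sort(c4$distance), tolerance = 1e-6)
})

test_that("category totals partition the polymer contact total", {
  m <- generateToyComplex(22, 9, seed = 10)
  ct <- findContacts(m)
  tot <- vapply(c("rna-rna", "rna-protein", "protein-protein"),
                function(cat) totalContacts(contactMatrix(ct, cat)), 0)
  expect_equal(sum(tot), nrow(ct))
  # symmetry through canonical unordered keys
  cm <- contactMatrix(ct, "rna-rna")
  cc <- contactCounts(cm)
  expect_false(any(paste(cc$keyB, cc$keyA) %in% paste(cc$keyA, cc$keyB)
                   & cc$keyA != cc$keyB))
})

test_that("contact matrix counts atom pairs per residue pair", {
  ct <- data.frame(
    chainA = "A", resA = c("A:1:", "A:1:", "A:1:"), atomA = c("P", "OP1", "C1'"),
    elementA = c("P", "O", "C"), chainB = "B", resB = "B:1:",
    atomB = c("CB", "CB", "OG"), elementB = c("C", "C", "O"),
    distance = c(3.2, 3.5, 3.9), category = "rna-protein",
    stringsAsFactors = FALSE)
  cm <- contactMatrix(ct, "rna-protein")
  expect_equal(nrow(contactCounts(cm)), 1L)
  expect_equal(contactCounts(cm)$count, 3L)
  expect_equal(totalContacts(contactMatrix(ct, "rna-rna")), 0L)
})

test_that("interface counting matches a planted brute-force count", {
  m <- generateToyComplex(20, 8, seed = 14)
  ct <- findContacts(m, 4.0)
  k <- sum(ct$category == "rna-protein")
  expect_gt(k, 0)
  expect_equal(countInterfaceContacts(m, "B", "A", 4.0), k)
  got_atoms <- countInterfaceContacts(m, "B", "A", 4.0,
                                      convention = "atoms")
  got_res <- countInterfaceContacts(m, "B", "A", 4.0,
                                    convention = "residues")
  sub <- ct[ct$category == "rna-protein", ]
  expect_equal(got_atoms,
               length(unique(c(paste(sub$resA, sub$atomA),
                               paste(sub$resB, sub$atomB)))))
  expect_equal(got_res, nrow(unique(sub[, c("resA", "resB")])))
  expect_lte(got_atoms, 2L * k)
  expect_error(countInterfaceContacts(m, c("A", "B"), "B"), "overlap")
  # far-apart selections count zero
  expect_equal(countInterfaceContacts(m, "A:1:", "B:8:", 4.0), 0L)
})

test_that("polar proximity detection keeps only N/O/S pairs", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N1    C A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  O2    C A   2       2.900   0.000   0.000  1.00  0.00           O",
    "ATOM      3  C2    C A   3       0.000   2.900   0.000  1.00  0.00           C",
    "ATOM      4  C4    C A   4       2.900   2.900   0.000  1.00  0.00           C",
    "END"), f)
  m <- readStructure(f)
  pol <- detectPolarProximities(m, 3.5)
  expect_equal(nrow(pol), 1L)
  expect_setequal(c(pol$elementA, pol$elementB), c("N", "O"))
  # equals a direct brute-force polar scan on a toy complex
  m2 <- generateToyComplex(14, 6, seed = 15)
  want <- bruteForceContacts(m2, 3.5)
  want <- want[want$elementA %in% c("N", "O", "S") &
                 want$elementB %in% c("N", "O", "S"), ]
  expect_equal(nrow(detectPolarProximities(m2, 3.5)), nrow(want))
})
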