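# Kabsch superposition, RMSD, centers of mass and displacement flags.

test_that("superposing identical point sets gives identity and rmsd 0", {
  set.seed(31)
  A <- matrix(rnorm(30, sd = 5), 10, 3)
  sp <- superpose(A, A)
  expect_lt(sp$rmsd, 1e-12)
  expect_equal(sp$transform@rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp$transform@translation, rep(0, 3), tolerance = 1e-9)
  expect_error(superpose(A[1:2, ], A[1:2, ]), "3 points")
  collinear <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(collinear, collinear), "degenerate")
})

test_that("a rigid-moved copy superposes back exactly", {
  set.seed(32)
  for (i in 1:10) {
    A <- matrix(rnorm(45, sd = 8), 15, 3)
    R <- randomRotation(); tr <- rnorm(3, sd = 30)
    B <- sweep(A %*% t(R), 2, tr, "+")
    sp <- superpose(A, B)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(sp$transform@rotation, R, tolerance = 1e-8)
  }
})

test_that("Kabsch agrees with the quaternion oracle under jitter", {
  set.seed(33)
  devs <- replicate(200, {
    n <- sample(4:30, 1)
    A <- matrix(rnorm(3 * n, sd = 6), n, 3)
    B <- sweep(A %*% t(randomRotation()), 2, rnorm(3, sd = 10), "+") +
      matrix(rnorm(3 * n, sd = 0.3), n, 3)
    abs(superpose(A, B)$rmsd - quaternionSuperpose(A, B))
  })
  expect_lt(max(devs), 1e-8)
})

test_that("rmsd is symmetric and invariant to rigid pre-transforms", {
  set.seed(34)
  A <- matrix(rnorm(60, sd = 6), 20, 3)
  B <- A + matrix(rnorm(60, sd = 0.5), 20, 3)
  r1 <- superpose(A, B)$rmsd
  expect_equal(r1, superpose(B, A)$rmsd, tolerance = 1e-9)
  Bp <- sweep(B %*% t(randomRotation()), 2, rnorm(3, sd = 50), "+")
  expect_equal(r1, superpose(A, Bp)$rmsd, tolerance = 1e-9)
  # superposed rmsd never exceeds the unsuperposed one
  raw <- sqrt(mean(rowSums((A - B)^2)))
  expect_lte(r1, raw + 1e-12)
})

test_that("chainRmsd recovers a planted single-residue displacement", {
  m <- generateToyComplex(30, 0, seed = 35)
  pp <- perturb(m, perturbationPlan(
    displaced = data.frame(reskey = "A:15:", dx = 3, dy = 0, dz = 4)))
  map <- buildResidueMap(pp$model, m)
  r <- chainRmsd(pp$model, m, map, atom_selection = "P")
  expect_equal(r$n_atoms, 30L)
  # analytic check: direct least-squares evaluation on the P coordinates
  mc <- RiboDelta:::.matchedCoords(pp$model, m, map, "P")
  expect_equal(r$rmsd, quaternionSuperpose(mc$A, mc$B), tolerance = 1e-8)
  expect_gt(r$rmsd, 0)
  # rigid-moved copy of itself: 0
  R <- randomRotation()
  m2 <- m
  xyz <- as.matrix(atoms(m)[, c("x", "y", "z")]) %*% t(R)
  m2@atoms$x <- xyz[, 1] + 5; m2@atoms$y <- xyz[, 2] - 3
  m2@atoms$z <- xyz[, 3] + 1
  expect_lt(chainRmsd(m2, m, buildResidueMap(m2, m))$rmsd, 1e-9)
})

test_that("centers of mass are mass-weighted over heavy atoms", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C2    C A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  O2    C A   1       1.000   0.000   0.000  1.00  0.00           O",
    "ATOM      3  N1    C A   2       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      4  N3    C A   2       2.000   0.000   0.000  1.00  0.00           N",
    "ATOM      5  P     A A   3       3.000   4.000   0.000  1.00  0.00           P",
    "END"), f)
  m <- readStructure(f)
  # C + O: x = 15.999/(12.011+15.999)
  expect_equal(residueCom(m, "A:1:")[1], 15.999 / (12.011 + 15.999),
               tolerance = 1e-9)
  # two identical elements: midpoint
  expect_equal(residueCom(m, "A:2:"), c(1, 0, 0), tolerance = 1e-12)
  # single-atom residue: its own position
  expect_equal(residueCom(m, "A:3:"), c(3, 4, 0), tolerance = 1e-12)
  # geometric variant ignores masses
  expect_equal(residueCom(m, "A:1:", weighting = "geometric")[1], 0.5)
})

test_that("COM distances are symmetric and metric", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N1    C A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  N1    C A   2       3.000   4.000   0.000  1.00  0.00           N",
    "ATOM      3  N1    C A   3       6.000   0.000   0.000  1.00  0.00           N",
    "END"), f)
  m <- readStructure(f)
  expect_equal(comDistance(m, "A:1:", "A:2:"), 5)
  expect_equal(comDistance(m, "A:2:", "A:1:"), 5)
  expect_equal(comDistance(m, "A:1:", "A:1:"), 0)
  d12 <- comDistance(m, "A:1:", "A:2:")
  d23 <- comDistance(m, "A:2:", "A:3:")
  d13 <- comDistance(m, "A:1:", "A:3:")
  expect_lte(d13, d12 + d23)
  expect_error(comDistance(m, "A:1:", "A:9:"), "A:9:")
})

test_that("displacement flags obey the 1 A threshold", {
  m <- generateToyComplex(25, 6, seed = 36)
  map0 <- buildResidueMap(m, m)
  d0 <- displacementReport(m, m, map0)
  expect_true(all(d0$magnitude < 1e-9))
  expect_false(any(d0$flagged))

  mk <- function(shift) {
    pp <- perturb(m, perturbationPlan(
      displaced = data.frame(reskey = "A:9:", dx = shift, dy = 0, dz = 0)))
    displacementReport(pp$model, m, buildResidueMap(pp$model, m))
  }
  d25 <- mk(2.5)
  expect_equal(d25$keyA[d25$flagged], "A:9:")
  expect_equal(d25$magnitude[d25$keyA == "A:9:"], 2.5, tolerance = 1e-6)
  d08 <- mk(0.8)
  expect_false(any(d08$flagged))
  # the global least-squares frame absorbs part of a single small shift,
  # so the magnitude is near but at most the planted 0.8 A
  expect_equal(which.max(d08$magnitude),
               which(d08$keyA == "A:9:"))
  expect_lt(abs(d08$magnitude[d08$keyA == "A:9:"] - 0.8), 0.15)
})
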