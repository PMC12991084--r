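# Independent oracles used to check the package's optimized paths, plus
# tiny in-code fixtures. Each oracle is a direct, unoptimized computation
# that shares no code with the implementation it checks.

# all-pairs heavy-atom contact scan over polymer chains (O(N^2))
bruteForceContacts <- function(model, cutoff = 4.0) {
  a <- atoms(model)
  ent <- chains(model)$entity_class[match(a$chain, chains(model)$chain)]
  a <- a[!a$hydrogen & ent %in% c("rna", "protein"), ]
  n <- nrow(a)
  if (n < 2) return(data.frame(resA = character(), resB = character(),
                               distance = numeric()))
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (a$reskey[i] == a$reskey[j]) next
    if (d[i, j] <= cutoff)
      out[[length(out) + 1L]] <- data.frame(
        resA = a$reskey[i], atomA = a$elety[i], elementA = a$elesy[i],
        resB = a$reskey[j], atomB = a$elety[j], elementB = a$elesy[j],
        distance = d[i, j], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(resA = character(),
                                      resB = character(),
                                      distance = numeric()))
  do.call(rbind, out)
}

# exhaustive enumeration of all global alignments (short sequences only);
# returns the maximum score under match/mismatch/gap scoring
bruteForceAlignScore <- function(a, b, match = 1, mismatch = -1,
                                 gap = -2) {
  rec <- function(i, j) {
    if (i > nchar(a) && j > nchar(b)) return(0)
    best <- -Inf
    if (i <= nchar(a) && j <= nchar(b)) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= nchar(a)) best <- max(best, gap + rec(i + 1, j))
    if (j <= nchar(b)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# quaternion (Horn) rigid superposition: independent of the Kabsch/SVD path
quaternionSuperpose <- function(A, B) {
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  M <- crossprod(Ac, Bc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  fit <- sweep(Ac %*% t(R), 2, cB, "+")
  sqrt(mean(rowSums((fit - B)^2)))
}

# random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1)
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# minimal hand-written PDB / mmCIF fixtures sharing identical content
miniPdbText <- function() c(
  "ATOM      1  P     A A  10      11.000  22.000  33.000  1.00 10.00           P",
  "ATOM      2  C1'   A A  10      12.000  22.500  33.500  1.00 11.00           C",
  "ATOM      3  N9    A A  10      13.100  23.000  34.000  1.00 12.00           N",
  "ATOM      4  CA  GLY B   1       1.000   2.000   3.000  1.00  5.00           C",
  "TER", "END")

miniCifText <- function() c(
  "data_mini", "loop_",
  "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
  "_atom_site.label_atom_id", "_atom_site.label_alt_id",
  "_atom_site.label_comp_id", "_atom_site.label_asym_id",
  "_atom_site.label_entity_id", "_atom_site.label_seq_id",
  "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
  "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
  "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
  "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
  "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
  "ATOM 1 P P . A A 1 10 ? 11.000 22.000 33.000 1.00 10.00 10 A A P 1",
  "ATOM 2 C \"C1'\" . A A 1 10 ? 12.000 22.500 33.500 1.00 11.00 10 A A \"C1'\" 1",
  "ATOM 3 N N9 . A A 1 10 ? 13.100 23.000 34.000 1.00 12.00 10 A A N9 1",
  "ATOM 4 C CA . GLY B 2 1 ? 1.000 2.000 3.000 1.00 5.00 1 GLY B CA 1")

# toy pair with planted changes used across delta/report tests
plantedPair <- function(seed = 1L, jitter = 0) {
  base <- generateToyComplex(24, 8, seed = seed)
  r <- residues(base)
  # substitution at a purine so the rename is guaranteed to differ
  site <- r$reskey[r$chain == "A" & r$resid %in% c("A", "G")][2]
  new_base <- if (r$resid[r$reskey == site] == "A") "U" else "C"
  # contact edit between residues already forming the planted interface
  ct <- findContacts(base)
  rp <- ct[ct$category == "rna-protein", ][1, ]
  plan <- perturbationPlan(
    substitutions = data.frame(reskey = site, new_base = new_base),
    displaced = data.frame(reskey = "A:12:", dx = 1.8, dy = 1.2, dz = 0.9),
    contact_edits = data.frame(keyA = rp$resB, keyB = rp$resA,
                               sign = 1L, magnitude = 3L),
    jitter_sigma = jitter, seed = seed + 1000L)
  pp <- perturb(base, plan)
  list(base = base, perturbed = pp$model, truth = pp$ground_truth,
       plan = plan)
}
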