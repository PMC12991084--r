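# Rigid-body superposition (Kabsch), RMSD between mapped chains,
# per-residue displacement flags, and nucleotide center-of-mass distances
# (the decoding-site open/closed metric).

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rigid transform mapping `coordsA` onto `coordsB`
#' (B ~ R A + t) by SVD of the cross-covariance matrix with reflection
#' correction, plus the post-fit RMSD. Deterministic.
#'
#' @param coordsA,coordsB n x 3 matrices of matched points (n >= 3,
#'   non-degenerate)
#' @return list with `transform` (a [RigidTransform-class]) and `rmsd`
#'   (Angstrom)
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' superpose(a, a)$rmsd
#' @export
superpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) != nrow(coordsB) || ncol(coordsA) != 3 ||
      ncol(coordsB) != 3)
    stop("need equal-length n x 3 coordinate matrices")
  n <- nrow(coordsA)
  if (n < 3) stop("need at least 3 points")
  cA <- colMeans(coordsA); cB <- colMeans(coordsB)
  Ac <- sweep(coordsA, 2, cA); Bc <- sweep(coordsB, 2, cB)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  if (sv$d[2] < 1e-12)
    stop("degenerate (collinear) geometry; superposition is ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cB - R %*% cA)
  fit <- sweep(Ac %*% t(R), 2, cB, "+")
  rmsd <- sqrt(mean(rowSums((fit - coordsB)^2)))
  list(transform = new("RigidTransform", rotation = R, translation = t),
       rmsd = rmsd)
}

#' Apply a RigidTransform to coordinates
#' @param transform a [RigidTransform-class]
#' @param coords n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
applyTransform <- function(transform, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform@rotation), 2, transform@translation, "+")
}

# matched coordinates of mapped residues for a given atom selection
.matchedCoords <- function(A, B, map, atom_selection = c("P", "C1'",
                                                         "all-heavy")) {
  atom_selection <- match.arg(atom_selection)
  m <- mappedResidues(map)
  aA <- atoms(A); aA <- aA[!aA$hydrogen, ]
  aB <- atoms(B); aB <- aB[!aB$hydrogen, ]
  if (atom_selection != "all-heavy") {
    aA <- aA[aA$elety == atom_selection, ]
    aB <- aB[aB$elety == atom_selection, ]
  }
  # join on (mapped residue, atom name)
  iA <- match(m$keyA, aA$reskey)  # not enough for all-heavy; handled below
  if (atom_selection == "all-heavy") {
    kA <- paste(aA$reskey, aA$elety, sep = "\r")
    kB <- paste(aB$reskey, aB$elety, sep = "\r")
    b2a <- m$keyA; names(b2a) <- m$keyB
    kBt <- paste(b2a[aB$reskey], aB$elety, sep = "\r")
    sel <- match(kA, kBt)
    ok <- !is.na(sel)
    list(A = as.matrix(aA[ok, c("x", "y", "z")]),
         B = as.matrix(aB[sel[ok], c("x", "y", "z")]),
         keys = aA$reskey[ok])
  } else {
    iB <- match(m$keyB, aB$reskey)
    ok <- !is.na(iA) & !is.na(iB)
    list(A = as.matrix(aA[iA[ok], c("x", "y", "z")]),
         B = as.matrix(aB[iB[ok], c("x", "y", "z")]),
         keys = m$keyA[ok])
  }
}

#' RMSD between two mapped models
#'
#' Superposes the selected atoms of mapped residues (default: phosphate P
#' atoms, standard rRNA practice and robust to base flips) and returns the
#' post-fit RMSD and atom count.
#'
#' @param A,B [StructureModel-class] objects
#' @param map a [ResidueMap-class]
#' @param atom_selection "P", "C1'" or "all-heavy"
#' @return list: rmsd (Angstrom), n_atoms, transform
#' @export
chainRmsd <- function(A, B, map, atom_selection = c("P", "C1'",
                                                    "all-heavy")) {
  mc <- .matchedCoords(A, B, map, atom_selection)
  if (nrow(mc$A) < 3)
    stop("fewer than 3 mapped residues carry the selected atom in both ",
         "models")
  sp <- superpose(mc$A, mc$B)
  list(rmsd = sp$rmsd, n_atoms = nrow(mc$A), transform = sp$transform)
}

#' Center of mass of a residue
#'
#' Mass-weighted mean position of the residue's heavy atoms using standard
#' atomic masses; `weighting = "geometric"` gives the unweighted centroid
#' for sensitivity analysis.
#'
#' @param model a [StructureModel-class]
#' @param reskey residue key "chain:seq_id:icode"
#' @param weighting "mass" or "geometric"
#' @return length-3 numeric position (Angstrom)
#' @export
residueCom <- function(model, reskey, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  a <- atoms(model)
  a <- a[a$reskey == reskey & !a$hydrogen, , drop = FALSE]
  if (!nrow(a)) stop("residue has no heavy atoms: ", reskey)
  w <- if (weighting == "mass") .elementMass(a$elesy) else rep(1, nrow(a))
  c(sum(a$x * w), sum(a$y * w), sum(a$z * w)) / sum(w)
}

#' Distance between two residue centers of mass
#'
#' The decoding-site open/closed metric: e.g. the distance between the
#' centers of mass of the two adjacent decoding-center adenosines
#' distinguishes open (~9 A) from closed (~6.6-6.9 A) conformations.
#'
#' @param model a [StructureModel-class]
#' @param resA,resB residue keys
#' @inheritParams residueCom
#' @return distance in Angstrom
#' @export
comDistance <- function(model, resA, resB, weighting = "mass") {
  keys <- atoms(model)$reskey
  for (k in c(resA, resB))
    if (!k %in% keys) stop("residue not present in model: ", k)
  sqrt(sum((residueCom(model, resA, weighting) -
              residueCom(model, resB, weighting))^2))
}

# representative point per mapped residue: P for RNA, CA for protein,
# fallback C1' then heavy-atom COM
.representativePoints <- function(model, keys) {
  a <- atoms(model)
  a <- a[!a$hydrogen, ]
  ent <- model@chains$entity_class[match(.splitKey(keys)$chain,
                                         model@chains$chain)]
  out <- matrix(NA_real_, length(keys), 3)
  for (i in seq_along(keys)) {
    ra <- a[a$reskey == keys[i], , drop = FALSE]
    pref <- if (identical(ent[i], "protein")) c("CA", "CB") else c("P", "C1'")
    hit <- ra[ra$elety %in% pref, , drop = FALSE]
    if (nrow(hit)) {
      hit <- hit[order(match(hit$elety, pref)), ]
      out[i, ] <- as.numeric(hit[1, c("x", "y", "z")])
    } else {
      w <- .elementMass(ra$elesy)
      out[i, ] <- c(sum(ra$x * w), sum(ra$y * w), sum(ra$z * w)) / sum(w)
    }
  }
  out
}

#' Per-residue displacement report
#'
#' Superposes the two models on the representative atoms of all mapped
#' residues (P for RNA, alpha carbon for protein, center of mass as
#' fallback), then reports each mapped residue's representative-point
#' displacement; residues shifted by more than `cfg@shift_threshold`
#' (default 1 A) are flagged as regions of significant structural change.
#' The fit is trimmed: after an initial all-residue superposition, the
#' transform is re-estimated on the residues at or below the threshold
#' (twice, while at least 3 remain), so that a few genuinely displaced
#' residues cannot skew the global frame and smear apparent shifts onto
#' unmoved ones.
#'
#' @param A,B [StructureModel-class] objects
#' @param map a [ResidueMap-class]
#' @param cfg an [AnalysisConfig-class]
#' @return data.frame: keyA, keyB, chain, seq_id, magnitude (Angstrom),
#'   flagged
#' @export
displacementReport <- function(A, B, map, cfg = analysisConfig()) {
  m <- mappedResidues(map)
  pA <- .representativePoints(A, m$keyA)
  pB <- .representativePoints(B, m$keyB)
  sp <- superpose(pA, pB)
  mag <- sqrt(rowSums((applyTransform(sp$transform, pA) - pB)^2))
  for (pass in 1:2) {
    keep <- mag <= cfg@shift_threshold
    if (sum(keep) < 3) break
    sp <- superpose(pA[keep, , drop = FALSE], pB[keep, , drop = FALSE])
    mag <- sqrt(rowSums((applyTransform(sp$transform, pA) - pB)^2))
  }
  s <- .splitKey(m$keyA)
  out <- data.frame(keyA = m$keyA, keyB = m$keyB, chain = s$chain,
                    seq_id = s$resno, magnitude = mag,
                    flagged = mag > cfg@shift_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$seq_id), ]
  rownames(out) <- NULL
  out
}

#' Write a displacement report as TSV
#' @param report data.frame from [displacementReport]
#' @param path output path
#' @return invisibly, the path
#' @export
writeDisplacementReport <- function(report, path) {
  out <- report[, c("chain", "seq_id", "magnitude", "flagged")]
  out$magnitude <- sprintf("%.3f", out$magnitude)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a RigidTransform as a 3x4 matrix text file
#' @param transform a [RigidTransform-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeTransform <- function(transform, path) {
  m <- cbind(transform@rotation, transform@translation)
  utils::write.table(format(m, digits = 12), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform: rotation angle ",
      sprintf("%.2f", acos(pmin(pmax((sum(diag(object@rotation)) - 1) / 2,
                                     -1), 1)) * 180 / pi),
      " deg, translation |t| = ",
      sprintf("%.2f", sqrt(sum(object@translation^2))), " A\n", sep = "")
  invisible(NULL)
})
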