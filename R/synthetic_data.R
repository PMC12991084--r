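# Paired toy ribonucleoprotein models with planted substitutions,
# displacements and interface contact edits, plus synthetic quality tables
# - ground truth for every pipeline stage without any downloads. The toy
# chemistry is geometrically controlled, not chemically plausible: real
# element symbols and standard masses are used so center-of-mass and
# polar-proximity code behaves as on real structures, but the fold is a
# coarse parametric helix.

# base atom templates: offsets along the inward radial direction (toward
# the helix axis) and small tangential/axial spreads, per parent base
.BASE_ATOMS <- list(
  A = data.frame(elety = c("N9", "C8", "N7", "C5", "N1"),
                 r = c(0.0, 0.7, 1.5, 2.1, 3.1),
                 t = c(0.0, 0.9, 0.8, 0.1, 0.3),
                 z = c(0.0, 0.1, 0.2, 0.1, 0.0)),
  G = data.frame(elety = c("N9", "C8", "N7", "C5", "O6"),
                 r = c(0.0, 0.7, 1.5, 2.1, 3.3),
                 t = c(0.0, 0.9, 0.8, 0.1, -0.4),
                 z = c(0.0, 0.1, 0.2, 0.1, 0.0)),
  C = data.frame(elety = c("N1", "C2", "O2", "N3"),
                 r = c(0.0, 0.9, 1.3, 2.1),
                 t = c(0.0, 0.7, -0.6, 0.5),
                 z = c(0.0, 0.1, 0.1, 0.0)),
  U = data.frame(elety = c("N1", "C2", "O2", "N3"),
                 r = c(0.0, 0.9, 1.4, 2.1),
                 t = c(0.0, 0.7, -0.7, 0.5),
                 z = c(0.0, 0.1, 0.1, 0.2)))

.SIDE_CHAINS <- list(
  ALA = data.frame(elety = "CB", d = 1.5),
  SER = data.frame(elety = c("CB", "OG"), d = c(1.5, 2.9)),
  ASP = data.frame(elety = c("CB", "CG", "OD1"), d = c(1.5, 2.9, 4.1)),
  LEU = data.frame(elety = c("CB", "CG", "CD1"), d = c(1.5, 2.9, 4.2)),
  LYS = data.frame(elety = c("CB", "CG", "NZ"), d = c(1.5, 2.9, 4.5)),
  THR = data.frame(elety = c("CB", "OG1"), d = c(1.5, 2.8)))

.elementFromName <- function(elety) substr(gsub("[^A-Z]", "", elety), 1, 1)

# atoms of one nucleotide at helix angle theta (rad) and height z0;
# u = inward radial unit vector, v = tangential unit vector
.nucleotideAtoms <- function(base, theta, z0, p_radius = 9.2) {
  u <- c(-cos(theta), -sin(theta), 0)
  v <- c(-sin(theta), cos(theta), 0)
  bb <- data.frame(
    elety = c("P", "OP1", "OP2", "C1'"),
    r = c(0.0, -0.4, -0.3, 1.8),
    t = c(0.0, 0.8, -0.9, 0.6),
    z = c(0.0, 0.6, -0.6, 0.3))
  ba <- .BASE_ATOMS[[base]]
  ba$r <- ba$r + 3.6            # base sits inward of C1'
  ba$t <- ba$t + 0.6
  ba$z <- ba$z + 0.3
  all <- rbind(bb, ba)
  origin <- c(p_radius * cos(theta), p_radius * sin(theta), z0)
  pos <- t(vapply(seq_len(nrow(all)), function(i)
    origin + all$r[i] * u + all$t[i] * v + c(0, 0, all$z[i]),
    numeric(3)))
  data.frame(elety = all$elety, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a toy RNA-protein complex
#'
#' Deterministic (for a fixed seed) toy model: an RNA chain "A" laid out as
#' a coarse single-helical backbone-plus-base arrangement (P, OP1, OP2,
#' C1', glycosidic nitrogen and 3-4 base heavy atoms per nucleotide) and,
#' if `n_protein > 0`, a protein chain "B" as a backbone trace with 1-3
#' side-chain atoms per residue, positioned alongside the RNA so that an
#' interface with heavy-atom contacts at 4 A exists (guaranteed for
#' `n_protein >= 5` by construction: one serine side-chain oxygen is
#' placed 3.4 A from an RNA phosphate).
#'
#' @param n_rna number of nucleotides (>= 4)
#' @param n_protein number of amino acids (>= 0)
#' @param seed integer seed; the global RNG state is left untouched
#' @return a [StructureModel-class]
#' @examples
#' generateToyComplex(12, 6, seed = 1)
#' @export
generateToyComplex <- function(n_rna, n_protein, seed = 1L) {
  if (n_rna < 4) stop("n_rna must be >= 4")
  if (n_protein < 0) stop("n_protein must be >= 0")
  .withSeed(seed, {
    bases <- sample(c("A", "C", "G", "U"), n_rna, replace = TRUE)
    twist <- 32 * pi / 180; rise <- 2.6
    rows <- list()
    for (i in seq_len(n_rna)) {
      at <- .nucleotideAtoms(bases[i], (i - 1) * twist, (i - 1) * rise)
      at$chain <- "A"; at$resno <- i; at$resid <- bases[i]
      rows[[length(rows) + 1L]] <- at
    }
    if (n_protein > 0) {
      resnames <- sample(names(.SIDE_CHAINS), n_protein, replace = TRUE)
      if (n_protein >= 5) resnames[3] <- "SER"
      # CA trace on a line parallel to the helix axis, facing it
      ca_r <- 14.5
      mid_z <- (n_rna - 1) * rise / 2
      theta0 <- ((n_rna - 1) / 2) * twist
      axis_dir <- c(cos(theta0), sin(theta0), 0)
      for (i in seq_len(n_protein)) {
        z <- mid_z + (i - (n_protein + 1) / 2) * 3.4
        ca <- ca_r * axis_dir + c(0, 0, z)
        u <- -axis_dir                      # toward the helix axis
        v <- c(-axis_dir[2], axis_dir[1], 0)
        bb <- rbind(ca + 1.46 * v + 0.4 * u,      # N
                    ca,                            # CA
                    ca - 1.52 * v + 0.5 * u,      # C
                    ca - 1.9 * v + 1.6 * u)       # O
        at <- data.frame(elety = c("N", "CA", "C", "O"),
                         x = bb[, 1], y = bb[, 2], z = bb[, 3],
                         stringsAsFactors = FALSE)
        sc <- .SIDE_CHAINS[[resnames[i]]]
        for (s in seq_len(nrow(sc))) {
          p <- ca + sc$d[s] * u + 0.2 * s * v
          at <- rbind(at, data.frame(elety = sc$elety[s],
                                     x = p[1], y = p[2], z = p[3]))
        }
        at$chain <- "B"; at$resno <- i; at$resid <- resnames[i]
        rows[[length(rows) + 1L]] <- at
      }
    }
    a <- do.call(rbind, rows)
    a$insert <- ""; a$alt <- ""; a$o <- 1; a$b <- 0
    a$elesy <- .elementFromName(a$elety)
    m <- .newStructureModel(
      a[, c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "b", "alt")],
      label = sprintf("toy-%d-%d-s%d", n_rna, n_protein, seed))
    if (n_protein >= 5) {
      # constructive interface guarantee: put residue 3's OG 3.4 A from
      # the nearest RNA phosphate
      at <- m@atoms
      og <- which(at$chain == "B" & at$resno == 3 & at$elety == "OG")
      ps <- at[at$chain == "A" & at$elety == "P", ]
      ogp <- as.numeric(at[og, c("x", "y", "z")])
      d2 <- (ps$x - ogp[1])^2 + (ps$y - ogp[2])^2 + (ps$z - ogp[3])^2
      k <- which.min(d2)
      p <- as.numeric(ps[k, c("x", "y", "z")])
      dir <- ogp - p; dir <- dir / sqrt(sum(dir^2))
      m@atoms[og, c("x", "y", "z")] <- as.list(p + 3.4 * dir)
    }
    m
  })
}

#' Construct a perturbation plan
#'
#' @param substitutions data.frame(reskey, new_base) or NULL
#' @param displaced data.frame(reskey, dx, dy, dz) or NULL
#' @param contact_edits data.frame(keyA, keyB, sign, magnitude) or NULL;
#'   sign +1 plants a contact gain in the perturbed model (delta >=
#'   +magnitude when the perturbed model is compared as A against the base
#'   as B), -1 a loss
#' @param global_transform a [RigidTransform-class] or NULL
#' @param jitter_sigma isotropic Gaussian coordinate noise sd (Angstrom)
#' @param seed integer seed
#' @return a [PerturbationPlan-class]
#' @export
perturbationPlan <- function(substitutions = NULL, displaced = NULL,
                             contact_edits = NULL, global_transform = NULL,
                             jitter_sigma = 0, seed = 1L) {
  emptyDf <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  if (is.null(substitutions))
    substitutions <- emptyDf(reskey = character(), new_base = character())
  if (is.null(displaced))
    displaced <- emptyDf(reskey = character(), dx = numeric(),
                         dy = numeric(), dz = numeric())
  if (is.null(contact_edits))
    contact_edits <- emptyDf(keyA = character(), keyB = character(),
                             sign = integer(), magnitude = integer())
  new("PerturbationPlan", substitutions = substitutions,
      displaced = displaced, contact_edits = contact_edits,
      global_transform = global_transform, jitter_sigma = jitter_sigma,
      seed = as.integer(seed))
}

# count heavy-atom pairs <= cutoff between two residues of an atom table
.pairContactCount <- function(a, keyA, keyB, cutoff) {
  p1 <- a[a$reskey == keyA & !a$hydrogen, c("x", "y", "z")]
  p2 <- a[a$reskey == keyB & !a$hydrogen, c("x", "y", "z")]
  d2 <- outer(seq_len(nrow(p1)), seq_len(nrow(p2)), function(i, j)
    (p1$x[i] - p2$x[j])^2 + (p1$y[i] - p2$y[j])^2 + (p1$z[i] - p2$z[j])^2)
  sum(d2 <= cutoff^2)
}

#' Apply a perturbation plan to a model
#'
#' Produces the perturbed ("mutant") model and exact ground truth.
#' Substitutions rename residues and re-place their base atoms from the
#' new base's template; displacements translate whole residues;
#' contact edits move the first residue of each pair along the
#' inter-residue axis in 0.25 A steps until the recomputed pair count
#' difference (perturbed - base) has the requested sign and magnitude;
#' the optional global transform and seeded Gaussian jitter are applied
#' last. Ground truth stores what was realized (recomputed after
#' construction), not what was requested.
#'
#' @param model base [StructureModel-class]
#' @param plan a [PerturbationPlan-class]
#' @param cutoff contact cutoff used when realizing contact edits
#' @param max_steps bound on contact-edit iterations before erroring
#' @return list: `model` (perturbed [StructureModel-class]) and
#'   `ground_truth`, a list with data.frames `substitutions` (reskey,
#'   old_base, new_base), `displacements` (reskey, magnitude: total
#'   pre-jitter translation applied), `contact_deltas` (keyA, keyB, delta:
#'   exact recomputed perturbed-minus-base pair count)
#' @export
perturb <- function(model, plan, cutoff = 4.0, max_steps = 200L) {
  a0 <- atoms(model)
  bad <- setdiff(c(plan@substitutions$reskey, plan@displaced$reskey,
                   plan@contact_edits$keyA, plan@contact_edits$keyB),
                 a0$reskey)
  if (length(bad))
    stop("plan addresses residues absent from the model: ",
         paste(bad, collapse = ", "))
  a <- a0
  shift <- matrix(0, nrow(residues(model)), 3,
                  dimnames = list(residues(model)$reskey, NULL))

  # substitutions: rename + re-place glycosidic/base atoms from template
  subs <- plan@substitutions
  gt_subs <- data.frame(reskey = character(), old_base = character(),
                        new_base = character(), stringsAsFactors = FALSE)
  backbone <- c("P", "OP1", "OP2", "C1'")
  for (i in seq_len(nrow(subs))) {
    k <- subs$reskey[i]; nb <- subs$new_base[i]
    idx <- which(a$reskey == k)
    old <- a$resid[idx[1]]
    if (old == nb) next
    keep <- idx[a$elety[idx] %in% backbone]
    drop <- setdiff(idx, keep)
    # local frame: inward direction approximated from C1' - P
    pP <- as.numeric(a[idx[a$elety[idx] == "P"][1], c("x", "y", "z")])
    pC <- as.numeric(a[idx[a$elety[idx] == "C1'"][1], c("x", "y", "z")])
    u <- pC - pP; u <- u / sqrt(sum(u^2))
    v <- c(-u[2], u[1], 0); v <- v / sqrt(sum(v^2))
    ba <- .BASE_ATOMS[[nb]]
    newrows <- a[rep(idx[1], nrow(ba)), ]
    for (s in seq_len(nrow(ba))) {
      p <- pC + (1.8 + ba$r[s]) * u + ba$t[s] * v + c(0, 0, ba$z[s])
      newrows$elety[s] <- ba$elety[s]
      newrows$x[s] <- p[1]; newrows$y[s] <- p[2]; newrows$z[s] <- p[3]
    }
    newrows$elesy <- .elementFromName(newrows$elety)
    newrows$hydrogen <- FALSE
    if (length(drop)) a <- a[-drop, ]
    a <- rbind(a, newrows)
    a$resid[a$reskey == k] <- nb
    gt_subs <- rbind(gt_subs, data.frame(reskey = k, old_base = old,
                                         new_base = nb))
  }

  # whole-residue displacements
  for (i in seq_len(nrow(plan@displaced))) {
    k <- plan@displaced$reskey[i]
    d <- as.numeric(plan@displaced[i, c("dx", "dy", "dz")])
    idx <- a$reskey == k
    a$x[idx] <- a$x[idx] + d[1]
    a$y[idx] <- a$y[idx] + d[2]
    a$z[idx] <- a$z[idx] + d[3]
    shift[k, ] <- shift[k, ] + d
  }

  # contact edits: walk residue keyA along the pair axis until the
  # recomputed perturbed-minus-base count difference meets the request
  ce <- plan@contact_edits
  for (i in seq_len(nrow(ce))) {
    kA <- ce$keyA[i]; kB <- ce$keyB[i]
    sgn <- ce$sign[i]; mag <- ce$magnitude[i]
    base_n <- .pairContactCount(a0, kA, kB, cutoff)
    if (sgn < 0 && base_n < mag)
      stop("unsatisfiable contact edit for pair ", kA, " / ", kB,
           ": base model has only ", base_n, " contacts to lose")
    comA <- function(tab, k) {
      r <- tab[tab$reskey == k, ]
      c(mean(r$x), mean(r$y), mean(r$z))
    }
    dir <- comA(a, kB) - comA(a, kA)
    dir <- dir / sqrt(sum(dir^2)) * sign(sgn)
    step <- 0.25; done <- FALSE
    for (s in seq_len(max_steps)) {
      cur <- .pairContactCount(a, kA, kB, cutoff)
      if (sgn > 0 && cur - base_n >= mag) { done <- TRUE; break }
      if (sgn < 0 && cur - base_n <= -mag) { done <- TRUE; break }
      idx <- a$reskey == kA
      a$x[idx] <- a$x[idx] + dir[1] * step
      a$y[idx] <- a$y[idx] + dir[2] * step
      a$z[idx] <- a$z[idx] + dir[3] * step
      shift[kA, ] <- shift[kA, ] + dir * step
    }
    if (!done && {
      cur <- .pairContactCount(a, kA, kB, cutoff)
      !((sgn > 0 && cur - base_n >= mag) ||
          (sgn < 0 && cur - base_n <= -mag))
    })
      stop("contact edit for pair ", kA, " / ", kB,
           " unsatisfied after ", max_steps, " steps")
  }

  # global rigid transform, then seeded jitter
  if (!is.null(plan@global_transform)) {
    xyz <- applyTransform(plan@global_transform,
                          as.matrix(a[, c("x", "y", "z")]))
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  }
  if (plan@jitter_sigma > 0) {
    .withSeed(plan@seed, {
      a$x <- a$x + stats::rnorm(nrow(a), 0, plan@jitter_sigma)
      a$y <- a$y + stats::rnorm(nrow(a), 0, plan@jitter_sigma)
      a$z <- a$z + stats::rnorm(nrow(a), 0, plan@jitter_sigma)
    })
  }

  pert <- .newStructureModel(
    a[, c("chain", "resno", "insert", "resid", "elety", "elesy",
          "x", "y", "z", "o", "b", "alt")],
    label = paste0(modelLabel(model), "-perturbed"))

  # exact recomputed ground truth for the edited/displaced pairs
  aP <- atoms(pert)
  gt_delta <- data.frame(keyA = character(), keyB = character(),
                         delta = integer(), stringsAsFactors = FALSE)
  touched <- unique(rbind(ce[, c("keyA", "keyB")]))
  for (i in seq_len(nrow(touched))) {
    d <- .pairContactCount(aP, touched$keyA[i], touched$keyB[i], cutoff) -
      .pairContactCount(a0, touched$keyA[i], touched$keyB[i], cutoff)
    gt_delta <- rbind(gt_delta, data.frame(keyA = touched$keyA[i],
                                           keyB = touched$keyB[i],
                                           delta = as.integer(d)))
  }
  mags <- sqrt(rowSums(shift^2))
  gt_disp <- data.frame(reskey = rownames(shift)[mags > 0],
                        magnitude = unname(mags[mags > 0]),
                        stringsAsFactors = FALSE)
  list(model = pert,
       ground_truth = list(substitutions = gt_subs,
                           displacements = gt_disp,
                           contact_deltas = gt_delta))
}

#' Generate a synthetic per-residue quality table
#'
#' Every residue receives q = base_q plus seeded Gaussian noise (sd
#' `noise_sd`, clipped to \[-1, 1\]); residues in `bad_residues` instead
#' draw q uniformly from \[0.05, 0.35\], i.e. below the 0.4 exclusion
#' threshold. Local resolution follows a center-to-periphery gradient
#' (best at the model centroid, worst at the periphery), emulating the
#' peripheral resolution drop-off of single-particle maps.
#'
#' @param model a [StructureModel-class]
#' @param base_q baseline Q-score in \[0, 1\]
#' @param bad_residues residue keys planted below the exclusion threshold
#' @param seed integer seed
#' @param noise_sd Gaussian sd of the Q-score noise
#' @param locres_range length-2 numeric: local resolution at the centroid
#'   and at the periphery (Angstrom)
#' @return a [QualityTable-class]
#' @export
generateQualityTable <- function(model, base_q = 0.8,
                                 bad_residues = character(), seed = 1L,
                                 noise_sd = 0.05,
                                 locres_range = c(2.2, 3.8)) {
  stopifnot(base_q >= 0, base_q <= 1)
  r <- residues(model)
  a <- atoms(model)
  .withSeed(seed, {
    q <- pmin(pmax(base_q + stats::rnorm(nrow(r), 0, noise_sd), -1), 1)
    bad <- r$reskey %in% bad_residues
    q[bad] <- stats::runif(sum(bad), 0.05, 0.35)
    ctr <- c(mean(a$x), mean(a$y), mean(a$z))
    com <- t(vapply(r$reskey, function(k) {
      ra <- a[a$reskey == k, ]
      c(mean(ra$x), mean(ra$y), mean(ra$z))
    }, numeric(3)))
    d <- sqrt(rowSums(sweep(com, 2, ctr)^2))
    rel <- if (max(d) > 0) d / max(d) else rep(0, length(d))
    lr <- locres_range[1] + rel * (locres_range[2] - locres_range[1])
    qualityTable(data.frame(chain = r$chain, seq_id = r$resno,
                            icode = r$insert, q_score = q,
                            local_resolution = lr,
                            stringsAsFactors = FALSE))
  })
}
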