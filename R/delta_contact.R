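# The core comparison procedure: quality tables, delta-contact matrices
# between mapped structures, residue-resolved gain/loss scores, quality
# exclusions, aggregation, significance flags and mutation neighborhoods.

#' Analysis configuration with the pipeline's default thresholds
#'
#' @param contact_cutoff heavy-atom contact cutoff, Angstrom
#' @param interface_cutoff interface counting cutoff, Angstrom
#' @param q_exclude residues with Q-score below this are excluded
#' @param q_change_frac relative Q-score change that flags a site (0.10 =
#'   10\%)
#' @param locres_change local-resolution change (Angstrom) that flags a site
#' @param neighborhood_radius mutation neighborhood radius, Angstrom
#' @param min_local_resolution neighborhoods keep residues resolved at
#'   local resolution at or better than (numerically <=) this value
#' @param shift_threshold displacement flag threshold, Angstrom
#' @return an [AnalysisConfig-class]
#' @examples
#' analysisConfig()
#' @export
analysisConfig <- function(contact_cutoff = 4.0, interface_cutoff = 4.0,
                           q_exclude = 0.4, q_change_frac = 0.10,
                           locres_change = 0.5, neighborhood_radius = 10.0,
                           min_local_resolution = 3.0,
                           shift_threshold = 1.0) {
  new("AnalysisConfig", contact_cutoff = contact_cutoff,
      interface_cutoff = interface_cutoff, q_exclude = q_exclude,
      q_change_frac = q_change_frac, locres_change = locres_change,
      neighborhood_radius = neighborhood_radius,
      min_local_resolution = min_local_resolution,
      shift_threshold = shift_threshold)
}

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n",
      "  contact_cutoff        ", object@contact_cutoff, " A\n",
      "  interface_cutoff      ", object@interface_cutoff, " A\n",
      "  q_exclude             ", object@q_exclude, "\n",
      "  q_change_frac         ", object@q_change_frac, "\n",
      "  locres_change         ", object@locres_change, " A\n",
      "  neighborhood_radius   ", object@neighborhood_radius, " A\n",
      "  min_local_resolution  ", object@min_local_resolution, " A\n",
      "  shift_threshold       ", object@shift_threshold, " A\n", sep = "")
  invisible(NULL)
})

#' Construct a QualityTable
#'
#' @param df data.frame with columns chain, seq_id, icode (optional),
#'   q_score, local_resolution (optional, NA allowed)
#' @return a [QualityTable-class]
#' @export
qualityTable <- function(df) {
  if (is.null(df$icode)) df$icode <- ""
  df$icode[is.na(df$icode)] <- ""
  if (is.null(df$local_resolution)) df$local_resolution <- NA_real_
  rows <- data.frame(chain = as.character(df$chain),
                     seq_id = as.integer(df$seq_id),
                     icode = as.character(df$icode),
                     q_score = as.numeric(df$q_score),
                     local_resolution = as.numeric(df$local_resolution),
                     stringsAsFactors = FALSE)
  rows$reskey <- .resKey(rows$chain, rows$seq_id, rows$icode)
  new("QualityTable", rows = rows)
}

#' Read a per-residue quality table from TSV
#'
#' Expected header: `chain seq_id icode q_score local_resolution` (tab
#' separated); blank local_resolution is allowed.
#'
#' @param path TSV path
#' @return a [QualityTable-class]
#' @export
readQualityTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chain = "character",
                                         icode = "character"),
                          na.strings = c("NA", ""), fill = TRUE)
  df$icode[is.na(df$icode)] <- ""
  qualityTable(df)
}

#' Write a QualityTable as TSV
#' @param qt a [QualityTable-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeQualityTable <- function(qt, path) {
  out <- qt@rows[, c("chain", "seq_id", "icode", "q_score",
                     "local_resolution")]
  out$q_score <- sprintf("%.4f", out$q_score)
  out$local_resolution <- ifelse(is.na(out$local_resolution), "",
                                 sprintf("%.3f", out$local_resolution))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn qualityTable rows accessor
#' @export
qualityRows <- function(qt) qt@rows

.qLookup <- function(qt, keys) {
  if (is.null(qt)) return(rep(NA_real_, length(keys)))
  qt@rows$q_score[match(keys, qt@rows$reskey)]
}
.lrLookup <- function(qt, keys) {
  if (is.null(qt)) return(rep(NA_real_, length(keys)))
  qt@rows$local_resolution[match(keys, qt@rows$reskey)]
}

#' Delta-contact matrix between two mapped models
#'
#' Translates model-B residue pairs into model-A numbering through the
#' residue map and forms the entrywise difference countA - countB (missing
#' entries are 0). Any pair touching a residue that is unmapped in either
#' model, or whose Q-score is below `cfg@q_exclude` in either quality
#' table, is excluded before differencing, with the reason recorded
#' (`unmapped`, `q_below_threshold`). Residues with no quality row pass the
#' exclusion but are marked `unassessed` in the report, not excluded.
#'
#' @param matA,matB [ContactMatrix-class] objects of the same category and
#'   cutoff (A and B respectively)
#' @param map [ResidueMap-class] from model A to model B
#' @param qualA,qualB optional [QualityTable-class] objects
#' @param cfg an [AnalysisConfig-class]
#' @return a [DeltaMatrix-class] keyed in model-A numbering
#' @export
deltaMatrix <- function(matA, matB, map, qualA = NULL, qualB = NULL,
                        cfg = analysisConfig()) {
  if (matA@category != matB@category)
    stop("contact matrices have different categories")
  if (matA@cutoff != matB@cutoff)
    stop("contact matrices were computed at different cutoffs")
  m <- mappedResidues(map)
  if (!nrow(m)) stop("residue map is empty")
  b2a <- m$keyA; names(b2a) <- m$keyB

  # residue-level exclusions, in A numbering
  excl <- data.frame(reskey = character(), reason = character(),
                     stringsAsFactors = FALSE)
  badQA <- m$keyA[!is.na(.qLookup(qualA, m$keyA)) &
                    .qLookup(qualA, m$keyA) < cfg@q_exclude]
  badQB <- m$keyA[!is.na(.qLookup(qualB, m$keyB)) &
                    .qLookup(qualB, m$keyB) < cfg@q_exclude]
  badQ <- union(badQA, badQB)
  if (length(badQ))
    excl <- rbind(excl, data.frame(reskey = badQ,
                                   reason = "q_below_threshold"))
  unm <- unmappedResidues(map, "A")
  if (length(unm))
    excl <- rbind(excl, data.frame(reskey = unm, reason = "unmapped"))

  cntA <- contactCounts(matA)
  cntB <- contactCounts(matB)
  # translate B pairs into A numbering; pairs touching unmapped B residues
  # are dropped (their A-side counterparts are excluded as unmapped too)
  if (nrow(cntB)) {
    kA1 <- b2a[cntB$keyA]; kA2 <- b2a[cntB$keyB]
    okB <- !is.na(kA1) & !is.na(kA2)
    cp <- if (any(okB)) .canonPairs(kA1[okB], kA2[okB]) else
      data.frame(keyA = character(), keyB = character())
    cntBt <- data.frame(cp, count = cntB$count[okB],
                        stringsAsFactors = FALSE)
  } else cntBt <- data.frame(keyA = character(), keyB = character(),
                             count = integer(), stringsAsFactors = FALSE)
  mappedA <- m$keyA
  if (nrow(cntA)) {
    okA <- cntA$keyA %in% mappedA & cntA$keyB %in% mappedA
    cntAt <- cntA[okA, , drop = FALSE]
  } else cntAt <- cntA

  dropBad <- function(df) {
    if (!nrow(df) || !nrow(excl)) return(df)
    df[!(df$keyA %in% excl$reskey | df$keyB %in% excl$reskey), ,
       drop = FALSE]
  }
  cntAt <- dropBad(cntAt); cntBt <- dropBad(cntBt)

  pk <- function(df) paste(df$keyA, df$keyB, sep = "\r")
  allp <- union(pk(cntAt), pk(cntBt))
  if (length(allp)) {
    keys <- strsplit(allp, "\r", fixed = TRUE)
    delta <- data.frame(keyA = vapply(keys, `[`, "", 1L),
                        keyB = vapply(keys, `[`, "", 2L),
                        stringsAsFactors = FALSE)
    a <- cntAt$count[match(allp, pk(cntAt))]
    b <- cntBt$count[match(allp, pk(cntBt))]
    a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
    delta$delta <- as.integer(a - b)
    delta <- delta[order(delta$keyA, delta$keyB), ]
    rownames(delta) <- NULL
  } else {
    delta <- data.frame(keyA = character(), keyB = character(),
                        delta = integer(), stringsAsFactors = FALSE)
  }
  excl <- unique(excl)
  new("DeltaMatrix", category = matA@category, cutoff = matA@cutoff,
      delta = delta, excluded = excl)
}

#' @describeIn deltaMatrix delta table accessor
#' @param dm a DeltaMatrix
#' @export
deltaCounts <- function(dm) dm@delta

#' @describeIn deltaMatrix excluded residues with reasons
#' @export
excludedResidues <- function(dm) dm@excluded

#' Residue-resolved gain/loss scores
#'
#' For each residue, gains is the sum of positive deltas and losses the sum
#' of negative-delta magnitudes over all of its partner pairs; net = gains
#' - losses. Each pair contributes to both of its residues, so the residue
#' nets sum to twice the pair-delta sum. Negative net marks net contact
#' loss (destabilization, red end of the spectrum), positive net marks net
#' gain (stabilization, blue).
#'
#' @param dm a [DeltaMatrix-class]
#' @return data.frame: reskey, gains, losses, net
#' @export
residueDeltaScores <- function(dm) {
  d <- deltaCounts(dm)
  if (!nrow(d))
    return(data.frame(reskey = character(), gains = integer(),
                      losses = integer(), net = integer(),
                      stringsAsFactors = FALSE))
  long <- data.frame(reskey = c(d$keyA, d$keyB), delta = c(d$delta, d$delta))
  gains <- tapply(pmax(long$delta, 0L), long$reskey, sum)
  losses <- tapply(pmax(-long$delta, 0L), long$reskey, sum)
  out <- data.frame(reskey = names(gains),
                    gains = as.integer(gains),
                    losses = as.integer(losses[names(gains)]),
                    stringsAsFactors = FALSE)
  out$net <- out$gains - out$losses
  out <- out[.orderKeys(out$reskey), ]
  rownames(out) <- NULL
  out
}

#' Aggregate residue scores per nucleotide or per chain
#'
#' The standard visualization convention for ribosome comparisons: RNA
#' scores stay per nucleotide, protein scores are summed per chain.
#'
#' @param scores data.frame from [residueDeltaScores]
#' @param model the [StructureModel-class] the residue keys refer to
#' @param mode "per_nucleotide" (RNA residues, unchanged) or "per_chain"
#'   (protein chains, summed)
#' @return data.frame of aggregated gains/losses/net
#' @export
aggregateScores <- function(scores, model,
                            mode = c("per_nucleotide", "per_chain")) {
  mode <- match.arg(mode)
  ent <- model@chains$entity_class[match(.splitKey(scores$reskey)$chain,
                                         model@chains$chain)]
  if (mode == "per_nucleotide") {
    out <- scores[!is.na(ent) & ent == "rna", , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  sub <- scores[!is.na(ent) & ent == "protein", , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(chain = character(), gains = integer(),
                      losses = integer(), net = integer(),
                      stringsAsFactors = FALSE))
  ch <- .splitKey(sub$reskey)$chain
  agg <- function(v) as.integer(tapply(v, ch, sum))
  out <- data.frame(chain = sort(unique(ch)), gains = agg(sub$gains),
                    losses = agg(sub$losses), net = agg(sub$net),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag residues with significant model-quality change
#'
#' A mapped residue is flagged when its relative Q-score change exceeds
#' `cfg@q_change_frac` (baseline: model B, denominator max(|qB|, 1e-9)) or
#' its local-resolution change exceeds `cfg@locres_change` Angstrom.
#' Residues not covered by both quality tables are skipped.
#'
#' @param qualA,qualB [QualityTable-class] objects for models A and B
#' @param map a [ResidueMap-class]
#' @param cfg an [AnalysisConfig-class]
#' @return data.frame: keyA, keyB, q_a, q_b, locres_a, locres_b, criterion
#'   ("q_score", "local_resolution" or "both"); one row per flagged residue
#' @export
flagSignificantSites <- function(qualA, qualB, map, cfg = analysisConfig()) {
  m <- mappedResidues(map)
  qA <- .qLookup(qualA, m$keyA); qB <- .qLookup(qualB, m$keyB)
  lA <- .lrLookup(qualA, m$keyA); lB <- .lrLookup(qualB, m$keyB)
  qflag <- !is.na(qA) & !is.na(qB) &
    abs(qA - qB) / pmax(abs(qB), 1e-9) > cfg@q_change_frac
  lflag <- !is.na(lA) & !is.na(lB) & abs(lA - lB) > cfg@locres_change
  hit <- qflag | lflag
  data.frame(keyA = m$keyA[hit], keyB = m$keyB[hit],
             q_a = qA[hit], q_b = qB[hit],
             locres_a = lA[hit], locres_b = lB[hit],
             criterion = ifelse(qflag[hit] & lflag[hit], "both",
                                ifelse(qflag[hit], "q_score",
                                       "local_resolution")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Residue neighborhood of each mutation site
#'
#' For each substitution site, the residues with any heavy atom within
#' `cfg@neighborhood_radius` (10 A) of any heavy atom of the site residue.
#' Where a quality table provides local resolution, neighbors are restricted
#' to those resolved at or better than `cfg@min_local_resolution`
#' (numeric value <= 3.0 A); residues without a resolution value are kept.
#' The site residue itself is always included.
#'
#' @param model the [StructureModel-class] the sites refer to
#' @param sites data.frame from [listSubstitutions] (column keyA), or a
#'   character vector of residue keys
#' @param qual optional [QualityTable-class]
#' @param cfg an [AnalysisConfig-class]
#' @return named list: site key -> character vector of residue keys
#' @export
mutationNeighborhood <- function(model, sites, qual = NULL,
                                 cfg = analysisConfig()) {
  keys <- if (is.data.frame(sites)) sites$keyA else sites
  a <- atoms(model)
  a <- a[!a$hydrogen, , drop = FALSE]
  out <- lapply(keys, function(k) {
    site <- a[a$reskey == k, c("x", "y", "z"), drop = FALSE]
    if (!nrow(site)) stop("site not present in model: ", k)
    sm <- as.matrix(site)
    d2min <- rep(Inf, nrow(a))
    for (s in seq_len(nrow(sm))) {
      d2 <- (a$x - sm[s, 1])^2 + (a$y - sm[s, 2])^2 + (a$z - sm[s, 3])^2
      d2min <- pmin(d2min, d2)
    }
    near <- unique(a$reskey[d2min <= cfg@neighborhood_radius^2])
    if (!is.null(qual)) {
      lr <- .lrLookup(qual, near)
      near <- near[is.na(lr) | lr <= cfg@min_local_resolution | near == k]
    }
    near <- union(k, near)
    near[.orderKeys(near)]
  })
  names(out) <- keys
  out
}

#' Encode delta-contact net scores as B-factors
#'
#' Writes the model as PDB with each residue's net delta score in the
#' temperature-factor column (delegates to [writeBfactorEncoded]); loss
#' stays negative so a red-white-blue spectrum maps loss to red and gain
#' to blue.
#'
#' @param model a [StructureModel-class]
#' @param scores data.frame from [residueDeltaScores]
#' @param path output PDB path
#' @return invisibly, the path
#' @export
encodeDeltaPdb <- function(model, scores, path) {
  v <- as.numeric(scores$net)
  names(v) <- scores$reskey
  writeBfactorEncoded(model, v, path)
}

#' Write a DeltaMatrix as long-format TSV
#' @param dm a [DeltaMatrix-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeDeltaMatrix <- function(dm, path) {
  d <- deltaCounts(dm)
  out <- data.frame(resA = d$keyA, resB = d$keyB, category = dm@category,
                    delta = d$delta, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

setMethod("show", "DeltaMatrix", function(object) {
  d <- object@delta
  cat("DeltaMatrix [", object@category, "] at ", object@cutoff, " A: ",
      nrow(d), " residue pairs (sum ", sum(d$delta), ", gains ",
      sum(pmax(d$delta, 0)), ", losses ", sum(pmax(-d$delta, 0)), "); ",
      nrow(object@excluded), " residues excluded\n", sep = "")
  invisible(NULL)
})

setMethod("show", "QualityTable", function(object) {
  r <- object@rows
  cat("QualityTable: ", nrow(r), " residues, Q in [",
      if (nrow(r)) sprintf("%.2f", min(r$q_score)) else "-", ", ",
      if (nrow(r)) sprintf("%.2f", max(r$q_score)) else "-", "]\n", sep = "")
  invisible(NULL)
})
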