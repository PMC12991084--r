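# Residue-level correspondence between two homologous models: deterministic
# global (Needleman-Wunsch) sequence alignment, greedy same-class chain
# pairing, the alignment-column residue map, and substitution enumeration.

#' Deterministic global sequence alignment
#'
#' Needleman-Wunsch with match +1, mismatch -1, linear gap -2. Traceback
#' ties prefer match/mismatch over a gap in A over a gap in B, so the
#' alignment is fully deterministic. Suited to the near-identical rRNA and
#' r-protein chain pairs this package compares; it is not a substitute for
#' a multiple aligner on divergent sequences.
#'
#' @param seqA,seqB non-empty residue-letter strings
#' @param match,mismatch,gap integer scores
#' @return list with `score` (integer) and `pairs`, a data.frame of aligned
#'   columns with 1-based indices `a` and `b` (NA marks a gap on that side)
#' @examples
#' globalAlign("ACGU", "AGU")
#' @export
globalAlign <- function(seqA, seqB, match = 1L, mismatch = -1L, gap = -2L) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be non-empty")
  res <- nw_align_cpp(seqA, seqB, match, mismatch, gap)
  list(score = res$score,
       pairs = data.frame(a = res$a_idx, b = res$b_idx))
}

# fraction of aligned columns that are identical, over the longer sequence
.alnIdentity <- function(aln, seqA, seqB) {
  p <- aln$pairs
  both <- !is.na(p$a) & !is.na(p$b)
  if (!any(both)) return(0)
  ca <- strsplit(seqA, "")[[1]][p$a[both]]
  cb <- strsplit(seqB, "")[[1]][p$b[both]]
  sum(ca == cb) / max(nchar(seqA), nchar(seqB))
}

#' Pair chains of two models by sequence similarity
#'
#' Greedy best-score matching of chains sharing an entity class, scored by
#' [globalAlign]; candidate matches with fraction identity below
#' `min_identity` are dropped (with a message). The 0.30 default rejects
#' accidental pairings of unrelated RNAs while accepting inter-species 16S
#' rRNA homology.
#'
#' @param A,B [StructureModel-class] objects with at least one polymer chain
#' @param min_identity minimum fraction identity to accept a chain pair
#' @return data.frame: chainA, chainB, entity_class, score, identity
#' @export
pairChains <- function(A, B, min_identity = 0.30) {
  chA <- chains(A); chA <- chA[chA$entity_class != "other", ]
  chB <- chains(B); chB <- chB[chB$entity_class != "other", ]
  if (!nrow(chA) || !nrow(chB)) stop("both models need polymer chains")
  cand <- list()
  for (i in seq_len(nrow(chA))) for (j in seq_len(nrow(chB))) {
    if (chA$entity_class[i] != chB$entity_class[j]) next
    sA <- chainSequence(A, chA$chain[i])
    sB <- chainSequence(B, chB$chain[j])
    aln <- globalAlign(sA, sB)
    cand[[length(cand) + 1L]] <- data.frame(
      chainA = chA$chain[i], chainB = chB$chain[j],
      entity_class = chA$entity_class[i],
      score = aln$score, identity = .alnIdentity(aln, sA, sB),
      stringsAsFactors = FALSE)
  }
  out <- data.frame(chainA = character(), chainB = character(),
                    entity_class = character(), score = integer(),
                    identity = numeric(), stringsAsFactors = FALSE)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$score, cand$chainA, cand$chainB), ]
    dropped <- 0L
    for (k in seq_len(nrow(cand))) {
      row <- cand[k, ]
      if (row$chainA %in% out$chainA || row$chainB %in% out$chainB) next
      if (row$identity < min_identity) { dropped <- dropped + 1L; next }
      out <- rbind(out, row)
    }
    if (dropped) message(dropped, " candidate chain pair(s) below identity ",
                         min_identity, " dropped")
  }
  if (!nrow(out)) warning("no chain pair above the identity threshold")
  rownames(out) <- NULL
  out
}

#' Build the residue map between two models
#'
#' For each paired chain the sequences are globally aligned; aligned non-gap
#' columns become mapped residue pairs and gap columns populate the unmapped
#' sets (residues absent from either structure). The mapping is a partial
#' bijection keyed by author-numbered residue addresses.
#'
#' @param A,B [StructureModel-class] objects
#' @param pairing chain pairing from [pairChains]; computed if NULL
#' @return a [ResidueMap-class]
#' @export
buildResidueMap <- function(A, B, pairing = NULL) {
  if (is.null(pairing)) pairing <- pairChains(A, B)
  if (!nrow(pairing)) stop("chain pairing is empty")
  resA <- residues(A); resB <- residues(B)
  maps <- list(); unA <- character(); unB <- character()
  for (k in seq_len(nrow(pairing))) {
    ra <- resA[resA$chain == pairing$chainA[k], ]
    rb <- resB[resB$chain == pairing$chainB[k], ]
    aln <- globalAlign(paste(.oneLetter(ra$resid), collapse = ""),
                       paste(.oneLetter(rb$resid), collapse = ""))
    p <- aln$pairs
    both <- !is.na(p$a) & !is.na(p$b)
    maps[[k]] <- data.frame(
      keyA = ra$reskey[p$a[both]], keyB = rb$reskey[p$b[both]],
      nameA = ra$resid[p$a[both]], nameB = rb$resid[p$b[both]],
      normA = parentBase(ra$resid[p$a[both]]),
      normB = parentBase(rb$resid[p$b[both]]),
      chainA = pairing$chainA[k], resnoA = ra$resno[p$a[both]],
      chainB = pairing$chainB[k], resnoB = rb$resno[p$b[both]],
      stringsAsFactors = FALSE)
    unA <- c(unA, ra$reskey[p$a[!is.na(p$a) & is.na(p$b)]])
    unB <- c(unB, rb$reskey[p$b[is.na(p$a) & !is.na(p$b)]])
  }
  mapping <- do.call(rbind, maps)
  # residues of unpaired chains are unmapped too
  unA <- c(unA, setdiff(resA$reskey, c(mapping$keyA, unA)))
  unB <- c(unB, setdiff(resB$reskey, c(mapping$keyB, unB)))
  new("ResidueMap", pairing = pairing, mapping = mapping,
      unmappedA = unA, unmappedB = unB,
      labels = c(modelLabel(A), modelLabel(B)))
}

#' @describeIn buildResidueMap mapped residue pairs as a data.frame
#' @param map a ResidueMap
#' @export
mappedResidues <- function(map) map@mapping

#' @describeIn buildResidueMap unmapped residue keys of one side
#' @param side "A" or "B"
#' @export
unmappedResidues <- function(map, side = c("A", "B")) {
  side <- match.arg(side)
  if (side == "A") map@unmappedA else map@unmappedB
}

#' List substitutions between mapped residues
#'
#' Entries exactly where mapped residues differ in parent-base-normalized
#' name, reported in the reference (A) model's author numbering and sorted
#' by chain and sequence number.
#'
#' @param map a [ResidueMap-class]
#' @return data.frame: ref_name, ref_chain, ref_seq_id, alt_name, keyA,
#'   keyB, chain_pair
#' @examples
#' \dontrun{subs <- listSubstitutions(buildResidueMap(mutant, wildtype))}
#' @export
listSubstitutions <- function(map) {
  m <- mappedResidues(map)
  if (!nrow(m)) stop("residue map is empty")
  d <- m[m$normA != m$normB, ]
  d <- d[order(d$chainA, d$resnoA), ]
  data.frame(ref_name = d$normA, ref_chain = d$chainA,
             ref_seq_id = d$resnoA, alt_name = d$normB,
             keyA = d$keyA, keyB = d$keyB,
             chain_pair = paste(d$chainA, d$chainB, sep = "/"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write substitutions as TSV
#' @param subs data.frame from [listSubstitutions]
#' @param path output path
#' @return invisibly, the path
#' @export
writeSubstitutions <- function(subs, path) {
  utils::write.table(subs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

setMethod("show", "ResidueMap", function(object) {
  cat("ResidueMap ", object@labels[1], " <-> ", object@labels[2], ": ",
      nrow(object@mapping), " mapped residues over ",
      nrow(object@pairing), " chain pair(s); ",
      length(object@unmappedA), "/", length(object@unmappedB),
      " unmapped (A/B)\n", sep = "")
  invisible(NULL)
})
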