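# Heavy-atom contact detection at a distance cutoff, contact
# categorization (RNA-RNA / RNA-protein / protein-protein), residue-pair
# contact matrices and interface counts.

# heavy atoms of polymer (rna/protein) chains with entity class attached
.polymerHeavyAtoms <- function(model) {
  a <- atoms(model)
  ent <- model@chains$entity_class[match(a$chain, model@chains$chain)]
  keep <- !a$hydrogen & ent %in% c("rna", "protein")
  a <- a[keep, , drop = FALSE]
  a$entity <- ent[keep]
  a
}

.pairCategory <- function(entA, entB) {
  ifelse(entA == "rna" & entB == "rna", "rna-rna",
         ifelse(entA == "protein" & entB == "protein",
                "protein-protein", "rna-protein"))
}

#' Find heavy-atom contacts in a model
#'
#' All heavy-atom pairs from distinct residues of polymer chains with
#' Euclidean distance at or below `cutoff` (closed bound, exact double
#' comparison). Self-contacts (pairs within one residue) are excluded, as
#' are hydrogens, waters, ions and ligands. A cell-list spatial partition
#' is used whose output is identical to the all-pairs scan.
#'
#' @param model a [StructureModel-class]
#' @param cutoff distance cutoff in Angstrom (default 4.0)
#' @return data.frame with one row per contact: chainA, resA, atomA,
#'   elementA, chainB, resB, atomB, elementB, distance, category
#' @examples
#' m <- generateToyComplex(8, 4, seed = 1)
#' nrow(findContacts(m))
#' @export
findContacts <- function(model, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  a <- .polymerHeavyAtoms(model)
  empty <- data.frame(chainA = character(), resA = character(),
                      atomA = character(), elementA = character(),
                      chainB = character(), resB = character(),
                      atomB = character(), elementB = character(),
                      distance = numeric(), category = character(),
                      stringsAsFactors = FALSE)
  if (nrow(a) < 2) return(empty)
  pairs <- contact_pairs_cpp(as.matrix(a[, c("x", "y", "z")]),
                             as.integer(factor(a$reskey)), cutoff)
  if (!nrow(pairs)) return(empty)
  i <- pairs$i; j <- pairs$j
  out <- data.frame(chainA = a$chain[i], resA = a$reskey[i],
                    atomA = a$elety[i], elementA = a$elesy[i],
                    chainB = a$chain[j], resB = a$reskey[j],
                    atomB = a$elety[j], elementB = a$elesy[j],
                    distance = pairs$distance,
                    category = .pairCategory(a$entity[i], a$entity[j]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$resA, out$resB, out$atomA, out$atomB), ]
  rownames(out) <- NULL
  out
}

#' Build a residue-pair contact matrix for one category
#'
#' Counts the qualifying heavy-atom pairs between each residue pair of the
#' requested interaction category. Pairs are stored unordered (canonical
#' chain/number order), so the matrix is symmetric by construction.
#'
#' @param contacts contact table from [findContacts] (single cutoff)
#' @param category "rna-rna", "rna-protein" or "protein-protein"
#' @param cutoff the cutoff the contacts were computed at (metadata)
#' @return a [ContactMatrix-class]
#' @export
contactMatrix <- function(contacts, category, cutoff = 4.0) {
  category <- match.arg(category, .CATEGORIES)
  sub <- contacts[contacts$category == category, , drop = FALSE]
  if (!nrow(sub)) {
    counts <- data.frame(keyA = character(), keyB = character(),
                         count = integer(), stringsAsFactors = FALSE)
  } else {
    cp <- .canonPairs(sub$resA, sub$resB)
    tab <- table(paste(cp$keyA, cp$keyB, sep = "\r"))
    keys <- strsplit(names(tab), "\r", fixed = TRUE)
    counts <- data.frame(keyA = vapply(keys, `[`, "", 1L),
                         keyB = vapply(keys, `[`, "", 2L),
                         count = as.integer(tab), stringsAsFactors = FALSE)
    counts <- counts[order(counts$keyA, counts$keyB), ]
    rownames(counts) <- NULL
  }
  new("ContactMatrix", category = category, cutoff = cutoff, counts = counts)
}

#' @describeIn contactMatrix total contact count of a ContactMatrix
#' @param x a ContactMatrix
#' @export
totalContacts <- function(x) sum(x@counts$count)

#' @describeIn contactMatrix counts table accessor
#' @export
contactCounts <- function(x) x@counts

#' Count contacts across an interface
#'
#' Heavy-atom contacts between two disjoint residue selections, e.g.
#' r-protein atoms within 4.0 A of the 16S rRNA. Selections are character
#' vectors of chain identifiers and/or residue keys. Three counting
#' conventions are exposed because "atoms within 4 A" is ambiguous:
#' `pairs` (atom-pair count, default, consistent with the delta-matrix
#' convention), `atoms` (unique atoms of either group involved in a
#' qualifying pair), `residues` (unique residue pairs).
#'
#' @param model a [StructureModel-class]
#' @param groupA,groupB selections: chain ids and/or residue keys
#' @param cutoff Angstrom (default 4.0)
#' @param convention "pairs", "atoms" or "residues"
#' @return integer count
#' @export
countInterfaceContacts <- function(model, groupA, groupB, cutoff = 4.0,
                                   convention = c("pairs", "atoms",
                                                  "residues")) {
  convention <- match.arg(convention)
  a <- .polymerHeavyAtoms(model)
  inSel <- function(sel) a$chain %in% sel | a$reskey %in% sel
  selA <- inSel(groupA); selB <- inSel(groupB)
  if (any(selA & selB)) stop("selections overlap")
  if (!any(selA) || !any(selB)) return(0L)
  sub <- a[selA | selB, , drop = FALSE]
  grp <- ifelse(inSel(groupA)[selA | selB], 1L, 2L)
  pairs <- contact_pairs_cpp(as.matrix(sub[, c("x", "y", "z")]),
                             as.integer(factor(sub$reskey)), cutoff)
  if (!nrow(pairs)) return(0L)
  cross <- grp[pairs$i] != grp[pairs$j]
  i <- pairs$i[cross]; j <- pairs$j[cross]
  switch(convention,
         pairs = length(i),
         atoms = length(unique(c(i, j))),
         residues = {
           cp <- .canonPairs(sub$reskey[i], sub$reskey[j])
           nrow(unique(cp))
         })
}

#' Detect polar-atom proximities
#'
#' Subset of [findContacts] restricted to N/O/S atom pairs within `dmax`.
#' This is an explicit proxy for hydrogen bonding: no donor-hydrogen-
#' acceptor angle term is evaluated, so it over-calls relative to a true
#' geometric hydrogen-bond definition.
#'
#' @param model a [StructureModel-class]
#' @param dmax maximum heavy-atom distance in Angstrom (default 3.5)
#' @return contact data.frame as from [findContacts]
#' @export
detectPolarProximities <- function(model, dmax = 3.5) {
  stopifnot(dmax > 0)
  ct <- findContacts(model, cutoff = dmax)
  polar <- c("N", "O", "S")
  ct[ct$elementA %in% polar & ct$elementB %in% polar, , drop = FALSE]
}

#' Write a contact table as TSV
#' @param contacts data.frame from [findContacts]
#' @param path output path
#' @return invisibly, the path
#' @export
writeContacts <- function(contacts, path) {
  out <- contacts[, c("chainA", "resA", "atomA", "chainB", "resB", "atomB",
                      "distance", "category")]
  out$distance <- sprintf("%.3f", out$distance)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix [", object@category, "] at ", object@cutoff,
      " A: ", nrow(object@counts), " residue pairs, ",
      totalContacts(object), " contacts\n", sep = "")
  invisible(NULL)
})
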