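# Reading coordinate files into StructureModel objects and writing
# B-factor-encoded PDB files back out. Parsing of the raw records is done
# by bio3d (read.pdb / read.cif); this layer adds altloc reduction, element
# inference, hydrogen flagging, author-numbered residue keys and per-chain
# entity classification.

# build a StructureModel from a raw atom data.frame (bio3d-style columns)
.newStructureModel <- function(atoms, label, source = "") {
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$elety <- gsub('"', "", atoms$elety)
  blank <- is.na(atoms$elesy) | !nzchar(trimws(atoms$elesy))
  atoms$elesy[blank] <- .inferElement(atoms$elety[blank], atoms$resid[blank])
  atoms$elesy <- toupper(trimws(atoms$elesy))
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  atoms <- .reduceAltloc(atoms)
  atoms$hydrogen <- .isHydrogen(atoms$elesy)
  atoms$reskey <- .resKey(atoms$chain, atoms$resno, atoms$insert)
  # order residues by (chain, resno, icode), atoms in file order within
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert,
                       seq_len(nrow(atoms))), , drop = FALSE]
  rownames(atoms) <- NULL
  chains <- .classifyChains(atoms)
  atoms <- atoms[, c("chain", "resno", "insert", "resid", "elety", "elesy",
                     "x", "y", "z", "o", "b", "alt", "hydrogen", "reskey")]
  new("StructureModel", label = label, atoms = atoms, chains = chains,
      source = source)
}

# for altloc groups keep the highest-occupancy conformer; ties broken by
# altloc label order
.reduceAltloc <- function(atoms) {
  if (!any(nzchar(atoms$alt))) return(atoms)
  grp <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- atoms$o[idx]
    cand <- idx[o == max(o)]
    cand[order(atoms$alt[cand])][1L]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

# entity class by majority vote over residues with a known vocabulary name
.classifyChains <- function(atoms) {
  res <- atoms[!duplicated(atoms$reskey), c("chain", "resid")]
  cl <- vapply(split(res$resid, res$chain), function(names) {
    n_rna <- sum(.isNucName(names))
    n_pro <- sum(.isAminoName(names))
    if (n_rna == 0 && n_pro == 0) return("other")
    if (n_rna >= n_pro) "rna" else "protein"
  }, "")
  data.frame(chain = names(cl), entity_class = unname(cl),
             n_residues = as.integer(table(res$chain)[names(cl)]),
             stringsAsFactors = FALSE)
}

#' Read a coordinate file into a StructureModel
#'
#' Parses a PDB or mmCIF file (first model only) into a [StructureModel-class].
#' Format is chosen by extension (`.cif`/`.mmcif` vs anything else) unless
#' `format` is given. Hydrogens are retained but flagged, and excluded later
#' at contact time; for alternate-location groups only the highest-occupancy
#' conformer is kept (ties broken by altloc label order); waters, ions and
#' other non-polymer chains are classified `other` and ignored by the
#' contact categories. Residues are addressed by author numbering
#' (chain, seq_id, insertion code) throughout.
#'
#' @param path path to a PDB or mmCIF file
#' @param label free-text model label; defaults to the file name
#' @param format "auto", "pdb" or "cif"
#' @return a [StructureModel-class]
#' @examples
#' pdb <- system.file("extdata", "toy_helix.pdb", package = "RiboDelta")
#' m <- readStructure(pdb, label = "toy")
#' m
#' @export
readStructure <- function(path, label = basename(path), format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("auto", "pdb", "cif"))
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  raw <- tryCatch(
    if (format == "cif")
      suppressWarnings(bio3d::read.cif(path, multi = FALSE))
    else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, hex = TRUE),
    error = function(e)
      stop("cannot parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  atoms <- raw$atom
  atoms$resno <- as.integer(atoms$resno)
  m <- .newStructureModel(atoms, label = label, source = path)
  if (!any(m@chains$entity_class %in% c("rna", "protein")))
    stop("empty model: '", path, "' contains no polymer (RNA/protein) chains")
  m
}

#' Write a StructureModel as PDB
#'
#' @param model a [StructureModel-class]
#' @param path output file path
#' @return invisibly, the path
#' @export
writeStructure <- function(model, path) {
  a <- atoms(model)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, insert = a$insert,
                   resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Encode per-residue scores into the B-factor column
#'
#' Writes the model as PDB with every atom of a scored residue carrying the
#' residue's score in the temperature-factor column, for "color by B-factor"
#' visualization (e.g. a red-white-blue spectrum mapping net contact loss to
#' gain). Scores are clipped to the fixed-width PDB field range
#' \[-99.99, 999.99\]; atoms of unscored residues get 0.00. Score keys not
#' present in the model are skipped with one warning giving the count.
#'
#' @param model a [StructureModel-class]
#' @param scores named numeric vector, names are residue keys
#'   ("chain:seq_id:icode"), or a data.frame with columns reskey and score
#' @param path output PDB path
#' @return invisibly, the path
#' @export
writeBfactorEncoded <- function(model, scores, path) {
  if (is.data.frame(scores)) {
    v <- scores$score
    names(v) <- scores$reskey
    scores <- v
  }
  scores <- pmin(pmax(scores, -99.99), 999.99)
  missing <- setdiff(names(scores), atoms(model)$reskey)
  if (length(missing))
    warning(length(missing), " score key(s) not present in model; skipped")
  m <- model
  b <- scores[m@atoms$reskey]
  b[is.na(b)] <- 0
  m@atoms$b <- round(unname(b), 2)
  writeStructure(m, path)
}

#' @describeIn StructureModel atom table accessor
#' @param object,model a StructureModel
#' @export
atoms <- function(model) model@atoms

#' @describeIn StructureModel chain table (chain, entity_class, n_residues)
#' @export
chains <- function(model) model@chains

#' @describeIn StructureModel one row per residue (chain, resno, insert,
#'   resid, reskey, entity_class)
#' @export
residues <- function(model) {
  a <- model@atoms
  r <- a[!duplicated(a$reskey),
         c("chain", "resno", "insert", "resid", "reskey")]
  r$entity_class <- model@chains$entity_class[match(r$chain,
                                                    model@chains$chain)]
  rownames(r) <- NULL
  r
}

#' @describeIn StructureModel model label accessor
#' @export
modelLabel <- function(model) model@label

#' Residue-letter sequence of one chain
#'
#' Parent-base-normalized one-letter sequence (A/C/G/U for RNA, one-letter
#' amino-acid codes for protein, X for unknown) in residue order.
#'
#' @param model a [StructureModel-class]
#' @param chain chain identifier
#' @return character(1)
#' @export
chainSequence <- function(model, chain) {
  r <- residues(model)
  r <- r[r$chain == chain, ]
  if (!nrow(r)) stop("no such chain: ", chain)
  paste(.oneLetter(r$resid), collapse = "")
}

setMethod("show", "StructureModel", function(object) {
  ch <- object@chains
  cat("StructureModel '", object@label, "': ",
      nrow(ch), " chain(s), ",
      length(unique(object@atoms$reskey)), " residues, ",
      nrow(object@atoms), " atoms\n", sep = "")
  for (i in seq_len(nrow(ch)))
    cat("  chain ", ch$chain[i], " [", ch$entity_class[i], "]: ",
        ch$n_residues[i], " residues\n", sep = "")
  invisible(NULL)
})
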