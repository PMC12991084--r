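# Residue vocabularies, element inference, keys and small shared helpers.

# modified-nucleotide -> parent base (common rRNA modifications)
.MOD_NUC <- c(PSU = "U", "1MA" = "A", "2MA" = "A", "6MA" = "A", MA6 = "A",
              A2M = "A", "1MG" = "G", "2MG" = "G", M2G = "G", "7MG" = "G",
              G7M = "G", OMG = "G", YG = "G", QUO = "G", "5MC" = "C",
              OMC = "C", "4OC" = "C", "5MU" = "U", UR3 = "U", "4SU" = "U",
              H2U = "U", OMU = "U", "3MU" = "U", U8U = "U", I = "G",
              DA = "A", DC = "C", DG = "G", DT = "U", DU = "U")

.STD_NUC <- c("A", "C", "G", "U", "N")

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

.ELEMENT_MASS <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, SE = 78.971, MG = 24.305,
                   K = 39.098, NA. = 22.99, ZN = 65.38, FE = 55.845,
                   CL = 35.45, BR = 79.904, F = 18.998)

.elementMass <- function(sym) {
  sym <- toupper(sym)
  sym[sym == "NA"] <- "NA."
  m <- .ELEMENT_MASS[sym]
  m[is.na(m)] <- 12.011   # fall back to carbon for exotic elements
  unname(m)
}

#' Normalize a residue name to its parent base
#'
#' Modified nucleotides (pseudouridine, methylated bases, ...) map to their
#' parent base identity so that sequence alignment and substitution calls
#' compare base identity, not modification state. Amino acids and unknown
#' names are returned unchanged (MSE is reported as MET).
#'
#' @param name character vector of residue names
#' @return character vector of normalized names
#' @export
parentBase <- function(name) {
  out <- name
  hit <- name %in% names(.MOD_NUC)
  out[hit] <- .MOD_NUC[name[hit]]
  out[out == "MSE"] <- "MET"
  out
}

.isNucName <- function(name) {
  name %in% .STD_NUC | name %in% names(.MOD_NUC)
}

.isAminoName <- function(name) name %in% names(.AA3)

# one-letter code for alignment; parent-normalized; unknown -> X
.oneLetter <- function(name) {
  name <- parentBase(name)
  out <- rep("X", length(name))
  nuc <- name %in% .STD_NUC
  out[nuc] <- name[nuc]
  aa <- name %in% names(.AA3)
  out[aa] <- unname(.AA3[name[aa]])
  out
}

# residue key: chain:resno:icode (author numbering)
.resKey <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste(chain, resno, insert, sep = ":")
}

.splitKey <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resno = as.integer(vapply(parts, `[`, "", 2L)),
             insert = vapply(parts, function(p)
               if (length(p) >= 3L) p[3L] else "", ""),
             stringsAsFactors = FALSE)
}

# canonical order of residue keys: chain, then number, then insertion code
.orderKeys <- function(keys) {
  s <- .splitKey(keys)
  order(s$chain, s$resno, s$insert)
}

# put each residue pair in canonical (keyA <= keyB) order
.canonPairs <- function(keyA, keyB) {
  s1 <- .splitKey(keyA); s2 <- .splitKey(keyB)
  swap <- (s2$chain < s1$chain) |
    (s2$chain == s1$chain & s2$resno < s1$resno) |
    (s2$chain == s1$chain & s2$resno == s1$resno & s2$insert < s1$insert)
  data.frame(keyA = ifelse(swap, keyB, keyA),
             keyB = ifelse(swap, keyA, keyB), stringsAsFactors = FALSE)
}

# element inference from PDB atom names when the element column is blank
.inferElement <- function(elety, resid) {
  name <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(name, 1, 2))
  one <- toupper(substr(name, 1, 1))
  out <- one
  # two-letter elements seen in biomolecules and common ligands
  known2 <- c("FE", "MG", "ZN", "SE", "CL", "BR", "MN", "CU", "NI", "CO")
  out[two %in% known2] <- two[two %in% known2]
  out[one == "D"] <- "D"
  out
}

.isHydrogen <- function(elesy) toupper(elesy) %in% c("H", "D")

# run code with a private, restored RNG state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.CATEGORIES <- c("rna-rna", "rna-protein", "protein-protein")
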