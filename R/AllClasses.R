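#' @useDynLib RiboDelta, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' StructureModel: a hierarchical atomic model
#'
#' Flat atom-table representation of a (first-model, asymmetric-unit) atomic
#' coordinate file. Each row of `atoms` is one atom; residues are groups of
#' rows sharing a residue key `chain:seq_id:icode` (author numbering), and
#' every polymer chain carries exactly one entity class (`rna`, `protein` or
#' `other`) inferred from its residue vocabulary.
#'
#' @slot label free-text label for the model (e.g. "PA-ST")
#' @slot atoms data.frame with columns chain, resno, insert, resid, elety,
#'   elesy, x, y, z, o, b, alt, hydrogen, reskey
#' @slot chains data.frame with columns chain, entity_class, n_residues
#' @slot source path the model was read from ("" for in-memory models)
#' @export
setClass("StructureModel",
  representation(label = "character", atoms = "data.frame",
                 chains = "data.frame", source = "character"),
  validity = function(object) {
    msg <- character()
    a <- object@atoms
    need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
              "x", "y", "z", "o", "b", "alt", "hydrogen", "reskey")
    if (!all(need %in% names(a)))
      msg <- c(msg, paste("atoms must have columns:",
                          paste(setdiff(need, names(a)), collapse = ", ")))
    else {
      if (nrow(a) && !all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
        msg <- c(msg, "atom positions must be finite")
      if (nrow(a) && !all(a$o >= 0 & a$o <= 1))
        msg <- c(msg, "occupancies must lie in [0, 1]")
      if (nrow(a) && any(!nzchar(a$elesy)))
        msg <- c(msg, "every atom needs an element symbol")
    }
    if (anyDuplicated(object@chains$chain))
      msg <- c(msg, "chain identifiers must be unique")
    if (length(msg)) msg else TRUE
  })

#' ResidueMap: residue correspondence between two models
#'
#' Chain pairing plus an alignment-derived partial bijection between residue
#' addresses of two homologous models. Residues absent from either structure
#' fall into the unmapped sets.
#'
#' @slot pairing data.frame: chainA, chainB, entity_class, score, identity
#' @slot mapping data.frame: keyA, keyB, nameA, nameB (parent-normalized
#'   names in normA/normB), chainA, resnoA, chainB, resnoB
#' @slot unmappedA,unmappedB character vectors of residue keys
#' @slot labels character(2): labels of models A and B
#' @export
setClass("ResidueMap",
  representation(pairing = "data.frame", mapping = "data.frame",
                 unmappedA = "character", unmappedB = "character",
                 labels = "character"),
  validity = function(object) {
    m <- object@mapping
    if (nrow(m) && (anyDuplicated(m$keyA) || anyDuplicated(m$keyB)))
      return("mapping must be bijective on its domain")
    if (length(intersect(m$keyA, object@unmappedA)))
      return("a residue cannot be both mapped and unmapped (A)")
    TRUE
  })

#' ContactMatrix: residue-pair heavy-atom contact counts for one category
#'
#' Sparse symmetric matrix stored as an unordered-pair long table: each row
#' is one residue pair with the number of qualifying heavy-atom pairs at or
#' below the cutoff. Pairs are canonically ordered (keyA <= keyB in
#' chain/number order) so the matrix is symmetric by construction; self
#' pairs never occur.
#'
#' @slot category "rna-rna", "rna-protein" or "protein-protein"
#' @slot cutoff distance cutoff in Angstrom
#' @slot counts data.frame: keyA, keyB, count
#' @export
setClass("ContactMatrix",
  representation(category = "character", cutoff = "numeric",
                 counts = "data.frame"),
  validity = function(object) {
    ok <- c("rna-rna", "rna-protein", "protein-protein")
    if (!object@category %in% ok)
      return(paste("category must be one of:", paste(ok, collapse = ", ")))
    if (object@cutoff <= 0) return("cutoff must be positive")
    cnt <- object@counts
    if (nrow(cnt)) {
      if (any(cnt$keyA == cnt$keyB)) return("self pairs are not allowed")
      if (any(cnt$count < 0)) return("counts must be non-negative")
    }
    TRUE
  })

#' QualityTable: per-residue cryo-EM model quality
#'
#' Per-residue Q-score (map-model agreement, in [-1, 1]) and optional local
#' resolution (Angstrom, larger is worse), keyed by residue address. Used
#' for Q < 0.4 exclusions, significance flags and neighborhood filtering.
#'
#' @slot rows data.frame: chain, seq_id, icode, q_score, local_resolution,
#'   reskey
#' @export
setClass("QualityTable",
  representation(rows = "data.frame"),
  validity = function(object) {
    r <- object@rows
    if (nrow(r)) {
      if (any(r$q_score < -1 | r$q_score > 1, na.rm = TRUE))
        return("q_score must lie in [-1, 1]")
      if (any(r$local_resolution <= 0, na.rm = TRUE))
        return("local_resolution must be positive where present")
      if (anyDuplicated(r$reskey))
        return("one row per residue address")
    }
    TRUE
  })

#' DeltaMatrix: mapped contact-count difference between two models
#'
#' Entrywise difference countA - countB of two same-category contact
#' matrices after translating model-B residue pairs through a ResidueMap,
#' with residues excluded for absence or poor Q-score recorded alongside.
#' All keys are in model-A (reference) numbering.
#'
#' @slot category contact category
#' @slot cutoff contact cutoff in Angstrom
#' @slot delta data.frame: keyA, keyB, delta (signed integer)
#' @slot excluded data.frame: reskey, reason
#' @export
setClass("DeltaMatrix",
  representation(category = "character", cutoff = "numeric",
                 delta = "data.frame", excluded = "data.frame"),
  validity = function(object) {
    d <- object@delta
    if (nrow(d) && any(d$keyA == d$keyB)) return("self pairs are not allowed")
    TRUE
  })

#' AnalysisConfig: every numeric threshold of the comparison pipeline
#'
#' One object holding the distance cutoffs and quality thresholds the
#' pipeline applies: 4 A heavy-atom contact cutoff, 4 A interface cutoff,
#' Q < 0.4 exclusion, >10% Q-score change or >0.5 A local-resolution change
#' significance, 10 A mutation neighborhoods restricted to local resolution
#' better than 3.0 A, and the >1 A displacement flag.
#'
#' @slot contact_cutoff,interface_cutoff Angstrom
#' @slot q_exclude Q-score below which residues are excluded
#' @slot q_change_frac relative Q-score change flag threshold
#' @slot locres_change local-resolution change flag threshold, Angstrom
#' @slot neighborhood_radius mutation neighborhood radius, Angstrom
#' @slot min_local_resolution best-resolution filter for neighborhoods, A
#' @slot shift_threshold displacement flag threshold, Angstrom
#' @export
setClass("AnalysisConfig",
  representation(contact_cutoff = "numeric", interface_cutoff = "numeric",
                 q_exclude = "numeric", q_change_frac = "numeric",
                 locres_change = "numeric", neighborhood_radius = "numeric",
                 min_local_resolution = "numeric", shift_threshold = "numeric"),
  validity = function(object) {
    vals <- c(object@contact_cutoff, object@interface_cutoff,
              object@q_exclude, object@q_change_frac, object@locres_change,
              object@neighborhood_radius, object@min_local_resolution,
              object@shift_threshold)
    if (any(!is.finite(vals)) || any(vals <= 0))
      return("all thresholds must be positive and finite")
    TRUE
  })

#' RigidTransform: proper rigid-body transform
#'
#' Rotation (3x3, orthonormal, det +1) plus translation (Angstrom); maps
#' coordinates x to R x + t.
#'
#' @slot rotation 3x3 matrix
#' @slot translation length-3 numeric
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      return("rotation must be orthonormal (R'R = I to 1e-9)")
    if (abs(det(R) - 1) > 1e-9) return("rotation must have det +1")
    if (length(object@translation) != 3) return("translation must be length 3")
    TRUE
  })

#' PerturbationPlan: planted changes for a synthetic model pair
#'
#' @slot substitutions data.frame: reskey, new_base
#' @slot displaced data.frame: reskey, dx, dy, dz
#' @slot contact_edits data.frame: keyA, keyB, sign (+1 gain / -1 loss in
#'   the perturbed model relative to the base), magnitude
#' @slot global_transform RigidTransform or NULL
#' @slot jitter_sigma isotropic Gaussian coordinate noise sd, Angstrom
#' @slot seed integer seed driving every random choice
#' @export
setClass("PerturbationPlan",
  representation(substitutions = "data.frame", displaced = "data.frame",
                 contact_edits = "data.frame", global_transform = "ANY",
                 jitter_sigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@jitter_sigma < 0) return("jitter_sigma must be >= 0")
    TRUE
  })

#' ComparisonReport: end-to-end two-model comparison results
#'
#' @slot contact_totals data.frame: model, category, total
#' @slot percent_change data.frame per category and counting convention
#' @slot delta_summary data.frame per category
#' @slot flagged data.frame of significance-flagged residues
#' @slot substitutions data.frame of sequence differences
#' @slot neighborhoods named list of residue-key vectors per substitution
#' @slot rmsd data.frame of superposition RMSDs
#' @slot com_distances data.frame of named center-of-mass distances
#' @slot config the AnalysisConfig used
#' @slot labels character(2)
#' @export
setClass("ComparisonReport",
  representation(contact_totals = "data.frame", percent_change = "data.frame",
                 delta_summary = "data.frame", flagged = "data.frame",
                 substitutions = "data.frame", neighborhoods = "list",
                 rmsd = "data.frame", com_distances = "data.frame",
                 config = "AnalysisConfig", labels = "character"))
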