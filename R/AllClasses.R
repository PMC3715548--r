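#' @import methods
NULL

## Residue bookkeeping is kept as a plain data.frame with columns
## chain, resno, insert, resname.  Author (PDB) numbering is authoritative and
## never rewritten; insertion codes are carried alongside the number so that
## (chain, resno, insert) is the unique residue key.

.validResidueFrame <- function(res) {
  need <- c("chain", "resno", "insert", "resname")
  if (!is.data.frame(res) || !all(need %in% names(res)))
    return("residues must be a data.frame with columns chain, resno, insert, resname")
  if (anyNA(res$chain) || anyNA(res$resno))
    return("residue chain/resno must not contain NA")
  key <- paste(res$chain, res$resno, res$insert)
  if (anyDuplicated(key))
    return("(chain, resno, insert) keys must be unique within one conformer")
  NULL
}

#' Single conformer reduced to its Calpha trace
#'
#' A \code{CalphaStructure} holds one conformer of a macromolecule reduced to
#' one node per residue (the alpha carbon): residue identities (chain,
#' author residue number, insertion code, residue name) and an N x 3
#' coordinate matrix in Angstrom.  All network calculations in this package
#' operate on this representation.
#'
#' @slot residues data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resname}; one row per Calpha node, in the order used
#'   by every downstream matrix.
#' @slot coords numeric N x 3 matrix of coordinates (Angstrom).
#' @slot modelId integer model number the conformer came from.
#'
#' @seealso [calphaStructure()], [readPdbModels()]
#' @exportClass CalphaStructure
setClass("CalphaStructure",
  representation(residues = "data.frame", coords = "matrix",
                 modelId = "integer"))

setValidity("CalphaStructure", function(object) {
  msg <- .validResidueFrame(object@residues)
  if (!is.null(msg)) return(msg)
  n <- nrow(object@residues)
  if (n < 2L) return("a CalphaStructure needs at least 2 residues")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    return("coords must be a numeric N x 3 matrix")
  if (nrow(object@coords) != n)
    return("coords row count must equal the number of residues")
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  TRUE
})

#' Construct a CalphaStructure
#'
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param chain character vector of chain identifiers (recycled).
#' @param resno integer vector of author residue numbers; defaults to
#'   sequential numbering per chain.
#' @param resname residue names (recycled; default \code{"ALA"}).
#' @param insert insertion codes (recycled; default \code{""}).
#' @param modelId integer model number.
#' @return A [CalphaStructure-class] object.
#' @examples
#' xyz <- cbind(seq(0, 7.6, by = 3.8), 0, 0)
#' calphaStructure(xyz, chain = "A")
#' @export
calphaStructure <- function(coords, chain = "A", resno = NULL,
                            resname = "ALA", insert = "", modelId = 1L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  chain <- rep_len(as.character(chain), n)
  if (is.null(resno)) {
    resno <- integer(n)
    for (ch in unique(chain)) {
      idx <- which(chain == ch)
      resno[idx] <- seq_along(idx)
    }
  }
  res <- data.frame(chain = chain, resno = as.integer(resno),
                    insert = rep_len(as.character(insert), n),
                    resname = rep_len(as.character(resname), n),
                    stringsAsFactors = FALSE)
  new("CalphaStructure", residues = res, coords = coords,
      modelId = as.integer(modelId))
}

#' Set of conformers sharing (or not) one residue topology
#'
#' @slot members list of [CalphaStructure-class] conformers.
#' @slot sharedTopology logical; \code{TRUE} when every member carries an
#'   identical residue list (required for ensemble averaging).
#' @exportClass StructureEnsemble
setClass("StructureEnsemble",
  representation(members = "list", sharedTopology = "logical"))

setValidity("StructureEnsemble", function(object) {
  if (length(object@members) < 1L) return("ensemble must have >= 1 member")
  if (!all(vapply(object@members, is, logical(1), "CalphaStructure")))
    return("all members must be CalphaStructure objects")
  if (object@sharedTopology) {
    ref <- object@members[[1L]]@residues
    same <- vapply(object@members, function(m) identical(
      m@residues[c("chain", "resno", "insert")],
      ref[c("chain", "resno", "insert")]), logical(1))
    if (!all(same))
      return("sharedTopology is TRUE but residue lists differ between members")
  }
  TRUE
})

#' Construct a StructureEnsemble
#'
#' Shared topology is detected automatically from the members' residue keys.
#'
#' @param members list of [CalphaStructure-class] objects.
#' @return A [StructureEnsemble-class].
#' @export
structureEnsemble <- function(members) {
  if (is(members, "CalphaStructure")) members <- list(members)
  shared <- length(members) >= 1L &&
    all(vapply(members, function(m) identical(
      m@residues[c("chain", "resno", "insert")],
      members[[1L]]@residues[c("chain", "resno", "insert")]), logical(1)))
  new("StructureEnsemble", members = members, sharedTopology = shared)
}

#' Contiguous range of nonzero normal modes
#'
#' Mode 1 is the slowest nonzero mode (smallest nonzero eigenvalue); zero
#' modes are never addressed through a \code{ModeRange}.
#'
#' @slot first integer index of the first nonzero mode used.
#' @slot last integer index of the last mode used.
#' @slot label free-text record of how the range was chosen.
#' @exportClass ModeRange
setClass("ModeRange",
  representation(first = "integer", last = "integer", label = "character"))

setValidity("ModeRange", function(object) {
  if (length(object@first) != 1L || length(object@last) != 1L)
    return("first and last must be scalars")
  if (object@first < 1L || object@last < object@first)
    return("need 1 <= first <= last")
  TRUE
})

#' @rdname ModeRange-class
#' @param first,last integer mode indices (1 = slowest nonzero mode).
#' @param label free-text label.
#' @return A [ModeRange-class].
#' @examples
#' modeRange(1, 10, "ten slowest modes")
#' @export
modeRange <- function(first = 1L, last = first, label = "") {
  new("ModeRange", first = as.integer(first), last = as.integer(last),
      label = as.character(label))
}

#' Kirchhoff (connectivity) matrix of a Calpha contact network
#'
#' The graph Laplacian of the Calpha contact topology: -1 for residue pairs
#' within the cutoff, node degree on the diagonal, zero row sums.
#'
#' @slot gamma numeric N x N symmetric Laplacian.
#' @slot cutoff numeric contact cutoff (Angstrom).
#' @slot residues residue bookkeeping data.frame of the source structure.
#' @exportClass KirchhoffMatrix
setClass("KirchhoffMatrix",
  representation(gamma = "matrix", cutoff = "numeric", residues = "data.frame"))

setValidity("KirchhoffMatrix", function(object) {
  g <- object@gamma
  if (nrow(g) != ncol(g)) return("gamma must be square")
  if (nrow(g) != nrow(object@residues))
    return("gamma dimension must match residue count")
  if (!isSymmetric(unname(g))) return("gamma must be symmetric")
  off <- g[row(g) != col(g)]
  if (!all(off %in% c(0, -1))) return("off-diagonal entries must be 0 or -1")
  if (any(abs(rowSums(g)) > 1e-9)) return("row sums must be zero")
  TRUE
})

#' Spectral decomposition of a Kirchhoff matrix
#'
#' @slot eigenvalues numeric vector, ascending; the leading \code{nZero}
#'   entries are numerically zero.
#' @slot eigenvectors orthonormal N x N matrix, columns matching
#'   \code{eigenvalues}.
#' @slot nZero integer count of numerically zero eigenvalues (1 for a
#'   connected contact graph).
#' @slot residues residue bookkeeping of the source structure.
#' @exportClass GNMModes
setClass("GNMModes",
  representation(eigenvalues = "numeric", eigenvectors = "matrix",
                 nZero = "integer", residues = "data.frame"))

setValidity("GNMModes", function(object) {
  if (is.unsorted(object@eigenvalues)) return("eigenvalues must be ascending")
  if (length(object@eigenvalues) != ncol(object@eigenvectors))
    return("eigenvalue/eigenvector count mismatch")
  if (object@nZero < 1L) return("a Laplacian always has at least one zero mode")
  TRUE
})

#' Per-residue mean-square fluctuation profile
#'
#' Values are in reduced units of 3kT/gamma for GNM-derived profiles (the
#' physical prefactor is set to 1) or Angstrom^2 for trajectory-derived ones.
#'
#' @slot values numeric vector of per-residue mean-square fluctuations.
#' @slot modeRange the [ModeRange-class] used (label records provenance).
#' @slot residues residue bookkeeping.
#' @exportClass MSFProfile
setClass("MSFProfile",
  representation(values = "numeric", modeRange = "ModeRange",
                 residues = "data.frame"))

#' Normalized cross-correlation map of residue fluctuations
#'
#' @slot raw numeric N x N covariance matrix in reduced 3kT/gamma units.
#' @slot normalized numeric N x N matrix in [-1, 1] with unit diagonal.
#' @slot modeRange the mode subset used.
#' @slot residues residue bookkeeping (row/column order of the matrices).
#' @slot label free-text provenance (e.g. ensemble member count).
#' @exportClass CorrelationMap
setClass("CorrelationMap",
  representation(raw = "matrix", normalized = "matrix",
                 modeRange = "ModeRange", residues = "data.frame",
                 label = "character"))

setValidity("CorrelationMap", function(object) {
  n <- nrow(object@residues)
  if (!all(dim(object@raw) == n) || !all(dim(object@normalized) == n))
    return("matrix dimensions must match residue count")
  if (max(abs(object@normalized)) > 1 + 1e-9)
    return("normalized correlations must lie in [-1, 1]")
  TRUE
})

#' Averaged squared slow-mode shape
#'
#' Per-residue squared eigenvector entries, averaged over a mode range.  Each
#' single-mode shape sums to 1 (unit eigenvectors); minima mark hinge regions.
#'
#' @slot values numeric nonnegative vector of length N.
#' @slot modeRange modes averaged over.
#' @slot residues residue bookkeeping.
#' @exportClass ModeShape
setClass("ModeShape",
  representation(values = "numeric", modeRange = "ModeRange",
                 residues = "data.frame"))

#' Detected hinge residues
#'
#' @slot residues rows of the source residue table flagged as hinge sites,
#'   with a \code{segment} column grouping contiguous runs.
#' @slot method \code{"minima"} or \code{"crossover"}.
#' @slot modeRange supporting mode range.
#' @exportClass HingeSet
setClass("HingeSet",
  representation(residues = "data.frame", method = "character",
                 modeRange = "ModeRange"))

#' Named chain/residue-range region
#'
#' @slot name region name (e.g. \code{"hinge"}).
#' @slot chain single chain identifier.
#' @slot from,to inclusive author residue number range.
#' @exportClass RegionSpec
setClass("RegionSpec",
  representation(name = "character", chain = "character",
                 from = "integer", to = "integer"))

setValidity("RegionSpec", function(object) {
  if (object@to < object@from) return("need from <= to")
  TRUE
})

#' @rdname RegionSpec-class
#' @param name region name.
#' @param chain chain identifier.
#' @param from,to inclusive residue number range.
#' @return A [RegionSpec-class].
#' @examples
#' regionSpec("hinge", "A", 134, 138)
#' @export
regionSpec <- function(name, chain, from, to = from) {
  new("RegionSpec", name = as.character(name), chain = as.character(chain),
      from = as.integer(from), to = as.integer(to))
}

#' Mean correlation of one region with every residue
#'
#' @slot values numeric vector in [-1, 1], one entry per map residue.
#' @slot region the [RegionSpec-class] averaged over.
#' @slot residues residue bookkeeping of the source map.
#' @exportClass RegionProfile
setClass("RegionProfile",
  representation(values = "numeric", region = "RegionSpec",
                 residues = "data.frame"))

#' Difference between two normalized correlation maps
#'
#' Values are state A minus state B on the residue intersection, hence
#' bounded by [-2, 2] and antisymmetric under swapping the states.
#'
#' @slot values numeric M x M difference matrix.
#' @slot residues shared residue keys, in map order.
#' @slot stateLabels character pair naming states (A, B).
#' @exportClass DifferenceMap
setClass("DifferenceMap",
  representation(values = "matrix", residues = "data.frame",
                 stateLabels = "character"))

#' Ordered conformer series treated as a trajectory
#'
#' @slot frames list of [CalphaStructure-class] frames with shared topology.
#' @slot frameInterval time per frame, arbitrary units.
#' @slot equilibration integer count of leading frames discarded by analyses.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(frames = "list", frameInterval = "numeric",
                 equilibration = "integer"))

setValidity("Trajectory", function(object) {
  if (length(object@frames) - object@equilibration < 2L)
    return("need >= 2 frames after the equilibration discard")
  ref <- object@frames[[1L]]@residues
  same <- vapply(object@frames, function(m) identical(
    m@residues[c("chain", "resno", "insert")],
    ref[c("chain", "resno", "insert")]), logical(1))
  if (!all(same)) return("all frames must share one residue topology")
  TRUE
})

#' @rdname Trajectory-class
#' @param frames list of [CalphaStructure-class] frames (or a
#'   [StructureEnsemble-class] with shared topology).
#' @param frameInterval time per frame (arbitrary units).
#' @param equilibration number of leading frames discarded by analyses.
#' @return A [Trajectory-class].
#' @export
trajectory <- function(frames, frameInterval = 1, equilibration = 0L) {
  if (is(frames, "StructureEnsemble")) frames <- frames@members
  new("Trajectory", frames = frames, frameInterval = as.numeric(frameInterval),
      equilibration = as.integer(equilibration))
}

#' Radius-controlled clustering of a conformer series
#'
#' @slot radius clustering radius (Angstrom RMSD).
#' @slot assignments integer cluster index per retained frame.
#' @slot centroids list of N x 3 mean coordinate matrices.
#' @slot populations integer per-cluster frame counts.
#' @slot bestMembers integer frame index (within retained frames) of the
#'   member nearest its centroid.
#' @slot frameOffset integer count of discarded equilibration frames, so that
#'   \code{bestMembers + frameOffset} indexes the original trajectory.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(radius = "numeric", assignments = "integer",
                 centroids = "list", populations = "integer",
                 bestMembers = "integer", frameOffset = "integer"))

setValidity("ClusterResult", function(object) {
  if (sum(object@populations) != length(object@assignments))
    return("populations must sum to the frame count")
  k <- length(object@centroids)
  if (length(object@populations) != k || length(object@bestMembers) != k)
    return("per-cluster slots must have one entry per cluster")
  if (!all(object@assignments[object@bestMembers] == seq_len(k)))
    return("each best member must belong to its own cluster")
  TRUE
})

#' Essential-dynamics (PCA) decomposition of a trajectory
#'
#' Principal components of the 3N-dimensional Calpha fluctuation covariance
#' after rigid-body superposition onto the first retained frame.
#'
#' @slot meanStructure N x 3 time-mean coordinates after superposition.
#' @slot eigenvalues all covariance eigenvalues, descending (Angstrom^2).
#' @slot eigenvectors 3N x k orthonormal matrix of the kept modes.
#' @slot nModesKept integer number of retained modes.
#' @slot residues residue bookkeeping.
#' @exportClass EssentialModes
setClass("EssentialModes",
  representation(meanStructure = "matrix", eigenvalues = "numeric",
                 eigenvectors = "matrix", nModesKept = "integer",
                 residues = "data.frame"))

#' Hinge-mediated switch-coupling report
#'
#' Region-region mean normalized correlations for the hinge network of a
#' two-subunit structure, plus a deterministic on/off label per subunit.
#'
#' @slot couplings data.frame with columns \code{subunit}, \code{coupling},
#'   \code{value}.
#' @slot stateLabels named character vector, one \code{"on"}/\code{"off"}
#'   label per subunit.
#' @slot thresholds numeric; \code{theta1} (hinge-to-other-hinge) and
#'   \code{theta2} (hinge-to-other-subunit cAMP-site analogue).
#' @exportClass SwitchReport
setClass("SwitchReport",
  representation(couplings = "data.frame", stateLabels = "character",
                 thresholds = "numeric"))
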