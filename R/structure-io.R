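#' @include methods.R
NULL

#' Read a (multi-model) PDB file into a Calpha conformer ensemble
#'
#' Each \code{MODEL} record becomes one [CalphaStructure-class] (a file
#' without \code{MODEL} records yields exactly one).  Only Calpha atoms of
#' standard \code{ATOM} records are retained; alternate locations are resolved
#' by keeping the first listed; residues are ordered by chain, then author
#' residue number, then insertion code.  Unresolved residues are simply
#' absent - nothing is imputed.
#'
#' @param path path to a PDB file.
#' @param chains optional character vector of chain identifiers to keep.
#' @param includeHetero if \code{TRUE}, non-water HETATM heavy atoms (e.g. a
#'   bound ligand) are appended as extra network nodes, one node per atom.
#'   Default \code{FALSE}: the network is built on protein Calpha atoms only.
#' @return A [StructureEnsemble-class].
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeCalphaPdb(structureEnsemble(makeChain(5, seed = 1)), f)
#' readPdbModels(f)
#' @export
readPdbModels <- function(path, chains = NULL, includeHetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  atom <- pdb$atom
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- " "
  keep <- atom$type == "ATOM" & atom$elety == "CA"
  if (includeHetero)
    keep <- keep | (atom$type == "HETATM" & !(atom$resid %in% c("HOH", "WAT"))
                    & !startsWith(atom$elety, "H"))
  if (!any(atom$type == "ATOM" & atom$elety == "CA"))
    stop("no Calpha atoms found in ", path)
  idx <- which(keep)
  if (!is.null(chains)) {
    idx <- idx[atom$chain[idx] %in% chains]
    if (length(idx) == 0L)
      stop("chain filter [", paste(chains, collapse = ","),
           "] matches no Calpha atoms")
  }
  ## first-listed wins for duplicated (chain, resno, insert) Calpha keys;
  ## hetero nodes are keyed per atom (eno) and never collapse
  sub <- atom[idx, ]
  key <- ifelse(sub$type == "ATOM",
                paste(sub$chain, sub$resno, sub$insert),
                paste(sub$chain, sub$resno, sub$insert, sub$eno))
  idx <- idx[!duplicated(key)]
  sub <- atom[idx, ]
  ord <- order(sub$chain, sub$resno, sub$insert)
  idx <- idx[ord]
  sub <- atom[idx, ]

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  cols <- bio3d::atom2xyz(idx)
  members <- lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, cols], ncol = 3L, byrow = TRUE)
    new("CalphaStructure",
        residues = data.frame(chain = sub$chain, resno = as.integer(sub$resno),
                              insert = sub$insert, resname = sub$resid,
                              stringsAsFactors = FALSE),
        coords = co, modelId = as.integer(m))
  })
  structureEnsemble(members)
}

#' Write a conformer ensemble as a multi-model Calpha PDB file
#'
#' Writes one \code{MODEL}/\code{ENDMDL} block per member with standard
#' fixed-width 3-decimal coordinate fields, so that
#' \code{readPdbModels(writeCalphaPdb(x))} reproduces \code{x} to the PDB
#' format's precision.
#'
#' @param x a [StructureEnsemble-class], [CalphaStructure-class] or
#'   [Trajectory-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeCalphaPdb <- function(x, path) {
  if (is(x, "CalphaStructure")) x <- structureEnsemble(x)
  if (is(x, "Trajectory")) x <- structureEnsemble(x@frames)
  if (!is(x, "StructureEnsemble")) stop("cannot write a ", class(x))
  if (length(x@members) == 0L) stop("refusing to write an empty ensemble")
  if (!x@sharedTopology && length(x@members) > 1L)
    stop("multi-model output requires shared topology")
  res <- x@members[[1L]]@residues
  xyz <- do.call(rbind, lapply(x@members,
                               function(m) as.numeric(t(m@coords))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = res$resno,
                   chain = res$chain, insert = ifelse(res$insert == "",
                                                      NA, res$insert),
                   resid = res$resname, elety = rep("CA", nrow(res)))
  invisible(path)
}

.asLabels <- function(labels) {
  if (is.data.frame(labels)) .labels(labels) else as.character(labels)
}

#' Write / read a labelled square matrix as CSV
#'
#' Plain comma-separated text with a header row of \code{chain:resnum} labels
#' and the same labels in the first column; numeric round trip is lossless to
#' more than 6 significant digits.
#'
#' @param mat numeric N x N matrix.
#' @param labels character vector of N labels, or a residue data.frame (the
#'   \code{chain:resnum} labels are derived).
#' @param path file path.
#' @return \code{writeMatrixCsv} invisibly returns \code{path};
#'   \code{readMatrixCsv} returns the labelled matrix.
#' @export
writeMatrixCsv <- function(mat, labels, path) {
  labels <- .asLabels(labels)
  if (nrow(mat) != ncol(mat)) stop("matrix must be square")
  if (length(labels) != nrow(mat))
    stop("label count (", length(labels), ") does not match matrix dimension (",
         nrow(mat), ")")
  df <- data.frame(label = labels, mat, check.names = FALSE)
  names(df) <- c("label", labels)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeMatrixCsv
#' @export
readMatrixCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a labelled per-residue profile as CSV
#'
#' @param values numeric vector of per-residue values.
#' @param labels character labels or a residue data.frame.
#' @param path file path.
#' @return \code{writeProfileCsv} invisibly returns \code{path};
#'   \code{readProfileCsv} returns a named numeric vector.
#' @export
writeProfileCsv <- function(values, labels, path) {
  labels <- .asLabels(labels)
  if (length(labels) != length(values))
    stop("label count does not match value count")
  utils::write.csv(data.frame(label = labels, value = values), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeProfileCsv
#' @export
readProfileCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stats::setNames(as.numeric(df$value), df$label)
}
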