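#' @include AllGenerics.R
NULL

## ---- residue label helper (internal) ----------------------------------

## "chain:resno" labels, with insertion codes appended when present.
.labels <- function(res) {
  paste0(res$chain, ":", res$resno,
         ifelse(res$insert == "" | is.na(res$insert), "", res$insert))
}

## ---- accessors ---------------------------------------------------------

#' @rdname gnmswitch-accessors
#' @export
setMethod("residues", "CalphaStructure", function(x, ...) x@residues)
#' @rdname gnmswitch-accessors
#' @export
setMethod("residues", "KirchhoffMatrix", function(x, ...) x@residues)
#' @rdname gnmswitch-accessors
#' @export
setMethod("residues", "GNMModes", function(x, ...) x@residues)
#' @rdname gnmswitch-accessors
#' @export
setMethod("residues", "CorrelationMap", function(x, ...) x@residues)
#' @rdname gnmswitch-accessors
#' @export
setMethod("residues", "MSFProfile", function(x, ...) x@residues)
#' @rdname gnmswitch-accessors
#' @export
setMethod("residues", "ModeShape", function(x, ...) x@residues)
#' @rdname gnmswitch-accessors
#' @export
setMethod("residues", "DifferenceMap", function(x, ...) x@residues)
#' @rdname gnmswitch-accessors
#' @export
setMethod("residues", "EssentialModes", function(x, ...) x@residues)

#' @rdname gnmswitch-accessors
#' @export
setMethod("coords", "CalphaStructure", function(x, ...) x@coords)

#' @rdname gnmswitch-accessors
#' @export
setMethod("nResidues", "CalphaStructure", function(x) nrow(x@residues))
#' @rdname gnmswitch-accessors
#' @export
setMethod("nResidues", "CorrelationMap", function(x) nrow(x@residues))

#' @rdname gnmswitch-accessors
#' @export
setMethod("residueLabels", "CalphaStructure", function(x) .labels(x@residues))
#' @rdname gnmswitch-accessors
#' @export
setMethod("residueLabels", "CorrelationMap", function(x) .labels(x@residues))
#' @rdname gnmswitch-accessors
#' @export
setMethod("residueLabels", "MSFProfile", function(x) .labels(x@residues))

#' @rdname gnmswitch-accessors
#' @export
setMethod("members", "StructureEnsemble", function(x) x@members)

#' @rdname gnmswitch-accessors
#' @export
setMethod("length", "StructureEnsemble", function(x) length(x@members))
#' @rdname gnmswitch-accessors
#' @export
setMethod("length", "Trajectory", function(x) length(x@frames))

setMethod("[[", "StructureEnsemble", function(x, i) x@members[[i]])
setMethod("[[", "Trajectory", function(x, i) x@frames[[i]])

#' @rdname gnmswitch-accessors
#' @export
setMethod("eigenvalues", "GNMModes", function(x) x@eigenvalues)
#' @rdname gnmswitch-accessors
#' @export
setMethod("eigenvalues", "EssentialModes", function(x) x@eigenvalues)
#' @rdname gnmswitch-accessors
#' @export
setMethod("eigenvectors", "GNMModes", function(x) x@eigenvectors)
#' @rdname gnmswitch-accessors
#' @export
setMethod("eigenvectors", "EssentialModes", function(x) x@eigenvectors)
#' @rdname gnmswitch-accessors
#' @export
setMethod("nZeroModes", "GNMModes", function(x) x@nZero)

#' @rdname gnmswitch-accessors
#' @export
setMethod("rawMap", "CorrelationMap", function(x) x@raw)
#' @rdname gnmswitch-accessors
#' @export
setMethod("normalizedMap", "CorrelationMap", function(x) x@normalized)

#' @rdname gnmswitch-accessors
#' @export
setMethod("profileValues", "MSFProfile", function(x) x@values)
#' @rdname gnmswitch-accessors
#' @export
setMethod("profileValues", "ModeShape", function(x) x@values)
#' @rdname gnmswitch-accessors
#' @export
setMethod("profileValues", "RegionProfile", function(x) x@values)

#' @rdname gnmswitch-accessors
#' @export
setMethod("hingeResidues", "HingeSet", function(x) x@residues)

#' @rdname gnmswitch-accessors
#' @export
setMethod("clusterAssignments", "ClusterResult", function(x) x@assignments)
#' @rdname gnmswitch-accessors
#' @export
setMethod("clusterPopulations", "ClusterResult", function(x) x@populations)
#' @rdname gnmswitch-accessors
#' @export
setMethod("bestMembers", "ClusterResult", function(x) x@bestMembers)

#' @rdname gnmswitch-accessors
#' @export
setMethod("stateLabels", "SwitchReport", function(x) x@stateLabels)
#' @rdname gnmswitch-accessors
#' @export
setMethod("couplings", "SwitchReport", function(x) x@couplings)

## ---- show methods ------------------------------------------------------

setMethod("show", "CalphaStructure", function(object) {
  res <- object@residues
  cat("CalphaStructure:", nrow(res), "Calpha nodes,",
      length(unique(res$chain)), "chain(s) [",
      paste(unique(res$chain), collapse = ","), "], model",
      object@modelId, "\n")
})

setMethod("show", "StructureEnsemble", function(object) {
  cat("StructureEnsemble:", length(object@members), "member(s),",
      if (object@sharedTopology) "shared topology" else "mixed topology", "\n")
})

setMethod("show", "ModeRange", function(object) {
  cat("ModeRange: modes ", object@first, ":", object@last,
      if (nzchar(object@label)) paste0(" (", object@label, ")"), "\n", sep = "")
})

setMethod("show", "KirchhoffMatrix", function(object) {
  cat("KirchhoffMatrix:", nrow(object@gamma), "nodes, cutoff",
      object@cutoff, "A, mean degree",
      round(mean(diag(object@gamma)), 2), "\n")
})

setMethod("show", "GNMModes", function(object) {
  n <- length(object@eigenvalues)
  cat("GNMModes:", n, "modes,", object@nZero, "zero mode(s);",
      "slowest nonzero eigenvalue",
      signif(object@eigenvalues[object@nZero + 1L], 4), "\n")
})

setMethod("show", "CorrelationMap", function(object) {
  cat("CorrelationMap: ", nrow(object@residues), " residues, modes ",
      object@modeRange@first, ":", object@modeRange@last, sep = "")
  if (nzchar(object@label)) cat(" [", object@label, "]", sep = "")
  cat("\n")
})

setMethod("show", "MSFProfile", function(object) {
  cat("MSFProfile:", length(object@values), "residues; range [",
      signif(min(object@values), 3), ",", signif(max(object@values), 3), "]\n")
})

setMethod("show", "HingeSet", function(object) {
  cat("HingeSet (", object@method, "): ", nrow(object@residues),
      " hinge residue(s)", sep = "")
  if (nrow(object@residues) > 0)
    cat(": ", paste(.labels(object@residues), collapse = " "), sep = "")
  cat("\n")
})

setMethod("show", "RegionSpec", function(object) {
  cat("RegionSpec ", object@name, ": chain ", object@chain, ", residues ",
      object@from, "-", object@to, "\n", sep = "")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@frames), "frames (",
      object@equilibration, "equilibration ),",
      nrow(object@frames[[1L]]@residues), "residues\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: radius", object@radius, "A,",
      length(object@centroids), "cluster(s); populations:",
      paste(object@populations, collapse = " "), "\n")
})

setMethod("show", "EssentialModes", function(object) {
  cat("EssentialModes:", object@nModesKept, "modes kept of",
      length(object@eigenvalues), "; top eigenvalue",
      signif(object@eigenvalues[1L], 4), "A^2\n")
})

setMethod("show", "SwitchReport", function(object) {
  cat("SwitchReport: subunits [",
      paste(names(object@stateLabels), object@stateLabels, sep = "=",
            collapse = ", "), "]\n")
  print(object@couplings, row.names = FALSE)
})
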