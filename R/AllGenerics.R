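#' @include AllClasses.R
NULL

#' Accessors for gnmswitch objects
#'
#' Small accessor generics used across the package: residue bookkeeping,
#' coordinates, spectral components, and matrix views of correlation maps.
#'
#' @param x,object a gnmswitch object.
#' @param ... unused.
#' @return The slot content documented per method.
#' @name gnmswitch-accessors
NULL

#' @rdname gnmswitch-accessors
#' @export
setGeneric("residues", function(x, ...) standardGeneric("residues"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("nZeroModes", function(x) standardGeneric("nZeroModes"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("rawMap", function(x) standardGeneric("rawMap"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("normalizedMap", function(x) standardGeneric("normalizedMap"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("hingeResidues", function(x) standardGeneric("hingeResidues"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("clusterPopulations", function(x) standardGeneric("clusterPopulations"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("bestMembers", function(x) standardGeneric("bestMembers"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname gnmswitch-accessors
#' @export
setGeneric("couplings", function(x) standardGeneric("couplings"))
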