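#' @include gnm-core.R
NULL

#' Ensemble-averaged cross-correlation map
#'
#' Computes the GNM cross-correlation map of every conformer in a
#' shared-topology ensemble and averages the per-member \emph{normalized}
#' maps elementwise (members may differ in overall stiffness, so averaging
#' is done on the scale-free normalized correlations; the averaged raw
#' covariances are carried along for reference).  The member count is
#' recorded in the map label.
#'
#' @param ensemble a [StructureEnsemble-class] with shared topology; every
#'   member's contact graph must be connected.
#' @param cutoff contact cutoff (Angstrom), default 10.
#' @param range a [ModeRange-class], default the ten slowest modes.
#' @return A [CorrelationMap-class].
#' @export
ensembleCorrelationMap <- function(ensemble, cutoff = 10,
                                   range = modeRange(1L, 10L)) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  if (!ensemble@sharedTopology)
    stop("ensemble averaging requires shared topology")
  n <- length(ensemble@members)
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    modes <- withCallingHandlers(
      gnmDecompose(buildKirchhoff(ensemble@members[[i]], cutoff)),
      warning = function(w) invokeRestart("muffleWarning"))
    if (modes@nZero != 1L)
      stop("ensemble member ", i, " has a disconnected contact graph (",
           modes@nZero, " components)")
    maps[[i]] <- crossCorrelations(modes, range)
  }
  raw <- Reduce(`+`, lapply(maps, function(m) m@raw)) / n
  norm <- Reduce(`+`, lapply(maps, function(m) m@normalized)) / n
  new("CorrelationMap", raw = raw, normalized = norm,
      modeRange = maps[[1L]]@modeRange, residues = maps[[1L]]@residues,
      label = paste0("mean of ", n, " member maps"))
}

## resolve a RegionSpec onto the row indices of a residue table
.regionIndex <- function(res, region) {
  which(res$chain == region@chain & res$resno >= region@from &
          res$resno <= region@to)
}

#' Mean correlation of a region with every residue
#'
#' Averages the rows of the normalized map over the region's residues,
#' giving a per-residue profile of how the region couples to the rest of
#' the structure (the quantity usually painted onto ribbon diagrams).
#'
#' @param map a [CorrelationMap-class].
#' @param region a [RegionSpec-class].
#' @return A [RegionProfile-class].
#' @export
regionProfile <- function(map, region) {
  stopifnot(is(map, "CorrelationMap"), is(region, "RegionSpec"))
  idx <- .regionIndex(map@residues, region)
  if (length(idx) == 0L)
    stop("region ", region@name, " (", region@chain, ":", region@from, "-",
         region@to, ") matches no residues of the map")
  vals <- colMeans(map@normalized[idx, , drop = FALSE])
  new("RegionProfile", values = vals, region = region,
      residues = map@residues)
}

## align two residue tables on (chain, resno, insert); returns index pairs
.alignResidues <- function(resA, resB) {
  keyA <- paste(resA$chain, resA$resno, resA$insert)
  keyB <- paste(resB$chain, resB$resno, resB$insert)
  common <- intersect(keyA, keyB)
  list(a = match(common, keyA), b = match(common, keyB))
}

#' Difference-correlation map between two functional states
#'
#' Aligns the two maps on their shared (chain, residue number) keys and
#' subtracts the normalized correlations, state A minus state B.  The result
#' is bounded by [-2, 2] and exactly antisymmetric under swapping the
#' arguments.
#'
#' @param mapA,mapB [CorrelationMap-class] objects for the two states.
#' @param labels character pair naming the states.
#' @return A [DifferenceMap-class].
#' @export
differenceCorrelationMap <- function(mapA, mapB, labels = c("A", "B")) {
  stopifnot(is(mapA, "CorrelationMap"), is(mapB, "CorrelationMap"))
  al <- .alignResidues(mapA@residues, mapB@residues)
  if (length(al$a) < 2L)
    stop("residue intersection of the two maps has fewer than 2 residues")
  diff <- mapA@normalized[al$a, al$a, drop = FALSE] -
    mapB@normalized[al$b, al$b, drop = FALSE]
  res <- mapA@residues[al$a, , drop = FALSE]
  rownames(res) <- NULL
  new("DifferenceMap", values = diff, residues = res,
      stateLabels = as.character(labels))
}

#' Difference of two per-residue fluctuation profiles
#'
#' Elementwise state A minus state B on the residue intersection of the two
#' profiles (e.g. difference-MSF between monomeric and dimeric forms).
#'
#' @param profileA,profileB [MSFProfile-class] objects.
#' @return A named numeric vector (names are \code{chain:resnum} labels).
#' @export
differenceMsf <- function(profileA, profileB) {
  stopifnot(is(profileA, "MSFProfile"), is(profileB, "MSFProfile"))
  al <- .alignResidues(profileA@residues, profileB@residues)
  if (length(al$a) < 1L) stop("profiles share no residues")
  stats::setNames(profileA@values[al$a] - profileB@values[al$b],
                  .labels(profileA@residues[al$a, , drop = FALSE]))
}

## mean normalized correlation over a region pair's residue product
.regionCoupling <- function(map, regionI, regionJ) {
  i <- .regionIndex(map@residues, regionI)
  j <- .regionIndex(map@residues, regionJ)
  if (length(i) == 0L || length(j) == 0L)
    stop("region ", if (length(i) == 0L) regionI@name else regionJ@name,
         " matches no residues of the map")
  mean(map@normalized[i, j, drop = FALSE])
}

#' Hinge-mediated switch-coupling score
#'
#' Quantifies the on/off conformational-switch picture of a two-subunit,
#' two-domain structure: in the \emph{on} state the inter-domain hinge
#' couples to the hinge and cAMP-site analogue of the neighbouring subunit
#' (and to the functional sites of both subunits); in the \emph{off} state
#' it correlates only within its own subunit.  Each coupling is the mean
#' normalized correlation over the region pair's residue product.  A subunit
#' is labelled \code{"on"} iff its hinge-to-other-hinge coupling is at least
#' \code{thresholds[1]} \emph{and} its hinge-to-other-subunit cAMP-site
#' coupling is at least \code{thresholds[2]}; all couplings are reported
#' regardless of the label, so conclusions never rest on the defaults.
#'
#' @param map a [CorrelationMap-class] of the dimer.
#' @param hinge,campSite,dnaSite,dnaDomain each a list of two
#'   [RegionSpec-class] objects, one per subunit (in subunit order).
#' @param thresholds numeric \code{c(theta1, theta2)}; defaults
#'   \code{c(0.2, 0.2)}.
#' @return A [SwitchReport-class].
#' @export
switchScore <- function(map, hinge, campSite, dnaSite, dnaDomain,
                        thresholds = c(theta1 = 0.2, theta2 = 0.2)) {
  stopifnot(is(map, "CorrelationMap"), length(hinge) == 2L,
            length(campSite) == 2L, length(dnaSite) == 2L,
            length(dnaDomain) == 2L, length(thresholds) == 2L)
  subunits <- vapply(hinge, function(r) r@chain, character(1))
  rows <- list()
  labels <- character(2L)
  for (s in 1:2) {
    o <- 3L - s
    cp <- c(
      hinge_dna_domain_own   = .regionCoupling(map, hinge[[s]], dnaDomain[[s]]),
      hinge_other_hinge      = .regionCoupling(map, hinge[[s]], hinge[[o]]),
      hinge_camp_site_own    = .regionCoupling(map, hinge[[s]], campSite[[s]]),
      hinge_camp_site_other  = .regionCoupling(map, hinge[[s]], campSite[[o]]),
      hinge_dna_site_own     = .regionCoupling(map, hinge[[s]], dnaSite[[s]]),
      hinge_dna_site_other   = .regionCoupling(map, hinge[[s]], dnaSite[[o]]),
      camp_site_dna_site_own = .regionCoupling(map, campSite[[s]], dnaSite[[s]]))
    rows[[s]] <- data.frame(subunit = subunits[s], coupling = names(cp),
                            value = unname(cp), stringsAsFactors = FALSE)
    labels[s] <- if (cp[["hinge_other_hinge"]] >= thresholds[[1L]] &&
                     cp[["hinge_camp_site_other"]] >= thresholds[[2L]])
      "on" else "off"
  }
  new("SwitchReport", couplings = do.call(rbind, rows),
      stateLabels = stats::setNames(labels, subunits),
      thresholds = stats::setNames(as.numeric(thresholds),
                                   c("theta1", "theta2")))
}

#' Read a region-definition config file
#'
#' Flat key-value text, one region per line in the form
#' \code{name = chain:start-end}; blank lines and lines starting with
#' \code{#} are ignored.  The package ships a default definition for the
#' catabolite activator protein regions under
#' \code{system.file("extdata", "crp_regions.cfg", package = "gnmswitch")}.
#'
#' @param path path to the config file.
#' @return Named list of [RegionSpec-class] objects.
#' @export
readRegionsConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec(
      "^([^=[:space:]]+)[[:space:]]*=[[:space:]]*(\\S+):(-?[0-9]+)-(-?[0-9]+)$",
      ln))[[1L]]
    if (length(m) != 5L)
      stop("cannot parse region line: '", ln,
           "' (expected 'name = chain:start-end')")
    out[[m[2L]]] <- regionSpec(m[2L], m[3L], as.integer(m[4L]),
                               as.integer(m[5L]))
  }
  out
}
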