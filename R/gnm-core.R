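#' @include methods.R
NULL

#' Build the Kirchhoff (connectivity) matrix of a Calpha network
#'
#' In the Gaussian Network Model two residues interact through an identical
#' harmonic spring whenever their Calpha atoms lie within a cutoff distance.
#' The resulting contact topology is encoded in the Kirchhoff matrix (the
#' graph Laplacian): \eqn{\Gamma_{ij} = -1} for contacting pairs
#' (\eqn{d_{ij} \le} cutoff, \eqn{i \ne j}), \eqn{\Gamma_{ii}} = node degree,
#' zero row sums.
#'
#' @param structure a [CalphaStructure-class].
#' @param cutoff contact cutoff in Angstrom; default 10.
#' @return A [KirchhoffMatrix-class].
#' @examples
#' tri <- calphaStructure(3.8 * rbind(c(0, 0, 0), c(1, 0, 0),
#'                                    c(0.5, sqrt(3) / 2, 0)))
#' buildKirchhoff(tri, cutoff = 10)
#' @export
buildKirchhoff <- function(structure, cutoff = 10) {
  stopifnot(is(structure, "CalphaStructure"), cutoff > 0)
  xyz <- structure@coords
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(xyz))
  g <- -(d <= cutoff) * 1
  diag(g) <- 0
  diag(g) <- -rowSums(g)
  dimnames(g) <- NULL
  new("KirchhoffMatrix", gamma = g, cutoff = as.numeric(cutoff),
      residues = structure@residues)
}

#' Eigendecomposition of a Kirchhoff matrix
#'
#' Full symmetric eigendecomposition of the contact Laplacian.  An N-residue
#' network yields N-1 nonzero modes when its contact graph is connected; the
#' single zero mode is the uniform vector.  Eigenvalues below
#' \code{zeroTol * max(eigenvalue)} are classified as zero; more than one zero
#' mode means the contact graph is disconnected, which is recorded (with a
#' warning) and rejected by downstream correlation operations.
#'
#' @param kirchhoff a [KirchhoffMatrix-class].
#' @param zeroTol relative zero threshold; default \code{1e-8}.
#' @return A [GNMModes-class] with eigenvalues ascending and orthonormal
#'   eigenvector columns.  Each eigenvector's largest-magnitude entry is made
#'   positive to fix the (physically meaningless) global sign.
#' @export
gnmDecompose <- function(kirchhoff, zeroTol = 1e-8) {
  stopifnot(is(kirchhoff, "KirchhoffMatrix"))
  eig <- eigen(kirchhoff@gamma, symmetric = TRUE)
  ord <- order(eig$values)            # ascending
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  thr <- zeroTol * max(vals, zeroTol)   # guard the edgeless (all-zero) case
  vals[abs(vals) < thr] <- pmax(vals[abs(vals) < thr], 0)
  nZero <- sum(vals < thr)
  ## deterministic sign: largest-magnitude entry positive
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  if (nZero > 1L)
    warning("contact graph is disconnected: ", nZero, " zero modes")
  new("GNMModes", eigenvalues = vals, eigenvectors = vecs,
      nZero = as.integer(nZero), residues = kirchhoff@residues)
}

## map a ModeRange onto eigenvector column indices (skipping zero modes);
## truncation to the available nonzero modes is recorded in the label
.modeColumns <- function(modes, range) {
  nAvail <- length(modes@eigenvalues) - modes@nZero
  if (range@first > nAvail)
    stop("mode range starts beyond the ", nAvail, " available nonzero modes")
  last <- min(range@last, nAvail)
  label <- range@label
  if (last < range@last)
    label <- paste0(label, if (nzchar(label)) "; ",
                    "truncated to ", last, " nonzero modes")
  list(cols = modes@nZero + seq.int(range@first, last),
       range = modeRange(range@first, last, label))
}

#' Mode-restricted cross-correlations of residue fluctuations
#'
#' The fluctuation covariance of a connected GNM network is the
#' Moore-Penrose pseudo-inverse of the Kirchhoff matrix, expressed as a
#' superposition over nonzero modes:
#' \eqn{\langle \Delta R_i \cdot \Delta R_j \rangle \propto
#'   \sum_k \lambda_k^{-1} u_{ki} u_{kj}}.
#' Restricting the sum to a [ModeRange-class] isolates the contribution of
#' the chosen modes (e.g. the ten slowest).  The physical prefactor
#' \eqn{3 k_B T / \gamma} is set to 1, i.e. raw values are reported in those
#' reduced units; it cancels in the normalized map
#' \eqn{C_{ij} = raw_{ij} / \sqrt{raw_{ii}\, raw_{jj}} \in [-1, 1]}.
#'
#' @param modes a [GNMModes-class] with a connected contact graph
#'   (\code{nZeroModes(modes) == 1}).
#' @param range a [ModeRange-class]; ranges reaching past the available
#'   nonzero modes are truncated and the truncation recorded in the label.
#' @return A [CorrelationMap-class].
#' @examples
#' chain <- makeChain(20, seed = 1)
#' modes <- gnmDecompose(buildKirchhoff(chain, 10))
#' map <- crossCorrelations(modes, modeRange(1, 10))
#' range(normalizedMap(map))
#' @export
crossCorrelations <- function(modes, range = modeRange(1L, 10L)) {
  stopifnot(is(modes, "GNMModes"), is(range, "ModeRange"))
  if (modes@nZero != 1L)
    stop("correlations require a connected contact graph (nZero = 1, got ",
         modes@nZero, ")")
  mc <- .modeColumns(modes, range)
  u <- modes@eigenvectors[, mc$cols, drop = FALSE]
  lam <- modes@eigenvalues[mc$cols]
  raw <- u %*% (t(u) / lam)
  raw <- (raw + t(raw)) / 2
  d <- diag(raw)
  if (any(d <= 0))
    stop("non-positive diagonal in the raw covariance; cannot normalize")
  norm <- raw / sqrt(outer(d, d))
  norm[norm > 1] <- 1
  norm[norm < -1] <- -1
  diag(norm) <- 1
  new("CorrelationMap", raw = raw, normalized = norm, modeRange = mc$range,
      residues = modes@residues, label = "")
}

#' Mode-restricted mean-square fluctuations
#'
#' Per-residue mean-square fluctuation over a mode subset,
#' \eqn{\langle \Delta R_i^2 \rangle \propto \sum_k \lambda_k^{-1} u_{ki}^2},
#' in reduced \eqn{3 k_B T / \gamma} units.  Equals the diagonal of the
#' same-range raw correlation map.
#'
#' @inheritParams crossCorrelations
#' @return An [MSFProfile-class].
#' @export
meanSquareFluctuations <- function(modes, range = modeRange(1L, 10L)) {
  stopifnot(is(modes, "GNMModes"), is(range, "ModeRange"))
  if (modes@nZero != 1L)
    stop("fluctuations require a connected contact graph (nZero = 1, got ",
         modes@nZero, ")")
  mc <- .modeColumns(modes, range)
  u <- modes@eigenvectors[, mc$cols, drop = FALSE]
  lam <- modes@eigenvalues[mc$cols]
  vals <- as.numeric((u^2) %*% (1 / lam))
  new("MSFProfile", values = vals, modeRange = mc$range,
      residues = modes@residues)
}

#' One-call GNM of a single structure
#'
#' Convenience wrapper: Kirchhoff build, decomposition, and mode-restricted
#' fluctuations/correlations in one step.
#'
#' @param structure a [CalphaStructure-class].
#' @param cutoff contact cutoff (Angstrom), default 10.
#' @param range a [ModeRange-class], default modes 1:10.
#' @return A list with elements \code{modes} ([GNMModes-class]),
#'   \code{map} ([CorrelationMap-class]) and \code{msf} ([MSFProfile-class]).
#' @export
gnmAnalysis <- function(structure, cutoff = 10, range = modeRange(1L, 10L)) {
  modes <- gnmDecompose(buildKirchhoff(structure, cutoff))
  list(modes = modes,
       map = crossCorrelations(modes, range),
       msf = meanSquareFluctuations(modes, range))
}
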