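#' @include gnm-core.R
NULL

#' Averaged slow-mode shape
#'
#' The shape of mode k is the vector of squared eigenvector entries
#' \eqn{u_{ki}^2} (each summing to 1 for a unit eigenvector); the returned
#' shape is the mean over the modes in \code{range}.  Minima of slow-mode
#' shapes mark the hinge regions that coordinate cooperative motion.
#'
#' @inheritParams crossCorrelations
#' @return A [ModeShape-class].
#' @export
slowModeShape <- function(modes, range = modeRange(1L, 3L)) {
  stopifnot(is(modes, "GNMModes"), is(range, "ModeRange"))
  if (modes@nZero != 1L)
    stop("mode shapes require a connected contact graph")
  mc <- .modeColumns(modes, range)
  u <- modes@eigenvectors[, mc$cols, drop = FALSE]
  new("ModeShape", values = rowMeans(u^2), modeRange = mc$range,
      residues = modes@residues)
}

#' Hinge detection from slow-mode shape minima
#'
#' A residue qualifies as a hinge site when it is a local minimum of the
#' mode shape over a centred sliding window \emph{and} its shape value lies
#' below the given quantile of all shape values.  Contiguous qualifying
#' residues are merged into hinge segments (a \code{segment} column in the
#' result).
#'
#' @param shape a [ModeShape-class].
#' @param window odd integer sliding-window width (default 5).
#' @param floorQuantile quantile of shape values a hinge must lie below
#'   (default 0.25).
#' @return A [HingeSet-class]; possibly empty.
#' @export
detectHingesMinima <- function(shape, window = 5L, floorQuantile = 0.25) {
  stopifnot(is(shape, "ModeShape"), window %% 2L == 1L)
  v <- shape@values
  n <- length(v)
  if (n < window) stop("structure smaller than the detection window")
  half <- (window - 1L) %/% 2L
  floorVal <- stats::quantile(v, floorQuantile, names = FALSE)
  isMin <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    v[i] <= min(v[lo:hi]) && v[i] <= floorVal
  }, logical(1))
  .hingeSet(shape@residues, isMin, "minima", shape@modeRange)
}

#' Hinge detection from slow-mode sign crossovers
#'
#' Global hinge centres sit at the crossover between positive and negative
#' displacements of an individual slow mode.  For each chain, consecutive
#' residues between which the eigenvector changes sign are reported (both
#' flanking residues); exact zero entries are assigned to the hinge segment.
#' Crossovers are never detected across chain boundaries, and the result is
#' invariant to a global sign flip of the mode.
#'
#' @param modes a [GNMModes-class] with a connected contact graph.
#' @param modeIndex index of the nonzero mode to analyse (1 = slowest).
#' @return A [HingeSet-class].
#' @export
detectHingesCrossover <- function(modes, modeIndex = 1L) {
  stopifnot(is(modes, "GNMModes"))
  if (modes@nZero != 1L)
    stop("crossover detection requires a connected contact graph")
  mc <- .modeColumns(modes, modeRange(modeIndex, modeIndex, "crossover"))
  u <- modes@eigenvectors[, mc$cols]
  res <- modes@residues
  flag <- logical(length(u))
  zeroTol <- 1e-9 * max(abs(u))   # amplitudes this small count as nodes
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch)
    s <- sign(u[idx])
    s[abs(u[idx]) < zeroTol] <- 0
    flag[idx[s == 0]] <- TRUE
    nz <- which(s != 0)
    if (length(nz) > 1L) {
      for (j in seq_len(length(nz) - 1L)) {
        ## a sign change between consecutive nonzero entries flags both
        ## flanks and any exact zeros bracketed between them
        if (s[nz[j]] * s[nz[j + 1L]] < 0)
          flag[idx[nz[j]:nz[j + 1L]]] <- TRUE
      }
    }
  }
  .hingeSet(res, flag, "crossover", mc$range)
}

.hingeSet <- function(res, flag, method, range) {
  out <- res[flag, , drop = FALSE]
  if (nrow(out) > 0L) {
    idx <- which(flag)
    out$segment <- cumsum(c(1L, diff(idx) > 1L))
  } else {
    out$segment <- integer(0)
  }
  rownames(out) <- NULL
  new("HingeSet", residues = out, method = method, modeRange = range)
}
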