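#' @include methods.R
NULL

## ---- Kabsch machinery (internal) --------------------------------------

## optimal proper rotation of P onto Q (both centred), via SVD with the
## determinant correction that forbids reflections
.kabschRotation <- function(P, Q) {
  sv <- svd(crossprod(P, Q))
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

.rmsdCoords <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

## superpose coordinate matrix 'mob' onto 'ref'; returns list(coords, rmsd)
.superposeCoords <- function(mob, ref) {
  cm <- colMeans(mob); cr <- colMeans(ref)
  P <- sweep(mob, 2L, cm); Q <- sweep(ref, 2L, cr)
  R <- .kabschRotation(P, Q)
  fit <- sweep(P %*% R, 2L, cr, `+`)
  list(coords = fit, rmsd = .rmsdCoords(fit, ref))
}

#' Kabsch superposition of one conformer onto another
#'
#' Optimal rigid-body rotation and translation minimizing the Calpha RMSD,
#' computed by the SVD-based Kabsch algorithm with the determinant
#' correction, so reflections are never applied.
#'
#' @param mobile,reference [CalphaStructure-class] objects with identical
#'   residue lists.
#' @return List with \code{structure} (the superposed mobile conformer) and
#'   \code{rmsd} (the minimized Calpha RMSD, Angstrom).
#' @export
kabschSuperpose <- function(mobile, reference) {
  stopifnot(is(mobile, "CalphaStructure"), is(reference, "CalphaStructure"))
  if (!identical(mobile@residues[c("chain", "resno", "insert")],
                 reference@residues[c("chain", "resno", "insert")]))
    stop("superposition requires identical residue lists")
  if (identical(mobile@coords, reference@coords))
    return(list(structure = mobile, rmsd = 0))
  sp <- .superposeCoords(mobile@coords, reference@coords)
  out <- mobile
  out@coords <- sp$coords
  list(structure = out, rmsd = sp$rmsd)
}

## retained frames of a trajectory, superposed onto the first retained frame,
## as a T x 3N coordinate matrix (x1 y1 z1 x2 ...)
.trajMatrix <- function(traj, superpose = TRUE) {
  frames <- traj@frames
  if (traj@equilibration > 0L)
    frames <- frames[-seq_len(traj@equilibration)]
  ref <- frames[[1L]]@coords
  t(vapply(frames, function(f)
    as.numeric(t(if (superpose) .superposeCoords(f@coords, ref)$coords
                 else f@coords)),
    numeric(3L * nrow(ref))))
}

.retainedFrames <- function(traj) {
  if (traj@equilibration > 0L) traj@frames[-seq_len(traj@equilibration)]
  else traj@frames
}

#' Per-frame RMSD from a fixed reference
#'
#' Kabsch-minimized Calpha RMSD of every retained frame against a fixed
#' reference conformer (default: the first retained frame, i.e. the series
#' analogue of "deviation from the initial structure").
#'
#' @param traj a [Trajectory-class]; equilibration frames are discarded.
#' @param reference optional [CalphaStructure-class]; default first retained
#'   frame.
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsdSeries <- function(traj, reference = NULL) {
  stopifnot(is(traj, "Trajectory"))
  frames <- .retainedFrames(traj)
  if (is.null(reference)) reference <- frames[[1L]]
  vapply(frames, function(f) kabschSuperpose(f, reference)$rmsd, numeric(1))
}

#' Radius-controlled clustering of a conformer series
#'
#' Iterative clustering in the spirit of the MMTSB \code{kclust} tool: the
#' cluster count is an \emph{output} controlled by the radius, not an input.
#' All frames are first superposed onto the first retained frame and
#' inter-conformer distances are plain coordinate RMSDs in that common
#' frame.  Pass 1 walks the frames in order, seeding a new cluster whenever
#' a frame's minimum centroid RMSD exceeds \code{radius} and otherwise
#' assigning it to the nearest centroid (centroids are running coordinate
#' means).  Subsequent passes reassign every frame to its nearest centroid
#' and recompute centroids, until the assignment is stable or
#' \code{maxIter} is reached.  The radius is approximate in the same sense
#' as in \code{kclust}: at convergence members are near, but not strictly
#' within, \code{radius} of their centroid.  The best member of each cluster
#' is the frame with least RMSD to its centroid.
#'
#' @param traj a [Trajectory-class].
#' @param radius clustering radius (Angstrom RMSD); default 3.5.
#' @param maxIter maximum reassignment passes (default 100).
#' @return A [ClusterResult-class].
#' @export
radiusCluster <- function(traj, radius = 3.5, maxIter = 100L) {
  stopifnot(is(traj, "Trajectory"), radius > 0)
  X <- .trajMatrix(traj)
  nT <- nrow(X); n3 <- ncol(X)
  rmsdTo <- function(frame, cen) sqrt(sum((frame - cen)^2) / (n3 / 3))
  ## pass 1: ordered seeding
  centroids <- list(X[1L, ])
  counts <- 1L
  assign <- integer(nT); assign[1L] <- 1L
  if (nT > 1L) for (t in 2L:nT) {
    d <- vapply(centroids, rmsdTo, numeric(1), frame = X[t, ])
    j <- which.min(d)
    if (d[j] > radius) {
      centroids[[length(centroids) + 1L]] <- X[t, ]
      counts <- c(counts, 1L)
      assign[t] <- length(centroids)
    } else {
      assign[t] <- j
      counts[j] <- counts[j] + 1L
      centroids[[j]] <- centroids[[j]] + (X[t, ] - centroids[[j]]) / counts[j]
    }
  }
  ## reassignment passes
  for (iter in seq_len(maxIter)) {
    centroids <- lapply(sort(unique(assign)), function(k)
      colMeans(X[assign == k, , drop = FALSE]))
    newAssign <- vapply(seq_len(nT), function(t)
      which.min(vapply(centroids, rmsdTo, numeric(1), frame = X[t, ])),
      integer(1))
    if (all(newAssign == assign)) { assign <- newAssign; break }
    assign <- newAssign
    ## re-index in case a cluster emptied
    assign <- match(assign, sort(unique(assign)))
  }
  centroids <- lapply(sort(unique(assign)), function(k)
    colMeans(X[assign == k, , drop = FALSE]))
  assign <- match(assign, sort(unique(assign)))
  k <- length(centroids)
  best <- vapply(seq_len(k), function(j) {
    idx <- which(assign == j)
    idx[which.min(vapply(idx, function(t) rmsdTo(X[t, ], centroids[[j]]),
                         numeric(1)))]
  }, integer(1))
  new("ClusterResult", radius = as.numeric(radius),
      assignments = as.integer(assign),
      centroids = lapply(centroids, function(c)
        matrix(c, ncol = 3L, byrow = TRUE)),
      populations = as.integer(tabulate(assign, k)),
      bestMembers = best, frameOffset = traj@equilibration)
}

#' Essential-dynamics decomposition of a trajectory
#'
#' Principal components of the Calpha fluctuation matrix: retained frames
#' are superposed onto the first retained frame, per-frame 3N coordinate
#' deviations from the time mean form the fluctuation matrix, and its
#' covariance is diagonalized through a singular value decomposition.  The
#' eigenvalues (descending variances, Angstrom^2) sum to the total
#' positional variance; the leading modes are the essential modes of the
#' motion.
#'
#' @param traj a [Trajectory-class] with at least 2 retained frames.
#' @param nModes number of modes to retain (default 10); requests beyond the
#'   available rank are truncated with a warning.
#' @param superpose superpose frames onto the first retained frame before
#'   the decomposition (default \code{TRUE}).  Set \code{FALSE} only for
#'   series that are already aligned, e.g. synthetic fluctuations along a
#'   planted direction, where the rigid-body fit would itself perturb the
#'   spectrum.
#' @return An [EssentialModes-class].
#' @export
essentialModes <- function(traj, nModes = 10L, superpose = TRUE) {
  stopifnot(is(traj, "Trajectory"), nModes >= 1L)
  X <- .trajMatrix(traj, superpose = superpose)
  nT <- nrow(X)
  mu <- colMeans(X)
  D <- sweep(X, 2L, mu)
  sv <- svd(D)
  lam <- sv$d^2 / nT                    # population covariance eigenvalues
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  keep <- min(nModes, rank)
  if (keep < nModes)
    warning("only ", rank, " non-degenerate modes available; kept ", keep)
  new("EssentialModes",
      meanStructure = matrix(mu, ncol = 3L, byrow = TRUE),
      eigenvalues = lam,
      eigenvectors = sv$v[, seq_len(keep), drop = FALSE],
      nModesKept = as.integer(keep),
      residues = traj@frames[[1L]]@residues)
}

#' Residue cross-correlations from essential modes
#'
#' Reconstructs the residue-level fluctuation covariance from the first
#' \code{nModes} essential modes,
#' \eqn{raw_{ij} = \sum_k \lambda_k\, v_k^{(i)} \cdot v_k^{(j)}} where
#' \eqn{v_k^{(i)}} is the 3-vector block of mode k on residue i, then
#' normalizes to correlations in [-1, 1].  With all modes this equals the
#' direct covariance correlation.
#'
#' @param modes an [EssentialModes-class].
#' @param nModes number of modes to use (default 10, capped at the number
#'   kept in \code{modes}).
#' @return A [CorrelationMap-class].
#' @export
essentialCorrelations <- function(modes, nModes = 10L) {
  stopifnot(is(modes, "EssentialModes"))
  k <- min(nModes, modes@nModesKept)
  if (k < 1L) stop("no modes available")
  n <- nrow(modes@meanStructure)
  raw <- matrix(0, n, n)
  for (m in seq_len(k)) {
    V3 <- matrix(modes@eigenvectors[, m], ncol = 3L, byrow = TRUE)
    raw <- raw + modes@eigenvalues[m] * tcrossprod(V3)
  }
  raw <- (raw + t(raw)) / 2
  d <- diag(raw)
  if (any(d <= 0))
    stop("residue(s) with zero fluctuation in the selected modes; ",
         "cannot normalize")
  norm <- raw / sqrt(outer(d, d))
  norm[norm > 1] <- 1; norm[norm < -1] <- -1
  diag(norm) <- 1
  new("CorrelationMap", raw = raw, normalized = norm,
      modeRange = modeRange(1L, k, "essential modes"),
      residues = modes@residues, label = "essential dynamics")
}

#' Mean-square fluctuations from a trajectory
#'
#' Per-residue time-averaged squared deviation from the mean structure after
#' superposition of all retained frames onto the first (units Angstrom^2).
#'
#' @param traj a [Trajectory-class].
#' @return An [MSFProfile-class]; the mode-range label records that the
#'   profile covers all motions of the series.
#' @export
msfFromTrajectory <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  X <- .trajMatrix(traj)
  D <- sweep(X, 2L, colMeans(X))
  perCoord <- colMeans(D^2)
  msf <- rowSums(matrix(perCoord, ncol = 3L, byrow = TRUE))
  new("MSFProfile", values = msf,
      modeRange = modeRange(1L, 1L, "trajectory MSF (all motions, A^2)"),
      residues = traj@frames[[1L]]@residues)
}
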