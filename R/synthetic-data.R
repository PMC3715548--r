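#' @include methods.R
NULL

## run expr under a fixed seed without clobbering the caller's RNG stream
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## connectivity of the contact graph at 'cutoff' (BFS)
.isConnected <- function(coords, cutoff) {
  n <- nrow(coords)
  adj <- as.matrix(stats::dist(coords)) <= cutoff
  seen <- logical(n); seen[1L] <- TRUE
  front <- 1L
  while (length(front) > 0L) {
    nxt <- which(colSums(adj[front, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    front <- nxt
  }
  all(seen)
}

## uniform random packing of n points in a sphere with a minimum pair
## distance; the target density (volume per residue) is chosen to give a
## protein-like mean contact degree of about 10-14 at a 10 A cutoff
.packSphere <- function(n, minDist = 3.6, volPerRes = 150) {
  R <- (3 * n * volPerRes / (4 * pi))^(1 / 3)
  pts <- matrix(NA_real_, n, 3L)
  i <- 0L; tries <- 0L
  while (i < n) {
    p <- stats::runif(3L, -R, R)
    if (sum(p^2) > R^2) next
    tries <- tries + 1L
    if (tries > 20000L) { minDist <- minDist * 0.95; tries <- 0L }
    if (i == 0L ||
        min(rowSums((pts[seq_len(i), , drop = FALSE] -
                       matrix(p, i, 3L, byrow = TRUE))^2)) >= minDist^2) {
      i <- i + 1L
      pts[i, ] <- p
    }
  }
  pts
}

## L interior points of a circular arc from P1 to P2 with total arc length
## arcLen (falls back to linear interpolation when the chord is >= arcLen)
.arcPoints <- function(P1, P2, arcLen, L) {
  if (L < 1L) return(matrix(numeric(0), 0L, 3L))
  chord <- sqrt(sum((P2 - P1)^2))
  tFrac <- seq_len(L) / (L + 1)
  if (chord >= arcLen * 0.999) {
    return(t(vapply(tFrac, function(f) P1 + f * (P2 - P1), numeric(3))))
  }
  ## solve sin(t/2)/(t/2) = chord/arcLen for the central angle t
  g <- function(t) sin(t / 2) / (t / 2) - chord / arcLen
  theta <- stats::uniroot(g, c(1e-6, 2 * pi - 1e-6))$root
  R <- arcLen / theta
  u <- (P2 - P1) / chord
  ## in-plane normal: prefer the xz-plane bulge, fall back if degenerate
  ref <- if (abs(u[2L]) < 0.9) c(0, 1, 0) else c(0, 0, 1)
  w <- ref - sum(ref * u) * u
  w <- w / sqrt(sum(w^2))
  mid <- (P1 + P2) / 2
  O <- mid - w * sqrt(max(R^2 - (chord / 2)^2, 0))
  a1 <- atan2(sum((P1 - O) * w), sum((P1 - O) * u))
  a2 <- atan2(sum((P2 - O) * w), sum((P2 - O) * u))
  if (a2 < a1) a2 <- a2 + 2 * pi
  ang <- a1 + tFrac * (a2 - a1)
  t(vapply(ang, function(a) O + R * (cos(a) * u + sin(a) * w), numeric(3)))
}

#' Synthetic smooth Calpha chain
#'
#' A smooth self-avoiding chain with exact consecutive Calpha spacing
#' (default 3.8 Angstrom), built by randomly bending the walk direction at
#' each step.  \code{curvature = 0} gives a straight (collinear) chain.
#'
#' @param n number of residues.
#' @param spacing consecutive Calpha distance (Angstrom).
#' @param curvature standard deviation of the per-step direction change
#'   (radians-like scale); default 0.25.
#' @param seed integer seed; the generator is bit-reproducible under a
#'   fixed seed.
#' @return A [CalphaStructure-class] (single chain "A").
#' @export
makeChain <- function(n, spacing = 3.8, curvature = 0.25, seed = NULL) {
  stopifnot(n >= 2L, spacing > 0)
  .withSeed(seed, {
    pts <- matrix(0, n, 3L)
    dir <- c(1, 0, 0)
    for (i in 2L:n) {
      repeat {
        bend <- if (curvature > 0) stats::rnorm(3L, 0, curvature) else c(0, 0, 0)
        cand <- dir + bend
        cand <- cand / sqrt(sum(cand^2))
        p <- pts[i - 1L, ] + spacing * cand
        ## self-avoidance against all but the immediate predecessor
        if (i <= 2L || curvature == 0 ||
            min(rowSums((pts[seq_len(i - 2L), , drop = FALSE] -
                           matrix(p, i - 2L, 3L, byrow = TRUE))^2)) > 3^2) {
          pts[i, ] <- p
          dir <- cand
          break
        }
      }
    }
    calphaStructure(pts, chain = "A")
  })
}

#' Synthetic two-domain dumbbell with a designed hinge
#'
#' Two compact globular domains (spherical random packings) joined by an
#' extended linker of \code{hingeLength} residues.  With
#' \code{interDomainContacts = 0} the domains touch only through the linker
#' (apo-like isolation); with a positive value the domains are drawn
#' together until at least that many inter-domain residue pairs fall within
#' the cutoff (holo-like coupling), the linker bowing out on a circular arc
#' to keep its length.
#'
#' @param nPerDomain residues per domain (default 25).
#' @param hingeLength linker residues (default 3).
#' @param interDomainContacts target count of direct inter-domain contact
#'   pairs at \code{cutoff} (default 0).
#' @param spacing linker Calpha spacing (Angstrom).
#' @param cutoff contact cutoff used for the construction guarantees.
#' @param seed integer seed.
#' @return List with \code{structure} (a [CalphaStructure-class], chain "A",
#'   residues numbered 1..N) and \code{hinge} (the designed linker residue
#'   indices).
#' @export
makeDumbbell <- function(nPerDomain = 25L, hingeLength = 3L,
                         interDomainContacts = 0L, spacing = 3.8,
                         cutoff = 10, seed = NULL) {
  stopifnot(nPerDomain >= 4L, hingeLength >= 1L)
  .withSeed(seed, {
    dom1 <- .packSphere(nPerDomain)
    dom2 <- .packSphere(nPerDomain)
    e1 <- which.max(dom1[, 1L])             # +x exit of domain 1
    e2 <- which.min(dom2[, 1L])             # -x entry of domain 2
    linkLen <- (hingeLength + 1) * spacing
    place <- function(sep) {
      ## put domain 2 so its entry sits 'sep' along +x from domain 1's exit
      shift <- dom1[e1, ] + c(sep, 0, 0) - dom2[e2, ]
      sweep(dom2, 2L, shift, `+`)
    }
    crossContacts <- function(d2) {
      dd <- sqrt(outer(rowSums(dom1^2), rowSums(d2^2), `+`) -
                   2 * tcrossprod(dom1, d2))
      sum(dd <= cutoff)
    }
    sep <- linkLen
    if (interDomainContacts > 0L) {
      ## draw the domains together until the contact target is met or the
      ## surfaces abut (1.5 A gap); tight targets may saturate below the
      ## request for small domains
      while (sep > 1.5 && crossContacts(place(sep)) < interDomainContacts)
        sep <- sep - 0.25
    }
    d2 <- place(sep)
    hingePts <- .arcPoints(dom1[e1, ], d2[e2, ], linkLen, hingeLength)
    pts <- rbind(dom1, hingePts, d2)
    ## chain order: domain 1, linker, domain 2
    ord <- c(seq_len(nPerDomain), nPerDomain + seq_len(hingeLength),
             nPerDomain + hingeLength + seq_len(nPerDomain))
    st <- calphaStructure(pts[ord, , drop = FALSE], chain = "A")
    if (!.isConnected(st@coords, cutoff))
      stop("dumbbell construction produced a disconnected contact graph")
    list(structure = st,
         hinge = as.integer(nPerDomain) + seq_len(hingeLength))
  })
}

#' Symmetric two-chain dimer from a monomer
#'
#' Chain B is a C2 copy of chain A (180 degree rotation about the x axis
#' through the dimer centre), translated so that at least
#' \code{interfaceContacts} inter-chain residue pairs fall within the
#' cutoff.  With \code{interfaceContacts = 0} the chains are placed out of
#' reach, giving a disconnected (two-component) contact graph.
#'
#' @param monomer a [CalphaStructure-class] (its chain labels are replaced
#'   by "A"/"B").
#' @param interfaceContacts target count of inter-chain contact pairs.
#' @param cutoff contact cutoff (Angstrom).
#' @return List with \code{structure} (two-chain [CalphaStructure-class])
#'   and \code{interface} (data.frame of realized inter-chain contact pairs,
#'   indices into chain A / chain B).
#' @export
makeDimer <- function(monomer, interfaceContacts = 10L, cutoff = 10) {
  stopifnot(is(monomer, "CalphaStructure"))
  A0 <- sweep(monomer@coords, 2L, colMeans(monomer@coords))
  n <- nrow(A0)
  c2 <- function(p) cbind(p[, 1L], -p[, 2L], -p[, 3L])  # 180 deg about x
  crossCount <- function(off) {
    A <- sweep(A0, 2L, c(0, off, 0), `+`)
    B <- c2(A)
    dd <- sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B))
    sum(dd <= cutoff)
  }
  ext <- max(abs(A0[, 2L])) + cutoff
  if (interfaceContacts == 0L) {
    off <- ext + 1
  } else {
    off <- ext
    while (off > 0.5 && crossCount(off) < interfaceContacts) off <- off - 0.25
  }
  A <- sweep(A0, 2L, c(0, off, 0), `+`)
  B <- c2(A)
  res <- monomer@residues
  st <- new("CalphaStructure",
            residues = data.frame(chain = rep(c("A", "B"), each = n),
                                  resno = rep(res$resno, 2L),
                                  insert = rep(res$insert, 2L),
                                  resname = rep(res$resname, 2L),
                                  stringsAsFactors = FALSE),
            coords = rbind(A, B), modelId = 1L)
  dd <- sqrt(outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B))
  pairs <- which(dd <= cutoff, arr.ind = TRUE)
  list(structure = st,
       interface = data.frame(a = as.integer(pairs[, 1L]),
                              b = as.integer(pairs[, 2L])))
}

#' Gaussian-perturbed conformer ensemble
#'
#' Adds i.i.d. Gaussian displacements (standard deviation \code{sigma} per
#' coordinate) to a template structure, emulating an NMR-style model
#' ensemble with shared topology.
#'
#' @param structure template [CalphaStructure-class].
#' @param sigma per-coordinate displacement standard deviation (Angstrom).
#' @param nModels number of members.
#' @param seed integer seed (bit-reproducible).
#' @return A [StructureEnsemble-class] with shared topology.
#' @export
perturbEnsemble <- function(structure, sigma = 0.3, nModels = 10L,
                            seed = NULL) {
  stopifnot(is(structure, "CalphaStructure"), sigma >= 0, nModels >= 1L)
  .withSeed(seed, {
    n <- nrow(structure@coords)
    members <- lapply(seq_len(nModels), function(m) {
      s <- structure
      s@coords <- structure@coords +
        matrix(stats::rnorm(3L * n, 0, sigma), n, 3L)
      s@modelId <- as.integer(m)
      s
    })
    structureEnsemble(members)
  })
}

#' Two-state pseudo-trajectory with known labels
#'
#' Frames are one of two conformers plus i.i.d. Gaussian coordinate noise,
#' standing in for an MD series that hops between two conformational
#' states.  The separation margin (inter-conformer RMSD over noise sigma)
#' is recorded so cluster-recovery tests can state their operating point.
#'
#' @param confA,confB the two state conformers (shared topology).
#' @param nFrames frames per state (total \code{2 * nFrames}).
#' @param noiseSigma per-coordinate Gaussian noise (Angstrom).
#' @param mixing \code{"block"} (A-frames then B-frames) or
#'   \code{"alternate"} or \code{"random"} interleaving.
#' @param seed integer seed.
#' @return List with \code{trajectory} ([Trajectory-class]), \code{labels}
#'   (integer 1/2 ground-truth state per frame) and \code{margin}
#'   (RMSD(A,B) / noiseSigma; \code{Inf} for zero noise).
#' @export
makeTwoStateTrajectory <- function(confA, confB, nFrames = 25L,
                                   noiseSigma = 0.3,
                                   mixing = c("block", "alternate", "random"),
                                   seed = NULL) {
  stopifnot(is(confA, "CalphaStructure"), is(confB, "CalphaStructure"))
  if (!identical(confA@residues[c("chain", "resno", "insert")],
                 confB@residues[c("chain", "resno", "insert")]))
    stop("the two conformers must share one residue topology")
  mixing <- match.arg(mixing)
  .withSeed(seed, {
    labels <- switch(mixing,
      block = rep(1:2, each = nFrames),
      alternate = rep_len(1:2, 2L * nFrames),
      random = sample(rep(1:2, each = nFrames)))
    n <- nrow(confA@coords)
    frames <- lapply(seq_along(labels), function(t) {
      base <- if (labels[t] == 1L) confA else confB
      f <- base
      f@coords <- base@coords +
        if (noiseSigma > 0)
          matrix(stats::rnorm(3L * n, 0, noiseSigma), n, 3L)
        else 0
      f@modelId <- as.integer(t)
      f
    })
    sep <- kabschSuperpose(confA, confB)$rmsd
    list(trajectory = trajectory(frames),
         labels = labels,
         margin = if (noiseSigma > 0) sep / noiseSigma else Inf)
  })
}

## rotate a centred packing so its farthest-from-centre residue (the pole)
## points along the unit vector tgt (Rodrigues rotation)
.poleTo <- function(p, tgt) {
  i <- which.max(rowSums(p^2))
  v <- p[i, ] / sqrt(sum(p[i, ]^2))
  ax <- c(v[2L] * tgt[3L] - v[3L] * tgt[2L],
          v[3L] * tgt[1L] - v[1L] * tgt[3L],
          v[1L] * tgt[2L] - v[2L] * tgt[1L])
  s <- sqrt(sum(ax^2)); cth <- sum(v * tgt)
  if (s < 1e-12) { if (cth > 0) return(p) else return(-p) }
  ax <- ax / s; th <- atan2(s, cth)
  K <- matrix(c(0, -ax[3L], ax[2L], ax[3L], 0, -ax[1L],
                -ax[2L], ax[1L], 0), 3L, 3L, byrow = TRUE)
  p %*% t(diag(3L) + sin(th) * K + (1 - cth) * (K %*% K))
}

#' Synthetic switch dimer in the "on" or "off" coupling geometry
#'
#' Builds a symmetric two-chain dimer of two-domain subunits emulating the
#' hinge-mediated switch architecture.  Each subunit has a "cAMP" domain
#' whose near-axis surface patch forms the dimer interface (the cAMP-site
#' analogue), an inter-domain hinge, and a "DNA" domain carrying a
#' flexible-site analogue at the hinge attachment.  In the \code{"on"}
#' geometry the hinges are tucked along the dimer (C2) axis, in direct
#' contact with the neighbouring subunit's hinge and cAMP-site patch, and
#' the DNA domain docks against that rigid core; in the \code{"off"}
#' geometry each DNA domain hangs off its own cAMP domain through a thin
#' extended linker that bows away from both domains, so the hinge couples
#' only within its subunit.  Both geometries dimerize through the
#' cAMP-domain patch, keeping the contact graph connected.
#'
#' @param state \code{"on"} (holo-like) or \code{"off"} (apo-like).
#' @param nPerDomain residues per domain (default 20).
#' @param hingeLength hinge residues per subunit (default 4).
#' @param seed integer seed.
#' @return List with \code{structure} (two-chain [CalphaStructure-class])
#'   and \code{regions}: per-subunit [RegionSpec-class] lists \code{hinge},
#'   \code{campSite}, \code{dnaSite}, \code{dnaDomain} (subunit order A, B).
#' @export
makeSwitchDimer <- function(state = c("on", "off"), nPerDomain = 20L,
                            hingeLength = 4L, seed = NULL) {
  state <- match.arg(state)
  .withSeed(seed, {
    nc <- nPerDomain; nd <- nPerDomain; L <- hingeLength
    ## cAMP domain: interface pole faces the C2 (x) axis, sitting at
    ## (0, 2, 0) so it contacts its own C2 image across the axis
    camp <- .poleTo(.packSphere(nc), c(0, -1, 0))
    rCamp <- max(sqrt(rowSums(camp^2)))
    camp <- sweep(camp, 2L, c(0, rCamp + 2, 0), `+`)
    ## near-axis patch (interface/cAMP-site analogue) = last contiguous block
    axisDist <- sqrt(camp[, 2L]^2 + camp[, 3L]^2)
    camp <- camp[order(-axisDist), , drop = FALSE]
    if (state == "on") {
      core <- cbind(seq(0, 6, length.out = L - 1L), 1.2, 0)
      dnaCentre <- c(16, 9, 0)
      hingeAnchor <- core[L - 1L, ]
    } else {
      core <- NULL
      dnaCentre <- c(26, 19, 0)
      hingeAnchor <- camp[which.min(rowSums((camp - matrix(
        dnaCentre, nc, 3L, byrow = TRUE))^2)), ]
    }
    ## DNA domain: pole faces the hinge attachment, so the flexible-site
    ## analogue is a deterministic contiguous block at the attachment
    dir <- hingeAnchor - dnaCentre
    dir <- dir / sqrt(sum(dir^2))
    dna <- sweep(.poleTo(.packSphere(nd), dir), 2L, dnaCentre, `+`)
    dnaEntry <- dna[which.max(rowSums(sweep(dna, 2L, dnaCentre) *
                                        matrix(dir, nd, 3L, byrow = TRUE))), ]
    dna <- dna[order(rowSums((dna - matrix(dnaEntry, nd, 3L,
                                           byrow = TRUE))^2)), , drop = FALSE]
    if (state == "on") {
      hingePts <- rbind(core, (core[L - 1L, ] + dnaEntry) / 2)
    } else {
      f <- seq_len(L) / (L + 1)
      hingePts <- t(vapply(f, function(x)
        (1 - x) * hingeAnchor + x * dnaEntry + c(0, 0, 7 * sin(pi * x)),
        numeric(3)))
    }
    A <- rbind(camp, hingePts, dna)
    B <- cbind(A[, 1L], -A[, 2L], -A[, 3L])    # C2 about the x axis
    n <- nrow(A)
    st <- new("CalphaStructure",
              residues = data.frame(chain = rep(c("A", "B"), each = n),
                                    resno = rep(seq_len(n), 2L),
                                    insert = "", resname = "ALA",
                                    stringsAsFactors = FALSE),
              coords = rbind(A, B), modelId = 1L)
    if (!.isConnected(st@coords, 10))
      stop("switch-dimer construction produced a disconnected contact graph")
    reg <- function(name, from, to)
      list(regionSpec(name, "A", from, to), regionSpec(name, "B", from, to))
    list(structure = st,
         regions = list(
           hinge = reg("hinge", nc + 1L, nc + L),
           campSite = reg("campSite", nc - 4L, nc),
           dnaSite = reg("dnaSite", nc + L + 1L, nc + L + 4L),
           dnaDomain = reg("dnaDomain", nc + L + 1L, n)))
  })
}
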