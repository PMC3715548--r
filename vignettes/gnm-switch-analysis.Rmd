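---
title: "Elastic-network analysis of hinge-mediated conformational switches"
author: "gnmswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network analysis of hinge-mediated conformational switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnmswitch)
```

## The model

gnmswitch studies the internal dynamics of proteins through the Gaussian
Network Model (GNM), a one-dimensional elastic network in which each residue
is reduced to its Calpha atom and residues within a cutoff distance interact
through identical harmonic springs.  The contact topology is the Kirchhoff
(connectivity) matrix $\Gamma$ — the graph Laplacian of the Calpha contact
network: $\Gamma_{ij} = -1$ when residues $i \ne j$ are within the cutoff,
$\Gamma_{ii}$ is the contact degree, and every row sums to zero.  Assuming
Gaussian fluctuations about the equilibrium structure, residue fluctuation
covariances are proportional to the Moore–Penrose pseudo-inverse of
$\Gamma$, which the package evaluates through the spectral sum over the
$N-1$ nonzero modes of the full symmetric eigendecomposition:

$$\langle \Delta R_i \cdot \Delta R_j \rangle \;\propto\;
  \sum_{k}\, \lambda_k^{-1}\, u_{ki}\, u_{kj},$$

with eigenvalues $\lambda_k$ ascending and orthonormal eigenvectors $u_k$.
A connected contact graph has exactly one zero mode (the uniform vector);
additional zero modes mean the structure is disconnected at the chosen
cutoff, which `gnmDecompose()` records and the correlation operations
refuse.

Restricting the sum to the low ("slow") end of the spectrum isolates the
most cooperative, global motions.  The package follows the common
convention of the **ten slowest modes** for correlation maps and the
**three slowest** (or the single slowest) for mode shapes; both are plain
`modeRange()` arguments, never hard-wired.

Two conventions deserve explicit statement:

* **Units.**  The physical prefactor $3 k_B T/\gamma$ multiplying every
  covariance is set to 1, i.e. raw covariances are reported in reduced
  units.  Normalized correlations
  $C_{ij} = \langle \Delta R_i \cdot \Delta R_j\rangle /
  \sqrt{\langle \Delta R_i^2\rangle \langle \Delta R_j^2\rangle} \in [-1,1]$
  are prefactor-free, and all comparisons in this package are made on
  normalized maps, so no physical constant ever enters a reported number.
  Trajectory-derived fluctuations, by contrast, are genuine
  $\mathrm{\AA}^2$.
* **Mode-restricted maps are cumulative spectral sums.**  "The average ten
  slowest modes" is computed as the $\lambda^{-1}$-weighted sum over
  nonzero modes 1–10 followed by normalization — not as the mean of ten
  individually normalized per-mode maps.  The weighted sum preserves the
  spectral weighting of the underlying covariance; per-mode averaging
  would flatten it.  Structures with fewer than ten nonzero modes use all
  available modes, and the truncation is recorded in the `ModeRange`
  label.

### Defaults

| parameter | default | units | why |
|---|---|---|---|
| contact cutoff | 10 | Å | standard Calpha GNM contact radius |
| correlation mode range | 1:10 | – | slow-mode window for cooperative motions |
| shape mode range | 1:3 | – | hinge-reading window for mode shapes |
| zero-eigenvalue tolerance | 1e-8 (relative to $\lambda_{max}$) | – | robust for integer-valued Laplacians across sizes |
| hinge window / floor quantile | 5 / 0.25 | residues / – | see hinge detection below |
| switch thresholds $\theta_1, \theta_2$ | 0.2 / 0.2 | correlation | see switch score below |
| cluster radius | 3.5 | Å RMSD | coarsest informative radius for conformer families |
| essential modes kept | 10 | – | standard essential-dynamics window |

## Hinge detection

Two complementary definitions are implemented.

**Shape minima** (`detectHingesMinima`): the shape of a mode is the vector
of squared eigenvector entries; minima of slow-mode shapes mark residues
that stay still while the regions around them move cooperatively.  A
residue qualifies when it is the minimum of a centred window (default 5
residues) *and* lies below a global floor (default the 0.25 quantile of
shape values); contiguous qualifying residues merge into segments.  The
window suppresses one-residue noise minima, the floor suppresses shallow
local minima on plateaus.  No standard numeric rule exists for either, so
both are exposed parameters with the defaults above.

**Sign crossovers** (`detectHingesCrossover`): the global hinge centres of
an individual slow mode sit where the eigenvector changes sign between
consecutive residues of the same chain; both flanking residues are
reported, entries within $10^{-9} |u|_{max}$ of zero are assigned to the
hinge segment, and crossings are never read across chain boundaries (the
sequence adjacency of the last residue of one chain and the first of the
next is meaningless — the slowest mode of any symmetric dimer flips sign
exactly there).  Because eigenvector signs are arbitrary, each mode's
largest-magnitude entry is made positive; the detected sites are invariant
to this choice, only the reporting is made deterministic.

A practical caveat found while validating on synthetic dumbbells: for a
two-domain structure joined by a thin *exposed* linker, modes 2–3 are
linker-swinging modes with large amplitude on the linker, so the 1:3
averaged shape can mask the mode-1 minimum at the hinge.  The dumbbell
validation therefore reads minima from the slowest mode alone; for compact
structures whose hinge is packed between the domains the 1:3 window is the
better default.

## Ensembles, difference maps and the switch score

For a conformer ensemble (NMR-style models, cluster best members), the
package computes one map per member and averages the **normalized** maps
elementwise.  Members can differ in overall stiffness; averaging raw
covariances would let stiff members dominate, whereas the displayed and
compared quantity is always the normalized correlation.  Averaging over
members and over region residues commutes, which the tests assert
numerically.

Two functional states are compared by aligning residues on (chain, author
residue number, insertion code) — author numbering is never rewritten —
and subtracting normalized maps on the intersection
(`differenceCorrelationMap`), giving values in $[-2, 2]$ that are exactly
antisymmetric under swapping the states; `differenceMsf` does the same for
fluctuation profiles.

The **switch score** (`switchScore`) quantifies the on/off picture of a
hinge-mediated allosteric switch in a two-subunit, two-domain protein.
Inputs are four per-subunit regions: the inter-domain hinge, the flexible
site of the effector-binding domain (the dimer-interface-proximal "cAMP
site"), a flexible site of the output ("DNA") domain, and the output
domain span.  Every reported coupling is the mean normalized correlation
over the region pair's residue product.  A subunit is labelled **on** iff
its hinge couples to the *other* subunit's hinge at $\ge \theta_1$ and to
the *other* subunit's cAMP-site analogue at $\ge \theta_2$; otherwise
**off**.  The thresholds (default 0.2, a weak-but-real correlation on the
normalized scale) are configuration-exposed, and the report always carries
all raw couplings, so conclusions never rest on the default.  On the
synthetic switch dimers below, on-state hinge–hinge couplings are
typically 0.7–0.95 and off-state ones below $-0.5$, so the label is
insensitive to any reasonable threshold.

## Trajectory analysis

`kabschSuperpose` implements the SVD-based Kabsch fit with the determinant
correction, so reflections are never applied; superposing a structure onto
itself returns exactly zero.

`radiusCluster` is a radius-controlled iterative clustering in the spirit
of the MMTSB `kclust` tool, whose exact seeding and iteration rules are
not published; the variant here is documented as an interpretation.  All
frames are superposed onto the first retained frame and distances are
coordinate RMSDs in that common frame.  Pass 1 walks frames in order,
seeding a new cluster whenever the nearest centroid is farther than the
radius; subsequent passes reassign to nearest centroids and recompute them
until stable.  The cluster count is an output; the radius is approximate
in the same sense as in `kclust` (members end up near, not strictly
within, the radius).  The algorithm consumes no randomness — results are a
pure function of the frame order — which is why it takes no seed; the
partition (though not the cluster indices) is frame-order invariant on
well-separated states, and the tests check exactly that.  The **best
member** of a cluster is the frame with least RMSD to its centroid, the
standard stand-in for a representative low-energy conformation; the
pipeline's trajectory path feeds cluster best members into the GNM,
averaging their normalized maps.

`essentialModes` performs essential-dynamics PCA: retained frames are
superposed onto the first retained frame, per-frame 3N deviations from the
time mean form the fluctuation matrix, and its population covariance is
diagonalized via SVD.  Eigenvalues are variances in $\mathrm{\AA}^2$ and
sum to the total positional variance (a tested trace identity).
`essentialCorrelations` rebuilds residue-residue covariances from the
leading modes by summing $\lambda_k\, v_k^{(i)} \cdot v_k^{(j)}$ over
3-vector blocks and normalizes as above; with all modes it reproduces the
direct covariance correlation to machine precision.  One subtlety: the
rigid-body fit itself perturbs a mathematically rank-1 fluctuation into a
few tiny extra modes.  For synthetic series that are constructed
pre-aligned, `superpose = FALSE` skips the fit; the default keeps it, as
any real conformer series needs it.

## The synthetic generators

The generators are first-class, tested code: they define the operating
conditions under which every claim in the test suite holds.

* `makeChain(n)` — smooth self-avoiding Calpha chain with exact 3.8 Å
  consecutive spacing; `curvature = 0` gives a straight chain.
* Globular domains are uniform sphere packings with a 3.6 Å minimum pair
  distance at 150 Å$^3$ per residue.  That volume — typical protein
  packing density — yields a mean contact degree of 10–14 at the 10 Å
  cutoff across domain sizes of 20–40 residues, the regime in which GNM
  spectra behave protein-like; it was fixed once from that calibration.
* `makeDumbbell(25, 3)` — two such domains joined by an extended 3-residue
  linker, the minimal architecture with a designed, recoverable hinge.
  With `interDomainContacts = 0` the domains touch only through the
  linker; positive values draw the domains together (down to a 1.5 Å
  surface gap, so very large targets can saturate below the request for
  small domains) and the linker bows out on a circular arc to keep its
  length.
* `makeDimer` — C2 copy of any monomer about the x axis, translated until
  the requested number of inter-chain contact pairs forms; zero contacts
  places the chains out of reach (a deliberate two-component network).
* `makeSwitchDimer("on"/"off")` — the switch testbed.  Both states
  dimerize through a cAMP-domain surface patch facing the C2 axis (the
  cAMP-site analogue).  In the *on* geometry the hinges of both subunits
  run along the dimer axis, in contact with the partner hinge and the
  partner's cAMP-site patch, and the DNA domain docks against that rigid
  core — so the slow modes see one stiff centre with peripheral domains
  coupled through it.  In the *off* geometry each DNA domain hangs off
  its own cAMP domain through a thin linker bowed away from both domains,
  so the hinge couples only intra-subunit and the slow spectrum is
  dominated by independent domain swinging and anti-phase subunit motion.
  Across seeds this yields hinge–hinge couplings of about $+0.8$ (on)
  versus $-0.6$ (off) and a consistently negative off-minus-on
  (apo-minus-holo) difference in the cAMP-site x DNA-site block,
  reproducing the sign structure expected when effector binding locks the
  hinge and couples the two domains.
* `perturbEnsemble` (i.i.d. Gaussian coordinate noise; an NMR-model-like
  ensemble) and `makeTwoStateTrajectory` (two conformers plus noise with
  known labels and a recorded separation margin) stand in for model
  ensembles and state-hopping MD series.

Every generator consumes a single explicit seed and restores the caller's
RNG state, so reruns are bit-identical.

What the generators do **not** emulate: real secondary structure and its
anisotropic contact topology, sequence-specific interactions, solvent and
entropic effects, gradual conformational drift (frames hop between two
states instead), and the coil-to-helix transitions that accompany real
allosteric switching.  A green suite therefore shows that the machinery is
mathematically correct and that the designed coupling architectures are
detected — not that any particular real protein behaves this way.

## Numerical choices and edge cases

* Eigenvalues below $10^{-8} \lambda_{max}$ count as zero (with a floor
  guarding the edgeless all-zero spectrum).  Correlations and shapes
  require exactly one zero mode.
* Normalized values are clamped into $[-1,1]$ and the diagonal set to 1
  exactly, so bound checks are exact rather than tolerance-laden.
* Symmetric structures routinely produce exactly degenerate eigenvalues.
  A mode range that cuts through a degenerate group is basis-dependent
  (the eigensolver picks an arbitrary basis inside the group); full-range
  maps are always basis-independent.  The symmetry tests use full ranges
  for this reason, and users comparing slow-mode maps of symmetric
  structures should be aware of it.
* Mode ranges reaching past the available nonzero modes truncate and
  record the truncation; ranges starting past them are errors.
* Slow-mode-restricted maps respond more strongly to coordinate
  perturbation than full-spectrum maps (the retained subspace rotates):
  under 0.3 Å Gaussian noise a full-range dumbbell map is stable to
  better than 0.05 elementwise, while the 1:10 map is stable on average
  but not elementwise.

## Problem sizes

The suite and the acceptance script run entirely on synthetic structures
of 18–106 residues, ensembles of up to 10 members, and trajectories of
30–40 frames (plus one 2000-frame noise series for the MSF expectation
check) — sizes chosen so the whole suite completes in seconds while every
property is exercised at full strength.  Real-data workflows (multi-model
NMR ensembles, crystal structures, MD-derived conformer series as
multi-model PDB) use the identical code paths through `readPdbModels()`
and the pipeline.

## Known limitations

* The GNM is isotropic and harmonic: no directionality of motions
  (use an anisotropic model for that) and no anharmonic transitions.
* Ligands are excluded from the network by default
  (`includeHetero = FALSE` in `readPdbModels()`); whether to include
  bound-ligand heavy atoms as extra nodes is a modelling decision the
  user must make explicitly.
* Radius clustering depends on frame order through its seeding pass
  (partitions on well-separated states do not, but borderline
  assignments can).
* Region-coupling scores are descriptive statistics of one map; no
  statistical significance is attached to differences between states.
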