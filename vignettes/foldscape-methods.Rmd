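---
title: "Dissecting early helical misfolding with HLDA collective variables and well-tempered PT-metadynamics"
author: "foldscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foldscape methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small helical proteins that misfold into amyloid — the motivating system is
the 76-residue N-terminal fragment of serum amyloid A, a three-helix bundle —
pass through transient, partially folded intermediates that are hard to
observe directly. The computational strategy this package implements has four
stages: (1) compress the conformational state into a small set of physically
motivated descriptors; (2) learn a one-dimensional collective variable (CV)
that separates the folded and unfolded ensembles; (3) bias enhanced-sampling
simulations along that CV to obtain converged free-energy surfaces (FES);
(4) characterize the metastable basins and the lowest-saddle pathways
connecting them. All-atom molecular dynamics is out of scope here; every
stage instead runs against synthetic generators with known ground truth, so
the machinery is tested end to end at desk scale.

## Descriptors

Six descriptors summarize a backbone configuration:

* `d1`–`d3`: the alpha-helical content of helices I (residues 1–27),
  II (32–47) and III (50–69). For every contiguous six-residue window inside
  a helix range, the optimal-superposition RMSD of its backbone atoms
  (N, CA, C, O) against a canonical six-residue alpha template is mapped
  through a rational switching function and summed, so a fully helical range
  of length $L$ scores about $L-5$ and an extended chain scores near zero.
* `d4`–`d6`: the distances between the CA centroids of helix pairs I–II,
  I–III and II–III, each mapped through the switching function
  $s(r) = \frac{1 - (r/r_0)^n}{1 - (r/r_0)^m}$ with $n=6$, $m=12$ (the
  removable singularity at $r = r_0$ evaluates to $n/m$).

Choices that were genuinely open and how they were fixed:

* **Template geometry.** The canonical helix template is pinned at a rise of
  0.15 nm and a twist of 100 degrees per residue. With ideal peptide-plane
  internal coordinates these two screw parameters cannot be dialled
  independently by backbone dihedrals alone, so the builder derives
  cylindrical atom offsets from an ideal-geometry chain in the alpha region
  and then imposes the requested screw advance exactly; the emergent CA–CA
  distance is 0.384 nm and the backbone dihedrals sit within two degrees of
  the construction's own canonical values, uniformly along the chain.
* **RMSD-to-count switching.** $r_0 = 0.08$ nm with exponents (8, 12) — the
  convention of the common biasing libraries — exposed as a parameter.
* **Contact-map calibration.** No $r_0$ for the helix-distance contacts is
  prescribed anywhere, so each pair's $r_0$ defaults to its distance in the
  folded reference structure: folded contact descriptors then sit at
  $n/m = 0.5$, where the switching function is steepest and most
  informative.
* **Pair order.** `d4` is I–II; the assignment `d5` = I–III, `d6` = II–III is
  a documented convention and configurable.
* **Centroids** use unweighted CA atoms: the simplest defensible reading of
  "helix centers".

All descriptors are invariant under global rotations and translations
(tested to 1e-9).

## The HLDA collective variable

Given labelled folded (A) and unfolded (B) descriptor ensembles with means
$\mu_A, \mu_B$ and covariances $\Sigma_A, \Sigma_B$, harmonic linear
discriminant analysis maximizes the Rayleigh quotient
$J(W) = \frac{W^T S_b W}{W^T S_w W}$ with the between-class scatter
$S_b = (\mu_A - \mu_B)(\mu_A - \mu_B)^T$ and — the distinguishing choice —
the *harmonic* within-class scatter
$S_w = (\Sigma_A^{-1} + \Sigma_B^{-1})^{-1}$, which favours directions along
which *either* basin is narrow, exactly what a biasing coordinate needs. The
optimum is the leading eigenvector of $S_w^{-1} S_b$; because $S_b$ has rank
one this reduces to the closed form $W^* \propto S_w^{-1}(\mu_A - \mu_B)$
with leading eigenvalue $(\mu_A-\mu_B)^T S_w^{-1} (\mu_A-\mu_B)$ and all
other eigenvalues numerically zero. `hldaDirection()` solves the symmetric
whitened eigenproblem and the tests cross-check it against the closed form
(cosine ≥ 0.9999 over random instances); parameter recovery from sampled
planted ensembles reaches |cos| ≥ 0.99 at 5000 samples per class.

Numerical choices: a ridge of $10^{-8} \times \overline{\mathrm{diag}}$ is
added before inversion because frozen descriptors make class covariances
singular; the eigenvector sign is fixed so the largest-magnitude weight is
negative (the published convention for this CV); weights are unit-norm;
covariances use the unbiased $(n-1)$ estimator. Descriptors are not
standardized before the fit — the harmonic scatter already accounts for
scale — matching the printed weight pattern in which the contact descriptors
carry most of the weight.

## Well-tempered metadynamics with parallel tempering

The sampling engine is an overdamped Langevin (Euler–Maruyama) propagator on
analytic toy potentials, written in C++ for speed:
$x \leftarrow x - (\Delta t/\gamma_f)\nabla(U + V_{bias}) +
\sqrt{2 k_B T \Delta t/\gamma_f}\,\xi$. Its stationary statistics are tested
against closed forms (harmonic variance $k_BT/k$ within 5%; double-well
Boltzmann population ratios within Monte-Carlo error). Units are nm, kJ/mol,
K and ps throughout; barrier heights are reported in RT.

Biasing follows the well-tempered protocol with the deposition defaults used
throughout the analyses: Gaussian height 3.0 kJ/mol, width 0.02 (CV units),
bias factor $\gamma = 8$, deposition every 100 steps. The deposition width
only makes sense relative to the CV's basin scale — a discriminant CV's
basins are a few hundredths of a unit wide — so the toy potentials place
their wells on that same scale (the 1D double well has its minima at
$\pm L$ with $L = 0.15$ nm; the 2D double funnel uses well widths of
0.045 nm). When the wells are instead made an order of magnitude wider than
$\sigma$, the early full-height deposits leave $\sigma$-scale roughness of
order 1 $k_BT$ that the tempered (ever-shrinking) late deposits can no
longer heal — the estimate stays biased at any desk-scale run length. The
friction is raised accordingly (50/ps for the double well, 200/ps for the
funnel) so the Euler–Maruyama step resolves the stiffer well curvature. Heights decay as
$w\,e^{-V(s)/k_B\Delta T}$ with $\Delta T = (\gamma - 1)T$, and the
converged FES estimate is $F(s) = -\frac{\gamma}{\gamma-1} V(s)$, shifted to
zero at its minimum. The bias is accumulated on a grid (energy and force
nodes, Gaussians truncated at $6\sigma$, relative error < 1e-7) so the
per-step cost is O(1); depositions whose centre falls outside the grid are
skipped rather than clamped, because clamping piles Gaussians into an
artificial wall at the edge. Convergence is diagnosed by the superposition
of time-truncated FES snapshots becoming static (`fesTimeSeries`), and by CV
diffusion summaries (a biased run crosses the CV midpoint far more often
than an unbiased one).

Parallel tempering uses a geometric temperature ladder (endpoints exact,
constant ratio — chosen to target uniform acceptance; the reference ladder
in the field spans 300–450 K over 79 replicas, the toy default uses 4).
Exchanges are attempted between adjacent pairs with alternating parity every
`exchangeStride` steps, with acceptance
$\min(1, e^{\Delta})$, $\Delta = (\beta_i-\beta_j)(U_i-U_j) +
\beta_i[V_i(s_i)-V_i(s_j)] + \beta_j[V_j(s_j)-V_j(s_i)]$; configurations
swap while biases stay attached to their temperature slot (the ensemble the
FES is reported in). `exchangeStride` must be a multiple of the deposition
pace and of the recording stride, so segment boundaries never skip or double
a deposition — the one coupling between the two clocks, resolved explicitly
rather than silently. Determinism: one global seed is fanned out to
per-replica, per-segment streams by a counter-mixing scheme (`deriveSeed`),
so multi-replica runs are bit-reproducible.

## Free-energy surfaces and reweighting

`weightedFES` bins CV samples on a uniform grid (default 64 bins over the
sample range padded 5%; out-of-range samples are clipped to edge bins with a
reported count) and Boltzmann-inverts the weighted histogram; empty bins are
masked, written as an explicit sentinel, never $-\infty$. Frame weights for
projecting a biased run onto unbiased CVs use the final-bias estimator
$w_i \propto e^{+V(s_i)/k_BT}$ (max-shifted before exponentiation). The
time-dependent-offset estimator is deliberately not used: the convergence
argument here is precisely that the late-time bias is static, and the
burn-in during which it is not is discarded.

In the shipped end-to-end study the 2D surface over $(x, y)$ is assembled as
$F(x, y) = F_x(x) - k_BT \ln p_b(y \mid x)$: only $x$ is biased, so the
conditional of $y$ given $x$ in the biased run is already unbiased, and the
$x$-marginal comes from the converged bias, bin-averaged to integrate out
the $\sigma$-scale granularity of the deposited Gaussians. This factorized
estimator avoids the $e^{V/k_BT}$ weight spread of plain histogram
reweighting — with the narrow deposition Gaussians of the standard protocol,
that spread spans several orders of magnitude and would drown the shallower
basin at desk-scale run lengths. Plain reweighting remains available and
tested as `reweightFrames` + `weightedFES`.

## Basins and minimum-energy paths

`findMinima` locates strict local minima under 8-connectivity (plateaus
collapse to their lowest lexicographic node) and prunes shallow basins by
topological persistence: a basin whose depth below its lowest escape saddle
is less than `minDepth` (default 0.5 RT — below it, grid-noise dimples
survive) merges into its neighbour. Sparsely sampled high-free-energy bins
can still found statistical minima, so analyses may additionally cap
reported basins at `maxEnergy` (5 RT in the shipped study: metastable states
are thermally accessible by definition). `minimumEnergyPath` finds the
minimax path — the route minimizing the highest free energy encountered,
which is what "minimum energy pathway" means between metastable states —
in two stages: the minimax level by thresholded connectivity, then a
Dijkstra pass minimizing the energy sum for deterministic tie-breaking. On
grids small enough for exhaustive simple-path enumeration the path maximum
agrees exactly. Barriers are reported in RT per leg (max on the sub-path
minus the earlier basin), and frames are assigned to basins by Chebyshev
proximity below the basin's escape saddle.

## Structural characterization

Secondary structure uses a dihedral-window rule — helical when
$(\phi, \psi) \in [-100, -30] \times [-80, -5]$ degrees in a run of at least
4 residues — rather than hydrogen-bond (DSSP) logic, because the synthetic
backbones carry idealized geometry without reliable H-bond detail; window
and run length are configurable. Helicity is reported per helix relative to
the folded reference. SASA is Shrake–Rupley spherical quadrature
(golden-spiral points, probe 0.14 nm, default 960 points per atom; doubling
the quadrature changes helix-fixture totals by < 0.5%) with a pinned
van-der-Waals radius table (C 0.170, N 0.155, O 0.152 nm); subtotals are
reported for all residues, a standard apolar set (ALA, VAL, LEU, ILE, MET,
PHE, TRP, CYS) and the aggregation-prone region, residues 42–48, taken as a
given input.

## What the synthetic generators emulate — and what they do not

* `buildHelixBundle` packs three ideal helices (axis separation 0.9 nm) with
  coil loops and a C-terminal tail into a 76-residue chain: a geometric
  stand-in for the folded bundle with correct connectivity, helicity and
  burial patterns, but no side chains, no energetics and backbone-only SASA.
* `meltHelix` rebuilds a C-terminal fraction at extended dihedrals
  $(\phi, \psi) = (-135, 135)$ degrees — a reproducible "unfolded" reference
  analogous to a high-temperature unfolding run. Melting 27/76 of the chain
  removes exactly helix III plus the tail, giving the sequential-melting
  fixture; `aprExposureFixture` displaces helix II outward by 0.15 nm
  (re-bridging its loops), raising APR SASA while total SASA moves < 10% —
  localized core exposure rather than wholesale unfolding.
* `sampleTwoStateDescriptors` draws labelled Gaussian descriptor ensembles
  with planted means and covariances — the ground truth for discriminant
  recovery; real descriptor distributions are bounded and skewed, which the
  Gaussian model ignores.
* The toy potentials (tilted double well with quadrature-calibrated
  $\Delta F$; a double-funnel 2D surface) stand in for the molecular
  force field. Passing tests therefore demonstrate the correctness of the
  *machinery* — CV construction, biasing, reweighting, path analysis — not
  the physics of any real protein.

## The shipped end-to-end study

`runPipeline(defaultPipelineConfig())` runs seven file-coupled stages:
generate (folded/melted bundle ensembles, 25 jittered frames each, noise
0.015 nm), descriptors, HLDA fit, PT-metadynamics on the double-funnel
potential (4 replicas, 300–450 K, 3e6 steps of 2 fs per replica,
exchanges every 2000 steps), FES construction (28 bins per axis, burn-in
half discarded), basin/path analysis (persistence pruning at 0.75 RT, basin
cap 5 RT), and per-basin structural reports plus a temperature
secondary-structure profile. Problem sizes were chosen so the whole study
runs in well under a minute on one core while the planted two-basin
landscape is recovered with its forward barrier out of the deeper
(native-like) basin rate-limiting. Stages communicate only through files, so `resume = TRUE`
re-runs are bit-identical, and the manifest records parameters, seeds and
checksums.

## Known limitations

* The final-bias FES estimator ignores the time-dependent offset; it is
  only valid once the bias is quasi-static, hence the discarded burn-in.
* No multi-temperature WHAM: surfaces use the lowest-temperature replica.
* The Langevin integrator is first-order (Euler–Maruyama); time-step bias
  is controlled by the equipartition test, not eliminated.
* Backbone-only structures make absolute SASA values smaller than all-atom
  results; only comparisons between fixtures are meaningful.
* Basin labels are grid-dependent; paths are unique only up to minimax
  ties, which are broken deterministically.
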