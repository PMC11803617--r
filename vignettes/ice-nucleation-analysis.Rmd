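---
title: "Analyzing ice nucleation near an antifreeze protein surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing ice nucleation near an antifreeze protein surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpice)
```

## The problem

Hyperactive insect antifreeze proteins carry a flat ice-binding surface
(IBS): two ordered rows of threonine residues whose hydroxyl oxygens form a
two-dimensional array commensurate with the basal plane of ice Ih. In
atomistic simulations of supercooled water near such a surface, nucleation
proceeds through recognizable stages — a one-dimensional chain of "channel
water" anchored in the groove between the threonine rows, a two-dimensional
ice-like layer templated by the hydroxyl array, and finally a
three-dimensional nucleus that either grows or redissolves depending on
whether it has passed the critical size.

`afpice` implements the full observable chain for this kind of study:
structural classification of water into ice polymorphs, nucleus tracking,
seeding-based critical-size estimation, hydrogen-bond kinetics, interfacial
order profiles, IBS lattice-match geometry, and a classical-nucleation-theory
(CNT) barrier model with a line-tension term. Every analysis stage can be
exercised on synthetic configurations built by the package itself, so the
whole pipeline is testable without running molecular dynamics.

## Ice classification: q6 and staggered/eclipsed bonds

For each water oxygen we collect the O–O neighbor directions within a cutoff
and form the Steinhardt bond-order vectors
$q_{\ell m}(i) = \langle Y_{\ell m}(\hat r_{ij})\rangle_j$. The rotationally
invariant scalar
$q_6 = \sqrt{\tfrac{4\pi}{13}\sum_m |q_{6m}|^2}$
measures local orientational coherence (an ideal FCC shell gives
$q_6 \approx 0.574$; the value for an interior molecule of a proton-disordered
ice lattice is higher, and disordered liquid much lower).

Polymorph labels come from per-bond correlations of the $\ell = 3$ vectors,
$$c_{ij} = \frac{\mathrm{Re}\sum_m q_{3m}(i)\, q^*_{3m}(j)}
                {|q_3(i)|\,|q_3(j)|},$$
which separate *staggered* ($c_{ij} \le -0.8$) from *eclipsed*
($-0.35 \le c_{ij} \le 0.25$) hydrogen bonds. A molecule with exactly four
neighbor bonds is labeled cubic ice (four staggered), hexagonal ice (three
staggered, one eclipsed), interfacial (at least two classified bonds but
neither pattern), or liquid. Molecules with fewer than four neighbors can
never be hexagonal or cubic.

The thresholds are a design decision: they are validated by a synthetic-truth
confusion test (generated proton-disordered Ih and Ic lattices classify 100%
correctly on interior molecules for arbitrary disorder seeds, and random
liquid boxes produce below 1% hexagonal-plus-cubic false positives), not
fitted to any particular trajectory. The neighbor and cluster-linking cutoff
defaults to 0.35 nm, the first minimum of the water O–O coordination shell.

The largest nucleus is the biggest connected component over hexagonal plus
cubic molecules only — interfacial molecules are deliberately excluded, so
nucleus sizes are conservative. A consequence worth knowing: a small
crystalline cluster freshly embedded in disordered liquid reports only its
interior core as nucleus members, because the cluster surface classifies as
interfacial. Ties between equal-size components are broken by the smallest
member molecule id so results are deterministic.

## Synthetic reference systems

The generators produce every input class the analysis assumes:

* **Ice lattices** (`build_ice_lattice`): wurtzite (Ih) or diamond-cubic (Ic)
  oxygen sublattices at an exact nearest-neighbor distance
  $d_{OO}$ (default 0.275 nm), with hydrogens assigned along O–O links under
  the Bernal–Fowler ice rules (two donated hydrogens per oxygen, one hydrogen
  per link). Proton disorder is randomized by orienting the 4-regular bond
  graph at random and repairing over-donors by directed path reversal. The
  default $d_{OO}$ is chosen so the derived lattice constants round to the
  basal-plane ice values 0.45 nm ($\sqrt{8/3}\,d_{OO}$, the in-row repeat)
  and 0.73 nm ($\tfrac{8}{3}d_{OO}$, the bilayer repeat): the literature
  quotes lattice constants, not $d_{OO}$.
* **Liquid boxes** (`build_liquid_box`): random sequential insertion with a
  hard minimum O–O distance (0.26 nm) and isotropic orientations. This is a
  disordered geometric reference, not thermalized water — it has no
  realistic radial distribution function beyond the exclusion hole, which is
  exactly what the false-positive test needs and nothing more.
* **Embedded nuclei** (`embed_nucleus`): a compact cluster carved from an
  ideal lattice, inserted into a liquid box with overlap removal.
* **Channel-water chains** (`build_cw_chain`): collinear waters at the
  ice in-row repeat with dipoles perpendicular to, aligned with, or isotropic
  about the chain axis. Water geometry is rigid (104.5°, O–H 0.09572 nm);
  the chain is a geometric idealization of groove-anchored channel water,
  not a reconstruction of any particular protein groove.
* **Nucleus-size series** (`simulate_nucleus_series`): Euler–Maruyama paths
  of $dn = k(n - n_c)\,dt + \sigma\,dW$ reflected at zero. The linear drift
  reproduces the one property the seeding method uses — the sign change of
  $d\langle n\rangle/dt$ at the critical size — with defaults $k =
  0.1\,\mathrm{ns}^{-1}$, $\sigma = 2$, 10 ns duration. The drift gain is
  kept small deliberately: the linearized dynamics amplify deviations by
  $e^{k t}$, and large $k\,t$ products push paths onto the reflecting
  boundary, biasing ensemble means upward.
* **Bond-event series** (`simulate_bond_events`): two-state Markov chains
  sampled with exact transition probabilities; with zero reformation rate the
  bonded-state survival is exactly $e^{-\lambda t}$, giving closed-form
  expectations for the correlation machinery.

All generators are deterministic under a fixed seed.

## Hydrogen-bond kinetics

Bonds are detected geometrically: donor–acceptor O–O distance at most
0.35 nm and H–donor–acceptor angle at most 30°, the common water convention
(both config-exposed, since simulation studies rarely print their criterion).
The intermittent correlation
$C_H(t) = \langle h(0)h(t)\rangle / \langle h(0)\rangle$ is computed over the
pairs bonded at a window start; reformation counts again, so $C_H$ need not
be monotone. Its window-normalized integral
$\Gamma_{HB} = \tfrac{1}{T_w}\int_0^{T_w} C_H\,dt$ (trapezoid on the native
lag grid; no quadrature assumption beyond the sampled points) is the
probability that an initially bonded pair remains bonded within the window.
For the Poisson fixture with $\lambda T_w = 0.214$ the closed form
$(1 - e^{-x})/x$ gives 0.900 — long-lived interfacial hydrogen bonds sit in
exactly this regime. Residence correlation $C_R(t)$ uses the absorbing
definition (departure ends the molecule's contribution), hence is monotone
nonincreasing; the trough region is an axis-aligned box, the simplest
reproducible region definition.

## Order profiles

Density maps and distributions are plain histograms with conservation checks
(0.02 nm spatial bins, 2° angular bins by default). Peak positions in 1D
profiles are found on a Gaussian-smoothed histogram (kernel width one bin,
prominence threshold 5% of the maximum) and then refined to the mean of the
raw positions within the peak's bin window, so peak spacing is not quantized
to the bin grid. Dipoles use the H-bisector of the three real atoms,
independent of any virtual sites of the water model. Layers above a surface
are slabs of 0.35 nm (one molecular layer, three layers by default) starting
at a user-supplied surface height — the IBS plane is structure-specific, so
the package never guesses it.

## IBS lattice match

The hydroxyl-array spacings are defined as: $a_{OH}$, the mean cross-row
O–O distance within a helix loop (each short-side threonine paired with the
long-side threonine two residues downstream — the T-x-T motif); and
$b_{OH}$, the mean along-row adjacent-loop O–O distance. The source
literature describes this pairing only in prose, so the pairing algebra is
stated here explicitly and implemented in `ibs_layout()`. Deviations are
reported against the ice constants 0.73/0.45 nm. Dihedral angles
(N–Cα–Cβ–O_hydroxyl) are mapped to $[0°, 360°)$ because hydroxyl-flip
excursions in mutant studies exceed the fold of symmetric ranges; degenerate
colinear geometries are flagged `NA` and excluded from histograms.

`build_synthetic_ibs()` is a labelled synthetic stand-in: an exact (or
jittered) grid at the published spacings with minimal backbone atoms. It
validates the measurement operations; structural conclusions require a real
structure file (the reader accepts PDB with first-model/first-altloc
handling).

## Seeding estimate of the critical size

Groups of replicate nucleus-size series, keyed by initial size $n_0$, each
receive a verdict from the sign of the group growth rate. The group slope is
the mean of per-replicate OLS slopes, and its standard error comes from the
between-replicate scatter: the residuals of any single stochastic
nucleus-size curve are strongly autocorrelated, so the nominal OLS standard
error of the ensemble-mean curve is anti-conservative and would turn
near-critical groups into random significant verdicts. A group grows
(shrinks) when its slope exceeds two standard errors above (below) zero;
otherwise it is indeterminate. The critical size is bracketed between the
largest shrinking and smallest growing $n_0$, with the midpoint as point
estimate — mirroring how discrete seed sizes are read out in practice. The
analysis window drops the first 10% of the common time range as transient.
Parameter-recovery tests (true $n_c \in \{20, 38, 80\}$, seed groups at
±30%, 20 replicates) require the estimate within ±15% of truth in at least
90% of repeated experiments.

## CNT barriers with line tension

The free energy of an $n$-molecule nucleus is parameterized per molecule:
$$\Delta G_{hom}(n) = -n\,\Delta\mu + \gamma^N n^{2/3}, \qquad
  \Delta G_{het}(n) = -n\,\Delta\mu + \Delta\gamma^N n^{2/3}
  + 0.6022\,\tau\, l^N n^{e},$$
with $\Delta\mu = \mu_{wat} - \mu_{ice}$ in kJ/mol per molecule, surface
coefficients in kJ/mol multiplying $n^{2/3}$, line tension $\tau$ in pN
(default 5, temperature independent), contact-line coefficient $l^N$ in nm,
and $1\,\mathrm{pN\,nm} = 0.6022$ kJ/mol. The per-molecule form was chosen
over explicit spherical-cap geometry because published barrier equations mix
per-area and per-molecule conventions; this form covers both readings and is
directly oracle-checkable. The contact-line exponent defaults to $e = 1/3$
(cap-like nucleus: line length grows like the radius) with $e = 1/2$
(disk-like) selectable.

The homogeneous barrier has the closed form $n^* = (2\gamma^N/3\Delta\mu)^3$
and $\Delta G^* = n^*\Delta\mu/2$; the heterogeneous curve is maximized
numerically and both are cross-checked against brute-force integer
evaluation. Because $\gamma^N$ for a given water model is usually not
reported, `calibrate_gamma_hom()` solves it from a target $(n^*, \Delta\mu)$
pair. The potency factor $f(T) = \Delta G^*_{het}/\Delta G^*_{hom}$ is
tabulated over a thermodynamic table and summarized with a descriptive
degree-2 polynomial fit.

The shipped table (`inst/extdata/table1.tsv`) spans 240–255 K; its derived
driving force decreases from 0.87 to 0.38 kJ/mol toward melting, so barriers
and critical sizes grow with temperature — checked as a property, not
assumed. One column of the source table is unlabeled in the original; it is
parsed and carried through but used by nothing.

## Numerical conventions and degenerate inputs

Units are nm, ns, kJ/mol, degrees, Kelvin throughout; PDB/XYZ Ångström input
is converted at read. Minimum-image distances support full 3D periodicity or
xy-only (slab) periodicity. Neighbor finding uses the single nearest image,
so generated cells must be at least 2.5 $d_{OO}$ per edge (enforced).
Zero-neighbor molecules have undefined $q_6$ (`NA`), empty label sets give a
nucleus of size zero, colinear dihedrals give `NA`, an empty correlation
window or a windowless curve is an error rather than a silent zero. Pipeline
outputs are byte-reproducible given a fixed seed and configuration.

## Problem sizes

The test and acceptance workloads use lattices of 64–192 molecules, liquid
boxes of 100 molecules, 10,000 bond pairs over 20 ns, and seeding ensembles
of 20 replicates × 4 seed sizes × 10 ns at 0.05 ns resolution — sizes at
which every property is sharp while the whole suite runs in well under a
minute per module.

## Limitations

The package analyzes configurations; it does not generate physics. The
synthetic systems carry no energetics, no thermalization and no water-model
virtual sites, so passing tests demonstrate correctness of the *measurement
operations* on known ground truth — they do not validate any force field,
nor reproduce quantities that depend on real microsecond trajectories
(critical sizes of a specific water model, mutant orderings, convergence
times). Binary trajectory formats (XTC/TRR/DCD) are not read; multi-frame
analysis expects concatenated text formats. The classifier implements the
staggered/eclipsed family of algorithms only — no clathrate cages, no
high-pressure polymorphs.
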