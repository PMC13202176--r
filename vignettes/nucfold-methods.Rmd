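---
title: "The nucfold chromatin model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nucfold chromatin model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucfold)
```

nucfold is a physics-based, nucleosome-resolution coarse-grained model of
chromatin. Its purpose is to ask how much of the 3D organization of a gene
locus — sub-TAD compartments, packing domains, nucleosome clutches,
enhancer–promoter contacts — follows from epigenetic-dependent
nucleosome–nucleosome interactions alone, without loop extrusion. This
vignette documents the model, its parameters and units, the calibration
protocols behind the shipped defaults, the synthetic-data generator, and the
design decisions taken where more than one reasonable choice existed.

## The model

Chromatin is represented by point beads of a single diameter
$\sigma = 35\,\mathrm{\AA}$ (the length of one B-DNA helical turn):

* one bead per 10.5 bp of DNA — 14 beads for the canonical 147-bp wrap;
* one bead per histone protein — 8 per nucleosome core;
* two beads for linker histone H1 (globular domain + C-terminal tail).

A nucleosome is built by placing the wrapped DNA beads on a superhelix of
radius 40 Å and pitch 25 Å with a fixed 35 Å contour spacing between
consecutive beads, and the 8 histone beads on a coaxial superhelix of radius
18 Å with the same pitch, evenly spaced over the same angular span. With
these three constraints the 14-bead wrap spans $13 \times 35$ Å of arc
$\approx 1.8$ superhelical turns; the turn count is the derived quantity
(radius, pitch and bead spacing are the stated ones and the triple is
overdetermined). When H1 is bound, its globular bead sits on the dyad axis
70 Å from the nucleosome center and the tail bead one diameter further out
(105 Å).

Beads belong to one of 20 types grouped in 5 interaction classes: linker
DNA, canonical nucleosome, acetylated nucleosome, acetylated nucleosome
associated with BRD4, and linker histone. Linker-DNA beads carry $-7.35e$,
each H1 bead $+5e$ (charges chosen to absorb counter-ion condensation into a
Debye–Hückel description); nucleosome-core beads are neutral. Entry/exit DNA
beads of BRD4-associated nucleosomes reuse the acetylated entry/exit type:
breathing is an acetylation-level property, while the BRD4 enhancement is a
core–core nonbonded effect.

### Bonded terms

* **Harmonic bonds** ($U = k (r - r_0)^2$, $k = 10$ kcal/mol/Å²) join every
  intra-nucleosome bead pair closer than 38 Å in the reference geometry, and
  consecutive DNA-chain beads at 35 Å. The dense sub-38-Å network keeps the
  core near-rigid; $k$ is not a sensitive parameter and is configurable.
* **Morse bonds** replace the harmonic attachment of the first and last
  nucleosomal DNA beads (entry/exit DNA): each terminus keeps its chain bond
  to the adjacent DNA bead plus a single Morse bond
  ($U = D_e (1 - e^{-a(r - r_0)})^2$) to its nearest histone bead, and its
  remaining sub-38-Å reference pairs are excluded from all interactions so
  that the terminus can genuinely detach. This one-bond-per-terminus
  topology is what makes spontaneous nucleosome breathing a clean two-state
  process (4 Morse bonds in a dinucleosome).
* **DNA bending angles** ($U = K_\theta (\theta - \pi)^2$) act on every
  consecutive DNA-chain triplet centred on a linker or entry/exit bead;
  interior wrapped DNA needs no angle terms (the bond network holds it).
* **H1 anchoring**: the globular bead bonds to the dyad DNA beads within
  38 Å, with angle terms keeping the tail pointing radially outward.

### Nonbonded terms

Lennard–Jones with $\sigma = 35$ Å, truncated and shifted at $3\sigma$, with
class-pair strengths:

| pair | $\varepsilon$ (kcal/mol) |
|---|---|
| canonical–canonical | $\varepsilon_0 = 0.115$ |
| acetyl–acetyl | $\varepsilon_{ac} = 0.06$ |
| canonical–acetyl (and canonical–BRD4) | $\varepsilon_h = \sqrt{\varepsilon_0\,\varepsilon_{ac}} \approx 0.083$ |
| BRD4–acetyl and BRD4–BRD4 | $\varepsilon_B = 0.23$ |
| H1–linker DNA | $\varepsilon_{H1} = 0.50$ |
| everything else | $\varepsilon_w = 0.03$ (near excluded volume) |

BRD4 bridging is acetyl-specific: a BRD4-associated nucleosome interacts
with *any* acetylated nucleosome at $\varepsilon_B$, but with canonical
nucleosomes only at $\varepsilon_h$. Charged pairs additionally interact via
a Debye–Hückel potential with relative dielectric 78, screening length from
the salt concentration (7.9 Å at 150 mM, 300 K), truncated and shifted at 5
Debye lengths. Directly bonded (1–2) pairs are excluded from nonbonded
interactions; angle (1–3) pairs are not. $\varepsilon_B$ and
$\varepsilon_{H1}$ are not printed constants of the underlying description;
they are chosen so that BRD4 association rescues the condensation of
acetylated fibers and H1 compacts 12-mer fibers, and both are configurable
through `pair_matrix()`.

The model deliberately omits DNA torsional elasticity and
sequence-dependent flexibility; consequences include the absence of any
10-bp periodicity in compaction versus linker length.

## Dynamics

Langevin dynamics with the BAOAB splitting (accurate configurational
sampling at large steps), unit mass per bead, temperature 300 K. Internal
units are Å / kcal/mol / unit mass, so the internal time unit is
$t^* = \sqrt{m \mathrm{\AA}^2 / (\mathrm{kcal/mol})}$. The default timestep
is $0.02\,t^*$, comfortably below the stability limit of the stiffest bond
($\omega\,\mathrm{d}t \approx 0.13$). Physical time is metadata: one
timestep corresponds to 1.4 ns (a diffusion-based mapping), and the 140-ns
damping factor therefore equals 100 timesteps of internal time. The mapping
labels trajectory times and scales the damping input; it never changes the
equations of motion.

Every bead draws its thermal noise from its own counter-based random
substream derived from (seed, bead index), so trajectories are
bit-reproducible and independent of any parallel scheduling. Nonbonded
interactions use a cell-binned Verlet list with a $0.3\sigma$ skin rebuilt
on a displacement criterion. The spherical boundary is a purely repulsive
(WCA) wall; the slab boundary applies periodic images in all directions.
Soft-core relaxation caps pair forces below $0.8\sigma$ during a thermal
stage and finishes with a zero-temperature damped quench under the full
potential; if the input already has no clashes the thermal stage is skipped,
which makes relaxation a near-fixed-point on relaxed structures.

## Calibration of the shipped defaults

All calibrations below are reproducible with the shipped
`calibrate_bending()` and `calibrate_morse()` routines; the defaults were
fixed once from these protocols and are not tuned per analysis.

* **DNA bending constant** $K_\theta = 4.4$ kcal/mol/rad². The discrete
  wormlike-chain relation $l_p \approx 2 K_\theta b / k_B T$ puts the bare
  persistence length at $\approx 52$ nm for $b = 35$ Å; simulations of a
  1050-bp DNA molecule (100 beads) with the full electrostatics confirm
  $\approx 50$ nm at 150 mM, rising as salt decreases. Tangent correlations
  are fitted over the first decay length only, where bending modes
  equilibrate far faster than the chain end-to-end relaxation.
* **Morse well** $D_e = 3.05$ kcal/mol, $a = 0.2$ Å⁻¹. The width was chosen
  deliberately soft: unwrapping of a 10.5-bp DNA segment is a gradual,
  multi-contact peeling process, and a soft well both reflects that and
  yields breathing kinetics fast enough to converge equilibrium constants in
  tractable runs. The depth was calibrated on the canonical dinucleosome
  (two nucleosomes, 63-bp linker, 300 K, 150 mM) against a spontaneous
  unwrapping equilibrium constant of $K_{eq} = 0.10$, using
  $\ln K_{eq}$-versus-$D_e$ interpolation over long trajectories
  ($2 \times 10^7$ steps, several seeds). A terminus counts as unwrapped
  beyond $r_0 + 2/a$ from its Morse partner (the well-width scale).
* **Acetyl Morse scaling** 0.777. Acetylation weakens the entry/exit–core
  attachment; scaling $D_e$ by 0.777 reproduces the roughly three-fold
  increase of the unwrapping constant ($K_{eq} \approx 0.32$) of acetylated
  nucleosomes. The acetyl interaction scaling is applied through the Morse
  well depth because the Morse bond *is* the entry/exit–core interaction in
  this representation.

## Genomic mapping and the synthetic-track generator

`fiber_from_tracks()` converts signal tracks into a single stochastic
chromatin fiber: dyads by greedy descending-score peak calling with a 147-bp
exclusion zone; acetylation and H1 by Bernoulli draws with probability
proportional to the local signal (mean over dyad ± 73 bp), rescaled so the
expected fractions match the locus-average targets (20% acetylated, 31%
H1-bound, 16.7% of acetylated nucleosomes BRD4-bound); BRD4 drawn among
acetylated nucleosomes only. Probabilities are capped at one after
rescaling; when a signal is too sparse to reach its target the assignment
saturates with a warning instead of failing (only an all-zero signal is an
error). All genomic arithmetic is 0-based half-open.

`synth_tracks()` emulates the statistical structure of the experimental
inputs so the full pipeline runs without downloads: a nucleosome-position
track with jittered peaks at the experimental mean repeat length (195 bp);
acetylation organized in alternating high/low blocks at the sub-TAD
compartment scale (12.5 kb); a broad H1 signal anti-correlated with
acetylation; and narrow BRD4 peaks nested at the centers of acetylated
blocks. What the generator does **not** emulate: cell-to-cell epigenetic
heterogeneity, sequencing noise models, enzyme cleavage bias, or any
sequence dependence. Tests passing on synthetic tracks therefore validate
the mapping and simulation machinery, not the biological fidelity of any
particular locus model.

Initial structures grow each fiber along a self-avoiding random reference
backbone (step $\sigma$, persistent direction with full re-randomization
after repeated rejections) confined to the simulation volume; nucleosomes
are inserted as rigid units with seeded random roll about the walk
direction. The backbone is restricted to a margin-shrunken core region so a
whole chromatosome always fits; the pre-relaxation overlap tolerance is
$0.5\sigma$ (hard clashes only) and soft-core relaxation removes the rest.
Background fibers at nuclear composition fill the sphere to 12.4 Mbp/µm³
(the average density of a mouse nucleus, about 100 µM nucleosomes).

## Observables and their conventions

* **Contact maps**: two nucleosomes are in contact when the minimum
  inter-bead distance is below $1.5\sigma = 52.5$ Å (configurable, recorded
  on every matrix). Observed/expected normalization divides by the mean
  contact at each genomic separation; compartments come from the first
  principal component of the correlation-transformed O/E matrix, sign-fixed
  to correlate positively with acetylation (log of per-bin signal over its
  mean).
* **Compartmentalization coefficient**:
  $(S_{AA} + S_{BB} - 2S_{AB}) / (S_{AA} + S_{BB} + 2S_{AB})$ over the
  off-diagonal O/E entries with A/B from the PC1 sign — a definition chosen
  so that perfect segregation scores 1 and a uniform map 0; configurable
  and documented because more than one definition is current in the field.
* **Insulation**: $\log_2$ of the diamond-window mean over the genome-wide
  expected; window 10 nucleosomes by default.
* **Unwrapping** $K_{eq}$: pooled unwrapped/wrapped time-fraction ratio over
  all termini, with a moving-block bootstrap over frames for the
  uncertainty.
* **PMF**: standard self-consistent WHAM (tolerance $10^{-6}$ kcal/mol on
  window free energies) over umbrella windows on the centroid–centroid
  distance of two nucleosomes; the $2 k_B T \ln r$ Jacobian is removed so a
  non-interacting pair is flat, the profile is zeroed on the outer 15% of
  the sampled range, and the well depth is plateau minus minimum. Window
  springs must be matched to the spacing (a 1.4-Å-wide window every 5 Å has
  essentially no histogram overlap and produces garbage stitching; the
  shipped protocol uses $k = 0.04$ kcal/mol/Å² every 4 Å). The *stacking*
  PMF is conditional on the stacked configuration: identical-in-every-window
  nematic restraints ($k_o = 100$ kcal/mol on the axis–axis and
  axis–centerline angles, a ~3° wobble) confine sampling to the stacked
  channel and cancel in WHAM. Without them the distance-PMF well of a free
  pair is only ~3 $k_BT$ — most of the stacked interaction energy
  (−5.5 $k_BT$ canonical at contact) is spent on orientational entropy. The
  conditional depth is genuinely restraint-width-sensitive (weak restraints
  recover the unrestrained ~3 $k_BT$, very stiff ones approach the bare
  energy); under the shipped protocol it converges to ~4.2 $k_BT$ canonical
  and ~1 $k_BT$ acetylated.
* **Sedimentation**: Kirkwood bead-model friction with hydrodynamic radius
  $\sigma/2$, partial specific volume 0.65 mL/g, water at 20 °C; bead masses
  6825 g/mol per DNA turn, per-protein histone masses, 21.4 kDa split over
  the two H1 beads. Absolute values inherit the crudeness of a one-radius
  bead model; trends (salt, H1, compaction) are the meaningful output.
* **Spatial domains**: per-frame proximity graphs (same contact cutoff,
  unweighted edges — the weighted variant sits behind a flag) partitioned by
  two-level Infomap with 10 seeded trials. The package carries its own
  two-level map-equation scorer, used in the tests as an exhaustive-search
  oracle on small graphs.
* **Clutches**: sliding four-nucleosome window $R_g$; a maximal run of
  nucleosomes covered by windows strictly below the trajectory-average
  window $R_g$ is one clutch. The trajectory-average (not per-frame)
  threshold implements "remains below average"; ties break to not-clutch.
* **Stacking**: center distance < 7.5 nm and undirected axis angle < 30°.
  The nucleosome axis is estimated from the summed cross products of
  consecutive histone-bead chords rather than a total-least-squares line
  fit: the superhelix's axial and lateral extents are nearly equal, which
  makes the TLS direction degenerate under thermal noise, while the chord
  cross product is unambiguous.
* **Diffusion**: time- and particle-averaged MSD of nucleosome centers,
  log–log fit of $K_\alpha \tau^\alpha$ over pre-plateau lags.

## Numerical choices and degenerate inputs

Tolerances: superhelix geometry is exact to construction ($10^{-6}$ Å
asserted); energy continuity at the cutoffs is below $10^{-10}$ kcal/mol;
WHAM iterates to $10^{-6}$ kcal/mol. Degenerate inputs have defined
behavior: empty signal tracks call no nucleosomes (with a warning);
immobile trajectories reject the MSD fit; rigid rods report infinite
persistence length; identical structure frames collapse to one cluster; an
empty proximity graph yields singleton domains; a linker asked to shrink
below zero clamps at zero with a warning. K-means structure clustering uses
k = 3, 50 seeded restarts, standardized distances.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the measured quantities are
statistically meaningful: dinucleosome breathing runs of $10^7$–$4 \times
10^7$ steps (several hundred breathing transitions), umbrella sampling with
26 windows of several $10^5$ steps, persistence-length runs of a few
$10^6$ steps,
and a Pou5f1-like sphere assembly of ~14,000 beads that is built and
relaxed but not evolved to convergence. Reproducing the full locus
phenomenology (nine 0.7-s replicas, slab coexistence with 45 12-mers,
anomalous exponents, clutch statistics) requires cluster-scale runs of the
exported LAMMPS inputs; the package generates those inputs bit-reproducibly
and analyzes returned trajectories with the same functions.

## Known limitations

No loop extrusion, no DNA torsion or sequence-dependent stiffness, no
explicit histone tails, implicit BRD4 (a pair-strength enhancement, not a
particle), population-average epigenetic input realized as a single static
pattern per simulation, and a hydrodynamically naive sedimentation model.
The desk-scale analogs bundled here demonstrate mechanism, not converged
locus statistics.
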