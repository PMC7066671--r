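---
title: "Ranking congeneric ligands with a twin 3D convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking congeneric ligands with a twin 3D convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In lead optimization a medicinal-chemistry team iterates over a congeneric
series: tens to hundreds of analogues sharing a scaffold, differing by small
substituent changes, assayed against one target.  The quantity that matters
is not absolute affinity but the *difference* in potency between close
analogues — differences that are often smaller than the error of absolute
affinity predictors.  `pairpot` models that difference directly: it takes a
pair of ligands posed in the same protein pocket and predicts
$\Delta \mathrm{pIC}_{50} = \mathrm{pIC}_{50}(a) - \mathrm{pIC}_{50}(b)$.

## Descriptor

Each protein–ligand complex is voxelized on a cubic box of edge 24 Å
centered on the pocket (1 Å voxels by default, so $24^3$ voxels).  Eighteen
occupancy channels are stacked: eight pharmacophoric protein channels
(hydrophobic, aromatic, H-bond acceptor, H-bond donor, positive ionizable,
negative ionizable, metallic, total excluded volume) and ten ligand element
channels (C, N, O, F, P, S, Cl, Br, I, H).  An atom at distance $r$ from a
voxel center contributes an occupancy

$$n(r) = 1 - \exp\left(-\left(r_\mathrm{vdw}/r\right)^{12}\right),$$

which is 1 at the atom position, $1 - e^{-1}$ at one van der Waals radius,
and decays as the twelfth power beyond it.  Overlapping contributions to
the same channel are combined with the **maximum**, which keeps every voxel
in $[0, 1]$ regardless of atom density; summation would have required an
arbitrary re-normalization.  Atoms farther than a 5 Å cutoff from a voxel
center are skipped — the neglected occupancy is below $2.5\times10^{-6}$,
well under the resolution of everything downstream — and the cutoff is part
of the descriptor definition, so the test-suite oracle applies it too.
Voxel centers sit at half-integer offsets from the box corner; the box
center defaults to the heavy-atom centroid of the crystal-reference ligand.
Translation invariance of the grid holds to floating-point rounding (about
$10^{-15}$ relative), not bitwise, because translated coordinates round
before the distance is formed.

The protein channel rules are a residue/atom-name lookup shipped as an
editable table (`inst/extdata/protein_channels.tsv`): side-chain donors,
acceptors and charges per standard residue, backbone N/O as donor/acceptor,
aromatic ring carbons flagged aromatic, carbons of known residues
defaulting to hydrophobic, metals by element, and excluded volume on every
heavy atom.  Atoms of unknown residues get only the excluded-volume flag
(with a warning).  Van der Waals radii are Bondi values from
`inst/extdata/vdw_radii.tsv`; both tables are replaceable through function
arguments.

## Network

Both ligands of a pair are encoded by the *same* convolutional leg (tied
weights): two 3×3×3 convolutions (32 then 64 filters by default) with ReLU,
a 2× max pool, a third 3×3×3 convolution to 192 channels with ReLU, and a
global spatial max pool that flattens each complex into a 192-dimensional
latent vector.  The prediction is a bias-free linear map of the *latent
difference*:

$$f(a, b) = w^\top\!\left(z(a) - z(b)\right).$$

Because the difference is an exact floating-point negation under operand
exchange and the head has no bias, $f(a,b) = -f(b,a)$ holds exactly — the
test suite asserts a deviation of 0, not merely $\le 10^{-6}$ — and
$f(a,a) = 0$ for any weights.  Filter counts are configuration-exposed; the
latent width is what the architecture publishes (192) and the default head
length follows it.

Training minimizes the mean squared error of predicted versus labelled
potency differences over all unordered pairs of assayed ligands —
$n(n-1)/2$ pairs in one canonical order each, since exact antisymmetry
makes the mirrored pair's gradient identical.  Optimization uses Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-4}$), batches of 32
pairs, 50 epochs by default, Xavier-initialized weights, and dropout (rate
0.5 by default) applied to each leg's latent vector independently *before*
the difference; at prediction time dropout is off and the model is
deterministic.  The learning rate is not part of the published protocol;
the default is $10^{-4}$ (the published $10^{-4}$ is Adam's $\epsilon$,
a separate constant).  The loss is not published either; MSE is the natural
choice for an RMSE-reported quantity.  Rotation augmentation re-voxelizes
both complexes of a pair under one fresh uniform rotation (random unit
quaternion) per pair per epoch — rotating raw coordinates, not grid values.
A non-finite loss aborts with a diagnostic rather than training on.  Every
stochastic choice (initialization, shuffling, dropout, rotations, splits)
derives from one run seed through a documented stream derivation, so whole
trajectories are bit-reproducible.

Given predicted differences against $k$ references of known potency, the
absolute potency of a candidate is reconstructed per reference as
$\mathrm{pIC}_{50}(\mathrm{ref}) + \hat\Delta$; the mean of those estimates
is a maximum-a-posteriori absolute estimate $\mu$ and their population
standard deviation $\sigma$ measures the model's uncertainty ($\sigma = 0$
with a single reference).

## Evaluation protocols

`continuous_learning_run()` emulates a live campaign: for each training
size $n$ in a schedule, split the series, train on all pairwise differences
among the $n$ "tested" ligands (or fine-tune a warm-start model for 3
epochs, the cheap between-assay update), predict every (test, train)
difference — $n \cdot m$ pairs — and score RMSE, Pearson $R$ and Spearman
$\rho$ against experiment, repeated over independent seeds.  Whether test
ligands are scored against *all* training ligands or only the series
reference is a configuration switch (`test_against`); all-pairs is the
default, matching the $n\cdot m$ accounting of the published protocol.
Correlations on constant vectors are reported as missing with a flag, never
silently zero.

Three split schemes are provided: *random* (seeded shuffle), *temporal*
(first $n$ by assay timestamp — the realistic regime), and *similarity*
(greedy growth from the series reference by fingerprint Tanimoto
similarity, emulating close-analogue prediction).  The reference ligand is
the crystal-structure ligand when flagged, otherwise the ligand with the
lowest mean maximum-common-substructure distance
$d(a,b) = 1 - |\mathrm{MCS}(a,b)| / \max(|a|, |b|)$ (heavy atoms; a bounded,
symmetric form — the protocol names "MCS distance" without defining one).
MCS is computed exactly as a maximum clique of the modular product graph,
which is fast at congeneric-series molecule sizes.  Series deduplication
drops a ligand whose common substructure covers all heavy atoms of both
molecules — i.e. the element-labelled graphs are isomorphic.  The
similarity split uses a package-native circular fingerprint (Morgan-style
iterative neighbourhood hashing, radius 2, folded to 2048 bits — the ECFP4
parameterization).  Its bit assignments are deterministic and internally
consistent but not bit-compatible with other toolkits, which is all a
similarity ordering needs.

## Campaign simulation

`simulate_campaign()` plays a lead-optimization campaign against hidden
labels: train on the revealed pool, predict $(\mu, \sigma)$ for every
hidden candidate against all revealed references, reveal the batch with the
highest acquisition score

$$\mathrm{UCB} = \mu + \beta\,\sigma, \qquad \beta = 1.64,$$

and repeat until the most potent ligand of the series is revealed.  With a
single revealed reference $\sigma = 0$ and the first epoch is effectively
greedy; the initial pool size is a parameter.  Total sampling counts every
revealed batch including the one containing the top compound
(epochs × batch size), matching the published advantage arithmetic
`advantage_experimental = experimental order − sampled` and
`advantage_random = n/2 − sampled`.  Per-epoch model updates default to
3-epoch fine-tuning from the previous weights (full retraining is a
switch); whether the original protocol retrained or fine-tuned between
synthesis epochs is not stated, and fine-tuning is the cheaper,
behaviourally equivalent choice at series scale.

One structural consequence deserves emphasis: the twin head is exactly
additive, $f(a, b) = w^\top z(a) - w^\top z(b)$, so with deterministic
prediction the per-reference estimates of a candidate differ from those of
any other candidate by a constant, and $\sigma$ — the spread across
references — is *identical for every candidate*.  It measures how
consistent the revealed references are with the model, not which candidate
is uncertain, and the UCB ranking then coincides with greedy ranking on
$\mu$ for any $\beta$.  Candidate-specific exploration would require a
stochastic predictor (dropout or rotation sampling at prediction time),
which is left out of scope here; the acquisition machinery is nonetheless
implemented and tested in full generality, and $\sigma$ does vary when the
predictor is stochastic.

## Synthetic test system

Because the published benchmarks rest on proprietary series and a large
public database, the package ships a fully synthetic stand-in
(`make_series()`), used by the tests and clearly labelled synthetic.  A
pocket of 30–60 typed pseudo-atoms occupies the lower hemisphere shell
(radius ≈ 8 Å) around the origin, with four fixed anchor atoms — a lysine
donor, an aspartate acceptor, an aromatic carbon, a zinc — lining the
pocket floor beneath the ligand.  Every ligand is a six-carbon scaffold
through the pocket center with one single-atom substituent per attachment
site, drawn from {C, N, O, F, Cl}.  The potency oracle is

$$\mathrm{pIC}_{50} = 5.0 + \sum_{\mathrm{substituents}}
w(\mathrm{element}) \cdot \frac{1}{1 + (d/3)^2} + \varepsilon,$$

where $d$ is the distance to the nearest donor/acceptor pocket atom,
$w = (C{:}\,0,\ N{:}\,1.2,\ O{:}\,0.9,\ F{:}\,0.5,\ Cl{:}\,-0.6)$ in pIC50
units, and $\varepsilon \sim \mathcal N(0, 0.3^2)$ — weights chosen once so
that the noise-free potency spread (≈ 1 pIC50 s.d.) comfortably dominates
the label noise.  The potency depends on *pocket-proximal polar contacts*,
not on ligand composition alone, so the joint protein–ligand descriptor
carries signal a composition-only model lacks; and because each anchor has
a distinct channel signature, substituent–site combinations remain
separable after the global max pool, which preserves presence (not count)
information.  What the fixture does **not** emulate: conformational
flexibility, binding-mode changes, activity cliffs, inter-target transfer,
or assay heterogeneity — so green tests certify the machinery and the
learning dynamics, not performance on real campaign data.

## Desk-scale test conditions

The published training configuration (1 Å voxels, 32/64 filter stack,
50 epochs) is the package default.  The *test-suite and acceptance-script*
runs use a reduced configuration chosen once for single-CPU turnaround:
2 Å voxels on the same 24 Å box ($12^3$ grid), 8/16 filters, latent 32,
dropout 0.2, learning rate $2\times10^{-3}$, 5–10 epochs, augmentation off,
series of 40–50 ligands.  Under these conditions the learning signal is
strong (held-out $\rho \approx 0.85$–0.99 on the synthetic series), the
incremental-training curve rises with training-set size, and the UCB
campaign finds the top compound in well under the $n/2$ random baseline.
Architecture constants (18 × 24³ grids, 192-dimensional latent, eight
protein channels) are always verified at the full published geometry.

## Numerical choices and edge cases

* $n(r)$ at $r = 0$ is defined as its limit, 1.
* Ties: reference selection and batch selection break ties by series
  position; the similarity split adds the first-position maximizer.
* A complex with no atoms inside the box voxelizes to an all-zero grid with
  a warning (not an error); an all-zero grid encodes to a finite latent.
* Training with fewer than two labelled ligands is an error; a schedule
  step at or beyond the series size is skipped with a warning.
* ΔG inputs convert at $T = 298.15$ K with
  $R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹ (treating IC50 as a dissociation
  constant under the non-competitive assumption).
* The campaign loop is guaranteed to terminate (the hidden pool shrinks
  every epoch) and asserts its epoch bound.

## Known limitations

The encoder's internal filter counts and pooling extents beyond the
published constants (latent 192, kernel 3, one pooling stage) are
under-documented in the original description; the defaults here are one
reasonable realization and are configuration-exposed.  The pharmacophore
rule table is a documented stand-in for the original (unavailable) channel
definitions.  The CNN is not rotation-equivariant — augmentation only
mitigates this.  Global max pooling discards occupancy counts, so potency
models that depend on *how many* identical motifs a ligand carries are
outside the representable family; the synthetic oracle was designed with
this in mind, and real series with strongly additive composition effects
may need a different pooling choice.
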