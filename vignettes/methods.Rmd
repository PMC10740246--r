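---
title: "Methods: labelling, ranking and learning bioactive-like conformers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: labelling, ranking and learning bioactive-like conformers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the quantities
it computes, the model it trains, the choices that were genuinely open and
how they were settled, and what the bundled synthetic benchmark does and
does not establish.

## The labelling model

A molecule's conformational ensemble is interpreted against one or more
*bioactive* reference geometries (experimentally, the target-bound
conformations). Each generated conformer is scored by **ARMSD_bio**: the
overlaid heavy-atom root-mean-square deviation to the *closest* reference,

\[
\mathrm{ARMSD}(a, b) \;=\; \min_{\sigma \in \mathrm{Aut}(G)}
\;\min_{R \in SO(3),\,t}
\sqrt{\tfrac{1}{N} \sum_i \lVert R x_{a,i} + t - x_{b,\sigma(i)} \rVert^2},
\]

where the inner minimum is the Kabsch superposition and the outer minimum
runs over automorphisms of the heavy-atom molecular graph, so chemically
indistinguishable atoms (a phenylene flip, a ring relabelling) never
inflate the deviation. Two deliberate restrictions:

* **Proper rotations only.** Reflections are excluded from the
  superposition, so an enantiomeric geometry is *not* considered close to
  its mirror image.
* **Heavy atoms only.** Hydrogen positions are neither read nor compared.

Conformers with ARMSD_bio strictly below 1 Å are labelled *bioactive-like*,
strictly above 2.5 Å *non-bioactive*, and *intermediate* otherwise. The
boundary values themselves are intermediate. An ensemble *retrieves* the
bioactive conformation when its minimum ARMSD_bio is below 1 Å.

Automorphisms are enumerated with VF2 on the vertex/edge-coloured graph,
capped at 10,000 (the truncated list is flagged); drug-like molecules stay
far below the cap. Ring bonds joining two unsaturated atoms are merged into
one "conjugated" bond colour, so the two kekulé assignments of an aromatic
ring compare equal. This surrogate is deliberately permissive (a
1,3-cyclohexadiene motif is coloured like an aromatic ring); for matching it
errs towards finding a mapping, and the chirality and element constraints
still apply.

## Structure curation

Reference structures arrive as line notation, observed structures as SDF
(V2000); hydrogens are stripped on read. Standardization keeps the largest
connected component and neutralizes charges that can be removed by an
implicit (de)protonation — skipping atoms adjacent to an opposite formal
charge, which keeps nitro and N-oxide groups intact — and records a
canonical reference string (via OpenBabel). Matching against the reference
is a chirality-aware graph isomorphism: every specified tetrahedral parity
and double-bond tag must be preserved under the mapping. When the direct
match fails, bond orders are copied from the reference through a
connectivity-only isomorphism and the match is retried exactly once,
mirroring the common situation where a deposited structure lost its bond
orders. Failures are reported per molecule, never raised, so batch curation
drops individual ligands.

Tetrahedral parity is perceived from 3D as the sign of the signed volume
over the three lowest-index neighbours; candidate stereocentres need
three or four heavy neighbours, no multiple bond, and pairwise-distinct
branches (compared by a depth-6 neighbourhood hash — deeply symmetric ring
systems may evade detection, a known limitation).

## Conformer generation

Ensembles come from a seeded knowledge-based distance-geometry embedder
(ETKDG, with experimental torsion-angle terms), run single-threaded with a
per-molecule seed derived from the master seed, so the same seed yields
bitwise-identical coordinates. Near-duplicate geometries are pruned at
0.05 Å RMS — rigid molecules collapse to one conformer while flexible
chains keep essentially their full budget (a C10 chain retains roughly 85%
of 250 requested). The generator's native output order is recorded as
`gen_order`; it stands in for the torsion-likelihood order of
knowledge-based commercial generators and doubles as the deterministic
tie-break of every ranker.

## Rankers

Six reference rankers are implemented besides the learned model:

* **random** — standard-normal score per conformer, ascending; the chance
  level.
* **generator_order** — ascending `gen_order`.
* **energy** — ascending single-point MMFF94 energy (hydrogens added at
  standard geometry first); a typing failure skips the molecule, never the
  batch.
* **sasa** — descending solvent-accessible surface area (Shrake–Rupley,
  Bondi radii, probe 1.4 Å, 256 deterministic golden-spiral points per
  atom, heavy atoms only).
* **rgyr** — descending mass-weighted radius of gyration.
* **tfd2simrefmcs** — the bioactivity-based baseline: nearest reference
  molecule by Tanimoto similarity of hashed circular fingerprints
  (radius 3, chirality-aware, 2048 bits), maximum common substructure
  (element-, bond-colour- and chirality-respecting, McGregor-style
  backtracking with a 10 s budget and best-so-far fallback), then ascending
  torsion fingerprint deviation over the torsions wholly inside the MCS
  against the reference's first bioactive conformation. Torsion deviations
  are |Δθ|/180 with weights halving per bond of topological distance from
  the graph centre, computed on the whole test molecule and restricted to
  the MCS torsion set. An MCS without torsions falls back to the generator
  order with a logged flag.

The **oracle** ranker (ascending true ARMSD_bio) provides the per-molecule
ceiling every practical ranker is compared against.

## The atomistic network

The learned ranker is a distance-only atomistic neural network of the
SchNet class. Input is the atomic point cloud: atomic numbers and an
interatomic-distance graph with edges below a cutoff — no bonds. The
pipeline is: learnable element embedding → `n_interactions` interaction
blocks → atom-wise two-layer readout, summed over atoms to one scalar.
Each interaction block is a continuous-filter convolution: distances are
expanded in Gaussian radial basis functions (centres evenly spaced on
[0, cutoff], width equal to the spacing), passed through a two-layer filter
network with shifted-softplus nonlinearity, multiplied by a cosine cutoff
envelope, then combined with linearly transformed neighbour features,
summed per atom, and added back residually. By construction the output is
invariant to rigid motions, reflections and atom permutations, and sums
additively over fragments farther apart than the cutoff.

Two presets are provided:

| parameter | full | desk |
|---|---|---|
| embedding width | 128 | 64 |
| interaction blocks | 6 | 3 |
| radial basis functions | 50 | 20 |
| cutoff (Å) | 10 | 10 |
| readout hidden width | 64 | 32 |

The **cutoff stays at 10 Å in both presets**: ARMSD_bio is a global
quantity, and during development a 5 Å cutoff — attractive for CPU cost —
turned out to erase the long-range distance information the target depends
on (even the radius of gyration became essentially unlearnable). The desk
preset narrows widths and depth instead.

Training minimizes the mean squared error of predicted versus true
ARMSD_bio with Adam, stopping when the validation loss has not improved
for `patience` consecutive epochs and restoring the best-epoch weights.
The default learning rate is the published 10⁻⁵ for this model family;
desk-scale runs use 10⁻³ with target standardization and a global
gradient-norm clip (default 5), which reach useful minima within tens of
epochs on hundreds of samples. Two initialization choices matter at this
scale and are defaults: filter-network biases start at 0.5 (the active
region of the shifted softplus, avoiding near-zero filters at step one),
and the final readout layer starts near zero so the atom-summed output
does not begin with a large constant offset proportional to the atom
count. Training is seeded end to end: identical seeds give identical loss
histories on one machine. A non-finite loss aborts with diagnostics rather
than continuing silently.

The forward/backward pass is a single fused C++ (RcppArmadillo) routine;
analytic gradients are checked against central finite differences in the
test suite, and a plain-R reference forward pass is kept alongside (the
two agree exactly on test batches).

## Evaluation

Early enrichment is measured with BEDROC in the Truchon–Bayly discrete
formulation at α = 20, at which the top-ranked 8% of items carry 80% of
the exponential weight mass — `exponential_weight_fraction()` documents
exactly this identity. BEDROC_bio-like takes bioactive-like conformers as
positives; BEDROC_non-bio takes non-bioactive conformers (low values mean
early *impoverishment*, the desirable direction). Intermediate conformers
count as negatives on both sides — the interpretation adopted here because
it preserves the per-molecule variable positive fraction; a side with no
positives (or only positives) is recorded as missing, not zero, to keep
medians unbiased. Only *eligible* molecules — at least one but not only
bioactive-like conformers — enter the medians; per-split medians are
summarized across splits as mean ± standard deviation. The *hard subset*
flags molecules with a full-size ensemble and under 5% bioactive-like
conformers. Ranks are 1-based and scale as rank/n into (0, 1]; top-fraction
selection takes ⌈fraction·n⌉ conformers, at least one.

## Dataset splitting

Random splits shuffle molecules with a seed and slice at the cumulative
80/10/10 boundaries (floors, remainder to test). Scaffold splits cluster
Bemis–Murcko scaffolds (acyclic molecules fall back to the whole molecule,
avoiding one degenerate empty-scaffold cluster) by complete-linkage
agglomeration on Tanimoto distance cut at 0.5 — complete linkage is chosen
precisely because the cut height then *guarantees* at least 50% pairwise
similarity within every cluster — and assign whole clusters in seeded
random order to train until 80% of the conformation weight is covered,
then to validation until 90%, remainder to test. Five replicate seeds per
split type is the default.

## The synthetic benchmark

Real inputs for this problem are curated protein–ligand archives, which
cannot be bundled. The synthetic generator emulates their *structure*: each
molecule gets a seeded conformer ensemble plus one or two withheld
"bioactive" references, built as torsion-jittered copies (default 5°
standard deviation) of a generated conformer, so the ARMSD_bio spectrum is
anchored near zero and spreads across the 1 Å and 2.5 Å thresholds with the
molecule's real flexibility. In family mode, molecules are grouped into six
families of substituted variants sharing a 20–32-heavy-atom core. The
families deliberately span the flexibility range of a curated ligand set —
two highly flexible cores (12–13 rotatable bonds, whose ensembles are rich
in non-bioactive conformers), two moderate and two low-flexibility cores
(4–6 rotatable bonds, dense in bioactive-like conformers) — because a
benchmark built only from very flexible molecules collapses into the
hard-to-rank regime where bioactive-like conformers are so rare (a few per
cent) that chance-level early enrichment is nearly zero; the mixture
reproduces a chance-level median BEDROC of roughly 0.1, the regime a full
curated test set exhibits. The reference conformer of each member is chosen
closest to the family's canonical core torsions (the per-torsion dominant
rotamer well of the first member's ensemble), giving members consistent
bioactive core geometry — the regime in which a reference-based torsion
comparison and a substructure-memorizing network are expected to work. A
configurable fraction of molecules (default 80%) is designed retrievable;
the rest get references with every core torsion pushed 35–55° off the
rotamer wells the generator samples. Designs are retried a few times and
flagged when the label constraints cannot be met.

What the benchmark does *not* emulate: protein pockets, binding
affinities, docking poses, crystallographic coordinate error, and the
chemotype diversity of a real archive (six cores versus thousands of
scaffolds). Passing the directional checks here shows the machinery ranks
as intended when the assumed structure (shared cores, consistent bioactive
torsions) holds — it does not certify performance on real screening data.

## Problem sizes

The package's own benchmark experiments use 54 molecules (9 per family)
with ensembles of up to 80 conformers, two held-out members per family for
testing and one for validation/early stopping, networks at the desk preset,
training on up to 15 conformers per molecule — subsampled at evenly
spaced ARMSD_bio quantiles so the rare bioactive-like tail is always
represented — for up to 40 epochs at batch size 8 with learning rate 10⁻³,
standardized targets and gradient-norm clipping at 10. Unit fixtures are far smaller (chains, rings, 4-atom stereocentres)
with closed-form expected values.

## Known limitations

* Stereocentre perception uses simplified priorities (atomic number, then
  neighbourhood rank), not full CIP rules; exotic stereochemistry
  (atropisomerism, ring pseudo-asymmetry) is out of scope.
* The MCS search is exact only within its time budget; on pathological
  pairs it returns the best mapping found, flagged.
* The TFD implementation covers acyclic rotatable torsions; ring torsions
  and torsion-symmetry normalization (e.g. a 2-fold phenyl) are not
  special-cased.
* The aromaticity surrogate is heuristic (see above); molecules whose
  identity hinges on precise kekulé assignment may over-match, though the
  template-retry path keeps true mismatches detectable by element and
  connectivity.
* The network is distance-only by design; angle- and torsion-aware
  backbones can be registered behind the same graph-in/scalar-out
  interface but are not implemented.
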