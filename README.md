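# confbias

Biasing conformer ensembles towards bioactive-like conformations.

## The problem

Geometry-based virtual screening (rigid-ligand docking, pharmacophore
searching) needs 3D conformations of each candidate molecule, but a
conformer generator emits hundreds of plausible geometries per molecule and
only a handful resemble the target-bound (*bioactive*) conformation.
`confbias` implements a complete workflow for learning to put those
bioactive-like geometries first:

1. **Label.** Every generated conformer is scored by its ARMSD_bio — the
   symmetry-aware, overlaid heavy-atom root-mean-square deviation (minimum
   over graph automorphisms, proper rotations only) to the *closest* known
   bioactive conformation of its molecule. Conformers under 1 Å are
   *bioactive-like*, above 2.5 Å *non-bioactive*.
2. **Learn.** A distance-only atomistic neural network (SchNet-class:
   learnable element embeddings, Gaussian radial-basis distance encoding,
   continuous-filter convolution interaction blocks, atom-wise readout
   summed per conformation) is trained to regress ARMSD_bio from atomic
   numbers and coordinates alone — no bond information.
3. **Rank.** Conformers are sorted by predicted ARMSD_bio and compared with
   five bioactivity-unaware baselines (random order, generator order,
   ascending MMFF94 energy, descending SASA, descending radius of gyration)
   and a bioactivity-based baseline, **TFD2SimRefMCS**: find the nearest
   reference molecule by Morgan-fingerprint Tanimoto, compute the
   chirality-respecting maximum common substructure (MCS), and rank by the
   torsion fingerprint deviation (TFD) over MCS torsions to the reference's
   bioactive conformation.
4. **Score.** Early enrichment of bioactive-like conformers (and early
   impoverishment of non-bioactive ones) is measured with BEDROC at
   α = 20, where the top-ranked 8 % of conformers carry 80 % of the score
   mass; results aggregate as per-split medians over eligible molecules
   (at least one, but not only, bioactive-like conformers).

Datasets are partitioned per molecule, either at random (80/10/10) or by
scaffold clusters (Bemis–Murcko scaffold, circular fingerprint radius 3,
complete-linkage clustering at 50 % minimum within-cluster Tanimoto,
clusters assigned whole, weighted by conformation counts).

Because curated protein–ligand archives cannot be bundled, the package
ships a synthetic benchmark generator that emulates their structure:
drug-like molecules with seeded distance-geometry conformer ensembles and
designated bioactive references whose ARMSD_bio spectrum spans both label
regimes, optionally organized into families sharing a ≥ 20-heavy-atom core
(the regime where reference-based and learned rankers shine).

## A worked example

```r
library(confbias)

# a small family-structured benchmark: 12 molecules in 6 families,
# up to 40 conformers each, fully reproducible from the seed
bench <- make_benchmark(synthetic_spec(n_molecules = 12,
                                       max_conformers = 40, seed = 7))
ens <- bench$ensembles[["famF_01"]]
ens
#> <cb_ensemble famF_01: 27 generated, 2 bioactive, 20 bio-like / 0 non-bio, retrieved>

# rank its conformers by TFD to the nearest reference, using the other
# molecules as the reference set
refs <- bench$ensembles[names(bench$ensembles) != "famF_01"]
rk <- rank_tfd2simrefmcs(ens, refs)
met <- bedroc_pair(rk, ens)
round(met$bedroc_bio_like, 3)
#> [1] 1
round(bedroc_pair(rank_random(ens, seed = 1), ens)$bedroc_bio_like, 3)
#> [1] 0.296
```

A BEDROC_bio-like of 1 against a chance level of 0.3 means the
reference-based ranker concentrates this molecule's twenty bioactive-like
conformers (of 27) at the very top of the ranking, where a docking or
pharmacophore budget would actually test them. `predict_and_rank()` does
the same with a
trained network (see the vignette for the full training loop), and
`evaluate_rankings()` / `summarize_eval()` aggregate such comparisons over
molecules and splits.

The staged pipeline (`run_stage`: `synth` → `split` → `train` → `rank` →
`evaluate`) exchanges SDF/TSV artifacts on disk; `inst/scripts/confbias`
wraps it for the shell.

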