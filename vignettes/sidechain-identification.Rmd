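---
title: "Identifying proteins in cryo-EM maps from side-chain density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying proteins in cryo-EM maps from side-chain density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoseqid)
```

## The problem

Single-particle cryo-EM can reconstruct a map of a protein that was never
purified to homogeneity — for instance from a fractionated cellular lysate —
so the identity of the molecule in the map may be unknown. At resolutions of
roughly 3.5 Å or better, the shapes of side-chain densities along a traced
backbone carry enough information to pick the right protein out of a
database of hundreds of candidate sequences. `cryoseqid` implements this
identification: given a density map, a *sequence-free* backbone trace, and a
FASTA database, it scores every candidate by the likelihood of its
side chains explaining the observed density and ranks the database.

## The model

**Scoring matrix.** For each break-free backbone segment, every position
gets a local frame from its N, CA, C atoms (CA at the origin, x along
CA→C, y the orthogonalized CA→N direction). For each of the 20 residue
types, every rotamer template — expected density at grid offsets around the
side chain, in that standard frame — is correlated with the map
(Pearson, hence invariant to the map's arbitrary scale and offset), and the
best rotamer's correlation is kept. Per residue type, correlations across
the segment's positions are standardized to Z-scores

z(i, aa) = max(0, (corr(i, aa) − mean_i corr(·, aa)) / sd_i corr(·, aa)),

with the population SD taken per segment. Clipping at zero keeps only
positive evidence; a residue type whose correlation is flat across the
segment carries no signal and its column is zeroed. These Z-scores are used
directly as position-specific match scores (larger is better).

**Reduced alphabet.** Many side chains are indistinguishable at these
resolutions (valine vs threonine), so scoring and alignment operate over six
size/shape classes: G = VGASCTI, P, L = LDNEQM, K = KR, Y = FHY, W. A group's
score at a position is the *maximum* over its members, so the true residue is
never penalized by its group assignment. The per-position argmax spells the
map's "pseudo-sequence".

**Alignment.** Automated chain tracing makes an insertion or deletion about
once every ten residues, so candidate sequences are aligned to each
segment's collapsed L×6 matrix with an affine-gap dynamic program. The mode
is semi-global: the segment is a contiguous window of the unknown protein,
so the candidate sequence's overhangs are free, while unmatched segment
positions are penalized wherever they occur. Gap runs cost
`open + (len − 1) · extend` with defaults open = 2.0 and extend = 0.5 in
Z-score units — sized so that a handful of single-residue indels per
hundred residues is affordable against typical per-position evidence of
1–3 Z units, while spurious gaps are not. Ties are broken toward fewer gap
events, then the leftmost placement, making results deterministic. The
implementation is exact dynamic programming (verified against brute-force
enumeration over all monotone alignments in the test suite).

**Null adjustment and ranking.** A raw segment score grows with sequence
length regardless of correctness, so the mean alignment score of random
sequences of the same length — drawn i.i.d. from eukaryotic residue
frequencies (King & Jukes, 1969), overridable via
`seqid_config(default_sequence=)` — is subtracted. The default null uses 100
random sequences per (segment, length), cached by length; its Monte-Carlo
error is small against typical true-vs-decoy gaps, and the unbiasedness of
the adjustment is itself a test. Candidates are scored by a greedy loop:
align all remaining segments, commit the best (adjusted) segment-sequence
alignment, remove the segment, repeat; the candidate's total is the sum over
committed segments. Optional behaviors mirror the method's keywords:
`allow_duplicates = FALSE` forbids two segments reusing a sequence position
(enforced by masking used positions in later alignments), `positive_only`
floors per-segment contributions at zero, `skip_if_too_short` rejects
candidates shorter than the model; all are off by default, as is model
trimming (`minimum_discrimination`, `trim_models`). The database Z-score is
(adjusted − database mean)/population SD, and candidates are ranked by
adjusted score with ties broken by id.

**Refit.** The winning alignment assigns a residue type to each matched
backbone position; the best-correlating rotamer of that type is placed
through the residue frame (torsion-space placement only — no coordinate
refinement), unaligned positions keep a flagged alanine placeholder, and
the model is written as PDB.

## Template library

The library holds, for each canonical rotamer of each residue type, the
expected density at grid offsets within 2.5 Å of the side-chain atoms (the
stated construction gives no radius; 2.5 Å covers a heavy atom and its
bonded neighborhood at these resolutions). The residue's own N, CA, C and
CB contribute to the expected density; glycine carries a pseudo-CB probe
region, which is what separates it from alanine. Each rotamer is used
without weighting by frequency.

Two provenances exist:

* **Idealized** (default, download-free): side chains built from standard
  bond lengths/angles at canonical chi angles (a shipped table: three
  staggered chi1 values, chi1×chi2 grids for longer chains, ring-specific
  chi2 for aromatics, two proline puckers; distal torsions extended) and
  rendered as single-Gaussian atoms with σ = resolution/(π√2), weighted by
  approximate electron counts.
* **Learned**: per-offset mean and variance of observed density accumulated
  from example map/model pairs. Each example residue is assigned to the
  nearest canonical rotamer by its chi angles within a ±40° window
  (unbinnable residues are skipped), and its density is z-normalized over
  the template region before accumulation, since maps have arbitrary
  scale. Bins with fewer than 3 examples fall back to idealized templates
  with a warning.

Templates are normalized per region, so only density *shape* matters —
consistent with the correlation-based score.

### Sampling conventions

All sampling tracks the feature scale, as deposited cryo-EM data do:
template offsets default to a `resolution/3` grid and the synthetic-map
voxel defaults to `resolution/3` (~3× oversampling). Holding either fixed
while varying resolution introduces a discretization artifact that
penalizes *finer* maps — with scale-proportional sampling, resolution
comparisons isolate the physical information loss from blurring.

## What the synthetic fixtures emulate — and what they do not

`simulate_identification_fixture()` draws a true sequence from eukaryotic
frequencies, builds an ideal extended polypeptide (φ = −140°, ψ = 135°;
extended rather than helical so consecutive side chains stay resolved from
one another) with uniformly sampled canonical rotamers, renders a
Gaussian-atom map, and perturbs the backbone the way automated tracing
does: one indel event per ten residues by default (deletions split the
chain; insertions locally resample a three-residue window into four, giving
the spurious-residue geometry of a mistraced chain), plus 0.1 Å coordinate
jitter — modest, since automated traces are usually sub-Ångström accurate.
The database is the true sequence plus 99 i.i.d. decoys with lengths within
±30% of the truth (a desk-scale stand-in for lysate-scale databases of
several hundred sequences).

Passing these tests shows the pipeline is internally consistent and that
the statistics behave as designed (rank-1 recovery, null unbiasedness,
resolution degradation). It does **not** show performance on real maps:
real data add reconstruction noise and anisotropy, B-factor variation,
model-free map scaling, non-ideal side-chain geometry, and tracing errors
that correlate with local map quality. The fixture's Gaussian-atom
convention is shared between map rendering and idealized templates, which
flatters correlations relative to real data.

## Numerical choices and degenerate inputs

* Population SD in all Z-scores (segment columns and database scores);
  segments need ≥ 2 residues, databases ≥ 2 candidates.
* Argmax ties anywhere resolve to the first residue in the fixed
  alphabetical order `AA_ORDER`.
* Constant observed density under a template gives correlation 0;
  out-of-box template points interpolate to 0 (maps are padded in
  practice, and a fixed value cannot inflate a correlation).
* CA–CA breaks above 5.0 Å split chains (a generous bound on trans/cis
  peptide CA separation).
* Degenerate residue frequencies (point mass) are allowed for the null but
  warned about; an all-identical score database warns and sets Z = 0.

## Validation scale

The shipped validation studies use 100-residue proteins, 99 decoys, 20
replicates for the 3 Å recovery study and 5 seeds per resolution in
{2.5, 3.0, 3.5, 4.0, 4.5} Å for the degradation trend — sizes chosen so the
whole suite runs on a laptop in minutes while leaving the statistical
assertions (binomial counts, Monte-Carlo SEs) well-powered.

## A worked example

```{r example, eval = FALSE}
fx <- simulate_identification_fixture(seed = 1, n_res = 100, n_decoys = 99)
res <- identify_protein(fx$map, fx$backbone, fx$database,
                        seqid_config(seed = 1))
glance(res)
head(tidy(res), 3)
autoplot(res)
fit <- refit_side_chains(res, fx$map, fx$sequence)
write_model(fit$model, "identified.pdb")
```

## Known limitations

* The idealized library uses a compact canonical rotamer set (115 rotamers);
  rare rotamers are approximated by their nearest canonical neighbor.
* Aromatic ring geometry is idealized; histidine tautomers are not
  distinguished (they are invisible at these resolutions anyway).
* No map sharpening, symmetry handling, or chain tracing — the map and
  trace are taken as given.
* Scores are relative (database Z), not calibrated probabilities; there is
  no E-value model beyond the database Z-score.
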