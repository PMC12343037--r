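---
title: "Active-site geometric search: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-site geometric search: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteseek)
```

## The problem and the model

Catalytic function is frequently carried by a small constellation of residues
— a nucleophile-acid-histidine triad is the canonical example — whose mutual
3D arrangement is conserved far beyond sequence or fold similarity. `siteseek`
treats that constellation as a rigid geometric template. The seed protein
contributes three *anchor* residues (the template proper), optionally further
*additional* residues used for ranking, and a substitution rule per position
listing the amino-acid types accepted there. Each query structure is then
asked: does it contain residues of acceptable types that can be rigidly
superposed onto the template with small residual distances?

The assumptions baked into this model are worth stating:

* **Rigidity.** The site is compared as a rigid body; conformational change
  (induced fit, loop motion) appears as score degradation, not as a modelled
  degree of freedom.
* **Residue-level resolution.** Only the Cα and Cβ atoms represent a residue.
  Cβ captures the side-chain direction; rotamer detail is deliberately out of
  scope, which suits predicted models whose side chains are less reliable
  than backbones.
* **Single chain.** One chain per structure is searched (the first chain with
  Cα atoms unless specified). Predicted proteome models are single-chain;
  composite sites spanning chain boundaries are a known limitation.

## The pipeline, stage by stage

**Candidate enumeration.** All assignments of type-compatible query residues
to the three anchors are formed as a Cartesian product without residue reuse.
The phrase "all possible combinations" is ambiguous between this permissive
reading and one restricted to assignments preserving the anchors' sequence
order; we default to the permissive product — it can find circular permutants,
a genuine biological phenomenon — and expose `enforce_seed_order = TRUE` for
the restrictive reading.

**Pre-screening.** Pairwise Cα–Cα distances are rotation-invariant, so a
candidate whose three pair distances deviate ≥ 3 Å from the seed's cannot
superpose well and is rejected before any fitting. The comparison is strict
(`< 3`), and Cα is used because it exists for every residue. When more than
`max_combinations` (default 2000) candidates survive, a uniform random subset
of that size is scored. The subset is drawn with an RNG seeded by
`(global seed, structure id)` — never by batch position — so batch results are
invariant to file ordering and worker count, and reproducible structure by
structure.

**Superposition.** The optimal proper rigid transform is the closed-form
Kabsch solution: SVD of the 3×3 cross-covariance of the centered anchor point
sets, with the smallest singular vector sign-flipped when the naive optimum
is a reflection. The fitted point set is the anchors' Cα+Cβ (3–6 points);
when either partner of an anchor pair lacks Cβ (glycine, missing atom), that
Cβ slot is dropped *on both sides* so the point lists stay paired. `fit_atoms
= "ca"` restricts the fit to Cα, since it is defensible to let Cβ participate
only in scoring; we default to including it in both, as side-chain
orientation is part of what makes a site a site. Rank-deficient
configurations (collinear points) still return a valid proper rotation — the
fit is then non-unique, which we document rather than error on, because the
downstream score remains well defined.

**Scoring.** The residue-level distance is the mean of the Cα and Cβ
separations after the transform (Cα alone when either side lacks Cβ). The
mapping score is

\[ \mathrm{score} = \frac{\overline{d}}{n_\mathrm{mapped}}, \]

the *average* mapped distance divided *again* by the number of mapped
residues. Taken literally this double-counts n — the alternative reading
(sum/n, i.e. the plain average) differs exactly by the factor n — but the
literal form is what gives the stated penalization: a mapping that fails to
find an additional residue loses a term from n and its score rises even if
the average is unchanged. Both variants are implemented
(`score_formula = "mean_over_n"` (default) / `"sum_over_n"`); scores from the
default formula should be compared only against thresholds calibrated for it
(the 1 Å default acceptance threshold, strict `<`).

Mapped residues are: the three anchors; additional residues matched in the
query; and the sequence neighbors at offsets ±1..w (default w = 4) of each of
those, paired by equal sequence offset regardless of type. Neighbor windows
truncate silently at chain termini, and a (seed, query) pair reachable from
several windows — or coinciding with a core pair — is counted once.

*Additional-residue association.* How an additional seed residue finds its
query partner is not fully determined by the method's description; our rule
is: candidates are query residues of an accepted type, excluding those
already consumed by the anchor mapping; pairs are ranked by residue distance
and assigned greedily one-to-one; a pair is kept only below 2 Å
(`additional_match_radius`, consistent with the 2 Å cutoff used by the
whole-structure pairing). Greedy-by-distance is deterministic, one pass, and
coincides with the optimal assignment except in contrived near-tie
geometries.

*Two open choices resolved.* (1) "Four neighbors by default" could mean four
total or four per side; we chose ±4 (symmetric, maximizes local context) and
expose it as `neighbor_window`. (2) Anchor auto-completion from fewer than
three given residues uses "the first three" residues within a 10 Å radius of
the first anchor; we define *first* as ascending sequence position, keeping
the user's residue first — deterministic and sequence-natural. The 10 Å
default radius is a typical active-site span.

**Whole-structure metrics.** With the winning transform fixed (no further
refinement), the full Cα traces are aligned by dynamic programming. The DP
objective is our concretization: match reward 1 when the pair is closer than
2 Å, 0 otherwise, gap penalty 0 — i.e. it maximizes the number of sub-2 Å
monotone pairs, parameter-free. The *structural mapping percentage* is 100 ×
(retained pairs)/(query length); the denominator is the query because the
question asked is "how much of this candidate matches the seed". The
*structural local similarity* groups pairs into maximal runs where both
indices advance together; with c_L the fraction of query residues in runs of
length ≥ L,

\[ \mathrm{sls} = \frac{\sum_{L \in \{5,10,15,20\}} L\,c_L}{5+10+15+20} \in [0,1]. \]

The weights (proportional to L, normalized by 50) are a design choice — the
length-proportional weighting makes one run of 20 worth more than four runs
of 5 — and the thresholds are exposed as the `lengths` argument. In practice
hits are post-filtered on this value (e.g. keep ≥ 0.4 when only the anchors
mapped, ≥ 0.1 when additional residues were also found).

## Parameters at a glance

| parameter | default | unit | role |
|---|---|---|---|
| `prescreen_tol` | 3 | Å | strict upper bound on anchor pair-distance deviation |
| `max_combinations` | 2000 | — | cap on scored candidates per structure |
| `score_threshold` | 1 | Å | strict acceptance bound on the mapping score |
| `neighbor_window` | 4 | residues | sequence neighbors per side included in scoring |
| `additional_match_radius` | 2 | Å | acceptance radius for additional residues |
| `fit_atoms` | `ca+cb` | — | atom set for the rigid fit |
| `rng_seed` | 0 | — | global seed for cap subsampling |

## What the synthetic generator emulates — and what it does not

`make_backbone()` builds an ideal α-helical curve (rise 1.5 Å, radius 2.3 Å,
100°/residue), giving the true ~3.8 Å consecutive Cα spacing, with Cβ 1.5 Å
radially outward and uniformly random residue types. `plant_site()` rewrites
three well-separated positions (n/6, n/2, 5n/6) to a chosen triad and places
their Cα on a triangle realizing target pair distances (8, 10, 12 Å by
default — a typical catalytic-triad span) plus Gaussian jitter on each
distance; 0.3 Å jitter represents the coordinate uncertainty of a
well-predicted site. A random proper rigid motion is then applied to the
whole model so superposition is always genuinely exercised.

Decoys are engineered to fail exactly one stage: `wrong_types` keeps the
geometry but replaces the triad types (dies at enumeration), `wrong_geometry`
keeps the types but displaces every pair distance by +5 Å (dies at the 3 Å
pre-screen), and `shifted_site` displaces each triad atom by 2 Å (a near-miss
that may pass the score threshold but shows degraded whole-structure
metrics). To guarantee that each decoy tests only its own stage, the
generator resamples background residues that would collide with the triad
types; consequently every fixture structure contains exactly one candidate
mapping. Real proteins contain many type-compatible residues and hence many
candidate mappings — the combination cap and the lowest-score selection are
exercised by constructed mapping sets in the tests instead.

A green fixture benchmark therefore establishes that the geometry pipeline is
correct and deterministic; it does not establish recall on real structural
diversity (loops, domain motion, crystal-contact distortion), nor
discrimination against the background of genuinely similar sites in a
proteome, which require real structure collections outside this package's
test scope. The helical pseudo-fold also means the whole-structure metrics
take extreme values (near 100% / near 0%) more readily than on real folds.

## Numerical choices

* Strict inequalities at both thresholds (`< 3 Å`, `< 1 Å`) — boundary cases
  are rejections.
* Ties in best-mapping selection break by lexicographically smallest query
  position triple; DP traceback prefers skipping seed residues, then query
  residues, then taking the diagonal, making pair sets deterministic (the
  pair *count* is tie-free, being the DP optimum).
* The cap subsample is returned in original lexicographic order; sampling
  uses a 31-bit polynomial hash of the structure id mixed with the global
  seed, so it is stable across sessions and platforms.
* Structures are compared in double precision throughout; the TSV output
  rounds scores to six decimals, so round-trip equality holds to 1e-6 Å.
* Degenerate inputs: fewer than 3 residues rejects a structure before search;
  residues without Cα are dropped at parse time; insertion codes are rejected
  explicitly (predicted-model numbering has none); nonstandard residues map
  to parent types via a fixed table or are dropped with a warning.

## Known limitations

* No cavity detection or cavity-based comparison; the result table carries
  only the two trace-based metrics.
* No statistical significance (E-value/Z-score) is attached to the score; the
  acceptance threshold is a calibrated distance, not a probability.
* The whole-structure metrics reuse the active-site transform; they are
  measures of alignment *around the site*, not an optimal global
  superposition.
* Query acquisition is local-file only by design; network fetching belongs to
  a wrapper, not the search core.
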