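---
title: "Hybrid sequence-structure alignment with PC_sim: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid sequence-structure alignment with PC_sim: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `pcali`, the tunable
parameters, the numerical choices made where the design was genuinely open,
and what the synthetic-data tests do and do not demonstrate.

## Similarity measures

Protein similarity is scored on a pairwise alignment by four measures on
[0, 1]. The **aligned fraction** `ali = L_ali / max(L1, L2)` penalizes
indels; normalizing by the longer protein makes it symmetric and sensitive
to truncated constructs. **Sequence identity** `SI` counts identical aligned
residues over `L_ali`; indels are not scored, so flanking gaps leave it
unchanged. The **TM-score** is

$$TM = \max \frac{1}{L}\sum_i \frac{1}{1+(d_i/d_0)^2},
\qquad d_0 = 1.24\,(L-15)^{1/3} - 1.8\ \text{Å},$$

with `d_i` the Cα-Cα distance of aligned column *i* after the optimal rigid
superposition and `L` the number of aligned positions (an option normalizes
by `max(L1, L2)` instead). `d_0` is the distance expected between unrelated
positions; the printed formula turns non-positive for `L ≤ 21`, so it is
clamped at 0.5 Å — without a floor the score is undefined for short
alignments. The **contact overlap**

$$CO = \frac{\sum_{i<j} C_{ij}\,C'_{a(i)a(j)}}
            {\sqrt{\sum_{i<j} C_{ij}\,\sum_{i<j} C'_{ij}}}$$

uses binary heavy-atom contact maps (any heavy-atom pair closer than 4.5 Å)
and needs no rotation; the geometric-mean normalization makes its maximum 1
and keeps it symmetric. Contacts with sequence separation below `min_sep = 3`
are excluded: trivially adjacent contacts are present in every chain and
would inflate the overlap without carrying fold information (`min_sep` is a
visible argument of `compute_contacts()`).

The hybrid score is the fixed-weight combination

$$PC_{sim} = (0.84\,ali + 0.79\,SI + 0.95\,TM + 0.95\,CO)/3.53,$$

the leading principal component of the four measures; `pca_loads()` performs
that covariance PCA (no standardization — the inputs already share the [0, 1]
scale) so the weights can be recomputed on any user score table.

## Optimal superposition

The rotation maximizing the TM-score is found self-consistently. From each
seed transform the code alternates two refinements, keeping the best-scoring
transform ever seen: (i) plain least-squares (Kabsch) superposition on the
working subset of columns with current distance below `max(d0, 3 Å)` until
the subset stops changing (cap 50 passes), and (ii) iteratively reweighted
least squares with weights $w_i = (1+(d_i/d_0)^2)^{-2}$, which is the
stationarity condition of the TM objective itself. Seeds are the
least-squares fits of the full alignment and of its two halves; a final
Nelder-Mead polish over the six rigid degrees of freedom removes the last
~1e-3 of score. For alignments of eight or fewer columns the TM landscape is
sharply multimodal (d0 is at its floor), so a deterministic rotation grid
(6 × 4 × 6 orientations, centroid-matched translation) is added to the seed
set and the top eight candidates are polished. Everything is deterministic;
the tests verify agreement with an independent brute-force rotation-grid
maximizer to 1e-6 on four-residue toys and exact transform recovery on rigid
copies.

## Divergences

Each similarity S maps to an inferred divergence time
$-\ln\big((S - S_0)/(1 - S_0)\big)$, the Tajima–Nei form, where $S_0$ is the
similarity expected without homology: 0.05 for SI, 0.167 for TM,
$q(L) = 0.39\,L^{-0.55} + 6.64\,L^{-0.67}$ for CO (L = aligned positions of
that pair), and their weighted mixture $PC_0(L)$ for PC_sim. Below baseline
the divergence is UNDEFINED, represented as `NA`, never an error. Two open
points were settled as follows: the PC divergence denominator is $(1-PC_0)$,
by consistency with the other three transforms (the alternative $(1-PC)$ is
exposed as an argument); and for tree building UNDEFINED entries are imputed
as (largest defined divergence in the matrix) + 1, which preserves rank order
while keeping no-signal pairs most distant — the raw `NA` pattern is kept for
output files.

## Gap-free refinement of pairwise alignments

`ss_realign()` relocates gaps opened strictly inside a secondary-structure
element to the element's nearer end (displacement counted in residues; ties
go N-terminal), reflecting that a deletion inside a helix or strand
rearranges the structure to the element boundary. SI and TM are computed for
input and modified alignments and the larger of each is reported; the CO
follows the modified alignment only when its TM is higher.

`refine_pa()` raises a target score (TM, CO or PC) without gap parameters:
residues' nearest partners under the target are computed from the current
alignment (minimal superposed distance for TM; largest shared-contact count
for CO; for PC a per-residue reconstruction
$[0.79\,1\{aa\} + 0.95\,1\{d<d_0\} + 0.95\,\text{shared}/\text{maxdeg}]/2.69$
— the aligned-fraction term is global and has no per-residue analogue);
mutual nearest pairs ("double matches") that are already aligned become
fixed frames, and double matches falling sequentially between consecutive
frames are added left to right. The pass repeats with recomputed neighbors
until the alignment is stable or `max_iter = 5`. Tie-breaks keep the current
partner, so an already-optimal alignment is a fixed point after one pass.
The final result is the better of (refined, input) under the target — ties
go to the input, so the refinement never modifies without gain.

De novo pairwise alignment (`denovo_pa()`) is global affine-gap DP over
$S(i,j) = [0.79\,\hat B(aa_i, aa_j) + 0.95\,1\{ss_i = ss_j\} +
0.95\,cvs(i,j)]/2.69$: BLOSUM62 rescaled linearly to [0, 1], secondary
structure standing in for the TM term, and the contact-vector similarity
(one minus the normalized multiset difference of signed contact offsets)
standing in for CO, so no starting superposition is needed. Gap open/extend
default to 0.35/0.05 on the [0, 1] score scale; DP traceback prefers
diagonal, then gap-in-second, then gap-in-first.

## Clique seeding and progressive refinement

The refined PC-targeted alignments become a graph whose nodes are residues
and whose edges join aligned residues; with one alignment per protein pair a
residue has at most n − 1 links (the bound is n − 1, not n, since a residue
has at most one partner in each other protein). Candidate MSA columns are
grown per node exactly as an incremental clique construction over the
neighbor list, capped at the 100 largest cliques per step; nodes are visited
in decreasing clustering-coefficient order and skipped once their stored
maximum or summed clique size exceeds n/2 (the published exclusion sentence
is ambiguous about which quantity triggers it; both are used, matching its
"any of them" reading). Accepted columns must be pairwise order-consistent,
reuse no residue, and keep the precedence relation acyclic; cliques are
accepted in decreasing size (ties by summed clustering coefficient, then
lexicographic member order), orphan residues attach to the most-connected
consistent column (ties leftmost) or seed singletons, and columns are
ordered topologically with unordered ties resolved by average normalized
residue position.

Progressive refinement repeats up to seven times: consensus superposition of
all structures on the current MSA (medoid-initialized, iterated against the
evolving column-average coordinates, best transform set kept so the summed
TM never decreases), PC_div matrix, average-linkage (UPGMA) guide tree with
heights equal to half the cluster-average divergence, then leaf-to-root
cluster merging by global affine-gap DP over column pairs scored by the mean
cross-pair PC-style position score (rescaled BLOSUM62, TM distance term from
the consensus superposition, shared-contact term, and a 0.1 bonus for pairs
aligned in the current MSA — the bonus magnitude is unpublished and exposed
as an argument). Cluster-internal columns are never split. The DP family is
implemented as global (Needleman–Wunsch/Gotoh) alignment: profile merging
must align entire clusters, so a local variant would be ill-posed here. The
loop stops early when the average PC_sim converges (< 1e-6 change) or an MSA
repeats, and the iteration with the largest average pairwise PC_sim —
including the seed — is returned, which guarantees the output never scores
below the input. The guide tree uses average linkage; the tree written to
the `.PCAli.tree` output file is the neighbor-joining tree on the same
PC_div matrix, matching the output convention of the original tool family.

## MSA comparison

`sum_of_pairs()` counts residue pairs aligned in the same column in both
MSAs and normalizes by the geometric mean of the two pair counts (symmetric;
penalizes overalignment), or by the reference's count in reference mode.
`column_overlap()` needs a column correspondence, which is not uniquely
defined when columns split or merge; columns are matched greedily by shared
residue count (each used once, ties leftmost), and the tests verify the
greedy matching against exhaustive assignment on small cases.

## Synthetic families

`evolve_family()` generates the test bed: an idealized scaffold (helix,
strand hairpin, or two packed helices; pseudo side-chain atoms give
realistic non-empty contact maps) evolves along a planted tree with
(i) Poisson substitutions under uniform exchange, (ii) geometric-length
indels (mean 2, capped at 4, never within three positions of a terminus so
superposition stays well-posed at small L), spliced consistently into
sequence, coordinates and the global truth alignment via a site registry,
and (iii) Brownian coordinate drift with per-branch standard deviation
$\sigma\sqrt{t}$, accumulating along the tree so TM and CO decay with
divergence time as they must for divergence-time recovery to be a meaningful
test; each leaf finally receives a random rigid transform. Defaults are the
study conditions used throughout testing: n = 6, L = 60, substitution rate
0.25/site/unit time, about one to two short indels per family, σ = 0.5 Å,
balanced ultrametric tree of height 0.75. The generator is not physics:
drift is isotropic noise, indel coordinates are interpolated, and there is
no selection or covariation — so passing recovery tests shows the algorithms
recover planted signal under realistic noise magnitudes, not that they
handle conformational change, domain motion, or real indel placement biases.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale by design:
families of 2–6 proteins of length 6–200, a ten-step divergence ladder at
L = 150, brute-force oracles on ≤ 4-residue superpositions, ≤ 10-residue
clique graphs and ≤ 8-column MSAs. Every stochastic step is seeded; the same
seed reproduces a family bit for bit. `hclust` resolves guide-tree ties by
its own deterministic rule on the input order (rows ordered by group id),
and all DP and assembly tie-breaks are fixed as described above.

## Known limitations

Single-chain, single-conformer input (first PDB model; altloc 'A' or highest
occupancy); no mmCIF; the internal secondary-structure assignment is a
Cα-geometry heuristic (distance signatures over i,i+2/3/4) that
underestimates strands at chain edges — a DSSP file can override it; the
per-residue PC score and the profile bonus are reconstructions of
unpublished choices and are flagged as arguments; the clique assembly is
greedy, not an exact maximum-weight consistent subset (NP-hard), with ≥ 90%
of the optimum verified on small instances.
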