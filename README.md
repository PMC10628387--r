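# pcali

Multiple sequence alignments (MSAs) of distantly related proteins are the
weak link of much of evolutionary inference: sequence aligners degrade in the
twilight zone (pairwise identity below ~20%), while structure aligners
recover the geometry but systematically underestimate sequence identity and
aligned fraction. `pcali` is an R implementation of a hybrid
sequence-and-structure alignment approach built around a single integrated
similarity score, for structural bioinformaticians and molecular
evolutionists who have (real or simulated) coordinates for every sequence
they want to align.

## The score and the method

For a pairwise alignment of two protein structures the package computes four
similarities, each in [0, 1]:

* **ali** — aligned (non-gap) columns over max(L1, L2);
* **SI** — sequence identity over aligned columns (indels not scored);
* **TM** — TM-score, `max (1/L) Σ_i 1/(1 + (d_i/d0)²)` with
  `d0 = 1.24 (L−15)^{1/3} − 1.8` Å, the rotation found self-consistently by
  iteratively maximizing the score;
* **CO** — contact overlap, `Σ C_ij C'_{a(i)a(j)} / sqrt(Σ C Σ C')` over
  heavy-atom contact maps (4.5 Å cutoff), rotation-free.

These are combined into the hybrid similarity

```
PC_sim = (0.84 ali + 0.79 SI + 0.95 TM + 0.95 CO) / 3.53
```

whose weights are the leading principal component of the four measures
(`pca_loads()` recomputes them on any score table). Each similarity S maps
to an inferred evolutionary divergence `−ln((S − S0)/(1 − S0))` with a
measure-specific no-homology baseline S0 (0.05 for SI, 0.167 for TM, the
length-dependent `q(L) = 0.39 L^{−0.55} + 6.64 L^{−0.67}` for CO, and their
weighted combination PC0 for PC_sim); the hybrid one is **PC_div**.

The aligner itself: starting pairwise alignments (de novo DP, or projected
from an input MSA) are refined toward a target score without gap penalties
by aligning mutual-nearest-residue pairs between fixed "frames"; the refined
alignments become a residue graph whose maximal cliques seed an MSA; up to
seven progressive passes along a PC_div average-linkage guide tree re-align
clusters with a PC_sim-based profile score, and the MSA with the largest
average PC_sim is kept.

## Worked example

Everything is testable without downloads through the synthetic family
generator, which evolves a scaffold structure along a planted tree and
records the true alignment:

```r
library(pcali)

fam <- evolve_family(family_spec(n = 6, L = 60, sub_rate = 0.25,
                                 indel_rate = 1, sigma = 0.5, seed = 42))
res <- run_pipeline(fam$structures, mode = "seq")
res$stage_table[, c("stage", "ali", "SI", "TM", "CO", "PC")]
#>            stage       ali        SI        SS        TM        CO        PC
#> 1          input 0.9635070 0.7367481 0.7825296 0.8322060 0.7454677 0.8187442
#> 5         PC_ali 0.9614557 0.7429439 0.7775390 0.8399440 0.7684780 0.8279177
#> 6     clique_msa 0.9601737 0.7433753 0.7772377 0.8374678 0.7586826 0.8244066
#> 7  progressive_1 0.9635070 0.7401756 0.7768799 0.8408753 0.7733033 0.8293355
#> 9       selected 0.9635070 0.7401756 0.7768799 0.8408753 0.7733033 0.8293355

sum_of_pairs(res$final_msa, fam$truth_msa)$sum_of_pairs
#> [1] 1
```

(abridged rows; run it to see all stages). The stage table shows the point of
the method: the PC-targeted refinement raises SI, TM and CO together over the
de novo input, and the progressive pass improves the clique seed; the final
MSA here reproduces the planted truth exactly (sum-of-pairs 1.0).

The command-line driver writes the full file suite (`.sim`, `.div`,
`.prot.sim`, `.prot.div`, `.PCAli.fas`, `.PCAli_ss.msa`, `.PCAli.tree`,
`.PCAli.pdb`, `_summary.dat`, `.id`):

```sh
Rscript inst/cli/pc_ali.R -i manifest.txt -seq -o myrun
Rscript inst/cli/pc_ali.R -i manifest.txt -ali input_msa.fasta -o myrun
```

where the manifest lists one `path chain name` triple per line.

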