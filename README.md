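# aarsfp

Interaction fingerprints of amino acid recognition in aminoacyl-tRNA
synthetases (aaRSs).

aaRSs implement the genetic code at the chemical level: each of the 22
enzymes (20 standard, plus pyrrolysyl- and phosphoseryl-tRNA synthetase)
must pick its amino acid out of a pool of close chemical relatives before
attaching it to the cognate tRNA. `aarsfp` is a toolkit for quantifying how
that recognition works from annotated protein–ligand structures. It is
aimed at structural bioinformaticians who already have non-covalent
interaction annotations (e.g. PLIP reports) for aaRS·ligand complexes and
want to turn them into comparable, statistically summarized recognition
profiles.

## What it computes

1. **Specificity-conferring interactions.** The amino-acid scaffold (the
   ligand minus its terminal carboxyl hydroxyl, which is cleaved during
   activation) is matched into the full ligand graph by subgraph
   isomorphism; interactions are mapped onto scaffold atoms as the union
   over all isomorphisms, and contacts touching only the ATP/adenylate
   moiety are discarded.
2. **Occupancy profiles and frequency tables.** Per (scaffold atom,
   interaction type), the fraction of an aaRS's structures showing the
   contact (entries below a 0.1 cutoff neglected), and class-level
   interaction counts with relative frequencies.
3. **Segmented binary fingerprints.** Binding-site composition (20 bits),
   hashed interaction features (500 bits; type | ligand atom element |
   residue, FNV-1a), editing mechanisms (22 bits) and binding cavity volume
   (12 one-hot bins over 30–270 Å³ in 20 Å³ steps) — 534 bits in full.
4. **Recognition space.** Pairwise Jaccard distances

   d(a, b) = 1 − n_{a∧b} / (n_a + n_b − n_{a∧b}),

   a 2-D embedding (UMAP-style fuzzy-kNN neighbour embedding implemented in
   the package; n_neighbors = 60, min_dist = 0.1 by default; classical MDS
   as alternative backend), and mean silhouette coefficients comparing
   fingerprint designs (Seq_sim, Seq+Int, Seq+Int+Ed, Seq+Int+Ed+Vol, Ed,
   Vol).
5. **Supporting statistics and curation.** Mann-Whitney U (exact for small
   samples, tie-corrected normal otherwise), Spearman/Pearson correlations,
   ligand torsion angles, Needleman-Wunsch identity clustering at 95% with
   representative selection, and MSA-based unified residue renumbering.
6. **Synthetic data.** A declarative generator produces complex sets with
   the statistical structure of a crystallographic aaRS dataset
   (template-driven per-atom occupancies, class-skewed interaction types,
   class-dependent cavity volumes), so the whole pipeline is testable
   without any downloads.

## Worked example

```r
library(aarsfp)

# synthetic dataset: 20 complexes for each of the 22 aaRSs
cx <- generate_complexes(default_spec(), n_per_aars = 20, seed = 1) |>
  assign_specificity_interactions()

# per-atom occupancy profile of ThrRS
thr <- dplyr::filter(cx, aars == "ThrRS")
compute_occupancy(thr)
#> # A tibble: 7 x 4
#>   scaffold_atom itype         n_present occupancy
#>   <chr>         <chr>             <int>     <dbl>
#> 1 CG2           hydrophobic           9      0.45
#> 2 N             hydrogen_bond        18      0.9
#> 3 N             metal_complex         9      0.45
#> 4 O             hydrogen_bond        11      0.55
#> 5 O             salt_bridge           5      0.25
#> 6 OG1           hydrogen_bond        19      0.95
#> 7 OG1           metal_complex        10      0.5

# fingerprints, recognition space, design comparison
comp <- compare_designs(cx, c("seq_sim", "seq_int", "seq_int_ed"), seeds = 1)
glance(comp)
#> # A tibble: 3 x 4
#>   design     mean_silhouette sd_silhouette n_seeds
#>   <chr>                <dbl>         <dbl>   <int>
#> 1 seq_int            -0.179             NA       1
#> 2 seq_int_ed          0.0601            NA       1
#> 3 seq_sim            -0.215             NA       1
```

The occupancy table reads: 90% of ThrRS structures hydrogen-bond the
ligand's backbone amine and nearly half coordinate it in the zinc complex;
95% hydrogen-bond the side-chain hydroxyl, half of them through the metal
as well; the methyl group is bound hydrophobically. The silhouette
comparison shows the monotone gain from enriching the fingerprint:
composition alone hardly separates the 22 aaRSs (-0.215), adding typed
interactions helps (-0.179), and adding editing mechanisms helps further
(+0.060). Numbers vary with the generation seed; those above come from the
seed shown.

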