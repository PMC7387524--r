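---
title: "Quantifying amino acid recognition in aminoacyl-tRNA synthetases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amino acid recognition in aminoacyl-tRNA synthetases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aarsfp)
```

## The problem

Aminoacyl-tRNA synthetases (aaRSs) enforce the genetic code by selecting
one amino acid from a pool of chemically similar candidates. Their binding
sites split into an ATP/adenylate moiety, conserved within each of the two
structurally unrelated aaRS classes, and a specificity-conferring moiety
whose non-covalent contacts with the amino-acid part of the ligand differ
between enzymes. `aarsfp` turns per-complex interaction annotations into
comparable recognition profiles: per-atom occupancy statistics, segmented
binary fingerprints, and a low-dimensional "recognition space" whose
cluster structure can be scored.

This vignette documents the models and the design decisions; the README
shows the surface-level workflow.

## Specificity assignment by subgraph matching

Interactions are annotated on the *full* ligand (free amino acid,
aminoacyl-adenylate, or sulfamoyl analog), but only contacts with the
amino-acid substructure confer specificity. Each of the 22 ligands has a
built-in scaffold graph: the heavy atoms of the amino acid with the
carboxyl hydroxyl removed, because that oxygen is cleaved during activation
(in post-activation ligands the corresponding position is the ester bridge
oxygen, likewise excluded). Scaffolds are matched into ligand graphs by an
exhaustive backtracking subgraph monomorphism: injective, element
preserving, and bond preserving, while *ignoring bond orders and
aromaticity* — ligand dictionaries disagree on orders, and order-free
matching lets AMP esters and sulfamoyl analogs hit the same scaffold.
Results are exactly deduplicated and reported in lexicographic order, so
downstream behaviour never depends on enumeration order.

Symmetric substructures (valine's two methyls, carboxylate oxygens,
aromatic ring positions) make the atom assignment ambiguous. We keep every
automorphic mapping and annotate each interaction with the **union** of
scaffold atoms across isomorphisms: a contact on one valine methyl is
recorded on both. This convention is what the occupancy statistics and the
hashed fingerprint features consume, and it makes assignment idempotent and
order-independent.

## Occupancy and frequency statistics

Occupancy counts *structures*, not records: an aaRS's profile entry for
(atom, type) is the fraction of its complexes showing that contact at least
once, and entries below the cutoff (default 0.1) are neglected — an entry
observed in exactly 10% of structures is retained, since only strictly
lower occupancies are "below" the cutoff. Class-level frequency tables
count *records* over the five interaction types observed in amino-acid
binding (hydrogen bond, hydrophobic, salt bridge, pi-stacking, metal
complex). Water bridges are parsed but excluded by default: many deposited
structures lack ordered water, and counting water-mediated contacts only
where waters happen to be resolved would bias comparisons. Pi-cation
contacts, never observed in these binding sites, are likewise excluded
from the five-type tables. Percentages are rounded half-up to two decimals;
printed tables of this kind mix rounding and truncation, so we fix one
rule and document it.

The Mann-Whitney U test is implemented in-package because the contract
differs from `stats::wilcox.test`: for pooled sizes up to 16 the two-sided
p-value comes from exhaustive enumeration of all group assignments, which
remains exact under ties, and larger samples use the tie-corrected normal
approximation without continuity correction. `wilcox.test` is used as an
independent cross-check on tie-free cases in the test suite. Pearson and
Spearman correlations delegate to `stats::cor.test`.

## Fingerprint design

Each complex becomes a binary vector with up to four segments:

* **Seq (20 bits)** — occurrence of residue types among interacting
  binding-site residues, multiplicity ignored; nonstandard residues map to
  their parent standard residue, unknowns never set a bit.
* **Int (500 bits)** — one feature per (interaction type, ligand group,
  residue type), where the ligand group is the element symbol of the
  assigned scaffold atom (one feature per atom of the union assignment) and
  pi-stacking contributes a single `ring` group. The canonical lower-case
  feature string is hashed with FNV-1a (32-bit) modulo 500. Any stable hash
  would do; absolute bit indices are implementation-specific, distances are
  not. A diagnostic enumerates the chemically realizable feature vocabulary
  (76 features: hydrophobic contacts need a side-chain carbon partner, salt
  bridges a charged residue, pi-stacking an aromatic one, metal complexes
  coordinate O/N/S via zinc) and reports the collision rate
  (features without a dedicated bit), 6.6% at 500 bits.
* **Ed (22 bits)** — one bit per ligand the aaRS edits against, in the
  fixed alphabetical ligand order. The bundled default table approximates
  the editing literature restricted to the 22-ligand vocabulary and is
  deliberately configuration, not code: the authoritative per-aaRS editing
  sets are not fully published, and two aaRSs whose editing targets fall
  outside the vocabulary (MetRS, LysRS) are omitted by default.
* **Vol (12 bits)** — one-hot cavity volume over half-open 20 Å³ bins from
  30 to 270 Å³ (45 Å³ → bin 1, 52 Å³ → bin 2); out-of-range volumes clamp
  to the boundary bins rather than erroring, since a 280 Å³ cavity is
  large, not invalid.

The full design concatenates Int + Ed + Vol = 534 bits; the "Seq, Int"
designs use the 500-bit hashed segment (whose features already encode
residue types), while Seq_sim is the standalone 20-bit composition vector.
Both reaction states are fingerprinted identically; state is metadata.

Dissimilarity is the Jaccard distance on active bits. Two all-zero
fingerprints get distance 0: observations that activate nothing are
indistinguishable.

## Recognition space and silhouettes

The pairwise Jaccard matrix is embedded in two dimensions. The default
backend implements the UMAP algorithm on precomputed distances: a fuzzy
k-nearest-neighbour graph (bandwidths calibrated by bisection so each
point's total membership is log2(k), connectivity anchored at the nearest
neighbour, probabilistic-union symmetrization), principal-coordinate
initialization, and negative-sampling SGD on the fuzzy-set cross-entropy
with the low-dimensional kernel 1/(1 + a d^(2b)) fitted from `min_dist`.
Defaults follow the reference parameters (n_neighbors = 60, min_dist = 0.1,
two components). The backend contract — distance matrix in, coordinates
out, seed-deterministic — is pluggable; a classical MDS backend is included
for fully deterministic global-structure views, with the caveat that MDS
collapses many mutually equidistant clusters and therefore understates
cluster separation.

Design quality is scored by the mean silhouette of the aaRS labels,
computed on the embedded coordinates (the score quantifies the embedding);
a precomputed-Jaccard mode is provided because the fingerprint-space
silhouette is the model-free alternative. Singleton clusters and
zero-distance ties score 0. Whether to average silhouettes over several
embedding seeds is left to the caller: `compare_designs()` takes a seed
vector and reports per-seed values and dispersion rather than hiding the
choice.

## The synthetic generator

Real aaRS complex sets require structure downloads plus external
interaction and cavity annotation, so the package ships a generator whose
defaults emulate the statistical structure such a dataset exhibits:

* per-aaRS interaction templates (declarative JSON, user-replaceable), each
  entry an (atom set, type, occupancy probability, residue distribution,
  residue number) realized independently per complex. Backbone-amine
  hydrogen bonds are high-probability in both classes (0.85/0.92,
  mirroring the observed 83.16%/92.15% conservation); carboxyl-oxygen
  hydrogen bonds and salt bridges sit at the observed class rates; Class I
  templates carry the hydrophobic contact networks of the
  aliphatic/aromatic handlers so hydrophobic is the modal Class I type
  while hydrogen bonds dominate Class II; pi-stacking appears only for
  PheRS/TyrRS/TrpRS and zinc complexes for CysRS/ThrRS/SerRS.
* at most one template entry per (automorphism orbit, type), so the union
  assignment leaves each atom's expected occupancy equal to its entry
  probability — this is what makes parameter-recovery tests exact.
* cavity volumes from class-dependent truncated normals
  (Class I 143.40 ± 39.62 Å³, Class II 90.36 ± 32.09 Å³, rejection-sampled
  above a 10 Å³ physical floor).
* a 0.05-per-complex rate of spurious uniform (atom, type, residue)
  contacts, exercising the occupancy cutoff.
* a pre-/post-activation mix of 240:184; post-activation ligands carry a
  truncated adenylate stub so the matcher has real non-substructure atoms
  to reject.

What the generator does **not** emulate: real residue-number conservation
across organisms, crystallographic artifacts, correlated interactions,
editing-set diversity, or 3-D geometry (only a toy torsion ligand is
provided for dihedral validation). Passing tests on synthetic data
therefore demonstrate algorithmic correctness and the qualitative behaviour
of the statistics, not biological conclusions. One visible consequence:
with only eight distinct editing profiles among 22 aaRSs, the editing-only
fingerprint design scores a *positive* silhouette on synthetic data,
whereas on the real dataset — with its richer editing structure — that
baseline is reported negative.

## Numerical choices and degenerate inputs

* Exact occupancy cutoff semantics: `>= cutoff` retained.
* Percentages: round half away from zero, two decimals.
* Jaccard of two empty fingerprints: 0.
* Silhouette singletons and all-zero distances: 0.
* Volume bins: half-open, clamped at both ends.
* Dihedrals: IUPAC sign convention via the atan2 cross-product formula;
  coincident or collinear defining points are errors, not NaNs.
* Alignment identity: identical aligned positions over the full alignment
  length including gap columns (configurable to shorter-sequence length);
  gap penalties default to open 10 / extend 0.5 with BLOSUM62, a common
  pairing left configurable because no single convention is universal.
* Matcher determinism: lexicographic result order; candidate pruning by
  element and degree only, so correctness never depends on heuristics.
* Problem sizes used in the shipped checks: 200 random graphs for the
  matcher oracle, 30-point instances for the silhouette oracle, 200
  complexes per aaRS for parameter recovery, 20 per aaRS across five seeds
  for the design comparison. These sizes give stable statistics at
  desk-scale run times.

## Known limitations

* The editing table is an approximation and should be replaced for real
  analyses.
* The exact atom quadruple behind reported ligand-orientation torsions is
  not specified there; the default (O5'-equivalent, PA, bridge ester O,
  carbonyl C) is configurable, and recovered values on real data should be
  compared as signs and separations rather than absolute angles.
* mmCIF coordinate input is not supported (PDB and plain tables are).
* The embedding is an in-package implementation of the UMAP algorithm
  class; coordinates will not numerically match any specific external UMAP
  release, which is why all scoring is comparative (silhouettes, orderings)
  rather than coordinate-based.
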