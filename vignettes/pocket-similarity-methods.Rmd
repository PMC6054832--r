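---
title: "Pocket similarity from ligand contact profiles: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket similarity from ligand contact profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketmap)
```

## Scope and model

`pocketmap` organizes a protein family pharmacologically: instead of
asking "how similar are these sequences overall?", it asks "how similar
are the residues that ligands actually contact?". The package was built
with SET-domain lysine methyltransferases in mind — a family where the
cofactor (SAM/SAH) pocket and the substrate-peptide groove are analyzed
separately — but nothing in the code is family-specific. The inputs are
(i) protein–ligand complexes as single-chain PDB files, pre-superposed
upstream, (ii) a master multiple sequence alignment of the catalytic
domains, and (iii) a manifest tying each complex to a target name, a
site label and an alignment row.

Two complementary descriptions of ligand recognition are computed.

**Soft contact profiles.** Each heavy ligand/protein atom pair at
distance $d$ contributes a contact strength $w(d)$ that is 1 up to
3.23 Å, 0 from 4.63 Å, and linear in between. Strengths are summed per
residue over *all* pairs — backbone and side chain alike, because in
many pockets backbone carbonyls are the dominant anchors (the
"total contact strength" convention). Residue weights are keyed by
alignment column, and the complexes of one target are aggregated
column-wise.

**Explicit interaction fingerprints.** Independently, discrete
interactions are detected per residue and typed as HBD (ligand donates a
hydrogen bond), HBA (ligand accepts), IONIC, ARENE and SURFACE, and
encoded as one bit per (column, type) — at most one bit regardless of
how many atom pairs qualify and of backbone/side-chain identity.
Fingerprints are compared with Tanimoto coefficients and clustered with
average linkage.

**Profile-weighted sequence comparison.** Residue exchangeability is the
Gonnet (1992) matrix $M$ in normalized form,
$S(a,b) = M(a,b)/\sqrt{M(a,a)\,M(b,b)}$, so $S(a,a)=1$ and, on the
shipped table, $S(a,b) \le 1$ (asserted at load). For a profile $L$ the
similarity of rows $s_1, s_2$ is
$\sum_c w_L(c)\, S(s_1[c], s_2[c])$, with gap columns contributing 0
(contact residues falling into alignment gaps simply cannot be
propagated). Per profile the pairwise matrix is Z-standardized, the
Z-matrices are averaged with equal weight, the average is min–max
normalized to $[0,1]$, and $1 - \text{score}$ feeds UPGMA.

A note on the normalization formula: the formulation this method
descends from is sometimes printed in a degenerate self-normalized form
(the numerator normalized by itself, which collapses to ±1). We
implement the evident intent — normalization by the geometric mean of
the diagonal entries — which is the standard way to turn a log-odds
matrix into a per-residue similarity with unit self-similarity.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| contact ramp plateau | 3.23 | Å | full-strength contact boundary of the soft ramp |
| contact ramp cutoff | 4.63 | Å | beyond this, atoms are not in contact |
| H-bond distance | 3.5 | Å | donor-heavy to acceptor-heavy, standard literature cutoff |
| H-bond angle proxy | 100 | degrees | acceptor–donor–antecedent, heavy atoms only |
| ionic distance | 4.0 | Å | cation–anion heavy-atom cutoff |
| arene distance | 4.5 | Å | ring-centroid to ring-centroid, attraction only |
| surface distance | 4.5 | Å | unclassified heavy-atom contact |
| ensemble mode | max | — | per-column max across a target's complexes removes redundancy between near-identical structures; `mean` available |
| profile rescale | TRUE | — | max weight set to 1 so targets with many vs few complexes are comparable |
| mapping identity floor | 0.60 | — | guards against assigning a structure to the wrong alignment row |
| alignment gap penalties | open 10, extend 0.5 | matrix units | affine gaps for the structure-to-row alignment |

The interaction-detection criteria replace a proprietary contact-energy
model with plain geometric rules; they are configurable
(`plif_config()`) and echoed into the run metadata so any result can be
reproduced from its audit block. Two conventions worth knowing: a donor
with no bonded heavy neighbour passes the angle proxy by definition
(relevant for single-atom probes), and ARENE is a pure
centroid-distance test with no ring-orientation term.

## Numerical conventions

* **Populations.** Z-scores and the min–max normalization use the
  off-diagonal upper triangle only. Self-pairs would inflate the mean
  and the maximum — a self-pair's raw score is provably the row maximum,
  since weights are non-negative and $S(a,a) = 1 \ge S(a,b)$. The
  normalized diagonal is *set* to 1 by convention for heat maps;
  clustering consumes off-diagonal distances only.
* **Degeneracy.** A profile whose raw matrix is constant over all pairs
  (e.g. fewer than 3 sequences, or identical sequences) has no spread to
  standardize; this is an error, never silently NaN.
* **UPGMA.** Arithmetic-mean linkage with the Lance–Williams update;
  cluster height is merge distance / 2, so cophenetic distances on
  ultrametric input reproduce the input exactly. Ties are broken
  lexicographically on the sorted leaf-name tuples of the candidate
  pair, making merge order platform-independent. Newick children are
  ordered by the same keys.
* **Altlocs.** Highest occupancy wins; ties break by altloc label.
  Hydrogens and waters are always discarded; all criteria are defined on
  heavy atoms.
* **Reporting.** Neighbor similarities are reported at full precision
  plus a 2-decimal column, the family's customary display precision.

## What the synthetic generator emulates — and what it does not

`make_toy_complex()` builds complexes in which each ligand atom sits at
a *prescribed* distance from one anchor atom and is rejection-sampled to
be isolated (beyond the contact cutoff) from every other protein atom,
so the expected contact vector follows analytically from the prescribed
distances and the expected fingerprint from the prescribed roles. One
deliberate deviation from free placement on a sphere: directions are
axis-aligned, because PDB files carry 3-decimal coordinates and an
arbitrary direction would corrupt the prescribed distance by up to
~2 mÅ in the round-trip — enough to break the 1e-9 agreement between
analytic expectation and pipeline output that the tests demand.

`make_planted_alignment()` plants neighbor pairs that are identical at
designated "binding-site" columns and mutated elsewhere at a background
rate (default 0.8, i.e. barely any off-site signal), with all other
sequences uniformly random. This reproduces the statistical structure
the method exploits — conservation concentrated at contact columns — at
a default difficulty (10 sequences, 120 columns, 20 site columns) where
recovery is expected but not trivial.

What the generator does *not* emulate: realistic protein geometry,
rotamers, correlated substitution processes, alignment gaps in the
generated alignments, cofactor chemistry, or the curation judgments
involved in preparing real crystal structures. A green test therefore
establishes algorithmic correctness (each operation equals its
independent oracle, invariants hold, planted signal is recovered), not
that the pipeline reproduces any published family map; reproducing one
would require the original curated complexes and alignment, which are
external downloads prepared with proprietary tools.

## Design choices that were genuinely open

* *Ensemble semantics.* Aggregation across a target's complexes is not
  standardized anywhere; per-column **max** was chosen because it is
  idempotent and order-independent — adding a duplicate complex changes
  nothing, which is exactly "avoiding redundancy". `mean` is a flag.
* *Profile weighting in the average.* Profiles enter the Z-score
  average with equal weight regardless of how many complexes produced
  them; the per-profile Z-standardization already removes scale.
* *Summary denominators.* Interaction percentages are per complex by
  default, with a per-target grouping option, since either reading of a
  "fraction of ligands interacting" is defensible.
* *Config format.* JSON rather than YAML, to stay within the
  pre-installed dependency set (`jsonlite`).
* *Structure-to-row alignment.* Backed by `Biostrings::pairwiseAlignment`
  (global-local, Gonnet scoring) rather than re-implemented; the module's
  contract (column mapping, identity floor, injectivity) is what is
  tested.

## Known limitations

* Water-mediated contacts are not modeled, explicit hydrogens are never
  used, and the H-bond angle criterion is a heavy-atom proxy.
* PDB only (fixed-column ATOM/HETATM); no mmCIF, no superposition
  engine — complexes must arrive in a common frame, and
  `ligand_rmsd_matrix()` measures, in that frame, how well they agree.
* The interaction typing is template/heuristic-driven; exotic ligand
  chemistry (boron clusters, metals) falls back to a warning and an
  untyped atom.
* Similarity scales are population-relative: scores from different
  sequence sets or sites are not directly comparable, by construction
  of the Z-score/min–max cascade.
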