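---
title: "Intrinsic dynamics and sequence evolution of the Hsp70 ATPase domain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic dynamics and sequence evolution of the Hsp70 ATPase domain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaperonemodes)
```

## The scientific problem

Hsp70 chaperones hydrolyse ATP in a two-lobed ATPase (nucleotide-binding)
domain whose subdomains IA/IB (lobe I) and IIA/IIB (lobe II) close around
the nucleotide. Nucleotide exchange factors (NEFs) — GrpE, BAG-1, HspBP1,
Hsp110/Sse1 — bind this domain, stabilize an *open* conformer, and thereby
accelerate ADP release. Two complementary questions drive the analyses in
this package:

1. **Dynamics.** Is the closed-to-open transition *induced* by NEF binding,
   or is it *pre-existing* — encoded in the softest normal modes of the
   unbound domain? This is answered by comparing elastic-network-model
   modes with the experimentally observed deformation between crystal
   structures.
2. **Evolution.** How are the NEF-recognition surface (variable,
   co-evolving) and the nucleotide-binding site (conserved, mechanically
   constrained) written into the sequence record of the family? This is
   answered by Evolutionary Trace conservation ranking and
   mutual-information co-evolution maps over a refined family alignment.

The package implements every stage — structure I/O, elastic networks, MSA
refinement, Evolutionary Trace, mutual information, interface analysis,
and their integration — plus synthetic-data generators that let every stage
be validated against planted ground truth without any downloads.

## Elastic network models

A structure is reduced to its Cα trace. The **GNM** places unit springs
between residues within a cutoff (default 7.3 Å) and decomposes the
resulting Kirchhoff (graph Laplacian) matrix Γ; one zero mode is
discarded. The **ANM** builds the 3N×3N Hessian with super-elements
−γ/|r_ij|² · r_ij r_ijᵀ at a wider cutoff (default 13.0 Å); six zero modes
(rigid-body motions) are discarded, leaving 3N−6 internal modes. The
cutoffs are the conventional values from the founding method
publications; published Hsp70 overlap values do not pin down the cutoff
convention behind them, which is why the reproduction tolerances on
overlap values are generous (±0.08). The spring constant γ = 1 throughout: mobilities are normalized
and overlaps are cosines, so both are γ-invariant.

**Mobility profile.** Over the m softest modes (default m = 10),

  M_i = Σ_k λ_k⁻¹ [u⁽ᵏ⁾]_i² / Σ_k λ_k⁻¹,

with the three Cartesian components of a residue summed for the ANM, and
the profile normalized so Σ_i M_i = 1 (the area under every profile is 1,
making bound and unbound structures comparable).

**Mode–deformation overlap.** The deformation vector **d** concatenates
the per-residue Cα displacements between two conformers after Kabsch
superposition over their mapped common residues (so rigid-body motion is
removed). The overlap of mode k is the correlation cosine
|v⁽ᵏ⁾·d|/|d|, and the cumulative overlap
CO(m) = √(Σ_{k≤m} (v⁽ᵏ⁾·d/|d|)²) is nondecreasing and reaches 1 over all
modes. When the model is built on a larger structure than the deformation
covers, the eigenvector components are *restricted to the mapped residues
and not renormalized*: this keeps the dimensions consistent while
preserving the property that CO can only reach 1 if the deformation truly
lies in the subspace the modes span on those residues.

**Numerical choices.** Eigenvalues below 1e-8 × max(λ) are treated as
zero; a wrong zero-mode count is an error, not a warning (it signals a
disconnected network or degenerate geometry, both reported). Degenerate
soft eigenvalue pairs are kept in solver order with a warning; overlap for
such pairs is meaningful only jointly, via `cumulative_overlap` over the
pair.

## Structure handling

PDB files are parsed by fixed columns; HETATM records are kept and
flagged so bound nucleotides remain inspectable. Alternate locations keep
the highest-occupancy altloc (ties prefer `"A"`). Residues between two
structures are paired by global alignment of their one-letter sequences
(match +1, mismatch −1, gap −2) rather than by author numbering, because
bound and unbound crystals differ in resolved residues. Superposition
uses all mapped Cα atoms by default; a subdomain subset can be passed to
`kabsch_superpose` directly when a core-based fit is wanted. All reports
use the author numbering of the unbound structure as the canonical
coordinate system.

## MSA refinement

The three-step refinement distils a raw family alignment to the columns
of a reference-domain consensus: (i) every sequence is screened by
Smith–Waterman alignment (BLOSUM62, gap open 11 / extend 1 — the scoring
scheme is a configurable default; the published screen characterizes
its score cut only through this identity equivalent) against the consensus
and dropped below 40 % identity; (ii) insertion columns relative to the
consensus are deleted; (iii) sequences with more than 10 gaps are
removed. Identity is, by default, identical positions over the local
alignment length including internal gaps; because a local alignment of a
garbage sequence can be short and trivially identical, the
`identity_on = "target"` alternative (identity over the full consensus
length) is available and is what the binomial-survival property test
uses. Insertion columns are defined by the alignment's own gapped
majority row (gap counted as a symbol); a pre-gapped consensus row can be
supplied instead. The refinement is idempotent, and its per-step counts
are always reported.

## Evolutionary Trace

The family tree is built by UPGMA on p-distances (mismatch fraction over
shared non-gap columns). Published Hsp70 traces were built with an
external tree server whose construction is not fully reproducible; UPGMA
on p-distance is this package's explicit reimplementation choice, with
neighbor-joining (midpoint-rooted) as an alternative. Cutting the tree at
level ℓ yields exactly ℓ classes. A class is *conserved* at a column if
at least 90 % of its non-gap members share a symbol — the relaxation
that makes ET applicable to >1000-sequence families — with two guards:
gaps are excluded from the denominator, but a class with under 50 %
non-gap rows at a column is not conserved there (otherwise nearly-all-gap
classes would be vacuously conserved), and singleton classes are
vacuously conserved (the original ET convention). The ET rank of a column
is the smallest level at which every class is conserved; columns that
never make it within L levels (default 20) get rank L+1. Raising the
threshold to 100 % can only increase ranks, a property the suite asserts.

## Mutual information

Each column is a random variable over 21 symbols — the 20 amino acids
*plus the gap*. MI uses plug-in probabilities with no pseudocounts and no
sequence weighting (deliberately: this flavour of MI is meant to contrast
with weighted alternatives such as SCA, and it retains
phylogenetic correlations rather than applying APC-style corrections).
Natural-log units are the default; the published cutoff values (average
MI > 0.32, top pairs above ~0.8) are treated as configuration values, not
constants, because their log base is not stated. A Miller–Madow
small-sample correction is available behind a flag, off by default. Top
co-evolving pairs exclude neighbours with |i−j| ≤ 2 and report
floor(f·N(N−1)/2) pairs in fraction mode (f = 1 % of a 380-column
alignment is 720 pairs).

## Interface analysis

Contacts are heavy-atom pairs across two chain groups closer than 4 Å
(strict). SASA is Shrake–Rupley with 960 Fibonacci-lattice sphere points,
probe 1.4 Å, radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å; unknown elements
fall back to 1.70 Å with a warning. Exact agreement with any particular
SASA implementation is *not* a contract — the tested contracts are the
analytic sphere limits, monotone burial, and the sign of ΔSASA. ΔSASA is
bound minus apo (apo = the target chains in isolation), and only
ΔSASA < 0 residues are reported. Salt bridges require a side-chain
nitrogen of Lys/Arg/His against a side-chain carboxylate oxygen of
Asp/Glu across the interface within the same 4 Å convention.

One geometric caveat the test fixtures honour: a residue between 4 and
6.2 Å ( = 2(r_C + r_probe)) of a partner atom can lose surface without
being a 4 Å contact, so "ΔSASA < 0 implies contact" is an empirical
property of packed interfaces, not a theorem; fixtures asserting the
subset property keep non-contact residues beyond the burial range.

## The synthetic world

**Hinge protein.** Two compact lobes (beads on a 3.8 Å grid — the Cα
virtual bond length — filling a sphere) joined by a narrow three-bead-wide
ribbon in the x–z plane. The ribbon geometry is deliberate: a hinge with
z-extent but no y-extent makes in-plane bending (rotation about z) the
softest direction, separating it from the otherwise nearly degenerate
out-of-plane bending and torsion. The open conformer rotates one lobe by
20° about the hinge; 0.3 Å Gaussian jitter roughens both forms. The gap
between each lobe surface and the hinge (7 Å) keeps the lobes out of
direct contact at the 13 Å ANM cutoff while the chain stays connected at
the 7.3 Å GNM cutoff. On this fixture the softest ANM mode of the closed
form overlaps the planted open-close deformation at >0.95 — the
pre-existing-path picture in its cleanest form.

**Simulated family.** Four clades, 200 sequences, 100 columns by default.
A random root evolves down a balanced binary tree per clade with a
per-branch, per-site substitution probability of 0.03, uniform over the
19 alternatives — exchangeability realism is irrelevant because every
downstream statistic depends only on column patterns. Planted structure:
five never-substituting conserved columns; three trace columns set to a
clade-specific symbol on the founding branch and frozen after; five
co-evolving pairs whose substitution events reset both columns through a
fixed random bijection with probability 0.9 (and one side alone
otherwise) at three times the background rate — recognition surfaces
evolve faster than the average site. Clade-founding branches are five
ordinary branches long: subfamilies must diverge from each other more
than they diversify internally, or no distance tree can recover them as
classes (without this, the trace-column recovery property is unattainable
in principle, not just in practice). Gaps are injected per cell at 1 %.

**What a green test does and does not establish.** The generators emulate
column-pattern statistics and hinge kinematics, not real proteins: no
rate heterogeneity, no indel process, no side chains, no realistic
contact topology. Green recovery tests establish that the estimators
identify the structure they are defined to identify at desk-scale sample
sizes; they say nothing about database-scale alignments or about
structures whose softest modes do not align with their functional
transition.

## Reproduction of published numbers

The quantitative endpoints tied to the real system — single-mode overlap
0.62 at mode 3 and CO(6) = 0.86 for the closed-to-open transition against
the BAG-1-bound form, CO(9) = 0.82 against the Sse1-bound form, reverse
overlaps 0.88/0.92, interlobe marker distances 5.0 → 10.9/19.0 Å — require
downloading three PDB entries and are therefore in the optional
`scripts/reproduction.R` job (±0.08 on overlaps, ±0.2 Å on distances),
not in the offline test suite. The database-dependent endpoints (the
1627×380 refined alignment itself, the rank-1 uniqueness of the key
catalytic glycine, the 0.92 mobility-conservation fit correlation) are
checked qualitatively there only; they are not reproducible from a fixed
desk-scale input and the suite does not pretend otherwise.

## Known limitations

* mmCIF, biological assemblies and hydrogens are out of scope; PDB
  fixed-column only (gzip accepted).
* The ET tree is a reimplementation choice; ranks on real data are
  expected to agree qualitatively with server-based traces, not
  identically.
* MI log-base and threshold conventions follow the defaults above;
  published cutoff values should be re-derived per alignment.
* Dense eigendecomposition bounds practical problem sizes at a few
  thousand residues — ample for single domains and their complexes.
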